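#' Configuration for a synthetic multi-echo phantom
#'
#' Describes a 3D digital phantom emulating a breath-hold multi-echo
#' gradient-echo (MEGE) acquisition: an ellipsoidal "placenta" embedded in
#' a voxel grid, a smoothly modulated T2* field at lobule spatial scale,
#' mono-exponential signal decay over the six echo times, and optional
#' additive Gaussian noise. Optionally a set of voxels can be assigned a
#' long T2* (>= 250 ms) to mimic amniotic-fluid contamination, which the
#' mapping stage must exclude.
#'
#' Defaults follow the acquisition the package emulates: echo times 4.92,
#' 9.84, 19.68, 29.52, 36.90, 49.20 ms and voxel size 1.75 x 1.75 x 3.5 mm.
#'
#' @param grid_shape Integer vector of 3 voxel counts (x, y, z).
#' @param voxel_dims_mm Voxel edge lengths, mm.
#' @param echo_times_ms Strictly increasing positive echo times.
#' @param center Ellipsoid center in voxel coordinates (default grid
#'   center).
#' @param semi_axes Ellipsoid semi-axes in voxels.
#' @param t2star_base_ms Base T2* of the placental field, ms.
#' @param modulation_amplitude Fractional amplitude (< 1) of the smooth
#'   lobule-scale modulation of the T2* field; 0 gives a uniform field.
#' @param modulation_period_mm Spatial period of the modulation, mm
#'   (default 15 mm, the scale of placental lobules).
#' @param s0 Proton-density signal scale at TE = 0.
#' @param noise_sd SD of additive Gaussian noise on the signal, same units
#'   as `s0`; must be >= 0.
#' @param amniotic_voxels Optional integer matrix (n x 3) of voxel
#'   coordinates assigned `amniotic_t2star_ms`.
#' @param amniotic_t2star_ms T2* given to those voxels (default 300 ms).
#' @param seed Integer seed.
#' @return An object of class `pn_phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 12L),
                           voxel_dims_mm = c(1.75, 1.75, 3.5),
                           echo_times_ms = c(4.92, 9.84, 19.68, 29.52,
                                             36.90, 49.20),
                           center = NULL,
                           semi_axes = c(16, 16, 4),
                           t2star_base_ms = 50,
                           modulation_amplitude = 0.2,
                           modulation_period_mm = 15,
                           s0 = 100,
                           noise_sd = 0,
                           amniotic_voxels = NULL,
                           amniotic_t2star_ms = 300,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(voxel_dims_mm) == 3L, all(voxel_dims_mm > 0))
  if (any(echo_times_ms <= 0) || any(diff(echo_times_ms) <= 0)) {
    stop("echo times must be positive and strictly increasing")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (t2star_base_ms <= 0) stop("t2star_base_ms must be > 0")
  if (modulation_amplitude < 0 || modulation_amplitude >= 1) {
    stop("modulation_amplitude must be in [0, 1)")
  }
  if (is.null(center)) center <- (grid_shape + 1) / 2
  if (any(center - semi_axes < 1) || any(center + semi_axes > grid_shape)) {
    stop("ellipsoid exceeds the voxel grid")
  }
  if (!is.null(amniotic_voxels)) {
    amniotic_voxels <- matrix(as.integer(amniotic_voxels), ncol = 3L)
    if (any(amniotic_voxels < 1L) ||
        any(sweep(amniotic_voxels, 2L, grid_shape, `>`))) {
      stop("amniotic_voxels outside the grid")
    }
    if (amniotic_t2star_ms < 250) {
      stop("amniotic_t2star_ms must be >= 250 ms")
    }
  }
  structure(list(grid_shape = grid_shape, voxel_dims_mm = voxel_dims_mm,
                 echo_times_ms = echo_times_ms, center = center,
                 semi_axes = semi_axes, t2star_base_ms = t2star_base_ms,
                 modulation_amplitude = modulation_amplitude,
                 modulation_period_mm = modulation_period_mm, s0 = s0,
                 noise_sd = noise_sd, amniotic_voxels = amniotic_voxels,
                 amniotic_t2star_ms = amniotic_t2star_ms,
                 seed = as.integer(seed)),
            class = "pn_phantom_config")
}

#' Simulate a multi-echo phantom acquisition
#'
#' Builds the ground-truth T2* field (base value times a smooth sinusoidal
#' modulation with seeded random phases, emulating lobule-scale contrast),
#' an ellipsoidal binary placental mask, and the 4D signal array
#' `S(v, e) = s0 * exp(-TE_e / T2*(v)) + noise`. The ground-truth map is
#' returned so recovery of the mapping stage can be tested voxel by voxel.
#'
#' @param config A [phantom_config()].
#' @return List of class `pn_phantom`: `signal` (4D array x,y,z,echo),
#'   `mask` (3D logical), `truth` (3D ground-truth T2*, ms),
#'   `echo_times_ms`, `voxel_dims_mm`, `missing_slices` (empty by
#'   default).
#' @examples
#' ph <- simulate_multiecho_phantom(phantom_config(grid_shape = c(16, 16, 6),
#'                                                 semi_axes = c(5, 5, 2)))
#' sum(ph$mask)
#' @export
simulate_multiecho_phantom <- function(config) {
  stopifnot(inherits(config, "pn_phantom_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(config$seed)
  dims <- config$grid_shape
  x <- seq_len(dims[1L]); y <- seq_len(dims[2L]); z <- seq_len(dims[3L])
  # normalized squared distances to the ellipsoid center
  dx2 <- ((x - config$center[1L]) / config$semi_axes[1L])^2
  dy2 <- ((y - config$center[2L]) / config$semi_axes[2L])^2
  dz2 <- ((z - config$center[3L]) / config$semi_axes[3L])^2
  dist2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  mask <- dist2 <= 1

  phase <- stats::runif(3, 0, 2 * pi)
  kx <- 2 * pi * config$voxel_dims_mm[1L] / config$modulation_period_mm
  ky <- 2 * pi * config$voxel_dims_mm[2L] / config$modulation_period_mm
  kz <- 2 * pi * config$voxel_dims_mm[3L] / config$modulation_period_mm
  modx <- sin(kx * x + phase[1L])
  mody <- sin(ky * y + phase[2L])
  modz <- sin(kz * z + phase[3L])
  mod3 <- outer(outer(modx, mody, `*`), modz, `*`)
  truth <- config$t2star_base_ms * (1 + config$modulation_amplitude * mod3)
  if (!is.null(config$amniotic_voxels)) {
    truth[config$amniotic_voxels] <- config$amniotic_t2star_ms
  }

  ne <- length(config$echo_times_ms)
  signal <- array(0, c(dims, ne))
  for (e in seq_len(ne)) {
    signal[, , , e] <- config$s0 * exp(-config$echo_times_ms[e] / truth)
  }
  if (config$noise_sd > 0) {
    signal <- signal + stats::rnorm(length(signal), 0, config$noise_sd)
  }
  structure(list(signal = signal, mask = mask, truth = truth,
                 echo_times_ms = config$echo_times_ms,
                 voxel_dims_mm = config$voxel_dims_mm,
                 missing_slices = integer(0)),
            class = "pn_phantom")
}

#' Write / read a phantom as NIfTI-1
#'
#' Writes the 4D signal, 3D mask and 3D ground-truth T2* map as NIfTI-1
#' files (`signal.nii.gz`, `mask.nii.gz`, `truth.nii.gz`) plus a JSON
#' sidecar (`echoes.json`) carrying the echo times and voxel dimensions.
#'
#' @param phantom A `pn_phantom`.
#' @param dir Output directory (created if absent).
#' @return `read_phantom` returns a `pn_phantom`; `write_phantom` the
#'   directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "pn_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pd <- c(phantom$voxel_dims_mm, 1)
  RNifti::writeNifti(RNifti::asNifti(phantom$signal, pixdim = pd),
                     file.path(dir, "signal.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(phantom$mask),
                                           dim(phantom$mask)),
                                     pixdim = phantom$voxel_dims_mm),
                     file.path(dir, "mask.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$truth,
                                     pixdim = phantom$voxel_dims_mm),
                     file.path(dir, "truth.nii.gz"))
  jsonlite::write_json(list(echo_times_ms = phantom$echo_times_ms,
                            voxel_dims_mm = phantom$voxel_dims_mm,
                            missing_slices = phantom$missing_slices),
                       file.path(dir, "echoes.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "echoes.json"),
                              simplifyVector = TRUE)
  signal <- array(as.numeric(RNifti::readNifti(file.path(dir, "signal.nii.gz"))),
                  dim = dim(RNifti::readNifti(file.path(dir, "signal.nii.gz"))))
  mask_img <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  truth_img <- RNifti::readNifti(file.path(dir, "truth.nii.gz"))
  structure(list(signal = signal,
                 mask = array(as.numeric(mask_img) > 0.5, dim(mask_img)),
                 truth = array(as.numeric(truth_img), dim(truth_img)),
                 echo_times_ms = as.numeric(side$echo_times_ms),
                 voxel_dims_mm = as.numeric(side$voxel_dims_mm),
                 missing_slices = as.integer(side$missing_slices)),
            class = "pn_phantom")
}
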