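# Shared fixtures: published generative parameters and small oracles.

un_sigmoid <- c(-59.2, -0.24, 29.3, 84.6)  # UN median T2* trajectory
un_resid_sd <- 9.6                         # ms
un_rate_params <- c(-64.9, -0.20, 30.1)    # UN rate-of-change model
paper_te <- c(4.92, 9.84, 19.68, 29.52, 36.90, 49.20)  # ms
paper_voxel_mm <- c(1.75, 1.75, 3.5)

# n observations from the UN sigmoid with Gaussian residuals, GA ~ U(11, 38)
make_un_data <- function(n, seed, sd = un_resid_sd, params = un_sigmoid) {
  withr::with_seed(seed, {
    t <- runif(n, 11, 38)
    list(t = t, y = evaluate_model("sigmoid", params, t) + rnorm(n, 0, sd))
  })
}

# exhaustive pairwise concordance AUC (Mann-Whitney, ties counted 1/2),
# with the low-score-positive orientation used by roc_curve()
auc_pairwise <- function(score, is_adverse) {
  pos <- score[as.logical(is_adverse)]
  neg <- score[!as.logical(is_adverse)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p < q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# brute-force two-sample KS D: max ECDF gap over all observed points
ks_d_bruteforce <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# hand chi-square for a 2x2 table of (events, non-events) per group
chisq_by_hand <- function(a1, a2, b1, b2) {
  obs <- matrix(c(a1, a2, b1, b2), 2, byrow = TRUE)
  exp <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - exp)^2 / exp)
}
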