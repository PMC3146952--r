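# Shared fixtures and independent oracles used across test files.

# 6-row, 3-cluster toy regression dataset, small enough to verify by hand.
# The treatment varies within cluster so that no coefficient's clustered
# score sums are collinear (which would degenerate a robust SE to zero).
toy_cluster_data <- function() {
  tibble::tibble(
    cluster_id = c(1L, 1L, 2L, 2L, 3L, 3L),
    unit_id = c(1L, 2L, 1L, 2L, 1L, 2L),
    time = 1L,
    A = c(1L, 0L, 1L, 1L, 0L, 0L),
    y = c(0.3, 0.7, -0.2, 0.4, -0.9, -0.5)
  )
}

# Brute-force clustered sandwich for OLS: (X'X)^-1 (sum_g s_g s_g') (X'X)^-1
# times the G/(G-1) small-sample factor, built from raw matrix arithmetic
# so it is independent of the package's fitting path.
bruteforce_cluster_sandwich <- function(y, X, cluster) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- as.vector(y - X %*% beta)
  groups <- unique(cluster)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in groups) {
    idx <- cluster == g
    s_g <- t(X[idx, , drop = FALSE]) %*% resid[idx]
    meat <- meat + s_g %*% t(s_g)
  }
  g_n <- length(groups)
  vc <- XtX_inv %*% meat %*% XtX_inv * g_n / (g_n - 1)
  list(beta = as.vector(beta), vcov = vc)
}

# Brute-force two-sided KS statistic against Uniform(0,1): evaluate the
# step ECDF just before and at every sample point.
bruteforce_ks_d <- function(p) {
  n <- length(p)
  s <- sort(p)
  ecdf_at <- vapply(s, function(x) mean(p <= x), numeric(1))
  ecdf_before <- vapply(s, function(x) mean(p < x), numeric(1))
  max(abs(ecdf_at - s), abs(ecdf_before - s))
}

# Default null scenario at a modest size for unit tests (acceptance tests
# use the full study geometry).
small_null_scenario <- function(n_reps = 300, seed = 11,
                                clusters_per_arm = 20, units = 10,
                                sidedness = "two") {
  suppressWarnings(scenario(
    design_spec(clusters_per_arm = clusters_per_arm, units_per_cluster = units),
    continuous_params(mu = -0.875, beta1 = 0, sigma_g = 0.482, sigma_e = 1.297),
    analysis_spec("A", sidedness = sidedness),
    n_reps = n_reps, seed = seed
  ))
}
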