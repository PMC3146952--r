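make_crt_frame <- function(clusters_per_arm = 10, units = 10, seed = 1) {
  d <- design_spec(clusters_per_arm = clusters_per_arm, units_per_cluster = units)
  set.seed(seed)
  randomize(build_frame(d), d)
}

test_that("noise-free continuous model is exact arithmetic", {
  f <- make_crt_frame()
  out <- simulate_continuous(f, continuous_params(mu = -0.875, beta1 = 0.2,
                                                  sigma_g = 0, sigma_e = 0))
  expect_equal(unique(out$y[out$A == 1]), -0.675)
  expect_equal(unique(out$y[out$A == 0]), -0.875)
})

test_that("continuous model reproduces the closed-form total variance", {
  # var(y) = sigma_g^2 + sigma_e^2 when beta1 = 0, here 0.482^2 + 1.297^2
  d <- design_spec(clusters_per_arm = 50000, units_per_cluster = 10, arms = 2)
  set.seed(3)
  f <- randomize(build_frame(d), d)
  out <- simulate_continuous(f, continuous_params(-0.875, 0, 0.482, 1.297))
  expect_equal(nrow(out), 1e6)
  total_var <- 0.482^2 + 1.297^2
  expect_lt(abs(var(out$y) - total_var) / total_var, 0.01)
  # null symmetry: arm difference ~ 0 within 4 MC SEs of the difference
  diff <- mean(out$y[out$A == 1]) - mean(out$y[out$A == 0])
  # clustered SE of an arm mean: (sigma_g^2/c + sigma_e^2/(c n)) per arm
  se_diff <- sqrt(2 * (0.482^2 / 1e5 + 1.297^2 / 1e6))
  expect_lt(abs(diff), 4 * se_diff)
})

test_that("cluster random effects are shared within cluster", {
  # with sigma_e = 0 and beta = 0, within-cluster variance is exactly 0
  f <- make_crt_frame(clusters_per_arm = 5, units = 8)
  set.seed(8)
  out <- simulate_continuous(f, continuous_params(0, 0, sigma_g = 1, sigma_e = 0))
  wv <- tapply(out$y, out$cluster_id, var)
  expect_true(all(wv == 0))
  # and clusters do differ
  expect_gt(var(tapply(out$y, out$cluster_id, mean)), 0)
})

test_that("binary model matches link-inversion and integration oracles", {
  f <- make_crt_frame(clusters_per_arm = 5000, units = 10)
  # sigma_g = 0, mu = 0: prevalence 1/2
  set.seed(10)
  out <- simulate_binary(f, binary_params(mu = 0, beta1 = 0, sigma_g = 0))
  expect_true(all(out$y %in% c(0, 1)))
  se <- sqrt(0.25 / nrow(out))
  expect_lt(abs(mean(out$y) - 0.5), 4 * se)

  # sigma_g = 0, mu = logit(0.1): prevalence 0.1
  set.seed(11)
  out <- simulate_binary(f, binary_params(mu = qlogis(0.1), beta1 = 0, sigma_g = 0))
  expect_lt(abs(mean(out$y) - 0.1), 4 * sqrt(0.1 * 0.9 / nrow(out)))

  # sigma_g = 1, mu = 0: marginal prevalence = integral of expit vs N(0,1)
  marginal <- integrate(function(b) plogis(b) * dnorm(b), -Inf, Inf)$value
  expect_equal(marginal, 0.5, tolerance = 1e-6) # symmetry of expit around 0
  set.seed(12)
  out <- simulate_binary(f, binary_params(mu = 0, beta1 = 0, sigma_g = 1))
  # conservative SE: clustering inflates the binomial variance
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(out$y) - marginal), 4 * se)
})

test_that("factorial model is the exact noise-free sum of effects", {
  d <- design_spec(clusters_per_arm = 4, units_per_cluster = 10, timepoints = 2,
                   unit_treatments = "X", unit_allocation_fraction = 0.5)
  set.seed(5)
  f <- randomize(build_frame(d), d)
  out <- simulate_factorial(f, factorial_params(
    mu = -1.98, beta1 = 0.15, beta2 = 0.15, beta3 = 0.15,
    sigma_v = 0, sigma_c = 0, sigma_e = 0))
  expect_true(all(out$y[out$time == 0] == -1.98))
  both <- out$time == 1 & out$A == 1 & out$X == 1
  expect_true(any(both))
  expect_equal(unique(out$y[both]), -1.98 + 0.45)
  only_a <- out$time == 1 & out$A == 1 & out$X == 0
  expect_equal(unique(out$y[only_a]), -1.98 + 0.15)
})

test_that("within-child change has variance 2*sigma_e^2 under the null", {
  d <- design_spec(clusters_per_arm = 100, units_per_cluster = 20,
                   timepoints = 2, unit_treatments = "X")
  set.seed(6)
  f <- randomize(build_frame(d), d)
  out <- simulate_factorial(f, factorial_params(
    mu = -1.98, sigma_v = 0.297, sigma_c = 1.259, sigma_e = 1.079))
  wide <- tidyr::pivot_wider(out, id_cols = c("cluster_id", "unit_id"),
                             names_from = "time", values_from = "y")
  chg <- wide$`1` - wide$`0`
  # random effects cancel in the change score; chi-square CI scale check
  expect_lt(abs(var(chg) - 2 * 1.079^2) / (2 * 1.079^2),
            4 * sqrt(2 / length(chg)))
  # baseline arm means are equal up to MC error (pre-treatment)
  base <- out[out$time == 0, ]
  treated_cl <- unique(out$cluster_id[out$A == 1])
  in_a <- base$cluster_id %in% treated_cl
  d0 <- mean(base$y[in_a]) - mean(base$y[!in_a])
  se0 <- sqrt(2 * (0.297^2 / 100 + (1.259^2 + 1.079^2) / 2000))
  expect_lt(abs(d0), 4 * se0)
})

test_that("random components are uncorrelated by construction", {
  set.seed(13)
  n <- 1e5
  b <- rnorm(n, 0, 0.482)
  e <- rnorm(n, 0, 1.297)
  expect_lt(abs(cor(b, e)), 4 / sqrt(n))
})

test_that("dropout removes only follow-up rows at the declared rate", {
  d <- design_spec(clusters_per_arm = 500, units_per_cluster = 20,
                   timepoints = 2, unit_treatments = "X", dropout_rate = 0.1)
  set.seed(7)
  out <- simulate_factorial(randomize(build_frame(d), d), factorial_params(
    mu = 0, sigma_v = 0.3, sigma_c = 1, sigma_e = 1))
  n_children <- 20000

  expect_identical(apply_dropout(out, 0), out)

  set.seed(71)
  kept <- apply_dropout(out, 0.1)
  expect_equal(sum(kept$time == 0), n_children)
  n_follow <- sum(kept$time == 1)
  expect_lt(abs(n_follow - 0.9 * n_children),
            4 * sqrt(n_children * 0.1 * 0.9))

  set.seed(72)
  none <- apply_dropout(out, 1)
  expect_equal(sum(none$time == 1), 0)
  expect_equal(sum(none$time == 0), n_children)

  expect_error(apply_dropout(out, 1.2), "probability")
})

test_that("identical seeds give bit-identical outcome tables", {
  f <- make_crt_frame(clusters_per_arm = 10, units = 5)
  p <- continuous_params(-0.875, 0.2, 0.482, 1.297)
  set.seed(99); a <- simulate_continuous(f, p)
  set.seed(99); b <- simulate_continuous(f, p)
  expect_identical(a, b)
})
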