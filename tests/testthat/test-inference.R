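test_that("cluster-robust fit matches the brute-force matrix oracle", {
  toy <- toy_cluster_data()
  fit <- fit_cluster_robust(toy, analysis_spec("A"))
  X <- cbind(1, toy$A)
  oracle <- bruteforce_cluster_sandwich(toy$y, X, toy$cluster_id)
  expect_equal(unname(fit$coefficients), oracle$beta, tolerance = 1e-12)
  expect_equal(unname(fit$robust_se),
               sqrt(diag(oracle$vcov)), tolerance = 1e-12)
  # closed-form OLS slope on the toy: difference of arm means
  expect_equal(unname(fit$coefficients["A"]),
               mean(toy$y[toy$A == 1]) - mean(toy$y[toy$A == 0]))
})

test_that("clustered sandwich reduces to per-observation sandwich at size-1 clusters", {
  # random toys: one unit per cluster -> HC0 * n/(n-1)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    dat <- tibble::tibble(cluster_id = 1:n, unit_id = 1L, time = 1L,
                          A = rbinom(n, 1, 0.5), y = rnorm(n))
    fit <- fit_cluster_robust(dat, analysis_spec("A"))
    lmfit <- lm(y ~ A, data = dat)
    hc0 <- sandwich::vcovHC(lmfit, type = "HC0") * n / (n - 1)
    expect_equal(unname(fit$robust_se), unname(sqrt(diag(hc0))),
                 tolerance = 1e-10)
  }
})

test_that("coefficients are invariant to row shuffling and cluster relabeling", {
  set.seed(21)
  d <- design_spec(clusters_per_arm = 10, units_per_cluster = 5)
  dat <- simulate_continuous(randomize(build_frame(d), d),
                             continuous_params(-0.875, 0.3, 0.482, 1.297))
  fit1 <- fit_cluster_robust(dat, analysis_spec("A"))
  shuffled <- dat[sample(nrow(dat)), ]
  shuffled$cluster_id <- match(shuffled$cluster_id,
                               sample(unique(dat$cluster_id)))
  fit2 <- fit_cluster_robust(shuffled, analysis_spec("A"))
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
  expect_equal(fit1$robust_se, fit2$robust_se, tolerance = 1e-10)
})

test_that("perfect separation is flagged, not silently reported", {
  sep <- tibble::tibble(cluster_id = c(1L, 2L, 3L, 4L), unit_id = 1L,
                        time = 1L, A = c(0L, 0L, 1L, 1L),
                        y = c(0L, 0L, 1L, 1L))
  fit <- fit_cluster_robust(sep, analysis_spec("A", family = "logistic"))
  expect_false(fit$converged)
  expect_true(all(is.na(fit$p)))
  expect_error(wald_pvalue(fit, "A"), "non-converged")
})

test_that("fewer than two clusters is an error", {
  one <- tibble::tibble(cluster_id = 1L, unit_id = 1:4, time = 1L,
                        A = c(0L, 0L, 1L, 1L), y = rnorm(4))
  expect_error(fit_cluster_robust(one, analysis_spec("A")), "2 clusters")
})

test_that("wald_pvalue follows the normal reference and sidedness rules", {
  toy <- toy_cluster_data()
  fit <- fit_cluster_robust(toy, analysis_spec("A", df_reference = "normal"))
  # construct known z-values by direct injection
  fit$z["A"] <- 0
  expect_equal(wald_pvalue(fit, "A", "two"), 1)
  fit$z["A"] <- 1.959964
  expect_equal(wald_pvalue(fit, "A", "two"), 0.05, tolerance = 1e-6)
  # estimate in the hypothesized direction: one-sided = two-sided / 2
  fit$z["A"] <- 1.3
  expect_equal(wald_pvalue(fit, "A", "one"),
               wald_pvalue(fit, "A", "two") / 2)
})

test_that("t reference is more conservative than the normal at small G", {
  toy <- toy_cluster_data()
  fit_n <- fit_cluster_robust(toy, analysis_spec("A", df_reference = "normal"))
  fit_t <- fit_cluster_robust(toy, analysis_spec("A", df_reference = "t"))
  expect_gt(fit_t$p[["A"]], fit_n$p[["A"]])
})

test_that("tidy and glance return well-formed tibbles", {
  fit <- fit_cluster_robust(toy_cluster_data(), analysis_spec("A"))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$term, c("(Intercept)", "A"))
  expect_true(is.na(td$p.value[td$term == "(Intercept)"]))
  gl <- glance(fit)
  expect_equal(gl$n_clusters, 3)
  expect_true(gl$converged)
})

test_that("variance components recover two-level generating values", {
  # east-java geometry: 160 clusters, ~13 children each
  vc <- estimate_variance_components(
    generate_training_fixture(training_profile("east-java"), seed = 42))
  expect_lt(abs(vc$sigma[["cluster"]] - 0.482), 0.05)
  expect_lt(abs(vc$sigma[["residual"]] - 1.297), 0.05)
  expect_lt(abs(vc$mu - (-0.875)), 0.2)
  expect_named(tidy(vc), c("level", "sd"))
})

test_that("variance components recover three-level generating values", {
  train <- generate_training_fixture(training_profile("india-longitudinal"),
                                     seed = 42)
  vc <- suppressWarnings(
    estimate_variance_components(train, levels = "three_level"))
  expect_lt(abs(vc$sigma[["cluster"]] - 0.297) / 0.297, 0.30)
  expect_lt(abs(vc$sigma[["child"]] - 1.259) / 1.259, 0.15)
  expect_lt(abs(vc$sigma[["residual"]] - 1.079) / 1.079, 0.15)
})

test_that("identical cluster means yield a zero cluster component", {
  set.seed(30)
  flat <- tibble::tibble(cluster_id = rep(1:40, each = 20),
                         unit_id = rep(1:20, 40),
                         y = rnorm(800))
  # center within cluster so every cluster mean is exactly equal
  flat$y <- flat$y - stats::ave(flat$y, flat$cluster_id)
  vc <- suppressMessages(estimate_variance_components(flat))
  expect_lt(vc$sigma[["cluster"]], 1e-6)
})

test_that("missing replication at a level is a named error", {
  singleton <- tibble::tibble(cluster_id = 1:50, unit_id = 1L, y = rnorm(50))
  expect_error(estimate_variance_components(singleton), "cluster")
  one_measure <- generate_training_fixture(training_profile("east-java"),
                                           seed = 3)
  expect_error(estimate_variance_components(one_measure, levels = "three_level"),
               "child")
})

test_that("icc matches the defining ratio and its limits", {
  expect_equal(round(icc(0.482, 1.297), 2), 0.12)
  expect_equal(icc(0.7, 0), 1)
  expect_equal(icc(0, 2.3), 0)
  expect_error(icc(0, 0), "undefined")
})

test_that("icc is monotone in each SD", {
  grid <- expand.grid(sg = c(0.1, 0.5, 1, 2), se = c(0.1, 0.5, 1, 2))
  for (i in seq_len(nrow(grid))) {
    sg <- grid$sg[i]; se <- grid$se[i]
    expect_gt(icc(sg * 1.1, se), icc(sg, se))
    expect_lt(icc(sg, se * 1.1), icc(sg, se))
  }
})

test_that("training data reader validates and renames columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  train <- generate_training_fixture(training_profile("east-java"), seed = 5)
  utils::write.csv(
    data.frame(vil = train$cluster_id, kid = train$unit_id, haz = train$y),
    path, row.names = FALSE)
  got <- suppressMessages(read_training_data(
    path, cluster = "vil", unit = "kid", outcome = "haz", time = NULL))
  expect_named(got, c("cluster_id", "unit_id", "y"))
  expect_equal(got$y, train$y)
  expect_error(
    suppressMessages(read_training_data(path, cluster = "nope",
                                        outcome = "haz", time = NULL)),
    "nope")
})
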