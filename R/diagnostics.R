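#' Validate a simulation under the null hypothesis
#'
#' A simulation program should be audited before it is trusted: run it with
#' every treatment effect set to zero, and the fraction of replicates
#' declared significant must match the Type-I error rate — 5% at
#' `alpha = 0.05` for a two-sided test, and 10% for a one-sided test (the
#' one-sided p-value is half the two-sided one, so either tail can reject).
#' The p-values themselves should be uniform on `[0, 1]`: the report
#' includes a bootstrapped Kolmogorov-Smirnov uniformity test and a QQ
#' table of sorted p-values against uniform plotting positions
#' `(k - 0.5) / R`.
#'
#' @param scn A [scenario()] whose effect parameters are all zero. A
#'   non-null scenario is rejected with an error, guarding against
#'   accidentally "calibrating" under an alternative.
#' @param n_boot Bootstrap replicates for the KS test.
#' @return A `calibration_report` with elements `rejection_rate`, `mc_se`,
#'   `ks_D`, `ks_boot_p`, `qq` (tibble with `uniform` and `pvalue`
#'   columns), `n_reps`, `alpha`, `sidedness`, `seed`, and `note`
#'   (annotates binary-outcome runs, whose discrete p-values need not be
#'   exactly uniform). Supports [tidy()] and [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' d <- design_spec(clusters_per_arm = 25, units_per_cluster = 10)
#' p <- continuous_params(mu = -0.875, beta1 = 0,
#'                        sigma_g = 0.482, sigma_e = 1.297)
#' null_calibration(scenario(d, p, n_reps = 1000, seed = 3))
#' }
#' @export
null_calibration <- function(scn, n_boot = 1000) {
  stopifnot(inherits(scn, "scenario"))
  effects <- unlist(scn$params[effect_names(scn$params)])
  if (any(effects != 0)) {
    stop("null calibration requires all effect parameters to be zero; ",
         "non-zero: ",
         paste(names(effects)[effects != 0], collapse = ", "), call. = FALSE)
  }
  if (scn$n_reps < 1000) {
    warning("calibration with fewer than 1,000 replicates is unreliable",
            call. = FALSE)
  }
  est <- empirical_power(scn, keep_pvalues = TRUE)
  pmat <- attr(est, "pvalues")
  p <- pmat[, scn$analysis$test_terms[1]]
  p <- p[!is.na(p)]
  # one-sided p-values live on [0, 0.5]; rescale to [0, 1] for the
  # uniformity check (equivalently, check the two-sided p-values)
  p_unif <- if (scn$analysis$sidedness == "one") 2 * p else p
  ks <- ks_uniform_boot(p_unif, n_boot = n_boot)
  r <- length(p)
  rate <- mean(p < scn$alpha)
  qq <- tibble::tibble(
    uniform = (seq_len(r) - 0.5) / r,
    pvalue = sort(p_unif)
  )
  note <- if (scn$analysis$family == "logistic") {
    paste("binary outcome: p-values are discrete in small samples and need",
          "not be exactly uniform; interpret the KS test loosely")
  } else {
    NA_character_
  }
  structure(
    list(rejection_rate = rate,
         mc_se = sqrt(rate * (1 - rate) / r),
         ks_D = ks[["D"]], ks_boot_p = ks[["boot_p"]],
         qq = qq, n_reps = r, alpha = scn$alpha,
         sidedness = scn$analysis$sidedness, seed = scn$seed, note = note),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  target <- if (x$sidedness == "one") 2 * x$alpha else x$alpha
  cat("<calibration_report>\n")
  cat(sprintf("  %s-sided rejection rate at alpha = %g: %.4f (MC SE %.4f, target %.3g)\n",
              x$sidedness, x$alpha, x$rejection_rate, x$mc_se, target))
  cat(sprintf("  KS D = %.4f, bootstrap p = %.3f (%d reps)\n",
              x$ks_D, x$ks_boot_p, x$n_reps))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @rdname null_calibration
#' @param x A `calibration_report`.
#' @param ... Unused.
#' @export
tidy.calibration_report <- function(x, ...) {
  tibble::tibble(
    rejection_rate = x$rejection_rate, mc_se = x$mc_se,
    ks_D = x$ks_D, ks_boot_p = x$ks_boot_p,
    n_reps = x$n_reps, alpha = x$alpha, sidedness = x$sidedness
  )
}

#' Bootstrapped Kolmogorov-Smirnov test of uniformity
#'
#' Computes the two-sided KS statistic `D = sup |ECDF(p) - p|` against the
#' Uniform(0, 1) CDF and calibrates it by parametric bootstrap: `n_boot`
#' uniform samples of the same size are drawn and `boot_p` is the fraction
#' whose D is at least the observed one. The bootstrap sidesteps the
#' asymptotic KS null distribution, which is slightly off at finite sample
#' sizes.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param n_boot Number of bootstrap samples (at least 100).
#' @return Named numeric vector with elements `D` and `boot_p`.
#' @examples
#' set.seed(1)
#' ks_uniform_boot(runif(500))
#' @export
ks_uniform_boot <- function(pvalues, n_boot = 1000) {
  if (length(pvalues) == 0) stop("`pvalues` is empty", call. = FALSE)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  }
  if (n_boot < 100) stop("`n_boot` must be at least 100", call. = FALSE)
  n <- length(pvalues)
  d_stat <- function(x) {
    s <- sort(x)
    i <- seq_len(n)
    max(i / n - s, s - (i - 1) / n)
  }
  d_obs <- d_stat(pvalues)
  d_boot <- vapply(seq_len(n_boot),
                   function(b) d_stat(stats::runif(n)), numeric(1))
  c(D = d_obs, boot_p = mean(d_boot >= d_obs))
}
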