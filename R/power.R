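#' Bundle a design, a data-generating model, and an analysis into a scenario
#'
#' A scenario is the complete, reproducible description of one power
#' simulation: the trial geometry, the outcome model and its parameters, the
#' analysis applied to every replicate, the test level, the replication
#' count, and the seed.
#'
#' @param design A [design_spec()].
#' @param params A [continuous_params()], [binary_params()] or
#'   [factorial_params()] object.
#' @param analysis An [analysis_spec()]; if `NULL`, a default is derived:
#'   `y ~ A` (linear or logistic) for the two-level models, and
#'   `y ~ time + A + X + A:X` over both timepoints, clustered at the
#'   village, for the factorial model.
#' @param alpha Type-I error rate of the test.
#' @param n_reps Number of Monte-Carlo replicates. At least 1,000 is
#'   recommended (a warning is issued below that); 10,000 gives a
#'   Monte-Carlo SE of about 0.2 percentage points near the 5% level.
#' @param seed Integer master seed; every random draw in the run derives
#'   from it.
#' @param redraw_randomization If `TRUE` (default) the treatment assignment
#'   is redrawn every replicate, so power averages over assignments; if
#'   `FALSE` one assignment is drawn up front and held fixed, and only the
#'   random effects and errors are redrawn each replicate.
#' @return An object of class `scenario`.
#' @export
scenario <- function(design, params, analysis = NULL,
                     alpha = 0.05, n_reps = 10000, seed = 1,
                     redraw_randomization = TRUE) {
  stopifnot(inherits(design, "design_spec"), inherits(params, "dgm_params"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  check_count(n_reps, "n_reps")
  if (n_reps < 1000) {
    warning("n_reps = ", n_reps, " is below the recommended minimum of ",
            "1,000 replicates; power estimates will be noisy", call. = FALSE)
  }
  analysis <- analysis %||% default_analysis(design, params)
  stopifnot(inherits(analysis, "analysis_spec"))
  structure(
    list(design = design, params = params, analysis = analysis,
         alpha = alpha, n_reps = as.integer(n_reps),
         seed = as.integer(seed),
         redraw_randomization = isTRUE(redraw_randomization)),
    class = "scenario"
  )
}

default_analysis <- function(design, params) {
  switch(class(params)[1],
    continuous_params = analysis_spec(design$cluster_treatments[1],
                                      family = "linear"),
    binary_params = analysis_spec(design$cluster_treatments[1],
                                  family = "logistic"),
    factorial_params = {
      a <- design$cluster_treatments[1]
      x <- design$unit_treatments[1]
      analysis_spec(c("time", a, x, paste0(a, ":", x)), family = "linear")
    }
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>\n")
  print(x$design)
  print(x$params)
  cat(sprintf("  analysis: %s y ~ %s, %s SE clustered on %s, %s-sided\n",
              x$analysis$family, paste(x$analysis$terms, collapse = " + "),
              x$analysis$se_type, x$analysis$cluster, x$analysis$sidedness))
  cat(sprintf("  alpha = %g, n_reps = %d, seed = %d, %s randomization\n",
              x$alpha, x$n_reps, x$seed,
              if (x$redraw_randomization) "per-replicate" else "fixed"))
  invisible(x)
}

simulate_outcomes <- function(frame, params, design) {
  switch(class(params)[1],
    continuous_params = simulate_continuous(frame, params,
                                            design$cluster_treatments[1]),
    binary_params = simulate_binary(frame, params,
                                    design$cluster_treatments[1]),
    factorial_params = simulate_factorial(frame, params,
                                          design$cluster_treatments[1],
                                          design$unit_treatments[1])
  )
}

#' Estimate empirical power by Monte-Carlo simulation
#'
#' Runs the full simulation loop: each replicate draws a (fresh or fixed)
#' randomization, simulates outcomes from the scenario's data-generating
#' model, applies dropout if the design has any, fits the analysis model
#' with cluster-robust standard errors, and records the Wald p-value for
#' every tested term. Empirical power is the fraction of replicates with
#' `p < alpha`. Identical scenarios (including seed) produce bit-identical
#' results: each replicate uses its own sub-seed derived from the master
#' seed, so results do not depend on execution order.
#'
#' Replicates whose analysis fails to converge are excluded from the
#' denominator and counted; if more than 1% fail, the run stops with an
#' error rather than reporting a power estimate built on a biased subset.
#'
#' @param scn A [scenario()].
#' @param keep_pvalues If `TRUE`, the matrix of per-replicate p-values is
#'   attached as attribute `"pvalues"` (used by [null_calibration()]).
#' @return A `power_estimate`: a tibble with one row per tested term and
#'   columns `term`, `power`, `mc_se` (binomial Monte-Carlo SE),
#'   `n_reps_requested`, `n_reps_used`, `n_failed`, `alpha`, `sidedness`.
#'   The scenario is attached as attribute `"scenario"`.
#' @examples
#' \donttest{
#' d <- design_spec(clusters_per_arm = 20, units_per_cluster = 10)
#' p <- continuous_params(mu = -0.875, beta1 = 0.4,
#'                        sigma_g = 0.482, sigma_e = 1.297)
#' empirical_power(scenario(d, p, n_reps = 1000, seed = 42))
#' }
#' @export
empirical_power <- function(scn, keep_pvalues = FALSE) {
  stopifnot(inherits(scn, "scenario"))
  design <- scn$design
  base_frame <- build_frame(design)

  set.seed(scn$seed)
  assignment_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, scn$n_reps)

  fixed_frame <- NULL
  if (!scn$redraw_randomization) {
    set.seed(assignment_seed)
    fixed_frame <- randomize(base_frame, design)
  }

  terms <- scn$analysis$test_terms
  pmat <- matrix(NA_real_, nrow = scn$n_reps, ncol = length(terms),
                 dimnames = list(NULL, terms))
  n_failed <- 0L

  for (r in seq_len(scn$n_reps)) {
    set.seed(rep_seeds[r])
    frame <- if (scn$redraw_randomization) {
      randomize(base_frame, design)
    } else {
      fixed_frame
    }
    dat <- simulate_outcomes(frame, scn$params, design)
    if (design$dropout_rate > 0) {
      dat <- apply_dropout(dat, design$dropout_rate)
    }
    fit <- fit_cluster_robust(dat, scn$analysis)
    if (fit$converged) {
      pmat[r, ] <- fit$p[terms]
    } else {
      n_failed <- n_failed + 1L
    }
  }

  if (n_failed > 0.01 * scn$n_reps) {
    stop("analysis failed to converge in ", n_failed, " of ", scn$n_reps,
         " replicates (> 1%); check the scenario (family = ",
         scn$analysis$family, ", ", design$arms * design$clusters_per_arm,
         " clusters x ", design$units_per_cluster, " units)", call. = FALSE)
  }

  used <- scn$n_reps - n_failed
  power <- colMeans(pmat < scn$alpha, na.rm = TRUE)
  out <- tibble::tibble(
    term = terms,
    power = unname(power),
    mc_se = sqrt(unname(power) * (1 - unname(power)) / used),
    n_reps_requested = scn$n_reps,
    n_reps_used = used,
    n_failed = n_failed,
    alpha = scn$alpha,
    sidedness = scn$analysis$sidedness
  )
  class(out) <- c("power_estimate", class(out))
  attr(out, "scenario") <- scn
  if (keep_pvalues) attr(out, "pvalues") <- pmat
  out
}

#' One-row summary of a power estimate
#'
#' @param x A `power_estimate`.
#' @param ... Unused.
#' @return A tibble with replication counts and the test level.
#' @export
glance.power_estimate <- function(x, ...) {
  tibble::tibble(
    n_reps_requested = x$n_reps_requested[1],
    n_reps_used = x$n_reps_used[1],
    n_failed = x$n_failed[1],
    alpha = x$alpha[1],
    sidedness = x$sidedness[1]
  )
}

#' Analytic power for a parallel two-arm cluster-randomized trial
#'
#' The closed-form normal-approximation benchmark
#' \deqn{1 - \beta = \Phi\!\left(\sqrt{\frac{c\,n\,d^2}
#'   {2\sigma^2\,(1 + (n-1)\rho)}} - Z_{\alpha/2}\right)}
#' where `c` is the number of clusters per arm, `n` the individuals per
#' cluster, `d` the mean difference between arms, `sigma2` the total outcome
#' variance, `rho` the ICC, and `1 + (n-1)*rho` the design effect.
#' Vectorized over `clusters_per_arm` and `d` for power curves.
#'
#' @param clusters_per_arm Clusters per arm `c`.
#' @param units_per_cluster Individuals per cluster `n`.
#' @param d Mean difference between treatment groups.
#' @param sigma2 Total outcome variance (between-cluster + within-cluster).
#' @param rho Intraclass correlation coefficient.
#' @param alpha Two-sided Type-I error rate.
#' @return Power, in `[0, 1]`.
#' @examples
#' analytic_power(clusters_per_arm = 100, units_per_cluster = 20,
#'                d = 0.2, sigma2 = 1.384^2, rho = 0.12)
#' @export
analytic_power <- function(clusters_per_arm, units_per_cluster, d,
                           sigma2, rho, alpha = 0.05) {
  stopifnot(all(clusters_per_arm >= 1), all(units_per_cluster >= 1),
            sigma2 > 0, rho >= 0, rho <= 1, alpha > 0, alpha < 1)
  deff <- 1 + (units_per_cluster - 1) * rho
  ncp <- sqrt(clusters_per_arm * units_per_cluster * d^2 / (2 * sigma2 * deff))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Empirical power across a grid of cluster counts
#'
#' Convenience wrapper that re-runs [empirical_power()] for each value of
#' `clusters_per_arm`, returning a tidy tibble ready for plotting (one row
#' per grid point per tested term). For continuous two-level scenarios the
#' analytic benchmark power is included as a column.
#'
#' @param scn A [scenario()]; its design's `clusters_per_arm` is overridden
#'   by each grid value. Each grid point derives its own sub-seed from the
#'   scenario seed.
#' @param clusters_per_arm Integer vector of clusters-per-arm values.
#' @return A `power_curve` tibble with columns `clusters_per_arm`, `term`,
#'   `power`, `mc_se` (and `analytic` where available). Supports
#'   [ggplot2::autoplot()].
#' @export
power_curve <- function(scn, clusters_per_arm) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(scn$seed)
  point_seeds <- sample.int(.Machine$integer.max - 1L, length(clusters_per_arm))
  rows <- purrr::map2(clusters_per_arm, point_seeds, function(c_arm, sd_i) {
    design_i <- scn$design
    design_i$clusters_per_arm <- as.integer(c_arm)
    scn_i <- scenario(design_i, scn$params, scn$analysis,
                      alpha = scn$alpha, n_reps = scn$n_reps, seed = sd_i,
                      redraw_randomization = scn$redraw_randomization)
    est <- empirical_power(scn_i)
    tibble::tibble(clusters_per_arm = c_arm, term = est$term,
                   power = est$power, mc_se = est$mc_se)
  })
  out <- dplyr::bind_rows(rows)
  if (inherits(scn$params, "continuous_params")) {
    p <- scn$params
    sigma2 <- p$sigma_g^2 + p$sigma_e^2
    out$analytic <- analytic_power(out$clusters_per_arm,
                                   scn$design$units_per_cluster,
                                   p$beta1, sigma2,
                                   icc(p$sigma_g, p$sigma_e), scn$alpha)
  }
  class(out) <- c("power_curve", class(out))
  out
}

#' Minimum detectable effect for a fixed design
#'
#' Searches (by bisection) for the effect size at which the design reaches a
#' target power. The `"analytic"` backend inverts the closed-form
#' cluster-randomized trial formula and applies to continuous two-level
#' scenarios; the `"simulation"` backend bisects on [empirical_power()] and
#' stops when the target lies within the estimate's 95% Monte-Carlo interval
#' (or the bracket is narrower than `tolerance`).
#'
#' @param scn A [scenario()]; its effect parameter (`beta1`) is the search
#'   variable and any value it holds is ignored.
#' @param target_power Desired power, strictly between `alpha` and 1.
#' @param tolerance Convergence tolerance on power (analytic backend) and
#'   fallback bracket width on the effect scale (simulation backend).
#' @param backend `"analytic"` or `"simulation"`.
#' @param effect_bounds Search bracket for the effect size.
#' @return The minimum detectable effect (a single number) with attribute
#'   `"power"` giving the power achieved there.
#' @examples
#' d <- design_spec(clusters_per_arm = 100, units_per_cluster = 20)
#' p <- continuous_params(mu = -0.875, sigma_g = 0.482, sigma_e = 1.297)
#' mde_search(scenario(d, p), target_power = 0.8)
#' @export
mde_search <- function(scn, target_power = 0.8, tolerance = 1e-4,
                       backend = c("analytic", "simulation"),
                       effect_bounds = c(1e-8, 10)) {
  stopifnot(inherits(scn, "scenario"))
  backend <- match.arg(backend)
  if (target_power <= scn$alpha || target_power >= 1) {
    stop("`target_power` must lie strictly between alpha and 1", call. = FALSE)
  }
  if (tolerance <= 0) stop("`tolerance` must be positive", call. = FALSE)

  if (backend == "analytic") {
    if (!inherits(scn$params, "continuous_params")) {
      stop("the analytic backend applies to continuous two-level scenarios",
           call. = FALSE)
    }
    p <- scn$params
    sigma2 <- p$sigma_g^2 + p$sigma_e^2
    rho <- icc(p$sigma_g, p$sigma_e)
    f <- function(d) {
      analytic_power(scn$design$clusters_per_arm,
                     scn$design$units_per_cluster,
                     d, sigma2, rho, scn$alpha) - target_power
    }
    if (f(effect_bounds[1]) > 0 || f(effect_bounds[2]) < 0) {
      stop("no bracket for the target power within effect_bounds [",
           effect_bounds[1], ", ", effect_bounds[2], "]", call. = FALSE)
    }
    lo <- effect_bounds[1]; hi <- effect_bounds[2]
    mde <- (lo + hi) / 2
    for (iter in seq_len(200L)) {
      mde <- (lo + hi) / 2
      fm <- f(mde)
      if (abs(fm) <= tolerance || (hi - lo) < .Machine$double.eps * 10) break
      if (fm < 0) lo <- mde else hi <- mde
    }
    structure(mde, power = analytic_power(
      scn$design$clusters_per_arm, scn$design$units_per_cluster,
      mde, sigma2, rho, scn$alpha))
  } else {
    power_at <- function(d, seed) {
      params_d <- scn$params
      params_d$beta1 <- d
      scn_d <- scenario(scn$design, params_d, scn$analysis,
                        alpha = scn$alpha, n_reps = scn$n_reps, seed = seed,
                        redraw_randomization = scn$redraw_randomization)
      est <- empirical_power(scn_d)
      est[est$term == scn$analysis$test_terms[1], ]
    }
    set.seed(scn$seed)
    seeds <- sample.int(.Machine$integer.max - 1L, 64L)
    lo <- effect_bounds[1]; hi <- effect_bounds[2]
    p_lo <- power_at(lo, seeds[1]); p_hi <- power_at(hi, seeds[2])
    if (p_lo$power > target_power || p_hi$power < target_power) {
      stop("no bracket for the target power within effect_bounds [",
           effect_bounds[1], ", ", effect_bounds[2], "]", call. = FALSE)
    }
    for (iter in seq_len(60L)) {
      mid <- (lo + hi) / 2
      est <- power_at(mid, seeds[2 + iter])
      in_ci <- abs(est$power - target_power) <= 1.96 * est$mc_se
      if (in_ci || (hi - lo) < tolerance) {
        return(structure(mid, power = est$power))
      }
      if (est$power < target_power) lo <- mid else hi <- mid
    }
    structure((lo + hi) / 2, power = est$power)
  }
}
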