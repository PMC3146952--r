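#' Parameters of the two-level continuous data-generating model
#'
#' The continuous model generates `y = mu + beta1 * A + b_i + e_ij` with a
#' cluster random effect `b_i ~ N(0, sigma_g)` shared by every unit in
#' cluster `i` and an independent individual error `e_ij ~ N(0, sigma_e)`.
#' All spread parameters are standard deviations, never variances.
#'
#' @param mu Control-arm mean outcome (e.g. HAZ units).
#' @param beta1 Treatment effect: the mean difference between treated and
#'   control units, on the outcome scale. `beta1 = 0` gives a null model.
#' @param sigma_g SD of the cluster-level random effect.
#' @param sigma_e SD of the individual-level error.
#' @return An object of class `continuous_params`.
#' @examples
#' # village-level and child-level SDs fitted from an East Java HAZ cohort
#' continuous_params(mu = -0.875, beta1 = 0.2, sigma_g = 0.482, sigma_e = 1.297)
#' @export
continuous_params <- function(mu, beta1 = 0, sigma_g, sigma_e) {
  check_sd(sigma_g, "sigma_g")
  check_sd(sigma_e, "sigma_e")
  structure(
    list(mu = mu, beta1 = beta1, sigma_g = sigma_g, sigma_e = sigma_e),
    class = c("continuous_params", "dgm_params")
  )
}

#' Parameters of the two-level binary (logistic) data-generating model
#'
#' The binary model draws `y ~ Bernoulli(p_ij)` with
#' `logit(p_ij) = mu + beta1 * A + b_i` and a cluster random effect
#' `b_i ~ N(0, sigma_g)` on the log-odds scale.
#'
#' @param mu Log-odds of the control-arm outcome probability (e.g.
#'   `qlogis(0.1)` for 10% baseline prevalence).
#' @param beta1 Log odds ratio of the treatment effect.
#' @param sigma_g SD of the cluster random effect (log-odds scale).
#' @return An object of class `binary_params`.
#' @export
binary_params <- function(mu, beta1 = 0, sigma_g) {
  check_sd(sigma_g, "sigma_g")
  structure(
    list(mu = mu, beta1 = beta1, sigma_g = sigma_g),
    class = c("binary_params", "dgm_params")
  )
}

#' Parameters of the three-level factorial data-generating model
#'
#' The factorial model generates longitudinal outcomes
#' `y = mu + beta1*A + beta2*X + beta3*A*X + b_i + b_ij + e_ijt`, where `A`
#' is a cluster-level treatment (e.g. village sanitation mobilization), `X`
#' a unit-level treatment (e.g. household nutrient supplementation), and
#' `beta3` their interaction (synergy). `b_i ~ N(0, sigma_v)` is a village
#' random effect, `b_ij ~ N(0, sigma_c)` a child random effect shared across
#' that child's measurements, and `e_ijt ~ N(0, sigma_e)` a fresh residual
#' per measurement occasion. Exposure indicators are time-indexed (0 at
#' baseline), so the single formula covers both timepoints.
#'
#' @param mu Population mean outcome (e.g. HAZ units).
#' @param beta1,beta2,beta3 Effects of the cluster-level treatment, the
#'   unit-level treatment, and their interaction.
#' @param sigma_v SD of the village (cluster) random effect.
#' @param sigma_c SD of the child (unit) random effect.
#' @param sigma_e SD of the occasion-level residual.
#' @return An object of class `factorial_params`.
#' @examples
#' # SDs fitted from a longitudinal Indian cohort with repeated HAZ measures
#' factorial_params(mu = -1.98, beta1 = 0.15, beta2 = 0.15, beta3 = 0.15,
#'                  sigma_v = 0.297, sigma_c = 1.259, sigma_e = 1.079)
#' @export
factorial_params <- function(mu, beta1 = 0, beta2 = 0, beta3 = 0,
                             sigma_v, sigma_c, sigma_e) {
  check_sd(sigma_v, "sigma_v")
  check_sd(sigma_c, "sigma_c")
  check_sd(sigma_e, "sigma_e")
  structure(
    list(mu = mu, beta1 = beta1, beta2 = beta2, beta3 = beta3,
         sigma_v = sigma_v, sigma_c = sigma_c, sigma_e = sigma_e),
    class = c("factorial_params", "dgm_params")
  )
}

#' @export
print.dgm_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  for (nm in names(x)) cat(" ", nm, "=", format(x[[nm]]), "\n")
  invisible(x)
}

check_sd <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    stop("`", name, "` must be a single non-negative standard deviation",
         call. = FALSE)
  }
  invisible(x)
}

# which effect parameters must be zero for a null run
effect_names <- function(params) {
  switch(class(params)[1],
    continuous_params = "beta1",
    binary_params = "beta1",
    factorial_params = c("beta1", "beta2", "beta3"),
    stop("unknown params class")
  )
}
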