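#' Simulate continuous outcomes from the two-level mixed model
#'
#' Draws one cluster random effect per cluster (in cluster-id order), one
#' residual per unit (in row order), and computes
#' `y = mu + beta1 * A + b_i + e_ij`. The fixed draw ordering means a seed
#' fully determines the table.
#'
#' @param frame A randomized population frame with a single treatment column
#'   and one timepoint.
#' @param params [continuous_params()].
#' @param treatment Name of the treatment indicator column; defaults to the
#'   first non-structural column.
#' @return The frame with an added `y` column (an outcome table).
#' @examples
#' d <- design_spec(clusters_per_arm = 4, units_per_cluster = 5)
#' set.seed(1)
#' build_frame(d) |>
#'   randomize(d) |>
#'   simulate_continuous(continuous_params(-0.875, 0.2, 0.482, 1.297))
#' @export
simulate_continuous <- function(frame, params, treatment = NULL) {
  stopifnot(inherits(params, "continuous_params"))
  treatment <- treatment %||% treatment_cols(frame)[1]
  a <- frame[[treatment]]
  b <- cluster_effects(frame$cluster_id, params$sigma_g)
  eps <- stats::rnorm(nrow(frame), 0, params$sigma_e)
  frame$y <- params$mu + params$beta1 * a + b + eps
  frame
}

#' Simulate binary outcomes from the two-level logistic model
#'
#' Computes `p_ij = plogis(mu + beta1 * A + b_i)` with one cluster random
#' effect per cluster and draws `y ~ Bernoulli(p_ij)`.
#'
#' @inheritParams simulate_continuous
#' @param params [binary_params()].
#' @return The frame with an added 0/1 `y` column.
#' @export
simulate_binary <- function(frame, params, treatment = NULL) {
  stopifnot(inherits(params, "binary_params"))
  treatment <- treatment %||% treatment_cols(frame)[1]
  a <- frame[[treatment]]
  b <- cluster_effects(frame$cluster_id, params$sigma_g)
  p <- stats::plogis(params$mu + params$beta1 * a + b)
  frame$y <- stats::rbinom(nrow(frame), 1L, p)
  frame
}

#' Simulate longitudinal factorial outcomes from the three-level model
#'
#' Draws one village effect per cluster, one child effect per child (shared
#' across that child's baseline and follow-up rows), and a fresh residual per
#' row, then computes
#' `y = mu + beta1*A + beta2*X + beta3*A*X + b_i + b_ij + e_ijt`.
#' Exposure indicators must be 0 on baseline rows (as [randomize()]
#' guarantees), so baseline outcomes are pre-treatment.
#'
#' @param frame A randomized two-timepoint frame with a cluster-level and a
#'   unit-level treatment column.
#' @param params [factorial_params()].
#' @param cluster_treatment,unit_treatment Column names of the two
#'   treatments; default `"A"` and `"X"`.
#' @return The frame with an added `y` column.
#' @export
simulate_factorial <- function(frame, params,
                               cluster_treatment = "A",
                               unit_treatment = "X") {
  stopifnot(inherits(params, "factorial_params"))
  if (!all(c(cluster_treatment, unit_treatment) %in% names(frame))) {
    stop("frame must contain treatment columns `", cluster_treatment,
         "` and `", unit_treatment, "`", call. = FALSE)
  }
  a <- frame[[cluster_treatment]]
  x <- frame[[unit_treatment]]
  b_village <- cluster_effects(frame$cluster_id, params$sigma_v)
  child_key <- frame$cluster_id * (max(frame$unit_id) + 1) + frame$unit_id
  b_child <- cluster_effects(child_key, params$sigma_c)
  eps <- stats::rnorm(nrow(frame), 0, params$sigma_e)
  frame$y <- params$mu + params$beta1 * a + params$beta2 * x +
    params$beta3 * a * x + b_village + b_child + eps
  frame
}

#' Remove follow-up observations completely at random
#'
#' Each child independently loses its follow-up (`time = 1`) row with the
#' given probability; baseline rows are never removed, and dropout is
#' independent of treatment and outcome (missing completely at random).
#'
#' @param table An outcome table (or frame) with two timepoints.
#' @param rate Dropout probability in `[0, 1]`.
#' @return The table with a random subset of `time = 1` rows removed.
#' @export
apply_dropout <- function(table, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) ||
      rate < 0 || rate > 1) {
    stop("`rate` must be a probability in [0, 1]", call. = FALSE)
  }
  if (rate == 0) return(table)
  children <- dplyr::distinct(table[table$time == 1L, c("cluster_id", "unit_id")])
  lost <- children[stats::runif(nrow(children)) < rate, ]
  if (nrow(lost) == 0) return(table)
  drop_key <- paste(lost$cluster_id, lost$unit_id)
  keep <- !(table$time == 1L & paste(table$cluster_id, table$unit_id) %in% drop_key)
  table[keep, ]
}

# one N(0, sd) draw per distinct id, in sorted-id order, mapped back to rows
cluster_effects <- function(id, sd) {
  ids <- sort(unique(id))
  draws <- stats::rnorm(length(ids), 0, sd)
  draws[match(id, ids)]
}

treatment_cols <- function(frame) {
  cols <- setdiff(names(frame), c("cluster_id", "unit_id", "time", "y"))
  if (length(cols) == 0) {
    stop("frame has no treatment columns", call. = FALSE)
  }
  cols
}

`%||%` <- function(a, b) if (is.null(a)) b else a
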