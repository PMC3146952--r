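#' Describe a synthetic training-data cohort
#'
#' A fixture profile declares the statistical shape of a synthetic
#' training dataset: how many clusters and children, the grand mean, the
#' per-level SDs, and whether children contribute one or up to two
#' measurements. Children are spread over clusters by a multinomial draw
#' (then adjusted so every cluster keeps at least one child), emulating the
#' cluster-size imbalance of field cohorts rather than fixed equal sizes.
#'
#' @param name Profile label.
#' @param n_clusters Number of clusters (villages).
#' @param n_children Total number of children across clusters.
#' @param mu Grand mean outcome.
#' @param sigma Named numeric vector of SDs: `c(cluster =, residual =)` for
#'   a two-level cross-sectional profile, or
#'   `c(cluster =, child =, residual =)` for a three-level longitudinal one.
#' @param measurements_per_child 1, or 2 for "up to two" longitudinal
#'   measurements.
#' @param second_measurement_prob Probability a child's second measurement
#'   is realized (only used when `measurements_per_child = 2`).
#' @return An object of class `fixture_profile`.
#' @seealso [training_profile()] for the built-in cohort profiles.
#' @export
fixture_profile <- function(name, n_clusters, n_children, mu, sigma,
                            measurements_per_child = 1,
                            second_measurement_prob = 1) {
  check_count(n_clusters, "n_clusters")
  check_count(n_children, "n_children")
  if (n_children < n_clusters) {
    stop("infeasible profile: more clusters (", n_clusters,
         ") than children (", n_children, ")", call. = FALSE)
  }
  if (!measurements_per_child %in% c(1, 2)) {
    stop("`measurements_per_child` must be 1 or 2", call. = FALSE)
  }
  need <- if (measurements_per_child == 2) {
    c("cluster", "child", "residual")
  } else {
    c("cluster", "residual")
  }
  if (!all(need %in% names(sigma))) {
    stop("`sigma` must be named with: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (nm in need) check_sd(sigma[[nm]], paste0("sigma[", nm, "]"))
  structure(
    list(name = name, n_clusters = as.integer(n_clusters),
         n_children = as.integer(n_children), mu = mu, sigma = sigma[need],
         measurements_per_child = as.integer(measurements_per_child),
         second_measurement_prob = second_measurement_prob),
    class = "fixture_profile"
  )
}

#' Built-in training-cohort profiles
#'
#' Two named profiles with the statistical structure of field anthropometry
#' training cohorts:
#'
#' * `"east-java"` — a two-level cross-sectional HAZ survey: 2,090 children
#'   in 160 rural villages, mean HAZ -0.875, village-level SD 0.482 and
#'   child-level SD 1.297 (total SD 1.384, implied ICC 0.12).
#' * `"india-longitudinal"` — a three-level longitudinal cohort: 1,236
#'   children in 25 villages with up to two HAZ measurements each, mean
#'   -1.98, SDs 0.297 (village), 1.259 (child), 1.079 (residual); total SD
#'   about 1.68. Second measurements are retained with probability 0.9.
#'
#' Both are synthetic stand-ins generated from the declared mixed models;
#' they reproduce the cohorts' variance structure, not their age structure,
#' covariates or spatial features.
#'
#' @param name `"east-java"` or `"india-longitudinal"`.
#' @return A [fixture_profile()].
#' @export
training_profile <- function(name = c("east-java", "india-longitudinal")) {
  name <- match.arg(name)
  switch(name,
    "east-java" = fixture_profile(
      name = "east-java", n_clusters = 160, n_children = 2090,
      mu = -0.875, sigma = c(cluster = 0.482, residual = 1.297),
      measurements_per_child = 1
    ),
    "india-longitudinal" = fixture_profile(
      name = "india-longitudinal", n_clusters = 25, n_children = 1236,
      mu = -1.98,
      sigma = c(cluster = 0.297, child = 1.259, residual = 1.079),
      measurements_per_child = 2, second_measurement_prob = 0.9
    )
  )
}

#' Generate a synthetic training dataset from a profile
#'
#' Allocates children to clusters by a multinomial draw (adjusted so every
#' cluster has at least one child), then generates outcomes from the
#' matching intercept-only mixed model: two-level profiles give one row per
#' child (`time = 0`), three-level profiles give a baseline row per child
#' plus a second-measurement row (`time = 1`) retained with the profile's
#' probability. No treatment columns are involved — this is training data
#' for variance-component estimation.
#'
#' @param profile A [fixture_profile()].
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return A tibble with columns `cluster_id`, `unit_id`, `time`, `y`.
#' @examples
#' train <- generate_training_fixture(training_profile("east-java"), seed = 7)
#' c(mean = mean(train$y), sd = sd(train$y))
#' @export
generate_training_fixture <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "fixture_profile"))
  if (!is.null(seed)) set.seed(seed)
  k <- profile$n_clusters
  sizes <- as.vector(stats::rmultinom(1, profile$n_children, rep(1 / k, k)))
  # every cluster keeps at least one child: move children from the largest
  while (any(sizes == 0)) {
    empty <- which(sizes == 0)[1]
    donor <- which.max(sizes)
    sizes[empty] <- sizes[empty] + 1L
    sizes[donor] <- sizes[donor] - 1L
  }
  cluster_id <- rep(seq_len(k), times = sizes)
  unit_id <- unlist(lapply(sizes, seq_len))
  n <- length(cluster_id)
  b_cluster <- stats::rnorm(k, 0, profile$sigma[["cluster"]])

  if (profile$measurements_per_child == 1) {
    y <- profile$mu + b_cluster[cluster_id] +
      stats::rnorm(n, 0, profile$sigma[["residual"]])
    out <- tibble::tibble(cluster_id = cluster_id, unit_id = unit_id,
                          time = 0L, y = y)
  } else {
    b_child <- stats::rnorm(n, 0, profile$sigma[["child"]])
    has_second <- stats::runif(n) < profile$second_measurement_prob
    base <- tibble::tibble(cluster_id = cluster_id, unit_id = unit_id,
                           child = seq_len(n))
    long <- dplyr::bind_rows(
      dplyr::mutate(base, time = 0L),
      dplyr::mutate(base[has_second, ], time = 1L)
    )
    long$y <- profile$mu + b_cluster[long$cluster_id] + b_child[long$child] +
      stats::rnorm(nrow(long), 0, profile$sigma[["residual"]])
    out <- dplyr::arrange(long[, c("cluster_id", "unit_id", "time", "y")],
                          .data$cluster_id, .data$unit_id, .data$time)
  }
  out
}
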