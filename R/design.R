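#' Declare the geometry and randomization plan of a trial design
#'
#' A design spec captures everything about a trial's structure that is fixed
#' before outcomes exist: how many arms, clusters and units there are, how
#' many measurement occasions each unit has, which treatments are randomized
#' at the cluster level versus the unit level, and the expected attrition
#' between baseline and follow-up.
#'
#' @param clusters_per_arm Number of clusters (villages, communities) per arm.
#' @param units_per_cluster Number of units (children, households) enrolled in
#'   each cluster. One child per household is assumed, so "unit" and "child"
#'   are interchangeable.
#' @param arms Number of treatment arms at the cluster level (2 for a simple
#'   parallel cluster-randomized trial, and also 2 for the factorial design,
#'   where the second treatment is randomized *within* clusters).
#' @param timepoints 1 (a single post-intervention measurement) or 2
#'   (baseline at `time = 0` plus follow-up at `time = 1`).
#' @param cluster_treatments Character vector of treatment labels randomized
#'   across whole clusters (e.g. `"A"` for a sanitation campaign).
#' @param unit_treatments Character vector of treatment labels randomized
#'   across units within every cluster (e.g. `"X"` for household nutrient
#'   supplementation). May be empty.
#' @param unit_allocation_fraction Fraction of units per cluster receiving
#'   each unit-level treatment. `unit_allocation_fraction * units_per_cluster`
#'   must be a whole number (exact within-cluster balance).
#' @param dropout_rate Probability in `[0, 1]` that a unit's follow-up
#'   observation is missing. Requires `timepoints = 2` when positive.
#'
#' @return An object of class `design_spec`.
#' @examples
#' # 2 arms x 100 clusters/arm x 10 children/cluster, one follow-up measure
#' design_spec(clusters_per_arm = 100, units_per_cluster = 10)
#'
#' # factorial: sanitation across villages, LNS to half the children within
#' design_spec(
#'   clusters_per_arm = 60, units_per_cluster = 20, timepoints = 2,
#'   cluster_treatments = "A", unit_treatments = "X",
#'   unit_allocation_fraction = 0.5, dropout_rate = 0.1
#' )
#' @export
design_spec <- function(clusters_per_arm,
                        units_per_cluster,
                        arms = 2,
                        timepoints = 1,
                        cluster_treatments = "A",
                        unit_treatments = character(),
                        unit_allocation_fraction = 0.5,
                        dropout_rate = 0) {
  check_count(arms, "arms")
  check_count(clusters_per_arm, "clusters_per_arm")
  check_count(units_per_cluster, "units_per_cluster")
  if (!timepoints %in% c(1, 2)) {
    stop("`timepoints` must be 1 or 2, got ", timepoints, call. = FALSE)
  }
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 1 ||
      is.na(dropout_rate) || dropout_rate < 0 || dropout_rate > 1) {
    stop("`dropout_rate` must be a probability in [0, 1]", call. = FALSE)
  }
  if (dropout_rate > 0 && timepoints != 2) {
    stop("`dropout_rate` > 0 requires `timepoints` = 2 ",
         "(dropout removes follow-up observations)", call. = FALSE)
  }
  if (length(unit_treatments) > 0) {
    n_treated <- unit_allocation_fraction * units_per_cluster
    if (!isTRUE(all.equal(n_treated, round(n_treated)))) {
      stop("`unit_allocation_fraction` (", unit_allocation_fraction,
           ") times `units_per_cluster` (", units_per_cluster,
           ") must be an integer for exact within-cluster balance",
           call. = FALSE)
    }
  }
  trt <- c(cluster_treatments, unit_treatments)
  if (anyDuplicated(trt)) {
    stop("treatment labels must be unique across levels", call. = FALSE)
  }
  structure(
    list(
      arms = as.integer(arms),
      clusters_per_arm = as.integer(clusters_per_arm),
      units_per_cluster = as.integer(units_per_cluster),
      timepoints = as.integer(timepoints),
      cluster_treatments = as.character(cluster_treatments),
      unit_treatments = as.character(unit_treatments),
      unit_allocation_fraction = unit_allocation_fraction,
      dropout_rate = dropout_rate
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  g <- x$arms * x$clusters_per_arm
  cat("<design_spec>\n")
  cat(sprintf("  %d arms x %d clusters/arm x %d units/cluster x %d timepoint(s) (%d rows)\n",
              x$arms, x$clusters_per_arm, x$units_per_cluster, x$timepoints,
              g * x$units_per_cluster * x$timepoints))
  cat("  cluster-level treatments:",
      if (length(x$cluster_treatments)) paste(x$cluster_treatments, collapse = ", ") else "none", "\n")
  if (length(x$unit_treatments)) {
    cat(sprintf("  unit-level treatments: %s (fraction %.3g per cluster)\n",
                paste(x$unit_treatments, collapse = ", "),
                x$unit_allocation_fraction))
  }
  if (x$dropout_rate > 0) cat(sprintf("  dropout rate: %.3g\n", x$dropout_rate))
  invisible(x)
}

#' Build the population skeleton for a design
#'
#' Expands a design spec into a long-format population frame with one row per
#' unit per measurement occasion and one 0/1 indicator column per treatment
#' label, all initialized to 0. Treatment assignment happens separately in
#' [randomize()], so the same skeleton can be re-randomized cheaply inside
#' the power loop.
#'
#' With `timepoints = 2` each unit contributes a `time = 0` (baseline) and a
#' `time = 1` (follow-up) row; exposure indicators stay 0 at baseline because
#' treatment begins after baseline. With `timepoints = 1` the single
#' measurement is post-intervention and is coded `time = 1`.
#'
#' @param design A [design_spec()].
#' @return A tibble (the population frame) with columns `cluster_id`
#'   (globally unique integer), `unit_id` (unique within cluster), `time`,
#'   and one column per treatment label.
#' @examples
#' d <- design_spec(clusters_per_arm = 100, units_per_cluster = 10)
#' nrow(build_frame(d)) # 2,000 children
#' @export
build_frame <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  n_clusters <- design$arms * design$clusters_per_arm
  times <- if (design$timepoints == 2L) c(0L, 1L) else 1L
  frame <- tidyr::expand_grid(
    cluster_id = seq_len(n_clusters),
    unit_id = seq_len(design$units_per_cluster),
    time = times
  )
  for (trt in c(design$cluster_treatments, design$unit_treatments)) {
    frame[[trt]] <- 0L
  }
  frame
}

#' Randomize treatments at their declared levels
#'
#' Assigns every cluster-level treatment to exactly half of the clusters
#' (balanced complete randomization — the assignment is a random permutation,
#' not independent coin flips) and every unit-level treatment to exactly
#' `unit_allocation_fraction * units_per_cluster` units within each cluster.
#' With two timepoints the exposure indicators are set only on follow-up
#' (`time = 1`) rows; baseline rows remain 0.
#'
#' Because assignment draws a fresh permutation, cluster labels carry no
#' information about the arm. Uses the current RNG state, so wrap in
#' `set.seed()` (or use [empirical_power()], which manages seeding) for
#' reproducibility.
#'
#' @param frame A population frame from [build_frame()].
#' @param design The [design_spec()] that produced `frame`.
#' @return The frame with treatment indicator columns filled in.
#' @examples
#' d <- design_spec(clusters_per_arm = 3, units_per_cluster = 4,
#'                  unit_treatments = "X")
#' set.seed(1)
#' randomize(build_frame(d), d)
#' @export
randomize <- function(frame, design) {
  stopifnot(inherits(design, "design_spec"))
  need <- c("cluster_id", "unit_id", "time",
            design$cluster_treatments, design$unit_treatments)
  missing_cols <- setdiff(need, names(frame))
  if (length(missing_cols)) {
    stop("frame is missing columns: ", paste(missing_cols, collapse = ", "),
         "; was it produced by build_frame() for this design?", call. = FALSE)
  }
  cluster_ids <- unique(frame$cluster_id)
  g <- length(cluster_ids)
  exposed <- if (design$timepoints == 2L) frame$time == 1L else rep(TRUE, nrow(frame))

  for (trt in design$cluster_treatments) {
    if (g %% 2L != 0L) {
      stop("cannot balance 1:1 cluster allocation with an odd number of ",
           "clusters (", g, ")", call. = FALSE)
    }
    treated <- sample(cluster_ids, g / 2L)
    frame[[trt]] <- as.integer(exposed & frame$cluster_id %in% treated)
  }

  if (length(design$unit_treatments)) {
    n_treat <- as.integer(round(design$unit_allocation_fraction *
                                  design$units_per_cluster))
    unit_ids <- seq_len(design$units_per_cluster)
    for (trt in design$unit_treatments) {
      # one balanced draw per cluster, in cluster-id order for determinism
      picks <- lapply(cluster_ids, function(cl) sample(unit_ids, n_treat))
      names(picks) <- as.character(cluster_ids)
      key <- paste(frame$cluster_id, frame$unit_id)
      treated_key <- unlist(lapply(cluster_ids, function(cl) {
        paste(cl, picks[[as.character(cl)]])
      }))
      frame[[trt]] <- as.integer(exposed & key %in% treated_key)
    }
  }
  frame
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 ||
      !isTRUE(all.equal(x, round(x)))) {
    stop("`", name, "` must be a positive whole number, got ",
         deparse(substitute(x)), " = ", format(x), call. = FALSE)
  }
  invisible(x)
}
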