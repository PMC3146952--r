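#' Load a scenario from a config file or list
#'
#' Reads a YAML or JSON scenario configuration with sections `design`,
#' `params`, optional `analysis`, and `run`, validates every field, rejects
#' unknown keys, and materializes defaults (`alpha = 0.05`, two-sided test,
#' `n_reps = 10000`). The accepted keys mirror the arguments of
#' [design_spec()], the `*_params()` constructors (plus a `family` key
#' naming which one), [analysis_spec()], and [scenario()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` when
#'   `config` is given directly.
#' @param config A named list with the same structure as the file contents
#'   (e.g. a deserialized run report); overrides `path`.
#' @return A validated [scenario()].
#' @examples
#' cfg <- list(
#'   design = list(clusters_per_arm = 50, units_per_cluster = 10),
#'   params = list(family = "continuous", mu = -0.875, beta1 = 0.2,
#'                 sigma_g = 0.482, sigma_e = 1.297),
#'   run = list(n_reps = 1000, seed = 42)
#' )
#' load_scenario(config = cfg)
#' @export
load_scenario <- function(path = NULL, config = NULL) {
  if (is.null(config)) {
    if (is.null(path) || !file.exists(path)) {
      stop("config file not found: ", path %||% "<NULL>", call. = FALSE)
    }
    config <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }

  allowed <- list(
    top = c("design", "params", "analysis", "run"),
    design = c("arms", "clusters_per_arm", "units_per_cluster", "timepoints",
               "cluster_treatments", "unit_treatments",
               "unit_allocation_fraction", "dropout_rate"),
    params = c("family", "mu", "beta1", "beta2", "beta3",
               "sigma_g", "sigma_e", "sigma_v", "sigma_c"),
    analysis = c("terms", "family", "cluster", "test_terms", "sidedness",
                 "se_type", "df_reference"),
    run = c("alpha", "n_reps", "seed", "redraw_randomization")
  )
  offending <- character()
  bad_top <- setdiff(names(config), allowed$top)
  if (length(bad_top)) offending <- paste0("top-level: ", bad_top)
  for (sec in intersect(names(config), c("design", "params", "analysis", "run"))) {
    bad <- setdiff(names(config[[sec]]), allowed[[sec]])
    if (length(bad)) offending <- c(offending, paste0(sec, ": ", bad))
  }
  if (length(offending)) {
    stop("unknown config keys: ", paste(offending, collapse = "; "),
         call. = FALSE)
  }
  for (sec in c("design", "params")) {
    if (is.null(config[[sec]])) {
      stop("config is missing required section `", sec, "`", call. = FALSE)
    }
  }

  d <- config$design
  design <- do.call(design_spec, d)

  p <- config$params
  fam <- p$family %||% "continuous"
  p$family <- NULL
  params <- switch(fam,
    continuous = do.call(continuous_params, p),
    binary = do.call(binary_params, p),
    factorial = do.call(factorial_params, p),
    stop("params$family must be continuous, binary or factorial; got `",
         fam, "`", call. = FALSE)
  )

  analysis <- if (!is.null(config$analysis)) {
    a <- config$analysis
    a$terms <- unlist(a$terms)
    if (!is.null(a$test_terms)) a$test_terms <- unlist(a$test_terms)
    do.call(analysis_spec, a)
  } else {
    NULL
  }

  r <- config$run %||% list()
  scenario(design, params, analysis,
           alpha = r$alpha %||% 0.05,
           n_reps = r$n_reps %||% 10000,
           seed = r$seed %||% 1,
           redraw_randomization = r$redraw_randomization %||% TRUE)
}

#' Serialize a scenario back to a plain config list
#'
#' The returned list is accepted by `load_scenario(config = )` and
#' reproduces the scenario (and hence any run made from it) exactly.
#'
#' @param scn A [scenario()].
#' @return A named list with sections `design`, `params`, `analysis`, `run`.
#' @export
scenario_to_list <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  fam <- sub("_params$", "", class(scn$params)[1])
  params <- c(list(family = fam), unclass(scn$params))
  list(
    design = unclass(scn$design),
    params = params,
    analysis = unclass(scn$analysis),
    run = list(alpha = scn$alpha, n_reps = scn$n_reps, seed = scn$seed,
               redraw_randomization = scn$redraw_randomization)
  )
}

#' Write a scenario config to YAML or JSON
#'
#' @param scn A [scenario()].
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  cfg <- scenario_to_list(scn)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Build a reproducible run report from a power estimate
#'
#' The report echoes the fully resolved scenario (sufficient to reproduce
#' the run exactly via [load_scenario()]), the per-term power estimates,
#' the package version and a timestamp.
#'
#' @param est A `power_estimate` from [empirical_power()].
#' @return A named list, ready for [jsonlite::write_json()].
#' @export
run_report <- function(est) {
  stopifnot(inherits(est, "power_estimate"))
  scn <- attr(est, "scenario")
  list(
    scenario = scenario_to_list(scn),
    results = as.data.frame(est),
    software = list(
      package = "powersim",
      version = as.character(utils::packageVersion("powersim"))
    ),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

#' Read long-format training data from delimited text
#'
#' Reads one row per observation with configurable column names for the
#' cluster id, unit id, optional time, and outcome, renames them to the
#' package's canonical names, validates them, and reports the replication
#' structure (rows, clusters, observations per level) as a message.
#'
#' @param path Delimited text file (comma-separated by default).
#' @param cluster,unit,outcome,time Column names in the file; set
#'   `time = NULL` when there is no time column.
#' @param sep Field separator.
#' @param quiet Suppress the validation message.
#' @return A tibble with columns `cluster_id`, `unit_id`, (`time`,) `y`.
#' @export
read_training_data <- function(path, cluster = "cluster_id",
                               unit = "unit_id", outcome = "y",
                               time = "time", sep = ",", quiet = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c(cluster, unit, outcome, time)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("training file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    cluster_id = raw[[cluster]],
    unit_id = raw[[unit]]
  )
  if (!is.null(time)) out$time <- raw[[time]]
  out$y <- raw[[outcome]]
  if (anyNA(out$y) || any(!is.finite(out$y))) {
    stop("outcome column contains missing or non-finite values", call. = FALSE)
  }
  if (!quiet) {
    per_child <- table(paste(out$cluster_id, out$unit_id))
    message(sprintf(
      "read %d rows: %d clusters, %d children, %d with repeated measures",
      nrow(out), length(unique(out$cluster_id)), length(per_child),
      sum(per_child >= 2)))
  }
  out
}
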