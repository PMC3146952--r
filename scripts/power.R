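#!/usr/bin/env Rscript
# Thin command-line wrapper over the powersim package.
#
#   Rscript scripts/power.R run --config scenario.yaml [--seed 42] [--reps 10000] [--out report.json]
#   Rscript scripts/power.R analytic --c 100 --n 20 --d 0.2 --sd 1.384 --icc 0.12 [--alpha 0.05]
#   Rscript scripts/power.R mde --config scenario.yaml --target 0.8
#   Rscript scripts/power.R nullcheck --config scenario.yaml [--reps 10000] [--out report.json]
#   Rscript scripts/power.R fixture --profile east-java --seed 7 --out train.csv
#   Rscript scripts/power.R estimate-params --train train.csv [--levels two_level] [--out vc.json]
#
# Exit codes: 0 success, 2 config/usage error, 3 convergence-failure budget
# exceeded.

suppressPackageStartupMessages(library(powersim))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) {
  message("usage: power.R <run|analytic|mde|nullcheck|fixture|estimate-params> [flags]")
  quit(status = 2)
}
cmd <- argv[1]
flags <- argv[-1]
get_flag <- function(name, default = NULL) {
  i <- which(flags == paste0("--", name))
  if (length(i) == 1 && i < length(flags)) flags[i + 1] else default
}

fail <- function(status, ...) {
  message(...)
  quit(status = status, save = "no")
}

load_scn <- function() {
  path <- get_flag("config")
  if (is.null(path)) fail(2, "--config is required")
  scn <- tryCatch(load_scenario(path), error = function(e) fail(2, conditionMessage(e)))
  seed <- get_flag("seed"); reps <- get_flag("reps")
  if (!is.null(seed)) scn$seed <- as.integer(seed)
  if (!is.null(reps)) scn$n_reps <- as.integer(reps)
  scn
}

emit_json <- function(x, out) {
  if (is.null(out)) {
    cat(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE), "\n")
  } else {
    jsonlite::write_json(x, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message("wrote ", out)
  }
}

if (cmd == "run") {
  scn <- load_scn()
  est <- tryCatch(empirical_power(scn), error = function(e) {
    if (grepl("converge", conditionMessage(e))) fail(3, conditionMessage(e))
    fail(2, conditionMessage(e))
  })
  print(est)
  emit_json(run_report(est), get_flag("out"))
  csv <- get_flag("csv")
  if (!is.null(csv)) utils::write.csv(as.data.frame(est), csv, row.names = FALSE)
} else if (cmd == "analytic") {
  need <- c("c", "n", "d", "sd", "icc")
  vals <- lapply(need, get_flag)
  if (any(vapply(vals, is.null, logical(1)))) {
    fail(2, "analytic requires --c --n --d --sd --icc")
  }
  v <- as.numeric(vals)
  pw <- analytic_power(v[1], v[2], v[3], sigma2 = v[4]^2, rho = v[5],
                       alpha = as.numeric(get_flag("alpha", "0.05")))
  cat(sprintf("analytic power: %.4f\n", pw))
} else if (cmd == "mde") {
  scn <- load_scn()
  m <- mde_search(scn,
                  target_power = as.numeric(get_flag("target", "0.8")),
                  backend = get_flag("backend", "analytic"))
  cat(sprintf("MDE: %.5f (power %.4f)\n", as.numeric(m), attr(m, "power")))
} else if (cmd == "nullcheck") {
  scn <- load_scn()
  rep <- tryCatch(null_calibration(scn),
                  error = function(e) fail(2, conditionMessage(e)))
  print(rep)
  out <- get_flag("out")
  emit_json(c(tidy(rep), list(seed = rep$seed, note = rep$note)), out)
  csv <- get_flag("csv")
  if (!is.null(csv)) utils::write.csv(rep$qq, csv, row.names = FALSE)
} else if (cmd == "fixture") {
  prof <- tryCatch(training_profile(get_flag("profile", "east-java")),
                   error = function(e) fail(2, conditionMessage(e)))
  train <- generate_training_fixture(prof, seed = as.integer(get_flag("seed", "1")))
  out <- get_flag("out")
  if (is.null(out)) fail(2, "--out is required for fixture")
  utils::write.csv(train, out, row.names = FALSE)
  message("wrote ", nrow(train), " rows to ", out)
} else if (cmd == "estimate-params") {
  path <- get_flag("train")
  if (is.null(path)) fail(2, "--train is required")
  train <- tryCatch(
    read_training_data(path,
                       cluster = get_flag("cluster", "cluster_id"),
                       unit = get_flag("unit", "unit_id"),
                       outcome = get_flag("outcome", "y"),
                       time = get_flag("time", "time")),
    error = function(e) fail(2, conditionMessage(e)))
  vc <- estimate_variance_components(train,
                                     levels = get_flag("levels", "two_level"),
                                     family = get_flag("family", "linear"))
  print(vc)
  emit_json(list(mu = vc$mu, sigma = as.list(vc$sigma), family = vc$family,
                 levels = vc$levels),
            get_flag("out"))
} else {
  fail(2, "unknown subcommand: ", cmd)
}
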