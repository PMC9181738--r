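#!/usr/bin/env Rscript
# Thin command-line front-end over the dualbench package.
#
#   Rscript scripts/dualbench.R run --config cfg.json [--out-dir DIR] [--seed N]
#   Rscript scripts/dualbench.R simulate --out cohort.csv [--seed N]
#   Rscript scripts/dualbench.R benchmark --input cohort.csv [--B N] [--seed N]
#                                         [--subgroups all|none] [--stratified]
#                                         [--completeness-threshold F]
#
# The config file (JSON or YAML) may set: seed, split_fraction,
# completeness_threshold, bootstrap.B, bootstrap.stratified, and either
# input_csv or synthetic: {n_centers, patients_per_center}.

suppressMessages(library(dualbench))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  stop("usage: dualbench.R <run|simulate|benchmark> [options]", call. = FALSE)
}
cmd <- args[1]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
has_flag <- function(flag) flag %in% args

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package needed for YAML configs; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

seed <- as.integer(opt("--seed", "1"))

if (cmd == "run") {
  cfg_path <- opt("--config")
  cfg <- if (is.null(cfg_path)) list() else read_config(cfg_path)
  if (!is.null(cfg$synthetic)) {
    cfg$synthetic <- do.call(synthetic_config, as.list(cfg$synthetic))
  } else if (is.null(cfg$input_csv)) {
    cfg$synthetic <- synthetic_config()
  }
  if (is.null(cfg$seed)) cfg$seed <- seed
  default_dir <- if (is.null(cfg$out_dir)) "dualbench_out" else cfg$out_dir
  cfg$out_dir <- opt("--out-dir", default_dir)
  bundle <- run_pipeline(cfg)
  message("pipeline complete; artifacts in ", cfg$out_dir)
  print(bundle$flowchart)
} else if (cmd == "simulate") {
  out <- opt("--out", "cohort.csv")
  g <- generate_cohort(synthetic_config(seed = seed))
  write_cohort_csv(g$cohort, out)
  jsonlite::write_json(g$true_values$centers, sub("\\.csv$", "_truth.json", out),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("wrote ", out)
} else if (cmd == "benchmark") {
  input <- opt("--input")
  if (is.null(input)) stop("benchmark needs --input cohort.csv", call. = FALSE)
  cfg <- list(
    input_csv = input,
    bootstrap = list(B = as.integer(opt("--B", "1000")),
                     stratified = has_flag("--stratified")),
    completeness_threshold = as.numeric(opt("--completeness-threshold",
                                            "0.10")),
    subgroups = if (identical(opt("--subgroups", "all"), "none")) list()
                else default_subgroups(),
    seed = seed,
    out_dir = opt("--out-dir", "dualbench_out")
  )
  bundle <- run_pipeline(cfg)
  print(export_forest(bundle$benchmarks))
} else {
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
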