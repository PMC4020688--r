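# allowed fields per config section, for field-level validation messages
.config_fields <- list(
  distribution = c("family", "mu", "pi", "size", "dispersion",
                   "dispersion_scale", "delta"),
  design = c("layout", "n_replicates", "block_var_count", "block_var_zero"),
  varieties = c("name", "role", "effect", "effect_var", "zero_effect",
                "zero_effect_var", "gxe_var", "zero_gxe_var", "n_reference",
                "time_coef", "zero_time_coef", "time_coef_var",
                "zero_time_coef_var"),
  trials = c("kind", "n_trials", "n_sites", "n_years", "trial_var",
             "site_var", "year_var", "site_year_var", "zero_trial_var",
             "zero_site_var", "zero_year_var", "zero_site_year_var",
             "ref_trial_var", "zero_ref_trial_var"),
  time = c("timepoints", "pattern", "correlation", "rho", "var", "zero_var")
)

.check_fields <- function(x, section) {
  extra <- setdiff(names(x), .config_fields[[section]])
  if (length(extra))
    abort(sprintf("unknown field(s) in [%s]: %s", section,
                  paste(extra, collapse = ", ")))
  x
}

#' Read a scenario from a YAML configuration file
#'
#' The file mirrors the scenario structure: a `distribution` section
#' (family, dispersion, and for binary families `size`), a `design`
#' section, a list of `varieties`, and optional `trials` and `time`
#' sections. Validation errors name the offending section and field.
#'
#' @param path Path to a YAML file.
#' @return An [scenario()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  for (section in c("distribution", "design", "varieties")) {
    if (is.null(cfg[[section]]))
      abort(sprintf("config is missing the required [%s] section.", section))
  }
  d <- .check_fields(cfg$distribution, "distribution")
  if (is.null(d$family)) abort("[distribution] requires a `family` field.")
  dist <- if (d$family %in% c("binomial", "betabinom", "binlogitnorm")) {
    if (is.null(d$size)) abort("[distribution] binary families require `size`.")
    binary_dist(d$family, size = d$size, pi = d$pi %||% 0.5,
                dispersion = d$dispersion, delta = d$delta %||% 0)
  } else {
    count_dist(d$family, mu = d$mu %||% 1, dispersion = d$dispersion,
               delta = d$delta %||% 0,
               dispersion_scale = d$dispersion_scale %||% "omega")
  }
  de <- .check_fields(cfg$design, "design")
  if (is.null(de$n_replicates))
    abort("[design] requires an `n_replicates` field.")
  design <- design_spec(de$layout %||% "crd", de$n_replicates,
                        de$block_var_count %||% 0, de$block_var_zero %||% 0)
  vars <- lapply(cfg$varieties, function(v) {
    v <- .check_fields(v, "varieties")
    if (is.null(v$name) || is.null(v$role))
      abort("each entry of [varieties] requires `name` and `role`.")
    do.call(variety, v)
  })
  trials <- if (!is.null(cfg$trials))
    do.call(trial_structure, .check_fields(cfg$trials, "trials"))
    else trial_structure("single")
  time <- if (!is.null(cfg$time))
    do.call(time_spec, .check_fields(cfg$time, "time"))
    else NULL
  scenario(dist, vars, design, trials, time)
}

#' Write a deterministic run manifest
#'
#' Records the configuration checksum, the master seed, the package
#' version, per-output md5 checksums and the wall time, so a run can be
#' verified as exactly reproduced.
#'
#' @param out_dir Output directory.
#' @param seed Master seed of the run.
#' @param outputs Character vector of produced file paths.
#' @param config_path Optional path of the configuration used.
#' @param elapsed Wall time in seconds.
#' @return Path of the written `manifest.json`, invisibly.
#' @export
write_run_manifest <- function(out_dir, seed, outputs, config_path = NULL,
                               elapsed = NA_real_) {
  manifest <- list(
    tool = "ntopower",
    version = as.character(utils::packageVersion("ntopower")),
    config = if (!is.null(config_path))
      list(path = config_path, md5 = unname(tools::md5sum(config_path))),
    seed = seed,
    outputs = lapply(outputs, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    wall_time_sec = elapsed)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate datasets from a configuration file
#'
#' @param config_path YAML scenario configuration.
#' @param seed Master seed.
#' @param n_datasets Number of datasets to write.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths of the written CSV files.
#' @export
cmd_simulate <- function(config_path, seed = 1, n_datasets = 1,
                         out_dir = ".") {
  t0 <- proc.time()["elapsed"]
  scen <- read_scenario_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sets <- simulate_batch(scen, n_datasets, master_seed = seed)
  paths <- vapply(seq_along(sets), function(k) {
    p <- file.path(out_dir, sprintf("dataset_%03d.csv", k))
    write_trial_csv(sets[[k]], p)
    p
  }, character(1))
  write_run_manifest(out_dir, seed, paths, config_path,
                     proc.time()["elapsed"] - t0)
  invisible(paths)
}

#' Estimate a power curve from a configuration file
#'
#' @inheritParams cmd_simulate
#' @inheritParams estimate_power
#' @param target Target power for the required-replication interpolation.
#' @return Invisibly, a list with the `power_curve` and `required_n`
#'   tibbles (also written as CSV with a manifest).
#' @export
cmd_power <- function(config_path, analysis,
                      n_grid = c(4, 6, 8, 10, 15, 20, 30, 40),
                      n_sims = 1000, alpha = 0.05, target = 0.80,
                      level = 0.95, limits = c(0.5, 2), seed = 1,
                      out_dir = ".") {
  t0 <- proc.time()["elapsed"]
  scen <- read_scenario_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pc <- estimate_power(scen, analysis, n_grid = n_grid, n_sims = n_sims,
                       alpha = alpha, level = level, limits = limits,
                       seed = seed)
  rn <- required_replications(pc, target)
  p1 <- file.path(out_dir, "power_curve.csv")
  p2 <- file.path(out_dir, "required_n.csv")
  write.csv(pc, p1, row.names = FALSE)
  write.csv(rn, p2, row.names = FALSE)
  write_run_manifest(out_dir, seed, c(p1, p2), config_path,
                     proc.time()["elapsed"] - t0)
  invisible(list(power_curve = pc, required_n = rn))
}

#' Run a canonical required-replication table from the command line
#'
#' @inheritParams reproduce_table
#' @param out_dir Output directory.
#' @return Invisibly, the table tibble (written as CSV, aligned text, and
#'   a standard-error companion CSV, with a manifest).
#' @export
cmd_table <- function(table, n_sims = 1000, seed = 1, out_dir = ".", ...) {
  t0 <- proc.time()["elapsed"]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- reproduce_table(table, n_sims = n_sims, seed = seed, ...)
  p1 <- file.path(out_dir, sprintf("table_%s.csv", table))
  p2 <- file.path(out_dir, sprintf("table_%s.txt", table))
  p3 <- file.path(out_dir, sprintf("table_%s_se.csv", table))
  write.csv(tbl[setdiff(names(tbl), "se_nearest")], p1, row.names = FALSE)
  writeLines(format_required_table(tbl), p2)
  write.csv(tbl[c("table", "block", "omega", "mu", "theta", "se_nearest")],
            p3, row.names = FALSE)
  write_run_manifest(out_dir, seed, c(p1, p2, p3), NULL,
                     proc.time()["elapsed"] - t0)
  invisible(tbl)
}
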