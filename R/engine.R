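#' Simulate one complete trial dataset
#'
#' Draws all random effects for the scenario, assembles the unit-level
#' means and structural-zero probabilities, and samples one response per
#' experimental unit and time point from the scenario's family with its
#' common dispersion. The result is a long-format table; `mu_true` and
#' `delta_true` carry the generating means for diagnostics.
#'
#' @param scen An [scenario()].
#' @param seed Optional integer seed; given the same seed the dataset is
#'   bit-reproducible.
#' @param truth Keep the `mu_true`/`delta_true` columns (set `FALSE` for
#'   blinded method evaluation).
#' @return A tibble with columns `trial`, `site`, `year`, `block`, `plot`,
#'   `variety`, `role`, `time`, `n` (binomial size, `NA` for counts),
#'   `response`, and optionally `mu_true`, `delta_true`.
#' @examples
#' ds <- simulate_dataset(
#'   single_trial_scenario("poisson", mu = 10, n_replicates = 5), seed = 1)
#' @export
simulate_dataset <- function(scen, seed = NULL, truth = TRUE) {
  stopifnot(inherits(scen, "nto_scenario"))
  if (!is.null(seed)) set.seed(seed)
  lp <- linear_predictor(scen, draw_effects(scen))
  dist <- scen$distribution
  m <- nrow(lp)
  binary <- inherits(dist, "binary_dist")

  if (binary) {
    pi <- plogis(lp$eta_count)
    x <- switch(dist$family,
      binomial = rbinom(m, dist$size, pi),
      betabinom = {
        phi <- dist$dispersion
        if (phi == 0) rbinom(m, dist$size, pi)
        else rbinom(m, dist$size,
                    rbeta(m, pi * (1 - phi) / phi,
                          (1 - pi) * (1 - phi) / phi))
      },
      binlogitnorm = {
        s2 <- dist$dispersion
        if (s2 == 0) rbinom(m, dist$size, pi)
        else rbinom(m, dist$size, plogis(rnorm(m, lp$eta_count, sqrt(s2))))
      })
    n_col <- rep(dist$size, m)
  } else {
    mu <- lp$mu
    x <- switch(dist$family,
      poisson = rpois(m, mu),
      odpoisson = {
        phi <- dist$dispersion
        if (phi == 1) rpois(m, mu)
        else rpois(m, rgamma(m, shape = mu / (phi - 1), scale = phi - 1))
      },
      negbin = {
        omega <- dist$dispersion
        if (omega == 0) rpois(m, mu) else rnbinom(m, size = 1 / omega, mu = mu)
      },
      poislognorm = {
        s2 <- dist$sigma2
        if (s2 == 0) rpois(m, mu)
        else rpois(m, exp(rnorm(m, log(mu) - s2 / 2, sqrt(s2))))
      })
    n_col <- rep(NA_integer_, m)
  }
  if (scen$zero_inflated) x <- x * (runif(m) >= lp$delta)

  T_ <- if (is.null(scen$time)) 1L else scen$time$n_timepoints
  unit <- (seq_len(m) - 1L) %/% T_ + 1L
  n_units_per_trial <- m / T_ / scen$trials$n_trials
  out <- .tbl(
    trial = lp$trial, site = lp$site, year = lp$year, block = lp$block,
    plot = (unit - 1L) %% n_units_per_trial + 1L,
    variety = lp$variety, role = lp$role, time = lp$time, n = n_col,
    response = x, .nrow = m)
  if (truth) {
    out$mu_true <- lp$mu
    out$delta_true <- if (scen$zero_inflated) lp$delta else rep(0, m)
  }
  class(out) <- c("trial_dataset", class(out))
  out
}

# derive a stream of dataset seeds from one master seed
.spawn_seeds <- function(master_seed, n) {
  if (!is.null(master_seed)) set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a batch of independent datasets
#'
#' Each dataset gets its own seed derived from the master seed, so the k-th
#' dataset is identical across runs. Fixed effects stay constant across
#' datasets while every random effect (blocks, trials, reference-variety
#' effects, time vectors) is redrawn per dataset.
#'
#' @param scen An [scenario()].
#' @param n_datasets Number of datasets.
#' @param master_seed Optional integer master seed.
#' @return A list of dataset tibbles (see [simulate_dataset()]).
#' @export
simulate_batch <- function(scen, n_datasets, master_seed = NULL) {
  if (n_datasets < 1) abort("`n_datasets` must be >= 1.")
  seeds <- .spawn_seeds(master_seed, n_datasets)
  lapply(seeds, function(s) simulate_dataset(scen, seed = s))
}

#' Sum repeated measurements per experimental unit
#'
#' Collapses the time dimension by summing the responses of every
#' experimental unit over its time points (the summed count is the usual
#' analysis endpoint for repeated measures). `mu_true` is summed as well;
#' `delta_true` is dropped as it is no longer a per-observation quantity.
#'
#' @param ds A dataset from [simulate_dataset()].
#' @return A dataset tibble with one row per unit (`time` dropped).
#' @export
aggregate_time <- function(ds) {
  keys <- c("trial", "site", "year", "block", "plot", "variety", "role", "n")
  keys <- intersect(keys, names(ds))
  tcount <- table(ds$time)
  if (length(unique(tcount)) != 1L)
    abort("unbalanced time points: every unit must be observed at every time point.")
  out <- ds |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_times = dplyr::n(),
      response = sum(.data$response),
      mu_true = if ("mu_true" %in% names(ds)) sum(.data$mu_true) else NA_real_,
      .groups = "drop")
  if (length(unique(out$n_times)) != 1L)
    abort("unbalanced time points: every unit must be observed at every time point.")
  out$n_times <- NULL
  if (!"mu_true" %in% names(ds)) out$mu_true <- NULL
  out <- out[order(out$trial, out$block, out$plot), ]
  class(out) <- c("trial_dataset", class(tibble()))
  out
}

#' Write or read a trial dataset as CSV
#'
#' Fixed column layout
#' `trial,site,year,block,plot,variety,role,time,n,response,mu_true,delta_true`;
#' inapplicable fields are empty.
#'
#' @param ds A dataset tibble.
#' @param path File path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns the dataset tibble.
#' @export
write_trial_csv <- function(ds, path) {
  cols <- c("trial", "site", "year", "block", "plot", "variety", "role",
            "time", "n", "response", "mu_true", "delta_true")
  for (cc in setdiff(cols, names(ds))) ds[[cc]] <- NA
  write.csv(ds[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  class(out) <- c("trial_dataset", class(out))
  out
}
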