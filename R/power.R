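# analysis registry: each entry takes a dataset and returns TRUE when the
# null hypothesis (no difference / non-equivalence) is rejected
.analysis_fun <- function(analysis, alpha, level, limits) {
  lrt_reject <- function(family) function(ds) {
    stat <- .fast_lrt_stat(ds$response, ds$variety, ds$role, family)
    pchisq(stat, 1, lower.tail = FALSE) < alpha
  }
  tost_reject <- function(family) function(ds) {
    ci <- .profile_ci_core(ds$response, ds$variety, ds$role, family, level)
    !anyNA(ci) && limits[1] < ci[2] && ci[3] < limits[2]
  }
  switch(analysis,
    nb_lrt = lrt_reject("negbin"),
    poisson_lrt = lrt_reject("poisson"),
    quasi_poisson = function(ds)
      .fast_quasi_p(ds$response, ds$variety, ds$role) < alpha,
    log_anova = function(ds)
      .fast_loganova_p(ds$response, ds$variety, ds$role) < alpha,
    tost_poisson = tost_reject("poisson"),
    tost_negbin = tost_reject("negbin"),
    abort(sprintf(
      "unknown analysis '%s'; options: nb_lrt, poisson_lrt, quasi_poisson, log_anova, tost_poisson, tost_negbin.",
      analysis))
  )
}

#' Monte-Carlo power curve over a replication grid
#'
#' For each replication level `N` in `n_grid`, simulates `n_sims` datasets
#' from the scenario (with `N` replicates), runs the chosen analysis, and
#' records the fraction of rejections — the power of a difference test, or
#' the probability of declaring equivalence for the TOST analyses. Repeated
#' measures are summed per unit before analysis. Datasets whose analysis
#' fails are excluded from the denominator and counted in `n_failed`.
#'
#' @param scen An [scenario()]; its `design$n_replicates` is overridden by
#'   the grid.
#' @param analysis One of `"nb_lrt"`, `"poisson_lrt"`, `"quasi_poisson"`,
#'   `"log_anova"`, `"tost_poisson"`, `"tost_negbin"`.
#' @param n_grid Integer vector of replication levels (default the
#'   customary grid 4, 6, 8, 10, 15, 20, 30, 40).
#' @param n_sims Simulated datasets per grid point (>= 100).
#' @param alpha Two-sided significance level of the difference tests.
#' @param level Confidence level of the TOST interval.
#' @param limits Equivalence limits of concern for the TOST analyses.
#' @param seed Optional master seed; every dataset seed derives from it.
#' @return A `power_curve` tibble: one row per `N` with `power`, its
#'   Monte-Carlo standard error `se = sqrt(p (1 - p) / n)`, rejection
#'   count, failures, and the analysis settings.
#' @examples
#' \donttest{
#' sc <- single_trial_scenario("poisson", mu = 10, theta = 2)
#' estimate_power(sc, "poisson_lrt", n_grid = c(4, 8), n_sims = 200, seed = 1)
#' }
#' @export
estimate_power <- function(scen, analysis,
                           n_grid = c(4, 6, 8, 10, 15, 20, 30, 40),
                           n_sims = 1000, alpha = 0.05, level = 0.95,
                           limits = c(0.5, 2), seed = NULL) {
  stopifnot(inherits(scen, "nto_scenario"))
  if (n_sims < 100) abort("`n_sims` must be >= 100.")
  fun <- .analysis_fun(analysis, alpha, level, limits)
  has_time <- !is.null(scen$time) && scen$time$n_timepoints > 1
  seeds <- .spawn_seeds(seed, length(n_grid) * n_sims)
  rows <- vector("list", length(n_grid))
  for (j in seq_along(n_grid)) {
    cfg <- scen
    cfg$design$n_replicates <- as.integer(n_grid[j])
    rej <- 0L; ok <- 0L; fail <- 0L
    for (i in seq_len(n_sims)) {
      ds <- simulate_dataset(cfg, seed = seeds[(j - 1L) * n_sims + i])
      if (has_time) ds <- aggregate_time(ds)
      res <- tryCatch(fun(ds), error = function(e) NA)
      if (is.na(res)) fail <- fail + 1L
      else { ok <- ok + 1L; rej <- rej + as.integer(res) }
    }
    p <- if (ok > 0) rej / ok else NA_real_
    rows[[j]] <- tibble(
      analysis = analysis, n_replicates = n_grid[j], n_sims = n_sims,
      n_failed = fail, rejections = rej, power = p,
      se = sqrt(p * (1 - p) / ok), alpha = alpha)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("power_curve", class(out))
  out
}

#' Replications required to reach a target power
#'
#' Applies isotonic regression to the raw power curve (power is known to be
#' monotone in `N`; Monte-Carlo noise may violate that), then linearly
#' interpolates power between adjacent grid points and reports the smallest
#' `N` reaching the target, rounded to the nearest integer. Values outside
#' the simulated grid are censored and rendered as e.g. `"<=4"` / `">=40"`.
#'
#' @param curve A `power_curve` from [estimate_power()].
#' @param target Target power (default 0.80).
#' @return One-row tibble: numeric `n_required` (the censoring bound when
#'   censored), display `label`, `censored` (`"none"`, `"left"`,
#'   `"right"`), `target`.
#' @export
required_replications <- function(curve, target = 0.80) {
  curve <- curve[order(curve$n_replicates), ]
  keep <- !is.na(curve$power)
  N <- curve$n_replicates[keep]
  p <- isoreg(N, curve$power[keep])$yf
  if (p[1] >= target) {
    res <- list(n = as.numeric(N[1]), label = paste0("<=", N[1]),
                cens = "left")
  } else if (max(p) < target) {
    res <- list(n = as.numeric(N[length(N)]),
                label = paste0(">=", N[length(N)]), cens = "right")
  } else {
    i <- which(p >= target)[1]
    n_star <- N[i - 1] +
      (N[i] - N[i - 1]) * (target - p[i - 1]) / (p[i] - p[i - 1])
    n_int <- round(n_star)
    res <- list(n = n_int, label = as.character(n_int), cens = "none")
  }
  tibble(n_required = res$n, label = res$label, censored = res$cens,
         target = target)
}

#' Required-replication tables for canonical power studies
#'
#' Reproduces the three standard required-replication sweeps over the
#' `N = 4, 6, 8, 10, 15, 20, 30, 40` grid (two-sided `alpha = 0.05`, one
#' additional variety at the comparator mean, target power 0.80):
#'
#' * `"T3"`: negative-binomial difference test at GM/comparator ratio
#'   `theta = 2`, over comparator means `mu` in 1, 2, 5, 10, 20, 40 and
#'   dispersions `omega` in 0.25, 0.5, 1.
#' * `"T4"`: Poisson data; difference-test and equivalence-test blocks over
#'   `theta` in 1, 1.2, ..., 2 and the same `mu` values; equivalence uses a
#'   95% profile-likelihood interval with limits (1/2, 2).
#' * `"T5"`: Poisson-lognormal data (`omega = 0.25`) with a quadratic time
#'   pattern peaking at `mu` (`beta_opt = 0`, `beta_tol = 47.96`, GM peak
#'   `2 mu`); three sampling schemes — a single observation at the peak,
#'   the sum of 5 independent observations at days -14 ... 14, and the sum
#'   of 5 AR1-correlated observations (`rho = 0.8`) — analyzed with a
#'   negative-binomial profile interval against equivalence limits
#'   (1/3, 3).
#'
#' `mu_values`, `theta_values` and `omega_values` subset the sweep for
#' scaled-down runs.
#'
#' @param table `"T3"`, `"T4"` or `"T5"`.
#' @param n_sims Simulated datasets per cell and replication level.
#' @param seed Optional master seed.
#' @param n_grid Replication grid.
#' @param mu_values,theta_values,omega_values Optional subsets of the
#'   sweep values.
#' @param target Target power.
#' @return A tibble with one row per table cell: the cell coordinates,
#'   `block` (difference/equivalence or the sampling scheme), `n_required`,
#'   `label`, `censored`, and the Monte-Carlo standard error at the grid
#'   point nearest the interpolated value.
#' @export
reproduce_table <- function(table = c("T3", "T4", "T5"), n_sims = 1000,
                            seed = NULL,
                            n_grid = c(4, 6, 8, 10, 15, 20, 30, 40),
                            mu_values = NULL, theta_values = NULL,
                            omega_values = NULL, target = 0.80) {
  table <- match.arg(table)
  seeds_master <- .spawn_seeds(seed, 10000L)
  cell_seed <- function(i) seeds_master[i]
  rows <- list(); idx <- 0L

  run_cell <- function(scen, analysis, limits, i) {
    pc <- estimate_power(scen, analysis, n_grid = n_grid, n_sims = n_sims,
                         limits = limits, seed = cell_seed(i))
    rn <- required_replications(pc, target)
    se_near <- pc$se[which.min(abs(pc$n_replicates - rn$n_required))]
    dplyr::mutate(rn, se_nearest = se_near)
  }

  if (table == "T3") {
    mus <- mu_values %||% c(1, 2, 5, 10, 20, 40)
    omegas <- omega_values %||% c(0.25, 0.5, 1)
    for (om in omegas) for (mu in mus) {
      idx <- idx + 1L
      sc <- single_trial_scenario("negbin", mu = mu, theta = 2,
                                  dispersion = om)
      rows[[idx]] <- dplyr::bind_cols(
        tibble(table = "T3", block = "difference", omega = om, mu = mu,
               theta = 2),
        run_cell(sc, "nb_lrt", c(0.5, 2), idx))
    }
  } else if (table == "T4") {
    mus <- mu_values %||% c(1, 2, 5, 10, 20, 40)
    thetas <- theta_values %||% c(1, 1.2, 1.4, 1.6, 1.8, 2)
    for (block in c("difference", "equivalence")) {
      for (th in thetas) for (mu in mus) {
        if (block == "difference" && th == 1) next  # power = alpha, no cell
        if (block == "equivalence" && th == 2) next # at the limit
        idx <- idx + 1L
        sc <- single_trial_scenario("poisson", mu = mu, theta = th)
        rows[[idx]] <- dplyr::bind_cols(
          tibble(table = "T4", block = block, omega = 0, mu = mu,
                 theta = th),
          run_cell(sc,
                   if (block == "difference") "poisson_lrt" else "tost_poisson",
                   c(0.5, 2), idx))
      }
    }
  } else {
    mus <- mu_values %||% c(1, 2, 5, 10, 20, 40)
    schemes <- c("single", "independent", "dependent")
    for (scheme in schemes) for (mu in mus) {
      idx <- idx + 1L
      sc <- repeated_measures_scenario(mu, theta = 2, omega = 0.25,
                                       scheme = scheme)
      rows[[idx]] <- dplyr::bind_cols(
        tibble(table = "T5", block = scheme, omega = 0.25, mu = mu,
               theta = 2),
        run_cell(sc, "tost_negbin", c(1 / 3, 3), idx))
    }
  }
  dplyr::bind_rows(rows)
}

#' Repeated-measures power-study scenario
#'
#' The abundance of the organism follows a quadratic pattern on the log
#' scale with its peak `mu` (GM: `theta * mu`) at day 0 and 60% of the peak
#' at days +-7 (tolerance 47.96), sampled either once at the peak
#' (`"single"`), or at days -14, -7, 0, 7, 14 with independent
#' (`"independent"`) or AR1-correlated (`"dependent"`, `rho = 0.8`)
#' lognormal overdispersion of variance `log(1 + omega)` on the log scale.
#' The single-observation scheme uses the Poisson-lognormal family with the
#' same `omega`.
#'
#' @param mu Peak mean of the comparator.
#' @param theta Multiplicative GM effect.
#' @param omega Overdispersion on the negative-binomial-compatible scale.
#' @param scheme `"single"`, `"independent"` or `"dependent"`.
#' @param rho AR1 correlation for `"dependent"`.
#' @param n_replicates Replicates per variety.
#' @return An `nto_scenario`.
#' @export
repeated_measures_scenario <- function(mu, theta = 2, omega = 0.25,
                                       scheme = c("single", "independent",
                                                  "dependent"),
                                       rho = 0.8, n_replicates = 4) {
  scheme <- match.arg(scheme)
  sigma2 <- log1p(omega)
  if (scheme == "single") {
    sc <- single_trial_scenario("poislognorm", mu = mu, theta = theta,
                                dispersion = omega, n_additional = 1,
                                n_replicates = n_replicates)
    return(sc)
  }
  coef_for <- function(peak) list(beta_max = log(peak), beta_opt = 0,
                                  beta_tol = 47.96)
  vars <- list(
    variety("gm", "gm", time_coef = coef_for(theta * mu)),
    variety("comparator", "comparator", time_coef = coef_for(mu)),
    variety("additional1", "additional", time_coef = coef_for(mu)))
  tspec <- time_spec(
    timepoints = c(-14, -7, 0, 7, 14), pattern = "quadratic",
    correlation = if (scheme == "dependent") "ar1" else "equal",
    rho = if (scheme == "dependent") rho else 0,
    var = sigma2)
  scenario(count_dist("poisson", mu = mu), varieties = vars,
           design = design_spec("crd", n_replicates = n_replicates),
           time = tspec)
}

#' Aligned-text rendering of a required-replication table
#'
#' @param tbl Output of [reproduce_table()].
#' @return Character vector of formatted lines (invisibly printed with
#'   `cat`).
#' @export
format_required_table <- function(tbl) {
  rowvar <- if (all(tbl$table == "T3")) "omega"
            else if (all(tbl$table == "T4")) "theta" else "block"
  colvar <- "mu"
  lines <- character(0)
  for (blk in unique(tbl$block)) {
    sub <- tbl[tbl$block == blk, ]
    wide <- tidyr::pivot_wider(
      sub[, c(rowvar, colvar, "label")],
      names_from = dplyr::all_of(colvar), values_from = "label",
      names_prefix = "mu=")
    lines <- c(lines, sprintf("[%s]", blk),
               utils::capture.output(print(as.data.frame(wide),
                                           row.names = FALSE)), "")
  }
  lines
}
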