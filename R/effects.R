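#' Construct an effect-draw object by hand
#'
#' A realization of every random effect of a scenario. Usually produced by
#' [draw_effects()]; this constructor lets quoted or hypothetical draws be
#' plugged in directly (e.g. to inspect the unit means implied by given
#' block and reference-variety draws).
#'
#' @param trials Tibble with columns `trial`, `site`, `year`, `t_count`,
#'   `t_zero` (trial-level effects, transformed scale).
#' @param blocks Tibble with columns `trial`, `block`, `b_count`, `b_zero`.
#' @param varieties Tibble with columns `trial`, `variety`, `base`, `role`,
#'   `effect_count`, `effect_zero`: the realized per-trial variety effects
#'   (fixed effects for gm/comparator/additional, normal draws for
#'   reference-population members).
#' @param time_coefs Optional tibble with columns `trial`, `variety`,
#'   `b0`, `b1`, `b2`, `z0`, `z1`, `z2`: realized time-polynomial
#'   coefficients (count and zero part).
#' @param v Optional tibble with columns `trial`, `block`, `variety`,
#'   `tindex`, `v_count`, `v_zero`: the repeated-measures random vectors.
#' @return An object of class `effect_draw`.
#' @export
effect_draw <- function(trials, blocks, varieties, time_coefs = NULL,
                        v = NULL) {
  need <- function(df, cols, what) {
    if (!all(cols %in% names(df)))
      abort(sprintf("`%s` must have columns: %s", what,
                    paste(cols, collapse = ", ")))
  }
  need(trials, c("trial", "t_count", "t_zero"), "trials")
  need(blocks, c("trial", "block", "b_count", "b_zero"), "blocks")
  need(varieties, c("trial", "variety", "base", "role", "effect_count",
                    "effect_zero"), "varieties")
  structure(list(trials = as_tibble(trials), blocks = as_tibble(blocks),
                 varieties = as_tibble(varieties),
                 time_coefs = if (!is.null(time_coefs)) as_tibble(time_coefs),
                 v = if (!is.null(v)) as_tibble(v)),
            class = "effect_draw")
}

# expand varieties to instances (reference populations contribute
# n_reference members); deterministic naming and ordering
.variety_instances <- function(scen) {
  out <- lapply(scen$varieties, function(v) {
    if (v$role == "reference" && v$n_reference >= 1) {
      list(variety = paste0(v$name, "_", seq_len(v$n_reference)),
           base = rep(v$name, v$n_reference), role = rep(v$role, v$n_reference))
    } else {
      list(variety = v$name, base = v$name, role = v$role)
    }
  })
  .tbl(variety = unname(unlist(lapply(out, `[[`, "variety"))),
       base = unname(unlist(lapply(out, `[[`, "base"))),
       role = unname(unlist(lapply(out, `[[`, "role"))),
       .nrow = sum(lengths(lapply(out, `[[`, "variety"))))
}

# eigenvalue square root of a PSD matrix (handles the singular rho = 1 case)
.mat_sqrt <- function(V) {
  e <- eigen(V, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

.rnorm_or_zero <- function(n, mean = 0, var = 0) {
  if (all(var == 0) && all(mean == 0)) rep(0, n)
  else if (all(var == 0)) rep(mean, length.out = n)
  else rnorm(n, mean, sqrt(var))
}

#' Draw one realization of all random effects of a scenario
#'
#' Every random effect is drawn independently from its normal law on the
#' transformed scale: trial/site/year effects, block effects (count part
#' and, under zero inflation, zero part, drawn independently),
#' reference-variety effects (two-stage in multi-trial settings: trial
#' reference mean `M ~ N(mean, s1^2)`, member effects `~ N(M, s2^2)`),
#' genotype-by-environment deviations, per-variety time-coefficient draws,
#' and the repeated-measures vectors `v ~ MVN(0, var * V)` per experimental
#' unit.
#'
#' Draws are keyed by variety name (processed in sorted-name order), so
#' permuting the variety list of a scenario does not change the realized
#' effects. Zero-variance components are exactly zero and consume no random
#' numbers.
#'
#' @param scen An [scenario()].
#' @return An [effect_draw()].
#' @export
draw_effects <- function(scen) {
  stopifnot(inherits(scen, "nto_scenario"))
  tr <- scen$trials
  des <- scen$design
  zi <- scen$zero_inflated
  n_trials <- tr$n_trials

  # 1. trial-level effects
  if (tr$kind == "site_by_year") {
    grid <- expand.grid(site = seq_len(tr$n_sites), year = seq_len(tr$n_years))
    s_c <- .rnorm_or_zero(tr$n_sites, 0, tr$site_var)
    y_c <- .rnorm_or_zero(tr$n_years, 0, tr$year_var)
    sy_c <- .rnorm_or_zero(nrow(grid), 0, tr$site_year_var)
    s_z <- if (zi) .rnorm_or_zero(tr$n_sites, 0, tr$zero_site_var) else rep(0, tr$n_sites)
    y_z <- if (zi) .rnorm_or_zero(tr$n_years, 0, tr$zero_year_var) else rep(0, tr$n_years)
    sy_z <- if (zi) .rnorm_or_zero(nrow(grid), 0, tr$zero_site_year_var) else rep(0, nrow(grid))
    trials_tbl <- .tbl(
      trial = seq_len(nrow(grid)), site = grid$site, year = grid$year,
      t_count = s_c[grid$site] + y_c[grid$year] + sy_c,
      t_zero = s_z[grid$site] + y_z[grid$year] + sy_z, .nrow = nrow(grid))
  } else {
    trials_tbl <- .tbl(
      trial = seq_len(n_trials), site = NA_integer_, year = NA_integer_,
      t_count = .rnorm_or_zero(n_trials, 0, tr$trial_var),
      t_zero = if (zi) .rnorm_or_zero(n_trials, 0, tr$zero_trial_var)
               else rep(0, n_trials), .nrow = n_trials)
  }

  # 2. block effects within trials
  nb <- n_trials * des$n_replicates
  blocks_tbl <- .tbl(
    trial = rep(seq_len(n_trials), each = des$n_replicates),
    block = rep(seq_len(des$n_replicates), times = n_trials),
    b_count = .rnorm_or_zero(nb, 0, des$block_var_count),
    b_zero = if (zi) .rnorm_or_zero(nb, 0, des$block_var_zero) else rep(0, nb),
    .nrow = nb)

  # 3. per-trial variety effects, sorted-name order for permutation
  #    invariance
  ord <- order(vapply(scen$varieties, `[[`, character(1), "name"))
  var_rows <- list()
  for (v in scen$varieties[ord]) {
    if (v$role == "reference") {
      M_c <- .rnorm_or_zero(n_trials, v$effect, tr$ref_trial_var)
      eff_c <- matrix(0, n_trials, v$n_reference)
      for (k in seq_len(n_trials))
        eff_c[k, ] <- .rnorm_or_zero(v$n_reference, M_c[k], v$effect_var)
      if (zi) {
        M_z <- .rnorm_or_zero(n_trials, v$zero_effect, tr$zero_ref_trial_var)
        eff_z <- matrix(0, n_trials, v$n_reference)
        for (k in seq_len(n_trials))
          eff_z[k, ] <- .rnorm_or_zero(v$n_reference, M_z[k], v$zero_effect_var)
      } else eff_z <- matrix(0, n_trials, v$n_reference)
      var_rows[[v$name]] <- .tbl(
        trial = rep(seq_len(n_trials), times = v$n_reference),
        variety = rep(paste0(v$name, "_", seq_len(v$n_reference)),
                      each = n_trials),
        base = v$name, role = v$role,
        effect_count = as.vector(eff_c),
        effect_zero = as.vector(eff_z), .nrow = n_trials * v$n_reference)
    } else {
      eff_c <- if (v$gxe_var > 0) .rnorm_or_zero(n_trials, v$effect, v$gxe_var)
               else rep(v$effect, n_trials)
      eff_z <- if (!zi) rep(0, n_trials)
               else if (v$zero_gxe_var > 0)
                 .rnorm_or_zero(n_trials, v$zero_effect, v$zero_gxe_var)
               else rep(v$zero_effect, n_trials)
      var_rows[[v$name]] <- .tbl(
        trial = seq_len(n_trials), variety = v$name, base = v$name,
        role = v$role, effect_count = eff_c, effect_zero = eff_z,
        .nrow = n_trials)
    }
  }
  varieties_tbl <- dplyr::bind_rows(var_rows)

  # 4. realized time-polynomial coefficients
  time_tbl <- NULL
  if (!is.null(scen$time)) {
    draw_coef <- function(coef, coef_var, fallback_level, n) {
      # returns n x 3 matrix of (b0, b1, b2)
      if (is.null(coef)) return(cbind(fallback_level, 0, 0))
      cv <- coef_var %||% list()
      if (!is.null(coef$beta_tol)) {
        bm <- .rnorm_or_zero(n, coef$beta_max, cv$beta_max %||% 0)
        bo <- .rnorm_or_zero(n, coef$beta_opt, cv$beta_opt %||% 0)
        bt <- .rnorm_or_zero(n, coef$beta_tol, cv$beta_tol %||% 0)
        if (any(bt == 0)) abort("realized beta_tol of 0 is not a valid curve.")
        cbind(bm - bo^2 / (2 * bt), bo / bt, -1 / (2 * bt))
      } else {
        cbind(.rnorm_or_zero(n, coef$beta0 %||% 0, cv$beta0 %||% 0),
              .rnorm_or_zero(n, coef$beta1 %||% 0, cv$beta1 %||% 0),
              .rnorm_or_zero(n, coef$beta2 %||% 0, cv$beta2 %||% 0))
      }
    }
    rows <- list()
    for (v in scen$varieties[ord]) {
      inst <- if (v$role == "reference")
        paste0(v$name, "_", seq_len(v$n_reference)) else v$name
      key <- varieties_tbl[varieties_tbl$base == v$name, ]
      n_draw <- nrow(key)
      cc <- draw_coef(v$time_coef, v$time_coef_var, key$effect_count, n_draw)
      zz <- if (zi) draw_coef(v$zero_time_coef, v$zero_time_coef_var,
                              key$effect_zero, n_draw)
            else cbind(key$effect_zero, 0, 0)
      rows[[v$name]] <- .tbl(
        trial = key$trial, variety = key$variety,
        b0 = cc[, 1], b1 = cc[, 2], b2 = cc[, 3],
        z0 = zz[, 1], z1 = zz[, 2], z2 = zz[, 3], .nrow = n_draw)
    }
    time_tbl <- dplyr::bind_rows(rows)
  }

  # 5. repeated-measures random vectors per experimental unit
  v_tbl <- NULL
  if (!is.null(scen$time) && (scen$time$var > 0 || scen$time$zero_var > 0)) {
    T_ <- scen$time$n_timepoints
    V <- correlation_matrix(scen$time)
    S <- .mat_sqrt(V)
    inst <- .variety_instances(scen)
    inst <- inst[order(inst$variety), ]
    units <- merge(blocks_tbl[c("trial", "block")], inst["variety"])
    units <- units[order(units$trial, units$block, units$variety), ]
    n_units <- nrow(units)
    vc <- if (scen$time$var > 0)
      t(S %*% matrix(rnorm(T_ * n_units, 0, sqrt(scen$time$var)), T_, n_units))
      else matrix(0, n_units, T_)
    vz <- if (zi && scen$time$zero_var > 0)
      t(S %*% matrix(rnorm(T_ * n_units, 0, sqrt(scen$time$zero_var)), T_, n_units))
      else matrix(0, n_units, T_)
    v_tbl <- .tbl(
      trial = rep(units$trial, each = T_),
      block = rep(units$block, each = T_),
      variety = rep(units$variety, each = T_),
      tindex = rep(seq_len(T_), times = n_units),
      v_count = as.vector(t(vc)), v_zero = as.vector(t(vz)),
      .nrow = n_units * T_)
  }

  effect_draw(trials_tbl, blocks_tbl, varieties_tbl, time_tbl, v_tbl)
}

#' Assemble unit-level linear predictors and means
#'
#' Combines the fixed and realized random effects of a draw into the
#' transformed-scale linear predictors for every experimental unit and time
#' point: `eta_count = variety effect + block + trial + f_p(t) + v_t`, the
#' unit mean `mu = exp(eta_count)` (for binary families the presence
#' probability `pi = logit^-1(eta_count)`), and the structural-zero
#' probability `delta = logit^-1(eta_zero)`.
#'
#' @param scen An [scenario()].
#' @param draw An [effect_draw()] for it.
#' @return A tibble with one row per trial x block x variety x time point:
#'   keys plus `eta_count`, `eta_zero`, `mu` (response-scale mean of the
#'   count part; `size * pi` for binary families) and `delta`.
#' @export
linear_predictor <- function(scen, draw) {
  stopifnot(inherits(scen, "nto_scenario"), inherits(draw, "effect_draw"))
  inst <- .variety_instances(scen)
  n_inst <- nrow(inst)
  N <- scen$design$n_replicates
  n_trials <- scen$trials$n_trials
  tp <- if (is.null(scen$time)) 1 else scen$time$timepoints
  T_ <- length(tp)

  # unit x time grid ordered trial, block, variety (scenario order), time
  trial <- rep(seq_len(n_trials), each = N * n_inst * T_)
  block <- rep(rep(seq_len(N), each = n_inst * T_), times = n_trials)
  vidx <- rep(rep(seq_len(n_inst), each = T_), times = n_trials * N)
  tindex <- rep(seq_len(T_), times = n_trials * N * n_inst)
  vname <- inst$variety[vidx]

  tkey <- match(trial, draw$trials$trial)
  bkey <- match(paste(trial, block), paste(draw$blocks$trial, draw$blocks$block))
  vkey <- match(paste(trial, vname),
                paste(draw$varieties$trial, draw$varieties$variety))
  t_c <- draw$trials$t_count[tkey]
  t_z <- draw$trials$t_zero[tkey]
  b_c <- draw$blocks$b_count[bkey]
  b_z <- draw$blocks$b_zero[bkey]

  tt <- tp[tindex]
  if (!is.null(draw$time_coefs)) {
    ck <- match(paste(trial, vname),
                paste(draw$time_coefs$trial, draw$time_coefs$variety))
    tc <- draw$time_coefs
    f_c <- tc$b0[ck] + tc$b1[ck] * tt + tc$b2[ck] * tt^2
    f_z <- tc$z0[ck] + tc$z1[ck] * tt + tc$z2[ck] * tt^2
  } else {
    f_c <- draw$varieties$effect_count[vkey]
    f_z <- draw$varieties$effect_zero[vkey]
  }
  if (!is.null(draw$v)) {
    vk <- match(paste(trial, block, vname, tindex),
                paste(draw$v$trial, draw$v$block, draw$v$variety,
                      draw$v$tindex))
    v_c <- draw$v$v_count[vk]
    v_z <- draw$v$v_zero[vk]
  } else v_c <- v_z <- 0

  eta_count <- t_c + b_c + f_c + v_c
  eta_zero <- t_z + b_z + f_z + v_z
  binary <- inherits(scen$distribution, "binary_dist")
  mu <- if (binary) scen$distribution$size * plogis(eta_count)
        else exp(eta_count)
  delta <- if (scen$zero_inflated) plogis(eta_zero) else 0

.tbl(
    trial = trial, site = draw$trials$site[tkey],
    year = draw$trials$year[tkey], block = block,
    variety = vname, role = inst$role[vidx],
    time = tt, eta_count = eta_count, eta_zero = eta_zero,
    mu = mu, delta = delta, .nrow = length(trial))
}
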