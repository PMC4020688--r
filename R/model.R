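#' Specify a variety (or treatment) entering a trial scenario
#'
#' A scenario minimally contains one GM variety and one conventional
#' comparator; further entries are either `additional` varieties with fixed
#' effects, or a `reference` population whose member varieties have their
#' effects drawn from a normal distribution with mean `effect` and variance
#' `effect_var` (they represent the natural variation used to set limits of
#' concern). All effects are on the log scale for counts and the logit
#' scale for probabilities.
#'
#' @param name Unique variety name.
#' @param role One of `"gm"`, `"comparator"`, `"additional"`, `"reference"`.
#' @param effect Log-scale (counts) effect; for a reference population the
#'   population mean.
#' @param effect_var Normal variance of the effect; used for reference
#'   populations (between-variety variance, the within-trial stage in
#'   multi-trial settings).
#' @param zero_effect Optional logit-scale effect for the structural-zero
#'   probability; enables the excess-zero model when non-`NULL`.
#' @param zero_effect_var Variance of `zero_effect` for reference
#'   populations.
#' @param gxe_var,zero_gxe_var Genotype-by-environment variances: in
#'   multi-trial scenarios the per-trial variety effect is drawn from
#'   `N(effect, gxe_var)` so variety differences keep a common basis across
#'   trials.
#' @param n_reference Number of member varieties in a reference population.
#' @param time_coef,zero_time_coef Optional per-variety time-pattern
#'   coefficients (see [time_spec()]): a named list with either
#'   `beta0`/`beta1`/`beta2` or the peak form `beta_max`/`beta_opt`/
#'   `beta_tol`. When given, the polynomial level replaces `effect`.
#' @param time_coef_var,zero_time_coef_var Optional named list of variances
#'   for the time coefficients (reference populations draw each beta from a
#'   normal distribution).
#' @return An object of class `nto_variety`.
#' @examples
#' variety("gm", "gm", effect = log(10))
#' variety("refs", "reference", effect = 1, effect_var = 1, n_reference = 3)
#' @export
variety <- function(name, role = c("comparator", "gm", "additional", "reference"),
                    effect = 0, effect_var = 0,
                    zero_effect = NULL, zero_effect_var = 0,
                    gxe_var = 0, zero_gxe_var = 0,
                    n_reference = 1,
                    time_coef = NULL, zero_time_coef = NULL,
                    time_coef_var = NULL, zero_time_coef_var = NULL) {
  role <- match.arg(role)
  if (any(c(effect_var, zero_effect_var, gxe_var, zero_gxe_var) < 0))
    abort("variance components must be >= 0.")
  if (role == "reference" && (n_reference < 1 || n_reference != round(n_reference)))
    abort("`n_reference` must be a positive integer.")
  structure(
    list(name = as.character(name), role = role,
         effect = effect, effect_var = effect_var,
         zero_effect = zero_effect, zero_effect_var = zero_effect_var,
         gxe_var = gxe_var, zero_gxe_var = zero_gxe_var,
         n_reference = as.integer(n_reference),
         time_coef = time_coef, zero_time_coef = zero_time_coef,
         time_coef_var = time_coef_var,
         zero_time_coef_var = zero_time_coef_var),
    class = "nto_variety"
  )
}

#' Specify the within-trial experimental design
#'
#' Block effects are normal on the transformed scale. A completely
#' randomized design is handled as a randomized block design with zero
#' block variance (replicates relabelled as plots). With an excess-zero
#' model a separate block variance applies to the structural-zero
#' probability.
#'
#' @param layout `"crd"` or `"rcb"`.
#' @param n_replicates Number of replicates (blocks) per trial.
#' @param block_var_count Block variance on the log/logit scale of the
#'   count/presence part (ignored and forced to 0 under `"crd"`).
#' @param block_var_zero Block variance for the structural-zero logit.
#' @return An object of class `nto_design`.
#' @export
design_spec <- function(layout = c("crd", "rcb"), n_replicates,
                        block_var_count = 0, block_var_zero = 0) {
  layout <- match.arg(layout)
  if (n_replicates < 1 || n_replicates != round(n_replicates))
    abort("`n_replicates` must be a positive integer.")
  if (block_var_count < 0 || block_var_zero < 0)
    abort("block variances must be >= 0.")
  if (layout == "crd") block_var_count <- block_var_zero <- 0
  structure(
    list(layout = layout, n_replicates = as.integer(n_replicates),
         block_var_count = block_var_count, block_var_zero = block_var_zero),
    class = "nto_design"
  )
}

#' Specify the multi-environment trial structure
#'
#' Trials either have no further structure (`"multiple"`, with a random
#' trial main effect) or follow a site-by-year layout with random site,
#' year and site-by-year effects. All effects are additive on the
#' transformed scale. Reference populations in multi-trial settings use a
#' two-stage draw: a trial-level reference mean `M ~ N(effect, ref_trial_var)`
#' followed by per-variety effects `N(M, effect_var)`.
#'
#' @param kind `"single"`, `"multiple"` or `"site_by_year"`.
#' @param n_trials Number of trials (`"multiple"`).
#' @param n_sites,n_years Grid dimensions (`"site_by_year"`).
#' @param trial_var,site_var,year_var,site_year_var Variance components for
#'   the count/presence part.
#' @param zero_trial_var,zero_site_var,zero_year_var,zero_site_year_var
#'   Corresponding components for the structural-zero logit.
#' @param ref_trial_var,zero_ref_trial_var Between-trial variance of the
#'   reference-population mean (first stage of the two-stage draw).
#' @return An object of class `nto_trials`.
#' @export
trial_structure <- function(kind = c("single", "multiple", "site_by_year"),
                            n_trials = 1, n_sites = 1, n_years = 1,
                            trial_var = 0, site_var = 0, year_var = 0,
                            site_year_var = 0,
                            zero_trial_var = 0, zero_site_var = 0,
                            zero_year_var = 0, zero_site_year_var = 0,
                            ref_trial_var = 0, zero_ref_trial_var = 0) {
  kind <- match.arg(kind)
  vars <- c(trial_var, site_var, year_var, site_year_var, zero_trial_var,
            zero_site_var, zero_year_var, zero_site_year_var, ref_trial_var,
            zero_ref_trial_var)
  if (any(vars < 0)) abort("variance components must be >= 0.")
  if (kind == "single") {
    if (any(vars > 0))
      abort("a single-trial scenario cannot carry trial-level variance components.")
    n_trials <- 1L
  }
  if (kind == "multiple" && (n_trials < 1 || n_trials != round(n_trials)))
    abort("`n_trials` must be a positive integer.")
  if (kind == "site_by_year") n_trials <- n_sites * n_years
  structure(
    list(kind = kind, n_trials = as.integer(n_trials),
         n_sites = as.integer(n_sites), n_years = as.integer(n_years),
         trial_var = trial_var, site_var = site_var, year_var = year_var,
         site_year_var = site_year_var,
         zero_trial_var = zero_trial_var, zero_site_var = zero_site_var,
         zero_year_var = zero_year_var,
         zero_site_year_var = zero_site_year_var,
         ref_trial_var = ref_trial_var,
         zero_ref_trial_var = zero_ref_trial_var),
    class = "nto_trials"
  )
}

#' Specify repeated measurements in time
#'
#' Units are sampled at the given time points (assumed equidistant; the
#' labels, e.g. `-14, -7, 0, 7, 14` days, are the scale on which the
#' polynomial coefficients are interpreted). The mean at time `t` follows
#' `log(mu_t) = f_p(t) + v_t` with `f_p` constant, linear or quadratic and
#' `v` a zero-mean multivariate normal vector with variance `var` and
#' correlation matrix given by `correlation`:
#' `"independent"` (no extra variability), `"equal"` (all off-diagonals
#' `rho`) or `"ar1"` (`rho^|k-l|`). Equal correlation with `rho = 0`
#' combined with a Poisson family is one lognormal mixing layer, i.e. the
#' Poisson-lognormal.
#'
#' @param timepoints Numeric vector of equidistant time labels.
#' @param pattern `"constant"`, `"linear"` or `"quadratic"`.
#' @param correlation `"independent"`, `"equal"` or `"ar1"`.
#' @param rho Correlation parameter in (-1, 1); for `"equal"` additionally
#'   `rho >= -1/(T-1)` so the matrix stays positive semi-definite.
#' @param var Variance of the time random effect `v` (count part).
#' @param zero_var Variance of `v` for the structural-zero logit.
#' @return An object of class `nto_time`.
#' @export
time_spec <- function(timepoints = 1,
                      pattern = c("constant", "linear", "quadratic"),
                      correlation = c("independent", "equal", "ar1"),
                      rho = 0, var = 0, zero_var = 0) {
  pattern <- match.arg(pattern)
  correlation <- match.arg(correlation)
  if (var < 0 || zero_var < 0) abort("variances must be >= 0.")
  if (correlation == "independent" && (var > 0 || zero_var > 0))
    abort("`correlation = \"independent\"` means no extra time variability; use \"equal\" or \"ar1\" with rho = 0 for uncorrelated random effects.")
  tp <- as.numeric(timepoints)
  if (anyDuplicated(tp)) abort("`timepoints` must be distinct.")
  if (length(tp) > 2 && max(abs(diff(diff(tp)))) > 1e-8 * max(abs(diff(tp))))
    abort("`timepoints` must be equidistant.")
  structure(
    list(timepoints = tp, n_timepoints = length(tp), pattern = pattern,
         correlation = correlation, rho = rho, var = var,
         zero_var = zero_var),
    class = "nto_time"
  )
}

#' Convert the peak parameterization of a quadratic time pattern
#'
#' The quadratic pattern can be given as `f(t) = beta_max -
#' (t - beta_opt)^2 / (2 * beta_tol)`: the extreme value `beta_max` is
#' attained at the optimal time `beta_opt`, and the tolerance `beta_tol`
#' controls the curve width (positive: maximum; negative: minimum). This
#' returns the equivalent polynomial coefficients of
#' `f(t) = beta0 + beta1 * t + beta2 * t^2`.
#'
#' @param beta_max Extreme value of `f`.
#' @param beta_opt Time at which the extreme is attained.
#' @param beta_tol Non-zero tolerance (width) parameter.
#' @return Named list with `beta0`, `beta1`, `beta2`.
#' @examples
#' quad_coefficients(beta_max = log(10), beta_opt = 0, beta_tol = 47.96)
#' @export
quad_coefficients <- function(beta_max, beta_opt, beta_tol) {
  if (beta_tol == 0) abort("`beta_tol` must be non-zero.")
  list(beta0 = beta_max - beta_opt^2 / (2 * beta_tol),
       beta1 = beta_opt / beta_tol,
       beta2 = -1 / (2 * beta_tol))
}

#' Correlation matrix of the repeated-measures random effect
#'
#' @param time A [time_spec()].
#' @return A `T x T` correlation matrix: the identity for
#'   `"independent"`, compound symmetry for `"equal"`, `rho^|k-l|` for
#'   `"ar1"`. Positive semi-definiteness is verified.
#' @examples
#' correlation_matrix(time_spec(1:3, correlation = "ar1", rho = 0.8))
#' @export
correlation_matrix <- function(time) {
  stopifnot(inherits(time, "nto_time"))
  T_ <- time$n_timepoints
  rho <- time$rho
  V <- switch(time$correlation,
    independent = diag(T_),
    equal = {
      if (T_ > 1 && (rho < -1 / (T_ - 1) || rho > 1))
        abort("equal correlation requires rho in [-1/(T-1), 1] for a valid matrix.")
      M <- matrix(rho, T_, T_); diag(M) <- 1; M
    },
    ar1 = {
      if (rho <= -1 || rho >= 1)
        abort("ar1 requires rho in (-1, 1).")
      rho^abs(outer(seq_len(T_), seq_len(T_), "-"))
    }
  )
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    abort("correlation matrix is not positive semi-definite.")
  V
}

#' Assemble a full trial scenario
#'
#' Binds a distribution family (with its common dispersion, shared across
#' varieties and trials), the varieties, the within-trial design, the trial
#' structure and an optional time structure into a validated scenario that
#' [simulate_dataset()] can run.
#'
#' The distribution is given as a template [count_dist()] or
#' [binary_dist()]; its `mu` (or `pi`) slot is only a placeholder — unit
#' means are assembled from the variety/block/trial effects on the
#' transformed scale. Zero inflation is active when any variety carries a
#' `zero_effect`.
#'
#' @param distribution Template [count_dist()] or [binary_dist()].
#' @param varieties List of [variety()] objects: exactly one `gm` and one
#'   `comparator`.
#' @param design A [design_spec()].
#' @param trials A [trial_structure()]; defaults to a single trial.
#' @param time Optional [time_spec()].
#' @return An object of class `nto_scenario`.
#' @examples
#' scenario(
#'   count_dist("negbin", mu = 1, dispersion = 0.5),
#'   varieties = list(
#'     variety("gm", "gm", effect = log(20)),
#'     variety("comp", "comparator", effect = log(10))
#'   ),
#'   design = design_spec("crd", n_replicates = 10)
#' )
#' @export
scenario <- function(distribution, varieties, design,
                     trials = trial_structure("single"), time = NULL) {
  if (!inherits(distribution, c("count_dist", "binary_dist")))
    abort("`distribution` must be a count_dist or binary_dist.")
  if (!all(vapply(varieties, inherits, logical(1), "nto_variety")))
    abort("`varieties` must be a list of variety() objects.")
  if (!inherits(design, "nto_design")) abort("`design` must be a design_spec().")
  if (!inherits(trials, "nto_trials"))
    abort("`trials` must be a trial_structure().")
  if (!is.null(time) && !inherits(time, "nto_time"))
    abort("`time` must be a time_spec() or NULL.")
  roles <- vapply(varieties, `[[`, character(1), "role")
  if (sum(roles == "gm") != 1L || sum(roles == "comparator") != 1L)
    abort("a scenario needs exactly one 'gm' and one 'comparator' variety.")
  nm <- vapply(varieties, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("variety names must be unique.")
  if (trials$kind == "single" &&
      any(vapply(varieties, function(v) v$gxe_var > 0 || v$zero_gxe_var > 0,
                 logical(1))))
    abort("genotype-by-environment variances require a multi-trial structure.")
  names(varieties) <- nm
  zero_inflated <- any(vapply(varieties,
                              function(v) !is.null(v$zero_effect), logical(1)))
  if (zero_inflated &&
      !all(vapply(varieties, function(v) !is.null(v$zero_effect), logical(1))))
    abort("either all or none of the varieties must carry a `zero_effect`.")
  structure(
    list(distribution = distribution, varieties = varieties, design = design,
         trials = trials, time = time, zero_inflated = zero_inflated),
    class = "nto_scenario"
  )
}

#' Single-trial power-study scenario
#'
#' Convenience constructor for the canonical power-study layout: a
#' completely randomized single trial with the comparator and
#' `n_additional` additional varieties at mean `mu` and the GM variety at
#' mean `theta * mu` (so `theta` is the multiplicative GM/comparator
#' difference), all sampled at a single time point.
#'
#' @param family Count family name (see [count_dist()]).
#' @param mu Comparator mean of the count part.
#' @param theta Multiplicative GM effect (GM mean `theta * mu`).
#' @param dispersion Common dispersion (omitted for `"poisson"`).
#' @param delta Structural-zero probability applied to all varieties
#'   (`0` disables zero inflation). Means are means of the count part, so
#'   the marginal means are `(1 - delta) * mu` etc.
#' @param n_replicates Replicates per variety.
#' @param n_additional Number of additional varieties at the comparator
#'   mean.
#' @param dispersion_scale Passed to [count_dist()].
#' @return An `nto_scenario`.
#' @examples
#' single_trial_scenario("negbin", mu = 40, theta = 2, dispersion = 0.25,
#'                       n_replicates = 10)
#' @export
single_trial_scenario <- function(family, mu, theta = 1, dispersion = NULL,
                                  delta = 0, n_replicates = 4,
                                  n_additional = 1,
                                  dispersion_scale = "omega") {
  zero_eff <- if (delta > 0) qlogis(delta) else NULL
  vars <- list(
    variety("gm", "gm", effect = log(theta * mu), zero_effect = zero_eff),
    variety("comparator", "comparator", effect = log(mu),
            zero_effect = zero_eff)
  )
  if (n_additional > 0) {
    for (i in seq_len(n_additional)) {
      vars <- c(vars, list(
        variety(paste0("additional", i), "additional", effect = log(mu),
                zero_effect = zero_eff)))
    }
  }
  scenario(
    distribution = count_dist(family, mu = mu, dispersion = dispersion,
                              dispersion_scale = dispersion_scale,
                              delta = 0),
    varieties = vars,
    design = design_spec("crd", n_replicates = n_replicates)
  )
}

#' @export
print.nto_scenario <- function(x, ...) {
  d <- x$distribution
  cat("<nto_scenario>\n")
  cat(sprintf("  family: %s%s%s\n", d$family,
              if (!is.null(d$dispersion))
                sprintf(" (dispersion %g)", d$dispersion) else "",
              if (x$zero_inflated) " + excess zeros" else ""))
  cat(sprintf("  varieties: %s\n",
              paste(sprintf("%s [%s]", names(x$varieties),
                            vapply(x$varieties, `[[`, character(1), "role")),
                    collapse = ", ")))
  cat(sprintf("  design: %s, N = %d; trials: %s (%d)\n", x$design$layout,
              x$design$n_replicates, x$trials$kind, x$trials$n_trials))
  if (!is.null(x$time))
    cat(sprintf("  time: %d points, %s pattern, %s correlation\n",
                x$time$n_timepoints, x$time$pattern, x$time$correlation))
  invisible(x)
}
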