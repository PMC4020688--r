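# ---- internal likelihood machinery ----------------------------------------
#
# For group-saturated mean structures (one free mean per variety, or a
# pooled GM = comparator mean under the null) the ML estimates of the means
# equal the group sample means for ANY common dispersion: the score in mu_g
# is sum_g (y - mu) / (mu (1 + omega mu)) which vanishes at the sample
# mean. Fitting therefore reduces to a 1-D optimisation of the profile
# likelihood over log(omega).

.nb_loglik <- function(y, mu, log_omega) {
  sum(dnbinom(y, size = exp(-log_omega), mu = mu, log = TRUE))
}

.pois_loglik <- function(y, mu) sum(dpois(y, mu, log = TRUE))

# maximise the NB likelihood given per-observation means; returns list
# (loglik, omega, boundary)
.nb_ml_dispersion <- function(y, mu, lower = -30, upper = 10) {
  opt <- optimize(function(lo) .nb_loglik(y, mu, lo),
                  c(lower, upper), maximum = TRUE, tol = 1e-8)
  ll_pois <- .pois_loglik(y, mu)
  omega <- exp(opt$maximum)
  # boundary omega -> 0: the NB likelihood approaches the Poisson one
  if (omega < 1e-10 || ll_pois >= opt$objective) {
    list(loglik = max(ll_pois, opt$objective), omega = 0, boundary = TRUE)
  } else {
    list(loglik = opt$objective, omega = omega, boundary = FALSE)
  }
}

# fast vector-level group means (sorted by group label)
.fast_means <- function(y, g) {
  gf <- factor(g)
  m <- as.vector(rowsum(y, gf)) / tabulate(gf)
  names(m) <- levels(gf)
  m
}

# LRT statistic for GM = comparator, vector interface (hot Monte-Carlo path)
.fast_lrt_stat <- function(y, variety, role, family) {
  m_full <- .fast_means(y, variety)
  m_null <- m_full
  gmc <- role %in% c("gm", "comparator")
  m_null[unique(variety[gmc])] <- mean(y[gmc])
  m_full <- pmax(m_full, 1e-8)
  m_null <- pmax(m_null, 1e-8)
  mu_f <- m_full[variety]
  mu_n <- m_null[variety]
  if (family == "poisson") {
    ll_f <- .pois_loglik(y, mu_f)
    ll_n <- .pois_loglik(y, mu_n)
  } else {
    ll_f <- .nb_ml_dispersion(y, mu_f)$loglik
    ll_n <- .nb_ml_dispersion(y, mu_n)$loglik
  }
  max(0, 2 * (ll_f - ll_n))
}

.fast_quasi_p <- function(y, variety, role) {
  stat <- .fast_lrt_stat(y, variety, role, "poisson")
  means <- pmax(.fast_means(y, variety), 1e-8)
  mu <- means[variety]
  deviance <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  scale <- max(1, deviance / (length(y) - length(means)))
  pchisq(stat / scale, 1, lower.tail = FALSE)
}

.fast_loganova_p <- function(y0, variety, role) {
  y <- log(y0 + 0.5 * any(y0 == 0))
  gm <- .fast_means(y, variety)
  df_res <- length(y) - length(gm)
  s2 <- sum((y - gm[variety])^2) / df_res
  i_gm <- role == "gm"; i_c <- role == "comparator"
  tval <- (mean(y[i_gm]) - mean(y[i_c])) /
    sqrt(s2 * (1 / sum(i_gm) + 1 / sum(i_c)))
  2 * pt(-abs(tval), df_res)
}

.check_single_occasion <- function(ds) {
  if ("time" %in% names(ds) && length(unique(ds$time)) > 1L)
    abort("dataset has repeated measures; aggregate_time() it before fitting.")
  if (length(unique(ds$trial)) > 1L)
    abort("multi-trial datasets are not supported by the single-trial fits.")
}

.group_means <- function(ds, constraint) {
  means <- .fast_means(ds$response, ds$variety)
  if (constraint == "null") {
    gmc <- ds$role %in% c("gm", "comparator")
    means[unique(ds$variety[gmc])] <- mean(ds$response[gmc])
  }
  means
}

# ---- user-facing fits and tests -------------------------------------------

#' Fit a count model with per-variety means and common dispersion
#'
#' Maximum-likelihood fit of a Poisson or negative-binomial model with one
#' mean per variety (`constraint = "full"`) or with the GM mean constrained
#' to equal the comparator mean while any additional varieties keep free
#' means (`constraint = "null"`). The dispersion `omega` is common to all
#' varieties. Group means are the exact ML estimates; the NB dispersion is
#' profiled numerically. An all-zero variety puts its mean estimate at a
#' small floor and flags the fit as a boundary case.
#'
#' @param ds A single-trial, single-occasion dataset (see
#'   [simulate_dataset()]; sum repeated measures with [aggregate_time()]
#'   first).
#' @param family `"negbin"` or `"poisson"`.
#' @param constraint `"full"` or `"null"` (GM mean = comparator mean).
#' @return An object of class `count_fit` with [tidy()] and [glance()]
#'   methods.
#' @export
fit_count_model <- function(ds, family = c("negbin", "poisson"),
                            constraint = c("full", "null")) {
  family <- match.arg(family)
  constraint <- match.arg(constraint)
  .check_single_occasion(ds)
  if (min(table(ds$variety)) < 2L)
    abort("need at least 2 observations per variety.")
  means <- .group_means(ds, constraint)
  boundary_mean <- any(means == 0)
  means_f <- pmax(means, 1e-8)
  mu_obs <- means_f[ds$variety]
  if (family == "poisson") {
    ll <- .pois_loglik(ds$response, mu_obs)
    omega <- 0; boundary <- FALSE
  } else {
    fit <- .nb_ml_dispersion(ds$response, mu_obs)
    ll <- fit$loglik; omega <- fit$omega; boundary <- fit$boundary
  }
  roles <- ds$role[!duplicated(ds$variety)]
  names(roles) <- ds$variety[!duplicated(ds$variety)]
  structure(
    list(means = tibble(variety = names(means_f),
                        role = unname(roles[names(means_f)]),
                        estimate = unname(means_f)),
         dispersion = omega, loglik = ll, family = family,
         constraint = constraint, converged = TRUE,
         boundary = boundary || boundary_mean,
         n = nrow(ds)),
    class = "count_fit")
}

#' @export
print.count_fit <- function(x, ...) {
  cat(sprintf("<count_fit> %s, %s model; logLik %.3f, dispersion %.4g%s\n",
              x$family, x$constraint, x$loglik, x$dispersion,
              if (x$boundary) " (boundary)" else ""))
  print(x$means)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.count_fit <- function(x, ...) x$means

#' @export
glance.count_fit <- function(x, ...) {
  tibble(family = x$family, constraint = x$constraint,
         dispersion = x$dispersion, logLik = x$loglik, nobs = x$n,
         converged = x$converged, boundary = x$boundary)
}

#' Likelihood-ratio test for a GM-vs-comparator difference
#'
#' Fits the model with and without the restriction that the GM mean equals
#' the comparator mean and forms twice the log-likelihood difference,
#' referred to a chi-squared distribution with 1 degree of freedom.
#'
#' @inheritParams fit_count_model
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
lrt_difference <- function(ds, family = c("negbin", "poisson")) {
  family <- match.arg(family)
  full <- fit_count_model(ds, family, "full")
  null <- fit_count_model(ds, family, "null")
  stat <- max(0, 2 * (full$loglik - null$loglik))
  tibble(method = paste0(family, "_lrt"), statistic = stat, df = 1,
         p_value = pchisq(stat, 1, lower.tail = FALSE))
}

#' Quasi-Poisson scaled likelihood-ratio test
#'
#' The Poisson likelihood-ratio statistic divided by the mean deviance of
#' the full Poisson model whenever that mean deviance exceeds 1 (otherwise
#' the unscaled statistic), referred to chi-squared with 1 df. This mimics
#' an overdispersion-robust quasi-likelihood analysis of count data.
#'
#' @inheritParams fit_count_model
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`, plus the
#'   `scale` applied (the mean deviance, floored at 1).
#' @export
quasi_poisson_test <- function(ds) {
  .check_single_occasion(ds)
  lrt <- lrt_difference(ds, "poisson")
  means <- pmax(.group_means(ds, "full"), 1e-8)
  mu <- means[ds$variety]
  y <- ds$response
  dev_terms <- ifelse(y > 0, y * log(y / mu), 0) - (y - mu)
  deviance <- 2 * sum(dev_terms)
  mean_dev <- deviance / (nrow(ds) - length(means))
  scale <- max(1, mean_dev)
  stat <- lrt$statistic / scale
  tibble(method = "quasi_poisson", statistic = stat, df = 1,
         p_value = pchisq(stat, 1, lower.tail = FALSE), scale = scale)
}

#' Log-transform analysis of variance
#'
#' Log-transforms the counts — after adding 0.5 whenever the dataset
#' contains at least one zero — and performs a one-way analysis of variance
#' on variety. The reported test is the GM-vs-comparator contrast t-test
#' with the pooled residual variance (two-sided).
#'
#' @inheritParams fit_count_model
#' @return One-row tibble: `method`, `statistic` (t), `df`, `p_value`.
#' @export
loganova_test <- function(ds) {
  .check_single_occasion(ds)
  y <- log(ds$response + 0.5 * any(ds$response == 0))
  g <- ds$variety
  k <- length(unique(g))
  df_res <- length(y) - k
  if (df_res < 2) abort("fewer than 2 residual degrees of freedom.")
  gm <- tapply(y, g, mean)
  s2 <- sum((y - gm[g])^2) / df_res
  i_gm <- ds$role == "gm"; i_c <- ds$role == "comparator"
  n1 <- sum(i_gm); n2 <- sum(i_c)
  tval <- (mean(y[i_gm]) - mean(y[i_c])) / sqrt(s2 * (1 / n1 + 1 / n2))
  tibble(method = "log_anova", statistic = tval, df = df_res,
         p_value = 2 * pt(-abs(tval), df_res))
}

# profile log-likelihood of the ratio theta = mu_GM / mu_comp for Poisson:
# the nuisance comparator mean has the closed-form maximiser
# (S_C + S_G) / (n_C + theta n_G); additional varieties drop out.
.pois_profile_dev <- function(log_theta, sC, nC, sG, nG, ll_hat) {
  theta <- exp(log_theta)
  mu <- (sC + sG) / (nC + theta * nG)
  ll <- sC * log(mu) + sG * (log_theta + log(mu)) - mu * (nC + theta * nG)
  2 * (ll_hat - ll)
}

# NB: nuisance (log mu_C, log omega) maximised numerically; additional
# varieties contribute through the common omega with their sample means.
.nb_profile_loglik <- function(log_theta, yG, yC, yA, muA, start) {
  obj <- function(p) {
    muC <- exp(p[1]); om <- exp(p[2]); k <- 1 / om
    -(sum(dnbinom(yC, size = k, mu = muC, log = TRUE)) +
        sum(dnbinom(yG, size = k, mu = exp(log_theta) * muC, log = TRUE)) +
        (if (length(yA)) sum(dnbinom(yA, size = k, mu = muA, log = TRUE))
         else 0))
  }
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 500))
  list(loglik = -opt$value, par = opt$par)
}

#' Profile-likelihood confidence interval for the GM/comparator mean ratio
#'
#' Inverts the likelihood-ratio test for the ratio `theta` of the GM and
#' comparator means: the interval collects all `theta` with profile
#' deviance `2 (lhat - l(theta))` below the chi-squared(1) quantile.
#' Endpoints are found by root bisection on the log-ratio scale to a
#' tolerance of 1e-6. For the Poisson family the profile is closed-form;
#' for the negative binomial the nuisance mean and dispersion are profiled
#' out numerically.
#'
#' @inheritParams fit_count_model
#' @param level Confidence level (default 0.95, the operational TOST
#'   construction at one-sided 2.5%).
#' @return One-row tibble: `estimate` (the ratio), `lower`, `upper`,
#'   `level`, `method`.
#' @export
profile_ci_ratio <- function(ds, family = c("poisson", "negbin"),
                             level = 0.95) {
  family <- match.arg(family)
  .check_single_occasion(ds)
  ci <- .profile_ci_core(ds$response, ds$variety, ds$role, family, level)
  tibble(estimate = ci[1], lower = ci[2], upper = ci[3], level = level,
         method = paste0(family, "_profile"))
}

# vector-interface profile CI; returns c(estimate, lower, upper) (NA on a
# degenerate all-zero arm)
.profile_ci_core <- function(y, variety, role, family, level) {
  crit <- qchisq(level, 1)
  iG <- role == "gm"; iC <- role == "comparator"
  yG <- y[iG]; yC <- y[iC]
  sG <- sum(yG); sC <- sum(yC); nG <- length(yG); nC <- length(yC)
  if (sG == 0 || sC == 0) return(c(NA_real_, NA_real_, NA_real_))
  theta_hat <- (sG / nG) / (sC / nC)
  lt_hat <- log(theta_hat)

  if (family == "poisson") {
    ll_hat <- sC * log(sC / nC) + sG * log(sG / nG) - sC - sG
    dev <- function(lt) .pois_profile_dev(lt, sC, nC, sG, nG, ll_hat) - crit
  } else {
    iA <- !iG & !iC
    yA <- y[iA]
    muA <- if (length(yA)) pmax(.fast_means(yA, variety[iA]), 1e-8)[variety[iA]]
           else numeric(0)
    mC <- sC / nC
    v <- var(c(yC, yG / theta_hat))
    om0 <- max((v - mC) / mC^2, 0.01)
    start <- c(log(mC), log(om0))
    ll_hat <- .nb_profile_loglik(lt_hat, yG, yC, yA, muA, start)$loglik
    dev <- function(lt) {
      2 * (ll_hat - .nb_profile_loglik(lt, yG, yC, yA, muA, start)$loglik) -
        crit
    }
  }

  find_root <- function(direction) {
    step <- 0.25
    lo <- lt_hat
    for (i in seq_len(200)) {
      hi <- lt_hat + direction * step * i
      if (dev(hi) > 0)
        return(uniroot(dev, sort(c(lo, hi)), tol = 1e-6)$root)
      lo <- hi
    }
    abort("profile CI endpoint search did not converge.")
  }
  c(theta_hat, exp(find_root(-1)), exp(find_root(+1)))
}

#' TOST equivalence decision from a confidence interval
#'
#' The null hypothesis of non-equivalence is rejected when the confidence
#' interval for the GM/comparator ratio lies completely inside the
#' equivalence limits (the two one-sided tests construction).
#'
#' @param ci A one-row tibble from [profile_ci_ratio()].
#' @param limits Length-2 numeric `(L, U)` with `0 < L < U`, e.g. the
#'   default limits of concern `c(0.5, 2)`.
#' @return One-row tibble: the interval columns plus `limit_lower`,
#'   `limit_upper` and logical `equivalent`.
#' @examples
#' ci <- tibble::tibble(estimate = 1, lower = 0.6, upper = 1.8,
#'                      level = 0.95, method = "poisson_profile")
#' tost_equivalence(ci, c(0.5, 2))
#' @export
tost_equivalence <- function(ci, limits = c(0.5, 2)) {
  if (length(limits) != 2 || limits[1] <= 0 || limits[1] >= limits[2])
    abort("`limits` must satisfy 0 < L < U.")
  eq <- !is.na(ci$lower) && !is.na(ci$upper) &&
    limits[1] < ci$lower && ci$upper < limits[2]
  dplyr::mutate(ci, limit_lower = limits[1], limit_upper = limits[2],
                equivalent = eq)
}
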