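#' Specify a count distribution for one observational unit
#'
#' Builds a specification of a (possibly zero-inflated) count distribution
#' with marginal mean `mu`. Overdispersion relative to the Poisson is
#' introduced by mixing the Poisson rate with a gamma (`odpoisson`,
#' `negbin`) or lognormal (`poislognorm`) variable:
#'
#' * `poisson`: variance `mu`.
#' * `odpoisson`: gamma mixing with variance proportional to the mean;
#'   marginal variance `phi * mu`, `dispersion` is `phi >= 1`.
#' * `negbin`: gamma mixing with variance `omega * mu^2`; marginal variance
#'   `mu + omega * mu^2`, `dispersion` is `omega >= 0`.
#' * `poislognorm`: lognormal mixing; marginal variance
#'   `mu + (exp(sigma2) - 1) * mu^2`. The dispersion may be given either as
#'   the lognormal variance `sigma2` or on the negative-binomial-compatible
#'   `omega = exp(sigma2) - 1` scale, selected by `dispersion_scale`.
#'
#' A structural-zero proportion `delta` mixes a point mass at zero into the
#' count distribution: the zero-inflated variable equals the count with
#' probability `1 - delta` and zero otherwise.
#'
#' @param family One of `"poisson"`, `"odpoisson"`, `"negbin"`,
#'   `"poislognorm"`.
#' @param mu Positive marginal mean of the count part.
#' @param dispersion Dispersion parameter (`phi`, `omega` or `sigma2`
#'   depending on family and `dispersion_scale`); ignored for `poisson`.
#' @param delta Structural-zero probability in `[0, 1)`.
#' @param dispersion_scale For `poislognorm` only: scale on which
#'   `dispersion` is given, `"omega"` (default) or `"sigma2"`.
#' @return An object of class `count_dist`.
#' @examples
#' count_dist("negbin", mu = 10, dispersion = 0.5)
#' count_dist("poisson", mu = 5, delta = 0.2)
#' @export
count_dist <- function(family = c("poisson", "odpoisson", "negbin", "poislognorm"),
                       mu, dispersion = NULL, delta = 0,
                       dispersion_scale = c("omega", "sigma2")) {
  family <- match.arg(family)
  dispersion_scale <- match.arg(dispersion_scale)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    abort("`mu` must be a single positive number.")
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta >= 1)
    abort("`delta` must be in [0, 1).")
  if (family == "poisson") {
    dispersion <- NULL
  } else {
    if (is.null(dispersion))
      abort(sprintf("family '%s' requires a dispersion parameter.", family))
    if (!is.finite(dispersion))
      abort("`dispersion` must be finite.")
    if (family == "odpoisson" && dispersion < 1)
      abort("odpoisson dispersion phi must be >= 1.")
    if (family %in% c("negbin", "poislognorm") && dispersion < 0)
      abort(sprintf("%s dispersion must be >= 0.", family))
  }
  sigma2 <- NULL
  if (family == "poislognorm") {
    # canonical internal scale is sigma2
    sigma2 <- if (dispersion_scale == "sigma2") dispersion else log1p(dispersion)
  }
  structure(
    list(family = family, mu = mu, dispersion = dispersion,
         dispersion_scale = dispersion_scale, sigma2 = sigma2, delta = delta),
    class = "count_dist"
  )
}

#' Specify a presence/absence distribution for one observational unit
#'
#' The response is the number of plants, out of `size`, on which an organism
#' is present. Overdispersion relative to the binomial arises by giving the
#' presence probability its own distribution: a beta (`betabinom`, variance
#' `size * pi * (1 - pi) * (1 + (size - 1) * phi)` with intraclass
#' correlation `phi`) or a normal on the logit scale (`binlogitnorm`, with
#' logit-scale variance `sigma2`; probabilities require numerical
#' integration).
#'
#' @param family One of `"binomial"`, `"betabinom"`, `"binlogitnorm"`.
#' @param size Number of plants (binomial trials) per unit.
#' @param pi Success probability in (0, 1). For `binlogitnorm` this is the
#'   logit-scale location transformed back, i.e. the conditional probability
#'   at a zero random effect; use [match_logitnormal()] to calibrate
#'   marginal moments.
#' @param dispersion Intraclass correlation `phi` in `[0, 1)` for
#'   `betabinom`; logit-normal variance `sigma2 >= 0` for `binlogitnorm`.
#' @param delta Structural-zero probability in `[0, 1)`.
#' @return An object of class `binary_dist`.
#' @examples
#' binary_dist("betabinom", size = 16, pi = 0.25, dispersion = 0.1)
#' @export
binary_dist <- function(family = c("binomial", "betabinom", "binlogitnorm"),
                        size, pi, dispersion = NULL, delta = 0) {
  family <- match.arg(family)
  if (!is.numeric(size) || length(size) != 1L || size < 1 || size != round(size))
    abort("`size` must be a positive integer.")
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi >= 1)
    abort("`pi` must be in (0, 1).")
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta >= 1)
    abort("`delta` must be in [0, 1).")
  if (family == "binomial") {
    dispersion <- NULL
  } else {
    if (is.null(dispersion))
      abort(sprintf("family '%s' requires a dispersion parameter.", family))
    if (family == "betabinom" && (dispersion < 0 || dispersion >= 1))
      abort("betabinom intraclass correlation phi must be in [0, 1).")
    if (family == "binlogitnorm" && dispersion < 0)
      abort("binlogitnorm sigma2 must be >= 0.")
  }
  structure(
    list(family = family, size = as.integer(size), pi = pi,
         dispersion = dispersion, delta = delta),
    class = "binary_dist"
  )
}

#' Family-native parameters of a distribution specification
#'
#' Converts the mean-scale parameterization (`mu` plus a dispersion) into
#' the parameters used for direct sampling: the gamma mixing law for the
#' overdispersed Poisson, size/probability for the negative binomial, the
#' lognormal location for the Poisson-lognormal, and the beta shapes for the
#' beta-binomial.
#'
#' @param spec A [count_dist()] or [binary_dist()] specification.
#' @return A named list of native parameters; contents depend on the family.
#' @examples
#' native_params(count_dist("negbin", mu = 1, dispersion = 1))
#' @export
native_params <- function(spec) UseMethod("native_params")

#' @export
native_params.count_dist <- function(spec) {
  switch(spec$family,
    poisson = list(family = "poisson", lambda = spec$mu),
    odpoisson = {
      phi <- spec$dispersion
      if (phi == 1) {
        list(family = "odpoisson", degenerate = TRUE, lambda = spec$mu)
      } else {
        # gamma mixing: mean mu, variance (phi - 1) * mu
        list(family = "odpoisson", degenerate = FALSE,
             shape = spec$mu / (phi - 1), scale = phi - 1,
             size = spec$mu / (phi - 1), prob = 1 / phi)
      }
    },
    negbin = {
      omega <- spec$dispersion
      if (omega == 0) {
        list(family = "negbin", degenerate = TRUE, lambda = spec$mu)
      } else {
        k <- 1 / omega
        list(family = "negbin", degenerate = FALSE,
             size = k, prob = k / (k + spec$mu))
      }
    },
    poislognorm = {
      s2 <- spec$sigma2
      list(family = "poislognorm", lambda = log(spec$mu) - s2 / 2, sigma2 = s2)
    }
  )
}

#' @export
native_params.binary_dist <- function(spec) {
  switch(spec$family,
    binomial = list(family = "binomial", size = spec$size, prob = spec$pi),
    betabinom = {
      phi <- spec$dispersion
      if (phi == 0) {
        list(family = "betabinom", degenerate = TRUE,
             size = spec$size, prob = spec$pi)
      } else {
        list(family = "betabinom", degenerate = FALSE, size = spec$size,
             a = spec$pi * (1 - phi) / phi,
             b = (1 - spec$pi) * (1 - phi) / phi)
      }
    },
    binlogitnorm = list(family = "binlogitnorm", size = spec$size,
                        eta = qlogis(spec$pi), sigma2 = spec$dispersion)
  )
}

# Gauss-Hermite nodes/weights, cached per order. Used to integrate out the
# normal random effect of the poislognorm and binlogitnorm families.
.gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(order) {
  key <- as.character(order)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(order)
  .gh_cache[[key]]
}

# E[g(Z)], Z ~ N(0,1), for vectorised g returning a matrix (rows = nodes)
.gh_expect <- function(g, order) {
  rule <- gh_rule(order)
  w <- rule$w / sqrt(pi)
  z <- sqrt(2) * rule$x
  vals <- vapply(seq_along(z), function(i) g(z[i]), numeric(length(g(z[1]))))
  if (is.matrix(vals)) as.vector(vals %*% w) else sum(vals * w)
}

#' Probability mass function of a count or presence/absence specification
#'
#' Evaluates `P(Y = x)` under the (possibly zero-inflated) family. With
#' structural-zero probability `delta`, the zero-inflated mass is
#' `delta * I(x = 0) + (1 - delta) * P_c(X = x)` where `P_c` is the count
#' part. Families with a normal random effect (`poislognorm`,
#' `binlogitnorm`) are integrated by fixed-order Gauss-Hermite quadrature.
#'
#' @param spec A [count_dist()] or [binary_dist()].
#' @param x Vector of non-negative integers (at most `size` for binary
#'   families).
#' @param gh_order Quadrature order for the logit-/log-normal mixtures.
#' @return Numeric vector of probabilities.
#' @examples
#' dist_pmf(count_dist("poisson", mu = 4), 0)         # exp(-4)
#' dist_pmf(count_dist("negbin", mu = 1, dispersion = 1), 0)  # 0.5
#' @export
dist_pmf <- function(spec, x, gh_order = 50) {
  if (any(x < 0)) abort("`x` must be non-negative.")
  if (any(x != round(x))) abort("`x` must be integer-valued.")
  if (inherits(spec, "binary_dist") && any(x > spec$size))
    abort("`x` exceeds the number of binomial trials `size`.")
  p_count <- .pmf_count_part(spec, x, gh_order)
  d <- spec$delta
  (1 - d) * p_count + d * as.numeric(x == 0)
}

.pmf_count_part <- function(spec, x, gh_order) {
  np <- native_params(spec)
  switch(np$family,
    poisson = dpois(x, np$lambda),
    odpoisson = if (isTRUE(np$degenerate)) dpois(x, np$lambda)
                else dnbinom(x, size = np$size, prob = np$prob),
    negbin = if (isTRUE(np$degenerate)) dpois(x, np$lambda)
             else dnbinom(x, size = np$size, prob = np$prob),
    poislognorm = {
      if (np$sigma2 == 0) return(dpois(x, exp(np$lambda)))
      s <- sqrt(np$sigma2)
      .gh_expect(function(z) dpois(x, exp(np$lambda + s * z)), gh_order)
    },
    binomial = dbinom(x, np$size, np$prob),
    betabinom = {
      if (isTRUE(np$degenerate)) return(dbinom(x, np$size, np$prob))
      n <- np$size
      exp(lchoose(n, x) + lbeta(x + np$a, n - x + np$b) - lbeta(np$a, np$b))
    },
    binlogitnorm = {
      if (np$sigma2 == 0) return(dbinom(x, np$size, plogis(np$eta)))
      s <- sqrt(np$sigma2)
      .gh_expect(function(z) dbinom(x, np$size, plogis(np$eta + s * z)),
                 gh_order)
    }
  )
}

#' Draw random samples from a distribution specification
#'
#' Overdispersed families are sampled through their mixing representation
#' (gamma or lognormal rate for counts, beta or logit-normal probability for
#' presence/absence). Zero inflation is applied as an independent
#' Bernoulli(`delta`) structural-zero mask.
#'
#' @param spec A [count_dist()] or [binary_dist()].
#' @param m Number of draws.
#' @return Integer-valued numeric vector of length `m`.
#' @examples
#' set.seed(1)
#' mean(dist_sample(count_dist("poisson", mu = 10), 1e4))
#' @export
dist_sample <- function(spec, m) {
  if (m < 1) abort("`m` must be >= 1.")
  np <- native_params(spec)
  x <- switch(np$family,
    poisson = rpois(m, np$lambda),
    odpoisson = if (isTRUE(np$degenerate)) rpois(m, np$lambda)
                else rpois(m, rgamma(m, shape = np$shape, scale = np$scale)),
    negbin = if (isTRUE(np$degenerate)) rpois(m, np$lambda)
             else rnbinom(m, size = np$size, prob = np$prob),
    poislognorm = if (np$sigma2 == 0) rpois(m, exp(np$lambda))
                  else rpois(m, exp(rnorm(m, np$lambda, sqrt(np$sigma2)))),
    binomial = rbinom(m, np$size, np$prob),
    betabinom = if (isTRUE(np$degenerate)) rbinom(m, np$size, np$prob)
                else rbinom(m, np$size, rbeta(m, np$a, np$b)),
    binlogitnorm = if (np$sigma2 == 0) rbinom(m, np$size, plogis(np$eta))
                   else rbinom(m, np$size,
                               plogis(rnorm(m, np$eta, sqrt(np$sigma2))))
  )
  if (spec$delta > 0) x <- x * (runif(m) >= spec$delta)
  x
}

#' Analytic mean and variance of a distribution specification
#'
#' Returns the marginal moments of the (possibly zero-inflated) family. For
#' a zero-inflated variable with count-part mean `m` and variance `v`, the
#' mean is `(1 - delta) * m` and the variance
#' `(1 - delta) * v + delta * (1 - delta) * m^2`. Moments of the
#' binomial-logitnormal have no closed form and are computed by quadrature.
#'
#' @inheritParams dist_pmf
#' @return A one-row tibble with columns `mean` and `variance`.
#' @export
dist_moments <- function(spec, gh_order = 50) {
  cm <- .count_part_moments(spec, gh_order)
  d <- spec$delta
  tibble(mean = (1 - d) * cm[1],
         variance = (1 - d) * cm[2] + d * (1 - d) * cm[1]^2)
}

.count_part_moments <- function(spec, gh_order = 50) {
  if (inherits(spec, "count_dist")) {
    mu <- spec$mu
    v <- switch(spec$family,
      poisson = mu,
      odpoisson = spec$dispersion * mu,
      negbin = mu + spec$dispersion * mu^2,
      poislognorm = mu + (exp(spec$sigma2) - 1) * mu^2
    )
    c(mu, v)
  } else {
    n <- spec$size
    switch(spec$family,
      binomial = c(n * spec$pi, n * spec$pi * (1 - spec$pi)),
      betabinom = {
        p <- spec$pi; phi <- spec$dispersion
        c(n * p, n * p * (1 - p) * (1 + (n - 1) * phi))
      },
      binlogitnorm = {
        np <- native_params(spec)
        s <- sqrt(np$sigma2)
        m1 <- .gh_expect(function(z) plogis(np$eta + s * z), gh_order)
        m2 <- .gh_expect(function(z) plogis(np$eta + s * z)^2, gh_order)
        c(n * m1, n * (m1 - m2) + n^2 * (m2 - m1^2))
      }
    )
  }
}

#' Moments of the zero-inflated Poisson distribution
#'
#' With Poisson mean `mu` and structural-zero probability `delta`, the
#' zero-inflated variable has mean `mu * (1 - delta)` and variance
#' `mu * (1 - delta) * (1 + delta * mu)`.
#'
#' @param mu Positive Poisson mean of the count part.
#' @param delta Structural-zero probability in `[0, 1)`.
#' @return A one-row tibble with columns `mean` and `variance`.
#' @examples
#' zi_poisson_moments(5, 0.2)  # mean 4, variance 8
#' @export
zi_poisson_moments <- function(mu, delta) {
  if (mu <= 0) abort("`mu` must be positive.")
  if (delta < 0 || delta >= 1) abort("`delta` must be in [0, 1).")
  tibble(mean = mu * (1 - delta),
         variance = mu * (1 - delta) * (1 + delta * mu))
}

#' Calibrate a binomial-logitnormal to target marginal moments
#'
#' Solves for the logit-scale location `eta` and variance `sigma2` such
#' that the binomial-logitnormal with `size` trials has marginal mean
#' `size * pi` and variance `omega * size * pi * (1 - pi)`. The moments are
#' evaluated by Gauss-Hermite quadrature; the solution is found by nested
#' root finding (inner: `eta` matches the mean at fixed `sigma2`; outer:
#' `sigma2` matches the variance).
#'
#' The achievable overdispersion is bounded: as `sigma2` grows the
#' distribution concentrates on 0 and `size`, with maximal variance factor
#' `omega = size`. Targets at or beyond that bound fail with a diagnostic
#' error.
#'
#' @param size Number of binomial trials.
#' @param pi Target marginal mean probability in (0, 1).
#' @param omega Target variance inflation factor, `>= 1`.
#' @param gh_order Quadrature order.
#' @param tol Relative tolerance on the matched moments.
#' @return A list with `eta`, `sigma2`, and the achieved `mean` and
#'   `variance`.
#' @examples
#' match_logitnormal(16, 0.25, 3)
#' @export
match_logitnormal <- function(size, pi, omega, gh_order = 50, tol = 1e-9) {
  if (pi <= 0 || pi >= 1) abort("`pi` must be in (0, 1).")
  if (omega < 1) abort("`omega` must be >= 1 (no underdispersion).")
  if (omega >= size)
    abort(sprintf(
      "target omega = %g is not achievable: binomial-logitnormal variance is bounded by omega = size = %d.",
      omega, size))
  if (omega == 1)
    return(list(eta = qlogis(pi), sigma2 = 0,
                mean = size * pi, variance = size * pi * (1 - pi)))
  moments_at <- function(eta, s2) {
    s <- sqrt(s2)
    m1 <- .gh_expect(function(z) plogis(eta + s * z), gh_order)
    m2 <- .gh_expect(function(z) plogis(eta + s * z)^2, gh_order)
    c(mean = size * m1, variance = size * (m1 - m2) + size^2 * (m2 - m1^2))
  }
  eta_for <- function(s2) {
    # mean is increasing in eta; bracket generously
    uniroot(function(e) moments_at(e, s2)[1] - size * pi,
            lower = qlogis(pi) - 10 * (1 + sqrt(s2)),
            upper = qlogis(pi) + 10 * (1 + sqrt(s2)),
            tol = tol)$root
  }
  target_var <- omega * size * pi * (1 - pi)
  gap <- function(s2) moments_at(eta_for(s2), s2)[2] - target_var
  # variance is increasing in sigma2; expand the upper bracket if needed
  hi <- 4
  while (gap(hi) < 0 && hi < 400) hi <- hi * 2
  if (gap(hi) < 0)
    abort("match_logitnormal did not converge: variance target not reached within the sigma2 search range.")
  s2 <- uniroot(gap, lower = 1e-12, upper = hi, tol = tol)$root
  eta <- eta_for(s2)
  mm <- moments_at(eta, s2)
  rel_err <- max(abs(mm[1] - size * pi) / (size * pi),
                 abs(mm[2] - target_var) / target_var)
  if (rel_err > 1e-6)
    abort(sprintf("match_logitnormal did not converge: relative moment error %.2e.", rel_err))
  list(eta = eta, sigma2 = s2, mean = unname(mm[1]), variance = unname(mm[2]))
}
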