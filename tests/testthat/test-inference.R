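# deterministic fixture: counts with mild overdispersion
make_fixture <- function(seed = 101, N = 15, mu = 10, theta = 1.8,
                         omega = 0.4) {
  simulate_dataset(single_trial_scenario("negbin", mu = mu, theta = theta,
                                         dispersion = omega,
                                         n_replicates = N), seed = seed)
}

test_that("ML means equal group sample means and the LRT is zero under identical arms", {
  ds <- make_fixture()
  fit <- fit_count_model(ds, "poisson", "full")
  obs <- c(tapply(ds$response, ds$variety, mean))
  expect_equal(setNames(fit$means$estimate, fit$means$variety),
               obs[fit$means$variety])
  # duplicate the comparator counts into the GM arm: statistic must be 0
  ds2 <- ds
  ds2$response[ds2$role == "gm"] <- ds2$response[ds2$role == "comparator"]
  expect_equal(lrt_difference(ds2, "negbin")$statistic, 0)
  expect_equal(lrt_difference(ds2, "poisson")$statistic, 0)
  # null loglik never exceeds full loglik
  expect_lte(fit_count_model(ds, "negbin", "null")$loglik,
             fit_count_model(ds, "negbin", "full")$loglik)
})

test_that("negative-binomial fit agrees with an independent glm.nb fit", {
  skip_if_not_installed("MASS")
  ds <- make_fixture(seed = 7, N = 30)
  fit <- fit_count_model(ds, "negbin", "full")
  ref <- MASS::glm.nb(response ~ 0 + factor(variety), data = ds)
  mu_ref <- exp(coef(ref))
  names(mu_ref) <- levels(factor(ds$variety))
  expect_equal(setNames(fit$means$estimate, fit$means$variety),
               mu_ref[fit$means$variety], tolerance = 1e-5)
  expect_equal(fit$dispersion, 1 / ref$theta, tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("tidy and glance summarise fits", {
  fit <- fit_count_model(make_fixture(), "negbin", "full")
  td <- tidy(fit)
  expect_named(td, c("variety", "role", "estimate"))
  gl <- glance(fit)
  expect_equal(gl$constraint, "full")
  expect_true(gl$converged)
})

test_that("quasi-Poisson scaling kicks in only above mean deviance 1", {
  ds <- make_fixture(seed = 3, N = 25, omega = 1)
  qp <- quasi_poisson_test(ds)
  plain <- lrt_difference(ds, "poisson")
  expect_gt(qp$scale, 1)
  expect_equal(qp$statistic * qp$scale, plain$statistic, tolerance = 1e-10)
  # near-equidispersed Poisson data usually gives mean deviance <= 1
  ds0 <- simulate_dataset(single_trial_scenario("poisson", 20,
                                                n_replicates = 8), seed = 12)
  qp0 <- quasi_poisson_test(ds0)
  if (qp0$scale == 1)
    expect_equal(qp0$statistic, lrt_difference(ds0, "poisson")$statistic)
})

test_that("log-ANOVA transform adds 0.5 only when zeros occur; contrast is calibrated", {
  ds <- make_fixture(seed = 5)
  ds$response <- ds$response + 1L  # no zeros
  res <- loganova_test(ds)
  y <- log(ds$response)
  g <- ds$variety
  s2 <- sum((y - tapply(y, g, mean)[g])^2) / (length(y) - 3)
  tman <- (mean(y[ds$role == "gm"]) - mean(y[ds$role == "comparator"])) /
    sqrt(s2 * 2 / 15)
  expect_equal(res$statistic, tman)
  # type-I error under a lognormal-mean null
  set.seed(77)
  rej <- mean(replicate(800, {
    d <- data.frame(response = rpois(30, exp(rnorm(30, 2, 0.4))),
                    variety = rep(c("gm", "c", "a"), each = 10),
                    role = rep(c("gm", "comparator", "additional"), each = 10),
                    trial = 1, time = 1)
    .res <- loganova_test(d)$p_value
    .res < 0.05
  }))
  expect_lt(abs(rej - 0.05), 4 * sqrt(0.05 * 0.95 / 800))
})

test_that("Poisson profile interval matches a brute-force profile scan", {
  ds <- simulate_dataset(single_trial_scenario("poisson", 5, theta = 1.4,
                                               n_replicates = 10), seed = 9)
  ci <- profile_ci_ratio(ds, "poisson")
  # independent oracle: profile the likelihood on a fine theta grid,
  # maximizing the nuisance mean numerically
  y_g <- ds$response[ds$role == "gm"]; y_c <- ds$response[ds$role == "comparator"]
  prof <- function(th) {
    opt <- optimize(function(m)
      sum(dpois(y_c, m, log = TRUE)) + sum(dpois(y_g, th * m, log = TRUE)),
      c(1e-3, 60), maximum = TRUE, tol = 1e-10)
    opt$objective
  }
  grid <- seq(0.2, 5, by = 5e-4)
  ll <- vapply(grid, prof, numeric(1))
  inside <- grid[2 * (max(ll) - ll) <= qchisq(0.95, 1)]
  expect_equal(ci$lower, min(inside), tolerance = 2e-3)
  expect_equal(ci$upper, max(inside), tolerance = 2e-3)
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
})

test_that("profile interval width shrinks with replication and coverage is nominal", {
  med_width <- vapply(c(4, 10, 40), function(N) {
    w <- vapply(1:80, function(s) {
      ds <- simulate_dataset(single_trial_scenario("poisson", 5,
                                                   n_replicates = N),
                             seed = 1000 + s)
      ci <- profile_ci_ratio(ds, "poisson")
      log(ci$upper / ci$lower)
    }, numeric(1))
    median(w)
  }, numeric(1))
  expect_true(all(diff(med_width) < 0))
  set.seed(5150)
  cover <- mean(vapply(1:800, function(s) {
    ds <- simulate_dataset(single_trial_scenario("poisson", 5,
                                                 n_replicates = 20),
                           seed = 40000 + s)
    ci <- profile_ci_ratio(ds, "poisson")
    ci$lower <= 1 && 1 <= ci$upper
  }, logical(1)))
  expect_lt(abs(cover - 0.95), 4 * sqrt(0.95 * 0.05 / 800))
})

test_that("negbin profile interval brackets the estimate and matches Poisson at omega ~ 0", {
  ds <- simulate_dataset(single_trial_scenario("poisson", 20, theta = 1.5,
                                               n_replicates = 15), seed = 44)
  ci_p <- profile_ci_ratio(ds, "poisson")
  ci_nb <- profile_ci_ratio(ds, "negbin")
  expect_true(ci_nb$lower <= ci_nb$estimate && ci_nb$estimate <= ci_nb$upper)
  # equidispersed data: the NB profile should land close to the Poisson one
  expect_equal(ci_nb$lower, ci_p$lower, tolerance = 0.08)
  expect_equal(ci_nb$upper, ci_p$upper, tolerance = 0.08)
})

test_that("TOST decision is containment of the interval in the limits", {
  ci <- tibble::tibble(estimate = 1, lower = 0.6, upper = 1.8, level = 0.95,
                       method = "poisson_profile")
  expect_true(tost_equivalence(ci, c(0.5, 2))$equivalent)
  ci$lower <- 0.4; ci$upper <- 1.2
  expect_false(tost_equivalence(ci, c(0.5, 2))$equivalent)
  expect_error(tost_equivalence(ci, c(2, 0.5)), "L < U")
})
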