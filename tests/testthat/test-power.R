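test_that("difference-test power equals the significance level under the null", {
  sc <- single_trial_scenario("poisson", mu = 10, theta = 1)
  pc <- estimate_power(sc, "poisson_lrt", n_grid = c(6, 20), n_sims = 600,
                       seed = 314)
  for (p in pc$power)
    expect_lt(abs(p - 0.05), 4 * sqrt(0.05 * 0.95 / 600))
  expect_equal(pc$se, sqrt(pc$power * (1 - pc$power) / 600))
})

test_that("required replications interpolate, round and censor as specified", {
  curve <- function(N, p) {
    out <- tibble::tibble(analysis = "x", n_replicates = N,
                          n_sims = 1000, n_failed = 0,
                          rejections = round(p * 1000), power = p,
                          se = sqrt(p * (1 - p) / 1000), alpha = 0.05)
    class(out) <- c("power_curve", class(out))
    out
  }
  # stated interpolation example: 0.75 at N = 20, 0.82 at N = 30 -> 27
  rn <- required_replications(curve(c(10, 20, 30), c(0.5, 0.75, 0.82)))
  expect_equal(rn$n_required, 27)
  expect_equal(rn$label, "27")
  rn <- required_replications(curve(c(4, 6, 8), c(0.9, 0.95, 0.99)))
  expect_equal(rn$label, "<=4")
  expect_equal(rn$censored, "left")
  rn <- required_replications(curve(c(20, 30, 40), c(0.3, 0.5, 0.7)))
  expect_equal(rn$label, ">=40")
  expect_equal(rn$censored, "right")
  # non-monotone noise is isotonized, not an error
  rn <- required_replications(curve(c(4, 6, 8, 10), c(0.5, 0.84, 0.78, 0.9)))
  expect_equal(rn$censored, "none")
  expect_true(rn$n_required >= 4 && rn$n_required <= 10)
})

test_that("failed fits are excluded from the denominator and reported", {
  sc <- single_trial_scenario("poisson", mu = 10, theta = 2)
  pc <- estimate_power(sc, "poisson_lrt", n_grid = 8, n_sims = 150, seed = 2)
  expect_equal(pc$n_failed, 0)
  expect_error(estimate_power(sc, "nope", n_grid = 4, n_sims = 100),
               "unknown analysis")
  expect_error(estimate_power(sc, "poisson_lrt", n_grid = 4, n_sims = 10),
               "n_sims")
})

test_that("table reproduction returns the expected cells on a scaled grid", {
  tbl <- reproduce_table("T3", n_sims = 150, seed = 8, n_grid = c(4, 10, 20),
                         mu_values = c(10, 40), omega_values = 0.25)
  expect_equal(nrow(tbl), 2)
  expect_true(all(tbl$block == "difference"))
  expect_true(all(tbl$label %in% c(as.character(1:40),
                                   paste0("<=", 4), paste0(">=", 20))))
  txt <- format_required_table(tbl)
  expect_true(any(grepl("mu=40", txt)))
  tbl4 <- reproduce_table("T4", n_sims = 120, seed = 9, n_grid = c(4, 10),
                          mu_values = 20, theta_values = c(1, 2))
  # theta = 1 only enters the equivalence block, theta = 2 only the difference
  expect_equal(sort(tbl4$block), c("difference", "equivalence"))
})

test_that("repeated-measures scenario encodes the quadratic peak pattern", {
  sc <- repeated_measures_scenario(10, theta = 2, omega = 0.25,
                                   scheme = "dependent")
  expect_equal(sc$time$timepoints, c(-14, -7, 0, 7, 14))
  expect_equal(sc$time$var, log(1.25))
  expect_equal(sc$time$rho, 0.8)
  cf <- sc$varieties$comparator$time_coef
  f <- function(t) cf$beta_max - (t - cf$beta_opt)^2 / (2 * cf$beta_tol)
  expect_equal(exp(f(7) - f(0)), 0.6, tolerance = 1e-3)
  # single-observation scheme reduces to a Poisson-lognormal unit
  sc1 <- repeated_measures_scenario(10, scheme = "single")
  expect_equal(sc1$distribution$family, "poislognorm")
  expect_null(sc1$time)
})

test_that("equal-correlation zero-rho time effects reproduce lognormal mixing variance", {
  # marginal counts from the time model: Poisson(exp(beta0 + v)),
  # v ~ N(0, s2) independent per observation
  s2 <- 0.4; beta0 <- log(6)
  sc <- scenario(
    count_dist("poisson", 1),
    varieties = list(variety("gm", "gm", effect = beta0),
                     variety("c", "comparator", effect = beta0)),
    design = design_spec("crd", 2500),
    time = time_spec(1:4, correlation = "equal", rho = 0, var = s2))
  ds <- simulate_dataset(sc, seed = 61)
  mu_marg <- exp(beta0 + s2 / 2)
  omega <- exp(s2) - 1
  expect_moments_mc(ds$response, mu_marg, mu_marg + omega * mu_marg^2)
})
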