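test_that("peak and polynomial forms of the quadratic time pattern agree", {
  cases <- list(c(2.3, 0, 47.96), c(log(10), 3, -12.5), c(0.5, -4, 8))
  tgrid <- seq(-20, 20, by = 0.5)
  for (cs in cases) {
    b <- quad_coefficients(cs[1], cs[2], cs[3])
    peak <- cs[1] - (tgrid - cs[2])^2 / (2 * cs[3])
    poly <- b$beta0 + b$beta1 * tgrid + b$beta2 * tgrid^2
    expect_lt(max(abs(peak - poly)), 1e-12)
    # extreme attained at beta_opt with value beta_max
    expect_equal(b$beta0 + b$beta1 * cs[2] + b$beta2 * cs[2]^2, cs[1])
  }
  # very large tolerance flattens the curve towards a constant pattern
  b <- quad_coefficients(1, 2, 1e12)
  expect_lt(abs(b$beta1) + abs(b$beta2), 1e-11)
  expect_error(quad_coefficients(1, 0, 0), "non-zero")
})

test_that("correlation matrices follow the stated structures", {
  V <- correlation_matrix(time_spec(1:3, correlation = "ar1", rho = 0.8))
  expect_equal(V, rbind(c(1, .8, .64), c(.8, 1, .8), c(.64, .8, 1)))
  expect_equal(correlation_matrix(time_spec(1:4, correlation = "ar1", rho = 0)),
               diag(4))
  expect_equal(correlation_matrix(time_spec(1:4, correlation = "equal", rho = 0)),
               diag(4))
  V1 <- correlation_matrix(time_spec(1:3, correlation = "equal", rho = 1))
  expect_equal(V1, matrix(1, 3, 3))
  expect_equal(qr(V1)$rank, 1L)
  expect_error(correlation_matrix(time_spec(1:5, correlation = "equal",
                                            rho = -0.5)), "rho")
  expect_error(correlation_matrix(time_spec(1:3, correlation = "ar1", rho = 1)),
               "rho")
})

test_that("scenario validation enforces roles, names and variance domains", {
  v_gm <- variety("gm", "gm", effect = 1)
  v_c <- variety("c", "comparator", effect = 1)
  d <- design_spec("crd", 4)
  expect_error(scenario(count_dist("poisson", 1), list(v_gm), d), "exactly one")
  expect_error(scenario(count_dist("poisson", 1),
                        list(v_gm, v_gm, v_c), d), "exactly one|unique")
  expect_error(trial_structure("single", trial_var = 1), "single-trial")
  expect_error(variety("x", "additional", effect_var = -1), ">= 0")
  # zero-effects must be all-or-none so the excess-zero model is coherent
  expect_error(scenario(count_dist("poisson", 1),
                        list(variety("gm", "gm", zero_effect = -1), v_c), d),
               "all or none")
})

test_that("zero variances give exactly zero random effects; draws are seeded", {
  sc <- single_trial_scenario("poisson", mu = 5, n_replicates = 6)
  set.seed(1); dr <- draw_effects(sc)
  expect_true(all(dr$blocks$b_count == 0))
  expect_true(all(dr$trials$t_count == 0))
  set.seed(9); d1 <- draw_effects(worked_example_scenario())
  set.seed(9); d2 <- draw_effects(worked_example_scenario())
  expect_identical(d1, d2)
  # reference draws actually vary
  expect_gt(var(d1$varieties$effect_count[d1$varieties$role == "reference"]), 0)
})

test_that("two-stage reference draws have marginal variance s1^2 + s2^2", {
  sc <- scenario(
    count_dist("poisson", 1),
    varieties = list(
      variety("gm", "gm"), variety("c", "comparator"),
      variety("refs", "reference", effect = 1, effect_var = 0.7,
              n_reference = 2)),
    design = design_spec("crd", 2),
    trials = trial_structure("multiple", n_trials = 2, ref_trial_var = 0.5))
  set.seed(3)
  draws <- replicate(4000, {
    d <- draw_effects(sc)$varieties
    d$effect_count[d$variety == "refs_1"][1]
  })
  expect_lt(abs(var(draws) - 1.2), 4 * sqrt(2 / 4000) * 1.2)
  expect_lt(abs(mean(draws) - 1), 4 * sqrt(1.2 / 4000))
})

test_that("simulated law is invariant to variety ordering in the scenario", {
  mk <- function(order) {
    vs <- list(
      a = variety("alpha", "additional", effect = log(3)),
      g = variety("gm", "gm", effect = log(8)),
      c = variety("comp", "comparator", effect = log(4)))
    scenario(count_dist("negbin", 1, 0.5), unname(vs[order]),
             design_spec("rcb", 5, block_var_count = 0.2))
  }
  d1 <- simulate_dataset(mk(c("a", "g", "c")), seed = 21)
  d2 <- simulate_dataset(mk(c("c", "a", "g")), seed = 21)
  k1 <- d1[order(d1$block, d1$variety), c("block", "variety", "mu_true")]
  k2 <- d2[order(d2$block, d2$variety), c("block", "variety", "mu_true")]
  expect_equal(as.data.frame(k1), as.data.frame(k2))
})

test_that("linear predictor composes effects on log and logit scales", {
  sc <- worked_example_scenario()
  lp <- linear_predictor(sc, worked_example_draw())
  expect_equal(nrow(lp), 2 * 5)
  gm1 <- lp[lp$variety == "gm" & lp$block == 1, ]
  expect_equal(gm1$mu, exp(0.4 - 0.4))
  expect_equal(gm1$delta, plogis(-0.3 - 0.1))
  # quadratic time pattern enters the predictor through f_p(t)
  sc_t <- repeated_measures_scenario(10, theta = 2, scheme = "independent")
  sc_t$time$var <- 0  # strip the random part to test the deterministic curve
  set.seed(2)
  lp <- linear_predictor(sc_t, draw_effects(sc_t))
  comp <- lp[lp$variety == "comparator" & lp$block == 1, ]
  expect_equal(comp$mu[comp$time == 0], 10)
  expect_equal(comp$mu[comp$time == 7] / 10, 0.6, tolerance = 1e-3)
})
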