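test_that("native parameterizations match the mixing-representation identities", {
  # poislognorm: omega = exp(sigma2) - 1, so omega = e - 1 gives sigma2 = 1
  np <- native_params(count_dist("poislognorm", mu = 3, dispersion = exp(1) - 1))
  expect_equal(np$sigma2, 1, tolerance = 1e-12)
  expect_equal(np$lambda, log(3) - 0.5, tolerance = 1e-12)
  # same spec on the sigma2 scale
  np2 <- native_params(count_dist("poislognorm", mu = 3, dispersion = 1,
                                  dispersion_scale = "sigma2"))
  expect_equal(np2$lambda, np$lambda)

  np <- native_params(count_dist("negbin", mu = 1, dispersion = 1))
  expect_equal(np$size, 1)
  expect_equal(np$prob, 0.5)

  np <- native_params(count_dist("odpoisson", mu = 7, dispersion = 1))
  expect_true(np$degenerate)
  np <- native_params(count_dist("odpoisson", mu = 6, dispersion = 3))
  expect_equal(np$shape * np$scale, 6)          # gamma mean mu
  expect_equal(np$shape * np$scale^2, (3 - 1) * 6)  # gamma variance (phi-1) mu

  bb <- native_params(binary_dist("betabinom", 16, 0.25, 0.2))
  expect_equal(bb$a / (bb$a + bb$b), 0.25)

  expect_error(count_dist("odpoisson", mu = 1, dispersion = 0.5), "phi")
  expect_error(count_dist("negbin", mu = 1, dispersion = -0.1), ">= 0")
  expect_error(count_dist("poisson", mu = 0), "positive")
})

test_that("pmf values agree with closed forms and the zero-inflation mixture", {
  expect_equal(dist_pmf(count_dist("poisson", mu = 4), 0), exp(-4))
  expect_equal(dist_pmf(count_dist("negbin", mu = 1, dispersion = 1), 0),
               dnbinom(0, size = 1, prob = 0.5))
  expect_equal(dist_pmf(count_dist("poisson", mu = 5, delta = 0.2), 0),
               0.2 + 0.8 * exp(-5))
  # zero-inflation leaves positive outcomes scaled by (1 - delta)
  expect_equal(dist_pmf(count_dist("poisson", mu = 5, delta = 0.2), 3),
               0.8 * dpois(3, 5))
  expect_error(dist_pmf(binary_dist("binomial", 4, 0.5), 5), "exceeds")
})

test_that("pmf sums to one across families and parameter grids", {
  specs <- list(
    count_dist("poisson", 4),
    count_dist("odpoisson", 4, 3),
    count_dist("negbin", 10, 1),
    count_dist("poislognorm", 10, 1),
    count_dist("negbin", 5, 0.5, delta = 0.3),
    count_dist("poislognorm", 2, 0.25, delta = 0.1),
    binary_dist("binomial", 16, 0.25),
    binary_dist("betabinom", 16, 0.25, 0.3),
    binary_dist("binlogitnorm", 16, 0.25, 1.5),
    binary_dist("betabinom", 16, 0.5, 0.1, delta = 0.2))
  for (sp in specs) {
    # the Poisson-lognormal has a heavy right tail: truncate far out
    upper <- if (inherits(sp, "binary_dist")) sp$size
             else if (sp$family == "poislognorm") 5000 else 400
    expect_equal(sum(dist_pmf(sp, 0:upper)), 1, tolerance = 1e-8,
                 label = sp$family)
  }
})

test_that("sampled moments match the printed mean-variance identities", {
  set.seed(42)
  m <- 1e5
  cases <- list(
    list(spec = count_dist("odpoisson", 4, 3), v = 3 * 4),
    list(spec = count_dist("negbin", 10, 0.5), v = 10 + 0.5 * 100),
    list(spec = count_dist("poislognorm", 10, 0.5), v = 10 + 0.5 * 100),
    list(spec = binary_dist("betabinom", 16, 0.25, 0.2),
         v = 16 * 0.25 * 0.75 * (1 + 15 * 0.2)))
  for (cs in cases) {
    mm <- dist_moments(cs$spec)
    expect_equal(mm$variance, cs$v, tolerance = 1e-12)
    x <- dist_sample(cs$spec, m)
    expect_moments_mc(x, mm$mean, mm$variance)
  }
})

test_that("zero-inflated Poisson moments follow mu(1-delta) and mu(1-delta)(1+delta mu)", {
  expect_equal(zi_poisson_moments(5, 0.2),
               tibble::tibble(mean = 4, variance = 8))
  expect_equal(zi_poisson_moments(7, 0), tibble::tibble(mean = 7, variance = 7))
  # sampling oracle and consistency with the generic moment formula
  set.seed(7)
  x <- dist_sample(count_dist("poisson", mu = 5, delta = 0.2), 1e5)
  expect_moments_mc(x, 4, 8)
  expect_equal(dist_moments(count_dist("poisson", mu = 5, delta = 0.2)),
               zi_poisson_moments(5, 0.2))
})

test_that("negative binomial degrades to Poisson as omega -> 0", {
  x <- 0:40
  d <- abs(dist_pmf(count_dist("negbin", 8, 1e-8), x) -
             dist_pmf(count_dist("poisson", 8), x))
  expect_lt(max(d), 1e-6)
})

test_that("poislognorm and negbin share moments but differ in shape at large mu, omega", {
  nb <- count_dist("negbin", 10, 1)
  pl <- count_dist("poislognorm", 10, 1)
  expect_equal(dist_moments(nb), dist_moments(pl), tolerance = 1e-9)
  expect_gt(max(abs(dist_pmf(nb, 0:100) - dist_pmf(pl, 0:100))), 0.005)
})

test_that("sampling is deterministic given a seed", {
  sp <- count_dist("negbin", 5, 0.5, delta = 0.2)
  set.seed(11); a <- dist_sample(sp, 1000)
  set.seed(11); b <- dist_sample(sp, 1000)
  expect_identical(a, b)
})

test_that("match_logitnormal reproduces target moments and fails beyond the bound", {
  r <- match_logitnormal(16, 0.25, 1)
  expect_equal(r$sigma2, 0)
  expect_equal(r$eta, qlogis(0.25))
  expect_equal(match_logitnormal(16, 0.5, 3)$eta, 0, tolerance = 1e-7)
  r <- match_logitnormal(16, 0.25, 3)
  expect_equal(r$mean, 16 * 0.25, tolerance = 1e-6)
  expect_equal(r$variance, 3 * 16 * 0.25 * 0.75, tolerance = 1e-6)
  # calibrated spec matches by quadrature too
  sp <- binary_dist("binlogitnorm", 16, plogis(r$eta), r$sigma2)
  mm <- dist_moments(sp)
  expect_equal(mm$mean, 4, tolerance = 1e-6)
  expect_equal(mm$variance, 9, tolerance = 1e-5)
  expect_error(match_logitnormal(16, 0.25, 16), "not achievable")
})
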