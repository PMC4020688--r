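# Monte-Carlo moment check: sample mean within 4 standard errors, sample
# variance within 4 standard errors of the variance estimator (SE derived
# from the empirical fourth central moment).
expect_moments_mc <- function(x, mean_expected, var_expected) {
  n <- length(x)
  se_mean <- sd(x) / sqrt(n)
  m4 <- mean((x - mean(x))^4)
  se_var <- sqrt(max(m4 - var(x)^2, 0) / n)
  expect_lt(abs(mean(x) - mean_expected), 4 * se_mean)
  expect_lt(abs(var(x) - var_expected), 4 * se_var)
}

# two-sample chi-squared test on pooled count bins (bins merged so every
# expected cell count is at least 5)
two_sample_count_test <- function(x, y) {
  k <- max(x, y)
  tab <- cbind(tabulate(x + 1L, k + 1L), tabulate(y + 1L, k + 1L))
  # merge sparse upper tail
  keep <- which(rowSums(tab) >= 10)
  cut <- if (length(keep)) max(keep) else 1L
  merged <- rbind(tab[seq_len(cut - 1L), , drop = FALSE],
                  colSums(tab[cut:nrow(tab), , drop = FALSE]))
  suppressWarnings(stats::chisq.test(merged))$p.value
}

# the canonical worked-example scenario: zero-inflated Poisson, GM +
# comparator + a three-member reference population, two blocks
worked_example_scenario <- function() {
  scenario(
    count_dist("poisson", mu = 1),
    varieties = list(
      variety("gm", "gm", effect = 0.4, zero_effect = -0.3),
      variety("comparator", "comparator", effect = 0.5, zero_effect = -0.2),
      variety("refs", "reference", effect = 1, effect_var = 1,
              zero_effect = -0.8, zero_effect_var = 0.5, n_reference = 3)),
    design = design_spec("rcb", n_replicates = 2, block_var_count = 0.1,
                         block_var_zero = 0.01))
}

# the quoted draws for that example, as an effect_draw
worked_example_draw <- function() {
  effect_draw(
    trials = tibble::tibble(trial = 1L, site = NA_integer_,
                            year = NA_integer_, t_count = 0, t_zero = 0),
    blocks = tibble::tibble(trial = 1L, block = 1:2,
                            b_count = c(-0.4, 0.1), b_zero = c(-0.1, 0.2)),
    varieties = tibble::tibble(
      trial = 1L,
      variety = c("gm", "comparator", "refs_1", "refs_2", "refs_3"),
      base = c("gm", "comparator", "refs", "refs", "refs"),
      role = c("gm", "comparator", "reference", "reference", "reference"),
      effect_count = c(0.4, 0.5, 0.8, 0.9, 1.2),
      effect_zero = c(-0.3, -0.2, -1.2, -0.9, -0.6)))
}
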