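test_that("Mann-Whitney exact p matches hand enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 orderings as extreme
  expect_equal(r$method, "exact_enumeration")

  r2 <- mann_whitney(c(1, 2), 3)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 2 / 3)

  # identical multisets tie everywhere: association is null
  r3 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$p_value, 1)
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with wilcox.test on all small untied inputs", {
  set.seed(2)
  for (i in 1:150) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    vals <- sample(1:50, n1 + n2)  # untied
    x <- vals[1:n1]; y <- vals[-(1:n1)]
    ours <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$method, "exact_enumeration")
    expect_equal(ours$u1, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("tied samples use the tie-corrected normal approximation", {
  set.seed(3)
  for (i in 1:50) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    x <- sample(0:3, n1, replace = TRUE)
    y <- sample(0:3, n2, replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    ours <- mann_whitney(x, y)
    expect_equal(ours$method, "normal_approx")
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Somers' D matches the explicit pair-counting oracle", {
  expect_equal(somers_d(c(1, 2, 3), c(1, 2, 3))$d, 1)
  expect_equal(somers_d(c(1, 2, 3), c(3, 2, 1))$d, -1)
  expect_equal(somers_d(c(1, 1, 2, 2), c(1, 2, 1, 2))$d, 0)
  expect_error(somers_d(c(1, 1, 1), c(1, 2, 3)), "tied")

  set.seed(4)
  for (i in 1:120) {
    n <- sample(4:12, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(0:3, n, replace = TRUE)
    if (length(unique(x)) == 1) next
    got <- somers_d(x, y)
    expect_equal(got$d, somers_pair_oracle(x, y))
    expect_gte(got$d, -1); expect_lte(got$d, 1)
    # antisymmetric under response reversal
    expect_equal(somers_d(x, -y)$d, -got$d)
  }
})

test_that("the adjusted group effect recovers known coefficients", {
  df <- tibble::tibble(
    arm = rep(c("usual_care", "intervention"), each = 6),
    baseline = c(1, 2, 3, 4, 5, 6, 2, 3, 4, 5, 6, 7)
  )
  # null case: identical change in both arms
  df$change <- 1.5
  fit0 <- suppressWarnings(adjusted_group_effect(df, change, arm, baseline))
  expect_equal(fit0$group_effect, 0, tolerance = 1e-10)

  # deterministic covariate: change equals baseline exactly
  df$change <- df$baseline
  fit1 <- suppressWarnings(adjusted_group_effect(df, change, arm, baseline))
  expect_equal(fit1$group_effect, 0, tolerance = 1e-10)
  expect_equal(fit1$covariate_effects$estimate[
    fit1$covariate_effects$term == ".baseline"], 1, tolerance = 1e-10)

  # noise-free additive design is recovered exactly
  df$change <- 2 * (df$arm == "intervention") + 0.5 * df$baseline - 1
  fit2 <- suppressWarnings(adjusted_group_effect(df, change, arm, baseline))
  expect_equal(fit2$group_effect, 2, tolerance = 1e-10)

  one_arm <- df[df$arm == "usual_care", ]
  expect_error(suppressWarnings(adjusted_group_effect(one_arm, change, arm, baseline)),
               "both arms")
  coll <- df
  coll$baseline <- as.numeric(coll$arm == "intervention")
  expect_error(adjusted_group_effect(coll, change, arm, baseline), "singular")
})

test_that("pooled Cohen's d reproduces the pilot effect size", {
  expect_equal(cohens_d_pooled(0, 1, 5, 0, 1, 5), 0)
  expect_equal(round(cohens_d_pooled(-0.60, 1.07, 10, 1.00, 0.86, 9), 2), 1.64)
  expect_equal(cohens_d_pooled(0, 1, 2, 1, 1, 2), 1)
  expect_warning(d <- cohens_d_pooled(0, 0, 3, 1, 0, 3), "infinite")
  expect_equal(d, Inf)
})

test_that("noncentral-t sample size matches the published plan", {
  plan <- sample_size_two_arm_t(delta = 1, sd = 1.14)
  expect_equal(plan$n_per_group, 22L)
  expect_equal(plan$n_total, 44L)
  expect_equal(plan$n_total_inflated, 44L)

  infl <- sample_size_two_arm_t(delta = 1, sd = 1.14, dropout_rate = 0.2)
  expect_equal(infl$n_total_inflated, 56L)  # 44 / 0.8 = 55, next even

  # power bracketing: n achieves the target, n - 1 does not
  pow <- function(n) compadhere:::power_two_sample_t(n, 1, 1.14, 0.05)
  expect_gte(pow(22), 0.8)
  expect_lt(pow(21), 0.8)
  # continuous-solution cross-check
  expect_equal(plan$n_per_group,
               ceiling(power.t.test(delta = 1, sd = 1.14, power = 0.8)$n))

  floor_plan <- sample_size_two_arm_t(delta = 10, sd = 1)
  expect_equal(floor_plan$n_per_group, 2L)
})

test_that("sample size is monotone in effect size, SD and power", {
  n_at <- function(delta, sd, power = 0.8) {
    sample_size_two_arm_t(delta, sd, power = power)$n_per_group
  }
  expect_gte(n_at(0.5, 1), n_at(1, 1))
  expect_gte(n_at(1, 2), n_at(1, 1))
  expect_gte(n_at(1, 1, power = 0.9), n_at(1, 1, power = 0.8))
})

test_that("the ARE-corrected Mann-Whitney plan gives the definitive-trial size", {
  plan <- sample_size_mann_whitney_are(d = 1.64)
  expect_equal(plan$n_per_group, 9L)  # t-test 7 per group, / 0.864, ceiling
  expect_equal(plan$n_total, 18L)
  expect_equal(plan$are_correction, 0.864)

  # ARE of 1 reduces to the t-test plan
  t_plan <- sample_size_two_arm_t(delta = 1.64, sd = 1)
  expect_equal(sample_size_mann_whitney_are(d = 1.64, are = 1)$n_per_group,
               t_plan$n_per_group)
  # ARE of 0.5 doubles the per-group n before rounding
  expect_equal(sample_size_mann_whitney_are(d = 1.64, are = 0.5)$n_per_group,
               as.integer(ceiling(t_plan$n_per_group / 0.5)))
})

test_that("tidiers return one-row summaries", {
  td <- tidy(mann_whitney(c(1, 2, 3), c(4, 5, 6)))
  expect_named(td, c("statistic", "p.value", "method", "n1", "n2"))
  g <- glance(cost_utility_analysis(tiny_cohort()))
  expect_equal(nrow(g), 1L)
  expect_true(is.character(g$dominance))
})
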