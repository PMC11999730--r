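test_that("participant costing applies the printed unit prices", {
  expect_equal(cost_participant()$total, 0)
  expect_equal(cost_participant(2, 1)$total, 2 * 193 + 177)  # 563
  mats <- tibble::tibble(item = "heavy_duty_applicator", unit_cost = 891.92)
  expect_equal(cost_participant(1, 0, materials = mats)$total, 1084.92)
  # catalogue fallback when no unit cost is carried
  expect_equal(cost_participant(materials = "postage")$materials_cost, 19.99)
  expect_error(cost_participant(materials = "mystery_item"), "mystery_item")
  expect_error(cost_participant(-1, 0), "non-negative")
  # custom specialist / admission prices
  pt <- price_table(specialist_cost = 250, admission_cost = 5000)
  expect_equal(cost_participant(0, 0, 2, 1, prices = pt)$total, 5500)
})

test_that("costing is additive over concatenated resource-use records", {
  set.seed(6)
  for (i in 1:20) {
    a <- sample(0:4, 2); b <- sample(0:4, 2)
    m1 <- sprintf("compression_stocking_pair=%.2f", runif(1, 20, 800))
    m2 <- sprintf("stocking_applicator=%.2f", runif(1, 20, 800))
    c1 <- cost_participant(a[1], a[2], materials = m1)
    c2 <- cost_participant(b[1], b[2], materials = m2)
    both <- cost_participant(a[1] + b[1], a[2] + b[2],
                             materials = paste(m1, m2, sep = ";"))
    expect_equal(both$total, c1$total + c2$total)
  }
})

test_that("QALY area under the curve follows trapezoid-plus-extrapolation", {
  expect_equal(as.numeric(qaly_auc(1, 1)), 1)
  u <- runif(5, -0.6, 1)
  expect_equal(as.numeric(qaly_auc(u, u)), u)  # constant utility identity
  expect_equal(as.numeric(qaly_auc(0.70, 0.60)), 0.625)
  # linear extrapolation continues the trend
  expect_equal(as.numeric(qaly_auc(0.70, 0.60, extrapolation = "linear")),
               0.5 * 0.65 + 0.5 * (0.60 + 0.50) / 2)
  # missing 6-month value carries baseline forward, flagged
  q <- qaly_auc(0.8, NA)
  expect_equal(as.numeric(q), 0.8)
  expect_true(attr(q, "baseline_carried"))
  expect_error(qaly_auc(NA, 0.5), "required")
  expect_error(qaly_auc(1.2, 0.5), "utilities")
})

test_that("QALY is monotone in each utility and bounded by the horizon", {
  set.seed(8)
  for (i in 1:50) {
    u0 <- runif(1, -0.6, 0.9); u6 <- runif(1, -0.6, 0.9)
    q <- qaly_auc(u0, u6)
    expect_lte(qaly_auc(u0, u6), qaly_auc(u0 + 0.1, u6))
    expect_lte(qaly_auc(u0, u6), qaly_auc(u0, u6 + 0.1))
    expect_gte(q, min(u0, u6)); expect_lte(q, max(u0, u6))
    expect_lte(q, 1)  # one year of perfect health
  }
})

test_that("the cost-utility analysis assembles increments, ICER and dominance", {
  cohort <- tiny_cohort()
  res <- cost_utility_analysis(cohort)
  # intervention here costs more (extra appointments) and gains utility
  expect_gt(res$delta_cost, 0)
  expect_gt(res$delta_qaly_adjusted, 0)
  expect_equal(res$dominance, "tradeoff_ne")
  expect_equal(res$icer, res$delta_cost / res$delta_qaly_adjusted)
  expect_true(res$cost_effective)  # small ICER vs 28033 threshold
  expect_equal(res$wtp_threshold, 28033)
  # arm means agree with per-participant table
  pp <- res$per_participant
  expect_equal(res$delta_cost,
               mean(pp$total_cost[pp$arm == "intervention"]) -
                 mean(pp$total_cost[pp$arm == "usual_care"]))
})

test_that("dominance quadrants and WTP logic follow the sign conventions", {
  expect_equal(compadhere:::classify_dominance(-10, 0.1), "dominant")
  expect_equal(compadhere:::classify_dominance(10, -0.1), "dominated")
  expect_equal(compadhere:::classify_dominance(10, 0.1), "tradeoff_ne")
  expect_equal(compadhere:::classify_dominance(-10, -0.1), "tradeoff_sw")

  # cheaper and more effective intervention dominates regardless of WTP
  cohort <- tiny_cohort()
  cohort$n_f2f_appointments[cohort$arm == "usual_care"] <- 5L
  cohort$n_f2f_appointments[cohort$arm == "intervention"] <- 0L
  cohort$n_phone_appointments <- 0L
  res <- cost_utility_analysis(cohort, wtp = 0)
  expect_equal(res$dominance, "dominant")
  expect_true(res$cost_effective)
  expect_true(is.na(res$icer))
})

test_that("ICER scales linearly with costs, utilities unchanged", {
  cohort <- tiny_cohort()
  k <- 3
  base <- cost_utility_analysis(cohort, prices = price_table())
  scaled <- cost_utility_analysis(
    cohort, prices = price_table(f2f_cost = 193 * k, phone_cost = 177 * k))
  # materials costs are carried in the records, so scale only the appointment
  # part: verify on the appointment-cost component directly
  expect_equal(scaled$delta_qaly_adjusted, base$delta_qaly_adjusted)
  costs_b <- cost_cohort(cohort, price_table())
  costs_s <- cost_cohort(cohort, price_table(f2f_cost = 193 * k,
                                             phone_cost = 177 * k))
  expect_equal(costs_s$appointment_cost, k * costs_b$appointment_cost)
})

test_that("missing utilities are handled per intention-to-treat rules", {
  cohort <- tiny_cohort()
  # one participant unreachable at follow-up: QALY carries baseline forward
  cohort[cohort$participant_id == "U3", ] <-
    drop_followup(cohort[cohort$participant_id == "U3", ])
  res <- suppressWarnings(cost_utility_analysis(cohort))
  pp <- res$per_participant
  expect_true(pp$baseline_carried[pp$participant_id == "U3"])
  expect_equal(pp$qaly[pp$participant_id == "U3"], 0.7)
  # a missing baseline excludes the participant with a warning
  cohort$baseline_eq5d_utility[cohort$participant_id == "U2"] <- NA
  expect_warning(  # small residual cohort also triggers a perfect-fit note
    expect_warning(res2 <- cost_utility_analysis(cohort), "excluded"))
  expect_false("U2" %in% res2$per_participant$participant_id)
})
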