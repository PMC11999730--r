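test_that("adherence percentage reproduces hand-computed cases", {
  expect_equal(adherence_percentage(16, 16, 16, 7)$percentage, 100)
  expect_equal(adherence_percentage(16, 8, NA, 7)$percentage, 50)
  # two legs, ranged days: legs average then lowest-days rule
  r <- adherence_percentage(12, 12, 6, c(3, 4))
  expect_equal(round(r$percentage, 2), 32.14)
  expect_equal(round(r$pct_max, 2), 42.86)  # days at 4
  # midpoint mode resolves ranges at their centres
  m <- adherence_percentage(c(14, 18), 8, NA, 7, mode = "midpoint")
  expect_equal(m$percentage, 8 / 16 * 100)
})

test_that("degenerate wear reports behave as specified", {
  expect_error(suppressWarnings(adherence_percentage(0, 4, NA, 7)), "undefined")
  expect_equal(adherence_percentage(0, 0, NA, 7)$percentage, 0)
  expect_warning(r <- adherence_percentage(10, 14, NA, 7), "clamping")
  expect_equal(r$percentage, 100)
  expect_error(adherence_percentage(16, NA, NA, 7), "at least one leg")
  expect_error(adherence_percentage(16, 8, NA, "9"), "days_per_week")
})

test_that("adherence percentage is monotone and bounded on random reports", {
  set.seed(10)
  for (i in 1:100) {
    aw <- sort(runif(2, 4, 24)); wl <- sort(runif(2, 0, 24))
    d <- sort(runif(2, 0, 7))
    r <- suppressWarnings(adherence_percentage(aw, wl, NA, d))
    expect_true(r$percentage >= 0 && r$percentage <= 100)
    expect_lte(r$pct_min, r$percentage + 1e-9)
    expect_gte(r$pct_max, r$percentage - 1e-9)
    # more worn hours never decreases the score; more awake never increases
    up <- suppressWarnings(adherence_percentage(aw, pmin(wl + 1, 24), NA, d))
    expect_gte(up$percentage, r$percentage - 1e-9)
    more_awake <- suppressWarnings(
      adherence_percentage(pmin(aw + 1, 24), wl, NA, d))
    expect_lte(more_awake$percentage, r$percentage + 1e-9)
  }
})

test_that("modified Q10 banding rounds half-up and covers all categories", {
  expect_equal(modified_q10(c(100, 51, 10.4, 0)), c(3L, 2L, 0L, 0L))
  expect_equal(modified_q10(c(10.5, 50.4, 50.5, 90.4, 90.5)),
               c(1L, 1L, 2L, 2L, 3L))
  expect_error(modified_q10(101), "0, 100")
  # surjective onto 0-3 and monotone over the whole domain
  grid <- modified_q10(seq(0, 100, by = 0.25))
  expect_equal(sort(unique(grid)), 0:3)
  expect_true(all(diff(grid) >= 0))
})

test_that("resolution points are a bijection onto 1-4", {
  expect_equal(resolution_points(c(FALSE, FALSE, TRUE, TRUE),
                                 c(FALSE, TRUE, FALSE, TRUE)),
               1:4)
  expect_error(resolution_points(NA, TRUE), "non-missing")
})

test_that("mean barrier resolution matches the printed per-participant scores", {
  expect_equal(mean_barrier_resolution(FALSE, FALSE), 1.00)
  expect_equal(mean_barrier_resolution(c(FALSE, FALSE, TRUE),
                                       c(FALSE, FALSE, FALSE)), 1.67)
  expect_equal(mean_barrier_resolution(rep(TRUE, 3), rep(TRUE, 3)), 4.00)
  expect_error(mean_barrier_resolution(logical(), logical()), "undefined")
})

test_that("resolution summaries reproduce the pilot's pooled categories", {
  usual <- tibble::tibble(addressed = c(TRUE, rep(TRUE, 7), rep(FALSE, 20)),
                          resolved = c(TRUE, rep(FALSE, 27)))
  s <- summarize_resolution(usual)
  expect_equal(s$pct, c(3.57, 25.00, 71.43, 0.00))
  expect_equal(s$total_barriers, rep(28L, 4))

  intervention <- tibble::tibble(addressed = rep(TRUE, 25),
                                 resolved = c(rep(TRUE, 18), rep(FALSE, 7)))
  expect_equal(summarize_resolution(intervention)$pct,
               c(72.00, 28.00, 0.00, 0.00))

  lone <- summarize_resolution(tibble::tibble(addressed = FALSE, resolved = TRUE))
  expect_equal(lone$pct, c(0, 0, 0, 100))

  none <- summarize_resolution(tibble::tibble(addressed = logical(),
                                              resolved = logical()))
  expect_true(all(is.na(none$pct)))
  expect_equal(none$total_barriers, rep(0L, 4))
})

test_that("group bookkeeping: sum of mean scores x counts equals pooled points", {
  # pilot usual-care reconstruction: pooled points must equal 45
  outs <- usual_care_outcome_sets()
  per <- outs |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(n = dplyr::n(),
                     m = mean_barrier_resolution(addressed, resolved))
  expect_equal(sum(outs$addressed & outs$resolved), 1L)
  expect_equal(sum(outs$addressed & !outs$resolved), 7L)
  expect_equal(sum(!outs$addressed & !outs$resolved), 20L)
  expect_equal(sum(resolution_points(outs$addressed, outs$resolved)), 45L)
  # identity holds on random cohorts too (up to the 2-dp score rounding)
  set.seed(12)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    a <- runif(n) < 0.5; r <- runif(n) < 0.5
    expect_equal(mean_barrier_resolution(a, r) * n,
                 sum(resolution_points(a, r)), tolerance = 0.005 * n)
  }
})

test_that("cohort-level scoring joins barriers, outcomes and wear reports", {
  cohort <- tiny_cohort()
  res <- score_resolution(cohort)
  expect_equal(res$mean_resolution_score[res$participant_id == "U1"], 1.00)
  expect_equal(res$mean_resolution_score[res$participant_id == "I1"], 4.00)
  expect_false("U3" %in% res$participant_id)  # no recorded barriers

  adh <- score_adherence(cohort)
  u1 <- adh[adh$participant_id == "U1", ]
  expect_equal(u1$percentage[u1$timepoint == "baseline"], 50)
  expect_equal(u1$percentage[u1$timepoint == "followup"], 25)

  ch <- change_scores(cohort)
  expect_equal(ch$pct_change[ch$participant_id == "U1"], -25)
  expect_equal(ch$modified_q10_change[ch$participant_id == "I1"],
               modified_q10(87.5) - modified_q10(50))
})
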