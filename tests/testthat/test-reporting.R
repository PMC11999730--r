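test_that("the pipeline produces a fully populated report on pilot defaults", {
  cohort <- generate_cohort(pilot_config(seed = 9))
  rep <- run_pipeline(cohort, flow = c(screened = 846, contacted = 60,
                                       consented = 20))
  expect_s3_class(rep, "trial_report")
  fc <- rep$flow_counts
  expect_equal(fc$total[fc$stage == "randomised"], 20)
  expect_equal(fc$total[fc$stage == "screened"], 846)
  expect_lte(fc$total[fc$stage == "analysed"], fc$total[fc$stage == "randomised"])
  expect_gt(nrow(rep$baseline_table), 5)
  expect_equal(nrow(rep$barrier_table), 20)
  expect_equal(nrow(rep$resolution_summary), 8)  # 2 arms x 4 categories
  expect_s3_class(rep$cua, "cua_result")
  expect_true(all(c("modified_q10", "unmodified_q10", "eq5d_utility") %in%
                    rep$outcomes_table$outcome))
  # effective per-arm ns in tables match the flow counts
  expect_equal(max(rep$outcomes_table$usual_care_n),
               fc$usual_care[fc$stage == "analysed"])
})

test_that("reported statistics equal direct calls into the stats layer", {
  cohort <- generate_cohort(pilot_config(seed = 13))
  rep <- run_pipeline(cohort)
  ch <- change_scores(cohort)
  direct <- mann_whitney(ch$modified_q10_change[ch$arm == "usual_care"],
                         ch$modified_q10_change[ch$arm == "intervention"])
  expect_equal(
    rep$outcomes_table$p_value[rep$outcomes_table$outcome == "modified_q10"],
    direct$p_value)
  fit <- adjusted_group_effect(ch, utility_change, arm, utility_baseline)
  expect_equal(
    rep$outcomes_table$p_value[rep$outcomes_table$outcome == "eq5d_utility"],
    fit$p_value)
  res <- score_resolution(cohort)
  assoc <- dplyr::inner_join(res, ch[, c("participant_id", "modified_q10_change")],
                             by = "participant_id")
  assoc <- assoc[!is.na(assoc$modified_q10_change), ]
  expect_equal(rep$somers_d$d,
               somers_d(assoc$mean_resolution_score, assoc$modified_q10_change)$d)
})

test_that("re-running the pipeline is deterministic", {
  cohort <- generate_cohort(pilot_config(seed = 2))
  r1 <- run_pipeline(cohort)
  r2 <- run_pipeline(cohort)
  expect_equal(render_report(r1, "json"), render_report(r2, "json"))
})

test_that("a null cohort of duplicated arms shows no effects", {
  half <- dplyr::bind_rows(
    with_barriers(make_participant("A1", "usual_care"), 1, addressed = TRUE),
    with_barriers(make_participant("A2", "usual_care",
                                   baseline_eq5d_utility = 0.5,
                                   followup_hours_worn_left = "12",
                                   followup_hours_worn_right = "12"), 2),
    make_participant("A3", "usual_care", baseline_eq5d_vas = 60)
  )
  mirror <- half
  mirror$arm <- "intervention"
  mirror$participant_id <- paste0("B", 1:3)
  cohort <- dplyr::bind_rows(half, mirror)
  rep <- suppressWarnings(run_pipeline(cohort))
  expect_true(all(abs(rep$outcomes_table$difference) < 1e-12))
  mw <- rep$outcomes_table[rep$outcomes_table$test == "mann_whitney", ]
  expect_true(all(mw$p_value == 1))
  expect_equal(rep$cua$delta_cost, 0)
})

test_that("a cohort resolving everything vs nothing hits the extreme contrast", {
  usual <- purrr::map(1:4, function(i) {
    with_barriers(make_participant(paste0("U", i), "usual_care"),
                  ids = c(1, 2), addressed = FALSE, resolved = FALSE)
  })
  interv <- purrr::map(1:4, function(i) {
    with_barriers(make_participant(paste0("I", i), "intervention"),
                  ids = c(3, 4), addressed = TRUE, resolved = TRUE)
  })
  cohort <- dplyr::bind_rows(c(usual, interv))
  rep <- suppressWarnings(run_pipeline(cohort))
  rs <- rep$resolution_summary
  pct_resolved <- function(a) {
    sum(rs$pct[rs$arm == a & rs$category == "addressed_resolved"])
  }
  expect_equal(pct_resolved("intervention") - pct_resolved("usual_care"), 100)
})

test_that("renders are deterministic, parseable and structurally complete", {
  cohort <- generate_cohort(pilot_config(seed = 4, n_per_arm = 6))
  rep <- run_pipeline(cohort)

  js <- render_report(rep, "json")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$outcomes_table$p_value,
               rep$outcomes_table$p_value, tolerance = 1e-12)
  expect_equal(parsed$resolution_summary$n,
               rep$resolution_summary$n)

  md <- render_report(rep, "markdown")
  # one row per participant in the barrier table
  expect_equal(stringr::str_count(md, "\\| P\\d+ \\|"), 12)

  csvs <- render_report(rep, "csv")
  out_tab <- readr::read_csv(I(csvs[["outcomes_table"]]), show_col_types = FALSE)
  expect_true(all(c("usual_care_mean", "intervention_mean", "difference",
                    "p_value") %in% names(out_tab)))
  expect_error(render_report(rep, "pdf"))
})

test_that("the pipeline rejects a one-arm cohort", {
  one <- dplyr::bind_rows(make_participant("P1"), make_participant("P2"))
  expect_error(run_pipeline(one), "both arms")
})

test_that("plots build without error", {
  cohort <- generate_cohort(pilot_config(seed = 5, n_per_arm = 5))
  rep <- run_pipeline(cohort)
  p1 <- autoplot(rep)
  p2 <- autoplot(rep, which = "percentage")
  p3 <- autoplot(rep$cua)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p3, "ggplot")
  expect_silent(ggplot2::ggplot_build(p1))
  expect_silent(ggplot2::ggplot_build(p3))
})
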