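#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

#' Run the full trial analysis pipeline
#'
#' Orchestrates every stage on a validated cohort, following
#' intention-to-treat with available data: participants are analysed in
#' their randomised arm; a participant with a missing follow-up block
#' contributes baseline summaries only, and each outcome uses its effective
#' n. Produces baseline and outcome tables (per-arm mean/SD and change
#' comparisons with Mann-Whitney p-values for the two adherence scales and
#' baseline-adjusted regression p-values for the secondary outcomes), the
#' per-participant barrier table with mean resolution scores, the pooled
#' barrier-resolution category summary, the pooled Somers' D association
#' between barrier resolution and modified-Q10 change, and the cost-utility
#' analysis.
#'
#' @param cohort A validated cohort tibble with both arms present.
#' @param prices A [price_table()].
#' @param wtp Willingness-to-pay threshold (AUD per QALY).
#' @param mode Interval-resolution mode for adherence scoring.
#' @param flow Optional named numeric vector with any of `screened`,
#'   `contacted`, `consented` to populate the recruitment-flow counts;
#'   `randomised` and `analysed` are derived from the cohort.
#' @return A `trial_report` object (list of tibbles plus fitted objects).
#' @export
run_pipeline <- function(cohort, prices = price_table(), wtp = 28033,
                         mode = "conservative", flow = NULL) {
  validate_cohort(cohort)
  assert_arm(cohort$arm)
  if (length(unique(cohort$arm)) < 2) {
    stop("cohort must contain both arms", call. = FALSE)
  }
  ch <- change_scores(cohort, mode = mode)
  resol <- score_resolution(cohort)
  outcomes <- barrier_outcomes(cohort)

  randomised <- table(factor(cohort$arm, levels = arm_levels()))
  analysed <- table(factor(cohort$arm[!followup_missing(cohort)],
                           levels = arm_levels()))
  flow <- as.list(flow %||% numeric())
  # pre-randomisation stages are whole-trial counts; per-arm splits exist
  # only from randomisation onward
  flow_counts <- tibble::tibble(
    stage = c("screened", "contacted", "consented", "randomised", "analysed"),
    usual_care = c(rep(NA_real_, 3), randomised[["usual_care"]],
                   analysed[["usual_care"]]),
    intervention = c(rep(NA_real_, 3), randomised[["intervention"]],
                     analysed[["intervention"]]),
    total = c(flow$screened %||% NA_real_, flow$contacted %||% NA_real_,
              flow$consented %||% NA_real_, sum(randomised), sum(analysed))
  )
  cons <- flow_counts$total[flow_counts$stage == "consented"]
  if (!is.na(cons) && sum(randomised) > cons) {
    stop("flow counts inconsistent: randomised exceeds consented", call. = FALSE)
  }

  # Table-1-style baseline summary
  base_stat <- function(v, a) {
    v <- v[cohort$arm == a]
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  }
  base_vars <- list(
    age = cohort$age, bmi = cohort$bmi,
    vcss_q10 = cohort$baseline_vcss_q10,
    modified_q10 = ch$modified_q10_baseline[match(cohort$participant_id, ch$participant_id)],
    adherence_pct = ch$percentage_baseline[match(cohort$participant_id, ch$participant_id)],
    vcss_total = ch$vcss_baseline[match(cohort$participant_id, ch$participant_id)],
    civiq14_gis = cohort$baseline_civiq14_gis,
    eq5d_utility = cohort$baseline_eq5d_utility,
    eq5d_vas = cohort$baseline_eq5d_vas
  )
  baseline_table <- purrr::imap_dfr(base_vars, function(v, nm) {
    u <- base_stat(v, "usual_care"); i <- base_stat(v, "intervention")
    tibble::tibble(characteristic = nm,
                   usual_care_mean = u["mean"], usual_care_sd = u["sd"],
                   intervention_mean = i["mean"], intervention_sd = i["sd"])
  })

  # Table-2-style outcomes: per-arm mean (SD) change, difference, p
  primary <- c(unmodified_q10 = "unmodified_q10_change",
               modified_q10 = "modified_q10_change")
  secondary <- c(adherence_pct = "pct_change", vcss_total = "vcss_change",
                 civiq14_gis = "civiq_change", eq5d_utility = "utility_change",
                 eq5d_vas = "vas_change")
  base_cols <- c(unmodified_q10 = "unmodified_q10_baseline",
                 modified_q10 = "modified_q10_baseline",
                 adherence_pct = "percentage_baseline",
                 vcss_total = "vcss_baseline", civiq14_gis = "civiq_baseline",
                 eq5d_utility = "utility_baseline", eq5d_vas = "vas_baseline")
  outcome_row <- function(nm, col, test) {
    v_u <- ch[[col]][ch$arm == "usual_care"]
    v_i <- ch[[col]][ch$arm == "intervention"]
    n_u <- sum(!is.na(v_u)); n_i <- sum(!is.na(v_i))
    diff <- mean(v_i, na.rm = TRUE) - mean(v_u, na.rm = TRUE)
    p <- if (n_u == 0 || n_i == 0) {
      NA_real_
    } else if (test == "mann_whitney") {
      mann_whitney(v_u[!is.na(v_u)], v_i[!is.na(v_i)])$p_value
    } else {
      # a degenerate cohort (e.g. constant baseline) cannot be adjusted;
      # the table reports NA rather than aborting the whole report
      tryCatch(
        adjusted_group_effect(ch, .data[[col]], .data$arm,
                              .data[[base_cols[[nm]]]])$p_value,
        error = function(e) NA_real_)
    }
    tibble::tibble(
      outcome = nm, test = test,
      usual_care_mean = mean(v_u, na.rm = TRUE),
      usual_care_sd = stats::sd(v_u, na.rm = TRUE), usual_care_n = n_u,
      intervention_mean = mean(v_i, na.rm = TRUE),
      intervention_sd = stats::sd(v_i, na.rm = TRUE), intervention_n = n_i,
      difference = diff, p_value = p
    )
  }
  outcomes_table <- dplyr::bind_rows(
    purrr::imap_dfr(primary, function(col, nm) outcome_row(nm, col, "mann_whitney")),
    purrr::imap_dfr(secondary, function(col, nm) outcome_row(nm, col, "ancova"))
  )

  # Table-3-style per-participant barrier table
  barrier_table <- ch |>
    dplyr::select("participant_id", "arm", "pct_change", "modified_q10_change") |>
    dplyr::left_join(resol, by = c("participant_id", "arm")) |>
    dplyr::mutate(n_barriers = tidyr::replace_na(.data$n_barriers, 0L)) |>
    dplyr::arrange(.data$arm, .data$participant_id)

  resolution_summary <- outcomes |>
    dplyr::group_by(.data$arm) |>
    summarize_resolution()

  # pooled association between barrier resolution and adherence change
  assoc_df <- barrier_table[!is.na(barrier_table$mean_resolution_score) &
                              !is.na(barrier_table$modified_q10_change), ]
  somers <- if (nrow(assoc_df) >= 2 &&
                length(unique(assoc_df$mean_resolution_score)) > 1) {
    somers_d(assoc_df$mean_resolution_score, assoc_df$modified_q10_change)
  } else NULL

  cua <- cost_utility_analysis(cohort, prices = prices, wtp = wtp)
  costs <- cost_cohort(cohort, prices)
  econ_table <- dplyr::left_join(
    costs,
    cohort[, c("participant_id", "n_f2f_appointments", "n_phone_appointments",
               "n_specialist_vlu_appointments", "n_vlu_admissions")],
    by = "participant_id") |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_n_f2f = mean(.data$n_f2f_appointments),
      mean_n_phone = mean(.data$n_phone_appointments),
      mean_n_specialist = mean(.data$n_specialist_vlu_appointments),
      mean_n_admissions = mean(.data$n_vlu_admissions),
      mean_appointment_cost = mean(.data$appointment_cost),
      sd_appointment_cost = stats::sd(.data$appointment_cost),
      mean_materials_cost = mean(.data$materials_cost),
      sd_materials_cost = stats::sd(.data$materials_cost),
      mean_total_cost = mean(.data$total),
      sd_total_cost = stats::sd(.data$total),
      .groups = "drop"
    )

  structure(
    list(flow_counts = flow_counts, baseline_table = baseline_table,
         outcomes_table = outcomes_table, barrier_table = barrier_table,
         resolution_summary = resolution_summary, somers_d = somers,
         econ_table = econ_table, cua = cua, change_scores = ch),
    class = "trial_report"
  )
}

#' @export
print.trial_report <- function(x, ...) {
  r <- x$flow_counts
  cat("Trial report\n")
  cat(sprintf("  randomised: %d usual care, %d intervention; analysed: %d / %d\n",
              r$usual_care[r$stage == "randomised"],
              r$intervention[r$stage == "randomised"],
              r$usual_care[r$stage == "analysed"],
              r$intervention[r$stage == "analysed"]))
  prim <- x$outcomes_table[x$outcomes_table$outcome == "modified_q10", ]
  cat(sprintf("  modified Q10 change: %.2f vs %.2f (diff %.2f, Mann-Whitney p = %.4g)\n",
              prim$usual_care_mean, prim$intervention_mean, prim$difference,
              prim$p_value))
  if (!is.null(x$somers_d)) {
    cat(sprintf("  Somers' D (resolution -> adherence change): %.3f (p = %.4g)\n",
                x$somers_d$d, x$somers_d$p_value))
  }
  cat(sprintf("  incremental cost $%.2f, adjusted incremental QALY %.4f",
              x$cua$delta_cost, x$cua$delta_qaly_adjusted))
  if (!is.na(x$cua$icer)) cat(sprintf(", ICER $%.2f/QALY", x$cua$icer))
  cat("\n")
  invisible(x)
}

md_table <- function(df) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ fmt2(.x)))
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.character))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(ifelse(is.na(r), "NA", r), collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

report_tables <- function(report) {
  tabs <- list(
    flow_counts = report$flow_counts,
    baseline_table = report$baseline_table,
    outcomes_table = report$outcomes_table,
    barrier_table = report$barrier_table,
    resolution_summary = dplyr::mutate(report$resolution_summary,
                                       category = as.character(.data$category)),
    econ_table = report$econ_table,
    cua_summary = glance(report$cua)
  )
  if (!is.null(report$somers_d)) tabs$somers_d <- tidy(report$somers_d)
  tabs
}

#' Render a trial report
#'
#' Deterministic serialization of a [run_pipeline()] report. Numeric
#' formatting in the markdown render follows the trial's conventions
#' (scores, costs and percentages to 2 decimals).
#'
#' @param report A `trial_report`.
#' @param format `"markdown"` (single document string), `"json"` (single
#'   JSON string that parses back to the report's tables), or `"csv"`
#'   (named character vector, one CSV document per table).
#' @return A character scalar (markdown/json) or named character vector
#'   (csv).
#' @export
render_report <- function(report, format = c("markdown", "json", "csv")) {
  stopifnot(inherits(report, "trial_report"))
  format <- match.arg(format)
  tabs <- report_tables(report)
  if (format == "markdown") {
    sections <- purrr::imap_chr(tabs, function(df, nm) {
      paste0("## ", nm, "\n\n", md_table(df))
    })
    paste0("# Trial report\n\n", paste(sections, collapse = "\n\n"), "\n")
  } else if (format == "json") {
    jsonlite::toJSON(tabs, dataframe = "columns", na = "null", digits = NA,
                     auto_unbox = TRUE, pretty = TRUE)
  } else {
    vapply(tabs, function(df) readr::format_csv(df, na = "NA"), character(1))
  }
}

#' Boxplots of adherence change by arm
#'
#' Mirrors the pilot's distribution figures: post-minus-pre change in the
#' modified Q10 score and in the adherence percentage, by arm.
#'
#' @param object A `trial_report`.
#' @param which `"modified_q10"` or `"percentage"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_report <- function(object, which = c("modified_q10", "percentage"),
                                  ...) {
  which <- match.arg(which)
  ch <- object$change_scores
  col <- if (which == "modified_q10") "modified_q10_change" else "pct_change"
  lab <- if (which == "modified_q10") "Modified Q10 change" else "Adherence % change"
  df <- ch[!is.na(ch[[col]]), c("arm", col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data[[col]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = lab,
                  title = "Post- minus pre-trial adherence change by arm") +
    ggplot2::theme_minimal()
}
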