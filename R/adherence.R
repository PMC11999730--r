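resolve_interval <- function(lo, hi, orientation, mode) {
  # orientation: which bound the conservative mode takes
  if (mode == "midpoint") (lo + hi) / 2 else if (orientation == "lower") lo else hi
}

leg_pct <- function(worn, awake, days_frac) {
  if (is.na(worn)) return(NA_real_)
  if (awake == 0) {
    if (worn > 0) {
      stop("hours awake resolve to 0 with worn hours > 0: adherence undefined",
         call. = FALSE)
    }
    return(0)
  }
  w <- min(worn, awake)  # self-report noise must not produce > 100%
  min(max(w / awake * days_frac * 100, 0), 100)
}

#' Adherence percentage from a wear-time report
#'
#' The percentage of waking hours that compression stockings were worn:
#' per leg, (hours worn / hours awake) x (days per week / 7) x 100, averaged
#' over the legs that have a report, clamped to \[0, 100\]. Worn hours
#' exceeding awake hours are clamped to awake hours with a warning.
#'
#' Self-reported quantities may be ranges. Two interval-resolution modes are
#' provided: `"conservative"` (default) takes the lower bound of worn hours
#' and days and the upper bound of hours awake, biasing the estimate
#' downward in a documented direction; `"midpoint"` takes interval
#' midpoints. Alongside the point estimate the attainable `[pct_min,
#' pct_max]` envelope over all bound orientations is reported so callers can
#' audit the sensitivity to the range rules.
#'
#' @param hours_awake Numeric length 1 or 2 (interval) or `"lo-hi"` string.
#' @param hours_worn_left,hours_worn_right As `hours_awake`; at least one leg
#'   must be non-`NA`.
#' @param days_per_week As `hours_awake`, in 0-7.
#' @param mode `"conservative"` or `"midpoint"`.
#' @return A one-row tibble: `percentage`, `pct_min`, `pct_max`.
#' @examples
#' adherence_percentage(16, 16, 16, 7)                  # 100%
#' adherence_percentage(16, 8, NA, 7)                   # one leg only: 50%
#' adherence_percentage(12, 12, 6, c(3, 4))             # ranged days: 32.14%
#' @export
adherence_percentage <- function(hours_awake, hours_worn_left = NA,
                                 hours_worn_right = NA, days_per_week,
                                 mode = c("conservative", "midpoint")) {
  mode <- match.arg(mode)
  as_iv <- function(v, what, max_val) {
    if (is.character(v)) {
      iv <- parse_interval(v)
      v <- c(iv$lo[1], iv$hi[1])
    }
    if (all(is.na(v))) return(c(NA_real_, NA_real_))
    if (length(v) == 1) v <- c(v, v)
    if (length(v) != 2 || v[1] > v[2] || v[1] < 0 || v[2] > max_val) {
      stop(what, " must be an interval within [0, ", max_val, "]", call. = FALSE)
    }
    v
  }
  awake <- as_iv(hours_awake, "hours_awake", 24)
  left <- as_iv(hours_worn_left, "hours_worn_left", 24)
  right <- as_iv(hours_worn_right, "hours_worn_right", 24)
  days <- as_iv(days_per_week, "days_per_week", 7)
  if (anyNA(awake) || anyNA(days)) {
    stop("hours_awake and days_per_week are required", call. = FALSE)
  }
  if (all(is.na(left)) && all(is.na(right))) {
    stop("at least one leg's worn-hours interval is required", call. = FALSE)
  }
  eval_at <- function(a, wl, wr, d) {
    mean(c(leg_pct(wl, a, d / 7), leg_pct(wr, a, d / 7)), na.rm = TRUE)
  }
  if (mode == "conservative") {
    # conservative orientation: worn and days at their lower bounds, awake at
    # its upper bound (consistent with the explicit lowest-days rule)
    a_res <- awake[2]; wl_res <- left[1]; wr_res <- right[1]; d_res <- days[1]
  } else {
    a_res <- mean(awake); wl_res <- mean(left); wr_res <- mean(right)
    d_res <- mean(days)
  }
  if ((!is.na(wl_res) && wl_res > a_res) || (!is.na(wr_res) && wr_res > a_res)) {
    warning("worn hours exceed hours awake; clamping to hours awake", call. = FALSE)
  }
  pct <- eval_at(a_res, wl_res, wr_res, d_res)
  # audit envelope over all bound orientations (monotone in each resolved bound)
  lo_env <- eval_at(awake[2], left[1], right[1], days[1])
  hi_env <- if (awake[1] == 0 && isTRUE(max(left[2], right[2], na.rm = TRUE) > 0)) {
    100  # zero-awake lower bound with positive wear: ratio unbounded, clamp
  } else {
    eval_at(awake[1], left[2], right[2], days[2])
  }
  tibble::tibble(percentage = pct, pct_min = lo_env, pct_max = hi_env)
}

#' Modified VCSS Q10 banding of an adherence percentage
#'
#' The modified compliance subscore quantifies the original Q10 categories by
#' the percentage of waking hours worn: 0 = 1-10%, 1 = 11-50%, 2 = 51-90%,
#' 3 = 91-100%. The percentage is rounded half-up to the nearest integer
#' before banding, and 0% is assigned to category 0 (making the scale a
#' total function on \[0, 100\] even though the printed bottom band starts
#' at 1%).
#'
#' @param percentage Numeric vector in \[0, 100\].
#' @return Integer vector in 0-3.
#' @examples
#' modified_q10(c(100, 51, 10.4, 0))
#' @export
modified_q10 <- function(percentage) {
  if (any(!is.na(percentage) & (percentage < 0 | percentage > 100))) {
    stop("percentage must be in [0, 100]", call. = FALSE)
  }
  p <- round_half_up(percentage)
  out <- dplyr::case_when(
    is.na(p) ~ NA_integer_,
    p <= 10 ~ 0L,
    p <= 50 ~ 1L,
    p <= 90 ~ 2L,
    TRUE ~ 3L
  )
  out
}

#' Barrier-resolution points
#'
#' Each barrier outcome is scored on a 4-point scale from its
#' addressed/resolved status: 1 = not addressed, not resolved; 2 = not
#' addressed but resolved; 3 = addressed but not resolved (an attempt was
#' made); 4 = addressed and resolved ("resolved" means the barrier did not
#' reappear at 6 months).
#'
#' @param addressed,resolved Logical vectors (recycled to common length).
#' @return Integer vector in 1-4.
#' @examples
#' resolution_points(addressed = c(FALSE, FALSE, TRUE, TRUE),
#'                   resolved  = c(FALSE, TRUE, FALSE, TRUE))  # 1 2 3 4
#' @export
resolution_points <- function(addressed, resolved) {
  if (anyNA(addressed) || anyNA(resolved)) {
    stop("addressed/resolved flags must be non-missing", call. = FALSE)
  }
  as.integer(1L + 2L * addressed + resolved)
}

#' Mean barrier resolution score
#'
#' The per-participant mean of the 1-4 resolution points over their active
#' barriers; the mean (rather than a sum) adjusts for participants with
#' fewer than three barriers. Reported to 2 decimals.
#'
#' @param addressed,resolved Logical vectors of equal length (one element per
#'   barrier outcome).
#' @return A single number in \[1, 4\], rounded to 2 decimals.
#' @examples
#' mean_barrier_resolution(c(FALSE, FALSE, TRUE), c(FALSE, FALSE, FALSE)) # 1.67
#' @export
mean_barrier_resolution <- function(addressed, resolved) {
  if (length(addressed) == 0) {
    stop("mean barrier resolution is undefined with no barrier outcomes",
         call. = FALSE)
  }
  round_half_up(mean(resolution_points(addressed, resolved)), 2)
}

resolution_category_levels <- function() {
  c("addressed_resolved", "addressed_unresolved",
    "unaddressed_unresolved", "unaddressed_resolved")
}

#' Summarize barrier outcomes into the four resolution categories
#'
#' Pools barrier outcomes (optionally per group) and tabulates the four
#' addressed-by-resolved categories with percentages of the group total.
#'
#' @param outcomes A tibble with logical columns `addressed` and `resolved`,
#'   one row per barrier outcome; any dplyr grouping (e.g. by `arm`) is
#'   respected.
#' @return A tibble with (per group) one row per category: `category`, `n`,
#'   `pct` (2 decimals; `NA` with zero total), `total_barriers`.
#' @examples
#' outcomes <- tibble::tibble(
#'   addressed = c(rep(TRUE, 8), rep(FALSE, 20)),
#'   resolved = c(TRUE, rep(FALSE, 27))
#' )
#' summarize_resolution(outcomes)  # 3.57 / 25.00 / 71.43 / 0.00
#' @export
summarize_resolution <- function(outcomes) {
  lvls <- resolution_category_levels()
  one <- function(df) {
    total <- nrow(df)
    cat <- dplyr::case_when(
      df$addressed & df$resolved ~ lvls[1],
      df$addressed & !df$resolved ~ lvls[2],
      !df$addressed & !df$resolved ~ lvls[3],
      TRUE ~ lvls[4]
    )
    n <- unname(vapply(lvls, function(l) sum(cat == l), integer(1)))
    tibble::tibble(
      category = factor(lvls, levels = lvls),
      n = n,
      pct = if (total == 0) NA_real_ else round_half_up(100 * n / total, 2),
      total_barriers = total
    )
  }
  if (dplyr::is_grouped_df(outcomes)) {
    dplyr::ungroup(dplyr::group_modify(outcomes, function(df, key) one(df)))
  } else {
    one(tibble::as_tibble(outcomes))
  }
}

#' Long-format barrier outcomes from a cohort
#'
#' @param cohort A validated cohort tibble.
#' @return A tibble with one row per recorded barrier outcome:
#'   `participant_id`, `arm`, `barrier_id`, `severity`, `addressed`,
#'   `resolved`, `points`.
#' @export
barrier_outcomes <- function(cohort) {
  validate_cohort(cohort)
  long <- function(prefix, value_name) {
    cohort |>
      dplyr::select("participant_id", "arm",
                    dplyr::all_of(sprintf("%s_%02d", prefix, 1:24))) |>
      tidyr::pivot_longer(-c("participant_id", "arm"),
                          names_to = "barrier_id",
                          names_prefix = paste0(prefix, "_"),
                          values_to = value_name) |>
      dplyr::mutate(barrier_id = as.integer(.data$barrier_id))
  }
  out <- long("barrier_severity", "severity") |>
    dplyr::inner_join(long("barrier_addressed", "addressed"),
                      by = c("participant_id", "arm", "barrier_id")) |>
    dplyr::inner_join(long("barrier_resolved", "resolved"),
                      by = c("participant_id", "arm", "barrier_id")) |>
    dplyr::filter(!is.na(.data$addressed) & !is.na(.data$resolved))
  out$points <- resolution_points(out$addressed, out$resolved)
  out
}

#' Per-participant resolution scores for a cohort
#'
#' @param cohort A validated cohort tibble.
#' @return A tibble, one row per participant with at least one barrier
#'   outcome: `participant_id`, `arm`, `n_barriers`,
#'   `mean_resolution_score`.
#' @export
score_resolution <- function(cohort) {
  barrier_outcomes(cohort) |>
    dplyr::group_by(.data$participant_id, .data$arm) |>
    dplyr::summarise(
      n_barriers = dplyr::n(),
      mean_resolution_score = mean_barrier_resolution(.data$addressed, .data$resolved),
      .groups = "drop"
    )
}

#' Adherence scores for a cohort
#'
#' Computes the adherence percentage (with its audit envelope), the modified
#' Q10 band derived from it, and carries the clinician-assigned unmodified
#' Q10 (VCSS item 10) for each participant and timepoint with a wear report.
#'
#' @param cohort A validated cohort tibble.
#' @param mode Interval-resolution mode, see [adherence_percentage()].
#' @return A tibble: `participant_id`, `arm`, `timepoint`
#'   (baseline/followup), `percentage`, `pct_min`, `pct_max`,
#'   `modified_q10`, `unmodified_q10`.
#' @export
score_adherence <- function(cohort, mode = c("conservative", "midpoint")) {
  mode <- match.arg(mode)
  validate_cohort(cohort)
  one_tp <- function(tp) {
    has <- !is.na(cohort[[paste0(tp, "_hours_awake")]])
    if (!any(has)) return(NULL)
    sub <- cohort[has, ]
    scores <- purrr::pmap_dfr(
      list(sub[[paste0(tp, "_hours_awake")]],
           sub[[paste0(tp, "_hours_worn_left")]],
           sub[[paste0(tp, "_hours_worn_right")]],
           sub[[paste0(tp, "_days_per_week")]]),
      function(aw, wl, wr, d) adherence_percentage(aw, wl, wr, d, mode = mode)
    )
    tibble::tibble(
      participant_id = sub$participant_id, arm = sub$arm, timepoint = tp,
      percentage = scores$percentage, pct_min = scores$pct_min,
      pct_max = scores$pct_max,
      modified_q10 = modified_q10(scores$percentage),
      unmodified_q10 = as.integer(sub[[paste0(tp, "_vcss_q10")]])
    )
  }
  dplyr::bind_rows(one_tp("baseline"), one_tp("followup"))
}

#' Baseline-to-followup change scores per participant
#'
#' @param cohort A validated cohort tibble.
#' @param mode Interval-resolution mode for the adherence percentage.
#' @return A tibble with one row per participant:
#'   baseline/followup/change of adherence percentage, modified and
#'   unmodified Q10, VCSS total, CIVIQ-14, utility and VAS. Change columns
#'   are `NA` for participants with a missing follow-up block.
#' @export
change_scores <- function(cohort, mode = "conservative") {
  adh <- score_adherence(cohort, mode = mode) |>
    dplyr::select("participant_id", "timepoint", "percentage",
                  "modified_q10", "unmodified_q10") |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = c("percentage", "modified_q10", "unmodified_q10"))
  for (col in c(paste0(c("percentage_", "modified_q10_", "unmodified_q10_"),
                       rep(c("baseline", "followup"), each = 3)))) {
    if (!col %in% names(adh)) adh[[col]] <- NA_real_
  }
  vcss_total <- function(tp) {
    rowSums(cohort[, paste0(tp, "_vcss_q", 1:10), drop = FALSE])
  }
  cohort |>
    dplyr::transmute(
      .data$participant_id, .data$arm,
      vcss_baseline = vcss_total("baseline"),
      vcss_followup = vcss_total("followup"),
      civiq_baseline = .data$baseline_civiq14_gis,
      civiq_followup = .data$followup_civiq14_gis,
      utility_baseline = .data$baseline_eq5d_utility,
      utility_followup = .data$followup_eq5d_utility,
      vas_baseline = .data$baseline_eq5d_vas,
      vas_followup = .data$followup_eq5d_vas
    ) |>
    dplyr::left_join(adh, by = "participant_id") |>
    dplyr::mutate(
      pct_change = .data$percentage_followup - .data$percentage_baseline,
      modified_q10_change = .data$modified_q10_followup - .data$modified_q10_baseline,
      unmodified_q10_change = .data$unmodified_q10_followup - .data$unmodified_q10_baseline,
      vcss_change = .data$vcss_followup - .data$vcss_baseline,
      civiq_change = .data$civiq_followup - .data$civiq_baseline,
      utility_change = .data$utility_followup - .data$utility_baseline,
      vas_change = .data$vas_followup - .data$vas_baseline
    )
}
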