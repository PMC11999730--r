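#' Cost a participant's resource use
#'
#' Appointment costs are counts times the configured unit prices; materials
#' are summed from their recorded unit costs, falling back to the catalogue
#' price when a cost is not carried with the item (a label with neither is a
#' configuration error). Specialist appointments and admissions are costed
#' at their configured unit prices (zero usage, hence zero cost, in the
#' pilot).
#'
#' @param n_f2f,n_phone,n_specialist,n_admissions Non-negative counts.
#' @param materials A tibble with columns `item` and `unit_cost` (may have
#'   zero rows), or a materials string as stored in a cohort file
#'   (`"item=cost;item"`).
#' @param prices A [price_table()].
#' @return A one-row tibble: `appointment_cost`, `materials_cost`,
#'   `specialist_cost`, `admission_cost`, `total` (all AUD; `total` is the
#'   exact sum of the components).
#' @examples
#' cost_participant(2, 1, prices = price_table())  # 2 x 193 + 177 = 563
#' @export
cost_participant <- function(n_f2f = 0, n_phone = 0, n_specialist = 0,
                             n_admissions = 0, materials = NULL,
                             prices = price_table()) {
  validate_price_table(prices)
  counts <- c(n_f2f, n_phone, n_specialist, n_admissions)
  if (any(is.na(counts) | counts < 0 | counts != floor(counts))) {
    stop("appointment/admission counts must be non-negative integers",
         call. = FALSE)
  }
  if (is.null(materials)) {
    materials <- tibble::tibble(item = character(), unit_cost = numeric())
  } else if (is.character(materials)) {
    materials <- parse_materials(materials)[[1]]
  }
  mat_cost <- 0
  if (nrow(materials) > 0) {
    cat_prices <- setNames(prices$material_catalogue$unit_cost,
                           prices$material_catalogue$item)
    costs <- materials$unit_cost
    need <- is.na(costs)
    if (any(need)) {
      unknown <- materials$item[need][!materials$item[need] %in% names(cat_prices)]
      if (length(unknown)) {
        stop("material item(s) not in catalogue and no unit cost recorded: ",
             paste(unique(unknown), collapse = ", "), call. = FALSE)
      }
      costs[need] <- cat_prices[materials$item[need]]
      if (anyNA(costs)) {
        stop("catalogue has no price for material item(s): ",
             paste(unique(materials$item[need][is.na(costs[need])]), collapse = ", "),
             call. = FALSE)
      }
    }
    mat_cost <- sum(costs)
  }
  appt <- n_f2f * prices$f2f_cost + n_phone * prices$phone_cost
  spec <- n_specialist * prices$specialist_cost
  adm <- n_admissions * prices$admission_cost
  tibble::tibble(appointment_cost = appt, materials_cost = mat_cost,
                 specialist_cost = spec, admission_cost = adm,
                 total = appt + mat_cost + spec + adm)
}

#' Per-participant cost breakdown for a cohort
#'
#' @param cohort A validated cohort tibble.
#' @param prices A [price_table()].
#' @return A tibble with one row per participant: `participant_id`, `arm`
#'   and the [cost_participant()] breakdown columns.
#' @export
cost_cohort <- function(cohort, prices = price_table()) {
  validate_cohort(cohort)
  bd <- purrr::pmap_dfr(
    list(cohort$n_f2f_appointments, cohort$n_phone_appointments,
         cohort$n_specialist_vlu_appointments, cohort$n_vlu_admissions,
         cohort$materials),
    function(f2f, ph, sp, adm, mat) {
      cost_participant(f2f, ph, sp, adm, mat, prices = prices)
    }
  )
  dplyr::bind_cols(cohort[, c("participant_id", "arm")], bd)
}

#' QALYs by area under the utility curve over one year
#'
#' Utilities are measured at baseline and 6 months; the 6-month value is
#' extrapolated to 12 months and the area under the utility-time curve gives
#' the QALY. Two extrapolation modes: `"locf"` (default) carries the
#' 6-month value flat to the horizon after trapezoidal integration of the
#' first segment, `QALY = 0.5 * (u0 + u6) / 2 + (horizon - 0.5) * u6`;
#' `"linear"` continues the baseline-to-6-month linear trend. A missing
#' 6-month utility carries the baseline forward (`QALY = u0 * horizon`); no
#' discounting is applied within the one-year horizon.
#'
#' @param u_baseline Baseline utility in `[-0.6, 1]` (required).
#' @param u_6mo Six-month utility; may be `NA`.
#' @param horizon_years Time horizon in years (>= 0.5).
#' @param extrapolation `"locf"` or `"linear"`.
#' @return Numeric vector of QALYs.
#' @examples
#' qaly_auc(0.70, 0.60)  # 0.625
#' @export
qaly_auc <- function(u_baseline, u_6mo, horizon_years = 1,
                     extrapolation = c("locf", "linear")) {
  extrapolation <- match.arg(extrapolation)
  stopifnot(horizon_years >= 0.5)
  if (anyNA(u_baseline)) {
    stop("baseline utility is required for each participant", call. = FALSE)
  }
  chk <- function(u) any(!is.na(u) & (u < -0.6 | u > 1))
  if (chk(u_baseline) || chk(u_6mo)) {
    stop("utilities must lie in [-0.6, 1]", call. = FALSE)
  }
  n <- max(length(u_baseline), length(u_6mo))
  u0 <- rep_len(u_baseline, n); u6 <- rep_len(u_6mo, n)
  carried <- is.na(u6)
  first <- 0.5 * (u0 + ifelse(carried, u0, u6)) / 2
  tail_len <- horizon_years - 0.5
  u12 <- if (extrapolation == "locf") {
    ifelse(carried, u0, u6)
  } else {
    # linear trend continuation, clamped to the utility scale
    pmin(pmax(u6 + (u6 - u0) * (tail_len / 0.5), -0.6), 1)
  }
  tail_area <- if (extrapolation == "locf") {
    tail_len * ifelse(carried, u0, u6)
  } else {
    tail_len * (ifelse(carried, u0, u6) + ifelse(carried, u0, u12)) / 2
  }
  out <- ifelse(carried, u0 * horizon_years, first + tail_area)
  attr(out, "baseline_carried") <- carried
  out
}

classify_dominance <- function(delta_cost, delta_qaly) {
  if (delta_cost <= 0 && delta_qaly >= 0) "dominant"
  else if (delta_cost >= 0 && delta_qaly <= 0) "dominated"
  else if (delta_cost > 0 && delta_qaly > 0) "tradeoff_ne"
  else "tradeoff_sw"
}

#' Within-trial cost-utility analysis
#'
#' From the health service perspective: per-arm mean total costs over the
#' trial period, per-participant QALYs by [qaly_auc()], the incremental
#' cost (intervention minus usual care), the incremental QALY both raw and
#' adjusted for baseline utility disparity (the arm coefficient of an OLS
#' regression of participant QALY on arm + baseline utility), the ICER
#' `delta_cost / delta_qaly_adjusted`, a dominance classification from the
#' signs of the increments, and comparison against a willingness-to-pay
#' threshold (default AUD 28,033 per QALY). Participants with a missing
#' 6-month utility contribute a baseline-carried-forward QALY (flagged);
#' participants missing baseline utility are excluded.
#'
#' @param cohort A validated cohort tibble with both arms represented.
#' @param prices A [price_table()].
#' @param wtp Willingness-to-pay threshold, AUD per QALY.
#' @param horizon_years,extrapolation Passed to [qaly_auc()].
#' @return A `cua_result` object: per-participant tibble, per-arm summary,
#'   `delta_cost`, `delta_qaly_unadjusted`, `delta_qaly_adjusted`, `icer`
#'   (`NA` outside the trade-off quadrants or when the adjusted delta is 0),
#'   `dominance`, `wtp_threshold`, `cost_effective`, and the underlying
#'   `ancova_fit`. Supports [tidy()] and [glance()].
#' @export
cost_utility_analysis <- function(cohort, prices = price_table(), wtp = 28033,
                                  horizon_years = 1,
                                  extrapolation = c("locf", "linear")) {
  extrapolation <- match.arg(extrapolation)
  validate_cohort(cohort)
  costs <- cost_cohort(cohort, prices)
  keep <- !is.na(cohort$baseline_eq5d_utility)
  if (!all(keep)) {
    warning(sum(!keep), " participant(s) excluded from the CUA: missing baseline utility",
            call. = FALSE)
  }
  dat <- cohort[keep, ]
  per_arm_n <- table(factor(dat$arm, levels = arm_levels()))
  if (any(per_arm_n < 2)) {
    stop("the cost-utility analysis needs >= 2 participants per arm with baseline utility",
         call. = FALSE)
  }
  q <- qaly_auc(dat$baseline_eq5d_utility, dat$followup_eq5d_utility,
                horizon_years = horizon_years, extrapolation = extrapolation)
  pp <- tibble::tibble(
    participant_id = dat$participant_id, arm = dat$arm,
    total_cost = costs$total[keep],
    baseline_utility = dat$baseline_eq5d_utility,
    followup_utility = dat$followup_eq5d_utility,
    qaly = as.numeric(q),
    baseline_carried = attr(q, "baseline_carried")
  )
  arm_summary <- pp |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cost = mean(.data$total_cost), sd_cost = stats::sd(.data$total_cost),
      mean_qaly = mean(.data$qaly), sd_qaly = stats::sd(.data$qaly),
      .groups = "drop"
    )
  get <- function(col, a) arm_summary[[col]][arm_summary$arm == a]
  delta_cost <- get("mean_cost", "intervention") - get("mean_cost", "usual_care")
  delta_q_raw <- get("mean_qaly", "intervention") - get("mean_qaly", "usual_care")
  fit <- tryCatch(
    adjusted_group_effect(pp, .data$qaly, .data$arm, .data$baseline_utility),
    error = function(e) {
      warning("baseline-utility adjustment unavailable (", conditionMessage(e),
              "); using the unadjusted QALY difference", call. = FALSE)
      NULL
    })
  delta_q_adj <- if (is.null(fit)) delta_q_raw else fit$group_effect
  dominance <- classify_dominance(delta_cost, delta_q_adj)
  icer <- if (dominance %in% c("tradeoff_ne", "tradeoff_sw") && delta_q_adj != 0) {
    delta_cost / delta_q_adj
  } else NA_real_
  cost_effective <- dominance == "dominant" ||
    (dominance == "tradeoff_ne" && !is.na(icer) && icer <= wtp)
  structure(
    list(per_participant = pp, arm_summary = arm_summary,
         delta_cost = delta_cost, delta_qaly_unadjusted = delta_q_raw,
         delta_qaly_adjusted = delta_q_adj, icer = icer,
         dominance = dominance, wtp_threshold = wtp,
         cost_effective = cost_effective, adjustment_fit = fit,
         horizon_years = horizon_years, extrapolation = extrapolation),
    class = "cua_result"
  )
}

#' @export
print.cua_result <- function(x, ...) {
  cat("Within-trial cost-utility analysis\n")
  s <- x$arm_summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s n = %d, mean cost $%.2f (SD %.2f), mean QALY %.3f\n",
                s$arm[i], s$n[i], s$mean_cost[i], s$sd_cost[i], s$mean_qaly[i]))
  }
  cat(sprintf("  incremental cost: $%.2f\n", x$delta_cost))
  cat(sprintf("  incremental QALY: %.4f raw, %.4f baseline-adjusted\n",
              x$delta_qaly_unadjusted, x$delta_qaly_adjusted))
  if (is.na(x$icer)) {
    cat("  ICER: undefined (", x$dominance, ")\n", sep = "")
  } else {
    cat(sprintf("  ICER: $%.2f per QALY (%s)\n", x$icer, x$dominance))
  }
  cat(sprintf("  cost-effective at WTP $%.0f/QALY: %s\n",
              x$wtp_threshold, x$cost_effective))
  invisible(x)
}

#' Cost-effectiveness plane for a CUA result
#'
#' A single-point incremental cost vs incremental (adjusted) QALY plot with
#' the willingness-to-pay threshold line.
#'
#' @param object A `cua_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cua_result <- function(object, ...) {
  df <- tibble::tibble(dq = object$delta_qaly_adjusted, dc = object$delta_cost)
  lim_q <- max(abs(df$dq), 0.05) * 1.4
  lim_c <- max(abs(df$dc), 100) * 1.4
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dq, y = .data$dc)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = object$wtp_threshold, intercept = 0,
                         linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_cartesian(xlim = c(-lim_q, lim_q), ylim = c(-lim_c, lim_c)) +
    ggplot2::labs(x = "Incremental QALY (baseline-adjusted)",
                  y = "Incremental cost (AUD)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("dashed line: WTP $%.0f per QALY",
                                     object$wtp_threshold)) +
    ggplot2::theme_minimal()
}
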