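cohort_schema_version <- "1.0"

tp_cols <- function(tp) {
  c(paste0(tp, "_", c("hours_awake", "hours_worn_left", "hours_worn_right",
                      "days_per_week")),
    paste0(tp, "_vcss_q", 1:10),
    paste0(tp, "_", c("civiq14_gis", "eq5d_utility", "eq5d_vas")))
}

barrier_cols <- function() {
  c(sprintf("barrier_severity_%02d", 1:24),
    sprintf("barrier_addressed_%02d", 1:24),
    sprintf("barrier_resolved_%02d", 1:24))
}

resource_cols <- function() {
  c("n_f2f_appointments", "n_phone_appointments",
    "n_specialist_vlu_appointments", "n_vlu_admissions", "materials")
}

cohort_columns <- function() {
  c("participant_id", "arm", "age", "gender", "bmi", "education", "marital",
    "smoker", tp_cols("baseline"), tp_cols("followup"), barrier_cols(),
    resource_cols())
}

#' Column dictionary for cohort files
#'
#' One row per participant, wide format with `baseline_`/`followup_` prefixed
#' measurement blocks. Interval-valued quantities (hours awake, hours worn per
#' leg, days per week) are strings in `"lo-hi"` form, a single number when a
#' single value was reported. Missingness is the literal `NA` token — a
#' withdrawn or unreachable participant has an all-`NA` follow-up block, which
#' is distinct from zeros. Materials are encoded `"item=cost;item=cost"`
#' (cost omitted when the price comes from the catalogue).
#'
#' @return A tibble with columns `column`, `type` and `description`, covering
#'   every column of a cohort file. A JSON rendering of the same dictionary
#'   ships in `inst/extdata/cohort_schema.json`.
#' @examples
#' cohort_dictionary()
#' @export
cohort_dictionary <- function() {
  base <- tibble::tribble(
    ~column, ~type, ~description,
    "participant_id", "string", "Unique participant label, e.g. P01",
    "arm", "enum", "usual_care or intervention",
    "age", "number", "Age in years",
    "gender", "enum", "female, male or other",
    "bmi", "number", "Body mass index, kg/m^2",
    "education", "enum", "below_grade10, grade10_12, trade_cert, degree",
    "marital", "enum", "partnered or unpartnered",
    "smoker", "enum", "never, previous or current",
  )
  tp_dict <- function(tp) {
    tibble::tibble(
      column = tp_cols(tp),
      type = c(rep("interval", 4), rep("integer", 10), rep("number", 3)),
      description = c(
        paste0(tp, ": estimated hours awake per day, 0-24, possibly a range"),
        paste0(tp, ": hours stockings worn per day, left leg, 0-24, possibly a range"),
        paste0(tp, ": hours stockings worn per day, right leg, 0-24, possibly a range"),
        paste0(tp, ": days per week stockings worn, 0-7, possibly a range"),
        sprintf("%s: VCSS item %d, 0-3%s", tp, 1:10,
                c(rep("", 9), " (Q10: clinician-scored compression compliance)")),
        paste0(tp, ": CIVIQ-14 global index score, 0-100"),
        paste0(tp, ": EQ-5D-5L utility, in [-0.6, 1.0]"),
        paste0(tp, ": EQ-5D-5L visual analogue scale, 0-100")
      )
    )
  }
  barr <- tibble::tibble(
    column = barrier_cols(),
    type = c(rep("integer", 24), rep("flag", 48)),
    description = c(
      sprintf("Severity (1 mild - 5 severe) of barrier %d; NA when not applicable", 1:24),
      sprintf("Barrier %d addressed during the trial (TRUE/FALSE)", 1:24),
      sprintf("Barrier %d resolved, i.e. did not reappear at 6 months (TRUE/FALSE)", 1:24)
    )
  )
  res <- tibble::tibble(
    column = resource_cols(),
    type = c(rep("integer", 4), "string"),
    description = c(
      "Number of face-to-face occupational-therapy appointments",
      "Number of phone/telehealth appointments",
      "Number of specialist VLU-recurrence appointments",
      "Number of VLU-related hospital admissions",
      "Materials as item=cost pairs separated by ';' (cost in AUD)"
    )
  )
  dplyr::bind_rows(base, tp_dict("baseline"), tp_dict("followup"), barr, res)
}

#' An empty cohort tibble with the full column set
#'
#' Useful for building small cohorts by hand (tests, examples).
#'
#' @param n Number of blank rows.
#' @return A tibble with all cohort columns, correctly typed, all values `NA`
#'   except appointment counts (0) and materials ("").
#' @export
cohort_template <- function(n = 0L) {
  cols <- cohort_columns()
  dict <- cohort_dictionary()
  type_of <- setNames(dict$type, dict$column)
  vals <- lapply(cols, function(cn) {
    switch(type_of[[cn]],
           string = rep(NA_character_, n),
           enum = rep(NA_character_, n),
           interval = rep(NA_character_, n),
           integer = rep(NA_integer_, n),
           number = rep(NA_real_, n),
           flag = rep(NA, n))
  })
  out <- tibble::as_tibble(setNames(vals, cols))
  if (n > 0) {
    out$n_f2f_appointments <- 0L
    out$n_phone_appointments <- 0L
    out$n_specialist_vlu_appointments <- 0L
    out$n_vlu_admissions <- 0L
    out$materials <- ""
  }
  out
}

parse_materials <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      return(tibble::tibble(item = character(), unit_cost = numeric()))
    }
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts[nzchar(trimws(parts))])
    kv <- strsplit(parts, "=", fixed = TRUE)
    tibble::tibble(
      item = vapply(kv, function(p) trimws(p[1]), character(1)),
      unit_cost = vapply(kv, function(p) {
        if (length(p) < 2) NA_real_ else as.numeric(p[2])
      }, numeric(1))
    )
  })
}

format_materials <- function(mats) {
  vapply(mats, function(m) {
    if (nrow(m) == 0) return("")
    paste(ifelse(is.na(m$unit_cost), m$item,
                 paste0(m$item, "=", sprintf("%.2f", m$unit_cost))),
          collapse = ";")
  }, character(1))
}

#' Validate a cohort tibble
#'
#' Checks the full column dictionary: arm labels, Likert severities in 1-5,
#' VCSS items in 0-3, utilities in \[-0.6, 1\], interval bounds (hours in
#' \[0, 24\], days in \[0, 7\]), non-negative counts, and that any present
#' wear report has at least one leg interval. A follow-up block that is
#' entirely `NA` is a legal missing marker (withdrawn/unreachable
#' participant). Errors name the offending participant and column.
#'
#' @param cohort A cohort tibble (see [cohort_dictionary()]).
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cohort) == 0) return(invisible(cohort))
  fail <- function(rows, col, why) {
    ids <- cohort$participant_id[rows]
    ids[is.na(ids)] <- paste0("row ", which(rows)[is.na(ids)])
    stop("invalid cohort: column '", col, "' ", why, " for participant(s) ",
         paste(utils::head(unique(ids), 5), collapse = ", "), call. = FALSE)
  }
  if (anyNA(cohort$participant_id) || any(!nzchar(cohort$participant_id))) {
    stop("invalid cohort: participant_id must be non-missing", call. = FALSE)
  }
  if (anyDuplicated(cohort$participant_id)) {
    stop("invalid cohort: duplicate participant_id ",
         paste(unique(cohort$participant_id[duplicated(cohort$participant_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(cohort$arm)) stop("invalid cohort: arm must be non-missing", call. = FALSE)
  assert_arm(cohort$arm)

  check_range <- function(col, lo, hi, integer = FALSE) {
    v <- cohort[[col]]
    bad <- !is.na(v) & (v < lo | v > hi | (integer & v != floor(v)))
    if (any(bad)) fail(bad, col, sprintf("outside %s-%s", lo, hi))
  }
  for (tp in c("baseline", "followup")) {
    for (q in 1:10) check_range(paste0(tp, "_vcss_q", q), 0, 3, integer = TRUE)
    check_range(paste0(tp, "_eq5d_utility"), -0.6, 1.0)
    check_range(paste0(tp, "_eq5d_vas"), 0, 100)
    check_range(paste0(tp, "_civiq14_gis"), 0, 100)
    for (col in paste0(tp, "_", c("hours_awake", "hours_worn_left", "hours_worn_right"))) {
      iv <- parse_interval(cohort[[col]])
      bad <- !is.na(iv$lo) & (iv$lo < 0 | iv$hi > 24)
      if (any(bad)) fail(bad, col, "outside 0-24 hours")
    }
    dcol <- paste0(tp, "_days_per_week")
    iv <- parse_interval(cohort[[dcol]])
    bad <- !is.na(iv$lo) & (iv$lo < 0 | iv$hi > 7)
    if (any(bad)) fail(bad, dcol, "outside 0-7 days")
    # a present wear report needs at least one leg
    awake <- !is.na(cohort[[paste0(tp, "_hours_awake")]])
    no_leg <- awake & is.na(cohort[[paste0(tp, "_hours_worn_left")]]) &
      is.na(cohort[[paste0(tp, "_hours_worn_right")]])
    if (any(no_leg)) {
      fail(no_leg, paste0(tp, "_hours_worn_left"),
           "wear report has hours awake but no worn-hours interval for either leg")
    }
  }
  for (b in 1:24) {
    col <- sprintf("barrier_severity_%02d", b)
    v <- cohort[[col]]
    bad <- !is.na(v) & !(v %in% 1:5)
    if (any(bad)) fail(bad, col, sprintf("severity outside 1-5 (barrier %d)", b))
  }
  for (col in resource_cols()[1:4]) {
    v <- cohort[[col]]
    bad <- !is.na(v) & (v < 0 | v != floor(v))
    if (any(bad)) fail(bad, col, "must be a non-negative count")
  }
  mats <- parse_materials(cohort$materials)
  badm <- vapply(mats, function(m) any(!is.na(m$unit_cost) & m$unit_cost < 0), logical(1))
  if (any(badm)) fail(badm, "materials", "has a negative unit cost")
  invisible(cohort)
}

#' Which participants are missing their follow-up block?
#'
#' A follow-up block that is entirely `NA` marks a participant who withdrew or
#' was unreachable at 6 months; such participants contribute baseline data
#' only (intention-to-treat with available data).
#'
#' @param cohort A cohort tibble.
#' @return Logical vector, `TRUE` where the follow-up block is entirely `NA`.
#' @export
followup_missing <- function(cohort) {
  fu <- cohort[, tp_cols("followup"), drop = FALSE]
  apply(is.na(fu), 1, all)
}
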