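# Small cohorts built in code for unit tests.

# A fully-populated participant row with sensible defaults; override any
# column by name.
make_participant <- function(id, arm = "usual_care", ...) {
  row <- cohort_template(1)
  row$participant_id <- id
  row$arm <- arm
  row$age <- 70
  row$gender <- "female"
  row$bmi <- 29
  row$education <- "grade10_12"
  row$marital <- "partnered"
  row$smoker <- "previous"
  for (tp in c("baseline", "followup")) {
    row[[paste0(tp, "_hours_awake")]] <- "16"
    row[[paste0(tp, "_hours_worn_left")]] <- "8"
    row[[paste0(tp, "_hours_worn_right")]] <- "8"
    row[[paste0(tp, "_days_per_week")]] <- "7"
    for (q in 1:10) row[[paste0(tp, "_vcss_q", q)]] <- 1L
    row[[paste0(tp, "_civiq14_gis")]] <- 40
    row[[paste0(tp, "_eq5d_utility")]] <- 0.7
    row[[paste0(tp, "_eq5d_vas")]] <- 55
  }
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# attach barrier records (severity + outcome flags) to a one-row cohort
with_barriers <- function(row, ids, severity = 3L, addressed = FALSE,
                          resolved = FALSE) {
  severity <- rep_len(severity, length(ids))
  addressed <- rep_len(addressed, length(ids))
  resolved <- rep_len(resolved, length(ids))
  for (j in seq_along(ids)) {
    row[[sprintf("barrier_severity_%02d", ids[j])]] <- as.integer(severity[j])
    row[[sprintf("barrier_addressed_%02d", ids[j])]] <- addressed[j]
    row[[sprintf("barrier_resolved_%02d", ids[j])]] <- resolved[j]
  }
  row
}

# blank out the follow-up block (withdrawn / unreachable participant)
drop_followup <- function(row) {
  for (col in grep("^followup_", names(row), value = TRUE)) {
    row[[col]] <- row[[col]][NA]
  }
  row
}

# a small two-arm cohort: 3 usual care + 3 intervention, deterministic values
tiny_cohort <- function() {
  dplyr::bind_rows(
    with_barriers(make_participant("U1", "usual_care",
                                   followup_hours_worn_left = "4",
                                   followup_hours_worn_right = "4"),
                  ids = c(1, 2), addressed = FALSE, resolved = FALSE),
    with_barriers(make_participant("U2", "usual_care", baseline_eq5d_utility = 0.6,
                                   followup_eq5d_utility = 0.55),
                  ids = 3, addressed = TRUE, resolved = FALSE),
    make_participant("U3", "usual_care"),
    with_barriers(make_participant("I1", "intervention",
                                   n_f2f_appointments = 3L,
                                   followup_hours_worn_left = "14",
                                   followup_hours_worn_right = "14"),
                  ids = c(1, 4), addressed = TRUE, resolved = TRUE),
    with_barriers(make_participant("I2", "intervention", baseline_eq5d_utility = 0.5,
                                   followup_eq5d_utility = 0.8,
                                   n_phone_appointments = 2L),
                  ids = 2, addressed = TRUE, resolved = TRUE),
    make_participant("I3", "intervention")
  )
}

# Reconstruction of the pilot's usual-care arm barrier outcomes: per
# participant, the multiset of (addressed, resolved) pairs consistent with
# the printed per-participant mean scores and the pooled category counts
# (1 addressed+resolved, 7 addressed only, 20 neither; 28 in total).
usual_care_outcome_sets <- function() {
  pts <- list(
    P01 = c(1), P03 = c(1, 1, 1), P05 = c(3, 1, 1), P07 = c(3, 3, 1),
    P10 = c(4, 1, 1), P12 = c(3, 1, 1), P14 = c(3, 1, 1), P15 = c(1, 1, 1),
    P17 = c(3, 3, 1), P18 = c(1, 1, 1)
  )
  purrr::imap_dfr(pts, function(points, id) {
    tibble::tibble(
      participant_id = id,
      addressed = points >= 3,
      resolved = points %in% c(2, 4)
    )
  })
}
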