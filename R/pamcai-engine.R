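#' Adhesig eligibility screen
#'
#' Five screening questions each scored 0-4; the total grades current
#' adherence and a participant is eligible when the total is strictly above
#' the threshold (default 3).
#'
#' @param answers Integer vector of exactly five answers, each in 0-4.
#' @param threshold Eligibility threshold; eligibility is `total > threshold`
#'   (strict).
#' @return A one-row tibble with columns `total` and `eligible`.
#' @examples
#' adhesig_screen(c(1, 1, 1, 1, 0))  # total 4 -> eligible
#' adhesig_screen(c(1, 1, 1, 0, 0))  # total 3 -> not eligible (strict >)
#' @export
adhesig_screen <- function(answers, threshold = 3L) {
  if (length(answers) != 5L) {
    stop("the screen has exactly five answers; got ", length(answers),
         call. = FALSE)
  }
  if (anyNA(answers) || any(answers < 0 | answers > 4 | answers != floor(answers))) {
    stop("screen answers must be integers in 0-4", call. = FALSE)
  }
  total <- as.integer(sum(answers))
  tibble::tibble(total = total, eligible = total > threshold)
}

#' Select the top three weighted barriers
#'
#' The decision aid sorts a participant's barrier responses by severity and
#' surfaces the top three. Display is contractually *unordered* (the tool
#' shows the three without ranking them); this function nevertheless returns
#' a deterministic order for reproducibility. When the third and fourth
#' barriers share a severity the selection is ambiguous in principle and is
#' delegated to clinician discretion in practice: the deterministic tie-break
#' used here is ascending barrier id, and `tie_flag` is set so the discretion
#' point is visible.
#'
#' @param severities Either a tibble with columns `barrier_id` and `severity`,
#'   or a named numeric vector (names = barrier ids). Absent barriers are
#'   simply omitted (never selected).
#' @return An object of class `top_barriers`: a list with `selected` (tibble
#'   `barrier_id`, `severity`, in selection order), `tie_flag`, and
#'   `discretion_note` (non-`NA` only when `tie_flag` is set). An empty
#'   assessment yields an empty selection with a warning, not an error.
#' @examples
#' select_top_barriers(c("2" = 5, "7" = 4, "9" = 3, "11" = 1))
#' @export
select_top_barriers <- function(severities) {
  if (is.numeric(severities)) {
    if (is.null(names(severities)) && length(severities) > 0) {
      stop("a numeric severities vector must be named by barrier id", call. = FALSE)
    }
    severities <- tibble::tibble(
      barrier_id = as.integer(names(severities)),
      severity = as.numeric(severities)
    )
  }
  severities <- tibble::as_tibble(severities)[, c("barrier_id", "severity")]
  severities <- dplyr::filter(severities, !is.na(.data$severity))
  if (any(!severities$severity %in% 1:5)) {
    stop("barrier severities must be in 1-5", call. = FALSE)
  }
  if (any(!severities$barrier_id %in% 1:24)) {
    stop("barrier ids must be in the 24-item catalogue (1-24)", call. = FALSE)
  }
  if (anyDuplicated(severities$barrier_id)) {
    stop("duplicate barrier ids in assessment", call. = FALSE)
  }
  if (nrow(severities) == 0) {
    warning("empty barrier assessment: no barriers to select", call. = FALSE)
    return(structure(list(selected = severities, tie_flag = FALSE,
                          discretion_note = NA_character_),
                     class = "top_barriers"))
  }
  ord <- order(-severities$severity, severities$barrier_id)
  sorted <- severities[ord, ]
  k <- min(3L, nrow(sorted))
  tie <- nrow(sorted) > 3L && sorted$severity[4L] == sorted$severity[3L]
  structure(
    list(
      selected = sorted[seq_len(k), ],
      tie_flag = tie,
      discretion_note = if (tie) {
        "more than three barriers share the cutoff severity; selection shown uses ascending barrier id - clinician discretion applies"
      } else NA_character_
    ),
    class = "top_barriers"
  )
}

#' @export
print.top_barriers <- function(x, ...) {
  cat("Top weighted barriers (displayed unordered):\n")
  if (nrow(x$selected) == 0) {
    cat("  <none>\n")
  } else {
    cat(sprintf("  barrier %d (severity %d)\n",
                x$selected$barrier_id, as.integer(x$selected$severity)), sep = "")
  }
  if (isTRUE(x$tie_flag)) cat("  note:", x$discretion_note, "\n")
  invisible(x)
}

#' Recommend resources for selected barriers
#'
#' Pure lookup of each selected barrier in the barrier-to-resource map, in
#' selection order; resources within a barrier are not ranked.
#'
#' @param top A `top_barriers` object from [select_top_barriers()].
#' @param map Named list mapping barrier id to resource labels
#'   (default [default_resource_map()]).
#' @return A tibble with columns `barrier_id` and `resource` (one row per
#'   barrier-resource pair); empty selection gives an empty tibble.
#' @export
recommend_resources <- function(top, map = default_resource_map()) {
  stopifnot(inherits(top, "top_barriers"))
  validate_resource_map(map)
  ids <- top$selected$barrier_id
  if (length(ids) == 0) {
    return(tibble::tibble(barrier_id = integer(), resource = character()))
  }
  absent <- ids[!as.character(ids) %in% names(map)]
  if (length(absent)) {
    stop("resource map has no entry for barrier id(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(ids, function(b) {
    tibble::tibble(barrier_id = b, resource = map[[as.character(b)]])
  })
}

#' Top-three barrier selection across a cohort
#'
#' Applies [select_top_barriers()] to every participant's baseline barrier
#' assessment and joins catalogue labels.
#'
#' @param cohort A validated cohort tibble.
#' @param map Optional resource map; when supplied, recommended resource
#'   labels are attached (collapsed with `"; "`).
#' @return A tibble with one row per participant and selected barrier:
#'   `participant_id`, `arm`, `barrier_id`, `key`, `label`, `severity`,
#'   `tie_flag` (and `resources` when a map is given). Participants with no
#'   recorded barriers contribute no rows.
#' @export
score_barriers <- function(cohort, map = NULL) {
  validate_cohort(cohort)
  if (!is.null(map)) validate_resource_map(map)
  cat <- barrier_catalogue()
  sev <- cohort |>
    dplyr::select("participant_id", "arm",
                  dplyr::all_of(sprintf("barrier_severity_%02d", 1:24))) |>
    tidyr::pivot_longer(dplyr::starts_with("barrier_severity_"),
                        names_to = "barrier_id", names_prefix = "barrier_severity_",
                        values_to = "severity") |>
    dplyr::mutate(barrier_id = as.integer(.data$barrier_id)) |>
    dplyr::filter(!is.na(.data$severity))
  out <- sev |>
    dplyr::group_by(.data$participant_id, .data$arm) |>
    dplyr::group_modify(function(df, key) {
      top <- select_top_barriers(df[, c("barrier_id", "severity")])
      dplyr::mutate(top$selected, tie_flag = top$tie_flag)
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(cat, by = "barrier_id")
  if (!is.null(map)) {
    out$resources <- vapply(out$barrier_id, function(b) {
      if (!as.character(b) %in% names(map)) {
        stop("resource map has no entry for barrier id ", b, call. = FALSE)
      }
      paste(map[[as.character(b)]], collapse = "; ")
    }, character(1))
  }
  out
}
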