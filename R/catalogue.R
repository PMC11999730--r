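#' The 24-item barrier catalogue
#'
#' The barriers-to-compression questionnaire covers 24 patient-specific
#' barriers to stocking wear, each rated on a Likert severity scale from 1
#' (mild) to 5 (severe). Only some item texts are public (the items actually
#' selected by pilot participants, e.g. heat, donning difficulty); the
#' remaining slots ship with explicit placeholder labels so the catalogue is
#' total over ids 1-24.
#'
#' @return A tibble with columns `barrier_id` (integer 1-24), `key`
#'   (machine-friendly label) and `label` (display text).
#' @examples
#' barrier_catalogue()
#' @export
barrier_catalogue <- function() {
  named <- tibble::tribble(
    ~barrier_id, ~key,                  ~label,
    1L,  "too_hot",              "Stockings too hot to wear",
    2L,  "difficulty_donning",   "Difficulty donning stockings (can't don)",
    3L,  "difficulty_doffing",   "Difficulty removing stockings (can't doff)",
    4L,  "skin_irritation",      "Skin irritation",
    5L,  "too_tight",            "Stockings feel too tight",
    6L,  "too_tight_over_toes",  "Too tight over the toes",
    7L,  "digs_in_at_ankle",     "Digs in at the ankle",
    8L,  "digs_in_at_top",       "Digs in at the top band",
    9L,  "slides_down",          "Stockings slide down",
    10L, "slides_up_foot",       "Stocking slides up the foot",
    11L, "looks_old",            "Perception of looking old",
    12L, "low_mood",             "Low mood",
  )
  placeholder <- tibble::tibble(
    barrier_id = 13:24,
    key = sprintf("barrier_%02d", 13:24),
    label = sprintf("Catalogue item %d (text not publicly specified)", 13:24)
  )
  dplyr::bind_rows(named, placeholder)
}

#' Default barrier-to-resource map
#'
#' Each barrier maps to one or more resource labels (information sheets,
#' video links, clinical considerations) used to tailor a treatment plan.
#' The actual resource *content* is out of scope; the map carries opaque
#' labels only, and is configurable via YAML ([read_resource_map()]).
#'
#' @return A named list: `"<barrier_id>"` -> character vector of resource
#'   labels; every id 1-24 has at least one entry.
#' @examples
#' default_resource_map()[["1"]]
#' @export
default_resource_map <- function() {
  cat <- barrier_catalogue()
  out <- lapply(seq_len(nrow(cat)), function(i) {
    key <- cat$key[i]
    c(paste0("info_sheet_", key), paste0("clinical_consideration_", key))
  })
  names(out) <- as.character(cat$barrier_id)
  # a couple of barriers with a known video resource in addition
  out[["2"]] <- c(out[["2"]], "video_donning_techniques")
  out[["3"]] <- c(out[["3"]], "video_doffing_techniques")
  out
}

validate_resource_map <- function(map) {
  if (!is.list(map) || is.null(names(map))) {
    stop("resource map must be a named list keyed by barrier_id", call. = FALSE)
  }
  ids <- suppressWarnings(as.integer(names(map)))
  if (anyNA(ids) || any(ids < 1L | ids > 24L)) {
    stop("resource map keys must be barrier ids 1-24", call. = FALSE)
  }
  empty <- vapply(map, function(v) length(v) == 0L || all(!nzchar(v)), logical(1))
  if (any(empty)) {
    stop("resource map has empty entries for barrier id(s): ",
         paste(names(map)[empty], collapse = ", "), call. = FALSE)
  }
  invisible(map)
}

#' Read / write a resource map as YAML
#'
#' @param path File path of a YAML document keyed by barrier id.
#' @return For `read_resource_map`, a validated named list as in
#'   [default_resource_map()].
#' @export
read_resource_map <- function(path) {
  map <- yaml::read_yaml(path)
  map <- lapply(map, as.character)
  validate_resource_map(map)
}

#' @rdname read_resource_map
#' @param map Named list mapping barrier id to resource labels.
#' @export
write_resource_map <- function(map, path) {
  validate_resource_map(map)
  yaml::write_yaml(map, path)
  invisible(path)
}
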