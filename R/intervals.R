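#' Parse "lo-hi" interval strings
#'
#' Wear-time quantities (hours awake, hours worn per leg, days per week) are
#' recorded as single values or ranges. Ranges are serialized as `"lo-hi"`
#' (decimal point, never a comma); a single value stands for a degenerate
#' interval with `lo == hi`.
#'
#' @param x Character vector of interval strings (`"16"`, `"12-14"`), or `NA`.
#' @return A tibble with numeric columns `lo` and `hi` (`NA` rows for `NA`
#'   input).
#' @examples
#' parse_interval(c("16", "12-14", NA))
#' @export
parse_interval <- function(x) {
  stopifnot(is.character(x) | all(is.na(x)))
  x <- as.character(x)
  out <- tibble::tibble(lo = rep(NA_real_, length(x)), hi = NA_real_)
  ok <- !is.na(x) & nzchar(trimws(x))
  if (!any(ok)) return(out)
  xs <- trimws(x[ok])
  # split on a hyphen that sits between two number parts (all quantities >= 0)
  parts <- stringr::str_match(xs, "^([0-9]*\\.?[0-9]+)\\s*(?:-\\s*([0-9]*\\.?[0-9]+))?$")
  if (anyNA(parts[, 1])) {
    bad <- xs[is.na(parts[, 1])]
    stop("malformed interval string(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  lo <- as.numeric(parts[, 2])
  hi <- ifelse(is.na(parts[, 3]), lo, as.numeric(parts[, 3]))
  if (any(lo > hi)) {
    stop("interval lower bound exceeds upper bound in: ",
         paste(xs[lo > hi], collapse = ", "), call. = FALSE)
  }
  out$lo[ok] <- lo
  out$hi[ok] <- hi
  out
}

#' Format intervals back to "lo-hi" strings
#'
#' Inverse of [parse_interval()]: degenerate intervals collapse to a single
#' number so that write/read round-trips are exact.
#'
#' @param lo,hi Numeric vectors of interval bounds.
#' @return Character vector (`NA` where `lo` is `NA`).
#' @export
format_interval <- function(lo, hi = lo) {
  stopifnot(length(lo) == length(hi))
  num <- function(v) {
    # %.12g keeps round-trip precision without trailing zeros
    vapply(v, function(z) if (is.na(z)) NA_character_ else sprintf("%.12g", z),
           character(1))
  }
  out <- ifelse(is.na(lo), NA_character_,
                ifelse(!is.na(hi) & hi > lo,
                       paste0(num(lo), "-", num(hi)), num(lo)))
  out
}
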