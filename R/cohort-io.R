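#' Read a cohort file
#'
#' Cohort files are comma-separated, one row per participant, with the column
#' dictionary of [cohort_dictionary()] and a versioned header comment
#' (`# cohort_schema_version: 1.0`) on the first line. Records are validated
#' on read; blank follow-up blocks are preserved as explicit missing markers,
#' never coerced to zeros.
#'
#' @param path Path to a cohort CSV.
#' @param schema_version Expected schema version string.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, schema_version = cohort_schema_version) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  m <- stringr::str_match(first, "^#\\s*cohort_schema_version:\\s*(\\S+)")
  if (is.na(m[1, 1])) {
    stop("cohort file lacks the '# cohort_schema_version' header line: ", path,
         call. = FALSE)
  }
  if (m[1, 2] != schema_version) {
    stop("cohort schema version mismatch: file has ", m[1, 2],
         ", expected ", schema_version, call. = FALSE)
  }
  dict <- cohort_dictionary()
  col_spec <- do.call(readr::cols, c(
    setNames(lapply(dict$type, function(t) {
      switch(t,
             string = readr::col_character(), enum = readr::col_character(),
             interval = readr::col_character(), integer = readr::col_integer(),
             number = readr::col_double(), flag = readr::col_logical())
    }), dict$column),
    list(.default = readr::col_skip())
  ))
  cohort <- readr::read_csv(path, comment = "#", col_types = col_spec,
                            na = "NA", progress = FALSE,
                            show_col_types = FALSE)
  probs <- readr::problems(cohort)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    stop("malformed cohort file at row ", p$row, ", column ", p$col,
         " (expected ", p$expected, ", got ", p$actual, ")", call. = FALSE)
  }
  cohort$materials[is.na(cohort$materials)] <- ""
  validate_cohort(cohort)
  cohort
}

#' Write a cohort file
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, path))`
#' reproduces `x` field for field. Intervals stay in their `"lo-hi"` string
#' form; missing fields are written as the literal `NA` token.
#'
#' @param cohort A validated cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# cohort_schema_version: ", cohort_schema_version), con)
  readr::write_csv(cohort[, cohort_columns(), drop = FALSE], con, na = "NA",
                   append = TRUE, col_names = TRUE)
  invisible(path)
}
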