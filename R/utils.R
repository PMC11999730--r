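#' @importFrom rlang %||% .data
#' @importFrom stats dnorm pnorm qnorm pt qt lm coef rpois runif setNames
#' @importFrom utils combn
NULL

# round half up (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

arm_levels <- function() c("usual_care", "intervention")

assert_arm <- function(arm) {
  bad <- setdiff(unique(arm[!is.na(arm)]), arm_levels())
  if (length(bad)) {
    stop("unknown arm label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(arm_levels(), collapse = ", "),
         call. = FALSE)
  }
  invisible(arm)
}
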