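#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for fitted pipeline objects
#'
#' Broom-style accessors: `tidy()` returns one row per estimated quantity,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object (`mw_test`, `somers_d`, `ancova_fit`,
#'   `sample_size_plan`, `cua_result`).
#' @param ... Unused.
#' @return A tibble.
#' @name compadhere-tidiers
NULL

#' @rdname compadhere-tidiers
#' @export
tidy.mw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 method = x$method, n1 = x$n1, n2 = x$n2)
}

#' @rdname compadhere-tidiers
#' @export
tidy.somers_d <- function(x, ...) {
  tibble::tibble(estimate = x$d, statistic = x$concordant - x$discordant,
                 p.value = x$p_value, n = x$n)
}

#' @rdname compadhere-tidiers
#' @export
tidy.ancova_fit <- function(x, ...) {
  dplyr::rename(x$covariate_effects, std.error = "std_error",
                p.value = "p_value")
}

#' @rdname compadhere-tidiers
#' @export
glance.ancova_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(group_effect = x$group_effect, std.error = x$std_error,
                 p.value = x$p_value, r.squared = s$r.squared, n = x$n)
}

#' @rdname compadhere-tidiers
#' @export
tidy.sample_size_plan <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname compadhere-tidiers
#' @export
tidy.cua_result <- function(x, ...) {
  tibble::tibble(
    term = c("delta_cost", "delta_qaly_unadjusted", "delta_qaly_adjusted",
             "icer"),
    estimate = c(x$delta_cost, x$delta_qaly_unadjusted, x$delta_qaly_adjusted,
                 x$icer)
  )
}

#' @rdname compadhere-tidiers
#' @export
glance.cua_result <- function(x, ...) {
  tibble::tibble(
    delta_cost = x$delta_cost, delta_qaly_adjusted = x$delta_qaly_adjusted,
    icer = x$icer, dominance = x$dominance, wtp_threshold = x$wtp_threshold,
    cost_effective = x$cost_effective
  )
}
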