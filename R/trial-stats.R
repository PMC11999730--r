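#' Mann-Whitney U test
#'
#' Two-sample rank test for a location difference between arms. The U
#' statistic is computed from midrank sums (so ties are handled); the
#' reported `statistic` is `min(U1, U2)`. For small untied samples
#' (`n1 + n2 <= 20`) the two-sided p-value is exact, computed by full
#' enumeration of all `choose(n1 + n2, n1)` group assignments and doubling
#' the smaller tail (capped at 1). Otherwise a normal approximation with tie
#' correction and a continuity correction is used — the pilot's ordinal
#' outcomes are heavily tied, so this is the path real data take.
#'
#' @param x,y Numeric samples for the two groups (non-empty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) chooses exact iff `n1 + n2 <= 20` and there are no
#'   ties. Forcing `exact = TRUE` in the presence of ties enumerates the
#'   permutation distribution of the midrank U.
#' @return An object of class `mw_test` (also a tibble row): `statistic`
#'   (min U), `u1`, `p_value`, `method` (`exact_enumeration` /
#'   `normal_approx`), `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  n <- n1 + n2
  r <- rank(pooled)  # midranks
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  has_ties <- anyDuplicated(pooled) > 0
  do_exact <- if (is.null(exact)) (n <= 20 && !has_ties) else isTRUE(exact)
  if (do_exact) {
    idx <- combn(n, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    total <- ncol(idx)
    eps <- 1e-9
    p <- min(1, 2 * min(sum(u_all <= u1 + eps), sum(u_all >= u1 - eps)) / total)
    method <- "exact_enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(u1 - mu) - 0.5) / sigma  # continuity correction toward the mean
      z <- max(z, 0)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal_approx"
  }
  structure(
    tibble::tibble(statistic = min(u1, u2), u1 = u1, p_value = p,
                   method = method, n1 = n1, n2 = n2),
    class = c("mw_test", "tbl_df", "tbl", "data.frame")
  )
}

#' Somers' D ordinal association
#'
#' The asymmetric rank association D(response | predictor): concordant minus
#' discordant pairs over all pairs not tied on the predictor. Used in the
#' pipeline with the mean barrier resolution score as the predictor and the
#' modified Q10 change score as the response. Counting is done on the
#' predictor-by-response contingency table; the p-value is a two-sided
#' asymptotic z-test of `C - D` against the null of no association, using
#' the tie-corrected null variance (the same null variance used for
#' tie-corrected Kendall tests).
#'
#' @param predictor,response Ordinal (numeric) vectors of equal length >= 2;
#'   pairs with a missing value in either are dropped.
#' @return An object of class `somers_d` (a tibble row): `d`, `concordant`,
#'   `discordant`, `n`, `p_value`.
#' @examples
#' somers_d(c(1, 2, 3), c(1, 2, 3))  # d = 1
#' @export
somers_d <- function(predictor, response) {
  keep <- !is.na(predictor) & !is.na(response)
  x <- predictor[keep]; y <- response[keep]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1) {
    stop("Somers' D undefined: all predictor values are tied", call. = FALSE)
  }
  tab <- table(x, y)
  nr <- nrow(tab); nc <- ncol(tab)
  # cells strictly greater / strictly smaller in both margins
  con <- 0; dis <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      nij <- tab[i, j]
      if (nij == 0) next
      if (i < nr && j < nc) con <- con + nij * sum(tab[(i + 1):nr, (j + 1):nc])
      if (i < nr && j > 1) dis <- dis + nij * sum(tab[(i + 1):nr, 1:(j - 1)])
    }
  }
  total_pairs <- n * (n - 1) / 2
  tx <- rowSums(tab)
  tied_x <- sum(tx * (tx - 1) / 2)
  d <- (con - dis) / (total_pairs - tied_x)
  # tie-corrected null variance of S = C - D
  ty <- colSums(tab)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
  } else 0
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  p <- if (var_s <= 0) NA_real_ else min(1, 2 * pnorm(-abs(con - dis) / sqrt(var_s)))
  structure(
    tibble::tibble(d = d, concordant = con, discordant = dis, n = n,
                   p_value = p),
    class = c("somers_d", "tbl_df", "tbl", "data.frame")
  )
}

#' Baseline-adjusted group effect (ANCOVA-style regression)
#'
#' Ordinary least squares of an outcome change score on the arm indicator
#' plus the baseline value of the outcome, the standard way to account for
#' baseline disparity in a small two-arm trial. The group effect is the arm
#' coefficient, oriented as intervention minus usual care.
#'
#' @param data A data frame.
#' @param outcome,arm,baseline Column names (tidy-eval) of the change score,
#'   the arm label (`usual_care`/`intervention`) and the baseline covariate.
#'   Rows with missing values are dropped.
#' @return An object of class `ancova_fit` wrapping the `lm` fit, with
#'   `group_effect`, `std_error`, `p_value` and the underlying model.
#'   Supports [tidy()] and [glance()].
#' @examples
#' df <- data.frame(arm = rep(c("usual_care", "intervention"), each = 5),
#'                  base = rnorm(10), change = rnorm(10))
#' adjusted_group_effect(df, change, arm, base)
#' @export
adjusted_group_effect <- function(data, outcome, arm, baseline) {
  df <- dplyr::transmute(
    data,
    .outcome = {{ outcome }},
    .arm = {{ arm }},
    .baseline = {{ baseline }}
  )
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 4) stop("need at least 4 complete observations", call. = FALSE)
  assert_arm(df$.arm)
  if (length(unique(df$.arm)) < 2) {
    stop("both arms must be represented", call. = FALSE)
  }
  df$.arm <- factor(df$.arm, levels = arm_levels())  # usual_care is reference
  fit <- lm(.outcome ~ .arm + .baseline, data = df)
  if (anyNA(coef(fit))) {
    stop("singular design: arm and baseline are collinear", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  structure(
    list(
      group_effect = unname(coef(fit)[".armintervention"]),
      std_error = sm[".armintervention", "Std. Error"],
      p_value = sm[".armintervention", "Pr(>|t|)"],
      covariate_effects = tibble::tibble(
        term = rownames(sm), estimate = unname(sm[, "Estimate"]),
        std_error = unname(sm[, "Std. Error"]),
        p_value = unname(sm[, "Pr(>|t|)"])
      ),
      n = nrow(df),
      model = fit
    ),
    class = "ancova_fit"
  )
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("Baseline-adjusted group effect (intervention - usual care)\n")
  cat(sprintf("  effect %.4f (SE %.4f), p = %.4g, n = %d\n",
              x$group_effect, x$std_error, x$p_value, x$n))
  invisible(x)
}

#' Pooled Cohen's d
#'
#' Standardised mean difference using the pooled standard deviation,
#' `d = (m2 - m1) / sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#' Applied in the pipeline to the per-arm modified-Q10 change summaries to
#' size a definitive trial from pilot results.
#'
#' @param m1,sd1,n1 Mean, SD and size of the first (reference) group.
#' @param m2,sd2,n2 Mean, SD and size of the second group.
#' @return The effect size `d` (positive when `m2 > m1`); `Inf` with a
#'   warning when the pooled SD is 0 and the means differ.
#' @examples
#' cohens_d_pooled(-0.60, 1.07, 10, 1.00, 0.86, 9)  # 1.64
#' @export
cohens_d_pooled <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    if (m1 == m2) return(0)
    warning("pooled SD is 0 with unequal means: effect size is infinite",
            call. = FALSE)
    return(sign(m2 - m1) * Inf)
  }
  (m2 - m1) / sp
}

power_two_sample_t <- function(n_per_group, delta, sd, alpha) {
  df <- 2 * n_per_group - 2
  ncp <- (delta / sd) * sqrt(n_per_group / 2)
  tc <- qt(1 - alpha / 2, df)
  1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
}

new_sample_size_plan <- function(delta, sd, alpha, power, n_per_group,
                                 dropout_rate, are_correction = NA_real_) {
  n_total <- 2L * n_per_group
  n_infl <- if (dropout_rate > 0) {
    2L * as.integer(ceiling(n_total / (1 - dropout_rate) / 2))  # keep arms balanced
  } else n_total
  structure(
    tibble::tibble(delta = delta, sd = sd, alpha = alpha, power = power,
                   n_per_group = n_per_group, n_total = n_total,
                   dropout_rate = dropout_rate, n_total_inflated = n_infl,
                   are_correction = are_correction),
    class = c("sample_size_plan", "tbl_df", "tbl", "data.frame")
  )
}

#' Sample size for a two-arm two-sided t test
#'
#' Smallest per-group n such that the two-sided two-sample t test at level
#' `alpha` reaches the target power, using exact noncentral-t power
#' (noncentrality `(delta/sd) * sqrt(n/2)`, `2n - 2` degrees of freedom)
#' iterated over integer n from a floor of 2 (variance estimability).
#' Dropout inflation divides the total by `1 - dropout_rate` and rounds up
#' to the next even integer so the arms stay balanced.
#'
#' @param delta Target difference (score points), > 0.
#' @param sd Assumed common standard deviation, > 0.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param dropout_rate Anticipated dropout proportion in `[0, 1)`.
#' @param n_max Iteration cap; exceeding it raises an error.
#' @return A `sample_size_plan` tibble row: `delta`, `sd`, `alpha`, `power`,
#'   `n_per_group`, `n_total`, `dropout_rate`, `n_total_inflated`,
#'   `are_correction` (`NA` here).
#' @examples
#' sample_size_two_arm_t(delta = 1, sd = 1.14)                      # 44 total
#' sample_size_two_arm_t(delta = 1, sd = 1.14, dropout_rate = 0.2)  # 56 inflated
#' @export
sample_size_two_arm_t <- function(delta, sd, alpha = 0.05, power = 0.8,
                                  dropout_rate = 0, n_max = 1e6) {
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            dropout_rate >= 0, dropout_rate < 1)
  n <- 2L
  while (power_two_sample_t(n, delta, sd, alpha) < power) {
    n <- n + 1L
    if (n > n_max) stop("target power unattainable within iteration cap",
                        call. = FALSE)
  }
  new_sample_size_plan(delta, sd, alpha, power, n, dropout_rate)
}

#' Sample size for a Mann-Whitney trial via the ARE correction
#'
#' Converts the noncentral-t sample size at a given standardised effect into
#' a Mann-Whitney plan by dividing the per-group n by the asymptotic
#' relative efficiency and rounding up. The default ARE of 0.864 is the
#' distribution-free minimum (3/pi would apply under normality); the minimal
#' value is used because the parent distribution is unspecified.
#'
#' @param d Standardised effect size, > 0.
#' @inheritParams sample_size_two_arm_t
#' @param are Asymptotic relative efficiency in (0, 1].
#' @return A `sample_size_plan` tibble row with `are_correction` filled in.
#' @examples
#' sample_size_mann_whitney_are(d = 1.64)  # 18 total
#' @export
sample_size_mann_whitney_are <- function(d, alpha = 0.05, power = 0.8,
                                         are = 0.864, dropout_rate = 0) {
  stopifnot(d > 0, are > 0, are <= 1)
  t_plan <- sample_size_two_arm_t(delta = d, sd = 1, alpha = alpha,
                                  power = power, dropout_rate = 0)
  n_mw <- as.integer(ceiling(t_plan$n_per_group / are))
  new_sample_size_plan(d, 1, alpha, power, n_mw, dropout_rate,
                       are_correction = are)
}
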