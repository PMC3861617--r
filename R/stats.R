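#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The p-value is exact (enumeration of
#' rank arrangements) when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with mid-rank tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`.
#' @return One-row tibble: `u` (U statistic for `x`), `p_value`, `method`
#'   (`"exact"` or `"approximate"`), `alternative`, `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty", class = "wntwave_input_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  alt <- switch(alternative, two_sided = "two.sided", less = "less",
                greater = "greater")
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = exact, correct = TRUE)
  )
  tibble(
    u = unname(ht$statistic),
    p_value = min(ht$p.value, 1),
    method = if (exact) "exact" else "approximate",
    alternative = alternative,
    n_x = length(x),
    n_y = length(y)
  )
}

#' Simple ordinary least squares
#'
#' @param x Predictor (non-constant, length >= 3).
#' @param y Response.
#' @return One-row tibble: `slope`, `intercept`, `slope_se`, `intercept_se`,
#'   `rss`, `r_squared`, `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    abort("need >= 3 paired points", class = "wntwave_input_error")
  }
  if (diff(range(x)) == 0) {
    abort("predictor is constant", class = "wntwave_input_error")
  }
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit)) # zero-residual designs are legitimate here
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    slope_se = s$coefficients[2, 2],
    intercept_se = s$coefficients[1, 2],
    rss = deviance(fit),
    r_squared = s$r.squared,
    n = length(x)
  )
}
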