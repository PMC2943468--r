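#' Group summary: mean and standard error
#'
#' @param values Numeric vector of per-replicate measurements.
#' @param label Group label.
#' @return An object of class `group_summary`: `group`, `n`, `mean`, `sem`
#'   (`sd/sqrt(n)`; 0 when `n = 1`).
#' @export
group_summary <- function(values, label = "group") {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("need >= 1 finite value")
  }
  n <- length(values)
  structure(
    list(group = label, n = n, mean = mean(values),
         sem = if (n > 1) stats::sd(values) / sqrt(n) else 0),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (n = %d)\n", x$group, x$mean, x$sem, x$n))
  invisible(x)
}

#' Two-tailed Student's t-test between two groups
#'
#' Pooled-variance (classical Student) unpaired test by default, with a
#' paired option for within-animal comparisons (clamped vs contralateral
#' kidney). Significance is flagged at p < 0.05.
#'
#' @param a,b Numeric vectors of measurements (equal length if paired).
#' @param paired Use the paired test.
#' @return List with `t`, `p_value`, `df`, `significant` (p < 0.05),
#'   `paired`.
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires equal group sizes")
  }
  ht <- stats::t.test(a, b, paired = paired, var.equal = TRUE,
                      alternative = "two.sided")
  list(
    t = unname(ht$statistic),
    p_value = ht$p.value,
    df = unname(ht$parameter),
    significant = ht$p.value < 0.05,
    paired = paired
  )
}

#' Fold ratio of two group means
#'
#' @param numerator,denominator [group_summary()] objects (or numbers).
#' @param rounding `"none"` or `"nearest_int"` (how fold changes are quoted
#'   in results text).
#' @return Unitless ratio of means.
#' @export
fold_ratio <- function(numerator, denominator,
                       rounding = c("none", "nearest_int")) {
  rounding <- match.arg(rounding)
  num <- if (inherits(numerator, "group_summary")) numerator$mean else
    as.numeric(numerator)
  den <- if (inherits(denominator, "group_summary")) denominator$mean else
    as.numeric(denominator)
  if (!is.finite(den) || den <= 0) {
    stop("denominator mean must be positive")
  }
  r <- num / den
  if (rounding == "nearest_int") round(r) else r
}

#' Ordinary least squares fit of expression on contrast volume
#'
#' Simple linear regression `y ~ x` with `r_squared` equal to the squared
#' Pearson correlation and the two-sided p-value of the slope.
#'
#' @param x Contrast volumes (um^3); must have nonzero variance.
#' @param y Relative expression values.
#' @return An object of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
fit_linear <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need >= 3 points")
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  # exact fits are legitimate here (zero-noise synthetic data); drop the
  # "essentially perfect fit" warning but let anything else through
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2, 4] else NA_real_
  r2 <- sm$r.squared
  if (stats::var(y) == 0) {  # flat response: no variance explained
    r2 <- 0
    p <- 1
  }
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      p_value = p,
      n = length(x)
    ),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "regression_fit: slope %.4g, intercept %.4g, R^2 = %.3f, p = %.3g (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}
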