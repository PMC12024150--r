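## Validation of image-based weight estimates against hand-weighed values:
## absolute percent error, and a two-sample comparison guarded by
## normality (Shapiro-Wilk) and variance-homogeneity (Levene) checks. The
## t statistic and Levene's W are computed from their formulas; they are
## the decision rule under test, so they are not delegated.

#' Absolute percent error of an estimate
#'
#' `|estimated - actual| / actual * 100`, with the hand-weighed value as
#' denominator. Vectorized.
#'
#' @param estimated_g estimated weights (g).
#' @param actual_g actual weights (g), strictly positive.
#' @return percent errors.
#' @export
percent_error <- function(estimated_g, actual_g) {
  if (any(actual_g <= 0)) stop("actual_g must be strictly positive")
  abs(estimated_g - actual_g) / actual_g * 100
}

#' Levene's test for homogeneity of variance (two samples, mean-centred)
#'
#' One-way ANOVA F statistic on the absolute deviations from each group
#' mean.
#'
#' @param x,y the two samples.
#' @return list with `statistic` (W), `df` (1, n1 + n2 - 2), `p_value`.
#' @export
levene_test <- function(x, y) {
  z <- list(abs(x - mean(x)), abs(y - mean(y)))
  n <- lengths(z); k <- 2L; N <- sum(n)
  zbar <- mean(unlist(z))
  zi <- vapply(z, mean, numeric(1))
  num <- (N - k) * sum(n * (zi - zbar)^2)
  den <- (k - 1) * sum(vapply(seq_len(k), function(i) sum((z[[i]] - zi[i])^2),
                              numeric(1)))
  if (den == 0) {
    w <- if (num == 0) 0 else Inf
  } else w <- num / den
  p <- if (is.finite(w)) pf(w, k - 1, N - k, lower.tail = FALSE) else 0
  list(statistic = w, df = c(k - 1L, N - k), p_value = p)
}

#' Two-sample t test from first principles
#'
#' @param x,y the two samples.
#' @param pooled use the pooled-variance form? Otherwise Welch.
#' @return list with `statistic`, `df`, `p_value` (two-sided).
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) stop("degenerate input: zero variance in both samples")
  t <- (mean(x) - mean(y)) / se
  list(statistic = t, df = df, p_value = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Validate estimated against actual weights
#'
#' Computes the percent-error summary and the assumption-checked
#' independent two-sample comparison: Shapiro-Wilk normality on each
#' sample, Levene's test (mean-centred) across the two, then the
#' two-sample t test - pooled-variance form when Levene's p >= alpha,
#' Welch form otherwise - with a two-sided p value. Assumption-test
#' outcomes are recorded, never silently fatal.
#'
#' @param estimated estimated weights (g).
#' @param actual actual weights (g), same length, n >= 3.
#' @param alpha significance level.
#' @return a `validation_report` list: `n`, `percent_errors`,
#'   `mean_error_pct`, `sd_error_pct`, `shapiro_p_estimated`,
#'   `shapiro_p_actual`, `levene_p`, `pooled`, `t_statistic`, `t_df`,
#'   `t_p_value`, `alpha`, `significant`.
#' @export
validate_weights <- function(estimated, actual, alpha = 0.05) {
  if (length(estimated) != length(actual))
    stop("estimated and actual must have the same length")
  n <- length(estimated)
  if (n < 3L) stop("validation needs at least 3 paired weights")
  pe <- percent_error(estimated, actual)
  ## shapiro.test needs non-constant input; record NA for degenerate samples
  sw <- function(v) if (length(unique(v)) > 1L) shapiro.test(v)$p.value else NA_real_
  lev <- levene_test(estimated, actual)
  pooled <- is.na(lev$p_value) || lev$p_value >= alpha
  tt <- two_sample_t(estimated, actual, pooled = pooled)
  structure(list(
    n = n, percent_errors = pe,
    mean_error_pct = mean(pe), sd_error_pct = sd(pe),
    shapiro_p_estimated = sw(estimated), shapiro_p_actual = sw(actual),
    levene_p = lev$p_value, pooled = pooled,
    t_statistic = tt$statistic, t_df = tt$df, t_p_value = tt$p_value,
    alpha = alpha, significant = tt$p_value < alpha),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation of %d weight estimates:\n", x$n))
  cat(sprintf("  error: %.2f +/- %.2f %%\n", x$mean_error_pct, x$sd_error_pct))
  cat(sprintf("  Shapiro-Wilk p: estimated %.3f, actual %.3f; Levene p: %.3f\n",
              x$shapiro_p_estimated, x$shapiro_p_actual, x$levene_p))
  cat(sprintf("  %s t = %.4f (df %.1f), p = %.4f -> %s at alpha = %g\n",
              if (x$pooled) "pooled" else "Welch", x$t_statistic, x$t_df,
              x$t_p_value,
              if (x$significant) "significant difference" else "no significant difference",
              x$alpha))
  invisible(x)
}

#' Write a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
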