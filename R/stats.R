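# Significance machinery: an F-test for equal variances gates the choice
# between the pooled-variance and the Welch (unequal-variance) two-sample
# t-test; one- or two-tailed as the comparison demands; star annotation for
# report tables. No multiple-testing correction is applied by default.

#' Two-sided F-test for equality of two variances
#'
#' The larger sample variance goes in the numerator, so the statistic is
#' >= 1 and the two-sided p-value is `min(1, 2 * P(F >= observed))`. If
#' exactly one sample has zero variance the variance ratio is infinite and
#' the p-value is 0 (maximally unequal); two zero-variance samples are
#' degenerate and raise an error.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return the p-value.
#' @examples
#' f_test_equal_variance(c(1, 2, 3), c(10, 20, 30))
#' @export
f_test_equal_variance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) {
    stop("degenerate samples: both variances are zero", call. = FALSE)
  }
  if (v1 == 0 || v2 == 0) return(0)
  if (v1 >= v2) {
    f <- v1 / v2; df1 <- length(a) - 1L; df2 <- length(b) - 1L
  } else {
    f <- v2 / v1; df1 <- length(b) - 1L; df2 <- length(a) - 1L
  }
  min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' F-test-gated two-sample t-test
#'
#' Runs [f_test_equal_variance()]; if its p-value falls below `alpha_var` the
#' Welch unequal-variance t-test (Welch-Satterthwaite df) is used, otherwise
#' the pooled-variance t-test. One-tailed tests require the hypothesized
#' `direction` of the difference `a - b`.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param tails 1 or 2.
#' @param direction for `tails = 1`: `"greater"` (a > b expected) or
#'   `"less"`.
#' @param alpha_var significance level of the variance-equality gate.
#' @return a `stat_result` list: `test` (`"pooled_t"`/`"welch_t"`), `tails`,
#'   `statistic`, `df`, `p_value`, `stars`, `f_p`.
#' @examples
#' auto_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5), tails = 2)
#' @export
auto_t_test <- function(a, b, tails = 2,
                        direction = c("greater", "less"),
                        alpha_var = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2", call. = FALSE)
  f_p <- f_test_equal_variance(a, b)
  pooled <- f_p >= alpha_var
  alternative <- if (tails == 2) "two.sided" else match.arg(direction)
  tt <- stats::t.test(a, b, var.equal = pooled, alternative = alternative)
  structure(list(
    test = if (pooled) "pooled_t" else "welch_t",
    tails = as.integer(tails),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = unname(tt$p.value),
    stars = star_annotation(unname(tt$p.value)),
    f_p = f_p
  ), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s, %d-tailed> t = %.4g, df = %.3g, p = %.4g %s\n",
              x$test, x$tails, x$statistic, x$df, x$p_value, x$stars))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' `"****"` for p < 1e-4, `"***"` for p < 1e-3, `"**"` for p < 0.01, `"*"`
#' for p < 0.05, `""` otherwise (strict inequalities).
#'
#' @param p p-value(s) in \[0, 1\]; vectorized.
#' @return character vector of star strings.
#' @export
star_annotation <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- character(length(p))
  out[which(p < 0.05)] <- "*"
  out[which(p < 0.01)] <- "**"
  out[which(p < 1e-3)] <- "***"
  out[which(p < 1e-4)] <- "****"
  out
}

#' Exact two-sample permutation test (oracle)
#'
#' Enumerates every split of the pooled observations into groups of the
#' original sizes, computes the pooled-variance t statistic for each, and
#' returns the mid-p value (half weight on ties), which is the standard
#' continuity recommendation for discrete permutation distributions. Intended
#' as an independent check on [auto_t_test()] at small n; the full enumeration
#' is only feasible for total n around 12 or less.
#'
#' @param a,b numeric samples.
#' @param tails 1 or 2.
#' @param direction for `tails = 1`, direction of the alternative `a - b`.
#' @return the permutation p-value.
#' @export
permutation_t_test <- function(a, b, tails = 2,
                               direction = c("greater", "less")) {
  a <- as.numeric(a); b <- as.numeric(b)
  x <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(x), na)
  tstat <- function(g1, g2) {
    sp2 <- ((length(g1) - 1) * stats::var(g1) +
              (length(g2) - 1) * stats::var(g2)) /
      (length(g1) + length(g2) - 2)
    (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / length(g1) + 1 / length(g2)))
  }
  ts <- apply(idx, 2, function(k) tstat(x[k], x[-k]))
  obs <- tstat(a, b)
  eps <- 1e-9
  if (tails == 2) {
    ts <- abs(ts); obs <- abs(obs)
  } else if (match.arg(direction) == "less") {
    ts <- -ts; obs <- -obs
  }
  mean(ts > obs + eps) + 0.5 * mean(abs(ts - obs) <= eps)
}
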