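#' Group summary (n, mean, sd)
#'
#' Summary statistics of one measurement group, the unit of input for the
#' coefficient-of-variation machinery: published tables print summaries, not
#' raw samples.
#'
#' @param n number of observations (>= 2).
#' @param mean group mean (non-zero, or the CV is undefined).
#' @param sd group standard deviation (>= 0).
#' @param label optional group label.
#' @return an object of class `"group_summary"`.
#' @export
group_summary <- function(n, mean, sd, label = "") {
  stopifnot(n >= 2, sd >= 0)
  if (mean == 0) stop("group_summary: mean is zero; CV undefined")
  structure(list(n = as.integer(n), mean = mean, sd = sd, label = label),
            class = "group_summary")
}

#' Coefficient of variation
#'
#' `sd / mean` — a scale-free precision measure. For reporting alongside
#' published tables, round to 3 decimals.
#'
#' @param x a [group_summary()], or a numeric mean.
#' @param sd standard deviation (when `x` is a numeric mean).
#' @return the coefficient of variation.
#' @export
cv <- function(x, sd = NULL) {
  if (inherits(x, "group_summary")) return(x$sd / x$mean)
  stopifnot(is.numeric(x), is.numeric(sd))
  if (any(x == 0)) stop("cv: mean is zero; CV undefined")
  sd / x
}

#' Summarize a raw sample into a group summary
#'
#' @param x numeric vector (length >= 2).
#' @param label optional group label.
#' @return a [group_summary()].
#' @export
summarize_sample <- function(x, label = "") {
  stopifnot(length(x) >= 2L)
  group_summary(length(x), mean(x), sd(x), label)
}

#' Asymptotic test for equality of coefficients of variation (Feltz-Miller)
#'
#' Tests whether k populations share a common coefficient of variation,
#' using only group summaries. With `m_i = n_i - 1`, `c_i = sd_i / mean_i`
#' and the pooled CV `c = sum(m_i c_i) / sum(m_i)`, the statistic
#'
#' \deqn{D = \frac{\sum_i m_i (c_i - c)^2}{c^2 (0.5 + c^2)}}
#'
#' is asymptotically chi-square with `k - 1` degrees of freedom under the
#' null of equal CVs. This is the plain asymptotic form (no small-sample
#' correction), computed from summaries exactly as printed.
#'
#' @param groups list of [group_summary()] objects, or a data frame with
#'   columns `n`, `mean`, `sd` (and optionally `label`).
#' @return object of class `"feltz_miller"` with `statistic`, `df`,
#'   `p.value`, `pooled_cv` and the per-group `cvs`.
#' @export
feltz_miller_test <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- lapply(seq_len(nrow(groups)), function(i)
      group_summary(groups$n[i], groups$mean[i], groups$sd[i],
                    if ("label" %in% names(groups))
                      as.character(groups$label[i]) else ""))
  }
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, inherits, logical(1L), "group_summary")))
  n <- vapply(groups, `[[`, numeric(1L), "n")
  cvs <- vapply(groups, function(g) g$sd / g$mean, numeric(1L))
  m <- n - 1
  pooled <- sum(m * cvs) / sum(m)
  D <- if (pooled == 0) 0 else
    sum(m * (cvs - pooled)^2) / (pooled^2 * (0.5 + pooled^2))
  df <- length(groups) - 1L
  p <- pchisq(D, df, lower.tail = FALSE)
  structure(list(statistic = D, df = df, p.value = p, pooled_cv = pooled,
                 cvs = cvs,
                 labels = vapply(groups, `[[`, character(1L), "label"),
                 method = "Feltz-Miller asymptotic test for equality of CVs"),
            class = "feltz_miller")
}

#' @export
print.feltz_miller <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  D = %.4f, df = %d, p = %.4g\n", x$statistic, x$df, x$p.value))
  cat(sprintf("  group CVs: %s (pooled %.4f)\n",
              paste(sprintf("%.3f", x$cvs), collapse = ", "), x$pooled_cv))
  invisible(x)
}

#' Feltz-Miller test from raw samples
#'
#' Convenience wrapper: summarizes each sample, then calls
#' [feltz_miller_test()].
#'
#' @param samples list of numeric vectors (each length >= 2).
#' @return a `"feltz_miller"` result.
#' @export
feltz_miller_test_samples <- function(samples) {
  feltz_miller_test(lapply(samples, summarize_sample))
}

#' Log-log OLS scaling fit
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`: the standard
#' allometric scaling analysis (e.g. body surface area against body volume,
#' where a slope of 2/3 indicates isometry). Returns the slope with its 95%
#' confidence interval.
#'
#' @param x,y positive numeric vectors.
#' @return list with `slope`, `ci` (length-2), `intercept`, and the fitted
#'   `lm` object.
#' @export
loglog_ols <- function(x, y) {
  stopifnot(length(x) == length(y), all(x > 0), all(y > 0))
  fit <- lm(ly ~ lx, data = data.frame(lx = log10(x), ly = log10(y)))
  ci <- confint(fit)["lx", ]
  list(slope = unname(coef(fit)["lx"]), ci = unname(ci),
       intercept = unname(coef(fit)["(Intercept)"]), fit = fit)
}
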