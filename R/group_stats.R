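#' Square-root transformation for skewed parameter distributions
#'
#' Discounting parameters are bounded below by 0 and heavily right-skewed;
#' the square root keeps the lower bound at 0 (unlike the log, which
#' diverges as values approach 0) while taming the skew for parametric
#' tests. Monotone, so ranks are unchanged.
#'
#' @param values Non-negative numeric vector.
#' @return Element-wise square roots.
#' @export
sqrt_transform <- function(values) {
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and non-negative", call. = FALSE)
  }
  sqrt(values)
}

.td_comparison_row <- function(parameter, test, statistic, df, p) {
  tibble::tibble(parameter = parameter, test = test,
                 statistic = as.numeric(statistic),
                 df = if (is.null(df)) NA_real_ else as.numeric(df),
                 p_value = as.numeric(p))
}

#' Compare a model parameter between two groups or conditions
#'
#' Applies the transform, then runs a two-tailed t-test (two-sample with
#' pooled variance by default, or paired) alongside the matching Wilcoxon
#' variant (rank-sum for independent groups, signed-rank for paired data).
#' The rank tests are run on the untransformed values -- ranks are invariant
#' to any monotone transform. Both results are reported.
#'
#' @param group_a,group_b Numeric parameter values per group/condition.
#' @param paired Within-subject comparison? Requires equal lengths.
#' @param transform Transform for the parametric test: `"sqrt"` (default)
#'   or `"identity"`.
#' @param var_equal Pooled-variance t-test (default `TRUE`, classical
#'   df `n1 + n2 - 2`); `FALSE` gives Welch.
#' @param parameter Label for the output rows.
#' @return Tibble with one row per test: `parameter`, `test`, `statistic`,
#'   `df`, `p_value`.
#' @export
compare_parameter <- function(group_a, group_b, paired = FALSE,
                              transform = c("sqrt", "identity"),
                              var_equal = TRUE, parameter = "parameter") {
  transform <- match.arg(transform)
  if (paired && length(group_a) != length(group_b)) {
    stop("paired comparison requires equal lengths", call. = FALSE)
  }
  if (min(length(group_a), length(group_b)) < 5L) {
    warning("fewer than 5 observations in a group", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0 &&
      mean(group_a) != mean(group_b)) {
    stop("both groups have zero variance; test is degenerate", call. = FALSE)
  }
  ta <- if (transform == "sqrt") sqrt_transform(group_a) else group_a
  tb <- if (transform == "sqrt") sqrt_transform(group_b) else group_b

  if (paired) {
    d <- ta - tb
    if (all(d == 0)) {
      warning("all paired differences are zero; p = 1", call. = FALSE)
      tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
      wt <- list(statistic = NA_real_, p.value = 1)
    } else {
      tt <- stats::t.test(ta, tb, paired = TRUE)
      wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                                paired = TRUE))
    }
    rbind(
      .td_comparison_row(parameter, "paired_t", tt$statistic, tt$parameter,
                         tt$p.value),
      .td_comparison_row(parameter, "wilcoxon_signed_rank", wt$statistic,
                         NULL, wt$p.value)
    )
  } else {
    identical_groups <- length(ta) == length(tb) &&
      isTRUE(all.equal(sort(ta), sort(tb)))
    tt <- if (identical_groups && stats::var(c(ta, tb)) == 0) {
      list(statistic = 0, parameter = length(ta) + length(tb) - 2, p.value = 1)
    } else {
      stats::t.test(ta, tb, var.equal = var_equal)
    }
    wt <- suppressWarnings(stats::wilcox.test(group_a, group_b))
    rbind(
      .td_comparison_row(parameter, "two_sample_t", tt$statistic,
                         tt$parameter, tt$p.value),
      .td_comparison_row(parameter, "wilcoxon_rank_sum", wt$statistic, NULL,
                         wt$p.value)
    )
  }
}

#' Test whether scaling exponents differ from 1
#'
#' One-sample Wilcoxon signed-rank test of the exponent estimates against 1
#' (two-sided). An exponent of 1 means a linear representation of time;
#' values below 1 indicate compressive non-linear scaling. A normal-
#' approximation Z value is reported alongside the exact-when-possible
#' p-value.
#'
#' @param exponents Numeric vector of per-subject exponent estimates
#'   (`s` or `b`).
#' @param parameter Label for the output row.
#' @return Tibble row: `parameter`, `test`, `statistic` (signed-rank V),
#'   `z_value`, `df` (`NA`), `p_value`.
#' @export
exponent_vs_one <- function(exponents, parameter = "exponent") {
  if (!length(exponents)) stop("empty input", call. = FALSE)
  d <- exponents - 1
  nz <- d[d != 0]
  if (!length(nz)) {
    warning("all exponents are exactly 1; p = 1", call. = FALSE)
    out <- .td_comparison_row(parameter, "wilcoxon_signed_rank_vs_1",
                              NA_real_, NULL, 1)
    out$z_value <- 0
    return(out[, c("parameter", "test", "statistic", "z_value", "df",
                   "p_value")])
  }
  wt <- suppressWarnings(stats::wilcox.test(exponents, mu = 1))
  n <- length(nz)
  v <- as.numeric(wt$statistic)
  mu_v <- n * (n + 1) / 4
  sd_v <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (v - mu_v) / sd_v
  out <- .td_comparison_row(parameter, "wilcoxon_signed_rank_vs_1", v, NULL,
                            wt$p.value)
  out$z_value <- z
  out[, c("parameter", "test", "statistic", "z_value", "df", "p_value")]
}
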