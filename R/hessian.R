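#' Numerical Hessian by central finite differences
#'
#' Second derivatives of a scalar objective by central differencing with an
#' absolute step `h` (default 1e-3): diagonal entries from the standard
#' three-point stencil, off-diagonal entries from the four-point cross
#' stencil, symmetrized as `(H + t(H))/2`. Exact (up to rounding) on
#' quadratics.
#'
#' @param objective Function of a numeric parameter vector returning a
#'   finite scalar near `point`.
#' @param point Numeric vector at which to differentiate (typically the ML
#'   estimate).
#' @param step Positive finite-difference step, absolute by default.
#' @param relative If `TRUE`, the step for coordinate i is
#'   `step * max(|point[i]|, 1)` (better conditioning when parameter scales
#'   differ wildly).
#' @return Symmetric numeric matrix `length(point) x length(point)`.
#' @export
numerical_hessian <- function(objective, point, step = 1e-3, relative = FALSE) {
  stopifnot(is.function(objective), step > 0)
  d <- length(point)
  h <- if (relative) step * pmax(abs(point), 1) else rep(step, d)
  probe <- function(offset) {
    v <- objective(point + offset)
    if (!is.finite(v)) {
      stop("objective not finite at offset (",
           paste(signif(offset, 4), collapse = ", "), ")", call. = FALSE)
    }
    v
  }
  f0 <- probe(rep(0, d))
  H <- matrix(NA_real_, d, d)
  e <- function(i, s) {
    v <- rep(0, d)
    v[i] <- s * h[i]
    v
  }
  for (i in seq_len(d)) {
    H[i, i] <- (probe(e(i, 1)) - 2 * f0 + probe(e(i, -1))) / h[i]^2
  }
  if (d > 1L) {
    for (i in seq_len(d - 1L)) {
      for (j in seq(i + 1L, d)) {
        H[i, j] <- H[j, i] <-
          (probe(e(i, 1) + e(j, 1)) - probe(e(i, 1) + e(j, -1)) -
           probe(e(i, -1) + e(j, 1)) + probe(e(i, -1) + e(j, -1))) /
          (4 * h[i] * h[j])
      }
    }
  }
  (H + t(H)) / 2
}

#' Covariance and correlation from a Hessian
#'
#' Inverts the Hessian of the negative log-likelihood to the asymptotic
#' covariance and normalizes to a correlation matrix. The Hessian is deemed
#' non-invertible -- as happens when the ML estimate sits near a bound or on
#' a likelihood plateau/ridge -- when the Cholesky factorization fails, the
#' condition number exceeds `cond_limit`, or the implied variances are not
#' positive; in that case no correlation is emitted.
#'
#' @param hessian Square symmetric numeric matrix.
#' @param cond_limit Condition-number threshold for declaring the matrix
#'   numerically singular (default 1e8).
#' @return A list: `invertible` (logical), `condition_number`, and (when
#'   invertible) `covariance` and `correlation`.
#' @export
correlation_from_hessian <- function(hessian, cond_limit = 1e8) {
  H <- as.matrix(hessian)
  if (nrow(H) != ncol(H)) stop("hessian must be square", call. = FALSE)
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H)))) {
    stop("hessian must be symmetric", call. = FALSE)
  }
  H <- (H + t(H)) / 2
  ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  cond <- if (anyNA(ev) || min(ev) <= 0) Inf else max(ev) / min(ev)
  fail <- function() list(invertible = FALSE, condition_number = cond)
  if (!is.finite(cond) || cond > cond_limit) return(fail())
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) return(fail())
  cov <- chol2inv(ch)
  v <- diag(cov)
  if (any(v <= 0)) return(fail())
  sds <- sqrt(v)
  corr <- cov / tcrossprod(sds)
  diag(corr) <- 1
  dimnames(cov) <- dimnames(corr) <- dimnames(H)
  list(invertible = TRUE, condition_number = cond,
       covariance = cov, correlation = corr)
}

#' Cohort-averaged inter-parameter correlations
#'
#' For each fitted subject, rebuilds the negative log-likelihood on the
#' natural parameter scale, evaluates its Hessian at the ML estimate
#' (including `beta`, so 2x2 for single- and 3x3 for dual-parameter
#' models), converts it to a correlation matrix, and averages the
#' correlation between the two discounting parameters across the subjects
#' whose Hessians were invertible. Non-invertible subjects are counted, not
#' averaged.
#'
#' For the CS model the impatience parameter `a` often sits close to zero,
#' where an absolute finite-difference step conditions the Hessian poorly;
#' with `rescale_cs = TRUE` (default) the CS objective is reparameterized in
#' `100 a` before differentiation, which typically reduces the
#' non-invertible count without changing the correlation of an exactly
#' quadratic objective.
#'
#' @param fits A `td_cohort_fit` or list of `td_fit` objects (each carries
#'   its trials, so the objective can be rebuilt).
#' @param step Finite-difference step (absolute), default 1e-3.
#' @param rescale_cs Refit the CS curvature in the rescaled `100 a`
#'   coordinate (see Details).
#' @param relative Use relative stepping instead (see
#'   [numerical_hessian()]).
#' @return A tibble, one row per model present: `model_id`, `n_subjects`,
#'   `n_noninvertible`, `mean_corr` (mean discount-parameter correlation;
#'   `NA` for single-parameter models), `mean_abs_corr`, and `corr_matrix`
#'   (list column: the full averaged correlation matrix including `beta`).
#' @export
cohort_mean_correlations <- function(fits, step = 1e-3, rescale_cs = TRUE,
                                     relative = FALSE) {
  fits <- cohort_fits(fits)
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  models <- unique(vapply(fits, `[[`, "", "model_id"))
  rows <- lapply(models, function(m) {
    mfits <- Filter(function(f) f$model_id == m, fits)
    spec <- .td_model(m)
    scale1 <- if (m == "CS" && rescale_cs) 100 else 1
    corrs <- list()
    n_bad <- 0L
    for (f in mfits) {
      nll <- .td_nll_natural(f$trials, m, f$beta_convention,
                             rescale_first = scale1)
      theta <- c(f$params$discount_params, beta = f$params$beta)
      theta[1L] <- theta[1L] * scale1
      H <- tryCatch(numerical_hessian(nll, theta, step = step,
                                      relative = relative),
                    error = function(e) NULL)
      res <- if (is.null(H)) list(invertible = FALSE) else
        correlation_from_hessian(H)
      if (isTRUE(res$invertible)) {
        corr <- res$correlation
        dimnames(corr) <- list(names(theta), names(theta))
        corrs[[length(corrs) + 1L]] <- corr
      } else {
        n_bad <- n_bad + 1L
      }
    }
    if (!length(corrs)) {
      stop("no invertible Hessians for model ", m, call. = FALSE)
    }
    mean_mat <- Reduce(`+`, corrs) / length(corrs)
    pair <- if (spec$n_params == 2L) mean_mat[1L, 2L] else NA_real_
    abs_pair <- if (spec$n_params == 2L) {
      mean(vapply(corrs, function(cm) abs(cm[1L, 2L]), 0))
    } else {
      NA_real_
    }
    tibble::tibble(
      model_id = m,
      n_subjects = length(mfits),
      n_noninvertible = n_bad,
      mean_corr = pair,
      mean_abs_corr = abs_pair,
      corr_matrix = list(mean_mat)
    )
  })
  do.call(rbind, rows)
}

#' Write cohort-averaged correlations as CSV
#' @param corr Tibble from [cohort_mean_correlations()].
#' @param path File path for the CSV.
#' @return The tibble written (without the matrix column), invisibly.
#' @export
write_correlations <- function(corr, path) {
  out <- corr[setdiff(names(corr), "corr_matrix")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
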