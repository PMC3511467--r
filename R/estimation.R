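# Random starting values for the multi-start search, on the natural scale.
# Rates (k, a) and beta are drawn log-uniformly, exponents (s, b) uniformly;
# ranges cover the bulk of parameter estimates seen in laboratory
# inter-temporal choice work with wide margin.
.td_random_starts <- function(spec, n_starts) {
  # one start is drawn completely before the next, so under a fixed seed the
  # first m starts coincide for any n_starts >= m (best-of is then monotone
  # in n_starts)
  one <- function() {
    p <- vapply(spec$param_names, function(nm) {
      if (nm %in% c("k", "a")) exp(stats::runif(1, log(1e-4), log(1)))
      else stats::runif(1, 0.25, 2.5)
    }, 0)
    c(p, beta = exp(stats::runif(1, log(0.1), log(10))))
  }
  t(vapply(seq_len(n_starts), function(i) one(),
           numeric(spec$n_params + 1L)))
}

#' Fit one discounting model to one subject's trials by maximum likelihood
#'
#' Maximizes the softmax log-likelihood with a derivative-free Nelder-Mead
#' simplex, restarted from `n_starts` random starting points; the best
#' (highest log-likelihood) solution is returned. All positive parameters are
#' searched on the log scale, which enforces positivity without penalties;
#' estimates are reported on the natural scale and flagged when they land on
#' a box bound. AIC/BIC count `beta` as a free parameter, so the number of
#' free parameters is 2 for H/E and 3 for GM/R/CS.
#'
#' Subjects whose choices are all identical are fit anyway (the likelihood
#' then pushes the rate toward a bound); a warning is raised and the
#' boundary flags record the capping.
#'
#' @param trials Data frame of one subject's trials (columns `amount_ss`,
#'   `amount_ll`, `delay_days`, `choice`; optionally `subject_id`).
#' @param model_id Model to fit (see [model_catalog()]).
#' @param n_starts Number of random starting points (default 20).
#' @param seed Integer seed making the fit reproducible; `NULL` uses the
#'   current RNG stream.
#' @param beta_convention Softmax convention, see [choice_probability()].
#' @param reltol,maxit Simplex convergence tolerance and iteration cap per
#'   start.
#' @return An object of class `td_fit`: a list with `subject_id`,
#'   `model_id`, `params` (a [param_vector()]), `loglik`, `aic`, `bic`,
#'   `n_trials`, `n_starts`, `best_start_index`, `converged`,
#'   `boundary_flags`, `degenerate`, and the `trials` used (retained so
#'   curvature diagnostics can rebuild the objective).
#' @seealso [fit_cohort()] for whole-dataset fitting.
#' @export
fit_subject <- function(trials, model_id, n_starts = 20L, seed = NULL,
                        beta_convention = c("temperature", "inverse"),
                        reltol = 1e-6, maxit = 5000L) {
  beta_convention <- match.arg(beta_convention)
  spec <- .td_model(model_id)
  .td_check_trials(trials)
  if (n_starts < 1L) stop("n_starts must be >= 1", call. = FALSE)
  n <- nrow(trials)
  if (n < 10L) {
    warning("only ", n, " trials; estimates may be unstable", call. = FALSE)
  }
  degenerate <- length(unique(trials$choice)) == 1L
  if (degenerate) {
    warning("all choices identical; parameters are weakly identified and ",
            "may be capped at a bound", call. = FALSE)
  }

  nll <- .td_nll_factory(trials, model_id, beta_convention)
  lo <- log(c(spec$lower, beta = .td_beta_bounds[["lower"]]))
  hi <- log(c(spec$upper, beta = .td_beta_bounds[["upper"]]))

  starts <- .td_with_seed(seed, .td_random_starts(spec, n_starts))

  best <- NULL
  best_val <- Inf
  best_idx <- NA_integer_
  any_converged <- FALSE
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(log(starts[i, ]), nll, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) next
    if (fit$convergence == 0L) any_converged <- TRUE
    if (fit$value < best_val) {
      best_val <- fit$value
      best <- fit
      best_idx <- i
    }
  }
  if (is.null(best)) {
    stop("estimation failed: no start produced a finite objective (model ",
         model_id, ", ", n, " trials)", call. = FALSE)
  }

  # A subject with identical choices leaves the likelihood flat once the
  # choice probabilities saturate; take the canonical boundary representative
  # of that flat ML region (rate at the bound, minimal stochasticity) when it
  # is at least as good as the simplex solution.
  if (degenerate) {
    cand <- best$par
    cand[1L] <- if (all(trials$choice == "LL")) lo[1L] else hi[1L]
    cand[spec$n_params + 1L] <- lo[spec$n_params + 1L]
    if (nll(cand) <= best_val + 1e-9) {
      best$par <- cand
      best_val <- nll(cand)
    }
  }

  log_par <- pmin(pmax(best$par, lo), hi)
  nat_lo <- c(spec$lower, beta = .td_beta_bounds[["lower"]])
  nat_hi <- c(spec$upper, beta = .td_beta_bounds[["upper"]])
  par <- pmin(pmax(exp(log_par), nat_lo), nat_hi)  # exact at the bounds
  names(par) <- c(spec$param_names, "beta")
  boundary <- abs(log_par - lo) < 1e-6 | abs(log_par - hi) < 1e-6
  names(boundary) <- names(par)

  loglik <- -best_val
  n_free <- spec$n_params + 1L
  subject_id <- if ("subject_id" %in% names(trials)) {
    as.character(trials$subject_id[1L])
  } else {
    NA_character_
  }

  structure(
    list(
      subject_id = subject_id,
      model_id = model_id,
      params = param_vector(model_id, par[spec$param_names], par[["beta"]]),
      loglik = loglik,
      aic = aic(loglik, n_free),
      bic = bic(loglik, n_free, n),
      n_trials = n,
      n_starts = as.integer(n_starts),
      best_start_index = best_idx,
      converged = any_converged && best$convergence == 0L,
      boundary_flags = boundary,
      degenerate = degenerate,
      low_trials = n < 10L,
      beta_convention = beta_convention,
      trials = trials
    ),
    class = "td_fit"
  )
}

#' @export
print.td_fit <- function(x, ...) {
  cat("<td_fit> subject ", x$subject_id, ", model ", x$model_id, "\n",
      "  ", paste(sprintf("%s = %.5g", names(x$params$discount_params),
                          x$params$discount_params), collapse = ", "),
      ", beta = ", format(x$params$beta, digits = 5), "\n",
      "  loglik ", format(x$loglik, digits = 6),
      ", AIC ", format(x$aic, digits = 6),
      ", ", x$n_trials, " trials, converged: ", x$converged, "\n", sep = "")
  if (any(x$boundary_flags)) {
    cat("  boundary-capped:",
        paste(names(x$boundary_flags)[x$boundary_flags], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit a set of models to every subject in a dataset
#'
#' Runs [fit_subject()] for each (subject, model) pair. Per-subject seeds are
#' derived deterministically from `seed`, so the whole table is reproducible.
#' Failures and warnings for individual subjects are captured in the output
#' flags rather than aborting the cohort.
#'
#' @param trials Data frame of trials for all subjects (must contain
#'   `subject_id`).
#' @param models Character vector of model ids to fit (default: all five).
#' @param n_starts,seed,beta_convention Passed to [fit_subject()].
#' @return A tibble of class `td_cohort_fit` with one row per
#'   (subject, model): columns `subject_id`, `model_id`, `k_a`, `s_b`
#'   (`NA` for single-parameter models), `beta`, `loglik`, `aic`, `bic`,
#'   `n_trials`, `converged`, `boundary_capped`, `degenerate`, `low_trials`,
#'   `failed`. The full `td_fit` objects are attached as attribute `"fits"`.
#' @export
fit_cohort <- function(trials, models = model_ids(), n_starts = 20L,
                       seed = 1L,
                       beta_convention = c("temperature", "inverse")) {
  beta_convention <- match.arg(beta_convention)
  if (!"subject_id" %in% names(trials)) {
    stop("trials must contain a subject_id column", call. = FALSE)
  }
  models <- match.arg(models, model_ids(), several.ok = TRUE)
  subjects <- unique(as.character(trials$subject_id))
  by_subject <- split(trials, factor(as.character(trials$subject_id),
                                     levels = subjects))

  rows <- vector("list", length(subjects) * length(models))
  fits <- vector("list", length(rows))
  idx <- 0L
  for (si in seq_along(subjects)) {
    sub_trials <- by_subject[[si]]
    for (m in models) {
      idx <- idx + 1L
      sub_seed <- .td_derive_seed(seed, si * 101L + match(m, model_ids()))
      fit <- tryCatch(
        suppressWarnings(
          fit_subject(sub_trials, m, n_starts = n_starts, seed = sub_seed,
                      beta_convention = beta_convention)
        ),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        rows[[idx]] <- tibble::tibble(
          subject_id = subjects[si], model_id = m,
          k_a = NA_real_, s_b = NA_real_, beta = NA_real_,
          loglik = NA_real_, aic = NA_real_, bic = NA_real_,
          n_trials = nrow(sub_trials), converged = FALSE,
          boundary_capped = NA, degenerate = NA, low_trials = NA,
          failed = TRUE
        )
        fits[[idx]] <- NULL
        next
      }
      dp <- fit$params$discount_params
      rows[[idx]] <- tibble::tibble(
        subject_id = subjects[si], model_id = m,
        k_a = dp[[1L]],
        s_b = if (length(dp) > 1L) dp[[2L]] else NA_real_,
        beta = fit$params$beta,
        loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
        n_trials = fit$n_trials, converged = fit$converged,
        boundary_capped = any(fit$boundary_flags),
        degenerate = fit$degenerate, low_trials = fit$low_trials,
        failed = FALSE
      )
      fits[[idx]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits[!vapply(fits, is.null, TRUE)]
  class(out) <- c("td_cohort_fit", class(out))
  out
}

#' Extract the per-fit objects from a cohort fit
#' @param x A `td_cohort_fit` (from [fit_cohort()]) or a list of `td_fit`.
#' @return List of `td_fit` objects.
#' @export
cohort_fits <- function(x) {
  if (inherits(x, "td_cohort_fit")) return(attr(x, "fits"))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "td_fit"))) return(x)
  stop("expected a td_cohort_fit or a list of td_fit objects", call. = FALSE)
}
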