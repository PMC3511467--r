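#' Akaike information criterion
#'
#' `AIC = -2 loglik + 2 n_free`. Throughout the package `n_free` counts the
#' softmax `beta` in addition to the discounting parameters (2 for H/E,
#' 3 for GM/R/CS).
#'
#' @param loglik Maximized log-likelihood.
#' @param n_free Number of free parameters (>= 1).
#' @return Numeric AIC score (lower is better).
#' @export
aic <- function(loglik, n_free) {
  stopifnot(n_free >= 1)
  -2 * loglik + 2 * n_free
}

#' Bayesian information criterion
#'
#' `BIC = -2 loglik + n_free * log(n_trials)`. Exceeds the AIC whenever
#' `n_trials > exp(2)` (about 7 trials).
#'
#' @inheritParams aic
#' @param n_trials Number of trials entering the likelihood (>= 1).
#' @return Numeric BIC score (lower is better).
#' @export
bic <- function(loglik, n_free, n_trials) {
  stopifnot(n_trials >= 1)
  -2 * loglik + n_free * log(n_trials)
}

#' Subject-by-model score matrix from a cohort fit
#'
#' @param cohort A `td_cohort_fit` from [fit_cohort()].
#' @param kind `"AIC"` or `"BIC"`.
#' @return Numeric matrix (subjects x models) with attribute
#'   `score_kind`; failed fits yield `NA` cells.
#' @export
score_table <- function(cohort, kind = c("AIC", "BIC")) {
  kind <- match.arg(kind)
  col <- if (kind == "AIC") "aic" else "bic"
  subjects <- unique(cohort$subject_id)
  models <- unique(cohort$model_id)
  m <- matrix(NA_real_, length(subjects), length(models),
              dimnames = list(subjects, models))
  m[cbind(match(cohort$subject_id, subjects),
          match(cohort$model_id, models))] <- cohort[[col]]
  attr(m, "score_kind") <- kind
  m
}

# Parsimony-consistent deterministic argmin: fewest free parameters first,
# then canonical model order H < E < GM < R < CS.
.td_pick_winner <- function(scores, models) {
  best <- which(scores <= min(scores) + 1e-12)
  if (length(best) > 1L) {
    npar <- vapply(models[best], function(m) {
      if (m %in% names(.td_registry)) .td_registry[[m]]$n_params
      else NA_integer_
    }, 0L)
    if (!anyNA(npar)) best <- best[npar == min(npar)]
    if (length(best) > 1L) {
      key <- match(models[best], model_ids())
      key[is.na(key)] <- length(model_ids()) + best[is.na(key)]
      best <- best[order(key)][1L]
    }
  }
  models[best[1L]]
}

#' Per-subject and group delta scores
#'
#' Subtracts, for each subject, the best model's score so the winning model
#' sits at 0 (relative differences, not absolute scores, are meaningful).
#' The group-level delta is computed on the column sums of the score matrix
#' (sum first, then min-center), not by summing per-subject deltas.
#'
#' Ties for the per-subject winner are broken toward the model with fewer
#' free parameters, then by the order H, E, GM, R, CS.
#'
#' @param scores Matrix from [score_table()] (subjects x models), complete.
#' @return A list of class `td_delta`: `delta` (per-subject matrix, row
#'   minima exactly 0), `group_delta` (named vector, minimum exactly 0),
#'   `winner` (named character vector per subject), `score_kind`.
#' @export
delta_scores <- function(scores) {
  if (anyNA(scores)) {
    stop("score table has missing cells; complete the fits or drop subjects",
         call. = FALSE)
  }
  models <- colnames(scores)
  delta <- scores - apply(scores, 1L, min)
  group <- colSums(scores)
  group_delta <- group - min(group)
  winner <- apply(scores, 1L, .td_pick_winner, models = models)
  structure(
    list(delta = delta, group_delta = group_delta, winner = winner,
         score_kind = attr(scores, "score_kind")),
    class = "td_delta"
  )
}

#' @export
print.td_delta <- function(x, ...) {
  cat("<td_delta> ", nrow(x$delta), " subjects x ", ncol(x$delta),
      " models (", x$score_kind %||% "score", ")\n", sep = "")
  cat("group delta:\n")
  print(round(x$group_delta, 2))
  cat("winner counts:\n")
  print(table(factor(x$winner, levels = colnames(x$delta))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proportion of subjects best fit by each model
#'
#' @param delta A `td_delta` from [delta_scores()].
#' @return Named numeric vector of winner proportions (sums to 1).
#' @export
winner_frequencies <- function(delta) {
  stopifnot(inherits(delta, "td_delta"))
  tab <- table(factor(delta$winner, levels = colnames(delta$delta)))
  props <- as.vector(tab) / sum(tab)
  names(props) <- names(tab)
  props
}

#' Pairwise tests on per-subject delta scores
#'
#' Two-sided Wilcoxon tests on the per-subject score differences between
#' every model pairing; the paired signed-rank test is the default (the same
#' subjects are scored under each model), with the unpaired rank-sum variant
#' available. Per-subject min-centering cancels in paired differences, so
#' the signed-rank test is identical on raw scores and delta scores. Zero
#' differences are dropped (standard signed-rank convention); exact p-values
#' are used for n <= 25 without ties, a normal approximation with continuity
#' correction otherwise. An all-zero difference vector yields p = 1 with a
#' tie warning.
#'
#' @param delta A `td_delta` from [delta_scores()].
#' @param method `"signed_rank"` (paired, default) or `"rank_sum"`.
#' @param p_adjust `"none"` (default, uncorrected pairwise p-values) or
#'   `"holm"`.
#' @return Symmetric matrix of two-sided p-values with `NA` diagonal.
#' @export
pairwise_wilcoxon <- function(delta, method = c("signed_rank", "rank_sum"),
                              p_adjust = c("none", "holm")) {
  stopifnot(inherits(delta, "td_delta"))
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  d <- delta$delta
  if (nrow(d) < 6L) {
    warning("fewer than 6 subjects; p-values are of limited use",
            call. = FALSE)
  }
  models <- colnames(d)
  K <- length(models)
  p <- matrix(NA_real_, K, K, dimnames = list(models, models))
  for (i in seq_len(K - 1L)) {
    for (j in seq(i + 1L, K)) {
      diffs <- d[, i] - d[, j]
      pij <- if (all(diffs == 0)) {
        warning("all per-subject differences between ", models[i], " and ",
                models[j], " are zero; p = 1", call. = FALSE)
        1
      } else if (method == "signed_rank") {
        suppressWarnings(
          stats::wilcox.test(diffs, alternative = "two.sided",
                             exact = sum(diffs != 0) <= 25,
                             correct = TRUE)$p.value
        )
      } else {
        suppressWarnings(
          stats::wilcox.test(d[, i], d[, j], alternative = "two.sided",
                             paired = FALSE, correct = TRUE)$p.value
        )
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  if (p_adjust == "holm") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = "holm")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  p
}

#' Write a tidy per-subject model-comparison summary
#'
#' One row per (subject, model) with fit scores, the subject's delta score
#' and the subject's winning model.
#'
#' @param cohort A `td_cohort_fit` from [fit_cohort()].
#' @param path File path for the CSV.
#' @param kind Score used for the delta/winner columns (`"AIC"`/`"BIC"`).
#' @return The summary tibble, invisibly.
#' @export
write_fit_summary <- function(cohort, path, kind = c("AIC", "BIC")) {
  kind <- match.arg(kind)
  scores <- score_table(cohort, kind)
  delta <- delta_scores(scores)
  d_long <- as.vector(delta$delta[cbind(match(cohort$subject_id, rownames(delta$delta)),
                                        match(cohort$model_id, colnames(delta$delta)))])
  out <- tibble::tibble(
    subject_id = cohort$subject_id,
    model_id = cohort$model_id,
    loglik = cohort$loglik,
    aic = cohort$aic,
    bic = cohort$bic,
    delta_score = d_long,
    winner = delta$winner[cohort$subject_id]
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
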