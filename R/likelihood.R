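# Probability floor applied before taking logs; prevents -Inf contributions
# from near-deterministic subjects.
.td_p_floor <- 1e-12

#' Softmax probability of choosing the larger-later option
#'
#' Logistic choice rule on the subjective-value difference. Under the
#' default `"temperature"` convention the value difference is divided by
#' `beta`, so larger `beta` means noisier (more stochastic) choices and a
#' shallower sigmoid. The `"inverse"` convention multiplies instead
#' (larger `beta` = more deterministic); it is exposed for sensitivity
#' checks only.
#'
#' @param sv_ss Subjective value of the smaller-sooner (immediate) option.
#' @param sv_ll Subjective value of the larger-later option.
#' @param beta Positive stochasticity parameter.
#' @param beta_convention `"temperature"` (default) or `"inverse"`.
#' @return Probability of choosing the larger-later option, in (0, 1).
#' @examples
#' choice_probability(20, 20, 1.5)                 # 0.5 at equal value
#' choice_probability(20, 20 + 2 * log(3), 2)      # 0.75, analytically forced
#' @export
choice_probability <- function(sv_ss, sv_ll, beta,
                               beta_convention = c("temperature", "inverse")) {
  beta_convention <- match.arg(beta_convention)
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    stop("beta must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(sv_ss)) || any(!is.finite(sv_ll))) {
    stop("subjective values must be finite", call. = FALSE)
  }
  x <- if (beta_convention == "temperature") {
    (sv_ll - sv_ss) / beta
  } else {
    (sv_ll - sv_ss) * beta
  }
  stats::plogis(x)
}

.td_check_trials <- function(trials) {
  req <- c("amount_ss", "amount_ll", "delay_days", "choice")
  missing <- setdiff(req, names(trials))
  if (length(missing)) {
    stop("trials is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0L) stop("empty trial list", call. = FALSE)
  if (!all(trials$choice %in% c("SS", "LL"))) {
    stop("choice must be 'SS' or 'LL'", call. = FALSE)
  }
  invisible(trials)
}

# Stable per-trial log choice probabilities of the chosen option.
# x is the (scaled) value difference LL - SS; chose_ll is logical.
# log plogis is used for numerical stability; the result is clamped to the
# probability floor/ceiling [1e-12, 1 - 1e-12].
.td_log_choice_prob <- function(x, chose_ll) {
  lp <- ifelse(chose_ll,
               stats::plogis(x, log.p = TRUE),
               stats::plogis(-x, log.p = TRUE))
  pmin(pmax(lp, log(.td_p_floor)), log1p(-.td_p_floor))
}

#' Log-likelihood of a subject's choices under a discounting model
#'
#' Sums the log softmax probability of the chosen option across all trials.
#' Probabilities are clamped to `[1e-12, 1 - 1e-12]` before the log, so the
#' result is bounded below by `n_trials * log(1e-12)`.
#'
#' @param trials Data frame of trials with columns `amount_ss`, `amount_ll`,
#'   `delay_days`, `choice` (`"SS"`/`"LL"`).
#' @param params A [param_vector()] (carries the model id, discounting
#'   parameters and `beta`).
#' @param beta_convention Passed to [choice_probability()].
#' @return A list of class `td_loglik` with elements `loglik` (non-positive)
#'   and `n_trials`.
#' @export
dataset_log_likelihood <- function(trials, params,
                                   beta_convention = c("temperature", "inverse")) {
  beta_convention <- match.arg(beta_convention)
  stopifnot(inherits(params, "td_params"))
  .td_check_trials(trials)
  sv_ll <- .td_sv(params$model_id, params$discount_params,
                  trials$amount_ll, trials$delay_days)
  dv <- sv_ll - trials$amount_ss
  x <- if (beta_convention == "temperature") dv / params$beta else dv * params$beta
  ll <- sum(.td_log_choice_prob(x, trials$choice == "LL"))
  structure(list(loglik = ll, n_trials = nrow(trials)), class = "td_loglik")
}

#' @export
print.td_loglik <- function(x, ...) {
  cat("<td_loglik> log-likelihood ", format(x$loglik, digits = 6),
      " over ", x$n_trials, " trials\n", sep = "")
  invisible(x)
}

# Negative log-likelihood objective factory used by the optimizer and the
# Hessian diagnostics. Returns a function of the log-scale free parameter
# vector c(log discount params, log beta); log parameters are clamped to the
# box bounds so the unconstrained simplex search respects them.
.td_nll_factory <- function(trials, model_id, beta_convention = "temperature") {
  spec <- .td_model(model_id)
  lo <- log(c(spec$lower, beta = .td_beta_bounds[["lower"]]))
  hi <- log(c(spec$upper, beta = .td_beta_bounds[["upper"]]))
  a_ll <- trials$amount_ll
  d_ll <- trials$delay_days
  a_ss <- trials$amount_ss
  chose_ll <- trials$choice == "LL"
  np <- spec$n_params
  temperature <- beta_convention == "temperature"
  log_floor <- log(.td_p_floor)
  log_ceil <- log1p(-.td_p_floor)
  function(log_par) {
    log_par <- pmin(pmax(log_par, lo), hi)
    par <- exp(log_par)
    p <- par[seq_len(np)]
    names(p) <- spec$param_names
    sv_ll <- .td_sv(model_id, p, a_ll, d_ll)
    dv <- sv_ll - a_ss
    x <- if (temperature) dv / par[np + 1L] else dv * par[np + 1L]
    lp <- ifelse(chose_ll,
                 stats::plogis(x, log.p = TRUE),
                 stats::plogis(-x, log.p = TRUE))
    -sum(pmin(pmax(lp, log_floor), log_ceil))
  }
}

# Natural-scale counterpart (no clamping) used for Hessian evaluation at the
# ML estimate; par = c(discount params, beta), optionally with the first CS
# parameter rescaled (par[1] = 100 a).
.td_nll_natural <- function(trials, model_id, beta_convention = "temperature",
                            rescale_first = 1) {
  spec <- .td_model(model_id)
  a_ll <- trials$amount_ll
  d_ll <- trials$delay_days
  a_ss <- trials$amount_ss
  chose_ll <- trials$choice == "LL"
  np <- spec$n_params
  temperature <- beta_convention == "temperature"
  log_floor <- log(.td_p_floor)
  log_ceil <- log1p(-.td_p_floor)
  function(par) {
    p <- par[seq_len(np)]
    p[1L] <- p[1L] / rescale_first
    if (any(p <= 0) || par[np + 1L] <= 0) return(NaN)
    names(p) <- spec$param_names
    sv_ll <- .td_sv(model_id, p, a_ll, d_ll)
    dv <- sv_ll - a_ss
    x <- if (temperature) dv / par[np + 1L] else dv * par[np + 1L]
    lp <- ifelse(chose_ll,
                 stats::plogis(x, log.p = TRUE),
                 stats::plogis(-x, log.p = TRUE))
    -sum(pmin(pmax(lp, log_floor), log_ceil))
  }
}
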