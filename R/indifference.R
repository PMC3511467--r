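#' Indifference points from an adaptive staircase session
#'
#' The indifference amount at each delay is the midpoint of the terminal
#' bracket (lowest accepted, highest rejected delayed amount) recorded when
#' the staircase reached its delay-specific criterion. Delays whose
#' staircase did not terminate are returned with `NA` and flagged. The
#' discount fraction is the immediate amount divided by the indifference
#' amount.
#'
#' @param session A `td_session` from [run_adaptive_session()].
#' @return A tibble with one row per delay: `subject_id`, `delay_days`,
#'   `indifference_amount`, `fraction`, `terminated`.
#' @export
staircase_indifference <- function(session) {
  stopifnot(inherits(session, "td_session"))
  br <- session$brackets
  amount <- ifelse(br$terminated,
                   (br$lowest_accepted + br$highest_rejected) / 2,
                   NA_real_)
  tibble::tibble(
    subject_id = session$agent_id,
    delay_days = br$delay_days,
    indifference_amount = amount,
    fraction = session$amount_ss / amount,
    terminated = br$terminated
  )
}

# Model curve formulas for the fraction-vs-delay non-linear regression;
# normalizing indifference amounts to fractions makes the amount drop out
# of every model.
.td_curve_formulas <- list(
  H  = fraction ~ 1 / (1 + k * delay_days),
  E  = fraction ~ exp(-k * delay_days),
  GM = fraction ~ (1 + k * delay_days)^(-s),
  R  = fraction ~ 1 / (1 + k * delay_days^s),
  CS = fraction ~ exp(-(a * delay_days)^b)
)

#' Non-linear least-squares fit of a discount curve to indifference points
#'
#' Fits the model's discount-fraction curve to (delay, fraction) points by
#' Levenberg-Marquardt least squares, restarted from multiple random
#' starting values (drawn as in [fit_subject()]); the lowest-SSR solution is
#' kept. R-squared is `1 - SS_res / SS_tot` with `SS_tot` about the mean
#' fraction, reported as computed -- it can be negative for data flatter
#' than their mean.
#'
#' @param points Data frame with columns `delay_days` and `fraction` (or
#'   `indifference_amount` plus `amount_ss` from which fractions are
#'   computed).
#' @param model_id Model to fit.
#' @param n_starts Number of random starts (default 20).
#' @param seed Seed for the starts.
#' @return An object of class `td_curvefit`: `model_id`, `params` (named),
#'   `r_squared`, `residuals`, `fitted`, `n_points`.
#' @export
fit_indifference_curve <- function(points, model_id, n_starts = 20L,
                                   seed = NULL) {
  spec <- .td_model(model_id)
  if (!"fraction" %in% names(points)) {
    if (all(c("indifference_amount", "amount_ss") %in% names(points))) {
      points$fraction <- points$amount_ss / points$indifference_amount
    } else {
      stop("points must contain 'fraction' (or 'indifference_amount' and ",
           "'amount_ss')", call. = FALSE)
    }
  }
  points <- points[is.finite(points$fraction) & is.finite(points$delay_days), ]
  n <- nrow(points)
  if (n < spec$n_params + 1L) {
    stop("need at least ", spec$n_params + 1L, " points to fit model ",
         model_id, call. = FALSE)
  }
  dat <- data.frame(delay_days = points$delay_days, fraction = points$fraction)
  starts <- .td_with_seed(seed, .td_random_starts(spec, n_starts))
  # prepend a deterministic coarse-grid start: guards against all random
  # starts landing in one basin of a ridged (rate x exponent) surface
  grid_axes <- lapply(seq_len(spec$n_params), function(i) {
    if (spec$param_names[i] %in% c("k", "a")) {
      exp(seq(log(1e-4), log(1), length.out = 24))
    } else {
      seq(0.25, 2.5, length.out = 10)
    }
  })
  grid <- as.matrix(do.call(expand.grid, grid_axes))
  ssr_grid <- apply(grid, 1L, function(g) {
    names(g) <- spec$param_names
    sum((dat$fraction - .td_fraction(model_id, g, dat$delay_days))^2)
  })
  starts <- rbind(c(grid[which.min(ssr_grid), ], beta = 1), starts)
  n_starts <- n_starts + 1L

  best <- NULL
  best_ssr <- Inf
  for (i in seq_len(n_starts)) {
    st <- as.list(starts[i, seq_len(spec$n_params)])
    names(st) <- spec$param_names
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        .td_curve_formulas[[model_id]], data = dat, start = st,
        lower = spec$lower, upper = spec$upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(stats::residuals(fit)^2)
    if (ssr < best_ssr) {
      best_ssr <- ssr
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("curve fit failed for model ", model_id, call. = FALSE)
  }
  pars <- stats::coef(best)
  fitted <- .td_fraction(model_id, pars, dat$delay_days)
  resid <- dat$fraction - fitted
  ss_tot <- sum((dat$fraction - mean(dat$fraction))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else -Inf
  structure(
    list(model_id = model_id, params = pars, r_squared = r2,
         residuals = resid, fitted = fitted, n_points = n),
    class = "td_curvefit"
  )
}

#' @export
print.td_curvefit <- function(x, ...) {
  cat("<td_curvefit> model ", x$model_id, ": ",
      paste(sprintf("%s = %.5g", names(x$params), x$params), collapse = ", "),
      "; R^2 = ", format(x$r_squared, digits = 4),
      " (", x$n_points, " points)\n", sep = "")
  invisible(x)
}

#' Group-median indifference points on a shared delay grid
#'
#' Takes the per-delay median of the discount fractions across subjects.
#' All subjects must share the same delay grid; cohorts mixing grids (e.g.
#' six- and seven-point protocols) should be split and aggregated per
#' subgroup. For an even subject count the median is the mean of the two
#' central values (R's default).
#'
#' @param points Data frame with `subject_id`, `delay_days`, `fraction`.
#' @return Tibble with `delay_days`, `fraction` (median), `n_subjects`.
#' @export
group_median_points <- function(points) {
  stopifnot(all(c("subject_id", "delay_days", "fraction") %in% names(points)))
  points <- points[is.finite(points$fraction), ]
  grids <- tapply(points$delay_days, points$subject_id,
                  function(d) paste(sort(unique(d)), collapse = ","))
  if (length(unique(grids)) > 1L) {
    stop("subjects use different delay grids; split the cohort by grid and ",
         "aggregate each subgroup separately", call. = FALSE)
  }
  med <- tapply(points$fraction, points$delay_days, stats::median)
  n <- tapply(points$fraction, points$delay_days, length)
  delays <- as.numeric(names(med))
  ord <- order(delays)
  tibble::tibble(
    delay_days = delays[ord],
    fraction = as.numeric(med)[ord],
    n_subjects = as.integer(n)[ord]
  )
}
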