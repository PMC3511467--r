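# Registry of the five discount functions. Bounds are shared across the
# package: estimation clamps to them, the synthetic generator truncates
# population draws to them.
.td_registry <- list(
  H = list(
    model_id = "H", name = "Hyperbolic", n_params = 1L,
    param_names = "k",
    lower = c(k = 1e-8), upper = c(k = 10)
  ),
  E = list(
    model_id = "E", name = "Exponential", n_params = 1L,
    param_names = "k",
    lower = c(k = 1e-8), upper = c(k = 10)
  ),
  GM = list(
    model_id = "GM", name = "Hyperboloid (denominator exponent)", n_params = 2L,
    param_names = c("k", "s"),
    lower = c(k = 1e-8, s = 0.01), upper = c(k = 10, s = 20)
  ),
  R = list(
    model_id = "R", name = "Hyperboloid (delay exponent)", n_params = 2L,
    param_names = c("k", "s"),
    lower = c(k = 1e-8, s = 0.01), upper = c(k = 10, s = 20)
  ),
  CS = list(
    model_id = "CS", name = "Constant sensitivity (exponential-power)", n_params = 2L,
    param_names = c("a", "b"),
    lower = c(a = 1e-8, b = 0.01), upper = c(a = 10, b = 20)
  )
)

# Softmax stochasticity parameter beta is estimated for every model; its
# bounds are not model-specific.
.td_beta_bounds <- c(lower = 1e-6, upper = 100)

#' Canonical model identifiers in package order
#'
#' Order is used for deterministic tie-breaking in model selection:
#' fewer free parameters first, then this ordering.
#' @return Character vector `c("H", "E", "GM", "R", "CS")`.
#' @export
model_ids <- function() names(.td_registry)

.td_model <- function(model_id) {
  if (length(model_id) != 1L || !model_id %in% names(.td_registry)) {
    stop("unknown model_id: ", paste(model_id, collapse = ", "),
         " (must be one of ", paste(names(.td_registry), collapse = ", "), ")",
         call. = FALSE)
  }
  .td_registry[[model_id]]
}

#' Catalog of the candidate discount models
#'
#' Returns one row per model with its number of discounting parameters
#' (excluding the softmax `beta`), ordered parameter names, and default
#' box bounds used by the estimation routines.
#'
#' @return A tibble with columns `model_id`, `name`, `n_params`,
#'   `param_names` (list), `lower` (list), `upper` (list).
#' @examples
#' model_catalog()
#' @export
model_catalog <- function() {
  tibble::tibble(
    model_id = unname(vapply(.td_registry, `[[`, "", "model_id")),
    name = unname(vapply(.td_registry, `[[`, "", "name")),
    n_params = unname(vapply(.td_registry, `[[`, 0L, "n_params")),
    param_names = unname(lapply(.td_registry, `[[`, "param_names")),
    lower = unname(lapply(.td_registry, `[[`, "lower")),
    upper = unname(lapply(.td_registry, `[[`, "upper"))
  )
}

.td_check_params <- function(spec, discount_params) {
  p <- as.numeric(discount_params)
  if (length(p) != spec$n_params) {
    stop("model ", spec$model_id, " expects ", spec$n_params,
         " discounting parameter(s) (", paste(spec$param_names, collapse = ", "),
         "), got ", length(p), call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("discounting parameters must be finite and strictly positive",
         call. = FALSE)
  }
  names(p) <- spec$param_names
  p
}

#' Subjective (discounted) value of a delayed reward
#'
#' Evaluates one of the five candidate discount functions. With amount `A`,
#' delay `D` (days) and parameters as named below:
#' \describe{
#'   \item{H}{`A / (1 + k D)` -- standard hyperbolic.}
#'   \item{E}{`A exp(-k D)` -- exponential.}
#'   \item{GM}{`A / (1 + k D)^s` -- hyperbolic with the whole denominator
#'     raised to a power; equivalent to exponential discounting of
#'     log-compressed time.}
#'   \item{R}{`A / (1 + k D^s)` -- hyperbolic with power-scaled delay.}
#'   \item{CS}{`A exp(-(a D)^b)` -- constant-sensitivity exponential-power
#'     model; `b = 1` recovers E with `k = a`.}
#' }
#'
#' At `D = 0` every model returns `A` exactly; for CS with `b < 1` the
#' term `(a D)^b` is taken as its limit 0 at `D = 0`.
#'
#' @param model_id One of `"H"`, `"E"`, `"GM"`, `"R"`, `"CS"`.
#' @param discount_params Numeric vector of the model's discounting
#'   parameters, in catalog order (`k`; or `k, s`; or `a, b`).
#' @param amount Reward amount(s), strictly positive (euros).
#' @param delay Delay(s) in days, non-negative; fractional days allowed.
#' @return Numeric vector of subjective values, recycled over
#'   `amount`/`delay`.
#' @examples
#' subjective_value("H", 0.05, amount = 40, delay = 20)  # 20: kD = 1 halves
#' subjective_value("CS", c(0.05, 1), 40, 20)            # equals E with k = 0.05
#' @export
subjective_value <- function(model_id, discount_params, amount, delay) {
  spec <- .td_model(model_id)
  p <- .td_check_params(spec, discount_params)
  if (any(!is.finite(amount)) || any(amount <= 0)) {
    stop("amount must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(delay)) || any(delay < 0)) {
    stop("delay must be finite and non-negative", call. = FALSE)
  }
  .td_sv(model_id, p, amount, delay)
}

# Internal hot path: no validation, params named & positive.
.td_sv <- function(model_id, p, amount, delay) {
  switch(model_id,
    H  = amount / (1 + p[["k"]] * delay),
    E  = amount * exp(-p[["k"]] * delay),
    GM = amount / (1 + p[["k"]] * delay)^p[["s"]],
    R  = amount / (1 + p[["k"]] * delay^p[["s"]]),
    CS = amount * exp(-(p[["a"]] * delay)^p[["b"]])
  )
}

# Discount fraction SV/A as a function of delay (amount drops out of all
# five models); used by the indifference-curve fits.
.td_fraction <- function(model_id, p, delay) .td_sv(model_id, p, 1, delay)

#' Parameter vector for a discounting model
#'
#' Bundles a model's discounting parameters with the softmax stochasticity
#' `beta`. Values outside the model's default bounds are rejected.
#'
#' @param model_id Model identifier (see [model_catalog()]).
#' @param discount_params Named or positional numeric vector of discounting
#'   parameters.
#' @param beta Softmax stochasticity (temperature), strictly positive.
#' @return An object of class `td_params`.
#' @export
param_vector <- function(model_id, discount_params, beta) {
  spec <- .td_model(model_id)
  p <- .td_check_params(spec, discount_params)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("beta must be a single positive number", call. = FALSE)
  }
  out_low <- p < spec$lower | beta < .td_beta_bounds[["lower"]]
  out_high <- p > spec$upper | beta > .td_beta_bounds[["upper"]]
  if (any(out_low) || any(out_high)) {
    stop("parameters outside the model's default bounds; see model_catalog()",
         call. = FALSE)
  }
  structure(
    list(model_id = model_id, discount_params = p, beta = beta),
    class = "td_params"
  )
}

#' @export
print.td_params <- function(x, ...) {
  cat("<td_params> model ", x$model_id, ": ",
      paste(sprintf("%s = %.5g", names(x$discount_params), x$discount_params),
            collapse = ", "),
      ", beta = ", format(x$beta, digits = 5), "\n", sep = "")
  invisible(x)
}
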