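#' Read a trial-by-trial choice table
#'
#' Expects a UTF-8 CSV with header columns `subject_id`, `amount_ss`,
#' `amount_ll`, `delay_days`, `choice`. Amounts are euros (decimal), delays
#' are days (fractional allowed, e.g. 0.25), choices are the strings `"SS"`
#' (immediate) or `"LL"` (delayed) -- strings rather than 0/1 to prevent
#' silent polarity bugs. Validation failures name the offending row.
#'
#' @param path CSV file path.
#' @return Tibble of validated trials.
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  req <- c("subject_id", "amount_ss", "amount_ll", "delay_days", "choice")
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("amount_ss", "amount_ll", "delay_days")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " in row ", bad[1L], call. = FALSE)
    }
    if (anyNA(v)) {
      stop("missing ", col, " in row ", which(is.na(v))[1L], call. = FALSE)
    }
    raw[[col]] <- v
  }
  bad <- which(!raw$choice %in% c("SS", "LL"))
  if (length(bad)) {
    stop("choice must be 'SS' or 'LL'; offending row ", bad[1L],
         call. = FALSE)
  }
  bad <- which(raw$amount_ss <= 0 | raw$amount_ll <= raw$amount_ss)
  if (length(bad)) {
    stop("need amount_ll > amount_ss > 0; offending row ", bad[1L],
         call. = FALSE)
  }
  bad <- which(raw$delay_days <= 0)
  if (length(bad)) {
    stop("delay_days must be positive; offending row ", bad[1L],
         call. = FALSE)
  }
  tibble::as_tibble(raw[req])
}

#' Write a trial table as CSV
#'
#' Inverse of [read_trials()]; a written table reads back field-identical.
#'
#' @param trials Trial data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  req <- c("subject_id", "amount_ss", "amount_ll", "delay_days", "choice")
  stopifnot(all(req %in% names(trials)))
  utils::write.csv(trials[req], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble a reproducible run configuration
#'
#' A plain serializable record of every setting a full pipeline run
#' depends on; [write_run_config()] echoes it into the output directory so
#' any run can be reproduced from its artifacts.
#'
#' @param models Model ids to fit.
#' @param score_kind `"AIC"` or `"BIC"`.
#' @param n_starts Multi-start count for estimation.
#' @param seed Master seed.
#' @param bms_mc_samples Monte-Carlo samples for exceedance probabilities.
#' @param hessian_step Finite-difference step.
#' @param rescale_cs CS curvature rescaling flag.
#' @param beta_convention Softmax convention.
#' @param output_dir Where pipeline outputs go.
#' @return A list of class `td_run_config`.
#' @export
run_config <- function(models = model_ids(), score_kind = "AIC",
                       n_starts = 20L, seed = 1L, bms_mc_samples = 1e6,
                       hessian_step = 1e-3, rescale_cs = TRUE,
                       beta_convention = "temperature",
                       output_dir = ".") {
  stopifnot(all(models %in% model_ids()),
            score_kind %in% c("AIC", "BIC"),
            n_starts >= 1,
            beta_convention %in% c("temperature", "inverse"))
  structure(
    list(models = models, score_kind = score_kind,
         n_starts = as.integer(n_starts), seed = as.integer(seed),
         bms_mc_samples = bms_mc_samples, hessian_step = hessian_step,
         rescale_cs = rescale_cs, beta_convention = beta_convention,
         output_dir = output_dir),
    class = "td_run_config"
  )
}

#' Write a run configuration next to its outputs
#' @param config A `td_run_config`.
#' @param path Destination file; format by extension (`.yaml`/`.yml` needs
#'   the yaml package, `.json` needs jsonlite).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "td_run_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML output", call. = FALSE)
    }
    yaml::write_yaml(x, path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the jsonlite package is required for JSON output", call. = FALSE)
    }
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE), path)
  }
  invisible(path)
}
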