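# Shared fixture builders: everything is generated in code under fixed
# seeds; no data files beyond the tiny CSV example under inst/extdata.

# Trials from a fixed-offer style design for a known agent, with choices
# simulated from its softmax rule.
make_toy_trials <- function(n = 30, model_id = "H",
                            discount_params = 0.02, beta = 1.5,
                            subject_id = "toy", seed = 42) {
  agent <- agent_spec(subject_id, model_id, discount_params, beta)
  withr::with_seed(seed, {
    delays <- sample(c(0.25, 1, 7, 30, 90, 180), n, replace = TRUE)
    amounts <- runif(n, 20.5, 80)
    choice <- simulate_choice(agent, 20, amounts, delays)
    tibble::tibble(subject_id = subject_id, amount_ss = 20,
                   amount_ll = amounts, delay_days = delays, choice = choice)
  })
}

# Exhaustive log-spaced lattice maximum of the log-likelihood; independent
# brute-force oracle for the optimizer.
grid_loglik_max <- function(trials, model_id, n_axis = 20) {
  cat_row <- model_catalog()[model_catalog()$model_id == model_id, ]
  lower <- cat_row$lower[[1]]
  upper <- cat_row$upper[[1]]
  axes <- lapply(seq_along(lower), function(i) {
    exp(seq(log(lower[i] * 1.001), log(upper[i] * 0.999),
            length.out = n_axis))
  })
  axes$beta <- exp(seq(log(1e-6 * 1.001), log(100 * 0.999),
                       length.out = n_axis))
  grid <- do.call(expand.grid, axes)
  best <- -Inf
  np <- length(lower)
  for (r in seq_len(nrow(grid))) {
    pv <- param_vector(model_id, as.numeric(grid[r, seq_len(np)]),
                       grid[r, np + 1L])
    ll <- dataset_log_likelihood(trials, pv)$loglik
    if (ll > best) best <- ll
  }
  best
}
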