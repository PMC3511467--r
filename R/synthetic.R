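# Population calibration for the synthetic generator: medians and
# inter-quartile ranges of single-subject ML estimates typical of laboratory
# inter-temporal choice samples -- healthy adults on a fixed-offer task
# ("controls_fixed"), healthy adults on the adaptive adjusting-amount task
# ("controls_adaptive"), and pathological gamblers ("gamblers"). Rates
# (k, a) and beta are treated as log-normal; exponents (s, b) as normal
# truncated to the model bounds.
.td_population <- local({
  row <- function(preset, model, param, m, lo, hi) {
    data.frame(preset = preset, model_id = model, param = param,
               median = m, iqr_lo = lo, iqr_hi = hi,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # beta
    row("controls_fixed", "H", "beta", 2.16, 1.06, 2.88),
    row("controls_adaptive", "H", "beta", 4.29, 2.59, 6.66),
    row("gamblers", "H", "beta", 2.66, 1.51, 4.41),
    row("controls_fixed", "E", "beta", 2.44, 1.16, 3.87),
    row("controls_adaptive", "E", "beta", 6.59, 3.04, 10.99),
    row("gamblers", "E", "beta", 3.32, 1.66, 5.18),
    row("controls_fixed", "GM", "beta", 1.36, 0.72, 1.93),
    row("controls_adaptive", "GM", "beta", 2.56, 1.46, 3.51),
    row("gamblers", "GM", "beta", 1.82, 1.09, 2.45),
    row("controls_fixed", "R", "beta", 1.36, 0.65, 1.97),
    row("controls_adaptive", "R", "beta", 2.28, 1.38, 3.51),
    row("gamblers", "R", "beta", 1.77, 1.02, 2.43),
    row("controls_fixed", "CS", "beta", 1.22, 0.62, 1.94),
    row("controls_adaptive", "CS", "beta", 2.16, 1.31, 3.64),
    row("gamblers", "CS", "beta", 1.86, 0.86, 2.69),
    # rate k / a
    row("controls_fixed", "H", "k", 0.0083, 0.0042, 0.0166),
    row("controls_adaptive", "H", "k", 0.0112, 0.0047, 0.0249),
    row("gamblers", "H", "k", 0.0463, 0.0125, 0.144),
    row("controls_fixed", "E", "k", 0.0055, 0.0032, 0.009),
    row("controls_adaptive", "E", "k", 0.0055, 0.0029, 0.0097),
    row("gamblers", "E", "k", 0.0314, 0.0073, 0.102),
    row("controls_fixed", "GM", "k", 0.0434, 0.0064, 0.0409),
    row("controls_adaptive", "GM", "k", 0.0991, 0.0087, 0.4231),
    row("gamblers", "GM", "k", 0.0778, 0.0047, 0.328),
    row("controls_fixed", "R", "k", 0.0366, 0.0068, 0.091),
    row("controls_adaptive", "R", "k", 0.0573, 0.01, 0.117),
    row("gamblers", "R", "k", 0.0749, 0.0097, 0.191),
    row("controls_fixed", "CS", "a", 0.0049, 0.0015, 0.0084),
    row("controls_adaptive", "CS", "a", 0.0067, 0.0028, 0.0162),
    row("gamblers", "CS", "a", 0.0287, 0.0068, 0.0592),
    # exponent s / b
    row("controls_fixed", "GM", "s", 0.403, 0.174, 0.895),
    row("controls_adaptive", "GM", "s", 0.543, 0.159, 1.03),
    row("gamblers", "GM", "s", 0.712, 0.26, 1.34),
    row("controls_fixed", "R", "s", 0.713, 0.429, 0.938),
    row("controls_adaptive", "R", "s", 0.751, 0.449, 1.03),
    row("gamblers", "R", "s", 0.752, 0.467, 0.998),
    row("controls_fixed", "CS", "b", 0.562, 0.348, 0.755),
    row("controls_adaptive", "CS", "b", 0.511, 0.357, 0.779),
    row("gamblers", "CS", "b", 0.681, 0.411, 0.899)
  ))
})

#' Population calibration presets for the synthetic generator
#'
#' Medians and inter-quartile ranges of the generating-parameter
#' populations, per preset (`"controls_fixed"`, `"controls_adaptive"`,
#' `"gamblers"`), model and parameter. Rates (`k`, `a`) and `beta` are drawn
#' log-normally with `meanlog = log(median)` and `sdlog` chosen so the
#' distribution's IQR ratio matches the preset; exponents (`s`, `b`) are
#' drawn from a normal with matching median and IQR, truncated to the model
#' bounds.
#'
#' @return A tibble with columns `preset`, `model_id`, `param`, `median`,
#'   `iqr_lo`, `iqr_hi`.
#' @export
population_presets <- function() tibble::as_tibble(.td_population)

.td_q75 <- stats::qnorm(0.75)

# Draw n parameter vectors (incl. beta) for one model from a preset.
# beta_meanlog/beta_sdlog override the preset's beta distribution (used for
# low-noise recovery cohorts).
.td_draw_params <- function(model_id, n, preset,
                            beta_meanlog = NULL, beta_sdlog = NULL) {
  spec <- .td_model(model_id)
  cal <- .td_population[.td_population$preset == preset &
                          .td_population$model_id == model_id, ]
  if (!nrow(cal)) stop("unknown preset: ", preset, call. = FALSE)
  draw1 <- function(param, lower, upper) {
    r <- cal[cal$param == param, ]
    if (param %in% c("k", "a", "beta")) {
      meanlog <- log(r$median)
      sdlog <- log(r$iqr_hi / r$iqr_lo) / (2 * .td_q75)
      if (param == "beta" && !is.null(beta_meanlog)) meanlog <- beta_meanlog
      if (param == "beta" && !is.null(beta_sdlog)) sdlog <- beta_sdlog
      x <- stats::rlnorm(n, meanlog, sdlog)
    } else {
      mu <- r$median
      sd <- (r$iqr_hi - r$iqr_lo) / (2 * .td_q75)
      x <- stats::rnorm(n, mu, sd)
      while (any(bad <- x < lower | x > upper)) {
        x[bad] <- stats::rnorm(sum(bad), mu, sd)
      }
    }
    pmin(pmax(x, lower), upper)
  }
  out <- matrix(NA_real_, n, spec$n_params + 1L,
                dimnames = list(NULL, c(spec$param_names, "beta")))
  for (p in spec$param_names) {
    out[, p] <- draw1(p, spec$lower[[p]], spec$upper[[p]])
  }
  out[, "beta"] <- draw1("beta", .td_beta_bounds[["lower"]],
                         .td_beta_bounds[["upper"]])
  out
}

#' Specify a simulated agent
#'
#' @param agent_id Identifier string.
#' @param model_id Generating discount model.
#' @param discount_params Named or positional discounting parameters.
#' @param beta Softmax stochasticity of the agent.
#' @param seed Optional per-agent seed (used by session runners).
#' @return An object of class `td_agent`.
#' @export
agent_spec <- function(agent_id, model_id, discount_params, beta, seed = NULL) {
  pv <- param_vector(model_id, discount_params, beta)
  structure(
    list(agent_id = as.character(agent_id), model_id = model_id,
         discount_params = pv$discount_params, beta = pv$beta, seed = seed),
    class = "td_agent"
  )
}

#' Simulate choices of an agent on offered trials
#'
#' Bernoulli draw from the agent's softmax choice probability for each
#' offer; consumes the current RNG stream (seed it with `set.seed()` or via
#' the session runners for reproducibility). In the `beta -> 0` limit the
#' agent deterministically chooses the option with the higher subjective
#' value.
#'
#' @param agent A `td_agent`.
#' @param amount_ss,amount_ll,delay_days Offer vectors (recycled).
#' @return Character vector of `"SS"`/`"LL"` choices.
#' @export
simulate_choice <- function(agent, amount_ss, amount_ll, delay_days) {
  stopifnot(inherits(agent, "td_agent"))
  sv_ll <- .td_sv(agent$model_id, agent$discount_params, amount_ll, delay_days)
  p <- choice_probability(amount_ss, sv_ll, agent$beta)
  n <- max(length(amount_ss), length(amount_ll), length(delay_days))
  ifelse(stats::runif(n) < p, "LL", "SS")
}

#' Run an adaptive adjusting-amount session for one agent
#'
#' Emulates the adjusting-amount titration task: at each delay the agent
#' repeatedly chooses between a fixed immediate 20 (euro) and a delayed
#' amount. After two successive choices of the delayed reward the delayed
#' amount is reduced; after two successive choices of the immediate reward
#' it is increased. The adjustment step starts at `start_step` and halves at
#' each direction reversal (floor `step_floor`). Delayed amounts never fall
#' below `min_amount` (20.5) and have no upper limit. The staircase for a
#' delay terminates as soon as the gap between the lowest accepted and
#' highest rejected delayed amount reaches that delay's criterion. An amount
#' counts as accepted (rejected) only when two successive choices of the
#' delayed (immediate) reward confirm it -- the same evidence that triggers
#' an adjustment -- so isolated inconsistent choices neither move nor
#' terminate the staircase; the immediate amount itself stands in as the
#' initial rejected delayed amount. Staircases not terminated within
#' `max_trials_per_delay` presentations are flagged.
#'
#' @param agent A `td_agent`.
#' @param delays Delays in days (default the seven-delay protocol
#'   1, 2, 7, 14, 30, 90, 180).
#' @param criteria Termination criterion in euros per delay (default
#'   1, 1.5, 2, 2, 3, 4, 4).
#' @param amount_ss Immediate amount (default 20).
#' @param start_amount Initial delayed amount (default 50).
#' @param start_step Initial adjustment step in euros (default 15).
#' @param step_floor Smallest step after halving (default 0.25).
#' @param min_amount Smallest offered delayed amount (default 20.5).
#' @param max_trials_per_delay Presentation cap per delay (default 100).
#' @param seed Session seed; per-delay substreams are derived from it.
#' @return An object of class `td_session`: `agent_id`, `amount_ss`,
#'   `trials` (tibble: `subject_id`, `amount_ss`, `amount_ll`, `delay_days`,
#'   `choice`), and `brackets` (tibble: `delay_days`, `lowest_accepted`,
#'   `highest_rejected`, `terminated`, `n_trials`).
#' @export
run_adaptive_session <- function(agent,
                                 delays = c(1, 2, 7, 14, 30, 90, 180),
                                 criteria = c(1, 1.5, 2, 2, 3, 4, 4),
                                 amount_ss = 20, start_amount = 50,
                                 start_step = 15, step_floor = 0.25,
                                 min_amount = 20.5,
                                 max_trials_per_delay = 100L,
                                 seed = NULL) {
  stopifnot(inherits(agent, "td_agent"))
  if (length(criteria) != length(delays)) {
    stop("criteria must align with delays", call. = FALSE)
  }
  if (is.null(seed)) seed <- agent$seed

  all_trials <- list()
  brackets <- list()
  for (d_idx in seq_along(delays)) {
    delay <- delays[d_idx]
    crit <- criteria[d_idx]
    res <- .td_with_seed(
      if (is.null(seed)) NULL else .td_derive_seed(seed, d_idx),
      .td_staircase_one_delay(agent, delay, crit, amount_ss, start_amount,
                              start_step, step_floor, min_amount,
                              max_trials_per_delay)
    )
    all_trials[[d_idx]] <- res$trials
    brackets[[d_idx]] <- res$bracket
  }
  trials <- do.call(rbind, all_trials)
  trials <- tibble::tibble(
    subject_id = agent$agent_id,
    amount_ss = amount_ss,
    amount_ll = trials$amount_ll,
    delay_days = trials$delay_days,
    choice = trials$choice
  )
  structure(
    list(agent_id = agent$agent_id, amount_ss = amount_ss,
         trials = trials, brackets = do.call(rbind, brackets)),
    class = "td_session"
  )
}

.td_staircase_one_delay <- function(agent, delay, criterion, amount_ss,
                                    start_amount, start_step, step_floor,
                                    min_amount, max_trials) {
  amount <- start_amount
  step <- start_step
  last_dir <- 0L
  run_choice <- NA_character_
  run_len <- 0L
  # an amount counts as accepted/rejected only when two successive choices
  # confirm it (the same rule that triggers an adjustment); the immediate
  # amount itself stands in as the initial rejected delayed amount
  lowest_acc <- Inf
  highest_rej <- amount_ss
  amounts <- numeric(0)
  choices <- character(0)
  terminated <- FALSE
  for (t in seq_len(max_trials)) {
    choice <- simulate_choice(agent, amount_ss, amount, delay)
    amounts[t] <- amount
    choices[t] <- choice
    if (identical(choice, run_choice)) run_len <- run_len + 1L
    else {
      run_choice <- choice
      run_len <- 1L
    }
    if (run_len == 2L) {
      dir <- if (choice == "LL") -1L else 1L
      if (dir == -1L) lowest_acc <- min(lowest_acc, amount)
      else highest_rej <- max(highest_rej, amount)
      if (is.finite(lowest_acc) && lowest_acc - highest_rej <= criterion) {
        terminated <- TRUE
        break
      }
      if (last_dir != 0L && dir != last_dir) step <- max(step / 2, step_floor)
      amount <- max(min_amount, amount + dir * step)
      last_dir <- dir
      run_len <- 0L
      run_choice <- NA_character_
    }
  }
  list(
    trials = data.frame(amount_ll = amounts, delay_days = delay,
                        choice = choices, stringsAsFactors = FALSE),
    bracket = tibble::tibble(
      delay_days = delay,
      lowest_accepted = if (is.finite(lowest_acc)) lowest_acc else NA_real_,
      highest_rejected = highest_rej,
      terminated = terminated,
      n_trials = length(amounts)
    )
  )
}

#' Generate a fixed-offer set around a hyperbolic indifference prediction
#'
#' Mirrors the pre-computed offer design: per delay, the hyperbolically
#' predicted indifference amount `A* = 20 (1 + k_hat D)` is clipped to
#' `[20.5, 80]`, then half the offers are drawn uniformly on `[20.5, A*]`
#' (below the predicted indifference) and half on `[A*, 80]` (above).
#' When clipping collapses an interval the corresponding offers equal the
#' bound and are flagged.
#'
#' @param k_hat Hyperbolic discount-rate estimate used to place the offers.
#' @param delays Delays in days (default 0.25, 1, 7, 30, 90, 180).
#' @param n_per_delay Even number of offers per delay (default 16).
#' @param amount_ss Immediate amount (default 20).
#' @param min_amount,max_amount Offer bounds (defaults 20.5 and 80).
#' @param seed Seed for the uniform draws.
#' @return Tibble with `delay_days`, `amount_ll`, `side`
#'   (`"below"`/`"above"` the predicted indifference), `clipped`.
#' @export
generate_fixed_offer_set <- function(k_hat,
                                     delays = c(0.25, 1, 7, 30, 90, 180),
                                     n_per_delay = 16L, amount_ss = 20,
                                     min_amount = 20.5, max_amount = 80,
                                     seed = NULL) {
  stopifnot(k_hat > 0, n_per_delay >= 2, n_per_delay %% 2 == 0)
  .td_with_seed(seed, {
    out <- lapply(delays, function(d) {
      a_star <- min(max(amount_ss * (1 + k_hat * d), min_amount), max_amount)
      nh <- n_per_delay / 2
      below <- stats::runif(nh, min_amount, a_star)
      above <- stats::runif(nh, a_star, max_amount)
      tibble::tibble(
        delay_days = d,
        amount_ll = c(below, above),
        side = rep(c("below", "above"), each = nh),
        clipped = c(rep(a_star <= min_amount, nh),
                    rep(a_star >= max_amount, nh))
      )
    })
    do.call(rbind, out)
  })
}

#' Run a fixed-offer session for one agent
#'
#' @param agent A `td_agent`.
#' @param offers Offer tibble from [generate_fixed_offer_set()].
#' @param amount_ss Immediate amount (default 20).
#' @param seed Seed for the choice draws.
#' @return Trials tibble (`subject_id`, `amount_ss`, `amount_ll`,
#'   `delay_days`, `choice`).
#' @export
run_fixed_offer_session <- function(agent, offers, amount_ss = 20,
                                    seed = NULL) {
  stopifnot(inherits(agent, "td_agent"))
  if (is.null(seed)) seed <- agent$seed
  choice <- .td_with_seed(seed,
    simulate_choice(agent, amount_ss, offers$amount_ll, offers$delay_days))
  tibble::tibble(
    subject_id = agent$agent_id,
    amount_ss = amount_ss,
    amount_ll = offers$amount_ll,
    delay_days = offers$delay_days,
    choice = choice
  )
}

#' Configuration of a synthetic cohort
#'
#' @param n_agents Number of simulated participants.
#' @param model_mix Generating model(s): a single model id, or a named
#'   probability vector over model ids (e.g. `c(H = 0.5, CS = 0.5)`).
#' @param design `"adaptive"` (adjusting-amount staircase) or
#'   `"fixed_offers"`.
#' @param preset Population preset name (see [population_presets()]).
#' @param delays,criteria Task protocol; defaults depend on `design`
#'   (seven delays with euro criteria for adaptive; six delays for fixed
#'   offers).
#' @param n_per_delay Offers per delay for the fixed-offer design.
#' @param beta_meanlog,beta_sdlog Optional overrides of the preset's
#'   log-normal `beta` distribution (e.g. for low-noise recovery cohorts).
#' @param seed Master seed; agent-level and session-level substreams are
#'   derived from it.
#' @return A list of class `td_cohort_config`.
#' @export
cohort_config <- function(n_agents, model_mix = "CS",
                          design = c("adaptive", "fixed_offers"),
                          preset = "controls_adaptive",
                          delays = NULL, criteria = NULL,
                          n_per_delay = 16L,
                          beta_meanlog = NULL, beta_sdlog = NULL,
                          seed = 1L) {
  design <- match.arg(design)
  stopifnot(n_agents >= 1)
  if (is.null(names(model_mix))) {
    if (length(model_mix) != 1L) {
      stop("model_mix must be one model id or a named probability vector",
           call. = FALSE)
    }
    model_mix <- stats::setNames(1, model_mix)
  }
  if (!all(names(model_mix) %in% model_ids()) || any(model_mix < 0) ||
      sum(model_mix) <= 0) {
    stop("invalid model_mix", call. = FALSE)
  }
  model_mix <- model_mix / sum(model_mix)
  if (!preset %in% unique(.td_population$preset)) {
    stop("unknown preset: ", preset, call. = FALSE)
  }
  if (is.null(delays)) {
    delays <- if (design == "adaptive") c(1, 2, 7, 14, 30, 90, 180)
              else c(0.25, 1, 7, 30, 90, 180)
  }
  if (design == "adaptive" && is.null(criteria)) {
    criteria <- if (identical(delays, c(1, 2, 7, 14, 30, 90, 180))) {
      c(1, 1.5, 2, 2, 3, 4, 4)
    } else {
      rep(2, length(delays))
    }
  }
  structure(
    list(n_agents = as.integer(n_agents), model_mix = model_mix,
         design = design, preset = preset, delays = delays,
         criteria = criteria, n_per_delay = as.integer(n_per_delay),
         beta_meanlog = beta_meanlog, beta_sdlog = beta_sdlog,
         seed = as.integer(seed)),
    class = "td_cohort_config"
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws each agent's generating model and parameters from the configured
#' population, runs the configured task design per agent (with seeds derived
#' deterministically from the master seed), and returns the pooled trials
#' together with a separate ground-truth table. Trials and truth are kept in
#' distinct components so generating parameters can never leak into fitting
#' inputs.
#'
#' For the fixed-offer design, each agent's offer set is placed around the
#' hyperbolic indifference prediction obtained by matching the agent's true
#' discount fraction at the 30-day delay (a deterministic stand-in for the
#' pre-task discount-rate estimate of the two-stage protocol).
#'
#' @param config A [cohort_config()].
#' @return An object of class `td_cohort`: `trials` (tibble over all
#'   agents), `truth` (tibble: `agent_id`, `model_id`, `k_a`, `s_b`,
#'   `beta`), `sessions` (list of `td_session`, adaptive design only),
#'   `config`.
#' @export
generate_cohort_dataset <- function(config) {
  stopifnot(inherits(config, "td_cohort_config"))
  n <- config$n_agents
  models <- .td_with_seed(.td_derive_seed(config$seed, 0L),
    sample(names(config$model_mix), n, replace = TRUE,
           prob = config$model_mix))
  # parameter draws per model, under one derived substream
  params <- vector("list", n)
  .td_with_seed(.td_derive_seed(config$seed, 1L), {
    for (m in unique(models)) {
      idx <- which(models == m)
      draws <- .td_draw_params(m, length(idx), config$preset,
                               config$beta_meanlog, config$beta_sdlog)
      for (j in seq_along(idx)) params[[idx[j]]] <- draws[j, ]
    }
  })

  trials <- vector("list", n)
  sessions <- if (config$design == "adaptive") vector("list", n) else NULL
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("agent%03d", i)
    par <- params[[i]]
    m <- models[i]
    np <- .td_model(m)$n_params
    agent <- agent_spec(id, m, par[seq_len(np)], par[["beta"]],
                        seed = .td_derive_seed(config$seed, 100L + i))
    if (config$design == "adaptive") {
      ses <- run_adaptive_session(agent, delays = config$delays,
                                  criteria = config$criteria)
      sessions[[i]] <- ses
      trials[[i]] <- ses$trials
    } else {
      fr30 <- .td_fraction(m, agent$discount_params, 30)
      k_hat <- max((1 / fr30 - 1) / 30, 1e-4)
      offers <- generate_fixed_offer_set(
        k_hat, delays = config$delays, n_per_delay = config$n_per_delay,
        seed = .td_derive_seed(agent$seed, 1L))
      trials[[i]] <- run_fixed_offer_session(
        agent, offers, seed = .td_derive_seed(agent$seed, 2L))
    }
    truth[[i]] <- tibble::tibble(
      agent_id = id, model_id = m,
      k_a = par[[1L]],
      s_b = if (np > 1L) par[[2L]] else NA_real_,
      beta = par[["beta"]]
    )
  }
  structure(
    list(trials = do.call(rbind, trials), truth = do.call(rbind, truth),
         sessions = sessions, config = config),
    class = "td_cohort"
  )
}

#' @export
print.td_cohort <- function(x, ...) {
  cat("<td_cohort> ", x$config$n_agents, " agents, design ",
      x$config$design, ", ", nrow(x$trials), " trials\n", sep = "")
  cat("generating models:\n")
  print(table(x$truth$model_id))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Trials and ground truth go to separate files so the truth can never be
#' read back as fitting input by accident.
#'
#' @param cohort A `td_cohort`.
#' @param dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "td_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trials_path <- file.path(dir, "trials.csv")
  truth_path <- file.path(dir, "ground_truth.csv")
  write_trials(cohort$trials, trials_path)
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(c(trials = trials_path, truth = truth_path))
}
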