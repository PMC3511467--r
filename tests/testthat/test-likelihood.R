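test_that("softmax choice probabilities match the logistic closed form", {
  expect_equal(choice_probability(20, 20, 1.5), 0.5)
  # value edge of beta*log(3) forces p = 0.75 under the temperature form
  for (beta in c(0.3, 1, 4)) {
    expect_equal(choice_probability(20, 20 + beta * log(3), beta), 0.75,
                 tolerance = 1e-12)
  }
  expect_equal(choice_probability(20, 30, 1), 1 / (1 + exp(-10)),
               tolerance = 1e-12)
  # complementarity of the two options
  p <- choice_probability(18, 26, 2.2)
  expect_equal(p + choice_probability(26, 18, 2.2), 1)
  # monotone in the value difference
  dv <- seq(-10, 10, by = 0.5)
  expect_true(all(diff(choice_probability(20, 20 + dv, 1.7)) > 0))
  # temperature convention: towards 0.5 as beta grows
  expect_equal(choice_probability(20, 30, 1e6), 0.5, tolerance = 1e-4)
  expect_error(choice_probability(20, 30, 0), "beta")
  expect_error(choice_probability(20, 30, -2), "beta")
})

test_that("inverse convention multiplies instead of divides", {
  expect_equal(choice_probability(20, 24, 0.5, beta_convention = "inverse"),
               stats::plogis(2))
  expect_equal(choice_probability(20, 24, 2), stats::plogis(2))
})

test_that("dataset log-likelihood sums per-trial log choice probabilities", {
  # trials engineered so the delayed value equals the immediate value: p = 0.5
  k <- 0.02
  delays <- rep(c(7, 30), 5)
  trials <- tibble::tibble(
    subject_id = "s", amount_ss = 20, amount_ll = 20 * (1 + k * delays),
    delay_days = delays, choice = rep(c("LL", "SS"), 5)
  )
  ll <- dataset_log_likelihood(trials, param_vector("H", k, 1.3))
  expect_equal(ll$loglik, 10 * log(0.5), tolerance = 1e-12)
  expect_equal(ll$n_trials, 10L)

  # hand-summed oracle over three printed trials under (H, k = 0.01, beta = 2)
  toy <- tibble::tibble(
    subject_id = "s", amount_ss = 20,
    amount_ll = c(30, 50, 70), delay_days = c(7, 30, 180),
    choice = c("LL", "LL", "SS")
  )
  sv <- c(30 / (1 + 0.01 * 7), 50 / (1 + 0.01 * 30), 70 / (1 + 0.01 * 180))
  p_ll <- 1 / (1 + exp(-(sv - 20) / 2))
  oracle <- log(p_ll[1]) + log(p_ll[2]) + log(1 - p_ll[3])
  expect_equal(dataset_log_likelihood(toy, param_vector("H", 0.01, 2))$loglik,
               oracle, tolerance = 1e-12)
})

test_that("log-likelihood is permutation invariant and floor-bounded", {
  trials <- make_toy_trials(n = 40, seed = 7)
  pv <- param_vector("H", 0.02, 1.5)
  ll <- dataset_log_likelihood(trials, pv)$loglik
  perm <- trials[sample(nrow(trials)), ]
  expect_equal(dataset_log_likelihood(perm, pv)$loglik, ll)
  expect_lte(ll, 0)
  # near-deterministic mispredicted subject hits the probability floor,
  # not -Inf
  bad <- tibble::tibble(subject_id = "s", amount_ss = 20, amount_ll = 80,
                        delay_days = 1, choice = "SS")
  llb <- dataset_log_likelihood(bad, param_vector("H", 1e-6, 1e-4))$loglik
  expect_true(is.finite(llb))
  expect_gte(llb, log(1e-12))
})

test_that("a perfectly consistent subject gains likelihood as beta shrinks", {
  # all choices follow the sign of the value difference
  agent <- agent_spec("c", "H", 0.02, 1e-6)
  delays <- rep(c(1, 7, 30, 90, 180), each = 4)
  amounts <- rep(c(22, 30, 45, 70), 5)
  choice <- simulate_choice(agent, 20, amounts, delays)
  trials <- tibble::tibble(subject_id = "c", amount_ss = 20,
                           amount_ll = amounts, delay_days = delays,
                           choice = choice)
  betas <- c(8, 4, 2, 1, 0.5, 0.25)
  lls <- vapply(betas, function(b) {
    dataset_log_likelihood(trials, param_vector("H", 0.02, b))$loglik
  }, 0)
  expect_true(all(diff(lls) > 0))
})

test_that("empty or malformed trial tables are rejected", {
  empty <- tibble::tibble(subject_id = character(), amount_ss = numeric(),
                          amount_ll = numeric(), delay_days = numeric(),
                          choice = character())
  expect_error(dataset_log_likelihood(empty, param_vector("H", 0.02, 1)),
               "empty")
  bad <- tibble::tibble(amount_ss = 20, amount_ll = 30, delay_days = 7,
                        choice = "yes")
  expect_error(dataset_log_likelihood(bad, param_vector("H", 0.02, 1)),
               "choice")
})
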