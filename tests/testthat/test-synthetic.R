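test_that("choices at the exact indifference point are a fair coin", {
  agent <- agent_spec("a", "H", 0.02, 1.5)
  a_star <- 20 * (1 + 0.02 * 30)  # delayed value equals immediate 20
  set.seed(8)
  choices <- simulate_choice(agent, 20, rep(a_star, 1e4), 30)
  rate <- mean(choices == "LL")
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("the beta -> 0 limit is a deterministic value maximizer", {
  agent <- agent_spec("d", "H", 0.02, 1e-6)
  set.seed(1)
  above <- simulate_choice(agent, 20, rep(40, 50), 30)   # SV = 25 > 20
  below <- simulate_choice(agent, 20, rep(25, 50), 30)   # SV = 15.6 < 20
  expect_true(all(above == "LL"))
  expect_true(all(below == "SS"))
})

test_that("an empirical choice curve recovers the generating beta", {
  beta_true <- 2
  agent <- agent_spec("b", "H", 0.01, beta_true)
  set.seed(33)
  delays <- sample(c(1, 7, 30, 90, 180), 500, replace = TRUE)
  amounts <- runif(500, 20.5, 80)
  sv <- subjective_value("H", 0.01, amounts, delays)
  choice <- simulate_choice(agent, 20, amounts, delays)
  # logistic refit of choice on the value difference: slope estimates 1/beta
  g <- stats::glm(I(choice == "LL") ~ I(sv - 20), family = binomial())
  beta_hat <- 1 / unname(stats::coef(g)[2])
  expect_lt(abs(beta_hat - beta_true) / beta_true, 0.2)
})

test_that("the adaptive staircase honors the task's offer constraints", {
  agent <- agent_spec("s", "CS", c(0.008, 0.6), 2, seed = 13)
  ses <- run_adaptive_session(agent, seed = 13)
  expect_true(all(ses$trials$amount_ss == 20))
  expect_true(all(ses$trials$amount_ll >= 20.5))
  expect_equal(sort(unique(ses$trials$delay_days)),
               c(1, 2, 7, 14, 30, 90, 180))
  crit <- c(1, 1.5, 2, 2, 3, 4, 4)
  br <- ses$brackets
  done <- br$terminated
  expect_true(any(done))
  expect_true(all((br$lowest_accepted - br$highest_rejected)[done] <=
                    crit[done] + 1e-9))
  expect_true(all(br$n_trials <= 100))
})

test_that("a noiseless exponential agent titrates to the closed-form point", {
  agent <- agent_spec("e", "E", 0.01, 1e-6, seed = 3)
  ses <- run_adaptive_session(agent, delays = 90, criteria = 4, seed = 3)
  ip <- staircase_indifference(ses)
  expect_lt(abs(ip$indifference_amount - 20 * exp(0.9)), 4)
})

test_that("fixed offers straddle the predicted indifference and stay bounded", {
  # far-delay prediction gets clipped to the 80-euro cap
  off <- generate_fixed_offer_set(0.05, delays = 180, n_per_delay = 10,
                                  seed = 1)
  expect_true(all(off$amount_ll[off$side == "above"] == 80))
  expect_true(all(off$clipped[off$side == "above"]))
  # unclipped case splits 50/50 around A* = 26
  off2 <- generate_fixed_offer_set(0.01, delays = 30, n_per_delay = 12,
                                   seed = 2)
  expect_equal(sum(off2$amount_ll < 26), 6L)
  expect_equal(sum(off2$amount_ll > 26), 6L)
  expect_false(any(off2$clipped))
  off3 <- generate_fixed_offer_set(0.02, n_per_delay = 8, seed = 3)
  expect_true(all(off3$amount_ll >= 20.5 & off3$amount_ll <= 80))
  expect_equal(nrow(off3), 6 * 8)
  expect_error(generate_fixed_offer_set(0.02, n_per_delay = 7), "2 == 0")
})

test_that("cohort generation is reproducible with separated ground truth", {
  cfg <- cohort_config(8, model_mix = c(H = 0.5, CS = 0.5),
                       design = "adaptive", seed = 17)
  coh1 <- generate_cohort_dataset(cfg)
  coh2 <- generate_cohort_dataset(cfg)
  expect_identical(coh1$trials, coh2$trials)
  expect_identical(coh1$truth, coh2$truth)
  expect_equal(length(unique(coh1$trials$subject_id)), 8L)
  expect_equal(nrow(coh1$truth), 8L)
  # every agent worked through all seven delay blocks
  blocks <- tapply(coh1$trials$delay_days, coh1$trials$subject_id,
                   function(d) length(unique(d)))
  expect_true(all(blocks == 7))
  # the trial table carries no generating-parameter columns
  expect_false(any(c("k_a", "s_b", "beta", "model_id") %in%
                     names(coh1$trials)))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh1, dir)
  expect_identical(read_trials(paths[["trials"]])$choice,
                   coh1$trials$choice)
})

test_that("fixed-offer cohorts have the expected shape", {
  cfg <- cohort_config(5, model_mix = "H", design = "fixed_offers",
                       preset = "controls_fixed", n_per_delay = 8, seed = 23)
  coh <- generate_cohort_dataset(cfg)
  expect_equal(nrow(coh$trials), 5 * 6 * 8)
  expect_true(0.25 %in% coh$trials$delay_days)
  expect_true(all(coh$trials$amount_ll >= 20.5 &
                    coh$trials$amount_ll <= 80))
})

test_that("population draws match their preset medians", {
  pres <- population_presets()
  expect_true(all(c("controls_fixed", "controls_adaptive", "gamblers") %in%
                    pres$preset))
  draw <- tempodisc:::.td_draw_params("H", 4000, "controls_fixed")
  expect_lt(abs(median(draw[, "k"]) / 0.0083 - 1), 0.1)
  expect_lt(abs(median(draw[, "beta"]) / 2.16 - 1), 0.1)
  drawg <- tempodisc:::.td_draw_params("H", 4000, "gamblers")
  expect_lt(abs(median(drawg[, "k"]) / 0.0463 - 1), 0.1)
  # gamblers are steeper discounters than controls
  expect_gt(median(drawg[, "k"]), median(draw[, "k"]))
  drawcs <- tempodisc:::.td_draw_params("CS", 2000, "controls_adaptive")
  expect_true(all(drawcs[, "b"] >= 0.01 & drawcs[, "b"] <= 20))
  expect_lt(abs(median(drawcs[, "a"]) / 0.0067 - 1), 0.15)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(0, "H"), "n_agents")
  expect_error(cohort_config(5, "XX"), "model_mix")
  expect_error(cohort_config(5, c(0.5, 0.5)), "model_mix")
  expect_error(cohort_config(5, "H", preset = "nope"), "preset")
  expect_error(agent_spec("a", "H", -0.1, 1), "positive")
})
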