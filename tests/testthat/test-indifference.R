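fake_session <- function(lowest_accepted, highest_rejected, delay = 30,
                         terminated = TRUE, amount_ss = 20) {
  structure(
    list(agent_id = "s", amount_ss = amount_ss, trials = NULL,
         brackets = tibble::tibble(
           delay_days = delay, lowest_accepted = lowest_accepted,
           highest_rejected = highest_rejected, terminated = terminated,
           n_trials = 10L)),
    class = "td_session"
  )
}

test_that("indifference amount is the terminal bracket midpoint", {
  ip <- staircase_indifference(fake_session(41, 38))
  expect_equal(ip$indifference_amount, 39.5)
  # fraction of 20 over an indifference amount of 40 is one half
  ip2 <- staircase_indifference(fake_session(42, 38))
  expect_equal(ip2$fraction, 0.5)
  # non-terminated staircases yield flagged missing points
  ip3 <- staircase_indifference(fake_session(41, 38, terminated = FALSE))
  expect_true(is.na(ip3$indifference_amount))
  expect_false(ip3$terminated)
})

test_that("a near-deterministic hyperbolic agent titrates to its true point", {
  agent <- agent_spec("det", "H", 0.02, 1e-6, seed = 2)
  ses <- run_adaptive_session(agent, delays = 30, criteria = 3, seed = 2)
  ip <- staircase_indifference(ses)
  expect_true(ip$terminated)
  # true indifference at 30 d: 20 * (1 + 0.6) = 32, recovered within half
  # the 3-euro criterion
  expect_lt(abs(ip$indifference_amount - 32), 1.5)
})

test_that("noiseless fractions are recovered exactly by the curve fit", {
  delays <- c(1, 2, 7, 14, 30, 90, 180)
  pts <- tibble::tibble(delay_days = delays,
                        fraction = 1 / (1 + 0.01 * delays))
  fit <- fit_indifference_curve(pts, "H", seed = 1)
  expect_equal(fit$params[["k"]], 0.01, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # dual-parameter nesting: GM and R contain H as the s = 1 special case
  for (m in c("GM", "R")) {
    fit2 <- fit_indifference_curve(pts, m, seed = 1)
    expect_gte(fit2$r_squared, fit$r_squared - 1e-9)
  }
  # and CS contains E: noiseless exponential fractions, same check
  ptsE <- tibble::tibble(delay_days = delays,
                         fraction = exp(-0.01 * delays))
  fitE <- fit_indifference_curve(ptsE, "E", seed = 1)
  fitCS <- fit_indifference_curve(ptsE, "CS", seed = 1)
  expect_gte(fitCS$r_squared, fitE$r_squared - 1e-9)
  expect_equal(fitE$params[["k"]], 0.01, tolerance = 1e-6)
})

test_that("R-squared matches its definitional oracle on noisy data", {
  delays <- c(1, 2, 7, 14, 30, 90, 180)
  set.seed(5)
  pts <- tibble::tibble(
    delay_days = delays,
    fraction = pmin(pmax(1 / (1 + 0.02 * delays) + rnorm(7, sd = 0.05),
                         0.01), 1)
  )
  fit <- fit_indifference_curve(pts, "H", seed = 1)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((pts$fraction - mean(pts$fraction))^2)
  expect_equal(fit$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-12)
  expect_lte(fit$r_squared, 1)
})

test_that("R-squared goes negative for data flatter than their mean", {
  # fractions nearly constant: any discounting curve fits worse than the mean
  pts <- tibble::tibble(delay_days = c(1, 7, 30, 90, 180),
                        fraction = c(0.52, 0.50, 0.51, 0.50, 0.52))
  fit <- fit_indifference_curve(pts, "E", seed = 1)
  expect_lt(fit$r_squared, 0)
})

test_that("fractions can be derived from indifference amounts", {
  pts <- tibble::tibble(delay_days = c(7, 30, 90),
                        indifference_amount = c(25, 32, 50),
                        amount_ss = 20)
  fit <- fit_indifference_curve(pts, "H", seed = 1)
  expect_s3_class(fit, "td_curvefit")
  expect_error(fit_indifference_curve(
    tibble::tibble(delay_days = 7, fraction = 0.5), "GM"), "at least")
})

test_that("group medians use the shared grid and the even-count convention", {
  pts <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 2),
    delay_days = rep(c(7, 30), 3),
    fraction = c(0.2, 0.1, 0.5, 0.3, 0.8, 0.7)
  )
  med <- group_median_points(pts)
  expect_equal(med$fraction[med$delay_days == 7], 0.5)
  expect_equal(med$n_subjects, c(3L, 3L))
  # even count: mean of the central pair
  pts4 <- tibble::tibble(subject_id = letters[1:4], delay_days = 7,
                         fraction = c(0.1, 0.4, 0.6, 0.9))
  expect_equal(group_median_points(pts4)$fraction, 0.5)
  # mixed grids must be split by the caller
  mixed <- rbind(pts,
                 tibble::tibble(subject_id = "d", delay_days = 90,
                                fraction = 0.4))
  expect_error(group_median_points(mixed), "grids")
})
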