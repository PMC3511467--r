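test_that("information criteria follow their definitions", {
  expect_equal(aic(-6.9315, 3), 19.863)
  expect_equal(aic(0, 2), 4)
  # penalty trade-off: one extra parameter offsets one log-likelihood unit
  expect_equal(aic(-100, 3), aic(-99, 4))
  expect_equal(bic(-6.9315, 3, 100), 13.863 + 3 * log(100))
  expect_equal(bic(-5, 3, 1), 10)
  # BIC penalty exceeds AIC's once ln(n) > 2
  expect_gt(bic(-5, 3, 8), aic(-5, 3))
  expect_lt(bic(-5, 3, 7), aic(-5, 3))
})

make_scores <- function(m, kind = "AIC") {
  attr(m, "score_kind") <- kind
  m
}

test_that("delta scores are min-centered per subject and on group sums", {
  m <- make_scores(matrix(c(10, 12, 15,
                            20, 18, 21,
                            30, 33, 29), nrow = 3, byrow = TRUE,
                          dimnames = list(paste0("s", 1:3),
                                          c("H", "GM", "CS"))))
  d <- delta_scores(m)
  expect_equal(unname(d$delta["s1", ]), c(0, 2, 5))
  expect_equal(unname(apply(d$delta, 1, min)), c(0, 0, 0))
  # group delta works on column sums, not on summed per-subject deltas
  sums <- colSums(m)
  expect_equal(d$group_delta, sums - min(sums))
  expect_false(isTRUE(all.equal(unname(d$group_delta),
                                unname(colSums(d$delta)))))
  expect_equal(unname(d$winner), c("H", "GM", "CS"))
})

test_that("winner ties break toward parsimony, then canonical order", {
  m <- make_scores(matrix(c(5, 5, 5, 5, 5), nrow = 1,
                          dimnames = list("s1", model_ids())))
  d <- delta_scores(m)
  expect_true(all(d$delta == 0))
  expect_equal(unname(d$winner), "H")
  # among equally scoring dual-parameter models, GM precedes R and CS
  m2 <- make_scores(matrix(c(9, 8, 7, 7, 7), nrow = 1,
                           dimnames = list("s1", model_ids())))
  expect_equal(unname(delta_scores(m2)$winner), "GM")
})

test_that("winner frequencies are proportions summing to one", {
  m <- make_scores(matrix(c(1, 2, 2, 1, 3, 1), nrow = 3, byrow = TRUE,
                          dimnames = list(paste0("s", 1:3), c("H", "CS"))))
  d <- delta_scores(m)
  wf <- winner_frequencies(d)
  expect_equal(sum(wf), 1)
  expect_equal(unname(wf["CS"]), 2 / 3)
  # single subject: an indicator vector
  m1 <- make_scores(matrix(c(4, 2), nrow = 1,
                           dimnames = list("s", c("H", "CS"))))
  expect_equal(unname(winner_frequencies(delta_scores(m1))), c(0, 1))
  # invariant to subject ordering
  d_perm <- delta_scores(make_scores(m[c(3, 1, 2), , drop = FALSE]))
  expect_equal(winner_frequencies(d_perm), wf)
})

test_that("per-subject delta is invariant to per-subject score shifts", {
  m <- make_scores(matrix(runif(15, 10, 40), nrow = 5,
                          dimnames = list(paste0("s", 1:5),
                                          c("H", "GM", "CS"))))
  shifted <- make_scores(m + matrix(rep(c(3, -8, 0, 12, 5), 3), nrow = 5))
  expect_equal(delta_scores(shifted)$delta, delta_scores(m)$delta)
})

test_that("missing score cells are an error", {
  m <- make_scores(matrix(c(1, NA, 2, 3), nrow = 2,
                          dimnames = list(c("a", "b"), c("H", "E"))))
  expect_error(delta_scores(m), "missing")
})

test_that("pairwise signed-rank tests behave at the extremes", {
  base <- matrix(rexp(40, 0.1), nrow = 20)
  m <- make_scores(cbind(A = base[, 1], B = base[, 1], C = base[, 1] + 5))
  rownames(m) <- paste0("s", 1:20)
  d <- delta_scores(m)
  expect_warning(p <- pairwise_wilcoxon(d), "zero")
  expect_equal(p["A", "B"], 1)
  # uniform 5-point advantage across 20 subjects: one-signed ranks
  expect_lt(p["A", "C"], 0.001)
  # symmetric matrix, empty diagonal
  expect_equal(p, t(p))
  expect_true(all(is.na(diag(p))))
})

test_that("rank-sum option and Holm correction are available", {
  set.seed(1)
  m <- make_scores(cbind(A = rexp(12), B = rexp(12) + 2, C = rexp(12) + 4))
  rownames(m) <- paste0("s", 1:12)
  d <- delta_scores(m)
  p_sr <- pairwise_wilcoxon(d)
  p_rs <- pairwise_wilcoxon(d, method = "rank_sum")
  expect_true(all(p_rs[upper.tri(p_rs)] <= 1 & p_rs[upper.tri(p_rs)] >= 0))
  p_holm <- pairwise_wilcoxon(d, p_adjust = "holm")
  expect_true(all(p_holm[upper.tri(p_holm)] >= p_sr[upper.tri(p_sr)] - 1e-12))
})

test_that("few subjects triggers a warning", {
  m <- make_scores(matrix(c(1, 2, 3, 4), nrow = 2,
                          dimnames = list(c("a", "b"), c("H", "E"))))
  expect_warning(pairwise_wilcoxon(delta_scores(m)), "6 subjects")
})

test_that("score tables and the tidy summary round through fit_cohort", {
  trials <- rbind(
    make_toy_trials(n = 20, subject_id = "s1", seed = 1),
    make_toy_trials(n = 20, subject_id = "s2", seed = 2)
  )
  fits <- fit_cohort(trials, models = c("H", "E"), n_starts = 4, seed = 5)
  sc <- score_table(fits, "AIC")
  expect_equal(dim(sc), c(2L, 2L))
  expect_equal(sc["s1", "H"], fits$aic[fits$subject_id == "s1" &
                                         fits$model_id == "H"])
  scb <- score_table(fits, "BIC")
  expect_true(all(scb > sc))  # 20 trials > 7
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_fit_summary(fits, path)
  re <- utils::read.csv(path)
  expect_equal(nrow(re), 4L)
  expect_true(all(c("delta_score", "winner") %in% names(re)))
  expect_equal(min(re$delta_score[re$subject_id == "s1"]), 0)
})
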