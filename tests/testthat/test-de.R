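test_that("weighted concatenation scales blocks and keeps widths", {
  ft <- gen_multiview_dataset(n = 10L, blocks = c(A = 3L, B = 2L),
                              informative = list(), seed = 1)
  same <- weighted_concat(ft, c(1, 1))
  expect_equal(same$matrix, ft$matrix)

  zeroed <- weighted_concat(ft, c(0, 1))
  expect_true(all(zeroed$matrix[, 1:3] == 0))
  expect_equal(zeroed$matrix[, 4:5], ft$matrix[, 4:5])
  expect_equal(ncol(zeroed$matrix), 5L)

  expect_error(weighted_concat(ft, c(1, 2, 3)), "weights")
})

test_that("the four default view widths integrate to 1899 features", {
  ft <- gen_multiview_dataset(
    n = 8L,
    blocks = c(ESM = 1280L, `PSSM-CLBP` = 236L, QLC = 147L,
               `RECM-CLBP` = 236L),
    informative = list(ESM = 1:2), seed = 2)
  wt <- weighted_concat(ft, c(-1.1776, 1, 1.1734, 0.1735))
  expect_equal(ncol(wt$matrix), 1899L)
  expect_identical(names(wt$blocks),
                   c("ESM", "PSSM-CLBP", "QLC", "RECM-CLBP"))
})

test_that("degenerate DE operators only change the forced coordinate", {
  # F = 0, CR = 0: the trial equals the target except at k_rand, where it
  # copies a population member's coordinate
  seen <- new.env(); seen$w <- list()
  fitness <- function(w) { seen$w[[length(seen$w) + 1L]] <- w; -sum(w^2) }
  cfg <- de_config(N = 6L, G_max = 3L, CR = 0, F = 1e-12, seed = 9L)
  res <- de_optimize(fitness, cfg)
  expect_length(res$w_best, 4L)
  # every evaluated candidate stays in bounds
  all_w <- do.call(rbind, seen$w)
  expect_true(all(all_w >= -2 & all_w <= 2))
})

test_that("DE recovers the optimum of a separable quadratic", {
  res <- de_optimize(function(w) -sum((w - 0.5)^2), de_config(seed = 42L))
  expect_lt(max(abs(res$w_best - 0.5)), 0.01)
  expect_equal(res$evaluations, 100L + 100L * 50L)
})

test_that("best-fitness traces never decrease and runs are reproducible", {
  for (seed in 1:10) {
    res <- de_optimize(function(w) sum(sin(3 * w)) - sum(w^2) / 4,
                       de_config(N = 12L, G_max = 10L, seed = seed))
    expect_true(all(diff(res$trace) >= 0))
  }
  a <- de_optimize(function(w) -sum(abs(w - 0.2)), de_config(N = 10L, G_max = 5L, seed = 3L))
  b <- de_optimize(function(w) -sum(abs(w - 0.2)), de_config(N = 10L, G_max = 5L, seed = 3L))
  expect_identical(a$w_best, b$w_best)
  expect_identical(a$trace, b$trace)
})

test_that("DE rejects invalid configurations and non-finite fitness", {
  expect_error(de_config(N = 3L), "N >= 4")
  expect_error(de_optimize(function(w) NA_real_, de_config(N = 5L, G_max = 1L)),
               "non-finite")
})

test_that("cv fitness separates, nulls out, and is deterministic", {
  sep <- gen_multiview_dataset(n = 60L, blocks = c(SIG = 6L, NOISE = 6L),
                               informative = list(SIG = 1:6), shift = 6,
                               seed = 11)
  expect_equal(cv_mcc_fitness(sep, c(1, 0.3), seed = 2L), 1.0)

  f1 <- cv_mcc_fitness(sep, c(0.8, -0.4), seed = 5L)
  f2 <- cv_mcc_fitness(sep, c(0.8, -0.4), seed = 5L)
  expect_identical(f1, f2)

  # permutation null: shuffled labels give |MCC| near zero
  mccs <- vapply(1:5, function(i) {
    shuf <- sep
    set.seed(i - 1)
    shuf$labels <- sample(sep$labels)
    cv_mcc_fitness(shuf, c(1, 1), seed = 1L)
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("learned weights favor the signal-carrying view", {
  wins <- 0L
  for (seed in 1:10) {
    ft <- gen_multiview_dataset(n = 50L, blocks = c(SIG = 5L, NOISE = 5L),
                                informative = list(SIG = 1:3), shift = 1.5,
                                seed = 100 + seed)
    res <- de_integrate(ft, de_config(N = 8L, G_max = 8L, seed = seed))
    w <- abs(res$w)
    if (w[1] >= w[2]) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
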