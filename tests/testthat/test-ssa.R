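test_that("pure-birth chain reproduces the analytic means", {
  # k = 1: ensemble mean within 3 SE of exp(t/C)
  es <- ensemble_summary(erlang_params(1, 0.1), reps = 10000,
                         record_times = c(10, 30), seed = 101)
  se <- sqrt(es$var_total / attr(es, "reps"))
  expect_true(all(abs(es$mean_total - exp(c(1, 3))) < 3 * se))

  # k = 4: per-stage ensemble means against the series solution. 12 z-scores
  # are checked at once, so bound max |z| at 4 (Bonferroni family error
  # ~8e-4) rather than 3 per comparison (~3% family error).
  es4 <- ensemble_summary(erlang_params(4, 0.4), reps = 10000,
                          record_times = c(5, 10, 20), seed = 102)
  sm <- attr(es4, "stage_mean")
  sv <- attr(es4, "stage_var")
  for (j in 1:4) {
    exact <- exact_stage_mean(c(5, 10, 20), j, 4, 10)
    expect_true(all(abs(sm[, j] - exact) < 4 * sqrt(sv[, j] / 10000)))
  }
  # and the total against the closed form at the spec'd 3 SE
  exact_tot <- exact_total_mean(c(5, 10, 20), 4, 10)
  expect_true(all(abs(es4$mean_total - exact_tot) <
                    3 * sqrt(es4$var_total / 10000)))
})

test_that("first division time is distributed as the CCTD", {
  fd <- first_division_times(erlang_params(4, 0.4), reps = 10000,
                             t_end = 200, seed = 103)
  expect_true(all(is.finite(fd)))
  ks <- suppressWarnings(ks.test(fd, function(q) pgamma(q, 4, 0.4)))
  expect_gt(ks$p.value, 0.01)

  # EME chain: first division follows the convolved distribution; check the
  # sample mean against k/lam1 + 1/lam2
  fde <- first_division_times(eme_params(3, 0.5, 0.05), reps = 5000,
                              t_end = 500, seed = 104)
  expect_lt(abs(mean(fde) - (3 / 0.5 + 1 / 0.05)),
            3 * sd(fde) / sqrt(5000))
})

test_that("trajectories are reproducible, non-decreasing and conservative", {
  p <- erlang_params(3, 0.3)
  t1 <- simulate_chain(p, record_times = 1:20, seed = 7)
  t2 <- simulate_chain(p, record_times = 1:20, seed = 7)
  expect_identical(t1, t2)
  t3 <- simulate_chain(p, record_times = 1:20, seed = 8)
  expect_false(identical(t1, t3))

  # pure-birth totals never decrease
  expect_true(all(diff(t1$total) >= 0))
  # stage counts match the recorded total
  stages <- as.matrix(t1[paste0("stage_", 1:3)])
  expect_equal(rowSums(stages), t1$total)

  expect_error(simulate_chain(p, record_times = 1:3, x0 = c(0, 0, 0)),
               "at least one cell")
  expect_error(simulate_chain(p, record_times = c(2, 1)), "increasing")
})

test_that("division process with trivial fate tables reduces correctly", {
  p <- erlang_params(2, 0.4)
  # fate 2x stage-1 w.p. 1 == plain chain (same seed, same trajectory)
  f2 <- tibble::tibble(prob = 1, stage1 = 2L, progenitors = 0L)
  a <- simulate_chain(p, record_times = 1:20, seed = 31)
  b <- simulate_division_process(p, f2, record_times = 1:20, seed = 31)
  expect_equal(a$total, b$total)

  # asymmetric-only fate: total stem count pinned at 1 in every realization
  f1 <- tibble::tibble(prob = 1, stage1 = 1L, progenitors = 1L)
  for (s in 1:5) {
    tr <- simulate_division_process(p, f1, record_times = seq(5, 50, 5),
                                    seed = s)
    expect_true(all(tr$total == 1))
    expect_true(all(diff(tr$progenitors) >= 0))
  }

  # pure-extinction fate: dies after exactly one CCT, distributed as the CCTD
  f0 <- tibble::tibble(prob = 1, stage1 = 0L, progenitors = 0L)
  es <- ensemble_summary(p, reps = 5000, record_times = 100, fates = f0,
                         seed = 32)
  ext <- attr(es, "first_division_times")
  ks <- suppressWarnings(ks.test(ext, function(q) pgamma(q, 2, 0.4)))
  expect_gt(ks$p.value, 0.01)
  expect_equal(unname(es$mean_total), 0, tolerance = 1e-12)

  expect_error(
    simulate_division_process(p, tibble::tibble(prob = c(0.5, 0.4),
                                                stage1 = c(2L, 0L),
                                                progenitors = c(0L, 0L)),
                              record_times = 1:3),
    "sum to 1")
})

test_that("ensemble summaries: variance, dispersion and first passage", {
  es <- ensemble_summary(erlang_params(1, 0.1), reps = 10000,
                         record_times = c(10, 20, 30), threshold = 5,
                         seed = 105)
  # Yule process: variance exp(2t/C) - exp(t/C), checked within 3 SE
  tot30 <- attr(es, "totals")[, 3]
  expect_lt(abs(var(tot30) - (exp(6) - exp(3))), 3 * se_of_variance(tot30))
  # super-Poissonian dispersion
  expect_true(all(es$var_total / es$mean_total > 1))
  # running-maximum first passage is non-decreasing and hits 1 for threshold 1
  expect_true(all(diff(es$passage_prob) >= 0))
  es1 <- ensemble_summary(erlang_params(2, 1), reps = 50,
                          record_times = c(1, 2), threshold = 1, seed = 1)
  expect_true(all(es1$passage_prob == 1))
  # "current" mode can decrease in general but never exceeds first passage
  esc <- ensemble_summary(erlang_params(1, 0.1), reps = 2000,
                          record_times = c(10, 20, 30), threshold = 5,
                          seed = 105, mode = "current")
  expect_true(all(esc$passage_prob <= es$passage_prob[1:3] + 0.05))
})

test_that("larger k at fixed mean CCT slows ensemble growth", {
  means <- vapply(c(1, 2, 5, 10), function(k) {
    es <- ensemble_summary(erlang_params(k, k / 10), reps = 4000,
                           record_times = 20, seed = 600 + k)
    es$mean_total
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
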