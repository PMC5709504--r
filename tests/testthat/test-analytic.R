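test_that("mean ODE right-hand side encodes the doubling chain", {
  # k = 1: dM/dt = lambda M (division doubles the single stage)
  expect_equal(mean_ode_rhs(3, 0.1), 0.3)

  # equal rates, cells spread evenly: total derivative is M / C
  k <- 5; C <- 10; M <- 7
  rhs <- mean_ode_rhs(rep(M / k, k), rep(k / C, k))
  expect_equal(sum(rhs), M / C)

  expect_error(mean_ode_rhs(c(1, 0), rep(1, 3)), "same number of stages")
})

test_that("root-of-unity series matches the k = 4 closed forms and the ODE", {
  C <- 10; k <- 4
  tt <- c(0, 5, 10, 20, 30)
  closed <- oracle_k4_stage_means(tt, C)
  for (j in 1:4) {
    expect_equal(exact_stage_mean(tt, j, k, C), unname(closed[, j]),
                 tolerance = 1e-10)
  }
  # total = sum over stages
  expect_equal(exact_total_mean(tt, k, C), unname(rowSums(closed)),
               tolerance = 1e-9)

  # numerical integration of the mean system agrees to 1e-8
  sol <- integrate_stage_means(erlang_params(k, k / C), times = tt)
  for (j in 1:4) {
    expect_equal(sol[[paste0("stage_", j)]], unname(closed[, j]),
                 tolerance = 1e-8)
  }
})

test_that("series solutions satisfy initial conditions and the k = 1 form", {
  for (k in c(1, 3, 7)) {
    expect_equal(exact_stage_mean(0, 1, k, 10), 1)
    if (k > 1) for (j in 2:k) expect_equal(exact_stage_mean(0, j, k, 10), 0)
    expect_equal(exact_total_mean(0, k, 10), 1)
  }
  tt <- c(0, 10, 30)
  expect_equal(exact_total_mean(tt, 1, 10), exp(tt / 10))
  expect_equal(exact_stage_mean(tt, 1, 1, 10), exp(tt / 10))
  expect_error(exact_stage_mean(1, 5, 4, 10), "stage index")
})

test_that("exact total mean equals ODE totals across stage counts", {
  C <- 10
  tt <- seq(0, 30, by = 3)
  for (k in c(1, 2, 4, 5, 10)) {
    sol <- integrate_stage_means(erlang_params(k, k / C), times = tt)
    expect_equal(exact_total_mean(tt, k, C), sol$total, tolerance = 1e-8)
  }
})

test_that("multi-stage growth is slower than single-stage at every k", {
  tt <- seq(1, 30, by = 1)
  single <- exact_total_mean(tt, 1, 10)
  for (k in c(2, 4, 5, 10, 20)) {
    expect_true(all(exact_total_mean(tt, k, 10) < single))
  }
  # alpha_k strictly decreasing in k
  a <- asymptotic_law(1:50)$alpha
  expect_true(all(diff(a) < 0))
  expect_true(all(a > log(2) & a <= 1))
})

test_that("asymptotic law has the right endpoints and infinite-k limits", {
  law1 <- asymptotic_law(1)
  expect_equal(law1$alpha, 1)
  expect_equal(law1$prefactor, 1)
  expect_lt(abs(asymptotic_law(1e6)$alpha - log(2)), 1e-5)
  expect_equal(asymptotic_law(1e6)$prefactor, 1 / (2 * log(2)),
               tolerance = 1e-5)
  expect_error(asymptotic_law(0), "positive")
})

test_that("subdominant modes peak at the first mode and die out up to k = 28", {
  # the per-k maximum real part is attained at r = 1 (and k - 1 by symmetry)
  for (k in 3:40) {
    modes <- subdominant_mode_re(k)
    m <- max(modes$re)
    at_max <- modes$r[modes$re > m - 1e-12]
    expect_equal(sort(at_max), c(1, k - 1))
  }
  expect_equal(subdominant_mode_re(2)$re, -(1 + sqrt(2)))
  thr <- subdominant_decay_threshold(40)
  expect_identical(as.integer(thr), 28L)
  scan <- attr(thr, "scan")
  expect_true(all(scan$max_re[scan$k <= 28] < 0))
  expect_true(all(scan$max_re[scan$k > 28] > 0))
})

test_that("steady-state proportions are geometric, normalized and decreasing", {
  expect_equal(steady_state_proportions(1), 1)
  for (k in c(2, 5, 17, 60)) {
    prop <- steady_state_proportions(k)
    expect_lt(abs(sum(prop) - 1), 1e-12)
    expect_true(all(diff(prop) < 0))
    # recurrence fixed point: Mhat_j = Mhat_{j-1} / (1 + Mhat_k)
    expect_equal(prop[-1], prop[-k] / (1 + prop[k]), tolerance = 1e-12)
    expect_equal(prop[1], 2 * prop[k] / (1 + prop[k]), tolerance = 1e-12)
  }
  # first/last ratio 2^((k-1)/k) tends to 2
  expect_equal(steady_state_proportions(5)[1] / steady_state_proportions(5)[5],
               2^(4 / 5))
  r <- steady_state_proportions(1e6)
  expect_lt(abs(r[1] / r[1e6] - 2), 1e-5)
})

test_that("proportion dynamics conserve mass and settle on the fixed point", {
  # conservation for random simplex points
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    m <- as.numeric(stats::rbeta(k, 2, 2))
    m <- m / sum(m)
    expect_lt(abs(sum(proportion_ode_rhs(m, 0.7))), 1e-12)
  }
  # the analytic steady state is a fixed point
  for (k in c(1, 5, 12)) {
    expect_lt(max(abs(proportion_ode_rhs(steady_state_proportions(k), 0.5))),
              1e-10)
  }
  expect_error(proportion_ode_rhs(c(0.5, 0.4), 1), "normalized")

  # long-time integration from uniform proportions reaches the steady state
  k <- 5
  sol <- integrate_stage_proportions(rep(1 / k, k), lam1 = 0.5,
                                     times = c(0, 200))
  final <- as.numeric(sol[2, paste0("stage_", 1:k)])
  expect_equal(final, steady_state_proportions(k), tolerance = 1e-8)
})

test_that("stage occupancies are not proportional to stage durations", {
  # unequal rates: partition C = 10 into k = 5 random stage means
  set.seed(7)
  w <- diff(sort(c(0, runif(4), 1)))
  mu <- 10 * w
  rates <- 1 / mu
  sol <- integrate_stage_means(rates, times = c(0, 300))
  final <- as.numeric(sol[2, paste0("stage_", 1:5)])
  props <- final / sum(final)
  expect_gt(max(abs(props - mu / sum(mu))), 0.01)
})

test_that("the infinite-stage limit is the doubling staircase", {
  # non-integer t/C: 2^floor(t/C), approached by the series at large k
  expect_equal(limit_total_mean(c(5, 15, 25), 10), c(1, 2, 4))
  expect_equal(exact_total_mean(15, 1e4, 10), 2, tolerance = 0.02)
  # integer t/C: the (3/4) 2^(t/C) mean of the two one-sided limits
  expect_equal(limit_total_mean(c(10, 20), 10), c(1.5, 3))
})
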