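test_that("histogram constructor and CSV round trip preserve the data", {
  h <- generate_synthetic_histogram(erlang_params(4, 0.4), n = 5000,
                                    bins = 30, seed = 41)
  # exact unit area by construction
  expect_equal(sum(h$density * (h$bin_right - h$bin_left)), 1,
               tolerance = 1e-12)
  expect_identical(h, generate_synthetic_histogram(erlang_params(4, 0.4),
                                                   n = 5000, bins = 30,
                                                   seed = 41))
  f <- tempfile(fileext = ".csv")
  write_cct_histogram(h, f)
  h2 <- read_cct_histogram(f)
  expect_equal(h2$bin_left, h$bin_left)
  expect_equal(h2$density, h$density)

  expect_error(cct_histogram(c(0, 1, 2), c(0.2, 0.2)), "\\[0.9, 1.1\\]")
  expect_error(cct_histogram(c(0, 2, 1), c(0.5, 0.5)), "increasing")
  expect_error(generate_synthetic_histogram(erlang_params(1, 1), n = 10),
               "at least 100")
})

test_that("a noiseless histogram is a zero-residual fixed point", {
  # heights are exact density values at the bin centres
  p <- erlang_params(12, 0.0083)
  edges <- seq(0, 4000, length.out = 61)
  mids <- (edges[-1] + edges[-61]) / 2
  h <- cct_histogram(edges, erlang_pdf(mids, p))
  fit <- fit_cctd(h, "erlang", k_range = 8:16)
  expect_equal(fit$params$k, 12L)
  expect_equal(fit$params$rate, 0.0083, tolerance = 1e-6)
  expect_lt(fit$ssr, 1e-16)
})

test_that("exponential rate is recovered and erlang selects k = 1 on it", {
  h <- generate_synthetic_histogram(erlang_params(1, 0.1), n = 1e5,
                                    bins = 50, seed = 42)
  fe <- fit_cctd(h, "exponential")
  expect_lt(abs(fe$params$rate - 0.1) / 0.1, 0.05)
  fr <- fit_cctd(h, "erlang", k_range = 1:10)
  expect_equal(fr$params$k, 1L)
})

test_that("Erlang shape and rate are recovered from a sampled histogram", {
  h <- generate_synthetic_histogram(erlang_params(12, 0.0083), n = 1e5,
                                    bins = 50, seed = 43)
  fr <- fit_cctd(h, "erlang", k_range = 1:30)
  expect_true(fr$params$k %in% 11:13)
  expect_lt(abs(fr$params$rate - 0.0083) / 0.0083, 0.1)
  fe <- fit_cctd(h, "exponential")
  expect_lt(fr$ssr, fe$ssr)
})

test_that("nested families are ordered on an EME fixture and recover its mode", {
  p <- eme_params(26, 0.0251, 0.0019)
  h <- generate_synthetic_histogram(p, n = 1e5, bins = 50, seed = 44)
  # histogram mode near the Erlang-part mode (k - 1)/lam1 plus a small shift
  mode_bin <- h$mid[which.max(h$density)]
  expect_lt(abs(mode_bin - 25 / 0.0251), 500)

  fe <- fit_cctd(h, "exponential")
  fr <- fit_cctd(h, "erlang", k_range = 1:40)
  fm <- fit_cctd(h, "eme", k_range = 1:40)
  expect_lte(fm$ssr, fr$ssr + 1e-12)
  expect_lte(fr$ssr, fe$ssr + 1e-12)
  # EME fit should sit near the generating parameters
  expect_lt(abs(hypoexp_moments(fm$params)$mean -
                  hypoexp_moments(p)$mean) / hypoexp_moments(p)$mean, 0.1)
})

test_that("nested ordering also holds on Erlang and exponential fixtures", {
  for (gen in list(erlang_params(1, 0.05), erlang_params(6, 0.3))) {
    h <- generate_synthetic_histogram(gen, n = 2e4, bins = 40, seed = 45)
    fe <- fit_cctd(h, "exponential")
    fr <- fit_cctd(h, "erlang", k_range = 1:20)
    fm <- fit_cctd(h, "eme", k_range = 1:20)
    expect_lte(fm$ssr, fr$ssr + 1e-12)
    expect_lte(fr$ssr, fe$ssr + 1e-12)
  }
})

test_that("fitted Erlang means sharpen as the sample grows", {
  # average relative mean error over seeds roughly halves from n to 4n
  gen <- erlang_params(8, 0.8)
  err <- function(n, seed) {
    h <- generate_synthetic_histogram(gen, n = n, bins = 40, seed = seed)
    f <- fit_cctd(h, "erlang", k_range = 1:20)
    abs(hypoexp_moments(f$params)$mean - 10) / 10
  }
  e1 <- mean(vapply(1:10, function(s) err(1e4, 100 + s), numeric(1)))
  e2 <- mean(vapply(1:10, function(s) err(4e4, 200 + s), numeric(1)))
  expect_lt(e2, e1)
})

test_that("bin-integrated residuals give a valid alternative objective", {
  h <- generate_synthetic_histogram(erlang_params(5, 0.5), n = 2e4,
                                    bins = 30, seed = 46)
  fc <- fit_cctd(h, "erlang", k_range = 1:12, residuals = "centre")
  fi <- fit_cctd(h, "erlang", k_range = 1:12, residuals = "integrated")
  expect_true(fi$params$k %in% 4:6)
  # the two objectives agree on the broad location of the optimum
  expect_lt(abs(fi$params$rate - fc$params$rate) / fc$params$rate, 0.2)
})

test_that("tidy and glance expose the fit in broom style", {
  h <- generate_synthetic_histogram(eme_params(5, 0.5, 0.1), n = 5000,
                                    bins = 30, seed = 47)
  fm <- fit_cctd(h, "eme", k_range = 2:8)
  td <- tidy(fm)
  expect_equal(td$term, c("k", "lam1", "lam2"))
  gl <- glance(fm)
  expect_equal(gl$family, "eme")
  expect_true(gl$ssr >= 0)
  expect_type(gl$converged, "logical")
})
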