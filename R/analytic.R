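#' Mean ODE system of the stage-structured pure-birth chain
#'
#' Right-hand side of the evolution equations for the mean number of cells in
#' each stage, `M_1 .. M_k`, of the division chain: stage `j` drains at rate
#' `rate_j M_j` into stage `j + 1`, and the final stage feeds back with
#' doubling, `dM_1/dt = 2 rate_k M_k - rate_1 M_1`.
#'
#' @param m Numeric vector of stage means (length `k`).
#' @param rates A [cct_params] object or numeric vector of stage rates, same
#'   length as `m`.
#' @return Numeric vector `dM/dt`.
#' @seealso [integrate_stage_means()], [exact_stage_mean()]
#' @export
mean_ode_rhs <- function(m, rates) {
  r <- if (inherits(rates, "cct_params")) stage_rates(rates) else rates
  if (length(m) != length(r)) {
    abort("`m` and `rates` must describe the same number of stages.")
  }
  k <- length(r)
  flux_out <- r * m
  flux_in <- c(2 * flux_out[k], flux_out[-k])
  flux_in - flux_out
}

#' Numerically integrate the stage-mean ODE system
#'
#' @param rates A [cct_params] object or numeric rate vector.
#' @param times Output time grid (first entry is the initial time).
#' @param m0 Initial stage means; defaults to a single cell in stage 1.
#' @param ... Passed to [deSolve::ode()] (default tolerances `1e-10`).
#' @return A tibble with columns `time`, `stage_1 .. stage_k`, `total`.
#' @export
integrate_stage_means <- function(rates, times, m0 = NULL, ...) {
  r <- if (inherits(rates, "cct_params")) stage_rates(rates) else rates
  k <- length(r)
  if (is.null(m0)) m0 <- c(1, rep(0, k - 1))
  stopifnot(length(m0) == k)
  sol <- deSolve::ode(y = m0, times = times,
                      func = function(t, y, p) list(mean_ode_rhs(y, r)),
                      rtol = 1e-10, atol = 1e-10, ...)
  out <- as_tibble(as.data.frame(sol))
  names(out) <- c("time", paste0("stage_", seq_len(k)))
  out$total <- rowSums(out[paste0("stage_", seq_len(k))])
  out
}

#' Exact mean number of cells in one stage (root-of-unity series)
#'
#' Closed-form solution of the equal-rates mean system started from a single
#' cell in stage 1:
#' `M_j(t) = (2^((1-j)/k)/k) * sum_r z^((1-j) r) exp((2^(1/k) z^r - 1) k t / C)`
#' where `z = exp(2 pi i / k)` and the sum runs over modes 0 to `k - 1`. The `k`
#' complex terms are summed in increasing order of magnitude and the real part
#' returned; the imaginary residual is asserted to be below `1e-9` (relative
#' to the magnitude of the result).
#'
#' @param t Vector of nonnegative times.
#' @param j Stage index in `1..k`.
#' @param k Number of stages.
#' @param C Mean cell-cycle time (the common stage rate is `k / C`).
#' @return Mean cell count in stage `j` at each time.
#' @export
exact_stage_mean <- function(t, j, k, C) {
  check_stage_count(k)
  check_nonneg_times(t)
  if (!is.numeric(j) || length(j) != 1 || j < 1 || j > k || j != round(j)) {
    abort("`j` must be a stage index in 1..k.")
  }
  r <- 0:(k - 1)
  z <- exp(2i * pi * r / k)
  ev <- (2^(1 / k) * z - 1) * k / C
  wts <- 2^((1 - j) / k) / k * z^(1 - j)  # z holds z^r, so this is z^((1-j) r)
  series_real(t, wts, ev)
}

#' Exact mean total cell number (root-of-unity series)
#'
#' Closed-form total mean of the equal-rates division chain from one cell,
#' obtained by summing the geometric stage weights of [exact_stage_mean()]
#' over the stages:
#' `M(t) = (1/(2k)) sum_r 2^(1/k) z^r / (2^(1/k) z^r - 1) *`
#' `exp((2^(1/k) z^r - 1) k t / C)`,
#' which satisfies `M(0) = 1` and whose dominant mode gives
#' [asymptotic_law()].
#'
#' @inheritParams exact_stage_mean
#' @return Mean total cell count at each time.
#' @export
exact_total_mean <- function(t, k, C) {
  check_stage_count(k)
  check_nonneg_times(t)
  r <- 0:(k - 1)
  z <- exp(2i * pi * r / k)
  ev <- (2^(1 / k) * z - 1) * k / C
  wts <- 2^(1 / k) * z / (2 * k * (2^(1 / k) * z - 1))
  series_real(t, wts, ev)
}

# Sum wts * exp(ev * t) over complex modes, smallest-magnitude terms first,
# and return the real part, asserting the imaginary residual bound.
series_real <- function(t, wts, ev) {
  vapply(t, function(ti) {
    terms <- wts * exp(ev * ti)
    s <- sum(terms[order(Mod(terms))])
    if (abs(Im(s)) > 1e-9 * max(1, abs(Re(s)))) {
      abort("Imaginary residual of the mode series exceeded 1e-9.")
    }
    Re(s)
  }, numeric(1))
}

#' Asymptotic growth law of the mean population
#'
#' For large times the mean total obeys
#' `M(t) ~ prefactor * exp(alpha_k t / C)` with growth exponent coefficient
#' `alpha_k = k (2^(1/k) - 1)` and prefactor `2^(1/k) / (2 alpha_k)`.
#' `alpha_1 = 1` recovers the naive exponential model `exp(t/C)`; as
#' `k -> Inf`, `alpha_k -> log(2)` and the prefactor tends to
#' `1 / (2 log 2) = 0.7213...`, so the synchronously dividing limit grows like
#' `0.721 * 2^(t/C)` rather than doubling with unit coefficient.
#'
#' @param k Vector of stage counts (`>= 1`).
#' @return A tibble with columns `k`, `alpha` and `prefactor`.
#' @export
asymptotic_law <- function(k) {
  if (any(k < 1) || any(k != round(k))) abort("`k` must be positive integers.")
  a <- growth_alpha(k)
  tibble(k = as.numeric(k), alpha = a, prefactor = 2^(1 / k) / (2 * a))
}

# alpha_k = k (2^(1/k) - 1), via expm1 so the k -> Inf limit is accurate
growth_alpha <- function(k) k * expm1(log(2) / k)

#' Largest stage count with all subdominant modes decaying
#'
#' The mode series of [exact_stage_mean()] has eigenvalue exponents
#' `(2^(1/k) z^r - 1) k / C`. The zeroth mode always grows; this function
#' computes, by brute force over the remaining modes, the largest `k <= k_max` for
#' which every other mode has strictly negative real part (so the mean
#' approaches clean exponential growth without persistent oscillation).
#'
#' @param k_max Largest stage count scanned (`>= 2`).
#' @return The largest `k` with all subdominant modes decaying, with the
#'   per-`k` scan attached as attribute `"scan"` (tibble of `k`, `max_re`).
#' @export
subdominant_decay_threshold <- function(k_max) {
  if (k_max < 2) abort("`k_max` must be at least 2.")
  scan <- purrr::map_dfr(2:k_max, function(k) {
    tibble(k = k, max_re = max(subdominant_mode_re(k)$re))
  })
  ok <- scan$k[scan$max_re < 0]
  structure(if (length(ok)) max(ok) else NA_integer_, scan = scan)
}

#' Real parts of the subdominant mode coefficients for one stage count
#'
#' @param k Number of stages (`>= 2`).
#' @return A tibble with columns `r` (mode index, 1 to `k - 1`) and `re`, the
#'   real part of `2^(1/k) exp(2 pi i r / k) - 1`.
#' @export
subdominant_mode_re <- function(k) {
  check_stage_count(k)
  if (k < 2) abort("`k` must be at least 2 to have subdominant modes.")
  r <- 1:(k - 1)
  tibble(r = r, re = 2^(1 / k) * cos(2 * pi * r / k) - 1)
}

#' Steady-state proportions of cells per stage
#'
#' Long-time fractions of the population in each stage of the equal-rates
#' chain: `Mhat_j = 2^((k-j)/k) (2^(1/k) - 1)`. They sum to one exactly,
#' decrease strictly in `j`, and are *not* proportional to stage durations:
#' the first stage always holds the most cells, with
#' `Mhat_1 / Mhat_k = 2^((k-1)/k) -> 2` as `k -> Inf`.
#'
#' @param k Number of stages.
#' @return Numeric vector of `k` proportions.
#' @export
steady_state_proportions <- function(k) {
  check_stage_count(k)
  j <- seq_len(k)
  2^((k - j) / k) * expm1(log(2) / k)
}

#' ODE system for the mean proportions of cells per stage (equal rates)
#'
#' Right-hand side of the proportion dynamics `Mhat_j = M_j / M`:
#' `dMhat_1/dt = lam1 (2 Mhat_k - Mhat_1 - Mhat_1 Mhat_k)` and, for `j >= 2`,
#' `dMhat_j/dt = lam1 (Mhat_{j-1} - Mhat_j - Mhat_j Mhat_k)`. The derivatives
#' sum to zero, so the simplex is invariant; the fixed point is
#' [steady_state_proportions()].
#'
#' @param mhat Numeric proportion vector summing to 1 (within `1e-9`).
#' @param lam1 Common stage rate (1/time).
#' @return Numeric vector `dMhat/dt`.
#' @export
proportion_ode_rhs <- function(mhat, lam1) {
  if (abs(sum(mhat) - 1) > 1e-9) {
    abort("`mhat` must be normalized: proportions must sum to 1 within 1e-9.")
  }
  proportion_rhs_raw(mhat, lam1)
}

# unvalidated right-hand side: the integrator may drift off the simplex by
# slightly more than the user-facing tolerance between internal steps
proportion_rhs_raw <- function(mhat, lam1) {
  k <- length(mhat)
  prev <- c(2 * mhat[k], mhat[-k])
  lam1 * (prev - mhat - mhat * mhat[k])
}

#' Numerically integrate the stage-proportion ODE system
#'
#' @param mhat0 Initial proportion vector (must sum to 1).
#' @param lam1 Common stage rate.
#' @param times Output time grid.
#' @param ... Passed to [deSolve::ode()].
#' @return A tibble with columns `time` and `stage_1 .. stage_k`.
#' @export
integrate_stage_proportions <- function(mhat0, lam1, times, ...) {
  proportion_ode_rhs(mhat0, lam1)  # validates normalization
  k <- length(mhat0)
  sol <- deSolve::ode(y = mhat0, times = times,
                      func = function(t, y, p) list(proportion_rhs_raw(y, lam1)),
                      rtol = 1e-10, atol = 1e-12, ...)
  out <- as_tibble(as.data.frame(sol))
  names(out) <- c("time", paste0("stage_", seq_len(k)))
  out
}

#' Infinite-stage limit of the mean total cell number
#'
#' As `k -> Inf` at fixed mean cell-cycle time `C`, division becomes
#' synchronous and the mean total converges to a deterministic doubling
#' staircase: `2^floor(t/C)` for non-integer `t/C`, and `(3/4) 2^(t/C)` at
#' integer `t/C` (the algebraic mean of the left and right limits of the
#' staircase).
#'
#' @param t Vector of nonnegative times.
#' @param C Mean cell-cycle time.
#' @param tol Tolerance for detecting integer `t/C`.
#' @return The limiting mean total at each time.
#' @export
limit_total_mean <- function(t, C, tol = 1e-9) {
  check_nonneg_times(t)
  x <- t / C
  is_int <- abs(x - round(x)) < tol
  ifelse(is_int, 0.75 * 2^round(x), 2^floor(x))
}
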