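#' Erlang cell-cycle-time density
#'
#' Density of the Erlang CCTD, `rate^k t^(k-1) exp(-rate t) / (k-1)!` — the
#' distribution of the sum of `k` exponential stage times with a common rate.
#' For `k = 1` this collapses to the exponential density.
#'
#' @param t Vector of nonnegative times.
#' @param p An [erlang_params] object.
#' @return Density values (1/time), nonnegative, integrating to one.
#' @seealso [eme_pdf()], [hypoexp_moments()], [sample_cct()]
#' @export
erlang_pdf <- function(t, p) {
  stopifnot(inherits(p, "erlang_params"))
  check_nonneg_times(t)
  dgamma(t, shape = p$k, rate = p$rate)
}

#' Exponentially modified Erlang density (closed form)
#'
#' Closed-form density of the EME CCTD,
#' `lam2 exp(-lam2 t) (lam1/(lam1 - lam2))^k {1 - Gamma(k, L t)/(k-1)!}` with
#' `L = lam1 - lam2` and `Gamma(.,.)` the upper incomplete gamma function.
#' The bracket is evaluated as the regularized lower incomplete gamma (on the
#' log scale) to avoid catastrophic cancellation at large `k`.
#'
#' The closed form is only used on the branch `lam1 > lam2`, where `L > 0`;
#' for `lam1 < lam2` the incomplete gamma would take a negative argument, and
#' the numerically convolved density [eme_pdf_conv()] must be used instead.
#'
#' @param t Vector of nonnegative times.
#' @param p An [eme_params] object with `lam1 > lam2`.
#' @return Density values (1/time).
#' @export
eme_pdf <- function(t, p) {
  stopifnot(inherits(p, "eme_params"))
  check_nonneg_times(t)
  if (p$lam1 <= p$lam2) {
    abort(paste0("The closed-form EME density requires lam1 > lam2; ",
                 "use eme_pdf_conv() for the lam1 < lam2 branch."))
  }
  logf <- log(p$lam2) - p$lam2 * t + p$k * (log(p$lam1) - log(p$L)) +
    pgamma(p$L * t, shape = p$k, log.p = TRUE)
  exp(logf)
}

#' Exponentially modified Erlang density by numerical convolution
#'
#' Evaluates the EME density as the convolution integral of the
#' Erlang(`k`, `lam1`) and exponential(`lam2`) densities by adaptive
#' quadrature. Valid on both branches `lam1 > lam2` and `lam1 < lam2`;
#' slower than the closed form but free of its branch restriction.
#'
#' @inheritParams eme_pdf
#' @param rel.tol Relative tolerance passed to [stats::integrate()].
#' @return Density values (1/time).
#' @export
eme_pdf_conv <- function(t, p, rel.tol = 1e-10) {
  stopifnot(inherits(p, "eme_params"))
  check_nonneg_times(t)
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    integrate(function(s) dgamma(s, shape = p$k, rate = p$lam1) *
                dexp(ti - s, rate = p$lam2),
              lower = 0, upper = ti, rel.tol = rel.tol)$value
  }, numeric(1))
}

#' EME cumulative distribution function (closed form, lam1 > lam2)
#'
#' `P(X + Y <= t)` for `X ~ Erlang(k, lam1)`, `Y ~ Exp(lam2)`:
#' `pgamma(t, k, lam1) - exp(-lam2 t) (lam1/L)^k P(k, L t)` with `P` the
#' regularized lower incomplete gamma and `L = lam1 - lam2`. Used for
#' bin-integrated fitting residuals.
#'
#' @inheritParams eme_pdf
#' @return Cumulative probabilities.
#' @export
eme_cdf <- function(t, p) {
  stopifnot(inherits(p, "eme_params"))
  check_nonneg_times(t)
  if (p$lam1 <= p$lam2) {
    abort("The closed-form EME CDF requires lam1 > lam2.")
  }
  pgamma(t, shape = p$k, rate = p$lam1) -
    exp(-p$lam2 * t + p$k * (log(p$lam1) - log(p$L)) +
          pgamma(p$L * t, shape = p$k, log.p = TRUE))
}

#' Mean and variance of a multi-stage cell-cycle-time distribution
#'
#' The CCT is the sum of the independent exponential stage times, so the mean
#' is the sum of the stage means `1/rate_i` and the variance the sum of the
#' stage variances `1/rate_i^2`. Works for all three parameter families
#' (Erlang, EME, general hypoexponential).
#'
#' @param p A [cct_params] object.
#' @return A one-row tibble with columns `mean` (time) and `variance`
#'   (time squared).
#' @examples
#' hypoexp_moments(hypoexp_params(c(0.4, 0.4, 0.4, 0.4)))  # mean 10, var 25
#' @export
hypoexp_moments <- function(p) {
  r <- stage_rates(p)
  tibble(mean = sum(1 / r), variance = sum(1 / r^2))
}

#' Sample cell-cycle times by summing exponential stage times
#'
#' Draws i.i.d. cell-cycle times by simulating the stage mechanism directly:
#' one exponential draw per stage, summed. This mirrors what the Gillespie
#' chain does for a lone cell, so samples are exact for every family
#' (including the EME, whose final stage has its own rate).
#'
#' @param p A [cct_params] object.
#' @param n Number of draws (`>= 1`).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Numeric vector of `n` cell-cycle times.
#' @export
sample_cct <- function(p, n, seed = NULL) {
  stopifnot(inherits(p, "cct_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a positive count.")
  }
  n <- as.integer(n)
  r <- stage_rates(p)
  with_seed(seed, {
    draws <- matrix(rexp(n * length(r), rate = rep(r, each = n)), nrow = n)
    rowSums(draws)
  })
}

check_nonneg_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    abort("Times must be finite and nonnegative.")
  }
  invisible(t)
}
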