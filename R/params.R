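#' Cell-cycle-time distribution parameters
#'
#' Constructors for the three cell-cycle-time distribution (CCTD) families the
#' package simulates and fits. All three describe the total time a cell takes
#' to traverse a serial chain of exponentially distributed stages, so all
#' three can be simulated event-by-event with the Gillespie algorithm:
#'
#' * `hypoexp_params()` — the general hypoexponential CCTD: `k = length(rates)`
#'   stages with per-stage rates `rates[i]` (1/time). Mean `sum(1/rates)`,
#'   variance `sum(1/rates^2)`.
#' * `erlang_params()` — the equal-rates special case: `k` stages at a common
#'   `rate`, i.e. an Erlang (integer-shape Gamma) CCTD with mean `k/rate` and
#'   scale `1/rate`.
#' * `eme_params()` — the exponentially modified Erlang (EME): `k` stages at
#'   rate `lam1` followed by one final stage at a distinct rate `lam2`; the
#'   CCTD is the convolution of an Erlang(`k`, `lam1`) and an exponential
#'   (`lam2`), with mean `k/lam1 + 1/lam2`.
#'
#' Time units are arbitrary; the package never assumes minutes versus hours.
#'
#' @param rates Numeric vector of strictly positive per-stage rates.
#' @param k Positive integer number of (equal-rate) stages.
#' @param rate,lam1,lam2 Strictly positive rates (1/time); `lam1` and `lam2`
#'   must differ.
#' @return An object of class `"erlang_params"`, `"eme_params"` or
#'   `"hypoexp_params"` (all inheriting from `"cct_params"`).
#' @examples
#' erlang_params(k = 12, rate = 0.0083)
#' eme_params(k = 26, lam1 = 0.0251, lam2 = 0.0019)
#' hypoexp_params(rates = c(0.4, 0.4, 0.4, 0.4))
#' @name cct_params
NULL

#' @rdname cct_params
#' @export
hypoexp_params <- function(rates) {
  if (!is.numeric(rates) || length(rates) < 1) {
    abort("`rates` must be a numeric vector with at least one stage rate.")
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    abort("All stage rates must be strictly positive and finite.")
  }
  structure(list(rates = as.numeric(rates)),
            class = c("hypoexp_params", "cct_params"))
}

#' @rdname cct_params
#' @export
erlang_params <- function(k, rate) {
  check_stage_count(k)
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single strictly positive number.")
  }
  structure(list(k = as.integer(k), rate = as.numeric(rate)),
            class = c("erlang_params", "cct_params"))
}

#' @rdname cct_params
#' @export
eme_params <- function(k, lam1, lam2) {
  check_stage_count(k)
  for (r in list(lam1, lam2)) {
    if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0) {
      abort("`lam1` and `lam2` must be single strictly positive numbers.")
    }
  }
  if (lam1 == lam2) {
    abort(paste0("`lam1` and `lam2` must differ; with equal rates use ",
                 "erlang_params(k + 1, lam1) instead."))
  }
  structure(list(k = as.integer(k), lam1 = as.numeric(lam1),
                 lam2 = as.numeric(lam2), L = as.numeric(lam1 - lam2)),
            class = c("eme_params", "cct_params"))
}

check_stage_count <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k < 1 ||
      k != round(k)) {
    abort("`k` must be a single positive integer.")
  }
  invisible(k)
}

#' Per-stage rate vector of a CCTD parameter object
#'
#' The ordered rates of the exponential stages making up the cell cycle: the
#' `rates` field for hypoexponential parameters, `k` copies of `rate` for
#' Erlang parameters, and `k` copies of `lam1` followed by `lam2` for EME
#' parameters (so the chain has `k + 1` stages).
#'
#' @param p A [cct_params] object.
#' @return Numeric vector of stage rates.
#' @export
stage_rates <- function(p) UseMethod("stage_rates")

#' @export
stage_rates.hypoexp_params <- function(p) p$rates

#' @export
stage_rates.erlang_params <- function(p) rep(p$rate, p$k)

#' @export
stage_rates.eme_params <- function(p) c(rep(p$lam1, p$k), p$lam2)

#' @export
print.cct_params <- function(x, ...) {
  r <- stage_rates(x)
  fam <- switch(class(x)[1],
                hypoexp_params = "hypoexponential",
                erlang_params = "Erlang",
                eme_params = "exponentially modified Erlang")
  cat(sprintf("<%s CCTD: %d stage%s, mean %.6g>\n", fam, length(r),
              if (length(r) > 1) "s" else "", sum(1 / r)))
  invisible(x)
}
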