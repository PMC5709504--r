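#' Cancer stem-cell model parameters
#'
#' Parameters of the stochastic stem-cell proliferation/differentiation model:
#' stem cells `S` divide with rate `rho_s` (mean cell-cycle time `1/rho_s`),
#' and at the instant of division a fate is drawn — symmetric division
#' `S -> S + S` with probability `r1`, asymmetric self-renewal `S -> S + P`
#' with probability `r2 = 1 - r1 - r3`, or symmetric differentiation
#' `S -> P + P` with probability `r3` (progenitor cells `P` are inert
#' counters). The cell cycle is broken into `k` exponential stages of rate
#' `rho_s * k`, so the CCT is Erlang with shape `k` and the same mean for
#' every `k`; `k = 1` recovers the exponential-CCT model.
#'
#' @param rho_s Division rate (1/time).
#' @param r1,r3 Fate probabilities of symmetric division and symmetric
#'   differentiation; `r1 + r3 <= 1`.
#' @param k Number of cell-cycle stages.
#' @param s0 Initial number of stem cells (all in stage 1).
#' @return An object of class `"stemcell_params"`.
#' @export
stemcell_params <- function(rho_s = 1, r1 = 0.2, r3 = 0.15, k = 1, s0 = 1) {
  check_stage_count(k)
  if (rho_s <= 0) abort("`rho_s` must be strictly positive.")
  if (r1 < 0 || r3 < 0 || r1 + r3 > 1) {
    abort("Fate probabilities must satisfy r1 >= 0, r3 >= 0 and r1 + r3 <= 1.")
  }
  if (s0 < 1 || s0 != round(s0)) abort("`s0` must be a positive integer.")
  structure(list(rho_s = rho_s, r1 = r1, r2 = 1 - r1 - r3, r3 = r3,
                 k = as.integer(k), s0 = as.integer(s0)),
            class = "stemcell_params")
}

#' @export
print.stemcell_params <- function(x, ...) {
  cat(sprintf(
    "<stem-cell model: rho_s=%g, r1=%g, r2=%g, r3=%g, k=%d, S0=%d>\n",
    x$rho_s, x$r1, x$r2, x$r3, x$k, x$s0))
  invisible(x)
}

#' Simulate the stem-cell proliferation/differentiation model
#'
#' Exact Gillespie ensemble of the stem-cell model with Erlang(`k`) cell-cycle
#' times: each stem cell advances through `k` stages at per-stage rate
#' `rho_s * k`; a final-stage firing draws the division fate (see
#' [stemcell_params()]). Reports the mean and variance of the stem-cell count
#' and the probability that the population has reached `threshold` cells —
#' with the default threshold of 1000 this is the tumour-regrowth probability
#' `p1000(t)`.
#'
#' @param p A [stemcell_params] object.
#' @param record_times Times at which to summarise the ensemble.
#' @param t_end Simulation horizon.
#' @param reps Number of replicate simulations.
#' @param threshold Stem-cell count for the passage probability.
#' @param seed Integer root seed.
#' @param mode Passage-probability convention, see [ensemble_summary()].
#' @return An `"msc_ensemble"` tibble (see [ensemble_summary()]); the
#'   `mean_progenitors` column tracks the inert progenitor pool.
#' @examples
#' \donttest{
#' p <- stemcell_params(rho_s = 1, r1 = 0.2, r3 = 0.15, k = 5)
#' simulate_stemcells(p, record_times = seq(5, 40, by = 5), reps = 500)
#' }
#' @export
simulate_stemcells <- function(p, record_times, t_end = max(record_times),
                               reps = 10000, threshold = 1000, seed = 1L,
                               mode = c("first_passage", "current")) {
  stopifnot(inherits(p, "stemcell_params"))
  fates <- tibble(prob = c(p$r1, p$r2, p$r3),
                  stage1 = c(2L, 1L, 0L),
                  progenitors = c(0L, 1L, 2L))
  fates <- fates[fates$prob > 0, , drop = FALSE]
  if (nrow(fates) == 0) abort("At least one fate probability must be positive.")
  x0 <- c(p$s0, rep(0L, p$k - 1))
  ensemble_summary(rep(p$rho_s * p$k, p$k), reps = reps,
                   record_times = record_times, t_end = t_end,
                   threshold = threshold, x0 = x0, fates = fates,
                   seed = seed, mode = match.arg(mode))
}

#' Mean-field stem-cell count for the exponential (k = 1) model
#'
#' Deterministic mean of the `k = 1` stem-cell model,
#' `S(t) = S0 exp(rho_s (r1 - r3) t)`, the solution of
#' `dS/dt = rho_s (r1 - r3) S`: each division changes the stem count by `+1`
#' with probability `r1` and `-1` with probability `r3`. With multi-stage
#' cell cycles (`k > 1`) the true mean grows strictly more slowly, so this
#' mean-field law overestimates the population — calling it with `k > 1`
#' warns accordingly.
#'
#' @param p A [stemcell_params] object.
#' @param t Vector of times.
#' @return Mean stem-cell count at each time.
#' @export
stemcell_mean_field <- function(p, t) {
  stopifnot(inherits(p, "stemcell_params"))
  if (p$k > 1) {
    warn(paste0("The exponential mean-field law is exact only for k = 1; ",
                "for k > 1 it overestimates the mean stem-cell count."))
  }
  p$s0 * exp(p$rho_s * (p$r1 - p$r3) * t)
}
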