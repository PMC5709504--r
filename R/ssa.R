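#' Exact Gillespie simulation of a multi-stage division chain
#'
#' Simulates one statistically exact realization of the stage chain with the
#' direct method: each stage `i` fires with propensity `rate_i x_i`; firing an
#' intermediate stage advances one cell, and firing the final stage replaces
#' one final-stage cell with two fresh stage-1 cells (division). For
#' [eme_params()] the chain has `k + 1` stages, the last at rate `lam2`.
#'
#' The state is sampled at fixed `record_times` with last-event-before
#' semantics, so ensemble summaries built from many replicates are aligned in
#' time. Identical seeds give bit-identical event sequences.
#'
#' @param model A [cct_params] object defining the stage rates.
#' @param t_end End time; defaults to the last record time.
#' @param record_times Strictly increasing times at which to record the state.
#' @param x0 Integer vector of initial cells per stage; defaults to a single
#'   cell in stage 1.
#' @param seed Integer root seed for the simulation's own RNG stream
#'   (independent of R's global RNG).
#' @return A tibble of class `"msc_trajectory"` with columns `time`,
#'   `stage_1 .. stage_k` and `total`.
#' @seealso [ensemble_summary()], [simulate_division_process()]
#' @export
simulate_chain <- function(model, record_times, t_end = max(record_times),
                           x0 = NULL, seed = 1L) {
  rates <- stage_rates(model)
  fates <- division_fates()
  sim_stage_process(rates, fates, x0, record_times, t_end, reps = 1L,
                    threshold = Inf, seed = seed)$trajectory
}

#' Exact simulation of a stage chain with division-fate choice
#'
#' Generalizes [simulate_chain()]: when the final stage fires, a fate is drawn
#' from `fates` and the state updated by that fate's stoichiometry. Each fate
#' row gives its probability, the number of fresh stage-1 cells it creates,
#' and the number of inert progenitor cells it adds. The plain division chain
#' is the single fate `(prob = 1, stage1 = 2, progenitors = 0)`.
#'
#' @inheritParams simulate_chain
#' @param rates Numeric vector of per-stage rates, or a [cct_params] object.
#' @param fates Data frame with columns `prob`, `stage1`, `progenitors`;
#'   probabilities must sum to 1 within `1e-12`.
#' @return A tibble of class `"msc_trajectory"`; column `progenitors` holds
#'   the cumulative progenitor count.
#' @export
simulate_division_process <- function(rates, fates, record_times,
                                      t_end = max(record_times), x0 = NULL,
                                      seed = 1L) {
  r <- if (inherits(rates, "cct_params")) stage_rates(rates) else rates
  sim_stage_process(r, validate_fates(fates), x0, record_times, t_end,
                    reps = 1L, threshold = Inf, seed = seed)$trajectory
}

#' Ensemble summary of a stage-chain or division process
#'
#' Runs `reps` independent replicates (deterministic per-replicate RNG streams
#' derived from `seed`, so the ensemble is reproducible and order-independent)
#' and summarises them at the record times: mean and unbiased variance of the
#' total cell count, and the fraction of replicates whose population has
#' reached `threshold` cells. By default that fraction is a first-passage
#' probability — the running maximum of the total has reached the threshold by
#' time `t` — which for a growing tumour answers "what is the probability the
#' population has ever reached size `threshold` by `t`". `mode = "current"`
#' instead reports the fraction currently at or above the threshold.
#'
#' @inheritParams simulate_division_process
#' @param reps Number of replicates (`>= 1`).
#' @param threshold Population size for the passage probability.
#' @param mode `"first_passage"` (default) or `"current"`.
#' @param fates Optional fate table (see [simulate_division_process()]);
#'   defaults to plain division into two stage-1 cells.
#' @return A tibble of class `"msc_ensemble"` with columns `time`,
#'   `mean_total`, `var_total`, `passage_prob` and `mean_progenitors`.
#'   Attributes: `reps`, `threshold`, `stage_mean` and `stage_var` (time-by-
#'   stage matrices), `totals` (replicate-by-time matrix), `fp_times`
#'   (per-replicate first-passage times), `first_division_times`
#'   (per-replicate time of the first division event) and `fate_counts`.
#' @export
ensemble_summary <- function(rates, reps, record_times,
                             t_end = max(record_times), threshold = Inf,
                             x0 = NULL, fates = NULL, seed = 1L,
                             mode = c("first_passage", "current")) {
  mode <- match.arg(mode)
  if (!is.numeric(reps) || length(reps) != 1 || reps < 1) {
    abort("`reps` must be a positive count.")
  }
  r <- if (inherits(rates, "cct_params")) stage_rates(rates) else rates
  fates <- if (is.null(fates)) division_fates() else validate_fates(fates)
  sim <- sim_stage_process(r, fates, x0, record_times, t_end,
                           reps = as.integer(reps), threshold = threshold,
                           seed = seed)
  raw <- sim$raw
  reps <- as.integer(reps)
  n_t <- length(record_times)

  mean_total <- colMeans(raw$totals)
  var_total <- apply(raw$totals, 2, var)
  passage <- if (mode == "first_passage") {
    vapply(record_times, function(tt) mean(raw$fp_time <= tt), numeric(1))
  } else {
    colMeans(raw$totals >= threshold)
  }
  stage_mean <- raw$stage_sum / reps
  stage_var <- if (reps > 1) {
    (raw$stage_sumsq - reps * stage_mean^2) / (reps - 1)
  } else {
    matrix(NA_real_, n_t, ncol(stage_mean))
  }

  out <- tibble(time = as.numeric(record_times), mean_total = mean_total,
                var_total = var_total, passage_prob = passage,
                mean_progenitors = colMeans(raw$progenitors))
  structure(out,
            class = c("msc_ensemble", class(out)),
            reps = reps, threshold = threshold, mode = mode,
            stage_mean = stage_mean, stage_var = stage_var,
            totals = raw$totals, fp_times = raw$fp_time,
            first_division_times = raw$first_fate_time,
            fate_counts = as.numeric(raw$fate_counts))
}

# Shared driver around the compiled SSA kernel.
sim_stage_process <- function(rates, fates, x0, record_times, t_end, reps,
                              threshold, seed) {
  k <- length(rates)
  if (is.null(x0)) x0 <- c(1L, rep(0L, k - 1))
  if (length(x0) != k) abort("`x0` must have one count per stage.")
  if (any(x0 < 0) || any(x0 != round(x0))) {
    abort("`x0` must contain nonnegative integer counts.")
  }
  if (sum(x0) < 1) abort("The initial state must contain at least one cell.")
  if (length(record_times) < 1 || is.unsorted(record_times, strictly = TRUE)) {
    abort("`record_times` must be non-empty and strictly increasing.")
  }
  if (t_end < max(record_times)) {
    abort("`t_end` must reach the last record time.")
  }
  raw <- cpp_stage_ssa(as.numeric(rates), as.numeric(fates$prob),
                       as.integer(fates$stage1), as.integer(fates$progenitors),
                       as.integer(x0), as.numeric(record_times),
                       as.integer(reps), as.numeric(threshold),
                       as.numeric(seed))
  traj <- tibble(time = as.numeric(record_times))
  counts <- raw$stage_sum  # with reps = 1 these are the recorded counts
  for (j in seq_len(k)) traj[[paste0("stage_", j)]] <- counts[, j]
  traj$total <- raw$totals[1, ]
  traj$progenitors <- raw$progenitors[1, ]
  traj <- structure(traj, class = c("msc_trajectory", class(traj)))
  list(trajectory = traj, raw = raw)
}

division_fates <- function() {
  tibble(prob = 1, stage1 = 2L, progenitors = 0L)
}

validate_fates <- function(fates) {
  need <- c("prob", "stage1", "progenitors")
  if (!is.data.frame(fates) || !all(need %in% names(fates))) {
    abort("`fates` must have columns prob, stage1 and progenitors.")
  }
  if (abs(sum(fates$prob) - 1) > 1e-12) {
    abort("Fate probabilities must sum to 1 within 1e-12.")
  }
  if (any(fates$prob < 0) || any(fates$stage1 < 0) || any(fates$progenitors < 0)) {
    abort("Fate probabilities and stoichiometries must be nonnegative.")
  }
  fates
}

#' Per-replicate first-division times of a stage chain
#'
#' Convenience accessor: simulates `reps` single-cell chains and returns the
#' time of the first division in each. Starting from one cell in stage 1, the
#' first division time is distributed exactly as the cell-cycle-time
#' distribution itself, which makes this the natural cross-check between the
#' SSA engine and [sample_cct()].
#'
#' @inheritParams ensemble_summary
#' @param model A [cct_params] object.
#' @param t_end Simulation horizon (should comfortably exceed typical CCTs).
#' @return Numeric vector of `reps` first-division times (`Inf` if none
#'   occurred before `t_end`).
#' @export
first_division_times <- function(model, reps, t_end, seed = 1L) {
  # The first division time does not depend on what the division produces, so
  # run the chain with an absorbing (extinction) fate: each replicate stops
  # right after its first division instead of simulating the growing clone.
  absorb <- tibble(prob = 1, stage1 = 0L, progenitors = 0L)
  es <- ensemble_summary(model, reps = reps, record_times = t_end,
                         t_end = t_end, threshold = Inf, fates = absorb,
                         seed = seed)
  attr(es, "first_division_times")
}
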