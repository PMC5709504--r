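#' Lattice growth-to-confluence model configuration
#'
#' Configuration of the 2-D on-lattice volume-exclusion model of cell
#' migration and multi-stage proliferation. Cells occupy at most one site of
#' an `lx` by `ly` periodic square lattice. Each cell migrates with rate `pm`
#' into a uniformly chosen von Neumann neighbour (aborted if occupied) and
#' undergoes a proliferation stage change with rate `pp * k` (so an unhindered
#' pass through the `k` stages takes mean time `1/pp`). A stage-`k` cell
#' selected for a stage change attempts to place a daughter in a uniform von
#' Neumann neighbour: on success both parent and daughter restart at stage 1;
#' on failure the abort rule applies — `"reset"` sends the parent back to
#' stage 1 (same average division-attempt rate as the `k = 1` model) or
#' `"hold"` keeps it at stage `k` (a cell held at a checkpoint, ready to
#' re-attempt). For `k = 1` the two rules coincide.
#'
#' @param lx,ly Lattice dimensions in sites (`>= 2`).
#' @param pm Migration rate (1/time).
#' @param pp Proliferation rate (1/time); the mean cell-cycle time is `1/pp`.
#' @param k Number of proliferation stages.
#' @param abort_rule `"reset"` or `"hold"`.
#' @param initial_density Initial occupied fraction in `(0, 1]`.
#' @param initial_stage Stage assigned to the seeded cells (default 1).
#' @param h Site length (bookkeeping only; the dynamics are h-free).
#' @return An object of class `"lattice_config"`.
#' @export
lattice_config <- function(lx = 100, ly = 100, pm = 1, pp = 1, k = 1,
                           abort_rule = c("reset", "hold"),
                           initial_density = 0.01, initial_stage = 1, h = 1) {
  abort_rule <- match.arg(abort_rule)
  check_stage_count(k)
  if (lx < 2 || ly < 2) abort("`lx` and `ly` must be at least 2.")
  if (pm < 0 || pp < 0) abort("`pm` and `pp` must be nonnegative rates.")
  if (initial_density <= 0 || initial_density > 1) {
    abort("`initial_density` must lie in (0, 1].")
  }
  if (initial_stage < 1 || initial_stage > k) {
    abort("`initial_stage` must lie in 1..k.")
  }
  structure(list(lx = as.integer(lx), ly = as.integer(ly), pm = pm, pp = pp,
                 k = as.integer(k), abort_rule = abort_rule,
                 initial_density = initial_density,
                 initial_stage = as.integer(initial_stage), h = h),
            class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  cat(sprintf(
    "<lattice model: %dx%d periodic, Pm=%g, Pp=%g, k=%d, abort=%s, density=%g>\n",
    x$lx, x$ly, x$pm, x$pp, x$k, x$abort_rule, x$initial_density))
  invisible(x)
}

#' Seed a lattice uniformly at random
#'
#' Places exactly `round(initial_density * lx * ly)` cells uniformly at random
#' without replacement across the lattice, all in `initial_stage`.
#'
#' @param cfg A [lattice_config].
#' @param seed Optional integer seed (caller's RNG state restored).
#' @return An integer `lx` by `ly` matrix: 0 for empty sites, otherwise the
#'   occupying cell's stage.
#' @export
initialise_lattice <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "lattice_config"))
  n_sites <- cfg$lx * cfg$ly
  n_cells <- round(cfg$initial_density * n_sites)
  if (n_cells < 1) abort("The seeding density must place at least one cell.")
  with_seed(seed, {
    grid <- matrix(0L, cfg$lx, cfg$ly)
    grid[sample.int(n_sites, n_cells)] <- cfg$initial_stage
    grid
  })
}

#' Simulate the lattice model to confluence
#'
#' One exact realization of the migration/proliferation exclusion process (see
#' [lattice_config()]), recorded on a rescaled-time grid `tbar = pp * t` so
#' that runs at different proliferation rates are comparable. When `pp = 0`
#' (pure excluded random walk) the record grid is interpreted in raw time.
#'
#' @param cfg A [lattice_config].
#' @param record_tbar Strictly increasing record grid in rescaled time.
#' @param seed Integer root seed (drives both the seeding and the event
#'   stream).
#' @param snapshots_tbar Optional rescaled times at which to copy out the full
#'   stage-labelled grid.
#' @param init Optional pre-built initial grid (overrides the random seeding).
#' @return A tibble of class `"msc_density"` with columns `tbar` and
#'   `density`; snapshot grids, if requested, are attached as attribute
#'   `"snapshots"` (named list).
#' @export
simulate_lattice <- function(cfg, record_tbar, seed = 1L,
                             snapshots_tbar = NULL, init = NULL) {
  stopifnot(inherits(cfg, "lattice_config"))
  if (length(record_tbar) < 1 || is.unsorted(record_tbar, strictly = TRUE)) {
    abort("`record_tbar` must be non-empty and strictly increasing.")
  }
  scale <- if (cfg$pp > 0) cfg$pp else 1
  if (is.null(init)) init <- initialise_lattice(cfg, seed = seed)
  snaps <- if (is.null(snapshots_tbar)) numeric(0) else snapshots_tbar / scale
  raw <- cpp_lattice_ssa(init, cfg$pm, cfg$pp, cfg$k,
                         cfg$abort_rule == "reset", record_tbar / scale,
                         snaps, as.numeric(seed), 0)
  out <- tibble(tbar = as.numeric(record_tbar),
                density = raw$counts / (cfg$lx * cfg$ly))
  out <- structure(out, class = c("msc_density", class(out)))
  if (length(snaps)) {
    attr(out, "snapshots") <- setNames(raw$snapshots,
                                       paste0("tbar_", snapshots_tbar))
  }
  out
}

#' Ensemble mean lattice density
#'
#' Averages the occupied fraction over `reps` independent realizations of the
#' lattice model. Each replicate gets its own random initial seeding and its
#' own deterministic event stream derived from `seed`.
#'
#' @inheritParams simulate_lattice
#' @param reps Number of replicates.
#' @return A tibble of class `"msc_density_ensemble"` with columns `tbar`,
#'   `mean_density` and `sd_density`; per-replicate densities are attached as
#'   attribute `"densities"` (replicate-by-time matrix).
#' @export
ensemble_density <- function(cfg, record_tbar, reps, seed = 1L) {
  stopifnot(inherits(cfg, "lattice_config"))
  if (reps < 1) abort("`reps` must be a positive count.")
  scale <- if (cfg$pp > 0) cfg$pp else 1
  grids <- with_seed(seed, {
    lapply(seq_len(reps), function(i) initialise_lattice(cfg))
  })
  dens <- vapply(seq_len(reps), function(i) {
    raw <- cpp_lattice_ssa(grids[[i]], cfg$pm, cfg$pp, cfg$k,
                           cfg$abort_rule == "reset", record_tbar / scale,
                           numeric(0), as.numeric(seed), i)
    raw$counts / (cfg$lx * cfg$ly)
  }, numeric(length(record_tbar)))
  dens <- t(matrix(dens, nrow = length(record_tbar)))  # reps x times
  out <- tibble(tbar = as.numeric(record_tbar),
                mean_density = colMeans(dens),
                sd_density = apply(dens, 2, stats::sd))
  structure(out, class = c("msc_density_ensemble", class(out)),
            reps = reps, densities = dens)
}
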