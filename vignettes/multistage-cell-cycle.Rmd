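---
title: "Multi-stage Markov models of the cell cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage Markov models of the cell cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multistage)
```

## The problem

Stochastic models of proliferating cell populations are routinely simulated
with the Gillespie algorithm, which represents every event — including cell
division — as exponentially distributed. Measured cell-cycle times (CCTs) are
not exponential: a newborn cell must traverse G1, S, G2 and M before it can
divide, so the empirical CCT distribution (CCTD) has far less variance than
an exponential with the same mean, vanishes at zero lag, and is unimodal with
an interior mode. Treating division as a single exponential event therefore
misrepresents both the fluctuations *and the mean* of a growing population.

This package implements the standard repair: break the cell cycle into `k`
serial stages, each an independent exponential waiting time. The total CCT is
then hypoexponential — still a continuous-time Markov chain when the stage
label is tracked, so the Gillespie algorithm applies exactly — while the CCTD
can be made as concentrated as the data demand by increasing `k`.

Two special cases carry the package:

* **Erlang**: `k` stages at a common rate `lambda`; mean `C = k/lambda`,
  variance `C^2/k`. Two parameters.
* **Exponentially modified Erlang (EME)**: `k` equal-rate stages at `lambda1`
  followed by one final stage at a distinct `lambda2`; the CCTD is the
  Erlang–exponential convolution, with closed form
  `lambda2 e^{-lambda2 t} (lambda1/(lambda1-lambda2))^k P(k, (lambda1-lambda2) t)`
  where `P` is the regularized lower incomplete gamma. Three parameters.

Both families fit published CCT data sets well, and both are simulable
stage-by-stage, which is the entire point: no non-Markovian machinery is
needed.

## Mean dynamics of the stage chain

For the pure-birth chain (final stage fires, one cell is replaced by two
stage-1 cells) with equal rates, the mean stage occupancies solve a linear
cyclic system whose eigen-modes are indexed by the `k`-th roots of unity
`z^r = exp(2 pi i r / k)`:

* `exact_stage_mean()` and `exact_total_mean()` evaluate those complex
  series; terms are summed in increasing magnitude and the imaginary residual
  is asserted below `1e-9` (relative to the result's magnitude).
* `asymptotic_law()` gives the long-time law
  `M(t) ~ (2^{1/k} / (2 alpha_k)) exp(alpha_k t / C)` with
  `alpha_k = k (2^{1/k} - 1)`. `alpha_k` decreases from 1 (naive exponential
  model) towards `log 2`, and the prefactor towards `1/(2 log 2) = 0.7213`:
  even in the synchronous-division limit the mean is `0.721 * 2^{t/C}`, not
  `2^{t/C}`.
* `subdominant_decay_threshold()` scans, by brute force, the largest `k` for
  which every non-dominant mode has negative real part (28): beyond that the
  mean approaches its growth law with persistent oscillation.
* `steady_state_proportions()` returns the geometric long-time stage
  occupancies `2^{(k-j)/k} (2^{1/k} - 1)`. These are *not* uniform even
  though every stage has the same mean duration — stage 1 is refilled twice
  per division — which matters for experimental designs that infer cell-cycle
  phase durations from occupancy fractions. The first/last ratio
  `2^{(k-1)/k}` tends to 2.

One substantive correction was needed while validating these forms: the
literature display of the total-mean series omits a `z^r` factor in the
numerator (without it the series gives `M(0) = 1/sqrt(2)` at `k = 2`).
The implemented weight `2^{1/k} z^r / (2^{1/k} z^r - 1)` follows from
summing the per-stage geometric weights, restores `M(0) = 1`, agrees with
direct ODE integration to `1e-8`, and leaves the dominant `r = 0` mode — and
hence the asymptotic law — unchanged. The infinite-stage limits are exposed
as an explicit staircase function (`limit_total_mean()`: `2^{floor(t/C)}`,
with coefficient 3/4 at integer `t/C`) rather than by evaluating the series
at astronomically large `k`.

## The simulation engine

`simulate_chain()`, `simulate_division_process()` and `ensemble_summary()`
wrap one compiled direct-method Gillespie kernel: exponential waiting time
from the total propensity, linear event selection, no tau-leaping —
exactness is the point. Design choices:

* **Recording** uses fixed record times with last-event-before semantics, so
  replicate summaries are aligned; totals, per-stage means/variances,
  progenitor counts and fate counts are accumulated in the kernel.
* **Seeding**: each replicate gets its own `mt19937_64` stream seeded through
  a SplitMix64 mix of (root seed, replicate index); ensembles are
  reproducible bit-for-bit and independent of R's global RNG, and replicate
  order is irrelevant.
* **First passage**: the probability that a population "has reached" size `n`
  is read as a running-maximum first-passage probability (non-decreasing in
  `t`); the alternative "currently at or above `n`" reading is available via
  `mode = "current"`.
* **Sampling CCTs** (`sample_cct()`) sums one exponential draw per stage —
  the stage mechanism itself, not an inverse-CDF shortcut — so samples and
  chain first-division times are identically distributed by construction,
  and the test suite checks exactly that equivalence.

## The two illustrative models

**Stem cells** (`simulate_stemcells()`): stem cells divide at rate `rho_s`
(Erlang CCT with `k` stages, same mean for every `k`); at division a fate is
drawn — symmetric renewal (probability `r1`, +1 stem), asymmetric renewal
(`r2 = 1 - r1 - r3`, +1 inert progenitor), symmetric differentiation (`r3`,
-1 stem, +2 progenitors). Fate choice happens at the division instant, not at
birth. With `r1 > r3` the mean grows like `S0 exp(rho_s (r1 - r3) t)` only
for `k = 1` (`stemcell_mean_field()`, which warns otherwise); for `k > 1` the
mean, the variance and the probability of reaching 1000 cells all fall below
the exponential-CCT model at matched mean CCT. Progenitors are kept as inert
counters because the analysis concerns the stem-cell population; richer
progenitor dynamics would bolt onto the same fate table.

**Growth to confluence** (`simulate_lattice()`, `ensemble_density()`): a 2-D
periodic lattice with at-most-one-cell-per-site exclusion; cells migrate at
rate `Pm` to uniform von Neumann neighbours (blocked moves abort) and advance
their division stage at rate `Pp k`. A stage-`k` cell attempting division
into an occupied site aborts, and the two biological readings of an aborted
division are both implemented: `reset` (back to stage 1 — same attempt rate
as the `k = 1` model) and `hold` (stay at stage `k`, like a cell held at a
checkpoint). For `k = 1` they coincide exactly, and the engine exploits that
every cell carries the same total rate `Pm + Pp k` to pick cells uniformly —
an exact scheme, not an approximation. At 1% seeding and `Pm = Pp = 1`,
increasing `k` *lowers* the density at rescaled time `Pp t = 10` under
`reset` but *raises* it under `hold`, because held cells at the colony rim
re-attempt division immediately; time is recorded in rescaled units so runs
at different `Pp` are comparable. Initial cells start in stage 1 (the choice
is configurable; early-time densities depend on it).

## Histogram fitting

`fit_cctd()` fits exponential, Erlang or EME densities to a binned CCT
density histogram by unweighted least squares — residuals are density values
at bin centres minus bar heights, matching how such fits are usually done on
published histograms; a bin-integrated variant (`residuals = "integrated"`)
is provided because the choice changes the objective on coarse bins. The
integer shape is handled by an exhaustive grid (default 1..60) with a
continuous rate optimization nested inside: the ssr landscape flattens onto
the plateau `sum(h^2)` once the density leaves the binned window, so the
rate search scans a log-rate grid before polishing with golden-section. The
EME search is constrained to `lambda1 > lambda2` (the branch on which the
closed form is valid — and where empirical CCT fits live, the slow
exponential tail being the point of the EME); its multi-start includes an
Erlang-degenerate point (`lambda2` just under `lambda1` reproduces the best
Erlang with one fewer stage) and an exponential-degenerate point (`lambda1`
large), so the nested ordering `ssr_EME <= ssr_Erlang <= ssr_exponential`
holds by construction up to optimizer tolerance.

`generate_synthetic_histogram()` is the fixture generator: experimental CCT
histograms are published as figures rather than deposited data, so tests and
examples draw `n` CCTs from a known generator and bin them (equal-width bins
over `[0, max]`, unit area by construction). Synthetic fixtures exercise
sampling noise and binning, but not measurement error, censoring, or
between-cell heritable correlation in CCTs — passing recovery tests says the
fitter works on clean draws from the model family, not that any particular
biological data set is Erlang.

## Problem sizes used in the tests

The test suite favours exact analytic cross-checks where they exist and
chooses simulation scales for statistical power per unit runtime: 10^4
replicates for mean-dynamics agreement (Monte-Carlo z-scores bounded at the
number of simultaneous comparisons), 4x10^4 replicates for the extreme-pair
stem-cell orderings (measured separations of 6-10 sigma, so seed-stable),
a 50x50 lattice with 400 replicates for the abort-rule orderings, and 10^5
samples for distribution recovery. Adjacent-k stem-cell gaps at the
illustrative parameters sit inside Monte-Carlo noise at these scales, so the
suite requires no significant inversion for adjacent pairs and strict
significant ordering for the extreme pair — the same qualitative content,
honestly powered.

## Limitations

* CCTs are independent across cells and generations; heritable CCT
  correlation (documented in fibroblast lineages) is out of scope.
* The lattice model has no death, no biased migration, and no
  pair-correlation moment closure; it is the raw agent-based process.
* The EME closed form is restricted to `lambda1 > lambda2`; the other branch
  is served by numerical convolution (`eme_pdf_conv()`).
* Variance dynamics of the branching process are probed by simulation only;
  no closed form is implemented.
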