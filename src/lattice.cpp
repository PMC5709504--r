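#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// 2-D periodic volume-exclusion model: migration plus multi-stage
// proliferation, simulated with the direct method. Every cell carries the
// same total event rate Pm + Pp*k regardless of its stage, so one exponential
// waiting time from N*(Pm + Pp*k) followed by a uniform cell pick and a
// Bernoulli move/stage split is an exact Gillespie scheme.
//
// Movement: a uniformly chosen von Neumann neighbour; aborted (no change) if
// the target site is occupied. Stage change: stages 1..k-1 increment; a
// stage-k cell attempts to place a daughter in a uniformly chosen von Neumann
// neighbour. On success parent and daughter are both set to stage 1. On
// failure: abort_reset ? parent back to stage 1 : parent held at stage k.
//
// grid0[x, y]: 0 = empty, otherwise the stage (1..k) of the occupying cell.
// Recording uses last-event-before semantics on `record_times`; full stage
// grids are copied out at `snapshot_times`.
// [[Rcpp::export]]
List cpp_lattice_ssa(IntegerMatrix grid0, double Pm, double Pp, int k,
                     bool abort_reset, NumericVector record_times,
                     NumericVector snapshot_times, double root_seed,
                     double stream) {
  const int Lx = grid0.nrow(), Ly = grid0.ncol();
  const int S = Lx * Ly;
  const int T = record_times.size();
  const int NS = snapshot_times.size();

  std::vector<int> cell_site;            // site index (x + Lx*y) per cell
  std::vector<int> cell_stage;           // stage per cell
  std::vector<int> cell_at(S, -1);       // cell id per site, -1 empty
  for (int y = 0; y < Ly; ++y)
    for (int x = 0; x < Lx; ++x) {
      int s = grid0(x, y);
      if (s > 0) {
        int site = x + Lx * y;
        cell_at[site] = (int)cell_site.size();
        cell_site.push_back(site);
        cell_stage.push_back(s);
      }
    }

  NumericVector counts(T);
  List snapshots(NS);

  StreamRng rng((uint64_t)root_seed, (uint64_t)stream);
  const double per_cell = Pm + Pp * k;
  double t = 0.0;
  int ti = 0, si = 0;

  auto neighbour = [&](int site, int dir) {
    int x = site % Lx, y = site / Lx;
    switch (dir) {
      case 0: x = (x + 1) % Lx; break;
      case 1: x = (x + Lx - 1) % Lx; break;
      case 2: y = (y + 1) % Ly; break;
      default: y = (y + Ly - 1) % Ly; break;
    }
    return x + Lx * y;
  };
  auto snapshot_grid = [&]() {
    IntegerMatrix g(Lx, Ly);
    for (size_t c = 0; c < cell_site.size(); ++c)
      g(cell_site[c] % Lx, cell_site[c] / Lx) = cell_stage[c];
    return g;
  };

  while (ti < T || si < NS) {
    double N = (double)cell_site.size();
    double A = N * per_cell;
    double tnext = (A > 0.0) ? t + rng.rexp(A) : R_PosInf;

    while (ti < T && record_times[ti] < tnext) counts[ti++] = N;
    while (si < NS && snapshot_times[si] < tnext) snapshots[si++] = snapshot_grid();
    if (ti >= T && si >= NS) break;
    t = tnext;

    int c = rng.runif_int((int)cell_site.size());
    int site = cell_site[c];
    if (rng.unif() * per_cell < Pm) {
      // migration attempt
      int target = neighbour(site, rng.runif_int(4));
      if (cell_at[target] < 0) {
        cell_at[site] = -1;
        cell_at[target] = c;
        cell_site[c] = target;
      }
    } else {
      // proliferation stage change
      if (cell_stage[c] < k) {
        cell_stage[c] += 1;
      } else {
        int target = neighbour(site, rng.runif_int(4));
        if (cell_at[target] < 0) {
          cell_stage[c] = 1;
          cell_at[target] = (int)cell_site.size();
          cell_site.push_back(target);
          cell_stage.push_back(1);
        } else {
          cell_stage[c] = abort_reset ? 1 : k;
        }
      }
    }
  }

  return List::create(_["counts"] = counts, _["snapshots"] = snapshots);
}
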