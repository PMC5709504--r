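#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// Exact direct-method SSA for a serial stage chain with a division/fate event
// at the final stage.
//
// Stage i has propensity rates[i] * x[i]. Firing stage i < k-1 moves one cell
// to stage i+1. Firing the final stage removes the firing cell and draws a
// fate f with probability fate_probs[f]; the fate adds fate_stage1[f] fresh
// stage-1 cells and fate_prog[f] inert progenitor cells.
//
// The plain pure-birth chain (one final-stage cell -> two stage-1 cells) is
// the single fate {stage1 = 2, prog = 0}.
//
// Recording uses last-event-before semantics: the state reported at a record
// time is the state immediately before the first event past that time.
//
// Returns per-replicate totals and progenitor counts at the record times,
// stage-count sums and sums of squares across replicates, the first time the
// running maximum of the total reached `threshold`, the time of the first
// final-stage (division) firing, and total fate counts.
// [[Rcpp::export]]
List cpp_stage_ssa(NumericVector rates, NumericVector fate_probs,
                   IntegerVector fate_stage1, IntegerVector fate_prog,
                   IntegerVector x0, NumericVector record_times,
                   int reps, double threshold, double root_seed) {
  const int k = rates.size();
  const int T = record_times.size();
  const int nf = fate_probs.size();

  NumericMatrix totals(reps, T);
  NumericMatrix progs(reps, T);
  NumericMatrix stage_sum(T, k);
  NumericMatrix stage_sumsq(T, k);
  NumericVector fp_time(reps, R_PosInf);
  NumericVector first_fate(reps, R_PosInf);
  NumericVector fate_counts(nf);

  std::vector<double> x(k);

  for (int rep = 0; rep < reps; ++rep) {
    StreamRng rng((uint64_t)root_seed, (uint64_t)rep);
    double total = 0.0, prog = 0.0;
    for (int i = 0; i < k; ++i) { x[i] = x0[i]; total += x[i]; }
    double maxtot = total;
    if (maxtot >= threshold) fp_time[rep] = 0.0;
    double t = 0.0;
    int ti = 0;
    bool seen_fate = false;

    while (ti < T) {
      double A = 0.0;
      for (int i = 0; i < k; ++i) A += rates[i] * x[i];
      double tnext = (A > 0.0) ? t + rng.rexp(A) : R_PosInf;

      while (ti < T && record_times[ti] < tnext) {
        totals(rep, ti) = total;
        progs(rep, ti) = prog;
        for (int i = 0; i < k; ++i) {
          stage_sum(ti, i) += x[i];
          stage_sumsq(ti, i) += x[i] * x[i];
        }
        ++ti;
      }
      if (ti >= T) break;
      t = tnext;

      double u = rng.unif() * A;
      int i = 0;
      double c = rates[0] * x[0];
      while (u > c && i < k - 1) { ++i; c += rates[i] * x[i]; }

      if (i < k - 1) {
        x[i] -= 1.0;
        x[i + 1] += 1.0;
      } else {
        x[k - 1] -= 1.0;
        int f = 0;
        if (nf > 1) {
          double v = rng.unif();
          double cp = fate_probs[0];
          while (v > cp && f < nf - 1) { ++f; cp += fate_probs[f]; }
        }
        fate_counts[f] += 1.0;
        x[0] += fate_stage1[f];
        prog += fate_prog[f];
        total += fate_stage1[f] - 1.0;
        if (!seen_fate) { first_fate[rep] = t; seen_fate = true; }
        if (total > maxtot) {
          maxtot = total;
          if (maxtot >= threshold && !R_FINITE(fp_time[rep])) fp_time[rep] = t;
        }
      }
    }
  }

  return List::create(_["totals"] = totals, _["progenitors"] = progs,
                      _["stage_sum"] = stage_sum, _["stage_sumsq"] = stage_sumsq,
                      _["fp_time"] = fp_time, _["first_fate_time"] = first_fate,
                      _["fate_counts"] = fate_counts);
}
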