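#include <Rcpp.h>
using namespace Rcpp;

// Nick-translation junction engine.
//
// A junction is the boundary between the 3' end of an upstream Okazaki
// fragment and the 5' end of its downstream neighbour.  It is represented as
// a genome *boundary* coordinate (0-based, half-open convention).  A junction
// advancing in direction dir = +1 occupies boundary x and next removes the
// base at genome position x; with dir = -1 it next removes the base at x - 1.
// Each successful cycle displaces Uniform{dmin..dmax} nucleotides; the
// per-cycle success probability is p_continue * exp(-pen[base]) evaluated at
// the base about to be removed.  On the first failure the junction pauses.
//
// R's RNG is used throughout (RNGScope via Rcpp attributes), so set.seed()
// in R makes every run reproducible.

static inline double pass_prob(const NumericVector &pen, double base,
                               double p_continue) {
  R_xlen_t i = (R_xlen_t)base;
  if (i < 0 || i >= pen.size()) return p_continue;  // outside profile: free DNA
  return p_continue * std::exp(-pen[i]);
}

// advance one junction through up to n_cycles cycles, stopping at the first
// failed cycle or when the bound is reached; returns the new boundary.
static double advance(double cur, int dir, double bound, long n_cycles,
                      const NumericVector &pen, double p_continue,
                      int dmin, int dmax, double hard_stop,
                      bool has_hard_stop) {
  for (long c = 0; c < n_cycles; ++c) {
    if (cur == bound) break;
    if (has_hard_stop && dir * (cur - hard_stop) >= 0) break;
    double base = (dir > 0) ? cur : cur - 1;
    if (unif_rand() >= pass_prob(pen, base, p_continue)) break;
    int step = dmin;
    if (dmax > dmin)
      step = dmin + (int)std::floor(unif_rand() * (dmax - dmin + 1));
    if (step > dmax) step = dmax;  // guard against unif_rand() == 1
    cur += dir * step;
    if (dir > 0 ? (cur > bound) : (cur < bound)) cur = bound;
    if (has_hard_stop && dir * (cur - hard_stop) > 0) cur = hard_stop;
  }
  return cur;
}

// [[Rcpp::export]]
NumericVector cpp_nick_translate(NumericVector pos, IntegerVector dir,
                                 NumericVector bound, double n_cycles,
                                 NumericVector pen, double p_continue,
                                 int dmin, int dmax) {
  R_xlen_t n = pos.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = advance(pos[i], dir[i], bound[i], (long)n_cycles, pen,
                     p_continue, dmin, dmax, 0.0, false);
  return out;
}

// Full junction life cycle for one cell.
//
// Each junction is born when the fork primes the next fragment upstream of
// it.  At birth it performs a replication-coupled burst of cycles (geometric
// stopping: cycles continue until the first failure).  Thereafter time runs
// in ticks: while ligase is present (t < t_dep) a paused, primer-removed
// junction ligates with probability p_ligate per tick and is frozen;
// otherwise it attempts Poisson(rate * tick) further cycles per tick (first
// failure ends that tick's cycles) until t_harvest.
//
// prem is the boundary at/beyond which the RNA primer of the downstream
// fragment has been fully removed: primer_removed <=> dir * (cur - prem) >= 0.
// If nt_after_primer is false the junction never advances beyond prem.
//
// [[Rcpp::export]]
List cpp_run_junctions(NumericVector cur0, IntegerVector dir,
                       NumericVector bound, NumericVector prem,
                       NumericVector birth, IntegerVector chrom_idx,
                       List penalties, double p_continue, int dmin, int dmax,
                       double p_ligate, double rate, double t_dep,
                       double t_harvest, double tick, bool nt_after_primer) {
  R_xlen_t n = cur0.size();
  NumericVector fin(n);
  LogicalVector lig(n);
  NumericVector lig_time(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    NumericVector pen = penalties[chrom_idx[i] - 1];
    double cur = cur0[i];
    bool ligated = false;
    double ltime = NA_REAL;
    double hstop = prem[i];
    bool use_h = !nt_after_primer;
    // replication-coupled burst
    cur = advance(cur, dir[i], bound[i], LONG_MAX, pen, p_continue,
                  dmin, dmax, hstop, use_h);
    // tick loop
    for (double t = birth[i]; t < t_harvest - 1e-9; t += tick) {
      bool ligase = t < t_dep;
      bool primer_removed = dir[i] * (cur - prem[i]) >= 0;
      if (ligase && primer_removed && p_ligate > 0 &&
          unif_rand() < p_ligate) {
        ligated = true; ltime = t; break;
      }
      if (rate > 0) {
        double dt = std::min(tick, t_harvest - t);
        int nc = (int)R::rpois(rate * dt);
        if (nc > 0)
          cur = advance(cur, dir[i], bound[i], nc, pen, p_continue,
                        dmin, dmax, hstop, use_h);
      }
    }
    fin[i] = cur; lig[i] = ligated; lig_time[i] = ltime;
  }
  return List::create(_["final"] = fin, _["ligated"] = lig,
                      _["lig_time"] = lig_time);
}
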