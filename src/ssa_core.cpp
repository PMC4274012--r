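#include <Rcpp.h>
using namespace Rcpp;

// Exact SSA for G independent reporter genes inside one cell, between two
// scheduled wall-clock times (divisions and interventions are handled by the
// caller; no division occurs inside a segment).
//
// Reaction channels per gene (propensities):
//   0 chromatin switch : k_open if CLOSED, k_close if OPEN, 0 if clamped
//   1 burst initiation : k_burst if OPEN else 0 (burst adds 1+Geom(q) mRNAs)
//   2 mRNA decay       : m * delta_m
//   3 translation      : m * k_tl  (adds one protein, mRNA unchanged)
//   4 protein decay    : p * delta_p
//
// `par` is a 7 x G matrix with rows
//   k_open, k_close, k_burst, burst_q, k_tl, delta_m, delta_p
// `clamp` per gene: 0 = free, 1 = clamped OPEN, 2 = clamped CLOSED.
// `grid` holds sample times in [t0, t1]; the piecewise-constant state is
// sampled by last-value-carried-forward.
//
// Uses R's RNG stream so set.seed() gives bit-identical trajectories.

static const double COUNT_MAX = 1e9;

// [[Rcpp::export(name = ".ssa_segment_cpp")]]
List ssa_segment_cpp(IntegerVector chrom, IntegerVector m, IntegerVector p,
                     NumericMatrix par, IntegerVector clamp,
                     double t0, double t1, NumericVector grid) {
  const int G = chrom.size();
  if (par.ncol() != G || m.size() != G || p.size() != G || clamp.size() != G)
    stop("inconsistent state/parameter dimensions");
  if (t1 < t0) stop("segment end precedes start");
  for (int g = 0; g < G; ++g) {
    if (m[g] < 0 || p[g] < 0) stop("invalid-state: negative molecule count");
    for (int r = 0; r < 7; ++r)
      if (!R_finite(par(r, g)) || par(r, g) < 0)
        stop("invalid-parameter: rates must be finite and non-negative");
  }

  std::vector<int> ch(chrom.begin(), chrom.end());
  std::vector<double> mm(m.begin(), m.end()), pp(p.begin(), p.end());
  const int ns = grid.size();
  IntegerMatrix ch_out(G, ns);
  NumericMatrix m_out(G, ns), p_out(G, ns);

  std::vector<double> a(5 * G);
  double t = t0;
  int gi = 0;

  for (;;) {
    double a0 = 0.0;
    for (int g = 0; g < G; ++g) {
      const int base = 5 * g;
      const bool open = ch[g] == 1;
      a[base + 0] = clamp[g] != 0 ? 0.0 : (open ? par(1, g) : par(0, g));
      a[base + 1] = open ? par(2, g) : 0.0;
      a[base + 2] = mm[g] * par(5, g);
      a[base + 3] = mm[g] * par(4, g);
      a[base + 4] = pp[g] * par(6, g);
      for (int r = 0; r < 5; ++r) a0 += a[base + r];
    }
    if (!R_finite(a0)) stop("simulation error: propensity overflow");

    double t_next = (a0 > 0.0) ? t + exp_rand() / a0 : R_PosInf;
    if (t_next > t1) {
      while (gi < ns && grid[gi] <= t1) {
        for (int g = 0; g < G; ++g) {
          ch_out(g, gi) = ch[g];
          m_out(g, gi) = mm[g];
          p_out(g, gi) = pp[g];
        }
        ++gi;
      }
      break;
    }
    while (gi < ns && grid[gi] < t_next) {
      for (int g = 0; g < G; ++g) {
        ch_out(g, gi) = ch[g];
        m_out(g, gi) = mm[g];
        p_out(g, gi) = pp[g];
      }
      ++gi;
    }
    t = t_next;

    double u = unif_rand() * a0, acc = 0.0;
    int hit = 5 * G - 1;
    for (int r = 0; r < 5 * G; ++r) {
      acc += a[r];
      if (u <= acc) { hit = r; break; }
    }
    const int g = hit / 5;
    switch (hit % 5) {
    case 0: ch[g] = 1 - ch[g]; break;
    case 1: {
      double q = par(3, g);
      double size = 1.0 + (q < 1.0 ? R::rgeom(q) : 0.0);
      mm[g] += size;
      break;
    }
    case 2: mm[g] -= 1.0; break;
    case 3: pp[g] += 1.0; break;
    case 4: pp[g] -= 1.0; break;
    }
    if (mm[g] > COUNT_MAX || pp[g] > COUNT_MAX)
      stop("simulation error: molecule count overflow");
  }

  return List::create(
    _["chrom"] = ch_out, _["m"] = m_out, _["p"] = p_out,
    _["chrom_end"] = IntegerVector(ch.begin(), ch.end()),
    _["m_end"] = NumericVector(mm.begin(), mm.end()),
    _["p_end"] = NumericVector(pp.begin(), pp.end()));
}
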