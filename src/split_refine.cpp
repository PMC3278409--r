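#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Module score for a bipartition: mean of the m largest squared pooled-variance
// t statistics, with an additive variance floor s0 stabilising near-constant
// genes. All heavy loops live here; the R layer owns seeding and bookkeeping.

namespace {

struct GeneSums {
  std::vector<double> tot;    // per-gene sum over all samples
  std::vector<double> totsq;  // per-gene sum of squares
};

GeneSums precompute(const NumericMatrix& X) {
  const int G = X.nrow(), n = X.ncol();
  GeneSums gs;
  gs.tot.assign(G, 0.0);
  gs.totsq.assign(G, 0.0);
  for (int s = 0; s < n; ++s) {
    for (int g = 0; g < G; ++g) {
      double v = X(g, s);
      gs.tot[g] += v;
      gs.totsq[g] += v * v;
    }
  }
  return gs;
}

// t^2 for every gene given class-1 sums; buf is overwritten.
void tsq_fill(const GeneSums& gs, const std::vector<double>& S1,
              int n, int n1, double s0, std::vector<double>& buf) {
  const int G = (int)gs.tot.size();
  const int n0 = n - n1;
  const double inv = 1.0 / n1 + 1.0 / n0;
  for (int g = 0; g < G; ++g) {
    const double m1 = S1[g] / n1;
    const double m0 = (gs.tot[g] - S1[g]) / n0;
    double ssw = gs.totsq[g] - n1 * m1 * m1 - n0 * m0 * m0;
    if (ssw < 0) ssw = 0;
    const double sp2 = ssw / (n - 2);
    const double d = m1 - m0;
    buf[g] = d * d / ((sp2 + s0) * inv);
  }
}

double topm_mean(std::vector<double>& buf, int m) {
  const int G = (int)buf.size();
  const int mm = std::min(m, G);
  std::nth_element(buf.begin(), buf.begin() + mm - 1, buf.end(),
                   std::greater<double>());
  double s = 0;
  for (int g = 0; g < mm; ++g) s += buf[g];
  return s / mm;
}

double score_of(const GeneSums& gs, const std::vector<double>& S1,
                int n, int n1, int m, double s0, std::vector<double>& buf) {
  tsq_fill(gs, S1, n, n1, s0, buf);
  return topm_mean(buf, m);
}

// Greedy single-sample reassignment until no flip improves the score.
double refine_one(const NumericMatrix& X, const GeneSums& gs,
                  std::vector<int>& lab, int m, double s0,
                  int min_group, int max_sweeps) {
  const int G = X.nrow(), n = X.ncol();
  std::vector<double> S1(G, 0.0), buf(G);
  int n1 = 0;
  for (int s = 0; s < n; ++s) {
    if (lab[s] == 1) {
      ++n1;
      for (int g = 0; g < G; ++g) S1[g] += X(g, s);
    }
  }
  double cur = score_of(gs, S1, n, n1, m, s0, buf);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool moved = false;
    for (int s = 0; s < n; ++s) {
      const int new1 = lab[s] == 1 ? n1 - 1 : n1 + 1;
      const int new0 = n - new1;
      if (new1 < min_group || new0 < min_group || new1 < 2 || new0 < 2)
        continue;
      const double sign = lab[s] == 1 ? -1.0 : 1.0;
      for (int g = 0; g < G; ++g) S1[g] += sign * X(g, s);
      const double cand = score_of(gs, S1, n, new1, m, s0, buf);
      if (cand > cur + 1e-12) {
        cur = cand;
        n1 = new1;
        lab[s] = 1 - lab[s];
        moved = true;
      } else {
        for (int g = 0; g < G; ++g) S1[g] -= sign * X(g, s);
      }
    }
    if (!moved) break;
  }
  return cur;
}

} // namespace

// [[Rcpp::export]]
List cpp_split_score(NumericMatrix X, IntegerVector labels, int m, double s0) {
  const int G = X.nrow(), n = X.ncol();
  GeneSums gs = precompute(X);
  std::vector<double> S1(G, 0.0);
  int n1 = 0;
  for (int s = 0; s < n; ++s) {
    if (labels[s] == 1) {
      ++n1;
      for (int g = 0; g < G; ++g) S1[g] += X(g, s);
    }
  }
  const int n0 = n - n1;
  const double inv = 1.0 / n1 + 1.0 / n0;
  NumericVector t(G);
  std::vector<double> buf(G);
  for (int g = 0; g < G; ++g) {
    const double m1 = S1[g] / n1;
    const double m0 = (gs.tot[g] - S1[g]) / n0;
    double ssw = gs.totsq[g] - n1 * m1 * m1 - n0 * m0 * m0;
    if (ssw < 0) ssw = 0;
    const double sp2 = ssw / (n - 2);
    t[g] = (m1 - m0) / std::sqrt((sp2 + s0) * inv);
    buf[g] = t[g] * t[g];
  }
  const double sc = topm_mean(buf, m);
  return List::create(_["score"] = sc, _["t"] = t);
}

// [[Rcpp::export]]
List cpp_refine_many(NumericMatrix X, IntegerMatrix seeds, int m, double s0,
                     int min_group, int max_sweeps) {
  const int n = X.ncol(), K = seeds.ncol();
  GeneSums gs = precompute(X);
  IntegerMatrix out(n, K);
  NumericVector scores(K);
  std::vector<int> lab(n);
  for (int k = 0; k < K; ++k) {
    for (int s = 0; s < n; ++s) lab[s] = seeds(s, k);
    scores[k] = refine_one(X, gs, lab, m, s0, min_group, max_sweeps);
    for (int s = 0; s < n; ++s) out(s, k) = lab[s];
  }
  return List::create(_["labels"] = out, _["scores"] = scores);
}
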