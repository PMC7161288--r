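#include <Rcpp.h>
using namespace Rcpp;

// Log-space machinery for conditional (CML) inference in polytomous Rasch
// models. A model is represented as a set of independent "blocks": single
// items, or composite super-items formed by a locally dependent item pair.
// Block b has cells c = 1..C_b, each with an integer score contribution
// s_b[c] and a log-weight w_b[c] (alpha + lambda + delta terms). All
// conditional quantities follow from elementary symmetric functions (ESF)
// over blocks, computed strictly in log space.

static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// ESF over a subset of blocks (mask[b] == true -> include block b).
static std::vector<double> esf_subset(const std::vector<IntegerVector>& s,
                                      const std::vector<NumericVector>& w,
                                      const std::vector<bool>& mask) {
  std::vector<double> g(1, 0.0); // log gamma_0 = 0 for the empty product
  for (size_t b = 0; b < s.size(); ++b) {
    if (!mask[b]) continue;
    int smax = 0;
    for (int c = 0; c < s[b].size(); ++c) if (s[b][c] > smax) smax = s[b][c];
    std::vector<double> out(g.size() + smax, R_NegInf);
    for (int c = 0; c < s[b].size(); ++c) {
      const int sc = s[b][c];
      const double wc = w[b][c];
      if (wc == R_NegInf) continue;
      for (size_t r = 0; r < g.size(); ++r) {
        if (g[r] == R_NegInf) continue;
        out[r + sc] = logadd(out[r + sc], g[r] + wc);
      }
    }
    g.swap(out);
  }
  return g;
}

static void unpack(const List& s_list, const List& w_list,
                   std::vector<IntegerVector>& s, std::vector<NumericVector>& w) {
  int B = s_list.size();
  s.reserve(B); w.reserve(B);
  for (int b = 0; b < B; ++b) {
    s.push_back(as<IntegerVector>(s_list[b]));
    w.push_back(as<NumericVector>(w_list[b]));
  }
}

// [[Rcpp::export(name = ".esf_log_cpp")]]
NumericVector esf_log_cpp(List s_list, List w_list) {
  std::vector<IntegerVector> s; std::vector<NumericVector> w;
  unpack(s_list, w_list, s, w);
  std::vector<bool> mask(s.size(), true);
  std::vector<double> g = esf_subset(s, w, mask);
  return NumericVector(g.begin(), g.end());
}

// Conditional cell posteriors P(block b in cell c | R = r) for all b, c, r,
// plus the log normalizer logK[r] (the full ESF).
// [[Rcpp::export(name = ".block_posteriors_cpp")]]
List block_posteriors_cpp(List s_list, List w_list) {
  std::vector<IntegerVector> s; std::vector<NumericVector> w;
  unpack(s_list, w_list, s, w);
  const int B = s.size();
  std::vector<bool> mask(B, true);
  std::vector<double> g = esf_subset(s, w, mask);
  const int RR = g.size(); // Rmax + 1
  List P(B);
  for (int b = 0; b < B; ++b) {
    std::vector<bool> m2(B, true); m2[b] = false;
    std::vector<double> d = esf_subset(s, w, m2);
    NumericMatrix Pb(s[b].size(), RR);
    for (int c = 0; c < s[b].size(); ++c) {
      const int sc = s[b][c];
      const double wc = w[b][c];
      for (int r = 0; r < RR; ++r) {
        const int rem = r - sc;
        if (wc == R_NegInf || rem < 0 || rem >= (int)d.size() ||
            d[rem] == R_NegInf || g[r] == R_NegInf) {
          Pb(c, r) = 0.0;
        } else {
          Pb(c, r) = std::exp(wc + d[rem] - g[r]);
        }
      }
    }
    P[b] = Pb;
  }
  return List::create(_["logK"] = NumericVector(g.begin(), g.end()),
                      _["P"] = P);
}

// Normalizing part of the conditional log-likelihood and expected cell
// counts for one covariate profile. counts[r] = number of persons with
// total score r (0-based index r = 0..Rmax).
// Returns: norm = sum_r counts[r] * logK[r];
//          M[[b]][c] = sum_r counts[r] * P(block b cell c | r).
// [[Rcpp::export(name = ".cml_expected_cpp")]]
List cml_expected_cpp(List s_list, List w_list, NumericVector counts) {
  std::vector<IntegerVector> s; std::vector<NumericVector> w;
  unpack(s_list, w_list, s, w);
  const int B = s.size();
  std::vector<bool> mask(B, true);
  std::vector<double> g = esf_subset(s, w, mask);
  const int RR = g.size();
  if (counts.size() != RR) stop("counts has wrong length");
  double norm = 0.0;
  for (int r = 0; r < RR; ++r)
    if (counts[r] != 0.0) norm += counts[r] * g[r];
  List M(B);
  for (int b = 0; b < B; ++b) {
    std::vector<bool> m2(B, true); m2[b] = false;
    std::vector<double> d = esf_subset(s, w, m2);
    NumericVector Mb(s[b].size());
    for (int c = 0; c < s[b].size(); ++c) {
      const int sc = s[b][c];
      const double wc = w[b][c];
      if (wc == R_NegInf) continue;
      double acc = 0.0;
      for (int r = 0; r < RR; ++r) {
        if (counts[r] == 0.0) continue;
        const int rem = r - sc;
        if (rem < 0 || rem >= (int)d.size() || d[rem] == R_NegInf) continue;
        acc += counts[r] * std::exp(wc + d[rem] - g[r]);
      }
      Mb[c] = acc;
    }
    M[b] = Mb;
  }
  return List::create(_["norm"] = norm, _["M"] = M);
}

// Draw response patterns conditional on total scores. r_vec gives the total
// score of each draw; returns a matrix (length(r_vec) x B) of 1-based cell
// indices. Sequential sampling over blocks; the per-block conditional cell
// distributions given the remaining score are precomputed from suffix ESF
// tables, so each draw only does cumulative-probability lookups. Uses R's
// RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".sample_conditional_cpp")]]
IntegerMatrix sample_conditional_cpp(List s_list, List w_list, IntegerVector r_vec) {
  std::vector<IntegerVector> s; std::vector<NumericVector> w;
  unpack(s_list, w_list, s, w);
  const int B = s.size();
  const int N = r_vec.size();
  // suffix[b] = ESF over blocks b+1..B-1 (suffix[B-1] = {0})
  std::vector<std::vector<double> > suffix(B);
  {
    std::vector<double> acc(1, 0.0);
    for (int b = B - 1; b >= 0; --b) {
      suffix[b] = acc;
      int smax = 0;
      for (int c = 0; c < s[b].size(); ++c) if (s[b][c] > smax) smax = s[b][c];
      std::vector<double> out(acc.size() + smax, R_NegInf);
      for (int c = 0; c < s[b].size(); ++c) {
        const int sc = s[b][c];
        const double wc = w[b][c];
        if (wc == R_NegInf) continue;
        for (size_t r = 0; r < acc.size(); ++r) {
          if (acc[r] == R_NegInf) continue;
          out[r + sc] = logadd(out[r + sc], acc[r] + wc);
        }
      }
      acc.swap(out);
    }
  }
  // cum[b][rem * C + c]: cumulative (unnormalized) P(cell <= c | remaining
  // score rem when reaching block b)
  std::vector<std::vector<double> > cum(B);
  std::vector<int> remmax(B);
  for (int b = 0; b < B; ++b) {
    const int C = s[b].size();
    int smax = 0;
    for (int c = 0; c < C; ++c) if (s[b][c] > smax) smax = s[b][c];
    const int RR = (int)suffix[b].size() + smax; // rem in 0..RR-1
    remmax[b] = RR;
    cum[b].assign((size_t)RR * C, 0.0);
    for (int rem = 0; rem < RR; ++rem) {
      double mx = R_NegInf;
      for (int c = 0; c < C; ++c) {
        const int r2 = rem - s[b][c];
        if (w[b][c] != R_NegInf && r2 >= 0 && r2 < (int)suffix[b].size() &&
            suffix[b][r2] != R_NegInf) {
          const double lp = w[b][c] + suffix[b][r2];
          if (lp > mx) mx = lp;
        }
      }
      double acc2 = 0.0;
      for (int c = 0; c < C; ++c) {
        const int r2 = rem - s[b][c];
        if (mx != R_NegInf && w[b][c] != R_NegInf && r2 >= 0 &&
            r2 < (int)suffix[b].size() && suffix[b][r2] != R_NegInf)
          acc2 += std::exp(w[b][c] + suffix[b][r2] - mx);
        cum[b][(size_t)rem * C + c] = acc2;
      }
    }
  }
  IntegerMatrix res(N, B);
  for (int v = 0; v < N; ++v) {
    int rem = r_vec[v];
    for (int b = 0; b < B; ++b) {
      const int C = s[b].size();
      if (rem < 0 || rem >= remmax[b]) stop("conditional sampler: unreachable score");
      const double* row = &cum[b][(size_t)rem * C];
      const double tot = row[C - 1];
      if (tot <= 0.0) stop("conditional sampler: unreachable score");
      const double u = unif_rand() * tot;
      int pick = C - 1;
      for (int c = 0; c < C; ++c) if (u <= row[c]) { pick = c; break; }
      res(v, b) = pick + 1;
      rem -= s[b][pick];
    }
  }
  return res;
}
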