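#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Connected components of supra-threshold (channel, time) cells.
// Connectivity: temporal adjacency within a channel, or channel adjacency
// (adj, 1-based neighbor lists) at the same time point. For two-sided maps
// (tail = 0) positive and negative exceedances are clustered separately.
// Returns labels (0 = sub-threshold) and per-cluster masses/signs.
typedef std::vector< std::vector<int> > AdjVec;

static AdjVec adj_to_vec(const List &adj) {
  AdjVec out(adj.size());
  for (int i = 0; i < adj.size(); ++i) {
    IntegerVector nb = adj[i];
    out[i].assign(nb.begin(), nb.end());
  }
  return out;
}

static void flood(const NumericMatrix &stat, IntegerMatrix &lab,
                  const AdjVec &adj, int ch0, int t0, int id, double thr,
                  int sign, double &mass, std::vector<int> &stack_c,
                  std::vector<int> &stack_t) {
  const int nt = stat.ncol();
  stack_c.clear(); stack_t.clear();
  stack_c.push_back(ch0); stack_t.push_back(t0);
  lab(ch0, t0) = id;
  while (!stack_c.empty()) {
    int c = stack_c.back(); stack_c.pop_back();
    int t = stack_t.back(); stack_t.pop_back();
    mass += stat(c, t);
    for (int dt = -1; dt <= 1; dt += 2) {
      int t2 = t + dt;
      if (t2 >= 0 && t2 < nt && lab(c, t2) == 0 &&
          sign * stat(c, t2) > thr) {
        lab(c, t2) = id;
        stack_c.push_back(c); stack_t.push_back(t2);
      }
    }
    const std::vector<int> &nb = adj[c];
    for (size_t k = 0; k < nb.size(); ++k) {
      int c2 = nb[k] - 1;
      if (lab(c2, t) == 0 && sign * stat(c2, t) > thr) {
        lab(c2, t) = id;
        stack_c.push_back(c2); stack_t.push_back(t);
      }
    }
  }
}

// [[Rcpp::export]]
List form_clusters_cpp(NumericMatrix stat, double threshold, List adj_list,
                       int tail) {
  // tail: 0 = two-sided (positive and negative separately), 1 = positive only
  AdjVec adj = adj_to_vec(adj_list);
  const int nch = stat.nrow(), nt = stat.ncol();
  IntegerMatrix lab(nch, nt);
  std::vector<double> masses;
  std::vector<int> signs;
  std::vector<int> sc, st;
  int id = 0;
  for (int s = 1; s >= (tail == 0 ? -1 : 1); s -= 2) {
    for (int c = 0; c < nch; ++c) {
      for (int t = 0; t < nt; ++t) {
        if (lab(c, t) == 0 && s * stat(c, t) > threshold) {
          ++id;
          double mass = 0.0;
          flood(stat, lab, adj, c, t, id, threshold, s, mass, sc, st);
          masses.push_back(mass);
          signs.push_back(s);
        }
      }
    }
  }
  return List::create(_["labels"] = lab, _["mass"] = wrap(masses),
                      _["sign"] = wrap(signs));
}

static double max_abs_mass(const NumericMatrix &stat, double thr,
                           const AdjVec &adj, int tail, IntegerMatrix &lab,
                           std::vector<int> &sc, std::vector<int> &st) {
  std::fill(lab.begin(), lab.end(), 0);
  const int nch = stat.nrow(), nt = stat.ncol();
  double best = 0.0;
  int id = 0;
  for (int s = 1; s >= (tail == 0 ? -1 : 1); s -= 2) {
    for (int c = 0; c < nch; ++c) {
      for (int t = 0; t < nt; ++t) {
        if (lab(c, t) == 0 && s * stat(c, t) > thr) {
          ++id;
          double mass = 0.0;
          flood(stat, lab, adj, c, t, id, thr, s, mass, sc, st);
          if (std::fabs(mass) > best) best = std::fabs(mass);
        }
      }
    }
  }
  return best;
}

// one-sample t map over columns of X (n x cells) given signs
static void t_map(const NumericMatrix &X, const NumericVector &s2sum,
                  const std::vector<double> &signs, NumericMatrix &out) {
  const int n = X.nrow(), p = X.ncol();
  const int nch = out.nrow();
  const double nn = (double)n;
  for (int j = 0; j < p; ++j) {
    double sum = 0.0;
    for (int i = 0; i < n; ++i) sum += signs[i] * X(i, j);
    double m = sum / nn;
    double var = (s2sum[j] - nn * m * m) / (nn - 1.0);
    double t = 0.0;
    if (var > 0) t = m / std::sqrt(var / nn);
    out[j] = t;  // column-major fill matches cells = ch-major layout
    (void)nch;
  }
}

// Paired-t (sign-flip) cluster permutation null: X holds within-subject
// difference ERPs, n x (nch*nt), cells channel-major (cell = ch + nch*t).
// Returns the observed t map, observed clusters and the permutation null
// of max |cluster mass|. Uses R's RNG (respects set.seed).
// [[Rcpp::export]]
List perm_cluster_t_cpp(NumericMatrix X, int nch, int nt, double threshold,
                        List adj_list, int n_perm) {
  AdjVec adj = adj_to_vec(adj_list);
  const int n = X.nrow(), p = X.ncol();
  if (p != nch * nt) stop("cell count mismatch");
  NumericVector s2sum(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    s2sum[j] = s;
  }
  std::vector<double> signs(n, 1.0);
  NumericMatrix tmap(nch, nt);
  t_map(X, s2sum, signs, tmap);
  List obs = form_clusters_cpp(tmap, threshold, adj_list, 0);

  IntegerMatrix lab(nch, nt);
  std::vector<int> sc, st;
  NumericVector nullmax(n_perm);
  NumericMatrix pm(nch, nt);
  GetRNGstate();
  for (int b = 0; b < n_perm; ++b) {
    for (int i = 0; i < n; ++i) signs[i] = unif_rand() < 0.5 ? -1.0 : 1.0;
    t_map(X, s2sum, signs, pm);
    nullmax[b] = max_abs_mass(pm, threshold, adj, 0, lab, sc, st);
  }
  PutRNGstate();
  return List::create(_["stat_map"] = tmap, _["clusters"] = obs,
                      _["null_max_mass"] = nullmax);
}

// one-way repeated-measures F map for k=3 conditions.
// X1, X2, X3: n x cells condition matrices; perm[i] in {0,1,2,...} selects
// the within-subject label rotation/permutation for subject i (index into
// the 6 permutations of 3 labels).
static const int PERM3[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
};

static void f_map(const NumericMatrix &X1, const NumericMatrix &X2,
                  const NumericMatrix &X3, const std::vector<int> &perm,
                  NumericMatrix &out) {
  const int n = X1.nrow(), p = X1.ncol();
  const double k = 3.0, nn = (double)n;
  for (int j = 0; j < p; ++j) {
    double c1 = 0, c2 = 0, c3 = 0, ss = 0;
    std::vector<double> srow(n);
    for (int i = 0; i < n; ++i) {
      double v[3] = {X1(i, j), X2(i, j), X3(i, j)};
      const int *pp = PERM3[perm[i]];
      double a = v[pp[0]], b = v[pp[1]], c = v[pp[2]];
      c1 += a; c2 += b; c3 += c;
      srow[i] = a + b + c;
      ss += a * a + b * b + c * c;
    }
    double g = (c1 + c2 + c3) / (nn * k);
    double ss_cond = nn * ((c1 / nn - g) * (c1 / nn - g) +
                           (c2 / nn - g) * (c2 / nn - g) +
                           (c3 / nn - g) * (c3 / nn - g));
    double ss_subj = 0.0;
    for (int i = 0; i < n; ++i) {
      double mi = srow[i] / k - g;
      ss_subj += k * mi * mi;
    }
    double ss_tot = ss - nn * k * g * g;
    double ss_err = ss_tot - ss_cond - ss_subj;
    double df_err = (k - 1.0) * (nn - 1.0);
    double msc = ss_cond / (k - 1.0);
    double mse = ss_err / df_err;
    out[j] = mse > 0 ? msc / mse : 0.0;
  }
}

// [[Rcpp::export]]
List perm_cluster_f_cpp(NumericMatrix X1, NumericMatrix X2, NumericMatrix X3,
                        int nch, int nt, double threshold, List adj_list,
                        int n_perm) {
  AdjVec adj = adj_to_vec(adj_list);
  const int n = X1.nrow(), p = X1.ncol();
  if (p != nch * nt) stop("cell count mismatch");
  std::vector<int> perm(n, 0);
  NumericMatrix fmap(nch, nt);
  f_map(X1, X2, X3, perm, fmap);
  List obs = form_clusters_cpp(fmap, threshold, adj_list, 1);

  IntegerMatrix lab(nch, nt);
  std::vector<int> sc, st;
  NumericVector nullmax(n_perm);
  NumericMatrix pm(nch, nt);
  GetRNGstate();
  for (int b = 0; b < n_perm; ++b) {
    for (int i = 0; i < n; ++i) perm[i] = (int)(unif_rand() * 6.0) % 6;
    f_map(X1, X2, X3, perm, pm);
    nullmax[b] = max_abs_mass(pm, threshold, adj, 1, lab, sc, st);
  }
  PutRNGstate();
  return List::create(_["stat_map"] = fmap, _["clusters"] = obs,
                      _["null_max_mass"] = nullmax);
}
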