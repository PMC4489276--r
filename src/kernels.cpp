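#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Encoding conventions shared with R/encode.R:
//  * MI alphabet: 0 = gap/unknown (excluded from counts), 1..q residue states.
//  * DCA alphabet: 1..q with the gap as state q; no zeros.

// Fraction of identical positions over columns where both rows are non-gap.
// Encoding: 0 = gap, -1 = unknown 'X' (non-gap but never matching),
// 1..q residue states. 0 when no comparable column.
static double pair_identity(const IntegerMatrix& x, int r, int s) {
  const int L = x.ncol();
  int match = 0, comp = 0;
  for (int c = 0; c < L; ++c) {
    int a = x(r, c), b = x(s, c);
    if (a != 0 && b != 0) {
      ++comp;
      if (a == b && a > 0) ++match;
    }
  }
  return comp == 0 ? 0.0 : (double)match / comp;
}

// [[Rcpp::export]]
NumericVector cpp_identity_neighbors(IntegerMatrix x, double theta) {
  const int n = x.nrow();
  NumericVector counts(n, 1.0); // self included
  for (int r = 0; r < n; ++r)
    for (int s = r + 1; s < n; ++s)
      if (pair_identity(x, r, s) >= theta) {
        counts[r] += 1.0;
        counts[s] += 1.0;
      }
  return counts;
}

// Greedy Hobohm-1: first-fit against cluster representatives in record order.
// Returns 1-based cluster ids; representative of a cluster is its founder.
// [[Rcpp::export]]
IntegerVector cpp_hobohm1(IntegerMatrix x, double threshold) {
  const int n = x.nrow();
  IntegerVector cl(n);
  std::vector<int> reps;
  for (int r = 0; r < n; ++r) {
    int assigned = 0;
    for (size_t k = 0; k < reps.size(); ++k) {
      if (pair_identity(x, reps[k], r) >= threshold) {
        assigned = (int)k + 1;
        break;
      }
    }
    if (assigned == 0) {
      reps.push_back(r);
      assigned = (int)reps.size();
    }
    cl[r] = assigned;
  }
  return cl;
}

// Raw mutual information for every column pair, natural log.
// f_i(a): per-column weighted frequency with per-cell pseudocount lambda over
// rows non-gap at i. f_ij(a,b): pair-complete rows only (both non-gap),
// lambda per cell over q*q cells. MI(i,j) = sum f_ij log(f_ij/(f_i f_j)),
// 0*log0 := 0, clamped at 0 from below.
// [[Rcpp::export]]
NumericMatrix cpp_mi_matrix(IntegerMatrix x, NumericVector w, double lambda,
                            int q) {
  const int n = x.nrow(), L = x.ncol();
  NumericMatrix mi(L, L);
  // per-column singles
  NumericMatrix f1(q, L);
  for (int i = 0; i < L; ++i) {
    double tot = 0.0;
    for (int r = 0; r < n; ++r) {
      int a = x(r, i);
      if (a > 0) {
        f1(a - 1, i) += w[r];
        tot += w[r];
      }
    }
    double denom = q * lambda + tot;
    for (int a = 0; a < q; ++a) f1(a, i) = (lambda + f1(a, i)) / denom;
  }
  std::vector<double> joint(q * q);
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      std::fill(joint.begin(), joint.end(), 0.0);
      double tot = 0.0;
      for (int r = 0; r < n; ++r) {
        int a = x(r, i), b = x(r, j);
        if (a > 0 && b > 0) {
          joint[(a - 1) + q * (b - 1)] += w[r];
          tot += w[r];
        }
      }
      double denom = q * (double)q * lambda + tot;
      double s = 0.0;
      for (int a = 0; a < q; ++a)
        for (int b = 0; b < q; ++b) {
          double fab = (lambda + joint[a + q * b]) / denom;
          if (fab > 0.0)
            s += fab * std::log(fab / (f1(a, i) * f1(b, j)));
        }
      if (s < 0.0) s = 0.0;
      mi(i, j) = mi(j, i) = s;
    }
  }
  return mi;
}

// Negative weighted pseudo-log-likelihood and gradient of a Potts model.
// par layout: h (q x L, column-major), then for ordered pairs i<j the q x q
// coupling block e_ij(a,b) column-major (a = state at i). States in x: 1..q.
// [[Rcpp::export]]
List cpp_plm_obj_grad(NumericVector par, IntegerMatrix x, NumericVector w,
                      double lambda_h, double lambda_e, int q) {
  const int n = x.nrow(), L = x.ncol();
  const int nh = q * L;
  const int npair = L * (L - 1) / 2;
  if (par.size() != nh + npair * q * q)
    stop("parameter vector has wrong length");
  NumericVector grad(par.size());
  double value = 0.0;

  // pair block offsets: pair (i,j), i<j, index p = offset of block
  std::vector<int> poff(L * L, -1);
  {
    int p = 0;
    for (int i = 0; i < L; ++i)
      for (int j = i + 1; j < L; ++j) {
        poff[i * L + j] = nh + p * q * q;
        ++p;
      }
  }

  std::vector<double> s(L * q), prob(L * q);
  for (int r = 0; r < n; ++r) {
    const double wr = w[r];
    // s(i,a) = h_i(a) + sum_{j != i} e_ij(a, x_j)
    for (int i = 0; i < L; ++i)
      for (int a = 0; a < q; ++a) s[i * q + a] = par[a + q * i];
    for (int i = 0; i < L; ++i) {
      const int xi = x(r, i) - 1;
      for (int j = i + 1; j < L; ++j) {
        const int xj = x(r, j) - 1;
        const int off = poff[i * L + j];
        const double* blk = &par[off];
        // contribution to site i: e_ij(a, x_j)
        const double* colj = blk + q * xj;
        double* si = &s[i * q];
        for (int a = 0; a < q; ++a) si[a] += colj[a];
        // contribution to site j: e_ij(x_i, b)
        double* sj = &s[j * q];
        for (int b = 0; b < q; ++b) sj[b] += blk[xi + q * b];
      }
    }
    // per-site softmax, objective and field gradient
    for (int i = 0; i < L; ++i) {
      const int xi = x(r, i) - 1;
      double* si = &s[i * q];
      double m = si[0];
      for (int a = 1; a < q; ++a)
        if (si[a] > m) m = si[a];
      double z = 0.0;
      for (int a = 0; a < q; ++a) z += std::exp(si[a] - m);
      const double lse = m + std::log(z);
      value -= wr * (si[xi] - lse);
      double* pi = &prob[i * q];
      for (int a = 0; a < q; ++a) pi[a] = std::exp(si[a] - lse);
      for (int a = 0; a < q; ++a)
        grad[a + q * i] += wr * (pi[a] - (a == xi ? 1.0 : 0.0));
    }
    // coupling gradient
    for (int i = 0; i < L; ++i) {
      const int xi = x(r, i) - 1;
      const double* pi = &prob[i * q];
      for (int j = i + 1; j < L; ++j) {
        const int xj = x(r, j) - 1;
        const int off = poff[i * L + j];
        const double* pj = &prob[j * q];
        double* gcol = &grad[off + q * xj];
        for (int a = 0; a < q; ++a)
          gcol[a] += wr * (pi[a] - (a == xi ? 1.0 : 0.0));
        double* g = &grad[off];
        for (int b = 0; b < q; ++b)
          g[xi + q * b] += wr * (pj[b] - (b == xj ? 1.0 : 0.0));
      }
    }
  }
  // L2 regularization
  for (int k = 0; k < nh; ++k) {
    value += lambda_h * par[k] * par[k];
    grad[k] += 2.0 * lambda_h * par[k];
  }
  for (int k = nh; k < (int)par.size(); ++k) {
    value += lambda_e * par[k] * par[k];
    grad[k] += 2.0 * lambda_e * par[k];
  }
  return List::create(_["value"] = value, _["gradient"] = grad);
}

// Gibbs sampler for a Potts model with Ising-like planted couplings
// e_ij(a,b) = strength * [a == b] on the given (0-based) pairs; no fields.
// One independent chain per sequence; the state after `burnin` full sweeps is
// returned. Uses R's RNG, so set.seed() in R makes draws reproducible.
// [[Rcpp::export]]
IntegerMatrix cpp_potts_gibbs(int n_seq, int L, int q, IntegerMatrix pairs,
                              NumericVector strength, int burnin) {
  RNGScope scope;
  IntegerMatrix out(n_seq, L);
  // adjacency lists over planted pairs
  std::vector<std::vector<int> > adj(L);
  std::vector<std::vector<double> > adj_s(L);
  if (strength.size() != pairs.nrow())
    stop("one coupling strength per planted pair is required");
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0), j = pairs(p, 1);
    if (i < 0 || j < 0 || i >= L || j >= L || i == j)
      stop("planted pair out of range");
    adj[i].push_back(j);
    adj[j].push_back(i);
    adj_s[i].push_back(strength[p]);
    adj_s[j].push_back(strength[p]);
  }
  std::vector<int> x(L);
  std::vector<double> pr(q);
  for (int r = 0; r < n_seq; ++r) {
    for (int i = 0; i < L; ++i) {
      int a = (int)std::floor(unif_rand() * q);
      if (a >= q) a = q - 1;
      x[i] = a;
    }
    for (int sweep = 0; sweep < burnin; ++sweep) {
      for (int i = 0; i < L; ++i) {
        double z = 0.0;
        for (int a = 0; a < q; ++a) {
          double e = 0.0;
          for (size_t k = 0; k < adj[i].size(); ++k)
            if (x[adj[i][k]] == a) e += adj_s[i][k];
          pr[a] = std::exp(e);
          z += pr[a];
        }
        double u = unif_rand() * z, cum = 0.0;
        int pick = q - 1;
        for (int a = 0; a < q; ++a) {
          cum += pr[a];
          if (u <= cum) {
            pick = a;
            break;
          }
        }
        x[i] = pick;
      }
    }
    for (int i = 0; i < L; ++i) out(r, i) = x[i] + 1;
  }
  return out;
}

// Weighted joint frequency matrix for DCA: x has states 1..q (no zeros),
// weights w. Returns the (L*q) x (L*q) matrix F with
// F[(i-1)*q+a, (j-1)*q+b] = sum_r w_r [x_ri=a][x_rj=b] / sum_r w_r for i != j
// and the diagonal blocks diag(f_i).
// [[Rcpp::export]]
NumericMatrix cpp_pair_freqs(IntegerMatrix x, NumericVector w, int q) {
  const int n = x.nrow(), L = x.ncol();
  double W = 0.0;
  for (int r = 0; r < n; ++r) W += w[r];
  NumericMatrix F(L * q, L * q);
  for (int r = 0; r < n; ++r) {
    const double wr = w[r] / W;
    for (int i = 0; i < L; ++i) {
      const int ai = i * q + (x(r, i) - 1);
      F(ai, ai) += wr;
      for (int j = i + 1; j < L; ++j) {
        const int bj = j * q + (x(r, j) - 1);
        F(ai, bj) += wr;
        F(bj, ai) += wr;
      }
    }
  }
  return F;
}
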