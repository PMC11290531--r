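#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <string>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Felsenstein pruning over a postorder edge list with per-node rescaling.
//
// Partial likelihoods for internal nodes are kept in caller-owned buffers so
// that repeated evaluations during optimisation only recompute the nodes whose
// subtree intersects the edges whose transition matrices changed.
//
// Layouts (column-major):
//   P        [16, nedge, ncat]   P[x + 4*y] = Pr(child state y | parent state x)
//   tipdata  [npat, ntip]        1-based row index into `contrast`
//   contrast [ncontrast, 4]      partial-likelihood row per observed symbol
//   partials [4, npat, nint, ncat]
//   scalelog [npat, nint, ncat]
//
// todo_nodes: internal node ids (ape numbering, > ntip) in postorder;
// todo_ptr / todo_edges: CSR-style list of child-edge indices (0-based into the
// edge arrays) for each node in todo_nodes. Every listed node is recomputed
// from *all* of its child edges (clean children contribute cached partials).

// [[Rcpp::export]]
double C_prune(IntegerVector edge_child, IntegerVector edge_parent,
               NumericVector P, IntegerMatrix tipdata, NumericMatrix contrast,
               NumericVector weights, NumericVector rootfreq,
               int ntip, int root, int ncat,
               IntegerVector todo_nodes, IntegerVector todo_ptr,
               IntegerVector todo_edges,
               NumericVector partials, NumericVector scalelog) {
  const int nedge = edge_child.size();
  const int npat = weights.size();
  const int nint = (int)(scalelog.size() / (npat * (size_t)ncat));
  const int ntodo = todo_nodes.size();
  double *pp = REAL(partials);
  double *sl = REAL(scalelog);
  double *Pp = REAL(P);
  double *ct = REAL(contrast);
  const int ncon = contrast.nrow();
  int *td = INTEGER(tipdata);

  for (int c = 0; c < ncat; ++c) {
    for (int ni = 0; ni < ntodo; ++ni) {
      const int node = todo_nodes[ni];
      const int ii = node - ntip - 1;
      double *np = pp + ((size_t)c * nint + ii) * 4 * npat;
      double *ns = sl + ((size_t)c * nint + ii) * npat;
      bool first = true;
      for (int k = todo_ptr[ni]; k < todo_ptr[ni + 1]; ++k) {
        const int e = todo_edges[k];
        const int child = edge_child[e];
        const double *Pe = Pp + ((size_t)c * nedge + e) * 16;
        if (child <= ntip) {
          const int *row = td + (size_t)(child - 1) * npat;
          if (first) {
            for (int p = 0; p < npat; ++p) {
              const int r = row[p] - 1;
              const double l0 = ct[r], l1 = ct[r + ncon],
                           l2 = ct[r + 2 * ncon], l3 = ct[r + 3 * ncon];
              double *L = np + 4 * p;
              L[0] = Pe[0] * l0 + Pe[4] * l1 + Pe[8] * l2 + Pe[12] * l3;
              L[1] = Pe[1] * l0 + Pe[5] * l1 + Pe[9] * l2 + Pe[13] * l3;
              L[2] = Pe[2] * l0 + Pe[6] * l1 + Pe[10] * l2 + Pe[14] * l3;
              L[3] = Pe[3] * l0 + Pe[7] * l1 + Pe[11] * l2 + Pe[15] * l3;
              ns[p] = 0.0;
            }
          } else {
            for (int p = 0; p < npat; ++p) {
              const int r = row[p] - 1;
              const double l0 = ct[r], l1 = ct[r + ncon],
                           l2 = ct[r + 2 * ncon], l3 = ct[r + 3 * ncon];
              double *L = np + 4 * p;
              L[0] *= Pe[0] * l0 + Pe[4] * l1 + Pe[8] * l2 + Pe[12] * l3;
              L[1] *= Pe[1] * l0 + Pe[5] * l1 + Pe[9] * l2 + Pe[13] * l3;
              L[2] *= Pe[2] * l0 + Pe[6] * l1 + Pe[10] * l2 + Pe[14] * l3;
              L[3] *= Pe[3] * l0 + Pe[7] * l1 + Pe[11] * l2 + Pe[15] * l3;
            }
          }
        } else {
          const int ci = child - ntip - 1;
          const double *cp = pp + ((size_t)c * nint + ci) * 4 * npat;
          const double *cs = sl + ((size_t)c * nint + ci) * npat;
          if (first) {
            for (int p = 0; p < npat; ++p) {
              const double *Lc = cp + 4 * p;
              const double l0 = Lc[0], l1 = Lc[1], l2 = Lc[2], l3 = Lc[3];
              double *L = np + 4 * p;
              L[0] = Pe[0] * l0 + Pe[4] * l1 + Pe[8] * l2 + Pe[12] * l3;
              L[1] = Pe[1] * l0 + Pe[5] * l1 + Pe[9] * l2 + Pe[13] * l3;
              L[2] = Pe[2] * l0 + Pe[6] * l1 + Pe[10] * l2 + Pe[14] * l3;
              L[3] = Pe[3] * l0 + Pe[7] * l1 + Pe[11] * l2 + Pe[15] * l3;
              ns[p] = cs[p];
            }
          } else {
            for (int p = 0; p < npat; ++p) {
              const double *Lc = cp + 4 * p;
              const double l0 = Lc[0], l1 = Lc[1], l2 = Lc[2], l3 = Lc[3];
              double *L = np + 4 * p;
              L[0] *= Pe[0] * l0 + Pe[4] * l1 + Pe[8] * l2 + Pe[12] * l3;
              L[1] *= Pe[1] * l0 + Pe[5] * l1 + Pe[9] * l2 + Pe[13] * l3;
              L[2] *= Pe[2] * l0 + Pe[6] * l1 + Pe[10] * l2 + Pe[14] * l3;
              L[3] *= Pe[3] * l0 + Pe[7] * l1 + Pe[11] * l2 + Pe[15] * l3;
              ns[p] += cs[p];
            }
          }
        }
        first = false;
      }
      // rescale to guard against underflow on deep trees
      for (int p = 0; p < npat; ++p) {
        double *L = np + 4 * p;
        double m = L[0];
        if (L[1] > m) m = L[1];
        if (L[2] > m) m = L[2];
        if (L[3] > m) m = L[3];
        if (m > 0.0 && R_finite(m)) {
          const double im = 1.0 / m;
          L[0] *= im; L[1] *= im; L[2] *= im; L[3] *= im;
          ns[p] += std::log(m);
        } else {
          ns[p] = R_NegInf;
        }
      }
    }
  }

  // combine categories (equal weights) at the root
  const int ri = root - ntip - 1;
  const double f0 = rootfreq[0], f1 = rootfreq[1], f2 = rootfreq[2],
               f3 = rootfreq[3];
  const double lk = std::log((double)ncat);
  double total = 0.0;
  for (int p = 0; p < npat; ++p) {
    double site;
    if (ncat == 1) {
      const double *L = pp + (size_t)ri * 4 * npat + 4 * p;
      site = std::log(f0 * L[0] + f1 * L[1] + f2 * L[2] + f3 * L[3]) +
             sl[(size_t)ri * npat + p];
    } else {
      double mx = R_NegInf;
      double v[16];
      for (int c = 0; c < ncat; ++c) {
        const double *L = pp + ((size_t)c * nint + ri) * 4 * npat + 4 * p;
        v[c] = std::log(f0 * L[0] + f1 * L[1] + f2 * L[2] + f3 * L[3]) +
               sl[((size_t)c * nint + ri) * npat + p];
        if (v[c] > mx) mx = v[c];
      }
      double s = 0.0;
      for (int c = 0; c < ncat; ++c) s += std::exp(v[c] - mx);
      site = mx + std::log(s) - lk;
    }
    total += weights[p] * site;
  }
  return total;
}

// Deduplicate site patterns restricted to a subset of tips.
// tipdata: [npat, ntip] contrast-row indices; tips: 1-based column ids.
// Returns map (1-based subpattern id per pattern) and the unique rows
// [nsub, ntips_sel] in first-appearance order.
// [[Rcpp::export]]
List C_subpatterns(IntegerMatrix tipdata, IntegerVector tips) {
  const int npat = tipdata.nrow();
  const int k = tips.size();
  std::unordered_map<std::string, int> seen;
  seen.reserve(npat * 2);
  IntegerVector map(npat);
  std::vector<int> uniq_rows;  // indices of first-appearance patterns
  std::string key(k * sizeof(int), '\0');
  for (int p = 0; p < npat; ++p) {
    char *kp = &key[0];
    for (int j = 0; j < k; ++j) {
      const int v = tipdata(p, tips[j] - 1);
      memcpy(kp, &v, sizeof(int));
      kp += sizeof(int);
    }
    auto it = seen.find(key);
    if (it == seen.end()) {
      const int id = (int)uniq_rows.size() + 1;
      seen.emplace(key, id);
      uniq_rows.push_back(p);
      map[p] = id;
    } else {
      map[p] = it->second;
    }
  }
  const int nsub = (int)uniq_rows.size();
  IntegerMatrix sub(nsub, k);
  for (int i = 0; i < nsub; ++i)
    for (int j = 0; j < k; ++j)
      sub(i, j) = tipdata(uniq_rows[i], tips[j] - 1);
  return List::create(_["map"] = map, _["sub"] = sub);
}

// Combine outside weights at a clade's stem with inside partials at the
// clade root: total lnL = sum_p w_p log sum_y W_p(y) [P_stem L_sub(map_p)](y)
// (per gamma category, categories averaged with equal weights).
//   W        [4, npat, ncat]   outside likelihood at the shift node's parent
//   lsW      [npat, ncat]      log-scale accompanying W
//   Pstem    [16, ncat]        stem-edge transition matrix (parent x -> child y
//                              at flat index x + 4*y)
//   subpart  [4, nsub, nint_sub, ncat], subscale [nsub, nint_sub, ncat]
// [[Rcpp::export]]
double C_anchor_lnl(NumericVector W, NumericVector lsW, NumericVector Pstem,
                    NumericVector subpart, NumericVector subscale,
                    int subroot_ii, int nint_sub, int nsub, int ncat,
                    IntegerVector map, NumericVector weights) {
  const int npat = weights.size();
  const double *Wp = REAL(W);
  const double *lp = REAL(lsW);
  const double *Pp = REAL(Pstem);
  const double *sp = REAL(subpart);
  const double *ss = REAL(subscale);
  std::vector<double> T(4 * (size_t)nsub * ncat);
  std::vector<double> Tsc((size_t)nsub * ncat);
  for (int c = 0; c < ncat; ++c) {
    const double *Pe = Pp + (size_t)c * 16;
    const double *Ls = sp + ((size_t)c * nint_sub + subroot_ii) * 4 * nsub;
    const double *Sc = ss + ((size_t)c * nint_sub + subroot_ii) * nsub;
    double *Tc = &T[(size_t)c * 4 * nsub];
    for (int m = 0; m < nsub; ++m) {
      const double *L = Ls + 4 * m;
      // T[y] = sum_x Pstem[y, x] L(x); y indexes the parent-side state
      Tc[4 * m + 0] = Pe[0] * L[0] + Pe[4] * L[1] + Pe[8] * L[2] + Pe[12] * L[3];
      Tc[4 * m + 1] = Pe[1] * L[0] + Pe[5] * L[1] + Pe[9] * L[2] + Pe[13] * L[3];
      Tc[4 * m + 2] = Pe[2] * L[0] + Pe[6] * L[1] + Pe[10] * L[2] + Pe[14] * L[3];
      Tc[4 * m + 3] = Pe[3] * L[0] + Pe[7] * L[1] + Pe[11] * L[2] + Pe[15] * L[3];
      Tsc[(size_t)c * nsub + m] = Sc[m];
    }
  }
  const double lk = std::log((double)ncat);
  double total = 0.0;
  for (int p = 0; p < npat; ++p) {
    const int m = map[p] - 1;
    double site;
    if (ncat == 1) {
      const double *w4 = Wp + 4 * (size_t)p;
      const double *Tc = &T[4 * (size_t)m];
      const double v = w4[0] * Tc[0] + w4[1] * Tc[1] + w4[2] * Tc[2] +
                       w4[3] * Tc[3];
      site = std::log(v) + lp[p] + Tsc[m];
    } else {
      double vv[16], mx = R_NegInf;
      for (int c = 0; c < ncat; ++c) {
        const double *w4 = Wp + ((size_t)c * npat + p) * 4;
        const double *Tc = &T[((size_t)c * nsub + m) * 4];
        const double v = w4[0] * Tc[0] + w4[1] * Tc[1] + w4[2] * Tc[2] +
                         w4[3] * Tc[3];
        vv[c] = std::log(v) + lp[(size_t)c * npat + p] +
                Tsc[(size_t)c * nsub + m];
        if (vv[c] > mx) mx = vv[c];
      }
      double sum = 0.0;
      for (int c = 0; c < ncat; ++c) sum += std::exp(vv[c] - mx);
      site = mx + std::log(sum) - lk;
    }
    total += weights[p] * site;
  }
  return total;
}
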