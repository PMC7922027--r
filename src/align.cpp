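// Geometry and assignment kernels for sequence-order-independent
// structural alignment: weighted Kabsch superposition, fragment seed
// scanning, a sparse Hungarian solver for the residue assignment step,
// and the per-seed refinement loop of align_pair().
#include <RcppArmadillo.h>
#include <vector>
#include <utility>
#include <algorithm>
#include <cmath>
#include <limits>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BIG = std::numeric_limits<double>::infinity();
// deterministic lexicographic tie-break: among score-tied matchings the
// solver prefers low (row, col) pairs; far below score resolution.
static const double TIE_EPS = 1e-10;

struct KabschFit {
  arma::mat33 R;
  arma::vec3 t;
  double rmsd;
};

// Least-squares rigid transform mapping B onto A (minimizes the
// w-weighted rmsd of R*B + t against A); rotation proper by construction.
static KabschFit kabsch_core(const arma::mat& A, const arma::mat& B,
                             const arma::vec& w) {
  const double wsum = arma::accu(w);
  arma::rowvec muA = (w.t() * A) / wsum;
  arma::rowvec muB = (w.t() * B) / wsum;
  arma::mat Ac = A.each_row() - muA;
  arma::mat Bc = B.each_row() - muB;
  arma::mat H = Bc.t() * (Ac.each_col() % w);   // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H))
    stop("SVD failure in Kabsch superposition (degenerate coordinates?)");
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  arma::mat33 R = V * arma::diagmat(arma::vec3{1.0, 1.0, d}) * U.t();
  arma::vec3 t = muA.t() - R * muB.t();
  arma::mat res = (Bc * R.t()) - Ac;
  double msd = arma::accu((arma::sum(arma::square(res), 1)) % w) / wsum;
  KabschFit out;
  out.R = R;
  out.t = t;
  out.rmsd = std::sqrt(std::max(0.0, msd));
  return out;
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& A, const arma::mat& B, const arma::vec& w) {
  KabschFit f = kabsch_core(A, B, w);
  return List::create(_["rotation"] = arma::mat(f.R),
                      _["translation"] = arma::vec(f.t),
                      _["rmsd"] = f.rmsd);
}

// Sparse min-cost assignment (Jonker-Volgenant style shortest augmenting
// paths with potentials). adj[i] lists (col, cost) options for row i; a
// per-row dummy column makes leaving any row unmatched feasible at cost 0.
// Columns are 0-based on input, shifted to 1-based internally (col 0 is
// the virtual start of the alternating path).
static std::vector<int> lap_sparse(int n, int m,
    const std::vector<std::vector<std::pair<int, double>>>& adj) {
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0), minv(m + 1, BIG);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  std::vector<char> used(m + 1, 0), seen(m + 1, 0);
  std::vector<int> touched;

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    touched.clear();
    used[0] = 1;
    touched.push_back(0);
    while (true) {
      int i0 = p[j0];
      // relax columns reachable from row i0
      for (const auto& e : adj[i0 - 1]) {
        int jj = e.first + 1;
        if (used[jj]) continue;
        double cur = e.second - u[i0] - v[jj];
        if (!seen[jj]) {
          seen[jj] = 1;
          minv[jj] = BIG;
          touched.push_back(jj);
        }
        if (cur < minv[jj]) {
          minv[jj] = cur;
          way[jj] = j0;
        }
      }
      double delta = BIG;
      int j1 = -1;
      for (int jj : touched) {
        if (jj == 0 || used[jj]) continue;
        if (minv[jj] < delta) {
          delta = minv[jj];
          j1 = jj;
        }
      }
      if (j1 < 0) stop("assignment infeasible (internal error)");
      for (int jj : touched) {
        if (used[jj]) {
          u[p[jj]] += delta;
          v[jj] -= delta;
        } else {
          minv[jj] -= delta;
        }
      }
      j0 = j1;
      used[j0] = 1;
      if (!touched.empty()) {} // j0 already in touched (came from seen)
      if (p[j0] == 0) break;
    }
    // augment along the alternating path
    while (j0) {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    }
    for (int jj : touched) {
      used[jj] = 0;
      seen[jj] = 0;
      minv[jj] = BIG;
    }
  }
  std::vector<int> rowMatch(n, -1);
  for (int jj = 1; jj <= m; ++jj)
    if (p[jj] > 0) rowMatch[p[jj] - 1] = jj - 1;
  return rowMatch;
}

// Maximum-weight one-to-one matching on a similarity matrix; entries
// <= 0 (or non-finite) are forbidden. Returns 0-based column per row,
// -1 for unmatched. Exposed for oracle tests of the assignment step.
// [[Rcpp::export]]
IntegerVector cpp_assignment(const NumericMatrix& S) {
  int nA = S.nrow(), nB = S.ncol();
  std::vector<std::vector<std::pair<int, double>>> adj(nA);
  for (int i = 0; i < nA; ++i) {
    for (int j = 0; j < nB; ++j) {
      double s = S(i, j);
      if (R_finite(s) && s > 0)
        adj[i].push_back({j, -s + TIE_EPS * (double)(i * nB + j)});
    }
    adj[i].push_back({nB + i, 0.0});  // stay unmatched
  }
  std::vector<int> rm = lap_sparse(nA, nB + nA, adj);
  IntegerVector out(nA);
  for (int i = 0; i < nA; ++i)
    out[i] = (rm[i] >= 0 && rm[i] < nB) ? rm[i] + 1 : NA_INTEGER;
  return out;
}

// Scan all contiguous fragment pairs of length L, superpose each, and
// return the n_seeds transforms of lowest fragment rmsd, deduplicated so
// retained rotations differ pairwise by more than dedup_deg degrees.
// [[Rcpp::export]]
List cpp_seed_scan(const arma::mat& A, const arma::mat& B, int L,
                   int n_seeds, double dedup_deg) {
  int nA = A.n_rows, nB = B.n_rows;
  int na = nA - L + 1, nb = nB - L + 1;
  if (na < 1 || nb < 1) stop("fragment length exceeds a structure length");
  arma::vec w(L, arma::fill::ones);

  struct Frag { double rmsd; int i, j; };
  std::vector<Frag> frags;
  frags.reserve((size_t)na * nb);
  for (int i = 0; i < na; ++i) {
    arma::mat Af = A.rows(i, i + L - 1);
    arma::rowvec muA = arma::mean(Af, 0);
    arma::mat Ac = Af.each_row() - muA;
    double EA = arma::accu(arma::square(Ac));
    for (int j = 0; j < nb; ++j) {
      arma::mat Bf = B.rows(j, j + L - 1);
      arma::rowvec muB = arma::mean(Bf, 0);
      arma::mat Bc = Bf.each_row() - muB;
      double EB = arma::accu(arma::square(Bc));
      arma::mat H = Bc.t() * Ac;
      arma::vec sv;
      if (!arma::svd(sv, H)) continue;
      double sgn = arma::det(H) < 0 ? -1.0 : 1.0;
      double msd = (EA + EB - 2.0 * (sv(0) + sv(1) + sgn * sv(2))) / L;
      frags.push_back({std::sqrt(std::max(0.0, msd)), i, j});
    }
  }
  std::stable_sort(frags.begin(), frags.end(),
                   [](const Frag& a, const Frag& b) {
                     if (a.rmsd != b.rmsd) return a.rmsd < b.rmsd;
                     if (a.i != b.i) return a.i < b.i;
                     return a.j < b.j;
                   });

  double cos_thr = std::cos(dedup_deg * M_PI / 180.0);
  std::vector<arma::mat33> Rs;
  std::vector<arma::vec3> ts;
  std::vector<double> rmsds;
  for (const Frag& f : frags) {
    if ((int)Rs.size() >= n_seeds) break;
    KabschFit k = kabsch_core(A.rows(f.i, f.i + L - 1),
                              B.rows(f.j, f.j + L - 1), w);
    bool dup = false;
    for (const arma::mat33& Rk : Rs) {
      double c = (arma::trace(Rk.t() * k.R) - 1.0) / 2.0;
      if (c > cos_thr) { dup = true; break; }
    }
    if (dup) continue;
    Rs.push_back(k.R);
    ts.push_back(k.t);
    rmsds.push_back(f.rmsd);
  }
  int k = Rs.size();
  arma::cube Rc(3, 3, k);
  arma::mat tc(k, 3);
  for (int q = 0; q < k; ++q) {
    Rc.slice(q) = Rs[q];
    tc.row(q) = ts[q].t();
  }
  return List::create(_["rotations"] = Rc, _["translations"] = tc,
                      _["frag_rmsd"] = NumericVector(rmsds.begin(), rmsds.end()));
}

struct MatchResult {
  std::vector<int> rows, cols;     // 0-based matched pairs
  std::vector<double> sims;
  double score = 0.0;
};

// One assignment round at a fixed transform: candidate pairs are those
// with post-superposition distance <= d_max; similarity is the weighted
// sum of a Gaussian geometric kernel, secondary-structure agreement and
// amino-acid class agreement.
static MatchResult match_at(const arma::mat& A, const arma::mat& Bt,
                            const IntegerVector& ssA, const IntegerVector& ssB,
                            const IntegerVector& clA, const IntegerVector& clB,
                            double sigma, double wg, double wss, double waa,
                            double dmax) {
  int nA = A.n_rows, nB = Bt.n_rows;
  double dmax2 = dmax * dmax, inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<std::vector<std::pair<int, double>>> adj(nA);
  std::vector<std::vector<std::pair<int, double>>> simlist(nA);
  for (int i = 0; i < nA; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nB; ++j) {
      double dx = ax - Bt(j, 0), dy = ay - Bt(j, 1), dz = az - Bt(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > dmax2) continue;
      double s = wg * std::exp(-d2 * inv2s2);
      if (ssA[i] == ssB[j]) s += wss;
      if (clA[i] > 0 && clA[i] == clB[j]) s += waa;
      if (s <= 0) continue;
      adj[i].push_back({j, -s + TIE_EPS * (double)(i * nB + j)});
      simlist[i].push_back({j, s});
    }
    adj[i].push_back({nB + i, 0.0});
  }
  std::vector<int> rm = lap_sparse(nA, nB + nA, adj);
  MatchResult out;
  for (int i = 0; i < nA; ++i) {
    int j = rm[i];
    if (j < 0 || j >= nB) continue;
    for (const auto& e : simlist[i]) {
      if (e.first == j) {
        out.rows.push_back(i);
        out.cols.push_back(j);
        out.sims.push_back(e.second);
        out.score += e.second;
        break;
      }
    }
  }
  return out;
}

// Full alignment refinement: for every seed transform iterate
// {assignment, similarity-weighted re-superposition} to convergence and
// return the highest-scoring correspondence over all seeds.
// [[Rcpp::export]]
List cpp_align_refine(const arma::mat& A, const arma::mat& B,
                      const IntegerVector& ssA, const IntegerVector& ssB,
                      const IntegerVector& clA, const IntegerVector& clB,
                      const arma::cube& seedR, const arma::mat& seedT,
                      double sigma, double wg, double wss, double waa,
                      double dmax, int max_iter, double tol) {
  int nseed = seedR.n_slices;
  double best_score = -1.0;
  MatchResult best;
  arma::mat33 bestR;
  arma::vec3 bestT;
  int best_seed = -1, best_iter = 0;

  for (int q = 0; q < nseed; ++q) {
    arma::mat33 R = seedR.slice(q);
    arma::vec3 t = seedT.row(q).t();
    double prev = -BIG;
    for (int it = 1; it <= max_iter; ++it) {
      arma::mat Bt = B * R.t();
      Bt.each_row() += t.t();
      MatchResult m = match_at(A, Bt, ssA, ssB, clA, clB,
                               sigma, wg, wss, waa, dmax);
      if (m.score > best_score) {
        best_score = m.score;
        best = m;
        bestR = R;
        bestT = t;
        best_seed = q;
        best_iter = it;
      }
      if (m.rows.size() < 3 || m.score - prev < tol) break;
      prev = m.score;
      arma::mat Am(m.rows.size(), 3), Bm(m.rows.size(), 3);
      arma::vec w(m.rows.size());
      for (size_t p = 0; p < m.rows.size(); ++p) {
        Am.row(p) = A.row(m.rows[p]);
        Bm.row(p) = B.row(m.cols[p]);
        w(p) = m.sims[p];
      }
      KabschFit k = kabsch_core(Am, Bm, w);
      R = k.R;
      t = k.t;
    }
  }

  int npair = best.rows.size();
  IntegerMatrix pairs(npair, 2);
  NumericVector sims(npair);
  double ss2 = 0.0;
  arma::mat Bt;
  if (npair > 0) {
    Bt = B * bestR.t();
    Bt.each_row() += bestT.t();
  }
  for (int p = 0; p < npair; ++p) {
    pairs(p, 0) = best.rows[p] + 1;
    pairs(p, 1) = best.cols[p] + 1;
    sims[p] = best.sims[p];
    arma::rowvec d = A.row(best.rows[p]) - Bt.row(best.cols[p]);
    ss2 += arma::accu(arma::square(d));
  }
  double rmsd = npair > 0 ? std::sqrt(ss2 / npair) : 0.0;
  return List::create(_["pairs"] = pairs, _["similarities"] = sims,
                      _["rotation"] = arma::mat(bestR),
                      _["translation"] = arma::vec(bestT),
                      _["score"] = best_score < 0 ? 0.0 : best_score,
                      _["rmsd"] = rmsd,
                      _["seed_index"] = best_seed + 1,
                      _["iterations"] = best_iter);
}
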