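// Core numerical routines: Kabsch superposition, TM-score style iterative
// structural alignment, and global sequence alignment with identity counting.
// All heavy per-pair work lives here; R wrappers validate inputs.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// d0 length scale of the TM-score; clamped below at 0.5 Angstrom.
static double d0_tm(const int L) {
  const double base = L > 15 ? std::cbrt(static_cast<double>(L - 15)) : 0.0;
  const double d = 1.24 * base - 1.8;
  return d < 0.5 ? 0.5 : d;
}

// [[Rcpp::export]]
double cpp_tm_d0(const int L) { return d0_tm(L); }

// Optimal proper rotation mapping centred P onto centred Q (rows = points).
// Reflection is excluded by sign-correcting the smallest singular value.
static arma::mat kabsch_rotation(const arma::mat& Pc, const arma::mat& Qc) {
  arma::mat H = Pc.t() * Qc;       // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) stop("SVD failed in Kabsch superposition");
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  return V * D * U.t();            // q ~= R * p  (column vectors)
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& P, const arma::mat& Q) {
  const arma::rowvec cp = arma::mean(P, 0);
  const arma::rowvec cq = arma::mean(Q, 0);
  const arma::mat Pc = P.each_row() - cp;
  const arma::mat Qc = Q.each_row() - cq;
  const arma::mat R = kabsch_rotation(Pc, Qc);
  const arma::mat diff = Pc * R.t() - Qc;
  const double rmsd = std::sqrt(arma::accu(arma::square(diff)) / P.n_rows);
  const arma::vec t = cq.t() - R * cp.t();
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["rmsd"] = rmsd);
}

// Global alignment over a similarity matrix S (no residue identities) with an
// affine gap: opening costs `gap_open` (negative), extension is free. Ties in
// both state choice and traceback prefer diagonal, then up (gap in columns /
// advance i), then left. Returns matched (i, j) pairs, 1-based, colinear.
static std::vector<std::pair<int, int>> nw_align_matrix(const arma::mat& S,
                                                        const double gap_open) {
  const int n = S.n_rows, m = S.n_cols;
  const double NEG = -1e30;
  arma::mat M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // backpointers: predecessor state of each cell, 0 = M, 1 = X(up), 2 = Y(left)
  arma::Mat<unsigned char> bM(n + 1, m + 1), bX(n + 1, m + 1), bY(n + 1, m + 1);
  M.fill(NEG); X.fill(NEG); Y.fill(NEG);
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) { X(i, 0) = gap_open; bX(i, 0) = (i == 1) ? 0 : 1; }
  for (int j = 1; j <= m; ++j) { Y(0, j) = gap_open; bY(0, j) = (j == 1) ? 0 : 2; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume (i, j) as a pair
      double best = M(i - 1, j - 1); unsigned char arg = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 2; }
      M(i, j) = S(i - 1, j - 1) + best;
      bM(i, j) = arg;
      // X: gap in the column sequence, i advances
      best = M(i - 1, j) + gap_open; arg = 0;
      if (X(i - 1, j) > best) { best = X(i - 1, j); arg = 1; }
      if (Y(i - 1, j) + gap_open > best) { best = Y(i - 1, j) + gap_open; arg = 2; }
      X(i, j) = best; bX(i, j) = arg;
      // Y: gap in the row sequence, j advances
      best = M(i, j - 1) + gap_open; arg = 0;
      if (X(i, j - 1) + gap_open > best) { best = X(i, j - 1) + gap_open; arg = 1; }
      if (Y(i, j - 1) > best) { best = Y(i, j - 1); arg = 2; }
      Y(i, j) = best; bY(i, j) = arg;
    }
  }

  int state = 0;
  double fin = M(n, m);
  if (X(n, m) > fin) { fin = X(n, m); state = 1; }
  if (Y(n, m) > fin) { fin = Y(n, m); state = 2; }

  std::vector<std::pair<int, int>> pairs;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pairs.push_back(std::make_pair(i, j));
      state = bM(i, j); --i; --j;
    } else if (state == 1) {
      state = bX(i, j); --i;
    } else {
      state = bY(i, j); --j;
    }
  }
  std::reverse(pairs.begin(), pairs.end());
  return pairs;
}

struct AlignScore {
  double tm_ab, tm_ba, tm_sym, rmsd;
  arma::mat rotation;
  arma::vec translation;
};

static AlignScore score_correspondence(const arma::mat& A, const arma::mat& B,
                                       const std::vector<std::pair<int, int>>& corr) {
  const int m = corr.size();
  arma::mat P(m, 3), Q(m, 3);
  for (int k = 0; k < m; ++k) {
    P.row(k) = A.row(corr[k].first - 1);
    Q.row(k) = B.row(corr[k].second - 1);
  }
  const arma::rowvec cp = arma::mean(P, 0), cq = arma::mean(Q, 0);
  const arma::mat Pc = P.each_row() - cp, Qc = Q.each_row() - cq;
  const arma::mat R = kabsch_rotation(Pc, Qc);
  const arma::mat diff = Pc * R.t() - Qc;
  const arma::vec d2 = arma::sum(arma::square(diff), 1);
  AlignScore out;
  out.rmsd = std::sqrt(arma::accu(d2) / m);
  const double d0a = d0_tm(A.n_rows), d0b = d0_tm(B.n_rows);
  double sa = 0.0, sb = 0.0;
  for (int k = 0; k < m; ++k) {
    sa += 1.0 / (1.0 + d2(k) / (d0a * d0a));
    sb += 1.0 / (1.0 + d2(k) / (d0b * d0b));
  }
  out.tm_ab = sa / A.n_rows;
  out.tm_ba = sb / B.n_rows;
  out.tm_sym = 0.5 * (out.tm_ab + out.tm_ba);
  out.rotation = R;
  out.translation = cq.t() - R * cp.t();
  return out;
}

// One candidate: iterate superpose -> score matrix -> DP until the
// correspondence is unchanged (or oscillates with period 2) or max_iter is
// reached.
static std::vector<std::pair<int, int>> refine_candidate(
    const arma::mat& A, const arma::mat& B,
    std::vector<std::pair<int, int>> corr,
    const double gap_open, const int max_iter, const double d0) {
  const int n = A.n_rows, m = B.n_rows;
  const double d0sq = d0 * d0;
  std::vector<std::pair<int, int>> prev;
  for (int it = 0; it < max_iter; ++it) {
    const int nc = corr.size();
    if (nc < 3) break;
    arma::mat P(nc, 3), Q(nc, 3);
    for (int k = 0; k < nc; ++k) {
      P.row(k) = A.row(corr[k].first - 1);
      Q.row(k) = B.row(corr[k].second - 1);
    }
    const arma::rowvec cp = arma::mean(P, 0), cq = arma::mean(Q, 0);
    const arma::mat R = kabsch_rotation(P.each_row() - cp, Q.each_row() - cq);
    const arma::vec t = cq.t() - R * cp.t();
    arma::mat At = A * R.t();
    At.each_row() += t.t();
    arma::mat S(n, m);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < m; ++j) {
        const double dx = At(i, 0) - B(j, 0);
        const double dy = At(i, 1) - B(j, 1);
        const double dz = At(i, 2) - B(j, 2);
        S(i, j) = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / d0sq);
      }
    }
    std::vector<std::pair<int, int>> next = nw_align_matrix(S, gap_open);
    if (next == corr || next == prev) break;
    prev = corr;
    corr = next;
  }
  return corr;
}

// [[Rcpp::export]]
List cpp_structural_align(const arma::mat& A, const arma::mat& B,
                          const double gap_open, const int max_iter,
                          const int stride) {
  const int n = A.n_rows, m = B.n_rows;
  const int Lmin = std::min(n, m);
  const double d0 = d0_tm(Lmin);

  // Initial correspondences: gapless threading of the shorter chain onto the
  // longer at all offsets (by stride, endpoints always included).
  std::vector<std::vector<std::pair<int, int>>> seeds;
  const int max_off = std::abs(n - m);
  std::vector<int> offsets;
  for (int off = 0; off <= max_off; off += std::max(stride, 1)) offsets.push_back(off);
  if (offsets.back() != max_off) offsets.push_back(max_off);
  for (size_t oi = 0; oi < offsets.size(); ++oi) {
    std::vector<std::pair<int, int>> c(Lmin);
    for (int k = 0; k < Lmin; ++k) {
      if (n <= m) c[k] = std::make_pair(k + 1, k + 1 + offsets[oi]);
      else        c[k] = std::make_pair(k + 1 + offsets[oi], k + 1);
    }
    seeds.push_back(c);
  }

  // Two-phase search: every seed gets a short refinement, then only the most
  // promising candidates are refined to convergence.
  const int quick = std::min(2, max_iter);
  std::vector<std::vector<std::pair<int, int>>> cands;
  std::vector<double> cand_tm;
  for (size_t s = 0; s < seeds.size(); ++s) {
    std::vector<std::pair<int, int>> corr =
        refine_candidate(A, B, seeds[s], gap_open, quick, d0);
    if (corr.size() < 3) continue;
    cands.push_back(corr);
    cand_tm.push_back(score_correspondence(A, B, corr).tm_sym);
  }
  std::vector<size_t> order(cands.size());
  for (size_t k = 0; k < order.size(); ++k) order[k] = k;
  std::stable_sort(order.begin(), order.end(),
                   [&](size_t a, size_t b) { return cand_tm[a] > cand_tm[b]; });
  const size_t keep = std::min<size_t>(3, order.size());

  bool have_best = false;
  std::vector<std::pair<int, int>> best_corr;
  AlignScore best;
  for (size_t k = 0; k < keep; ++k) {
    std::vector<std::pair<int, int>> corr =
        refine_candidate(A, B, cands[order[k]], gap_open, max_iter, d0);
    if (corr.size() < 3) continue;
    const AlignScore sc = score_correspondence(A, B, corr);
    if (!have_best || sc.tm_sym > best.tm_sym) {
      best = sc;
      best_corr = corr;
      have_best = true;
    }
  }
  if (!have_best) stop("structural alignment produced no usable correspondence");

  IntegerMatrix pairs(best_corr.size(), 2);
  for (size_t k = 0; k < best_corr.size(); ++k) {
    pairs(k, 0) = best_corr[k].first;
    pairs(k, 1) = best_corr[k].second;
  }
  return List::create(
      _["pairs"] = pairs, _["rotation"] = best.rotation,
      _["translation"] = best.translation, _["tm_ab"] = best.tm_ab,
      _["tm_ba"] = best.tm_ba, _["tm_sym"] = best.tm_sym,
      _["rmsd"] = best.rmsd, _["n_aligned"] = (int)best_corr.size());
}

// Global sequence alignment, match +1 / mismatch 0 / linear gap -1,
// deterministic traceback preferring diagonal, then up, then left.
// [[Rcpp::export]]
List cpp_nw_identity(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  const int GAP = -1;
  arma::Mat<int> F(n + 1, m + 1);
  for (int i = 0; i <= n; ++i) F(i, 0) = i * GAP;
  for (int j = 0; j <= m; ++j) F(0, j) = j * GAP;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int sc = (a[i - 1] == b[j - 1]) ? 1 : 0;
      int best = F(i - 1, j - 1) + sc;
      if (F(i - 1, j) + GAP > best) best = F(i - 1, j) + GAP;
      if (F(i, j - 1) + GAP > best) best = F(i, j - 1) + GAP;
      F(i, j) = best;
    }
  }
  int i = n, j = m, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        F(i, j) == F(i - 1, j - 1) + ((a[i - 1] == b[j - 1]) ? 1 : 0)) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && F(i, j) == F(i - 1, j) + GAP) {
      --i;
    } else {
      --j;
    }
    ++columns;
  }
  return List::create(_["score"] = F(n, m), _["matches"] = matches,
                      _["columns"] = columns);
}
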