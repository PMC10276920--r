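// Core forest machinery: covariance-heterogeneity trees, OOB
// nearest-neighbour (BOP) covariance estimation, and the Mahalanobis
// multivariate regression forest used for fit-the-fit importance.
//
// All randomness flows through a per-tree deterministic mt19937_64 stream
// derived from (master seed, stream id), so forests are reproducible and
// subsample draws are identical across nodesize levels (common random
// numbers for the tuning procedure).

#include <RcppArmadillo.h>
#include <algorithm>
#include <cstdint>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct Rng {
  std::mt19937_64 g;
  Rng(uint64_t seed, uint64_t stream) {
    g.seed(splitmix64(splitmix64(seed) ^ (0x632be59bd9b4e019ULL * (stream + 1))));
  }
  uint64_t u64() { return g(); }
  // modulo draw: tiny bias is irrelevant here and keeps results
  // platform-stable (std::uniform_int_distribution is not portable)
  int unif_int(int n) { return (int)(u64() % (uint64_t)n); }
  // first k entries of a partial Fisher-Yates permutation of 0..n-1
  std::vector<int> sample_wor(int n, int k) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < k; ++i) {
      int j = i + unif_int(n - i);
      std::swap(idx[i], idx[j]);
    }
    idx.resize(k);
    return idx;
  }
  template <class T> void shuffle(std::vector<T>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) std::swap(v[i], v[(size_t)unif_int(i + 1)]);
  }
};

// --------------------------------------------------------------- trees ----

struct Tree {
  std::vector<int> var;        // split covariate; -1 for terminal
  std::vector<double> thr;     // numeric threshold (x <= thr goes left)
  std::vector<uint64_t> mask;  // categorical: level codes routed left
  std::vector<int> left, right;
  std::vector<int> inbag;      // training row ids used to grow this tree
  int add_node() {
    var.push_back(-1); thr.push_back(0.0); mask.push_back(0);
    left.push_back(-1); right.push_back(-1);
    return (int)var.size() - 1;
  }
};

// route a row with fully known covariate codes to its terminal node
static int route_row(const Tree& t, const arma::mat& X,
                     const std::vector<int>& ncat, int row) {
  int nd = 0;
  while (t.var[nd] >= 0) {
    int v = t.var[nd];
    bool goleft;
    if (ncat[v] == 0) {
      goleft = X(row, v) <= t.thr[nd];
    } else {
      int code = (int)X(row, v);
      goleft = code >= 0 && ((t.mask[nd] >> code) & 1ULL);
    }
    nd = goleft ? t.left[nd] : t.right[nd];
  }
  return nd;
}

// route allowing unseen categorical codes (< 0): the row is sent down both
// children and every reachable terminal is returned
static void route_row_multi(const Tree& t, const arma::mat& X,
                            const std::vector<int>& ncat, int row,
                            std::vector<int>& out) {
  out.clear();
  std::vector<int> stack{0};
  while (!stack.empty()) {
    int nd = stack.back(); stack.pop_back();
    while (t.var[nd] >= 0) {
      int v = t.var[nd];
      if (ncat[v] == 0) {
        nd = (X(row, v) <= t.thr[nd]) ? t.left[nd] : t.right[nd];
      } else {
        int code = (int)X(row, v);
        if (code < 0) { stack.push_back(t.right[nd]); nd = t.left[nd]; }
        else nd = ((t.mask[nd] >> code) & 1ULL) ? t.left[nd] : t.right[nd];
      }
    }
    out.push_back(nd);
  }
}

// ------------------------------------------------------------- scorers ----
//
// Both splitting rules are evaluated from additive sufficient statistics so
// that, for a numeric covariate, all candidate cut points are scored in one
// sweep of prefix sums, and for a categorical covariate from per-level
// aggregates.
//
// CovScorer  : score = sqrt(nL*nR) * d(Sigma_L, Sigma_R), d = Euclidean
//              distance over the upper triangle (diagonal included once).
//              stats per row: y (q) and upper triangle of y y^T (m).
// MahaScorer : score = impurity decrease with node impurity
//              sum_i (z_i - zbar)' Vinv (z_i - zbar)
//              stats per row: z (m) and scalar w = z' Vinv z.

struct CovScorer {
  arma::mat Yt;  // q x n transpose: contiguous per-row access in the hot path
  int q, m;
  std::vector<double> S1T, S2T;  // node totals
  CovScorer(const arma::mat& Y_) : Yt(Y_.t()), q((int)Y_.n_cols),
    m(q * (q + 1) / 2), S1T(q), S2T(m) {}
  int s1len() const { return q; }
  int s2len() const { return m; }
  void row_stats(int row, double* s1, double* s2) const {
    const double* y = Yt.colptr(row);
    int idx = 0;
    for (int i = 0; i < q; ++i) {
      s1[i] = y[i];
      for (int j = i; j < q; ++j) s2[idx++] = y[i] * y[j];
    }
  }
  // score a candidate from left stats + node totals; -1 if infeasible
  double score(const double* S1L, const double* S2L, int nL, int nTot) const {
    int nR = nTot - nL;
    if (nL < 2 || nR < 2) return -1.0;
    double ss = 0.0;
    int idx = 0;
    for (int i = 0; i < q; ++i) {
      double mLi = S1L[i] / nL, mRi = (S1T[i] - S1L[i]) / nR;
      for (int j = i; j < q; ++j) {
        double mLj = S1L[j] / nL, mRj = (S1T[j] - S1L[j]) / nR;
        double sl = (S2L[idx] - nL * mLi * mLj) / (nL - 1);
        double sr = ((S2T[idx] - S2L[idx]) - nR * mRi * mRj) / (nR - 1);
        double diff = sl - sr;
        ss += diff * diff;
        ++idx;
      }
    }
    return std::sqrt((double)nL * (double)nR) * std::sqrt(ss);
  }
  void set_totals(const std::vector<int>& members) {
    std::fill(S1T.begin(), S1T.end(), 0.0);
    std::fill(S2T.begin(), S2T.end(), 0.0);
    std::vector<double> s1(q), s2(m);
    for (int r : members) {
      row_stats(r, s1.data(), s2.data());
      for (int i = 0; i < q; ++i) S1T[i] += s1[i];
      for (int i = 0; i < m; ++i) S2T[i] += s2[i];
    }
  }
};

struct MahaScorer {
  arma::mat Zt;  // m x n transpose for contiguous row access
  const arma::mat& Vinv;
  int m;
  std::vector<double> S1T;
  double WT;
  std::vector<double> wrow;  // cached z_i' Vinv z_i per training row
  MahaScorer(const arma::mat& Z_, const arma::mat& Vinv_)
      : Zt(Z_.t()), Vinv(Vinv_), m((int)Z_.n_cols), S1T(m), WT(0.0) {
    wrow.resize(Z_.n_rows);
    for (arma::uword i = 0; i < Z_.n_rows; ++i) {
      arma::rowvec z = Z_.row(i);
      wrow[i] = arma::as_scalar(z * Vinv * z.t());
    }
  }
  int s1len() const { return m; }
  int s2len() const { return 1; }
  void row_stats(int row, double* s1, double* s2) const {
    const double* z = Zt.colptr(row);
    for (int i = 0; i < m; ++i) s1[i] = z[i];
    s2[0] = wrow[row];
  }
  double quad(const double* v) const {
    double s = 0.0;
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int j = 0; j < m; ++j) acc += Vinv(i, j) * v[j];
      s += v[i] * acc;
    }
    return s;
  }
  double score(const double* S1L, const double* S2L, int nL, int nTot) const {
    int nR = nTot - nL;
    if (nL < 1 || nR < 1) return -1.0;
    std::vector<double> S1R(m);
    for (int i = 0; i < m; ++i) S1R[i] = S1T[i] - S1L[i];
    double IL = S2L[0] - quad(S1L) / nL;
    double IR = (WT - S2L[0]) - quad(S1R.data()) / nR;
    double Iparent = WT - quad(S1T.data()) / nTot;
    return Iparent - IL - IR;  // >= 0 up to roundoff
  }
  void set_totals(const std::vector<int>& members) {
    std::fill(S1T.begin(), S1T.end(), 0.0);
    WT = 0.0;
    for (int r : members) {
      const double* z = Zt.colptr(r);
      for (int i = 0; i < m; ++i) S1T[i] += z[i];
      WT += wrow[r];
    }
  }
};

// -------------------------------------------------------------- grower ----

struct BestSplit {
  double score = -1.0;
  int var = -1;
  double thr = 0.0;
  uint64_t mask = 0;
  bool is_cat = false;
};

// evaluate all (sampled) candidates of one numeric covariate
template <class Scorer>
static void eval_numeric(const arma::mat& X, Scorer& sc, int v,
                         const std::vector<int>& members, int nsplit,
                         int min_child, Rng& rng, BestSplit& best) {
  const int n = (int)members.size();
  std::vector<std::pair<double, int>> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = {X(members[i], v), members[i]};
  std::stable_sort(ord.begin(), ord.end(),
                   [](const std::pair<double, int>& a, const std::pair<double, int>& b) {
                     return a.first < b.first;
                   });
  // boundaries between distinct values: cut after position k (1..n-1)
  std::vector<int> cuts;
  for (int k = 1; k < n; ++k)
    if (ord[k - 1].first < ord[k].first) cuts.push_back(k);
  if (cuts.empty()) return;
  std::vector<int> sel;
  if ((int)cuts.size() <= nsplit) {
    sel.resize(cuts.size());
    for (size_t i = 0; i < cuts.size(); ++i) sel[i] = (int)i;
  } else {
    sel = rng.sample_wor((int)cuts.size(), nsplit);
    std::sort(sel.begin(), sel.end());  // cut points ascending for tie-break
  }
  const int l1 = sc.s1len(), l2 = sc.s2len();
  // single streaming pass: accumulate running sums and score at the
  // selected (ascending) cut positions
  std::vector<double> S1((size_t)l1, 0.0), S2((size_t)l2, 0.0);
  std::vector<double> s1(l1), s2(l2);
  size_t nxt = 0;
  for (int k = 0; k < n && nxt < sel.size(); ++k) {
    sc.row_stats(ord[k].second, s1.data(), s2.data());
    for (int i = 0; i < l1; ++i) S1[i] += s1[i];
    for (int i = 0; i < l2; ++i) S2[i] += s2[i];
    while (nxt < sel.size() && cuts[sel[nxt]] == k + 1) {
      int kk = k + 1;
      if (kk >= min_child && n - kk >= min_child) {
        double sco = sc.score(S1.data(), S2.data(), kk, n);
        if (sco > best.score) {
          best.score = sco;
          best.var = v;
          best.thr = 0.5 * (ord[kk - 1].first + ord[kk].first);
          best.is_cat = false;
        }
      }
      ++nxt;
    }
  }
}

// evaluate (sampled) level-subset candidates of a categorical covariate
template <class Scorer>
static void eval_categorical(const arma::mat& X, Scorer& sc, int v,
                             const std::vector<int>& members, int nsplit,
                             int min_child, Rng& rng, BestSplit& best) {
  const int n = (int)members.size();
  // per-level aggregates over the levels present in this node
  std::vector<int> levels;           // sorted global codes present
  std::vector<int> lev_of_code(64, -1);
  for (int i = 0; i < n; ++i) {
    int code = (int)X(members[i], v);
    if (lev_of_code[code] < 0) { lev_of_code[code] = 0; levels.push_back(code); }
  }
  if ((int)levels.size() < 2) return;
  std::sort(levels.begin(), levels.end());
  const int L = (int)levels.size();
  for (int i = 0; i < L; ++i) lev_of_code[levels[i]] = i;
  const int l1 = sc.s1len(), l2 = sc.s2len();
  std::vector<double> A1((size_t)L * l1, 0.0), A2((size_t)L * l2, 0.0);
  std::vector<int> cnt(L, 0);
  std::vector<double> s1(l1), s2(l2);
  for (int i = 0; i < n; ++i) {
    int li = lev_of_code[(int)X(members[i], v)];
    sc.row_stats(members[i], s1.data(), s2.data());
    for (int k = 0; k < l1; ++k) A1[(size_t)li * l1 + k] += s1[k];
    for (int k = 0; k < l2; ++k) A2[(size_t)li * l2 + k] += s2[k];
    ++cnt[li];
  }
  // canonical proper partitions: the left side always contains levels[0];
  // j's bits select among levels[1..L-1]; j = 2^(L-1)-1 (full set) excluded
  uint64_t total = (1ULL << (L - 1)) - 1ULL;  // candidates are j = 0..total-1
  std::vector<uint64_t> js;
  if (total <= (uint64_t)nsplit) {
    for (uint64_t j = 0; j < total; ++j) js.push_back(j);
  } else {
    std::unordered_set<uint64_t> seen;
    while ((int)js.size() < nsplit) {
      uint64_t j = rng.u64() % total;
      if (seen.insert(j).second) js.push_back(j);
    }
    std::sort(js.begin(), js.end());
  }
  std::vector<double> S1L(l1), S2L(l2);
  for (uint64_t j : js) {
    std::fill(S1L.begin(), S1L.end(), 0.0);
    std::fill(S2L.begin(), S2L.end(), 0.0);
    uint64_t mask = 1ULL << levels[0];
    int nL = cnt[0];
    for (int k = 0; k < l1; ++k) S1L[k] += A1[k];
    for (int k = 0; k < l2; ++k) S2L[k] += A2[k];
    for (int b = 0; b < L - 1; ++b) {
      if ((j >> b) & 1ULL) {
        int li = b + 1;
        mask |= 1ULL << levels[li];
        nL += cnt[li];
        for (int k = 0; k < l1; ++k) S1L[k] += A1[(size_t)li * l1 + k];
        for (int k = 0; k < l2; ++k) S2L[k] += A2[(size_t)li * l2 + k];
      }
    }
    if (nL < min_child || n - nL < min_child) continue;
    double sco = sc.score(S1L.data(), S2L.data(), nL, n);
    if (sco > best.score) {
      best.score = sco;
      best.var = v;
      best.mask = mask;
      best.is_cat = true;
    }
  }
}

template <class Scorer>
static Tree grow_tree(const arma::mat& X, const std::vector<int>& ncat,
                      Scorer& sc, std::vector<int> inbag, int mtry, int nsplit,
                      int nodesize, int min_child, Rng& rng) {
  const int p = (int)X.n_cols;
  Tree t;
  t.inbag = inbag;
  int root = t.add_node();
  std::vector<std::pair<int, std::vector<int>>> stack;
  stack.push_back({root, std::move(inbag)});
  while (!stack.empty()) {
    int nd = stack.back().first;
    std::vector<int> members = std::move(stack.back().second);
    stack.pop_back();
    const int n = (int)members.size();
    // a node holding nodesize or fewer members is terminal (nodesize is the
    // stop-splitting threshold); both children must be able to hold min_child
    if (n <= nodesize || n < 2 * min_child) continue;
    std::vector<int> vars = rng.sample_wor(p, mtry);  // drawn order kept
    sc.set_totals(members);
    BestSplit best;
    for (int v : vars) {
      if (ncat[v] == 0)
        eval_numeric(X, sc, v, members, nsplit, min_child, rng, best);
      else
        eval_categorical(X, sc, v, members, nsplit, min_child, rng, best);
    }
    if (best.var < 0) continue;  // unsplittable -> terminal
    t.var[nd] = best.var;
    t.thr[nd] = best.thr;
    t.mask[nd] = best.is_cat ? best.mask : 0ULL;
    int lc = t.add_node(), rc = t.add_node();
    t.left[nd] = lc;
    t.right[nd] = rc;
    std::vector<int> lm, rm;
    for (int r : members) {
      bool goleft;
      if (best.is_cat) {
        int code = (int)X(r, best.var);
        goleft = (best.mask >> code) & 1ULL;
      } else {
        goleft = X(r, best.var) <= best.thr;
      }
      (goleft ? lm : rm).push_back(r);
    }
    stack.push_back({rc, std::move(rm)});
    stack.push_back({lc, std::move(lm)});
  }
  return t;
}

// ----------------------------------------------------- BOP + estimation ----

// sample covariance of the Y rows listed in `rows` (with multiplicity)
static void accumulate_cov(const arma::mat& Y, const std::vector<int>& rows,
                           arma::mat& out) {
  const int q = (int)Y.n_cols;
  const int nb = (int)rows.size();
  arma::vec s1(q, arma::fill::zeros);
  arma::mat s2(q, q, arma::fill::zeros);
  for (int r : rows) {
    arma::rowvec y = Y.row(r);
    s1 += y.t();
    s2 += y.t() * y;
  }
  arma::vec mu = s1 / nb;
  out = (s2 - nb * (mu * mu.t())) / (nb - 1);
  out = 0.5 * (out + out.t());
}

struct ForestRep {
  std::vector<Tree> trees;
  arma::imat term;                       // n_train x B terminal ids
  std::vector<std::vector<char>> isoob;  // [b][i]
};

// collect, per tree, the OOB rows lying in each terminal node
static void leaf_oob_index(const ForestRep& f, int b, int n,
                           std::vector<std::vector<int>>& leaf) {
  leaf.assign(f.trees[b].var.size(), {});
  for (int i = 0; i < n; ++i)
    if (f.isoob[b][i]) leaf[f.term(i, b)].push_back(i);
}

// ------------------------------------------------------------- exports ----

static std::vector<int> ncat_vec(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

// fit the covariance forest; optionally return tree structures and the
// OOB (training-row) BOP covariance estimates
// [[Rcpp::export]]
List cpp_cov_forest(NumericMatrix Xr, IntegerVector ncatr, NumericMatrix Yr,
                    int ntree, int mtry, int nsplit, int nodesize, int sampsize,
                    int min_child, double seedd, bool return_trees,
                    bool multiset, bool exclude_self, bool fallback_uncond,
                    bool return_bops) {
  const arma::mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  const arma::mat Y(Yr.begin(), Yr.nrow(), Yr.ncol(), false);
  const int n = (int)X.n_rows, q = (int)Y.n_cols;
  std::vector<int> ncat = ncat_vec(ncatr);
  const uint64_t seed = (uint64_t)(int64_t)seedd;

  ForestRep f;
  f.trees.reserve(ntree);
  f.term.set_size(n, ntree);
  f.isoob.assign(ntree, std::vector<char>(n, 1));
  CovScorer sc(Y);
  for (int b = 0; b < ntree; ++b) {
    Rng rng(seed, (uint64_t)b);
    std::vector<int> inbag = rng.sample_wor(n, sampsize);  // drawn first:
    // identical across nodesize levels for the same master seed
    Tree t = grow_tree(X, ncat, sc, inbag, mtry, nsplit, nodesize, min_child, rng);
    for (int r : inbag) f.isoob[b][r] = 0;
    for (int i = 0; i < n; ++i) f.term(i, b) = route_row(t, X, ncat, i);
    f.trees.push_back(std::move(t));
  }

  // OOB BOP estimates for every training row
  arma::cube est(q, q, n, arma::fill::zeros);
  IntegerVector bop_size(n);
  LogicalVector degenerate(n);
  std::vector<std::vector<int>> bops_keep;
  {
    // per-tree leaf index built once
    std::vector<std::vector<std::vector<int>>> leaf(ntree);
    for (int b = 0; b < ntree; ++b) leaf_oob_index(f, b, n, leaf[b]);
    arma::mat uncond;
    if (fallback_uncond) accumulate_cov(Y, [&] {
      std::vector<int> all(n);
      for (int i = 0; i < n; ++i) all[i] = i;
      return all;
    }(), uncond);
    std::vector<int> stamp(n, -1), members;
    for (int i = 0; i < n; ++i) {
      members.clear();
      for (int b = 0; b < ntree; ++b) {
        if (!f.isoob[b][i]) continue;  // only trees where i is OOB contribute
        const std::vector<int>& co = leaf[b][f.term(i, b)];
        for (int j : co) {
          if (exclude_self && j == i) continue;
          if (multiset) {
            members.push_back(j);
          } else if (stamp[j] != i) {
            stamp[j] = i;
            members.push_back(j);
          }
        }
      }
      if (!multiset) std::sort(members.begin(), members.end());
      bop_size[i] = (int)members.size();
      if ((int)members.size() < 2) {
        degenerate[i] = true;
        if (fallback_uncond) est.slice(i) = uncond;
      } else {
        arma::mat s;
        accumulate_cov(Y, members, s);
        est.slice(i) = s;
      }
      if (return_bops) bops_keep.push_back(members);
    }
  }

  List out;
  out["oob_est"] = est;
  out["bop_size"] = bop_size;
  out["degenerate"] = degenerate;
  IntegerMatrix inbagm(sampsize, ntree);
  for (int b = 0; b < ntree; ++b)
    for (int k = 0; k < sampsize; ++k) inbagm(k, b) = f.trees[b].inbag[k] + 1;
  out["inbag"] = inbagm;
  IntegerMatrix termm(n, ntree);
  for (int b = 0; b < ntree; ++b)
    for (int i = 0; i < n; ++i) termm(i, b) = (int)f.term(i, b);
  out["term"] = termm;
  if (return_trees) {
    List trees(ntree);
    for (int b = 0; b < ntree; ++b) {
      const Tree& t = f.trees[b];
      int nn = (int)t.var.size();
      NumericVector maskv(nn);
      for (int k = 0; k < nn; ++k) maskv[k] = (double)t.mask[k];
      trees[b] = List::create(
          _["var"] = IntegerVector(t.var.begin(), t.var.end()),
          _["thr"] = NumericVector(t.thr.begin(), t.thr.end()),
          _["mask"] = maskv,
          _["left"] = IntegerVector(t.left.begin(), t.left.end()),
          _["right"] = IntegerVector(t.right.begin(), t.right.end()));
    }
    out["trees"] = trees;
  }
  if (return_bops) {
    List bl(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector v(bops_keep[i].size());
      for (size_t k = 0; k < bops_keep[i].size(); ++k) v[k] = bops_keep[i][k] + 1;
      bl[i] = v;
    }
    out["bops"] = bl;
  }
  return out;
}

static Tree tree_from_list(const List& tl) {
  Tree t;
  IntegerVector var = tl["var"], left = tl["left"], right = tl["right"];
  NumericVector thr = tl["thr"], mask = tl["mask"];
  t.var.assign(var.begin(), var.end());
  t.thr.assign(thr.begin(), thr.end());
  t.left.assign(left.begin(), left.end());
  t.right.assign(right.begin(), right.end());
  t.mask.resize(mask.size());
  for (int k = 0; k < mask.size(); ++k) t.mask[k] = (uint64_t)mask[k];
  return t;
}

// BOP covariance estimates for new observations; unseen categorical codes
// (encoded < 0) are routed down both children and contributions merged
// [[Rcpp::export]]
List cpp_cov_forest_predict(List treesr, IntegerVector ncatr, NumericMatrix Xnewr,
                            NumericMatrix Ytrainr, IntegerMatrix inbagr,
                            IntegerMatrix termr, bool multiset,
                            bool fallback_uncond, bool return_bops) {
  const arma::mat Xnew(Xnewr.begin(), Xnewr.nrow(), Xnewr.ncol(), false);
  const arma::mat Y(Ytrainr.begin(), Ytrainr.nrow(), Ytrainr.ncol(), false);
  const int ntree = treesr.size();
  const int n = Ytrainr.nrow(), q = (int)Y.n_cols, nq = (int)Xnew.n_rows;
  std::vector<int> ncat = ncat_vec(ncatr);

  std::vector<Tree> trees(ntree);
  std::vector<std::vector<char>> isoob(ntree, std::vector<char>(n, 1));
  for (int b = 0; b < ntree; ++b) {
    trees[b] = tree_from_list(treesr[b]);
    for (int k = 0; k < inbagr.nrow(); ++k) isoob[b][inbagr(k, b) - 1] = 0;
  }
  // per-tree terminal -> OOB rows
  std::vector<std::vector<std::vector<int>>> leaf(ntree);
  for (int b = 0; b < ntree; ++b) {
    leaf[b].assign(trees[b].var.size(), {});
    for (int i = 0; i < n; ++i)
      if (isoob[b][i]) leaf[b][termr(i, b)].push_back(i);
  }
  arma::mat uncond;
  {
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    accumulate_cov(Y, all, uncond);
  }
  arma::cube est(q, q, nq, arma::fill::zeros);
  IntegerVector bop_size(nq);
  LogicalVector degenerate(nq);
  List bl(return_bops ? nq : 0);
  std::vector<int> stamp(n, -1), members, terms;
  for (int s = 0; s < nq; ++s) {
    members.clear();
    for (int b = 0; b < ntree; ++b) {
      route_row_multi(trees[b], Xnew, ncat, s, terms);
      for (int td : terms) {
        for (int j : leaf[b][td]) {
          if (multiset) {
            members.push_back(j);
          } else if (stamp[j] != s) {
            stamp[j] = s;
            members.push_back(j);
          }
        }
      }
    }
    if (!multiset) std::sort(members.begin(), members.end());
    bop_size[s] = (int)members.size();
    if ((int)members.size() < 2) {
      degenerate[s] = true;
      if (fallback_uncond) est.slice(s) = uncond;
    } else {
      arma::mat sig;
      accumulate_cov(Y, members, sig);
      est.slice(s) = sig;
    }
    if (return_bops) {
      IntegerVector v(members.size());
      for (size_t k = 0; k < members.size(); ++k) v[k] = members[k] + 1;
      bl[s] = v;
    }
  }
  List out;
  out["est"] = est;
  out["bop_size"] = bop_size;
  out["degenerate"] = degenerate;
  if (return_bops) out["bops"] = bl;
  return out;
}

// multivariate regression forest on flattened covariance estimates with a
// Mahalanobis impurity rule; returns OOB permutation importance per covariate
// [[Rcpp::export]]
List cpp_vimp_forest(NumericMatrix Xr, IntegerVector ncatr, NumericMatrix Zr,
                     int ntree, int mtry, int nsplit, int nodesize,
                     int sampsize, int min_child, double seedd, double eps) {
  const arma::mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  const arma::mat Z(Zr.begin(), Zr.nrow(), Zr.ncol(), false);
  const int n = (int)X.n_rows, p = (int)X.n_cols, m = (int)Z.n_cols;
  std::vector<int> ncat = ncat_vec(ncatr);
  const uint64_t seed = (uint64_t)(int64_t)seedd;

  // root-level metric: V = cov(Z), regularized when ill-conditioned
  arma::mat V;
  {
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    accumulate_cov(Z, all, V);
  }
  arma::mat Vinv;
  arma::mat Vreg = V;
  for (int attempt = 0; attempt < 12; ++attempt) {
    if (arma::inv_sympd(Vinv, Vreg)) break;
    Vreg += eps * arma::diagmat(V.diag() + 1e-12);
    eps *= 10.0;
    Vinv.reset();
  }
  if (Vinv.n_rows == 0) Vinv = arma::pinv(Vreg);

  // per-response scale for standardized squared error
  arma::rowvec sdz = arma::stddev(Z, 0, 0);
  for (int k = 0; k < m; ++k) if (sdz[k] <= 0) sdz[k] = 1.0;

  MahaScorer sc(Z, Vinv);
  arma::vec vimp(p, arma::fill::zeros);
  std::vector<int> oob;
  for (int b = 0; b < ntree; ++b) {
    Rng rng(seed, (uint64_t)b);
    std::vector<int> inbag = rng.sample_wor(n, sampsize);
    Tree t = grow_tree(X, ncat, sc, inbag, mtry, nsplit, nodesize, min_child, rng);
    // terminal means of in-bag responses
    std::vector<arma::vec> leafmean(t.var.size());
    std::vector<int> leafn(t.var.size(), 0);
    for (size_t k = 0; k < leafmean.size(); ++k) leafmean[k].zeros(m);
    for (int r : t.inbag) {
      int td = route_row(t, X, ncat, r);
      leafmean[td] += Z.row(r).t();
      ++leafn[td];
    }
    for (size_t k = 0; k < leafmean.size(); ++k)
      if (leafn[k] > 0) leafmean[k] /= leafn[k];
    std::vector<char> inb(n, 0);
    for (int r : inbag) inb[r] = 1;
    oob.clear();
    for (int i = 0; i < n; ++i) if (!inb[i]) oob.push_back(i);
    if (oob.empty()) continue;
    auto sse = [&](int row, int td) {
      double e = 0.0;
      const arma::vec& mu = leafmean[td];
      for (int k = 0; k < m; ++k) {
        double d = (mu[k] - Z(row, k)) / sdz[k];
        e += d * d;
      }
      return e / m;
    };
    double base = 0.0;
    for (int i : oob) base += sse(i, route_row(t, X, ncat, i));
    base /= oob.size();
    // permute each covariate's OOB values in turn and re-route
    Rng prng(seed, (uint64_t)(ntree + b));
    arma::mat Xw = X;  // working copy for this tree
    for (int v = 0; v < p; ++v) {
      std::vector<double> vals(oob.size());
      for (size_t k = 0; k < oob.size(); ++k) vals[k] = X(oob[k], v);
      prng.shuffle(vals);
      for (size_t k = 0; k < oob.size(); ++k) Xw(oob[k], v) = vals[k];
      double perm = 0.0;
      for (int i : oob) perm += sse(i, route_row(t, Xw, ncat, i));
      perm /= oob.size();
      vimp[v] += perm - base;
      for (size_t k = 0; k < oob.size(); ++k) Xw(oob[k], v) = X(oob[k], v);
    }
  }
  vimp /= ntree;
  return List::create(_["importance"] = NumericVector(vimp.begin(), vimp.end()));
}
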