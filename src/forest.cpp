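// Honest instrumental-variable causal trees.
//
// Each tree is grown on a random subsample (without replacement) of the
// training data.  Under honesty the subsample is divided into a split half,
// used only to search for splits, and an honest half, used only to estimate
// leaf effects.  Leaf effects are Wald ratios Cov(Y,Z)/Cov(W,Z); the split
// criterion is the exhaustive child-Wald heterogeneity score
// n_L n_R / (n_L+n_R)^2 * (tau_L - tau_R)^2.  Ordinal covariates split as
// "level <= c"; candidate splits must leave both children with at least
// min_leaf observations and a non-degenerate Wald denominator in BOTH halves.
//
// Randomness is independent of R's RNG: every tree derives its own
// generator from the master seed and the tree index, so results do not
// depend on execution order.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// xorshift-based generator: avoids reliance on library distribution
// implementations so streams are identical across platforms.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x853c49e6748fea9bULL) {}
  uint64_t next() {
    uint64_t x = s;
    x ^= x << 13;
    x ^= x >> 7;
    x ^= x << 17;
    s = x;
    return x * 0x2545f4914f6cdd1dULL;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct SuffStats {
  double n = 0, sy = 0, sw = 0, sz = 0, syz = 0, swz = 0;
  void add(double yi, double wi, double zi) {
    n += 1; sy += yi; sw += wi; sz += zi; syz += yi * zi; swz += wi * zi;
  }
  double cov_wz() const {
    if (n < 2) return 0.0;
    return (swz - sw * sz / n) / (n - 1);
  }
  double cov_yz() const {
    if (n < 2) return 0.0;
    return (syz - sy * sz / n) / (n - 1);
  }
};

struct Node {
  int id = 0, parent = 0, var = -1;  // var: 0-based covariate, -1 = leaf
  double threshold = NA_REAL;
  int left = 0, right = 0;           // 1-based node ids, 0 = none
  double effect = NA_REAL, denom = NA_REAL;
  int hon_n = 0;
  int s_lo = 0, s_hi = 0, h_lo = 0, h_hi = 0;  // ranges into index arrays
};

struct TreeGrower {
  const IntegerMatrix &X;
  const NumericVector &y, &w, &z;
  int min_leaf, mtry;
  double tol;
  const std::vector<int> &lo_lvl, &hi_lvl;
  Rng &rng;
  std::vector<int> sidx, hidx, scratch, varpool;
  std::vector<Node> nodes;

  TreeGrower(const IntegerMatrix &X_, const NumericVector &y_,
             const NumericVector &w_, const NumericVector &z_, int min_leaf_,
             int mtry_, double tol_, const std::vector<int> &lo,
             const std::vector<int> &hi, Rng &rng_)
      : X(X_), y(y_), w(w_), z(z_), min_leaf(min_leaf_), mtry(mtry_),
        tol(tol_), lo_lvl(lo), hi_lvl(hi), rng(rng_) {}

  SuffStats range_stats(const std::vector<int> &idx, int lo, int hi) const {
    SuffStats s;
    for (int k = lo; k < hi; ++k) s.add(y[idx[k]], w[idx[k]], z[idx[k]]);
    return s;
  }

  // returns true if a split was found; fills out parameters
  bool best_split(const Node &nd, int &bvar, double &bthr, double &bscore) {
    int p = X.ncol();
    int m = std::min(mtry, p);
    // sample m distinct covariates, then scan in ascending order (tie-break)
    varpool.resize(p);
    for (int j = 0; j < p; ++j) varpool[j] = j;
    for (int j = 0; j < m; ++j) {
      int k = j + rng.below(p - j);
      std::swap(varpool[j], varpool[k]);
    }
    std::sort(varpool.begin(), varpool.begin() + m);

    bscore = 0.0; bvar = -1; bthr = NA_REAL;
    for (int jj = 0; jj < m; ++jj) {
      int v = varpool[jj];
      int L = hi_lvl[v] - lo_lvl[v] + 1;
      if (L < 2) continue;
      std::vector<SuffStats> sl(L), hl(L);
      for (int k = nd.s_lo; k < nd.s_hi; ++k) {
        int i = sidx[k];
        sl[X(i, v) - lo_lvl[v]].add(y[i], w[i], z[i]);
      }
      for (int k = nd.h_lo; k < nd.h_hi; ++k) {
        int i = hidx[k];
        hl[X(i, v) - lo_lvl[v]].add(y[i], w[i], z[i]);
      }
      SuffStats stot = range_stats(sidx, nd.s_lo, nd.s_hi);
      SuffStats htot = range_stats(hidx, nd.h_lo, nd.h_hi);
      SuffStats sL, hL;
      for (int c = 0; c < L - 1; ++c) {
        sL.n += sl[c].n; sL.sy += sl[c].sy; sL.sw += sl[c].sw;
        sL.sz += sl[c].sz; sL.syz += sl[c].syz; sL.swz += sl[c].swz;
        hL.n += hl[c].n; hL.sy += hl[c].sy; hL.sw += hl[c].sw;
        hL.sz += hl[c].sz; hL.syz += hl[c].syz; hL.swz += hl[c].swz;
        if (sL.n == 0 || sL.n == stot.n) continue;  // no observed split here
        SuffStats sR, hR;
        sR.n = stot.n - sL.n; sR.sy = stot.sy - sL.sy; sR.sw = stot.sw - sL.sw;
        sR.sz = stot.sz - sL.sz; sR.syz = stot.syz - sL.syz; sR.swz = stot.swz - sL.swz;
        hR.n = htot.n - hL.n; hR.sy = htot.sy - hL.sy; hR.sw = htot.sw - hL.sw;
        hR.sz = htot.sz - hL.sz; hR.syz = htot.syz - hL.syz; hR.swz = htot.swz - hL.swz;
        if (sL.n < min_leaf || sR.n < min_leaf) continue;
        if (hL.n < min_leaf || hR.n < min_leaf) continue;
        double dsL = sL.cov_wz(), dsR = sR.cov_wz();
        double dhL = hL.cov_wz(), dhR = hR.cov_wz();
        if (std::fabs(dsL) <= tol || std::fabs(dsR) <= tol) continue;
        if (std::fabs(dhL) <= tol || std::fabs(dhR) <= tol) continue;
        double tauL = sL.cov_yz() / dsL, tauR = sR.cov_yz() / dsR;
        double ntot = sL.n + sR.n;
        double score = (sL.n * sR.n) / (ntot * ntot) * (tauL - tauR) * (tauL - tauR);
        if (score > bscore) {
          bscore = score; bvar = v; bthr = (double)(lo_lvl[v] + c);
        }
      }
    }
    return bvar >= 0;
  }

  // stable partition of idx[lo,hi) by X[,var] <= thr; returns split point
  int partition(std::vector<int> &idx, int lo, int hi, int var, double thr) {
    scratch.clear();
    int write = lo;
    for (int k = lo; k < hi; ++k) {
      int i = idx[k];
      if ((double)X(i, var) <= thr) idx[write++] = i; else scratch.push_back(i);
    }
    for (size_t k = 0; k < scratch.size(); ++k) idx[write + (int)k] = scratch[k];
    return lo + (hi - lo - (int)scratch.size());
  }

  // grow from prepared sidx/hidx; returns false if root denominator invalid
  bool grow() {
    nodes.clear();
    Node root;
    root.id = 1; root.parent = 0;
    root.s_lo = 0; root.s_hi = (int)sidx.size();
    root.h_lo = 0; root.h_hi = (int)hidx.size();
    SuffStats hs = range_stats(hidx, 0, (int)hidx.size());
    double d = hs.cov_wz();
    if (hs.n < 2 || std::fabs(d) <= tol) return false;
    nodes.push_back(root);
    std::vector<int> stack;  // indices into nodes
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back(); stack.pop_back();
      Node nd = nodes[ni];
      SuffStats h = range_stats(hidx, nd.h_lo, nd.h_hi);
      double dn = h.cov_wz();
      nodes[ni].hon_n = (int)h.n;
      nodes[ni].denom = dn;
      nodes[ni].effect = h.cov_yz() / dn;
      int bvar; double bthr, bscore;
      bool can_split = (nd.s_hi - nd.s_lo) >= 2 * min_leaf &&
                       (nd.h_hi - nd.h_lo) >= 2 * min_leaf &&
                       best_split(nd, bvar, bthr, bscore);
      if (!can_split) continue;
      int smid = partition(sidx, nd.s_lo, nd.s_hi, bvar, bthr);
      int hmid = partition(hidx, nd.h_lo, nd.h_hi, bvar, bthr);
      Node l, r;
      l.id = (int)nodes.size() + 1; l.parent = nd.id;
      l.s_lo = nd.s_lo; l.s_hi = smid; l.h_lo = nd.h_lo; l.h_hi = hmid;
      r.id = (int)nodes.size() + 2; r.parent = nd.id;
      r.s_lo = smid; r.s_hi = nd.s_hi; r.h_lo = hmid; r.h_hi = nd.h_hi;
      nodes[ni].var = bvar; nodes[ni].threshold = bthr;
      nodes[ni].left = l.id; nodes[ni].right = r.id;
      nodes.push_back(l); nodes.push_back(r);
      // push right first so the left child is expanded first (DFS)
      stack.push_back(r.id - 1);
      stack.push_back(l.id - 1);
    }
    return true;
  }
};

static NumericMatrix pack_tree(const std::vector<Node> &nodes) {
  NumericMatrix out((int)nodes.size(), 9);
  for (size_t i = 0; i < nodes.size(); ++i) {
    const Node &n = nodes[i];
    out((int)i, 0) = n.id;
    out((int)i, 1) = n.parent;
    out((int)i, 2) = n.var >= 0 ? n.var + 1 : 0;  // 1-based, 0 = leaf
    out((int)i, 3) = n.threshold;
    out((int)i, 4) = n.left;
    out((int)i, 5) = n.right;
    out((int)i, 6) = n.effect;
    out((int)i, 7) = n.hon_n;
    out((int)i, 8) = n.denom;
  }
  colnames(out) = CharacterVector::create("id", "parent", "var", "threshold",
                                          "left", "right", "effect",
                                          "honest_n", "denominator");
  return out;
}

// [[Rcpp::export]]
List cpp_grow_forest(IntegerMatrix X, NumericVector y, NumericVector w,
                     NumericVector z, int num_trees, int min_leaf,
                     double subsample_fraction, bool honesty,
                     double split_fraction, int mtry, double seed, double tol,
                     int max_retries, bool store_subsample) {
  int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 observations");
  std::vector<int> lo(p), hi(p);
  for (int v = 0; v < p; ++v) {
    int mn = X(0, v), mx = X(0, v);
    for (int i = 1; i < n; ++i) {
      if (X(i, v) < mn) mn = X(i, v);
      if (X(i, v) > mx) mx = X(i, v);
    }
    lo[v] = mn; hi[v] = mx;
    if (hi[v] - lo[v] + 1 > 4096) stop("covariate %d has too many levels", v + 1);
  }
  int m = (int)std::floor(subsample_fraction * n);
  if (m < 2) stop("subsample too small");
  List trees(num_trees);
  List subs(store_subsample ? num_trees : 0);
  std::vector<int> pool(n), sample_idx(m);
  uint64_t master = (uint64_t)seed;
  for (int t = 0; t < num_trees; ++t) {
    bool ok = false;
    for (int retry = 0; retry <= max_retries && !ok; ++retry) {
      Rng rng(mix64(master ^ mix64((uint64_t)(t + 1) + ((uint64_t)retry << 32))));
      for (int i = 0; i < n; ++i) pool[i] = i;
      for (int j = 0; j < m; ++j) {
        int k = j + rng.below(n - j);
        std::swap(pool[j], pool[k]);
        sample_idx[j] = pool[j];
      }
      TreeGrower g(X, y, w, z, min_leaf, mtry, tol, lo, hi, rng);
      if (honesty) {
        int s = (int)std::floor(split_fraction * m);
        if (s < 1 || s >= m) stop("split_fraction leaves an empty half");
        g.sidx.assign(sample_idx.begin(), sample_idx.begin() + s);
        g.hidx.assign(sample_idx.begin() + s, sample_idx.end());
      } else {
        g.sidx.assign(sample_idx.begin(), sample_idx.end());
        g.hidx.assign(sample_idx.begin(), sample_idx.end());
      }
      if (g.grow()) {
        trees[t] = pack_tree(g.nodes);
        if (store_subsample) {
          IntegerVector sv(m);
          for (int j = 0; j < m; ++j) sv[j] = sample_idx[j] + 1;
          subs[t] = sv;
        }
        ok = true;
      }
    }
    if (!ok)
      stop("tree %d: root Wald denominator below tolerance after %d retries "
           "(instrument may carry no variation)", t + 1, max_retries + 1);
  }
  List out = List::create(_["trees"] = trees);
  if (store_subsample) out["subsamples"] = subs;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, IntegerMatrix X,
                                 Nullable<List> subsamples_, bool oob) {
  int n = X.nrow();
  int T = trees.size();
  std::vector<double> sum(n, 0.0);
  std::vector<int> cnt(n, 0);
  std::vector<char> inbag;
  List subsamples;
  if (oob) {
    if (subsamples_.isNull())
      stop("out-of-bag prediction requires stored subsamples");
    subsamples = subsamples_.get();
    inbag.resize(n);
  }
  for (int t = 0; t < T; ++t) {
    NumericMatrix tr = trees[t];
    if (oob) {
      std::fill(inbag.begin(), inbag.end(), 0);
      IntegerVector sv = subsamples[t];
      for (int k = 0; k < sv.size(); ++k) {
        int i = sv[k] - 1;
        if (i >= 0 && i < n) inbag[i] = 1;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (oob && inbag[i]) continue;
      int node = 0;
      while ((int)tr(node, 2) > 0) {
        int v = (int)tr(node, 2) - 1;
        node = ((double)X(i, v) <= tr(node, 3)) ? (int)tr(node, 4) - 1
                                                : (int)tr(node, 5) - 1;
      }
      sum[i] += tr(node, 6);
      cnt[i] += 1;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cnt[i] > 0 ? sum[i] / cnt[i] : NA_REAL;
  return out;
}
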