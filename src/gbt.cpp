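#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// tree containers
// ---------------------------------------------------------------------------

// A regression tree under construction (preorder node storage;
// var = -1 marks a leaf, children are -1 when absent).
struct TreeBuf {
  std::vector<int> var, left, right;
  std::vector<double> split, value, weight, improv;
  int add_node() {
    var.push_back(-1); left.push_back(-1); right.push_back(-1);
    split.push_back(0.0); value.push_back(0.0);
    weight.push_back(0.0); improv.push_back(0.0);
    return static_cast<int>(var.size()) - 1;
  }
  int size() const { return static_cast<int>(var.size()); }
};

// All trees of an ensemble flattened into contiguous arrays for fast
// traversal (built once per exported call from the R-side list).
struct FlatTrees {
  std::vector<int> var, left, right, offset;  // offset has M+1 entries
  std::vector<double> split, value, weight;
  int M;
  explicit FlatTrees(const List &trees) {
    M = trees.size();
    offset.resize(M + 1);
    int total = 0;
    for (int m = 0; m < M; ++m) {
      offset[m] = total;
      total += as<NumericMatrix>(trees[m]).nrow();
    }
    offset[M] = total;
    var.resize(total); left.resize(total); right.resize(total);
    split.resize(total); value.resize(total); weight.resize(total);
    for (int m = 0; m < M; ++m) {
      NumericMatrix tr = trees[m];
      const int k = tr.nrow(), off = offset[m];
      const double *c0 = &tr(0, 0), *c1 = &tr(0, 1), *c2 = &tr(0, 2),
                   *c3 = &tr(0, 3), *c4 = &tr(0, 4), *c5 = &tr(0, 5);
      for (int i = 0; i < k; ++i) {
        var[off + i] = static_cast<int>(c0[i]) - 1;        // -1 = leaf
        split[off + i] = c1[i];
        left[off + i] = static_cast<int>(c2[i]) - 1 + off; // absolute index
        right[off + i] = static_cast<int>(c3[i]) - 1 + off;
        value[off + i] = c4[i];
        weight[off + i] = c5[i];
      }
    }
  }
};

static double median_of(std::vector<double> v) {
  const size_t n = v.size();
  if (n == 0) return 0.0;
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.begin() + n / 2);
  return 0.5 * (v[n / 2 - 1] + hi);
}

// ---------------------------------------------------------------------------
// fitting
// ---------------------------------------------------------------------------

// Workspace for growing one tree: per-feature index arrays sorted by that
// feature, all features sharing the same [lo, hi) segment per node.
struct GrowWork {
  int p, cap;
  std::vector<std::vector<int> > idx;  // p arrays of length cap
  std::vector<int> bufL, bufR;
  GrowWork(int p_, int cap_) : p(p_), cap(cap_),
    idx(p_, std::vector<int>(cap_)), bufL(cap_), bufR(cap_) {}
};

struct GrowCtx {
  const std::vector<const double*> &cols;
  const std::vector<double> &z;
  int minobs, nsub;
};

// best least-squares split of segment [lo, hi); scanning features and
// thresholds in ascending order with a strict improvement test breaks
// ties in favour of the lowest variable index, then the lowest threshold
struct SplitInfo { int f; double thr, gain; };
static SplitInfo best_split(const GrowWork &W, const GrowCtx &C,
                            int lo, int hi, double sum) {
  SplitInfo best{-1, 0.0, 0.0};
  const int n = hi - lo;
  if (n < 2 * C.minobs) return best;
  const double base = sum * sum / n;
  const int minobs = C.minobs;
  for (int f = 0; f < W.p; ++f) {
    const int *sf = W.idx[f].data();
    const double *xf = C.cols[f];
    double sL = 0.0;
    const int last = hi - 1;
    for (int i = lo; i < last; ++i) {
      sL += C.z[sf[i]];
      const int nL = i - lo + 1, nR = n - nL;
      if (nL < minobs) continue;
      if (nR < minobs) break;
      const double xl = xf[sf[i]], xr = xf[sf[i + 1]];
      if (!(xr > xl)) continue;  // cannot separate equal values
      const double sR = sum - sL;
      const double gain = sL * sL / nL + sR * sR / nR - base;
      if (gain > best.gain) {
        best.gain = gain; best.f = f; best.thr = 0.5 * (xl + xr);
      }
    }
  }
  return best;
}

// Best-first tree growth: starting from the root, repeatedly split the
// current leaf whose best split most reduces the residual sum of squares,
// up to `depth` splits in total.  A tree with d splits has d + 1 leaves
// and no root-to-leaf path longer than d splits, so it can represent
// interactions of order at most d (d = 1 gives a stump, hence an
// additive model).  Ties in gain fall to the earliest-created leaf.
struct LeafCand {
  int node, lo, hi;
  double sum;
  SplitInfo sp;
};
static void grow_tree(TreeBuf &T, GrowWork &W, const GrowCtx &C, int depth) {
  const int root = T.add_node();
  T.weight[root] = 1.0;
  double sum = 0.0;
  {
    const int *a = W.idx[0].data();
    for (int i = 0; i < C.nsub; ++i) sum += C.z[a[i]];
  }
  T.value[root] = sum / C.nsub;

  std::vector<LeafCand> leaves;
  leaves.push_back(LeafCand{root, 0, C.nsub, sum,
                            best_split(W, C, 0, C.nsub, sum)});

  for (int s = 0; s < depth; ++s) {
    int pick = -1;
    double bestgain = 0.0;
    for (size_t q = 0; q < leaves.size(); ++q) {
      if (leaves[q].sp.f >= 0 && leaves[q].sp.gain > bestgain) {
        bestgain = leaves[q].sp.gain; pick = static_cast<int>(q);
      }
    }
    if (pick < 0) break;

    LeafCand L = leaves[pick];
    T.var[L.node] = L.sp.f;
    T.split[L.node] = L.sp.thr;
    T.improv[L.node] = L.sp.gain;

    // stable partition of every feature's segment around the split
    const double *xb = C.cols[L.sp.f];
    const double thr = L.sp.thr;
    int nL = 0;
    double sumL = 0.0;
    for (int f = 0; f < W.p; ++f) {
      int *sf = W.idx[f].data();
      int cl = 0, cr = 0;
      for (int i = L.lo; i < L.hi; ++i) {
        const int o = sf[i];
        if (xb[o] <= thr) W.bufL[cl++] = o; else W.bufR[cr++] = o;
      }
      std::memcpy(sf + L.lo, W.bufL.data(), cl * sizeof(int));
      std::memcpy(sf + L.lo + cl, W.bufR.data(), cr * sizeof(int));
      nL = cl;
    }
    if (W.p == 0) break;
    {
      const int *a = W.idx[0].data();
      for (int i = L.lo; i < L.lo + nL; ++i) sumL += C.z[a[i]];
    }
    const int mid = L.lo + nL;

    const int l = T.add_node(), r = T.add_node();
    T.left[L.node] = l; T.right[L.node] = r;
    T.weight[l] = static_cast<double>(nL) / C.nsub;
    T.weight[r] = static_cast<double>(L.hi - mid) / C.nsub;
    T.value[l] = sumL / nL;
    T.value[r] = (L.sum - sumL) / (L.hi - mid);

    leaves[pick] = LeafCand{l, L.lo, mid, sumL,
                            best_split(W, C, L.lo, mid, sumL)};
    leaves.push_back(LeafCand{r, mid, L.hi, L.sum - sumL,
                              best_split(W, C, mid, L.hi, L.sum - sumL)});
  }
}

static int descend(const TreeBuf &T, const std::vector<const double*> &cols,
                   int row) {
  int node = 0;
  while (T.var[node] >= 0) {
    node = (cols[T.var[node]][row] <= T.split[node]) ? T.left[node]
                                                     : T.right[node];
  }
  return node;
}

static NumericMatrix tree_to_matrix(const TreeBuf &T) {
  const int k = T.size();
  NumericMatrix M(k, 7);
  for (int i = 0; i < k; ++i) {
    M(i, 0) = T.var[i] >= 0 ? T.var[i] + 1 : 0;   // 1-based, 0 = leaf
    M(i, 1) = T.split[i];
    M(i, 2) = T.left[i] >= 0 ? T.left[i] + 1 : 0;
    M(i, 3) = T.right[i] >= 0 ? T.right[i] + 1 : 0;
    M(i, 4) = T.value[i];
    M(i, 5) = T.weight[i];
    M(i, 6) = T.improv[i];
  }
  colnames(M) = CharacterVector::create("var", "split", "left", "right",
                                        "value", "weight", "improvement");
  return M;
}

// Stochastic gradient boosting with regression-tree base learners.
// loss: 0 = squared error, 1 = absolute error.
// [[Rcpp::export]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int M, int depth,
                 double lambda, double eta, int loss, int minobs) {
  const int n = X.nrow(), p = X.ncol();

  std::vector<const double*> cols(p);
  for (int f = 0; f < p; ++f) cols[f] = &X(0, f);

  // global presort of each feature
  std::vector<std::vector<int> > ord(p, std::vector<int>(n));
  for (int f = 0; f < p; ++f) {
    std::vector<int> &of = ord[f];
    for (int i = 0; i < n; ++i) of[i] = i;
    const double *xf = cols[f];
    std::stable_sort(of.begin(), of.end(),
                     [xf](int a, int b) { return xf[a] < xf[b]; });
  }

  double init;
  if (loss == 0) {
    init = std::accumulate(y.begin(), y.end(), 0.0) / n;
  } else {
    init = median_of(std::vector<double>(y.begin(), y.end()));
  }

  std::vector<double> F(n, init), resid(n), z(n);
  int nsub = static_cast<int>(std::floor(eta * n + 0.5));
  if (nsub < 1) nsub = 1;
  if (nsub > n) nsub = n;

  std::vector<int> perm(n);
  std::vector<char> ins(n);
  GrowWork W(p, n);
  GrowCtx C{cols, z, minobs, nsub};
  List trees(M);

  for (int m = 0; m < M; ++m) {
    // subsample without replacement (partial Fisher-Yates on R's RNG)
    std::fill(ins.begin(), ins.end(), 0);
    if (nsub >= n) {
      std::fill(ins.begin(), ins.end(), 1);
    } else {
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int j = 0; j < nsub; ++j) {
        int k = j + static_cast<int>(unif_rand() * (n - j));
        if (k >= n) k = n - 1;
        std::swap(perm[j], perm[k]);
        ins[perm[j]] = 1;
      }
    }

    for (int i = 0; i < n; ++i) {
      resid[i] = y[i] - F[i];
      z[i] = (loss == 0) ? resid[i]
                         : (resid[i] > 0 ? 1.0 : (resid[i] < 0 ? -1.0 : 0.0));
    }

    // root segments: presorted order filtered to the subsample
    for (int f = 0; f < p; ++f) {
      const int *of = ord[f].data();
      int *sf = W.idx[f].data();
      int c = 0;
      for (int i = 0; i < n; ++i) {
        const int o = of[i];
        if (ins[o]) sf[c++] = o;
      }
    }

    TreeBuf T;
    grow_tree(T, W, C, depth);

    if (loss == 1) {
      // terminal values are loss-optimal constants: medians of the raw
      // residuals of the subsampled observations in each leaf
      std::vector<std::vector<double> > leafres(T.size());
      for (int i = 0; i < n; ++i) {
        if (!ins[i]) continue;
        leafres[descend(T, cols, i)].push_back(resid[i]);
      }
      for (int q = 0; q < T.size(); ++q) {
        if (T.var[q] < 0 && !leafres[q].empty())
          T.value[q] = median_of(leafres[q]);
      }
    }

    for (int i = 0; i < n; ++i)
      F[i] += lambda * T.value[descend(T, cols, i)];

    trees[m] = tree_to_matrix(T);
  }

  return List::create(_["init"] = init, _["trees"] = trees,
                      _["fitted"] = NumericVector(F.begin(), F.end()));
}

// ---------------------------------------------------------------------------
// prediction
// ---------------------------------------------------------------------------

static inline double predict_flat(const FlatTrees &FT, int root,
                                  const std::vector<const double*> &cols,
                                  int row) {
  int node = root;
  while (FT.var[node] >= 0) {
    node = (cols[FT.var[node]][row] <= FT.split[node]) ? FT.left[node]
                                                       : FT.right[node];
  }
  return FT.value[node];
}

// [[Rcpp::export]]
NumericVector gbt_predict_cpp(List trees, double init, double lambda,
                              NumericMatrix X, int ntrees) {
  const int n = X.nrow(), p = X.ncol();
  FlatTrees FT(trees);
  std::vector<const double*> cols(p);
  for (int f = 0; f < p; ++f) cols[f] = &X(0, f);
  NumericVector out(n, init);
  for (int m = 0; m < ntrees; ++m) {
    const int root = FT.offset[m];
    for (int i = 0; i < n; ++i)
      out[i] += lambda * predict_flat(FT, root, cols, i);
  }
  return out;
}

// Predictions after each ensemble size in mgrid (ascending); one pass.
// [[Rcpp::export]]
NumericMatrix gbt_staged_cpp(List trees, double init, double lambda,
                             NumericMatrix X, IntegerVector mgrid) {
  const int n = X.nrow(), p = X.ncol(), g = mgrid.size();
  FlatTrees FT(trees);
  std::vector<const double*> cols(p);
  for (int f = 0; f < p; ++f) cols[f] = &X(0, f);
  NumericMatrix out(n, g);
  std::vector<double> F(n, init);
  int col = 0;
  for (int m = 0; m <= FT.M && col < g; ++m) {
    while (col < g && mgrid[col] == m) {
      for (int i = 0; i < n; ++i) out(i, col) = F[i];
      ++col;
    }
    if (m == FT.M) break;
    const int root = FT.offset[m];
    for (int i = 0; i < n; ++i)
      F[i] += lambda * predict_flat(FT, root, cols, i);
  }
  return out;
}

// ---------------------------------------------------------------------------
// partial dependence
// ---------------------------------------------------------------------------

// Reference-data prepass for one tree: cnt[node] counts the reference
// rows whose complement-variable values satisfy the complement
// constraints on the path to the node -- exactly the weighting of the
// definitional average.  Splits on subset variables do not filter (the
// partial-dependence average fixes those coordinates), so both children
// share the parent's row set without copying; splits on complement
// variables partition it.
static void pd_count(const FlatTrees &FT, int root, int node,
                     const std::vector<const double*> &refcols,
                     const std::vector<int> &smap,
                     std::vector<int> &rows, std::vector<double> &cnt) {
  cnt[node - root] = static_cast<double>(rows.size());
  const int v = FT.var[node];
  if (v < 0) return;
  if (smap[v] >= 0) {
    pd_count(FT, root, FT.left[node], refcols, smap, rows, cnt);
    pd_count(FT, root, FT.right[node], refcols, smap, rows, cnt);
  } else {
    std::vector<int> L, R;
    L.reserve(rows.size()); R.reserve(rows.size());
    const double *xv = refcols[v];
    const double thr = FT.split[node];
    for (size_t q = 0; q < rows.size(); ++q) {
      if (xv[rows[q]] <= thr) L.push_back(rows[q]); else R.push_back(rows[q]);
    }
    pd_count(FT, root, FT.left[node], refcols, smap, L, cnt);
    pd_count(FT, root, FT.right[node], refcols, smap, R, cnt);
  }
}

// Collapse pass: subtrees containing no split on a subset variable have a
// point-independent partial-dependence value (the weighted average of
// their leaves); precomputing it prunes the per-point traversal to the
// spine of subset splits.  Nodes are stored in preorder, so children have
// larger indices than their parent and a reverse sweep visits children
// first.
static void pd_collapse(const FlatTrees &FT, int root, int nnodes,
                        const std::vector<int> &smap, const double *w,
                        std::vector<char> &hasS, std::vector<double> &val0) {
  for (int q = nnodes - 1; q >= 0; --q) {
    const int node = root + q;
    const int v = FT.var[node];
    if (v < 0) {
      hasS[q] = 0; val0[q] = FT.value[node];
    } else if (smap[v] >= 0) {
      hasS[q] = 1; val0[q] = 0.0;
    } else {
      const int lq = FT.left[node] - root, rq = FT.right[node] - root;
      hasS[q] = hasS[lq] || hasS[rq];
      const double wl = w[lq], wr = w[rq], tot = wl + wr;
      val0[q] = tot > 0.0 ? (wl * val0[lq] + wr * val0[rq]) / tot
                          : 0.5 * (val0[lq] + val0[rq]);
    }
  }
}

// evaluate the weighted traversal for one point
static double pd_eval(const FlatTrees &FT, int root, int node,
                      const std::vector<int> &smap, const double *w,
                      const std::vector<char> &hasS,
                      const std::vector<double> &val0,
                      const std::vector<const double*> &ptcols, int row) {
  const int q = node - root;
  if (!hasS[q]) return val0[q];
  const int v = FT.var[node];
  const int l = FT.left[node], r = FT.right[node];
  const int sidx = smap[v];
  if (sidx >= 0) {
    const int next = (ptcols[sidx][row] <= FT.split[node]) ? l : r;
    return pd_eval(FT, root, next, smap, w, hasS, val0, ptcols, row);
  }
  const double wl = w[l - root], wr = w[r - root];
  const double vl = pd_eval(FT, root, l, smap, w, hasS, val0, ptcols, row);
  const double vr = pd_eval(FT, root, r, smap, w, hasS, val0, ptcols, row);
  const double tot = wl + wr;
  if (tot <= 0.0) return 0.5 * (vl + vr);
  return (wl * vl + wr * vr) / tot;
}

// Partial dependence by weighted tree traversal.  svars: 0-based column
// indices (into the training design) of the subset, in the order of the
// columns of `points`.  When `refdata` (full-width data) is supplied the
// traversal weights are recomputed per tree by routing the reference rows
// (exact: reproduces the brute-force definitional average over refdata);
// otherwise the training-weight fractions stored in the nodes are used
// (data-free approximation).
// [[Rcpp::export]]
NumericVector gbt_pd_cpp(List trees, double init, double lambda,
                         NumericMatrix points, IntegerVector svars, int pfull,
                         Nullable<NumericMatrix> refdata = R_NilValue) {
  const int npts = points.nrow(), k = points.ncol();
  FlatTrees FT(trees);
  std::vector<int> smap(pfull, -1);
  for (int q = 0; q < svars.size(); ++q) smap[svars[q]] = q;
  std::vector<const double*> ptcols(k);
  for (int q = 0; q < k; ++q) ptcols[q] = &points(0, q);

  NumericVector out(npts, init);

  const bool have_ref = refdata.isNotNull();
  NumericMatrix ref;
  std::vector<const double*> refcols;
  int nref = 0, maxnodes = 0;
  for (int m = 0; m < FT.M; ++m)
    maxnodes = std::max(maxnodes, FT.offset[m + 1] - FT.offset[m]);
  if (have_ref) {
    ref = refdata.get();
    nref = ref.nrow();
    refcols.resize(ref.ncol());
    for (int f = 0; f < ref.ncol(); ++f) refcols[f] = &ref(0, f);
  }
  std::vector<double> w(maxnodes);
  std::vector<char> hasS(maxnodes);
  std::vector<double> val0(maxnodes);
  std::vector<int> allrows(nref);
  for (int i = 0; i < nref; ++i) allrows[i] = i;

  for (int m = 0; m < FT.M; ++m) {
    const int root = FT.offset[m];
    const int nnodes = FT.offset[m + 1] - root;
    if (have_ref) {
      std::vector<int> rows(allrows);
      pd_count(FT, root, root, refcols, smap, rows, w);
    } else {
      for (int q = 0; q < nnodes; ++q) w[q] = FT.weight[root + q];
    }
    pd_collapse(FT, root, nnodes, smap, w.data(), hasS, val0);
    for (int i = 0; i < npts; ++i)
      out[i] += lambda * pd_eval(FT, root, root, smap, w.data(), hasS, val0,
                                 ptcols, i);
  }
  return out;
}
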