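#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact Shapley attributions for tree ensembles.
//
// The ensemble is flattened into parallel arrays over all nodes of all
// trees: feature[i] (0-based column, -1 for a leaf), split[i], yes[i]/no[i]
// (0-based global node indices), value[i] (leaf contribution), cover[i]
// (training weight reaching the node). tree_offset gives each tree's root
// index. Routing rule: go to `yes` when x < split (lt = true) or
// x <= split (lt = false).
//
// The coalition game explained is the standard path-cover one: for a
// coalition S the tree is evaluated by following the split when its feature
// is in S and averaging both children with cover weights otherwise. The
// weight a leaf receives factorises over the distinct features on its path
// (per feature: product of split indicators if the feature is in S, product
// of child/parent cover ratios otherwise), so each leaf defines a
// multilinear game whose Shapley values have a closed form. Summing leaves
// gives the exact attribution in O(leaves * depth^2) per record and tree.

static const int MAXD = 64;

struct PathEdge {
  int feat;
  double ratio;  // cover(child)/cover(parent)
  double ind;    // 1 if the record satisfies the split, else 0
};

struct ShapCtx {
  const int *feature;
  const double *split;
  const int *yes;
  const int *no_;
  const double *value;
  const double *cover;
  const double *x;  // one record, length p
  bool lt;
  double *phi;      // length p accumulator
  // factorial table for Shapley weights
  double fact[MAXD + 2];
};

// accumulate one leaf's contribution into ctx->phi
static void leaf_contrib(ShapCtx *ctx, PathEdge *path, int depth,
                         double leaf_value) {
  // collapse edges by distinct feature
  int feats[MAXD];
  double a[MAXD], b[MAXD];
  int m = 0;
  for (int e = 0; e < depth; ++e) {
    int j = -1;
    for (int q = 0; q < m; ++q) if (feats[q] == path[e].feat) { j = q; break; }
    if (j < 0) {
      feats[m] = path[e].feat; a[m] = path[e].ind; b[m] = path[e].ratio; ++m;
    } else {
      a[j] *= path[e].ind; b[j] *= path[e].ratio;
    }
  }
  if (m == 0) return;  // root is a leaf: constant tree, no attribution

  // full subset-size polynomial: c[t] = sum over subsets T (|T| = t, all
  // members with a=1) of prod_{j not in T} b_j
  double c[MAXD + 1], cm[MAXD + 1];
  c[0] = 1.0;
  for (int t = 1; t <= m; ++t) c[t] = 0.0;
  for (int q = 0; q < m; ++q) {
    for (int t = q + 1; t >= 1; --t)
      c[t] = c[t] * b[q] + (a[q] == 1.0 ? c[t - 1] : 0.0);
    c[0] *= b[q];
  }

  for (int i = 0; i < m; ++i) {
    double diff = a[i] - b[i];
    if (diff == 0.0) continue;
    // unwind feature i out of the polynomial
    if (a[i] == 1.0) {
      cm[m - 1] = c[m];
      for (int t = m - 1; t >= 1; --t) cm[t - 1] = c[t] - cm[t] * b[i];
    } else {
      // a = 0, so diff != 0 forces b > 0 and plain division inverts the
      // polynomial extension
      for (int t = 0; t <= m - 1; ++t) cm[t] = c[t] / b[i];
    }
    double s = 0.0;
    for (int t = 0; t <= m - 1; ++t) {
      double w = ctx->fact[t] * ctx->fact[m - 1 - t] / ctx->fact[m];
      s += w * cm[t];
    }
    ctx->phi[feats[i]] += leaf_value * diff * s;
  }
}

static void recurse(ShapCtx *ctx, int node, PathEdge *path, int depth) {
  int f = ctx->feature[node];
  if (f < 0) {
    leaf_contrib(ctx, path, depth, ctx->value[node]);
    return;
  }
  if (depth >= MAXD) stop("tree deeper than supported maximum");
  int ch_yes = ctx->yes[node], ch_no = ctx->no_[node];
  double cv = ctx->cover[node];
  if (cv <= 0) stop("node with nonpositive cover");
  bool go_yes = ctx->lt ? (ctx->x[f] < ctx->split[node])
                        : (ctx->x[f] <= ctx->split[node]);
  path[depth].feat = f;
  path[depth].ratio = ctx->cover[ch_yes] / cv;
  path[depth].ind = go_yes ? 1.0 : 0.0;
  recurse(ctx, ch_yes, path, depth + 1);
  path[depth].ratio = ctx->cover[ch_no] / cv;
  path[depth].ind = go_yes ? 0.0 : 1.0;
  recurse(ctx, ch_no, path, depth + 1);
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(IntegerVector feature, NumericVector split,
                  IntegerVector yes, IntegerVector no,
                  NumericVector value, NumericVector cover,
                  IntegerVector tree_offset, NumericMatrix X, bool lt) {
  int n = X.nrow(), p = X.ncol(), T = tree_offset.size();
  NumericMatrix phi(n, p);

  // base value: cover-weighted leaf mean per tree (independent of x)
  double base = 0.0;
  std::vector<int> stack;
  for (int t = 0; t < T; ++t) {
    int root = tree_offset[t];
    double root_cover = cover[root];
    stack.clear();
    stack.push_back(root);
    while (!stack.empty()) {
      int nd = stack.back(); stack.pop_back();
      if (feature[nd] < 0) base += value[nd] * cover[nd] / root_cover;
      else { stack.push_back(yes[nd]); stack.push_back(no[nd]); }
    }
  }

  ShapCtx ctx;
  ctx.feature = INTEGER(feature);
  ctx.split = REAL(split);
  ctx.yes = INTEGER(yes);
  ctx.no_ = INTEGER(no);
  ctx.value = REAL(value);
  ctx.cover = REAL(cover);
  ctx.lt = lt;
  ctx.fact[0] = 1.0;
  for (int i = 1; i <= MAXD + 1; ++i) ctx.fact[i] = ctx.fact[i - 1] * i;

  std::vector<double> xrow(p), phirow(p);
  PathEdge path[MAXD];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) { xrow[j] = X(i, j); phirow[j] = 0.0; }
    ctx.x = xrow.data();
    ctx.phi = phirow.data();
    for (int t = 0; t < T; ++t) recurse(&ctx, tree_offset[t], path, 0);
    for (int j = 0; j < p; ++j) phi(i, j) = phirow[j];
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}

// training-cover computation: route weighted records and accumulate the
// weight visiting every node; W has one weight column per tree (bootstrap
// in-bag counts for forests, all-ones for boosting)
// [[Rcpp::export(name = ".tree_covers_cpp")]]
NumericVector tree_covers_cpp(IntegerVector feature, NumericVector split,
                              IntegerVector yes, IntegerVector no,
                              IntegerVector tree_offset, NumericMatrix X,
                              NumericMatrix W, bool lt) {
  int n = X.nrow(), T = tree_offset.size();
  NumericVector cover(feature.size());
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) {
      double w = W(i, t);
      if (w == 0.0) continue;
      int nd = tree_offset[t];
      for (;;) {
        cover[nd] += w;
        int f = feature[nd];
        if (f < 0) break;
        bool go_yes = lt ? (X(i, f) < split[nd]) : (X(i, f) <= split[nd]);
        nd = go_yes ? yes[nd] : no[nd];
      }
    }
  }
  return cover;
}

// raw ensemble output (sum of reached leaf values) per record
// [[Rcpp::export(name = ".ensemble_margin_cpp")]]
NumericVector ensemble_margin_cpp(IntegerVector feature, NumericVector split,
                                  IntegerVector yes, IntegerVector no,
                                  NumericVector value,
                                  IntegerVector tree_offset, NumericMatrix X,
                                  bool lt) {
  int n = X.nrow(), T = tree_offset.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
      int nd = tree_offset[t];
      while (feature[nd] >= 0) {
        bool go_yes = lt ? (X(i, feature[nd]) < split[nd])
                         : (X(i, feature[nd]) <= split[nd]);
        nd = go_yes ? yes[nd] : no[nd];
      }
      s += value[nd];
    }
    out[i] = s;
  }
  return out;
}
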