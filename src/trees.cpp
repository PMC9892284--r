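#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "lnbart.h"

using namespace Rcpp;

// Backfitting engine for the regression-tree ensemble.  One BartState holds
// the training data, cutpoint grids, the H trees, the per-observation leaf
// assignments and the running ensemble fit.  The R driver calls
// .bart_iter_cpp() once per MCMC iteration (all H tree updates), passing in
// the current split-probability vector s and noise variance; the
// split-probability and sigma^2 updates themselves live in R.
//
// Tree moves are GROW / PRUNE / CHANGE with fixed probabilities
// 0.25 / 0.25 / 0.50; an infeasible selection (e.g. PRUNE on a stump, or a
// proposal with no valid cutpoint) is a rejected proposal, which keeps the
// move-type proposal probabilities symmetric in every Metropolis-Hastings
// ratio.  Predictor and cutpoint proposal probabilities equal their prior
// (predictor ~ s, cutpoint uniform on the cuts valid at the node), so they
// cancel from the ratios.

struct Node {
  int var;    // -1 leaf, -2 free slot
  int cut;    // cutpoint index into the predictor's grid
  int left, right, parent;
  int depth;
  double mu;  // terminal value (leaves)
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> freed;

  int new_node() {
    if (!freed.empty()) { int id = freed.back(); freed.pop_back(); return id; }
    nodes.push_back(Node());
    return (int)nodes.size() - 1;
  }
  void free_node(int id) { nodes[id].var = -2; freed.push_back(id); }
  bool is_leaf(int id) const { return nodes[id].var == -1; }
  bool is_nog(int id) const { // interior with two terminal children
    const Node &nd = nodes[id];
    return nd.var >= 0 && is_leaf(nd.left) && is_leaf(nd.right);
  }
};

struct BartState {
  int n, p, H, ntree_nodes_max;
  std::vector<double> x;        // n x p, column major
  std::vector<double> yc;       // centered outcome
  std::vector<std::vector<double>> cuts;  // per-predictor grids (ascending)
  std::vector<Tree> trees;
  std::vector<std::vector<int>> leaf;     // per tree: leaf id for each obs
  std::vector<double> F;        // ensemble fit
  // structure prior
  double alpha, lam, leaf_var;
  int depth_form;               // 0: alpha*(1+lam)^-d, 1: alpha*(1+d)^-lam
  double pgrow, pprune;         // move probabilities (change = remainder)

  double xval(int i, int j) const { return x[(size_t)j * n + i]; }
  double delta(int d) const {
    return depth_form == 0 ? alpha * std::pow(1.0 + lam, -(double)d)
                           : alpha * std::pow(1.0 + (double)d, -lam);
  }
};

// varying part of the log marginal likelihood of one leaf (terms that are
// identical between a node and its two children cancel and are dropped)
static inline double lhalf(double m, double sumr, double sigma2, double v) {
  double denom = sigma2 + m * v;
  return 0.5 * std::log(sigma2 / denom) + 0.5 * v * sumr * sumr / (sigma2 * denom);
}

static int sample_categorical(const std::vector<double> &cum) {
  double u = R::unif_rand() * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) { int mid = (lo + hi) / 2; if (u <= cum[mid]) hi = mid; else lo = mid + 1; }
  return lo;
}

// valid cut index range [lo, hi] for predictor j over [minx, maxx):
// rule "x <= cut goes left" needs minx <= cut < maxx for both children
// to be nonempty
static bool valid_cut_range(const std::vector<double> &grid, double minx,
                            double maxx, int &lo, int &hi) {
  lo = (int)(std::lower_bound(grid.begin(), grid.end(), minx) - grid.begin());
  hi = (int)(std::lower_bound(grid.begin(), grid.end(), maxx) - grid.begin()) - 1;
  return lo <= hi && lo < (int)grid.size();
}

static void collect_leaves(const Tree &tr, std::vector<int> &out) {
  out.clear();
  for (int id = 0; id < (int)tr.nodes.size(); ++id)
    if (tr.nodes[id].var == -1) out.push_back(id);
}

static void collect_nogs(const Tree &tr, std::vector<int> &out) {
  out.clear();
  for (int id = 0; id < (int)tr.nodes.size(); ++id)
    if (tr.nodes[id].var >= 0 && tr.is_nog(id)) out.push_back(id);
}

// ---- moves ----------------------------------------------------------------

static void try_grow(BartState &st, int h, const std::vector<double> &scum,
                     double sigma2, const std::vector<double> &r) {
  Tree &tr = st.trees[h];
  std::vector<int> leaves;
  collect_leaves(tr, leaves);
  int nterm = (int)leaves.size();
  int nd = leaves[(int)(R::unif_rand() * nterm) % nterm];
  int j = sample_categorical(scum);

  // node pass: size, residual sum, x_j range
  double m = 0.0, sumr = 0.0, minx = R_PosInf, maxx = R_NegInf;
  std::vector<int> &lf = st.leaf[h];
  for (int i = 0; i < st.n; ++i) {
    if (lf[i] != nd) continue;
    m += 1.0; sumr += r[i];
    double xv = st.xval(i, j);
    if (xv < minx) minx = xv;
    if (xv > maxx) maxx = xv;
  }
  if (m == 0.0) return; // empty leaf cannot be grown (no valid split)
  int lo, hi;
  if (!valid_cut_range(st.cuts[j], minx, maxx, lo, hi)) return;
  int cidx = lo + (int)(R::unif_rand() * (hi - lo + 1));
  if (cidx > hi) cidx = hi;
  double cval = st.cuts[j][cidx];

  double ml = 0.0, sl = 0.0;
  for (int i = 0; i < st.n; ++i) {
    if (lf[i] != nd) continue;
    if (st.xval(i, j) <= cval) { ml += 1.0; sl += r[i]; }
  }
  double mr = m - ml, sr = sumr - sl;

  int d = tr.nodes[nd].depth;
  double dd = st.delta(d), dd1 = st.delta(d + 1);
  double lprior = std::log(dd) + 2.0 * std::log1p(-dd1) - std::log1p(-dd);
  int nnog = 0;
  {
    std::vector<int> nogs;
    collect_nogs(tr, nogs);
    nnog = (int)nogs.size();
  }
  int par = tr.nodes[nd].parent;
  int nnog_new = nnog + 1 - ((par >= 0 && tr.is_nog(par)) ? 1 : 0);
  double ltrans = std::log((double)nterm) - std::log((double)nnog_new);
  double llik = lhalf(ml, sl, sigma2, st.leaf_var) + lhalf(mr, sr, sigma2, st.leaf_var) -
                lhalf(m, sumr, sigma2, st.leaf_var);

  if (std::log(R::unif_rand()) < lprior + ltrans + llik) {
    int lchild = tr.new_node();
    int rchild = tr.new_node();
    Node &ndr = tr.nodes[nd];
    ndr.var = j; ndr.cut = cidx;
    ndr.left = lchild; ndr.right = rchild;
    tr.nodes[lchild] = Node{-1, 0, -1, -1, nd, ndr.depth + 1, 0.0};
    tr.nodes[rchild] = Node{-1, 0, -1, -1, nd, ndr.depth + 1, 0.0};
    for (int i = 0; i < st.n; ++i)
      if (lf[i] == nd) lf[i] = (st.xval(i, j) <= cval) ? lchild : rchild;
  }
}

static void try_prune(BartState &st, int h, double sigma2,
                      const std::vector<double> &r) {
  Tree &tr = st.trees[h];
  std::vector<int> nogs;
  collect_nogs(tr, nogs);
  int nnog = (int)nogs.size();
  if (nnog == 0) return;
  int nd = nogs[(int)(R::unif_rand() * nnog) % nnog];
  int lc = tr.nodes[nd].left, rc = tr.nodes[nd].right;

  double ml = 0.0, sl = 0.0, mr = 0.0, sr = 0.0;
  std::vector<int> &lf = st.leaf[h];
  for (int i = 0; i < st.n; ++i) {
    if (lf[i] == lc) { ml += 1.0; sl += r[i]; }
    else if (lf[i] == rc) { mr += 1.0; sr += r[i]; }
  }
  double m = ml + mr, sumr = sl + sr;

  std::vector<int> leaves;
  collect_leaves(tr, leaves);
  int nterm = (int)leaves.size();      // leaves in current tree
  int d = tr.nodes[nd].depth;
  double dd = st.delta(d), dd1 = st.delta(d + 1);
  double lprior = std::log(dd) + 2.0 * std::log1p(-dd1) - std::log1p(-dd);
  double ltrans = std::log((double)(nterm - 1)) - std::log((double)nnog);
  double llik = lhalf(ml, sl, sigma2, st.leaf_var) + lhalf(mr, sr, sigma2, st.leaf_var) -
                lhalf(m, sumr, sigma2, st.leaf_var);

  if (std::log(R::unif_rand()) < -(lprior + ltrans + llik)) {
    Node &ndr = tr.nodes[nd];
    ndr.var = -1; ndr.left = -1; ndr.right = -1; ndr.mu = 0.0;
    tr.free_node(lc);
    tr.free_node(rc);
    for (int i = 0; i < st.n; ++i)
      if (lf[i] == lc || lf[i] == rc) lf[i] = nd;
  }
}

static void try_change(BartState &st, int h, const std::vector<double> &scum,
                       double sigma2, const std::vector<double> &r) {
  Tree &tr = st.trees[h];
  std::vector<int> nogs;
  collect_nogs(tr, nogs);
  int nnog = (int)nogs.size();
  if (nnog == 0) return;
  int nd = nogs[(int)(R::unif_rand() * nnog) % nnog];
  int lc = tr.nodes[nd].left, rc = tr.nodes[nd].right;
  int jn = sample_categorical(scum);

  double ol = 0.0, osl = 0.0, orr = 0.0, osr = 0.0;
  double minx = R_PosInf, maxx = R_NegInf;
  std::vector<int> &lf = st.leaf[h];
  for (int i = 0; i < st.n; ++i) {
    bool inl = (lf[i] == lc), inr = (lf[i] == rc);
    if (!inl && !inr) continue;
    if (inl) { ol += 1.0; osl += r[i]; } else { orr += 1.0; osr += r[i]; }
    double xv = st.xval(i, jn);
    if (xv < minx) minx = xv;
    if (xv > maxx) maxx = xv;
  }
  int lo, hi;
  if (!valid_cut_range(st.cuts[jn], minx, maxx, lo, hi)) return;
  int cidx = lo + (int)(R::unif_rand() * (hi - lo + 1));
  if (cidx > hi) cidx = hi;
  double cval = st.cuts[jn][cidx];

  double nl = 0.0, nsl = 0.0, nr = 0.0, nsr = 0.0;
  for (int i = 0; i < st.n; ++i) {
    if (lf[i] != lc && lf[i] != rc) continue;
    if (st.xval(i, jn) <= cval) { nl += 1.0; nsl += r[i]; }
    else { nr += 1.0; nsr += r[i]; }
  }
  double llik = lhalf(nl, nsl, sigma2, st.leaf_var) + lhalf(nr, nsr, sigma2, st.leaf_var) -
                lhalf(ol, osl, sigma2, st.leaf_var) - lhalf(orr, osr, sigma2, st.leaf_var);

  if (std::log(R::unif_rand()) < llik) {
    Node &ndr = tr.nodes[nd];
    ndr.var = jn; ndr.cut = cidx;
    for (int i = 0; i < st.n; ++i)
      if (lf[i] == lc || lf[i] == rc)
        lf[i] = (st.xval(i, jn) <= cval) ? lc : rc;
  }
}

// conjugate draw of all terminal values of tree h given residuals r
static void leaf_draw(BartState &st, int h, double sigma2,
                      const std::vector<double> &r) {
  Tree &tr = st.trees[h];
  int nn = (int)tr.nodes.size();
  std::vector<double> m(nn, 0.0), s(nn, 0.0);
  std::vector<int> &lf = st.leaf[h];
  for (int i = 0; i < st.n; ++i) { m[lf[i]] += 1.0; s[lf[i]] += r[i]; }
  for (int id = 0; id < nn; ++id) {
    if (tr.nodes[id].var != -1) continue;
    double prec = m[id] / sigma2 + 1.0 / st.leaf_var;  // empty leaf -> prior
    double mean = (s[id] / sigma2) / prec;
    tr.nodes[id].mu = mean + R::norm_rand() / std::sqrt(prec);
  }
}

// ---- exported interface ---------------------------------------------------

// [[Rcpp::export(name = ".bart_init_cpp")]]
SEXP bart_init_cpp(NumericMatrix x, NumericVector yc, List cutpoints, int H,
                   double alpha, double lam, int depth_form, double leaf_sd) {
  BartState *st = new BartState();
  st->n = x.nrow(); st->p = x.ncol(); st->H = H;
  st->x.assign(x.begin(), x.end());
  st->yc.assign(yc.begin(), yc.end());
  st->cuts.resize(st->p);
  for (int j = 0; j < st->p; ++j) {
    NumericVector cj = cutpoints[j];
    st->cuts[j].assign(cj.begin(), cj.end());
  }
  st->alpha = alpha; st->lam = lam; st->depth_form = depth_form;
  st->leaf_var = leaf_sd * leaf_sd;
  st->pgrow = 0.25; st->pprune = 0.25;
  st->trees.assign(H, Tree());
  for (int h = 0; h < H; ++h)
    st->trees[h].nodes.push_back(Node{-1, 0, -1, -1, -1, 0, 0.0});
  st->leaf.assign(H, std::vector<int>(st->n, 0));
  st->F.assign(st->n, 0.0);
  XPtr<BartState> ptr(st, true);
  return ptr;
}

// one full backfitting sweep over the H trees; returns split counts, the
// updated ensemble fit on the training data and the residual sum of squares
// [[Rcpp::export(name = ".bart_iter_cpp")]]
List bart_iter_cpp(SEXP ptr_, NumericVector s, double sigma2) {
  XPtr<BartState> ptr(ptr_);
  BartState &st = *ptr;
  std::vector<double> scum(st.p);
  double acc = 0.0;
  for (int j = 0; j < st.p; ++j) { acc += s[j]; scum[j] = acc; }

  std::vector<double> r(st.n), oldg(st.n);
  for (int h = 0; h < st.H; ++h) {
    Tree &tr = st.trees[h];
    std::vector<int> &lf = st.leaf[h];
    for (int i = 0; i < st.n; ++i) {
      oldg[i] = tr.nodes[lf[i]].mu;
      r[i] = st.yc[i] - st.F[i] + oldg[i];
    }
    double u = R::unif_rand();
    if (u < st.pgrow) try_grow(st, h, scum, sigma2, r);
    else if (u < st.pgrow + st.pprune) try_prune(st, h, sigma2, r);
    else try_change(st, h, scum, sigma2, r);
    leaf_draw(st, h, sigma2, r);
    for (int i = 0; i < st.n; ++i)
      st.F[i] += tr.nodes[lf[i]].mu - oldg[i];
  }

  IntegerVector counts(st.p);
  int ninterior = 0;
  for (int h = 0; h < st.H; ++h) {
    const Tree &tr = st.trees[h];
    for (int id = 0; id < (int)tr.nodes.size(); ++id)
      if (tr.nodes[id].var >= 0) { counts[tr.nodes[id].var] += 1; ++ninterior; }
  }
  double rss = 0.0;
  NumericVector fit(st.n);
  for (int i = 0; i < st.n; ++i) {
    fit[i] = st.F[i];
    double e = st.yc[i] - st.F[i];
    rss += e * e;
  }
  return List::create(_["counts"] = counts, _["R"] = ninterior,
                      _["fit"] = fit, _["rss"] = rss);
}

// route new observations through the current ensemble
// [[Rcpp::export(name = ".bart_predict_cpp")]]
NumericVector bart_predict_cpp(SEXP ptr_, NumericMatrix xnew) {
  XPtr<BartState> ptr(ptr_);
  BartState &st = *ptr;
  int m = xnew.nrow();
  NumericVector out(m);
  for (int h = 0; h < st.H; ++h) {
    const Tree &tr = st.trees[h];
    for (int i = 0; i < m; ++i) {
      int id = 0;
      while (tr.nodes[id].var >= 0) {
        const Node &nd = tr.nodes[id];
        id = (xnew(i, nd.var) <= st.cuts[nd.var][nd.cut]) ? nd.left : nd.right;
      }
      out[i] += tr.nodes[id].mu;
    }
  }
  return out;
}

// serialize the current ensemble (1-based node ids and predictor indices)
// [[Rcpp::export(name = ".bart_trees_cpp")]]
List bart_trees_cpp(SEXP ptr_) {
  XPtr<BartState> ptr(ptr_);
  BartState &st = *ptr;
  List out(st.H);
  for (int h = 0; h < st.H; ++h) {
    const Tree &tr = st.trees[h];
    int nn = (int)tr.nodes.size();
    std::vector<int> keep;
    std::vector<int> remap(nn, -1);
    for (int id = 0; id < nn; ++id)
      if (tr.nodes[id].var != -2) { remap[id] = (int)keep.size(); keep.push_back(id); }
    int nk = (int)keep.size();
    IntegerVector node(nk), parent(nk), left(nk), right(nk), var(nk), depth(nk);
    NumericVector cut(nk), mu(nk);
    for (int k = 0; k < nk; ++k) {
      const Node &nd = tr.nodes[keep[k]];
      node[k] = k + 1;
      parent[k] = nd.parent < 0 ? NA_INTEGER : remap[nd.parent] + 1;
      depth[k] = nd.depth;
      if (nd.var >= 0) {
        var[k] = nd.var + 1;
        cut[k] = st.cuts[nd.var][nd.cut];
        left[k] = remap[nd.left] + 1;
        right[k] = remap[nd.right] + 1;
        mu[k] = NA_REAL;
      } else {
        var[k] = NA_INTEGER; cut[k] = NA_REAL;
        left[k] = NA_INTEGER; right[k] = NA_INTEGER;
        mu[k] = nd.mu;
      }
    }
    out[h] = DataFrame::create(_["node"] = node, _["parent"] = parent,
                               _["left"] = left, _["right"] = right,
                               _["var"] = var, _["cut"] = cut,
                               _["mu"] = mu, _["depth"] = depth);
  }
  return out;
}

// one Gibbs sweep of the logit-normal state: for each j != ref (ascending),
// draw omega_j ~ PG(R, psi_j - phi_j) then psi_j from its conditional normal;
// phi_j = log sum_{j' != j} exp(psi_{j'}) via a running overflow-safe sum
// [[Rcpp::export(name = ".ln_sweep_cpp")]]
List ln_sweep_cpp(NumericVector psi_, IntegerVector counts, int ref1,
                  NumericVector m0, double tau2, int pg_threshold) {
  int p = psi_.size();
  int ref = ref1 - 1;
  int Rtot = 0;
  for (int j = 0; j < p; ++j) Rtot += counts[j];
  std::vector<double> psi(psi_.begin(), psi_.end());
  NumericVector omega(p);

  double M = psi[0];
  for (int j = 1; j < p; ++j) if (psi[j] > M) M = psi[j];
  std::vector<double> ex(p);
  double S = 0.0;
  for (int j = 0; j < p; ++j) { ex[j] = std::exp(psi[j] - M); S += ex[j]; }

  for (int j = 0; j < p; ++j) {
    if (j == ref) continue;
    double Smj = S - ex[j];
    double phi;
    if (Smj <= S * 1e-12) {
      // psi_j dominates the sum: recompute excluding j for accuracy
      double M2 = R_NegInf;
      for (int k = 0; k < p; ++k) if (k != j && psi[k] > M2) M2 = psi[k];
      double s2 = 0.0;
      for (int k = 0; k < p; ++k) if (k != j) s2 += std::exp(psi[k] - M2);
      phi = M2 + std::log(s2);
    } else {
      phi = M + std::log(Smj);
    }
    double om = 0.0;
    if (Rtot > 0) om = pg_draw_one((double)Rtot, psi[j] - phi, pg_threshold);
    omega[j] = om;
    double kap = counts[j] - 0.5 * Rtot;
    double den = om * tau2 + 1.0;
    double V = tau2 / den;
    double mean = (m0[j] + tau2 * (kap + om * phi)) / den;
    double newpsi = mean + std::sqrt(V) * R::norm_rand();
    // update running sum; rescale if the new value would overflow the scale
    if (newpsi - M > 30.0) {
      psi[j] = newpsi;
      M = newpsi;
      S = 0.0;
      for (int k = 0; k < p; ++k) { ex[k] = std::exp(psi[k] - M); S += ex[k]; }
    } else {
      double exn = std::exp(newpsi - M);
      S += exn - ex[j];
      ex[j] = exn;
      psi[j] = newpsi;
    }
  }
  return List::create(_["psi"] = NumericVector(psi.begin(), psi.end()),
                      _["omega"] = omega);
}
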