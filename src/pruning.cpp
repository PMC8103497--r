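// Felsenstein pruning with per-pattern log scaling, discrete-gamma rate
// categories, and a cached coordinate-sweep branch-length optimizer.
//
// Conventions shared with the R wrappers:
//  - nodes are numbered as in ape: tips 1..ntip, internal ntip+1..nnode
//  - `edge` is the postorder edge matrix (child rows precede parent rows)
//  - tip states are 1-based column indices into the state space, 0 = missing
//  - the transition matrix is reconstructed from the symmetric
//    eigendecomposition of the reversible generator:
//      P(t, r) = A diag(exp(eva * t * r)) B
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

static const double LOG_ZERO_FLOOR = 1e-300;

static mat pmat(const mat& A, const mat& B, const vec& eva, double t, double r)
{
  vec e = exp(eva * (t * r));
  mat P = A * diagmat(e) * B;
  // eigendecomposition round-off can leave tiny negatives
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

struct TreeIdx {
  int ntip, nnode, root;
  // children[u] = edge row indices whose parent is u
  std::vector<std::vector<int>> children;
};

static TreeIdx index_tree(const imat& edge, int ntip, int nnode)
{
  TreeIdx t;
  t.ntip = ntip;
  t.nnode = nnode;
  t.children.assign(nnode + 1, {});
  std::vector<bool> is_child(nnode + 1, false);
  for (uword e = 0; e < edge.n_rows; ++e) {
    t.children[edge(e, 0)].push_back((int)e);
    is_child[edge(e, 1)] = true;
  }
  t.root = 0;
  for (int u = ntip + 1; u <= nnode; ++u)
    if (!is_child[u] && !t.children[u].empty()) t.root = u;
  return t;
}

// contribution of one child edge to its parent's partial: (P %*% D_child),
// with tips expanded from observed states (missing => row sums == 1)
static mat edge_contrib(const mat& P, int child, int ntip,
                        const imat& tips, const mat* Dchild)
{
  if (child <= ntip) {
    const uword npat = tips.n_cols;
    uvec idx(npat);
    std::vector<uword> miss;
    for (uword p = 0; p < npat; ++p) {
      int s = tips(child - 1, p);
      if (s > 0) idx(p) = (uword)(s - 1);
      else { idx(p) = 0; miss.push_back(p); }
    }
    mat contrib = P.cols(idx);
    for (uword j : miss) contrib.col(j).ones();
    return contrib;
  }
  return P * (*Dchild);
}

// one postorder pass for a single rate category; fills D (internal nodes)
// and per-node accumulated log scalers
static void lower_partials(const TreeIdx& tr, const imat& edge, const vec& el,
                           const imat& tips, const mat& A, const mat& B,
                           const vec& eva, double rate,
                           std::vector<mat>& D, std::vector<vec>& sc)
{
  const uword c = A.n_rows, npat = tips.n_cols;
  D.assign(tr.nnode + 1, mat());
  sc.assign(tr.nnode + 1, vec());
  for (uword e = 0; e < edge.n_rows; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    mat P = pmat(A, B, eva, el(e), rate);
    mat contrib = edge_contrib(P, ch, tr.ntip, tips,
                               ch > tr.ntip ? &D[ch] : nullptr);
    if (D[par].n_elem == 0) {
      D[par] = contrib;
      sc[par] = (ch > tr.ntip) ? sc[ch] : vec(npat, fill::zeros);
    } else {
      D[par] %= contrib;
      if (ch > tr.ntip) sc[par] += sc[ch];
    }
    // rescale per pattern to avoid underflow
    rowvec m = max(D[par], 0);
    m.transform([](double x) { return x > LOG_ZERO_FLOOR ? x
                                                         : LOG_ZERO_FLOOR; });
    D[par].each_row() /= m;
    sc[par] += log(m).t();
    (void)c; (void)npat;
  }
}

// [[Rcpp::export]]
List plik_cpp(const arma::imat& edge, const arma::vec& el, int ntip, int nnode,
              const arma::imat& tips, const arma::vec& weights,
              const arma::mat& A, const arma::mat& B, const arma::vec& eva,
              const arma::vec& pi, const arma::vec& rates, bool want_cats)
{
  TreeIdx tr = index_tree(edge, ntip, nnode);
  const uword npat = tips.n_cols;
  const int K = rates.n_elem;
  mat catll(npat, K);
  std::vector<mat> D;
  std::vector<vec> sc;
  for (int k = 0; k < K; ++k) {
    lower_partials(tr, edge, el, tips, A, B, eva, rates(k), D, sc);
    vec v = (pi.t() * D[tr.root]).t();
    v.transform([](double x) { return x > LOG_ZERO_FLOOR ? x
                                                         : LOG_ZERO_FLOOR; });
    catll.col(k) = log(v) + sc[tr.root];
  }
  vec mx = max(catll, 1);
  vec site = mx + log(sum(exp(catll.each_col() - mx), 1)) -
             std::log((double)K);
  double ll = dot(weights, site);
  List out = List::create(_["loglik"] = ll, _["site_loglik"] = site);
  if (want_cats) out["cat_loglik"] = catll;
  return out;
}

// ---------------------------------------------------------------------------
// branch-length optimization: coordinate sweeps with cached partials
// ---------------------------------------------------------------------------

struct EdgeObjective {
  // per category: UpEx (c x npat), its log scaler (npat), D of the child
  // (or tip states), D scaler
  const std::vector<mat>* upex;
  const std::vector<vec>* upsc;
  const std::vector<const mat*>* dchild;
  const std::vector<const vec*>* dsc;
  const mat *A, *B;
  const vec *eva, *rates, *weights;
  const imat* tips;
  int child, ntip;

  double eval(double t) const
  {
    const int K = rates->n_elem;
    const uword npat = tips->n_cols;
    mat catll(npat, K);
    for (int k = 0; k < K; ++k) {
      mat P = pmat(*A, *B, *eva, t, (*rates)(k));
      const mat& U = (*upex)[k];
      vec val(npat);
      if (child <= ntip) {
        mat W = U.t() * P;                    // npat x c
        vec ucs = sum(U, 0).t();              // for missing tips
        for (uword p = 0; p < npat; ++p) {
          int s = (*tips)(child - 1, p);
          val(p) = s > 0 ? W(p, (uword)(s - 1)) : ucs(p);
        }
      } else {
        val = sum(U % (P * (*(*dchild)[k])), 0).t();
      }
      val.transform([](double x) { return x > LOG_ZERO_FLOOR ? x
                                                             : LOG_ZERO_FLOOR; });
      catll.col(k) = log(val) + (*upsc)[k] +
                     ((*dsc)[k] ? *(*dsc)[k] : vec(npat, fill::zeros));
    }
    vec mx = max(catll, 1);
    vec lse = mx + log(sum(exp(catll.each_col() - mx), 1)) -
              std::log((double)K);
    return dot(*weights, lse);
  }
};

// Brent 1-D maximization of obj over log branch length in [lx, ux]
static double brent_maximize(const EdgeObjective& obj, double lx, double ux,
                             double tol, int maxit, double* fbest)
{
  const double gold = 0.3819660112501051;
  double a = lx, b = ux;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = -obj.eval(std::exp(x)), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int it = 0; it < maxit; ++it) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10, tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool parab = false;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etmp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etmp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        parab = true;
      }
    }
    if (!parab) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = -obj.eval(std::exp(u));
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fbest = -fx;
  return std::exp(x);
}

// [[Rcpp::export]]
List optimize_blen_cpp(const arma::imat& edge, const arma::vec& el0, int ntip,
                       int nnode, const arma::imat& tips,
                       const arma::vec& weights, const arma::mat& A,
                       const arma::mat& B, const arma::vec& eva,
                       const arma::vec& pi, const arma::vec& rates,
                       double min_blen, double max_blen, double tol_sweep,
                       int max_sweeps, double brent_tol)
{
  TreeIdx tr = index_tree(edge, ntip, nnode);
  const int K = rates.n_elem;
  const uword npat = tips.n_cols;
  vec el = el0;
  el.transform([&](double x) {
    return std::min(std::max(x, min_blen), max_blen);
  });
  double lx = std::log(min_blen), ux = std::log(max_blen);

  // edge row index by child node
  std::vector<int> edge_of(nnode + 1, -1);
  for (uword e = 0; e < edge.n_rows; ++e) edge_of[edge(e, 1)] = (int)e;

  std::vector<std::vector<mat>> D(K);
  std::vector<std::vector<vec>> Dsc(K);
  std::vector<double> trace;
  double prev = -datum::inf;
  bool converged = false;
  int sweeps_done = 0;

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    ++sweeps_done;
    // fresh lower partials under current lengths
    double ll_now = 0.0;
    {
      mat catll(npat, K);
      for (int k = 0; k < K; ++k) {
        lower_partials(tr, edge, el, tips, A, B, eva, rates(k), D[k], Dsc[k]);
        vec v = (pi.t() * D[k][tr.root]).t();
        v.transform([](double x) { return x > LOG_ZERO_FLOOR ? x
                                                             : LOG_ZERO_FLOOR; });
        catll.col(k) = log(v) + Dsc[k][tr.root];
      }
      vec mx = max(catll, 1);
      vec site = mx + log(sum(exp(catll.each_col() - mx), 1)) -
                 std::log((double)K);
      ll_now = dot(weights, site);
    }
    trace.push_back(ll_now);
    if (sweep > 0 && ll_now - prev < tol_sweep) { converged = true; break; }
    prev = ll_now;

    // preorder descent with upper partials
    std::vector<std::vector<mat>> Up(tr.nnode + 1);
    std::vector<std::vector<vec>> Upsc(tr.nnode + 1);
    Up[tr.root].assign(K, mat(pi.n_elem, npat));
    Upsc[tr.root].assign(K, vec(npat, fill::zeros));
    for (int k = 0; k < K; ++k)
      Up[tr.root][k].each_col() = pi;

    std::vector<int> stack = {tr.root};
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      const std::vector<int>& kids = tr.children[u];
      size_t m = kids.size();
      // per-child contributions under current lengths
      std::vector<std::vector<mat>> C(m, std::vector<mat>(K));
      auto recompute_contrib = [&](size_t j) {
        int e = kids[j];
        int ch = edge(e, 1);
        for (int k = 0; k < K; ++k) {
          mat P = pmat(A, B, eva, el(e), rates(k));
          C[j][k] = edge_contrib(P, ch, ntip, tips,
                                 ch > ntip ? &D[k][ch] : nullptr);
        }
      };
      for (size_t j = 0; j < m; ++j) recompute_contrib(j);

      auto upex_for = [&](size_t j, std::vector<mat>& UX,
                          std::vector<vec>& UXsc) {
        UX.assign(K, mat());
        UXsc.assign(K, vec());
        for (int k = 0; k < K; ++k) {
          mat U = Up[u][k];
          vec s = Upsc[u][k];
          for (size_t i = 0; i < m; ++i) {
            if (i == j) continue;
            U %= C[i][k];
            int chi = edge(kids[i], 1);
            if (chi > ntip) s += Dsc[k][chi];
          }
          rowvec mx = max(U, 0);
          mx.transform([](double x) { return x > LOG_ZERO_FLOOR
                                                 ? x : LOG_ZERO_FLOOR; });
          U.each_row() /= mx;
          s += log(mx).t();
          UX[k] = std::move(U);
          UXsc[k] = std::move(s);
        }
      };

      for (size_t j = 0; j < m; ++j) {
        int e = kids[j];
        int ch = edge(e, 1);
        std::vector<mat> UX;
        std::vector<vec> UXsc;
        upex_for(j, UX, UXsc);
        std::vector<const mat*> dch(K);
        std::vector<const vec*> dsc(K);
        for (int k = 0; k < K; ++k) {
          dch[k] = ch > ntip ? &D[k][ch] : nullptr;
          dsc[k] = ch > ntip ? &Dsc[k][ch] : nullptr;
        }
        EdgeObjective obj{&UX, &UXsc, &dch, &dsc, &A, &B, &eva,
                          &rates, &weights, &tips, ch, ntip};
        double fcur = obj.eval(el(e));
        // bracket locally around the current length first; fall back to
        // the full range only if the optimum presses against the bracket
        double x0 = std::log(el(e));
        double lo = std::max(lx, x0 - 3.0), hi = std::min(ux, x0 + 3.0);
        double fbest;
        double tbest = brent_maximize(obj, lo, hi, brent_tol, 50, &fbest);
        double xb = std::log(tbest);
        if ((xb - lo < 0.05 && lo > lx + 1e-12) ||
            (hi - xb < 0.05 && hi < ux - 1e-12)) {
          double fbest2;
          double tbest2 = brent_maximize(obj, lx, ux, brent_tol, 50,
                                         &fbest2);
          if (fbest2 > fbest) { fbest = fbest2; tbest = tbest2; }
        }
        if (fbest > fcur) {
          el(e) = tbest;
          recompute_contrib(j);
        }
      }
      // push internal children with their upper partials (final lengths)
      for (size_t j = 0; j < m; ++j) {
        int e = kids[j];
        int ch = edge(e, 1);
        if (ch <= ntip) continue;
        std::vector<mat> UX;
        std::vector<vec> UXsc;
        upex_for(j, UX, UXsc);
        Up[ch].assign(K, mat());
        Upsc[ch].assign(K, vec());
        for (int k = 0; k < K; ++k) {
          mat P = pmat(A, B, eva, el(e), rates(k));
          mat U = P.t() * UX[k];
          vec s = UXsc[k];
          rowvec mx = max(U, 0);
          mx.transform([](double x) { return x > LOG_ZERO_FLOOR
                                                 ? x : LOG_ZERO_FLOOR; });
          U.each_row() /= mx;
          s += log(mx).t();
          Up[ch][k] = std::move(U);
          Upsc[ch][k] = std::move(s);
        }
        stack.push_back(ch);
      }
    }
  }

  // final likelihood under optimized lengths
  List fin = plik_cpp(edge, el, ntip, nnode, tips, weights, A, B, eva, pi,
                      rates, false);
  double ll_fin = as<double>(fin["loglik"]);
  if (trace.empty() || ll_fin > trace.back()) trace.push_back(ll_fin);
  return List::create(_["edge_length"] = el, _["loglik"] = ll_fin,
                      _["trace"] = trace, _["converged"] = converged,
                      _["sweeps"] = sweeps_done,
                      _["site_loglik"] = fin["site_loglik"]);
}
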