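// Dense bounded-variable primal simplex (two-phase) used as the LP engine
// for flux-balance analysis. Problems are small (tens of reactions); the
// basis is kept as a dense matrix with one LU factorisation per iteration.
// Anti-cycling: Dantzig pricing with a switch to Bland's rule after a stall.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double FEAS_TOL = 1e-9;   // bound / mass-balance tolerance
const double RC_TOL   = 1e-9;   // reduced-cost optimality tolerance
const double PIV_TOL  = 1e-9;   // smallest acceptable pivot element

enum Status { OPTIMAL = 0, INFEASIBLE = 1, UNBOUNDED = 2, MAXIT = 3 };

struct Simplex {
  int m, n, N;                  // rows, structural vars, total (n + m)
  mat A;                        // m x N, artificial +/-1 columns appended
  vec lo, hi, xval;             // bounds and current values, length N
  std::vector<int> basis;       // row -> variable
  std::vector<int> vstat;       // 0 at lower, 1 at upper, 2 basic
  mat Binv;                     // explicit basis inverse (revised simplex)
  vec cB, dual, aq;
  rowvec pr;
  int pivots;                   // pivots since last refactorisation
  std::vector<std::vector<std::pair<int, double> > > cols;  // sparse columns

  // A x = b with lbs <= x <= ubs (structural bounds finite)
  void build(const mat& Ain, const vec& b, const vec& lbs, const vec& ubs) {
    m = Ain.n_rows; n = Ain.n_cols; N = n + m;
    A.zeros(m, N);
    A.cols(0, n - 1) = Ain;
    lo.set_size(N); hi.set_size(N); xval.set_size(N);
    basis.resize(m); vstat.assign(N, 0);
    for (int j = 0; j < n; ++j) {
      lo(j) = lbs(j); hi(j) = ubs(j);
      // start at the bound of smaller magnitude
      if (std::fabs(lbs(j)) <= std::fabs(ubs(j))) { vstat[j] = 0; xval(j) = lbs(j); }
      else { vstat[j] = 1; xval(j) = ubs(j); }
    }
    vec d = b - A.cols(0, n - 1) * xval.subvec(0, n - 1);
    Binv.zeros(m, m);
    for (int i = 0; i < m; ++i) {
      int ai = n + i;
      double s = (d(i) >= 0) ? 1.0 : -1.0;
      A(i, ai) = s;
      lo(ai) = 0.0; hi(ai) = datum::inf;
      basis[i] = ai; vstat[ai] = 2; xval(ai) = std::fabs(d(i));
      Binv(i, i) = s;            // inverse of diag(+/-1) is itself
    }
    cB.set_size(m); dual.set_size(m); aq.set_size(m);
    pr.set_size(N);
    pivots = 0;
    cols.assign(N, std::vector<std::pair<int, double> >());
    for (int j = 0; j < N; ++j) {
      const double* ap = A.colptr(j);
      for (int i = 0; i < m; ++i)
        if (ap[i] != 0.0) cols[j].push_back(std::make_pair(i, ap[i]));
    }
  }

  bool refactor() {
    mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = A.col(basis[i]);
    mat I;
    if (!inv(I, B)) return false;
    Binv = I;
    pivots = 0;
    return true;
  }

  // dual = Binv^T cB, exploiting sparsity of cB
  void compute_dual() {
    dual.zeros();
    const double* bp = Binv.memptr();
    for (int i = 0; i < m; ++i) {
      double ci = cB(i);
      if (ci == 0.0) continue;
      for (int j = 0; j < m; ++j) dual(j) += ci * bp[(size_t) j * m + i];
    }
  }

  // aq = Binv * A.col(q), exploiting sparsity of the column
  void compute_aq(int q) {
    aq.zeros();
    const std::vector<std::pair<int, double> >& cq = cols[q];
    for (size_t k = 0; k < cq.size(); ++k)
      aq += cq[k].second * Binv.col(cq[k].first);
  }

  // maximise c'x from the current (feasible) basis
  int optimize(const vec& c, int maxit) {
    int stall = 0;
    bool bland = false;
    for (int it = 0; it < maxit; ++it) {
      for (int i = 0; i < m; ++i) cB(i) = c(basis[i]);
      compute_dual();
      const double* dp = dual.memptr();
      for (int j = 0; j < N; ++j) {
        if (vstat[j] == 2) { pr(j) = 0; continue; }
        const std::vector<std::pair<int, double> >& cj = cols[j];
        double s = 0;
        for (size_t k = 0; k < cj.size(); ++k)
          s += dp[cj[k].first] * cj[k].second;
        pr(j) = s;
      }

      int q = -1, dir = 0;
      double best = RC_TOL;
      for (int j = 0; j < N; ++j) {
        if (vstat[j] == 2) continue;
        double rj = c(j) - pr(j);
        int dj = 0;
        if (vstat[j] == 0 && rj > RC_TOL && hi(j) > lo(j)) dj = 1;
        else if (vstat[j] == 1 && rj < -RC_TOL && hi(j) > lo(j)) dj = -1;
        if (dj == 0) continue;
        if (bland) { q = j; dir = dj; best = std::fabs(rj); break; }
        if (std::fabs(rj) > best) { best = std::fabs(rj); q = j; dir = dj; }
      }
      if (q < 0) return OPTIMAL;

      compute_aq(q);

      // ratio test: entering moves t >= 0 in direction dir;
      // basic i changes by -dir*aq(i)*t and must stay within [lo, hi]
      double tmax = hi(q) - lo(q);        // own travel before a bound flip
      int leave = -1, leave_to = 0;
      for (int i = 0; i < m; ++i) {
        double delta = -dir * aq(i);
        double t; int to;
        int bi = basis[i];
        if (delta < -PIV_TOL) {
          t = (xval(bi) - lo(bi)) / (-delta); to = 0;
        } else if (delta > PIV_TOL && std::isfinite(hi(bi))) {
          t = (hi(bi) - xval(bi)) / delta; to = 1;
        } else continue;
        if (t < 0) t = 0;
        bool take = false;
        if (t < tmax - FEAS_TOL) take = true;
        else if (t <= tmax + FEAS_TOL) {
          if (leave < 0) take = true;
          else if (bland && bi < basis[leave]) take = true;
          else if (!bland && std::fabs(aq(i)) > std::fabs(aq(leave))) take = true;
        }
        if (take) { if (t < tmax) tmax = t; leave = i; leave_to = to; }
      }
      if (leave < 0 && !std::isfinite(tmax)) return UNBOUNDED;
      if (tmax < 0) tmax = 0;

      xval(q) += dir * tmax;
      for (int i = 0; i < m; ++i) xval(basis[i]) += -dir * aq(i) * tmax;

      if (leave < 0) {                    // flip to own opposite bound
        vstat[q] = (dir > 0) ? 1 : 0;
        xval(q) = (dir > 0) ? hi(q) : lo(q);
      } else {
        int lv = basis[leave];
        vstat[lv] = leave_to;
        xval(lv) = (leave_to == 0) ? lo(lv) : hi(lv);
        basis[leave] = q; vstat[q] = 2;
        // product-form update of the basis inverse
        double piv = aq(leave);
        if (std::fabs(piv) < PIV_TOL || ++pivots >= 128) {
          if (!refactor()) return MAXIT;
        } else {
          Binv.row(leave) /= piv;
          for (int i = 0; i < m; ++i) {
            if (i == leave) continue;
            double f = aq(i);
            if (f != 0.0) Binv.row(i) -= f * Binv.row(leave);
          }
        }
      }

      if (std::fabs(best) * tmax > 1e-12) { stall = 0; bland = false; }
      else if (++stall > 2 * (m + N)) bland = true;
    }
    return MAXIT;
  }

  // phase 1: minimise the artificial sum; returns status
  int phase1() {
    vec c1 = zeros<vec>(N);
    c1.subvec(n, N - 1).fill(-1.0);
    int st = optimize(c1, 20000);
    if (st != OPTIMAL) return st;
    double art = 0;
    for (int j = n; j < N; ++j) art += std::max(xval(j), 0.0);
    if (art > 1e-7) return INFEASIBLE;
    // pivot residual basic artificials onto structural columns if possible
    for (int i = 0; i < m; ++i) {
      if (basis[i] < n) continue;
      xval(basis[i]) = 0.0;
      rowvec arow = Binv.row(i) * A;    // row i of B^-1 A
      int q = -1;
      for (int j = 0; j < n; ++j)
        if (vstat[j] != 2 && std::fabs(arow(j)) > 1e-7) { q = j; break; }
      if (q < 0) continue;              // redundant row: artificial stays 0
      int lv = basis[i];
      vstat[lv] = 0; xval(lv) = 0.0;
      basis[i] = q; vstat[q] = 2;
      if (!refactor()) return MAXIT;
    }
    for (int j = n; j < N; ++j) hi(j) = 0.0;   // seal artificials
    return OPTIMAL;
  }

  // fix a structural variable at its current value (used for lexicographic
  // objectives: the point stays feasible, re-optimise with new costs)
  void fix_at_current(int j) { lo(j) = xval(j); hi(j) = xval(j); }

  int solve_from_feasible(const vec& cstruct) {
    vec c2 = zeros<vec>(N);
    c2.subvec(0, n - 1) = cstruct;
    return optimize(c2, 20000);
  }
};

// maximise c'x  s.t.  A x = b, lb <= x <= ub
int lp_core(const mat& Ain, const vec& b, const vec& c,
            const vec& lb, const vec& ub, vec& xout, double& objout,
            Simplex* keep = nullptr) {
  for (uword j = 0; j < Ain.n_cols; ++j)
    if (lb(j) > ub(j) + FEAS_TOL) return INFEASIBLE;
  Simplex local;
  Simplex& sx = keep ? *keep : local;
  sx.build(Ain, b, lb, ub);
  int st = sx.phase1();
  if (st != OPTIMAL) return st;
  st = sx.solve_from_feasible(c);
  if (st != OPTIMAL) return st;
  xout = sx.xval.subvec(0, sx.n - 1);
  for (int j = 0; j < sx.n; ++j) {
    if (xout(j) < lb(j)) xout(j) = lb(j);
    if (xout(j) > ub(j)) xout(j) = ub(j);
  }
  objout = dot(c, xout);
  return OPTIMAL;
}

// parsimonious refinement: minimise total |v| over S v = 0 with the
// objective reaction(s) held at their optimal value via bound fixing
// (single-variable objective) or an appended equality row (general c).
// Sign-definite variables are kept whole; only mixed-sign variables split.
int pfba_core(const mat& S, const vec& c, const vec& lb, const vec& ub,
              double zstar, vec& vout) {
  int m = S.n_rows, n = S.n_cols;
  uvec nz = find(abs(c) > 0);
  bool single = (nz.n_elem == 1);
  vec lb2 = lb, ub2 = ub;
  if (single) {
    int j = nz(0);
    double val = zstar / c(j);
    lb2(j) = std::max(lb(j), val - 1e-9);
    ub2(j) = std::min(ub(j), val + 1e-9);
  }
  int extra = single ? 0 : 1;
  std::vector<int> split;                 // mixed-sign variables
  for (int j = 0; j < n; ++j)
    if (lb2(j) < -FEAS_TOL && ub2(j) > FEAS_TOL) split.push_back(j);
  int n2 = n + (int) split.size();
  mat A2(m + extra, n2);
  vec b2 = zeros<vec>(m + extra);
  vec lo2(n2), hi2(n2), c2(n2);
  A2.submat(0, 0, m - 1, n - 1) = S;
  if (extra) {
    A2.row(m).cols(0, n - 1) = c.t();
    b2(m) = zstar;
  }
  for (int j = 0; j < n; ++j) {
    if (lb2(j) >= -FEAS_TOL) {            // v >= 0: |v| = v
      lo2(j) = std::max(lb2(j), 0.0); hi2(j) = ub2(j); c2(j) = -1.0;
    } else if (ub2(j) <= FEAS_TOL) {      // v <= 0: |v| = -v
      lo2(j) = lb2(j); hi2(j) = std::min(ub2(j), 0.0); c2(j) = 1.0;
    } else {                              // split below: this is the p part
      lo2(j) = 0.0; hi2(j) = ub2(j); c2(j) = -1.0;
    }
  }
  for (size_t k = 0; k < split.size(); ++k) {
    int j = split[k], jq = n + (int) k;
    A2.col(jq).rows(0, m - 1) = -S.col(j);
    if (extra) A2(m, jq) = -c(j);
    lo2(jq) = 0.0; hi2(jq) = -lb2(j); c2(jq) = -1.0;
  }
  vec x; double o;
  int st = lp_core(A2, b2, c2, lo2, hi2, x, o);
  if (st != OPTIMAL) return st;
  vout = x.subvec(0, n - 1);
  for (size_t k = 0; k < split.size(); ++k)
    vout(split[k]) -= x(n + (int) k);
  for (int j = 0; j < n; ++j) {
    if (vout(j) < lb(j)) vout(j) = lb(j);
    if (vout(j) > ub(j)) vout(j) = ub(j);
  }
  return OPTIMAL;
}

} // namespace

// [[Rcpp::export(name = ".lp_solve")]]
Rcpp::List lp_solve_cpp(const arma::mat& A, const arma::vec& b, const arma::vec& c,
                        const arma::vec& lb, const arma::vec& ub, bool maximize) {
  vec x; double obj = NA_REAL;
  vec cc = maximize ? c : vec(-c);
  int st = lp_core(A, b, cc, lb, ub, x, obj);
  if (st != OPTIMAL)
    return Rcpp::List::create(Rcpp::Named("status") = st,
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("objective") = NA_REAL);
  if (!maximize) obj = -obj;
  return Rcpp::List::create(Rcpp::Named("status") = st,
                            Rcpp::Named("x") = x,
                            Rcpp::Named("objective") = obj);
}

// FBA solve with parsimonious tie-break: optimise c'v over
// {S v = 0, lb <= v <= ub}, then minimise total |v| at the fixed optimum.
// [[Rcpp::export(name = ".lp_fba")]]
Rcpp::List lp_fba_cpp(const arma::mat& S, const arma::vec& c,
                      const arma::vec& lb, const arma::vec& ub,
                      bool maximize, bool pfba) {
  int m = S.n_rows;
  vec b = zeros<vec>(m);
  vec cc = maximize ? c : vec(-c);
  vec x; double obj = NA_REAL;
  int st = lp_core(S, b, cc, lb, ub, x, obj);
  if (st != OPTIMAL)
    return Rcpp::List::create(Rcpp::Named("status") = st,
                              Rcpp::Named("fluxes") = R_NilValue,
                              Rcpp::Named("objective") = NA_REAL);
  if (pfba) {
    vec v;
    if (pfba_core(S, cc, lb, ub, obj, v) == OPTIMAL) x = v;
  }
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("fluxes") = x,
                            Rcpp::Named("objective") = maximize ? obj : -obj);
}

// Lexicographic phase-2 evaluation: maximise growth (phosphate-release
// limited), then maximise proton export warm-started from the growth
// optimum, then a parsimonious flux vector. One entry point per individual.
// [[Rcpp::export(name = ".lp_phase2")]]
Rcpp::List lp_phase2_cpp(const arma::mat& S, const arma::vec& lb, const arma::vec& ub,
                         int bio_idx, int h_idx, bool pfba) {
  int m = S.n_rows, n = S.n_cols;
  int ib = bio_idx - 1, ih = h_idx - 1;   // 1-based from R
  for (int j = 0; j < n; ++j)
    if (lb(j) > ub(j) + FEAS_TOL)
      return Rcpp::List::create(Rcpp::Named("status") = 1,
                                Rcpp::Named("fluxes") = R_NilValue,
                                Rcpp::Named("mu") = NA_REAL,
                                Rcpp::Named("objective") = NA_REAL);
  Simplex sx;
  sx.build(S, zeros<vec>(m), lb, ub);
  int st = sx.phase1();
  vec c1 = zeros<vec>(n); c1(ib) = 1.0;
  if (st == OPTIMAL) st = sx.solve_from_feasible(c1);
  if (st != OPTIMAL)
    return Rcpp::List::create(Rcpp::Named("status") = st,
                              Rcpp::Named("fluxes") = R_NilValue,
                              Rcpp::Named("mu") = NA_REAL,
                              Rcpp::Named("objective") = NA_REAL);
  double mu = sx.xval(ib);
  sx.fix_at_current(ib);
  vec c2 = zeros<vec>(n); c2(ih) = 1.0;
  st = sx.solve_from_feasible(c2);        // warm start from growth optimum
  if (st != OPTIMAL)
    return Rcpp::List::create(Rcpp::Named("status") = st,
                              Rcpp::Named("fluxes") = R_NilValue,
                              Rcpp::Named("mu") = NA_REAL,
                              Rcpp::Named("objective") = NA_REAL);
  double h = sx.xval(ih);
  vec x = sx.xval.subvec(0, n - 1);
  if (pfba) {
    vec lb2 = lb, ub2 = ub;
    lb2(ib) = mu; ub2(ib) = mu;
    vec v;
    if (pfba_core(S, c2, lb2, ub2, h, v) == OPTIMAL) x = v;
  }
  for (int j = 0; j < n; ++j) {
    if (x(j) < lb(j)) x(j) = lb(j);
    if (x(j) > ub(j)) x(j) = ub(j);
  }
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("fluxes") = x,
                            Rcpp::Named("mu") = mu,
                            Rcpp::Named("objective") = h);
}
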