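#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Table-driven evaluation of a reaction-rate network.
//
// A compiled rate table (built in R by compile_pathway()) is a list of flat
// arrays describing nt signed reaction terms:
//   term_k : rate constant of each term
//   fac_ptr/fac_sp/fac_ex : CSR-style mass-action factors prod(y[sp]^ex)
//   mm_sp/mm_k : optional Michaelis-Menten factor y[sp]/(k + y[sp]), sp = -1
//                when absent
//   st_ptr/st_sp/st_co : CSR-style stoichiometry (species index, +/- coef)
// Species indices are 0-based.  Derivatives of "clamped" species (externally
// driven inputs, e.g. ligand set from the extracellular field) are zeroed.

struct RateTable {
  int nt, nsp;
  NumericVector term_k;
  IntegerVector fac_ptr, fac_sp;
  NumericVector fac_ex;
  IntegerVector mm_sp;
  NumericVector mm_k;
  IntegerVector st_ptr, st_sp;
  NumericVector st_co;
  LogicalVector clamped;
};

static RateTable unpack_table(const List& tab) {
  RateTable rt;
  rt.term_k = tab["term_k"];
  rt.nt = rt.term_k.size();
  rt.nsp = as<int>(tab["n_species"]);
  rt.fac_ptr = tab["fac_ptr"];
  rt.fac_sp  = tab["fac_sp"];
  rt.fac_ex  = tab["fac_ex"];
  rt.mm_sp   = tab["mm_sp"];
  rt.mm_k    = tab["mm_k"];
  rt.st_ptr  = tab["st_ptr"];
  rt.st_sp   = tab["st_sp"];
  rt.st_co   = tab["st_co"];
  rt.clamped = tab["clamped"];
  return rt;
}

static inline void eval_deriv(const RateTable& rt, const double* y, double* dy) {
  for (int s = 0; s < rt.nsp; ++s) dy[s] = 0.0;
  for (int t = 0; t < rt.nt; ++t) {
    double rate = rt.term_k[t];
    for (int f = rt.fac_ptr[t]; f < rt.fac_ptr[t + 1]; ++f) {
      double base = y[rt.fac_sp[f]];
      if (base < 0.0) base = 0.0;
      double ex = rt.fac_ex[f];
      rate *= (ex == 1.0) ? base : std::pow(base, ex);
    }
    int ms = rt.mm_sp[t];
    if (ms >= 0) {
      double s = y[ms] > 0.0 ? y[ms] : 0.0;
      rate *= s / (rt.mm_k[t] + s);
    }
    for (int s = rt.st_ptr[t]; s < rt.st_ptr[t + 1]; ++s)
      dy[rt.st_sp[s]] += rt.st_co[s] * rate;
  }
  for (int s = 0; s < rt.nsp; ++s)
    if (rt.clamped[s]) dy[s] = 0.0;
}

// [[Rcpp::export]]
NumericVector pathway_deriv_cpp(NumericVector y, List tab) {
  RateTable rt = unpack_table(tab);
  if ((int)y.size() != rt.nsp) stop("state length does not match rate table");
  NumericVector dy(rt.nsp);
  eval_deriv(rt, y.begin(), dy.begin());
  return dy;
}

// Cash-Karp embedded Runge-Kutta 4(5) coefficients
static const double CK_A[6] = {0., 0.2, 0.3, 0.6, 1.0, 0.875};
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {0.2, 0, 0, 0, 0},
  {3.0 / 40.0, 9.0 / 40.0, 0, 0, 0},
  {0.3, -0.9, 1.2, 0, 0},
  {-11.0 / 54.0, 2.5, -70.0 / 27.0, 35.0 / 27.0, 0},
  {1631.0 / 55296.0, 175.0 / 512.0, 575.0 / 13824.0,
   44275.0 / 110592.0, 253.0 / 4096.0}};
static const double CK_C[6]  = {37.0 / 378.0, 0, 250.0 / 621.0,
                                125.0 / 594.0, 0, 512.0 / 1771.0};
static const double CK_DC[6] = {37.0 / 378.0 - 2825.0 / 27648.0, 0,
                                250.0 / 621.0 - 18575.0 / 48384.0,
                                125.0 / 594.0 - 13525.0 / 55296.0,
                                -277.0 / 14336.0, 512.0 / 1771.0 - 0.25};

#define MAX_SPECIES 64

// Integrate one cell's state over [0, dt].  Returns 0 on success, 1 when the
// step-count guard was hit (non-convergence).  nclamp counts negative
// concentrations clamped to zero after accepted steps.
static int rk45_one(const RateTable& rt, double* y, double dt,
                    double rtol, double atol, long max_steps, long* nclamp) {
  int n = rt.nsp;
  double k[6][MAX_SPECIES], ytmp[MAX_SPECIES], yerr[MAX_SPECIES],
      ynew[MAX_SPECIES];
  double t = 0.0, h = dt;
  long steps = 0;
  while (t < dt) {
    if (++steps > max_steps) return 1;
    if (h > dt - t) h = dt - t;
    eval_deriv(rt, y, k[0]);
    for (int s = 1; s < 6; ++s) {
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < s; ++j) acc += CK_B[s][j] * k[j][i];
        ytmp[i] = y[i] + h * acc;
      }
      eval_deriv(rt, ytmp, k[s]);
    }
    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double acc = 0.0, eacc = 0.0;
      for (int s = 0; s < 6; ++s) {
        acc += CK_C[s] * k[s][i];
        eacc += CK_DC[s] * k[s][i];
      }
      ynew[i] = y[i] + h * acc;
      yerr[i] = h * eacc;
      double sk = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double e = std::fabs(yerr[i]) / sk;
      if (e > errmax) errmax = e;
      if (!std::isfinite(ynew[i])) errmax = 1e30;
    }
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) {
        if (ynew[i] < 0.0) { ynew[i] = 0.0; ++(*nclamp); }
        y[i] = ynew[i];
      }
      double fac = errmax > 0 ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
    }
  }
  return 0;
}

// Integrate a batch of cells (rows of Y) over the same interval dt under the
// same rate table.  Per-row parameter differences must be baked into the
// table beforehand (so batched use applies to cells sharing one parameter
// set; the per-cell inputs TGFa and effective EGFR are baked into the state).
// [[Rcpp::export]]
List pathway_integrate_cpp(NumericMatrix Y, List tab, double dt,
                           double rtol, double atol, double max_steps) {
  RateTable rt = unpack_table(tab);
  if (Y.ncol() != rt.nsp) stop("state width does not match rate table");
  if (rt.nsp > MAX_SPECIES) stop("too many species (max 64)");
  int nc = Y.nrow();
  NumericMatrix Yout(nc, rt.nsp), Dout(nc, rt.nsp);
  IntegerVector status(nc);
  long nclamp = 0;
  double ybuf[MAX_SPECIES], dybuf[MAX_SPECIES];
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < rt.nsp; ++i) ybuf[i] = Y(c, i);
    status[c] = rk45_one(rt, ybuf, dt, rtol, atol, (long)max_steps, &nclamp);
    eval_deriv(rt, ybuf, dybuf);
    for (int i = 0; i < rt.nsp; ++i) {
      Yout(c, i) = ybuf[i];
      Dout(c, i) = dybuf[i];
    }
  }
  return List::create(_["y"] = Yout, _["dy"] = Dout,
                      _["status"] = status, _["n_clamped"] = nclamp);
}
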