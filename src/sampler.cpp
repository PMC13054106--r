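#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

// Meuwissen-Luo inbreeding: for each animal with both parents known, the
// self-relationship a(i,i) = sum_j L_ij^2 D_j is accumulated by pushing the
// generalized-Cholesky weights of i up the pedigree; F_i = a(i,i) - 1.
// sire/dam are 1-based positions in a topologically sorted pedigree, 0 =
// unknown, so every ancestor index is < i.
// [[Rcpp::export]]
NumericVector cpp_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> v(n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s < 0 || d < 0) { F[i] = 0.0; continue; }
    std::fill(v.begin(), v.begin() + i + 1, 0.0);
    v[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      double vj = v[j];
      if (vj == 0.0) continue;
      int sj = sire[j] - 1, dj = dam[j] - 1;
      double Dj = 0.5;
      if (sj >= 0) { v[sj] += 0.5 * vj; Dj -= 0.25 * F[sj]; } else Dj += 0.25;
      if (dj >= 0) { v[dj] += 0.5 * vj; Dj -= 0.25 * F[dj]; } else Dj += 0.25;
      aii += vj * vj * Dj;
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Truncated-normal draw by inversion; the far-tail fallback (interval mass
// below ~1e-12) uses a one-sided exponential proposal anchored at the near
// boundary, which keeps draws inside the interval where inversion underflows.
static double rtnorm1(double mu, double sd, double lo, double hi) {
  double pa = R_finite(lo) ? R::pnorm(lo, mu, sd, 1, 0) : 0.0;
  double pb = R_finite(hi) ? R::pnorm(hi, mu, sd, 1, 0) : 1.0;
  double x;
  if (pb - pa > 1e-12) {
    double p = pa + R::unif_rand() * (pb - pa);
    if (p < 1e-15) p = 1e-15;
    if (p > 1.0 - 1e-15) p = 1.0 - 1e-15;
    x = R::qnorm(p, mu, sd, 1, 0);
  } else if (R_finite(lo) && R_finite(hi)) {
    x = lo + R::unif_rand() * (hi - lo);
  } else if (R_finite(lo)) {                       // far right tail
    double a = std::max((lo - mu) / sd, 1.0);
    x = lo + sd * R::exp_rand() / a;
  } else {                                         // far left tail
    double a = std::max((mu - hi) / sd, 1.0);
    x = hi - sd * R::exp_rand() / a;
  }
  if (R_finite(lo) && x < lo) x = lo;
  if (R_finite(hi) && x > hi) x = hi;
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_rtnorm(int n, NumericVector mean, NumericVector sd,
                         NumericVector lower, NumericVector upper) {
  NumericVector out(n);
  int nm = mean.size(), ns = sd.size(), nl = lower.size(), nu = upper.size();
  for (int i = 0; i < n; ++i)
    out[i] = rtnorm1(mean[i % nm], sd[i % ns], lower[i % nl], upper[i % nu]);
  return out;
}

// One Gibbs pass over the augmented-data entries (ordinal liabilities and
// missing continuous traits). Each latent residual is drawn from its normal
// conditional given the record's other residuals, e_t | e_-t ~
// N(-sum_{u!=t} E_tu e_u / E_tt, 1/E_tt) with E the residual precision, then
// truncated to the observed category's interval on the liability scale.
// [[Rcpp::export]]
NumericMatrix cpp_liability_sweep(NumericMatrix e, NumericMatrix fitted,
                                  IntegerMatrix latent, NumericMatrix lower,
                                  NumericMatrix upper, NumericMatrix E) {
  int n = e.nrow(), T = e.ncol();
  NumericMatrix en = clone(e);
  for (int r = 0; r < n; ++r) {
    for (int t = 0; t < T; ++t) {
      if (!latent(r, t)) continue;
      double s = 0.0;
      for (int u = 0; u < T; ++u)
        if (u != t) s += E(t, u) * en(r, u);
      double csd = std::sqrt(1.0 / E(t, t));
      double mu = fitted(r, t) - s / E(t, t);
      double U = rtnorm1(mu, csd, lower(r, t), upper(r, t));
      en(r, t) = U - fitted(r, t);
    }
  }
  return en;
}

// Single-site Gauss-Seidel pass over all location parameters: every fixed
// effect, then every animal effect in pedigree order (traits innermost), each
// replaced by a draw from its scalar normal full conditional. Residuals are
// updated incrementally through raw column pointers (the sweep is the
// sampler's hot loop). Fixed-effect incidence is passed column-wise as
// (trait, ptr, rows, vals); records per animal as CSR (anim_ptr, anim_rows);
// A-inverse as full-pattern CSC (Ap, Ai, Ax). E = R0^-1, Ginv = G0^-1.
// The trait count is fixed at 3 (ww, wy, ac liability).
// [[Rcpp::export]]
List cpp_location_sweep(NumericMatrix e_, NumericVector beta_,
                        NumericMatrix a_,
                        IntegerVector fpar_trait, IntegerVector fpar_ptr,
                        IntegerVector frows, NumericVector fvals,
                        IntegerVector anim_ptr, IntegerVector anim_rows,
                        IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                        NumericMatrix E_, NumericMatrix Ginv_,
                        double beta_prec) {
  if (E_.ncol() != 3 || Ginv_.ncol() != 3 || e_.ncol() != 3)
    stop("location sweep expects the fixed 3-trait layout");
  NumericMatrix en = clone(e_);
  NumericVector b = clone(beta_);
  NumericMatrix an = clone(a_);
  int n = en.nrow(), q = an.nrow();
  double *e0 = REAL(en), *e1 = e0 + n, *e2 = e1 + n;
  double *a0 = REAL(an), *a1 = a0 + q, *a2 = a1 + q;
  double *ecol[3] = {e0, e1, e2}, *acol[3] = {a0, a1, a2};
  double E[3][3], G[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) { E[i][j] = E_(i, j); G[i][j] = Ginv_(i, j); }

  const int *ft = INTEGER(fpar_trait), *fp = INTEGER(fpar_ptr),
            *fr = INTEGER(frows);
  const double *fv = REAL(fvals);
  double *bp = REAL(b);
  int P = fpar_trait.size();
  for (int j = 0; j < P; ++j) {
    int t = ft[j];
    double Et0 = E[t][0], Et1 = E[t][1], Et2 = E[t][2], Ett = E[t][t];
    double rhs = 0.0, sz2 = 0.0, old = bp[j];
    for (int k = fp[j]; k < fp[j + 1]; ++k) {
      int r = fr[k];
      double z = fv[k];
      rhs += z * (Et0 * e0[r] + Et1 * e1[r] + Et2 * e2[r]) +
             Ett * z * z * old;
      sz2 += z * z;
    }
    double prec = sz2 * Ett + beta_prec;
    double nv = R::rnorm(rhs / prec, 1.0 / std::sqrt(prec));
    double dlt = nv - old;
    double *et = ecol[t];
    if (dlt != 0.0)
      for (int k = fp[j]; k < fp[j + 1]; ++k) et[fr[k]] -= fv[k] * dlt;
    bp[j] = nv;
  }

  const int *ap = INTEGER(anim_ptr), *ar = INTEGER(anim_rows),
            *App = INTEGER(Ap), *Arow = INTEGER(Ai);
  const double *Axx = REAL(Ax);
  for (int i = 0; i < q; ++i) {
    double w[3] = {0.0, 0.0, 0.0}, aii = 0.0;
    for (int k = App[i]; k < App[i + 1]; ++k) {
      int row = Arow[k];
      double x = Axx[k];
      w[0] += x * a0[row]; w[1] += x * a1[row]; w[2] += x * a2[row];
      if (row == i) aii = x;
    }
    for (int t = 0; t < 3; ++t) {
      double Gtt = G[t][t], Ett = E[t][t];
      double Et0 = E[t][0], Et1 = E[t][1], Et2 = E[t][2];
      double old = acol[t][i];
      double rhs = -(G[t][0] * w[0] + G[t][1] * w[1] + G[t][2] * w[2] -
                     Gtt * aii * old);
      double cnt = 0.0;
      for (int k = ap[i]; k < ap[i + 1]; ++k) {
        int r = ar[k];
        rhs += Et0 * e0[r] + Et1 * e1[r] + Et2 * e2[r] + Ett * old;
        cnt += 1.0;
      }
      double prec = cnt * Ett + aii * Gtt;
      double nv = R::rnorm(rhs / prec, 1.0 / std::sqrt(prec));
      double dlt = nv - old;
      double *et = ecol[t];
      if (dlt != 0.0)
        for (int k = ap[i]; k < ap[i + 1]; ++k) et[ar[k]] -= dlt;
      acol[t][i] = nv;
      w[t] += aii * dlt;
    }
  }
  return List::create(_["beta"] = b, _["a"] = an, _["e"] = en);
}

// Sa = a' Ainv a for the G0 full conditional (Ainv in full-pattern CSC)
// [[Rcpp::export]]
NumericMatrix cpp_quadform(IntegerVector Ap, IntegerVector Ai,
                           NumericVector Ax, NumericMatrix a_) {
  int q = a_.nrow(), T = a_.ncol();
  NumericMatrix out(T, T);
  const int *p = INTEGER(Ap), *ri = INTEGER(Ai);
  const double *x = REAL(Ax), *a = REAL(a_);
  std::vector<double> Aa(q);
  for (int t = 0; t < T; ++t) {
    const double *at = a + (size_t)t * q;
    std::fill(Aa.begin(), Aa.end(), 0.0);
    for (int col = 0; col < q; ++col) {
      double ac = at[col];
      if (ac == 0.0) continue;
      for (int k = p[col]; k < p[col + 1]; ++k) Aa[ri[k]] += x[k] * ac;
    }
    for (int u = 0; u < T; ++u) {
      const double *au = a + (size_t)u * q;
      double s = 0.0;
      for (int row = 0; row < q; ++row) s += au[row] * Aa[row];
      out(u, t) = s;
    }
  }
  return out;
}
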