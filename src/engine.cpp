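// Core numerical engine: two-block PLS path model fitter and the
// resampling loops (bootstrap, label permutation) that dominate runtime.
// All randomness comes from R's RNG (unif_rand), so set.seed() on the R
// side makes every routine deterministic.
//
// The mode-A / centroid iteration is a function of the block correlation
// matrices only, so every resampled refit reduces to one cross-product
// accumulation (S = Z'Z, column sums) followed by O(pq) iterations; for
// label permutations the control stratum's cross-products are obtained
// as S_full - S_case.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;
using arma::uword;

// correlation matrix from cross-product sufficient statistics
// S = Z'Z (m x m), s = column sums, n rows; false if a column is constant
static bool corr_from_stats(const mat &S, const vec &s, double n, mat &R) {
  mat C = (S - s * s.t() / n) / (n - 1.0);
  vec d = C.diag();
  if (d.min() < 1e-12) return false;
  vec isd = 1.0 / arma::sqrt(d);
  R = C % (isd * isd.t());
  return true;
}

static bool corr_of_rows(const mat &Z, mat &R) {
  mat S = Z.t() * Z;
  vec s = arma::sum(Z, 0).t();
  return corr_from_stats(S, s, (double)Z.n_rows, R);
}

// deterministic sign convention: largest-magnitude component positive
static void sign_fix(vec &w) {
  if (w(arma::abs(w).index_max()) < 0) w = -w;
}

struct PlspmFitRes {
  vec wa, wb, la, lb;
  double beta, sx, sy;
  int iters;
  bool converged;
  int e;
  bool e_tie;
  bool ok;
};

// Resolve the two-block sign indeterminacy.  With reference weights
// (ref non-empty) each weight vector is flipped to have positive inner
// product with its reference -- this makes every resampled refit
// orient coherently with the observed fit and keeps the whole test
// equivariant under a 2-d allele recode.  Without a reference, the
// largest-magnitude component is made positive (deterministic default
// for a standalone fit).
static void orient_weights(vec &w, const vec &ref) {
  if (ref.n_elem == w.n_elem) {
    double d = arma::dot(w, ref);
    if (d < 0) { w = -w; return; }
    if (d > 0) return;
  }
  sign_fix(w);
}

// Lohmoller two-block algorithm, reflective (mode A) outer estimation,
// centroid inner scheme, expressed on the correlation matrices
// Rxx (p x p), Ryy (q x q), Rxy (p x q) of the standardized indicators.
// init: 0 = equal weights, 1 = dominant eigenvector of the block
// correlation.
static PlspmFitRes plspm_core(const mat &Rxx, const mat &Ryy,
                              const mat &Rxy, double tol, int max_iter,
                              int init, const vec &ref_a, const vec &ref_b) {
  PlspmFitRes r;
  r.ok = true; r.e_tie = false; r.converged = false; r.e = 1;
  const uword p = Rxx.n_rows, q = Ryy.n_rows;

  vec wa(p), wb(q);
  if (init == 1) {
    vec ev; mat evec;
    arma::eig_sym(ev, evec, Rxx);
    wa = evec.col(p - 1);
    arma::eig_sym(ev, evec, Ryy);
    wb = evec.col(q - 1);
    sign_fix(wa); sign_fix(wb);
  } else {
    wa.fill(1.0 / std::sqrt((double)p));
    wb.fill(1.0 / std::sqrt((double)q));
  }

  double sx = 0, sy = 0;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // outer step: score sd's under current weights
    sx = std::sqrt(arma::as_scalar(wa.t() * Rxx * wa));
    sy = std::sqrt(arma::as_scalar(wb.t() * Ryy * wb));
    if (sx < 1e-12 || sy < 1e-12) { r.ok = false; break; }
    double rho = arma::as_scalar(wa.t() * Rxy * wb) / (sx * sy);
    if (rho == 0.0) { r.e = 1; r.e_tie = true; } else r.e = (rho > 0) ? 1 : -1;
    // inner step z_A = e*eta, z_B = e*xi; mode-A update w = cor(x_j, z)
    vec wa_new = (r.e / sy) * (Rxy * wb);
    vec wb_new = (r.e / sx) * (Rxy.t() * wa);
    double na = arma::norm(wa_new, 2), nb = arma::norm(wb_new, 2);
    if (na < 1e-300 || nb < 1e-300) { r.ok = false; break; }
    wa_new /= na; wb_new /= nb;
    double d = std::max(arma::abs(wa_new - wa).max(),
                        arma::abs(wb_new - wb).max());
    wa = wa_new; wb = wb_new;
    if (d < tol) { r.converged = true; break; }
  }
  r.iters = std::min(it, max_iter);
  if (!r.ok) {
    // degenerate sign balance: equal starting weights can annihilate a
    // score exactly (e.g. a perfectly anticorrelated column pair);
    // restart from the dominant eigenvector of the block correlation
    if (init == 0)
      return plspm_core(Rxx, Ryy, Rxy, tol, max_iter, 1, ref_a, ref_b);
    return r;
  }

  orient_weights(wa, ref_a);
  orient_weights(wb, ref_b);
  sx = std::sqrt(arma::as_scalar(wa.t() * Rxx * wa));
  sy = std::sqrt(arma::as_scalar(wb.t() * Ryy * wb));
  r.beta = arma::as_scalar(wa.t() * Rxy * wb) / (sx * sy);
  r.wa = wa; r.wb = wb; r.sx = sx; r.sy = sy;
  r.la = Rxx * wa / sx;   // loadings: cor(x_j, own score)
  r.lb = Ryy * wb / sy;
  return r;
}

static PlspmFitRes fit_joint(const mat &R, uword p, uword q, double tol,
                             int max_iter, int init, const vec &ref_a,
                             const vec &ref_b) {
  return plspm_core(R.submat(0, 0, p - 1, p - 1),
                    R.submat(p, p, p + q - 1, p + q - 1),
                    R.submat(0, p, p - 1, p + q - 1), tol, max_iter, init,
                    ref_a, ref_b);
}

// [[Rcpp::export]]
List cpp_plspm_fit(const arma::mat &X, const arma::mat &Y, double tol,
                   int max_iter, int init, const arma::vec &ref_a,
                   const arma::vec &ref_b) {
  const uword p = X.n_cols, q = Y.n_cols;
  const double n = (double)X.n_rows;
  mat R;
  if (!corr_of_rows(arma::join_rows(X, Y), R))
    stop("zero-variance column in a block passed to the PLS fitter");
  PlspmFitRes r = fit_joint(R, p, q, tol, max_iter, init, ref_a, ref_b);
  if (!r.ok)
    stop("PLS path model fit degenerated: a latent score had zero variance (try init = 'dominant_eigvec')");
  // latent scores from the standardized indicators
  mat Xs = X.each_row() - arma::mean(X, 0);
  mat Ys = Y.each_row() - arma::mean(Y, 0);
  for (uword j = 0; j < p; ++j)
    Xs.col(j) /= std::sqrt(arma::dot(Xs.col(j), Xs.col(j)) / (n - 1.0));
  for (uword j = 0; j < q; ++j)
    Ys.col(j) /= std::sqrt(arma::dot(Ys.col(j), Ys.col(j)) / (n - 1.0));
  vec xi = Xs * r.wa / r.sx;
  vec eta = Ys * r.wb / r.sy;
  return List::create(
      _["weights_a"] = r.wa, _["weights_b"] = r.wb,
      _["scores_a"] = xi, _["scores_b"] = eta,
      _["loadings_a"] = r.la, _["loadings_b"] = r.lb,
      _["path_coefficient"] = r.beta, _["n_iterations"] = r.iters,
      _["converged"] = r.converged, _["inner_sign"] = r.e,
      _["e_tie"] = r.e_tie);
}

static uvec boot_indices(uword n) {
  uvec idx(n);
  for (uword i = 0; i < n; ++i) {
    uword j = (uword)(unif_rand() * n);
    if (j >= n) j = n - 1;
    idx(i) = j;
  }
  return idx;
}

static void shuffle_labels(arma::ivec &lab) {
  for (uword i = lab.n_elem - 1; i > 0; --i) {
    uword j = (uword)(unif_rand() * (i + 1));
    if (j > i) j = i;
    int tmp = lab(i); lab(i) = lab(j); lab(j) = tmp;
  }
}

// Bootstrap path coefficients for ONE stratum: rows resampled with
// replacement jointly across the two blocks, re-standardized (via the
// replicate's own correlation matrix), refit.  Failed replicates are
// redrawn; more than max_fail_frac * n_boot failures aborts.
// [[Rcpp::export]]
List cpp_boot_paths(const arma::mat &A, const arma::mat &B, int n_boot,
                    double tol, int max_iter, int init,
                    double max_fail_frac, const arma::vec &ref_a,
                    const arma::vec &ref_b) {
  const uword n = A.n_rows, p = A.n_cols, q = B.n_cols;
  mat Z = arma::join_rows(A, B);
  vec betas(n_boot);
  mat load_a(n_boot, p), load_b(n_boot, q);
  int fails = 0;
  const int fail_cap = (int)std::ceil(max_fail_frac * n_boot);
  for (int b = 0; b < n_boot; ++b) {
    bool done = false;
    while (!done) {
      uvec idx = boot_indices(n);
      mat R;
      if (!corr_of_rows(Z.rows(idx), R)) {
        if (++fails > fail_cap)
          return List::create(_["error"] = true, _["n_redraws"] = fails);
        continue;
      }
      PlspmFitRes r = fit_joint(R, p, q, tol, max_iter, init, ref_a, ref_b);
      if (!r.ok) {
        if (++fails > fail_cap)
          return List::create(_["error"] = true, _["n_redraws"] = fails);
        continue;
      }
      betas(b) = r.beta;
      load_a.row(b) = r.la.t();
      load_b.row(b) = r.lb.t();
      done = true;
    }
  }
  return List::create(_["error"] = false, _["betas"] = betas,
                      _["loadings_a"] = load_a, _["loadings_b"] = load_b,
                      _["n_redraws"] = fails);
}

// per-stratum correlation matrices of a permuted split, exploiting
// S_control = S_full - S_case
struct SplitCorr {
  mat R1, R0;
  bool ok;
};

static SplitCorr split_corr(const mat &Z, const mat &S_full,
                            const vec &s_full, const arma::ivec &lab) {
  SplitCorr out;
  uvec i1 = arma::find(lab == 1);
  mat Z1 = Z.rows(i1);
  mat S1 = Z1.t() * Z1;
  vec s1 = arma::sum(Z1, 0).t();
  double n1 = (double)Z1.n_rows;
  double n0 = (double)Z.n_rows - n1;
  out.ok = corr_from_stats(S1, s1, n1, out.R1) &&
           corr_from_stats(S_full - S1, s_full - s1, n0, out.R0);
  return out;
}

// Permutation distribution of beta_case - beta_control (numerator-only
// scheme: the bootstrap denominator is held fixed by the caller).
// [[Rcpp::export]]
List cpp_perm_beta_diff(const arma::mat &A, const arma::mat &B,
                        const arma::ivec &pheno, int n_perm, double tol,
                        int max_iter, int init, const arma::vec &ref_a,
                        const arma::vec &ref_b) {
  const uword p = A.n_cols, q = B.n_cols;
  mat Z = arma::join_rows(A, B);
  mat S_full = Z.t() * Z;
  vec s_full = arma::sum(Z, 0).t();
  vec diffs(n_perm);
  arma::ivec lab = pheno;
  int fails = 0;
  const int fail_cap = 10 * n_perm + 100;
  for (int k = 0; k < n_perm; ++k) {
    bool done = false;
    while (!done) {
      shuffle_labels(lab);
      SplitCorr sc = split_corr(Z, S_full, s_full, lab);
      if (!sc.ok) {
        if (++fails > fail_cap)
          return List::create(_["error"] = true, _["n_redraws"] = fails);
        continue;
      }
      PlspmFitRes r1 = fit_joint(sc.R1, p, q, tol, max_iter, init, ref_a,
                                 ref_b);
      PlspmFitRes r0 = fit_joint(sc.R0, p, q, tol, max_iter, init, ref_a,
                                 ref_b);
      if (!r1.ok || !r0.ok) {
        if (++fails > fail_cap)
          return List::create(_["error"] = true, _["n_redraws"] = fails);
        continue;
      }
      diffs(k) = r1.beta - r0.beta;
      done = true;
    }
  }
  return List::create(_["error"] = false, _["diffs"] = diffs,
                      _["n_redraws"] = fails);
}

// Full-recompute permutation scheme: re-estimates the bootstrap variances
// inside every permutation (reduced n_boot); returns permuted U values.
// [[Rcpp::export]]
List cpp_perm_U_full(const arma::mat &A, const arma::mat &B,
                     const arma::ivec &pheno, int n_perm, int n_boot,
                     double tol, int max_iter, int init,
                     double max_fail_frac, const arma::vec &ref_a,
                     const arma::vec &ref_b) {
  const uword p = A.n_cols, q = B.n_cols;
  mat Z = arma::join_rows(A, B);
  mat S_full = Z.t() * Z;
  vec s_full = arma::sum(Z, 0).t();
  vec U(n_perm);
  arma::ivec lab = pheno;
  int guard = 0;
  for (int k = 0; k < n_perm; ++k) {
    if (++guard > 10 * n_perm + 100)
      return List::create(_["error"] = true);
    shuffle_labels(lab);
    SplitCorr sc = split_corr(Z, S_full, s_full, lab);
    if (!sc.ok) { --k; continue; }
    PlspmFitRes r1 = fit_joint(sc.R1, p, q, tol, max_iter, init, ref_a,
                               ref_b);
    PlspmFitRes r0 = fit_joint(sc.R0, p, q, tol, max_iter, init, ref_a,
                               ref_b);
    if (!r1.ok || !r0.ok) { --k; continue; }
    uvec i1 = arma::find(lab == 1), i0 = arma::find(lab == 0);
    List b1 = cpp_boot_paths(A.rows(i1), B.rows(i1), n_boot, tol, max_iter,
                             init, max_fail_frac, r1.wa, r1.wb);
    List b0 = cpp_boot_paths(A.rows(i0), B.rows(i0), n_boot, tol, max_iter,
                             init, max_fail_frac, r0.wa, r0.wb);
    if (as<bool>(b1["error"]) || as<bool>(b0["error"])) { --k; continue; }
    double v1 = arma::var(as<vec>(b1["betas"]));
    double v0 = arma::var(as<vec>(b0["betas"]));
    U(k) = (r1.beta - r0.beta) / std::sqrt(v1 + v0);
  }
  return List::create(_["error"] = false, _["U"] = U);
}

// ---------------------------------------------------------------------
// First canonical correlation (for the CCU comparator)

static double cc1_corr(const mat &Rxx, const mat &Ryy, const mat &Rxy,
                       bool &ridged) {
  mat Lx, Ly;
  mat Rxx_ = Rxx, Ryy_ = Ryy;
  if (!arma::chol(Lx, Rxx_, "lower")) {
    Rxx_.diag() += 1e-8; ridged = true;
    if (!arma::chol(Lx, Rxx_, "lower")) return NA_REAL;
  }
  if (!arma::chol(Ly, Ryy_, "lower")) {
    Ryy_.diag() += 1e-8; ridged = true;
    if (!arma::chol(Ly, Ryy_, "lower")) return NA_REAL;
  }
  mat T1 = arma::solve(arma::trimatl(Lx), Rxy);       // p x q
  mat U = arma::solve(arma::trimatl(Ly), T1.t());     // q x p
  vec ev = arma::eig_sym(U.t() * U);
  double l = ev(ev.n_elem - 1);
  if (l < 0) l = 0; if (l > 1) l = 1;
  return std::sqrt(l);
}

static double cc1_joint(const mat &R, uword p, uword q, bool &ridged) {
  return cc1_corr(R.submat(0, 0, p - 1, p - 1),
                  R.submat(p, p, p + q - 1, p + q - 1),
                  R.submat(0, p, p - 1, p + q - 1), ridged);
}

// [[Rcpp::export]]
List cpp_cc1(const arma::mat &X, const arma::mat &Y) {
  mat R;
  if (!corr_of_rows(arma::join_rows(X, Y), R))
    stop("zero-variance column in canonical-correlation input");
  bool ridged = false;
  double cc = cc1_joint(R, X.n_cols, Y.n_cols, ridged);
  return List::create(_["cc1"] = cc, _["ridged"] = ridged);
}

// [[Rcpp::export]]
List cpp_ccu_boot(const arma::mat &A, const arma::mat &B, int n_boot,
                  double max_fail_frac) {
  const uword n = A.n_rows, p = A.n_cols, q = B.n_cols;
  mat Z = arma::join_rows(A, B);
  vec cc(n_boot);
  int fails = 0;
  const int fail_cap = (int)std::ceil(max_fail_frac * n_boot);
  for (int b = 0; b < n_boot; ++b) {
    bool done = false;
    while (!done) {
      uvec idx = boot_indices(n);
      mat R;
      bool ridged = false;
      double v = NA_REAL;
      if (corr_of_rows(Z.rows(idx), R)) v = cc1_joint(R, p, q, ridged);
      if (!std::isfinite(v)) {
        if (++fails > fail_cap)
          return List::create(_["error"] = true, _["n_redraws"] = fails);
        continue;
      }
      cc(b) = v;
      done = true;
    }
  }
  return List::create(_["error"] = false, _["cc1"] = cc,
                      _["n_redraws"] = fails);
}

// [[Rcpp::export]]
List cpp_ccu_perm(const arma::mat &A, const arma::mat &B,
                  const arma::ivec &pheno, int n_perm) {
  const uword p = A.n_cols, q = B.n_cols;
  mat Z = arma::join_rows(A, B);
  mat S_full = Z.t() * Z;
  vec s_full = arma::sum(Z, 0).t();
  vec diffs(n_perm);
  arma::ivec lab = pheno;
  int fails = 0;
  const int fail_cap = 10 * n_perm + 100;
  for (int k = 0; k < n_perm; ++k) {
    bool done = false;
    while (!done) {
      shuffle_labels(lab);
      SplitCorr sc = split_corr(Z, S_full, s_full, lab);
      bool ridged = false;
      double c1 = NA_REAL, c0 = NA_REAL;
      if (sc.ok) {
        c1 = cc1_joint(sc.R1, p, q, ridged);
        c0 = cc1_joint(sc.R0, p, q, ridged);
      }
      if (!std::isfinite(c1) || !std::isfinite(c0)) {
        if (++fails > fail_cap)
          return List::create(_["error"] = true, _["n_redraws"] = fails);
        continue;
      }
      diffs(k) = c1 - c0;
      done = true;
    }
  }
  return List::create(_["error"] = false, _["diffs"] = diffs,
                      _["n_redraws"] = fails);
}

// ---------------------------------------------------------------------
// Covariance-difference comparator helpers

static vec crosscov_vec(const mat &A, const mat &B) {
  const double nm1 = (double)A.n_rows - 1.0;
  mat Ac = A.each_row() - arma::mean(A, 0);
  mat Bc = B.each_row() - arma::mean(B, 0);
  mat C = Ac.t() * Bc / nm1;
  return arma::vectorise(C);
}

// [[Rcpp::export]]
arma::vec cpp_crosscov_vec(const arma::mat &A, const arma::mat &B) {
  return crosscov_vec(A, B);
}

// bootstrap replicates of the vectorized cross-gene covariance (one stratum)
// [[Rcpp::export]]
arma::mat cpp_cov_boot(const arma::mat &A, const arma::mat &B, int n_boot) {
  const uword n = A.n_rows;
  mat out(n_boot, A.n_cols * B.n_cols);
  for (int b = 0; b < n_boot; ++b) {
    uvec idx = boot_indices(n);
    out.row(b) = crosscov_vec(A.rows(idx), B.rows(idx)).t();
  }
  return out;
}

// symmetric pseudo-inverse with a relative eigenvalue cut
static mat sym_pinv(const mat &W, double rel_tol) {
  vec ev; mat evec;
  arma::eig_sym(ev, evec, (W + W.t()) / 2.0);
  double cut = rel_tol * ev.max();
  vec inv_ev(ev.n_elem, arma::fill::zeros);
  for (uword i = 0; i < ev.n_elem; ++i)
    if (ev(i) > cut) inv_ev(i) = 1.0 / ev(i);
  return evec * arma::diagmat(inv_ev) * evec.t();
}

// Permutation distribution of d' W^- d with W re-estimated by stratified
// bootstrap inside every permutation -- the statistic is then the same
// function of the label assignment as the observed one, so the
// permutation test is exact under exchangeability (a fixed W estimated
// from the observed labeling is not label-invariant and mis-calibrates).
// [[Rcpp::export]]
arma::vec cpp_cov_perm_full(const arma::mat &A, const arma::mat &B,
                            const arma::ivec &pheno, int n_perm,
                            int n_boot, double rel_tol) {
  const uword n = A.n_rows, p = A.n_cols, q = B.n_cols, m = p * q;
  // per-row outer products: the cross-covariance of ANY row multiset is
  // (sum_P - vec(sum_A sum_B')/nn) / (nn - 1), so every bootstrap
  // replicate reduces to index-driven row sums
  mat P(n, m);
  for (uword i = 0; i < n; ++i)
    P.row(i) = arma::vectorise(A.row(i).t() * B.row(i)).t();

  arma::rowvec sumP(m), sA(p), sB(q);
  auto crosscov_of = [&](const uvec &idx) -> vec {
    sumP.zeros(); sA.zeros(); sB.zeros();
    for (uword t = 0; t < idx.n_elem; ++t) {
      sumP += P.row(idx(t));
      sA += A.row(idx(t));
      sB += B.row(idx(t));
    }
    double nn = (double)idx.n_elem;
    arma::rowvec mean_op = arma::vectorise(sA.t() * sB).t() / nn;
    return ((sumP - mean_op) / (nn - 1.0)).t();
  };

  vec stats(n_perm);
  arma::ivec lab = pheno;
  mat r1(n_boot, m), r0(n_boot, m);
  for (int k = 0; k < n_perm; ++k) {
    shuffle_labels(lab);
    uvec i1 = arma::find(lab == 1), i0 = arma::find(lab == 0);
    vec d = crosscov_of(i1) - crosscov_of(i0);
    for (int b = 0; b < n_boot; ++b) {
      r1.row(b) = crosscov_of(i1.elem(boot_indices(i1.n_elem))).t();
      r0.row(b) = crosscov_of(i0.elem(boot_indices(i0.n_elem))).t();
    }
    mat W = arma::cov(r1) + arma::cov(r0);
    stats(k) = arma::as_scalar(d.t() * sym_pinv(W, rel_tol) * d);
  }
  return stats;
}

// [[Rcpp::export]]
arma::mat cpp_sym_pinv(const arma::mat &W, double rel_tol) {
  return sym_pinv(W, rel_tol);
}

// permutation distribution of d' Winv d with W held fixed
// [[Rcpp::export]]
arma::vec cpp_cov_perm(const arma::mat &A, const arma::mat &B,
                       const arma::ivec &pheno, int n_perm,
                       const arma::mat &Winv) {
  vec stats(n_perm);
  arma::ivec lab = pheno;
  for (int k = 0; k < n_perm; ++k) {
    shuffle_labels(lab);
    uvec i1 = arma::find(lab == 1), i0 = arma::find(lab == 0);
    vec d = crosscov_vec(A.rows(i1), B.rows(i1)) -
            crosscov_vec(A.rows(i0), B.rows(i0));
    stats(k) = arma::dot(d, Winv * d);
  }
  return stats;
}

// ---------------------------------------------------------------------
// Fast IRLS logistic regression (Newton scoring) for the single-SNP
// min-p comparator's permutation loop.

static bool irls(const mat &X, const vec &y, vec &beta, mat &cov_out) {
  const uword k = X.n_cols;
  beta.zeros(k);
  for (int it = 0; it < 30; ++it) {
    vec eta = X * beta;
    eta = arma::clamp(eta, -30.0, 30.0);
    vec mu = 1.0 / (1.0 + arma::exp(-eta));
    vec w = mu % (1.0 - mu);
    mat XtWX = X.t() * (X.each_col() % w);
    vec grad = X.t() * (y - mu);
    vec delta;
    if (!arma::solve(delta, XtWX, grad, arma::solve_opts::no_approx))
      return false;
    beta += delta;
    if (!beta.is_finite() || arma::abs(beta).max() > 25.0) return false;
    if (arma::abs(delta).max() < 1e-8) {
      if (!arma::inv_sympd(cov_out, XtWX)) return false;
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_irls_logistic(const arma::mat &X, const arma::vec &y) {
  vec beta; mat covb;
  bool ok = irls(X, y, beta, covb);
  if (!ok)
    return List::create(_["converged"] = false);
  return List::create(_["converged"] = true, _["beta"] = beta,
                      _["se"] = arma::sqrt(covb.diag()));
}

static double pair_interaction_p(const mat &D, const vec &y) {
  vec beta; mat covb;
  if (!irls(D, y, beta, covb)) return NA_REAL;
  double se = std::sqrt(covb(3, 3));
  if (!std::isfinite(se) || se <= 0) return NA_REAL;
  double z = beta(3) / se;
  return 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
}

// All SNP-pair logistic interaction Wald tests + min-p permutation null.
// [[Rcpp::export]]
List cpp_snp_logistic_minp(const arma::mat &A, const arma::mat &B,
                           const arma::vec &y, int n_perm) {
  const uword n = A.n_rows, p = A.n_cols, q = B.n_cols;
  // fixed per-pair designs: intercept, snp_a, snp_b, product
  std::vector<mat> designs;
  designs.reserve(p * q);
  for (uword j = 0; j < p; ++j)
    for (uword k = 0; k < q; ++k) {
      mat D(n, 4);
      D.col(0).ones();
      D.col(1) = A.col(j);
      D.col(2) = B.col(k);
      D.col(3) = A.col(j) % B.col(k);
      designs.push_back(D);
    }
  mat pmat(p, q);
  double minp = arma::datum::inf;
  uword n_ok = 0;
  for (uword j = 0; j < p; ++j)
    for (uword k = 0; k < q; ++k) {
      double pv = pair_interaction_p(designs[j * q + k], y);
      pmat(j, k) = pv;
      if (std::isfinite(pv)) {
        ++n_ok;
        if (pv < minp) minp = pv;
      }
    }
  if (n_ok == 0)
    return List::create(_["error"] = true);
  vec perm_minp(n_perm);
  vec yp = y;
  for (int r = 0; r < n_perm; ++r) {
    for (uword i = yp.n_elem - 1; i > 0; --i) {
      uword jj = (uword)(unif_rand() * (i + 1));
      if (jj > i) jj = i;
      double tmp = yp(i); yp(i) = yp(jj); yp(jj) = tmp;
    }
    double m = arma::datum::inf;
    for (uword d = 0; d < designs.size(); ++d) {
      double pv = pair_interaction_p(designs[d], yp);
      if (std::isfinite(pv) && pv < m) m = pv;
    }
    perm_minp(r) = std::isfinite(m) ? m : 1.0;
  }
  return List::create(_["error"] = false, _["p_matrix"] = pmat,
                      _["min_p"] = minp, _["perm_min_p"] = perm_minp,
                      _["n_pairs_ok"] = (int)n_ok);
}
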