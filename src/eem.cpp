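// Dense EEM linear solves. The (N+1)x(N+1) bordered system per molecule is
// small, but parameterization evaluates it for every molecule at every
// objective evaluation, so the hot path lives here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// types: 0-based indices into A/B. Returns false on a (near-)singular
// system, detected by reciprocal condition estimate < rcond_min;
// rcond_min <= 0 skips the estimate (fast path for objective loops).
static bool solve_one(const arma::mat& invR, const arma::ivec& types,
                      const arma::vec& A, const arma::vec& B,
                      double kappa, double Q, double rcond_min,
                      arma::vec& q, double& chi) {
  const arma::uword n = invR.n_rows;
  arma::mat M(n + 1, n + 1);
  M.submat(0, 0, n - 1, n - 1) = kappa * invR;
  for (arma::uword i = 0; i < n; ++i) {
    M(i, i) = B(types(i));
    M(i, n) = -1.0;
    M(n, i) = 1.0;
  }
  M(n, n) = 0.0;

  arma::vec rhs(n + 1);
  for (arma::uword i = 0; i < n; ++i) rhs(i) = -A(types(i));
  rhs(n) = Q;

  arma::vec sol;
  if (rcond_min > 0) {
    if (arma::rcond(M) < rcond_min) return false;
    if (!arma::solve(sol, M, rhs, arma::solve_opts::no_approx)) return false;
  } else {
    // hot path: plain LU without condition estimation or refinement;
    // failures and wild solutions map to the caller's sentinel
    if (!arma::solve(sol, M, rhs,
                     arma::solve_opts::fast + arma::solve_opts::no_approx)) {
      return false;
    }
  }
  if (!sol.is_finite()) return false;
  q = sol.head(n);
  chi = sol(n);
  return true;
}

// [[Rcpp::export(name = ".eem_solve_cpp", rng = false)]]
List eem_solve_cpp(const arma::mat& invR, const arma::ivec& types,
                   const arma::vec& A, const arma::vec& B,
                   double kappa, double Q, double rcond_min) {
  arma::vec q;
  double chi = 0.0;
  bool ok = solve_one(invR, types, A, B, kappa, Q, rcond_min, q, chi);
  if (!ok) return List::create(Named("ok") = false);
  return List::create(Named("ok") = true,
                      Named("charges") = NumericVector(q.begin(), q.end()),
                      Named("chi") = chi);
}

// Batch over molecules; `mols` is a list of lists with elements
// invR (matrix), types (0-based integer vector), Q (scalar). Returns the
// pooled charge vector in input order, or ok = FALSE on the first failed
// solve (index of the offender reported).
// [[Rcpp::export(name = ".eem_pooled_cpp", rng = false)]]
List eem_pooled_cpp(const List& mols, const arma::vec& A,
                    const arma::vec& B, double kappa, double rcond_min) {
  const int m = mols.size();
  std::vector<double> pooled;
  NumericVector chis(m);
  for (int k = 0; k < m; ++k) {
    List mol = mols[k];
    arma::mat invR = as<arma::mat>(mol["invR"]);
    arma::ivec types = as<arma::ivec>(mol["types"]);
    double Q = as<double>(mol["Q"]);
    arma::vec q;
    double chi = 0.0;
    if (!solve_one(invR, types, A, B, kappa, Q, rcond_min, q, chi)) {
      return List::create(Named("ok") = false, Named("failed_at") = k + 1);
    }
    pooled.insert(pooled.end(), q.begin(), q.end());
    chis[k] = chi;
  }
  return List::create(Named("ok") = true,
                      Named("charges") = NumericVector(pooled.begin(), pooled.end()),
                      Named("chi") = chis);
}

// Fused objective evaluation for parameterization: solve every molecule
// and compare the pooled EEM charges with pooled reference charges.
// type_codes are 0-based pooled atom-type indices (< n_types). Returns
// c(ok, R, R2, rmsd, avg_rmsd_a, max_rmsd_a); ok = 0 flags a failed or
// degenerate evaluation.
// [[Rcpp::export(name = ".eem_fitness_cpp", rng = false)]]
NumericVector eem_fitness_cpp(const List& mols, const arma::vec& A,
                              const arma::vec& B, double kappa,
                              double rcond_min, const arma::vec& ref,
                              const arma::ivec& type_codes, int n_types) {
  const int m = mols.size();
  arma::vec eem(ref.n_elem);
  arma::uword pos = 0;
  for (int k = 0; k < m; ++k) {
    List mol = mols[k];
    arma::mat invR = as<arma::mat>(mol["invR"]);
    arma::ivec types = as<arma::ivec>(mol["types"]);
    double Q = as<double>(mol["Q"]);
    arma::vec q;
    double chi = 0.0;
    if (!solve_one(invR, types, A, B, kappa, Q, rcond_min, q, chi)) {
      return NumericVector::create(0, NA_REAL, NA_REAL, NA_REAL, NA_REAL,
                                   NA_REAL);
    }
    eem.subvec(pos, pos + q.n_elem - 1) = q;
    pos += q.n_elem;
  }

  const arma::uword n = ref.n_elem;
  arma::vec d = eem - ref;
  double rmsd = std::sqrt(arma::dot(d, d) / n);

  arma::vec ss(n_types, arma::fill::zeros);
  arma::vec cnt(n_types, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    ss(type_codes(i)) += d(i) * d(i);
    cnt(type_codes(i)) += 1.0;
  }
  double sum_rmsd_a = 0.0, max_rmsd_a = 0.0;
  int represented = 0;
  for (int t = 0; t < n_types; ++t) {
    if (cnt(t) > 0) {
      double r = std::sqrt(ss(t) / cnt(t));
      sum_rmsd_a += r;
      if (r > max_rmsd_a) max_rmsd_a = r;
      ++represented;
    }
  }
  double avg_rmsd_a = represented > 0 ? sum_rmsd_a / represented : NA_REAL;

  double mr = arma::mean(ref), me = arma::mean(eem);
  arma::vec cr = ref - mr, ce = eem - me;
  double denom = std::sqrt(arma::dot(cr, cr) * arma::dot(ce, ce));
  double R = NA_REAL;
  if (denom > 0) R = arma::dot(cr, ce) / denom;
  double R2 = ISNAN(R) ? NA_REAL : R * R;
  return NumericVector::create(1, R, R2, rmsd, avg_rmsd_a, max_rmsd_a);
}

// Persistent evaluation context: all per-molecule inputs converted once,
// so each objective evaluation costs only the linear solves.
struct EemContext {
  std::vector<arma::mat> invR;
  std::vector<arma::ivec> types;
  std::vector<double> Q;
  arma::vec ref;
  arma::ivec codes;
  int n_types;
};

// [[Rcpp::export(name = ".eem_ctx_cpp", rng = false)]]
SEXP eem_ctx_cpp(const List& mols, const arma::vec& ref,
                 const arma::ivec& codes, int n_types) {
  XPtr<EemContext> ctx(new EemContext(), true);
  const int m = mols.size();
  ctx->invR.reserve(m);
  ctx->types.reserve(m);
  ctx->Q.reserve(m);
  for (int k = 0; k < m; ++k) {
    List mol = mols[k];
    ctx->invR.push_back(as<arma::mat>(mol["invR"]));
    ctx->types.push_back(as<arma::ivec>(mol["types"]));
    ctx->Q.push_back(as<double>(mol["Q"]));
  }
  ctx->ref = ref;
  ctx->codes = codes;
  ctx->n_types = n_types;
  return ctx;
}

// Same contract as .eem_fitness_cpp, against a prebuilt context.
// [[Rcpp::export(name = ".eem_fitness_ctx_cpp", rng = false)]]
NumericVector eem_fitness_ctx_cpp(SEXP ctx_ptr, const arma::vec& A,
                                  const arma::vec& B, double kappa,
                                  double rcond_min) {
  XPtr<EemContext> ctx(ctx_ptr);
  const size_t m = ctx->invR.size();
  arma::vec eem(ctx->ref.n_elem);
  arma::uword pos = 0;
  arma::vec q;
  double chi = 0.0;
  for (size_t k = 0; k < m; ++k) {
    if (!solve_one(ctx->invR[k], ctx->types[k], A, B, kappa, ctx->Q[k],
                   rcond_min, q, chi)) {
      return NumericVector::create(0, NA_REAL, NA_REAL, NA_REAL, NA_REAL,
                                   NA_REAL);
    }
    eem.subvec(pos, pos + q.n_elem - 1) = q;
    pos += q.n_elem;
  }

  const arma::uword n = ctx->ref.n_elem;
  arma::vec d = eem - ctx->ref;
  double rmsd = std::sqrt(arma::dot(d, d) / n);
  arma::vec ss(ctx->n_types, arma::fill::zeros);
  arma::vec cnt(ctx->n_types, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    ss(ctx->codes(i)) += d(i) * d(i);
    cnt(ctx->codes(i)) += 1.0;
  }
  double sum_rmsd_a = 0.0, max_rmsd_a = 0.0;
  int represented = 0;
  for (int t = 0; t < ctx->n_types; ++t) {
    if (cnt(t) > 0) {
      double r = std::sqrt(ss(t) / cnt(t));
      sum_rmsd_a += r;
      if (r > max_rmsd_a) max_rmsd_a = r;
      ++represented;
    }
  }
  double avg_rmsd_a = represented > 0 ? sum_rmsd_a / represented : NA_REAL;
  double mr = arma::mean(ctx->ref), me = arma::mean(eem);
  arma::vec cr = ctx->ref - mr, ce = eem - me;
  double denom = std::sqrt(arma::dot(cr, cr) * arma::dot(ce, ce));
  double R = NA_REAL;
  if (denom > 0) R = arma::dot(cr, ce) / denom;
  double R2 = ISNAN(R) ? NA_REAL : R * R;
  return NumericVector::create(1, R, R2, rmsd, avg_rmsd_a, max_rmsd_a);
}
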