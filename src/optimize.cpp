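#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Smoothed off-diagonal L1 cost: sum_{i!=j} sqrt(|M_ij|^2 + eps)
static double cost_eps(const cx_mat& M, double eps) {
  mat s = sqrt(square(abs(M)) + eps);
  s.diag().zeros();
  return accu(s);
}

static double offdiag_l1(const cx_mat& M) {
  mat a = abs(M);
  a.diag().zeros();
  return accu(a);
}

// Inner product on the tangent space: <A,B> = 0.5 Re tr(A^H B)
static double ip(const cx_mat& A, const cx_mat& B) {
  return 0.5 * real(accu(conj(A) % B));
}

// Riemannian conjugate-gradient minimization of the smoothed off-diagonal L1
// norm of U*B0 over the unitary group.  The Euclidean gradient is projected
// to the skew-Hermitian tangent space; updates move along geodesics
// U <- expm(mu*D)*U with Armijo backtracking; the smoothing eps is annealed
// over `eps_schedule` with warm starts.  Since U enters the cost only via
// M = U*B0, line-search trials update M directly (one eigendecomposition of
// the skew-Hermitian direction per iteration, then cheap diagonal rescales).
// [[Rcpp::export]]
Rcpp::List cpp_optimize_unitary(const arma::cx_mat& B0, const arma::cx_mat& U0,
                                const arma::vec& eps_schedule, int max_iter,
                                double tol, double armijo_c) {
  const uword n = B0.n_rows;
  const cx_double I1(0.0, 1.0);
  cx_mat U = U0;
  cx_mat M = U * B0;
  std::vector<double> trace;
  trace.reserve(256);
  bool converged = true;
  int total_iter = 0, accepted_steps = 0;
  double mu = 0.1;  // carried initial step between iterations

  for (uword ei = 0; ei < eps_schedule.n_elem; ++ei) {
    const double eps = eps_schedule(ei);
    double J = cost_eps(M, eps);
    trace.push_back(J);
    cx_mat Gprev, Dprev;
    double gprev2 = 0.0;
    bool have_prev = false;
    int since_reset = 0;
    bool steepest_failed = false;

    while (true) {
      if (total_iter >= max_iter) { converged = false; break; }
      ++total_iter;
      // Riemannian gradient: G = Gamma*U^H - U*Gamma^H with
      // Gamma = (M/s)_offdiag * B0^H; equivalently G = Gm*M^H - M*Gm^H.
      cx_mat Gm = M / cx_mat(sqrt(square(abs(M)) + eps), mat(n, n, fill::zeros));
      Gm.diag().zeros();
      cx_mat G = Gm * M.t() - M * Gm.t();
      const double g2 = ip(G, G);  // 0.5*||G||_F^2
      if (std::sqrt(std::max(g2, 0.0)) < 1e-12 * std::max(1.0, J)) break;

      // conjugate direction (Polak-Ribiere+, reset on schedule/non-descent)
      cx_mat D;
      if (!have_prev || since_reset >= (int)(2 * n * n)) {
        D = -G;
        since_reset = 0;
      } else {
        double beta = ip(G, G - Gprev) / gprev2;
        if (beta < 0 || !std::isfinite(beta)) beta = 0;
        D = -G + beta * Dprev;
      }
      double slope = ip(G, D);
      if (slope >= 0) { D = -G; slope = -g2; since_reset = 0; }

      // geodesic step via eigendecomposition of the Hermitian matrix i*D
      vec lam;
      cx_mat V;
      if (!eig_sym(lam, V, cx_mat(I1 * D)))
        Rcpp::stop("eigendecomposition of descent direction failed");
      const double lmax = abs(lam).max();
      if (lmax < 1e-300) break;
      cx_mat VhM = V.t() * M;
      const cx_vec clam = conv_to<cx_vec>::from(lam);

      double mu_try = std::min(2.0 * mu, datum::pi / lmax);
      bool accepted = false;
      cx_mat Mnew;
      double Jn = J;
      for (int ls = 0; ls < 45; ++ls) {
        cx_vec ph = exp(-I1 * mu_try * clam);
        cx_mat T1 = VhM;
        T1.each_col() %= ph;
        Mnew = V * T1;
        Jn = cost_eps(Mnew, eps);
        if (std::isfinite(Jn) && Jn <= J + armijo_c * mu_try * slope) {
          accepted = true;
          break;
        }
        mu_try *= 0.5;
      }

      if (!accepted) {
        if (have_prev) {  // retry from steepest descent
          have_prev = false;
          since_reset = 0;
          continue;
        }
        if (steepest_failed) break;
        steepest_failed = true;
        break;  // no descent along steepest direction: stage converged
      }
      steepest_failed = false;

      // apply the accepted rotation to U as well
      cx_vec ph = exp(-I1 * mu_try * clam);
      cx_mat T2 = V.t() * U;
      T2.each_col() %= ph;
      U = V * T2;
      const double Jold = J;
      M = Mnew;
      J = Jn;
      mu = mu_try;
      trace.push_back(J);
      Gprev = G; Dprev = D; gprev2 = g2;
      have_prev = true;
      ++since_reset;
      ++accepted_steps;

      if (accepted_steps % 100 == 0) {
        // drift control: polar re-unitarization of U
        cx_mat A, Bm;
        vec sv;
        if (svd(A, sv, Bm, U)) { U = A * Bm.t(); M = U * B0; J = cost_eps(M, eps); }
      }
      if (std::fabs(Jold - J) <= tol * std::max(1.0, std::fabs(Jold))) break;
    }
    if (!converged) break;
  }

  return Rcpp::List::create(
      Rcpp::Named("u") = U,
      Rcpp::Named("cost_trace") = trace,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iter") = total_iter,
      Rcpp::Named("final_cost") = offdiag_l1(M));
}
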