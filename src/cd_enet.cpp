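#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double softt(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Coordinate descent for the weighted elastic-net problem
//
//   min_u  u'Gu - 2 g'u + sum_j lam1_j |u_j| + sum_j lam2_j u_j^2
//   s.t.   c'u = 0
//
// where G = X'X and g = X'y, so the quadratic part is the least-squares
// objective up to a constant. The single linear equality is handled by an
// augmented Lagrangian (multiplier ymult, stiffness rho); soft thresholding
// keeps coordinates exactly zero, and the multiplier converges to the KKT
// value of the constrained problem, so the support is unaffected by the
// constraint term at the solution. Inner sweeps use an active-set strategy:
// full passes establish the working set, then only nonzero coordinates are
// cycled until convergence. ymult0 allows warm-starting the multiplier along
// a lambda path; the final multiplier is returned for reuse.
// [[Rcpp::export(name = ".cdConstrainedEnet")]]
Rcpp::List cdConstrainedEnet(const arma::mat& G, const arma::vec& g,
                             const arma::vec& c, const arma::vec& lam1,
                             const arma::vec& lam2, arma::vec u,
                             double ymult0 = 0.0, double tol = 1e-8,
                             int maxSweeps = 400, int maxOuter = 40,
                             double cTol = 1e-10) {
  const unsigned int P = G.n_rows;
  vec Gu = G * u;
  double cu = dot(c, u);
  double ymult = ymult0;
  double meanDiag = mean(G.diag());
  double rho = 10.0 * (meanDiag > 0 ? meanDiag : 1.0) /
               std::max(mean(square(c)), 1e-12);
  double prevViol = datum::inf;

  auto update = [&](unsigned int j) -> double {
    double uj = u(j);
    double a = 2.0 * G(j, j) + 2.0 * lam2(j) + rho * c(j) * c(j);
    if (a <= 0.0) return 0.0;
    double b = 2.0 * (Gu(j) - G(j, j) * uj) - 2.0 * g(j)
             + c(j) * (rho * (cu - c(j) * uj) + ymult);
    double unew = softt(-b, lam1(j)) / a;
    if (unew != uj) {
      double dlt = unew - uj;
      Gu += G.col(j) * dlt;
      cu += c(j) * dlt;
      u(j) = unew;
      return std::abs(dlt);
    }
    return 0.0;
  };

  for (int outer = 0; outer < maxOuter; ++outer) {
    int sweeps = 0;
    while (sweeps < maxSweeps) {
      // full pass: updates every coordinate and (re)builds the active set
      double maxDelta = 0.0, scale = 1.0;
      for (unsigned int j = 0; j < P; ++j) {
        double d = update(j);
        if (d > maxDelta) maxDelta = d;
        double au = std::abs(u(j));
        if (au > scale) scale = au;
      }
      ++sweeps;
      if (maxDelta < tol * scale) break;
      uvec active = find(u != 0.0);
      while (sweeps < maxSweeps) {
        double mD = 0.0, sc = 1.0;
        for (unsigned int k = 0; k < active.n_elem; ++k) {
          double d = update(active(k));
          if (d > mD) mD = d;
          double au = std::abs(u(active(k)));
          if (au > sc) sc = au;
        }
        ++sweeps;
        if (mD < tol * sc) break;
      }
    }
    double unorm = norm(u, 2);
    double viol = std::abs(cu);
    if (viol <= cTol * std::max(1.0, unorm)) break;
    ymult += rho * cu;
    if (viol > 0.25 * prevViol) rho *= 5.0;  // constraint not closing: stiffen
    prevViol = viol;
    Gu = G * u;  // refresh accumulated products against drift
    cu = dot(c, u);
  }
  return Rcpp::List::create(Rcpp::Named("u") = u,
                            Rcpp::Named("ymult") = ymult);
}
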