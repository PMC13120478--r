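// Hamiltonian point-system geodesic shooting (explicit Euler) and its
// exact reverse-mode adjoint, with Gaussian kernel K_ij =
// exp(-|x_i-x_j|^2/sigma^2). The R interface uses n x 3 states; internally
// everything is kept transposed (3 x n) so one point's coordinates are
// contiguous.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// velocities v = K(x) p ; momentum force g_i = c sum_j K_ij (p_i.p_j)(x_i-x_j)
// all arguments 3 x n
static void rhs_T(const arma::mat& x, const arma::mat& p, double sigma2,
                  arma::mat& v, arma::mat& g) {
  const arma::uword n = x.n_cols;
  const double cc = 2.0 / sigma2;
  v = p;  // diagonal K_ii = 1
  g.zeros(3, n);
  for (arma::uword i = 0; i < n; ++i) {
    const double xi0 = x(0, i), xi1 = x(1, i), xi2 = x(2, i);
    const double pi0 = p(0, i), pi1 = p(1, i), pi2 = p(2, i);
    for (arma::uword j = i + 1; j < n; ++j) {
      const double dx = xi0 - x(0, j), dy = xi1 - x(1, j), dz = xi2 - x(2, j);
      const double K = std::exp(-(dx * dx + dy * dy + dz * dz) / sigma2);
      v(0, i) += K * p(0, j); v(1, i) += K * p(1, j); v(2, i) += K * p(2, j);
      v(0, j) += K * pi0;     v(1, j) += K * pi1;     v(2, j) += K * pi2;
      const double s = pi0 * p(0, j) + pi1 * p(1, j) + pi2 * p(2, j);
      const double w = cc * K * s;
      g(0, i) += w * dx; g(1, i) += w * dy; g(2, i) += w * dz;
      g(0, j) -= w * dx; g(1, j) -= w * dy; g(2, j) -= w * dz;
    }
  }
}

// [[Rcpp::export]]
List cpp_shoot(const arma::mat& x0, const arma::mat& p0, double sigma2,
               int steps) {
  const double h = 1.0 / steps;
  arma::mat x = x0.t(), p = p0.t(), v, g;
  arma::cube tx(3, x.n_cols, steps), tp(3, x.n_cols, steps);
  for (int t = 0; t < steps; ++t) {
    tx.slice(t) = x; tp.slice(t) = p;
    rhs_T(x, p, sigma2, v, g);
    x += h * v;
    p += h * g;
  }
  return List::create(_["x"] = x.t(), _["p"] = p.t(),
                      _["tx"] = tx, _["tp"] = tp);
}

// Reverse sweep: given d(loss)/d(x_final), returns gradients with respect
// to the initial momenta and positions. Trajectories are 3 x n x steps as
// produced by cpp_shoot.
// [[Rcpp::export]]
List cpp_shoot_pullback(const arma::cube& tx, const arma::cube& tp,
                        const arma::mat& gx_final, double sigma2) {
  const int steps = tx.n_slices;
  const arma::uword n = tx.n_cols;
  const double h = 1.0 / steps;
  const double cc = 2.0 / sigma2;
  arma::mat A = gx_final.t();             // adjoint of x (3 x n)
  arma::mat B(3, n, arma::fill::zeros);   // adjoint of p
  arma::mat dvdp(3, n), dvdx(3, n), dgdp(3, n), dgdx(3, n);
  for (int t = steps - 1; t >= 0; --t) {
    const arma::mat& x = tx.slice(t);
    const arma::mat& p = tp.slice(t);
    dvdp = A;  // diagonal K_ii = 1
    dvdx.zeros(); dgdp.zeros(); dgdx.zeros();
    for (arma::uword i = 0; i < n; ++i) {
      const double xi0 = x(0, i), xi1 = x(1, i), xi2 = x(2, i);
      const double pi0 = p(0, i), pi1 = p(1, i), pi2 = p(2, i);
      const double Ai0 = A(0, i), Ai1 = A(1, i), Ai2 = A(2, i);
      const double Bi0 = B(0, i), Bi1 = B(1, i), Bi2 = B(2, i);
      for (arma::uword j = i + 1; j < n; ++j) {
        const double dxx = xi0 - x(0, j), dxy = xi1 - x(1, j),
                     dxz = xi2 - x(2, j);
        const double K = std::exp(-(dxx * dxx + dxy * dxy + dxz * dxz) /
                                  sigma2);
        // (dv/dp)' A
        dvdp(0, i) += K * A(0, j); dvdp(1, i) += K * A(1, j);
        dvdp(2, i) += K * A(2, j);
        dvdp(0, j) += K * Ai0; dvdp(1, j) += K * Ai1; dvdp(2, j) += K * Ai2;
        // (dv/dx)' A : contribution +- c K [(A_j.p_i)+(A_i.p_j)] (x_j-x_i)
        const double S1 =
          A(0, j) * pi0 + A(1, j) * pi1 + A(2, j) * pi2 +
          Ai0 * p(0, j) + Ai1 * p(1, j) + Ai2 * p(2, j);
        const double w1 = cc * K * S1;
        dvdx(0, i) -= w1 * dxx; dvdx(1, i) -= w1 * dxy; dvdx(2, i) -= w1 * dxz;
        dvdx(0, j) += w1 * dxx; dvdx(1, j) += w1 * dxy; dvdx(2, j) += w1 * dxz;
        // E = (B_i - B_j).(x_i - x_j) (symmetric in i, j)
        const double Eb0 = Bi0 - B(0, j), Eb1 = Bi1 - B(1, j),
                     Eb2 = Bi2 - B(2, j);
        const double E = Eb0 * dxx + Eb1 * dxy + Eb2 * dxz;
        // (dg/dp)' B
        const double w2 = cc * K * E;
        dgdp(0, i) += w2 * p(0, j); dgdp(1, i) += w2 * p(1, j);
        dgdp(2, i) += w2 * p(2, j);
        dgdp(0, j) += w2 * pi0; dgdp(1, j) += w2 * pi1; dgdp(2, j) += w2 * pi2;
        // (dg/dx)' B
        const double s = pi0 * p(0, j) + pi1 * p(1, j) + pi2 * p(2, j);
        const double w3 = cc * K * s;
        const double w4 = cc * w3 * E;
        const double t0 = w3 * Eb0 - w4 * dxx;
        const double t1 = w3 * Eb1 - w4 * dxy;
        const double t2 = w3 * Eb2 - w4 * dxz;
        dgdx(0, i) += t0; dgdx(1, i) += t1; dgdx(2, i) += t2;
        dgdx(0, j) -= t0; dgdx(1, j) -= t1; dgdx(2, j) -= t2;
      }
    }
    A += h * (dvdx + dgdx);
    B += h * (dvdp + dgdp);
  }
  return List::create(_["gp"] = B.t(), _["gx"] = A.t());
}

// Forward shoot that also returns the per-step kernel matrices, so the
// reverse sweep can reuse them without recomputing exponentials.
// [[Rcpp::export]]
List cpp_shoot_cache(const arma::mat& x0, const arma::mat& p0,
                     double sigma2, int steps) {
  const arma::uword n = x0.n_rows;
  const double h = 1.0 / steps;
  const double cc = 2.0 / sigma2;
  arma::mat x = x0.t(), p = p0.t(), v, g;
  arma::cube tx(3, n, steps), tp(3, n, steps);
  arma::cube Ks(n, n, steps);
  for (int t = 0; t < steps; ++t) {
    tx.slice(t) = x; tp.slice(t) = p;
    arma::mat& K = Ks.slice(t);
    v = p; g.zeros(3, n);
    for (arma::uword i = 0; i < n; ++i) {
      K(i, i) = 1.0;
      const double xi0 = x(0, i), xi1 = x(1, i), xi2 = x(2, i);
      const double pi0 = p(0, i), pi1 = p(1, i), pi2 = p(2, i);
      for (arma::uword j = i + 1; j < n; ++j) {
        const double dx = xi0 - x(0, j), dy = xi1 - x(1, j),
                     dz = xi2 - x(2, j);
        const double Kij = std::exp(-(dx * dx + dy * dy + dz * dz) / sigma2);
        K(i, j) = Kij; K(j, i) = Kij;
        v(0, i) += Kij * p(0, j); v(1, i) += Kij * p(1, j);
        v(2, i) += Kij * p(2, j);
        v(0, j) += Kij * pi0; v(1, j) += Kij * pi1; v(2, j) += Kij * pi2;
        const double s = pi0 * p(0, j) + pi1 * p(1, j) + pi2 * p(2, j);
        const double w = cc * Kij * s;
        g(0, i) += w * dx; g(1, i) += w * dy; g(2, i) += w * dz;
        g(0, j) -= w * dx; g(1, j) -= w * dy; g(2, j) -= w * dz;
      }
    }
    x += h * v;
    p += h * g;
  }
  return List::create(_["x"] = x.t(), _["tx"] = tx, _["tp"] = tp,
                      _["Ks"] = Ks);
}

// Reverse sweep reusing cached kernel matrices from cpp_shoot_cache.
// Full (non-symmetric) traversal with register-local accumulation: each
// point's adjoint contributions are summed in scalars, avoiding scattered
// writes; the kernel matrix is symmetric and already cached.
// [[Rcpp::export]]
List cpp_shoot_reverse(const arma::cube& tx, const arma::cube& tp,
                       const arma::cube& Ks, const arma::mat& gx_final,
                       double sigma2) {
  const int steps = tx.n_slices;
  const arma::uword n = tx.n_cols;
  const double h = 1.0 / steps;
  const double cc = 2.0 / sigma2;
  arma::mat A = gx_final.t();
  arma::mat B(3, n, arma::fill::zeros);
  arma::mat A_new(3, n), B_new(3, n);
  for (int t = steps - 1; t >= 0; --t) {
    const arma::mat& xs = tx.slice(t);
    const arma::mat& ps = tp.slice(t);
    const arma::mat& K = Ks.slice(t);
    for (arma::uword i = 0; i < n; ++i) {
      const double xi0 = xs(0, i), xi1 = xs(1, i), xi2 = xs(2, i);
      const double pi0 = ps(0, i), pi1 = ps(1, i), pi2 = ps(2, i);
      const double Ai0 = A(0, i), Ai1 = A(1, i), Ai2 = A(2, i);
      const double Bi0 = B(0, i), Bi1 = B(1, i), Bi2 = B(2, i);
      // diagonal: K_ii = 1 contributes A_i to (dv/dp)'A only
      double dp0 = Ai0, dp1 = Ai1, dp2 = Ai2;          // dvdp + dgdp
      double dx0 = 0, dx1 = 0, dx2 = 0;                // dvdx + dgdx
      const double* Kcol = K.colptr(i);
      for (arma::uword j = 0; j < n; ++j) {
        if (j == i) continue;
        const double Kij = Kcol[j];
        const double dxx = xi0 - xs(0, j), dxy = xi1 - xs(1, j),
                     dxz = xi2 - xs(2, j);
        // (dv/dp)' A
        dp0 += Kij * A(0, j); dp1 += Kij * A(1, j); dp2 += Kij * A(2, j);
        // (dv/dx)' A
        const double S1 =
          A(0, j) * pi0 + A(1, j) * pi1 + A(2, j) * pi2 +
          Ai0 * ps(0, j) + Ai1 * ps(1, j) + Ai2 * ps(2, j);
        const double w1 = cc * Kij * S1;
        dx0 -= w1 * dxx; dx1 -= w1 * dxy; dx2 -= w1 * dxz;
        // E = (B_i - B_j).(x_i - x_j)
        const double Eb0 = Bi0 - B(0, j), Eb1 = Bi1 - B(1, j),
                     Eb2 = Bi2 - B(2, j);
        const double E = Eb0 * dxx + Eb1 * dxy + Eb2 * dxz;
        // (dg/dp)' B
        const double w2 = cc * Kij * E;
        dp0 += w2 * ps(0, j); dp1 += w2 * ps(1, j); dp2 += w2 * ps(2, j);
        // (dg/dx)' B
        const double sdot = pi0 * ps(0, j) + pi1 * ps(1, j) + pi2 * ps(2, j);
        const double w3 = cc * Kij * sdot;
        const double w4 = cc * w3 * E;
        dx0 += w3 * Eb0 - w4 * dxx;
        dx1 += w3 * Eb1 - w4 * dxy;
        dx2 += w3 * Eb2 - w4 * dxz;
      }
      A_new(0, i) = Ai0 + h * dx0;
      A_new(1, i) = Ai1 + h * dx1;
      A_new(2, i) = Ai2 + h * dx2;
      B_new(0, i) = Bi0 + h * dp0;
      B_new(1, i) = Bi1 + h * dp1;
      B_new(2, i) = Bi2 + h * dp2;
    }
    A = A_new; B = B_new;
  }
  return List::create(_["gp"] = B.t(), _["gx"] = A.t());
}
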