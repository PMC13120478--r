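// Fused kernels for the functional-varifold inner products and their
// face-level gradients. Row layout: one face per row; Ca/Cb are centroids,
// Na/Nb unnormalized normals (cross products), nla/nlb their lengths,
// fa/fb mean face signals. Pair weight:
//   G = exp(-|Cf-Cg|^2/sW2) * (Nf.Ng)^2 / (4 |Nf||Ng|) * exp(-(fa-fb)^2/ssig2)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// sum of G over all pairs
// [[Rcpp::export]]
double cpp_inner_value(const arma::mat& Ca, const arma::mat& Na,
                       const arma::vec& nla, const arma::vec& fa,
                       const arma::mat& Cb, const arma::mat& Nb,
                       const arma::vec& nlb, const arma::vec& fb,
                       double sW2, double ssig2) {
  const arma::mat CaT = Ca.t();
  const arma::mat NaT = Na.t();
  const arma::mat CbT = Cb.t();
  const arma::mat NbT = Nb.t();

  const arma::uword ma = Ca.n_rows, mb = Cb.n_rows;
  double total = 0.0;
  for (arma::uword i = 0; i < ma; ++i) {
    const double cax = CaT(0, i), cay = CaT(1, i), caz = CaT(2, i);
    const double nax = NaT(0, i), nay = NaT(1, i), naz = NaT(2, i);
    const double fi = fa(i), nli = nla(i);
    double row = 0.0;
    for (arma::uword j = 0; j < mb; ++j) {
      const double dx = cax - CbT(0, j), dy = cay - CbT(1, j),
                   dz = caz - CbT(2, j);
      const double dot = nax * NbT(0, j) + nay * NbT(1, j) + naz * NbT(2, j);
      const double df = fi - fb(j);
      row += std::exp(-(dx * dx + dy * dy + dz * dz) / sW2 -
                      df * df / ssig2) *
             dot * dot / (4.0 * nli * nlb(j));
    }
    total += row;
  }
  return total;
}

// geometry-only kernel matrix GK (position x squared-cos x areas)
// [[Rcpp::export]]
arma::mat cpp_geom_block(const arma::mat& Ca, const arma::mat& Na,
                         const arma::vec& nla,
                         const arma::mat& Cb, const arma::mat& Nb,
                         const arma::vec& nlb, double sW2) {
  const arma::mat CaT = Ca.t();
  const arma::mat NaT = Na.t();
  const arma::mat CbT = Cb.t();
  const arma::mat NbT = Nb.t();

  const arma::uword ma = Ca.n_rows, mb = Cb.n_rows;
  arma::mat GK(ma, mb);
  for (arma::uword j = 0; j < mb; ++j) {
    const double cbx = CbT(0, j), cby = CbT(1, j), cbz = CbT(2, j);
    const double nbx = NbT(0, j), nby = NbT(1, j), nbz = NbT(2, j);
    const double nlj = nlb(j);
    for (arma::uword i = 0; i < ma; ++i) {
      const double dx = CaT(0, i) - cbx, dy = CaT(1, i) - cby,
                   dz = CaT(2, i) - cbz;
      const double dot = NaT(0, i) * nbx + NaT(1, i) * nby + NaT(2, i) * nbz;
      GK(i, j) = std::exp(-(dx * dx + dy * dy + dz * dz) / sW2) *
                 dot * dot / (4.0 * nla(i) * nlj);
    }
  }
  return GK;
}

// signal kernel matrix exp(-(fa_i - fb_j)^2 / ssig2)
// [[Rcpp::export]]
arma::mat cpp_sig_block(const arma::vec& fa, const arma::vec& fb,
                        double ssig2) {
  const arma::uword ma = fa.n_elem, mb = fb.n_elem;
  arma::mat S(ma, mb);
  for (arma::uword j = 0; j < mb; ++j) {
    const double fj = fb(j);
    for (arma::uword i = 0; i < ma; ++i) {
      const double df = fa(i) - fj;
      S(i, j) = std::exp(-df * df / ssig2);
    }
  }
  return S;
}

// sum(GK * sig_kernel(fa, fb)) with GK precomputed (signal-only trials)
// [[Rcpp::export]]
double cpp_sum_gk_sig(const arma::mat& GK, const arma::vec& fa,
                      const arma::vec& fb, double ssig2) {
  const arma::uword ma = GK.n_rows, mb = GK.n_cols;
  double total = 0.0;
  for (arma::uword j = 0; j < mb; ++j) {
    const double fj = fb(j);
    double col = 0.0;
    for (arma::uword i = 0; i < ma; ++i) {
      const double df = fa(i) - fj;
      col += GK(i, j) * std::exp(-df * df / ssig2);
    }
    total += col;
  }
  return total;
}

// sum(geom_kernel * S) with S precomputed (geometry-only trials)
// [[Rcpp::export]]
double cpp_sum_geom_sig(const arma::mat& Ca, const arma::mat& Na,
                        const arma::vec& nla,
                        const arma::mat& Cb, const arma::mat& Nb,
                        const arma::vec& nlb,
                        const arma::mat& S, double sW2) {
  const arma::mat CaT = Ca.t();
  const arma::mat NaT = Na.t();
  const arma::mat CbT = Cb.t();
  const arma::mat NbT = Nb.t();

  const arma::uword ma = Ca.n_rows, mb = Cb.n_rows;
  double total = 0.0;
  for (arma::uword j = 0; j < mb; ++j) {
    const double cbx = CbT(0, j), cby = CbT(1, j), cbz = CbT(2, j);
    const double nbx = NbT(0, j), nby = NbT(1, j), nbz = NbT(2, j);
    const double nlj = nlb(j);
    double col = 0.0;
    for (arma::uword i = 0; i < ma; ++i) {
      const double dx = CaT(0, i) - cbx, dy = CaT(1, i) - cby,
                   dz = CaT(2, i) - cbz;
      const double dot = NaT(0, i) * nbx + NaT(1, i) * nby + NaT(2, i) * nbz;
      col += S(i, j) * std::exp(-(dx * dx + dy * dy + dz * dz) / sW2) *
             dot * dot / (4.0 * nla(i) * nlj);
    }
    total += col;
  }
  return total;
}

// value and first-slot gradients of <a, b> with respect to a's face
// centroids, normals and mean signals
// [[Rcpp::export]]
List cpp_block_grad(const arma::mat& Ca, const arma::mat& Na,
                    const arma::vec& nla, const arma::vec& fa,
                    const arma::mat& Cb, const arma::mat& Nb,
                    const arma::vec& nlb, const arma::vec& fb,
                    double sW2, double ssig2) {
  const arma::mat CaT = Ca.t();
  const arma::mat NaT = Na.t();
  const arma::mat CbT = Cb.t();
  const arma::mat NbT = Nb.t();

  const arma::uword ma = Ca.n_rows, mb = Cb.n_rows;
  arma::mat gC(ma, 3, arma::fill::zeros);
  arma::mat gN(ma, 3, arma::fill::zeros);
  arma::vec gfb(ma, arma::fill::zeros);
  double total = 0.0;
  for (arma::uword i = 0; i < ma; ++i) {
    const double cax = CaT(0, i), cay = CaT(1, i), caz = CaT(2, i);
    const double nax = NaT(0, i), nay = NaT(1, i), naz = NaT(2, i);
    const double fi = fa(i), nli = nla(i);
    double sgc0 = 0, sgc1 = 0, sgc2 = 0, sgf = 0;
    double sgn0 = 0, sgn1 = 0, sgn2 = 0, scoef = 0, sval = 0;
    for (arma::uword j = 0; j < mb; ++j) {
      const double dx = cax - CbT(0, j), dy = cay - CbT(1, j),
                   dz = caz - CbT(2, j);
      const double nbx = NbT(0, j), nby = NbT(1, j), nbz = NbT(2, j);
      const double dot = nax * nbx + nay * nby + naz * nbz;
      const double df = fi - fb(j);
      const double nlj = nlb(j);
      const double PS = std::exp(-(dx * dx + dy * dy + dz * dz) / sW2 -
                                 df * df / ssig2);
      const double G = PS * dot * dot / (4.0 * nli * nlj);
      sval += G;
      sgc0 += G * dx; sgc1 += G * dy; sgc2 += G * dz;
      sgf += G * df;
      const double w1 = PS * dot / (2.0 * nli * nlj);
      sgn0 += w1 * nbx; sgn1 += w1 * nby; sgn2 += w1 * nbz;
      scoef += PS * dot * dot / (4.0 * nli * nli * nli * nlj);
    }
    total += sval;
    gC(i, 0) = (-2.0 / sW2) * sgc0;
    gC(i, 1) = (-2.0 / sW2) * sgc1;
    gC(i, 2) = (-2.0 / sW2) * sgc2;
    gfb(i) = (-2.0 / ssig2) * sgf;
    gN(i, 0) = sgn0 - scoef * nax;
    gN(i, 1) = sgn1 - scoef * nay;
    gN(i, 2) = sgn2 - scoef * naz;
  }
  return List::create(_["value"] = total, _["gC"] = gC, _["gN"] = gN,
                      _["gfb"] = gfb);
}

// ---- symmetric (self-block) variants: a against itself ------------------

// [[Rcpp::export]]
double cpp_inner_value_sym(const arma::mat& Ca, const arma::mat& Na,
                           const arma::vec& nla, const arma::vec& fa,
                           double sW2, double ssig2) {
  const arma::mat CaT = Ca.t();
  const arma::mat NaT = Na.t();

  const arma::uword m = Ca.n_rows;
  double total = 0.0;
  for (arma::uword i = 0; i < m; ++i) {
    total += nla(i) * nla(i) / 4.0;  // diagonal: G_ii = area_i^2
    const double cax = CaT(0, i), cay = CaT(1, i), caz = CaT(2, i);
    const double nax = NaT(0, i), nay = NaT(1, i), naz = NaT(2, i);
    const double fi = fa(i), nli = nla(i);
    double row = 0.0;
    for (arma::uword j = i + 1; j < m; ++j) {
      const double dx = cax - CaT(0, j), dy = cay - CaT(1, j),
                   dz = caz - CaT(2, j);
      const double dot = nax * NaT(0, j) + nay * NaT(1, j) + naz * NaT(2, j);
      const double df = fi - fa(j);
      row += std::exp(-(dx * dx + dy * dy + dz * dz) / sW2 -
                      df * df / ssig2) *
             dot * dot / (4.0 * nli * nla(j));
    }
    total += 2.0 * row;
  }
  return total;
}

// [[Rcpp::export]]
arma::mat cpp_geom_block_sym(const arma::mat& Ca, const arma::mat& Na,
                             const arma::vec& nla, double sW2) {
  const arma::mat CaT = Ca.t();
  const arma::mat NaT = Na.t();

  const arma::uword m = Ca.n_rows;
  arma::mat GK(m, m);
  for (arma::uword i = 0; i < m; ++i) {
    GK(i, i) = nla(i) * nla(i) / 4.0;
    for (arma::uword j = i + 1; j < m; ++j) {
      const double dx = CaT(0, i) - CaT(0, j), dy = CaT(1, i) - CaT(1, j),
                   dz = CaT(2, i) - CaT(2, j);
      const double dot = NaT(0, i) * NaT(0, j) + NaT(1, i) * NaT(1, j) +
                         NaT(2, i) * NaT(2, j);
      const double v = std::exp(-(dx * dx + dy * dy + dz * dz) / sW2) *
                       dot * dot / (4.0 * nla(i) * nla(j));
      GK(i, j) = v; GK(j, i) = v;
    }
  }
  return GK;
}

// [[Rcpp::export]]
double cpp_sum_gk_sig_sym(const arma::mat& GK, const arma::vec& fa,
                          double ssig2) {
  const arma::uword m = GK.n_rows;
  double total = 0.0;
  for (arma::uword i = 0; i < m; ++i) {
    total += GK(i, i);
    const double fi = fa(i);
    double row = 0.0;
    for (arma::uword j = i + 1; j < m; ++j) {
      const double df = fi - fa(j);
      row += GK(i, j) * std::exp(-df * df / ssig2);
    }
    total += 2.0 * row;
  }
  return total;
}

// [[Rcpp::export]]
double cpp_sum_geom_sig_sym(const arma::mat& Ca, const arma::mat& Na,
                            const arma::vec& nla, const arma::mat& S,
                            double sW2) {
  const arma::mat CaT = Ca.t();
  const arma::mat NaT = Na.t();

  const arma::uword m = Ca.n_rows;
  double total = 0.0;
  for (arma::uword i = 0; i < m; ++i) {
    total += nla(i) * nla(i) / 4.0;
    const double cax = CaT(0, i), cay = CaT(1, i), caz = CaT(2, i);
    const double nax = NaT(0, i), nay = NaT(1, i), naz = NaT(2, i);
    const double nli = nla(i);
    double row = 0.0;
    for (arma::uword j = i + 1; j < m; ++j) {
      const double dx = cax - CaT(0, j), dy = cay - CaT(1, j),
                   dz = caz - CaT(2, j);
      const double dot = nax * NaT(0, j) + nay * NaT(1, j) + naz * NaT(2, j);
      row += S(i, j) * std::exp(-(dx * dx + dy * dy + dz * dz) / sW2) *
             dot * dot / (4.0 * nli * nla(j));
    }
    total += 2.0 * row;
  }
  return total;
}

// first-slot gradient of <a, a> (equal to cpp_block_grad(a, a) but at
// roughly half the cost via pair symmetry)
// [[Rcpp::export]]
List cpp_block_grad_sym(const arma::mat& Ca, const arma::mat& Na,
                        const arma::vec& nla, const arma::vec& fa,
                        double sW2, double ssig2) {
  const arma::mat CaT = Ca.t();
  const arma::mat NaT = Na.t();

  const arma::uword m = Ca.n_rows;
  arma::mat gC(m, 3, arma::fill::zeros);
  arma::mat gN(m, 3, arma::fill::zeros);
  arma::vec gfb(m, arma::fill::zeros);
  double total = 0.0;
  const double c2w = -2.0 / sW2, c2s = -2.0 / ssig2;
  for (arma::uword i = 0; i < m; ++i) {
    // diagonal pair (i, i): G = area^2; d/dN (first slot) = N/4
    total += nla(i) * nla(i) / 4.0;
    gN(i, 0) += NaT(0, i) / 4.0;
    gN(i, 1) += NaT(1, i) / 4.0;
    gN(i, 2) += NaT(2, i) / 4.0;
    const double cax = CaT(0, i), cay = CaT(1, i), caz = CaT(2, i);
    const double nax = NaT(0, i), nay = NaT(1, i), naz = NaT(2, i);
    const double fi = fa(i), nli = nla(i);
    for (arma::uword j = i + 1; j < m; ++j) {
      const double dx = cax - CaT(0, j), dy = cay - CaT(1, j),
                   dz = caz - CaT(2, j);
      const double nbx = NaT(0, j), nby = NaT(1, j), nbz = NaT(2, j);
      const double dot = nax * nbx + nay * nby + naz * nbz;
      const double df = fi - fa(j);
      const double nlj = nla(j);
      const double PS = std::exp(-(dx * dx + dy * dy + dz * dz) / sW2 -
                                 df * df / ssig2);
      const double G = PS * dot * dot / (4.0 * nli * nlj);
      total += 2.0 * G;
      // centroid / signal: first-slot grads of (i,j) and (j,i)
      gC(i, 0) += c2w * G * dx; gC(i, 1) += c2w * G * dy;
      gC(i, 2) += c2w * G * dz;
      gC(j, 0) -= c2w * G * dx; gC(j, 1) -= c2w * G * dy;
      gC(j, 2) -= c2w * G * dz;
      gfb(i) += c2s * G * df;
      gfb(j) -= c2s * G * df;
      // normals: first-slot grad of (i,j) on i, of (j,i) on j
      const double w1 = PS * dot / (2.0 * nli * nlj);
      const double coef_i = PS * dot * dot / (4.0 * nli * nli * nli * nlj);
      const double coef_j = PS * dot * dot / (4.0 * nlj * nlj * nlj * nli);
      gN(i, 0) += w1 * nbx - coef_i * nax;
      gN(i, 1) += w1 * nby - coef_i * nay;
      gN(i, 2) += w1 * nbz - coef_i * naz;
      gN(j, 0) += w1 * nax - coef_j * nbx;
      gN(j, 1) += w1 * nay - coef_j * nby;
      gN(j, 2) += w1 * naz - coef_j * nbz;
    }
  }
  return List::create(_["value"] = total, _["gC"] = gC, _["gN"] = gN,
                      _["gfb"] = gfb);
}

// first-slot signal gradient of <a, a> from a cached symmetric geometry
// kernel: gfb_i = (-2/ssig2) * sum_j GK_ij exp(-(fa_i-fa_j)^2/ssig2) (fa_i-fa_j)
// [[Rcpp::export]]
arma::vec cpp_sig_grad_sym(const arma::mat& GK, const arma::vec& fa,
                           double ssig2) {
  const arma::uword m = GK.n_rows;
  arma::vec gfb(m, arma::fill::zeros);
  const double c2s = -2.0 / ssig2;
  for (arma::uword i = 0; i < m; ++i) {
    const double fi = fa(i);
    for (arma::uword j = i + 1; j < m; ++j) {
      const double df = fi - fa(j);
      const double w = c2s * GK(i, j) * std::exp(-df * df / ssig2) * df;
      gfb(i) += w;
      gfb(j) -= w;
    }
  }
  return gfb;
}

// first-slot signal gradient of <a, b> from a cached geometry kernel
// [[Rcpp::export]]
arma::vec cpp_sig_grad(const arma::mat& GK, const arma::vec& fa,
                       const arma::vec& fb, double ssig2) {
  const arma::uword ma = GK.n_rows, mb = GK.n_cols;
  arma::vec gfb(ma, arma::fill::zeros);
  const double c2s = -2.0 / ssig2;
  for (arma::uword j = 0; j < mb; ++j) {
    const double fj = fb(j);
    for (arma::uword i = 0; i < ma; ++i) {
      const double df = fa(i) - fj;
      gfb(i) += c2s * GK(i, j) * std::exp(-df * df / ssig2) * df;
    }
  }
  return gfb;
}
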