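// P1 tetrahedral finite-element kernels: neo-Hookean mechanics assembly and
// scalar transport operators. Node dof ordering for mechanics is
// (node1_x, node1_y, node1_z, node2_x, ...).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// shape-function gradients (3x4) and signed volume of a tetrahedron
static inline bool tet_grads(const arma::mat& X, arma::mat& g, double& vol) {
  arma::mat J(3, 3);
  for (int a = 0; a < 3; ++a) J.col(a) = X.col(a + 1) - X.col(0);
  double detJ = arma::det(J);
  vol = detJ / 6.0;
  if (vol <= 0.0) return false;
  arma::mat Jinv = arma::inv(J);
  for (int a = 0; a < 3; ++a) g.col(a + 1) = Jinv.row(a).t();
  g.col(0) = -(g.col(1) + g.col(2) + g.col(3));
  return true;
}

// [[Rcpp::export(name = ".fem_geometry")]]
List fem_geometry(const arma::mat& nodes, const arma::imat& tets) {
  const int m = tets.n_rows;
  arma::vec vols(m);
  arma::cube grads(3, 4, m);
  for (int e = 0; e < m; ++e) {
    arma::mat X(3, 4), g(3, 4);
    for (int a = 0; a < 4; ++a) X.col(a) = nodes.row(tets(e, a) - 1).t();
    double vol;
    if (!tet_grads(X, g, vol))
      stop("element %d has non-positive volume", e + 1);
    vols(e) = vol;
    grads.slice(e) = g;
  }
  return List::create(_["vol"] = vols, _["grads"] = grads);
}

// First Piola-Kirchhoff stress of the grown neo-Hookean solid plus the
// interstitial-pressure contribution -p J F^{-T}; also reports the Cauchy
// solid stress. lam are the diagonal growth stretches (Fg = diag(lam)).
static bool piola(const arma::mat& F, double G, double k,
                  const arma::vec& lam, double p, bool isochoric,
                  arma::mat& P, arma::mat* sigma, double* Jout, double* Jeout) {
  double J = arma::det(F);
  if (J <= 0.0 || !std::isfinite(J)) return false;
  arma::mat Fe = F;
  Fe.col(0) /= lam(0); Fe.col(1) /= lam(1); Fe.col(2) /= lam(2);
  double Je = arma::det(Fe);
  if (Je <= 0.0) return false;
  arma::mat FeinvT = arma::inv(Fe).t();
  arma::mat dWdFe;
  if (isochoric) {
    double I1 = arma::accu(Fe % Fe);
    double Jm23 = std::pow(Je, -2.0 / 3.0);
    dWdFe = G * Jm23 * (Fe - (I1 / 3.0) * FeinvT) + k * (Je - 1.0) * Je * FeinvT;
  } else {
    dWdFe = G * Fe + k * (Je - 1.0) * Je * FeinvT;
  }
  double Jg = lam(0) * lam(1) * lam(2);
  P = Jg * dWdFe;
  P.col(0) /= lam(0); P.col(1) /= lam(1); P.col(2) /= lam(2);
  if (p != 0.0) P -= p * J * arma::inv(F).t();
  if (sigma) *sigma = (dWdFe * Fe.t()) / Je;
  if (Jout) *Jout = J;
  if (Jeout) *Jeout = Je;
  return true;
}

static bool elem_force(const arma::mat& g, double vol, const arma::mat& ue,
                       double G, double k, const arma::vec& lam, double p,
                       bool isochoric, arma::vec& f,
                       arma::mat* sigma, double* Jout, double* Jeout) {
  arma::mat F = arma::eye(3, 3) + ue * g.t();
  arma::mat P;
  if (!piola(F, G, k, lam, p, isochoric, P, sigma, Jout, Jeout)) return false;
  arma::mat fn = vol * (P * g);   // 3x4 nodal internal forces
  f = arma::vectorise(fn);
  return true;
}

// Assemble internal-force residual, element Cauchy stresses and (optionally)
// the consistent tangent by central finite differences on the 12 element dofs.
// p_node: nodal interstitial pressure (may be zero length).
// [[Rcpp::export(name = ".mech_assemble")]]
List mech_assemble(const arma::mat& nodes, const arma::imat& tets,
                   const arma::cube& grads, const arma::vec& vols,
                   const arma::mat& u, const arma::vec& Gel,
                   const arma::vec& kel, const arma::mat& lam,
                   const arma::vec& p_node, bool isochoric,
                   bool want_tangent) {
  const int m = tets.n_rows, n = nodes.n_rows;
  arma::vec resid(3 * n, arma::fill::zeros);
  arma::mat sig(m, 6);
  arma::vec Jv(m), Jev(m);
  std::vector<int> Ti, Tj;
  std::vector<double> Tx;
  if (want_tangent) { Ti.reserve(m * 144); Tj.reserve(m * 144); Tx.reserve(m * 144); }
  for (int e = 0; e < m; ++e) {
    arma::mat ue(3, 4);
    double pbar = 0.0;
    for (int a = 0; a < 4; ++a) {
      ue.col(a) = u.row(tets(e, a) - 1).t();
      if (p_node.n_elem) pbar += 0.25 * p_node(tets(e, a) - 1);
    }
    arma::vec lam_e = lam.row(e).t();
    arma::vec f(12);
    arma::mat sigma;
    double J, Je;
    if (!elem_force(grads.slice(e), vols(e), ue, Gel(e), kel(e), lam_e, pbar,
                    isochoric, f, &sigma, &J, &Je))
      return List::create(_["ok"] = false, _["bad_element"] = e + 1);
    sig(e, 0) = sigma(0, 0); sig(e, 1) = sigma(1, 0); sig(e, 2) = sigma(1, 1);
    sig(e, 3) = sigma(2, 0); sig(e, 4) = sigma(2, 1); sig(e, 5) = sigma(2, 2);
    Jv(e) = J; Jev(e) = Je;
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c)
        resid(3 * (tets(e, a) - 1) + c) += f(3 * a + c);
    if (want_tangent) {
      double h = 1e-6 * std::cbrt(6.0 * vols(e));
      arma::mat Ke(12, 12);
      arma::vec fp(12), fm(12);
      for (int d = 0; d < 12; ++d) {
        arma::mat up = ue, um = ue;
        up(d % 3, d / 3) += h;
        um(d % 3, d / 3) -= h;
        bool okp = elem_force(grads.slice(e), vols(e), up, Gel(e), kel(e),
                              lam_e, pbar, isochoric, fp, nullptr, nullptr, nullptr);
        bool okm = elem_force(grads.slice(e), vols(e), um, Gel(e), kel(e),
                              lam_e, pbar, isochoric, fm, nullptr, nullptr, nullptr);
        if (okp && okm) {
          Ke.col(d) = (fp - fm) / (2.0 * h);
        } else if (okp) {
          Ke.col(d) = (fp - f) / h;
        } else if (okm) {
          Ke.col(d) = (f - fm) / h;
        } else {
          return List::create(_["ok"] = false, _["bad_element"] = e + 1);
        }
      }
      for (int a = 0; a < 12; ++a) {
        int gi = 3 * (tets(e, a / 3) - 1) + a % 3;
        for (int b = 0; b < 12; ++b) {
          int gj = 3 * (tets(e, b / 3) - 1) + b % 3;
          Ti.push_back(gi + 1);
          Tj.push_back(gj + 1);
          Tx.push_back(Ke(a, b));
        }
      }
    }
  }
  List out = List::create(_["ok"] = true, _["resid"] = resid,
                          _["sigma"] = sig, _["J"] = Jv, _["Je"] = Jev);
  if (want_tangent) {
    out["Ti"] = IntegerVector(Ti.begin(), Ti.end());
    out["Tj"] = IntegerVector(Tj.begin(), Tj.end());
    out["Tx"] = NumericVector(Tx.begin(), Tx.end());
  }
  return out;
}

// residual only (for line searches)
// [[Rcpp::export(name = ".mech_residual")]]
List mech_residual(const arma::mat& nodes, const arma::imat& tets,
                   const arma::cube& grads, const arma::vec& vols,
                   const arma::mat& u, const arma::vec& Gel,
                   const arma::vec& kel, const arma::mat& lam,
                   const arma::vec& p_node, bool isochoric) {
  const int m = tets.n_rows, n = nodes.n_rows;
  arma::vec resid(3 * n, arma::fill::zeros);
  for (int e = 0; e < m; ++e) {
    arma::mat ue(3, 4);
    double pbar = 0.0;
    for (int a = 0; a < 4; ++a) {
      ue.col(a) = u.row(tets(e, a) - 1).t();
      if (p_node.n_elem) pbar += 0.25 * p_node(tets(e, a) - 1);
    }
    arma::vec f(12);
    if (!elem_force(grads.slice(e), vols(e), ue, Gel(e), kel(e),
                    lam.row(e).t(), pbar, isochoric, f, nullptr, nullptr, nullptr))
      return List::create(_["ok"] = false, _["bad_element"] = e + 1);
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c)
        resid(3 * (tets(e, a) - 1) + c) += f(3 * a + c);
  }
  return List::create(_["ok"] = true, _["resid"] = resid);
}

// Stiffness triplets for the anisotropic diffusion operator
// K_ij = int grad(phi_i) . D grad(phi_j); D per element as 6-vector in
// lower-triangular order (xx, yx, yy, zx, zy, zz), or a single column for
// isotropic coefficients.
// [[Rcpp::export(name = ".scalar_stiffness")]]
List scalar_stiffness(const arma::imat& tets, const arma::cube& grads,
                      const arma::vec& vols, const arma::mat& D) {
  const int m = tets.n_rows;
  bool iso = (D.n_cols == 1);
  IntegerVector Ti(m * 16), Tj(m * 16);
  NumericVector Tx(m * 16);
  int idx = 0;
  for (int e = 0; e < m; ++e) {
    arma::mat Dm(3, 3);
    if (iso) {
      Dm = D(e, 0) * arma::eye(3, 3);
    } else {
      Dm(0, 0) = D(e, 0); Dm(1, 0) = Dm(0, 1) = D(e, 1); Dm(1, 1) = D(e, 2);
      Dm(2, 0) = Dm(0, 2) = D(e, 3); Dm(2, 1) = Dm(1, 2) = D(e, 4); Dm(2, 2) = D(e, 5);
    }
    const arma::mat& g = grads.slice(e);
    arma::mat Ke = vols(e) * (g.t() * Dm * g);
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        Ti[idx] = tets(e, a); Tj[idx] = tets(e, b); Tx[idx] = Ke(a, b); ++idx;
      }
  }
  return List::create(_["i"] = Ti, _["j"] = Tj, _["x"] = Tx);
}

// lumped mass vector: row sums of the consistent P1 mass matrix
// [[Rcpp::export(name = ".lumped_mass")]]
arma::vec lumped_mass(int n, const arma::imat& tets, const arma::vec& vols) {
  arma::vec mlump(n, arma::fill::zeros);
  for (arma::uword e = 0; e < tets.n_rows; ++e)
    for (int a = 0; a < 4; ++a)
      mlump(tets(e, a) - 1) += vols(e) / 4.0;
  return mlump;
}

// Convection triplets C_ij = int (grad(phi_i) . v) phi_j dV, v per element.
// Weak (integrated-by-parts) form of -div(c v) with zero boundary flux;
// column sums vanish so the scheme conserves mass exactly.
// [[Rcpp::export(name = ".convection_matrix")]]
List convection_matrix(const arma::imat& tets, const arma::cube& grads,
                       const arma::vec& vols, const arma::mat& v) {
  const int m = tets.n_rows;
  IntegerVector Ti(m * 16), Tj(m * 16);
  NumericVector Tx(m * 16);
  int idx = 0;
  for (int e = 0; e < m; ++e) {
    const arma::mat& g = grads.slice(e);
    arma::vec ve = v.row(e).t();
    for (int a = 0; a < 4; ++a) {
      double gv = arma::dot(g.col(a), ve) * vols(e) / 4.0;
      for (int b = 0; b < 4; ++b) {
        Ti[idx] = tets(e, a); Tj[idx] = tets(e, b); Tx[idx] = gv; ++idx;
      }
    }
  }
  return List::create(_["i"] = Ti, _["j"] = Tj, _["x"] = Tx);
}

// per-element gradient of a nodal scalar field
// [[Rcpp::export(name = ".elem_gradient")]]
arma::mat elem_gradient(const arma::imat& tets, const arma::cube& grads,
                        const arma::vec& f) {
  const int m = tets.n_rows;
  arma::mat gf(m, 3, arma::fill::zeros);
  for (int e = 0; e < m; ++e) {
    const arma::mat& g = grads.slice(e);
    arma::vec fe(4);
    for (int a = 0; a < 4; ++a) fe(a) = f(tets(e, a) - 1);
    gf.row(e) = (g * fe).t();
  }
  return gf;
}
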