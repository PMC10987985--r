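#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Stiffness triplets for linear (4-node) tetrahedra, split into a unit
// deviatoric part (to be scaled by 2*G, possibly time-dependent) and a unit
// volumetric part (to be scaled by the bulk modulus kappa).  The split lets a
// Prony shear-relaxation law act on the deviatoric operator only while the
// bulk response stays elastic.
//
// Voigt order: (xx, yy, zz, xy, yz, zx) with engineering shear strain.
// D_iso = kappa * Jvol + 2G * (Mshear - Jvol/3),  Jvol = ones(3,3) block.
//
// nodes : n x 3 coordinates (mm)
// elems : m x 4 1-based connectivity
// scale : per-element stiffness multiplier (regional modulus scaling)
// [[Rcpp::export]]
List tet_stiffness_triplets(const arma::mat& nodes,
                            const arma::imat& elems,
                            const arma::vec& scale) {
  const arma::uword m = elems.n_rows;
  if (scale.n_elem != m) stop("scale must have one entry per element");

  arma::uvec I(144 * m), J(144 * m);
  arma::vec Vdev(144 * m), Vvol(144 * m);
  arma::vec vol(m);

  arma::mat Mshear = arma::diagmat(arma::vec({1, 1, 1, 0.5, 0.5, 0.5}));
  arma::mat Jvol(6, 6, arma::fill::zeros);
  Jvol.submat(0, 0, 2, 2).ones();
  arma::mat Ddev = Mshear - Jvol / 3.0;

  arma::uword pos = 0;
  for (arma::uword e = 0; e < m; ++e) {
    arma::uvec id(4);
    for (int a = 0; a < 4; ++a) id(a) = (arma::uword)(elems(e, a) - 1);

    arma::vec x1 = nodes.row(id(0)).t();
    arma::mat D(3, 3);
    for (int a = 0; a < 3; ++a)
      D.col(a) = nodes.row(id(a + 1)).t() - x1;

    double detD = arma::det(D);
    vol(e) = detD / 6.0;
    if (!(vol(e) > 0.0)) {
      // report 1-based element index for the caller's error message
      return List::create(_["degenerate"] = (double)(e + 1));
    }
    arma::mat Dinv = arma::inv(D);

    // shape-function gradients: rows of Dinv are grad(lambda_2..4)
    arma::mat G(4, 3);
    G.rows(1, 3) = Dinv;
    G.row(0) = -arma::sum(Dinv, 0);

    arma::mat B(6, 12, arma::fill::zeros);
    for (int a = 0; a < 4; ++a) {
      double bx = G(a, 0), by = G(a, 1), bz = G(a, 2);
      int c = 3 * a;
      B(0, c) = bx;
      B(1, c + 1) = by;
      B(2, c + 2) = bz;
      B(3, c) = by; B(3, c + 1) = bx;
      B(4, c + 1) = bz; B(4, c + 2) = by;
      B(5, c) = bz; B(5, c + 2) = bx;
    }

    double w = vol(e) * scale(e);
    arma::mat Kd = w * (B.t() * Ddev * B);
    arma::mat Kv = w * (B.t() * Jvol * B);

    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        arma::uword gi = 3 * id(a) + i;  // 0-based dof
        for (int b = 0; b < 4; ++b)
          for (int j = 0; j < 3; ++j) {
            arma::uword gj = 3 * id(b) + j;
            I(pos) = gi + 1;
            J(pos) = gj + 1;
            Vdev(pos) = Kd(3 * a + i, 3 * b + j);
            Vvol(pos) = Kv(3 * a + i, 3 * b + j);
            ++pos;
          }
      }
  }

  return List::create(_["i"] = wrap(arma::conv_to<std::vector<double>>::from(I)),
                      _["j"] = wrap(arma::conv_to<std::vector<double>>::from(J)),
                      _["dev"] = Vdev,
                      _["vol"] = Vvol,
                      _["volume"] = vol);
}
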