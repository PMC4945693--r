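// Total-Lagrangian assembly kernel for 4-node bilinear plane-stress
// quadrilaterals (St. Venant-Kirchhoff material, Green-Lagrange strain,
// 2x2 Gauss quadrature).  Units: lengths mm, moduli N/mm^2 (MPa), forces N;
// element forces scale with the out-of-plane thickness (mm).
//
// Returns the tangent stiffness as COO triplets plus the internal force
// vector, so the R side can build a sparse matrix and run Newton.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".tl_q4_assemble")]]
List tl_q4_assemble(NumericMatrix nodes, IntegerMatrix elems,
                    NumericVector u, NumericVector Evec, NumericVector nuvec,
                    double thickness, bool nlgeom = true) {
  const int ne = elems.nrow();
  const int nn = nodes.nrow();
  if ((int)u.size() != 2 * nn) stop("displacement vector has wrong length");

  const double g = 1.0 / std::sqrt(3.0);
  const double gp[4][2] = {{-g, -g}, {g, -g}, {g, g}, {-g, g}};

  std::vector<int> ti; ti.reserve(ne * 64);
  std::vector<int> tj; tj.reserve(ne * 64);
  std::vector<double> tx; tx.reserve(ne * 64);
  NumericVector fint(2 * nn);
  double detj_min = R_PosInf;
  int bad_elem = -1;

  for (int e = 0; e < ne; ++e) {
    int id[4];
    double X[4], Y[4], ux[4], uy[4];
    for (int a = 0; a < 4; ++a) {
      id[a] = elems(e, a) - 1;
      X[a] = nodes(id[a], 0);
      Y[a] = nodes(id[a], 1);
      ux[a] = u[2 * id[a]];
      uy[a] = u[2 * id[a] + 1];
    }
    const double E = Evec[e], nu = nuvec[e];
    const double c0 = E / (1.0 - nu * nu);
    const double C11 = c0, C12 = c0 * nu, C33 = c0 * (1.0 - nu) / 2.0;

    double Ke[8][8] = {{0}};
    double fe[8] = {0};

    for (int q = 0; q < 4; ++q) {
      const double xi = gp[q][0], eta = gp[q][1];
      // dN/dxi, dN/deta for nodes in CCW order (-1,-1),(1,-1),(1,1),(-1,1)
      const double dNxi[4] = {-(1 - eta) / 4, (1 - eta) / 4,
                              (1 + eta) / 4, -(1 + eta) / 4};
      const double dNeta[4] = {-(1 - xi) / 4, -(1 + xi) / 4,
                               (1 + xi) / 4, (1 - xi) / 4};
      double J11 = 0, J12 = 0, J21 = 0, J22 = 0;
      for (int a = 0; a < 4; ++a) {
        J11 += dNxi[a] * X[a];  J12 += dNxi[a] * Y[a];
        J21 += dNeta[a] * X[a]; J22 += dNeta[a] * Y[a];
      }
      const double detJ = J11 * J22 - J12 * J21;
      if (detJ < detj_min) { detj_min = detJ; bad_elem = e; }
      const double i11 = J22 / detJ, i12 = -J12 / detJ;
      const double i21 = -J21 / detJ, i22 = J11 / detJ;
      double dNx[4], dNy[4];
      for (int a = 0; a < 4; ++a) {
        dNx[a] = i11 * dNxi[a] + i12 * dNeta[a];
        dNy[a] = i21 * dNxi[a] + i22 * dNeta[a];
      }
      // deformation gradient F = I + grad(u); with nlgeom off the
      // kinematics stay linear (F treated as I in B, small strain)
      double F11 = 1, F12 = 0, F21 = 0, F22 = 1;
      double gxx = 0, gxy = 0, gyx = 0, gyy = 0;
      for (int a = 0; a < 4; ++a) {
        gxx += ux[a] * dNx[a]; gxy += ux[a] * dNy[a];
        gyx += uy[a] * dNx[a]; gyy += uy[a] * dNy[a];
      }
      double E11, E22, E12_2;
      if (nlgeom) {
        F11 += gxx; F12 += gxy; F21 += gyx; F22 += gyy;
        E11 = 0.5 * (F11 * F11 + F21 * F21 - 1.0);
        E22 = 0.5 * (F12 * F12 + F22 * F22 - 1.0);
        E12_2 = F11 * F12 + F21 * F22;
      } else {
        E11 = gxx; E22 = gyy; E12_2 = gxy + gyx;
      }
      // 2nd Piola-Kirchhoff stress
      const double S11 = C11 * E11 + C12 * E22;
      const double S22 = C12 * E11 + C11 * E22;
      const double S12 = C33 * E12_2;

      // material strain-displacement matrix B_L (3 x 8)
      double B[3][8];
      for (int a = 0; a < 4; ++a) {
        B[0][2 * a] = F11 * dNx[a];     B[0][2 * a + 1] = F21 * dNx[a];
        B[1][2 * a] = F12 * dNy[a];     B[1][2 * a + 1] = F22 * dNy[a];
        B[2][2 * a] = F11 * dNy[a] + F12 * dNx[a];
        B[2][2 * a + 1] = F21 * dNy[a] + F22 * dNx[a];
      }
      const double w = detJ * thickness;  // unit Gauss weights

      // internal force: B^T S
      const double Sv[3] = {S11, S22, S12};
      for (int i = 0; i < 8; ++i) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += B[k][i] * Sv[k];
        fe[i] += s * w;
      }
      // material tangent: B^T C B
      for (int i = 0; i < 8; ++i) {
        const double CB0 = C11 * B[0][i] + C12 * B[1][i];
        const double CB1 = C12 * B[0][i] + C11 * B[1][i];
        const double CB2 = C33 * B[2][i];
        for (int j = 0; j < 8; ++j)
          Ke[i][j] += (CB0 * B[0][j] + CB1 * B[1][j] + CB2 * B[2][j]) * w;
      }
      // geometric tangent: (dN_a . S dN_b) I2
      if (nlgeom)
      for (int a = 0; a < 4; ++a) {
        const double SgA0 = S11 * dNx[a] + S12 * dNy[a];
        const double SgA1 = S12 * dNx[a] + S22 * dNy[a];
        for (int b = 0; b < 4; ++b) {
          const double gab = (SgA0 * dNx[b] + SgA1 * dNy[b]) * w;
          Ke[2 * a][2 * b] += gab;
          Ke[2 * a + 1][2 * b + 1] += gab;
        }
      }
    }

    int dof[8];
    for (int a = 0; a < 4; ++a) {
      dof[2 * a] = 2 * id[a];
      dof[2 * a + 1] = 2 * id[a] + 1;
    }
    for (int i = 0; i < 8; ++i) {
      fint[dof[i]] += fe[i];
      for (int j = 0; j < 8; ++j) {
        ti.push_back(dof[i] + 1);
        tj.push_back(dof[j] + 1);
        tx.push_back(Ke[i][j]);
      }
    }
  }

  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx), _["fint"] = fint,
                      _["detj_min"] = detj_min,
                      _["detj_min_elem"] = bad_elem + 1);
}
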