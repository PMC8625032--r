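#include <Rcpp.h>
using namespace Rcpp;

// Gaussian-density overlap volume between two atom sets (first-order,
// pairwise product integrals). Each heavy atom i carries a Gaussian
// p * exp(-alpha_i * r^2) whose integral reproduces its van der Waals
// sphere volume at amplitude p.
// [[Rcpp::export]]
double cpp_gauss_overlap(const NumericMatrix& A, const NumericVector& alphaA,
                         const NumericMatrix& B, const NumericVector& alphaB,
                         double p) {
  const double pi = M_PI;
  double total = 0.0;
  const int na = A.nrow(), nb = B.nrow();
  for (int i = 0; i < na; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2), ai = alphaA[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double aj = alphaB[j], s = ai + aj;
      total += p * p * std::pow(pi / s, 1.5) * std::exp(-ai * aj * d2 / s);
    }
  }
  return total;
}

// Pharmacophore match kernel: sum over same-kind feature pairs of a
// Gaussian of the inter-feature distance.
// [[Rcpp::export]]
double cpp_feature_sum(const NumericMatrix& FA, const IntegerVector& kindA,
                       const NumericMatrix& FB, const IntegerVector& kindB,
                       double sigma) {
  double total = 0.0;
  const double den = 2.0 * sigma * sigma;
  for (int i = 0; i < FA.nrow(); ++i) {
    for (int j = 0; j < FB.nrow(); ++j) {
      if (kindA[i] != kindB[j]) continue;
      const double dx = FA(i, 0) - FB(j, 0);
      const double dy = FA(i, 1) - FB(j, 1);
      const double dz = FA(i, 2) - FB(j, 2);
      total += std::exp(-(dx * dx + dy * dy + dz * dz) / den);
    }
  }
  return total;
}

// Empirical protein-ligand interaction terms over heavy-atom pairs within
// a cutoff. d is the surface distance r - R_i - R_j. Returns
// (gauss1, gauss2, repulsion, hydrophobic, hbond).
// [[Rcpp::export]]
NumericVector cpp_vina_terms(const NumericMatrix& L, const NumericVector& Lrad,
                             const LogicalVector& Lhyd, const LogicalVector& Ldon,
                             const LogicalVector& Lacc,
                             const NumericMatrix& P, const NumericVector& Prad,
                             const LogicalVector& Phyd, const LogicalVector& Pdon,
                             const LogicalVector& Pacc, double cutoff) {
  double g1 = 0, g2 = 0, rep = 0, hyd = 0, hb = 0;
  const double cut2 = cutoff * cutoff;
  for (int i = 0; i < L.nrow(); ++i) {
    for (int j = 0; j < P.nrow(); ++j) {
      const double dx = L(i, 0) - P(j, 0);
      const double dy = L(i, 1) - P(j, 1);
      const double dz = L(i, 2) - P(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cut2) continue;
      const double d = std::sqrt(r2) - Lrad[i] - Prad[j];
      g1 += std::exp(-(d / 0.5) * (d / 0.5));
      const double e2 = (d - 3.0) / 2.0;
      g2 += std::exp(-e2 * e2);
      if (d < 0) rep += d * d;
      if (Lhyd[i] && Phyd[j]) {
        if (d <= 0.5) hyd += 1.0;
        else if (d < 1.5) hyd += (1.5 - d);
      }
      const bool pair_hb = (Ldon[i] && Pacc[j]) || (Lacc[i] && Pdon[j]);
      if (pair_hb) {
        if (d <= -0.7) hb += 1.0;
        else if (d < 0) hb += d / -0.7;
      }
    }
  }
  return NumericVector::create(g1, g2, rep, hyd, hb);
}

// Shrake-Rupley solvent-accessible surface area. pts is a unit-sphere point
// set; each atom's accessible area is (exposed fraction) * 4*pi*(r+probe)^2.
// ctx supplies additional occluding spheres (e.g. the protein).
// [[Rcpp::export]]
NumericVector cpp_sasa(const NumericMatrix& xyz, const NumericVector& rad,
                       const NumericMatrix& pts, double probe,
                       const NumericMatrix& ctx, const NumericVector& ctxrad) {
  const int n = xyz.nrow(), np = pts.nrow(), nc = ctx.nrow();
  NumericVector area(n);
  for (int i = 0; i < n; ++i) {
    const double ri = rad[i] + probe;
    int exposed = 0;
    for (int k = 0; k < np; ++k) {
      const double px = xyz(i, 0) + ri * pts(k, 0);
      const double py = xyz(i, 1) + ri * pts(k, 1);
      const double pz = xyz(i, 2) + ri * pts(k, 2);
      bool free_pt = true;
      for (int j = 0; j < n && free_pt; ++j) {
        if (j == i) continue;
        const double rj = rad[j] + probe;
        const double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) free_pt = false;
      }
      for (int j = 0; j < nc && free_pt; ++j) {
        const double rj = ctxrad[j] + probe;
        const double dx = px - ctx(j, 0), dy = py - ctx(j, 1), dz = pz - ctx(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) free_pt = false;
      }
      if (free_pt) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * ((double)exposed / np);
  }
  return area;
}

// Apply a pose parameterization to ligand coordinates: torsion rotations
// about each rotatable bond (moving the listed branch atoms), then a rigid
// rotation about `center`, then a translation. par = (t xyz, rotvec,
// torsions...). Indices are 1-based.
static void rodrigues(const double* k, double theta, double R[3][3]) {
  const double c = std::cos(theta), s = std::sin(theta), t = 1.0 - c;
  R[0][0] = c + k[0] * k[0] * t;
  R[0][1] = k[0] * k[1] * t - k[2] * s;
  R[0][2] = k[0] * k[2] * t + k[1] * s;
  R[1][0] = k[1] * k[0] * t + k[2] * s;
  R[1][1] = c + k[1] * k[1] * t;
  R[1][2] = k[1] * k[2] * t - k[0] * s;
  R[2][0] = k[2] * k[0] * t - k[1] * s;
  R[2][1] = k[2] * k[1] * t + k[0] * s;
  R[2][2] = c + k[2] * k[2] * t;
}

// [[Rcpp::export]]
NumericMatrix cpp_pose_xyz(const NumericMatrix& xyz0, const IntegerVector& ti,
                           const IntegerVector& tj, const List& branches,
                           const NumericVector& par,
                           const NumericVector& center) {
  NumericMatrix xyz = clone(xyz0);
  const int ntor = ti.size();
  double R[3][3];
  for (int k = 0; k < ntor; ++k) {
    const double ang = par[6 + k];
    if (std::fabs(ang) < 1e-9) continue;
    const int i = ti[k] - 1, j = tj[k] - 1;
    double ax[3] = {xyz(j, 0) - xyz(i, 0), xyz(j, 1) - xyz(i, 1),
                    xyz(j, 2) - xyz(i, 2)};
    const double nrm = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    if (nrm < 1e-12) continue;
    for (int d = 0; d < 3; ++d) ax[d] /= nrm;
    rodrigues(ax, ang, R);
    const double px = xyz(j, 0), py = xyz(j, 1), pz = xyz(j, 2);
    IntegerVector mv = branches[k];
    for (int m = 0; m < mv.size(); ++m) {
      const int a = mv[m] - 1;
      const double x = xyz(a, 0) - px, y = xyz(a, 1) - py, z = xyz(a, 2) - pz;
      xyz(a, 0) = R[0][0] * x + R[0][1] * y + R[0][2] * z + px;
      xyz(a, 1) = R[1][0] * x + R[1][1] * y + R[1][2] * z + py;
      xyz(a, 2) = R[2][0] * x + R[2][1] * y + R[2][2] * z + pz;
    }
  }
  double rv[3] = {par[3], par[4], par[5]};
  const double theta = std::sqrt(rv[0] * rv[0] + rv[1] * rv[1] + rv[2] * rv[2]);
  if (theta > 1e-12) {
    for (int d = 0; d < 3; ++d) rv[d] /= theta;
    rodrigues(rv, theta, R);
  } else {
    rodrigues(rv, 0.0, R);  // identity
  }
  for (int a = 0; a < xyz.nrow(); ++a) {
    const double x = xyz(a, 0) - center[0], y = xyz(a, 1) - center[1],
                 z = xyz(a, 2) - center[2];
    xyz(a, 0) = R[0][0] * x + R[0][1] * y + R[0][2] * z + center[0] + par[0];
    xyz(a, 1) = R[1][0] * x + R[1][1] * y + R[1][2] * z + center[1] + par[1];
    xyz(a, 2) = R[2][0] * x + R[2][1] * y + R[2][2] * z + center[2] + par[2];
  }
  return xyz;
}
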