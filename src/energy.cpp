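#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coulomb constant, kcal mol^-1 A e^-2
static const double KE2 = 332.0636;

// Deterministic quasi-uniform points on the unit sphere (golden-spiral
// lattice).  Used by the Shrake-Rupley accessibility count below.
static void sphere_points(int n, std::vector<double> &px,
                          std::vector<double> &py, std::vector<double> &pz) {
  px.resize(n); py.resize(n); pz.resize(n);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * k;
    px[k] = rho * std::cos(phi);
    py[k] = rho * std::sin(phi);
    pz[k] = z;
  }
}

// Shrake-Rupley solvent-accessible surface area.  Atom radius =
// born_radius + probe.  Piecewise constant in the coordinates at the
// lattice resolution, so it carries no gradient term.
// [[Rcpp::export]]
double sasa_cpp(NumericMatrix coords, NumericVector radius, int n_points,
                double probe) {
  const int n = coords.nrow();
  std::vector<double> px, py, pz;
  sphere_points(n_points, px, py, pz);
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = radius[i] + probe;
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    // neighbours able to occlude atom i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double rc = r[i] + r[j];
      if (d2 < rc * rc) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double x = coords(i, 0) + r[i] * px[k];
      double y = coords(i, 1) + r[i] * py[k];
      double z = coords(i, 2) + r[i] * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = x - coords(j, 0);
        double dy = y - coords(j, 1);
        double dz = z - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < r[j] * r[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    total += 4.0 * M_PI * r[i] * r[i] * acc / (double)n_points;
  }
  return total;
}

// Toy MM-GBSA potential energy and analytic gradient.
//
// E = sum_bonds k_b (b - b0)^2
//   + sum_nb 4 eps_ij [(sig_ij/d)^12 - (sig_ij/d)^6]       (Lorentz-Berthelot)
//   + sum_nb KE2 q_i q_j / (eps_in d)
//   + E_GB  (Still pairwise, all atom pairs incl. self, fixed Born radii)
//   + gamma_sasa * SASA
//
// E_GB = -0.5 KE2 (1/eps_in - 1/eps_w) sum_{i,j} q_i q_j / f_ij,
// f_ij = sqrt(d^2 + a_i a_j exp(-d^2 / (4 a_i a_j))).
//
// The SASA term is treated as locally constant (zero gradient).
// [[Rcpp::export]]
List toy_energy_cpp(NumericMatrix coords, NumericVector charge,
                    NumericVector sigma, NumericVector epsilon,
                    NumericVector born, IntegerMatrix bonds,
                    NumericVector kb, NumericVector b0, IntegerMatrix nbpairs,
                    double eps_in, double eps_w, double gamma_sasa,
                    int sasa_points, double probe, bool want_gradient,
                    bool want_sasa) {
  const int n = coords.nrow();
  double e_bond = 0.0, e_lj = 0.0, e_coul = 0.0, e_gb = 0.0, e_np = 0.0;
  NumericMatrix grad;
  if (want_gradient) grad = NumericMatrix(n, 3);

  // bonded
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = coords(i, 0) - coords(j, 0);
    double dy = coords(i, 1) - coords(j, 1);
    double dz = coords(i, 2) - coords(j, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < 1e-12) stop("bonded atoms %d and %d are coincident", i + 1, j + 1);
    double dev = d - b0[b];
    e_bond += kb[b] * dev * dev;
    if (want_gradient) {
      double c = 2.0 * kb[b] * dev / d;
      grad(i, 0) += c * dx; grad(i, 1) += c * dy; grad(i, 2) += c * dz;
      grad(j, 0) -= c * dx; grad(j, 1) -= c * dy; grad(j, 2) -= c * dz;
    }
  }

  // nonbonded LJ + screened Coulomb
  for (int p = 0; p < nbpairs.nrow(); ++p) {
    int i = nbpairs(p, 0), j = nbpairs(p, 1);
    double dx = coords(i, 0) - coords(j, 0);
    double dy = coords(i, 1) - coords(j, 1);
    double dz = coords(i, 2) - coords(j, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < 1e-24)
      stop("singular energy: atoms %d and %d coincide in a nonbonded pair",
           i + 1, j + 1);
    double d = std::sqrt(d2);
    double sij = 0.5 * (sigma[i] + sigma[j]);
    double eij = std::sqrt(epsilon[i] * epsilon[j]);
    double sr2 = sij * sij / d2;
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    e_lj += 4.0 * eij * (sr12 - sr6);
    double qq = KE2 * charge[i] * charge[j] / eps_in;
    e_coul += qq / d;
    if (want_gradient) {
      // dE/dd for LJ + Coulomb, then chain rule through d
      double dE_dd = 4.0 * eij * (-12.0 * sr12 + 6.0 * sr6) / d - qq / d2;
      double c = dE_dd / d;
      grad(i, 0) += c * dx; grad(i, 1) += c * dy; grad(i, 2) += c * dz;
      grad(j, 0) -= c * dx; grad(j, 1) -= c * dy; grad(j, 2) -= c * dz;
    }
  }

  // generalized-Born polar term: all pairs including self
  double gbpref = -0.5 * KE2 * (1.0 / eps_in - 1.0 / eps_w);
  if (gbpref != 0.0) {
    for (int i = 0; i < n; ++i) {
      if (charge[i] != 0.0)
        e_gb += gbpref * charge[i] * charge[i] / born[i];
      for (int j = i + 1; j < n; ++j) {
        double qq = charge[i] * charge[j];
        if (qq == 0.0) continue;
        double dx = coords(i, 0) - coords(j, 0);
        double dy = coords(i, 1) - coords(j, 1);
        double dz = coords(i, 2) - coords(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        double aa = born[i] * born[j];
        double ex = std::exp(-d2 / (4.0 * aa));
        double f = std::sqrt(d2 + aa * ex);
        e_gb += 2.0 * gbpref * qq / f;   // ordered double-sum counts ij and ji
        if (want_gradient) {
          // df/d(d2) = (1 - ex/4) / (2 f);  dE/dxi = -2 pref qq f^-2 df/d(d2) * 2 dx
          double dfdd2 = (1.0 - 0.25 * ex) / (2.0 * f);
          double c = -2.0 * gbpref * qq / (f * f) * dfdd2 * 2.0;
          grad(i, 0) += c * dx; grad(i, 1) += c * dy; grad(i, 2) += c * dz;
          grad(j, 0) -= c * dx; grad(j, 1) -= c * dy; grad(j, 2) -= c * dz;
        }
      }
    }
  }

  double sasa = NA_REAL;
  if (want_sasa && gamma_sasa != 0.0) {
    sasa = sasa_cpp(coords, born, sasa_points, probe);
    e_np = gamma_sasa * sasa;
  }

  double total = e_bond + e_lj + e_coul + e_gb + e_np;
  List out = List::create(
      _["energy"] = total,
      _["components"] = NumericVector::create(
          _["bond"] = e_bond, _["lj"] = e_lj, _["coulomb"] = e_coul,
          _["gb"] = e_gb, _["sasa"] = e_np),
      _["sasa_area"] = sasa);
  if (want_gradient) out["gradient"] = grad;
  return out;
}

// Minimum distance between two coordinate blocks (clash screening).
// [[Rcpp::export]]
double min_cross_distance_cpp(NumericMatrix a, NumericMatrix b) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i)
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = a(i, 0) - b(j, 0);
      double dy = a(i, 1) - b(j, 1);
      double dz = a(i, 2) - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
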