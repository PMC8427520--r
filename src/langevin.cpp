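#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Internal unit system: Angstrom, ps, amu, kcal/mol, K.
// ACC converts (kcal/mol/A)/amu into A/ps^2; KB is Boltzmann's constant in
// kcal/(mol K).  KB*ACC is then kB in amu A^2 / (ps^2 K), the combination
// entering Maxwell-Boltzmann velocity widths.
static const double ACC = 418.4;
static const double KB  = 0.0019872041;

struct PotParams {
  bool funnel = false;  double f_depth = 0.0, f_width = 1.0;
  bool rep = false;     double r_eps = 0.0, r_cut = 1.0;
  bool sph = false;     double s_rad = 0.0, s_k = 0.0, s_c[3] = {0, 0, 0};
  bool harm = false;    double h_k = 0.0;
  bool dw = false;      double dw_h = 0.0, dw_a = 1.0, dw_kyz = 0.0,
                               dw_c[3] = {0, 0, 0};
  double site[3] = {0, 0, 0};
  double rest_k = 0.0;  // harmonic restraint on mobile receptor beads
};

static void read_vec3(const List& src, const char* key, double out[3]) {
  NumericVector v = src[key];
  for (int k = 0; k < 3; ++k) out[k] = v[k];
}

static PotParams unpack_pot(const List& pot) {
  PotParams P;
  read_vec3(pot, "site", P.site);
  P.rest_k = as<double>(pot["restraint_k"]);
  if (pot.containsElementNamed("funnel") && !Rf_isNull(pot["funnel"])) {
    List f = pot["funnel"];
    P.funnel = true;
    P.f_depth = as<double>(f["depth"]);
    P.f_width = as<double>(f["width"]);
  }
  if (pot.containsElementNamed("repulsion") && !Rf_isNull(pot["repulsion"])) {
    List r = pot["repulsion"];
    P.rep = true;
    P.r_eps = as<double>(r["epsilon"]);
    P.r_cut = as<double>(r["cutoff"]);
  }
  if (pot.containsElementNamed("sphere") && !Rf_isNull(pot["sphere"])) {
    List s = pot["sphere"];
    P.sph = true;
    P.s_rad = as<double>(s["radius"]);
    P.s_k = as<double>(s["k"]);
    read_vec3(s, "center", P.s_c);
  }
  if (pot.containsElementNamed("harmonic") && !Rf_isNull(pot["harmonic"])) {
    List h = pot["harmonic"];
    P.harm = true;
    P.h_k = as<double>(h["k"]);
  }
  if (pot.containsElementNamed("double_well") &&
      !Rf_isNull(pot["double_well"])) {
    List d = pot["double_well"];
    P.dw = true;
    P.dw_h = as<double>(d["height"]);
    P.dw_a = as<double>(d["half_sep"]);
    P.dw_kyz = as<double>(d["k_perp"]);
    read_vec3(d, "center", P.dw_c);
  }
  return P;
}

// Forces from the composite toy potential plus (optionally) a 1D
// metadynamics bias on the ligand-centroid-to-site distance.
// roles: 0 = ligand, 1 = receptor, 2 = solvent.
static void compute_forces(int n, const std::vector<double>& x,
                           std::vector<double>& f,
                           const IntegerVector& roles,
                           const std::vector<double>& xref,
                           const PotParams& P,
                           const std::vector<int>& lig,
                           int n_hills,
                           const double* hc, const double* hh,
                           double sigma) {
  std::fill(f.begin(), f.end(), 0.0);

  for (int i = 0; i < n; ++i) {
    const double* xi = &x[3 * i];
    double* fi = &f[3 * i];
    int ri = roles[i];

    if (ri == 0) {  // ligand-only terms
      double d[3], r2 = 0.0;
      for (int k = 0; k < 3; ++k) { d[k] = xi[k] - P.site[k]; r2 += d[k] * d[k]; }
      if (P.funnel) {
        double w2 = P.f_width * P.f_width;
        double g = P.f_depth * std::exp(-r2 / (2.0 * w2)) / w2;
        for (int k = 0; k < 3; ++k) fi[k] -= g * d[k];
      }
      if (P.harm) {
        for (int k = 0; k < 3; ++k) fi[k] -= P.h_k * d[k];
      }
      if (P.dw) {
        double dx = xi[0] - P.dw_c[0];
        double a2 = P.dw_a * P.dw_a;
        // V = h ((dx^2 - a^2)/a^2)^2 ; dV/ddx = 4 h dx (dx^2 - a^2)/a^4
        fi[0] -= 4.0 * P.dw_h * dx * (dx * dx - a2) / (a2 * a2);
        fi[1] -= P.dw_kyz * (xi[1] - P.dw_c[1]);
        fi[2] -= P.dw_kyz * (xi[2] - P.dw_c[2]);
      }
    }

    if (P.sph && ri != 1) {  // confining sphere on mobile species
      double d[3], r2 = 0.0;
      for (int k = 0; k < 3; ++k) { d[k] = xi[k] - P.s_c[k]; r2 += d[k] * d[k]; }
      double r = std::sqrt(r2);
      if (r > P.s_rad && r > 1e-12) {
        double g = 2.0 * P.s_k * (r - P.s_rad) / r;
        for (int k = 0; k < 3; ++k) fi[k] -= g * d[k];
      }
    }

    if (ri == 1 && P.rest_k > 0.0) {  // restrained (mobile) receptor bead
      for (int k = 0; k < 3; ++k)
        fi[k] -= P.rest_k * (xi[k] - xref[3 * i + k]);
    }
  }

  if (P.rep) {  // pairwise soft-core repulsion, receptor-receptor excluded
    double rc = P.r_cut, rc2 = rc * rc;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (roles[i] == 1 && roles[j] == 1) continue;
        double d[3], r2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          d[k] = x[3 * i + k] - x[3 * j + k];
          r2 += d[k] * d[k];
        }
        if (r2 >= rc2 || r2 < 1e-20) continue;
        double r = std::sqrt(r2);
        // V = eps (1 - r/rc)^2 ; -dV/dr = 2 eps (1 - r/rc) / rc
        double g = 2.0 * P.r_eps * (1.0 - r / rc) / (rc * r);
        for (int k = 0; k < 3; ++k) {
          f[3 * i + k] += g * d[k];
          f[3 * j + k] -= g * d[k];
        }
      }
    }
  }

  if (n_hills > 0 && !lig.empty()) {
    // s = |ligand centroid - site|; V(s) = sum_k hh exp(-(s-hc)^2/(2 sigma^2))
    double c[3] = {0, 0, 0};
    int nl = (int)lig.size();
    for (int ii = 0; ii < nl; ++ii)
      for (int k = 0; k < 3; ++k) c[k] += x[3 * lig[ii] + k];
    double d[3], s2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      c[k] /= nl;
      d[k] = c[k] - P.site[k];
      s2 += d[k] * d[k];
    }
    double s = std::sqrt(s2);
    if (s > 1e-10) {
      double dVds = 0.0, cut = 8.0 * sigma, s22 = 2.0 * sigma * sigma;
      for (int k = 0; k < n_hills; ++k) {
        double ds = s - hc[k];
        if (std::fabs(ds) > cut) continue;
        dVds += hh[k] * (-ds / (sigma * sigma)) * std::exp(-ds * ds / s22);
      }
      double g = -dVds / (s * nl);
      for (int ii = 0; ii < nl; ++ii)
        for (int k = 0; k < 3; ++k) f[3 * lig[ii] + k] += g * d[k];
    }
  }
}

// BAOAB Langevin integrator over `nsteps` steps of length `dt`.
// Saves coordinates (and velocities) every `save_every` steps; save_every = 0
// keeps only the final state.  Uses R's RNG so runs are reproducible under
// set.seed().
// [[Rcpp::export]]
List cpp_langevin_chunk(NumericMatrix coords, NumericMatrix vels,
                        NumericVector mass, IntegerVector roles,
                        LogicalVector mobile, List pot,
                        double dt, double temperature, double friction,
                        int nsteps, int save_every,
                        NumericVector hill_centers,
                        NumericVector hill_heights,
                        double hill_sigma) {
  int n = coords.nrow();
  if (vels.nrow() != n || (int)mass.size() != n || (int)roles.size() != n)
    stop("inconsistent system arrays");
  PotParams P = unpack_pot(pot);

  std::vector<double> x(3 * n), v(3 * n), f(3 * n), xref(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] = coords(i, k);
      v[3 * i + k] = vels(i, k);
      xref[3 * i + k] = coords(i, k);
    }

  std::vector<int> lig;
  for (int i = 0; i < n; ++i) if (roles[i] == 0) lig.push_back(i);

  int n_hills = hill_centers.size();
  const double* hc = n_hills > 0 ? &hill_centers[0] : nullptr;
  const double* hh = n_hills > 0 ? &hill_heights[0] : nullptr;

  std::vector<double> invm(n), sdv(n);
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  for (int i = 0; i < n; ++i) {
    invm[i] = ACC / mass[i];
    sdv[i] = temperature > 0.0
      ? std::sqrt(KB * ACC * temperature / mass[i]) : 0.0;
  }

  int nsave = (save_every > 0) ? nsteps / save_every : 0;
  NumericVector sx(nsave > 0 ? (R_xlen_t)nsave * n * 3 : 0);
  NumericVector sv(nsave > 0 ? (R_xlen_t)nsave * n * 3 : 0);

  RNGScope scope;
  compute_forces(n, x, f, roles, xref, P, lig, n_hills, hc, hh, hill_sigma);

  int isave = 0;
  double hdt = 0.5 * dt;
  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      double* xi = &x[3 * i];
      double* vi = &v[3 * i];
      for (int k = 0; k < 3; ++k) {
        vi[k] += hdt * f[3 * i + k] * invm[i];          // B
        xi[k] += hdt * vi[k];                           // A
        vi[k] = c1 * vi[k] + c2 * sdv[i] * norm_rand(); // O
        xi[k] += hdt * vi[k];                           // A
      }
    }
    compute_forces(n, x, f, roles, xref, P, lig, n_hills, hc, hh, hill_sigma);
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] += hdt * f[3 * i + k] * invm[i];   // B
    }

    if (save_every > 0 && step % save_every == 0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          double xi = x[3 * i + k];
          if (!std::isfinite(xi) || std::fabs(xi) > 1e7)
            stop("integration blow-up at frame %d (step %d)",
                 isave + 1, step);
          sx[isave + (R_xlen_t)nsave * (i + (R_xlen_t)n * k)] = xi;
          sv[isave + (R_xlen_t)nsave * (i + (R_xlen_t)n * k)] = v[3 * i + k];
        }
      ++isave;
    }
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double xi = x[3 * i + k];
      if (!std::isfinite(xi) || std::fabs(xi) > 1e7)
        stop("integration blow-up at final step");
      xout(i, k) = xi;
      vout(i, k) = v[3 * i + k];
    }

  if (nsave > 0) {
    sx.attr("dim") = Dimension(nsave, n, 3);
    sv.attr("dim") = Dimension(nsave, n, 3);
  }
  return List::create(_["coords"] = xout, _["velocities"] = vout,
                      _["saved_coords"] = sx, _["saved_velocities"] = sv,
                      _["nsave"] = nsave);
}
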