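#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Explicit, conservative finite-volume update for the single- and
// multi-species Fisher-KPP (linear diffusion) and Porous-Fisher
// (degenerate, pressure-driven diffusion) systems.
//
// State layout: rho[(s*ny + j)*nx + i], i fastest (matches an R array
// with dim = c(nx, ny, ns)). For radial grids ny == 1 and i indexes the
// radial cell whose centre sits at (i + 1/2) h.
//
// family: 0 = linear (Fickian flux -D grad rho_s per species)
//         1 = porous (common pressure P = D * rho_tot^(m-1), species flux
//             -rho_s,upwind * grad P; mobility upwinded by the sign of the
//             pressure difference so vacuum cells carry zero flux)
// mode:   0 = cartesian2d, 1 = radial1d

namespace {

struct Problem {
  int nx, ny, ns, mode, family;
  double h, D, r, K, m;
};

inline int idx(const Problem& p, int s, int j, int i) {
  return (s * p.ny + j) * p.nx + i;
}

double max_total_density(const Problem& p, const std::vector<double>& rho) {
  const int ncell = p.nx * p.ny;
  double mx = 0.0;
  for (int c = 0; c < ncell; ++c) {
    double tot = 0.0;
    for (int s = 0; s < p.ns; ++s) tot += rho[s * ncell + c];
    if (tot > mx) mx = tot;
  }
  return mx;
}

// Largest stable time step: parabolic bound CFL * h^2 / (2 dim Dmax)
// combined with the reaction bound 0.1 / r. The radial operator's
// geometric face weights sum to the same coefficient as plain 1D.
double dt_bound(const Problem& p, const std::vector<double>& rho, double cfl) {
  double dmax;
  if (p.family == 0) {
    dmax = p.D;
  } else {
    double mx = max_total_density(p, rho);
    double fac = (p.m > 2.0) ? (p.m - 1.0) : 1.0;
    dmax = (mx > 0.0) ? fac * p.D * std::pow(mx, p.m - 1.0) : 0.0;
  }
  int dim = (p.mode == 0 && p.ny > 1) ? 2 : 1;
  double dt = R_PosInf;
  if (dmax > 0.0) dt = cfl * p.h * p.h / (2.0 * dim * dmax);
  if (p.r > 0.0) dt = std::min(dt, 0.1 / p.r);
  return dt;
}

// One explicit step of size dt (assumed admissible). work: ncell scratch.
void step(const Problem& p, std::vector<double>& rho, std::vector<double>& tot,
          std::vector<double>& P, std::vector<double>& out, double dt) {
  const int nx = p.nx, ny = p.ny, ns = p.ns, ncell = nx * ny;
  const double h = p.h;

  for (int c = 0; c < ncell; ++c) {
    double t = 0.0;
    for (int s = 0; s < ns; ++s) t += rho[s * ncell + c];
    tot[c] = t;
  }
  const bool porous = (p.family == 1);
  if (porous) {
    for (int c = 0; c < ncell; ++c)
      P[c] = p.D * ((p.m == 2.0) ? tot[c] : std::pow(tot[c], p.m - 1.0));
  }

  // reaction (explicit, uses old total density)
  for (int s = 0; s < ns; ++s)
    for (int c = 0; c < ncell; ++c) {
      double rs = rho[s * ncell + c];
      out[s * ncell + c] = rs + dt * p.r * rs * (1.0 - tot[c] / p.K);
    }

  if (p.mode == 1) {
    // radial: face i sits at radius i*h (face 0 at r = 0 carries no flux),
    // cell centre i at (i + 1/2) h; fluxes weighted by face radius.
    for (int s = 0; s < ns; ++s) {
      const double* rs = &rho[s * ncell];
      double* os = &out[s * ncell];
      for (int i = 1; i < nx; ++i) {
        double F;  // flux through face i, positive outward
        if (porous) {
          double dP = P[i] - P[i - 1];
          double M = (dP < 0.0) ? rs[i - 1] : rs[i];
          F = -M * dP / h;
        } else {
          F = -p.D * (rs[i] - rs[i - 1]) / h;
        }
        double rf = i * h;
        os[i - 1] -= dt * rf * F / (((i - 1) + 0.5) * h * h);
        os[i]     += dt * rf * F / ((i + 0.5) * h * h);
      }
    }
  } else {
    for (int s = 0; s < ns; ++s) {
      const double* rs = &rho[s * ncell];
      double* os = &out[s * ncell];
      for (int j = 0; j < ny; ++j) {
        const int row = j * nx;
        for (int i = 1; i < nx; ++i) {  // x faces
          int l = row + i - 1, rgt = row + i;
          double F;
          if (porous) {
            double dP = P[rgt] - P[l];
            double M = (dP < 0.0) ? rs[l] : rs[rgt];
            F = -M * dP / h;
          } else {
            F = -p.D * (rs[rgt] - rs[l]) / h;
          }
          os[l]   -= dt * F / h;
          os[rgt] += dt * F / h;
        }
      }
      for (int j = 1; j < ny; ++j) {  // y faces
        for (int i = 0; i < nx; ++i) {
          int l = (j - 1) * nx + i, u = j * nx + i;
          double F;
          if (porous) {
            double dP = P[u] - P[l];
            double M = (dP < 0.0) ? rs[l] : rs[u];
            F = -M * dP / h;
          } else {
            F = -p.D * (rs[u] - rs[l]) / h;
          }
          os[l] -= dt * F / h;
          os[u] += dt * F / h;
        }
      }
    }
  }
  rho.swap(out);
}

Problem make_problem(IntegerVector dims, int mode, double h, int family,
                     double D, double r, double K, double m) {
  Problem p;
  p.nx = dims[0]; p.ny = dims[1]; p.ns = dims[2];
  p.mode = mode; p.family = family;
  p.h = h; p.D = D; p.r = r; p.K = K; p.m = m;
  return p;
}

}  // namespace

// [[Rcpp::export]]
double fv_dt_bound_cpp(NumericVector rho0, IntegerVector dims, int mode,
                       double h, int family, double D, double r, double K,
                       double m, double cfl) {
  Problem p = make_problem(dims, mode, h, family, D, r, K, m);
  std::vector<double> rho(rho0.begin(), rho0.end());
  return dt_bound(p, rho, cfl);
}

// [[Rcpp::export]]
NumericVector fv_step_cpp(NumericVector rho0, IntegerVector dims, int mode,
                          double h, int family, double D, double r, double K,
                          double m, double dt) {
  Problem p = make_problem(dims, mode, h, family, D, r, K, m);
  const int n = p.nx * p.ny * p.ns, ncell = p.nx * p.ny;
  std::vector<double> rho(rho0.begin(), rho0.end());
  std::vector<double> tot(ncell), P(ncell), out(n);
  step(p, rho, tot, P, out, dt);
  return NumericVector(rho.begin(), rho.end());
}

// [[Rcpp::export]]
List fv_solve_cpp(NumericVector rho0, IntegerVector dims, int mode, double h,
                  int family, double D, double r, double K, double m,
                  double t0, NumericVector t_out, double cfl) {
  Problem p = make_problem(dims, mode, h, family, D, r, K, m);
  const int n = p.nx * p.ny * p.ns, ncell = p.nx * p.ny;
  std::vector<double> rho(rho0.begin(), rho0.end());
  std::vector<double> tot(ncell), P(ncell), out(n);

  List snaps(t_out.size());
  double t = t0;
  long n_steps = 0;
  for (int k = 0; k < t_out.size(); ++k) {
    double target = t_out[k];
    while (t < target - 1e-12) {
      double dt = dt_bound(p, rho, cfl);
      if (!R_finite(dt)) dt = target - t;
      dt = std::min(dt, target - t);
      step(p, rho, tot, P, out, dt);
      t += dt;
      ++n_steps;
      if (n_steps % 1000 == 0) {
        for (int c = 0; c < n; ++c)
          if (!R_finite(rho[c]))
            stop("non-finite density encountered at t = %f", t);
      }
    }
    t = target;
    for (int c = 0; c < n; ++c)
      if (!R_finite(rho[c]))
        stop("non-finite density encountered at t = %f", t);
    snaps[k] = NumericVector(rho.begin(), rho.end());
  }
  return List::create(_["snapshots"] = snaps, _["n_steps"] = (double)n_steps);
}
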