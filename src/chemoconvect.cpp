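// Core numerical kernels: D2Q9 BGK lattice Boltzmann with Guo forcing and
// half-way bounce-back walls, flux-limited finite-volume advection-diffusion
// for the reagent, and semi-implicit overdamped Langevin tracer stepping.
// All kernels operate on flat arrays indexed id = i + nx*j (i: x, j: y),
// matching R's column-major nx-by-ny matrices.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- D2Q9 lattice
static const int    CX[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
static const int    CY[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
static const double W9[9] = {4.0 / 9.0,
                             1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0,
                             1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0};
static const int    OPP[9] = {0, 3, 4, 1, 2, 7, 8, 5, 6};

// One BGK collide (with Guo forcing) + push-streaming step with half-way
// bounce-back at solid walls (optionally periodic in x). ax, ay are lattice
// accelerations per node (force on the Boussinesq reference density
// rho0_lb = 1). Dual-buffer: reads fsrc, writes fdst; every (node, q) pair
// pushes exactly one value, so fdst is completely overwritten.
static void lbm_step(const std::vector<double> &fsrc, std::vector<double> &fdst,
                     const double *__restrict ax, const double *__restrict ay,
                     int nx, int ny, double tau, bool periodic_x,
                     bool fy_only) {
  const int nn = nx * ny;
  const double omega = 1.0 / tau;
  const double fpre = 1.0 - 0.5 * omega;
  const double *__restrict s0 = fsrc.data();
  double *__restrict d0 = fdst.data();

  // streaming offsets in the flat id = i + nx*j layout
  const int off[9] = {0, 1, nx, -1, -nx, 1 + nx, -1 + nx, -1 - nx, 1 - nx};

  for (int j = 0; j < ny; ++j) {
    const bool jlo = (j == 0), jhi = (j == ny - 1);
    for (int i = 0; i < nx; ++i) {
      const int id = i + nx * j;
      const double f0 = s0[id],
                   f1 = s0[nn + id], f2 = s0[2 * nn + id],
                   f3 = s0[3 * nn + id], f4 = s0[4 * nn + id],
                   f5 = s0[5 * nn + id], f6 = s0[6 * nn + id],
                   f7 = s0[7 * nn + id], f8 = s0[8 * nn + id];
      const double rho = f0 + f1 + f2 + f3 + f4 + f5 + f6 + f7 + f8;
      const double invr = 1.0 / rho;
      const double Fx = ax[id], Fy = ay[id];
      const double ux = (f1 - f3 + f5 - f6 - f7 + f8 + 0.5 * Fx) * invr;
      const double uy = (f2 - f4 + f5 + f6 - f7 - f8 + 0.5 * Fy) * invr;
      const double usq = 1.5 * (ux * ux + uy * uy);
      // hand-unrolled equilibria and Guo forcing terms
      const double w0r = (4.0 / 9.0) * rho, w1r = (1.0 / 9.0) * rho,
                   w2r = (1.0 / 36.0) * rho;
      const double ux3 = 3.0 * ux, uy3 = 3.0 * uy;
      const double cup = ux + uy, cum = ux - uy;   // diagonal projections
      const double uFx = ux * Fx + uy * Fy;        // u . F
      const double p0 = fpre * (4.0 / 9.0), p1 = fpre * (1.0 / 9.0),
                   p2 = fpre * (1.0 / 36.0);
      double v[9];
      if (fy_only) {          // vertical (buoyancy) forcing: common case
        const double A3 = 3.0 * (Fy - uFx), B3 = 3.0 * (-Fy - uFx);
        const double D9 = 9.0 * uy * Fy, E9 = 9.0 * cup * Fy,
                     F9 = 9.0 * cum * Fy;
        const double c3 = -3.0 * uFx;
        v[0] = f0 - omega * (f0 - w0r * (1.0 - usq)) + p0 * c3;
        v[1] = f1 - omega * (f1 - w1r * (1.0 + ux3 + 4.5 * ux * ux - usq)) +
               p1 * c3;
        v[3] = f3 - omega * (f3 - w1r * (1.0 - ux3 + 4.5 * ux * ux - usq)) +
               p1 * c3;
        v[2] = f2 - omega * (f2 - w1r * (1.0 + uy3 + 4.5 * uy * uy - usq)) +
               p1 * (A3 + D9);
        v[4] = f4 - omega * (f4 - w1r * (1.0 - uy3 + 4.5 * uy * uy - usq)) +
               p1 * (B3 + D9);
        v[5] = f5 - omega * (f5 - w2r * (1.0 + 3.0 * cup + 4.5 * cup * cup - usq)) +
               p2 * (A3 + E9);
        v[7] = f7 - omega * (f7 - w2r * (1.0 - 3.0 * cup + 4.5 * cup * cup - usq)) +
               p2 * (B3 + E9);
        v[6] = f6 - omega * (f6 - w2r * (1.0 - 3.0 * cum + 4.5 * cum * cum - usq)) +
               p2 * (A3 - F9);
        v[8] = f8 - omega * (f8 - w2r * (1.0 + 3.0 * cum + 4.5 * cum * cum - usq)) +
               p2 * (B3 - F9);
      } else {
        v[0] = f0 - omega * (f0 - w0r * (1.0 - usq)) + p0 * (-3.0 * uFx);
        v[1] = f1 - omega * (f1 - w1r * (1.0 + ux3 + 4.5 * ux * ux - usq)) +
               p1 * (3.0 * (Fx - uFx) + 9.0 * ux * Fx);
        v[3] = f3 - omega * (f3 - w1r * (1.0 - ux3 + 4.5 * ux * ux - usq)) +
               p1 * (3.0 * (-Fx - uFx) + 9.0 * ux * Fx);
        v[2] = f2 - omega * (f2 - w1r * (1.0 + uy3 + 4.5 * uy * uy - usq)) +
               p1 * (3.0 * (Fy - uFx) + 9.0 * uy * Fy);
        v[4] = f4 - omega * (f4 - w1r * (1.0 - uy3 + 4.5 * uy * uy - usq)) +
               p1 * (3.0 * (-Fy - uFx) + 9.0 * uy * Fy);
        const double Fp = Fx + Fy, Fm = Fx - Fy;
        v[5] = f5 - omega * (f5 - w2r * (1.0 + 3.0 * cup + 4.5 * cup * cup - usq)) +
               p2 * (3.0 * (Fp - uFx) + 9.0 * cup * Fp);
        v[7] = f7 - omega * (f7 - w2r * (1.0 - 3.0 * cup + 4.5 * cup * cup - usq)) +
               p2 * (3.0 * (-Fp - uFx) + 9.0 * cup * Fp);
        v[8] = f8 - omega * (f8 - w2r * (1.0 + 3.0 * cum + 4.5 * cum * cum - usq)) +
               p2 * (3.0 * (Fm - uFx) + 9.0 * cum * Fm);
        v[6] = f6 - omega * (f6 - w2r * (1.0 - 3.0 * cum + 4.5 * cum * cum - usq)) +
               p2 * (3.0 * (-Fm - uFx) + 9.0 * cum * Fm);
      }
      if (!jlo && !jhi && i > 0 && i < nx - 1) {   // interior: branch-free push
        d0[id] = v[0];
        d0[nn + id + off[1]] = v[1];
        d0[2 * nn + id + off[2]] = v[2];
        d0[3 * nn + id + off[3]] = v[3];
        d0[4 * nn + id + off[4]] = v[4];
        d0[5 * nn + id + off[5]] = v[5];
        d0[6 * nn + id + off[6]] = v[6];
        d0[7 * nn + id + off[7]] = v[7];
        d0[8 * nn + id + off[8]] = v[8];
      } else {                                     // edge: bounce back or wrap
        d0[id] = v[0];
        for (int q = 1; q < 9; ++q) {
          int it = i + CX[q], jt = j + CY[q];
          bool wall = false;
          if (it < 0 || it >= nx) {
            if (periodic_x) it = (it + nx) % nx; else wall = true;
          }
          if (jt < 0 || jt >= ny) wall = true;
          if (wall) d0[OPP[q] * nn + id] = v[q];
          else      d0[q * nn + it + nx * jt] = v[q];
        }
      }
    }
  }
}

// Macroscopic fields (lattice units) incl. half-force velocity correction.
static void lbm_macro(const std::vector<double> &f,
                      const double *ax, const double *ay,
                      int nx, int ny,
                      double *rho, double *ux, double *uy, double *umax) {
  const int nn = nx * ny;
  double um = 0.0;
  for (int id = 0; id < nn; ++id) {
    double r = 0.0, mx = 0.0, my = 0.0;
    for (int q = 0; q < 9; ++q) {
      const double fq = f[q * nn + id];
      r += fq;
      mx += fq * CX[q];
      my += fq * CY[q];
    }
    rho[id] = r;
    ux[id] = (mx + 0.5 * ax[id]) / r;
    uy[id] = (my + 0.5 * ay[id]) / r;
    const double s = std::sqrt(ux[id] * ux[id] + uy[id] * uy[id]);
    if (s > um) um = s;
  }
  *umax = um;
}

// [[Rcpp::export]]
List cc_lbm_steps(NumericVector f, NumericVector ax, NumericVector ay,
                  int nx, int ny, double tau, int nsteps, bool periodic_x) {
  const int nn = nx * ny;
  if (f.size() != 9 * nn) stop("distribution vector has wrong length");
  if (ax.size() != nn || ay.size() != nn) stop("force grid mismatch");
  std::vector<double> fv(f.begin(), f.end()), ftmp(9 * nn);
  bool fy_only = true;
  for (int id = 0; id < nn; ++id)
    if (ax[id] != 0.0) { fy_only = false; break; }
  for (int s = 0; s < nsteps; ++s) {
    lbm_step(fv, ftmp, ax.begin(), ay.begin(), nx, ny, tau, periodic_x,
             fy_only);
    fv.swap(ftmp);
  }
  NumericVector fout(fv.begin(), fv.end());
  NumericVector rho(nn), ux(nn), uy(nn);
  double umax;
  lbm_macro(fv, ax.begin(), ay.begin(), nx, ny,
            rho.begin(), ux.begin(), uy.begin(), &umax);
  if (!std::isfinite(umax)) stop("lattice Boltzmann state became non-finite");
  if (umax > 0.3)
    stop("lattice velocity %g exceeds the stability bound 0.3; reduce dt or forcing", umax);
  return List::create(_["f"] = fout, _["rho"] = rho,
                      _["ux"] = ux, _["uy"] = uy, _["umax_lb"] = umax);
}

// [[Rcpp::export]]
NumericVector cc_lbm_equilibrium(int nx, int ny) {
  const int nn = nx * ny;
  NumericVector f(9 * nn);
  for (int q = 0; q < 9; ++q)
    for (int id = 0; id < nn; ++id) f[q * nn + id] = W9[q];
  return f;
}

// ------------------------------------------------- reagent advection-diffusion
static inline double minmod(double a, double b) {
  if (a > 0.0 && b > 0.0) return a < b ? a : b;
  if (a < 0.0 && b < 0.0) return a > b ? a : b;
  return 0.0;
}

// One explicit substep of flux-form advection (second-order, minmod-limited)
// + central diffusion + implicit-linearized Michaelis-Menten floor sink.
// C in M; velocities in m/s; fluxes bookkept in M*m^2 (per unit z-thickness).
// bc family: 1 = Dirichlet (A/B, bcv in M), 2 = prescribed influx (C, bcv in M*m/s).
static void conc_substep(std::vector<double> &C,
                         const double *ux, const double *uy,
                         int nx, int ny, double dx, double dtc, double D,
                         int fam, double bcv, int ia0, int ia1,
                         double rmaxM, double KM,
                         double &injected, double &consumed, double &clipped,
                         std::vector<double> &Fx, std::vector<double> &Fy,
                         std::vector<double> &Cn) {
  const double cellA = dx * dx;
  // x-direction advective face fluxes, walls closed (u = 0 at wall faces)
  for (int j = 0; j < ny; ++j) {
    Fx[0 + (nx + 1) * j] = 0.0;
    Fx[nx + (nx + 1) * j] = 0.0;
    for (int i = 1; i < nx; ++i) {
      const double uf = 0.5 * (ux[i - 1 + nx * j] + ux[i + nx * j]);
      double val;
      if (uf >= 0.0) {
        const double c0 = C[i - 1 + nx * j];
        const double cm = (i >= 2) ? C[i - 2 + nx * j] : c0;
        const double cp = C[i + nx * j];
        val = c0 + 0.5 * minmod(cp - c0, c0 - cm);
      } else {
        const double c0 = C[i + nx * j];
        const double cm = C[i - 1 + nx * j];
        const double cp = (i + 1 < nx) ? C[i + 1 + nx * j] : c0;
        val = c0 - 0.5 * minmod(cp - c0, c0 - cm);
      }
      Fx[i + (nx + 1) * j] = uf * val;
    }
  }
  // y-direction
  for (int i = 0; i < nx; ++i) {
    Fy[i + nx * 0] = 0.0;
    Fy[i + nx * ny] = 0.0;
  }
  for (int j = 1; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const double uf = 0.5 * (uy[i + nx * (j - 1)] + uy[i + nx * j]);
      double val;
      if (uf >= 0.0) {
        const double c0 = C[i + nx * (j - 1)];
        const double cm = (j >= 2) ? C[i + nx * (j - 2)] : c0;
        const double cp = C[i + nx * j];
        val = c0 + 0.5 * minmod(cp - c0, c0 - cm);
      } else {
        const double c0 = C[i + nx * j];
        const double cm = C[i + nx * (j - 1)];
        const double cp = (j + 1 < ny) ? C[i + nx * (j + 1)] : c0;
        val = c0 - 0.5 * minmod(cp - c0, c0 - cm);
      }
      Fy[i + nx * j] = uf * val;
    }
  }
  // combined update: advection divergence + diffusion with ghost-cell BCs
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const int id = i + nx * j;
      const double c = C[id];
      double cw, ce, cs, cn2;
      if (i == 0) {
        if (fam == 2) cw = c + bcv * dx / D;       // prescribed influx
        else          cw = 2.0 * bcv - c;          // Dirichlet at the wall
      } else cw = C[id - 1];
      ce = (i == nx - 1) ? c : C[id + 1];
      cs = (j == 0) ? c : C[id - nx];              // floor: zero flux (sink separate)
      cn2 = (j == ny - 1) ? c : C[id + nx];
      const double lap = (cw + ce + cs + cn2 - 4.0 * c) / (dx * dx);
      const double divF = (Fx[i + 1 + (nx + 1) * j] - Fx[i + (nx + 1) * j] +
                           Fy[i + nx * (j + 1)] - Fy[i + nx * j]) / dx;
      Cn[id] = c + dtc * (D * lap - divF);
    }
  }
  // inlet bookkeeping: diffusive flux through the left wall faces
  for (int j = 0; j < ny; ++j) {
    const double c0 = C[0 + nx * j];
    const double flux_in = (fam == 2) ? bcv
                                      : 2.0 * D * (bcv - c0) / dx;  // M*m/s
    injected += flux_in * dx * dtc;
  }
  C.swap(Cn);
  // Michaelis-Menten sink on floor cells of region A (implicit-linearized)
  if (ia1 >= ia0 && rmaxM > 0.0) {
    for (int i = ia0; i <= ia1; ++i) {
      const double c = C[i];
      if (c <= 0.0) continue;
      const double cnew = c / (1.0 + dtc * rmaxM / (dx * (KM + c)));
      consumed += (c - cnew) * cellA;
      C[i] = cnew;
    }
  }
  // positivity safeguard (limited advection keeps this at round-off level)
  for (int id = 0; id < nx * ny; ++id) {
    if (C[id] < 0.0) {
      clipped += -C[id] * cellA;
      C[id] = 0.0;
    }
  }
}

// Substep count for the explicit advection-diffusion update. Positivity of
// the combined update needs the SUM of the directional Courant numbers and
// the diffusive Fourier numbers below one; 0.8 leaves headroom for the
// second-order (limited) advective fluxes.
static int conc_nsub(const double *ux, const double *uy, int nn,
                     double dt, double dx, double D) {
  double um = 0.0;
  for (int id = 0; id < nn; ++id) {
    const double s = std::fabs(ux[id]) + std::fabs(uy[id]);
    if (s > um) um = s;
  }
  const double load = dt * (um / dx + 4.0 * D / (dx * dx));
  int n = (int)std::ceil(load / 0.8);
  return n < 1 ? 1 : n;
}

// [[Rcpp::export]]
List cc_conc_step(NumericMatrix C, NumericMatrix ux, NumericMatrix uy,
                  double dx, double dt, double D,
                  int fam, double bcv, int ia0, int ia1,
                  double rmax, double KM) {
  const int nx = C.nrow(), ny = C.ncol();
  if (ux.nrow() != nx || ux.ncol() != ny || uy.nrow() != nx || uy.ncol() != ny)
    stop("velocity grid does not match the concentration grid");
  std::vector<double> Cv(C.begin(), C.end());
  std::vector<double> Fx((nx + 1) * ny), Fy(nx * (ny + 1)), Cn(nx * ny);
  double injected = 0.0, consumed = 0.0, clipped = 0.0;
  const double rmaxM = rmax / 1000.0;  // mol m^-2 s^-1 -> M m s^-1
  const int nsub = conc_nsub(ux.begin(), uy.begin(), nx * ny, dt, dx, D);
  const double dtc = dt / nsub;
  for (int s = 0; s < nsub; ++s)
    conc_substep(Cv, ux.begin(), uy.begin(), nx, ny, dx, dtc, D,
                 fam, bcv, ia0, ia1, rmaxM, KM,
                 injected, consumed, clipped, Fx, Fy, Cn);
  NumericMatrix Cout(nx, ny);
  std::copy(Cv.begin(), Cv.end(), Cout.begin());
  return List::create(_["C"] = Cout, _["injected"] = injected,
                      _["consumed"] = consumed, _["clipped"] = clipped,
                      _["nsub"] = nsub);
}

// ------------------------------------------------------------- tracer dynamics
// Bilinear interpolation of a node field (cell centres at (i+1/2)dx) with the
// no-slip value 0 on all four walls.
static double interp_wall0(const double *F, int nx, int ny, double dx,
                           double px, double py) {
  const double L = nx * dx, H = ny * dx;
  int i0, i1, j0, j1;
  double tx, ty, v00, v10, v01, v11;
  auto axis = [dx](double p, int n, double len, int &k0, int &k1, double &t) {
    if (p <= 0.5 * dx) { k0 = -1; k1 = 0; t = p / (0.5 * dx); }
    else if (p >= len - 0.5 * dx) { k0 = n - 1; k1 = -2; t = (p - (len - 0.5 * dx)) / (0.5 * dx); }
    else {
      const double s = p / dx - 0.5;
      k0 = (int)std::floor(s);
      if (k0 > n - 2) k0 = n - 2;
      k1 = k0 + 1;
      t = s - k0;
    }
  };
  axis(px, nx, L, i0, i1, tx);
  axis(py, ny, H, j0, j1, ty);
  auto val = [&](int i, int j) -> double {
    if (i < 0 || i == -2 || j < 0 || j == -2) return 0.0;  // wall
    return F[i + nx * j];
  };
  v00 = val(i0, j0); v10 = val(i1, j0); v01 = val(i0, j1); v11 = val(i1, j1);
  return (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
         (1 - tx) * ty * v01 + tx * ty * v11;
}

// [[Rcpp::export]]
NumericVector cc_interp_velocity(NumericMatrix ux, NumericMatrix uy,
                                 double dx, double px, double py) {
  const int nx = ux.nrow(), ny = ux.ncol();
  return NumericVector::create(
      interp_wall0(ux.begin(), nx, ny, dx, px, py),
      interp_wall0(uy.begin(), nx, ny, dx, px, py));
}

// Repulsive branch of the Morse wall force, as a function of wall distance d:
// F(d) = 2 eps omw s (s - 1), s = exp(-omw (d - d0)); zero for d >= d0.
static inline double morse_force(double d, double eps, double omw, double d0) {
  if (d >= d0) return 0.0;
  double e = omw * (d0 - d);
  if (e > 60.0) e = 60.0;  // overflow guard; never reached for sane states
  const double s = std::exp(e);
  return 2.0 * eps * omw * s * (s - 1.0);
}

// Solve z = b + A * F(z) (implicit Euler for the stiff wall-normal force)
// by safeguarded Newton; F is the repulsive Morse force from the wall at z=0.
static double wall_implicit(double b, double A, double eps, double omw,
                            double d0) {
  if (b >= d0) return b;  // outside the force range: explicit = implicit
  double z = b > 0.5 * d0 ? b : 0.5 * d0;
  for (int it = 0; it < 100; ++it) {
    const double e = omw * (d0 - z);
    const double s = std::exp(e > 60.0 ? 60.0 : e);
    const double F = (z >= d0) ? 0.0 : 2.0 * eps * omw * s * (s - 1.0);
    const double dF = (z >= d0) ? 0.0 : -2.0 * eps * omw * omw * s * (2.0 * s - 1.0);
    const double g = z - b - A * F;
    const double gp = 1.0 - A * dF;
    const double step = g / gp;
    z -= step;
    if (z < 0.0) z = 1e-12;
    if (std::fabs(step) < 1e-15 * (1.0 + std::fabs(z))) break;
  }
  return z;
}

// [[Rcpp::export]]
List cc_tracer_step(NumericVector x, NumericVector y, LogicalVector settled,
                    NumericMatrix ux, NumericMatrix uy, double dx,
                    double dt, double V, double Dt, double mu,
                    double eps, double omw, double Rtr, double y_settle,
                    bool noise) {
  const int N = x.size();
  const int nx = ux.nrow(), ny = ux.ncol();
  const double L = nx * dx, H = ny * dx;
  NumericVector xo(N), yo(N);
  LogicalVector so(N);
  int clamped = 0;
  const double sig = noise && Dt > 0.0 ? std::sqrt(2.0 * Dt * dt) : 0.0;
  const double A = dt * mu, d0 = Rtr;
  for (int k = 0; k < N; ++k) {
    const double u1 = interp_wall0(ux.begin(), nx, ny, dx, x[k], y[k]);
    const double u2 = interp_wall0(uy.begin(), nx, ny, dx, x[k], y[k]);
    double bx = x[k] + u1 * dt;
    double by = y[k] + (u2 - V) * dt;
    if (sig > 0.0) {
      bx += sig * norm_rand();
      by += sig * norm_rand();
    }
    // wall-normal Morse force, implicit per axis against the nearest wall
    double xn, yn;
    if (bx < 0.5 * L) xn = wall_implicit(bx, A, eps, omw, d0);
    else              xn = L - wall_implicit(L - bx, A, eps, omw, d0);
    if (by < 0.5 * H) yn = wall_implicit(by, A, eps, omw, d0);
    else              yn = H - wall_implicit(H - by, A, eps, omw, d0);
    // last-resort clamp; wall forces should make this unreachable
    if (xn < 0.0 || xn > L || yn < 0.0 || yn > H) {
      ++clamped;
      if (xn < 0.0) xn = 1e-12;
      if (xn > L) xn = L - 1e-12;
      if (yn < 0.0) yn = 1e-12;
      if (yn > H) yn = H - 1e-12;
    }
    xo[k] = xn;
    yo[k] = yn;
    so[k] = settled[k] || (yn < y_settle);  // settling is sticky
  }
  return List::create(_["x"] = xo, _["y"] = yo, _["settled"] = so,
                      _["clamped"] = clamped);
}

// ------------------------------------------------------------------ fused run
// Full coupled run: per coupling step of dt = n_couple * dt_lbm,
//  (1) n_couple LBM substeps with buoyancy frozen from the current C,
//  (2) reagent advection-diffusion with the updated flow,
//  (3) one Langevin tracer step with the updated flow.
// [[Rcpp::export]]
List cc_run(int nx, int ny, double dx,
            double tau, double dt_lbm, int n_couple,
            double g_eff, double betaC,
            double D_eff, double KM, double rmax_eff,
            int ia0, int ia1,
            int fam, double C0, double lam_eff, double q0_eff,
            NumericVector x0, NumericVector y0,
            double V_eff, double Dt_eff, double mu,
            double eps, double omw, double Rtr, double y_settle,
            double t_end, int out_every, bool noise) {
  const int nn = nx * ny;
  const double dt = n_couple * dt_lbm;
  const double conv_u = dx / dt_lbm;                 // lattice -> m/s
  const double acc_conv = dt_lbm * dt_lbm / dx;      // m/s^2 -> lattice accel
  const double rmaxM = rmax_eff / 1000.0;
  const int N = x0.size();

  std::vector<double> f(9 * nn), ftmp(9 * nn);
  for (int q = 0; q < 9; ++q)
    for (int id = 0; id < nn; ++id) f[q * nn + id] = W9[q];
  std::vector<double> C(nn, 0.0), ax(nn, 0.0), ay(nn, 0.0);
  std::vector<double> rho(nn), uxl(nn), uyl(nn), uxp(nn), uyp(nn);
  std::vector<double> Fx((nx + 1) * ny), Fy(nx * (ny + 1)), Cn(nn);
  std::vector<double> tx(x0.begin(), x0.end()), ty(y0.begin(), y0.end());
  std::vector<int> settled(N, 0);

  double t = 0.0, injected = 0.0, consumed = 0.0, clipped = 0.0;
  long clamped = 0;
  int max_nsub = 1, termination = 0;  // 0 horizon, 1 depleted
  const long nsteps = (long)std::ceil(t_end / dt - 1e-9);

  std::vector<double> rec_t, rec_umax, rec_inv, rec_inj, rec_cons, rec_settled;
  std::vector<double> prof_peak(nx, 0.0), prof(nx), prof_mid(nx, 0.0);
  double best_umax = -1.0, t_peakflow = 0.0, t_mid = -1.0;
  const double sig = noise && Dt_eff > 0.0 ? std::sqrt(2.0 * Dt_eff * dt) : 0.0;
  const double A = dt * mu, d0 = Rtr;
  const double L = nx * dx, H = ny * dx;

  for (long step = 1; step <= nsteps; ++step) {
    // (1) fluid: buoyancy from current C, frozen over the coupling interval
    for (int id = 0; id < nn; ++id)
      ay[id] = -g_eff * betaC * C[id] * acc_conv;
    for (int s = 0; s < n_couple; ++s) {
      lbm_step(f, ftmp, ax.data(), ay.data(), nx, ny, tau, false, true);
      f.swap(ftmp);
    }
    double umax_lb;
    lbm_macro(f, ax.data(), ay.data(), nx, ny,
              rho.data(), uxl.data(), uyl.data(), &umax_lb);
    if (!std::isfinite(umax_lb))
      stop("fluid state became non-finite at step %ld (t = %g s)", step, t);
    if (umax_lb > 0.3)
      stop("lattice velocity %g exceeded the stability bound at step %ld (t = %g s)",
           umax_lb, step, t);
    for (int id = 0; id < nn; ++id) {
      uxp[id] = uxl[id] * conv_u;
      uyp[id] = uyl[id] * conv_u;
    }

    // (2) reagent with the updated flow
    double bcv;
    if (fam == 1)      bcv = C0 * std::exp(-lam_eff * t);
    else if (fam == 3) bcv = (q0_eff / 1000.0) * std::exp(-lam_eff * t);
    else {
      bcv = C0 * (1.0 - lam_eff * t);
      if (bcv < 0.0) bcv = 0.0;
    }
    const int bcfam = (fam == 3) ? 2 : 1;
    const int nsub = conc_nsub(uxp.data(), uyp.data(), nn, dt, dx, D_eff);
    if (nsub > max_nsub) max_nsub = nsub;
    const double dtc = dt / nsub;
    for (int s = 0; s < nsub; ++s)
      conc_substep(C, uxp.data(), uyp.data(), nx, ny, dx, dtc, D_eff,
                   bcfam, bcv, ia0, ia1, rmaxM, KM,
                   injected, consumed, clipped, Fx, Fy, Cn);

    // (3) tracers with the updated flow
    int n_settled = 0;
    for (int k = 0; k < N; ++k) {
      const double u1 = interp_wall0(uxp.data(), nx, ny, dx, tx[k], ty[k]);
      const double u2 = interp_wall0(uyp.data(), nx, ny, dx, tx[k], ty[k]);
      double bx = tx[k] + u1 * dt;
      double by = ty[k] + (u2 - V_eff) * dt;
      if (sig > 0.0) {
        bx += sig * norm_rand();
        by += sig * norm_rand();
      }
      double xn, yn;
      if (bx < 0.5 * L) xn = wall_implicit(bx, A, eps, omw, d0);
      else              xn = L - wall_implicit(L - bx, A, eps, omw, d0);
      if (by < 0.5 * H) yn = wall_implicit(by, A, eps, omw, d0);
      else              yn = H - wall_implicit(H - by, A, eps, omw, d0);
      if (xn < 0.0 || xn > L || yn < 0.0 || yn > H) {
        ++clamped;
        if (xn < 0.0) xn = 1e-12;
        if (xn > L) xn = L - 1e-12;
        if (yn < 0.0) yn = 1e-12;
        if (yn > H) yn = H - 1e-12;
      }
      tx[k] = xn;
      ty[k] = yn;
      if (!settled[k] && yn < y_settle) settled[k] = 1;
      n_settled += settled[k];
    }
    t += dt;

    if (step % out_every == 0 || step == nsteps) {
      double inv = 0.0;
      for (int id = 0; id < nn; ++id) inv += C[id];
      inv *= dx * dx;  // M*m^2
      rec_t.push_back(t);
      rec_umax.push_back(umax_lb * conv_u);
      rec_inv.push_back(inv);
      rec_inj.push_back(injected);
      rec_cons.push_back(consumed);
      rec_settled.push_back((double)n_settled / N);
      if (umax_lb > best_umax) {
        best_umax = umax_lb;
        for (int i = 0; i < nx; ++i) {
          double m = -1e300;
          for (int j = 0; j < ny; ++j)
            if (uxp[i + nx * j] > m) m = uxp[i + nx * j];
          prof_peak[i] = m;
        }
        t_peakflow = t;
      }
      // flow snapshot at median deposition: representative of the transport
      if (t_mid < 0.0 && n_settled * 2 >= N) {
        for (int i = 0; i < nx; ++i) {
          double m = -1e300;
          for (int j = 0; j < ny; ++j)
            if (uxp[i + nx * j] > m) m = uxp[i + nx * j];
          prof_mid[i] = m;
        }
        t_mid = t;
      }
      if (injected > 0.0 && inv < 1e-3 * injected && n_settled == N) {
        termination = 1;
        break;
      }
    }
  }

  NumericMatrix Cout(nx, ny), uxo(nx, ny), uyo(nx, ny), rhoo(nx, ny);
  std::copy(C.begin(), C.end(), Cout.begin());
  std::copy(rho.begin(), rho.end(), rhoo.begin());
  for (int id = 0; id < nn; ++id) {
    uxo[id] = uxp[id];
    uyo[id] = uyp[id];
  }
  for (int i = 0; i < nx; ++i) {
    double m = -1e300;
    for (int j = 0; j < ny; ++j)
      if (uxp[i + nx * j] > m) m = uxp[i + nx * j];
    prof[i] = m;
  }
  return List::create(
      _["t"] = t, _["termination"] = termination,
      _["C"] = Cout, _["ux"] = uxo, _["uy"] = uyo, _["rho"] = rhoo,
      _["f"] = NumericVector(f.begin(), f.end()),
      _["tracer_x"] = NumericVector(tx.begin(), tx.end()),
      _["tracer_y"] = NumericVector(ty.begin(), ty.end()),
      _["settled"] = LogicalVector(settled.begin(), settled.end()),
      _["ledger"] = DataFrame::create(
          _["t"] = rec_t, _["umax"] = rec_umax, _["inventory"] = rec_inv,
          _["injected"] = rec_inj, _["consumed"] = rec_cons,
          _["settled_frac"] = rec_settled),
      _["profiles"] = List::create(
          _["peakflow"] = NumericVector(prof_peak.begin(), prof_peak.end()),
          _["t_peakflow"] = t_peakflow,
          _["transport"] = NumericVector(prof_mid.begin(), prof_mid.end()),
          _["t_transport"] = t_mid,
          _["final"] = NumericVector(prof.begin(), prof.end())),
      _["injected"] = injected, _["consumed"] = consumed,
      _["clipped"] = clipped, _["clamped"] = (double)clamped,
      _["max_conc_substeps"] = max_nsub);
}
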