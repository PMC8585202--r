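#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// All engine-internal quantities are SI per molecule: positions handed in
// as Angstrom are converted once, dipole dot products arrive premultiplied
// by D^2 / (4 pi eps0) so the per-site energy is k_i / (eps_r * d^3).

static const double ANGSTROM = 1e-10;

// Potential energy (J) and force (N) on the agent from all lattice sites.
// k: per-site coupling (mu_i . mu_agent) * D^2 / (4 pi eps0), SI.
// r_min_m: minimum-distance clamp in metres; n_clamped counts activations.
static void field_eval(const double *pos_m, const NumericMatrix &sites_m,
                       const NumericVector &k, double eps_r, double r_min_m,
                       double *ep, double *force, int *n_clamped) {
  const int n = sites_m.nrow();
  double e = 0.0, fx = 0.0, fy = 0.0, fz = 0.0;
  for (int i = 0; i < n; ++i) {
    double dx = pos_m[0] - sites_m(i, 0);
    double dy = pos_m[1] - sites_m(i, 1);
    double dz = pos_m[2] - sites_m(i, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    double d = std::sqrt(d2);
    if (d <= 0.0) stop("agent coincides with a dipole site (zero separation)");
    double dc = d;
    if (dc < r_min_m) { dc = r_min_m; ++*n_clamped; }
    double ki = k[i] / eps_r;
    double d3 = dc * dc * dc;
    e += ki / d3;
    // F = -dE/dr = +3 k / d^4 along the unit vector from site to agent
    double fmag = 3.0 * ki / (d3 * dc) / d; // includes 1/d for normalisation
    fx += fmag * dx;
    fy += fmag * dy;
    fz += fmag * dz;
  }
  *ep = e;
  force[0] = fx; force[1] = fy; force[2] = fz;
}

// [[Rcpp::export]]
List cpp_field_eval(NumericVector pos_ang, NumericMatrix sites_ang,
                    NumericVector k_si, double eps_r, double r_min_ang) {
  NumericMatrix sites_m(sites_ang.nrow(), 3);
  for (int i = 0; i < sites_ang.nrow(); ++i)
    for (int j = 0; j < 3; ++j) sites_m(i, j) = sites_ang(i, j) * ANGSTROM;
  double pos_m[3] = {pos_ang[0] * ANGSTROM, pos_ang[1] * ANGSTROM,
                     pos_ang[2] * ANGSTROM};
  double ep, f[3];
  int ncl = 0;
  field_eval(pos_m, sites_m, k_si, eps_r, r_min_ang * ANGSTROM, &ep, f, &ncl);
  return List::create(_["energy"] = ep,
                      _["force"] = NumericVector::create(f[0], f[1], f[2]),
                      _["n_clamped"] = ncl);
}

// Two-step Verlet recurrence with Stokes drag and a k_bT kinetic-energy cap:
//   r_{n+1}   = r_{n-1} + 2 dt v_n
//   v_{n+1}   = v_{n-1} (1 - 2 dt b/m) + 2 dt F(r_n)/m
// bootstrapped with r_0 = r_{-1} = start, v_0 = v_{-1} = v_start.
// Gibbs bookkeeping: per-step H = Ep + min(KE, k_bT); cumulative dG adds
// H_n - H_{n-1} plus sign * dH_transfer on water->membrane crossings (and
// the opposite on exit).
// [[Rcpp::export]]
List cpp_run_trajectory(NumericVector start_ang, NumericVector v0,
                        NumericMatrix sites_ang, NumericVector k_si,
                        double mass_kg, double dt, int n_steps,
                        double half_thickness_ang, double eps_water,
                        double eps_membrane, double b_water,
                        double b_membrane, double kbT, bool ke_cap,
                        double transfer_j, double transfer_sign,
                        bool stop_at_core, double r_min_ang,
                        double envelope_ang) {
  const int ns = sites_ang.nrow();
  NumericMatrix sites_m(ns, 3);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < 3; ++j) sites_m(i, j) = sites_ang(i, j) * ANGSTROM;
  const double h_m = half_thickness_ang * ANGSTROM;
  const double r_min_m = r_min_ang * ANGSTROM;
  const double env_m = envelope_ang * ANGSTROM;
  const double vcap = std::sqrt(2.0 * kbT / mass_kg);

  double r[3], r_prev[3], v[3], v_prev[3];
  for (int j = 0; j < 3; ++j) {
    r[j] = start_ang[j] * ANGSTROM;
    r_prev[j] = r[j];
    v[j] = v0[j];
    v_prev[j] = v0[j];
  }

  NumericVector t_out(n_steps), ep_out(n_steps), h_out(n_steps),
      dg_out(n_steps);
  NumericMatrix pos_out(n_steps, 3), vel_out(n_steps, 3);
  IntegerVector region_out(n_steps); // 1 = membrane, 0 = water
  int n_clamped = 0, n_recorded = 0, status = 0, bad_step = -1;

  double h_prev = 0.0;
  int reg_prev = 0;
  double cumG = 0.0;

  for (int n = 0; n < n_steps; ++n) {
    bool inside = std::fabs(r[2]) < h_m;
    double eps_r = inside ? eps_membrane : eps_water;
    double b = inside ? b_membrane : b_water;

    double ep, f[3];
    field_eval(r, sites_m, k_si, eps_r, r_min_m, &ep, f, &n_clamped);

    // kinetic part of the Hamiltonian for the state (r_n, v_n)
    double ke = 0.5 * mass_kg * (v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    double ke_h = (ke_cap && ke > kbT) ? kbT : ke;
    double H = ep + ke_h;
    if (n == 0) { h_prev = H; reg_prev = inside ? 1 : 0; }
    double dG = H - h_prev;
    int reg = inside ? 1 : 0;
    if (reg == 1 && reg_prev == 0) dG += transfer_sign * transfer_j;
    else if (reg == 0 && reg_prev == 1) dG -= transfer_sign * transfer_j;
    cumG += dG;
    h_prev = H;
    reg_prev = reg;

    t_out[n] = n * dt;
    for (int j = 0; j < 3; ++j) {
      pos_out(n, j) = r[j] / ANGSTROM;
      vel_out(n, j) = v[j];
    }
    ep_out[n] = ep;
    h_out[n] = H;
    dg_out[n] = cumG;
    region_out[n] = reg;
    n_recorded = n + 1;

    if (!std::isfinite(ep) || !std::isfinite(cumG) ||
        !std::isfinite(r[0] + r[1] + r[2])) {
      status = 2; bad_step = n; break;
    }
    if (std::fabs(r[0]) > env_m || std::fabs(r[1]) > env_m ||
        std::fabs(r[2]) > env_m) {
      status = 1; bad_step = n; break;
    }
    if (stop_at_core && r[2] <= 0.0) break;

    // advance: v_{n+1} from v_{n-1}; r_{n+1} from r_{n-1} and v_n
    double v_next[3], r_next[3];
    double decay = 1.0 - 2.0 * dt * b / mass_kg;
    for (int j = 0; j < 3; ++j)
      v_next[j] = decay * v_prev[j] + 2.0 * dt * f[j] / mass_kg;
    if (ke_cap) {
      double ke_n = 0.5 * mass_kg *
                    (v_next[0] * v_next[0] + v_next[1] * v_next[1] +
                     v_next[2] * v_next[2]);
      if (ke_n > kbT) {
        double s = vcap / std::sqrt(2.0 * ke_n / mass_kg);
        for (int j = 0; j < 3; ++j) v_next[j] *= s;
      }
    }
    for (int j = 0; j < 3; ++j) r_next[j] = r_prev[j] + 2.0 * dt * v[j];

    for (int j = 0; j < 3; ++j) {
      r_prev[j] = r[j];
      r[j] = r_next[j];
      v_prev[j] = v[j];
      v[j] = v_next[j];
    }
  }

  return List::create(
      _["time"] = t_out, _["pos"] = pos_out, _["vel"] = vel_out,
      _["ep"] = ep_out, _["h"] = h_out, _["dg"] = dg_out,
      _["region"] = region_out, _["n_recorded"] = n_recorded,
      _["n_clamped"] = n_clamped, _["status"] = status,
      _["bad_step"] = bad_step);
}
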