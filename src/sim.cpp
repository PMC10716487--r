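// Brownian-dynamics photon-emission engine.
//
// Emitters diffuse in a periodic box centred on the optical axis; per time
// step each emitter's detection rate is evaluated against 3D-Gaussian
// detection volumes and photons are drawn Poisson(rate * dt).
//
// Detection models:
//  * FCS mode ("nested"): green photons are generated from the widest nested
//    volume (sum5x5) and assigned to the inner channel sets (sum3x3, central)
//    by acceptance thinning, so that merging channels reproduces each
//    calibrated volume exactly. Red photons are detected by the single-element
//    detector (channel 25) with its own Gaussian volume.
//  * Trajectory mode: cpp_sim_trajectories / cpp_emit_photons expose the same
//    motion and emission primitives on explicit position arrays for small
//    problems (used for per-element imaging checks and oracles).
//
// One xoshiro256++ generator per simulation; draws are consumed emitter by
// emitter, step by step: (1) motion increments, (2) motion-state events,
// (3) photon count, (4) per photon: time, thinning, channel, microtime.

#include <Rcpp.h>
#include "rng.h"
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Volume {
  double inv_w2;  // 2 / omega^2   (um^-2, lateral)
  double inv_z2;  // 2 / z0^2      (um^-2, axial), z0 = k * omega
};

inline Volume make_volume(double waist_nm, double k) {
  Volume v;
  const double w_um = waist_nm * 1e-3;
  const double z_um = k * w_um;
  v.inv_w2 = 2.0 / (w_um * w_um);
  v.inv_z2 = 2.0 / (z_um * z_um);
  return v;
}

inline double wrap(double x, double L) {
  // periodic wrap to [-L/2, L/2)
  x -= L * std::floor(x / L + 0.5);
  return x;
}

struct MotionParams {
  int kind;              // 0 free, 1 trap, 2 hop
  double domain_radius;  // um (trap)
  double trap_rate;      // 1/s
  double escape_rate;    // 1/s
  double d_in;           // um^2/s (trap, inside domain)
  double mesh_size;      // um (hop)
  double hop_prob;       // per barrier crossing
};

struct EmitterState {
  double x, y, z;
  bool trapped;
  double cx, cy, cz;  // trap domain centre
};

// One diffusion step (dt seconds, possibly coarse for free motion).
inline void step_emitter(EmitterState &e, double D, const MotionParams &mp,
                         double dt_s, double bx, double by, double bz,
                         SimRng &rng) {
  if (mp.kind == 1 && e.trapped) {
    const double s = std::sqrt(2.0 * mp.d_in * dt_s);
    double nx = e.x + s * rng.normal(), ny = e.y + s * rng.normal(),
           nz = e.z + s * rng.normal();
    // radial reflection at the domain boundary
    double dx = nx - e.cx, dy = ny - e.cy, dz = nz - e.cz;
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > mp.domain_radius && r > 0) {
      const double rr = (2.0 * mp.domain_radius - r);
      const double f = (rr > 0 ? rr : 0.0) / r;
      nx = e.cx + dx * f;
      ny = e.cy + dy * f;
      nz = e.cz + dz * f;
    }
    e.x = nx; e.y = ny; e.z = nz;
    if (rng.unif() < -std::expm1(-mp.escape_rate * dt_s)) e.trapped = false;
    return;
  }
  const double s = std::sqrt(2.0 * D * dt_s);
  double nx = e.x + s * rng.normal(), ny = e.y + s * rng.normal(),
         nz = e.z + s * rng.normal();
  if (mp.kind == 2 && mp.mesh_size > 0) {
    // meshwork barriers at multiples of mesh_size per axis
    double *olds[3] = {&e.x, &e.y, &e.z};
    double *news[3] = {&nx, &ny, &nz};
    for (int a = 0; a < 3; ++a) {
      const double o = *olds[a], n = *news[a];
      const double ko = std::floor(o / mp.mesh_size),
                   kn = std::floor(n / mp.mesh_size);
      if (kn != ko) {
        if (rng.unif() >= mp.hop_prob) {
          const double b = (kn > ko ? (ko + 1.0) : ko) * mp.mesh_size;
          *news[a] = 2.0 * b - n;  // reflect at the first crossed barrier
        }
      }
    }
  }
  e.x = wrap(nx, bx); e.y = wrap(ny, by); e.z = wrap(nz, bz);
  if (mp.kind == 1 && !e.trapped) {
    if (rng.unif() < -std::expm1(-mp.trap_rate * dt_s)) {
      e.trapped = true;
      e.cx = e.x; e.cy = e.y; e.cz = e.z;
    }
  }
}

struct PhotonBuf {
  std::vector<double> t_ns;
  std::vector<int> channel;
  std::vector<double> micro_ns;
};

inline double draw_microtime(double tau_ns, double irf_offset_ns,
                             double irf_sigma_ns, double rep_period_ns,
                             SimRng &rng) {
  double m = rng.expo() * tau_ns + irf_offset_ns;
  if (irf_sigma_ns > 0) m += irf_sigma_ns * rng.normal();
  m -= rep_period_ns * std::floor(m / rep_period_ns);  // fold to [0, T_rep)
  if (m >= rep_period_ns) m = 0.0;                     // guard rounding
  return m;
}

const int RING8[8] = {6, 7, 8, 11, 13, 16, 17, 18};
const int RING16[16] = {0, 1, 2, 3, 4, 5, 9, 10, 14, 15, 19, 20, 21, 22, 23, 24};

}  // namespace

// Fused trajectory + emission simulation (FCS / point / circular-scan mode).
//
// species: list of lists with fields n, D, brightness_cps, lifetime_ns,
//          color (0 green / 1 red / 2 both), motion list(kind, ...params).
// waists_nm / ecc: named central, sum3x3, sum5x5, single_element.
// scan_mode: 0 point, 1 circular (radius_nm, period_us).
// [[Rcpp::export]]
List cpp_simulate_stream(List species, double box_x, double box_y,
                         double box_z, double dt_us, double duration_s,
                         NumericVector waists_nm, NumericVector ecc,
                         double rep_period_ns, double irf_sigma_ns,
                         double irf_offset_ns, int scan_mode,
                         double scan_radius_nm, double scan_period_us,
                         double seed, bool coarse_far_steps) {
  const double dt_s = dt_us * 1e-6;
  const double dt_ns = dt_us * 1e3;
  const long n_steps = (long)std::floor(duration_s / dt_s + 0.5);

  const Volume v5 = make_volume(waists_nm[2], ecc[2]);
  const Volume v3 = make_volume(waists_nm[1], ecc[1]);
  const Volume vc = make_volume(waists_nm[0], ecc[0]);
  const Volume vse = make_volume(waists_nm[3], ecc[3]);
  // thinning exponents (guaranteed >= 0 for monotone nested waists)
  const double d3_w = v3.inv_w2 - v5.inv_w2, d3_z = v3.inv_z2 - v5.inv_z2;
  const double dc_w = vc.inv_w2 - v3.inv_w2, dc_z = vc.inv_z2 - v3.inv_z2;

  const double qcut = 13.8;  // rate factor below exp(-13.8) ~ 1e-6 ignored
  const double scan_R = scan_radius_nm * 1e-3;
  const double scan_w = (scan_mode == 1) ? 2.0 * M_PI / scan_period_us : 0.0;

  SimRng rng((uint64_t)seed);

  PhotonBuf buf;

  const int n_species = species.size();
  for (int is = 0; is < n_species; ++is) {
    List sp = species[is];
    const int n_em = as<int>(sp["n"]);
    const double D = as<double>(sp["D"]);
    const double B = as<double>(sp["brightness_cps"]);
    const double tau = as<double>(sp["lifetime_ns"]);
    const int color = as<int>(sp["color"]);
    List mo = sp["motion"];
    MotionParams mp;
    mp.kind = as<int>(mo["kind"]);
    mp.domain_radius = as<double>(mo["domain_radius_um"]);
    mp.trap_rate = as<double>(mo["trap_rate_s"]);
    mp.escape_rate = as<double>(mo["escape_rate_s"]);
    mp.d_in = as<double>(mo["d_in"]);
    mp.mesh_size = as<double>(mo["mesh_size_um"]);
    mp.hop_prob = as<double>(mo["hop_prob"]);

    const double mean_per_step = B * dt_s;  // peak photons per step
    const bool green = (color == 0 || color == 2);
    const bool red = (color == 1 || color == 2);

    // lateral radius beyond which emission is negligible (widest volume used)
    const double inv_w2_min = std::min(v5.inv_w2, vse.inv_w2);
    const double r_cut = std::sqrt(qcut / inv_w2_min);
    // coarse stepping thresholds (free motion only)
    const bool can_coarse = (mp.kind == 0) && coarse_far_steps;
    const double sig1 = std::sqrt(2.0 * D * dt_s);
    const double thr64 = r_cut + scan_R + 5.0 * sig1 * 8.0;    // sqrt(64)
    const double thr512 = r_cut + scan_R + 5.0 * sig1 * 22.7;  // sqrt(512)

    for (int ie = 0; ie < n_em; ++ie) {
      EmitterState e;
      e.x = (rng.unif() - 0.5) * box_x;
      e.y = (rng.unif() - 0.5) * box_y;
      e.z = (rng.unif() - 0.5) * box_z;
      e.trapped = false;
      e.cx = e.cy = e.cz = 0.0;

      long step = 0;
      while (step < n_steps) {
        const double rlat = std::sqrt(e.x * e.x + e.y * e.y);
        long K = 1;
        if (can_coarse) {
          if (rlat > thr512 && step + 512 <= n_steps) K = 512;
          else if (rlat > thr64 && step + 64 <= n_steps) K = 64;
        }
        if (K == 1) {
          // emission from the position at step start
          double cx = 0.0, cy = 0.0;
          if (scan_mode == 1) {
            const double ph = scan_w * (step * dt_us);
            cx = scan_R * std::cos(ph);
            cy = scan_R * std::sin(ph);
          }
          const double dx = e.x - cx, dy = e.y - cy;
          const double r2 = dx * dx + dy * dy, z2 = e.z * e.z;
          if (green) {
            const double q = r2 * v5.inv_w2 + z2 * v5.inv_z2;
            if (q < qcut && mean_per_step > 0) {
              const double mu = mean_per_step * std::exp(-q);
              int n_ph = rng.pois(mu);
              for (int ip = 0; ip < n_ph; ++ip) {
                const double t = (step * dt_ns) + rng.unif() * dt_ns;
                int ch;
                if (rng.unif() < std::exp(-(r2 * d3_w + z2 * d3_z))) {
                  if (rng.unif() < std::exp(-(r2 * dc_w + z2 * dc_z))) {
                    ch = 12;
                  } else {
                    ch = RING8[(int)(rng.unif() * 8.0) & 7];
                  }
                } else {
                  ch = RING16[(int)(rng.unif() * 16.0) % 16];
                }
                buf.t_ns.push_back(t);
                buf.channel.push_back(ch);
                buf.micro_ns.push_back(draw_microtime(
                    tau, irf_offset_ns, irf_sigma_ns, rep_period_ns, rng));
              }
            }
          }
          if (red) {
            const double q = r2 * vse.inv_w2 + z2 * vse.inv_z2;
            if (q < qcut && mean_per_step > 0) {
              const double mu = mean_per_step * std::exp(-q);
              int n_ph = rng.pois(mu);
              for (int ip = 0; ip < n_ph; ++ip) {
                const double t = (step * dt_ns) + rng.unif() * dt_ns;
                buf.t_ns.push_back(t);
                buf.channel.push_back(25);
                buf.micro_ns.push_back(draw_microtime(
                    tau, irf_offset_ns, irf_sigma_ns, rep_period_ns, rng));
              }
            }
          }
        }
        step_emitter(e, D, mp, K * dt_s, box_x, box_y, box_z, rng);
        step += K;
      }
      if (ie % 16 == 0) Rcpp::checkUserInterrupt();
    }
  }

  // time-order the union of all emitters' photons
  const size_t n = buf.t_ns.size();
  std::vector<size_t> idx(n);
  for (size_t i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    return buf.t_ns[a] < buf.t_ns[b];
  });
  NumericVector t_out(n), m_out(n);
  IntegerVector ch_out(n);
  for (size_t i = 0; i < n; ++i) {
    t_out[i] = buf.t_ns[idx[i]];
    ch_out[i] = buf.channel[idx[i]];
    m_out[i] = buf.micro_ns[idx[i]];
  }
  return List::create(_["t_ns"] = t_out, _["channel"] = ch_out,
                      _["microtime_ns"] = m_out);
}

// Explicit trajectory simulation: returns n_keep x n_emitters x 3 positions
// (um), recorded every `stride` steps.
// [[Rcpp::export]]
NumericVector cpp_simulate_trajectories(int n_emitters, double D, List motion,
                                        double box_x, double box_y,
                                        double box_z, double dt_us,
                                        long n_steps, int stride,
                                        double seed) {
  MotionParams mp;
  mp.kind = as<int>(motion["kind"]);
  mp.domain_radius = as<double>(motion["domain_radius_um"]);
  mp.trap_rate = as<double>(motion["trap_rate_s"]);
  mp.escape_rate = as<double>(motion["escape_rate_s"]);
  mp.d_in = as<double>(motion["d_in"]);
  mp.mesh_size = as<double>(motion["mesh_size_um"]);
  mp.hop_prob = as<double>(motion["hop_prob"]);

  SimRng rng((uint64_t)seed);
  const double dt_s = dt_us * 1e-6;

  const long n_keep = n_steps / stride + 1;
  NumericVector out(n_keep * n_emitters * 3);
  out.attr("dim") = IntegerVector::create((int)n_keep, n_emitters, 3);

  for (int ie = 0; ie < n_emitters; ++ie) {
    EmitterState e;
    e.x = (rng.unif() - 0.5) * box_x;
    e.y = (rng.unif() - 0.5) * box_y;
    e.z = (rng.unif() - 0.5) * box_z;
    e.trapped = false;
    e.cx = e.cy = e.cz = 0.0;
    for (long s = 0; s <= n_steps; ++s) {
      if (s % stride == 0) {
        const long r = s / stride;
        out[r + (long)ie * n_keep + 0L * n_keep * n_emitters] = e.x;
        out[r + (long)ie * n_keep + 1L * n_keep * n_emitters] = e.y;
        out[r + (long)ie * n_keep + 2L * n_keep * n_emitters] = e.z;
      }
      if (s < n_steps)
        step_emitter(e, D, mp, dt_s, box_x, box_y, box_z, rng);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Photon emission from explicit trajectories (positions: n_steps x n_em x 3,
// um, recorded at every step). Same detection and microtime model as the
// fused path.
// [[Rcpp::export]]
List cpp_emit_photons(NumericVector positions, double dt_us,
                      NumericVector waists_nm, NumericVector ecc,
                      double brightness_cps, double lifetime_ns, int color,
                      double rep_period_ns, double irf_sigma_ns,
                      double irf_offset_ns, double seed) {
  IntegerVector dim = positions.attr("dim");
  const long n_steps = dim[0];
  const int n_em = dim[1];
  const double dt_s = dt_us * 1e-6, dt_ns = dt_us * 1e3;

  const Volume v5 = make_volume(waists_nm[2], ecc[2]);
  const Volume v3 = make_volume(waists_nm[1], ecc[1]);
  const Volume vc = make_volume(waists_nm[0], ecc[0]);
  const Volume vse = make_volume(waists_nm[3], ecc[3]);
  const double d3_w = v3.inv_w2 - v5.inv_w2, d3_z = v3.inv_z2 - v5.inv_z2;
  const double dc_w = vc.inv_w2 - v3.inv_w2, dc_z = vc.inv_z2 - v3.inv_z2;
  const double qcut = 13.8;
  const double mean_per_step = brightness_cps * dt_s;
  const bool green = (color == 0 || color == 2);
  const bool red = (color == 1 || color == 2);

  SimRng rng((uint64_t)seed);

  PhotonBuf buf;
  for (int ie = 0; ie < n_em; ++ie) {
    for (long s = 0; s < n_steps; ++s) {
      const double x = positions[s + (long)ie * n_steps];
      const double y = positions[s + (long)ie * n_steps +
                                 1L * n_steps * n_em];
      const double z = positions[s + (long)ie * n_steps +
                                 2L * n_steps * n_em];
      const double r2 = x * x + y * y, z2 = z * z;
      if (green) {
        const double q = r2 * v5.inv_w2 + z2 * v5.inv_z2;
        if (q < qcut && mean_per_step > 0) {
          const double mu = mean_per_step * std::exp(-q);
          int n_ph = rng.pois(mu);
          for (int ip = 0; ip < n_ph; ++ip) {
            const double t = s * dt_ns + rng.unif() * dt_ns;
            int ch;
            if (rng.unif() < std::exp(-(r2 * d3_w + z2 * d3_z))) {
              ch = (rng.unif() < std::exp(-(r2 * dc_w + z2 * dc_z)))
                       ? 12
                       : RING8[(int)(rng.unif() * 8.0) & 7];
            } else {
              ch = RING16[(int)(rng.unif() * 16.0) % 16];
            }
            buf.t_ns.push_back(t);
            buf.channel.push_back(ch);
            buf.micro_ns.push_back(
                draw_microtime(lifetime_ns, irf_offset_ns, irf_sigma_ns,
                               rep_period_ns, rng));
          }
        }
      }
      if (red) {
        const double q = r2 * vse.inv_w2 + z2 * vse.inv_z2;
        if (q < qcut && mean_per_step > 0) {
          const double mu = mean_per_step * std::exp(-q);
          int n_ph = rng.pois(mu);
          for (int ip = 0; ip < n_ph; ++ip) {
            buf.t_ns.push_back(s * dt_ns + rng.unif() * dt_ns);
            buf.channel.push_back(25);
            buf.micro_ns.push_back(
                draw_microtime(lifetime_ns, irf_offset_ns, irf_sigma_ns,
                               rep_period_ns, rng));
          }
        }
      }
    }
  }
  const size_t n = buf.t_ns.size();
  std::vector<size_t> idx(n);
  for (size_t i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    return buf.t_ns[a] < buf.t_ns[b];
  });
  NumericVector t_out(n), m_out(n);
  IntegerVector ch_out(n);
  for (size_t i = 0; i < n; ++i) {
    t_out[i] = buf.t_ns[idx[i]];
    ch_out[i] = buf.channel[idx[i]];
    m_out[i] = buf.micro_ns[idx[i]];
  }
  return List::create(_["t_ns"] = t_out, _["channel"] = ch_out,
                      _["microtime_ns"] = m_out);
}
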