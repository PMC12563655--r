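// Overdamped Langevin (Brownian) dynamics of rigid multivalent anions in a
// fixed charged-nanoparticle lattice under a uniform field.
//
// Reduced units: length nm, energy kBT, time set by the per-bead friction.
// Interactions: per-bead field force q_b*E, screened Coulomb (Yukawa) with
// cutoff 4*debye_length, WCA repulsion with cutoff 2^(1/6)*sigma, and a
// Gaussian interfacial adsorption well centered at the bead-NP contact
// distance. Intra-anion bead pairs are excluded (rigid bodies).
//
// RNG: R's generator via norm_rand(), so set.seed() in R makes runs
// bit-reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double mi(double d, double L) {
  // minimum-image component for an orthorhombic box
  return d - L * std::round(d / L);
}

struct Pars {
  double kBT, gamma_bead, sigma, wca_eps, bjerrum, debye, ads_range;
  std::vector<double> ads_depth; // per-NP well depth (site-class scaled)
  double ads_depth_max;
  double efield[3];   // reduced force per unit charge (kBT/(e nm))
  double np_radius;
};

// rotation matrix from unit quaternion (w, x, y, z), row-major R[3][3]
static void quat_to_mat(const double* q, double R[3][3]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - w * z); R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y); R[2][1] = 2 * (y * z + w * x); R[2][2] = 1 - 2 * (x * x + y * y);
}

// q_out = rot(v) * q_in, rotation by vector v (axis*angle), lab frame
static void rotate_quat(const double* v, const double* q, double* out) {
  double th = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  double r[4];
  if (th < 1e-14) { r[0] = 1; r[1] = r[2] = r[3] = 0; }
  else {
    double s = std::sin(0.5 * th) / th;
    r[0] = std::cos(0.5 * th); r[1] = v[0] * s; r[2] = v[1] * s; r[3] = v[2] * s;
  }
  out[0] = r[0] * q[0] - r[1] * q[1] - r[2] * q[2] - r[3] * q[3];
  out[1] = r[0] * q[1] + r[1] * q[0] + r[2] * q[3] - r[3] * q[2];
  out[2] = r[0] * q[2] - r[1] * q[3] + r[2] * q[0] + r[3] * q[1];
  out[3] = r[0] * q[3] + r[1] * q[2] - r[2] * q[1] + r[3] * q[0];
  double n = std::sqrt(out[0] * out[0] + out[1] * out[1] + out[2] * out[2] + out[3] * out[3]);
  for (int k = 0; k < 4; ++k) out[k] /= n;
}

// Accumulate pair interaction (Yukawa + WCA) between a bead at displacement
// d (bead minus partner, minimum image), charges qprod, steric sigma s.
// Adds force on the bead into f[3] and energy into *u. Returns false on
// hard-core blowup.
static bool pair_force(const double* d, double r2, double qprod, double s,
                       const Pars& P, double* f, double* u) {
  double r = std::sqrt(r2);
  if (r < 0.1 * P.sigma) return false;
  double yuk_cut = 4.0 * P.debye;
  if (P.bjerrum > 0 && qprod != 0 && r < yuk_cut) {
    double k = P.bjerrum * qprod;
    double ex = std::exp(-r / P.debye);
    *u += k * ex / r;
    double fmag = k * ex * (1.0 / r2 + 1.0 / (P.debye * r)); // -dU/dr
    for (int a = 0; a < 3; ++a) f[a] += fmag * d[a] / r;
  }
  double wca_cut = 1.122462048309373 * s; // 2^(1/6) sigma
  if (P.wca_eps > 0 && r < wca_cut) {
    double sr2 = (s * s) / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
    *u += 4.0 * P.wca_eps * (sr12 - sr6) + P.wca_eps;
    double fmag = 24.0 * P.wca_eps * (2.0 * sr12 - sr6) / r;
    for (int a = 0; a < 3; ++a) f[a] += fmag * d[a] / r;
  }
  return true;
}

// Full force/torque/energy evaluation.
// bead_pos: (n*nb) x 3 workspace filled with lab-frame bead positions.
static bool eval_forces(const NumericMatrix& centers, const NumericMatrix& quats,
                        const NumericMatrix& body, const NumericVector& bead_q,
                        const NumericMatrix& np_pos, const NumericVector& np_q,
                        const NumericVector& box, const Pars& P,
                        std::vector<double>& bead_pos,
                        NumericMatrix& force, NumericMatrix& torque,
                        double* energy) {
  int n = centers.nrow(), nb = body.nrow(), nnp = np_pos.nrow();
  double R[3][3], q[4];
  *energy = 0.0;
  std::fill(force.begin(), force.end(), 0.0);
  std::fill(torque.begin(), torque.end(), 0.0);
  std::vector<double> bead_f(3 * n * nb, 0.0);

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 4; ++k) q[k] = quats(i, k);
    quat_to_mat(q, R);
    for (int b = 0; b < nb; ++b)
      for (int a = 0; a < 3; ++a)
        bead_pos[3 * (i * nb + b) + a] = centers(i, a) +
          R[a][0] * body(b, 0) + R[a][1] * body(b, 1) + R[a][2] * body(b, 2);
  }

  double rc_ads = P.np_radius + 0.5 * P.sigma;   // well center at contact
  double sigma_bn = P.np_radius + 0.5 * P.sigma; // bead-NP steric contact
  // outer cutoffs for cheap r^2 rejection before any sqrt/exp
  double yuk_cut = (P.bjerrum > 0) ? 4.0 * P.debye : 0.0;
  double cut_bb = std::max(yuk_cut, 1.122462048309373 * P.sigma);
  double cut_bb2 = cut_bb * cut_bb;
  double cut_bn = std::max(std::max(yuk_cut, 1.122462048309373 * sigma_bn),
                           (P.ads_depth_max > 0) ? rc_ads + 4.0 * P.ads_range : 0.0);
  double cut_bn2 = cut_bn * cut_bn;

  for (int i = 0; i < n; ++i) {
    for (int b = 0; b < nb; ++b) {
      int ib = i * nb + b;
      double* f = &bead_f[3 * ib];
      const double* x = &bead_pos[3 * ib];
      double qb = bead_q[b];
      // uniform field
      for (int a = 0; a < 3; ++a) f[a] += qb * P.efield[a];
      *energy -= qb * (P.efield[0] * x[0] + P.efield[1] * x[1] + P.efield[2] * x[2]);
      // lattice NPs
      for (int k = 0; k < nnp; ++k) {
        double d[3];
        for (int a = 0; a < 3; ++a) d[a] = mi(x[a] - np_pos(k, a), box[a]);
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        if (r2 > cut_bn2) continue;
        if (!pair_force(d, r2, qb * np_q[k], sigma_bn, P, f, energy)) return false;
        if (P.ads_depth[k] > 0) {
          double r = std::sqrt(r2);
          double dr = r - rc_ads;
          if (std::fabs(dr) < 4.0 * P.ads_range && r > 1e-12) {
            double w2 = P.ads_range * P.ads_range;
            double g = std::exp(-dr * dr / (2.0 * w2));
            *energy -= P.ads_depth[k] * g;
            double fmag = -P.ads_depth[k] * g * dr / w2; // -dU/dr
            for (int a = 0; a < 3; ++a) f[a] += fmag * d[a] / r;
          }
        }
      }
    }
  }

  // anion-anion bead pairs (intra-anion excluded); whole molecule pairs are
  // rejected on center distance first
  double ext = 0.0;
  for (int b = 0; b < nb; ++b)
    ext = std::max(ext, std::sqrt(body(b, 0) * body(b, 0) +
                                  body(b, 1) * body(b, 1) +
                                  body(b, 2) * body(b, 2)));
  double cut_cc = cut_bb + 2.0 * ext;
  double cut_cc2 = cut_cc * cut_cc;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dc[3];
      for (int a = 0; a < 3; ++a)
        dc[a] = mi(centers(i, a) - centers(j, a), box[a]);
      if (dc[0] * dc[0] + dc[1] * dc[1] + dc[2] * dc[2] > cut_cc2) continue;
      for (int bi = 0; bi < nb; ++bi)
        for (int bj = 0; bj < nb; ++bj) {
          int ib = i * nb + bi, jb = j * nb + bj;
          double d[3];
          for (int a = 0; a < 3; ++a)
            d[a] = mi(bead_pos[3 * ib + a] - bead_pos[3 * jb + a], box[a]);
          double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
          if (r2 > cut_bb2) continue;
          double fij[3] = {0, 0, 0};
          if (!pair_force(d, r2, bead_q[bi] * bead_q[bj], P.sigma, P, fij, energy))
            return false;
          for (int a = 0; a < 3; ++a) {
            bead_f[3 * ib + a] += fij[a];
            bead_f[3 * jb + a] -= fij[a];
          }
        }
    }

  // reduce bead forces to center forces and torques about the center
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 4; ++k) q[k] = quats(i, k);
    quat_to_mat(q, R);
    for (int b = 0; b < nb; ++b) {
      int ib = i * nb + b;
      double rrel[3];
      for (int a = 0; a < 3; ++a)
        rrel[a] = R[a][0] * body(b, 0) + R[a][1] * body(b, 1) + R[a][2] * body(b, 2);
      const double* f = &bead_f[3 * ib];
      for (int a = 0; a < 3; ++a) force(i, a) += f[a];
      torque(i, 0) += rrel[1] * f[2] - rrel[2] * f[1];
      torque(i, 1) += rrel[2] * f[0] - rrel[0] * f[2];
      torque(i, 2) += rrel[0] * f[1] - rrel[1] * f[0];
    }
  }
  return true;
}

static Pars make_pars(const List& pars) {
  Pars P;
  P.kBT = as<double>(pars["kBT"]);
  P.gamma_bead = as<double>(pars["gamma_bead"]);
  P.sigma = as<double>(pars["sigma"]);
  P.wca_eps = as<double>(pars["wca_epsilon"]);
  P.bjerrum = as<double>(pars["bjerrum"]);
  P.debye = as<double>(pars["debye"]);
  P.ads_depth = as<std::vector<double> >(pars["ads_depth"]);
  P.ads_depth_max = 0.0;
  for (double d : P.ads_depth) P.ads_depth_max = std::max(P.ads_depth_max, d);
  P.ads_range = as<double>(pars["ads_range"]);
  P.np_radius = as<double>(pars["np_radius"]);
  NumericVector ef = pars["efield"];
  for (int a = 0; a < 3; ++a) P.efield[a] = ef[a];
  return P;
}

// [[Rcpp::export]]
List bd_forces_cpp(NumericMatrix centers, NumericMatrix quats,
                   NumericMatrix body, NumericVector bead_q,
                   NumericMatrix np_pos, NumericVector np_q,
                   NumericVector box, List pars) {
  int n = centers.nrow(), nb = body.nrow();
  Pars P = make_pars(pars);
  NumericMatrix force(n, 3), torque(n, 3);
  std::vector<double> bead_pos(3 * n * nb);
  double energy = 0.0;
  bool ok = eval_forces(centers, quats, body, bead_q, np_pos, np_q, box, P,
                        bead_pos, force, torque, &energy);
  if (!ok)
    stop("bead overlap below hard floor (pair distance < 0.1*sigma): "
         "reduce the timestep");
  NumericMatrix bp(n * nb, 3);
  for (int ib = 0; ib < n * nb; ++ib)
    for (int a = 0; a < 3; ++a) bp(ib, a) = bead_pos[3 * ib + a];
  return List::create(_["force"] = force, _["torque"] = torque,
                      _["energy"] = energy, _["bead_positions"] = bp);
}

// [[Rcpp::export]]
List bd_run_cpp(NumericMatrix centers0, NumericMatrix quats0,
                NumericMatrix body, NumericVector bead_q,
                NumericMatrix np_pos, NumericVector np_q,
                NumericVector box, List pars,
                double dt, int n_steps, int save_every, bool save_beads) {
  int n = centers0.nrow(), nb = body.nrow();
  Pars P = make_pars(pars);

  NumericMatrix centers = clone(centers0), quats = clone(quats0);
  IntegerMatrix wraps(n, 3);
  NumericMatrix force(n, 3), torque(n, 3);
  std::vector<double> bead_pos(3 * n * nb);
  double energy;

  double mu = 1.0 / (nb * P.gamma_bead);          // translational mobility
  double Dt = P.kBT * mu;
  double inertia = 0.0;
  for (int b = 0; b < nb; ++b)
    inertia += body(b, 0) * body(b, 0) + body(b, 1) * body(b, 1) + body(b, 2) * body(b, 2);
  double gamma_r = P.gamma_bead * inertia;        // isotropic rotational drag
  bool rotate = inertia > 1e-12;
  double Dr = rotate ? P.kBT / gamma_r : 0.0;
  double step_noise = std::sqrt(2.0 * Dt * dt);
  double rot_noise = rotate ? std::sqrt(2.0 * Dr * dt) : 0.0;
  double max_step = 0.25 * std::min(box[0], std::min(box[1], box[2]));
  // Deterministic-drift clamp: steep WCA contacts occasionally produce very
  // large forces under explicit Euler; capping the drift displacement at
  // 0.1*sigma per step (far above any physical drift here) keeps overlap
  // recovery stable without touching ordinary dynamics.
  double drift_cap = 0.1 * P.sigma;
  double rot_cap = 0.2; // rad

  int n_frames = n_steps / save_every + 1;
  NumericVector out_centers(n_frames * n * 3);
  IntegerVector out_wraps(n_frames * n * 3);
  NumericVector out_times(n_frames);
  NumericVector out_beads(save_beads ? n_frames * n * nb * 3 : 0);

  int frame = 0;
  auto save_frame = [&](double t) {
    out_times[frame] = t;
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a) {
        out_centers[frame * n * 3 + a * n + i] = centers(i, a);
        out_wraps[frame * n * 3 + a * n + i] = wraps(i, a);
      }
    if (save_beads) {
      double R[3][3], q[4];
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < 4; ++k) q[k] = quats(i, k);
        quat_to_mat(q, R);
        for (int b = 0; b < nb; ++b)
          for (int a = 0; a < 3; ++a)
            out_beads[frame * n * nb * 3 + a * n * nb + (i * nb + b)] =
              centers(i, a) +
              R[a][0] * body(b, 0) + R[a][1] * body(b, 1) + R[a][2] * body(b, 2);
      }
    }
    ++frame;
  };
  save_frame(0.0);

  for (int s = 1; s <= n_steps; ++s) {
    bool ok = eval_forces(centers, quats, body, bead_q, np_pos, np_q, box, P,
                          bead_pos, force, torque, &energy);
    if (!ok)
      stop("integration blow-up at step %d: bead pair below hard floor; "
           "reduce the timestep", s);
    for (int i = 0; i < n; ++i) {
      double drift[3];
      double dn = 0.0;
      for (int a = 0; a < 3; ++a) {
        drift[a] = mu * force(i, a) * dt;
        dn += drift[a] * drift[a];
      }
      dn = std::sqrt(dn);
      if (dn > drift_cap)
        for (int a = 0; a < 3; ++a) drift[a] *= drift_cap / dn;
      for (int a = 0; a < 3; ++a) {
        double dx = drift[a] + step_noise * norm_rand();
        if (std::fabs(dx) > max_step)
          stop("single-step displacement %g nm exceeds box/4 at step %d: "
               "timestep too large", dx, s);
        double c = centers(i, a) + dx;
        while (c < 0) { c += box[a]; wraps(i, a) -= 1; }
        while (c >= box[a]) { c -= box[a]; wraps(i, a) += 1; }
        centers(i, a) = c;
      }
      if (rotate) {
        double v[3], qn[4], q[4];
        double det[3], tn = 0.0;
        for (int a = 0; a < 3; ++a) {
          det[a] = torque(i, a) / gamma_r * dt;
          tn += det[a] * det[a];
        }
        tn = std::sqrt(tn);
        if (tn > rot_cap)
          for (int a = 0; a < 3; ++a) det[a] *= rot_cap / tn;
        for (int a = 0; a < 3; ++a)
          v[a] = det[a] + rot_noise * norm_rand();
        for (int k = 0; k < 4; ++k) q[k] = quats(i, k);
        rotate_quat(v, q, qn);
        for (int k = 0; k < 4; ++k) quats(i, k) = qn[k];
      }
    }
    if (s % save_every == 0) save_frame(s * dt);
  }

  out_centers.attr("dim") = IntegerVector::create(n, 3, n_frames);
  out_wraps.attr("dim") = IntegerVector::create(n, 3, n_frames);
  List out = List::create(
    _["centers"] = out_centers, _["wrap_counts"] = out_wraps,
    _["times"] = out_times, _["quats"] = quats);
  if (save_beads) {
    out_beads.attr("dim") = IntegerVector::create(n * nb, 3, n_frames);
    out["beads"] = out_beads;
  }
  return out;
}
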