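// Core numerics: lambda-coupled toy landscapes, BAOAB Langevin integration,
// Gibbs reference-point moves and the shared-bias AWH loop. Units are
// kJ/mol, nm, ps throughout; conversion to experimental units happens in R.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-free deterministic RNG: per-walker xoshiro256++ streams seeded via
// splitmix64 of (run seed, walker id). std:: distributions are avoided so
// results are bit-identical across platforms/compilers.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  bool has_cached;
  double cached;

  void seed(uint64_t run_seed, uint64_t stream_id) {
    uint64_t x = run_seed ^ (0x9e3779b97f4a7c15ULL * (stream_id + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    has_cached = false;
    cached = 0.0;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // standard normal, Box-Muller (deterministic, cached pair)
  double norm() {
    if (has_cached) { has_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    cached = r * std::sin(a);
    has_cached = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// Landscape: membrane free-energy profile as a sum of Gaussian components on
// top of a constant solvent level, an optional slow orientational degree of
// freedom theta, and a soft-core alchemical coupling with a single scalar
// lambda scaling all permeant-environment terms simultaneously.
// ---------------------------------------------------------------------------

struct Landscape {
  double L;
  int boundary;            // 0 reflective, 1 periodic
  double solvent_level;
  std::vector<double> gh, gc, gw;  // Gaussian heights (signed), centers, widths
  int theta_mode;          // 0 none, 1 cosine trap, 2 harmonic
  double trap_depth;       // favourable-orientation depth (kJ/mol), cosine mode
  double trap_barrier;     // orientational barrier (kJ/mol), cosine mode
  double trap_c, trap_w;   // Gaussian envelope of the trap along z
  double theta_k;          // spring constant, harmonic mode (kJ/mol/rad^2)
  double sc_alpha, sc_sigma, sc_eps;
  std::vector<double> lambdas;

  static Landscape from_list(const List &land) {
    Landscape l;
    l.L = as<double>(land["L"]);
    l.boundary = as<std::string>(land["boundary"]) == "periodic" ? 1 : 0;
    l.solvent_level = as<double>(land["solvent_level"]);
    NumericVector h = land["gauss_height"], c = land["gauss_center"],
                  w = land["gauss_width"];
    l.gh = std::vector<double>(h.begin(), h.end());
    l.gc = std::vector<double>(c.begin(), c.end());
    l.gw = std::vector<double>(w.begin(), w.end());
    l.theta_mode = as<int>(land["theta_mode"]);
    l.trap_depth = as<double>(land["trap_depth"]);
    l.trap_barrier = as<double>(land["trap_barrier"]);
    l.trap_c = as<double>(land["trap_center"]);
    l.trap_w = as<double>(land["trap_width"]);
    l.theta_k = as<double>(land["theta_k"]);
    List sc = land["softcore"];
    l.sc_alpha = as<double>(sc["alpha"]);
    l.sc_sigma = as<double>(sc["sigma"]);
    l.sc_eps = as<double>(sc["epsilon"]);
    NumericVector lv = land["lambda_values"];
    l.lambdas = std::vector<double>(lv.begin(), lv.end());
    return l;
  }

  // repulsive (positive Gaussians) and attractive/linear (solvent level +
  // negative Gaussians) parts of the environment interaction, with d/dz
  void env_parts(double z, double &erep, double &derep,
                 double &eatt, double &deatt) const {
    erep = 0.0; derep = 0.0; eatt = solvent_level; deatt = 0.0;
    for (size_t i = 0; i < gh.size(); ++i) {
      double u = (z - gc[i]) / gw[i];
      double g = gh[i] * std::exp(-0.5 * u * u);
      double dg = -g * u / gw[i];
      if (gh[i] > 0) { erep += g; derep += dg; }
      else           { eatt += g; deatt += dg; }
    }
  }

  // orientational term at full coupling, with partials
  void theta_parts(double z, double theta, double &eth,
                   double &dethdz, double &dethdth) const {
    eth = 0.0; dethdz = 0.0; dethdth = 0.0;
    if (theta_mode == 0) return;
    if (theta_mode == 2) {
      eth = 0.5 * theta_k * theta * theta;
      dethdth = theta_k * theta;
      return;
    }
    double u = (z - trap_c) / trap_w;
    double env = std::exp(-0.5 * u * u);
    double denv = -env * u / trap_w;
    double st = std::sin(theta), ct = std::cos(theta);
    double shape = 0.5 * trap_depth * (ct - 1.0) + trap_barrier * st * st;
    double dshape = -0.5 * trap_depth * st + 2.0 * trap_barrier * st * ct;
    eth = env * shape;
    dethdz = denv * shape;
    dethdth = env * dshape;
  }

  // Beutler-style soft-core applied to the repulsive part, mapping the full
  // repulsive energy E to an effective inverse-12 pair distance via
  // E = eps (sigma/r)^12; V = (1-lam) eps sigma^12 / (alpha sigma^6 lam + r^6)^2.
  // Algebraically V = (1-lam) eps / (alpha lam + sqrt(eps/E))^2.
  double softcore(double E, double lam, double &dVdE) const {
    if (lam >= 1.0) { dVdE = 0.0; return 0.0; }
    if (E < 1e-12) { dVdE = (1.0 - lam); return (1.0 - lam) * E; }
    double s = std::sqrt(sc_eps / E);
    double den = sc_alpha * lam + s;
    double V = (1.0 - lam) * sc_eps / (den * den);
    dVdE = (1.0 - lam) * std::pow(sc_eps, 1.5) *
           std::pow(E, -1.5) / (den * den * den);
    return V;
  }

  double potential(double z, double theta, int lam_idx,
                   double *fz = nullptr, double *fth = nullptr) const {
    double lam = lambdas[lam_idx];
    double erep, derep, eatt, deatt, eth, dethdz, dethdth;
    env_parts(z, erep, derep, eatt, deatt);
    theta_parts(z, theta, eth, dethdz, dethdth);
    double dVdE;
    double vrep = softcore(erep, lam, dVdE);
    double u = vrep + (1.0 - lam) * (eatt + eth);
    if (fz)  *fz  = -(dVdE * derep + (1.0 - lam) * (deatt + dethdz));
    if (fth) *fth = -(1.0 - lam) * dethdth;
    return u;
  }
};

// map z back into the landscape domain; reflective flips velocity
static inline void apply_boundary(const Landscape &l, double &z, double &v) {
  if (l.boundary == 1) {
    z -= l.L * std::floor(z / l.L);
  } else {
    while (z < 0.0 || z > l.L) {
      if (z < 0.0) { z = -z; v = -v; }
      if (z > l.L) { z = 2.0 * l.L - z; v = -v; }
    }
  }
}

static inline void wrap_theta(double &th) {
  const double pi = 3.14159265358979323846;
  while (th >= pi) th -= 2.0 * pi;
  while (th < -pi) th += 2.0 * pi;
}

// [[Rcpp::export]]
NumericVector potential_cpp(List land, NumericVector z, NumericVector theta,
                            int lam_idx) {
  Landscape l = Landscape::from_list(land);
  if (lam_idx < 0 || lam_idx >= (int)l.lambdas.size())
    stop("lambda index out of range");
  R_xlen_t n = z.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double th = theta.size() == n ? theta[i] : theta[0];
    out[i] = l.potential(z[i], th, lam_idx);
  }
  return out;
}

// [[Rcpp::export]]
List potential_force_cpp(List land, double z, double theta, int lam_idx) {
  Landscape l = Landscape::from_list(land);
  double fz, fth;
  double u = l.potential(z, theta, lam_idx, &fz, &fth);
  return List::create(_["energy"] = u, _["force_z"] = fz,
                      _["force_theta"] = fth);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin step (velocity Langevin): exact Ornstein-Uhlenbeck kick in
// the O-substep gives exact fluctuation-dissipation for the free particle.
// ---------------------------------------------------------------------------

struct Integrator {
  double dt, gamma, mass, kT;
  double c1, c2, sv;
  void init(double dt_, double gamma_, double mass_, double kT_) {
    dt = dt_; gamma = gamma_; mass = mass_; kT = kT_;
    c1 = std::exp(-gamma * dt);
    c2 = std::sqrt(1.0 - c1 * c1);
    sv = std::sqrt(kT / mass);
  }
};

struct Walker {
  double z, v, theta, vth;
  int jref, lref;
  Rng rng;
  double fz, fth;       // cached forces (potential part only)
  // covering bookkeeping (since last covering reset)
  double zvis_lo, zvis_hi;
  std::vector<uint8_t> lam_vis;
  std::vector<uint8_t> pt_vis;
};

// one BAOAB step for a walker; umbrella force -k (z - zref) added to fz
static inline void baoab_step(Walker &w, const Landscape &land,
                              const Integrator &ig, double k_umb,
                              double zref, double f_ext, int lam_idx) {
  double fz = w.fz - k_umb * (w.z - zref) + f_ext;
  w.v += 0.5 * ig.dt * fz / ig.mass;
  w.vth += 0.5 * ig.dt * w.fth / ig.mass;
  w.z += 0.5 * ig.dt * w.v;
  w.theta += 0.5 * ig.dt * w.vth;
  w.v = ig.c1 * w.v + ig.c2 * ig.sv * w.rng.norm();
  w.vth = ig.c1 * w.vth + ig.c2 * ig.sv * w.rng.norm();
  w.z += 0.5 * ig.dt * w.v;
  w.theta += 0.5 * ig.dt * w.vth;
  apply_boundary(land, w.z, w.v);
  wrap_theta(w.theta);
  w.fz = 0.0; w.fth = 0.0;
  land.potential(w.z, w.theta, lam_idx, &w.fz, &w.fth);
  fz = w.fz - k_umb * (w.z - zref) + f_ext;
  if (!std::isfinite(fz) || std::fabs(fz) > 1e12)
    stop("force overflow in Langevin step");
  w.v += 0.5 * ig.dt * fz / ig.mass;
  w.vth += 0.5 * ig.dt * w.fth / ig.mass;
}

// Plain (optionally umbrella-restrained) Langevin run at fixed lambda.
// Returns a matrix with columns t, z, v, theta, vtheta sampled every
// record_every steps.
// [[Rcpp::export]]
NumericMatrix langevin_run_cpp(List land, int lam_idx, int n_steps,
                               double dt, double gamma, double mass,
                               double kT, double seed,
                               double z0, double v0, double theta0,
                               double vtheta0, int record_every,
                               double k_umb, double z_ref, double f_ext) {
  Landscape l = Landscape::from_list(land);
  if (lam_idx < 0 || lam_idx >= (int)l.lambdas.size())
    stop("lambda index out of range");
  Integrator ig; ig.init(dt, gamma, mass, kT);
  Walker w;
  w.z = z0; w.v = v0; w.theta = theta0; w.vth = vtheta0;
  w.rng.seed((uint64_t)seed, 0);
  w.fz = 0.0; w.fth = 0.0;
  l.potential(w.z, w.theta, lam_idx, &w.fz, &w.fth);
  int n_rec = n_steps / record_every;
  NumericMatrix out(n_rec, 5);
  int r = 0;
  for (int t = 1; t <= n_steps; ++t) {
    baoab_step(w, l, ig, k_umb, z_ref, f_ext, lam_idx);
    if (t % record_every == 0 && r < n_rec) {
      out(r, 0) = t * dt; out(r, 1) = w.z; out(r, 2) = w.v;
      out(r, 3) = w.theta; out(r, 4) = w.vth;
      ++r;
    }
  }
  colnames(out) = CharacterVector::create("t", "z", "v", "theta", "vtheta");
  return out;
}

// ---------------------------------------------------------------------------
// AWH machinery
// ---------------------------------------------------------------------------

struct Grid {
  double zmin, dz;
  int nz, nlam;
  int npt() const { return nz * nlam; }
  double zj(int j) const { return zmin + j * dz; }
  int bin(double z) const {
    int j = (int)std::lround((z - zmin) / dz);
    if (j < 0) j = 0;
    if (j >= nz) j = nz - 1;
    return j;
  }
  static Grid from_list(const List &g) {
    Grid gr;
    gr.zmin = as<double>(g["z_min"]);
    gr.dz = as<double>(g["z_spacing"]);
    gr.nz = as<int>(g["n_z"]);
    gr.nlam = as<int>(g["n_lambda"]);
    return gr;
  }
};

// Weighted-histogram bias update; shared by the run loop and the exported
// update operation. dW holds accumulated sample weights per point; n is the
// number of samples in the batch. f is re-anchored so min over support is 0.
static void awh_update(std::vector<double> &f, const std::vector<double> &tgt,
                       double &N, const std::vector<double> &dW, double n,
                       double kT) {
  size_t np = f.size();
  for (size_t m = 0; m < np; ++m) {
    if (tgt[m] <= 0.0) continue;
    if (!std::isfinite(dW[m])) stop("non-finite sample weight in bias update");
    f[m] -= kT * std::log((N * tgt[m] + dW[m]) / (N * tgt[m] + n * tgt[m]));
  }
  double fmin = R_PosInf;
  for (size_t m = 0; m < np; ++m)
    if (tgt[m] > 0.0 && f[m] < fmin) fmin = f[m];
  for (size_t m = 0; m < np; ++m)
    if (tgt[m] > 0.0) f[m] -= fmin;
}

// [[Rcpp::export]]
List awh_update_cpp(NumericVector f, NumericVector target, double N,
                    NumericVector dW, double n_samples, double kT) {
  std::vector<double> fv(f.begin(), f.end());
  std::vector<double> tv(target.begin(), target.end());
  std::vector<double> wv(dW.begin(), dW.end());
  double Nv = N;
  awh_update(fv, tv, Nv, wv, n_samples, kT);
  return List::create(_["f"] = NumericVector(fv.begin(), fv.end()),
                      _["N"] = Nv);
}

// Log of the umbrella kernel between walker position z and reference z_m,
// folded at the domain boundaries: reflected dynamics sample the folded
// Gaussian, so the Gibbs weights must use the image sum or spurious free
// energy offsets (~kT log 2) appear at the edge bins.
static inline double log_folded_kernel(const Landscape &l, double beta,
                                       double k_umb, double z, double zm) {
  double e0 = -0.5 * beta * k_umb * (z - zm) * (z - zm);
  double e1, e2;
  if (l.boundary == 1) {  // periodic images
    e1 = -0.5 * beta * k_umb * (z - zm - l.L) * (z - zm - l.L);
    e2 = -0.5 * beta * k_umb * (z - zm + l.L) * (z - zm + l.L);
  } else {                // mirror images across both walls
    e1 = -0.5 * beta * k_umb * (z + zm) * (z + zm);
    e2 = -0.5 * beta * k_umb * (2.0 * l.L - z - zm) * (2.0 * l.L - z - zm);
  }
  double mx = std::max(e0, std::max(e1, e2));
  return mx + std::log(std::exp(e0 - mx) + std::exp(e1 - mx) +
                       std::exp(e2 - mx));
}

// Gibbs weights over candidate reference points (z window x all lambda) for a
// walker at (z, theta) currently governed by lambda index lcur:
//   w(m) = target(m) exp(beta f(m)) K(z, z_m) exp(-beta [U(lam_m) - U(lcur)])
// with K the boundary-folded umbrella kernel.
static void gibbs_weights(const Landscape &l, const Grid &g,
                          const std::vector<double> &f,
                          const std::vector<double> &tgt, double beta,
                          double k_umb, double z, double theta, int lcur,
                          int jlo, int jhi,
                          std::vector<double> &logw, std::vector<int> &idx) {
  logw.clear(); idx.clear();
  double ucur = l.potential(z, theta, lcur);
  std::vector<double> ulam(g.nlam);
  for (int lidx = 0; lidx < g.nlam; ++lidx)
    ulam[lidx] = l.potential(z, theta, lidx);
  std::vector<double> lker(jhi - jlo + 1);
  for (int j = jlo; j <= jhi; ++j)
    lker[j - jlo] = g.nz == 1 ? 0.0
                              : log_folded_kernel(l, beta, k_umb, z, g.zj(j));
  for (int lidx = 0; lidx < g.nlam; ++lidx) {
    for (int j = jlo; j <= jhi; ++j) {
      int m = lidx * g.nz + j;
      if (tgt[m] <= 0.0) continue;
      double lw = std::log(tgt[m]) + beta * f[m] + lker[j - jlo] -
                  beta * (ulam[lidx] - ucur);
      logw.push_back(lw);
      idx.push_back(m);
    }
  }
  if (idx.empty()) stop("no admissible reference point (empty target window)");
}

// [[Rcpp::export]]
List gibbs_move_cpp(List land, List grid, NumericVector f,
                    NumericVector target, double beta, double k_umb,
                    double z, double theta, int lcur, int window_bins,
                    double seed) {
  Landscape l = Landscape::from_list(land);
  Grid g = Grid::from_list(grid);
  std::vector<double> fv(f.begin(), f.end());
  std::vector<double> tv(target.begin(), target.end());
  int jc = g.bin(z);
  int jlo = std::max(0, jc - window_bins);
  int jhi = std::min(g.nz - 1, jc + window_bins);
  std::vector<double> logw; std::vector<int> idx;
  gibbs_weights(l, g, fv, tv, beta, k_umb, z, theta, lcur, jlo, jhi, logw, idx);
  double mx = R_NegInf;
  for (double lw : logw) if (lw > mx) mx = lw;
  if (!std::isfinite(mx)) stop("all Gibbs weights are zero or non-finite");
  double tot = 0.0;
  std::vector<double> w(logw.size());
  for (size_t i = 0; i < logw.size(); ++i) { w[i] = std::exp(logw[i] - mx); tot += w[i]; }
  Rng rng; rng.seed((uint64_t)seed, 1);
  double u = rng.unif() * tot, acc = 0.0;
  size_t pick = w.size() - 1;
  for (size_t i = 0; i < w.size(); ++i) { acc += w[i]; if (u <= acc) { pick = i; break; } }
  int m = idx[pick];
  NumericVector wfull(g.npt());
  for (size_t i = 0; i < w.size(); ++i) wfull[idx[i]] = w[i] / tot;
  return List::create(_["point"] = m + 1,
                      _["z_bin"] = (m % g.nz) + 1,
                      _["lambda_index"] = (m / g.nz) + 1,
                      _["weights"] = wfull);
}

// ---------------------------------------------------------------------------
// Full multi-walker AWH run.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_awh_cpp(List land, List grid, List cfg, int n_steps,
                 NumericVector seeds, NumericVector f_init,
                 NumericVector target, bool freeze_bias,
                 int force_sample_interval, int traj_interval) {
  Landscape l = Landscape::from_list(land);
  Grid g = Grid::from_list(grid);
  int nw = seeds.size();
  int np = g.npt();

  double kT = as<double>(cfg["kT"]);
  double beta = 1.0 / kT;
  double k_umb = as<double>(cfg["force_constant"]);
  int mc_interval = as<int>(cfg["mc_interval"]);
  int samples_per_update = as<int>(cfg["samples_per_update"]);
  double cov_diam = as<double>(cfg["covering_min_diameter"]);
  bool cov_full_lambda = as<bool>(cfg["covering_requires_full_lambda"]);
  double growth = as<double>(cfg["growth_factor"]);
  double N0 = as<double>(cfg["N0"]);
  double dt = as<double>(cfg["dt"]);
  double gamma = as<double>(cfg["friction"]);
  double mass = as<double>(cfg["mass"]);
  bool start_decoupled = as<bool>(cfg["start_decoupled"]);

  Integrator ig; ig.init(dt, gamma, mass, kT);

  // Gibbs window: 4 umbrella sigma, at least one neighbouring bin
  double sig_umb = std::sqrt(kT / k_umb);
  int window_bins = g.nz == 1 ? 0 :
      std::max(1, (int)std::ceil(4.0 * sig_umb / g.dz));

  std::vector<double> f(f_init.begin(), f_init.end());
  std::vector<double> tgt(target.begin(), target.end());
  std::vector<double> dW(np, 0.0), Wtot(np, 0.0);
  double N = N0;
  int stage = 0;  // 0 initial, 1 final
  double total_samples = 0.0, batch_samples = 0.0;
  int covering_count = 0, n_updates = 0;
  long long stage_exit_step = -1;
  std::vector<double> covering_steps;

  double required_diam = std::min(cov_diam, (g.nz - 1) * g.dz);

  std::vector<Walker> walkers(nw);
  for (int w = 0; w < nw; ++w) {
    Walker &wk = walkers[w];
    wk.rng.seed((uint64_t)seeds[w], 17);
    wk.z = g.zmin + wk.rng.unif() * ((g.nz - 1) * g.dz);
    if (g.nz == 1) wk.z = g.zj(0);
    wk.theta = (wk.rng.unif() - 0.5) * 6.283185307179586;
    wk.v = ig.sv * wk.rng.norm();
    wk.vth = ig.sv * wk.rng.norm();
    wk.lref = (start_decoupled && g.nlam > 1) ? g.nlam - 1 : 0;
    wk.jref = g.bin(wk.z);
    wk.fz = 0.0; wk.fth = 0.0;
    l.potential(wk.z, wk.theta, wk.lref, &wk.fz, &wk.fth);
    wk.zvis_lo = R_PosInf; wk.zvis_hi = R_NegInf;
    wk.lam_vis.assign(g.nlam, 0);
    wk.pt_vis.assign(np, 0);
  }

  // force series storage, one block per walker
  bool rec_forces = force_sample_interval > 0;
  int nf = rec_forces ? n_steps / force_sample_interval : 0;
  std::vector<NumericMatrix> fser;
  std::vector<int> frow(nw, 0);
  if (rec_forces)
    for (int w = 0; w < nw; ++w) fser.push_back(NumericMatrix(nf, 4));

  bool rec_traj = traj_interval > 0;
  int nt = rec_traj ? (n_steps / traj_interval) * nw : 0;
  NumericMatrix traj(nt, 6);
  int trow = 0;

  std::vector<double> logw; std::vector<int> idx;

  for (long long t = 1; t <= n_steps; ++t) {
    for (int w = 0; w < nw; ++w) {
      Walker &wk = walkers[w];
      baoab_step(wk, l, ig, k_umb, g.zj(wk.jref), 0.0, wk.lref);
    }

    if (rec_forces && t % force_sample_interval == 0) {
      for (int w = 0; w < nw; ++w) {
        Walker &wk = walkers[w];
        NumericMatrix &m = fser[w];
        int r = frow[w];
        if (r < nf) {
          m(r, 0) = t * dt;
          m(r, 1) = -k_umb * (wk.z - g.zj(wk.jref));
          m(r, 2) = wk.jref + 1;
          m(r, 3) = wk.lref + 1;
          frow[w] = r + 1;
        }
      }
    }

    if (t % mc_interval == 0) {
      for (int w = 0; w < nw; ++w) {
        Walker &wk = walkers[w];
        int jc = g.bin(wk.z);
        int jlo = std::max(0, jc - window_bins);
        int jhi = std::min(g.nz - 1, jc + window_bins);
        gibbs_weights(l, g, f, tgt, beta, k_umb, wk.z, wk.theta, wk.lref,
                      jlo, jhi, logw, idx);
        double mx = R_NegInf;
        for (double lw : logw) if (lw > mx) mx = lw;
        if (!std::isfinite(mx))
          stop("all Gibbs weights are zero or non-finite (walker %d, step %lld)",
               w + 1, t);
        double tot = 0.0;
        size_t nc = logw.size();
        std::vector<double> wv(nc);
        for (size_t i = 0; i < nc; ++i) { wv[i] = std::exp(logw[i] - mx); tot += wv[i]; }
        double u = wk.rng.unif() * tot, acc = 0.0;
        size_t pick = nc - 1;
        for (size_t i = 0; i < nc; ++i) { acc += wv[i]; if (u <= acc) { pick = i; break; } }
        int mpick = idx[pick];
        int lnew = mpick / g.nz, jnew = mpick % g.nz;
        wk.jref = jnew;
        wk.lref = lnew;
        // recompute cached forces under the (possibly new) Hamiltonian
        wk.fz = 0.0; wk.fth = 0.0;
        l.potential(wk.z, wk.theta, wk.lref, &wk.fz, &wk.fth);
        // accumulate normalised Gibbs weights as this walker's sample
        for (size_t i = 0; i < nc; ++i) {
          dW[idx[i]] += wv[i] / tot;
          Wtot[idx[i]] += wv[i] / tot;
        }
        batch_samples += 1.0;
        // covering bookkeeping at the chosen reference point
        double zj = g.zj(jnew);
        if (zj < wk.zvis_lo) wk.zvis_lo = zj;
        if (zj > wk.zvis_hi) wk.zvis_hi = zj;
        wk.lam_vis[lnew] = 1;
        wk.pt_vis[mpick] = 1;
      }

      if (batch_samples >= samples_per_update) {
        total_samples += batch_samples;
        if (!freeze_bias) {
          awh_update(f, tgt, N, dW, batch_samples, kT);
          if (stage == 1) N += batch_samples;
        }
        std::fill(dW.begin(), dW.end(), 0.0);
        batch_samples = 0.0;
        ++n_updates;

        if (stage == 0 && !freeze_bias) {
          // covering check: union over qualifying walkers
          std::vector<uint8_t> cov(np, 0);
          for (int w = 0; w < nw; ++w) {
            Walker &wk = walkers[w];
            bool full_lam = true;
            if (cov_full_lambda && g.nlam > 1)
              for (int lidx = 0; lidx < g.nlam; ++lidx)
                if (!wk.lam_vis[lidx]) { full_lam = false; break; }
            double diam = wk.zvis_hi - wk.zvis_lo;
            bool spatial_ok = g.nz == 1 ||
                (std::isfinite(diam) && diam >= required_diam - 1e-12);
            if (full_lam && spatial_ok)
              for (int m = 0; m < np; ++m) if (wk.pt_vis[m]) cov[m] = 1;
          }
          bool covered = true;
          for (int m = 0; m < np; ++m)
            if (tgt[m] > 0.0 && !cov[m]) { covered = false; break; }
          if (covered) {
            N *= growth;
            ++covering_count;
            covering_steps.push_back((double)t);
            for (int w = 0; w < nw; ++w) {
              Walker &wk = walkers[w];
              wk.zvis_lo = R_PosInf; wk.zvis_hi = R_NegInf;
              std::fill(wk.lam_vis.begin(), wk.lam_vis.end(), 0);
              std::fill(wk.pt_vis.begin(), wk.pt_vis.end(), 0);
            }
            if (N >= total_samples) {
              stage = 1;
              stage_exit_step = t;
            }
          }
        }
      }
    }

    if (rec_traj && t % traj_interval == 0) {
      for (int w = 0; w < nw; ++w) {
        if (trow < nt) {
          Walker &wk = walkers[w];
          traj(trow, 0) = t * dt; traj(trow, 1) = w + 1;
          traj(trow, 2) = wk.z;   traj(trow, 3) = wk.theta;
          traj(trow, 4) = wk.jref + 1; traj(trow, 5) = wk.lref + 1;
          ++trow;
        }
      }
    }
    if (t % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix fmat(g.nz, g.nlam), tmat(g.nz, g.nlam), wmat(g.nz, g.nlam);
  for (int lidx = 0; lidx < g.nlam; ++lidx)
    for (int j = 0; j < g.nz; ++j) {
      fmat(j, lidx) = f[lidx * g.nz + j];
      tmat(j, lidx) = tgt[lidx * g.nz + j];
      wmat(j, lidx) = Wtot[lidx * g.nz + j];
    }

  NumericMatrix wstate(nw, 6);
  for (int w = 0; w < nw; ++w) {
    Walker &wk = walkers[w];
    wstate(w, 0) = wk.z; wstate(w, 1) = wk.v;
    wstate(w, 2) = wk.theta; wstate(w, 3) = wk.vth;
    wstate(w, 4) = wk.jref + 1; wstate(w, 5) = wk.lref + 1;
  }
  colnames(wstate) = CharacterVector::create("z", "v", "theta", "vtheta",
                                             "z_bin", "lambda_index");

  List fout(nw);
  if (rec_forces) {
    for (int w = 0; w < nw; ++w) {
      colnames(fser[w]) = CharacterVector::create("t", "force", "z_bin",
                                                  "lambda_index");
      fout[w] = fser[w];
    }
  }
  if (rec_traj)
    colnames(traj) = CharacterVector::create("t", "walker", "z", "theta",
                                             "z_bin", "lambda_index");

  return List::create(
      _["f"] = fmat, _["target"] = tmat, _["visit_weights"] = wmat,
      _["N"] = N, _["N0"] = N0,
      _["stage"] = stage == 0 ? "initial" : "final",
      _["covering_count"] = covering_count,
      _["covering_steps"] = NumericVector(covering_steps.begin(),
                                          covering_steps.end()),
      _["stage_exit_step"] = (double)stage_exit_step,
      _["total_samples"] = total_samples,
      _["n_updates"] = n_updates,
      _["walkers"] = wstate,
      _["force_series"] = fout,
      _["traj"] = rec_traj ? traj : NumericMatrix(0, 6));
}
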