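// Metropolis Monte Carlo engine for the two-site-per-residue Go model
// with the Phi-value pseudo-energy restraint.
//
// Energy terms (kcal/mol, coordinates in nm):
//   bonds     k (r - r0)^2              chain geometry (1-2, 1-3, 1-4)
//   tethers   k |x - x0|^2              receptor held near native
//   contacts  D [5 (s/r)^12 - 6 (s/r)^10], s = native distance
//   repulsion eps (sig_ij / r)^12, sig_ij = min(sig_max, 0.85 r_native)
//   confine   k (d - R)^2 on the ligand centroid beyond radius R
//   restraint k_phi sum_res (phi_exp - phi_sim)^2, with a smooth
//             logistic contact indicator so the restraint exerts a
//             force near the contact radius (1.2 x native distance).
//
// The reported per-frame phi_sim uses the hard criterion
// r < 1.2 r_native; the smooth indicator only shapes the energy.
//
// The RNG (splitmix64 -> xoshiro256+, Box-Muller normals) is owned by
// this file so runs are bit-reproducible for a given seed across
// platforms.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct RNG {
  uint64_t s[4];
  bool have_cached = false;
  double cached = 0.0;
  explicit RNG(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed + 0x9E3779B97f4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  double normal() {
    if (have_cached) { have_cached = false; return cached; }
    double u1 = 0.0, u2;
    while (u1 <= 1e-300) u1 = unif();
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2);
    have_cached = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

const double KB = 1.98720425e-3;  // kcal mol^-1 K^-1

struct Model {
  int n = 0, nres = 0;
  std::vector<double> x0;              // 3n native coords
  std::vector<int> chain;              // 0 receptor, 1 ligand (per site)
  std::vector<int> resord;             // global residue ordinal per site
  // bonds
  std::vector<int> b_i, b_j;
  std::vector<double> b_r0, b_k;
  // tethers
  std::vector<int> t_idx;
  std::vector<double> t_k;
  // contacts
  std::vector<int> c_i, c_j, c_ra, c_rb;
  std::vector<double> c_rn, c_d;
  // repulsion sigma matrix (0 => excluded / contact pair)
  std::vector<double> sig;
  double eps_rep = 1.0;
  // confinement
  double conf_c[3] = {0, 0, 0};
  double conf_R = 3.5, conf_k = 10.0;
  // restraint geometry
  double contact_factor = 1.2;  // hard criterion multiplier
  double smooth_w = 0.08;       // logistic width (nm)
  std::vector<int> n_native;    // per residue, number of native contact pairs
  // adjacency
  std::vector<std::vector<int>> bonds_of, contacts_of;
  std::vector<int> tether_of;   // index into t_* or -1
  std::vector<int> lig_sites;
  std::vector<int> inter_contacts;  // contact ids crossing the chains

  double sigma(int i, int j) const { return sig[(size_t)i * n + j]; }
};

inline double dist(const std::vector<double>& x, int i, int j) {
  double dx = x[3 * i] - x[3 * j];
  double dy = x[3 * i + 1] - x[3 * j + 1];
  double dz = x[3 * i + 2] - x[3 * j + 2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

Model build_model(const List& m) {
  Model M;
  NumericMatrix coords0 = m["coords0"];
  M.n = coords0.nrow();
  M.x0.resize(3 * M.n);
  for (int i = 0; i < M.n; ++i)
    for (int d = 0; d < 3; ++d) M.x0[3 * i + d] = coords0(i, d);
  M.chain = as<std::vector<int>>(m["chain"]);
  M.resord = as<std::vector<int>>(m["resord"]);
  M.nres = as<int>(m["nres"]);
  NumericMatrix bonds = m["bonds"];
  for (int b = 0; b < bonds.nrow(); ++b) {
    M.b_i.push_back((int)bonds(b, 0) - 1);
    M.b_j.push_back((int)bonds(b, 1) - 1);
    M.b_r0.push_back(bonds(b, 2));
    M.b_k.push_back(bonds(b, 3));
  }
  IntegerVector tidx = m["tether_idx"];
  NumericVector tk = m["tether_k"];
  for (int t = 0; t < tidx.size(); ++t) {
    M.t_idx.push_back(tidx[t] - 1);
    M.t_k.push_back(tk[t]);
  }
  NumericMatrix con = m["contacts"];
  for (int c = 0; c < con.nrow(); ++c) {
    M.c_i.push_back((int)con(c, 0) - 1);
    M.c_j.push_back((int)con(c, 1) - 1);
    M.c_rn.push_back(con(c, 2));
    M.c_d.push_back(con(c, 3));
    M.c_ra.push_back((int)con(c, 4) - 1);
    M.c_rb.push_back((int)con(c, 5) - 1);
  }
  M.n_native = as<std::vector<int>>(m["n_native"]);
  List params = m["params"];
  M.eps_rep = as<double>(params["eps_rep"]);
  double sig_max = as<double>(params["sig_rep"]);
  double sig_frac = as<double>(params["sig_native_frac"]);
  M.conf_R = as<double>(params["conf_radius"]);
  M.conf_k = as<double>(params["conf_k"]);
  M.contact_factor = as<double>(params["contact_factor"]);
  M.smooth_w = as<double>(params["smooth_width"]);
  NumericVector cc = params["conf_center"];
  for (int d = 0; d < 3; ++d) M.conf_c[d] = cc[d];

  // same-residue / chain-adjacent / bonded / contact pairs are
  // excluded from generic repulsion
  std::vector<int> reslocal = as<std::vector<int>>(m["res_local"]);
  M.sig.assign((size_t)M.n * M.n, 0.0);
  for (int i = 0; i < M.n; ++i)
    for (int j = i + 1; j < M.n; ++j) {
      if (M.resord[i] == M.resord[j]) continue;
      if (M.chain[i] == M.chain[j] &&
          std::abs(reslocal[i] - reslocal[j]) <= 1) continue;
      double rn = dist(M.x0, i, j);
      double s = std::min(sig_max, sig_frac * rn);
      M.sig[(size_t)i * M.n + j] = s;
      M.sig[(size_t)j * M.n + i] = s;
    }
  for (size_t b = 0; b < M.b_i.size(); ++b) {
    M.sig[(size_t)M.b_i[b] * M.n + M.b_j[b]] = 0.0;
    M.sig[(size_t)M.b_j[b] * M.n + M.b_i[b]] = 0.0;
  }
  for (size_t c = 0; c < M.c_i.size(); ++c) {
    M.sig[(size_t)M.c_i[c] * M.n + M.c_j[c]] = 0.0;
    M.sig[(size_t)M.c_j[c] * M.n + M.c_i[c]] = 0.0;
  }

  M.bonds_of.assign(M.n, {});
  for (size_t b = 0; b < M.b_i.size(); ++b) {
    M.bonds_of[M.b_i[b]].push_back((int)b);
    M.bonds_of[M.b_j[b]].push_back((int)b);
  }
  M.contacts_of.assign(M.n, {});
  for (size_t c = 0; c < M.c_i.size(); ++c) {
    M.contacts_of[M.c_i[c]].push_back((int)c);
    M.contacts_of[M.c_j[c]].push_back((int)c);
    if (M.chain[M.c_i[c]] != M.chain[M.c_j[c]])
      M.inter_contacts.push_back((int)c);
  }
  M.tether_of.assign(M.n, -1);
  for (size_t t = 0; t < M.t_idx.size(); ++t) M.tether_of[M.t_idx[t]] = (int)t;
  for (int i = 0; i < M.n; ++i)
    if (M.chain[i] == 1) M.lig_sites.push_back(i);
  return M;
}

inline double go_well(double r, double rn, double d) {
  double q = rn / r;
  double q2 = q * q;
  double q10 = q2 * q2 * q2 * q2 * q2;
  return d * (5.0 * q10 * q2 - 6.0 * q10);
}

inline double rep_en(double r, double s, double eps) {
  if (s <= 0.0 || r >= 3.0 * s) return 0.0;
  double q = s / r;
  double q4 = q * q * q * q;
  return eps * q4 * q4 * q4;
}

inline double smooth_formed(double r, double rc, double w) {
  return 1.0 / (1.0 + std::exp((r - rc) / w));
}

struct State {
  std::vector<double> x;
  std::vector<double> scon;   // smooth indicator per contact
  std::vector<double> S;      // per-residue sum of smooth indicators
  double lig_cen[3] = {0, 0, 0};
};

void init_phi_state(const Model& M, State& st) {
  st.scon.assign(M.c_i.size(), 0.0);
  st.S.assign(M.nres, 0.0);
  for (size_t c = 0; c < M.c_i.size(); ++c) {
    double r = dist(st.x, M.c_i[c], M.c_j[c]);
    double s = smooth_formed(r, M.contact_factor * M.c_rn[c], M.smooth_w);
    st.scon[c] = s;
    st.S[M.c_ra[c]] += s;
    st.S[M.c_rb[c]] += s;
  }
}

void update_lig_cen(const Model& M, State& st) {
  for (int d = 0; d < 3; ++d) st.lig_cen[d] = 0.0;
  for (int i : M.lig_sites)
    for (int d = 0; d < 3; ++d) st.lig_cen[d] += st.x[3 * i + d];
  for (int d = 0; d < 3; ++d) st.lig_cen[d] /= M.lig_sites.size();
}

double conf_energy(const Model& M, const double cen[3]) {
  double dx = cen[0] - M.conf_c[0], dy = cen[1] - M.conf_c[1],
         dz = cen[2] - M.conf_c[2];
  double d = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (d <= M.conf_R) return 0.0;
  double e = d - M.conf_R;
  return M.conf_k * e * e;
}

double phi_energy(const Model& M, const State& st,
                  const std::vector<double>& phi_exp, double k_phi) {
  double e = 0.0;
  for (int r = 0; r < M.nres; ++r) {
    if (!std::isfinite(phi_exp[r]) || M.n_native[r] == 0) continue;
    double d = phi_exp[r] - st.S[r] / M.n_native[r];
    e += k_phi * d * d;
  }
  return e;
}

// full mechanical (non-restraint) energy; also used to reset
// accumulated drift at cycle boundaries
double mech_energy(const Model& M, const State& st) {
  double e = 0.0;
  for (size_t b = 0; b < M.b_i.size(); ++b) {
    double d = dist(st.x, M.b_i[b], M.b_j[b]) - M.b_r0[b];
    e += M.b_k[b] * d * d;
  }
  for (size_t t = 0; t < M.t_idx.size(); ++t) {
    int i = M.t_idx[t];
    double dx = st.x[3 * i] - M.x0[3 * i];
    double dy = st.x[3 * i + 1] - M.x0[3 * i + 1];
    double dz = st.x[3 * i + 2] - M.x0[3 * i + 2];
    e += M.t_k[t] * (dx * dx + dy * dy + dz * dz);
  }
  for (size_t c = 0; c < M.c_i.size(); ++c)
    e += go_well(dist(st.x, M.c_i[c], M.c_j[c]), M.c_rn[c], M.c_d[c]);
  for (int i = 0; i < M.n; ++i)
    for (int j = i + 1; j < M.n; ++j) {
      double s = M.sigma(i, j);
      if (s > 0.0) e += rep_en(dist(st.x, i, j), s, M.eps_rep);
    }
  e += conf_energy(M, st.lig_cen);
  return e;
}

// energy of site i against everything (for local delta-E); excludes
// the restraint, which is handled by the caller via contact updates
double site_energy(const Model& M, const State& st, int i) {
  double e = 0.0;
  for (int b : M.bonds_of[i]) {
    double d = dist(st.x, M.b_i[b], M.b_j[b]) - M.b_r0[b];
    e += M.b_k[b] * d * d;
  }
  int t = M.tether_of[i];
  if (t >= 0) {
    double dx = st.x[3 * i] - M.x0[3 * i];
    double dy = st.x[3 * i + 1] - M.x0[3 * i + 1];
    double dz = st.x[3 * i + 2] - M.x0[3 * i + 2];
    e += M.t_k[t] * (dx * dx + dy * dy + dz * dz);
  }
  for (int c : M.contacts_of[i])
    e += go_well(dist(st.x, M.c_i[c], M.c_j[c]), M.c_rn[c], M.c_d[c]);
  const double* srow = &M.sig[(size_t)i * M.n];
  for (int j = 0; j < M.n; ++j)
    if (srow[j] > 0.0) e += rep_en(dist(st.x, i, j), srow[j], M.eps_rep);
  return e;
}

double interchain_energy(const Model& M, const State& st) {
  double e = 0.0;
  for (int c : M.inter_contacts)
    e += go_well(dist(st.x, M.c_i[c], M.c_j[c]), M.c_rn[c], M.c_d[c]);
  for (int i : M.lig_sites) {
    const double* srow = &M.sig[(size_t)i * M.n];
    for (int j = 0; j < M.n; ++j)
      if (M.chain[j] == 0 && srow[j] > 0.0)
        e += rep_en(dist(st.x, i, j), srow[j], M.eps_rep);
  }
  return e;
}

// delta of the restraint energy if the contacts in `cids` take the
// smooth values in `snew`; does not mutate the state
double phi_delta(const Model& M, const State& st,
                 const std::vector<double>& phi_exp, double k_phi,
                 const std::vector<int>& cids,
                 const std::vector<double>& snew,
                 std::vector<double>& dS, std::vector<int>& touched) {
  touched.clear();
  for (size_t k = 0; k < cids.size(); ++k) {
    int c = cids[k];
    double ds = snew[k] - st.scon[c];
    if (ds == 0.0) continue;
    int ra = M.c_ra[c], rb = M.c_rb[c];
    if (dS[ra] == 0.0) touched.push_back(ra);
    dS[ra] += ds;
    if (dS[rb] == 0.0) touched.push_back(rb);
    dS[rb] += ds;
  }
  double de = 0.0;
  for (int r : touched) {
    if (std::isfinite(phi_exp[r]) && M.n_native[r] > 0) {
      double p_old = st.S[r] / M.n_native[r];
      double p_new = (st.S[r] + dS[r]) / M.n_native[r];
      double a = phi_exp[r] - p_old, b = phi_exp[r] - p_new;
      de += k_phi * (b * b - a * a);
    }
  }
  return de;
}

void apply_phi(const Model& M, State& st, const std::vector<int>& cids,
               const std::vector<double>& snew, std::vector<double>& dS,
               const std::vector<int>& touched) {
  for (size_t k = 0; k < cids.size(); ++k) st.scon[cids[k]] = snew[k];
  for (int r : touched) { st.S[r] += dS[r]; dS[r] = 0.0; }
}

void clear_dS(std::vector<double>& dS, const std::vector<int>& touched) {
  for (int r : touched) dS[r] = 0.0;
}

NumericVector hard_phi(const Model& M, const State& st) {
  NumericVector out(M.nres, NA_REAL);
  std::vector<int> formed(M.nres, 0);
  for (size_t c = 0; c < M.c_i.size(); ++c) {
    double r = dist(st.x, M.c_i[c], M.c_j[c]);
    if (r < M.contact_factor * M.c_rn[c]) {
      formed[M.c_ra[c]]++;
      formed[M.c_rb[c]]++;
    }
  }
  for (int r = 0; r < M.nres; ++r)
    if (M.n_native[r] > 0) out[r] = (double)formed[r] / M.n_native[r];
  return out;
}

void random_rotation(RNG& rng, double R[3][3]) {
  // uniform random rotation from a normalized quaternion of normals
  double q[4];
  double n2 = 0.0;
  for (int k = 0; k < 4; ++k) { q[k] = rng.normal(); n2 += q[k] * q[k]; }
  double n = std::sqrt(n2);
  for (int k = 0; k < 4; ++k) q[k] /= n;
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - z * w); R[0][2] = 2 * (x * z + y * w);
  R[1][0] = 2 * (x * y + z * w); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - x * w);
  R[2][0] = 2 * (x * z - y * w); R[2][1] = 1 - 2 * (y * y + x * x); R[2][2] = 2 * (y * z + x * w);
}

void axis_rotation(RNG& rng, double angle_sd, double R[3][3]) {
  double ax[3];
  double n2 = 0.0;
  for (int k = 0; k < 3; ++k) { ax[k] = rng.normal(); n2 += ax[k] * ax[k]; }
  double n = std::sqrt(std::max(n2, 1e-300));
  for (int k = 0; k < 3; ++k) ax[k] /= n;
  double th = angle_sd * rng.normal();
  double c = std::cos(th), s = std::sin(th), C = 1 - c;
  R[0][0] = c + ax[0] * ax[0] * C; R[0][1] = ax[0] * ax[1] * C - ax[2] * s; R[0][2] = ax[0] * ax[2] * C + ax[1] * s;
  R[1][0] = ax[1] * ax[0] * C + ax[2] * s; R[1][1] = c + ax[1] * ax[1] * C; R[1][2] = ax[1] * ax[2] * C - ax[0] * s;
  R[2][0] = ax[2] * ax[0] * C - ax[1] * s; R[2][1] = ax[2] * ax[1] * C + ax[0] * s; R[2][2] = c + ax[2] * ax[2] * C;
}

}  // namespace

// [[Rcpp::export]]
List cpp_cg_energy(List model, NumericMatrix coords, NumericVector phi_exp,
                   double k_phi) {
  Model M = build_model(model);
  State st;
  st.x.resize(3 * M.n);
  for (int i = 0; i < M.n; ++i)
    for (int d = 0; d < 3; ++d) st.x[3 * i + d] = coords(i, d);
  update_lig_cen(M, st);
  init_phi_state(M, st);
  std::vector<double> pe = as<std::vector<double>>(phi_exp);
  double e_mech = mech_energy(M, st);
  double e_phi = phi_energy(M, st, pe, k_phi);
  return List::create(_["total"] = e_mech + e_phi, _["mechanical"] = e_mech,
                      _["restraint"] = e_phi,
                      _["phi_sim"] = hard_phi(M, st));
}

// [[Rcpp::export]]
NumericVector cpp_phi_sim(List model, NumericMatrix coords) {
  Model M = build_model(model);
  State st;
  st.x.resize(3 * M.n);
  for (int i = 0; i < M.n; ++i)
    for (int d = 0; d < 3; ++d) st.x[3 * i + d] = coords(i, d);
  return hard_phi(M, st);
}

// [[Rcpp::export]]
List cpp_run_mc(List model, NumericMatrix coords_init, NumericVector phi_exp,
                double k_phi, int n_cycles, int sweeps_per_cycle,
                double T_high, double T_low, double seed,
                bool random_pose, double pose_radius,
                double step_site, double step_trans, double step_rot,
                int rigid_per_sweep, int record_stride) {
  Model M = build_model(model);
  std::vector<double> pe = as<std::vector<double>>(phi_exp);
  RNG rng((uint64_t)seed);

  State st;
  st.x.resize(3 * M.n);
  for (int i = 0; i < M.n; ++i)
    for (int d = 0; d < 3; ++d) st.x[3 * i + d] = coords_init(i, d);

  int nlig = (int)M.lig_sites.size();
  if (random_pose && nlig > 0) {
    update_lig_cen(M, st);
    double R[3][3];
    random_rotation(rng, R);
    // rotate about the centroid, then displace the centroid uniformly
    // within a ball of pose_radius around its native position
    double t[3];
    for (;;) {
      for (int d = 0; d < 3; ++d) t[d] = (2 * rng.unif() - 1) * pose_radius;
      if (t[0] * t[0] + t[1] * t[1] + t[2] * t[2] <= pose_radius * pose_radius)
        break;
    }
    for (int i : M.lig_sites) {
      double v[3], w[3];
      for (int d = 0; d < 3; ++d) v[d] = st.x[3 * i + d] - st.lig_cen[d];
      for (int d = 0; d < 3; ++d)
        w[d] = R[d][0] * v[0] + R[d][1] * v[1] + R[d][2] * v[2];
      for (int d = 0; d < 3; ++d) st.x[3 * i + d] = st.lig_cen[d] + w[d] + t[d];
    }
  }
  update_lig_cen(M, st);
  init_phi_state(M, st);

  // record layout
  int n_rec = (record_stride > 0)
                  ? n_cycles * ((sweeps_per_cycle + record_stride - 1) / record_stride)
                  : n_cycles;
  NumericVector frames(Dimension(M.n, 3, n_rec));
  NumericVector rec_mech(n_rec), rec_phi(n_rec), rec_T(n_rec);
  NumericMatrix rec_phisim(n_rec, M.nres);
  int irec = 0;

  std::vector<double> dS(M.nres, 0.0);
  std::vector<int> touched;
  std::vector<int> cids;
  std::vector<double> snew;
  std::vector<double> xold(3);
  std::vector<double> xlig_old(3 * std::max(nlig, 1));

  long acc_site = 0, try_site = 0, acc_rig = 0, try_rig = 0;
  double f_site = 1.0, f_rig = 1.0;  // auto-tuning factors
  int n_retune = 0;

  auto record = [&](double T) {
    for (int i = 0; i < M.n; ++i)
      for (int d = 0; d < 3; ++d)
        frames[i + M.n * d + (size_t)M.n * 3 * irec] = st.x[3 * i + d];
    rec_mech[irec] = mech_energy(M, st);
    rec_phi[irec] = phi_energy(M, st, pe, k_phi);
    rec_T[irec] = T;
    NumericVector hp = hard_phi(M, st);
    for (int r = 0; r < M.nres; ++r) rec_phisim(irec, r) = hp[r];
    ++irec;
  };

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    long cyc_acc = 0, cyc_try = 0;
    double T = T_high;
    for (int sw = 0; sw < sweeps_per_cycle; ++sw) {
      T = (sweeps_per_cycle > 1)
              ? T_high - (T_high - T_low) * (double)sw / (sweeps_per_cycle - 1)
              : T_low;
      double beta = 1.0 / (KB * T);

      // single-site displacements
      for (int i = 0; i < M.n; ++i) {
        ++try_site; ++cyc_try;
        double e_old = site_energy(M, st, i);
        bool is_lig = (M.chain[i] == 1);
        double cen_old[3] = {st.lig_cen[0], st.lig_cen[1], st.lig_cen[2]};
        double e_conf_old = is_lig ? conf_energy(M, st.lig_cen) : 0.0;
        for (int d = 0; d < 3; ++d) {
          xold[d] = st.x[3 * i + d];
          st.x[3 * i + d] += f_site * step_site * rng.normal();
        }
        if (is_lig)
          for (int d = 0; d < 3; ++d)
            st.lig_cen[d] += (st.x[3 * i + d] - xold[d]) / nlig;
        double e_new = site_energy(M, st, i);
        double de = e_new - e_old;
        if (is_lig) de += conf_energy(M, st.lig_cen) - e_conf_old;
        // restraint delta over the contacts of this site
        cids.clear(); snew.clear();
        for (int c : M.contacts_of[i]) {
          cids.push_back(c);
          double r = dist(st.x, M.c_i[c], M.c_j[c]);
          snew.push_back(smooth_formed(r, M.contact_factor * M.c_rn[c], M.smooth_w));
        }
        double de_phi = phi_delta(M, st, pe, k_phi, cids, snew, dS, touched);
        de += de_phi;
        if (de <= 0.0 || rng.unif() < std::exp(-beta * de)) {
          apply_phi(M, st, cids, snew, dS, touched);
          ++acc_site; ++cyc_acc;
        } else {
          clear_dS(dS, touched);
          for (int d = 0; d < 3; ++d) st.x[3 * i + d] = xold[d];
          if (is_lig)
            for (int d = 0; d < 3; ++d) st.lig_cen[d] = cen_old[d];
        }
      }

      // rigid-body ligand moves
      for (int rm = 0; rm < rigid_per_sweep && nlig > 0; ++rm) {
        ++try_rig; ++cyc_try;
        double e_old = interchain_energy(M, st) + conf_energy(M, st.lig_cen);
        for (int k = 0; k < nlig; ++k)
          for (int d = 0; d < 3; ++d)
            xlig_old[3 * k + d] = st.x[3 * M.lig_sites[k] + d];
        double cen_old[3] = {st.lig_cen[0], st.lig_cen[1], st.lig_cen[2]};
        double R[3][3];
        axis_rotation(rng, f_rig * step_rot, R);
        double t[3];
        for (int d = 0; d < 3; ++d) t[d] = f_rig * step_trans * rng.normal();
        for (int k = 0; k < nlig; ++k) {
          int i = M.lig_sites[k];
          double v[3], w[3];
          for (int d = 0; d < 3; ++d) v[d] = xlig_old[3 * k + d] - cen_old[d];
          for (int d = 0; d < 3; ++d)
            w[d] = R[d][0] * v[0] + R[d][1] * v[1] + R[d][2] * v[2];
          for (int d = 0; d < 3; ++d)
            st.x[3 * i + d] = cen_old[d] + w[d] + t[d];
        }
        for (int d = 0; d < 3; ++d) st.lig_cen[d] = cen_old[d] + t[d];
        double de = interchain_energy(M, st) + conf_energy(M, st.lig_cen) - e_old;
        cids.clear(); snew.clear();
        for (int c : M.inter_contacts) {
          cids.push_back(c);
          double r = dist(st.x, M.c_i[c], M.c_j[c]);
          snew.push_back(smooth_formed(r, M.contact_factor * M.c_rn[c], M.smooth_w));
        }
        de += phi_delta(M, st, pe, k_phi, cids, snew, dS, touched);
        if (de <= 0.0 || rng.unif() < std::exp(-beta * de)) {
          apply_phi(M, st, cids, snew, dS, touched);
          ++acc_rig;
        } else {
          clear_dS(dS, touched);
          for (int k = 0; k < nlig; ++k)
            for (int d = 0; d < 3; ++d)
              st.x[3 * M.lig_sites[k] + d] = xlig_old[3 * k + d];
          for (int d = 0; d < 3; ++d) st.lig_cen[d] = cen_old[d];
        }
      }

      if (record_stride > 0 && (sw + 1) % record_stride == 0) record(T);
    }
    if (record_stride == 0) record(T);
    // step auto-tuning: engage when acceptance over a cycle drops
    // below 1%
    if (cyc_try > 0 && (double)cyc_acc / cyc_try < 0.01) {
      f_site *= 0.5;
      f_rig *= 0.5;
      ++n_retune;
    }
    // refresh the smooth-contact bookkeeping to cancel any float drift
    update_lig_cen(M, st);
    init_phi_state(M, st);
  }

  return List::create(
      _["frames"] = frames, _["mechanical"] = rec_mech,
      _["restraint"] = rec_phi, _["temperature"] = rec_T,
      _["phi_sim"] = rec_phisim,
      _["acceptance_site"] = try_site ? (double)acc_site / try_site : NA_REAL,
      _["acceptance_rigid"] = try_rig ? (double)acc_rig / try_rig : NA_REAL,
      _["n_retune"] = n_retune);
}
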