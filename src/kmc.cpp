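// Kinetic Monte Carlo engine for the stored-length polymer on an fcc
// lattice.  The lattice is embedded as the even-parity sites of a cubic
// grid of edge 2S (grid spacing b/sqrt(2)); the 12 nearest-neighbour
// offsets have two components equal to +/-1.  At most two monomers occupy
// one site, and only if consecutive along the chain (stored length).
//
// Energy: bending E(theta) = kappa * (1 - cos theta) per angle between two
// consecutive non-zero bonds (a zero-length bond contributes no term and
// breaks the angle chain), plus a state-pair energy U[e(i)][e(j)] for every
// unordered pair |i-j| >= 2 occupying nearest-neighbour sites.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding: a fast, high-quality stream per
// run, fully determined by the run seed (independent of R's RNG state)
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) { return (int)(runif() * n); }
};

static const int OFF[12][3] = {
  { 1,  1, 0}, { 1, -1, 0}, {-1,  1, 0}, {-1, -1, 0},
  { 1, 0,  1}, { 1, 0, -1}, {-1, 0,  1}, {-1, 0, -1},
  {0,  1,  1}, {0,  1, -1}, {0, -1,  1}, {0, -1, -1}};

struct Engine {
  int N, m;                 // monomers, grid edge (= 2S)
  int mm2;                  // m*m
  double kappa;
  bool hasU, bonded_pairs;
  std::vector<double> U;    // nstate x nstate, column-major
  int nstate;
  std::vector<int> state;   // 0-based state per monomer, -1 if none

  // positions: wrapped grid coords (for site lookup) and unwrapped coords
  // (exact real-space bookkeeping; bond vectors are plain differences)
  std::vector<int> px, py, pz;
  std::vector<int64_t> ux, uy, uz;
  std::vector<int8_t> occ_cnt;   // per site: 0, 1, 2
  std::vector<int> occ_first;    // lowest-index occupant

  double E;                 // incrementally tracked total energy

  inline int sidx(int x, int y, int z) const { return (x * m + y) * m + z; }

  void load(const IntegerMatrix &pos, const IntegerMatrix &img) {
    px.resize(N); py.resize(N); pz.resize(N);
    ux.resize(N); uy.resize(N); uz.resize(N);
    occ_cnt.assign((size_t)m * m * m, 0);
    occ_first.assign((size_t)m * m * m, -1);
    for (int i = 0; i < N; ++i) {
      px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
      ux[i] = px[i] + (int64_t)img(i, 0) * m;
      uy[i] = py[i] + (int64_t)img(i, 1) * m;
      uz[i] = pz[i] + (int64_t)img(i, 2) * m;
      int s = sidx(px[i], py[i], pz[i]);
      if (occ_cnt[s] == 0) occ_first[s] = i;
      else occ_first[s] = std::min(occ_first[s], i);
      occ_cnt[s]++;
      if (occ_cnt[s] > 2) stop("invalid conformation: site occupancy > 2");
    }
  }

  inline double uij(int a, int b) const { return U[(size_t)a + (size_t)nstate * b]; }

  // bending energy at vertex j with monomer `mv` virtually at (x,y,z)
  // (unwrapped); pass mv = -1 for the as-is configuration
  inline double angle_E(int j, int mv, int64_t x, int64_t y, int64_t z) const {
    if (j < 1 || j > N - 2) return 0.0;
    int64_t ax = (j - 1 == mv) ? x : ux[j - 1];
    int64_t ay = (j - 1 == mv) ? y : uy[j - 1];
    int64_t az = (j - 1 == mv) ? z : uz[j - 1];
    int64_t bx = (j == mv) ? x : ux[j], by = (j == mv) ? y : uy[j],
            bz = (j == mv) ? z : uz[j];
    int64_t cx = (j + 1 == mv) ? x : ux[j + 1],
            cy = (j + 1 == mv) ? y : uy[j + 1],
            cz = (j + 1 == mv) ? z : uz[j + 1];
    int64_t u1 = bx - ax, u2 = by - ay, u3 = bz - az;
    int64_t v1 = cx - bx, v2 = cy - by, v3 = cz - bz;
    if ((u1 | u2 | u3) == 0 || (v1 | v2 | v3) == 0) return 0.0;
    double cosq = 0.5 * (double)(u1 * v1 + u2 * v2 + u3 * v3);
    return kappa * (1.0 - cosq);
  }

  // interaction energy between monomer mv (state smv) at wrapped site
  // (x,y,z) and all eligible occupants of the 12 neighbouring sites
  inline double pair_E(int mv, int x, int y, int z) const {
    double e = 0.0;
    int smv = state[mv];
    for (int r = 0; r < 12; ++r) {
      int qx = x + OFF[r][0]; if (qx < 0) qx += m; else if (qx >= m) qx -= m;
      int qy = y + OFF[r][1]; if (qy < 0) qy += m; else if (qy >= m) qy -= m;
      int qz = z + OFF[r][2]; if (qz < 0) qz += m; else if (qz >= m) qz -= m;
      int q = sidx(qx, qy, qz);
      int c = occ_cnt[q];
      if (c == 0) continue;
      int f = occ_first[q];
      for (int t = 0; t < c; ++t) {
        int id = f + t;
        if (id == mv) continue;
        int gap = id > mv ? id - mv : mv - id;
        if (gap == 1 && !bonded_pairs) continue;
        e += uij(smv, state[id]);
      }
    }
    return e;
  }

  double total_energy() const {
    double e = 0.0;
    if (kappa != 0.0)
      for (int j = 1; j <= N - 2; ++j) e += angle_E(j, -1, 0, 0, 0);
    if (hasU) {
      for (int i = 0; i < N; ++i) {
        int si = state[i];
        for (int r = 0; r < 12; ++r) {
          int qx = px[i] + OFF[r][0]; if (qx < 0) qx += m; else if (qx >= m) qx -= m;
          int qy = py[i] + OFF[r][1]; if (qy < 0) qy += m; else if (qy >= m) qy -= m;
          int qz = pz[i] + OFF[r][2]; if (qz < 0) qz += m; else if (qz >= m) qz -= m;
          int q = sidx(qx, qy, qz);
          int c = occ_cnt[q];
          if (c == 0) continue;
          int f = occ_first[q];
          for (int t = 0; t < c; ++t) {
            int id = f + t;
            int lo = id > i ? i : id, hi = id > i ? id : i;
            if (hi - lo < (bonded_pairs ? 1 : 2)) continue;
            if (id > i) e += uij(si, state[id]);   // count each pair once
          }
        }
      }
    }
    return e;
  }

  // one trial move; monomer/dir may be forced (>= 0) or drawn from the
  // stream (rng) or from R's RNG (rng == nullptr).
  // returns: 0 rejected-illegal, 1 rejected-metropolis, 2 accepted
  int attempt(int force_m, int force_dir, double *dE_out,
              const double *exp_cache, Xoshiro *rng) {
    int mv = force_m >= 0 ? force_m
             : (rng ? rng->below(N) : (int)(unif_rand() * N));
    if (mv >= N) mv = N - 1;
    int dir = force_dir >= 0 ? force_dir
              : (rng ? rng->below(12) : (int)(unif_rand() * 12));
    if (dir >= 12) dir = 11;

    int nx = px[mv] + OFF[dir][0]; if (nx < 0) nx += m; else if (nx >= m) nx -= m;
    int ny = py[mv] + OFF[dir][1]; if (ny < 0) ny += m; else if (ny >= m) ny -= m;
    int nz = pz[mv] + OFF[dir][2]; if (nz < 0) nz += m; else if (nz >= m) nz -= m;
    int nsite = sidx(nx, ny, nz);
    int ssite = sidx(px[mv], py[mv], pz[mv]);

    // occupancy rule at the target
    int c = occ_cnt[nsite];
    if (c >= 2) { *dE_out = NA_REAL; return 0; }
    if (c == 1) {
      int q = occ_first[nsite];
      if (q != mv - 1 && q != mv + 1) { *dE_out = NA_REAL; return 0; }
    }

    int64_t nux = ux[mv] + OFF[dir][0], nuy = uy[mv] + OFF[dir][1],
            nuz = uz[mv] + OFF[dir][2];

    // connectivity: both bonds must stay zero or nearest-neighbour
    int half = m / 2;
    for (int d = -1; d <= 1; d += 2) {
      int nb = mv + d;
      if (nb < 0 || nb >= N) continue;
      int dx = px[nb] - nx; if (dx > half) dx -= m; else if (dx < -half) dx += m;
      int dy = py[nb] - ny; if (dy > half) dy -= m; else if (dy < -half) dy += m;
      int dz = pz[nb] - nz; if (dz > half) dz -= m; else if (dz < -half) dz += m;
      int s1 = std::abs(dx) + std::abs(dy) + std::abs(dz);
      if (!((s1 == 0) || (s1 == 2 && std::abs(dx) <= 1 && std::abs(dy) <= 1 &&
                          std::abs(dz) <= 1))) {
        *dE_out = NA_REAL; return 0;
      }
    }

    // energy difference
    double dE = 0.0;
    int half_units = 0;          // bending dE in units of kappa/2 (exact)
    if (kappa != 0.0) {
      double eo = angle_E(mv - 1, -1, 0, 0, 0) + angle_E(mv, -1, 0, 0, 0) +
                  angle_E(mv + 1, -1, 0, 0, 0);
      double en = angle_E(mv - 1, mv, nux, nuy, nuz) +
                  angle_E(mv, mv, nux, nuy, nuz) +
                  angle_E(mv + 1, mv, nux, nuy, nuz);
      dE += en - eo;
      if (!hasU && kappa > 0)
        half_units = (int)std::lround(2.0 * (en - eo) / kappa);
    }
    if (hasU)
      dE += pair_E(mv, nx, ny, nz) - pair_E(mv, px[mv], py[mv], pz[mv]);

    // Metropolis
    if (dE > 0.0) {
      double acc;
      if (!hasU && exp_cache && half_units > 0 && half_units <= 24)
        acc = exp_cache[half_units];
      else
        acc = std::exp(-dE);
      double u = rng ? rng->runif() : unif_rand();
      if (u >= acc) { *dE_out = dE; return 1; }
    }

    // accept: update occupancy, positions, energy
    if (occ_cnt[ssite] == 2) {
      if (occ_first[ssite] == mv) occ_first[ssite] = mv + 1;
      occ_cnt[ssite] = 1;
    } else {
      occ_cnt[ssite] = 0; occ_first[ssite] = -1;
    }
    if (occ_cnt[nsite] == 0) { occ_first[nsite] = mv; occ_cnt[nsite] = 1; }
    else { occ_first[nsite] = std::min(occ_first[nsite], mv); occ_cnt[nsite] = 2; }
    px[mv] = nx; py[mv] = ny; pz[mv] = nz;
    ux[mv] = nux; uy[mv] = nuy; uz[mv] = nuz;
    E += dE;
    *dE_out = dE;
    return 2;
  }
};

static Engine make_engine(const IntegerMatrix &pos, const IntegerMatrix &img,
                          int twoS, double kappa, const IntegerVector &states,
                          const NumericMatrix &U, bool include_bonded_pairs) {
  Engine eng;
  eng.N = pos.nrow();
  eng.m = twoS;
  eng.mm2 = twoS * twoS;
  eng.kappa = kappa;
  eng.bonded_pairs = include_bonded_pairs;
  eng.nstate = U.nrow();
  eng.hasU = false;
  for (int i = 0; i < U.size(); ++i) if (U[i] != 0.0) { eng.hasU = true; break; }
  eng.U.assign(U.begin(), U.end());
  eng.state.assign(eng.N, -1);
  if (states.size() == eng.N)
    for (int i = 0; i < eng.N; ++i) eng.state[i] = states[i] - 1;  // 1-based in R
  if (eng.hasU)
    for (int i = 0; i < eng.N; ++i)
      if (eng.state[i] < 0 || eng.state[i] >= eng.nstate)
        stop("monomer states required (and in range) when U is non-zero");
  eng.load(pos, img);
  return eng;
}

// [[Rcpp::export]]
double cpp_total_energy(IntegerMatrix pos, IntegerMatrix img, int twoS,
                        double kappa, IntegerVector states, NumericMatrix U,
                        bool include_bonded_pairs) {
  Engine eng = make_engine(pos, img, twoS, kappa, states, U,
                           include_bonded_pairs);
  return eng.total_energy();
}

// [[Rcpp::export]]
List cpp_kmc_run(IntegerMatrix pos, IntegerMatrix img, int twoS, double kappa,
                 IntegerVector states, NumericMatrix U,
                 bool include_bonded_pairs, double n_mcs, int snapshot_every,
                 int energy_check_every, double seed) {
  Engine eng = make_engine(pos, img, twoS, kappa, states, U,
                           include_bonded_pairs);
  const int N = eng.N;
  eng.E = eng.total_energy();

  double exp_cache[25];
  for (int h = 0; h < 25; ++h) exp_cache[h] = std::exp(-0.5 * kappa * h);

  int64_t total_mcs = (int64_t)n_mcs;
  int64_t nsnap = total_mcs / snapshot_every + 1;
  IntegerVector snaps((R_xlen_t)nsnap * N * 3);
  NumericVector snap_mcs(nsnap), snap_E(nsnap);
  int *sp = INTEGER(snaps);

  auto record = [&](int64_t k, int64_t mcs) {
    int64_t base = k * (int64_t)N * 3;
    for (int i = 0; i < N; ++i) {
      sp[base + i] = (int)eng.ux[i];
      sp[base + N + i] = (int)eng.uy[i];
      sp[base + 2 * N + i] = (int)eng.uz[i];
    }
    snap_mcs[k] = (double)mcs;
    snap_E[k] = eng.E;
  };

  Xoshiro rng((uint64_t)seed);
  record(0, 0);
  int64_t accepted = 0, ksnap = 1;
  double audit_max = 0.0;
  double dE;
  for (int64_t step = 1; step <= total_mcs; ++step) {
    for (int t = 0; t < N; ++t)
      if (eng.attempt(-1, -1, &dE, exp_cache, &rng) == 2) ++accepted;
    if (step % snapshot_every == 0) record(ksnap++, step);
    if (energy_check_every > 0 && step % energy_check_every == 0) {
      double ref = eng.total_energy();
      double err = std::fabs(ref - eng.E);
      if (err > audit_max) audit_max = err;
      if (err > 1e-6)
        stop("energy bookkeeping drift %g at MCS %g", err, (double)step);
      eng.E = ref;
    }
    if (step % 4096 == 0) checkUserInterrupt();
  }

  return List::create(
    _["snapshots"] = snaps, _["mcs"] = snap_mcs, _["energy"] = snap_E,
    _["n_snapshots"] = (double)nsnap,
    _["acceptance_rate"] = total_mcs > 0
        ? (double)accepted / ((double)total_mcs * N) : NA_REAL,
    _["audit_max_error"] = audit_max);
}

// [[Rcpp::export]]
List cpp_attempt_move(IntegerMatrix pos, IntegerMatrix img, int twoS,
                      double kappa, IntegerVector states, NumericMatrix U,
                      bool include_bonded_pairs, int monomer, int direction) {
  Engine eng = make_engine(pos, img, twoS, kappa, states, U,
                           include_bonded_pairs);
  eng.E = 0.0;
  double dE;
  GetRNGstate();
  int res = eng.attempt(monomer >= 1 ? monomer - 1 : -1,
                        direction >= 1 ? direction - 1 : -1, &dE, nullptr,
                        nullptr);
  PutRNGstate();
  IntegerMatrix pos_out(eng.N, 3), img_out(eng.N, 3);
  for (int i = 0; i < eng.N; ++i) {
    pos_out(i, 0) = eng.px[i]; pos_out(i, 1) = eng.py[i]; pos_out(i, 2) = eng.pz[i];
    img_out(i, 0) = (int)((eng.ux[i] - eng.px[i]) / twoS);
    img_out(i, 1) = (int)((eng.uy[i] - eng.py[i]) / twoS);
    img_out(i, 2) = (int)((eng.uz[i] - eng.pz[i]) / twoS);
  }
  return List::create(_["accepted"] = (res == 2), _["legal"] = (res != 0),
                      _["dE"] = dE, _["pos"] = pos_out, _["img"] = img_out);
}
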