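// Lattice Monte Carlo core: canonical-ensemble Metropolis sampling of
// multichain self-avoiding polymers on a periodic cubic lattice.
//
// Conventions (shared with the R layer):
//  - one bead per lattice site; vacant sites are solvent
//  - contacts and bonds use the 26-site (Chebyshev distance 1) shell
//  - pair energy = contact_energy[type_i][type_j] + elec[spc_a][spc_b],
//    where elec is the precomputed electrostatic penalty per species pair;
//    chain-bonded pairs are excluded when bonded_excluded is true
//  - all coordinates are 0-based and wrapped into [0, L)
//
// The RNG is std::mt19937_64 with hand-rolled bounded draws so that
// trajectories are bit-for-bit reproducible across platforms.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  uint64_t raw() { return gen(); }
  // uniform integer in [0, n)
  uint32_t below(uint32_t n) {
    uint64_t limit = UINT64_MAX - UINT64_MAX % n;
    uint64_t x;
    do { x = gen(); } while (x >= limit);
    return static_cast<uint32_t>(x % n);
  }
  // uniform double in [0, 1)
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
};

inline int wrap(int v, int L) { v %= L; if (v < 0) v += L; return v; }

// wrap for coordinates already within [-L, 2L): one conditional each way
// (hot path: shell offsets are +/-1)
inline int wrap1(int v, int L) {
  if (v < 0) return v + L;
  if (v >= L) return v - L;
  return v;
}

// minimal-image separation; |result| <= L/2
inline int mindiff(int a, int b, int L) {
  int d = a - b;
  if (d > L / 2) d -= L;
  else if (d < -(L / 2)) d += L;
  return d;
}

inline int cheb(int ax, int ay, int az, int bx, int by, int bz,
                int Lx, int Ly, int Lz) {
  int dx = std::abs(mindiff(ax, bx, Lx));
  int dy = std::abs(mindiff(ay, by, Ly));
  int dz = std::abs(mindiff(az, bz, Lz));
  return std::max(dx, std::max(dy, dz));
}

// the 26 shell offsets
struct Shell {
  int off[26][3];
  Shell() {
    int k = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          off[k][0] = dx; off[k][1] = dy; off[k][2] = dz; ++k;
        }
  }
};
static const Shell SHELL;

// the 48 signed permutations of the cube (index 0 = identity)
struct PointGroup {
  int perm[48][3];
  int sign[48][3];
  PointGroup() {
    const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
    int k = 0;
    for (int p = 0; p < 6; ++p)
      for (int s = 0; s < 8; ++s) {
        for (int a = 0; a < 3; ++a) {
          perm[k][a] = perms[p][a];
          sign[k][a] = (s >> a & 1) ? -1 : 1;
        }
        ++k;
      }
    // put identity at index 0
    for (int i = 0; i < 48; ++i) {
      if (perm[i][0] == 0 && perm[i][1] == 1 && perm[i][2] == 2 &&
          sign[i][0] == 1 && sign[i][1] == 1 && sign[i][2] == 1) {
        for (int a = 0; a < 3; ++a) {
          std::swap(perm[i][a], perm[0][a]);
          std::swap(sign[i][a], sign[0][a]);
        }
        break;
      }
    }
  }
};
static const PointGroup PG;

class Lattice {
public:
  int Lx, Ly, Lz, V;
  int nb, nchain, ntype, nspecies;
  std::vector<int> x, y, z;          // per bead
  std::vector<int> chain_of;         // per bead, 0-based
  std::vector<int> type_of;          // per bead, 0-based
  std::vector<int> spc_of_chain;     // per chain, 0-based
  std::vector<int> chain_begin, chain_end; // bead index ranges
  std::vector<int> grid;             // site -> bead index or -1
  std::vector<double> E;             // ntype x ntype, row-major
  std::vector<double> elec;          // nspecies x nspecies
  bool bonded_excluded;
  double Etot;

  // scratch for move evaluation
  std::vector<int> mv_stamp;         // per bead
  std::vector<int> site_stamp;       // per site
  std::vector<int> site_val;         // per site: moved-bead occupying it
  int stamp;

  Lattice(IntegerMatrix coords, IntegerVector chain, IntegerVector type,
          IntegerVector spc, IntegerVector box,
          NumericMatrix Emat, NumericMatrix elecmat, bool bexcl) {
    Lx = box[0]; Ly = box[1]; Lz = box[2]; V = Lx * Ly * Lz;
    nb = coords.nrow();
    x.resize(nb); y.resize(nb); z.resize(nb);
    chain_of.resize(nb); type_of.resize(nb);
    for (int i = 0; i < nb; ++i) {
      x[i] = wrap(coords(i, 0), Lx);
      y[i] = wrap(coords(i, 1), Ly);
      z[i] = wrap(coords(i, 2), Lz);
      chain_of[i] = chain[i] - 1;
      type_of[i] = type[i] - 1;
    }
    nchain = spc.size();
    spc_of_chain.resize(nchain);
    for (int c = 0; c < nchain; ++c) spc_of_chain[c] = spc[c] - 1;
    chain_begin.assign(nchain, -1);
    chain_end.assign(nchain, -1);
    for (int i = 0; i < nb; ++i) {
      int c = chain_of[i];
      if (chain_begin[c] < 0) chain_begin[c] = i;
      chain_end[c] = i + 1;
    }
    for (int c = 0; c < nchain; ++c) {
      if (chain_begin[c] < 0) stop("chain with no beads");
      for (int i = chain_begin[c]; i < chain_end[c]; ++i)
        if (chain_of[i] != c) stop("beads of a chain must be contiguous");
    }
    ntype = Emat.nrow();
    E.resize(ntype * ntype);
    for (int i = 0; i < ntype; ++i)
      for (int j = 0; j < ntype; ++j) E[i * ntype + j] = Emat(i, j);
    nspecies = elecmat.nrow();
    elec.resize(nspecies * nspecies);
    for (int i = 0; i < nspecies; ++i)
      for (int j = 0; j < nspecies; ++j)
        elec[i * nspecies + j] = elecmat(i, j);
    bonded_excluded = bexcl;
    grid.assign(V, -1);
    for (int i = 0; i < nb; ++i) {
      int s = site(x[i], y[i], z[i]);
      if (grid[s] != -1) stop("two beads occupy one lattice site");
      grid[s] = i;
    }
    // bond invariant
    for (int c = 0; c < nchain; ++c)
      for (int i = chain_begin[c] + 1; i < chain_end[c]; ++i)
        if (cheb(x[i], y[i], z[i], x[i-1], y[i-1], z[i-1], Lx, Ly, Lz) != 1)
          stop("consecutive beads of a chain must lie in each other's 26-neighbor shell");
    mv_stamp.assign(nb, 0);
    site_stamp.assign(V, 0);
    site_val.assign(V, -1);
    stamp = 0;
    Etot = total_energy();
  }

  inline int site(int xi, int yi, int zi) const {
    return (zi * Ly + yi) * Lx + xi;
  }
  inline bool bonded(int a, int b) const {
    return chain_of[a] == chain_of[b] && std::abs(a - b) == 1;
  }
  inline double pair_e(int a, int b) const {
    if (bonded_excluded && bonded(a, b)) return 0.0;
    return E[type_of[a] * ntype + type_of[b]] +
           elec[spc_of_chain[chain_of[a]] * nspecies + spc_of_chain[chain_of[b]]];
  }

  double total_energy() const {
    double e = 0.0;
    for (int b = 0; b < nb; ++b) {
      for (int k = 0; k < 26; ++k) {
        int xs = wrap1(x[b] + SHELL.off[k][0], Lx);
        int ys = wrap1(y[b] + SHELL.off[k][1], Ly);
        int zs = wrap1(z[b] + SHELL.off[k][2], Lz);
        int o = grid[site(xs, ys, zs)];
        if (o > b) e += pair_e(b, o);
      }
    }
    return e;
  }

  // ---- generic move evaluation -------------------------------------------
  // moved beads mb with new coordinates (nx, ny, nz); rigid => mutual
  // separations of moved beads are preserved, so moved-moved pairs cancel.
  // Returns true if geometrically feasible; dE set on success.
  bool eval_move(const std::vector<int>& mb,
                 const std::vector<int>& nx, const std::vector<int>& ny,
                 const std::vector<int>& nz, bool rigid, double& dE) {
    int m = mb.size();
    ++stamp;
    for (int i = 0; i < m; ++i) mv_stamp[mb[i]] = stamp;
    // feasibility: new sites distinct and free of non-moving beads
    for (int i = 0; i < m; ++i) {
      int s = site(nx[i], ny[i], nz[i]);
      if (site_stamp[s] == stamp) return false;     // duplicate new site
      site_stamp[s] = stamp; site_val[s] = mb[i];
      int g = grid[s];
      if (g != -1 && mv_stamp[g] != stamp) return false;
    }
    double e_old = 0.0, e_new = 0.0;
    for (int i = 0; i < m; ++i) {
      int b = mb[i];
      for (int k = 0; k < 26; ++k) {
        // old neighborhood
        int xs = wrap1(x[b] + SHELL.off[k][0], Lx);
        int ys = wrap1(y[b] + SHELL.off[k][1], Ly);
        int zs = wrap1(z[b] + SHELL.off[k][2], Lz);
        int o = grid[site(xs, ys, zs)];
        if (o != -1) {
          if (mv_stamp[o] == stamp) {
            if (!rigid && o > b) e_old += pair_e(b, o);
          } else {
            e_old += pair_e(b, o);
          }
        }
        // new neighborhood
        int xn = wrap1(nx[i] + SHELL.off[k][0], Lx);
        int yn = wrap1(ny[i] + SHELL.off[k][1], Ly);
        int zn = wrap1(nz[i] + SHELL.off[k][2], Lz);
        int sn = site(xn, yn, zn);
        int gn = grid[sn];
        if (gn != -1 && mv_stamp[gn] != stamp) e_new += pair_e(b, gn);
        if (!rigid && site_stamp[sn] == stamp) {
          int on = site_val[sn];
          if (on > b) e_new += pair_e(b, on);
        }
      }
    }
    dE = e_new - e_old;
    return true;
  }

  void apply_move(const std::vector<int>& mb,
                  const std::vector<int>& nx, const std::vector<int>& ny,
                  const std::vector<int>& nz) {
    int m = mb.size();
    for (int i = 0; i < m; ++i) grid[site(x[mb[i]], y[mb[i]], z[mb[i]])] = -1;
    for (int i = 0; i < m; ++i) {
      int b = mb[i];
      x[b] = nx[i]; y[b] = ny[i]; z[b] = nz[i];
      grid[site(x[b], y[b], z[b])] = b;
    }
  }

  void check_invariants() const {
    int occ = 0;
    for (int s = 0; s < V; ++s) if (grid[s] != -1) ++occ;
    if (occ != nb) stop("self-avoidance violated");
    for (int b = 0; b < nb; ++b)
      if (grid[site(x[b], y[b], z[b])] != b) stop("grid inconsistent");
    for (int c = 0; c < nchain; ++c)
      for (int i = chain_begin[c] + 1; i < chain_end[c]; ++i)
        if (cheb(x[i], y[i], z[i], x[i-1], y[i-1], z[i-1], Lx, Ly, Lz) != 1)
          stop("bond broken");
  }
};

// candidate sites for a single-bead relocation (determined by the bonded
// neighbors' positions only, hence a symmetric proposal)
int local_candidates(const Lattice& L, int b, int cand[27][3]) {
  int c = L.chain_of[b];
  bool has_prev = b > L.chain_begin[c];
  bool has_next = b < L.chain_end[c] - 1;
  int ax, ay, az;           // anchor to scan around
  int ox = -1, oy = -1, oz = -1; // other bonded neighbor, if any
  if (has_prev) {
    ax = L.x[b-1]; ay = L.y[b-1]; az = L.z[b-1];
    if (has_next) { ox = L.x[b+1]; oy = L.y[b+1]; oz = L.z[b+1]; }
  } else {
    ax = L.x[b+1]; ay = L.y[b+1]; az = L.z[b+1];
  }
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int sx = wrap1(ax + dx, L.Lx);
        int sy = wrap1(ay + dy, L.Ly);
        int sz = wrap1(az + dz, L.Lz);
        if (ox >= 0 && cheb(sx, sy, sz, ox, oy, oz, L.Lx, L.Ly, L.Lz) > 1)
          continue;
        cand[k][0] = sx; cand[k][1] = sy; cand[k][2] = sz; ++k;
      }
  return k;
}

// BFS over the chain-contact graph starting at chain c0
void chain_cluster(const Lattice& L, int c0, std::vector<int>& members,
                   std::vector<char>& inset) {
  std::fill(inset.begin(), inset.end(), 0);
  members.clear();
  std::vector<int> queue;
  queue.push_back(c0); inset[c0] = 1;
  while (!queue.empty()) {
    int c = queue.back(); queue.pop_back();
    members.push_back(c);
    for (int b = L.chain_begin[c]; b < L.chain_end[c]; ++b) {
      for (int k = 0; k < 26; ++k) {
        int xs = wrap1(L.x[b] + SHELL.off[k][0], L.Lx);
        int ys = wrap1(L.y[b] + SHELL.off[k][1], L.Ly);
        int zs = wrap1(L.z[b] + SHELL.off[k][2], L.Lz);
        int o = L.grid[L.site(xs, ys, zs)];
        if (o != -1) {
          int oc = L.chain_of[o];
          if (!inset[oc]) { inset[oc] = 1; queue.push_back(oc); }
        }
      }
    }
  }
}

} // namespace

// [[Rcpp::export]]
double cpp_total_energy(IntegerMatrix coords, IntegerVector chain_of,
                        IntegerVector type_of, IntegerVector species_of_chain,
                        IntegerVector box, NumericMatrix Emat,
                        NumericMatrix elec, bool bonded_excluded) {
  Lattice L(coords, chain_of, type_of, species_of_chain, box, Emat, elec,
            bonded_excluded);
  return L.Etot;
}

// Run n_steps of Metropolis MC. Returns energies sampled every energy_stride
// steps, frames sampled every frame_stride steps from frame_start on, the
// final coordinates, and per-move-kind acceptance counters.
// move_weights: local, snake, translate, pivot, double_pivot, co_local,
// cluster_translate (in this order).
// [[Rcpp::export]]
List cpp_run_mc(IntegerMatrix coords, IntegerVector chain_of,
                IntegerVector type_of, IntegerVector species_of_chain,
                IntegerVector box, NumericMatrix Emat, NumericMatrix elec,
                bool bonded_excluded, NumericVector move_weights, int dmax,
                double n_steps_d, double temperature, double seed,
                double energy_stride_d, double frame_stride_d,
                double frame_start_d, bool validate) {
  Lattice L(coords, chain_of, type_of, species_of_chain, box, Emat, elec,
            bonded_excluded);
  Rng rng(static_cast<uint64_t>(seed));
  long long n_steps = static_cast<long long>(n_steps_d);
  long long energy_stride = static_cast<long long>(energy_stride_d);
  long long frame_stride = static_cast<long long>(frame_stride_d);
  long long frame_start = static_cast<long long>(frame_start_d);
  if (energy_stride < 1) energy_stride = 1;
  if (frame_stride < 1) frame_stride = 1;
  const int NKIND = 7;
  if (move_weights.size() != NKIND) stop("move_weights must have length 7");
  double wcum[NKIND], tot = 0.0;
  for (int i = 0; i < NKIND; ++i) { tot += move_weights[i]; wcum[i] = tot; }
  if (tot <= 0) stop("move weights must sum to a positive value");
  const double T = temperature;
  if (T <= 0) stop("temperature must be positive");

  std::vector<double> e_steps, e_vals;
  List frames;
  std::vector<long long> frame_steps;
  std::vector<long long> prop(NKIND, 0), acc(NKIND, 0);
  std::vector<int> mb, nx, ny, nz, members;
  std::vector<char> inset(L.nchain, 0);
  double max_drift = 0.0;

  e_steps.push_back(0); e_vals.push_back(L.Etot);

  for (long long step = 1; step <= n_steps; ++step) {
    double u = rng.unif() * tot;
    int kind = 0;
    while (kind < NKIND - 1 && u >= wcum[kind]) ++kind;
    ++prop[kind];
    mb.clear(); nx.clear(); ny.clear(); nz.clear();
    bool feasible = true, rigid = true;

    switch (kind) {
    case 0: { // local bead relocation
      int b = rng.below(L.nb);
      int cand[27][3];
      int k = local_candidates(L, b, cand);
      int pick = rng.below(k);
      mb.push_back(b);
      nx.push_back(cand[pick][0]); ny.push_back(cand[pick][1]);
      nz.push_back(cand[pick][2]);
      break;
    }
    case 1: { // slithering snake
      int c = rng.below(L.nchain);
      int b0 = L.chain_begin[c], b1 = L.chain_end[c] - 1;
      if (b1 - b0 < 1) { feasible = false; break; }
      int grow_begin = rng.below(2);
      int k = rng.below(26);
      rigid = false;
      if (grow_begin) {
        int sx = wrap(L.x[b0] + SHELL.off[k][0], L.Lx);
        int sy = wrap(L.y[b0] + SHELL.off[k][1], L.Ly);
        int sz = wrap(L.z[b0] + SHELL.off[k][2], L.Lz);
        mb.push_back(b0); nx.push_back(sx); ny.push_back(sy); nz.push_back(sz);
        for (int b = b0 + 1; b <= b1; ++b) {
          mb.push_back(b);
          nx.push_back(L.x[b-1]); ny.push_back(L.y[b-1]); nz.push_back(L.z[b-1]);
        }
      } else {
        int sx = wrap(L.x[b1] + SHELL.off[k][0], L.Lx);
        int sy = wrap(L.y[b1] + SHELL.off[k][1], L.Ly);
        int sz = wrap(L.z[b1] + SHELL.off[k][2], L.Lz);
        for (int b = b0; b < b1; ++b) {
          mb.push_back(b);
          nx.push_back(L.x[b+1]); ny.push_back(L.y[b+1]); nz.push_back(L.z[b+1]);
        }
        mb.push_back(b1); nx.push_back(sx); ny.push_back(sy); nz.push_back(sz);
      }
      break;
    }
    case 2: { // rigid chain translation
      int c = rng.below(L.nchain);
      int span = 2 * dmax + 1;
      int dx = static_cast<int>(rng.below(span)) - dmax;
      int dy = static_cast<int>(rng.below(span)) - dmax;
      int dz = static_cast<int>(rng.below(span)) - dmax;
      for (int b = L.chain_begin[c]; b < L.chain_end[c]; ++b) {
        mb.push_back(b);
        nx.push_back(wrap(L.x[b] + dx, L.Lx));
        ny.push_back(wrap(L.y[b] + dy, L.Ly));
        nz.push_back(wrap(L.z[b] + dz, L.Lz));
      }
      break;
    }
    case 3: case 4: { // pivot / internal double pivot
      int c = rng.below(L.nchain);
      int b0 = L.chain_begin[c], N = L.chain_end[c] - b0;
      if (N < 3) { feasible = false; break; }
      int op = 1 + rng.below(47); // exclude identity
      int lo, hi, pvt, bond_to = -1; // rotate beads [lo, hi] about pvt
      if (kind == 3) {
        int p = rng.below(N);
        int side = rng.below(2);
        pvt = b0 + p;
        if (side == 0) { lo = b0; hi = pvt - 1; }
        else { lo = pvt + 1; hi = b0 + N - 1; }
        if (lo > hi) { feasible = false; break; }
      } else {
        int i = rng.below(N);
        int umax = std::min(10, N - 1 - i);
        if (umax < 2) { feasible = false; break; }
        int u = 2 + rng.below(umax - 1);
        pvt = b0 + i;
        lo = pvt + 1; hi = pvt + u - 1;
        bond_to = pvt + u;
      }
      int px = L.x[pvt], py = L.y[pvt], pz = L.z[pvt];
      for (int b = lo; b <= hi && feasible; ++b) {
        int d[3];
        d[0] = mindiff(L.x[b], px, L.Lx);
        d[1] = mindiff(L.y[b], py, L.Ly);
        d[2] = mindiff(L.z[b], pz, L.Lz);
        // reject ambiguous minimal images (component exactly L/2 on even box)
        if ((L.Lx % 2 == 0 && std::abs(d[0]) == L.Lx / 2) ||
            (L.Ly % 2 == 0 && std::abs(d[1]) == L.Ly / 2) ||
            (L.Lz % 2 == 0 && std::abs(d[2]) == L.Lz / 2)) {
          feasible = false; break;
        }
        int r[3];
        for (int a = 0; a < 3; ++a) r[a] = PG.sign[op][a] * d[PG.perm[op][a]];
        mb.push_back(b);
        nx.push_back(wrap(px + r[0], L.Lx));
        ny.push_back(wrap(py + r[1], L.Ly));
        nz.push_back(wrap(pz + r[2], L.Lz));
      }
      if (feasible && bond_to >= 0) {
        int last = mb.size() - 1; // bead bond_to - 1 is the last rotated bead
        if (cheb(nx[last], ny[last], nz[last],
                 L.x[bond_to], L.y[bond_to], L.z[bond_to],
                 L.Lx, L.Ly, L.Lz) != 1)
          feasible = false;
      }
      break;
    }
    case 5: { // co-local: shift a bead and a contacting foreign bead together
      int b = rng.below(L.nb);
      int k1 = rng.below(26);
      int sx = wrap(L.x[b] + SHELL.off[k1][0], L.Lx);
      int sy = wrap(L.y[b] + SHELL.off[k1][1], L.Ly);
      int sz = wrap(L.z[b] + SHELL.off[k1][2], L.Lz);
      int o = L.grid[L.site(sx, sy, sz)];
      int k2 = rng.below(26);
      if (o == -1 || L.chain_of[o] == L.chain_of[b]) { feasible = false; break; }
      int dx = SHELL.off[k2][0], dy = SHELL.off[k2][1], dz = SHELL.off[k2][2];
      int two[2] = {b, o};
      for (int t = 0; t < 2 && feasible; ++t) {
        int bb = two[t];
        int tx = wrap(L.x[bb] + dx, L.Lx);
        int ty = wrap(L.y[bb] + dy, L.Ly);
        int tz = wrap(L.z[bb] + dz, L.Lz);
        int c = L.chain_of[bb];
        if (bb > L.chain_begin[c] &&
            cheb(tx, ty, tz, L.x[bb-1], L.y[bb-1], L.z[bb-1],
                 L.Lx, L.Ly, L.Lz) > 1) feasible = false;
        if (bb < L.chain_end[c] - 1 &&
            cheb(tx, ty, tz, L.x[bb+1], L.y[bb+1], L.z[bb+1],
                 L.Lx, L.Ly, L.Lz) > 1) feasible = false;
        mb.push_back(bb); nx.push_back(tx); ny.push_back(ty); nz.push_back(tz);
      }
      break;
    }
    case 6: { // rigid translation of a whole connected cluster
      int c = rng.below(L.nchain);
      chain_cluster(L, c, members, inset);
      int span = 2 * dmax + 1;
      int dx = static_cast<int>(rng.below(span)) - dmax;
      int dy = static_cast<int>(rng.below(span)) - dmax;
      int dz = static_cast<int>(rng.below(span)) - dmax;
      for (size_t i = 0; i < members.size(); ++i) {
        int cc = members[i];
        for (int b = L.chain_begin[cc]; b < L.chain_end[cc]; ++b) {
          mb.push_back(b);
          nx.push_back(wrap(L.x[b] + dx, L.Lx));
          ny.push_back(wrap(L.y[b] + dy, L.Ly));
          nz.push_back(wrap(L.z[b] + dz, L.Lz));
        }
      }
      break;
    }
    }

    double dE = 0.0;
    if (feasible) feasible = L.eval_move(mb, nx, ny, nz, rigid, dE);
    if (feasible && kind == 6) {
      // forbid cluster merges: keeps the proposal symmetric
      for (size_t i = 0; i < mb.size() && feasible; ++i) {
        for (int k = 0; k < 26; ++k) {
          int xs = wrap1(nx[i] + SHELL.off[k][0], L.Lx);
          int ys = wrap1(ny[i] + SHELL.off[k][1], L.Ly);
          int zs = wrap1(nz[i] + SHELL.off[k][2], L.Lz);
          int o = L.grid[L.site(xs, ys, zs)];
          if (o != -1 && L.mv_stamp[o] != L.stamp) { feasible = false; break; }
        }
      }
    }
    bool accepted = false;
    if (feasible) {
      if (dE <= 0.0 || rng.unif() < std::exp(-dE / T)) accepted = true;
    }
    if (accepted) {
      L.apply_move(mb, nx, ny, nz);
      L.Etot += dE;
      ++acc[kind];
      if (validate) {
        double full = L.total_energy();
        double drift = std::fabs(full - L.Etot);
        if (drift > max_drift) max_drift = drift;
        L.check_invariants();
      }
    }
    if (step % energy_stride == 0) {
      e_steps.push_back(static_cast<double>(step));
      e_vals.push_back(L.Etot);
    }
    if (step >= frame_start && (step - frame_start) % frame_stride == 0) {
      IntegerMatrix f(L.nb, 3);
      for (int i = 0; i < L.nb; ++i) {
        f(i, 0) = L.x[i]; f(i, 1) = L.y[i]; f(i, 2) = L.z[i];
      }
      frames.push_back(f);
      frame_steps.push_back(step);
    }
  }

  IntegerMatrix final_coords(L.nb, 3);
  for (int i = 0; i < L.nb; ++i) {
    final_coords(i, 0) = L.x[i]; final_coords(i, 1) = L.y[i];
    final_coords(i, 2) = L.z[i];
  }
  return List::create(
    _["energy_steps"] = wrap(e_steps), _["energies"] = wrap(e_vals),
    _["frames"] = frames, _["frame_steps"] = wrap(frame_steps),
    _["coords"] = final_coords, _["energy_final"] = L.Etot,
    _["energy_recomputed"] = L.total_energy(),
    _["proposals"] = wrap(prop), _["accepts"] = wrap(acc),
    _["max_energy_drift"] = max_drift);
}

// Dense-seed initialization: grow each chain as a self-avoiding walk inside
// the central init_box^3 subregion of the full box.
// [[Rcpp::export]]
IntegerMatrix cpp_init_dense(IntegerVector chain_lengths, IntegerVector box,
                             int init_box, double seed) {
  int Lx = box[0], Ly = box[1], Lz = box[2];
  int ib = std::min(init_box, std::min(Lx, std::min(Ly, Lz)));
  int nb = 0;
  for (int i = 0; i < chain_lengths.size(); ++i) nb += chain_lengths[i];
  if (nb > ib * ib * ib)
    stop("init_dense: bead count exceeds init_box^3; increase init_box");
  int ox = (Lx - ib) / 2, oy = (Ly - ib) / 2, oz = (Lz - ib) / 2;
  Rng rng(static_cast<uint64_t>(seed));
  int V = Lx * Ly * Lz;
  std::vector<char> occ;
  IntegerMatrix coords(nb, 3);
  auto sidx = [&](int xi, int yi, int zi) { return (zi * Ly + yi) * Lx + xi; };
  for (int attempt = 0; attempt < 50; ++attempt) {
    occ.assign(V, 0);
    int bead = 0;
    bool ok = true;
    for (int c = 0; c < chain_lengths.size() && ok; ++c) {
      int N = chain_lengths[c];
      bool placed = false;
      for (int retry = 0; retry < 500 && !placed; ++retry) {
        std::vector<int> cx(N), cy(N), cz(N);
        int x0 = ox + rng.below(ib), y0 = oy + rng.below(ib),
            z0 = oz + rng.below(ib);
        if (occ[sidx(x0, y0, z0)]) continue;
        cx[0] = x0; cy[0] = y0; cz[0] = z0;
        occ[sidx(x0, y0, z0)] = 1;
        int grown = 1;
        while (grown < N) {
          int fx[26], fy[26], fz[26], nf = 0;
          for (int k = 0; k < 26; ++k) {
            int xs = cx[grown-1] + SHELL.off[k][0];
            int ys = cy[grown-1] + SHELL.off[k][1];
            int zs = cz[grown-1] + SHELL.off[k][2];
            if (xs < ox || xs >= ox + ib || ys < oy || ys >= oy + ib ||
                zs < oz || zs >= oz + ib) continue;
            if (occ[sidx(xs, ys, zs)]) continue;
            fx[nf] = xs; fy[nf] = ys; fz[nf] = zs; ++nf;
          }
          if (nf == 0) break; // dead end
          int pick = rng.below(nf);
          cx[grown] = fx[pick]; cy[grown] = fy[pick]; cz[grown] = fz[pick];
          occ[sidx(cx[grown], cy[grown], cz[grown])] = 1;
          ++grown;
        }
        if (grown == N) {
          for (int i = 0; i < N; ++i) {
            coords(bead + i, 0) = cx[i];
            coords(bead + i, 1) = cy[i];
            coords(bead + i, 2) = cz[i];
          }
          placed = true;
        } else {
          for (int i = 0; i < grown; ++i) occ[sidx(cx[i], cy[i], cz[i])] = 0;
        }
      }
      if (!placed) { ok = false; break; }
      bead += N;
    }
    if (ok) return coords;
  }
  stop("init_dense: chain placement failed after bounded retries; increase init_box");
}

// Inter-chain bead-bead contact counts, aggregated per unordered chain pair.
// Returns an m x 3 matrix (chain_i, chain_j, n_contacts), 1-based chain ids.
// [[Rcpp::export]]
IntegerMatrix cpp_chain_contacts(IntegerMatrix coords, IntegerVector chain_of,
                                 IntegerVector box) {
  int Lx = box[0], Ly = box[1], Lz = box[2];
  int nb = coords.nrow();
  int nchain = 0;
  for (int i = 0; i < nb; ++i) nchain = std::max(nchain, chain_of[i]);
  std::vector<int> grid(Lx * Ly * Lz, -1);
  std::vector<int> X(nb), Y(nb), Z(nb);
  for (int i = 0; i < nb; ++i) {
    X[i] = wrap(coords(i, 0), Lx); Y[i] = wrap(coords(i, 1), Ly);
    Z[i] = wrap(coords(i, 2), Lz);
    int s = (Z[i] * Ly + Y[i]) * Lx + X[i];
    if (grid[s] != -1) stop("two beads occupy one lattice site");
    grid[s] = i;
  }
  std::map<std::pair<int,int>, int> counts;
  for (int b = 0; b < nb; ++b) {
    for (int k = 0; k < 26; ++k) {
      int xs = wrap(X[b] + SHELL.off[k][0], Lx);
      int ys = wrap(Y[b] + SHELL.off[k][1], Ly);
      int zs = wrap(Z[b] + SHELL.off[k][2], Lz);
      int o = grid[(zs * Ly + ys) * Lx + xs];
      if (o > b && chain_of[o] != chain_of[b]) {
        int ci = chain_of[b], cj = chain_of[o];
        if (ci > cj) std::swap(ci, cj);
        ++counts[std::make_pair(ci, cj)];
      }
    }
  }
  IntegerMatrix out(counts.size(), 3);
  int r = 0;
  for (std::map<std::pair<int,int>, int>::iterator it = counts.begin();
       it != counts.end(); ++it, ++r) {
    out(r, 0) = it->first.first;
    out(r, 1) = it->first.second;
    out(r, 2) = it->second;
  }
  return out;
}

// Spherical-shell histogram of bead counts (per species) and lattice-site
// counts around a center, with minimal-image distances.
// [[Rcpp::export]]
List cpp_radial_histogram(IntegerMatrix coords, IntegerVector species_of_bead,
                          NumericVector com, IntegerVector box,
                          double binwidth, int nbins, int nspecies) {
  int Lx = box[0], Ly = box[1], Lz = box[2];
  NumericMatrix beadcnt(nspecies, nbins);
  NumericVector sitecnt(nbins);
  // site counts: histogram of all lattice sites' distances from com
  for (int zi = 0; zi < Lz; ++zi) {
    double dz = std::fabs(zi - com[2]); if (dz > Lz / 2.0) dz = Lz - dz;
    for (int yi = 0; yi < Ly; ++yi) {
      double dy = std::fabs(yi - com[1]); if (dy > Ly / 2.0) dy = Ly - dy;
      double dyz = dy * dy + dz * dz;
      for (int xi = 0; xi < Lx; ++xi) {
        double dx = std::fabs(xi - com[0]); if (dx > Lx / 2.0) dx = Lx - dx;
        double r = std::sqrt(dx * dx + dyz);
        int bin = static_cast<int>(r / binwidth);
        if (bin < nbins) sitecnt[bin] += 1.0;
      }
    }
  }
  int nb = coords.nrow();
  for (int i = 0; i < nb; ++i) {
    double dx = std::fabs(wrap(coords(i,0), Lx) - com[0]);
    if (dx > Lx / 2.0) dx = Lx - dx;
    double dy = std::fabs(wrap(coords(i,1), Ly) - com[1]);
    if (dy > Ly / 2.0) dy = Ly - dy;
    double dz = std::fabs(wrap(coords(i,2), Lz) - com[2]);
    if (dz > Lz / 2.0) dz = Lz - dz;
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    int bin = static_cast<int>(r / binwidth);
    if (bin < nbins) beadcnt(species_of_bead[i] - 1, bin) += 1.0;
  }
  return List::create(_["site_counts"] = sitecnt, _["bead_counts"] = beadcnt);
}

namespace {

// conformation store for exact enumeration
struct Conf {
  std::vector<int> sites;
  double intra_E;
};

void grow_saw(int chain, int bead, int N, std::vector<int>& cur,
              std::vector<char>& occ, int Lx, int Ly, int Lz,
              const std::vector<int>& types, int spc, int ntype, int nspecies,
              const std::vector<double>& E, const std::vector<double>& elec,
              bool bexcl, std::vector<Conf>& out, double max_confs) {
  if (bead == N) {
    Conf c; c.sites = cur;
    // intra-chain energy (non-bonded shell contacts; elec uses own species)
    double e = 0.0;
    for (int i = 0; i < N; ++i) {
      int xi = cur[i] % Lx, yi = (cur[i] / Lx) % Ly, zi = cur[i] / (Lx * Ly);
      for (int j = i + 1; j < N; ++j) {
        int xj = cur[j] % Lx, yj = (cur[j] / Lx) % Ly, zj = cur[j] / (Lx * Ly);
        if (cheb(xi, yi, zi, xj, yj, zj, Lx, Ly, Lz) == 1) {
          if (bexcl && j == i + 1) continue;
          e += E[types[i] * ntype + types[j]] + elec[spc * nspecies + spc];
        }
      }
    }
    c.intra_E = e;
    out.push_back(c);
    if (out.size() > static_cast<size_t>(max_confs))
      stop("enumerate_exact: state space too large");
    return;
  }
  int prev = cur[bead - 1];
  int px = prev % Lx, py = (prev / Lx) % Ly, pz = prev / (Lx * Ly);
  for (int k = 0; k < 26; ++k) {
    int xs = wrap(px + SHELL.off[k][0], Lx);
    int ys = wrap(py + SHELL.off[k][1], Ly);
    int zs = wrap(pz + SHELL.off[k][2], Lz);
    int s = (zs * Ly + ys) * Lx + xs;
    if (occ[s]) continue;
    cur[bead] = s; occ[s] = 1;
    grow_saw(chain, bead + 1, N, cur, occ, Lx, Ly, Lz, types, spc, ntype,
             nspecies, E, elec, bexcl, out, max_confs);
    occ[s] = 0;
  }
}

} // namespace

// Exact canonical averages for a tiny system by exhaustive enumeration.
// Chain 1's first bead is pinned at the origin (translational reduction);
// intensive averages are unaffected. Returns, per temperature: mean energy
// and mean inter-chain bead-contact counts per unordered species pair.
// [[Rcpp::export]]
List cpp_enumerate_exact(List type_seqs, IntegerVector species_of_chain,
                         IntegerVector box, NumericMatrix Emat,
                         NumericMatrix elec, bool bonded_excluded,
                         NumericVector temperatures, double max_confs) {
  int Lx = box[0], Ly = box[1], Lz = box[2], V = Lx * Ly * Lz;
  int nchain = type_seqs.size();
  int ntype = Emat.nrow(), nspecies = elec.nrow();
  std::vector<double> E(ntype * ntype), EL(nspecies * nspecies);
  for (int i = 0; i < ntype; ++i)
    for (int j = 0; j < ntype; ++j) E[i * ntype + j] = Emat(i, j);
  for (int i = 0; i < nspecies; ++i)
    for (int j = 0; j < nspecies; ++j) EL[i * nspecies + j] = elec(i, j);

  std::vector<std::vector<int> > types(nchain);
  std::vector<int> spc(nchain);
  for (int c = 0; c < nchain; ++c) {
    IntegerVector tv = type_seqs[c];
    types[c].resize(tv.size());
    for (int i = 0; i < tv.size(); ++i) types[c][i] = tv[i] - 1;
    spc[c] = species_of_chain[c] - 1;
  }

  // per-chain conformations
  std::vector<std::vector<Conf> > confs(nchain);
  for (int c = 0; c < nchain; ++c) {
    int N = types[c].size();
    std::vector<int> cur(N);
    std::vector<char> occ(V, 0);
    int starts = (c == 0) ? 1 : V;
    for (int s0 = 0; s0 < starts; ++s0) {
      cur[0] = s0; occ[s0] = 1;
      grow_saw(c, 1, N, cur, occ, Lx, Ly, Lz, types[c], spc[c], ntype,
               nspecies, E, EL, bonded_excluded, confs[c], max_confs);
      occ[s0] = 0;
    }
  }
  double est = 1.0;
  for (int c = 0; c < nchain; ++c) est *= confs[c].size();
  if (est > max_confs) stop("enumerate_exact: state space too large");

  int nT = temperatures.size();
  int npair = nspecies * (nspecies + 1) / 2;
  std::vector<double> Z(nT, 0.0), EW(nT, 0.0);
  std::vector<std::vector<double> > CW(nT, std::vector<double>(npair, 0.0));
  double n_states = 0.0;

  // joint enumeration with incremental inter-chain terms
  std::vector<int> pick(nchain, 0);
  std::vector<char> occ(V, 0);
  std::vector<int> beadtype(V, -1), beadspc(V, -1), beadchain(V, -1);
  std::vector<double> interE(nchain + 1, 0.0);
  std::vector<std::vector<double> > interC(nchain + 1,
                                           std::vector<double>(npair, 0.0));
  // recursion via explicit stack
  int level = 0;
  std::vector<int> idx(nchain, 0);
  std::vector<char> placedflag(nchain, 0);
  while (level >= 0) {
    if (level == nchain) {
      double Etot = interE[nchain];
      for (int c = 0; c < nchain; ++c) Etot += confs[c][idx[c] - 1].intra_E;
      n_states += 1.0;
      for (int t = 0; t < nT; ++t) {
        double w = std::exp(-Etot / temperatures[t]);
        Z[t] += w; EW[t] += Etot * w;
        for (int p = 0; p < npair; ++p) CW[t][p] += interC[nchain][p] * w;
      }
      --level;
      continue;
    }
    // remove previous successful placement at this level, if any
    if (placedflag[level]) {
      const Conf& prev = confs[level][idx[level] - 1];
      for (size_t i = 0; i < prev.sites.size(); ++i) {
        occ[prev.sites[i]] = 0; beadchain[prev.sites[i]] = -1;
      }
      placedflag[level] = 0;
    }
    if (idx[level] >= static_cast<int>(confs[level].size())) {
      idx[level] = 0;
      --level;
      continue;
    }
    const Conf& cf = confs[level][idx[level]];
    ++idx[level];
    // overlap check
    bool clash = false;
    for (size_t i = 0; i < cf.sites.size() && !clash; ++i)
      if (occ[cf.sites[i]]) clash = true;
    if (clash) continue;
    // inter-chain contributions against already-placed chains
    double addE = 0.0;
    std::vector<double> addC(npair, 0.0);
    int N = cf.sites.size();
    for (int i = 0; i < N; ++i) {
      int s = cf.sites[i];
      int xi = s % Lx, yi = (s / Lx) % Ly, zi = s / (Lx * Ly);
      for (int k = 0; k < 26; ++k) {
        int xs = wrap(xi + SHELL.off[k][0], Lx);
        int ys = wrap(yi + SHELL.off[k][1], Ly);
        int zs = wrap(zi + SHELL.off[k][2], Lz);
        int so = (zs * Ly + ys) * Lx + xs;
        if (!occ[so]) continue;
        int tj = beadtype[so], sj = beadspc[so];
        int ti = types[level][i], si = spc[level];
        addE += E[ti * ntype + tj] + EL[si * nspecies + sj];
        int a = std::min(si, sj), b = std::max(si, sj);
        addC[a * nspecies - a * (a - 1) / 2 + (b - a)] += 1.0;
      }
    }
    for (int i = 0; i < N; ++i) {
      occ[cf.sites[i]] = 1;
      beadtype[cf.sites[i]] = types[level][i];
      beadspc[cf.sites[i]] = spc[level];
      beadchain[cf.sites[i]] = level;
    }
    placedflag[level] = 1;
    interE[level + 1] = interE[level] + addE;
    for (int p = 0; p < npair; ++p)
      interC[level + 1][p] = interC[level][p] + addC[p];
    ++level;
  }

  NumericVector mean_E(nT);
  NumericMatrix mean_C(nT, npair);
  for (int t = 0; t < nT; ++t) {
    mean_E[t] = EW[t] / Z[t];
    for (int p = 0; p < npair; ++p) mean_C(t, p) = CW[t][p] / Z[t];
  }
  return List::create(_["mean_energy"] = mean_E,
                      _["mean_contacts"] = mean_C,
                      _["n_states"] = n_states);
}
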