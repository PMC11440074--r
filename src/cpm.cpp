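// Core of the Cellular Potts engine: Metropolis voxel-copy dynamics on a
// 3D lattice with per-cell volume/surface constraints, contact energies
// and a frozen wall shell. All randomness comes from R's RNG so runs are
// reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// entity types, indexed by label ID (0 = medium)
enum { T_MEDIUM = 0, T_CELL = 1, T_WALL = 2 };

struct EngineParams {
  double lambda_V, lambda_A, J_cc, J_cm, J_cw, temperature;
};

static inline double sq(double x) { return x * x; }

// contact energy between the entities owning two voxels; a pair within
// the same entity carries no energy
static inline double jpair(int a, int b, const int *type,
                           const EngineParams &p) {
  if (a == b) return 0.0;
  const int ta = type[a], tb = type[b];
  if (ta == T_CELL && tb == T_CELL) return p.J_cc;
  if ((ta == T_CELL && tb == T_MEDIUM) || (ta == T_MEDIUM && tb == T_CELL))
    return p.J_cm;
  if ((ta == T_CELL && tb == T_WALL) || (ta == T_WALL && tb == T_CELL))
    return p.J_cw;
  return 0.0;
}

// Metropolis acceptance; shared by the engine and the exported helper so
// tests exercise the exact production rule
static inline bool metro_accept(double dh, double temperature) {
  if (dh <= 0.0) return true;
  return unif_rand() < std::exp(-dh / temperature);
}

struct Offsets {
  std::vector<int> lin;     // linear strides
};

static Offsets make_offsets(int nx, int ny, int order_max2) {
  // order_max2: squared-distance cutoff (1 = faces, 2 = +edges, 3 = +corners)
  Offsets o;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int r2 = dx * dx + dy * dy + dz * dz;
        if (r2 > 0 && r2 <= order_max2)
          o.lin.push_back(dx + dy * nx + dz * nx * ny);
      }
  return o;
}

static const int FACE_STRIDES_N = 6;

// recompute per-ID volume and face-contact surface from the lattice
static void recount(const int *lat, int nx, int ny, int nz,
                    std::vector<double> &V, std::vector<double> &A) {
  std::fill(V.begin(), V.end(), 0.0);
  std::fill(A.begin(), A.end(), 0.0);
  const long nxy = (long)nx * ny;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long i = x + (long)y * nx + (long)z * nxy;
        int id = lat[i];
        if (id > 0) V[id] += 1.0;
        // faces counted once per boundary face, attributed to each side
        const int dx[3] = {1, 0, 0}, dy[3] = {0, 1, 0}, dz3[3] = {0, 0, 1};
        for (int k = 0; k < 3; ++k) {
          int x2 = x + dx[k], y2 = y + dy[k], z2 = z + dz3[k];
          if (x2 >= nx || y2 >= ny || z2 >= nz) continue;
          long j = x2 + (long)y2 * nx + (long)z2 * nxy;
          int jd = lat[j];
          if (id != jd) {
            if (id > 0) A[id] += 1.0;
            if (jd > 0) A[jd] += 1.0;
          }
        }
      }
}

// full Hamiltonian from the lattice (used to seed the energy trace)
static double full_h(const int *lat, int nx, int ny, int nz, const int *type,
                     const double *Vt, const double *At,
                     const std::vector<double> &V,
                     const std::vector<double> &A, const EngineParams &p,
                     int contact_order) {
  double h = 0.0;
  for (size_t id = 1; id < V.size(); ++id) {
    if (type[id] == T_CELL) {
      h += p.lambda_V * sq(V[id] - Vt[id]);
      h += p.lambda_A * sq(A[id] - At[id]);
    }
  }
  // contact term: each unordered voxel pair once (positive half-space)
  const long nxy = (long)nx * ny;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int r2 = dx * dx + dy * dy + dz * dz;
        if (r2 == 0 || r2 > contact_order) continue;
        if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) continue;
        for (int z = 0; z < nz; ++z) {
          int z2 = z + dz;
          if (z2 >= nz) continue;
          for (int y = 0; y < ny; ++y) {
            int y2 = y + dy;
            if (y2 < 0 || y2 >= ny) continue;
            for (int x = 0; x < nx; ++x) {
              int x2 = x + dx;
              if (x2 < 0 || x2 >= nx) continue;
              h += jpair(lat[x + (long)y * nx + (long)z * nxy],
                         lat[x2 + (long)y2 * nx + (long)z2 * nxy], type, p);
            }
          }
        }
      }
  return h;
}

// local energy change for copying candidate `n_id` into `site`
static double local_dh(const int *lat, long site, int nx, int ny,
                       const Offsets &contact, const int *type,
                       const double *Vt, const double *At,
                       const std::vector<double> &V,
                       const std::vector<double> &A, int o_id, int n_id,
                       const EngineParams &p) {
  const long face[FACE_STRIDES_N] = {1, -1, nx, -nx, (long)nx * ny,
                                     -(long)nx * ny};
  int c_o = 0, c_n = 0;
  for (int k = 0; k < FACE_STRIDES_N; ++k) {
    int q = lat[site + face[k]];
    if (q == o_id) ++c_o;
    if (q == n_id) ++c_n;
  }
  double dh = 0.0;
  if (type[o_id] == T_CELL) {
    dh += p.lambda_V * (sq(V[o_id] - 1.0 - Vt[o_id]) - sq(V[o_id] - Vt[o_id]));
    int dA = 2 * c_o - 6;
    dh += p.lambda_A * (sq(A[o_id] + dA - At[o_id]) - sq(A[o_id] - At[o_id]));
  }
  if (type[n_id] == T_CELL) {
    dh += p.lambda_V * (sq(V[n_id] + 1.0 - Vt[n_id]) - sq(V[n_id] - Vt[n_id]));
    int dA = 6 - 2 * c_n;
    dh += p.lambda_A * (sq(A[n_id] + dA - At[n_id]) - sq(A[n_id] - At[n_id]));
  }
  for (size_t k = 0; k < contact.lin.size(); ++k) {
    int q = lat[site + contact.lin[k]];
    dh += jpair(n_id, q, type, p) - jpair(o_id, q, type, p);
  }
  return dh;
}

static EngineParams unpack_params(double lambda_V, double lambda_A,
                                  double J_cc, double J_cm, double J_cw,
                                  double temperature) {
  EngineParams p;
  p.lambda_V = lambda_V; p.lambda_A = lambda_A;
  p.J_cc = J_cc; p.J_cm = J_cm; p.J_cw = J_cw;
  p.temperature = temperature;
  return p;
}

// [[Rcpp::export]]
List cpm_run_cpp(IntegerVector lattice, IntegerVector dims,
                 IntegerVector type, NumericVector target_v,
                 NumericVector target_a, double lambda_V, double lambda_A,
                 double J_cc, double J_cm, double J_cw, double temperature,
                 int contact_order, int copy_neighborhood, int n_mcs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n_ids = type.size();          // indexed by ID, entry 0 = medium
  EngineParams p = unpack_params(lambda_V, lambda_A, J_cc, J_cm, J_cw,
                                 temperature);
  IntegerVector lat = clone(lattice);
  int *latp = lat.begin();
  std::vector<double> V(n_ids, 0.0), A(n_ids, 0.0);
  recount(latp, nx, ny, nz, V, A);

  Offsets contact = make_offsets(nx, ny, contact_order);
  Offsets copies = make_offsets(nx, ny, copy_neighborhood == 6 ? 1 : 3);
  const int n_off = (int)copies.lin.size();

  // interior sites: one voxel in from every face (the wall shell)
  std::vector<long> interior;
  interior.reserve((long)(nx - 2) * (ny - 2) * (nz - 2));
  for (int z = 1; z < nz - 1; ++z)
    for (int y = 1; y < ny - 1; ++y)
      for (int x = 1; x < nx - 1; ++x)
        interior.push_back(x + (long)y * nx + (long)z * (long)nx * ny);
  const long n_int = (long)interior.size();

  NumericVector h_trace(n_mcs + 1);
  h_trace[0] = full_h(latp, nx, ny, nz, type.begin(), target_v.begin(),
                      target_a.begin(), V, A, p, contact_order);
  long attempted = 0, accepted = 0;
  double h = h_trace[0];

  for (int m = 0; m < n_mcs; ++m) {
    for (long t = 0; t < n_int; ++t) {
      ++attempted;
      long k1 = (long)(unif_rand() * n_int);
      if (k1 >= n_int) k1 = n_int - 1;
      long site = interior[k1];
      int k2 = (int)(unif_rand() * n_off);
      if (k2 >= n_off) k2 = n_off - 1;
      int o_id = latp[site];
      int n_id = latp[site + copies.lin[k2]];
      if (o_id == n_id) continue;
      if (type[o_id] == T_WALL || type[n_id] == T_WALL) continue;
      double dh = local_dh(latp, site, nx, ny, contact, type.begin(),
                           target_v.begin(), target_a.begin(), V, A,
                           o_id, n_id, p);
      if (metro_accept(dh, p.temperature)) {
        // bookkeeping: volumes, face-contact surfaces, running energy
        const long face[FACE_STRIDES_N] = {1, -1, nx, -nx, (long)nx * ny,
                                           -(long)nx * ny};
        int c_o = 0, c_n = 0;
        for (int k = 0; k < FACE_STRIDES_N; ++k) {
          int q = latp[site + face[k]];
          if (q == o_id) ++c_o;
          if (q == n_id) ++c_n;
        }
        if (o_id > 0) { V[o_id] -= 1.0; A[o_id] += 2 * c_o - 6; }
        if (n_id > 0) { V[n_id] += 1.0; A[n_id] += 6 - 2 * c_n; }
        latp[site] = n_id;
        h += dh;
        ++accepted;
      }
    }
    h_trace[m + 1] = h;
  }

  return List::create(_["lattice"] = lat, _["volume"] = wrap(V),
                      _["surface"] = wrap(A), _["h_trace"] = h_trace,
                      _["attempted"] = (double)attempted,
                      _["accepted"] = (double)accepted);
}

// [[Rcpp::export]]
double cpm_delta_h_cpp(IntegerVector lattice, IntegerVector dims,
                       IntegerVector type, NumericVector volume,
                       NumericVector surface, NumericVector target_v,
                       NumericVector target_a, IntegerVector site,
                       int candidate_id, double lambda_V, double lambda_A,
                       double J_cc, double J_cm, double J_cw,
                       double temperature, int contact_order) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  EngineParams p = unpack_params(lambda_V, lambda_A, J_cc, J_cm, J_cw,
                                 temperature);
  int x = site[0] - 1, y = site[1] - 1, z = site[2] - 1; // 1-based in R
  if (x < 1 || y < 1 || z < 1 || x >= nx - 1 || y >= ny - 1 || z >= nz - 1)
    stop("site must lie in the lattice interior");
  long s = x + (long)y * nx + (long)z * (long)nx * ny;
  int o_id = lattice[s];
  if (o_id == candidate_id) stop("candidate ID equals the site's current ID");
  if (type[o_id] == T_WALL || type[candidate_id] == T_WALL)
    stop("wall voxels can be neither source nor target of a copy");
  std::vector<double> V(volume.begin(), volume.end());
  std::vector<double> A(surface.begin(), surface.end());
  Offsets contact = make_offsets(nx, ny, contact_order);
  return local_dh(lattice.begin(), s, nx, ny, contact, type.begin(),
                  target_v.begin(), target_a.begin(), V, A, o_id,
                  candidate_id, p);
}

// [[Rcpp::export]]
LogicalVector metropolis_accept_cpp(NumericVector dh, double temperature) {
  LogicalVector out(dh.size());
  for (R_xlen_t i = 0; i < dh.size(); ++i)
    out[i] = metro_accept(dh[i], temperature);
  return out;
}

// [[Rcpp::export]]
List cpm_recount_cpp(IntegerVector lattice, IntegerVector dims, int n_ids) {
  std::vector<double> V(n_ids, 0.0), A(n_ids, 0.0);
  recount(lattice.begin(), dims[0], dims[1], dims[2], V, A);
  return List::create(_["volume"] = wrap(V), _["surface"] = wrap(A));
}
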