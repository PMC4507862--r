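#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Positions are converted to row-major flat storage (x_i = P[3i+k]) on
// entry: R matrices are column-major and the inner loops want contiguous
// coordinates per particle.
static std::vector<double> rowmajor(const NumericMatrix &pos) {
  int N = pos.nrow();
  std::vector<double> P(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) P[3 * i + k] = pos(i, k);
  return P;
}

static NumericMatrix to_matrix(const std::vector<double> &P) {
  int N = (int)P.size() / 3;
  NumericMatrix m(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) m(i, k) = P[3 * i + k];
  return m;
}

// Uniform-grid table lookup with linear interpolation.  Tables store u and
// f = -du/dr on r = 0, dr, 2dr, ...; values at or beyond rcut are zero.
struct PairTable {
  double dr, rcut;
  const double *u, *f;
  int n;
};

static inline double mi_dist2(const double *a, const double *b, double L) {
  double d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = a[k] - b[k];
    d -= L * std::nearbyint(d / L);
    d2 += d * d;
  }
  return d2;
}

static inline double tab_interp(const PairTable &t, double r, bool force) {
  if (r >= t.rcut) return 0.0;
  double x = r / t.dr;
  int i = (int)x;
  if (i >= t.n - 1) return 0.0;
  double w = x - i;
  const double *v = force ? t.f : t.u;
  return v[i] * (1.0 - w) + v[i + 1] * w;
}

static std::vector<PairTable> unpack_tables(const List &tables) {
  std::vector<PairTable> out;
  for (int i = 0; i < tables.size(); ++i) {
    List tl = tables[i];
    PairTable t;
    t.dr   = as<double>(tl["dr"]);
    t.rcut = as<double>(tl["rcut"]);
    NumericVector u = tl["u"], f = tl["f"];
    t.u = REAL(u); t.f = REAL(f);
    t.n = u.size();
    out.push_back(t);
  }
  return out;
}

static double total_energy_vec(const std::vector<double> &P,
                               const IntegerVector &type,
                               const IntegerVector &mol, double L,
                               const std::vector<PairTable> &tabs,
                               const IntegerMatrix &pair_idx) {
  int N = (int)P.size() / 3;
  double U = 0.0;
  for (int i = 0; i < N - 1; ++i)
    for (int j = i + 1; j < N; ++j) {
      if (mol[i] == mol[j]) continue;
      int ti = pair_idx(type[i] - 1, type[j] - 1);
      double r = std::sqrt(mi_dist2(&P[3 * i], &P[3 * j], L));
      U += tab_interp(tabs[ti - 1], r, false);
    }
  return U;
}

// [[Rcpp::export]]
double cpp_total_energy(const NumericMatrix &pos, const IntegerVector &type,
                        const IntegerVector &mol, double L,
                        const List &tables, const IntegerMatrix &pair_idx) {
  std::vector<PairTable> tabs = unpack_tables(tables);
  std::vector<double> P = rowmajor(pos);
  return total_energy_vec(P, type, mol, L, tabs, pair_idx);
}

// [[Rcpp::export]]
double cpp_virial_frame(const NumericMatrix &pos, const IntegerVector &type,
                        const IntegerVector &mol, double L,
                        const List &tables, const IntegerMatrix &pair_idx) {
  std::vector<PairTable> tabs = unpack_tables(tables);
  std::vector<double> P = rowmajor(pos);
  int N = pos.nrow();
  double W = 0.0;
  for (int i = 0; i < N - 1; ++i)
    for (int j = i + 1; j < N; ++j) {
      if (mol[i] == mol[j]) continue;
      int ti = pair_idx(type[i] - 1, type[j] - 1);
      double r = std::sqrt(mi_dist2(&P[3 * i], &P[3 * j], L));
      W += tab_interp(tabs[ti - 1], r, true) * r;
    }
  return W;
}

// Interaction energy of the sites of one molecule with all other molecules
// (intramolecular pairs excluded; bonded degrees of freedom are frozen).
static double mol_energy(const std::vector<double> &P,
                         const std::vector<PairTable> &tabs,
                         const IntegerVector &type, const IntegerVector &mol,
                         const IntegerMatrix &pair_idx, double L,
                         const std::vector<int> &sites,
                         const std::vector<double> &xyz, bool use_prop) {
  int N = (int)P.size() / 3;
  double U = 0.0;
  int m = mol[sites[0]];
  for (size_t s = 0; s < sites.size(); ++s) {
    int i = sites[s];
    const double *pi = use_prop ? &xyz[3 * s] : &P[3 * i];
    for (int j = 0; j < N; ++j) {
      if (mol[j] == m) continue;
      int ti = pair_idx(type[i] - 1, type[j] - 1);
      double r = std::sqrt(mi_dist2(pi, &P[3 * j], L));
      U += tab_interp(tabs[ti - 1], r, false);
    }
  }
  return U;
}

static inline double pbc(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;
  return x;
}

// NVT Metropolis chain.  Moves: single-molecule displacement; for
// molecules with >1 site, rigid translation or rigid rotation about the
// geometric center (symmetric proposals).  Uses R's RNG so a set.seed()
// call in R makes the chain fully reproducible.  Every 1000 moves the
// incrementally tracked energy is compared against a full recomputation
// and the largest discrepancy reported (bookkeeping diagnostic).
// [[Rcpp::export]]
List cpp_mc_nvt(const NumericMatrix &pos0, const IntegerVector &type,
                const IntegerVector &mol, double L, const List &tables,
                const IntegerMatrix &pair_idx, double beta, int n_steps,
                double max_disp, double max_rot, int n_equil, int stride) {
  std::vector<PairTable> tabs = unpack_tables(tables);
  std::vector<double> P = rowmajor(pos0);
  int N = pos0.nrow();

  int nmol = 0;
  for (int i = 0; i < N; ++i) nmol = std::max(nmol, mol[i]);
  std::vector<std::vector<int> > groups(nmol);
  for (int i = 0; i < N; ++i) groups[mol[i] - 1].push_back(i);

  double U = total_energy_vec(P, type, mol, L, tabs, pair_idx);
  double drift_max = 0.0;
  long n_acc = 0;
  List frames;
  std::vector<double> prop;

  for (int step = 1; step <= n_steps; ++step) {
    int m = (int)(unif_rand() * nmol);
    if (m >= nmol) m = nmol - 1;
    const std::vector<int> &sites = groups[m];
    int ns = (int)sites.size();
    prop.assign(3 * ns, 0.0);

    bool rotate = (ns > 1) && (unif_rand() < 0.5);
    if (!rotate) {
      double dx = (unif_rand() - 0.5) * 2.0 * max_disp;
      double dy = (unif_rand() - 0.5) * 2.0 * max_disp;
      double dz = (unif_rand() - 0.5) * 2.0 * max_disp;
      for (int s = 0; s < ns; ++s) {
        prop[3 * s]     = pbc(P[3 * sites[s]] + dx, L);
        prop[3 * s + 1] = pbc(P[3 * sites[s] + 1] + dy, L);
        prop[3 * s + 2] = pbc(P[3 * sites[s] + 2] + dz, L);
      }
    } else {
      // unwrap sites around the first one, rotate about the centroid
      const double *ref = &P[3 * sites[0]];
      std::vector<double> uw(3 * ns);
      double cen[3] = {0, 0, 0};
      for (int s = 0; s < ns; ++s) {
        for (int k = 0; k < 3; ++k) {
          double d = P[3 * sites[s] + k] - ref[k];
          d -= L * std::nearbyint(d / L);
          uw[3 * s + k] = ref[k] + d;
          cen[k] += uw[3 * s + k];
        }
      }
      for (int k = 0; k < 3; ++k) cen[k] /= ns;
      // random axis (Marsaglia) + uniform angle in (-max_rot, max_rot)
      double ax, ay, az;
      for (;;) {
        double u1 = 2.0 * unif_rand() - 1.0, u2 = 2.0 * unif_rand() - 1.0;
        double s2 = u1 * u1 + u2 * u2;
        if (s2 < 1.0 && s2 > 1e-12) {
          double rt = 2.0 * std::sqrt(1.0 - s2);
          ax = u1 * rt; ay = u2 * rt; az = 1.0 - 2.0 * s2;
          break;
        }
      }
      double th = (unif_rand() - 0.5) * 2.0 * max_rot;
      double c = std::cos(th), s = std::sin(th), cc = 1.0 - c;
      double R[3][3] = {
        {c + ax * ax * cc,      ax * ay * cc - az * s, ax * az * cc + ay * s},
        {ay * ax * cc + az * s, c + ay * ay * cc,      ay * az * cc - ax * s},
        {az * ax * cc - ay * s, az * ay * cc + ax * s, c + az * az * cc}
      };
      for (int si = 0; si < ns; ++si) {
        double v[3];
        for (int k = 0; k < 3; ++k) v[k] = uw[3 * si + k] - cen[k];
        for (int k = 0; k < 3; ++k) {
          double nv = R[k][0] * v[0] + R[k][1] * v[1] + R[k][2] * v[2];
          prop[3 * si + k] = pbc(cen[k] + nv, L);
        }
      }
    }

    double U_old = mol_energy(P, tabs, type, mol, pair_idx, L, sites, prop, false);
    double U_new = mol_energy(P, tabs, type, mol, pair_idx, L, sites, prop, true);
    double dU = U_new - U_old;
    if (dU <= 0.0 || unif_rand() < std::exp(-beta * dU)) {
      for (int s = 0; s < ns; ++s)
        for (int k = 0; k < 3; ++k) P[3 * sites[s] + k] = prop[3 * s + k];
      U += dU;
      ++n_acc;
    }

    if (step % 1000 == 0) {
      double Ur = total_energy_vec(P, type, mol, L, tabs, pair_idx);
      double d = std::fabs(Ur - U);
      if (d > drift_max) drift_max = d;
    }
    if (step > n_equil && stride > 0 && (step - n_equil) % stride == 0)
      frames.push_back(to_matrix(P));
  }

  return List::create(_["frames"] = frames, _["final"] = to_matrix(P),
                      _["acceptance"] = (double)n_acc / n_steps,
                      _["energy"] = U, _["drift_max"] = drift_max);
}

// [[Rcpp::export]]
List cpp_neighbor_simple(const NumericMatrix &pos, double L, double cutoff) {
  std::vector<double> P = rowmajor(pos);
  int N = pos.nrow();
  std::vector<int> vi, vj;
  std::vector<double> vr;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < N - 1; ++i)
    for (int j = i + 1; j < N; ++j) {
      double d2 = mi_dist2(&P[3 * i], &P[3 * j], L);
      if (d2 <= c2) {
        vi.push_back(i + 1); vj.push_back(j + 1);
        vr.push_back(std::sqrt(d2));
      }
    }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj), _["r"] = wrap(vr));
}

struct CellGrid {
  int nc;
  double cell;
  std::vector<std::vector<int> > cells;
  std::vector<int> cx, cy, cz;
};

static CellGrid build_grid(const std::vector<double> &P, double L,
                           double cutoff) {
  int N = (int)P.size() / 3;
  CellGrid g;
  g.nc = (int)std::floor(L / cutoff);
  if (g.nc < 3) stop("grid search needs >= 3 cells per box edge");
  g.cell = L / g.nc;
  g.cells.resize((size_t)g.nc * g.nc * g.nc);
  g.cx.resize(N); g.cy.resize(N); g.cz.resize(N);
  for (int i = 0; i < N; ++i) {
    int cx = (int)(pbc(P[3 * i], L) / g.cell);     if (cx >= g.nc) cx = g.nc - 1;
    int cy = (int)(pbc(P[3 * i + 1], L) / g.cell); if (cy >= g.nc) cy = g.nc - 1;
    int cz = (int)(pbc(P[3 * i + 2], L) / g.cell); if (cz >= g.nc) cz = g.nc - 1;
    g.cells[((size_t)cx * g.nc + cy) * g.nc + cz].push_back(i);
    g.cx[i] = cx; g.cy[i] = cy; g.cz[i] = cz;
  }
  return g;
}

// Cell-list search: particles binned into a grid with cell edge >= cutoff;
// pairs collected from each cell and its 26 periodic neighbors.  Caller
// guarantees at least 3 cells per edge.
// [[Rcpp::export]]
List cpp_neighbor_grid(const NumericMatrix &pos, double L, double cutoff) {
  std::vector<double> P = rowmajor(pos);
  int N = pos.nrow();
  CellGrid g = build_grid(P, L, cutoff);
  std::vector<int> vi, vj;
  std::vector<double> vr;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < N; ++i)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int cx = (g.cx[i] + dx + g.nc) % g.nc;
          int cy = (g.cy[i] + dy + g.nc) % g.nc;
          int cz = (g.cz[i] + dz + g.nc) % g.nc;
          const std::vector<int> &cl =
            g.cells[((size_t)cx * g.nc + cy) * g.nc + cz];
          for (size_t q = 0; q < cl.size(); ++q) {
            int j = cl[q];
            if (j <= i) continue;
            double d2 = mi_dist2(&P[3 * i], &P[3 * j], L);
            if (d2 <= c2) {
              vi.push_back(i + 1); vj.push_back(j + 1);
              vr.push_back(std::sqrt(d2));
            }
          }
        }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj), _["r"] = wrap(vr));
}

// Count-only variants used by the scaling study (no pair storage, so the
// timing reflects the search itself).
// [[Rcpp::export]]
double cpp_neighbor_simple_count(const NumericMatrix &pos, double L,
                                 double cutoff) {
  std::vector<double> P = rowmajor(pos);
  int N = pos.nrow();
  double c2 = cutoff * cutoff, n = 0;
  for (int i = 0; i < N - 1; ++i)
    for (int j = i + 1; j < N; ++j)
      if (mi_dist2(&P[3 * i], &P[3 * j], L) <= c2) n += 1;
  return n;
}

// [[Rcpp::export]]
double cpp_neighbor_grid_count(const NumericMatrix &pos, double L,
                               double cutoff) {
  std::vector<double> P = rowmajor(pos);
  int N = pos.nrow();
  CellGrid g = build_grid(P, L, cutoff);
  double c2 = cutoff * cutoff, n = 0;
  for (int i = 0; i < N; ++i)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int cx = (g.cx[i] + dx + g.nc) % g.nc;
          int cy = (g.cy[i] + dy + g.nc) % g.nc;
          int cz = (g.cz[i] + dz + g.nc) % g.nc;
          const std::vector<int> &cl =
            g.cells[((size_t)cx * g.nc + cy) * g.nc + cz];
          for (size_t q = 0; q < cl.size(); ++q) {
            int j = cl[q];
            if (j <= i) continue;
            if (mi_dist2(&P[3 * i], &P[3 * j], L) <= c2) n += 1;
          }
        }
  return n;
}

// Histogram of minimum-image pair distances for one frame; bins are
// half-open [k*dr, (k+1)*dr), distances exactly at rmax excluded.
// typeA/typeB are 1-based species codes; typeA == typeB counts i<j pairs.
// [[Rcpp::export]]
IntegerVector cpp_pair_hist(const NumericMatrix &pos, const IntegerVector &type,
                            const IntegerVector &mol, double L, int typeA,
                            int typeB, double rmax, double dr,
                            bool exclude_same_mol) {
  std::vector<double> P = rowmajor(pos);
  int N = pos.nrow();
  int nb = (int)std::nearbyint(rmax / dr);
  IntegerVector h(nb);
  double r2max = rmax * rmax;
  for (int i = 0; i < N; ++i) {
    if (type[i] != typeA) continue;
    for (int j = 0; j < N; ++j) {
      if (type[j] != typeB) continue;
      if (typeA == typeB && j <= i) continue;
      if (typeA != typeB && j == i) continue;
      if (exclude_same_mol && mol[i] == mol[j]) continue;
      double d2 = mi_dist2(&P[3 * i], &P[3 * j], L);
      if (d2 < r2max) {
        int b = (int)(std::sqrt(d2) / dr);
        if (b < nb) ++h[b];
      }
    }
  }
  return h;
}

// Per-frame sums of d u_CG(r_ij)/d c_k over all pairs: the cubic B-spline
// basis weights of each pair distance scattered onto knot indices.  pots is
// a list of list(dr, rcut, rmin, offset) aligned with pair_idx codes; the
// result row holds the full concatenated parameter vector for one frame.
// [[Rcpp::export]]
NumericMatrix cpp_deriv_frames(const List &frames, const IntegerVector &type,
                               const IntegerVector &mol, double L,
                               const List &pots, const IntegerMatrix &pair_idx,
                               int total_dim) {
  int nf = frames.size();
  int np = pots.size();
  std::vector<double> pdr(np), prcut(np), prmin(np);
  std::vector<int> poff(np);
  for (int p = 0; p < np; ++p) {
    List pl = pots[p];
    pdr[p] = as<double>(pl["dr"]);
    prcut[p] = as<double>(pl["rcut"]);
    prmin[p] = as<double>(pl["rmin"]);
    poff[p] = as<int>(pl["offset"]);
  }
  NumericMatrix D(nf, total_dim);
  for (int f = 0; f < nf; ++f) {
    NumericMatrix pos = frames[f];
    std::vector<double> P = rowmajor(pos);
    int N = pos.nrow();
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        if (mol[i] == mol[j]) continue;
        int p = pair_idx(type[i] - 1, type[j] - 1) - 1;
        double r = std::sqrt(mi_dist2(&P[3 * i], &P[3 * j], L));
        if (r >= prcut[p] || r <= prmin[p]) continue;
        int k = (int)(r / pdr[p]);
        double t = r / pdr[p] - k;
        double t2 = t * t, t3 = t2 * t;
        double w0 = (1 - 3 * t + 3 * t2 - t3) / 6.0;
        double w1 = (4 - 6 * t2 + 3 * t3) / 6.0;
        double w2 = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
        double w3 = t3 / 6.0;
        int o = poff[p] + k;
        D(f, o) += w0; D(f, o + 1) += w1; D(f, o + 2) += w2; D(f, o + 3) += w3;
      }
    }
  }
  return D;
}
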