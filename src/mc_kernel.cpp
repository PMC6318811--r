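// Voxelized Monte Carlo photon transport with implicit-capture weight
// deposition, Henyey-Greenstein scattering and Russian roulette.
//
// Geometry: z in [0, zmax] with variable bin edges (z increases into the
// tissue); x (and y in 3-D mode) on a uniform lattice.  Label lookup is
// edge-clamped laterally, i.e. the tissue continues unchanged beyond the
// scored window, so photons never escape laterally.  All lengths in mm,
// coefficients in mm^-1.
//
// Scoring modes:
//   0 "xz"     labels (nz x nx), y-invariant; deposit into (z, x) cells
//              when |y| <= slab_half (slab_half = Inf gives y-summed
//              scoring).
//   1 "planar" labels (nz), laterally homogeneous; photons launch at the
//              origin and deposit into z bins when the radial
//              displacement is within the beam radius.  This is the
//              exact center-axis deposition under a flat-top disk beam.
//   2 "xyz"    labels (nz x nx x ny); deposit into 3-D cells inside the
//              lattice window.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {  // xoshiro256++
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

inline int find_z_bin(const NumericVector& ze, double z, int nz) {
  // binary search: largest k with ze[k] <= z, clamped to [0, nz-1]
  int lo = 0, hi = nz;  // ze has nz+1 entries
  if (z <= ze[0]) return 0;
  if (z >= ze[nz]) return nz - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (ze[mid] <= z) lo = mid; else hi = mid;
  }
  return lo;
}

inline void hg_scatter(Rng& rng, double g, double& ux, double& uy, double& uz) {
  double ct;
  if (std::fabs(g) < 1e-6) {
    ct = 2.0 * rng.unif() - 1.0;
  } else {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 6.283185307179586 * rng.unif();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nuz = -st * cp * den + uz * ct;
    ux = nux; uy = nuy; uz = nuz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// unpolarized Fresnel reflectance, internal incidence (n_t = n1 -> 1.0)
inline double fresnel_internal(double n1, double cos_i) {
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n1 * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  if (cos_i > 0.99999) {
    double r = (n1 - 1.0) / (n1 + 1.0);
    return r * r;
  }
  double rs = (n1 * cos_i - cos_t) / (n1 * cos_i + cos_t);
  double rp = (n1 * cos_t - cos_i) / (n1 * cos_t + cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// [[Rcpp::export(name = ".mc_kernel")]]
List mc_kernel(IntegerVector labels, IntegerVector dims, int mode,
               NumericVector mua_lut, NumericVector mus_lut, NumericVector g_lut,
               NumericVector z_edges, double x0, double dx,
               double y0, double dy,
               double beam_radius, int n_photons, double seed,
               bool fresnel, double n_tissue,
               double slab_half, double launch_half_x, double launch_half_y,
               double w_min, double p_survive) {
  const int nz = dims[0];
  const int nx = (mode == 1) ? 1 : dims[1];
  const int ny = (mode == 2) ? dims[2] : 1;
  const double zmax = z_edges[nz];
  const double R2 = beam_radius * beam_radius;

  std::vector<double> dep((size_t)nz * nx * ny, 0.0);
  double absorbed_total = 0.0, absorbed_scored = 0.0;
  double reflected = 0.0, transmitted = 0.0, roulette_lost = 0.0;

  Rng rng((uint64_t)seed);
  const double r_specular =
      fresnel ? std::pow((n_tissue - 1.0) / (n_tissue + 1.0), 2.0) : 0.0;
  const double inv_p_survive = 1.0 / p_survive;

  for (int ip = 0; ip < n_photons; ++ip) {
    // launch on the flat-top disk (planar mode: at the origin)
    double lx = 0.0, ly = 0.0;
    if (mode != 1) {
      for (int tries = 0; tries < 100000; ++tries) {
        double ax = beam_radius * (2.0 * rng.unif() - 1.0);
        double ay = beam_radius * (2.0 * rng.unif() - 1.0);
        if (ax * ax + ay * ay <= R2 &&
            std::fabs(ax) <= launch_half_x && std::fabs(ay) <= launch_half_y) {
          lx = ax; ly = ay; break;
        }
      }
    }
    double x = lx, y = ly, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - r_specular;
    reflected += r_specular;
    int iz = 0;
    bool alive = true;

    while (alive) {
      double tau = -std::log(rng.unif());  // sampled optical depth
      // consume tau across voxel faces
      while (true) {
        // material of the current voxel
        int ix = 0, iy = 0;
        if (mode != 1) {
          ix = (int)std::floor((x - x0) / dx);
          if (ix < 0) ix = 0; else if (ix >= nx) ix = nx - 1;
        }
        if (mode == 2) {
          iy = (int)std::floor((y - y0) / dy);
          if (iy < 0) iy = 0; else if (iy >= ny) iy = ny - 1;
        }
        int lab = (mode == 1) ? labels[iz]
                 : (mode == 0) ? labels[iz + (size_t)nz * ix]
                               : labels[iz + (size_t)nz * ix + (size_t)nz * nx * iy];
        double mua = mua_lut[lab], mus = mus_lut[lab];
        double mut = mua + mus;

        // distance to nearest voxel face along the direction
        double d_face = 1e30;
        int face = -1;  // 0: z-face, 1: x-face, 2: y-face
        if (uz > 1e-12) {
          double d = (z_edges[iz + 1] - z) / uz;
          if (d < d_face) { d_face = d; face = 0; }
        } else if (uz < -1e-12) {
          double d = (z_edges[iz] - z) / uz;
          if (d < d_face) { d_face = d; face = 0; }
        }
        if (mode != 1) {  // infinite x lattice (labels clamped laterally)
          if (ux > 1e-12) {
            double xf = x0 + (std::floor((x - x0) / dx) + 1.0) * dx;
            double d = (xf - x) / ux;
            if (d < d_face) { d_face = d; face = 1; }
          } else if (ux < -1e-12) {
            double xf = x0 + std::floor((x - x0) / dx) * dx;
            double d = (xf - x) / ux;
            if (d >= 0 && d < d_face) { d_face = d; face = 1; }
          }
        }
        if (mode == 2) {
          if (uy > 1e-12) {
            double yf = y0 + (std::floor((y - y0) / dy) + 1.0) * dy;
            double d = (yf - y) / uy;
            if (d < d_face) { d_face = d; face = 2; }
          } else if (uy < -1e-12) {
            double yf = y0 + std::floor((y - y0) / dy) * dy;
            double d = (yf - y) / uy;
            if (d >= 0 && d < d_face) { d_face = d; face = 2; }
          }
        }
        if (d_face < 0) d_face = 0;

        double d_int = (mut > 0) ? tau / mut : 1e30;
        if (d_int < d_face) {
          // interact inside this voxel
          x += ux * d_int; y += uy * d_int; z += uz * d_int;
          double adep = w * mua / mut;
          absorbed_total += adep;
          // score
          if (mode == 1) {
            if (x * x + y * y <= R2) {
              dep[iz] += adep; absorbed_scored += adep;
            }
          } else if (mode == 0) {
            if (std::fabs(y) <= slab_half && x >= x0 && x < x0 + nx * dx) {
              dep[iz + (size_t)nz * ix] += adep; absorbed_scored += adep;
            }
          } else {
            if (x >= x0 && x < x0 + nx * dx && y >= y0 && y < y0 + ny * dy) {
              dep[iz + (size_t)nz * ix + (size_t)nz * nx * iy] += adep;
              absorbed_scored += adep;
            }
          }
          w -= adep;
          // scatter
          if (mus > 0) {
            hg_scatter(rng, g_lut[lab], ux, uy, uz);
          } else {
            // pure absorber: photon continues forward, weight decays
          }
          // roulette
          if (w < w_min) {
            if (rng.unif() < p_survive) {
              w *= inv_p_survive;
            } else {
              roulette_lost += w;
              alive = false;
            }
          }
          break;  // new tau
        }

        // advance to the face
        const double eps = 1e-9;
        x += ux * (d_face + eps); y += uy * (d_face + eps); z += uz * (d_face + eps);
        tau -= mut * d_face;
        if (tau < 0) tau = 0;
        if (face == 0) {
          if (uz < 0 && z <= z_edges[0]) {
            // top surface
            bool escapes = true;
            if (fresnel) {
              double r = fresnel_internal(n_tissue, -uz);
              if (rng.unif() < r) escapes = false;
            }
            if (escapes) {
              reflected += w;
              alive = false;
              break;
            } else {
              uz = -uz;
              z = z_edges[0] + eps;
              iz = 0;
              continue;
            }
          }
          if (uz > 0 && z >= zmax) {
            transmitted += w;
            alive = false;
            break;
          }
          iz = find_z_bin(z_edges, z, nz);
        }
        // x/y faces need no action beyond the move (labels are clamped)
      }
    }
  }

  double n = (double)n_photons;
  return List::create(
      _["dep"] = NumericVector(dep.begin(), dep.end()),
      _["absorbed_total"] = absorbed_total / n,
      _["absorbed_scored"] = absorbed_scored / n,
      _["reflected"] = reflected / n,
      _["transmitted"] = transmitted / n,
      _["roulette_lost"] = roulette_lost / n);
}
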