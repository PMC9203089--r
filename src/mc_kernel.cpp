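// Weighted-photon Monte-Carlo transport in a layered slab, MCML-style:
// exponential step sampling, Henyey-Greenstein scattering, absorption by
// weight decay, Fresnel reflection/refraction at all index mismatches,
// Russian roulette termination. Exit weight is tallied into a rectangular
// field-of-view grid (restricted to the collection acceptance cone) and
// into azimuthal radial bins (all diffusely reflected photons).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

// xoshiro256++ seeded through splitmix64; self-contained so that results
// are bit-reproducible across platforms independent of R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
};

// Unpolarized Fresnel reflectance for incidence cosine cos_i going from
// index n1 into n2; on transmission cos_t receives the refracted cosine.
double fresnel(double n1, double n2, double cos_i, double &cos_t) {
  if (cos_i > 1.0) cos_i = 1.0;
  if (n1 == n2) { cos_t = cos_i; return 0.0; }
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n1 / n2 * sin_i;
  if (sin_t >= 1.0) { cos_t = 0.0; return 1.0; }  // total internal reflection
  cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

inline void spin(double g, double &ux, double &uy, double &uz, Xoshiro &rng) {
  double cost;
  if (std::fabs(g) < 1e-6) {
    cost = 2.0 * rng.unif() - 1.0;
  } else {
    double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
    cost = (1.0 + g * g - t * t) / (2.0 * g);
  }
  if (cost > 1.0) cost = 1.0;
  if (cost < -1.0) cost = -1.0;
  double sint = std::sqrt(1.0 - cost * cost);
  double phi = 2.0 * M_PI * rng.unif();
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp;
    uy = sint * sinp;
    uz = (uz >= 0.0 ? cost : -cost);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nux = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    double nuy = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    double nuz = -sint * cosp * den + uz * cost;
    ux = nux; uy = nuy; uz = nuz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

}  // namespace

// [[Rcpp::export]]
List mc_layered(NumericVector mua, NumericVector mus, NumericVector g,
                NumericVector n_layer, NumericVector thickness,
                double n_ambient, double spot_radius, double incidence_deg,
                double fov_x0, double fov_x1, double fov_y0, double fov_y1,
                double accept_half_deg, double bin_mm,
                double radial_bin_mm, int n_radial,
                int n_photons, double seed, double stream,
                int max_steps = 1000000) {
  const int nl = mua.size();
  const int nx = (int) std::lround((fov_x1 - fov_x0) / bin_mm);
  const int ny = (int) std::lround((fov_y1 - fov_y0) / bin_mm);
  NumericMatrix fov(ny, nx);
  NumericVector radial(n_radial);

  // layer z boundaries; last layer may be semi-infinite (thickness = Inf)
  std::vector<double> z_top(nl), z_bot(nl);
  double z = 0.0;
  for (int l = 0; l < nl; ++l) {
    z_top[l] = z;
    z_bot[l] = (R_FINITE(thickness[l])) ? z + thickness[l] : R_PosInf;
    z = z_bot[l];
  }

  const double cos_accept = std::cos(accept_half_deg * M_PI / 180.0);
  const double theta_i = incidence_deg * M_PI / 180.0;
  const double cos_in = std::cos(theta_i);
  const double roulette_floor = 1e-4, roulette_p = 0.1;

  uint64_t sd = (uint64_t) seed * 0x9E3779B97F4A7C15ULL +
                (uint64_t) stream * 0xBF58476D1CE4E5B9ULL + 1ULL;
  Xoshiro rng(sd);

  double t_spec = 0.0, t_refl = 0.0, t_trans = 0.0, t_abs = 0.0;

  for (int ip = 0; ip < n_photons; ++ip) {
    // launch: uniform top-hat disk, tilted toward +x by the incidence angle
    double rr = spot_radius * std::sqrt(rng.unif());
    double phi0 = 2.0 * M_PI * rng.unif();
    double x = rr * std::cos(phi0), y = rr * std::sin(phi0), pz = 0.0;

    double cos_t;
    double rsp = fresnel(n_ambient, n_layer[0], cos_in, cos_t);
    t_spec += rsp;
    double w = 1.0 - rsp;
    if (w <= 0.0) continue;
    double sin_t = std::sqrt(std::max(0.0, 1.0 - cos_t * cos_t));
    double ux = sin_t, uy = 0.0, uz = cos_t;

    int layer = 0;
    int steps = 0;
    bool alive = true;

    while (alive) {
      if (++steps > max_steps) {
        // pathological long walker (only reachable in near-lossless media,
        // where it escapes eventually): count toward total reflectance,
        // position no longer tracked so no spatial tally
        t_refl += w;
        alive = false;
        break;
      }
      double su = -std::log(rng.unif_pos());  // dimensionless step
      while (su > 0.0 && alive) {
        double mut = mua[layer] + mus[layer];
        double db;  // distance to the boundary along the flight direction
        if (uz > 0.0)      db = (z_bot[layer] - pz) / uz;
        else if (uz < 0.0) db = (z_top[layer] - pz) / uz;
        else               db = R_PosInf;
        double s = su / mut;
        if (db > s) {
          x += ux * s; y += uy * s; pz += uz * s;
          su = 0.0;
        } else {
          x += ux * db; y += uy * db; pz += uz * db;
          su -= db * mut;
          if (uz < 0.0 && layer == 0) {
            // tissue -> ambient surface
            double ct;
            double rf = fresnel(n_layer[0], n_ambient, -uz, ct);
            if (rng.unif() < rf) {
              uz = -uz; pz = z_top[0];
            } else {
              t_refl += w;
              double r_exit = std::sqrt(x * x + y * y);
              int ir = (int) std::floor(r_exit / radial_bin_mm);
              if (ir >= 0 && ir < n_radial) radial[ir] += w;
              if (ct >= cos_accept &&
                  x >= fov_x0 && x < fov_x1 && y >= fov_y0 && y < fov_y1) {
                int ix = (int) std::floor((x - fov_x0) / bin_mm);
                int iy = (int) std::floor((y - fov_y0) / bin_mm);
                if (ix >= 0 && ix < nx && iy >= 0 && iy < ny)
                  fov(iy, ix) += w;
              }
              alive = false;
            }
          } else if (uz > 0.0 && layer == nl - 1) {
            // bottom escape (finite stack only)
            double ct;
            double rf = fresnel(n_layer[layer], n_ambient, uz, ct);
            if (rng.unif() < rf) {
              uz = -uz; pz = z_bot[layer];
            } else {
              t_trans += w;
              alive = false;
            }
          } else {
            // internal interface
            int lnext = (uz > 0.0) ? layer + 1 : layer - 1;
            double ct;
            double rf = fresnel(n_layer[layer], n_layer[lnext],
                                std::fabs(uz), ct);
            if (rng.unif() < rf) {
              uz = -uz;
            } else {
              double scale = n_layer[layer] / n_layer[lnext];
              ux *= scale; uy *= scale;
              uz = (uz > 0.0) ? ct : -ct;
              double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
              ux /= norm; uy /= norm; uz /= norm;
              layer = lnext;
            }
          }
        }
      }
      if (!alive) break;

      // drop
      double mut = mua[layer] + mus[layer];
      if (mua[layer] > 0.0) {
        double dw = w * mua[layer] / mut;
        t_abs += dw;
        w -= dw;
      }
      // spin
      spin(g[layer], ux, uy, uz, rng);
      // roulette, with exact weight bookkeeping: the survival boost is
      // debited from the absorbed tally so all tallies sum to unity
      if (w < roulette_floor) {
        if (rng.unif() < roulette_p) {
          t_abs -= w * (1.0 / roulette_p - 1.0);
          w /= roulette_p;
        } else {
          t_abs += w;
          alive = false;
        }
      }
    }
  }

  double np = (double) n_photons;
  for (int i = 0; i < ny; ++i)
    for (int j = 0; j < nx; ++j) fov(i, j) /= np;
  for (int i = 0; i < n_radial; ++i) radial[i] /= np;

  return List::create(
    _["fov"] = fov,
    _["radial"] = radial,
    _["tallies"] = NumericVector::create(
      _["specular"] = t_spec / np,
      _["reflected"] = t_refl / np,
      _["transmitted"] = t_trans / np,
      _["absorbed"] = t_abs / np));
}
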