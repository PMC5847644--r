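// Monte Carlo photon transport through a homogeneous scattering slab for
// forward/backward SHG directionality lookup tables.
//
// Geometry: slab occupies z in [0, thickness] (um); z = 0 is the
// objective-side (backward) face, z = thickness the condenser-side (forward)
// face. Photons are created at a given depth, launched up (+z) with
// probability r/(1+r) or down with 1/(1+r), uniformly in solid angle within
// a cone about the axis. Henyey-Greenstein scattering, weight-based
// absorption, NA-limited collection with Snell refraction at the exit face.
//
// Uses a self-contained xoshiro256** RNG so tables are bit-reproducible for
// a fixed seed independently of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

namespace {

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
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]: never 0 so log() is safe
  double runif_pos() {
    return (static_cast<double>(next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  // uniform in [0, 1)
  double runif() {
    return static_cast<double>(next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// rotate direction (ux,uy,uz) by polar angle with cos ct about itself,
// azimuth phi (standard MCML update)
inline void scatter(double &ux, double &uy, double &uz, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0) ? ct : -ct;
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  // renormalise against drift
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

} // namespace

// Returns c(collected_F, collected_B, escaped, absorbed, n) as summed photon
// weights (divide by n for fractions). Lengths in um, mus/mua in um^-1.
// [[Rcpp::export(name = ".mc_transport_cpp")]]
Rcpp::NumericVector mc_transport_cpp(double depth, double creation_ratio,
                                     double mus, double g, double n_tissue,
                                     double mua, double thickness,
                                     double na_forward, double na_backward,
                                     double cos_half_angle, double n_photons,
                                     double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  const double p_forward = creation_ratio / (1.0 + creation_ratio);
  const double mut = mus + mua;
  const double albedo = (mut > 0.0) ? mus / mut : 1.0;
  const long n = static_cast<long>(n_photons);
  double wF = 0.0, wB = 0.0, wEsc = 0.0, wAbs = 0.0;

  for (long i = 0; i < n; ++i) {
    // launch: cone about +z or -z, uniform in solid angle
    double axis = (rng.runif() < p_forward) ? 1.0 : -1.0;
    double ct0 = cos_half_angle + (1.0 - cos_half_angle) * rng.runif();
    double st0 = std::sqrt(std::max(0.0, 1.0 - ct0 * ct0));
    double phi0 = 2.0 * M_PI * rng.runif();
    double ux = st0 * std::cos(phi0);
    double uy = st0 * std::sin(phi0);
    double uz = axis * ct0;
    double z = depth;
    double w = 1.0;

    for (;;) {
      double step;
      if (mut <= 0.0) {
        step = 2.0 * thickness + 1.0; // ballistic: guaranteed to exit
      } else {
        step = -std::log(rng.runif_pos()) / mut;
      }
      double zn = z + uz * step;
      if (uz > 0.0 && zn >= thickness) {
        double sin_in = std::sqrt(std::max(0.0, 1.0 - uz * uz));
        if (n_tissue * sin_in <= na_forward) wF += w; else wEsc += w;
        break;
      }
      if (uz < 0.0 && zn <= 0.0) {
        double sin_in = std::sqrt(std::max(0.0, 1.0 - uz * uz));
        if (n_tissue * sin_in <= na_backward) wB += w; else wEsc += w;
        break;
      }
      z = zn;
      if (mua > 0.0) {
        wAbs += w * (1.0 - albedo);
        w *= albedo;
        // no roulette: exact weight accounting (F + B + escaped + absorbed
        // = launched); deposit negligible residual weight instead
        if (w < 1e-12) { wAbs += w; break; }
      }
      double ct = hg_cos(g, rng.runif());
      double phi = 2.0 * M_PI * rng.runif();
      scatter(ux, uy, uz, ct, phi);
      if (uz == 0.0) uz = 1e-12; // pathological exact-horizontal direction
    }
  }

  Rcpp::NumericVector out(5);
  out[0] = wF; out[1] = wB; out[2] = wEsc; out[3] = wAbs;
  out[4] = static_cast<double>(n);
  return out;
}
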