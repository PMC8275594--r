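#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

// Self-contained counter-free RNG (xoshiro256++) so simulation results are
// bit-reproducible for a given seed independently of R's RNG state, and so
// worker chunks can run on splitmix-derived streams.
namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
};

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    SplitMix64 sm(seed);
    for (int i = 0; i < 4; ++i) s[i] = sm.next();
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

inline double fresnel_unpolarized(double cosi, double n1, double n2) {
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n1 / n2 * sini;
  if (sint >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

inline void hg_scatter(Xoshiro256pp& rng, double g,
                       double& ux, double& uy, double& uz) {
  double ct;
  double u = rng.unif();
  if (g == 0.0) {
    ct = 2.0 * u - 1.0;
  } else {
    double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
    ct = (1.0 + g * g - t * t) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * rng.unif();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -den * st * cp + uz * ct;
    double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm; uy = ny / norm; uz = nz / norm;
  }
}

}  // namespace

// Weighted-photon Monte Carlo transport through a layered slab.
// Geometry: z = 0 at the air-tissue surface, +z downward; source beam
// centered at (beam_cx, beam_cy), detector disk centered at (separation, 0).
// Internal layer interfaces are index-matched; only the top surface refracts.
// [[Rcpp::export(name = ".mc_run_cpp")]]
Rcpp::List mc_run_cpp(Rcpp::NumericVector z_top, Rcpp::NumericVector z_bot,
                      Rcpp::NumericVector mua, Rcpp::NumericVector mus,
                      double g, double n_tissue, double n_external,
                      double lateral_halfwidth, double total_depth,
                      double src_radius, double det_radius, double separation,
                      bool ring_detector,
                      double beam_cx, double beam_cy, bool flat_beam,
                      double n_photons_d, double seed_d, int n_chunks,
                      double weight_threshold, double roulette_survival,
                      double max_events_d,
                      bool record_map, bool map_all_photons,
                      Rcpp::NumericVector map_lo, Rcpp::NumericVector map_hi,
                      double voxel) {
  const int n_layers = z_top.size();
  const long long n_photons = (long long)n_photons_d;
  const long long max_events = (long long)max_events_d;
  const double r_spec =
      std::pow((n_tissue - n_external) / (n_tissue + n_external), 2.0);
  const double det_r2 = det_radius * det_radius;
  const double sigma = src_radius / 2.0;       // 1/e^2 radius -> Gaussian sd
  const double trunc_r = 2.0 * src_radius;     // beam truncated at 2 radii

  // event map geometry
  int nx = 0, ny = 0, nz = 0;
  std::vector<double> emap;
  if (record_map) {
    nx = (int)std::ceil((map_hi[0] - map_lo[0]) / voxel - 1e-9);
    ny = (int)std::ceil((map_hi[1] - map_lo[1]) / voxel - 1e-9);
    nz = (int)std::ceil((map_hi[2] - map_lo[2]) / voxel - 1e-9);
    emap.assign((size_t)nx * ny * nz, 0.0);
  }

  long double launched = 0.0L, detected = 0.0L, absorbed = 0.0L;
  long double esc_surface = 0.0L, esc_lateral = 0.0L, esc_bottom = 0.0L;
  long double roulette_lost = 0.0L, cap_lost = 0.0L;
  long long n_detected = 0, n_capped = 0;

  std::vector<double> rec_x, rec_y, rec_w, rec_maxz, rec_pl;
  std::vector<int> rec_nev;
  std::vector<long long> ebuf;            // per-photon voxel indices
  std::vector<double> plbuf(n_layers);    // per-photon pathlength per layer

  SplitMix64 seeder((uint64_t)seed_d);
  std::vector<uint64_t> chunk_seeds(n_chunks);
  for (int c = 0; c < n_chunks; ++c) chunk_seeds[c] = seeder.next();

  for (int chunk = 0; chunk < n_chunks; ++chunk) {
    Xoshiro256pp rng(chunk_seeds[chunk]);
    long long lo = n_photons * chunk / n_chunks;
    long long hi = n_photons * (chunk + 1) / n_chunks;
    for (long long p = lo; p < hi; ++p) {
      // launch
      double x, y;
      if (flat_beam) {
        double r = src_radius * std::sqrt(rng.unif());
        double a = 2.0 * M_PI * rng.unif();
        x = r * std::cos(a); y = r * std::sin(a);
      } else {
        do {
          // Box-Muller
          double u1 = rng.unif(), u2 = rng.unif();
          double m = std::sqrt(-2.0 * std::log(1.0 - u1));
          x = sigma * m * std::cos(2.0 * M_PI * u2);
          y = sigma * m * std::sin(2.0 * M_PI * u2);
        } while (x * x + y * y > trunc_r * trunc_r);
      }
      x += beam_cx; y += beam_cy;
      double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
      double w = 1.0 - r_spec;
      launched += w;
      int layer = 0;
      double maxz = 0.0;
      long long nev = 0;
      bool alive = true;
      if (record_map) ebuf.clear();
      std::fill(plbuf.begin(), plbuf.end(), 0.0);

      double tau = -std::log(1.0 - rng.unif());  // dimensionless optical path
      while (alive) {
        double mt = mua[layer] + mus[layer];
        double s_free = tau / mt;
        double s_bound;
        if (uz > 0.0)      s_bound = (z_bot[layer] - z) / uz;
        else if (uz < 0.0) s_bound = (z - z_top[layer]) / (-uz);
        else               s_bound = INFINITY;

        if (s_free < s_bound) {
          // interaction inside the layer
          x += ux * s_free; y += uy * s_free; z += uz * s_free;
          plbuf[layer] += s_free;
          if (z > maxz) maxz = z;
          if (std::fabs(x) > lateral_halfwidth ||
              std::fabs(y) > lateral_halfwidth) {
            esc_lateral += w; alive = false; break;
          }
          double dep = w * mua[layer] / mt;
          absorbed += dep;
          w -= dep;
          ++nev;
          if (record_map) {
            int ix = (int)std::floor((x - map_lo[0]) / voxel);
            int iy = (int)std::floor((y - map_lo[1]) / voxel);
            int iz = (int)std::floor((z - map_lo[2]) / voxel);
            if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz)
              ebuf.push_back((long long)ix + nx * ((long long)iy + (long long)ny * iz));
          }
          hg_scatter(rng, g, ux, uy, uz);
          if (nev >= max_events) {
            cap_lost += w; ++n_capped; alive = false; break;
          }
          if (w < weight_threshold) {
            if (rng.unif() < roulette_survival) {
              w /= roulette_survival;
            } else {
              roulette_lost += w; alive = false; break;
            }
          }
          tau = -std::log(1.0 - rng.unif());
        } else {
          // reach a layer interface / slab boundary
          x += ux * s_bound; y += uy * s_bound; z += uz * s_bound;
          plbuf[layer] += s_bound;
          if (z > maxz) maxz = z;
          tau -= s_bound * mt;
          if (std::fabs(x) > lateral_halfwidth ||
              std::fabs(y) > lateral_halfwidth) {
            esc_lateral += w; alive = false; break;
          }
          if (uz > 0.0) {
            if (layer == n_layers - 1) {
              esc_bottom += w; alive = false; break;
            }
            ++layer;
            z = z_top[layer];
          } else {
            if (layer == 0) {
              // air-tissue surface
              double cosi = -uz;
              double R = (n_tissue == n_external)
                             ? 0.0
                             : fresnel_unpolarized(cosi, n_tissue, n_external);
              if (R >= 1.0 || (R > 0.0 && rng.unif() < R)) {
                uz = -uz;  // internal reflection
                z = 0.0;
              } else {
                // transmitted: escapes with its full current weight
                bool det;
                if (ring_detector) {
                  double rr = std::sqrt(x * x + y * y);
                  det = std::fabs(rr - separation) <= det_radius;
                } else {
                  det = ((x - separation) * (x - separation) + y * y)
                        <= det_r2;
                }
                if (det) {
                  detected += w; ++n_detected;
                  rec_x.push_back(x); rec_y.push_back(y);
                  rec_w.push_back(w); rec_maxz.push_back(maxz);
                  rec_nev.push_back((int)nev);
                  for (int l = 0; l < n_layers; ++l)
                    rec_pl.push_back(plbuf[l]);
                  if (record_map && !map_all_photons)
                    for (size_t k = 0; k < ebuf.size(); ++k)
                      emap[ebuf[k]] += 1.0;
                } else {
                  esc_surface += w;
                }
                alive = false; break;
              }
            } else {
              --layer;
              z = z_bot[layer];
            }
          }
        }
      }
      if (record_map && map_all_photons)
        for (size_t k = 0; k < ebuf.size(); ++k) emap[ebuf[k]] += 1.0;
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("n_photons") = (double)n_photons,
      Rcpp::Named("incident_weight") = (double)n_photons,
      Rcpp::Named("launched_weight") = (double)launched,
      Rcpp::Named("detected_weight") = (double)detected,
      Rcpp::Named("absorbed_weight") = (double)absorbed,
      Rcpp::Named("escaped_surface_weight") = (double)esc_surface,
      Rcpp::Named("escaped_lateral_weight") = (double)esc_lateral,
      Rcpp::Named("escaped_bottom_weight") = (double)esc_bottom,
      Rcpp::Named("roulette_lost_weight") = (double)roulette_lost,
      Rcpp::Named("cap_lost_weight") = (double)cap_lost,
      Rcpp::Named("specular_weight") = (double)n_photons * r_spec,
      Rcpp::Named("n_detected") = (double)n_detected,
      Rcpp::Named("n_capped") = (double)n_capped,
      Rcpp::Named("exit_x") = Rcpp::wrap(rec_x),
      Rcpp::Named("exit_y") = Rcpp::wrap(rec_y),
      Rcpp::Named("exit_weights") = Rcpp::wrap(rec_w),
      Rcpp::Named("max_depths") = Rcpp::wrap(rec_maxz),
      Rcpp::Named("n_events") = Rcpp::wrap(rec_nev),
      Rcpp::Named("path_lengths") = Rcpp::wrap(rec_pl));
  if (record_map) {
    Rcpp::NumericVector m(emap.begin(), emap.end());
    m.attr("dim") = Rcpp::IntegerVector::create(nx, ny, nz);
    out["event_map"] = m;
  }
  return out;
}
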