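#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel Monte-Carlo photon transport with Henyey-Greenstein scattering.
//
// Scattering distances are sampled against the local mu_s; absorption is
// handled by continuous weight attenuation along each intravoxel segment,
// which makes the per-segment energy split exact:
//   fluence contribution = w * (1 - exp(-mu_a s)) / mu_a   (track-length, m)
//   absorbed energy      = mu_a * fluence contribution
// Weight-roulette below 1e-4 keeps the walk unbiased. Randomness comes from
// R's own RNG stream (RNGScope), so results are reproducible via set.seed().
//
// Grid convention: voxel (ix,iy,iz), 0-based, x = [ix*dl,(ix+1)*dl); z is
// depth, photons enter at z = 0 travelling towards +z. Exits through the top
// or lateral faces are tallied "escaped", through the bottom face
// "transmitted".

static const double W_ROULETTE = 1e-4;
static const double P_SURVIVE = 0.1;

static inline int vox_index(int ix, int iy, int iz, int nx, int ny) {
  return ix + nx * (iy + (long)ny * iz);
}

// [[Rcpp::export]]
List mc_transport_cpp(IntegerVector dims, double dl,
                      NumericVector mu_a, NumericVector mu_s, NumericVector g,
                      int profile, double radius, double cx, double cy,
                      int n_photons) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double Lx = nx * dl, Ly = ny * dl, Lz = nz * dl;
  NumericVector acc((long)nx * ny * nz);  // sum of w*ds per voxel (m)
  double escaped = 0.0, transmitted = 0.0, dead = 0.0;
  const double eps = 1e-9 * dl;

  for (int ph = 0; ph < n_photons; ++ph) {
    // launch position on the top surface
    double r, phi = 2.0 * M_PI * unif_rand();
    if (profile == 0) {            // gaussian, radius = 1/e^2 intensity radius
      r = radius * std::sqrt(-std::log(unif_rand()) / 2.0);
    } else {                       // flat-top disc
      r = radius * std::sqrt(unif_rand());
    }
    double x = cx + r * std::cos(phi), y = cy + r * std::sin(phi), z = eps;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;

    if (x < 0 || x >= Lx || y < 0 || y >= Ly) { escaped += w; continue; }

    double tau = -std::log(unif_rand());  // dimensionless optical path to next scatter
    bool alive = true;
    long guard = 0;

    while (alive) {
      if (++guard > 1000000L) { dead += w; break; }
      int ix = (int)std::floor(x / dl), iy = (int)std::floor(y / dl),
          iz = (int)std::floor(z / dl);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) { escaped += w; break; }
      if (iz < 0) { escaped += w; break; }
      if (iz >= nz) { transmitted += w; break; }
      const int idx = vox_index(ix, iy, iz, nx, ny);
      const double mua = mu_a[idx], mus = mu_s[idx];

      // distance to the nearest voxel face along the current direction
      double db = HUGE_VAL;
      if (ux > 0) db = std::min(db, ((ix + 1) * dl - x) / ux);
      else if (ux < 0) db = std::min(db, (ix * dl - x) / ux);
      if (uy > 0) db = std::min(db, ((iy + 1) * dl - y) / uy);
      else if (uy < 0) db = std::min(db, (iy * dl - y) / uy);
      if (uz > 0) db = std::min(db, ((iz + 1) * dl - z) / uz);
      else if (uz < 0) db = std::min(db, (iz * dl - z) / uz);
      if (db < 0) db = 0;

      bool cross;
      double s;
      if (mus <= 0.0) { s = db; cross = true; }
      else if (tau > mus * db) { s = db; tau -= mus * db; cross = true; }
      else { s = tau / mus; cross = false; }

      // deposit track length with continuous absorption weighting
      if (mua > 0.0) {
        double att = std::exp(-mua * s);
        acc[idx] += w * (1.0 - att) / mua;
        w *= att;
      } else {
        acc[idx] += w * s;
      }

      x += ux * s; y += uy * s; z += uz * s;

      if (cross) {
        x += ux * eps; y += uy * eps; z += uz * eps;  // nudge across the face
        continue;
      }

      // Henyey-Greenstein scatter
      double gg = g[idx], ct;
      if (std::fabs(gg) < 1e-6) {
        ct = 1.0 - 2.0 * unif_rand();
      } else {
        double tmp = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * unif_rand());
        ct = (1.0 + gg * gg - tmp * tmp) / (2.0 * gg);
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      }
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double psi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(psi), sp = std::sin(psi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz > 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -st * cp * den + uz * ct;
        ux = nux; uy = nuy; uz = nuz;
      }
      double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= norm; uy /= norm; uz /= norm;

      tau = -std::log(unif_rand());

      if (w < W_ROULETTE) {
        if (unif_rand() < P_SURVIVE) w /= P_SURVIVE;
        else { dead += w; alive = false; }
      }
    }
  }

  double absorbed = 0.0;
  for (long i = 0; i < (long)nx * ny * nz; ++i) absorbed += mu_a[i] * acc[i];

  return List::create(_["track_length"] = acc,
                      _["absorbed"] = absorbed / n_photons,
                      _["escaped"] = escaped / n_photons,
                      _["transmitted"] = transmitted / n_photons,
                      _["lost"] = dead / n_photons);
}
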