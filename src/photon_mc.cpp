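#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Unpolarised Fresnel reflectance for a photon hitting the top surface from
// inside (index n1) against the external medium (index n2), incidence cosine ci.
static inline double fresnel_R(double n1, double n2, double ci) {
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) return 1.0; // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Layered semi-infinite random-walk photon transport with isotropic
// scattering at the reduced scattering rate (similarity relation).
// Absorption is NOT applied during flight; detected photons carry exact
// per-layer geometric pathlengths so any absorption can be applied later
// by reweighting.  Uses R's RNG stream, so results are reproducible under
// set.seed().
//
// boundaries: depths (mm) of the K-1 internal layer interfaces, increasing;
//   layer k (0-based) spans [boundaries[k-1], boundaries[k]), the last layer
//   is semi-infinite.
// mus: reduced scattering coefficient per layer (mm^-1), all > 0.
// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(NumericVector boundaries, NumericVector mus,
                      double n_in, double n_out,
                      double rho_min, double rho_max,
                      int n_photons, double max_path_mm) {
  const int K = mus.size();
  std::vector<double> det_paths;   // n_detected * K, row-major
  std::vector<double> det_rho;
  std::vector<double> pl(K);
  long long n_exit_top = 0;

  GetRNGstate();
  for (int ph = 0; ph < n_photons; ++ph) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0; // pencil beam straight down
    int layer = 0;
    double total = 0.0;
    std::fill(pl.begin(), pl.end(), 0.0);
    bool alive = true;

    while (alive) {
      double tau = -std::log(unif_rand()); // optical step in scattering MFPs
      while (tau > 0.0 && alive) {
        double s_full = tau / mus[layer];
        // geometric distance to the next z-interface along the flight path
        double d_bound = R_PosInf;
        int next_layer = layer;
        bool to_surface = false;
        if (uz > 0.0 && layer < K - 1) {
          d_bound = (boundaries[layer] - z) / uz;
          next_layer = layer + 1;
        } else if (uz < 0.0) {
          double zb = (layer == 0) ? 0.0 : boundaries[layer - 1];
          d_bound = (zb - z) / uz;
          next_layer = layer - 1;
          to_surface = (layer == 0);
        }
        if (d_bound < 0.0) d_bound = 0.0;

        double step = (s_full < d_bound) ? s_full : d_bound;
        x += step * ux; y += step * uy; z += step * uz;
        pl[layer] += step;
        total += step;
        tau -= step * mus[layer];
        if (total > max_path_mm) { alive = false; break; }

        if (s_full < d_bound) {
          // scattering site reached inside the current layer
          break;
        }
        // interface reached before the scattering site
        if (to_surface) {
          z = 0.0;
          double ci = -uz;
          if (unif_rand() < fresnel_R(n_in, n_out, ci)) {
            uz = -uz; // internally reflected, keep walking
          } else {
            ++n_exit_top;
            double rho = std::sqrt(x * x + y * y);
            if (rho >= rho_min && rho <= rho_max) {
              for (int k = 0; k < K; ++k) det_paths.push_back(pl[k]);
              det_rho.push_back(rho);
            }
            alive = false;
          }
        } else {
          z = (next_layer > layer) ? boundaries[layer] : boundaries[layer - 1];
          layer = next_layer;
        }
      }
      if (!alive) break;
      // isotropic scatter
      uz = 2.0 * unif_rand() - 1.0;
      double phi = 2.0 * M_PI * unif_rand();
      double sz = std::sqrt(std::max(0.0, 1.0 - uz * uz));
      ux = sz * std::cos(phi);
      uy = sz * std::sin(phi);
    }
  }
  PutRNGstate();

  const int n_det = det_rho.size();
  NumericMatrix L(n_det, K);
  for (int i = 0; i < n_det; ++i)
    for (int k = 0; k < K; ++k)
      L(i, k) = det_paths[(size_t)i * K + k];
  return List::create(_["layer_pathlengths"] = L,
                      _["exit_rho"] = NumericVector(det_rho.begin(), det_rho.end()),
                      _["n_exit_top"] = (double)n_exit_top,
                      _["n_launched"] = (double)n_photons);
}
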