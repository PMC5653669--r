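#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Deterministic RNG independent of R's RNG state: splitmix64 with Box-Muller
// normals. Same seed => bitwise-identical streams on a given build.
struct Rng {
  uint64_t s;
  bool have_norm;
  double cached_norm;
  explicit Rng(uint64_t seed) : s(seed), have_norm(false), cached_norm(0.0) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    if (have_norm) { have_norm = false; return cached_norm; }
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.28318530717958647692 * u2;
    cached_norm = r * std::sin(a);
    have_norm = true;
    return r * std::cos(a);
  }
};

// 2D binding landscape: flat plateau, inverted-Gaussian wells, hard excluded
// volume (protein slab with a binding channel) wrapped in a soft repulsive
// skin. Energies in units of kBT (kBT == 1).
struct Surface {
  std::vector<double> cx, cy, depth, sig2;
  double plateau;
  double xlo, xhi, ylo, yhi; // box
  double slab_xhi;           // protein occupies x <= slab_xhi ...
  double ch_xlo, ch_hw;      // ... except channel x in [ch_xlo, slab_xhi], |y| <= ch_hw
  double wall_k, wall_skin;

  bool excluded(double x, double y) const {
    if (x < xlo || x > xhi || y < ylo || y > yhi) return true;
    if (x < slab_xhi) {
      bool in_channel = (x >= ch_xlo) && (std::fabs(y) <= ch_hw);
      if (!in_channel) return true;
    }
    return false;
  }

  // distance from an accessible point to the excluded set
  double wall_dist(double x, double y) const {
    double d = std::min(std::min(x - xlo, xhi - x), std::min(y - ylo, yhi - y));
    double ay = std::fabs(y);
    if (x >= slab_xhi) {
      double ds = (ay > ch_hw) ? (x - slab_xhi)
                               : std::sqrt((x - slab_xhi) * (x - slab_xhi) +
                                           (ch_hw - ay) * (ch_hw - ay));
      d = std::min(d, ds);
    } else {
      // inside the channel: side walls and the channel end wall
      d = std::min(d, std::min(ch_hw - ay, x - ch_xlo));
    }
    return d;
  }

  // lambda_alpha scales away the attractive wells; walls/plateau untouched
  double energy(double x, double y, double lambda_alpha) const {
    double e = plateau;
    double d = wall_dist(x, y);
    if (d < wall_skin) {
      double t = 1.0 - d / wall_skin;
      e += wall_k * t * t;
    }
    double s = 1.0 - lambda_alpha;
    for (size_t w = 0; w < cx.size(); ++w) {
      double dx = x - cx[w], dy = y - cy[w];
      e -= s * depth[w] * std::exp(-(dx * dx + dy * dy) / (2.0 * sig2[w]));
    }
    return e;
  }
};

static Surface surface_from_list(const List& s) {
  Surface sf;
  NumericMatrix wells = s["wells"]; // columns: cx, cy, depth, sigma
  int nw = wells.nrow();
  sf.cx.resize(nw); sf.cy.resize(nw); sf.depth.resize(nw); sf.sig2.resize(nw);
  for (int w = 0; w < nw; ++w) {
    sf.cx[w] = wells(w, 0);
    sf.cy[w] = wells(w, 1);
    sf.depth[w] = wells(w, 2);
    sf.sig2[w] = wells(w, 3) * wells(w, 3);
  }
  sf.plateau = as<double>(s["plateau"]);
  NumericVector box = s["box"];
  sf.xlo = box[0]; sf.xhi = box[1]; sf.ylo = box[2]; sf.yhi = box[3];
  sf.slab_xhi = as<double>(s["slab_xhi"]);
  NumericVector ch = s["channel"];
  sf.ch_xlo = ch[0]; sf.ch_hw = ch[1];
  sf.wall_k = as<double>(s["wall_k"]);
  sf.wall_skin = as<double>(s["wall_skin"]);
  return sf;
}

// [[Rcpp::export(name = ".toy_energy_cpp")]]
NumericVector toy_energy_cpp(List surface, NumericMatrix pts, double lambda_alpha) {
  Surface sf = surface_from_list(surface);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (sf.excluded(pts(i, 0), pts(i, 1)))
      out[i] = R_PosInf;
    else
      out[i] = sf.energy(pts(i, 0), pts(i, 1), lambda_alpha);
  }
  return out;
}

// [[Rcpp::export(name = ".toy_excluded_cpp")]]
LogicalVector toy_excluded_cpp(List surface, NumericMatrix pts) {
  Surface sf = surface_from_list(surface);
  int n = pts.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sf.excluded(pts(i, 0), pts(i, 1));
  return out;
}

// [[Rcpp::export(name = ".metropolis_cpp")]]
List metropolis_cpp(List surface, double lambda_alpha, NumericVector start,
                    int n_steps, double step_size, double seed_d, int thin) {
  Surface sf = surface_from_list(surface);
  uint64_t seed = (uint64_t)seed_d;
  Rng rng(seed * 2654435761ULL + 1ULL);
  double x = start[0], y = start[1];
  if (sf.excluded(x, y)) stop("start position lies in the excluded region");
  if (thin < 1) thin = 1;
  int n_rec = n_steps / thin + 1;
  NumericMatrix pos(n_rec, 2);
  pos(0, 0) = x; pos(0, 1) = y;
  double e = sf.energy(x, y, lambda_alpha);
  long accepted = 0;
  int rec = 1;
  for (int t = 1; t <= n_steps; ++t) {
    double px = x + step_size * rng.norm();
    double py = y + step_size * rng.norm();
    if (!sf.excluded(px, py)) {
      double pe = sf.energy(px, py, lambda_alpha);
      double de = pe - e;
      if (de <= 0.0 || rng.unif() < std::exp(-de)) {
        x = px; y = py; e = pe; ++accepted;
      }
    }
    if (t % thin == 0) { pos(rec, 0) = x; pos(rec, 1) = y; ++rec; }
  }
  return List::create(_["positions"] = pos,
                      _["acceptance_fraction"] = (double)accepted / n_steps);
}

// Hamiltonian replica exchange over a ladder of flattening factors.
// Trajectory k records the coordinates simulated in ensemble k (fixed
// ensemble label; coordinates swap between ensembles on accepted exchanges).
// Per-replica move streams are independent of the swap-decision stream.
// [[Rcpp::export(name = ".replica_exchange_cpp")]]
List replica_exchange_cpp(List surface, NumericVector lambda_alphas,
                          NumericMatrix start, int n_steps,
                          int exchange_interval, double step_size,
                          double seed_d, int thin) {
  Surface sf = surface_from_list(surface);
  int K = lambda_alphas.size();
  uint64_t seed = (uint64_t)seed_d;
  std::vector<Rng> rngs;
  for (int k = 0; k < K; ++k)
    rngs.emplace_back(seed * 2654435761ULL + 1000003ULL * (k + 1));
  Rng swap_rng(seed * 2654435761ULL + 0xD1B54A32D192ED03ULL);

  std::vector<double> x(K), y(K), e(K);
  for (int k = 0; k < K; ++k) {
    x[k] = start(k, 0); y[k] = start(k, 1);
    if (sf.excluded(x[k], y[k])) stop("start position lies in the excluded region");
    e[k] = sf.energy(x[k], y[k], lambda_alphas[k]);
  }
  if (thin < 1) thin = 1;
  int n_rec = n_steps / thin + 1;
  // positions array: n_rec x 2 x K
  NumericVector posv(Dimension(n_rec, 2, K));
  for (int k = 0; k < K; ++k) {
    posv[0 + 0 * n_rec + (R_xlen_t)k * n_rec * 2] = x[k];
    posv[0 + 1 * n_rec + (R_xlen_t)k * n_rec * 2] = y[k];
  }
  std::vector<long> accepted(K, 0);
  long swaps_tried = 0, swaps_acc = 0;
  int parity = 0;
  int rec = 1;
  for (int t = 1; t <= n_steps; ++t) {
    for (int k = 0; k < K; ++k) {
      double px = x[k] + step_size * rngs[k].norm();
      double py = y[k] + step_size * rngs[k].norm();
      if (!sf.excluded(px, py)) {
        double pe = sf.energy(px, py, lambda_alphas[k]);
        double de = pe - e[k];
        if (de <= 0.0 || rngs[k].unif() < std::exp(-de)) {
          x[k] = px; y[k] = py; e[k] = pe; ++accepted[k];
        }
      }
    }
    if (exchange_interval > 0 && t % exchange_interval == 0) {
      for (int k = parity; k + 1 < K; k += 2) {
        int l = k + 1;
        double ekl = sf.energy(x[l], y[l], lambda_alphas[k]);
        double elk = sf.energy(x[k], y[k], lambda_alphas[l]);
        double delta = (e[k] + e[l]) - (ekl + elk);
        ++swaps_tried;
        if (delta >= 0.0 || swap_rng.unif() < std::exp(delta)) {
          std::swap(x[k], x[l]); std::swap(y[k], y[l]);
          e[k] = ekl; e[l] = elk;
          ++swaps_acc;
        }
      }
      parity = 1 - parity;
    }
    if (t % thin == 0) {
      for (int k = 0; k < K; ++k) {
        posv[rec + 0 * n_rec + (R_xlen_t)k * n_rec * 2] = x[k];
        posv[rec + 1 * n_rec + (R_xlen_t)k * n_rec * 2] = y[k];
      }
      ++rec;
    }
  }
  NumericVector acc(K);
  for (int k = 0; k < K; ++k) acc[k] = (double)accepted[k] / n_steps;
  return List::create(
      _["positions"] = posv, _["acceptance_fraction"] = acc,
      _["swap_acceptance"] =
          swaps_tried > 0 ? (double)swaps_acc / swaps_tried : NA_REAL);
}

// First-passage time (in steps) from `start` to distance > threshold from
// `mouth`, simulated without storing the trajectory. Returns -1 if max_steps
// is exceeded.
// [[Rcpp::export(name = ".exit_time_cpp")]]
double exit_time_cpp(List surface, double lambda_alpha, NumericVector start,
                     NumericVector mouth, double threshold, double step_size,
                     double seed_d, double max_steps) {
  Surface sf = surface_from_list(surface);
  Rng rng((uint64_t)seed_d * 2654435761ULL + 1ULL);
  double x = start[0], y = start[1];
  if (sf.excluded(x, y)) stop("start position lies in the excluded region");
  double e = sf.energy(x, y, lambda_alpha);
  double th2 = threshold * threshold;
  for (double t = 1; t <= max_steps; ++t) {
    double px = x + step_size * rng.norm();
    double py = y + step_size * rng.norm();
    if (!sf.excluded(px, py)) {
      double pe = sf.energy(px, py, lambda_alpha);
      double de = pe - e;
      if (de <= 0.0 || rng.unif() < std::exp(-de)) { x = px; y = py; e = pe; }
    }
    double dx = x - mouth[0], dy = y - mouth[1];
    if (dx * dx + dy * dy > th2) return t;
  }
  return -1.0;
}
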