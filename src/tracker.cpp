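// Probabilistic streamline tracker.
//
// All randomness comes from a counter-based splitmix64 stream keyed by
// (master seed, seed index, sample index, draw counter), so results are
// bit-reproducible across runs and platforms and independent of R's RNG.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline uint64_t sm_mix(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return x;
}

struct Rng {
  uint64_t base;
  uint64_t ctr;
  Rng(uint64_t seed, uint64_t k1, uint64_t k2) : ctr(0) {
    base = sm_mix(sm_mix(sm_mix(seed + 1) ^ (k1 + 0x632BE59BD9B4E019ULL))
                  ^ (k2 + 0x9E3779B97F4A7C15ULL));
  }
  double unif() {
    uint64_t x = sm_mix(base + (++ctr) * 0xD1B54A32D192ED03ULL);
    return (double)(x >> 11) * (1.0 / 9007199254740992.0);
  }
};

struct Vec3 { double x, y, z; };

static inline double dot3(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline void normalize3(Vec3& v) {
  double n = std::sqrt(dot3(v, v));
  if (n > 0) { v.x /= n; v.y /= n; v.z /= n; }
}

// orthonormal frame completing mu
static inline void frame(const Vec3& mu, Vec3& e1, Vec3& e2) {
  if (std::fabs(mu.x) < 0.9) { e1.x = 1; e1.y = 0; e1.z = 0; }
  else { e1.x = 0; e1.y = 1; e1.z = 0; }
  double d = dot3(e1, mu);
  e1.x -= d * mu.x; e1.y -= d * mu.y; e1.z -= d * mu.z;
  normalize3(e1);
  e2.x = mu.y * e1.z - mu.z * e1.y;
  e2.y = mu.z * e1.x - mu.x * e1.z;
  e2.z = mu.x * e1.y - mu.y * e1.x;
}

// Axial Watson draw about mu with concentration kappa.
// Proposal t ~ density prop. to exp(kappa*t) on [0,1] (inverse CDF, stable
// for large kappa), accepted with probability exp(kappa*(t^2 - t)) <= 1;
// accepted t has density prop. to exp(kappa*t^2). Sign of t then uniform,
// azimuth uniform.
static inline Vec3 watson_draw(const Vec3& mu, double kappa, Rng& rng) {
  if (!R_finite(kappa) || kappa > 1e8) {
    Vec3 v = mu;
    if (rng.unif() < 0.5) { v.x = -v.x; v.y = -v.y; v.z = -v.z; }
    return v;
  }
  double t;
  if (kappa < 1e-12) {
    t = rng.unif();
  } else {
    for (int it = 0; it < 1000; ++it) {
      double u = rng.unif();
      t = 1.0 + std::log(u + (1.0 - u) * std::exp(-kappa)) / kappa;
      double v = rng.unif();
      if (std::log(std::max(v, 1e-300)) <= kappa * (t * t - t)) break;
    }
  }
  if (rng.unif() < 0.5) t = -t;
  double phi = 2.0 * M_PI * rng.unif();
  double r = std::sqrt(std::max(1.0 - t * t, 0.0));
  Vec3 e1, e2;
  frame(mu, e1, e2);
  Vec3 out;
  out.x = t * mu.x + r * (std::cos(phi) * e1.x + std::sin(phi) * e2.x);
  out.y = t * mu.y + r * (std::cos(phi) * e1.y + std::sin(phi) * e2.y);
  out.z = t * mu.z + r * (std::cos(phi) * e1.z + std::sin(phi) * e2.z);
  return out;
}

// [[Rcpp::export]]
NumericMatrix rwatson_cpp(int n, NumericVector mu, double kappa, int seed) {
  NumericMatrix out(n, 3);
  Vec3 m; m.x = mu[0]; m.y = mu[1]; m.z = mu[2];
  for (int i = 0; i < n; ++i) {
    Rng rng((uint64_t)seed, 7777, (uint64_t)i);
    Vec3 v = watson_draw(m, kappa, rng);
    out(i, 0) = v.x; out(i, 1) = v.y; out(i, 2) = v.z;
  }
  return out;
}

struct Field {
  const double* dir1;
  const double* dir2;
  const double* frac1;
  const double* kappa;
  const int* mask;
  int nx, ny, nz;
  long nvox;
  Vec3 mean_dir(long v, int pop) const {
    const double* d = (pop == 0) ? dir1 : dir2;
    Vec3 m;
    m.x = d[v]; m.y = d[v + nvox]; m.z = d[v + 2 * nvox];
    return m;
  }
};

// population choice + Watson draw + sign handling; prev = 0 aligns to the
// stored polarity of the chosen population mean
static inline Vec3 sample_dir(const Field& f, long v, const Vec3& prev,
                              bool have_prev, Rng& rng) {
  int pop = 0;
  double fr = f.frac1[v];
  if (fr < 1.0) {
    Vec3 m2 = f.mean_dir(v, 1);
    if (dot3(m2, m2) > 0.25 && rng.unif() >= fr) pop = 1;
  }
  Vec3 mu = f.mean_dir(v, pop);
  double kap = f.kappa[v];
  Vec3 out;
  if (!R_finite(kap) || kap > 1e8) {
    out = mu;  // deterministic limit, no draws consumed
  } else {
    out = watson_draw(mu, kap, rng);
  }
  const Vec3& ref = have_prev ? prev : mu;
  if (dot3(out, ref) < 0) { out.x = -out.x; out.y = -out.y; out.z = -out.z; }
  return out;
}

// [[Rcpp::export]]
NumericVector sample_orientation_cpp(NumericVector dir1, NumericVector dir2,
                                     NumericVector frac1, NumericVector kappa,
                                     IntegerVector dims, IntegerVector voxel0,
                                     NumericVector prev, int seed,
                                     int counter) {
  Field f;
  f.nx = dims[0]; f.ny = dims[1]; f.nz = dims[2];
  f.nvox = (long)f.nx * f.ny * f.nz;
  f.dir1 = dir1.begin(); f.dir2 = dir2.begin();
  f.frac1 = frac1.begin(); f.kappa = kappa.begin();
  f.mask = nullptr;
  long v = voxel0[0] + (long)f.nx * (voxel0[1] + (long)f.ny * voxel0[2]);
  Vec3 p; p.x = prev[0]; p.y = prev[1]; p.z = prev[2];
  bool have_prev = dot3(p, p) > 0;
  Rng rng((uint64_t)seed, 4242, (uint64_t)counter);
  Vec3 out = sample_dir(f, v, p, have_prev, rng);
  return NumericVector::create(out.x, out.y, out.z);
}

enum Reason { TARGET_HIT = 0, MASK_EXIT = 1, LOOP = 2, CURVATURE = 3,
              MAX_STEPS = 4, REJECTED = 5, TARGET_MISS = 6 };

struct TrackCtx {
  Field f;
  const double* ainv;     // 3 x 4, row-major rows of inverse affine
  const double* afwd;     // 3 x 4, voxel -> world
  const int* target_label;
  const int* wp_label;
  const int* terminal;
  int n_waypoints;
  int mode;               // 0 = first-target counting, 1 = ordered waypoints
  double step, cos_curv;
  int max_steps;
  std::vector<int> stamps;
  int sid;
};

static inline bool world_to_vox(const TrackCtx& c, const Vec3& p,
                                int& i, int& j, int& k) {
  double vi = c.ainv[0] * p.x + c.ainv[1] * p.y + c.ainv[2] * p.z + c.ainv[3];
  double vj = c.ainv[4] * p.x + c.ainv[5] * p.y + c.ainv[6] * p.z + c.ainv[7];
  double vk = c.ainv[8] * p.x + c.ainv[9] * p.y + c.ainv[10] * p.z + c.ainv[11];
  i = (int)std::lround(vi); j = (int)std::lround(vj); k = (int)std::lround(vk);
  return i >= 0 && i < c.f.nx && j >= 0 && j < c.f.ny && k >= 0 && k < c.f.nz;
}

// one streamline; fills visited voxel list and (optionally) points
static int run_streamline(TrackCtx& c, Vec3 pos, Rng& rng,
                          std::vector<long>& visited,
                          std::vector<double>* points,
                          int& hit_target) {
  hit_target = 0;
  int i, j, k;
  if (!world_to_vox(c, pos, i, j, k)) return MASK_EXIT;
  long v = i + (long)c.f.nx * (j + (long)c.f.ny * k);
  if (c.f.mask && !c.f.mask[v]) return MASK_EXIT;
  c.sid++;
  c.stamps[v] = c.sid;
  visited.clear();
  visited.push_back(v);
  if (points) { points->clear(); points->push_back(pos.x);
                points->push_back(pos.y); points->push_back(pos.z); }
  Vec3 prev; prev.x = prev.y = prev.z = 0;
  bool have_prev = false;
  int next_wp = 1;
  for (int step = 0; step < c.max_steps; ++step) {
    Vec3 d = sample_dir(c.f, v, prev, have_prev, rng);
    if (have_prev && dot3(d, prev) < c.cos_curv) return CURVATURE;
    pos.x += c.step * d.x; pos.y += c.step * d.y; pos.z += c.step * d.z;
    prev = d; have_prev = true;
    if (points) { points->push_back(pos.x); points->push_back(pos.y);
                  points->push_back(pos.z); }
    if (!world_to_vox(c, pos, i, j, k)) return MASK_EXIT;
    long nv = i + (long)c.f.nx * (j + (long)c.f.ny * k);
    if (c.f.mask && !c.f.mask[nv]) return MASK_EXIT;
    if (nv != v) {
      if (c.stamps[nv] == c.sid) return LOOP;   // loops/recursions disallowed
      c.stamps[nv] = c.sid;
      visited.push_back(nv);
      v = nv;
      if (c.mode == 0) {
        int t = c.target_label ? c.target_label[v] : 0;
        if (t > 0) { hit_target = t; return TARGET_HIT; }
      } else {
        int w = c.wp_label[v];
        if (w > 0) {
          if (w == next_wp) next_wp++;
          else if (w > next_wp) return REJECTED;  // order inversion
        }
        if (c.terminal[v]) {
          return (next_wp > c.n_waypoints) ? TARGET_HIT : TARGET_MISS;
        }
      }
    }
  }
  return MAX_STEPS;
}

static TrackCtx make_ctx(NumericVector dir1, NumericVector dir2,
                         NumericVector frac1, NumericVector kappa,
                         LogicalVector mask, IntegerVector dims,
                         NumericMatrix ainv, NumericMatrix afwd,
                         double step, double cos_curv, int max_steps) {
  TrackCtx c;
  c.f.nx = dims[0]; c.f.ny = dims[1]; c.f.nz = dims[2];
  c.f.nvox = (long)c.f.nx * c.f.ny * c.f.nz;
  c.f.dir1 = dir1.begin(); c.f.dir2 = dir2.begin();
  c.f.frac1 = frac1.begin(); c.f.kappa = kappa.begin();
  c.f.mask = mask.begin();
  static thread_local std::vector<double> ainv_buf, afwd_buf;
  ainv_buf.assign(12, 0.0); afwd_buf.assign(12, 0.0);
  for (int r = 0; r < 3; ++r)
    for (int cc = 0; cc < 4; ++cc) {
      ainv_buf[r * 4 + cc] = ainv(r, cc);
      afwd_buf[r * 4 + cc] = afwd(r, cc);
    }
  c.ainv = ainv_buf.data(); c.afwd = afwd_buf.data();
  c.target_label = nullptr; c.wp_label = nullptr; c.terminal = nullptr;
  c.n_waypoints = 0; c.mode = 0;
  c.step = step; c.cos_curv = cos_curv; c.max_steps = max_steps;
  c.stamps.assign(c.f.nvox, -1);
  c.sid = 0;
  return c;
}

// [[Rcpp::export]]
List propagate_cpp(NumericVector start_world, NumericVector dir1,
                   NumericVector dir2, NumericVector frac1,
                   NumericVector kappa, LogicalVector mask,
                   IntegerVector dims, NumericMatrix ainv, NumericMatrix afwd,
                   double step, double cos_curv, int max_steps,
                   int seed, int sample_id) {
  TrackCtx c = make_ctx(dir1, dir2, frac1, kappa, mask, dims, ainv, afwd,
                        step, cos_curv, max_steps);
  Vec3 pos; pos.x = start_world[0]; pos.y = start_world[1];
  pos.z = start_world[2];
  Rng rng((uint64_t)seed, 0, (uint64_t)sample_id);
  std::vector<long> visited;
  std::vector<double> points;
  int hit;
  int reason = run_streamline(c, pos, rng, visited, &points, hit);
  int npts = (int)points.size() / 3;
  NumericMatrix pm(npts, 3);
  for (int p = 0; p < npts; ++p) {
    pm(p, 0) = points[3 * p]; pm(p, 1) = points[3 * p + 1];
    pm(p, 2) = points[3 * p + 2];
  }
  return List::create(_["points"] = pm, _["reason"] = reason);
}

// [[Rcpp::export]]
List track_cpp(IntegerMatrix seeds, NumericVector dir1, NumericVector dir2,
               NumericVector frac1, NumericVector kappa, LogicalVector mask,
               IntegerVector dims, NumericMatrix ainv, NumericMatrix afwd,
               IntegerVector target_label, int n_targets,
               IntegerVector wp_label, int n_waypoints,
               IntegerVector terminal, int mode,
               int samples, bool jitter, double step, double cos_curv,
               int max_steps, int seed, bool store_streamlines,
               bool visitation) {
  TrackCtx c = make_ctx(dir1, dir2, frac1, kappa, mask, dims, ainv, afwd,
                        step, cos_curv, max_steps);
  c.mode = mode;
  c.target_label = target_label.size() ? target_label.begin() : nullptr;
  c.wp_label = wp_label.size() ? wp_label.begin() : nullptr;
  c.terminal = terminal.size() ? terminal.begin() : nullptr;
  c.n_waypoints = n_waypoints;

  int n_seeds = seeds.nrow();
  NumericMatrix counts(n_seeds, std::max(n_targets, 1));
  double waytotal = 0;
  std::vector<double> visit;
  if (visitation) visit.assign(c.f.nvox, 0.0);
  std::vector<long> visited;
  std::vector<double> points;
  List kept_streamlines;
  std::vector<NumericMatrix> kept;
  IntegerVector reason_tally(7);

  for (int s = 0; s < n_seeds; ++s) {
    int si = seeds(s, 0), sj = seeds(s, 1), sk = seeds(s, 2); // 0-based
    for (int m = 0; m < samples; ++m) {
      Rng rng((uint64_t)seed, (uint64_t)(s + 1), (uint64_t)(m + 1));
      double fi = si, fj = sj, fk = sk;
      if (jitter) {
        fi += rng.unif() - 0.5; fj += rng.unif() - 0.5; fk += rng.unif() - 0.5;
      }
      Vec3 pos;
      pos.x = c.afwd[0] * fi + c.afwd[1] * fj + c.afwd[2] * fk + c.afwd[3];
      pos.y = c.afwd[4] * fi + c.afwd[5] * fj + c.afwd[6] * fk + c.afwd[7];
      pos.z = c.afwd[8] * fi + c.afwd[9] * fj + c.afwd[10] * fk + c.afwd[11];
      int hit;
      int reason = run_streamline(c, pos, rng, visited,
                                  store_streamlines ? &points : nullptr, hit);
      reason_tally[reason]++;
      if (reason == TARGET_HIT) {
        waytotal += 1;
        if (mode == 0 && hit >= 1) {
          counts(s, hit - 1) += 1;
        } else if (mode == 1) {
          if (visitation)
            for (long v : visited) visit[v] += 1;
          if (store_streamlines) {
            int npts = (int)points.size() / 3;
            NumericMatrix pm(npts, 3);
            for (int p = 0; p < npts; ++p) {
              pm(p, 0) = points[3 * p]; pm(p, 1) = points[3 * p + 1];
              pm(p, 2) = points[3 * p + 2];
            }
            kept.push_back(pm);
          }
        }
      }
    }
  }
  List out = List::create(_["counts"] = counts, _["waytotal"] = waytotal,
                          _["reasons"] = reason_tally);
  if (visitation) out["visitation"] = NumericVector(visit.begin(), visit.end());
  if (mode == 1 && store_streamlines) {
    List ks((int)kept.size());
    for (int i = 0; i < (int)kept.size(); ++i) ks[i] = kept[i];
    out["streamlines"] = ks;
  }
  return out;
}
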