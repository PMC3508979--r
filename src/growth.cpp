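// Microtubule growth core.
//
// Polylines of fixed-length steps are grown inside a cytosolic voxel
// mask, starting at the centrosome.  Free steps keep an exact angle
// with the previous direction (dot product == collinearity); when the
// cone step would exit the cytosol, candidate directions are drawn
// uniformly within the solid cone of half-angle alpha_local about the
// previous direction.  A sliding window over the last `window` step
// directions terminates growth when more than `max_bad` unordered
// pairs differ by more than alpha_global.
//
// Randomness comes from R's generator (unif_rand) so set.seed() in R
// fully determines the output.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Vec3 { double x, y, z; };

static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 scale(Vec3 a, double s) { return {a.x * s, a.y * s, a.z * s}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

static inline Vec3 normalize(Vec3 a) {
  double n = std::sqrt(dot(a, a));
  return {a.x / n, a.y / n, a.z / n};
}

// uniform direction on the unit sphere
static inline Vec3 random_unit() {
  double z = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  return {r * std::cos(phi), r * std::sin(phi), z};
}

// orthonormal basis (e1, e2) perpendicular to unit vector d
static inline void basis(Vec3 d, Vec3 &e1, Vec3 &e2) {
  Vec3 a = std::fabs(d.x) < 0.9 ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
  e1 = normalize({d.y * a.z - d.z * a.y,
                  d.z * a.x - d.x * a.z,
                  d.x * a.y - d.y * a.x});
  e2 = {d.y * e1.z - d.z * e1.y,
        d.z * e1.x - d.x * e1.z,
        d.x * e1.y - d.y * e1.x};
}

// direction at exact angle acos(cos_a) from d, uniform azimuth
static inline Vec3 cone_surface(Vec3 d, double cos_a) {
  Vec3 e1, e2;
  basis(d, e1, e2);
  double sin_a = std::sqrt(std::max(0.0, 1.0 - cos_a * cos_a));
  double phi = 2.0 * M_PI * unif_rand();
  return normalize(scale(d, cos_a) +
                   scale(e1, sin_a * std::cos(phi)) +
                   scale(e2, sin_a * std::sin(phi)));
}

// direction uniform within the solid cone of half-angle acos(cos_min)
static inline Vec3 cone_solid(Vec3 d, double cos_min) {
  Vec3 e1, e2;
  basis(d, e1, e2);
  double c = cos_min + (1.0 - cos_min) * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  double phi = 2.0 * M_PI * unif_rand();
  return normalize(scale(d, c) + scale(e1, s * std::cos(phi)) +
                   scale(e2, s * std::sin(phi)));
}

class CytosolMask {
public:
  CytosolMask(const LogicalVector &m, const IntegerVector &dim,
              double voxel_xy, double z_step)
    : m_(m), nx_(dim[0]), ny_(dim[1]), nz_(dim[2]),
      vxy_(voxel_xy), vz_(z_step) {}
  bool contains(Vec3 p) const {
    int x = (int)std::floor(p.x / vxy_);
    int y = (int)std::floor(p.y / vxy_);
    int z = (int)std::floor(p.z / vz_);
    if (x < 0 || y < 0 || z < 0 || x >= nx_ || y >= ny_ || z >= nz_)
      return false;
    return m_[x + (R_xlen_t)nx_ * (y + (R_xlen_t)ny_ * z)];
  }
private:
  const LogicalVector &m_;
  int nx_, ny_, nz_;
  double vxy_, vz_;
};

// sliding window of step directions with incremental bad-pair count;
// pair_mode 0 counts all unordered pairs in the window, pair_mode 1
// counts only consecutive-step pairs
class DirectionWindow {
public:
  DirectionWindow(int capacity, double cos_global, int max_bad,
                  int pair_mode)
    : cap_(capacity), cg_(cos_global), max_bad_(max_bad),
      mode_(pair_mode), bad_(0) {}
  // push a direction; returns false when the curvature rule fires
  bool push(Vec3 d) {
    if (mode_ == 1) {
      if (!buf_.empty())
        flags_.push_back(dot(buf_.back(), d) < cg_ ? 1 : 0);
      buf_.push_back(d);
      if ((int)buf_.size() > cap_) {
        buf_.erase(buf_.begin());
        flags_.erase(flags_.begin());
      }
      int bad = 0;
      for (int f : flags_) bad += f;
      return bad <= max_bad_;
    }
    if ((int)buf_.size() == cap_) {
      Vec3 old = buf_.front();
      buf_.erase(buf_.begin());
      for (const Vec3 &v : buf_)
        if (dot(old, v) < cg_) --bad_;
    }
    for (const Vec3 &v : buf_)
      if (dot(d, v) < cg_) ++bad_;
    buf_.push_back(d);
    return bad_ <= max_bad_;
  }
private:
  int cap_;
  double cg_;
  int max_bad_, mode_, bad_;
  std::vector<Vec3> buf_;
  std::vector<int> flags_;
};

// [[Rcpp::export]]
List grow_mt_cpp(LogicalVector cytosol, IntegerVector dim,
                 NumericVector start, double voxel_xy, double z_step,
                 double step, double collinearity, double cos_local,
                 double cos_global, int window, int max_bad,
                 int pair_mode, int n_candidates, int target_steps,
                 int max_first_tries) {
  CytosolMask mask(cytosol, dim, voxel_xy, z_step);
  Vec3 p = {start[0], start[1], start[2]};
  if (!mask.contains(p)) stop("centrosome position is not cytosolic");

  std::vector<Vec3> pts;
  pts.reserve(target_steps + 1);
  pts.push_back(p);

  // first step: uniform on the sphere, resampled against the cytosol
  Vec3 dir{0, 0, 0};
  bool placed = false;
  for (int t = 0; t < max_first_tries; ++t) {
    Vec3 d = random_unit();
    Vec3 q = p + scale(d, step);
    if (mask.contains(q)) { dir = d; p = q; placed = true; break; }
  }
  bool complete = false;
  if (placed) {
    pts.push_back(p);
    DirectionWindow win(window, cos_global, max_bad, pair_mode);
    bool alive = win.push(dir);
    int s = 1;
    while (alive && s < target_steps) {
      Vec3 d = cone_surface(dir, collinearity);
      Vec3 q = p + scale(d, step);
      if (!mask.contains(q)) {
        // boundary rebound: candidates uniform in the local cone; the
        // first feasible one is uniform over the feasible part of the
        // cone, so rebounds do not stick to the boundary
        bool found = false;
        for (int t = 0; t < n_candidates; ++t) {
          Vec3 c = cone_solid(dir, cos_local);
          Vec3 qc = p + scale(c, step);
          if (mask.contains(qc)) { d = c; q = qc; found = true; break; }
        }
        if (!found) break;  // trapped: terminate
      }
      dir = d; p = q;
      pts.push_back(p);
      ++s;
      alive = win.push(dir);  // curvature rule, applied after every step
    }
    complete = (s == target_steps) && alive;
  }

  NumericMatrix out(pts.size(), 3);
  for (size_t i = 0; i < pts.size(); ++i) {
    out(i, 0) = pts[i].x; out(i, 1) = pts[i].y; out(i, 2) = pts[i].z;
  }
  return List::create(_["points"] = out, _["complete"] = complete,
                      _["realized_steps"] = (int)pts.size() - 1);
}

// same-size 3D convolution with zero padding outside the volume
// [[Rcpp::export]]
NumericVector conv3d_cpp(NumericVector vol, IntegerVector dv,
                         NumericVector ker, IntegerVector dk) {
  int nx = dv[0], ny = dv[1], nz = dv[2];
  int kx = dk[0], ky = dk[1], kz = dk[2];
  int hx = kx / 2, hy = ky / 2, hz = kz / 2;
  NumericVector out(vol.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int c = 0; c < kz; ++c) {
          int zz = z + hz - c;
          if (zz < 0 || zz >= nz) continue;
          for (int b = 0; b < ky; ++b) {
            int yy = y + hy - b;
            if (yy < 0 || yy >= ny) continue;
            R_xlen_t kbase = (R_xlen_t)kx * (b + (R_xlen_t)ky * c);
            R_xlen_t vbase = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            for (int a = 0; a < kx; ++a) {
              int xx = x + hx - a;
              if (xx < 0 || xx >= nx) continue;
              acc += ker[a + kbase] * vol[xx + vbase];
            }
          }
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = acc;
      }
  return out;
}
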