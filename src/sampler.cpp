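// RJMCMC/MCMC engine for Poisson multi-emitter fitting with pixel-integrated
// 3D Gaussian PSFs (astigmatic single-plane or biplane).
//
// All randomness goes through R's RNG so that set.seed() on the R side makes
// every chain reproducible.
//
// Parameter conventions (shared with the R wrappers):
//  calib vector (length 15), axial quantities in micrometres:
//    [0] s0x [1] gx [2] dx [3] Ax [4] s0y [5] gy [6] dy [7] Ay
//    [8] zmin [9] zmax [10] nplanes [11] poff1 [12] poff2 [13] pfrac1 [14] pfrac2
//  prior vector (length 17):
//    [0] xlo [1] xhi [2] ylo [3] yhi [4] zlo [5] zhi [6] blo [7] bhi [8] kmax
//    [9] imean [10] isd [11] icut [12] wtail [13] ta [14] tb [15] tc [16] td
//    (tail trapezoid knots ta<=tb<=tc<=td; wtail = tail mass fraction)
//  jumps vector (length 9):
//    [0] sx [1] sy [2] sz [3] sI [4] sb [5] split_xy [6] split_z
//    [7] gmerge_xy [8] gmerge_I
//  moves are numbered 1..9:
//    single, group, background, split, merge, g-split, g-merge, birth, death

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double Z_TO_PX = 10.0; // 100 nm pixels: 1 um = 10 px, for distances

struct Calib {
  double s0x, gx, dx, Ax, s0y, gy, dy, Ay, zmin, zmax;
  int nplanes;
  double poff[2], pfrac[2];
};

static Calib as_calib(const NumericVector& c) {
  Calib k;
  k.s0x = c[0]; k.gx = c[1]; k.dx = c[2]; k.Ax = c[3];
  k.s0y = c[4]; k.gy = c[5]; k.dy = c[6]; k.Ay = c[7];
  k.zmin = c[8]; k.zmax = c[9];
  k.nplanes = (int)c[10];
  k.poff[0] = c[11]; k.poff[1] = c[12];
  k.pfrac[0] = c[13]; k.pfrac[1] = c[14];
  return k;
}

struct Prior {
  double xlo, xhi, ylo, yhi, zlo, zhi, blo, bhi;
  int kmax;
  double imean, isd, icut, wtail, ta, tb, tc, td;
  double lpos;   // log-density of the uniform position block (x*y*z)
  double lb;     // log-density of the uniform background
  double zg;     // truncated-normal normalising constant on (0, icut)
  double th;     // trapezoid plateau height
};

static Prior as_prior(const NumericVector& p) {
  Prior q;
  q.xlo = p[0]; q.xhi = p[1]; q.ylo = p[2]; q.yhi = p[3];
  q.zlo = p[4]; q.zhi = p[5]; q.blo = p[6]; q.bhi = p[7];
  q.kmax = (int)p[8];
  q.imean = p[9]; q.isd = p[10]; q.icut = p[11];
  q.wtail = p[12]; q.ta = p[13]; q.tb = p[14]; q.tc = p[15]; q.td = p[16];
  q.lpos = -std::log(q.xhi - q.xlo) - std::log(q.yhi - q.ylo) - std::log(q.zhi - q.zlo);
  q.lb = -std::log(q.bhi - q.blo);
  q.zg = R::pnorm(q.icut, q.imean, q.isd, 1, 0) - R::pnorm(0.0, q.imean, q.isd, 1, 0);
  double span = (q.td - q.ta) + (q.tc - q.tb);
  q.th = span > 0 ? 2.0 / span : 0.0;
  return q;
}

struct State {
  int k;
  std::vector<double> x, y, z, I;
  double b;
};

// sigma(z) = s0 * sqrt(1 + u^2 + A u^3), u = (z - gamma)/d; <= 0 radicand -> -1
static double width_at(double s0, double g, double d, double A, double z) {
  double u = (z - g) / d;
  double r = 1.0 + u * u + A * u * u * u;
  if (r <= 0.0) return -1.0;
  return s0 * std::sqrt(r);
}

static inline double ncdf(double t) { return 0.5 * erfc(-t * M_SQRT1_2); }

// per-axis pixel-integrated fractions for pixels [0,1),...,[n-1,n)
static bool axis_frac(double pos, double sigma, int n, double* out) {
  if (sigma <= 0.0) return false;
  double prev = ncdf((0.0 - pos) / sigma);
  for (int i = 0; i < n; i++) {
    double cur = ncdf((i + 1.0 - pos) / sigma);
    out[i] = cur - prev;
    prev = cur;
  }
  return true;
}

// add (sign * I * fractions) of one emitter to mu grids; false if invalid width
static bool add_emitter(std::vector<double>* mu, double x, double y, double z,
                        double I, const Calib& c, int nx, int ny, double sign) {
  std::vector<double> ex(nx), ey(ny);
  for (int p = 0; p < c.nplanes; p++) {
    double zz = z - c.poff[p];
    double sx = width_at(c.s0x, c.gx, c.dx, c.Ax, zz);
    double sy = width_at(c.s0y, c.gy, c.dy, c.Ay, zz);
    if (sx <= 0.0 || sy <= 0.0) return false;
    axis_frac(x, sx, nx, ex.data());
    axis_frac(y, sy, ny, ey.data());
    double w = sign * I * c.pfrac[p];
    double* m = mu[p].data();
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++)
        m[i + nx * j] += w * ex[i] * ey[j];
  }
  return true;
}

// expected counts for a full state; false on invalid width
static bool expected(const State& s, const Calib& c, int nx, int ny,
                     std::vector<double>* mu) {
  for (int p = 0; p < c.nplanes; p++) {
    mu[p].assign((size_t)nx * ny, s.b * c.pfrac[p]);
  }
  for (int j = 0; j < s.k; j++)
    if (!add_emitter(mu, s.x[j], s.y[j], s.z[j], s.I[j], c, nx, ny, 1.0))
      return false;
  return true;
}

// Poisson log-likelihood (without the data-only lgamma term)
static double loglik(const std::vector<double>* mu, const std::vector<int>* D,
                     int nplanes, int npix) {
  double ll = 0.0;
  for (int p = 0; p < nplanes; p++) {
    const double* m = mu[p].data();
    const int* d = D[p].data();
    for (int i = 0; i < npix; i++) {
      if (m[i] <= 0.0) return R_NegInf;
      ll += d[i] * std::log(m[i]) - m[i];
    }
  }
  return ll;
}

// intensity prior: mixture of a truncated Gaussian and (optionally) a
// trapezoidal low-intensity tail; zero outside (0, icut]
static double intensity_dens(double I, const Prior& p) {
  if (I <= 0.0 || I > p.icut) return 0.0;
  double g = R::dnorm(I, p.imean, p.isd, 0) / p.zg;
  if (p.wtail <= 0.0) return g;
  double t = 0.0;
  if (I >= p.ta && I <= p.td) {
    if (I < p.tb)      t = p.th * (I - p.ta) / (p.tb - p.ta);
    else if (I <= p.tc) t = p.th;
    else               t = p.th * (p.td - I) / (p.td - p.tc);
  }
  return (1.0 - p.wtail) * g + p.wtail * t;
}

static double sample_intensity(const Prior& p) {
  if (p.wtail > 0.0 && unif_rand() < p.wtail) {
    // accept-reject from the bounding box of the trapezoid
    for (;;) {
      double I = p.ta + unif_rand() * (p.td - p.ta);
      double dI;
      if (I < p.tb)      dI = p.th * (I - p.ta) / (p.tb - p.ta);
      else if (I <= p.tc) dI = p.th;
      else               dI = p.th * (p.td - I) / (p.td - p.tc);
      if (unif_rand() * p.th <= dI) return I;
    }
  }
  for (;;) { // truncated Gaussian on (0, icut]
    double I = R::rnorm(p.imean, p.isd);
    if (I > 0.0 && I <= p.icut) return I;
  }
}

// log prior density of one emitter (position uniform + intensity)
static double emitter_lprior(double x, double y, double z, double I, const Prior& p) {
  if (x < p.xlo || x > p.xhi || y < p.ylo || y > p.yhi || z < p.zlo || z > p.zhi)
    return R_NegInf;
  double di = intensity_dens(I, p);
  if (di <= 0.0) return R_NegInf;
  return p.lpos + std::log(di);
}

// Set-space prior density: emitters are exchangeable and the proposal
// densities are written over unordered configurations, so the density over
// ordered tuples carries the k! multiplicity factor. The k-marginal of the
// posterior is unaffected (the factor cancels against the quotient volume).
static double state_lprior(const State& s, const Prior& p) {
  if (s.k < 0 || s.k > p.kmax) return R_NegInf;
  if (s.b < p.blo || s.b > p.bhi) return R_NegInf;
  double lp = p.lb - std::log((double)(p.kmax + 1)); // uniform count prior
  lp += std::lgamma((double)s.k + 1.0);              // exchangeability factor
  for (int j = 0; j < s.k; j++) {
    double e = emitter_lprior(s.x[j], s.y[j], s.z[j], s.I[j], p);
    if (!R_FINITE(e)) return R_NegInf;
    lp += e;
  }
  return lp;
}

static void draw_emitter(const Prior& p, double* x, double* y, double* z, double* I) {
  *x = p.xlo + unif_rand() * (p.xhi - p.xlo);
  *y = p.ylo + unif_rand() * (p.yhi - p.ylo);
  *z = p.zlo + unif_rand() * (p.zhi - p.zlo);
  *I = sample_intensity(p);
}

// squared distance in pixel units (z converted at 10 px/um)
static double dist2(const State& s, int i, int j) {
  double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j];
  double dz = (s.z[i] - s.z[j]) * Z_TO_PX;
  return dx * dx + dy * dy + dz * dz;
}

static int nearest(const State& s, int i) {
  int best = -1; double bd = R_PosInf;
  for (int j = 0; j < s.k; j++) {
    if (j == i) continue;
    double d = dist2(s, i, j);
    if (d < bd) { bd = d; best = j; }
  }
  return best;
}

// connected components by lateral distance < 4 * s0x; returns count, labels in lab
static int components(const State& s, double rad, std::vector<int>* lab) {
  lab->assign(s.k, -1);
  int nc = 0;
  double r2 = rad * rad;
  for (int i = 0; i < s.k; i++) {
    if ((*lab)[i] >= 0) continue;
    // BFS
    std::vector<int> stack(1, i);
    (*lab)[i] = nc;
    while (!stack.empty()) {
      int a = stack.back(); stack.pop_back();
      for (int j = 0; j < s.k; j++) {
        if ((*lab)[j] >= 0) continue;
        double dx = s.x[a] - s.x[j], dy = s.y[a] - s.y[j];
        if (dx * dx + dy * dy < r2) { (*lab)[j] = nc; stack.push_back(j); }
      }
    }
    nc++;
  }
  return nc;
}

// Data-driven placement proposal for model build-up moves (birth, g-split):
// lateral position drawn from a mixture of the uniform prior support and the
// photon-count image (pixel picked proportionally to its counts, uniform
// within the pixel); depth uniform; intensity from the prior. With no data
// table attached the draw falls back to the plain prior.
struct PlaceProp {
  const double* cdf;   // cumulative pixel weights over the summed planes
  double total;        // total weight
  int nx, ny;
  double wu;           // mass of the uniform mixture component
};

static void place_draw(const Prior& p, const PlaceProp* pp,
                       double* x, double* y, double* z, double* I) {
  if (pp == nullptr || pp->total <= 0.0 || unif_rand() < pp->wu) {
    *x = p.xlo + unif_rand() * (p.xhi - p.xlo);
    *y = p.ylo + unif_rand() * (p.yhi - p.ylo);
  } else {
    double u = unif_rand() * pp->total;
    int lo = 0, hi = pp->nx * pp->ny - 1;
    while (lo < hi) { // first index with cdf >= u
      int mid = (lo + hi) / 2;
      if (pp->cdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    int i = lo % pp->nx, j = lo / pp->nx;
    *x = i + unif_rand();
    *y = j + unif_rand();
  }
  *z = p.zlo + unif_rand() * (p.zhi - p.zlo);
  *I = sample_intensity(p);
}

static double place_logq(const Prior& p, const PlaceProp* pp,
                         double x, double y, double z, double I) {
  double lzi = emitter_lprior(x, y, z, I, p); // uniform pos + z + intensity
  if (pp == nullptr || pp->total <= 0.0) return lzi;
  if (!R_FINITE(lzi)) return R_NegInf;
  double d_unif = 1.0 / ((p.xhi - p.xlo) * (p.yhi - p.ylo));
  double d_data = 0.0;
  int i = (int)std::floor(x), j = (int)std::floor(y);
  if (i >= 0 && i < pp->nx && j >= 0 && j < pp->ny) {
    int idx = i + pp->nx * j;
    double w = pp->cdf[idx] - (idx > 0 ? pp->cdf[idx - 1] : 0.0);
    d_data = w / pp->total; // per unit pixel area
  }
  double q_xy = pp->wu * d_unif + (1.0 - pp->wu) * d_data;
  // replace the uniform lateral factor of the prior with q_xy
  return lzi + std::log(q_xy) - std::log(d_unif);
}

// g-merge replacement proposal: given an emitter pair, the merged emitter is
// drawn around the pair's lateral midpoint, with depth uniform over the
// axial range and intensity near the pair's total. This lets the sampler
// undo a degenerate deep split in one jump (the prior-based alternative
// almost never proposes a viable merged emitter). The same density is the
// reverse factor of a g-split.
// With sg <= 0 the classic prior-based construction is used instead (the
// replacement emitter is a fresh prior draw).
static void gmerge_draw(double x1, double y1, double x2, double y2,
                        double Isum, const Prior& p, double sg, double sgI,
                        double* xn, double* yn, double* zn, double* In) {
  if (sg <= 0.0) { draw_emitter(p, xn, yn, zn, In); return; }
  *xn = 0.5 * (x1 + x2) + norm_rand() * sg;
  *yn = 0.5 * (y1 + y2) + norm_rand() * sg;
  *zn = p.zlo + unif_rand() * (p.zhi - p.zlo);
  *In = Isum + norm_rand() * sgI;
}

static double gmerge_logq(double xn, double yn, double zn, double In,
                          double x1, double y1, double x2, double y2,
                          double Isum, const Prior& p, double sg, double sgI) {
  if (sg <= 0.0) return emitter_lprior(xn, yn, zn, In, p);
  if (zn < p.zlo || zn > p.zhi) return R_NegInf;
  return R::dnorm(xn, 0.5 * (x1 + x2), sg, 1)
       + R::dnorm(yn, 0.5 * (y1 + y2), sg, 1)
       - std::log(p.zhi - p.zlo)
       + R::dnorm(In, Isum, sgI, 1);
}

struct Proposal {
  State s;
  double lq;       // log(q_reverse) - log(q_forward), move-selection probs excluded
  double lj;       // log |Jacobian|
  bool valid;      // false => auto-rejected no-op
};

static Proposal propose(const State& s, int move, const Prior& pr,
                        const NumericVector& jumps, const Calib& cal,
                        const NumericVector& sched_row,
                        const PlaceProp* pp = nullptr) {
  Proposal out; out.s = s; out.lq = 0.0; out.lj = 0.0; out.valid = true;
  double sx = jumps[0], sy = jumps[1], sz = jumps[2], sI = jumps[3], sb = jumps[4];
  double ssxy = jumps[5], ssz = jumps[6], sg = jumps[7], sgI = jumps[8];
  switch (move) {
  case 1: { // single: perturb one emitter's (x,y,z,I)
    if (s.k < 1) { out.valid = false; break; }
    int j = (int)std::floor(unif_rand() * s.k);
    out.s.x[j] += norm_rand() * sx;
    out.s.y[j] += norm_rand() * sy;
    out.s.z[j] += norm_rand() * sz;
    out.s.I[j] += norm_rand() * sI;
    break;
  }
  case 2: { // group: rigid translation of one overlap component
    if (s.k < 1) { out.valid = false; break; }
    std::vector<int> lab;
    int nc = components(s, 4.0 * cal.s0x, &lab);
    int g = (int)std::floor(unif_rand() * nc);
    double ddx = norm_rand() * sx, ddy = norm_rand() * sy, ddz = norm_rand() * sz;
    for (int j = 0; j < s.k; j++) {
      if (lab[j] != g) continue;
      out.s.x[j] += ddx; out.s.y[j] += ddy; out.s.z[j] += ddz;
    }
    std::vector<int> lab2;
    int nc2 = components(out.s, 4.0 * cal.s0x, &lab2);
    out.lq = std::log((double)nc) - std::log((double)nc2);
    break;
  }
  case 3: { // background
    out.s.b += norm_rand() * sb;
    break;
  }
  case 4: { // split, conserving intensity and intensity-weighted centroid
    if (s.k < 1 || s.k >= pr.kmax) { out.valid = false; break; }
    int j = (int)std::floor(unif_rand() * s.k);
    double f = unif_rand();
    double ddx = norm_rand() * ssxy, ddy = norm_rand() * ssxy, ddz = norm_rand() * ssz;
    double x = s.x[j], y = s.y[j], z = s.z[j], I = s.I[j];
    out.s.x[j] = x + (1 - f) * ddx; out.s.y[j] = y + (1 - f) * ddy;
    out.s.z[j] = z + (1 - f) * ddz; out.s.I[j] = f * I;
    out.s.x.push_back(x - f * ddx); out.s.y.push_back(y - f * ddy);
    out.s.z.push_back(z - f * ddz); out.s.I.push_back((1 - f) * I);
    out.s.k = s.k + 1;
    // forward: set-based, (2/k) * N(dx) N(dy) N(dz)
    double lqf = std::log(2.0 / s.k)
      + R::dnorm(ddx, 0, ssxy, 1) + R::dnorm(ddy, 0, ssxy, 1) + R::dnorm(ddz, 0, ssz, 1);
    // reverse merge: pick a or b uniformly, partner must be its nearest neighbour
    int a = j, bidx = out.s.k - 1;
    int hits = (nearest(out.s, a) == bidx) + (nearest(out.s, bidx) == a);
    if (hits == 0) { out.valid = false; break; } // unreachable by merge
    double lqr = std::log((double)hits / out.s.k);
    out.lq = lqr - lqf;
    out.lj = std::log(I); // |J| of (x,y,z,I,f,dx,dy,dz) -> two emitters
    break;
  }
  case 5: { // merge nearest pair, exact inverse of split
    if (s.k < 2) { out.valid = false; break; }
    int i = (int)std::floor(unif_rand() * s.k);
    int j = nearest(s, i);
    int hits = (nearest(s, i) == j) + (nearest(s, j) == i);
    double lqf = std::log((double)hits / s.k);
    double I = s.I[i] + s.I[j];
    double f = s.I[i] / I;
    double mx = f * s.x[i] + (1 - f) * s.x[j];
    double my = f * s.y[i] + (1 - f) * s.y[j];
    double mz = f * s.z[i] + (1 - f) * s.z[j];
    double ddx = s.x[i] - s.x[j], ddy = s.y[i] - s.y[j], ddz = s.z[i] - s.z[j];
    int lo = i < j ? i : j, hi = i < j ? j : i;
    out.s.x[lo] = mx; out.s.y[lo] = my; out.s.z[lo] = mz; out.s.I[lo] = I;
    out.s.x.erase(out.s.x.begin() + hi); out.s.y.erase(out.s.y.begin() + hi);
    out.s.z.erase(out.s.z.begin() + hi); out.s.I.erase(out.s.I.begin() + hi);
    out.s.k = s.k - 1;
    double lqr = std::log(2.0 / out.s.k)
      + R::dnorm(ddx, 0, ssxy, 1) + R::dnorm(ddy, 0, ssxy, 1) + R::dnorm(ddz, 0, ssz, 1);
    out.lq = lqr - lqf;
    out.lj = -std::log(I);
    break;
  }
  case 6: { // g-split: replace one emitter by two fresh prior draws
    if (s.k < 1 || s.k >= pr.kmax) { out.valid = false; break; }
    int j = (int)std::floor(unif_rand() * s.k);
    double ox = s.x[j], oy = s.y[j], oz = s.z[j], oI = s.I[j];
    double x1, y1, z1, I1, x2, y2, z2, I2;
    place_draw(pr, pp, &x1, &y1, &z1, &I1);
    place_draw(pr, pp, &x2, &y2, &z2, &I2);
    out.s.x[j] = x1; out.s.y[j] = y1; out.s.z[j] = z1; out.s.I[j] = I1;
    out.s.x.push_back(x2); out.s.y.push_back(y2); out.s.z.push_back(z2); out.s.I.push_back(I2);
    out.s.k = s.k + 1;
    double lp1 = place_logq(pr, pp, x1, y1, z1, I1);
    double lp2 = place_logq(pr, pp, x2, y2, z2, I2);
    // forward: (1/k) * 2 * q(e1) q(e2)
    // reverse g-merge: (hits/(k+1)) * q(e_old | {e1, e2})
    int a = j, bidx = out.s.k - 1;
    int hits = (nearest(out.s, a) == bidx) + (nearest(out.s, bidx) == a);
    if (hits == 0) { out.valid = false; break; }
    double lqf = std::log(2.0 / s.k) + lp1 + lp2;
    double lqr = std::log((double)hits / out.s.k)
      + gmerge_logq(ox, oy, oz, oI, x1, y1, x2, y2, I1 + I2, pr, sg, sgI);
    out.lq = lqr - lqf;
    break;
  }
  case 7: { // g-merge: replace nearest pair by one merged-proposal draw
    if (s.k < 2) { out.valid = false; break; }
    int i = (int)std::floor(unif_rand() * s.k);
    int j = nearest(s, i);
    int hits = (nearest(s, i) == j) + (nearest(s, j) == i);
    double lp1 = place_logq(pr, pp, s.x[i], s.y[i], s.z[i], s.I[i]);
    double lp2 = place_logq(pr, pp, s.x[j], s.y[j], s.z[j], s.I[j]);
    double Isum = s.I[i] + s.I[j];
    double xn, yn, zn, In;
    gmerge_draw(s.x[i], s.y[i], s.x[j], s.y[j], Isum, pr, sg, sgI,
                &xn, &yn, &zn, &In);
    double lqn = gmerge_logq(xn, yn, zn, In, s.x[i], s.y[i], s.x[j], s.y[j],
                             Isum, pr, sg, sgI);
    int lo = i < j ? i : j, hi = i < j ? j : i;
    out.s.x[lo] = xn; out.s.y[lo] = yn; out.s.z[lo] = zn; out.s.I[lo] = In;
    out.s.x.erase(out.s.x.begin() + hi); out.s.y.erase(out.s.y.begin() + hi);
    out.s.z.erase(out.s.z.begin() + hi); out.s.I.erase(out.s.I.begin() + hi);
    out.s.k = s.k - 1;
    double lqf = std::log((double)hits / s.k) + lqn;
    double lqr = std::log(2.0 / out.s.k) + lp1 + lp2;
    out.lq = lqr - lqf;
    break;
  }
  case 8: { // birth from the placement proposal (prior when no data table)
    if (s.k >= pr.kmax) { out.valid = false; break; }
    double xn, yn, zn, In;
    place_draw(pr, pp, &xn, &yn, &zn, &In);
    out.s.x.push_back(xn); out.s.y.push_back(yn);
    out.s.z.push_back(zn); out.s.I.push_back(In);
    out.s.k = s.k + 1;
    double lpn = place_logq(pr, pp, xn, yn, zn, In);
    out.lq = std::log(1.0 / out.s.k) - lpn; // reverse death minus forward density
    break;
  }
  case 9: { // death of a uniformly chosen emitter
    if (s.k < 1) { out.valid = false; break; }
    int j = (int)std::floor(unif_rand() * s.k);
    double lpj = place_logq(pr, pp, s.x[j], s.y[j], s.z[j], s.I[j]);
    out.s.x.erase(out.s.x.begin() + j); out.s.y.erase(out.s.y.begin() + j);
    out.s.z.erase(out.s.z.begin() + j); out.s.I.erase(out.s.I.begin() + j);
    out.s.k = s.k - 1;
    out.lq = lpj - std::log(1.0 / s.k); // reverse birth density minus forward
    break;
  }
  default: stop("unknown move id");
  }
  (void)sched_row;
  return out;
}

// log of the move-selection probability ratio P(reverse move)/P(forward move)
static double move_prob_ratio(int move, const NumericVector& sched_row) {
  int rev;
  switch (move) {
  case 4: rev = 5; break; case 5: rev = 4; break;
  case 6: rev = 7; break; case 7: rev = 6; break;
  case 8: rev = 9; break; case 9: rev = 8; break;
  default: return 0.0; // symmetric parameter-space moves
  }
  double pf = sched_row[move - 1], prv = sched_row[rev - 1];
  if (pf <= 0.0) return R_NegInf; // should not happen: move was selected
  if (prv <= 0.0) return R_NegInf;
  return std::log(prv) - std::log(pf);
}

static int pick_move(const NumericVector& sched_row) {
  double u = unif_rand(), acc = 0.0;
  int last = 0;
  for (int m = 0; m < 9; m++) {
    if (sched_row[m] <= 0.0) continue;
    last = m;
    acc += sched_row[m];
    if (u < acc) return m + 1;
  }
  return last + 1; // guards against float drift in a row summing to 1
}

static State state_from_list(const List& st) {
  State s;
  NumericVector x = st["x"], y = st["y"], z = st["z"], I = st["I"];
  s.k = x.size();
  s.x.assign(x.begin(), x.end()); s.y.assign(y.begin(), y.end());
  s.z.assign(z.begin(), z.end()); s.I.assign(I.begin(), I.end());
  s.b = as<double>(st["b"]);
  return s;
}

static List state_to_list(const State& s) {
  return List::create(_["x"] = NumericVector(s.x.begin(), s.x.end()),
                      _["y"] = NumericVector(s.y.begin(), s.y.end()),
                      _["z"] = NumericVector(s.z.begin(), s.z.end()),
                      _["I"] = NumericVector(s.I.begin(), s.I.end()),
                      _["b"] = s.b, _["k"] = s.k);
}

// [[Rcpp::export]]
NumericVector cpp_width_at_depth(NumericVector z, double s0, double g, double d, double A) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = width_at(s0, g, d, A, z[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_pixel_fractions(double x, double y, double z, NumericVector calib,
                         int nx, int ny) {
  Calib c = as_calib(calib);
  List out(c.nplanes);
  std::vector<double> ex(nx), ey(ny);
  for (int p = 0; p < c.nplanes; p++) {
    double zz = z - c.poff[p];
    double sx = width_at(c.s0x, c.gx, c.dx, c.Ax, zz);
    double sy = width_at(c.s0y, c.gy, c.dy, c.Ay, zz);
    if (sx <= 0.0 || sy <= 0.0)
      stop("PSF width model has non-positive radicand at z = %f", z);
    axis_frac(x, sx, nx, ex.data());
    axis_frac(y, sy, ny, ey.data());
    NumericMatrix m(nx, ny);
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++)
        m(i, j) = c.pfrac[p] * ex[i] * ey[j];
    out[p] = m;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_expected_counts(List state, NumericVector calib, int nx, int ny) {
  Calib c = as_calib(calib);
  State s = state_from_list(state);
  std::vector<double> mu[2];
  if (!expected(s, c, nx, ny, mu))
    stop("PSF width model has non-positive radicand for an emitter depth");
  List out(c.nplanes);
  for (int p = 0; p < c.nplanes; p++) {
    NumericMatrix m(nx, ny);
    std::copy(mu[p].begin(), mu[p].end(), m.begin());
    out[p] = m;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_intensity_dens(double I, NumericVector prior) {
  Prior p = as_prior(prior);
  return intensity_dens(I, p);
}

// [[Rcpp::export]]
NumericVector cpp_sample_intensity(int n, NumericVector prior) {
  Prior p = as_prior(prior);
  RNGScope scope;
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = sample_intensity(p);
  return out;
}

// [[Rcpp::export]]
double cpp_state_lprior(List state, NumericVector prior) {
  Prior p = as_prior(prior);
  State s = state_from_list(state);
  return state_lprior(s, p);
}

// [[Rcpp::export]]
List cpp_sample_prior_state(int k, NumericVector prior) {
  Prior p = as_prior(prior);
  RNGScope scope;
  State s; s.k = k;
  s.x.resize(k); s.y.resize(k); s.z.resize(k); s.I.resize(k);
  for (int j = 0; j < k; j++) draw_emitter(p, &s.x[j], &s.y[j], &s.z[j], &s.I[j]);
  s.b = p.blo + unif_rand() * (p.bhi - p.blo);
  return state_to_list(s);
}

// single proposal, exposed for the move-level API and its tests
// [[Rcpp::export]]
List cpp_propose(List state, int move, NumericVector calib, NumericVector prior,
                 NumericVector jumps, NumericVector sched_row) {
  Calib c = as_calib(calib);
  Prior p = as_prior(prior);
  RNGScope scope;
  State s = state_from_list(state);
  Proposal pr = propose(s, move, p, jumps, c, sched_row);
  return List::create(_["state"] = state_to_list(pr.s),
                      _["log_q_ratio"] = pr.lq,
                      _["log_jacobian"] = pr.lj,
                      _["valid"] = pr.valid,
                      _["log_move_ratio"] = pr.valid ? move_prob_ratio(move, sched_row) : 0.0);
}

// The chain engine. Phases: during the first n_burn iterations the burn-in
// schedule row is used, afterwards the post-burn-in row. With fixed_k = true a
// single row is used and model-space moves must have probability zero.
// [[Rcpp::export]]
List cpp_run_chain(List planes, NumericVector calib, NumericVector prior,
                   NumericMatrix schedule, NumericVector jumps,
                   int n_iter, int n_burn, bool fixed_k, List init) {
  Calib cal = as_calib(calib);
  Prior pri = as_prior(prior);
  RNGScope scope;

  int nplanes = planes.size();
  if (nplanes != cal.nplanes) stop("frame plane count does not match calibration");
  std::vector<int> D[2];
  int nx = 0, ny = 0;
  for (int p = 0; p < nplanes; p++) {
    IntegerMatrix m = planes[p];
    if (p == 0) { nx = m.nrow(); ny = m.ncol(); }
    else if (m.nrow() != nx || m.ncol() != ny) stop("plane shapes differ");
    D[p].assign(m.begin(), m.end());
  }
  int npix = nx * ny;
  std::vector<double> wcdf(npix, 0.0);
  {
    double acc = 0.0;
    for (int i = 0; i < npix; i++) {
      double w = 0.0;
      for (int p = 0; p < nplanes; p++) w += D[p][i];
      acc += w;
      wcdf[i] = acc;
    }
  }
  PlaceProp pp_store = { wcdf.data(), wcdf.back(), nx, ny, 0.25 };
  const PlaceProp* pp = &pp_store;
  double lgam = 0.0;
  for (int p = 0; p < nplanes; p++)
    for (int i = 0; i < npix; i++) lgam += std::lgamma((double)D[p][i] + 1.0);

  State s = state_from_list(init);
  std::vector<double> mu[2], mup[2];
  if (!expected(s, cal, nx, ny, mu)) stop("initial state outside PSF validity");
  double ll = loglik(mu, D, nplanes, npix);
  double lp = state_lprior(s, pri);
  if (!R_FINITE(lp)) stop("initial state has zero prior density");

  int kmax = pri.kmax;
  IntegerVector k_out(n_iter), move_out(n_iter), acc_out(n_iter), phase_out(n_iter);
  NumericVector lpost_out(n_iter), b_out(n_iter);
  NumericMatrix theta(n_iter, 4 * kmax);
  std::fill(theta.begin(), theta.end(), NA_REAL);

  for (int it = 0; it < n_iter; it++) {
    int phase = fixed_k ? 2 : (it < n_burn ? 0 : 1);
    NumericVector row = schedule(phase, _);
    int mv = pick_move(row);
    Proposal prp = propose(s, mv, pri, jumps, cal, row, pp);
    bool accepted = false;
    if (prp.valid) {
      double lp_new = state_lprior(prp.s, pri);
      if (R_FINITE(lp_new)) {
        double ll_new;
        if (!expected(prp.s, cal, nx, ny, mup)) {
          ll_new = R_NegInf;
        } else {
          ll_new = loglik(mup, D, nplanes, npix);
        }
        double lmove = move_prob_ratio(mv, row);
        double la = (ll_new - ll) + (lp_new - lp) + prp.lq + prp.lj + lmove;
        if (ISNAN(la)) stop("NaN acceptance ratio (model bug)");
        if (R_FINITE(la) ? (std::log(unif_rand()) < la) : (la > 0)) {
          s = prp.s; ll = ll_new; lp = lp_new;
          for (int p = 0; p < nplanes; p++) mu[p].swap(mup[p]);
          accepted = true;
        }
      }
    }
    k_out[it] = s.k; move_out[it] = mv; acc_out[it] = accepted ? 1 : 0;
    phase_out[it] = phase; lpost_out[it] = ll - lgam + lp; b_out[it] = s.b;
    for (int j = 0; j < s.k; j++) {
      theta(it, 4 * j) = s.x[j]; theta(it, 4 * j + 1) = s.y[j];
      theta(it, 4 * j + 2) = s.z[j]; theta(it, 4 * j + 3) = s.I[j];
    }
  }

  return List::create(_["k"] = k_out, _["move"] = move_out, _["accepted"] = acc_out,
                      _["phase"] = phase_out, _["log_posterior"] = lpost_out,
                      _["b"] = b_out, _["theta"] = theta,
                      _["final_state"] = state_to_list(s));
}

// Monte-Carlo mode-confusion: fraction of frames simulated from mu_gen on which
// mu_other attains the higher Poisson likelihood (ties counted half)
// [[Rcpp::export]]
double cpp_mode_confusion(NumericVector mu_gen, NumericVector mu_other, int n_sim) {
  int n = mu_gen.size();
  RNGScope scope;
  std::vector<double> w(n), lam(n);
  double drift = 0.0;
  for (int i = 0; i < n; i++) {
    w[i] = std::log(mu_other[i] / mu_gen[i]);
    lam[i] = mu_gen[i];
    drift += mu_other[i] - mu_gen[i];
  }
  double err = 0.0;
  for (int r = 0; r < n_sim; r++) {
    double t = -drift;
    for (int i = 0; i < n; i++) {
      double d = R::rpois(lam[i]);
      t += d * w[i];
    }
    if (t > 0) err += 1.0; else if (t == 0) err += 0.5;
  }
  return err / n_sim;
}
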