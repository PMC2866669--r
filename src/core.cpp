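// Low-level 3D image operators. All arrays are R arrays with dim = (nz, ny, nx),
// column-major, so the linear index of voxel (z, y, x) is z + nz*(y + ny*x).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e20;

inline int reflect_idx(int i, int n) {
  // symmetric boundary (d c b a | a b c d)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

struct Dims {
  int nz, ny, nx;
  R_xlen_t n;
  explicit Dims(const IntegerVector& d) : nz(d[0]), ny(d[1]), nx(d[2]) {
    n = (R_xlen_t)nz * ny * nx;
  }
  inline R_xlen_t at(int z, int y, int x) const {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  }
};

// neighbourhood offsets for a given 3D connectivity (6, 18 or 26)
static std::vector<std::array<int,3> > neigh_offsets(int connectivity) {
  int maxsum = (connectivity == 6) ? 1 : (connectivity == 18 ? 2 : 3);
  std::vector<std::array<int,3> > off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (s == 0 || s > maxsum) continue;
        off.push_back({{dz, dy, dx}});
      }
  return off;
}

// ---------------------------------------------------------------- median ----

// [[Rcpp::export]]
NumericVector cpp_median2d(NumericVector img, IntegerVector dim, int radius) {
  Dims d(dim);
  if (radius < 1) stop("radius must be >= 1");
  NumericVector out(d.n);
  int k = 2 * radius + 1;
  std::vector<double> win((size_t)k * k);
  for (int z = 0; z < d.nz; ++z)
    for (int x = 0; x < d.nx; ++x)
      for (int y = 0; y < d.ny; ++y) {
        size_t m = 0;
        for (int dy = -radius; dy <= radius; ++dy) {
          int yy = reflect_idx(y + dy, d.ny);
          for (int dx = -radius; dx <= radius; ++dx) {
            int xx = reflect_idx(x + dx, d.nx);
            win[m++] = img[d.at(z, yy, xx)];
          }
        }
        std::nth_element(win.begin(), win.begin() + m / 2, win.begin() + m);
        out[d.at(z, y, x)] = win[m / 2];
      }
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------------------ hole filling ----

// [[Rcpp::export]]
LogicalVector cpp_fill_holes2d(LogicalVector mask, IntegerVector dim) {
  Dims d(dim);
  LogicalVector out(d.n);
  std::vector<char> reach((size_t)d.ny * d.nx);
  std::vector<int> stack;
  for (int z = 0; z < d.nz; ++z) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    // flood 4-connected background from the slice border
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        bool border = (y == 0 || y == d.ny - 1 || x == 0 || x == d.nx - 1);
        if (border && !mask[d.at(z, y, x)]) {
          int p = y + d.ny * x;
          if (!reach[p]) { reach[p] = 1; stack.push_back(p); }
        }
      }
    const int dy4[4] = {1, -1, 0, 0}, dx4[4] = {0, 0, 1, -1};
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int y = p % d.ny, x = p / d.ny;
      for (int i = 0; i < 4; ++i) {
        int yy = y + dy4[i], xx = x + dx4[i];
        if (yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
        int q = yy + d.ny * xx;
        if (!reach[q] && !mask[d.at(z, yy, xx)]) { reach[q] = 1; stack.push_back(q); }
      }
    }
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x)
        out[d.at(z, y, x)] = mask[d.at(z, y, x)] || !reach[y + d.ny * x];
  }
  out.attr("dim") = dim;
  return out;
}

// --------------------------------------------- exact Euclidean distance ----

// 1D squared-distance transform (lower envelope of parabolas), grid spacing s
static void dt1d(const std::vector<double>& f, std::vector<double>& out,
                 std::vector<int>& v, std::vector<double>& zb, int n, double s) {
  int k = 0;
  v[0] = 0;
  zb[0] = -BIG; zb[1] = BIG;
  double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double fq = f[q] + s2 * q * q;
    while (true) {
      double fv = f[v[k]] + s2 * v[k] * v[k];
      double sec = (fq - fv) / (2.0 * s2 * (q - v[k]));
      if (sec <= zb[k]) { --k; continue; }
      ++k; v[k] = q; zb[k] = sec; zb[k + 1] = BIG;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = s * (q - v[k]);
    out[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector w) {
  // w = (wz, wy, wx): per-axis voxel spacing in distance units
  Dims d(dim);
  NumericVector g(d.n);
  for (R_xlen_t i = 0; i < d.n; ++i) g[i] = mask[i] ? BIG : 0.0;
  int nmax = std::max(d.nz, std::max(d.ny, d.nx));
  std::vector<double> f(nmax), o(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // along z
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y) {
      for (int z = 0; z < d.nz; ++z) f[z] = g[d.at(z, y, x)];
      dt1d(f, o, v, zb, d.nz, w[0]);
      for (int z = 0; z < d.nz; ++z) g[d.at(z, y, x)] = o[z];
    }
  // along y
  for (int x = 0; x < d.nx; ++x)
    for (int z = 0; z < d.nz; ++z) {
      for (int y = 0; y < d.ny; ++y) f[y] = g[d.at(z, y, x)];
      dt1d(f, o, v, zb, d.ny, w[1]);
      for (int y = 0; y < d.ny; ++y) g[d.at(z, y, x)] = o[y];
    }
  // along x
  for (int y = 0; y < d.ny; ++y)
    for (int z = 0; z < d.nz; ++z) {
      for (int x = 0; x < d.nx; ++x) f[x] = g[d.at(z, y, x)];
      dt1d(f, o, v, zb, d.nx, w[2]);
      for (int x = 0; x < d.nx; ++x) g[d.at(z, y, x)] = o[x];
    }
  for (R_xlen_t i = 0; i < d.n; ++i)
    g[i] = (g[i] >= BIG) ? R_PosInf : std::sqrt(g[i]);
  g.attr("dim") = dim;
  return g;
}

// ------------------------------------------- grayscale reconstruction ----

// Reconstruction by dilation of `marker` under `mask`, 26-connected:
// hybrid raster/anti-raster sweeps followed by FIFO-queue propagation
// (Vincent's algorithm). Returns the unique fixed point.
// [[Rcpp::export]]
NumericVector cpp_reconstruct(NumericVector marker, NumericVector mask,
                              IntegerVector dim) {
  Dims d(dim);
  for (R_xlen_t i = 0; i < d.n; ++i)
    if (marker[i] > mask[i]) stop("marker exceeds mask");
  NumericVector J = clone(marker);
  std::vector<std::array<int,3> > all = neigh_offsets(26), nminus, nplus;
  for (auto& o : all) {
    R_xlen_t lin = (R_xlen_t)o[0] + (R_xlen_t)d.nz * ((R_xlen_t)o[1] + (R_xlen_t)d.ny * o[2]);
    if (lin < 0) nminus.push_back(o); else nplus.push_back(o);
  }
  // forward sweep (ascending linear order: z fastest, x slowest)
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t p = d.at(z, y, x);
        double m = J[p];
        for (auto& o : nminus) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
          double jq = J[d.at(zz, yy, xx)];
          if (jq > m) m = jq;
        }
        J[p] = std::min(mask[p], m);
      }
  // backward sweep + queue seeding
  std::queue<R_xlen_t> fifo;
  for (int x = d.nx - 1; x >= 0; --x)
    for (int y = d.ny - 1; y >= 0; --y)
      for (int z = d.nz - 1; z >= 0; --z) {
        R_xlen_t p = d.at(z, y, x);
        double m = J[p];
        for (auto& o : nplus) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
          double jq = J[d.at(zz, yy, xx)];
          if (jq > m) m = jq;
        }
        J[p] = std::min(mask[p], m);
        for (auto& o : nplus) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
          R_xlen_t q = d.at(zz, yy, xx);
          if (J[q] < J[p] && J[q] < mask[q]) { fifo.push(p); break; }
        }
      }
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front(); fifo.pop();
    int z = (int)(p % d.nz);
    R_xlen_t r = p / d.nz;
    int y = (int)(r % d.ny), x = (int)(r / d.ny);
    for (auto& o : all) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
      R_xlen_t q = d.at(zz, yy, xx);
      if (J[q] < J[p] && J[q] < mask[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  J.attr("dim") = dim;
  return J;
}

// --------------------------------------------- connected components ----

// Labels positive voxels in raster-scan order (deterministic, consecutive
// labels from 1). If same_value_only, two voxels connect only when they hold
// the same input value (used to relabel within watershed regions).
// [[Rcpp::export]]
IntegerVector cpp_label(IntegerVector vals, IntegerVector dim,
                        int connectivity, bool same_value_only) {
  Dims d(dim);
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<std::array<int,3> > off = neigh_offsets(connectivity);
  IntegerVector lab(d.n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t p = d.at(z, y, x);
        if (vals[p] <= 0 || lab[p] != 0) continue;
        int value = vals[p];
        ++next;
        lab[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          R_xlen_t c = stack.back(); stack.pop_back();
          int cz = (int)(c % d.nz);
          R_xlen_t r = c / d.nz;
          int cy = (int)(r % d.ny), cx = (int)(r / d.ny);
          for (auto& o : off) {
            int zz = cz + o[0], yy = cy + o[1], xx = cx + o[2];
            if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
            R_xlen_t q = d.at(zz, yy, xx);
            if (lab[q] != 0 || vals[q] <= 0) continue;
            if (same_value_only && vals[q] != value) continue;
            lab[q] = next;
            stack.push_back(q);
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// ------------------------------------------------------ IFT watershed ----

struct WsNode {
  double cost;
  int label;
  long long seq;
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.label != b.label) return a.label > b.label;
    return a.seq > b.seq;
  }
};

// Seeded watershed of the inverted distance map as an optimum-path forest:
// path cost = max over the path of (dmax - dist), 6-connected foreground
// graph. Seed voxels are finalized first (never reassigned); ties resolved
// to the lower seed label, FIFO within equal (cost, label).
// [[Rcpp::export]]
IntegerVector cpp_ift_watershed(NumericVector dist, IntegerVector seeds,
                                LogicalVector mask, IntegerVector dim) {
  Dims d(dim);
  double dmax = 0.0;
  for (R_xlen_t i = 0; i < d.n; ++i) {
    if (seeds[i] > 0 && !mask[i]) stop("seed voxel outside foreground mask");
    if (mask[i] && dist[i] > dmax) dmax = dist[i];
  }
  IntegerVector out(d.n);
  std::vector<char> done(d.n, 0);
  // seed voxels sorted by (label, raster index)
  std::vector<std::pair<int, R_xlen_t> > sv;
  for (R_xlen_t i = 0; i < d.n; ++i)
    if (seeds[i] > 0) sv.push_back(std::make_pair(seeds[i], i));
  std::sort(sv.begin(), sv.end());
  for (auto& s : sv) { out[s.second] = s.first; done[s.second] = 1; }
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long seq = 0;
  std::vector<std::array<int,3> > off = neigh_offsets(6);
  auto relax = [&](R_xlen_t p, double pcost, int label) {
    int z = (int)(p % d.nz);
    R_xlen_t r = p / d.nz;
    int y = (int)(r % d.ny), x = (int)(r / d.ny);
    for (auto& o : off) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
      R_xlen_t q = d.at(zz, yy, xx);
      if (!mask[q] || done[q]) continue;
      WsNode nd;
      nd.cost = std::max(pcost, dmax - dist[q]);
      nd.label = label;
      nd.seq = seq++;
      nd.idx = q;
      pq.push(nd);
    }
  };
  for (auto& s : sv) relax(s.second, dmax - dist[s.second], s.first);
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    if (done[nd.idx]) continue;
    done[nd.idx] = 1;
    out[nd.idx] = nd.label;
    relax(nd.idx, nd.cost, nd.label);
  }
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------- separable Gaussian ----

// [[Rcpp::export]]
NumericVector cpp_blur_sep(NumericVector img, IntegerVector dim,
                           NumericVector sigma) {
  // sigma = (sz, sy, sx) in voxels; an axis with sigma <= 0 is skipped
  Dims d(dim);
  NumericVector cur = clone(img);
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += k[i + r];
    }
    for (auto& v : k) v /= sum;
    NumericVector nxt(d.n);
    int nax = (ax == 0) ? d.nz : (ax == 1 ? d.ny : d.nx);
    for (int x = 0; x < d.nx; ++x)
      for (int y = 0; y < d.ny; ++y)
        for (int z = 0; z < d.nz; ++z) {
          double acc = 0;
          for (int i = -r; i <= r; ++i) {
            int zz = z, yy = y, xx = x;
            if (ax == 0) zz = reflect_idx(z + i, nax);
            else if (ax == 1) yy = reflect_idx(y + i, nax);
            else xx = reflect_idx(x + i, nax);
            acc += k[i + r] * cur[d.at(zz, yy, xx)];
          }
          nxt[d.at(z, y, x)] = acc;
        }
    cur = nxt;
  }
  cur.attr("dim") = dim;
  return cur;
}
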