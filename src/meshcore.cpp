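// Low-level 3D geometry kernels: isosurface extraction (marching tetrahedra),
// triangle-mesh queries (closest point, voxelization, self-intersection),
// marker-based priority-flood watershed, separable Gaussian smoothing,
// binary morphology and trilinear affine resampling.
//
// All voxel coordinates here are 0-based indices; callers convert to world mm.

#include <Rcpp.h>
#include <queue>
#include <functional>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// marching tetrahedra
// ---------------------------------------------------------------------------

// Cube corner offsets (x,y,z)
static const int CUBE[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
// Six tetrahedra per cube, all sharing the 0-6 main diagonal. Face diagonals
// induced by this split match those of the neighbouring cube's split, so the
// extracted surface is watertight across cube boundaries.
static const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
};

struct MTBuilder {
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  std::unordered_map<uint64_t, int> edge_vertex;

  int vertex_on_edge(int64_t ia, int64_t ib,
                     double ax, double ay, double az, double va,
                     double bx, double by, double bz, double vb,
                     double iso) {
    if (ia > ib) { std::swap(ia, ib); std::swap(ax, bx); std::swap(ay, by);
                   std::swap(az, bz); std::swap(va, vb); }
    uint64_t key = ((uint64_t)(uint32_t)ia << 32) | (uint32_t)ib;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vz.push_back(az + t * (bz - az));
    int id = (int)vx.size() - 1;
    edge_vertex[key] = id;
    return id;
  }

  void add_tri(int a, int b, int c,
               double inx, double iny, double inz) {
    // orient so the normal points away from the inside reference point
    double cx = (vx[a] + vx[b] + vx[c]) / 3.0;
    double cy = (vy[a] + vy[b] + vy[c]) / 3.0;
    double cz = (vz[a] + vz[b] + vz[c]) / 3.0;
    double ux = vx[b]-vx[a], uy = vy[b]-vy[a], uz = vz[b]-vz[a];
    double wx = vx[c]-vx[a], wy = vy[c]-vy[a], wz = vz[c]-vz[a];
    double nx = uy*wz - uz*wy, ny = uz*wx - ux*wz, nz = ux*wy - uy*wx;
    double dx = inx - cx, dy = iny - cy, dz = inz - cz;
    if (nx*dx + ny*dy + nz*dz > 0) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  }
};

// [[Rcpp::export(name = ".mc_marching_tets")]]
List mc_marching_tets(NumericVector vol, IntegerVector dims, double iso,
                      double pad_value) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // padded grid has one extra sample on every side so surfaces close
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  auto val = [&](int i, int j, int k) -> double {
    int a = i - 1, b = j - 1, c = k - 1;
    if (a < 0 || b < 0 || c < 0 || a >= nx || b >= ny || c >= nz)
      return pad_value;
    return vol[a + (int64_t)nx * (b + (int64_t)ny * c)];
  };
  auto lin = [&](int i, int j, int k) -> int64_t {
    return i + (int64_t)px * (j + (int64_t)py * k);
  };

  MTBuilder B;
  double cx_[8], cy_[8], cz_[8], cv_[8];
  int64_t ci_[8];
  for (int k = 0; k + 1 < pz; ++k)
    for (int j = 0; j + 1 < py; ++j)
      for (int i = 0; i + 1 < px; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CUBE[c][0], jj = j + CUBE[c][1], kk = k + CUBE[c][2];
          cv_[c] = val(ii, jj, kk);
          // vertex coordinates in the *unpadded* index space
          cx_[c] = ii - 1; cy_[c] = jj - 1; cz_[c] = kk - 1;
          ci_[c] = lin(ii, jj, kk);
          if (cv_[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4]; bool in[4]; int nin = 0;
          for (int c = 0; c < 4; ++c) {
            id[c] = TETS[t][c];
            in[c] = cv_[id[c]] > iso;
            if (in[c]) nin++;
          }
          if (nin == 0 || nin == 4) continue;
          auto ev = [&](int a, int b) {
            return B.vertex_on_edge(ci_[a], ci_[b],
                                    cx_[a], cy_[a], cz_[a], cv_[a],
                                    cx_[b], cy_[b], cz_[b], cv_[b], iso);
          };
          if (nin == 1 || nin == 3) {
            bool target = (nin == 1);
            int a = -1, o[3], no = 0;
            for (int c = 0; c < 4; ++c) {
              if (in[c] == target) a = id[c]; else o[no++] = id[c];
            }
            int va = ev(a, o[0]), vb = ev(a, o[1]), vc = ev(a, o[2]);
            // reference inside point: an interior corner of the tet
            int ref = target ? a : o[0];
            if (!target) { // nin==3: inside corners are o[]
              B.add_tri(va, vb, vc, cx_[ref], cy_[ref], cz_[ref]);
            } else {
              B.add_tri(va, vb, vc, cx_[a], cy_[a], cz_[a]);
            }
          } else { // nin == 2 -> quad
            int a[2], o[2], na = 0, no = 0;
            for (int c = 0; c < 4; ++c) {
              if (in[c]) a[na++] = id[c]; else o[no++] = id[c];
            }
            int v00 = ev(a[0], o[0]), v01 = ev(a[0], o[1]);
            int v10 = ev(a[1], o[0]), v11 = ev(a[1], o[1]);
            double inx = 0.5 * (cx_[a[0]] + cx_[a[1]]);
            double iny = 0.5 * (cy_[a[0]] + cy_[a[1]]);
            double inz = 0.5 * (cz_[a[0]] + cz_[a[1]]);
            B.add_tri(v00, v01, v11, inx, iny, inz);
            B.add_tri(v00, v11, v10, inx, iny, inz);
          }
        }
      }

  int nv = (int)B.vx.size(), nf = (int)B.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i,0) = B.vx[i]; V(i,1) = B.vy[i]; V(i,2) = B.vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    F(i,0) = B.f0[i]; F(i,1) = B.f1[i]; F(i,2) = B.f2[i];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// mesh audits: edge manifoldness, components, volume, area
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mc_mesh_audit")]]
List mc_mesh_audit(NumericMatrix V, IntegerMatrix F) {
  int nv = V.nrow(), nf = F.nrow();
  std::unordered_map<uint64_t, int> ecount;
  std::unordered_map<uint64_t, int> esigned; // +1 for (a<b) traversal, -1 rev
  ecount.reserve(nf * 2);
  for (int f = 0; f < nf; ++f) {
    int idx[3] = {F(f,0), F(f,1), F(f,2)};
    for (int e = 0; e < 3; ++e) {
      int a = idx[e], b = idx[(e+1)%3];
      uint64_t key = ((uint64_t)(uint32_t)std::min(a,b) << 32) |
                     (uint32_t)std::max(a,b);
      ecount[key]++;
      esigned[key] += (a < b) ? 1 : -1;
    }
  }
  int n_edges = (int)ecount.size();
  int boundary = 0, nonmanifold = 0, misoriented = 0;
  for (auto &kv : ecount) {
    if (kv.second == 1) boundary++;
    else if (kv.second > 2) nonmanifold++;
    else if (esigned[kv.first] != 0) misoriented++;
  }
  // connected components over vertices via union-find
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int f = 0; f < nf; ++f) {
    int a = find(F(f,0)), b = find(F(f,1)), c = find(F(f,2));
    parent[a] = b; parent[find(b)] = find(c);
  }
  std::unordered_map<int,int> roots;
  for (int i = 0; i < nv; ++i) roots[find(i)]++;
  int ncomp = (int)roots.size();

  double vol6 = 0.0, area2 = 0.0;
  for (int f = 0; f < nf; ++f) {
    double ax = V(F(f,0),0), ay = V(F(f,0),1), az = V(F(f,0),2);
    double bx = V(F(f,1),0), by = V(F(f,1),1), bz = V(F(f,1),2);
    double cx = V(F(f,2),0), cy = V(F(f,2),1), cz = V(F(f,2),2);
    vol6 += ax*(by*cz - bz*cy) - ay*(bx*cz - bz*cx) + az*(bx*cy - by*cx);
    double ux = bx-ax, uy = by-ay, uz = bz-az;
    double wx = cx-ax, wy = cy-ay, wz = cz-az;
    double nx = uy*wz-uz*wy, ny = uz*wx-ux*wz, nz = ux*wy-uy*wx;
    area2 += std::sqrt(nx*nx + ny*ny + nz*nz);
  }
  int euler = nv - n_edges + nf;
  return List::create(
    _["n_vertices"] = nv, _["n_faces"] = nf, _["n_edges"] = n_edges,
    _["n_boundary_edges"] = boundary, _["n_nonmanifold_edges"] = nonmanifold,
    _["n_misoriented_edges"] = misoriented,
    _["n_components"] = ncomp, _["euler"] = euler,
    _["volume"] = vol6 / 6.0, _["area"] = area2 / 2.0);
}

// [[Rcpp::export(name = ".mc_mesh_vertex_components")]]
IntegerVector mc_mesh_vertex_components(int nv, IntegerMatrix F) {
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int f = 0; f < F.nrow(); ++f) {
    parent[find(F(f,0))] = find(F(f,1));
    parent[find(F(f,1))] = find(F(f,2));
  }
  IntegerVector comp(nv);
  std::unordered_map<int,int> remap;
  int next = 1;
  for (int i = 0; i < nv; ++i) {
    int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = next++; }
    comp[i] = remap[r];
  }
  return comp;
}

// ---------------------------------------------------------------------------
// Taubin smoothing (uniform Laplacian, lambda/mu)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mc_taubin_smooth")]]
NumericMatrix mc_taubin_smooth(NumericMatrix V, IntegerMatrix F, int iters,
                               double lambda, double mu) {
  int nv = V.nrow(), nf = F.nrow();
  std::vector<std::vector<int>> nbr(nv);
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0), b = F(f,1), c = F(f,2);
    nbr[a].push_back(b); nbr[a].push_back(c);
    nbr[b].push_back(a); nbr[b].push_back(c);
    nbr[c].push_back(a); nbr[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(nbr[i].begin(), nbr[i].end());
    nbr[i].erase(std::unique(nbr[i].begin(), nbr[i].end()), nbr[i].end());
  }
  NumericMatrix X = clone(V);
  NumericMatrix Y(nv, 3);
  auto pass = [&](double w) {
    for (int i = 0; i < nv; ++i) {
      if (nbr[i].empty()) {
        Y(i,0)=X(i,0); Y(i,1)=X(i,1); Y(i,2)=X(i,2); continue;
      }
      double mx=0, my=0, mz=0;
      for (int j : nbr[i]) { mx += X(j,0); my += X(j,1); mz += X(j,2); }
      double n = (double)nbr[i].size();
      Y(i,0) = X(i,0) + w * (mx/n - X(i,0));
      Y(i,1) = X(i,1) + w * (my/n - X(i,1));
      Y(i,2) = X(i,2) + w * (mz/n - X(i,2));
    }
    std::swap(X, Y);
  };
  for (int it = 0; it < iters; ++it) { pass(lambda); pass(mu); }
  return X;
}

// ---------------------------------------------------------------------------
// closest point on mesh (uniform-grid accelerated)
// ---------------------------------------------------------------------------

struct Vec3 { double x, y, z; };
static inline Vec3 sub(const Vec3&a, const Vec3&b){return {a.x-b.x,a.y-b.y,a.z-b.z};}
static inline double dot(const Vec3&a, const Vec3&b){return a.x*b.x+a.y*b.y+a.z*b.z;}
static inline Vec3 add(const Vec3&a, const Vec3&b){return {a.x+b.x,a.y+b.y,a.z+b.z};}
static inline Vec3 scl(const Vec3&a, double s){return {a.x*s,a.y*s,a.z*s};}
static inline Vec3 cross(const Vec3&a,const Vec3&b){
  return {a.y*b.z-a.z*b.y, a.z*b.x-a.x*b.z, a.x*b.y-a.y*b.x};}

// Ericson, Real-Time Collision Detection: closest point on triangle
static Vec3 closest_on_tri(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                           const Vec3 &c) {
  Vec3 ab = sub(b,a), ac = sub(c,a), ap = sub(p,a);
  double d1 = dot(ab,ap), d2 = dot(ac,ap);
  if (d1 <= 0 && d2 <= 0) return a;
  Vec3 bp = sub(p,b);
  double d3 = dot(ab,bp), d4 = dot(ac,bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return add(a, scl(ab, d1/(d1-d3)));
  Vec3 cp = sub(p,c);
  double d5 = dot(ab,cp), d6 = dot(ac,cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return add(a, scl(ac, d2/(d2-d6)));
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4-d3) >= 0 && (d5-d6) >= 0) {
    double w = (d4-d3)/((d4-d3)+(d5-d6));
    return add(b, scl(sub(c,b), w));
  }
  double denom = 1.0/(va+vb+vc);
  double v = vb*denom, w = vc*denom;
  return add(a, add(scl(ab,v), scl(ac,w)));
}

struct TriGrid {
  int nx, ny, nz;
  double ox, oy, oz, cs; // origin, cell size (cubic cells)
  std::vector<std::vector<int>> cells;
  NumericMatrix V; IntegerMatrix F;

  TriGrid(NumericMatrix V_, IntegerMatrix F_) : V(V_), F(F_) {
    int nf = F.nrow();
    double lo[3] = {1e300,1e300,1e300}, hi[3] = {-1e300,-1e300,-1e300};
    for (int i = 0; i < V.nrow(); ++i)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], V(i,d)); hi[d] = std::max(hi[d], V(i,d));
      }
    double ext = std::max({hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2], 1e-9});
    int target = std::max(1, (int)std::cbrt((double)std::max(nf,1)));
    target = std::min(target, 96);
    cs = ext / target;
    ox = lo[0]; oy = lo[1]; oz = lo[2];
    nx = std::max(1, (int)std::floor((hi[0]-lo[0])/cs) + 1);
    ny = std::max(1, (int)std::floor((hi[1]-lo[1])/cs) + 1);
    nz = std::max(1, (int)std::floor((hi[2]-lo[2])/cs) + 1);
    cells.resize((size_t)nx*ny*nz);
    for (int f = 0; f < nf; ++f) {
      double tlo[3] = {1e300,1e300,1e300}, thi[3] = {-1e300,-1e300,-1e300};
      for (int c = 0; c < 3; ++c)
        for (int d = 0; d < 3; ++d) {
          tlo[d] = std::min(tlo[d], V(F(f,c),d));
          thi[d] = std::max(thi[d], V(F(f,c),d));
        }
      int i0 = cell_of(tlo[0], ox), i1 = cell_of(thi[0], ox);
      int j0 = cell_of(tlo[1], oy), j1 = cell_of(thi[1], oy);
      int k0 = cell_of(tlo[2], oz), k1 = cell_of(thi[2], oz);
      i0 = std::max(0,i0); j0 = std::max(0,j0); k0 = std::max(0,k0);
      i1 = std::min(nx-1,i1); j1 = std::min(ny-1,j1); k1 = std::min(nz-1,k1);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i)
            cells[i + (size_t)nx*(j + (size_t)ny*k)].push_back(f);
    }
  }
  int cell_of(double x, double o) const { return (int)std::floor((x-o)/cs); }

  void query(const Vec3 &p, double &best_d2, Vec3 &best_pt, int &best_f) const {
    int ci = std::min(std::max(cell_of(p.x, ox),0), nx-1);
    int cj = std::min(std::max(cell_of(p.y, oy),0), ny-1);
    int ck = std::min(std::max(cell_of(p.z, oz),0), nz-1);
    best_d2 = std::numeric_limits<double>::infinity();
    best_f = -1;
    int rmax = std::max({nx, ny, nz});
    for (int r = 0; r <= rmax; ++r) {
      if (best_f >= 0) {
        double lb = (r - 1) * cs; // conservative ring lower bound
        if (lb > 0 && lb*lb > best_d2) break;
      }
      int i0 = std::max(0, ci-r), i1 = std::min(nx-1, ci+r);
      int j0 = std::max(0, cj-r), j1 = std::min(ny-1, cj+r);
      int k0 = std::max(0, ck-r), k1 = std::min(nz-1, ck+r);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            // only the shell of the ring
            if (r > 0 && std::abs(i-ci) != r && std::abs(j-cj) != r &&
                std::abs(k-ck) != r) continue;
            for (int f : cells[i + (size_t)nx*(j + (size_t)ny*k)]) {
              Vec3 a{V(F(f,0),0), V(F(f,0),1), V(F(f,0),2)};
              Vec3 b{V(F(f,1),0), V(F(f,1),1), V(F(f,1),2)};
              Vec3 c{V(F(f,2),0), V(F(f,2),1), V(F(f,2),2)};
              Vec3 q = closest_on_tri(p, a, b, c);
              Vec3 dpq = sub(p,q);
              double d2 = dot(dpq,dpq);
              if (d2 < best_d2) { best_d2 = d2; best_pt = q; best_f = f; }
            }
          }
      if (r == rmax) break;
    }
  }
};

// [[Rcpp::export(name = ".mc_closest_points")]]
List mc_closest_points(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  TriGrid G(V, F);
  int n = P.nrow();
  NumericVector d(n);
  NumericMatrix Q(n, 3);
  IntegerVector fid(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p{P(i,0), P(i,1), P(i,2)};
    double d2; Vec3 q{0,0,0}; int f;
    G.query(p, d2, q, f);
    d[i] = std::sqrt(d2);
    Q(i,0)=q.x; Q(i,1)=q.y; Q(i,2)=q.z;
    fid[i] = f + 1;
  }
  return List::create(_["distance"] = d, _["point"] = Q, _["face"] = fid);
}

// ---------------------------------------------------------------------------
// deterministic surface sampling (area-weighted, golden-ratio barycentric)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mc_sample_surface")]]
NumericMatrix mc_sample_surface(NumericMatrix V, IntegerMatrix F, int n) {
  int nf = F.nrow();
  std::vector<double> area(nf);
  double total = 0;
  for (int f = 0; f < nf; ++f) {
    Vec3 a{V(F(f,0),0), V(F(f,0),1), V(F(f,0),2)};
    Vec3 b{V(F(f,1),0), V(F(f,1),1), V(F(f,1),2)};
    Vec3 c{V(F(f,2),0), V(F(f,2),1), V(F(f,2),2)};
    Vec3 nrm = cross(sub(b,a), sub(c,a));
    area[f] = 0.5 * std::sqrt(dot(nrm,nrm));
    total += area[f];
  }
  if (total <= 0) return NumericMatrix(0, 3);
  std::vector<int> cnt(nf);
  int assigned = 0;
  for (int f = 0; f < nf; ++f) {
    cnt[f] = (int)std::floor(n * area[f] / total);
    assigned += cnt[f];
  }
  // largest-remainder top-up
  std::vector<std::pair<double,int>> rem(nf);
  for (int f = 0; f < nf; ++f)
    rem[f] = {-(n * area[f] / total - cnt[f]), f};
  std::sort(rem.begin(), rem.end());
  for (int t = 0; t < n - assigned && t < nf; ++t) cnt[rem[t].second]++;

  const double g1 = 0.7548776662466927, g2 = 0.5698402909980532; // R2 sequence
  std::vector<double> px, py, pz;
  for (int f = 0; f < nf; ++f) {
    for (int s = 1; s <= cnt[f]; ++s) {
      double u = s * g1 - std::floor(s * g1);
      double v = s * g2 - std::floor(s * g2);
      if (u + v > 1) { u = 1 - u; v = 1 - v; }
      double w = 1 - u - v;
      px.push_back(w*V(F(f,0),0) + u*V(F(f,1),0) + v*V(F(f,2),0));
      py.push_back(w*V(F(f,0),1) + u*V(F(f,1),1) + v*V(F(f,2),1));
      pz.push_back(w*V(F(f,0),2) + u*V(F(f,1),2) + v*V(F(f,2),2));
    }
  }
  NumericMatrix P((int)px.size(), 3);
  for (int i = 0; i < (int)px.size(); ++i) {
    P(i,0)=px[i]; P(i,1)=py[i]; P(i,2)=pz[i];
  }
  return P;
}

// ---------------------------------------------------------------------------
// scanline voxelization: inside mask of a closed mesh, index space
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mc_voxelize")]]
LogicalVector mc_voxelize(NumericMatrix V, IntegerMatrix F,
                          IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // rays parallel to the i axis through (j + ej, k + ek); tiny fixed jitter
  // avoids samples landing exactly on projected edges
  const double ej = 3.1459e-4, ek = 2.7182e-4;
  std::vector<std::vector<double>> cross_x((size_t)ny*nz);
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    double ax = V(F(f,0),0), ay = V(F(f,0),1), az = V(F(f,0),2);
    double bx = V(F(f,1),0), by = V(F(f,1),1), bz = V(F(f,1),2);
    double cx = V(F(f,2),0), cy = V(F(f,2),1), cz = V(F(f,2),2);
    double ylo = std::min({ay,by,cy}), yhi = std::max({ay,by,cy});
    double zlo = std::min({az,bz,cz}), zhi = std::max({az,bz,cz});
    int j0 = std::max(0, (int)std::ceil(ylo - ej));
    int j1 = std::min(ny-1, (int)std::floor(yhi - ej));
    int k0 = std::max(0, (int)std::ceil(zlo - ek));
    int k1 = std::min(nz-1, (int)std::floor(zhi - ek));
    double d = (by-ay)*(cz-az) - (bz-az)*(cy-ay); // projected doubled area
    if (std::fabs(d) < 1e-14) continue;           // ray-parallel: no crossing
    for (int k = k0; k <= k1; ++k) {
      double pz_ = k + ek;
      for (int j = j0; j <= j1; ++j) {
        double py_ = j + ej;
        double u = ((py_-ay)*(cz-az) - (pz_-az)*(cy-ay)) / d;
        double v = ((by-ay)*(pz_-az) - (bz-az)*(py_-ay)) / d;
        if (u <= 0 || v <= 0 || u + v >= 1) continue;
        double x = ax + u*(bx-ax) + v*(cx-ax);
        cross_x[j + (size_t)ny*k].push_back(x);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx*ny*nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      auto &xs = cross_x[j + (size_t)ny*k];
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      for (int i = 0; i < nx; ++i) {
        // parity of crossings strictly below the voxel centre
        size_t c = std::lower_bound(xs.begin(), xs.end(), (double)i) -
                   xs.begin();
        if (c & 1) out[i + (R_xlen_t)nx*(j + (R_xlen_t)ny*k)] = true;
      }
    }
  return out;
}

// ---------------------------------------------------------------------------
// triangle-triangle self-intersection count (Moller interval test)
// ---------------------------------------------------------------------------

static bool tri_tri_overlap(const Vec3 *t1, const Vec3 *t2, double tol) {
  const double EPS = tol;
  Vec3 n1 = cross(sub(t1[1],t1[0]), sub(t1[2],t1[0]));
  double l1 = std::sqrt(dot(n1,n1));
  if (l1 < 1e-30) return false;
  n1 = scl(n1, 1.0/l1);
  double d1 = -dot(n1, t1[0]);
  double dv2[3];
  for (int i = 0; i < 3; ++i) dv2[i] = dot(n1, t2[i]) + d1;
  for (int i = 0; i < 3; ++i) if (std::fabs(dv2[i]) < EPS) dv2[i] = 0;
  // a proper crossing needs strictly mixed signs; touching (zeros) is not
  // an intersection at this tolerance
  bool pos2 = dv2[0] > 0 || dv2[1] > 0 || dv2[2] > 0;
  bool neg2 = dv2[0] < 0 || dv2[1] < 0 || dv2[2] < 0;
  if (!(pos2 && neg2)) return false;
  Vec3 n2 = cross(sub(t2[1],t2[0]), sub(t2[2],t2[0]));
  double l2 = std::sqrt(dot(n2,n2));
  if (l2 < 1e-30) return false;
  n2 = scl(n2, 1.0/l2);
  double d2 = -dot(n2, t2[0]);
  double dv1[3];
  for (int i = 0; i < 3; ++i) dv1[i] = dot(n2, t1[i]) + d2;
  for (int i = 0; i < 3; ++i) if (std::fabs(dv1[i]) < EPS) dv1[i] = 0;
  bool pos1 = dv1[0] > 0 || dv1[1] > 0 || dv1[2] > 0;
  bool neg1 = dv1[0] < 0 || dv1[1] < 0 || dv1[2] < 0;
  if (!(pos1 && neg1)) return false;
  Vec3 D = cross(n1, n2);
  double ax = std::fabs(D.x), ay = std::fabs(D.y), az = std::fabs(D.z);
  int axis = (ax >= ay && ax >= az) ? 0 : (ay >= az ? 1 : 2);
  auto proj = [&](const Vec3 &p) {
    return axis == 0 ? p.x : (axis == 1 ? p.y : p.z);
  };
  auto interval = [&](const Vec3 *t, const double *dv, double &lo, double &hi)
      -> bool {
    double p[3] = {proj(t[0]), proj(t[1]), proj(t[2])};
    // pick the vertex on one side, the two on the other
    int a=-1, b=-1, c=-1;
    if (dv[0]*dv[1] > 0) { a=2; b=0; c=1; }
    else if (dv[0]*dv[2] > 0) { a=1; b=0; c=2; }
    else if (dv[1]*dv[2] > 0) { a=0; b=1; c=2; }
    else {
      // zeros present: choose a vertex with nonzero dv as the lone one
      if (dv[0] != 0) { a=0; b=1; c=2; }
      else if (dv[1] != 0) { a=1; b=0; c=2; }
      else if (dv[2] != 0) { a=2; b=0; c=1; }
      else return false;
    }
    double t1_ = p[a] + (p[b]-p[a]) * dv[a] / (dv[a]-dv[b] + ((dv[a]==dv[b])?1e-300:0));
    double t2_ = p[a] + (p[c]-p[a]) * dv[a] / (dv[a]-dv[c] + ((dv[a]==dv[c])?1e-300:0));
    lo = std::min(t1_, t2_); hi = std::max(t1_, t2_);
    return true;
  };
  double lo1, hi1, lo2, hi2;
  if (!interval(t1, dv1, lo1, hi1)) return false;
  if (!interval(t2, dv2, lo2, hi2)) return false;
  return (hi1 > lo2 + tol) && (hi2 > lo1 + tol);
}

// [[Rcpp::export(name = ".mc_self_intersections")]]
int mc_self_intersections(NumericMatrix V, IntegerMatrix F, int max_count,
                          double tol) {
  TriGrid G(V, F);
  int nf = F.nrow(), count = 0;
  std::vector<char> seen(nf);
  for (int f = 0; f < nf; ++f) {
    double tlo[3] = {1e300,1e300,1e300}, thi[3] = {-1e300,-1e300,-1e300};
    for (int c = 0; c < 3; ++c)
      for (int d = 0; d < 3; ++d) {
        tlo[d] = std::min(tlo[d], V(F(f,c),d));
        thi[d] = std::max(thi[d], V(F(f,c),d));
      }
    int i0 = std::max(0, G.cell_of(tlo[0], G.ox));
    int i1 = std::min(G.nx-1, G.cell_of(thi[0], G.ox));
    int j0 = std::max(0, G.cell_of(tlo[1], G.oy));
    int j1 = std::min(G.ny-1, G.cell_of(thi[1], G.oy));
    int k0 = std::max(0, G.cell_of(tlo[2], G.oz));
    int k1 = std::min(G.nz-1, G.cell_of(thi[2], G.oz));
    std::vector<int> cand;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          for (int g : G.cells[i + (size_t)G.nx*(j + (size_t)G.ny*k)])
            if (g > f && !seen[g]) { seen[g] = 1; cand.push_back(g); }
    Vec3 t1[3];
    for (int c = 0; c < 3; ++c)
      t1[c] = {V(F(f,c),0), V(F(f,c),1), V(F(f,c),2)};
    for (int g : cand) {
      seen[g] = 0;
      // skip pairs sharing a vertex
      bool share = false;
      for (int c1 = 0; c1 < 3 && !share; ++c1)
        for (int c2 = 0; c2 < 3; ++c2)
          if (F(f,c1) == F(g,c2)) { share = true; break; }
      if (share) continue;
      Vec3 t2[3];
      for (int c = 0; c < 3; ++c)
        t2[c] = {V(F(g,c),0), V(F(g,c),1), V(F(g,c),2)};
      if (tri_tri_overlap(t1, t2, tol)) {
        if (++count >= max_count) return count;
      }
    }
    for (int g : cand) seen[g] = 0;
  }
  return count;
}

// [[Rcpp::export(name = ".mc_self_intersection_pairs")]]
IntegerMatrix mc_self_intersection_pairs(NumericMatrix V, IntegerMatrix F,
                                         int max_count, double tol) {
  TriGrid G(V, F);
  int nf = F.nrow();
  std::vector<std::pair<int,int>> hits;
  std::vector<char> seen(nf);
  for (int f = 0; f < nf && (int)hits.size() < max_count; ++f) {
    double tlo[3] = {1e300,1e300,1e300}, thi[3] = {-1e300,-1e300,-1e300};
    for (int c = 0; c < 3; ++c)
      for (int d = 0; d < 3; ++d) {
        tlo[d] = std::min(tlo[d], V(F(f,c),d));
        thi[d] = std::max(thi[d], V(F(f,c),d));
      }
    int i0 = std::max(0, G.cell_of(tlo[0], G.ox));
    int i1 = std::min(G.nx-1, G.cell_of(thi[0], G.ox));
    int j0 = std::max(0, G.cell_of(tlo[1], G.oy));
    int j1 = std::min(G.ny-1, G.cell_of(thi[1], G.oy));
    int k0 = std::max(0, G.cell_of(tlo[2], G.oz));
    int k1 = std::min(G.nz-1, G.cell_of(thi[2], G.oz));
    std::vector<int> cand;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          for (int g : G.cells[i + (size_t)G.nx*(j + (size_t)G.ny*k)])
            if (g > f && !seen[g]) { seen[g] = 1; cand.push_back(g); }
    Vec3 t1[3];
    for (int c = 0; c < 3; ++c)
      t1[c] = {V(F(f,c),0), V(F(f,c),1), V(F(f,c),2)};
    for (int g : cand) {
      seen[g] = 0;
      bool share = false;
      for (int c1 = 0; c1 < 3 && !share; ++c1)
        for (int c2 = 0; c2 < 3; ++c2)
          if (F(f,c1) == F(g,c2)) { share = true; break; }
      if (share) continue;
      Vec3 t2[3];
      for (int c = 0; c < 3; ++c)
        t2[c] = {V(F(g,c),0), V(F(g,c),1), V(F(g,c),2)};
      if (tri_tri_overlap(t1, t2, tol)) hits.push_back({f, g});
    }
    for (int g : cand) seen[g] = 0;
  }
  IntegerMatrix out((int)hits.size(), 2);
  for (int i = 0; i < (int)hits.size(); ++i) {
    out(i,0) = hits[i].first + 1; out(i,1) = hits[i].second + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// marker-based priority-flood watershed, 6-connected, deterministic
// ---------------------------------------------------------------------------

struct WSItem {
  double prio; int64_t idx; int label;
};
struct WSCmp {
  bool operator()(const WSItem &a, const WSItem &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;        // min-heap
    return a.idx > b.idx;                                // lexicographic tie
  }
};

// [[Rcpp::export(name = ".mc_watershed")]]
IntegerVector mc_watershed(NumericVector priority, IntegerVector markers,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx*ny*nz;
  IntegerVector labels(n);
  std::priority_queue<WSItem, std::vector<WSItem>, WSCmp> pq;
  for (int64_t i = 0; i < n; ++i) {
    if (markers[i] != 0) pq.push({priority[i], i, markers[i]});
  }
  const int64_t strides[3] = {1, nx, (int64_t)nx*ny};
  while (!pq.empty()) {
    WSItem it = pq.top(); pq.pop();
    if (labels[it.idx] != 0) continue;
    labels[it.idx] = it.label;
    int64_t k = it.idx / ((int64_t)nx*ny);
    int64_t rem = it.idx % ((int64_t)nx*ny);
    int64_t j = rem / nx, i = rem % nx;
    int64_t pos[3] = {i, j, k};
    int64_t lim[3] = {nx, ny, nz};
    for (int d = 0; d < 3; ++d) {
      for (int s = -1; s <= 1; s += 2) {
        int64_t p = pos[d] + s;
        if (p < 0 || p >= lim[d]) continue;
        int64_t nidx = it.idx + s * strides[d];
        if (labels[nidx] == 0)
          pq.push({priority[nidx], nidx, it.label});
      }
    }
  }
  return labels;
}

// ---------------------------------------------------------------------------
// connected components of a binary volume (6- or 26-connected)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mc_label_components")]]
IntegerVector mc_label_components(LogicalVector mask, IntegerVector dims,
                                  int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx*ny*nz;
  IntegerVector labels(n);
  std::vector<int64_t> stack;
  int next = 0;
  std::vector<int64_t> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di)+std::abs(dj)+std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back(di + (int64_t)nx*dj + (int64_t)nx*ny*dk);
      }
  auto coords = [&](int64_t idx, int64_t &i, int64_t &j, int64_t &k) {
    k = idx / ((int64_t)nx*ny);
    int64_t rem = idx % ((int64_t)nx*ny);
    j = rem / nx; i = rem % nx;
  };
  for (int64_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    next++;
    stack.push_back(s);
    labels[s] = next;
    while (!stack.empty()) {
      int64_t cur = stack.back(); stack.pop_back();
      int64_t ci, cj, ck; coords(cur, ci, cj, ck);
      for (size_t o = 0; o < offs.size(); ++o) {
        int64_t nb = cur + offs[o];
        if (nb < 0 || nb >= n) continue;
        int64_t ni, nj, nk; coords(nb, ni, nj, nk);
        if (std::abs(ni-ci) > 1 || std::abs(nj-cj) > 1 || std::abs(nk-ck) > 1)
          continue;
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return labels;
}

// ---------------------------------------------------------------------------
// binary morphology with a Euclidean ball structuring element
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mc_binary_morph")]]
LogicalVector mc_binary_morph(LogicalVector mask, IntegerVector dims,
                              double radius, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int r = (int)std::floor(radius);
  std::vector<int> di, dj, dk;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      for (int c = -r; c <= r; ++c)
        if (a*a + b*b + c*c <= radius*radius) {
          di.push_back(a); dj.push_back(b); dk.push_back(c);
        }
  LogicalVector out((R_xlen_t)nx*ny*nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool acc = !dilate;
        for (size_t o = 0; o < di.size(); ++o) {
          int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
          bool v;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            v = false;
          else
            v = mask[ii + (R_xlen_t)nx*(jj + (R_xlen_t)ny*kk)];
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[i + (R_xlen_t)nx*(j + (R_xlen_t)ny*k)] = acc;
      }
  return out;
}

// ---------------------------------------------------------------------------
// separable Gaussian smoothing, reflective boundary
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mc_gauss_smooth")]]
NumericVector mc_gauss_smooth(NumericVector vol, IntegerVector dims,
                              double sd) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (sd <= 0) return clone(vol);
  int r = std::max(1, (int)std::ceil(3.0 * sd));
  std::vector<double> kern(2*r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) {
    kern[t+r] = std::exp(-0.5 * t * t / (sd*sd));
    s += kern[t+r];
  }
  for (auto &v : kern) v /= s;
  NumericVector a = clone(vol), b((R_xlen_t)nx*ny*nz);
  int dim_[3] = {nx, ny, nz};
  int64_t strides[3] = {1, nx, (int64_t)nx*ny};
  auto reflect = [](int t, int n) {
    while (t < 0 || t >= n) { if (t < 0) t = -t - 1; if (t >= n) t = 2*n - t - 1; }
    return t;
  };
  for (int axis = 0; axis < 3; ++axis) {
    int n_ax = dim_[axis];
    int64_t st = strides[axis];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int pos[3] = {i, j, k};
          int64_t base = i + (int64_t)nx*(j + (int64_t)ny*k);
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int p = reflect(pos[axis] + t, n_ax);
            acc += kern[t+r] * a[base + (int64_t)(p - pos[axis]) * st];
          }
          b[base] = acc;
        }
    std::swap(a, b);
  }
  return a;
}

// ---------------------------------------------------------------------------
// trilinear interpolation at arbitrary (0-based) index-space points
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mc_interp")]]
NumericVector mc_interp(NumericVector src, IntegerVector sdims,
                        NumericMatrix P, double fill) {
  const int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  int n = P.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double x = P(q,0), y = P(q,1), z = P(q,2);
    if (x < 0 || y < 0 || z < 0 || x > sx-1 || y > sy-1 || z > sz-1) {
      out[q] = fill; continue;
    }
    int x0 = std::max(0, std::min((int)std::floor(x), sx-2));
    int y0 = std::max(0, std::min((int)std::floor(y), sy-2));
    int z0 = std::max(0, std::min((int)std::floor(z), sz-2));
    if (sx == 1) x0 = 0; if (sy == 1) y0 = 0; if (sz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    auto at = [&](int a, int b, int c) {
      a = std::min(a, sx-1); b = std::min(b, sy-1); c = std::min(c, sz-1);
      return src[a + (R_xlen_t)sx*(b + (R_xlen_t)sy*c)];
    };
    out[q] =
      at(x0,y0,z0)     * (1-fx)*(1-fy)*(1-fz) +
      at(x0+1,y0,z0)   * fx*(1-fy)*(1-fz) +
      at(x0,y0+1,z0)   * (1-fx)*fy*(1-fz) +
      at(x0+1,y0+1,z0) * fx*fy*(1-fz) +
      at(x0,y0,z0+1)   * (1-fx)*(1-fy)*fz +
      at(x0+1,y0,z0+1) * fx*(1-fy)*fz +
      at(x0,y0+1,z0+1) * (1-fx)*fy*fz +
      at(x0+1,y0+1,z0+1) * fx*fy*fz;
  }
  return out;
}

// ---------------------------------------------------------------------------
// trilinear resampling through a 4x4 index-space map
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mc_resample")]]
NumericVector mc_resample(NumericVector src, IntegerVector sdims,
                          NumericMatrix M, IntegerVector odims,
                          double fill) {
  const int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  const int ox = odims[0], oy = odims[1], oz = odims[2];
  NumericVector out((R_xlen_t)ox*oy*oz);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double x = M(0,0)*i + M(0,1)*j + M(0,2)*k + M(0,3);
        double y = M(1,0)*i + M(1,1)*j + M(1,2)*k + M(1,3);
        double z = M(2,0)*i + M(2,1)*j + M(2,2)*k + M(2,3);
        R_xlen_t oidx = i + (R_xlen_t)ox*(j + (R_xlen_t)oy*k);
        if (x < 0 || y < 0 || z < 0 || x > sx-1 || y > sy-1 || z > sz-1) {
          out[oidx] = fill; continue;
        }
        int x0 = std::min((int)std::floor(x), sx-2 >= 0 ? sx-2 : 0);
        int y0 = std::min((int)std::floor(y), sy-2 >= 0 ? sy-2 : 0);
        int z0 = std::min((int)std::floor(z), sz-2 >= 0 ? sz-2 : 0);
        if (sx == 1) x0 = 0; if (sy == 1) y0 = 0; if (sz == 1) z0 = 0;
        double fx = x - x0, fy = y - y0, fz = z - z0;
        auto at = [&](int a, int b, int c) {
          a = std::min(a, sx-1); b = std::min(b, sy-1); c = std::min(c, sz-1);
          return src[a + (R_xlen_t)sx*(b + (R_xlen_t)sy*c)];
        };
        double v =
          at(x0,y0,z0)     * (1-fx)*(1-fy)*(1-fz) +
          at(x0+1,y0,z0)   * fx*(1-fy)*(1-fz) +
          at(x0,y0+1,z0)   * (1-fx)*fy*(1-fz) +
          at(x0+1,y0+1,z0) * fx*fy*(1-fz) +
          at(x0,y0,z0+1)   * (1-fx)*(1-fy)*fz +
          at(x0+1,y0,z0+1) * fx*(1-fy)*fz +
          at(x0,y0+1,z0+1) * (1-fx)*fy*fz +
          at(x0+1,y0+1,z0+1) * fx*fy*fz;
        out[oidx] = v;
      }
  return out;
}
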