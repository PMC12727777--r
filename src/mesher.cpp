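#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction (level 0.5) from a binary voxel mask.
//
// Grid points sit at voxel centres and the mask is implicitly padded with one
// layer of background, so every foreground region yields a closed, watertight,
// outward-oriented surface. Per grid cell the surface polygon is built by
// marching squares on the six cell faces: each face contributes crossing
// segments, segments chain into closed loops inside the cell, and each loop is
// fan-triangulated from its centroid. Face rules depend only on the face's own
// corner values (ambiguous diagonal faces always separate the two inside
// corners), so neighbouring cells agree on shared faces and the mesh is
// crack-free. Crossing points are edge midpoints (linear interpolation of a
// 0/1 field at level 0.5).
//
// Array layout matches R: dim = (ny, nx, nz), element [j,i,k] (1-based in R),
// voxel centre of (j,i,k) at ((i-0.5)dx, (j-0.5)dy, (k-0.5)dz) nm.

namespace {

struct V3 { double x, y, z; };
inline V3 cross(const V3& a, const V3& b) {
  return V3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline V3 sub(const V3& a, const V3& b) { return V3{a.x - b.x, a.y - b.y, a.z - b.z}; }
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// cube corner offsets (dj, di, dk), corner index c = dj | di<<1 | dk<<2
static const int CJ[8] = {0,1,0,1,0,1,0,1};
static const int CI[8] = {0,0,1,1,0,0,1,1};
static const int CK[8] = {0,0,0,0,1,1,1,1};

// six cell faces, each as 4 corner indices in cyclic order
static const int FACES[6][4] = {
  {0,1,3,2}, // k = 0
  {4,5,7,6}, // k = 1
  {0,1,5,4}, // i = 0
  {2,3,7,6}, // i = 1
  {0,2,6,4}, // j = 0
  {1,3,7,5}  // j = 1
};

} // namespace

// [[Rcpp::export(name = ".mc_isosurface")]]
List mc_isosurface(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];

  const int64_t gy = ny + 2, gx = nx + 2, gz = nz + 2;
  auto gid = [&](int j, int i, int k) -> int64_t {
    return (int64_t)(j + 1) + gy * ((int64_t)(i + 1) + gx * (int64_t)(k + 1));
  };
  auto val = [&](int j, int i, int k) -> int {
    if (j < 0 || j >= ny || i < 0 || i >= nx || k < 0 || k >= nz) return 0;
    return mask[(int64_t)j + (int64_t)ny * ((int64_t)i + (int64_t)nx * (int64_t)k)] ? 1 : 0;
  };
  auto pos = [&](int j, int i, int k) -> V3 {
    return V3{(i + 0.5) * dx, (j + 0.5) * dy, (k + 0.5) * dz};
  };

  std::unordered_map<uint64_t, int> vmap; // global edge -> vertex id
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;

  // crossing vertex on the edge between two grid points (values must differ)
  auto edge_vertex = [&](int64_t ga, int64_t gb, const V3& pa, const V3& pb) -> int {
    int64_t a = ga, b = gb;
    if (a > b) std::swap(a, b);
    uint64_t key = (uint64_t)a * (uint64_t)(gy * gx * gz) + (uint64_t)b;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)vx.size();
    vx.push_back(0.5 * (pa.x + pb.x));
    vy.push_back(0.5 * (pa.y + pb.y));
    vz.push_back(0.5 * (pa.z + pb.z));
    vmap.emplace(key, id);
    return id;
  };

  int cj[8], ci[8], ck[8], cv[8];
  int64_t cg[8];
  V3 cp[8];

  // segment buffer per cell: pairs of crossing-vertex ids, plus per-segment
  // record of the inside corner adjacent to each endpoint's edge
  std::vector<std::array<int,2>> segs;
  std::vector<std::array<int,2>> seg_in; // inside corner per endpoint

  for (int k = -1; k < nz; ++k)
    for (int i = -1; i < nx; ++i)
      for (int j = -1; j < ny; ++j) {
        int s = 0;
        for (int c = 0; c < 8; ++c) {
          cj[c] = j + CJ[c]; ci[c] = i + CI[c]; ck[c] = k + CK[c];
          cv[c] = val(cj[c], ci[c], ck[c]);
          s += cv[c];
        }
        if (s == 0 || s == 8) continue;
        for (int c = 0; c < 8; ++c) {
          cg[c] = gid(cj[c], ci[c], ck[c]);
          cp[c] = pos(cj[c], ci[c], ck[c]);
        }

        segs.clear(); seg_in.clear();

        auto fev = [&](int a, int b) -> int { // crossing vertex on corner pair
          return edge_vertex(cg[a], cg[b], cp[a], cp[b]);
        };
        auto add_seg = [&](int a0, int b0, int a1, int b1) {
          // segment between crossing(a0,b0) and crossing(a1,b1);
          // a0/a1 are the inside corners of their edges
          segs.push_back({fev(a0, b0), fev(a1, b1)});
          seg_in.push_back({a0, a1});
        };

        for (int f = 0; f < 6; ++f) {
          const int* q = FACES[f];
          int m = cv[q[0]] | cv[q[1]] << 1 | cv[q[2]] << 2 | cv[q[3]] << 3;
          if (m == 0 || m == 15) continue;
          // single-corner cases (inside or outside corner isolated)
          for (int c = 0; c < 4; ++c) {
            int bit = 1 << c;
            int prev = q[(c + 3) & 3], cur = q[c], nxt = q[(c + 1) & 3];
            if (m == bit) { // lone inside corner
              add_seg(cur, prev, cur, nxt);
              goto face_done;
            }
            if (m == (15 ^ bit)) { // lone outside corner
              add_seg(prev, cur, nxt, cur);
              goto face_done;
            }
          }
          // adjacent pairs
          for (int c = 0; c < 4; ++c) {
            int pair = (1 << c) | (1 << ((c + 1) & 3));
            if (m == pair) {
              int a = q[c], b = q[(c + 1) & 3];
              int pa = q[(c + 3) & 3], nb = q[(c + 2) & 3];
              add_seg(a, pa, b, nb);
              goto face_done;
            }
          }
          // diagonal (ambiguous): always separate the two inside corners
          {
            int d0 = (m == 5) ? 0 : 1; // corners (0,2) or (1,3) of the face
            int a = q[d0], b = q[d0 + 2];
            add_seg(a, q[(d0 + 1) & 3], a, q[(d0 + 3) & 3]);
            add_seg(b, q[(d0 + 1) & 3], b, q[(d0 + 3) & 3]);
          }
          face_done:;
        }

        // chain segments into closed loops (every crossing vertex has degree 2)
        const int nseg = (int)segs.size();
        std::vector<char> used(nseg, 0);
        for (int s0 = 0; s0 < nseg; ++s0) {
          if (used[s0]) continue;
          std::vector<int> loop;       // crossing-vertex ids in order
          std::vector<int> loop_in;    // inside corners seen along the loop
          used[s0] = 1;
          loop.push_back(segs[s0][0]);
          loop.push_back(segs[s0][1]);
          loop_in.push_back(seg_in[s0][0]);
          loop_in.push_back(seg_in[s0][1]);
          int cur = segs[s0][1];
          for (;;) {
            int nxt = -1;
            for (int t = 0; t < nseg; ++t) {
              if (used[t]) continue;
              if (segs[t][0] == cur || segs[t][1] == cur) { nxt = t; break; }
            }
            if (nxt < 0) break;
            used[nxt] = 1;
            cur = (segs[nxt][0] == cur) ? segs[nxt][1] : segs[nxt][0];
            if (cur == loop.front()) break;
            loop.push_back(cur);
            loop_in.push_back(seg_in[nxt][0]);
          }
          const int L = (int)loop.size();
          if (L < 3) continue;

          // outward sense for this loop: from its own inside corners toward
          // the cell's outside corners adjacent to the loop edges
          V3 cin{0,0,0};
          for (int t : loop_in) { cin.x += cp[t].x; cin.y += cp[t].y; cin.z += cp[t].z; }
          cin.x /= loop_in.size(); cin.y /= loop_in.size(); cin.z /= loop_in.size();
          V3 cpoly{0,0,0};
          for (int t : loop) { cpoly.x += vx[t]; cpoly.y += vy[t]; cpoly.z += vz[t]; }
          cpoly.x /= L; cpoly.y /= L; cpoly.z /= L;
          V3 outdir = sub(cpoly, cin);

          // orient the whole loop once via its Newell normal, then fan with
          // consistent winding (robust on non-planar loops)
          V3 nn{0,0,0};
          for (int t = 0; t < L; ++t) {
            int a = loop[t], b = loop[(t + 1) % L];
            nn.x += (vy[a] - vy[b]) * (vz[a] + vz[b]);
            nn.y += (vz[a] - vz[b]) * (vx[a] + vx[b]);
            nn.z += (vx[a] - vx[b]) * (vy[a] + vy[b]);
          }
          if (dot(nn, outdir) < 0) std::reverse(loop.begin(), loop.end());

          if (L == 3) {
            fa.push_back(loop[0]); fb.push_back(loop[1]); fc.push_back(loop[2]);
          } else {
            // fan from the loop centroid (a new vertex interior to the loop)
            int cid = (int)vx.size();
            vx.push_back(cpoly.x); vy.push_back(cpoly.y); vz.push_back(cpoly.z);
            for (int t = 0; t < L; ++t) {
              fa.push_back(cid);
              fb.push_back(loop[t]);
              fc.push_back(loop[(t + 1) % L]);
            }
          }
        }
      }

  const int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v) { verts(v,0) = vx[v]; verts(v,1) = vy[v]; verts(v,2) = vz[v]; }
  IntegerMatrix faces(nf, 3);
  for (int f = 0; f < nf; ++f) { faces(f,0) = fa[f] + 1; faces(f,1) = fb[f] + 1; faces(f,2) = fc[f] + 1; }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// 6-connected component labelling of a binary mask (same (ny,nx,nz) layout).
// Returns integer labels, 0 for background, components numbered from 1 in
// raster-scan order of their first voxel.
// [[Rcpp::export(name = ".label_components_6")]]
IntegerVector label_components_6(LogicalVector mask, IntegerVector dims) {
  const int64_t ny = dims[0], nx = dims[1], nz = dims[2], n = ny * nx * nz;
  IntegerVector lab(n, 0);
  std::vector<int64_t> stack;
  int next = 0;
  for (int64_t idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++next;
    lab[idx] = next;
    stack.push_back(idx);
    while (!stack.empty()) {
      int64_t cur = stack.back(); stack.pop_back();
      int64_t j = cur % ny, rest = cur / ny, i = rest % nx, k = rest / nx;
      const int64_t dj[6] = {-1, 1, 0, 0, 0, 0};
      const int64_t di[6] = {0, 0, -1, 1, 0, 0};
      const int64_t dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int64_t jj = j + dj[d], ii = i + di[d], kk = k + dk[d];
        if (jj < 0 || jj >= ny || ii < 0 || ii >= nx || kk < 0 || kk >= nz) continue;
        int64_t nb = jj + ny * (ii + nx * kk);
        if (mask[nb] && lab[nb] == 0) { lab[nb] = next; stack.push_back(nb); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
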