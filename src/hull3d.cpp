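#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// 3D convex hull (quickhull) returning surface area, volume and vertex
// count. Coplanar points (within a relative tolerance of a face plane) are
// absorbed rather than added as vertices, which keeps lattice-derived point
// clouds fast and the recursion finite.

struct Face {
  int a, b, c;
  double nx, ny, nz, off;  // outward normal (unit-free) and plane offset
  std::vector<int> outside;
  double far_d;
  int far_p;
  bool alive;
};

static inline void face_plane(Face &f, const std::vector<double> &X,
                              const std::vector<double> &Y,
                              const std::vector<double> &Z, double cx,
                              double cy, double cz) {
  double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
  double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  // orient away from the interior reference point
  double d = f.nx * (cx - X[f.a]) + f.ny * (cy - Y[f.a]) + f.nz * (cz - Z[f.a]);
  if (d > 0) {
    std::swap(f.b, f.c);
    f.nx = -f.nx; f.ny = -f.ny; f.nz = -f.nz;
  }
  double nl = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
  if (nl > 0) { f.nx /= nl; f.ny /= nl; f.nz /= nl; }
  f.off = f.nx * X[f.a] + f.ny * Y[f.a] + f.nz * Z[f.a];
}

static inline double face_dist(const Face &f, double px, double py,
                               double pz) {
  return f.nx * px + f.ny * py + f.nz * pz - f.off;
}

// [[Rcpp::export]]
List cpp_convex_hull(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) return List::create(_["ok"] = false);
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2); }

  double xmin = X[0], xmax = X[0], ymin = Y[0], ymax = Y[0], zmin = Z[0],
         zmax = Z[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, X[i]); xmax = std::max(xmax, X[i]);
    ymin = std::min(ymin, Y[i]); ymax = std::max(ymax, Y[i]);
    zmin = std::min(zmin, Z[i]); zmax = std::max(zmax, Z[i]);
  }
  double diag = std::sqrt((xmax - xmin) * (xmax - xmin) +
                          (ymax - ymin) * (ymax - ymin) +
                          (zmax - zmin) * (zmax - zmin));
  if (diag <= 0) return List::create(_["ok"] = false);
  double eps = 1e-9 * diag;

  // initial extreme pair: farthest apart among axis extremes
  int ext[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 0; i < n; ++i) {
    if (X[i] < X[ext[0]]) ext[0] = i;
    if (X[i] > X[ext[1]]) ext[1] = i;
    if (Y[i] < Y[ext[2]]) ext[2] = i;
    if (Y[i] > Y[ext[3]]) ext[3] = i;
    if (Z[i] < Z[ext[4]]) ext[4] = i;
    if (Z[i] > Z[ext[5]]) ext[5] = i;
  }
  int p0 = ext[0], p1 = ext[1];
  double bestd = -1;
  for (int i = 0; i < 6; ++i)
    for (int j = i + 1; j < 6; ++j) {
      double dx = X[ext[i]] - X[ext[j]], dy = Y[ext[i]] - Y[ext[j]],
             dz = Z[ext[i]] - Z[ext[j]];
      double d = dx * dx + dy * dy + dz * dz;
      if (d > bestd) { bestd = d; p0 = ext[i]; p1 = ext[j]; }
    }
  if (bestd <= eps * eps) return List::create(_["ok"] = false);

  // farthest from the line p0-p1
  double ux = X[p1] - X[p0], uy = Y[p1] - Y[p0], uz = Z[p1] - Z[p0];
  double ul = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= ul; uy /= ul; uz /= ul;
  int p2 = -1; bestd = eps;
  for (int i = 0; i < n; ++i) {
    double wx = X[i] - X[p0], wy = Y[i] - Y[p0], wz = Z[i] - Z[p0];
    double t = wx * ux + wy * uy + wz * uz;
    double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d > bestd) { bestd = d; p2 = i; }
  }
  if (p2 < 0) return List::create(_["ok"] = false);

  // farthest from the plane p0-p1-p2
  double vx = X[p2] - X[p0], vy = Y[p2] - Y[p0], vz = Z[p2] - Z[p0];
  double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz,
         nz = ux * vy - uy * vx;
  double nl = std::sqrt(nx * nx + ny * ny + nz * nz);
  nx /= nl; ny /= nl; nz /= nl;
  int p3 = -1; bestd = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(nx * (X[i] - X[p0]) + ny * (Y[i] - Y[p0]) +
                         nz * (Z[i] - Z[p0]));
    if (d > bestd) { bestd = d; p3 = i; }
  }
  if (p3 < 0) return List::create(_["ok"] = false);  // coplanar cloud

  double cx = (X[p0] + X[p1] + X[p2] + X[p3]) / 4.0;
  double cy = (Y[p0] + Y[p1] + Y[p2] + Y[p3]) / 4.0;
  double cz = (Z[p0] + Z[p1] + Z[p2] + Z[p3]) / 4.0;

  std::vector<Face> faces;
  faces.reserve(512);
  int tetra[4][3] = {{p0, p1, p2}, {p0, p1, p3}, {p0, p2, p3}, {p1, p2, p3}};
  for (int k = 0; k < 4; ++k) {
    Face f;
    f.a = tetra[k][0]; f.b = tetra[k][1]; f.c = tetra[k][2];
    f.alive = true; f.far_d = 0; f.far_p = -1;
    face_plane(f, X, Y, Z, cx, cy, cz);
    faces.push_back(f);
  }
  // assign points to the first face they are outside of
  for (int i = 0; i < n; ++i) {
    for (size_t k = 0; k < faces.size(); ++k) {
      double d = face_dist(faces[k], X[i], Y[i], Z[i]);
      if (d > eps) {
        faces[k].outside.push_back(i);
        if (d > faces[k].far_d) { faces[k].far_d = d; faces[k].far_p = i; }
        break;
      }
    }
  }

  long guard = 0, guard_max = 100L * n + 1000L;
  while (true) {
    if (++guard > guard_max) return List::create(_["ok"] = false);
    int fi = -1;
    for (size_t k = 0; k < faces.size(); ++k) {
      if (faces[k].alive && !faces[k].outside.empty()) { fi = (int)k; break; }
    }
    if (fi < 0) break;
    int p = faces[fi].far_p;
    double px = X[p], py = Y[p], pz = Z[p];

    std::vector<int> visible;
    for (size_t k = 0; k < faces.size(); ++k) {
      if (faces[k].alive && face_dist(faces[k], px, py, pz) > eps)
        visible.push_back((int)k);
    }
    if (visible.empty()) {  // numerical corner: drop the point
      faces[fi].outside.clear();
      faces[fi].far_p = -1; faces[fi].far_d = 0;
      continue;
    }
    // horizon edges: edges of visible faces shared with no other visible face
    std::map<std::pair<int, int>, int> edge_count;
    for (int k : visible) {
      int vv[3] = {faces[k].a, faces[k].b, faces[k].c};
      for (int e = 0; e < 3; ++e) {
        int a = vv[e], b = vv[(e + 1) % 3];
        if (a > b) std::swap(a, b);
        edge_count[std::make_pair(a, b)] += 1;
      }
    }
    std::vector<int> cand;
    for (int k : visible) {
      for (int q : faces[k].outside) if (q != p) cand.push_back(q);
      faces[k].alive = false;
      faces[k].outside.clear();
    }
    std::vector<int> new_faces;
    for (std::map<std::pair<int, int>, int>::iterator it = edge_count.begin();
         it != edge_count.end(); ++it) {
      if (it->second != 1) continue;
      Face f;
      f.a = it->first.first; f.b = it->first.second; f.c = p;
      f.alive = true; f.far_d = 0; f.far_p = -1;
      face_plane(f, X, Y, Z, cx, cy, cz);
      faces.push_back(f);
      new_faces.push_back((int)faces.size() - 1);
    }
    for (int q : cand) {
      for (int k : new_faces) {
        double d = face_dist(faces[k], X[q], Y[q], Z[q]);
        if (d > eps) {
          faces[k].outside.push_back(q);
          if (d > faces[k].far_d) { faces[k].far_d = d; faces[k].far_p = q; }
          break;
        }
      }
    }
  }

  double area = 0, volume = 0;
  std::vector<bool> is_vertex(n, false);
  int n_faces = 0;
  for (size_t k = 0; k < faces.size(); ++k) {
    if (!faces[k].alive) continue;
    ++n_faces;
    const Face &f = faces[k];
    is_vertex[f.a] = is_vertex[f.b] = is_vertex[f.c] = true;
    double ax = X[f.b] - X[f.a], ay = Y[f.b] - Y[f.a], az = Z[f.b] - Z[f.a];
    double bx = X[f.c] - X[f.a], by = Y[f.c] - Y[f.a], bz = Z[f.c] - Z[f.a];
    double crx = ay * bz - az * by, cry = az * bx - ax * bz,
           crz = ax * by - ay * bx;
    area += 0.5 * std::sqrt(crx * crx + cry * cry + crz * crz);
    // signed tetra volume w.r.t. the interior reference point
    double wx = X[f.a] - cx, wy = Y[f.a] - cy, wz = Z[f.a] - cz;
    volume += std::fabs(wx * crx + wy * cry + wz * crz) / 6.0;
  }
  int n_vertices = 0;
  for (int i = 0; i < n; ++i) if (is_vertex[i]) ++n_vertices;
  return List::create(_["ok"] = true, _["area"] = area,
                      _["volume"] = volume, _["n_vertices"] = n_vertices,
                      _["n_faces"] = n_faces);
}
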