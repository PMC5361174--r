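// Periodic Voronoi tessellation of point sites in an orthorhombic box.
//
// Each cell is built by half-space clipping (the classic cell-based
// algorithm): starting from the cuboid bounded by the bisector planes to the
// site's own periodic images, bisector planes to other sites (including all
// 26 ghost images) are applied in order of increasing distance until no
// remaining plane can cut the cell (plane distance/2 exceeds the cell's
// current circumradius).  Faces keep track of the site that generated them,
// which yields the face-sharing neighbor graph and shared face areas.
//
// Sites are atoms; atomic cells are merged into molecular cells here
// (volumes summed, faces between atoms of the same molecule discarded).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <map>
#include <random>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

struct Face {
  int owner;                 // index into the site array (primary index)
  double nx, ny, nz, d;      // plane n.x = d, n unit, site at origin, d > 0
  std::vector<Vec3> v;       // ordered polygon vertices
};

struct Cand {
  double d2;
  double dx, dy, dz;
  int j;                     // primary site index of the ghost
};

inline double dot3(double ax, double ay, double az, const Vec3 &v) {
  return ax * v.x + ay * v.y + az * v.z;
}

// polygon vector area (valid for planar polygons, any origin)
inline double poly_area(const std::vector<Vec3> &p) {
  double ax = 0, ay = 0, az = 0;
  const int n = (int)p.size();
  for (int i = 0; i < n; ++i) {
    const Vec3 &a = p[i];
    const Vec3 &b = p[(i + 1) % n];
    ax += a.y * b.z - a.z * b.y;
    ay += a.z * b.x - a.x * b.z;
    az += a.x * b.y - a.y * b.x;
  }
  return 0.5 * std::sqrt(ax * ax + ay * ay + az * az);
}

// Clip the convex polyhedron by half-space n.x <= d.  Returns true if cut.
bool clip_cell(std::vector<Face> &faces, double nx, double ny, double nz,
               double d, int owner, double tol, double pt_tol) {
  // quick reject: any vertex strictly outside?
  bool any_out = false;
  for (const Face &f : faces) {
    for (const Vec3 &v : f.v) {
      if (dot3(nx, ny, nz, v) - d > tol) { any_out = true; break; }
    }
    if (any_out) break;
  }
  if (!any_out) return false;

  std::vector<Vec3> cap;
  std::vector<Face> out;
  out.reserve(faces.size() + 1);

  for (Face &f : faces) {
    const int n = (int)f.v.size();
    std::vector<Vec3> kept;
    kept.reserve(n + 2);
    for (int i = 0; i < n; ++i) {
      const Vec3 &a = f.v[i];
      const Vec3 &b = f.v[(i + 1) % n];
      const double da = dot3(nx, ny, nz, a) - d;
      const double db = dot3(nx, ny, nz, b) - d;
      if (da <= 0) kept.push_back(a);
      if ((da < 0 && db > 0) || (da > 0 && db < 0)) {
        const double t = da / (da - db);
        Vec3 c{a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
               a.z + t * (b.z - a.z)};
        kept.push_back(c);
        cap.push_back(c);
      }
    }
    if ((int)kept.size() >= 3) {
      f.v.swap(kept);
      out.push_back(std::move(f));
    }
  }

  // de-duplicate cap vertices, order them by angle around the cap centroid
  if (!cap.empty()) {
    std::vector<Vec3> uniq;
    for (const Vec3 &c : cap) {
      bool dup = false;
      for (const Vec3 &u : uniq) {
        const double dx = c.x - u.x, dy = c.y - u.y, dz = c.z - u.z;
        if (dx * dx + dy * dy + dz * dz < pt_tol * pt_tol) { dup = true; break; }
      }
      if (!dup) uniq.push_back(c);
    }
    if ((int)uniq.size() >= 3) {
      Vec3 cen{0, 0, 0};
      for (const Vec3 &u : uniq) { cen.x += u.x; cen.y += u.y; cen.z += u.z; }
      const double inv = 1.0 / uniq.size();
      cen.x *= inv; cen.y *= inv; cen.z *= inv;
      // in-plane basis
      double ux, uy, uz;
      if (std::fabs(nx) < 0.9) { ux = 1; uy = 0; uz = 0; }
      else                     { ux = 0; uy = 1; uz = 0; }
      // e1 = u - (u.n) n
      const double un = ux * nx + uy * ny + uz * nz;
      double e1x = ux - un * nx, e1y = uy - un * ny, e1z = uz - un * nz;
      const double e1n = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
      e1x /= e1n; e1y /= e1n; e1z /= e1n;
      const double e2x = ny * e1z - nz * e1y;
      const double e2y = nz * e1x - nx * e1z;
      const double e2z = nx * e1y - ny * e1x;
      std::vector<std::pair<double, int> > ang(uniq.size());
      for (size_t i = 0; i < uniq.size(); ++i) {
        const double px = uniq[i].x - cen.x, py = uniq[i].y - cen.y,
                     pz = uniq[i].z - cen.z;
        ang[i] = std::make_pair(
            std::atan2(px * e2x + py * e2y + pz * e2z,
                       px * e1x + py * e1y + pz * e1z),
            (int)i);
      }
      std::sort(ang.begin(), ang.end());
      Face cf;
      cf.owner = owner;
      cf.nx = nx; cf.ny = ny; cf.nz = nz; cf.d = d;
      cf.v.reserve(uniq.size());
      for (size_t i = 0; i < uniq.size(); ++i) cf.v.push_back(uniq[ang[i].second]);
      out.push_back(std::move(cf));
    }
  }
  faces.swap(out);
  return true;
}

inline double max_vertex_r2(const std::vector<Face> &faces) {
  double m = 0;
  for (const Face &f : faces)
    for (const Vec3 &v : f.v) {
      const double r2 = v.x * v.x + v.y * v.y + v.z * v.z;
      if (r2 > m) m = r2;
    }
  return m;
}

void init_box_cell(std::vector<Face> &faces, double hx, double hy, double hz,
                   int self) {
  faces.clear();
  const double sx[2] = {-1, 1};
  for (int axis = 0; axis < 3; ++axis) {
    for (int s = 0; s < 2; ++s) {
      Face f;
      f.owner = self;
      f.nx = (axis == 0) ? sx[s] : 0;
      f.ny = (axis == 1) ? sx[s] : 0;
      f.nz = (axis == 2) ? sx[s] : 0;
      f.d = (axis == 0) ? hx : (axis == 1) ? hy : hz;
      // rectangle vertices, counter-clockwise seen from outside
      const double a = (axis == 0) ? hy : hx;
      const double b = (axis == 2) ? hy : hz;
      const double corn[4][2] = {{-a, -b}, {a, -b}, {a, b}, {-a, b}};
      for (int k = 0; k < 4; ++k) {
        Vec3 v;
        if (axis == 0)      v = Vec3{sx[s] * hx, corn[k][0], corn[k][1]};
        else if (axis == 1) v = Vec3{corn[k][0], sx[s] * hy, corn[k][1]};
        else                v = Vec3{corn[k][0], corn[k][1], sx[s] * hz};
        f.v.push_back(v);
      }
      faces.push_back(std::move(f));
    }
  }
}

} // namespace

// [[Rcpp::export(rng = false)]]
List voronoi_cells_cpp(NumericMatrix coords, NumericVector box,
                       IntegerVector mol, double jitter, int jitter_seed) {
  const int n = coords.nrow();
  if (n < 1) stop("no sites");
  const double Lx = box[0], Ly = box[1], Lz = box[2];

  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) {
    X[i] = coords(i, 0); Y[i] = coords(i, 1); Z[i] = coords(i, 2);
  }
  if (jitter > 0) {
    std::mt19937 rng((unsigned)jitter_seed);
    std::uniform_real_distribution<double> u(-jitter, jitter);
    for (int i = 0; i < n; ++i) { X[i] += u(rng); Y[i] += u(rng); Z[i] += u(rng); }
  }

  const int nmol = *std::max_element(mol.begin(), mol.end());
  const double Lmax = std::max(Lx, std::max(Ly, Lz));
  const double tol = 1e-9 * Lmax;      // plane-cut tolerance
  const double pt_tol = 1e-9 * Lmax;   // cap-vertex merge tolerance
  const double diag2 = Lx * Lx + Ly * Ly + Lz * Lz; // (2*R0)^2 bound

  NumericVector site_vol(n);
  NumericVector mol_vol(nmol);
  std::map<std::pair<int, int>, double> mol_face; // directed (mi, mj) -> area

  std::vector<Cand> cand;
  cand.reserve(27 * (size_t)n);
  std::vector<Face> faces;

  // adaptive neighbor-search radius: start at a few mean spacings and
  // escalate until no remaining site can cut the finished cell
  const double diag = std::sqrt(diag2);
  const double r_cut0 = std::min(diag, 4.0 * std::cbrt(Lx * Ly * Lz / n));

  for (int i = 0; i < n; ++i) {
    double r_cut = r_cut0;
    double maxr2 = 0;
    for (;;) {
      cand.clear();
      const double rc2 = r_cut * r_cut;
      for (int j = 0; j < n; ++j) {
        const double bx = X[j] - X[i], by = Y[j] - Y[i], bz = Z[j] - Z[i];
        // per-axis admissible image shifts
        double sxs[3], sys[3], szs[3];
        int nx = 0, ny = 0, nz = 0;
        for (int s = -1; s <= 1; ++s) {
          if (std::fabs(bx + s * Lx) <= r_cut) sxs[nx++] = bx + s * Lx;
          if (std::fabs(by + s * Ly) <= r_cut) sys[ny++] = by + s * Ly;
          if (std::fabs(bz + s * Lz) <= r_cut) szs[nz++] = bz + s * Lz;
        }
        for (int a = 0; a < nx; ++a)
          for (int b = 0; b < ny; ++b)
            for (int c = 0; c < nz; ++c) {
              const double dx = sxs[a], dy = sys[b], dz = szs[c];
              const double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < 1e-20 || d2 > rc2) continue;
              cand.push_back(Cand{d2, dx, dy, dz, j});
            }
      }
      std::sort(cand.begin(), cand.end(),
                [](const Cand &a, const Cand &b) { return a.d2 < b.d2; });

      init_box_cell(faces, Lx / 2, Ly / 2, Lz / 2, i);
      maxr2 = max_vertex_r2(faces);
      for (const Cand &c : cand) {
        if (c.d2 >= 4.0 * maxr2) break;
        const double dn = std::sqrt(c.d2);
        if (clip_cell(faces, c.dx / dn, c.dy / dn, c.dz / dn, 0.5 * dn,
                      c.j, tol, pt_tol))
          maxr2 = max_vertex_r2(faces);
      }
      // candidate set complete if nothing beyond r_cut could cut the cell
      if (4.0 * maxr2 <= rc2 || r_cut >= diag) break;
      r_cut = std::min(diag, 2.0 * r_cut);
    }

    // volume and molecular face areas
    double vol = 0;
    const int mi = mol[i];
    for (const Face &f : faces) {
      const double A = poly_area(f.v);
      vol += f.d * A / 3.0;
      const int mj = mol[f.owner];
      if (mj != mi) {
        auto key = std::make_pair(mi, mj);
        auto it = mol_face.find(key);
        if (it == mol_face.end()) mol_face[key] = A;
        else it->second += A;
      }
    }
    site_vol[i] = vol;
    mol_vol[mi - 1] += vol;
  }

  const size_t ne = mol_face.size();
  IntegerVector ei(ne), ej(ne);
  NumericVector ea(ne);
  size_t idx = 0;
  for (const auto &kv : mol_face) {
    ei[idx] = kv.first.first;
    ej[idx] = kv.first.second;
    ea[idx] = kv.second;
    ++idx;
  }

  return List::create(_["site_volumes"] = site_vol,
                      _["mol_volumes"] = mol_vol,
                      _["edge_i"] = ei, _["edge_j"] = ej,
                      _["edge_area"] = ea);
}
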