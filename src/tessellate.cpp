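#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Deterministic 64-bit LCG used for the symbolic joggle of degenerate inputs.
// Never touches R's RNG: identical inputs always yield identical perturbations.
static inline double lcgUnif(uint64_t &state) {
  state = state * 6364136223846793005ULL + 1442695040888963407ULL;
  return static_cast<double>((state >> 11) & ((1ULL << 52) - 1)) /
         static_cast<double>(1ULL << 52);
}

static inline double dist2(const double *a, const double *b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// Circumsphere of four points: solve the perpendicular-bisector system.
// Returns false when the points are (near-)coplanar.
static bool circumsphere(const double *A, const double *B, const double *C,
                         const double *D, double *center, double &r2) {
  double M[3][3], rhs[3];
  const double *P[3] = {B, C, D};
  double scale = 0.0;
  for (int i = 0; i < 3; ++i) {
    double s = 0.0;
    for (int j = 0; j < 3; ++j) {
      M[i][j] = 2.0 * (P[i][j] - A[j]);
      if (std::fabs(M[i][j]) > scale) scale = std::fabs(M[i][j]);
      s += P[i][j] * P[i][j] - A[j] * A[j];
    }
    rhs[i] = s;
  }
  double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
               M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
               M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  if (std::fabs(det) <= 1e-10 * scale * scale * scale) return false;
  // Cramer's rule
  double X[3];
  for (int c = 0; c < 3; ++c) {
    double T[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) T[i][j] = (j == c) ? rhs[i] : M[i][j];
    double d = T[0][0] * (T[1][1] * T[2][2] - T[1][2] * T[2][1]) -
               T[0][1] * (T[1][0] * T[2][2] - T[1][2] * T[2][0]) +
               T[0][2] * (T[1][0] * T[2][1] - T[1][1] * T[2][0]);
    X[c] = d / det;
  }
  center[0] = X[0];
  center[1] = X[1];
  center[2] = X[2];
  r2 = dist2(center, A);
  return true;
}

// Delaunay tetrahedra restricted to edge length <= cutoff, by direct
// empty-circumsphere enumeration over 4-cliques of the distance graph.
// A retained tetrahedron is exactly a 4-subset whose 6 edges are all within
// the cutoff and whose circumsphere contains no other point; this matches
// the definitional Delaunay property rather than a particular incremental
// algorithm. Cospherical ties trigger a deterministic joggle and a rerun.
// [[Rcpp::export]]
List cppDelaunayCutoff(NumericMatrix pts, double cutoff, double tieTol,
                       int maxJoggle, double joggleScale) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");

  std::vector<double> base(3 * n);
  for (int i = 0; i < n; ++i) {
    base[3 * i] = pts(i, 0);
    base[3 * i + 1] = pts(i, 1);
    base[3 * i + 2] = pts(i, 2);
  }
  // bounding-box diagonal sets the joggle amplitude
  double lo[3] = {base[0], base[1], base[2]}, hi[3] = {base[0], base[1], base[2]};
  for (int i = 1; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      if (base[3 * i + j] < lo[j]) lo[j] = base[3 * i + j];
      if (base[3 * i + j] > hi[j]) hi[j] = base[3 * i + j];
    }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diag <= 0.0) stop("all points coincide");

  const double cut2 = cutoff * cutoff;
  // cosphericality is judged by distance to the sphere surface in length
  // units relative to the cloud size, so that near-coplanar quadruples with
  // enormous circumspheres cannot raise spurious ties
  const double tieEps = tieTol * diag;
  std::vector<double> xyz(3 * n);
  std::vector<int> out;
  int rounds = 0;
  bool joggled = false;

  for (int round = 0; round <= maxJoggle; ++round) {
    rounds = round;
    xyz = base;
    if (round > 0) {
      joggled = true;
      uint64_t state = 0x9E3779B97F4A7C15ULL + static_cast<uint64_t>(round);
      double amp = joggleScale * diag * round;
      for (int i = 0; i < 3 * n; ++i)
        xyz[i] += amp * (lcgUnif(state) - 0.5);
    }

    // adjacency under the edge cutoff
    std::vector<unsigned char> adj(static_cast<size_t>(n) * n, 0);
    std::vector<std::vector<int> > nbr(n);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (dist2(&xyz[3 * i], &xyz[3 * j]) <= cut2) {
          adj[static_cast<size_t>(i) * n + j] = 1;
          adj[static_cast<size_t>(j) * n + i] = 1;
          nbr[i].push_back(j);  // ascending, > i
        }

    out.clear();
    bool tie = false;
    double center[3], r2;
    for (int i = 0; i < n && !tie; ++i) {
      const std::vector<int> &Ni = nbr[i];
      const size_t m = Ni.size();
      for (size_t a = 0; a < m && !tie; ++a) {
        int j = Ni[a];
        for (size_t b = a + 1; b < m && !tie; ++b) {
          int k = Ni[b];
          if (!adj[static_cast<size_t>(j) * n + k]) continue;
          for (size_t c = b + 1; c < m && !tie; ++c) {
            int l = Ni[c];
            if (!adj[static_cast<size_t>(j) * n + l] ||
                !adj[static_cast<size_t>(k) * n + l])
              continue;
            if (!circumsphere(&xyz[3 * i], &xyz[3 * j], &xyz[3 * k],
                              &xyz[3 * l], center, r2))
              continue;  // coplanar quadruple: not a simplex
            bool empty = true;
            double r = std::sqrt(r2);
            for (int q = 0; q < n; ++q) {
              if (q == i || q == j || q == k || q == l) continue;
              double d = std::sqrt(dist2(center, &xyz[3 * q]));
              if (std::fabs(d - r) <= tieEps) {
                tie = true;  // cospherical degeneracy: joggle and rerun
                break;
              }
              if (d < r) {
                empty = false;
                break;
              }
            }
            if (tie) break;
            if (empty) {
              out.push_back(i + 1);
              out.push_back(j + 1);
              out.push_back(k + 1);
              out.push_back(l + 1);
            }
          }
        }
      }
    }
    if (!tie) break;
    if (round == maxJoggle)
      stop("cospherical degeneracies persist after %d joggle rounds", maxJoggle);
  }

  const int ntet = static_cast<int>(out.size() / 4);
  IntegerMatrix tets(ntet, 4);
  for (int t = 0; t < ntet; ++t)
    for (int v = 0; v < 4; ++v) tets(t, v) = out[4 * t + v];
  return List::create(_["tetrahedra"] = tets, _["joggled"] = joggled,
                      _["joggleRounds"] = rounds);
}

// Convex-hull vertex identification by supporting-plane enumeration: a
// triangle (i,j,k) spans a hull facet iff every other point lies on one
// closed side of its plane; hull vertices are the union of facet vertices.
// [[Rcpp::export]]
LogicalVector cppHullVertices(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<double> xyz(3 * n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      xyz[3 * i + j] = pts(i, j);
      if (std::fabs(pts(i, j)) > scale) scale = std::fabs(pts(i, j));
    }
  LogicalVector hull(n, false);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      for (int k = j + 1; k < n; ++k) {
        const double *A = &xyz[3 * i], *B = &xyz[3 * j], *C = &xyz[3 * k];
        double u[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
        double v[3] = {C[0] - A[0], C[1] - A[1], C[2] - A[2]};
        double nv[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                        u[0] * v[1] - u[1] * v[0]};
        double nn = std::sqrt(nv[0] * nv[0] + nv[1] * nv[1] + nv[2] * nv[2]);
        if (nn <= 1e-12 * scale * scale) continue;  // collinear triple
        double eps = 1e-9 * nn * scale;
        bool pos = false, neg = false;
        for (int q = 0; q < n; ++q) {
          if (q == i || q == j || q == k) continue;
          const double *P = &xyz[3 * q];
          double s = nv[0] * (P[0] - A[0]) + nv[1] * (P[1] - A[1]) +
                     nv[2] * (P[2] - A[2]);
          if (s > eps) pos = true;
          else if (s < -eps) neg = true;
          if (pos && neg) break;
        }
        if (!(pos && neg)) {
          hull[i] = true;
          hull[j] = true;
          hull[k] = true;
        }
      }
    }
  }
  return hull;
}
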