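// Exact closest-point-on-mesh queries.
//
// Each query point is tested against triangles with the standard
// region-classified point-triangle projection (face / edge / vertex), under
// a median-split AABB tree so that curve projection over thousands of points
// stays cheap. Ties between equidistant triangles resolve to the lowest
// triangle index, making results independent of traversal order.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// Closest point on triangle (a,b,c) to p. Ericson-style barycentric
// region classification; exact up to floating point.
static Vec3 closest_on_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                                const Vec3 &c) {
  Vec3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;

  Vec3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return {a.x + v * ab.x, a.y + v * ab.y, a.z + v * ab.z};
  }

  Vec3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return {a.x + w * ac.x, a.y + w * ac.y, a.z + w * ac.z};
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    Vec3 bc = sub(c, b);
    return {b.x + w * bc.x, b.y + w * bc.y, b.z + w * bc.z};
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return {a.x + ab.x * v + ac.x * w, a.y + ab.y * v + ac.y * w,
          a.z + ab.z * v + ac.z * w};
}

struct Box {
  double lo[3], hi[3];
};

static inline double box_dist2(const Box &b, const Vec3 &p) {
  double q[3] = {p.x, p.y, p.z}, d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = 0.0;
    if (q[k] < b.lo[k]) d = b.lo[k] - q[k];
    else if (q[k] > b.hi[k]) d = q[k] - b.hi[k];
    d2 += d * d;
  }
  return d2;
}

struct Node {
  Box box;
  int left, right;    // children indices, -1 for leaf
  int begin, end;     // triangle id range (into order[]) for leaves
};

struct MeshTree {
  std::vector<Vec3> v;         // vertices
  std::vector<int> tri;        // 3 * ntri vertex indices (0-based)
  std::vector<int> order;      // triangle ids, partitioned by the tree
  std::vector<Node> nodes;
  int root;

  int build(std::vector<double> &cent, int begin, int end) {
    Node node;
    node.begin = begin;
    node.end = end;
    node.left = node.right = -1;
    for (int k = 0; k < 3; ++k) {
      node.box.lo[k] = R_PosInf;
      node.box.hi[k] = R_NegInf;
    }
    for (int i = begin; i < end; ++i) {
      int t = order[i];
      for (int j = 0; j < 3; ++j) {
        const Vec3 &p = v[tri[3 * t + j]];
        double q[3] = {p.x, p.y, p.z};
        for (int k = 0; k < 3; ++k) {
          node.box.lo[k] = std::min(node.box.lo[k], q[k]);
          node.box.hi[k] = std::max(node.box.hi[k], q[k]);
        }
      }
    }
    int id = (int)nodes.size();
    nodes.push_back(node);
    if (end - begin > 8) {
      int axis = 0;
      double best = node.box.hi[0] - node.box.lo[0];
      for (int k = 1; k < 3; ++k) {
        double w = node.box.hi[k] - node.box.lo[k];
        if (w > best) { best = w; axis = k; }
      }
      int mid = (begin + end) / 2;
      std::nth_element(order.begin() + begin, order.begin() + mid,
                       order.begin() + end, [&](int a, int b) {
                         double ca = cent[3 * a + axis];
                         double cb = cent[3 * b + axis];
                         if (ca != cb) return ca < cb;
                         return a < b;
                       });
      int l = build(cent, begin, mid);
      int r = build(cent, mid, end);
      nodes[id].left = l;
      nodes[id].right = r;
    }
    return id;
  }

  void query(const Vec3 &p, double &bestD2, int &bestTri, Vec3 &bestPt,
             int nodeId) const {
    const Node &node = nodes[nodeId];
    if (node.left >= 0) {
      double dl = box_dist2(nodes[node.left].box, p);
      double dr = box_dist2(nodes[node.right].box, p);
      int first = node.left, second = node.right;
      double dfirst = dl, dsecond = dr;
      if (dr < dl) {
        first = node.right; second = node.left;
        dfirst = dr; dsecond = dl;
      }
      if (dfirst <= bestD2) query(p, bestD2, bestTri, bestPt, first);
      if (dsecond <= bestD2) query(p, bestD2, bestTri, bestPt, second);
      return;
    }
    for (int i = node.begin; i < node.end; ++i) {
      int t = order[i];
      Vec3 q = closest_on_triangle(p, v[tri[3 * t]], v[tri[3 * t + 1]],
                                   v[tri[3 * t + 2]]);
      Vec3 d = sub(p, q);
      double d2 = dot(d, d);
      if (d2 < bestD2 || (d2 == bestD2 && t < bestTri)) {
        bestD2 = d2;
        bestTri = t;
        bestPt = q;
      }
    }
  }
};

// [[Rcpp::export(name = ".cpp_mesh_tree")]]
SEXP cpp_mesh_tree(NumericMatrix vertices, IntegerMatrix triangles) {
  MeshTree *tree = new MeshTree();
  int nv = vertices.nrow(), nt = triangles.nrow();
  tree->v.resize(nv);
  for (int i = 0; i < nv; ++i)
    tree->v[i] = {vertices(i, 0), vertices(i, 1), vertices(i, 2)};
  tree->tri.resize(3 * nt);
  tree->order.resize(nt);
  std::vector<double> cent(3 * nt);
  for (int t = 0; t < nt; ++t) {
    tree->order[t] = t;
    double cx = 0, cy = 0, cz = 0;
    for (int j = 0; j < 3; ++j) {
      int vi = triangles(t, j) - 1;  // 1-based from R
      tree->tri[3 * t + j] = vi;
      cx += tree->v[vi].x; cy += tree->v[vi].y; cz += tree->v[vi].z;
    }
    cent[3 * t] = cx / 3.0;
    cent[3 * t + 1] = cy / 3.0;
    cent[3 * t + 2] = cz / 3.0;
  }
  tree->root = tree->build(cent, 0, nt);
  XPtr<MeshTree> ptr(tree, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_closest_points")]]
List cpp_closest_points(SEXP treePtr, NumericMatrix queries) {
  XPtr<MeshTree> tree(treePtr);
  int n = queries.nrow();
  NumericMatrix foot(n, 3);
  NumericVector dist(n);
  IntegerVector triIdx(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p = {queries(i, 0), queries(i, 1), queries(i, 2)};
    double bestD2 = R_PosInf;
    int bestTri = -1;
    Vec3 bestPt = p;
    tree->query(p, bestD2, bestTri, bestPt, tree->root);
    foot(i, 0) = bestPt.x;
    foot(i, 1) = bestPt.y;
    foot(i, 2) = bestPt.z;
    dist[i] = std::sqrt(bestD2);
    triIdx[i] = bestTri + 1;
  }
  return List::create(_["point"] = foot, _["distance"] = dist,
                      _["triangle"] = triIdx);
}
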