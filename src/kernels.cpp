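// Low-level voxel kernels shared by the segmentation, morphometry and
// alignment layers.  All arrays are R column-major with dim = (d1, d2, d3);
// linear index = i1 + d1 * (i2 + d2 * i3), 0-based.  `spacing` is the
// physical size of a voxel along each of the three dims (nm).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
#include <limits>
#include <utility>

using namespace Rcpp;

namespace {

struct Grid {
    int d1, d2, d3;
    Grid(const IntegerVector &dim) : d1(dim[0]), d2(dim[1]), d3(dim[2]) {}
    inline int size() const { return d1 * d2 * d3; }
    inline int idx(int i, int j, int k) const { return i + d1 * (j + d2 * k); }
    inline void coords(int v, int &i, int &j, int &k) const {
        i = v % d1;
        j = (v / d1) % d2;
        k = v / (d1 * d2);
    }
};

// neighbour offsets for 6- or 26-connectivity
void neighbour_offsets(int connectivity,
                       std::vector<int> &di, std::vector<int> &dj,
                       std::vector<int> &dk) {
    di.clear(); dj.clear(); dk.clear();
    for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
                if (a == 0 && b == 0 && c == 0) continue;
                int nz = std::abs(a) + std::abs(b) + std::abs(c);
                if (connectivity == 6 && nz != 1) continue;
                di.push_back(a); dj.push_back(b); dk.push_back(c);
            }
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity = 26) {
    Grid g(dim);
    const int n = g.size();
    IntegerVector labels(n, 0);
    std::vector<int> di, dj, dk;
    neighbour_offsets(connectivity, di, dj, dk);
    const int nn = (int)di.size();

    int next = 0;
    std::queue<int> q;
    for (int v = 0; v < n; ++v) {
        if (!mask[v] || labels[v] != 0) continue;
        ++next;
        labels[v] = next;
        q.push(v);
        while (!q.empty()) {
            int u = q.front(); q.pop();
            int i, j, k;
            g.coords(u, i, j, k);
            for (int t = 0; t < nn; ++t) {
                int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
                if (ii < 0 || jj < 0 || kk < 0 ||
                    ii >= g.d1 || jj >= g.d2 || kk >= g.d3) continue;
                int w = g.idx(ii, jj, kk);
                if (mask[w] && labels[w] == 0) {
                    labels[w] = next;
                    q.push(w);
                }
            }
        }
    }
    return labels;
}

// [[Rcpp::export]]
LogicalVector cpp_flood_fill(LogicalVector mask, IntegerVector dim,
                             int seed0, int connectivity = 26) {
    Grid g(dim);
    LogicalVector out(g.size(), false);
    if (seed0 < 0 || seed0 >= g.size() || !mask[seed0]) return out;
    std::vector<int> di, dj, dk;
    neighbour_offsets(connectivity, di, dj, dk);
    const int nn = (int)di.size();
    std::queue<int> q;
    out[seed0] = true;
    q.push(seed0);
    while (!q.empty()) {
        int u = q.front(); q.pop();
        int i, j, k;
        g.coords(u, i, j, k);
        for (int t = 0; t < nn; ++t) {
            int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
            if (ii < 0 || jj < 0 || kk < 0 ||
                ii >= g.d1 || jj >= g.d2 || kk >= g.d3) continue;
            int w = g.idx(ii, jj, kk);
            if (mask[w] && !out[w]) {
                out[w] = true;
                q.push(w);
            }
        }
    }
    return out;
}

namespace {

// 1D squared Euclidean distance transform (lower envelope of parabolas),
// samples at positions p * s.
void dt1d(const std::vector<double> &f, std::vector<double> &d, double s) {
    const int n = (int)f.size();
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = -1;
    for (int q = 0; q < n; ++q) {
        if (f[q] == INF) continue; // infinite parabolas never win
        double xq = q * s;
        while (k >= 0) {
            double xv = v[k] * s;
            double sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) /
                (2.0 * xq - 2.0 * xv);
            if (sint <= z[k]) { --k; continue; }
            ++k;
            v[k] = q;
            z[k] = sint;
            z[k + 1] = INF;
            break;
        }
        if (k < 0) {
            k = 0;
            v[0] = q;
            z[0] = -INF;
            z[1] = INF;
        }
    }
    if (k < 0) { // no finite source on this line
        d.assign(n, INF);
        return;
    }
    d.assign(n, 0.0);
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * s;
        while (z[k + 1] < xq) ++k;
        double xv = v[k] * s;
        d[q] = (xq - xv) * (xq - xv) + f[v[k]];
    }
}

} // namespace

// Anisotropic Euclidean distance (nm) from every foreground voxel to the
// nearest background voxel; with `border_background` (default) the space
// outside the grid counts as background too.  Background voxels get 0.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing,
                      bool border_background = true) {
    Grid g(dim);
    const double INF = std::numeric_limits<double>::infinity();
    // pad one voxel on each side (background or unreachable)
    int p1 = g.d1 + 2, p2 = g.d2 + 2, p3 = g.d3 + 2;
    std::vector<double> f((size_t)p1 * p2 * p3,
                          border_background ? 0.0 : INF);
    if (!border_background)
        for (int k = 0; k < g.d3; ++k)
            for (int j = 0; j < g.d2; ++j)
                for (int i = 0; i < g.d1; ++i)
                    if (!mask[g.idx(i, j, k)])
                        f[(size_t)(i + 1) + (size_t)p1 * ((j + 1) + (size_t)p2 * (k + 1))] = 0.0;
    for (int k = 0; k < g.d3; ++k)
        for (int j = 0; j < g.d2; ++j)
            for (int i = 0; i < g.d1; ++i)
                if (mask[g.idx(i, j, k)])
                    f[(size_t)(i + 1) + (size_t)p1 * ((j + 1) + (size_t)p2 * (k + 1))] = INF;

    std::vector<double> line, out;
    // pass along dim 1
    line.resize(p1); out.resize(p1);
    for (int k = 0; k < p3; ++k)
        for (int j = 0; j < p2; ++j) {
            size_t base = (size_t)p1 * (j + (size_t)p2 * k);
            for (int i = 0; i < p1; ++i) line[i] = f[base + i];
            dt1d(line, out, spacing[0]);
            for (int i = 0; i < p1; ++i) f[base + i] = out[i];
        }
    // pass along dim 2
    line.resize(p2); out.resize(p2);
    for (int k = 0; k < p3; ++k)
        for (int i = 0; i < p1; ++i) {
            for (int j = 0; j < p2; ++j)
                line[j] = f[(size_t)i + (size_t)p1 * (j + (size_t)p2 * k)];
            dt1d(line, out, spacing[1]);
            for (int j = 0; j < p2; ++j)
                f[(size_t)i + (size_t)p1 * (j + (size_t)p2 * k)] = out[j];
        }
    // pass along dim 3
    line.resize(p3); out.resize(p3);
    for (int j = 0; j < p2; ++j)
        for (int i = 0; i < p1; ++i) {
            for (int k = 0; k < p3; ++k)
                line[k] = f[(size_t)i + (size_t)p1 * (j + (size_t)p2 * k)];
            dt1d(line, out, spacing[2]);
            for (int k = 0; k < p3; ++k)
                f[(size_t)i + (size_t)p1 * (j + (size_t)p2 * k)] = out[k];
        }

    NumericVector res(g.size());
    for (int k = 0; k < g.d3; ++k)
        for (int j = 0; j < g.d2; ++j)
            for (int i = 0; i < g.d1; ++i) {
                int v = g.idx(i, j, k);
                res[v] = mask[v]
                    ? std::sqrt(f[(size_t)(i + 1) + (size_t)p1 * ((j + 1) + (size_t)p2 * (k + 1))])
                    : 0.0;
            }
    return res;
}

// Dijkstra geodesic distances inside a mask.  Edge length is the physical
// distance between voxel centres, optionally scaled by the mean of a
// per-voxel weight (used to keep extracted paths close to the medial axis).
// Returns distances (Inf where unreachable), 0-based predecessor indices
// (-1 for sources/unreached) and the 1-based index of the claiming source.
// [[Rcpp::export]]
List cpp_geodesic(LogicalVector mask, IntegerVector dim,
                  NumericVector spacing, IntegerVector sources,
                  NumericVector nodeweight) {
    Grid g(dim);
    const int n = g.size();
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<double> dist(n, INF);
    std::vector<int> pred(n, -1), src(n, 0);
    const bool weighted = nodeweight.size() == n;

    std::vector<int> di, dj, dk;
    neighbour_offsets(26, di, dj, dk);
    const int nn = (int)di.size();
    std::vector<double> step(nn);
    for (int t = 0; t < nn; ++t) {
        double a = di[t] * spacing[0], b = dj[t] * spacing[1],
               c = dk[t] * spacing[2];
        step[t] = std::sqrt(a * a + b * b + c * c);
    }

    typedef std::pair<double, int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    for (int s = 0; s < sources.size(); ++s) {
        int v = sources[s];
        if (v < 0 || v >= n || !mask[v]) continue;
        if (dist[v] > 0.0) {
            dist[v] = 0.0;
            src[v] = s + 1;
            pq.push(QE(0.0, v));
        }
    }
    while (!pq.empty()) {
        QE top = pq.top(); pq.pop();
        int u = top.second;
        if (top.first > dist[u]) continue;
        int i, j, k;
        g.coords(u, i, j, k);
        for (int t = 0; t < nn; ++t) {
            int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
            if (ii < 0 || jj < 0 || kk < 0 ||
                ii >= g.d1 || jj >= g.d2 || kk >= g.d3) continue;
            int w = g.idx(ii, jj, kk);
            if (!mask[w]) continue;
            double cost = step[t];
            if (weighted) cost *= 0.5 * (nodeweight[u] + nodeweight[w]);
            double nd = dist[u] + cost;
            if (nd < dist[w]) {
                dist[w] = nd;
                pred[w] = u;
                src[w] = src[u];
                pq.push(QE(nd, w));
            }
        }
    }

    NumericVector rdist(n);
    IntegerVector rpred(n), rsrc(n);
    for (int v = 0; v < n; ++v) {
        rdist[v] = dist[v];
        rpred[v] = pred[v];
        rsrc[v] = src[v];
    }
    return List::create(_["dist"] = rdist, _["pred"] = rpred,
                        _["src"] = rsrc);
}

// Exhaustive translation-only registration of `mov` against `ref` over an
// integer shift window.  Score is the normalized cross-correlation over the
// overlap region.  Ties prefer the smallest |dy|+|dx|, then lexicographic.
// Returns c(dy, dx, score, boundary_limited).
// [[Rcpp::export]]
NumericVector cpp_align_pair(NumericMatrix ref, NumericMatrix mov,
                             int max_shift) {
    const int nr = ref.nrow(), nc = ref.ncol();
    double best = -2.0;
    int bdy = 0, bdx = 0;
    for (int dy = -max_shift; dy <= max_shift; ++dy) {
        for (int dx = -max_shift; dx <= max_shift; ++dx) {
            // mov shifted by (dy, dx) compared against ref on the overlap
            int r0 = std::max(0, dy), r1 = std::min(nr, nr + dy);
            int c0 = std::max(0, dx), c1 = std::min(nc, nc + dx);
            long cnt = (long)(r1 - r0) * (c1 - c0);
            if (cnt < 16) continue;
            double sr = 0, sm = 0, srr = 0, smm = 0, srm = 0;
            for (int c = c0; c < c1; ++c) {
                for (int r = r0; r < r1; ++r) {
                    double a = ref(r, c);
                    double b = mov(r - dy, c - dx);
                    sr += a; sm += b;
                    srr += a * a; smm += b * b; srm += a * b;
                }
            }
            double va = srr - sr * sr / cnt;
            double vb = smm - sm * sm / cnt;
            if (va <= 0 || vb <= 0) continue;
            double score = (srm - sr * sm / cnt) / std::sqrt(va * vb);
            bool better = score > best + 1e-12;
            if (!better && score > best - 1e-12) {
                int cand = std::abs(dy) + std::abs(dx);
                int cur = std::abs(bdy) + std::abs(bdx);
                if (cand < cur ||
                    (cand == cur && (dy < bdy || (dy == bdy && dx < bdx))))
                    better = true;
            }
            if (better) {
                best = score;
                bdy = dy;
                bdx = dx;
            }
        }
    }
    int boundary = (std::abs(bdy) == max_shift || std::abs(bdx) == max_shift)
        ? 1 : 0;
    return NumericVector::create(bdy, bdx, best, boundary);
}

// Per-slice (2D, dims 1-2) separable Gaussian blur with symmetric
// (reflective) boundary handling.
// [[Rcpp::export]]
NumericVector cpp_blur_slices(NumericVector grid, IntegerVector dim,
                              double sigma) {
    Grid g(dim);
    NumericVector out = clone(grid);
    if (sigma <= 0) return out;
    int h = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> w(2 * h + 1);
    double tot = 0;
    for (int t = -h; t <= h; ++t) {
        w[t + h] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
        tot += w[t + h];
    }
    for (size_t t = 0; t < w.size(); ++t) w[t] /= tot;

    std::vector<double> buf(std::max(g.d1, g.d2));
    for (int k = 0; k < g.d3; ++k) {
        size_t off = (size_t)g.d1 * g.d2 * k;
        // along dim 1 (columns of each slice)
        for (int j = 0; j < g.d2; ++j) {
            size_t base = off + (size_t)g.d1 * j;
            for (int i = 0; i < g.d1; ++i) buf[i] = out[base + i];
            for (int i = 0; i < g.d1; ++i) {
                double acc = 0;
                for (int t = -h; t <= h; ++t) {
                    int p = i + t;
                    while (p < 0 || p >= g.d1) {
                        if (p < 0) p = -p - 1;
                        if (p >= g.d1) p = 2 * g.d1 - 1 - p;
                    }
                    acc += w[t + h] * buf[p];
                }
                out[base + i] = acc;
            }
        }
        // along dim 2 (rows)
        for (int i = 0; i < g.d1; ++i) {
            for (int j = 0; j < g.d2; ++j)
                buf[j] = out[off + (size_t)g.d1 * j + i];
            for (int j = 0; j < g.d2; ++j) {
                double acc = 0;
                for (int t = -h; t <= h; ++t) {
                    int p = j + t;
                    while (p < 0 || p >= g.d2) {
                        if (p < 0) p = -p - 1;
                        if (p >= g.d2) p = 2 * g.d2 - 1 - p;
                    }
                    acc += w[t + h] * buf[p];
                }
                out[off + (size_t)g.d1 * j + i] = acc;
            }
        }
    }
    return out;
}

// Counts of 26-adjacent voxel pairs carrying two different nonzero labels.
// [[Rcpp::export]]
DataFrame cpp_label_adjacency(IntegerVector labels, IntegerVector dim) {
    Grid g(dim);
    std::vector<int> di, dj, dk;
    neighbour_offsets(26, di, dj, dk);
    // forward half of the neighbourhood so each pair is visited once
    std::vector<int> fdi, fdj, fdk;
    for (size_t t = 0; t < di.size(); ++t) {
        int a = di[t], b = dj[t], c = dk[t];
        if (c > 0 || (c == 0 && (b > 0 || (b == 0 && a > 0)))) {
            fdi.push_back(a); fdj.push_back(b); fdk.push_back(c);
        }
    }
    std::map<std::pair<int, int>, int> counts;
    for (int k = 0; k < g.d3; ++k)
        for (int j = 0; j < g.d2; ++j)
            for (int i = 0; i < g.d1; ++i) {
                int la = labels[g.idx(i, j, k)];
                if (la == 0) continue;
                for (size_t t = 0; t < fdi.size(); ++t) {
                    int ii = i + fdi[t], jj = j + fdj[t], kk = k + fdk[t];
                    if (ii < 0 || jj < 0 || kk < 0 ||
                        ii >= g.d1 || jj >= g.d2 || kk >= g.d3) continue;
                    int lb = labels[g.idx(ii, jj, kk)];
                    if (lb == 0 || lb == la) continue;
                    std::pair<int, int> key(std::min(la, lb),
                                            std::max(la, lb));
                    counts[key] += 1;
                }
            }
    int m = (int)counts.size();
    IntegerVector a(m), b(m), cnt(m);
    int r = 0;
    for (std::map<std::pair<int, int>, int>::const_iterator it =
             counts.begin(); it != counts.end(); ++it, ++r) {
        a[r] = it->first.first;
        b[r] = it->first.second;
        cnt[r] = it->second;
    }
    return DataFrame::create(_["a"] = a, _["b"] = b, _["n_contact"] = cnt);
}

namespace {

struct V3 {
    double x, y, z;
    V3() : x(0), y(0), z(0) {}
    V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
inline V3 sub(const V3 &a, const V3 &b) {
    return V3(a.x - b.x, a.y - b.y, a.z - b.z);
}
inline V3 cross(const V3 &a, const V3 &b) {
    return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
inline double dot(const V3 &a, const V3 &b) {
    return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline V3 lerp(const V3 &a, const V3 &b, double va, double vb, double iso) {
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    return V3(a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
              a.z + t * (b.z - a.z));
}

struct MeshAcc {
    double area, vol;
    MeshAcc() : area(0), vol(0) {}
    // triangle oriented away from `ref` (an interior reference point)
    void add(V3 p0, V3 p1, V3 p2, const V3 &ref) {
        V3 n = cross(sub(p1, p0), sub(p2, p0));
        V3 c((p0.x + p1.x + p2.x) / 3.0 - ref.x,
             (p0.y + p1.y + p2.y) / 3.0 - ref.y,
             (p0.z + p1.z + p2.z) / 3.0 - ref.z);
        if (dot(n, c) < 0) {
            V3 tmp = p1; p1 = p2; p2 = tmp;
            n = cross(sub(p1, p0), sub(p2, p0));
        }
        area += 0.5 * std::sqrt(dot(n, n));
        vol += dot(p0, cross(p1, p2)) / 6.0;
    }
};

} // namespace

// Iso-surface area (nm^2) and enclosed volume (nm^3) of `field > iso`
// extracted by marching tetrahedra on the Kuhn (Freudenthal) decomposition
// of each grid cell.  Field values live at voxel centres (i * spacing).
// [[Rcpp::export]]
NumericVector cpp_march_tets(NumericVector field, IntegerVector dim,
                             NumericVector spacing, double iso) {
    Grid g(dim);
    // cube corner offsets, bit 0 -> dim1, bit 1 -> dim2, bit 2 -> dim3
    static const int co[8][3] = {
        {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
        {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}
    };
    static const int tets[6][4] = {
        {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
        {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
    };
    MeshAcc acc;
    double val[8];
    V3 pos[8];
    for (int k = 0; k + 1 < g.d3; ++k)
        for (int j = 0; j + 1 < g.d2; ++j)
            for (int i = 0; i + 1 < g.d1; ++i) {
                bool any_in = false, any_out = false;
                for (int c = 0; c < 8; ++c) {
                    int ii = i + co[c][0], jj = j + co[c][1],
                        kk = k + co[c][2];
                    val[c] = field[g.idx(ii, jj, kk)];
                    pos[c] = V3(ii * spacing[0], jj * spacing[1],
                                kk * spacing[2]);
                    if (val[c] > iso) any_in = true; else any_out = true;
                }
                if (!any_in || !any_out) continue;
                for (int t = 0; t < 6; ++t) {
                    int vi[4] = {tets[t][0], tets[t][1], tets[t][2],
                                 tets[t][3]};
                    int ins[4], outs[4], ni = 0, no = 0;
                    for (int c = 0; c < 4; ++c) {
                        if (val[vi[c]] > iso) ins[ni++] = vi[c];
                        else outs[no++] = vi[c];
                    }
                    if (ni == 0 || ni == 4) continue;
                    if (ni == 1) {
                        int A = ins[0];
                        V3 p0 = lerp(pos[A], pos[outs[0]], val[A],
                                     val[outs[0]], iso);
                        V3 p1 = lerp(pos[A], pos[outs[1]], val[A],
                                     val[outs[1]], iso);
                        V3 p2 = lerp(pos[A], pos[outs[2]], val[A],
                                     val[outs[2]], iso);
                        acc.add(p0, p1, p2, pos[A]);
                    } else if (ni == 3) {
                        int D = outs[0];
                        V3 ref((pos[ins[0]].x + pos[ins[1]].x +
                                pos[ins[2]].x) / 3.0,
                               (pos[ins[0]].y + pos[ins[1]].y +
                                pos[ins[2]].y) / 3.0,
                               (pos[ins[0]].z + pos[ins[1]].z +
                                pos[ins[2]].z) / 3.0);
                        V3 p0 = lerp(pos[ins[0]], pos[D], val[ins[0]],
                                     val[D], iso);
                        V3 p1 = lerp(pos[ins[1]], pos[D], val[ins[1]],
                                     val[D], iso);
                        V3 p2 = lerp(pos[ins[2]], pos[D], val[ins[2]],
                                     val[D], iso);
                        acc.add(p0, p1, p2, ref);
                    } else { // 2 in, 2 out
                        int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
                        V3 ref((pos[A].x + pos[B].x) / 2.0,
                               (pos[A].y + pos[B].y) / 2.0,
                               (pos[A].z + pos[B].z) / 2.0);
                        V3 pAC = lerp(pos[A], pos[C], val[A], val[C], iso);
                        V3 pAD = lerp(pos[A], pos[D], val[A], val[D], iso);
                        V3 pBD = lerp(pos[B], pos[D], val[B], val[D], iso);
                        V3 pBC = lerp(pos[B], pos[C], val[B], val[C], iso);
                        acc.add(pAC, pAD, pBD, ref);
                        acc.add(pAC, pBD, pBC, ref);
                    }
                }
            }
    return NumericVector::create(acc.area, acc.vol);
}

// Separable 3D Gaussian smoothing with sigma in voxels per axis and
// symmetric (reflective) boundaries; used to band-limit binary indicator
// fields before iso-surface extraction.
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector grid, IntegerVector dim,
                           double sigma) {
    Grid g(dim);
    NumericVector out = clone(grid);
    if (sigma <= 0) return out;
    int h = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> w(2 * h + 1);
    double tot = 0;
    for (int t = -h; t <= h; ++t) {
        w[t + h] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
        tot += w[t + h];
    }
    for (size_t t = 0; t < w.size(); ++t) w[t] /= tot;

    const int dims[3] = {g.d1, g.d2, g.d3};
    for (int ax = 0; ax < 3; ++ax) {
        int n = dims[ax];
        long stride = (ax == 0) ? 1 : (ax == 1 ? g.d1 : (long)g.d1 * g.d2);
        int n_other1 = (ax == 0) ? g.d2 : g.d1;
        int n_other2 = (ax == 2) ? g.d2 : g.d3;
        long stride1 = (ax == 0) ? g.d1 : 1;
        long stride2 = (ax == 2) ? g.d1 : (long)g.d1 * g.d2;
        std::vector<double> buf(n);
        for (int b = 0; b < n_other2; ++b)
            for (int a = 0; a < n_other1; ++a) {
                long base = a * stride1 + b * stride2;
                for (int i = 0; i < n; ++i) buf[i] = out[base + i * stride];
                for (int i = 0; i < n; ++i) {
                    double acc = 0;
                    for (int t = -h; t <= h; ++t) {
                        int p = i + t;
                        while (p < 0 || p >= n) {
                            if (p < 0) p = -p - 1;
                            if (p >= n) p = 2 * n - 1 - p;
                        }
                        acc += w[t + h] * buf[p];
                    }
                    out[base + i * stride] = acc;
                }
            }
    }
    return out;
}
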