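#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Large finite stand-in for "no feature yet": keeps the parabola algebra
// finite while dominating any real squared distance on these grids.
static const double QA_FAR = 1e15;

// 1-D squared-distance transform of Felzenszwalb & Huttenlocher along one
// line, with physical sample spacing s (mm).  f holds squared distances on
// input and is overwritten with min_p ((q-p)^2 s^2 + f[p]).
static void dt1d(std::vector<double>& f, double s, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
    const int n = (int)f.size();
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    const double s2 = s * s;
    for (int q = 1; q < n; ++q) {
        double sq;
        while (true) {
            double num = (f[q] - f[v[k]]) / s2 + (double)q * q - (double)v[k] * v[k];
            sq = num / (2.0 * (q - v[k]));
            if (sq <= z[k] && k > 0) { --k; } else break;
        }
        if (sq <= z[k]) {           // new parabola dominates the whole line
            k = 0;
            v[0] = q;
            z[0] = -INF;
            z[1] = INF;
            continue;
        }
        ++k;
        v[k] = q;
        z[k] = sq;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        double dq = (double)(q - v[k]) * s;
        d[q] = dq * dq + f[v[k]];
    }
    for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact squared Euclidean distance (mm^2) from every voxel to the nearest
// TRUE voxel of `inside`, on an axis-aligned grid with per-axis spacing.
// Returns +Inf everywhere when `inside` is empty.
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector inside, IntegerVector dim,
                              NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = inside[i] ? 0.0 : QA_FAR;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along X
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
            f.assign(out.begin() + base, out.begin() + base + nx);
            dt1d(f, spacing[0], d, v, z);
            for (int i = 0; i < nx; ++i) out[base + i] = f[i];
        }
    // pass along Y
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + i;
            f.resize(ny);
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
            dt1d(f, spacing[1], d, v, z);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = f[j];
        }
    // pass along Z
    const R_xlen_t sz = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)j * nx + i;
            f.resize(nz);
            for (int k = 0; k < nz; ++k) f[k] = out[base + k * sz];
            dt1d(f, spacing[2], d, v, z);
            for (int k = 0; k < nz; ++k) out[base + k * sz] = f[k];
        }
    return out;
}

// Separable Gaussian smoothing with per-axis sigma in voxel units.
// Truncated kernel (radius 3 sigma), renormalized at the boundaries so the
// filter preserves constants everywhere.
// [[Rcpp::export]]
NumericVector gaussian_smooth3_cpp(NumericVector arr, IntegerVector dim,
                                   NumericVector sigma_vox) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector cur = clone(arr);
    NumericVector nxt(n);
    const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
    const int len[3] = {nx, ny, nz};

    for (int ax = 0; ax < 3; ++ax) {
        double sg = sigma_vox[ax];
        if (sg <= 0) continue;
        int r = (int)std::ceil(3.0 * sg);
        std::vector<double> ker(2 * r + 1);
        for (int t = -r; t <= r; ++t)
            ker[t + r] = std::exp(-0.5 * (double)t * t / (sg * sg));
        const int na = len[ax];
        const R_xlen_t st = stride[ax];
        // iterate over all lines along axis ax
        const int nb = len[(ax + 1) % 3], nc = len[(ax + 2) % 3];
        const R_xlen_t stb = stride[(ax + 1) % 3], stc = stride[(ax + 2) % 3];
        for (int c = 0; c < nc; ++c)
            for (int b = 0; b < nb; ++b) {
                R_xlen_t base = (R_xlen_t)b * stb + (R_xlen_t)c * stc;
                for (int q = 0; q < na; ++q) {
                    double acc = 0.0, wsum = 0.0;
                    int lo = std::max(-r, -q), hi = std::min(r, na - 1 - q);
                    for (int t = lo; t <= hi; ++t) {
                        double w = ker[t + r];
                        acc += w * cur[base + (R_xlen_t)(q + t) * st];
                        wsum += w;
                    }
                    nxt[base + (R_xlen_t)q * st] = acc / wsum;
                }
            }
        std::swap(cur, nxt);
    }
    return cur;
}
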