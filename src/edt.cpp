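#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact squared Euclidean distance transform along one sampled line
// (Felzenszwalb & Huttenlocher lower-envelope algorithm, generalised to a
// physical sample spacing s so anisotropic grids are handled exactly).
// f holds squared distances on input; overwritten with the transform.
static void dt1d(std::vector<double>& f, double s, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
    const int n = static_cast<int>(f.size());
    const double s2 = s * s;
    int k = 0;
    v[0] = 0;
    z[0] = -std::numeric_limits<double>::infinity();
    z[1] = std::numeric_limits<double>::infinity();
    for (int q = 1; q < n; ++q) {
        double sq;
        while (true) {
            const int p = v[k];
            sq = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
                 (2.0 * s2 * (q - p));
            if (sq <= z[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = sq;
        z[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < static_cast<double>(q)) ++k;
        const double dq = s * (q - v[k]);
        d[q] = dq * dq + f[v[k]];
    }
    for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Distance (mm) from every voxel centre to the nearest voxel centre of the
// mask. Zero inside the mask. `mask` is a logical 3D array, `spacing` the
// per-axis voxel size in mm. Background is seeded with a large finite value
// rather than infinity so the envelope intersections stay well defined.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, NumericVector spacing) {
    IntegerVector dims = mask.attr("dim");
    if (dims.size() != 3) stop("mask must be a 3D array");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    if (spacing.size() != 3) stop("spacing must have length 3");
    const double BIG = 1e20;

    NumericVector out(mask.size());
    out.attr("dim") = dims;
    for (R_xlen_t i = 0; i < mask.size(); ++i)
        out[i] = (mask[i] == TRUE) ? 0.0 : BIG;

    const int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (fastest-varying index)
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            const R_xlen_t base = static_cast<R_xlen_t>(k) * nx * ny +
                                  static_cast<R_xlen_t>(j) * nx;
            f.assign(out.begin() + base, out.begin() + base + nx);
            f.resize(nx);
            dt1d(f, spacing[0], d, v, z);
            for (int i = 0; i < nx; ++i) out[base + i] = f[i];
        }
    // pass along y
    f.resize(ny);
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            const R_xlen_t base = static_cast<R_xlen_t>(k) * nx * ny + i;
            for (int j = 0; j < ny; ++j) f[j] = out[base + static_cast<R_xlen_t>(j) * nx];
            dt1d(f, spacing[1], d, v, z);
            for (int j = 0; j < ny; ++j) out[base + static_cast<R_xlen_t>(j) * nx] = f[j];
        }
    // pass along z
    f.resize(nz);
    const R_xlen_t slab = static_cast<R_xlen_t>(nx) * ny;
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            const R_xlen_t base = static_cast<R_xlen_t>(j) * nx + i;
            for (int k = 0; k < nz; ++k) f[k] = out[base + static_cast<R_xlen_t>(k) * slab];
            dt1d(f, spacing[2], d, v, z);
            for (int k = 0; k < nz; ++k) out[base + static_cast<R_xlen_t>(k) * slab] = f[k];
        }

    for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = std::sqrt(out[i]);
    return out;
}

// Maximum pairwise Euclidean distance between points given as an n x 3
// matrix of physical coordinates (mm). O(n^2); callers pass surface voxels.
// [[Rcpp::export(name = ".maxPairDist")]]
double maxPairDist(NumericMatrix pts) {
    const int n = pts.nrow();
    double best = 0.0;
    for (int i = 0; i < n; ++i) {
        const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
        for (int j = i + 1; j < n; ++j) {
            const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi,
                         dz = pts(j, 2) - zi;
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 > best) best = d2;
        }
    }
    return std::sqrt(best);
}
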