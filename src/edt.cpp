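#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Separable squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// Theory of Computing 2012), generalised to anisotropic voxel spacing.
// Distances are between voxel centres, in the physical units of `spacing`.

static const double EDT_INF = 1e30;

// 1-D lower-envelope pass over a line of squared distances f, grid step w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double w) {
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        double xq = q * w;
        double s = 0.0;
        while (true) {
            double xv = v[k] * w;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
            if (s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * w;
        while (z[k + 1] < xq) ++k;
        double dx = xq - v[k] * w;
        d[q] = dx * dx + f[v[k]];
    }
}

// Squared EDT of a 3-D logical mask: for every voxel, squared distance (mm^2)
// to the nearest TRUE voxel. Voxels of the mask itself get 0.
// [[Rcpp::export(name = ".edt_squared_cpp")]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dim,
                              NumericVector spacing) {
    if (dim.size() != 3 || spacing.size() != 3)
        stop("dim and spacing must have length 3");
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
    if (mask.size() != ntot) stop("mask length does not match dim");

    NumericVector out(ntot);
    for (R_xlen_t i = 0; i < ntot; ++i)
        out[i] = (mask[i] == TRUE) ? 0.0 : EDT_INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (fastest-varying index)
    for (int kz = 0; kz < nz; ++kz)
        for (int jy = 0; jy < ny; ++jy) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)jy * nx;
            for (int i = 0; i < nx; ++i) f[i] = out[base + i];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    // pass along y
    for (int kz = 0; kz < nz; ++kz)
        for (int ix = 0; ix < nx; ++ix) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + ix;
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
        }
    // pass along z
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int jy = 0; jy < ny; ++jy)
        for (int ix = 0; ix < nx; ++ix) {
            R_xlen_t base = (R_xlen_t)jy * nx + ix;
            for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = d[k];
        }

    out.attr("dim") = dim;
    return out;
}
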