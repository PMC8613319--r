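#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample of img at fractional (row, col), 0-based; zero outside.
static inline double sample_bilinear(const NumericMatrix& img, double row, double col) {
    const int n = img.nrow(), m = img.ncol();
    const int r0 = (int)std::floor(row), c0 = (int)std::floor(col);
    if (r0 < -1 || r0 >= n || c0 < -1 || c0 >= m) return 0.0;
    const double fr = row - r0, fc = col - c0;
    const int r1 = r0 + 1, c1 = c0 + 1;
    double v00 = 0.0, v01 = 0.0, v10 = 0.0, v11 = 0.0;
    if (r0 >= 0 && c0 >= 0) v00 = img(r0, c0);
    if (r0 >= 0 && c1 < m)  v01 = img(r0, c1);
    if (r1 < n && c0 >= 0)  v10 = img(r1, c0);
    if (r1 < n && c1 < m)   v11 = img(r1, c1);
    return (1.0 - fr) * ((1.0 - fc) * v00 + fc * v01) +
           fr         * ((1.0 - fc) * v10 + fc * v11);
}

// Parallel-beam forward projection (line integrals, units value * mm).
// img: n x n, pixel spacing dx mm, centred on the origin; row index grows
// downward (y decreases), column index grows with x. Detector bins share the
// pixel pitch unless dbin is given. Integration step: `step` mm.
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(const NumericMatrix& img,
                                  const NumericVector& angles,
                                  const int nbins, const double dx,
                                  const double dbin, const double step) {
    const int n = img.nrow();
    const int nang = angles.size();
    NumericMatrix sino(nang, nbins);
    const double half = (n - 1) / 2.0;
    const double shalf = (nbins - 1) / 2.0;
    const double tmax = 0.75 * n * dx;  // covers the grid diagonal
    const int nstep = (int)std::ceil(2.0 * tmax / step);
    for (int a = 0; a < nang; ++a) {
        const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
        for (int b = 0; b < nbins; ++b) {
            const double s = (b - shalf) * dbin;
            // ray: (x, y) = s * (ct, st) + t * (-st, ct)
            double acc = 0.0;
            for (int k = 0; k < nstep; ++k) {
                const double t = -tmax + (k + 0.5) * step;
                const double px = s * ct - t * st;
                const double py = s * st + t * ct;
                const double col = px / dx + half;
                const double row = half - py / dx;
                acc += sample_bilinear(img, row, col);
            }
            sino(a, b) = acc * step;
        }
    }
    return sino;
}

// Forward projection of two images sharing the ray geometry (one traversal):
// returns line integrals of both, as list(first, second).
// [[Rcpp::export]]
List cpp_forward_project_pair(const NumericMatrix& imgA,
                              const NumericMatrix& imgB,
                              const NumericVector& angles,
                              const int nbins, const double dx,
                              const double dbin, const double step) {
    const int n = imgA.nrow();
    const int nang = angles.size();
    NumericMatrix sinoA(nang, nbins), sinoB(nang, nbins);
    const double half = (n - 1) / 2.0;
    const double shalf = (nbins - 1) / 2.0;
    const double tmax = 0.75 * n * dx;
    const int nstep = (int)std::ceil(2.0 * tmax / step);
    for (int a = 0; a < nang; ++a) {
        const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
        for (int b = 0; b < nbins; ++b) {
            const double s = (b - shalf) * dbin;
            double accA = 0.0, accB = 0.0;
            for (int k = 0; k < nstep; ++k) {
                const double t = -tmax + (k + 0.5) * step;
                const double px = s * ct - t * st;
                const double py = s * st + t * ct;
                const double col = px / dx + half;
                const double row = half - py / dx;
                accA += sample_bilinear(imgA, row, col);
                accB += sample_bilinear(imgB, row, col);
            }
            sinoA(a, b) = accA * step;
            sinoB(a, b) = accB * step;
        }
    }
    return List::create(Named("first") = sinoA, Named("second") = sinoB);
}

// Pixel-driven backprojection of a filtered sinogram onto an n x n grid with
// spacing dx; linear interpolation between detector bins. The pi/nangles
// normalisation is applied by the caller.
// [[Rcpp::export]]
NumericMatrix cpp_back_project(const NumericMatrix& qsino,
                               const NumericVector& angles,
                               const int n, const double dx,
                               const double dbin) {
    const int nang = angles.size();
    const int nbins = qsino.ncol();
    NumericMatrix out(n, n);
    const double half = (n - 1) / 2.0;
    const double shalf = (nbins - 1) / 2.0;
    for (int a = 0; a < nang; ++a) {
        const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
        for (int i = 0; i < n; ++i) {
            const double y = (half - i) * dx;
            const double yst = y * st;
            for (int j = 0; j < n; ++j) {
                const double x = (j - half) * dx;
                const double s = x * ct + yst;
                const double bin = s / dbin + shalf;
                const int b0 = (int)std::floor(bin);
                if (b0 < -1 || b0 >= nbins) continue;
                const double fb = bin - b0;
                double v = 0.0;
                if (b0 >= 0) v += (1.0 - fb) * qsino(a, b0);
                if (b0 + 1 < nbins) v += fb * qsino(a, b0 + 1);
                out(i, j) += v;
            }
        }
    }
    return out;
}
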