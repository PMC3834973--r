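#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of img at fractional (row, col), zero outside the grid.
static inline double sample_bilinear(const NumericMatrix &img, double r, double c) {
    const int nr = img.nrow(), nc = img.ncol();
    if (r <= -1.0 || c <= -1.0 || r >= nr || c >= nc) return 0.0;
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    double fr = r - r0, fc = c - c0;
    double v00 = 0.0, v01 = 0.0, v10 = 0.0, v11 = 0.0;
    bool r0in = (r0 >= 0 && r0 < nr), r1in = (r0 + 1 >= 0 && r0 + 1 < nr);
    bool c0in = (c0 >= 0 && c0 < nc), c1in = (c0 + 1 >= 0 && c0 + 1 < nc);
    if (r0in && c0in) v00 = img(r0, c0);
    if (r0in && c1in) v01 = img(r0, c0 + 1);
    if (r1in && c0in) v10 = img(r0 + 1, c0);
    if (r1in && c1in) v11 = img(r0 + 1, c0 + 1);
    return (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
}

// Parallel-beam forward projection (discrete Radon transform).
// Rays for view angle theta run along direction (-sin t, cos t) in physical
// (x, y) coordinates with x to the right, y up, origin at the image center;
// detector offsets s_b = (b - (n_bins-1)/2) * bin_spacing along (cos t, sin t).
// Line integrals are accumulated by sampling the image bilinearly at steps of
// `step` (physical units) and multiplying by the step length.
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, NumericVector angles_rad,
                                  int n_bins, double bin_spacing,
                                  double pixel_spacing, double step) {
    const int nr = img.nrow(), nc = img.ncol(), na = angles_rad.size();
    NumericMatrix out(na, n_bins);
    const double cr0 = (nr - 1) / 2.0, cc0 = (nc - 1) / 2.0;
    const double half_diag = 0.5 * pixel_spacing * std::sqrt((double)nr * nr + (double)nc * nc);
    const double T = half_diag + bin_spacing;
    const int n_steps = (int)std::ceil(2.0 * T / step);
    const double s_mid = (n_bins - 1) / 2.0;
    for (int a = 0; a < na; ++a) {
        const double ca = std::cos(angles_rad[a]), sa = std::sin(angles_rad[a]);
        for (int b = 0; b < n_bins; ++b) {
            const double s = (b - s_mid) * bin_spacing;
            // start point at t = -T
            double x = s * ca + T * sa;
            double y = s * sa - T * ca;
            const double dx = -sa * step, dy = ca * step;
            double acc = 0.0;
            for (int k = 0; k <= n_steps; ++k) {
                const double col = x / pixel_spacing + cc0;
                const double row = cr0 - y / pixel_spacing;
                acc += sample_bilinear(img, row, col);
                x += dx; y += dy;
            }
            out(a, b) = acc * step;
        }
    }
    return out;
}

// Back-projection of (already filtered) projections onto an image grid.
// For each pixel, each view contributes the linearly interpolated filtered
// projection value at detector offset s = x cos t + y sin t; the caller
// applies the pi / n_angles view weighting.
// [[Rcpp::export]]
NumericMatrix cpp_back_project(NumericMatrix filtered, NumericVector angles_rad,
                               int out_rows, int out_cols, double bin_spacing,
                               double pixel_spacing) {
    const int na = angles_rad.size(), nb = filtered.ncol();
    NumericMatrix out(out_rows, out_cols);
    const double cr0 = (out_rows - 1) / 2.0, cc0 = (out_cols - 1) / 2.0;
    const double s_mid = (nb - 1) / 2.0;
    std::vector<double> cs(na), sn(na);
    for (int a = 0; a < na; ++a) { cs[a] = std::cos(angles_rad[a]); sn[a] = std::sin(angles_rad[a]); }
    for (int r = 0; r < out_rows; ++r) {
        const double y = (cr0 - r) * pixel_spacing;
        for (int c = 0; c < out_cols; ++c) {
            const double x = (c - cc0) * pixel_spacing;
            double acc = 0.0;
            for (int a = 0; a < na; ++a) {
                const double s = x * cs[a] + y * sn[a];
                const double u = s / bin_spacing + s_mid;
                if (u <= -1.0 || u >= nb) continue;
                int u0 = (int)std::floor(u);
                const double fu = u - u0;
                double v0 = (u0 >= 0 && u0 < nb) ? filtered(a, u0) : 0.0;
                double v1 = (u0 + 1 >= 0 && u0 + 1 < nb) ? filtered(a, u0 + 1) : 0.0;
                acc += (1 - fu) * v0 + fu * v1;
            }
            out(r, c) = acc;
        }
    }
    return out;
}
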