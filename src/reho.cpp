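#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Average ranks (midranks) of x, written into r. Ties get the mean rank.
static void midranks(const double* x, int n, double* r, double* tiesum) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return x[a] < x[b]; });
    double ts = 0.0;
    int i = 0;
    while (i < n) {
        int j = i;
        while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
        double avg = 0.5 * (i + j) + 1.0;
        int t = j - i + 1;
        if (t > 1) ts += (double)t * t * t - t;
        for (int k = i; k <= j; ++k) r[idx[k]] = avg;
        i = j + 1;
    }
    *tiesum = ts;
}

// Kendall's W over the 3x3x3 neighbourhood of every in-mask voxel.
// vol: nx*ny*nz*T array (voxel-fastest); mask: nx*ny*nz logical.
// Neighbourhoods are clipped to the mask; K (number of member series) is
// per-voxel. Voxels with K < 2 get W = 0. With tie_correction the
// denominator subtracts K * sum_j T_j where T_j = sum(t^3 - t) over tie
// groups of series j.
// [[Rcpp::export(name = ".reho_core")]]
NumericVector reho_core(NumericVector vol, IntegerVector dims,
                        LogicalVector mask, bool tie_correction) {
    const int nx = dims[0], ny = dims[1], nz = dims[2], T = dims[3];
    const R_xlen_t V = (R_xlen_t)nx * ny * nz;
    if ((R_xlen_t)vol.size() != V * T) stop("volume size mismatch");
    if ((R_xlen_t)mask.size() != V) stop("mask size mismatch");

    // rank every in-mask voxel's time series once
    std::vector<double> ranks(V * (R_xlen_t)T, 0.0);
    std::vector<double> tiesums(V, 0.0);
    std::vector<double> series(T);
    for (R_xlen_t v = 0; v < V; ++v) {
        if (!mask[v]) continue;
        for (int t = 0; t < T; ++t) series[t] = vol[v + V * t];
        std::vector<double> r(T);
        double ts;
        midranks(series.data(), T, r.data(), &ts);
        for (int t = 0; t < T; ++t) ranks[v + V * t] = r[t];
        tiesums[v] = ts;
    }

    NumericVector W(V);
    std::vector<double> Rsum(T);
    const double Tn = (double)T;
    for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) {
            for (int x = 0; x < nx; ++x) {
                R_xlen_t v = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
                if (!mask[v]) { W[v] = 0.0; continue; }
                std::fill(Rsum.begin(), Rsum.end(), 0.0);
                int K = 0;
                double tie_total = 0.0;
                for (int dz = -1; dz <= 1; ++dz) {
                    int zz = z + dz;
                    if (zz < 0 || zz >= nz) continue;
                    for (int dy = -1; dy <= 1; ++dy) {
                        int yy = y + dy;
                        if (yy < 0 || yy >= ny) continue;
                        for (int dx = -1; dx <= 1; ++dx) {
                            int xx = x + dx;
                            if (xx < 0 || xx >= nx) continue;
                            R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                            if (!mask[u]) continue;
                            ++K;
                            tie_total += tiesums[u];
                            for (int t = 0; t < T; ++t)
                                Rsum[t] += ranks[u + V * t];
                        }
                    }
                }
                if (K < 2) { W[v] = 0.0; continue; }
                const double rbar = K * (Tn + 1.0) / 2.0;
                double S = 0.0;
                for (int t = 0; t < T; ++t) {
                    double d = Rsum[t] - rbar;
                    S += d * d;
                }
                double denom = (double)K * K * (Tn * Tn * Tn - Tn);
                if (tie_correction) denom -= (double)K * tie_total;
                W[v] = denom > 0.0 ? 12.0 * S / denom : 0.0;
            }
        }
    }
    return W;
}

// Connected components of a 3D logical array under 6/18/26 connectivity.
// Returns an integer label array (0 = background), labels 1..n_components.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t V = (R_xlen_t)nx * ny * nz;
    if ((R_xlen_t)mask.size() != V) stop("mask size mismatch");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");

    std::vector<int> ox, oy, oz;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int nzr = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (nzr == 0) continue;
                if (connectivity == 6 && nzr > 1) continue;
                if (connectivity == 18 && nzr > 2) continue;
                ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
            }

    IntegerVector lab(V, 0);
    std::vector<R_xlen_t> stack;
    int cur = 0;
    for (R_xlen_t s = 0; s < V; ++s) {
        if (!mask[s] || lab[s]) continue;
        ++cur;
        lab[s] = cur;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t v = stack.back();
            stack.pop_back();
            int x = (int)(v % nx);
            int y = (int)((v / nx) % ny);
            int z = (int)(v / ((R_xlen_t)nx * ny));
            for (size_t k = 0; k < ox.size(); ++k) {
                int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz) continue;
                R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                if (mask[u] && !lab[u]) { lab[u] = cur; stack.push_back(u); }
            }
        }
    }
    return lab;
}
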