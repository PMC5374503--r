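#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Median of v[lo, hi) by partial selection; reorders that range in place.
// Even-sized ranges average the two central order statistics.
static double median_range(std::vector<double> &v, int lo, int hi) {
    const int n = hi - lo;
    const int m = lo + (n - 1) / 2;
    std::nth_element(v.begin() + lo, v.begin() + m, v.begin() + hi);
    double med = v[m];
    if (n % 2 == 0) {
        double hi_min = *std::min_element(v.begin() + m + 1, v.begin() + hi);
        med = 0.5 * (med + hi_min);
    }
    return med;
}

// Uniform in-place shuffle driven by R's RNG, so results are reproducible
// under set.seed() and independent of the platform.
static void shuffle_r(std::vector<double> &v) {
    const int n = (int)v.size();
    for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(v[i], v[j]);
    }
}

//' @noRd
// [[Rcpp::export]]
List cpp_perm_abm(NumericVector values, LogicalVector in_a, int n_perm,
                  bool tie_ge, bool add_one) {
    const int n = values.size();
    if (in_a.size() != n) stop("values and in_a must have equal length");
    std::vector<double> v;
    v.reserve(n);
    int n_a = 0;
    // group A values first so the observed split matches the permuted layout
    for (int i = 0; i < n; ++i) if (in_a[i]) { v.push_back(values[i]); ++n_a; }
    for (int i = 0; i < n; ++i) if (!in_a[i]) v.push_back(values[i]);
    const int n_b = n - n_a;
    if (n_a == 0 || n_b == 0) stop("both groups must be non-empty");

    std::vector<double> w(v);
    const double med_a = median_range(w, 0, n_a);
    const double med_b = median_range(w, n_a, n);
    const double abm_obs = std::fabs(med_a - med_b);

    long long n_exceed = 0;
    for (int p = 0; p < n_perm; ++p) {
        shuffle_r(v);
        const double ma = median_range(v, 0, n_a);
        const double mb = median_range(v, n_a, n);
        const double abm = std::fabs(ma - mb);
        const bool exceed = tie_ge ? (abm >= abm_obs) : (abm > abm_obs);
        if (exceed) ++n_exceed;
    }
    const double s = add_one ? 1.0 : 0.0;
    const double pval = ((double)n_exceed + s) / ((double)n_perm + s);
    return List::create(_["p"] = pval, _["abm_obs"] = abm_obs,
                        _["n_exceed"] = (double)n_exceed);
}

//' @noRd
// [[Rcpp::export]]
List cpp_perm_srcc(NumericVector rx, NumericVector ry, int n_perm,
                   bool tie_ge, bool add_one) {
    const int n = rx.size();
    if (ry.size() != n) stop("rx and ry must have equal length");
    std::vector<double> x(rx.begin(), rx.end());
    std::vector<double> y(ry.begin(), ry.end());
    double mx = 0, my = 0;
    for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
    mx /= n; my /= n;
    double sxx = 0, syy = 0;
    for (int i = 0; i < n; ++i) {
        x[i] -= mx; y[i] -= my;
        sxx += x[i] * x[i];
        syy += y[i] * y[i];
    }
    if (sxx <= 0 || syy <= 0) stop("constant ranks: correlation undefined");
    const double denom = std::sqrt(sxx * syy);
    double sxy = 0;
    for (int i = 0; i < n; ++i) sxy += x[i] * y[i];
    const double r_obs = sxy / denom;
    const double a_obs = std::fabs(r_obs);

    long long n_exceed = 0;
    for (int p = 0; p < n_perm; ++p) {
        shuffle_r(y);
        double s = 0;
        for (int i = 0; i < n; ++i) s += x[i] * y[i];
        const double a = std::fabs(s / denom);
        const bool exceed = tie_ge ? (a >= a_obs) : (a > a_obs);
        if (exceed) ++n_exceed;
    }
    const double add = add_one ? 1.0 : 0.0;
    const double pval = ((double)n_exceed + add) / ((double)n_perm + add);
    return List::create(_["p"] = pval, _["rho_obs"] = r_obs,
                        _["n_exceed"] = (double)n_exceed);
}
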