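#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <stack>
#include <algorithm>

using namespace Rcpp;

// Maximum circular-arc statistic for a segment.
// Arcs are (i, j] with min_width <= j - i <= n - min_width; the statistic is
// the absolute standardized difference between the arc mean and the mean of
// its complement, up to the segment sd (constant across arcs and
// permutations, so it is factored out and applied by the caller).
// Returns the unscaled max and writes the arg-max arc to (bi, bj).
static double scan_max_arc(const std::vector<double> &S, int n, int min_width,
                           int *bi, int *bj, double stop_at) {
    const double T = S[n];
    double best = -1.0;
    *bi = 0; *bj = n;
    int kmin = std::max(1, min_width);
    int kmax = std::min(n - 1, n - min_width);
    for (int k = kmin; k <= kmax; ++k) {
        const double invk = 1.0 / k, invnk = 1.0 / (n - k);
        const double w = 1.0 / std::sqrt(invk + invnk);
        for (int i = 0; i + k <= n; ++i) {
            const double arc = S[i + k] - S[i];
            const double t = std::fabs(arc * invk - (T - arc) * invnk) * w;
            if (t > best) {
                best = t; *bi = i; *bj = i + k;
                if (stop_at > 0 && best >= stop_at) return best;
            }
        }
    }
    return best;
}

// Permutation p-value with early stopping: shuffles x (R RNG stream) and
// counts permutations whose max arc statistic reaches t_obs. Stops once the
// exceedance count rules out p < alpha.
static bool accept_split(std::vector<double> x, double t_obs, int min_width,
                         int n_perm, double alpha) {
    const int n = (int)x.size();
    // reject as soon as (1 + count) >= alpha * (1 + n_perm)
    const double limit = alpha * (1.0 + n_perm);
    int count = 0;
    std::vector<double> S(n + 1);
    const double tol = t_obs * (1.0 - 1e-12);
    for (int p = 0; p < n_perm; ++p) {
        for (int i = n - 1; i > 0; --i) {
            int j = (int)std::floor(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(x[i], x[j]);
        }
        S[0] = 0.0;
        for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
        int bi, bj;
        double m = scan_max_arc(S, n, min_width, &bi, &bj, tol);
        if (m >= tol) {
            if (++count + 1 >= limit) return false;
        }
    }
    return (1.0 + count) < limit;
}

// [[Rcpp::export(name = ".cbs_breakpoints_cpp")]]
IntegerVector cbs_breakpoints_cpp(NumericVector x, double alpha, int min_width,
                                  int n_perm) {
    const int n = x.size();
    std::vector<int> bps;
    std::stack<std::pair<int, int> > todo;
    todo.push(std::make_pair(0, n));
    while (!todo.empty()) {
        const int lo = todo.top().first, hi = todo.top().second;
        todo.pop();
        const int m = hi - lo;
        if (m < std::max(2, 2 * min_width)) continue;
        std::vector<double> seg(x.begin() + lo, x.begin() + hi);
        double mean = 0.0;
        for (int i = 0; i < m; ++i) mean += seg[i];
        mean /= m;
        double ss = 0.0;
        for (int i = 0; i < m; ++i) ss += (seg[i] - mean) * (seg[i] - mean);
        const double sd = std::sqrt(ss / (m - 1));
        if (sd < 1e-12) continue;  // constant segment
        std::vector<double> S(m + 1);
        S[0] = 0.0;
        for (int i = 0; i < m; ++i) S[i + 1] = S[i] + seg[i];
        int bi, bj;
        const double t_obs = scan_max_arc(S, m, min_width, &bi, &bj, -1.0);
        if (t_obs <= 0) continue;
        if (!accept_split(seg, t_obs, min_width, n_perm, alpha)) continue;
        if (bi > 0) bps.push_back(lo + bi);
        if (bj < m) bps.push_back(lo + bj);
        if (bi > 0) todo.push(std::make_pair(lo, lo + bi));
        todo.push(std::make_pair(lo + bi, lo + bj));
        if (bj < m) todo.push(std::make_pair(lo + bj, hi));
    }
    std::sort(bps.begin(), bps.end());
    return IntegerVector(bps.begin(), bps.end());
}
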