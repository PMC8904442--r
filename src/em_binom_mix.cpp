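#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Binomial log-pmf with explicit boundary conventions (0*log 0 = 0 at
// theta in {0, 1}).
static inline double binom_lpmf(double ad, double dp, double th,
                                double lch) {
    if (th <= 0.0) return (ad == 0.0) ? 0.0 : R_NegInf;
    if (th >= 1.0) return (ad == dp) ? 0.0 : R_NegInf;
    return lch + ad * std::log(th) + (dp - ad) * std::log1p(-th);
}

static inline double clip01(double x, double eps) {
    if (x < eps) return eps;
    if (x > 1.0 - eps) return 1.0 - eps;
    return x;
}

// Snap a clipped parameter back to the exact boundary for the final
// unclipped likelihood evaluation.
static inline double snap01(double x) {
    if (x < 1e-8) return 0.0;
    if (x > 1.0 - 1e-8) return 1.0;
    return x;
}

static double mix_loglik(const std::vector<double>& ad,
                         const std::vector<double>& dp,
                         const std::vector<double>& lch,
                         double pi, double t0, double t1) {
    const size_t n = ad.size();
    double ll = 0.0;
    const double lpi = (pi > 0.0) ? std::log(pi) : R_NegInf;
    const double l1mpi = (pi < 1.0) ? std::log1p(-pi) : R_NegInf;
    for (size_t j = 0; j < n; ++j) {
        double a = lpi + binom_lpmf(ad[j], dp[j], t1, lch[j]);
        double b = l1mpi + binom_lpmf(ad[j], dp[j], t0, lch[j]);
        double m = (a > b) ? a : b;
        if (m == R_NegInf) return R_NegInf;
        ll += m + std::log(std::exp(a - m) + std::exp(b - m));
    }
    return ll;
}

// Per-variant EM for the two-component binomial mixture, over multiple
// restarts, plus the closed-form one-component fit. AD/DP are
// variants x cells; cells with DP < min_dp are excluded from both the
// likelihood and the cell count. init_* are variants x restarts.
// [[Rcpp::export]]
List em_batch_cpp(NumericMatrix AD, NumericMatrix DP,
                  NumericMatrix init_pi, NumericMatrix init_t0,
                  NumericMatrix init_t1,
                  double tol, int max_iter, double min_dp,
                  bool keep_trace) {
    const int V = AD.nrow(), C = AD.ncol();
    const int R = init_pi.ncol();
    const double EPS = 1e-10;

    NumericVector out_t0(V, NA_REAL), out_t1(V, NA_REAL), out_pi(V, NA_REAL);
    NumericVector out_ll1(V, NA_REAL), out_ll0(V, NA_REAL),
        out_th_m0(V, NA_REAL);
    IntegerVector out_n(V, 0), out_iter(V, 0);
    List traces(keep_trace ? V : 0);

    std::vector<double> ad, dp, lch;
    ad.reserve(C); dp.reserve(C); lch.reserve(C);

    for (int v = 0; v < V; ++v) {
        ad.clear(); dp.clear(); lch.clear();
        double sum_ad = 0.0, sum_dp = 0.0;
        for (int j = 0; j < C; ++j) {
            double d = DP(v, j);
            if (d >= min_dp && d > 0.0) {
                double a = AD(v, j);
                ad.push_back(a);
                dp.push_back(d);
                lch.push_back(Rf_lchoose(d, a));
                sum_ad += a;
                sum_dp += d;
            }
        }
        const int n = (int) ad.size();
        out_n[v] = n;
        if (n == 0 || sum_dp <= 0.0) continue;

        // one-component closed form
        const double th0hat = sum_ad / sum_dp;
        double ll0 = 0.0;
        for (int j = 0; j < n; ++j)
            ll0 += binom_lpmf(ad[j], dp[j], th0hat, lch[j]);
        out_th_m0[v] = th0hat;
        out_ll0[v] = ll0;

        double best_ll = R_NegInf, best_pi = NA_REAL,
            best_t0 = NA_REAL, best_t1 = NA_REAL;
        int iter_total = 0;
        List var_trace(keep_trace ? R : 0);

        for (int r = 0; r < R; ++r) {
            double pi = clip01(init_pi(v, r), 1e-9);
            double t0 = clip01(init_t0(v, r), EPS);
            double t1 = clip01(init_t1(v, r), EPS);
            double ll_prev = R_NegInf, ll = R_NegInf;
            std::vector<double> tr;
            int it = 0;
            for (it = 0; it < max_iter; ++it) {
                // E-step quantities and observed-data log-likelihood
                double sg = 0.0, sga = 0.0, sgd = 0.0, s1a = 0.0, s1d = 0.0;
                const double lpi = std::log(pi), l1mpi = std::log1p(-pi);
                ll = 0.0;
                for (int j = 0; j < n; ++j) {
                    double a = lpi + binom_lpmf(ad[j], dp[j], t1, lch[j]);
                    double b = l1mpi + binom_lpmf(ad[j], dp[j], t0, lch[j]);
                    double m = (a > b) ? a : b;
                    ll += m + std::log(std::exp(a - m) + std::exp(b - m));
                    double g = 1.0 / (1.0 + std::exp(b - a));
                    sg += g;
                    sga += g * ad[j];
                    sgd += g * dp[j];
                    s1a += (1.0 - g) * ad[j];
                    s1d += (1.0 - g) * dp[j];
                }
                if (keep_trace) tr.push_back(ll);
                if (it > 0 && std::fabs(ll - ll_prev) < tol) break;
                ll_prev = ll;
                // M-step
                pi = clip01(sg / n, 1e-9);
                if (sgd > 0.0) t1 = clip01(sga / sgd, EPS);
                if (s1d > 0.0) t0 = clip01(s1a / s1d, EPS);
            }
            iter_total += it;
            // final unclipped evaluation at boundary-snapped parameters
            double ps = snap01(pi), t0s = snap01(t0), t1s = snap01(t1);
            if (ps != pi || t0s != t0 || t1s != t1) {
                double lls = mix_loglik(ad, dp, lch, ps, t0s, t1s);
                if (lls >= ll) { ll = lls; pi = ps; t0 = t0s; t1 = t1s; }
            }
            if (keep_trace) var_trace[r] = wrap(tr);
            if (ll > best_ll) {
                best_ll = ll; best_pi = pi; best_t0 = t0; best_t1 = t1;
            }
        }
        // canonical labelling: theta1 >= theta0
        if (best_t0 > best_t1) {
            std::swap(best_t0, best_t1);
            best_pi = 1.0 - best_pi;
        }
        if (!std::isfinite(best_ll))
            stop("non-finite mixture likelihood for variant index %d", v + 1);
        out_pi[v] = best_pi;
        out_t0[v] = best_t0;
        out_t1[v] = best_t1;
        out_ll1[v] = best_ll;
        out_iter[v] = iter_total;
        if (keep_trace) traces[v] = var_trace;
    }

    List res = List::create(
        _["theta0"] = out_t0, _["theta1"] = out_t1, _["pi"] = out_pi,
        _["logL_M1"] = out_ll1, _["theta_M0"] = out_th_m0,
        _["logL_M0"] = out_ll0, _["n_cells_used"] = out_n,
        _["n_iter"] = out_iter);
    if (keep_trace) res["trace"] = traces;
    return res;
}
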