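#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Relative tolerance when deciding whether a lattice cell belongs to the
// rejection region {(n,b): HGT(n,b) <= mhg_stat}; absorbs round-off
// between the scan's phyper() values and the DP's recurrence-built tails.
static const double REL_TOL = 1e-12;

// Hypergeometric upper tail P[X >= b] for X ~ Hypergeom(N, B, n).
static double hgt(int b, int N, int B, int n) {
    if (b <= 0) return 1.0;
    return R::phyper(b - 1, B, N - B, n, 0, 0);
}

// Minimum hypergeometric statistic of a 0/1 series: the minimum over all
// prefixes n = 1..N of the hypergeometric tail P[X >= b_n], with the
// smallest n attaining it.
// [[Rcpp::export(name = ".mhg_scan")]]
List mhg_scan(IntegerVector indicator) {
    int N = indicator.size();
    if (N < 1) stop("indicator must be non-empty");
    int B = 0;
    for (int i = 0; i < N; ++i) {
        if (indicator[i] != 0 && indicator[i] != 1)
            stop("indicator must be 0/1");
        B += indicator[i];
    }
    double best = 1.0;
    int n_opt = N, b_opt = B;
    int b = 0;
    for (int n = 1; n <= N; ++n) {
        b += indicator[n - 1];
        double h = hgt(b, N, B, n);
        if (h < best * (1.0 - REL_TOL)) {
            best = h;
            n_opt = n;
            b_opt = b;
        }
    }
    return List::create(_["mhg_stat"] = best, _["n_opt"] = n_opt,
                        _["b_at_cutoff"] = b_opt, _["N"] = N, _["B"] = B);
}

// Exact p-value of the mHG statistic: the probability, under uniform
// random placement of B ones among N positions, that some prefix attains
// a hypergeometric tail <= stat. Dynamic program over the (n, b) lattice
// in probability space: D(n, b) is the probability that the random
// prefix walk reaches (n, b) without having entered the rejection
// region; mass entering a rejection cell is added to the p-value and
// absorbed. Conditional step probabilities (B-b)/(N-n) keep every
// quantity in [0, 1], so no overflow occurs for any N, B. The per-row
// tails HGT(n, b) are built by a descending-b pmf recurrence, O(N * B)
// overall.
// [[Rcpp::export(name = ".mhg_pvalue")]]
double mhg_pvalue(double stat, int N, int B) {
    if (N < 1 || B < 0 || B > N) stop("need 0 <= B <= N, N >= 1");
    if (B == 0 || B == N) return 1.0;
    if (stat >= 1.0) return 1.0;
    double thresh = stat * (1.0 + REL_TOL);

    // log-factorials for the O(1) pmf anchor per row
    std::vector<double> lf(N + 1);
    lf[0] = 0.0;
    for (int i = 1; i <= N; ++i) lf[i] = lf[i - 1] + std::log((double)i);
    auto lchoose = [&](int n, int k) { return lf[n] - lf[k] - lf[n - k]; };

    std::vector<double> D(B + 1, 0.0), Dnext(B + 1, 0.0);
    D[0] = 1.0;
    double p = 0.0;

    for (int n = 1; n <= N; ++n) {
        int bmin = std::max(0, n - (N - B));
        int bmax = std::min(n, B);
        // propagate survival mass from row n-1
        std::fill(Dnext.begin(), Dnext.end(), 0.0);
        int pbmin = std::max(0, (n - 1) - (N - B));
        int pbmax = std::min(n - 1, B);
        for (int b = pbmin; b <= pbmax; ++b) {
            double d = D[b];
            if (d == 0.0) continue;
            double pone = (double)(B - b) / (double)(N - (n - 1));
            if (b < B) Dnext[b + 1] += d * pone;
            Dnext[b] += d * (1.0 - pone);
        }
        // row tails: pmf(n, b) = C(B,b) C(N-B,n-b) / C(N,n), descending b
        double pmf = std::exp(lchoose(B, bmax) + lchoose(N - B, n - bmax) -
                              lchoose(N, n));
        double tail = 0.0;
        for (int b = bmax; b >= bmin; --b) {
            tail += pmf;
            if (tail <= thresh && b > 0) {  // b = 0 has HGT 1
                p += Dnext[b];              // absorbed into rejection
                Dnext[b] = 0.0;
            }
            if (b > bmin)
                pmf *= (double)b * (double)(N - B - n + b) /
                       ((double)(B - b + 1) * (double)(n - b + 1));
        }
        std::swap(D, Dnext);
    }
    if (p > 1.0) p = 1.0;
    return p;
}
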