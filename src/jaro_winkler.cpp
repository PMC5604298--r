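#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Jaro similarity. Matching window is floor(max(|a|,|b|)/2) - 1; transpositions
// are half the matched characters that appear in a different order.
static double jaro(const std::string &a, const std::string &b) {
    const int la = static_cast<int>(a.size());
    const int lb = static_cast<int>(b.size());
    if (la == 0 && lb == 0) return 1.0;
    if (la == 0 || lb == 0) return 0.0;
    int window = std::max(la, lb) / 2 - 1;
    if (window < 0) window = 0;

    std::vector<char> amatch(la, 0), bmatch(lb, 0);
    int m = 0;
    for (int i = 0; i < la; ++i) {
        const int lo = std::max(0, i - window);
        const int hi = std::min(lb - 1, i + window);
        for (int j = lo; j <= hi; ++j) {
            if (!bmatch[j] && a[i] == b[j]) {
                amatch[i] = 1;
                bmatch[j] = 1;
                ++m;
                break;
            }
        }
    }
    if (m == 0) return 0.0;

    int t = 0, k = 0;
    for (int i = 0; i < la; ++i) {
        if (!amatch[i]) continue;
        while (!bmatch[k]) ++k;
        if (a[i] != b[k]) ++t;
        ++k;
    }
    const double half_t = t / 2.0;
    return ((double)m / la + (double)m / lb + (m - half_t) / m) / 3.0;
}

// Winkler prefix boost: applied when the Jaro score exceeds 0.7, using up to
// `max_prefix` shared leading characters at scale `p`.
static double jaro_winkler_one(const std::string &a, const std::string &b,
                               double p, int max_prefix) {
    double j = jaro(a, b);
    if (j > 0.7) {
        const int lim = std::min({max_prefix, (int)a.size(), (int)b.size()});
        int l = 0;
        while (l < lim && a[l] == b[l]) ++l;
        j += l * p * (1.0 - j);
    }
    return j;
}

// [[Rcpp::export]]
NumericVector jw_pairwise(CharacterVector a, CharacterVector b,
                          double prefix_scale = 0.1, int max_prefix = 4) {
    if (a.size() != b.size())
        stop("'a' and 'b' must have the same length");
    NumericVector out(a.size());
    for (R_xlen_t i = 0; i < a.size(); ++i) {
        if (a[i] == NA_STRING || b[i] == NA_STRING) {
            out[i] = NA_REAL;
            continue;
        }
        out[i] = jaro_winkler_one(as<std::string>(a[i]), as<std::string>(b[i]),
                                  prefix_scale, max_prefix);
    }
    return out;
}

// [[Rcpp::export]]
NumericMatrix jw_self_matrix(CharacterVector x,
                             double prefix_scale = 0.1, int max_prefix = 4) {
    const R_xlen_t n = x.size();
    std::vector<std::string> s(n);
    for (R_xlen_t i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
    NumericMatrix out(n, n);
    for (R_xlen_t i = 0; i < n; ++i) {
        out(i, i) = 1.0;
        for (R_xlen_t j = i + 1; j < n; ++j) {
            const double v = jaro_winkler_one(s[i], s[j], prefix_scale, max_prefix);
            out(i, j) = v;
            out(j, i) = v;
        }
    }
    return out;
}

// Maximum Jaro-Winkler over the cross product of two string sets; the shape
// both the core-concept and the value similarities reduce to.
// [[Rcpp::export]]
double jw_max_cross(CharacterVector a, CharacterVector b,
                    double prefix_scale = 0.1, int max_prefix = 4) {
    if (a.size() == 0 || b.size() == 0) return 0.0;
    std::vector<std::string> sa(a.size()), sb(b.size());
    for (R_xlen_t i = 0; i < a.size(); ++i) sa[i] = as<std::string>(a[i]);
    for (R_xlen_t j = 0; j < b.size(); ++j) sb[j] = as<std::string>(b[j]);
    double best = 0.0;
    for (size_t i = 0; i < sa.size(); ++i) {
        for (size_t j = 0; j < sb.size(); ++j) {
            const double v = jaro_winkler_one(sa[i], sb[j], prefix_scale, max_prefix);
            if (v > best) best = v;
            if (best == 1.0) return 1.0;
        }
    }
    return best;
}
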