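#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Approximate matching core. Semi-global convention throughout: the whole
// pattern is aligned against any substring of the text (both text ends free);
// unit costs for substitution / insertion / deletion. 'N' matches nothing,
// including another 'N'.

static inline int base_index(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or anything else: matches nothing
    }
}

// Plain dynamic-programming column scan. Returns the score D[m][j] for every
// text offset j = 0..n (j is 1-past-end of the matched substring).
static std::vector<int> dp_end_scores(const std::string &pat,
                                      const std::string &txt) {
    const int m = (int) pat.size(), n = (int) txt.size();
    std::vector<int> col(m + 1), prev(m + 1), scores(n + 1);
    for (int i = 0; i <= m; ++i) prev[i] = i;  // D[i][0] = i
    scores[0] = m;
    for (int j = 1; j <= n; ++j) {
        col[0] = 0;  // free text start
        const char tc = txt[j - 1];
        const int ti = base_index(tc);
        for (int i = 1; i <= m; ++i) {
            const int pi = base_index(pat[i - 1]);
            const int sub = (pi >= 0 && pi == ti) ? 0 : 1;
            int best = prev[i - 1] + sub;
            if (prev[i] + 1 < best) best = prev[i] + 1;
            if (col[i - 1] + 1 < best) best = col[i - 1] + 1;
            col[i] = best;
        }
        scores[j] = col[m];
        std::swap(col, prev);
    }
    return scores;
}

// Myers (1999) bit-parallel column update, approximate-search variant:
// D[0][j] = 0 for all j. Pattern length must be <= 64.
static std::vector<int> myers_end_scores(const std::string &pat,
                                         const std::string &txt) {
    const int m = (int) pat.size(), n = (int) txt.size();
    uint64_t Peq[4] = {0, 0, 0, 0};
    for (int i = 0; i < m; ++i) {
        int b = base_index(pat[i]);
        if (b >= 0) Peq[b] |= (uint64_t) 1 << i;
    }
    const uint64_t hb = (uint64_t) 1 << (m - 1);
    uint64_t Pv = ~(uint64_t) 0, Mv = 0;
    int score = m;
    std::vector<int> scores(n + 1);
    scores[0] = m;
    for (int j = 0; j < n; ++j) {
        int b = base_index(txt[j]);
        uint64_t Eq = (b >= 0) ? Peq[b] : 0;
        uint64_t Xv = Eq | Mv;
        uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
        uint64_t Ph = Mv | ~(Xh | Pv);
        uint64_t Mh = Pv & Xh;
        if (Ph & hb) ++score;
        else if (Mh & hb) --score;
        Ph <<= 1;          // carry-in 0: D[0][j] stays 0 (free text start)
        Mh <<= 1;
        Pv = Mh | ~(Xv | Ph);
        Mv = Ph & Xv;
        scores[j + 1] = score;
    }
    return scores;
}

static List result_from_scores(const std::vector<int> &scores) {
    int best = scores[0];
    for (size_t j = 1; j < scores.size(); ++j)
        if (scores[j] < best) best = scores[j];
    std::vector<int> ends;
    for (size_t j = 0; j < scores.size(); ++j)
        if (scores[j] == best) ends.push_back((int) j);
    return List::create(_["min_distance"] = best,
                        _["end_positions"] = wrap(ends));
}

// [[Rcpp::export(name = ".cpp_semiglobal")]]
List cpp_semiglobal(std::string pattern, std::string text) {
    if (pattern.empty()) stop("pattern must be non-empty");
    if (text.empty())
        return List::create(_["min_distance"] = (int) pattern.size(),
                            _["end_positions"] = IntegerVector::create(0));
    return result_from_scores(dp_end_scores(pattern, text));
}

// [[Rcpp::export(name = ".cpp_myers")]]
List cpp_myers(std::string pattern, std::string text) {
    if (pattern.empty()) stop("pattern must be non-empty");
    if (pattern.size() > 64) stop("pattern longer than 64");
    if (text.empty())
        return List::create(_["min_distance"] = (int) pattern.size(),
                            _["end_positions"] = IntegerVector::create(0));
    return result_from_scores(myers_end_scores(pattern, text));
}

static int min_distance(const std::string &pat, const std::string &txt) {
    if (txt.empty()) return (int) pat.size();
    std::vector<int> s = (pat.size() <= 64) ? myers_end_scores(pat, txt)
                                            : dp_end_scores(pat, txt);
    int best = s[0];
    for (size_t j = 1; j < s.size(); ++j) if (s[j] < best) best = s[j];
    return best;
}

static std::string revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) {
        switch (r[i]) {
        case 'A': case 'a': r[i] = 'T'; break;
        case 'C': case 'c': r[i] = 'G'; break;
        case 'G': case 'g': r[i] = 'C'; break;
        case 'T': case 't': r[i] = 'A'; break;
        default: r[i] = 'N';
        }
    }
    return r;
}

// Batch contaminant screen: read i is flagged when it (or its reverse
// complement) matches any contaminant within k[i] errors.
// [[Rcpp::export(name = ".cpp_contaminant_flag")]]
LogicalVector cpp_contaminant_flag(CharacterVector inserts,
                                   CharacterVector contaminants,
                                   IntegerVector k) {
    const int n = inserts.size();
    LogicalVector out(n);
    std::vector<std::string> refs;
    for (int c = 0; c < contaminants.size(); ++c)
        refs.push_back(as<std::string>(contaminants[c]));
    for (int i = 0; i < n; ++i) {
        std::string ins = as<std::string>(inserts[i]);
        std::string rc = revcomp(ins);
        bool hit = false;
        for (size_t c = 0; c < refs.size() && !hit; ++c) {
            if (min_distance(ins, refs[c]) <= k[i]) hit = true;
            else if (min_distance(rc, refs[c]) <= k[i]) hit = true;
        }
        out[i] = hit;
    }
    return out;
}

// Oligo-artifact coverage: fraction of insert positions lying inside a
// sliding window (length w, step 1) that matches some library sequence
// within k errors. Inserts shorter than w are tested as a single window.
// [[Rcpp::export(name = ".cpp_artifact_coverage")]]
NumericVector cpp_artifact_coverage(CharacterVector inserts,
                                    CharacterVector library,
                                    int w, int k) {
    const int n = inserts.size();
    NumericVector out(n);
    std::vector<std::string> lib;
    for (int c = 0; c < library.size(); ++c)
        lib.push_back(as<std::string>(library[c]));
    for (int i = 0; i < n; ++i) {
        std::string ins = as<std::string>(inserts[i]);
        const int L = (int) ins.size();
        if (L == 0) { out[i] = 0.0; continue; }
        const int ww = std::min(w, L);
        std::vector<char> covered(L, 0);
        for (int s = 0; s + ww <= L; ++s) {
            std::string win = ins.substr(s, ww);
            bool hit = false;
            for (size_t c = 0; c < lib.size() && !hit; ++c)
                if (min_distance(win, lib[c]) <= k) hit = true;
            if (hit) for (int p = s; p < s + ww; ++p) covered[p] = 1;
        }
        int tot = 0;
        for (int p = 0; p < L; ++p) tot += covered[p];
        out[i] = (double) tot / (double) L;
    }
    return out;
}

// Best semi-global hits of a pattern in a long text: minimum distance and
// all end offsets achieving it (capped to avoid pathological all-N cases).
// [[Rcpp::export(name = ".cpp_scan_best")]]
List cpp_scan_best(std::string pattern, std::string text, int max_ends) {
    if (pattern.empty()) stop("pattern must be non-empty");
    std::vector<int> s = (pattern.size() <= 64) ? myers_end_scores(pattern, text)
                                                : dp_end_scores(pattern, text);
    int best = s[0];
    for (size_t j = 1; j < s.size(); ++j) if (s[j] < best) best = s[j];
    std::vector<int> ends;
    for (size_t j = 0; j < s.size(); ++j) {
        if (s[j] == best) {
            ends.push_back((int) j);
            if ((int) ends.size() >= max_ends) break;
        }
    }
    return List::create(_["min_distance"] = best,
                        _["end_positions"] = wrap(ends));
}
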