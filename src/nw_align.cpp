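#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh), optionally with free terminal gaps
// (ends-free "overlap" mode). Three states per cell:
//   M  : a[i] aligned to b[j]
//   GA : gap character in a (column consumes b[j])
//   GB : gap character in b (column consumes a[i])
// A gap of length L costs open + L * ext (open, ext are positive costs here).
// Tie-breaking is deterministic: M is preferred over GA over GB, both when
// choosing the terminal cell/state and at every traceback step.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct AlnResult {
    std::string aligned_a;
    std::string aligned_b;
    double score;
};

static AlnResult gotoh(const std::string& a, const std::string& b,
                       double match, double mismatch,
                       double open, double ext, bool free_ends) {
    const int n = (int) a.size(), m = (int) b.size();
    const size_t W = (size_t) m + 1;
    std::vector<double> M((size_t)(n + 1) * W, NEG_INF);
    std::vector<double> GA((size_t)(n + 1) * W, NEG_INF);
    std::vector<double> GB((size_t)(n + 1) * W, NEG_INF);
    // traceback: for each state, which predecessor state (0=M,1=GA,2=GB)
    std::vector<unsigned char> tM((size_t)(n + 1) * W, 0);
    std::vector<unsigned char> tGA((size_t)(n + 1) * W, 0);
    std::vector<unsigned char> tGB((size_t)(n + 1) * W, 0);

#define IDX(i, j) ((size_t)(i) * W + (size_t)(j))

    M[IDX(0, 0)] = 0.0;
    for (int j = 1; j <= m; ++j) {
        GA[IDX(0, j)] = free_ends ? 0.0 : -(open + j * ext);
        tGA[IDX(0, j)] = 1;
    }
    for (int i = 1; i <= n; ++i) {
        GB[IDX(i, 0)] = free_ends ? 0.0 : -(open + i * ext);
        tGB[IDX(i, 0)] = 2;
    }

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const size_t d = IDX(i - 1, j - 1), u = IDX(i - 1, j),
                         l = IDX(i, j - 1), c = IDX(i, j);
            // M state: prefer M > GA > GB on ties
            double s = (a[(size_t)i - 1] == b[(size_t)j - 1]) ? match : mismatch;
            double best = M[d]; unsigned char bt = 0;
            if (GA[d] > best) { best = GA[d]; bt = 1; }
            if (GB[d] > best) { best = GB[d]; bt = 2; }
            M[c] = best + s; tM[c] = bt;
            // GA state (gap in a, consume b[j]): from left neighbour
            best = M[l] - (open + ext); bt = 0;
            if (GA[l] - ext > best) { best = GA[l] - ext; bt = 1; }
            if (GB[l] - (open + ext) > best) { best = GB[l] - (open + ext); bt = 2; }
            GA[c] = best; tGA[c] = bt;
            // GB state (gap in b, consume a[i]): from upper neighbour
            best = M[u] - (open + ext); bt = 0;
            if (GA[u] - (open + ext) > best) { best = GA[u] - (open + ext); bt = 1; }
            if (GB[u] - ext > best) { best = GB[u] - ext; bt = 2; }
            GB[c] = best; tGB[c] = bt;
        }
    }

    // terminal cell and state
    int ei = n, ej = m; unsigned char estate = 0; double score;
    auto cell_best = [&](int i, int j, unsigned char& st) {
        const size_t c = IDX(i, j);
        double best = M[c]; st = 0;
        if (GA[c] > best) { best = GA[c]; st = 1; }
        if (GB[c] > best) { best = GB[c]; st = 2; }
        return best;
    };
    if (free_ends) {
        unsigned char st;
        score = cell_best(n, m, st); estate = st;
        // trailing gap in a (end of last row) preferred over trailing gap in b
        for (int j = m - 1; j >= 0; --j) {
            double v = cell_best(n, j, st);
            if (v > score) { score = v; ei = n; ej = j; estate = st; }
        }
        for (int i = n - 1; i >= 0; --i) {
            double v = cell_best(i, m, st);
            if (v > score) { score = v; ei = i; ej = m; estate = st; }
        }
    } else {
        score = cell_best(n, m, estate);
    }

    std::string ra, rb;
    ra.reserve((size_t) n + m); rb.reserve((size_t) n + m);
    // free trailing overhangs
    for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[(size_t)j - 1]); }
    for (int i = n; i > ei; --i) { ra.push_back(a[(size_t)i - 1]); rb.push_back('-'); }

    int i = ei, j = ej; unsigned char st = estate;
    while (i > 0 || j > 0) {
        const size_t c = IDX(i, j);
        if (st == 0) {
            if (i == 0 && j == 0) break;
            ra.push_back(a[(size_t)i - 1]); rb.push_back(b[(size_t)j - 1]);
            st = tM[c]; --i; --j;
        } else if (st == 1) {
            ra.push_back('-'); rb.push_back(b[(size_t)j - 1]);
            st = tGA[c]; --j;
        } else {
            ra.push_back(a[(size_t)i - 1]); rb.push_back('-');
            st = tGB[c]; --i;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    AlnResult res; res.aligned_a = ra; res.aligned_b = rb; res.score = score;
    return res;
}

static inline bool is_acgt(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// columns where both symbols are unambiguous nucleotides and differ
static void count_pdist(const std::string& ra, const std::string& rb,
                        int& diffs, int& cols) {
    cols = (int) ra.size(); diffs = 0;
    for (size_t k = 0; k < ra.size(); ++k) {
        if (is_acgt(ra[k]) && is_acgt(rb[k]) && ra[k] != rb[k]) ++diffs;
    }
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double open, double ext, bool free_ends) {
    AlnResult r = gotoh(a, b, match, mismatch, open, ext, free_ends);
    return List::create(_["aligned_a"] = r.aligned_a,
                        _["aligned_b"] = r.aligned_b,
                        _["score"] = r.score);
}

// [[Rcpp::export]]
NumericVector nw_counts_cpp(std::string a, std::string b, double match,
                            double mismatch, double open, double ext,
                            bool free_ends) {
    int diffs, cols;
    if (a == b) {
        diffs = 0; cols = (int) a.size();
        return NumericVector::create(diffs, cols, match * (double) a.size());
    }
    AlnResult r = gotoh(a, b, match, mismatch, open, ext, free_ends);
    count_pdist(r.aligned_a, r.aligned_b, diffs, cols);
    return NumericVector::create(diffs, cols, r.score);
}

// All unordered pairs of (deduplicated upstream) sequences: difference and
// aligned-column count matrices for p-distance work.
// [[Rcpp::export]]
List pdist_counts_cpp(CharacterVector seqs, double match, double mismatch,
                      double open, double ext, bool free_ends) {
    const int k = seqs.size();
    IntegerMatrix diffs(k, k), cols(k, k);
    std::vector<std::string> s(k);
    for (int i = 0; i < k; ++i) s[i] = as<std::string>(seqs[i]);
    for (int i = 0; i < k; ++i) cols(i, i) = (int) s[i].size();
    for (int i = 0; i < k - 1; ++i) {
        for (int j = i + 1; j < k; ++j) {
            int d, c;
            if (s[i] == s[j]) { d = 0; c = (int) s[i].size(); }
            else {
                AlnResult r = gotoh(s[i], s[j], match, mismatch, open, ext, free_ends);
                count_pdist(r.aligned_a, r.aligned_b, d, c);
            }
            diffs(i, j) = d; diffs(j, i) = d;
            cols(i, j) = c; cols(j, i) = c;
        }
        Rcpp::checkUserInterrupt();
    }
    return List::create(_["diffs"] = diffs, _["cols"] = cols);
}
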