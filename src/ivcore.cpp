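// Interval-coded binary domain kernels.
//
// A domain is an integer matrix with one row per maximal interval and columns
// (z, y, start, end): plane index, row index, half-open [start, end) column
// range, all 0-based. Canonical form: rows sorted lexicographically by
// (z, y, start) with a strict gap between consecutive intervals on the same
// (z, y) line. Set operations walk intervals, never pixels, so cost scales
// with the interval count (one dimension below area/volume).

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <vector>

using namespace Rcpp;

typedef std::array<int, 4> Iv; // z, y, start, end

static std::vector<Iv> mat_to_vec(const IntegerMatrix &m) {
    std::vector<Iv> v(m.nrow());
    for (int i = 0; i < m.nrow(); ++i)
        v[i] = {m(i, 0), m(i, 1), m(i, 2), m(i, 3)};
    return v;
}

static IntegerMatrix vec_to_mat(const std::vector<Iv> &v) {
    IntegerMatrix m((int)v.size(), 4);
    for (size_t i = 0; i < v.size(); ++i) {
        m(i, 0) = v[i][0]; m(i, 1) = v[i][1];
        m(i, 2) = v[i][2]; m(i, 3) = v[i][3];
    }
    colnames(m) = CharacterVector::create("z", "y", "start", "end");
    return m;
}

static bool iv_less(const Iv &a, const Iv &b) {
    if (a[0] != b[0]) return a[0] < b[0];
    if (a[1] != b[1]) return a[1] < b[1];
    return a[2] < b[2];
}

static bool same_line(const Iv &a, const Iv &b) {
    return a[0] == b[0] && a[1] == b[1];
}

// Sort and merge overlapping or adjacent intervals into canonical form.
// Because canonical(concat(A, B)) has the voxel set of A | B, this kernel
// doubles as n-ary union.
// [[Rcpp::export]]
IntegerMatrix cpp_iv_canon(IntegerMatrix ivs) {
    std::vector<Iv> v = mat_to_vec(ivs);
    for (const Iv &iv : v)
        if (iv[2] >= iv[3]) stop("interval with start >= end");
    std::sort(v.begin(), v.end(), iv_less);
    std::vector<Iv> out;
    out.reserve(v.size());
    for (const Iv &iv : v) {
        if (!out.empty() && same_line(out.back(), iv) && iv[2] <= out.back()[3]) {
            if (iv[3] > out.back()[3]) out.back()[3] = iv[3];
        } else {
            out.push_back(iv);
        }
    }
    return vec_to_mat(out);
}

// Check canonical-form invariants without repairing them.
// [[Rcpp::export]]
bool cpp_iv_is_canonical(IntegerMatrix ivs) {
    std::vector<Iv> v = mat_to_vec(ivs);
    for (size_t i = 0; i < v.size(); ++i) {
        if (v[i][2] >= v[i][3]) return false;
        if (i > 0) {
            if (!iv_less(v[i - 1], v[i])) return false;
            if (same_line(v[i - 1], v[i]) && v[i][2] <= v[i - 1][3]) return false;
        }
    }
    return true;
}

// Intersection of two interval lists on one (z, y) line (two-pointer sweep).
static void line_intersect(const std::vector<Iv> &a, size_t a0, size_t a1,
                           const std::vector<Iv> &b, size_t b0, size_t b1,
                           std::vector<Iv> &out) {
    size_t i = a0, j = b0;
    while (i < a1 && j < b1) {
        int lo = std::max(a[i][2], b[j][2]);
        int hi = std::min(a[i][3], b[j][3]);
        if (lo < hi) out.push_back({a[i][0], a[i][1], lo, hi});
        if (a[i][3] <= b[j][3]) ++i; else ++j;
    }
}

// A minus B on one line.
static void line_diff(const std::vector<Iv> &a, size_t a0, size_t a1,
                      const std::vector<Iv> &b, size_t b0, size_t b1,
                      std::vector<Iv> &out) {
    size_t j = b0;
    for (size_t i = a0; i < a1; ++i) {
        int cur = a[i][2];
        const int end = a[i][3];
        while (j < b1 && b[j][3] <= cur) ++j;
        size_t jj = j;
        while (jj < b1 && b[jj][2] < end) {
            if (b[jj][2] > cur)
                out.push_back({a[i][0], a[i][1], cur, b[jj][2]});
            cur = std::max(cur, b[jj][3]);
            if (cur >= end) break;
            ++jj;
        }
        if (cur < end) out.push_back({a[i][0], a[i][1], cur, end});
    }
}

// op: 1 = intersect, 2 = difference (A \ B). Union goes through cpp_iv_canon.
// [[Rcpp::export]]
IntegerMatrix cpp_iv_setop(IntegerMatrix A, IntegerMatrix B, int op) {
    std::vector<Iv> a = mat_to_vec(A), b = mat_to_vec(B);
    std::vector<Iv> out;
    out.reserve(a.size());
    size_t i = 0, j = 0;
    while (i < a.size()) {
        // line extent in a
        size_t i1 = i + 1;
        while (i1 < a.size() && same_line(a[i], a[i1])) ++i1;
        // advance b to this line
        while (j < b.size() && (b[j][0] < a[i][0] ||
               (b[j][0] == a[i][0] && b[j][1] < a[i][1]))) ++j;
        size_t j1 = j;
        bool match = j < b.size() && same_line(b[j], a[i]);
        if (match) {
            j1 = j + 1;
            while (j1 < b.size() && same_line(b[j], b[j1])) ++j1;
        }
        if (op == 1) {
            if (match) line_intersect(a, i, i1, b, j, j1, out);
        } else {
            if (match) line_diff(a, i, i1, b, j, j1, out);
            else for (size_t k = i; k < i1; ++k) out.push_back(a[k]);
        }
        i = i1;
        if (match) j = j1;
    }
    return vec_to_mat(out);
}

// Total voxel count of an already-canonical matrix.
// [[Rcpp::export]]
double cpp_iv_size(IntegerMatrix ivs) {
    double s = 0;
    for (int i = 0; i < ivs.nrow(); ++i) s += ivs(i, 3) - ivs(i, 2);
    return s;
}

// Size of the intersection without materialising it (hot path for ranked
// similarity queries over large pattern databases).
// [[Rcpp::export]]
double cpp_iv_isect_size(IntegerMatrix A, IntegerMatrix B) {
    std::vector<Iv> a = mat_to_vec(A), b = mat_to_vec(B);
    double s = 0;
    size_t i = 0, j = 0;
    while (i < a.size() && j < b.size()) {
        if (a[i][0] != b[j][0] || a[i][1] != b[j][1]) {
            if (iv_less(a[i], b[j])) ++i; else ++j;
            continue;
        }
        int lo = std::max(a[i][2], b[j][2]);
        int hi = std::min(a[i][3], b[j][3]);
        if (lo < hi) s += hi - lo;
        if (a[i][3] <= b[j][3]) ++i; else ++j;
    }
    return s;
}
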