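// Affine-gap global (Needleman-Wunsch) alignment with traceback.
// Scoring: +match for identical characters, +mismatch otherwise; a gap of
// length L costs gap_open + L * gap_ext (open charged once per gap, plus
// extension per gap column). Terminal gaps are penalized (true global).
// Integer arithmetic with rolling score rows; traceback states for the
// three matrices are packed into one byte per cell.

#include <Rcpp.h>
#include <vector>
#include <climits>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// [[Rcpp::export(name = ".nwAffine")]]
List nwAffine(std::string a, std::string b, int match_score,
              int mismatch_score, int gap_open, int gap_ext) {
    const int n = (int)a.size(), m = (int)b.size();
    const int go = gap_open, ge = gap_ext, goe = go + ge;
    const size_t W = (size_t)m + 1;
    std::vector<int> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);
    // packed traceback: bits 0-1 state-before for M, 2-3 for X, 4-5 for Y
    std::vector<unsigned char> tb((size_t)(n + 1) * W, 0);

    Mp[0] = 0; Xp[0] = NEG; Yp[0] = NEG;
    for (int j = 1; j <= m; ++j) {
        Mp[j] = NEG; Xp[j] = NEG; Yp[j] = -(go + ge * j);
        tb[(size_t)j] = 2u << 4;  // Y from Y
    }
    for (int i = 1; i <= n; ++i) {
        Mc[0] = NEG; Yc[0] = NEG; Xc[0] = -(go + ge * i);
        unsigned char* trow = &tb[(size_t)i * W];
        trow[0] = 1u << 2;  // X from X
        const char ai = a[(size_t)i - 1];
        int Mdiag = Mp[0], Xdiag = Xp[0], Ydiag = Yp[0];
        for (int j = 1; j <= m; ++j) {
            const int s = (ai == b[(size_t)j - 1]) ? match_score
                                                   : mismatch_score;
            // M from diagonal (i-1, j-1)
            int best = Mdiag; unsigned char tm = 0;
            if (Xdiag > best) { best = Xdiag; tm = 1; }
            if (Ydiag > best) { best = Ydiag; tm = 2; }
            const int Mij = best + s;
            // X from up (i-1, j): gap in b
            int xb = Mp[j] - goe; unsigned char tx = 0;
            if (Xp[j] - ge > xb) { xb = Xp[j] - ge; tx = 1; }
            if (Yp[j] - goe > xb) { xb = Yp[j] - goe; tx = 2; }
            // Y from left (i, j-1): gap in a
            int yb = Mc[j - 1] - goe; unsigned char ty = 0;
            if (Xc[j - 1] - goe > yb) { yb = Xc[j - 1] - goe; ty = 1; }
            if (Yc[j - 1] - ge > yb) { yb = Yc[j - 1] - ge; ty = 2; }
            Mdiag = Mp[j]; Xdiag = Xp[j]; Ydiag = Yp[j];
            Mc[j] = Mij; Xc[j] = xb; Yc[j] = yb;
            trow[j] = (unsigned char)(tm | (tx << 2) | (ty << 4));
        }
        std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    int score = Mp[m], state = 0;
    if (Xp[m] > score) { score = Xp[m]; state = 1; }
    if (Yp[m] > score) { score = Yp[m]; state = 2; }

    std::string ra, rb;
    ra.reserve((size_t)n + m); rb.reserve((size_t)n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        const unsigned char t = tb[(size_t)i * W + j];
        if (j == 0) state = 1;       // only X moves remain
        else if (i == 0) state = 2;  // only Y moves remain
        if (state == 0) {
            ra.push_back(a[(size_t)i - 1]); rb.push_back(b[(size_t)j - 1]);
            --i; --j; state = t & 3u;
        } else if (state == 1) {
            ra.push_back(a[(size_t)i - 1]); rb.push_back('-');
            --i; state = (t >> 2) & 3u;
        } else {
            ra.push_back('-'); rb.push_back(b[(size_t)j - 1]);
            --j; state = (t >> 4) & 3u;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return List::create(Named("score") = (double)score,
                        Named("aligned1") = ra, Named("aligned2") = rb);
}

// Exact k-mer seed matching: positions (1-based) of query k-mers in the
// subject. Seeds containing non-ACGT characters are skipped on both
// sides. Returns a two-column matrix (qpos, spos).

static inline int baseCode(char c) {
    switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
    }
}

#include <unordered_map>

// [[Rcpp::export(name = ".seedMatch")]]
IntegerMatrix seedMatch(std::string query, std::string subject, int k,
                        int stride) {
    const int qn = (int)query.size(), sn = (int)subject.size();
    std::vector<int> qpos_out, spos_out;
    if (k < 1 || k > 31 || qn < k || sn < k)
        return IntegerMatrix(0, 2);
    std::unordered_multimap<uint64_t, int> index;
    for (int p = 0; p + k <= qn; p += stride) {
        uint64_t h = 0; bool ok = true;
        for (int t = 0; t < k; ++t) {
            const int c = baseCode(query[(size_t)(p + t)]);
            if (c < 0) { ok = false; break; }
            h = (h << 2) | (uint64_t)c;
        }
        if (ok) index.emplace(h, p + 1);
    }
    if (index.empty()) return IntegerMatrix(0, 2);
    const uint64_t mask = (k == 32) ? ~0ULL
                                    : ((1ULL << (2 * k)) - 1ULL);
    uint64_t h = 0; int valid = 0;
    for (int p = 0; p < sn; ++p) {
        const int c = baseCode(subject[(size_t)p]);
        if (c < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++valid < k) continue;
        auto range = index.equal_range(h);
        for (auto it = range.first; it != range.second; ++it) {
            qpos_out.push_back(it->second);
            spos_out.push_back(p - k + 2);  // 1-based start
        }
    }
    IntegerMatrix out((int)qpos_out.size(), 2);
    for (int i = 0; i < (int)qpos_out.size(); ++i) {
        out(i, 0) = qpos_out[(size_t)i];
        out(i, 1) = spos_out[(size_t)i];
    }
    colnames(out) = CharacterVector::create("qpos", "spos");
    return out;
}

// Smith-Waterman local alignment with the same affine convention as the
// global aligner. Returns the best-scoring local alignment, its score,
// and the 1-based coordinate ranges it covers in both sequences.

// [[Rcpp::export(name = ".swLocal")]]
List swLocal(std::string a, std::string b, int match_score,
             int mismatch_score, int gap_open, int gap_ext) {
    const int n = (int)a.size(), m = (int)b.size();
    const int goe = gap_open + gap_ext, ge = gap_ext;
    const size_t W = (size_t)m + 1;
    std::vector<int> Mp(W, 0), Xp(W, NEG), Yp(W, NEG),
        Mc(W), Xc(W), Yc(W);
    // bits 0-1: M origin (0=M,1=X,2=Y,3=fresh start); 2-3: X; 4-5: Y
    std::vector<unsigned char> tb((size_t)(n + 1) * W, 3);
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        Mc[0] = 0; Xc[0] = NEG; Yc[0] = NEG;
        unsigned char* trow = &tb[(size_t)i * W];
        trow[0] = 3;
        const char ai = a[(size_t)i - 1];
        int Mdiag = Mp[0], Xdiag = Xp[0], Ydiag = Yp[0];
        for (int j = 1; j <= m; ++j) {
            const int s = (ai == b[(size_t)j - 1]) ? match_score
                                                   : mismatch_score;
            int pb = Mdiag; unsigned char tm = 0;
            if (Xdiag > pb) { pb = Xdiag; tm = 1; }
            if (Ydiag > pb) { pb = Ydiag; tm = 2; }
            if (pb <= 0) { pb = 0; tm = 3; }  // alignment starts here
            int Mij = pb + s;
            if (Mij < 0) Mij = 0;
            int xb = Mp[j] - goe; unsigned char tx = 0;
            if (Xp[j] - ge > xb) { xb = Xp[j] - ge; tx = 1; }
            int yb = Mc[j - 1] - goe; unsigned char ty = 0;
            if (Yc[j - 1] - ge > yb) { yb = Yc[j - 1] - ge; ty = 2; }
            Mdiag = Mp[j]; Xdiag = Xp[j]; Ydiag = Yp[j];
            Mc[j] = Mij; Xc[j] = xb; Yc[j] = yb;
            trow[j] = (unsigned char)(tm | (tx << 2) | (ty << 4));
            if (Mij > best) { best = Mij; bi = i; bj = j; }
        }
        std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    std::string ra, rb;
    int i = bi, j = bj, state = 0;
    while (i > 0 && j > 0) {
        const unsigned char t = tb[(size_t)i * W + j];
        if (state == 0) {
            const unsigned char tm = t & 3u;
            ra.push_back(a[(size_t)i - 1]); rb.push_back(b[(size_t)j - 1]);
            --i; --j;
            if (tm == 3u) break;  // first aligned column reached
            state = tm;
        } else if (state == 1) {
            ra.push_back(a[(size_t)i - 1]); rb.push_back('-');
            --i; state = (t >> 2) & 3u;
        } else {
            ra.push_back('-'); rb.push_back(b[(size_t)j - 1]);
            --j; state = (t >> 4) & 3u;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return List::create(Named("score") = (double)best,
                        Named("aligned1") = ra, Named("aligned2") = rb,
                        Named("start1") = (best > 0) ? i + 1 : 0,
                        Named("end1") = bi, Named("start2") = (best > 0) ? j + 1 : 0,
                        Named("end2") = bj);
}
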