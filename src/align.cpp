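#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman) over integer-encoded
// sequences. A gap of length L costs gap_open + L * gap_ext, matching
// the NCBI convention for the BLOSUM62 / 11 / 1 parameter set.
//
// Three-state DP: M ends in an aligned pair, IX ends with a gap in b
// (an a-residue against '-'), IY ends with a gap in a. A local optimum
// always ends in M because trailing gaps only subtract.

static const int NEG_INF = -1000000000;

struct SwResult {
    int score;
    int align_length;
    int matches;
};

static SwResult sw_core(const int *a, int n, const int *b, int m,
                        const IntegerMatrix &sub, int gap_open, int gap_ext,
                        bool traceback) {
    std::vector<int> Mrow(m + 1, 0), IXrow(m + 1, NEG_INF), IYrow(m + 1, NEG_INF);
    // traceback codes per state, row-major (n+1) x (m+1)
    // tbM: 0 = fresh start, 1 = from M, 2 = from IX, 3 = from IY
    // tbX/tbY: 0 = opened from M, 1 = extended
    std::vector<unsigned char> tbM, tbX, tbY;
    if (traceback) {
        tbM.assign((size_t)(n + 1) * (m + 1), 0);
        tbX.assign((size_t)(n + 1) * (m + 1), 0);
        tbY.assign((size_t)(n + 1) * (m + 1), 0);
    }
    int best = 0, bi = 0, bj = 0;
    int go = gap_open + gap_ext; // cost of opening a length-1 gap

    for (int i = 1; i <= n; ++i) {
        int Mdiag = Mrow[0];   // M[i-1][0]
        int IYdiag = IYrow[0]; // IY[i-1][0]
        Mrow[0] = 0;
        IYrow[0] = NEG_INF;
        int IXprev_col0 = IXrow[0]; // IX[i-1][0]
        IXrow[0] = NEG_INF;
        int IXdiag = IXprev_col0;
        for (int j = 1; j <= m; ++j) {
            int Mup = Mrow[j];   // M[i-1][j]
            int IXup = IXrow[j]; // IX[i-1][j]
            int IYleftOld = IYrow[j]; // IY[i-1][j] (not used for IY recurrence)
            (void)IYleftOld;

            // IX: gap in b, consume a_i
            int openX = (Mup > NEG_INF) ? Mup - go : NEG_INF;
            int extX = (IXup > NEG_INF) ? IXup - gap_ext : NEG_INF;
            int ix = openX >= extX ? openX : extX;
            unsigned char cx = openX >= extX ? 0 : 1;

            // IY: gap in a, consume b_j (uses current row, column j-1)
            int Mleft = Mrow[j - 1];
            int IYleft = IYrow[j - 1];
            int openY = (Mleft > NEG_INF) ? Mleft - go : NEG_INF;
            int extY = (IYleft > NEG_INF) ? IYleft - gap_ext : NEG_INF;
            int iy = openY >= extY ? openY : extY;
            unsigned char cy = openY >= extY ? 0 : 1;

            // M: aligned pair a_i, b_j
            int s = sub(a[i - 1], b[j - 1]);
            int fromM = Mdiag, fromX = IXdiag, fromY = IYdiag;
            int pred = fromM;
            unsigned char cm = 1;
            if (fromX > pred) { pred = fromX; cm = 2; }
            if (fromY > pred) { pred = fromY; cm = 3; }
            int mm;
            if (pred <= 0) { mm = s; cm = 0; }
            else mm = pred + s;
            if (mm < 0) { mm = s; cm = 0; } // never extend through negative
            if (mm < 0) mm = NEG_INF;       // single negative pair: dead cell

            // save diagonals for next j
            Mdiag = Mup;
            IXdiag = IXup;
            IYdiag = IYrow[j]; // IY[i-1][j] before overwrite

            Mrow[j] = mm;
            IXrow[j] = ix;
            IYrow[j] = iy;

            if (traceback) {
                size_t off = (size_t)i * (m + 1) + j;
                tbM[off] = cm;
                tbX[off] = cx;
                tbY[off] = cy;
            }
            if (mm > best) { best = mm; bi = i; bj = j; }
        }
    }

    SwResult res;
    res.score = best;
    res.align_length = 0;
    res.matches = 0;
    if (!traceback || best <= 0) return res;

    // walk back from (bi, bj) in state M until a fresh start
    int i = bi, j = bj, state = 0; // 0 = M, 1 = IX, 2 = IY
    while (i > 0 && j > 0) {
        size_t off = (size_t)i * (m + 1) + j;
        if (state == 0) {
            res.align_length++;
            if (a[i - 1] == b[j - 1]) res.matches++;
            unsigned char cm = tbM[off];
            i--; j--;
            if (cm == 0) break;
            state = (cm == 1) ? 0 : (cm == 2 ? 1 : 2);
        } else if (state == 1) { // IX: gap in b
            res.align_length++;
            unsigned char cx = tbX[off];
            i--;
            state = (cx == 0) ? 0 : 1;
        } else { // IY: gap in a
            res.align_length++;
            unsigned char cy = tbY[off];
            j--;
            state = (cy == 0) ? 0 : 1 + 1;
            if (cy == 0) state = 0; else state = 2;
        }
    }
    return res;
}

// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
    SwResult r = sw_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                         sub, gap_open, gap_ext, true);
    return List::create(_["score"] = r.score,
                        _["align_length"] = r.align_length,
                        _["matches"] = r.matches);
}

// k-mer index of a query sequence: packed k-mer -> start positions
typedef std::unordered_map<long long, std::vector<int> > KmerIndex;

static void build_kmer_index(const int *q, int n, int k, int alpha,
                             KmerIndex &idx) {
    if (n < k) return;
    long long base = 1;
    for (int i = 1; i < k; ++i) base *= alpha;
    long long key = 0;
    for (int i = 0; i < k; ++i) key = key * alpha + q[i];
    idx[key].push_back(0);
    for (int i = k; i < n; ++i) {
        key = (key % base) * alpha + q[i];
        idx[key].push_back(i - k + 1);
    }
}

// Two-hit seeding: the pair passes when some diagonal carries two exact
// k-mer matches whose offsets differ by at least k (non-overlapping).
// Sequences too short to hold two non-overlapping words pass on a
// single hit.
static bool two_hit(const KmerIndex &idx, const int *s, int m, int k,
                    int alpha, int qlen) {
    if (m < k) return false;
    std::unordered_map<int, std::pair<int, int> > diag_span; // diag -> min,max s-pos
    long long base = 1;
    for (int i = 1; i < k; ++i) base *= alpha;
    long long key = 0;
    for (int i = 0; i < k; ++i) key = key * alpha + s[i];
    bool short_seq = (qlen < 2 * k) || (m < 2 * k);
    for (int pos = 0; pos <= m - k; ++pos) {
        if (pos > 0) key = (key % base) * alpha + s[pos + k - 1];
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        if (short_seq) return true;
        const std::vector<int> &qpos = it->second;
        for (size_t t = 0; t < qpos.size(); ++t) {
            int d = pos - qpos[t];
            std::unordered_map<int, std::pair<int, int> >::iterator dit =
                diag_span.find(d);
            if (dit == diag_span.end()) {
                diag_span[d] = std::make_pair(pos, pos);
            } else {
                if (pos < dit->second.first) dit->second.first = pos;
                if (pos > dit->second.second) dit->second.second = pos;
                if (dit->second.second - dit->second.first >= k) return true;
            }
        }
    }
    return false;
}

// Seeded search of a query set against a subject set. Pairs failing the
// two-hit filter are skipped (implicit score 0); survivors get the full
// affine Smith-Waterman with traceback. Returns one row per surviving
// pair with a positive score.
// [[Rcpp::export]]
DataFrame cpp_seeded_search(List queries, List subjects, IntegerMatrix sub,
                            int gap_open, int gap_ext, int k, int alpha) {
    int nq = queries.size(), ns = subjects.size();
    std::vector<int> out_q, out_s, out_score, out_len, out_match;
    std::vector<IntegerVector> subj(ns);
    for (int j = 0; j < ns; ++j) subj[j] = as<IntegerVector>(subjects[j]);
    for (int i = 0; i < nq; ++i) {
        IntegerVector q = as<IntegerVector>(queries[i]);
        KmerIndex idx;
        build_kmer_index(INTEGER(q), q.size(), k, alpha, idx);
        for (int j = 0; j < ns; ++j) {
            const IntegerVector &s = subj[j];
            if (!two_hit(idx, INTEGER(s), s.size(), k, alpha, q.size()))
                continue;
            SwResult r = sw_core(INTEGER(q), q.size(), INTEGER(s), s.size(),
                                 sub, gap_open, gap_ext, true);
            if (r.score <= 0) continue;
            out_q.push_back(i + 1);
            out_s.push_back(j + 1);
            out_score.push_back(r.score);
            out_len.push_back(r.align_length);
            out_match.push_back(r.matches);
        }
    }
    return DataFrame::create(_["query"] = out_q, _["subject"] = out_s,
                             _["score"] = out_score,
                             _["align_length"] = out_len,
                             _["matches"] = out_match);
}
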