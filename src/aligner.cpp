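#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Exhaustive ungapped all-hits search on ONE strand: every query is given in
// the orientation of the forward reference, and every placement with at most
// k mismatches is reported (no cap, no best-hit selection).
//
// Queries are plain byte strings; mismatch = byte inequality, so the same
// code serves base space (ACGT, with reference N never equal to a read base)
// and color space (digits 0-3, with 'n' marking colors broken by an N).
//
// Strategy per (chromosome, query length): pigeonhole seeding -- partition
// the query into k+1 pieces; any placement with <= k mismatches contains at
// least one exact piece, so exact-matching the leading s bytes of each piece
// against an s-mer index of the chromosome enumerates a candidate superset,
// each candidate then verified by a full Hamming count with early exit.
// When seeds would be shorter than MIN_SEED the index buys nothing and a
// plain scan is used instead; both paths are exhaustive.

static const int MIN_SEED = 4;

struct Hit {
    int query;  // 1-based query index
    int chrom;  // 1-based chromosome index
    int start;  // 1-based leftmost position
    int nm;
    std::string mm;  // "j:R>Q;..." window offsets, 0-based
};

static void verify_and_push(const std::string &S, const std::string &q,
                            int st0 /*0-based*/, int k, int qi, int ci,
                            std::vector<Hit> &hits) {
    const int r = (int)q.size();
    int nm = 0;
    for (int j = 0; j < r; ++j) {
        if (S[st0 + j] != q[j] && ++nm > k) return;
    }
    Hit h;
    h.query = qi + 1;
    h.chrom = ci + 1;
    h.start = st0 + 1;
    h.nm = nm;
    if (nm > 0) {
        std::string mm;
        mm.reserve(nm * 8);
        for (int j = 0; j < r; ++j) {
            if (S[st0 + j] != q[j]) {
                if (!mm.empty()) mm += ';';
                mm += std::to_string(j);
                mm += ':';
                mm += S[st0 + j];
                mm += '>';
                mm += q[j];
            }
        }
        h.mm = mm;
    }
    hits.push_back(h);
}

// [[Rcpp::export]]
DataFrame cpp_align_hits(CharacterVector queries, CharacterVector chroms,
                         int k) {
    if (k < 0) stop("k must be >= 0");
    const int nq = queries.size(), nc = chroms.size();
    std::vector<std::string> Q(nq);
    for (int i = 0; i < nq; ++i) Q[i] = as<std::string>(queries[i]);

    // group query indices by length so one index serves each group
    std::unordered_map<int, std::vector<int>> by_len;
    for (int i = 0; i < nq; ++i) {
        if ((int)Q[i].size() < 1) stop("empty query");
        by_len[(int)Q[i].size()].push_back(i);
    }

    std::vector<Hit> hits;
    for (int ci = 0; ci < nc; ++ci) {
        const std::string S = as<std::string>(chroms[ci]);
        const int L = (int)S.size();
        for (auto &grp : by_len) {
            const int r = grp.first;
            if (r > L) continue;
            const int s = r / (k + 1);
            const bool use_index = (s >= MIN_SEED) && (L >= 4 * s);
            if (use_index) {
                std::unordered_map<std::string, std::vector<int>> index;
                index.reserve(L);
                for (int p = 0; p + s <= L; ++p)
                    index[S.substr(p, s)].push_back(p);
                std::vector<int> cand;
                std::unordered_set<int> seen;
                for (int qi : grp.second) {
                    const std::string &q = Q[qi];
                    cand.clear();
                    seen.clear();
                    for (int piece = 0; piece <= k; ++piece) {
                        const int off = piece * s;
                        auto it = index.find(q.substr(off, s));
                        if (it == index.end()) continue;
                        for (int p : it->second) {
                            const int st0 = p - off;
                            if (st0 < 0 || st0 + r > L) continue;
                            if (seen.insert(st0).second) cand.push_back(st0);
                        }
                    }
                    std::sort(cand.begin(), cand.end());
                    for (int st0 : cand)
                        verify_and_push(S, q, st0, k, qi, ci, hits);
                }
            } else {
                for (int qi : grp.second) {
                    const std::string &q = Q[qi];
                    for (int st0 = 0; st0 + r <= L; ++st0)
                        verify_and_push(S, q, st0, k, qi, ci, hits);
                }
            }
        }
    }

    const int n = (int)hits.size();
    IntegerVector query(n), chrom(n), start(n), nm(n);
    CharacterVector mm(n);
    for (int i = 0; i < n; ++i) {
        query[i] = hits[i].query;
        chrom[i] = hits[i].chrom;
        start[i] = hits[i].start;
        nm[i] = hits[i].nm;
        mm[i] = hits[i].mm;
    }
    return DataFrame::create(_["query"] = query, _["chrom"] = chrom,
                             _["start"] = start, _["nm"] = nm, _["mm"] = mm,
                             _["stringsAsFactors"] = false);
}
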