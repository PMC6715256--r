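#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Positional Burrows-Wheeler transform (Durbin 2014, algorithm 2) over a
// binary haplotype matrix, plus streaming maximum-shared-haplotype queries.
//
// Conventions (all 0-based internally; R wrappers are 1-based):
//  - state at "insertion column" c covers prefix columns [0, c);
//  - a: ordering of rows by reversed prefix; d[i]: start column of the
//    longest match between a[i-1] and a[i] (d[0] == c, the empty match).
//  - the match between ranks i < j starts at max(d[i+1..j]).

struct PbwtState {
    int M;
    std::vector<int> a, d, inv, a0, a1, d0, d1;
    explicit PbwtState(int M_) : M(M_), a(M_), d(M_, 0), inv(M_) {
        for (int i = 0; i < M; ++i) { a[i] = i; inv[i] = i; }
        a0.reserve(M); a1.reserve(M); d0.reserve(M); d1.reserve(M);
    }
    // incorporate column c with alleles x (by row index)
    void update(const int *x, int c) {
        a0.clear(); a1.clear(); d0.clear(); d1.clear();
        int p = c + 1, q = c + 1;
        for (int i = 0; i < M; ++i) {
            if (d[i] > p) p = d[i];
            if (d[i] > q) q = d[i];
            if (x[a[i]] == 0) {
                a0.push_back(a[i]); d0.push_back(p); p = 0;
            } else {
                a1.push_back(a[i]); d1.push_back(q); q = 0;
            }
        }
        int n0 = (int)a0.size();
        for (int i = 0; i < n0; ++i) { a[i] = a0[i]; d[i] = d0[i]; }
        for (int i = 0; i < (int)a1.size(); ++i) {
            a[n0 + i] = a1[i]; d[n0 + i] = d1[i];
        }
        for (int i = 0; i < M; ++i) inv[a[i]] = i;
    }
};

// [[Rcpp::export(name = ".pbwt_build_cpp")]]
List pbwt_build_cpp(const IntegerMatrix &X) {
    const int M = X.nrow(), N = X.ncol();
    PbwtState st(M);
    IntegerMatrix A(M, N + 1), D(M, N + 1);
    std::vector<int> col(M);
    for (int c = 0; c <= N; ++c) {
        for (int i = 0; i < M; ++i) { A(i, c) = st.a[i]; D(i, c) = st.d[i]; }
        if (c < N) {
            for (int r = 0; r < M; ++r) col[r] = X(r, c);
            st.update(col.data(), c);
        }
    }
    return List::create(_["a"] = A, _["d"] = D);
}

// Streaming msh queries. qcol: insertion column (0-based, in [0, N]);
// qrow: focal row; qexcl: rows never considered as match partners (the focal
// row is always excluded). Returns per query the match start column s
// (s == qcol means zero matched columns) and the best partner row
// (lowest row index among ties); partner = -1 when no row is allowed.
// [[Rcpp::export(name = ".pbwt_msh_query_cpp")]]
List pbwt_msh_query_cpp(const IntegerMatrix &X, const IntegerVector &qcol,
                        const IntegerVector &qrow, const List &qexcl) {
    const int M = X.nrow(), N = X.ncol(), Q = qcol.size();
    // process queries in column order
    std::vector<int> ord(Q);
    for (int i = 0; i < Q; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int i, int j) { return qcol[i] < qcol[j]; });
    IntegerVector start(Q), partner(Q);
    PbwtState st(M);
    std::vector<int> col(M);
    std::vector<char> excl(M, 0);
    int qi = 0;
    for (int c = 0; c <= N && qi < Q; ++c) {
        while (qi < Q && qcol[ord[qi]] == c) {
            int q = ord[qi];
            int r = qrow[q];
            IntegerVector ex = qexcl[q];
            for (int e = 0; e < ex.size(); ++e) excl[ex[e]] = 1;
            excl[r] = 1;
            int j = st.inv[r];
            long bestS = -1; int bestRow = -1;
            // Scan away from rank j in both directions. The running max of d
            // can only grow, so the first allowed row in a direction realizes
            // that direction's longest match; keep scanning while the running
            // max is unchanged so ties resolve to the lowest row index.
            int m = 0;
            for (int i = j; i > 0; --i) {              // toward rank 0
                if (st.d[i] > m) m = st.d[i];
                if (bestS >= 0 && m > bestS) break;
                int row = st.a[i - 1];
                if (!excl[row]) {
                    if (bestS < 0 || m < bestS) { bestS = m; bestRow = row; }
                    else if (row < bestRow) bestRow = row;
                }
            }
            m = 0;
            for (int i = j + 1; i < M; ++i) {          // toward rank M-1
                if (st.d[i] > m) m = st.d[i];
                if (bestS >= 0 && m > bestS) break;
                int row = st.a[i];
                if (!excl[row]) {
                    if (bestS < 0 || m < bestS) { bestS = m; bestRow = row; }
                    else if (row < bestRow) bestRow = row;
                }
            }
            start[q] = bestS < 0 ? NA_INTEGER : (int)bestS;
            partner[q] = bestRow;
            for (int e = 0; e < ex.size(); ++e) excl[ex[e]] = 0;
            excl[r] = 0;
            ++qi;
        }
        if (c < N) {
            for (int r = 0; r < M; ++r) col[r] = X(r, c);
            st.update(col.data(), c);
        }
    }
    return List::create(_["start"] = start, _["partner"] = partner);
}
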