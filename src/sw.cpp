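#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman over integer-encoded peptides (0..19).
// Gap of length L costs gap_open + L * gap_ext (BLAST existence/extension
// convention). Returns the optimal local score and the 1-based inclusive
// spans of one optimal alignment (ties broken towards the smallest end
// coordinates, then the longest extension back).
static void sw_one(const int *q, int m, const int *t, int n,
                   const IntegerMatrix &sub, int gap_open, int gap_ext,
                   int out[5]) {
    if (m == 0 || n == 0) {
        out[0] = 0; out[1] = out[2] = out[3] = out[4] = 0;
        return;
    }
    std::vector<int> H((m + 1) * (n + 1), 0), E(H), F(H);
    // start coordinates propagated alongside each DP state
    std::vector<int> Hs(2 * (m + 1) * (n + 1), 0), Es(Hs), Fs(Hs);
    const int NEG = -1000000;
    int best = 0, bi = 0, bj = 0, bsi = 0, bsj = 0;
    for (int i = 0; i <= m; ++i) { E[i * (n + 1)] = NEG; F[i * (n + 1)] = NEG; }
    for (int j = 0; j <= n; ++j) { E[j] = NEG; F[j] = NEG; }
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            int idx = i * (n + 1) + j;
            int up = idx - (n + 1), left = idx - 1, diag = up - 1;
            // E: gap in query (move along target)
            int open = H[left] - gap_open - gap_ext;
            int ext  = E[left] - gap_ext;
            if (open >= ext) { E[idx] = open; Es[2*idx] = Hs[2*left]; Es[2*idx+1] = Hs[2*left+1]; }
            else             { E[idx] = ext;  Es[2*idx] = Es[2*left]; Es[2*idx+1] = Es[2*left+1]; }
            // F: gap in target (move along query)
            open = H[up] - gap_open - gap_ext;
            ext  = F[up] - gap_ext;
            if (open >= ext) { F[idx] = open; Fs[2*idx] = Hs[2*up]; Fs[2*idx+1] = Hs[2*up+1]; }
            else             { F[idx] = ext;  Fs[2*idx] = Fs[2*up]; Fs[2*idx+1] = Fs[2*up+1]; }
            // H: best of stop, diagonal, E, F
            int dsc = H[diag] + sub(q[i - 1], t[j - 1]);
            int h = 0, si = i, sj = j; // fresh start at (i, j)
            if (dsc > h) {
                h = dsc;
                if (H[diag] == 0) { si = i - 1; sj = j - 1; }
                else { si = Hs[2*diag]; sj = Hs[2*diag+1]; }
            }
            if (E[idx] > h) { h = E[idx]; si = Es[2*idx]; sj = Es[2*idx+1]; }
            if (F[idx] > h) { h = F[idx]; si = Fs[2*idx]; sj = Fs[2*idx+1]; }
            H[idx] = h; Hs[2*idx] = si; Hs[2*idx+1] = sj;
            if (h > best) { best = h; bi = i; bj = j; bsi = si; bsj = sj; }
        }
    }
    out[0] = best;
    if (best > 0) { out[1] = bsi + 1; out[2] = bi; out[3] = bsj + 1; out[4] = bj; }
    else { out[1] = out[2] = out[3] = out[4] = 0; }
}

// [[Rcpp::export]]
IntegerVector sw_align_cpp(IntegerVector q, IntegerVector t, IntegerMatrix sub,
                           int gap_open, int gap_ext) {
    int out[5];
    sw_one(q.begin(), q.size(), t.begin(), t.size(), sub, gap_open, gap_ext, out);
    return IntegerVector(out, out + 5);
}

// [[Rcpp::export]]
IntegerMatrix sw_batch_cpp(IntegerVector q, List targets, IntegerMatrix sub,
                           int gap_open, int gap_ext) {
    int nt = targets.size();
    IntegerMatrix res(nt, 5);
    int out[5];
    for (int k = 0; k < nt; ++k) {
        IntegerVector t = targets[k];
        sw_one(q.begin(), q.size(), t.begin(), t.size(), sub, gap_open, gap_ext, out);
        for (int c = 0; c < 5; ++c) res(k, c) = out[c];
    }
    return res;
}
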