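#include <Rcpp.h>
using namespace Rcpp;

// Weighted Nussinov folding for short stem-loop windows (DNA alphabet,
// T plays the role of U). Pair weights: GC=3, AU=2, GU=1.

static inline int pair_weight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
    return 0;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop) {
    const int n = (int) seq.size();
    if (n == 0) {
        return List::create(_["score"] = 0,
                            _["pairs"] = IntegerMatrix(0, 2));
    }
    // S[i][j]: best weighted pairing score of subsequence i..j (0-based)
    std::vector< std::vector<int> > S(n, std::vector<int>(n, 0));
    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = S[i + 1][j];                 // i unpaired
            if (S[i][j - 1] > best) best = S[i][j - 1];  // j unpaired
            int w = pair_weight(seq[i], seq[j]);
            if (w > 0 && j - i > min_loop) {
                int v = S[i + 1][j - 1] + w;
                if (v > best) best = v;
            }
            for (int k = i + 1; k < j; ++k) {       // bifurcation
                int v = S[i][k] + S[k + 1][j];
                if (v > best) best = v;
            }
            S[i][j] = best;
        }
    }

    // Traceback, preferring the pairing branch so long complementary runs
    // come out as contiguous helices.
    std::vector< std::pair<int,int> > pairs;
    std::vector< std::pair<int,int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j || j - i <= min_loop) continue;
        int s = S[i][j];
        if (s == 0) continue;
        int w = pair_weight(seq[i], seq[j]);
        if (w > 0 && j - i > min_loop && s == S[i + 1][j - 1] + w) {
            pairs.push_back(std::make_pair(i + 1, j + 1));  // 1-based
            stack.push_back(std::make_pair(i + 1, j - 1));
            continue;
        }
        if (s == S[i + 1][j]) { stack.push_back(std::make_pair(i + 1, j)); continue; }
        if (s == S[i][j - 1]) { stack.push_back(std::make_pair(i, j - 1)); continue; }
        bool done = false;
        for (int k = i + 1; k < j && !done; ++k) {
            if (s == S[i][k] + S[k + 1][j]) {
                stack.push_back(std::make_pair(i, k));
                stack.push_back(std::make_pair(k + 1, j));
                done = true;
            }
        }
    }
    IntegerMatrix pm((int) pairs.size(), 2);
    for (size_t r = 0; r < pairs.size(); ++r) {
        pm(r, 0) = pairs[r].first;
        pm(r, 1) = pairs[r].second;
    }
    return List::create(_["score"] = S[0][n - 1], _["pairs"] = pm);
}

// Leftmost 3'-adapter occurrence allowing <= max_mismatch substitutions over
// the aligned adapter prefix; minimum overlap enforced at the read 3' end.
// Returns the 1-based start of the adapter match, or 0 if none.

// [[Rcpp::export(name = ".find_adapter_start")]]
IntegerVector find_adapter_start(CharacterVector reads, std::string adapter,
                                 int max_mismatch, int min_overlap) {
    const int alen = (int) adapter.size();
    IntegerVector out(reads.size());
    for (int r = 0; r < reads.size(); ++r) {
        std::string rd = as<std::string>(reads[r]);
        const int n = (int) rd.size();
        int hit = 0;
        for (int p = 0; p + min_overlap <= n; ++p) {
            int ov = std::min(alen, n - p);
            int mm = 0;
            for (int q = 0; q < ov && mm <= max_mismatch; ++q) {
                if (rd[p + q] != adapter[q]) ++mm;
            }
            if (mm <= max_mismatch) { hit = p + 1; break; }
        }
        out[r] = hit;
    }
    return out;
}
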