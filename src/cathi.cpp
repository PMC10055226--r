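#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right tract tokenizer over one window of sequence.
//
// A tract opens at each G that begins a run of >= 4 consecutive G/T
// characters. Extension stops (inclusive) at the first T of a TT pair or
// at the third G of a run of >= 4 consecutive Gs; scanning resumes at the
// character immediately after the stop point, so one G/T run can yield
// several tracts. Tracts shorter than 4 after truncation, or containing
// no T (all-G), are discarded. Any character other than G/T breaks runs.
static void find_tracts(const char* s, int n,
                        std::vector<int>& starts, std::vector<int>& ends) {
  int i = 0;
  while (i < n) {
    if (s[i] != 'G') { ++i; continue; }
    int j = i;  // end (exclusive) of the G/T run containing i
    while (j < n && (s[j] == 'G' || s[j] == 'T')) ++j;
    if (j - i < 4) { i = j; continue; }  // later Gs in this run are shorter
    int stop = -1;  // inclusive index of last tract char; -1 = run end
    int grun = 1;   // s[i] == 'G'
    for (int k = i + 1; k < j; ++k) {
      if (s[k] == 'T') {
        grun = 0;
        if (k + 1 < j && s[k + 1] == 'T') { stop = k; break; }  // first T of TT
      } else {
        if (++grun == 4) { stop = k - 1; break; }               // third G
      }
    }
    int end = (stop >= 0) ? stop + 1 : j;  // exclusive
    bool hasT = false;
    for (int k = i; k < end; ++k) if (s[k] == 'T') { hasT = true; break; }
    if (end - i >= 4 && hasT) { starts.push_back(i); ends.push_back(end); }
    i = end;  // resume at the character after the stop point
  }
}

static double score_chunk(const char* s, int n,
                          double ggtgg_penalty, double tt_penalty) {
  std::vector<int> st, en;
  find_tracts(s, n, st, en);
  double score = 0.0;
  for (size_t q = 0; q < st.size(); ++q) score += en[q] - st[q];
  if (ggtgg_penalty != 0.0) {
    int npen = 0;  // overlapping occurrences count ("GGTGGTGG" -> 2)
    for (int k = 0; k + 5 <= n; ++k)
      if (s[k] == 'G' && s[k + 1] == 'G' && s[k + 2] == 'T' &&
          s[k + 3] == 'G' && s[k + 4] == 'G') ++npen;
    score -= ggtgg_penalty * npen;
  }
  if (tt_penalty != 0.0) {
    int nt = 0;  // one deduction per T immediately flanking a tract
    for (size_t q = 0; q < st.size(); ++q) {
      if (st[q] > 0 && s[st[q] - 1] == 'T') ++nt;
      if (en[q] < n && s[en[q]] == 'T') ++nt;
    }
    score -= tt_penalty * nt;
  }
  return score;
}

// [[Rcpp::export]]
List cpp_tokenize(std::string seq) {
  std::vector<int> st, en;
  find_tracts(seq.c_str(), (int) seq.size(), st, en);
  return List::create(_["start"] = wrap(st), _["end"] = wrap(en));
}

// [[Rcpp::export]]
double cpp_score_window(std::string seq, double ggtgg_penalty,
                        double tt_penalty) {
  return score_chunk(seq.c_str(), (int) seq.size(), ggtgg_penalty, tt_penalty);
}

// Scores of all full windows (stride = step); a sequence shorter than the
// window is scored whole as a single window.
// [[Rcpp::export]]
NumericVector cpp_scan(std::string seq, int window, int step,
                       double ggtgg_penalty, double tt_penalty) {
  int n = (int) seq.size();
  const char* s = seq.c_str();
  if (n < window)
    return NumericVector::create(score_chunk(s, n, ggtgg_penalty, tt_penalty));
  int m = (n - window) / step + 1;
  NumericVector out(m);
  for (int idx = 0; idx < m; ++idx)
    out[idx] = score_chunk(s + (R_xlen_t) idx * step, window,
                           ggtgg_penalty, tt_penalty);
  return out;
}
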