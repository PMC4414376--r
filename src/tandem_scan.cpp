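#include <Rcpp.h>
using namespace Rcpp;

// Maximal runs of positions i (0-based) where seq[i] == seq[i + k] and neither
// byte is 'N'. A run of length L starting at i corresponds to a tandem region
// seq[i .. i + L + k - 1] whose minimal period divides k. Only runs with
// L >= min_run are returned; interpretation (unit truncation, irreducibility,
// per-motif-length minima) happens on the R side.
// [[Rcpp::export]]
IntegerMatrix eq_runs(RawVector seq, int k, int min_run) {
  const int n = seq.size();
  std::vector<int> starts, lens;
  if (n > k) {
    int run = 0;
    for (int i = 0; i + k < n; ++i) {
      unsigned char a = seq[i], b = seq[i + k];
      bool eq = (a == b) && a != 'N' && a != 'n';
      if (eq) {
        ++run;
      } else if (run > 0) {
        if (run >= min_run) { starts.push_back(i - run); lens.push_back(run); }
        run = 0;
      }
    }
    if (run >= min_run) { starts.push_back(n - k - run); lens.push_back(run); }
  }
  IntegerMatrix out(starts.size(), 2);
  for (size_t j = 0; j < starts.size(); ++j) {
    out(j, 0) = starts[j] + 1;  // 1-based for R
    out(j, 1) = lens[j];
  }
  colnames(out) = CharacterVector::create("start", "len");
  return out;
}

// Overlapping count of a 2-byte pattern (e.g. "CG") in seq, skipping nothing:
// the caller is responsible for N handling semantics.
// [[Rcpp::export]]
int count_dinucleotide(RawVector seq, RawVector pat) {
  const int n = seq.size();
  if (pat.size() != 2 || n < 2) return 0;
  const unsigned char p0 = pat[0], p1 = pat[1];
  int cnt = 0;
  for (int i = 0; i + 1 < n; ++i)
    if (seq[i] == p0 && seq[i + 1] == p1) ++cnt;
  return cnt;
}
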