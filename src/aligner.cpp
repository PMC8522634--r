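#include <Rcpp.h>
using namespace Rcpp;

static char comp(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp(out[i]);
  return out;
}

// Exhaustive gapless placement of each read (and its reverse complement)
// within a single reference. Returns, per read, the minimum-mismatch
// placement with tie-break (smaller start, then '+' strand) and the number
// of placements achieving the minimum (for the uniqueness-based mapq
// proxy). Reads longer than the reference get start = NA.
// [[Rcpp::export]]
DataFrame gapless_align_cpp(CharacterVector seqs, std::string ref) {
  const int n = seqs.size();
  const int L = ref.size();
  IntegerVector start(n), mismatch(n), n_best(n);
  CharacterVector strand(n), seq_ref(n);

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(seqs[i]);
    int rl = fwd.size();
    if (rl == 0 || rl > L) {
      start[i] = NA_INTEGER; mismatch[i] = NA_INTEGER;
      n_best[i] = NA_INTEGER; strand[i] = NA_STRING; seq_ref[i] = NA_STRING;
      continue;
    }
    std::string rev = revcomp_str(fwd);
    int best_mm = rl + 1, best_start = -1, count = 0;
    char best_strand = '+';
    for (int s = 0; s <= L - rl; ++s) {
      for (int k = 0; k < 2; ++k) {
        const std::string& q = (k == 0) ? fwd : rev;
        int mm = 0;
        for (int j = 0; j < rl && mm < best_mm + 1; ++j)
          if (q[j] != ref[s + j]) ++mm;
        if (mm < best_mm) {
          best_mm = mm; best_start = s; best_strand = (k == 0) ? '+' : '-';
          count = 1;
        } else if (mm == best_mm) {
          ++count;
        }
      }
    }
    start[i] = best_start + 1;
    mismatch[i] = best_mm;
    n_best[i] = count;
    strand[i] = std::string(1, best_strand);
    seq_ref[i] = (best_strand == '+') ? fwd : rev;
  }
  return DataFrame::create(_["start"] = start, _["strand"] = strand,
                           _["mismatch_count"] = mismatch,
                           _["n_best"] = n_best,
                           _["seq_ref"] = seq_ref,
                           _["stringsAsFactors"] = false);
}
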