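#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Ungapped placement of short reads against a reference sequence.
// 'N' (either side) always counts as a mismatch.

static inline char comp_base(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// Best (fewest-mismatch) ungapped offset of `read` on `ref`, one strand.
// Early exit per offset once the running best cannot be beaten.
static int best_mm_one_strand(const std::string& read, const std::string& ref,
                              int best_in) {
  const int r = (int) read.size(), L = (int) ref.size();
  int best = best_in;
  for (int off = 0; off + r <= L; ++off) {
    int mm = 0;
    for (int i = 0; i < r; ++i) {
      char a = read[i], b = ref[off + i];
      if (a != b || a == 'N') {
        if (++mm >= best) break;
      }
    }
    if (mm < best) best = mm;
    if (best == 0) break;
  }
  return best;
}

// Mismatches of `read` at a fixed offset, early-exiting at `bound`.
static int mm_at_offset(const std::string& read, const std::string& ref,
                        int off, int bound) {
  const int r = (int) read.size();
  int mm = 0;
  for (int i = 0; i < r; ++i) {
    char a = read[i], b = ref[off + i];
    if (a != b || a == 'N') {
      if (++mm >= bound) return bound;
    }
  }
  return mm;
}

// Best offset variant that also reports where the minimum was found.
static int best_mm_track(const std::string& read, const std::string& ref,
                         int best_in, int* best_off) {
  const int r = (int) read.size(), L = (int) ref.size();
  int best = best_in;
  for (int off = 0; off + r <= L; ++off) {
    int mm = mm_at_offset(read, ref, off, best);
    if (mm < best) { best = mm; *best_off = off; }
    if (best == 0) break;
  }
  return best;
}

//' @name pair_allele_mismatches
//' @title Per-mate mismatch counts against two alleles
//' @description For each read pair, places both mates at their best ungapped
//'   offset (both strands) on each allele and returns the pair-total mismatch
//'   counts. Counts are exact up to `max_mm` per mate and clamped at
//'   `max_mm + 1` beyond it (such reads fail any sensible score gate, so the
//'   clamp never changes downstream decisions). The search on the second
//'   allele is seeded with the first allele's best placement, which is cheap
//'   and exact because the scan still visits every offset. `NA` marks pairs
//'   with a mate longer than an allele.
//' @param r1,r2 character vectors of mate sequences
//' @param surface,cave allele sequences
//' @param max_mm per-mate exactness cap
//' @return integer matrix, columns `surface` and `cave`, one row per pair
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix pair_allele_mismatches(CharacterVector r1, CharacterVector r2,
                                     std::string surface, std::string cave,
                                     int max_mm) {
  const int n = r1.size();
  IntegerMatrix out(n, 2);
  colnames(out) = CharacterVector::create("surface", "cave");
  const int Ls = (int) surface.size(), Lc = (int) cave.size();
  for (int k = 0; k < n; ++k) {
    int tot_s = 0, tot_c = 0;
    bool ok = true;
    for (int mate = 0; mate < 2 && ok; ++mate) {
      std::string rd = as<std::string>(mate == 0 ? r1[k] : r2[k]);
      const int r = (int) rd.size();
      if (r == 0 || r > Ls || r > Lc) { ok = false; break; }
      std::string rc = revcomp(rd);
      int cap = max_mm + 1;
      int off_f = -1, off_r = -1;
      int best_f = best_mm_track(rd, surface, cap, &off_f);
      int best_r = best_mm_track(rc, surface, cap, &off_r);
      int mm_s = std::min(best_f, best_r);
      // seed the cave search from the surface placement (same strand)
      int seed = cap;
      if (best_f <= best_r && off_f >= 0 && off_f + r <= Lc)
        seed = mm_at_offset(rd, cave, off_f, cap);
      else if (best_r < best_f && off_r >= 0 && off_r + r <= Lc)
        seed = mm_at_offset(rc, cave, off_r, cap);
      int dummy = -1;
      int mm_c = std::min(seed, cap);
      mm_c = best_mm_track(rd, cave, mm_c, &dummy);
      mm_c = best_mm_track(rc, cave, mm_c, &dummy);
      tot_s += std::min(mm_s, cap);
      tot_c += std::min(mm_c, cap);
    }
    if (ok) { out(k, 0) = tot_s; out(k, 1) = tot_c; }
    else { out(k, 0) = NA_INTEGER; out(k, 1) = NA_INTEGER; }
  }
  return out;
}

//' @name align_reads_ungapped
//' @title Mismatch count of each read at its best ungapped offset
//' @description For each read, scans every ungapped offset on both strands of
//'   the reference and returns the minimum mismatch count, or NA when the read
//'   is longer than the reference. Internal workhorse for allele likelihoods.
//' @param reads character vector of read sequences (A/C/G/T/N)
//' @param ref single reference sequence
//' @return integer vector of per-read minimum mismatch counts
//' @keywords internal
// [[Rcpp::export]]
IntegerVector align_reads_ungapped(CharacterVector reads, std::string ref) {
  const int n = reads.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string rd = as<std::string>(reads[k]);
    if ((int) rd.size() > (int) ref.size() || rd.size() == 0) {
      out[k] = NA_INTEGER;
      continue;
    }
    int best = (int) rd.size() + 1;
    best = best_mm_one_strand(rd, ref, best);
    best = best_mm_one_strand(revcomp(rd), ref, best);
    out[k] = best;
  }
  return out;
}
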