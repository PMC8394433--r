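#include <Rcpp.h>
#include <climits>
#include <cstring>
using namespace Rcpp;

// Sequence kernels for flank anchoring. Patterns (flanks) are short
// (typically 20 nt) and reads are short (typically 150 nt), so a full
// affine-gap Smith-Waterman per read is cheap in C.

static inline char upbase(char c) {
  if (c >= 'a' && c <= 'z') c = (char)(c - 'a' + 'A');
  return c;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Best local alignment of `pattern` against each read.
// Gap of length L costs gap_open + L * gap_extend (the
// Biostrings::pairwiseAlignment convention). Any base outside ACGT scores
// as a mismatch. Returns the best score and the 1-based start/end of the
// aligned region ON THE READ; ties resolve to the first cell reached in
// (read position, pattern position) order, so results are deterministic.
// [[Rcpp::export(name = ".sw_batch")]]
DataFrame sw_batch(CharacterVector reads, std::string pattern,
                   int match, int mismatch, int gap_open, int gap_extend) {
  const int NEG = INT_MIN / 4;
  int nreads = reads.size();
  int m = (int)pattern.size();
  if (m < 1) stop("empty pattern");
  std::string pat(pattern);
  for (int i = 0; i < m; ++i) pat[i] = upbase(pat[i]);

  IntegerVector score(nreads), st(nreads), en(nreads);

  // column state indexed by pattern position i (1..m)
  std::vector<int> Hprev(m + 1), Eprev(m + 1), Hcur(m + 1);
  std::vector<int> SHprev(m + 1), SEprev(m + 1), SHcur(m + 1);

  for (int r = 0; r < nreads; ++r) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    int n = (int)std::strlen(rd);
    int best = 0, best_st = NA_INTEGER, best_en = NA_INTEGER;

    std::fill(Hprev.begin(), Hprev.end(), 0);
    std::fill(Eprev.begin(), Eprev.end(), NEG);
    std::fill(SHprev.begin(), SHprev.end(), 0);
    std::fill(SEprev.begin(), SEprev.end(), 0);

    for (int j = 1; j <= n; ++j) {
      char cj = upbase(rd[j - 1]);
      bool okj = is_acgt(cj);
      Hcur[0] = 0;
      SHcur[0] = 0;
      int F = NEG, SF = 0; // gap consuming pattern, runs down column j
      for (int i = 1; i <= m; ++i) {
        // E: gap consuming read (from column j-1, same row)
        int e_open = Hprev[i] - gap_open - gap_extend;
        int e_ext = Eprev[i] - gap_extend;
        int e, se;
        if (e_open >= e_ext) { e = e_open; se = SHprev[i]; }
        else { e = e_ext; se = SEprev[i]; }

        // F: gap consuming pattern (from row i-1, same column)
        int f_open = Hcur[i - 1] - gap_open - gap_extend;
        int f_ext = F - gap_extend;
        if (f_open >= f_ext) { F = f_open; SF = SHcur[i - 1]; }
        else { F = f_ext; }

        int s = (okj && pat[i - 1] == cj) ? match : -mismatch;
        int diag = Hprev[i - 1] + s;
        int sdiag = (Hprev[i - 1] > 0) ? SHprev[i - 1] : j;

        int h = diag, sh = sdiag;       // priority: diag > E > F
        if (e > h) { h = e; sh = se; }
        if (F > h) { h = F; sh = SF; }
        if (h < 0) { h = 0; sh = 0; }

        Hcur[i] = h;
        SHcur[i] = sh;
        Eprev[i] = e;
        SEprev[i] = se;

        if (h > best) { best = h; best_st = sh; best_en = j; }
      }
      std::swap(Hprev, Hcur);
      std::swap(SHprev, SHcur);
    }
    score[r] = best;
    st[r] = best_st;
    en[r] = best_en;
  }
  return DataFrame::create(_["score"] = score, _["start"] = st, _["end"] = en);
}

static inline int code2(char c) {
  switch (upbase(c)) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// TRUE where the read contains an exact seed_len-mer of `flank`.
// Seeds are 2-bit packed into a lookup table and each read is scanned once
// with a rolling code. seed_len is capped at 12 (table of 4^12 bits).
// [[Rcpp::export(name = ".seed_hits")]]
LogicalVector seed_hits(CharacterVector reads, std::string flank, int seed_len) {
  int nreads = reads.size();
  LogicalVector out(nreads);
  int m = (int)flank.size();
  if (seed_len < 1 || seed_len > m) {
    std::fill(out.begin(), out.end(), true);
    return out;
  }
  if (seed_len > 12) seed_len = 12;
  const unsigned mask = (1u << (2 * seed_len)) - 1u;
  std::vector<bool> table(mask + 1u, false);
  {
    unsigned code = 0;
    int run = 0;
    for (int i = 0; i < m; ++i) {
      int b = code2(flank[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (unsigned)b) & mask;
      if (++run >= seed_len) table[code] = true;
    }
  }
  for (int r = 0; r < nreads; ++r) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    bool hit = false;
    unsigned code = 0;
    int run = 0;
    for (int j = 0; rd[j]; ++j) {
      int b = code2(rd[j]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (unsigned)b) & mask;
      if (++run >= seed_len && table[code]) { hit = true; break; }
    }
    out[r] = hit;
  }
  return out;
}

// Longest run of `base` and total count of `base` per sequence.
// [[Rcpp::export(name = ".run_stats")]]
DataFrame run_stats(CharacterVector seqs, std::string base) {
  if (base.size() != 1) stop("base must be a single character");
  char b = upbase(base[0]);
  int n = seqs.size();
  IntegerVector run(n), count(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int best = 0, cur = 0, cnt = 0;
    for (int j = 0; s[j]; ++j) {
      if (upbase(s[j]) == b) {
        ++cnt;
        if (++cur > best) best = cur;
      } else cur = 0;
    }
    run[r] = best;
    count[r] = cnt;
  }
  return DataFrame::create(_["run"] = run, _["count"] = count);
}

// Reverse complement (A<->T, C<->G; anything else -> N).
// [[Rcpp::export(name = ".revcomp")]]
CharacterVector revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int len = (int)std::strlen(s);
    std::string rc(len, 'N');
    for (int j = 0; j < len; ++j) {
      char c = upbase(s[len - 1 - j]);
      switch (c) {
        case 'A': rc[j] = 'T'; break;
        case 'T': rc[j] = 'A'; break;
        case 'C': rc[j] = 'G'; break;
        case 'G': rc[j] = 'C'; break;
        default: rc[j] = 'N';
      }
    }
    out[r] = rc;
  }
  return out;
}
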