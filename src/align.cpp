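#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// IUPAC nucleotide bit masks: A=1, C=2, G=4, T=8; degenerate codes are unions.
// N in a *read* is given mask 0 so it matches nothing (counts as mismatch).
static inline int iupac_mask(char c, bool read_context) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    case 'N': case 'n': return read_context ? 0 : 15;
    default: return 0;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

// Mismatch count between the 5' window of each read and an IUPAC primer.
// Reads shorter than the primer get primer_length + 1 (guaranteed rejection).
// [[Rcpp::export]]
IntegerVector cpp_primer_mismatch(CharacterVector reads, std::string primer) {
  int n = reads.size(), plen = primer.size();
  std::vector<int> pmask(plen);
  for (int j = 0; j < plen; ++j) pmask[j] = iupac_mask(primer[j], false);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (reads[i] == NA_STRING) { out[i] = plen + 1; continue; }
    const char *s = CHAR(STRING_ELT(reads, i));
    int len = std::strlen(s);
    if (len < plen) { out[i] = plen + 1; continue; }
    int mm = 0;
    for (int j = 0; j < plen; ++j)
      if (!(pmask[j] & iupac_mask(s[j], true))) ++mm;
    out[i] = mm;
  }
  return out;
}

// Arithmetic mean of Phred scores encoded as Phred+33 strings; NA for empty.
// [[Rcpp::export]]
NumericVector cpp_mean_phred(CharacterVector quals) {
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (quals[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char *s = CHAR(STRING_ELT(quals, i));
    int len = std::strlen(s);
    if (len == 0) { out[i] = NA_REAL; continue; }
    long sum = 0;
    for (int j = 0; j < len; ++j) sum += s[j] - 33;
    out[i] = (double) sum / len;
  }
  return out;
}

// Merge read pairs by scanning candidate overlap lengths.  The reverse mate is
// reverse-complemented internally.  Score = overlap identity (matches /
// overlap length, N matching nothing); the best-identity overlap of at least
// min_identity is accepted, ties broken towards the longest overlap.
// Consensus in the overlap takes the base with the higher Phred score, ties
// going to the forward base.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fwd, CharacterVector fwd_qual,
                     CharacterVector rev, CharacterVector rev_qual,
                     int min_overlap, int max_overlap, double min_identity) {
  int n = fwd.size();
  CharacterVector seq(n);
  IntegerVector overlap(n);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    seq[i] = NA_STRING; overlap[i] = NA_INTEGER; ok[i] = false;
    if (fwd[i] == NA_STRING || rev[i] == NA_STRING) continue;
    std::string f = as<std::string>(fwd[i]);
    std::string fq = as<std::string>(fwd_qual[i]);
    std::string r = as<std::string>(rev[i]);
    std::string rq = as<std::string>(rev_qual[i]);
    int lf = f.size(), lr = r.size();
    if (lf == 0 || lr == 0) continue;
    // reverse complement the reverse mate (and reverse its qualities)
    std::string rc(lr, 'N'), rcq(lr, '!');
    for (int j = 0; j < lr; ++j) {
      rc[j] = comp_base(r[lr - 1 - j]);
      rcq[j] = rq[lr - 1 - j];
    }
    int hi = std::min(std::min(lf, lr), max_overlap);
    double best_ident = -1.0;
    int best_o = -1;
    for (int o = min_overlap; o <= hi; ++o) {
      int matches = 0;
      const char *fs = f.c_str() + (lf - o);
      for (int j = 0; j < o; ++j) {
        char a = fs[j], b = rc[j];
        if (a == b && (a == 'A' || a == 'C' || a == 'G' || a == 'T')) ++matches;
      }
      double ident = (double) matches / o;
      if (ident >= min_identity && ident >= best_ident) {
        // >= on equal identity prefers the longer (later) overlap
        best_ident = ident; best_o = o;
      }
    }
    if (best_o < 0) continue;
    int o = best_o;
    std::string merged = f.substr(0, lf - o);
    for (int j = 0; j < o; ++j) {
      char a = f[lf - o + j], b = rc[j];
      char qa = fq[lf - o + j], qb = rcq[j];
      merged.push_back(qb > qa ? b : a);
    }
    merged += rc.substr(o);
    seq[i] = merged;
    overlap[i] = o;
    ok[i] = true;
  }
  return List::create(_["seq"] = seq, _["overlap"] = overlap, _["ok"] = ok);
}

// Local (Smith-Waterman) alignment with affine gaps of each read against one
// reference.  A gap of length L costs gap_open + (L-1)*gap_ext.  Returns per
// read: score, identity (matches / alignment columns, gap columns included in
// the denominator) and coverage (read positions aligned / read length).
// Integer DP with a packed traceback byte per cell:
// bits 0-1 = M predecessor state, bits 2-3 = X, bits 4-5 = Y.
// [[Rcpp::export]]
NumericMatrix cpp_sw_batch(CharacterVector reads, std::string ref,
                           int match, int mismatch,
                           int gap_open, int gap_ext) {
  const int NEG = INT_MIN / 4;
  int nref = ref.size();
  int nreads = reads.size();
  NumericMatrix out(nreads, 3);
  colnames(out) = CharacterVector::create("score", "identity", "coverage");
  auto code = [](char c) -> int {
    switch (c) {
      case 'A': case 'a': return 0;
      case 'C': case 'c': return 1;
      case 'G': case 'g': return 2;
      case 'T': case 't': return 3;
      default: return 4;  // N / anything else: never a match
    }
  };
  std::vector<int> rv(nref);
  for (int j = 0; j < nref; ++j) rv[j] = code(ref[j]);

  std::vector<int> Mp, Xp, Yp, Mc, Xc, Yc, qv;
  std::vector<unsigned char> tb;

  for (int ri = 0; ri < nreads; ++ri) {
    if (reads[ri] == NA_STRING) { out(ri,0)=0; out(ri,1)=0; out(ri,2)=0; continue; }
    const char *qs = CHAR(STRING_ELT(reads, ri));
    int nq = std::strlen(qs);
    if (nq == 0 || nref == 0) { out(ri,0)=0; out(ri,1)=0; out(ri,2)=0; continue; }
    qv.assign(nq, 4);
    for (int i = 0; i < nq; ++i) qv[i] = code(qs[i]);

    Mp.assign(nref + 1, 0); Xp.assign(nref + 1, NEG); Yp.assign(nref + 1, NEG);
    Mc.assign(nref + 1, 0); Xc.assign(nref + 1, NEG); Yc.assign(nref + 1, NEG);
    tb.assign((size_t)(nq + 1) * (nref + 1), 0);
    int best = 0, bi = -1, bj = -1;

    for (int i = 1; i <= nq; ++i) {
      int *M = Mc.data(), *X = Xc.data(), *Y = Yc.data();
      const int *Mq = Mp.data(), *Xq = Xp.data(), *Yq = Yp.data();
      unsigned char *trow = tb.data() + (size_t) i * (nref + 1);
      M[0] = 0; X[0] = NEG; Y[0] = NEG;
      const int qc = qv[i - 1];
      for (int j = 1; j <= nref; ++j) {
        const int s = (qc == rv[j - 1] && qc < 4) ? match : mismatch;
        int bestpre = 0; unsigned char from = 0;
        if (Mq[j - 1] > bestpre) { bestpre = Mq[j - 1]; from = 1; }
        if (Xq[j - 1] > bestpre) { bestpre = Xq[j - 1]; from = 2; }
        if (Yq[j - 1] > bestpre) { bestpre = Yq[j - 1]; from = 3; }
        int mval = bestpre + s;
        if (mval < 0) { mval = NEG; from = 0; }
        M[j] = mval;
        const int xm = Mq[j] - gap_open, xx = Xq[j] - gap_ext;
        unsigned char xf;
        if (xm >= xx) { X[j] = xm; xf = 1; } else { X[j] = xx; xf = 2; }
        const int ym = M[j - 1] - gap_open, yy = Y[j - 1] - gap_ext;
        unsigned char yf;
        if (ym >= yy) { Y[j] = ym; yf = 1; } else { Y[j] = yy; yf = 3; }
        trow[j] = from | (xf << 2) | (yf << 4);
        if (mval > best) { best = mval; bi = i; bj = j; }
      }
      std::swap(Mc, Mp); std::swap(Xc, Xp); std::swap(Yc, Yp);
    }

    if (best <= 0 || bi < 0) { out(ri,0)=0; out(ri,1)=0; out(ri,2)=0; continue; }
    // walk back from the best cell in state M
    int i = bi, j = bj, state = 1;
    long matches = 0, cols = 0, read_cols = 0;
    while (state != 0) {
      unsigned char t = tb[(size_t) i * (nref + 1) + j];
      if (state == 1) {
        if (qv[i - 1] == rv[j - 1] && qv[i - 1] < 4) ++matches;
        ++cols; ++read_cols;
        state = t & 3;
        --i; --j;
      } else if (state == 2) {
        ++cols; ++read_cols;
        state = (t >> 2) & 3;
        --i;
      } else {
        ++cols;
        state = (t >> 4) & 3;
        --j;
      }
    }
    out(ri, 0) = best;
    out(ri, 1) = cols > 0 ? (double) matches / cols : 0.0;
    out(ri, 2) = (double) read_cols / nq;
  }
  return out;
}

// Shared k-mer counts between each read and each reference: the number of
// k-mer positions in the read whose k-mer occurs anywhere in the reference.
// k-mers containing non-ACGT characters are skipped.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_screen(CharacterVector reads, CharacterVector refs, int k) {
  int nreads = reads.size(), nrefs = refs.size();
  size_t nk = (size_t) 1 << (2 * k);
  std::vector<std::vector<bool>> refset(nrefs, std::vector<bool>(nk, false));
  auto code2 = [](char c) -> int {
    switch (c) {
      case 'A': case 'a': return 0;
      case 'C': case 'c': return 1;
      case 'G': case 'g': return 2;
      case 'T': case 't': return 3;
      default: return -1;
    }
  };
  for (int r = 0; r < nrefs; ++r) {
    if (refs[r] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(refs, r));
    int len = std::strlen(s);
    size_t kmer = 0; int valid = 0;
    size_t mask = nk - 1;
    for (int j = 0; j < len; ++j) {
      int c = code2(s[j]);
      if (c < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | c) & mask;
      if (++valid >= k) refset[r][kmer] = true;
    }
  }
  IntegerMatrix out(nreads, nrefs);
  for (int i = 0; i < nreads; ++i) {
    if (reads[i] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(reads, i));
    int len = std::strlen(s);
    size_t kmer = 0; int valid = 0;
    size_t mask = nk - 1;
    for (int j = 0; j < len; ++j) {
      int c = code2(s[j]);
      if (c < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | c) & mask;
      if (++valid >= k)
        for (int r = 0; r < nrefs; ++r)
          if (refset[r][kmer]) ++out(i, r);
    }
  }
  return out;
}
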