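#include <Rcpp.h>
#include <cstdint>
#include <string>
using namespace Rcpp;

// 2-bit base packing: A=0, C=1, G=2, T=3. A k-mer is stored as
// sum(code[i] * 4^(k-1-i)), computed in uint64 and returned as a double
// (exact for k <= 26, since 4^26 < 2^53); numeric order of codes equals
// lexicographic order of the k-mer strings.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char code_base(int b) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  return bases[b];
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export(name = ".encode_windows_cpp")]]
List encode_windows_cpp(CharacterVector seqs, int k) {
  const R_xlen_t ns = seqs.size();
  const uint64_t mask = (k > 1) ? ((1ULL << (2 * (k - 1))) - 1ULL) : 0ULL;
  R_xlen_t total = 0;
  IntegerVector nwin(ns);
  for (R_xlen_t i = 0; i < ns; ++i) {
    const R_xlen_t len = LENGTH(STRING_ELT(seqs, i));
    const R_xlen_t n = len >= k ? len - k + 1 : 0;
    nwin[i] = (int) n;
    total += n;
  }
  NumericVector out(total);
  R_xlen_t pos = 0;
  for (R_xlen_t i = 0; i < ns; ++i) {
    if (nwin[i] == 0) continue;
    const char* s = CHAR(STRING_ELT(seqs, i));
    const R_xlen_t len = LENGTH(STRING_ELT(seqs, i));
    uint64_t code = 0;
    R_xlen_t last_bad = -1;
    for (R_xlen_t j = 0; j < len; ++j) {
      const int b = base_code(s[j]);
      if (b < 0) { last_bad = j; code = (code & mask) << 2; }
      else       { code = ((code & mask) << 2) | (uint64_t) b; }
      if (j >= k - 1) {
        const R_xlen_t w = j - k + 1;       // window start (0-based)
        out[pos++] = (last_bad >= w) ? NA_REAL : (double) code;
      }
    }
  }
  return List::create(_["codes"] = out, _["n"] = nwin);
}

// window code at a fixed 1-based start per sequence (starts recycled if
// length 1); NA when the window falls outside the sequence or holds a
// non-ACGT base
// [[Rcpp::export(name = ".encode_at_cpp")]]
NumericVector encode_at_cpp(CharacterVector seqs, IntegerVector starts, int k) {
  const R_xlen_t ns = seqs.size();
  NumericVector out(ns);
  for (R_xlen_t i = 0; i < ns; ++i) {
    const int start = starts.size() == 1 ? starts[0] : starts[i];
    const char* s = CHAR(STRING_ELT(seqs, i));
    const R_xlen_t len = LENGTH(STRING_ELT(seqs, i));
    if (start < 1 || start + k - 1 > len) { out[i] = NA_REAL; continue; }
    uint64_t code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      const int b = base_code(s[start - 1 + j]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | (uint64_t) b;
    }
    out[i] = ok ? (double) code : NA_REAL;
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_codes_cpp")]]
NumericVector revcomp_codes_cpp(NumericVector codes, int k) {
  const R_xlen_t n = codes.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_REAL; continue; }
    uint64_t code = (uint64_t) codes[i], rc = 0;
    for (int j = 0; j < k; ++j) {
      rc = (rc << 2) | (3ULL - (code & 3ULL));
      code >>= 2;
    }
    out[i] = (double) rc;
  }
  return out;
}

// [[Rcpp::export(name = ".decode_codes_cpp")]]
CharacterVector decode_codes_cpp(NumericVector codes, int k) {
  const R_xlen_t n = codes.size();
  CharacterVector out(n);
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_STRING; continue; }
    uint64_t code = (uint64_t) codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = code_base((int) (code & 3ULL));
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (STRING_ELT(seqs, i) == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(STRING_ELT(seqs, i));
    const R_xlen_t len = LENGTH(STRING_ELT(seqs, i));
    buf.assign(len, 'N');
    for (R_xlen_t j = 0; j < len; ++j) buf[j] = comp_base(s[len - 1 - j]);
    out[i] = buf;
  }
  return out;
}

// single-base substitutions on a copy of `reads`; idx/off 1-based
// [[Rcpp::export(name = ".apply_subs_cpp")]]
CharacterVector apply_subs_cpp(CharacterVector reads, IntegerVector idx,
                               IntegerVector off, CharacterVector base) {
  CharacterVector out = clone(reads);
  const R_xlen_t n = idx.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const R_xlen_t r = idx[i] - 1;
    std::string s = as<std::string>(out[r]);
    if (off[i] >= 1 && (size_t) off[i] <= s.size())
      s[off[i] - 1] = CHAR(STRING_ELT(base, i))[0];
    out[r] = s;
  }
  return out;
}

// Bidirectional edge scan. For each read with at least one anchored end,
// compare the read base-by-base against the reference inward from that end
// (in the anchor's frame, reverse-complementing for '-' anchors) and report
// the first mismatch. At the mismatch the following `lookahead` bases are
// compared in-register; with fewer than `min_mm` of them mismatching the
// edge is a point mismatch.
//
// c5/c3: 1-based chromosome index of the anchor (0 = anchor absent)
// p5/p3: 1-based forward-strand position of the anchor k-mer's first base
// s5/s3: +1 / -1 strand
// Returned (per read, integer): found, ref (1-based), off (1-based read
// offset), point, oob, refb, altb (genome-frame base codes), clean.
// [[Rcpp::export(name = ".scan_reads_cpp")]]
List scan_reads_cpp(CharacterVector reads, CharacterVector chroms,
                    IntegerVector c5, IntegerVector p5, IntegerVector s5,
                    IntegerVector c3, IntegerVector p3, IntegerVector s3,
                    int k, int margin, int lookahead, int min_mm) {
  const R_xlen_t n = reads.size();
  IntegerVector f5(n), r5(n), o5(n), pt5(n), ob5(n), rb5(n), ab5(n), cl5(n);
  IntegerVector f3(n), r3(n), o3(n), pt3(n), ob3(n), rb3(n), ab3(n), cl3(n);

  for (R_xlen_t i = 0; i < n; ++i) {
    const char* rd = CHAR(STRING_ELT(reads, i));
    const int L = (int) LENGTH(STRING_ELT(reads, i));

    for (int side = 0; side < 2; ++side) {
      const int ci = side == 0 ? c5[i] : c3[i];
      IntegerVector& f  = side == 0 ? f5  : f3;
      IntegerVector& rr = side == 0 ? r5  : r3;
      IntegerVector& oo = side == 0 ? o5  : o3;
      IntegerVector& pt = side == 0 ? pt5 : pt3;
      IntegerVector& ob = side == 0 ? ob5 : ob3;
      IntegerVector& rb = side == 0 ? rb5 : rb3;
      IntegerVector& ab = side == 0 ? ab5 : ab3;
      IntegerVector& cl = side == 0 ? cl5 : cl3;
      f[i] = 0; rr[i] = NA_INTEGER; oo[i] = NA_INTEGER; pt[i] = 0;
      ob[i] = 0; rb[i] = NA_INTEGER; ab[i] = NA_INTEGER; cl[i] = 0;
      if (ci == 0) continue;

      const char* chr = CHAR(STRING_ELT(chroms, ci - 1));
      const int clen = (int) LENGTH(STRING_ELT(chroms, ci - 1));
      const int strand = side == 0 ? s5[i] : s3[i];
      const int apos   = side == 0 ? p5[i] : p3[i];
      // read offset of the anchor k-mer's first base
      const int aoff   = side == 0 ? margin + 1 : L - margin - k + 1;
      // ref position of read offset j:
      //   '+': apos + (j - aoff);  '-': (apos + k - 1) - (j - aoff)
      const int jstart = side == 0 ? 1 : L;
      const int jstep  = side == 0 ? 1 : -1;

      bool hit = false, oob = false;
      for (int j = jstart; j >= 1 && j <= L; j += jstep) {
        const int rp = strand == 1 ? apos + (j - aoff)
                                   : (apos + k - 1) - (j - aoff);
        if (rp < 1 || rp > clen) { oob = true; break; }
        const char gb = chr[rp - 1];
        const char rg = strand == 1 ? rd[j - 1] : comp_base(rd[j - 1]);
        if (rg != gb) {
          hit = true;
          f[i] = 1; rr[i] = rp; oo[i] = j;
          rb[i] = base_code(gb); ab[i] = base_code(rg);
          int mm = 0;
          for (int t = 1; t <= lookahead; ++t) {
            const int jj = j + t * jstep;
            if (jj < 1 || jj > L) break;
            const int rp2 = strand == 1 ? apos + (jj - aoff)
                                        : (apos + k - 1) - (jj - aoff);
            if (rp2 < 1 || rp2 > clen) break;
            const char rg2 = strand == 1 ? rd[jj - 1] : comp_base(rd[jj - 1]);
            if (rg2 != chr[rp2 - 1]) ++mm;
          }
          pt[i] = (mm < min_mm) ? 1 : 0;
          break;
        }
      }
      ob[i] = oob ? 1 : 0;
      if (!hit && !oob) cl[i] = 1;
    }
  }

  return List::create(
    _["f5"] = f5, _["r5"] = r5, _["o5"] = o5, _["pt5"] = pt5, _["ob5"] = ob5,
    _["rb5"] = rb5, _["ab5"] = ab5, _["cl5"] = cl5,
    _["f3"] = f3, _["r3"] = r3, _["o3"] = o3, _["pt3"] = pt3, _["ob3"] = ob3,
    _["rb3"] = rb3, _["ab3"] = ab3, _["cl3"] = cl3);
}

// Compare reads against the reference at fixed positions: for read i aligned
// at chrom[ci]-1, start p (1-based, forward strand), count mismatches (capped
// at `cap`) and report the first mismatch offset and read base code.
// [[Rcpp::export(name = ".compare_at_cpp")]]
List compare_at_cpp(CharacterVector reads, CharacterVector chroms,
                    IntegerVector ci, IntegerVector p, int cap) {
  const R_xlen_t n = reads.size();
  IntegerVector mm(n), off1(n), b1(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    mm[i] = NA_INTEGER; off1[i] = NA_INTEGER; b1[i] = NA_INTEGER;
    if (ci[i] == NA_INTEGER || ci[i] == 0) continue;
    const char* rd = CHAR(STRING_ELT(reads, i));
    const int L = (int) LENGTH(STRING_ELT(reads, i));
    const char* chr = CHAR(STRING_ELT(chroms, ci[i] - 1));
    const int clen = (int) LENGTH(STRING_ELT(chroms, ci[i] - 1));
    if (p[i] < 1 || p[i] + L - 1 > clen) continue;
    int cnt = 0, o1 = 0, c1 = -1;
    for (int j = 0; j < L; ++j) {
      if (rd[j] != chr[p[i] - 1 + j]) {
        if (cnt == 0) { o1 = j + 1; c1 = base_code(rd[j]); }
        if (++cnt >= cap) break;
      }
    }
    mm[i] = cnt; off1[i] = cnt >= 1 ? o1 : NA_INTEGER;
    b1[i] = cnt >= 1 ? c1 : NA_INTEGER;
  }
  return List::create(_["mm"] = mm, _["off"] = off1, _["base"] = b1);
}

// sort a chunk of packed k-mer codes and run-length encode it into a sorted
// (code, count) pair; the input vector is consumed (sorted in place)
// [[Rcpp::export(name = ".count_codes_cpp")]]
List count_codes_cpp(NumericVector codes) {
  const R_xlen_t n = codes.size();
  double* x = REAL(codes);
  std::sort(x, x + n);
  R_xlen_t runs = 0;
  for (R_xlen_t i = 0; i < n; ++i) if (i == 0 || x[i] != x[i - 1]) ++runs;
  NumericVector code(runs);
  IntegerVector cnt(runs);
  R_xlen_t j = -1;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (i == 0 || x[i] != x[i - 1]) { code[++j] = x[i]; cnt[j] = 1; }
    else ++cnt[j];
  }
  return List::create(_["code"] = code, _["count"] = cnt);
}

// merge two sorted (code, count) arrays, summing counts of equal codes;
// two passes (size, then fill) into exactly-sized output vectors
// [[Rcpp::export(name = ".merge_counts_cpp")]]
List merge_counts_cpp(NumericVector c1, IntegerVector n1,
                      NumericVector c2, IntegerVector n2) {
  const R_xlen_t a = c1.size(), b = c2.size();
  R_xlen_t m = 0, i = 0, j = 0;
  while (i < a || j < b) {
    if (j >= b || (i < a && c1[i] < c2[j])) ++i;
    else if (i >= a || c2[j] < c1[i]) ++j;
    else { ++i; ++j; }
    ++m;
  }
  NumericVector code(m);
  IntegerVector cnt(m);
  R_xlen_t o = 0;
  i = 0; j = 0;
  while (i < a || j < b) {
    if (j >= b || (i < a && c1[i] < c2[j])) {
      code[o] = c1[i]; cnt[o] = n1[i]; ++i;
    } else if (i >= a || c2[j] < c1[i]) {
      code[o] = c2[j]; cnt[o] = n2[j]; ++j;
    } else {
      code[o] = c1[i]; cnt[o] = n1[i] + n2[j]; ++i; ++j;
    }
    ++o;
  }
  return List::create(_["code"] = code, _["count"] = cnt);
}

// collapse a sorted (k-mer code, count) array into the last-base table:
// one row per (k-1)-mer prefix with counts of the following A/C/G/T
// [[Rcpp::export(name = ".last_base_from_counts_cpp")]]
List last_base_from_counts_cpp(NumericVector code, IntegerVector count) {
  const R_xlen_t n = code.size();
  R_xlen_t rows = 0;
  uint64_t prev = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const uint64_t pfx = ((uint64_t) code[i]) >> 2;
    if (i == 0 || pfx != prev) ++rows;
    prev = pfx;
  }
  NumericVector prefix(rows);
  IntegerVector a(rows), c(rows), g(rows), t(rows);
  R_xlen_t j = -1;
  for (R_xlen_t i = 0; i < n; ++i) {
    const uint64_t cd = (uint64_t) code[i];
    const uint64_t pfx = cd >> 2;
    if (i == 0 || pfx != prev) prefix[++j] = (double) pfx;
    prev = pfx;
    switch ((int) (cd & 3ULL)) {
      case 0: a[j] += count[i]; break;
      case 1: c[j] += count[i]; break;
      case 2: g[j] += count[i]; break;
      case 3: t[j] += count[i]; break;
    }
  }
  return List::create(_["prefix"] = prefix, _["A"] = a, _["C"] = c,
                      _["G"] = g, _["T"] = t);
}
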