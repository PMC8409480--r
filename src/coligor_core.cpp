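#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Unit-cost Levenshtein distance, two-row DP. Stack buffers for the short
// strings this package works with (MIDs, identifiers); heap fallback.
static int lev_dp(const char* a, int la, const char* b, int lb) {
  if (lb < 255) {
    int buf0[256], buf1[256];
    int *prev = buf0, *cur = buf1;
    for (int j = 0; j <= lb; ++j) prev[j] = j;
    for (int i = 1; i <= la; ++i) {
      cur[0] = i;
      for (int j = 1; j <= lb; ++j) {
        int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
        int del = prev[j] + 1;
        int ins = cur[j - 1] + 1;
        cur[j] = std::min(sub, std::min(del, ins));
      }
      std::swap(prev, cur);
    }
    return prev[lb];
  }
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// IUPAC nucleotide code -> 4-bit base mask (A=1, C=2, G=4, T=8).
static int iupac_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 5;
    case 'Y': case 'y': return 10;
    case 'S': case 's': return 6;
    case 'W': case 'w': return 9;
    case 'K': case 'k': return 12;
    case 'M': case 'm': return 3;
    case 'B': case 'b': return 14;
    case 'D': case 'd': return 13;
    case 'H': case 'h': return 11;
    case 'V': case 'v': return 7;
    case 'N': case 'n': return 15;
    default: return 0;
  }
}

// Mismatches of seq[off .. off+|pat|-1] against an IUPAC pattern
// (substitutions only). Returns INT_MAX-ish sentinel if seq too short.
static int iupac_mm(const char* s, int ls, int off, const char* p, int lp) {
  if (off + lp > ls) return 1000000;
  int mm = 0;
  for (int j = 0; j < lp; ++j)
    if ((iupac_mask(s[off + j]) & iupac_mask(p[j])) == 0) ++mm;
  return mm;
}

// [[Rcpp::export]]
IntegerVector cpp_levenshtein(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* sa = CHAR(STRING_ELT(a, i % a.size()));
    const char* sb = CHAR(STRING_ELT(b, i % b.size()));
    out[i] = lev_dp(sa, std::strlen(sa), sb, std::strlen(sb));
  }
  return out;
}

// All pairwise distances within a set (symmetric matrix).
// [[Rcpp::export]]
IntegerMatrix cpp_lev_pairwise(CharacterVector x) {
  int n = x.size();
  IntegerMatrix out(n, n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = lev_dp(s[i].c_str(), s[i].size(), s[j].c_str(), s[j].size());
      out(i, j) = d;
      out(j, i) = d;
    }
  return out;
}

// For each query: index (1-based) of nearest candidate, its distance, and
// how many candidates attain that distance.
// [[Rcpp::export]]
DataFrame cpp_lev_nearest(CharacterVector queries, CharacterVector candidates) {
  int nq = queries.size(), nc = candidates.size();
  IntegerVector idx(nq), dist(nq), nties(nq);
  std::vector<std::string> cs(nc);
  for (int j = 0; j < nc; ++j) cs[j] = as<std::string>(candidates[j]);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    int best = INT_MAX, besti = 0, ties = 0;
    for (int j = 0; j < nc; ++j) {
      int d = lev_dp(q.c_str(), q.size(), cs[j].c_str(), cs[j].size());
      if (d < best) { best = d; besti = j + 1; ties = 1; }
      else if (d == best) ++ties;
    }
    idx[i] = besti; dist[i] = best; nties[i] = ties;
  }
  return DataFrame::create(_["idx"] = idx, _["dist"] = dist, _["n_at_best"] = nties);
}

// [[Rcpp::export]]
IntegerVector cpp_iupac_mismatch(CharacterVector seqs, std::string pattern,
                                 IntegerVector offsets) {
  int n = seqs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int off = offsets.size() == 1 ? offsets[0] : offsets[i];
    out[i] = iupac_mm(s, std::strlen(s), off, pattern.c_str(), pattern.size());
  }
  return out;
}

// Primer-anchored variable-length MID matching.
//
// For each read, candidate MID lengths are tried in descending order; at a
// given length L the window seq[0:L] is scored against every candidate of
// length L (unit-cost edit distance) and the primer against seq[L:L+|primer|]
// (IUPAC-aware substitutions only). A candidate is acceptable when
// mid_edits <= max_mid_edits and primer_mm <= max_primer_mm; the first length
// holding any acceptable candidate is used and the unique lexicographic
// minimiser of (mid_edits, primer_mm) is accepted. A tie yields
// reason = ambiguous_mid.
//
// reason codes: 0 assigned, 1 no_mid, 2 ambiguous_mid, 3 no_primer
// [[Rcpp::export]]
DataFrame cpp_match_prefix(CharacterVector seqs, CharacterVector mid_seqs,
                           std::string primer, int max_mid_edits,
                           int max_primer_mm) {
  int n = seqs.size(), nm = mid_seqs.size();
  std::vector<std::string> mids(nm);
  std::vector<int> mlen(nm);
  std::vector<int> lengths; // distinct, descending
  for (int j = 0; j < nm; ++j) {
    mids[j] = as<std::string>(mid_seqs[j]);
    mlen[j] = mids[j].size();
    if (std::find(lengths.begin(), lengths.end(), mlen[j]) == lengths.end())
      lengths.push_back(mlen[j]);
  }
  std::sort(lengths.rbegin(), lengths.rend());
  int lp = primer.size();

  IntegerVector idx(n), consumed(n), edits(n), pmm(n), reason(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int ls = std::strlen(s);
    bool any_mid = false;
    int ridx = 0, rcons = 0, redits = 0, rpmm = 0, rcode = 1;
    for (size_t li = 0; li < lengths.size(); ++li) {
      int L = lengths[li];
      if (L > ls) continue;
      int best_e = INT_MAX, best_p = INT_MAX, besti = 0, ties = 0;
      for (int j = 0; j < nm; ++j) {
        if (mlen[j] != L) continue;
        int d;
        if (std::strncmp(s, mids[j].c_str(), L) == 0) d = 0;
        else d = lev_dp(s, L, mids[j].c_str(), L);
        if (d > max_mid_edits) continue;
        any_mid = true;
        int mm = iupac_mm(s, ls, L, primer.c_str(), lp);
        if (mm > max_primer_mm) continue;
        if (d < best_e || (d == best_e && mm < best_p)) {
          best_e = d; best_p = mm; besti = j + 1; ties = 1;
        } else if (d == best_e && mm == best_p) ++ties;
      }
      if (besti > 0) {
        if (ties > 1) { rcode = 2; }
        else {
          rcode = 0; ridx = besti; rcons = L + lp; redits = best_e; rpmm = best_p;
        }
        break;
      }
    }
    if (rcode == 1 && any_mid) rcode = 3;
    idx[i] = ridx; consumed[i] = rcons; edits[i] = redits; pmm[i] = rpmm;
    reason[i] = rcode;
  }
  return DataFrame::create(_["idx"] = idx, _["consumed"] = consumed,
                           _["mid_edits"] = edits, _["primer_mm"] = pmm,
                           _["reason"] = reason);
}

// Coligo identifier extraction from primer-trimmed forward reads: exact
// id_len-prefix match preferred; otherwise the unique identifier within
// max_edits of any of the length id_len-1, id_len, id_len+1 prefixes
// (the flexible window absorbs single indels). Returns 0 when no unique
// match exists.
// [[Rcpp::export]]
IntegerVector cpp_coligo_match(CharacterVector seqs, CharacterVector ids,
                               int id_len, int max_edits) {
  int n = seqs.size(), nc = ids.size();
  std::vector<std::string> cs(nc);
  for (int j = 0; j < nc; ++j) cs[j] = as<std::string>(ids[j]);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int ls = std::strlen(s);
    if (ls < id_len - 1) { out[i] = 0; continue; }
    int hit = 0;
    if (ls >= id_len) {
      for (int j = 0; j < nc; ++j)
        if ((int)cs[j].size() == id_len &&
            std::strncmp(s, cs[j].c_str(), id_len) == 0) { hit = j + 1; break; }
    }
    if (hit == 0 && max_edits > 0) {
      int best = INT_MAX, besti = 0, ties = 0;
      for (int j = 0; j < nc; ++j) {
        int d = INT_MAX;
        for (int w = id_len - 1; w <= id_len + 1; ++w) {
          if (w > ls) continue;
          d = std::min(d, lev_dp(s, w, cs[j].c_str(), cs[j].size()));
        }
        if (d < best) { best = d; besti = j + 1; ties = 1; }
        else if (d == best) ++ties;
      }
      if (best <= max_edits && ties == 1) hit = besti;
    }
    out[i] = hit;
  }
  return out;
}
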