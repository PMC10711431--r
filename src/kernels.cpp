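// Dynamic-programming and read-classification kernels.
//
// Sequences cross the R/C++ boundary as 1-based integer codes into the
// caller's alphabet; 0 encodes a gap in returned alignments.  All penalties
// are negative numbers; a gap of length L costs gap_open + L * gap_ext.

#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const double NEG_INF = -1e30;

// ---------------------------------------------------------------------------
// Global (Needleman-Wunsch) alignment with affine gaps and traceback.
// Returns score, number of identical aligned positions, and the two gapped
// sequences as integer codes (0 = gap).
// [[Rcpp::export]]
List cpp_nw_affine(IntegerVector a, IntegerVector b, NumericMatrix sub,
                   double gap_open, double gap_ext) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("empty sequence in global alignment");

  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> X((m + 1) * (n + 1), NEG_INF); // gap in b (a consumed)
  std::vector<double> Y((m + 1) * (n + 1), NEG_INF); // gap in a (b consumed)
  std::vector<unsigned char> pM((m + 1) * (n + 1), 0), pX((m + 1) * (n + 1), 0),
      pY((m + 1) * (n + 1), 0);
  const int W = n + 1;
  auto id = [W](int i, int j) { return i * W + j; };

  M[id(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) {
    X[id(i, 0)] = gap_open + i * gap_ext;
    pX[id(i, 0)] = 2;
  }
  for (int j = 1; j <= n; ++j) {
    Y[id(0, j)] = gap_open + j * gap_ext;
    pY[id(0, j)] = 3;
  }

  for (int i = 1; i <= m; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= n; ++j) {
      const int bj = b[j - 1] - 1;
      // M: consume both
      double dM = M[id(i - 1, j - 1)], dX = X[id(i - 1, j - 1)],
             dY = Y[id(i - 1, j - 1)];
      double best = dM; unsigned char ptr = 1;
      if (dX > best) { best = dX; ptr = 2; }
      if (dY > best) { best = dY; ptr = 3; }
      M[id(i, j)] = best + sub(ai, bj);
      pM[id(i, j)] = ptr;
      // X: consume a[i] against gap
      double oM = M[id(i - 1, j)] + gap_open + gap_ext;
      double oX = X[id(i - 1, j)] + gap_ext;
      double oY = Y[id(i - 1, j)] + gap_open + gap_ext;
      if (oM >= oX && oM >= oY) { X[id(i, j)] = oM; pX[id(i, j)] = 1; }
      else if (oX >= oY)        { X[id(i, j)] = oX; pX[id(i, j)] = 2; }
      else                      { X[id(i, j)] = oY; pX[id(i, j)] = 3; }
      // Y: consume b[j] against gap (pointer codes: 1 = M, 2 = X, 3 = Y)
      double qM = M[id(i, j - 1)] + gap_open + gap_ext;
      double qY = Y[id(i, j - 1)] + gap_ext;
      double qX = X[id(i, j - 1)] + gap_open + gap_ext;
      if (qM >= qY && qM >= qX) { Y[id(i, j)] = qM; pY[id(i, j)] = 1; }
      else if (qY >= qX)        { Y[id(i, j)] = qY; pY[id(i, j)] = 3; }
      else                      { Y[id(i, j)] = qX; pY[id(i, j)] = 2; }
    }
  }

  double sM = M[id(m, n)], sX = X[id(m, n)], sY = Y[id(m, n)];
  int state = 1; double score = sM;
  if (sX > score) { score = sX; state = 2; }
  if (sY > score) { score = sY; state = 3; }

  // traceback
  std::vector<int> ra, rb;
  int i = m, j = n, matches = 0;
  while (i > 0 || j > 0) {
    if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++matches;
      state = pM[id(i, j)];
      --i; --j;
    } else if (state == 2) {
      ra.push_back(a[i - 1]); rb.push_back(0);
      state = pX[id(i, j)];
      --i;
    } else {
      ra.push_back(0); rb.push_back(b[j - 1]);
      state = pY[id(i, j)];
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["aligned_a"] = wrap(ra), _["aligned_b"] = wrap(rb));
}

// ---------------------------------------------------------------------------
// Local (Smith-Waterman) alignment of a sequence against a position-specific
// score matrix prof (L columns x alphabet), affine gaps.  When traceback is
// requested, returns cols: for each profile column the residue code aligned
// to it (0 = not covered / gap).
// [[Rcpp::export]]
List cpp_sw_profile(NumericMatrix prof, IntegerVector seq, double gap_open,
                    double gap_ext, bool traceback) {
  const int L = prof.nrow(), n = seq.size();
  if (L == 0 || n == 0) stop("empty profile or sequence");

  std::vector<double> M((L + 1) * (n + 1), 0.0), X((L + 1) * (n + 1), NEG_INF),
      Y((L + 1) * (n + 1), NEG_INF);
  std::vector<unsigned char> pM, pX, pY;
  if (traceback) {
    pM.assign((L + 1) * (n + 1), 0);
    pX.assign((L + 1) * (n + 1), 0);
    pY.assign((L + 1) * (n + 1), 0);
  }
  const int W = n + 1;
  auto id = [W](int i, int j) { return i * W + j; };

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int cj = seq[j - 1] - 1;
      double dM = M[id(i - 1, j - 1)], dX = X[id(i - 1, j - 1)],
             dY = Y[id(i - 1, j - 1)];
      double pre = 0.0; unsigned char ptr = 0; // 0 = local start
      if (dM > pre) { pre = dM; ptr = 1; }
      if (dX > pre) { pre = dX; ptr = 2; }
      if (dY > pre) { pre = dY; ptr = 3; }
      double v = pre + prof(i - 1, cj);
      if (v < 0) { v = 0; ptr = 0; } // never keep negative local prefixes
      M[id(i, j)] = v;
      if (traceback) pM[id(i, j)] = ptr;
      if (v > best) { best = v; bi = i; bj = j; }

      double oM = M[id(i - 1, j)] + gap_open + gap_ext;
      double oX = X[id(i - 1, j)] + gap_ext;
      if (oM >= oX) { X[id(i, j)] = oM; if (traceback) pX[id(i, j)] = 1; }
      else          { X[id(i, j)] = oX; if (traceback) pX[id(i, j)] = 2; }

      double qM = M[id(i, j - 1)] + gap_open + gap_ext;
      double qY = Y[id(i, j - 1)] + gap_ext;
      if (qM >= qY) { Y[id(i, j)] = qM; if (traceback) pY[id(i, j)] = 1; }
      else          { Y[id(i, j)] = qY; if (traceback) pY[id(i, j)] = 3; }
    }
  }

  if (!traceback)
    return List::create(_["score"] = best, _["cols"] = R_NilValue);

  IntegerVector cols(L, 0);
  int i = bi, j = bj, state = 1;
  while (i > 0 && j > 0 && state != 0) {
    if (state == 1) {
      cols[i - 1] = seq[j - 1];
      state = pM[id(i, j)];
      --i; --j;
    } else if (state == 2) {
      state = pX[id(i, j)];
      --i;
    } else {
      state = pY[id(i, j)];
      --j;
    }
  }
  return List::create(_["score"] = best, _["cols"] = cols);
}

// ---------------------------------------------------------------------------
// Banded local alignment (linear gap) of read a against reference b around
// diagonal `diag` (j ~ i + diag), half-width `band`.  DNA codes 1..4; code 0
// (unknown base) always mismatches.
// [[Rcpp::export]]
double cpp_banded_local(IntegerVector a, IntegerVector b, int diag, int band,
                        double match, double mismatch, double gap) {
  const int m = a.size(), n = b.size();
  const int width = 2 * band + 1;
  std::vector<double> prev(width, 0.0), cur(width, 0.0);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    const int ai = a[i - 1];
    for (int c = 0; c < width; ++c) {
      const int j = i + diag - band + c;
      if (j < 1 || j > n) { cur[c] = 0.0; continue; }
      const int bj = b[j - 1];
      double s = (ai != 0 && ai == bj) ? match : mismatch;
      double v = prev[c] + s;                       // diagonal (i-1, j-1)
      if (c + 1 < width) v = std::max(v, prev[c + 1] + gap); // up (i-1, j)
      if (c - 1 >= 0)    v = std::max(v, cur[c - 1] + gap);  // left (i, j-1)
      if (v < 0) v = 0;
      cur[c] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// ---------------------------------------------------------------------------
// Minimizers: (k,w)-minimizers of the forward strand.  Non-ACGT bases break
// k-mers.  Hash is a multiplicative scramble truncated to 31 bits.
static void minimizer_list(const char *s, int len, int k, int w,
                           std::vector<std::pair<int, int>> &out) {
  out.clear();
  if (len < k) return;
  const uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  std::vector<int> hash(len - k + 1, -1); // -1 = invalid k-mer
  uint32_t code = 0;
  int run = 0;
  for (int i = 0; i < len; ++i) {
    int bcode;
    switch (s[i]) {
      case 'A': case 'a': bcode = 0; break;
      case 'C': case 'c': bcode = 1; break;
      case 'G': case 'g': bcode = 2; break;
      case 'T': case 't': bcode = 3; break;
      default: bcode = -1;
    }
    if (bcode < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)bcode) & mask;
    if (++run >= k) {
      uint32_t h = (code * 2654435761u) & 0x7FFFFFFFu;
      hash[i - k + 1] = (int)h;
    }
  }
  const int nk = len - k + 1;
  int last_pos = -1;
  for (int start = 0; start + w <= nk; ++start) {
    int mh = INT32_MAX, mp = -1;
    for (int t = 0; t < w; ++t) {
      const int h = hash[start + t];
      if (h >= 0 && h < mh) { mh = h; mp = start + t; }
    }
    if (mp >= 0 && mp != last_pos) {
      out.push_back(std::make_pair(mh, mp));
      last_pos = mp;
    }
  }
  if (nk < w) { // short sequence: single window over what exists
    int mh = INT32_MAX, mp = -1;
    for (int t = 0; t < nk; ++t)
      if (hash[t] >= 0 && hash[t] < mh) { mh = hash[t]; mp = t; }
    if (mp >= 0) out.push_back(std::make_pair(mh, mp));
  }
}

// [[Rcpp::export]]
IntegerVector cpp_minimizers(std::string seq, int k, int w) {
  std::vector<std::pair<int, int>> mins;
  minimizer_list(seq.c_str(), (int)seq.size(), k, w, mins);
  std::vector<int> vals;
  vals.reserve(mins.size());
  for (size_t i = 0; i < mins.size(); ++i) vals.push_back(mins[i].first);
  std::sort(vals.begin(), vals.end());
  vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
  return wrap(vals);
}

static std::vector<int> encode_dna(const char *s, int len) {
  std::vector<int> v(len);
  for (int i = 0; i < len; ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 1; break;
      case 'C': case 'c': v[i] = 2; break;
      case 'G': case 'g': v[i] = 3; break;
      case 'T': case 't': v[i] = 4; break;
      default: v[i] = 0;
    }
  }
  return v;
}

// ---------------------------------------------------------------------------
// Classify reads against reference genes by shared minimizers, with banded
// local-alignment rescoring of the top two references when the runner-up
// shares any minimizer.  Returns 0 for unassigned reads.
// [[Rcpp::export]]
List cpp_assign_reads(CharacterVector reads, CharacterVector refs, int k,
                      int w, double min_margin, int band, double match,
                      double mismatch, double gap) {
  const int nref = refs.size(), nread = reads.size();
  if (nref == 0) stop("empty reference set");

  // index: minimizer hash -> list of (ref id, k-mer position)
  std::unordered_map<int, std::vector<std::pair<int, int>>> index;
  std::vector<std::vector<int>> ref_codes(nref);
  std::vector<std::pair<int, int>> mins;
  for (int r = 0; r < nref; ++r) {
    const char *s = CHAR(STRING_ELT(refs, r));
    const int len = (int)LENGTH(STRING_ELT(refs, r));
    ref_codes[r] = encode_dna(s, len);
    minimizer_list(s, len, k, w, mins);
    for (size_t t = 0; t < mins.size(); ++t)
      index[mins[t].first].push_back(std::make_pair(r, mins[t].second));
  }

  IntegerVector assignment(nread, 0);
  NumericVector margin_out(nread, NA_REAL);
  std::vector<int> counts(nref, 0);
  std::vector<std::vector<int>> diffs(nref);
  std::vector<int> touched;
  std::vector<char> seen(nref, 0);

  for (int q = 0; q < nread; ++q) {
    const char *s = CHAR(STRING_ELT(reads, q));
    const int len = (int)LENGTH(STRING_ELT(reads, q));
    minimizer_list(s, len, k, w, mins);
    // dedupe read minimizers by hash (keep first position)
    std::sort(mins.begin(), mins.end());
    for (size_t t = 0; t < touched.size(); ++t) {
      counts[touched[t]] = 0;
      diffs[touched[t]].clear();
    }
    touched.clear();
    int prev_hash = -1;
    for (size_t t = 0; t < mins.size(); ++t) {
      if (mins[t].first == prev_hash) continue;
      prev_hash = mins[t].first;
      std::unordered_map<int, std::vector<std::pair<int, int>>>::iterator it =
          index.find(mins[t].first);
      if (it == index.end()) continue;
      std::fill(seen.begin(), seen.end(), 0);
      for (size_t e = 0; e < it->second.size(); ++e) {
        const int rid = it->second[e].first;
        if (!seen[rid]) {
          seen[rid] = 1;
          if (counts[rid] == 0) touched.push_back(rid);
          counts[rid]++;
        }
        diffs[rid].push_back(it->second[e].second - mins[t].second);
      }
    }
    int best = -1, second = -1;
    for (size_t t = 0; t < touched.size(); ++t) {
      const int rid = touched[t];
      if (best < 0 || counts[rid] > counts[best]) {
        second = best; best = rid;
      } else if (second < 0 || counts[rid] > counts[second]) {
        second = rid;
      }
    }
    if (best < 0 || counts[best] == 0) continue; // unassigned: no evidence
    if (second < 0 || counts[second] == 0) {
      assignment[q] = best + 1; // forced: count margin is 1
      margin_out[q] = 1.0;
      continue;
    }
    std::vector<int> rcodes = encode_dna(s, len);
    auto median_diag = [&](int rid) {
      std::vector<int> d = diffs[rid];
      std::sort(d.begin(), d.end());
      return d[d.size() / 2];
    };
    double s1 = cpp_banded_local(wrap(rcodes), wrap(ref_codes[best]),
                                 median_diag(best), band, match, mismatch, gap);
    double s2 = cpp_banded_local(wrap(rcodes), wrap(ref_codes[second]),
                                 median_diag(second), band, match, mismatch, gap);
    int winner = best;
    if (s2 > s1) { std::swap(s1, s2); winner = second; }
    if (s1 <= 0) continue;
    const double margin = (s1 - s2) / s1;
    margin_out[q] = margin;
    if (margin < min_margin) continue; // ambiguous
    assignment[q] = winner + 1;
  }
  return List::create(_["assignment"] = assignment, _["margin"] = margin_out);
}

// ---------------------------------------------------------------------------
// Noisy fragment emission for simulated long reads.  For each read, a
// uniformly placed fragment (>= min_frag nt, or the full gene when shorter)
// of its source gene is copied with i.i.d. substitution / insertion /
// deletion errors.  Uses R's RNG.
// [[Rcpp::export]]
CharacterVector cpp_mutate_fragments(CharacterVector genes,
                                     IntegerVector gene_idx, int min_frag,
                                     double error_rate, double f_sub,
                                     double f_ins, double f_del) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  const int nread = gene_idx.size();
  CharacterVector out(nread);
  const double t_sub = error_rate * f_sub;
  const double t_ins = t_sub + error_rate * f_ins;
  const double t_del = t_ins + error_rate * f_del;
  std::string buf;
  for (int q = 0; q < nread; ++q) {
    const int g = gene_idx[q] - 1;
    const char *s = CHAR(STRING_ELT(genes, g));
    const int len = (int)LENGTH(STRING_ELT(genes, g));
    int fl, start;
    if (len <= min_frag) {
      fl = len; start = 0;
    } else {
      fl = min_frag + (int)(unif_rand() * (len - min_frag + 1));
      if (fl > len) fl = len;
      start = (int)(unif_rand() * (len - fl + 1));
      if (start > len - fl) start = len - fl;
    }
    buf.clear();
    buf.reserve(fl + 16);
    for (int i = start; i < start + fl; ++i) {
      const double u = unif_rand();
      const char base = s[i];
      if (u < t_sub) {
        int off = 1 + (int)(unif_rand() * 3.0);
        if (off > 3) off = 3;
        int bi;
        switch (base) {
          case 'A': bi = 0; break; case 'C': bi = 1; break;
          case 'G': bi = 2; break; case 'T': bi = 3; break;
          default: bi = (int)(unif_rand() * 4.0) % 4;
        }
        buf.push_back(BASES[(bi + off) % 4]);
      } else if (u < t_ins) {
        buf.push_back(base);
        buf.push_back(BASES[(int)(unif_rand() * 4.0) % 4]);
      } else if (u < t_del) {
        // skip base
      } else {
        buf.push_back(base);
      }
    }
    if (buf.empty()) buf.push_back(s[start]); // never emit an empty read
    out[q] = buf;
  }
  return out;
}
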