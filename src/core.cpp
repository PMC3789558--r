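#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Watson-Crick pairing; N never pairs.
static inline bool wc_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A';
  case 'C': return b == 'G';
  case 'G': return b == 'C';
  default:  return false;
  }
}

// Enumerate maximal hairpins in seq[win_start, win_end).
//
// A hairpin is identified by its loop interval [a, b). The stem grows
// outward from the loop, pairing seq[a-1-t] with seq[b+t]. For stem length
// L the mismatch budget is min(max_mm, floor(max_mm_frac * L)); the
// reported stem is the longest L within [stem_min, stem_max] whose
// cumulative mismatch count is within budget and whose outermost pair is a
// match (stems never end on a mismatch). One hairpin per qualifying loop.
// Coordinates returned are 0-based.
// [[Rcpp::export]]
DataFrame hairpin_scan_cpp(std::string seq, int win_start, int win_end,
                           int stem_min, int stem_max,
                           int loop_min, int loop_max,
                           int max_mm, double max_mm_frac) {
  std::vector<int> arm5_start, stem_len, loop_start, loop_len, mism;
  const int n = (int) seq.size();
  if (win_start < 0) win_start = 0;
  if (win_end > n) win_end = n;
  for (int a = win_start + stem_min; a < win_end; ++a) {
    for (int l = loop_min; l <= loop_max; ++l) {
      int b = a + l;
      if (b + stem_min > win_end) break;
      int best_L = 0, best_mm = 0, mm = 0;
      int Lmax = std::min(std::min(a - win_start, win_end - b), stem_max);
      for (int t = 0; t < Lmax; ++t) {
        bool match = wc_pair(seq[a - 1 - t], seq[b + t]);
        if (!match) ++mm;
        int L = t + 1;
        int budget = std::min(max_mm, (int) std::floor(max_mm_frac * L));
        if (match && mm <= budget) { best_L = L; best_mm = mm; }
      }
      if (best_L >= stem_min) {
        arm5_start.push_back(a - best_L);
        stem_len.push_back(best_L);
        loop_start.push_back(a);
        loop_len.push_back(l);
        mism.push_back(best_mm);
      }
    }
  }
  return DataFrame::create(_["arm5_start"] = arm5_start,
                           _["stem_len"] = stem_len,
                           _["loop_start"] = loop_start,
                           _["loop_len"] = loop_len,
                           _["mismatches"] = mism);
}

// Greedy centroid clustering of equal-length windows presented in their
// processing order. Each window joins the first centroid with identity
// strictly above t_id (matches / width, ungapped), else founds a new
// cluster. Returns the 1-based index (into the input vector) of each
// window's centroid.
// [[Rcpp::export]]
IntegerVector greedy_assign_cpp(CharacterVector windows, double t_id) {
  const int n = windows.size();
  IntegerVector cent(n);
  std::vector<std::string> w(n);
  for (int i = 0; i < n; ++i) w[i] = as<std::string>(windows[i]);
  std::vector<int> centroids;   // indices of cluster founders
  const int W = n ? (int) w[0].size() : 0;
  const int max_mm = W - (int) std::floor(t_id * W) - 1; // matches > t_id*W
  for (int i = 0; i < n; ++i) {
    if ((int) w[i].size() != W) stop("mixed window lengths");
    int found = -1;
    for (size_t c = 0; c < centroids.size(); ++c) {
      const std::string &cw = w[centroids[c]];
      int mm = 0;
      for (int p = 0; p < W; ++p) {
        if (w[i][p] != cw[p] && ++mm > max_mm) break;
      }
      if (mm <= max_mm && (double)(W - mm) / W > t_id) { found = centroids[c]; break; }
    }
    if (found < 0) { centroids.push_back(i); found = i; }
    cent[i] = found + 1;
  }
  return cent;
}

// Banded Levenshtein distance (unit costs), score only. band < 0 gives the
// exact distance; otherwise the result is exact whenever the true distance
// fits inside the corridor.
// [[Rcpp::export]]
int edit_distance_cpp(std::string a, std::string b, int band = -1) {
  const int na = (int) a.size(), nb = (int) b.size();
  if (band < 0) band = std::max(na, nb) + 1;
  const int lo = std::min(0, nb - na) - band;
  const int hi = std::max(0, nb - na) + band;
  const int width = hi - lo + 1;
  const int BIG = 1 << 29;
  std::vector<int> prev(width, BIG), cur(width, BIG);
  for (int j = 0; j <= nb; ++j) {
    int k = j - lo;
    if (k >= 0 && k < width) prev[k] = j;
  }
  for (int i = 1; i <= na; ++i) {
    std::fill(cur.begin(), cur.end(), BIG);
    int jmin = std::max(0, i + lo), jmax = std::min(nb, i + hi);
    const char *ai = a.data() + i - 1;
    for (int j = jmin; j <= jmax; ++j) {
      int k = j - i - lo;
      int best;
      if (j == 0) best = i;
      else {
        best = prev[k] + (*ai == b[j - 1] ? 0 : 1);
        if (k + 1 < width && prev[k + 1] + 1 < best) best = prev[k + 1] + 1;
        if (k - 1 >= 0 && cur[k - 1] + 1 < best) best = cur[k - 1] + 1;
      }
      cur[k] = best;
    }
    std::swap(prev, cur);
  }
  return prev[nb - na - lo];
}

// Pairwise alignment with linear gap penalties.
//  - local = false: global (Needleman-Wunsch), optionally banded. The band
//    corridor allows j - i in [min(0, nb-na) - band, max(0, nb-na) + band];
//    band < 0 means full DP.
//  - local = true: full Smith-Waterman (band ignored).
// score_only skips traceback. Coordinates in the result are 0-based
// half-open over the input strings.
// [[Rcpp::export]]
List align_cpp(std::string a, std::string b,
               double match, double mismatch, double gap,
               int band = -1, bool local = false, bool score_only = false) {
  const int na = (int) a.size(), nb = (int) b.size();
  const double NEG = -1e18;
  if (local || band < 0) band = std::max(na, nb) + 1; // full corridor
  const int lo = std::min(0, nb - na) - band;
  const int hi = std::max(0, nb - na) + band;
  const int width = hi - lo + 1;

  std::vector<double> prev(width, NEG), cur(width, NEG);
  // traceback codes: 0 stop/origin, 1 diag, 2 up (gap in b), 3 left (gap in a)
  std::vector<unsigned char> tb;
  if (!score_only) tb.assign((size_t)(na + 1) * width, 0);

  double best = local ? 0.0 : NEG;
  int best_i = 0, best_j = 0;

  // row i = 0
  for (int j = 0; j <= nb; ++j) {
    int k = j - 0 - lo;
    if (k < 0 || k >= width) continue;
    prev[k] = local ? 0.0 : gap * j;
    if (!score_only && j > 0 && !local) tb[(size_t)0 * width + k] = 3;
  }
  for (int i = 1; i <= na; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    int jmin = std::max(0, i + lo), jmax = std::min(nb, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      int k = j - i - lo;
      double s = NEG; unsigned char dir = 0;
      if (j == 0) {
        s = local ? 0.0 : gap * i; dir = local ? 0 : 2;
      } else {
        // diagonal: prev row, same k (since k = j-i-lo shifts together)
        double d = prev[k];
        if (d > NEG / 2) {
          double v = d + (a[i - 1] == b[j - 1] ? match : mismatch);
          if (v > s) { s = v; dir = 1; }
        }
        // up: (i-1, j) -> prev row, k+1
        if (k + 1 < width && prev[k + 1] > NEG / 2) {
          double v = prev[k + 1] + gap;
          if (v > s) { s = v; dir = 2; }
        }
        // left: (i, j-1) -> cur row, k-1
        if (k - 1 >= 0 && cur[k - 1] > NEG / 2) {
          double v = cur[k - 1] + gap;
          if (v > s) { s = v; dir = 3; }
        }
        if (local && s < 0) { s = 0; dir = 0; }
      }
      cur[k] = s;
      if (!score_only) tb[(size_t) i * width + k] = dir;
      if (local && s > best) { best = s; best_i = i; best_j = j; }
    }
    std::swap(prev, cur);
  }
  if (!local) {
    int k = nb - na - lo;
    best = prev[k]; best_i = na; best_j = nb;
  }
  if (score_only)
    return List::create(_["score"] = best);

  // traceback
  std::string aa, bb;
  int i = best_i, j = best_j;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[(size_t) i * width + (j - i - lo)];
    if (local && dir == 0) break;
    if (dir == 1)      { aa += a[i - 1]; bb += b[j - 1]; --i; --j; }
    else if (dir == 2) { aa += a[i - 1]; bb += '-';      --i; }
    else if (dir == 3) { aa += '-';      bb += b[j - 1]; --j; }
    else break;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = best,
                      _["a_aln"] = aa, _["b_aln"] = bb,
                      _["a_start"] = i, _["a_end"] = best_i,
                      _["b_start"] = j, _["b_end"] = best_j);
}
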