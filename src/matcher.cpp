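#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Seed-and-extend ungapped local matcher.
//
// Exact k-mer seeds on both strands, per-diagonal deduplication, ungapped
// X-drop extension with +match/-mismatch scoring.  Any non-ACGT symbol is
// excluded from seeds and scored as a mismatch during extension, so the
// N-spacers used to join replicons terminate extensions quickly.

static inline int encode_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

struct Hsp {
  int a_start, a_end, b_start, b_end; // 0-based half-open, forward coords
  int strand;                         // +1 or -1
  int length, identities, score;
  std::vector<int> mism;              // mismatch offsets from a_start
};

// covered intervals per diagonal, to avoid re-extending seeds inside an
// already-computed segment on the same diagonal
typedef std::unordered_map<int64_t, std::vector<std::pair<int,int> > > CoverMap;

static bool diag_covered(const CoverMap &cov, int64_t diag, int apos) {
  CoverMap::const_iterator it = cov.find(diag);
  if (it == cov.end()) return false;
  const std::vector<std::pair<int,int> > &v = it->second;
  for (size_t i = 0; i < v.size(); ++i)
    if (apos >= v[i].first && apos < v[i].second) return true;
  return false;
}

static void match_one_strand(const std::vector<int> &a,
                             const std::vector<int> &b,
                             int strand, int len_b_fwd,
                             int k, int match, int mismatch, int xdrop,
                             std::vector<Hsp> &out) {
  const int na = (int) a.size(), nb = (int) b.size();
  if (na < k || nb < k) return;

  // index k-mers of A (2-bit packed); windows containing non-ACGT skipped
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve((size_t) na);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t key = 0; int run = 0;
  for (int i = 0; i < na; ++i) {
    int c = a[i];
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) c) & mask;
    if (++run >= k) index[key].push_back(i - k + 1);
  }

  CoverMap cov;
  key = 0; run = 0;
  for (int j = 0; j < nb; ++j) {
    int c = b[j];
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) c) & mask;
    if (++run < k) continue;
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator hit =
      index.find(key);
    if (hit == index.end()) continue;
    int js = j - k + 1;
    for (size_t h = 0; h < hit->second.size(); ++h) {
      int is = hit->second[h];
      int64_t diag = (int64_t) is - (int64_t) js;
      if (diag_covered(cov, diag, is)) continue;

      // right extension from the end of the seed
      int score = k * match, best = score;
      int bestR = k; // offset past seed start on A
      std::vector<int> mismR;
      for (int off = k; is + off < na && js + off < nb; ++off) {
        bool ok = (a[is + off] == b[js + off]) && a[is + off] <= 3;
        score += ok ? match : mismatch;
        if (!ok) mismR.push_back(off);
        if (score > best) { best = score; bestR = off + 1; }
        if (best - score > xdrop) break;
      }
      // left extension from the start of the seed
      int lscore = 0, lbest = 0, bestL = 0;
      std::vector<int> mismL; // offsets are negative distances from is
      for (int off = 1; is - off >= 0 && js - off >= 0; ++off) {
        bool ok = (a[is - off] == b[js - off]) && a[is - off] <= 3;
        lscore += ok ? match : mismatch;
        if (!ok) mismL.push_back(off);
        if (lscore > lbest) { lbest = lscore; bestL = off; }
        if (lbest - lscore > xdrop) break;
      }

      int a_s = is - bestL, a_e = is + bestR;
      int len = a_e - a_s;
      Hsp hsp;
      hsp.mism.reserve(mismL.size() + mismR.size());
      for (size_t m = mismL.size(); m > 0; --m)
        if (mismL[m - 1] <= bestL) hsp.mism.push_back(bestL - mismL[m - 1]);
      for (size_t m = 0; m < mismR.size(); ++m)
        if (mismR[m] < bestR) hsp.mism.push_back(bestL + mismR[m]);
      hsp.a_start = a_s; hsp.a_end = a_e;
      int b_s = js - bestL, b_e = js + bestR;
      if (strand > 0) { hsp.b_start = b_s; hsp.b_end = b_e; }
      else { hsp.b_start = len_b_fwd - b_e; hsp.b_end = len_b_fwd - b_s; }
      hsp.strand = strand;
      hsp.length = len;
      hsp.identities = len - (int) hsp.mism.size();
      hsp.score = hsp.identities * match + (len - hsp.identities) * mismatch;
      cov[diag].push_back(std::make_pair(a_s, a_e));
      out.push_back(hsp);
    }
  }
}

// [[Rcpp::export(name = ".match_pair_cpp")]]
List match_pair_cpp(std::string a, std::string b,
                    int k, int match, int mismatch, int xdrop) {
  std::vector<int> ea(a.size()), eb(b.size()), ebrc(b.size());
  for (size_t i = 0; i < a.size(); ++i) ea[i] = encode_base(a[i]);
  for (size_t i = 0; i < b.size(); ++i) eb[i] = encode_base(b[i]);
  const size_t nb = b.size();
  for (size_t i = 0; i < nb; ++i) {
    int c = eb[nb - 1 - i];
    ebrc[i] = (c <= 3) ? (3 - c) : 4;
  }

  std::vector<Hsp> out;
  match_one_strand(ea, eb, +1, (int) nb, k, match, mismatch, xdrop, out);
  match_one_strand(ea, ebrc, -1, (int) nb, k, match, mismatch, xdrop, out);

  const int n = (int) out.size();
  IntegerVector a_start(n), a_end(n), b_start(n), b_end(n),
    length(n), identities(n), score(n);
  CharacterVector strand(n);
  List mism(n);
  for (int i = 0; i < n; ++i) {
    a_start[i] = out[i].a_start; a_end[i] = out[i].a_end;
    b_start[i] = out[i].b_start; b_end[i] = out[i].b_end;
    strand[i] = out[i].strand > 0 ? "+" : "-";
    length[i] = out[i].length; identities[i] = out[i].identities;
    score[i] = out[i].score;
    mism[i] = IntegerVector(out[i].mism.begin(), out[i].mism.end());
  }
  return List::create(
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end,
    _["strand"] = strand, _["length"] = length,
    _["identities"] = identities, _["score"] = score,
    _["mismatch_offsets"] = mism);
}
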