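#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding; k <= 31 fits a 64-bit word.
static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;  // N or anything else breaks the window
  }
}

struct KmerRec {
  uint64_t canon;
  int32_t seq;    // scaffold index (0-based)
  int32_t pos;    // 1-based start of the k-mer
  bool fwd;       // canonical form == forward form at this site
};

// Collect every valid k-mer of `seqs` in canonical form, sorted by code.
static void scanAssembly(const std::vector<std::string>& seqs, int k,
                         std::vector<KmerRec>& recs) {
  size_t total = 0;
  for (auto& s : seqs) if ((int)s.size() >= k) total += s.size() - k + 1;
  recs.reserve(total);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  for (size_t s = 0; s < seqs.size(); ++s) {
    const std::string& seq = seqs[s];
    if ((int)seq.size() < k) continue;
    uint64_t fw = 0, rc = 0;
    int valid = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int c = baseCode(seq[i]);
      if (c < 0) { valid = 0; fw = 0; rc = 0; continue; }
      fw = ((fw << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | (((uint64_t)(3 - c)) << shift);
      if (++valid < k) continue;
      bool isFwd = fw <= rc;
      recs.push_back(KmerRec{isFwd ? fw : rc, (int32_t)s,
                             (int32_t)(i - k + 2), isFwd});
    }
  }
  std::sort(recs.begin(), recs.end(),
            [](const KmerRec& a, const KmerRec& b) {
              return a.canon < b.canon;
            });
}

// Keep only k-mers occurring exactly once, in place.
static void uniqueOnly(std::vector<KmerRec>& recs) {
  size_t out = 0, i = 0, n = recs.size();
  while (i < n) {
    size_t j = i + 1;
    while (j < n && recs[j].canon == recs[i].canon) ++j;
    if (j - i == 1) recs[out++] = recs[i];
    i = j;
  }
  recs.resize(out);
}

// [[Rcpp::export(name = ".kmerAnchors")]]
DataFrame kmerAnchors(CharacterVector seqsA, CharacterVector seqsB, int k) {
  if (k < 11 || k > 31 || k % 2 == 0)
    stop("k must be odd and within [11, 31]");
  std::vector<std::string> A(seqsA.size()), B(seqsB.size());
  for (R_xlen_t i = 0; i < seqsA.size(); ++i) A[i] = as<std::string>(seqsA[i]);
  for (R_xlen_t i = 0; i < seqsB.size(); ++i) B[i] = as<std::string>(seqsB[i]);

  std::vector<KmerRec> ra, rb;
  scanAssembly(A, k, ra);
  scanAssembly(B, k, rb);
  uniqueOnly(ra);
  uniqueOnly(rb);

  // merge-join the two sorted unique lists
  size_t i = 0, j = 0, nMatch = 0;
  {
    size_t ii = 0, jj = 0;
    while (ii < ra.size() && jj < rb.size()) {
      if (ra[ii].canon < rb[jj].canon) ++ii;
      else if (rb[jj].canon < ra[ii].canon) ++jj;
      else { ++nMatch; ++ii; ++jj; }
    }
  }
  IntegerVector aSeq(nMatch), aPos(nMatch), bSeq(nMatch), bPos(nMatch),
      fwd(nMatch);
  size_t m = 0;
  while (i < ra.size() && j < rb.size()) {
    if (ra[i].canon < rb[j].canon) ++i;
    else if (rb[j].canon < ra[i].canon) ++j;
    else {
      aSeq[m] = ra[i].seq + 1;
      aPos[m] = ra[i].pos;
      bSeq[m] = rb[j].seq + 1;
      bPos[m] = rb[j].pos;
      fwd[m] = (ra[i].fwd == rb[j].fwd) ? 1 : 0;
      ++m; ++i; ++j;
    }
  }
  return DataFrame::create(_["a_seq"] = aSeq, _["a_pos"] = aPos,
                           _["b_seq"] = bSeq, _["b_pos"] = bPos,
                           _["forward"] = fwd);
}
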