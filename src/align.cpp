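#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding; anything outside ACGT maps to 4 (never matches, never a seed)
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;
  }
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_char(c);
  return r;
}

struct Hsp {
  int qs, qe, ss, se;   // 0-based half-open
  int score;
  int mism;             // mismatch columns (N columns count here)
  int gapo;             // gap opens
  int gapcols;          // total gap columns
};

// index of all word-size k-mers of the subject (k <= 16, 2 bits/base)
struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<int>> pos;
  void build(const std::vector<int> &codes, int word) {
    k = word;
    int n = (int) codes.size();
    if (n < k) return;
    uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0; // consecutive valid bases
    for (int i = 0; i < n; ++i) {
      int c = codes[i];
      if (c > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) c) & mask;
      if (++run >= k) pos[key].push_back(i - k + 1);
    }
  }
};

// ungapped x-drop extension around an exact seed
static Hsp extend_ungapped(const std::vector<int> &q, const std::vector<int> &s,
                           int qi, int si, int k, int match, int mismatch, int xdrop) {
  int m = (int) q.size(), n = (int) s.size();
  int score = k * match;
  // right
  int best = score, bq = qi + k, bs = si + k;
  int cq = bq, cs = bs, cur = score;
  while (cq < m && cs < n) {
    cur += (q[cq] <= 3 && q[cq] == s[cs]) ? match : mismatch;
    ++cq; ++cs;
    if (cur > best) { best = cur; bq = cq; bs = cs; }
    if (cur < best - xdrop) break;
  }
  int qe = bq, se = bs;
  // left
  score = best;
  int bq2 = qi, bs2 = si;
  cq = qi - 1; cs = si - 1; cur = score; best = score;
  while (cq >= 0 && cs >= 0) {
    cur += (q[cq] <= 3 && q[cq] == s[cs]) ? match : mismatch;
    if (cur > best) { best = cur; bq2 = cq; bs2 = cs; }
    if (cur < best - xdrop) break;
    --cq; --cs;
  }
  Hsp h;
  h.qs = bq2; h.qe = qe; h.ss = bs2; h.se = se;
  h.score = best;
  int len = h.qe - h.qs;
  // recount mismatches over the kept span
  int mm = 0;
  for (int i = 0; i < len; ++i)
    if (!(q[h.qs + i] <= 3 && q[h.qs + i] == s[h.ss + i])) ++mm;
  h.mism = mm; h.gapo = 0; h.gapcols = 0;
  return h;
}

// chain same-locus HSPs into gapped hits (diagonal-banded, affine gap costs)
static std::vector<Hsp> chain_hsps(std::vector<Hsp> hsps, int match, int mismatch,
                                   int gap_open, int gap_extend,
                                   int band, int max_gap) {
  if (hsps.empty()) return hsps;
  std::sort(hsps.begin(), hsps.end(), [](const Hsp &a, const Hsp &b) {
    if (a.qs != b.qs) return a.qs < b.qs;
    return a.ss < b.ss;
  });
  std::vector<Hsp> out;
  std::vector<bool> used(hsps.size(), false);
  for (size_t i = 0; i < hsps.size(); ++i) {
    if (used[i]) continue;
    Hsp cur = hsps[i];
    used[i] = true;
    bool progress = true;
    while (progress) {
      progress = false;
      for (size_t j = 0; j < hsps.size(); ++j) {
        if (used[j]) continue;
        const Hsp &nx = hsps[j];
        int gq = nx.qs - cur.qe;
        int gs = nx.ss - cur.se;
        if (gq < 0 || gs < 0) continue;           // overlapping HSPs: leave separate
        if (gq > max_gap || gs > max_gap) continue;
        int dd = std::abs(gq - gs);
        if (dd > band) continue;
        int bridge = std::min(gq, gs);            // unaligned columns scored as mismatch
        int pen = bridge * (-mismatch) + (dd > 0 ? (-gap_open) + dd * (-gap_extend) : 0);
        int merged = cur.score + nx.score - pen;
        if (merged <= std::max(cur.score, nx.score)) continue;
        cur.score = merged;
        cur.mism += bridge + nx.mism;
        cur.gapo += (dd > 0 ? 1 : 0) + nx.gapo;
        cur.gapcols += dd + nx.gapcols;
        cur.qe = nx.qe; cur.se = nx.se;
        used[j] = true;
        progress = true;
      }
    }
    out.push_back(cur);
  }
  return out;
}

// drop hits fully contained (both sides, and on a compatible diagonal) in a
// higher-scoring hit; diagonal agreement keeps e.g. repeat-pair hits that sit
// inside the bounding box of a long self-alignment
static std::vector<Hsp> drop_contained(std::vector<Hsp> hits, int band) {
  std::sort(hits.begin(), hits.end(), [](const Hsp &a, const Hsp &b) {
    return a.score > b.score;
  });
  std::vector<Hsp> keep;
  for (const auto &h : hits) {
    long hd1 = (long) h.qs - h.ss, hd2 = (long) h.qe - h.se;
    long hlo = std::min(hd1, hd2), hhi = std::max(hd1, hd2);
    bool contained = false;
    for (const auto &k : keep) {
      if (h.qs >= k.qs && h.qe <= k.qe && h.ss >= k.ss && h.se <= k.se) {
        long kd1 = (long) k.qs - k.ss, kd2 = (long) k.qe - k.se;
        long klo = std::min(kd1, kd2), khi = std::max(kd1, kd2);
        if (hlo >= klo - band && hhi <= khi + band) {
          contained = true; break;
        }
      }
    }
    if (!contained) keep.push_back(h);
  }
  return keep;
}

static void collect_hits(const std::string &qseq, const std::vector<int> &scodes,
                         const KmerIndex &idx, int word, int match, int mismatch,
                         int gap_open, int gap_extend, int xdrop,
                         int band, int max_gap, std::vector<Hsp> &res) {
  int m = (int) qseq.size();
  if (m < word) return;
  std::vector<int> qcodes(m);
  for (int i = 0; i < m; ++i) qcodes[i] = base_code(qseq[i]);
  int n = (int) scodes.size();
  // per-diagonal extension frontier: skip seeds inside an already-extended HSP
  std::unordered_map<long, int> diag_end;
  std::vector<Hsp> hsps;
  uint64_t key = 0, mask = (1ULL << (2 * word)) - 1;
  int run = 0;
  for (int i = 0; i < m; ++i) {
    int c = qcodes[i];
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) c) & mask;
    if (++run < word) continue;
    int qpos = i - word + 1;
    auto it = idx.pos.find(key);
    if (it == idx.pos.end()) continue;
    for (int spos : it->second) {
      long d = (long) qpos - (long) spos;
      auto de = diag_end.find(d);
      if (de != diag_end.end() && qpos < de->second) continue;
      Hsp h = extend_ungapped(qcodes, scodes, qpos, spos, word, match, mismatch, xdrop);
      diag_end[d] = h.qe;
      if (h.qe - h.qs >= word) hsps.push_back(h);
      if (hsps.size() > 400000) stop("homology search produced too many HSPs");
    }
  }
  (void) n;
  hsps = drop_contained(std::move(hsps), band);
  hsps = chain_hsps(std::move(hsps), match, mismatch, gap_open, gap_extend, band, max_gap);
  hsps = drop_contained(std::move(hsps), band);
  for (auto &h : hsps) res.push_back(h);
}

// [[Rcpp::export(name = ".find_hits_cpp")]]
DataFrame find_hits_cpp(CharacterVector queries, std::string subject,
                        int word, int match, int mismatch,
                        int gap_open, int gap_extend, int xdrop,
                        double evalue_max, double K, double lambda,
                        int band, int max_gap, bool both_strands) {
  int n = (int) subject.size();
  std::vector<int> scodes(n);
  for (int i = 0; i < n; ++i) scodes[i] = base_code(subject[i]);
  KmerIndex idx;
  idx.build(scodes, word);

  std::vector<int> o_query, o_qs, o_qe, o_ss, o_se, o_len, o_mism, o_gapo;
  std::vector<double> o_score, o_ident, o_bits, o_eval;
  std::vector<std::string> o_strand;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    int m = (int) q.size();
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::string qs = (strand == 0) ? q : revcomp_str(q);
      std::vector<Hsp> hits;
      collect_hits(qs, scodes, idx, word, match, mismatch, gap_open, gap_extend,
                   xdrop, band, max_gap, hits);
      for (const auto &h : hits) {
        int aln_len = (h.qe - h.qs) + h.gapcols;
        if (aln_len < word) continue;
        double ev = K * (double) m * (double) n * std::exp(-lambda * (double) h.score);
        if (ev > evalue_max) continue;
        double bits = (lambda * (double) h.score - std::log(K)) / std::log(2.0);
        int matches = aln_len - h.mism - h.gapcols;
        double ident = 100.0 * (double) matches / (double) aln_len;
        int hqs = h.qs, hqe = h.qe;
        if (strand == 1) { hqs = m - h.qe; hqe = m - h.qs; } // map back to forward query
        o_query.push_back(qi + 1);
        o_qs.push_back(hqs); o_qe.push_back(hqe);
        o_ss.push_back(h.ss); o_se.push_back(h.se);
        o_strand.push_back(strand == 0 ? "+" : "-");
        o_len.push_back(aln_len);
        o_mism.push_back(h.mism);
        o_gapo.push_back(h.gapo);
        o_score.push_back((double) h.score);
        o_ident.push_back(ident);
        o_bits.push_back(bits);
        o_eval.push_back(ev);
      }
    }
  }
  return DataFrame::create(
    _["query_idx"] = o_query,
    _["q_start"] = o_qs, _["q_end"] = o_qe,
    _["s_start"] = o_ss, _["s_end"] = o_se,
    _["strand"] = o_strand,
    _["identity"] = o_ident,
    _["aln_len"] = o_len,
    _["mismatches"] = o_mism,
    _["gap_opens"] = o_gapo,
    _["raw_score"] = o_score,
    _["bitscore"] = o_bits,
    _["evalue"] = o_eval,
    _["stringsAsFactors"] = false);
}
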