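#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Banded local alignment of short amplicon reads against a (possibly
// N-masked) reference. Candidate placements come from exact k-mer seeding;
// each candidate diagonal cluster is scored by banded Smith-Waterman in
// which an 'N' reference base never matches. Mapping confidence derives
// from the gap between the best and second-best placement.

namespace {

inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1; // N or anything else: not indexable
  }
}

inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

struct AlnResult {
  int score = 0;
  int ref_start = -1;   // 0-based inclusive
  int read_start = 0;   // 0-based inclusive (soft-clipped prefix length)
  std::string cigar;
  int nm = 0;
  bool valid = false;
};

// Banded local DP around diagonal d (= ref_pos - read_pos). Traceback kept.
AlnResult banded_local(const std::string& read, const std::string& ref,
                       int d, int band, int match, int mismatch, int gap) {
  const int m = (int) read.size();
  const int n = (int) ref.size();
  const int w = 2 * band + 1;
  std::vector<int> prev(w, 0), cur(w, 0);
  std::vector<uint8_t> tb((size_t) m * w, 0); // 0 stop, 1 diag, 2 up(del in read? see below), 3 left
  int best = 0, bi = -1, bc = -1;

  for (int i = 0; i < m; ++i) {
    int off = d + i - band; // ref index of column 0 at row i
    for (int c = 0; c < w; ++c) {
      int j = off + c;
      int h = 0; uint8_t dir = 0;
      if (j >= 0 && j < n) {
        char rb = ref[(size_t) j];
        int s = (rb != 'N' && rb == read[(size_t) i]) ? match : mismatch;
        int diag = (i > 0 ? prev[c] : 0) + s; // c' = c for diagonal
        if (i == 0) diag = s;                  // first row: start fresh
        if (diag > h) { h = diag; dir = 1; }
        if (i > 0 && c + 1 < w) {              // up: gap in read (deletion of ref? no: ref stays, read advances)
          int up = prev[c + 1] + gap;
          if (up > h) { h = up; dir = 2; }
        }
        if (c > 0) {                           // left: gap in ref consumption
          int left = cur[c - 1] + gap;
          if (left > h) { h = left; dir = 3; }
        }
      }
      cur[c] = h;
      tb[(size_t) i * w + c] = (h > 0) ? dir : 0;
      if (h > best) { best = h; bi = i; bc = c; }
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), 0);
  }

  AlnResult res;
  res.score = best;
  if (best <= 0) return res;

  // traceback from (bi, bc)
  std::vector<char> ops; // 'M','I','D' per step (I: read base not in ref; D: ref base not in read)
  int i = bi, c = bc, nm = 0;
  int end_read = bi;                      // inclusive
  while (i >= 0) {
    uint8_t dir = tb[(size_t) i * w + c];
    if (dir == 0) break;
    int off = d + i - band;
    int j = off + c;
    if (dir == 1) {
      ops.push_back('M');
      char rb = ref[(size_t) j];
      if (!(rb != 'N' && rb == read[(size_t) i])) nm++;
      if (i == 0) { res.ref_start = j; res.read_start = 0; i = -1; break; }
      // check whether predecessor existed (score from prev row) or fresh start
      int pred = (i > 0) ? 1 : 0;
      if (pred) {
        int prev_tb = tb[(size_t) (i - 1) * w + c];
        // fresh start if previous cell value was effectively 0: detect by re-walk;
        // we conservatively continue traceback; dir==0 at prev cell ends it.
        (void) prev_tb;
      }
      res.ref_start = j; res.read_start = i;
      i -= 1; // c unchanged for diagonal
    } else if (dir == 2) { // up: read base consumed, no ref base -> insertion in read
      ops.push_back('I');
      nm++;
      res.read_start = i;
      i -= 1; c += 1;
    } else { // left: ref base consumed, no read base -> deletion from read
      ops.push_back('D');
      nm++;
      int off2 = d + i - band;
      res.ref_start = off2 + c;
      c -= 1;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // build cigar with soft clips
  std::string cig;
  if (res.read_start > 0) cig += std::to_string(res.read_start) + "S";
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p);
    cig += ops[p];
    p = q;
  }
  int tail = m - 1 - end_read;
  if (tail > 0) cig += std::to_string(tail) + "S";
  res.cigar = cig;
  res.nm = nm;
  res.valid = true;
  return res;
}

struct Candidate { int diag; int votes; bool rc; };

} // namespace

// [[Rcpp::export]]
List cpp_align_batch(std::string ref, CharacterVector reads,
                     int match, int mismatch, int gap,
                     int band, int k, int stride, int max_cand) {
  const int n = (int) ref.size();
  // k-mer index of reference (skip windows containing N)
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve((size_t) std::max(16, n));
  uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int j = 0; j < n; ++j) {
    int b = base2bits(ref[(size_t) j]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) b) & mask;
    if (++run >= k) index[key].push_back(j - k + 1);
  }

  const int nr = reads.size();
  IntegerVector out_pos(nr), out_score(nr), out_second(nr), out_nm(nr), out_ties(nr);
  CharacterVector out_cigar(nr), out_strand(nr), out_seq(nr);
  LogicalVector out_mapped(nr);

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    for (char c : fwd) {
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T')
        stop("read %d contains non-ACGT symbol '%c'", r + 1, c);
    }
    std::string rev = revcomp(fwd);
    const int m = (int) fwd.size();

    // collect candidate diagonals per strand
    std::vector<Candidate> cands;
    for (int rc = 0; rc < 2; ++rc) {
      const std::string& rd = rc ? rev : fwd;
      std::unordered_map<int, int> votes;
      for (int o = 0; o + k <= m; o += stride) {
        uint64_t kk = 0; bool ok = true;
        for (int t = 0; t < k; ++t) {
          int b = base2bits(rd[(size_t)(o + t)]);
          if (b < 0) { ok = false; break; }
          kk = (kk << 2) | (uint64_t) b;
        }
        if (!ok) continue;
        auto it = index.find(kk);
        if (it == index.end()) continue;
        if ((int) it->second.size() > 64) continue; // highly repetitive seed
        for (int p : it->second) votes[p - o]++;
      }
      // cluster nearby diagonals (within band) keeping the vote-richest center
      std::vector<std::pair<int,int>> dv(votes.begin(), votes.end());
      std::sort(dv.begin(), dv.end());
      size_t a = 0;
      while (a < dv.size()) {
        size_t b2 = a; int best_d = dv[a].first, tot = 0, best_v = -1;
        while (b2 < dv.size() && dv[b2].first - dv[a].first <= band) {
          tot += dv[b2].second;
          if (dv[b2].second > best_v) { best_v = dv[b2].second; best_d = dv[b2].first; }
          ++b2;
        }
        cands.push_back({best_d, tot, rc == 1});
        a = b2;
      }
    }
    if (cands.empty()) { out_mapped[r] = false; out_strand[r] = "+"; out_cigar[r] = "*"; continue; }
    std::sort(cands.begin(), cands.end(),
              [](const Candidate& x, const Candidate& y) { return x.votes > y.votes; });
    if ((int) cands.size() > max_cand) cands.resize((size_t) max_cand);

    // score each candidate
    struct Scored { AlnResult aln; bool rc; int diag; };
    std::vector<Scored> scored;
    for (auto& cd : cands) {
      const std::string& rd = cd.rc ? rev : fwd;
      AlnResult a = banded_local(rd, ref, cd.diag, band, match, mismatch, gap);
      if (a.valid) scored.push_back({a, cd.rc, cd.diag});
    }
    if (scored.empty()) { out_mapped[r] = false; out_strand[r] = "+"; out_cigar[r] = "*"; continue; }

    // best placement: max score; ties -> leftmost ref_start, forward first
    std::sort(scored.begin(), scored.end(), [](const Scored& x, const Scored& y) {
      if (x.aln.score != y.aln.score) return x.aln.score > y.aln.score;
      if (x.aln.ref_start != y.aln.ref_start) return x.aln.ref_start < y.aln.ref_start;
      return !x.rc && y.rc;
    });
    const Scored& bst = scored[0];
    int second = 0, ties = 0;
    for (size_t t = 1; t < scored.size(); ++t) {
      bool distinct = scored[t].rc != bst.rc ||
        std::abs(scored[t].aln.ref_start - bst.aln.ref_start) > m / 2;
      if (!distinct) continue;
      if (scored[t].aln.score > second) second = scored[t].aln.score;
      if (scored[t].aln.score == bst.aln.score) ties++;
    }
    out_mapped[r] = true;
    out_pos[r] = bst.aln.ref_start + 1; // 1-based
    out_score[r] = bst.aln.score;
    out_second[r] = second;
    out_ties[r] = ties;
    out_nm[r] = bst.aln.nm;
    out_cigar[r] = bst.aln.cigar;
    out_strand[r] = bst.rc ? "-" : "+";
    out_seq[r] = bst.rc ? rev : fwd;
  }

  return List::create(
    _["mapped"] = out_mapped, _["pos"] = out_pos, _["score"] = out_score,
    _["second_score"] = out_second, _["n_ties"] = out_ties, _["nm"] = out_nm,
    _["cigar"] = out_cigar, _["strand"] = out_strand, _["aligned_seq"] = out_seq);
}

// Pileup counting: each read contributes exactly one allele per reference
// position its alignment consumes. Deletions are left-aligned and recorded
// as "-<seq>" at the anchor base (position before the gap), deleted
// positions themselves carry "*"; insertions are left-aligned and recorded
// as "+<seq>" at their anchor base.
// [[Rcpp::export]]
DataFrame cpp_pileup(std::string ref, IntegerVector pos, CharacterVector cigar,
                     CharacterVector seq, CharacterVector strand) {
  const int n = (int) ref.size();
  // key: pos * 2 + strand -> map allele -> count
  std::unordered_map<std::string, int> counts;
  auto add = [&](int p, const std::string& allele, bool fwd) {
    if (p < 1 || p > n) return;
    std::string key = std::to_string(p) + "\t" + allele + "\t" + (fwd ? "+" : "-");
    counts[key]++;
  };

  const int nr = pos.size();
  for (int r = 0; r < nr; ++r) {
    std::string cg = as<std::string>(cigar[r]);
    if (cg == "*") continue;
    std::string sq = as<std::string>(seq[r]);
    bool fwd = as<std::string>(strand[r]) == "+";
    int rp = pos[r];        // 1-based ref cursor
    int qp = 0;             // 0-based read cursor
    // parse cigar into ops
    std::vector<std::pair<int,char>> ops;
    int num = 0;
    for (char c : cg) {
      if (c >= '0' && c <= '9') num = num * 10 + (c - '0');
      else { ops.push_back({num, c}); num = 0; }
    }
    // per-read allele map (allows replacing the anchor base with indel allele)
    std::vector<std::pair<int, std::string>> alleles; // (ref pos, allele)
    for (auto& op : ops) {
      int len = op.first; char o = op.second;
      if (o == 'S') { qp += len; }
      else if (o == 'M' || o == '=' || o == 'X') {
        for (int t = 0; t < len; ++t)
          alleles.push_back({rp + t, std::string(1, sq[(size_t)(qp + t)])});
        rp += len; qp += len;
      } else if (o == 'D') {
        int start = rp;                     // first deleted ref base (1-based)
        std::string del = ref.substr((size_t)(start - 1), (size_t) len);
        // left-align: shift while base before deletion equals last deleted base
        int s0 = start;
        while (s0 > 1 && ref[(size_t)(s0 - 2)] == ref[(size_t)(s0 + len - 2)]) s0--;
        std::string del2 = ref.substr((size_t)(s0 - 1), (size_t) len);
        int anchor = s0 - 1;
        if (anchor >= 1) {
          // replace anchor base allele if already recorded
          bool replaced = false;
          for (auto& al : alleles)
            if (al.first == anchor) { al.second = "-" + del2; replaced = true; break; }
          if (!replaced) alleles.push_back({anchor, "-" + del2});
        }
        for (int t = 0; t < len; ++t) alleles.push_back({rp + t, "*"});
        rp += len;
      } else if (o == 'I') {
        std::string ins = sq.substr((size_t) qp, (size_t) len);
        int anchor = rp - 1;                // base before insertion point
        // left-align: rotate while ref base at anchor equals last inserted base
        while (anchor > 1 && ref[(size_t)(anchor - 1)] == ins[(size_t)(len - 1)]) {
          ins = ins.back() + ins.substr(0, (size_t)(len - 1));
          anchor--;
        }
        if (anchor >= 1) {
          bool replaced = false;
          for (auto& al : alleles)
            if (al.first == anchor) { al.second = "+" + ins; replaced = true; break; }
          if (!replaced) alleles.push_back({anchor, "+" + ins});
        }
        qp += len;
      } else if (o == 'H') {
        // hard clip: nothing
      } else {
        stop("unsupported CIGAR op '%c'", o);
      }
    }
    for (auto& al : alleles) add(al.first, al.second, fwd);
  }

  std::vector<int> out_pos; std::vector<std::string> out_allele, out_strand;
  std::vector<int> out_count;
  out_pos.reserve(counts.size());
  for (auto& kv : counts) {
    size_t t1 = kv.first.find('\t');
    size_t t2 = kv.first.find('\t', t1 + 1);
    int p = 0; // parse the position prefix (decimal digits only)
    for (size_t t = 0; t < t1; ++t) p = p * 10 + (kv.first[t] - '0');
    out_pos.push_back(p);
    out_allele.push_back(kv.first.substr(t1 + 1, t2 - t1 - 1));
    out_strand.push_back(kv.first.substr(t2 + 1));
    out_count.push_back(kv.second);
  }
  return DataFrame::create(
    _["pos"] = wrap(out_pos), _["allele"] = wrap(out_allele),
    _["strand"] = wrap(out_strand), _["count"] = wrap(out_count),
    _["stringsAsFactors"] = false);
}
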