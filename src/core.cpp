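// Core of the seed-hash mapper: k-mer index construction and lookup,
// hotspot collection with diagonal banding (so short indels do not split a
// locus), end-to-end DP verification inside a candidate window, the per-read
// mapping loop, pileup accumulation from edit transcripts, and an exhaustive
// semi-global DP oracle used only for validation.
//
// Conventions: coordinates are 0-based half-open throughout; strand 0 = "+",
// 1 = "-" (a minus-strand alignment places the reverse complement of the
// read on the forward reference). Edit transcripts are strings of tokens
//   <n>=   run of n matches
//   X<b>   one mismatch, <b> is the (oriented) read base
//   I<seq> insertion of <seq> relative to the reference
//   <n>D   deletion of n reference bases
// which makes the transcript self-contained for pileup reconstruction.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <map>
#include <string>
#include <tuple>
#include <vector>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N and anything ambiguous: never matches
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// Non-overlapping seeds at 0, s, 2s, ...; if a tail remains, one extra seed
// anchored at L - s so the read end is covered.
std::vector<int> seed_offsets_vec(int L, int s) {
  std::vector<int> off;
  if (L < s) return off;
  for (int o = 0; o + s <= L; o += s) off.push_back(o);
  if (L % s != 0) off.push_back(L - s);
  return off;
}

struct Hotspot {
  int ref, strand, cand, votes, spread;
};

// Collect hotspots for one read orientation. Raw candidate start = hit_pos -
// read_offset (clamped at -band); raw candidates on a reference are grouped
// greedily in sorted order with max - min <= band; votes count distinct
// contributing read offsets.
void collect_hotspots_one(const std::string& oriented_read, int strand,
                          const IntegerVector& icode, const IntegerVector& iref,
                          const IntegerVector& ipos, int seed_len, int band,
                          std::vector<Hotspot>& out) {
  const int L = (int)oriented_read.size();
  std::vector<std::array<int, 3>> raw;  // (ref, cand, offset)
  for (int o : seed_offsets_vec(L, seed_len)) {
    int code = 0;
    bool ok = true;
    for (int j = 0; j < seed_len; ++j) {
      int b = base_code(oriented_read[o + j]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | b;
    }
    if (!ok) continue;  // seeds containing N anchor nothing
    const int* beg = icode.begin();
    const int* end = icode.end();
    const int* lo = std::lower_bound(beg, end, code);
    const int* hi = std::upper_bound(lo, end, code);
    for (const int* it = lo; it != hi; ++it) {
      int k = (int)(it - beg);
      int cand = ipos[k] - o;
      if (cand < -band) cand = -band;
      raw.push_back({iref[k], cand, o});
    }
  }
  std::sort(raw.begin(), raw.end());
  size_t i = 0;
  while (i < raw.size()) {
    int ref = raw[i][0], base = raw[i][1], maxc = base;
    std::vector<int> offs;
    size_t j = i;
    while (j < raw.size() && raw[j][0] == ref && raw[j][1] - base <= band) {
      maxc = raw[j][1];
      offs.push_back(raw[j][2]);
      ++j;
    }
    std::sort(offs.begin(), offs.end());
    int votes = (int)(std::unique(offs.begin(), offs.end()) - offs.begin());
    out.push_back({ref, strand, base, votes, maxc - base});
    i = j;
  }
}

// Total, deterministic hotspot order: votes desc, then reference ordinal,
// candidate start, strand ("+" before "-").
inline bool hotspot_before(const Hotspot& a, const Hotspot& b) {
  if (a.votes != b.votes) return a.votes > b.votes;
  if (a.ref != b.ref) return a.ref < b.ref;
  if (a.cand != b.cand) return a.cand < b.cand;
  return a.strand < b.strand;
}

struct AlnRes {
  bool ok = false;
  int ref_start = 0, ref_end = 0, mism = 0, ins_b = 0, del_b = 0;
  std::string cig;
};

// Append ops ('=', 'X'+base, 'I'+base, 'D') to a compact transcript.
struct CigBuilder {
  std::string out;
  char pend = 0;
  int n = 0;
  std::string iseq;
  void flush() {
    if (pend == '=') out += std::to_string(n) + "=";
    else if (pend == 'D') out += std::to_string(n) + "D";
    else if (pend == 'I') out += "I" + iseq;
    pend = 0; n = 0; iseq.clear();
  }
  void match() { if (pend != '=') { flush(); pend = '='; } ++n; }
  void mism(char b) { flush(); out += 'X'; out += b; }
  void del() { if (pend != 'D') { flush(); pend = 'D'; } ++n; }
  void ins(char b) { if (pend != 'I') { flush(); pend = 'I'; } iseq += b; }
};

// End-to-end alignment of the full (oriented) read against the reference
// window [cand - band, cand + L + band), unit-cost edit distance, free
// leading/trailing reference gaps inside the window only. Returns the
// minimum-distance alignment if <= allowance. With allow_indels false this
// degenerates to a Hamming comparison at cand.
AlnRes verify_one(const std::string& ref, const std::string& read, int cand,
                  int band, int allowance, bool allow_indels,
                  int spread = 0) {
  AlnRes res;
  const int L = (int)read.size();
  const int RL = (int)ref.size();
  if (L == 0) return res;
  if (!allow_indels) {
    if (cand < 0 || cand + L > RL) return res;
    int mism = 0;
    for (int i = 0; i < L; ++i) {
      int a = base_code(read[i]), b = base_code(ref[cand + i]);
      if (a < 0 || b < 0 || a != b) if (++mism > allowance) return res;
    }
    CigBuilder cb;
    for (int i = 0; i < L; ++i) {
      int a = base_code(read[i]), b = base_code(ref[cand + i]);
      if (a < 0 || b < 0 || a != b) cb.mism(read[i]); else cb.match();
    }
    cb.flush();
    res.ok = true; res.ref_start = cand; res.ref_end = cand + L;
    res.mism = mism; res.cig = cb.out;
    return res;
  }
  // cand is the hotspot group minimum; candidates up to cand + spread
  // support the same locus, so the window must extend past them too
  int w0 = std::max(0, cand - band);
  int w1 = std::min(RL, cand + spread + L + band);
  int W = w1 - w0;
  if (W < L - allowance || W <= 0) return res;  // window cannot host the read

  const int stride = W + 1;
  std::vector<int> D((L + 1) * stride);
  for (int j = 0; j <= W; ++j) D[j] = 0;
  for (int i = 1; i <= L; ++i) {
    D[i * stride] = i;  // read prefix unmatched => insertions
    const int rb = base_code(read[i - 1]);
    for (int j = 1; j <= W; ++j) {
      const int wb = base_code(ref[w0 + j - 1]);
      const int sub = (rb < 0 || wb < 0 || rb != wb) ? 1 : 0;
      int best = D[(i - 1) * stride + (j - 1)] + sub;
      const int up = D[(i - 1) * stride + j] + 1;
      if (up < best) best = up;
      const int left = D[i * stride + (j - 1)] + 1;
      if (left < best) best = left;
      D[i * stride + j] = best;
    }
  }
  int bestj = 0, bestd = D[L * stride];
  for (int j = 1; j <= W; ++j)
    if (D[L * stride + j] < bestd) { bestd = D[L * stride + j]; bestj = j; }
  if (bestd > allowance) return res;

  // Traceback. Ties prefer continuing an open gap (so a multi-base indel
  // stays one contiguous event rather than splitting around a chance
  // match), then diagonal, then insertion, then deletion.
  std::vector<std::pair<char, char>> ops;  // op, read base (for X/I)
  int i = L, j = bestj;
  char last = 0;
  while (i > 0) {
    const int here = D[i * stride + j];
    const int rb = base_code(read[i - 1]);
    const int wb = (j > 0) ? base_code(ref[w0 + j - 1]) : -2;
    const int sub = (rb < 0 || wb < 0 || rb != wb) ? 1 : 0;
    const bool can_diag =
        j > 0 && D[(i - 1) * stride + (j - 1)] + sub == here;
    const bool can_up = D[(i - 1) * stride + j] + 1 == here;
    const bool can_left = j > 0 && D[i * stride + (j - 1)] + 1 == here;
    char mv;
    if (last == 'I' && can_up) mv = 'I';
    else if (last == 'D' && can_left) mv = 'D';
    else if (can_diag) mv = 'M';
    else if (can_up) mv = 'I';
    else mv = 'D';
    if (mv == 'M') {
      if (sub) ops.push_back({'X', read[i - 1]});
      else ops.push_back({'=', 0});
      --i; --j;
    } else if (mv == 'I') {
      ops.push_back({'I', read[i - 1]});
      --i;
    } else {
      ops.push_back({'D', 0});
      --j;
    }
    last = mv;
  }
  std::reverse(ops.begin(), ops.end());
  CigBuilder cb;
  for (auto& op : ops) {
    switch (op.first) {
      case '=': cb.match(); break;
      case 'X': cb.mism(op.second); ++res.mism; break;
      case 'I': cb.ins(op.second); ++res.ins_b; break;
      case 'D': cb.del(); ++res.del_b; break;
    }
  }
  cb.flush();
  res.ok = true;
  res.ref_start = w0 + j;
  res.ref_end = w0 + bestj;
  res.cig = cb.out;
  return res;
}

struct Loc {
  int ref, strand, start, end, mism, edits;
  std::string cig;
};

// Two locations are the same iff same reference, same strand, and starts
// within the indel band.
inline bool same_location(const Loc& a, const Loc& b, int band) {
  return a.ref == b.ref && a.strand == b.strand &&
         std::abs(a.start - b.start) <= band;
}

// Per-read mapping: seeds on both orientations -> hotspots -> prioritized
// verification with pigeonhole-bounded early stop -> all distinct best
// locations. status: 0 unmapped, 1 unique, 2 multi.
void map_one(const std::string& read, const IntegerVector& icode,
             const IntegerVector& iref, const IntegerVector& ipos,
             const std::vector<std::string>& refs, int seed_len, int allowance,
             bool allow_indels, int band, int max_loc, std::vector<Loc>& best,
             int& status, std::string& reason) {
  best.clear();
  status = 0;
  reason = "";
  const int L = (int)read.size();
  if (L < seed_len) { reason = "too_short"; return; }
  const int m0 = L / seed_len;  // non-overlapping seed count, pigeonhole bound
  const int eff_band = allow_indels ? band : 0;

  std::vector<Hotspot> hs;
  collect_hotspots_one(read, 0, icode, iref, ipos, seed_len, eff_band, hs);
  std::string rc = revcomp(read);
  collect_hotspots_one(rc, 1, icode, iref, ipos, seed_len, eff_band, hs);
  if (hs.empty()) { reason = "no_hotspot"; return; }
  std::sort(hs.begin(), hs.end(), hotspot_before);

  int best_d = allowance;  // current bar: alignments must be <= this
  bool found = false;
  for (const Hotspot& h : hs) {
    // A location at edit distance d retains at least m0 - d exact
    // non-overlapping seeds, all implying starts within the band; greedy
    // grouping can cut that diagonal set at most once (a group window
    // boundary), so the larger fragment holds at least half the votes.
    // Once votes drop below (m0 - best_d) / 2 no remaining hotspot can
    // host a location as good as the current best.
    if (2 * h.votes < m0 - best_d) break;
    const std::string& oread = (h.strand == 0) ? read : rc;
    AlnRes a = verify_one(refs[h.ref], oread, h.cand, eff_band, best_d,
                          allow_indels, h.spread);
    if (!a.ok) continue;
    int d = a.mism + a.ins_b + a.del_b;
    Loc loc{h.ref, h.strand, a.ref_start, a.ref_end, a.mism, d, a.cig};
    if (!found || d < best_d) {
      best.clear();
      best.push_back(loc);
      best_d = d;
      found = true;
    } else if (d == best_d) {
      bool dup = false;
      for (const Loc& x : best)
        if (same_location(x, loc, eff_band)) { dup = true; break; }
      if (!dup && (int)best.size() < max_loc) best.push_back(loc);
    }
  }
  if (!found) { reason = "no_alignment"; return; }
  status = ((int)best.size() >= 2) ? 2 : 1;
}

}  // namespace

// [[Rcpp::export]]
List cpp_build_index(CharacterVector seqs, int seed_len) {
  struct Entry { int code, ref, pos; };
  std::vector<Entry> es;
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    const int L = (int)s.size();
    if (L < seed_len) continue;
    const int mask = (1 << (2 * seed_len)) - 1;
    int valid = 0, code = 0;
    for (int i = 0; i < L; ++i) {
      int b = base_code(s[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | b) & mask;
      if (++valid >= seed_len) es.push_back({code, r, i - seed_len + 1});
    }
  }
  std::sort(es.begin(), es.end(), [](const Entry& a, const Entry& b) {
    return std::tie(a.code, a.ref, a.pos) < std::tie(b.code, b.ref, b.pos);
  });
  const R_xlen_t n = (R_xlen_t)es.size();
  IntegerVector code(n), ref(n), pos(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    code[i] = es[i].code;
    ref[i] = es[i].ref;
    pos[i] = es[i].pos;
  }
  return List::create(_["code"] = code, _["ref"] = ref, _["pos"] = pos);
}

// [[Rcpp::export]]
IntegerVector cpp_encode_kmer(std::string kmer) {
  int code = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b < 0) return IntegerVector::create(NA_INTEGER);
    code = (code << 2) | b;
  }
  return IntegerVector::create(code);
}

// [[Rcpp::export]]
DataFrame cpp_collect_hotspots(std::string read, int strand,
                               IntegerVector icode, IntegerVector iref,
                               IntegerVector ipos, int seed_len, int band) {
  std::vector<Hotspot> hs;
  collect_hotspots_one(read, strand, icode, iref, ipos, seed_len, band, hs);
  const int n = (int)hs.size();
  IntegerVector ref(n), cand(n), votes(n), spread(n), str(n);
  for (int i = 0; i < n; ++i) {
    ref[i] = hs[i].ref; cand[i] = hs[i].cand; votes[i] = hs[i].votes;
    spread[i] = hs[i].spread; str[i] = hs[i].strand;
  }
  return DataFrame::create(_["ref"] = ref, _["strand"] = str,
                           _["candidate_start"] = cand, _["votes"] = votes,
                           _["diagonal_spread"] = spread);
}

// [[Rcpp::export]]
List cpp_verify(std::string ref, std::string read, int cand, int band,
                int allowance, bool allow_indels) {
  AlnRes a = verify_one(ref, read, cand, band, allowance, allow_indels);
  if (!a.ok) return List::create(_["ok"] = false);
  return List::create(
      _["ok"] = true, _["ref_start"] = a.ref_start, _["ref_end"] = a.ref_end,
      _["mismatches"] = a.mism, _["ins_bases"] = a.ins_b,
      _["del_bases"] = a.del_b,
      _["edit_distance"] = a.mism + a.ins_b + a.del_b, _["cigar"] = a.cig);
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, IntegerVector icode,
                   IntegerVector iref, IntegerVector ipos,
                   CharacterVector refseqs, int seed_len, double max_errors,
                   double error_percent, bool percent_mode, bool allow_indels,
                   int band, int max_loc) {
  const R_xlen_t n = reads.size();
  std::vector<std::string> refs(refseqs.size());
  for (int i = 0; i < refseqs.size(); ++i) refs[i] = as<std::string>(refseqs[i]);

  IntegerVector status(n), n_best(n);
  CharacterVector reason(n);
  std::vector<int> a_read, a_ref, a_strand, a_start, a_end, a_mism, a_edit;
  std::vector<std::string> a_cig;

  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int allowance = percent_mode
                        ? (int)std::floor(error_percent * (double)rd.size())
                        : (int)max_errors;
    std::vector<Loc> best;
    int st;
    std::string rs;
    map_one(rd, icode, iref, ipos, refs, seed_len, allowance, allow_indels,
            band, max_loc, best, st, rs);
    status[i] = st;
    reason[i] = rs;
    n_best[i] = (int)best.size();
    for (const Loc& l : best) {
      a_read.push_back((int)i + 1);
      a_ref.push_back(l.ref);
      a_strand.push_back(l.strand);
      a_start.push_back(l.start);
      a_end.push_back(l.end);
      a_mism.push_back(l.mism);
      a_edit.push_back(l.edits);
      a_cig.push_back(l.cig);
    }
  }
  return List::create(
      _["status"] = status, _["reason"] = reason, _["n_best"] = n_best,
      _["aln"] = List::create(
          _["read_idx"] = wrap(a_read), _["ref"] = wrap(a_ref),
          _["strand"] = wrap(a_strand), _["ref_start"] = wrap(a_start),
          _["ref_end"] = wrap(a_end), _["mismatches"] = wrap(a_mism),
          _["edit_distance"] = wrap(a_edit), _["alignment"] = wrap(a_cig)));
}

// Exhaustive validation oracle: semi-global unit-cost DP of the read (both
// orientations) against every full reference; returns the global minimum
// edit distance and every end position achieving it, or dist = -1 when no
// placement is within the allowance. Independent of the seed/hotspot path.
// [[Rcpp::export]]
List cpp_oracle_best(CharacterVector refseqs, std::string read,
                     int allowance) {
  const int L = (int)read.size();
  const int K = allowance;
  int best = K + 1;
  std::vector<int> o_ref, o_strand, o_end, o_dist;
  // Column-wise semi-global DP with the Ukkonen last-active-row cutoff:
  // rows whose value exceeds the allowance are never materialized, so each
  // column costs O(allowance) instead of O(read length).
  std::vector<int> rd_code(L);
  for (int strand = 0; strand < 2; ++strand) {
    std::string rd = (strand == 0) ? read : revcomp(read);
    for (int i = 0; i < L; ++i) rd_code[i] = base_code(rd[i]);
    for (int r = 0; r < refseqs.size(); ++r) {
      std::string ref = as<std::string>(refseqs[r]);
      const int T = (int)ref.size();
      std::vector<int> col(L + 1);
      for (int i = 0; i <= L; ++i) col[i] = std::min(i, K + 1);
      int lact = std::min(L, K);
      if (lact == L && col[L] <= K) {  // degenerate: read no longer than K
        o_ref.push_back(r); o_strand.push_back(strand);
        o_end.push_back(0); o_dist.push_back(col[L]);
        if (col[L] < best) best = col[L];
      }
      for (int j = 1; j <= T; ++j) {
        const int tb = base_code(ref[j - 1]);
        int diag = col[0];  // D[0][j-1] == 0
        const int lim = std::min(L, lact + 1);
        int newlact = 0;
        int above = 0;  // D[0][j] == 0
        for (int i = 1; i <= lim; ++i) {
          const int old = col[i];
          const int rb = rd_code[i - 1];
          int v = diag + ((rb < 0 || tb < 0 || rb != tb) ? 1 : 0);
          if (above + 1 < v) v = above + 1;
          if (old + 1 < v) v = old + 1;
          if (v > K + 1) v = K + 1;
          col[i] = v;
          diag = old;
          above = v;
          if (v <= K) newlact = i;
        }
        if (lim < L) col[lim + 1] = K + 1;  // guard against stale entries
        lact = newlact;
        if (lact == L && col[L] <= K) {
          o_ref.push_back(r); o_strand.push_back(strand);
          o_end.push_back(j); o_dist.push_back(col[L]);
          if (col[L] < best) best = col[L];
        }
      }
    }
  }
  // keep only the globally best ends
  {
    std::vector<int> f_ref, f_strand, f_end;
    for (size_t t = 0; t < o_dist.size(); ++t) {
      if (o_dist[t] == best) {
        f_ref.push_back(o_ref[t]);
        f_strand.push_back(o_strand[t]);
        f_end.push_back(o_end[t]);
      }
    }
    o_ref.swap(f_ref); o_strand.swap(f_strand); o_end.swap(f_end);
  }
  if (best > allowance)
    return List::create(_["dist"] = -1, _["ref"] = IntegerVector(0),
                        _["strand"] = IntegerVector(0),
                        _["end"] = IntegerVector(0));
  return List::create(_["dist"] = best, _["ref"] = wrap(o_ref),
                      _["strand"] = wrap(o_strand), _["end"] = wrap(o_end));
}

namespace {

struct CigOp {
  char op;          // '=', 'X', 'I', 'D'
  int len;          // '=' / 'D' run length; 1 for 'X'
  std::string seq;  // read base for 'X', inserted bases for 'I'
};

std::vector<CigOp> parse_transcript(const std::string& cig) {
  std::vector<CigOp> ops;
  size_t i = 0;
  while (i < cig.size()) {
    char c = cig[i];
    if (c >= '0' && c <= '9') {
      int num = 0;
      while (i < cig.size() && cig[i] >= '0' && cig[i] <= '9')
        num = num * 10 + (cig[i++] - '0');
      if (i >= cig.size() || (cig[i] != '=' && cig[i] != 'D') || num == 0)
        stop("malformed alignment transcript");
      ops.push_back({cig[i++], num, ""});
    } else if (c == 'X') {
      if (i + 1 >= cig.size()) stop("malformed alignment transcript");
      ops.push_back({'X', 1, std::string(1, cig[i + 1])});
      i += 2;
    } else if (c == 'I') {
      ++i;
      std::string seq;
      while (i < cig.size() &&
             (base_code(cig[i]) >= 0 || cig[i] == 'N' || cig[i] == 'n'))
        seq += cig[i++];
      if (seq.empty()) stop("malformed alignment transcript");
      ops.push_back({'I', (int)seq.size(), seq});
    } else {
      stop("malformed alignment transcript");
    }
  }
  return ops;
}

// Left-normalize indel ops in place (VCF-style): an insertion or deletion
// is shifted left through the preceding match run while the flanking
// reference base equals the trailing base of the event, so that equivalent
// alignments from different reads (and strands) report one canonical
// event. `start` is the alignment's reference start.
void left_normalize(std::vector<CigOp>& ops, const std::string& ref,
                    int start) {
  // reference position at which each op begins
  for (size_t k = 0; k < ops.size(); ++k) {
    if (ops[k].op != 'I' && ops[k].op != 'D') continue;
    if (k == 0 || ops[k - 1].op != '=') continue;
    // position of this op on the reference
    int p = start;
    for (size_t t = 0; t < k; ++t)
      if (ops[t].op != 'I') p += ops[t].len;
    int shift = 0;
    const int room = ops[k - 1].len;
    if (ops[k].op == 'D') {
      const int l = ops[k].len;
      while (shift < room && p - shift - 1 >= 0 &&
             ref[p - shift - 1] == ref[p - shift + l - 1])
        ++shift;
    } else {
      std::string& s = ops[k].seq;
      const int l = (int)s.size();
      while (shift < room && p - shift - 1 >= 0 &&
             ref[p - shift - 1] == s[l - 1]) {
        s = std::string(1, ref[p - shift - 1]) + s.substr(0, l - 1);
        ++shift;
      }
    }
    if (shift > 0) {
      ops[k - 1].len -= shift;
      // matched bases displaced to the right of the event
      if (k + 1 < ops.size() && ops[k + 1].op == '=') {
        ops[k + 1].len += shift;
      } else {
        ops.insert(ops.begin() + k + 1, {'=', shift, ""});
      }
      if (ops[k - 1].len == 0) ops.erase(ops.begin() + (k - 1));
    }
  }
}

}  // namespace

// Pileup accumulation. Returns one 6 x L_ref count matrix per reference
// (rows A, C, G, T, N, del) plus an insertion-event table anchored at the
// 0-based reference position of the base preceding the insertion. Indel
// events are left-normalized before counting.
// [[Rcpp::export]]
List cpp_build_pileup(CharacterVector refseqs, IntegerVector aref,
                      IntegerVector astart, CharacterVector acig) {
  const int nref = (int)refseqs.size();
  std::vector<int> rlen(nref);
  List counts(nref);
  std::vector<IntegerMatrix> mats;
  std::vector<std::string> refs(nref);
  for (int r = 0; r < nref; ++r) {
    refs[r] = as<std::string>(refseqs[r]);
    rlen[r] = (int)refs[r].size();
    IntegerMatrix m(6, rlen[r]);
    mats.push_back(m);
    counts[r] = m;
  }
  std::map<std::tuple<int, int, std::string>, int> ins;

  auto row_of = [](char b) {
    switch (b) {
      case 'A': case 'a': return 0;
      case 'C': case 'c': return 1;
      case 'G': case 'g': return 2;
      case 'T': case 't': return 3;
      default: return 4;
    }
  };

  for (R_xlen_t k = 0; k < acig.size(); ++k) {
    const int r = aref[k];
    if (r < 0 || r >= nref) stop("alignment references unknown sequence");
    const std::string& ref = refs[r];
    std::vector<CigOp> ops = parse_transcript(as<std::string>(acig[k]));
    left_normalize(ops, ref, astart[k]);
    int p = astart[k];
    IntegerMatrix& m = mats[r];
    for (const CigOp& op : ops) {
      switch (op.op) {
        case '=':
          if (p + op.len > rlen[r])
            stop("alignment runs past reference end");
          for (int t = 0; t < op.len; ++t, ++p) m(row_of(ref[p]), p) += 1;
          break;
        case 'X':
          if (p >= rlen[r]) stop("alignment runs past reference end");
          m(row_of(op.seq[0]), p) += 1;
          ++p;
          break;
        case 'D':
          if (p + op.len > rlen[r])
            stop("alignment runs past reference end");
          for (int t = 0; t < op.len; ++t, ++p) m(5, p) += 1;
          break;
        case 'I':
          if (p >= 1) ins[std::make_tuple(r, p - 1, op.seq)] += 1;
          break;
      }
    }
  }
  const int ni = (int)ins.size();
  IntegerVector i_ref(ni), i_pos(ni), i_count(ni);
  CharacterVector i_seq(ni);
  int t = 0;
  for (auto& kv : ins) {
    i_ref[t] = std::get<0>(kv.first);
    i_pos[t] = std::get<1>(kv.first);
    i_seq[t] = std::get<2>(kv.first);
    i_count[t] = kv.second;
    ++t;
  }
  return List::create(
      _["counts"] = counts,
      _["insertions"] = DataFrame::create(
          _["ref"] = i_ref, _["pos"] = i_pos, _["seq"] = i_seq,
          _["count"] = i_count, _["stringsAsFactors"] = false));
}
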