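#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; -1 for anything outside ACGT
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Distances between consecutive occurrences of identical k-mers.
// Returns a two-column matrix (pos, dist), pos 0-based start of the earlier
// occurrence. Basis of tandem-period detection: within a concatemer, the
// same k-mer recurs one template copy apart.
// [[Rcpp::export(name = ".period_votes_cpp")]]
IntegerMatrix period_votes_cpp(std::string seq, int k, int min_dist, int max_dist) {
  int n = (int) seq.size();
  std::vector<int> pos_out, dist_out;
  if (n < k) return IntegerMatrix(0, 2);
  std::unordered_map<uint64_t, int> last;
  last.reserve(n * 2);
  uint64_t kmer = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) b) & mask;
    if (++valid < k) continue;
    int start = i - k + 1;
    auto it = last.find(kmer);
    if (it != last.end()) {
      int d = start - it->second;
      if (d >= min_dist && d <= max_dist) {
        pos_out.push_back(it->second);
        dist_out.push_back(d);
      }
      it->second = start;
    } else {
      last.emplace(kmer, start);
    }
  }
  IntegerMatrix out((int) pos_out.size(), 2);
  for (size_t i = 0; i < pos_out.size(); ++i) {
    out(i, 0) = pos_out[i];
    out(i, 1) = dist_out[i];
  }
  colnames(out) = CharacterVector::create("pos", "dist");
  return out;
}

// Plain global edit distance (unit costs).
// [[Rcpp::export(name = ".edit_dist_cpp")]]
int edit_dist_cpp(std::string a, std::string b) {
  int m = (int) a.size(), n = (int) b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Infix edit distance: the whole of `query` aligned against any substring of
// `ref` (free ref ends). Used to score a consensus against a rotated template
// by doubling the template.
// [[Rcpp::export(name = ".infix_edit_cpp")]]
int infix_edit_cpp(std::string query, std::string ref) {
  int m = (int) query.size(), n = (int) ref.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = 0;   // free start in ref
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (query[i - 1] == ref[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  int best = prev[0];
  for (int j = 1; j <= n; ++j) best = std::min(best, prev[j]); // free end in ref
  return best;
}

// ---------------------------------------------------------------------------
// Consensus calling: banded alignment of a unit sequence against successive
// copy windows of the raw read, with per-column base/gap/insertion voting.
// ---------------------------------------------------------------------------

struct Votes {
  int m;
  std::vector<int> base;  // 4 x m
  std::vector<int> gap;   // m
  std::vector<int> ins;   // 4 x (m+1): insertion before unit position s
  Votes(int m_) : m(m_), base(4 * m_, 0), gap(m_, 0), ins(4 * (m_ + 1), 0) {}
  void vote_base(int p, char c) {
    int b = base2bit(c);
    if (p >= 0 && p < m && b >= 0) base[4 * p + b]++;
  }
  void vote_gap(int p) { if (p >= 0 && p < m) gap[p]++; }
  void vote_ins(int s, char c) {
    int b = base2bit(c);
    if (s >= 0 && s <= m && b >= 0) ins[4 * s + b]++;
  }
};

// Banded DP of unit (rows) against window (cols). Band: j in [i-w, i+2w].
// mode 0: unit fully consumed, free window end (interior/leading full copy)
// mode 1: window fully consumed, free unit end (partial terminal copy)
// rev: both strings are reversed; vote positions are mapped back to forward
// unit coordinates.
// Returns consumed window length (and votes recorded); -1 if alignment is
// worse than max_edits.
static int align_unit(const std::string &unit, const char *win, int n, int w,
                      int mode, bool rev, Votes *V, int max_edits, int &edits_out) {
  int m = (int) unit.size();
  if (m == 0 || n <= 0) return -1;
  const int INF = 1 << 28;
  int width = 3 * w + 1;
  std::vector<int> dp((size_t)(m + 1) * width, INF);
  std::vector<uint8_t> mv((size_t)(m + 1) * width, 0); // 1 diag, 2 up, 3 left
  auto idx = [&](int i, int j) { return (size_t) i * width + (j - (i - w)); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= n && j >= i - w && j <= i + 2 * w;
  };
  for (int j = 0; j <= std::min(n, 2 * w); ++j) { dp[idx(0, j)] = j; mv[idx(0, j)] = 3; }
  mv[idx(0, 0)] = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(0, i - w), jhi = std::min(n, i + 2 * w);
    for (int j = jlo; j <= jhi; ++j) {
      int best = INF; uint8_t bm = 0;
      if (inband(i - 1, j - 1) && j >= 1) {
        int c = dp[idx(i - 1, j - 1)] + (unit[i - 1] == win[j - 1] ? 0 : 1);
        if (c < best) { best = c; bm = 1; }
      }
      if (inband(i - 1, j)) {
        int c = dp[idx(i - 1, j)] + 1;
        if (c < best) { best = c; bm = 2; }
      }
      if (j >= 1 && inband(i, j - 1)) {
        int c = dp[idx(i, j - 1)] + 1;
        if (c < best) { best = c; bm = 3; }
      }
      dp[idx(i, j)] = best; mv[idx(i, j)] = bm;
    }
  }
  int ei, ej, best = INF;
  if (mode == 0) {
    ei = m; ej = -1;
    int jlo = std::max(0, m - w), jhi = std::min(n, m + 2 * w);
    for (int j = jlo; j <= jhi; ++j)
      if (dp[idx(m, j)] < best) { best = dp[idx(m, j)]; ej = j; }
  } else {
    ej = n; ei = -1;
    for (int i = 0; i <= m; ++i)
      if (inband(i, n) && dp[idx(i, n)] < best) { best = dp[idx(i, n)]; ei = i; }
  }
  if (ej < 0 || ei < 0 || best >= INF || best > max_edits) return -1;
  edits_out = best;
  // traceback with votes
  if (V) {
    int i = ei, j = ej;
    uint8_t lastmv = 0;
    while (i > 0 || j > 0) {
      uint8_t mvv = mv[idx(i, j)];
      if (mvv == 0) break;
      if (mvv == 1) {
        int p = rev ? (m - i) : (i - 1);
        V->vote_base(p, win[j - 1]);
        i--; j--;
      } else if (mvv == 2) {
        int p = rev ? (m - i) : (i - 1);
        V->vote_gap(p);
        i--;
      } else {
        // insertion run: vote only once per run (first base in forward sense)
        if (lastmv != 3) {
          int s = rev ? (m - i) : i;
          V->vote_ins(s, win[j - 1]);
        }
        j--;
      }
      lastmv = mvv;
    }
  }
  return ej; // consumed window length
}

static std::string build_consensus(const Votes &V, const std::string &unit) {
  std::string out;
  int m = V.m;
  out.reserve(m + 8);
  const char *B = "ACGT";
  for (int s = 0; s <= m; ++s) {
    // coverage near this column
    int covpos = (s < m) ? s : m - 1;
    int cov = V.gap[covpos];
    for (int b = 0; b < 4; ++b) cov += V.base[4 * covpos + b];
    // insertion before position s if strictly majority-supported
    int ib = -1, ic = 0;
    for (int b = 0; b < 4; ++b)
      if (V.ins[4 * s + b] > ic) { ic = V.ins[4 * s + b]; ib = b; }
    if (ib >= 0 && 2 * ic > cov) out.push_back(B[ib]);
    if (s == m) break;
    int tot = V.gap[s];
    for (int b = 0; b < 4; ++b) tot += V.base[4 * s + b];
    if (tot == 0) { out.push_back(unit[s]); continue; }
    if (2 * V.gap[s] > tot) continue; // strict gap majority deletes the column
    int ub = base2bit(unit[s]);
    int bb = 0, bc = -1;
    for (int b = 0; b < 4; ++b)
      if (V.base[4 * s + b] > bc) { bc = V.base[4 * s + b]; bb = b; }
    // tie toward the draft's own base (deterministic two-copy rule)
    if (ub >= 0 && V.base[4 * s + ub] == bc) bb = ub;
    out.push_back(B[bb]);
  }
  return out;
}

// One voting pass: walk the read forward and backward from draft_start using
// `unit` as the backbone; returns consensus, span and copy support.
static List consensus_pass(const std::string &seq, const std::string &unit,
                           int draft_start, bool collect) {
  int L = (int) seq.size(), m = (int) unit.size();
  int w = std::max(16, m / 6);
  int max_edits = std::max(8, (int) (0.45 * m));
  Votes V(m);
  Votes *Vp = collect ? &V : NULL;
  double aligned = 0.0;
  int n_full = 0, edits_total = 0, edits;
  int sub_start = draft_start, sub_end = draft_start;
  // forward
  int cur = draft_start;
  while (L - cur >= (int) (0.5 * m)) {
    int n = std::min(L - cur, m + 2 * w);
    int mode = (L - cur >= m - w) ? 0 : 1;
    int consumed = align_unit(unit, seq.c_str() + cur, n, w, mode, false, Vp,
                              max_edits, edits);
    if (consumed <= 0) break;
    aligned += consumed; edits_total += edits;
    if (mode == 0) n_full++;
    cur += consumed;
    sub_end = cur;
    if (mode == 1) break;
  }
  // short forward tail
  if (sub_end == cur && L - cur >= 10 && L - cur < (int) (0.5 * m)) {
    int consumed = align_unit(unit, seq.c_str() + cur, L - cur, w, 1, false, Vp,
                              std::max(4, (L - cur) / 2), edits);
    if (consumed > 0) { aligned += consumed; edits_total += edits; sub_end = cur + consumed; }
  }
  // backward (reversed strings)
  std::string runit(unit.rbegin(), unit.rend());
  int back = draft_start;
  std::string rwin;
  while (back >= 10) {
    int take = std::min(back, m + 2 * w);
    rwin.assign(seq.rend() - back, seq.rend() - back + take); // seq[back-take .. back) reversed
    int mode = (back >= m - w) ? 0 : 1;
    int consumed = align_unit(runit, rwin.c_str(), take, w, mode, true, Vp,
                              (back >= (int) (0.5 * m)) ? max_edits : std::max(4, back / 2),
                              edits);
    if (consumed <= 0) break;
    aligned += consumed; edits_total += edits;
    if (mode == 0) n_full++;
    back -= consumed;
    sub_start = back;
    if (mode == 1) break;
  }
  std::string cons = collect ? build_consensus(V, unit) : unit;
  int match_votes = 0;
  if (collect) {
    for (int s = 0; s < m; ++s) {
      int mx = 0;
      for (int b = 0; b < 4; ++b) mx = std::max(mx, V.base[4 * s + b]);
      match_votes += mx;
    }
  }
  return List::create(_["consensus"] = cons,
                      _["aligned"] = aligned,
                      _["n_full"] = n_full,
                      _["edits"] = edits_total,
                      _["sub_start"] = sub_start,
                      _["sub_end"] = sub_end,
                      _["match_votes"] = match_votes);
}

// Full consensus call: pass 1 votes against the draft copy, pass 2 re-aligns
// every copy against the pass-1 consensus.
// [[Rcpp::export(name = ".consensus_call_cpp")]]
List consensus_call_cpp(std::string seq, int draft_start, int period, int passes = 2) {
  if (draft_start < 0 || period <= 0 ||
      draft_start + period > (int) seq.size())
    stop("invalid draft window");
  std::string unit = seq.substr(draft_start, period);
  List res = consensus_pass(seq, unit, draft_start, true);
  for (int p = 1; p < passes; ++p) {
    std::string cons = as<std::string>(res["consensus"]);
    if (cons.size() < 5) break;
    res = consensus_pass(seq, cons, draft_start, true);
  }
  double aligned = as<double>(res["aligned"]);
  std::string cons = as<std::string>(res["consensus"]);
  double cn = cons.size() > 0 ? aligned / (double) cons.size() : 0.0;
  return List::create(_["consensus"] = cons,
                      _["copy_number"] = cn,
                      _["n_full"] = as<int>(res["n_full"]),
                      _["sub_start"] = as<int>(res["sub_start"]),
                      _["sub_end"] = as<int>(res["sub_end"]),
                      _["edits"] = as<int>(res["edits"]),
                      _["score"] = (double) as<int>(res["match_votes"]));
}

// ---------------------------------------------------------------------------
// Toy spliced aligner support: exact k-mer anchors + colinear chaining.
// ---------------------------------------------------------------------------

// Exact k-mer matches of query into target. Target k-mers occurring more than
// max_hits times are masked (repeats). Returns (qpos, tpos), 0-based.
// [[Rcpp::export(name = ".kmer_anchors_cpp")]]
IntegerMatrix kmer_anchors_cpp(std::string query, std::string target, int k,
                               int max_hits) {
  int nq = (int) query.size(), nt = (int) target.size();
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(nt * 2);
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t kmer = 0; int valid = 0;
  for (int i = 0; i < nt; ++i) {
    int b = base2bit(target[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) b) & mask;
    if (++valid < k) continue;
    index[kmer].push_back(i - k + 1);
  }
  std::vector<int> qp, tp;
  kmer = 0; valid = 0;
  for (int i = 0; i < nq; ++i) {
    int b = base2bit(query[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) b) & mask;
    if (++valid < k) continue;
    auto it = index.find(kmer);
    if (it == index.end()) continue;
    if ((int) it->second.size() > max_hits) continue;
    for (int t : it->second) { qp.push_back(i - k + 1); tp.push_back(t); }
  }
  IntegerMatrix out((int) qp.size(), 2);
  for (size_t i = 0; i < qp.size(); ++i) { out(i, 0) = qp[i]; out(i, 1) = tp[i]; }
  colnames(out) = CharacterVector::create("qpos", "tpos");
  return out;
}

// Batched variant: one target index shared across many queries.
// [[Rcpp::export(name = ".kmer_anchors_multi_cpp")]]
List kmer_anchors_multi_cpp(CharacterVector queries, std::string target, int k,
                            int max_hits) {
  int nt = (int) target.size();
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(nt * 2);
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t kmer = 0; int valid = 0;
  for (int i = 0; i < nt; ++i) {
    int b = base2bit(target[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) b) & mask;
    if (++valid < k) continue;
    index[kmer].push_back(i - k + 1);
  }
  List out(queries.size());
  for (int q = 0; q < queries.size(); ++q) {
    std::string query = as<std::string>(queries[q]);
    std::vector<int> qp, tp;
    kmer = 0; valid = 0;
    int nq = (int) query.size();
    for (int i = 0; i < nq; ++i) {
      int b = base2bit(query[i]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t) b) & mask;
      if (++valid < k) continue;
      auto it = index.find(kmer);
      if (it == index.end()) continue;
      if ((int) it->second.size() > max_hits) continue;
      for (int t : it->second) { qp.push_back(i - k + 1); tp.push_back(t); }
    }
    IntegerMatrix m((int) qp.size(), 2);
    for (size_t i = 0; i < qp.size(); ++i) { m(i, 0) = qp[i]; m(i, 1) = tp[i]; }
    colnames(m) = CharacterVector::create("qpos", "tpos");
    out[q] = m;
  }
  return out;
}

// Colinear chaining of anchors (increasing query and target positions; intron
// gaps allowed on target). Returns up to max_chains chains of 1-based anchor
// indices, best first, with scores.
// [[Rcpp::export(name = ".chain_anchors_cpp")]]
List chain_anchors_cpp(IntegerVector qpos, IntegerVector tpos, int k,
                       int max_intron, int max_chains) {
  int n = qpos.size();
  if (n == 0) return List::create(_["chains"] = List(), _["scores"] = NumericVector());
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (qpos[a] != qpos[b]) return qpos[a] < qpos[b];
    return tpos[a] < tpos[b];
  });
  std::vector<double> f(n);
  std::vector<int> pre(n, -1);
  const int LOOKBACK = 80;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    f[i] = k;
    for (int oj = oi - 1; oj >= std::max(0, oi - LOOKBACK); --oj) {
      int j = ord[oj];
      int dq = qpos[i] - qpos[j], dt = tpos[i] - tpos[j];
      if (dq <= 0 || dt <= 0) continue;
      if (dt > max_intron + dq) continue;
      int gd = dt - dq;
      if (gd < -40) continue;
      // intron opening must cost more than one random anchor can repay
      double pen = (gd > 40) ? 25.0 : std::abs(gd) * 0.5;
      double cand = f[j] + std::min(k, dq) - pen;
      if (cand > f[i]) { f[i] = cand; pre[i] = j; }
    }
  }
  std::vector<int> by_score(n);
  for (int i = 0; i < n; ++i) by_score[i] = i;
  std::sort(by_score.begin(), by_score.end(),
            [&](int a, int b) { return f[a] > f[b]; });
  std::vector<char> used(n, 0);
  List chains;
  std::vector<double> scores;
  double best_score = f[by_score[0]];
  for (int s = 0; s < n && (int) chains.size() < max_chains; ++s) {
    int end = by_score[s];
    if (used[end]) continue;
    if (f[end] < 0.25 * best_score || f[end] < 2 * k) {
      if (chains.size() > 0) break;
    }
    std::vector<int> chain;
    int overlap = 0, len = 0;
    for (int c = end; c >= 0; c = pre[c]) {
      chain.push_back(c);
      len++;
      if (used[c]) overlap++;
    }
    if (overlap * 2 > len) continue;
    std::reverse(chain.begin(), chain.end());
    IntegerVector cv((int) chain.size());
    for (size_t i = 0; i < chain.size(); ++i) { cv[i] = chain[i] + 1; used[chain[i]] = 1; }
    chains.push_back(cv);
    scores.push_back(f[end]);
  }
  return List::create(_["chains"] = chains, _["scores"] = wrap(scores));
}
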