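#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// 2-bit nucleotide encoding; 4 = anything that is not A/C/G/T (scores as a
// mismatch against every base, including itself -- N carries no information).
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<int> encode(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'a': c = 'T'; break;
    case 'C': c = 'G'; break; case 'c': c = 'G'; break;
    case 'G': c = 'C'; break; case 'g': c = 'C'; break;
    case 'T': c = 'A'; break; case 't': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct Hsp {
  int qs, qe, ss, se, score, mism;
};

typedef std::unordered_map<uint32_t, std::vector<int> > WordIndex;

static WordIndex build_index(const std::vector<int> &s, int w) {
  WordIndex idx;
  if ((int)s.size() < w) return idx;
  uint32_t mask = (w >= 16) ? 0xFFFFFFFFu : ((1u << (2 * w)) - 1);
  uint32_t key = 0;
  int run = 0; // length of current clean (ACGT-only) suffix
  for (int i = 0; i < (int)s.size(); ++i) {
    if (s[i] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)s[i]) & mask;
    if (++run >= w) idx[key].push_back(i - w + 1);
  }
  return idx;
}

// Two-sided x-drop extension of an exact word seed on one diagonal.
// Returns the maximal-scoring ungapped segment reachable from the seed.
static Hsp extend_seed(const std::vector<int> &q, const std::vector<int> &s,
                       int qi, int si, int w, int match, int mismatch,
                       int x_drop) {
  int score0 = w * match;
  // right extension from position just past the seed word
  int cur = 0, best = 0, bestoff = 0;
  int i = qi + w, j = si + w;
  while (i < (int)q.size() && j < (int)s.size()) {
    cur += (q[i] <= 3 && q[i] == s[j]) ? match : mismatch;
    ++i; ++j;
    if (cur > best) { best = cur; bestoff = i - (qi + w); }
    if (cur < best - x_drop) break;
  }
  int right = bestoff, right_best = best;
  // left extension
  cur = 0; best = 0; bestoff = 0;
  i = qi - 1; j = si - 1;
  while (i >= 0 && j >= 0) {
    cur += (q[i] <= 3 && q[i] == s[j]) ? match : mismatch;
    --i; --j;
    if (cur > best) { best = cur; bestoff = (qi - 1) - i; }
    if (cur < best - x_drop) break;
  }
  int left = bestoff, left_best = best;
  Hsp h;
  h.qs = qi - left;
  h.qe = qi + w + right;
  h.ss = si - left;
  h.se = si + w + right;
  h.score = score0 + left_best + right_best;
  h.mism = 0;
  for (int k = 0; k < h.qe - h.qs; ++k)
    if (!(q[h.qs + k] <= 3 && q[h.qs + k] == s[h.ss + k])) ++h.mism;
  return h;
}

static std::vector<Hsp> seed_extend(const std::vector<int> &q,
                                    const std::vector<int> &s,
                                    const WordIndex &idx, int w, int match,
                                    int mismatch, int x_drop, int min_score) {
  // collect seeds grouped by diagonal d = qi - si
  std::unordered_map<int, std::vector<std::pair<int, int> > > diag; // d -> (qi,si)
  if ((int)q.size() >= w) {
    uint32_t mask = (w >= 16) ? 0xFFFFFFFFu : ((1u << (2 * w)) - 1);
    uint32_t key = 0;
    int run = 0;
    for (int i = 0; i < (int)q.size(); ++i) {
      if (q[i] > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)q[i]) & mask;
      if (++run >= w) {
        int qi = i - w + 1;
        WordIndex::const_iterator it = idx.find(key);
        if (it != idx.end())
          for (int si : it->second)
            diag[qi - si].push_back(std::make_pair(qi, si));
      }
    }
  }
  std::vector<Hsp> out;
  for (auto &kv : diag) {
    std::vector<std::pair<int, int> > &seeds = kv.second;
    std::sort(seeds.begin(), seeds.end());
    int covered_to = -1; // q-end of last extension on this diagonal
    for (auto &sd : seeds) {
      if (sd.first + w <= covered_to) continue; // seed inside previous segment
      Hsp h = extend_seed(q, s, sd.first, sd.second, w, match, mismatch, x_drop);
      covered_to = std::max(covered_to, h.qe);
      if (h.score >= min_score) out.push_back(h);
    }
  }
  // dedupe identical intervals (two seeds can extend to the same segment)
  std::sort(out.begin(), out.end(), [](const Hsp &a, const Hsp &b) {
    if (a.qs != b.qs) return a.qs < b.qs;
    if (a.qe != b.qe) return a.qe < b.qe;
    return a.ss < b.ss;
  });
  out.erase(std::unique(out.begin(), out.end(), [](const Hsp &a, const Hsp &b) {
              return a.qs == b.qs && a.qe == b.qe && a.ss == b.ss;
            }),
            out.end());
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_ungapped_hsps(std::string query, std::string subject,
                            int word_size, int match, int mismatch,
                            int x_drop, int min_score) {
  std::vector<int> q = encode(query), s = encode(subject);
  WordIndex idx = build_index(s, word_size);
  std::vector<Hsp> hs =
      seed_extend(q, s, idx, word_size, match, mismatch, x_drop, min_score);
  int n = hs.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), sc(n), mm(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = hs[i].qs; qe[i] = hs[i].qe; ss[i] = hs[i].ss; se[i] = hs[i].se;
    sc[i] = hs[i].score; mm[i] = hs[i].mism;
  }
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["s_start"] = ss, _["s_end"] = se,
                           _["score"] = sc, _["mismatches"] = mm);
}

// Best ungapped local alignment of each read (both strands) to one template.
// Coordinates of the read interval refer to the strand-oriented read (the
// reverse complement for strand "-"), so oriented read and template always
// run in the same direction.
// [[Rcpp::export]]
DataFrame cpp_align_reads(CharacterVector reads, std::string tmpl,
                          int word_size, int match, int mismatch, int x_drop,
                          int min_len, double max_mismatch_frac) {
  std::vector<int> t = encode(tmpl);
  WordIndex idx = build_index(t, word_size);
  int min_score =
      (int)std::ceil(min_len * (match - max_mismatch_frac * (match - mismatch)));
  std::vector<int> o_read; std::vector<char> o_strand;
  std::vector<Hsp> o_hsp;
  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    bool have = false; Hsp best; char best_strand = '+';
    for (int st = 0; st < 2; ++st) {
      std::string rs = st == 0 ? fwd : revcomp(fwd);
      std::vector<int> q = encode(rs);
      std::vector<Hsp> hs = seed_extend(q, t, idx, word_size, match, mismatch,
                                        x_drop, min_score);
      for (auto &h : hs) {
        int len = h.qe - h.qs;
        if (len < min_len) continue;
        if (h.mism > max_mismatch_frac * len) continue;
        if (!have || h.score > best.score ||
            (h.score == best.score && st == 0 && best_strand == '-')) {
          best = h; best_strand = st == 0 ? '+' : '-'; have = true;
        }
      }
    }
    if (have) {
      o_read.push_back(r + 1);
      o_strand.push_back(best_strand);
      o_hsp.push_back(best);
    }
  }
  int n = o_read.size();
  IntegerVector ri(n), rs_(n), re_(n), ts(n), te(n), sc(n), mm(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    ri[i] = o_read[i];
    rs_[i] = o_hsp[i].qs; re_[i] = o_hsp[i].qe;
    ts[i] = o_hsp[i].ss; te[i] = o_hsp[i].se;
    sc[i] = o_hsp[i].score; mm[i] = o_hsp[i].mism;
    strand[i] = std::string(1, o_strand[i]);
  }
  return DataFrame::create(_["read"] = ri, _["strand"] = strand,
                           _["read_start"] = rs_, _["read_end"] = re_,
                           _["tmpl_start"] = ts, _["tmpl_end"] = te,
                           _["score"] = sc, _["mismatches"] = mm);
}

// ---- translated (protein) HSP scoring: ungapped diagonal anchors followed
// ---- by two-sided gapped x-drop extension, the HSP semantics of seeded
// ---- translated aligners (unconstrained Smith-Waterman instead bridges
// ---- long non-matching stretches and banks composition-driven chains,
// ---- which breaks the scrambled-control null).

static const double NEG_BIG = -1e30;

// Gapped x-drop extension outward from the last aligned pair (q0, s0).
// dir = +1 extends right (aligning a[q0+i] with b[s0+j]), dir = -1 left.
// Affine gaps (open+ext per gap opening); cells whose running score falls
// more than X below the best so far are pruned, and extension stops when a
// row has no live cell -- so long non-matching stretches terminate the
// alignment instead of being bridged.
static double xdrop_extend(const std::vector<int> &a, const std::vector<int> &b,
                           int q0, int s0, int dir,
                           const Rcpp::NumericMatrix &smat, double go,
                           double ge, double X) {
  int n = dir > 0 ? (int)a.size() - q0 - 1 : q0;
  int m = dir > 0 ? (int)b.size() - s0 - 1 : s0;
  if (n <= 0 || m <= 0) return 0.0;
  std::vector<double> H(m + 1, NEG_BIG), F(m + 1, NEG_BIG);
  std::vector<double> Hn(m + 1), Fn(m + 1);
  H[0] = 0.0;
  double best = 0.0;
  int lo = 0, hi = 0; // live j-range of the previous row
  for (int i = 1; i <= n; ++i) {
    int nlo = -1, nhi = -1;
    double e = NEG_BIG; // gap-in-query running score within this row
    int jcap = m;
    for (int j = std::max(0, lo); j <= jcap; ++j) {
      Hn[j] = NEG_BIG; Fn[j] = NEG_BIG;
      double h = NEG_BIG;
      if (j >= 1) {
        double diag = (j - 1 >= lo && j - 1 <= hi) ? H[j - 1] : NEG_BIG;
        if (diag > NEG_BIG / 2) {
          int ai = dir > 0 ? q0 + i : q0 - i;
          int bj = dir > 0 ? s0 + j : s0 - j;
          h = diag + smat(a[ai], b[bj]);
        }
      }
      double f = NEG_BIG; // gap in subject (vertical)
      if (j >= lo && j <= hi) {
        if (H[j] > NEG_BIG / 2) f = H[j] - go - ge;
        if (F[j] > NEG_BIG / 2 && F[j] - ge > f) f = F[j] - ge;
      }
      double hv = std::max(h, std::max(e, f));
      // update row-wise E for the next column before pruning decision
      double enext = NEG_BIG;
      if (hv > NEG_BIG / 2) enext = hv - go - ge;
      if (e > NEG_BIG / 2 && e - ge > enext) enext = e - ge;
      if (hv < best - X || hv <= NEG_BIG / 2) {
        e = enext;
        if (nhi >= 0 && j > hi + 1 && e < best - X) break;
        continue;
      }
      Hn[j] = hv;
      Fn[j] = f;
      if (hv > best) best = hv;
      if (nlo < 0) nlo = j;
      nhi = j;
      e = enext;
    }
    if (nlo < 0) break;
    H.swap(Hn); F.swap(Fn);
    lo = nlo; hi = nhi;
  }
  return best;
}

// [[Rcpp::export]]
double cpp_translated_hsp_score(IntegerVector q, IntegerVector s,
                                NumericMatrix smat, double gap_open,
                                double gap_extend, double x_drop,
                                double anchor_min) {
  std::vector<int> a(q.begin(), q.end()), b(s.begin(), s.end());
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  double best_total = 0.0;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    int i0 = std::max(0, -d);
    int len = std::min(n - i0, m - (i0 + d));
    if (len <= 0) continue;
    // ungapped x-drop segments of the diagonal anchor the gapped
    // extension; the x-drop applies here too, so an anchor never bridges a
    // long negative stretch between two matching blocks
    double cur = 0.0, curbest = 0.0;
    int start = i0, beststart = i0, bestend = i0 - 1;
    for (int k = 0; k < len; ++k) {
      int i = i0 + k, j = i + d;
      double v = smat(a[i], b[j]);
      if (cur <= 0) { cur = v; start = i; }
      else cur += v;
      if (cur > curbest) { curbest = cur; beststart = start; bestend = i; }
      bool close = (k == len - 1) || cur < curbest - x_drop;
      if (close) {
        if (curbest >= anchor_min) {
          double tot = curbest +
              xdrop_extend(a, b, bestend, bestend + d, +1, smat, gap_open,
                           gap_extend, x_drop) +
              xdrop_extend(a, b, beststart, beststart + d, -1, smat,
                           gap_open, gap_extend, x_drop);
          if (tot > best_total) best_total = tot;
        }
        cur = 0.0; curbest = 0.0;
        start = i + 1; beststart = start; bestend = start - 1;
      }
    }
  }
  return best_total;
}
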