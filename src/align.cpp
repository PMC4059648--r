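// Local alignment engine for all-to-all read comparison and read mapping.
//
// Scoring: +match, -mismatch, affine gaps where a gap of length g costs
// gap_open + (g-1)*gap_ext (first gap base pays gap_open). Identity is
// matches / alignment columns (gap columns count); overlap is the number
// of alignment columns of the best-scoring local alignment. Among
// co-optimal traceback steps the diagonal is preferred, so the reported
// alignment maximises matches at equal score. 'N' never matches anything.
//
// The hot path is a score-only Smith-Waterman with two rolling rows; the
// traceback pass (packed one-byte pointers) runs only for pairs whose
// score clears the minimum any threshold-passing alignment can have.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

static inline int encode_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N or anything else
  }
}

typedef std::vector<uint8_t> Seq;

static Seq encode_seq(const char* s, size_t n) {
  Seq out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (uint8_t) encode_base(s[i]);
  return out;
}

static Seq revcomp_seq(const Seq& s) {
  Seq out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    uint8_t c = s[s.size() - 1 - i];
    out[i] = (c < 4) ? (uint8_t)(3 - c) : (uint8_t)4;
  }
  return out;
}

struct AlnResult {
  int score, matches, cols;
  int astart, aend, bstart, bend; // 1-based inclusive on each sequence
};

struct Aligner {
  int match, mismatch, gap_open, gap_ext;
  std::vector<int> H, E;        // rolling rows
  std::vector<uint8_t> tb;      // packed traceback, (m+1)*(n+1)

  Aligner(int ma, int mi, int go, int ge)
    : match(ma), mismatch(mi), gap_open(go), gap_ext(ge) {}

  // best local score only; two rolling rows, no traceback
  int score_only(const Seq& a, const Seq& b) {
    const int m = (int) a.size(), n = (int) b.size();
    if ((int) H.size() < n + 1) { H.resize(n + 1); E.resize(n + 1); }
    const int NEG = -1000000000;
    for (int j = 0; j <= n; ++j) { H[j] = 0; E[j] = NEG; }
    int best = 0;
    for (int i = 1; i <= m; ++i) {
      const uint8_t ai = a[i - 1];
      int hdiag = 0;      // H[i-1][j-1]
      int f = NEG;        // horizontal gap state within this row
      int hleft = 0;      // H[i][j-1]
      for (int j = 1; j <= n; ++j) {
        const int hup = H[j];
        int e = std::max(hup - gap_open, E[j] - gap_ext);
        E[j] = e;
        f = std::max(hleft - gap_open, f - gap_ext);
        const uint8_t bj = b[j - 1];
        int h = hdiag + ((ai < 4 && ai == bj) ? match : -mismatch);
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        if (h > best) best = h;
        hdiag = hup;
        H[j] = h;
        hleft = h;
      }
    }
    return best;
  }

  // full alignment with traceback; packed pointers:
  // bits 0-1 H source (0 stop, 1 diag, 2 E, 3 F); bit 2 E-extends;
  // bit 3 F-extends
  AlnResult align(const Seq& a, const Seq& b) {
    const int m = (int) a.size(), n = (int) b.size();
    const size_t sz = (size_t)(m + 1) * (n + 1);
    if ((int) H.size() < n + 1) { H.resize(n + 1); E.resize(n + 1); }
    if (tb.size() < sz) tb.resize(sz);
    const int NEG = -1000000000;
    for (int j = 0; j <= n; ++j) { H[j] = 0; E[j] = NEG; tb[j] = 0; }
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
      const uint8_t ai = a[i - 1];
      size_t row = (size_t) i * (n + 1);
      tb[row] = 0;
      int hdiag = 0, f = NEG, hleft = 0;
      for (int j = 1; j <= n; ++j) {
        const int hup = H[j];
        uint8_t t = 0;
        int e_open = hup - gap_open, e_ext = E[j] - gap_ext;
        int e = e_open;
        if (e_ext > e_open) { e = e_ext; t |= 4; }
        E[j] = e;
        int f_open = hleft - gap_open, f_ext = f - gap_ext;
        if (f_ext > f_open) { f = f_ext; t |= 8; } else f = f_open;
        const uint8_t bj_ = b[j - 1];
        int h = hdiag + ((ai < 4 && ai == bj_) ? match : -mismatch);
        uint8_t hsrc = 1;
        if (e > h) { h = e; hsrc = 2; }
        if (f > h) { h = f; hsrc = 3; }
        if (h <= 0) { h = 0; hsrc = 0; }
        tb[row + j] = (uint8_t)(t | hsrc);
        if (h > best) { best = h; bi = i; bj = j; }
        hdiag = hup;
        H[j] = h;
        hleft = h;
      }
    }
    AlnResult r; r.score = best; r.matches = 0; r.cols = 0;
    r.aend = bi; r.bend = bj;
    if (best <= 0) { r.astart = r.bstart = 0; r.aend = r.bend = 0; return r; }
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E (vertical, consumes a), 2 = F (horizontal)
    for (;;) {
      uint8_t t = tb[(size_t) i * (n + 1) + j];
      if (state == 0) {
        uint8_t hsrc = t & 3;
        if (hsrc == 0) break;
        if (hsrc == 1) {
          ++r.cols;
          if (a[i - 1] < 4 && a[i - 1] == b[j - 1]) ++r.matches;
          --i; --j;
        } else if (hsrc == 2) state = 1;
        else state = 2;
      } else if (state == 1) { // E: gap in b, consumes a_i
        ++r.cols;
        bool ext = (t & 4) != 0;
        --i;
        if (!ext) state = 0;
      } else {                 // F: gap in a, consumes b_j
        ++r.cols;
        bool ext = (t & 8) != 0;
        --j;
        if (!ext) state = 0;
      }
    }
    r.astart = i + 1; r.bstart = j + 1;
    return r;
  }
};

// Lowest score any alignment passing (min_identity, min_overlap) can
// have: c = min_overlap columns, ceil(min_identity*c) matches, the rest
// charged at the worst per-column penalty. The bound grows with c, so
// evaluating at c = min_overlap is a valid global lower bound.
static int min_passing_score(double min_identity, int min_overlap,
                             int match, int mismatch, int gap_open) {
  int mat = (int) std::ceil(min_identity * min_overlap - 1e-9);
  int other = min_overlap - mat;
  int worst = std::max(mismatch, gap_open);
  return mat * match - other * worst;
}

// ---- k-mer machinery -------------------------------------------------------

static inline uint32_t rc_kmer(uint32_t km, int k) {
  uint32_t out = 0;
  for (int i = 0; i < k; ++i) {
    out = (out << 2) | (3u - (km & 3u));
    km >>= 2;
  }
  return out;
}

// Sorted unique canonical k-mers of a sequence; windows containing N skipped.
static std::vector<uint32_t> canonical_kmers(const Seq& s, int k) {
  std::vector<uint32_t> out;
  if ((int) s.size() < k) return out;
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  const int shift = 2 * (k - 1);
  uint32_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    uint8_t c = s[i];
    if (c > 3) { run = 0; continue; }
    fwd = ((fwd << 2) | c) & mask;
    rev = (rev >> 2) | ((3u - c) << shift);
    if (++run >= k) out.push_back(fwd < rev ? fwd : rev);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

// ---- single pair alignment (exported for tests / cross-checks) -------------

// [[Rcpp::export(name = ".sw_pair")]]
List sw_pair_cpp(std::string a, std::string b,
                 int match = 1, int mismatch = 2,
                 int gap_open = 3, int gap_ext = 1) {
  Aligner al(match, mismatch, gap_open, gap_ext);
  Seq ea = encode_seq(a.c_str(), a.size());
  Seq eb = encode_seq(b.c_str(), b.size());
  AlnResult r = al.align(ea, eb);
  return List::create(
    _["score"] = r.score, _["matches"] = r.matches, _["cols"] = r.cols,
    _["astart"] = r.astart, _["aend"] = r.aend,
    _["bstart"] = r.bstart, _["bend"] = r.bend);
}

// ---- all-to-all hit search -------------------------------------------------

// [[Rcpp::export(name = ".sw_all_hits")]]
DataFrame sw_all_hits_cpp(CharacterVector seqs,
                          double min_identity, int min_overlap,
                          int match, int mismatch, int gap_open, int gap_ext,
                          bool seeded, int seed_k) {
  const int n = seqs.size();
  std::vector<Seq> fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    fwd[i] = encode_seq(s, LENGTH(STRING_ELT(seqs, i)));
    rev[i] = revcomp_seq(fwd[i]);
  }
  Aligner al(match, mismatch, gap_open, gap_ext);
  const int smin = min_passing_score(min_identity, min_overlap,
                                     match, mismatch, gap_open);

  std::vector<int> ia, ja, ov, sc;
  std::vector<double> idv;
  std::vector<int> orient; // 0 forward, 1 reverse

  auto consider = [&](int i, int j) {
    int sf = al.score_only(fwd[i], fwd[j]);
    int sr = al.score_only(fwd[i], rev[j]);
    int smax = std::max(sf, sr);
    if (smax < smin) return;
    int o = (sr > sf) ? 1 : 0; // tie -> forward
    AlnResult best = al.align(fwd[i], o ? rev[j] : fwd[j]);
    if (best.cols >= min_overlap &&
        (double) best.matches >= min_identity * (double) best.cols - 1e-9) {
      ia.push_back(i + 1); ja.push_back(j + 1);
      idv.push_back((double) best.matches / (double) best.cols);
      ov.push_back(best.cols); orient.push_back(o); sc.push_back(best.score);
    }
  };

  if (!seeded) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) consider(i, j);
      if (i % 16 == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    std::vector<std::vector<uint32_t> > kms(n);
    std::unordered_map<uint32_t, std::vector<int> > index;
    for (int i = 0; i < n; ++i) {
      kms[i] = canonical_kmers(fwd[i], seed_k);
      for (uint32_t km : kms[i]) index[km].push_back(i);
    }
    std::vector<int> lastseen(n, -1);
    for (int i = 0; i < n; ++i) {
      for (uint32_t km : kms[i]) {
        std::vector<int>& bucket = index[km];
        for (int j : bucket) {
          if (j > i && lastseen[j] != i) {
            lastseen[j] = i;
            consider(i, j);
          }
        }
      }
      if (i % 16 == 0) Rcpp::checkUserInterrupt();
    }
  }
  // deterministic order
  std::vector<size_t> ord(ia.size());
  for (size_t t = 0; t < ord.size(); ++t) ord[t] = t;
  std::sort(ord.begin(), ord.end(), [&](size_t x, size_t y) {
    if (ia[x] != ia[y]) return ia[x] < ia[y];
    return ja[x] < ja[y];
  });
  IntegerVector oa(ia.size()), ob(ia.size()), oo(ia.size()), os(ia.size()),
                oor(ia.size());
  NumericVector oid(ia.size());
  for (size_t t = 0; t < ord.size(); ++t) {
    size_t u = ord[t];
    oa[t] = ia[u]; ob[t] = ja[u]; oid[t] = idv[u];
    oo[t] = ov[u]; oor[t] = orient[u]; os[t] = sc[u];
  }
  return DataFrame::create(
    _["a"] = oa, _["b"] = ob, _["identity"] = oid, _["overlap"] = oo,
    _["reverse"] = oor, _["score"] = os);
}

// ---- seeded mapping of reads onto long subjects ----------------------------

// Best local alignment per (read, subject) pair, found by clustering shared
// k-mer diagonals, scoring the read against each implied subject window and
// tracing back only the best one. Returns hits passing the thresholds.
// [[Rcpp::export(name = ".sw_map_reads")]]
DataFrame sw_map_reads_cpp(CharacterVector reads, CharacterVector subjects,
                           double min_identity, int min_overlap,
                           int match, int mismatch, int gap_open, int gap_ext,
                           int seed_k) {
  const int nr = reads.size(), ns = subjects.size();
  Aligner al(match, mismatch, gap_open, gap_ext);
  const int smin = min_passing_score(min_identity, min_overlap,
                                     match, mismatch, gap_open);
  const uint32_t mask = (seed_k == 16) ? 0xFFFFFFFFu
                                       : ((1u << (2 * seed_k)) - 1u);
  std::vector<int> out_r, out_s, out_ov, out_sc, out_ss, out_se, out_rev;
  std::vector<double> out_id;

  std::vector<Seq> rf(nr), rr(nr);
  for (int i = 0; i < nr; ++i) {
    rf[i] = encode_seq(CHAR(STRING_ELT(reads, i)),
                       LENGTH(STRING_ELT(reads, i)));
    rr[i] = revcomp_seq(rf[i]);
  }

  for (int s = 0; s < ns; ++s) {
    Seq sub = encode_seq(CHAR(STRING_ELT(subjects, s)),
                         LENGTH(STRING_ELT(subjects, s)));
    const int slen = (int) sub.size();
    if (slen < seed_k) continue;
    // forward-strand k-mer position index of the subject
    std::unordered_map<uint32_t, std::vector<int> > index;
    {
      uint32_t km = 0; int run = 0;
      for (int p = 0; p < slen; ++p) {
        uint8_t c = sub[p];
        if (c > 3) { run = 0; continue; }
        km = ((km << 2) | c) & mask;
        if (++run >= seed_k) index[km].push_back(p - seed_k + 1);
      }
    }
    for (int i = 0; i < nr; ++i) {
      const int rlen = (int) rf[i].size();
      int best_score = 0, best_w0 = 0, best_w1 = 0, best_rev = 0;
      for (int strand = 0; strand < 2; ++strand) {
        const Seq& rd = (strand == 0) ? rf[i] : rr[i];
        std::vector<int> diags;
        uint32_t km = 0; int run = 0;
        for (int p = 0; p < rlen; ++p) {
          uint8_t c = rd[p];
          if (c > 3) { run = 0; continue; }
          km = ((km << 2) | c) & mask;
          if (++run >= seed_k) {
            auto it = index.find(km);
            if (it != index.end()) {
              int rpos = p - seed_k + 1;
              for (int sp : it->second) diags.push_back(sp - rpos);
            }
          }
        }
        if (diags.empty()) continue;
        std::sort(diags.begin(), diags.end());
        diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
        size_t g0 = 0;
        for (size_t t = 1; t <= diags.size(); ++t) {
          if (t == diags.size() || diags[t] - diags[t - 1] > 60) {
            int dlo = diags[g0], dhi = diags[t - 1];
            int w0 = std::max(0, dlo - 60);
            int w1 = std::min(slen, dhi + rlen + 60);
            if (w1 - w0 >= seed_k) {
              Seq win(sub.begin() + w0, sub.begin() + w1);
              int sc_ = al.score_only(rd, win);
              if (sc_ > best_score) {
                best_score = sc_; best_w0 = w0; best_w1 = w1;
                best_rev = strand;
              }
            }
            g0 = t;
          }
        }
      }
      if (best_score >= smin && best_score > 0) {
        const Seq& rd = (best_rev == 0) ? rf[i] : rr[i];
        Seq win(sub.begin() + best_w0, sub.begin() + best_w1);
        AlnResult best = al.align(rd, win);
        if (best.cols >= min_overlap &&
            (double) best.matches >=
              min_identity * (double) best.cols - 1e-9) {
          out_r.push_back(i + 1); out_s.push_back(s + 1);
          out_id.push_back((double) best.matches / (double) best.cols);
          out_ov.push_back(best.cols); out_sc.push_back(best.score);
          out_ss.push_back(best_w0 + best.bstart); // 1-based on subject
          out_se.push_back(best_w0 + best.bend);
          out_rev.push_back(best_rev);
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
    _["read"] = out_r, _["subject"] = out_s, _["identity"] = out_id,
    _["overlap"] = out_ov, _["score"] = out_sc,
    _["sstart"] = out_ss, _["send"] = out_se, _["reverse"] = out_rev);
}
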