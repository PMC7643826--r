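// Seed-and-extend read recruitment with explicit identity arithmetic.
//
// Identity semantics (fixed contract, recomputable from stored counts):
//   identity = 100 * matches / (matches + mismatches + gap_columns)
// where every gap column (read base vs gap, or gap vs reference base) counts
// once. N never counts as a match, on either side.
//
// The production path is seeded: exact k-mer hits define candidate windows on
// the reference and a full Smith-Waterman (affine gaps) is run inside each
// window. The test oracle (oracle_sw below) is an independently written,
// exhaustive full-matrix DP with no seeding or windowing; both use the same
// deterministic tie preferences (diagonal > ref-gap > read-gap; gap open >
// extend; first-encountered maximum cell) so co-optimal tracebacks agree.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N / ambiguous: never a match
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': case 'a': r[i] = 'T'; break;
    case 'C': case 'c': r[i] = 'G'; break;
    case 'G': case 'g': r[i] = 'C'; break;
    case 'T': case 't': r[i] = 'A'; break;
    default: r[i] = 'N';
    }
  }
  return r;
}

struct Aln {
  int score = 0;
  int matches = 0, mismatches = 0, gaps = 0;
  int read_aligned = 0;       // read bases consumed by the alignment
  int ref_start = 0, ref_end = 0; // 0-based half-open on the full sequence
  bool valid = false;
  double identity() const {
    int cols = matches + mismatches + gaps;
    return cols > 0 ? 100.0 * matches / cols : 0.0;
  }
};

// ---------------------------------------------------------------------------
// Windowed Smith-Waterman with affine gaps and stored-direction traceback.
// Aligns read against ref[ws, we). Production path.
// ---------------------------------------------------------------------------
static Aln sw_window(const std::string& read, const std::string& ref,
                     int ws, int we,
                     int ma, int mi, int go, int ge) {
  const int m = (int) read.size();
  const int n = we - ws;
  Aln out;
  if (m <= 0 || n <= 0) return out;
  const int NEG = -1000000000;

  std::vector<int> rc(m), bc(n);
  for (int i = 0; i < m; ++i) rc[i] = base_code(read[i]);
  for (int j = 0; j < n; ++j) bc[j] = base_code(ref[ws + j]);

  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Fcol(n + 1, NEG);
  // direction matrices, (m+1) x (n+1)
  std::vector<uint8_t> dH((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> dE((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> dF((size_t)(m + 1) * (n + 1), 0);
  auto idx = [n](int i, int j) { return (size_t) i * (n + 1) + j; };

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    int Ei = NEG; // E[i][0]
    Hcur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      // E: gap consuming a reference base (gap column, ref side)
      int e_open = Hcur[j - 1] + go;
      int e_ext  = Ei + ge;
      int E;
      if (e_open >= e_ext) { E = e_open; dE[idx(i, j)] = 1; }
      else                 { E = e_ext;  dE[idx(i, j)] = 2; }
      Ei = E;
      // F: gap consuming a read base
      int f_open = Hprev[j] + go;
      int f_ext  = Fcol[j] + ge;
      int F;
      if (f_open >= f_ext) { F = f_open; dF[idx(i, j)] = 1; }
      else                 { F = f_ext;  dF[idx(i, j)] = 2; }
      Fcol[j] = F;
      // H with tie preference diag > E > F > stop
      bool is_match = (rc[i - 1] == bc[j - 1]) && rc[i - 1] < 4;
      int diag = Hprev[j - 1] + (is_match ? ma : mi);
      int H; uint8_t d;
      if (diag >= E && diag >= F && diag > 0)      { H = diag; d = 1; }
      else if (E >= F && E > 0)                    { H = E;    d = 2; }
      else if (F > 0)                              { H = F;    d = 3; }
      else                                         { H = 0;    d = 0; }
      Hcur[j] = H; dH[idx(i, j)] = d;
      if (H > best) { best = H; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) return out;

  // traceback
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  for (;;) {
    if (state == 0) {
      uint8_t d = dH[idx(i, j)];
      if (d == 0) break;
      if (d == 1) {
        bool is_match = base_code(read[i - 1]) == base_code(ref[ws + j - 1]) &&
                        base_code(read[i - 1]) < 4;
        if (is_match) out.matches++; else out.mismatches++;
        out.read_aligned++;
        --i; --j;
      } else if (d == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      out.gaps++;
      uint8_t d = dE[idx(i, j)];
      --j;
      if (d == 1) state = 0;
    } else {
      out.gaps++;
      out.read_aligned++;
      uint8_t d = dF[idx(i, j)];
      --i;
      if (d == 1) state = 0;
    }
  }
  out.score = best;
  out.ref_start = ws + j;
  out.ref_end = ws + bj;
  out.valid = true;
  return out;
}

// Score-only pass over a window (no traceback bookkeeping); used to rank
// candidate windows cheaply before the full DP runs on the survivors.
static int sw_score_window(const std::string& read, const std::string& ref,
                           int ws, int we,
                           int ma, int mi, int go, int ge) {
  const int m = (int) read.size();
  const int n = we - ws;
  if (m <= 0 || n <= 0) return 0;
  const int NEG = -1000000000;
  std::vector<int> rc(m), bc(n);
  for (int i = 0; i < m; ++i) rc[i] = base_code(read[i]);
  for (int j = 0; j < n; ++j) bc[j] = base_code(ref[ws + j]);
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fcol(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int Ei = NEG;
    Hcur[0] = 0;
    const int ri = rc[i - 1];
    for (int j = 1; j <= n; ++j) {
      Ei = std::max(Hcur[j - 1] + go, Ei + ge);
      int F = std::max(Hprev[j] + go, Fcol[j] + ge);
      Fcol[j] = F;
      int diag = Hprev[j - 1] + ((ri == bc[j - 1] && ri < 4) ? ma : mi);
      int H = diag > Ei ? diag : Ei;
      if (F > H) H = F;
      if (H < 0) H = 0;
      Hcur[j] = H;
      if (H > best) best = H;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// ---------------------------------------------------------------------------
// Exhaustive oracle: full-matrix affine local DP, traceback by recomputation.
// Independently written test oracle; no seeding, no windows.
// ---------------------------------------------------------------------------
static Aln oracle_sw(const std::string& read, const std::string& ref,
                     int ma, int mi, int go, int ge) {
  const int m = (int) read.size();
  const int n = (int) ref.size();
  Aln out;
  if (m <= 0 || n <= 0) return out;
  const int NEG = -1000000000;
  std::vector<std::vector<int>> H(m + 1, std::vector<int>(n + 1, 0));
  std::vector<std::vector<int>> E(m + 1, std::vector<int>(n + 1, NEG));
  std::vector<std::vector<int>> F(m + 1, std::vector<int>(n + 1, NEG));

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E[i][j] = std::max(H[i][j - 1] + go, E[i][j - 1] + ge);
      F[i][j] = std::max(H[i - 1][j] + go, F[i - 1][j] + ge);
      bool is_match = base_code(read[i - 1]) == base_code(ref[j - 1]) &&
                      base_code(read[i - 1]) < 4;
      int diag = H[i - 1][j - 1] + (is_match ? ma : mi);
      int h = std::max(0, std::max(diag, std::max(E[i][j], F[i][j])));
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return out;

  int i = bi, j = bj, state = 0;
  for (;;) {
    if (state == 0) {
      if (H[i][j] == 0) break;
      bool is_match = base_code(read[i - 1]) == base_code(ref[j - 1]) &&
                      base_code(read[i - 1]) < 4;
      int diag = H[i - 1][j - 1] + (is_match ? ma : mi);
      if (H[i][j] == diag) {               // diagonal preferred
        if (is_match) out.matches++; else out.mismatches++;
        out.read_aligned++;
        --i; --j;
      } else if (H[i][j] == E[i][j]) {     // then ref-gap
        state = 1;
      } else {                             // then read-gap
        state = 2;
      }
    } else if (state == 1) {
      out.gaps++;
      bool open = (E[i][j] == H[i][j - 1] + go); // open preferred
      --j;
      if (open) state = 0;
    } else {
      out.gaps++;
      out.read_aligned++;
      bool open = (F[i][j] == H[i - 1][j] + go);
      --i;
      if (open) state = 0;
    }
  }
  out.score = best;
  out.ref_start = j;
  out.ref_end = bj;
  out.valid = true;
  return out;
}

// ---------------------------------------------------------------------------
// Seed index
// ---------------------------------------------------------------------------
struct SeedIndex {
  int k = 13;
  std::vector<std::string> seqs;
  std::vector<std::string> ids;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> pos;
  size_t n_positions = 0;
};

// rolling k-mer encoder; emits (valid, code) pairs along a sequence
template <typename F>
static void for_each_kmer(const std::string& s, int k, F fn) {
  const int n = (int) s.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0; // length of current run of unambiguous bases
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c >= 4) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) c) & mask;
    if (++run >= k) fn(i - k + 1, code);
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector ids, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  XPtr<SeedIndex> p(new SeedIndex(), true);
  p->k = k;
  p->seqs.reserve(seqs.size());
  p->ids.reserve(ids.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    p->seqs.push_back(as<std::string>(seqs[s]));
    p->ids.push_back(as<std::string>(ids[s]));
  }
  for (size_t s = 0; s < p->seqs.size(); ++s) {
    for_each_kmer(p->seqs[s], k, [&](int at, uint64_t code) {
      p->pos[code].emplace_back((int32_t) s, (int32_t) at);
      p->n_positions++;
    });
  }
  return p;
}

// [[Rcpp::export]]
double cpp_index_n_positions(SEXP idx) {
  XPtr<SeedIndex> p(idx);
  return (double) p->n_positions;
}

// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP idx, std::string kmer) {
  XPtr<SeedIndex> p(idx);
  if ((int) kmer.size() != p->k) stop("query length must equal k");
  uint64_t code = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b >= 4) return DataFrame::create(Named("scaffold") = IntegerVector(0),
                                         Named("pos") = IntegerVector(0));
    code = (code << 2) | (uint64_t) b;
  }
  auto it = p->pos.find(code);
  std::vector<int> sc, ps;
  if (it != p->pos.end()) {
    for (auto& pr : it->second) { sc.push_back(pr.first + 1); ps.push_back(pr.second + 1); }
  }
  return DataFrame::create(Named("scaffold") = wrap(sc), Named("pos") = wrap(ps));
}

// candidate window list for one read orientation on one index
struct Window { int scaf; int ws; int we; };

static void candidate_windows(const SeedIndex& ix, const std::string& read,
                              int band, std::vector<Window>& out) {
  const int m = (int) read.size();
  // diagonals per scaffold
  std::unordered_map<int, std::vector<int>> diags;
  for_each_kmer(read, ix.k, [&](int at, uint64_t code) {
    auto it = ix.pos.find(code);
    if (it == ix.pos.end()) return;
    for (auto& pr : it->second) diags[pr.first].push_back(pr.second - at);
  });
  for (auto& kv : diags) {
    int scaf = kv.first;
    int len = (int) ix.seqs[scaf].size();
    std::vector<int>& d = kv.second;
    std::sort(d.begin(), d.end());
    d.erase(std::unique(d.begin(), d.end()), d.end());
    size_t i = 0;
    while (i < d.size()) {
      size_t j = i;
      // merge diagonals within `band` of each other, capping cluster span
      while (j + 1 < d.size() && d[j + 1] - d[j] <= band &&
             d[j + 1] - d[i] <= 4 * band) ++j;
      int ws = std::max(0, d[i] - band);
      int we = std::min(len, d[j] + m + band);
      if (we > ws) out.push_back({scaf, ws, we});
      i = j + 1;
    }
  }
}

struct Hit {
  int read_ix = -1;
  int scaf = -1;
  char strand = '+';
  Aln aln;
  bool valid = false;
};

// returns true if a beats b under the deterministic tie-break
static bool hit_better(const Hit& a, const Hit& b, const SeedIndex& ix) {
  if (!b.valid) return a.valid;
  if (!a.valid) return false;
  if (a.aln.score != b.aln.score) return a.aln.score > b.aln.score;
  double ia = a.aln.identity(), ib = b.aln.identity();
  if (ia != ib) return ia > ib;
  if (a.aln.matches != b.aln.matches) return a.aln.matches > b.aln.matches;
  int c = ix.ids[a.scaf].compare(ix.ids[b.scaf]);
  if (c != 0) return c < 0;
  if (a.aln.ref_start != b.aln.ref_start) return a.aln.ref_start < b.aln.ref_start;
  return a.strand == '+' && b.strand == '-';
}

static Hit best_hit_for_read(const SeedIndex& ix, const std::string& read,
                             double min_identity, double min_frac,
                             int band, int ma, int mi, int go, int ge) {
  Hit best;
  const int m = (int) read.size();
  if (m < ix.k) return best;
  const std::string rcread = revcomp(read);

  // gather candidate windows on both strands and score them cheaply
  struct Scored { Window w; int strand; int score; };
  std::vector<Scored> cand;
  for (int s = 0; s < 2; ++s) {
    const std::string& q = (s == 0) ? read : rcread;
    std::vector<Window> wins;
    candidate_windows(ix, q, band, wins);
    for (const Window& w : wins) {
      int sc = sw_score_window(q, ix.seqs[w.scaf], w.ws, w.we, ma, mi, go, ge);
      if (sc > 0) cand.push_back({w, s, sc});
    }
  }
  std::sort(cand.begin(), cand.end(),
            [](const Scored& a, const Scored& b) { return a.score > b.score; });

  // full traceback DP in descending score order; the first score group that
  // yields a threshold-passing hit must contain the overall best hit, since
  // the hit ranking is lexicographic with score first
  size_t i = 0;
  while (i < cand.size()) {
    size_t j = i;
    while (j < cand.size() && cand[j].score == cand[i].score) ++j;
    for (size_t t = i; t < j; ++t) {
      const std::string& q = (cand[t].strand == 0) ? read : rcread;
      Aln a = sw_window(q, ix.seqs[cand[t].w.scaf], cand[t].w.ws, cand[t].w.we,
                        ma, mi, go, ge);
      if (!a.valid) continue;
      if (a.identity() < min_identity - 1e-9) continue;
      if ((double) a.read_aligned / m < min_frac - 1e-9) continue;
      Hit h; h.valid = true; h.scaf = cand[t].w.scaf;
      h.strand = (cand[t].strand == 0) ? '+' : '-';
      h.aln = a;
      if (hit_better(h, best, ix)) best = h;
    }
    if (best.valid) break;
    i = j;
  }
  return best;
}

// [[Rcpp::export]]
DataFrame cpp_recruit(SEXP idx, CharacterVector reads, CharacterVector read_ids,
                      double min_identity, double min_aligned_fraction,
                      int band_width, int match, int mismatch,
                      int gap_open, int gap_extend) {
  XPtr<SeedIndex> p(idx);
  std::vector<std::string> rid;
  std::vector<std::string> sid;
  std::vector<int> rs, re, mt, mm, gp;
  std::vector<double> ident, frac;
  std::vector<int> score;
  std::vector<std::string> strand;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string seq = as<std::string>(reads[r]);
    Hit h = best_hit_for_read(*p, seq, min_identity, min_aligned_fraction,
                              band_width, match, mismatch, gap_open, gap_extend);
    if (!h.valid) continue;
    rid.push_back(as<std::string>(read_ids[r]));
    sid.push_back(p->ids[h.scaf]);
    rs.push_back(h.aln.ref_start + 1);  // 1-based inclusive
    re.push_back(h.aln.ref_end);
    strand.push_back(std::string(1, h.strand));
    mt.push_back(h.aln.matches);
    mm.push_back(h.aln.mismatches);
    gp.push_back(h.aln.gaps);
    ident.push_back(h.aln.identity());
    frac.push_back((double) h.aln.read_aligned / seq.size());
    score.push_back(h.aln.score);
  }
  return DataFrame::create(
    Named("read_id") = wrap(rid),
    Named("scaffold_id") = wrap(sid),
    Named("ref_start") = wrap(rs),
    Named("ref_end") = wrap(re),
    Named("strand") = wrap(strand),
    Named("matches") = wrap(mt),
    Named("mismatches") = wrap(mm),
    Named("gap_columns") = wrap(gp),
    Named("identity") = wrap(ident),
    Named("aligned_read_fraction") = wrap(frac),
    Named("score") = wrap(score),
    Named("stringsAsFactors") = false);
}

static List aln_to_list(const Aln& a, char strand, int read_len) {
  return List::create(
    Named("score") = a.score,
    Named("matches") = a.matches,
    Named("mismatches") = a.mismatches,
    Named("gap_columns") = a.gaps,
    Named("identity") = a.identity(),
    Named("aligned_read_fraction") = read_len > 0 ? (double) a.read_aligned / read_len : 0.0,
    Named("ref_start") = a.valid ? a.ref_start + 1 : NA_INTEGER,
    Named("ref_end") = a.valid ? a.ref_end : NA_INTEGER,
    Named("strand") = std::string(1, strand),
    Named("mapped") = a.valid);
}

// [[Rcpp::export]]
List cpp_oracle_align(std::string read, std::string ref,
                      int match, int mismatch, int gap_open, int gap_extend) {
  if (read.size() > 10000 || ref.size() > 10000)
    stop("oracle_align refuses sequences longer than 10 kb (quadratic DP)");
  if (read.empty() || ref.empty()) stop("sequences must be non-empty");
  Aln fwd = oracle_sw(read, ref, match, mismatch, gap_open, gap_extend);
  Aln rev = oracle_sw(revcomp(read), ref, match, mismatch, gap_open, gap_extend);
  // same preference order as recruitment tie-break, '+' preferred last
  bool take_rev;
  if (fwd.valid != rev.valid) take_rev = rev.valid;
  else if (!fwd.valid) take_rev = false;
  else if (fwd.score != rev.score) take_rev = rev.score > fwd.score;
  else if (fwd.identity() != rev.identity()) take_rev = rev.identity() > fwd.identity();
  else if (fwd.matches != rev.matches) take_rev = rev.matches > fwd.matches;
  else if (fwd.ref_start != rev.ref_start) take_rev = rev.ref_start < fwd.ref_start;
  else take_rev = false;
  int L = (int) read.size();
  return List::create(
    Named("best") = aln_to_list(take_rev ? rev : fwd, take_rev ? '-' : '+', L),
    Named("forward") = aln_to_list(fwd, '+', L),
    Named("reverse") = aln_to_list(rev, '-', L));
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }
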