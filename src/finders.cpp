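#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bases are encoded 0=A, 1=C, 2=G, 3=T, 4=N. N never contributes to counts
// and scores as background (log-odds 0).

static inline int site_base(const std::vector<int> &s, int p, int strand,
                            int w, int W) {
  if (strand == 0) return s[p + w];
  int b = s[p + W - 1 - w];
  return b == 4 ? 4 : 3 - b;
}

static double config_ic(const std::vector<std::vector<int>> &seqs,
                        const std::vector<int> &pos,
                        const std::vector<int> &strand, int W,
                        const NumericVector &bg, double pc) {
  int n = seqs.size();
  double ic = 0.0;
  for (int w = 0; w < W; ++w) {
    double cnt[4] = {0, 0, 0, 0};
    double tot = 0;
    for (int i = 0; i < n; ++i) {
      int b = site_base(seqs[i], pos[i], strand[i], w, W);
      if (b < 4) { cnt[b] += 1.0; tot += 1.0; }
    }
    for (int b = 0; b < 4; ++b) {
      double f = (cnt[b] + pc) / (tot + 4.0 * pc);
      ic += f * std::log2(f / bg[b]);
    }
  }
  return ic;
}

// Classic one-occurrence-per-sequence Gibbs site sampler. Hold out one
// sequence, build the PWM from the remaining sites (pseudocount pc), sample
// the held-out site proportional to the PWM/background likelihood ratio over
// both strands. The best-information-content configuration seen is kept;
// sampling stops after max_iters sweeps or `patience` sweeps without
// improvement; `restarts` independent restarts, best kept. Uses R's RNG.
// [[Rcpp::export]]
List gibbs_sample_cpp(List seqs_, int W, NumericVector background,
                      int max_iters, int patience, int restarts,
                      double pseudocount) {
  int n = seqs_.size();
  std::vector<std::vector<int>> seqs(n);
  std::vector<int> npos(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs_[i];
    seqs[i].assign(v.begin(), v.end());
    npos[i] = (int)seqs[i].size() - W + 1;
    if (npos[i] < 1)
      stop("sequence %d is shorter than motif width %d", i + 1, W);
  }

  std::vector<int> best_pos(n), best_strand(n);
  double best_ic = -1.0;

  std::vector<int> pos(n), strand(n);
  std::vector<double> scores;

  for (int r = 0; r < restarts; ++r) {
    for (int i = 0; i < n; ++i) {
      pos[i] = std::min((int)(unif_rand() * npos[i]), npos[i] - 1);
      strand[i] = unif_rand() < 0.5 ? 0 : 1;
    }
    double local_best = -1.0;
    int stale = 0;
    for (int iter = 0; iter < max_iters; ++iter) {
      for (int i = 0; i < n; ++i) {
        // PWM (as log-odds) from all sites but i
        double lo[64][4];
        for (int w = 0; w < W; ++w) {
          double cnt[4] = {0, 0, 0, 0};
          double tot = 0;
          for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            int b = site_base(seqs[j], pos[j], strand[j], w, W);
            if (b < 4) { cnt[b] += 1.0; tot += 1.0; }
          }
          for (int b = 0; b < 4; ++b)
            lo[w][b] = std::log(((cnt[b] + pseudocount) / (tot + 4.0 * pseudocount)) /
                                background[b]);
        }
        int nopt = 2 * npos[i];
        scores.assign(nopt, 0.0);
        double mx = -1e300;
        for (int s = 0; s < 2; ++s) {
          for (int p = 0; p < npos[i]; ++p) {
            double sc = 0.0;
            for (int w = 0; w < W; ++w) {
              int b = site_base(seqs[i], p, s, w, W);
              if (b < 4) sc += lo[w][b];
            }
            scores[s * npos[i] + p] = sc;
            if (sc > mx) mx = sc;
          }
        }
        double tot = 0.0;
        for (int k = 0; k < nopt; ++k) {
          scores[k] = std::exp(scores[k] - mx);
          tot += scores[k];
        }
        double u = unif_rand() * tot, acc = 0.0;
        int chosen = nopt - 1;
        for (int k = 0; k < nopt; ++k) {
          acc += scores[k];
          if (u <= acc) { chosen = k; break; }
        }
        strand[i] = chosen / npos[i];
        pos[i] = chosen % npos[i];
      }
      double ic = config_ic(seqs, pos, strand, W, background, pseudocount);
      if (ic > local_best + 1e-12) {
        local_best = ic;
        stale = 0;
        if (ic > best_ic) {
          best_ic = ic;
          best_pos = pos;
          best_strand = strand;
        }
      } else {
        ++stale;
      }
      if (stale >= patience) break;
    }
  }

  return List::create(_["positions"] = IntegerVector(best_pos.begin(), best_pos.end()),
                      _["strands"] = IntegerVector(best_strand.begin(), best_strand.end()),
                      _["ic"] = best_ic);
}

// ---- word-enumeration finder ------------------------------------------------

static inline int hamming2bit(unsigned int a, unsigned int b) {
  unsigned int d = a ^ b;
  d = (d | (d >> 1)) & 0x55555555u;
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(d);
#else
  int c = 0;
  while (d) { d &= d - 1; ++c; }
  return c;
#endif
}

static inline unsigned int rc_code(unsigned int c, int W) {
  unsigned int r = 0;
  for (int w = 0; w < W; ++w) {
    r = (r << 2) | (3u - (c & 3u));
    c >>= 2;
  }
  return r;
}

// Enumerate all W-mers present on either strand; for each, count supporting
// sequences (an occurrence within Hamming distance <= max_mismatch on either
// strand) and total occurrences. Candidates are ranked by support, then
// total occurrences, then lexicographically (A<C<G<T). Returns the top
// n_best candidates with >= 2 supporting sequences, with the best occurrence
// per supporting sequence (fewest mismatches, then + strand, then leftmost).
// [[Rcpp::export]]
List consensus_count_cpp(List seqs_, int W, int max_mismatch, int n_best) {
  int n = seqs_.size();
  std::vector<std::vector<unsigned int>> wcode(n);
  std::vector<std::vector<bool>> wvalid(n);
  std::unordered_set<unsigned int> cand_set;

  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs_[i];
    int L = v.size();
    int np = L - W + 1;
    if (np < 1) continue;
    wcode[i].resize(np);
    wvalid[i].resize(np);
    unsigned int code = 0;
    int nrun = 0;  // N bases inside the current window
    unsigned int mask = (W >= 16) ? 0xFFFFFFFFu : ((1u << (2 * W)) - 1u);
    for (int p = 0; p < L; ++p) {
      int b = v[p];
      code = ((code << 2) | (unsigned int)(b == 4 ? 0 : b)) & mask;
      if (b == 4) nrun = W;  // window poisoned for the next W positions
      else if (nrun > 0) --nrun;
      if (p >= W - 1) {
        int w0 = p - W + 1;
        wvalid[i][w0] = (nrun == 0);
        wcode[i][w0] = code;
        if (nrun == 0) {
          cand_set.insert(code);
          cand_set.insert(rc_code(code, W));
        }
      }
    }
  }

  std::vector<unsigned int> cands(cand_set.begin(), cand_set.end());
  std::sort(cands.begin(), cands.end());

  struct Hit { int pos; int strand; int mm; };
  struct Result {
    unsigned int code;
    int support, occ;
    std::vector<int> seq_idx, pos, strand;
  };
  std::vector<Result> kept;

  std::vector<int> order;  // indices into kept, maintained ranked
  for (size_t ci = 0; ci < cands.size(); ++ci) {
    unsigned int c = cands[ci];
    unsigned int rc = rc_code(c, W);
    int support = 0, occ = 0;
    std::vector<int> sidx, spos, sstr;
    for (int i = 0; i < n; ++i) {
      Hit best = {-1, 0, W + 1};
      for (size_t p = 0; p < wcode[i].size(); ++p) {
        if (!wvalid[i][p]) continue;
        int mp = hamming2bit(c, wcode[i][p]);
        if (mp <= max_mismatch) {
          ++occ;
          if (mp < best.mm) best = {(int)p, 0, mp};
        }
        int mm = hamming2bit(rc, wcode[i][p]);
        if (mm <= max_mismatch) {
          ++occ;
          if (mm < best.mm) best = {(int)p, 1, mm};
        }
      }
      if (best.pos >= 0) {
        ++support;
        sidx.push_back(i);
        spos.push_back(best.pos);
        sstr.push_back(best.strand);
      }
    }
    if (support >= 2) {
      Result r;
      r.code = c; r.support = support; r.occ = occ;
      r.seq_idx = sidx; r.pos = spos; r.strand = sstr;
      kept.push_back(r);
    }
  }

  std::vector<int> idx(kept.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (kept[a].support != kept[b].support) return kept[a].support > kept[b].support;
    if (kept[a].occ != kept[b].occ) return kept[a].occ > kept[b].occ;
    return kept[a].code < kept[b].code;  // lexicographic: A<C<G<T
  });

  int nout = std::min((int)idx.size(), n_best);
  List out(nout);
  const char *letters = "ACGT";
  for (int k = 0; k < nout; ++k) {
    const Result &r = kept[idx[k]];
    std::string word(W, 'A');
    for (int w = 0; w < W; ++w)
      word[w] = letters[(r.code >> (2 * (W - 1 - w))) & 3u];
    out[k] = List::create(_["word"] = word,
                          _["support"] = r.support,
                          _["occurrences"] = r.occ,
                          _["seq_idx"] = IntegerVector(r.seq_idx.begin(), r.seq_idx.end()),
                          _["pos"] = IntegerVector(r.pos.begin(), r.pos.end()),
                          _["strand"] = IntegerVector(r.strand.begin(), r.strand.end()));
  }
  return out;
}

// ---- PWM-PWM alignment scan -------------------------------------------------

// C0 and C0rc are Wq x Wd matrices of per-column Pearson correlations of the
// query against the db motif and against its reverse complement. perm, if
// non-empty, is a 0-based permutation of db columns (a column shuffle of the
// db motif). Returns the best mean column correlation over all ungapped
// offsets with overlap >= min_overlap, in both orientations.
static void scan_best(const NumericMatrix &C0, const NumericMatrix &C0rc,
                      int min_overlap, const std::vector<int> *perm,
                      double &best, int &best_off, int &best_orient) {
  int Wq = C0.nrow(), Wd = C0.ncol();
  best = R_NegInf; best_off = 0; best_orient = 0;
  for (int orient = 0; orient < 2; ++orient) {
    const NumericMatrix &C = orient == 0 ? C0 : C0rc;
    // offset d: query col i (0-based) aligns db col i - d
    for (int d = -(Wd - min_overlap); d <= Wq - min_overlap; ++d) {
      int lo = std::max(0, d), hi = std::min(Wq - 1, Wd - 1 + d);
      int len = hi - lo + 1;
      if (len < min_overlap) continue;
      double s = 0.0;
      for (int i = lo; i <= hi; ++i) {
        int j = i - d;  // column of the (possibly shuffled) db motif
        int col;
        if (perm == nullptr) {
          col = j;
        } else if (orient == 0) {
          col = (*perm)[j];
        } else {
          // column j of rc(shuffled db) is column Wd-1-perm[Wd-1-j] of rc(db)
          col = Wd - 1 - (*perm)[Wd - 1 - j];
        }
        s += C(i, col);
      }
      s /= len;
      if (s > best + 1e-15) { best = s; best_off = d; best_orient = orient; }
    }
  }
}

// [[Rcpp::export]]
List best_alignment_cpp(NumericMatrix C0, NumericMatrix C0rc, int min_overlap) {
  double best; int off, orient;
  scan_best(C0, C0rc, min_overlap, nullptr, best, off, orient);
  return List::create(_["score"] = best, _["offset"] = off,
                      _["orientation"] = orient == 0 ? "+" : "-");
}

// Null distribution of best alignment scores under K random column shuffles
// of the db motif (re-scanning all offsets and both orientations per
// shuffle). Uses R's RNG for the permutations.
// [[Rcpp::export]]
NumericVector null_best_scores_cpp(NumericMatrix C0, NumericMatrix C0rc,
                                   int min_overlap, int K) {
  int Wd = C0.ncol();
  NumericVector out(K);
  std::vector<int> perm(Wd);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < Wd; ++j) perm[j] = j;
    for (int j = Wd - 1; j > 0; --j) {
      int u = std::min((int)(unif_rand() * (j + 1)), j);
      std::swap(perm[j], perm[u]);
    }
    double best; int off, orient;
    scan_best(C0, C0rc, min_overlap, &perm, best, off, orient);
    out[k] = best;
  }
  return out;
}
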