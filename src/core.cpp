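#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// IUPAC nucleotide bitmasks: A=1, C=2, G=4, T=8.
static unsigned char IUPAC[256];
static bool iupac_ready = false;

static void init_iupac() {
  if (iupac_ready) return;
  for (int i = 0; i < 256; ++i) IUPAC[i] = 0;
  const char *codes = "ACGTRYSWKMBDHVN";
  const unsigned char masks[] = {1, 2, 4, 8, 1|4, 2|8, 2|4, 1|8, 4|8, 1|2,
                                 2|4|8, 1|4|8, 1|2|8, 1|2|4, 15};
  for (int i = 0; codes[i]; ++i) {
    IUPAC[(unsigned char)codes[i]] = masks[i];
    IUPAC[(unsigned char)tolower(codes[i])] = masks[i];
  }
  IUPAC[(unsigned char)'U'] = 8; IUPAC[(unsigned char)'u'] = 8;
  iupac_ready = true;
}

static inline bool is_concrete(unsigned char m) {
  return m == 1 || m == 2 || m == 4 || m == 8;
}

// A primer position matches a read base iff the base is concrete and lies in
// the primer code's expansion. Ambiguous read bases (incl. N) mismatch unless
// allow_ambig_read is set, in which case any intersection counts.
static inline bool primer_base_match(unsigned char primer_c, unsigned char read_c,
                                     bool allow_ambig_read) {
  unsigned char pm = IUPAC[primer_c], rm = IUPAC[read_c];
  if (pm == 0 || rm == 0) return false;
  if (!allow_ambig_read && !is_concrete(rm)) return false;
  return (pm & rm) != 0;
}

// mismatches of primer laid on seq at 0-based offset; returns len+1 if off end
static int primer_mismatches_at(const std::string &primer, const std::string &seq,
                                int offset, int max_mm, bool allow_ambig) {
  int L = primer.size();
  if (offset < 0 || offset + L > (int)seq.size()) return L + 1;
  int mm = 0;
  for (int i = 0; i < L; ++i) {
    if (!primer_base_match(primer[i], seq[offset + i], allow_ambig)) {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
List primer_scan_cpp(std::string seq, std::string primer, int max_mismatch,
                     bool allow_ambig_read = false) {
  init_iupac();
  std::vector<int> pos, mms;
  int n = seq.size(), L = primer.size();
  for (int off = 0; off + L <= n; ++off) {
    int mm = primer_mismatches_at(primer, seq, off, max_mismatch, allow_ambig_read);
    if (mm <= max_mismatch) { pos.push_back(off + 1); mms.push_back(mm); }
  }
  return List::create(_["pos"] = wrap(pos), _["mismatches"] = wrap(mms));
}

// Anchored two-sided primer identification for merged reads.
// rev_rc primers are the reverse complements of the reverse primers, expected
// near the 3' end. slack allows +/- nt play at either anchor.
// reason codes: 0 = assigned, 1 = no primer pair, 2 = ambiguous marker, 3 = short insert
// [[Rcpp::export]]
List split_reads_cpp(CharacterVector seqs, CharacterVector fwd_primers,
                     CharacterVector rev_rc_primers, int max_mismatch,
                     int slack, int min_insert, bool allow_ambig_read = false) {
  init_iupac();
  int n = seqs.size(), nm = fwd_primers.size();
  std::vector<std::string> fps(nm), rps(nm);
  for (int m = 0; m < nm; ++m) {
    fps[m] = as<std::string>(fwd_primers[m]);
    rps[m] = as<std::string>(rev_rc_primers[m]);
  }
  IntegerVector marker(n), reason(n);
  CharacterVector insert(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int len = s.size();
    int hit_marker = 0, n_hits = 0, best_ins_start = 0, best_ins_end = 0;
    std::vector<int> f_marker, r_marker;
    for (int m = 0; m < nm; ++m) {
      int fl = fps[m].size(), rl = rps[m].size();
      // forward primer anchored at 5' end
      int f_off = -1, f_best = max_mismatch + 1;
      for (int off = 0; off <= slack; ++off) {
        int mm = primer_mismatches_at(fps[m], s, off, max_mismatch, allow_ambig_read);
        if (mm < f_best) { f_best = mm; f_off = off; }
      }
      // reverse-complemented reverse primer anchored at 3' end
      int r_off = -1, r_best = max_mismatch + 1;
      for (int d = 0; d <= slack; ++d) {
        int off = len - rl - d;
        int mm = primer_mismatches_at(rps[m], s, off, max_mismatch, allow_ambig_read);
        if (mm < r_best) { r_best = mm; r_off = off; }
      }
      bool f_ok = f_best <= max_mismatch, r_ok = r_best <= max_mismatch;
      if (f_ok) f_marker.push_back(m);
      if (r_ok) r_marker.push_back(m);
      if (f_ok && r_ok && r_off > f_off + fl) {
        ++n_hits;
        hit_marker = m + 1;
        best_ins_start = f_off + fl;
        best_ins_end = r_off;  // exclusive
      }
    }
    if (n_hits == 0) {
      // mixed flanks (forward of one marker, reverse of another) are a
      // conflicting double identification, not a missing one
      bool mixed = !f_marker.empty() && !r_marker.empty();
      marker[i] = NA_INTEGER; reason[i] = mixed ? 2 : 1; insert[i] = NA_STRING;
    }
    else if (n_hits > 1) { marker[i] = NA_INTEGER; reason[i] = 2; insert[i] = NA_STRING; }
    else {
      int ins_len = best_ins_end - best_ins_start;
      if (ins_len < min_insert) { marker[i] = NA_INTEGER; reason[i] = 3; insert[i] = NA_STRING; }
      else {
        marker[i] = hit_marker; reason[i] = 0;
        insert[i] = s.substr(best_ins_start, ins_len);
      }
    }
  }
  return List::create(_["marker"] = marker, _["reason"] = reason, _["insert"] = insert);
}

// Sliding-window quality trim: keep the longest prefix such that every window
// of window_len fully inside it has mean quality >= threshold. For prefixes
// shorter than window_len the mean over the whole prefix must pass.
// [[Rcpp::export]]
IntegerVector trim_lengths_cpp(CharacterVector quals, int window_len,
                               double threshold, int phred_offset = 33) {
  int n = quals.size();
  IntegerVector out(n);
  double need = threshold * window_len;
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    int len = q.size();
    if (len < window_len) {
      // single short window: whole prefix mean must pass, scanned from full length down
      int L = len;
      while (L > 0) {
        double s = 0;
        for (int j = 0; j < L; ++j) s += q[j] - phred_offset;
        if (s >= threshold * L) break;
        --L;
      }
      out[i] = L;
      continue;
    }
    double wsum = 0;
    for (int j = 0; j < window_len; ++j) wsum += q[j] - phred_offset;
    int first_bad = -1;  // 0-based window start of first failing window
    if (wsum < need) first_bad = 0;
    for (int s = 1; first_bad < 0 && s + window_len <= len; ++s) {
      wsum += (q[s + window_len - 1] - phred_offset) - (q[s - 1] - phred_offset);
      if (wsum < need) first_bad = s;
    }
    if (first_bad < 0) { out[i] = len; continue; }
    // longest prefix that excludes the first failing window: that window is
    // fully contained once the prefix reaches first_bad + window_len (0-based)
    int L = first_bad + window_len - 1;
    if (L < window_len - 1) {
      // prefix shorter than a window: fall back to whole-prefix mean
      while (L > 0) {
        double s2 = 0;
        for (int j = 0; j < L; ++j) s2 += q[j] - phred_offset;
        if (s2 >= threshold * L) break;
        --L;
      }
    }
    out[i] = std::max(L, 0);
  }
  return out;
}

// Pair merging by overlap scan. rev_rc / rq_rev are the reverse-complemented
// reverse reads and their reversed quality strings. Overlaps are scanned from
// the longest down to min_overlap; the overlap minimising mismatch fraction
// wins, ties going to the longer (earlier-scanned) overlap.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector fwd, CharacterVector fq,
                     CharacterVector rev_rc, CharacterVector rq,
                     int min_overlap, double max_mismatch_frac) {
  int n = fwd.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector overlap(n), mism(n);
  LogicalVector merged(n);
  for (int i = 0; i < n; ++i) {
    std::string f = as<std::string>(fwd[i]);
    std::string qf = as<std::string>(fq[i]);
    std::string r = as<std::string>(rev_rc[i]);
    std::string qr = as<std::string>(rq[i]);
    int lf = f.size(), lr = r.size();
    if (lf == 0 || lr == 0) stop("zero-length mate in pair %d", i + 1);
    int omax = std::min(lf, lr);
    int best_o = -1, best_mm = 0;
    double best_frac = 1e9;
    for (int o = omax; o >= min_overlap; --o) {
      // suffix of f (length o) vs prefix of r (length o)
      double cap = std::min(max_mismatch_frac, best_frac) * o;
      int allowed = (int)std::floor(cap + 1e-9);
      int mm = 0;
      bool aborted = false;
      const char *pf = f.data() + (lf - o);
      const char *pr = r.data();
      for (int j = 0; j < o; ++j) {
        if (pf[j] != pr[j]) {
          if (++mm > allowed) { aborted = true; break; }
        }
      }
      if (aborted) continue;
      double frac = (double)mm / o;
      if (frac < best_frac - 1e-12) { best_frac = frac; best_o = o; best_mm = mm; }
      if (mm == 0) break;  // no later (shorter) overlap can strictly beat 0
    }
    if (best_o < 0 || best_frac > max_mismatch_frac) {
      merged[i] = false; mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      overlap[i] = NA_INTEGER; mism[i] = NA_INTEGER;
      continue;
    }
    int o = best_o;
    std::string out = f.substr(0, lf - o);
    std::string oq = qf.substr(0, lf - o);
    for (int j = 0; j < o; ++j) {
      char bf = f[lf - o + j], br = r[j];
      char qb_f = qf[lf - o + j], qb_r = qr[j];
      if (bf == br) { out.push_back(bf); oq.push_back(std::max(qb_f, qb_r)); }
      else if (qb_f >= qb_r) { out.push_back(bf); oq.push_back(qb_f); }
      else { out.push_back(br); oq.push_back(qb_r); }
    }
    out += r.substr(o);
    oq += qr.substr(o);
    merged[i] = true; mseq[i] = out; mqual[i] = oq;
    overlap[i] = o; mism[i] = best_mm;
  }
  return List::create(_["merged"] = merged, _["sequence"] = mseq,
                      _["quality"] = mqual, _["overlap"] = overlap,
                      _["mismatches"] = mism);
}

// Full semiglobal DP: terminal gaps on the reference (b) are free; gaps in the
// query and internal gaps are penalised. Returns matches, aligned columns
// (excluding free terminal reference overhangs) and identity.
// [[Rcpp::export]]
NumericVector identity_dp_cpp(std::string a, std::string b) {
  const double MATCH = 1.0, MISMATCH = -1.0, GAP = -1.5;
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  // dp over a (rows, query: global) and b (cols, reference: free end gaps)
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<signed char> tb((n + 1) * (m + 1));  // 0 diag, 1 up(gap in b), 2 left(gap in a)
  for (int j = 0; j <= m; ++j) { prev[j] = 0.0; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * GAP;
    tb[i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? MATCH : MISMATCH);
      double sup = prev[j] + GAP;
      double sleft = cur[j - 1] + GAP;
      double best = sdiag; signed char t = 0;
      if (sup > best) { best = sup; t = 1; }
      if (sleft > best) { best = sleft; t = 2; }
      cur[j] = best; tb[i * (m + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  // free trailing reference gaps: best over last row
  int jbest = m;
  for (int j = 0; j <= m; ++j) if (prev[j] > prev[jbest] + 1e-12) jbest = j;
  // traceback from (n, jbest)
  int i = n, j = jbest;
  int matches = 0, cols = 0;
  while (i > 0) {
    signed char t = tb[i * (m + 1) + j];
    if (t == 0) { if (a[i - 1] == b[j - 1]) ++matches; ++cols; --i; --j; }
    else if (t == 1) { ++cols; --i; }
    else {
      // gap in query: free only if i == 0 (leading reference overhang)
      ++cols; --j;
    }
  }
  // any remaining j corresponds to the free leading reference overhang (i == 0):
  // those columns were counted above only if consumed while i > 0; the loop
  // exits at i == 0, so leading reference-only columns are excluded. But the
  // j-gap columns consumed while i > 0 were internal gaps in a and counted.
  // Correction: trailing overhang j > jbest never entered cols (free).
  double identity = cols > 0 ? (double)matches / cols : 0.0;
  return NumericVector::create(_["matches"] = matches, _["columns"] = cols,
                               _["identity"] = identity);
}

// Ungapped identity of equal-length sequences, with early abort below floor.
// Returns -1 if identity provably < floor.
static double hamming_identity(const char *a, const char *b, int len, double floor_id) {
  int allowed = (int)std::floor((1.0 - floor_id) * len + 1e-9);
  int mm = 0;
  for (int j = 0; j < len; ++j) {
    if (a[j] != b[j]) { if (++mm > allowed) return -1.0; }
  }
  return (double)(len - mm) / len;
}

// Diagonal identity of query laid on ref at offset (ref_pos - q_pos); query
// overhang positions count as unmatched columns.
static double diag_identity(const std::string &q, const std::string &r,
                            int diag, double floor_id) {
  int qlen = q.size(), rlen = r.size();
  int allowed = (int)std::floor((1.0 - floor_id) * qlen + 1e-9);
  int mm = 0;
  for (int j = 0; j < qlen; ++j) {
    int rj = j + diag;
    if (rj < 0 || rj >= rlen || q[j] != r[rj]) {
      if (++mm > allowed) return -1.0;
    }
  }
  return (double)(qlen - mm) / qlen;
}

static inline bool encode_kmer(const char *s, int k, uint64_t &code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    uint64_t b;
    switch (s[i]) {
      case 'A': case 'a': b = 0; break;
      case 'C': case 'c': b = 1; break;
      case 'G': case 'g': b = 2; break;
      case 'T': case 't': b = 3; break;
      default: return false;
    }
    code = (code << 2) | b;
  }
  return true;
}

// Seed-and-extend best-hit search of queries against references.
// Exact k-mer seeds sampled every `step` positions of the query nominate
// (reference, diagonal) candidates; candidates are scored by ungapped diagonal
// identity with early abort below `floor`. Substitution-only data makes the
// best diagonal the optimal semiglobal alignment; agreement with the DP is
// asserted in the tests. Returns, per query, the best identity (NA if < floor)
// and the 1-based indices of all references tied at the best identity.
// [[Rcpp::export]]
List best_hits_cpp(CharacterVector queries, CharacterVector refs,
                   int k, int step, double floor_id) {
  init_iupac();
  int nq = queries.size(), nr = refs.size();
  if (nr == 0) stop("no references");
  std::vector<std::string> R(nr);
  for (int r = 0; r < nr; ++r) R[r] = as<std::string>(refs[r]);
  // k-mer index over references
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > index;
  index.reserve(1 << 20);
  for (int r = 0; r < nr; ++r) {
    int L = R[r].size();
    for (int p = 0; p + k <= L; ++p) {
      uint64_t code;
      if (encode_kmer(R[r].data() + p, k, code))
        index[code].push_back(std::make_pair(r, p));
    }
  }
  NumericVector best(nq);
  List hits(nq);
  std::vector<int64_t> cand;  // packed (ref, diag)
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    int qlen = q.size();
    cand.clear();
    for (int p = 0; p + k <= qlen; p += step) {
      uint64_t code;
      if (!encode_kmer(q.data() + p, k, code)) continue;
      auto it = index.find(code);
      if (it == index.end()) continue;
      for (size_t h = 0; h < it->second.size(); ++h) {
        int r = it->second[h].first;
        int diag = it->second[h].second - p;
        cand.push_back(((int64_t)r << 24) | (uint32_t)(diag + (1 << 20)));
      }
    }
    // last window too, so 3'-terminal seeds are not skipped
    if (qlen >= k && (qlen - k) % step != 0) {
      uint64_t code;
      if (encode_kmer(q.data() + (qlen - k), k, code)) {
        auto it = index.find(code);
        if (it != index.end())
          for (size_t h = 0; h < it->second.size(); ++h) {
            int r = it->second[h].first;
            int diag = it->second[h].second - (qlen - k);
            cand.push_back(((int64_t)r << 24) | (uint32_t)(diag + (1 << 20)));
          }
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    double bid = -1.0;
    std::vector<double> ref_best(0);
    std::vector<int> ref_idx;
    // best identity per reference over its candidate diagonals
    int last_r = -1;
    double cur_best = -1.0;
    std::vector<std::pair<int,double> > per_ref;
    for (size_t c = 0; c <= cand.size(); ++c) {
      int r = (c < cand.size()) ? (int)(cand[c] >> 24) : -2;
      if (r != last_r) {
        if (last_r >= 0 && cur_best >= 0) per_ref.push_back(std::make_pair(last_r, cur_best));
        last_r = r; cur_best = -1.0;
      }
      if (c == cand.size()) break;
      int diag = (int)(cand[c] & 0xFFFFFF) - (1 << 20);
      double id = diag_identity(q, R[r], diag, floor_id);
      if (id > cur_best) cur_best = id;
    }
    for (size_t h = 0; h < per_ref.size(); ++h)
      if (per_ref[h].second > bid) bid = per_ref[h].second;
    if (bid < floor_id - 1e-12 || bid < 0) {
      best[i] = NA_REAL;
      hits[i] = IntegerVector(0);
    } else {
      std::vector<int> tied;
      for (size_t h = 0; h < per_ref.size(); ++h)
        if (per_ref[h].second >= bid - 1e-9) tied.push_back(per_ref[h].first + 1);
      best[i] = bid;
      hits[i] = wrap(tied);
    }
  }
  return List::create(_["best_identity"] = best, _["hit_refs"] = hits);
}

// Greedy abundance-sorted centroid clustering. seqs must already be sorted by
// descending abundance (ties lexicographic). Returns 1-based centroid index of
// the cluster each sequence joins (centroids point to themselves).
// [[Rcpp::export]]
IntegerVector cluster_greedy_cpp(CharacterVector seqs, double similarity) {
  int n = seqs.size();
  IntegerVector memb(n);
  std::vector<std::string> S(n);
  for (int i = 0; i < n; ++i) S[i] = as<std::string>(seqs[i]);
  std::vector<int> centroids;
  for (int i = 0; i < n; ++i) {
    int joined = -1;
    for (size_t c = 0; c < centroids.size(); ++c) {
      const std::string &cs = S[centroids[c]];
      double id;
      if (cs.size() == S[i].size())
        id = hamming_identity(cs.data(), S[i].data(), cs.size(), similarity);
      else {
        NumericVector v = identity_dp_cpp(
          S[i].size() <= cs.size() ? S[i] : cs,
          S[i].size() <= cs.size() ? cs : S[i]);
        id = v["identity"];
      }
      if (id >= similarity - 1e-12) { joined = centroids[c]; break; }
    }
    if (joined < 0) { centroids.push_back(i); memb[i] = i + 1; }
    else memb[i] = joined + 1;
  }
  return memb;
}

// [[Rcpp::export]]
CharacterVector apply_substitutions_cpp(CharacterVector seqs, IntegerVector idx,
                                        IntegerVector pos, CharacterVector base) {
  CharacterVector out = clone(seqs);
  int n = idx.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(out[idx[i] - 1]);
    std::string b = as<std::string>(base[i]);
    s[pos[i] - 1] = b[0];
    out[idx[i] - 1] = s;
  }
  return out;
}

// Within-group sums of squared distances for PERMANOVA permutations.
// labels: n_perm x N matrix of 1-based group labels. Returns SS_W per row.
// [[Rcpp::export]]
NumericVector permanova_ssw_cpp(NumericMatrix d2, IntegerMatrix labels) {
  int N = d2.nrow(), P = labels.nrow();
  int a = 0;
  for (int p = 0; p < P; ++p)
    for (int i = 0; i < N; ++i) a = std::max(a, labels(p, i));
  NumericVector out(P);
  std::vector<double> ss(a);
  std::vector<int> cnt(a);
  for (int p = 0; p < P; ++p) {
    std::fill(ss.begin(), ss.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < N; ++i) cnt[labels(p, i) - 1]++;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j)
        if (labels(p, i) == labels(p, j)) ss[labels(p, i) - 1] += d2(i, j);
    double tot = 0;
    for (int g = 0; g < a; ++g) if (cnt[g] > 0) tot += ss[g] / cnt[g];
    out[p] = tot;
  }
  return out;
}

// Pairwise ungapped identity matrix for equal-length sequences.
// [[Rcpp::export]]
NumericMatrix hamming_identity_matrix_cpp(CharacterVector seqs) {
  int n = seqs.size();
  std::vector<std::string> S(n);
  for (int i = 0; i < n; ++i) S[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      if (S[i].size() != S[j].size()) stop("sequences must have equal length");
      int mm = 0, L = S[i].size();
      for (int p = 0; p < L; ++p) if (S[i][p] != S[j][p]) ++mm;
      out(i, j) = out(j, i) = (double)(L - mm) / L;
    }
  }
  return out;
}
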