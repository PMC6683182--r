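// k-mer index and ungapped seed-and-extend alignment against a small
// dual reference (host contigs + transgene). Substitution-only extension:
// segments are maximal diagonal runs holding mismatches within budget,
// with terminal mismatches trimmed so segment ends are always matches.
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

struct Hit { int32_t ref; int32_t pos; };

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<Hit> > map;
};

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  if (k < 8) stop("k must be >= 8");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  CharacterVector nm = seqs.names();
  size_t total = 0;
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    if ((int)s.size() < k)
      stop("k (%d) longer than reference '%s' (%d bp)", k,
           as<std::string>(nm[r]).c_str(), (int)s.size());
    total += s.size();
    idx->names.push_back(as<std::string>(nm[r]));
    idx->seqs.push_back(s);
  }
  idx->map.reserve(total);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t r = 0; r < idx->seqs.size(); ++r) {
    const std::string& s = idx->seqs[r];
    uint64_t code = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        Hit h; h.ref = (int32_t)r; h.pos = (int32_t)(i + 1 - k);
        idx->map[code].push_back(h);
      }
    }
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export(name = ".cpp_index_info")]]
List cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  IntegerVector len(idx->names.size());
  CharacterVector nm(idx->names.size());
  for (size_t i = 0; i < idx->names.size(); ++i) {
    nm[i] = idx->names[i];
    len[i] = (int)idx->seqs[i].size();
  }
  return List::create(_["k"] = idx->k, _["names"] = nm, _["lengths"] = len,
                      _["n_kmers"] = (double)idx->map.size());
}

static bool encode_kmer(const std::string& s, int start, int k, uint64_t& code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bit(s[start + i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

// [[Rcpp::export(name = ".cpp_query_index")]]
DataFrame cpp_query_index(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal index k");
  std::vector<int> ref, pos; std::vector<std::string> strand;
  uint64_t code;
  if (encode_kmer(kmer, 0, idx->k, code)) {
    std::unordered_map<uint64_t, std::vector<Hit> >::const_iterator it =
      idx->map.find(code);
    if (it != idx->map.end())
      for (size_t i = 0; i < it->second.size(); ++i) {
        ref.push_back(it->second[i].ref + 1);
        pos.push_back(it->second[i].pos);
        strand.push_back("+");
      }
  }
  std::string rc = revcomp(kmer);
  if (rc != kmer && encode_kmer(rc, 0, idx->k, code)) {
    std::unordered_map<uint64_t, std::vector<Hit> >::const_iterator it =
      idx->map.find(code);
    if (it != idx->map.end())
      for (size_t i = 0; i < it->second.size(); ++i) {
        ref.push_back(it->second[i].ref + 1);
        pos.push_back(it->second[i].pos);
        strand.push_back("-");
      }
  }
  return DataFrame::create(_["ref"] = ref, _["pos"] = pos, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

struct Seg {
  int ref;        // 0-based reference id
  long diag;      // ref_pos - read_pos (on the oriented read)
  int rs, re;     // oriented-read span, half-open
  int mm;
  bool minus;     // true if this came from the reverse-complement pass
};

// Extend a seed match at oriented-read position [s, s+k) along its diagonal.
// Greedy right-then-left within the shared mismatch budget; terminal
// mismatches are trimmed afterwards.
static Seg extend_seed(const std::string& rd, const std::string& ref,
                       long diag, int s, int k, int budget) {
  int L = (int)rd.size(), RL = (int)ref.size();
  int lo = s, hi = s + k, mm = 0;
  std::vector<int> mmpos;
  // right
  while (hi < L) {
    long rp = diag + hi;
    if (rp < 0 || rp >= RL) break;
    if (rd[hi] == ref[rp] && base2bit(rd[hi]) >= 0) { ++hi; continue; }
    if (mm < budget) { mmpos.push_back(hi); ++mm; ++hi; continue; }
    break;
  }
  // left
  while (lo > 0) {
    long rp = diag + lo - 1;
    if (rp < 0 || rp >= RL) break;
    if (rd[lo - 1] == ref[rp] && base2bit(rd[lo - 1]) >= 0) { --lo; continue; }
    if (mm < budget) { mmpos.push_back(lo - 1); ++mm; --lo; continue; }
    break;
  }
  // trim terminal mismatches
  bool trimmed = true;
  while (trimmed && lo < hi) {
    trimmed = false;
    for (size_t i = 0; i < mmpos.size(); ++i) {
      if (mmpos[i] == lo) { ++lo; --mm; mmpos.erase(mmpos.begin() + i); trimmed = true; break; }
      if (mmpos[i] == hi - 1) { --hi; --mm; mmpos.erase(mmpos.begin() + i); trimmed = true; break; }
    }
  }
  Seg sg; sg.ref = 0; sg.diag = diag; sg.rs = lo; sg.re = hi; sg.mm = mm; sg.minus = false;
  return sg;
}

typedef std::unordered_map<uint64_t, std::vector<Hit> >::const_iterator MapIt;

// collect candidate segments for one oriented read (plus-orientation scan)
static void scan_oriented(const KmerIndex& idx, const std::string& rd,
                          int budget, bool minus, std::vector<Seg>& out,
                          bool full_only_probe, bool& found_full) {
  int k = idx.k, L = (int)rd.size();
  if (L < k) return;
  // memo of extended intervals per (ref, diag)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > done;
  std::vector<int> starts;
  if (full_only_probe) { starts.push_back(0); if (L - k != 0) starts.push_back(L - k); }
  else for (int s = 0; s + k <= L; ++s) starts.push_back(s);
  for (size_t si = 0; si < starts.size(); ++si) {
    int s = starts[si];
    uint64_t code;
    if (!encode_kmer(rd, s, k, code)) continue;
    MapIt it = idx.map.find(code);
    if (it == idx.map.end()) continue;
    const std::vector<Hit>& hits = it->second;
    for (size_t h = 0; h < hits.size(); ++h) {
      long diag = (long)hits[h].pos - s;
      uint64_t key = ((uint64_t)(uint32_t)hits[h].ref << 40) ^
                     (uint64_t)(diag + (1L << 34));
      std::vector<std::pair<int,int> >& iv = done[key];
      bool covered = false;
      for (size_t j = 0; j < iv.size(); ++j)
        if (s >= iv[j].first && s + k <= iv[j].second) { covered = true; break; }
      if (covered) continue;
      Seg sg = extend_seed(rd, idx.seqs[hits[h].ref], diag, s, k, budget);
      sg.ref = hits[h].ref; sg.minus = minus;
      iv.push_back(std::make_pair(sg.rs, sg.re));
      out.push_back(sg);
      if (sg.rs == 0 && sg.re == L) found_full = true;
    }
  }
}

static bool seg_better(const Seg& a, const Seg& b) {
  int la = a.re - a.rs, lb = b.re - b.rs;
  if (la != lb) return la > lb;
  if (a.mm != b.mm) return a.mm < b.mm;
  if (a.ref != b.ref) return a.ref < b.ref;      // host contigs first, transgene last
  long pa = a.diag + a.rs, pb = b.diag + b.rs;
  if (pa != pb) return pa < pb;
  return a.minus < b.minus;                       // plus strand first
}

// [[Rcpp::export(name = ".cpp_align_reads")]]
List cpp_align_reads(SEXP xp, CharacterVector reads, int max_mismatch,
                     int max_cand_per_side) {
  XPtr<KmerIndex> idx(xp);
  int n = reads.size();
  std::vector<int> o_read, o_rs, o_re, o_ref, o_mm;
  std::vector<long> o_refstart;
  std::vector<int> o_minus, o_full;
  int n_ambiguous = 0;
  std::vector<int> ambig_reads;
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int L = (int)rd.size();
    std::string rc = revcomp(rd);
    std::vector<Seg> segs;
    bool found_full = false;
    // fast probe: end seeds only, both orientations
    scan_oriented(*idx, rd, max_mismatch, false, segs, true, found_full);
    if (!found_full) scan_oriented(*idx, rc, max_mismatch, true, segs, true, found_full);
    if (!found_full) {
      segs.clear();
      scan_oriented(*idx, rd, max_mismatch, false, segs, false, found_full);
      scan_oriented(*idx, rc, max_mismatch, true, segs, false, found_full);
    }
    if (segs.empty()) continue;
    std::sort(segs.begin(), segs.end(), seg_better);
    if (found_full) {
      const Seg* best = 0;
      for (size_t j = 0; j < segs.size(); ++j)
        if (segs[j].rs == 0 && segs[j].re == L) { best = &segs[j]; break; }
      o_read.push_back(i + 1);
      int rs = best->rs, re = best->re;
      if (best->minus) { rs = L - best->re; re = L - best->rs; }
      o_rs.push_back(rs); o_re.push_back(re);
      o_ref.push_back(best->ref + 1);
      o_refstart.push_back(best->diag + best->rs);
      o_mm.push_back(best->mm);
      o_minus.push_back(best->minus ? 1 : 0);
      o_full.push_back(1);
      continue;
    }
    // keep maximal (non-contained) segments; containment is judged in
    // read-frame coordinates (minus-pass spans flipped back to the read)
    std::vector<Seg> kept;
    for (size_t j = 0; j < segs.size(); ++j) {
      int jrs = segs[j].minus ? L - segs[j].re : segs[j].rs;
      int jre = segs[j].minus ? L - segs[j].rs : segs[j].re;
      bool contained = false;
      for (size_t m = 0; m < kept.size(); ++m) {
        int mrs = kept[m].minus ? L - kept[m].re : kept[m].rs;
        int mre = kept[m].minus ? L - kept[m].rs : kept[m].re;
        if (jrs >= mrs && jre <= mre &&
            !(jrs == mrs && jre == mre &&
              segs[j].ref == kept[m].ref && segs[j].diag == kept[m].diag &&
              segs[j].minus == kept[m].minus)) { contained = true; break; }
      }
      if (!contained) kept.push_back(segs[j]);
    }
    // ambiguity guard: too many placements touching either read end
    int left = 0, right = 0;
    for (size_t m = 0; m < kept.size(); ++m) {
      int rs = kept[m].rs, re = kept[m].re;
      if (kept[m].minus) { rs = L - kept[m].re; re = L - kept[m].rs; }
      if (rs <= 2) ++left;
      if (re >= L - 2) ++right;
    }
    if (left > max_cand_per_side || right > max_cand_per_side) {
      ++n_ambiguous; ambig_reads.push_back(i + 1);
      continue;
    }
    for (size_t m = 0; m < kept.size(); ++m) {
      int rs = kept[m].rs, re = kept[m].re;
      if (kept[m].minus) { rs = L - kept[m].re; re = L - kept[m].rs; }
      o_read.push_back(i + 1);
      o_rs.push_back(rs); o_re.push_back(re);
      o_ref.push_back(kept[m].ref + 1);
      o_refstart.push_back(kept[m].diag + kept[m].rs);
      o_mm.push_back(kept[m].mm);
      o_minus.push_back(kept[m].minus ? 1 : 0);
      o_full.push_back(0);
    }
  }
  int m = (int)o_read.size();
  IntegerVector read(m), rs(m), re(m), ref(m), mm(m), full(m);
  NumericVector refstart(m);
  CharacterVector strand(m);
  for (int j = 0; j < m; ++j) {
    read[j] = o_read[j]; rs[j] = o_rs[j]; re[j] = o_re[j];
    ref[j] = o_ref[j]; refstart[j] = (double)o_refstart[j];
    mm[j] = o_mm[j]; strand[j] = o_minus[j] ? "-" : "+"; full[j] = o_full[j];
  }
  return List::create(
    _["segments"] = DataFrame::create(
      _["read"] = read, _["read_start"] = rs, _["read_end"] = re,
      _["ref"] = ref, _["ref_start"] = refstart, _["strand"] = strand,
      _["mismatches"] = mm, _["full_length"] = full,
      _["stringsAsFactors"] = false),
    _["n_ambiguous"] = n_ambiguous,
    _["ambiguous_reads"] = wrap(ambig_reads));
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
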