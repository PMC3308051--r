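#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Ungapped, end-to-end, unique-alignment short-read aligner with bowtie-like
// semantics: at most `max_seed_mm` mismatches in the first `seed_len` bases
// and `max_total_mm` overall; reads with more than one valid placement are
// suppressed (multi_hit). Candidate placements are found by pigeonhole seed
// chunks (max_seed_mm+1 disjoint exact chunks) hashed over the reference;
// with very short seeds it falls back to a full scan.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

struct Hit { int target; int pos; int strand; int nm; };

// count mismatches; any non-identical pair (incl. N) is a mismatch
static inline bool verify(const std::string &read, const std::string &ref,
                          int start, int seed, int max_seed_mm,
                          int max_total_mm, int &nm_out) {
  int n = (int)read.size();
  int mm_seed = 0, mm_tot = 0;
  for (int i = 0; i < n; ++i) {
    if (read[i] != ref[start + i]) {
      ++mm_tot;
      if (i < seed) { if (++mm_seed > max_seed_mm) return false; }
      if (mm_tot > max_total_mm) return false;
    }
  }
  nm_out = mm_tot;
  return true;
}

static void collect_hits(const std::string &s, int strand,
                         const std::vector<std::string> &refs,
                         const std::unordered_map<std::string, std::vector<std::pair<int,int> > > &index,
                         int chunk, int n_chunks, int seed_len,
                         int max_seed_mm, int max_total_mm,
                         std::vector<Hit> &hits) {
  int len = (int)s.size();
  int seed = std::min(seed_len, len);
  if (chunk > 0) {
    std::vector<std::pair<int,int> > cand;
    for (int j = 0; j < n_chunks; ++j) {
      int off = j * chunk;
      if (off + chunk > seed) break;
      std::string key = s.substr(off, chunk);
      if (key.find_first_not_of("ACGT") != std::string::npos) continue;
      auto it = index.find(key);
      if (it == index.end()) continue;
      for (auto &tp : it->second) {
        int start = tp.second - off;
        if (start < 0) continue;
        if (start + len > (int)refs[tp.first].size()) continue;
        cand.push_back(std::make_pair(tp.first, start));
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (auto &c : cand) {
      int nm;
      if (verify(s, refs[c.first], c.second, seed, max_seed_mm, max_total_mm, nm))
        hits.push_back(Hit{c.first, c.second, strand, nm});
    }
  } else {
    for (int t = 0; t < (int)refs.size(); ++t) {
      int maxs = (int)refs[t].size() - len;
      for (int start = 0; start <= maxs; ++start) {
        int nm;
        if (verify(s, refs[t], start, seed, max_seed_mm, max_total_mm, nm))
          hits.push_back(Hit{t, start, strand, nm});
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_align_batch")]]
DataFrame cpp_align_batch(CharacterVector reads, CharacterVector ref_seqs,
                          int seed_len, int max_seed_mm, int max_total_mm,
                          bool unique_only) {
  int nref = ref_seqs.size();
  if (nref == 0) stop("empty reference");
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);

  int n = reads.size();
  int min_seed = seed_len;
  for (int i = 0; i < n; ++i) {
    int l = LENGTH(STRING_ELT(reads, i));
    if (l < min_seed) min_seed = l;
  }
  int n_chunks = max_seed_mm + 1;
  int chunk = min_seed / n_chunks;
  if (chunk < 6) chunk = 0;  // brute-force fallback for tiny seeds

  std::unordered_map<std::string, std::vector<std::pair<int,int> > > index;
  if (chunk > 0) {
    for (int t = 0; t < nref; ++t) {
      const std::string &r = refs[t];
      if ((int)r.size() < chunk) continue;
      for (int p = 0; p + chunk <= (int)r.size(); ++p) {
        std::string key = r.substr(p, chunk);
        if (key.find_first_not_of("ACGT") != std::string::npos) continue;
        index[key].push_back(std::make_pair(t, p));
      }
    }
  }

  IntegerVector status(n), target(n), pos(n), nm(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::vector<Hit> hits;
    collect_hits(fwd, 0, refs, index, chunk, n_chunks, seed_len,
                 max_seed_mm, max_total_mm, hits);
    std::string rev = revcomp(fwd);
    collect_hits(rev, 1, refs, index, chunk, n_chunks, seed_len,
                 max_seed_mm, max_total_mm, hits);
    // distinct placements (target, pos, strand)
    std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
      if (a.target != b.target) return a.target < b.target;
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.strand < b.strand;
    });
    hits.erase(std::unique(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
      return a.target == b.target && a.pos == b.pos && a.strand == b.strand;
    }), hits.end());
    if (hits.size() > 1 && !unique_only) {
      // best-hit mode: fewest mismatches, then lowest (target, pos, strand)
      size_t best = 0;
      for (size_t h = 1; h < hits.size(); ++h)
        if (hits[h].nm < hits[best].nm) best = h;
      hits[0] = hits[best];
      hits.resize(1);
    }
    if (hits.size() == 1) {
      status[i] = 1;
      target[i] = hits[0].target + 1;
      pos[i] = hits[0].pos + 1;
      strand[i] = hits[0].strand == 0 ? "+" : "-";
      nm[i] = hits[0].nm;
    } else if (hits.empty()) {
      status[i] = 2;  // no_hit
      target[i] = NA_INTEGER; pos[i] = NA_INTEGER; nm[i] = NA_INTEGER;
      strand[i] = NA_STRING;
    } else {
      status[i] = 3;  // multi_hit
      target[i] = NA_INTEGER; pos[i] = NA_INTEGER; nm[i] = NA_INTEGER;
      strand[i] = NA_STRING;
    }
  }
  return DataFrame::create(_["status"] = status, _["target"] = target,
                           _["pos"] = pos, _["strand"] = strand, _["nm"] = nm,
                           _["stringsAsFactors"] = false);
}

// Scan a raw read pool (both strands) for reads matching a flank query with
// at most max_mm mismatches over the overlap, covering the query's centre
// base and agreeing with the substituted candidate variant there.
// [[Rcpp::export(name = ".cpp_flank_scan")]]
LogicalVector cpp_flank_scan(CharacterVector queries, IntegerVector centers,
                             CharacterVector reads, int max_mm, int min_overlap) {
  int nr = reads.size(), nq = queries.size();
  std::vector<std::string> pool;
  pool.reserve(2 * nr);
  for (int i = 0; i < nr; ++i) {
    std::string s = as<std::string>(reads[i]);
    pool.push_back(s);
    pool.push_back(revcomp(s));
  }
  const int K = 10;
  std::unordered_map<std::string, std::vector<std::pair<int,int> > > index;
  for (int r = 0; r < (int)pool.size(); ++r) {
    const std::string &s = pool[r];
    for (int p = 0; p + K <= (int)s.size(); ++p)
      index[s.substr(p, K)].push_back(std::make_pair(r, p));
  }
  LogicalVector found(nq);
  for (int q = 0; q < nq; ++q) {
    std::string qu = as<std::string>(queries[q]);
    int qlen = (int)qu.size();
    int cpos = centers[q] - 1;  // 0-based index of variant within query
    bool ok = false;
    int n_chunks = std::min(max_mm + 1, qlen / K);
    for (int j = 0; j < n_chunks && !ok; ++j) {
      int off = j * K;
      auto it = index.find(qu.substr(off, K));
      if (it == index.end()) continue;
      for (auto &rp : it->second) {
        const std::string &s = pool[rp.first];
        int d = rp.second - off;  // read index of query[0]
        int rc = d + cpos;
        if (rc < 0 || rc >= (int)s.size()) continue;
        if (s[rc] != qu[cpos]) continue;
        int lo = std::max(0, -d);
        int hi = std::min(qlen - 1, (int)s.size() - 1 - d);
        if (hi - lo + 1 < min_overlap) continue;
        int mm = 0;
        bool pass = true;
        for (int i = lo; i <= hi; ++i) {
          if (qu[i] != s[d + i] && ++mm > max_mm) { pass = false; break; }
        }
        if (pass) { ok = true; break; }
      }
    }
    found[q] = ok;
  }
  return found;
}

static inline int base2bits(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

static std::string decode_kmer(uint64_t v, int k) {
  static const char *B = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = B[v & 3ULL]; v >>= 2; }
  return s;
}

// 2-bit rolling k-mer counter; windows containing non-ACGT bases are skipped.
// [[Rcpp::export(name = ".cpp_kmer_count")]]
DataFrame cpp_kmer_count(CharacterVector seqs, int k, bool canonical) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  std::unordered_map<uint64_t, double> counts;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (int i = 0; i < (int)seq.size(); ++i) {
      int b = base2bits(seq[i]);
      if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t key = (canonical && rev < fwd) ? rev : fwd;
        counts[key] += 1.0;
      }
    }
  }
  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (auto &kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  int n = (int)keys.size();
  CharacterVector kmer(n);
  NumericVector count(n);
  for (int i = 0; i < n; ++i) {
    kmer[i] = decode_kmer(keys[i], k);
    count[i] = counts[keys[i]];
  }
  return DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".cpp_kmer_encode")]]
CharacterVector cpp_kmer_encode(CharacterVector kmers) {
  int n = kmers.size();
  CharacterVector out(n);
  char buf[17];
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if (s.size() < 1 || s.size() > 32) stop("k-mer length must be in 1..32");
    uint64_t v = 0;
    for (char c : s) {
      int b = base2bits(c);
      if (b < 0) stop("ambiguous base in k-mer");
      v = (v << 2) | (uint64_t)b;
    }
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)v);
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_kmer_decode")]]
CharacterVector cpp_kmer_decode(CharacterVector codes, int k) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  int n = codes.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string h = as<std::string>(codes[i]);
    uint64_t v = 0;
    for (char c : h) {
      int d;
      if (c >= '0' && c <= '9') d = c - '0';
      else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
      else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
      else stop("invalid hexadecimal k-mer code");
      v = (v << 4) | (uint64_t)d;
    }
    out[i] = decode_kmer(v, k);
  }
  return out;
}
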