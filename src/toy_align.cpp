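// Ungapped seed-and-extend read aligner over a k-mer index of the
// reference genomes. Substitution-only model: every candidate diagonal
// with enough exact seeds is extended across the whole read (clipped at
// genome ends) and reported, so downstream best-hit selection sees all
// competing placements. Score = max(0, 2*matches - 3*mismatches).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
  }
  return 'N';
}

// Collect the 2-bit encoded k-mers of s; kmers[i] valid iff ok[i].
static void encode_kmers(const std::string& s, int k,
                         std::vector<uint64_t>& kmers,
                         std::vector<char>& ok) {
  const int n = (int)s.size();
  const int m = n - k + 1;
  kmers.assign(m > 0 ? m : 0, 0);
  ok.assign(m > 0 ? m : 0, 0);
  if (m <= 0) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t cur = 0;
  int run = 0; // consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      kmers[i - k + 1] = cur;
      ok[i - k + 1] = 1;
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_toy_align(CharacterVector ref_seqs, CharacterVector ref_ids,
                        CharacterVector read_seqs, CharacterVector read_ids,
                        int k, int min_seed_hits) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  const int n_ref = ref_seqs.size();
  std::vector<std::string> refs(n_ref);
  for (int r = 0; r < n_ref; ++r) refs[r] = as<std::string>(ref_seqs[r]);

  // k-mer -> postings of (ref << 32 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  {
    std::vector<uint64_t> kmers; std::vector<char> ok;
    size_t total = 0;
    for (int r = 0; r < n_ref; ++r) total += refs[r].size();
    index.reserve(total);
    for (int r = 0; r < n_ref; ++r) {
      encode_kmers(refs[r], k, kmers, ok);
      for (size_t p = 0; p < kmers.size(); ++p)
        if (ok[p])
          index[kmers[p]].push_back(((uint64_t)r << 32) | (uint32_t)p);
    }
  }

  std::vector<std::string> out_q, out_s;
  std::vector<double> out_qlen, out_pid, out_alen, out_qs, out_qe,
      out_ss, out_se, out_bits;

  std::vector<uint64_t> kmers; std::vector<char> ok;
  std::unordered_map<int64_t, int> diag_count;
  const int n_reads = read_seqs.size();
  for (int i = 0; i < n_reads; ++i) {
    std::string fwd = as<std::string>(read_seqs[i]);
    const int L = (int)fwd.size();
    std::string rev(L, 'N');
    for (int j = 0; j < L; ++j) rev[j] = comp_base(fwd[L - 1 - j]);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = strand == 0 ? fwd : rev;
      encode_kmers(rd, k, kmers, ok);
      if (kmers.empty()) continue;
      diag_count.clear();
      for (size_t p = 0; p < kmers.size(); ++p) {
        if (!ok[p]) continue;
        std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator
            it = index.find(kmers[p]);
        if (it == index.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j) {
          int r = (int)(it->second[j] >> 32);
          int64_t pos = (int64_t)(uint32_t)it->second[j];
          int64_t diag = pos - (int64_t)p; // ref offset of read position 0
          diag_count[((int64_t)r << 33) + diag + L]++;
        }
      }
      for (std::unordered_map<int64_t, int>::const_iterator it =
               diag_count.begin(); it != diag_count.end(); ++it) {
        if (it->second < min_seed_hits) continue;
        int r = (int)(it->first >> 33);
        int64_t diag = (it->first & ((1LL << 33) - 1)) - L;
        const std::string& rf = refs[r];
        const int64_t rlen = (int64_t)rf.size();
        int64_t qs0 = diag < 0 ? -diag : 0;
        int64_t qe0 = std::min((int64_t)L - 1, rlen - 1 - diag);
        if (qe0 < qs0) continue;
        int matches = 0, mism = 0;
        for (int64_t q = qs0; q <= qe0; ++q) {
          if (rd[(size_t)q] == rf[(size_t)(diag + q)]) ++matches;
          else ++mism;
        }
        const double alen = (double)(qe0 - qs0 + 1);
        double bits = 2.0 * matches - 3.0 * mism;
        if (bits < 0) bits = 0;
        double qstart, qend, sstart, send;
        if (strand == 0) {
          qstart = (double)(qs0 + 1); qend = (double)(qe0 + 1);
          sstart = (double)(diag + qs0 + 1); send = (double)(diag + qe0 + 1);
        } else { // report on the original read orientation
          qstart = (double)(L - qe0); qend = (double)(L - qs0);
          sstart = (double)(diag + qe0 + 1); send = (double)(diag + qs0 + 1);
        }
        out_q.push_back(as<std::string>(read_ids[i]));
        out_s.push_back(as<std::string>(ref_ids[r]));
        out_qlen.push_back((double)L);
        out_pid.push_back(100.0 * matches / alen);
        out_alen.push_back(alen);
        out_qs.push_back(qstart); out_qe.push_back(qend);
        out_ss.push_back(sstart); out_se.push_back(send);
        out_bits.push_back(bits);
      }
    }
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(
      Named("query_id") = out_q,
      Named("query_length") = out_qlen,
      Named("subject_id") = out_s,
      Named("percent_identity") = out_pid,
      Named("alignment_length") = out_alen,
      Named("query_start") = out_qs,
      Named("query_end") = out_qe,
      Named("subject_start") = out_ss,
      Named("subject_end") = out_se,
      Named("bitscore") = out_bits,
      Named("stringsAsFactors") = false);
}
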