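#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes; -1 for anything outside ACGT (acgt accepted).
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_char(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_char(c);
  return r;
}

// k-mer index: 2-bit packed k-mer -> list of (seq index, position)
struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> map;
};

static bool pack_kmer(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static KmerIndex build_index(const std::vector<std::string>& seqs, int k) {
  KmerIndex idx;
  idx.k = k;
  for (size_t i = 0; i < seqs.size(); ++i) {
    const std::string& s = seqs[i];
    if ((int)s.size() < k) continue;
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint64_t v;
      if (pack_kmer(s, p, k, v)) idx.map[v].push_back({(int)i, p});
    }
  }
  return idx;
}

// Best ungapped local segment along one diagonal (Kadane on +match/-mismatch
// column scores). Returns score; fills [qs,qe) span on `q` and match count.
static int best_segment(const std::string& q, const std::string& s, int diag,
                        int match, int mismatch,
                        int& qs, int& qe, int& nmatch) {
  // diag = s_pos - q_pos. Overlap in q coordinates:
  int q0 = std::max(0, -diag);
  int q1 = std::min((int)q.size(), (int)s.size() - diag);
  int best = 0, cur = 0, cur_start = q0, cur_match = 0;
  int best_qs = q0, best_qe = q0, best_match = 0;
  for (int i = q0; i < q1; ++i) {
    bool m = base_code(q[i]) >= 0 && base_code(q[i]) == base_code(s[i + diag]);
    int sc = m ? match : mismatch;
    if (cur <= 0) { cur = 0; cur_start = i; cur_match = 0; }
    cur += sc;
    if (m) cur_match++;
    if (cur > best) {
      best = cur; best_qs = cur_start; best_qe = i + 1; best_match = cur_match;
    } else if (cur <= 0) {
      cur = 0; cur_match = 0;
    }
  }
  // trim leading mismatches inside the best window (Kadane never starts on
  // one, but the match counter can lag after resets; recount exactly)
  nmatch = 0;
  for (int i = best_qs; i < best_qe; ++i)
    if (base_code(q[i]) >= 0 && base_code(q[i]) == base_code(s[i + diag]))
      nmatch++;
  qs = best_qs; qe = best_qe;
  return best;
}

// [[Rcpp::export]]
DataFrame cpp_find_hits(CharacterVector query_seqs, CharacterVector query_ids,
                        CharacterVector subject_seqs, CharacterVector subject_ids,
                        int k, int min_aln_len, double min_identity,
                        bool skip_same_id, int match_score, int mismatch_score) {
  std::vector<std::string> subs(subject_seqs.size());
  for (int i = 0; i < subject_seqs.size(); ++i) subs[i] = as<std::string>(subject_seqs[i]);
  KmerIndex idx = build_index(subs, k);

  std::vector<std::string> out_q, out_s, out_strand;
  std::vector<double> out_ident;
  std::vector<int> out_len, out_qs, out_qe, out_ss, out_se, out_score;

  for (int qi = 0; qi < query_seqs.size(); ++qi) {
    std::string qfwd = as<std::string>(query_seqs[qi]);
    if ((int)qfwd.size() < k) continue;
    std::string qname = as<std::string>(query_ids[qi]);
    // best hit per subject: score, then data
    std::unordered_map<int, std::array<int,7>> best; // sj -> score,qs,qe,ss,se,strand,nmatch

    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? qfwd : revcomp(qfwd);
      // collect seed diagonals per subject
      std::unordered_map<int, std::unordered_set<int>> diags;
      for (int p = 0; p + k <= (int)q.size(); ++p) {
        uint64_t v;
        if (!pack_kmer(q, p, k, v)) continue;
        auto it = idx.map.find(v);
        if (it == idx.map.end()) continue;
        for (auto& hit : it->second) diags[hit.first].insert(hit.second - p);
      }
      for (auto& kv : diags) {
        int sj = kv.first;
        if (skip_same_id && as<std::string>(subject_ids[sj]) == qname) continue;
        for (int diag : kv.second) {
          int qs, qe, nmatch;
          int sc = best_segment(q, subs[sj], diag, match_score, mismatch_score,
                                qs, qe, nmatch);
          auto it = best.find(sj);
          if (it == best.end() || sc > it->second[0]) {
            best[sj] = {sc, qs, qe, qs + diag, qe + diag, strand, nmatch};
          }
        }
      }
    }
    for (auto& kv : best) {
      auto& b = kv.second;
      int alen = b[2] - b[1];
      if (alen < min_aln_len) continue;
      double ident = alen > 0 ? (double)b[6] / alen : 0.0;
      if (ident < min_identity) continue;
      int qs = b[1], qe = b[2];
      if (b[5] == 1) { // map back to original query orientation
        int L = (int)qfwd.size();
        int nqs = L - qe, nqe = L - qs;
        qs = nqs; qe = nqe;
      }
      out_q.push_back(qname);
      out_s.push_back(as<std::string>(subject_ids[kv.first]));
      out_ident.push_back(ident);
      out_len.push_back(alen);
      out_qs.push_back(qs); out_qe.push_back(qe);
      out_ss.push_back(b[3]); out_se.push_back(b[4]);
      out_strand.push_back(b[5] == 0 ? "+" : "-");
      out_score.push_back(b[0]);
    }
  }
  return DataFrame::create(
    _["query"] = out_q, _["subject"] = out_s, _["identity"] = out_ident,
    _["aln_len"] = out_len, _["q_start"] = out_qs, _["q_end"] = out_qe,
    _["s_start"] = out_ss, _["s_end"] = out_se, _["strand"] = out_strand,
    _["score"] = out_score, _["stringsAsFactors"] = false);
}

// Ungapped read mapping: every read k-mer seeds candidate placements on both
// strands; the minimal-mismatch full-length placement wins; ties across
// distinct placements -> ambiguous.
// status: 0 unmapped, 1 unique, 2 ambiguous
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector ref_seqs, CharacterVector reads,
                        double max_mismatch_frac, int k) {
  std::vector<std::string> refs(ref_seqs.size());
  for (int i = 0; i < ref_seqs.size(); ++i) refs[i] = as<std::string>(ref_seqs[i]);
  KmerIndex idx = build_index(refs, k);

  int n = reads.size();
  IntegerVector status(n), ref_idx(n), pos(n), mism(n);
  CharacterVector strand(n);

  for (int ri = 0; ri < n; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int len = (int)fwd.size();
    status[ri] = 0; ref_idx[ri] = NA_INTEGER; pos[ri] = NA_INTEGER;
    mism[ri] = NA_INTEGER; strand[ri] = NA_STRING;
    if (len < k) continue;
    int budget = (int)(max_mismatch_frac * len) + 1;
    std::string rev = revcomp(fwd);
    int best_mm = budget + 1, best_ref = -1, best_pos = -1, best_strand = 0;
    int n_best = 0;
    std::unordered_set<int64_t> seen; // (strand, ref, pos) keys

    for (int strd = 0; strd < 2; ++strd) {
      const std::string& rd = strd == 0 ? fwd : rev;
      for (int p = 0; p + k <= len; ++p) {
        uint64_t v;
        if (!pack_kmer(rd, p, k, v)) continue;
        auto it = idx.map.find(v);
        if (it == idx.map.end()) continue;
        for (auto& hit : it->second) {
          int rpos = hit.second - p;
          if (rpos < 0 || rpos + len > (int)refs[hit.first].size()) continue;
          int64_t key = ((int64_t)strd << 62) | ((int64_t)hit.first << 32) | (uint32_t)rpos;
          if (!seen.insert(key).second) continue;
          const std::string& R = refs[hit.first];
          int mm = 0;
          for (int j = 0; j < len && mm <= best_mm; ++j)
            if (base_code(rd[j]) != base_code(R[rpos + j])) mm++;
          if (mm > budget) continue;
          if (mm < best_mm) {
            best_mm = mm; best_ref = hit.first; best_pos = rpos;
            best_strand = strd; n_best = 1;
          } else if (mm == best_mm) {
            n_best++;
          }
        }
      }
    }
    if (n_best == 1) {
      status[ri] = 1; ref_idx[ri] = best_ref + 1; pos[ri] = best_pos;
      mism[ri] = best_mm; strand[ri] = best_strand == 0 ? "+" : "-";
    } else if (n_best > 1) {
      status[ri] = 2; mism[ri] = best_mm;
    }
  }
  return DataFrame::create(
    _["status"] = status, _["ref_idx"] = ref_idx, _["pos"] = pos,
    _["strand"] = strand, _["mismatches"] = mism,
    _["stringsAsFactors"] = false);
}

// Long-format pileup from uniquely mapped, ungapped alignments.
// ref_idx/pos/strand parallel to reads/quals (already filtered to mapped).
// quals are Phred+33 strings. Returns one row per (read, base) observation.
// [[Rcpp::export]]
List cpp_pileup(IntegerVector ref_idx, IntegerVector pos, CharacterVector strand,
                CharacterVector reads, CharacterVector quals) {
  size_t total = 0;
  int n = reads.size();
  for (int i = 0; i < n; ++i) total += LENGTH(STRING_ELT(reads, i));
  std::vector<int> o_ref; o_ref.reserve(total);
  std::vector<int> o_pos; o_pos.reserve(total);
  std::vector<int> o_base; o_base.reserve(total);
  std::vector<int> o_qual; o_qual.reserve(total);

  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::string qu = as<std::string>(quals[i]);
    int len = (int)rd.size();
    bool minus = as<std::string>(strand[i]) == "-";
    for (int j = 0; j < len; ++j) {
      char b; int q;
      if (!minus) { b = rd[j]; q = qu[j] - 33; }
      else { b = comp_char(rd[len - 1 - j]); q = qu[len - 1 - j] - 33; }
      int code = base_code(b);
      if (code < 0) continue;
      o_ref.push_back(ref_idx[i]);
      o_pos.push_back(pos[i] + j);
      o_base.push_back(code);
      o_qual.push_back(q);
    }
  }
  return List::create(
    _["ref_idx"] = wrap(o_ref), _["pos"] = wrap(o_pos),
    _["base"] = wrap(o_base), _["qual"] = wrap(o_qual));
}
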