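// Byte-pair encoding over DNA alphabets.
//
// Training uses the classic greedy scheme: start from the unique characters of
// the corpus, repeatedly merge the most frequent adjacent token pair (ties:
// lexicographically smallest merged string) until the vocabulary target is
// reached or no pair occurs at least twice. The corpus is held as a doubly
// linked token list so each merge touches only the occurrences of the chosen
// pair; pair counts are maintained exactly, occurrence position lists may hold
// stale entries that are validated at merge time.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline uint64_t pair_key(int a, int b) {
  return (static_cast<uint64_t>(static_cast<uint32_t>(a)) << 32) |
         static_cast<uint32_t>(b);
}

// [[Rcpp::export(name = ".cpp_bpe_train")]]
List cpp_bpe_train(CharacterVector seqs, int vocab_size) {
  if (seqs.size() == 0) stop("empty corpus");

  // Alphabet = sorted unique characters of the corpus.
  std::vector<bool> seen(256, false);
  size_t total = 0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    for (; *p; ++p) { seen[static_cast<unsigned char>(*p)] = true; ++total; }
  }
  if (total == 0) stop("empty corpus");
  std::vector<int> char2id(256, -1);
  std::vector<std::string> tokens;
  for (int c = 0; c < 256; ++c) {
    if (seen[c]) {
      char2id[c] = static_cast<int>(tokens.size());
      tokens.push_back(std::string(1, static_cast<char>(c)));
    }
  }

  // Linked token list over the concatenated corpus; sequences are not linked
  // across their boundaries.
  std::vector<int> tok(total), prv(total), nxt(total);
  {
    size_t i = 0;
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
      const char* p = CHAR(STRING_ELT(seqs, s));
      size_t start = i;
      for (; *p; ++p, ++i) {
        tok[i] = char2id[static_cast<unsigned char>(*p)];
        prv[i] = (i > start) ? static_cast<int>(i - 1) : -1;
      }
      for (size_t j = start; j < i; ++j)
        nxt[j] = (j + 1 < i) ? static_cast<int>(j + 1) : -1;
    }
  }

  std::unordered_map<uint64_t, long long> counts;
  std::unordered_map<uint64_t, std::vector<int> > positions;
  counts.reserve(1 << 16);
  positions.reserve(1 << 16);
  for (size_t i = 0; i < total; ++i) {
    int j = nxt[i];
    if (j < 0) continue;
    uint64_t k = pair_key(tok[i], tok[j]);
    ++counts[k];
    positions[k].push_back(static_cast<int>(i));
  }

  std::vector<int> merge_left, merge_right;
  const int target = vocab_size;

  while (static_cast<int>(tokens.size()) < target) {
    // Select highest-count pair; ties broken on the merged string.
    long long best_n = 0;
    uint64_t best_k = 0;
    std::string best_s;
    for (std::unordered_map<uint64_t, long long>::const_iterator it = counts.begin();
         it != counts.end(); ++it) {
      if (it->second < 2 || it->second < best_n) continue;
      int a = static_cast<int>(it->first >> 32);
      int b = static_cast<int>(it->first & 0xffffffffu);
      if (it->second > best_n) {
        best_n = it->second; best_k = it->first; best_s = tokens[a] + tokens[b];
      } else { // tie
        std::string s = tokens[a] + tokens[b];
        if (s < best_s) { best_k = it->first; best_s = s; }
      }
    }
    if (best_n < 2) break;

    int a = static_cast<int>(best_k >> 32);
    int b = static_cast<int>(best_k & 0xffffffffu);
    int nid = static_cast<int>(tokens.size());
    tokens.push_back(best_s);
    merge_left.push_back(a);
    merge_right.push_back(b);

    std::vector<int> occ;
    occ.swap(positions[best_k]);
    positions.erase(best_k);

    for (size_t oi = 0; oi < occ.size(); ++oi) {
      int i = occ[oi];
      if (tok[i] != a) continue;
      int j = nxt[i];
      if (j < 0 || tok[j] != b) continue;

      int lp = prv[i], rn = nxt[j];
      if (lp >= 0) {
        uint64_t ko = pair_key(tok[lp], a);
        if (--counts[ko] <= 0) counts.erase(ko);
        uint64_t kn = pair_key(tok[lp], nid);
        ++counts[kn];
        positions[kn].push_back(lp);
      }
      if (rn >= 0) {
        uint64_t ko = pair_key(b, tok[rn]);
        if (--counts[ko] <= 0) counts.erase(ko);
        uint64_t kn = pair_key(nid, tok[rn]);
        ++counts[kn];
        positions[kn].push_back(i);
      }
      long long &cab = counts[best_k];
      if (--cab <= 0) counts.erase(best_k);

      tok[i] = nid;
      tok[j] = -2; // consumed
      nxt[i] = rn;
      if (rn >= 0) prv[rn] = i;
    }
    counts.erase(best_k);
  }

  return List::create(
    _["tokens"] = wrap(tokens),
    _["merge_left"] = wrap(merge_left),   // 0-based token ids
    _["merge_right"] = wrap(merge_right),
    _["n_alphabet"] = static_cast<int>(tokens.size()) -
                      static_cast<int>(merge_left.size()));
}

// Encode sequences by applying learned merges in rank order: repeatedly merge
// the present pair with the lowest rank (left-to-right within a pass).
// Characters outside the learned alphabet become id -1 (UNK) and never merge.
// [[Rcpp::export(name = ".cpp_bpe_encode")]]
List cpp_bpe_encode(CharacterVector seqs, CharacterVector tokens,
                    IntegerVector merge_left, IntegerVector merge_right) {
  std::vector<int> char2id(256, -1);
  int n_tok = tokens.size();
  for (int t = 0; t < n_tok; ++t) {
    const char* s = CHAR(STRING_ELT(tokens, t));
    if (s[0] != '\0' && s[1] == '\0')
      char2id[static_cast<unsigned char>(s[0])] = t;
  }
  // rank map: pair -> (rank, new id)
  std::unordered_map<uint64_t, std::pair<int, int> > rank;
  rank.reserve(merge_left.size() * 2 + 1);
  int n_alpha = n_tok - merge_left.size();
  for (int r = 0; r < merge_left.size(); ++r)
    rank[pair_key(merge_left[r], merge_right[r])] = std::make_pair(r, n_alpha + r);

  List out(seqs.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    std::vector<int> ids;
    std::vector<int> st, en;
    for (int i = 0; p[i]; ++i) {
      ids.push_back(char2id[static_cast<unsigned char>(p[i])]);
      st.push_back(i);
      en.push_back(i + 1);
    }
    while (true) {
      int best_rank = INT_MAX, best_new = -1;
      for (size_t i = 0; i + 1 < ids.size(); ++i) {
        if (ids[i] < 0 || ids[i + 1] < 0) continue;
        std::unordered_map<uint64_t, std::pair<int, int> >::const_iterator it =
          rank.find(pair_key(ids[i], ids[i + 1]));
        if (it != rank.end() && it->second.first < best_rank) {
          best_rank = it->second.first;
          best_new = it->second.second;
        }
      }
      if (best_new < 0) break;
      int a = merge_left[best_rank], b = merge_right[best_rank];
      std::vector<int> nids, nst, nen;
      nids.reserve(ids.size());
      for (size_t i = 0; i < ids.size(); ) {
        if (i + 1 < ids.size() && ids[i] == a && ids[i + 1] == b) {
          nids.push_back(best_new);
          nst.push_back(st[i]);
          nen.push_back(en[i + 1]);
          i += 2;
        } else {
          nids.push_back(ids[i]); nst.push_back(st[i]); nen.push_back(en[i]);
          ++i;
        }
      }
      ids.swap(nids); st.swap(nst); en.swap(nen);
    }
    out[s] = List::create(_["ids"] = wrap(ids), _["start"] = wrap(st),
                          _["end"] = wrap(en));
  }
  return out;
}
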