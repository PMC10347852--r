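#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>
#include <memory>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

// lexicographic min of kmer and its reverse complement
static std::string canonical(const std::string &kmer) {
  std::string rc = revcomp(kmer);
  return (rc < kmer) ? rc : kmer;
}

// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> counts;
  counts.reserve(1 << 16);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) continue;
    std::string s = as<std::string>(seqs[i]);
    int n = (int) s.size();
    if (n < k) continue;
    // positions of invalid bases invalidate overlapping k-mers
    int last_bad = -1;
    for (int j = 0; j < n; ++j) {
      if (!valid_base(s[j])) last_bad = j;
      if (j >= k - 1 && last_bad <= j - k) {
        counts[canonical(s.substr(j - k + 1, k))]++;
      }
    }
  }
  std::vector<std::string> keys;
  keys.reserve(counts.size());
  for (auto &kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmers(keys.size());
  IntegerVector cnt(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmers[i] = keys[i];
    cnt[i] = counts[keys[i]];
  }
  return List::create(_["kmer"] = kmers, _["count"] = cnt);
}

struct PathState {
  std::string seq;                             // spelled sequence, starts with START
  std::unordered_map<std::string, int> visits; // canonical k-mer -> times used
};

// Breadth-first enumeration of paths START -> STOP over the solid k-mer set.
// STOP is absorbing; a path may use a canonical k-mer at most `max_visits`
// times; the frontier is capped at `max_branches` partial paths and the whole
// search at `max_nodes` accepted extensions.
// [[Rcpp::export(name = ".traverse_cpp")]]
List traverse_cpp(CharacterVector solid, std::string start, std::string stop,
                  int k, int max_len, int max_branches, double max_nodes,
                  int max_visits = 2) {
  std::unordered_set<std::string> graph;
  graph.reserve(solid.size() * 2);
  for (R_xlen_t i = 0; i < solid.size(); ++i)
    graph.insert(as<std::string>(solid[i]));

  bool limit_reached = false;
  double nodes = 0;
  std::vector<std::string> results;

  if ((int) start.size() != k || (int) stop.size() != k ||
      graph.find(canonical(start)) == graph.end() ||
      graph.find(canonical(stop)) == graph.end()) {
    return List::create(_["sequences"] = CharacterVector(0),
                        _["limit_reached"] = false,
                        _["nodes_explored"] = 0.0,
                        _["anchors_in_graph"] = false);
  }
  if (start == stop) {
    return List::create(_["sequences"] = CharacterVector::create(start),
                        _["limit_reached"] = false,
                        _["nodes_explored"] = 0.0,
                        _["anchors_in_graph"] = true);
  }

  const char bases[4] = {'A', 'C', 'G', 'T'};
  std::vector<std::unique_ptr<PathState>> frontier;
  {
    auto p0 = std::make_unique<PathState>();
    p0->seq = start;
    p0->visits[canonical(start)] = 1;
    frontier.push_back(std::move(p0));
  }

  while (!frontier.empty() && !limit_reached) {
    std::vector<std::unique_ptr<PathState>> next;
    for (auto &p : frontier) {
      if (limit_reached) break;
      std::string suffix = p->seq.substr(p->seq.size() - (k - 1));
      // collect admissible extensions first so the path state can be moved
      // into the last one instead of copied
      std::vector<char> ext;
      for (int b = 0; b < 4; ++b) {
        std::string kmer = suffix + bases[b];
        std::string canon = canonical(kmer);
        if (graph.find(canon) == graph.end()) continue;
        nodes += 1;
        if (nodes > max_nodes) { limit_reached = true; break; }
        if (kmer == stop) {
          results.push_back(p->seq + bases[b]);
          continue;
        }
        auto it = p->visits.find(canon);
        int v = (it == p->visits.end()) ? 0 : it->second;
        if (v >= max_visits) continue;
        if ((int) p->seq.size() + 1 > max_len) { limit_reached = true; continue; }
        ext.push_back(bases[b]);
      }
      for (size_t e = 0; e < ext.size(); ++e) {
        std::unique_ptr<PathState> q;
        if (e + 1 == ext.size()) q = std::move(p);
        else q = std::make_unique<PathState>(*p);
        q->seq.push_back(ext[e]);
        q->visits[canonical(q->seq.substr(q->seq.size() - k))]++;
        next.push_back(std::move(q));
      }
    }
    if ((int) next.size() > max_branches) {
      next.resize(max_branches);
      limit_reached = true;
    }
    frontier = std::move(next);
  }

  std::sort(results.begin(), results.end(),
            [](const std::string &a, const std::string &b) {
              if (a.size() != b.size()) return a.size() < b.size();
              return a < b;
            });
  results.erase(std::unique(results.begin(), results.end()), results.end());

  return List::create(_["sequences"] = wrap(results),
                      _["limit_reached"] = limit_reached,
                      _["nodes_explored"] = nodes,
                      _["anchors_in_graph"] = true);
}

// Apply iid substitution errors at `rate` per base, using R's RNG so results
// are reproducible under set.seed(). Substituted base is drawn uniformly from
// the three alternatives.
// [[Rcpp::export(name = ".mutate_seqs_cpp")]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double rate) {
  RNGScope scope;
  const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < rate && valid_base(s[j])) {
        char cur = s[j];
        char nb = cur;
        while (nb == cur) nb = bases[(int) (unif_rand() * 4) & 3];
        s[j] = nb;
      }
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// [[Rcpp::export(name = ".canonical_cpp")]]
CharacterVector canonical_cpp(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    out[i] = canonical(as<std::string>(kmers[i]));
  return out;
}
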