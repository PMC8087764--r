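#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// fast internal generator for the event loop (xoshiro256+), seeded from
// R's RNG so set.seed() controls all randomness
struct FastRNG {
  uint64_t s[4];
  FastRNG() {
    for (int i = 0; i < 4; ++i)
      s[i] = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
             (uint64_t)(unif_rand() * 4294967296.0) | 1ull;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double u() { return (next() >> 11) * 1.1102230246251565e-16; }
  inline double e() { return -std::log(1.0 - u()); }
};

// Structured coalescent with population splits (backward-time merges),
// optional per-generation migration active on a time window [0, mig_end),
// and instantaneous admixture pulses.  Time is in generations; the pairwise
// coalescence rate for haploid lineages in a diploid deme of size N is
// 1/(2N) per pair per generation.

namespace {

struct SplitEv { double t; int derived; int ancestral; double newsize; };
struct PulseEv { double t; int deme; int source; double prob; };

struct ModelC {
  int D;
  std::vector<double> N0;
  std::vector<SplitEv> splits;
  std::vector<PulseEv> pulses;
  std::vector<double> mig;   // D x D row-major, m[i][j] backward rate i -> j
  double mig_end;
  bool has_mig;
};

ModelC parse_model(const List& model) {
  ModelC mc;
  NumericVector N = model["N"];
  mc.D = N.size();
  mc.N0.assign(N.begin(), N.end());
  NumericVector st = model["split_time"];
  IntegerVector sd = model["split_derived"];
  IntegerVector sa = model["split_ancestral"];
  NumericVector sn = model["split_newsize"];
  for (int i = 0; i < st.size(); ++i) {
    SplitEv e; e.t = st[i]; e.derived = sd[i]; e.ancestral = sa[i];
    e.newsize = NumericVector::is_na(sn[i]) ? -1.0 : sn[i];
    mc.splits.push_back(e);
  }
  std::sort(mc.splits.begin(), mc.splits.end(),
            [](const SplitEv& a, const SplitEv& b) { return a.t < b.t; });
  NumericVector pt = model["pulse_time"];
  IntegerVector pd = model["pulse_deme"];
  IntegerVector ps = model["pulse_source"];
  NumericVector pp = model["pulse_prob"];
  for (int i = 0; i < pt.size(); ++i) {
    PulseEv e; e.t = pt[i]; e.deme = pd[i]; e.source = ps[i]; e.prob = pp[i];
    mc.pulses.push_back(e);
  }
  std::sort(mc.pulses.begin(), mc.pulses.end(),
            [](const PulseEv& a, const PulseEv& b) { return a.t < b.t; });
  NumericMatrix M = model["mig"];
  mc.mig.assign(mc.D * mc.D, 0.0);
  for (int i = 0; i < mc.D; ++i)
    for (int j = 0; j < mc.D; ++j) mc.mig[i * mc.D + j] = M(i, j);
  mc.mig_end = as<double>(model["mig_end"]);
  mc.has_mig = false;
  for (double v : mc.mig) if (v > 0) mc.has_mig = true;
  if (mc.mig_end <= 0) mc.has_mig = false;
  return mc;
}

struct Tree {
  std::vector<int> parent;    // 2n-1 entries, root has -1
  std::vector<double> time;   // node times
  int n;                      // leaves
};

// scheduled-event tags
enum EvType { EV_SPLIT = 0, EV_PULSE = 1, EV_MIGOFF = 2 };
struct Sched { double t; int type; int idx; };

// workspace reused across trees to avoid per-step allocation
struct SimWS {
  std::vector<std::vector<int>> pool;
  std::vector<bool> active;
  std::vector<double> N, inv2N, coal, migd, mrow;
  std::vector<Sched> sched;
  // per-tree scratch reused across trees (no per-tree allocation)
  std::vector<int> kids;      // 2 entries per node
  std::vector<int> stack;
  std::vector<double> cum;
};

// A per-tree event budget guards against prior corners with extreme
// migration (expected event counts in the millions).  On overflow the
// migration-connected active demes are collapsed into one panmictic deme
// with the pooled size: the strong-migration limit of the structured
// coalescent.
static const long EVENT_BUDGET = 800;

void simulate_tree(const ModelC& mc, const std::vector<int>& samp, Tree& tr,
                   SimWS& ws, FastRNG& rng) {
  const int D = mc.D;
  int n = 0; for (int d = 0; d < D; ++d) n += samp[d];
  tr.n = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);

  if ((int)ws.pool.size() != D) ws.pool.assign(D, {});
  for (int d = 0; d < D; ++d) ws.pool[d].clear();
  int id = 0;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < samp[d]; ++k) ws.pool[d].push_back(id++);
  ws.active.assign(D, true);
  ws.N = mc.N0;
  ws.inv2N.resize(D);
  for (int d = 0; d < D; ++d) ws.inv2N[d] = 0.5 / ws.N[d];
  ws.coal.assign(D, 0.0);
  ws.migd.assign(D, 0.0);
  ws.mrow.assign(D, 0.0);
  std::vector<int> redir(D);
  for (int d = 0; d < D; ++d) redir[d] = d;
  auto resolve = [&](int d) {
    while (!ws.active[d] && redir[d] != d) d = redir[d];
    return d;
  };

  if (ws.sched.empty()) {
    for (size_t i = 0; i < mc.splits.size(); ++i)
      ws.sched.push_back({mc.splits[i].t, EV_SPLIT, (int)i});
    for (size_t i = 0; i < mc.pulses.size(); ++i)
      ws.sched.push_back({mc.pulses[i].t, EV_PULSE, (int)i});
    ws.sched.push_back({R_PosInf, EV_MIGOFF, 0});  // sentinel
    if (mc.has_mig && R_finite(mc.mig_end))
      ws.sched.push_back({mc.mig_end, EV_MIGOFF, 0});
    std::sort(ws.sched.begin(), ws.sched.end(),
              [](const Sched& a, const Sched& b) { return a.t < b.t; });
  }

  bool mig_alive = mc.has_mig;
  // migration row sums over active destinations
  auto refresh_mrow = [&]() {
    for (int d = 0; d < D; ++d) {
      double s = 0.0;
      if (mig_alive && ws.active[d])
        for (int j = 0; j < D; ++j)
          if (j != d && ws.active[j]) s += mc.mig[d * D + j];
      ws.mrow[d] = s;
    }
  };
  refresh_mrow();

  double t = 0.0;
  size_t ev = 0;
  int nlive = n;
  int next_node = n;
  long events = 0;

  while (nlive > 1) {
    double coal_tot = 0.0, mig_tot = 0.0;
    bool mig_on = mig_alive && t < mc.mig_end;
    for (int d = 0; d < D; ++d) {
      if (!ws.active[d]) { ws.coal[d] = ws.migd[d] = 0.0; continue; }
      double k = (double)ws.pool[d].size();
      ws.coal[d] = k * (k - 1.0) * 0.5 * ws.inv2N[d];
      coal_tot += ws.coal[d];
      ws.migd[d] = mig_on ? k * ws.mrow[d] : 0.0;
      mig_tot += ws.migd[d];
    }
    double tot = coal_tot + mig_tot;
    double tnext = (ev < ws.sched.size()) ? ws.sched[ev].t : R_PosInf;
    double dt = (tot > 0) ? rng.e() / tot : R_PosInf;
    if (t + dt >= tnext) {
      if (!R_finite(tnext))
        stop("non-coalescing configuration: isolated demes are never joined");
      t = tnext;
      const Sched& s = ws.sched[ev++];
      if (s.type == EV_SPLIT) {
        const SplitEv& e = mc.splits[s.idx];
        int anc = resolve(e.ancestral);
        for (int v : ws.pool[e.derived]) ws.pool[anc].push_back(v);
        ws.pool[e.derived].clear();
        ws.active[e.derived] = false;
        redir[e.derived] = anc;
        if (e.newsize > 0) { ws.N[anc] = e.newsize; ws.inv2N[anc] = 0.5 / e.newsize; }
        refresh_mrow();
      } else if (s.type == EV_PULSE) {
        const PulseEv& e = mc.pulses[s.idx];
        if (ws.active[e.deme] && ws.active[e.source]) {
          std::vector<int>& from = ws.pool[e.deme];
          for (int k = (int)from.size() - 1; k >= 0; --k) {
            if (rng.u() < e.prob) {
              ws.pool[e.source].push_back(from[k]);
              from[k] = from.back(); from.pop_back();
            }
          }
        }
      } // EV_MIGOFF: nothing, the t < mig_end test handles it
      continue;
    }
    t += dt;
    if (++events > EVENT_BUDGET && mig_on) {
      // strong-migration collapse: pool migration-connected active demes
      int tgt = -1;
      for (int d = 0; d < D; ++d)
        if (ws.active[d] && ws.mrow[d] > 0) { tgt = d; break; }
      if (tgt >= 0) {
        double Nsum = ws.N[tgt];
        for (int d = tgt + 1; d < D; ++d) {
          if (!ws.active[d] || ws.mrow[d] <= 0) continue;
          for (int v : ws.pool[d]) ws.pool[tgt].push_back(v);
          ws.pool[d].clear();
          ws.active[d] = false;
          redir[d] = tgt;
          Nsum += ws.N[d];
        }
        ws.N[tgt] = Nsum;
        ws.inv2N[tgt] = 0.5 / Nsum;
        mig_alive = false;
        refresh_mrow();
        continue;
      }
    }
    double u = rng.u() * tot;
    if (u < coal_tot) {
      int d = 0; double acc = 0.0;
      for (; d < D; ++d) { acc += ws.coal[d]; if (u < acc) break; }
      if (d >= D) d = D - 1;
      std::vector<int>& pl = ws.pool[d];
      int i = (int)(rng.u() * pl.size());
      int j = (int)(rng.u() * (pl.size() - 1));
      if (j >= i) ++j;
      int a = pl[i], b = pl[j];
      int nn = next_node++;
      tr.parent[a] = nn; tr.parent[b] = nn; tr.time[nn] = t;
      if (i > j) std::swap(i, j);
      pl[j] = pl.back(); pl.pop_back();
      pl[i] = nn;  // i < j, so index i is still valid after the pop
      --nlive;
    } else {
      u -= coal_tot;
      int d = 0; double acc = 0.0;
      for (; d < D; ++d) { acc += ws.migd[d]; if (u < acc) break; }
      if (d >= D) d = D - 1;
      double v = rng.u() * ws.mrow[d]; int dest = -1; acc = 0.0;
      for (int j = 0; j < D; ++j) {
        if (j == d || !ws.active[j]) continue;
        acc += mc.mig[d * D + j];
        if (v < acc) { dest = j; break; }
      }
      if (dest < 0) continue;
      std::vector<int>& pl = ws.pool[d];
      int i = (int)(rng.u() * pl.size());
      ws.pool[dest].push_back(pl[i]);
      pl[i] = pl.back(); pl.pop_back();
    }
  }
}

// per-deme leaf counts below node v (flat child array, shared stack)
void count_leaves(const Tree& tr, SimWS& ws, int v,
                  const std::vector<int>& leaf_deme, int D,
                  std::vector<int>& out) {
  std::fill(out.begin(), out.end(), 0);
  ws.stack.clear();
  ws.stack.push_back(v);
  while (!ws.stack.empty()) {
    int x = ws.stack.back(); ws.stack.pop_back();
    if (x < tr.n) out[leaf_deme[x]]++;
    else {
      ws.stack.push_back(ws.kids[2 * x]);
      ws.stack.push_back(ws.kids[2 * x + 1]);
    }
  }
}

void leaf_set(const Tree& tr, SimWS& ws, int v, std::vector<int>& out) {
  out.clear();
  ws.stack.clear();
  ws.stack.push_back(v);
  while (!ws.stack.empty()) {
    int x = ws.stack.back(); ws.stack.pop_back();
    if (x < tr.n) out.push_back(x);
    else {
      ws.stack.push_back(ws.kids[2 * x]);
      ws.stack.push_back(ws.kids[2 * x + 1]);
    }
  }
}

void build_kids(const Tree& tr, SimWS& ws) {
  int nn = 2 * tr.n - 1;
  if ((int)ws.kids.size() < 2 * nn) ws.kids.assign(2 * nn, -1);
  std::vector<int> cnt(nn, 0);
  for (int v = 0; v < 2 * tr.n - 2; ++v) {
    int p = tr.parent[v];
    if (p >= 0) ws.kids[2 * p + cnt[p]++] = v;
  }
}

// sample a branch (= non-root node) proportional to its length
int sample_branch(const Tree& tr, SimWS& ws, double& total_len) {
  int m = 2 * tr.n - 2;  // root excluded
  ws.cum.resize(m);
  double s = 0.0;
  for (int v = 0; v < m; ++v) {
    s += tr.time[tr.parent[v]] - tr.time[v];
    ws.cum[v] = s;
  }
  total_len = s;
  double u = unif_rand() * s;
  return (int)(std::lower_bound(ws.cum.begin(), ws.cum.end(), u) -
               ws.cum.begin());
}

std::vector<int> leaf_demes(const std::vector<int>& samp) {
  std::vector<int> ld;
  for (size_t d = 0; d < samp.size(); ++d)
    for (int k = 0; k < samp[d]; ++k) ld.push_back((int)d);
  return ld;
}

} // namespace

// [[Rcpp::export]]
NumericVector sim_tmrca_cpp(List model, IntegerVector samples, int n_reps) {
  ModelC mc = parse_model(model);
  std::vector<int> samp(samples.begin(), samples.end());
  NumericVector out(n_reps);
  Tree tr;
  SimWS ws;
  FastRNG rng;
  for (int r = 0; r < n_reps; ++r) {
    simulate_tree(mc, samp, tr, ws, rng);
    out[r] = tr.time[2 * tr.n - 2];
  }
  return out;
}

namespace {

double total_length(const Tree& tr) {
  double tl = 0.0;
  for (int v = 0; v < 2 * tr.n - 2; ++v)
    tl += tr.time[tr.parent[v]] - tr.time[v];
  return tl;
}

// Mutation rate per unit branch length calibrated so ~1 SNP arises per
// genealogy: segregating sites sampled this way follow the infinite-sites
// process (trees contribute in proportion to their total branch length,
// which a fixed one-mutation-per-tree scheme would not honour).
double calibrate_rate(const ModelC& mc, const std::vector<int>& samp,
                      SimWS& ws, FastRNG& rng) {
  Tree tr;
  double s = 0.0;
  const int warm = 100;
  for (int i = 0; i < warm; ++i) {
    simulate_tree(mc, samp, tr, ws, rng);
    s += total_length(tr);
  }
  return warm / s;
}

} // namespace

// Independent segregating sites: derived-allele counts per deme.
// [[Rcpp::export]]
IntegerMatrix sim_snp_counts_cpp(List model, IntegerVector samples,
                                 int n_snps) {
  ModelC mc = parse_model(model);
  std::vector<int> samp(samples.begin(), samples.end());
  const int D = mc.D;
  IntegerMatrix out(n_snps, D);
  std::vector<int> ld = leaf_demes(samp), cnt(D);
  Tree tr;
  SimWS ws;
  FastRNG rng;
  double rate = calibrate_rate(mc, samp, ws, rng);
  int s = 0;
  long guard = 0, guard_max = 1000L * n_snps + 1000L;
  while (s < n_snps) {
    if (++guard > guard_max) stop("mutation sampling failed to progress");
    simulate_tree(mc, samp, tr, ws, rng);
    int nmut = (int)R::rpois(rate * total_length(tr));
    if (nmut == 0) continue;
    build_kids(tr, ws);
    for (int m = 0; m < nmut && s < n_snps; ++m) {
      double tl;
      int v = sample_branch(tr, ws, tl);
      count_leaves(tr, ws, v, ld, D, cnt);
      for (int d = 0; d < D; ++d) out(s, d) = cnt[d];
      ++s;
    }
  }
  return out;
}

// Expected joint SFS by branch-length accumulation: every branch of
// every simulated genealogy contributes its length to the cell indexed
// by its subtree's per-deme leaf counts.  This is the Rao-Blackwellized
// (zero mutation-sampling noise) estimator of the spectrum produced by
// dropping mutations on the same genealogies.
// [[Rcpp::export]]
NumericVector sim_expected_sfs_cpp(List model, IntegerVector samples,
                                   int n_trees) {
  ModelC mc = parse_model(model);
  std::vector<int> samp(samples.begin(), samples.end());
  const int D = mc.D;
  std::vector<int> dims(D), mult(D);
  int total = 1;
  for (int d = 0; d < D; ++d) {
    dims[d] = samp[d] + 1;
    mult[d] = total;
    total *= dims[d];
  }
  NumericVector out(total);
  std::vector<int> ld = leaf_demes(samp);
  Tree tr;
  SimWS ws;
  FastRNG rng;
  int n = 0; for (int v : samp) n += v;
  int nn = 2 * n - 1;
  std::vector<int> cellIdx(nn);
  for (int t = 0; t < n_trees; ++t) {
    simulate_tree(mc, samp, tr, ws, rng);
    build_kids(tr, ws);
    // the cell index is linear in the subtree leaf counts, so it can be
    // accumulated directly; node indices are created in coalescence-time
    // order, so children precede parents
    for (int v = 0; v < nn; ++v)
      cellIdx[v] = (v < n) ? mult[ld[v]]
        : cellIdx[ws.kids[2 * v]] + cellIdx[ws.kids[2 * v + 1]];
    for (int v = 0; v < nn - 1; ++v)   // root excluded
      out[cellIdx[v]] += tr.time[tr.parent[v]] - tr.time[v];
  }
  return out;
}

// Independent segregating sites tabulated directly into the joint SFS
// (same sampling scheme as sim_snp_counts_cpp).
// [[Rcpp::export]]
IntegerVector sim_sfs_cpp(List model, IntegerVector samples, int n_snps) {
  ModelC mc = parse_model(model);
  std::vector<int> samp(samples.begin(), samples.end());
  const int D = mc.D;
  std::vector<int> dims(D), mult(D);
  int total = 1;
  for (int d = 0; d < D; ++d) {
    dims[d] = samp[d] + 1;
    mult[d] = total;
    total *= dims[d];
  }
  IntegerVector out(total);
  std::vector<int> ld = leaf_demes(samp), cnt(D);
  Tree tr;
  SimWS ws;
  FastRNG rng;
  double rate = calibrate_rate(mc, samp, ws, rng);
  int s = 0;
  long guard = 0, guard_max = 1000L * n_snps + 1000L;
  while (s < n_snps) {
    if (++guard > guard_max) stop("mutation sampling failed to progress");
    simulate_tree(mc, samp, tr, ws, rng);
    int nmut = (int)R::rpois(rate * total_length(tr));
    if (nmut == 0) continue;
    build_kids(tr, ws);
    for (int m = 0; m < nmut && s < n_snps; ++m) {
      double tl;
      int v = sample_branch(tr, ws, tl);
      count_leaves(tr, ws, v, ld, D, cnt);
      int lin = 0;
      for (int d = 0; d < D; ++d) lin += cnt[d] * mult[d];
      out[lin]++;
      ++s;
    }
  }
  return out;
}

// Independent segregating sites: 0/1 carrier matrix (sites x haplotypes).
// [[Rcpp::export]]
List sim_snp_haplotypes_cpp(List model, IntegerVector samples, int n_snps) {
  ModelC mc = parse_model(model);
  std::vector<int> samp(samples.begin(), samples.end());
  int H = 0; for (int v : samp) H += v;
  IntegerMatrix out(n_snps, H);
  NumericVector tmrca(n_snps);
  Tree tr;
  SimWS ws;
  std::vector<int> carriers;
  FastRNG rng;
  double rate = calibrate_rate(mc, samp, ws, rng);
  int s = 0;
  long guard = 0, guard_max = 1000L * n_snps + 1000L;
  while (s < n_snps) {
    if (++guard > guard_max) stop("mutation sampling failed to progress");
    simulate_tree(mc, samp, tr, ws, rng);
    int nmut = (int)R::rpois(rate * total_length(tr));
    if (nmut == 0) continue;
    build_kids(tr, ws);
    for (int m = 0; m < nmut && s < n_snps; ++m) {
      double tl;
      int v = sample_branch(tr, ws, tl);
      leaf_set(tr, ws, v, carriers);
      for (int c : carriers) out(s, c) = 1;
      tmrca[s] = tr.time[2 * tr.n - 2];
      ++s;
    }
  }
  return List::create(_["genotypes"] = out, _["tmrca"] = tmrca);
}

// Infinite-sites mutation: n_loci independent genealogies, Poisson mutations
// with rate mu per site per generation over locus_bp sites each.
// [[Rcpp::export]]
List sim_seq_haplotypes_cpp(List model, IntegerVector samples, int n_loci,
                            double mu, double locus_bp) {
  ModelC mc = parse_model(model);
  std::vector<int> samp(samples.begin(), samples.end());
  int H = 0; for (int v : samp) H += v;
  std::vector<std::vector<int>> rows;   // carrier lists per site
  std::vector<double> relpos;           // locus index + uniform offset
  NumericVector tmrca(n_loci);
  Tree tr;
  SimWS ws;
  std::vector<int> carriers;
  FastRNG rng;
  for (int l = 0; l < n_loci; ++l) {
    simulate_tree(mc, samp, tr, ws, rng);
    tmrca[l] = tr.time[2 * tr.n - 2];
    build_kids(tr, ws);
    double tl = total_length(tr);
    int nmut = (int)R::rpois(mu * locus_bp * tl);
    for (int m = 0; m < nmut; ++m) {
      double dummy;
      int v = sample_branch(tr, ws, dummy);
      leaf_set(tr, ws, v, carriers);
      rows.push_back(carriers);
      relpos.push_back(l + unif_rand());
    }
  }
  int S = (int)rows.size();
  IntegerMatrix G(S, H);
  NumericVector rp(S);
  for (int s = 0; s < S; ++s) {
    for (int c : rows[s]) G(s, c) = 1;
    rp[s] = relpos[s];
  }
  return List::create(_["genotypes"] = G, _["relpos"] = rp,
                      _["tmrca"] = tmrca);
}
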