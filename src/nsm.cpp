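// Next Sub-volume Method sampler of the reaction-diffusion master equation.
//
// One next-event time per voxel is kept in an indexed binary min-heap; the
// channel within the firing voxel (reaction vs per-species outbound
// diffusion) is chosen by Gillespie's direct method.  Propensity sums of a
// voxel are recomputed only when one of its counts (or the stimulus field)
// changes; unaffected voxels keep their event times, rescaled by the
// old/new propensity ratio in the standard next-reaction-method fashion.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// xoshiro256++: fast, seedable, platform-independent
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t v) {
    uint64_t x = v;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double exp1() { return -std::log(unif()); }
};

struct Heap {  // indexed min-heap over voxels keyed by next event time
  std::vector<int> h, pos;
  std::vector<double> key;
  int n;
  void init(int N) {
    n = N; h.resize(N); pos.resize(N); key.assign(N, R_PosInf);
    for (int i = 0; i < N; ++i) { h[i] = i; pos[i] = i; }
  }
  void swap_at(int a, int b) {
    std::swap(h[a], h[b]); pos[h[a]] = a; pos[h[b]] = b;
  }
  void up(int i) {
    while (i > 0) {
      int p = (i - 1) / 2;
      if (key[h[p]] <= key[h[i]]) break;
      swap_at(i, p); i = p;
    }
  }
  void down(int i) {
    for (;;) {
      int l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && key[h[l]] < key[h[m]]) m = l;
      if (r < n && key[h[r]] < key[h[m]]) m = r;
      if (m == i) break;
      swap_at(i, m); i = m;
    }
  }
  void update(int v, double t) {
    double old = key[v]; key[v] = t;
    if (t < old) up(pos[v]); else down(pos[v]);
  }
  int top() const { return h[0]; }
  double top_key() const { return key[h[0]]; }
};

enum PropType { P_ZEROTH = 0, P_FIRST = 1, P_SECOND = 2, P_SECOND_SELF = 3,
                P_POOL_SECOND = 4, P_STEN_R3 = 5, P_CAT_GATED = 6 };

struct Engine {
  int N, S, R;
  std::vector<int> counts;          // S x N, species-major per voxel: counts[v*S+s]
  std::vector<double> uV;           // one-molecule concentration per voxel (uM)

  // graphs (CSR over voxels); one per localization class
  struct Graph { std::vector<int> ptr, idx; std::vector<double> w, wsum; };
  std::vector<Graph> graphs;
  std::vector<int> sp_graph;        // species -> graph id
  std::vector<double> sp_D;

  // reactions
  std::vector<int> rtype, rs1, rs2, rcamp;
  std::vector<std::vector<double>> rrate;       // per-voxel rate parameter
  std::vector<std::vector<double>> rpool;       // pool totals (pool_second)
  std::vector<std::vector<int>> st_sp;          // stoichiometry
  std::vector<std::vector<int>> st_dl;
  // sten_r3 extras
  double r3_a30 = 0, r3_a3 = 0, r3_a4 = 0;
  int r3_pip2 = -1;
  int rr_mode = -1, rr_sp = -1, rr_g = -1, rr_i = -1;
  std::vector<double> rr_par;

  // stimulus: piecewise-constant cAMP field, uM at node
  std::vector<double> seg_start;
  std::vector<std::vector<double>> seg_conc;    // per segment, length N (empty = 0)
  int cur_seg = -1;
  bool any_camp = false;

  // caches
  std::vector<double> prop;         // R x N: prop[v*R+j]
  std::vector<double> arxn, adif, atot;
  std::vector<double> totals;       // per-species molecule totals
  std::vector<double> rxn_count;    // event counters
  std::vector<double> dif_count;

  Heap heap;
  double t = 0;

  double camp_at(int v) const {
    if (cur_seg < 0 || seg_conc[cur_seg].empty()) return 0.0;
    return seg_conc[cur_seg][v];
  }

  double rr_conc(int v) const {
    switch (rr_mode) {
      case 0: return uV[v] * counts[v * S + rr_sp];
      case 1: {
        double g = uV[v] * counts[v * S + rr_g];
        double i = uV[v] * counts[v * S + rr_i];
        double x = rr_par[0] + rr_par[1] * (g - rr_par[2] * i);
        return x > 0 ? x : 0.0;
      }
      case 2: {
        double g = uV[v] * counts[v * S + rr_g];
        double i = uV[v] * counts[v * S + rr_i];
        return rr_par[0] * (rr_par[1] + g) / (rr_par[2] + i);
      }
      default: return 0.0;
    }
  }

  double propensity(int j, int v) const {
    double k = rrate[j][v];
    if (k == 0) return 0.0;
    if (rcamp[j]) {
      k *= camp_at(v);
      if (k == 0) return 0.0;
    }
    const int* c = &counts[v * S];
    switch (rtype[j]) {
      case P_ZEROTH: return k;
      case P_FIRST:  return k * c[rs1[j]];
      case P_SECOND: return k * c[rs1[j]] * (double)c[rs2[j]];
      case P_SECOND_SELF: {
        double n = c[rs1[j]];
        return k * n * (n - 1);
      }
      case P_POOL_SECOND: {
        double pool = rpool[j][v] - c[rs1[j]];
        if (pool < 0) pool = 0;
        return k * pool * c[rs2[j]];
      }
      case P_CAT_GATED:
        return c[rs2[j]] >= 1 ? k * c[rs1[j]] : 0.0;
      case P_STEN_R3: {
        double num = r3_a30 + r3_a3 * rr_conc(v);
        double p2 = c[r3_pip2];
        double den = r3_a4 * r3_a4 * uV[v] * uV[v] * p2 * (p2 - 1) + 1.0;
        return k * num / den * c[rs1[j]];
      }
    }
    return 0.0;
  }

  void refresh_voxel(int v) {
    double ar = 0;
    if (R > 0) {
      double* pv = &prop[(size_t)v * R];
      for (int j = 0; j < R; ++j) { pv[j] = propensity(j, v); ar += pv[j]; }
    }
    double ad = 0;
    const int* c = &counts[v * S];
    for (int s = 0; s < S; ++s) {
      double D = sp_D[s];
      if (D > 0 && c[s] > 0) ad += D * graphs[sp_graph[s]].wsum[v] * c[s];
    }
    arxn[v] = ar; adif[v] = ad; atot[v] = ar + ad;
    if (!(atot[v] >= 0) || !std::isfinite(atot[v]))
      stop("propensity overflow/NaN in voxel %d at t=%g", v + 1, t);
  }

  void reschedule(int v, Rng& rng) {  // fresh exponential (voxel that fired)
    heap.update(v, atot[v] > 0 ? t + rng.exp1() / atot[v] : R_PosInf);
  }
  void rescale(int v, double a_old, Rng& rng) {  // affected neighbour
    double tn;
    double tv = heap.key[v];
    if (a_old > 0 && std::isfinite(tv))
      tn = atot[v] > 0 ? t + (a_old / atot[v]) * (tv - t) : R_PosInf;
    else
      tn = atot[v] > 0 ? t + rng.exp1() / atot[v] : R_PosInf;
    heap.update(v, tn);
  }

  void apply_stoich(int j, int v) {
    int* c = &counts[v * S];
    const std::vector<int>& sp = st_sp[j];
    const std::vector<int>& dl = st_dl[j];
    for (size_t q = 0; q < sp.size(); ++q) {
      c[sp[q]] += dl[q];
      totals[sp[q]] += dl[q];
      if (c[sp[q]] < 0)
        stop("internal consistency error: negative count (species %d, voxel %d, t=%g)",
             sp[q] + 1, v + 1, t);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".nsm_run")]]
List nsm_run(List prep, IntegerMatrix init, double t0, double t_end,
             double seed, NumericVector rec_times, IntegerVector rec_species) {
  Engine E;
  E.S = init.nrow();
  E.N = init.ncol();
  E.uV = as<std::vector<double>>(prep["uV"]);

  // counts, voxel-major
  E.counts.resize((size_t)E.N * E.S);
  E.totals.assign(E.S, 0.0);
  for (int v = 0; v < E.N; ++v)
    for (int s = 0; s < E.S; ++s) {
      int c = init(s, v);
      if (c < 0) stop("negative initial count");
      E.counts[(size_t)v * E.S + s] = c;
      E.totals[s] += c;
    }

  List gl = prep["graphs"];
  for (int g = 0; g < gl.size(); ++g) {
    List G = gl[g];
    Engine::Graph gg;
    gg.ptr = as<std::vector<int>>(G["ptr"]);
    gg.idx = as<std::vector<int>>(G["idx"]);   // 0-based
    gg.w = as<std::vector<double>>(G["w"]);
    gg.wsum = as<std::vector<double>>(G["wsum"]);
    E.graphs.push_back(gg);
  }
  E.sp_graph = as<std::vector<int>>(prep["sp_graph"]);
  E.sp_D = as<std::vector<double>>(prep["sp_D"]);

  List rl = prep["reactions"];
  E.R = rl.size();
  for (int j = 0; j < E.R; ++j) {
    List rj = rl[j];
    E.rtype.push_back(as<int>(rj["type"]));
    E.rs1.push_back(as<int>(rj["s1"]));
    E.rs2.push_back(as<int>(rj["s2"]));
    E.rcamp.push_back(as<int>(rj["camp"]));
    E.rrate.push_back(as<std::vector<double>>(rj["rate"]));
    if (rj.containsElementNamed("pool") && !Rf_isNull(rj["pool"]))
      E.rpool.push_back(as<std::vector<double>>(rj["pool"]));
    else
      E.rpool.push_back(std::vector<double>());
    E.st_sp.push_back(as<std::vector<int>>(rj["st_sp"]));
    E.st_dl.push_back(as<std::vector<int>>(rj["st_dl"]));
    if (E.rtype[j] == P_STEN_R3) {
      E.r3_a30 = as<double>(rj["a30"]);
      E.r3_a3 = as<double>(rj["a3"]);
      E.r3_a4 = as<double>(rj["a4"]);
      E.r3_pip2 = as<int>(rj["pip2"]);
    }
  }
  if (prep.containsElementNamed("rr") && !Rf_isNull(prep["rr"])) {
    List rr = prep["rr"];
    E.rr_mode = as<int>(rr["mode"]);
    E.rr_sp = as<int>(rr["sp"]);
    E.rr_g = as<int>(rr["g"]);
    E.rr_i = as<int>(rr["i"]);
    E.rr_par = as<std::vector<double>>(rr["par"]);
  }

  if (prep.containsElementNamed("stim") && !Rf_isNull(prep["stim"])) {
    List st = prep["stim"];
    E.seg_start = as<std::vector<double>>(st["start"]);
    List sc = st["conc"];
    for (int q = 0; q < sc.size(); ++q)
      E.seg_conc.push_back(as<std::vector<double>>(sc[q]));
    for (int j = 0; j < E.R; ++j) if (E.rcamp[j]) E.any_camp = true;
  }
  // initial stimulus segment
  E.cur_seg = -1;
  size_t nseg = E.seg_start.size();
  for (size_t q = 0; q < nseg; ++q)
    if (E.seg_start[q] <= t0 + 1e-12) E.cur_seg = q;

  E.t = t0;
  E.prop.assign((size_t)E.N * E.R, 0.0);
  E.arxn.assign(E.N, 0.0); E.adif.assign(E.N, 0.0); E.atot.assign(E.N, 0.0);
  E.rxn_count.assign(E.R, 0.0);
  E.dif_count.assign(E.S, 0.0);

  Rng rng((uint64_t)(seed >= 0 ? seed : -seed) + 0x2545F4914F6CDD1DULL);
  E.heap.init(E.N);
  for (int v = 0; v < E.N; ++v) {
    E.refresh_voxel(v);
    E.heap.key[v] = E.atot[v] > 0 ? t0 + rng.exp1() / E.atot[v] : R_PosInf;
  }
  for (int v = E.N / 2 - 1; v >= 0; --v) E.heap.down(v);

  // outputs
  int T = rec_times.size();
  int K = rec_species.size();
  NumericMatrix wc(E.S, T);
  IntegerVector node_rec((R_xlen_t)K * E.N * T);
  int next_rec = 0;

  auto emit = [&](int ti) {
    for (int s = 0; s < E.S; ++s) wc(s, ti) = E.totals[s];
    for (int k = 0; k < K; ++k) {
      int s = rec_species[k];
      R_xlen_t off = ((R_xlen_t)ti * K + k) * E.N;
      for (int v = 0; v < E.N; ++v)
        node_rec[off + v] = E.counts[(size_t)v * E.S + s];
    }
  };

  double n_events = 0;
  for (;;) {
    double tnext = E.heap.top_key();
    double tcamp = R_PosInf;
    if (E.cur_seg + 1 < (int)nseg) tcamp = E.seg_start[E.cur_seg + 1];

    double tstop = std::min(std::min(tnext, tcamp), t_end);
    while (next_rec < T && rec_times[next_rec] <= tstop + 1e-12) {
      emit(next_rec); ++next_rec;
    }
    if (tnext >= t_end && tcamp >= t_end) break;

    if (tcamp < tnext) {  // stimulus changepoint: refresh cAMP-dependent voxels
      E.t = tcamp;
      E.cur_seg += 1;
      if (E.any_camp) {
        for (int v = 0; v < E.N; ++v) {
          double a_old = E.atot[v];
          E.refresh_voxel(v);
          if (E.atot[v] != a_old) E.rescale(v, a_old, rng);
        }
      }
      continue;
    }

    int v = E.heap.top();
    E.t = tnext;
    n_events += 1;

    double u = rng.unif() * E.atot[v];
    if (u < E.arxn[v]) {
      // reaction channel
      double acc = 0; int j = -1, last_pos = -1;
      for (int q = 0; q < E.R; ++q) {
        double pq = E.prop[(size_t)v * E.R + q];
        if (pq <= 0) continue;
        last_pos = q; acc += pq;
        if (u <= acc) { j = q; break; }
      }
      if (j < 0) j = last_pos;            // float rounding at the boundary
      if (j < 0) { E.refresh_voxel(v); E.reschedule(v, rng); continue; }
      E.apply_stoich(j, v);
      E.rxn_count[j] += 1;
      E.refresh_voxel(v);
      E.reschedule(v, rng);
    } else {
      // diffusion channel: pick species, then destination
      u -= E.arxn[v];
      int* c = &E.counts[(size_t)v * E.S];
      int s = -1; double as = 0;
      for (int q = 0; q < E.S; ++q) {
        if (E.sp_D[q] <= 0 || c[q] == 0) continue;
        as = E.sp_D[q] * E.graphs[E.sp_graph[q]].wsum[v] * c[q];
        if (u <= as || q == E.S - 1) { s = q; break; }
        u -= as;
      }
      if (s < 0 || c[s] == 0) { E.refresh_voxel(v); E.reschedule(v, rng); continue; }
      const Engine::Graph& G = E.graphs[E.sp_graph[s]];
      double target = (u / as) * G.wsum[v];
      int dest = -1; double acc = 0;
      for (int p = G.ptr[v]; p < G.ptr[v + 1]; ++p) {
        acc += G.w[p];
        if (target <= acc || p == G.ptr[v + 1] - 1) { dest = G.idx[p]; break; }
      }
      if (dest < 0) { E.refresh_voxel(v); E.reschedule(v, rng); continue; }
      c[s] -= 1;
      E.counts[(size_t)dest * E.S + s] += 1;
      E.dif_count[s] += 1;
      E.refresh_voxel(v);
      E.reschedule(v, rng);
      double a_old = E.atot[dest];
      E.refresh_voxel(dest);
      E.rescale(dest, a_old, rng);
    }
  }

  // final counts back to S x N
  IntegerMatrix fin(E.S, E.N);
  for (int v = 0; v < E.N; ++v)
    for (int s = 0; s < E.S; ++s) fin(s, v) = E.counts[(size_t)v * E.S + s];

  return List::create(
    _["wc"] = wc, _["node_rec"] = node_rec, _["final"] = fin,
    _["n_events"] = n_events,
    _["rxn_count"] = NumericVector(E.rxn_count.begin(), E.rxn_count.end()),
    _["dif_count"] = NumericVector(E.dif_count.begin(), E.dif_count.end()));
}
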