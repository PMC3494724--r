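// Exact SSA engines: Direct Method, Optimized Direct Method, and the
// blocked-partial-sum variant with three-level hierarchical selection.
// All three share one stepping loop and one RNG contract: exactly two
// uniforms per step, z1 (selection) then z2 (waiting time), both in (0,1].

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG (PCG32)

struct Pcg32 {
  uint64_t state;
  uint64_t inc;

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  // One stream per trajectory: (seed, stream) fully determines the sequence.
  Pcg32(uint64_t seed, uint64_t stream) {
    uint64_t mix = seed;
    uint64_t initstate = splitmix64(mix);
    mix ^= 0x632BE59BD9B4E019ULL * (stream + 1);
    uint64_t initseq = splitmix64(mix);
    state = 0u;
    inc = (initseq << 1u) | 1u;
    next();
    state += initstate;
    next();
  }

  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }

  // Uniform on (0, 1]: excludes 0 (log singularity / zero selection target).
  double u01() {
    return (static_cast<double>(next()) + 1.0) * (1.0 / 4294967296.0);
  }
};

// [[Rcpp::export]]
NumericVector cpp_rng_uniforms(int seed, int stream, int n, int skip = 0) {
  Pcg32 rng((uint64_t)(uint32_t)seed, (uint64_t)(uint32_t)stream);
  for (int i = 0; i < skip; ++i) rng.next();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.u01();
  return out;
}

// ------------------------------------------------------------------ the model

struct Model {
  int M, N;
  std::vector<int> rtype;     // 1, 2, 3
  std::vector<int> re1, re2;  // 0-based reactant indices; re2 = -1 if absent
  std::vector<double> k;
  std::vector<int> st_sp;     // 4*M, species index or -1
  std::vector<int> st_d;      // 4*M, delta in {-2,-1,+1,+2}
  std::vector<double> x0;     // initial counts

  explicit Model(const List &m) {
    M = as<int>(m["M"]);
    N = as<int>(m["N"]);
    rtype = as<std::vector<int> >(m["rtype"]);
    re1 = as<std::vector<int> >(m["re1"]);
    re2 = as<std::vector<int> >(m["re2"]);
    k = as<std::vector<double> >(m["k"]);
    st_sp = as<std::vector<int> >(m["st_sp"]);
    st_d = as<std::vector<int> >(m["st_d"]);
    x0 = as<std::vector<double> >(m["x0"]);
    if ((int)rtype.size() != M || (int)st_sp.size() != 4 * M)
      stop("malformed engine model");
  }

  double propensity(int j, const std::vector<double> &x) const {
    switch (rtype[j]) {
    case 1:
      return k[j] * x[re1[j]];
    case 2:
      return k[j] * x[re1[j]] * x[re2[j]];
    case 3: {
      double s = x[re1[j]];
      return k[j] * s * (s - 1.0) * 0.5;
    }
    default:
      stop("unknown reaction type");
    }
    return 0.0; // not reached
  }

  void apply(int j, std::vector<double> &x) const {
    for (int q = 0; q < 4; ++q) {
      int sp = st_sp[4 * j + q];
      if (sp < 0) break;
      x[sp] += st_d[4 * j + q];
      if (x[sp] < 0)
        stop("internal-consistency error: species count went negative "
             "(reaction %d fired with insufficient reactants)", j + 1);
    }
  }
};

struct Graph {
  std::vector<int> ptr; // M + 1
  std::vector<int> idx; // dependents, ascending (= block-sorted)
  explicit Graph(const List &g) {
    ptr = as<std::vector<int> >(g["dep_ptr"]);
    idx = as<std::vector<int> >(g["dep_idx"]);
  }
};

struct Partition {
  int p, b, chunk, lane;
  explicit Partition(const List &pp) {
    p = as<int>(pp["num_blocks"]);
    b = as<int>(pp["block_size"]);
    chunk = as<int>(pp["chunk_size"]);
    lane = as<int>(pp["lane_width"]);
  }
};

// Chunk sum in the lane-strided reduction order: lane j accumulates elements
// j, j+lane, j+2*lane, ...; lane partials are then combined in lane order.
// Both the R and the C++ selection paths use this exact order.
static double chunk_sum_strided(const double *a, int n, int lane,
                                long long *touch) {
  double lanes[256];
  int L = lane;
  if (L > 256) L = 256;
  for (int j = 0; j < L; ++j) lanes[j] = 0.0;
  for (int i = 0; i < n; ++i) lanes[i % L] += a[i];
  double s = 0.0;
  for (int j = 0; j < L; ++j) s += lanes[j];
  if (touch) *touch += n;
  return s;
}

// ------------------------------------------------------------- engine state

struct Engine {
  const Model &mod;
  const Graph &gr;
  Partition part;
  int method; // 0 = direct, 1 = odm, 2 = blocked
  long long refresh_interval;
  int dense_update_threshold;

  std::vector<double> x;    // species counts
  std::vector<double> a;    // propensities
  std::vector<double> cum;  // cumulative block sums (blocked)
  std::vector<double> dblk; // per-block delta scratch (blocked)
  double aR;
  long long steps_since_refresh;
  long long n_refresh;
  long long sel_touch, upd_touch;
  bool dense_path;

  Engine(const Model &m, const Graph &g, const Partition &pp, int meth,
         long long refresh_iv, int dense_thr)
      : mod(m), gr(g), part(pp), method(meth), refresh_interval(refresh_iv),
        dense_update_threshold(dense_thr), aR(0.0), steps_since_refresh(0),
        n_refresh(0), sel_touch(0), upd_touch(0), dense_path(false) {
    x = mod.x0;
    a.assign(mod.M, 0.0);
    cum.assign(part.p, 0.0);
    dblk.assign(part.p, 0.0);
    // Mean dependents per block selects the scheduling path (one lane per
    // block vs a full lane group per block). Both paths accumulate per-block
    // deltas in ascending dependent order, so results are bitwise identical;
    // only the work scheduling label differs.
    double mean_deps = mod.M > 0 ? (double)gr.idx.size() / mod.M : 0.0;
    dense_path = mean_deps / std::max(1, part.p) >=
                 (double)dense_update_threshold;
    refresh();
  }

  int block_of(int j) const { return j / part.b; }

  int block_end(int l) const {
    int e = (l + 1) * part.b;
    return e < mod.M ? e : mod.M;
  }

  // recompute all propensities and block sums from scratch
  void refresh() {
    for (int j = 0; j < mod.M; ++j) a[j] = mod.propensity(j, x);
    double run = 0.0;
    for (int l = 0; l < part.p; ++l) {
      double bs = 0.0;
      int lo = l * part.b, hi = block_end(l);
      for (int j = lo; j < hi; ++j) bs += a[j];
      run += bs;
      cum[l] = run;
    }
    aR = part.p > 0 ? cum[part.p - 1] : 0.0;
    if (method != 2) { // serial methods keep a plain running total
      double s = 0.0;
      for (int j = 0; j < mod.M; ++j) s += a[j];
      aR = s;
    }
    steps_since_refresh = 0;
    ++n_refresh;
  }

  // Direct Method: full recompute + linear cumulative scan.
  int select_direct(double z1) {
    double s = 0.0;
    for (int j = 0; j < mod.M; ++j) {
      a[j] = mod.propensity(j, x);
      s += a[j];
    }
    aR = s;
    if (aR <= 0.0) return -1;
    double target = z1 * aR;
    double c = 0.0;
    int last_pos = -1;
    for (int j = 0; j < mod.M; ++j) {
      c += a[j];
      if (a[j] > 0.0) last_pos = j;
      ++sel_touch;
      if (c >= target) return j;
    }
    return last_pos; // fp fallback: target overshot the total by rounding
  }

  // ODM: incremental aR + linear cumulative scan over stored propensities.
  int select_odm(double z1) {
    if (aR <= 0.0) return -1;
    double target = z1 * aR;
    double c = 0.0;
    int last_pos = -1;
    for (int j = 0; j < mod.M; ++j) {
      c += a[j];
      if (a[j] > 0.0) last_pos = j;
      ++sel_touch;
      if (c >= target) return j;
    }
    return last_pos;
  }

  // Blocked: three-level hierarchical search.
  // Level 1: first block whose cumulative sum reaches the target
  // (warp-ballot/ffs realized as first-index-satisfying-predicate).
  // Level 2: chunk scan inside the block via lane-strided reductions.
  // Level 3: prefix scan in batches of lane_width within the chunk.
  int select_blocked(double z1) {
    if (aR <= 0.0) return -1;
    return select_blocked_target(z1 * aR);
  }

  // selection from an explicit target in (0, a_R] (exact at boundaries)
  int select_blocked_target(double target) {
    int l = -1;
    for (int i = 0; i < part.p; ++i) {
      ++sel_touch;
      if (cum[i] >= target) { l = i; break; }
    }
    if (l < 0) l = part.p - 1;
    double residual = target - (l > 0 ? cum[l - 1] : 0.0);
    int lo = l * part.b, hi = block_end(l);
    // level 2: chunks
    double run = 0.0;
    int clo = lo, chi = lo;
    bool found = false;
    for (int cs = lo; cs < hi; cs += part.chunk) {
      int ce = cs + part.chunk < hi ? cs + part.chunk : hi;
      double csum = chunk_sum_strided(&a[cs], ce - cs, part.lane, &sel_touch);
      if (run + csum >= residual) { clo = cs; chi = ce; found = true; break; }
      run += csum;
    }
    if (!found) { // fp edge: take last chunk with positive mass
      for (int j = hi - 1; j >= lo; --j)
        if (a[j] > 0.0) return j;
      return fallback_global();
    }
    // level 3: batches of lane_width within the chunk
    double r2 = residual - run;
    double brun = 0.0;
    for (int bs = clo; bs < chi; bs += part.lane) {
      int be = bs + part.lane < chi ? bs + part.lane : chi;
      double s = brun;
      for (int j = bs; j < be; ++j) {
        s += a[j];
        ++sel_touch;
        if (s >= r2) return j;
      }
      brun = s;
    }
    for (int j = chi - 1; j >= lo; --j) // fp edge within chunk
      if (a[j] > 0.0) return j;
    return fallback_global();
  }

  int fallback_global() {
    for (int j = mod.M - 1; j >= 0; --j)
      if (a[j] > 0.0) return j;
    return -1;
  }

  // Propensity refresh of the fired reaction's dependents, with per-block
  // delta accumulation, prefix sum over blocks, and cumulative-sum update.
  void update_after(int f) {
    int lo = gr.ptr[f], hi = gr.ptr[f + 1];
    if (method == 2) {
      int touched_lo = part.p, touched_hi = -1;
      for (int q = lo; q < hi; ++q) {
        int d = gr.idx[q];
        double old = a[d];
        double nw = mod.propensity(d, x);
        if (nw < 0.0) stop("internal-consistency error: negative propensity");
        a[d] = nw;
        int bl = block_of(d);
        dblk[bl] += nw - old;
        if (bl < touched_lo) touched_lo = bl;
        if (bl > touched_hi) touched_hi = bl;
        ++upd_touch;
      }
      if (touched_hi >= 0) {
        // prefix sum over block deltas, then parallel-style cumulative update
        double run = 0.0;
        for (int i = touched_lo; i < part.p; ++i) {
          run += dblk[i];
          cum[i] += run;
          dblk[i] = 0.0;
          ++upd_touch;
        }
        aR = cum[part.p - 1];
      }
    } else { // odm: incremental total
      for (int q = lo; q < hi; ++q) {
        int d = gr.idx[q];
        double old = a[d];
        double nw = mod.propensity(d, x);
        a[d] = nw;
        aR += nw - old;
        ++upd_touch;
      }
    }
    if (++steps_since_refresh >= refresh_interval) refresh();
  }
};

// --------------------------------------------------------------- trajectories

struct RunResult {
  NumericMatrix grid_counts;
  long long n_steps;
  double t_end;
  std::vector<int> ev_idx;
  std::vector<double> ev_dt;
};

// Linear interpolation of recorded species between bracketing event states.
// interp = 0: linear between bracketing event states (biased low by
// ~E[w]*delta on a jump process -- the inspection-paradox artifact of
// interpolating a piecewise-constant path); interp = 1: hold the pre-event
// state (the unbiased estimator of E[X(t)]).
static void record_interval(const std::vector<double> &xprev,
                            const std::vector<double> &xnew, double tprev,
                            double tnew, const std::vector<int> &rec,
                            NumericMatrix &out, int &gptr, double dt_rec,
                            int G, int interp) {
  while (gptr < G) {
    double tau = gptr * dt_rec;
    if (tau > tnew) break;
    double w;
    if (interp == 1) w = (tau >= tnew) ? 1.0 : 0.0;
    else w = (tnew > tprev) ? (tau - tprev) / (tnew - tprev) : 1.0;
    for (size_t s = 0; s < rec.size(); ++s) {
      double v0 = xprev[rec[s]], v1 = xnew[rec[s]];
      out(gptr, s) = v0 + (v1 - v0) * w;
    }
    ++gptr;
  }
}

static void run_one(Engine &eng, Pcg32 &rng, double t_final, double dt_rec,
                    const std::vector<int> &rec, long long max_steps,
                    int max_events, int interp, RunResult &res) {
  int G = (int)std::floor(t_final / dt_rec + 1e-9) + 1;
  NumericMatrix out(G, (int)rec.size());
  int gptr = 0;
  double t = 0.0;
  std::vector<double> xprev(eng.x); // snapshot at previous event
  // grid point 0 is the initial state
  record_interval(xprev, xprev, 0.0, 0.0, rec, out, gptr, dt_rec, G,
                  interp);
  long long steps = 0;
  while (t < t_final && steps < max_steps) {
    int f;
    double z1, z2;
    if (eng.method == 0) {
      // direct method recomputes propensities before drawing
      z1 = rng.u01();
      f = eng.select_direct(z1);
    } else {
      if (eng.aR <= 0.0) { f = -1; z1 = 0.0; }
      else {
        z1 = rng.u01();
        f = (eng.method == 1) ? eng.select_odm(z1) : eng.select_blocked(z1);
      }
    }
    if (f < 0) break; // a_R = 0: no reaction can fire; hold state to t_final
    z2 = rng.u01();
    double dt = std::log(1.0 / z2) / eng.aR;
    double tnew = t + dt;
    eng.mod.apply(f, eng.x);
    if (eng.method != 0) eng.update_after(f);
    record_interval(xprev, eng.x, t, tnew, rec, out, gptr, dt_rec, G,
                    interp);
    if ((int)res.ev_idx.size() < max_events) {
      res.ev_idx.push_back(f);
      res.ev_dt.push_back(dt);
    }
    xprev = eng.x;
    t = tnew;
    ++steps;
  }
  // a_R hit zero (or step cap): remaining grid points hold the final state
  record_interval(eng.x, eng.x, t, t_final, rec, out, gptr, dt_rec, G,
                  interp);
  while (gptr < G) {
    for (size_t s = 0; s < rec.size(); ++s) out(gptr, s) = eng.x[rec[s]];
    ++gptr;
  }
  res.grid_counts = out;
  res.n_steps = steps;
  res.t_end = t;
}

static int method_code(const std::string &m) {
  if (m == "direct") return 0;
  if (m == "odm") return 1;
  if (m == "blocked") return 2;
  stop("unknown method '%s'", m.c_str());
  return -1;
}

// [[Rcpp::export]]
List cpp_run_trajectory(List model, List graph, List partition,
                        std::string method, double t_final, double record_dt,
                        int seed, int stream, IntegerVector record_species,
                        double refresh_interval, double max_steps,
                        int max_events, int dense_update_threshold,
                        int interpolation_mode) {
  Model mod(model);
  Graph gr(graph);
  Partition part(partition);
  Engine eng(mod, gr, part, method_code(method),
             (long long)refresh_interval, dense_update_threshold);
  Pcg32 rng((uint64_t)(uint32_t)seed, (uint64_t)(uint32_t)stream);
  std::vector<int> rec = as<std::vector<int> >(record_species);
  RunResult res;
  run_one(eng, rng, t_final, record_dt, rec, (long long)max_steps, max_events,
          interpolation_mode, res);
  return List::create(
      _["counts"] = res.grid_counts, _["n_steps"] = (double)res.n_steps,
      _["t_end"] = res.t_end, _["event_index"] = wrap(res.ev_idx),
      _["event_dt"] = wrap(res.ev_dt),
      _["final_counts"] = wrap(eng.x), _["final_propensities"] = wrap(eng.a),
      _["final_block_cumsum"] = wrap(eng.cum), _["a_R"] = eng.aR,
      _["n_refresh"] = (double)eng.n_refresh,
      _["sel_touch"] = (double)eng.sel_touch,
      _["upd_touch"] = (double)eng.upd_touch,
      _["update_path"] = std::string(eng.dense_path ? "dense" : "sparse"));
}

// Ensemble: trajectories are accumulated in stream order so that batched and
// sequential execution give bitwise-identical sums.
// [[Rcpp::export]]
List cpp_run_ensemble(List model, List graph, List partition,
                      std::string method, double t_final, double record_dt,
                      int n_real, int seed, int stream_offset,
                      IntegerVector record_species, double refresh_interval,
                      double max_steps, int dense_update_threshold,
                      int interpolation_mode) {
  Model mod(model);
  Graph gr(graph);
  Partition part(partition);
  std::vector<int> rec = as<std::vector<int> >(record_species);
  int G = (int)std::floor(t_final / record_dt + 1e-9) + 1;
  int S = (int)rec.size();
  NumericMatrix sum(G, S), sumsq(G, S);
  double tot_steps = 0.0;
  int meth = method_code(method);
  for (int r = 0; r < n_real; ++r) {
    Engine eng(mod, gr, part, meth, (long long)refresh_interval,
               dense_update_threshold);
    Pcg32 rng((uint64_t)(uint32_t)seed,
              (uint64_t)(uint32_t)(stream_offset + r));
    RunResult res;
    run_one(eng, rng, t_final, record_dt, rec, (long long)max_steps, 0,
            interpolation_mode, res);
    for (int gi = 0; gi < G; ++gi)
      for (int s = 0; s < S; ++s) {
        double v = res.grid_counts(gi, s);
        sum(gi, s) += v;
        sumsq(gi, s) += v * v;
      }
    tot_steps += (double)res.n_steps;
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq,
                      _["total_steps"] = tot_steps, _["n_real"] = n_real);
}

// Bulk hierarchical selection against a frozen propensity vector: used for
// large randomized equivalence tests and frozen-state distribution tests.
// [[Rcpp::export]]
IntegerVector cpp_select_many(NumericVector propensities, List partition,
                              NumericVector targets) {
  Partition part(partition);
  int M = propensities.size();
  List fake_model = List::create(
      _["M"] = M, _["N"] = 1, _["rtype"] = IntegerVector(M, 1),
      _["re1"] = IntegerVector(M, 0), _["re2"] = IntegerVector(M, -1),
      _["k"] = NumericVector(M, 0.0), _["st_sp"] = IntegerVector(4 * M, -1),
      _["st_d"] = IntegerVector(4 * M, 0),
      _["x0"] = NumericVector(1, 0.0));
  Model mod(fake_model);
  List fake_graph =
      List::create(_["dep_ptr"] = IntegerVector(M + 1, 0),
                   _["dep_idx"] = IntegerVector(0));
  Graph gr(fake_graph);
  Engine eng(mod, gr, part, 2, (long long)1e18, 32);
  // overwrite the engine's propensity state with the supplied vector
  for (int j = 0; j < M; ++j) eng.a[j] = propensities[j];
  double run = 0.0;
  for (int l = 0; l < part.p; ++l) {
    double bs = 0.0;
    int lo = l * part.b, hi = (l + 1) * part.b < M ? (l + 1) * part.b : M;
    for (int j = lo; j < hi; ++j) bs += eng.a[j];
    run += bs;
    eng.cum[l] = run;
  }
  eng.aR = eng.cum[part.p - 1];
  int n = targets.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = eng.select_blocked_target(targets[i]) + 1; // 1-based for R
  return out;
}

// Pre-simulation with the ODM, counting propensity recomputations per
// reaction and molecular-count updates per species.
// [[Rcpp::export]]
List cpp_presim_access(List model, List graph, List partition, double steps,
                       int seed, int stream) {
  Model mod(model);
  Graph gr(graph);
  Partition part(partition);
  Engine eng(mod, gr, part, 1, (long long)1e4, 32);
  Pcg32 rng((uint64_t)(uint32_t)seed, (uint64_t)(uint32_t)stream);
  std::vector<double> racc(mod.M, 0.0), sacc(mod.N, 0.0), psum(mod.M, 0.0);
  long long nstep = 0;
  double t = 0.0;
  while (nstep < (long long)steps && eng.aR > 0.0) {
    double z1 = rng.u01();
    int f = eng.select_odm(z1);
    if (f < 0) break;
    double z2 = rng.u01();
    double dt = std::log(1.0 / z2) / eng.aR;
    // time-averaged propensity (the classical ODM ordering criterion)
    for (int j = 0; j < mod.M; ++j) psum[j] += eng.a[j] * dt;
    t += dt;
    for (int q = 0; q < 4; ++q) {
      int sp = mod.st_sp[4 * f + q];
      if (sp < 0) break;
      sacc[sp] += 1.0;
    }
    eng.mod.apply(f, eng.x);
    for (int q = gr.ptr[f]; q < gr.ptr[f + 1]; ++q) racc[gr.idx[q]] += 1.0;
    eng.update_after(f);
    ++nstep;
  }
  if (t > 0.0)
    for (int j = 0; j < mod.M; ++j) psum[j] /= t;
  return List::create(_["reaction_access"] = wrap(racc),
                      _["species_access"] = wrap(sacc),
                      _["mean_propensity"] = wrap(psum),
                      _["steps"] = (double)nstep);
}
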