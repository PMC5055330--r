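// Simulation engine for the coupled structural-balance / bounded-confidence
// dynamics.  One triad revision per time step; one asynchronous opinion
// revision every M steps (or per-step with rate 6/((N-1)(N-2)) under the
// stochastic schedule).  After the network reaches balance (absorbing for
// the signs), opinions are iterated in full random-order sweeps until the
// largest per-agent change in a sweep drops below tol_fixedpoint.
//
// All randomness is drawn from R's RNG (unif_rand), so a run is fully
// reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

static inline int rand_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static inline double pair_dist(const NumericMatrix& x, int i, int j,
                               int metric, int F) {
  if (F == 1) return std::fabs(x(i, 0) - x(j, 0));
  double acc = 0.0;
  if (metric == 0) {            // chebyshev
    for (int f = 0; f < F; ++f) {
      double d = std::fabs(x(i, f) - x(j, f));
      if (d > acc) acc = d;
    }
    return acc;
  }
  for (int f = 0; f < F; ++f) { // euclidean
    double d = x(i, f) - x(j, f);
    acc += d * d;
  }
  return std::sqrt(acc);
}

// Bounded-confidence revision of agent a: mean over {a} + friends within
// eps (per the configured metric).  Returns max component change.
static double revise_agent(NumericMatrix& x, const IntegerMatrix& S, int a,
                           double eps, int metric, int N, int F,
                           std::vector<double>& buf) {
  int cnt = 1;
  for (int f = 0; f < F; ++f) buf[f] = x(a, f);
  for (int j = 0; j < N; ++j) {
    if (j == a || S(a, j) != 1) continue;
    if (pair_dist(x, a, j, metric, F) <= eps) {
      ++cnt;
      for (int f = 0; f < F; ++f) buf[f] += x(j, f);
    }
  }
  double maxch = 0.0;
  for (int f = 0; f < F; ++f) {
    double nv = buf[f] / cnt;
    double ch = std::fabs(nv - x(a, f));
    if (ch > maxch) maxch = ch;
    x(a, f) = nv;
  }
  return maxch;
}

// Change in the global unbalanced-triad count if link (a,b) were flipped:
// each of the N-2 triads containing the pair toggles its balance.
static int flip_delta(const IntegerMatrix& S, int a, int b, int N) {
  int delta = 0;
  int sab = S(a, b);
  for (int k = 0; k < N; ++k) {
    if (k == a || k == b) continue;
    delta += (sab * S(a, k) * S(b, k) == 1) ? 1 : -1;
  }
  return delta;
}

static void apply_flip(IntegerMatrix& S, int a, int b, int N,
                       long long& u) {
  u += flip_delta(S, a, b, N);
  S(a, b) = -S(a, b);
  S(b, a) = S(a, b);
}

static long long brute_unbalanced(const IntegerMatrix& S, int N) {
  long long u = 0;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j)
      for (int k = j + 1; k < N; ++k)
        if (S(i, j) * S(i, k) * S(j, k) == -1) ++u;
  return u;
}

// Number of single-linkage opinion clusters at tolerance tol (union-find).
static int count_clusters(const NumericMatrix& x, int N, int F, int metric,
                          double tol, std::vector<int>& parent) {
  for (int i = 0; i < N; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j)
      if (pair_dist(x, i, j, metric, F) <= tol) {
        int ra = find(i), rb = find(j);
        if (ra != rb) parent[ra] = rb;
      }
  int n = 0;
  for (int i = 0; i < N; ++i) if (find(i) == i) ++n;
  return n;
}

// [[Rcpp::export]]
List engine_run(IntegerMatrix signs0, NumericMatrix x0,
                double p, double eps, int metric, int flip_rule,
                int M, double max_rounds, double tol_fix, double tol_cluster,
                bool network_frozen, bool record_series, bool record_flips,
                bool stochastic, double opinion_rate,
                int jam_rounds, double max_sweeps, double snapshot_tol) {
  const int N = signs0.nrow();
  const int F = x0.ncol();
  IntegerMatrix S = clone(signs0);
  NumericMatrix x = clone(x0);
  std::vector<double> buf(F);
  std::vector<int> uf(N);

  long long u = network_frozen ? 0 : brute_unbalanced(S, N);
  const long long round_len = (long long)N * (long long)M;
  const double total_triads = (double)N * (N - 1) * (N - 2) / 6.0;
  const double step_cap = max_rounds * (double)round_len;
  const double q_op = std::min(1.0, opinion_rate * 6.0 /
                               ((double)(N - 1) * (N - 2)));

  long long t = 0, rounds = 0;
  double t_balance = (u == 0) ? 0.0 : NA_REAL;
  int termination = -1;   // 0 absorbed, 1 max_rounds, 2 jammed, 3 opinion_cap
  long long last_flip_round = 0;

  // flip-event counters by branch
  long long n_all_neg = 0, n_p_branch = 0, n_break_friend = 0, n_rejected = 0;

  // optional flip log
  std::vector<double> log_t; std::vector<int> log_i, log_j, log_old;
  std::vector<int> log_branch; // 0 smallestD, 1 neg->pos (p), 2 largestD/random pos->neg, 3 rejected

  // per-round series
  std::vector<double> se_round, se_t, se_funbal, se_dplus, se_dminus;
  std::vector<int> se_nop;
  auto push_series = [&](double rnd) {
    double sp = 0.0, sm = 0.0; long long np = 0, nm = 0;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double d = pair_dist(x, i, j, metric, F);
        if (S(i, j) == 1) { sp += d; ++np; } else { sm += d; ++nm; }
      }
    se_round.push_back(rnd);
    se_t.push_back((double)t);
    se_funbal.push_back((double)u / total_triads);
    se_dplus.push_back(np > 0 ? sp / np : NA_REAL);
    se_dminus.push_back(nm > 0 ? sm / nm : NA_REAL);
    se_nop.push_back(count_clusters(x, N, F, metric, tol_cluster, uf));
  };
  if (record_series) push_series(0.0);

  auto log_flip = [&](int a, int b, int branch) {
    if (!record_flips) return;
    log_t.push_back((double)t); log_i.push_back(a + 1); log_j.push_back(b + 1);
    log_old.push_back(branch == 3 ? S(a, b) : -S(a, b));
    log_branch.push_back(branch);
  };

  // ---- phase 1: interleaved triad + opinion revisions until balance ----
  while (u > 0) {
    if ((double)t >= step_cap) { termination = 1; break; }
    ++t;
    int i, j, k;
    do { i = rand_int(N); j = rand_int(N); k = rand_int(N); }
    while (i == j || i == k || j == k);
    int sij = S(i, j), sik = S(i, k), sjk = S(j, k);
    if (sij * sik * sjk == -1) {
      // pairs of the triad
      int pa[3] = {i, i, j}, pb[3] = {j, k, k};
      int sg[3] = {sij, sik, sjk};
      int n_neg = (sij == -1) + (sik == -1) + (sjk == -1);
      int choice = -1, branch = -1;
      if (flip_rule == 0) { // preferential
        if (n_neg == 3) {
          // flip the pair with the smallest opinion distance to friendship
          double d[3]; int best = 0, nties = 1;
          for (int q = 0; q < 3; ++q) d[q] = pair_dist(x, pa[q], pb[q], metric, F);
          for (int q = 1; q < 3; ++q) {
            if (d[q] < d[best]) { best = q; nties = 1; }
            else if (d[q] == d[best]) ++nties;
          }
          if (nties > 1) { // uniform among argmin
            int pickn = rand_int(nties), seen = 0;
            for (int q = 0; q < 3; ++q)
              if (d[q] == d[best] && seen++ == pickn) { best = q; break; }
          }
          choice = best; branch = 0;
        } else { // (-++)
          if (unif_rand() < p) { // negative link becomes friendship
            for (int q = 0; q < 3; ++q) if (sg[q] == -1) choice = q;
            branch = 1;
          } else { // break the friendship with the largest distance
            int q1 = -1, q2 = -1;
            for (int q = 0; q < 3; ++q) { if (sg[q] == 1) { if (q1 < 0) q1 = q; else q2 = q; } }
            double d1 = pair_dist(x, pa[q1], pb[q1], metric, F);
            double d2 = pair_dist(x, pa[q2], pb[q2], metric, F);
            if (d1 == d2) choice = (unif_rand() < 0.5) ? q1 : q2;
            else choice = (d1 > d2) ? q1 : q2;
            branch = 2;
          }
        }
        apply_flip(S, pa[choice], pb[choice], N, u);
        log_flip(pa[choice], pb[choice], branch);
        if (branch == 0) ++n_all_neg; else if (branch == 1) ++n_p_branch; else ++n_break_friend;
        last_flip_round = rounds;
      } else { // random candidate (LTD), optionally constrained (CTD)
        if (n_neg == 3) { choice = rand_int(3); branch = 0; }
        else if (unif_rand() < p) {
          for (int q = 0; q < 3; ++q) if (sg[q] == -1) choice = q;
          branch = 1;
        } else {
          int q1 = -1, q2 = -1;
          for (int q = 0; q < 3; ++q) { if (sg[q] == 1) { if (q1 < 0) q1 = q; else q2 = q; } }
          choice = (unif_rand() < 0.5) ? q1 : q2;
          branch = 2;
        }
        bool ok = true;
        if (flip_rule == 2 && flip_delta(S, pa[choice], pb[choice], N) > 0)
          ok = false;  // would increase the global unbalanced count
        if (ok) {
          apply_flip(S, pa[choice], pb[choice], N, u);
          log_flip(pa[choice], pb[choice], branch);
          if (branch == 0) ++n_all_neg; else if (branch == 1) ++n_p_branch; else ++n_break_friend;
          last_flip_round = rounds;
        } else {
          ++n_rejected;
          log_flip(pa[choice], pb[choice], 3);
        }
      }
    }
    // scheduled opinion revision
    if (stochastic) {
      if (unif_rand() < q_op)
        revise_agent(x, S, rand_int(N), eps, metric, N, F, buf);
    } else if (t % M == 0) {
      revise_agent(x, S, rand_int(N), eps, metric, N, F, buf);
    }
    if (t % round_len == 0) {
      ++rounds;
      if (record_series && u > 0) push_series((double)rounds);
      if (flip_rule == 2 && u > 0 && rounds - last_flip_round >= jam_rounds) {
        termination = 2; break;
      }
    }
    if (u == 0) t_balance = (double)t;
  }

  // ---- phase 2: asynchronous opinion ticks on the frozen balanced ----
  // network: one uniformly random agent revised per tick (the same
  // opinion-update process as in phase 1, without the now-inert triad
  // revisions).  Every N ticks a non-mutating fixed-point check computes
  // the prospective change of every agent; the run is absorbed when no
  // agent would move by tol_fix or more in a full revision sweep.
  long long sweeps = 0;  // number of N-tick blocks
  NumericMatrix x_near = clone(x);
  bool snap_taken = false;
  if (termination == -1) {
    NumericMatrix x_prev(N, F);
    std::vector<double> probe(F);
    while (true) {
      if ((double)sweeps >= max_sweeps) { termination = 3; break; }
      ++sweeps;
      if (!snap_taken)
        for (int a = 0; a < N; ++a)
          for (int f = 0; f < F; ++f) x_prev(a, f) = x(a, f);
      for (int tick = 0; tick < N; ++tick)
        revise_agent(x, S, rand_int(N), eps, metric, N, F, buf);
      // prospective per-agent change if every agent were revised once now
      double maxch = 0.0;
      for (int a = 0; a < N; ++a) {
        int cnt = 1;
        for (int f = 0; f < F; ++f) probe[f] = x(a, f);
        for (int j = 0; j < N; ++j) {
          if (j == a || S(a, j) != 1) continue;
          if (pair_dist(x, a, j, metric, F) <= eps) {
            ++cnt;
            for (int f = 0; f < F; ++f) probe[f] += x(j, f);
          }
        }
        for (int f = 0; f < F; ++f) {
          double ch = std::fabs(probe[f] / cnt - x(a, f));
          if (ch > maxch) maxch = ch;
        }
      }
      if (!snap_taken && maxch < snapshot_tol) {
        // state one block before opinion motion fell below snapshot_tol
        for (int a = 0; a < N; ++a)
          for (int f = 0; f < F; ++f) x_near(a, f) = x_prev(a, f);
        snap_taken = true;
      }
      if (maxch < tol_fix) { termination = 0; break; }
    }
  }
  if (record_series) push_series((double)rounds);

  List series = List::create(
    _["round"] = wrap(se_round), _["t"] = wrap(se_t),
    _["F_unbal"] = wrap(se_funbal), _["D_plus"] = wrap(se_dplus),
    _["D_minus"] = wrap(se_dminus), _["N_op"] = wrap(se_nop));

  List flips = List::create(
    _["t"] = wrap(log_t), _["i"] = wrap(log_i), _["j"] = wrap(log_j),
    _["old_sign"] = wrap(log_old), _["branch"] = wrap(log_branch));

  return List::create(
    _["signs"] = S, _["opinions"] = x,
    _["t"] = (double)t, _["rounds"] = (double)rounds,
    _["t_balance"] = t_balance, _["sweeps"] = (double)sweeps,
    _["termination"] = termination, _["unbalanced"] = (double)u,
    _["opinions_near_absorption"] = x_near, _["snapshot_taken"] = snap_taken,
    _["flip_counts"] = NumericVector::create(
        _["all_negative_smallest"] = (double)n_all_neg,
        _["neg_to_pos_p"] = (double)n_p_branch,
        _["pos_to_neg"] = (double)n_break_friend,
        _["rejected"] = (double)n_rejected),
    _["series"] = series, _["flip_log"] = flips);
}
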