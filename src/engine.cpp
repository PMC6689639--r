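// Fused simulation loop. Consumes R's global RNG (unif_rand /
// norm_rand) in exactly the same draw order as the R-level stage
// functions, so a run stepped in R reproduces a compiled run
// trajectory-for-trajectory. Draw order per iteration:
//   Science:    n-permutation (n draws), then per funded lab:
//               hypothesis, result, publication (3 draws).
//   Evolution:  death d-sample (d draws), death tie-break (1),
//               parent d-sample (d draws) + tie-break (1) in strong
//               mode or a single weighted draw (1) in proportional
//               mode, mutation (1 normal).
//   Funding:    applicant d-sample (d draws), then per strategy:
//               PH/MI tie-break (1), RA (1), MS coin (1) + branch (1),
//               ML qualified draw (1, none when no lab qualifies).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int unif_idx(int k) {
  int j = (int)std::floor(unif_rand() * k);
  if (j >= k) j = k - 1;
  if (j < 0) j = 0;
  return j;
}

// Partial Fisher-Yates: after the call, pool[0..d-1] is a uniform
// d-subset of the original pool, in sampled order. Consumes d draws.
static inline void sample_prefix(std::vector<int>& pool, int d) {
  int m = (int)pool.size();
  for (int i = 0; i < d; ++i) {
    int j = i + unif_idx(m - i);
    std::swap(pool[i], pool[j]);
  }
}

enum Strategy { PH = 1, MI = 2, RA = 3, MS = 4, ML = 5 };

// [[Rcpp::export]]
List run_engine_cpp(int n, double b, double W, double alpha0,
                    int G0, int G, int d, double epsilon,
                    double r, double p,
                    int strategy, double X, double A, int selection_mode,
                    int iterations, int record_interval,
                    bool do_evolution, bool do_funding, bool auto_refund,
                    bool keep_stats) {
  std::vector<int> id(n), funds(n, G0), age(n, 0), pubs(n, 0), errs(n, 0);
  std::vector<double> alpha(n, alpha0);
  for (int i = 0; i < n; ++i) id[i] = i + 1;
  int max_id = n;

  double cum_pub = 0.0, cum_err = 0.0;

  std::vector<double> rec_t, rec_alpha, rec_pub, rec_err;
  rec_t.reserve(iterations / record_interval + 2);
  std::vector<int> st_inv, st_pub, st_err, st_award, st_deadfunds, st_ftot;
  std::vector<double> st_walpha;
  if (keep_stats) {
    st_inv.reserve(iterations); st_pub.reserve(iterations);
    st_err.reserve(iterations); st_award.reserve(iterations);
    st_deadfunds.reserve(iterations); st_ftot.reserve(iterations);
    st_walpha.reserve(iterations);
  }

  std::vector<int> perm(n), samp(n), samp2(n > 1 ? n - 1 : 1);
  std::vector<int> ties; ties.reserve(n);

  auto record = [&](int t) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += alpha[i];
    rec_t.push_back((double)t);
    rec_alpha.push_back(s / n);
    rec_pub.push_back(cum_pub);
    rec_err.push_back(cum_err);
  };
  record(0);

  int dd = d < n ? d : n;

  for (int t = 1; t <= iterations; ++t) {
    // ---- Science ----
    if (auto_refund) {
      for (int i = 0; i < n; ++i) if (funds[i] < 1) funds[i] = 1;
    }
    for (int i = 0; i < n; ++i) perm[i] = i;
    sample_prefix(perm, n);
    int inv = 0, pub = 0, err = 0;
    for (int k = 0; k < n; ++k) {
      int i = perm[k];
      if (funds[i] >= 1) {
        funds[i] -= 1; ++inv;
        bool h = unif_rand() < b;
        double pr = h ? W : alpha[i];
        bool pos = unif_rand() < pr;
        bool e = (h != pos);
        double q = (pos ? 1.0 : p) * (e ? (1.0 - r) : 1.0);
        bool published = unif_rand() < q;
        if (published) {
          ++pubs[i]; ++pub;
          if (e) { ++errs[i]; ++err; }
        }
      }
    }
    cum_pub += pub; cum_err += err;

    // ---- Evolution ----
    int child_slot = -1, dead_funds = 0;
    if (do_evolution) {
      for (int i = 0; i < n; ++i) samp[i] = i;
      sample_prefix(samp, dd);
      int max_age = -1;
      ties.clear();
      for (int k = 0; k < dd; ++k) {
        int a = age[samp[k]];
        if (a > max_age) { max_age = a; ties.clear(); ties.push_back(samp[k]); }
        else if (a == max_age) ties.push_back(samp[k]);
      }
      int dead = ties[unif_idx((int)ties.size())];
      dead_funds = funds[dead];

      int m = n - 1;
      int parent = -1;
      if (selection_mode == 1) {  // strong
        int dp = d < m ? d : m;
        for (int i = 0; i < m; ++i) samp2[i] = i;
        sample_prefix(samp2, dp);
        int max_pub = -1;
        ties.clear();
        for (int k = 0; k < dp; ++k) {
          int slot = samp2[k] < dead ? samp2[k] : samp2[k] + 1;
          int w = pubs[slot];
          if (w > max_pub) { max_pub = w; ties.clear(); ties.push_back(slot); }
          else if (w == max_pub) ties.push_back(slot);
        }
        parent = ties[unif_idx((int)ties.size())];
      } else {  // proportional over the whole post-death population
        double total = 0.0;
        for (int i = 0; i < n; ++i) if (i != dead) total += pubs[i];
        double u = unif_rand();
        if (total <= 0.0) {
          int j = (int)std::floor(u * m);
          if (j >= m) j = m - 1;
          parent = j < dead ? j : j + 1;
        } else {
          double target = u * total, acc = 0.0;
          for (int i = 0; i < n; ++i) {
            if (i == dead) continue;
            acc += pubs[i];
            if (target < acc) { parent = i; break; }
          }
          if (parent < 0) parent = dead == n - 1 ? n - 2 : n - 1;
        }
      }
      double z = norm_rand();
      double ca = alpha[parent] + epsilon * z;
      if (ca < 0.0) ca = 0.0;
      if (ca > 1.0) ca = 1.0;
      id[dead] = ++max_id;
      alpha[dead] = ca;
      funds[dead] = G0;
      age[dead] = 0;
      pubs[dead] = 0;
      errs[dead] = 0;
      child_slot = dead;
    }

    // ---- Grant-Seeking ----
    bool awarded = false;
    double winner_alpha = NA_REAL;
    if (do_funding) {
      for (int i = 0; i < n; ++i) samp[i] = i;
      sample_prefix(samp, dd);
      int wslot = -1;
      int strat = strategy;
      if (strat == MS) {
        strat = (unif_rand() < X) ? MI : RA;
      }
      if (strat == PH) {
        int best = -1; ties.clear();
        for (int k = 0; k < dd; ++k) {
          int w = pubs[samp[k]];
          if (w > best) { best = w; ties.clear(); ties.push_back(samp[k]); }
          else if (w == best) ties.push_back(samp[k]);
        }
        wslot = ties[unif_idx((int)ties.size())];
      } else if (strat == MI) {
        double best = 2.0; ties.clear();
        for (int k = 0; k < dd; ++k) {
          double a = alpha[samp[k]];
          if (a < best) { best = a; ties.clear(); ties.push_back(samp[k]); }
          else if (a == best) ties.push_back(samp[k]);
        }
        wslot = ties[unif_idx((int)ties.size())];
      } else if (strat == RA) {
        wslot = samp[unif_idx(dd)];
      } else {  // ML
        ties.clear();
        for (int k = 0; k < dd; ++k)
          if (alpha[samp[k]] <= A) ties.push_back(samp[k]);
        if (!ties.empty()) wslot = ties[unif_idx((int)ties.size())];
      }
      if (wslot >= 0) {
        funds[wslot] += G;
        awarded = true;
        winner_alpha = alpha[wslot];
      }
    }

    // ---- Age increment (newborn stays at age 0) ----
    for (int i = 0; i < n; ++i) if (i != child_slot) ++age[i];

    if (t % record_interval == 0 || t == iterations) record(t);
    if (keep_stats) {
      int ftot = 0;
      for (int i = 0; i < n; ++i) ftot += funds[i];
      st_inv.push_back(inv); st_pub.push_back(pub); st_err.push_back(err);
      st_award.push_back(awarded ? 1 : 0);
      st_walpha.push_back(winner_alpha);
      st_deadfunds.push_back(dead_funds);
      st_ftot.push_back(ftot);
    }
  }

  List out = List::create(
    Named("times") = wrap(rec_t),
    Named("mean_alpha") = wrap(rec_alpha),
    Named("cum_publications") = wrap(rec_pub),
    Named("cum_erroneous") = wrap(rec_err),
    Named("id") = wrap(id),
    Named("alpha") = wrap(alpha),
    Named("funds") = wrap(funds),
    Named("age") = wrap(age),
    Named("publications") = wrap(pubs),
    Named("erroneous_publications") = wrap(errs)
  );
  if (keep_stats) {
    out["stat_investigations"] = wrap(st_inv);
    out["stat_publications"] = wrap(st_pub);
    out["stat_erroneous"] = wrap(st_err);
    out["stat_awarded"] = wrap(st_award);
    out["stat_winner_alpha"] = wrap(st_walpha);
    out["stat_dead_funds"] = wrap(st_deadfunds);
    out["stat_funds_total"] = wrap(st_ftot);
  }
  return out;
}
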