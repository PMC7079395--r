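// Compiled core: pruning likelihood with island-wide events interleaved on
// branches, and the reversible-jump MCMC sweep loop. The R sources carry a
// reference implementation of the same likelihood; tests assert agreement.
//
// Performance structure: observed site columns are collapsed to unique
// patterns per island; per-island composite branch operators are cached so
// that a branch-length proposal rebuilds one edge only, and per-pattern
// rate-category likelihoods are cached so that updates of the invariant
// fraction r only reweight the mixture.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Event {
  int branch;     // child-node index of the branch (0-based)
  double rel;     // position as a fraction of the branch length, in (0,1)
  double pi[3];   // equilibrium triple in force after the event
};

struct Isl {
  int n_sites;
  int n_pat;
  std::vector<int> pat;      // pattern * n_nodes + node; 0..2, -1 missing
  std::vector<double> patw;  // pattern multiplicities
  double root_pi[3];
  std::vector<Event> ev;     // sorted by (branch, rel)
  double ll;
  bool fast;                 // all nodes observed, no missing entries
  // committed caches (consistent with the current state)
  std::vector<double> comp;      // (cat * n + node) * 9 composite operators
  std::vector<double> tripleAt;  // 3 * n triples in force at node
  std::vector<double> logLc;     // pattern * 4 log cat-likelihoods
  // scratch caches holding the latest proposal
  std::vector<double> comp2, tripleAt2, logLc2;
};

// closed-form SSE transition matrix (F81-style)
static inline void sse_P(const double* pi, double R, double dt, double* P) {
  double e = std::exp(-R * dt);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      P[i * 3 + j] = (i == j) ? pi[j] + (1.0 - pi[j]) * e : (1.0 - e) * pi[j];
}

// minimal-motion IWE transition matrix moving pi_old to pi_new
static inline void iwe_M(const double* po, const double* pn, double* M) {
  for (int k = 0; k < 9; ++k) M[k] = 0.0;
  M[0] = M[4] = M[8] = 1.0;
  int inc[3], dec[3], ni = 0, nd = 0;
  for (int s = 0; s < 3; ++s) {
    double d = pn[s] - po[s];
    if (d > 0) inc[ni++] = s; else if (d < 0) dec[nd++] = s;
  }
  if (ni == 0) return;
  if (ni == 1) {
    for (int k = 0; k < nd; ++k) {
      int a = dec[k];
      M[a * 3 + a] = pn[a] / po[a];
      M[a * 3 + inc[0]] = 1.0 - M[a * 3 + a];
    }
  } else { // one decrease feeding two increases
    int a = dec[0];
    M[a * 3 + a] = pn[a] / po[a];
    for (int k = 0; k < ni; ++k) M[a * 3 + inc[k]] = (pn[inc[k]] - po[inc[k]]) / po[a];
  }
}

static inline void matmul3(const double* A, const double* B, double* C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[i * 3 + j] = A[i * 3] * B[j] + A[i * 3 + 1] * B[3 + j] + A[i * 3 + 2] * B[6 + j];
}

// equal-probability slice means of a mean-1 gamma, renormalized to mean 1
static void disc_gamma(double alpha, double* g) {
  double q1 = R::qgamma(1.0 / 3.0, alpha, 1.0 / alpha, 1, 0);
  double q2 = R::qgamma(2.0 / 3.0, alpha, 1.0 / alpha, 1, 0);
  double p1 = R::pgamma(q1, alpha + 1.0, 1.0 / alpha, 1, 0);
  double p2 = R::pgamma(q2, alpha + 1.0, 1.0 / alpha, 1, 0);
  g[0] = 3.0 * p1; g[1] = 3.0 * (p2 - p1); g[2] = 3.0 * (1.0 - p2);
  double m = (g[0] + g[1] + g[2]) / 3.0;
  g[0] /= m; g[1] /= m; g[2] /= m;
}

struct Model {
  int n, root, nb;
  std::vector<int> parent;
  std::vector<double> len;           // per node; 0 at root
  std::vector<int> pre, post;        // node orders
  std::vector<int> branchlist;       // non-root nodes, preorder
  std::vector<std::vector<int>> kids;
  std::vector<std::vector<int>> subtree; // per node: its subtree, preorder
  std::vector<char> observed;
  int N;
  std::vector<Isl> isl;
  double r, alpha, mu;
  double grates[3];
  bool lik_off;
  // workspace
  std::vector<int> eb0, eb1;         // event index ranges per branch
  std::vector<double> wsW, wsT, wsLS;
  std::vector<double> pll;           // proposed per-island logliks
  std::vector<int> ntot_b;           // IWE count per branch over islands
  int ntot;
  double Ltot;

  void init_tree(const IntegerVector& parent0, const NumericVector& length,
                 int root0, const LogicalVector& obs) {
    n = parent0.size();
    root = root0;
    nb = n - 1;
    parent.assign(parent0.begin(), parent0.end());
    len.assign(length.begin(), length.end());
    len[root] = 0.0;
    observed.resize(n);
    for (int i = 0; i < n; ++i) observed[i] = obs[i];
    kids.assign(n, {});
    for (int i = 0; i < n; ++i) if (i != root) kids[parent[i]].push_back(i);
    pre.clear(); pre.push_back(root);
    for (size_t k = 0; k < pre.size(); ++k)
      for (int c : kids[pre[k]]) pre.push_back(c);
    post.assign(pre.rbegin(), pre.rend());
    branchlist.clear();
    for (int v : pre) if (v != root) branchlist.push_back(v);
    subtree.assign(n, {});
    for (auto it = pre.rbegin(); it != pre.rend(); ++it) {
      int v = *it;
      subtree[v].push_back(v);
      for (int c : kids[v])
        subtree[v].insert(subtree[v].end(), subtree[c].begin(), subtree[c].end());
    }
    eb0.resize(n); eb1.resize(n);
    wsW.resize(3 * n); wsT.resize(3); wsLS.resize(n);
    ntot_b.assign(n, 0);
    ntot = 0;
    Ltot = 0.0;
    for (int b : branchlist) Ltot += len[b];
  }

  void init_islands(const List& states, const List& root_pis, const List& events) {
    N = states.size();
    isl.resize(N);
    pll.resize(N);
    for (int i = 0; i < N; ++i) {
      Isl& I = isl[i];
      IntegerMatrix S = states[i];
      I.n_sites = S.nrow();
      I.fast = true;
      for (int v = 0; v < n; ++v) if (!observed[v]) I.fast = false;
      // collapse identical site columns into weighted patterns
      std::map<std::vector<int>, int> seen;
      I.pat.clear(); I.patw.clear();
      for (int s = 0; s < I.n_sites; ++s) {
        std::vector<int> row(n);
        for (int v = 0; v < n; ++v) {
          row[v] = S(s, v);
          if (row[v] < 0) I.fast = false;
        }
        auto it = seen.find(row);
        if (it == seen.end()) {
          seen[row] = (int)I.patw.size();
          I.pat.insert(I.pat.end(), row.begin(), row.end());
          I.patw.push_back(1.0);
        } else {
          I.patw[it->second] += 1.0;
        }
      }
      I.n_pat = (int)I.patw.size();
      NumericVector rp = root_pis[i];
      for (int k = 0; k < 3; ++k) I.root_pi[k] = rp[k];
      NumericMatrix E = events[i]; // cols: branch(0-based), abs pos, pi x3
      for (int e = 0; e < E.nrow(); ++e) {
        Event ev;
        ev.branch = (int)E(e, 0);
        ev.rel = E(e, 1) / len[ev.branch];
        for (int k = 0; k < 3; ++k) ev.pi[k] = E(e, 2 + k);
        I.ev.push_back(ev);
      }
      std::sort(I.ev.begin(), I.ev.end(), [](const Event& a, const Event& b) {
        return a.branch < b.branch || (a.branch == b.branch && a.rel < b.rel);
      });
      for (const Event& ev : I.ev) { ntot_b[ev.branch]++; ntot++; }
      I.comp.assign(4 * n * 9, 0.0);
      I.tripleAt.assign(3 * n, 0.0);
      I.logLc.assign((size_t)I.n_pat * 4, 0.0);
      I.comp2 = I.comp; I.tripleAt2 = I.tripleAt; I.logLc2 = I.logLc;
      I.ll = 0.0;
    }
  }

  void event_ranges(const Isl& I) {
    std::fill(eb0.begin(), eb0.end(), 0);
    std::fill(eb1.begin(), eb1.end(), 0);
    size_t k = 0;
    while (k < I.ev.size()) {
      int b = I.ev[k].branch;
      size_t k2 = k;
      while (k2 < I.ev.size() && I.ev[k2].branch == b) ++k2;
      eb0[b] = (int)k; eb1[b] = (int)k2;
      k = k2;
    }
  }

  void build_edge_composite(const Isl& I, int b, int c, double R,
                            const double* pi0, double* Ab) {
    double tmpM[9], tmpP[9], tmpA[9];
    double l = len[b];
    double tnext = (eb1[b] > eb0[b]) ? I.ev[eb0[b]].rel : 1.0;
    sse_P(pi0, R, tnext * l, Ab);
    const double* pic = pi0;
    for (int e = eb0[b]; e < eb1[b]; ++e) {
      const Event& ev = I.ev[e];
      double tafter = (e + 1 < eb1[b]) ? I.ev[e + 1].rel : 1.0;
      iwe_M(pic, ev.pi, tmpM);
      sse_P(ev.pi, R, (tafter - ev.rel) * l, tmpP);
      matmul3(Ab, tmpM, tmpA);
      matmul3(tmpA, tmpP, Ab);
      pic = ev.pi;
    }
    (void)c;
  }

  // Compute the island log-likelihood into the island's scratch caches.
  // changed_edge == -1 rebuilds everything. changed_edge >= 0 with
  // in_subtree = false reuses the committed composites except for that one
  // edge (valid for proportional branch-length proposals: configuration and
  // triples untouched). With in_subtree = true the triples and composites of
  // the whole subtree hanging from the edge are rebuilt (valid for event
  // changes on that branch, whose triples propagate downward only).
  double compute_island(Isl& I, int changed_edge, bool in_subtree = false) {
    if (lik_off) return 0.0;
    double rates[4] = {0.0, grates[0], grates[1], grates[2]};
    double probs[4] = {r, (1.0 - r) / 3.0, (1.0 - r) / 3.0, (1.0 - r) / 3.0};
    event_ranges(I);
    if (changed_edge < 0) {
      // triples in force at each node (child end of its branch)
      for (int v : pre) {
        double* tv = &I.tripleAt2[3 * v];
        if (v == root) {
          for (int k = 0; k < 3; ++k) tv[k] = I.root_pi[k];
        } else if (eb1[v] > eb0[v]) {
          const double* p = I.ev[eb1[v] - 1].pi;
          for (int k = 0; k < 3; ++k) tv[k] = p[k];
        } else {
          const double* p = &I.tripleAt2[3 * parent[v]];
          for (int k = 0; k < 3; ++k) tv[k] = p[k];
        }
      }
      // all four categories are always built so that cached values stay
      // valid under later moves of the invariant fraction r
      for (int c = 0; c < 4; ++c) {
        for (int b : branchlist)
          build_edge_composite(I, b, c, rates[c],
                               &I.tripleAt2[3 * parent[b]],
                               &I.comp2[(c * n + b) * 9]);
      }
    } else if (in_subtree) {
      I.tripleAt2 = I.tripleAt;
      I.comp2 = I.comp;
      for (int v : subtree[changed_edge]) {
        double* tv = &I.tripleAt2[3 * v];
        if (eb1[v] > eb0[v]) {
          const double* p = I.ev[eb1[v] - 1].pi;
          for (int k = 0; k < 3; ++k) tv[k] = p[k];
        } else {
          const double* p = &I.tripleAt2[3 * parent[v]];
          for (int k = 0; k < 3; ++k) tv[k] = p[k];
        }
      }
      for (int c = 0; c < 4; ++c)
        for (int v : subtree[changed_edge])
          build_edge_composite(I, v, c, rates[c],
                               &I.tripleAt2[3 * parent[v]],
                               &I.comp2[(c * n + v) * 9]);
    } else {
      I.tripleAt2 = I.tripleAt;
      I.comp2 = I.comp;
      for (int c = 0; c < 4; ++c)
        build_edge_composite(I, changed_edge, c, rates[c],
                             &I.tripleAt2[3 * parent[changed_edge]],
                             &I.comp2[(c * n + changed_edge) * 9]);
    }
    // per-pattern, per-category log likelihoods
    double tot = 0.0;
    for (int p = 0; p < I.n_pat; ++p) {
      const int* st = &I.pat[(size_t)p * n];
      double* lc = &I.logLc2[(size_t)p * 4];
      if (I.fast) {
        for (int c = 0; c < 4; ++c) {
          double v = I.root_pi[st[root]];
          const double* Ac = &I.comp2[(size_t)c * n * 9];
          for (int b : branchlist) {
            v *= Ac[b * 9 + st[parent[b]] * 3 + st[b]];
            if (v <= 0.0) break;
          }
          lc[c] = (v > 0.0) ? std::log(v) : NEG_INF;
        }
      } else {
        for (int c = 0; c < 4; ++c) {
          const double* Ac = &I.comp2[(size_t)c * n * 9];
          for (int v : post) {
            double* w = &wsW[3 * v];
            double ls = 0.0;
            if (observed[v] && st[v] >= 0) {
              w[0] = w[1] = w[2] = 0.0; w[st[v]] = 1.0;
            } else {
              w[0] = w[1] = w[2] = 1.0;
            }
            for (int ch : kids[v]) {
              const double* Ab = &Ac[ch * 9];
              const double* wc = &wsW[3 * ch];
              double t0 = Ab[0] * wc[0] + Ab[1] * wc[1] + Ab[2] * wc[2];
              double t1 = Ab[3] * wc[0] + Ab[4] * wc[1] + Ab[5] * wc[2];
              double t2 = Ab[6] * wc[0] + Ab[7] * wc[1] + Ab[8] * wc[2];
              w[0] *= t0; w[1] *= t1; w[2] *= t2;
              ls += wsLS[ch];
            }
            double m = std::max(w[0], std::max(w[1], w[2]));
            if (m > 0.0) { w[0] /= m; w[1] /= m; w[2] /= m; ls += std::log(m); }
            wsLS[v] = ls;
          }
          const double* w = &wsW[3 * root];
          double v0 = I.root_pi[0] * w[0] + I.root_pi[1] * w[1] +
                      I.root_pi[2] * w[2];
          lc[c] = (v0 > 0.0) ? std::log(v0) + wsLS[root] : NEG_INF;
        }
      }
      double mx = NEG_INF;
      for (int c = 0; c < 4; ++c)
        if (probs[c] > 0.0 && lc[c] > mx) mx = lc[c];
      if (mx == NEG_INF) return NEG_INF;
      double sum = 0.0;
      for (int c = 0; c < 4; ++c)
        if (probs[c] > 0.0 && lc[c] > NEG_INF)
          sum += probs[c] * std::exp(lc[c] - mx);
      tot += I.patw[p] * (mx + std::log(sum));
    }
    return tot;
  }

  void commit_island(Isl& I) {
    I.comp.swap(I.comp2);
    I.tripleAt.swap(I.tripleAt2);
    I.logLc.swap(I.logLc2);
  }

  // log-likelihood under a different invariant fraction, from cached
  // per-pattern category values (composites unchanged)
  double reweight_island(const Isl& I, double rnew) {
    if (lik_off) return 0.0;
    double probs[4] = {rnew, (1.0 - rnew) / 3.0, (1.0 - rnew) / 3.0,
                       (1.0 - rnew) / 3.0};
    double tot = 0.0;
    for (int p = 0; p < I.n_pat; ++p) {
      const double* lc = &I.logLc[(size_t)p * 4];
      double mx = NEG_INF;
      for (int c = 0; c < 4; ++c)
        if (probs[c] > 0.0 && lc[c] > mx) mx = lc[c];
      if (mx == NEG_INF) return NEG_INF;
      double sum = 0.0;
      for (int c = 0; c < 4; ++c)
        if (probs[c] > 0.0 && lc[c] > NEG_INF)
          sum += probs[c] * std::exp(lc[c] - mx);
      tot += I.patw[p] * (mx + std::log(sum));
    }
    return tot;
  }

  double total_ll() const {
    double s = 0.0;
    for (const Isl& I : isl) s += I.ll;
    return s;
  }
};

static void build_model(Model& M, const IntegerVector& parent0,
                        const NumericVector& len, int root0,
                        const LogicalVector& observed, const List& states,
                        const List& root_pis, const List& events,
                        double r, double alpha, const NumericVector& grates) {
  M.init_tree(parent0, len, root0, observed);
  M.r = r; M.alpha = alpha; M.mu = 0.0;
  for (int k = 0; k < 3; ++k) M.grates[k] = grates[k];
  M.lik_off = false;
  M.init_islands(states, root_pis, events);
}

// [[Rcpp::export]]
NumericVector cpp_tree_loglik(IntegerVector parent0, NumericVector len,
                              int root0, LogicalVector observed, List states,
                              List root_pis, List events, double r,
                              double alpha, NumericVector grates) {
  Model M;
  build_model(M, parent0, len, root0, observed, states, root_pis, events,
              r, alpha, grates);
  NumericVector out(M.N);
  for (int i = 0; i < M.N; ++i) out[i] = M.compute_island(M.isl[i], -1);
  return out;
}

static inline void rdirichlet3(double* p) {
  double a = exp_rand(), b = exp_rand(), c = exp_rand();
  double s = a + b + c;
  p[0] = a / s; p[1] = b / s; p[2] = c / s;
}

struct Accept { long att = 0, acc = 0; };

// [[Rcpp::export]]
List cpp_run_chain(IntegerVector parent0, NumericVector len, int root0,
                   LogicalVector observed, List states, List root_pis,
                   List events, double r, double alpha, double mu,
                   List priors, List prop, List ctrl) {
  Model M;
  {
    NumericVector g(3);
    double gg[3]; disc_gamma(alpha, gg);
    for (int k = 0; k < 3; ++k) g[k] = gg[k];
    build_model(M, parent0, len, root0, observed, states, root_pis, events,
                r, alpha, g);
  }
  M.mu = mu;
  const double ml = priors["m_l"], sl = priors["s_l"];
  const double ma = priors["m_alpha"], sa = priors["s_alpha"];
  const double mm = priors["m_mu"], sm = priors["s_mu"];
  const double w_small = prop["w_small"], sd_small = prop["sd_small"],
               sd_big = prop["sd_big"], step_r = prop["step_r"],
               step_la = prop["step_log_alpha"], step_lm = prop["step_log_mu"],
               step_resc = prop["step_rescale"], step_ext = prop["step_extend"];
  const int n_sweeps = ctrl["n_sweeps"], burn_in = ctrl["burn_in"],
            thin = ctrl["thin"], cache_every = ctrl["cache_check_every"],
            island_reps = ctrl["island_reps"], length_reps = ctrl["length_reps"];
  const bool iwe_moves = ctrl["iwe_moves"], up_len = ctrl["update_lengths"],
             up_r = ctrl["update_r"], up_a = ctrl["update_alpha"],
             up_m = ctrl["update_mu"];
  M.lik_off = ctrl["likelihood_off"];

  for (int i = 0; i < M.N; ++i) {
    M.isl[i].ll = M.compute_island(M.isl[i], -1);
    M.commit_island(M.isl[i]);
  }

  const int nb = M.nb;
  const int n_rec = (thin > 0) ? n_sweeps / thin : 0;
  NumericMatrix trace(n_rec, 5 + 3 * nb);
  Accept a_birth, a_death, a_freq, a_len, a_r, a_alpha, a_mu, a_resc, a_ext;
  double max_cache_diff = 0.0;
  int rec = 0;

  for (int sweep = 1; sweep <= burn_in + n_sweeps; ++sweep) {
    for (int irep = 0; irep < island_reps; ++irep)
    for (int i = 0; i < M.N; ++i) {
      Isl& I = M.isl[i];
      if (iwe_moves) {
        int b = M.branchlist[(int)(unif_rand() * nb) % nb];
        double l = M.len[b];
        // island's current event count on this branch
        int lo = 0, hi = 0;
        for (size_t k = 0; k < I.ev.size(); ++k) {
          if (I.ev[k].branch < b) { lo = (int)k + 1; hi = (int)k + 1; }
          else if (I.ev[k].branch == b) hi = (int)k + 1;
        }
        int nbi = hi - lo;
        if (unif_rand() < 0.5) { // birth
          a_birth.att++;
          if (M.mu > 0.0 && l > 0.0) {
            Event e;
            e.branch = b;
            e.rel = unif_rand();
            rdirichlet3(e.pi);
            bool ok = e.rel > 0.0 && e.rel < 1.0 &&
                      e.pi[0] > 1e-12 && e.pi[1] > 1e-12 && e.pi[2] > 1e-12;
            if (ok) {
              int at = lo;
              while (at < hi && I.ev[at].rel < e.rel) ++at;
              I.ev.insert(I.ev.begin() + at, e);
              double llnew = M.compute_island(I, b, true);
              double logacc = (llnew - I.ll) + std::log(M.mu * l) -
                              std::log((double)nbi + 1.0);
              if (std::log(unif_rand()) < logacc) {
                I.ll = llnew; M.commit_island(I);
                M.ntot_b[b]++; M.ntot++; a_birth.acc++;
              } else {
                I.ev.erase(I.ev.begin() + at);
              }
            }
          }
        } else if (nbi > 0) { // death
          a_death.att++;
          int at = lo + (int)(unif_rand() * nbi) % nbi;
          Event saved = I.ev[at];
          I.ev.erase(I.ev.begin() + at);
          double llnew = M.compute_island(I, b, true);
          double logacc = (llnew - I.ll) + std::log((double)nbi) -
                          std::log(M.mu * l);
          if (std::log(unif_rand()) < logacc) {
            I.ll = llnew; M.commit_island(I);
            M.ntot_b[b]--; M.ntot--; a_death.acc++;
          } else {
            I.ev.insert(I.ev.begin() + at, saved);
          }
        } else {
          a_death.att++; // death proposed on an empty branch: auto-reject
        }
      }
      { // frequency update (root triple or one event's triple)
        a_freq.att++;
        int m = (int)I.ev.size();
        int j = (int)(unif_rand() * (m + 1)) % (m + 1);
        double* target = (j == 0) ? I.root_pi : I.ev[j - 1].pi;
        double saved[3] = {target[0], target[1], target[2]};
        double nw[3];
        rdirichlet3(nw);
        if (nw[0] > 1e-12 && nw[1] > 1e-12 && nw[2] > 1e-12) {
          target[0] = nw[0]; target[1] = nw[1]; target[2] = nw[2];
          double llnew = (j == 0) ? M.compute_island(I, -1)
                                  : M.compute_island(I, I.ev[j - 1].branch, true);
          if (std::log(unif_rand()) < llnew - I.ll) {
            I.ll = llnew; M.commit_island(I); a_freq.acc++;
          } else {
            target[0] = saved[0]; target[1] = saved[1]; target[2] = saved[2];
          }
        }
      }
    }
    if (up_len) {
      for (int lrep = 0; lrep < length_reps; ++lrep)
      for (int b : M.branchlist) {
        a_len.att++;
        double lc = std::log(M.len[b]);
        double sd = (unif_rand() < w_small) ? sd_small : sd_big;
        double lnew = lc + sd * norm_rand();
        double l2 = std::exp(lnew);
        double lold = M.len[b];
        M.len[b] = l2;
        double dll = 0.0;
        if (!M.lik_off) {
          for (int i = 0; i < M.N; ++i) {
            M.pll[i] = M.compute_island(M.isl[i], b);
            dll += M.pll[i] - M.isl[i].ll;
          }
        }
        double logacc = dll + M.ntot_b[b] * (lnew - lc) -
                        M.mu * M.N * (l2 - lold) +
                        R::dnorm(lnew, ml, sl, 1) - R::dnorm(lc, ml, sl, 1);
        if (std::log(unif_rand()) < logacc) {
          if (!M.lik_off) {
            for (int i = 0; i < M.N; ++i) {
              M.isl[i].ll = M.pll[i];
              M.commit_island(M.isl[i]);
            }
          }
          M.Ltot += l2 - lold;
          a_len.acc++;
        } else {
          M.len[b] = lold;
        }
      }
    }
    if (up_r) {
      a_r.att++;
      double r2 = M.r + step_r * (2.0 * unif_rand() - 1.0);
      if (r2 < 0.0) r2 = -r2;
      if (r2 > 1.0) r2 = 2.0 - r2;
      double dll = 0.0;
      if (!M.lik_off) {
        for (int i = 0; i < M.N; ++i) {
          M.pll[i] = M.reweight_island(M.isl[i], r2);
          dll += M.pll[i] - M.isl[i].ll;
        }
      }
      if (std::log(unif_rand()) < dll) {
        M.r = r2;
        if (!M.lik_off) for (int i = 0; i < M.N; ++i) M.isl[i].ll = M.pll[i];
        a_r.acc++;
      }
    }
    if (up_a) {
      a_alpha.att++;
      double la = std::log(M.alpha);
      // small/large mixture keeps the walk mobile against the wide prior
      double lanew = la + step_la * ((unif_rand() < w_small) ? 1.0 : 5.0) *
                     norm_rand();
      double aold = M.alpha;
      double gold[3] = {M.grates[0], M.grates[1], M.grates[2]};
      M.alpha = std::exp(lanew);
      disc_gamma(M.alpha, M.grates);
      double dll = 0.0;
      if (!M.lik_off) {
        for (int i = 0; i < M.N; ++i) {
          M.pll[i] = M.compute_island(M.isl[i], -1);
          dll += M.pll[i] - M.isl[i].ll;
        }
      }
      double logacc = dll + R::dnorm(lanew, ma, sa, 1) - R::dnorm(la, ma, sa, 1);
      if (std::log(unif_rand()) < logacc) {
        if (!M.lik_off) {
          for (int i = 0; i < M.N; ++i) {
            M.isl[i].ll = M.pll[i];
            M.commit_island(M.isl[i]);
          }
        }
        a_alpha.acc++;
      } else {
        M.alpha = aold;
        for (int k = 0; k < 3; ++k) M.grates[k] = gold[k];
      }
    }
    if (up_m) {
      a_mu.att++;
      double lm = std::log(M.mu);
      double lmnew = lm + step_lm * ((unif_rand() < w_small) ? 1.0 : 5.0) *
                     norm_rand();
      double mu2 = std::exp(lmnew);
      // Poisson-process prior over current IWE counts + log-normal prior
      double logacc = M.ntot * (lmnew - lm) - (mu2 - M.mu) * M.N * M.Ltot +
                      R::dnorm(lmnew, mm, sm, 1) - R::dnorm(lm, mm, sm, 1);
      if (std::log(unif_rand()) < logacc) { M.mu = mu2; a_mu.acc++; }
    }
    if (up_len && up_m && M.mu > 0.0 && step_resc > 0.0) {
      // ridge move: scale every branch length by c and mu by 1/c. The
      // Poisson-process factor mu^n e^{-mu N Ltot} and the event-position
      // densities are exactly invariant under this map (relative positions
      // are kept), so only the likelihood and the normal priors remain.
      a_resc.att++;
      double eps = step_resc * norm_rand();
      double c = std::exp(eps);
      double lm = std::log(M.mu);
      std::vector<double> lold(M.len);
      for (int b : M.branchlist) M.len[b] *= c;
      double dll = 0.0;
      if (!M.lik_off) {
        for (int i = 0; i < M.N; ++i) {
          M.pll[i] = M.compute_island(M.isl[i], -1);
          dll += M.pll[i] - M.isl[i].ll;
        }
      }
      double logacc = dll + R::dnorm(lm - eps, mm, sm, 1) -
                      R::dnorm(lm, mm, sm, 1);
      for (int b : M.branchlist) {
        logacc += R::dnorm(std::log(lold[b]) + eps, ml, sl, 1) -
                  R::dnorm(std::log(lold[b]), ml, sl, 1);
      }
      if (std::log(unif_rand()) < logacc) {
        if (!M.lik_off) {
          for (int i = 0; i < M.N; ++i) {
            M.isl[i].ll = M.pll[i];
            M.commit_island(M.isl[i]);
          }
        }
        M.mu /= c;
        M.Ltot *= c;
        a_resc.acc++;
      } else {
        M.len = lold;
      }
    }
    if (up_len && iwe_moves && M.mu > 0.0 && step_ext > 0.0) {
      // extend/truncate length move: lengthening a branch keeps existing
      // events at their absolute offsets and fills the new segment with
      // events drawn from the Poisson-process prior; shortening truncates
      // events beyond the new length. Proposal and prior cancel exactly,
      // so the acceptance ratio carries no event terms — this move crosses
      // the barrier that couples a branch's length to its event count.
      for (int b : M.branchlist) {
      if (unif_rand() >= 0.5) continue; // thinned attempts bound the cost
      a_ext.att++;
      double lc = std::log(M.len[b]);
      double lnew = lc + step_ext * norm_rand();
      double l2 = std::exp(lnew);
      double lold = M.len[b];
      // symmetric guard (same value in both directions, so detailed
      // balance is unaffected): never draw astronomically many events
      if (!std::isfinite(l2) || l2 <= 0.0 ||
          M.mu * std::fabs(l2 - lold) > 5e3) continue;
      std::vector<std::vector<Event>> saved(M.N);
      std::vector<int> lo_at(M.N);
      int dn = 0;
      bool degenerate = false;
      for (int i = 0; i < M.N; ++i) {
        Isl& I = M.isl[i];
        int lo = 0, hi = 0;
        for (size_t k = 0; k < I.ev.size(); ++k) {
          if (I.ev[k].branch < b) { lo = (int)k + 1; hi = (int)k + 1; }
          else if (I.ev[k].branch == b) hi = (int)k + 1;
        }
        lo_at[i] = lo;
        saved[i].assign(I.ev.begin() + lo, I.ev.begin() + hi);
        std::vector<Event> prop;
        for (const Event& e : saved[i]) {
          double absp = e.rel * lold;
          if (absp < l2) {
            Event e2 = e;
            e2.rel = absp / l2;
            prop.push_back(e2);
          }
        }
        if (l2 > lold) {
          int k = (int)R::rpois(M.mu * (l2 - lold));
          for (int j = 0; j < k; ++j) {
            Event e2;
            e2.branch = b;
            e2.rel = (lold + unif_rand() * (l2 - lold)) / l2;
            rdirichlet3(e2.pi);
            if (e2.pi[0] <= 1e-12 || e2.pi[1] <= 1e-12 || e2.pi[2] <= 1e-12 ||
                e2.rel <= 0.0 || e2.rel >= 1.0)
              degenerate = true;
            prop.push_back(e2);
          }
          std::sort(prop.begin(), prop.end(),
                    [](const Event& a, const Event& c) { return a.rel < c.rel; });
        }
        dn += (int)prop.size() - (int)saved[i].size();
        I.ev.erase(I.ev.begin() + lo, I.ev.begin() + hi);
        I.ev.insert(I.ev.begin() + lo, prop.begin(), prop.end());
      }
      bool accepted = false;
      if (!degenerate) {
        M.len[b] = l2;
        double dll = 0.0;
        if (!M.lik_off) {
          for (int i = 0; i < M.N; ++i) {
            M.pll[i] = M.compute_island(M.isl[i], b, true);
            dll += M.pll[i] - M.isl[i].ll;
          }
        }
        double logacc = dll + R::dnorm(lnew, ml, sl, 1) - R::dnorm(lc, ml, sl, 1);
        if (std::log(unif_rand()) < logacc) {
          accepted = true;
          if (!M.lik_off) {
            for (int i = 0; i < M.N; ++i) {
              M.isl[i].ll = M.pll[i];
              M.commit_island(M.isl[i]);
            }
          }
          M.ntot_b[b] += dn;
          M.ntot += dn;
          M.Ltot += l2 - lold;
          a_ext.acc++;
        }
      }
      if (!accepted) {
        M.len[b] = lold;
        for (int i = 0; i < M.N; ++i) {
          Isl& I = M.isl[i];
          int lo = 0, hi = 0;
          for (size_t k = 0; k < I.ev.size(); ++k) {
            if (I.ev[k].branch < b) { lo = (int)k + 1; hi = (int)k + 1; }
            else if (I.ev[k].branch == b) hi = (int)k + 1;
          }
          I.ev.erase(I.ev.begin() + lo, I.ev.begin() + hi);
          I.ev.insert(I.ev.begin() + lo, saved[i].begin(), saved[i].end());
        }
      }
      }
    }
    if (cache_every > 0 && sweep % cache_every == 0 && !M.lik_off) {
      for (int i = 0; i < M.N; ++i) {
        double fresh = M.compute_island(M.isl[i], -1);
        double d = std::fabs(fresh - M.isl[i].ll);
        if (d > max_cache_diff) max_cache_diff = d;
        M.isl[i].ll = fresh;
        M.commit_island(M.isl[i]);
      }
    }
    if (sweep > burn_in && thin > 0 && (sweep - burn_in) % thin == 0 &&
        rec < n_rec) {
      trace(rec, 0) = sweep;
      trace(rec, 1) = M.total_ll();
      trace(rec, 2) = M.r;
      trace(rec, 3) = M.alpha;
      trace(rec, 4) = M.mu;
      for (int k = 0; k < nb; ++k)
        trace(rec, 5 + k) = std::log(M.len[M.branchlist[k]]);
      std::vector<int> cnt(M.n, 0), nisl(M.n, 0);
      for (int i = 0; i < M.N; ++i) {
        int prevb = -1; // events are sorted by branch within an island
        for (const Event& e : M.isl[i].ev) {
          cnt[e.branch]++;
          if (e.branch != prevb) { nisl[e.branch]++; prevb = e.branch; }
        }
      }
      for (int k = 0; k < nb; ++k) {
        trace(rec, 5 + nb + k) = cnt[M.branchlist[k]];
        trace(rec, 5 + 2 * nb + k) = nisl[M.branchlist[k]];
      }
      ++rec;
    }
  }

  // final state back to R (absolute event offsets, 1-based branch ids)
  List fin_events(M.N), fin_root(M.N);
  for (int i = 0; i < M.N; ++i) {
    const Isl& I = M.isl[i];
    NumericMatrix E(I.ev.size(), 5);
    for (size_t e = 0; e < I.ev.size(); ++e) {
      E(e, 0) = I.ev[e].branch + 1;
      E(e, 1) = I.ev[e].rel * M.len[I.ev[e].branch];
      for (int k = 0; k < 3; ++k) E(e, 2 + k) = I.ev[e].pi[k];
    }
    fin_events[i] = E;
    fin_root[i] = NumericVector::create(I.root_pi[0], I.root_pi[1], I.root_pi[2]);
  }
  NumericVector flen(M.n);
  for (int v = 0; v < M.n; ++v) flen[v] = (v == M.root) ? NA_REAL : M.len[v];
  NumericMatrix acc(9, 2);
  const Accept* as[9] = {&a_birth, &a_death, &a_freq, &a_len, &a_r, &a_alpha,
                         &a_mu, &a_resc, &a_ext};
  for (int k = 0; k < 9; ++k) { acc(k, 0) = as[k]->att; acc(k, 1) = as[k]->acc; }
  return List::create(_["trace"] = trace, _["events"] = fin_events,
                      _["root_pis"] = fin_root, _["r"] = M.r,
                      _["alpha"] = M.alpha, _["mu"] = M.mu,
                      _["lengths"] = flen, _["accept"] = acc,
                      _["max_cache_diff"] = max_cache_diff,
                      _["loglik"] = M.total_ll());
}
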