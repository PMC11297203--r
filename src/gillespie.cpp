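#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fenwick (binary indexed) tree over per-patch particle counts, so that a
// uniformly random particle can be located in O(log D) by weighted patch
// sampling. Patch indices are 0-based internally.
struct Fenwick {
  int n;
  std::vector<long long> tree;
  explicit Fenwick(int n_) : n(n_), tree(n_ + 1, 0) {}
  void add(int i, long long delta) {
    for (++i; i <= n; i += i & (-i)) tree[i] += delta;
  }
  long long total() const {
    long long s = 0;
    for (int i = n; i > 0; i -= i & (-i)) s += tree[i];
    return s;
  }
  // smallest index i with prefix_sum(i) > u
  int find(long long u) const {
    int pos = 0;
    int logn = 1;
    while ((1 << logn) <= n) ++logn;
    for (int k = logn; k >= 0; --k) {
      int next = pos + (1 << k);
      if (next <= n && tree[next] <= u) {
        pos = next;
        u -= tree[next];
      }
    }
    return pos;  // 0-based patch index
  }
};

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Exact event-driven simulation of the meta-population jump process.
// Events occur at total rate equal to the particle count; the acting
// particle is uniform. It consumes one resource item and duplicates with
// probability p(theta, n) (offspring trait mutated with probability mu by a
// Gaussian kick of sd sigma, clipped to [0,1]) or disperses as a propagule.
// Dispersal: with dispersal_uniform, the target is a uniformly random
// adjacent patch and the propagule dies if the target is occupied (the
// mean-field dead-on-arrival rule); otherwise the target is uniform among
// currently empty adjacent patches and the propagule dies only when none
// exists. Depletion kills all residents and replenishes the stock to the
// patch's target; a patch vacated by dispersal is replenished immediately
// when replenish_on_empty is set.
//
// Uses R's RNG stream: set.seed() on the R side makes runs reproducible.
// [[Rcpp::export(name = ".sim_gillespie_cpp")]]
List sim_gillespie_cpp(List adj, IntegerVector R_target, bool model_dd,
                       IntegerVector resources, List thetas0,
                       double mu, double sigma,
                       double t0, double t_end, double snapshot_interval,
                       bool dispersal_uniform, bool replenish_on_empty) {
  const int D = R_target.size();
  std::vector<std::vector<int> > nbr(D);
  for (int j = 0; j < D; ++j) {
    IntegerVector v = adj[j];
    nbr[j].assign(v.begin(), v.end());
    for (size_t k = 0; k < nbr[j].size(); ++k) nbr[j][k] -= 1;  // to 0-based
  }
  std::vector<int> res(resources.begin(), resources.end());
  std::vector<std::vector<double> > th(D);
  Fenwick fw(D);
  for (int j = 0; j < D; ++j) {
    NumericVector v = thetas0[j];
    th[j].assign(v.begin(), v.end());
    if (!th[j].empty()) fw.add(j, (long long)th[j].size());
  }

  long long events = 0, propagules = 0, colonisations = 0, prop_deaths = 0;

  // snapshot accumulators (long format)
  std::vector<double> snap_time, snap_meantheta;
  std::vector<int> snap_patch, snap_n, snap_r;
  double next_snap = t0;
  bool do_snap = snapshot_interval > 0;

  double t = t0;
  std::vector<int> empties;

  auto record_snapshot = [&](double at) {
    for (int j = 0; j < D; ++j) {
      const int n = (int)th[j].size();
      double m = NA_REAL;
      if (n > 0) {
        double s = 0;
        for (int k = 0; k < n; ++k) s += th[j][k];
        m = s / n;
      }
      snap_time.push_back(at);
      snap_patch.push_back(j + 1);
      snap_n.push_back(n);
      snap_r.push_back(res[j]);
      snap_meantheta.push_back(m);
    }
  };

  while (true) {
    long long N = fw.total();
    if (N == 0) break;
    double dt = -std::log(unif_rand()) / (double)N;
    double t_next = t + dt;
    while (do_snap && next_snap <= t_next && next_snap <= t_end) {
      record_snapshot(next_snap);  // state is constant on (t, t_next)
      next_snap += snapshot_interval;
    }
    if (t_next > t_end) { t = t_end; break; }
    t = t_next;

    // locate the acting particle
    long long u = (long long)(unif_rand() * (double)N);
    if (u >= N) u = N - 1;
    int j = fw.find(u);
    int n = (int)th[j].size();
    int idx = (int)(unif_rand() * n);
    if (idx >= n) idx = n - 1;
    double theta = th[j][idx];

    double p = model_dd ? (n == 1 ? theta : 1.0 - theta) : theta;
    res[j] -= 1;
    ++events;

    bool emigrated = false;
    double prop_theta = 0.0;
    if (unif_rand() < p) {
      double child = theta;
      if (mu > 0 && unif_rand() < mu) child = clip01(child + sigma * norm_rand());
      th[j].push_back(child);
      fw.add(j, 1);
    } else {
      prop_theta = theta;
      th[j][idx] = th[j].back();
      th[j].pop_back();
      fw.add(j, -1);
      emigrated = true;
      ++propagules;
    }

    // resolve the source patch
    if (res[j] == 0) {
      if (!th[j].empty()) {
        fw.add(j, -(long long)th[j].size());
        th[j].clear();
      }
      res[j] = R_target[j];
    } else if (th[j].empty() && replenish_on_empty) {
      res[j] = R_target[j];
    }

    // settle the propagule
    if (emigrated) {
      const std::vector<int>& nb = nbr[j];
      int target = -1;
      if (nb.empty()) {
        // isolated patch: nowhere to go
      } else if (dispersal_uniform) {
        int k = (int)(unif_rand() * nb.size());
        if (k >= (int)nb.size()) k = (int)nb.size() - 1;
        if (th[nb[k]].empty()) target = nb[k];
      } else {
        empties.clear();
        for (size_t k = 0; k < nb.size(); ++k) {
          if (th[nb[k]].empty()) empties.push_back(nb[k]);
        }
        if (!empties.empty()) {
          int k = (int)(unif_rand() * empties.size());
          if (k >= (int)empties.size()) k = (int)empties.size() - 1;
          target = empties[k];
        }
      }
      if (target >= 0) {
        th[target].push_back(prop_theta);
        fw.add(target, 1);
        ++colonisations;
      } else {
        ++prop_deaths;
      }
    }
  }

  // population extinct or horizon reached: fill remaining snapshot times
  while (do_snap && next_snap <= t_end + 1e-12) {
    record_snapshot(next_snap);
    next_snap += snapshot_interval;
  }
  if (fw.total() > 0) t = t_end;

  List th_out(D);
  IntegerVector res_out(D);
  for (int j = 0; j < D; ++j) {
    th_out[j] = NumericVector(th[j].begin(), th[j].end());
    res_out[j] = res[j];
  }

  return List::create(
    _["time"] = t,
    _["resources"] = res_out,
    _["thetas"] = th_out,
    _["snap_time"] = NumericVector(snap_time.begin(), snap_time.end()),
    _["snap_patch"] = IntegerVector(snap_patch.begin(), snap_patch.end()),
    _["snap_n"] = IntegerVector(snap_n.begin(), snap_n.end()),
    _["snap_r"] = IntegerVector(snap_r.begin(), snap_r.end()),
    _["snap_mean_theta"] = NumericVector(snap_meantheta.begin(), snap_meantheta.end()),
    _["events"] = (double)events,
    _["propagules_emitted"] = (double)propagules,
    _["colonisations"] = (double)colonisations,
    _["propagule_deaths"] = (double)prop_deaths);
}
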