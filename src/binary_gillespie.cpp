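// Exact stochastic simulation (Gillespie direct method) of competitive
// binary association/dissociation:  A_i + A_j <=> C_ij  over an arbitrary
// set of pair channels (i == j allowed: homodimerization).  Propensities are
// kept in a Fenwick (binary indexed) tree for O(log M) sampling/updates, so
// networks with tens of thousands of nonspecific channels stay fast.
//
// Steady state is declared when the time-averaged (specific, nonspecific,
// free) totals of two consecutive averaging windows agree within rel_tol.
// The reported counts are time averages over the final window.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Fenwick {
  int n;
  std::vector<double> t;
  explicit Fenwick(int n_) : n(n_), t(n_ + 1, 0.0) {}
  void add(int i, double d) {
    for (++i; i <= n; i += i & -i) t[i] += d;
  }
  double total() const {
    double s = 0;
    int i = n;
    for (; i > 0; i -= i & -i) s += t[i];
    return s;
  }
  // smallest index with prefix sum > u
  int find(double u) const {
    int pos = 0;
    int logn = 1;
    while ((1 << logn) <= n) ++logn;
    for (int pw = 1 << (logn - 1); pw > 0; pw >>= 1) {
      if (pos + pw <= n && t[pos + pw] <= u) {
        pos += pw;
        u -= t[pos];
      }
    }
    return pos;  // 0-based element index
  }
};

}  // namespace

// [[Rcpp::export]]
List binary_gillespie_cpp(int n_species, IntegerVector copies,
                          IntegerVector chan_i, IntegerVector chan_j,
                          NumericVector kon, NumericVector koff,
                          LogicalVector specific,
                          int n_runs, IntegerVector seeds,
                          double window, double rel_tol,
                          int max_windows, double max_events,
                          bool check_conservation) {
  const int m = chan_i.size();
  std::vector<std::vector<int>> chans_of(n_species);
  for (int c = 0; c < m; ++c) {
    chans_of[chan_i[c]].push_back(c);
    if (chan_j[c] != chan_i[c]) chans_of[chan_j[c]].push_back(c);
  }

  NumericVector mean_complex(m), mean_free(n_species);
  double sum_spec = 0, sum_nonspec = 0, sum_free = 0;
  int converged_runs = 0;
  bool conservation_ok = true;

  std::vector<double> free_cnt(n_species);
  std::vector<double> cplx(m);

  for (int run = 0; run < n_runs; ++run) {
    std::mt19937_64 rng(static_cast<uint64_t>(seeds[run]) * 2654435761u + 12345u);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    for (int i = 0; i < n_species; ++i) free_cnt[i] = copies[i];
    std::fill(cplx.begin(), cplx.end(), 0.0);

    Fenwick prop(2 * m);  // [0, m): binding, [m, 2m): unbinding
    auto bind_prop = [&](int c) {
      const int i = chan_i[c], j = chan_j[c];
      if (i == j) return kon[c] * free_cnt[i] * (free_cnt[i] - 1.0) * 0.5;
      return kon[c] * free_cnt[i] * free_cnt[j];
    };
    std::vector<double> cur(2 * m, 0.0);
    auto refresh_bind = [&](int c) {
      double p = bind_prop(c);
      prop.add(c, p - cur[c]);
      cur[c] = p;
    };
    auto refresh_unbind = [&](int c) {
      double p = koff[c] * cplx[c];
      prop.add(m + c, p - cur[m + c]);
      cur[m + c] = p;
    };
    for (int c = 0; c < m; ++c) { refresh_bind(c); refresh_unbind(c); }

    // windowed time averages of per-channel complexes and per-species free
    std::vector<double> acc_c(m, 0.0), acc_f(n_species, 0.0);
    std::vector<double> last_c(m, 0.0), last_f(n_species, 0.0);
    double t_in_window = 0.0;
    double prev_spec = -1, prev_nonspec = -1, prev_free = -1;
    int windows_done = 0;
    bool run_converged = false;
    double events = 0.0;

    auto finish_window = [&](double wlen) {
      double w_spec = 0, w_nonspec = 0, w_free = 0;
      for (int c = 0; c < m; ++c) {
        last_c[c] = acc_c[c] / wlen;
        (specific[c] ? w_spec : w_nonspec) += last_c[c];
      }
      for (int i = 0; i < n_species; ++i) {
        last_f[i] = acc_f[i] / wlen;
        w_free += last_f[i];
      }
      bool ok = false;
      if (windows_done > 0) {
        auto drift = [&](double a, double b) {
          double scale = std::max(std::max(std::fabs(a), std::fabs(b)), 1e-9);
          return std::fabs(a - b) / scale;
        };
        ok = drift(prev_spec, w_spec) < rel_tol &&
             drift(prev_nonspec, w_nonspec) < rel_tol &&
             drift(prev_free, w_free) < rel_tol;
      }
      prev_spec = w_spec; prev_nonspec = w_nonspec; prev_free = w_free;
      ++windows_done;
      return ok;
    };

    while (true) {
      double a0 = prop.total();
      if (a0 <= 0) {  // frozen state (e.g. koff = 0 and everything bound)
        // pad the window with the static state
        double remain = window - t_in_window;
        for (int c = 0; c < m; ++c) acc_c[c] += cplx[c] * remain;
        for (int i = 0; i < n_species; ++i) acc_f[i] += free_cnt[i] * remain;
        finish_window(window);
        run_converged = true;
        break;
      }
      double dt = -std::log(std::max(unif(rng), 1e-300)) / a0;
      double step = dt;
      if (t_in_window + dt >= window) step = window - t_in_window;
      for (int c = 0; c < m; ++c) acc_c[c] += cplx[c] * step;
      for (int i = 0; i < n_species; ++i) acc_f[i] += free_cnt[i] * step;
      if (t_in_window + dt >= window) {
        bool ok = finish_window(window);
        // carry the remaining slice of dt into the next window
        double rest = dt - step;
        for (int c = 0; c < m; ++c) acc_c[c] = cplx[c] * rest;
        for (int i = 0; i < n_species; ++i) acc_f[i] = free_cnt[i] * rest;
        t_in_window = rest;
        if (ok && windows_done >= 2) { run_converged = true; break; }
        if (windows_done >= max_windows) break;
      } else {
        t_in_window += dt;
      }

      // fire one reaction
      double u = unif(rng) * a0;
      int idx = prop.find(u);
      if (idx >= 2 * m) idx = 2 * m - 1;
      int c = idx % m;
      const int i = chan_i[c], j = chan_j[c];
      if (idx < m) {  // bind
        if (i == j) free_cnt[i] -= 2; else { free_cnt[i] -= 1; free_cnt[j] -= 1; }
        cplx[c] += 1;
      } else {        // unbind
        if (i == j) free_cnt[i] += 2; else { free_cnt[i] += 1; free_cnt[j] += 1; }
        cplx[c] -= 1;
      }
      refresh_unbind(c);
      for (int cc : chans_of[i]) refresh_bind(cc);
      if (j != i) for (int cc : chans_of[j]) refresh_bind(cc);

      if (++events > max_events) break;
    }

    if (run_converged) ++converged_runs;
    if (check_conservation) {
      for (int i = 0; i < n_species; ++i) {
        double tot = free_cnt[i];
        for (int c : chans_of[i])
          tot += (chan_i[c] == chan_j[c]) ? 2.0 * cplx[c] : cplx[c];
        if (std::fabs(tot - copies[i]) > 1e-6) conservation_ok = false;
      }
    }

    // accumulate final completed-window averages across runs
    for (int c = 0; c < m; ++c) mean_complex[c] += last_c[c];
    for (int i = 0; i < n_species; ++i) mean_free[i] += last_f[i];
    sum_spec += std::max(prev_spec, 0.0);
    sum_nonspec += std::max(prev_nonspec, 0.0);
    sum_free += std::max(prev_free, 0.0);
  }

  for (int c = 0; c < m; ++c) mean_complex[c] /= n_runs;
  for (int i = 0; i < n_species; ++i) mean_free[i] /= n_runs;

  return List::create(
      _["n_specific"] = sum_spec / n_runs,
      _["n_nonspecific"] = sum_nonspec / n_runs,
      _["n_free"] = sum_free / n_runs,
      _["mean_complex"] = mean_complex,
      _["mean_free"] = mean_free,
      _["converged_runs"] = converged_runs,
      _["conservation_ok"] = conservation_ok);
}
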