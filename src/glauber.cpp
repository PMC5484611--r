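#include <Rcpp.h>
using namespace Rcpp;

// Event-driven Glauber dynamics of a binary network.
//
// Global update events arrive as a Poisson process of rate n / tau (or on a
// fixed grid dt = tau / n when fixed_step); at each event one uniformly
// chosen neuron is re-drawn: a dynamic neuron is set active iff its summed
// recurrent input plus the sinusoidal drive plus fresh Gaussian noise
// reaches its threshold; a clamped neuron is set active with its fixed
// probability. The recurrent input of every neuron is maintained
// incrementally through the out-edge lists, so an event costs O(1) unless
// the state flips (then O(out-degree)).
//
// Snapshots of the tracked neurons and of the per-population active counts
// are taken at the supplied (sorted) times with the state left of the next
// event; per-neuron cumulative active time is integrated from active_from.
// [[Rcpp::export]]
List glauber_run_cpp(int n,
                     IntegerVector pop,
                     int n_pop,
                     IntegerVector out_ptr,
                     IntegerVector out_to,
                     NumericVector out_w,
                     NumericVector theta,
                     LogicalVector clamped,
                     NumericVector m_clamp,
                     NumericVector sigma_noise,
                     double tau,
                     double h_ext,
                     double omega,
                     double duration,
                     IntegerVector init,
                     NumericVector snap_times,
                     IntegerVector tracked,
                     bool record_events,
                     bool record_inputs,
                     double active_from,
                     bool fixed_step) {
  const int n_snaps = snap_times.size();
  const int n_tracked = tracked.size();

  std::vector<int> s(init.begin(), init.end());
  std::vector<double> curh(n, 0.0);
  std::vector<int> popcount(n_pop, 0);
  std::vector<double> last_t(n, 0.0);
  std::vector<double> active(n, 0.0);

  for (int j = 0; j < n; ++j) {
    popcount[pop[j]] += s[j];
    if (s[j]) {
      for (int k = out_ptr[j]; k < out_ptr[j + 1]; ++k) curh[out_to[k]] += out_w[k];
    }
  }

  IntegerMatrix snaps(n_tracked, n_snaps);
  IntegerMatrix popcounts(n_pop, n_snaps);
  std::vector<double> ev_t;
  std::vector<int> ev_id, ev_state;
  std::vector<double> inputs;

  double t = 0.0;
  const double mean_dt = tau / n;
  int snap_i = 0;
  long long n_events = 0;

  auto take_snapshots_before = [&](double t_next) {
    while (snap_i < n_snaps && snap_times[snap_i] < t_next) {
      for (int k = 0; k < n_tracked; ++k) snaps(k, snap_i) = s[tracked[k]];
      for (int q = 0; q < n_pop; ++q) popcounts(q, snap_i) = popcount[q];
      ++snap_i;
    }
  };

  while (true) {
    double dt = fixed_step ? mean_dt : R::rexp(mean_dt);
    double t_next = t + dt;
    if (t_next >= duration) {
      take_snapshots_before(duration);
      break;
    }
    take_snapshots_before(t_next);
    t = t_next;

    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;

    int newstate;
    if (clamped[i]) {
      newstate = (unif_rand() < m_clamp[i]) ? 1 : 0;
    } else {
      double inp = curh[i] + h_ext * sin(omega * t) + sigma_noise[i] * norm_rand();
      newstate = (inp >= theta[i]) ? 1 : 0;
      if (record_inputs) inputs.push_back(inp);
    }
    ++n_events;
    if (record_events) {
      ev_t.push_back(t);
      ev_id.push_back(i + 1);
      ev_state.push_back(newstate);
    }
    if (newstate != s[i]) {
      if (s[i] == 1 && t > active_from) {
        double a0 = last_t[i] > active_from ? last_t[i] : active_from;
        active[i] += t - a0;
      }
      last_t[i] = t;
      popcount[pop[i]] += newstate - s[i];
      double dw = (double)(newstate - s[i]);
      for (int k = out_ptr[i]; k < out_ptr[i + 1]; ++k) {
        curh[out_to[k]] += out_w[k] * dw;
      }
      s[i] = newstate;
    }
  }

  for (int j = 0; j < n; ++j) {
    if (s[j] == 1 && duration > active_from) {
      double a0 = last_t[j] > active_from ? last_t[j] : active_from;
      if (duration > a0) active[j] += duration - a0;
    }
  }

  List out = List::create(
    _["snapshots"] = snaps,
    _["popcounts"] = popcounts,
    _["active_time"] = NumericVector(active.begin(), active.end()),
    _["final_state"] = IntegerVector(s.begin(), s.end()),
    _["n_events"] = (double)n_events);
  if (record_events) {
    out["event_time"] = NumericVector(ev_t.begin(), ev_t.end());
    out["event_neuron"] = IntegerVector(ev_id.begin(), ev_id.end());
    out["event_state"] = IntegerVector(ev_state.begin(), ev_state.end());
  }
  if (record_inputs) out["inputs"] = NumericVector(inputs.begin(), inputs.end());
  return out;
}
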