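#include <Rcpp.h>
using namespace Rcpp;

// Forward Monte Carlo of the pairwise-comparison imitation process with
// explicit mutation, over one (Dictator Game) or two (Anticipation Game)
// populations of N individuals each.
//
// Per update: choose a population (probability 1/2 each when bipartite),
// choose a learner uniformly; with probability mu the learner adopts a
// uniformly random strategy of its population, otherwise it imitates a
// uniformly chosen role model (among the other N-1 individuals of the same
// population) with the Fermi probability, payoffs being averages against the
// current composition of the opposite population.
//
// While both populations are homogeneous no imitation can change the state,
// so the waiting time to the next mutation is drawn geometrically and the
// occupancy is credited in bulk; this is distributionally identical to the
// naive per-update loop.

static inline int sample_by_counts(const std::vector<int>& c, int total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int last = -1;
  for (size_t s = 0; s < c.size(); ++s) {
    if (c[s] > 0) last = (int)s;
    acc += c[s];
    if (u < acc) return (int)s;
  }
  return last;  // guard against rounding
}

static inline int homogeneous_resident(const std::vector<int>& c, int N) {
  for (size_t s = 0; s < c.size(); ++s) if (c[s] == N) return (int)s;
  return -1;
}

// [[Rcpp::export(name = ".mc_run")]]
List mc_run(int N, NumericVector strat_d, NumericVector strat_r,
            NumericMatrix pay_d, NumericMatrix pay_r,
            double beta, double mu, double steps, double burn_in,
            double sample_every, bool bipartite,
            IntegerVector init_d, IntegerVector init_r, int max_samples) {
  const int nD = strat_d.size(), nR = strat_r.size();
  std::vector<int> cD(init_d.begin(), init_d.end());
  std::vector<int> cR(init_r.begin(), init_r.end());

  std::vector<double> accD(nD, 0.0), accR(nR, 0.0);
  NumericMatrix accState(nD, nR);
  double hom_time = 0.0;

  std::vector<double> traj_t, traj_p, traj_q;
  double next_sample = burn_in;
  double n_mut = 0.0, n_active = 0.0;

  double t = 0.0;
  const double total_obs = steps - burn_in;

  auto mean_strat = [&](const std::vector<int>& c, const NumericVector& v) {
    double m = 0.0;
    for (size_t s = 0; s < c.size(); ++s) m += c[s] * v[s];
    return m / N;
  };

  // credit occupancy for the interval [t, t + dt) in the current state
  auto credit = [&](double dt) {
    double lo = std::max(t, burn_in), hi = std::min(t + dt, steps);
    double w = hi - lo;
    if (w > 0) {
      for (int s = 0; s < nD; ++s) accD[s] += w * cD[s];
      for (int s = 0; s < nR; ++s) accR[s] += w * cR[s];
      int rd = homogeneous_resident(cD, N);
      int rr = bipartite ? homogeneous_resident(cR, N) : 0;
      if (rd >= 0 && rr >= 0) {
        accState(rd, rr) += w;
        hom_time += w;
      }
    }
    while (next_sample < t + dt && next_sample < steps &&
           (int)traj_t.size() < max_samples) {
      traj_t.push_back(next_sample);
      traj_p.push_back(mean_strat(cD, strat_d));
      traj_q.push_back(mean_strat(cR, strat_r));
      next_sample += sample_every;
    }
  };

  auto payoff_d = [&](int s) {
    if (!bipartite) return pay_d(s, 0);
    double f = 0.0;
    for (int q = 0; q < nR; ++q) f += cR[q] * pay_d(s, q);
    return f / N;
  };
  auto payoff_r = [&](int s) {
    double f = 0.0;
    for (int p = 0; p < nD; ++p) f += cD[p] * pay_r(s, p);
    return f / N;
  };

  auto mutate = [&](std::vector<int>& c, int nS) {
    int s = sample_by_counts(c, N);
    int s2 = (int)(unif_rand() * nS);
    if (s2 >= nS) s2 = nS - 1;
    c[s]--; c[s2]++;
    n_mut += 1.0;
  };

  while (t < steps) {
    bool homD = homogeneous_resident(cD, N) >= 0;
    bool homR = !bipartite || homogeneous_resident(cR, N) >= 0;
    if (homD && homR && mu > 0) {
      // geometric skip to the next mutation event
      double g = R::rgeom(mu);
      double dt = std::min(g, steps - t);
      credit(dt);
      t += dt;
      if (t >= steps) break;
      credit(1.0);  // the mutation update itself
      bool popD = (!bipartite) || (unif_rand() < 0.5);
      if (popD) mutate(cD, nD); else mutate(cR, nR);
      t += 1.0;
      continue;
    }
    credit(1.0);
    n_active += 1.0;
    bool popD = (!bipartite) || (unif_rand() < 0.5);
    std::vector<int>& c = popD ? cD : cR;
    int nS = popD ? nD : nR;
    int s = sample_by_counts(c, N);
    if (mu > 0 && unif_rand() < mu) {
      int s2 = (int)(unif_rand() * nS);
      if (s2 >= nS) s2 = nS - 1;
      c[s]--; c[s2]++;
      n_mut += 1.0;
    } else {
      // role model among the other N - 1 individuals
      double u = unif_rand() * (N - 1);
      double acc = 0.0;
      int m = s;
      for (int v = 0; v < nS; ++v) {
        int cnt = c[v] - (v == s ? 1 : 0);
        acc += cnt;
        if (u < acc) { m = v; break; }
      }
      if (m != s) {
        double fs = popD ? payoff_d(s) : payoff_r(s);
        double fm = popD ? payoff_d(m) : payoff_r(m);
        double pr = 1.0 / (1.0 + exp(-beta * (fm - fs)));
        if (unif_rand() < pr) { c[s]--; c[m]++; }
      }
    }
    t += 1.0;
  }

  NumericVector freq_d(nD), freq_r(nR);
  for (int s = 0; s < nD; ++s) freq_d[s] = accD[s] / (total_obs * N);
  for (int s = 0; s < nR; ++s) freq_r[s] = accR[s] / (total_obs * N);
  double tot_state = 0.0;
  for (int i = 0; i < nD; ++i) for (int j = 0; j < nR; ++j)
    tot_state += accState(i, j);
  NumericMatrix state_occ(nD, nR);
  if (tot_state > 0) {
    for (int i = 0; i < nD; ++i) for (int j = 0; j < nR; ++j)
      state_occ(i, j) = accState(i, j) / tot_state;
  }

  return List::create(
    _["freq_d"] = freq_d, _["freq_r"] = freq_r,
    _["state_occupancy"] = state_occ,
    _["homogeneous_fraction"] = tot_state / total_obs,
    _["trajectory"] = DataFrame::create(
      _["step"] = wrap(traj_t), _["mean_p"] = wrap(traj_p),
      _["mean_q"] = wrap(traj_q)),
    _["n_mutations"] = n_mut, _["n_active_updates"] = n_active);
}
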