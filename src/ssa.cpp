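#include <Rcpp.h>
using namespace Rcpp;

// Exact Gillespie direct-method simulation of the battle reaction network.
// The reactant and net-change stoichiometries are passed in from the R-side
// registry so the compiled core and the mean-field code share one source of
// truth.  Propensity of channel j: k[j] * prod_i state[i]^react(i,j), zero
// unless state[i] >= react(i,j) for all i (integer feasibility guard).
// Uses R's RNG, so set.seed() on the R side makes runs bit-reproducible.
// [[Rcpp::export(name = ".ssa_cpp")]]
List ssa_cpp(IntegerVector init, NumericVector k,
             IntegerMatrix react, IntegerMatrix nu,
             double t_max, int max_events) {
  const int ns = init.size();       // 5 species
  const int nc = k.size();          // 15 channels

  std::vector<double> times;
  std::vector<int> states;          // row-major ns-blocks
  std::vector<int> channels;

  std::vector<int> x(init.begin(), init.end());
  double t = 0.0;
  times.reserve(1024); channels.reserve(1024); states.reserve(1024 * ns);

  std::vector<double> a(nc);
  bool absorbed = false;

  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < nc; ++j) {
      bool feasible = true;
      double prop = k[j];
      for (int i = 0; i < ns; ++i) {
        int r = react(i, j);
        if (r > 0) {
          if (x[i] < r) { feasible = false; break; }
          for (int p = 0; p < r; ++p) prop *= x[i];
        }
      }
      a[j] = feasible ? prop : 0.0;
      a0 += a[j];
    }
    if (a0 <= 0.0) { absorbed = true; break; }     // absorbing state

    double tau = R::rexp(1.0 / a0);
    if (t + tau > t_max) break;
    t += tau;

    double u = unif_rand() * a0;
    int j = 0;
    double acc = a[0];
    while (u > acc && j < nc - 1) acc += a[++j];

    for (int i = 0; i < ns; ++i) x[i] += nu(i, j);

    times.push_back(t);
    channels.push_back(j + 1);
    for (int i = 0; i < ns; ++i) states.push_back(x[i]);

    if ((int)times.size() >= max_events) break;
  }

  int ne = times.size();
  IntegerMatrix smat(ne, ns);
  for (int e = 0; e < ne; ++e)
    for (int i = 0; i < ns; ++i) smat(e, i) = states[e * ns + i];

  return List::create(_["times"] = wrap(times),
                      _["states"] = smat,
                      _["channels"] = wrap(channels),
                      _["final"] = wrap(x),
                      _["absorbed"] = absorbed,
                      _["t_final"] = t);
}
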