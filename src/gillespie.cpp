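// Exact type-level Gillespie simulation of the branching treatment model,
// used as an independent cross-check of the hybrid engine on small
// instances. State is (sensitive count, one count per resistant clone);
// rates are linear in the counts, so events are simulated one at a time.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_gillespie_run(double b, double d, double d_prime, double mu,
                       double detect_size, double treat_days) {
  RNGScope scope;
  std::vector<double> clones;
  double ns;
  // growth phase, conditioned on reaching detection
  int attempts = 0;
  for (;;) {
    ns = 1;
    clones.clear();
    ++attempts;
    for (;;) {
      double nr = 0;
      for (size_t i = 0; i < clones.size(); ++i) nr += clones[i];
      double tot = ns + nr;
      if (tot <= 0 || tot >= detect_size) break;
      double rate_sb = b * ns, rate_sd = d * ns;
      double rate_rb = b * nr, rate_rd = d * nr;
      double total = rate_sb + rate_sd + rate_rb + rate_rd;
      double u = unif_rand() * total;
      if (u < rate_sb) {
        if (unif_rand() < mu)
          clones.push_back(1); // one daughter founds a resistant clone
        else
          ns += 1;
      } else if (u < rate_sb + rate_sd) {
        ns -= 1;
      } else if (u < rate_sb + rate_sd + rate_rb) {
        // resistant birth: pick clone proportional to size
        double v = unif_rand() * nr, acc = 0;
        for (size_t i = 0; i < clones.size(); ++i) {
          acc += clones[i];
          if (v < acc) { clones[i] += 1; break; }
        }
      } else {
        double v = unif_rand() * nr, acc = 0;
        for (size_t i = 0; i < clones.size(); ++i) {
          acc += clones[i];
          if (v < acc) { clones[i] -= 1; break; }
        }
      }
    }
    double nr = 0;
    for (size_t i = 0; i < clones.size(); ++i) nr += clones[i];
    if (ns + nr >= detect_size) break;
  }
  double pre_sensitive = ns;

  // treatment phase: no new aberrations, sensitive die at d_prime
  double t = 0;
  for (;;) {
    double nr = 0;
    for (size_t i = 0; i < clones.size(); ++i) nr += clones[i];
    if (ns + nr <= 0) break;
    double total = (b + d_prime) * ns + (b + d) * nr;
    t += R::rexp(1.0 / total);
    if (t > treat_days) break;
    double u = unif_rand() * total;
    if (u < b * ns) ns += 1;
    else if (u < (b + d_prime) * ns) ns -= 1;
    else if (u < (b + d_prime) * ns + b * nr) {
      double v = unif_rand() * nr, acc = 0;
      for (size_t i = 0; i < clones.size(); ++i) {
        acc += clones[i];
        if (v < acc) { clones[i] += 1; break; }
      }
    } else {
      double v = unif_rand() * nr, acc = 0;
      for (size_t i = 0; i < clones.size(); ++i) {
        acc += clones[i];
        if (v < acc) { clones[i] -= 1; break; }
      }
    }
  }
  double resid = ns;
  double mx = 0;
  for (size_t i = 0; i < clones.size(); ++i) {
    resid += clones[i];
    if (clones[i] > mx) mx = clones[i];
  }
  return List::create(_["sensitive"] = ns, _["residual"] = resid,
                      _["max_clone"] = mx,
                      _["pre_sensitive"] = pre_sensitive,
                      _["extinct_attempts"] = attempts - 1);
}
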