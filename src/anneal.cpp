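#include <Rcpp.h>
using namespace Rcpp;

// Best-of-reads single-flip Metropolis annealing for a QUBO given as
// E(x) = sum_i lin[i] x_i + sum_{i<j} B[i,j] x_i x_j   (B symmetric, diag 0).
// Each read restarts from a random configuration and sweeps all variables
// sequentially while the temperature decays geometrically from t_hot to
// t_cold. Uses R's RNG, so results are reproducible under set.seed(), and
// reads consume the stream sequentially (best-of is monotone in reads).
// [[Rcpp::export]]
List anneal_qubo_cpp(NumericVector lin, NumericMatrix B, int reads,
                     int sweeps, double t_hot, double t_cold) {
  const int p = lin.size();
  RNGScope scope;

  std::vector<int> x(p), best_x(p), read_best_x(p);
  std::vector<double> field(p);
  NumericVector read_energies(reads);
  double best_e = R_PosInf;

  const double ratio = (sweeps > 1) ? std::pow(t_cold / t_hot,
                                               1.0 / (sweeps - 1)) : 1.0;

  for (int r = 0; r < reads; ++r) {
    // random start
    double e = 0.0;
    for (int i = 0; i < p; ++i) x[i] = (unif_rand() < 0.5) ? 1 : 0;
    for (int i = 0; i < p; ++i) {
      double f = 0.0;
      for (int j = 0; j < p; ++j) f += B(i, j) * x[j];
      field[i] = f;
      e += lin[i] * x[i] + 0.5 * f * x[i];
    }
    double read_best = e;
    for (int i = 0; i < p; ++i) read_best_x[i] = x[i];

    double T = t_hot;
    for (int s = 0; s < sweeps; ++s) {
      for (int i = 0; i < p; ++i) {
        const double de = (1 - 2 * x[i]) * (lin[i] + field[i]);
        if (de <= 0.0 || unif_rand() < std::exp(-de / T)) {
          const int delta = 1 - 2 * x[i];
          x[i] += delta;
          e += de;
          for (int j = 0; j < p; ++j) field[j] += B(j, i) * delta;
          if (e < read_best) {
            read_best = e;
            for (int q = 0; q < p; ++q) read_best_x[q] = x[q];
          }
        }
      }
      T *= ratio;
    }
    read_energies[r] = read_best;
    if (read_best < best_e) {
      best_e = read_best;
      for (int i = 0; i < p; ++i) best_x[i] = read_best_x[i];
    }
  }

  return List::create(_["x"] = IntegerVector(best_x.begin(), best_x.end()),
                      _["energy"] = best_e,
                      _["read_energies"] = read_energies);
}
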