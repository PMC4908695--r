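#include <Rcpp.h>
#include <cmath>
#include <cstdint>

// Self-contained per-locus PRNG (xorshift128+ seeded via splitmix64) so each
// locus's chain is reproducible from its own seed and results do not depend
// on the order in which loci are processed.
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    // splitmix64 initialization
    for (int k = 0; k < 2; ++k) {
      seed += 0x9E3779B97F4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      z = z ^ (z >> 31);
      if (k == 0) s0 = z; else s1 = z;
    }
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  inline uint64_t next() {
    uint64_t x = s0;
    uint64_t const y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() {
    // 53-bit mantissa uniform in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double normal() {
    // Box-Muller (single value; cheap enough for the gamma rejection loop)
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  // Marsaglia-Tsang for shape a >= 1 (all uses here have a >= 1)
  double gamma(double a) {
    double d = a - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do {
        x = normal();
        v = 1.0 + c * x;
      } while (v <= 0.0);
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
  inline double beta(double a, double b) {
    double x = gamma(a);
    double y = gamma(b);
    return x / (x + y);
  }
};

// Per-locus Gibbs sampler for the hierarchical genotype model:
//   q ~ Beta(1, 1);  g_i | q ~ HWE(q);  reads | g_i via the likelihood triple.
// Alternates (i) sampling each individual's genotype from
// L_i(g) * HWE(g | q) and (ii) q ~ Beta(1 + sum g_i, 1 + sum (2 - g_i)).
// Retained iterations accumulate the conditional genotype probabilities
// (Rao-Blackwellized average) and the sampled q.
// [[Rcpp::export(name = ".gibbs_dosage")]]
Rcpp::List gibbs_dosage(Rcpp::NumericVector lik, int n_ind, int n_loci,
                        int n_steps, int burn_in, int thin,
                        Rcpp::NumericVector locus_seeds) {
  const double *L = lik.begin();
  Rcpp::NumericMatrix dosage(n_ind, n_loci);
  Rcpp::NumericVector probs(static_cast<R_xlen_t>(n_ind) * n_loci * 3);
  Rcpp::NumericVector qbar(n_loci);

  std::vector<double> l0(n_ind), l1(n_ind), l2(n_ind);
  std::vector<double> p1acc(n_ind), p2acc(n_ind);
  const R_xlen_t plane = static_cast<R_xlen_t>(n_ind) * n_loci;

  for (int j = 0; j < n_loci; ++j) {
    Rng rng(static_cast<uint64_t>(locus_seeds[j]));
    double qinit_num = 0.0;
    for (int i = 0; i < n_ind; ++i) {
      l0[i] = L[i + static_cast<R_xlen_t>(j) * n_ind];
      l1[i] = L[i + static_cast<R_xlen_t>(j) * n_ind + plane];
      l2[i] = L[i + static_cast<R_xlen_t>(j) * n_ind + 2 * plane];
      double tot = l0[i] + l1[i] + l2[i];
      qinit_num += (l1[i] + 2.0 * l2[i]) / (2.0 * tot);
      p1acc[i] = 0.0;
      p2acc[i] = 0.0;
    }
    double q = qinit_num / n_ind;
    if (q < 0.01) q = 0.01;
    if (q > 0.99) q = 0.99;

    double qacc = 0.0;
    int nacc = 0;
    for (int step = 1; step <= n_steps + burn_in; ++step) {
      const bool retained = step > burn_in && ((step - burn_in) % thin == 0);
      const double h0 = (1.0 - q) * (1.0 - q);
      const double h1 = 2.0 * q * (1.0 - q);
      const double h2 = q * q;
      int sumg = 0;
      for (int i = 0; i < n_ind; ++i) {
        const double w0 = l0[i] * h0;
        const double w1 = l1[i] * h1;
        const double w2 = l2[i] * h2;
        const double tot = w0 + w1 + w2;
        const double u = rng.unif() * tot;
        int g = (u < w0) ? 0 : ((u < w0 + w1) ? 1 : 2);
        sumg += g;
        if (retained) {
          p1acc[i] += w1 / tot;
          p2acc[i] += w2 / tot;
        }
      }
      q = rng.beta(1.0 + sumg, 1.0 + 2.0 * n_ind - sumg);
      if (retained) {
        qacc += q;
        ++nacc;
      }
    }

    qbar[j] = qacc / nacc;
    for (int i = 0; i < n_ind; ++i) {
      const double p1 = p1acc[i] / nacc;
      const double p2 = p2acc[i] / nacc;
      dosage(i, j) = p1 + 2.0 * p2;
      probs[i + static_cast<R_xlen_t>(j) * n_ind] = 1.0 - p1 - p2;
      probs[i + static_cast<R_xlen_t>(j) * n_ind + plane] = p1;
      probs[i + static_cast<R_xlen_t>(j) * n_ind + 2 * plane] = p2;
    }
  }

  probs.attr("dim") = Rcpp::IntegerVector::create(n_ind, n_loci, 3);
  return Rcpp::List::create(Rcpp::Named("dosage") = dosage,
                            Rcpp::Named("probs") = probs,
                            Rcpp::Named("qbar") = qbar);
}
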