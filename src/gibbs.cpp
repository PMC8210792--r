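#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Six-class genotype-frequency Gibbs sampler (NewHybrids-style model,
// unlinked biallelic loci, uniform Dirichlet priors on allele frequencies).
//
// State: class label z_i for every individual; reference-allele
// frequencies pA[l], pB[l] of the two parental gene pools.
// Sweep: (1) sample each z_i from its conditional given frequencies;
// (2) impute the ancestral origin of every allele copy given z and the
// genotype, and sample frequencies from their Beta posteriors.
//
// The sampler runs hot (hundreds of thousands of sweeps over hundreds of
// individuals), so it uses its own small seeded RNG (xoshiro256++) rather
// than paying the R RNG call overhead per draw.

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed + 0x9E3779B97f4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {           // uniform on (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double cached_normal = 0.0;
  bool has_normal = false;
  inline double normal() {         // polar Box-Muller
    if (has_normal) { has_normal = false; return cached_normal; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cached_normal = v * f; has_normal = true;
    return u * f;
  }
  // Marsaglia-Tsang; valid for alpha >= 1 (always true here: 1 + counts)
  double gamma(double alpha) {
    double d = alpha - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do { x = normal(); v = 1.0 + c * x; } while (v <= 0.0);
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
  inline double beta(double a, double b) {
    double x = gamma(a), y = gamma(b);
    return x / (x + y);
  }
};

// phi[z][o]: P(a locus of class z carries o alleles of A origin), o = 2,1,0
const double PHI[6][3] = {
  {1.0,  0.0,  0.0 },   // PureA
  {0.0,  0.0,  1.0 },   // PureB
  {0.0,  1.0,  0.0 },   // F1
  {0.25, 0.5,  0.25},   // F2
  {0.5,  0.5,  0.0 },   // BCA
  {0.0,  0.5,  0.5 }    // BCB
};

} // namespace

// [[Rcpp::export(name = ".gibbs_chain")]]
List gibbs_chain(IntegerMatrix calls, NumericVector prior,
                 int burnin, int sweeps, double seed) {
  const int n = calls.nrow(), L = calls.ncol(), K = 6;
  if (sweeps <= 0) stop("sweeps must be positive");
  if (burnin < 0) stop("burnin must be non-negative");

  // row-major copy, missing = -1
  std::vector<int8_t> G((size_t)n * L);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      int g = calls(i, l);
      G[(size_t)i * L + l] = (g == NA_INTEGER) ? -1 : (int8_t)g;
    }

  Xoshiro rng((uint64_t)seed);
  std::vector<double> pA(L), pB(L);
  std::vector<int> z(n);
  std::vector<double> logT((size_t)L * 3 * K);  // log P(g | z, locus)
  std::vector<double> Pg((size_t)L * 3 * 3);    // P(g | origin o, locus)
  std::vector<double> postCount((size_t)n * K, 0.0);
  std::vector<double> pAsum(L, 0.0), pBsum(L, 0.0);
  std::vector<double> refA(L), totA(L), refB(L), totB(L);
  double logPrior[6];
  for (int k = 0; k < K; ++k)
    logPrior[k] = std::log(prior[k] > 0 ? prior[k] : 1e-300);

  for (int l = 0; l < L; ++l) { pA[l] = rng.unif(); pB[l] = rng.unif(); }
  for (int i = 0; i < n; ++i) z[i] = (int)(rng.unif() * K) % K;

  const int total = burnin + sweeps;
  for (int it = 0; it < total; ++it) {
    // per-locus tables under current frequencies
    for (int l = 0; l < L; ++l) {
      const double pa = pA[l], pb = pB[l], qa = 1.0 - pa, qb = 1.0 - pb;
      // og[o][g]: genotype probs for origin o = 2 (AA), 1 (AB), 0 (BB)
      const double og[3][3] = {
        { qa * qa, 2.0 * pa * qa, pa * pa },
        { qa * qb, pa * qb + qa * pb, pa * pb },
        { qb * qb, 2.0 * pb * qb, pb * pb } };
      for (int g = 0; g < 3; ++g) {
        double *pg = &Pg[((size_t)l * 3 + g) * 3];
        pg[0] = og[0][g]; pg[1] = og[1][g]; pg[2] = og[2][g];
        double *lt = &logT[((size_t)l * 3 + g) * K];
        for (int k = 0; k < K; ++k) {
          double t = PHI[k][0] * pg[0] + PHI[k][1] * pg[1] + PHI[k][2] * pg[2];
          lt[k] = std::log(t > 0 ? t : 1e-300);
        }
      }
    }
    std::fill(refA.begin(), refA.end(), 0.0);
    std::fill(totA.begin(), totA.end(), 0.0);
    std::fill(refB.begin(), refB.end(), 0.0);
    std::fill(totB.begin(), totB.end(), 0.0);

    for (int i = 0; i < n; ++i) {
      const int8_t *gi = &G[(size_t)i * L];
      // (1) sample the class label
      double ll[6] = { logPrior[0], logPrior[1], logPrior[2],
                       logPrior[3], logPrior[4], logPrior[5] };
      for (int l = 0; l < L; ++l) {
        int g = gi[l];
        if (g < 0) continue;
        const double *lt = &logT[((size_t)l * 3 + g) * K];
        ll[0] += lt[0]; ll[1] += lt[1]; ll[2] += lt[2];
        ll[3] += lt[3]; ll[4] += lt[4]; ll[5] += lt[5];
      }
      double m = ll[0];
      for (int k = 1; k < K; ++k) if (ll[k] > m) m = ll[k];
      double w[6], s = 0.0;
      for (int k = 0; k < K; ++k) { w[k] = std::exp(ll[k] - m); s += w[k]; }
      double u = rng.unif() * s, csum = 0.0;
      int pick = K - 1;
      for (int k = 0; k < K; ++k) { csum += w[k]; if (u <= csum) { pick = k; break; } }
      z[i] = pick;
      // (2) impute the ancestral origin of this individual's allele copies
      const double *phi_z = PHI[pick];
      for (int l = 0; l < L; ++l) {
        int g = gi[l];
        if (g < 0) continue;
        const double *pg = &Pg[((size_t)l * 3 + g) * 3];
        double w2 = phi_z[0] * pg[0];   // both copies from pool A
        double w1 = phi_z[1] * pg[1];   // one from each pool
        double ws = w2 + w1 + phi_z[2] * pg[2];
        int o;
        if (ws <= 0) o = 1;
        else {
          double v = rng.unif() * ws;
          o = (v <= w2) ? 2 : ((v <= w2 + w1) ? 1 : 0);
        }
        if (o == 2)      { totA[l] += 2.0; refA[l] += g; }
        else if (o == 0) { totB[l] += 2.0; refB[l] += g; }
        else {
          totA[l] += 1.0; totB[l] += 1.0;
          if (g == 2) { refA[l] += 1.0; refB[l] += 1.0; }
          else if (g == 1) {
            // which of the two copies carries the reference allele?
            double wa = pA[l] * (1.0 - pB[l]);
            double wb = (1.0 - pA[l]) * pB[l];
            double tw = wa + wb;
            bool toA = (tw <= 0) ? (rng.unif() < 0.5)
                                 : (rng.unif() * tw <= wa);
            if (toA) refA[l] += 1.0; else refB[l] += 1.0;
          }
        }
      }
    }
    // (3) frequencies from their Beta posteriors (uniform priors)
    for (int l = 0; l < L; ++l) {
      pA[l] = rng.beta(1.0 + refA[l], 1.0 + totA[l] - refA[l]);
      pB[l] = rng.beta(1.0 + refB[l], 1.0 + totB[l] - refB[l]);
    }
    if (it >= burnin) {
      for (int i = 0; i < n; ++i) postCount[(size_t)i * K + z[i]] += 1.0;
      for (int l = 0; l < L; ++l) { pAsum[l] += pA[l]; pBsum[l] += pB[l]; }
    }
  }

  NumericMatrix post(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      post(i, k) = postCount[(size_t)i * K + k] / sweeps;
  NumericVector fA(L), fB(L);
  for (int l = 0; l < L; ++l) {
    fA[l] = pAsum[l] / sweeps;
    fB[l] = pBsum[l] / sweeps;
  }
  return List::create(_["posterior"] = post, _["freq_A"] = fA,
                      _["freq_B"] = fB);
}
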