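#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Diploid Li-Stephens forward-backward over an ordered-pair state space of
// K reference haplotypes (K^2 states). Each haplotype switches template
// between adjacent sites with probability r = 1 - exp(-n_eff * dcm / K),
// landing uniformly on any of the K haplotypes; the two haplotypes move
// independently, so the transition kernel factorizes and each update is
// O(K^2) via row/column sums rather than O(K^4).
//
// Emission at a site for state (h1, h2) depends only on the number of
// alternate template alleles c = a(h1) + a(h2): each copied allele miscopies
// with probability mu, so
//   e(c) = sum_g lik(g) * P(emitted genotype g | c, mu).
//
// Returns the L x 3 per-site posterior genotype distribution
//   P(g | data) = sum_c w_c * lik(g) T[c][g] / e(c),
// where w_c is the posterior mass of states in class c.
//
// Inner loops are written against contiguous per-site buffers (emission
// values gathered per haplotype, alleles as doubles) so they vectorize.

// [[Rcpp::export(name = ".diploid_ls_posteriors")]]
NumericMatrix diploid_ls_posteriors(NumericMatrix lik, IntegerMatrix alleles,
                                    NumericVector cm, double n_eff, double mu,
                                    double min_floor) {
  const int K = alleles.nrow();
  const int L = alleles.ncol();
  if (lik.nrow() != L || lik.ncol() != 3)
    stop("likelihood matrix must be L x 3 and aligned with the panel sites");
  if (cm.size() != L) stop("cm positions must align with panel sites");
  if (K < 1) stop("panel must contain at least one haplotype");

  // genotype-given-class miscopy table T[c][g]
  double T[3][3];
  T[0][0] = (1 - mu) * (1 - mu); T[0][1] = 2 * mu * (1 - mu); T[0][2] = mu * mu;
  T[1][0] = mu * (1 - mu);
  T[1][1] = (1 - mu) * (1 - mu) + mu * mu;
  T[1][2] = mu * (1 - mu);
  T[2][0] = mu * mu; T[2][1] = 2 * mu * (1 - mu); T[2][2] = (1 - mu) * (1 - mu);

  const int KK = K * K;
  std::vector<double> fwd((size_t)L * KK);
  std::vector<double> esite((size_t)L * 3);
  std::vector<double> rvec(L, 0.0);
  const int* amat = INTEGER(alleles);

  for (int s = 0; s < L; ++s) {
    for (int c = 0; c < 3; ++c) {
      double e = lik(s, 0) * T[c][0] + lik(s, 1) * T[c][1] + lik(s, 2) * T[c][2];
      esite[(size_t)s * 3 + c] = std::max(e, min_floor);
    }
    if (s > 0) {
      double d = cm[s] - cm[s - 1];
      if (d < 0) stop("cm positions must be non-decreasing");
      rvec[s] = 1.0 - std::exp(-n_eff * d / K);
    }
  }

  std::vector<double> rowsum(K), colsum(K);
  std::vector<double> e0(K), e1(K), av(K);

  // gather per-site emission vectors: e0[j] = e(a_j), e1[j] = e(1 + a_j)
  auto load_site = [&](int s) {
    const double* es = &esite[(size_t)s * 3];
    const int* as = amat + (size_t)s * K;
    for (int j = 0; j < K; ++j) {
      const int a = as[j];
      e0[j] = es[a];
      e1[j] = es[a + 1];
      av[j] = (double)a;
    }
  };

  // forward, rescaled to sum 1 at each site
  load_site(0);
  {
    double* A = &fwd[0];
    double tot = 0.0;
    for (int i = 0; i < K; ++i) {
      const double* er = amat[i] ? e1.data() : e0.data();
      double* Ai = A + (size_t)i * K;
      double rs = 0.0;
      for (int j = 0; j < K; ++j) {
        Ai[j] = er[j];
        rs += er[j];
      }
      tot += rs;
    }
    for (int x = 0; x < KK; ++x) A[x] /= tot;
  }
  for (int s = 1; s < L; ++s) {
    const double* A = &fwd[(size_t)(s - 1) * KK];
    double* B = &fwd[(size_t)s * KK];
    const double r = rvec[s];
    const double q = 1.0 - r;
    const double qq = q * q;
    const double rk = r / K;
    const double qrk = q * rk;
    std::fill(colsum.begin(), colsum.end(), 0.0);
    for (int i = 0; i < K; ++i) {
      const double* Ai = A + (size_t)i * K;
      double rs = 0.0;
      for (int j = 0; j < K; ++j) {
        rs += Ai[j];
        colsum[j] += Ai[j];
      }
      rowsum[i] = rs;
    }
    load_site(s);
    const int* as = amat + (size_t)s * K;
    double tot = 0.0;
    for (int i = 0; i < K; ++i) {
      const double ri = qrk * rowsum[i] + rk * rk; // forward mass is 1
      const double* er = as[i] ? e1.data() : e0.data();
      const double* Ai = A + (size_t)i * K;
      double* Bi = B + (size_t)i * K;
      double rs = 0.0;
      for (int j = 0; j < K; ++j) {
        const double v = (qq * Ai[j] + ri + qrk * colsum[j]) * er[j];
        Bi[j] = v;
        rs += v;
      }
      tot += rs;
    }
    if (!(tot > 0)) stop("forward pass underflow; raise min_posterior_floor");
    const double inv = 1.0 / tot;
    for (int x = 0; x < KK; ++x) B[x] *= inv;
  }

  // backward (streamed) + posterior combine
  NumericMatrix post(L, 3);
  std::vector<double> bwd(KK, 1.0 / KK), work(KK);
  for (int s = L - 1; s >= 0; --s) {
    const double* A = &fwd[(size_t)s * KK];
    const double* es = &esite[(size_t)s * 3];
    const int* as = amat + (size_t)s * K;
    load_site(s);
    // class weights of gamma = A .* bwd, using sum(g) and sum(g * a_j)
    double w[3] = {0.0, 0.0, 0.0};
    for (int i = 0; i < K; ++i) {
      const double* Ai = A + (size_t)i * K;
      const double* Bi = &bwd[(size_t)i * K];
      double sg = 0.0, sga = 0.0;
      for (int j = 0; j < K; ++j) {
        const double g = Ai[j] * Bi[j];
        sg += g;
        sga += g * av[j];
      }
      const int ai = as[i];
      w[ai] += sg - sga;
      w[ai + 1] += sga;
    }
    const double tot = w[0] + w[1] + w[2];
    if (!(tot > 0)) stop("posterior underflow; raise min_posterior_floor");
    double pg[3];
    double ptot = 0.0;
    for (int g = 0; g < 3; ++g) {
      double v = 0.0;
      for (int c = 0; c < 3; ++c)
        v += (w[c] / tot) * lik(s, g) * T[c][g] / es[c];
      pg[g] = v;
      ptot += v;
    }
    for (int g = 0; g < 3; ++g) post(s, g) = pg[g] / ptot;

    if (s == 0) break;
    // step bwd from site s to s-1: M = e_s .* bwd, then transition-combine
    const double r = rvec[s];
    const double q = 1.0 - r;
    const double qq = q * q;
    const double rk = r / K;
    const double qrk = q * rk;
    std::fill(colsum.begin(), colsum.end(), 0.0);
    double msum = 0.0;
    for (int i = 0; i < K; ++i) {
      const double* er = as[i] ? e1.data() : e0.data();
      double* Wi = &work[(size_t)i * K];
      const double* Bi = &bwd[(size_t)i * K];
      double rs = 0.0;
      for (int j = 0; j < K; ++j) {
        const double m = er[j] * Bi[j];
        Wi[j] = m;
        rs += m;
        colsum[j] += m;
      }
      rowsum[i] = rs;
      msum += rs;
    }
    double btot = 0.0;
    for (int i = 0; i < K; ++i) {
      const double ri = qrk * rowsum[i] + rk * rk * msum;
      const double* Wi = &work[(size_t)i * K];
      double* Bi = &bwd[(size_t)i * K];
      double rs = 0.0;
      for (int j = 0; j < K; ++j) {
        const double v = qq * Wi[j] + ri + qrk * colsum[j];
        Bi[j] = v;
        rs += v;
      }
      btot += rs;
    }
    if (!(btot > 0)) stop("backward pass underflow; raise min_posterior_floor");
    const double inv = 1.0 / btot;
    for (int x = 0; x < KK; ++x) bwd[x] *= inv;
  }

  return post;
}
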