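// Collapsed Gibbs sampler for the extended latent Dirichlet allocation
// deconvolution model.  Each RNA-Seq read (token) carries a gene id and a
// sample id; the sampler resamples its latent cell-type assignment from the
// collapsed conditional
//
//   p(t) propto (n_gt + beta_g) / (n_t + sum(beta)) * (n_it + alpha_t)
//
// where counts exclude the token itself.  Gene-length and cell-size
// corrections are applied outside the sampler (in R) because they compose
// multiplicatively with the categorical parameters and leave the read-space
// sufficient statistics untouched.
//
// Tokens are sample-major (all reads of sample 0, then sample 1, ...), so
// the sample index is implied by per-sample offsets and the sample-side
// factor w[t] = (n_it + alpha_t) / (n_t + sum beta) is cached and updated
// incrementally.  The token loop is instantiated per compile-time T for the
// common range so the probability loop and the binary search fully unroll.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// splitmix64 finalizer: the counter-based RNG.  A draw for (seed, sweep,
// token) is a pure hash, so trajectories are reproducible and independent of
// how sweeps are chunked across calls.
static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return x;
}

static inline double unif_hash(uint64_t sweep_base, uint64_t token) {
  uint64_t x = mix64(sweep_base ^ ((token + 1ULL) * 0x9E3779B97F4A7C15ULL));
  // 53-bit mantissa in (0, 1)
  return (static_cast<double>(x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline uint64_t sweep_base(uint64_t seed, uint64_t sweep) {
  return mix64(seed ^ (sweep * 0xD1B54A32D192ED03ULL));
}

// [[Rcpp::export]]
IntegerVector cpp_init_assignments(int n_tokens, int T, double seed) {
  IntegerVector z(n_tokens);
  uint64_t base = sweep_base(static_cast<uint64_t>(seed), 0ULL);
  for (int j = 0; j < n_tokens; ++j) {
    int t = static_cast<int>(unif_hash(base, static_cast<uint64_t>(j)) * T);
    if (t >= T) t = T - 1;
    z[j] = t; // 0-based
  }
  return z;
}

struct SweepArgs {
  const int* tg;              // 0-based gene per token
  const R_xlen_t* off;        // per-sample token offsets, length M + 1
  int* z;                     // 0-based assignments
  int* ngt;                   // G x T, gene-major rows
  int* nit;                   // M x T, sample-major rows
  int* nt;
  double* inv_nt;             // 1 / (nt + sum_beta), kept in sync
  const double* a;            // alpha, length T
  const double* b;            // beta, length G
  double sum_beta;
  int G, M, T;
};

template <int TT>
static void sweep_once(const SweepArgs& s, uint64_t base) {
  const int T = (TT > 0) ? TT : s.T;
  double cum_buf[TT > 0 ? TT : 1];
  std::vector<double> cum_dyn;
  double* cum = cum_buf;
  std::vector<double> w(T);
  if (TT == 0) { cum_dyn.resize(T); cum = cum_dyn.data(); }

  for (int i = 0; i < s.M; ++i) {
    int* nit_row = s.nit + static_cast<size_t>(i) * T;
    for (int t = 0; t < T; ++t) w[t] = s.inv_nt[t] * (nit_row[t] + s.a[t]);
    const R_xlen_t jend = s.off[i + 1];
    for (R_xlen_t j = s.off[i]; j < jend; ++j) {
      const int g = s.tg[j];
      const int told = s.z[j];
      int* ngt_row = s.ngt + static_cast<size_t>(g) * T;

      // remove token from counts
      if (--ngt_row[told] < 0 || --nit_row[told] < 0)
        stop("internal consistency error: negative count after decrement");
      --s.nt[told];
      const double inv_old = s.inv_nt[told];
      const double w_old = w[told];
      s.inv_nt[told] = 1.0 / (s.nt[told] + s.sum_beta);
      w[told] = s.inv_nt[told] * (nit_row[told] + s.a[told]);

      // cumulative collapsed conditional
      const double bg = s.b[g];
      double acc = 0.0;
      for (int t = 0; t < T; ++t) {
        acc += (ngt_row[t] + bg) * w[t];
        cum[t] = acc;
      }
      const double u = unif_hash(base, static_cast<uint64_t>(j)) * acc;

      // binary search for the first cum[t] > u
      int lo = 0, hi = T - 1;
      while (lo < hi) {
        const int mid = (lo + hi) >> 1;
        if (cum[mid] > u) hi = mid; else lo = mid + 1;
      }
      const int tnew = lo;

      ++ngt_row[tnew];
      ++nit_row[tnew];
      ++s.nt[tnew];
      if (tnew == told) {          // net count change is zero: restore
        s.inv_nt[tnew] = inv_old;
        w[tnew] = w_old;
      } else {
        s.inv_nt[tnew] = 1.0 / (s.nt[tnew] + s.sum_beta);
        w[tnew] = s.inv_nt[tnew] * (nit_row[tnew] + s.a[tnew]);
      }
      s.z[j] = tnew;
    }
  }
}

typedef void (*sweep_fn)(const SweepArgs&, uint64_t);

static sweep_fn pick_sweep(int T) {
  switch (T) {
    case 1: return sweep_once<1>;   case 2: return sweep_once<2>;
    case 3: return sweep_once<3>;   case 4: return sweep_once<4>;
    case 5: return sweep_once<5>;   case 6: return sweep_once<6>;
    case 7: return sweep_once<7>;   case 8: return sweep_once<8>;
    case 9: return sweep_once<9>;   case 10: return sweep_once<10>;
    case 11: return sweep_once<11>; case 12: return sweep_once<12>;
    case 13: return sweep_once<13>; case 14: return sweep_once<14>;
    case 15: return sweep_once<15>; case 16: return sweep_once<16>;
    default: return sweep_once<0>;  // runtime-T fallback
  }
}

// gene part log P(g | c, beta): product over types of Dirichlet-multinomial
// beta-function ratios.  Returned separately from the allocation part
// log P(c | alpha) because the gene part alone is the model-evidence score
// used for selecting T.
static double loglik_gene(const std::vector<int>& ngt,
                          const std::vector<int>& nt,
                          int G, int T, const double* beta,
                          double sum_beta, double log_const_gene) {
  double ll = log_const_gene;
  for (int g = 0; g < G; ++g) {
    const int* row = &ngt[static_cast<size_t>(g) * T];
    const double bg = beta[g];
    for (int t = 0; t < T; ++t) ll += std::lgamma(row[t] + bg);
  }
  for (int t = 0; t < T; ++t) ll -= std::lgamma(nt[t] + sum_beta);
  return ll;
}

static double loglik_alloc(const std::vector<int>& nit,
                           const std::vector<R_xlen_t>& off,
                           int M, int T, const double* alpha,
                           double sum_alpha, double log_const_alloc) {
  double ll = log_const_alloc;
  for (int i = 0; i < M; ++i) {
    const int* row = &nit[static_cast<size_t>(i) * T];
    for (int t = 0; t < T; ++t) ll += std::lgamma(row[t] + alpha[t]);
    ll -= std::lgamma(static_cast<double>(off[i + 1] - off[i]) + sum_alpha);
  }
  return ll;
}

// Run `n_sweeps` full sweeps starting from sweep index `sweep_from + 1`.
// token_gene is 0-based and sample-major; Ni gives reads per sample (so the
// sample of token j is implied); z is 0-based.  Returns final sufficient
// statistics, assignments, the per-sweep collapsed log-likelihood trace and
// (optionally) post-burn-in averaged counts.
// [[Rcpp::export]]
List cpp_gibbs_run(IntegerVector token_gene, IntegerVector Ni,
                   IntegerVector z_in, int G, int T,
                   NumericVector alpha, NumericVector beta,
                   double seed, int sweep_from, int n_sweeps,
                   int burn_in, bool average, bool trace) {
  const R_xlen_t R = token_gene.size();
  const int M = Ni.size();
  if (z_in.size() != R) stop("z must have one entry per token");
  if (alpha.size() != T) stop("alpha must have length T");
  if (beta.size() != G) stop("beta must have length G");

  std::vector<R_xlen_t> off(M + 1, 0);
  for (int i = 0; i < M; ++i) off[i + 1] = off[i] + Ni[i];
  if (off[M] != R) stop("sum(Ni) must equal the number of tokens");

  std::vector<int> z(z_in.begin(), z_in.end());
  std::vector<int> ngt(static_cast<size_t>(G) * T, 0); // gene-major rows
  std::vector<int> nit(static_cast<size_t>(M) * T, 0);
  std::vector<int> nt(T, 0);

  const int* tg = INTEGER(token_gene);
  for (int i = 0; i < M; ++i) {
    for (R_xlen_t j = off[i]; j < off[i + 1]; ++j) {
      const int g = tg[j], t = z[j];
      if (g < 0 || g >= G || t < 0 || t >= T)
        stop("token/assignment index out of range");
      ++ngt[static_cast<size_t>(g) * T + t];
      ++nit[static_cast<size_t>(i) * T + t];
      ++nt[t];
    }
  }

  double sum_alpha = 0.0, sum_beta = 0.0, lg_alpha = 0.0, lg_beta = 0.0;
  for (int t = 0; t < T; ++t) { sum_alpha += alpha[t]; lg_alpha += std::lgamma(alpha[t]); }
  for (int g = 0; g < G; ++g) { sum_beta += beta[g]; lg_beta += std::lgamma(beta[g]); }
  const double log_const_gene = -T * (lg_beta - std::lgamma(sum_beta));
  const double log_const_alloc = -M * (lg_alpha - std::lgamma(sum_alpha));

  std::vector<double> inv_nt(T);
  for (int t = 0; t < T; ++t) inv_nt[t] = 1.0 / (nt[t] + sum_beta);

  NumericVector ll_gene_trace(trace ? n_sweeps : 0);
  NumericVector ll_alloc_trace(trace ? n_sweeps : 0);
  std::vector<double> avg_ngt, avg_nit;
  int n_avg = 0;
  if (average) {
    avg_ngt.assign(ngt.size(), 0.0);
    avg_nit.assign(nit.size(), 0.0);
  }

  SweepArgs args;
  args.tg = tg; args.off = off.data(); args.z = z.data();
  args.ngt = ngt.data(); args.nit = nit.data(); args.nt = nt.data();
  args.inv_nt = inv_nt.data(); args.a = REAL(alpha); args.b = REAL(beta);
  args.sum_beta = sum_beta; args.G = G; args.M = M; args.T = T;
  const sweep_fn sweep = pick_sweep(T);
  const uint64_t useed = static_cast<uint64_t>(seed);

  for (int s = 1; s <= n_sweeps; ++s) {
    sweep(args, sweep_base(useed, static_cast<uint64_t>(sweep_from + s)));
    if (trace) {
      ll_gene_trace[s - 1] = loglik_gene(ngt, nt, G, T, REAL(beta),
                                         sum_beta, log_const_gene);
      ll_alloc_trace[s - 1] = loglik_alloc(nit, off, M, T, REAL(alpha),
                                           sum_alpha, log_const_alloc);
    }
    if (average && sweep_from + s > burn_in) {
      for (size_t k = 0; k < ngt.size(); ++k) avg_ngt[k] += ngt[k];
      for (size_t k = 0; k < nit.size(); ++k) avg_nit[k] += nit[k];
      ++n_avg;
    }
    if ((s & 15) == 0) Rcpp::checkUserInterrupt();
  }

  // copy out as G x T and M x T matrices (row-major internal -> col-major R)
  IntegerMatrix ngt_out(G, T), nit_out(M, T);
  for (int g = 0; g < G; ++g)
    for (int t = 0; t < T; ++t) ngt_out(g, t) = ngt[static_cast<size_t>(g) * T + t];
  for (int i = 0; i < M; ++i)
    for (int t = 0; t < T; ++t) nit_out(i, t) = nit[static_cast<size_t>(i) * T + t];

  List out = List::create(
      _["ngt"] = ngt_out, _["nit"] = nit_out,
      _["nt"] = IntegerVector(nt.begin(), nt.end()),
      _["z"] = IntegerVector(z.begin(), z.end()),
      _["loglik_gene"] = ll_gene_trace,
      _["loglik_alloc"] = ll_alloc_trace,
      _["sweep"] = sweep_from + n_sweeps);
  if (average && n_avg > 0) {
    NumericMatrix angt(G, T), anit(M, T);
    for (int g = 0; g < G; ++g)
      for (int t = 0; t < T; ++t)
        angt(g, t) = avg_ngt[static_cast<size_t>(g) * T + t] / n_avg;
    for (int i = 0; i < M; ++i)
      for (int t = 0; t < T; ++t)
        anit(i, t) = avg_nit[static_cast<size_t>(i) * T + t] / n_avg;
    out["avg_ngt"] = angt;
    out["avg_nit"] = anit;
    out["n_averaged"] = n_avg;
  }
  return out;
}
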