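#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Permutation machinery for the significance index. The shuffle uses a
// self-contained splitmix64 generator rather than std::shuffle /
// uniform_int_distribution, both of which are implementation-defined:
// results must be bit-identical across platforms and thread counts, so each
// (seed, iteration, replicate) triple owns an independent stream.

static inline uint64_t sm64_next(uint64_t& state) {
  state += 0x9E3779B97F4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t mix(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t stream_state(double seed, double offset, double rep) {
  uint64_t s = (uint64_t)((int64_t)seed);
  uint64_t o = (uint64_t)((int64_t)offset);
  uint64_t r = (uint64_t)((int64_t)rep);
  return mix(s + 0x9E3779B97F4A7C15ULL * (o + 1)) ^
         mix(r + 0x94D049BB133111EBULL);
}

// Independent Fisher-Yates shuffle of every column (each gene's values are
// re-assigned across cells with its own random permutation).
static void shuffle_columns(arma::mat& Y, uint64_t state) {
  const arma::uword m = Y.n_rows, n = Y.n_cols;
  for (arma::uword j = 0; j < n; ++j) {
    double* col = Y.colptr(j);
    for (arma::uword i = m - 1; i > 0; --i) {
      uint64_t rnd = sm64_next(state);
      arma::uword k = (arma::uword)(rnd % (uint64_t)(i + 1));
      double tmp = col[i];
      col[i] = col[k];
      col[k] = tmp;
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".permute_columns_cpp")]]
arma::mat permute_columns_cpp(const arma::mat& Y, double seed, double offset,
                              double rep) {
  arma::mat Yp = Y;
  shuffle_columns(Yp, stream_state(seed, offset, rep));
  return Yp;
}

// Null statistics for the significance index: for each replicate, permute
// each column of Y, project out the known design (U = orthonormal basis of
// X), and return lambda_1^2 / sum_k lambda_k^2 of the permuted residual.
// The denominator is the squared Frobenius norm (exact for any SVD mode).
//' @noRd
// [[Rcpp::export(name = ".si_null_stats_cpp")]]
arma::vec si_null_stats_cpp(const arma::mat& Y, const arma::mat& U, int num_p,
                            double seed, double offset) {
  arma::vec out(num_p);
  for (int r = 0; r < num_p; ++r) {
    arma::mat Yp = Y;
    shuffle_columns(Yp, stream_state(seed, offset, (double)r));
    arma::mat Z = U.t() * Yp;          // p x n
    arma::mat Rm = Yp - U * Z;         // residual, m x n
    double fro2 = arma::accu(arma::square(Rm));
    if (fro2 <= 0.0) {
      out(r) = 0.0;
      continue;
    }
    arma::mat G = Rm * Rm.t();         // m x m Gram
    arma::vec ev;
    arma::eig_sym(ev, G);
    out(r) = ev.max() / fro2;
  }
  return out;
}
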