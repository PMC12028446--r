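// Gauss-Newton inner terms for the Levenberg-Marquardt trainer.
//
// For a feed-forward network with outputs y[i, k], the error Jacobian J has
// one row per (sample, output-unit) pair. Columns belonging to the final
// layer's weights are nonzero only within the output unit's own slice, so
// J'J and J'e are accumulated from a dense "shared" block (all lower-layer
// parameters) plus small per-output "private" blocks instead of forming the
// full J. This is algebraically identical to crossprod(J) on the full
// Jacobian (the R reference implementation, used as the oracle in tests).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat act_apply(const mat& Z, int code) {
  switch (code) {
    case 0: return tanh(Z);                 // tanh
    case 1: return 1.0 / (1.0 + exp(-Z));   // logistic
    default: return Z;                      // linear
  }
}

static mat act_deriv(const mat& A, int code) {
  switch (code) {
    case 0: return 1.0 - square(A);
    case 1: return A % (1.0 - A);
    default: return ones<mat>(A.n_rows, A.n_cols);
  }
}

// layers: list of list(W, b); acts: integer codes per layer;
// X: inputs; T: targets; use_bias: flag.
// Returns JtJ, Jte, E (residual matrix), E_D.
// [[Rcpp::export]]
Rcpp::List gn_terms(Rcpp::List layers, Rcpp::IntegerVector acts,
                    const arma::mat& X, const arma::mat& T,
                    bool use_bias) {
  const int L = layers.size();
  const uword n = X.n_rows;

  std::vector<mat> W(L);
  std::vector<vec> b(L);
  for (int l = 0; l < L; ++l) {
    Rcpp::List lay = layers[l];
    W[l] = Rcpp::as<mat>(lay["W"]);
    b[l] = Rcpp::as<vec>(lay["b"]);
  }

  // forward pass keeping activations and derivatives
  std::vector<mat> A(L + 1), D(L);
  A[0] = X;
  for (int l = 0; l < L; ++l) {
    mat Z = A[l] * W[l];
    if (use_bias) Z.each_row() += b[l].t();
    A[l + 1] = act_apply(Z, acts[l]);
    D[l] = act_deriv(A[l + 1], acts[l]);
  }
  const int K = W[L - 1].n_cols;          // output width
  mat E = A[L] - T;
  const double E_D = accu(square(E));

  // parameter layout: per layer, vec(W) then b
  uvec p_off(L);
  uword pos = 0;
  for (int l = 0; l < L; ++l) {
    p_off[l] = pos;
    pos += W[l].n_rows * W[l].n_cols + (use_bias ? W[l].n_cols : 0);
  }
  const uword Np = pos;
  // shared columns = all parameters of layers 1..L-1
  const uword S = p_off[L - 1];
  const uword nLm1 = W[L - 1].n_rows;     // width of last hidden layer
  const uword npriv = nLm1 + (use_bias ? 1 : 0);

  mat JtJ(Np, Np, fill::zeros);
  vec Jte(Np, fill::zeros);

  mat Sh;                                  // stacked shared blocks, (K*n) x S
  if (S > 0) Sh.zeros(K * n, S);

  mat Pr(n, npriv);
  for (int k = 0; k < K; ++k) {
    const vec dL = D[L - 1].col(k);
    // private block: d y_k / d W_L[, k] = A[L-1] * dL ; d y_k / d b_L[k] = dL
    Pr.cols(0, nLm1 - 1) = A[L - 1].each_col() % dL;
    if (use_bias) Pr.col(nLm1) = dL;

    if (S > 0) {
      // backprop the sensitivity through the lower layers
      mat delta = dL * W[L - 1].col(k).t();      // n x n_{L-1}
      for (int l = L - 2; l >= 0; --l) {
        delta %= D[l];                            // now wrt Z_l
        const uword nin = W[l].n_rows, nout = W[l].n_cols;
        uword off = p_off[l];
        for (uword j = 0; j < nout; ++j) {
          for (uword m = 0; m < nin; ++m) {
            Sh.col(off + j * nin + m).subvec(k * n, (k + 1) * n - 1) =
              A[l].col(m) % delta.col(j);
          }
        }
        if (use_bias) {
          for (uword j = 0; j < nout; ++j) {
            Sh.col(off + nin * nout + j).subvec(k * n, (k + 1) * n - 1) =
              delta.col(j);
          }
        }
        if (l > 0) delta *= W[l].t();
      }
      const mat Sh_k = Sh.rows(k * n, (k + 1) * n - 1);
      // shared x private cross block and private diagonal block
      mat cross = Sh_k.t() * Pr;                  // S x npriv
      uvec pcols(npriv);
      for (uword j = 0; j < nLm1; ++j) pcols[j] = p_off[L - 1] + k * nLm1 + j;
      if (use_bias) pcols[nLm1] = p_off[L - 1] + nLm1 * K + k;
      JtJ.submat(regspace<uvec>(0, S - 1), pcols) += cross;
      JtJ.submat(pcols, regspace<uvec>(0, S - 1)) += cross.t();
      JtJ.submat(pcols, pcols) += Pr.t() * Pr;
      Jte.elem(pcols) += Pr.t() * E.col(k);
    } else {
      uvec pcols(npriv);
      for (uword j = 0; j < nLm1; ++j) pcols[j] = k * nLm1 + j;
      if (use_bias) pcols[nLm1] = nLm1 * K + k;
      JtJ.submat(pcols, pcols) += Pr.t() * Pr;
      Jte.elem(pcols) += Pr.t() * E.col(k);
    }
  }
  if (S > 0) {
    JtJ.submat(0, 0, S - 1, S - 1) = Sh.t() * Sh;  // one big syrk
    Jte.subvec(0, S - 1) = Sh.t() * vectorise(E);
  }

  return Rcpp::List::create(Rcpp::Named("JtJ") = JtJ,
                            Rcpp::Named("Jte") = Jte,
                            Rcpp::Named("E_D") = E_D);
}

// Zero-phase IIR filtering: odd (point-reflected) edge padding, one forward
// and one backward pass of the difference equation (direct form II
// transposed), returning the central n samples.
// [[Rcpp::export]]
arma::vec iir_filtfilt(const arma::vec& b_in, const arma::vec& a_in,
                       const arma::vec& x, int npad) {
  vec b = b_in / a_in[0];
  vec a = a_in / a_in[0];
  const uword n = x.n_elem;
  const uword order = std::max(b.n_elem, a.n_elem) - 1;
  vec bb(order + 1, fill::zeros), aa(order + 1, fill::zeros);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;

  auto filt = [&](const vec& u) {
    vec y(u.n_elem);
    vec z(order, fill::zeros);
    for (uword i = 0; i < u.n_elem; ++i) {
      const double xi = u[i];
      const double yi = bb[0] * xi + (order ? z[0] : 0.0);
      for (uword k = 1; k < order; ++k) {
        z[k - 1] = bb[k] * xi + z[k] - aa[k] * yi;
      }
      if (order) z[order - 1] = bb[order] * xi - aa[order] * yi;
      y[i] = yi;
    }
    return y;
  };

  vec padded(n + 2 * npad);
  for (int i = 0; i < npad; ++i) {
    padded[i] = 2.0 * x[0] - x[npad - i];
    padded[npad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  }
  padded.subvec(npad, npad + n - 1) = x;

  vec fwd = filt(padded);
  vec bwd = reverse(filt(reverse(fwd)));
  return bwd.subvec(npad, npad + n - 1);
}
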