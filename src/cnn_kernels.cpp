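// Compute kernels for the height-1 convolution/pooling stage and the Adam
// parameter update. Activations are stored transposed (feature planes x
// positions) so that a "position" (one batch row at one time step) is a
// contiguous column; im2col gathers and their scatter adjoints are then
// plain column copies. Position p = b * t_len + t where b indexes the
// (sample, electrode-row) pairs of the batch.
//
// All large outputs are written into caller-provided R matrices (reused
// across mini-batches by the training loop), so the hot path performs no
// large allocations and nothing big is copied across the R/C++ boundary.
//
// idx is the (t_out x k) window map: 1-based input time index per output
// step and kernel offset, 0 marking zero padding.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#if defined(__GLIBC__)
#include <malloc.h>
#endif
using namespace Rcpp;

static arma::mat view(NumericMatrix m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
static arma::mat cview(const NumericMatrix m) {
  return arma::mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(), false,
                   true);
}

// Forward conv: fills P_buf ((k*c_in) x (n_b*t_out)) and Z_buf
// (f x (n_b*t_out)) in place.
// [[Rcpp::export]]
void cpp_conv_forward(const NumericMatrix A, const NumericMatrix W,
                      const arma::vec& b, const IntegerMatrix idx,
                      const int n_b, const int t_in, const bool relu,
                      NumericMatrix P_buf, NumericMatrix Z_buf) {
  const int t_out = idx.nrow(), k = idx.ncol();
  const arma::uword c_in = A.nrow();
  const arma::mat Av = cview(A), Wv = cview(W);
  arma::mat P = view(P_buf);
  for (int bi = 0; bi < n_b; ++bi) {
    const arma::uword col0 = (arma::uword)bi * t_out;
    const arma::uword src0 = (arma::uword)bi * t_in;
    for (int t = 0; t < t_out; ++t) {
      double* dst = P.colptr(col0 + t);
      for (int j = 0; j < k; ++j) {
        const int s = idx(t, j);
        if (s > 0)
          std::memcpy(dst + (arma::uword)j * c_in, Av.colptr(src0 + s - 1),
                      c_in * sizeof(double));
        else
          std::memset(dst + (arma::uword)j * c_in, 0, c_in * sizeof(double));
      }
    }
  }
  arma::mat Z = view(Z_buf);
  Z = Wv.t() * P;
  Z.each_col() += b;
  if (relu) {
    double* z = Z.memptr();
    const arma::uword n = Z.n_elem;
    for (arma::uword i = 0; i < n; ++i) if (z[i] < 0) z[i] = 0;
  }
}

// Backward conv. dA (gradient wrt this layer's post-activation output) is
// masked IN PLACE through the ReLU; dW_buf/db_buf receive the weight
// gradients; when need_input_grad, dP_buf and dAprev_buf receive the
// patch-gradient and its scatter (gradient wrt the layer input).
// [[Rcpp::export]]
void cpp_conv_backward(const NumericMatrix P, const NumericMatrix A_out,
                       const NumericMatrix W, NumericMatrix dA,
                       const IntegerMatrix idx, const int n_b,
                       const int t_in, const bool relu,
                       NumericMatrix dW_buf, NumericVector db_buf,
                       const bool need_input_grad, NumericMatrix dP_buf,
                       NumericMatrix dAprev_buf) {
  const int t_out = idx.nrow(), k = idx.ncol();
  const arma::mat Pv = cview(P), Wv = cview(W);
  arma::mat dZ = view(dA);
  if (relu) {
    const double* a = A_out.begin();
    double* z = dZ.memptr();
    const arma::uword n = dZ.n_elem;
    for (arma::uword i = 0; i < n; ++i) if (a[i] <= 0) z[i] = 0;
  }
  arma::mat dW = view(dW_buf);
  dW = Pv * dZ.t();
  arma::vec db(db_buf.begin(), db_buf.size(), false, true);
  db = arma::sum(dZ, 1);
  if (!need_input_grad) return;
  const arma::uword c_in = W.nrow() / k;
  arma::mat dP = view(dP_buf);
  dP = Wv * dZ;
  arma::mat dAprev = view(dAprev_buf);
  dAprev.zeros();
  for (int bi = 0; bi < n_b; ++bi) {
    const arma::uword col0 = (arma::uword)bi * t_out;
    const arma::uword dst0 = (arma::uword)bi * t_in;
    for (int t = 0; t < t_out; ++t) {
      const double* src = dP.colptr(col0 + t);
      for (int j = 0; j < k; ++j) {
        const int s = idx(t, j);
        if (s > 0) {
          double* dst = dAprev.colptr(dst0 + s - 1);
          const double* blk = src + (arma::uword)j * c_in;
          for (arma::uword c = 0; c < c_in; ++c) dst[c] += blk[c];
        }
      }
    }
  }
}

// Max pooling: fills out_buf and which_buf (winning kernel offset, 1-based;
// ties keep the earliest offset).
// [[Rcpp::export]]
void cpp_maxpool_forward(const NumericMatrix A, const IntegerMatrix idx,
                         const int n_b, const int t_in,
                         NumericMatrix out_buf, IntegerMatrix which_buf) {
  const int t_out = idx.nrow(), k = idx.ncol();
  const int c = A.nrow();
  const arma::mat Av = cview(A);
  arma::mat out = view(out_buf);
  for (int bi = 0; bi < n_b; ++bi) {
    const arma::uword col0 = (arma::uword)bi * t_out;
    const arma::uword src0 = (arma::uword)bi * t_in;
    for (int t = 0; t < t_out; ++t) {
      double* o = out.colptr(col0 + t);
      int* w = &which_buf(0, col0 + t);
      for (int cc = 0; cc < c; ++cc) o[cc] = -arma::datum::inf;
      for (int j = 0; j < k; ++j) {
        const int s = idx(t, j);
        if (s <= 0) continue;
        const double* a = Av.colptr(src0 + s - 1);
        for (int cc = 0; cc < c; ++cc) {
          if (a[cc] > o[cc]) {
            o[cc] = a[cc];
            w[cc] = j + 1;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
void cpp_maxpool_backward(const NumericMatrix dOut, const IntegerMatrix which,
                          const IntegerMatrix idx, const int n_b,
                          const int t_in, NumericMatrix dAprev_buf) {
  const int t_out = idx.nrow();
  const int c = dOut.nrow();
  arma::mat dAprev = view(dAprev_buf);
  dAprev.zeros();
  for (int bi = 0; bi < n_b; ++bi) {
    const arma::uword col0 = (arma::uword)bi * t_out;
    const arma::uword dst0 = (arma::uword)bi * t_in;
    for (int t = 0; t < t_out; ++t) {
      const double* g = &dOut(0, col0 + t);
      const int* w = &which(0, col0 + t);
      for (int cc = 0; cc < c; ++cc) {
        if (w[cc] > 0) {
          const int s = idx(t, w[cc] - 1);
          dAprev(cc, dst0 + s - 1) += g[cc];
        }
      }
    }
  }
}

// In-place Adam update: p, m, v are modified directly (they are owned by the
// model object and never aliased elsewhere).
// [[Rcpp::export]]
void cpp_adam_step(NumericVector p, NumericVector m, NumericVector v,
                   const NumericVector g, const double lr, const double b1,
                   const double b2, const double bc1, const double bc2,
                   const double eps) {
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}

// Mid-sized buffers (tens of MB: per-batch gradients, slices, reshapes) are
// allocated and freed every mini-batch; with glibc's default dynamic mmap
// threshold (capped at 32 MB) each goes through mmap/munmap and is
// re-faulted page by page on every batch. Raising the thresholds moderately
// keeps those on the heap for reuse, while the few very large buffers
// (>128 MB, reused across batches via the workspace pool) still go through
// mmap and are returned to the OS promptly when a fold ends.
// [[Rcpp::export]]
void cpp_tune_malloc() {
#if defined(__GLIBC__)
  mallopt(M_MMAP_THRESHOLD, 128 << 20);
  mallopt(M_TRIM_THRESHOLD, 64 << 20);
#endif
}
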