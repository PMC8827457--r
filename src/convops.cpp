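// Batched 3x3 same-padding convolution kernels used by the U-Net.
// Tensors are R arrays [H, W, C, N] (column-major); weights are
// (9*Cin) x Cout matrices with row index c*9 + (dj+1)*3 + (di+1),
// i.e. offsets run di (rows) fastest within each input channel block.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill colsT (H*W x 9*C) with the shifted copies of one sample's planes.
static void im2col3(const double* xp, int H, int W, int C, arma::mat& colsT) {
  for (int c = 0; c < C; ++c) {
    const arma::mat xplane(const_cast<double*>(xp) + (std::size_t)c * H * W,
                           H, W, false, true);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = c * 9 + (dj + 1) * 3 + (di + 1);
        arma::mat dest(colsT.colptr(k), H, W, false, true);
        const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        const int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
        if (i1 < i0 || j1 < j0) { dest.zeros(); continue; }
        // zero only the (at most 1-px) border outside the valid shift region
        if (j0 > 0) dest.cols(0, j0 - 1).zeros();
        if (j1 < W - 1) dest.cols(j1 + 1, W - 1).zeros();
        if (i0 > 0) dest.submat(0, j0, i0 - 1, j1).zeros();
        if (i1 < H - 1) dest.submat(i1 + 1, j0, H - 1, j1).zeros();
        dest.submat(i0, j0, i1, j1) =
            xplane.submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3x3_fw(NumericVector x, NumericMatrix Wm, NumericVector b,
                         IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int F = Wm.ncol();
  if (Wm.nrow() != 9 * C) stop("weight rows must equal 9 * input channels");
  arma::mat Wa(Wm.begin(), Wm.nrow(), F, false, true);
  arma::rowvec ba(b.begin(), F);
  NumericVector y((std::size_t)H * W * F * N);
  arma::mat colsT(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (std::size_t)n * H * W * C, H, W, C, colsT);
    arma::mat Y(y.begin() + (std::size_t)n * H * W * F, H * W, F, false, true);
    Y = colsT * Wa;
    Y.each_row() += ba;
  }
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  return y;
}

// [[Rcpp::export]]
List conv3x3_bw(NumericVector x, NumericMatrix Wm, NumericVector dy,
                IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int F = Wm.ncol();
  arma::mat Wa(Wm.begin(), Wm.nrow(), F, false, true);
  NumericVector dx((std::size_t)H * W * C * N);
  NumericMatrix dW(9 * C, F);
  NumericVector db(F);
  arma::mat dWa(dW.begin(), 9 * C, F, false, true);
  arma::vec dba(db.begin(), F, false, true);
  arma::mat colsT(H * W, 9 * C);
  arma::mat dcols(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (std::size_t)n * H * W * C, H, W, C, colsT);
    arma::mat dY(const_cast<double*>(dy.begin()) + (std::size_t)n * H * W * F,
                 H * W, F, false, true);
    dWa += colsT.t() * dY;
    dba += arma::sum(dY, 0).t();
    dcols = dY * Wa.t();
    // col2im: scatter-add shifted planes back into dx
    double* dxp = dx.begin() + (std::size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      arma::mat dxplane(dxp + (std::size_t)c * H * W, H, W, false, true);
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int k = c * 9 + (dj + 1) * 3 + (di + 1);
          arma::mat src(dcols.colptr(k), H, W, false, true);
          const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
          const int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
          if (i1 < i0 || j1 < j0) continue;
          dxplane.submat(i0 + di, j0 + dj, i1 + di, j1 + dj) +=
              src.submat(i0, j0, i1, j1);
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Fused batch-normalization + ReLU over [H, W, C, N] tensors, per channel.
// In train mode batch statistics are computed; otherwise the running
// statistics passed in are used.
// [[Rcpp::export]]
List bnrelu_fw(NumericVector z, NumericVector gamma, NumericVector beta,
               IntegerVector dims, bool train, NumericVector rm,
               NumericVector rv, double eps = 1e-5) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const std::size_t HW = (std::size_t)H * W;
  NumericVector y(z.size());
  LogicalVector mask(z.size());
  NumericVector mu(C), var(C);
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double m = 0, v = 0;
    if (train) {
      for (int n = 0; n < N; ++n) {
        const double* p = z.begin() + ((std::size_t)n * C + c) * HW;
        for (std::size_t i = 0; i < HW; ++i) { m += p[i]; v += p[i] * p[i]; }
      }
      m /= M; v = v / M - m * m; if (v < 0) v = 0;
    } else {
      m = rm[c]; v = rv[c];
    }
    mu[c] = m; var[c] = v;
    const double a = gamma[c] / std::sqrt(v + eps);
    const double b = beta[c] - m * a;
    for (int n = 0; n < N; ++n) {
      const std::size_t off = ((std::size_t)n * C + c) * HW;
      const double* p = z.begin() + off;
      double* q = y.begin() + off;
      int* mk = mask.begin() + off;
      for (std::size_t i = 0; i < HW; ++i) {
        const double val = p[i] * a + b;
        q[i] = val > 0 ? val : 0;
        mk[i] = val > 0;
      }
    }
  }
  y.attr("dim") = dims;
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = var,
                      _["mask"] = mask);
}

// Backward of the fused BN + ReLU given the pre-BN input z and the
// gradient dy w.r.t. the ReLU output.
// [[Rcpp::export]]
List bnrelu_bw(NumericVector z, NumericVector dy, LogicalVector mask,
               NumericVector mu, NumericVector var, NumericVector gamma,
               IntegerVector dims, double eps = 1e-5) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const std::size_t HW = (std::size_t)H * W;
  NumericVector dz(z.size());
  NumericVector dgamma(C), dbeta(C);
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    const double s = 1.0 / std::sqrt(var[c] + eps);
    const double m = mu[c];
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const std::size_t off = ((std::size_t)n * C + c) * HW;
      const double* pz = z.begin() + off;
      const double* pd = dy.begin() + off;
      const int* mk = mask.begin() + off;
      for (std::size_t i = 0; i < HW; ++i) {
        if (!mk[i]) continue;
        const double xhat = (pz[i] - m) * s;
        sg += pd[i] * xhat;
        sb += pd[i];
      }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double S1 = gamma[c] * sb;     // sum of dxhat
    const double S2 = gamma[c] * sg;     // sum of dxhat * xhat
    const double k = s / M;
    for (int n = 0; n < N; ++n) {
      const std::size_t off = ((std::size_t)n * C + c) * HW;
      const double* pz = z.begin() + off;
      const double* pd = dy.begin() + off;
      const int* mk = mask.begin() + off;
      double* pq = dz.begin() + off;
      for (std::size_t i = 0; i < HW; ++i) {
        const double dxhat = mk[i] ? pd[i] * gamma[c] : 0.0;
        const double xhat = (pz[i] - m) * s;
        pq[i] = k * (M * dxhat - S1 - xhat * S2);
      }
    }
  }
  dz.attr("dim") = dims;
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
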