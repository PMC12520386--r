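// Low-level kernels for the anisotropic 3D segmentation network.
//
// Feature maps are (C x N) matrices; voxel n = ix + X*(iy + Y*it), so x is
// the fastest axis. Convolutions are 3x3x3 with zero padding 1; weights are
// (Cout x Cin*27) with the 27 offset blocks ordered
// k = (dx+1) + 3*((dy+1) + 3*(dt+1)). im2col is blocked over voxels to keep
// the scratch buffer small.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int BLOCK = 8192;

// gather the (Cin*27 x nb) im2col block for voxels [n0, n0+nb)
static void im2col_block(const mat& M, int X, int Y, int T,
                         int n0, int nb, mat& K) {
  const int C = M.n_rows;
  K.zeros();
  for (int j = 0; j < nb; ++j) {
    const int n = n0 + j;
    const int ix = n % X;
    const int iy = (n / X) % Y;
    const int it = n / (X * Y);
    double* kcol = K.colptr(j);
    for (int dt = -1; dt <= 1; ++dt) {
      const int jt = it + dt;
      if (jt < 0 || jt >= T) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int jy = iy + dy;
        if (jy < 0 || jy >= Y) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          const int jx = ix + dx;
          if (jx < 0 || jx >= X) continue;
          const int k = (dx + 1) + 3 * ((dy + 1) + 3 * (dt + 1));
          const int nn = jx + X * (jy + Y * jt);
          std::memcpy(kcol + k * C, M.colptr(nn), C * sizeof(double));
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3Fwd")]]
arma::mat conv3_fwd(const arma::mat& M, int X, int Y, int T,
                    const arma::mat& W, const arma::vec& b) {
  const int N = X * Y * T;
  if ((int)M.n_cols != N) Rcpp::stop("conv3_fwd: dims mismatch");
  if (W.n_cols != 27 * M.n_rows) Rcpp::stop("conv3_fwd: weight shape");
  mat out(W.n_rows, N);
  mat K(M.n_rows * 27, std::min(BLOCK, N));
  for (int n0 = 0; n0 < N; n0 += BLOCK) {
    const int nb = std::min(BLOCK, N - n0);
    if ((int)K.n_cols != nb) K.set_size(M.n_rows * 27, nb);
    im2col_block(M, X, Y, T, n0, nb, K);
    out.cols(n0, n0 + nb - 1) = W * K;
  }
  out.each_col() += b;
  return out;
}

// [[Rcpp::export(name = ".conv3Bwd")]]
Rcpp::List conv3_bwd(const arma::mat& M, int X, int Y, int T,
                     const arma::mat& W, const arma::mat& dOut) {
  const int N = X * Y * T;
  const int C = M.n_rows;
  if ((int)dOut.n_cols != N || dOut.n_rows != W.n_rows)
    Rcpp::stop("conv3_bwd: dims mismatch");
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  mat dM(C, N, fill::zeros);
  mat K(C * 27, std::min(BLOCK, N));
  for (int n0 = 0; n0 < N; n0 += BLOCK) {
    const int nb = std::min(BLOCK, N - n0);
    if ((int)K.n_cols != nb) K.set_size(C * 27, nb);
    im2col_block(M, X, Y, T, n0, nb, K);
    const mat dOb = dOut.cols(n0, n0 + nb - 1);
    dW += dOb * K.t();
    const mat G = W.t() * dOb;  // (C*27 x nb)
    // scatter-add (col2im)
    for (int j = 0; j < nb; ++j) {
      const int n = n0 + j;
      const int ix = n % X;
      const int iy = (n / X) % Y;
      const int it = n / (X * Y);
      const double* gcol = G.colptr(j);
      for (int dt = -1; dt <= 1; ++dt) {
        const int jt = it + dt;
        if (jt < 0 || jt >= T) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int jy = iy + dy;
          if (jy < 0 || jy >= Y) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int jx = ix + dx;
            if (jx < 0 || jx >= X) continue;
            const int k = (dx + 1) + 3 * ((dy + 1) + 3 * (dt + 1));
            const int nn = jx + X * (jy + Y * jt);
            double* dst = dM.colptr(nn);
            const double* src = gcol + k * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  vec db = sum(dOut, 1);
  return Rcpp::List::create(Rcpp::Named("dM") = dM,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// max-pooling over (x, y) only; t keeps full resolution
// [[Rcpp::export(name = ".poolXYFwd")]]
Rcpp::List pool_xy_fwd(const arma::mat& M, int X, int Y, int T) {
  const int C = M.n_rows;
  if (X % 2 || Y % 2) Rcpp::stop("pool_xy: X and Y must be even");
  const int Xo = X / 2, Yo = Y / 2;
  mat out(C, Xo * Yo * T);
  Mat<unsigned int> amax(C, Xo * Yo * T);
  for (int it = 0; it < T; ++it)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const int no = ox + Xo * (oy + Yo * it);
        const int n00 = 2 * ox + X * (2 * oy + Y * it);
        const int cand[4] = {n00, n00 + 1, n00 + X, n00 + X + 1};
        for (int c = 0; c < C; ++c) {
          double best = M(c, cand[0]);
          int bi = cand[0];
          for (int q = 1; q < 4; ++q)
            if (M(c, cand[q]) > best) { best = M(c, cand[q]); bi = cand[q]; }
          out(c, no) = best;
          amax(c, no) = (unsigned int)bi;
        }
      }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export(name = ".poolXYBwd")]]
arma::mat pool_xy_bwd(const arma::mat& dOut,
                      const arma::Mat<unsigned int>& amax, int N) {
  mat dM(dOut.n_rows, N, fill::zeros);
  for (uword j = 0; j < dOut.n_cols; ++j)
    for (uword c = 0; c < dOut.n_rows; ++c)
      dM(c, amax(c, j)) += dOut(c, j);
  return dM;
}

// nearest-neighbour 2x upsampling in (x, y)
// [[Rcpp::export(name = ".upXYFwd")]]
arma::mat up_xy_fwd(const arma::mat& M, int X, int Y, int T) {
  const int Xo = 2 * X, Yo = 2 * Y;
  mat out(M.n_rows, Xo * Yo * T);
  for (int it = 0; it < T; ++it)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const int no = ox + Xo * (oy + Yo * it);
        const int ni = (ox / 2) + X * ((oy / 2) + Y * it);
        out.col(no) = M.col(ni);
      }
  return out;
}

// [[Rcpp::export(name = ".upXYBwd")]]
arma::mat up_xy_bwd(const arma::mat& dOut, int X, int Y, int T) {
  // X, Y, T are the *input* (coarse) dims
  const int Xo = 2 * X, Yo = 2 * Y;
  mat dM(dOut.n_rows, X * Y * T, fill::zeros);
  for (int it = 0; it < T; ++it)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const int no = ox + Xo * (oy + Yo * it);
        const int ni = (ox / 2) + X * ((oy / 2) + Y * it);
        dM.col(ni) += dOut.col(no);
      }
  return dM;
}
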