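// Hot kernels of the denoiser: 3x3 convolution (as gathered patches x weight
// matrix), group normalization, and windowed multi-head self-attention.
// Layout matches R/nn-ops.R: feature maps are (B*H*W) x C matrices, rows
// image-major then row-major; idx matrices hold 1-based row indices with
// N+1 marking an out-of-bounds (zero) neighbour.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static mat gather_patches(const mat& x, const imat& idx) {
  const uword n = idx.n_rows, k = idx.n_cols, c = x.n_cols, N = x.n_rows;
  mat out(n, k * c);
  for (uword j = 0; j < k; ++j) {
    const int* id = idx.colptr(j);
    for (uword cc = 0; cc < c; ++cc) {
      double* o = out.colptr(j * c + cc);
      const double* xc = x.colptr(cc);
      for (uword i = 0; i < n; ++i) {
        const uword v = (uword)id[i];
        o[i] = (v <= N) ? xc[v - 1] : 0.0;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = "cpp_conv3x3_fw")]]
arma::mat cpp_conv3x3_fw(const arma::mat& x, const arma::imat& idx,
                         const arma::mat& w, const arma::vec& b) {
  mat y = gather_patches(x, idx) * w;
  y.each_row() += b.t();
  return y;
}

// [[Rcpp::export(name = "cpp_conv3x3_bw")]]
List cpp_conv3x3_bw(const arma::mat& x, const arma::mat& g,
                    const arma::imat& idx, const arma::mat& w) {
  const uword cin = x.n_cols, cout = g.n_cols;
  mat dW = gather_patches(x, idx).t() * g;
  // dX[n] = sum_k W_k^T g[n + off_{10-k}]: gather g, multiply mirrored blocks
  mat gpatch = gather_patches(g, idx);          // N x 9*cout
  mat wb(9 * cout, cin);
  for (uword k = 0; k < 9; ++k)
    wb.rows(k * cout, (k + 1) * cout - 1) =
      w.rows((8 - k) * cin, (9 - k) * cin - 1).t();
  mat dX = gpatch * wb;
  return List::create(Named("dx") = dX, Named("dw") = dW,
                      Named("db") = sum(g, 0).t());
}

// [[Rcpp::export(name = "cpp_groupnorm_fw")]]
List cpp_groupnorm_fw(const arma::mat& x, int B, int groups,
                      const arma::vec& gamma, const arma::vec& beta,
                      double eps) {
  const uword N = x.n_rows, C = x.n_cols;
  const uword cg = C / groups, HW = N / B;
  mat xhat(N, C), y(N, C);
  mat inv_sd(B, groups);
  for (int b = 0; b < B; ++b) {
    for (int gi = 0; gi < groups; ++gi) {
      auto blk = x.submat(b * HW, gi * cg, (b + 1) * HW - 1, (gi + 1) * cg - 1);
      double mu = accu(blk) / (HW * cg);
      double var = accu(square(blk - mu)) / (HW * cg);
      double isd = 1.0 / std::sqrt(var + eps);
      inv_sd(b, gi) = isd;
      xhat.submat(b * HW, gi * cg, (b + 1) * HW - 1, (gi + 1) * cg - 1) =
        (blk - mu) * isd;
    }
  }
  y = xhat;
  y.each_row() %= gamma.t();
  y.each_row() += beta.t();
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("inv_sd") = inv_sd);
}

// [[Rcpp::export(name = "cpp_groupnorm_bw")]]
List cpp_groupnorm_bw(const arma::mat& g, const arma::mat& xhat,
                      const arma::mat& inv_sd, const arma::vec& gamma,
                      int B, int groups) {
  const uword N = g.n_rows, C = g.n_cols;
  const uword cg = C / groups, HW = N / B;
  vec dgamma = sum(g % xhat, 0).t();
  vec dbeta = sum(g, 0).t();
  mat dxhat = g;
  dxhat.each_row() %= gamma.t();
  mat dx(N, C);
  for (int b = 0; b < B; ++b) {
    for (int gi = 0; gi < groups; ++gi) {
      auto dh = dxhat.submat(b * HW, gi * cg, (b + 1) * HW - 1,
                             (gi + 1) * cg - 1);
      auto xh = xhat.submat(b * HW, gi * cg, (b + 1) * HW - 1,
                            (gi + 1) * cg - 1);
      double m1 = accu(dh) / (HW * cg);
      double m2 = accu(dh % xh) / (HW * cg);
      dx.submat(b * HW, gi * cg, (b + 1) * HW - 1, (gi + 1) * cg - 1) =
        inv_sd(b, gi) * (dh - m1 - xh * m2);
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// [[Rcpp::export(name = "cpp_window_attn_fw")]]
List cpp_window_attn_fw(const arma::mat& q, const arma::mat& k,
                        const arma::mat& v, const arma::imat& win,
                        int n_heads) {
  const uword C = q.n_cols, l2 = win.n_rows, nw = win.n_cols;
  const uword d = C / n_heads;
  const double isd = 1.0 / std::sqrt((double)d);
  mat y(q.n_rows, C, fill::zeros);
  cube A(l2, l2, nw * n_heads);
  uvec r(l2);
  for (uword g = 0; g < nw; ++g) {
    for (uword i = 0; i < l2; ++i) r(i) = (uword)win(i, g) - 1;
    for (int m = 0; m < n_heads; ++m) {
      span cols(m * d, (m + 1) * d - 1);
      mat S = q.submat(r, regspace<uvec>(m * d, (m + 1) * d - 1)) *
              k.submat(r, regspace<uvec>(m * d, (m + 1) * d - 1)).t() * isd;
      S.each_col() -= max(S, 1);
      S = exp(S);
      S.each_col() /= sum(S, 1);
      A.slice(g * n_heads + m) = S;
      y.submat(r, regspace<uvec>(m * d, (m + 1) * d - 1)) =
        S * v.submat(r, regspace<uvec>(m * d, (m + 1) * d - 1));
    }
  }
  return List::create(Named("y") = y, Named("A") = A);
}

// [[Rcpp::export(name = "cpp_window_attn_bw")]]
List cpp_window_attn_bw(const arma::mat& gr, const arma::mat& q,
                        const arma::mat& k, const arma::mat& v,
                        const arma::imat& win, int n_heads,
                        const arma::cube& A) {
  const uword C = q.n_cols, l2 = win.n_rows, nw = win.n_cols;
  const uword d = C / n_heads;
  const double isd = 1.0 / std::sqrt((double)d);
  mat dQ(q.n_rows, C, fill::zeros), dK(q.n_rows, C, fill::zeros),
      dV(q.n_rows, C, fill::zeros);
  uvec r(l2);
  for (uword g = 0; g < nw; ++g) {
    for (uword i = 0; i < l2; ++i) r(i) = (uword)win(i, g) - 1;
    for (int m = 0; m < n_heads; ++m) {
      uvec cols = regspace<uvec>(m * d, (m + 1) * d - 1);
      const mat& Ag = A.slice(g * n_heads + m);
      mat dO = gr.submat(r, cols);
      dV.submat(r, cols) += Ag.t() * dO;
      mat dA = dO * v.submat(r, cols).t();
      dA.each_col() -= sum(Ag % dA, 1);
      mat dS = Ag % dA;
      dQ.submat(r, cols) += dS * k.submat(r, cols) * isd;
      dK.submat(r, cols) += dS.t() * q.submat(r, cols) * isd;
    }
  }
  return List::create(Named("dq") = dQ, Named("dk") = dK, Named("dv") = dV);
}
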