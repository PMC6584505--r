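// Core numerical kernels for the grid-regression detector.
//
// Feature maps are arma::cube (rows = image rows y, cols = image cols x,
// slices = channels); this matches an R array with dim (H, W, C) exactly
// (column-major, slice-major). Convolution weights arrive as matrices with
// k*k*Cin rows (R array (k, k, Cin, Cout) flattened column-major) so that
// row index = dy + k*dx + k*k*c.
//
// The network is a fixed topology driven by a config list:
//   21 "feature" convolutions (same padding, no bias) each followed by
//   batch normalization and leaky ReLU; 2x2/stride-2 max pooling after a
//   configured subset of them; one skip ("passthrough") connection that
//   takes the activated output of layer `pass_from` (pre-pool), applies
//   space-to-depth by 2 and concatenates it channel-wise into the input of
//   layer `pass_into`; inverted dropout on the final feature map (training
//   only); and a 1x1 detection convolution with bias producing 6 channels.
//
// A single entry point runs forward (optionally caching), calls back into R
// for the loss gradient at the head, and backpropagates, returning analytic
// gradients for every parameter. All state lives in R; nothing persists
// between calls.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static const double BN_EPS = 1e-5;

// im2col with zero "same" padding; layout (H*W) x (k*k*C) so that
// column writes are contiguous and conv is cols * W.
static mat im2col_same(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (k == 1) {
    mat cols(H * (size_t)W, C);
    for (int c = 0; c < C; ++c)
      cols.col(c) = vectorise(x.slice(c));
    return cols;
  }
  const int pad = (k - 1) / 2;
  mat cols(H * (size_t)W, (size_t)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = dy + k * dx + k * k * c;
        const int y0 = std::max(0, pad - dy), y1 = std::min(H, H + pad - dy);
        const int x0 = std::max(0, pad - dx), x1 = std::min(W, W + pad - dx);
        double* dst = cols.colptr(col);
        for (int xx = x0; xx < x1; ++xx) {
          const double* src = s.colptr(xx + dx - pad) + (y0 + dy - pad);
          double* d = dst + (size_t)xx * H + y0;
          std::copy(src, src + (y1 - y0), d);
        }
      }
    }
  }
  return cols;
}

// scatter-add inverse of im2col_same
static cube col2im_add(const mat& dcols, const int k, const int H, const int W,
                       const int C) {
  cube dx(H, W, C, fill::zeros);
  if (k == 1) {
    for (int c = 0; c < C; ++c)
      dx.slice(c) = reshape(dcols.col(c), H, W);
    return dx;
  }
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    mat& s = dx.slice(c);
    for (int dxk = 0; dxk < k; ++dxk) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = dy + k * dxk + k * k * c;
        const int y0 = std::max(0, pad - dy), y1 = std::min(H, H + pad - dy);
        const int x0 = std::max(0, pad - dxk), x1 = std::min(W, W + pad - dxk);
        const double* src0 = dcols.colptr(col);
        for (int xx = x0; xx < x1; ++xx) {
          double* d = s.colptr(xx + dxk - pad) + (y0 + dy - pad);
          const double* src = src0 + (size_t)xx * H + y0;
          for (int y = 0; y < y1 - y0; ++y) d[y] += src[y];
        }
      }
    }
  }
  return dx;
}

static cube mat_to_cube(const mat& m, const int H, const int W) {
  // m is (H*W) x C
  cube out(H, W, m.n_cols);
  for (uword c = 0; c < m.n_cols; ++c)
    out.slice(c) = reshape(m.col(c), H, W);
  return out;
}

static mat cube_to_mat(const cube& x) {
  mat out(x.n_rows * (size_t)x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    out.col(c) = vectorise(x.slice(c));
  return out;
}

static void maxpool2(const cube& x, cube& out, ucube& idx) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  out.set_size(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const int h2 = 2 * h, w2 = 2 * w;
        double best = s(h2, w2);
        int bi = 0;
        if (s(h2 + 1, w2) > best) { best = s(h2 + 1, w2); bi = 1; }
        if (s(h2, w2 + 1) > best) { best = s(h2, w2 + 1); bi = 2; }
        if (s(h2 + 1, w2 + 1) > best) { best = s(h2 + 1, w2 + 1); bi = 3; }
        out(h, w, c) = best;
        idx(h, w, c) = bi;
      }
    }
  }
}

static cube maxpool2_back(const cube& d, const ucube& idx) {
  const int H = d.n_rows, W = d.n_cols, C = d.n_slices;
  cube dx(2 * H, 2 * W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const uword bi = idx(h, w, c);
        dx(2 * h + (bi % 2), 2 * w + (bi / 2), c) = d(h, w, c);
      }
    }
  }
  return dx;
}

// space-to-depth, factor 2: output slice 4*c + 2*dx + dy holds x(2h+dy, 2w+dx, c)
static cube space_to_depth2(const cube& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube out(H, W, 4 * C);
  for (int c = 0; c < C; ++c)
    for (int dx = 0; dx < 2; ++dx)
      for (int dy = 0; dy < 2; ++dy) {
        mat& o = out.slice(4 * c + 2 * dx + dy);
        const mat& s = x.slice(c);
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h)
            o(h, w) = s(2 * h + dy, 2 * w + dx);
      }
  return out;
}

static cube space_to_depth2_back(const cube& d) {
  const int H = d.n_rows, W = d.n_cols, C = d.n_slices / 4;
  cube dx(2 * H, 2 * W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dxk = 0; dxk < 2; ++dxk)
      for (int dy = 0; dy < 2; ++dy) {
        const mat& o = d.slice(4 * c + 2 * dxk + dy);
        mat& s = dx.slice(c);
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h)
            s(2 * h + dy, 2 * w + dxk) = o(h, w);
      }
  return dx;
}

struct ConvParams {
  mat W;
  vec gamma, beta, rmean, rvar;
  int k;
};

// [[Rcpp::export]]
List cpp_net_run(List cfg, List conv_weights, List head_weights, List xbatch,
                 bool training, SEXP drop_mask_sexp, SEXP head_fn_sexp,
                 double bn_momentum) {
  const IntegerVector conv_k = cfg["conv_k"];
  const LogicalVector pool_after = cfg["pool_after"];
  const int n_conv = conv_k.size();
  const int pass_from = as<int>(cfg["pass_from"]);   // 1-based conv index
  const int pass_into = as<int>(cfg["pass_into"]);
  const double alpha = as<double>(cfg["leak_alpha"]);
  const bool want_grad = head_fn_sexp != R_NilValue;

  std::vector<ConvParams> P(n_conv);
  for (int i = 0; i < n_conv; ++i) {
    List li = conv_weights[i];
    P[i].W = as<mat>(li["W"]);
    P[i].gamma = as<vec>(li["gamma"]);
    P[i].beta = as<vec>(li["beta"]);
    P[i].rmean = as<vec>(li["rmean"]);
    P[i].rvar = as<vec>(li["rvar"]);
    P[i].k = conv_k[i];
  }
  mat Wh = as<mat>(head_weights["W"]);
  vec bh = as<vec>(head_weights["b"]);

  const int B = xbatch.size();
  std::vector<cube> cur(B);
  for (int b = 0; b < B; ++b) {
    NumericMatrix xm = xbatch[b];
    cur[b] = cube(xm.begin(), xm.nrow(), xm.ncol(), 1);
  }

  // caches (allocated only when a backward pass is requested)
  std::vector<std::vector<cube>> inputs, xhat;
  std::vector<std::vector<ucube>> poolidx;
  std::vector<cube> head_in(B);
  std::vector<vec> bmean(n_conv), bvar(n_conv);
  std::vector<cube> saved(B);
  if (want_grad) {
    inputs.assign(n_conv, std::vector<cube>(B));
    xhat.assign(n_conv, std::vector<cube>(B));
    int npool = 0;
    for (int i = 0; i < n_conv; ++i) if (pool_after[i]) ++npool;
    poolidx.assign(npool, std::vector<ucube>(B));
  }

  List new_running(n_conv);

  // ---------------- forward ----------------
  int pool_i = 0;
  for (int i = 0; i < n_conv; ++i) {
    if (i + 1 == pass_into) {
      for (int b = 0; b < B; ++b)
        cur[b] = join_slices(cur[b], space_to_depth2(saved[b]));
    }
    const int cout = P[i].W.n_cols;
    std::vector<cube> z(B);
    for (int b = 0; b < B; ++b) {
      if (want_grad) inputs[i][b] = cur[b];
      mat cols = im2col_same(cur[b], P[i].k);
      z[b] = mat_to_cube(cols * P[i].W, cur[b].n_rows, cur[b].n_cols);
    }
    vec mu(cout), va(cout);
    if (training) {
      mu.zeros(); va.zeros();
      double n = 0;
      for (int b = 0; b < B; ++b) {
        n += z[b].n_rows * (double)z[b].n_cols;
        for (int c = 0; c < cout; ++c) mu[c] += accu(z[b].slice(c));
      }
      mu /= n;
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < cout; ++c)
          va[c] += accu(square(z[b].slice(c) - mu[c]));
      va /= n;
      vec nm = bn_momentum * P[i].rmean + (1.0 - bn_momentum) * mu;
      vec nv = bn_momentum * P[i].rvar + (1.0 - bn_momentum) * va;
      new_running[i] = List::create(_["rmean"] = nm, _["rvar"] = nv);
    } else {
      mu = P[i].rmean;
      va = P[i].rvar;
    }
    bmean[i] = mu; bvar[i] = va;
    const vec isd = 1.0 / sqrt(va + BN_EPS);
    for (int b = 0; b < B; ++b) {
      cube& zb = z[b];
      if (want_grad) xhat[i][b].set_size(size(zb));
      for (int c = 0; c < cout; ++c) {
        mat xh = (zb.slice(c) - mu[c]) * isd[c];
        if (want_grad) xhat[i][b].slice(c) = xh;
        mat a = P[i].gamma[c] * xh + P[i].beta[c];
        // leaky ReLU
        zb.slice(c) = a % (conv_to<mat>::from(a > 0) * (1.0 - alpha) + alpha);
      }
      cur[b] = std::move(zb);
    }
    if (i + 1 == pass_from)
      for (int b = 0; b < B; ++b) saved[b] = cur[b];
    if (pool_after[i]) {
      for (int b = 0; b < B; ++b) {
        cube out; ucube idx;
        maxpool2(cur[b], out, idx);
        cur[b] = std::move(out);
        if (want_grad) poolidx[pool_i][b] = std::move(idx);
      }
      ++pool_i;
    }
  }

  // dropout (inverted; mask pre-scaled by 1/(1-rate), zeros where dropped)
  const bool have_mask = drop_mask_sexp != R_NilValue;
  NumericVector drop_mask;
  size_t mask_per = 0;
  if (training && have_mask) {
    drop_mask = NumericVector(drop_mask_sexp);
    mask_per = drop_mask.size() / B;
    for (int b = 0; b < B; ++b) {
      double* p = cur[b].memptr();
      const double* m = drop_mask.begin() + (size_t)b * mask_per;
      for (size_t j = 0; j < mask_per; ++j) p[j] *= m[j];
    }
  }

  // detection head: 1x1 conv with bias
  const int S = cur[0].n_rows;
  NumericVector out_arr((size_t)S * S * 6 * B);
  out_arr.attr("dim") = IntegerVector::create(S, S, 6, B);
  for (int b = 0; b < B; ++b) {
    if (want_grad) head_in[b] = cur[b];
    mat X = cube_to_mat(cur[b]);
    mat o = X * Wh;
    o.each_row() += bh.t();
    std::copy(o.begin(), o.end(), out_arr.begin() + (size_t)b * S * S * 6);
  }

  if (!want_grad)
    return List::create(_["out"] = out_arr);

  // ---------------- loss gradient from R ----------------
  Function head_fn(head_fn_sexp);
  List lg = head_fn(out_arr);
  NumericVector dvec = lg["d"];
  std::vector<cube> d(B);
  for (int b = 0; b < B; ++b) {
    d[b] = cube(S, S, 6);
    std::copy(dvec.begin() + (size_t)b * S * S * 6,
              dvec.begin() + (size_t)(b + 1) * S * S * 6, d[b].memptr());
  }

  // ---------------- backward ----------------
  mat dWh(Wh.n_rows, Wh.n_cols, fill::zeros);
  vec dbh(6, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat Dm = cube_to_mat(d[b]);                    // (S*S) x 6
    mat X = cube_to_mat(head_in[b]);               // (S*S) x C
    dWh += X.t() * Dm;
    dbh += sum(Dm, 0).t();
    d[b] = mat_to_cube(Dm * Wh.t(), S, S);
  }
  if (training && have_mask) {
    for (int b = 0; b < B; ++b) {
      double* p = d[b].memptr();
      const double* m = drop_mask.begin() + (size_t)b * mask_per;
      for (size_t j = 0; j < mask_per; ++j) p[j] *= m[j];
    }
  }

  List grads(n_conv);
  std::vector<cube> pass_grad(B);
  bool have_pass = false;
  pool_i = poolidx.size();
  for (int i = n_conv - 1; i >= 0; --i) {
    if (pool_after[i]) {
      --pool_i;
      for (int b = 0; b < B; ++b)
        d[b] = maxpool2_back(d[b], poolidx[pool_i][b]);
    }
    if (i + 1 == pass_from && have_pass)
      for (int b = 0; b < B; ++b) d[b] += pass_grad[b];

    const int cout = P[i].W.n_cols;
    const vec isd = 1.0 / sqrt(bvar[i] + BN_EPS);
    vec dgamma(cout, fill::zeros), dbeta(cout, fill::zeros);
    // leaky ReLU + BN backward (batch statistics)
    double n = 0;
    for (int b = 0; b < B; ++b) n += d[b].n_rows * (double)d[b].n_cols;
    std::vector<cube> dz(B);
    vec s_dxh(cout, fill::zeros), s_dxh_xh(cout, fill::zeros);
    for (int b = 0; b < B; ++b) {
      dz[b].set_size(size(d[b]));
      for (int c = 0; c < cout; ++c) {
        const mat z = P[i].gamma[c] * xhat[i][b].slice(c) + P[i].beta[c];
        const mat m = conv_to<mat>::from(z > 0) * (1.0 - alpha) + alpha;
        const mat dzb = d[b].slice(c) % m;          // grad wrt gamma*xhat+beta
        dgamma[c] += accu(dzb % xhat[i][b].slice(c));
        dbeta[c] += accu(dzb);
        dz[b].slice(c) = dzb * P[i].gamma[c];       // grad wrt xhat
        s_dxh[c] += accu(dz[b].slice(c));
        s_dxh_xh[c] += accu(dz[b].slice(c) % xhat[i][b].slice(c));
      }
    }
    for (int b = 0; b < B; ++b) {
      for (int c = 0; c < cout; ++c) {
        if (training) {
          dz[b].slice(c) = isd[c] * (dz[b].slice(c) - s_dxh[c] / n -
                                     xhat[i][b].slice(c) * (s_dxh_xh[c] / n));
        } else {
          dz[b].slice(c) *= isd[c];
        }
      }
    }
    // conv backward
    mat dW(P[i].W.n_rows, P[i].W.n_cols, fill::zeros);
    for (int b = 0; b < B; ++b) {
      const cube& xin = inputs[i][b];
      mat cols = im2col_same(xin, P[i].k);
      mat dout = cube_to_mat(dz[b]);
      dW += cols.t() * dout;
      mat dcols = dout * P[i].W.t();
      d[b] = col2im_add(dcols, P[i].k, xin.n_rows, xin.n_cols, xin.n_slices);
    }
    grads[i] = List::create(_["dW"] = dW, _["dgamma"] = dgamma,
                            _["dbeta"] = dbeta);
    if (i + 1 == pass_into) {
      const int c_all = d[0].n_slices;
      const int c_pass = 4 * saved[0].n_slices;
      const int c_main = c_all - c_pass;
      for (int b = 0; b < B; ++b) {
        cube dpass = d[b].slices(c_main, c_all - 1);
        pass_grad[b] = space_to_depth2_back(dpass);
        cube dmain = d[b].slices(0, c_main - 1);
        d[b] = std::move(dmain);
      }
      have_pass = true;
    }
  }

  return List::create(
      _["out"] = out_arr, _["loss"] = lg["loss"], _["grads"] = grads,
      _["head_grads"] = List::create(_["dW"] = dWh, _["db"] = dbh),
      _["new_running"] = new_running);
}
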