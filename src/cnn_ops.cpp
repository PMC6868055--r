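// Compiled kernels for the native CNN: im2col convolution, 2x2 max pool
// and spatial batch normalisation, forward and backward. Activations are
// column-major matrices (H*W*N rows ordered pixel-within-image fastest,
// one column per channel); convolutions zero-pad by one pixel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col_fill(const arma::mat& x, arma::mat& cols,
                        arma::vec& xp, int H, int W, int N) {
  const int C = x.n_cols;
  const int Hp = H + 2, Wp = W + 2;
  const int HW = H * W;
  xp.zeros();
  // pad: xp laid out [Hp, Wp, N, C]
  for (int ch = 0; ch < C; ++ch) {
    const double* src = x.colptr(ch);
    for (int n = 0; n < N; ++n) {
      double* dst = xp.memptr() + (size_t)ch * Hp * Wp * N +
        (size_t)n * Hp * Wp;
      for (int c = 0; c < W; ++c)
        std::copy(src + (size_t)n * HW + (size_t)c * H,
                  src + (size_t)n * HW + (size_t)c * H + H,
                  dst + (size_t)(c + 1) * Hp + 1);
    }
  }
  int j = 0;
  for (int ch = 0; ch < C; ++ch)
    for (int dc = 0; dc < 3; ++dc)
      for (int dr = 0; dr < 3; ++dr, ++j) {
        double* dst = cols.colptr(j);
        const double* base = xp.memptr() + (size_t)ch * Hp * Wp * N;
        for (int n = 0; n < N; ++n) {
          const double* pn = base + (size_t)n * Hp * Wp;
          for (int c = 0; c < W; ++c) {
            const double* pc = pn + (size_t)(c + dc) * Hp + dr;
            std::copy(pc, pc + H, dst);
            dst += H;
          }
        }
      }
}

// [[Rcpp::export]]
List conv_fwd_cpp(const arma::mat& x, const arma::mat& Wm,
                  const arma::vec& b, int H, int W, int N,
                  bool keep_cols) {
  const int C = x.n_cols;
  arma::mat cols((size_t)H * W * N, 9 * C);
  arma::vec xp((size_t)(H + 2) * (W + 2) * N * C);
  im2col_fill(x, cols, xp, H, W, N);
  arma::mat out = cols * Wm;
  out.each_row() += b.t();
  if (keep_cols)
    return List::create(_["out"] = out, _["cols"] = cols);
  return List::create(_["out"] = out);
}

// [[Rcpp::export]]
List conv_bwd_cpp(const arma::mat& dout, const arma::mat& cols,
                  const arma::mat& Wm, int H, int W, int C, int N,
                  bool need_dx) {
  arma::mat dW = cols.t() * dout;
  arma::rowvec db = arma::sum(dout, 0);
  if (!need_dx)
    return List::create(_["dW"] = dW, _["db"] = db);
  arma::mat dcols = dout * Wm.t();
  const int Hp = H + 2, Wp = W + 2;
  arma::vec dxp((size_t)Hp * Wp * N * C, arma::fill::zeros);
  int j = 0;
  for (int ch = 0; ch < C; ++ch)
    for (int dc = 0; dc < 3; ++dc)
      for (int dr = 0; dr < 3; ++dr, ++j) {
        const double* src = dcols.colptr(j);
        double* base = dxp.memptr() + (size_t)ch * Hp * Wp * N;
        for (int n = 0; n < N; ++n) {
          double* pn = base + (size_t)n * Hp * Wp;
          for (int c = 0; c < W; ++c) {
            double* pc = pn + (size_t)(c + dc) * Hp + dr;
            for (int r = 0; r < H; ++r) pc[r] += *src++;
          }
        }
      }
  // unpad
  arma::mat dx((size_t)H * W * N, C);
  for (int ch = 0; ch < C; ++ch) {
    double* dst = dx.colptr(ch);
    const double* base = dxp.memptr() + (size_t)ch * Hp * Wp * N;
    for (int n = 0; n < N; ++n) {
      const double* pn = base + (size_t)n * Hp * Wp;
      for (int c = 0; c < W; ++c) {
        const double* pc = pn + (size_t)(c + 1) * Hp + 1;
        std::copy(pc, pc + H, dst);
        dst += H;
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// [[Rcpp::export]]
List pool_fwd_cpp(const arma::mat& x, int H, int W, int N) {
  const int C = x.n_cols;
  const int H2 = H / 2, W2 = W / 2;
  const size_t HW = (size_t)H * W;
  arma::mat out((size_t)H2 * W2 * N, C);
  IntegerMatrix arg((size_t)H2 * W2 * N, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* src = x.colptr(ch);
    double* dst = out.colptr(ch);
    size_t o = 0;
    for (int n = 0; n < N; ++n) {
      const size_t nb = (size_t)n * HW;
      for (int c = 0; c < W2; ++c) {
        for (int r = 0; r < H2; ++r, ++o) {
          size_t i00 = nb + (size_t)(2 * c) * H + 2 * r;
          size_t best = i00;
          double v = src[i00];
          if (src[i00 + 1] > v) { v = src[i00 + 1]; best = i00 + 1; }
          size_t i01 = i00 + H;
          if (src[i01] > v) { v = src[i01]; best = i01; }
          if (src[i01 + 1] > v) { v = src[i01 + 1]; best = i01 + 1; }
          dst[o] = v;
          arg(o, ch) = (int)best;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
arma::mat pool_bwd_cpp(const arma::mat& dout, const IntegerMatrix& arg,
                       int HWN) {
  const int C = dout.n_cols;
  arma::mat dx(HWN, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    double* dst = dx.colptr(ch);
    const double* src = dout.colptr(ch);
    for (size_t o = 0; o < dout.n_rows; ++o)
      dst[arg(o, ch)] += src[o];
  }
  return dx;
}

// Fused batch norm + ReLU. Returns the rectified activations, the
// normalised pre-activation (xhat), isd, updated running stats.
// [[Rcpp::export]]
List bnrelu_fwd_cpp(const arma::mat& x, const arma::vec& gamma,
                    const arma::vec& beta, const arma::vec& rmean,
                    const arma::vec& rvar, bool training,
                    double momentum, double eps) {
  const int C = x.n_cols;
  const size_t m = x.n_rows;
  arma::mat xhat(m, C), out(m, C);
  arma::vec mu(C), v(C), isd(C);
  arma::vec nrmean(rmean), nrvar(rvar);
  for (int j = 0; j < C; ++j) {
    const double* xc = x.colptr(j);
    if (training) {
      double s = 0;
      for (size_t i = 0; i < m; ++i) s += xc[i];
      mu[j] = s / m;
      double ss = 0;
      for (size_t i = 0; i < m; ++i) {
        double d = xc[i] - mu[j];
        ss += d * d;
      }
      v[j] = ss / m;
      nrmean[j] = (1 - momentum) * rmean[j] + momentum * mu[j];
      nrvar[j] = (1 - momentum) * rvar[j] +
        momentum * v[j] * m / std::max((double)m - 1.0, 1.0);
    } else {
      mu[j] = rmean[j];
      v[j] = rvar[j];
    }
    isd[j] = 1.0 / std::sqrt(v[j] + eps);
    double* xh = xhat.colptr(j);
    double* oo = out.colptr(j);
    const double g = gamma[j], be = beta[j], is = isd[j], mj = mu[j];
    for (size_t i = 0; i < m; ++i) {
      double h = (xc[i] - mj) * is;
      xh[i] = h;
      double y = h * g + be;
      oo[i] = y > 0 ? y : 0.0;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["isd"] = isd,
                      _["rmean"] = nrmean, _["rvar"] = nrvar);
}

// Backward through ReLU (mask from the rectified output) and batch norm.
// [[Rcpp::export]]
List bnrelu_bwd_cpp(const arma::mat& dout, const arma::mat& y,
                    const arma::mat& xhat, const arma::vec& isd,
                    const arma::vec& gamma) {
  const int C = dout.n_cols;
  const size_t m = dout.n_rows;
  arma::mat dx(m, C);
  arma::vec dgamma(C), dbeta(C);
  for (int j = 0; j < C; ++j) {
    const double* dd = dout.colptr(j);
    const double* yy = y.colptr(j);
    const double* xh = xhat.colptr(j);
    double dg = 0, db = 0;
    // first pass: relu mask + reductions
    for (size_t i = 0; i < m; ++i) {
      double d = yy[i] > 0 ? dd[i] : 0.0;
      dg += d * xh[i];
      db += d;
    }
    dgamma[j] = dg;
    dbeta[j] = db;
    const double g = gamma[j], is = isd[j];
    const double c1 = g * db / m, c2 = g * dg / m;
    double* dxp = dx.colptr(j);
    for (size_t i = 0; i < m; ++i) {
      double d = yy[i] > 0 ? dd[i] : 0.0;
      dxp[i] = (d * g - c1 - xh[i] * c2) * is;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- bead-spring polymer helpers ----

// Squared distances of the listed bead pairs (1-based indices).
// [[Rcpp::export]]
arma::vec pair_d2_cpp(const arma::mat& pos, const arma::ivec& i,
                      const arma::ivec& j) {
  arma::vec out(i.n_elem);
  for (size_t k = 0; k < i.n_elem; ++k) {
    const int a = i[k] - 1, b = j[k] - 1;
    const double dx = pos(b, 0) - pos(a, 0);
    const double dy = pos(b, 1) - pos(a, 1);
    const double dz = pos(b, 2) - pos(a, 2);
    out[k] = dx * dx + dy * dy + dz * dz;
  }
  return out;
}

// Accumulate harmonic pair forces F += k * (len - rest) * unit(a -> b)
// on bead a (and the opposite on b) for every listed pair.
// [[Rcpp::export]]
arma::mat spring_pair_forces_cpp(const arma::mat& pos, const arma::ivec& i,
                                 const arma::ivec& j, double kspr,
                                 double rest, int n) {
  arma::mat F(n, 3, arma::fill::zeros);
  for (size_t k = 0; k < i.n_elem; ++k) {
    const int a = i[k] - 1, b = j[k] - 1;
    double d[3];
    for (int ax = 0; ax < 3; ++ax) d[ax] = pos(b, ax) - pos(a, ax);
    double len = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (len < 1e-12) len = 1e-12;
    const double fm = kspr * (len - rest) / len;
    for (int ax = 0; ax < 3; ++ax) {
      F(a, ax) += fm * d[ax];
      F(b, ax) -= fm * d[ax];
    }
  }
  return F;
}

// Half-harmonic excluded-volume push for pairs closer than range:
// magnitude kev * (range - len), directed apart.
// [[Rcpp::export]]
arma::mat ev_pair_forces_cpp(const arma::mat& pos, const arma::ivec& i,
                             const arma::ivec& j, double kev,
                             double range, int n) {
  arma::mat F(n, 3, arma::fill::zeros);
  const double r2 = range * range;
  for (size_t k = 0; k < i.n_elem; ++k) {
    const int a = i[k] - 1, b = j[k] - 1;
    double d[3];
    for (int ax = 0; ax < 3; ++ax) d[ax] = pos(b, ax) - pos(a, ax);
    const double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (d2 >= r2) continue;
    double len = std::sqrt(d2);
    if (len < 1e-9) len = 1e-9;
    const double fm = kev * (range - len) / len;
    for (int ax = 0; ax < 3; ++ax) {
      F(a, ax) -= fm * d[ax];
      F(b, ax) += fm * d[ax];
    }
  }
  return F;
}
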