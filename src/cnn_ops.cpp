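// Minimal CNN engine: valid convolutions (stride 1) via im2col + GEMM,
// max pooling with stride = window, ReLU, inverted dropout, softmax
// cross-entropy. Single precision; one image at a time, gradients
// accumulated over the mini-batch in C++ to keep the R-side loop cheap.
// Patch matrices are laid out (P x K), P = oh*ow output positions,
// K = k*k*Cin, so every im2col copy is contiguous; a conv output (P x F)
// then has exactly the memory layout of the (oh, ow, F) activation cube.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

// Layer plan codes (see build_architecture() on the R side):
// c(1, window, filters)  conv + ReLU
// c(2, window)           max pool, stride = window
// c(3, units, relu)      fully connected (relu = 0 on the softmax head)
// c(4, rate)             dropout (training only)

struct ConvCache {
  arma::fmat col;   // P x K
  arma::fmat pre;   // P x F pre-ReLU
  int oh, ow, ih, iw, ic;
};

struct PoolCache {
  arma::uvec argmax;  // linear index into the input cube per output element
  int oh, ow, ch, ih, iw;
};

struct FcCache {
  arma::fvec in;
  arma::fvec pre;
  bool relu;
};

// X is an (ih*iw x C) matrix whose columns are the input channel planes.
static arma::fmat im2col(const arma::fmat& X, int ih, int iw, int k,
                         int& oh, int& ow) {
  const int C = X.n_cols;
  oh = ih - k + 1;
  ow = iw - k + 1;
  const size_t P = (size_t)oh * ow;
  arma::fmat col(P, (size_t)k * k * C);
  size_t r = 0;
  for (int c = 0; c < C; ++c) {
    const float* plane = X.colptr(c);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        float* dst = col.colptr(r++);
        for (int j = 0; j < ow; ++j)
          std::memcpy(dst + (size_t)j * oh,
                      plane + (size_t)(j + kj) * ih + ki,
                      oh * sizeof(float));
      }
  }
  return col;
}

static void col2im_add(arma::fmat& dX, const arma::fmat& dcol,
                       int ih, int iw, int k, int oh, int ow) {
  const int C = dX.n_cols;
  size_t r = 0;
  for (int c = 0; c < C; ++c) {
    float* plane = dX.colptr(c);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const float* src = dcol.colptr(r++);
        for (int j = 0; j < ow; ++j) {
          float* d = plane + (size_t)(j + kj) * ih + ki;
          const float* s = src + (size_t)j * oh;
          for (int i = 0; i < oh; ++i) d[i] += s[i];
        }
      }
  }
}

// X: (ih*iw x C) planes; returns (oh*ow x C) planes.
static arma::fmat maxpool(const arma::fmat& X, int ih, int iw, int win,
                          PoolCache& pc) {
  const int C = X.n_cols;
  const int oh = ih / win, ow = iw / win;
  arma::fmat Y((size_t)oh * ow, C);
  pc.argmax.set_size((size_t)oh * ow * C);
  pc.oh = oh; pc.ow = ow; pc.ch = C; pc.ih = ih; pc.iw = iw;
  size_t q = 0;
  for (int c = 0; c < C; ++c) {
    const float* plane = X.colptr(c);
    float* out = Y.colptr(c);
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        float best = -1e30f;
        size_t bidx = 0;
        for (int dj = 0; dj < win; ++dj) {
          const float* colp = plane + (size_t)(j * win + dj) * ih + i * win;
          for (int di = 0; di < win; ++di)
            if (colp[di] > best) {
              best = colp[di];
              bidx = (size_t)c * ih * iw +
                     (size_t)(j * win + dj) * ih + i * win + di;
            }
        }
        out[(size_t)j * oh + i] = best;
        pc.argmax(q++) = bidx;
      }
  }
  return Y;
}

static arma::fmat tile_to_planes(const RawVector& tiles, int H, int W,
                                 int C, size_t img) {
  arma::fmat X((size_t)H * W, C);
  const size_t stride = (size_t)H * W * C;
  const unsigned char* p = (const unsigned char*)RAW(tiles) + img * stride;
  float* xp = X.memptr();
  // centre to [-1, 1]: zero-mean inputs condition the deep stack far
  // better than raw [0, 1] stain intensities
  for (size_t i = 0; i < stride; ++i) xp[i] = p[i] / 127.5f - 1.0f;
  return X;
}

struct Net {
  std::vector<arma::fvec> plan;
  std::vector<arma::fmat> W;   // conv: F x K; fc: out x in
  std::vector<arma::fvec> b;
};

static Net unpack(const List& plan, const List& params) {
  Net net;
  for (int i = 0; i < plan.size(); ++i) {
    NumericVector v = plan[i];
    net.plan.push_back(arma::conv_to<arma::fvec>::from(
        arma::vec(v.begin(), v.size())));
  }
  for (int i = 0; i < params.size(); ++i) {
    List p = params[i];
    NumericMatrix Wm = p["W"];
    NumericVector bv = p["b"];
    arma::mat Wd(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
    net.W.push_back(arma::conv_to<arma::fmat>::from(Wd));
    net.b.push_back(arma::conv_to<arma::fvec>::from(
        arma::vec(bv.begin(), bv.size())));
  }
  return net;
}

static arma::fvec forward_one(const Net& net, arma::fmat X, int ih, int iw,
                              bool train, std::mt19937& rng,
                              std::vector<ConvCache>* convc,
                              std::vector<PoolCache>* poolc,
                              std::vector<FcCache>* fcc,
                              std::vector<arma::fvec>* dropm) {
  arma::fvec flat;
  bool flat_mode = false;
  size_t pi = 0;
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  for (size_t li = 0; li < net.plan.size(); ++li) {
    const arma::fvec& L = net.plan[li];
    int code = (int)L(0);
    if (code == 1) {
      int k = (int)L(1);
      int oh, ow;
      arma::fmat col = im2col(X, ih, iw, k, oh, ow);
      arma::fmat pre = col * net.W[pi].t();   // P x F
      pre.each_row() += net.b[pi].t();
      X = arma::clamp(pre, 0.0f, arma::datum::inf);
      if (train) {
        ConvCache cc;
        cc.col = std::move(col); cc.pre = std::move(pre);
        cc.oh = oh; cc.ow = ow; cc.ih = ih; cc.iw = iw;
        cc.ic = cc.col.n_cols / (k * k);
        convc->push_back(std::move(cc));
      }
      ih = oh; iw = ow;
      ++pi;
    } else if (code == 2) {
      PoolCache pc;
      X = maxpool(X, ih, iw, (int)L(1), pc);
      ih = pc.oh; iw = pc.ow;
      if (train) poolc->push_back(pc);
    } else if (code == 3) {
      if (!flat_mode) { flat = arma::vectorise(X); flat_mode = true; }
      arma::fvec pre = net.W[pi] * flat + net.b[pi];
      bool relu = L(2) > 0.5f;
      if (train) {
        FcCache fc; fc.in = flat; fc.pre = pre; fc.relu = relu;
        fcc->push_back(fc);
      }
      flat = relu ? arma::clamp(pre, 0.0f, arma::datum::inf) : pre;
      ++pi;
    } else if (code == 4) {
      if (!flat_mode) { flat = arma::vectorise(X); flat_mode = true; }
      if (train) {
        float rate = L(1);
        arma::fvec msk(flat.n_elem);
        for (arma::uword i = 0; i < flat.n_elem; ++i)
          msk(i) = unif(rng) < rate ? 0.0f : 1.0f / (1.0f - rate);
        flat %= msk;
        dropm->push_back(msk);
      }
    }
  }
  float mx = flat.max();
  arma::fvec e = arma::exp(flat - mx);
  return e / arma::accu(e);
}

// [[Rcpp::export]]
NumericMatrix cnn_forward_cpp(List plan, List params, RawVector tiles,
                              IntegerVector dims, IntegerVector idx) {
  Net net = unpack(plan, params);
  const int H = dims[0], W = dims[1], C = dims[2];
  std::mt19937 rng(0);
  NumericMatrix out(idx.size(), 2);
  for (int i = 0; i < idx.size(); ++i) {
    arma::fmat X = tile_to_planes(tiles, H, W, C, (size_t)idx[i] - 1);
    arma::fvec p = forward_one(net, X, H, W, false, rng, nullptr, nullptr,
                               nullptr, nullptr);
    out(i, 0) = p(0);
    out(i, 1) = p(1);
  }
  return out;
}

// [[Rcpp::export]]
List cnn_batch_grad_cpp(List plan, List params, RawVector tiles,
                        IntegerVector dims, IntegerVector idx,
                        IntegerVector y, int seed) {
  Net net = unpack(plan, params);
  const int H = dims[0], W = dims[1], C = dims[2];
  std::mt19937 rng((unsigned)seed);
  const size_t nP = net.W.size();
  std::vector<arma::fmat> gW(nP);
  std::vector<arma::fvec> gb(nP);
  for (size_t i = 0; i < nP; ++i) {
    gW[i] = arma::zeros<arma::fmat>(net.W[i].n_rows, net.W[i].n_cols);
    gb[i] = arma::zeros<arma::fvec>(net.b[i].n_elem);
  }
  double loss = 0.0;
  int correct = 0;

  for (int n = 0; n < idx.size(); ++n) {
    std::vector<ConvCache> convc;
    std::vector<PoolCache> poolc;
    std::vector<FcCache> fcc;
    std::vector<arma::fvec> dropm;
    arma::fmat X0 = tile_to_planes(tiles, H, W, C, (size_t)idx[n] - 1);
    arma::fvec p = forward_one(net, X0, H, W, true, rng, &convc, &poolc,
                               &fcc, &dropm);
    int cls = y[n];
    loss += -std::log(std::max(p(cls), 1e-12f));
    if ((p(1) >= p(0) ? 1 : 0) == cls) ++correct;

    arma::fvec dflat = p;
    dflat(cls) -= 1.0f;
    int pi = (int)nP - 1;
    int ci = (int)convc.size() - 1;
    int pli = (int)poolc.size() - 1;
    int fi = (int)fcc.size() - 1;
    int di = (int)dropm.size() - 1;
    for (int li = (int)net.plan.size() - 1; li >= 0; --li) {
      const arma::fvec& L = net.plan[li];
      int code = (int)L(0);
      if (code == 3) {
        const FcCache& fc = fcc[fi--];
        arma::fvec dpre = dflat;
        if (fc.relu) dpre %= arma::conv_to<arma::fvec>::from(fc.pre > 0.0f);
        gW[pi] += dpre * fc.in.t();
        gb[pi] += dpre;
        dflat = net.W[pi].t() * dpre;
        --pi;
      } else if (code == 4) {
        dflat %= dropm[di--];
      } else if (code == 2) {
        const PoolCache& pc = poolc[pli--];
        arma::fvec dIn((size_t)pc.ih * pc.iw * pc.ch, arma::fill::zeros);
        for (arma::uword q = 0; q < pc.argmax.n_elem; ++q)
          dIn(pc.argmax(q)) += dflat(q);
        dflat = dIn;
      } else if (code == 1) {
        const ConvCache& cc = convc[ci];
        int F = net.W[pi].n_rows;
        // dflat is the flattened (oh, ow, F) activation = (P x F) matrix
        arma::fmat dY(dflat.memptr(), (size_t)cc.oh * cc.ow, F, false);
        arma::fmat dYm = dY % arma::conv_to<arma::fmat>::from(
            cc.pre > 0.0f);
        gW[pi] += dYm.t() * cc.col;
        gb[pi] += arma::sum(dYm, 0).t();
        if (li > 0) {
          arma::fmat dcol = dYm * net.W[pi];   // P x K
          arma::fmat dX((size_t)cc.ih * cc.iw, cc.ic, arma::fill::zeros);
          col2im_add(dX, dcol, cc.ih, cc.iw, (int)L(1), cc.oh, cc.ow);
          dflat = arma::vectorise(dX);
        }
        --ci;
        --pi;
      }
    }
  }

  List gout(nP);
  for (size_t i = 0; i < nP; ++i) {
    arma::mat Wd = arma::conv_to<arma::mat>::from(gW[i] / (float)idx.size());
    arma::vec bd = arma::conv_to<arma::vec>::from(gb[i] / (float)idx.size());
    gout[i] = List::create(_["W"] = wrap(Wd), _["b"] = wrap(bd));
  }
  return List::create(_["loss"] = loss / idx.size(),
                      _["acc"] = (double)correct / idx.size(),
                      _["grads"] = gout);
}
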