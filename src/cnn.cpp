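// Patch CNN: valid 2-D convolutions via im2col + GEMM, 2x2 max pooling,
// ReLU, softmax cross-entropy, minibatch SGD with Nesterov momentum, and
// dense (fully convolutional, shift-and-stitch) sliding-window inference
// that is arithmetically identical to classifying every 46x46 window.
//
// Feature maps are stored as (channels x H*W) matrices with the spatial
// linear index idx = y + x*H (column-major, matching R arrays).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Layer {
  int k = 0;            // square kernel edge
  bool relu = true;
  bool pool = false;    // 2x2 stride-2 max pool after this layer
  arma::mat W;          // Cout x (Cin * k * k), row index c*k*k + dx*k + dy
  arma::vec b;          // Cout
  arma::mat vW;         // momentum velocities
  arma::vec vb;
};

std::vector<Layer> parse_layers(const List& layers) {
  std::vector<Layer> out(layers.size());
  for (int l = 0; l < layers.size(); ++l) {
    List ll = layers[l];
    out[l].k = as<int>(ll["k"]);
    out[l].relu = as<bool>(ll["relu"]);
    out[l].pool = as<bool>(ll["pool"]);
    out[l].W = as<arma::mat>(ll["W"]);
    out[l].b = as<arma::vec>(ll["b"]);
    out[l].vW = arma::zeros<arma::mat>(out[l].W.n_rows, out[l].W.n_cols);
    out[l].vb = arma::zeros<arma::vec>(out[l].b.n_elem);
  }
  return out;
}

List export_layers(const List& layers, const std::vector<Layer>& net) {
  List out = clone(layers);
  for (size_t l = 0; l < net.size(); ++l) {
    List ll = out[l];
    ll["W"] = wrap(net[l].W);
    ll["b"] = wrap(net[l].b);
    out[l] = ll;
  }
  return out;
}

void im2col(const arma::mat& feat, int H, int W, int k, arma::mat& B,
            int& Hout, int& Wout) {
  const int Cin = feat.n_rows;
  Hout = H - k + 1;
  Wout = W - k + 1;
  B.set_size(Cin * k * k, Hout * Wout);
  for (int xo = 0; xo < Wout; ++xo) {
    for (int yo = 0; yo < Hout; ++yo) {
      double* dst = B.colptr(yo + xo * Hout);
      for (int c = 0; c < Cin; ++c) {
        for (int dx = 0; dx < k; ++dx) {
          const double* src = feat.memptr() + c +
            (std::size_t)((yo) + (xo + dx) * H) * Cin;
          for (int dy = 0; dy < k; ++dy) {
            dst[c * k * k + dx * k + dy] = src[(std::size_t)dy * Cin];
          }
        }
      }
    }
  }
}

// scatter-add of column gradients back onto the input feature map
void col2im(const arma::mat& dB, int H, int W, int k, int Cin,
            arma::mat& dfeat) {
  const int Hout = H - k + 1, Wout = W - k + 1;
  dfeat.zeros(Cin, H * W);
  for (int xo = 0; xo < Wout; ++xo) {
    for (int yo = 0; yo < Hout; ++yo) {
      const double* src = dB.colptr(yo + xo * Hout);
      for (int c = 0; c < Cin; ++c) {
        for (int dx = 0; dx < k; ++dx) {
          double* dst = dfeat.memptr() + c +
            (std::size_t)((yo) + (xo + dx) * H) * Cin;
          for (int dy = 0; dy < k; ++dy) {
            dst[(std::size_t)dy * Cin] += src[c * k * k + dx * k + dy];
          }
        }
      }
    }
  }
}

void maxpool2(const arma::mat& in, int H, int W, arma::mat& out,
              arma::Mat<int>& argmax, int& Hp, int& Wp) {
  const int C = in.n_rows;
  Hp = H / 2;
  Wp = W / 2;
  out.set_size(C, Hp * Wp);
  argmax.set_size(C, Hp * Wp);
  for (int xp = 0; xp < Wp; ++xp) {
    for (int yp = 0; yp < Hp; ++yp) {
      const int o = yp + xp * Hp;
      const int i00 = 2 * yp + 2 * xp * H;
      const int cand[4] = { i00, i00 + 1, i00 + H, i00 + H + 1 };
      for (int c = 0; c < C; ++c) {
        double best = in(c, cand[0]);
        int bi = cand[0];
        for (int j = 1; j < 4; ++j) {
          const double v = in(c, cand[j]);
          if (v > best) { best = v; bi = cand[j]; }
        }
        out(c, o) = best;
        argmax(c, o) = bi;
      }
    }
  }
}

struct Cache {
  // per layer: input feature map + its spatial dims, pre-ReLU output,
  // pooled argmax (if pooled), post-everything output + dims
  std::vector<arma::mat> in_feat;
  std::vector<int> in_H, in_W;
  std::vector<arma::mat> conv_out;          // post-ReLU, pre-pool
  std::vector<arma::Mat<int>> pool_arg;
  std::vector<int> conv_H, conv_W;
};

// forward through all layers; returns final feature map (2 x npos) of
// class scores (no softmax) plus final spatial dims
arma::mat forward(const std::vector<Layer>& net, const arma::mat& input,
                  int H, int W, int& Hf, int& Wf, Cache* cache) {
  arma::mat feat = input;
  arma::mat B;
  int curH = H, curW = W;
  for (size_t l = 0; l < net.size(); ++l) {
    const Layer& L = net[l];
    if (curH < L.k || curW < L.k)
      stop("input too small for layer %d (need >= %d px)", (int)l + 1, L.k);
    if (cache) {
      cache->in_feat.push_back(feat);
      cache->in_H.push_back(curH);
      cache->in_W.push_back(curW);
    }
    int Ho, Wo;
    im2col(feat, curH, curW, L.k, B, Ho, Wo);
    arma::mat out = L.W * B;
    out.each_col() += L.b;
    if (L.relu) out.transform([](double v) { return v > 0.0 ? v : 0.0; });
    curH = Ho; curW = Wo;
    if (cache) {
      cache->conv_out.push_back(out);
      cache->conv_H.push_back(curH);
      cache->conv_W.push_back(curW);
    }
    if (L.pool) {
      arma::mat pooled;
      arma::Mat<int> argmax;
      int Hp, Wp;
      maxpool2(out, curH, curW, pooled, argmax, Hp, Wp);
      if (cache) cache->pool_arg.push_back(argmax);
      feat = pooled;
      curH = Hp; curW = Wp;
    } else {
      if (cache) cache->pool_arg.push_back(arma::Mat<int>());
      feat = out;
    }
  }
  Hf = curH; Wf = curW;
  return feat;
}

inline arma::vec softmax2(const arma::vec& z) {
  const double m = z.max();
  arma::vec e = arma::exp(z - m);
  return e / arma::accu(e);
}

struct Grads {
  std::vector<arma::mat> dW;
  std::vector<arma::vec> db;
  void init(const std::vector<Layer>& net) {
    dW.resize(net.size());
    db.resize(net.size());
    for (size_t l = 0; l < net.size(); ++l) {
      dW[l] = arma::zeros<arma::mat>(net[l].W.n_rows, net[l].W.n_cols);
      db[l] = arma::zeros<arma::vec>(net[l].b.n_elem);
    }
  }
  void zero() {
    for (size_t l = 0; l < dW.size(); ++l) { dW[l].zeros(); db[l].zeros(); }
  }
};

// backward pass for a single 1x1-output sample; accumulates into g
void backward(const std::vector<Layer>& net, const Cache& cache,
              const arma::vec& dlogits, Grads& g) {
  arma::mat dout = dlogits;  // (C x 1) gradient w.r.t. final layer output
  arma::mat B, dB, dfeat;
  for (int l = (int)net.size() - 1; l >= 0; --l) {
    const Layer& L = net[l];
    const int Hc = cache.conv_H[l], Wc = cache.conv_W[l];
    arma::mat dconv;
    if (L.pool) {
      dconv.zeros(L.W.n_rows, Hc * Wc);
      const arma::Mat<int>& am = cache.pool_arg[l];
      for (arma::uword j = 0; j < dout.n_cols; ++j)
        for (arma::uword c = 0; c < dout.n_rows; ++c)
          dconv(c, am(c, j)) += dout(c, j);
    } else {
      dconv = dout;
    }
    if (L.relu) dconv %= arma::conv_to<arma::mat>::from(cache.conv_out[l] > 0);
    int Ho, Wo;
    im2col(cache.in_feat[l], cache.in_H[l], cache.in_W[l], L.k, B, Ho, Wo);
    g.dW[l] += dconv * B.t();
    g.db[l] += arma::sum(dconv, 1);
    if (l > 0) {
      dB = L.W.t() * dconv;
      col2im(dB, cache.in_H[l], cache.in_W[l], L.k,
             cache.in_feat[l].n_rows, dfeat);
      dout = dfeat;
    }
  }
}

// sample i of an (p x p x 3 x N) array, scaled to [0,1], as (3 x p*p)
arma::mat patch_feat(const NumericVector& X, int p, int i) {
  const std::size_t npix = (std::size_t)p * p;
  arma::mat feat(3, npix);
  const double* src = X.begin() + (std::size_t)i * npix * 3;
  for (int c = 0; c < 3; ++c)
    for (std::size_t s = 0; s < npix; ++s)
      feat(c, s) = src[c * npix + s] / 255.0;
  return feat;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_cnn_forward(List layers, NumericVector X) {
  IntegerVector d = X.attr("dim");
  if (d.size() != 4 || d[2] != 3) stop("X must be a p x p x 3 x N array");
  const int p = d[0], N = d[3];
  std::vector<Layer> net = parse_layers(layers);
  NumericMatrix out(N, 2);
  for (int i = 0; i < N; ++i) {
    int Hf, Wf;
    arma::mat z = forward(net, patch_feat(X, p, i), p, p, Hf, Wf, nullptr);
    if (Hf != 1 || Wf != 1) stop("network does not reduce a patch to 1x1");
    arma::vec pr = softmax2(z.col(0));
    out(i, 0) = pr(0);
    out(i, 1) = pr(1);
    if (i % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cnn_train(List layers, NumericVector X, IntegerVector y,
                   List epoch_orders, double lr, double momentum,
                   int batch_size, double clip_norm,
                   Nullable<NumericVector> Xval,
                   Nullable<IntegerVector> yval) {
  IntegerVector d = X.attr("dim");
  if (d.size() != 4 || d[2] != 3) stop("X must be a p x p x 3 x N array");
  const int p = d[0], N = d[3];
  if (y.size() != N) stop("label length mismatch");
  std::vector<Layer> net = parse_layers(layers);
  Grads g;
  g.init(net);
  std::vector<double> losses;
  std::vector<double> val_acc;
  for (int ep = 0; ep < epoch_orders.size(); ++ep) {
    IntegerVector ord = epoch_orders[ep];
    for (int start = 0; start < ord.size(); start += batch_size) {
      const int bs = std::min<int>(batch_size, ord.size() - start);
      g.zero();
      double loss = 0.0;
      for (int j = 0; j < bs; ++j) {
        const int i = ord[start + j];
        if (i < 0 || i >= N) stop("sample index out of range");
        Cache cache;
        int Hf, Wf;
        arma::mat z = forward(net, patch_feat(X, p, i), p, p, Hf, Wf, &cache);
        if (Hf != 1 || Wf != 1) stop("network does not reduce a patch to 1x1");
        arma::vec pr = softmax2(z.col(0));
        const int cls = y[i];
        loss += -std::log(std::max(pr(cls), 1e-12));
        arma::vec dlogits = pr;
        dlogits(cls) -= 1.0;
        backward(net, cache, dlogits, g);
      }
      loss /= bs;
      if (!std::isfinite(loss))
        stop("training diverged: non-finite loss at epoch %d, batch start %d",
             ep + 1, start);
      losses.push_back(loss);
      // global gradient-norm clipping guards the one-pass schedule
      // against outlier batches blowing up the momentum update
      double scale = 1.0;
      if (clip_norm > 0) {
        double sq = 0.0;
        for (size_t l = 0; l < net.size(); ++l) {
          sq += arma::accu(arma::square(g.dW[l] / bs));
          sq += arma::accu(arma::square(g.db[l] / bs));
        }
        const double gnorm = std::sqrt(sq);
        if (gnorm > clip_norm) scale = clip_norm / gnorm;
      }
      // Nesterov momentum: v <- mu*v - eta*grad; theta <- theta + mu*v - eta*grad
      for (size_t l = 0; l < net.size(); ++l) {
        arma::mat gW = scale * g.dW[l] / bs;
        arma::vec gb = scale * g.db[l] / bs;
        net[l].vW = momentum * net[l].vW - lr * gW;
        net[l].vb = momentum * net[l].vb - lr * gb;
        net[l].W += momentum * net[l].vW - lr * gW;
        net[l].b += momentum * net[l].vb - lr * gb;
      }
      Rcpp::checkUserInterrupt();
    }
    if (Xval.isNotNull() && yval.isNotNull()) {
      NumericVector Xv(Xval);
      IntegerVector yv(yval);
      IntegerVector dv = Xv.attr("dim");
      const int Nv = dv[3];
      int correct = 0;
      for (int i = 0; i < Nv; ++i) {
        int Hf, Wf;
        arma::mat z = forward(net, patch_feat(Xv, p, i), p, p, Hf, Wf, nullptr);
        arma::vec pr = softmax2(z.col(0));
        if ((pr(1) >= 0.5 ? 1 : 0) == yv[i]) ++correct;
      }
      val_acc.push_back((double)correct / Nv);
    }
  }
  return List::create(_["layers"] = export_layers(layers, net),
                      _["loss"] = wrap(losses),
                      _["val_accuracy"] = wrap(val_acc));
}

// Dense inference. Returns the positive-class probability for every
// sliding-window top-left position (matrix (H-win+1) x (W-win+1)) when
// exact = TRUE, by running the fully convolutional network on each of
// stride^2 shifted copies of the image; when exact = FALSE only the
// (0,0)-shifted coarse grid is computed (caller interpolates).
// [[Rcpp::export]]
List cpp_cnn_dense(List layers, NumericVector img, int win, bool exact) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3 || d[2] != 3) stop("img must be an H x W x 3 array");
  const int H = d[0], W = d[1];
  if (H < win || W < win) stop("image smaller than the %d-px patch", win);
  std::vector<Layer> net = parse_layers(layers);
  int stride = 1;
  for (size_t l = 0; l < net.size(); ++l) if (net[l].pool) stride *= 2;
  const std::size_t npix = (std::size_t)H * W;

  arma::mat full(3, npix);
  for (int c = 0; c < 3; ++c)
    for (std::size_t s = 0; s < npix; ++s)
      full(c, s) = img[c * npix + s] / 255.0;

  const int nHo = H - win + 1, nWo = W - win + 1;
  arma::mat P;
  int coarseH = 0, coarseW = 0;
  if (exact) P.set_size(nHo, nWo);
  const int max_shift = exact ? stride : 1;
  arma::mat sub;
  for (int dy = 0; dy < max_shift; ++dy) {
    for (int dx = 0; dx < max_shift; ++dx) {
      if (dy >= nHo || dx >= nWo) continue;
      const int Hs = H - dy, Ws = W - dx;
      sub.set_size(3, (std::size_t)Hs * Ws);
      for (int x = 0; x < Ws; ++x)
        for (int yy = 0; yy < Hs; ++yy)
          sub.col(yy + (std::size_t)x * Hs) =
            full.col((yy + dy) + (std::size_t)(x + dx) * H);
      int Hf, Wf;
      arma::mat z = forward(net, sub, Hs, Ws, Hf, Wf, nullptr);
      if (!exact) {
        coarseH = Hf; coarseW = Wf;
        P.set_size(Hf, Wf);
      }
      for (int v = 0; v < Wf; ++v) {
        for (int u = 0; u < Hf; ++u) {
          arma::vec pr = softmax2(z.col(u + (std::size_t)v * Hf));
          if (exact) {
            const int r = dy + stride * u, c = dx + stride * v;
            if (r < nHo && c < nWo) P(r, c) = pr(1);
          } else {
            P(u, v) = pr(1);
          }
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["P"] = wrap(P), _["stride"] = stride,
                      _["coarse"] = !exact);
}
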