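// CNN engine: a fixed-topology LeNet-style network
//   conv-relu -> pool (x3) -> dropout -> conv-relu -> pool
//   -> flatten -> dense-relu -> dropout -> dense -> softmax
// trained with mini-batch Adam on softmax cross-entropy.
// Convolutions are stride-1 "same" (odd kernel); pooling is pool_size^2
// windows with configurable stride. All randomness (shuffling, dropout)
// comes from one std::mt19937 so a fixed seed reproduces a run exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::vec;
using arma::uword;

// im2col for stride-1 same-padded convolution: row p = r + H*c of the
// output holds the kernel patch centred on input pixel (r, c); column
// index di + k*dj + k*k*ch matches an R (k, k, Cin, Cout) array flattened
// column-major into a (k*k*Cin x Cout) weight matrix.
static void im2col(const cube& in, int k, mat& cols) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices, pad = k / 2;
  cols.set_size((uword)H * W, (uword)k * k * C);
  for (int ch = 0; ch < C; ++ch) {
    const double* sl = in.slice(ch).memptr();
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        double* dst = cols.colptr(di + k * dj + k * k * ch);
        const int roff = di - pad;
        const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff); // valid out rows
        for (int c = 0; c < W; ++c) {
          const int sc = c + dj - pad;
          double* d = dst + (size_t)H * c;
          if (sc < 0 || sc >= W) { std::fill(d, d + H, 0.0); continue; }
          const double* s = sl + (size_t)H * sc + roff;
          if (r0 > 0) std::fill(d, d + r0, 0.0);
          if (r1 > r0) std::copy(s + r0, s + r1, d + r0);
          if (r1 < H) std::fill(d + std::max(r1, 0), d + H, 0.0);
        }
      }
    }
  }
}

// scatter-add of column gradients back onto the input (adjoint of im2col)
static void col2im(const mat& dcols, int k, cube& dinp) {
  const int H = dinp.n_rows, W = dinp.n_cols, C = dinp.n_slices, pad = k / 2;
  dinp.zeros();
  for (int ch = 0; ch < C; ++ch) {
    double* sl = dinp.slice(ch).memptr();
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const double* src = dcols.colptr(di + k * dj + k * k * ch);
        const int roff = di - pad;
        const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
        for (int c = 0; c < W; ++c) {
          const int sc = c + dj - pad;
          if (sc < 0 || sc >= W) continue;
          const double* s = src + (size_t)H * c;
          double* d = sl + (size_t)H * sc + roff;
          for (int r = r0; r < r1; ++r) d[r] += s[r];
        }
      }
    }
  }
}

static void maxpool_fwd(const cube& in, int p, int s, cube& out, arma::umat& arg) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const int Ho = (H - p) / s + 1, Wo = (W - p) / s + 1;
  out.set_size(Ho, Wo, C);
  arg.set_size((uword)Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const mat& sl = in.slice(ch);
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        const int rs = ro * s, cs = co * s;
        double best = sl(rs, cs);
        uword besti = rs + (uword)H * cs;
        for (int dc = 0; dc < p; ++dc)
          for (int dr = 0; dr < p; ++dr) {
            const double v = sl(rs + dr, cs + dc);
            if (v > best) { best = v; besti = (rs + dr) + (uword)H * (cs + dc); }
          }
        out(ro, co, ch) = best;
        arg(ro + (uword)Ho * co, ch) = besti;
      }
    }
  }
}

static void maxpool_bwd(const cube& dout, const arma::umat& arg, cube& dinp) {
  dinp.zeros();
  const int Ho = dout.n_rows, Wo = dout.n_cols, C = dout.n_slices;
  for (int ch = 0; ch < C; ++ch) {
    double* sl = dinp.slice(ch).memptr();
    const double* dsl = dout.slice(ch).memptr();
    for (uword i = 0; i < (uword)Ho * Wo; ++i) sl[arg(i, ch)] += dsl[i];
  }
}

struct Params {
  std::vector<mat> W;   // 4 conv weights (k*k*Cin x Cout), then dense1, dense2
  std::vector<vec> b;
};

static Params params_from_list(List weights) {
  Params p;
  const char* wn[6] = {"W1", "W2", "W3", "W4", "Wd1", "Wd2"};
  const char* bn[6] = {"b1", "b2", "b3", "b4", "bd1", "bd2"};
  for (int i = 0; i < 6; ++i) {
    p.W.push_back(as<mat>(weights[wn[i]]));
    p.b.push_back(as<vec>(weights[bn[i]]));
  }
  return p;
}

static List params_to_list(const Params& p) {
  return List::create(
    Named("W1") = p.W[0], Named("b1") = p.b[0],
    Named("W2") = p.W[1], Named("b2") = p.b[1],
    Named("W3") = p.W[2], Named("b3") = p.b[2],
    Named("W4") = p.W[3], Named("b4") = p.b[3],
    Named("Wd1") = p.W[4], Named("bd1") = p.b[4],
    Named("Wd2") = p.W[5], Named("bd2") = p.b[5]);
}

// per-image forward/backward workspace (buffers reused across images)
struct Net {
  int kernel, pool, pstride, n_classes;
  std::vector<mat> cols;        // im2col matrices per conv layer
  std::vector<mat> convz;       // pre-pool activations (HW x C), post-relu
  std::vector<cube> act;        // pooled activations a0..a4 (a0 = input)
  std::vector<arma::umat> arg;  // pool argmax per layer
  cube drop_mask;               // conv dropout mask (on act[3])
  vec dense_mask;               // dense dropout mask
  vec flat, h1, logits, probs;

  Net(int k, int p, int ps, int K) : kernel(k), pool(p), pstride(ps), n_classes(K) {
    cols.resize(4); convz.resize(4); act.resize(5); arg.resize(4);
  }

  // returns cross-entropy loss for label y (y < 0: skip loss)
  double forward(const mat& img, int y, const Params& P, bool train,
                 double p_conv, double p_dense, std::mt19937& gen) {
    act[0].set_size(img.n_rows, img.n_cols, 1);
    act[0].slice(0) = img;
    std::uniform_real_distribution<double> U(0.0, 1.0);
    for (int l = 0; l < 4; ++l) {
      cube in = act[l];
      if (l == 3 && p_conv > 0) {  // dropout between third pool and conv4
        if (train) {
          drop_mask.set_size(in.n_rows, in.n_cols, in.n_slices);
          for (uword i = 0; i < in.n_elem; ++i)
            drop_mask(i) = (U(gen) >= p_conv) ? 1.0 / (1.0 - p_conv) : 0.0;
          in %= drop_mask;
          act[l] = in;             // keep dropped activations for backward
        }
      }
      im2col(in, kernel, cols[l]);
      convz[l] = cols[l] * P.W[l];
      convz[l].each_row() += P.b[l].t();
      convz[l].transform([](double v) { return v > 0 ? v : 0.0; });
      cube cz(convz[l].memptr(), in.n_rows, in.n_cols, P.W[l].n_cols, false);
      maxpool_fwd(cz, pool, pstride, act[l + 1], arg[l]);
    }
    flat = arma::vectorise(act[4]);
    h1 = P.W[4].t() * flat + P.b[4];
    h1.transform([](double v) { return v > 0 ? v : 0.0; });
    if (train && p_dense > 0) {
      dense_mask.set_size(h1.n_elem);
      for (uword i = 0; i < h1.n_elem; ++i)
        dense_mask(i) = (U(gen) >= p_dense) ? 1.0 / (1.0 - p_dense) : 0.0;
      h1 %= dense_mask;
    }
    logits = P.W[5].t() * h1 + P.b[5];
    const double mx = logits.max();
    probs = arma::exp(logits - mx);
    probs /= arma::accu(probs);
    if (y < 0) return 0.0;
    return -std::log(std::max(probs(y), 1e-300));
  }

  void backward(int y, const Params& P, bool p_conv_on, bool p_dense_on,
                Params& G) {
    vec dlog = probs;
    dlog(y) -= 1.0;
    G.W[5] += h1 * dlog.t();
    G.b[5] += dlog;
    vec dh1 = P.W[5] * dlog;
    if (p_dense_on) dh1 %= dense_mask;
    for (uword i = 0; i < dh1.n_elem; ++i) if (h1(i) <= 0) dh1(i) = 0;
    G.W[4] += flat * dh1.t();
    G.b[4] += dh1;
    vec dflat = P.W[4] * dh1;
    cube dpool(dflat.memptr(), act[4].n_rows, act[4].n_cols, act[4].n_slices);
    for (int l = 3; l >= 0; --l) {
      cube dz(act[l].n_rows, act[l].n_cols, P.W[l].n_cols);
      maxpool_bwd(dpool, arg[l], dz);
      mat dzm(dz.memptr(), dz.n_rows * dz.n_cols, dz.n_slices, false);
      // relu gate on the stored post-relu activations
      for (uword i = 0; i < dzm.n_elem; ++i) if (convz[l](i) <= 0) dzm(i) = 0;
      G.W[l] += cols[l].t() * dzm;
      G.b[l] += arma::sum(dzm, 0).t();
      if (l > 0) {
        mat dcols = dzm * P.W[l].t();
        cube dinp(act[l].n_rows, act[l].n_cols, act[l].n_slices);
        col2im(dcols, kernel, dinp);
        if (l == 3 && p_conv_on) dinp %= drop_mask;
        dpool = dinp;
      }
    }
  }
};

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const Params& p) {
    for (auto& w : p.W) { mW.push_back(arma::zeros<mat>(arma::size(w)));
                          vW.push_back(arma::zeros<mat>(arma::size(w))); }
    for (auto& b : p.b) { mb.push_back(arma::zeros<vec>(arma::size(b)));
                          vb.push_back(arma::zeros<vec>(arma::size(b))); }
  }
  void step(Params& p, const Params& g, double lr) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < p.W.size(); ++i) {
      mW[i] = b1 * mW[i] + (1 - b1) * g.W[i];
      vW[i] = b2 * vW[i] + (1 - b2) * arma::square(g.W[i]);
      p.W[i] -= lr * (mW[i] / c1) / (arma::sqrt(vW[i] / c2) + eps);
      mb[i] = b1 * mb[i] + (1 - b1) * g.b[i];
      vb[i] = b2 * vb[i] + (1 - b2) * arma::square(g.b[i]);
      p.b[i] -= lr * (mb[i] / c1) / (arma::sqrt(vb[i] / c2) + eps);
    }
  }
};

static Params zero_like(const Params& p) {
  Params g;
  for (auto& w : p.W) g.W.push_back(arma::zeros<mat>(arma::size(w)));
  for (auto& b : p.b) g.b.push_back(arma::zeros<vec>(arma::size(b)));
  return g;
}

// [[Rcpp::export]]
List cnn_train_cpp(const arma::cube& X, const arma::ivec& y, List weights,
                   int n_classes, int kernel, int pool_size, int pool_stride,
                   double dropout_conv, double dropout_dense,
                   int epochs, int batch_size, double lr, int seed,
                   bool verbose) {
  Params P = params_from_list(weights);
  Adam opt(P);
  Net net(kernel, pool_size, pool_stride, n_classes);
  std::mt19937 gen((unsigned)seed);
  const int N = X.n_slices;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  vec ep_loss(std::max(epochs, 0), arma::fill::zeros);
  vec ep_acc(std::max(epochs, 0), arma::fill::zeros);
  bool bad = false;

  for (int e = 0; e < epochs && !bad; ++e) {
    std::shuffle(idx.begin(), idx.end(), gen);
    double loss_sum = 0; int correct = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int end = std::min(start + batch_size, N);
      Params G = zero_like(P);
      for (int ii = start; ii < end; ++ii) {
        const int i = idx[ii];
        const double li = net.forward(X.slice(i), y(i), P, true,
                                      dropout_conv, dropout_dense, gen);
        loss_sum += li;
        if ((int)net.probs.index_max() == y(i)) ++correct;
        net.backward(y(i), P, dropout_conv > 0, dropout_dense > 0, G);
      }
      const double inv = 1.0 / (end - start);
      for (auto& w : G.W) w *= inv;
      for (auto& b : G.b) b *= inv;
      opt.step(P, G, lr);
      if (!std::isfinite(loss_sum)) { bad = true; break; }
      Rcpp::checkUserInterrupt();
    }
    ep_loss(e) = loss_sum / N;
    ep_acc(e) = (double)correct / N;
    if (!std::isfinite(ep_loss(e))) bad = true;
    if (verbose) Rcout << "epoch " << e + 1 << "/" << epochs
                       << "  loss " << ep_loss(e) << "  acc " << ep_acc(e) << "\n";
  }
  return List::create(Named("weights") = params_to_list(P),
                      Named("loss") = ep_loss, Named("accuracy") = ep_acc,
                      Named("diverged") = bad);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const arma::cube& X, List weights, int n_classes,
                          int kernel, int pool_size, int pool_stride) {
  Params P = params_from_list(weights);
  Net net(kernel, pool_size, pool_stride, n_classes);
  std::mt19937 gen(0);  // unused: no dropout at inference
  const int N = X.n_slices;
  mat out(N, n_classes);
  for (int i = 0; i < N; ++i) {
    net.forward(X.slice(i), -1, P, false, 0.0, 0.0, gen);
    out.row(i) = net.probs.t();
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
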