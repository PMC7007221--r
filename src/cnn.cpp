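// Multi-task sequence CNN: three valid-mode convolution layers (ReLU + max
// pooling) over one-hot DNA, two fully connected hidden layers, sigmoid
// multi-task output, binary cross-entropy loss, RMSprop, early stopping on
// mean validation AUROC. Implemented with im2col + GEMM so the heavy lifting
// is BLAS. All randomness flows through a private xorshift generator so that
// results are bit-reproducible for a given seed, independent of the C++
// standard library's distribution implementations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// deterministic RNG (xorshift64* + Box-Muller)
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int unif_int(int n) { return (int)(unif() * n) % n; }
};

void shuffle_vec(std::vector<arma::uword>& v, Rng& rng) {
  for (size_t i = v.size(); i > 1; --i)
    std::swap(v[i - 1], v[rng.unif_int((int)i)]);
}

// ---------------------------------------------------------------------------
struct LayerDims {
  int cin, k, f, pool, lin, lout, lpool;
};

struct Net {
  std::vector<arma::mat> W; // 6 weight matrices
  std::vector<arma::vec> b;
  std::vector<LayerDims> conv; // 3
  int fc1, fc2, F, L, flat;
};

Net net_from_list(const List& params) {
  Net n;
  IntegerVector d = params["dims"];
  // dims: L, F, then per conv layer (cin,k,f,pool,lin,lout,lpool), fc1, fc2
  n.L = d[0]; n.F = d[1];
  int off = 2;
  for (int l = 0; l < 3; ++l) {
    LayerDims ld;
    ld.cin = d[off]; ld.k = d[off + 1]; ld.f = d[off + 2]; ld.pool = d[off + 3];
    ld.lin = d[off + 4]; ld.lout = d[off + 5]; ld.lpool = d[off + 6];
    n.conv.push_back(ld);
    off += 7;
  }
  n.fc1 = d[off]; n.fc2 = d[off + 1];
  n.flat = n.conv[2].f * n.conv[2].lpool;
  List Ws = params["W"], bs = params["b"];
  for (int i = 0; i < 6; ++i) {
    n.W.push_back(as<arma::mat>(Ws[i]));
    n.b.push_back(as<arma::vec>(bs[i]));
  }
  return n;
}

List net_to_list(const Net& n, IntegerVector dims) {
  List Ws(6), bs(6);
  for (int i = 0; i < 6; ++i) { Ws[i] = n.W[i]; bs[i] = n.b[i]; }
  return List::create(Named("W") = Ws, Named("b") = bs, Named("dims") = dims);
}

// im2col: input (cin x lin x B) -> (cin*k) x (lout*B), sample-major columns
arma::mat im2col(const arma::cube& x, int k, int lout) {
  const arma::uword cin = x.n_rows, B = x.n_slices;
  arma::mat out(cin * k, (arma::uword)lout * B);
  for (arma::uword b = 0; b < B; ++b) {
    const double* xp = x.slice_memptr(b);
    for (int j = 0; j < lout; ++j) {
      double* op = out.colptr(b * lout + j);
      std::memcpy(op, xp + (arma::uword)j * cin, sizeof(double) * cin * k);
    }
  }
  return out;
}

// col2im adjoint: accumulate (cin*k) x (lout*B) gradients back onto cube
void col2im_add(arma::cube& dx, const arma::mat& dcol, int k, int lout) {
  const arma::uword cin = dx.n_rows, B = dx.n_slices;
  for (arma::uword b = 0; b < B; ++b) {
    double* xp = dx.slice_memptr(b);
    for (int j = 0; j < lout; ++j) {
      const double* dp = dcol.colptr(b * lout + j);
      double* tgt = xp + (arma::uword)j * cin;
      for (arma::uword t = 0; t < cin * k; ++t) tgt[t] += dp[t];
    }
  }
}

struct ConvCache {
  arma::mat col;     // im2col of input
  arma::mat z;       // pre-activation f x (lout*B)
  arma::cube pooled; // f x lpool x B
  arma::umat argmax; // f x (lpool*B), offset within pool window
};

// forward one conv layer
ConvCache conv_forward(const arma::cube& x, const LayerDims& ld,
                       const arma::mat& W, const arma::vec& b) {
  ConvCache c;
  const arma::uword B = x.n_slices;
  c.col = im2col(x, ld.k, ld.lout);
  c.z = W * c.col;
  c.z.each_col() += b;
  c.pooled.set_size(ld.f, ld.lpool, B);
  c.argmax.set_size(ld.f, (arma::uword)ld.lpool * B);
  for (arma::uword bb = 0; bb < B; ++bb) {
    for (int t = 0; t < ld.lpool; ++t) {
      for (int f = 0; f < ld.f; ++f) {
        double best = -1e300; int bu = 0;
        for (int u = 0; u < ld.pool; ++u) {
          double v = c.z(f, bb * ld.lout + (arma::uword)t * ld.pool + u);
          if (v > best) { best = v; bu = u; }
        }
        if (best < 0.0) best = 0.0; // ReLU after pooling of pre-activations
        c.pooled(f, t, bb) = best;
        c.argmax(f, bb * ld.lpool + t) = bu;
      }
    }
  }
  return c;
}

struct FwdCache {
  std::vector<ConvCache> conv;
  arma::mat flat, h1, h2, logits, probs;
  arma::mat drop1, drop2; // inverted-dropout masks (empty if unused)
};

arma::mat flatten_cube(const arma::cube& x) {
  const arma::uword B = x.n_slices, m = x.n_rows * x.n_cols;
  arma::mat out(m, B);
  for (arma::uword b = 0; b < B; ++b)
    std::memcpy(out.colptr(b), x.slice_memptr(b), sizeof(double) * m);
  return out;
}

FwdCache forward(const Net& n, const arma::cube& x, double dropout, Rng* rng) {
  FwdCache fc;
  const arma::cube* cur = &x;
  for (int l = 0; l < 3; ++l) {
    fc.conv.push_back(conv_forward(*cur, n.conv[l], n.W[l], n.b[l]));
    cur = &fc.conv.back().pooled;
  }
  fc.flat = flatten_cube(*cur);
  fc.h1 = n.W[3] * fc.flat;
  fc.h1.each_col() += n.b[3];
  fc.h1.transform([](double v) { return v > 0 ? v : 0.0; });
  if (dropout > 0 && rng) {
    fc.drop1 = arma::mat(fc.h1.n_rows, fc.h1.n_cols);
    fc.drop1.imbue([&]() { return rng->unif() < dropout ? 0.0 : 1.0 / (1.0 - dropout); });
    fc.h1 %= fc.drop1;
  }
  fc.h2 = n.W[4] * fc.h1;
  fc.h2.each_col() += n.b[4];
  fc.h2.transform([](double v) { return v > 0 ? v : 0.0; });
  if (dropout > 0 && rng) {
    fc.drop2 = arma::mat(fc.h2.n_rows, fc.h2.n_cols);
    fc.drop2.imbue([&]() { return rng->unif() < dropout ? 0.0 : 1.0 / (1.0 - dropout); });
    fc.h2 %= fc.drop2;
  }
  fc.logits = n.W[5] * fc.h2;
  fc.logits.each_col() += n.b[5];
  fc.probs = 1.0 / (1.0 + arma::exp(-fc.logits));
  return fc;
}

struct Grads {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

// backward pass; yT is F x B; returns mean BCE
double backward(const Net& n, const arma::cube& x, const arma::mat& yT,
                const FwdCache& fc, Grads& g) {
  const arma::uword B = x.n_slices;
  const double scale = 1.0 / (double)(B * n.F);
  arma::mat P = arma::clamp(fc.probs, 1e-12, 1.0 - 1e-12);
  double loss = -arma::accu(yT % arma::log(P) + (1.0 - yT) % arma::log(1.0 - P)) * scale;

  arma::mat dz = (fc.probs - yT) * scale; // F x B
  g.W[5] = dz * fc.h2.t();
  g.b[5] = arma::sum(dz, 1);
  arma::mat dh2 = n.W[5].t() * dz;
  if (fc.drop2.n_elem) dh2 %= fc.drop2;
  dh2.elem(arma::find(fc.h2 <= 0)).zeros();
  g.W[4] = dh2 * fc.h1.t();
  g.b[4] = arma::sum(dh2, 1);
  arma::mat dh1 = n.W[4].t() * dh2;
  if (fc.drop1.n_elem) dh1 %= fc.drop1;
  dh1.elem(arma::find(fc.h1 <= 0)).zeros();
  g.W[3] = dh1 * fc.flat.t();
  g.b[3] = arma::sum(dh1, 1);
  arma::mat dflat = n.W[3].t() * dh1; // flat x B

  // reshape to cube grad of conv3 pooled output
  arma::cube dpool(n.conv[2].f, n.conv[2].lpool, B);
  for (arma::uword b = 0; b < B; ++b)
    std::memcpy(dpool.slice_memptr(b), dflat.colptr(b),
                sizeof(double) * dpool.n_rows * dpool.n_cols);

  for (int l = 2; l >= 0; --l) {
    const LayerDims& ld = n.conv[l];
    const ConvCache& cc = fc.conv[l];
    // unpool: route gradient to argmax position, zero where ReLU clipped
    arma::mat dzc(ld.f, (arma::uword)ld.lout * B, arma::fill::zeros);
    for (arma::uword bb = 0; bb < B; ++bb)
      for (int t = 0; t < ld.lpool; ++t)
        for (int f = 0; f < ld.f; ++f) {
          double gv = dpool(f, t, bb);
          if (gv == 0.0) continue;
          arma::uword u = cc.argmax(f, bb * ld.lpool + t);
          arma::uword col = bb * ld.lout + (arma::uword)t * ld.pool + u;
          if (cc.z(f, col) > 0) dzc(f, col) = gv;
        }
    g.W[l] = dzc * cc.col.t();
    g.b[l] = arma::sum(dzc, 1);
    if (l > 0) {
      arma::mat dcol = n.W[l].t() * dzc;
      const LayerDims& prev = n.conv[l - 1];
      arma::cube dx(prev.f, prev.lpool, B, arma::fill::zeros);
      col2im_add(dx, dcol, ld.k, ld.lout);
      dpool = dx;
    }
  }
  return loss;
}

arma::cube gather_slices(const arma::cube& x, const std::vector<arma::uword>& idx) {
  arma::cube out(x.n_rows, x.n_cols, idx.size());
  for (size_t i = 0; i < idx.size(); ++i) out.slice(i) = x.slice(idx[i]);
  return out;
}

// AUROC via mid-rank statistic (internal copy for the early-stopping metric;
// the user-facing implementation lives in R and is oracle-tested there)
double auroc_ranks(const arma::vec& score, const arma::vec& label) {
  const arma::uword n = score.n_elem;
  arma::uvec ord = arma::stable_sort_index(score);
  arma::vec ranks(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && score(ord(j + 1)) == score(ord(i))) ++j;
    double r = 0.5 * ((i + 1) + (j + 1));
    for (arma::uword t = i; t <= j; ++t) ranks(ord(t)) = r;
    i = j + 1;
  }
  double n1 = arma::accu(label), n0 = n - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  double rsum = arma::accu(ranks.elem(arma::find(label > 0.5)));
  return (rsum - n1 * (n1 + 1) / 2.0) / (n1 * n0);
}

arma::mat predict_batched(const Net& n, const arma::cube& X, int batch) {
  const arma::uword N = X.n_slices;
  arma::mat out(N, n.F);
  for (arma::uword s = 0; s < N; s += batch) {
    arma::uword e = std::min(N, s + (arma::uword)batch);
    arma::cube xb = X.slices(s, e - 1);
    FwdCache fc = forward(n, xb, 0.0, nullptr);
    out.rows(s, e - 1) = fc.probs.t();
  }
  return out;
}

} // namespace

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_cnn_init(IntegerVector conv_filters, IntegerVector conv_sizes,
                  IntegerVector pools, IntegerVector fc_sizes,
                  int n_features, int window_length, int seed) {
  if (conv_filters.size() != 3 || conv_sizes.size() != 3 || pools.size() != 3)
    stop("exactly 3 convolutional stages are required");
  if (fc_sizes.size() != 2) stop("exactly 2 fully connected stages are required");
  std::vector<int> dims;
  dims.push_back(window_length);
  dims.push_back(n_features);
  int cin = 4, lin = window_length;
  std::vector<LayerDims> conv;
  for (int l = 0; l < 3; ++l) {
    LayerDims ld;
    ld.cin = cin; ld.k = conv_sizes[l]; ld.f = conv_filters[l]; ld.pool = pools[l];
    ld.lin = lin;
    ld.lout = lin - ld.k + 1;
    if (ld.lout < 1)
      stop("pooling/filter chain incompatible with input length: conv layer %d "
           "receives length %d but has filter size %d", l + 1, lin, ld.k);
    ld.lpool = ld.lout / ld.pool;
    if (ld.lpool < 1)
      stop("pooling chain collapses spatial axis at layer %d (conv output %d, pool %d)",
           l + 1, ld.lout, ld.pool);
    conv.push_back(ld);
    dims.push_back(ld.cin); dims.push_back(ld.k); dims.push_back(ld.f);
    dims.push_back(ld.pool); dims.push_back(ld.lin); dims.push_back(ld.lout);
    dims.push_back(ld.lpool);
    cin = ld.f; lin = ld.lpool;
  }
  dims.push_back(fc_sizes[0]); dims.push_back(fc_sizes[1]);

  Rng rng((uint64_t)seed * 2654435761ULL + 1);
  Net n;
  n.conv = conv; n.F = n_features; n.L = window_length;
  n.fc1 = fc_sizes[0]; n.fc2 = fc_sizes[1];
  int flat = conv[2].f * conv[2].lpool;
  std::vector<std::pair<int, int>> shapes = {
    {conv[0].f, conv[0].cin * conv[0].k},
    {conv[1].f, conv[1].cin * conv[1].k},
    {conv[2].f, conv[2].cin * conv[2].k},
    {fc_sizes[0], flat},
    {fc_sizes[1], fc_sizes[0]},
    {n_features, fc_sizes[1]}};
  for (int i = 0; i < 6; ++i) {
    double sd = std::sqrt((i == 5 ? 1.0 : 2.0) / shapes[i].second); // He / Glorot-out
    arma::mat W(shapes[i].first, shapes[i].second);
    W.imbue([&]() { return rng.norm() * sd; });
    n.W.push_back(W);
    n.b.push_back(arma::vec(shapes[i].first, arma::fill::zeros));
  }
  return net_to_list(n, wrap(dims));
}

// [[Rcpp::export]]
List cpp_cnn_train(List params, arma::cube X, arma::mat Y,
                   arma::cube Xval, arma::mat Yval,
                   double lr, int batch_size, int patience, int max_epochs,
                   double dropout, double weight_decay, int seed,
                   int eval_batch) {
  Net n = net_from_list(params);
  arma::mat yT = Y.t();        // F x N
  const arma::uword N = X.n_slices;
  Rng rng((uint64_t)seed * 0xD1B54A32D192ED03ULL + 7);

  // which validation features carry both classes (others are excluded from
  // the stopping metric)
  arma::vec valmask(n.F, arma::fill::zeros);
  for (int f = 0; f < n.F; ++f) {
    double s = arma::accu(Yval.col(f));
    if (s > 0 && s < Yval.n_rows) valmask(f) = 1;
  }

  Grads g; g.W.resize(6); g.b.resize(6);
  std::vector<arma::mat> cW(6); std::vector<arma::vec> cb(6);
  for (int i = 0; i < 6; ++i) {
    cW[i] = arma::mat(arma::size(n.W[i]), arma::fill::zeros);
    cb[i] = arma::vec(n.b[i].n_elem, arma::fill::zeros);
  }
  const double rho = 0.9, eps = 1e-8;

  std::vector<arma::uword> idx(N);
  for (arma::uword i = 0; i < N; ++i) idx[i] = i;

  Net best = n;
  double best_auc = -1.0;
  int best_epoch = 0, since_best = 0;
  std::vector<double> log_loss, log_auc;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    shuffle_vec(idx, rng);
    double epoch_loss = 0; int nb = 0;
    for (arma::uword s = 0; s < N; s += batch_size) {
      arma::uword e = std::min(N, s + (arma::uword)batch_size);
      std::vector<arma::uword> bidx(idx.begin() + s, idx.begin() + e);
      arma::cube xb = gather_slices(X, bidx);
      arma::mat yb(n.F, bidx.size());
      for (size_t i = 0; i < bidx.size(); ++i) yb.col(i) = yT.col(bidx[i]);
      FwdCache fc = forward(n, xb, dropout, &rng);
      epoch_loss += backward(n, xb, yb, fc, g);
      ++nb;
      for (int i = 0; i < 6; ++i) {
        if (weight_decay > 0) g.W[i] += weight_decay * n.W[i];
        cW[i] = rho * cW[i] + (1 - rho) * arma::square(g.W[i]);
        n.W[i] -= lr * g.W[i] / (arma::sqrt(cW[i]) + eps);
        cb[i] = rho * cb[i] + (1 - rho) * arma::square(g.b[i]);
        n.b[i] -= lr * g.b[i] / (arma::sqrt(cb[i]) + eps);
      }
    }
    arma::mat pv = predict_batched(n, Xval, eval_batch);
    double asum = 0; int acnt = 0;
    for (int f = 0; f < n.F; ++f) {
      if (valmask(f) < 0.5) continue;
      double a = auroc_ranks(pv.col(f), Yval.col(f));
      if (!ISNAN(a)) { asum += a; ++acnt; }
    }
    double mean_auc = acnt ? asum / acnt : NA_REAL;
    log_loss.push_back(epoch_loss / std::max(nb, 1));
    log_auc.push_back(mean_auc);
    if (!ISNAN(mean_auc) && mean_auc > best_auc) {
      best_auc = mean_auc; best = n; best_epoch = epoch; since_best = 0;
    } else {
      ++since_best;
      if (since_best >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  IntegerVector dims = params["dims"];
  List out = net_to_list(best, dims);
  int ne = (int)log_loss.size();
  IntegerVector ep(ne);
  for (int i = 0; i < ne; ++i) ep[i] = i + 1;
  return List::create(
    Named("params") = out,
    Named("log") = DataFrame::create(Named("epoch") = ep,
                                     Named("train_loss") = wrap(log_loss),
                                     Named("val_auroc") = wrap(log_auc)),
    Named("best_epoch") = best_epoch,
    Named("best_val_auroc") = best_auc);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(List params, arma::cube X, int batch_size) {
  Net n = net_from_list(params);
  if ((int)X.n_cols != n.L)
    stop("window length %d does not match model input length %d",
         (int)X.n_cols, n.L);
  return predict_batched(n, X, batch_size);
}

// [[Rcpp::export]]
arma::cube cpp_conv1_activations(List params, arma::cube X) {
  Net n = net_from_list(params);
  if ((int)X.n_cols != n.L)
    stop("window length %d does not match model input length %d",
         (int)X.n_cols, n.L);
  const LayerDims& ld = n.conv[0];
  arma::cube out(ld.f, ld.lout, X.n_slices);
  for (arma::uword b = 0; b < X.n_slices; ++b) {
    arma::cube xb = X.slices(b, b);
    arma::mat col = im2col(xb, ld.k, ld.lout);
    arma::mat z = n.W[0] * col;
    z.each_col() += n.b[0];
    out.slice(b) = z;
  }
  return out;
}
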