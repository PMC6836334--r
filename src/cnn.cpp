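// 1D convolutional RWC regressor: forward, backprop and SGDM training.
//
// Single-precision throughout; convolutions are evaluated as im2col +
// BLAS gemm. Activation layout: an fmat of size C x (L*B) whose columns
// are sample-major blocks of L positions, so flattening a sample is a
// plain memory reshape.
//
// Architecture (fixed family, sizes from the config):
//   input (Cin x L)
//   -> conv(c1,k1) + BN + ReLU
//   -> conv(c2,k2) + BN + ReLU -> maxpool(2)
//   -> conv(c3,k3) + BN + ReLU -> maxpool(2)
//   -> flatten -> FC(f1) -> dropout -> FC(f2) -> dropout -> FC(1)
// trained with mean-squared-error loss.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// the training loop allocates multi-megabyte temporaries every batch;
// keeping them on the heap instead of fresh mmap segments avoids
// repeated page-fault + zeroing costs
static void keep_large_allocs_on_heap() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1024 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 1024 * 1024 * 1024);
#endif
}

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

struct Cfg {
  int Cin, L, c1, k1, c2, k2, c3, k3, f1, f2;
  int L2, L3, flat;  // lengths after the two pools; flattened size
  float drop;
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.Cin = Rcpp::as<int>(cfg["n_channels"]);
  c.L = Rcpp::as<int>(cfg["input_length"]);
  Rcpp::IntegerVector kc = cfg["conv_kernel_counts"];
  Rcpp::IntegerVector ks = cfg["conv_kernel_sizes"];
  c.c1 = kc[0]; c.c2 = kc[1]; c.c3 = kc[2];
  c.k1 = ks[0]; c.k2 = ks[1]; c.k3 = ks[2];
  Rcpp::IntegerVector fc = cfg["fc_sizes"];
  c.f1 = fc[0]; c.f2 = fc[1];
  c.drop = Rcpp::as<double>(cfg["dropout_prob"]);
  c.L2 = c.L / 2;
  c.L3 = c.L2 / 2;
  c.flat = c.c3 * c.L3;
  return c;
}

// ---- parameter container ------------------------------------------------

struct Net {
  fmat Wc1, Wc2, Wc3, Wf1, Wf2, Wf3;
  fvec bc1, bc2, bc3, bf1, bf2, bf3;
  fvec g1, be1, g2, be2, g3, be3;        // BN scale/shift
  fvec rm1, rv1, rm2, rv2, rm3, rv3;     // BN running mean/var

  std::vector<fmat*> mats() { return {&Wc1, &Wc2, &Wc3, &Wf1, &Wf2, &Wf3}; }
  std::vector<fvec*> vecs() {
    return {&bc1, &bc2, &bc3, &bf1, &bf2, &bf3,
            &g1, &be1, &g2, &be2, &g3, &be3};
  }
  static std::vector<std::string> mat_names() {
    return {"Wc1", "Wc2", "Wc3", "Wf1", "Wf2", "Wf3"};
  }
  static std::vector<std::string> vec_names() {
    return {"bc1", "bc2", "bc3", "bf1", "bf2", "bf3",
            "g1", "be1", "g2", "be2", "g3", "be3"};
  }
};

static Net net_from_lists(const List& params, const List& bn) {
  Net n;
  auto getm = [&](const char* nm) {
    return conv_to<fmat>::from(Rcpp::as<arma::mat>(params[nm]));
  };
  auto getv = [&](const List& l, const char* nm) {
    return conv_to<fvec>::from(Rcpp::as<arma::vec>(l[nm]));
  };
  n.Wc1 = getm("Wc1"); n.Wc2 = getm("Wc2"); n.Wc3 = getm("Wc3");
  n.Wf1 = getm("Wf1"); n.Wf2 = getm("Wf2"); n.Wf3 = getm("Wf3");
  n.bc1 = getv(params, "bc1"); n.bc2 = getv(params, "bc2");
  n.bc3 = getv(params, "bc3"); n.bf1 = getv(params, "bf1");
  n.bf2 = getv(params, "bf2"); n.bf3 = getv(params, "bf3");
  n.g1 = getv(params, "g1"); n.be1 = getv(params, "be1");
  n.g2 = getv(params, "g2"); n.be2 = getv(params, "be2");
  n.g3 = getv(params, "g3"); n.be3 = getv(params, "be3");
  n.rm1 = getv(bn, "rm1"); n.rv1 = getv(bn, "rv1");
  n.rm2 = getv(bn, "rm2"); n.rv2 = getv(bn, "rv2");
  n.rm3 = getv(bn, "rm3"); n.rv3 = getv(bn, "rv3");
  return n;
}

static List params_to_list(Net& n) {
  List out;
  auto ms = n.mats(); auto mn = Net::mat_names();
  for (size_t i = 0; i < ms.size(); ++i)
    out[mn[i]] = Rcpp::wrap(conv_to<arma::mat>::from(*ms[i]));
  auto vs = n.vecs(); auto vn = Net::vec_names();
  for (size_t i = 0; i < vs.size(); ++i)
    out[vn[i]] = Rcpp::wrap(conv_to<arma::vec>::from(*vs[i]));
  return out;
}

static List bn_to_list(const Net& n) {
  auto w = [](const fvec& v) { return Rcpp::wrap(conv_to<arma::vec>::from(v)); };
  return List::create(
    Named("rm1") = w(n.rm1), Named("rv1") = w(n.rv1),
    Named("rm2") = w(n.rm2), Named("rv2") = w(n.rv2),
    Named("rm3") = w(n.rm3), Named("rv3") = w(n.rv3));
}

// ---- primitive layers ---------------------------------------------------

// Same-padding 1D convolution evaluated as one gemm per kernel tap on a
// zero-padded copy of the activations (padded block stride P = L + 2*pad,
// interior at columns [pad, pad + L) of each sample block). The global
// column shift u -> u + (j - pad) never crosses into a neighbouring
// sample's interior because |j - pad| <= pad, so a single gemm covers
// all samples at once. Weight layout: W(c_out, j*Cin + c_in).

static fmat pad_blocks(const fmat& A, int C, int L, int B, int pad) {
  int P = L + 2 * pad;
  fmat Ap(C, (uword)P * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    Ap.cols((uword)b * P + pad, (uword)b * P + pad + L - 1) =
      A.cols((uword)b * L, (uword)b * L + L - 1);
  return Ap;
}

static fmat unpad_blocks(const fmat& Ap, int C, int L, int B, int pad) {
  int P = L + 2 * pad;
  fmat A(C, (uword)L * B);
  for (int b = 0; b < B; ++b)
    A.cols((uword)b * L, (uword)b * L + L - 1) =
      Ap.cols((uword)b * P + pad, (uword)b * P + pad + L - 1);
  return A;
}

// forward: Y[, u] = sum_j W_j A_pad[, u + j - pad]; returns the padded
// input via `ApOut` for reuse in the backward pass
static fmat conv_forward(const fmat& A, const fmat& W, const fvec& bias,
                         int Cin, int L, int B, int ks, fmat& ApOut) {
  int pad = (ks - 1) / 2, P = L + 2 * pad;
  uword n = (uword)P * B;
  fmat Ap = pad_blocks(A, Cin, L, B, pad);
  fmat Yp(W.n_rows, n, fill::zeros);
  for (int j = 0; j < ks; ++j) {
    int s = j - pad;
    uword u0 = s < 0 ? (uword)(-s) : 0, u1 = s > 0 ? n - 1 - s : n - 1;
    Yp.cols(u0, u1) +=
      W.cols((uword)j * Cin, (uword)(j + 1) * Cin - 1) * Ap.cols(u0 + s, u1 + s);
  }
  fmat Y = unpad_blocks(Yp, W.n_rows, L, B, pad);
  Y.each_col() += bias;
  ApOut = std::move(Ap);
  return Y;
}

// backward: fills dW/db and (when wantInput) returns dA
static fmat conv_backward(const fmat& dY, const fmat& Ap, const fmat& W,
                          int Cin, int L, int B, int ks, bool wantInput,
                          fmat& dW, fvec& db) {
  int pad = (ks - 1) / 2, P = L + 2 * pad;
  uword n = (uword)P * B;
  int Cout = W.n_rows;
  fmat dYp = pad_blocks(dY, Cout, L, B, pad);  // zero outside the interior
  dW.zeros(Cout, (uword)Cin * ks);
  db = sum(dY, 1);
  fmat dAp;
  if (wantInput) dAp.zeros(Cin, n);
  for (int j = 0; j < ks; ++j) {
    int s = j - pad;
    uword u0 = s < 0 ? (uword)(-s) : 0, u1 = s > 0 ? n - 1 - s : n - 1;
    dW.cols((uword)j * Cin, (uword)(j + 1) * Cin - 1) =
      dYp.cols(u0, u1) * Ap.cols(u0 + s, u1 + s).t();
    if (wantInput)
      dAp.cols(u0 + s, u1 + s) +=
        W.cols((uword)j * Cin, (uword)(j + 1) * Cin - 1).t() * dYp.cols(u0, u1);
  }
  if (!wantInput) return fmat();
  return unpad_blocks(dAp, Cin, L, B, pad);
}

struct BnCache { fmat xhat; fvec invstd; };

// batch normalization over each channel (row), fused with the following
// ReLU. Transforms Z in place; training mode uses batch statistics,
// updates the running estimates, and stores xhat plus the ReLU mask.
static void bn_relu_forward(fmat& Z, const fvec& g, const fvec& be,
                            fvec& rm, fvec& rv, bool train,
                            BnCache* cache, fmat* reluMask) {
  const uword C = Z.n_rows, n = Z.n_cols;
  if (train) {
    fvec s(C, fill::zeros), q(C, fill::zeros);
    for (uword c = 0; c < n; ++c) {
      const float* z = Z.colptr(c);
      for (uword r = 0; r < C; ++r) { s[r] += z[r]; q[r] += z[r] * z[r]; }
    }
    fvec mu = s / (float)n;
    fvec sig2 = q / (float)n - square(mu);
    sig2.transform([](float v) { return v < 0.0f ? 0.0f : v; });
    fvec invstd = 1.0f / sqrt(sig2 + BN_EPS);
    rm = (1.0f - BN_MOMENTUM) * rm + BN_MOMENTUM * mu;
    rv = (1.0f - BN_MOMENTUM) * rv + BN_MOMENTUM * sig2;
    fmat xhat(C, n);
    if (reluMask) reluMask->set_size(C, n);
    for (uword c = 0; c < n; ++c) {
      float* z = Z.colptr(c);
      float* xh = xhat.colptr(c);
      float* mk = reluMask ? reluMask->colptr(c) : nullptr;
      for (uword r = 0; r < C; ++r) {
        float x = (z[r] - mu[r]) * invstd[r];
        xh[r] = x;
        float v = g[r] * x + be[r];
        if (mk) { float m = v > 0.0f ? 1.0f : 0.0f; mk[r] = m; z[r] = v * m; }
        else z[r] = v;
      }
    }
    if (cache) { cache->xhat = std::move(xhat); cache->invstd = std::move(invstd); }
    return;
  }
  fvec invstd = 1.0f / sqrt(rv + BN_EPS);
  for (uword c = 0; c < n; ++c) {
    float* z = Z.colptr(c);
    for (uword r = 0; r < C; ++r) {
      float v = g[r] * (z[r] - rm[r]) * invstd[r] + be[r];
      if (reluMask) v = v > 0.0f ? v : 0.0f;
      z[r] = v;
    }
  }
}

// backward through ReLU (mask) + batch norm, in place on dY
static void bn_relu_backward(fmat& dY, const fmat& reluMask, const BnCache& c,
                             const fvec& g, fvec& dg, fvec& dbe) {
  const uword C = dY.n_rows, n = dY.n_cols;
  dbe.zeros(C); dg.zeros(C);
  for (uword cc = 0; cc < n; ++cc) {
    float* dy = dY.colptr(cc);
    const float* mk = reluMask.colptr(cc);
    const float* xh = c.xhat.colptr(cc);
    for (uword r = 0; r < C; ++r) {
      float d = dy[r] * mk[r];
      dy[r] = d;                 // store the masked gradient back
      dbe[r] += d;
      dg[r] += d * xh[r];
    }
  }
  // sums of dxhat and dxhat*xhat follow from dbe/dg since dxhat = g*dy
  fvec s1 = (g % dbe) / (float)n;
  fvec s2 = (g % dg) / (float)n;
  for (uword cc = 0; cc < n; ++cc) {
    float* dy = dY.colptr(cc);
    const float* xh = c.xhat.colptr(cc);
    for (uword r = 0; r < C; ++r)
      dy[r] = c.invstd[r] * (g[r] * dy[r] - s1[r] - xh[r] * s2[r]);
  }
}

// pooling index helpers: column indices of the two pooled neighbours
static void pool_indices(int L, int Lout, int B, uvec& i0, uvec& i1) {
  i0.set_size((uword)Lout * B); i1.set_size((uword)Lout * B);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < Lout; ++l) {
      i0[(uword)b * Lout + l] = (uword)b * L + 2 * l;
      i1[(uword)b * Lout + l] = (uword)b * L + 2 * l + 1;
    }
}

// ---- full forward pass --------------------------------------------------

struct FwdCache {
  fmat A1p, A2p, A3p;        // zero-padded conv inputs
  fmat R1, R2, R3;           // ReLU masks (as float 0/1)
  BnCache B1, B2, B3;
  fmat K2, K3;               // pool argmax masks
  uvec i0a, i1a, i0b, i1b;   // pool index maps
  fmat F, H1d, H2d;          // flatten, post-dropout FC activations
  fmat D1, D2;               // dropout masks
  frowvec pred;
};

static frowvec forward(const Cfg& c, Net& n, const fmat& A0, int B,
                       bool train, FwdCache* cc, std::mt19937* gen) {
  // block 1
  fmat A1p;
  fmat Z = conv_forward(A0, n.Wc1, n.bc1, c.Cin, c.L, B, c.k1, A1p);
  fmat R1;
  bn_relu_forward(Z, n.g1, n.be1, n.rm1, n.rv1, train,
                  cc ? &cc->B1 : nullptr, &R1);
  // block 2 + pool
  fmat A2p;
  fmat Z2 = conv_forward(Z, n.Wc2, n.bc2, c.c1, c.L, B, c.k2, A2p);
  fmat R2;
  bn_relu_forward(Z2, n.g2, n.be2, n.rm2, n.rv2, train,
                  cc ? &cc->B2 : nullptr, &R2);
  uvec i0a, i1a; pool_indices(c.L, c.L2, B, i0a, i1a);
  fmat A2a = Z2.cols(i0a), A2b = Z2.cols(i1a);
  fmat K2 = conv_to<fmat>::from(A2a >= A2b);
  fmat P2 = K2 % A2a + (1.0f - K2) % A2b;
  // block 3 + pool
  fmat A3p;
  fmat Z3 = conv_forward(P2, n.Wc3, n.bc3, c.c2, c.L2, B, c.k3, A3p);
  fmat R3;
  bn_relu_forward(Z3, n.g3, n.be3, n.rm3, n.rv3, train,
                  cc ? &cc->B3 : nullptr, &R3);
  uvec i0b, i1b; pool_indices(c.L2, c.L3, B, i0b, i1b);
  fmat A3a = Z3.cols(i0b), A3b = Z3.cols(i1b);
  fmat K3 = conv_to<fmat>::from(A3a >= A3b);
  fmat P3 = K3 % A3a + (1.0f - K3) % A3b;
  // head
  fmat F = reshape(P3, c.flat, B);
  fmat H1 = n.Wf1 * F; H1.each_col() += n.bf1;
  fmat D1;
  if (train && c.drop > 0.0f && gen) {
    std::uniform_real_distribution<float> unif(0.0f, 1.0f);
    D1.set_size(H1.n_rows, H1.n_cols);
    for (uword i = 0; i < D1.n_elem; ++i)
      D1[i] = unif(*gen) < c.drop ? 0.0f : 1.0f / (1.0f - c.drop);
    H1 %= D1;
  }
  fmat H2 = n.Wf2 * H1; H2.each_col() += n.bf2;
  fmat D2;
  if (train && c.drop > 0.0f && gen) {
    std::uniform_real_distribution<float> unif(0.0f, 1.0f);
    D2.set_size(H2.n_rows, H2.n_cols);
    for (uword i = 0; i < D2.n_elem; ++i)
      D2[i] = unif(*gen) < c.drop ? 0.0f : 1.0f / (1.0f - c.drop);
    H2 %= D2;
  }
  fmat Yp = n.Wf3 * H2; Yp.each_col() += n.bf3;
  frowvec pred = Yp.row(0);
  if (cc) {
    cc->A1p = std::move(A1p); cc->A2p = std::move(A2p); cc->A3p = std::move(A3p);
    cc->R1 = std::move(R1); cc->R2 = std::move(R2); cc->R3 = std::move(R3);
    cc->K2 = std::move(K2); cc->K3 = std::move(K3);
    cc->i0a = std::move(i0a); cc->i1a = std::move(i1a);
    cc->i0b = std::move(i0b); cc->i1b = std::move(i1b);
    cc->F = std::move(F); cc->H1d = std::move(H1); cc->H2d = std::move(H2);
    cc->D1 = std::move(D1); cc->D2 = std::move(D2);
    cc->pred = pred;
  }
  return pred;
}

// ---- backward pass: fills a gradient Net --------------------------------

static void backward(const Cfg& c, Net& n, const FwdCache& cc,
                     const frowvec& dpred, int B, Net& g) {
  fmat dY(1, B);
  dY.row(0) = dpred;
  // FC3
  g.Wf3 = dY * cc.H2d.t();
  g.bf3 = sum(dY, 1);
  fmat dH2 = n.Wf3.t() * dY;
  if (cc.D2.n_elem) dH2 %= cc.D2;
  // FC2
  g.Wf2 = dH2 * cc.H1d.t();
  g.bf2 = sum(dH2, 1);
  fmat dH1 = n.Wf2.t() * dH2;
  if (cc.D1.n_elem) dH1 %= cc.D1;
  // FC1
  g.Wf1 = dH1 * cc.F.t();
  g.bf1 = sum(dH1, 1);
  fmat dF = n.Wf1.t() * dH1;
  // unflatten + unpool 3
  fmat dP3 = reshape(dF, c.c3, (uword)c.L3 * B);
  fmat dZ3(c.c3, (uword)c.L2 * B, fill::zeros);
  dZ3.cols(cc.i0b) += dP3 % cc.K3;
  dZ3.cols(cc.i1b) += dP3 % (1.0f - cc.K3);
  bn_relu_backward(dZ3, cc.R3, cc.B3, n.g3, g.g3, g.be3);
  fmat dP2 = conv_backward(dZ3, cc.A3p, n.Wc3, c.c2, c.L2, B, c.k3,
                           true, g.Wc3, g.bc3);
  // unpool 2
  fmat dZ2(c.c2, (uword)c.L * B, fill::zeros);
  dZ2.cols(cc.i0a) += dP2 % cc.K2;
  dZ2.cols(cc.i1a) += dP2 % (1.0f - cc.K2);
  bn_relu_backward(dZ2, cc.R2, cc.B2, n.g2, g.g2, g.be2);
  fmat dZ1 = conv_backward(dZ2, cc.A2p, n.Wc2, c.c1, c.L, B, c.k2,
                           true, g.Wc2, g.bc2);
  bn_relu_backward(dZ1, cc.R1, cc.B1, n.g1, g.g1, g.be1);
  conv_backward(dZ1, cc.A1p, n.Wc1, c.Cin, c.L, B, c.k1,
                false, g.Wc1, g.bc1);  // input gradient not needed
}

// assemble the activation matrix (Cin x L*B) for a set of sample columns
static fmat gather_batch(const Cfg& c, const fmat& X, const uvec& idx) {
  int B = idx.n_elem;
  fmat A0(c.Cin, (uword)c.L * B);
  for (int b = 0; b < B; ++b)
    for (int ch = 0; ch < c.Cin; ++ch)
      for (int l = 0; l < c.L; ++l)
        A0(ch, (uword)b * c.L + l) = X((uword)ch * c.L + l, idx[b]);
  return A0;
}

// ---- exported interface -------------------------------------------------

// [[Rcpp::export]]
List cnn_init_cpp(List cfg, int seed) {
  Cfg c = parse_cfg(cfg);
  std::mt19937 gen(seed);
  auto uini = [&](int rows, int cols, float scale) {
    // uniform fan-in; the fully connected head uses a 10x smaller
    // scale so the (linear) head's initial gain stays well below 1,
    // which the large configured initial learning rate requires
    float lim = scale * std::sqrt(6.0f / (float)cols);
    std::uniform_real_distribution<float> unif(-lim, lim);
    fmat W(rows, cols);
    for (uword i = 0; i < W.n_elem; ++i) W[i] = unif(gen);
    return W;
  };
  Net n;
  n.Wc1 = uini(c.c1, c.Cin * c.k1, 1.0f); n.bc1 = fvec(c.c1, fill::zeros);
  n.Wc2 = uini(c.c2, c.c1 * c.k2, 1.0f); n.bc2 = fvec(c.c2, fill::zeros);
  n.Wc3 = uini(c.c3, c.c2 * c.k3, 1.0f); n.bc3 = fvec(c.c3, fill::zeros);
  n.Wf1 = uini(c.f1, c.flat, 0.1f); n.bf1 = fvec(c.f1, fill::zeros);
  n.Wf2 = uini(c.f2, c.f1, 0.1f); n.bf2 = fvec(c.f2, fill::zeros);
  n.Wf3 = uini(1, c.f2, 0.1f); n.bf3 = fvec(1, fill::zeros);
  n.g1 = fvec(c.c1, fill::ones); n.be1 = fvec(c.c1, fill::zeros);
  n.g2 = fvec(c.c2, fill::ones); n.be2 = fvec(c.c2, fill::zeros);
  n.g3 = fvec(c.c3, fill::ones); n.be3 = fvec(c.c3, fill::zeros);
  n.rm1 = fvec(c.c1, fill::zeros); n.rv1 = fvec(c.c1, fill::ones);
  n.rm2 = fvec(c.c2, fill::zeros); n.rv2 = fvec(c.c2, fill::ones);
  n.rm3 = fvec(c.c3, fill::zeros); n.rv3 = fvec(c.c3, fill::ones);
  return List::create(Named("params") = params_to_list(n),
                      Named("bn") = bn_to_list(n));
}

// [[Rcpp::export]]
List cnn_train_cpp(List params, List bn, arma::mat X, arma::vec y,
                   List cfg, int epochs, int batchSize, double lr0,
                   double momentum, double l2, arma::ivec lrDropEpochs,
                   int seed) {
  Cfg c = parse_cfg(cfg);
  keep_large_allocs_on_heap();
  Net n = net_from_lists(params, bn);
  fmat Xf = conv_to<fmat>::from(X);
  frowvec yf = conv_to<frowvec>::from(y.t());
  int N = Xf.n_cols;
  if ((int)Xf.n_rows != c.Cin * c.L) Rcpp::stop("shape error: input rows");
  if ((int)y.n_elem != N) Rcpp::stop("shape error: target length");

  // velocity state
  Net v = n;
  for (auto* m : v.mats()) m->zeros();
  for (auto* w : v.vecs()) w->zeros();

  std::mt19937 gen(seed);
  std::vector<uword> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  std::vector<double> lossTrace;
  for (int epoch = 1; epoch <= epochs; ++epoch) {
    float lr = (float)lr0;
    for (uword d = 0; d < lrDropEpochs.n_elem; ++d)
      if (epoch >= lrDropEpochs[d]) lr *= 0.1f;
    std::shuffle(order.begin(), order.end(), gen);
    double epochLoss = 0.0; int seen = 0;
    for (int start = 0; start < N; start += batchSize) {
      int B = std::min(batchSize, N - start);
      uvec idx(B);
      for (int b = 0; b < B; ++b) idx[b] = order[start + b];
      fmat A0 = gather_batch(c, Xf, idx);
      FwdCache cc;
      frowvec pred = forward(c, n, A0, B, true, &cc, &gen);
      frowvec err(B);
      for (int b = 0; b < B; ++b) err[b] = pred[b] - yf[idx[b]];
      double loss = mean(square(conv_to<vec>::from(err.t())));
      if (!std::isfinite(loss))
        Rcpp::stop("training failure: non-finite loss at epoch %d (lr0=%g, l2=%g)",
                   epoch, lr0, l2);
      epochLoss += loss * B; seen += B;
      frowvec dpred = 2.0f * err / (float)B;
      Net g = n;  // same shapes; contents overwritten
      backward(c, n, cc, dpred, B, g);
      // SGDM: weight decay on weight matrices only
      auto nm = n.mats(); auto gm = g.mats(); auto vm = v.mats();
      for (size_t i = 0; i < nm.size(); ++i) {
        *vm[i] = (float)momentum * (*vm[i]) -
                 lr * (*gm[i] + (float)l2 * (*nm[i]));
        *nm[i] += *vm[i];
      }
      auto nv = n.vecs(); auto gv = g.vecs(); auto vv = v.vecs();
      for (size_t i = 0; i < nv.size(); ++i) {
        *vv[i] = (float)momentum * (*vv[i]) - lr * (*gv[i]);
        *nv[i] += *vv[i];
      }
    }
    lossTrace.push_back(epochLoss / seen);
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    Named("params") = params_to_list(n),
    Named("bn") = bn_to_list(n),
    Named("lossTrace") = Rcpp::wrap(lossTrace));
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(List params, List bn, arma::mat X, List cfg) {
  Cfg c = parse_cfg(cfg);
  Net n = net_from_lists(params, bn);
  fmat Xf = conv_to<fmat>::from(X);
  int N = Xf.n_cols;
  if ((int)Xf.n_rows != c.Cin * c.L) Rcpp::stop("shape error: input rows");
  vec out(N);
  int batch = 128;
  for (int start = 0; start < N; start += batch) {
    int B = std::min(batch, N - start);
    uvec idx(B);
    for (int b = 0; b < B; ++b) idx[b] = start + b;
    fmat A0 = gather_batch(c, Xf, idx);
    frowvec pred = forward(c, n, A0, B, false, nullptr, nullptr);
    for (int b = 0; b < B; ++b) out[start + b] = pred[b];
  }
  return out;
}

// training-mode loss and gradients on one batch with dropout disabled;
// used by finite-difference gradient checks
// [[Rcpp::export]]
List cnn_grad_cpp(List params, List bn, arma::mat X, arma::vec y, List cfg) {
  Cfg c = parse_cfg(cfg);
  c.drop = 0.0f;
  Net n = net_from_lists(params, bn);
  fmat Xf = conv_to<fmat>::from(X);
  int B = Xf.n_cols;
  uvec idx(B);
  for (int b = 0; b < B; ++b) idx[b] = b;
  fmat A0 = gather_batch(c, Xf, idx);
  FwdCache cc;
  frowvec pred = forward(c, n, A0, B, true, &cc, nullptr);
  frowvec yf = conv_to<frowvec>::from(y.t());
  frowvec err = pred - yf;
  double loss = mean(square(conv_to<vec>::from(err.t())));
  frowvec dpred = 2.0f * err / (float)B;
  Net g = n;
  backward(c, n, cc, dpred, B, g);
  return List::create(Named("loss") = loss,
                      Named("grads") = params_to_list(g));
}

// [[Rcpp::export]]
double cnn_loss_cpp(List params, List bn, arma::mat X, arma::vec y, List cfg) {
  Cfg c = parse_cfg(cfg);
  c.drop = 0.0f;
  Net n = net_from_lists(params, bn);
  fmat Xf = conv_to<fmat>::from(X);
  int B = Xf.n_cols;
  uvec idx(B);
  for (int b = 0; b < B; ++b) idx[b] = b;
  fmat A0 = gather_batch(c, Xf, idx);
  FwdCache cc;
  frowvec pred = forward(c, n, A0, B, true, &cc, nullptr);
  frowvec yf = conv_to<frowvec>::from(y.t());
  return mean(square(conv_to<vec>::from((pred - yf).t())));
}
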