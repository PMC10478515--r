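// Persistent training workspace for the embedding / baseline network.
//
// All large buffers (im2col patch matrices, layer activations, gradients,
// Adam moments) are allocated once per workspace and reused across training
// steps; the R side only ships images in and embeddings/gradients out.
// Math is kept in exact correspondence with the plain-R reference engine in
// R/nn-engine.R (same batch-norm epsilon/momentum, first-wins pooling ties,
// ReLU masks on pre-activation sign), which the test suite verifies.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static const int K = 5;
static const double BN_EPS = 1e-5;
static const double BN_MOM = 0.1;

struct BNLayer {
  vec gamma, beta, rmean, rvar;   // learnable + running stats
  vec mu, invsd;                  // batch stats cache
  vec g_gamma, g_beta;            // gradients
  vec m_gamma, v_gamma, m_beta, v_beta;  // Adam moments
};

struct ConvLayer {
  mat W; vec b;
  mat gW; vec gb;
  mat mW, vW; vec mb, vb;
};

struct FCLayer {
  mat W; vec b;
  mat gW; vec gb;
  mat mW, vW; vec mb, vb;
};

struct NetWS {
  // architecture
  int S, C1, C2, hidden, out_dim;
  bool l2head;
  int s1, p1, s2, p2, flat;
  int N;          // batch capacity (buffers sized for this)
  int adam_t;

  ConvLayer c1, c2;
  BNLayer bn1, bn2;
  FCLayer f1, f2;

  // forward buffers
  mat cols1, Z1, A1, xh1, y1;
  mat P1out; arma::ivec which1;
  mat cols2, Z2, A2, xh2, y2;
  mat P2out; arma::ivec which2;
  mat H1, H1r, E, out;
  vec nrm;
  int cur_n;      // columns used in the last forward
  bool trained_fw;

  // backward scratch
  mat dZ1, dZ2, dBN1y, dX2, dH1, dE;
};

typedef Rcpp::XPtr<NetWS> WSPtr;

// ---- helpers ----------------------------------------------------------

static void im2col(const double* x, int Cin, int H, int W, int n, mat& cols) {
  // x: n image volumes (Cin,H,W) channel-fastest; cols: (K*K*Cin) x (pos*n)
  const int oh = H - K + 1, ow = W - K + 1;
  const size_t P = (size_t)K * K * Cin, img = (size_t)Cin * H * W;
  double* op = cols.memptr();
  for (int im = 0; im < n; ++im) {
    const double* xn = x + im * img;
    for (int cc = 0; cc < ow; ++cc)
      for (int r = 0; r < oh; ++r) {
        double* col = op + ((size_t)im * oh * ow + (size_t)cc * oh + r) * P;
        for (int kj = 0; kj < K; ++kj) {
          const double* src = xn + (size_t)Cin * (r + (size_t)H * (cc + kj));
          double* dst = col + (size_t)kj * K * Cin;
          for (int ki = 0; ki < K; ++ki) {
            std::copy(src, src + Cin, dst);
            src += Cin; dst += Cin;
          }
        }
      }
  }
}

static void col2im_acc(const mat& dcols, int Cin, int H, int W, int n, mat& dX) {
  const int oh = H - K + 1, ow = W - K + 1;
  const size_t P = (size_t)K * K * Cin, img = (size_t)Cin * H * W;
  dX.zeros();
  const double* dp = dcols.memptr();
  double* xp = dX.memptr();
  for (int im = 0; im < n; ++im) {
    double* xn = xp + im * img;
    for (int cc = 0; cc < ow; ++cc)
      for (int r = 0; r < oh; ++r) {
        const double* col = dp + ((size_t)im * oh * ow + (size_t)cc * oh + r) * P;
        for (int kj = 0; kj < K; ++kj) {
          double* dst = xn + (size_t)Cin * (r + (size_t)H * (cc + kj));
          const double* src = col + (size_t)kj * K * Cin;
          for (int ki = 0; ki < K; ++ki) {
            for (int c = 0; c < Cin; ++c) dst[c] += src[c];
            src += Cin; dst += Cin;
          }
        }
      }
  }
}

static void pool_fw(const mat& y, int C, int H, int W, int n,
                    mat& out, arma::ivec& which) {
  const int ph = H / 2, pw = W / 2;
  const double* ap = y.memptr();
  double* op = out.memptr();
  arma::sword* wp = which.memptr();
  const size_t img = (size_t)C * H * W;
  for (int im = 0; im < n; ++im) {
    const double* an = ap + im * img;
    for (int pc = 0; pc < pw; ++pc)
      for (int pr = 0; pr < ph; ++pr) {
        const double* b00 = an + (size_t)C * (2 * pr + (size_t)H * (2 * pc));
        const double* b10 = b00 + C;
        const double* b01 = b00 + (size_t)C * H;
        const double* b11 = b01 + C;
        size_t o = ((size_t)im * pw * ph + (size_t)pc * ph + pr) * C;
        for (int c = 0; c < C; ++c) {
          double m = b00[c]; int w = 0;
          if (b10[c] > m) { m = b10[c]; w = 1; }
          if (b01[c] > m) { m = b01[c]; w = 2; }
          if (b11[c] > m) { m = b11[c]; w = 3; }
          op[o + c] = m; wp[o + c] = w;
        }
      }
  }
}

static void pool_bw(const mat& dpool, const arma::ivec& which,
                    int C, int H, int W, int n, mat& dA) {
  const int ph = H / 2, pw = W / 2;
  dA.zeros();
  const double* dp = dpool.memptr();
  const arma::sword* wp = which.memptr();
  double* ap = dA.memptr();
  const size_t img = (size_t)C * H * W;
  for (int im = 0; im < n; ++im) {
    double* an = ap + im * img;
    for (int pc = 0; pc < pw; ++pc)
      for (int pr = 0; pr < ph; ++pr) {
        double* b00 = an + (size_t)C * (2 * pr + (size_t)H * (2 * pc));
        size_t o = ((size_t)im * pw * ph + (size_t)pc * ph + pr) * C;
        for (int c = 0; c < C; ++c) {
          int w = wp[o + c];
          double* dst = b00 + c;
          if (w == 1) dst = b00 + C + c;
          else if (w == 2) dst = b00 + (size_t)C * H + c;
          else if (w == 3) dst = b00 + (size_t)C * H + C + c;
          *dst += dp[o + c];
        }
      }
  }
}

static void relu_into(const mat& z, mat& a) {
  const double* zp = z.memptr();
  double* ap = a.memptr();
  for (size_t i = 0; i < z.n_elem; ++i) ap[i] = zp[i] > 0 ? zp[i] : 0;
}

// BN forward on the first m columns; training mode computes batch stats.
static void bn_fw(BNLayer& bn, const mat& x, int m, bool training,
                  mat& xhat, mat& y) {
  const int C = x.n_rows;
  const double* xp = x.memptr();
  if (training) {
    bn.mu.zeros(C);
    vec sq(C, arma::fill::zeros);
    for (size_t j = 0; j < (size_t)m; ++j) {
      const double* xc = xp + j * C;
      for (int c = 0; c < C; ++c) { bn.mu[c] += xc[c]; sq[c] += xc[c] * xc[c]; }
    }
    bn.mu /= m;
    vec v = sq / m - bn.mu % bn.mu;
    v.transform([](double z) { return z < 0 ? 0.0 : z; });
    bn.invsd = 1.0 / arma::sqrt(v + BN_EPS);
    double ub = m > 1 ? (double)m / (m - 1) : 1.0;
    bn.rmean = (1 - BN_MOM) * bn.rmean + BN_MOM * bn.mu;
    bn.rvar = (1 - BN_MOM) * bn.rvar + BN_MOM * v * ub;
    double* hp = xhat.memptr();
    double* yp = y.memptr();
    for (size_t j = 0; j < (size_t)m; ++j) {
      const double* xc = xp + j * C;
      double* hc = hp + j * C;
      double* yc = yp + j * C;
      for (int c = 0; c < C; ++c) {
        hc[c] = (xc[c] - bn.mu[c]) * bn.invsd[c];
        yc[c] = bn.gamma[c] * hc[c] + bn.beta[c];
      }
    }
  } else {
    vec inv = 1.0 / arma::sqrt(bn.rvar + BN_EPS);
    double* yp = y.memptr();
    for (size_t j = 0; j < (size_t)m; ++j) {
      const double* xc = xp + j * C;
      double* yc = yp + j * C;
      for (int c = 0; c < C; ++c)
        yc[c] = bn.gamma[c] * (xc[c] - bn.rmean[c]) * inv[c] + bn.beta[c];
    }
  }
}

// BN backward; overwrites dy with dx.
static void bn_bw(BNLayer& bn, mat& dy, const mat& xhat, int m) {
  const int C = dy.n_rows;
  bn.g_gamma.zeros(C);
  bn.g_beta.zeros(C);
  double* dp = dy.memptr();
  const double* hp = xhat.memptr();
  for (size_t j = 0; j < (size_t)m; ++j) {
    const double* hc = hp + j * C;
    double* dc = dp + j * C;
    for (int c = 0; c < C; ++c) {
      bn.g_gamma[c] += dc[c] * hc[c];
      bn.g_beta[c] += dc[c];
    }
  }
  // dx = inv/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  vec sum_dx = bn.g_beta % bn.gamma;        // sum of dxhat rows
  vec sum_dxh = bn.g_gamma % bn.gamma;      // sum of dxhat*xhat rows
  for (size_t j = 0; j < (size_t)m; ++j) {
    const double* hc = hp + j * C;
    double* dc = dp + j * C;
    for (int c = 0; c < C; ++c) {
      double dxhat = dc[c] * bn.gamma[c];
      dc[c] = (bn.invsd[c] / m) * (m * dxhat - sum_dx[c] - hc[c] * sum_dxh[c]);
    }
  }
}

// ---- workspace construction -------------------------------------------

// [[Rcpp::export]]
SEXP cpp_ws_create(int input_size, int C1, int C2, int hidden, int out_dim,
                   bool l2head, int batch_capacity) {
  NetWS* ws = new NetWS();
  ws->S = input_size; ws->C1 = C1; ws->C2 = C2;
  ws->hidden = hidden; ws->out_dim = out_dim; ws->l2head = l2head;
  ws->s1 = input_size - K + 1; ws->p1 = ws->s1 / 2;
  ws->s2 = ws->p1 - K + 1; ws->p2 = ws->s2 / 2;
  ws->flat = C2 * ws->p2 * ws->p2;
  ws->N = batch_capacity;
  ws->adam_t = 0;
  ws->cur_n = 0;
  ws->trained_fw = false;

  const int N = batch_capacity;
  const int M1 = ws->s1 * ws->s1 * N, M2 = ws->s2 * ws->s2 * N;

  ws->c1.W.set_size(C1, K * K); ws->c1.b.zeros(C1);
  ws->c2.W.set_size(C2, K * K * C1); ws->c2.b.zeros(C2);
  ws->f1.W.set_size(hidden, ws->flat); ws->f1.b.zeros(hidden);
  ws->f2.W.set_size(out_dim, hidden); ws->f2.b.zeros(out_dim);
  for (BNLayer* bn : {&ws->bn1, &ws->bn2}) {
    int C = (bn == &ws->bn1) ? C1 : C2;
    bn->gamma.ones(C); bn->beta.zeros(C);
    bn->rmean.zeros(C); bn->rvar.ones(C);
  }

  ws->cols1.set_size(K * K, M1);
  ws->Z1.set_size(C1, M1); ws->A1.set_size(C1, M1);
  ws->xh1.set_size(C1, M1); ws->y1.set_size(C1, M1);
  ws->P1out.set_size(C1 * ws->p1 * ws->p1, N);
  ws->which1.set_size((size_t)C1 * ws->p1 * ws->p1 * N);
  ws->cols2.set_size(K * K * C1, M2);
  ws->Z2.set_size(C2, M2); ws->A2.set_size(C2, M2);
  ws->xh2.set_size(C2, M2); ws->y2.set_size(C2, M2);
  ws->P2out.set_size(ws->flat, N);
  ws->which2.set_size((size_t)ws->flat * N);
  ws->H1.set_size(hidden, N); ws->H1r.set_size(hidden, N);
  ws->E.set_size(out_dim, N); ws->out.set_size(out_dim, N);
  ws->nrm.set_size(N);

  ws->dZ1.set_size(C1, M1); ws->dZ2.set_size(C2, M2);
  ws->dBN1y.set_size(C1, M1);
  ws->dX2.set_size(C1 * ws->p1 * ws->p1, N);
  ws->dH1.set_size(hidden, N); ws->dE.set_size(out_dim, N);

  // gradient and Adam buffers
  auto init_conv = [](ConvLayer& L) {
    L.gW.zeros(L.W.n_rows, L.W.n_cols); L.gb.zeros(L.b.n_elem);
    L.mW.zeros(L.W.n_rows, L.W.n_cols); L.vW.zeros(L.W.n_rows, L.W.n_cols);
    L.mb.zeros(L.b.n_elem); L.vb.zeros(L.b.n_elem);
  };
  init_conv(ws->c1); init_conv(ws->c2);
  auto init_fc = [](FCLayer& L) {
    L.gW.zeros(L.W.n_rows, L.W.n_cols); L.gb.zeros(L.b.n_elem);
    L.mW.zeros(L.W.n_rows, L.W.n_cols); L.vW.zeros(L.W.n_rows, L.W.n_cols);
    L.mb.zeros(L.b.n_elem); L.vb.zeros(L.b.n_elem);
  };
  init_fc(ws->f1); init_fc(ws->f2);
  auto init_bn = [](BNLayer& bn) {
    int C = bn.gamma.n_elem;
    bn.g_gamma.zeros(C); bn.g_beta.zeros(C);
    bn.m_gamma.zeros(C); bn.v_gamma.zeros(C);
    bn.m_beta.zeros(C); bn.v_beta.zeros(C);
  };
  init_bn(ws->bn1); init_bn(ws->bn2);

  return WSPtr(ws, true);
}

// [[Rcpp::export]]
void cpp_ws_set_params(SEXP p, List params) {
  WSPtr ws(p);
  ws->c1.W = as<mat>(params["conv1_W"]); ws->c1.b = as<vec>(params["conv1_b"]);
  ws->bn1.gamma = as<vec>(params["bn1_gamma"]); ws->bn1.beta = as<vec>(params["bn1_beta"]);
  ws->c2.W = as<mat>(params["conv2_W"]); ws->c2.b = as<vec>(params["conv2_b"]);
  ws->bn2.gamma = as<vec>(params["bn2_gamma"]); ws->bn2.beta = as<vec>(params["bn2_beta"]);
  ws->f1.W = as<mat>(params["fc1_W"]); ws->f1.b = as<vec>(params["fc1_b"]);
  ws->f2.W = as<mat>(params["fc2_W"]); ws->f2.b = as<vec>(params["fc2_b"]);
}

// [[Rcpp::export]]
void cpp_ws_set_state(SEXP p, List state) {
  WSPtr ws(p);
  ws->bn1.rmean = as<vec>(state["bn1_mean"]); ws->bn1.rvar = as<vec>(state["bn1_var"]);
  ws->bn2.rmean = as<vec>(state["bn2_mean"]); ws->bn2.rvar = as<vec>(state["bn2_var"]);
}

// [[Rcpp::export]]
List cpp_ws_get_params(SEXP p) {
  WSPtr ws(p);
  return List::create(
    _["conv1_W"] = ws->c1.W, _["conv1_b"] = ws->c1.b,
    _["bn1_gamma"] = ws->bn1.gamma, _["bn1_beta"] = ws->bn1.beta,
    _["conv2_W"] = ws->c2.W, _["conv2_b"] = ws->c2.b,
    _["bn2_gamma"] = ws->bn2.gamma, _["bn2_beta"] = ws->bn2.beta,
    _["fc1_W"] = ws->f1.W, _["fc1_b"] = ws->f1.b,
    _["fc2_W"] = ws->f2.W, _["fc2_b"] = ws->f2.b);
}

// [[Rcpp::export]]
List cpp_ws_get_state(SEXP p) {
  WSPtr ws(p);
  return List::create(
    _["bn1_mean"] = ws->bn1.rmean, _["bn1_var"] = ws->bn1.rvar,
    _["bn2_mean"] = ws->bn2.rmean, _["bn2_var"] = ws->bn2.rvar);
}

// ---- forward / backward / update --------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_ws_forward(SEXP p, const NumericMatrix& X, bool training) {
  WSPtr ws(p);
  const int n = X.ncol();
  if (n > ws->N) stop("batch of %d exceeds workspace capacity %d", n, ws->N);
  if (X.nrow() != ws->S * ws->S) stop("input rows do not match input_size^2");
  ws->cur_n = n;
  ws->trained_fw = training;

  const int M1 = ws->s1 * ws->s1 * n, M2 = ws->s2 * ws->s2 * n;

  im2col(X.begin(), 1, ws->S, ws->S, n, ws->cols1);
  {
    mat Zv(ws->Z1.memptr(), ws->c1.W.n_rows, M1, false, true);
    mat Cv(ws->cols1.memptr(), K * K, M1, false, true);
    Zv = ws->c1.W * Cv;
    Zv.each_col() += ws->c1.b;
  }
  relu_into(ws->Z1, ws->A1);  // full-buffer pass; unused columns are ignored
  {
    mat Av(ws->A1.memptr(), ws->C1, M1, false, true);
    mat Hv(ws->xh1.memptr(), ws->C1, M1, false, true);
    mat Yv(ws->y1.memptr(), ws->C1, M1, false, true);
    bn_fw(ws->bn1, Av, M1, training, Hv, Yv);
    pool_fw(Yv, ws->C1, ws->s1, ws->s1, n, ws->P1out, ws->which1);
  }

  im2col(ws->P1out.memptr(), ws->C1, ws->p1, ws->p1, n, ws->cols2);
  {
    mat Zv(ws->Z2.memptr(), ws->c2.W.n_rows, M2, false, true);
    mat Cv(ws->cols2.memptr(), K * K * ws->C1, M2, false, true);
    Zv = ws->c2.W * Cv;
    Zv.each_col() += ws->c2.b;
  }
  relu_into(ws->Z2, ws->A2);
  {
    mat Av(ws->A2.memptr(), ws->C2, M2, false, true);
    mat Hv(ws->xh2.memptr(), ws->C2, M2, false, true);
    mat Yv(ws->y2.memptr(), ws->C2, M2, false, true);
    bn_fw(ws->bn2, Av, M2, training, Hv, Yv);
    pool_fw(Yv, ws->C2, ws->s2, ws->s2, n, ws->P2out, ws->which2);
  }

  {
    mat Fv(ws->P2out.memptr(), ws->flat, n, false, true);
    mat Hv(ws->H1.memptr(), ws->hidden, n, false, true);
    Hv = ws->f1.W * Fv;
    Hv.each_col() += ws->f1.b;
    mat Hrv(ws->H1r.memptr(), ws->hidden, n, false, true);
    relu_into(Hv, Hrv);
    mat Ev(ws->E.memptr(), ws->out_dim, n, false, true);
    Ev = ws->f2.W * Hrv;
    Ev.each_col() += ws->f2.b;
    mat Ov(ws->out.memptr(), ws->out_dim, n, false, true);
    if (ws->l2head) {
      for (int j = 0; j < n; ++j) {
        double s = std::max(arma::norm(Ev.col(j), 2), 1e-12);
        ws->nrm[j] = s;
        Ov.col(j) = Ev.col(j) / s;
      }
    } else {
      Ov = 1.0 / (1.0 + arma::exp(-Ev));
    }
    return wrap(Ov);
  }
}

// dout: out_dim x n. For the sigmoid head, supply d(loss)/d(pre-sigmoid).
// [[Rcpp::export]]
void cpp_ws_backward(SEXP p, const NumericMatrix& dout_r) {
  WSPtr ws(p);
  const int n = ws->cur_n;
  if (!ws->trained_fw) stop("backward requires a preceding training-mode forward");
  if (dout_r.ncol() != n || dout_r.nrow() != ws->out_dim)
    stop("dout dimensions do not match the last forward batch");
  const int M1 = ws->s1 * ws->s1 * n, M2 = ws->s2 * ws->s2 * n;

  mat dE(ws->dE.memptr(), ws->out_dim, n, false, true);
  {
    mat dout(const_cast<double*>(dout_r.begin()), ws->out_dim, n, false, true);
    if (ws->l2head) {
      mat Ov(ws->out.memptr(), ws->out_dim, n, false, true);
      for (int j = 0; j < n; ++j) {
        double s = arma::dot(Ov.col(j), dout.col(j));
        dE.col(j) = (dout.col(j) - Ov.col(j) * s) / ws->nrm[j];
      }
    } else {
      dE = dout;
    }
  }

  mat H1rv(ws->H1r.memptr(), ws->hidden, n, false, true);
  mat H1v(ws->H1.memptr(), ws->hidden, n, false, true);
  mat Fv(ws->P2out.memptr(), ws->flat, n, false, true);
  ws->f2.gW = dE * H1rv.t();
  ws->f2.gb = arma::sum(dE, 1);
  mat dH1(ws->dH1.memptr(), ws->hidden, n, false, true);
  dH1 = ws->f2.W.t() * dE;
  // ReLU mask on fc1 pre-activation
  {
    double* dp = dH1.memptr(); const double* hp = H1v.memptr();
    for (size_t i = 0; i < (size_t)ws->hidden * n; ++i)
      if (hp[i] <= 0) dp[i] = 0;
  }
  ws->f1.gW = dH1 * Fv.t();
  ws->f1.gb = arma::sum(dH1, 1);

  // dflat -> pool2 backward -> bn2 -> relu -> conv2
  mat dBN2y(ws->dZ2.memptr(), ws->C2, M2, false, true);  // reuse dZ2 buffer
  {
    mat dflat = ws->f1.W.t() * dH1;   // flat x n (small)
    pool_bw(dflat, ws->which2, ws->C2, ws->s2, ws->s2, n, dBN2y);
  }
  {
    mat xh(ws->xh2.memptr(), ws->C2, M2, false, true);
    bn_bw(ws->bn2, dBN2y, xh, M2);
  }
  {
    const double* zp = ws->Z2.memptr(); double* dp = dBN2y.memptr();
    for (size_t i = 0; i < (size_t)ws->C2 * M2; ++i)
      if (zp[i] <= 0) dp[i] = 0;
  }
  mat cols2v(ws->cols2.memptr(), K * K * ws->C1, M2, false, true);
  ws->c2.gW = dBN2y * cols2v.t();
  ws->c2.gb = arma::sum(dBN2y, 1);
  // reuse cols2 buffer for dcols2 (cols2 no longer needed)
  cols2v = ws->c2.W.t() * dBN2y;
  {
    mat dX2(ws->dX2.memptr(), ws->C1 * ws->p1 * ws->p1, n, false, true);
    col2im_acc(cols2v, ws->C1, ws->p1, ws->p1, n, dX2);
    mat dBN1y(ws->dZ1.memptr(), ws->C1, M1, false, true);   // reuse dZ1
    pool_bw(dX2, ws->which1, ws->C1, ws->s1, ws->s1, n, dBN1y);
    mat xh(ws->xh1.memptr(), ws->C1, M1, false, true);
    bn_bw(ws->bn1, dBN1y, xh, M1);
    const double* zp = ws->Z1.memptr(); double* dp = dBN1y.memptr();
    for (size_t i = 0; i < (size_t)ws->C1 * M1; ++i)
      if (zp[i] <= 0) dp[i] = 0;
    mat cols1v(ws->cols1.memptr(), K * K, M1, false, true);
    ws->c1.gW = dBN1y * cols1v.t();
    ws->c1.gb = arma::sum(dBN1y, 1);
  }
}

static void adam_one(mat& w, mat& g, mat& m, mat& v, double lr, double b1,
                     double b2, double eps, double bc1, double bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}
static void adam_one(vec& w, vec& g, vec& m, vec& v, double lr, double b1,
                     double b2, double eps, double bc1, double bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

// [[Rcpp::export]]
void cpp_ws_adam_step(SEXP p, double lr, double beta1, double beta2,
                      double eps) {
  WSPtr ws(p);
  ws->adam_t += 1;
  double bc1 = 1 - std::pow(beta1, ws->adam_t);
  double bc2 = 1 - std::pow(beta2, ws->adam_t);
  adam_one(ws->c1.W, ws->c1.gW, ws->c1.mW, ws->c1.vW, lr, beta1, beta2, eps, bc1, bc2);
  adam_one(ws->c1.b, ws->c1.gb, ws->c1.mb, ws->c1.vb, lr, beta1, beta2, eps, bc1, bc2);
  adam_one(ws->bn1.gamma, ws->bn1.g_gamma, ws->bn1.m_gamma, ws->bn1.v_gamma, lr, beta1, beta2, eps, bc1, bc2);
  adam_one(ws->bn1.beta, ws->bn1.g_beta, ws->bn1.m_beta, ws->bn1.v_beta, lr, beta1, beta2, eps, bc1, bc2);
  adam_one(ws->c2.W, ws->c2.gW, ws->c2.mW, ws->c2.vW, lr, beta1, beta2, eps, bc1, bc2);
  adam_one(ws->c2.b, ws->c2.gb, ws->c2.mb, ws->c2.vb, lr, beta1, beta2, eps, bc1, bc2);
  adam_one(ws->bn2.gamma, ws->bn2.g_gamma, ws->bn2.m_gamma, ws->bn2.v_gamma, lr, beta1, beta2, eps, bc1, bc2);
  adam_one(ws->bn2.beta, ws->bn2.g_beta, ws->bn2.m_beta, ws->bn2.v_beta, lr, beta1, beta2, eps, bc1, bc2);
  adam_one(ws->f1.W, ws->f1.gW, ws->f1.mW, ws->f1.vW, lr, beta1, beta2, eps, bc1, bc2);
  adam_one(ws->f1.b, ws->f1.gb, ws->f1.mb, ws->f1.vb, lr, beta1, beta2, eps, bc1, bc2);
  adam_one(ws->f2.W, ws->f2.gW, ws->f2.mW, ws->f2.vW, lr, beta1, beta2, eps, bc1, bc2);
  adam_one(ws->f2.b, ws->f2.gb, ws->f2.mb, ws->f2.vb, lr, beta1, beta2, eps, bc1, bc2);
}

// [[Rcpp::export]]
List cpp_ws_get_grads(SEXP p) {
  WSPtr ws(p);
  return List::create(
    _["conv1_W"] = ws->c1.gW, _["conv1_b"] = ws->c1.gb,
    _["bn1_gamma"] = ws->bn1.g_gamma, _["bn1_beta"] = ws->bn1.g_beta,
    _["conv2_W"] = ws->c2.gW, _["conv2_b"] = ws->c2.gb,
    _["bn2_gamma"] = ws->bn2.g_gamma, _["bn2_beta"] = ws->bn2.g_beta,
    _["fc1_W"] = ws->f1.gW, _["fc1_b"] = ws->f1.gb,
    _["fc2_W"] = ws->f2.gW, _["fc2_b"] = ws->f2.gb);
}
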