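// Compact convolutional network for single-trial EEG classification.
//
// Architecture (input C channels x T samples, one trial per slice):
//   Block 1: temporal convolution (F1 kernels of length kt, same padding)
//            -> depthwise spatial convolution ((C,1), depth D, valid)
//            -> batch norm -> ELU -> dropout -> average pool (1,p1)
//   Block 2: depthwise temporal convolution (1,ks, same padding)
//            -> pointwise convolution (F2 = F1*D mixing filters)
//            -> batch norm -> ELU -> dropout -> average pool (1,p2)
//   Block 3: flatten -> dense -> softmax
//
// Convolutions are evaluated as banded (Toeplitz) matrix products so the
// heavy lifting is BLAS GEMM; gradients are analytic throughout and are
// verified against numerical differentiation in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uvec;

struct Dims {
  int C, T, F1, D, F2, kt, ks, p1, p2, ncls;
  int T1, T2, padL1, padL2;
};

static Dims read_dims(const List& params) {
  Dims d;
  IntegerVector dm = params["dims"]; // C,T,F1,D,kt,ks,p1,p2,ncls
  d.C = dm[0]; d.T = dm[1]; d.F1 = dm[2]; d.D = dm[3];
  d.kt = dm[4]; d.ks = dm[5]; d.p1 = dm[6]; d.p2 = dm[7]; d.ncls = dm[8];
  d.F2 = d.F1 * d.D;
  d.T1 = d.T / d.p1;
  d.T2 = d.T1 / d.p2;
  d.padL1 = (d.kt - 1) / 2;
  d.padL2 = (d.ks - 1) / 2;
  return d;
}

struct Weights {
  mat wt;                 // F1 x kt
  mat wsp;                // F2 x C   (row f*D+d acts on temporal map f)
  vec g1, b1, rm1, rv1;   // batch norm 1
  mat wsep;               // F2 x ks
  mat wpw;                // F2 x F2
  vec g2, b2, rm2, rv2;   // batch norm 2
  mat wd;                 // ncls x (F2*T2)
  vec bd;                 // ncls
};

static Weights read_weights(const List& params) {
  Weights w;
  w.wt = as<mat>(params["wt"]);     w.wsp = as<mat>(params["wsp"]);
  w.g1 = as<vec>(params["bn1_gamma"]); w.b1 = as<vec>(params["bn1_beta"]);
  w.rm1 = as<vec>(params["bn1_rmean"]); w.rv1 = as<vec>(params["bn1_rvar"]);
  w.wsep = as<mat>(params["wsep"]); w.wpw = as<mat>(params["wpw"]);
  w.g2 = as<vec>(params["bn2_gamma"]); w.b2 = as<vec>(params["bn2_beta"]);
  w.rm2 = as<vec>(params["bn2_rmean"]); w.rv2 = as<vec>(params["bn2_rvar"]);
  w.wd = as<mat>(params["wd"]);     w.bd = as<vec>(params["bd"]);
  return w;
}

static List write_weights(const Weights& w, const IntegerVector& dims) {
  return List::create(
    _["dims"] = dims,
    _["wt"] = w.wt, _["wsp"] = w.wsp,
    _["bn1_gamma"] = w.g1, _["bn1_beta"] = w.b1,
    _["bn1_rmean"] = w.rm1, _["bn1_rvar"] = w.rv1,
    _["wsep"] = w.wsep, _["wpw"] = w.wpw,
    _["bn2_gamma"] = w.g2, _["bn2_beta"] = w.b2,
    _["bn2_rmean"] = w.rm2, _["bn2_rvar"] = w.rv2,
    _["wd"] = w.wd, _["bd"] = w.bd);
}

// banded matrix for a "same"-padded 1-d convolution of length-T signals:
// y[i] = sum_k w[k] * x[i + k - padL]
static mat toeplitz_band(const arma::rowvec& w, int T, int padL) {
  mat M(T, T, arma::fill::zeros);
  for (int k = 0; k < (int)w.n_elem; ++k) {
    int o = k - padL;
    if (o >= 0 && o < T) M.diag(o).fill(w(k));
    else if (o < 0 && -o < T) M.diag(o).fill(w(k));
  }
  return M;
}

static const double BN_EPS = 1e-5;
static const double BN_MOM = 0.1;

// everything the backward pass needs from one forward evaluation
struct Cache {
  mat Xmat;                       // (nb*C) x T
  std::vector<mat> A1;            // F1 of (nb*C) x T
  cube xhat1, e1, drop1;          // F2 x T x nb
  vec std1;
  cube P1;                        // F2 x T1 x nb   (input to block 2)
  cube S;                         // after separable depthwise
  cube xhat2, e2, drop2;          // F2 x T1 x nb
  vec std2;
  mat flat;                       // (F2*T2) x nb
  mat probs;                      // ncls x nb
};

struct Grads {
  mat wt, wsp, wsep, wpw, wd;
  vec g1, b1, g2, b2, bd;
};

static double elu(double x) { return x > 0 ? x : std::expm1(x); }

// forward pass on a batch; training mode uses batch statistics for the
// batch-norm layers (updating the running estimates) and applies
// inverted dropout with the supplied RNG.
static void forward(const Dims& d, Weights& w, const cube& Xb, bool train,
                    double drop_p, std::mt19937& rng, Cache& cc) {
  int nb = Xb.n_slices;
  // flatten to (nb*C) x T, row n*C+c = channel c of trial n
  cc.Xmat.set_size(nb * d.C, d.T);
  for (int n = 0; n < nb; ++n)
    cc.Xmat.rows(n * d.C, n * d.C + d.C - 1) = Xb.slice(n);

  // temporal convolution
  cc.A1.resize(d.F1);
  for (int f = 0; f < d.F1; ++f) {
    mat Tf = toeplitz_band(w.wt.row(f), d.T, d.padL1);
    cc.A1[f] = cc.Xmat * Tf.t();
  }

  // depthwise spatial convolution
  cube Z(d.F2, d.T, nb);
  for (int n = 0; n < nb; ++n)
    for (int f = 0; f < d.F1; ++f)
      Z.slice(n).rows(f * d.D, f * d.D + d.D - 1) =
        w.wsp.rows(f * d.D, f * d.D + d.D - 1) *
        cc.A1[f].rows(n * d.C, n * d.C + d.C - 1);

  // batch norm 1 (per feature map over time x batch)
  double M = (double)d.T * nb;
  cc.xhat1.set_size(d.F2, d.T, nb);
  cc.std1.set_size(d.F2);
  for (int r = 0; r < d.F2; ++r) {
    mat row(1, d.T * nb);
    int at = 0;
    for (int n = 0; n < nb; ++n) { row.cols(at, at + d.T - 1) = Z.slice(n).row(r); at += d.T; }
    double mu, var;
    if (train) {
      mu = arma::mean(arma::vectorise(row));
      var = arma::mean(arma::square(arma::vectorise(row) - mu));
      w.rm1(r) = (1 - BN_MOM) * w.rm1(r) + BN_MOM * mu;
      w.rv1(r) = (1 - BN_MOM) * w.rv1(r) + BN_MOM * var * (M / std::max(M - 1.0, 1.0));
    } else { mu = w.rm1(r); var = w.rv1(r); }
    double sd = std::sqrt(var + BN_EPS);
    cc.std1(r) = sd;
    for (int n = 0; n < nb; ++n)
      cc.xhat1.slice(n).row(r) = (Z.slice(n).row(r) - mu) / sd;
  }

  // scale/shift, ELU, dropout
  cc.e1.set_size(d.F2, d.T, nb);
  cc.drop1.set_size(d.F2, d.T, nb);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double keep = 1.0 - drop_p;
  for (int n = 0; n < nb; ++n)
    for (int r = 0; r < d.F2; ++r)
      for (int t = 0; t < d.T; ++t) {
        double v = w.g1(r) * cc.xhat1(r, t, n) + w.b1(r);
        cc.e1(r, t, n) = elu(v);
        double mk = (train && drop_p > 0) ? (unif(rng) < keep ? 1.0 / keep : 0.0) : 1.0;
        cc.drop1(r, t, n) = mk;
      }

  // average pool (1, p1)
  cc.P1.zeros(d.F2, d.T1, nb);
  for (int n = 0; n < nb; ++n)
    for (int r = 0; r < d.F2; ++r)
      for (int t = 0; t < d.T1; ++t) {
        double s = 0;
        for (int j = 0; j < d.p1; ++j)
          s += cc.e1(r, t * d.p1 + j, n) * cc.drop1(r, t * d.p1 + j, n);
        cc.P1(r, t, n) = s / d.p1;
      }

  // separable: depthwise temporal then pointwise
  cc.S.set_size(d.F2, d.T1, nb);
  std::vector<mat> Tsep(d.F2);
  for (int r = 0; r < d.F2; ++r)
    Tsep[r] = toeplitz_band(w.wsep.row(r), d.T1, d.padL2);
  for (int n = 0; n < nb; ++n)
    for (int r = 0; r < d.F2; ++r)
      cc.S.slice(n).row(r) = cc.P1.slice(n).row(r) * Tsep[r].t();
  cube PW(d.F2, d.T1, nb);
  for (int n = 0; n < nb; ++n)
    PW.slice(n) = w.wpw * cc.S.slice(n);

  // batch norm 2
  double M2 = (double)d.T1 * nb;
  cc.xhat2.set_size(d.F2, d.T1, nb);
  cc.std2.set_size(d.F2);
  for (int r = 0; r < d.F2; ++r) {
    arma::rowvec all(d.T1 * nb);
    int at = 0;
    for (int n = 0; n < nb; ++n) { all.cols(at, at + d.T1 - 1) = PW.slice(n).row(r); at += d.T1; }
    double mu, var;
    if (train) {
      mu = arma::mean(all);
      var = arma::mean(arma::square(all - mu));
      w.rm2(r) = (1 - BN_MOM) * w.rm2(r) + BN_MOM * mu;
      w.rv2(r) = (1 - BN_MOM) * w.rv2(r) + BN_MOM * var * (M2 / std::max(M2 - 1.0, 1.0));
    } else { mu = w.rm2(r); var = w.rv2(r); }
    double sd = std::sqrt(var + BN_EPS);
    cc.std2(r) = sd;
    for (int n = 0; n < nb; ++n)
      cc.xhat2.slice(n).row(r) = (PW.slice(n).row(r) - mu) / sd;
  }

  cc.e2.set_size(d.F2, d.T1, nb);
  cc.drop2.set_size(d.F2, d.T1, nb);
  for (int n = 0; n < nb; ++n)
    for (int r = 0; r < d.F2; ++r)
      for (int t = 0; t < d.T1; ++t) {
        double v = w.g2(r) * cc.xhat2(r, t, n) + w.b2(r);
        cc.e2(r, t, n) = elu(v);
        double mk = (train && drop_p > 0) ? (unif(rng) < keep ? 1.0 / keep : 0.0) : 1.0;
        cc.drop2(r, t, n) = mk;
      }

  // average pool (1, p2) and flatten (column-major within each slice)
  cc.flat.set_size(d.F2 * d.T2, nb);
  for (int n = 0; n < nb; ++n)
    for (int t = 0; t < d.T2; ++t)
      for (int r = 0; r < d.F2; ++r) {
        double s = 0;
        for (int j = 0; j < d.p2; ++j)
          s += cc.e2(r, t * d.p2 + j, n) * cc.drop2(r, t * d.p2 + j, n);
        cc.flat(t * d.F2 + r, n) = s / d.p2;
      }

  // dense + softmax
  mat logits = w.wd * cc.flat;
  logits.each_col() += w.bd;
  cc.probs.set_size(d.ncls, nb);
  for (int n = 0; n < nb; ++n) {
    vec l = logits.col(n);
    l -= l.max();
    vec e = arma::exp(l);
    cc.probs.col(n) = e / arma::accu(e);
  }
}

// backward pass; returns mean cross-entropy gradients for all trainable
// parameters. y holds 0-based class indices.
static void backward(const Dims& d, const Weights& w, const Cache& cc,
                     const arma::ivec& y, Grads& g) {
  int nb = cc.probs.n_cols;
  g.wt.zeros(d.F1, d.kt); g.wsp.zeros(d.F2, d.C);
  g.wsep.zeros(d.F2, d.ks); g.wpw.zeros(d.F2, d.F2);
  g.wd.zeros(d.ncls, d.F2 * d.T2);
  g.g1.zeros(d.F2); g.b1.zeros(d.F2); g.g2.zeros(d.F2); g.b2.zeros(d.F2);
  g.bd.zeros(d.ncls);

  mat dlog = cc.probs;
  for (int n = 0; n < nb; ++n) dlog(y(n), n) -= 1.0;
  dlog /= nb;

  g.wd = dlog * cc.flat.t();
  g.bd = arma::sum(dlog, 1);
  mat dflat = w.wd.t() * dlog;

  // unpool (1,p2), dropout, ELU, BN2 pre-gamma
  cube dh2(d.F2, d.T1, nb, arma::fill::zeros); // grad wrt xhat2 (pre-gamma after chain)
  for (int n = 0; n < nb; ++n)
    for (int t = 0; t < d.T2; ++t)
      for (int r = 0; r < d.F2; ++r) {
        double gv = dflat(t * d.F2 + r, n) / d.p2;
        for (int j = 0; j < d.p2; ++j) {
          int tt = t * d.p2 + j;
          double de = gv * cc.drop2(r, tt, n);
          double e = cc.e2(r, tt, n);
          double dv = de * (e > 0 ? 1.0 : e + 1.0); // grad wrt BN2 output
          g.g2(r) += dv * cc.xhat2(r, tt, n);
          g.b2(r) += dv;
          dh2(r, tt, n) = dv * w.g2(r);
        }
      }

  // BN2 backward
  double M2 = (double)d.T1 * nb;
  cube dPW(d.F2, d.T1, nb);
  for (int r = 0; r < d.F2; ++r) {
    double sum_dh = 0, sum_dh_xh = 0;
    for (int n = 0; n < nb; ++n)
      for (int t = 0; t < d.T1; ++t) {
        sum_dh += dh2(r, t, n);
        sum_dh_xh += dh2(r, t, n) * cc.xhat2(r, t, n);
      }
    for (int n = 0; n < nb; ++n)
      for (int t = 0; t < d.T1; ++t)
        dPW(r, t, n) = (dh2(r, t, n) - sum_dh / M2 -
                        cc.xhat2(r, t, n) * sum_dh_xh / M2) / cc.std2(r);
  }

  // pointwise and separable depthwise backward
  cube dS(d.F2, d.T1, nb);
  for (int n = 0; n < nb; ++n) {
    g.wpw += dPW.slice(n) * cc.S.slice(n).t();
    dS.slice(n) = w.wpw.t() * dPW.slice(n);
  }
  std::vector<mat> Tsep(d.F2);
  for (int r = 0; r < d.F2; ++r)
    Tsep[r] = toeplitz_band(w.wsep.row(r), d.T1, d.padL2);
  cube dP1(d.F2, d.T1, nb);
  for (int r = 0; r < d.F2; ++r) {
    mat dYr(nb, d.T1), Xr(nb, d.T1);
    for (int n = 0; n < nb; ++n) {
      dYr.row(n) = dS.slice(n).row(r);
      Xr.row(n) = cc.P1.slice(n).row(r);
    }
    mat G = dYr.t() * Xr; // T1 x T1
    for (int k = 0; k < d.ks; ++k) {
      int o = k - d.padL2;
      if (std::abs(o) < d.T1) g.wsep(r, k) = arma::accu(G.diag(o));
    }
    mat dXr = dYr * Tsep[r];
    for (int n = 0; n < nb; ++n) dP1.slice(n).row(r) = dXr.row(n);
  }

  // unpool (1,p1), dropout, ELU, BN1 pre-gamma
  cube dh1(d.F2, d.T, nb, arma::fill::zeros);
  for (int n = 0; n < nb; ++n)
    for (int r = 0; r < d.F2; ++r)
      for (int t = 0; t < d.T1; ++t) {
        double gv = dP1(r, t, n) / d.p1;
        for (int j = 0; j < d.p1; ++j) {
          int tt = t * d.p1 + j;
          double de = gv * cc.drop1(r, tt, n);
          double e = cc.e1(r, tt, n);
          double dv = de * (e > 0 ? 1.0 : e + 1.0);
          g.g1(r) += dv * cc.xhat1(r, tt, n);
          g.b1(r) += dv;
          dh1(r, tt, n) = dv * w.g1(r);
        }
      }

  // BN1 backward
  double M1 = (double)d.T * nb;
  cube dZ(d.F2, d.T, nb);
  for (int r = 0; r < d.F2; ++r) {
    double sum_dh = 0, sum_dh_xh = 0;
    for (int n = 0; n < nb; ++n)
      for (int t = 0; t < d.T; ++t) {
        sum_dh += dh1(r, t, n);
        sum_dh_xh += dh1(r, t, n) * cc.xhat1(r, t, n);
      }
    for (int n = 0; n < nb; ++n)
      for (int t = 0; t < d.T; ++t)
        dZ(r, t, n) = (dh1(r, t, n) - sum_dh / M1 -
                       cc.xhat1(r, t, n) * sum_dh_xh / M1) / cc.std1(r);
  }

  // depthwise spatial backward (and grad wrt the temporal-conv output)
  std::vector<mat> dA1(d.F1);
  for (int f = 0; f < d.F1; ++f) dA1[f].zeros(nb * d.C, d.T);
  for (int n = 0; n < nb; ++n)
    for (int f = 0; f < d.F1; ++f) {
      mat dZr = dZ.slice(n).rows(f * d.D, f * d.D + d.D - 1); // D x T
      mat block = cc.A1[f].rows(n * d.C, n * d.C + d.C - 1);  // C x T
      g.wsp.rows(f * d.D, f * d.D + d.D - 1) += dZr * block.t();
      dA1[f].rows(n * d.C, n * d.C + d.C - 1) =
        w.wsp.rows(f * d.D, f * d.D + d.D - 1).t() * dZr;
    }

  // temporal convolution kernel gradients (input grads not needed)
  for (int f = 0; f < d.F1; ++f) {
    mat G = dA1[f].t() * cc.Xmat; // T x T
    for (int k = 0; k < d.kt; ++k) {
      int o = k - d.padL1;
      if (std::abs(o) < d.T) g.wt(f, k) = arma::accu(G.diag(o));
    }
  }
}

static double batch_loss(const mat& probs, const arma::ivec& y) {
  double L = 0;
  for (arma::uword n = 0; n < probs.n_cols; ++n)
    L -= std::log(std::max(probs(y(n), n), 1e-12));
  return L / probs.n_cols;
}

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<mat> m, v;
  void init(const std::vector<mat*>& ps, double lr_) {
    lr = lr_;
    for (auto p : ps) { m.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
                        v.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros)); }
  }
  void step(std::vector<mat*>& ps, const std::vector<mat*>& gs) {
    ++t;
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * (*gs[i]);
      v[i] = b2 * v[i] + (1 - b2) * arma::square(*gs[i]);
      *ps[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
    }
  }
};

// [[Rcpp::export]]
List eegnet_init_cpp(int C, int T, int F1, int D, int kt, int ks,
                     int p1, int p2, int ncls, int seed) {
  int F2 = F1 * D;
  int T1 = T / p1, T2 = T1 / p2;
  if (T2 < 1) stop("input of %d samples too short for the pooling chain", T);
  std::mt19937 rng((unsigned)seed);
  auto glorot = [&](int rows, int cols, double fan_in, double fan_out) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> u(-lim, lim);
    mat m(rows, cols);
    for (int i = 0; i < rows; ++i)
      for (int j = 0; j < cols; ++j) m(i, j) = u(rng);
    return m;
  };
  Weights w;
  w.wt = glorot(F1, kt, kt, kt * F1);
  w.wsp = glorot(F2, C, C, D);
  w.g1 = vec(F2, arma::fill::ones); w.b1 = vec(F2, arma::fill::zeros);
  w.rm1 = vec(F2, arma::fill::zeros); w.rv1 = vec(F2, arma::fill::ones);
  w.wsep = glorot(F2, ks, ks, ks);
  w.wpw = glorot(F2, F2, F2, F2);
  w.g2 = vec(F2, arma::fill::ones); w.b2 = vec(F2, arma::fill::zeros);
  w.rm2 = vec(F2, arma::fill::zeros); w.rv2 = vec(F2, arma::fill::ones);
  w.wd = glorot(ncls, F2 * T2, F2 * T2, ncls);
  w.bd = vec(ncls, arma::fill::zeros);
  IntegerVector dims = IntegerVector::create(C, T, F1, D, kt, ks, p1, p2, ncls);
  return write_weights(w, dims);
}

static cube slice_trials(const cube& X, const uvec& idx) {
  cube out(X.n_rows, X.n_cols, idx.n_elem);
  for (arma::uword i = 0; i < idx.n_elem; ++i) out.slice(i) = X.slice(idx(i));
  return out;
}

// eval-mode forward returning class probabilities (ncls x N)
static mat predict_probs(const Dims& d, Weights w, const cube& X) {
  std::mt19937 rng(0);
  mat probs(d.ncls, X.n_slices);
  int chunk = 256;
  for (int at = 0; at < (int)X.n_slices; at += chunk) {
    int hi = std::min<int>(at + chunk, X.n_slices) - 1;
    uvec idx = arma::regspace<uvec>(at, hi);
    Cache cc;
    forward(d, w, slice_trials(X, idx), false, 0.0, rng, cc);
    probs.cols(at, hi) = cc.probs;
  }
  return probs;
}

// [[Rcpp::export]]
List eegnet_train_cpp(List params, arma::cube X, arma::ivec y,
                      arma::cube Xval, arma::ivec yval,
                      int epochs, int batch, double lr, double dropout,
                      int patience, int seed) {
  Dims d = read_dims(params);
  Weights w = read_weights(params);
  int N = X.n_slices;
  bool has_val = Xval.n_slices > 0;
  std::mt19937 rng((unsigned)seed + 1000003u);

  std::vector<mat*> ps = { &w.wt, &w.wsp, &w.wsep, &w.wpw, &w.wd };
  std::vector<mat> vec_store; // gamma/beta/bias handled as 1-col mats
  mat g1m(w.g1), b1m(w.b1), g2m(w.g2), b2m(w.b2), bdm(w.bd);
  ps.push_back(&g1m); ps.push_back(&b1m);
  ps.push_back(&g2m); ps.push_back(&b2m); ps.push_back(&bdm);
  Adam opt; opt.init(ps, lr);

  NumericVector h_tl(epochs, NA_REAL), h_ta(epochs, NA_REAL),
                h_vl(epochs, NA_REAL), h_va(epochs, NA_REAL);
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = -1, wait = 0, ran = 0;
  Weights best = w;

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; int ep_hits = 0;
    for (int at = 0; at < N; at += batch) {
      int hi = std::min(at + batch, N) - 1;
      uvec idx(hi - at + 1);
      arma::ivec yb(hi - at + 1);
      for (int i = at; i <= hi; ++i) { idx(i - at) = order[i]; yb(i - at) = y(order[i]); }
      Cache cc;
      w.g1 = g1m.col(0); w.b1 = b1m.col(0);
      w.g2 = g2m.col(0); w.b2 = b2m.col(0); w.bd = bdm.col(0);
      forward(d, w, slice_trials(X, idx), true, dropout, rng, cc);
      ep_loss += batch_loss(cc.probs, yb) * idx.n_elem;
      for (arma::uword n = 0; n < idx.n_elem; ++n)
        if ((int)cc.probs.col(n).index_max() == yb(n)) ++ep_hits;
      Grads g;
      backward(d, w, cc, yb, g);
      mat gg1(g.g1), gb1(g.b1), gg2(g.g2), gb2(g.b2), gbd(g.bd);
      std::vector<mat*> gs = { &g.wt, &g.wsp, &g.wsep, &g.wpw, &g.wd,
                               &gg1, &gb1, &gg2, &gb2, &gbd };
      opt.step(ps, gs);
    }
    w.g1 = g1m.col(0); w.b1 = b1m.col(0);
    w.g2 = g2m.col(0); w.b2 = b2m.col(0); w.bd = bdm.col(0);
    h_tl[ep] = ep_loss / N;
    h_ta[ep] = 100.0 * ep_hits / N;
    ran = ep + 1;
    if (has_val) {
      mat vp = predict_probs(d, w, Xval);
      h_vl[ep] = batch_loss(vp, yval);
      int hits = 0;
      for (arma::uword n = 0; n < vp.n_cols; ++n)
        if ((int)vp.col(n).index_max() == yval(n)) ++hits;
      h_va[ep] = 100.0 * hits / vp.n_cols;
      if (h_vl[ep] < best_val - 1e-9) {
        best_val = h_vl[ep]; best = w; best_epoch = ep; wait = 0;
      } else if (++wait >= patience) break;
    }
  }
  if (has_val && best_epoch >= 0) w = best;
  IntegerVector dims = params["dims"];
  return List::create(
    _["params"] = write_weights(w, dims),
    _["history"] = DataFrame::create(
      _["epoch"] = seq_len(epochs), _["train_loss"] = h_tl,
      _["train_acc"] = h_ta, _["val_loss"] = h_vl, _["val_acc"] = h_va),
    _["epochs_run"] = ran,
    _["best_epoch"] = best_epoch + 1);
}

// [[Rcpp::export]]
arma::mat eegnet_predict_cpp(List params, arma::cube X) {
  Dims d = read_dims(params);
  Weights w = read_weights(params);
  return predict_probs(d, w, X).t(); // N x ncls
}

// training-mode loss and analytic gradients (dropout off) for the
// numerical gradient check in the test suite
// [[Rcpp::export]]
List eegnet_lossgrad_cpp(List params, arma::cube X, arma::ivec y) {
  Dims d = read_dims(params);
  Weights w = read_weights(params);
  std::mt19937 rng(0);
  Cache cc;
  forward(d, w, X, true, 0.0, rng, cc);
  Grads g;
  backward(d, w, cc, y, g);
  return List::create(
    _["loss"] = batch_loss(cc.probs, y),
    _["grads"] = List::create(
      _["wt"] = g.wt, _["wsp"] = g.wsp,
      _["bn1_gamma"] = mat(g.g1), _["bn1_beta"] = mat(g.b1),
      _["wsep"] = g.wsep, _["wpw"] = g.wpw,
      _["bn2_gamma"] = mat(g.g2), _["bn2_beta"] = mat(g.b2),
      _["wd"] = g.wd, _["bd"] = mat(g.bd)));
}
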