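// Fast path for the additive-unit network: fused forward/backward for one
// mini-batch, evaluation-mode forward, and per-position conv activations.
// Mirrors the reference implementation in R/nn-internal.R exactly
// (same layouts, same batch-norm conventions, same dropout RNG order), so
// the two can be cross-checked in tests.
//
// Batch layout: X is n x 4L, position-major; convolution windows are
// contiguous 4W column blocks. Conv scores are (n*conv_len) x U with rows
// grouped window-major (row (w-1)*n + i = window w of sequence i).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uword;

static const double BN_EPS = 1e-5;
static const double BN_MOM = 0.1;
static const double EXP_CLIP = 20.0;

struct Cfg {
  int n, L, U, W, CL, P, H, pool_size, pool_stride, T;
  bool exp_act, two_fc;
  double dropout;
};

static NumericVector as_num(const rowvec& v) {
  return NumericVector(v.begin(), v.end());
}

static Cfg read_cfg(const List& cfg, int n) {
  Cfg c;
  c.n = n;
  c.L = as<int>(cfg["input_length"]);
  c.U = as<int>(cfg["num_units"]);
  c.W = as<int>(cfg["filter_width"]);
  c.CL = c.L - c.W + 1;
  c.pool_size = as<int>(cfg["pool_size"]);
  c.pool_stride = as<int>(cfg["pool_stride"]);
  c.P = (c.CL - c.pool_size) / c.pool_stride + 1;
  c.H = as<int>(cfg["fc_hidden"]);
  c.T = as<int>(cfg["num_tasks"]);
  c.exp_act = as<std::string>(cfg["unit_activation"]) == "exponential";
  c.two_fc = as<std::string>(cfg["unit_head"]) == "two_fc_layers";
  c.dropout = as<double>(cfg["dropout_rate"]);
  return c;
}

static mat im2col(const mat& X, const Cfg& c) {
  mat Xw(c.n * c.CL, 4 * c.W);
  for (int w = 0; w < c.CL; ++w) {
    Xw.rows(w * c.n, (w + 1) * c.n - 1) = X.cols(4 * w, 4 * w + 4 * c.W - 1);
  }
  return Xw;
}

struct BnOut {
  mat xhat, y;
  rowvec ivar, mu, var_b;
};

static BnOut bn_train(const mat& x, const rowvec& gamma, const rowvec& beta) {
  BnOut o;
  o.mu = arma::mean(x, 0);
  mat xc = x.each_row() - o.mu;
  o.var_b = arma::mean(xc % xc, 0);
  o.ivar = 1.0 / arma::sqrt(o.var_b + BN_EPS);
  o.xhat = xc.each_row() % o.ivar;
  o.y = (o.xhat.each_row() % gamma).each_row() + beta;
  return o;
}

static mat bn_eval(const mat& x, const rowvec& gamma, const rowvec& beta,
                   const rowvec& rmean, const rowvec& rvar) {
  rowvec ivar = 1.0 / arma::sqrt(rvar + BN_EPS);
  mat xhat = (x.each_row() - rmean).each_row() % ivar;
  return (xhat.each_row() % gamma).each_row() + beta;
}

// dx for train-mode batch norm; fills dgamma/dbeta.
static mat bn_back(const mat& dy, const mat& xhat, const rowvec& ivar,
                   const rowvec& gamma, rowvec& dgamma, rowvec& dbeta) {
  double m = (double)dy.n_rows;
  dgamma = arma::sum(dy % xhat, 0);
  dbeta = arma::sum(dy, 0);
  mat dxhat = dy.each_row() % gamma;
  rowvec s1 = arma::sum(dxhat, 0);
  rowvec s2 = arma::sum(dxhat % xhat, 0);
  mat dx = dxhat * m;
  dx.each_row() -= s1;
  dx -= xhat.each_row() % s2;
  dx.each_row() %= (ivar / m);
  return dx;
}

static void activation(const mat& z, bool exp_act, mat& a, mat& grad) {
  if (exp_act) {
    mat zc = z;
    zc.transform([](double v) { return v > EXP_CLIP ? EXP_CLIP : v; });
    a = arma::exp(zc);
    grad = a;
    grad.elem(arma::find(z >= EXP_CLIP)).zeros();
  } else {
    a = z;
    a.transform([](double v) { return v > 0 ? v : 0.0; });
    grad = arma::conv_to<mat>::from(z > 0);
  }
}

// Max pool on window-major A ((n*CL) x U): returns pooled ((n*P) x U) and
// the argmax member k (0-based) per entry. Ties -> lowest position.
static void pool_fwd(const mat& A, const Cfg& c, int P, int psize, int pstride,
                     mat& pooled, arma::imat& argk) {
  pooled.set_size(c.n * P, c.U);
  argk.set_size(c.n * P, c.U);
  for (int u = 0; u < c.U; ++u) {
    const double* col = A.colptr(u);
    for (int g = 0; g < P; ++g) {
      int base = g * pstride;
      for (int i = 0; i < c.n; ++i) {
        double best = col[(size_t)base * c.n + i];
        int bk = 0;
        for (int k = 1; k < psize; ++k) {
          double v = col[(size_t)(base + k) * c.n + i];
          if (v > best) { best = v; bk = k; }
        }
        pooled((size_t)g * c.n + i, u) = best;
        argk((size_t)g * c.n + i, u) = bk;
      }
    }
  }
}

static mat pool_bwd(const mat& dpooled, const arma::imat& argk, const Cfg& c,
                    int P, int pstride) {
  mat dA(c.n * c.CL, c.U, arma::fill::zeros);
  for (int u = 0; u < c.U; ++u) {
    for (int g = 0; g < P; ++g) {
      for (int i = 0; i < c.n; ++i) {
        size_t r = (size_t)g * c.n + i;
        size_t src = (size_t)(g * pstride + argk(r, u)) * c.n + i;
        dA(src, u) += dpooled(r, u);
      }
    }
  }
  return dA;
}

// One fused training step: forward with batch statistics, loss, backward.
// Returns gradients (frozen filter columns nullified), updated running
// stats, the batch loss, and predictions. Dropout uses the R RNG in the
// same draw order as the reference implementation.
// [[Rcpp::export]]
List nn_train_batch_cpp(List params, List stats, List cfg_,
                        const arma::mat& X, const arma::mat& Y, std::string loss,
                        LogicalVector frozen, LogicalVector nullified) {
  Cfg c = read_cfg(cfg_, X.n_rows);
  RNGScope rngscope;

  mat F = as<mat>(params["filters"]);
  rowvec bn1_g = as<rowvec>(params["bn1_gamma"]);
  rowvec bn1_b = as<rowvec>(params["bn1_beta"]);
  mat Wf = as<mat>(params["Wf"]);
  rowvec bf = as<rowvec>(params["bf"]);

  mat Xw = im2col(X, c);
  mat M = Xw * F;
  BnOut bn1 = bn_train(M, bn1_g, bn1_b);
  mat A, Agrad;
  activation(bn1.y, c.exp_act, A, Agrad);

  List newstats = List::create(
      Named("bn1_mean") = as_num((1 - BN_MOM) * as<rowvec>(stats["bn1_mean"]) +
                                 BN_MOM * bn1.mu),
      Named("bn1_var") = as_num(
          (1 - BN_MOM) * as<rowvec>(stats["bn1_var"]) +
          BN_MOM * bn1.var_b *
              (M.n_rows > 1 ? (double)M.n_rows / (M.n_rows - 1.0) : 1.0)));

  mat O;                 // n x U unit outputs
  mat pooled, H1, h1d, Z;
  arma::imat argk, gargk;
  BnOut bn2, bn3;
  arma::cube W1;
  mat W2, drop_mask;
  rowvec bn2_g, bn2_b, bn3_g, bn3_b;
  bool dropped = false;

  if (c.two_fc) {
    pool_fwd(A, c, c.P, c.pool_size, c.pool_stride, pooled, argk);
    W1 = as<arma::cube>(params["W1"]); // P x H x U
    W2 = as<mat>(params["W2"]);        // H x U
    bn2_g = arma::vectorise(as<mat>(params["bn2_gamma"])).t();
    bn2_b = arma::vectorise(as<mat>(params["bn2_beta"])).t();
    bn3_g = as<rowvec>(params["bn3_gamma"]);
    bn3_b = as<rowvec>(params["bn3_beta"]);
    H1.set_size(c.n, c.H * c.U);
    for (int u = 0; u < c.U; ++u) {
      mat Pu(pooled.colptr(u), c.n, c.P, false, true);
      H1.cols(u * c.H, (u + 1) * c.H - 1) = Pu * W1.slice(u);
    }
    bn2 = bn_train(H1, bn2_g, bn2_b);
    mat relu2 = bn2.y;
    relu2.transform([](double v) { return v > 0 ? v : 0.0; });
    if (c.dropout > 0) {
      dropped = true;
      double keep = 1.0 - c.dropout;
      drop_mask.set_size(c.n, c.H * c.U);
      double* dm = drop_mask.memptr();
      size_t nel = (size_t)c.n * c.H * c.U;
      for (size_t j = 0; j < nel; ++j) {
        dm[j] = (R::runif(0.0, 1.0) < keep) ? 1.0 / keep : 0.0;
      }
      h1d = relu2 % drop_mask;
    } else {
      h1d = relu2;
    }
    Z.set_size(c.n, c.U);
    for (int u = 0; u < c.U; ++u) {
      Z.col(u) = h1d.cols(u * c.H, (u + 1) * c.H - 1) * W2.col(u);
    }
    bn3 = bn_train(Z, bn3_g, bn3_b);
    O = bn3.y;
    O.transform([](double v) { return v > 0 ? v : 0.0; });
    double mH = (double)H1.n_rows;
    double mZ = (double)Z.n_rows;
    rowvec rm2 = arma::vectorise(as<mat>(stats["bn2_mean"])).t();
    rowvec rv2 = arma::vectorise(as<mat>(stats["bn2_var"])).t();
    rowvec nm2 = (1 - BN_MOM) * rm2 + BN_MOM * bn2.mu;
    rowvec nv2 = (1 - BN_MOM) * rv2 + BN_MOM * bn2.var_b * (mH > 1 ? mH / (mH - 1.0) : 1.0);
    NumericVector nm2r = wrap(arma::conv_to<arma::vec>::from(nm2));
    NumericVector nv2r = wrap(arma::conv_to<arma::vec>::from(nv2));
    nm2r.attr("dim") = IntegerVector::create(c.H, c.U);
    nv2r.attr("dim") = IntegerVector::create(c.H, c.U);
    newstats["bn2_mean"] = nm2r;
    newstats["bn2_var"] = nv2r;
    newstats["bn3_mean"] = as_num((1 - BN_MOM) *
                                  as<rowvec>(stats["bn3_mean"]) +
                                  BN_MOM * bn3.mu);
    newstats["bn3_var"] = as_num((1 - BN_MOM) * as<rowvec>(stats["bn3_var"]) +
                                 BN_MOM * bn3.var_b * (mZ > 1 ? mZ / (mZ - 1.0) : 1.0));
  } else {
    pool_fwd(A, c, 1, c.CL, c.CL, O, gargk); // global max over positions
  }

  for (int u = 0; u < c.U; ++u) {
    if (nullified[u]) O.col(u).zeros();
  }

  mat preds = O * Wf;
  preds.each_row() += bf;

  // Loss and gradient wrt predictions (linear outputs).
  double lossval = 0;
  mat dY(c.n, c.T);
  double nel = (double)c.n * c.T;
  if (loss == "bce") {
    mat p = 1.0 / (1.0 + arma::exp(-preds));
    lossval = -arma::accu(Y % arma::log(p + 1e-12) +
                          (1.0 - Y) % arma::log(1.0 - p + 1e-12)) / nel;
    dY = (p - Y) / nel;
  } else if (loss == "mse") {
    mat d = preds - Y;
    lossval = arma::accu(d % d) / nel;
    dY = 2.0 * d / nel;
  } else { // cross_entropy over tasks-as-classes
    arma::colvec mx = arma::max(preds, 1);
    mat ez = arma::exp(preds.each_col() - mx);
    mat sm = ez.each_col() / arma::sum(ez, 1);
    lossval = -arma::accu(arma::log(arma::sum(sm % Y, 1) + 1e-12)) / c.n;
    dY = (sm - Y) / (double)c.n;
  }

  List grads;
  grads["Wf"] = O.t() * dY;
  grads["bf"] = as_num(arma::sum(dY, 0));
  mat dO = dY * Wf.t();
  for (int u = 0; u < c.U; ++u) {
    if (nullified[u]) dO.col(u).zeros();
  }

  mat dA;
  if (c.two_fc) {
    mat d3 = dO;
    d3.elem(arma::find(bn3.y <= 0)).zeros();
    rowvec dg3, db3;
    mat dZ = bn_back(d3, bn3.xhat, bn3.ivar, bn3_g, dg3, db3);
    grads["bn3_gamma"] = as_num(dg3);
    grads["bn3_beta"] = as_num(db3);
    mat dW2(c.H, c.U);
    mat dH1d(c.n, c.H * c.U);
    for (int u = 0; u < c.U; ++u) {
      dW2.col(u) = h1d.cols(u * c.H, (u + 1) * c.H - 1).t() * dZ.col(u);
      dH1d.cols(u * c.H, (u + 1) * c.H - 1) = dZ.col(u) * W2.col(u).t();
    }
    grads["W2"] = dW2;
    if (dropped) dH1d %= drop_mask;
    dH1d.elem(arma::find(bn2.y <= 0)).zeros();
    rowvec dg2, db2;
    mat dH1 = bn_back(dH1d, bn2.xhat, bn2.ivar, bn2_g, dg2, db2);
    NumericVector dg2r = wrap(arma::conv_to<arma::vec>::from(dg2));
    NumericVector db2r = wrap(arma::conv_to<arma::vec>::from(db2));
    dg2r.attr("dim") = IntegerVector::create(c.H, c.U);
    db2r.attr("dim") = IntegerVector::create(c.H, c.U);
    grads["bn2_gamma"] = dg2r;
    grads["bn2_beta"] = db2r;
    arma::cube dW1(c.P, c.H, c.U);
    mat dpooled(c.n * c.P, c.U);
    for (int u = 0; u < c.U; ++u) {
      mat Pu(pooled.colptr(u), c.n, c.P, false, true);
      mat du = dH1.cols(u * c.H, (u + 1) * c.H - 1);
      dW1.slice(u) = Pu.t() * du;
      mat dPu = du * W1.slice(u).t(); // n x P
      dpooled.col(u) = arma::vectorise(dPu);
    }
    grads["W1"] = dW1;
    dA = pool_bwd(dpooled, argk, c, c.P, c.pool_stride);
  } else {
    dA = pool_bwd(dO, gargk, c, 1, c.CL);
  }

  mat dM = dA % Agrad;
  rowvec dg1, db1;
  mat dMx = bn_back(dM, bn1.xhat, bn1.ivar, bn1_g, dg1, db1);
  grads["bn1_gamma"] = as_num(dg1);
  grads["bn1_beta"] = as_num(db1);
  mat dF = Xw.t() * dMx;
  for (int u = 0; u < c.U; ++u) {
    if (frozen[u]) dF.col(u).zeros();
  }
  grads["filters"] = dF;

  return List::create(Named("grads") = grads, Named("new_stats") = newstats,
                      Named("loss") = lossval, Named("predictions") = preds);
}

// Evaluation-mode forward: deterministic, running statistics, no dropout.
// [[Rcpp::export]]
List nn_eval_forward_cpp(List params, List stats, List cfg_,
                         const arma::mat& X, LogicalVector nullified) {
  Cfg c = read_cfg(cfg_, X.n_rows);
  mat F = as<mat>(params["filters"]);
  mat Xw = im2col(X, c);
  mat M = Xw * F;
  mat bn1y = bn_eval(M, as<rowvec>(params["bn1_gamma"]),
                     as<rowvec>(params["bn1_beta"]),
                     as<rowvec>(stats["bn1_mean"]),
                     as<rowvec>(stats["bn1_var"]));
  mat A, Agrad;
  activation(bn1y, c.exp_act, A, Agrad);

  mat O;
  if (c.two_fc) {
    mat pooled;
    arma::imat argk;
    pool_fwd(A, c, c.P, c.pool_size, c.pool_stride, pooled, argk);
    arma::cube W1 = as<arma::cube>(params["W1"]);
    mat W2 = as<mat>(params["W2"]);
    mat H1(c.n, c.H * c.U);
    for (int u = 0; u < c.U; ++u) {
      mat Pu(pooled.colptr(u), c.n, c.P, false, true);
      H1.cols(u * c.H, (u + 1) * c.H - 1) = Pu * W1.slice(u);
    }
    mat bn2y = bn_eval(H1, arma::vectorise(as<mat>(params["bn2_gamma"])).t(),
                       arma::vectorise(as<mat>(params["bn2_beta"])).t(),
                       arma::vectorise(as<mat>(stats["bn2_mean"])).t(),
                       arma::vectorise(as<mat>(stats["bn2_var"])).t());
    bn2y.transform([](double v) { return v > 0 ? v : 0.0; });
    mat Z(c.n, c.U);
    for (int u = 0; u < c.U; ++u) {
      Z.col(u) = bn2y.cols(u * c.H, (u + 1) * c.H - 1) * W2.col(u);
    }
    mat bn3y = bn_eval(Z, as<rowvec>(params["bn3_gamma"]),
                       as<rowvec>(params["bn3_beta"]),
                       as<rowvec>(stats["bn3_mean"]),
                       as<rowvec>(stats["bn3_var"]));
    bn3y.transform([](double v) { return v > 0 ? v : 0.0; });
    O = bn3y;
  } else {
    arma::imat gargk;
    pool_fwd(A, c, 1, c.CL, c.CL, O, gargk);
  }
  for (int u = 0; u < c.U; ++u) {
    if (nullified[u]) O.col(u).zeros();
  }
  mat preds = O * as<mat>(params["Wf"]);
  preds.each_row() += as<rowvec>(params["bf"]);
  return List::create(Named("predictions") = preds,
                      Named("unit_outputs") = O);
}

// Per-sequence, per-unit maximum of the post-activation convolution signal
// (evaluation mode) and its 1-based argmax position; ties -> lowest.
// [[Rcpp::export]]
List conv_activations_cpp(List params, List stats, List cfg_,
                          const arma::mat& X) {
  Cfg c = read_cfg(cfg_, X.n_rows);
  mat F = as<mat>(params["filters"]);
  mat Xw = im2col(X, c);
  mat M = Xw * F;
  mat bn1y = bn_eval(M, as<rowvec>(params["bn1_gamma"]),
                     as<rowvec>(params["bn1_beta"]),
                     as<rowvec>(stats["bn1_mean"]),
                     as<rowvec>(stats["bn1_var"]));
  mat A, Agrad;
  activation(bn1y, c.exp_act, A, Agrad);
  mat mx(c.n, c.U);
  arma::imat pos(c.n, c.U);
  for (int u = 0; u < c.U; ++u) {
    const double* col = A.colptr(u);
    for (int i = 0; i < c.n; ++i) {
      double best = col[i];
      int bw = 0;
      for (int w = 1; w < c.CL; ++w) {
        double v = col[(size_t)w * c.n + i];
        if (v > best) { best = v; bw = w; }
      }
      mx(i, u) = best;
      pos(i, u) = bw + 1;
    }
  }
  return List::create(Named("max") = mx, Named("pos") = pos);
}
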