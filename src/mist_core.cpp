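// Per-vertex intensity-profile mixture model: negative log posterior with
// the discrete displacement marginalised out, its analytic gradient, and
// shift log-likelihood tables. Hot path of training and fitting.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// log-sum-exp over a vector
static double lse(const vec &x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(accu(exp(x - m)));
}

struct Unpacked {
  std::vector<std::vector<vec>> mu;   // [m][r] length k
  std::vector<std::vector<vec>> d;    // [m][r] length k, log of diag(D)
  std::vector<vec> theta;             // [m] length Nr
  std::vector<vec> eta;               // [m] length Nr-1
};

static Unpacked unpack(const vec &par, int k, int Nr, int Nm) {
  Unpacked u;
  u.mu.resize(Nm); u.d.resize(Nm); u.theta.resize(Nm); u.eta.resize(Nm);
  uword off = 0;
  for (int m = 0; m < Nm; ++m) {
    u.mu[m].resize(Nr); u.d[m].resize(Nr);
    for (int r = 0; r < Nr; ++r) {
      u.mu[m][r] = par.subvec(off, off + k - 1); off += k;
      u.d[m][r]  = par.subvec(off, off + k - 1); off += k;
    }
  }
  for (int m = 0; m < Nm; ++m) {
    vec eta(Nr, fill::zeros);
    if (Nr > 1) {
      eta.subvec(0, Nr - 2) = par.subvec(off, off + Nr - 2);
      off += Nr - 1;
      u.eta[m] = eta.subvec(0, Nr - 2);
    } else {
      u.eta[m] = vec();
    }
    vec e = exp(eta - eta.max());
    u.theta[m] = e / accu(e);
  }
  return u;
}

// Negative log posterior of the per-vertex model and its gradient.
// Z: S x kp x Nm cube of observed profiles (training subjects).
// logpshift: log prior over the window start w = 0..Delta (symmetric in
// the displacement index, so the indexing direction does not matter).
// mu0: k x (Nm*Nr), column m*Nr + r. beta: Nm*Nr vector, same order.
// [[Rcpp::export]]
Rcpp::List vertex_nlp_cpp(const arma::vec &par, const arma::cube &Z,
                          const arma::mat &G, const arma::mat &Ginv,
                          double logdetG, const arma::mat &mu0,
                          const arma::vec &beta, double n0, double alpha0,
                          double dir_alpha, const arma::vec &logpshift,
                          int Nr, int Nm, bool want_grad) {
  const int k = G.n_rows;
  const int S = Z.n_rows;
  const int kp = Z.n_cols;
  const int W = k - kp + 1;  // number of windows = Delta + 1
  Unpacked u = unpack(par, k, Nr, Nm);

  auto fail = [&]() {
    return Rcpp::List::create(Rcpp::Named("value") = 1e12,
                              Rcpp::Named("gradient") =
                                Rcpp::NumericVector(par.n_elem, 0.0));
  };

  // per (m,r): Sigma, and per window: chol factor, logdet, whitened resid
  std::vector<std::vector<mat>> Sig(Nm);
  // cached per (m,r,w): upper chol R, Y = R^-T E (kp x S), logdet
  std::vector<std::vector<std::vector<mat>>> Rch(Nm), Ymat(Nm);
  std::vector<std::vector<vec>> logdets(Nm);
  std::vector<cube> logNc(Nm);  // per modality: (S, W, Nr)

  for (int m = 0; m < Nm; ++m) {
    Sig[m].resize(Nr);
    Rch[m].resize(Nr); Ymat[m].resize(Nr); logdets[m].resize(Nr);
    logNc[m].set_size(S, W, Nr);
    mat Zm = Z.slice(m);             // S x kp
    mat Zt = Zm.t();                 // kp x S
    for (int r = 0; r < Nr; ++r) {
      vec D = exp(u.d[m][r]);
      Sig[m][r] = G * diagmat(D) * G;
      Rch[m][r].resize(W); Ymat[m][r].resize(W);
      logdets[m][r].set_size(W);
      for (int w = 0; w < W; ++w) {
        mat Sw = Sig[m][r].submat(w, w, w + kp - 1, w + kp - 1);
        mat R;
        if (!chol(R, Sw)) return fail();
        Rch[m][r][w] = R;
        double ld = 2.0 * accu(log(R.diag()));
        logdets[m][r](w) = ld;
        mat E = Zt.each_col() - u.mu[m][r].subvec(w, w + kp - 1);
        mat Y = solve(trimatl(R.t()), E);
        Ymat[m][r][w] = Y;
        rowvec quad = sum(square(Y), 0);
        for (int s = 0; s < S; ++s)
          logNc[m](s, w, r) = -0.5 * (kp * LOG2PI + ld + quad(s));
      }
    }
  }

  // mixture over components, per modality
  cube logSmix(S, W, Nm);
  for (int m = 0; m < Nm; ++m) {
    vec lt = log(u.theta[m]);
    for (int s = 0; s < S; ++s)
      for (int w = 0; w < W; ++w) {
        vec tmp(Nr);
        for (int r = 0; r < Nr; ++r) tmp(r) = lt(r) + logNc[m](s, w, r);
        logSmix(s, w, m) = lse(tmp);
      }
  }

  // marginalise the shift
  mat A(S, W);
  vec Ls(S);
  for (int s = 0; s < S; ++s) {
    for (int w = 0; w < W; ++w) {
      double t = logpshift(w);
      for (int m = 0; m < Nm; ++m) t += logSmix(s, w, m);
      A(s, w) = t;
    }
    Ls(s) = lse(A.row(s).t());
  }
  double value = accu(Ls);
  if (!std::isfinite(value)) return fail();

  // priors
  for (int m = 0; m < Nm; ++m) {
    for (int r = 0; r < Nr; ++r) {
      int col = m * Nr + r;
      vec dmr = u.d[m][r];
      vec vgi = Ginv * (u.mu[m][r] - mu0.col(col));
      vec en = exp(-dmr);
      value += 0.5 * (alpha0 - k) * (-2.0 * logdetG - accu(dmr));
      value += -0.5 * beta(col) * accu(en);
      value += -0.5 * n0 * accu(square(vgi) % en);
    }
    value += dir_alpha * accu(log(u.theta[m]));
  }
  if (!std::isfinite(value)) return fail();

  vec grad(par.n_elem, fill::zeros);
  if (want_grad) {
    Unpacked g;  // reuse structure for gradient accumulators
    g.mu.resize(Nm); g.d.resize(Nm); g.theta.resize(Nm);
    for (int m = 0; m < Nm; ++m) {
      g.mu[m].assign(Nr, vec(k, fill::zeros));
      g.d[m].assign(Nr, vec(k, fill::zeros));
      g.theta[m] = vec(Nr, fill::zeros);
    }
    mat wgt = exp(A.each_col() - Ls);  // S x W responsibilities over shifts
    for (int m = 0; m < Nm; ++m) {
      vec lt = log(u.theta[m]);
      for (int r = 0; r < Nr; ++r) {
        vec D = exp(u.d[m][r]);
        for (int w = 0; w < W; ++w) {
          vec c(S);
          for (int s = 0; s < S; ++s)
            c(s) = wgt(s, w) *
              std::exp(lt(r) + logNc[m](s, w, r) - logSmix(s, w, m));
          double csum = accu(c);
          if (csum < 1e-300) continue;
          g.theta[m](r) += csum / u.theta[m](r);
          const mat &R = Rch[m][r][w];
          mat F = solve(trimatu(R), Ymat[m][r][w]);  // = Lambda_w * E
          g.mu[m][r].subvec(w, w + kp - 1) += F * c;
          mat Lam;
          {
            mat I = eye(kp, kp);
            mat Ri = solve(trimatu(R), I);
            Lam = Ri * Ri.t();
          }
          mat M = 0.5 * (F * diagmat(c) * F.t() - csum * Lam);
          mat Gw = G.rows(w, w + kp - 1);  // kp x k
          mat T = M * Gw;
          g.d[m][r] += (sum(Gw % T, 0).t()) % D;
        }
      }
    }
    // prior gradients
    for (int m = 0; m < Nm; ++m) {
      for (int r = 0; r < Nr; ++r) {
        int col = m * Nr + r;
        vec dmr = u.d[m][r];
        vec vgi = Ginv * (u.mu[m][r] - mu0.col(col));
        vec en = exp(-dmr);
        g.mu[m][r] += -n0 * (Ginv * (vgi % en));
        g.d[m][r] += -0.5 * (alpha0 - k) +
          0.5 * en % (beta(col) + n0 * square(vgi));
      }
      g.theta[m] += dir_alpha / u.theta[m];
    }
    // pack, converting theta gradients to the unconstrained scale
    uword off = 0;
    for (int m = 0; m < Nm; ++m)
      for (int r = 0; r < Nr; ++r) {
        grad.subvec(off, off + k - 1) = g.mu[m][r]; off += k;
        grad.subvec(off, off + k - 1) = g.d[m][r]; off += k;
      }
    for (int m = 0; m < Nm; ++m) {
      if (Nr > 1) {
        double dot = accu(u.theta[m] % g.theta[m]);
        for (int r = 0; r < Nr - 1; ++r)
          grad(off + r) = u.theta[m](r) * (g.theta[m](r) - dot);
        off += Nr - 1;
      }
    }
    grad = -grad;
  }
  return Rcpp::List::create(Rcpp::Named("value") = -value,
                            Rcpp::Named("gradient") =
                              Rcpp::NumericVector(grad.begin(), grad.end()));
}

// Mixture log-likelihood of observed profiles for every window start.
// Z: S x kp x Nm; mu, Dd: k x (Nm*Nr) (column m*Nr + r); theta: Nm x Nr.
// Returns S x W matrix of sum_m log sum_r theta_mr N(z | mu_w, Sigma_w).
// [[Rcpp::export]]
arma::mat shift_logliks_cpp(const arma::cube &Z, const arma::mat &mu,
                            const arma::mat &Dd, const arma::mat &theta,
                            const arma::mat &G, int Nr, int Nm) {
  const int k = G.n_rows;
  const int S = Z.n_rows;
  const int kp = Z.n_cols;
  const int W = k - kp + 1;
  mat out(S, W, fill::zeros);
  for (int m = 0; m < Nm; ++m) {
    mat Zt = Z.slice(m).t();  // kp x S
    cube logN(S, W, Nr);
    for (int r = 0; r < Nr; ++r) {
      int col = m * Nr + r;
      mat Sig = G * diagmat(Dd.col(col)) * G;
      for (int w = 0; w < W; ++w) {
        mat Sw = Sig.submat(w, w, w + kp - 1, w + kp - 1);
        mat R;
        if (!chol(R, Sw)) Rcpp::stop("covariance window not positive definite");
        double ld = 2.0 * accu(log(R.diag()));
        mat E = Zt.each_col() - mu.col(col).subvec(w, w + kp - 1);
        mat Y = solve(trimatl(R.t()), E);
        rowvec quad = sum(square(Y), 0);
        for (int s = 0; s < S; ++s)
          logN(s, w, r) = -0.5 * (kp * LOG2PI + ld + quad(s));
      }
    }
    for (int s = 0; s < S; ++s)
      for (int w = 0; w < W; ++w) {
        vec tmp(Nr);
        for (int r = 0; r < Nr; ++r)
          tmp(r) = std::log(theta(m, r)) + logN(s, w, r);
        out(s, w) += lse(tmp);
      }
  }
  return out;
}
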