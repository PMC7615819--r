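// Inner loops of the temporal predictive coding models. Training walks a
// sequence step by step (the hidden estimate of step mu-1 feeds step mu),
// so these loops cannot be vectorized across time and live in C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec f_apply(const vec& x, bool use_tanh) {
  return use_tanh ? vec(tanh(x)) : x;
}

static inline vec f_prime(const vec& x, bool use_tanh) {
  if (!use_tanh) return ones<vec>(x.n_elem);
  vec t = tanh(x);
  return 1.0 - t % t;
}

static void check_finite(const mat& W, const char* what, double lr) {
  if (!W.is_finite() || norm(W, "fro") > 1e6)
    Rcpp::stop("%s diverged during training (learning rate %g is too large "
               "for this input scale)", what, lr);
}

// [[Rcpp::export]]
Rcpp::List tpc_train_single_cpp(const arma::mat& X, arma::mat W, double lr,
                                int n_epochs, double conv_tol, bool use_tanh) {
  const uword L = X.n_rows;
  int epochs_run = 0;
  for (int e = 0; e < n_epochs; ++e) {
    mat W_old = W;
    for (uword mu = 1; mu < L; ++mu) {
      vec fprev = f_apply(X.row(mu - 1).t(), use_tanh);
      vec err = X.row(mu).t() - W * fprev;
      W += lr * err * fprev.t();
    }
    check_finite(W, "single-layer tPC weights", lr);
    epochs_run = e + 1;
    double rel = norm(W - W_old, "fro") / (norm(W_old, "fro") + 1e-12);
    if (rel < conv_tol) break;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("epochs_run") = epochs_run);
}

// [[Rcpp::export]]
Rcpp::List tpc_recall_single_cpp(const arma::mat& X, const arma::mat& W,
                                 double lr_inf, int n_inf, double inf_tol,
                                 bool use_tanh, bool online, bool trace) {
  const uword L = X.n_rows, N = X.n_cols;
  mat Xhat(L, N, fill::zeros);
  Xhat.row(0) = X.row(0);
  vec energy(L, fill::zeros);
  Rcpp::List traces(trace ? L : 0);
  for (uword mu = 1; mu < L; ++mu) {
    vec q = online ? X.row(mu - 1).t() : Xhat.row(mu - 1).t();
    vec target = W * f_apply(q, use_tanh);
    vec xhat(N, fill::zeros);
    std::vector<double> etr;
    for (int t = 0; t < n_inf; ++t) {
      vec eps = xhat - target;            // error neurons during recall
      if (trace) etr.push_back(dot(eps, eps));
      xhat -= lr_inf * eps;
      if (lr_inf * norm(eps) < inf_tol) break;
    }
    Xhat.row(mu) = xhat.t();
    vec eps = xhat - target;
    energy(mu) = dot(eps, eps);
    if (trace) traces[mu] = etr;
  }
  return Rcpp::List::create(Rcpp::Named("Xhat") = Xhat,
                            Rcpp::Named("energy") = energy,
                            Rcpp::Named("traces") = traces);
}

// Relax the hidden state for a clamped sensory input x, starting from the
// temporal prediction zpred = W_H f(zhat_prev) or, with recognition
// initialization, from the feedforward guess W_F^T x (which breaks the
// early-training degeneracy z ~ 0, f(z) ~ 0).
static inline double hidden_energy(const vec& x, const vec& z,
                                   const vec& zpred, const mat& WF,
                                   bool use_tanh) {
  vec eps_z = z - zpred;
  vec eps_x = x - WF * f_apply(z, use_tanh);
  return dot(eps_z, eps_z) + dot(eps_x, eps_x);
}

static vec infer_hidden(const vec& x, const vec& zpred, const mat& WF,
                        double lr_inf, int n_inf, double inf_tol,
                        bool use_tanh, bool recog_init,
                        std::vector<double>* etr) {
  vec z = recog_init ? vec(WF.t() * x) : zpred;
  double step = lr_inf;
  double E = hidden_energy(x, z, zpred, WF, use_tanh);
  for (int t = 0; t < n_inf; ++t) {
    if (etr) etr->push_back(E);
    vec eps_z = z - zpred;
    vec eps_x = x - WF * f_apply(z, use_tanh);
    vec dz = -eps_z + f_prime(z, use_tanh) % (WF.t() * eps_x);
    // backtracking: the nominal Euler step is only stable while the step
    // size is below 2 over the local curvature, which grows with |W_F|^2;
    // halve the step until the energy does not increase
    vec z_new = z + step * dz;
    double E_new = hidden_energy(x, z_new, zpred, WF, use_tanh);
    int bt = 0;
    while (E_new > E && bt < 30) {
      step *= 0.5;
      z_new = z + step * dz;
      E_new = hidden_energy(x, z_new, zpred, WF, use_tanh);
      ++bt;
    }
    z = z_new;
    E = E_new;
    if (step * norm(dz) < inf_tol) break;
    if (bt == 0 && step < lr_inf) step = std::min(lr_inf, step * 1.5);
  }
  return z;
}

// [[Rcpp::export]]
Rcpp::List tpc_infer_hidden_cpp(const arma::vec& x, const arma::vec& zhat_prev,
                                const arma::mat& WH, const arma::mat& WF,
                                double lr_inf, int n_inf, double inf_tol,
                                bool use_tanh, bool recog_init) {
  std::vector<double> etr;
  vec zpred = WH * f_apply(zhat_prev, use_tanh);
  vec z = infer_hidden(x, zpred, WF, lr_inf, n_inf, inf_tol, use_tanh,
                       recog_init, &etr);
  return Rcpp::List::create(Rcpp::Named("z") = z,
                            Rcpp::Named("energy_trace") = etr);
}

// [[Rcpp::export]]
Rcpp::List tpc_train_two_cpp(const Rcpp::List& Xs, arma::mat WH, arma::mat WF,
                             double lr_w, int n_epochs, double conv_tol,
                             double lr_inf, int n_inf, double inf_tol,
                             bool use_tanh, bool use_adam, bool recog_init,
                             const arma::mat& Z0) {
  const uword Nz = WH.n_rows;
  int epochs_run = 0;
  // adaptive (Adam) moment buffers; the update stays local and
  // outer-product-shaped, only rescaled per synapse
  mat mWH(size(WH), fill::zeros), vWH(size(WH), fill::zeros);
  mat mWF(size(WF), fill::zeros), vWF(size(WF), fill::zeros);
  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;
  double t_adam = 0;
  for (int e = 0; e < n_epochs; ++e) {
    mat WH_old = WH, WF_old = WF;
    for (int s = 0; s < Xs.size(); ++s) {
      mat X = Rcpp::as<mat>(Xs[s]);
      // the chain starts from the caller-supplied reset state (column of
      // Z0; the same state recall uses, so the cue's inferred context
      // matches between memorization and recall)
      vec zhat_prev = Z0.col(s);
      // accumulate the Hebbian gradients over the steps; weights are
      // updated once per presentation of the full sequence
      mat gH(size(WH), fill::zeros), gF(size(WF), fill::zeros);
      for (uword mu = 0; mu < X.n_rows; ++mu) {
        vec fzprev = f_apply(zhat_prev, use_tanh);
        vec zpred = WH * fzprev;
        vec x = X.row(mu).t();
        vec z = infer_hidden(x, zpred, WF, lr_inf, n_inf, inf_tol,
                             use_tanh, recog_init, nullptr);
        if (mu > 0) {
          vec eps_z = z - zpred;
          vec fz = f_apply(z, use_tanh);
          vec eps_x = x - WF * fz;
          gH += eps_z * fzprev.t();
          gF += eps_x * fz.t();
        }
        zhat_prev = z;
      }
      if (use_adam) {
        t_adam += 1.0;
        mWH = b1 * mWH + (1 - b1) * gH;
        vWH = b2 * vWH + (1 - b2) * square(gH);
        mWF = b1 * mWF + (1 - b1) * gF;
        vWF = b2 * vWF + (1 - b2) * square(gF);
        double c1 = 1 - std::pow(b1, t_adam), c2 = 1 - std::pow(b2, t_adam);
        WH += lr_w * (mWH / c1) / (sqrt(vWH / c2) + adam_eps);
        WF += lr_w * (mWF / c1) / (sqrt(vWF / c2) + adam_eps);
      } else {
        WH += lr_w * gH;
        WF += lr_w * gF;
      }
    }
    check_finite(WH, "two-layer tPC hidden weights", lr_w);
    check_finite(WF, "two-layer tPC forward weights", lr_w);
    epochs_run = e + 1;
    double rel = (norm(WH - WH_old, "fro") + norm(WF - WF_old, "fro")) /
                 (norm(WH_old, "fro") + norm(WF_old, "fro") + 1e-12);
    if (rel < conv_tol) break;
  }
  // final memorization energy of the inferred chain (scored steps only):
  // the objective value actually attained, used for multi-start selection
  double final_energy = 0;
  for (int s = 0; s < Xs.size(); ++s) {
    mat X = Rcpp::as<mat>(Xs[s]);
    vec zhat_prev = Z0.col(s);
    for (uword mu = 0; mu < X.n_rows; ++mu) {
      vec zpred = WH * f_apply(zhat_prev, use_tanh);
      vec x = X.row(mu).t();
      vec z = infer_hidden(x, zpred, WF, lr_inf, n_inf, inf_tol,
                           use_tanh, recog_init, nullptr);
      if (mu > 0) final_energy += hidden_energy(x, z, zpred, WF, use_tanh);
      zhat_prev = z;
    }
  }
  return Rcpp::List::create(Rcpp::Named("WH") = WH,
                            Rcpp::Named("WF") = WF,
                            Rcpp::Named("epochs_run") = epochs_run,
                            Rcpp::Named("final_energy") = final_energy);
}

// [[Rcpp::export]]
Rcpp::List tpc_recall_two_cpp(const arma::mat& X, const arma::mat& WH,
                              const arma::mat& WF, const arma::vec& z0,
                              double lr_inf, int n_inf, double inf_tol,
                              bool use_tanh, bool online, bool recog_init,
                              bool trace) {
  const uword L = X.n_rows, N = X.n_cols, Nz = WH.n_rows;
  mat Xhat(L, N, fill::zeros);
  mat Z(L, Nz, fill::zeros);
  vec energy(L, fill::zeros);
  Rcpp::List traces(trace ? L : 0);

  // step 1: the cue x^1 is shown; infer its hidden representation from the
  // randomly re-initialized carry-over state z0
  Xhat.row(0) = X.row(0);
  vec zhat = infer_hidden(X.row(0).t(), WH * f_apply(z0, use_tanh), WF,
                          lr_inf, n_inf, inf_tol, use_tanh, recog_init,
                          nullptr);
  Z.row(0) = zhat.t();

  for (uword mu = 1; mu < L; ++mu) {
    // joint relaxation of (z, xhat) with no sensory clamp
    vec zpred = WH * f_apply(zhat, use_tanh);
    vec z = zpred;
    vec xhat = WF * f_apply(z, use_tanh);   // top-down initialization
    std::vector<double> etr;
    double step = lr_inf;
    auto joint_energy = [&](const vec& zz, const vec& xx) {
      vec ez = zz - zpred;
      vec ex = xx - WF * f_apply(zz, use_tanh);
      return dot(ez, ez) + dot(ex, ex);
    };
    double E = joint_energy(z, xhat);
    for (int t = 0; t < n_inf; ++t) {
      if (trace) etr.push_back(E);
      vec eps_z = z - zpred;
      vec eps_x = xhat - WF * f_apply(z, use_tanh);
      vec dz = -eps_z + f_prime(z, use_tanh) % (WF.t() * eps_x);
      vec dx = -eps_x;
      vec z_new = z + step * dz;
      vec x_new = xhat + step * dx;
      double E_new = joint_energy(z_new, x_new);
      int bt = 0;
      while (E_new > E && bt < 30) {
        step *= 0.5;
        z_new = z + step * dz;
        x_new = xhat + step * dx;
        E_new = joint_energy(z_new, x_new);
        ++bt;
      }
      z = z_new;
      xhat = x_new;
      E = E_new;
      if (step * (norm(dz) + norm(dx)) < inf_tol) break;
      if (bt == 0 && step < lr_inf) step = std::min(lr_inf, step * 1.5);
    }
    Xhat.row(mu) = xhat.t();
    {
      vec eps_z = z - zpred;
      vec eps_x = xhat - WF * f_apply(z, use_tanh);
      energy(mu) = dot(eps_z, eps_z) + dot(eps_x, eps_x);
    }
    if (trace) traces[mu] = etr;
    if (online) {
      // re-infer the context from the ground-truth query
      zhat = infer_hidden(X.row(mu).t(), zpred, WF, lr_inf, n_inf, inf_tol,
                          use_tanh, recog_init, nullptr);
    } else {
      zhat = z;                         // carry the converged estimate
    }
    Z.row(mu) = zhat.t();
  }
  return Rcpp::List::create(Rcpp::Named("Xhat") = Xhat,
                            Rcpp::Named("Z") = Z,
                            Rcpp::Named("energy") = energy,
                            Rcpp::Named("traces") = traces);
}
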