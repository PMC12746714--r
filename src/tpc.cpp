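// Core numerical loops of the two-layer temporal predictive coding network.
// Only the inner iterative-inference dynamics and the epoch sweep live here;
// all bookkeeping stays on the R side. The inner loop avoids repeated
// activation evaluation: tanh(z) and its derivative are computed once per
// iteration into preallocated buffers.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// fz = f(z), dfz = f'(z)
static inline void act_both(const vec& z, vec& fz, vec& dfz, int code) {
  if (code == 1) {
    for (uword i = 0; i < z.n_elem; ++i) {
      const double t = std::tanh(z[i]);
      fz[i] = t;
      dfz[i] = 1.0 - t * t;
    }
  } else {
    fz = z;
    dfz.ones();
  }
}

static inline vec act(const vec& v, int code) {
  return code == 1 ? vec(tanh(v)) : v;
}

// One step of cued inference: explicit-Euler descent of the per-step energy
//   F = ||z - W_H f(z_prev)||^2 + ||x - W_F f(z)||^2
// with respect to z, starting from the temporal prediction W_H f(z_prev).
// Returns the converged z and the energy after initialisation and after each
// of the `iters` updates (length iters + 1).
// [[Rcpp::export(rng = false)]]
Rcpp::List tpc_infer_cpp(const arma::vec& x, const arma::vec& z_prev,
                         const arma::mat& W_H, const arma::mat& W_F,
                         int iters, double lr, int act_code) {
  const uword nh = W_H.n_rows;
  const vec mu_z = W_H * act(z_prev, act_code);  // constant within the step
  vec z = mu_z;
  vec fz(nh), dfz(nh);
  vec energies(iters + 1);

  act_both(z, fz, dfz, act_code);
  vec eps_x = x - W_F * fz;
  energies(0) = dot(eps_x, eps_x);  // eps_z = 0 at initialisation

  for (int k = 0; k < iters; ++k) {
    const vec g = W_F.t() * eps_x;
    double e_z = 0.0;
    for (uword i = 0; i < nh; ++i) {
      z[i] += lr * (-(z[i] - mu_z[i]) + dfz[i] * g[i]);
      const double d = z[i] - mu_z[i];
      e_z += d * d;
    }
    if (!z.is_finite())
      Rcpp::stop("inference diverged to non-finite values at iteration %d", k + 1);
    act_both(z, fz, dfz, act_code);
    eps_x = x - W_F * fz;
    energies(k + 1) = e_z + dot(eps_x, eps_x);
  }

  return Rcpp::List::create(Rcpp::Named("z") = z,
                            Rcpp::Named("energies") = energies);
}

// Full memorisation sweep: for each epoch, each sequence (rows = time steps),
// run inference at every step, apply the local weight updates
//   W_H += lr_w * eps_z f(z_prev)^T ;  W_F += lr_w * eps_x f(z)^T
// and carry the converged hidden state forward. Skills are interleaved within
// each epoch (the list order is one round-robin pass). The recorded energy is
// the converged value after inference, before the weight update. Returns
// updated weights and the mean converged energy per epoch.
// [[Rcpp::export(rng = false)]]
Rcpp::List tpc_memorise_cpp(const Rcpp::List& sequences,
                            arma::mat W_H, arma::mat W_F,
                            int epochs, int infer_iters, double infer_lr,
                            double weight_lr, int act_code) {
  const int n_seq = sequences.size();
  const uword nh = W_H.n_rows;
  vec epoch_energy(epochs > 0 ? epochs : 0, fill::zeros);

  std::vector<mat> seqs(n_seq);
  long n_steps_total = 0;
  for (int s = 0; s < n_seq; ++s) {
    seqs[s] = Rcpp::as<mat>(sequences[s]);
    n_steps_total += seqs[s].n_rows;
  }

  vec z(nh), fz(nh), dfz(nh), fz_prev(nh), dfz_prev(nh), mu_z(nh);

  for (int e = 0; e < epochs; ++e) {
    double acc = 0.0;
    for (int s = 0; s < n_seq; ++s) {
      const mat& X = seqs[s];
      vec z_prev(nh, fill::zeros);
      for (uword mu = 0; mu < X.n_rows; ++mu) {
        const vec x = X.row(mu).t();
        act_both(z_prev, fz_prev, dfz_prev, act_code);
        mu_z = W_H * fz_prev;
        z = mu_z;
        act_both(z, fz, dfz, act_code);
        vec eps_x = x - W_F * fz;
        for (int k = 0; k < infer_iters; ++k) {
          const vec g = W_F.t() * eps_x;
          for (uword i = 0; i < nh; ++i)
            z[i] += infer_lr * (-(z[i] - mu_z[i]) + dfz[i] * g[i]);
          act_both(z, fz, dfz, act_code);
          eps_x = x - W_F * fz;
        }
        if (!z.is_finite())
          Rcpp::stop("training diverged at epoch %d", e + 1);
        const vec eps_z = z - mu_z;
        acc += dot(eps_z, eps_z) + dot(eps_x, eps_x);
        // local Hebbian-like updates, one per time step
        W_H += weight_lr * (eps_z * fz_prev.t());
        W_F += weight_lr * (eps_x * fz.t());
        z_prev = z;
      }
    }
    epoch_energy(e) = acc / double(n_steps_total);
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(Rcpp::Named("W_H") = W_H,
                            Rcpp::Named("W_F") = W_F,
                            Rcpp::Named("epoch_energy") = epoch_energy);
}
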