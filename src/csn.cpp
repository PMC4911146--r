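// Core time-grid simulation kernels for continuous-signal-coding spiking
// networks (CSNs) and the stochastic pendulum plant.
//
// Layout conventions (column-major, matching the R wrappers):
//   inputs  : K_in  x n_steps, column k = input at the start of step k
//   targets : K_out x n_steps, column k = target at the END of step k
//   z       : K_out x n_steps, column k = readout at the end of step k
// Within one dt step the external input is held constant; the synaptic
// variable r decays exactly (r(t+h) = r(t) e^{-lambda_s h}) so RK4 is applied
// to V only, with the forcing evaluated at substep times.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int SCHEME_EULER = 0, SCHEME_RK4 = 1, SCHEME_EM = 2;
static const int LEARN_NONE = 0, LEARN_RLS = 1, LEARN_FORCE_REC = 2;

static void check_finite(const arma::vec& V, double t) {
  if (V.is_finite()) return;
  for (arma::uword n = 0; n < V.n_elem; ++n)
    if (!std::isfinite(V(n)))
      stop("non-finite membrane potential in neuron %d at t = %g s", (int)(n + 1), t);
}

// Sequential fast-interaction spike processing for the dendritic variant:
// repeatedly pick the neuron with the largest suprathreshold potential,
// apply the fast coupling column (which contains the self-reset on the
// diagonal) and increment its synaptic variable. Ties break at the lowest
// index (arma::index_max). Returns the spiking neuron indices in order.
static std::vector<int> dendritic_spike_pass_internal(
    arma::vec& V, arma::vec& r, arma::vec* q, const arma::mat& Gamma,
    const arma::mat& U, const arma::vec& theta_vec, int reset_mode,
    double t) {
  std::vector<int> spikes;
  const int cap = 10 * (int)V.n_elem;
  int iter = 0;
  while (true) {
    arma::vec excess = V - theta_vec;
    arma::uword n = excess.index_max();
    if (!(excess(n) > 0.0)) break;
    if (++iter > cap)
      stop("runaway excitation: more than 10*N sequential spikes in one step at t = %g s", t);
    double Vn_before = V(n);
    V -= U.col(n);
    if (reset_mode == 1) V(n) = -theta_vec(n);
    (void)Vn_before;
    r(n) += 1.0;
    if (q) *q += Gamma.col(n);
    spikes.push_back((int)n);
  }
  return spikes;
}

// [[Rcpp::export]]
List dendritic_spike_pass_cpp(arma::vec V, arma::vec r, const arma::mat& Gamma,
                              const arma::mat& U, const arma::vec& theta_vec,
                              int reset_mode, double t) {
  std::vector<int> sp =
      dendritic_spike_pass_internal(V, r, nullptr, Gamma, U, theta_vec, reset_mode, t);
  IntegerVector ids(sp.size());
  for (size_t i = 0; i < sp.size(); ++i) ids[i] = sp[i] + 1;
  return List::create(_["V"] = V, _["r"] = r, _["spikes"] = ids);
}

// Simulate (and optionally train) one CSN on a fixed time grid.
// variant: 0 saturating, 1 dendritic.
// learn_mode: 0 none, 1 RLS on readout weights, 2 FORCE with recurrent
//   absorption (readout weights plus A or D updated; w_fb act as learning rates).
// fb_explicit: 1 adds a feedback current w_fb (mix*z + (1-mix)*F); with
//   learn_mode 2 the loop is normally absorbed instead (fb_explicit = 0).
// [[Rcpp::export]]
List csn_simulate_cpp(int variant, int n_steps, double dt,
                      double lambda_V, double lambda_s,
                      double theta, double V_r, double gamma,
                      arma::mat A, arma::mat D,
                      const arma::mat& Gamma, const arma::mat& U,
                      const arma::vec& theta_vec, const arma::vec& bias_b,
                      double a_slow, double mu, int reset_mode,
                      const arma::mat& inputs, const arma::mat& w_in,
                      const arma::vec& I_const, double sigma_eta, int scheme,
                      arma::mat w_o, arma::mat P, const arma::mat& targets,
                      const arma::mat& w_fb, double fb_mix, int fb_explicit,
                      int learn_mode, int update_every,
                      arma::vec V, arma::vec r,
                      int record_every, bool record_r, bool record_V) {
  const int N = (int)V.n_elem;
  const bool dendr = (variant == 1);
  const int B = dendr ? (int)Gamma.n_rows : N;  // readout basis dimension
  const int K_out = (int)w_o.n_rows;
  const int K_in = (int)inputs.n_rows;
  const bool learning = (learn_mode != LEARN_NONE);
  const bool has_fb = (fb_explicit == 1) && (w_fb.n_cols > 0);
  const bool has_targets = (targets.n_cols > 0);

  arma::mat z_hist(K_out, n_steps, arma::fill::zeros);
  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<double> err_t, err_norm;
  int n_rec = (record_every > 0) ? (n_steps / record_every) : 0;
  arma::mat r_hist(record_r ? N : 0, record_r ? n_rec : 0);
  arma::mat V_hist(record_V ? N : 0, record_V ? n_rec : 0);
  arma::vec rec_times(n_rec, arma::fill::zeros);
  int rec_i = 0;

  const double dec_full = std::exp(-lambda_s * dt);
  const double dec_half = std::exp(-lambda_s * dt * 0.5);
  const double sq_dt = std::sqrt(dt);

  // Dendritic caches: q = Gamma * r is maintained incrementally (exact scalar
  // decay within a step, rank-one column updates at spikes).
  arma::vec q;
  if (dendr) q = Gamma * r;

  arma::vec rt(B);  // activations tanh(gamma r) or tanh(b + Gamma r)
  if (dendr) rt = arma::tanh(bias_b + q); else rt = arma::tanh(gamma * r);
  arma::vec z = w_o * rt;

  for (int k = 0; k < n_steps; ++k) {
    const double t_end = (k + 1) * dt;
    // external drive for this step (beta-space: N for saturating, J for dendritic)
    arma::vec I_in = I_const;
    if (K_in > 0) I_in += w_in * inputs.col(k);
    arma::vec Fk;
    if (has_targets) Fk = targets.col(k);

    // forcing G(h) at substep offset h in {0, dt/2, dt}: everything except -lambda_V V
    arma::vec Gq;
    if (dendr) Gq = Gamma.t() * q;  // Gamma^T (Gamma r) at step start
    auto forcing = [&](double dec) -> arma::vec {
      arma::vec out;
      arma::vec rt_h;
      if (dendr) {
        rt_h = arma::tanh(bias_b + dec * q);
        out = D * rt_h + (a_slow * dec) * Gq + (mu * lambda_s * dec) * r;
      } else {
        rt_h = arma::tanh((gamma * dec) * r);
        out = A * rt_h + (V_r * lambda_s * dec) * r;
      }
      arma::vec drive = I_in;
      if (has_fb) {
        arma::vec z_h = w_o * rt_h;
        if (fb_mix < 1.0 && has_targets)
          drive += w_fb * (fb_mix * z_h + (1.0 - fb_mix) * Fk);
        else
          drive += w_fb * z_h;
      }
      if (dendr) out += Gamma.t() * drive; else out += drive;
      return out;
    };

    if (scheme == SCHEME_RK4) {
      arma::vec G0 = forcing(1.0), Gh = forcing(dec_half), G1 = forcing(dec_full);
      arma::vec k1 = -lambda_V * V + G0;
      arma::vec k2 = -lambda_V * (V + 0.5 * dt * k1) + Gh;
      arma::vec k3 = -lambda_V * (V + 0.5 * dt * k2) + Gh;
      arma::vec k4 = -lambda_V * (V + dt * k3) + G1;
      V += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    } else {
      arma::vec G0 = forcing(1.0);
      V += dt * (-lambda_V * V + G0);
      if (scheme == SCHEME_EM && sigma_eta > 0.0) {
        const double s = sigma_eta * sq_dt;
        for (int n = 0; n < N; ++n) V(n) += s * norm_rand();
      }
    }
    r *= dec_full;
    if (dendr) q *= dec_full;
    // flush vanishing state to exact zero (far below one coding quantum):
    // after activity dies out, exponential decay otherwise reaches the
    // denormalized float range, where arithmetic is drastically slower
    if ((k & 1023) == 0) { r.clean(1e-30); V.clean(1e-30); if (dendr) q.clean(1e-30); }

    // threshold / reset / fast interactions
    if (dendr) {
      std::vector<int> sp =
          dendritic_spike_pass_internal(V, r, &q, Gamma, U, theta_vec, reset_mode, t_end);
      for (int id : sp) { spike_t.push_back(t_end); spike_id.push_back(id + 1); }
    } else {
      const double th2 = 0.5 * theta;
      for (int n = 0; n < N; ++n) {
        if (V(n) > th2) {
          V(n) -= theta;
          r(n) += 1.0;
          spike_t.push_back(t_end);
          spike_id.push_back(n + 1);
        }
      }
    }
    check_finite(V, t_end);

    // post-spike activations and readout
    if (dendr) rt = arma::tanh(bias_b + q); else rt = arma::tanh(gamma * r);
    z = w_o * rt;
    z_hist.col(k) = z;

    if (learning && ((k + 1) % update_every == 0) && has_targets) {
      arma::vec e = z - Fk;  // pre-update error
      double en = arma::norm(e, 2);
      if (!std::isfinite(en) || en > 1e6)
        stop("training diverged (|e| = %g) at t = %g s", en, t_end);
      err_t.push_back(t_end);
      err_norm.push_back(en);
      // Sherman-Morrison update of P, then weight updates with the updated P
      arma::vec Pr = P * rt;
      double denom = 1.0 + arma::dot(rt, Pr);
      if (!(denom > 0.0))
        stop("inverse-correlation estimate lost positive definiteness at t = %g s", t_end);
      P -= (Pr * Pr.t()) / denom;
      P = 0.5 * (P + P.t());
      arma::vec Pr_new = Pr / denom;  // equals P_new * rt
      w_o -= e * Pr_new.t();
      if (learn_mode == LEARN_FORCE_REC) {
        arma::vec fe = w_fb * e;  // beta-space learning-rate-weighted error
        if (dendr) D -= (Gamma.t() * fe) * Pr_new.t();
        else A -= fe * Pr_new.t();
      }
    }

    if (record_every > 0 && ((k + 1) % record_every == 0) && rec_i < n_rec) {
      if (record_r) r_hist.col(rec_i) = r;
      if (record_V) V_hist.col(rec_i) = V;
      rec_times(rec_i) = t_end;
      ++rec_i;
    }
  }

  return List::create(
      _["V"] = V, _["r"] = r, _["z"] = z_hist,
      _["spike_time"] = spike_t, _["spike_id"] = spike_id,
      _["w_o"] = w_o, _["P"] = P, _["A"] = A, _["D"] = D,
      _["err_time"] = err_t, _["err_norm"] = err_norm,
      _["r_hist"] = r_hist, _["V_hist"] = V_hist, _["rec_times"] = rec_times);
}

// M rollouts of a trained dendritic PCSN world model from a common initial
// state, each driven by one column of xi (fed through w_in) with pure-output
// feedback. Returns per-rollout integrated rewards sum(y) * dt (y = output
// row iy, 0-based) and optionally the full output trajectories.
// [[Rcpp::export]]
List csn_rollout_batch_cpp(int n_steps, double dt,
                           double lambda_V, double lambda_s,
                           const arma::mat& D, const arma::mat& Gamma,
                           const arma::mat& U, const arma::vec& theta_vec,
                           const arma::vec& bias_b, double a_slow, double mu,
                           int reset_mode, const arma::mat& w_in,
                           const arma::vec& I_const, int scheme,
                           const arma::mat& w_o, const arma::mat& w_fb,
                           const arma::vec& V0, const arma::vec& r0,
                           const arma::mat& xi, int iy, bool return_traj) {
  const int M = (int)xi.n_cols;
  const int K_out = (int)w_o.n_rows;
  arma::vec rewards(M, arma::fill::zeros);
  arma::ivec ok(M, arma::fill::ones);
  arma::cube traj;
  if (return_traj) traj.set_size(K_out, n_steps, M);

  const double dec_full = std::exp(-lambda_s * dt);
  const double dec_half = std::exp(-lambda_s * dt * 0.5);

  for (int m = 0; m < M; ++m) {
    arma::vec V = V0, r = r0;
    arma::vec q = Gamma * r;
    bool fine = true;
    for (int k = 0; k < n_steps && fine; ++k) {
      arma::vec I_in = I_const + w_in.col(0) * xi(k, m);
      arma::vec Gq = Gamma.t() * q;
      auto forcing = [&](double dec) -> arma::vec {
        arma::vec rt_h = arma::tanh(bias_b + dec * q);
        arma::vec out = D * rt_h + (a_slow * dec) * Gq + (mu * lambda_s * dec) * r;
        arma::vec drive = I_in + w_fb * (w_o * rt_h);
        return out + Gamma.t() * drive;
      };
      if (scheme == SCHEME_RK4) {
        arma::vec G0 = forcing(1.0), Gh = forcing(dec_half), G1 = forcing(dec_full);
        arma::vec k1 = -lambda_V * V + G0;
        arma::vec k2 = -lambda_V * (V + 0.5 * dt * k1) + Gh;
        arma::vec k3 = -lambda_V * (V + 0.5 * dt * k2) + Gh;
        arma::vec k4 = -lambda_V * (V + dt * k3) + G1;
        V += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      } else {
        V += dt * (-lambda_V * V + forcing(1.0));
      }
      r *= dec_full;
      q *= dec_full;
      if ((k & 1023) == 0) { r.clean(1e-30); V.clean(1e-30); q.clean(1e-30); }
      try {
        dendritic_spike_pass_internal(V, r, &q, Gamma, U, theta_vec, reset_mode,
                                      (k + 1) * dt);
      } catch (...) {
        fine = false;
        break;
      }
      if (!V.is_finite()) { fine = false; break; }
      arma::vec z = w_o * arma::tanh(bias_b + q);
      if (!z.is_finite()) { fine = false; break; }
      rewards(m) += z(iy) * dt;
      if (return_traj) traj.slice(m).col(k) = z;
    }
    if (!fine) ok(m) = 0;
  }
  List out = List::create(_["rewards"] = rewards, _["ok"] = ok);
  if (return_traj) out["traj"] = traj;
  return out;
}

// Euler-Maruyama simulation of the damped driven pendulum
//   phi'' + c w0 phi' + w0^2 sin(phi) = xi(t) + u(t)
// xi and u are per-step forces on the grid (xi already scaled by 1/sqrt(dt)
// times the step normal draw on the R side, or any deterministic force).
// [[Rcpp::export]]
List pendulum_simulate_cpp(double phi0, double omega0, const arma::vec& xi,
                           const arma::vec& u, double dt, double w0_sq,
                           double c_w0) {
  const int n = (int)xi.n_elem;
  arma::vec phi(n + 1), omega(n + 1);
  phi(0) = phi0; omega(0) = omega0;
  for (int k = 0; k < n; ++k) {
    phi(k + 1) = phi(k) + dt * omega(k);
    omega(k + 1) = omega(k) + dt * (-w0_sq * std::sin(phi(k)) - c_w0 * omega(k) +
                                    xi(k) + u(k));
  }
  return List::create(_["phi"] = phi, _["omega"] = omega);
}

// M pendulum rollouts from a common state, column m of xi driving rollout m
// (u = 0). Rewards are sum(-cos(phi)) * dt over the horizon.
// [[Rcpp::export]]
List pendulum_rollout_batch_cpp(double phi0, double omega0, const arma::mat& xi,
                                double dt, double w0_sq, double c_w0,
                                bool return_traj) {
  const int n = (int)xi.n_rows, M = (int)xi.n_cols;
  arma::vec rewards(M, arma::fill::zeros);
  arma::mat traj;
  if (return_traj) traj.set_size(n, M);
  for (int m = 0; m < M; ++m) {
    double phi = phi0, omega = omega0;
    for (int k = 0; k < n; ++k) {
      double phi_new = phi + dt * omega;
      omega += dt * (-w0_sq * std::sin(phi) - c_w0 * omega + xi(k, m));
      phi = phi_new;
      rewards(m) += -std::cos(phi) * dt;
      if (return_traj) traj(k, m) = phi;
    }
  }
  List out = List::create(_["rewards"] = rewards,
                          _["ok"] = arma::ivec(M, arma::fill::ones));
  if (return_traj) out["traj"] = traj;
  return out;
}
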