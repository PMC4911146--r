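#' Configuration of the path-integral controller
#'
#' @param M number of exploratory rollouts per planning cycle.
#' @param horizon rollout length `T_r` (s).
#' @param delta averaging window `delta` for the initial noise (s): the control
#'   estimate weights the rollout noise averaged over the first `delta`
#'   seconds of each rollout.
#' @param Delta replanning interval (s); each computed control is applied as a
#'   constant force for `Delta < delta` seconds before the next cycle.
#' @param lambda_c reward-weighting inverse temperature (1/s scale; weights
#'   are `softmax(lambda_c * R_i)`).
#' @param noise_density spectral density of the exploration noise (1/s^3).
#' @param dt_rollout integration step used inside rollouts (s); defaults to
#'   the model's own step.
#' @return An object of class `control_config`.
#' @export
control_config <- function(M = 200, horizon = 1, delta = 0.1, Delta = 0.01,
                           lambda_c = 0.01, noise_density = 1,
                           dt_rollout = NULL) {
  stopifnot(M >= 1, horizon >= delta, delta >= Delta)
  structure(list(M = M, horizon = horizon, delta = delta, Delta = Delta,
                 lambda_c = lambda_c, noise_density = noise_density,
                 dt_rollout = dt_rollout),
            class = "control_config")
}

#' Pendulum plant as a (perfect) forward model
#'
#' Wraps the pendulum itself so the controller can plan either on the true
#' dynamics or on a learned network model through one interface.
#'
#' @param w0_sq,c_w0 plant parameters (see [pendulum_step()]).
#' @param dt integration step for rollouts (s).
#' @export
pendulum_plant <- function(w0_sq = 10, c_w0 = 0.1, dt = 1e-3) {
  structure(list(w0_sq = w0_sq, c_w0 = c_w0, dt = dt),
            class = c("pendulum_plant", "forward_model"))
}

#' Trained network as a learned forward model
#'
#' A nonlinear-dendrite CSN trained on pendulum trajectories (outputs
#' `x = sin(phi)`, `y = -cos(phi)`, `omega`, with the noise-plus-control force
#' as input) used for mental exploration. Before each batch of rollouts the
#' model is synchronised to the observed plant state by clamping the feedback
#' to the observation for `washout` seconds with zero input.
#'
#' @param spec trained `dendritic_network`.
#' @param learner trained [readout_learner()] with the three output channels.
#' @param feedback the [feedback_spec()] used in training.
#' @param iy index of the height output `y = -cos(phi)` among the output
#'   channels (the reward is the time integral of this channel).
#' @param washout synchronisation time before each rollout batch (s).
#' @export
pcsn_world_model <- function(spec, learner, feedback, iy = 2, washout = 0.2) {
  stopifnot(spec$variant == "dendritic", iy >= 1, iy <= nrow(learner$w_o))
  structure(list(spec = spec, learner = learner, feedback = feedback,
                 iy = as.integer(iy), washout = washout),
            class = c("pcsn_world_model", "forward_model"))
}

#' Mental exploration: reward and initial noise of M rollouts
#'
#' Draws `M` independent white-noise force realisations, simulates the forward
#' model for `horizon` seconds from the current state under each realisation
#' (no control), and returns each rollout's reward `R_i = integral of y dt`
#' (pendulum height; +1 upright) together with the noise averaged over the
#' first `delta` seconds.
#'
#' @param model a [pendulum_plant()] or [pcsn_world_model()].
#' @param state observed plant state: list with `phi` and `omega`.
#' @param config a [control_config()].
#' @param return_traj keep the rollout trajectories (for diagnostics).
#' @return list with `rewards` (length M), `xi_bar` (length M), `ok` (logical,
#'   rollouts that stayed finite), optional `traj`, and for the network model
#'   the post-washout network state.
#' @export
mental_explore <- function(model, state, config, return_traj = FALSE) {
  UseMethod("mental_explore")
}

#' @export
mental_explore.pendulum_plant <- function(model, state, config,
                                          return_traj = FALSE) {
  dt <- if (!is.null(config$dt_rollout)) config$dt_rollout else model$dt
  n <- as.integer(round(config$horizon / dt))
  xi <- matrix(rnorm(n * config$M, sd = sqrt(config$noise_density / dt)),
               n, config$M)
  res <- pendulum_rollout_batch_cpp(state$phi, state$omega, xi, dt,
                                    model$w0_sq, model$c_w0, return_traj)
  n_bar <- max(1L, as.integer(round(config$delta / dt)))
  out <- list(rewards = as.numeric(res$rewards),
              xi_bar = colMeans(xi[seq_len(n_bar), , drop = FALSE]),
              ok = as.integer(res$ok) == 1L)
  if (return_traj) out$traj <- res$traj
  out
}

#' @export
mental_explore.pcsn_world_model <- function(model, state, config,
                                            return_traj = FALSE) {
  spec <- model$spec
  dt_net <- spec$params$dt
  # synchronise the model to the observation: clamp feedback, zero input
  obs <- c(sin(state$phi), -cos(state$phi), state$omega)
  n_wash <- as.integer(round(model$washout / dt_net))
  fb <- model$feedback
  fb$mix <- 0  # feed back the observation, not the output
  wash <- csn_run(spec, n_wash,
                  inputs = matrix(0, nrow = ncol(spec$w_in), ncol = n_wash),
                  targets = matrix(obs, 3L, n_wash),
                  learner = model$learner, feedback = fb, learn = "none",
                  init = model$state)
  V0 <- as.numeric(wash$V); r0 <- as.numeric(wash$r)

  dt <- if (!is.null(config$dt_rollout)) config$dt_rollout else dt_net
  n <- as.integer(round(config$horizon / dt))
  xi <- matrix(rnorm(n * config$M, sd = sqrt(config$noise_density / dt)),
               n, config$M)
  res <- csn_rollout_batch_cpp(
    n, dt, spec$params$lambda_V, spec$params$lambda_s,
    spec$D, spec$Gamma, spec$U, spec$theta_vec, spec$bias_b,
    spec$params$a, spec$params$mu,
    if (spec$reset_mode == "always_minus_theta") 1L else 0L,
    spec$w_in,
    if (!is.null(spec$I_const)) spec$I_const else numeric(spec$J),
    scheme_code(spec$scheme),
    model$learner$w_o, model$feedback$w_fb,
    V0, r0, xi, model$iy - 1L, return_traj)
  n_bar <- max(1L, as.integer(round(config$delta / dt)))
  out <- list(rewards = as.numeric(res$rewards),
              xi_bar = colMeans(xi[seq_len(n_bar), , drop = FALSE]),
              ok = as.integer(res$ok) == 1L,
              net_state = list(V = V0, r = r0))
  if (return_traj) out$traj <- res$traj
  out
}

#' Path-integral control estimate from exploratory rollouts
#'
#' Combines rollout rewards and initial noise into the control force
#' `u = sum_i softmax(lambda_c * R_i) * xi_bar_i`, using a log-sum-exp
#' stabilised softmax. Rollouts flagged as invalid are excluded.
#'
#' @param rewards rollout rewards.
#' @param xi_bar rollout noise averaged over the initial `delta` window.
#' @param lambda_c inverse temperature.
#' @param ok logical mask of valid rollouts.
#' @return The scalar control force `u`.
#' @export
path_integral_control <- function(rewards, xi_bar, lambda_c, ok = NULL) {
  if (!is.null(ok)) {
    rewards <- rewards[ok]
    xi_bar <- xi_bar[ok]
  }
  if (length(rewards) == 0) stop("no valid rollouts to compute a control from")
  lw <- lambda_c * rewards
  w <- exp(lw - max(lw))
  sum(w * xi_bar) / sum(w)
}

#' Closed-loop path-integral control of the pendulum
#'
#' Runs the full act-plan loop: every `Delta` seconds the controller performs
#' `M` mental rollouts on the forward model from the currently observed plant
#' state, computes the path-integral control, and applies it as a constant
#' force (added to fresh plant noise) until the next planning cycle.
#'
#' @param model forward model used for planning ([pendulum_plant()] for
#'   ground-truth planning, [pcsn_world_model()] for planning on the learned
#'   network).
#' @param config a [control_config()].
#' @param duration controlled time (s).
#' @param init initial plant state (list `phi`, `omega`).
#' @param dt_plant integration step of the real plant (s).
#' @param plant_noise_density spectral density of the real plant noise; the
#'   task's default equals the exploration noise density.
#' @param w0_sq,c_w0 real plant parameters.
#' @return list with `time`, `phi`, `omega`, `u` (per-cycle control log with
#'   `u$time`, `u$value`), and the fraction of valid rollouts.
#' @export
control_loop <- function(model, config, duration, init = list(phi = 0, omega = 0),
                         dt_plant = 1e-3, plant_noise_density = NULL,
                         w0_sq = 10, c_w0 = 0.1) {
  if (is.null(plant_noise_density)) plant_noise_density <- config$noise_density
  n_cycles <- as.integer(round(duration / config$Delta))
  steps_per_cycle <- as.integer(round(config$Delta / dt_plant))
  stopifnot(n_cycles >= 1, steps_per_cycle >= 1)

  phi <- numeric(n_cycles * steps_per_cycle + 1L)
  omega <- numeric(n_cycles * steps_per_cycle + 1L)
  phi[1] <- init$phi; omega[1] <- init$omega
  u_log <- numeric(n_cycles)
  ok_frac <- numeric(n_cycles)
  state <- init
  is_net <- inherits(model, "pcsn_world_model")

  for (cyc in seq_len(n_cycles)) {
    ex <- mental_explore(model, state, config)
    if (is_net && !is.null(ex$net_state)) model$state <- ex$net_state
    u <- path_integral_control(ex$rewards, ex$xi_bar, config$lambda_c, ex$ok)
    u_log[cyc] <- u
    ok_frac[cyc] <- mean(ex$ok)
    xi <- pendulum_noise(steps_per_cycle, dt_plant, plant_noise_density)
    res <- pendulum_simulate_cpp(state$phi, state$omega, xi,
                                 rep(u, steps_per_cycle), dt_plant,
                                 w0_sq, c_w0)
    idx <- (cyc - 1L) * steps_per_cycle + 1L + seq_len(steps_per_cycle)
    phi[idx] <- res$phi[-1]
    omega[idx] <- res$omega[-1]
    state <- list(phi = phi[idx[steps_per_cycle]],
                  omega = omega[idx[steps_per_cycle]])
  }
  list(time = dt_plant * seq(0, n_cycles * steps_per_cycle),
       phi = phi, omega = omega,
       u = data.frame(time = config$Delta * (seq_len(n_cycles) - 1L),
                      value = u_log),
       ok_fraction = ok_frac)
}

#' Train a network forward model of the noisy pendulum
#'
#' Simulates the freely fluctuating pendulum under white-noise forcing, and
#' trains a nonlinear-dendrite CSN by FORCE learning (with an explicit
#' feedback loop, mixing `mix` parts of the network's own output with
#' `1 - mix` parts of the true trajectory during training) to predict
#' `x = sin(phi)`, `y = -cos(phi)` and `omega`, receiving the same force
#' realisation as input.
#'
#' @param spec a `dendritic_network` with one input channel (the force) and
#'   a three-row-capable feedback; `spec$w_in` must be `J x 1`.
#' @param learner a [readout_learner()] with three outputs.
#' @param feedback a [feedback_spec()] with `J x 3` weights; during training
#'   `feedback$mix` is used as the convex mixing coefficient.
#' @param Tt training duration (s).
#' @param noise_density forcing noise density (1/s^3).
#' @param init_phi,init_omega initial plant state of the training trajectory.
#' @return list with the trained `spec`, `learner`, the pendulum trajectory
#'   used (`plant`), and the training `trace`.
#' @export
train_world_model <- function(spec, learner, feedback, Tt, noise_density = 1,
                              init_phi = 0, init_omega = 0) {
  dt <- spec$params$dt
  n <- as.integer(round(Tt / dt))
  pend <- simulate_pendulum(Tt, dt, phi0 = init_phi, omega0 = init_omega,
                            noise_density = noise_density)
  # targets at end-of-step times; input force constant over each step
  targets <- rbind(sin(pend$phi[-1]), -cos(pend$phi[-1]), pend$omega[-1])
  task <- task_bundle(dt * seq_len(n), matrix(pend$xi, 1L), targets,
                      name = "pendulum_model", params = list(dt = dt))
  fit <- train_csn(spec, task, learner, feedback, learn = "rls")
  list(spec = fit$spec, learner = fit$learner, plant = pend,
       trace = fit$trace, state = fit$state)
}
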