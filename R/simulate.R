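scheme_code <- function(scheme) {
  switch(scheme, euler = 0L, rk4 = 1L, em = 2L,
         stop("unknown integration scheme: ", scheme))
}

#' @keywords internal
#' Assemble arguments and invoke the C++ simulation/training kernel.
#' All user-facing entry points (run_network, train_csn, recall_csn, the step
#' helpers) go through here so that every code path shares one stepping rule.
csn_run <- function(spec, n_steps, inputs = NULL, targets = NULL,
                    learner = NULL, feedback = NULL,
                    learn = c("none", "rls", "force"),
                    init = NULL, scheme = NULL,
                    record_every = 0L, record_r = FALSE, record_V = FALSE) {
  learn <- match.arg(learn)
  p <- spec$params
  dendr <- spec$variant == "dendritic"
  N <- spec$N
  B <- if (dendr) spec$J else N
  beta <- B  # dimension of the external-drive space (J for dendritic, N else)

  if (is.null(scheme)) scheme <- if (p$sigma_eta > 0) "em" else spec$scheme
  if (p$sigma_eta > 0 && scheme != "em")
    stop("noisy dynamics (sigma_eta > 0) require the Euler-Maruyama scheme")

  if (is.null(inputs)) {
    inputs <- matrix(0, 0, n_steps)
    w_in <- matrix(0, beta, 0)
  } else {
    inputs <- as.matrix(inputs)
    if (ncol(inputs) != n_steps) stop("`inputs` must have n_steps columns")
    if (is.null(spec$w_in)) stop("network has no input weights `w_in`")
    w_in <- spec$w_in
    if (nrow(w_in) != beta || ncol(w_in) != nrow(inputs))
      stop("`w_in` dimensions do not match the input channels")
  }
  I_const <- if (!is.null(spec$I_const)) spec$I_const else numeric(beta)

  if (is.null(targets)) {
    targets <- matrix(0, 0, n_steps)
  } else {
    targets <- as.matrix(targets)
    if (ncol(targets) != n_steps) stop("`targets` must have n_steps columns")
  }

  if (is.null(learner)) {
    k_out <- max(1L, nrow(targets))
    learner <- list(w_o = matrix(0, k_out, B), P = diag(B),
                    delta_t_update = p$dt)
  }
  w_o <- learner$w_o
  P <- learner$P
  if (ncol(w_o) != B) stop("readout weights do not match the basis dimension")

  fb_explicit <- 0L
  fb_mix <- 1
  w_fb <- matrix(0, beta, nrow(w_o))
  if (!is.null(feedback)) {
    w_fb <- feedback$w_fb
    fb_mix <- feedback$mix
    fb_explicit <- if (isTRUE(feedback$explicit)) 1L else 0L
    if (nrow(w_fb) != beta) stop("`w_fb` must have one row per synapse/dendrite")
  }
  learn_mode <- switch(learn, none = 0L, rls = 1L, force = 2L)
  if (learn != "none" && nrow(targets) == 0)
    stop("training requires target signals")
  if (learn == "force" && is.null(feedback))
    stop("FORCE recurrent learning needs a feedback specification (learning rates)")
  update_every <- max(1L, as.integer(round(
    (if (!is.null(learner$delta_t_update)) learner$delta_t_update else p$dt) / p$dt)))

  if (is.null(init)) init <- list()
  V0 <- if (!is.null(init$V)) init$V else numeric(N)
  r0 <- if (!is.null(init$r)) init$r else numeric(N)
  if (any(r0 < 0)) stop("synaptic variables r must be non-negative")

  empty <- matrix(0, 0, 0)
  res <- csn_simulate_cpp(
    variant = if (dendr) 1L else 0L, n_steps = as.integer(n_steps), dt = p$dt,
    lambda_V = p$lambda_V, lambda_s = p$lambda_s,
    theta = if (dendr) 0 else p$theta,
    V_r = if (dendr) 0 else p$V_r,
    gamma = if (dendr) 0 else p$gamma,
    A = if (dendr) empty else spec$A,
    D = if (dendr) spec$D else empty,
    Gamma = if (dendr) spec$Gamma else empty,
    U = if (dendr) spec$U else empty,
    theta_vec = if (dendr) spec$theta_vec else numeric(0),
    bias_b = if (dendr) spec$bias_b else numeric(0),
    a_slow = p$a, mu = p$mu,
    reset_mode = if (dendr && spec$reset_mode == "always_minus_theta") 1L else 0L,
    inputs = inputs, w_in = w_in, I_const = I_const,
    sigma_eta = p$sigma_eta, scheme = scheme_code(scheme),
    w_o = w_o, P = P, targets = targets,
    w_fb = w_fb, fb_mix = fb_mix, fb_explicit = fb_explicit,
    learn_mode = learn_mode, update_every = update_every,
    V = V0, r = r0,
    record_every = as.integer(record_every),
    record_r = record_r, record_V = record_V)
  res$dt <- p$dt
  res$n_steps <- n_steps
  res
}

#' Simulate a CSN over a time grid
#'
#' Advances the network for `duration` seconds from a given (default: zero)
#' initial state under an optional external input, and returns the resulting
#' trace: readout-basis output history, spike log, and optionally decimated
#' membrane-potential and synaptic-current histories.
#'
#' Deterministic dynamics are integrated with classical 4th-order Runge-Kutta
#' on the smooth vector field between grid points (the synaptic variables
#' decay exactly exponentially within a step); with `sigma_eta > 0` an
#' Euler-Maruyama step is used. Thresholds and resets are processed at grid
#' points; in the dendritic variant spikes within one grid point are processed
#' sequentially in order of descending membrane potential, so that the fast
#' (unfiltered) couplings act before further spikes are emitted.
#'
#' @param spec a `network_spec` from [saturating_network()] or
#'   [dendritic_network()].
#' @param input `NULL`, or a `K_in x n_steps` matrix of input-channel values
#'   (weighted into the network by `spec$w_in`), or a function of time
#'   returning the `K_in` channel values.
#' @param duration simulated time (s); `n_steps = round(duration / dt)`.
#' @param init optional list with elements `V` and `r` (initial state).
#' @param learner optional readout learner whose weights define the recorded
#'   output `z` (weights are not updated here).
#' @param feedback optional [feedback_spec()]; if `explicit = TRUE` the output
#'   is fed back as an input current.
#' @param record_every record `V`/`r` every this many steps (0: never).
#' @param record_r,record_V which state histories to keep.
#' @param scheme override the integration scheme (`"rk4"`, `"euler"`, `"em"`).
#' @return A `simulation_trace`: list with `time`, `z`, `spikes` (data frame
#'   `time`, `neuron`), final `V` and `r`, and optional `r_hist`/`V_hist` with
#'   their `rec_times`.
#' @export
run_network <- function(spec, input = NULL, duration, init = NULL,
                        learner = NULL, feedback = NULL,
                        record_every = 0L, record_r = FALSE, record_V = FALSE,
                        scheme = NULL) {
  stopifnot(duration > 0)
  dt <- spec$params$dt
  n_steps <- as.integer(round(duration / dt))
  if (is.function(input)) {
    tt <- (seq_len(n_steps) - 1L) * dt
    vals <- vapply(tt, input, FUN.VALUE = input(0))
    input <- if (is.null(dim(vals))) matrix(vals, 1L) else vals
  }
  res <- csn_run(spec, n_steps, inputs = input, learner = learner,
                 feedback = feedback, init = init,
                 record_every = record_every,
                 record_r = record_r, record_V = record_V, scheme = scheme)
  as_simulation_trace(res)
}

as_simulation_trace <- function(res) {
  structure(list(
    time = res$dt * seq_len(res$n_steps),
    dt = res$dt,
    z = res$z,
    spikes = data.frame(time = as.numeric(res$spike_time),
                        neuron = as.integer(res$spike_id)),
    V = as.numeric(res$V), r = as.numeric(res$r),
    w_o = res$w_o, P = res$P, A = res$A, D = res$D,
    err = data.frame(time = as.numeric(res$err_time),
                     norm = as.numeric(res$err_norm)),
    r_hist = if (length(res$r_hist)) res$r_hist else NULL,
    V_hist = if (length(res$V_hist)) res$V_hist else NULL,
    rec_times = if (length(res$rec_times)) as.numeric(res$rec_times) else NULL),
    class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  dur <- if (length(x$time)) max(x$time) else 0
  cat(sprintf("simulation trace: %.4g s, %d spikes, %d output channel(s)\n",
              dur, nrow(x$spikes), nrow(x$z)))
  invisible(x)
}

#' Advance a saturating-synapse network by one grid step
#'
#' Single-step version of the simulator, mainly useful for inspecting the
#' integration and threshold rule. The external input `I_e` is held constant
#' over the step.
#'
#' @param state list with membrane potentials `V` and synaptic variables `r`.
#' @param spec a `saturating_network`.
#' @param I_e external input vector (length `N`).
#' @param scheme integration scheme override.
#' @return Updated `state` with a `spikes` element (neuron indices).
#' @export
step_saturating <- function(state, spec, I_e = NULL, scheme = NULL) {
  stopifnot(spec$variant == "saturating")
  if (!is.null(I_e)) spec$I_const <- I_e
  res <- csn_run(spec, 1L, init = state, scheme = scheme)
  list(V = as.numeric(res$V), r = as.numeric(res$r),
       spikes = as.integer(res$spike_id))
}

#' Advance a nonlinear-dendrite network by one grid step
#'
#' @param state list with `V` and `r`.
#' @param spec a `dendritic_network`.
#' @param I_e external input in the encoded space (length `J`); enters the
#'   somata through `Gamma^T`.
#' @param scheme integration scheme override.
#' @return Updated `state` with a `spikes` element.
#' @export
step_dendritic <- function(state, spec, I_e = NULL, scheme = NULL) {
  stopifnot(spec$variant == "dendritic")
  if (!is.null(I_e)) spec$I_const <- I_e
  res <- csn_run(spec, 1L, init = state, scheme = scheme)
  list(V = as.numeric(res$V), r = as.numeric(res$r),
       spikes = as.integer(res$spike_id))
}

#' Sequential fast-interaction spike processing (dendritic variant)
#'
#' Applies the within-grid-point spike rule: repeatedly select the neuron with
#' the highest suprathreshold membrane potential (ties break at the lowest
#' index), subtract its fast-coupling column `U[, n]` from all membrane
#' potentials (the diagonal implements the self-reset) and increment `r_n`,
#' until no neuron is above threshold. Errors out after `10 * N` spikes in one
#' call (runaway excitation).
#'
#' @param state list with `V` and `r`.
#' @param spec a `dendritic_network`.
#' @param t time stamp used in error messages.
#' @return list with updated `V`, `r` and the ordered spike indices.
#' @export
process_spikes_dendritic <- function(state, spec, t = 0) {
  stopifnot(spec$variant == "dendritic")
  res <- dendritic_spike_pass_cpp(
    state$V, state$r, spec$Gamma, spec$U, spec$theta_vec,
    if (spec$reset_mode == "always_minus_theta") 1L else 0L, t)
  list(V = as.numeric(res$V), r = as.numeric(res$r),
       spikes = as.integer(res$spikes))
}

#' Write a spike log as delimiter-separated text
#' @param trace a `simulation_trace` (or data frame with `time`, `neuron`).
#' @param file output path.
#' @export
write_spike_log <- function(trace, file) {
  spikes <- if (inherits(trace, "simulation_trace")) trace$spikes else trace
  utils::write.table(data.frame(time_s = spikes$time, neuron_id = spikes$neuron),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
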