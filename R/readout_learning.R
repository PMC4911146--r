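#' Create a readout learner for RLS / FORCE training
#'
#' Holds the linear output weights and the running inverse-correlation
#' estimate `P` of the activation vectors. Weights start at zero and
#' `P(0) = I / alpha`, so `1/alpha` acts as the initial learning rate and
#' `alpha` as an effective ridge regulariser: one RLS pass over a data batch
#' reproduces the ridge regression solution with penalty `alpha` exactly.
#'
#' @param n_basis number of activation channels (N saturating synapses or J
#'   nonlinear dendrites).
#' @param k_out number of output channels.
#' @param alpha regulariser / inverse initial learning rate, `> 0`.
#' @param delta_t_update weight-update interval (s); must be an integer
#'   multiple of the simulation step when used in training.
#' @return An object of class `readout_learner`.
#' @export
readout_learner <- function(n_basis, k_out = 1, alpha = 0.1,
                            delta_t_update = 0.01) {
  stopifnot(n_basis >= 1, k_out >= 1, alpha > 0, delta_t_update > 0)
  structure(list(w_o = matrix(0, k_out, n_basis),
                 P = diag(n_basis) / alpha,
                 alpha = alpha, delta_t_update = delta_t_update,
                 e = rep(NA_real_, k_out)),
            class = "readout_learner")
}

#' @export
print.readout_learner <- function(x, ...) {
  cat(sprintf("readout learner: %d output(s) on %d basis channels, alpha = %g, update every %g s\n",
              nrow(x$w_o), ncol(x$w_o), x$alpha, x$delta_t_update))
  invisible(x)
}

#' Static feedback specification
#'
#' @param w_fb feedback weight matrix (`N x K_out` for saturating synapses,
#'   `J x K_out` for nonlinear dendrites; feedback enters dendritic somata
#'   through `Gamma^T`). In recurrent (absorbed) FORCE learning these weights
#'   act as the per-unit learning rates.
#' @param mix convex mixing coefficient used during training: the current fed
#'   back is `mix * output + (1 - mix) * target`. 1 (the default) feeds back
#'   the pure output, as FORCE prescribes.
#' @param explicit whether the feedback loop is an explicit input current
#'   (`TRUE`) or absorbed into the recurrent weights (`FALSE`).
#' @export
feedback_spec <- function(w_fb, mix = 1, explicit = TRUE) {
  stopifnot(is.matrix(w_fb), mix >= 0, mix <= 1)
  structure(list(w_fb = w_fb, mix = mix, explicit = explicit),
            class = "feedback_spec")
}

#' Readout-basis activations
#'
#' The nonlinear somatic input currents that readouts (and the recurrent
#' network itself) combine linearly: `tanh(gamma * r_m)` per saturating
#' synapse, or `tanh(b_j + sum_m Gamma_jm r_m)` per nonlinear dendrite.
#'
#' @param spec a `network_spec`.
#' @param r synaptic-current vector (length N).
#' @return Activation vector of length N (saturating) or J (dendritic).
#' @export
activations <- function(spec, r) {
  if (spec$variant == "dendritic")
    tanh(spec$bias_b + as.numeric(spec$Gamma %*% r))
  else
    tanh(spec$params$gamma * r)
}

#' Linear readout
#' @param w_o output weight matrix (`K_out x B`).
#' @param rtilde activation vector (length B).
#' @return Output vector `z = w_o %*% rtilde` (length K_out).
#' @export
readout <- function(w_o, rtilde) {
  if (ncol(w_o) != length(rtilde)) stop("weight/activation shape mismatch")
  as.numeric(w_o %*% rtilde)
}

#' One recursive-least-squares update
#'
#' Updates the inverse-correlation estimate by the Sherman-Morrison rank-one
#' formula and then the output weights using the updated `P`; the error is
#' computed with the pre-update weights (`e = z - target`). `P` is
#' re-symmetrised after every update to control floating-point drift over long
#' training runs.
#'
#' @param learner a [readout_learner()].
#' @param rtilde activation vector.
#' @param target target output vector.
#' @param z current output (pre-update); defaults to `w_o %*% rtilde`.
#' @return The updated learner (with the error stored in `$e`).
#' @export
rls_update <- function(learner, rtilde, target, z = NULL) {
  if (is.null(z)) z <- readout(learner$w_o, rtilde)
  e <- z - target
  Pr <- learner$P %*% rtilde
  denom <- 1 + sum(rtilde * Pr)
  if (!(denom > 0))
    stop("inverse-correlation estimate lost positive definiteness")
  P <- learner$P - tcrossprod(Pr) / denom
  P <- (P + t(P)) / 2
  Pr_new <- Pr / denom  # equals P_new %*% rtilde
  learner$P <- P
  learner$w_o <- learner$w_o - e %*% t(Pr_new)
  learner$e <- as.numeric(e)
  learner
}

#' FORCE update of the recurrent couplings
#'
#' Absorbs the feedback loop into the recurrence: instead of feeding back
#' `w_fb %*% z`, the recurrent matrix itself is updated so that the network
#' input currents are identical at every step. For saturating synapses
#' `A <- A - (w_fb e) (P rtilde)^T`; for nonlinear dendrites
#' `D <- D - Gamma^T (w_fb e) (P rtilde)^T`. Call after [rls_update()] so that
#' `P` is the updated estimate, and pass the same pre-update error.
#'
#' @param spec a `network_spec`.
#' @param learner the learner holding the updated `P`.
#' @param feedback a [feedback_spec()]; its weights act as learning rates.
#' @param rtilde activation vector used in the update.
#' @param e pre-update error vector (`z - target`).
#' @return The spec with updated `A` (saturating) or `D` (dendritic).
#' @export
force_recurrent_update <- function(spec, learner, feedback, rtilde, e) {
  Pr <- as.numeric(learner$P %*% rtilde)
  fe <- as.numeric(feedback$w_fb %*% e)
  if (spec$variant == "dendritic") {
    spec$D <- spec$D - crossprod(spec$Gamma, fe) %*% t(Pr)
  } else {
    spec$A <- spec$A - fe %*% t(Pr)
  }
  spec
}

#' Train a CSN on a task by online RLS / FORCE learning
#'
#' Runs the network over the task's time grid; every `delta_t_update` seconds
#' the training error `e = z - F` is computed with the pre-update weights, the
#' inverse-correlation estimate is updated, and the output weights (and, for
#' `learn = "force_rec"`, the recurrent couplings) are updated. During
#' training with an explicit feedback loop the current fed back is
#' `mix * z + (1 - mix) * F`. After the training period all weights are
#' frozen; use [recall_csn()] for autonomous recall.
#'
#' @param spec a `network_spec`.
#' @param task a task-signal bundle (see [pattern_task()] and friends) whose
#'   `targets` (and optional `inputs`) live on the network's time grid.
#' @param learner a [readout_learner()].
#' @param feedback a [feedback_spec()], or `NULL` for open-loop RLS.
#' @param learn `"rls"` (readout only; feedback current added if `feedback`
#'   has `explicit = TRUE`) or `"force_rec"` (readout plus recurrent
#'   absorption of the feedback loop).
#' @param init optional initial state.
#' @return list with the trained `spec`, trained `learner`, and the training
#'   `trace` (a `simulation_trace` whose `err` records the per-update error
#'   norm).
#' @export
train_csn <- function(spec, task, learner, feedback = NULL,
                      learn = c("rls", "force_rec"), init = NULL) {
  learn <- match.arg(learn)
  n_steps <- ncol(task$targets)
  upd <- learner$delta_t_update / spec$params$dt
  if (abs(upd - round(upd)) > 1e-8)
    stop("`delta_t_update` must be an integer multiple of dt")
  res <- csn_run(spec, n_steps, inputs = task$inputs, targets = task$targets,
                 learner = learner, feedback = feedback,
                 learn = if (learn == "rls") "rls" else "force",
                 init = init)
  learner$w_o <- res$w_o
  learner$P <- res$P
  if (learn == "force_rec") {
    if (spec$variant == "dendritic") spec$D <- res$D else spec$A <- res$A
  }
  list(spec = spec, learner = learner, trace = as_simulation_trace(res),
       state = list(V = as.numeric(res$V), r = as.numeric(res$r)))
}

#' Autonomous recall after training
#'
#' Runs the trained network with frozen weights. With `learn = "force_rec"`
#' training the feedback loop already lives in the recurrent couplings and the
#' network runs fully autonomously; with explicit feedback the pure output is
#' fed back (`mix` is irrelevant during recall).
#'
#' @param spec trained `network_spec`.
#' @param learner trained [readout_learner()].
#' @param duration recall time (s).
#' @param feedback the [feedback_spec()] used in training when the loop is
#'   explicit; `NULL` for absorbed-recurrence networks.
#' @param init initial state; defaults to the end-of-training state if given.
#' @param input optional input matrix for input-driven tasks.
#' @param record_every,record_r,record_V recording options as in
#'   [run_network()].
#' @return A `simulation_trace`.
#' @export
recall_csn <- function(spec, learner, duration, feedback = NULL, init = NULL,
                       input = NULL, record_every = 0L, record_r = FALSE,
                       record_V = FALSE) {
  if (!is.null(feedback)) feedback$mix <- 1
  n_steps <- as.integer(round(duration / spec$params$dt))
  res <- csn_run(spec, n_steps, inputs = input, learner = learner,
                 feedback = feedback, learn = "none", init = init,
                 record_every = record_every, record_r = record_r,
                 record_V = record_V)
  as_simulation_trace(res)
}
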