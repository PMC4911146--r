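task_bundle <- function(time, inputs, targets, name, params = list()) {
  stopifnot(is.null(inputs) || ncol(inputs) == length(time),
            ncol(targets) == length(time))
  structure(list(time = time, inputs = inputs, targets = targets,
                 name = name, params = params),
            class = "task_signals")
}

#' @export
print.task_signals <- function(x, ...) {
  cat(sprintf("task '%s': %.4g s, %d input / %d target channel(s)\n",
              x$name, max(x$time), if (is.null(x$inputs)) 0L else nrow(x$inputs),
              nrow(x$targets)))
  invisible(x)
}

#' Periodic benchmark targets
#'
#' The three periodic pattern-generation targets: a sine of period `4 pi` s
#' and amplitude 2, `2 sin(t / 2s)`; a saw tooth of period 2 s and amplitude
#' 10 (peak-to-peak), rising from -5 to +5 over each period; and a
#' "camel's hump" superposition `sin(t / 0.5s) + cos(t / 1s)`.
#'
#' @param kind one of `"sine"`, `"sawtooth"`, `"camel"`.
#' @param t time (s); vectorised.
#' @return Target values at `t`.
#' @export
periodic_target <- function(kind = c("sine", "sawtooth", "camel"), t) {
  kind <- match.arg(kind)
  switch(kind,
         sine = 2 * sin(t / 2),
         sawtooth = 10 * ((t / 2) %% 1) - 5,
         camel = sin(t / 0.5) + cos(t / 1))
}

#' Task bundle for a periodic pattern-generation task
#' @param kind target kind, see [periodic_target()].
#' @param duration,dt time grid (s). Targets are sampled at the end of each
#'   step, `t = dt * (1:n)`.
#' @export
pattern_task <- function(kind, duration, dt) {
  n <- as.integer(round(duration / dt))
  tt <- dt * seq_len(n)
  task_bundle(tt, NULL, matrix(periodic_target(kind, tt), 1L),
              name = kind, params = list(dt = dt))
}

#' Lorenz-system teacher signal
#'
#' Integrates the standard Lorenz system (`sigma = 10`, `rho = 28`,
#' `beta = 8/3`) with fixed-step RK4, maps one dimensionless time unit to
#' 0.2 s and scales the dynamical variables by 0.1. The trajectory starts at
#' (0.1, 0.1, 0.1) and a 10-time-unit transient is discarded so the returned
#' signal lives on the attractor.
#'
#' @param duration length of the returned signal (s).
#' @param dt sampling step (s).
#' @param x0 initial condition before scaling.
#' @param transient discarded initial time (dimensionless Lorenz units).
#' @return A 3 x n matrix (rows x, y, z, scaled by 0.1) sampled at
#'   `t = dt * (1:n)`.
#' @export
lorenz_teacher <- function(duration, dt, x0 = c(0.1, 0.1, 0.1),
                           transient = 10) {
  stopifnot(duration > 0)
  unit <- 0.2  # seconds per dimensionless time unit
  field <- function(t, s, parms) {
    list(c(10 * (s[2] - s[1]),
           s[1] * (28 - s[3]) - s[2],
           s[1] * s[2] - 8 / 3 * s[3]))
  }
  n <- as.integer(round(duration / dt))
  # dimensionless grid matching the real-time grid, plus the transient
  tau <- seq(0, transient + n * dt / unit, by = dt / unit)
  out <- deSolve::ode(y = x0, times = tau, func = field, parms = NULL,
                      method = "rk4")
  keep <- seq.int(length(tau) - n + 1L, length(tau))
  0.1 * t(unname(as.matrix(out[keep, -1, drop = FALSE])))
}

#' Task bundle for the Lorenz pattern-generation task
#' @inheritParams lorenz_teacher
#' @export
lorenz_task <- function(duration, dt) {
  n <- as.integer(round(duration / dt))
  task_bundle(dt * seq_len(n), NULL, lorenz_teacher(duration, dt),
              name = "lorenz", params = list(dt = dt))
}

gauss_bump <- function(t, center, sigma, integral) {
  integral / (sigma * sqrt(2 * pi)) * exp(-0.5 * ((t - center) / sigma)^2)
}

#' Delayed-reaction trial signals
#'
#' Generates the input and target channels of the delayed-reaction / time
#' estimation task: trials start at random times with a 100 s refractory
#' period plus an exponential gap (mean 10 s); each trial contributes a
#' Gaussian input pulse (sd 0.2 s, integral 10 s) and a Gaussian target
#' response (sd 1 s, integral 1 s) centred `delay` seconds later. The first
#' onset follows a 5 s settle-in.
#'
#' @param Tt total duration (s).
#' @param delay reaction delay (s), in the task's 2-20 s range (0 allowed for
#'   degenerate checks).
#' @param dt time-grid step (s).
#' @param refractory,gap_mean inter-trial-interval parameters (s).
#' @return A task bundle with one input and one target channel; trial onset
#'   times are stored in `params$onsets`.
#' @export
delayed_reaction_trials <- function(Tt, delay, dt = 1e-3, refractory = 100,
                                    gap_mean = 10) {
  stopifnot(delay >= 0, delay <= 20)
  onsets <- c()
  t0 <- 5 + rexp(1, 1 / gap_mean)
  while (t0 + delay + 3 < Tt) {  # response must fit inside the window
    onsets <- c(onsets, t0)
    t0 <- t0 + refractory + rexp(1, 1 / gap_mean)
  }
  if (length(onsets) == 0)
    stop("`Tt` too short for a single trial at this delay")
  n <- as.integer(round(Tt / dt))
  tt <- dt * seq_len(n)
  inp <- rep(0, n); tgt <- rep(0, n)
  for (on in onsets) {
    inp <- inp + gauss_bump(tt, on, 0.2, 10)
    tgt <- tgt + gauss_bump(tt, on + delay, 1, 1)
  }
  task_bundle(tt, matrix(inp, 1L), matrix(tgt, 1L),
              name = "delayed_reaction",
              params = list(delay = delay, onsets = onsets, dt = dt))
}

# two cascaded first-order exponential filters (= alpha-function kernel)
double_exp_filter <- function(x, dt, tau) {
  a <- exp(-dt / tau)
  y <- as.numeric(stats::filter(x, a, method = "recursive"))
  as.numeric(stats::filter(y, a, method = "recursive"))
}

#' Signals for the persistent instruction-switching task
#'
#' Builds the four input channels and two targets of the memory-dependent
#' switching computation: two continuous operand channels (white noise
#' convolved twice with an exponential kernel — timescale 1 s during training,
#' 10 s during testing — normalised to mean 0, sd 0.5), and two pulsed
#' instruction channels (Poisson pulses convolved with a 1 s exponential
#' kernel, peak height 1; pulse rate 0.04/s during training, 0.01/s during
#' testing). When pulses on a channel would overlap to more than 1.01, the
#' later pulse is shifted by the minimal time that brings the sum back to
#' 1.01. The memory target `F_m` is +1 after a channel-1 pulse and -1 after a
#' channel-2 pulse; during switching it follows the cumulative integral of the
#' incoming pulse (an exponential ramp with the kernel's 1 s timescale). The
#' computation target is
#' `F_c = |f1 - f2| (F_m + 1)/2 - (f1 + f2)(F_m - 1)/2`, i.e. the absolute
#' difference of the operands while `F_m = +1` and their sum while
#' `F_m = -1`.
#'
#' @param duration duration (s).
#' @param mode `"train"` or `"test"` (sets filter timescale and pulse rate).
#' @param dt grid step (s).
#' @param fm_init initial memory state before any pulse.
#' @return A task bundle with inputs `(f1c, f2c, f1p, f2p)` and targets
#'   `(F_m, F_c)`; pulse times per channel are in `params$pulses`.
#' @export
instruction_task_signals <- function(duration, mode = c("train", "test"),
                                     dt = 0.01, fm_init = 1) {
  mode <- match.arg(mode)
  tau_c <- if (mode == "train") 1 else 10
  rate <- if (mode == "train") 0.04 else 0.01
  n <- as.integer(round(duration / dt))
  tt <- dt * seq_len(n)

  cont <- lapply(1:2, function(i) {
    y <- double_exp_filter(rnorm(n), dt, tau_c)
    (y - mean(y)) / sd(y) * 0.5
  })

  tau_p <- 1
  pulse_channel <- function() {
    n_p <- rpois(1, rate * duration)
    raw <- sort(runif(n_p, 0, duration))
    times <- c()
    sig <- rep(0, n)
    level_at <- function(tp) sum(exp(-(tp - times[times <= tp]) / tau_p))
    for (tp in raw) {
      if (length(times)) {
        s <- level_at(tp)
        if (s + 1 > 1.01) tp <- tp + tau_p * log(s / 0.01)
      }
      if (tp >= duration) next
      times <- c(times, tp)
      idx <- tt >= tp
      sig[idx] <- sig[idx] + exp(-(tt[idx] - tp) / tau_p)
    }
    list(times = times, sig = sig)
  }
  p1 <- pulse_channel(); p2 <- pulse_channel()

  # memory target: relax towards +-1 following the incoming pulse's integral
  events <- rbind(
    if (length(p1$times)) data.frame(t = p1$times, target = 1) else NULL,
    if (length(p2$times)) data.frame(t = p2$times, target = -1) else NULL)
  Fm <- rep(fm_init, n)
  if (!is.null(events) && nrow(events)) {
    events <- events[order(events$t), , drop = FALSE]
    cur <- fm_init
    bounds <- c(events$t, Inf)
    for (i in seq_len(nrow(events))) {
      seg <- tt >= events$t[i] & tt < bounds[i + 1]
      Fm[seg] <- events$target[i] +
        (cur - events$target[i]) * exp(-(tt[seg] - events$t[i]) / tau_p)
      if (any(seg)) cur <- Fm[which(seg)[sum(seg)]]
    }
    Fm <- pmin(1, pmax(-1, Fm))
  }
  f1 <- cont[[1]]; f2 <- cont[[2]]
  Fc <- abs(f1 - f2) * (Fm + 1) / 2 - (f1 + f2) * (Fm - 1) / 2

  task_bundle(tt,
              rbind(f1c = f1, f2c = f2, f1p = p1$sig, f2p = p2$sig),
              rbind(F_m = Fm, F_c = Fc),
              name = paste0("instruction_", mode),
              params = list(mode = mode, dt = dt,
                            pulses = list(ch1 = p1$times, ch2 = p2$times)))
}

#' One Euler-Maruyama step of the stochastic pendulum
#'
#' The plant is `phi'' + c w0 phi' + w0^2 sin(phi) = xi(t) + u(t)` with angle
#' `phi` (rad, 0 = hanging down), angular velocity `omega`, control force `u`
#' and noise force `xi` (pass `xi = sigma * rnorm(1) / sqrt(dt)` for white
#' noise of spectral density `sigma^2`).
#'
#' @param state list with `phi` and `omega`.
#' @param u control force (1/s^2 scale).
#' @param xi noise force sample (already scaled by `1/sqrt(dt)`).
#' @param dt step (s).
#' @param w0_sq squared small-amplitude angular frequency (default 10 /s^2).
#' @param c_w0 damping rate (default 0.1 /s).
#' @return Updated state.
#' @export
pendulum_step <- function(state, u = 0, xi = 0, dt, w0_sq = 10, c_w0 = 0.1) {
  res <- pendulum_simulate_cpp(state$phi, state$omega, xi, u, dt, w0_sq, c_w0)
  list(phi = res$phi[2], omega = res$omega[2])
}

#' White-noise force samples for the pendulum
#'
#' Per-step force values with `<xi(t) xi(t')> = density * delta(t - t')`
#' (the task uses density 1 in units of 1/s^3).
#'
#' @param n number of steps.
#' @param dt step (s).
#' @param density noise spectral density (1/s^3).
#' @export
pendulum_noise <- function(n, dt, density = 1) {
  rnorm(n, sd = sqrt(density / dt))
}

#' Simulate the stochastic pendulum over a grid
#'
#' @param duration,dt time grid (s).
#' @param phi0,omega0 initial state.
#' @param xi per-step noise force (vector of length `n`, a single value, or
#'   `NULL` to draw fresh white noise of density `noise_density`).
#' @param u per-step control force (vector or single value).
#' @param noise_density spectral density used when `xi` is `NULL`.
#' @param w0_sq,c_w0 plant parameters.
#' @return list with `time` (length n+1 including t = 0), `phi`, `omega`, and
#'   the applied `xi`.
#' @export
simulate_pendulum <- function(duration, dt, phi0 = 0, omega0 = 0, xi = NULL,
                              u = 0, noise_density = 1, w0_sq = 10,
                              c_w0 = 0.1) {
  n <- as.integer(round(duration / dt))
  if (is.null(xi)) xi <- pendulum_noise(n, dt, noise_density)
  if (length(xi) == 1) xi <- rep(xi, n)
  if (length(u) == 1) u <- rep(u, n)
  stopifnot(length(xi) == n, length(u) == n)
  res <- pendulum_simulate_cpp(phi0, omega0, xi, u, dt, w0_sq, c_w0)
  list(time = dt * (0:n), phi = as.numeric(res$phi),
       omega = as.numeric(res$omega), xi = xi)
}

#' Write a task-signal bundle as tab-separated text
#' @param task a `task_signals` bundle.
#' @param file output path.
#' @export
write_task_signals <- function(task, file) {
  df <- data.frame(time_s = task$time)
  if (!is.null(task$inputs))
    for (i in seq_len(nrow(task$inputs)))
      df[[paste0("input_", i)]] <- task$inputs[i, ]
  for (i in seq_len(nrow(task$targets)))
    df[[paste0("target_", i)]] <- task$targets[i, ]
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
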