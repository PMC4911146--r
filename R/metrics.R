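#' Mean population spike rate
#'
#' Number of spikes per neuron per second over the analysis window, discarding
#' an initial washout (transient after the zero initial state).
#'
#' @param trace a `simulation_trace`, or a data frame with a `time` column.
#' @param N number of neurons.
#' @param duration total simulated time (s); defaults to the trace's extent.
#' @param washout discarded initial time (s).
#' @return Mean rate in Hz.
#' @export
mean_spike_rate <- function(trace, N, duration = NULL, washout = 1) {
  spikes <- if (inherits(trace, "simulation_trace")) trace$spikes else trace
  if (is.null(duration)) {
    if (inherits(trace, "simulation_trace")) duration <- max(trace$time)
    else stop("`duration` is required when passing a bare spike log")
  }
  if (washout >= duration) stop("washout must be shorter than the run")
  n_sp <- sum(spikes$time > washout)
  n_sp / (N * (duration - washout))
}

#' Normalised root-mean-square error
#' @param z output signal.
#' @param target target signal of the same length.
#' @return `RMSE(z - target) / sd(target)`.
#' @export
nrmse <- function(z, target) {
  stopifnot(length(z) == length(target))
  sqrt(mean((z - target)^2)) / sd(target)
}

#' Phase-aligned NRMSE for periodic pattern generation
#'
#' An autonomous pattern generator reproduces the target waveform up to an
#' arbitrary phase, so the raw NRMSE conflates shape error with phase drift
#' accumulated since training. This metric minimises the RMSE over all
#' circular shifts of the target (computed exactly via FFT cross-correlation)
#' before normalising by the target's standard deviation.
#'
#' @param z output signal.
#' @param target periodic target sampled on the same grid; the window should
#'   cover an integer number of periods for the circular shift to be exact.
#' @return list with `nrmse` (at the best alignment) and `shift` (in samples,
#'   the amount the target was rotated).
#' @export
phase_aligned_nrmse <- function(z, target) {
  stopifnot(length(z) == length(target))
  if (sd(target) == 0)
    stop("constant target: normalisation undefined")
  n <- length(z)
  cc <- Re(stats::fft(Conj(stats::fft(z)) * stats::fft(target),
                      inverse = TRUE)) / n  # sum_k z[k] target[k + s]
  best <- which.max(cc)
  mse <- mean(z^2) + mean(target^2) - 2 * cc[best] / n
  list(nrmse = sqrt(max(mse, 0)) / sd(target), shift = best - 1L)
}

#' Normalised error of the delayed-reaction response
#'
#' RMSE between output and target, normalised by the RMSE of the all-zero
#' output: a value of 1 means the response is fully extinguished (no better
#' than staying silent), values well below 1 indicate a timed response.
#'
#' @param z output signal.
#' @param target target signal.
#' @return `RMSE(z - target) / RMSE(0 - target)`.
#' @export
delayed_reaction_error <- function(z, target) {
  stopifnot(length(z) == length(target))
  if (all(target == 0)) stop("zero target: baseline undefined")
  sqrt(mean((z - target)^2)) / sqrt(mean(target^2))
}

#' Local maxima of a signal with a minimum temporal separation
#'
#' Strict interior local maxima; when two maxima fall closer than `min_sep`
#' the smaller one is discarded.
#'
#' @param x signal.
#' @param dt sampling step (s).
#' @param min_sep minimum separation between reported maxima (s).
#' @return Integer indices of the maxima.
#' @export
local_maxima <- function(x, dt, min_sep = 0.1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (length(idx) < 2) return(idx)
  keep <- idx[1]
  for (i in idx[-1]) {
    last <- keep[length(keep)]
    if ((i - last) * dt >= min_sep) {
      keep <- c(keep, i)
    } else if (x[i] > x[last]) {
      keep[length(keep)] <- i
    }
  }
  keep
}

#' Successive-maxima pairs of a signal
#'
#' The classical first-return analysis of chaotic flows: the sequence of local
#' maxima `m_1, m_2, ...` of the Lorenz `z` variable defines a nearly
#' one-dimensional "tent"-shaped map `m_{k+1} = f(m_k)`.
#'
#' @inheritParams local_maxima
#' @return Two-column matrix of `(m_k, m_{k+1})` pairs.
#' @export
successive_maxima_pairs <- function(x, dt, min_sep = 0.1) {
  idx <- local_maxima(x, dt, min_sep)
  m <- x[idx]
  if (length(m) < 2) return(matrix(numeric(0), 0, 2))
  cbind(m[-length(m)], m[-1])
}

#' Reference first-return map of the Lorenz z variable
#'
#' Integrates a long reference Lorenz trajectory (same time unit and scaling
#' as [lorenz_teacher()]) and tabulates its successive-maxima map for use as
#' ground truth in [tent_map_outliers()].
#'
#' @param duration reference integration time (s).
#' @param dt sampling step (s).
#' @return list with the sorted reference `pairs` and an interpolating
#'   function `f` (constant extrapolation beyond the observed range).
#' @export
lorenz_tent_map_reference <- function(duration = 400, dt = 0.002) {
  z <- lorenz_teacher(duration, dt)[3, ]
  pairs <- successive_maxima_pairs(z, dt)
  if (nrow(pairs) < 10) stop("reference trajectory too short")
  ord <- order(pairs[, 1])
  px <- pairs[ord, 1]; py <- pairs[ord, 2]
  f <- function(m) approx(px, py, xout = m, rule = 2, ties = mean)$y
  list(pairs = pairs, f = f)
}

#' Tent-map outlier analysis of a generated Lorenz trajectory
#'
#' Extracts the successive-maxima pairs of the generated `z` signal and marks
#' as outliers the pairs whose deviation from the reference first-return map
#' exceeds `k` robust standard deviations (1.4826 times the median absolute
#' deviation of the residuals, an outlier-insensitive spread estimate).
#'
#' @param z generated Lorenz `z` signal (on the teacher's 0.1 scale).
#' @param dt sampling step (s).
#' @param reference a [lorenz_tent_map_reference()]; computed afresh when
#'   omitted.
#' @param k outlier threshold in robust standard deviations.
#' @param min_sep minimum maxima separation (s).
#' @return list with the `pairs`, their `residuals` from the reference map,
#'   the logical `outlier` flags, the `outlier_fraction`, and the
#'   `robust_sd` used.
#' @export
tent_map_outliers <- function(z, dt, reference = NULL, k = 3, min_sep = 0.1) {
  if (is.null(reference)) reference <- lorenz_tent_map_reference()
  pairs <- successive_maxima_pairs(z, dt, min_sep)
  if (nrow(pairs) < 2) stop("too few maxima for a tent-map analysis")
  res <- pairs[, 2] - reference$f(pairs[, 1])
  rsd <- 1.4826 * mad(res, constant = 1)
  if (rsd == 0) rsd <- sd(res)
  out <- abs(res) > k * rsd
  list(pairs = pairs, residuals = res, outlier = out,
       outlier_fraction = mean(out), robust_sd = rsd)
}
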