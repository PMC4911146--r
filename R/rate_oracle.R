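#' Direct integration of the encoded continuous dynamics (saturating coding)
#'
#' Integrates the rectified rate equations that a saturating-synapse CSN
#' encodes through `x = V + theta * r`:
#' `dx/dt = -lambda_V [x]_- - lambda_x [x]_+ + A tanh((gamma/theta) [x]_+) + I_e(t)`
#' with `[x]_+ = max(x, 0)` and `[x]_- = min(x, 0)`. Used as ground truth for
#' decode-equivalence tests. Fixed-step classical Runge-Kutta via deSolve.
#'
#' @param A coupling matrix (N x N, 1/s).
#' @param params a [neuron_params()] object supplying `lambda_V`, `lambda_x`,
#'   `gamma`, `theta`.
#' @param input_fn function of time returning the input vector `I_e(t)`
#'   (length N), or `NULL` for no input.
#' @param x0 initial state.
#' @param duration integration time (s).
#' @param dt integration step (s).
#' @return list with `time` (length `n+1`, starting at 0) and `x`
#'   (`(n+1) x N` matrix).
#' @export
integrate_rate_saturating <- function(A, params, input_fn = NULL, x0,
                                      duration, dt) {
  N <- length(x0)
  stopifnot(nrow(A) == N, ncol(A) == N)
  lv <- params$lambda_V; lx <- params$lambda_x
  gth <- params$gamma / params$theta
  field <- function(t, x, parms) {
    xp <- pmax(x, 0); xm <- pmin(x, 0)
    dx <- -lv * xm - lx * xp + as.numeric(A %*% tanh(gth * xp))
    if (!is.null(input_fn)) dx <- dx + input_fn(t)
    list(dx)
  }
  times <- seq(0, duration, by = dt)
  out <- deSolve::ode(y = x0, times = times, func = field, parms = NULL,
                      method = "rk4")
  x <- unname(as.matrix(out[, -1, drop = FALSE]))
  if (!all(is.finite(x))) stop("rate oracle diverged (non-finite state)")
  list(time = times, x = x)
}

#' Direct integration of the encoded continuous dynamics (distributed coding)
#'
#' Integrates the J-dimensional standard reservoir rate equations that a
#' nonlinear-dendrite CSN encodes through `x ~ Gamma r`:
#' `dx/dt = -lambda_x x + A tanh(x) + c(t)`.
#'
#' @param A coupling matrix (J x J, 1/s).
#' @param lambda_x leak rate of the encoded variables (1/s).
#' @param input_fn function of time returning `c(t)` (length J), or `NULL`.
#' @param x0 initial state (length J).
#' @param duration,dt integration time and step (s).
#' @return list with `time` and `x` (`(n+1) x J`).
#' @export
integrate_rate_dendritic <- function(A, lambda_x, input_fn = NULL, x0,
                                     duration, dt) {
  J <- length(x0)
  stopifnot(nrow(A) == J, ncol(A) == J)
  field <- function(t, x, parms) {
    dx <- -lambda_x * x + as.numeric(A %*% tanh(x))
    if (!is.null(input_fn)) dx <- dx + input_fn(t)
    list(dx)
  }
  times <- seq(0, duration, by = dt)
  out <- deSolve::ode(y = x0, times = times, func = field, parms = NULL,
                      method = "rk4")
  x <- unname(as.matrix(out[, -1, drop = FALSE]))
  if (!all(is.finite(x))) stop("rate oracle diverged (non-finite state)")
  list(time = times, x = x)
}

#' Sufficient condition for the echo-state property
#'
#' Checks whether the largest singular value of the coupling matrix is smaller
#' than `min(lambda_V, lambda_x)`. When this holds, the encoded rate dynamics
#' are a contraction: trajectories started from different initial conditions
#' under identical input converge, so the network state is a fading-memory
#' function of the input history. The bound is sufficient, not necessary.
#'
#' @param A square coupling matrix (1/s).
#' @param lambda_V,lambda_x leak rates (1/s).
#' @return `TRUE` if the sufficient condition holds.
#' @export
echo_state_sufficient <- function(A, lambda_V, lambda_x) {
  stopifnot(nrow(A) == ncol(A))
  smax <- if (all(A == 0)) 0 else max(svd(A, nu = 0, nv = 0)$d)
  smax < min(lambda_V, lambda_x)
}
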