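#' Neuron and coding parameters for a CSN
#'
#' Bundles the per-neuron rate constants of a continuous-signal-coding spiking
#' network. The encoded-signal leak rate `lambda_x` and the slow-coupling
#' coefficient `a = lambda_s - lambda_x` are tied to the other parameters by
#' identities and are always derived, never set independently: in the
#' saturating-synapse variant `lambda_x = lambda_s * (1 - V_r / theta)` (the
#' recovery current partially cancels the synaptic decay), in the dendritic
#' variant `lambda_x` is chosen directly.
#'
#' @param lambda_V membrane leak rate (1/s).
#' @param lambda_s synaptic decay rate (1/s).
#' @param dt integration step (s).
#' @param theta spike threshold scale (dimensionless; saturating variant).
#' @param V_r integrated recovery-current size (saturating variant). Either
#'   `V_r` or `lambda_x` must be given for the saturating variant.
#' @param lambda_x encoded-signal leak rate (1/s). Required for the dendritic
#'   variant; for the saturating variant it is derived from `V_r`.
#' @param gamma synaptic saturation scale (saturating variant). Defaults to
#'   `theta`, which keeps the encoded dynamics on the standard tanh scale.
#' @param mu spike-cost regulariser (dendritic variant), `mu >= 0`.
#' @param sigma_eta white-noise amplitude on the membrane potential (1/sqrt(s));
#'   0 disables noise.
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params(lambda_V = 10, lambda_s = 10, dt = 1e-3,
#'                    theta = 0.03, V_r = 0.9 * 0.03)
#' p$lambda_x  # lambda_s * (1 - V_r / theta) = 1
#' @export
neuron_params <- function(lambda_V, lambda_s, dt, theta = NULL, V_r = NULL,
                          lambda_x = NULL, gamma = NULL, mu = 0,
                          sigma_eta = 0) {
  stopifnot(lambda_V > 0, lambda_s > 0, dt > 0, mu >= 0, sigma_eta >= 0)
  if (!is.null(theta)) stopifnot(theta > 0)
  if (!is.null(V_r)) {
    if (is.null(theta)) stop("`theta` is required when `V_r` is given")
    lx <- lambda_s * (1 - V_r / theta)
    if (!is.null(lambda_x) && abs(lambda_x - lx) > 1e-10 * lambda_s)
      stop("`lambda_x` conflicts with lambda_s * (1 - V_r/theta)")
    lambda_x <- lx
  }
  if (is.null(lambda_x))
    stop("either `lambda_x` or (`theta`, `V_r`) must be given")
  if (!(lambda_x > 0 && lambda_x <= lambda_s))
    stop("`lambda_x` must satisfy 0 < lambda_x <= lambda_s")
  if (is.null(gamma)) gamma <- theta
  structure(list(lambda_V = lambda_V, lambda_s = lambda_s,
                 lambda_x = lambda_x, a = lambda_s - lambda_x,
                 theta = theta, V_r = V_r, gamma = gamma, mu = mu,
                 sigma_eta = sigma_eta, dt = dt),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("CSN neuron parameters\n")
  cat(sprintf("  lambda_V = %g/s, lambda_s = %g/s, lambda_x = %g/s (a = %g/s)\n",
              x$lambda_V, x$lambda_s, x$lambda_x, x$a))
  if (!is.null(x$theta))
    cat(sprintf("  theta = %g, V_r = %s, gamma = %s\n", x$theta,
                if (is.null(x$V_r)) "-" else format(x$V_r),
                if (is.null(x$gamma)) "-" else format(x$gamma)))
  cat(sprintf("  mu = %g, sigma_eta = %g, dt = %g s\n", x$mu, x$sigma_eta, x$dt))
  invisible(x)
}

#' Sparse random recurrent coupling matrix
#'
#' Draws a `dim x dim` coupling matrix whose entries are independently zero
#' with probability `1 - p` and otherwise Gaussian with mean 0 and variance
#' `g^2 / (p * dim)`, which sets the spectral radius approximately to `g` for
#' large `dim`.
#'
#' @param dim matrix dimension (number of units).
#' @param p connection probability, `0 < p <= 1`.
#' @param g target spectral radius (1/s), `g >= 0`.
#' @param allow_autapses if `FALSE`, the diagonal is forced to zero.
#' @return A `dim x dim` numeric matrix.
#' @export
build_sparse_coupling <- function(dim, p, g, allow_autapses = TRUE) {
  stopifnot(dim >= 1, p > 0, p <= 1)
  if (!is.finite(g)) stop("`g` must be finite")
  if (g < 0) stop("`g` must be non-negative")
  if (p * dim^2 < 1)
    warning("p * dim^2 < 1: no connections expected")
  mask <- matrix(runif(dim * dim) < p, dim, dim)
  A <- matrix(0, dim, dim)
  nz <- sum(mask)
  if (nz > 0) A[mask] <- rnorm(nz, sd = g / sqrt(p * dim))
  if (!allow_autapses) diag(A) <- 0
  A
}

#' Random decoding matrix with equal column norms
#'
#' Entries are drawn from a standard normal distribution and each column is
#' rescaled to Euclidean norm `gamma_s * sqrt(J)`. Standard-normal columns of
#' length `J` have norm ~ `sqrt(J)`, so `gamma_s` plays the role of a
#' per-entry scale. Equal column norms give all neurons identical thresholds
#' and hence a uniform distribution of spiking across the population.
#'
#' @param J number of encoded variables (rows).
#' @param N number of neurons (columns).
#' @param gamma_s column-norm scale, `> 0`.
#' @return A `J x N` matrix whose columns all have norm `gamma_s * sqrt(J)`.
#' @export
build_decoding_matrix <- function(J, N, gamma_s) {
  stopifnot(J >= 1, N >= 1)
  if (!is.numeric(gamma_s) || gamma_s <= 0) stop("`gamma_s` must be positive")
  G <- matrix(rnorm(J * N), J, N)
  norms <- sqrt(colSums(G^2))
  norms[norms == 0] <- 1
  sweep(G, 2, norms, "/") * (gamma_s * sqrt(J))
}

#' Optimal couplings of a network with nonlinear dendrites
#'
#' Given a decoding matrix `Gamma` (J x N) and a slow recurrent coupling
#' matrix `A` (J x J) of the encoded J-dimensional dynamics, derives the
#' coupling set under which the spiking network encodes those dynamics:
#' dendrite-to-soma couplings `D = Gamma^T A`, shared axon-to-dendrite weights
#' `W = Gamma`, slow somatic couplings `Utilde = a Gamma^T Gamma +
#' mu lambda_s I`, fast somatic couplings `U = Gamma^T Gamma + mu I` (whose
#' diagonal incorporates the reset) and thresholds `theta_n = U_nn / 2`.
#'
#' @param Gamma decoding matrix, J x N.
#' @param A slow recurrent coupling matrix, J x J (1/s).
#' @param params a [neuron_params()] object supplying `a = lambda_s - lambda_x`,
#'   `mu` and `lambda_s`.
#' @return A list with elements `D`, `W`, `Utilde`, `U`, `theta_vec`.
#' @export
derive_dendritic_params <- function(Gamma, A, params) {
  J <- nrow(Gamma); N <- ncol(Gamma)
  if (!is.matrix(A) || nrow(A) != J || ncol(A) != J)
    stop("`A` must be a square matrix matching nrow(Gamma)")
  stopifnot(params$mu >= 0)
  GtG <- crossprod(Gamma)  # N x N
  U <- GtG + params$mu * diag(N)
  list(D = crossprod(Gamma, A),          # N x J
       W = Gamma,
       Utilde = params$a * GtG + params$mu * params$lambda_s * diag(N),
       U = U,
       theta_vec = diag(U) / 2)
}

#' Random input/feedback weights
#'
#' Draws a `rows x cols` matrix of i.i.d. uniform weights on
#' `[-w_tilde, w_tilde]`.
#'
#' @param rows,cols matrix dimensions.
#' @param w_tilde amplitude, `>= 0`.
#' @export
draw_io_weights <- function(rows, cols, w_tilde) {
  if (!is.numeric(w_tilde) || w_tilde < 0) stop("`w_tilde` must be >= 0")
  matrix(runif(rows * cols, -w_tilde, w_tilde), rows, cols)
}

#' Construct a CSN with saturating synapses
#'
#' Builds the static specification of a network of `N` leaky integrate-and-fire
#' neurons with saturating (tanh) synapses. Each neuron codes for one
#' continuous variable `x_n = V_n + theta * r_n`.
#'
#' @param N number of neurons.
#' @param params a [neuron_params()] object (needs `theta`, `V_r`, `gamma`).
#' @param g target spectral radius of the recurrent coupling matrix (1/s).
#' @param p connection probability of the coupling matrix.
#' @param allow_autapses passed to [build_sparse_coupling()].
#' @param A optional coupling matrix to use instead of a random draw.
#' @param w_in optional `N x K_in` input weight matrix.
#' @param w_fb optional `N x K_out` feedback weight matrix.
#' @param scheme default integration scheme, `"rk4"` or `"euler"`
#'   (Euler-Maruyama is used automatically when `sigma_eta > 0`).
#' @return An object of class `c("saturating_network", "network_spec")`.
#' @export
saturating_network <- function(N, params, g = 1.5, p = 0.1,
                               allow_autapses = TRUE, A = NULL,
                               w_in = NULL, w_fb = NULL, scheme = "rk4") {
  stopifnot(inherits(params, "neuron_params"), N >= 1)
  if (is.null(params$theta) || is.null(params$V_r))
    stop("saturating networks need `theta` and `V_r` in `params`")
  if (is.null(A)) A <- build_sparse_coupling(N, p, g, allow_autapses)
  structure(list(variant = "saturating", N = N, J = N, A = A,
                 params = params, g = g, p = p,
                 w_in = w_in, w_fb = w_fb, scheme = scheme),
            class = c("saturating_network", "network_spec"))
}

#' Construct a CSN with nonlinear dendrites
#'
#' Builds a network of `N` neurons with `J` nonlinear dendrites per neuron that
#' distributedly encodes `J` continuous variables `x ~ Gamma r`. The coupling
#' set (`D`, `W`, `Utilde`, `U`, thresholds) is derived from `Gamma` and `A`
#' with [derive_dendritic_params()].
#'
#' @param N number of neurons.
#' @param J number of dendrites / encoded variables.
#' @param params a [neuron_params()] object (needs `lambda_x`, `mu`).
#' @param gamma_s decoding-matrix column-norm scale.
#' @param g,p spectral radius and sparsity of the `J x J` coupling matrix.
#' @param bias_sd standard deviation of the Gaussian per-dendrite bias inside
#'   the nonlinearity (0 for none).
#' @param reset_mode `"derived"` (reset through the diagonal of the fast
#'   coupling matrix) or `"always_minus_theta"` (reset to `-theta` regardless
#'   of fast input received in the same step).
#' @param allow_autapses,A,Gamma optional overrides of the random draws.
#' @param w_in,w_fb optional `J x K` input/feedback weight matrices (inputs
#'   and feedback enter the somata through `Gamma^T`).
#' @param scheme default integration scheme.
#' @return An object of class `c("dendritic_network", "network_spec")`.
#' @export
dendritic_network <- function(N, J, params, gamma_s, g = 1.5, p = 0.1,
                              bias_sd = 0, reset_mode = c("derived", "always_minus_theta"),
                              allow_autapses = TRUE, A = NULL, Gamma = NULL,
                              w_in = NULL, w_fb = NULL, scheme = "rk4") {
  stopifnot(inherits(params, "neuron_params"), N >= 1, J >= 1)
  reset_mode <- match.arg(reset_mode)
  if (is.null(Gamma)) Gamma <- build_decoding_matrix(J, N, gamma_s)
  if (is.null(A)) A <- build_sparse_coupling(J, p, g, allow_autapses)
  derived <- derive_dendritic_params(Gamma, A, params)
  bias_b <- if (bias_sd > 0) rnorm(J, 0, bias_sd) else numeric(J)
  structure(list(variant = "dendritic", N = N, J = J, A = A, Gamma = Gamma,
                 D = derived$D, U = derived$U, Utilde = derived$Utilde,
                 theta_vec = derived$theta_vec, bias_b = bias_b,
                 params = params, g = g, p = p, gamma_s = gamma_s,
                 reset_mode = reset_mode,
                 w_in = w_in, w_fb = w_fb, scheme = scheme),
            class = c("dendritic_network", "network_spec"))
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("CSN with %s (%d neurons%s)\n",
              if (x$variant == "dendritic") "nonlinear dendrites" else "saturating synapses",
              x$N,
              if (x$variant == "dendritic") sprintf(", %d dendrites", x$J) else ""))
  cat(sprintf("  g = %g/s, p = %g\n", x$g, x$p))
  print(x$params)
  invisible(x)
}

#' Serialise a network specification to a directory
#'
#' Writes all matrices as plain-text CSV files plus a JSON manifest with the
#' scalar metadata, so a specification round-trips across sessions without
#' binary files.
#'
#' @param spec a `network_spec`.
#' @param dir target directory (created if needed).
#' @export
write_network_spec <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- c("A", "Gamma", "D", "U", "Utilde", "w_in", "w_fb")
  stored <- character(0)
  for (m in mats) {
    if (!is.null(spec[[m]])) {
      utils::write.table(spec[[m]], file.path(dir, paste0(m, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      stored <- c(stored, m)
    }
  }
  vecs <- c("theta_vec", "bias_b")
  for (v in vecs) {
    if (!is.null(spec[[v]])) {
      utils::write.table(matrix(spec[[v]], ncol = 1),
                         file.path(dir, paste0(v, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      stored <- c(stored, v)
    }
  }
  meta <- spec[setdiff(names(spec), c(mats, vecs))]
  meta$params <- unclass(meta$params)
  meta$.class <- class(spec)
  meta$.stored <- stored
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read back a network specification written by [write_network_spec()]
#' @param dir directory containing `manifest.json` and the matrix CSV files.
#' @export
read_network_spec <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  cls <- meta$.class
  stored <- meta$.stored
  meta$.class <- NULL
  meta$.stored <- NULL
  spec <- meta
  spec$params <- structure(
    lapply(meta$params, function(v) if (is.null(v)) NULL else v),
    class = "neuron_params")
  for (m in intersect(stored, c("A", "Gamma", "D", "U", "Utilde", "w_in", "w_fb")))
    spec[[m]] <- as.matrix(utils::read.table(file.path(dir, paste0(m, ".csv")),
                                             sep = ",", header = FALSE))
  for (v in intersect(stored, c("theta_vec", "bias_b")))
    spec[[v]] <- as.numeric(utils::read.table(file.path(dir, paste0(v, ".csv")),
                                              sep = ",", header = FALSE)[[1]])
  for (m in c("A", "Gamma", "D", "U", "Utilde", "w_in", "w_fb"))
    if (!is.null(spec[[m]])) dimnames(spec[[m]]) <- NULL
  structure(spec, class = cls)
}
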