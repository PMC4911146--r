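# Shared helpers for the test suite.

# Standard small dendritic configuration used across tests.
small_dendritic <- function(N = 100, J = 10, g = 1.5, dt = 1e-3,
                            lambda_x = 1, mu = 0, p = 1, ...) {
  par <- neuron_params(lambda_V = 10, lambda_s = 10, dt = dt,
                       lambda_x = lambda_x, mu = mu)
  dendritic_network(N, J, par, gamma_s = 0.03, g = g, p = p, ...)
}

small_saturating <- function(N = 50, g = 1.5, dt = 1e-3, p = 1, ...) {
  par <- neuron_params(lambda_V = 10, lambda_s = 10, dt = dt,
                       theta = 0.03, V_r = 0.9 * 0.03)
  saturating_network(N, par, g = g, p = p, ...)
}

# Expensive shared runs (used by several acceptance blocks) are computed once
# per session and cached in an environment.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}
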