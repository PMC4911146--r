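test_that("saturating neuron with zero couplings is a pure leak", {
  p <- neuron_params(lambda_V = 10, lambda_s = 10, dt = 1e-4,
                     theta = 0.03, V_r = 0)
  spec <- saturating_network(1, p, A = matrix(0, 1, 1))
  state <- list(V = 0.01, r = 0)
  for (k in 1:100) state <- step_saturating(state, spec)
  expect_equal(state$V, 0.01 * exp(-10 * 0.01), tolerance = 1e-8)
  expect_equal(state$r, 0)
})

test_that("zero initial state with zero input stays silent", {
  spec <- small_saturating(N = 10)
  tr <- run_network(spec, duration = 0.1)
  expect_equal(nrow(tr$spikes), 0L)
  expect_true(all(tr$V == 0))
})

test_that("threshold, reset, and r-jump follow the direct-coding rule", {
  # constant suprathreshold drive; V crosses theta/2, resets by -theta, r += 1
  p <- neuron_params(lambda_V = 10, lambda_s = 10, dt = 1e-4,
                     theta = 0.03, V_r = 0)
  spec <- saturating_network(1, p, A = matrix(0, 1, 1))
  spec$I_const <- 1  # strong drive
  tr <- run_network(spec, duration = 0.2)
  expect_gt(nrow(tr$spikes), 3)
  # r jumps by exactly +1 at spikes and decays exponentially between them
  tr2 <- run_network(spec, duration = 0.05, record_every = 1L, record_r = TRUE)
  r <- tr2$r_hist[1, ]
  jumps <- diff(r) - (exp(-10 * 1e-4) - 1) * r[-length(r)]
  spike_steps <- round(tr2$spikes$time / 1e-4)
  # jump between recorded columns j and j+1 corresponds to step j+1
  expect_equal(sort(which(jumps > 0.5)) + 1L, sort(spike_steps))
  expect_equal(jumps[jumps > 0.5], rep(1, length(spike_steps)),
               tolerance = 1e-9)
  expect_true(all(r >= 0))
})

test_that("steady firing rate matches the exact threshold-crossing oracle", {
  # single neuron, A = 0, V_r = 0: between spikes
  #   dV/dt = -lambda_V V + I, with reset V -> V - theta after crossing theta/2.
  # The exact cycle time solves V(t): from V0 = theta/2 - theta to theta/2.
  lambda_V <- 10; theta <- 0.03; I <- 1
  p <- neuron_params(lambda_V = lambda_V, lambda_s = 10, dt = 1e-5,
                     theta = theta, V_r = 0)
  spec <- saturating_network(1, p, A = matrix(0, 1, 1))
  spec$I_const <- I
  tr <- run_network(spec, duration = 1)
  rate_sim <- nrow(tr$spikes) / 1
  Vinf <- I / lambda_V
  T_exact <- log((Vinf - (theta / 2 - theta)) / (Vinf - theta / 2)) / lambda_V
  expect_equal(rate_sim, 1 / T_exact, tolerance = 0.02)
})

test_that("non-finite state raises an error naming the neuron", {
  spec <- small_saturating(N = 3)
  expect_error(run_network(spec, duration = 0.01,
                           init = list(V = c(0, NaN, 0), r = rep(0, 3))),
               "neuron 2")
})

test_that("dendritic leak with all couplings zero is exponential", {
  p <- neuron_params(lambda_V = 10, lambda_s = 10, dt = 1e-4, lambda_x = 1)
  spec <- dendritic_network(5, 2, p, gamma_s = 0.03,
                            A = matrix(0, 2, 2),
                            Gamma = matrix(0, 2, 5))
  spec$theta_vec <- rep(1, 5)  # keep thresholds away from zero
  spec$U <- diag(2, 5)
  v0 <- c(0.5, -0.2, 0.1, 0, 0.3)
  tr <- run_network(spec, duration = 0.05, init = list(V = v0, r = rep(0, 5)),
                    record_every = 1L, record_V = TRUE)
  expect_equal(tr$V, v0 * exp(-10 * 0.05), tolerance = 1e-8)
  expect_equal(nrow(tr$spikes), 0L)
})

test_that("sequential dendritic spike processing follows the greedy rule", {
  set.seed(10)
  # mu > 0 keeps the fast coupling diagonally dominant so the avalanche ends
  spec <- small_dendritic(N = 8, J = 3, mu = 0.01)
  # force two neurons far above threshold
  V <- spec$theta_vec + c(0.5, 0.3, rep(-0.01, 6)) * max(spec$theta_vec)
  st <- process_spikes_dendritic(list(V = V, r = rep(0, 8)), spec)
  expect_gte(length(st$spikes), 2)
  expect_equal(st$spikes[1], 1L)  # highest potential first
  # fast effect: V reduced by the U columns of the spikers, r incremented
  V_expect <- V
  r_expect <- rep(0, 8)
  for (n in st$spikes) {
    V_expect <- V_expect - spec$U[, n]
    r_expect[n] <- r_expect[n] + 1
  }
  expect_equal(st$V, V_expect, tolerance = 1e-12)
  expect_equal(st$r, r_expect)
  expect_true(all(st$V - spec$theta_vec <= 1e-12))
})

test_that("ties break at the lowest neuron index", {
  spec <- small_dendritic(N = 4, J = 2)
  spec$Gamma <- matrix(0, 2, 4)   # spikes have no cross effect
  spec$U <- diag(2 * spec$theta_vec)
  V <- rep(spec$theta_vec[1] * 1.5, 4)
  spec$theta_vec <- rep(spec$theta_vec[1], 4)
  st <- process_spikes_dendritic(list(V = V, r = rep(0, 4)), spec)
  expect_equal(st$spikes[1], 1L)
})

test_that("runaway excitation is capped with an error", {
  spec <- small_dendritic(N = 5, J = 2)
  spec$U <- matrix(0, 5, 5)
  diag(spec$U) <- -0.01  # spiking raises own potential: runaway
  expect_error(process_spikes_dendritic(
    list(V = spec$theta_vec + 1, r = rep(0, 5)), spec), "runaway")
})

test_that("always_minus_theta reset pins the spiker at -theta_n", {
  set.seed(11)
  spec <- small_dendritic(N = 6, J = 2, reset_mode = "always_minus_theta")
  V <- spec$theta_vec * 1.4
  st <- process_spikes_dendritic(list(V = V, r = rep(0, 6)), spec)
  n1 <- st$spikes[1]
  if (length(st$spikes) == 1) {
    expect_equal(st$V[n1], -spec$theta_vec[n1], tolerance = 1e-12)
  }
  expect_gte(length(st$spikes), 1)
})

test_that("Euler-Maruyama noise has the right magnitude", {
  # leak-only neuron driven by noise: stationary variance sigma^2/(2 lambda_V)
  p <- neuron_params(lambda_V = 10, lambda_s = 10, dt = 1e-3,
                     theta = 1e6, V_r = 0, sigma_eta = 0.5)
  spec <- saturating_network(1, p, A = matrix(0, 1, 1))
  set.seed(12)
  tr <- run_network(spec, duration = 200, record_every = 1L, record_V = TRUE)
  v <- tr$V_hist[1, tr$rec_times > 1]
  expect_equal(var(v), 0.5^2 / (2 * 10), tolerance = 0.1)
  expect_equal(nrow(tr$spikes), 0L)
})

test_that("requesting a deterministic scheme with noise errors", {
  p <- neuron_params(lambda_V = 10, lambda_s = 10, dt = 1e-3,
                     theta = 0.03, V_r = 0, sigma_eta = 0.1)
  spec <- saturating_network(10, p)
  expect_error(run_network(spec, duration = 0.01, scheme = "rk4"),
               "Euler-Maruyama")
})

test_that("spike log writes as tab-separated text", {
  spec <- small_saturating(N = 5)
  spec$I_const <- rep(1, 5)
  tr <- run_network(spec, duration = 0.1)
  f <- tempfile(fileext = ".tsv")
  write_spike_log(tr, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(tr$spikes))
  expect_named(back, c("time_s", "neuron_id"))
  unlink(f)
})

test_that("spike times lie on the grid and traces share lengths", {
  set.seed(13)
  spec <- small_dendritic(N = 50, J = 5)
  tr <- run_network(spec, duration = 0.5, init = list(r = runif(50)),
                    record_every = 2L, record_r = TRUE, record_V = TRUE)
  expect_equal(length(tr$time), 500L)
  expect_equal(ncol(tr$r_hist), length(tr$rec_times))
  expect_equal(ncol(tr$V_hist), length(tr$rec_times))
  if (nrow(tr$spikes) > 0) {
    on_grid <- abs(tr$spikes$time / 1e-3 - round(tr$spikes$time / 1e-3))
    expect_true(all(on_grid < 1e-9))
  }
})
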