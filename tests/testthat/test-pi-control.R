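test_that("control_config validates its window ordering", {
  cfg <- control_config(M = 10, horizon = 1, delta = 0.1, Delta = 0.01)
  expect_s3_class(cfg, "control_config")
  expect_error(control_config(horizon = 0.05, delta = 0.1))
  expect_error(control_config(delta = 0.005, Delta = 0.01))
  expect_error(control_config(M = 0))
})

test_that("path-integral weighting obeys its limiting cases", {
  xi_bar <- c(-1, 0, 2, 5)
  # equal rewards -> plain average of the noise
  expect_equal(path_integral_control(rep(3, 4), xi_bar, 0.1), mean(xi_bar))
  # zero inverse temperature ignores rewards
  expect_equal(path_integral_control(c(0, 10, -5, 2), xi_bar, 0),
               mean(xi_bar))
  # large inverse temperature picks the best rollout
  expect_equal(path_integral_control(c(0, 10, -5, 2), xi_bar, 1e4), 0)
  # log-sum-exp stabilisation survives huge rewards
  expect_true(is.finite(path_integral_control(c(1e6, 2e6), c(1, 2), 1)))
  # invalid rollouts are excluded
  expect_equal(path_integral_control(c(1, 100), c(7, 9), 1,
                                     ok = c(TRUE, FALSE)), 7)
  expect_error(path_integral_control(1, 1, 1, ok = FALSE), "no valid")
})

test_that("ground-truth rollouts report height rewards and initial noise", {
  set.seed(60)
  model <- pendulum_plant(dt = 1e-3)
  cfg <- control_config(M = 30, horizon = 0.5, delta = 0.1, Delta = 0.01)
  ex <- mental_explore(model, list(phi = 0, omega = 0), cfg)
  expect_length(ex$rewards, 30)
  expect_length(ex$xi_bar, 30)
  expect_true(all(ex$ok))
  # reward = integral of height; |y| <= 1 bounds it by the horizon
  expect_true(all(abs(ex$rewards) <= 0.5 + 1e-9))
  # hanging start: height stays near -1 over a short horizon
  expect_true(all(ex$rewards < -0.3))
  # noiseless exploration is deterministic and yields zero control
  cfg0 <- control_config(M = 5, horizon = 0.5, delta = 0.1, Delta = 0.01,
                         noise_density = 0)
  ex0 <- mental_explore(model, list(phi = 1, omega = 0), cfg0)
  expect_equal(ex0$rewards, rep(ex0$rewards[1], 5))
  expect_equal(path_integral_control(ex0$rewards, ex0$xi_bar, 0.01), 0)
})

test_that("exploration reward ranks states by height", {
  set.seed(61)
  model <- pendulum_plant(dt = 1e-3)
  cfg <- control_config(M = 20, horizon = 0.3, delta = 0.1, Delta = 0.01,
                        noise_density = 0.1)
  lo <- mental_explore(model, list(phi = 0, omega = 0), cfg)
  hi <- mental_explore(model, list(phi = pi, omega = 0), cfg)
  expect_gt(mean(hi$rewards), mean(lo$rewards) + 0.3)
})

test_that("closed-loop control on the true plant has the stated layout", {
  set.seed(62)
  model <- pendulum_plant(dt = 1e-3)
  cfg <- control_config(M = 20, horizon = 0.3, delta = 0.05, Delta = 0.05,
                        dt_rollout = 5e-3)
  loop <- control_loop(model, cfg, duration = 0.2)
  expect_length(loop$phi, 201)
  expect_length(loop$time, 201)
  expect_equal(nrow(loop$u), 4)
  expect_equal(loop$u$time, c(0, 0.05, 0.1, 0.15))
  expect_true(all(loop$ok_fraction == 1))
  expect_true(all(is.finite(loop$phi)))
})

test_that("world-model constructor validates its inputs", {
  spec <- small_dendritic(N = 20, J = 4)
  l <- readout_learner(4, k_out = 3)
  fb <- feedback_spec(matrix(0.1, 4, 3))
  expect_s3_class(pcsn_world_model(spec, l, fb), "forward_model")
  expect_error(pcsn_world_model(spec, l, fb, iy = 5))
  specs <- small_saturating(N = 10)
  expect_error(pcsn_world_model(specs, readout_learner(10, k_out = 3), fb))
})

test_that("network mental exploration returns finite rewards and state", {
  set.seed(63)
  spec <- small_dendritic(N = 40, J = 4)
  spec$w_in <- matrix(0.1, 4, 1)
  l <- readout_learner(4, k_out = 3)          # untrained: outputs are zero
  fb <- feedback_spec(matrix(0.1, 4, 3), mix = 0.9)
  model <- pcsn_world_model(spec, l, fb, washout = 0.05)
  model$state <- list(V = rep(0, 40), r = runif(40))
  cfg <- control_config(M = 8, horizon = 0.2, delta = 0.1, Delta = 0.01)
  ex <- mental_explore(model, list(phi = 0.3, omega = 0), cfg)
  expect_length(ex$rewards, 8)
  expect_true(all(is.finite(ex$rewards)))
  expect_equal(ex$rewards, rep(0, 8))         # zero readout -> zero height
  expect_true(all(ex$ok))
  expect_length(ex$net_state$V, 40)
})

test_that("a trained world model predicts short pendulum trajectories", {
  set.seed(64)
  par <- neuron_params(lambda_V = 10, lambda_s = 10, dt = 1e-3,
                       lambda_x = 10, mu = 20 / 100^2)
  spec <- dendritic_network(100, 30, par, gamma_s = 0.03, g = 1.5, p = 1,
                            bias_sd = 0.01)
  spec$w_in <- draw_io_weights(30, 1, 27)
  spec$w_fb <- cbind(draw_io_weights(30, 1, 100),
                     draw_io_weights(30, 1, 100),
                     draw_io_weights(30, 1, 20))
  l <- readout_learner(30, k_out = 3, alpha = 1)
  fb <- feedback_spec(spec$w_fb, mix = 0.9)
  fit <- train_world_model(spec, l, fb, Tt = 30)
  # the closed training loop tracks the plant: late in training the readout
  # error is well below the target scale ||F|| = sqrt(1 + omega^2) on the
  # same window (a zero-output model would sit at the target scale itself)
  err <- fit$trace$err$norm
  n <- length(fit$plant$omega)
  f_scale <- median(sqrt(1 + fit$plant$omega[(n %/% 3):n]^2))
  expect_lt(median(err[-(1:1000)]), 0.5 * f_scale)
  # mental rollouts from the trained model stay finite and bounded
  model <- pcsn_world_model(fit$spec, fit$learner, feedback_spec(spec$w_fb))
  model$state <- fit$state
  cfg <- control_config(M = 5, horizon = 0.3, delta = 0.1, Delta = 0.01)
  ex <- mental_explore(model,
                       list(phi = tail(fit$plant$phi, 1),
                            omega = tail(fit$plant$omega, 1)), cfg)
  expect_true(all(is.finite(ex$rewards)))
  expect_true(all(abs(ex$rewards) <= 0.3 * 3))  # |y-hat| stays order-1
})
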