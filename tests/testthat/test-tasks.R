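test_that("periodic targets match their definitions", {
  expect_equal(periodic_target("sine", pi), 2)
  expect_equal(periodic_target("sine", 0), 0)
  expect_equal(periodic_target("camel", 0), 1)
  expect_equal(periodic_target("camel", 2), sin(4) + cos(2))
  # sawtooth: period 2 s, peak-to-peak 10, rising ramp
  t <- runif(1000, 0, 50)
  expect_equal(periodic_target("sawtooth", t + 2),
               periodic_target("sawtooth", t), tolerance = 1e-9)
  expect_equal(periodic_target("sawtooth", 0), -5)
  expect_equal(periodic_target("sawtooth", 0.999999 * 2), 5, tolerance = 1e-4)
  expect_error(periodic_target("square", 1))
})

test_that("pattern_task samples targets at end-of-step times", {
  tk <- pattern_task("sine", 1, 0.1)
  expect_equal(tk$time, seq(0.1, 1, by = 0.1))
  expect_equal(tk$targets[1, ], 2 * sin(tk$time / 2))
  expect_null(tk$inputs)
})

test_that("Lorenz teacher has the right fixed points and scaling", {
  # algebraic fixed point of the unscaled field
  beta <- 8 / 3; rho <- 28
  fp <- c(sqrt(beta * (rho - 1)), sqrt(beta * (rho - 1)), rho - 1)
  field <- function(s) c(10 * (s[2] - s[1]),
                         s[1] * (rho - s[3]) - s[2],
                         s[1] * s[2] - beta * s[3])
  expect_equal(field(fp), c(0, 0, 0), tolerance = 1e-12)

  z <- lorenz_teacher(100, 0.01)
  expect_equal(dim(z), c(3, 10000))
  expect_lt(max(abs(z[3, ])), 5.5)          # scaled attractor bound
  expect_gt(sd(z[1, ]), 0.1)                # on the attractor, not collapsed
  # time unit: dominant z-oscillation period ~ 0.75 Lorenz units = 0.15 s
  mx <- local_maxima(z[3, ], 0.01)
  expect_equal(median(diff(mx)) * 0.01, 0.75 * 0.2, tolerance = 0.25)
})

test_that("delayed-reaction trials have the stated pulse shapes and gaps", {
  set.seed(40)
  tk <- delayed_reaction_trials(800, 9, dt = 1e-3)
  dt <- 1e-3
  # pulse integrals: input 10 s, response (count trials) 1 s each
  n_tr <- length(tk$params$onsets)
  expect_gte(n_tr, 4)  # "about 6 to 8 trials" in 800 s
  expect_lte(n_tr, 9)
  expect_equal(sum(tk$inputs) * dt, 10 * n_tr, tolerance = 1e-3)
  expect_equal(sum(tk$targets) * dt, 1 * n_tr, tolerance = 1e-3)
  # peaks delayed by 9 s
  expect_equal(tk$time[which.max(tk$targets[1, ])] -
                 tk$time[which.max(tk$inputs[1, ])], 9, tolerance = 0.05)
  # gaps at least the refractory time
  expect_true(all(diff(tk$params$onsets) >= 100))
  expect_error(delayed_reaction_trials(10, 9), "too short")
  expect_error(delayed_reaction_trials(500, 25), "delay")
})

test_that("delay 0 puts target peak at the input peak", {
  set.seed(41)
  tk <- delayed_reaction_trials(150, 0, dt = 1e-3)
  expect_equal(tk$time[which.max(tk$targets[1, ])],
               tk$time[which.max(tk$inputs[1, ])], tolerance = 0.05)
})

test_that("instruction signals obey normalisation, pulse cap, and targets", {
  set.seed(42)
  tk <- instruction_task_signals(1000, "train", dt = 0.01)
  f1 <- tk$inputs[1, ]; f2 <- tk$inputs[2, ]
  expect_lt(abs(mean(f1)), 0.02)
  expect_equal(sd(f1), 0.5, tolerance = 1e-6)   # exact normalisation
  expect_equal(mean(f2), 0, tolerance = 0.02)

  # pulse channels never exceed 1.01 (hard cap after the shift rule)
  expect_lte(max(tk$inputs[3, ]), 1.01 + 1e-9)
  expect_lte(max(tk$inputs[4, ]), 1.01 + 1e-9)

  Fm <- tk$targets[1, ]; Fc <- tk$targets[2, ]
  expect_true(all(abs(Fm) <= 1 + 1e-12))
  # where F_m is settled at +1: F_c ~ |f1-f2|; at -1: f1+f2.  F_m approaches
  # +-1 only asymptotically, so allow a residual of order (1 - |F_m|).
  up <- Fm > 1 - 1e-6
  dn <- Fm < -(1 - 1e-6)
  expect_lt(max(abs(Fc[up] - abs(f1 - f2)[up])), 1e-5)
  expect_lt(max(abs(Fc[dn] - (f1 + f2)[dn])), 1e-5)
  # memory matches the last pulse channel once settled
  p1 <- tk$params$pulses$ch1
  if (length(p1)) {
    i <- which.max(tk$time > p1[1] + 5)  # 5 s after a channel-1 pulse
    later2 <- any(tk$params$pulses$ch2 > p1[1] & tk$params$pulses$ch2 < p1[1] + 5)
    if (!later2 && length(p1)) expect_gt(Fm[i], 0.9)
  }
  # train/test modes change the pulse rate
  set.seed(43)
  n_train <- length(instruction_task_signals(2000, "train")$params$pulses$ch1)
  set.seed(43)
  n_test <- length(instruction_task_signals(2000, "test")$params$pulses$ch1)
  expect_gt(n_train, n_test)
})

test_that("pendulum equilibrium, frequency, and energy dissipation", {
  s <- list(phi = 0, omega = 0)
  expect_equal(pendulum_step(s, 0, 0, 1e-3), s)

  # small-amplitude frequency ~ sqrt(10), lightly damped
  sim <- simulate_pendulum(20, 1e-4, phi0 = 0.02, xi = 0)
  zc <- which(diff(sign(sim$phi)) != 0)
  period <- 2 * mean(diff(sim$time[zc]))
  expect_equal(2 * pi / period, sqrt(10), tolerance = 0.02)

  # energy non-increasing without forcing
  E <- sim$omega^2 / 2 - 10 * cos(sim$phi)
  expect_true(all(diff(E) < 1e-6))
})

test_that("pendulum noise has the stated spectral density", {
  set.seed(44)
  xi <- pendulum_noise(1e5, 1e-3, density = 1)
  expect_equal(var(xi) * 1e-3, 1, tolerance = 0.02)
})

test_that("task bundles serialize as text", {
  tk <- pattern_task("camel", 0.5, 0.01)
  f <- tempfile(fileext = ".tsv")
  write_task_signals(tk, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$target_1, tk$targets[1, ], tolerance = 1e-9)
  unlink(f)
})

test_that("generators are reproducible under a fixed seed", {
  set.seed(7); a <- delayed_reaction_trials(150, 5)
  set.seed(7); b <- delayed_reaction_trials(150, 5)
  expect_identical(a$inputs, b$inputs)
  set.seed(7); i1 <- instruction_task_signals(300, "train")
  set.seed(7); i2 <- instruction_task_signals(300, "train")
  expect_identical(i1$targets, i2$targets)
})
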