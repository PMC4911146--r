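test_that("learner initialisation follows the stated conventions", {
  l <- readout_learner(10, k_out = 2, alpha = 0.5)
  expect_true(all(l$w_o == 0))
  expect_equal(l$P, diag(10) / 0.5)
  expect_error(readout_learner(10, alpha = 0), "alpha")
})

test_that("activations match the two coding nonlinearities", {
  spec <- small_saturating(N = 4)
  r <- c(0, 0.1, 1, 100)
  expect_equal(activations(spec, r), tanh(spec$params$gamma * r))
  expect_equal(activations(spec, rep(0, 4)), rep(0, 4))
  expect_equal(activations(spec, c(0, 0, 0, 1e9)), c(0, 0, 0, 1))

  specd <- small_dendritic(N = 6, J = 2)
  specd$bias_b <- c(0.3, -0.2)
  r <- runif(6)
  expect_equal(activations(specd, r),
               tanh(specd$bias_b + as.numeric(specd$Gamma %*% r)))
})

test_that("readout is the linear map with shape checking", {
  w <- matrix(1:6 / 10, 2, 3)
  expect_equal(readout(w, c(0, 1, 0)), as.numeric(w[, 2]))
  expect_equal(readout(matrix(0, 1, 3), runif(3)), 0)
  expect_error(readout(w, 1:4), "mismatch")
})

test_that("scalar RLS recursion matches its closed form", {
  # rtilde = 1 every step, P(0) = 1/alpha -> P after k updates = 1/(alpha + k)
  alpha <- 0.1
  l <- readout_learner(1, alpha = alpha)
  for (k in 1:25) {
    l <- rls_update(l, 1, target = 2)
    expect_equal(l$P[1, 1], 1 / (alpha + k), tolerance = 1e-12)
  }
  # and the weight solves the regularised normal equation k/(alpha+k)*2
  expect_equal(l$w_o[1, 1], 25 * 2 / (0.1 + 25), tolerance = 1e-10)
})

test_that("zero error leaves weights fixed but still updates P", {
  l <- readout_learner(3)
  P0 <- l$P
  l2 <- rls_update(l, c(1, 0.5, -0.2), target = 0)  # z = 0 = target
  expect_equal(l2$w_o, l$w_o)
  expect_false(isTRUE(all.equal(l2$P, P0)))
  expect_equal(l2$P, t(l2$P))  # symmetrised
})

test_that("one RLS pass over a batch equals ridge regression", {
  set.seed(30)
  n <- 400; B <- 12
  X <- matrix(rnorm(n * B), n, B)
  y <- as.numeric(X %*% rnorm(B) + 0.1 * rnorm(n))
  alpha <- 0.1
  l <- readout_learner(B, alpha = alpha)
  for (i in seq_len(n)) l <- rls_update(l, X[i, ], y[i])
  w_ridge <- solve(crossprod(X) + alpha * diag(B), crossprod(X, y))
  expect_equal(as.numeric(l$w_o), as.numeric(w_ridge), tolerance = 1e-8)
})

test_that("feedback_spec validates the mixing coefficient", {
  expect_error(feedback_spec(matrix(1, 2, 1), mix = 1.5))
  fb <- feedback_spec(matrix(1, 2, 1), mix = 0.9)
  expect_equal(fb$mix, 0.9)
  expect_true(fb$explicit)
})

test_that("force_recurrent_update absorbs the feedback into the recurrence", {
  set.seed(31)
  spec <- small_dendritic(N = 10, J = 3)
  l <- readout_learner(3)
  rt <- rnorm(3); e <- 0.4
  fb <- feedback_spec(matrix(rnorm(3), 3, 1), explicit = FALSE)
  l <- rls_update(l, rt, target = 1)
  spec2 <- force_recurrent_update(spec, l, fb, rt, e)
  Pr <- as.numeric(l$P %*% rt)
  expect_equal(spec2$D - spec$D,
               -crossprod(spec$Gamma, fb$w_fb %*% e) %*% t(Pr),
               tolerance = 1e-12)
  specs <- small_saturating(N = 3)
  spec2s <- force_recurrent_update(specs, l, fb, rt, e)
  expect_equal(spec2s$A - specs$A, -(fb$w_fb * e) %*% t(Pr), tolerance = 1e-12)
})

test_that("explicit-feedback and absorbed-recurrence training are equivalent", {
  # The absorbed recurrent matrix is A0 + w_fb w_o(t), and the drive is linear
  # in it, so both formulations produce identical states and outputs at every
  # step when seeded identically.
  set.seed(32)
  n_steps <- 400L
  target <- matrix(2 * sin((1:n_steps) * 1e-3 / 2), 1)
  task <- list(time = (1:n_steps) * 1e-3, inputs = NULL, targets = target)

  build <- function() small_dendritic(N = 80, J = 8, g = 1.5)
  spec <- build()
  w_fb <- draw_io_weights(8, 1, 1)
  l0 <- readout_learner(8, alpha = 0.1)
  init <- list(r = runif(80))

  fit_abs <- train_csn(spec, task, l0,
                       feedback = feedback_spec(w_fb, explicit = FALSE),
                       learn = "force_rec", init = init)
  fit_exp <- train_csn(spec, task, l0,
                       feedback = feedback_spec(w_fb, explicit = TRUE),
                       learn = "rls", init = init)
  expect_equal(fit_abs$trace$z, fit_exp$trace$z, tolerance = 1e-8)
  expect_equal(fit_abs$state$V, fit_exp$state$V, tolerance = 1e-8)
  expect_equal(fit_abs$learner$w_o, fit_exp$learner$w_o, tolerance = 1e-8)
  # and the absorbed recurrence equals D0 + Gamma^T w_fb w_o
  expect_equal(fit_abs$spec$D,
               spec$D + crossprod(spec$Gamma, w_fb) %*% fit_abs$learner$w_o,
               tolerance = 1e-8)
})

test_that("training error norm decreases over a FORCE run", {
  set.seed(33)
  spec <- small_dendritic(N = 150, J = 15)
  spec$w_fb <- draw_io_weights(15, 1, 1)
  task <- pattern_task("sine", 30, 1e-3)
  l <- readout_learner(15, alpha = 0.1)
  fit <- train_csn(spec, task, l,
                   feedback = feedback_spec(spec$w_fb, explicit = FALSE),
                   learn = "force_rec", init = list(r = runif(150)))
  err <- fit$trace$err$norm
  early <- median(err[seq_len(200)])
  late <- median(err[seq.int(length(err) - 199, length(err))])
  expect_lt(late, early)
})

test_that("training requires targets and update interval on the grid", {
  spec <- small_dendritic(N = 10, J = 2)
  l <- readout_learner(2, delta_t_update = 0.0105)
  task <- pattern_task("sine", 0.1, 1e-3)
  expect_error(train_csn(spec, task, l), "integer multiple")
})
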