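test_that("recurrent initialization is seeded, bounded and well shaped", {
  cfg <- train_config(seed = 77)
  n1 <- init_rnn(2, 4, cfg)
  n2 <- init_rnn(2, 4, cfg)
  expect_identical(n1, n2)
  expect_equal(dim(n1$W), c(2L, 6L))
  expect_true(all(n1$W >= 0) && all(n1$W <= 0.05))
  expect_equal(n1$feedback, c(0, 0))
  expect_error(init_rnn(0, 1), "at least 1")
})

test_that("a step concatenates external input with delayed feedback", {
  cfg <- train_config(seed = 1)
  net <- init_rnn(1, 1, cfg)
  net$W[] <- 1
  s1 <- rnn_step(net, 0.5)
  expect_equal(s1$outputs, tanh(0.5))
  s2 <- rnn_step(s1$net, 0.5)
  expect_equal(s2$outputs, tanh(0.5 + tanh(0.5)))
  expect_equal(s2$u, c(0.5, s1$outputs))      # feedback slot holds y(n-1)
  # zero weights: output zero whatever the input
  net0 <- init_rnn(3, 2, cfg)
  net0$W[] <- 0
  expect_equal(rnn_step(net0, c(5, -3))$outputs, rep(0, 3))
  expect_error(rnn_step(net0, 1), "length")
})

test_that("rtrl recursion starts from the direct term and tracks resimulation", {
  net <- random_rnn(2, 2, seed = 11)
  pc <- 4
  sens <- array(0, dim = c(2, 2, pc))
  st <- rnn_step(net, c(0.4, -0.2))
  sens <- rtrl_step(net, sens, st$u, st$outputs)
  # first step: only the delta term, scaled by the slope
  slope <- net$gain * (1 - st$outputs^2)
  for (k in 1:2) {
    for (l in 1:pc) {
      expected <- numeric(2)
      expected[k] <- slope[k] * st$u[l]
      expect_equal(sens[, k, l], expected)
    }
  }
  # perturb-and-resimulate oracle over a short sequence
  set.seed(12)
  x_ext <- matrix(stats::rnorm(10, sd = 0.5), 5, 2)
  run_sens <- function(net) {
    sens <- array(0, dim = c(2, 2, pc))
    net$feedback <- c(0, 0)
    for (t in 1:5) {
      st <- rnn_step(net, x_ext[t, ])
      sens <- rtrl_step(net, sens, st$u, st$outputs)
      net <- st$net
    }
    sens
  }
  sens_T <- run_sens(net)
  h <- 1e-6
  for (k in 1:2) {
    for (l in 1:pc) {
      np <- net
      nm <- net
      np$W[k, l] <- np$W[k, l] + h
      nm$W[k, l] <- nm$W[k, l] - h
      fd <- (resimulate_y1(np, x_ext) - resimulate_y1(nm, x_ext)) / (2 * h)
      expect_equal(sens_T[1, k, l], fd, tolerance = 1e-5)
    }
  }
  # error derivative is the negated first-neuron slice
  expect_equal(rnn_error_derivative(sens_T), -sens_T[1, , ])
  expect_equal(rnn_error_derivative(array(0, dim = c(2, 2, 4))),
               matrix(0, 2, 4))
})

test_that("with zero feedback weights the sensitivities are static backprop", {
  net <- random_rnn(2, 3, seed = 13)
  net$W[, 4:5] <- 0                      # sever the recurrence
  set.seed(13)
  x_ext <- matrix(stats::rnorm(12, sd = 0.7), 4, 3)
  sens <- array(0, dim = c(2, 2, 5))
  for (t in 1:4) {
    st <- rnn_step(net, x_ext[t, ])
    sens <- rtrl_step(net, sens, st$u, st$outputs)
    net <- st$net
    # static single-layer derivative: dy_i/dW[i, l] = slope_i * u_l
    slope <- net$gain * (1 - st$outputs^2)
    for (i in 1:2) {
      for (l in 1:5) {
        expect_equal(sens[i, i, l], slope[i] * st$u[l])
        expect_equal(sens[i, 3 - i, l], 0)   # no cross terms without feedback
      }
    }
  }
})

test_that("the compiled epoch sweep reproduces step-by-step composition", {
  net <- random_rnn(3, 2, seed = 14)
  set.seed(14)
  x_ext <- matrix(stats::rnorm(14, sd = 0.5), 7, 2)
  sweep_out <- synitl:::rnn_sweep(net, x_ext, sensitivities = TRUE)
  sens <- array(0, dim = c(3, 3, 5))
  net_r <- net
  net_r$feedback <- rep(0, 3)
  for (t in 1:7) {
    st <- rnn_step(net_r, x_ext[t, ])
    sens <- rtrl_step(net_r, sens, st$u, st$outputs)
    net_r <- st$net
    expect_equal(sweep_out$outputs[t, ], st$outputs)
    expect_equal(sweep_out$net_input[t, ], st$net_input)
    expect_equal(matrix(sweep_out$s1[t, ], 3, 5), sens[1, , ])
  }
})

test_that("the accumulated MEE-RTRL weight gradient matches finite differences", {
  net <- random_rnn(2, 3, seed = 15, sd = 0.2)
  set.seed(15)
  n <- 10
  x_ext <- matrix(stats::rnorm(3 * n, sd = 0.5), n, 3)
  d <- stats::rnorm(n, sd = 0.5)
  sigma <- 0.3
  v_of <- function(net2) {
    out <- synitl:::rnn_sweep(net2, x_ext, sensitivities = FALSE)
    information_potential(d - out$outputs[, 1], sigma)
  }
  sweep_out <- synitl:::rnn_sweep(net, x_ext, sensitivities = TRUE)
  g <- potential_gradient(d - sweep_out$outputs[, 1], sigma)
  grad <- matrix(-drop(crossprod(sweep_out$s1, g)), 2, 5)
  h <- 1e-6
  for (k in 1:2) {
    for (l in 1:5) {
      np <- net
      nm <- net
      np$W[k, l] <- np$W[k, l] + h
      nm$W[k, l] <- nm$W[k, l] - h
      expect_equal(grad[k, l], (v_of(np) - v_of(nm)) / (2 * h),
                   tolerance = 1e-5)
    }
  }
})

test_that("recurrent training learns, is deterministic and degenerates without IP", {
  data <- mg_train_data()
  X <- data$train$inputs
  d <- data$train$targets
  cfg <- train_config(epochs = 60, ip_eta0 = 5e-4, seed = 16)
  net0 <- init_rnn(2, 4, cfg)
  fit1 <- train_rnn(net0, X, d, cfg, ip = TRUE)
  fit2 <- train_rnn(net0, X, d, cfg, ip = TRUE)
  expect_identical(fit1$curves, fit2$curves)
  expect_lt(fit1$curves$mse[60], fit1$curves$mse[1])
  cfg0 <- cfg
  cfg0$ip_eta0 <- 0
  fit_no <- train_rnn(net0, X, d, cfg, ip = FALSE)
  fit_zero <- train_rnn(net0, X, d, cfg0, ip = TRUE)
  expect_identical(fit_no$curves, fit_zero$curves)
  expect_equal(fit_no$net$W, fit_zero$net$W)
  # shift invariance of the entropy trajectory
  fit_shift <- train_rnn(net0, X, d + 0.4, cfg, ip = FALSE)
  expect_equal(fit_no$curves$V, fit_shift$curves$V)
  expect_equal(fit_no$net$W, fit_shift$net$W)
})

test_that("recurrent evaluation reports corrected MSE and V", {
  net <- random_rnn(2, 4, seed = 17)
  data <- mg_train_data()
  X <- data$train$inputs[1:50, ]
  d <- data$train$targets[1:50]
  out <- synitl:::rnn_sweep(net, X, sensitivities = FALSE)
  net <- bias_correct(net, d, out$outputs[, 1])
  ev <- evaluate_rnn(net, X, d)
  e <- d - out$outputs[, 1] - net$bias_correction
  expect_equal(ev$mse, mean(e^2))
  expect_equal(mean(e), 0, tolerance = 1e-14)
})
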