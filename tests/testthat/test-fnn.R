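test_that("feedforward initialization is seeded, bounded and well shaped", {
  cfg <- train_config(seed = 99)
  n1 <- init_fnn(5, 4, cfg)
  n2 <- init_fnn(5, 4, cfg)
  expect_identical(n1, n2)
  expect_equal(dim(n1$W1), c(5L, 4L))
  expect_length(n1$W2, 5)
  expect_true(all(c(n1$W1, n1$W2) >= 0) && all(c(n1$W1, n1$W2) <= 0.05))
  expect_equal(n1$gain_h, rep(1, 5))
  expect_equal(n1$bias_correction, 0)
  expect_error(init_fnn(0, 4), "at least 1")
})

test_that("forward pass composes the two tanh layers", {
  cfg <- train_config(seed = 1)
  net <- init_fnn(1, 1, cfg)
  net$W1[] <- 1
  net$W2[] <- 1
  fwd <- fnn_forward(net, 0.5)
  expect_equal(fwd$y, tanh(tanh(0.5)))
  # zero weights produce zero output
  net0 <- init_fnn(3, 2, cfg)
  net0$W1[] <- 0
  net0$W2[] <- 0
  expect_equal(fnn_forward(net0, c(1, -1))$y, 0)
  # hidden outputs bounded
  net <- random_fnn(4, 3, seed = 2)
  fwd <- fnn_forward(net, matrix(stats::rnorm(30), 10, 3))
  expect_true(all(abs(fwd$hidden) < 1))
  expect_error(fnn_forward(net, c(1, 2)), "columns")
})

test_that("single-sample error derivatives match finite differences", {
  net <- random_fnn(3, 2, seed = 3)
  x <- c(0.7, -0.4)
  d <- 0.3
  gr <- fnn_error_derivatives(net, x)
  err_of <- function(w1, w2) {
    n2 <- net
    n2$W1 <- w1
    n2$W2 <- w2
    d - fnn_forward(n2, x)$y
  }
  h <- 1e-6
  for (j in 1:3) {
    w2p <- net$W2
    w2m <- net$W2
    w2p[j] <- w2p[j] + h
    w2m[j] <- w2m[j] - h
    fd <- (err_of(net$W1, w2p) - err_of(net$W1, w2m)) / (2 * h)
    expect_equal(gr$dW2[j], fd, tolerance = 1e-6)
    for (l in 1:2) {
      w1p <- net$W1
      w1m <- net$W1
      w1p[j, l] <- w1p[j, l] + h
      w1m[j, l] <- w1m[j, l] - h
      fd <- (err_of(w1p, net$W2) - err_of(w1m, net$W2)) / (2 * h)
      expect_equal(gr$dW1[j, l], fd, tolerance = 1e-6)
    }
  }
  # zero input kills every hidden-layer derivative
  gr0 <- fnn_error_derivatives(net, c(0, 0))
  expect_equal(gr0$dW1, matrix(0, 3, 2))
  # near the linear point the output-layer derivative scales with the gain
  lin <- random_fnn(3, 2, seed = 4)
  lin$W1 <- lin$W1 * 1e-4
  lin$W2 <- lin$W2 * 1e-4
  lin$bias_h <- rep(0, 3)
  lin$bias_o <- 0
  g1 <- fnn_error_derivatives(lin, x)$dW2
  lin2 <- lin
  lin2$gain_o <- 2 * lin$gain_o
  g2 <- fnn_error_derivatives(lin2, x)$dW2
  expect_equal(g2 / g1, rep(2, 3), tolerance = 1e-4)
})

test_that("epochwise MEE update ascends the information potential", {
  set.seed(51)
  net <- random_fnn(3, 2, seed = 5)
  X <- matrix(stats::rnorm(40), 20, 2)
  d <- stats::rnorm(20, sd = 0.5)
  sigma <- 0.3
  v_of <- function(n2) {
    information_potential(d - fnn_forward(n2, X)$y, sigma)
  }
  # assembled weight gradient matches finite differences of V
  eta <- 1e-7
  up <- fnn_mee_update(net, X, d, sigma, eta)
  gW1 <- (up$W1 - net$W1) / eta
  gW2 <- (up$W2 - net$W2) / eta
  h <- 1e-6
  for (j in 1:3) {
    n2 <- net
    n2$W2[j] <- n2$W2[j] + h
    n3 <- net
    n3$W2[j] <- n3$W2[j] - h
    expect_equal(gW2[j], (v_of(n2) - v_of(n3)) / (2 * h), tolerance = 1e-5)
    for (l in 1:2) {
      n2 <- net
      n2$W1[j, l] <- n2$W1[j, l] + h
      n3 <- net
      n3$W1[j, l] <- n3$W1[j, l] - h
      expect_equal(gW1[j, l], (v_of(n2) - v_of(n3)) / (2 * h),
                   tolerance = 1e-5)
    }
  }
  # a small step does not decrease V
  up2 <- fnn_mee_update(net, X, d, sigma, eta = 1e-4)
  expect_gte(v_of(up2), v_of(net))
  # identical errors give a zero gradient, hence no weight change
  d_flat <- fnn_forward(net, X)$y + 0.37
  up3 <- fnn_mee_update(net, X, d_flat, sigma, eta = 0.1)
  expect_equal(up3$W1, net$W1)
  expect_equal(up3$W2, net$W2)
})

test_that("bias correction cancels the mean error without touching V", {
  net <- random_fnn(3, 2, seed = 6)
  X <- matrix(stats::rnorm(30), 15, 2)
  d <- stats::rnorm(15)
  y_raw <- fnn_forward(net, X)$y_raw
  net2 <- bias_correct(net, d, y_raw)
  e2 <- d - fnn_forward(net2, X)$y
  expect_equal(mean(e2), 0, tolerance = 1e-14)
  expect_equal(information_potential(e2, 0.1),
               information_potential(d - y_raw, 0.1))
  # constant error: correction recovers it exactly and MSE drops to zero
  d_const <- y_raw + 0.25
  net3 <- bias_correct(net, d_const, y_raw)
  expect_equal(net3$bias_correction, 0.25)
  expect_equal(evaluate_fnn(net3, X, d_const)$mse, 0, tolerance = 1e-28)
})

test_that("evaluation reports MSE and V of the corrected errors", {
  net <- random_fnn(3, 2, seed = 7)
  X <- matrix(stats::rnorm(30), 15, 2)
  d <- fnn_forward(net, X)$y          # perfect targets
  ev <- evaluate_fnn(net, X, d, sigma = 0.1)
  expect_equal(ev$mse, 0)
  expect_equal(ev$V, 1 / (2 * 0.1 * sqrt(pi)))
  d2 <- stats::rnorm(15)
  ev_a <- evaluate_fnn(net, X, d2)
  perm <- sample(15)
  ev_b <- evaluate_fnn(net, X[perm, ], d2[perm])
  expect_equal(ev_a$mse, ev_b$mse)
  expect_identical(evaluate_fnn(net, X, d2), evaluate_fnn(net, X, d2))
})

test_that("training learns, is seed-deterministic and degenerates without IP", {
  data <- mg_train_data()
  X <- data$train$inputs
  d <- data$train$targets
  cfg <- train_config(epochs = 60, seed = 8)
  net0 <- init_fnn(5, 4, cfg)
  fit1 <- train_fnn(net0, X, d, cfg, ip = TRUE)
  fit2 <- train_fnn(net0, X, d, cfg, ip = TRUE)
  expect_identical(fit1$curves, fit2$curves)     # bit-identical by seed
  expect_lt(fit1$curves$mse[60], fit1$curves$mse[1])
  # disabling IP equals running IP with a zero rate, bit for bit
  fit_no <- train_fnn(net0, X, d, cfg, ip = FALSE)
  cfg0 <- cfg
  cfg0$ip_eta0 <- 0
  fit_zero <- train_fnn(net0, X, d, cfg0, ip = TRUE)
  expect_identical(fit_no$curves, fit_zero$curves)
  expect_equal(fit_no$net$W1, fit_zero$net$W1)
  # without IP the gains never move
  expect_equal(fit_no$net$gain_h, rep(1, 5))
})

test_that("constant target shifts leave the entropy trajectory untouched", {
  data <- mg_train_data()
  X <- data$train$inputs
  d <- data$train$targets
  cfg <- train_config(epochs = 40, seed = 9)
  net0 <- init_fnn(4, 4, cfg)
  fit_a <- train_fnn(net0, X, d, cfg, ip = FALSE)
  fit_b <- train_fnn(net0, X, d + 0.3, cfg, ip = FALSE)
  expect_equal(fit_a$curves$V, fit_b$curves$V)
  expect_equal(fit_a$net$W1, fit_b$net$W1)
  expect_equal(fit_b$net$bias_correction - fit_a$net$bias_correction, 0.3,
               tolerance = 1e-12)
})
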