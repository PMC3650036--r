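# Shared fixtures and independent oracles for the test suite.

# naive two-loop information potential (independent of the vectorized path)
naive_potential <- function(e, sigma) {
  n <- length(e)
  s <- sigma * sqrt(2)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + exp(-(e[j] - e[i])^2 / (2 * s^2)) / (s * sqrt(2 * pi))
    }
  }
  acc / n^2
}

# central finite difference of f at x, component-wise
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x
    xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# random small feedforward net with generic (non-default) activation state
random_fnn <- function(m, k, seed) {
  set.seed(seed)
  net <- init_fnn(m, k, train_config())
  net$W1 <- matrix(stats::rnorm(m * k, sd = 0.5), m, k)
  net$W2 <- stats::rnorm(m, sd = 0.5)
  net$gain_h <- stats::runif(m, 0.5, 2)
  net$bias_h <- stats::rnorm(m, sd = 0.3)
  net$gain_o <- stats::runif(1, 0.5, 2)
  net$bias_o <- stats::rnorm(1, sd = 0.3)
  net
}

random_rnn <- function(n_neurons, p, seed, sd = 0.3) {
  set.seed(seed)
  net <- init_rnn(n_neurons, p, train_config())
  net$W <- matrix(stats::rnorm(n_neurons * (p + n_neurons), sd = sd),
                  n_neurons, p + n_neurons)
  net$gain <- stats::runif(n_neurons, 0.5, 1.5)
  net$bias <- stats::rnorm(n_neurons, sd = 0.2)
  net
}

# rerun an rnn forward pass from zero state, returning y_1(t_final); used as
# the perturb-and-resimulate oracle for the RTRL sensitivities
resimulate_y1 <- function(net, x_ext) {
  net$feedback <- rep(0, net$n_neurons)
  out <- NULL
  for (t in seq_len(nrow(x_ext))) {
    st <- rnn_step(net, x_ext[t, ])
    net <- st$net
    out <- st$outputs
  }
  out[1]
}

# small cached Mackey-Glass training set shared across tests
mg_train_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_benchmark_split(n_train = 300, n_test = 200, seed = 1)
    }
    cache
  }
})
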