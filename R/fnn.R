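#' Initialize a single-hidden-layer feedforward network
#'
#' Builds an `m`-hidden-neuron, `k`-input, single-output feedforward network
#' with adaptive tanh activations. All synaptic weights are drawn i.i.d.
#' uniform on `[config$init_low, config$init_high]` (default [0, 0.05], i.e.
#' small positive values) from the seeded RNG; every activation starts at
#' gain 1, bias 0, and the output bias correction starts at 0.
#'
#' @param m Number of hidden neurons (>= 1).
#' @param k Number of external inputs (>= 1).
#' @param config A [train_config()]; supplies the init bounds and optional
#'   seed.
#' @return An object of class `"fnn"`: list with `W1` (m x k hidden weight
#'   matrix), `W2` (length-m output weight vector), hidden and output
#'   activation parameters, and `bias_correction`.
#' @export
init_fnn <- function(m, k, config = train_config()) {
  if (m < 1L || k < 1L) stop("`m` and `k` must be at least 1", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  structure(list(
    W1 = matrix(stats::runif(m * k, config$init_low, config$init_high), m, k),
    W2 = stats::runif(m, config$init_low, config$init_high),
    gain_h = rep(1, m), bias_h = rep(0, m),
    gain_o = 1, bias_o = 0,
    bias_correction = 0,
    m = as.integer(m), k = as.integer(k)
  ), class = "fnn")
}

#' @export
print.fnn <- function(x, ...) {
  cat(sprintf("Feedforward network: %d inputs -> %d hidden -> 1 output\n",
              x$k, x$m))
  cat(sprintf("  hidden gains: %s\n",
              paste(signif(x$gain_h, 4), collapse = " ")))
  cat(sprintf("  output gain: %s, bias correction: %s\n",
              signif(x$gain_o, 4), signif(x$bias_correction, 4)))
  invisible(x)
}

#' Forward pass of the feedforward network
#'
#' Hidden neuron j receives the weighted sum `net_j = sum_k W1[j,k] x_k` and
#' emits `tanh(gain_j * net_j + bias_j)`; the output neuron receives the
#' weighted sum of hidden outputs and emits the tanh of its own affine map,
#' plus the post-training additive bias correction. All per-layer
#' pre-activations are returned because both learning stages (synaptic and
#' intrinsic) consume them.
#'
#' @param net An `"fnn"` object.
#' @param x Input: length-`k` vector or N x k matrix of samples in rows.
#' @return A list with `net_h` (N x m hidden pre-activations), `hidden`
#'   (N x m hidden outputs), `net_o` (length-N output pre-activation),
#'   `y_raw` (length-N output before bias correction), and `y` (final
#'   prediction).
#' @export
fnn_forward <- function(net, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != net$k) {
    stop("input must have ", net$k, " columns", call. = FALSE)
  }
  net_h <- x %*% t(net$W1)
  hidden <- activate(net_h, net$gain_h, net$bias_h)
  net_o <- drop(hidden %*% net$W2)
  y_raw <- activate(net_o, net$gain_o, net$bias_o)
  list(net_h = net_h, hidden = hidden, net_o = net_o, y_raw = y_raw,
       y = y_raw + net$bias_correction)
}

#' Error derivatives of the feedforward network for one sample
#'
#' Exact partial derivatives `de/dw = -dy/dw` of the single-sample error
#' `e = d - y` with respect to both weight layers, by backpropagation through
#' the adaptive activations (each layer contributes its slope
#' `gain * (1 - y^2)`):
#' output layer `de/dW2[j] = -gain_o (1 - y_raw^2) * hidden_j`; hidden layer
#' `de/dW1[j,k] = -gain_o (1 - y_raw^2) * W2[j] * gain_j (1 - hidden_j^2) * x_k`.
#'
#' @param net An `"fnn"` object.
#' @param x Length-`k` input vector.
#' @param fwd Cached [fnn_forward()] result for this `x` (recomputed if
#'   omitted).
#' @return List with `dW2` (length m) and `dW1` (m x k matrix).
#' @export
fnn_error_derivatives <- function(net, x, fwd = fnn_forward(net, x)) {
  hidden <- drop(fwd$hidden)
  slope_o <- net$gain_o * (1 - fwd$y_raw^2)
  slope_h <- net$gain_h * (1 - hidden^2)
  list(dW2 = -slope_o * hidden,
       dW1 = -slope_o * (net$W2 * slope_h) %o% as.numeric(x))
}

#' One epochwise MEE weight update of the feedforward network
#'
#' Computes the errors over the whole training batch, chains the gradient of
#' the quadratic information potential with respect to the errors with the
#' per-sample error-weight derivatives, and takes one steepest-ascent step
#' `w <- w + eta * dV/dw` on both layers simultaneously (both gradients are
#' evaluated at the same pre-update network state). Activation parameters are
#' untouched; the intrinsic stage is separate.
#'
#' @param net An `"fnn"` object.
#' @param inputs N x k input matrix (N >= 2).
#' @param targets Length-N desired outputs.
#' @param sigma Parzen kernel bandwidth.
#' @param eta Synaptic learning rate for this step.
#' @param fwd Optional cached [fnn_forward()] result for `inputs`.
#' @return The updated `"fnn"` object.
#' @export
fnn_mee_update <- function(net, inputs, targets, sigma, eta,
                           fwd = fnn_forward(net, inputs)) {
  e <- targets - fwd$y
  g <- potential_gradient(e, sigma)
  fnn_apply_mee(net, inputs, fwd, g, eta)
}

# shared ascent step given dV/de (g); used by fnn_mee_update and train_fnn
fnn_apply_mee <- function(net, inputs, fwd, g, eta) {
  delta <- g * net$gain_o * (1 - fwd$y_raw^2)        # dV/de * output slope
  gW2 <- -drop(crossprod(fwd$hidden, delta))
  slope_h <- sweep(1 - fwd$hidden^2, 2L, net$gain_h, "*")
  b <- sweep(delta * slope_h, 2L, net$W2, "*")       # N x m backprop factor
  gW1 <- -crossprod(b, inputs)
  net$W2 <- net$W2 + eta * gW2
  net$W1 <- net$W1 + eta * gW1
  net
}

#' Train a feedforward network by synergistic MEE + intrinsic plasticity
#'
#' Epochwise training loop. Each epoch performs one forward sweep over all
#' training samples (cached), then the synaptic stage (steepest ascent on the
#' quadratic information potential of the errors, rate
#' `mee_eta0 * mee_gamma^(epoch-1)`), then the intrinsic stage (batch infomax
#' update of every neuron's gain and bias, hidden layer and output neuron,
#' rate `ip_eta0 * ip_gamma^(epoch-1)`), both consuming the quantities cached
#' by that epoch's sweep. With `ip = FALSE` the intrinsic stage is skipped
#' entirely and the trajectory is the pure MEE one. After the last epoch the
#' output bias correction is set to cancel the mean training error (entropy
#' is blind to the error mean, so the raw trained output needs this shift).
#'
#' Per-epoch learning curves record the information potential `V` of that
#' epoch's (pre-update) errors and the mean-cancelled MSE (the MSE after
#' removing the epoch's mean error), the reporting convention used for
#' entropy-trained networks.
#'
#' @param net An `"fnn"` object (see [init_fnn()]).
#' @param inputs N x k training input matrix.
#' @param targets Length-N training targets.
#' @param config A [train_config()].
#' @param ip Logical: apply the intrinsic-plasticity stage?
#' @return An object of class `"itl_fit"`: list with the trained `net`,
#'   `curves` (data.frame epoch/V/mse/mean_gain), and `diagnostics` holding
#'   the cached per-neuron samples of the first and last epoch (for
#'   distribution reports).
#' @export
train_fnn <- function(net, inputs, targets, config = train_config(),
                      ip = TRUE) {
  stopifnot(inherits(net, "fnn"))
  n <- nrow(inputs)
  if (is.null(n) || n < 2L || length(targets) != n) {
    stop("need an N x k input matrix and matching targets, N >= 2",
         call. = FALSE)
  }
  epochs <- config$epochs
  curve_v <- curve_mse <- curve_gain <- numeric(epochs)
  diagnostics <- list()
  for (epoch in seq_len(epochs)) {
    fwd <- fnn_forward(net, inputs)
    e <- targets - fwd$y
    if (!all(is.finite(e))) {
      stop(sprintf("training diverged at epoch %d (non-finite errors)",
                   epoch), call. = FALSE)
    }
    pg <- potential_and_gradient(e, config$sigma)
    curve_v[epoch] <- pg$V
    curve_mse[epoch] <- mean((e - mean(e))^2)
    curve_gain[epoch] <- mean(c(net$gain_h, net$gain_o))
    if (epoch == 1L) diagnostics$initial <- fnn_diag(fwd, e)
    # synaptic stage
    eta_w <- config$mee_eta0 * config$mee_gamma^(epoch - 1)
    net <- fnn_apply_mee(net, inputs, fwd, pg$grad, eta_w)
    # intrinsic stage (same cached sweep)
    if (ip) {
      eta_ip <- config$ip_eta0 * config$ip_gamma^(epoch - 1)
      up_h <- ip_update(fwd$net_h, fwd$hidden, net$gain_h, net$bias_h, eta_ip)
      net$gain_h <- up_h$gain
      net$bias_h <- up_h$bias
      up_o <- ip_update(fwd$net_o, fwd$y_raw, net$gain_o, net$bias_o, eta_ip)
      net$gain_o <- up_o$gain
      net$bias_o <- up_o$bias
    }
  }
  fwd <- fnn_forward(net, inputs)
  net <- bias_correct(net, targets, fwd$y_raw)
  diagnostics$final <- fnn_diag(fwd, targets - fwd$y_raw - net$bias_correction)
  structure(list(net = net,
                 curves = data.frame(epoch = seq_len(epochs), V = curve_v,
                                     mse = curve_mse,
                                     mean_gain = curve_gain),
                 diagnostics = diagnostics,
                 config = config, ip = ip, model = "fnn"),
            class = "itl_fit")
}

fnn_diag <- function(fwd, e) {
  list(hidden_input = fwd$net_h, hidden_output = fwd$hidden,
       output_input = fwd$net_o, output = fwd$y_raw, error = e)
}

#' Set the output bias correction from training errors
#'
#' Entropy-based training converges to weights whose errors need not have
#' zero mean; the standard remedy is an additive constant on the final
#' output that cancels the mean error over the training set. This function
#' sets `bias_correction = mean(targets - y_raw)`; after correction the mean
#' training error is zero to machine precision, while the information
#' potential of the errors is unchanged (it is shift-invariant).
#'
#' @param net An `"fnn"` or `"rnn"` object.
#' @param targets Training targets.
#' @param y_raw Uncorrected network outputs on the training set.
#' @return The network with `bias_correction` set.
#' @export
bias_correct <- function(net, targets, y_raw) {
  net$bias_correction <- mean(targets - y_raw)
  net
}

#' Evaluate a trained feedforward network
#'
#' Runs the forward pass (including the output bias correction) and reports
#' the mean squared error and the quadratic information potential of the
#' errors.
#'
#' @param net An `"fnn"` object (bias correction applied for MSE reporting).
#' @param inputs N x k input matrix.
#' @param targets Length-N targets.
#' @param sigma Parzen kernel bandwidth for the potential.
#' @return List with `mse` and `V`.
#' @export
evaluate_fnn <- function(net, inputs, targets, sigma = 0.1) {
  e <- targets - fnn_forward(net, inputs)$y
  list(mse = mean(e^2), V = information_potential(e, sigma))
}
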