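#' Initialize a fully recurrent network
#'
#' Builds a single-layer fully recurrent network of `n_neurons` adaptive
#' tanh neurons. Each neuron receives the `p` external inputs plus the
#' one-step-delayed outputs of all neurons, so the weight matrix `W` is
#' `n_neurons x (p + n_neurons)` (external columns first, feedback columns
#' last). There is no constant-bias input column; the activation bias
#' supplies the affine degree of freedom. Weights are drawn uniform on
#' `[init_low, init_high]` (default [0, 0.05]); activations start at gain 1,
#' bias 0; the feedback state starts at zero. The network prediction is the
#' output of the first neuron.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param p Number of external inputs (>= 1).
#' @param config A [train_config()].
#' @return An object of class `"rnn"`.
#' @export
init_rnn <- function(n_neurons, p, config = train_config()) {
  if (n_neurons < 1L || p < 1L) {
    stop("`n_neurons` and `p` must be at least 1", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  structure(list(
    W = matrix(stats::runif(n_neurons * (p + n_neurons), config$init_low,
                            config$init_high), n_neurons, p + n_neurons),
    gain = rep(1, n_neurons), bias = rep(0, n_neurons),
    feedback = rep(0, n_neurons),
    bias_correction = 0,
    n_neurons = as.integer(n_neurons), p = as.integer(p)
  ), class = "rnn")
}

#' @export
print.rnn <- function(x, ...) {
  cat(sprintf(
    "Fully recurrent network: %d neurons, %d external inputs (+%d feedback)\n",
    x$n_neurons, x$p, x$n_neurons))
  cat(sprintf("  gains: %s, bias correction: %s\n",
              paste(signif(x$gain, 4), collapse = " "),
              signif(x$bias_correction, 4)))
  invisible(x)
}

#' One time step of the recurrent network
#'
#' Forms the input `u(n) = [x_ext(n), y(n-1)]` from the external signal and
#' the stored one-step-delayed outputs, computes each neuron's output
#' `y_i(n) = tanh(gain_i * (W u(n))_i + bias_i)`, and advances the feedback
#' state. The network prediction at step `n` is the first neuron's output.
#'
#' @param net An `"rnn"` object.
#' @param x_ext Length-`p` external input vector.
#' @return List with `u` (the assembled input), `net_input` (per-neuron
#'   weighted sums), `outputs` (per-neuron outputs), and `net` (the network
#'   with updated feedback state).
#' @export
rnn_step <- function(net, x_ext) {
  if (length(x_ext) != net$p) {
    stop("external input must have length ", net$p, call. = FALSE)
  }
  u <- c(as.numeric(x_ext), net$feedback)
  net_input <- drop(net$W %*% u)
  outputs <- activate(net_input, net$gain, net$bias)
  net$feedback <- outputs
  list(u = u, net_input = net_input, outputs = outputs, net = net)
}

#' One RTRL recursion step
#'
#' Advances the sensitivity tensor `P[i, k, l] = dy_i(n)/dW[k, l]` from time
#' `n-1` to `n`:
#' \deqn{P_i(n) = gain_i (1 - y_i(n)^2) (\delta_{ik} u_l(n) +
#'   \sum_j W[i, p+j] P_j(n-1)),}
#' where the Kronecker delta contributes the direct term for the neuron that
#' owns weight `(k, l)` and the sum propagates through the feedback
#' connections. The initial tensor is all zeros (sensitivities reset at
#' sequence start).
#'
#' @param net An `"rnn"` object.
#' @param sens Sensitivity array of dimension
#'   `n_neurons x n_neurons x (p + n_neurons)` holding time `n-1` values.
#' @param u The assembled input vector `u(n)` of the current step.
#' @param outputs The outputs `y(n)` of the current step.
#' @return The updated sensitivity array for time `n`.
#' @export
rtrl_step <- function(net, sens, u, outputs) {
  nr <- net$n_neurons
  pc <- net$p + nr
  if (!identical(dim(sens), c(nr, nr, pc))) {
    stop("sensitivity array has the wrong shape", call. = FALSE)
  }
  slope <- net$gain * (1 - outputs^2)
  w_fb <- net$W[, net$p + seq_len(nr), drop = FALSE]
  new_sens <- array(0, dim = c(nr, nr, pc))
  for (k in seq_len(nr)) {
    for (l in seq_len(pc)) {
      direct <- numeric(nr)
      direct[k] <- u[l]
      new_sens[, k, l] <- slope * (direct + drop(w_fb %*% sens[, k, l]))
    }
  }
  new_sens
}

#' Error-weight derivative of the recurrent network at one step
#'
#' The error is defined on the first neuron only, `e(n) = d(n) - y_1(n)`, so
#' `de(n)/dW[k, l] = -dy_1(n)/dW[k, l]`: the negated first-neuron slice of
#' the sensitivity tensor.
#'
#' @param sens Sensitivity array current for time `n` (see [rtrl_step()]).
#' @return Matrix `n_neurons x (p + n_neurons)` of `de(n)/dW`.
#' @export
rnn_error_derivative <- function(sens) {
  -sens[1, , ]
}

# full epoch sweep: feedback and sensitivities reset to zero, then the C++
# recursion over all N steps; s1[n, ] is dy_1(n)/dW flattened column-major.
rnn_sweep <- function(net, x_ext, sensitivities = TRUE) {
  if (!is.matrix(x_ext)) x_ext <- matrix(x_ext, ncol = net$p)
  rnn_sweep_cpp(net$W, net$gain, net$bias, x_ext,
                rep(0, net$n_neurons), sensitivities)
}

#' Train a recurrent network by synergistic MEE-RTRL + intrinsic plasticity
#'
#' Epochwise training loop for the fully recurrent network. Each epoch
#' resets the feedback state and the RTRL sensitivities to zero, sweeps the
#' N training time steps once (collecting the errors on the first neuron and
#' the per-step sensitivities of its output with respect to every weight),
#' then applies the synaptic stage — steepest ascent on the quadratic
#' information potential, chaining `dV/de` with the accumulated per-step
#' error-weight derivatives — followed by the intrinsic stage, a batch
#' infomax update of every neuron's gain and bias from that epoch's cached
#' pre-/post-activation pairs. Learning-rate schedules, curve conventions,
#' divergence handling and the final mean-error bias correction are shared
#' with [train_fnn()].
#'
#' @param net An `"rnn"` object (see [init_rnn()]).
#' @param x_ext N x p matrix of external inputs (delay-embedded series).
#' @param targets Length-N desired outputs for the first neuron.
#' @param config A [train_config()] (recurrent runs typically use
#'   `ip_eta0 = 5e-4`).
#' @param ip Logical: apply the intrinsic-plasticity stage?
#' @return An `"itl_fit"` object (see [train_fnn()]).
#' @export
train_rnn <- function(net, x_ext, targets, config = train_config(),
                      ip = TRUE) {
  stopifnot(inherits(net, "rnn"))
  if (!is.matrix(x_ext)) x_ext <- matrix(x_ext, ncol = net$p)
  n <- nrow(x_ext)
  if (n < 2L || length(targets) != n) {
    stop("need an N x p input matrix and matching targets, N >= 2",
         call. = FALSE)
  }
  epochs <- config$epochs
  curve_v <- curve_mse <- curve_gain <- numeric(epochs)
  diagnostics <- list()
  for (epoch in seq_len(epochs)) {
    sweep_out <- rnn_sweep(net, x_ext, sensitivities = TRUE)
    e <- targets - sweep_out$outputs[, 1]
    if (!all(is.finite(e))) {
      stop(sprintf("training diverged at epoch %d (non-finite errors)",
                   epoch), call. = FALSE)
    }
    pg <- potential_and_gradient(e, config$sigma)
    curve_v[epoch] <- pg$V
    curve_mse[epoch] <- mean((e - mean(e))^2)
    curve_gain[epoch] <- mean(net$gain)
    if (epoch == 1L) diagnostics$initial <- rnn_diag(sweep_out, e)
    # synaptic stage: dV/dW = sum_n dV/de_n * (-dy_1(n)/dW)
    eta_w <- config$mee_eta0 * config$mee_gamma^(epoch - 1)
    grad_flat <- -drop(crossprod(sweep_out$s1, pg$grad))
    net$W <- net$W + eta_w * matrix(grad_flat, net$n_neurons,
                                    net$p + net$n_neurons)
    # intrinsic stage (same cached sweep)
    if (ip) {
      eta_ip <- config$ip_eta0 * config$ip_gamma^(epoch - 1)
      up <- ip_update(sweep_out$net_input, sweep_out$outputs, net$gain,
                      net$bias, eta_ip)
      net$gain <- up$gain
      net$bias <- up$bias
    }
  }
  sweep_out <- rnn_sweep(net, x_ext, sensitivities = FALSE)
  y_raw <- sweep_out$outputs[, 1]
  net <- bias_correct(net, targets, y_raw)
  diagnostics$final <- rnn_diag(sweep_out,
                                targets - y_raw - net$bias_correction)
  structure(list(net = net,
                 curves = data.frame(epoch = seq_len(epochs), V = curve_v,
                                     mse = curve_mse,
                                     mean_gain = curve_gain),
                 diagnostics = diagnostics,
                 config = config, ip = ip, model = "rnn"),
            class = "itl_fit")
}

rnn_diag <- function(sweep_out, e) {
  list(neuron_input = sweep_out$net_input, neuron_output = sweep_out$outputs,
       error = e)
}

#' Evaluate a trained recurrent network
#'
#' Runs the network over a (typically held-out) input sequence from a zero
#' feedback state and reports the mean squared error of the bias-corrected
#' first-neuron output and the quadratic information potential of the
#' errors.
#'
#' @param net An `"rnn"` object with its training bias correction set.
#' @param x_ext N x p matrix of external inputs.
#' @param targets Length-N targets.
#' @param sigma Parzen kernel bandwidth.
#' @return List with `mse` and `V`.
#' @export
evaluate_rnn <- function(net, x_ext, targets, sigma = 0.1) {
  if (!is.matrix(x_ext)) x_ext <- matrix(x_ext, ncol = net$p)
  out <- rnn_sweep(net, x_ext, sensitivities = FALSE)
  e <- targets - out$outputs[, 1] - net$bias_correction
  list(mse = mean(e^2), V = information_potential(e, sigma))
}

#' @export
print.itl_fit <- function(x, ...) {
  n_ep <- nrow(x$curves)
  cat(sprintf("Synergistic ITL fit (%s, %s intrinsic plasticity)\n",
              toupper(x$model), if (x$ip) "with" else "without"))
  cat(sprintf("  epochs: %d, final training V: %.4f, final mean-cancelled MSE: %.3g\n",
              n_ep, x$curves$V[n_ep], x$curves$mse[n_ep]))
  invisible(x)
}
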