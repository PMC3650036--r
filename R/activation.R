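#' Adaptive tanh activation
#'
#' Evaluates `y = tanh(gain * x + bias)`. Each neuron carries its own gain
#' (slope/sensitivity) and bias; these are the two parameters adapted by the
#' intrinsic-plasticity rule, while synaptic learning adapts the weights that
#' feed `x`.
#'
#' When `x` is a matrix (samples in rows, neurons in columns), `gain` and
#' `bias` are recycled per column so a whole layer is evaluated at once.
#'
#' @param x Pre-activation input: numeric vector, or matrix with one column
#'   per neuron.
#' @param gain Activation gain(s), strictly positive.
#' @param bias Activation bias(es).
#' @return Activation output(s) in (-1, 1), same shape as `x`.
#' @export
activate <- function(x, gain = 1, bias = 0) {
  check_gain(gain)
  tanh(scale_cols(x, gain, bias))
}

#' Slope of the adaptive tanh activation
#'
#' `dy/dx = gain * (1 - y^2)` with `y = activate(x, gain, bias)`; strictly
#' positive for positive gain. This is the chain-rule factor that the
#' backpropagation and RTRL derivatives pick up at every adaptive neuron.
#'
#' @inheritParams activate
#' @return Slope(s), same shape as `x`.
#' @export
activation_slope <- function(x, gain = 1, bias = 0) {
  y <- activate(x, gain, bias)
  if (is.matrix(y)) {
    sweep(1 - y^2, 2L, gain, "*")
  } else {
    gain * (1 - y^2)
  }
}

#' Batch infomax intrinsic-plasticity update
#'
#' One batch step of the infomax intrinsic-plasticity rule for adaptive tanh
#' neurons. For a deterministic monotone unit, maximizing input-output mutual
#' information is equivalent to ascending the expected log-slope
#' `E[log |dy/dx|] = E[log(gain * (1 - y^2))]`; the gradient of the sample
#' mean of that objective over the batch gives
#' \deqn{\Delta gain = \eta (1/gain - 2 \hat{E}[x y]), \quad
#'       \Delta bias = -2 \eta \hat{E}[y],}
#' where the hats denote sample means over the epoch's cached input-output
#' pairs. The update matches the activation's steep region to the mass of the
#' input distribution. It is applied once per epoch (batch rule).
#'
#' If a step would drive a gain non-positive, the gain is clamped at `1e-6`
#' and a warning is raised; the rule assumes positive gain throughout and in
#' practice gains grow during training.
#'
#' @param x Pre-activation inputs: numeric vector (one neuron) or N x m
#'   matrix (m neurons).
#' @param y Corresponding activation outputs, produced by the current
#'   `(gain, bias)` on `x`; same shape as `x`.
#' @param gain,bias Current activation parameters (length m).
#' @param eta Intrinsic-plasticity learning rate for this epoch (>= 0).
#' @return A list with updated `gain` and `bias` vectors.
#' @export
ip_update <- function(x, y, gain, bias, eta) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) {
    stop("`x` and `y` must have the same dimensions", call. = FALSE)
  }
  check_gain(gain)
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0) {
    stop("`eta` must be a single non-negative number", call. = FALSE)
  }
  new_gain <- gain + eta * (1 / gain - 2 * colMeans(x * y))
  new_bias <- bias + eta * (-2 * colMeans(y))
  if (any(new_gain <= 0)) {
    warning("intrinsic-plasticity step drove a gain non-positive; clamped",
            call. = FALSE)
    new_gain <- pmax(new_gain, 1e-6)
  }
  list(gain = new_gain, bias = new_bias)
}

# column-wise affine map gain * x + bias (vector x: plain arithmetic)
scale_cols <- function(x, gain, bias) {
  if (is.matrix(x)) {
    sweep(sweep(x, 2L, gain, "*"), 2L, bias, "+")
  } else {
    gain * x + bias
  }
}

check_gain <- function(gain) {
  if (!is.numeric(gain) || any(!is.finite(gain)) || any(gain <= 0)) {
    stop("activation gain must be finite and strictly positive",
         call. = FALSE)
  }
  invisible(gain)
}
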