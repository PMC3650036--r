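#' Training configuration
#'
#' Collects the schedule and kernel settings shared by the feedforward and
#' recurrent trainers. Both learning rates are damped exponentially: at epoch
#' `n` (counting from 1) the synaptic MEE rate is
#' `mee_eta0 * mee_gamma^(n-1)` and the intrinsic-plasticity rate is
#' `ip_eta0 * ip_gamma^(n-1)`, so learning is fast at the start and settles
#' in the long run.
#'
#' Defaults: 1000 epochs, Parzen bandwidth `sigma = 0.1` (appropriate for
#' series normalized to [-1, 1]), and the feedforward benchmark schedule of
#' [default_schedule()]; initial weights are drawn uniformly from [0, 0.05].
#' IP rates above roughly `3e-3` produce ripples in the late learning
#' curves and are best avoided.
#'
#' @param epochs Number of training epochs (batch iterations), >= 1.
#' @param sigma Parzen kernel bandwidth for the error-entropy estimate.
#' @param mee_eta0 Initial synaptic (MEE) learning rate.
#' @param mee_gamma Per-epoch exponential decay of the synaptic rate, in
#'   (0, 1].
#' @param ip_eta0 Initial intrinsic-plasticity learning rate (0 disables IP
#'   in effect).
#' @param ip_gamma Per-epoch exponential decay of the IP rate, in (0, 1].
#' @param seed Optional RNG seed applied by the weight initializers.
#' @param init_low,init_high Bounds of the uniform weight initialization.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 1000, sigma = 0.1, mee_eta0 = 0.015,
                         mee_gamma = 0.995, ip_eta0 = 1e-3, ip_gamma = 0.995,
                         seed = NULL, init_low = 0, init_high = 0.05) {
  if (epochs < 1L) stop("`epochs` must be at least 1", call. = FALSE)
  check_sigma(sigma)
  if (mee_eta0 < 0 || ip_eta0 < 0) {
    stop("learning rates must be non-negative", call. = FALSE)
  }
  if (mee_gamma <= 0 || mee_gamma > 1 || ip_gamma <= 0 || ip_gamma > 1) {
    stop("decay factors must lie in (0, 1]", call. = FALSE)
  }
  if (init_high < init_low) {
    stop("`init_high` must be >= `init_low`", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs), sigma = sigma,
                 mee_eta0 = mee_eta0, mee_gamma = mee_gamma,
                 ip_eta0 = ip_eta0, ip_gamma = ip_gamma, seed = seed,
                 init_low = init_low, init_high = init_high),
            class = "train_config")
}

#' Benchmark learning-rate schedules per model
#'
#' The damped learning-rate constants used for the Mackey-Glass prediction
#' benchmark. The feedforward and the recurrent network operate at different
#' points of the speed/stability trade-off (the recurrent gradient flows
#' through time, so its effective step is larger), hence the model-specific
#' synaptic rates; the intrinsic rate is `1e-3` for both, comfortably below
#' the ~`3e-3` ripple threshold.
#'
#' @param model `"fnn"` or `"rnn"`.
#' @return List with `mee_eta0`, `mee_gamma`, `ip_eta0`, `ip_gamma`.
#' @export
default_schedule <- function(model = c("fnn", "rnn")) {
  model <- match.arg(model)
  if (model == "fnn") {
    list(mee_eta0 = 0.015, mee_gamma = 0.995, ip_eta0 = 1e-3,
         ip_gamma = 0.995)
  } else {
    list(mee_eta0 = 0.03, mee_gamma = 0.999, ip_eta0 = 1e-3,
         ip_gamma = 0.999)
  }
}

#' @export
print.train_config <- function(x, ...) {
  cat("Training configuration\n")
  cat(sprintf("  epochs: %d, kernel sigma: %g\n", x$epochs, x$sigma))
  cat(sprintf("  MEE rate: %g * %g^(epoch-1)\n", x$mee_eta0, x$mee_gamma))
  cat(sprintf("  IP rate:  %g * %g^(epoch-1)\n", x$ip_eta0, x$ip_gamma))
  cat(sprintf("  weight init: U[%g, %g], seed: %s\n", x$init_low,
              x$init_high, if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
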