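#' Gaussian kernel
#'
#' Evaluates the Gaussian density kernel `G_sigma(u) = exp(-u^2 / (2 sigma^2)) /
#' (sigma * sqrt(2 * pi))`, the building block of Parzen density estimation and
#' of the quadratic information potential.
#'
#' @param u Numeric vector of evaluation points (differences).
#' @param sigma Kernel bandwidth; a single strictly positive number.
#' @return Numeric vector of kernel values, strictly positive, maximal at
#'   `u = 0`.
#' @examples
#' gaussian_kernel(0, 0.1)          # 1 / (0.1 * sqrt(2 * pi))
#' gaussian_kernel(c(-1, 0, 1), 0.5)
#' @export
gaussian_kernel <- function(u, sigma) {
  check_sigma(sigma)
  exp(-u^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

#' Parzen kernel density estimate
#'
#' Nonparametric density estimate `p(x) = (1/N) * sum_i G_sigma(x - s_i)`:
#' the average of Gaussian kernels centered on the samples. Integrates to 1
#' over the real line for any sample set.
#'
#' @param x Numeric vector of points at which to evaluate the density.
#' @param samples Numeric vector of observed samples (at least one, all
#'   finite).
#' @param sigma Kernel bandwidth, strictly positive.
#' @return Numeric vector of density values, one per element of `x`.
#' @export
parzen_pdf <- function(x, samples, sigma) {
  check_sigma(sigma)
  if (length(samples) < 1L || !all(is.finite(samples))) {
    stop("`samples` must contain at least one finite value", call. = FALSE)
  }
  vapply(x, function(xi) mean(gaussian_kernel(xi - samples, sigma)),
         numeric(1))
}

#' Quadratic information potential of an error batch
#'
#' The sample estimator of the Renyi quadratic information potential
#' `V = (1/N^2) * sum_i sum_j G_{sigma * sqrt(2)}(e_j - e_i)`. The kernel
#' inside the double sum uses the convolved bandwidth `sigma * sqrt(2)`
#' (a Gaussian convolved with itself); `sigma` is the Parzen bandwidth used
#' for the underlying density estimate. `V` is bounded by
#' `0 < V <= 1 / (2 * sigma * sqrt(pi))`, with equality iff all errors are
#' identical, and is invariant to adding a constant to every error.
#' Minimizing the Renyi quadratic entropy of the errors is equivalent to
#' maximizing `V`.
#'
#' @param errors Numeric vector of error samples, length at least 2, all
#'   finite.
#' @param sigma Parzen kernel bandwidth, strictly positive.
#' @return The scalar potential `V`.
#' @seealso [renyi_entropy()], [potential_gradient()]
#' @export
information_potential <- function(errors, sigma) {
  check_error_batch(errors)
  check_sigma(sigma)
  potential_and_gradient(errors, sigma)$V
}

#' Renyi quadratic entropy of an error batch
#'
#' `H2 = -log(V)` with `V` the quadratic information potential of the batch.
#' Minimized exactly when `V` is maximized, i.e. when the error distribution
#' collapses to a point.
#'
#' @inheritParams information_potential
#' @return The scalar entropy estimate `H2`.
#' @export
renyi_entropy <- function(errors, sigma) {
  -log(information_potential(errors, sigma))
}

#' Gradient of the information potential with respect to the errors
#'
#' Exact analytic partial derivatives `dV/de_i` of the double-sum estimator.
#' Writing `s = sigma * sqrt(2)`,
#' `dV/de_k = -(2 / (N^2 s^2)) * sum_i (e_k - e_i) * G_s(e_k - e_i)`.
#' The components sum to zero (shift invariance of `V`), and vanish for a
#' degenerate (all-equal) batch. Training rules chain this factor with the
#' network-specific `de_i/dw`.
#'
#' @inheritParams information_potential
#' @return Numeric vector of the `N` partial derivatives `dV/de_i`.
#' @export
potential_gradient <- function(errors, sigma) {
  check_error_batch(errors)
  check_sigma(sigma)
  potential_and_gradient(errors, sigma)$grad
}

# One pairwise pass returning both V and dV/de (the O(N^2) kernel matrix is
# the dominant cost of a training epoch, so compute it once). Rows are
# processed in blocks so that large batches (e.g. 10000 test errors) never
# materialize the full N x N matrix.
potential_and_gradient <- function(errors, sigma) {
  n <- length(errors)
  s2 <- 2 * sigma^2                        # variance of the convolved kernel
  norm <- 1 / sqrt(2 * pi * s2)
  block <- 512L
  vsum <- 0
  grad <- numeric(n)
  for (start in seq.int(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d <- outer(errors[idx], errors, "-")   # d[k, i] = e_k - e_i
    km <- exp(-d^2 / (2 * s2)) * norm
    vsum <- vsum + sum(km)
    grad[idx] <- rowSums(d * km)
  }
  list(V = vsum / n^2,
       grad = -(2 / (n^2 * s2)) * grad)
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single finite positive number", call. = FALSE)
  }
  invisible(sigma)
}

check_error_batch <- function(errors) {
  if (!is.numeric(errors) || length(errors) < 2L) {
    stop("error batch must contain at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(errors))) {
    stop("error batch must be finite", call. = FALSE)
  }
  invisible(errors)
}
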