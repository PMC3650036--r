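#' Mackey-Glass chaotic time series
#'
#' Integrates the Mackey-Glass delay differential equation
#' \deqn{dx/dt = \beta x(t-\tau) / (1 + x(t-\tau)^{q}) - \gamma x(t)}
#' with a 4th-order Runge-Kutta scheme at step `dt` (the delayed term is
#' taken from the stored trajectory, interpolated at half steps), discards a
#' transient, then subsamples every `sample_every` time units to obtain a
#' discrete series. With the standard coefficients `beta = 0.2`,
#' `gamma = 0.1`, `q = 10` and delay `tau = 17` the flow is chaotic; it is a
#' classic model of irregular behavior in physiological control systems and
#' a standard single-step prediction benchmark.
#'
#' The history is held constant at `x0` for `t <= 0`. `tau` and
#' `sample_every` are rounded to whole multiples of `dt`. The default
#' subsampling interval of 1 time unit is the benchmark cadence used
#' throughout this package; it sets the difficulty of the single-step
#' prediction task (see the methods vignette).
#'
#' @param n Number of samples to return.
#' @param tau Delay of the feedback term, in time units.
#' @param dt Runge-Kutta integration step, in time units.
#' @param sample_every Subsampling interval, in time units.
#' @param x0 Initial condition / constant history value.
#' @param discard Transient, in time units, dropped before sampling starts.
#' @param beta,gamma,q Equation coefficients (production rate, decay rate,
#'   nonlinearity exponent).
#' @return Numeric vector of `n` samples with the generator parameters
#'   attached as attribute `"mg_params"`.
#' @examples
#' x <- mackey_glass(500)
#' range(x)
#' @export
mackey_glass <- function(n, tau = 17, dt = 0.1, sample_every = 1, x0 = 1.2,
                         discard = 1000, beta = 0.2, gamma = 0.1, q = 10) {
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  if (tau <= 0 || dt <= 0 || sample_every <= 0 || discard < 0) {
    stop("`tau`, `dt` and `sample_every` must be positive and `discard` non-negative",
         call. = FALSE)
  }
  lag <- round(tau / dt)
  skip <- round(discard / dt)
  per <- round(sample_every / dt)
  if (lag < 1L || per < 1L) {
    stop("`dt` must be smaller than `tau` and `sample_every`", call. = FALSE)
  }
  n_steps <- skip + n * per
  x <- numeric(n_steps + 1L)
  x[1L] <- x0
  half <- dt / 2
  for (i in seq_len(n_steps)) {
    xd0 <- if (i > lag) x[i - lag] else x0
    xd1 <- if (i + 1L > lag) x[i + 1L - lag] else x0
    xdh <- (xd0 + xd1) / 2            # delayed value at the half step
    xc <- x[i]
    k1 <- beta * xd0 / (1 + xd0^q) - gamma * xc
    x2 <- xc + half * k1
    k2 <- beta * xdh / (1 + xdh^q) - gamma * x2
    x3 <- xc + half * k2
    k3 <- beta * xdh / (1 + xdh^q) - gamma * x3
    x4 <- xc + dt * k3
    k4 <- beta * xd1 / (1 + xd1^q) - gamma * x4
    x[i + 1L] <- xc + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out <- x[skip + per * seq_len(n) + 1L]
  attr(out, "mg_params") <- list(tau = tau, dt = dt,
                                 sample_every = sample_every, x0 = x0,
                                 discard = discard, beta = beta,
                                 gamma = gamma, q = q)
  out
}

#' Normalize a series to [-1, 1]
#'
#' Affine map sending `from[1] -> -1` and `from[2] -> +1`. By default the
#' normalizing range is the observed range of `x`, so both endpoints are
#' attained. The range used is stored as attribute `"norm_range"` so the map
#' can be inverted (see [denormalize_series()]) or reused on another series
#' (e.g. normalize a held-out test series with the training range).
#'
#' @param x Numeric series with at least two distinct values.
#' @param from Length-2 numeric `(min, max)` defining the affine map;
#'   defaults to `range(x)`.
#' @return The normalized series with attribute `"norm_range"`.
#' @export
normalize_series <- function(x, from = range(x)) {
  if (length(from) != 2L || !all(is.finite(from)) || from[2] <= from[1]) {
    stop("normalizing range must contain two distinct finite values",
         call. = FALSE)
  }
  out <- 2 * (as.numeric(x) - from[1]) / (from[2] - from[1]) - 1
  attr(out, "norm_range") <- as.numeric(from)
  out
}

#' Invert the [-1, 1] normalization
#'
#' @param x Normalized series.
#' @param from The `(min, max)` pair used to normalize; defaults to the
#'   `"norm_range"` attribute stored by [normalize_series()].
#' @return The series on its original scale.
#' @export
denormalize_series <- function(x, from = attr(x, "norm_range")) {
  if (is.null(from)) stop("no normalization range available", call. = FALSE)
  (as.numeric(x) + 1) / 2 * (from[2] - from[1]) + from[1]
}

#' Delay embedding of a series for single-step prediction
#'
#' Builds the supervised pairs for time-series prediction: each input row
#' holds `k` consecutive series values (in chronological order) and the
#' target is the value `horizon` steps after the most recent input element.
#' A series of length `L` yields `L - k - horizon + 1` pairs.
#'
#' @param x Numeric series.
#' @param k Embedding dimension (number of delays used as input).
#' @param horizon Prediction horizon in steps (default 1, single-step).
#' @return A list of class `"prediction_dataset"` with elements `inputs`
#'   (N x k matrix), `targets` (length-N vector), `k` and `horizon`.
#' @export
embed_series <- function(x, k, horizon = 1) {
  x <- as.numeric(x)
  if (k < 1L || horizon < 1L) {
    stop("`k` and `horizon` must be at least 1", call. = FALSE)
  }
  n <- length(x) - k - horizon + 1L
  if (n < 1L) stop("series too short for this embedding", call. = FALSE)
  inputs <- vapply(seq_len(k), function(j) x[seq_len(n) + j - 1L],
                   numeric(n))
  inputs <- matrix(inputs, nrow = n, ncol = k)
  structure(list(inputs = inputs,
                 targets = x[seq_len(n) + k + horizon - 1L],
                 k = k, horizon = horizon),
            class = "prediction_dataset")
}

#' Mackey-Glass train/test split for the prediction benchmark
#'
#' Generates a training series and a test series from distinct initial
#' conditions (the test initial condition is drawn from the seeded RNG),
#' normalizes both to [-1, 1], and delay-embeds both with the same
#' embedding dimension. By default the test series is normalized with the
#' training range, so train and test share one affine map, as a deployed
#' predictor would require; set `per_series_norm = TRUE` to normalize each
#' series by its own range instead.
#'
#' @param n_train,n_test Number of supervised training / test pairs.
#' @param k Embedding dimension.
#' @param horizon Prediction horizon in steps.
#' @param seed RNG seed controlling the test initial condition.
#' @param x0_train Training-series initial condition.
#' @param per_series_norm Normalize the test series by its own range?
#' @param ... Further arguments passed to [mackey_glass()] (e.g. `tau`,
#'   `dt`, `sample_every`).
#' @return A list of class `"benchmark_split"` with `train` and `test`
#'   prediction datasets and a `meta` list echoing every generator setting.
#' @export
make_benchmark_split <- function(n_train = 300, n_test = 10000, k = 4,
                                 horizon = 1, seed = 1, x0_train = 1.2,
                                 per_series_norm = FALSE, ...) {
  x0_test <- with_local_seed(seed, stats::runif(1, 0.6, 1.6))
  len_train <- n_train + k + horizon - 1L
  len_test <- n_test + k + horizon - 1L
  raw_train <- mackey_glass(len_train, x0 = x0_train, ...)
  raw_test <- mackey_glass(len_test, x0 = x0_test, ...)
  train_series <- normalize_series(raw_train)
  test_series <- if (per_series_norm) {
    normalize_series(raw_test)
  } else {
    normalize_series(raw_test, from = attr(train_series, "norm_range"))
  }
  structure(list(train = embed_series(train_series, k, horizon),
                 test = embed_series(test_series, k, horizon),
                 meta = c(list(n_train = n_train, n_test = n_test, k = k,
                               horizon = horizon, seed = seed,
                               x0_train = x0_train, x0_test = x0_test,
                               per_series_norm = per_series_norm),
                          attr(raw_train, "mg_params"))),
            class = "benchmark_split")
}

#' Read a univariate series from a text file
#'
#' Accepts one value per line, whitespace-separated values, or a one-column
#' CSV (comma-separated). Lines starting with `#` are ignored.
#'
#' @param path Path to the file.
#' @return Numeric vector.
#' @export
read_series <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  if (any(grepl(",", txt, fixed = TRUE))) {
    txt <- unlist(strsplit(txt, ","))
  }
  x <- suppressWarnings(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))))
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no numeric values found in ", path, call. = FALSE)
  x
}

#' Export / import a prediction dataset as a CSV pair
#'
#' Writes `<prefix>-inputs.csv` (one column per delay, named `lag1..lagk`)
#' and `<prefix>-targets.csv` (columns `target` plus the embedding metadata
#' `k` and `horizon`), and reads them back.
#'
#' @param ds A `"prediction_dataset"` (see [embed_series()]).
#' @param prefix Path prefix for the two files.
#' @return `write_dataset()` returns the two paths invisibly;
#'   `read_dataset()` returns the restored dataset.
#' @export
write_dataset <- function(ds, prefix) {
  stopifnot(inherits(ds, "prediction_dataset"))
  inputs <- as.data.frame(ds$inputs)
  names(inputs) <- paste0("lag", seq_len(ds$k))
  p1 <- paste0(prefix, "-inputs.csv")
  p2 <- paste0(prefix, "-targets.csv")
  utils::write.csv(inputs, p1, row.names = FALSE)
  utils::write.csv(data.frame(target = ds$targets, k = ds$k,
                              horizon = ds$horizon), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  inputs <- utils::read.csv(paste0(prefix, "-inputs.csv"))
  targets <- utils::read.csv(paste0(prefix, "-targets.csv"))
  structure(list(inputs = unname(as.matrix(inputs)),
                 targets = targets$target,
                 k = targets$k[1], horizon = targets$horizon[1]),
            class = "prediction_dataset")
}

#' Write a univariate series to a text file (one value per line)
#'
#' @param x Numeric series.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  writeLines(format(as.numeric(x), digits = 17, trim = TRUE, scientific = NA),
             path)
  invisible(path)
}

# run expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
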