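#' Paired comparison of MEE training with and without intrinsic plasticity
#'
#' Runs `n_runs` independently seeded repetitions of the same training
#' problem under two conditions — pure MEE (`no_ip`) and the synergistic
#' MEE + intrinsic-plasticity rule (`with_ip`) — using identical data and
#' identical initial weights within each run (paired design: run `r` uses
#' seed `base_seed + r` for initialization, and both conditions start from
#' the same initialized network). Reports per-condition means of training
#' and test information potential and MSE, the relative MSE improvement
#' `(mse_no_ip - mse_with_ip) / mse_no_ip * 100`, and the mean learning
#' curves. Runs that diverge are excluded from the means and counted in the
#' output metadata, never dropped silently.
#'
#' @param model `"fnn"` or `"rnn"`.
#' @param data A [make_benchmark_split()] result; built from defaults (with
#'   `seed = base_seed`) when omitted.
#' @param config A [train_config()]; defaults to the model's
#'   [default_schedule()]. Its `seed` field is overridden per run.
#' @param n_runs Number of seeded repetitions.
#' @param base_seed Base RNG seed; run `r` uses `base_seed + r`.
#' @param m Hidden-layer size (feedforward).
#' @param n_neurons Network size (recurrent).
#' @param ip_conditions Named list of the IP settings to contrast; the
#'   default contrasts `no_ip` (IP disabled) with `with_ip` (IP at the
#'   config's rate). Each entry is the `ip_eta0` to use, with `NA` meaning
#'   "IP stage skipped".
#' @return An object of class `"itl_comparison"`: list with `table` (the
#'   per-condition result table), `improvement` (train/test percentages),
#'   `runs` (per-run metrics), `mean_curves`, `run_curves` (per-condition
#'   lists of each run's learning curves), `init_weights` (per-run
#'   initial weight vectors, shared by both conditions), `excluded`
#'   (diverged run count per condition) and `settings` (full provenance of
#'   every default used).
#' @export
run_comparison <- function(model = c("fnn", "rnn"), data = NULL,
                           config = NULL, n_runs = 10,
                           base_seed = 1, m = 5, n_neurons = 2,
                           ip_conditions = NULL) {
  model <- match.arg(model)
  if (is.null(config)) config <- do.call(train_config, default_schedule(model))
  if (n_runs < 1L) stop("`n_runs` must be at least 1", call. = FALSE)
  if (is.null(data)) {
    data <- make_benchmark_split(seed = base_seed)
  }
  k <- data$train$k
  if (is.null(ip_conditions)) {
    ip_conditions <- list(no_ip = NA_real_, with_ip = config$ip_eta0)
  }
  conds <- names(ip_conditions)
  runs <- list()
  init_weights <- list()
  curves <- stats::setNames(vector("list", length(conds)), conds)
  excluded <- stats::setNames(integer(length(conds)), conds)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- base_seed + r
    net0 <- if (model == "fnn") init_fnn(m, k, cfg) else init_rnn(n_neurons, k, cfg)
    init_weights[[r]] <- as.numeric(if (model == "fnn") {
      c(net0$W1, net0$W2)
    } else {
      net0$W
    })
    for (cond in conds) {
      rate <- ip_conditions[[cond]]
      cfg_c <- cfg
      ip_on <- !is.na(rate)
      if (ip_on) cfg_c$ip_eta0 <- rate
      fit <- tryCatch(
        if (model == "fnn") {
          train_fnn(net0, data$train$inputs, data$train$targets, cfg_c,
                    ip = ip_on)
        } else {
          train_rnn(net0, data$train$inputs, data$train$targets, cfg_c,
                    ip = ip_on)
        },
        error = function(e) e)
      if (inherits(fit, "error")) {
        excluded[cond] <- excluded[cond] + 1L
        runs[[length(runs) + 1L]] <- data.frame(
          run = r, seed = cfg$seed, condition = cond, diverged = TRUE,
          train_V = NA_real_, train_mse = NA_real_, test_V = NA_real_,
          test_mse = NA_real_)
        next
      }
      ev_train <- if (model == "fnn") {
        evaluate_fnn(fit$net, data$train$inputs, data$train$targets,
                     cfg_c$sigma)
      } else {
        evaluate_rnn(fit$net, data$train$inputs, data$train$targets,
                     cfg_c$sigma)
      }
      ev_test <- if (model == "fnn") {
        evaluate_fnn(fit$net, data$test$inputs, data$test$targets,
                     cfg_c$sigma)
      } else {
        evaluate_rnn(fit$net, data$test$inputs, data$test$targets,
                     cfg_c$sigma)
      }
      runs[[length(runs) + 1L]] <- data.frame(
        run = r, seed = cfg$seed, condition = cond, diverged = FALSE,
        train_V = ev_train$V, train_mse = ev_train$mse,
        test_V = ev_test$V, test_mse = ev_test$mse)
      curves[[cond]][[length(curves[[cond]]) + 1L]] <- fit$curves
    }
  }
  runs <- do.call(rbind, runs)
  table <- do.call(rbind, lapply(conds, function(cond) {
    ok <- runs[runs$condition == cond & !runs$diverged, ]
    data.frame(condition = cond,
               train_V = mean(ok$train_V), train_mse = mean(ok$train_mse),
               test_V = mean(ok$test_V), test_mse = mean(ok$test_mse))
  }))
  improvement <- if (all(c("no_ip", "with_ip") %in% conds)) {
    no <- table[table$condition == "no_ip", ]
    yes <- table[table$condition == "with_ip", ]
    c(train = (no$train_mse - yes$train_mse) / no$train_mse * 100,
      test = (no$test_mse - yes$test_mse) / no$test_mse * 100)
  } else {
    NULL
  }
  mean_curves <- do.call(rbind, lapply(conds, function(cond) {
    cl <- curves[[cond]]
    if (length(cl) == 0L) return(NULL)
    out <- cl[[1]][, c("epoch", "V", "mse", "mean_gain")]
    if (length(cl) > 1L) {
      for (col in c("V", "mse", "mean_gain")) {
        out[[col]] <- rowMeans(vapply(cl, function(d) d[[col]],
                                      numeric(nrow(out))))
      }
    }
    out$condition <- cond
    out
  }))
  settings <- c(list(model = model, n_runs = n_runs, base_seed = base_seed,
                     m = m, n_neurons = n_neurons,
                     ip_conditions = ip_conditions),
                unclass(config), data$meta)
  structure(list(table = table, improvement = improvement, runs = runs,
                 mean_curves = mean_curves, run_curves = curves,
                 init_weights = init_weights,
                 excluded = excluded, settings = settings),
            class = "itl_comparison")
}

#' @export
print.itl_comparison <- function(x, ...) {
  cat(sprintf("Paired MEE comparison (%s, %d runs%s)\n",
              toupper(x$settings$model), x$settings$n_runs,
              if (any(x$excluded > 0)) {
                sprintf(", %d diverged run(s) excluded", sum(x$excluded))
              } else {
                ""
              }))
  print(x$table, row.names = FALSE, digits = 5)
  if (!is.null(x$improvement)) {
    cat(sprintf("MSE improvement with IP: %.2f%% (train), %.2f%% (test)\n",
                x$improvement["train"], x$improvement["test"]))
  }
  invisible(x)
}

#' Sweep the initial intrinsic-plasticity learning rate
#'
#' Repeats the paired-run protocol of [run_comparison()] once per requested
#' initial IP rate, on shared seeds and data, and returns the per-rate mean
#' learning curves and final metrics. Rate 0 reproduces the no-IP condition
#' exactly (every IP increment is identically zero).
#'
#' @param rates Numeric vector of initial IP learning rates (include 0 for
#'   the baseline).
#' @inheritParams run_comparison
#' @return An object of class `"itl_rate_sweep"`: list with `curves` (mean
#'   curves stacked with a `rate` column), `table` (final metrics per rate)
#'   and `settings`.
#' @export
sweep_ip_rate <- function(rates, model = c("fnn", "rnn"), data = NULL,
                          config = NULL, n_runs = 3,
                          base_seed = 1, m = 5, n_neurons = 2) {
  model <- match.arg(model)
  if (is.null(config)) config <- do.call(train_config, default_schedule(model))
  if (any(rates < 0)) stop("IP rates must be non-negative", call. = FALSE)
  if (is.null(data)) data <- make_benchmark_split(seed = base_seed)
  conds <- stats::setNames(as.list(rates), paste0("rate_", rates))
  cmp <- run_comparison(model, data, config, n_runs, base_seed, m,
                        n_neurons, ip_conditions = conds)
  curves <- cmp$mean_curves
  curves$rate <- rates[match(curves$condition, names(conds))]
  table <- cmp$table
  table$rate <- rates[match(table$condition, names(conds))]
  structure(list(curves = curves, table = table, runs = cmp$runs,
                 run_curves = cmp$run_curves, rates = conds,
                 settings = cmp$settings),
            class = "itl_rate_sweep")
}

#' Sweep the network size under both conditions
#'
#' Runs the paired with/without-IP comparison for each requested network
#' size (hidden neurons for the feedforward model, neurons for the
#' recurrent model) on shared seeds and data, and collects the final
#' training metrics and the synaptic weight counts per size.
#'
#' @param sizes Integer vector of network sizes.
#' @inheritParams run_comparison
#' @return An object of class `"itl_size_sweep"`: a data frame `table` with
#'   one row per size x condition (final mean train V and MSE, weight
#'   count), plus `settings`.
#' @export
sweep_size <- function(sizes, model = c("fnn", "rnn"), data = NULL,
                       config = NULL, n_runs = 3, base_seed = 1) {
  model <- match.arg(model)
  if (is.null(config)) config <- do.call(train_config, default_schedule(model))
  if (any(sizes < 1)) stop("sizes must be at least 1", call. = FALSE)
  if (is.null(data)) data <- make_benchmark_split(seed = base_seed)
  k <- data$train$k
  rows <- lapply(sizes, function(sz) {
    cmp <- run_comparison(model, data, config, n_runs, base_seed,
                          m = sz, n_neurons = sz)
    tab <- cmp$table
    tab$size <- sz
    tab$n_weights <- if (model == "fnn") sz * (k + 1L) else sz * (k + sz)
    tab$improvement_train <- cmp$improvement["train"]
    runs <- cmp$runs
    runs$size <- sz
    list(tab = tab, runs = runs)
  })
  structure(list(table = do.call(rbind, lapply(rows, `[[`, "tab")),
                 runs = do.call(rbind, lapply(rows, `[[`, "runs")),
                 settings = list(model = model, sizes = sizes,
                                 n_runs = n_runs, base_seed = base_seed,
                                 config = unclass(config), data = data$meta)),
            class = "itl_size_sweep")
}

#' Kernel-density distribution report for a trained run
#'
#' Evaluates Parzen densities of the per-neuron pre-activation inputs,
#' activation outputs and training errors cached by the trainer at the first
#' and last epoch, on a regular grid wide enough for the densities to
#' integrate to ~1. This reproduces the distribution diagnostics used to
#' analyze how intrinsic plasticity reshapes each neuron's operating range.
#'
#' @param fit An `"itl_fit"` from [train_fnn()] or [train_rnn()].
#' @param sigma Parzen bandwidth for the report densities.
#' @param grid_n Number of grid points per density.
#' @return A data frame with columns `stage` (initial/final), `quantity`,
#'   `neuron`, `x` and `density`.
#' @export
distribution_report <- function(fit, sigma = 0.1, grid_n = 201) {
  stopifnot(inherits(fit, "itl_fit"))
  if (is.null(fit$diagnostics$initial)) {
    stop("fit carries no cached per-neuron samples", call. = FALSE)
  }
  rows <- list()
  for (stage in c("initial", "final")) {
    diag_s <- fit$diagnostics[[stage]]
    for (quantity in names(diag_s)) {
      samples <- diag_s[[quantity]]
      if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1L)
      for (j in seq_len(ncol(samples))) {
        s <- samples[, j]
        grid <- seq(min(s) - 5 * sigma, max(s) + 5 * sigma,
                    length.out = grid_n)
        rows[[length(rows) + 1L]] <- data.frame(
          stage = stage, quantity = quantity, neuron = j, x = grid,
          density = parzen_pdf(grid, s, sigma))
      }
    }
  }
  do.call(rbind, rows)
}
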