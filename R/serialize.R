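#' Write a trained model to JSON
#'
#' Serializes an `"fnn"` or `"rnn"` object (weights, activation gains and
#' biases, bias correction, sizes) to a JSON file that [read_model()] can
#' restore exactly.
#'
#' @param net An `"fnn"` or `"rnn"` object.
#' @param path Output path.
#' @param config Optional [train_config()] echoed into the file for
#'   provenance.
#' @return `path`, invisibly.
#' @export
write_model <- function(net, path, config = NULL) {
  stopifnot(inherits(net, c("fnn", "rnn")))
  obj <- unclass(net)
  obj$W1 <- if (!is.null(obj$W1)) as.data.frame(obj$W1)
  obj$W <- if (!is.null(obj$W)) as.data.frame(obj$W)
  payload <- list(class = class(net)[1], model = obj)
  if (!is.null(config)) payload$config <- unclass(config)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a trained model from JSON
#'
#' @param path Path to a file written by [write_model()].
#' @return The restored `"fnn"` or `"rnn"` object.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- payload$model
  for (f in c("W1", "W")) {
    if (!is.null(obj[[f]])) obj[[f]] <- unname(as.matrix(obj[[f]]))
  }
  for (f in c("m", "k", "n_neurons", "p")) {
    if (!is.null(obj[[f]])) obj[[f]] <- as.integer(obj[[f]])
  }
  obj <- obj[!vapply(obj, is.null, logical(1))]
  structure(obj, class = payload$class)
}

#' Write learning curves to CSV
#'
#' @param curves The `curves` data frame of an `"itl_fit"` (or any data
#'   frame with an `epoch` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}
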