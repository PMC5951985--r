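#' Multichannel time-series container
#'
#' Bundles a nodes-by-samples real matrix with its sampling interval and node
#' labels. This is the universal input to the spectral and connectivity
#' estimators.
#'
#' @param data numeric matrix, rows = nodes, columns = samples.
#' @param dt sampling interval in seconds (> 0).
#' @param node_labels character vector of unique node labels; defaults to
#'   `"n1" ... "n<nrow>"`.
#' @return An object of class `time_series_set` with fields `data`, `dt`,
#'   `node_labels`.
#' @export
time_series_set <- function(data, dt, node_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (ncol(data) < 2L) stop("need at least 2 samples per node")
  if (!all(is.finite(data))) stop("`data` contains non-finite entries")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (seconds)")
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(nrow(data)))
  node_labels <- as.character(node_labels)
  if (length(node_labels) != nrow(data)) stop("one label per node required")
  if (anyDuplicated(node_labels)) stop("node labels must be unique")
  rownames(data) <- node_labels
  structure(list(data = data, dt = dt, node_labels = node_labels),
            class = "time_series_set")
}

#' @export
print.time_series_set <- function(x, ...) {
  cat(sprintf("time_series_set: %d nodes x %d samples, dt = %g s (%.1f s total)\n",
              nrow(x$data), ncol(x$data), x$dt, ncol(x$data) * x$dt))
  invisible(x)
}

n_nodes <- function(ts) nrow(ts$data)
n_samples <- function(ts) ncol(ts$data)

as_time_series_set <- function(x, dt = NULL) {
  if (inherits(x, "time_series_set")) return(x)
  if (is.null(dt)) stop("`dt` required when passing a bare matrix")
  time_series_set(x, dt)
}
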