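#' Estimation configuration
#'
#' Flat namespace of every tunable of the estimation pipeline, with defaults.
#' Unknown keys are rejected. The canonical hash of a config (see
#' [config_hash()]) stamps every output for provenance.
#'
#' @param nfft `"auto"` (use [choose_nfft()]) or an explicit integer.
#' @param hrf_correction halve the automatic NFFT once more (hemodynamically
#'   smoothed data).
#' @param overlap,window,detrend Welch segmentation parameters.
#' @param freq_bins integer indices of the (one-sided) frequency bins to
#'   estimate; `NULL` = all.
#' @param ridge fixed ridge for [initial_factor()] (0 = none).
#' @param ridge_auto ridge applied automatically when a slice is numerically
#'   singular.
#' @param max_iter,tol,smoothing_schedule,restarts,armijo_c optimizer
#'   settings, see [optimize_unitary()].
#' @param alpha significance level for the null thresholds.
#' @param n_null,n_boot replicate counts for [null_thresholds()] and
#'   [bootstrap_cis()].
#' @param pool_frequencies pool null values across frequencies instead of
#'   per-frequency thresholds.
#' @param band_edges,band_fraction defaults for [band_summary()].
#' @param seed integer seed for the stochastic stages.
#' @return A named list of class `ec_config`.
#' @export
ec_config <- function(nfft = "auto", hrf_correction = TRUE, overlap = 0.5,
                      window = "hanning", detrend = TRUE, freq_bins = NULL,
                      ridge = 0, ridge_auto = 1e-8, max_iter = 2000L,
                      tol = 1e-6, smoothing_schedule = c(1e-2, 1e-4, 1e-6, 1e-8),
                      restarts = 3L, armijo_c = 1e-4, alpha = 0.05,
                      n_null = 10L, n_boot = 1000L, pool_frequencies = FALSE,
                      band_edges = c(0, 0.31, 0.45), band_fraction = 2 / 3,
                      seed = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "ec_config")
}

as_ec_config <- function(config) {
  if (inherits(config, "ec_config")) return(config)
  if (!is.list(config)) stop("`config` must be an ec_config or named list")
  known <- names(formals(ec_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(ec_config, config)
}

#' Canonical hash of a configuration
#'
#' MD5 digest of the canonicalized (keys sorted, unclassed) JSON encoding;
#' stable under key reordering.
#'
#' @param config an [ec_config()] or named list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  cfg <- unclass(as_ec_config(config))
  cfg <- cfg[order(names(cfg))]
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

#' Write / read a multichannel time series as delimited text
#'
#' Rows are nodes (first column holds the node label), columns are samples.
#' A JSON sidecar file `<path>.meta.json` records the sampling interval,
#' and optionally a seed and config hash. Reading without a sidecar (or
#' without `dt` in it) is an error, never a silent default.
#'
#' @param ts a [time_series_set()].
#' @param path output file path (tab-separated).
#' @param meta named list merged into the sidecar (e.g. `seed`,
#'   `config_hash`).
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns a `time_series_set`.
#' @export
write_timeseries <- function(ts, path, meta = list()) {
  stopifnot(inherits(ts, "time_series_set"))
  df <- data.table::data.table(node = ts$node_labels, ts$data)
  data.table::fwrite(df, path, sep = "\t")
  side <- c(list(dt = ts$dt, n_nodes = nrow(ts$data),
                 n_samples = ncol(ts$data)), meta)
  jsonlite::write_json(side, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_timeseries
#' @param path input file path.
#' @export
read_timeseries <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop(sprintf("missing sidecar metadata file '%s' (need dt)", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$dt)) stop("sidecar metadata lacks `dt`")
  df <- tryCatch(data.table::fread(path, sep = "\t", header = TRUE),
                 error = function(e)
                   stop(sprintf("parse error in '%s': %s", path,
                                conditionMessage(e)), call. = FALSE))
  labels <- as.character(df[[1]])
  mat <- as.matrix(df[, -1])
  if (!is.numeric(mat)) stop("non-numeric cells in the time-series table")
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite cell at row %d (node '%s'), sample %d",
                 bad[1, 1], labels[bad[1, 1]], bad[1, 2]))
  if (anyDuplicated(labels))
    stop("duplicate node labels in the time-series table")
  time_series_set(mat, dt = meta$dt, node_labels = labels)
}

#' Write / read a (weighted) adjacency matrix as delimited text
#'
#' Square tab-separated matrix with matching row and column labels; entry
#' `(i, j)` is the influence of column node `j` on row node `i`.
#'
#' @param net square numeric matrix (row/column names optional).
#' @param path file path.
#' @return `write_adjacency` returns `path` invisibly; `read_adjacency`
#'   returns the matrix with a `symmetric` attribute.
#' @export
write_adjacency <- function(net, path) {
  net <- as.matrix(net)
  if (nrow(net) != ncol(net)) stop("adjacency must be square")
  labels <- rownames(net) %||% paste0("n", seq_len(nrow(net)))
  df <- data.table::data.table(node = labels, net)
  data.table::setnames(df, c("node", labels))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE)
  if (nrow(df) == 0) stop("empty adjacency file")
  labels <- as.character(df[[1]])
  mat <- as.matrix(df[, -1])
  if (nrow(mat) != ncol(mat))
    stop(sprintf("adjacency is not square: %d rows, %d columns",
                 nrow(mat), ncol(mat)))
  if (!identical(labels, colnames(mat)))
    stop("row labels do not match column labels")
  dimnames(mat) <- list(labels, labels)
  attr(mat, "symmetric") <- isTRUE(all.equal(mat, t(mat),
                                             check.attributes = FALSE))
  mat
}

#' Run the full estimation pipeline with provenance
#'
#' Chains [estimate_pipeline()], optionally [null_thresholds()] /
#' [bootstrap_cis()] and [apply_significance()], and returns the results
#' together with a structured log. Deterministic given `(ts, config)`.
#'
#' @param ts a [time_series_set()] or a path readable by
#'   [read_timeseries()].
#' @param config an [ec_config()].
#' @param threshold compute and apply null thresholds.
#' @param intervals compute bootstrap confidence intervals (and require them
#'   to exclude zero when thresholding).
#' @return List with `estimate`, `thresholds` (or NULL), `cis` (or NULL),
#'   `config`, `config_hash`, `log` (character vector).
#' @export
run_pipeline <- function(ts, config = ec_config(), threshold = FALSE,
                         intervals = FALSE) {
  if (is.character(ts)) ts <- read_timeseries(ts)
  config <- as_ec_config(config)
  hash <- config_hash(config)
  log <- sprintf("config hash %s", hash)
  nfft <- resolve_nfft(ts, config)
  log <- c(log, sprintf("nfft %d (%s)", nfft,
                        if (identical(config$nfft, "auto")) "auto" else "fixed"))
  est <- estimate_pipeline(ts, modifyList(config, list(nfft = nfft)))
  log <- c(log, sprintf("estimated %d frequencies; %d converged; ridge used at %d",
                        nrow(est$convergence), sum(est$convergence$converged),
                        sum(est$convergence$ridge > 0)))
  thr <- cis <- NULL
  seeds <- child_seeds(config$seed, 2L)
  if (threshold) {
    thr <- null_thresholds(ts, config, n_null = config$n_null,
                           alpha = config$alpha, seed = seeds[[1]])
    log <- c(log, sprintf("null thresholds from %d replicates (alpha %g)",
                          thr$n_replicates, thr$alpha))
  }
  if (intervals) {
    cis <- bootstrap_cis(ts, config, n_boot = config$n_boot,
                         seed = seeds[[2]])
    log <- c(log, sprintf("bootstrap intervals from %d replicates", cis$n_boot))
  }
  if (threshold) est <- apply_significance(est, thr, cis)
  list(estimate = est, thresholds = thr, cis = cis, config = config,
       config_hash = hash, log = log)
}
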