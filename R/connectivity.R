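#' Extract the directed coupling matrix from an optimized factor
#'
#' The factor satisfies `B = X^-1/2 (I - G)` with `X` the (unknown, diagonal)
#' drive spectrum, so `G` is identified up to a positive row scale. After
#' phase fixing, each row of `B` is divided by its real positive diagonal
#' entry and the coupling slice is `G = I - B_rownormalized`, whose diagonal
#' is exactly zero. Entry `(i, j)` is the influence of node `j` (column,
#' source) on node `i` (row, target).
#'
#' @param factor an optimized `spectral_factor` (see [optimize_unitary()]).
#' @return List with `weights` (complex coupling slice), `signed` (real part,
#'   the signed-strength view), `frequency`.
#' @export
extract_connectivity <- function(factor) {
  stopifnot(inherits(factor, "spectral_factor"))
  if (is.null(factor$b)) stop("factor has not been optimized yet")
  b <- fix_phases(factor$b)
  d <- Re(diag(b))
  n <- nrow(b)
  bad <- d == 0
  if (any(bad))
    warning(sprintf("zero diagonal in row(s) %s: emitted as missing",
                    paste(which(bad), collapse = ", ")))
  dsafe <- ifelse(bad, 1, d)
  G <- diag(1 + 0i, n) - b / dsafe  # row-normalize: row i divided by d[i]
  diag(G) <- 0 + 0i
  G[bad, ] <- NA
  list(weights = G, signed = Re(G), frequency = factor$frequency)
}

#' Full per-frequency estimation pipeline
#'
#' Runs Welch CSD estimation, then per frequency bin: positive-definite
#' square root of the inverse slice, sparse unitary rotation, phase fixing
#' and coupling extraction. Frequencies are processed independently.
#'
#' @param ts a [time_series_set()].
#' @param config an [ec_config()] list of estimation parameters.
#' @param csd optional precomputed `cross_spectral_density` (skips the Welch
#'   step; bins are still selected by `config$freq_bins`).
#' @return An object of class `connectivity_estimate`: `weights` (complex
#'   `n x n x F`), `signed_weights` (real part), `significant` (NULL until
#'   [apply_significance()]), `frequencies`, `nfft`, `convergence`
#'   (per-frequency data frame), `config`, `config_hash`.
#' @export
estimate_pipeline <- function(ts, config = ec_config(), csd = NULL) {
  config <- as_ec_config(config)
  if (is.null(csd)) {
    nfft <- resolve_nfft(ts, config)
    csd <- welch_csd(ts, nfft, config$overlap, config$window, config$detrend)
  }
  est <- estimate_from_csd(csd, config)
  est$config_hash <- config_hash(config)
  est
}

# core estimation loop shared by the pipeline, the null replicates and the
# bootstrap replicates
estimate_from_csd <- function(csd, config) {
  bins <- config$freq_bins %||% seq_along(csd$frequencies)
  if (any(bins < 1 | bins > length(csd$frequencies)))
    stop("`freq_bins` outside the available frequency range")
  n <- dim(csd$matrices)[1]
  F <- length(bins)
  weights <- array(NA_complex_, dim = c(n, n, F))
  conv <- data.frame(frequency = csd$frequencies[bins], cost = NA_real_,
                     n_iter = NA_integer_, converged = NA,
                     ridge = NA_real_, condition = NA_real_)
  opt_seeds <- child_seeds(config$seed, F)
  for (k in seq_len(F)) {
    slice <- csd$matrices[, , bins[k]]
    fct <- tryCatch(
      make_factor_safe(slice, config, csd$frequencies[bins[k]]),
      error = function(e)
        stop(sprintf("frequency %.4g Hz: %s", csd$frequencies[bins[k]],
                     conditionMessage(e)), call. = FALSE))
    fct <- optimize_unitary(fct, max_iter = config$max_iter, tol = config$tol,
                            smoothing_schedule = config$smoothing_schedule,
                            restarts = config$restarts, seed = opt_seeds[[k]],
                            armijo_c = config$armijo_c)
    out <- extract_connectivity(fct)
    weights[, , k] <- out$weights
    conv$cost[k] <- fct$final_cost
    conv$n_iter[k] <- fct$n_iter
    conv$converged[k] <- fct$converged
    conv$ridge[k] <- fct$regularization
    conv$condition[k] <- fct$condition
  }
  structure(list(weights = weights, signed_weights = Re(weights),
                 significant = NULL, frequencies = csd$frequencies[bins],
                 nfft = csd$nfft, convergence = conv, config = config),
            class = "connectivity_estimate")
}

# ridge only when the slice is numerically singular (logged via the factor)
make_factor_safe <- function(slice, config, frequency) {
  if (config$ridge > 0)
    return(initial_factor(slice, ridge = config$ridge, frequency = frequency))
  tryCatch(initial_factor(slice, ridge = 0, frequency = frequency),
           error = function(e) {
             if (!grepl("singular", conditionMessage(e))) stop(e)
             initial_factor(slice, ridge = config$ridge_auto,
                            frequency = frequency)
           })
}

resolve_nfft <- function(ts, config) {
  if (identical(config$nfft, "auto"))
    choose_nfft(n_samples(ts), n_nodes(ts), config$hrf_correction)
  else as.integer(config$nfft)
}

#' @export
print.connectivity_estimate <- function(x, ...) {
  cat(sprintf(paste0("connectivity_estimate: %d nodes, %d frequencies ",
                     "(%.4g-%.4g Hz)%s\n"),
              dim(x$weights)[1], length(x$frequencies), min(x$frequencies),
              max(x$frequencies),
              if (is.null(x$significant)) "" else ", thresholded"))
  invisible(x)
}

#' Per-frequency significance thresholds from the segment-shuffled null
#'
#' For each null replicate, the segment order is shuffled independently per
#' channel, the CSD recomputed, and the full estimation run; all off-diagonal
#' signed weights of the replicates are pooled per frequency into one
#' empirical null distribution whose `alpha/2` and `1 - alpha/2` quantiles
#' give the lower and upper thresholds. Since null "connections" are largely
#' independent, a small number of replicates yields a large pooled sample
#' (`n_null * n * (n-1)` values per frequency).
#'
#' @param ts a [time_series_set()].
#' @param config an [ec_config()].
#' @param n_null number of shuffled-null CSD replicates (>= 1).
#' @param alpha two-sided significance level.
#' @param seed integer seed for the shuffles.
#' @return An object of class `threshold_set`: `lower`, `upper` (per
#'   frequency), `frequencies`, `alpha`, `n_null_values`, `pooled` flag.
#' @export
null_thresholds <- function(ts, config = ec_config(), n_null = 10L,
                            alpha = 0.05, seed = NULL) {
  config <- as_ec_config(config)
  if (n_null < 1L) stop("`n_null` must be >= 1")
  nfft <- resolve_nfft(ts, config)
  sf <- segment_ffts(ts, nfft, config$overlap, config$window, config$detrend)
  n <- n_nodes(ts)
  seeds <- child_seeds(seed, n_null)
  reps <- vector("list", n_null)
  for (r in seq_len(n_null)) {
    perm <- run_seeded(seeds[[r]], t(replicate(n, sample.int(sf$n_segments))))
    csd <- csd_from_segffts(sf, perm = perm)
    reps[[r]] <- tryCatch(estimate_from_csd(csd, config),
                          error = function(e) {
                            warning(sprintf("null replicate %d dropped: %s",
                                            r, conditionMessage(e)))
                            NULL
                          })
  }
  reps <- Filter(Negate(is.null), reps)
  if (length(reps) < n_null / 2)
    stop("more than half of the null replicates failed")
  freqs <- reps[[1]]$frequencies
  pool <- lapply(seq_along(freqs), function(k)
    unlist(lapply(reps, function(r) offdiag_values(r$signed_weights[, , k]))))
  if (isTRUE(config$pool_frequencies)) {
    all_vals <- unlist(pool)
    pool <- replicate(length(freqs), all_vals, simplify = FALSE)
  }
  lower <- vapply(pool, stats::quantile, numeric(1), probs = alpha / 2,
                  na.rm = TRUE, names = FALSE)
  upper <- vapply(pool, stats::quantile, numeric(1), probs = 1 - alpha / 2,
                  na.rm = TRUE, names = FALSE)
  structure(list(lower = lower, upper = upper, frequencies = freqs,
                 alpha = alpha, n_null_values = lengths(pool),
                 n_replicates = length(reps),
                 pooled = isTRUE(config$pool_frequencies)),
            class = "threshold_set")
}

#' Bootstrap confidence intervals for the connection strengths
#'
#' For each bootstrap replicate, segments are drawn with replacement (the
#' same resample for every channel), the CSD recomputed and the estimation
#' rerun. Assuming an asymptotically Gaussian distribution of each
#' connection strength across replicates, the interval is
#' `mean +- z(level) * sd`.
#'
#' @param ts a [time_series_set()].
#' @param config an [ec_config()].
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param level confidence level (e.g. 0.95).
#' @param seed integer seed.
#' @param indices_list optional list of explicit resample index vectors
#'   (test hook).
#' @return An object of class `confidence_intervals`: `lower`, `upper`,
#'   `mean`, `sd` (all `n x n x F`), `frequencies`, `level`, `n_boot`.
#' @export
bootstrap_cis <- function(ts, config = ec_config(), n_boot = 1000L,
                          level = 0.95, seed = NULL, indices_list = NULL) {
  config <- as_ec_config(config)
  if (is.null(indices_list) && n_boot < 2L) stop("`n_boot` must be >= 2")
  nfft <- resolve_nfft(ts, config)
  sf <- segment_ffts(ts, nfft, config$overlap, config$window, config$detrend)
  if (is.null(indices_list)) {
    seeds <- child_seeds(seed, n_boot)
    indices_list <- lapply(seeds, function(s)
      run_seeded(s, sample.int(sf$n_segments, sf$n_segments, replace = TRUE)))
  }
  reps <- vector("list", length(indices_list))
  for (r in seq_along(indices_list)) {
    csd <- csd_from_segffts(sf, idx = indices_list[[r]])
    reps[[r]] <- tryCatch(estimate_from_csd(csd, config)$signed_weights,
                          error = function(e) {
                            warning(sprintf("bootstrap replicate %d dropped: %s",
                                            r, conditionMessage(e)))
                            NULL
                          })
  }
  reps <- Filter(Negate(is.null), reps)
  if (length(reps) < length(indices_list) / 2)
    stop("more than half of the bootstrap replicates failed")
  arr <- simplify2array(reps)  # n x n x F x R
  mean_w <- apply(arr, 1:3, mean)
  sd_w <- apply(arr, 1:3, stats::sd)
  z <- stats::qnorm(1 - (1 - level) / 2)
  onesided <- sf$freqs_full[seq(2L, sf$nfft %/% 2L)]
  freqs <- onesided[config$freq_bins %||% seq_along(onesided)]
  structure(list(lower = mean_w - z * sd_w, upper = mean_w + z * sd_w,
                 mean = mean_w, sd = sd_w, frequencies = freqs,
                 level = level, n_boot = length(reps)),
            class = "confidence_intervals")
}

#' Apply null thresholds (and optionally bootstrap intervals) to an estimate
#'
#' A connection is significant when its signed weight falls outside the
#' per-frequency null interval `(lower, upper)` AND, if confidence intervals
#' are supplied, its interval excludes zero. Non-significant weights are
#' zeroed in `signed_weights`; the complex `weights` are kept untouched.
#'
#' @param est a `connectivity_estimate`.
#' @param thr a `threshold_set` with matching frequencies.
#' @param cis optional `confidence_intervals` with matching frequencies.
#' @return The estimate with `significant` (logical `n x n x F`) filled and
#'   `signed_weights` masked.
#' @export
apply_significance <- function(est, thr, cis = NULL) {
  stopifnot(inherits(est, "connectivity_estimate"),
            inherits(thr, "threshold_set"))
  if (!isTRUE(all.equal(est$frequencies, thr$frequencies)))
    stop("threshold frequencies do not match the estimate")
  if (!is.null(cis) && !isTRUE(all.equal(est$frequencies, cis$frequencies)))
    stop("confidence-interval frequencies do not match the estimate")
  sw <- est$signed_weights
  mask <- array(FALSE, dim = dim(sw))
  for (k in seq_along(est$frequencies)) {
    m <- sw[, , k] < thr$lower[k] | sw[, , k] > thr$upper[k]
    if (!is.null(cis))
      m <- m & !(cis$lower[, , k] <= 0 & cis$upper[, , k] >= 0)
    m[is.na(m)] <- FALSE
    diag(m) <- FALSE
    mask[, , k] <- m
  }
  mask[sw == 0] <- FALSE
  est$significant <- mask
  est$signed_weights[!mask] <- 0
  est
}

#' Mirror (symmetrize) a directed network
#'
#' Adds the transposed matrix: `net + t(net)`. Used for comparison against
#' symmetric references such as structural connectivity.
#'
#' @param net square numeric matrix.
#' @return Symmetric matrix.
#' @export
mirror_network <- function(net) {
  net <- as.matrix(net)
  if (nrow(net) != ncol(net)) stop("matrix must be square")
  net + t(net)
}

#' Consensus network across realizations or subjects
#'
#' An edge is kept iff it is nonzero in at least `min_fraction` of the input
#' networks (ties kept: the comparison is `>=`); a kept edge's weight is the
#' mean of its nonzero values, all other entries are zero.
#'
#' @param nets list of equal-sized square matrices (e.g. thresholded signed
#'   weights per realization), or an `n x n x R` array.
#' @param min_fraction minimum occurrence fraction, e.g. 0.5.
#' @return Square consensus matrix.
#' @export
consensus_network <- function(nets, min_fraction = 0.5) {
  if (is.array(nets) && length(dim(nets)) == 3L)
    nets <- lapply(seq_len(dim(nets)[3]), function(r) nets[, , r])
  if (length(nets) < 1L) stop("need at least one network")
  dims <- vapply(nets, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all networks must have the same shape")
  arr <- simplify2array(nets)
  present <- arr != 0
  count <- apply(present, 1:2, sum)
  keep <- count >= min_fraction * length(nets) & count > 0
  sums <- apply(arr, 1:2, sum)
  out <- matrix(0, dims[1, 1], dims[2, 1])
  out[keep] <- sums[keep] / count[keep]
  out
}

#' Per-band consensus networks from a frequency-resolved estimate
#'
#' Groups frequency bins into bands defined by `band_edges` (band `b` covers
#' `[edge_b, edge_{b+1})`) and applies the consensus rule across the bins of
#' each band: an edge is kept when present in at least
#' `within_band_fraction` of the band's bins, with its weight averaged over
#' the bins where it is present.
#'
#' @param est a `connectivity_estimate` (thresholded or not).
#' @param band_edges increasing vector of band boundaries in Hz (length
#'   `n_bands + 1`).
#' @param within_band_fraction minimum occurrence fraction within a band.
#' @return Named list of square matrices, one per band.
#' @export
band_summary <- function(est, band_edges, within_band_fraction = 2 / 3) {
  stopifnot(inherits(est, "connectivity_estimate"))
  if (length(band_edges) < 2L || any(diff(band_edges) <= 0))
    stop("`band_edges` must be increasing with at least two values")
  out <- list()
  for (b in seq_len(length(band_edges) - 1L)) {
    bins <- which(est$frequencies >= band_edges[b] &
                  est$frequencies < band_edges[b + 1])
    if (length(bins) == 0)
      stop(sprintf("band [%g, %g) Hz contains no frequency bins",
                   band_edges[b], band_edges[b + 1]))
    nets <- lapply(bins, function(k) est$signed_weights[, , k])
    name <- sprintf("%g-%gHz", band_edges[b], band_edges[b + 1])
    out[[name]] <- consensus_network(nets, within_band_fraction)
  }
  out
}
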