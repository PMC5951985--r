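#' Simulated BOLD-like benchmark dataset
#'
#' Composes the generator: harmonic intrinsic drive -> lagged VAR recursion
#' on a ground-truth network -> hemodynamic (double-gamma) convolution ->
#' observation noise at a controlled SNR. Defaults reproduce the package's
#' reference simulation study: 100-node, 15%-density VAR(50) networks at
#' `dt = 0.1` s with the canonical hemodynamic response.
#'
#' @param network a [sample_network()] result.
#' @param n_samples number of returned samples.
#' @param dt sampling interval in seconds.
#' @param noise a [noise_spec()], or `NULL` for noiseless output.
#' @param hrf an [hrf_spec()], a list of per-node [hrf_spec()]s, or `NULL`
#'   to skip hemodynamic convolution.
#' @param drive_args named list of overrides for [gen_intrinsic_drive()].
#' @param seed integer seed (drive and noise realizations derive from it).
#' @return A [time_series_set()].
#' @export
benchmark_dataset <- function(network, n_samples, dt = 0.1, noise = NULL,
                              hrf = hrf_spec("canonical", dt = dt),
                              drive_args = list(), seed = NULL) {
  stopifnot(inherits(network, "ground_truth_network"))
  seeds <- child_seeds(seed, 2L)
  burn <- 10L * network$order
  drive <- do.call(gen_intrinsic_drive,
                   c(list(n_nodes = network$n_nodes,
                          n_samples = n_samples + burn, dt = dt,
                          seed = seeds[[1]]), drive_args))
  y <- simulate_var(network, drive, n_samples, burn_in = burn)
  if (!is.null(hrf)) {
    kernels <- if (inherits(hrf, "hrf_spec")) make_hrf(hrf)
               else lapply(hrf, make_hrf)
    y <- convolve_hrf(y, kernels)
  }
  if (!is.null(noise)) {
    noise$seed <- noise$seed %||% seeds[[2]]
    y <- add_observation_noise(y, noise)
  }
  time_series_set(y, dt = dt)
}

#' Benchmark recovery run: estimate and score against the ground truth
#'
#' Generates `n_real` noise/drive realizations of the same network, runs the
#' estimation pipeline on the requested low-frequency bins and reports the
#' off-diagonal weight correlation with the true adjacency per realization
#' and bin. Optionally thresholds each realization with the shuffled-segment
#' null, for consensus-network analyses.
#'
#' @param network a [sample_network()] result.
#' @param n_real number of realizations.
#' @param n_samples samples per realization.
#' @param noise_kind,snr observation-noise condition (see [noise_spec()]).
#' @param dt sampling interval (s).
#' @param config an [ec_config()]; `freq_bins` selects the analysis bins.
#' @param threshold also compute null thresholds and masked weights.
#' @param seed integer seed; realization seeds derive from it.
#' @return List with `correlations` (`n_real x n_bins` matrix), `estimates`
#'   (list of `connectivity_estimate`s, thresholded when requested),
#'   `frequencies`, `network`.
#' @export
benchmark_recovery <- function(network, n_real, n_samples,
                               noise_kind = "white", snr = 5, dt = 0.1,
                               config = ec_config(freq_bins = 1:3,
                                                  restarts = 1L),
                               threshold = FALSE, seed = 1L) {
  config <- as_ec_config(config)
  seeds <- child_seeds(seed, 2L * n_real)
  ests <- vector("list", n_real)
  cors <- NULL
  for (r in seq_len(n_real)) {
    ts <- benchmark_dataset(network, n_samples, dt = dt,
                            noise = noise_spec(noise_kind, snr = snr),
                            seed = seeds[[r]])
    est <- estimate_pipeline(ts, config)
    # raw-estimate correlations (parameter-influence analyses use the
    # unthresholded weights)
    cors <- rbind(cors, vapply(seq_along(est$frequencies), function(k)
      weight_correlation(est$signed_weights[, , k], network$adjacency),
      numeric(1)))
    if (threshold) {
      thr <- null_thresholds(ts, config, n_null = config$n_null,
                             alpha = config$alpha,
                             seed = seeds[[n_real + r]])
      est <- apply_significance(est, thr)
    }
    ests[[r]] <- est
  }
  list(correlations = cors, estimates = ests,
       frequencies = ests[[1]]$frequencies, network = network)
}
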