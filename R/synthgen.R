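#' Sample a ground-truth directed network with lagged coupling kernels
#'
#' Draws a directed Erdos-Renyi graph with signed uniform weights and builds
#' the stack of lag kernels `G(p) = A * d(p)` for `p = 1..order`, where `d(p)`
#' is a logistic decay over lags and `A` the base adjacency; `G(0)` is the
#' identity (instantaneous self term). Weights are rescaled globally so the
#' companion matrix of the implied VAR process has spectral radius
#' `target_radius` (< 1, i.e. the process is stable); the applied rescale
#' factor is recorded in the result.
#'
#' Entry `(i, j)` of the adjacency is the influence of node `j` (source,
#' column) on node `i` (target, row); the diagonal of the adjacency view is
#' zero.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param p_connect connection probability for each ordered off-diagonal pair,
#'   in (0, 1) (or exactly 1 for a fully connected test network).
#' @param order VAR order, i.e. number of lags (>= 1).
#' @param weight_range magnitude range `c(min, max)` of the uniform edge
#'   weights before rescaling.
#' @param neg_fraction probability that an edge is inhibitory (negative).
#' @param decay_midpoint,decay_steepness logistic-decay parameters: the decay
#'   factor at lag p is `1 / (1 + exp(steepness * (p - midpoint)))`.
#' @param target_radius desired companion spectral radius after rescaling
#'   (must be < 1 for stability).
#' @param seed integer seed; same seed gives a bit-identical network.
#' @return An object of class `ground_truth_network` with fields `n_nodes`,
#'   `adjacency` (rescaled signed weights), `lag_kernels` (n x n x (order+1)
#'   array, slice p+1 holds `G(p)`), `order`, `decay`, `rescale_factor`,
#'   `spectral_radius`, `seed`.
#' @export
sample_network <- function(n_nodes, p_connect = 0.15, order = 50L,
                           weight_range = c(0.1, 1), neg_fraction = 0.5,
                           decay_midpoint = 10, decay_steepness = 0.25,
                           target_radius = 0.95, seed = NULL) {
  if (n_nodes < 2L) stop("`n_nodes` must be >= 2")
  if (p_connect <= 0 || p_connect > 1) stop("`p_connect` must be in (0, 1]")
  if (order < 1L) stop("`order` must be >= 1")
  if (target_radius <= 0 || target_radius >= 1)
    stop("`target_radius` must be in (0, 1)")
  run_seeded(seed, {
    n <- as.integer(n_nodes)
    A <- matrix(0, n, n)
    off <- which(row(A) != col(A))
    present <- stats::runif(length(off)) < p_connect
    k <- sum(present)
    if (k > 0) {
      w <- stats::runif(k, weight_range[1], weight_range[2])
      sgn <- ifelse(stats::runif(k) < neg_fraction, -1, 1)
      A[off[present]] <- w * sgn
    }
    decay <- 1 / (1 + exp(decay_steepness * (seq_len(order) - decay_midpoint)))
    kernels_for <- function(s) {
      K <- array(0, dim = c(n, n, order))
      for (p in seq_len(order)) K[, , p] <- s * A * decay[p]
      K
    }
    radius_for <- function(s)
      cpp_companion_radius(kernels_for(s), n_iter = 400L, n_burn = 100L)
    s <- 1
    rho <- radius_for(s)
    if (abs(rho - target_radius) > 0.005 * target_radius) {
      if (rho <= 0) stop("degenerate network: zero companion spectral radius")
      # radius is monotone increasing in the global coupling scale; bracket
      # and bisect on log-scale
      lo <- s; hi <- s
      while (radius_for(hi) < target_radius && hi < 1e6) hi <- hi * 2
      while (radius_for(lo) > target_radius && lo > 1e-6) lo <- lo / 2
      for (i in 1:40) {
        s <- sqrt(lo * hi)
        rho <- radius_for(s)
        if (abs(rho - target_radius) < 0.002 * target_radius) break
        if (rho < target_radius) lo <- s else hi <- s
      }
    }
    if (rho >= 1)
      stop(sprintf("network unstable after rescaling (spectral radius %.4f)", rho))
    A <- s * A
    lag_kernels <- array(0, dim = c(n, n, order + 1L))
    lag_kernels[, , 1] <- diag(n)
    for (p in seq_len(order)) lag_kernels[, , p + 1L] <- A * decay[p]
    structure(list(n_nodes = n, adjacency = A, lag_kernels = lag_kernels,
                   order = as.integer(order), decay = decay,
                   rescale_factor = s, spectral_radius = rho, seed = seed),
              class = "ground_truth_network")
  })
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf(paste0("ground_truth_network: %d nodes, %d directed edges, ",
                     "VAR order %d, spectral radius %.3f\n"),
              x$n_nodes, sum(x$adjacency != 0), x$order, x$spectral_radius))
  invisible(x)
}

#' Intrinsic harmonic drive for the simulated neuronal activity
#'
#' Each node's drive is a superposition of `n_harmonics` sinusoids with
#' node-specific random frequencies and phases, plus additive Gaussian white
#' noise. This emulates the oscillatory character of resting-state activity
#' while keeping the per-node drives mutually independent (diagonal drive
#' cross-spectrum), which is the identifiability assumption of the estimator.
#'
#' @param n_nodes,n_samples dimensions of the returned matrix.
#' @param dt sampling interval in seconds.
#' @param n_harmonics sinusoids per node (0 gives pure white noise).
#' @param freq_range frequency range in Hz; upper end must be below Nyquist.
#' @param amplitude amplitude of each sinusoid.
#' @param noise_level standard deviation of the additive white component.
#' @param seed integer seed.
#' @return `n_nodes x n_samples` matrix.
#' @export
gen_intrinsic_drive <- function(n_nodes, n_samples, dt, n_harmonics = 10L,
                                freq_range = c(0.01, 0.5), amplitude = 1,
                                noise_level = 1, seed = NULL) {
  if (n_samples < 1L) stop("`n_samples` must be >= 1")
  if (max(freq_range) >= 1 / (2 * dt))
    stop(sprintf("drive frequencies must be below Nyquist (%g Hz)", 1 / (2 * dt)))
  run_seeded(seed, {
    tgrid <- (seq_len(n_samples) - 1) * dt
    drive <- matrix(0, n_nodes, n_samples)
    for (i in seq_len(n_nodes)) {
      x <- numeric(n_samples)
      if (n_harmonics > 0) {
        f <- stats::runif(n_harmonics, freq_range[1], freq_range[2])
        ph <- stats::runif(n_harmonics, 0, 2 * pi)
        for (k in seq_len(n_harmonics))
          x <- x + amplitude * sin(2 * pi * f[k] * tgrid + ph[k])
      }
      if (noise_level > 0) x <- x + stats::rnorm(n_samples, sd = noise_level)
      drive[i, ] <- x
    }
    drive
  })
}

#' Simulate the lagged vector-autoregressive dynamics
#'
#' Applies the recursion `y(t) = drive(t) + sum_p G(p) y(t-p)` with zero
#' initial history, discards an initial burn-in segment, and returns the last
#' `n_samples` columns. The drive must supply `n_samples + burn_in` columns.
#'
#' @param network a `ground_truth_network`.
#' @param drive matrix with `n_nodes` rows and at least `n_samples + burn_in`
#'   columns.
#' @param n_samples number of samples to return.
#' @param burn_in samples discarded from the start (default 10 x order).
#' @param overflow_guard simulation aborts with an instability error if any
#'   |y| exceeds this value.
#' @return `n_nodes x n_samples` matrix of simulated activity.
#' @export
simulate_var <- function(network, drive, n_samples,
                         burn_in = 10L * network$order, overflow_guard = 1e8) {
  stopifnot(inherits(network, "ground_truth_network"))
  drive <- as.matrix(drive)
  if (nrow(drive) != network$n_nodes)
    stop("`drive` must have one row per network node")
  total <- n_samples + burn_in
  if (ncol(drive) < total)
    stop(sprintf("`drive` has %d columns; need n_samples + burn_in = %d",
                 ncol(drive), total))
  kernels <- network$lag_kernels[, , -1L, drop = FALSE]  # G(1)..G(order)
  Y <- cpp_simulate_var(kernels, drive[, seq_len(total), drop = FALSE],
                        overflow_guard)
  if (!all(is.finite(Y))) stop("VAR simulation produced non-finite values")
  Y[, (burn_in + 1L):total, drop = FALSE]
}

#' Hemodynamic response specification
#'
#' Parameters of the double-gamma hemodynamic response: a positive response
#' gamma lobe followed by a weighted negative undershoot lobe. The canonical
#' kind uses shape 6 / scale 1 s (peak ~5 s) for the response and shape 16 /
#' scale 1 s for the undershoot with relative weight 1/6. The randomized kind
#' perturbs the onsets of both lobes within `+-onset_bound` seconds and the
#' dispersion (gamma scale) and amplitude of each lobe by factors in
#' `[1/factor_bound, factor_bound]`.
#'
#' @param kind `"canonical"` or `"randomized"`.
#' @param dt sampling interval of the kernel in seconds.
#' @param onset_bound maximum onset shift in seconds (randomized kind).
#' @param factor_bound maximum dispersion/amplitude factor (>= 1).
#' @param duration kernel support in seconds (>= 30 s recommended).
#' @param seed integer seed for the randomized kind.
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(kind = c("canonical", "randomized"), dt,
                     onset_bound = 5, factor_bound = 5, duration = 32,
                     seed = NULL) {
  kind <- match.arg(kind)
  if (dt <= 0) stop("`dt` must be positive")
  if (factor_bound < 1) stop("`factor_bound` must be >= 1")
  if (onset_bound < 0) stop("`onset_bound` must be >= 0")
  structure(list(kind = kind, dt = dt, onset_bound = onset_bound,
                 factor_bound = factor_bound, duration = duration,
                 seed = seed),
            class = "hrf_spec")
}

double_gamma <- function(tgrid, onset1, onset2, disp1, disp2, amp1, amp2) {
  g <- function(t, shape, scale)
    ifelse(t > 0, stats::dgamma(t, shape = shape, scale = scale), 0)
  amp1 * g(tgrid - onset1, 6, disp1) - (amp2 / 6) * g(tgrid - onset2, 16, disp2)
}

#' Evaluate a hemodynamic response kernel
#'
#' @param spec an [hrf_spec()].
#' @return Numeric kernel vector sampled at `spec$dt`, normalized to unit peak
#'   of the canonical kernel scale (the canonical kernel has peak 1).
#' @export
make_hrf <- function(spec) {
  stopifnot(inherits(spec, "hrf_spec"))
  tgrid <- seq(0, spec$duration, by = spec$dt)
  if (spec$kind == "canonical") {
    h <- double_gamma(tgrid, 0, 0, 1, 1, 1, 1)
  } else {
    h <- run_seeded(spec$seed, {
      b <- spec$factor_bound
      onsets <- stats::runif(2, -spec$onset_bound, spec$onset_bound)
      disps <- exp(stats::runif(2, -log(b), log(b)))
      amps <- exp(stats::runif(2, -log(b), log(b)))
      if (any(disps <= 0)) stop("nonpositive dispersion after perturbation")
      double_gamma(tgrid, onsets[1], onsets[2], disps[1], disps[2],
                   amps[1], amps[2])
    })
  }
  peak_canonical <- max(double_gamma(tgrid, 0, 0, 1, 1, 1, 1))
  h / peak_canonical
}

#' Convolve activity with hemodynamic response kernel(s)
#'
#' Causal one-sided convolution with zero initial history; the output is
#' truncated to the input length. A single kernel is applied to every node; a
#' list (or matrix with one row per node) applies node-specific kernels, as
#' in the hemodynamic-variability experiment.
#'
#' @param series `n x T` activity matrix.
#' @param kernels numeric vector (shared kernel), or list of length `n`.
#' @return `n x T` matrix of BOLD-like responses.
#' @export
convolve_hrf <- function(series, kernels) {
  series <- as.matrix(series)
  n <- nrow(series); T <- ncol(series)
  if (is.numeric(kernels) && is.null(dim(kernels)))
    kernels <- rep(list(kernels), n)
  if (is.matrix(kernels)) kernels <- split(kernels, row(kernels))
  if (length(kernels) != n)
    stop(sprintf("got %d kernels for %d nodes", length(kernels), n))
  out <- matrix(0, n, T)
  for (i in seq_len(n)) {
    h <- kernels[[i]]
    if (length(h) > T) stop("kernel longer than the time series")
    y <- stats::convolve(series[i, ], rev(h), type = "open")  # full convolution
    out[i, ] <- y[seq_len(T)]
  }
  dimnames(out) <- dimnames(series)
  out
}

#' Observation-noise specification
#'
#' @param kind `"white"` (i.i.d. Gaussian), `"temporal"` (AR(1)) or
#'   `"mixture"` (`mix_white * white + mix_temporal * temporal`, components
#'   normalized to unit variance before mixing).
#' @param snr target ratio of signal variance to noise variance, per node;
#'   `Inf` means noiseless.
#' @param ar_coefficient AR(1) coefficient of the temporal component, in
#'   (-1, 1).
#' @param mix_white,mix_temporal mixture weights.
#' @param seed integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("white", "temporal", "mixture"), snr,
                       ar_coefficient = 0.5, mix_white = 0.3,
                       mix_temporal = 0.7, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be > 0 (or Inf)")
  if (abs(ar_coefficient) >= 1) stop("`ar_coefficient` must be in (-1, 1)")
  structure(list(kind = kind, snr = snr, ar_coefficient = ar_coefficient,
                 mix_white = mix_white, mix_temporal = mix_temporal,
                 seed = seed),
            class = "noise_spec")
}

#' Add observation noise at a controlled signal-to-noise ratio
#'
#' Noise is generated per node and scaled so that
#' `var(signal) / var(noise) == snr` for each node. The temporal kind is an
#' AR(1) process; the mixture combines unit-variance white and temporal
#' components with the configured weights before the final SNR scaling.
#'
#' @param series `n x T` signal matrix.
#' @param spec a [noise_spec()].
#' @return `n x T` noisy matrix.
#' @export
add_observation_noise <- function(series, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  series <- as.matrix(series)
  if (is.infinite(spec$snr)) return(series)
  n <- nrow(series); T <- ncol(series)
  sig_var <- apply(series, 1, stats::var)
  if (any(sig_var == 0))
    stop("zero-variance signal row: SNR is undefined")
  run_seeded(spec$seed, {
    noise <- matrix(0, n, T)
    for (i in seq_len(n)) {
      e <- switch(spec$kind,
        white = stats::rnorm(T),
        temporal = ar1_noise(T, spec$ar_coefficient),
        mixture = {
          w <- stats::rnorm(T)
          a <- ar1_noise(T, spec$ar_coefficient)
          spec$mix_white * w / stats::sd(w) +
            spec$mix_temporal * a / stats::sd(a)
        })
      e <- e / stats::sd(e) * sqrt(sig_var[i] / spec$snr)
      noise[i, ] <- e
    }
    series + noise
  })
}

# unit-innovation AR(1) sample with stationary start
ar1_noise <- function(T, phi) {
  as.numeric(stats::filter(stats::rnorm(T), phi, method = "recursive",
                           init = stats::rnorm(1) / sqrt(1 - phi^2)))
}

#' Downsample a time series by an integer factor
#'
#' Keeps every `factor`-th sample, after an anti-alias low-pass step by
#' default (set `anti_alias = FALSE` for naive decimation). For a
#' `time_series_set` input, the sampling-interval metadata is multiplied by
#' the factor.
#'
#' @param x a `time_series_set` or an `n x T` matrix.
#' @param factor integer decimation factor (>= 1, < number of samples).
#' @param anti_alias apply an FIR low-pass before decimation.
#' @return Same type as `x`, with `floor(T / factor)` samples.
#' @export
downsample <- function(x, factor, anti_alias = TRUE) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1")
  mat <- if (inherits(x, "time_series_set")) x$data else as.matrix(x)
  T <- ncol(mat)
  if (factor >= T) stop("`factor` must be smaller than the number of samples")
  if (factor == 1L) return(x)
  dec <- if (anti_alias) {
    t(apply(mat, 1, function(row)
      signal::decimate(row, factor, ftype = "fir")[seq_len(T %/% factor)]))
  } else {
    mat[, seq(1, by = factor, length.out = T %/% factor), drop = FALSE]
  }
  if (inherits(x, "time_series_set"))
    time_series_set(dec, dt = x$dt * factor, node_labels = x$node_labels)
  else dec
}
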