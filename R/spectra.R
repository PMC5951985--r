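#' Choose the number of FFT bins for the Welch cross-spectral density
#'
#' For the inverse of the estimated CSD to exist, the number of frequency
#' bins must be smaller than the degrees of freedom per node, i.e.
#' `nfft < n_samples / n_nodes`. This returns the largest power of two
#' strictly below that ratio; with `hrf_correction` (hemodynamic convolution
#' further reduces the effective degrees of freedom) the next lower power of
#' two is returned.
#'
#' @param n_samples,n_nodes dimensions of the time series.
#' @param hrf_correction halve once more to compensate for hemodynamic
#'   smoothing.
#' @return Integer NFFT (>= 4; smaller values raise an error).
#' @export
choose_nfft <- function(n_samples, n_nodes, hrf_correction = FALSE) {
  if (n_samples <= n_nodes) stop("need more samples than nodes")
  nfft <- largest_pow2_below(n_samples / n_nodes)
  if (isTRUE(hrf_correction)) nfft <- nfft %/% 2L
  if (is.na(nfft) || nfft < 4L)
    stop(sprintf("too few samples per node: NFFT would be %s", nfft))
  as.integer(nfft)
}

window_vector <- function(window, nfft) {
  switch(window,
         hanning = , hann = 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))),
         boxcar = , rectangular = rep(1, nfft),
         stop(sprintf("unknown window '%s'", window)))
}

#' Windowed segment Fourier transforms
#'
#' Splits each channel into overlapping segments of length `nfft`, removes
#' the per-segment mean (when `detrend`), applies the window and Fourier
#' transforms. This single segmentation underlies the Welch estimator and
#' both resampling estimators (segment-shuffled null and bootstrap), so their
#' normalizations are identical by construction.
#'
#' @param ts a [time_series_set()] (or matrix plus `dt`).
#' @param nfft segment length (a power of two is conventional).
#' @param overlap fraction of overlap between consecutive segments, in
#'   `[0, 1)`.
#' @param window `"hanning"` (default) or `"boxcar"`.
#' @param detrend remove the per-segment mean before windowing.
#' @param dt sampling interval, only used when `ts` is a bare matrix.
#' @return List with `ffts` (complex array `n x nfft x n_segments`),
#'   `freqs_full` (all `nfft` bin frequencies in Hz), `norm` (sum of squared
#'   window values; the CSD normalization divisor), `nfft`, `n_segments`,
#'   `window`, `overlap`, `dt`.
#' @export
segment_ffts <- function(ts, nfft, overlap = 0.5, window = "hanning",
                         detrend = TRUE, dt = NULL) {
  ts <- as_time_series_set(ts, dt)
  nfft <- as.integer(nfft)
  T <- n_samples(ts); n <- n_nodes(ts)
  if (nfft > T) stop("`nfft` exceeds the number of samples")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  step <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq(1L, T - nfft + 1L, by = step)
  if (length(starts) < 2L)
    stop("fewer than 2 segments: increase samples or reduce nfft")
  w <- window_vector(window, nfft)
  out <- array(0i, dim = c(n, nfft, length(starts)))
  for (k in seq_along(starts)) {
    X <- ts$data[, starts[k]:(starts[k] + nfft - 1L), drop = FALSE]
    if (detrend) X <- X - rowMeans(X)
    X <- X * rep(w, each = n)
    out[, , k] <- t(stats::mvfft(t(X)))
  }
  list(ffts = out, freqs_full = (0:(nfft - 1)) / (nfft * ts$dt),
       norm = sum(w^2), nfft = nfft, n_segments = length(starts),
       window = window, overlap = overlap, dt = ts$dt)
}

# assemble a CSD object from segment FFTs; `perm` (n x n_segments integer
# matrix) applies an independent segment permutation per channel, `idx`
# (integer vector) selects a bootstrap multiset of segments shared across
# channels.  Only one of the two may be given.
csd_from_segffts <- function(sf, perm = NULL, idx = NULL, one_sided = TRUE) {
  n <- dim(sf$ffts)[1]; nfft <- sf$nfft; nseg <- sf$n_segments
  bins <- if (one_sided) seq(2L, nfft %/% 2L) else seq_len(nfft)
  scale <- 1 / (sf$norm * (if (is.null(idx)) nseg else length(idx)))
  mats <- array(0i, dim = c(n, n, length(bins)))
  for (b in seq_along(bins)) {
    Y <- sf$ffts[, bins[b], , drop = TRUE]
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = n)
    diag_unshuffled <- rowMeans(Mod(Y)^2) / sf$norm
    if (!is.null(perm)) {
      for (i in seq_len(n)) Y[i, ] <- Y[i, perm[i, ]]
    }
    if (!is.null(idx)) Y <- Y[, idx, drop = FALSE]
    C <- (Y %*% Conj(t(Y))) * scale
    C <- (C + Conj(t(C))) / 2  # exact Hermitian symmetrization
    if (!is.null(perm)) {
      # shuffling affects only the cross-spectra; power spectra (the
      # diagonal) are preserved exactly, by construction
      diag(C) <- diag_unshuffled
    }
    mats[, , b] <- C
  }
  structure(list(matrices = mats, frequencies = sf$freqs_full[bins],
                 nfft = nfft, n_segments = nseg, window = sf$window,
                 overlap = sf$overlap, dt = sf$dt),
            class = "cross_spectral_density")
}

#' @export
print.cross_spectral_density <- function(x, ...) {
  cat(sprintf(paste0("cross_spectral_density: %d nodes, %d frequencies ",
                     "(%.4g-%.4g Hz), nfft %d, %d segments (%s window, ",
                     "%.0f%% overlap)\n"),
              dim(x$matrices)[1], length(x$frequencies), min(x$frequencies),
              max(x$frequencies), x$nfft, x$n_segments, x$window,
              100 * x$overlap))
  invisible(x)
}

#' Welch estimate of the cross-spectral density
#'
#' Averages outer products of windowed, overlapping segment Fourier
#' transforms: `C(f) = mean_k y_k(f) y_k(f)^* / sum(w^2)`. Under this
#' normalization the mean of the diagonal over all `nfft` bins equals the
#' (windowed) signal variance. Only positive frequencies below Nyquist are
#' returned (the DC bin is excluded: data are segment-mean-removed).
#'
#' @inheritParams segment_ffts
#' @return A `cross_spectral_density` object: `matrices` (complex
#'   `n x n x F` array, each slice Hermitian with real nonnegative diagonal),
#'   `frequencies` (Hz), plus estimation metadata.
#' @export
welch_csd <- function(ts, nfft, overlap = 0.5, window = "hanning",
                      detrend = TRUE, dt = NULL) {
  sf <- segment_ffts(ts, nfft, overlap, window, detrend, dt)
  csd_from_segffts(sf)
}

#' Segment-shuffled null cross-spectral density
#'
#' Shuffles the segment order randomly and independently for each channel
#' before averaging, so that cross-terms pair mismatched segments while each
#' channel's own power spectrum (the diagonal of the CSD) is preserved
#' exactly. Used to build the null distribution of connectivity values.
#'
#' @inheritParams segment_ffts
#' @param seed integer seed for the permutations.
#' @param permutations optional `n x n_segments` integer matrix of explicit
#'   per-channel permutations (test hook; identity rows reproduce
#'   [welch_csd()] exactly).
#' @return A `cross_spectral_density` object.
#' @export
shuffled_null_csd <- function(ts, nfft, overlap = 0.5, window = "hanning",
                              detrend = TRUE, dt = NULL, seed = NULL,
                              permutations = NULL) {
  sf <- segment_ffts(ts, nfft, overlap, window, detrend, dt)
  n <- dim(sf$ffts)[1]
  if (is.null(permutations)) {
    permutations <- run_seeded(seed,
      t(replicate(n, sample.int(sf$n_segments))))
  }
  stopifnot(nrow(permutations) == n, ncol(permutations) == sf$n_segments)
  csd_from_segffts(sf, perm = permutations)
}

#' Bootstrap cross-spectral density
#'
#' Draws one resample of segment indices with replacement, shared across all
#' channels (the segment order stays aligned between channels), and averages
#' the corresponding outer products. Repeated calls with different seeds give
#' the bootstrap distribution of the CSD and of any quantity derived from it.
#'
#' @inheritParams segment_ffts
#' @param seed integer seed for the resample.
#' @param indices optional explicit integer vector of segment indices (test
#'   hook; `1:n_segments` reproduces [welch_csd()] exactly).
#' @return A `cross_spectral_density` object.
#' @export
bootstrap_csd <- function(ts, nfft, overlap = 0.5, window = "hanning",
                          detrend = TRUE, dt = NULL, seed = NULL,
                          indices = NULL) {
  sf <- segment_ffts(ts, nfft, overlap, window, detrend, dt)
  if (is.null(indices)) {
    indices <- run_seeded(seed,
      sample.int(sf$n_segments, sf$n_segments, replace = TRUE))
  }
  csd_from_segffts(sf, idx = indices)
}
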