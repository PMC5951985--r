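optimized_factor_from_b <- function(B) {
  # wrap a known factor as an "optimized" spectral_factor
  structure(list(b0 = B, u = diag(1 + 0i, nrow(B)), b = B,
                 frequency = 0.1, regularization = 0, condition = 1,
                 cost_trace = offdiag_l1(B), converged = TRUE),
            class = "spectral_factor")
}

test_that("coupling extraction inverts the row normalization exactly", {
  # B = identity: empty network
  out <- extract_connectivity(optimized_factor_from_b(diag(1 + 0i, 4)))
  expect_equal(out$weights, matrix(0 + 0i, 4, 4))
  # B = diag(d) (I - G_true): G recovered exactly, zero diagonal
  set.seed(41)
  G <- matrix(0, 5, 5)
  G[cbind(c(2, 4, 5), c(1, 3, 2))] <- c(0.4, -0.3, 0.2)
  d <- runif(5, 0.5, 3)
  B <- diag(d) %*% (diag(5) - G)
  out <- extract_connectivity(optimized_factor_from_b(B))
  expect_equal(Re(out$weights), G, tolerance = 1e-12)
  expect_identical(diag(out$weights), rep(0 + 0i, 5))
  # scaling any row by a positive constant leaves the coupling unchanged
  B2 <- B; B2[3, ] <- 7 * B2[3, ]
  out2 <- extract_connectivity(optimized_factor_from_b(B2))
  expect_equal(out2$weights, out$weights, tolerance = 1e-12)
})

test_that("the pipeline is deterministic and recovers a 20-node network", {
  # regression floor: this seeded 20-node, SNR-5, 20k-sample run yields a
  # mean off-diagonal weight correlation of ~0.66 over the three lowest
  # bins (recovery at small n is limited by collider availability, not by
  # noise; see the simulation benchmark for the full-scale behavior)
  net <- sample_network(20, 0.15, order = 50, seed = 101)
  ts <- benchmark_dataset(net, 20000, dt = 0.1,
                          noise = noise_spec("white", snr = 5), seed = 5)
  cfg <- ec_config(nfft = 128L, freq_bins = 1:3, restarts = 1L, seed = 3)
  est <- estimate_pipeline(ts, cfg)
  expect_s3_class(est, "connectivity_estimate")
  expect_equal(dim(est$weights), c(20, 20, 3))
  expect_true(all(est$convergence$converged))
  cors <- sapply(1:3, function(k)
    weight_correlation(est$signed_weights[, , k], net$adjacency))
  expect_gt(mean(cors), 0.55)
  expect_gt(cors[1], 0.6)
  # identical rerun
  est2 <- estimate_pipeline(ts, cfg)
  expect_identical(est$weights, est2$weights)
  expect_identical(est$config_hash, est2$config_hash)
})

test_that("null thresholds pool the configured number of values", {
  set.seed(42)
  ts <- time_series_set(matrix(rnorm(6 * 4000), 6), dt = 0.1)
  cfg <- ec_config(nfft = 64L, freq_bins = 1:2, restarts = 1L)
  thr <- null_thresholds(ts, cfg, n_null = 4, alpha = 0.05, seed = 9)
  expect_s3_class(thr, "threshold_set")
  # 4 replicates x 6*5 off-diagonal entries pooled per frequency
  expect_identical(thr$n_null_values, rep(4L * 30L, 2))
  expect_true(all(thr$lower <= 0 & thr$upper >= 0))
  expect_length(thr$lower, 2)
  # degenerate level: both thresholds at the median
  thr1 <- null_thresholds(ts, cfg, n_null = 2, alpha = 1, seed = 9)
  expect_equal(thr1$lower, thr1$upper)
})

test_that("significance masking applies the AND rule", {
  net <- matrix(c(0, 0.5, -0.4, 0, 0, 0.1, 0, 0, 0), 3, 3, byrow = TRUE)
  est <- structure(list(weights = array(net + 0i, c(3, 3, 1)),
                        signed_weights = array(net, c(3, 3, 1)),
                        significant = NULL, frequencies = 0.1),
                   class = "connectivity_estimate")
  thr <- structure(list(lower = -0.2, upper = 0.2, frequencies = 0.1,
                        alpha = 0.05), class = "threshold_set")
  out <- apply_significance(est, thr)
  expect_identical(out$significant[, , 1] , abs(net) > 0.2)
  expect_identical(out$signed_weights[1, 3, 1], -0.4)
  expect_identical(out$signed_weights[2, 3, 1], 0)   # inside the null band
  # with CIs: a connection whose interval includes zero is masked too
  cis <- structure(list(lower = array(-1, c(3, 3, 1)),
                        upper = array(1, c(3, 3, 1)),
                        frequencies = 0.1, level = 0.95),
                   class = "confidence_intervals")
  out2 <- apply_significance(est, thr, cis)
  expect_true(all(out2$signed_weights == 0))  # every CI includes zero
  # infinite thresholds: empty network; zero thresholds: all nonzero kept
  thr_inf <- structure(list(lower = -Inf, upper = Inf, frequencies = 0.1),
                       class = "threshold_set")
  expect_true(all(apply_significance(est, thr_inf)$signed_weights == 0))
  thr0 <- structure(list(lower = 0, upper = 0, frequencies = 0.1),
                    class = "threshold_set")
  out3 <- apply_significance(est, thr0)
  expect_identical(out3$signed_weights[, , 1] != 0, net != 0)
  # frequency mismatch is an error
  thr_bad <- structure(list(lower = 0, upper = 0, frequencies = 0.3),
                       class = "threshold_set")
  expect_error(apply_significance(est, thr_bad), "frequencies")
})

test_that("bootstrap intervals behave like resampling intervals should", {
  set.seed(43)
  ts <- time_series_set(matrix(rnorm(4 * 3000), 4), dt = 0.1)
  cfg <- ec_config(nfft = 64L, freq_bins = 1L, restarts = 1L)
  sf <- segment_ffts(ts, 64)
  # identical resamples: zero-width intervals at the point estimate
  idx <- seq_len(sf$n_segments)
  cis0 <- bootstrap_cis(ts, cfg, indices_list = list(idx, idx, idx))
  expect_equal(cis0$lower, cis0$upper, tolerance = 1e-10)
  est <- estimate_pipeline(ts, cfg)
  expect_equal(cis0$mean[, , 1], est$signed_weights[, , 1], tolerance = 1e-8)
  # proper bootstrap: intervals bracket the point estimate for most entries
  cis <- bootstrap_cis(ts, cfg, n_boot = 12, seed = 7)
  expect_true(all(cis$lower <= cis$upper))
  covered <- mean(est$signed_weights >= cis$lower - 1e-12 &
                  est$signed_weights <= cis$upper + 1e-12)
  expect_gt(covered, 0.7)
})

test_that("mirroring, consensus and band grouping follow their definitions", {
  # mirror: antisymmetric input cancels, symmetric input doubles
  A <- matrix(c(0, 1, -1, 0), 2, 2)
  expect_identical(mirror_network(A), matrix(0, 2, 2))
  S <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_identical(mirror_network(S), 2 * S)
  e <- matrix(0, 3, 3); e[1, 2] <- 0.7
  m <- mirror_network(e)
  expect_identical(m[1, 2], 0.7); expect_identical(m[2, 1], 0.7)

  # consensus: boundary 9/20 < 0.5 drops, >= keeps ties
  base <- matrix(0, 2, 2); base[1, 2] <- 1
  nets <- c(replicate(9, base, simplify = FALSE),
            replicate(11, matrix(0, 2, 2), simplify = FALSE))
  expect_identical(consensus_network(nets, 0.5), matrix(0, 2, 2))
  nets10 <- c(replicate(10, base, simplify = FALSE),
              replicate(10, matrix(0, 2, 2), simplify = FALSE))
  expect_identical(consensus_network(nets10, 0.5), base)  # tie kept
  # identical inputs: same network back, weights preserved
  w <- matrix(c(0, -0.3, 0.8, 0), 2, 2)
  expect_identical(consensus_network(replicate(5, w, simplify = FALSE)), w)
  expect_error(consensus_network(list(w, matrix(0, 3, 3))), "shape")

  # band grouping: edge in 2 of 3 bins kept at fraction 2/3, averaged
  sw <- array(0, c(2, 2, 3))
  sw[1, 2, 1] <- 0.4; sw[1, 2, 2] <- 0.6
  est <- structure(list(signed_weights = sw,
                        frequencies = c(0.1, 0.2, 0.3)),
                   class = "connectivity_estimate")
  bands <- band_summary(est, c(0, 0.35), within_band_fraction = 2 / 3)
  expect_equal(bands[[1]][1, 2], 0.5)
  # single-bin band returns that bin's network
  bands2 <- band_summary(est, c(0.05, 0.15))
  expect_equal(bands2[[1]], sw[, , 1])
  expect_error(band_summary(est, c(0.8, 0.9)), "no frequency bins")
})
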