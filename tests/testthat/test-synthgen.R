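test_that("sampled networks have the stated topology, decay and stability", {
  net <- sample_network(100, p_connect = 0.15, order = 50, seed = 301)
  expect_s3_class(net, "ground_truth_network")
  # directed Erdos-Renyi edge count: 0.15 * 100 * 99 = 1485 +- binomial noise
  k <- sum(net$adjacency != 0)
  expect_gt(k, 1485 - 4 * sqrt(1485 * 0.85))
  expect_lt(k, 1485 + 4 * sqrt(1485 * 0.85))
  expect_equal(diag(net$adjacency), rep(0, 100))
  # lag-0 kernel is the identity
  expect_identical(net$lag_kernels[, , 1], diag(100))
  # same off-diagonal support at every lag, magnitudes non-increasing in p
  supp <- net$lag_kernels[, , 2] != 0
  for (p in 3:51) {
    expect_identical(net$lag_kernels[, , p] != 0, supp)
    expect_true(all(abs(net$lag_kernels[, , p]) <= abs(net$lag_kernels[, , p - 1])))
  }
  expect_lt(net$spectral_radius, 1)
  # decay constraint: lag-50 factor well below 5% of lag-1
  expect_lt(net$decay[50] / net$decay[1], 0.05)
})

test_that("forced 2-node network and determinism contract", {
  net <- sample_network(2, p_connect = 1, order = 3, seed = 5)
  expect_true(all(net$adjacency[row(net$adjacency) != col(net$adjacency)] != 0))
  expect_identical(net$lag_kernels[, , 1], diag(2))
  net2 <- sample_network(2, p_connect = 1, order = 3, seed = 5)
  expect_identical(net, net2)
  expect_error(sample_network(2, p_connect = 0), "p_connect")
  expect_error(sample_network(1, p_connect = 0.5), "n_nodes")
})

test_that("intrinsic drive has the configured spectral content", {
  # single sinusoid at a bin-centered frequency: power concentrates there
  dt <- 0.1; T <- 4096
  d <- gen_intrinsic_drive(1, T, dt, n_harmonics = 1,
                           freq_range = c(0.25, 0.25), noise_level = 0,
                           seed = 2)
  p <- Mod(stats::fft(d[1, ]))^2
  peak_bin <- which.max(p[2:(T / 2)]) + 1
  expect_lt(abs((peak_bin - 1) / (T * dt) - 0.25), 2 / (T * dt))
  # no harmonics: white noise, negligible lag-1 autocorrelation
  w <- gen_intrinsic_drive(1, 10000, dt, n_harmonics = 0, noise_level = 1,
                           seed = 3)
  ac <- stats::acf(w[1, ], lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac), 3 / sqrt(10000))
  # determinism and Nyquist guard
  expect_identical(gen_intrinsic_drive(3, 50, dt, seed = 9),
                   gen_intrinsic_drive(3, 50, dt, seed = 9))
  expect_error(gen_intrinsic_drive(1, 50, dt, freq_range = c(0.1, 6)),
               "Nyquist")
})

test_that("VAR simulation matches a naive scalar-loop recursion", {
  for (s in 1:3) {
    net <- sample_network(3, p_connect = 0.8, order = 2, seed = s,
                          target_radius = 0.6)
    drive <- gen_intrinsic_drive(3, 60, 0.1, n_harmonics = 2, seed = s + 10)
    got <- simulate_var(net, drive, n_samples = 60, burn_in = 0)
    want <- naive_var(net$lag_kernels[, , -1, drop = FALSE], drive)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("VAR simulation handles degenerate and unstable cases", {
  net <- sample_network(2, p_connect = 1, order = 2, seed = 1)
  net$lag_kernels[, , 2:3] <- 0  # no coupling: output equals drive
  drive <- matrix(rnorm(2 * 120), 2)
  out <- simulate_var(net, drive, n_samples = 100, burn_in = 20)
  expect_equal(out, drive[, 21:120])
  # diverging recursion raises an instability error naming the sample
  net$lag_kernels[, , 2] <- diag(2) * 3
  expect_error(simulate_var(net, matrix(1, 2, 600), 100, burn_in = 500,
                            overflow_guard = 1e6),
               "diverged at sample")
  expect_error(simulate_var(net, drive, n_samples = 200), "n_samples")
})

test_that("simulated series are stationary and directed coupling is causal", {
  net <- sample_network(2, p_connect = 1, order = 1, seed = 8,
                        target_radius = 0.5)
  # keep only the 2 -> 1 edge
  net$adjacency[1, 2] <- 0.5; net$adjacency[2, 1] <- 0
  net$lag_kernels[, , 2] <- net$adjacency
  drive <- gen_intrinsic_drive(2, 5200, 0.1, n_harmonics = 0, seed = 4)
  y <- simulate_var(net, drive, 5000, burn_in = 200)
  cc <- stats::ccf(y[1, ], y[2, ], lag.max = 3, plot = FALSE)
  # the 2 -> 1 edge at lag 1 means y1(t+1) correlates with y2(t), and no
  # correlation flows the other way
  expect_gt(abs(cc$acf[cc$lag == 1]), 0.2)
  expect_lt(abs(cc$acf[cc$lag == -1]), 0.1)
  # variance stationarity across halves
  net2 <- sample_network(5, 0.4, order = 3, seed = 2)
  d2 <- gen_intrinsic_drive(5, 5200, 0.1, seed = 5)
  y2 <- simulate_var(net2, d2, 5000, burn_in = 200)
  v1 <- apply(y2[, 1:2500], 1, var); v2 <- apply(y2[, 2501:5000], 1, var)
  expect_true(all(abs(v1 - v2) / pmax(v1, v2) < 0.35))
})

test_that("hemodynamic kernels have the canonical double-gamma shape", {
  spec <- hrf_spec("canonical", dt = 0.1)
  h <- make_hrf(spec)
  tpeak <- (which.max(h) - 1) * 0.1
  expect_gt(tpeak, 4); expect_lt(tpeak, 7)
  expect_equal(max(h), 1)            # unit-peak normalization
  expect_lt(min(h), 0)               # undershoot exists
  tmin <- (which.min(h) - 1) * 0.1
  expect_gt(tmin, tpeak)             # undershoot after the main lobe
  # degenerate randomized kind equals the canonical kernel
  h0 <- make_hrf(hrf_spec("randomized", dt = 0.1, onset_bound = 0,
                          factor_bound = 1, seed = 1))
  expect_equal(h0, h, tolerance = 1e-12)
  # different seeds give different peak times
  h1 <- make_hrf(hrf_spec("randomized", dt = 0.1, seed = 1))
  h2 <- make_hrf(hrf_spec("randomized", dt = 0.1, seed = 2))
  expect_false(which.max(h1) == which.max(h2))
})

test_that("hemodynamic convolution is causal and low-pass", {
  x <- matrix(rnorm(2 * 3000), 2)
  expect_equal(convolve_hrf(x, 1), x)  # unit impulse: identity
  h <- make_hrf(hrf_spec("canonical", dt = 0.1))
  y <- convolve_hrf(x, h)
  expect_equal(dim(y), dim(x))
  # white input: power above 1 Hz strongly attenuated vs below 0.2 Hz
  p <- Mod(stats::fft(y[1, ]))^2
  f <- (0:2999) / (3000 * 0.1)
  expect_lt(mean(p[f > 1 & f < 5]), 0.01 * mean(p[f > 0.01 & f < 0.2]))
  # a 2 s kernel delay shifts the response peak by exactly 2 s
  h_delayed <- c(rep(0, 20), h)
  imp <- matrix(0, 2, 600); imp[, 100] <- 1
  y2 <- convolve_hrf(imp, list(h_delayed, h))
  expect_identical(which.max(y2[1, ]) - which.max(y2[2, ]), 20L)
  expect_error(convolve_hrf(x, list(h, h, h)), "kernels")
})

test_that("observation noise hits the requested SNR and autocorrelation", {
  x <- matrix(rnorm(2 * 10000), 2) * c(1, 5)
  noisy <- add_observation_noise(x, noise_spec("white", snr = 5, seed = 1))
  added <- noisy - x
  ratio <- apply(x, 1, var) / apply(added, 1, var)
  expect_true(all(ratio > 4.5 & ratio < 5.5))
  # temporal kind: AR(1) noise with lag-1 autocorrelation ~ 0.5
  noisy2 <- add_observation_noise(x, noise_spec("temporal", snr = 2, seed = 2))
  e <- (noisy2 - x)[1, ]
  ac <- stats::acf(e, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac - 0.5), 3 / sqrt(10000))
  # mixture uses both components; noiseless limit returns the input
  noisy3 <- add_observation_noise(x, noise_spec("mixture", snr = 5, seed = 3))
  expect_false(identical(noisy3, x))
  expect_identical(add_observation_noise(x, noise_spec("white", snr = Inf)), x)
  expect_error(add_observation_noise(rbind(x, 0), noise_spec("white", 5)),
               "zero-variance")
})

test_that("downsampling keeps in-band content and updates metadata", {
  dt <- 0.1; T <- 2000
  tt <- (0:(T - 1)) * dt
  x <- rbind(sin(2 * pi * 0.2 * tt), cos(2 * pi * 0.1 * tt))
  ts <- time_series_set(x, dt)
  down <- downsample(ts, 10)
  expect_equal(down$dt, 1.0)
  expect_equal(ncol(down$data), 200)
  p <- Mod(stats::fft(down$data[1, ]))^2
  f <- (0:199) / (200 * 1.0)
  expect_equal(f[which.max(p[2:100]) + 1], 0.2, tolerance = 0.01)
  expect_identical(downsample(ts, 1), ts)
  naive <- downsample(x, 4, anti_alias = FALSE)
  expect_identical(naive, x[, seq(1, 2000, by = 4)])
  expect_error(downsample(ts, 5000), "factor")
})
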