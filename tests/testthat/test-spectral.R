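test_that("DPSS tapers are orthonormal and band-concentrated", {
  V <- dpss_tapers(500, 3, 2)
  expect_equal(crossprod(V), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # leading taper concentrates its energy inside the +/- nw/n band
  spec <- Mod(fft(c(V[, 1], rep(0, 7500))))^2
  inband <- sum(spec[c(1:33, 7969:8000)])  # |f| <= 2/500 on the padded grid
  expect_gt(inband / sum(spec), 0.999)
})

test_that("multitaper PSD localizes tones and satisfies Parseval", {
  fs <- 2000
  t <- (0:999) / fs
  p <- multitaper_psd(cos(2 * pi * 44 * t), fs)
  expect_equal(p$freqs[which.max(p$power)], 44)
  expect_equal(diff(p$freqs)[1], 2)           # 0.5 s window -> 2 Hz bins
  expect_equal(p$window_length, 0.5)

  expect_true(all(multitaper_psd(rep(0, 1000), fs)$power == 0))

  set.seed(42)
  x <- rnorm(1000)
  p <- multitaper_psd(x, fs)
  integrated <- sum(p$power) * fs / length(x)
  expect_equal(integrated, var(x) * 999 / 1000, tolerance = 0.05)

  expect_error(multitaper_psd(rnorm(50), fs), "shorter than one cycle")
})

test_that("change in power is a per-bin dB difference, antisymmetric, with flagged zeros", {
  fs <- 2000
  set.seed(1)
  a <- multitaper_psd(rnorm(1000), fs)
  b <- multitaper_psd(rnorm(1000), fs)
  same <- change_in_power(a, a)
  expect_true(all(abs(same$db) < 1e-12))

  ten <- a
  ten$power <- a$power * 10
  expect_equal(change_in_power(ten, a)$db, rep(10, length(a$freqs)),
               tolerance = 1e-9)

  ab <- change_in_power(a, b)
  ba <- change_in_power(b, a)
  expect_equal(ab$db, -ba$db, tolerance = 1e-10)

  bad <- a
  bad$freqs <- bad$freqs + 1
  expect_error(change_in_power(a, bad), "grids")

  z <- a
  z$power[5] <- 0
  expect_true(change_in_power(a, z)$flagged[5])
})

test_that("gamma peak is the band-restricted argmax, ignoring out-of-band bins", {
  freqs <- seq(0, 200, by = 2)
  db <- rep(0, length(freqs))
  db[freqs == 44] <- 5
  spec <- structure(list(freqs = freqs, db = db), class = "db_spectrum")
  expect_equal(find_gamma_peak(spec), 44)

  db[freqs == 20] <- 5  # dB-equal out-of-band peak must be ignored
  spec$db <- db
  expect_equal(find_gamma_peak(spec), 44)
})

test_that("off-grid 41 Hz tone snaps to a neighboring 2 Hz bin", {
  fs <- 2000
  t <- (0:999) / fs
  p <- multitaper_psd(cos(2 * pi * 41 * t) + 0.25 * cos(2 * pi * 82 * t), fs)
  g <- find_gamma_peak(p)
  expect_true(g %in% c(40, 42))
  expect_equal(find_harmonic_peak(p, g), 82)
})

test_that("harmonic search band excludes the 12 Hz shoulder and is scale-invariant", {
  freqs <- seq(0, 200, by = 2)
  db <- rep(0, length(freqs))
  db[freqs == 88] <- 3
  spec <- structure(list(freqs = freqs, db = db), class = "db_spectrum")
  expect_equal(find_harmonic_peak(spec, 44), 88)

  # a bump at 50 Hz is within gamma+12 of gamma = 44 and must be skipped
  db2 <- rep(0, length(freqs))
  db2[freqs == 50] <- 10
  db2[freqs == 90] <- 1
  spec$db <- db2
  expect_equal(find_harmonic_peak(spec, 44), 90)

  expect_error(find_harmonic_peak(spec, 140), "empty")

  # amplitude scaling of the underlying signal does not move detected peaks
  fs <- 2000
  t <- (0:999) / fs
  x <- cos(2 * pi * 44 * t) + 0.25 * cos(2 * pi * 88 * t)
  p1 <- find_peaks(multitaper_psd(x, fs))
  p2 <- find_peaks(multitaper_psd(100 * x, fs))
  expect_equal(p1$gamma_peak, p2$gamma_peak)
  expect_equal(p1$harmonic_peak, p2$harmonic_peak)
  expect_equal(p1$ratio, 2)  # on-grid (f, 2f) pair -> ratio exactly 2
})

test_that("artifact rule keeps sinusoids, rejects inserted spikes, passes clean noise", {
  ts <- clean_trialset(n_trials = 3, n_channels = 1, noise_sd = 0)
  expect_true(all(reject_artifact_trials(ts)))  # sine: max dev/SD = sqrt(2)

  idx <- epoch_indices(ts, "stimulus")
  spiked <- ts
  x <- spiked$data[2, idx, 1]
  x[200] <- x[200] + 10 * sd(x)
  spiked$data[2, idx, 1] <- x
  expect_equal(reject_artifact_trials(spiked), c(TRUE, FALSE, TRUE))

  # Monte Carlo: the max-deviation statistic of 1000 Gaussian samples stays
  # below 6 SD in at least 99% of draws
  nts <- make_trialset(synthetic_spec(noise_sd = 1, harmonic_amp_ratio = 0,
                                      seed = 9), n_trials = 200)
  nts$data <- nts$data * 0
  set.seed(99)
  for (tr in 1:200) nts$data[tr, , 1] <- rnorm(3000)
  expect_gte(mean(reject_artifact_trials(nts)), 0.99)
})

test_that("ratio statistics match an exhaustive bootstrap oracle on a tiny set", {
  exact <- ratio_statistics(rep(2, 6))
  expect_equal(exact$median_ratio, 2)
  expect_equal(exact$se_median, 0)
  expect_equal(exact$wilcoxon_p, 1)

  # full enumeration of all 4^4 equally likely resamples of {1.95, 2.05} x 2
  ratios <- c(1.95, 2.05, 1.95, 2.05)
  draws <- expand.grid(i1 = 1:4, i2 = 1:4, i3 = 1:4, i4 = 1:4)
  meds <- apply(draws, 1, function(ix) median(ratios[ix]))
  oracle_se <- sqrt(mean((meds - mean(meds))^2))
  got <- ratio_statistics(ratios, n_boot = 20000, seed = 5)
  expect_equal(got$median_ratio, 2)
  expect_equal(got$se_median, oracle_se, tolerance = 0.05)

  one <- ratio_statistics(2.1)
  expect_false(one$se_defined)
  expect_true(is.na(one$se_median))
})
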