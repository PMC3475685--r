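flat_spectrum <- function(power, n = 513, fs = 1000) {
  structure(list(frequencies = seq(0, fs / 2, length.out = n),
                 power = rep(power, n), n_samples = 2 * (n - 1),
                 sample_rate = fs, n_runs_averaged = 1L),
            class = "lcm_spectrum")
}

test_that("LFP aggregation is the count-weighted mean with its identities", {
  # one layer, counts (3, 1), V_e = 0, V_i = 4 -> element potential 1 mV
  expect_equal(lfp_aggregate(0, 4, 3, 1), 1)
  # constant potential is preserved
  expect_equal(lfp_aggregate(rep(2.5, 5), rep(2.5, 5),
                             c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1)), 2.5)
  # invariant to uniform count scaling; equal counts reduce to a plain mean
  pe <- c(1, 2, 3); pi_ <- c(4, 5, 6)
  ne <- c(30, 20, 10); ni <- c(5, 10, 15)
  expect_equal(lfp_aggregate(pe, pi_, ne, ni),
               lfp_aggregate(pe, pi_, 2 * ne, 2 * ni))
  expect_equal(lfp_aggregate(pe, pi_, rep(2, 3), rep(2, 3)),
               mean(c(pe, pi_)))
  expect_error(lfp_aggregate(1, 1, 0, 0), "undefined")
})

test_that("power spectrum matches a pure tone, Parseval, and a straight-loop DFT", {
  t <- (0:1023) / 1000
  x <- sin(2 * pi * 40 * t)
  s <- power_spectrum(x)
  expect_equal(s$frequencies[1], 0)
  expect_equal(max(s$frequencies), 500)
  expect_true(all(diff(s$frequencies) > 0))
  # dominant bin nearest 40 Hz
  expect_equal(s$frequencies[which.max(s$power)],
               s$frequencies[which.min(abs(s$frequencies - 40))])
  # Parseval: spectrum sums to the variance of the windowed trace
  set.seed(3)
  y <- rnorm(1024)
  sy <- power_spectrum(y)
  expect_equal(sum(sy$power), mean((y - mean(y))^2), tolerance = 1e-9)
  # constant trace: zero power everywhere once the mean is removed
  expect_true(all(power_spectrum(rep(3.3, 1024))$power < 1e-25))
  # straight-loop DFT agreement on a 64-sample fixture
  set.seed(4)
  z <- rnorm(64)
  sz <- power_spectrum(z, sample_rate = 1000, window_samples = 64)
  ref <- reference_dft_power(z, 1000)
  expect_equal(sz$frequencies, ref$frequencies)
  expect_equal(sz$power, ref$power, tolerance = 1e-9)
  expect_error(power_spectrum(1:10, window_samples = 64), "longer than")
})

test_that("spectra average per-bin and the averaged variance shrinks as 1/k", {
  s1 <- flat_spectrum(2); s2 <- flat_spectrum(4)
  expect_equal(average_spectra(list(s1))$power, s1$power)
  av <- average_spectra(list(s1, s2))
  expect_equal(av$power, rep(3, length(av$power)))
  expect_equal(av$n_runs_averaged, 2L)
  bad <- flat_spectrum(1, n = 100)
  expect_error(average_spectra(list(s1, bad)), "mismatched")
  # Monte-Carlo 1/k variance scaling of averaged white-noise spectra
  set.seed(9)
  ks <- c(1, 4, 16, 64)
  vars <- sapply(ks, function(k) {
    reps <- replicate(30, {
      av <- average_spectra(lapply(seq_len(k), function(i)
        power_spectrum(rnorm(256), window_samples = 256)))
      mean(av$power[50:120])
    })
    var(reps)
  })
  slope <- coef(lm(log(vars) ~ log(ks)))[[2]]
  expect_gt(slope, -1.2)
  expect_lt(slope, -0.8)
})

test_that("band power is the mean over in-band bins", {
  s <- flat_spectrum(1)
  expect_equal(band_power(s, 5, 20), 1)
  # zero outside [30, 100): band below is zero
  s2 <- flat_spectrum(0)
  s2$power[s2$frequencies >= 30 & s2$frequencies < 100] <- 2
  expect_equal(band_power(s2, 5, 20), 0)
  expect_equal(band_power(s2, 30, 100), 2)
  # straight-loop oracle on random spectra
  set.seed(12)
  s3 <- flat_spectrum(0)
  s3$power <- runif(length(s3$power))
  sel <- s3$frequencies >= 12 & s3$frequencies < 47
  expect_equal(band_power(s3, 12, 47), sum(s3$power[sel]) / sum(sel))
  expect_error(band_power(s, 20, 5), "band edges")
  # a band falling between two bins is empty
  expect_error(band_power(s, 0.1, 0.2), "no frequency bins")
})

test_that("power-law exponent recovery: exact on pure laws, robust to noise", {
  s <- flat_spectrum(1)
  f <- s$frequencies
  s$power <- ifelse(f > 0, f^-2, 0)
  expect_equal(fit_power_law(s, 2, 100), 2, tolerance = 1e-12)
  s$power <- rep(1, length(f))
  expect_equal(fit_power_law(s, 2, 100), 0, tolerance = 1e-12)
  # Monte-Carlo: gamma = 1.5 with lognormal scatter lands in [1.3, 1.7]
  set.seed(31)
  hits <- replicate(40, {
    s$power <- ifelse(f > 0, f^-1.5, 0) * exp(rnorm(length(f), 0, 0.1))
    g <- fit_power_law(s, 2, 100)
    g >= 1.3 && g <= 1.7
  })
  expect_gt(mean(hits), 0.9)
  s$power <- rep(0, length(f))
  expect_error(fit_power_law(s, 2, 100), "positive power")
})

test_that("CSD second difference: affine profiles vanish, hand example, linearity", {
  # affine profile has zero curvature
  prof <- 3 * (1:7) + 2
  expect_equal(csd(prof, h = 0.4)$csd, rep(0, 5))
  # hand-computed example: [0, 1, 4] mV at 0.5 mm, sigma 0.3 S/m
  expect_equal(csd(c(0, 1, 4), sigma = 0.3, h = 0.5)$csd, -2400)
  # quadratic a i^2: CSD = -sigma * 2a / h^2 (after unit conversion)
  a <- 0.7
  prof <- a * (1:6)^2
  expect_equal(csd(prof, sigma = 0.3, h = 0.25)$csd,
               rep(-0.3 * 2 * a * 1e-3 / (0.25e-3)^2, 4))
  # linear in sigma
  expect_equal(csd(c(0, 1, 4), sigma = 0.6, h = 0.5)$csd,
               2 * csd(c(0, 1, 4), sigma = 0.3, h = 0.5)$csd)
  expect_error(csd(c(1, 2), h = 0.5), "at least 3")
  # interior length is input length minus 2
  expect_length(csd(rnorm(9), h = 1)$csd, 7)
})

test_that("Hamming smoothing: unit-sum, impulse response, double application", {
  expect_equal(hamming_smooth(rep(5, 8)), rep(5, 8))
  imp <- c(0, 0, 1, 0, 0)
  expect_equal(hamming_smooth(imp), c(0, 0.23, 0.54, 0.23, 0))
  # applying twice equals convolving with the self-convolved 5-point kernel
  set.seed(14)
  x <- rnorm(60)
  twice <- hamming_smooth(hamming_smooth(x))
  k <- c(0.23, 0.54, 0.23)
  k2 <- convolve(k, rev(k), type = "open")  # 5-point kernel
  ref <- stats::filter(x, k2, sides = 2)
  inner <- 3:58
  expect_equal(twice[inner], as.numeric(ref[inner]), tolerance = 1e-12)
  expect_error(hamming_smooth(c(1, 2)), "at least 3")
})

test_that("CSD + Hamming pipeline is linear", {
  set.seed(15)
  x <- rnorm(9); y <- rnorm(9)
  pipe <- function(v) hamming_smooth(csd(v, h = 0.3)$csd)
  expect_equal(pipe(2 * x + 3 * y), 2 * pipe(x) + 3 * pipe(y),
               tolerance = 1e-12)
})

test_that("harmonic detection finds constructed peaks and honours the threshold", {
  base <- flat_spectrum(1)
  stim <- flat_spectrum(1)
  for (f0 in c(10, 20, 30)) {
    stim$power[which.min(abs(stim$frequencies - f0))] <- 8
  }
  got <- detect_harmonics(stim, base, min_prominence = 2)
  want <- sapply(c(10, 20, 30), function(f0)
    base$frequencies[which.min(abs(base$frequencies - f0))])
  expect_equal(got, want)
  # identical spectra: nothing to detect
  expect_length(detect_harmonics(base, base, 2), 0)
  # bumps below the prominence threshold are excluded
  weak <- flat_spectrum(1)
  weak$power[which.min(abs(weak$frequencies - 10))] <- 1.1
  expect_length(detect_harmonics(weak, base, 2), 0)
  expect_error(detect_harmonics(stim, flat_spectrum(1, n = 11), 2),
               "mismatched")
})

test_that("spectrum classification separates pure power laws from peaked ones", {
  s <- flat_spectrum(1)
  f <- s$frequencies
  set.seed(16)
  s$power <- ifelse(f > 0, f^-2, 0) * exp(rnorm(length(f), 0, 0.05))
  c1 <- classify_spectrum(s)
  expect_equal(c1$class, "1/f-like")
  expect_equal(c1$gamma, 2, tolerance = 0.1)
  s$power[which.min(abs(f - 18))] <- 40 * s$power[which.min(abs(f - 18))]
  c2 <- classify_spectrum(s)
  expect_equal(c2$class, "peaked")
  expect_equal(c2$peak_frequency, f[which.min(abs(f - 18))])
})
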