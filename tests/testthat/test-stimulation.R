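test_that("white noise train has the right length, mean and determinism", {
  expect_equal(white_noise_train(7, 0, 50), rep(7, 50))
  set.seed(5)
  s1 <- white_noise_train(10, 2, 1e5)
  set.seed(5)
  s2 <- white_noise_train(10, 2, 1e5)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0))
  # CLT bound: sd of U(-2,2) is 2/sqrt(3); 3 standard errors
  se <- (2 / sqrt(3)) / sqrt(1e5)
  expect_lt(abs(mean(s1) - 10), 3 * se)
  expect_length(white_noise_train(5, 1, 0), 0)
})

test_that("gaussian pulse train peaks at the pulse rate and recurs at the period", {
  s <- gaussian_pulse_train(30, 6.25, 100, 1000)
  expect_equal(max(s), 30, tolerance = 1e-9)
  # value one sd from a centre is peak * exp(-1/2)
  centers <- which(s == max(s))
  expect_equal(s[centers[1] + round(6.25)],
               30 * exp(-0.5 * (round(6.25) / 6.25)^2), tolerance = 1e-3)
  # exactly 10 local maxima in one second at 10 Hz
  loc <- which(diff(sign(diff(s))) < 0) + 1
  expect_length(loc, 10)
  expect_equal(diff(loc), rep(100, 9))
  expect_true(all(s >= 0))
})

test_that("point source adds rate on listed elements for the exact window", {
  base <- rep(2, 100)
  els <- data.frame(x = c(5, 6, 5, 6), y = c(5, 5, 6, 6))
  f <- point_source(els, 100, onset = 30, duration = 20, base, grid_n = 10)
  expect_equal(dim(f), c(100, 100))
  extra <- f - 2
  expect_equal(sum(extra > 0), 4 * 20)
  # counting oracle: total added rate = elements x steps x rate
  expect_equal(sum(extra), 4 * 20 * 100)
  f0 <- point_source(els, 100, onset = 30, duration = 0, base, grid_n = 10)
  expect_equal(f0, matrix(2, 100, 100))
  expect_error(point_source(data.frame(x = 0, y = 1), 1, 0, 1, base, 10),
               "outside the grid")
})

test_that("protocol invariants are enforced and silent zeroes all inputs", {
  expect_error(lcm_protocol(pulse_period = 20, pulse_sd = 6.25),
               "pulse_period")
  expect_error(lcm_protocol(noise_mean = -1), "noise_mean")
  s <- lcm_protocol("silent")
  expect_equal(s$noise_amplitude + s$noise_mean + s$background_mean +
                 s$background_amplitude, 0)
})

test_that("epoch switch happens exactly at the end of warm-up", {
  prot <- lcm_protocol("constant_visual", noise_amplitude = 0,
                       stim_amplitude = 0)
  tr <- lamcor:::thalamic_series(prot, warmup_ms = 200, stim_ms = 100, dt = 1,
                                 noise_seed = 1, stim_seed = 2)
  expect_equal(tr[1:200], rep(prot$noise_mean, 200))
  expect_equal(tr[201:300], rep(prot$stim_mean, 100))
})

test_that("stimulus and noise streams are independently seeded", {
  prot <- lcm_protocol("constant_visual")
  a <- lamcor:::thalamic_series(prot, 500, 500, 1, noise_seed = 1,
                                stim_seed = 2)
  b <- lamcor:::thalamic_series(prot, 500, 500, 1, noise_seed = 1,
                                stim_seed = 99)
  # changing the stimulus seed alone leaves warm-up noise identical
  expect_identical(a[1:500], b[1:500])
  expect_false(identical(a[501:1000], b[501:1000]))
})
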