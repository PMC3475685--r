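# scenario mechanics on deliberately small configurations; the
# paper-level regime assertions live in test-acceptance.R
small_cfg <- function(warmup_s = 1.2, stim_s = 0.6, grid_n = 5, ...) {
  lcm_config(lcm_params(grid_n = grid_n, ...),
             protocol = lcm_protocol("constant_visual"),
             warmup_s = warmup_s, stim_s = stim_s, seed = 11)
}

test_that("a 1x1 gain sweep equals a plain run plus spectrum analysis", {
  cfg <- small_cfg()
  sw <- gain_sweep(cfg$params$gain_e, cfg$params$gain_i, cfg, n_runs = 1,
                   window = 512)
  direct <- lamcor:::run_epoch_spectra(cfg, 1, window = 512)
  expect_false(sw$table$failed)
  expect_equal(sw$spectra[[1]]$spontaneous$power, direct$spontaneous$power)
  expect_equal(sw$spectra[[1]]$stimulated$power, direct$stimulated$power)
})

test_that("unstable sweep cells are recorded as failed, not fatal", {
  cfg <- small_cfg(warmup_s = 1.2, stim_s = 0,
                   stability_grace = 0, gain_i = 0)
  sw <- gain_sweep(c(cfg$params$gain_e, 0.05), 0, cfg, n_runs = 1,
                   window = 512)
  expect_equal(nrow(sw$table), 2)
  expect_false(sw$table$failed[1])
  expect_true(sw$table$failed[2])
  expect_match(sw$table$message[2], "instability")
})

test_that("layer-IV reduction scales exactly the IV-source pathways", {
  cfg <- small_cfg()
  r0 <- layer4_reduction(0, cfg, n_runs = 1, window = 512)
  base <- lamcor:::run_epoch_spectra(cfg, 1, window = 512)
  # fraction 0 is the identity given the same seeds
  expect_equal(r0$spontaneous$power, base$spontaneous$power)
  r1 <- layer4_reduction(1, cfg, n_runs = 1, window = 512)
  expect_true(all(r1$config$map$count[r1$config$map$source_layer == "IV"] == 0))
  sel <- cfg$map$source_layer != "IV"
  expect_equal(r1$config$map$count[sel], cfg$map$count[sel])
})

test_that("laminar profile returns the full layer x epoch x band table", {
  cfg <- small_cfg()
  prof <- laminar_profile(cfg, n_runs = 1, window = 512)
  expect_equal(nrow(prof), 5 * 2 * 2)
  expect_setequal(unique(prof$layer), cfg$params$layers)
  expect_setequal(unique(prof$band), c("gamma", "sub-gamma"))
  expect_true(all(prof$power >= 0))
  # silent, zero-noise protocol: all band powers vanish
  cfg0 <- lcm_config(lcm_params(grid_n = 3), protocol = lcm_protocol("silent"),
                     warmup_s = 1.2, stim_s = 0.6, seed = 1)
  prof0 <- laminar_profile(cfg0, n_runs = 1, window = 512)
  expect_true(all(prof0$power < 1e-20))
})

test_that("point-source transient drives the centre and suppresses the surround", {
  p <- lcm_params(grid_n = 8)
  cfg <- lcm_config(p, protocol = lcm_protocol("point_source"),
                    warmup_s = 2, stim_s = 0.4, seed = 3)
  out <- point_source_csd(cfg)
  expect_equal(ncol(out$laminar), 3)   # interior layers II/III, IV, V
  expect_equal(ncol(out$transverse), 6)
  pre <- out$time < 0
  win <- out$time >= 0 & out$time < 60
  # strong central potential in layer IV during the transient
  l4 <- out$element_potentials[, "IV"]
  expect_gt(max(l4[win]) - mean(l4[pre]), 1)
  # surround suppression: a flanking element dips below its warm-up mean
  c0 <- floor(8 / 2) + 1
  flank <- out$transverse_potentials[, c0 - 3]
  expect_lt(min(flank[win]), mean(flank[pre]))
  # null transient: zero-rate source stays within warm-up fluctuation
  cfg0 <- cfg
  cfg0$protocol$source_rate <- 0
  out0 <- point_source_csd(cfg0)
  base_sd <- sd(out0$laminar[out0$time < 0, 2])
  expect_lt(mean(abs(out0$laminar[out0$time >= 0, 2])), 3 * base_sd +
              mean(abs(out0$laminar[out0$time < 0, 2])))
})

test_that("SSVEP scenario detects the fundamental and laminar ordering", {
  cfg <- lcm_config(lcm_params(grid_n = 5),
                    protocol = lcm_protocol("intermittent_light"),
                    warmup_s = 1.2, stim_s = 1.2, seed = 5)
  out <- ssvep(cfg, stim_frequency = 10, n_runs = 2, window = 1024)
  expect_true(length(out$harmonics) >= 1)
  # the fundamental bin is the grid frequency nearest 10 Hz
  expect_equal(out$fundamental, 9.765625)
  expect_true(any(abs(out$harmonics - out$fundamental) < 1e-9))
  expect_lt(out$layer_fundamental[["II/III"]], out$layer_fundamental[["IV"]])
})

test_that("psp_sweep reproduces the base run at scale one", {
  cfg <- small_cfg()
  tab <- psp_sweep(c(1), cfg, which = "e", n_runs = 1, window = 512)
  base <- lamcor:::run_epoch_spectra(cfg, 1, window = 512)$spontaneous
  sel <- base$frequencies >= 2
  expect_equal(tab$peak_frequency,
               base$frequencies[sel][which.max(base$power[sel])])
})
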