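#' Experiment scenarios
#'
#' End-to-end scenario runners composing the simulator and the analysis
#' stack: synaptic-gain sweeps, layer-IV synapse reduction, laminar
#' band-power profiles, transient point-source CSD, SSVEP entrainment and
#' PSP time-course sweeps. Every scenario is reproducible from its base
#' configuration and seed: run `k` of a scenario uses seed
#' `config$seed + k - 1`, and all outputs carry the configuration used.
#'
#' Spectra are always computed from the final 1.024 s of each epoch (the
#' end of the warm-up epoch for "spontaneous", the end of the stimulation
#' epoch for "stimulated") and averaged across runs.
#'
#' @name experiments
NULL

# replace the synaptic gains of a configuration
set_gains <- function(config, gain_e, gain_i) {
  p <- config$params
  p$gain_e <- gain_e
  p$gain_i <- gain_i
  config$params <- validate_lcm_params(p)
  config
}

# seeds for the k-th run of a scenario
run_seed <- function(config, k) config$seed + k - 1L

# last `window` samples of the two epochs of a trace
epoch_windows <- function(trace, config, window = 1024) {
  tw <- round(config$warmup_s * 1000 / config$params$dt)
  if (tw < window) {
    stop("warm-up epoch shorter than the analysis window", call. = FALSE)
  }
  list(spont = trace[seq_len(tw)], stim = trace)
}

# run n_runs simulations and return averaged spontaneous/stimulated LFP
# spectra plus the per-run results (invisibly heavy parts dropped)
run_epoch_spectra <- function(config, n_runs, window = 1024,
                              trace_fun = lfp_trace, keep_traces = FALSE) {
  sp <- st <- vector("list", n_runs)
  traces <- if (keep_traces) vector("list", n_runs) else NULL
  for (k in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- run_seed(config, k)
    cfg$stim_seed <- cfg$seed + 10007L
    res <- run_simulation(cfg)
    tr <- trace_fun(res)
    w <- epoch_windows(tr, cfg, window)
    fs <- 1000 / config$params$dt
    sp[[k]] <- power_spectrum(w$spont, fs, window)
    st[[k]] <- power_spectrum(w$stim, fs, window)
    if (keep_traces) traces[[k]] <- tr
  }
  list(spontaneous = average_spectra(sp), stimulated = average_spectra(st),
       traces = traces, n_runs = n_runs)
}

#' Synaptic-gain sweep
#'
#' Runs the constant-visual-stimulation protocol over a grid of
#' excitatory/inhibitory gain pairs, averages spectra over `n_runs` seeded
#' runs per cell, and classifies the spontaneous spectrum of each cell as
#' `1/f-like` or `peaked` (see [classify_spectrum()]). Cells whose
#' dynamics blow up are recorded as failed with the diagnostic message;
#' the sweep continues.
#'
#' @param gains_e,gains_i Gain values (V/spike) spanning the grid.
#' @param base_config An [lcm_config()]; its protocol should be
#'   `constant_visual`.
#' @param n_runs Seeded runs per cell.
#' @param window Spectral window (samples).
#' @return A list with `table` (one row per cell: gains, classification,
#'   fitted gamma, dominant peak frequency, failure flag) and `spectra`
#'   (per-cell averaged spectrum pairs, `NULL` for failed cells).
#' @export
gain_sweep <- function(gains_e, gains_i, base_config, n_runs = 10,
                       window = 1024) {
  stopifnot(length(gains_e) >= 1, length(gains_i) >= 1)
  cells <- expand.grid(gain_e = gains_e, gain_i = gains_i)
  spectra <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- set_gains(base_config, cells$gain_e[i], cells$gain_i[i])
    out <- tryCatch({
      sres <- run_epoch_spectra(cfg, n_runs, window)
      cls <- classify_spectrum(sres$spontaneous)
      spectra[[i]] <- sres[c("spontaneous", "stimulated")]
      data.frame(gain_e = cells$gain_e[i], gain_i = cells$gain_i[i],
                 class = cls$class, gamma = cls$gamma,
                 peak_frequency = cls$peak_frequency,
                 max_excess = cls$max_excess,
                 failed = FALSE, message = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(gain_e = cells$gain_e[i], gain_i = cells$gain_i[i],
                 class = NA_character_, gamma = NA_real_,
                 peak_frequency = NA_real_, max_excess = NA_real_,
                 failed = TRUE, message = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- out
  }
  list(table = do.call(rbind, rows), spectra = spectra,
       config = base_config, n_runs = n_runs)
}

#' Layer-IV synapse reduction
#'
#' Scales every connection whose presynaptic source lies in layer IV by
#' `1 - fraction` (modelling the layer-IV neuron loss of focal cortical
#' dysplasia) and runs the standard protocol.
#'
#' @param fraction Reduction fraction in `[0, 1]` (0.5 = the 50% scenario).
#' @param base_config An [lcm_config()].
#' @param n_runs Seeded runs to average.
#' @param window Spectral window (samples).
#' @return A list with the averaged `spontaneous` / `stimulated` spectra,
#'   the spontaneous-spectrum `classification` and the `fraction` used.
#' @export
layer4_reduction <- function(fraction, base_config, n_runs = 10,
                             window = 1024) {
  stopifnot(fraction >= 0, fraction <= 1)
  cfg <- base_config
  cfg$map <- scale_source_layer(cfg$map, "IV", 1 - fraction)
  sres <- run_epoch_spectra(cfg, n_runs, window)
  list(spontaneous = sres$spontaneous, stimulated = sres$stimulated,
       classification = classify_spectrum(sres$spontaneous),
       fraction = fraction, config = cfg)
}

#' Laminar band-power profile
#'
#' Per-layer mean power of the element-potential spectra in the gamma
#' (30-100 Hz) and sub-gamma (5-20 Hz) bands, for the spontaneous and
#' stimulated epochs, averaged over seeded runs.
#'
#' @param base_config An [lcm_config()].
#' @param n_runs Seeded runs to average.
#' @param window Spectral window (samples).
#' @param gamma_band,subgamma_band Band edges (Hz).
#' @return A data frame with columns `layer`, `epoch`, `band`, `power`
#'   (5 layers x 2 epochs x 2 bands), plus the per-layer averaged spectra
#'   as attribute `"spectra"`.
#' @export
laminar_profile <- function(base_config, n_runs = 10, window = 1024,
                            gamma_band = c(30, 100), subgamma_band = c(5, 20)) {
  layers <- base_config$params$layers
  per_layer <- lapply(layers, function(l) {
    run_epoch_spectra(base_config, n_runs, window,
                      trace_fun = function(res) element_potentials(res)[, l])
  })
  names(per_layer) <- layers
  rows <- list()
  for (l in layers) {
    for (ep in c("spontaneous", "stimulated")) {
      spec <- per_layer[[l]][[ep]]
      rows[[length(rows) + 1]] <- data.frame(
        layer = l, epoch = ep,
        band = c("gamma", "sub-gamma"),
        power = c(band_power(spec, gamma_band[1], gamma_band[2]),
                  band_power(spec, subgamma_band[1], subgamma_band[2])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "spectra") <- per_layer
  out
}

#' Transient point-source experiment with CSD analysis
#'
#' Drives a small block of layer-IV elements with a transient thalamic
#' spike source after warm-up, records the full potential fields around
#' the transient, and computes two baseline-subtracted, Hamming-smoothed
#' CSD maps: the laminar CSD of the central element (second derivative
#' across the layer depths) and the transverse CSD along the central line
#' of layer IV (second derivative across lateral positions). Baseline
#' subtraction removes the mean over the recorded epoch at each position,
#' so the maps show the deviation caused by the transient; positive values
#' are current sources.
#'
#' @param base_config An [lcm_config()] whose protocol is `point_source`;
#'   if `record_fields` is unset, a window from 100 ms before onset to
#'   200 ms after the source offset is recorded.
#' @return A list with `laminar` (time x interior-layer CSD matrix,
#'   A/m^3), `transverse` (time x interior-column CSD matrix), `time`
#'   (ms, relative to source onset), `element_potentials` (time x layer,
#'   central element), `transverse_potentials` and the simulation result.
#' @export
point_source_csd <- function(base_config) {
  stopifnot(base_config$protocol$kind == "point_source")
  cfg <- base_config
  onset <- cfg$protocol$source_onset
  if (is.null(onset)) onset <- cfg$warmup_s * 1000
  if (is.null(cfg$record_fields)) {
    cfg$record_fields <- c(onset - 100, onset + cfg$protocol$source_duration
                           + 200)
  }
  res <- run_simulation(cfg)
  p <- cfg$params
  n <- p$grid_n
  flds <- res$fields
  times <- attr(flds, "time")
  nt <- dim(flds)[3]
  nl <- length(p$layers)
  c0 <- floor(n / 2) + 1L
  center <- (c0 - 1L) * n + c0
  row_idx <- (c0 - 1L) * n + seq_len(n)  # central line, varying x

  # element potentials: count-weighted mean of E and I populations
  elem <- function(v_e, v_i, l) {
    ne <- p$neurons_e_per_layer[[l]]
    ni <- p$neurons_i_per_layer[[l]]
    (ne * v_e + ni * v_i) / (ne + ni)
  }
  lam_pot <- matrix(0, nt, nl, dimnames = list(NULL, p$layers))
  for (li in seq_len(nl)) {
    lam_pot[, li] <- elem(flds[center, 2 * li - 1, ], flds[center, 2 * li, ],
                          p$layers[li])
  }
  l4 <- match("IV", p$layers)
  tra_pot <- t(elem(flds[row_idx, 2 * l4 - 1, ], flds[row_idx, 2 * l4, ],
                    "IV"))  # nt x n

  sp <- p$layer_spacing
  if (length(sp) > 1) sp <- mean(sp)  # laminar CSD assumes equal spacing
  lam_csd <- t(apply(lam_pot, 1, function(prof)
    hamming_smooth(csd(prof, h = sp)$csd)))
  tra_csd <- t(apply(tra_pot, 1, function(prof)
    hamming_smooth(csd(prof, h = p$element_spacing)$csd)))
  # baseline: mean over the recorded epoch, per position
  lam_csd <- sweep(lam_csd, 2, colMeans(lam_csd))
  tra_csd <- sweep(tra_csd, 2, colMeans(tra_csd))
  colnames(lam_csd) <- p$layers[2:(nl - 1)]

  list(laminar = lam_csd, transverse = tra_csd, time = times - onset,
       element_potentials = lam_pot, transverse_potentials = tra_pot,
       result = res)
}

#' SSVEP entrainment experiment
#'
#' Runs the intermittent-light protocol at a given stimulus frequency,
#' averages LFP spectra over seeded runs, and detects the stimulus
#' harmonics as spectral peaks prominent over the spontaneous-epoch
#' baseline. Also reports the per-layer power at the fundamental bin.
#'
#' @param base_config An [lcm_config()]; its protocol kind is forced to
#'   `intermittent_light` with the pulse period matching `stim_frequency`.
#' @param stim_frequency Stimulus frequency (Hz); the 1000/frequency ms
#'   period must be representable on the 1 ms grid.
#' @param n_runs Seeded runs to average.
#' @param window Spectral window (samples).
#' @param min_prominence Harmonic detection threshold (power ratio).
#' @return A list with `spontaneous` / `stimulated` averaged LFP spectra,
#'   `harmonics` (detected peak frequencies, Hz), `fundamental` (Hz bin
#'   matched), and `layer_fundamental` (named per-layer power at the
#'   fundamental bin).
#' @export
ssvep <- function(base_config, stim_frequency = 10, n_runs = 10,
                  window = 1024, min_prominence = 2) {
  period <- 1000 / stim_frequency
  if (abs(period - round(period)) > 1e-9) {
    stop("pulse period 1000/stim_frequency must be a whole number of ms",
         call. = FALSE)
  }
  cfg <- base_config
  cfg$protocol$kind <- "intermittent_light"
  cfg$protocol$pulse_period <- period
  layers <- cfg$params$layers
  fs <- 1000 / cfg$params$dt
  sp <- st <- vector("list", n_runs)
  layer_pow <- matrix(0, n_runs, length(layers),
                      dimnames = list(NULL, layers))
  fund_bin <- NULL
  for (k in seq_len(n_runs)) {
    run_cfg <- cfg
    run_cfg$seed <- run_seed(cfg, k)
    run_cfg$stim_seed <- run_cfg$seed + 10007L
    res <- run_simulation(run_cfg)
    lfp <- epoch_windows(lfp_trace(res), run_cfg, window)
    sp[[k]] <- power_spectrum(lfp$spont, fs, window)
    st[[k]] <- power_spectrum(lfp$stim, fs, window)
    if (is.null(fund_bin)) {
      fund_bin <- which.min(abs(st[[k]]$frequencies - stim_frequency))
    }
    ep <- element_potentials(res)
    for (l in layers) {
      layer_pow[k, l] <-
        power_spectrum(ep[, l], fs, window)$power[fund_bin]
    }
  }
  spont <- average_spectra(sp)
  stim <- average_spectra(st)
  harm <- detect_harmonics(stim, spont, min_prominence, f_min = 2)
  list(spontaneous = spont, stimulated = stim,
       harmonics = harm, fundamental = stim$frequencies[fund_bin],
       layer_fundamental = colMeans(layer_pow),
       stim_frequency = stim_frequency, config = cfg)
}

#' PSP time-course sweep
#'
#' Scales the EPSP (or IPSP) rise and decay time constants by each factor
#' and reports the dominant non-DC spectral peak frequency of the
#' spontaneous-epoch LFP. Run in a peaked-regime gain pair, this traces
#' how the intrinsic oscillation frequency set by the excitatory-
#' inhibitory feedback loop shifts with the PSP time course (slower PSPs,
#' lower peak frequency).
#'
#' @param scale_factors Multiplicative factors for the PSP time constants.
#' @param base_config An [lcm_config()] with a peaked-regime gain pair.
#' @param which `"e"` to scale the EPSP kernel, `"i"` for the IPSP kernel.
#' @param n_runs Seeded runs to average.
#' @param window Spectral window (samples).
#' @param f_min Ignore bins below this frequency when locating the peak.
#' @return A data frame with columns `scale`, `peak_frequency` (Hz).
#' @export
psp_sweep <- function(scale_factors, base_config, which = c("e", "i"),
                      n_runs = 3, window = 1024, f_min = 2) {
  which <- match.arg(which)
  rows <- lapply(scale_factors, function(s) {
    cfg <- base_config
    p <- cfg$params
    if (which == "e") {
      p$psp_rise_e <- p$psp_rise_e * s
      p$psp_decay_e <- p$psp_decay_e * s
    } else {
      p$psp_rise_i <- p$psp_rise_i * s
      p$psp_decay_i <- p$psp_decay_i * s
    }
    cfg$params <- validate_lcm_params(p)
    sres <- run_epoch_spectra(cfg, n_runs, window)
    spec <- sres$spontaneous
    sel <- spec$frequencies >= f_min
    data.frame(scale = s,
               peak_frequency = spec$frequencies[sel][which.max(spec$power[sel])])
  })
  do.call(rbind, rows)
}
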