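#' Laminar LFP aggregation
#'
#' The model LFP is the neuron-count-weighted average of the layer element
#' potentials. Per layer, the element potential is the weighted mean of
#' its population potentials,
#' \deqn{\phi_j = (N_e V_e + N_i V_i) / (N_e + N_i),}
#' and the LFP is the weighted laminar mean
#' \deqn{LFP = \sum_j N_j \phi_j / \sum_j N_j, \qquad N_j = N_e + N_i.}
#' Both averages are invariant to uniform scaling of all neuron counts.
#'
#' @param potentials_e,potentials_i Per-layer excitatory / inhibitory
#'   central-element potentials (mV), equal length.
#' @param counts_e,counts_i Per-layer neuron counts (same length).
#' @return The aggregate LFP value (mV).
#' @examples
#' lfp_aggregate(c(0, 0), c(4, 4), counts_e = c(3, 3), counts_i = c(1, 1))
#' @export
lfp_aggregate <- function(potentials_e, potentials_i, counts_e, counts_i) {
  stopifnot(length(potentials_e) == length(potentials_i),
            length(counts_e) == length(potentials_e),
            length(counts_i) == length(potentials_e))
  nj <- counts_e + counts_i
  if (sum(nj) <= 0) {
    stop("all neuron counts are zero: the weighted average is undefined",
         call. = FALSE)
  }
  phi <- (counts_e * potentials_e + counts_i * potentials_i) / nj
  sum(nj * phi) / sum(nj)
}

#' Single-sided power spectrum of a trace
#'
#' FFT power spectrum of the final `window_samples` of the trace, after
#' mean removal, with no taper. The normalisation satisfies Parseval's
#' identity: the sum of the spectrum over all bins equals the variance of
#' the mean-removed window.
#'
#' @param trace Numeric series (mV).
#' @param sample_rate Sampling rate (Hz); 1000 Hz at the default 1 ms step.
#' @param window_samples Number of samples analysed (the trailing window);
#'   default 1024 (1.024 s at 1 kHz, frequency resolution ~0.977 Hz).
#' @return An object of class `lcm_spectrum`: a list with `frequencies`
#'   (Hz, 0 to Nyquist), `power` (mV^2 per bin), `n_samples`,
#'   `sample_rate`, `n_runs_averaged`.
#' @examples
#' s <- power_spectrum(sin(2 * pi * 40 * (0:1023) / 1000))
#' s$frequencies[which.max(s$power)]
#' @export
power_spectrum <- function(trace, sample_rate = 1000, window_samples = 1024) {
  if (window_samples > length(trace)) {
    stop("window (", window_samples, ") longer than trace (", length(trace),
         ")", call. = FALSE)
  }
  x <- utils::tail(trace, window_samples)
  x <- x - mean(x)
  N <- window_samples
  X <- stats::fft(x)
  half <- floor(N / 2)
  pw <- numeric(half + 1)
  pw[1] <- 0  # DC removed with the mean
  if (half >= 2) {
    pw[2:half] <- 2 * Mod(X[2:half])^2 / N^2
  }
  # Nyquist bin is unpaired for even N
  pw[half + 1] <- if (N %% 2 == 0) Mod(X[half + 1])^2 / N^2 else
    2 * Mod(X[half + 1])^2 / N^2
  structure(list(frequencies = (0:half) * sample_rate / N, power = pw,
                 n_samples = N, sample_rate = sample_rate,
                 n_runs_averaged = 1L),
            class = "lcm_spectrum")
}

#' Average spectra across runs
#'
#' Per-bin arithmetic mean of spectra computed on an identical frequency
#' grid (the across-run averaging used for all reported spectra).
#'
#' @param spectra A list of `lcm_spectrum` objects.
#' @return An `lcm_spectrum` with `n_runs_averaged` set.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  f0 <- spectra[[1]]$frequencies
  for (s in spectra) {
    if (length(s$frequencies) != length(f0) ||
        any(abs(s$frequencies - f0) > 1e-9)) {
      stop("spectra have mismatched frequency grids", call. = FALSE)
    }
  }
  out <- spectra[[1]]
  out$power <- Reduce(`+`, lapply(spectra, `[[`, "power")) / length(spectra)
  out$n_runs_averaged <- sum(vapply(spectra, `[[`, integer(1),
                                    "n_runs_averaged"))
  out
}

#' Mean band power of a spectrum
#'
#' Mean power over the bins with `f_lo <= f < f_hi` (the convention used
#' for the gamma, 30-100 Hz, and sub-gamma, 5-20 Hz, laminar profiles).
#'
#' @param spectrum An `lcm_spectrum`.
#' @param f_lo,f_hi Band edges (Hz), `0 <= f_lo < f_hi <=` Nyquist.
#' @return Mean power in the band (mV^2).
#' @export
band_power <- function(spectrum, f_lo, f_hi) {
  nyq <- max(spectrum$frequencies)
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= nyq)) {
    stop("band edges must satisfy 0 <= f_lo < f_hi <= Nyquist", call. = FALSE)
  }
  sel <- spectrum$frequencies >= f_lo & spectrum$frequencies < f_hi
  if (!any(sel)) stop("band contains no frequency bins", call. = FALSE)
  mean(spectrum$power[sel])
}

#' Fit the 1/f^gamma spectral exponent
#'
#' Least-squares slope of log power against log frequency over a band;
#' returns gamma, so spectra of the form `P(f) = c f^-gamma` are recovered
#' exactly (gamma = 2 for inverse-square spectra, 0 for flat). Bins with
#' non-positive power are excluded; at least 10 usable bins are required.
#'
#' @param spectrum An `lcm_spectrum`.
#' @param f_lo,f_hi Fit band (Hz); the DC bin is always excluded.
#' @return The exponent gamma (dimensionless).
#' @export
fit_power_law <- function(spectrum, f_lo = 2, f_hi = 100) {
  sel <- spectrum$frequencies >= f_lo & spectrum$frequencies <= f_hi &
    spectrum$frequencies > 0 & spectrum$power > 0
  if (sum(sel) < 10) {
    stop("fewer than 10 bins with positive power in the fit band",
         call. = FALSE)
  }
  lf <- log(spectrum$frequencies[sel])
  lp <- log(spectrum$power[sel])
  -unname(stats::coef(stats::lm(lp ~ lf))[2])
}

#' One-dimensional current source density
#'
#' Standard second-spatial-derivative CSD estimate from a potential
#' profile sampled at equally spaced depths:
#' \deqn{CSD_i = -\sigma (\phi_{i+1} - 2\phi_i + \phi_{i-1}) / h^2}
#' evaluated at interior points (the two endpoints are dropped). Inputs
#' are millivolts and millimetres; the result is reported in SI units,
#' A/m^3. Positive values mark current sources, negative values sinks.
#'
#' @param potential_profile Potentials (mV) at >= 3 equally spaced depths.
#' @param sigma Electrical conductivity of cortex (S/m), default 0.3.
#' @param h Spacing between adjacent points (mm).
#' @return An object of class `lcm_csd`: list with `csd` (A/m^3, length
#'   `length(profile) - 2`), `positions` (interior indices), `sigma`, `h`.
#' @examples
#' csd(c(0, 1, 4), sigma = 0.3, h = 0.5)$csd  # -2400 A/m^3
#' @export
csd <- function(potential_profile, sigma = 0.3, h) {
  np <- length(potential_profile)
  if (np < 3) stop("CSD needs a profile of at least 3 points", call. = FALSE)
  stopifnot(h > 0, sigma > 0)
  phi_v <- potential_profile * 1e-3       # mV -> V
  h_m <- h * 1e-3                         # mm -> m
  i <- 2:(np - 1)
  val <- -sigma * (phi_v[i + 1] - 2 * phi_v[i] + phi_v[i - 1]) / h_m^2
  structure(list(csd = val, positions = i, sigma = sigma, h = h),
            class = "lcm_csd")
}

#' Three-point Hamming smoothing
#'
#' Spatial noise reduction for CSD profiles: interior points are replaced
#' by the unit-sum three-point Hamming average
#' `0.23 x[i-1] + 0.54 x[i] + 0.23 x[i+1]`; the endpoints pass through
#' unchanged.
#'
#' @param profile Numeric vector of length >= 3.
#' @return Smoothed vector, same length.
#' @export
hamming_smooth <- function(profile) {
  np <- length(profile)
  if (np < 3) stop("Hamming smoothing needs at least 3 points", call. = FALSE)
  out <- profile
  i <- 2:(np - 1)
  out[i] <- 0.23 * profile[i - 1] + 0.54 * profile[i] + 0.23 * profile[i + 1]
  out
}

#' Detect stimulus harmonics in a power spectrum
#'
#' Compares a stimulated-epoch spectrum against a baseline (spontaneous)
#' spectrum and returns the frequencies where (a) the power ratio
#' stimulated / baseline exceeds `min_prominence` and is a local maximum,
#' and (b) the stimulated power itself is a local maximum — a genuine
#' spectral peak, which suppresses spurious detections caused by
#' bin-to-bin scatter of the ratio where the stimulated spectrum is
#' smooth. Zero-power baseline bins are floored at a small epsilon so the
#' ratio stays defined. Used to read off SSVEP fundamentals and harmonics.
#'
#' @param spectrum,baseline `lcm_spectrum` objects on the same grid.
#' @param min_prominence Minimum power ratio (default 2).
#' @param f_min Ignore bins below this frequency (Hz); excludes the DC
#'   neighbourhood.
#' @return Sorted vector of peak frequencies (Hz); empty if none.
#' @export
detect_harmonics <- function(spectrum, baseline, min_prominence = 2,
                             f_min = 0) {
  if (length(spectrum$frequencies) != length(baseline$frequencies) ||
      any(abs(spectrum$frequencies - baseline$frequencies) > 1e-9)) {
    stop("spectrum and baseline have mismatched frequency grids",
         call. = FALSE)
  }
  eps <- max(baseline$power, spectrum$power) * .Machine$double.eps
  if (eps == 0) return(numeric(0))
  base <- pmax(baseline$power, eps)
  ratio <- spectrum$power / base
  nb <- length(ratio)
  pw <- spectrum$power
  peaks <- logical(nb)
  i <- 2:(nb - 1)
  peaks[i] <- ratio[i] >= ratio[i - 1] & ratio[i] > ratio[i + 1] &
    pw[i] >= pw[i - 1] & pw[i] > pw[i + 1] &
    ratio[i] >= min_prominence
  peaks[spectrum$frequencies < f_min] <- FALSE
  sort(spectrum$frequencies[peaks])
}

#' Classify a spectrum as 1/f-like or peaked
#'
#' Operational rule for the synaptic-gain regime maps: fit the power-law
#' background over the band, then call the spectrum `"peaked"` if any
#' non-DC bin in the band exceeds `excess` times the fitted power-law
#' value at its frequency, and `"1/f-like"` otherwise.
#'
#' @param spectrum An `lcm_spectrum`.
#' @param f_lo,f_hi Analysis band (Hz).
#' @param excess Peak threshold as a multiple of the fitted background.
#' @return A list with `class` (`"peaked"` or `"1/f-like"`), `gamma` (the
#'   fitted exponent), `peak_frequency` (Hz of the largest excess, `NA` if
#'   none) and `max_excess` (largest power / background ratio).
#' @export
classify_spectrum <- function(spectrum, f_lo = 2, f_hi = 100, excess = 5) {
  gam <- fit_power_law(spectrum, f_lo, f_hi)
  sel <- spectrum$frequencies >= f_lo & spectrum$frequencies <= f_hi &
    spectrum$frequencies > 0 & spectrum$power > 0
  lf <- log(spectrum$frequencies[sel])
  lp <- log(spectrum$power[sel])
  fit <- stats::lm(lp ~ lf)
  bg <- exp(stats::fitted(fit))
  ratio <- spectrum$power[sel] / bg
  mx <- max(ratio)
  list(class = if (mx > excess) "peaked" else "1/f-like",
       gamma = gam,
       peak_frequency = if (mx > excess)
         spectrum$frequencies[sel][which.max(ratio)] else NA_real_,
       max_excess = mx)
}
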