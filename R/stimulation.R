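#' Visual stimulation protocols
#'
#' A protocol describes the external afferent spike-rate inputs of a run:
#' the thalamic (geniculate) drive carrying the visual stimulus and the
#' diffuse cortico-cortical background noise. Five kinds are supported:
#' \describe{
#'   \item{`spontaneous`}{small-amplitude uniform white noise throughout.}
#'   \item{`constant_visual`}{spontaneous noise during warm-up, then
#'     large-amplitude white noise during the stimulation epoch.}
#'   \item{`intermittent_light`}{spontaneous noise during warm-up, then
#'     recurring Gaussian rate pulses (plus the spontaneous baseline)
#'     during stimulation — the SSVEP protocol.}
#'   \item{`point_source`}{spontaneous baseline everywhere plus a transient
#'     extra rate on listed elements — the travelling-wave / CSD protocol.}
#'   \item{`silent`}{all external inputs zero.}
#' }
#' Thalamic input is applied uniformly across elements (diffuse full-field
#' stimulation), except for the `point_source` addition. All rates are
#' clipped at zero after noise addition.
#'
#' @param kind Protocol kind (see above).
#' @param noise_mean,noise_amplitude Spontaneous thalamic white-noise mean
#'   and half-range (spikes/s).
#' @param stim_mean,stim_amplitude Constant-visual-stimulation white-noise
#'   mean and half-range (spikes/s).
#' @param pulse_peak Gaussian pulse peak rate (spikes/s).
#' @param pulse_sd Gaussian pulse standard deviation (ms).
#' @param pulse_period Inter-pulse interval (ms); 100 ms = 10 Hz.
#' @param source_elements Integer matrix / data frame with columns `x`, `y`
#'   of point-source element coordinates (1-based).
#' @param source_rate Point-source rate (spikes/s).
#' @param source_duration Point-source duration (ms).
#' @param source_onset Point-source onset (ms); `NULL` = end of warm-up.
#' @param background_mean,background_amplitude Cortico-cortical background
#'   white-noise mean and half-range (spikes/s).
#' @return An object of class `lcm_protocol`.
#' @examples
#' lcm_protocol("intermittent_light")
#' @export
lcm_protocol <- function(kind = c("spontaneous", "constant_visual",
                                  "intermittent_light", "point_source",
                                  "silent"),
                         noise_mean = 5, noise_amplitude = 2,
                         stim_mean = 30, stim_amplitude = 20,
                         pulse_peak = 30, pulse_sd = 6.25, pulse_period = 100,
                         source_elements = NULL, source_rate = 100,
                         source_duration = 20, source_onset = NULL,
                         background_mean = 5, background_amplitude = 2) {
  kind <- match.arg(kind)
  stopifnot(noise_mean >= 0, noise_amplitude >= 0, stim_mean >= 0,
            stim_amplitude >= 0, pulse_peak >= 0, pulse_sd > 0,
            source_rate >= 0, source_duration >= 0,
            background_mean >= 0, background_amplitude >= 0)
  if (pulse_period <= 4 * pulse_sd) {
    stop("pulse_period must exceed 4 x pulse_sd so pulses are well separated",
         call. = FALSE)
  }
  if (kind == "silent") {
    noise_mean <- noise_amplitude <- background_mean <-
      background_amplitude <- 0
  }
  structure(list(kind = kind, noise_mean = noise_mean,
                 noise_amplitude = noise_amplitude, stim_mean = stim_mean,
                 stim_amplitude = stim_amplitude, pulse_peak = pulse_peak,
                 pulse_sd = pulse_sd, pulse_period = pulse_period,
                 source_elements = source_elements, source_rate = source_rate,
                 source_duration = source_duration,
                 source_onset = source_onset,
                 background_mean = background_mean,
                 background_amplitude = background_amplitude),
            class = "lcm_protocol")
}

#' Uniform white-noise spike-rate train
#'
#' Rates are `mean + U(-amplitude, +amplitude)`, clipped at zero. Draws use
#' the current R random-number stream; seed the stream for reproducibility.
#'
#' @param mean,amplitude Mean rate and half-range (spikes/s), both >= 0.
#' @param duration Duration (ms).
#' @param dt Step (ms).
#' @return A numeric vector of length `duration / dt` (spikes/s).
#' @examples
#' set.seed(1); white_noise_train(10, 2, duration = 5)
#' @export
white_noise_train <- function(mean, amplitude, duration, dt = 1) {
  stopifnot(mean >= 0, amplitude >= 0, duration >= 0)
  nsteps <- round(duration / dt)
  if (nsteps == 0) return(numeric(0))
  if (amplitude == 0) return(rep(mean, nsteps))
  pmax(0, mean + stats::runif(nsteps, -amplitude, amplitude))
}

#' Recurring Gaussian pulse train
#'
#' Deterministic rate series of Gaussian-shaped pulses recurring every
#' `period` ms; the intermittent-light (SSVEP) stimulus. Each pulse is
#' `peak * exp(-(t - t_c)^2 / (2 sd^2))` around its centre `t_c`; tails of
#' neighbouring pulses overlap additively (negligible when
#' `period > 4 * sd`). The first pulse is centred at `period / 2` so every
#' pulse lies wholly inside the series.
#'
#' @param peak Pulse peak rate (spikes/s).
#' @param sd Pulse standard deviation (ms).
#' @param period Inter-pulse interval (ms).
#' @param duration Series duration (ms).
#' @param dt Step (ms).
#' @return A numeric vector of length `duration / dt`.
#' @examples
#' s <- gaussian_pulse_train(30, 6.25, 100, 1000)
#' max(s)
#' @export
gaussian_pulse_train <- function(peak, sd, period, duration, dt = 1) {
  stopifnot(period > 0, sd > 0, duration >= 0)
  nsteps <- round(duration / dt)
  t <- (seq_len(nsteps) - 1) * dt
  centers <- seq(period / 2, by = period,
                 length.out = max(1, ceiling(duration / period)))
  out <- numeric(nsteps)
  for (tc in centers) {
    out <- out + peak * exp(-(t - tc)^2 / (2 * sd^2))
  }
  out
}

#' Transient point-source rate field
#'
#' Builds a time-by-element thalamic rate field equal to `baseline` (a
#' scalar per step) everywhere, plus `rate` on the listed elements during
#' `[onset, onset + duration)`.
#'
#' @param elements Matrix / data frame with columns `x`, `y` (1-based grid
#'   coordinates).
#' @param rate Added rate (spikes/s).
#' @param onset Onset time (ms) relative to the start of `baseline`.
#' @param duration Duration (ms).
#' @param baseline Numeric vector: the uniform thalamic rate per step.
#' @param grid_n Grid side length.
#' @param dt Step (ms).
#' @return A `length(baseline) x grid_n^2` matrix of rates.
#' @export
point_source <- function(elements, rate, onset, duration, baseline, grid_n,
                         dt = 1) {
  elements <- as.matrix(as.data.frame(elements)[, c("x", "y")])
  if (any(elements < 1) || any(elements > grid_n)) {
    stop("point-source element coordinates outside the grid", call. = FALSE)
  }
  nsteps <- length(baseline)
  field <- matrix(baseline, nsteps, grid_n^2)
  if (duration > 0) {
    idx <- (elements[, "y"] - 1) * grid_n + elements[, "x"]
    steps <- which((seq_len(nsteps) - 1) * dt >= onset &
                     (seq_len(nsteps) - 1) * dt < onset + duration)
    field[steps, idx] <- field[steps, idx] + rate
  }
  field
}

#' Central square of elements
#'
#' Convenience helper returning the coordinates of the `k x k` block of
#' elements at the grid centre (the default transient source of the
#' point-source experiment uses the four central elements, `k = 2`).
#'
#' @param grid_n Grid side length.
#' @param k Block side length.
#' @return A data frame with columns `x`, `y`.
#' @export
central_elements <- function(grid_n, k = 2) {
  start <- floor(grid_n / 2) + 1L - k %/% 2L
  ix <- start + seq_len(k) - 1L
  expand.grid(x = ix, y = ix)
}

# Build the uniform thalamic rate series for a protocol over a schedule.
# The warm-up epoch always uses the spontaneous noise parameters; the
# stimulation epoch switches at exactly warmup_ms. Two independent RNG
# substreams are used: `noise_seed` for warm-up noise (and the in-run
# background draws that follow), `stim_seed` for the stimulation epoch, so
# changing the stimulus seed alone leaves the warm-up noise identical.
thalamic_series <- function(protocol, warmup_ms, stim_ms, dt, noise_seed,
                            stim_seed) {
  set.seed(stim_seed)
  stim <- switch(protocol$kind,
    spontaneous = ,
    point_source = white_noise_train(protocol$noise_mean,
                                     protocol$noise_amplitude, stim_ms, dt),
    constant_visual = white_noise_train(protocol$stim_mean,
                                        protocol$stim_amplitude, stim_ms, dt),
    intermittent_light = pmax(0,
      white_noise_train(protocol$noise_mean, protocol$noise_amplitude,
                        stim_ms, dt) +
      gaussian_pulse_train(protocol$pulse_peak, protocol$pulse_sd,
                           protocol$pulse_period, stim_ms, dt)),
    silent = numeric(round(stim_ms / dt))
  )
  set.seed(noise_seed)
  warm <- white_noise_train(protocol$noise_mean, protocol$noise_amplitude,
                            warmup_ms, dt)
  c(warm, stim)
}
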