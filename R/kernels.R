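#' Population firing-rate (spike generation) function
#'
#' Maps mean membrane potential to mean population firing rate through the
#' standard sigmoid of continuum (mean-field) cortical models:
#' \deqn{Q(V) = Q_{max} / (1 + \exp(-(V - \theta)/\sigma))}
#' where \eqn{Q_{max}} is the maximum population rate, \eqn{\theta} the
#' firing threshold (the potential of half-maximal rate) and \eqn{\sigma}
#' the sigmoid steepness.
#'
#' @param potential Membrane potential(s), mV.
#' @param params An [lcm_params()] object.
#' @return Firing rate(s) in spikes/s, bounded in `[0, sigmoid_qmax]` and
#'   strictly increasing in the potential.
#' @examples
#' p <- lcm_params()
#' firing_rate(p$sigmoid_theta, p) # half of sigmoid_qmax
#' @export
firing_rate <- function(potential, params) {
  if (any(!is.finite(potential))) {
    stop("non-finite membrane potential passed to firing_rate(): ",
         "numerical blow-up", call. = FALSE)
  }
  params$sigmoid_qmax /
    (1 + exp(-(potential - params$sigmoid_theta) / params$sigmoid_slope))
}

#' Postsynaptic potential kernel
#'
#' Causal bi-exponential (difference-of-exponentials) PSP kernel
#' \deqn{h(t) = A (e^{-t/\tau_d} - e^{-t/\tau_r}), \quad t \ge 0}
#' with rise constant \eqn{\tau_r} strictly smaller than decay constant
#' \eqn{\tau_d}. The amplitude \eqn{A} is chosen so that the kernel peak
#' equals `gain`: the synaptic gain is the peak PSP evoked per afferent
#' spike (V/spike). The kernel is zero for `t < 0`, non-negative, unimodal
#' and decays to zero.
#'
#' @param t Time(s) since the afferent spike, ms. Vectorised.
#' @param rise,decay Rise and decay time constants, ms (`0 < rise < decay`).
#' @param gain Peak amplitude per afferent spike (V/spike by convention;
#'   the function simply scales the peak to `gain`).
#' @return Kernel value(s), same units as `gain` per unit spike.
#' @examples
#' psp_kernel(c(0, 2, 50), rise = 1, decay = 8, gain = 1e-4)
#' @export
psp_kernel <- function(t, rise, decay, gain = 1) {
  if (!(rise > 0 && decay > rise)) {
    stop("PSP kernel requires 0 < rise < decay", call. = FALSE)
  }
  tp <- psp_peak_time(rise, decay)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- gain * (exp(-t[pos] / decay) - exp(-t[pos] / rise)) / peak
  out
}

# time of the bi-exponential peak (ms)
psp_peak_time <- function(rise, decay) {
  rise * decay / (decay - rise) * log(decay / rise)
}

# Discrete-time recursion coefficients for the PSP convolution.  Two leaky
# accumulators u_d, u_r driven by the afferent rate A (spikes/s) reproduce
# the bi-exponential convolution exactly at the 1 ms grid:
#   u_d[t] = exp(-dt/decay) u_d[t-1] + A[t],   u_r likewise with rise,
#   drive[t] (mV) = gain * (u_d[t] - u_r[t]) / peak
# With dt in ms and A in spikes/s, the spikes-per-step factor dt/1000 and
# the V -> mV conversion cancel, so `scale` below already yields millivolts
# for `gain` given in V/spike.
psp_filter <- function(rise, decay, gain, dt = 1) {
  if (!(rise > 0 && decay > rise)) {
    stop("PSP kernel requires 0 < rise < decay", call. = FALSE)
  }
  tp <- psp_peak_time(rise, decay)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  list(beta_d = exp(-dt / decay), beta_r = exp(-dt / rise),
       scale = gain / peak)
}

#' Conduction delay between two grid positions
#'
#' Spikes travel laterally at `speed_horizontal` and between laminae at
#' `speed_vertical`. The total delay is the lateral travel time plus the
#' vertical travel time, rounded to the nearest whole integration step,
#' with a minimum of one step (the synaptic latency floor; sub-millisecond
#' delays are not representable at the fixed 1 ms step).
#'
#' @param source,target Lists with fields `x`, `y` (grid coordinates,
#'   1-based) and `layer` (layer index, 1 = most superficial).
#' @param params An [lcm_params()] object.
#' @return Delay in whole integration steps (integer >= 1).
#' @examples
#' p <- lcm_params(grid_n = 10)
#' conduction_delay(list(x = 1, y = 1, layer = 1),
#'                  list(x = 1, y = 1, layer = 1), p)
#' @export
conduction_delay <- function(source, target, params) {
  for (pt in list(source, target)) {
    if (pt$x < 1 || pt$x > params$grid_n || pt$y < 1 || pt$y > params$grid_n ||
        pt$layer < 1 || pt$layer > length(params$layers)) {
      stop("position outside the grid", call. = FALSE)
    }
  }
  lat_mm <- sqrt((source$x - target$x)^2 + (source$y - target$y)^2) *
    params$element_spacing
  vert_mm <- vertical_distance(params, source$layer, target$layer)
  delay_steps(lat_mm, vert_mm, params)
}

# delay in whole dt steps from lateral + vertical distances in mm;
# d [mm] / v [m/s] is already milliseconds
delay_steps <- function(lat_mm, vert_mm, params) {
  t_ms <- lat_mm / params$speed_horizontal + vert_mm / params$speed_vertical
  max(1L, as.integer(round(t_ms / params$dt)))
}

#' Lateral spread kernel of a population
#'
#' Enumerates the lateral connection offsets of one source population:
#' synaptic weight decays exponentially with lateral distance on the axonal
#' range scale (`range_e` or `range_i`), is cut off at three times the
#' range, and is normalised to unit sum so that the synapse count of a
#' connection-map entry is the sole strength scaling. Each offset carries
#' the conduction delay of its distance (minimum one step). Under the
#' default toroidal boundary, offsets are the minimal wrapped displacements.
#'
#' @param params An [lcm_params()] object.
#' @param pop `"E"` or `"I"`: selects `range_e` or `range_i`.
#' @return A data frame with columns `dx`, `dy` (element offsets),
#'   `distance` (mm), `weight` (sums to 1) and `delay` (steps).
#' @export
lateral_kernel <- function(params, pop = c("E", "I")) {
  pop <- match.arg(pop)
  rng <- if (pop == "E") params$range_e else params$range_i
  n <- params$grid_n
  # canonical offsets: each circular-shift class once, minimal displacement
  off <- seq_len(n) - 1L
  off <- ifelse(off > n / 2, off - n, off)
  g <- expand.grid(dx = off, dy = off)
  d <- sqrt(g$dx^2 + g$dy^2) * params$element_spacing
  keep <- d <= 3 * rng
  g <- g[keep, , drop = FALSE]
  d <- d[keep]
  w <- exp(-d / rng)
  w <- w / sum(w)
  delay <- pmax(1L, as.integer(round(d / params$speed_horizontal / params$dt)))
  out <- data.frame(dx = g$dx, dy = g$dy, distance = d, weight = w,
                    delay = delay)
  rownames(out) <- NULL
  out
}
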