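#' Model parameters for the laminar cortex simulator
#'
#' Constructs and validates the full parameter set of the laminar continuum
#' model: sigmoidal spike generation, conduction speeds and axonal ranges for
#' spike propagation, bi-exponential postsynaptic-potential (PSP) kernels,
#' first-order membrane aggregation, and the spatial discretisation of the
#' simulated patch.
#'
#' Each cortical layer is discretised into a `grid_n` x `grid_n` grid of
#' elements spaced `element_spacing` mm apart; at centimetre scale one
#' element corresponds to one cortical column. Every element holds one
#' excitatory and one inhibitory neuron population. The free parameters of
#' the model are the synaptic gains `gain_e` and `gain_i` (volts of peak PSP
#' per afferent spike); the shipped defaults are the calibrated pair
#' satisfying the model's operating criteria (near-1/f spontaneous spectrum,
#' gamma increase under stimulation, sub-10 mV excursions from rest) — see
#' the package vignette for the calibration procedure.
#'
#' @param resting_potential_e,resting_potential_i Resting membrane potential
#'   (mV) of excitatory / inhibitory populations.
#' @param reversal_potential_e,reversal_potential_i Synaptic reversal
#'   potentials (mV) of excitatory and inhibitory synapses. Synaptic
#'   drives are weighted by the normalised ionic driving force
#'   `(V_rev - V) / (V_rev - V_rest)` (floored at zero), so excitation
#'   fades as the membrane approaches `reversal_potential_e` and
#'   inhibition fades as it approaches `reversal_potential_i`. This keeps
#'   strongly driven dynamics within the physiological voltage range.
#' @param sigmoid_qmax Maximum population firing rate (spikes/s).
#' @param sigmoid_theta Sigmoid firing threshold (mV); the potential at which
#'   the population fires at `sigmoid_qmax / 2`.
#' @param sigmoid_slope Sigmoid steepness parameter (mV).
#' @param membrane_time_constant_e,membrane_time_constant_i Passive membrane
#'   decay time constants (ms).
#' @param gain_e,gain_i Excitatory / inhibitory synaptic gain (V/spike):
#'   peak PSP amplitude evoked per afferent spike. Must be non-negative; the
#'   hyperpolarising sign of inhibition is applied by the model, not by the
#'   gain.
#' @param psp_rise_e,psp_decay_e Rise and decay time constants (ms) of the
#'   excitatory PSP kernel; rise must be strictly smaller than decay.
#' @param psp_rise_i,psp_decay_i Same for the inhibitory PSP kernel.
#' @param speed_horizontal Lateral (within-layer) conduction speed (m/s).
#' @param speed_vertical Inter-laminar conduction speed (m/s); by default
#'   1.2 x `speed_horizontal` (collateral branches conduct slightly faster
#'   per unit path than long thin lateral axons in this parameterisation).
#' @param range_e,range_i Characteristic lateral spread (mm) of excitatory /
#'   inhibitory axonal arbours.
#' @param grid_n Elements per side of each layer's square grid.
#' @param element_spacing Lateral distance between adjacent elements (mm).
#' @param layer_spacing Vertical distance between adjacent layers (mm).
#'   Either a scalar or a vector of length `length(layers) - 1`.
#' @param dt Integration step (ms). Fixed at 1 ms; other values are rejected
#'   until validated.
#' @param stability_grace Time (ms) after which the divergence guard
#'   becomes active. Starting every state variable from rest produces a
#'   brief settling transient toward the noisy operating point; the guard
#'   (abort when any potential departs rest by more than 50 mV) is
#'   suspended during this window so that it flags divergence of the
#'   dynamics, not the settling path. Warm-up epochs are far longer than
#'   the default 1000 ms.
#' @param neurons_e_per_layer,neurons_i_per_layer Named numeric vectors of
#'   excitatory / inhibitory neuron counts per element for each layer; used
#'   as weights in laminar LFP aggregation.
#' @param layers Character vector of layer names, superficial to deep.
#' @param boundary Lateral boundary condition: `"toroidal"` (default) or
#'   `"reflecting"`.
#'
#' @return An object of class `lcm_params` (a validated named list).
#' @examples
#' p <- lcm_params(grid_n = 10)
#' p$gain_e
#' @export
lcm_params <- function(resting_potential_e = -64,
                       resting_potential_i = -64,
                       reversal_potential_e = 0,
                       reversal_potential_i = -74,
                       sigmoid_qmax = 100,
                       sigmoid_theta = -50,
                       sigmoid_slope = 5,
                       membrane_time_constant_e = 15,
                       membrane_time_constant_i = 15,
                       gain_e = 2e-4,
                       gain_i = 1e-4,
                       psp_rise_e = 1,
                       psp_decay_e = 8,
                       psp_rise_i = 2,
                       psp_decay_i = 16,
                       speed_horizontal = 0.24,
                       speed_vertical = 1.2 * speed_horizontal,
                       range_e = 2,
                       range_i = 0.4,
                       grid_n = 20,
                       element_spacing = 0.5,
                       layer_spacing = 0.3,
                       dt = 1,
                       stability_grace = 1000,
                       neurons_e_per_layer = c("I" = 800, "II/III" = 4800,
                                               "IV" = 4000, "V" = 3200,
                                               "VI" = 3200),
                       neurons_i_per_layer = c("I" = 200, "II/III" = 1200,
                                               "IV" = 1000, "V" = 800,
                                               "VI" = 800),
                       layers = c("I", "II/III", "IV", "V", "VI"),
                       boundary = c("toroidal", "reflecting")) {
  boundary <- match.arg(boundary)
  p <- list(
    resting_potential_e = resting_potential_e,
    resting_potential_i = resting_potential_i,
    reversal_potential_e = reversal_potential_e,
    reversal_potential_i = reversal_potential_i,
    sigmoid_qmax = sigmoid_qmax,
    sigmoid_theta = sigmoid_theta,
    sigmoid_slope = sigmoid_slope,
    membrane_time_constant_e = membrane_time_constant_e,
    membrane_time_constant_i = membrane_time_constant_i,
    gain_e = gain_e,
    gain_i = gain_i,
    psp_rise_e = psp_rise_e,
    psp_decay_e = psp_decay_e,
    psp_rise_i = psp_rise_i,
    psp_decay_i = psp_decay_i,
    speed_horizontal = speed_horizontal,
    speed_vertical = speed_vertical,
    range_e = range_e,
    range_i = range_i,
    grid_n = as.integer(grid_n),
    element_spacing = element_spacing,
    layer_spacing = layer_spacing,
    dt = dt,
    stability_grace = stability_grace,
    neurons_e_per_layer = neurons_e_per_layer,
    neurons_i_per_layer = neurons_i_per_layer,
    layers = layers,
    boundary = boundary
  )
  class(p) <- "lcm_params"
  validate_lcm_params(p)
}

#' Validate an `lcm_params` object
#'
#' Checks positivity of all time constants, speeds, ranges, spacings and
#' counts, non-negativity of the synaptic gains, ordering of the PSP time
#' constants, and the fixed 1 ms integration step.
#'
#' @param p An `lcm_params` object.
#' @return `p`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_lcm_params <- function(p) {
  stopifnot(inherits(p, "lcm_params"))
  pos <- c("sigmoid_qmax", "sigmoid_slope",
           "membrane_time_constant_e", "membrane_time_constant_i",
           "psp_rise_e", "psp_decay_e", "psp_rise_i", "psp_decay_i",
           "speed_horizontal", "speed_vertical", "range_e", "range_i",
           "grid_n", "element_spacing")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (any(!is.finite(p$layer_spacing)) || any(p$layer_spacing <= 0)) {
    stop("'layer_spacing' must be positive", call. = FALSE)
  }
  nl <- length(p$layers)
  if (nl < 1) stop("at least one layer is required", call. = FALSE)
  if (!length(p$layer_spacing) %in% c(1L, max(nl - 1L, 1L))) {
    stop("'layer_spacing' must be a scalar or one value per adjacent layer pair",
         call. = FALSE)
  }
  if (p$gain_e < 0 || p$gain_i < 0) {
    stop("synaptic gains must be non-negative; the sign of inhibition is ",
         "carried by the connection map, not the gain", call. = FALSE)
  }
  if (p$reversal_potential_e <= max(p$resting_potential_e,
                                    p$resting_potential_i) ||
      p$reversal_potential_i >= min(p$resting_potential_e,
                                    p$resting_potential_i)) {
    stop("reversal potentials must bracket the resting potentials ",
         "(excitatory above, inhibitory below)", call. = FALSE)
  }
  if (!is.numeric(p$stability_grace) || p$stability_grace < 0) {
    stop("'stability_grace' must be non-negative", call. = FALSE)
  }
  if (!isTRUE(all.equal(p$dt, 1))) {
    stop("the integration step is fixed at dt = 1 ms; other values have not ",
         "been validated", call. = FALSE)
  }
  if (p$psp_rise_e >= p$psp_decay_e || p$psp_rise_i >= p$psp_decay_i) {
    stop("PSP rise time constant must be smaller than the decay time constant",
         call. = FALSE)
  }
  for (nm in c("neurons_e_per_layer", "neurons_i_per_layer")) {
    v <- p[[nm]]
    if (!is.numeric(v) || is.null(names(v)) || !setequal(names(v), p$layers) ||
        any(v < 0)) {
      stop("'", nm, "' must be a non-negative vector named by the layers",
           call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.lcm_params <- function(x, ...) {
  cat("Laminar cortex model parameters\n")
  cat(sprintf("  layers: %s; grid %dx%d elements @ %.2f mm\n",
              paste(x$layers, collapse = ", "), x$grid_n, x$grid_n,
              x$element_spacing))
  cat(sprintf("  gains: G_e = %.3g, G_i = %.3g V/spike\n", x$gain_e, x$gain_i))
  cat(sprintf("  PSP (rise/decay ms): E %.3g/%.3g, I %.3g/%.3g\n",
              x$psp_rise_e, x$psp_decay_e, x$psp_rise_i, x$psp_decay_i))
  cat(sprintf("  conduction: %.3g m/s lateral, %.3g m/s vertical; dt = %g ms\n",
              x$speed_horizontal, x$speed_vertical, x$dt))
  invisible(x)
}

# spacing (mm) between layer i and layer j (indices into p$layers)
vertical_distance <- function(p, i, j) {
  nl <- length(p$layers)
  sp <- p$layer_spacing
  if (length(sp) == 1) sp <- rep(sp, max(nl - 1, 1))
  if (i == j) return(0)
  lo <- min(i, j); hi <- max(i, j)
  sum(sp[lo:(hi - 1)])
}
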