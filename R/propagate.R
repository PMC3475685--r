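#' Propagate delayed spikes through a lateral kernel
#'
#' Computes the afferent spike-rate field delivered to every element of a
#' target layer by one connection-map entry. Each lateral offset of the
#' source kernel contributes its (unit-sum) weight times the source firing
#' rate at that offset, read from the delay history at the offset's
#' conduction delay; the result is scaled by the entry's synapse count.
#' Because the weights sum to one, a spatially and temporally uniform
#' source field of rate `r` yields `r * synapse_count` everywhere.
#'
#' @param history A 3-D array `grid_n x grid_n x depth`; slice `[, , L]` is
#'   the source firing-rate field `L` steps in the past (L = 1 is the most
#'   recent usable field: the minimum conduction delay is one step).
#' @param kernel A lateral kernel from [lateral_kernel()].
#' @param synapse_count Synapse count (weight) of the connection entry.
#' @param boundary `"toroidal"` (wrap-around) or `"reflecting"` (kernel
#'   truncated at the grid edge and renormalised per target element).
#' @return A `grid_n x grid_n` matrix of afferent rates (spikes/s).
#' @export
propagate_spikes <- function(history, kernel, synapse_count = 1,
                             boundary = c("toroidal", "reflecting")) {
  boundary <- match.arg(boundary)
  stopifnot(length(dim(history)) == 3, dim(history)[1] == dim(history)[2])
  n <- dim(history)[1]
  depth <- dim(history)[3]
  if (max(kernel$delay) > depth) {
    stop("requested lag ", max(kernel$delay),
         " exceeds delay-buffer depth ", depth, call. = FALSE)
  }
  out <- matrix(0, n, n)
  if (boundary == "toroidal") {
    for (k in seq_len(nrow(kernel))) {
      ix <- ((seq_len(n) - 1 - kernel$dx[k]) %% n) + 1
      iy <- ((seq_len(n) - 1 - kernel$dy[k]) %% n) + 1
      out <- out + kernel$weight[k] * history[ix, iy, kernel$delay[k]]
    }
  } else {
    den <- matrix(0, n, n)
    for (k in seq_len(nrow(kernel))) {
      ix <- seq_len(n) - kernel$dx[k]
      iy <- seq_len(n) - kernel$dy[k]
      okx <- ix >= 1 & ix <= n
      oky <- iy >= 1 & iy <= n
      if (!any(okx) || !any(oky)) next
      out[okx, oky] <- out[okx, oky] +
        kernel$weight[k] * history[ix[okx], iy[oky], kernel$delay[k]]
      den[okx, oky] <- den[okx, oky] + kernel$weight[k]
    }
    out <- out / den
  }
  synapse_count * out
}

#' One integration step of membrane-potential aggregation
#'
#' The population membrane potential relaxes toward its resting value plus
#' the total synaptic drive with first-order dynamics:
#' \deqn{\tau \dot V = -(V - V_{rest}) + D, \quad D = D_e - D_i}
#' where the excitatory PSP drive \eqn{D_e} depolarises and the inhibitory
#' drive \eqn{D_i} hyperpolarises. The step uses the exact exponential
#' update with the drive held constant over one `dt`, so with zero drive
#' the potential decays exponentially to rest and with constant drive it
#' converges to `rest + D`.
#'
#' @param potential Current potential(s), mV.
#' @param drive_e,drive_i Excitatory and inhibitory PSP drives, mV
#'   (both non-negative by convention; the sign is applied here).
#' @param params An [lcm_params()] object.
#' @param pop `"E"` or `"I"`: selects the resting potential and membrane
#'   time constant.
#' @return Updated potential(s) after one `dt`.
#' @export
aggregate_membrane <- function(potential, drive_e = 0, drive_i = 0, params,
                               pop = c("E", "I")) {
  pop <- match.arg(pop)
  rest <- if (pop == "E") params$resting_potential_e else params$resting_potential_i
  tau <- if (pop == "E") params$membrane_time_constant_e else params$membrane_time_constant_i
  if (any(abs(potential - rest) > 50)) {
    stop("instability: membrane potential departed rest by more than 50 mV",
         call. = FALSE)
  }
  D <- drive_e - drive_i
  rest + D + (potential - rest - D) * exp(-params$dt / tau)
}
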