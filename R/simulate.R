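#' Full run configuration
#'
#' Bundles everything one simulation needs: model parameters, connection
#' map, stimulation protocol, run schedule and seed. The schedule is a
#' warm-up epoch (no particular visual stimulation; the system settles to
#' its noisy steady state) followed by a stimulation epoch; the standard
#' protocol is 60 s warm-up + 20 s stimulation, and shortened schedules are
#' supported for testing and desk-scale analysis.
#'
#' @param params An [lcm_params()] object.
#' @param map A connection map; defaults to [default_connection_map()].
#' @param protocol An [lcm_protocol()]; defaults to spontaneous noise.
#' @param warmup_s,stim_s Warm-up and stimulation epoch lengths (seconds).
#' @param seed Integer seed for the noise stream (warm-up thalamic noise
#'   and cortico-cortical background).
#' @param stim_seed Seed for the stimulation-epoch stimulus stream;
#'   defaults to `seed + 10007` so the two streams are distinct but fully
#'   determined by `seed`.
#' @param record_fields Optional length-2 numeric `c(start_ms, end_ms)`:
#'   record the full membrane-potential field of every population over
#'   this time window (needed by the point-source / CSD experiment).
#' @return An object of class `lcm_config`.
#' @export
lcm_config <- function(params = lcm_params(),
                       map = default_connection_map(params$layers),
                       protocol = lcm_protocol("spontaneous"),
                       warmup_s = 60, stim_s = 20,
                       seed = 1L, stim_seed = seed + 10007L,
                       record_fields = NULL) {
  stopifnot(inherits(params, "lcm_params"), inherits(protocol, "lcm_protocol"))
  if (warmup_s < 0 || stim_s < 0) {
    stop("epoch lengths must be non-negative", call. = FALSE)
  }
  map <- validate_connection_map(map, params$layers)
  if (protocol$kind == "point_source") {
    onset <- protocol$source_onset
    if (is.null(onset)) onset <- warmup_s * 1000
    if (onset < warmup_s * 1000) {
      stop("point-source stimulation cannot start before the end of warm-up",
           call. = FALSE)
    }
    protocol$source_onset <- onset
    if (is.null(protocol$source_elements)) {
      protocol$source_elements <- central_elements(params$grid_n, 2)
    }
  }
  structure(list(params = params, map = map, protocol = protocol,
                 warmup_s = warmup_s, stim_s = stim_s,
                 seed = as.integer(seed), stim_seed = as.integer(stim_seed),
                 record_fields = record_fields),
            class = "lcm_config")
}

#' Run one laminar cortex simulation
#'
#' Executes the full schedule of a configuration with [lcm_engine()]:
#' warm-up under spontaneous noise, then the protocol's stimulation epoch.
#' The membrane potential of both populations of the central element of
#' every layer is recorded at every step (1 kHz at the default 1 ms step).
#' The run is fully deterministic given the configuration and its seeds.
#'
#' @param config An [lcm_config()] object.
#' @param progress Print a progress message every `progress` seconds of
#'   simulated time (`NULL` = silent).
#' @return An object of class `lcm_result` with elements:
#'   \describe{
#'     \item{`traces`}{`n_steps x n_pop` matrix of central-element membrane
#'       potentials (mV), columns named `<layer>.<E|I>`.}
#'     \item{`time`}{time stamps (ms).}
#'     \item{`stimulus`}{the uniform thalamic rate series (spikes/s).}
#'     \item{`fields`}{if requested, a `grid_n^2 x n_pop x n_window` array
#'       of full potential fields with attribute `time`.}
#'     \item{`config`}{the full configuration (provenance).}
#'   }
#' @examples
#' cfg <- lcm_config(lcm_params(grid_n = 5, gain_e = 0, gain_i = 0),
#'                   warmup_s = 0.2, stim_s = 0, seed = 1)
#' res <- run_simulation(cfg)
#' dim(res$traces)
#' @export
run_simulation <- function(config, progress = NULL) {
  stopifnot(inherits(config, "lcm_config"))
  p <- config$params
  prot <- config$protocol
  dt <- p$dt
  warm_ms <- config$warmup_s * 1000
  stim_ms <- config$stim_s * 1000
  nsteps <- round((warm_ms + stim_ms) / dt)
  n2 <- p$grid_n^2

  thal <- thalamic_series(prot, warm_ms, stim_ms, dt,
                          noise_seed = config$seed,
                          stim_seed = config$stim_seed)
  src_idx <- NULL
  if (prot$kind == "point_source") {
    els <- as.matrix(as.data.frame(prot$source_elements)[, c("x", "y")])
    if (any(els < 1) || any(els > p$grid_n)) {
      stop("point-source element coordinates outside the grid", call. = FALSE)
    }
    src_idx <- (els[, "y"] - 1) * p$grid_n + els[, "x"]
  }

  eng <- lcm_engine(p, config$map)
  P <- length(eng$pop_names)
  traces <- matrix(NA_real_, nsteps, P, dimnames = list(NULL, eng$pop_names))
  rec <- config$record_fields
  fields <- NULL
  fsteps <- integer(0)
  if (!is.null(rec)) {
    fsteps <- which((seq_len(nsteps) - 1) * dt >= rec[1] &
                      (seq_len(nsteps) - 1) * dt < rec[2])
    fields <- array(NA_real_, dim = c(n2, P, length(fsteps)))
  }

  # background noise draws continue the noise stream seeded inside
  # thalamic_series(); per-element cortico-cortical rates each step
  cc_mean <- prot$background_mean
  cc_amp <- prot$background_amplitude
  fi <- 1L
  for (t in seq_len(nsteps)) {
    th <- thal[t]
    if (!is.null(src_idx)) {
      tms <- (t - 1) * dt
      if (tms >= prot$source_onset &&
          tms < prot$source_onset + prot$source_duration) {
        th <- rep(th, n2)
        th[src_idx] <- th[src_idx] + prot$source_rate
      }
    }
    cc <- if (cc_amp > 0) {
      pmax(0, cc_mean + stats::runif(n2, -cc_amp, cc_amp))
    } else cc_mean
    V <- eng$step(th, cc)
    traces[t, ] <- V[eng$center, ]
    if (fi <= length(fsteps) && t == fsteps[fi]) {
      fields[, , fi] <- V
      fi <- fi + 1L
    }
    if (!is.null(progress) && (t * dt) %% (progress * 1000) == 0) {
      message(sprintf("  t = %.1f s", t * dt / 1000))
    }
  }
  if (!is.null(fields)) attr(fields, "time") <- (fsteps - 1) * dt

  structure(list(traces = traces, time = (seq_len(nsteps) - 1) * dt,
                 stimulus = thal, fields = fields, config = config),
            class = "lcm_result")
}

#' @export
print.lcm_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Laminar cortex simulation: %.1f s warm-up + %.1f s %s, grid %dx%d, seed %d\n",
    cfg$warmup_s, cfg$stim_s, cfg$protocol$kind, cfg$params$grid_n,
    cfg$params$grid_n, cfg$seed))
  cat(sprintf("  %d steps x %d populations recorded at the central element\n",
              nrow(x$traces), ncol(x$traces)))
  invisible(x)
}

#' Per-layer element potential of a result
#'
#' The element potential of a layer is the neuron-count-weighted mean of
#' its excitatory and inhibitory population potentials,
#' `(N_e V_e + N_i V_i) / (N_e + N_i)`.
#'
#' @param result An `lcm_result`.
#' @return `n_steps x n_layers` matrix (mV), columns named by layer.
#' @export
element_potentials <- function(result) {
  p <- result$config$params
  out <- sapply(p$layers, function(l) {
    ne <- p$neurons_e_per_layer[[l]]
    ni <- p$neurons_i_per_layer[[l]]
    (ne * result$traces[, paste0(l, ".E")] +
       ni * result$traces[, paste0(l, ".I")]) / (ne + ni)
  })
  colnames(out) <- p$layers
  out
}

#' LFP trace of a result
#'
#' Aggregates the central-element potentials of all layers into the model
#' LFP via [lfp_aggregate()] (neuron-count-weighted laminar mean).
#'
#' @param result An `lcm_result`.
#' @return Numeric vector (mV), one value per step.
#' @export
lfp_trace <- function(result) {
  p <- result$config$params
  pe <- result$traces[, paste0(p$layers, ".E"), drop = FALSE]
  pi_ <- result$traces[, paste0(p$layers, ".I"), drop = FALSE]
  apply_rows_lfp(pe, pi_, p$neurons_e_per_layer[p$layers],
                 p$neurons_i_per_layer[p$layers])
}

# row-wise lfp_aggregate over trace matrices
apply_rows_lfp <- function(pe, pi_, ne, ni) {
  elem <- sweep(pe, 2, ne, "*") + sweep(pi_, 2, ni, "*")
  elem <- sweep(elem, 2, ne + ni, "/")
  nj <- ne + ni
  as.vector(elem %*% nj) / sum(nj)
}

#' Export recorded traces to CSV
#'
#' Writes time (ms), per-population central-element potentials, the
#' per-layer element potentials and the aggregate LFP as one plain CSV.
#'
#' @param result An `lcm_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(result, path) {
  df <- data.frame(time_ms = result$time, result$traces, check.names = FALSE)
  ep <- element_potentials(result)
  colnames(ep) <- paste0("elem.", colnames(ep))
  df <- cbind(df, ep, lfp = lfp_trace(result))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a run configuration as YAML
#'
#' Serialises an [lcm_config()] (parameters, connection map, protocol,
#' schedule, seeds) to a YAML file and back. The connection map is stored
#' inline as a list of rows.
#'
#' @param config An `lcm_config`.
#' @param path File path.
#' @return `read_config_yaml()` returns the reconstructed `lcm_config`.
#' @export
write_config_yaml <- function(config, path) {
  x <- list(
    params = unclass(config$params),
    map = lapply(seq_len(nrow(config$map)), function(i)
      as.list(config$map[i, ])),
    protocol = unclass(config$protocol),
    warmup_s = config$warmup_s, stim_s = config$stim_s,
    seed = config$seed, stim_seed = config$stim_seed,
    record_fields = config$record_fields
  )
  x$params$neurons_e_per_layer <- as.list(x$params$neurons_e_per_layer)
  x$params$neurons_i_per_layer <- as.list(x$params$neurons_i_per_layer)
  if (!is.null(x$protocol$source_elements)) {
    x$protocol$source_elements <- as.list(
      as.data.frame(x$protocol$source_elements))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  pp <- x$params
  pp$neurons_e_per_layer <- unlist(pp$neurons_e_per_layer)
  pp$neurons_i_per_layer <- unlist(pp$neurons_i_per_layer)
  pp$layers <- unlist(pp$layers)
  params <- do.call(lcm_params, pp)
  map <- validate_connection_map(
    do.call(rbind, lapply(x$map, as.data.frame)), params$layers)
  pr <- x$protocol
  if (!is.null(pr$source_elements)) {
    pr$source_elements <- as.data.frame(pr$source_elements)
  }
  protocol <- do.call(lcm_protocol, pr)
  lcm_config(params, map, protocol, warmup_s = x$warmup_s,
             stim_s = x$stim_s, seed = x$seed, stim_seed = x$stim_seed,
             record_fields = unlist(x$record_fields))
}
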