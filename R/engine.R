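#' Laminar cortex simulation engine
#'
#' Compiles a parameter set and connection map into a stepping engine for
#' the laminar continuum model. Each integration step executes the four
#' model components in order: (1) spike generation (sigmoid firing rate
#' from the current membrane potentials), (2) spike propagation through
#' delay buffers (lateral spread within layers on the toroidal grid,
#' vertical coupling of aligned elements between layers, external thalamic
#' and cortico-cortical afferents), (3) PSP generation (bi-exponential
#' kernel convolution, implemented as exact leaky-accumulator recursions,
#' with each drive weighted by the normalised ionic driving force toward
#' its reversal potential), and (4) membrane-potential aggregation
#' (first-order relaxation toward rest plus the net PSP drive). The
#' driving-force weighting makes synaptic efficacy conductance-like: it
#' vanishes as the membrane approaches the synapse's reversal potential,
#' which is what bounds the large-amplitude oscillations of the
#' strong-gain regime.
#'
#' Lateral propagation under the toroidal boundary is evaluated as a
#' circular convolution per delay lag in the Fourier domain; under the
#' reflecting boundary it falls back to dense per-lag weight matrices with
#' edge renormalisation. Both routes implement exactly the semantics of
#' [propagate_spikes()].
#'
#' The engine is deterministic: all stochasticity enters through the
#' stimulus fields passed to `step()`.
#'
#' @param params An [lcm_params()] object.
#' @param map A validated connection map (see [default_connection_map()]).
#' @return An engine object (a list of closures) with elements:
#'   \describe{
#'     \item{`reset()`}{(re)initialise all state to rest; delay buffers are
#'       prefilled with the resting firing rate.}
#'     \item{`step(thalamic, cc)`}{advance one `dt`. `thalamic` is a scalar
#'       rate or length-`grid_n^2` field (spikes/s) fed to thalamic
#'       entries; `cc` likewise for cortico-cortical entries. Returns the
#'       updated potential matrix invisibly.}
#'     \item{`potentials()`}{`grid_n^2 x n_pop` membrane-potential matrix
#'       (columns named `<layer>.<E|I>`).}
#'     \item{`rates()`}{current firing-rate matrix.}
#'     \item{`time()`}{current simulation time, ms.}
#'     \item{`center`}{linear index of the central element.}
#'     \item{`pop_names`, `pop_layer`, `pop_kind`}{population bookkeeping.}
#'   }
#' @examples
#' p <- lcm_params(grid_n = 5, gain_e = 0, gain_i = 0)
#' eng <- lcm_engine(p, default_connection_map())
#' eng$step(0, 0)
#' range(eng$potentials()) # at rest
#' @export
lcm_engine <- function(params, map) {
  p <- validate_lcm_params(params)
  map <- validate_connection_map(map, p$layers)

  n <- p$grid_n
  n2 <- n * n
  nl <- length(p$layers)
  P <- 2L * nl
  pop_layer <- rep(seq_len(nl), each = 2)
  pop_kind <- rep(c("E", "I"), nl)
  pop_names <- paste(p$layers[pop_layer], pop_kind, sep = ".")
  col_of <- function(layer, kind) {
    2L * match(layer, p$layers) - 2L + match(kind, c("E", "I"))
  }
  c0 <- floor(n / 2) + 1L
  center <- (c0 - 1L) * n + c0

  rest_v <- ifelse(pop_kind == "E", p$resting_potential_e,
                   p$resting_potential_i)
  tau_v <- ifelse(pop_kind == "E", p$membrane_time_constant_e,
                  p$membrane_time_constant_i)
  restmat <- matrix(rest_v, n2, P, byrow = TRUE)
  decaymat <- matrix(exp(-p$dt / tau_v), n2, P, byrow = TRUE)

  fE <- psp_filter(p$psp_rise_e, p$psp_decay_e, p$gain_e, p$dt)
  fI <- psp_filter(p$psp_rise_i, p$psp_decay_i, p$gain_i, p$dt)
  revE_den <- matrix(p$reversal_potential_e - rest_v, n2, P, byrow = TRUE)
  revI_den <- matrix(rest_v - p$reversal_potential_i, n2, P, byrow = TRUE)

  # --- lateral propagation operators ---------------------------------
  kerns <- list(E = lateral_kernel(p, "E"), I = lateral_kernel(p, "I"))
  lat <- lapply(kerns, function(k) {
    lags <- sort(unique(k$delay))
    if (p$boundary == "toroidal") {
      KF <- matrix(0 + 0i, n2, length(lags))
      for (j in seq_along(lags)) {
        K <- matrix(0, n, n)
        sel <- k$delay == lags[j]
        ix <- (k$dx[sel] %% n) + 1L
        iy <- (k$dy[sel] %% n) + 1L
        for (m in seq_along(ix)) {
          K[ix[m], iy[m]] <- K[ix[m], iy[m]] + k$weight[sel][m]
        }
        KF[, j] <- as.vector(stats::fft(K))
      }
      list(lags = lags, KF = KF)
    } else {
      # dense per-lag operators with per-target edge renormalisation
      xs <- rep(seq_len(n), times = n)
      ys <- rep(seq_len(n), each = n)
      den <- numeric(n2)
      W <- lapply(lags, function(l) matrix(0, n2, n2))
      names(W) <- as.character(lags)
      for (m in seq_len(nrow(k))) {
        sx <- xs - k$dx[m]
        sy <- ys - k$dy[m]
        ok <- sx >= 1 & sx <= n & sy >= 1 & sy <= n
        if (!any(ok)) next
        src <- (sy[ok] - 1L) * n + sx[ok]
        tgt <- which(ok)
        lj <- as.character(k$delay[m])
        W[[lj]][cbind(tgt, src)] <- W[[lj]][cbind(tgt, src)] + k$weight[m]
        den[tgt] <- den[tgt] + k$weight[m]
      }
      W <- lapply(W, function(w) w / den)
      list(lags = lags, W = W)
    }
  })
  Lmax <- max(lat$E$lags, lat$I$lags)
  DL <- Lmax

  # --- compile connection entries ------------------------------------
  ext <- map$source_layer == "external"
  ME <- matrix(0, P, P)  # lateral terms, excitatory class
  MI <- matrix(0, P, P)
  vert <- list()
  thal <- list()
  cc <- list()
  for (i in seq_len(nrow(map))) {
    tgt <- col_of(map$target_layer[i], map$target_pop[i])
    cnt <- map$count[i]
    if (cnt == 0) next
    if (ext[i]) {
      if (map$category[i] == "thalamic") {
        thal[[length(thal) + 1]] <- list(tgt = tgt, count = cnt)
      } else {
        cc[[length(cc) + 1]] <- list(tgt = tgt, count = cnt)
      }
    } else if (map$source_layer[i] == map$target_layer[i]) {
      src <- col_of(map$source_layer[i], map$source_pop[i])
      if (map$source_pop[i] == "E") ME[src, tgt] <- ME[src, tgt] + cnt
      else MI[src, tgt] <- MI[src, tgt] + cnt
    } else {
      src <- col_of(map$source_layer[i], map$source_pop[i])
      li <- match(map$source_layer[i], p$layers)
      lj <- match(map$target_layer[i], p$layers)
      lag <- delay_steps(0, vertical_distance(p, li, lj), p)
      vert[[length(vert) + 1]] <- list(src = src, tgt = tgt, lag = lag,
                                       count = cnt,
                                       class = map$source_pop[i])
    }
  }
  Dv <- max(1L, vapply(vert, function(v) v$lag, integer(1)),
            if (p$boundary == "reflecting") Lmax else 1L)

  frest <- p$sigmoid_qmax /
    (1 + exp(-(rest_v - p$sigmoid_theta) / p$sigmoid_slope))
  frestmat <- matrix(frest, n2, P, byrow = TRUE)

  # --- mutable state --------------------------------------------------
  V <- udE <- urE <- udI <- urI <- NULL
  fhist <- NULL   # n2 x P x Dv, spatial-domain rate history (vertical lags)
  PF <- NULL      # n2 x P x DL, Fourier-domain future lateral accumulators
  tstep <- 0L

  reset <- function() {
    V <<- restmat
    # PSP accumulators start at their steady values under the resting
    # firing rates (the resting-state value of the convolution state), so
    # initialisation does not inject an artificial onset transient; the
    # external afferents contribute nothing before the run starts
    A0E <- as.vector(frest %*% ME)
    A0I <- as.vector(frest %*% MI)
    for (v in vert) {
      if (v$class == "E") A0E[v$tgt] <- A0E[v$tgt] + v$count * frest[v$src]
      else A0I[v$tgt] <- A0I[v$tgt] + v$count * frest[v$src]
    }
    udE <<- matrix(A0E / (1 - fE$beta_d), n2, P, byrow = TRUE)
    urE <<- matrix(A0E / (1 - fE$beta_r), n2, P, byrow = TRUE)
    udI <<- matrix(A0I / (1 - fI$beta_d), n2, P, byrow = TRUE)
    urI <<- matrix(A0I / (1 - fI$beta_r), n2, P, byrow = TRUE)
    fhist <<- array(frestmat, dim = c(n2, P, Dv))
    tstep <<- 0L
    if (p$boundary == "toroidal") {
      PF <<- array(0 + 0i, dim = c(n2, P, DL))
      # contributions of the pre-run resting history: slot for step t'
      # still owes the lags L >= t' + 1 (lags <= t' arrive from in-run
      # pushes, the first of which carries the resting field itself)
      for (pp in seq_len(P)) {
        Fr <- as.vector(stats::fft(matrix(frest[pp], n, n)))
        L <- lat[[pop_kind[pp]]]
        for (tp in seq_len(DL)) {
          sel <- L$lags >= tp + 1
          if (any(sel)) {
            PF[, pp, ((tp - 1L) %% DL) + 1L] <<-
              PF[, pp, ((tp - 1L) %% DL) + 1L] +
              Fr * rowSums(L$KF[, sel, drop = FALSE])
          }
        }
      }
    }
    invisible(NULL)
  }

  step <- function(thalamic = 0, cc_rate = 0) {
    if (any(!is.finite(V))) {
      stop("non-finite membrane potential at t = ", tstep * p$dt, " ms",
           call. = FALSE)
    }
    tstep <<- tstep + 1L
    f <- p$sigmoid_qmax /
      (1 + exp(-(V - p$sigmoid_theta) / p$sigmoid_slope))

    # push rate field into delay buffers
    vslot <- ((tstep - 1L) %% Dv) + 1L
    fhist[, , vslot] <<- f

    # lateral propagation
    Plat <- matrix(0, n2, P)
    if (p$boundary == "toroidal") {
      cslot <- ((tstep - 1L) %% DL) + 1L
      for (pp in seq_len(P)) {
        L <- lat[[pop_kind[pp]]]
        Fp <- as.vector(stats::fft(matrix(f[, pp], n, n)))
        slots <- ((tstep + L$lags - 2L) %% DL) + 1L
        PF[, pp, slots] <<- PF[, pp, slots] + Fp * L$KF
        Plat[, pp] <- Re(as.vector(
          stats::fft(matrix(PF[, pp, cslot], n, n), inverse = TRUE))) / n2
        PF[, pp, cslot] <<- 0 + 0i
      }
    } else {
      for (pp in seq_len(P)) {
        L <- lat[[pop_kind[pp]]]
        acc <- numeric(n2)
        for (j in seq_along(L$lags)) {
          lg <- L$lags[j]
          sl <- ((tstep - lg) %% Dv) + 1L
          acc <- acc + L$W[[j]] %*% fhist[, pp, sl]
        }
        Plat[, pp] <- acc
      }
    }

    # afferent assembly per synapse class
    AE <- Plat %*% ME
    AI <- Plat %*% MI
    for (v in vert) {
      sl <- ((tstep - v$lag) %% Dv) + 1L
      if (v$class == "E") AE[, v$tgt] <- AE[, v$tgt] + v$count * fhist[, v$src, sl]
      else AI[, v$tgt] <- AI[, v$tgt] + v$count * fhist[, v$src, sl]
    }
    for (tt in thal) AE[, tt$tgt] <- AE[, tt$tgt] + tt$count * thalamic
    for (bb in cc) AE[, bb$tgt] <- AE[, bb$tgt] + bb$count * cc_rate

    # PSP kernel convolution (exact bi-exponential recursion)
    udE <<- udE * fE$beta_d + AE
    urE <<- urE * fE$beta_r + AE
    udI <<- udI * fI$beta_d + AI
    urI <<- urI * fI$beta_r + AI
    # normalised ionic driving force: synaptic efficacy fades as the
    # membrane approaches the corresponding reversal potential
    psiE <- pmax(0, (p$reversal_potential_e - V) / revE_den)
    psiI <- pmax(0, (V - p$reversal_potential_i) / revI_den)
    D <- psiE * (fE$scale * (udE - urE)) - psiI * (fI$scale * (udI - urI))

    # membrane aggregation (exponential update, drive held over the step)
    V <<- restmat + D + (V - restmat - D) * decaymat

    dev <- abs(V - restmat)
    if (tstep * p$dt > p$stability_grace && any(dev > 50)) {
      w <- which.max(dev)
      el <- ((w - 1L) %% n2) + 1L
      pp <- ((w - 1L) %/% n2) + 1L
      stop(sprintf(
        "instability: |V - rest| = %.1f mV (> 50 mV) at t = %d ms, element %d, population %s",
        max(dev), tstep * p$dt, el, pop_names[pp]), call. = FALSE)
    }
    invisible(V)
  }

  reset()
  list(reset = reset, step = step,
       potentials = function() {
         colnames(V) <- pop_names
         V
       },
       rates = function() {
         r <- p$sigmoid_qmax /
           (1 + exp(-(V - p$sigmoid_theta) / p$sigmoid_slope))
         colnames(r) <- pop_names
         r
       },
       time = function() tstep * p$dt,
       center = center, pop_names = pop_names, pop_layer = pop_layer,
       pop_kind = pop_kind, params = p, map = map)
}
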