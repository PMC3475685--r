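# Independent straight-loop reference implementation of the stepper, used
# as the small-instance oracle. Deliberately written with explicit scalar
# loops and its own derivations of the kernels, delays and recursions; it
# shares no code with the engine.
reference_simulate <- function(p, map, thal, cc, nsteps) {
  n <- p$grid_n; n2 <- n * n; nl <- length(p$layers); P <- 2 * nl
  kindv <- rep(c("E", "I"), nl)
  restv <- ifelse(kindv == "E", p$resting_potential_e, p$resting_potential_i)
  tauv <- ifelse(kindv == "E", p$membrane_time_constant_e,
                 p$membrane_time_constant_i)
  colof <- function(layer, kind)
    2 * match(layer, p$layers) - 2 + match(kind, c("E", "I"))
  Q <- function(v) p$sigmoid_qmax /
    (1 + exp(-(v - p$sigmoid_theta) / p$sigmoid_slope))

  kern <- function(rng) {
    offs <- list(); tot <- 0
    for (dx in 0:(n - 1)) for (dy in 0:(n - 1)) {
      cdx <- if (dx > n / 2) dx - n else dx
      cdy <- if (dy > n / 2) dy - n else dy
      d <- sqrt(cdx^2 + cdy^2) * p$element_spacing
      if (d <= 3 * rng) {
        w <- exp(-d / rng)
        lag <- max(1, round(d / p$speed_horizontal / p$dt))
        offs[[length(offs) + 1]] <- c(cdx, cdy, w, lag)
        tot <- tot + w
      }
    }
    lapply(offs, function(o) c(o[1], o[2], o[3] / tot, o[4]))
  }
  kE <- kern(p$range_e); kI <- kern(p$range_i)

  fb <- function(rise, decay, gain) {
    tp <- rise * decay / (decay - rise) * log(decay / rise)
    pk <- exp(-tp / decay) - exp(-tp / rise)
    c(exp(-p$dt / decay), exp(-p$dt / rise), gain / pk)
  }
  cEf <- fb(p$psp_rise_e, p$psp_decay_e, p$gain_e)
  cIf <- fb(p$psp_rise_i, p$psp_decay_i, p$gain_i)

  V <- matrix(restv, n2, P, byrow = TRUE)
  frest <- Q(restv)
  A0E <- numeric(P); A0I <- numeric(P)
  for (i in seq_len(nrow(map))) {
    if (map$source_layer[i] == "external") next
    tgt <- colof(map$target_layer[i], map$target_pop[i])
    src <- colof(map$source_layer[i], map$source_pop[i])
    if (map$source_pop[i] == "E")
      A0E[tgt] <- A0E[tgt] + map$count[i] * frest[src]
    else A0I[tgt] <- A0I[tgt] + map$count[i] * frest[src]
  }
  udE <- matrix(A0E / (1 - cEf[1]), n2, P, byrow = TRUE)
  urE <- matrix(A0E / (1 - cEf[2]), n2, P, byrow = TRUE)
  udI <- matrix(A0I / (1 - cIf[1]), n2, P, byrow = TRUE)
  urI <- matrix(A0I / (1 - cIf[2]), n2, P, byrow = TRUE)

  depth <- 64
  hist <- array(0, c(n2, P, depth))
  for (s in 1:depth) hist[, , s] <- matrix(frest, n2, P, byrow = TRUE)
  vspace <- function(i, j) {
    sp <- p$layer_spacing
    if (length(sp) == 1) sp <- rep(sp, max(nl - 1, 1))
    if (i == j) 0 else sum(sp[min(i, j):(max(i, j) - 1)])
  }
  traces <- array(NA_real_, c(nsteps, n2, P))
  for (t in 1:nsteps) {
    f <- Q(V)
    hist[, , 2:depth] <- hist[, , 1:(depth - 1)]
    hist[, , 1] <- f
    AE <- matrix(0, n2, P); AI <- matrix(0, n2, P)
    for (i in seq_len(nrow(map))) {
      tgt <- colof(map$target_layer[i], map$target_pop[i])
      cnt <- map$count[i]
      if (map$source_layer[i] == "external") {
        if (map$category[i] == "thalamic")
          AE[, tgt] <- AE[, tgt] + cnt * thal[t]
        else AE[, tgt] <- AE[, tgt] + cnt * cc[t]
      } else if (map$source_layer[i] == map$target_layer[i]) {
        src <- colof(map$source_layer[i], map$source_pop[i])
        kk <- if (map$source_pop[i] == "E") kE else kI
        aff <- numeric(n2)
        for (xt in 1:n) for (yt in 1:n) {
          s <- 0
          for (o in kk) {
            xs <- ((xt - 1 - o[1]) %% n) + 1
            ys <- ((yt - 1 - o[2]) %% n) + 1
            s <- s + o[3] * hist[(ys - 1) * n + xs, src, o[4]]
          }
          aff[(yt - 1) * n + xt] <- s
        }
        if (map$source_pop[i] == "E") AE[, tgt] <- AE[, tgt] + cnt * aff
        else AI[, tgt] <- AI[, tgt] + cnt * aff
      } else {
        src <- colof(map$source_layer[i], map$source_pop[i])
        li <- match(map$source_layer[i], p$layers)
        lj <- match(map$target_layer[i], p$layers)
        lag <- max(1, round(vspace(li, lj) / p$speed_vertical / p$dt))
        if (map$source_pop[i] == "E")
          AE[, tgt] <- AE[, tgt] + cnt * hist[, src, lag]
        else AI[, tgt] <- AI[, tgt] + cnt * hist[, src, lag]
      }
    }
    udE <- udE * cEf[1] + AE; urE <- urE * cEf[2] + AE
    udI <- udI * cIf[1] + AI; urI <- urI * cIf[2] + AI
    RE <- matrix(p$reversal_potential_e - restv, n2, P, byrow = TRUE)
    RI <- matrix(restv - p$reversal_potential_i, n2, P, byrow = TRUE)
    psiE <- pmax(0, (p$reversal_potential_e - V) / RE)
    psiI <- pmax(0, (V - p$reversal_potential_i) / RI)
    D <- psiE * (cEf[3] * (udE - urE)) - psiI * (cIf[3] * (udI - urI))
    R <- matrix(restv, n2, P, byrow = TRUE)
    V <- R + D + (V - R - D) * matrix(exp(-p$dt / tauv), n2, P, byrow = TRUE)
    traces[t, , ] <- V
  }
  traces
}

# straight-loop DFT for spectrum cross-checks
reference_dft_power <- function(x, sample_rate) {
  N <- length(x)
  x <- x - sum(x) / N
  half <- floor(N / 2)
  pw <- numeric(half + 1)
  for (k in 1:half) {
    re <- 0; im <- 0
    for (t in 0:(N - 1)) {
      re <- re + x[t + 1] * cos(2 * pi * k * t / N)
      im <- im - x[t + 1] * sin(2 * pi * k * t / N)
    }
    mult <- if (k < half || N %% 2 == 1) 2 else 1
    pw[k + 1] <- mult * (re^2 + im^2) / N^2
  }
  list(frequencies = (0:half) * sample_rate / N, power = pw)
}
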