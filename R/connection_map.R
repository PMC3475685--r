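#' Laminar synaptic connection maps
#'
#' A connection map lists every synaptic pathway of the model as one row of
#' a data frame: the source (a cortical layer and population, or an external
#' afferent category), the target (layer and population), the synapse count
#' (a dimensionless connection weight: afferent rates are multiplied by it),
#' and the afferent category. Three categories are distinguished:
#' `intracortical` (within the simulated area, including inter-laminar
#' pathways), `cortico-cortical` (from other cortical areas; drives the
#' background-noise input) and `thalamic` (geniculate projections carrying
#' the visual stimulus, restricted to layers IV, V and VI).
#'
#' External sources are written with `source_layer = "external"` and
#' `source_pop` equal to the category. Inhibitory populations only project
#' intracortically and, in the centimetre-scale model implemented here, all
#' inter-laminar pathways couple vertically aligned elements only.
#'
#' @name connection_map
NULL

LCM_CATEGORIES <- c("intracortical", "cortico-cortical", "thalamic")
LCM_THALAMIC_TARGETS <- c("IV", "V", "VI")

new_connection_map <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("lcm_connection_map", "data.frame")
  df
}

#' Default laminar connection map
#'
#' Builds the connection map shipped with the package. The qualitative
#' structure follows the canonical laminar circuit of primary visual cortex:
#' thalamic afferents terminate in layers IV (strongest), VI and, weakly, V;
#' layer IV excites layer II/III, II/III excites V, V excites VI and VI
#' closes the loop back onto IV; every layer carries local E-E, E-I, I-E and
#' I-I coupling; and diffuse cortico-cortical afferents reach all layers.
#' The numeric synapse counts are package defaults chosen so that, at the
#' calibrated synaptic gains, spontaneous activity produces a near-1/f power
#' spectrum with the largest fluctuations in the thalamo-recipient layers;
#' they are not a measured anatomical synapse census.
#'
#' @param layers Layer names (superficial to deep); the defaults of
#'   [lcm_params()].
#' @return An `lcm_connection_map` data frame with columns `source_layer`,
#'   `source_pop`, `target_layer`, `target_pop`, `count`, `category`.
#' @examples
#' map <- default_connection_map()
#' subset(map, category == "thalamic")
#' @export
default_connection_map <- function(layers = c("I", "II/III", "IV", "V", "VI")) {
  rows <- list()
  add <- function(sl, sp, tl, tp, n, cat) {
    rows[[length(rows) + 1]] <<- data.frame(
      source_layer = sl, source_pop = sp, target_layer = tl, target_pop = tp,
      count = n, category = cat, stringsAsFactors = FALSE)
  }
  # local circuitry, identical structure in every layer: recurrent
  # excitation is kept modest relative to the reciprocal E-I coupling so
  # that the dominant feedback at large synaptic gains is the
  # excitatory-inhibitory loop rather than runaway self-excitation
  for (l in layers) {
    add(l, "E", l, "E", 100, "intracortical")
    add(l, "E", l, "I", 400, "intracortical")
    add(l, "I", l, "E", 400, "intracortical")
    add(l, "I", l, "I", 25, "intracortical")
  }
  # inter-laminar excitatory loop IV -> II/III -> V -> VI -> IV; the
  # ascending/descending projections recruit interneurons more strongly
  # than pyramidal cells (feedforward inhibition)
  ladder <- list(c("IV", "II/III"), c("II/III", "V"), c("V", "VI"),
                 c("VI", "IV"))
  for (pr in ladder) {
    if (all(pr %in% layers)) {
      add(pr[1], "E", pr[2], "E", 75, "intracortical")
      add(pr[1], "E", pr[2], "I", 150, "intracortical")
    }
  }
  # diffuse cortico-cortical background afferents
  for (l in layers) {
    add("external", "cortico-cortical", l, "E", 100, "cortico-cortical")
    add("external", "cortico-cortical", l, "I", 50, "cortico-cortical")
  }
  # thalamic (geniculate) afferents to the deep, stimulus-recipient
  # layers, IV strongest, VI intermediate, V weak
  thal <- list(c("IV", 150, 75), c("VI", 75, 40), c("V", 10, 5))
  for (tt in thal) {
    if (tt[1] %in% layers) {
      add("external", "thalamic", tt[1], "E", as.numeric(tt[2]), "thalamic")
      add("external", "thalamic", tt[1], "I", as.numeric(tt[3]), "thalamic")
    }
  }
  validate_connection_map(new_connection_map(do.call(rbind, rows)), layers)
}

#' Validate a connection map
#'
#' Enforces the structural invariants of the laminar circuit: non-negative
#' synapse counts, known categories, inhibitory sources projecting only
#' intracortically, and thalamic afferents targeting only layers IV, V
#' and VI.
#'
#' @param map A connection-map data frame.
#' @param layers Layer names the map must be consistent with.
#' @return The validated map (with class `lcm_connection_map`).
#' @export
validate_connection_map <- function(map,
                                    layers = c("I", "II/III", "IV", "V", "VI")) {
  need <- c("source_layer", "source_pop", "target_layer", "target_pop",
            "count", "category")
  if (!all(need %in% names(map))) {
    stop("connection map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  map <- new_connection_map(map[need])
  if (any(!is.finite(map$count)) || any(map$count < 0)) {
    stop("synapse counts must be finite and non-negative", call. = FALSE)
  }
  if (!all(map$category %in% LCM_CATEGORIES)) {
    stop("unknown afferent category; expected one of: ",
         paste(LCM_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  external <- map$source_layer == "external"
  if (any(map$category[external] == "intracortical") ||
      any(map$category[!external] != "intracortical")) {
    stop("category must be intracortical exactly for cortical sources",
         call. = FALSE)
  }
  if (!all(map$source_layer[!external] %in% layers) ||
      !all(map$target_layer %in% layers)) {
    stop("connection map references unknown layers", call. = FALSE)
  }
  if (!all(map$source_pop[!external] %in% c("E", "I")) ||
      !all(map$target_pop %in% c("E", "I"))) {
    stop("populations must be 'E' or 'I'", call. = FALSE)
  }
  if (any(map$source_pop == "I" & map$category != "intracortical")) {
    stop("inhibitory populations project only intracortically", call. = FALSE)
  }
  bad_thal <- map$category == "thalamic" &
    !map$target_layer %in% LCM_THALAMIC_TARGETS
  if (any(bad_thal)) {
    stop("thalamic afferents may target only layers ",
         paste(LCM_THALAMIC_TARGETS, collapse = ", "), call. = FALSE)
  }
  map
}

#' Read / write a connection map as tab-separated text
#'
#' The on-disk format is a plain TSV with the six columns of
#' [default_connection_map()]; it round-trips losslessly.
#'
#' @param map A connection map.
#' @param path File path.
#' @param layers Layer names used for validation on read.
#' @return `read_connection_map()` returns the validated map;
#'   `write_connection_map()` returns `path` invisibly.
#' @export
write_connection_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_connection_map
#' @export
read_connection_map <- function(path, layers = c("I", "II/III", "IV", "V", "VI")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_connection_map(df, layers)
}

#' Scale all pathways originating from one layer
#'
#' Multiplies the synapse count of every entry whose presynaptic source lies
#' in `layer` by `factor`. Used by the layer-IV reduction experiment, which
#' models the loss of layer-IV neurons seen in focal cortical dysplasia by
#' scaling all layer-IV-source pathways by `1 - fraction`.
#'
#' @param map A connection map.
#' @param layer Source layer to scale.
#' @param factor Multiplicative factor (>= 0).
#' @return The modified map.
#' @export
scale_source_layer <- function(map, layer, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor >= 0)
  sel <- map$source_layer == layer
  map$count[sel] <- map$count[sel] * factor
  map
}
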