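#' @import methods
NULL

.emptyEdges <- function() {
  data.frame(from = character(), to = character(), sign = integer(),
             provenance = character(), stringsAsFactors = FALSE)
}

#' Signed directed (or undirected) interaction network
#'
#' Container for prior knowledge networks (PKNs) and data-driven networks
#' (DDNs): a set of nodes, signed edges with a provenance tag, and the
#' experimental roles (stimulated, inhibited, measured) of nodes.
#'
#' @slot nodes character vector of node identifiers.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{sign}
#'   (integer, +1 activation / -1 inhibition, \code{NA} for unsigned edges
#'   from mutual-information inference), \code{provenance} (one of
#'   \code{"prior"}, \code{"integrated"}, \code{"ddn"}).
#' @slot roles named list with character elements \code{stimulated},
#'   \code{inhibited}, \code{measured}.
#' @slot directed logical scalar; mutual-information networks are
#'   undirected (edges stored once, \code{from < to}).
#'
#' @seealso [signedNetwork()], [readSIF()], [compressNetwork()]
#' @export
setClass("SignedNetwork",
         representation(nodes = "character", edges = "data.frame",
                        roles = "list", directed = "logical"),
         prototype(nodes = character(), edges = .emptyEdges(),
                   roles = list(stimulated = character(),
                                inhibited = character(),
                                measured = character()),
                   directed = TRUE))

setValidity("SignedNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("from", "to", "sign", "provenance")
  if (!all(need %in% names(ed)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(ed)) {
    if (!all(ed$sign %in% c(-1L, 1L, NA_integer_)))
      msg <- c(msg, "edge signs must be +1, -1 or NA")
    key <- paste(ed$from, ed$to, ed$sign)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (from, to, sign) edges")
    if (!all(c(ed$from, ed$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints missing from nodes")
  }
  rn <- c("stimulated", "inhibited", "measured")
  if (!all(rn %in% names(object@roles)))
    return("roles must contain stimulated, inhibited, measured")
  for (r in rn)
    if (!all(object@roles[[r]] %in% object@nodes))
      msg <- c(msg, sprintf("%s nodes missing from node set", r))
  if (length(object@directed) != 1L)
    msg <- c(msg, "directed must be a logical scalar")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Logic model superstructure (signed hypergraph)
#'
#' An ordered list of hyperedges over a species set. Each hyperedge is one
#' candidate logic gate: its inputs are ANDed (with NOT for sign -1) and
#' hyperedges sharing a target are ORed. A candidate model is a bit string
#' over the hyperedges.
#'
#' @slot species ordered character vector of node names.
#' @slot hyperedges list; each element a list with components
#'   \code{inputs} (character), \code{signs} (integer, +1/-1, aligned to
#'   inputs), \code{target} (character), \code{provenance} (\code{"prior"}
#'   or \code{"integrated"}) and \code{links} (character vector of
#'   integrated-link identifiers \code{"from>to"} the gate depends on;
#'   empty for pure prior gates).
#'
#' @seealso [expandNetwork()], [simulateLogic()], [gaOptimize()]
#' @export
setClass("LogicModel",
         representation(species = "character", hyperedges = "list"),
         prototype(species = character(), hyperedges = list()))

setValidity("LogicModel", function(object) {
  msg <- character()
  for (he in object@hyperedges) {
    if (!all(c("inputs", "signs", "target", "provenance") %in% names(he)))
      return("hyperedge missing required components")
    if (length(he$inputs) < 1L)
      msg <- c(msg, "hyperedge with no inputs")
    if (length(he$inputs) != length(he$signs))
      msg <- c(msg, "inputs/signs length mismatch")
    if (he$target %in% he$inputs)
      msg <- c(msg, sprintf("hyperedge target %s among its inputs", he$target))
    if (!all(c(he$inputs, he$target) %in% object@species))
      msg <- c(msg, "hyperedge species missing from species list")
    if (!all(he$signs %in% c(-1L, 1L)))
      msg <- c(msg, "hyperedge signs must be +1 or -1")
  }
  if (length(msg)) paste(unique(msg), collapse = "; ") else TRUE
})

#' Perturbation experiment dataset
#'
#' The experimental design (per-condition stimulus and inhibitor
#' assignments) together with normalized readout values at one or more
#' acquisition times. Values lie in [0, 1]; the last timepoint is the
#' training timepoint.
#'
#' @slot stimuli,inhibitors,readouts character vectors of node names.
#' @slot design integer matrix (conditions x cues, 0/1), columns named by
#'   cue; stimuli columns first, then inhibitors.
#' @slot values numeric array conditions x readouts x timepoints in [0,1]
#'   (NA allowed for missing measurements).
#' @slot timepoints numeric vector of acquisition times (ascending; the
#'   first is the baseline, typically 0).
#'
#' @seealso [perturbationData()], [readMIDAS()], [simulateDataset()]
#' @export
setClass("PerturbationData",
         representation(stimuli = "character", inhibitors = "character",
                        readouts = "character", design = "matrix",
                        values = "array", timepoints = "numeric"))

setValidity("PerturbationData", function(object) {
  msg <- character()
  d <- object@design; v <- object@values
  cues <- c(object@stimuli, object@inhibitors)
  if (!identical(colnames(d), cues))
    msg <- c(msg, "design columns must be stimuli then inhibitors")
  if (nrow(d) && !all(d %in% c(0L, 1L)))
    msg <- c(msg, "design entries must be 0/1")
  if (length(dim(v)) != 3L)
    msg <- c(msg, "values must be a 3-d array (condition x readout x time)")
  else {
    if (dim(v)[1] != nrow(d)) msg <- c(msg, "values/design condition mismatch")
    if (dim(v)[2] != length(object@readouts))
      msg <- c(msg, "values/readouts mismatch")
    if (dim(v)[3] != length(object@timepoints))
      msg <- c(msg, "values/timepoints mismatch")
    fin <- v[is.finite(v)]
    if (length(fin) && (min(fin) < 0 || max(fin) > 1))
      msg <- c(msg, "values must lie in [0, 1]")
  }
  if (is.unsorted(object@timepoints, strictly = TRUE))
    msg <- c(msg, "timepoints must be strictly ascending")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Protein-protein interaction network (PIN)
#'
#' Undirected network of physical protein interactions; each edge carries
#' the number of experimental evidences supporting it. For shortest-path
#' scoring the traversal weight of an edge is 1/evidence.
#'
#' @slot edges data.frame with columns \code{a}, \code{b} (character,
#'   \code{a < b}) and \code{evidence} (positive integer); parallel
#'   evidences merged by summing, no self-edges.
#'
#' @seealso [interactionNetwork()], [readPIN()], [linkReliability()]
#' @export
setClass("InteractionNetwork",
         representation(edges = "data.frame"),
         prototype(edges = data.frame(a = character(), b = character(),
                                      evidence = integer(),
                                      stringsAsFactors = FALSE)))

setValidity("InteractionNetwork", function(object) {
  ed <- object@edges
  if (!all(c("a", "b", "evidence") %in% names(ed)))
    return("edges must have columns a, b, evidence")
  msg <- character()
  if (nrow(ed)) {
    if (any(ed$a == ed$b)) msg <- c(msg, "self-edges not allowed")
    if (any(ed$evidence < 1)) msg <- c(msg, "evidence counts must be >= 1")
    if (anyDuplicated(paste(pmin(ed$a, ed$b), pmax(ed$a, ed$b))))
      msg <- c(msg, "parallel edges must be merged")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
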