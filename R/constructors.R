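#' Construct a SignedNetwork
#'
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{sign}; a \code{provenance} column is optional (default
#'   \code{"prior"}).
#' @param nodes optional extra isolated nodes to include.
#' @param stimulated,inhibited,measured character vectors of node roles.
#' @param directed logical; set \code{FALSE} for undirected networks
#'   (edges are canonicalised so \code{from <= to}).
#' @return A [SignedNetwork-class] object.
#' @examples
#' net <- signedNetwork(data.frame(from = "A", to = "B", sign = 1),
#'                      stimulated = "A", measured = "B")
#' @export
signedNetwork <- function(edges = NULL, nodes = character(),
                          stimulated = character(), inhibited = character(),
                          measured = character(), directed = TRUE) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- .emptyEdges()
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$provenance)) edges$provenance <- "prior"
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$sign <- as.integer(edges$sign)
    if (!directed) {
      swap <- edges$from > edges$to
      tmp <- edges$from[swap]
      edges$from[swap] <- edges$to[swap]
      edges$to[swap] <- tmp
    }
    edges <- edges[!duplicated(paste(edges$from, edges$to, edges$sign)),
                   c("from", "to", "sign", "provenance"), drop = FALSE]
    edges <- edges[order(edges$from, edges$to, edges$sign), , drop = FALSE]
    rownames(edges) <- NULL
  }
  allNodes <- sort(unique(c(nodes, edges$from, edges$to,
                            stimulated, inhibited, measured)))
  new("SignedNetwork", nodes = allNodes, edges = edges,
      roles = list(stimulated = sort(unique(stimulated)),
                   inhibited = sort(unique(inhibited)),
                   measured = sort(unique(measured))),
      directed = directed)
}

#' Construct a PerturbationData object
#'
#' @param design 0/1 matrix or data.frame, conditions x cues.
#' @param values matrix (conditions x readouts, training timepoint only; a
#'   baseline timepoint of zeros is prepended) or 3-d array
#'   conditions x readouts x timepoints.
#' @param stimuli,inhibitors,readouts character vectors naming cues and
#'   readouts; design columns are reordered to stimuli then inhibitors.
#' @param timepoints numeric acquisition times; default \code{c(0, 30)}
#'   when a matrix is supplied, matching a 30-minute readout.
#' @return A [PerturbationData-class] object.
#' @export
perturbationData <- function(design, values, stimuli, inhibitors = character(),
                             readouts, timepoints = NULL) {
  design <- as.matrix(design)
  storage.mode(design) <- "integer"
  cues <- c(stimuli, inhibitors)
  if (is.null(colnames(design))) colnames(design) <- cues
  design <- design[, cues, drop = FALSE]
  if (length(dim(values)) == 2L) {
    if (is.null(timepoints)) timepoints <- c(0, 30)
    v <- array(NA_real_, dim = c(nrow(design), length(readouts), 2L),
               dimnames = list(NULL, readouts, timepoints))
    v[, , 1L] <- 0
    v[, , 2L] <- as.matrix(values)
    values <- v
  } else {
    if (is.null(timepoints))
      timepoints <- as.numeric(dimnames(values)[[3]])
    dimnames(values) <- list(NULL, readouts, timepoints)
  }
  new("PerturbationData", stimuli = stimuli, inhibitors = inhibitors,
      readouts = readouts, design = design, values = values,
      timepoints = as.numeric(timepoints))
}

#' Construct a protein-protein interaction network
#'
#' Parallel evidences for the same unordered pair are merged by summing
#' their counts; self-interactions are dropped.
#'
#' @param edges data.frame with columns \code{a}, \code{b},
#'   \code{evidence}.
#' @return An [InteractionNetwork-class] object.
#' @export
interactionNetwork <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:3] <- c("a", "b", "evidence")
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$evidence <- as.integer(edges$evidence)
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  lo <- pmin(edges$a, edges$b); hi <- pmax(edges$a, edges$b)
  key <- paste(lo, hi)
  ev <- tapply(edges$evidence, key, sum)
  uk <- sort(names(ev))
  parts <- strsplit(uk, " ", fixed = TRUE)
  out <- data.frame(a = vapply(parts, `[`, "", 1L),
                    b = vapply(parts, `[`, "", 2L),
                    evidence = as.integer(ev[uk]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  new("InteractionNetwork", edges = out)
}

#' Construct a LogicModel from explicit hyperedges
#'
#' Low-level constructor; most models come from [expandNetwork()].
#' Hyperedges are put into the canonical deterministic order
#' (lexicographic by target, then arity, then signed input labels).
#'
#' @param species character vector of species names.
#' @param hyperedges list of lists with components \code{inputs},
#'   \code{signs}, \code{target}, optional \code{provenance} (default
#'   \code{"prior"}) and \code{links}.
#' @return A [LogicModel-class] object.
#' @export
logicModel <- function(species, hyperedges) {
  hyperedges <- lapply(hyperedges, function(he) {
    he$inputs <- as.character(he$inputs)
    he$signs <- as.integer(he$signs)
    o <- order(he$inputs)
    he$inputs <- he$inputs[o]; he$signs <- he$signs[o]
    if (is.null(he$provenance)) he$provenance <- "prior"
    if (is.null(he$links)) he$links <- character()
    he
  })
  hyperedges <- hyperedges[order(
    vapply(hyperedges, `[[`, "", "target"),
    vapply(hyperedges, function(h) length(h$inputs), 1L),
    vapply(hyperedges, function(h)
      paste(ifelse(h$signs < 0, "!", ""), h$inputs, sep = "", collapse = "+"),
      ""))]
  new("LogicModel", species = sort(unique(species)), hyperedges = hyperedges)
}
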