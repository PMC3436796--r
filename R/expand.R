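#' Expand a network into its AND/OR logic superstructure
#'
#' For every target with k incoming edges the superstructure contains one
#' 1-input hyperedge per edge (the OR branches) plus one AND hyperedge
#' per input subset of size 2..min(k, maxAndArity), each input keeping
#' its sign. The hyperedge size weight nu equals its arity. Hyperedges
#' touching at least one integrated edge are tagged
#' \code{provenance = "integrated"} and remember the integrated link
#' identifiers they depend on, so that reliability weights can be applied
#' during training.
#'
#' @param network a directed [SignedNetwork-class] (typically the
#'   compressed, integrated network).
#' @param maxAndArity maximum number of inputs of an AND gate
#'   (default 2).
#' @return A [LogicModel-class] in deterministic hyperedge order
#'   (lexicographic by target, then arity, then signed input labels).
#' @examples
#' net <- signedNetwork(data.frame(from = c("A", "F"), to = c("G", "G"),
#'                                 sign = c(1, 1)),
#'                      stimulated = c("A", "F"), measured = "G")
#' hyperedgeLabels(expandNetwork(net))  # A=G, F=G, A+F=G
#' @export
expandNetwork <- function(network, maxAndArity = 2L) {
  if (maxAndArity < 1L) .inputError("maxAndArity must be >= 1")
  ed <- network@edges
  ed <- ed[ed$from != ed$to, , drop = FALSE]   # self-loops are not gates
  hes <- list()
  for (tgt in sort(unique(ed$to))) {
    inc <- ed[ed$to == tgt, , drop = FALSE]
    inc <- inc[order(inc$from, inc$sign), , drop = FALSE]
    k <- nrow(inc)
    for (s in seq_len(min(k, maxAndArity))) {
      for (comb in utils::combn(k, s, simplify = FALSE)) {
        if (anyDuplicated(inc$from[comb])) next  # x AND NOT x is vacuous
        prov <- if (any(inc$provenance[comb] == "integrated"))
          "integrated" else "prior"
        links <- inc$from[comb][inc$provenance[comb] == "integrated"]
        links <- if (length(links))
          paste0(links, ">", tgt) else character()
        hes[[length(hes) + 1L]] <-
          list(inputs = inc$from[comb], signs = inc$sign[comb],
               target = tgt, provenance = prov, links = links)
      }
    }
  }
  logicModel(species = network@nodes, hyperedges = hes)
}
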