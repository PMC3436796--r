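#' Compress a prior knowledge network to its identifiable core
#'
#' Iteratively removes nodes that are non-observable (no measured node
#' reachable downstream, the node itself included) or non-controllable
#' (no stimulated/inhibited node upstream), then repeatedly bypasses
#' pass-through intermediates that are neither measured nor perturbed,
#' creating edges whose sign is the product of the signs along the
#' bypassed path. Bypassing is restricted to nodes with in-degree 1, or
#' out-degree 1 with a positive outgoing edge: bypassing a multi-input
#' node through a negative edge would turn NOT(x OR y) into
#' NOT(x) OR NOT(y) and change the logic of the remaining nodes.
#'
#' @param pkn a [SignedNetwork-class] with at least one measured and one
#'   perturbed node among its roles.
#' @return A list with components \code{network} (the compressed
#'   [SignedNetwork-class]) and \code{map}, a compression map with
#'   elements \code{removedNonObservable}, \code{removedNonControllable},
#'   \code{bypassed} (list of node, incoming edges, outgoing edges) and
#'   \code{edgePaths} (per compressed edge, the original-network node
#'   paths it summarizes).
#' @examples
#' pkn <- signedNetwork(data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                 sign = c(1, 1)),
#'                      stimulated = "A", measured = "C")
#' compressNetwork(pkn)$network
#' @export
compressNetwork <- function(pkn) {
  roles <- pkn@roles
  if (!length(roles$measured) || !length(.cueNodes(pkn)))
    .inputError("PKN needs at least one measured and one perturbed node")
  ed <- pkn@edges
  nodes <- pkn@nodes
  ## per-edge list of original-network paths (node sequences)
  paths <- lapply(seq_len(nrow(ed)), function(i) list(c(ed$from[i], ed$to[i])))

  cue <- .cueNodes(pkn)
  measured <- roles$measured
  removedNO <- character(); removedNC <- character()

  dropNodes <- function(ed, paths, bad) {
    keep <- !(ed$from %in% bad) & !(ed$to %in% bad)
    list(ed = ed[keep, , drop = FALSE], paths = paths[keep])
  }

  ## phase 1: exhaust observability / controllability deletions
  repeat {
    net <- signedNetwork(ed, nodes = nodes, directed = TRUE)
    observable <- union(measured,
                        .reachableFrom(net, intersect(measured, nodes),
                                       mode = "in"))
    nonObs <- setdiff(nodes, observable)
    if (length(nonObs)) {
      removedNO <- union(removedNO, nonObs)
      nodes <- setdiff(nodes, nonObs)
      r <- dropNodes(ed, paths, nonObs); ed <- r$ed; paths <- r$paths
      next
    }
    controllable <- union(cue,
                          .reachableFrom(net, intersect(cue, nodes),
                                         mode = "out"))
    nonCtl <- setdiff(nodes, controllable)
    if (length(nonCtl)) {
      removedNC <- union(removedNC, nonCtl)
      nodes <- setdiff(nodes, nonCtl)
      r <- dropNodes(ed, paths, nonCtl); ed <- r$ed; paths <- r$paths
      next
    }
    break
  }
  if (!length(intersect(measured, nodes)) || !length(intersect(cue, nodes)))
    .infeasibleError("design covers no identifiable subnetwork")

  ## phase 2: bypass pass-through intermediates
  protected <- union(cue, measured)
  bypassed <- list()
  repeat {
    cand <- setdiff(nodes, protected)
    cand <- sort(cand)
    pick <- NULL
    for (v in cand) {
      inE <- which(ed$to == v); outE <- which(ed$from == v)
      if (!length(inE) || !length(outE)) next   # dead ends already removed
      if (length(inE) == 1L ||
          (length(outE) == 1L && all(ed$sign[outE] == 1L))) {
        pick <- v; break
      }
    }
    if (is.null(pick)) break
    v <- pick
    inE <- which(ed$to == v); outE <- which(ed$from == v)
    bypassed[[length(bypassed) + 1L]] <-
      list(node = v,
           incoming = ed[inE, c("from", "to", "sign"), drop = FALSE],
           outgoing = ed[outE, c("from", "to", "sign"), drop = FALSE])
    newEd <- ed; newPaths <- paths
    for (i in inE) for (o in outE) {
      u <- ed$from[i]; w <- ed$to[o]
      if (u == w) next                          # discard self-loops
      s <- ed$sign[i] * ed$sign[o]
      joined <- list()
      for (p1 in paths[[i]]) for (p2 in paths[[o]])
        joined[[length(joined) + 1L]] <- c(p1, p2[-1L])
      dup <- which(newEd$from == u & newEd$to == w & newEd$sign == s)
      if (length(dup)) {
        newPaths[[dup[1L]]] <- c(newPaths[[dup[1L]]], joined)
      } else {
        newEd <- rbind(newEd, data.frame(from = u, to = w, sign = s,
                                         provenance = "prior",
                                         stringsAsFactors = FALSE))
        newPaths[[nrow(newEd)]] <- joined
      }
    }
    drop <- sort(unique(c(inE, outE)))
    keep <- setdiff(seq_len(nrow(newEd)), drop)
    ed <- newEd[keep, , drop = FALSE]
    paths <- newPaths[keep]
    nodes <- setdiff(nodes, v)
  }

  o <- order(ed$from, ed$to, ed$sign)
  ed <- ed[o, , drop = FALSE]; rownames(ed) <- NULL
  paths <- paths[o]
  names(paths) <- paste(ed$from, ed$sign, ed$to)
  compressed <- signedNetwork(
    ed, nodes = nodes,
    stimulated = intersect(roles$stimulated, nodes),
    inhibited = intersect(roles$inhibited, nodes),
    measured = intersect(roles$measured, nodes))
  list(network = compressed,
       map = list(removedNonObservable = sort(removedNO),
                  removedNonControllable = sort(removedNC),
                  bypassed = bypassed,
                  edgePaths = paths))
}
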