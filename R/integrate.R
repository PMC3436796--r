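#' Map a data-driven link to its candidate prior-network insertions
#'
#' A link between a cue and a measured protein in the DDN can correspond
#' to several links in the uncompressed prior network, because the PKN
#' contains intermediate nodes the data cannot see. The candidate set is
#' the cross product U x V where U is the link source plus all nodes
#' reachable downstream of it, stopping at (and excluding) any other
#' cue, and V is the link target plus all its ancestors, stopping at
#' (and excluding) any measured node; pairs already adjacent in the PKN
#' and self-pairs are removed.
#'
#' @param from,to endpoints of the DDN link.
#' @param pkn the uncompressed [SignedNetwork-class] with role
#'   annotations.
#' @return A list with components \code{candidates} (data.frame with
#'   columns \code{u}, \code{v}) and \code{novel} (TRUE when an endpoint
#'   is absent from the PKN; the candidate set is then the link itself).
#' @export
mapLinkToPKN <- function(from, to, pkn) {
  if (!(from %in% pkn@nodes) || !(to %in% pkn@nodes))
    return(list(candidates = data.frame(u = from, v = to,
                                        stringsAsFactors = FALSE),
                novel = TRUE))
  cues <- .cueNodes(pkn)
  measured <- pkn@roles$measured
  ed <- pkn@edges
  succ <- split(ed$to, ed$from)
  pred <- split(ed$from, ed$to)
  closure <- function(start, adj, stopAt) {
    seen <- start
    frontier <- start
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- setdiff(nxt, c(seen, stopAt))
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  U <- closure(from, succ, setdiff(cues, from))
  V <- closure(to, pred, setdiff(measured, to))
  cand <- expand.grid(u = U, v = V, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$u != cand$v, , drop = FALSE]
  adjacent <- paste(ed$from, ed$to)
  cand <- cand[!(paste(cand$u, cand$v) %in% adjacent), , drop = FALSE]
  cand <- cand[order(cand$u, cand$v), , drop = FALSE]
  if (!nrow(cand))   # everything filtered: keep the link itself (J_i >= 1)
    cand <- data.frame(u = from, v = to, stringsAsFactors = FALSE)
  rownames(cand) <- NULL
  list(candidates = cand, novel = FALSE)
}

#' Integrate data-driven links into the compressed network
#'
#' Adds every DDN edge that maps into the compressed network and is not
#' already present there as a direct edge, with provenance
#' \code{"integrated"}. Undirected DDN edges (mutual-information
#' methods) are oriented cue -> readout when exactly one endpoint is a
#' cue and skipped otherwise (their direction cannot be assessed);
#' unsigned edges default to sign +1. Prior edges are never modified.
#' One integrated-link record is created per added edge, holding the
#' candidate insertions in the uncompressed PKN for later reliability
#' scoring.
#'
#' @param compressed the compressed [SignedNetwork-class] (from
#'   [compressNetwork()]).
#' @param ddn the data-driven [SignedNetwork-class].
#' @param pkn the uncompressed prior network the compression came from.
#' @return A list with components \code{network} (compressed network
#'   plus integrated edges) and \code{records}: one list per integrated
#'   link with elements \code{from}, \code{to}, \code{sign},
#'   \code{candidates}, \code{novel}, \code{reliability} (NA until
#'   [linkReliability()]), \code{weight} (1 until [penaltyWeights()]).
#' @export
integrateLinks <- function(compressed, ddn, pkn) {
  cues <- .cueNodes(compressed)
  measured <- compressed@roles$measured
  ed <- ddn@edges
  out <- compressed@edges
  records <- list()
  for (k in seq_len(nrow(ed))) {
    from <- ed$from[k]; to <- ed$to[k]; sgn <- ed$sign[k]
    if (!ddn@directed || is.na(sgn)) {
      endCue <- c(from, to) %in% cues
      if (!ddn@directed) {
        if (sum(endCue) != 1L) {
          warning(sprintf(
            "undirected link %s-%s skipped: direction cannot be assessed",
            from, to))
          next
        }
        if (endCue[2L]) { tmp <- from; from <- to; to <- tmp }
      }
      if (is.na(sgn)) sgn <- 1L  # unsigned data-driven link: assume activation
    }
    if (!(from %in% compressed@nodes) || !(to %in% compressed@nodes)) {
      warning(sprintf("DDN link %s->%s skipped: endpoint not in %s",
                      from, to, "compressed network"))
      next
    }
    if (from == to) next
    if (any(out$from == from & out$to == to & out$sign == sgn))
      next                                   # already present: no-op
    out <- rbind(out, data.frame(from = from, to = to, sign = sgn,
                                 provenance = "integrated",
                                 stringsAsFactors = FALSE))
    mp <- mapLinkToPKN(from, to, pkn)
    records[[length(records) + 1L]] <-
      list(from = from, to = to, sign = sgn,
           candidates = mp$candidates, novel = mp$novel,
           reliability = NA_real_, weight = 1)
  }
  net <- signedNetwork(out, nodes = compressed@nodes,
                       stimulated = compressed@roles$stimulated,
                       inhibited = compressed@roles$inhibited,
                       measured = compressed@roles$measured)
  list(network = net, records = records)
}
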