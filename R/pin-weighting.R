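#' Evidence-weighted shortest-path distance in a PIN
#'
#' Dijkstra shortest-path distance between two proteins, with each
#' interaction weighted by the inverse of the number of experimental
#' evidences validating it (well-supported interactions are cheap to
#' traverse). Returns \code{Inf} when the proteins are disconnected or
#' absent from the network; \code{d(u, u) = 0}.
#'
#' @param pin an [InteractionNetwork-class].
#' @param u,v protein identifiers.
#' @return Non-negative numeric distance, possibly \code{Inf}.
#' @export
shortestPathDistance <- function(pin, u, v) {
  if (u == v) return(0)
  g <- .pinIgraph(pin)
  vn <- igraph::V(g)$name
  if (!(u %in% vn) || !(v %in% vn)) return(Inf)
  as.numeric(igraph::distances(g, v = u, to = v,
                               weights = igraph::E(g)$weight))
}

#' Reliability score of an integrated link
#'
#' The reliability of an integrated link is the minimum evidence-weighted
#' shortest-path distance over all its candidate insertions in the
#' uncompressed prior network: if any candidate pair is connected by a
#' short, well-supported path of physical interactions, a molecular
#' pathway realizing the link is plausible.
#'
#' @param record one integrated-link record (from [integrateLinks()]).
#' @param pin an [InteractionNetwork-class].
#' @return The record with its \code{reliability} element set (may be
#'   \code{Inf} when no candidate pair is connected).
#' @export
linkReliability <- function(record, pin) {
  stopifnot(nrow(record$candidates) >= 1L)
  g <- .pinIgraph(pin)
  vn <- igraph::V(g)$name
  dvals <- vapply(seq_len(nrow(record$candidates)), function(i) {
    u <- record$candidates$u[i]; v <- record$candidates$v[i]
    if (u == v) return(0)
    if (!(u %in% vn) || !(v %in% vn)) return(Inf)
    as.numeric(igraph::distances(g, v = u, to = v,
                                 weights = igraph::E(g)$weight))
  }, 0)
  record$reliability <- min(dvals)
  record
}

#' Penalty weights for integrated links
#'
#' Converts reliability distances to training penalty weights in (0, 1]:
#' w_i = d_i / d_cap for finite d_i, where d_cap is the largest finite
#' reliability across records; disconnected or unmappable links get the
#' maximal weight 1 (lack of interaction support penalizes but does not
#' forbid a link — the optimizer may still select it if the data demand
#' it). Higher weight means a stronger penalty during training.
#'
#' @param records list of integrated-link records with reliabilities set
#'   (see [linkReliability()]).
#' @param pin optional [InteractionNetwork-class]: when supplied,
#'   reliabilities are (re)computed first.
#' @return The records with \code{weight} elements set.
#' @export
penaltyWeights <- function(records, pin = NULL) {
  if (!length(records)) return(records)
  if (!is.null(pin)) records <- lapply(records, linkReliability, pin = pin)
  d <- vapply(records, function(r) r$reliability, 0)
  if (anyNA(d))
    .inputError("reliabilities not computed; supply a PIN")
  finite <- d[is.finite(d)]
  dCap <- if (length(finite) && max(finite) > 0) max(finite) else NA_real_
  lapply(records, function(r) {
    r$weight <- if (is.na(dCap) || !is.finite(r$reliability) ||
                    r$reliability >= dCap) 1
    else max(r$reliability / dCap, 1e-6)  # keep weights in (0, 1]
    r
  })
}

#' Hop-count shortest-path distributions of PKN, integrated and random
#' links in the PIN
#'
#' For each group the unweighted (number-of-edges) shortest-path length
#' of the relevant node pairs in the interaction network: prior-network
#' edges, integrated links (minimum over each record's candidate pairs),
#' and uniformly drawn random protein pairs. Prior links are expected to
#' sit close in the interaction network; random pairs farther away.
#'
#' @param pkn the prior [SignedNetwork-class].
#' @param records integrated-link records.
#' @param pin an [InteractionNetwork-class].
#' @param nRandom number of random pairs to draw.
#' @param seed integer seed for the random pairs.
#' @return data.frame with columns \code{group} (\code{"pkn"},
#'   \code{"integrated"}, \code{"random"}) and \code{hops}
#'   (\code{Inf} for disconnected pairs).
#' @export
pinMappingReport <- function(pkn, records, pin, nRandom = 100L, seed = 1L) {
  g <- .pinIgraph(pin)
  vn <- igraph::V(g)$name
  hop <- function(u, v) {
    if (u == v) return(0)
    if (!(u %in% vn) || !(v %in% vn)) return(Inf)
    as.numeric(igraph::distances(g, v = u, to = v, weights = NA))
  }
  ed <- pkn@edges
  pknHops <- vapply(seq_len(nrow(ed)),
                    function(i) hop(ed$from[i], ed$to[i]), 0)
  intHops <- vapply(records, function(r)
    min(vapply(seq_len(nrow(r$candidates)), function(i)
      hop(r$candidates$u[i], r$candidates$v[i]), 0)), 0)
  set.seed(seed)
  rndHops <- vapply(seq_len(nRandom), function(i) {
    uv <- sample(vn, 2L)
    hop(uv[1L], uv[2L])
  }, 0)
  rbind(
    data.frame(group = "pkn", hops = pknHops, stringsAsFactors = FALSE),
    data.frame(group = "integrated", hops = intHops,
               stringsAsFactors = FALSE),
    data.frame(group = "random", hops = rndHops, stringsAsFactors = FALSE))
}
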