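#' Per-readout Boolean effect tables (FEED, step 1)
#'
#' For each measured protein, codifies which stimulus/inhibitor
#' combinations significantly affect it: a condition has a significant
#' effect when it shifts the readout, relative to the reference, by more
#' than \code{kSigma * epsilon}, i.e. by more than the uncertainty
#' associated with the measurement. The reference is the fully
#' unperturbed condition when the design contains one, and the baseline
#' value 0 otherwise (normalized values are changes from baseline).
#' The signed magnitude of change is retained per row.
#'
#' @param dataset a normalized [PerturbationData-class].
#' @param epsilon measurement uncertainty on the normalized scale
#'   (estimated from replicates when available, otherwise user-supplied).
#' @param kSigma significance multiplier (default 2).
#' @return A list with one element per readout: a list with components
#'   \code{readout} and \code{rows}, a data.frame with columns
#'   \code{condition}, \code{nStimuli}, \code{nInhibitors},
#'   \code{stimulus}, \code{inhibitor} (NA unless the row has exactly one
#'   of the kind), \code{delta}, \code{significant}.
#' @export
feedEffectTables <- function(dataset, epsilon = 0.1, kSigma = 2) {
  if (!(epsilon > 0)) .inputError("epsilon must be > 0")
  obs <- trainingValues(dataset)
  d <- dataset@design
  nS <- rowSums(d[, dataset@stimuli, drop = FALSE])
  nI <- rowSums(d[, dataset@inhibitors, drop = FALSE])
  baseRow <- which(nS == 0 & nI == 0)
  thr <- kSigma * epsilon
  oneName <- function(i, cues) {
    on <- cues[d[i, cues] == 1L]
    if (length(on) == 1L) on else NA_character_
  }
  lapply(readoutNames(dataset), function(m) {
    ref <- if (length(baseRow)) obs[baseRow[1L], m] else 0
    if (is.na(ref)) ref <- 0
    delta <- obs[, m] - ref
    rows <- data.frame(
      condition = seq_len(nrow(d)),
      nStimuli = nS, nInhibitors = nI,
      stimulus = vapply(seq_len(nrow(d)), oneName, "", cues = dataset@stimuli),
      inhibitor = vapply(seq_len(nrow(d)), oneName, "",
                         cues = dataset@inhibitors),
      delta = delta,
      significant = !is.na(delta) & abs(delta) > thr,
      stringsAsFactors = FALSE)
    list(readout = m, rows = rows)
  })
}

#' Translate effect tables into a data-driven network (FEED, step 2)
#'
#' Builds the cause-effect network among stimulated, inhibited and
#' measured nodes from the Boolean effect tables:
#' \enumerate{
#'   \item a stimulus s with a significant effect on readout m in its
#'     inhibitor-free row yields edge s -> m, signed by the direction of
#'     change;
#'   \item an inhibitor whose sole perturbation significantly shifts m
#'     yields edge i -> m (sign opposite to the shift: clamping i to 0
#'     lowering m means i activates m);
#'   \item when inhibiting i abolishes an (s, m) response, the response
#'     is rerouted through the inhibited protein: edges s -> i and
#'     i -> m (both +1) replace the direct s -> m edge; when inhibiting
#'     i enables a response absent without the drug, s -> i (+1) and
#'     i -> m (-1) are added.
#' }
#' Only single-perturbation contrasts are exploited; rows with multiple
#' simultaneous stimuli remain available in the tables for diagnostics.
#'
#' @param tables output of [feedEffectTables()].
#' @param dataset the [PerturbationData-class] the tables came from
#'   (provides cue/readout roles).
#' @return A directed [SignedNetwork-class] (the DDN) with edge
#'   provenance \code{"ddn"}.
#' @export
feedNetwork <- function(tables, dataset) {
  edges <- data.frame(from = character(), to = character(),
                      sign = integer(), stringsAsFactors = FALSE)
  drop <- data.frame(from = character(), to = character(),
                     stringsAsFactors = FALSE)
  addEdge <- function(from, to, sign) {
    edges[nrow(edges) + 1L, ] <<- list(from, to, as.integer(sign))
  }
  for (tab in tables) {
    m <- tab$readout
    r <- tab$rows
    singleS <- r[r$nStimuli == 1 & r$nInhibitors == 0 & !is.na(r$stimulus), ]
    singleI <- r[r$nStimuli == 0 & r$nInhibitors == 1 & !is.na(r$inhibitor), ]
    pairs <- r[r$nStimuli == 1 & r$nInhibitors == 1 &
                 !is.na(r$stimulus) & !is.na(r$inhibitor), ]
    ## rule (i): stimulus alone affects m
    for (j in seq_len(nrow(singleS)))
      if (singleS$significant[j] && singleS$stimulus[j] != m)
        addEdge(singleS$stimulus[j], m, sign(singleS$delta[j]))
    ## rule (ii): inhibitor alone affects m
    for (j in seq_len(nrow(singleI)))
      if (singleI$significant[j] && singleI$inhibitor[j] != m)
        addEdge(singleI$inhibitor[j], m, -sign(singleI$delta[j]))
    ## rule (iii): inhibition flips the stimulus response
    for (j in seq_len(nrow(pairs))) {
      s <- pairs$stimulus[j]; i <- pairs$inhibitor[j]
      ref <- singleS[singleS$stimulus == s, ]
      if (!nrow(ref)) next
      sigFree <- ref$significant[1L]
      sigPair <- pairs$significant[j]
      if (sigFree && !sigPair) {          # inhibition abolishes the response
        if (s != i) addEdge(s, i, 1L)
        if (i != m) addEdge(i, m, 1L)
        if (s != m) drop[nrow(drop) + 1L, ] <- list(s, m)
      } else if (!sigFree && sigPair) {   # inhibition enables a response
        if (s != i) addEdge(s, i, 1L)
        if (i != m) addEdge(i, m, -1L)
      }
    }
  }
  if (nrow(drop) && nrow(edges)) {
    bad <- paste(edges$from, edges$to) %in% paste(drop$from, drop$to) &
      edges$from %in% dataset@stimuli & edges$to %in% readoutNames(dataset)
    edges <- edges[!bad, , drop = FALSE]
  }
  if (nrow(edges)) {
    edges <- edges[!duplicated(paste(edges$from, edges$to, edges$sign)), ,
                   drop = FALSE]
    edges$provenance <- "ddn"
  } else edges <- NULL
  signedNetwork(edges,
                nodes = c(dataset@stimuli, dataset@inhibitors,
                          readoutNames(dataset)),
                stimulated = dataset@stimuli,
                inhibited = dataset@inhibitors,
                measured = readoutNames(dataset))
}

#' FEED inference of a data-driven network
#'
#' Convenience wrapper chaining [feedEffectTables()] and
#' [feedNetwork()].
#'
#' @inheritParams feedEffectTables
#' @return A directed [SignedNetwork-class] (the DDN).
#' @export
inferFEED <- function(dataset, epsilon = 0.1, kSigma = 2)
  feedNetwork(feedEffectTables(dataset, epsilon, kSigma), dataset)
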