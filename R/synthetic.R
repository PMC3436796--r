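#' Random gold-standard signalling network
#'
#' Generates a random acyclic signed network with assigned experimental
#' roles, interpreted as a Boolean logic model (one OR branch per edge,
#' all gates on) to serve as the ground truth for benchmarking the
#' inference pipeline. Stimuli are sources (first in the topological
#' order), readouts sit downstream, and every readout is guaranteed to
#' be reachable from at least one stimulus (the network is resampled a
#' bounded number of times otherwise).
#'
#' @param nNodes total number of nodes (default 12).
#' @param nStimuli number of stimulated nodes (default 3; must be >= 1).
#' @param nInhibited number of drug-inhibited nodes (default 2).
#' @param nReadouts number of measured nodes (default 4).
#' @param edgeDensity probability of each forward edge (default 0.25).
#' @param pNegative probability that an edge is inhibitory (default 0:
#'   signalling benchmark cascades are activating).
#' @param seed integer seed; identical seeds give identical networks.
#' @param maxTries resampling budget (default 200).
#' @return A list of class \code{"goldStandard"} with elements
#'   \code{network} ([SignedNetwork-class]), \code{truthModel}
#'   ([LogicModel-class], OR-only expansion) and \code{design} (list of
#'   stimuli, inhibited, readouts).
#' @export
randomGoldStandard <- function(nNodes = 12L, nStimuli = 3L, nInhibited = 2L,
                               nReadouts = 4L, edgeDensity = 0.25,
                               pNegative = 0, seed = 1L, maxTries = 200L) {
  if (nStimuli < 1L)
    .infeasibleError("need at least one stimulus (nothing controllable)")
  if (nStimuli + nInhibited + nReadouts > nNodes)
    .infeasibleError("role counts exceed nNodes")
  set.seed(.subSeed(seed, 0L))
  nHidden <- nNodes - nStimuli - nInhibited - nReadouts
  stimuli <- sprintf("S%02d", seq_len(nStimuli))
  readouts <- sprintf("M%02d", seq_len(nReadouts))
  inhibited <- if (nInhibited) sprintf("I%02d", seq_len(nInhibited))
    else character()
  hidden <- if (nHidden) sprintf("H%02d", seq_len(nHidden)) else character()
  for (try in seq_len(maxTries)) {
    middle <- sample(c(inhibited, hidden))
    ord <- c(sample(stimuli), middle, sample(readouts))
    n <- length(ord)
    edges <- NULL
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      if (stats::runif(1) < edgeDensity) {
        s <- if (stats::runif(1) < pNegative) -1L else 1L
        edges <- rbind(edges, data.frame(from = ord[i], to = ord[j],
                                         sign = s, stringsAsFactors = FALSE))
      }
    }
    if (is.null(edges)) next
    net <- signedNetwork(edges, nodes = ord, stimulated = stimuli,
                         inhibited = inhibited, measured = readouts)
    reach <- .reachableFrom(net, stimuli, mode = "out")
    if (all(readouts %in% reach)) {
      truth <- expandNetwork(net, maxAndArity = 1L)
      return(structure(list(network = net, truthModel = truth,
                            design = list(stimuli = stimuli,
                                          inhibited = inhibited,
                                          readouts = readouts)),
                       class = "goldStandard"))
    }
  }
  .infeasibleError(
    "could not generate a gold standard with all readouts reachable")
}

#' Simulate a perturbation dataset from a gold standard
#'
#' Simulates the Boolean steady state of the truth model under a
#' combinatorial stimulation design and adds truncated Gaussian noise.
#' A baseline (all cues off) timepoint-0 layer of zeros is included so
#' the dataset is MIDAS-writable.
#'
#' @param gs a gold standard from [randomGoldStandard()].
#' @param scheme \code{"single+pairs"} (default: unperturbed control,
#'   each stimulus alone, each stimulus x each inhibitor),
#'   \code{"single"}, or \code{"full-factorial"} (all on/off cue
#'   combinations).
#' @param noiseSd standard deviation of additive Gaussian noise,
#'   truncated to [0, 1] (default 0: exact Boolean responses).
#' @param seed integer seed for the noise.
#' @return A [PerturbationData-class].
#' @export
simulateDataset <- function(gs, scheme = c("single+pairs", "single",
                                           "full-factorial"),
                            noiseSd = 0, seed = 1L) {
  scheme <- match.arg(scheme)
  d <- gs$design
  cues <- c(d$stimuli, d$inhibited)
  rows <- list(stats::setNames(rep(0L, length(cues)), cues))
  for (s in d$stimuli) {
    r <- rows[[1L]]; r[s] <- 1L
    rows[[length(rows) + 1L]] <- r
  }
  if (scheme %in% c("single+pairs") && length(d$inhibited)) {
    for (s in d$stimuli) for (i in d$inhibited) {
      r <- rows[[1L]]; r[s] <- 1L; r[i] <- 1L
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (scheme == "full-factorial") {
    grid <- expand.grid(rep(list(0:1), length(cues)), KEEP.OUT.ATTRS = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i)
      stats::setNames(as.integer(grid[i, ]), cues))
  }
  design <- do.call(rbind, rows)
  design <- design[!duplicated(design), , drop = FALSE]
  ds0 <- perturbationData(design,
                          matrix(0, nrow(design), length(d$readouts)),
                          stimuli = d$stimuli, inhibitors = d$inhibited,
                          readouts = d$readouts)
  sim <- simulateConditions(gs$truthModel, dataset = ds0)
  vals <- sim[, d$readouts, drop = FALSE]
  if (noiseSd > 0) {
    set.seed(.subSeed(seed, 1L))
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noiseSd),
                          nrow(vals), ncol(vals))
    vals <- pmin(pmax(vals, 0), 1)
  }
  perturbationData(design, vals, stimuli = d$stimuli,
                   inhibitors = d$inhibited, readouts = d$readouts)
}

#' Classify data-driven links against a gold standard
#'
#' Each DDN edge is classified as \code{direct_tp} (present in the gold
#' standard), \code{indirect} (a directed gold-standard path connects
#' its endpoints) or \code{spurious} (neither). Gold-standard edges with
#' no direct DDN counterpart are counted \code{missed} (an indirect DDN
#' edge subsuming them does not rescue them: the individual link is
#' still not reconstructed).
#'
#' @param ddn a [SignedNetwork-class] inferred from data.
#' @param gs a gold standard from [randomGoldStandard()] (or any object
#'   with a \code{network} element).
#' @return Named integer vector with components \code{direct_tp},
#'   \code{indirect}, \code{missed}, \code{spurious};
#'   direct_tp + indirect + spurious equals the DDN edge count.
#' @export
classifyLinks <- function(ddn, gs) {
  gnet <- if (is(gs, "SignedNetwork")) gs else gs$network
  ged <- gnet@edges
  gKey <- paste(ged$from, ged$to)
  g <- .asIgraph(gnet)
  dist <- igraph::distances(g, mode = "out", weights = NA)
  reach <- is.finite(dist)
  ded <- ddn@edges
  classes <- character(nrow(ded))
  covered <- logical(nrow(ged))
  for (k in seq_len(nrow(ded))) {
    u <- ded$from[k]; v <- ded$to[k]
    if (!ddn@directed) {
      ## undirected edge: use whichever orientation the gold net supports
      if (!(u %in% rownames(reach)) || !(v %in% rownames(reach))) {
        classes[k] <- "spurious"; next
      }
      if (!(paste(u, v) %in% gKey) && !reach[u, v] &&
          ((paste(v, u) %in% gKey) || reach[v, u])) {
        tmp <- u; u <- v; v <- tmp
      }
    }
    if (!(u %in% rownames(reach)) || !(v %in% rownames(reach))) {
      classes[k] <- "spurious"
    } else if (paste(u, v) %in% gKey) {
      classes[k] <- "direct_tp"
      covered[gKey == paste(u, v)] <- TRUE
    } else if (reach[u, v]) {
      classes[k] <- "indirect"
    } else classes[k] <- "spurious"
  }
  c(direct_tp = sum(classes == "direct_tp"),
    indirect = sum(classes == "indirect"),
    missed = sum(!covered),
    spurious = sum(classes == "spurious"))
}

#' Synthetic protein-interaction network around a signed network
#'
#' Builds a PIN for testing: the undirected skeleton of the given
#' network, plus random decoy interactions, with per-edge evidence
#' counts sampled from 1-5. Labelled synthetic; real PINs come from
#' curated interaction databases via [readPIN()].
#'
#' @param network a [SignedNetwork-class] whose skeleton the PIN must
#'   contain.
#' @param nDecoys number of extra random interactions (default 10).
#' @param seed integer seed.
#' @return An [InteractionNetwork-class].
#' @export
syntheticPIN <- function(network, nDecoys = 10L, seed = 1L) {
  set.seed(.subSeed(seed, 2L))
  ed <- network@edges
  base <- unique(data.frame(a = pmin(ed$from, ed$to),
                            b = pmax(ed$from, ed$to),
                            stringsAsFactors = FALSE))
  nodes <- network@nodes
  have <- paste(base$a, base$b)
  k <- 0L; tries <- 0L
  while (k < nDecoys && tries < 50L * nDecoys && length(nodes) >= 2L) {
    uv <- sort(sample(nodes, 2L))
    tries <- tries + 1L
    if (paste(uv[1L], uv[2L]) %in% have) next
    base <- rbind(base, data.frame(a = uv[1L], b = uv[2L],
                                   stringsAsFactors = FALSE))
    have <- c(have, paste(uv[1L], uv[2L]))
    k <- k + 1L
  }
  base$evidence <- sample(1:5, nrow(base), replace = TRUE)
  interactionNetwork(base)
}
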