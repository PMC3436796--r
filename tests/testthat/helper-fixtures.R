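## shared fixtures and independent oracles (built in code, no files)

## one-readout dataset from explicit condition rows
## rows: list of list(s = stimuli on, i = inhibitors on, val = named readouts)
makeDataset <- function(rows, stimuli, inhibitors = character(), readouts) {
  cues <- c(stimuli, inhibitors)
  design <- do.call(rbind, lapply(rows, function(r) {
    on <- stats::setNames(rep(0L, length(cues)), cues)
    on[r$s] <- 1L; on[r$i] <- 1L
    matrix(on, 1L, dimnames = list(NULL, cues))
  }))
  vals <- do.call(rbind, lapply(rows, function(r) {
    v <- stats::setNames(rep(NA_real_, length(readouts)), readouts)
    v[names(r$val)] <- r$val
    matrix(v, 1L, dimnames = list(NULL, readouts))
  }))
  perturbationData(design, vals, stimuli = stimuli,
                   inhibitors = inhibitors, readouts = readouts)
}

## independent oracle: recursive Boolean evaluation for acyclic models
recursiveBooleanEval <- function(model, P, stimuli, inhibited) {
  sp <- speciesNames(model)
  hes <- hyperedges(model)[as.logical(P)]
  byTarget <- split(hes, vapply(hes, `[[`, "", "target"))
  memo <- new.env()
  value <- function(s) {
    if (s %in% inhibited) return(0)
    if (s %in% stimuli) return(1)
    if (!is.null(memo[[s]])) return(memo[[s]])
    hs <- byTarget[[s]]
    if (is.null(hs)) { memo[[s]] <- 0; return(0) }
    v <- 0
    for (he in hs) {
      term <- 1
      for (j in seq_along(he$inputs)) {
        x <- value(he$inputs[j])
        if (he$signs[j] < 0) x <- 1 - x
        term <- term * x
      }
      v <- max(v, term)
    }
    memo[[s]] <- v
    v
  }
  stats::setNames(vapply(sp, value, 0), sp)
}

## random acyclic signed PKN in which every root is a stimulus, so all
## nodes are controllable and compression is logic-preserving even with
## inhibitory edges
randomControllablePKN <- function(seed, nNodes = 10L, nStimuli = 2L,
                                  nInhibited = 1L, nReadouts = 3L,
                                  edgeDensity = 0.3, pNegative = 0.2) {
  set.seed(seed)
  stim <- sprintf("S%d", seq_len(nStimuli))
  inh <- if (nInhibited) sprintf("I%d", seq_len(nInhibited)) else character()
  meas <- sprintf("M%d", seq_len(nReadouts))
  nHidden <- nNodes - nStimuli - nInhibited - nReadouts
  hid <- if (nHidden > 0) sprintf("H%d", seq_len(nHidden)) else character()
  ord <- c(stim, sample(c(inh, hid)), meas)
  n <- length(ord)
  edges <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (stats::runif(1) < edgeDensity) {
      s <- if (stats::runif(1) < pNegative) -1L else 1L
      edges <- rbind(edges, data.frame(from = ord[i], to = ord[j], sign = s,
                                       stringsAsFactors = FALSE))
    }
  }
  ## every non-stimulus node gets an incoming edge from an earlier node
  for (j in (nStimuli + 1L):n) {
    if (is.null(edges) || !any(edges$to == ord[j])) {
      i <- sample.int(j - 1L, 1L)
      edges <- rbind(edges, data.frame(from = ord[i], to = ord[j], sign = 1L,
                                       stringsAsFactors = FALSE))
    }
  }
  signedNetwork(edges, nodes = ord, stimulated = stim, inhibited = inh,
                measured = meas)
}

## all cue on/off combinations of a network's roles
allCueConditions <- function(net) {
  roles <- networkRoles(net)
  cues <- c(roles$stimulated, roles$inhibited)
  grid <- expand.grid(rep(list(0:1), length(cues)), KEEP.OUT.ATTRS = FALSE)
  colnames(grid) <- cues
  grid
}

## brute-force minimum weighted path length in a PIN (independent oracle)
bruteForcePinDistance <- function(pin, u, v) {
  if (u == v) return(0)
  ed <- pinEdges(pin)
  g <- igraph::graph_from_data_frame(ed[, c("a", "b")], directed = FALSE,
                                     vertices = unique(c(ed$a, ed$b)))
  if (!(u %in% igraph::V(g)$name) || !(v %in% igraph::V(g)$name)) return(Inf)
  paths <- igraph::all_simple_paths(g, from = u, to = v)
  if (!length(paths)) return(Inf)
  w <- stats::setNames(1 / ed$evidence, paste(ed$a, ed$b))
  w2 <- stats::setNames(1 / ed$evidence, paste(ed$b, ed$a))
  w <- c(w, w2)
  min(vapply(paths, function(p) {
    nm <- names(p)
    sum(w[paste(nm[-length(nm)], nm[-1L])])
  }, 0))
}

## OR-only all-gates-on logic model of a signed network
orOnlyModel <- function(net) expandNetwork(net, maxAndArity = 1L)
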