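## internal helpers: error classes, igraph conversion, condition handling

.inputError <- function(fmt, ...) {
  stop(structure(class = c("bsnInputError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

.infeasibleError <- function(fmt, ...) {
  stop(structure(class = c("bsnInfeasibleError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

## SignedNetwork -> igraph, preserving isolated nodes
.asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    net@edges[, c("from", "to"), drop = FALSE],
    directed = net@directed, vertices = net@nodes)
}

## PIN -> igraph with traversal weight 1/evidence on each edge
.pinIgraph <- function(pin) {
  ed <- pin@edges
  g <- igraph::graph_from_data_frame(ed[, c("a", "b"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = sort(unique(c(ed$a, ed$b))))
  igraph::E(g)$weight <- 1 / ed$evidence
  g
}

## nodes from which `targets` are reachable / nodes reachable from `sources`
.reachableFrom <- function(net, sources, mode = "out") {
  if (!length(sources)) return(character())
  g <- .asIgraph(net)
  out <- unique(unlist(lapply(sources, function(s)
    names(igraph::subcomponent(g, s, mode = mode)))))
  out
}

.cueNodes <- function(net)
  unique(c(net@roles$stimulated, net@roles$inhibited))

## cue sets of condition i of a dataset
.conditionCues <- function(dataset, i) {
  d <- dataset@design[i, ]
  on <- names(d)[d == 1L]
  list(stimuliOn = intersect(on, dataset@stimuli),
       inhibitorsOn = intersect(on, dataset@inhibitors))
}

.conditionLabel <- function(dataset, i) {
  cc <- .conditionCues(dataset, i)
  paste0("S{", paste(cc$stimuliOn, collapse = ","), "}I{",
         paste(cc$inhibitorsOn, collapse = ","), "}")
}

## deterministic integer sub-seed derived from a base seed (< 2^31)
.subSeed <- function(seed, k) (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
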