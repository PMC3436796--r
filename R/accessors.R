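#' @name accessors
#' @title Accessors for BoolSigNet classes
#' @description Accessor generics for the network, logic-model, dataset
#'   and interaction-network classes.
#' @param object a BoolSigNet object.
#' @return The requested component (see each method).
NULL

#' @rdname accessors
#' @export
setGeneric("nodeNames", function(object) standardGeneric("nodeNames"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("networkRoles", function(object) standardGeneric("networkRoles"))
#' @rdname accessors
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setGeneric("hyperedges", function(object) standardGeneric("hyperedges"))
#' @rdname accessors
#' @export
setGeneric("nHyperedges", function(object) standardGeneric("nHyperedges"))
#' @rdname accessors
#' @export
setGeneric("hyperedgeLabels", function(object) standardGeneric("hyperedgeLabels"))
#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @rdname accessors
#' @export
setGeneric("readoutNames", function(object) standardGeneric("readoutNames"))
#' @rdname accessors
#' @export
setGeneric("dataValues", function(object) standardGeneric("dataValues"))
#' @rdname accessors
#' @export
setGeneric("trainingValues", function(object) standardGeneric("trainingValues"))
#' @rdname accessors
#' @export
setGeneric("nDataPoints", function(object) standardGeneric("nDataPoints"))
#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("pinEdges", function(object) standardGeneric("pinEdges"))

#' @rdname accessors
setMethod("nodeNames", "SignedNetwork", function(object) object@nodes)
#' @rdname accessors
setMethod("edgeTable", "SignedNetwork", function(object) object@edges)
#' @rdname accessors
setMethod("networkRoles", "SignedNetwork", function(object) object@roles)

#' @rdname accessors
setMethod("speciesNames", "LogicModel", function(object) object@species)
#' @rdname accessors
setMethod("hyperedges", "LogicModel", function(object) object@hyperedges)
#' @rdname accessors
setMethod("nHyperedges", "LogicModel", function(object) length(object@hyperedges))

#' @rdname accessors
setMethod("hyperedgeLabels", "LogicModel", function(object) {
  vapply(object@hyperedges, function(he)
    paste0(paste0(ifelse(he$signs < 0, "!", ""), he$inputs, collapse = "+"),
           "=", he$target), "")
})

#' @rdname accessors
setMethod("designMatrix", "PerturbationData", function(object) object@design)
#' @rdname accessors
setMethod("readoutNames", "PerturbationData", function(object) object@readouts)
#' @rdname accessors
setMethod("dataValues", "PerturbationData", function(object) object@values)
#' @rdname accessors
setMethod("timePoints", "PerturbationData", function(object) object@timepoints)

#' @rdname accessors
setMethod("trainingValues", "PerturbationData", function(object) {
  nt <- length(object@timepoints)
  m <- object@values[, , nt, drop = FALSE]
  dim(m) <- dim(object@values)[1:2]
  colnames(m) <- object@readouts
  m
})

#' @rdname accessors
setMethod("nDataPoints", "PerturbationData", function(object)
  sum(!is.na(trainingValues(object))))

#' @rdname accessors
setMethod("pinEdges", "InteractionNetwork", function(object) object@edges)

## arity (number of inputs) of each hyperedge -- the size weight nu
.heArity <- function(model)
  vapply(model@hyperedges, function(h) length(h$inputs), 1L)

.heTargets <- function(model)
  vapply(model@hyperedges, `[[`, "", "target")

.heProvenance <- function(model)
  vapply(model@hyperedges, `[[`, "", "provenance")

setMethod("show", "SignedNetwork", function(object) {
  r <- object@roles
  cat(sprintf("%s SignedNetwork: %d nodes, %d edges\n",
              if (object@directed) "directed" else "undirected",
              length(object@nodes), nrow(object@edges)))
  cat(sprintf("  stimulated: %s\n  inhibited:  %s\n  measured:   %s\n",
              paste(r$stimulated, collapse = " "),
              paste(r$inhibited, collapse = " "),
              paste(r$measured, collapse = " ")))
  pv <- table(object@edges$provenance)
  if (length(pv))
    cat("  provenance:", paste(names(pv), pv, sep = "=", collapse = " "), "\n")
})

setMethod("show", "LogicModel", function(object) {
  cat(sprintf("LogicModel: %d species, %d hyperedges\n",
              length(object@species), length(object@hyperedges)))
  lab <- hyperedgeLabels(object)
  if (length(lab)) {
    shown <- utils::head(lab, 12L)
    cat(" ", paste(shown, collapse = ", "))
    if (length(lab) > 12L) cat(", ...")
    cat("\n")
  }
})

setMethod("show", "PerturbationData", function(object) {
  cat(sprintf(paste0("PerturbationData: %d conditions x %d readouts x %d",
                     " timepoints (N = %d training points)\n"),
              nrow(object@design), length(object@readouts),
              length(object@timepoints), nDataPoints(object)))
  cat(sprintf("  stimuli: %s\n  inhibitors: %s\n",
              paste(object@stimuli, collapse = " "),
              paste(object@inhibitors, collapse = " ")))
})

setMethod("show", "InteractionNetwork", function(object) {
  ed <- object@edges
  cat(sprintf("InteractionNetwork: %d proteins, %d interactions\n",
              length(unique(c(ed$a, ed$b))), nrow(ed)))
  if (nrow(ed))
    cat(sprintf("  evidence counts: %d-%d (median %.0f)\n",
                min(ed$evidence), max(ed$evidence),
                stats::median(ed$evidence)))
})
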