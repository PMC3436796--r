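## Synchronous Boolean steady-state simulation of a logic model.
##
## Semantics: stimulated species are clamped to 1 and inhibited species to
## 0 (clamps override updates); every other species is updated
## synchronously as the OR over its selected hyperedges, each hyperedge
## being the AND over its inputs with NOT x = 1 - x for sign -1; species
## with no selected incoming hyperedge stay at their initial value 0.
## Iteration stops at a fixed point or after ceiling(1.2 * nSpecies)
## steps; species that have not reached a fixed point are returned NA.

## compile selected hyperedges into per-target input index lists
.compilePlan <- function(model, P) {
  sp <- model@species
  hes <- model@hyperedges[as.logical(P)]
  plan <- list()
  for (he in hes) {
    entry <- list(idx = match(he$inputs, sp), neg = he$signs < 0L)
    plan[[he$target]] <- c(plan[[he$target]], list(entry))
  }
  plan
}

## core engine: nCond x nSpecies state matrix, clamp masks same shape
.simulateCore <- function(model, P, clamp1, clamp0) {
  sp <- model@species
  n <- length(sp)
  nc <- nrow(clamp1)
  plan <- .compilePlan(model, P)
  tIdx <- match(names(plan), sp)
  X <- matrix(0, nc, n, dimnames = list(NULL, sp))
  applyClamp <- function(X) { X[clamp1] <- 1; X[clamp0] <- 0; X }
  X <- applyClamp(X)
  step <- function(X) {
    newX <- matrix(0, nc, n, dimnames = list(NULL, sp))
    for (k in seq_along(plan)) {
      val <- 0
      for (entry in plan[[k]]) {
        term <- 1
        for (j in seq_along(entry$idx)) {
          xi <- X[, entry$idx[j]]
          if (entry$neg[j]) xi <- 1 - xi
          term <- term * xi
        }
        val <- pmax(val, term)
      }
      newX[, tIdx[k]] <- val
    }
    applyClamp(newX)
  }
  maxit <- ceiling(1.2 * n)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    newX <- step(X)
    if (identical(newX, X)) { converged <- TRUE; break }
    X <- newX
  }
  if (!converged) {
    changed <- matrix(FALSE, nc, n)
    cur <- X
    for (it in seq_len(max(n, 2L))) {
      nxt <- step(cur)
      changed <- changed | (nxt != cur)
      cur <- nxt
    }
    X[changed] <- NA_real_
  }
  X
}

## clamp masks for every condition of a dataset (cue -> species columns)
.clampMasks <- function(model, dataset) {
  sp <- model@species
  nc <- nrow(dataset@design)
  clamp1 <- matrix(FALSE, nc, length(sp))
  clamp0 <- matrix(FALSE, nc, length(sp))
  for (s in dataset@stimuli) {
    j <- match(s, sp)
    if (!is.na(j)) clamp1[dataset@design[, s] == 1L, j] <- TRUE
  }
  for (i in dataset@inhibitors) {
    j <- match(i, sp)
    if (!is.na(j)) clamp0[dataset@design[, i] == 1L, j] <- TRUE
  }
  list(clamp1 = clamp1, clamp0 = clamp0)
}

#' Simulate the Boolean steady state of a logic model
#'
#' Runs the synchronous Boolean update of the sub-model selected by bit
#' string \code{P} under one experimental condition and returns the
#' steady-state value of every species (0, 1 or \code{NA} for species
#' that oscillate instead of reaching a fixed point).
#'
#' @param model a [LogicModel-class].
#' @param P bit string (0/1 vector) over the hyperedges; default all on.
#' @param stimuli character vector of stimulated species (clamped to 1).
#' @param inhibited character vector of inhibited species (clamped to 0);
#'   inhibition clamps the named protein itself, emulating a drug that
#'   blocks its activity.
#' @return Named numeric vector over species with values in
#'   \code{c(0, 1, NA)}.
#' @examples
#' m <- logicModel(species = c("A", "B"),
#'                 hyperedges = list(list(inputs = "A", signs = 1L,
#'                                        target = "B")))
#' simulateLogic(m, stimuli = "A")
#' @export
simulateLogic <- function(model, P = rep(1L, nHyperedges(model)),
                          stimuli = character(), inhibited = character()) {
  if (length(P) != nHyperedges(model))
    .inputError("bit string length %d != number of hyperedges %d",
                length(P), nHyperedges(model))
  unknown <- setdiff(c(stimuli, inhibited), model@species)
  if (length(unknown))
    .inputError("unknown species in condition: %s",
                paste(unknown, collapse = ", "))
  sp <- model@species
  clamp1 <- matrix(sp %in% stimuli, 1L)
  clamp0 <- matrix(sp %in% inhibited, 1L)  # inhibition wins over stimulation
  drop(.simulateCore(model, P, clamp1, clamp0))
}

#' Simulate all conditions of a perturbation dataset
#'
#' @inheritParams simulateLogic
#' @param dataset a [PerturbationData-class]; its design matrix defines
#'   the clamped cues per condition.
#' @return Numeric matrix conditions x species.
#' @export
simulateConditions <- function(model, P = rep(1L, nHyperedges(model)),
                               dataset) {
  if (length(P) != nHyperedges(model))
    .inputError("bit string length %d != number of hyperedges %d",
                length(P), nHyperedges(model))
  masks <- .clampMasks(model, dataset)
  .simulateCore(model, P, masks$clamp1, masks$clamp0)
}

#' Mean squared error between data and model prediction
#'
#' Computes the MSE deviation between the normalized experimental data
#' (continuous values in [0, 1]) and the Boolean model prediction at the
#' training (last) timepoint, over all N non-missing data points.
#' Readouts whose simulated value is unresolved (\code{NA}, oscillation)
#' contribute \code{naFac} per data point.
#'
#' @inheritParams simulateConditions
#' @param naFac penalty per data point with an unresolved (NA) prediction;
#'   default 1, the maximal squared deviation on [0, 1] data.
#' @return Non-negative scalar; bounded by 1 when \code{naFac <= 1}.
#' @export
fitMSE <- function(model, P, dataset, naFac = 1) {
  obs <- trainingValues(dataset)
  N <- sum(!is.na(obs))
  if (N == 0L) .inputError("dataset has no non-missing training data points")
  sim <- simulateConditions(model, P, dataset)
  ro <- readoutNames(dataset)
  missingRo <- setdiff(ro, colnames(sim))
  simR <- matrix(NA_real_, nrow(obs), length(ro), dimnames = list(NULL, ro))
  keep <- intersect(ro, colnames(sim))
  simR[, keep] <- sim[, keep, drop = FALSE]
  dev2 <- (obs - simR)^2
  dev2[!is.na(obs) & is.na(simR)] <- naFac
  sum(dev2[!is.na(obs)]) / N
}
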