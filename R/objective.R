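#' Objective-function parameters
#'
#' @param alpha size-penalty weight for prior hyperedges (default 0.001).
#' @param beta penalty weight for integrated hyperedges (default 700);
#'   larger values make data-driven links more expensive than prior
#'   links, reflecting their weaker support.
#' @param naFac MSE contribution per data point with an unresolved (NA)
#'   model prediction (default 1).
#' @return A list of class \code{"objectiveParams"}.
#' @export
objectiveParams <- function(alpha = 0.001, beta = 700, naFac = 1) {
  stopifnot(alpha >= 0, beta >= 0, is.finite(alpha), is.finite(beta))
  structure(list(alpha = alpha, beta = beta, naFac = naFac),
            class = "objectiveParams")
}

## per-model constants of the size terms: nu, group masks, reliability
## weights (from records, matched by integrated-link id), denominators
.objectivePrep <- function(model, records = list()) {
  nu <- .heArity(model)
  prov <- .heProvenance(model)
  isInt <- prov == "integrated"
  w <- rep(1, length(nu))
  if (length(records)) {
    rw <- vapply(records, function(r) r$weight, 0)
    names(rw) <- vapply(records, function(r) paste0(r$from, ">", r$to), "")
    for (i in which(isInt)) {
      ids <- model@hyperedges[[i]]$links
      hit <- rw[intersect(ids, names(rw))]
      if (length(hit)) w[i] <- max(hit)
    }
  }
  denomP <- sum(nu[!isInt])
  denomI <- sum(w[isInt] * nu[isInt])
  list(nu = nu, isInt = isInt, w = w, denomP = denomP, denomI = denomI)
}

.sizeTerms <- function(P, prep) {
  P <- as.numeric(P)
  sp <- if (prep$denomP > 0)
    sum(prep$nu[!prep$isInt] * P[!prep$isInt]) / prep$denomP else 0
  si <- if (prep$denomI > 0)
    sum(prep$w[prep$isInt] * prep$nu[prep$isInt] * P[prep$isInt]) /
      prep$denomI else 0
  c(sizePrior = sp, sizeIntegrated = si)
}

#' Bipartite fit-plus-size objective
#'
#' theta(P) = theta_f(P) + alpha * theta_s^prior(P) +
#' beta * theta_s^integrated(P), balancing fit and model size with a
#' stronger, reliability-weighted penalization of integrated links:
#' theta_f is the MSE between data and Boolean prediction; the prior
#' size term is the nu-weighted fraction of selected prior hyperedges
#' (a 2-input AND gate counts twice a single edge); the integrated term
#' additionally multiplies each hyperedge by the penalty weight w of the
#' integrated link(s) it uses. Both size terms are normalized by their
#' total possible weighted size so alpha and beta are comparable across
#' models; empty groups contribute 0.
#'
#' @param P bit string over the model's hyperedges.
#' @param model a [LogicModel-class].
#' @param dataset a [PerturbationData-class].
#' @param params an [objectiveParams()] list.
#' @param records integrated-link records carrying penalty weights (see
#'   [penaltyWeights()]); empty for a PKN-only model.
#' @param decompose return the three components instead of the scalar.
#' @return The objective value, or (with \code{decompose = TRUE}) a list
#'   with \code{theta}, \code{thetaF}, \code{sizePrior},
#'   \code{sizeIntegrated}.
#' @export
objectiveScore <- function(P, model, dataset, params = objectiveParams(),
                           records = list(), decompose = FALSE) {
  prep <- .objectivePrep(model, records)
  thetaF <- fitMSE(model, P, dataset, naFac = params$naFac)
  st <- .sizeTerms(P, prep)
  theta <- thetaF + params$alpha * st[["sizePrior"]] +
    params$beta * st[["sizeIntegrated"]]
  if (!decompose) return(theta)
  list(theta = theta, thetaF = thetaF, sizePrior = st[["sizePrior"]],
       sizeIntegrated = st[["sizeIntegrated"]])
}

## fast closure: theta_f evaluator with precomputed clamp masks
.makeThetaF <- function(model, dataset, naFac = 1) {
  masks <- .clampMasks(model, dataset)
  obs <- trainingValues(dataset)
  ro <- readoutNames(dataset)
  N <- sum(!is.na(obs))
  if (N == 0L) .inputError("dataset has no non-missing training data points")
  keep <- intersect(ro, model@species)
  function(P) {
    sim <- .simulateCore(model, P, masks$clamp1, masks$clamp0)
    simR <- matrix(NA_real_, nrow(obs), length(ro), dimnames = list(NULL, ro))
    simR[, keep] <- sim[, keep, drop = FALSE]
    dev2 <- (obs - simR)^2
    dev2[!is.na(obs) & is.na(simR)] <- naFac
    sum(dev2[!is.na(obs)]) / N
  }
}

.makeScorer <- function(model, dataset, params, records) {
  prep <- .objectivePrep(model, records)
  thetaF <- .makeThetaF(model, dataset, params$naFac)
  function(P) {
    st <- .sizeTerms(P, prep)
    thetaF(P) + params$alpha * st[["sizePrior"]] +
      params$beta * st[["sizeIntegrated"]]
  }
}

## TRUE if a precedes b: fewer selected bits, then lexicographic
.preferP <- function(aP, aScore, bP, bScore, tol = 1e-12) {
  if (aScore < bScore - tol) return(TRUE)
  if (aScore > bScore + tol) return(FALSE)
  na <- sum(aP); nb <- sum(bP)
  if (na != nb) return(na < nb)
  d <- which(aP != bP)
  if (!length(d)) return(FALSE)
  aP[d[1L]] < bP[d[1L]]
}

#' Exhaustive search over all candidate models
#'
#' Enumerates every bit string over the hyperedges (guarded to at most
#' 2^20) and returns the objective minimizer; ties are resolved toward
#' fewer selected hyperedges, then lexicographically smallest bit
#' string. Serves as the ground-truth oracle for the genetic algorithm
#' on small superstructures.
#'
#' @inheritParams objectiveScore
#' @param guard maximum allowed number of hyperedges (default 20).
#' @return List with \code{P}, \code{score}, \code{thetaF},
#'   \code{nSelected}.
#' @export
exhaustiveSearch <- function(model, dataset, params = objectiveParams(),
                             records = list(), guard = 20L) {
  M <- nHyperedges(model)
  if (M > guard)
    .inputError("exhaustive search refused: M = %d exceeds guard %d",
                M, guard)
  scorer <- .makeScorer(model, dataset, params, records)
  thetaF <- .makeThetaF(model, dataset, params$naFac)
  bestP <- NULL; bestS <- Inf
  for (code in 0:(2^M - 1)) {
    P <- as.integer(intToBits(code)[seq_len(M)] == 1)
    s <- scorer(P)
    if (is.null(bestP) || .preferP(P, s, bestP, bestS)) {
      bestP <- P; bestS <- s
    }
  }
  list(P = bestP, score = bestS, thetaF = thetaF(bestP),
       nSelected = sum(bestP))
}
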