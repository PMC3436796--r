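#' Genetic-algorithm parameters
#'
#' Defaults mirror common practice for logic-model training: a moderate
#' population with elitism, linear-rank selection, uniform crossover and
#' roughly half an expected bit flip per child.
#'
#' @param popSize population size (>= 2).
#' @param maxGenerations hard generation cap per run.
#' @param stallGenerations stop a run after this many generations
#'   without improvement of the best score.
#' @param elitism number of best individuals copied unchanged.
#' @param mutationProb expected number of flipped bits per child
#'   (per-bit flip probability is \code{mutationProb / M}).
#' @param selectionPressure linear-rank selection pressure in [1, 2].
#' @param nRuns number of independent runs pooled into the model family.
#' @param relTol relative tolerance defining family membership: models
#'   with score <= best * (1 + relTol).
#' @param seed integer seed; each run derives its own sub-seed, so the
#'   whole optimization is reproducible.
#' @return A list of class \code{"gaParams"}.
#' @export
gaParams <- function(popSize = 50L, maxGenerations = 500L,
                     stallGenerations = 100L, elitism = 5L,
                     mutationProb = 0.5, selectionPressure = 1.2,
                     nRuns = 3L, relTol = 0.1, seed = 1L) {
  stopifnot(popSize >= 2L, mutationProb > 0, elitism < popSize,
            relTol >= 0, selectionPressure >= 1, selectionPressure <= 2)
  structure(list(popSize = as.integer(popSize),
                 maxGenerations = as.integer(maxGenerations),
                 stallGenerations = as.integer(stallGenerations),
                 elitism = as.integer(elitism),
                 mutationProb = mutationProb,
                 selectionPressure = selectionPressure,
                 nRuns = as.integer(nRuns), relTol = relTol,
                 seed = as.integer(seed)),
            class = "gaParams")
}

#' Train a logic model by genetic-algorithm search
#'
#' Runs \code{nRuns} independent genetic-algorithm searches over the
#' bit-string space of the superstructure, minimizing the
#' [objectiveScore()] (fit + size + integrated-link penalties). Every
#' evaluated model is recorded so that, at the end, a family of
#' near-optimal models (within \code{relTol} of the best score) is
#' reported alongside the best model. Fully reproducible given the seed.
#'
#' @inheritParams objectiveScore
#' @param ga a [gaParams()] list.
#' @return A list of class \code{"modelFamily"} with elements
#'   \code{best} (list \code{P}, \code{score}, \code{thetaF},
#'   \code{nSelected}), \code{members} (list of \code{list(P, score)},
#'   scores ascending), \code{traces} (per-run best-score trajectories)
#'   and \code{nEvaluated}.
#' @export
gaOptimize <- function(model, dataset, params = objectiveParams(),
                       ga = gaParams(), records = list()) {
  M <- nHyperedges(model)
  if (M < 1L) .inputError("model has no hyperedges")
  scorer <- .makeScorer(model, dataset, params, records)
  thetaF <- .makeThetaF(model, dataset, params$naFac)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  score <- function(P) {
    key <- paste(P, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    s <- scorer(P)
    cache[[key]] <- s
    s
  }
  n <- ga$popSize
  ## linear-rank selection probabilities, best rank first
  sp <- ga$selectionPressure
  rankProb <- (2 - sp) / n + 2 * (n - seq_len(n)) * (sp - 1) / (n * (n - 1))
  pmut <- min(1, ga$mutationProb / M)
  traces <- vector("list", ga$nRuns)

  for (run in seq_len(ga$nRuns)) {
    set.seed(.subSeed(ga$seed, run))
    pop <- matrix(as.integer(stats::runif(n * M) < 0.5), n, M)
    pop[1L, ] <- 0L                      # empty and full models seeded
    if (n >= 2L) pop[2L, ] <- 1L
    fit <- apply(pop, 1L, score)
    bestSoFar <- min(fit)
    stall <- 0L
    trace <- numeric(0)
    for (gen in seq_len(ga$maxGenerations)) {
      o <- order(fit)
      pop <- pop[o, , drop = FALSE]; fit <- fit[o]
      trace <- c(trace, fit[1L])
      if (fit[1L] < bestSoFar - 1e-12) {
        bestSoFar <- fit[1L]; stall <- 0L
      } else stall <- stall + 1L
      if (stall >= ga$stallGenerations) break
      nOff <- n - ga$elitism
      pa <- sample.int(n, nOff, replace = TRUE, prob = rankProb)
      pb <- sample.int(n, nOff, replace = TRUE, prob = rankProb)
      mask <- matrix(stats::runif(nOff * M) < 0.5, nOff, M)
      off <- pop[pa, , drop = FALSE]
      pbm <- pop[pb, , drop = FALSE]
      off[mask] <- pbm[mask]
      flips <- matrix(stats::runif(nOff * M) < pmut, nOff, M)
      off[flips] <- 1L - off[flips]
      pop <- rbind(pop[seq_len(ga$elitism), , drop = FALSE], off)
      fit <- c(fit[seq_len(ga$elitism)], apply(off, 1L, score))
    }
    traces[[run]] <- trace
  }

  keys <- ls(cache)
  scores <- vapply(keys, function(k) cache[[k]], 0)
  o <- order(scores)
  keys <- keys[o]; scores <- unname(scores[o])
  bestS <- scores[1L]
  ## tie-break the reported best: fewer hyperedges, then lexicographic
  toP <- function(k) as.integer(strsplit(k, "")[[1L]])
  bestP <- toP(keys[1L])
  for (k in keys[scores <= bestS + 1e-12]) {
    P <- toP(k)
    if (.preferP(P, bestS, bestP, bestS)) bestP <- P
  }
  memberIdx <- which(scores <= bestS * (1 + ga$relTol) + 1e-12)
  members <- lapply(memberIdx, function(i)
    list(P = toP(keys[i]), score = scores[i]))
  structure(list(best = list(P = bestP, score = bestS,
                             thetaF = thetaF(bestP),
                             nSelected = sum(bestP)),
                 members = members, traces = traces,
                 nEvaluated = length(keys)),
            class = "modelFamily")
}

#' @export
print.modelFamily <- function(x, ...) {
  cat(sprintf(paste0("modelFamily: best score %.6g (theta_f %.6g, ",
                     "%d hyperedges selected)\n"),
              x$best$score, x$best$thetaF, x$best$nSelected))
  cat(sprintf("  %d family members within tolerance, %d models evaluated\n",
              length(x$members), x$nEvaluated))
  invisible(x)
}

#' Sweep the integrated-link penalty beta
#'
#' Optimizes the model at each value of beta and reports how many
#' integrated links the optimum selects and its fit. With exhaustive
#' optimization the selected weighted integrated size is non-increasing
#' and the MSE non-decreasing in beta.
#'
#' @inheritParams gaOptimize
#' @param betas numeric vector of beta values (use a large finite value
#'   such as 1e9 as an infinity proxy).
#' @param optimizer \code{"exhaustive"} (default, requires M <= 20) or
#'   \code{"ga"}.
#' @return data.frame with columns \code{beta},
#'   \code{nIntegratedSelected}, \code{weightedIntegratedSize},
#'   \code{thetaF}, \code{score}.
#' @export
betaSweep <- function(model, dataset, betas,
                      params = objectiveParams(), records = list(),
                      optimizer = c("exhaustive", "ga"), ga = gaParams()) {
  optimizer <- match.arg(optimizer)
  prep <- .objectivePrep(model, records)
  res <- lapply(betas, function(b) {
    p2 <- objectiveParams(alpha = params$alpha, beta = b,
                          naFac = params$naFac)
    opt <- if (optimizer == "exhaustive")
      exhaustiveSearch(model, dataset, p2, records)
    else gaOptimize(model, dataset, p2, ga, records)$best
    P <- opt$P
    data.frame(beta = b,
               nIntegratedSelected = sum(P[prep$isInt]),
               weightedIntegratedSize =
                 sum(prep$w[prep$isInt] * prep$nu[prep$isInt] *
                       P[prep$isInt]),
               thetaF = opt$thetaF, score = opt$score)
  })
  do.call(rbind, res)
}
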