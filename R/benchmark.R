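## Benchmark drivers: seeded experiments used to validate the pipeline on
## synthetic gold standards (no external data required).

## gold-standard reachability matrix (hop counts -> logical)
.goldReach <- function(gs) {
  ed <- edgeTable(gs$network)
  g <- igraph::graph_from_data_frame(ed[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = nodeNames(gs$network))
  is.finite(igraph::distances(g, mode = "out", weights = NA))
}

## pick a gold edge whose deletion (i) changes some readout response and
## (ii) leaves a dependency that link integration can functionally
## restore: on clean data the FEED DDN must contribute an integrated
## link, lying on a gold path through the deleted edge, whose addition
## to the all-gates-on remainder model strictly improves the fit
.pickSeverableEdge <- function(gs) {
  dsClean <- simulateDataset(gs, noiseSd = 0, seed = 1L)
  truthVals <- trainingValues(dsClean)
  ed <- edgeTable(gs$network)
  reach <- .goldReach(gs)
  d <- gs$design
  for (k in seq_len(nrow(ed))) {
    net2 <- signedNetwork(ed[-k, ], nodes = nodeNames(gs$network),
                          stimulated = d$stimuli, inhibited = d$inhibited,
                          measured = d$readouts)
    m2 <- expandNetwork(net2, maxAndArity = 1L)
    sim <- simulateConditions(m2, dataset = dsClean)
    if (!any(sim[, d$readouts, drop = FALSE] != truthVals)) next
    comp <- tryCatch(compressNetwork(net2), error = function(e) NULL)
    if (is.null(comp)) next
    intg <- suppressWarnings(
      integrateLinks(comp$network, inferFEED(dsClean), net2))
    if (!length(intg$records)) next
    model <- expandNetwork(intg$network, maxAndArity = 1L)
    prov <- .heProvenance(model)
    thetaF <- .makeThetaF(model, dsClean)
    base <- as.integer(prov == "prior")
    fBase <- thetaF(base)
    labs <- hyperedgeLabels(model)
    for (r in intg$records) {
      if (!(reach[r$from, ed$from[k]] && reach[ed$to[k], r$to])) next
      lab <- paste0(if (r$sign < 0) "!" else "", r$from, "=", r$to)
      i <- match(lab, labs)
      if (is.na(i)) next
      P <- base; P[i] <- 1L
      if (thetaF(P) < fBase - 1e-9) return(k)
    }
  }
  NA_integer_
}

#' Severed-link recovery benchmark
#'
#' For each replicate a random gold standard is drawn, one of its edges
#' whose loss demonstrably severs a cue-to-readout dependency is deleted
#' from the prior network handed to the pipeline, and the full chain
#' (FEED inference, compression, integration, PIN weighting with a
#' synthetic interaction network containing the gold skeleton, GA
#' training) is run on noisy data. A replicate counts as recovered when
#' the trained model selects an integrated link lying on a gold-standard
#' path through the deleted edge.
#'
#' @param nReplicates number of usable seeded replicates to accumulate
#'   (default 20); gold standards with no well-posed severable edge are
#'   recorded as NA and replaced, up to a bounded number of extra draws.
#' @param noiseSd measurement noise of the simulated data (default 0.05).
#' @param seed base seed; replicate r uses seed + r.
#' @param params,ga objective and GA parameters for the training stage;
#'   the default beta of 0.05 keeps a data-supported integrated link
#'   affordable against fit gains on the [0, 1] MSE scale.
#' @param verbose print one line per replicate.
#' @return A list with \code{rate} (recovered fraction of usable
#'   replicates), \code{nUsable}, and \code{details} (data.frame with
#'   seed, deleted edge, integrated-link count, recovery flag and fit).
#' @export
recoveryBenchmark <- function(nReplicates = 20L, noiseSd = 0.05,
                              seed = 1000L,
                              params = objectiveParams(alpha = 0.001,
                                                       beta = 0.05),
                              ga = gaParams(popSize = 30L,
                                            maxGenerations = 60L,
                                            stallGenerations = 25L,
                                            nRuns = 2L),
                              verbose = FALSE) {
  rows <- list()
  r <- 0L
  while (sum(vapply(rows, function(x) !is.na(x$recovered), TRUE)) <
           nReplicates && r < 3L * nReplicates) {
    r <- r + 1L
    s <- .subSeed(seed, r)
    gs <- randomGoldStandard(seed = s)
    k <- .pickSeverableEdge(gs)
    if (is.na(k)) {
      ## no edge of this gold standard yields a well-posed severing
      rows[[r]] <- data.frame(seed = s, cut = NA_character_,
                              nIntegrated = NA_integer_, recovered = NA,
                              thetaF = NA_real_)
      next
    }
    ed <- edgeTable(gs$network)
    pkn <- signedNetwork(ed[-k, ], nodes = nodeNames(gs$network),
                         stimulated = gs$design$stimuli,
                         inhibited = gs$design$inhibited,
                         measured = gs$design$readouts)
    ds <- simulateDataset(gs, noiseSd = noiseSd, seed = s)
    pin <- syntheticPIN(gs$network, seed = s)
    run <- suppressWarnings(runPipeline(pkn, ds, pin, params = params,
                                        ga = ga, seed = s,
                                        verbose = FALSE))
    reach <- .goldReach(gs)
    hes <- hyperedges(run$model)
    recovered <- FALSE
    for (i in which(as.logical(run$family$best$P))) {
      he <- hes[[i]]
      if (he$provenance != "integrated") next
      for (lk in he$links) {
        uv <- strsplit(lk, ">", fixed = TRUE)[[1L]]
        if (reach[uv[1L], ed$from[k]] && reach[ed$to[k], uv[2L]])
          recovered <- TRUE
      }
    }
    rows[[r]] <- data.frame(seed = s,
                            cut = paste0(ed$from[k], ">", ed$to[k]),
                            nIntegrated = length(run$records),
                            recovered = recovered,
                            thetaF = run$decomposition$thetaF)
    if (verbose)
      message(sprintf("replicate %d: cut %s, recovered=%s, thetaF=%.4f",
                      r, rows[[r]]$cut, recovered,
                      run$decomposition$thetaF))
  }
  details <- do.call(rbind, rows)
  usable <- details[!is.na(details$recovered), , drop = FALSE]
  list(rate = mean(usable$recovered), nUsable = nrow(usable),
       details = details)
}

#' Genetic-algorithm versus exhaustive-search benchmark
#'
#' Generates random small training instances (gold standard with one
#' deleted prior edge, FEED integration, superstructure capped at
#' \code{maxM} hyperedges) and checks on each whether the genetic
#' algorithm attains the exhaustive-search optimum of the objective.
#'
#' @param nInstances number of instances to accumulate (default 50).
#' @param maxM largest superstructure size admitted (default 12;
#'   exhaustive search enumerates 2^maxM models).
#' @param seed base seed.
#' @param params objective parameters.
#' @param ga GA parameters (per-instance seed derived from \code{seed}).
#' @param noiseSd data noise (default 0.05).
#' @return A list with \code{matchRate}, \code{nInstances} and
#'   \code{details} (per-instance M, GA and oracle scores).
#' @export
gaOracleBenchmark <- function(nInstances = 50L, maxM = 12L, seed = 2000L,
                              params = objectiveParams(alpha = 0.001,
                                                       beta = 0.01),
                              ga = gaParams(popSize = 30L,
                                            maxGenerations = 60L,
                                            stallGenerations = 25L,
                                            nRuns = 2L),
                              noiseSd = 0.05) {
  rows <- list()
  trySeed <- 0L
  while (length(rows) < nInstances && trySeed < 40L * nInstances) {
    trySeed <- trySeed + 1L
    s <- .subSeed(seed, trySeed)
    gs <- tryCatch(
      randomGoldStandard(nNodes = 7L, nStimuli = 2L, nInhibited = 1L,
                         nReadouts = 2L, seed = s),
      error = function(e) NULL)
    if (is.null(gs)) next
    ed <- edgeTable(gs$network)
    set.seed(s)
    k <- sample.int(nrow(ed), 1L)
    pkn <- signedNetwork(ed[-k, ], nodes = nodeNames(gs$network),
                         stimulated = gs$design$stimuli,
                         inhibited = gs$design$inhibited,
                         measured = gs$design$readouts)
    comp <- tryCatch(compressNetwork(pkn), error = function(e) NULL)
    if (is.null(comp)) next
    ds <- simulateDataset(gs, noiseSd = noiseSd, seed = s)
    intg <- suppressWarnings(
      integrateLinks(comp$network, inferFEED(ds), pkn))
    model <- expandNetwork(intg$network, maxAndArity = 2L)
    M <- nHyperedges(model)
    if (M < 2L || M > maxM) next
    recs <- penaltyWeights(intg$records,
                           pin = syntheticPIN(gs$network, seed = s))
    es <- exhaustiveSearch(model, ds, params, recs)
    ga$seed <- s
    fam <- gaOptimize(model, ds, params, ga, recs)
    rows[[length(rows) + 1L]] <-
      data.frame(seed = s, M = M, gaScore = fam$best$score,
                 oracleScore = es$score,
                 match = abs(fam$best$score - es$score) <= 1e-9)
  }
  details <- do.call(rbind, rows)
  list(matchRate = mean(details$match), nInstances = nrow(details),
       details = details)
}
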