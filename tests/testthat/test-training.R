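## toy model with one prior single edge (nu=1), one prior AND gate (nu=2)
## and integrated single links, plus a dataset driving the fit
trainingToy <- function() {
  net <- signedNetwork(
    data.frame(from = c("S1", "S2", "S1"), to = c("M", "M", "M2"),
               sign = 1L,
               provenance = c("prior", "prior", "integrated")),
    stimulated = c("S1", "S2"), measured = c("M", "M2"))
  model <- expandNetwork(net, maxAndArity = 2L)
  records <- list(list(from = "S1", to = "M2", sign = 1L,
                       candidates = data.frame(u = "S1", v = "M2"),
                       novel = FALSE, reliability = 0.5, weight = 1))
  list(model = model, records = records)
}

test_that("objective decomposes exactly into fit and two size terms", {
  tt <- trainingToy()
  ds <- makeDataset(list(
    list(s = "S1", i = character(), val = c(M = 1, M2 = 1)),
    list(s = "S2", i = character(), val = c(M = 1, M2 = 0))),
    stimuli = c("S1", "S2"), readouts = c("M", "M2"))
  params <- objectiveParams(alpha = 0.01, beta = 0.2)
  P <- rep(1L, nHyperedges(tt$model))
  d <- objectiveScore(P, tt$model, ds, params, tt$records, decompose = TRUE)
  expect_equal(d$theta,
               d$thetaF + 0.01 * d$sizePrior + 0.2 * d$sizeIntegrated)
  expect_gte(d$theta, d$thetaF)
  expect_gte(d$thetaF, 0)
  ## all prior hyperedges on: prior size term is 1; same for integrated
  expect_equal(d$sizePrior, 1)
  expect_equal(d$sizeIntegrated, 1)
})

test_that("a 2-input AND gate costs exactly twice a 1-input edge", {
  tt <- trainingToy()
  labs <- hyperedgeLabels(tt$model)
  single <- as.integer(labs == "S1=M")
  andGate <- as.integer(labs == "S1+S2=M")
  ds <- makeDataset(list(list(s = character(), i = character(),
                              val = c(M = 0, M2 = 0))),
                    stimuli = c("S1", "S2"), readouts = c("M", "M2"))
  params <- objectiveParams(alpha = 1, beta = 0)
  contribution <- function(P)
    objectiveScore(P, tt$model, ds, params, tt$records,
                   decompose = TRUE)$sizePrior
  expect_equal(contribution(andGate) / contribution(single), 2)
})

test_that("worked size-penalty example: select the nu=1 edge of a {1,2} model", {
  ## prior hyperedges with nu = {1, 2}: single S1=M and AND S1+S2=M
  net <- signedNetwork(
    data.frame(from = c("S1", "S2"), to = "M", sign = 1L),
    stimulated = c("S1", "S2"), measured = "M")
  model <- expandNetwork(net)  # S1=M, S2=M, S1+S2=M
  labs <- hyperedgeLabels(model)
  keep <- labs %in% c("S1=M", "S1+S2=M")
  hes <- hyperedges(model)[keep]
  m2 <- logicModel(speciesNames(model), hes)
  ds <- makeDataset(list(list(s = "S1", i = character(), val = c(M = 1))),
                    stimuli = c("S1", "S2"), readouts = "M")
  P <- as.integer(hyperedgeLabels(m2) == "S1=M")
  val <- objectiveScore(P, m2, ds, objectiveParams(alpha = 0.001, beta = 0))
  expect_equal(val, 0 + 0.001 * (1 / 3))
})

test_that("exhaustive search enumerates all bit strings with tie-breaks", {
  tt <- trainingToy()
  ds <- makeDataset(list(
    list(s = "S1", i = character(), val = c(M = 1, M2 = 0)),
    list(s = "S2", i = character(), val = c(M = 0, M2 = 0))),
    stimuli = c("S1", "S2"), readouts = c("M", "M2"))
  params <- objectiveParams(alpha = 0.001, beta = 0.001)
  es <- exhaustiveSearch(tt$model, ds, params, tt$records)
  ## independent oracle: score every bit string directly
  M <- nHyperedges(tt$model)
  best <- Inf
  for (code in 0:(2^M - 1)) {
    P <- as.integer(intToBits(code)[seq_len(M)] == 1)
    best <- min(best, objectiveScore(P, tt$model, ds, params, tt$records))
  }
  expect_equal(es$score, best)
  ## the data want S1=M only: M responds to S1 not S2, M2 silent
  expect_equal(hyperedgeLabels(tt$model)[as.logical(es$P)], "S1=M")
  expect_error(exhaustiveSearch(tt$model, ds, params, tt$records,
                                guard = 2L), "guard")
})

test_that("single irrelevant edge is dropped, helpful edge kept", {
  m1 <- logicModel(c("S", "M"),
                   list(list(inputs = "S", signs = 1L, target = "M")))
  dsUp <- makeDataset(list(list(s = "S", i = character(), val = c(M = 1))),
                      stimuli = "S", readouts = "M")
  dsFlat <- makeDataset(list(list(s = "S", i = character(), val = c(M = 0))),
                        stimuli = "S", readouts = "M")
  p <- objectiveParams(alpha = 0.1, beta = 0)
  expect_equal(exhaustiveSearch(m1, dsUp, p)$P, 1L)
  expect_equal(exhaustiveSearch(m1, dsFlat, p)$P, 0L)
})

test_that("GA is reproducible and finds the exhaustive optimum on small models", {
  tt <- trainingToy()
  ds <- makeDataset(list(
    list(s = "S1", i = character(), val = c(M = 1, M2 = 1)),
    list(s = "S2", i = character(), val = c(M = 1, M2 = 0))),
    stimuli = c("S1", "S2"), readouts = c("M", "M2"))
  params <- objectiveParams(alpha = 0.001, beta = 0.01)
  ga <- gaParams(popSize = 20L, maxGenerations = 40L,
                 stallGenerations = 15L, elitism = 2L, nRuns = 2L,
                 seed = 42L)
  f1 <- gaOptimize(tt$model, ds, params, ga, tt$records)
  f2 <- gaOptimize(tt$model, ds, params, ga, tt$records)
  expect_identical(f1$best, f2$best)
  expect_identical(lapply(f1$members, `[[`, "P"),
                   lapply(f2$members, `[[`, "P"))
  es <- exhaustiveSearch(tt$model, ds, params, tt$records)
  expect_equal(f1$best$score, es$score)
  ## family contract: best is a member, scores ascending within tolerance
  sc <- vapply(f1$members, `[[`, 0, "score")
  expect_true(all(diff(sc) >= 0))
  expect_true(all(sc <= f1$best$score * 1.1 + 1e-12))
  expect_equal(f1$members[[1L]]$score, f1$best$score)
})

test_that("a dominant integrated penalty excludes all integrated links", {
  tt <- trainingToy()
  ds <- makeDataset(list(
    list(s = "S1", i = character(), val = c(M = 1, M2 = 1))),
    stimuli = c("S1", "S2"), readouts = c("M", "M2"))
  params <- objectiveParams(alpha = 0.001, beta = 1e6)
  es <- exhaustiveSearch(tt$model, ds, params, tt$records)
  isInt <- vapply(hyperedges(tt$model), `[[`, "", "provenance") ==
    "integrated"
  expect_equal(sum(es$P[isInt]), 0)
  ## and with tiny beta the integrated link is worth selecting
  es2 <- exhaustiveSearch(tt$model, ds, objectiveParams(alpha = 0.001,
                                                        beta = 0.001),
                          tt$records)
  expect_gt(sum(es2$P[isInt]), 0)
})

test_that("beta sweep is monotone under exhaustive optimization", {
  set.seed(99)
  for (rep in 1:5) {
    gs <- randomGoldStandard(nNodes = 7L, nStimuli = 2L, nInhibited = 1L,
                             nReadouts = 2L, seed = 100L + rep)
    ds <- simulateDataset(gs, seed = 100L + rep)
    pkn <- gs$network
    ## sever one random edge into a readout to give integration a purpose
    ed <- edgeTable(pkn)
    cut <- which(ed$to %in% gs$design$readouts)[1L]
    if (is.na(cut)) next
    pkn2 <- signedNetwork(ed[-cut, ], nodes = nodeNames(pkn),
                          stimulated = gs$design$stimuli,
                          inhibited = gs$design$inhibited,
                          measured = gs$design$readouts)
    comp <- try(compressNetwork(pkn2), silent = TRUE)
    if (inherits(comp, "try-error")) next
    intg <- suppressWarnings(
      integrateLinks(comp$network, inferFEED(ds), pkn2))
    if (!length(intg$records)) next
    model <- expandNetwork(intg$network, maxAndArity = 1L)
    if (nHyperedges(model) > 14L) next
    sweep <- betaSweep(model, ds, c(0, 0.01, 0.1, 1, 1e9),
                       objectiveParams(alpha = 0.001), intg$records)
    expect_true(all(diff(sweep$weightedIntegratedSize) <= 1e-9))
    expect_true(all(diff(sweep$thetaF) >= -1e-9))
    expect_equal(sweep$nIntegratedSelected[sweep$beta == 1e9], 0)
  }
})

test_that("single-beta sweep equals one optimizer call", {
  tt <- trainingToy()
  ds <- makeDataset(list(
    list(s = "S1", i = character(), val = c(M = 1, M2 = 1))),
    stimuli = c("S1", "S2"), readouts = c("M", "M2"))
  params <- objectiveParams(alpha = 0.001, beta = 0.05)
  sw <- betaSweep(tt$model, ds, 0.05, params, tt$records)
  es <- exhaustiveSearch(tt$model, ds, params, tt$records)
  expect_equal(sw$score, es$score)
  expect_equal(sw$thetaF, es$thetaF)
})
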