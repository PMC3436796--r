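## three-condition toy shared by the FEED tests:
## baseline, stimulus S alone, S plus inhibitor I
feedToy <- function(vS, vSI, vBase = 0) {
  makeDataset(list(
    list(s = character(), i = character(), val = c(M = vBase)),
    list(s = "S", i = character(), val = c(M = vS)),
    list(s = "S", i = "I", val = c(M = vSI))),
    stimuli = "S", inhibitors = "I", readouts = "M")
}

test_that("effect tables flag changes exceeding the measurement uncertainty", {
  tabs <- feedEffectTables(feedToy(0.9, 0.9), epsilon = 0.1, kSigma = 2)
  rows <- tabs[[1L]]$rows
  expect_equal(tabs[[1L]]$readout, "M")
  expect_true(rows$significant[rows$nStimuli == 1 & rows$nInhibitors == 0])
  tabs2 <- feedEffectTables(feedToy(0.1, 0.1), epsilon = 0.1, kSigma = 2)
  expect_false(any(tabs2[[1L]]$rows$significant))
  ## identical values everywhere -> all-zero table
  tabs3 <- feedEffectTables(feedToy(0, 0, 0), epsilon = 0.1)
  expect_false(any(tabs3[[1L]]$rows$significant))
  expect_error(feedEffectTables(feedToy(1, 1), epsilon = 0), "epsilon")
})

test_that("inhibition abolishing a response reroutes it through the inhibited node", {
  ddn <- inferFEED(feedToy(0.9, 0.0), epsilon = 0.1)
  ed <- edgeTable(ddn)
  key <- paste(ed$from, ed$to)
  expect_setequal(key, c("S I", "I M"))
  expect_true(all(ed$sign == 1L))
})

test_that("unopposed stimulus responses and silent datasets map directly", {
  ddn <- inferFEED(feedToy(0.9, 0.9), epsilon = 0.1)
  ed <- edgeTable(ddn)
  expect_equal(paste(ed$from, ed$to), "S M")
  expect_equal(ed$sign, 1L)
  expect_equal(nrow(edgeTable(inferFEED(feedToy(0, 0)))), 0L)
})

test_that("inhibition enabling a response yields a negative regulator edge", {
  ddn <- inferFEED(feedToy(0.0, 0.9), epsilon = 0.1)
  ed <- edgeTable(ddn)
  expect_true(any(ed$from == "I" & ed$to == "M" & ed$sign == -1L))
})

test_that("feedNetwork is deterministic given the tables", {
  ds <- simulateDataset(randomGoldStandard(seed = 3L), seed = 3L)
  t1 <- feedEffectTables(ds)
  expect_identical(edgeTable(feedNetwork(t1, ds)),
                   edgeTable(feedNetwork(t1, ds)))
})

test_that("FEED on noise-free gold standards yields no spurious links", {
  for (seed in 1:8) {
    gs <- randomGoldStandard(seed = seed)
    ds <- simulateDataset(gs, noiseSd = 0, seed = seed)
    cls <- classifyLinks(inferFEED(ds), gs)
    expect_equal(cls[["spurious"]], 0L)
    expect_equal(sum(cls[c("direct_tp", "indirect", "spurious")]),
                 nrow(edgeTable(inferFEED(ds))))
  }
})

test_that("mutual information is symmetric, non-negative, zero-diagonal", {
  gs <- randomGoldStandard(seed = 5L)
  ds <- simulateDataset(gs, noiseSd = 0.05, seed = 5L)
  mi <- mutualInfoMatrix(ds)
  expect_equal(mi, t(mi))
  expect_true(all(mi >= 0))
  expect_equal(diag(mi), stats::setNames(rep(0, ncol(mi)), colnames(mi)))
  expect_error(mutualInfoMatrix(makeDataset(list(
    list(s = "S", i = character(), val = c(M = 1))),
    stimuli = "S", readouts = "M")), ">= 4 conditions")
})

test_that("identical columns share full entropy; independent columns near zero", {
  set.seed(42)
  n <- 400L
  x <- stats::runif(n)
  design <- matrix(0L, n, 1L, dimnames = list(NULL, "S"))
  ds <- perturbationData(design, cbind(M1 = x, M2 = x),
                         stimuli = "S", readouts = c("M1", "M2"))
  mi <- mutualInfoMatrix(ds)
  ## identical variables: MI equals the column entropy (about log 3 here)
  expect_gt(mi["M1", "M2"], 0.9)
  ds2 <- perturbationData(design, cbind(M1 = x, M2 = stats::runif(n)),
                          stimuli = "S", readouts = c("M1", "M2"))
  expect_lt(mutualInfoMatrix(ds2)["M1", "M2"], 0.05)
  ## constant variable -> zero row
  ds3 <- perturbationData(design, cbind(M1 = x, M2 = rep(0.5, n)),
                          stimuli = "S", readouts = c("M1", "M2"))
  expect_equal(mutualInfoMatrix(ds3)["M2", "M1"], 0)
})

test_that("ARACNe prunes the weakest edge of each triangle (DPI)", {
  mi <- matrix(c(0, .8, .3,
                 .8, 0, .7,
                 .3, .7, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ed <- edgeTable(aracneNetwork(mi, dpiTolerance = 0))
  key <- paste(ed$from, ed$to)
  expect_setequal(key, c("a b", "b c"))
  ## all-equal triangle: strict inequality fails, nothing removed
  miEq <- matrix(0.5, 3, 3, dimnames = dimnames(mi)); diag(miEq) <- 0
  expect_equal(nrow(edgeTable(aracneNetwork(miEq))), 3L)
  ## two variables: edge iff MI > 0
  mi2 <- matrix(c(0, .2, .2, 0), 2, 2,
                dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(nrow(edgeTable(aracneNetwork(mi2))), 1L)
  mi0 <- matrix(0, 2, 2, dimnames = dimnames(mi2))
  expect_equal(nrow(edgeTable(aracneNetwork(mi0))), 0L)
})

test_that("ARACNe output is a subset of the positive-MI network", {
  gs <- randomGoldStandard(seed = 9L)
  ds <- simulateDataset(gs, noiseSd = 0.05, seed = 9L)
  mi <- mutualInfoMatrix(ds)
  full <- which(mi > 0 & upper.tri(mi), arr.ind = TRUE)
  a <- rownames(mi)[full[, 1]]; b <- colnames(mi)[full[, 2]]
  fullKey <- paste(pmin(a, b), pmax(a, b))
  ed <- edgeTable(aracneNetwork(mi))
  expect_true(all(paste(pmin(ed$from, ed$to),
                        pmax(ed$from, ed$to)) %in% fullKey))
})

test_that("CLR keeps only pairs that stand out against their row background", {
  v <- c("a", "b", "c", "d")
  mi <- matrix(0.1, 4, 4, dimnames = list(v, v)); diag(mi) <- 0
  mi["a", "b"] <- mi["b", "a"] <- 2
  ed <- edgeTable(clrNetwork(mi, zThreshold = 1.5))
  expect_equal(paste(ed$from, ed$to), "a b")
  ## all-equal MI -> all z-scores 0 -> empty network
  miEq <- matrix(0.4, 4, 4, dimnames = list(v, v)); diag(miEq) <- 0
  expect_equal(nrow(edgeTable(clrNetwork(miEq, zThreshold = 0.5))), 0L)
})

test_that("permuting variables permutes ARACNe and CLR output", {
  gs <- randomGoldStandard(seed = 13L)
  ds <- simulateDataset(gs, noiseSd = 0.08, seed = 13L)
  mi <- mutualInfoMatrix(ds)
  perm <- rev(seq_len(ncol(mi)))
  miP <- mi[perm, perm]
  canon <- function(net) {
    ed <- edgeTable(net)
    sort(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to)))
  }
  expect_equal(canon(aracneNetwork(miP)), canon(aracneNetwork(mi)))
  expect_equal(canon(clrNetwork(miP)), canon(clrNetwork(mi)))
})

test_that("custom inference adapters plug into inferDDN", {
  ds <- feedToy(0.9, 0.0)
  adapter <- function(dataset)
    signedNetwork(data.frame(from = "S", to = "M", sign = 1L,
                             provenance = "ddn"),
                  stimulated = "S", measured = "M")
  ddn <- inferDDN(ds, method = adapter)
  expect_equal(paste(edgeTable(ddn)$from, edgeTable(ddn)$to), "S M")
})
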