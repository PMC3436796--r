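test_that("non-observable and non-controllable nodes are removed", {
  ## D has no readout downstream -> deleted; X has no cue upstream -> deleted
  pkn <- signedNetwork(
    data.frame(from = c("A", "B", "A", "X"), to = c("B", "C", "D", "C"),
               sign = 1L),
    stimulated = "A", measured = "C")
  cc <- compressNetwork(pkn)
  expect_false("D" %in% nodeNames(cc$network))
  expect_false("X" %in% nodeNames(cc$network))
  expect_true("D" %in% cc$map$removedNonObservable)
  expect_true("X" %in% cc$map$removedNonControllable)
})

test_that("pass-through intermediates are bypassed with sign products", {
  chain <- signedNetwork(
    data.frame(from = c("A", "B"), to = c("B", "C"), sign = c(1L, 1L)),
    stimulated = "A", measured = "C")
  cc <- compressNetwork(chain)
  expect_equal(edgeTable(cc$network)[, c("from", "to", "sign")],
               data.frame(from = "A", to = "C", sign = 1L))
  expect_equal(cc$map$edgePaths[["A 1 C"]], list(c("A", "B", "C")))

  mixed <- signedNetwork(
    data.frame(from = c("A", "B"), to = c("B", "C"), sign = c(1L, -1L)),
    stimulated = "A", measured = "C")
  expect_equal(edgeTable(compressNetwork(mixed)$network)$sign, -1L)
})

test_that("measured and perturbed nodes are never bypassed", {
  pkn <- signedNetwork(
    data.frame(from = c("A", "B"), to = c("B", "C"), sign = 1L),
    stimulated = "A", measured = c("B", "C"))
  cc <- compressNetwork(pkn)
  expect_setequal(nodeNames(cc$network), c("A", "B", "C"))
  expect_equal(nrow(edgeTable(cc$network)), 2L)
})

test_that("compression fails cleanly when nothing is identifiable", {
  pkn <- signedNetwork(data.frame(from = "A", to = "B", sign = 1L),
                       stimulated = "A", measured = "C", nodes = "C")
  expect_error(compressNetwork(pkn), "no identifiable subnetwork")
  noRoles <- signedNetwork(data.frame(from = "A", to = "B", sign = 1L))
  expect_error(compressNetwork(noRoles), "at least one measured")
})

test_that("compression is idempotent", {
  for (seed in 1:10) {
    pkn <- randomControllablePKN(seed)
    c1 <- compressNetwork(pkn)$network
    c2 <- compressNetwork(c1)$network
    expect_equal(edgeTable(c2), edgeTable(c1))
    expect_equal(nodeNames(c2), nodeNames(c1))
  }
})

test_that("compression preserves measured-node Boolean values across all cue combinations", {
  nOK <- 0L
  for (seed in 1:30) {
    pkn <- randomControllablePKN(seed, nNodes = 10L, pNegative = 0.2)
    cc <- compressNetwork(pkn)
    full <- orOnlyModel(pkn)
    small <- orOnlyModel(cc$network)
    roles <- networkRoles(pkn)
    grid <- allCueConditions(pkn)
    agree <- TRUE
    for (g in seq_len(nrow(grid))) {
      on <- colnames(grid)[grid[g, ] == 1]
      stim <- intersect(on, roles$stimulated)
      inh <- intersect(on, roles$inhibited)
      a <- simulateLogic(full, stimuli = stim, inhibited = inh)
      ## cues removed as non-observable cannot influence any readout
      b <- simulateLogic(small,
                         stimuli = intersect(stim, speciesNames(small)),
                         inhibited = intersect(inh, speciesNames(small)))
      for (mm in roles$measured)
        if (!isTRUE(all.equal(a[[mm]], b[[mm]]))) agree <- FALSE
    }
    expect_true(agree, label = sprintf("seed %d equivalence", seed))
    if (agree) nOK <- nOK + 1L
  }
  expect_equal(nOK, 30L)
})

test_that("superstructure expansion creates OR branches plus AND gates", {
  net <- signedNetwork(
    data.frame(from = c("A", "F"), to = c("G", "G"), sign = 1L),
    stimulated = c("A", "F"), measured = "G")
  m <- expandNetwork(net, maxAndArity = 2L)
  expect_setequal(hyperedgeLabels(m), c("A=G", "F=G", "A+F=G"))
  expect_setequal(vapply(hyperedges(m), function(h) length(h$inputs), 1L),
                  c(1L, 1L, 2L))

  net3 <- signedNetwork(
    data.frame(from = c("A", "B", "C"), to = "G", sign = 1L),
    stimulated = c("A", "B", "C"), measured = "G")
  expect_equal(nHyperedges(expandNetwork(net3, maxAndArity = 2L)), 6L)
  expect_equal(nHyperedges(expandNetwork(net3, maxAndArity = 3L)), 7L)

  net1 <- signedNetwork(data.frame(from = "A", to = "G", sign = 1L),
                        stimulated = "A", measured = "G")
  expect_equal(nHyperedges(expandNetwork(net1, maxAndArity = 4L)), 1L)
})

test_that("expansion count equals sum of binomials and order is deterministic", {
  for (k in 2:5) for (a in 1:4) {
    net <- signedNetwork(
      data.frame(from = sprintf("X%d", seq_len(k)), to = "G", sign = 1L),
      stimulated = sprintf("X%d", seq_len(k)), measured = "G")
    m <- expandNetwork(net, maxAndArity = a)
    expect_equal(nHyperedges(m),
                 sum(choose(k, seq_len(min(k, a)))))
    expect_identical(hyperedgeLabels(m),
                     hyperedgeLabels(expandNetwork(net, maxAndArity = a)))
  }
})

test_that("negative input signs are preserved through expansion", {
  net <- signedNetwork(
    data.frame(from = c("A", "B"), to = "G", sign = c(1L, -1L)),
    stimulated = c("A", "B"), measured = "G")
  m <- expandNetwork(net)
  expect_true("A+!B=G" %in% hyperedgeLabels(m))
})

test_that("threshold normalization maps raw values into [0,1]", {
  x0 <- matrix(100, 1, 1); same <- matrix(100, 1, 1)
  expect_equal(normalizeData(x0, same, 10, 500)[1, 1], 0)
  expect_equal(normalizeData(x0, matrix(105, 1, 1), 10, 500)[1, 1], 0)
  ## r = ec50 -> Hill midpoint 0.5
  x0 <- matrix(100, 1, 1); xt <- matrix(150, 1, 1)
  expect_equal(normalizeData(x0, xt, 10, 1e4, ec50 = 0.5)[1, 1], 0.5)
  ## saturation cap
  expect_equal(normalizeData(x0, matrix(600, 1, 1), 10, 500)[1, 1], 1)
  expect_error(normalizeData(matrix(-1, 1, 1), xt, 10, 500), "non-negative")
  expect_error(normalizeData(x0, xt, 50, 20), "noiseFloor")
  set.seed(1)
  r0 <- matrix(stats::runif(50, 0, 200), 10)
  rt <- matrix(stats::runif(50, 0, 400), 10)
  out <- normalizeData(r0, rt, 15, 350)
  expect_true(all(out >= 0 & out <= 1))
})
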