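test_that("evidence-weighted shortest paths follow Dijkstra on 1/evidence", {
  pin <- interactionNetwork(data.frame(a = c("u", "x"), b = c("x", "v"),
                                       evidence = c(2L, 1L)))
  expect_equal(shortestPathDistance(pin, "u", "v"), 1.5)
  pin2 <- interactionNetwork(data.frame(a = c("u", "x", "u"),
                                        b = c("x", "v", "v"),
                                        evidence = c(2L, 1L, 1L)))
  expect_equal(shortestPathDistance(pin2, "u", "v"), 1.0)
  expect_equal(shortestPathDistance(pin, "u", "u"), 0)
  expect_equal(shortestPathDistance(pin, "u", "nowhere"), Inf)
  disc <- interactionNetwork(data.frame(a = c("u", "p"), b = c("x", "q"),
                                        evidence = 1L))
  expect_equal(shortestPathDistance(disc, "u", "q"), Inf)
})

test_that("parallel evidences merge and self-interactions are rejected", {
  pin <- interactionNetwork(data.frame(a = c("a", "b"), b = c("b", "a"),
                                       evidence = c(2L, 3L)))
  expect_equal(pinEdges(pin)$evidence, 5L)
  expect_equal(shortestPathDistance(pin, "a", "b"), 1 / 5)
})

test_that("link reliability is the minimum over candidate insertions", {
  pin <- interactionNetwork(data.frame(
    a = c("A", "x", "B"), b = c("x", "E", "H"),
    evidence = c(2L, 1L, 2L)))
  rec <- list(from = "A", to = "H", sign = 1L,
              candidates = data.frame(u = c("A", "A", "B", "B"),
                                      v = c("E", "H", "E", "H"),
                                      stringsAsFactors = FALSE),
              novel = FALSE, reliability = NA_real_, weight = 1)
  rec <- linkReliability(rec, pin)
  ## d(A,E)=1.5, d(A,H) via B? A-x-E .. disconnected from H except B-H
  expect_equal(rec$reliability, 0.5)  # B-H direct, 1/2
  ## directly interacting pair with 4 evidences bounds reliability
  pin4 <- interactionNetwork(data.frame(a = "A", b = "E", evidence = 4L))
  rec4 <- linkReliability(rec, pin4)
  expect_lte(rec4$reliability, 0.25)
})

test_that("penalty weights normalize by the largest finite reliability", {
  recs <- lapply(c(0.5, 1.0, Inf), function(d)
    list(from = "a", to = "b", sign = 1L,
         candidates = data.frame(u = "a", v = "b"), novel = FALSE,
         reliability = d, weight = 1))
  w <- vapply(penaltyWeights(recs), function(r) r$weight, 0)
  expect_equal(w, c(0.5, 1.0, 1.0))
  single <- penaltyWeights(recs[2])
  expect_equal(single[[1L]]$weight, 1.0)
  allInf <- penaltyWeights(recs[c(3, 3)])
  expect_equal(vapply(allInf, function(r) r$weight, 0), c(1, 1))
  expect_true(all(w > 0 & w <= 1))
})

test_that("penalty-weight ranking is invariant to evidence rescaling", {
  set.seed(7)
  ed <- data.frame(a = c("a", "b", "c", "a"), b = c("b", "c", "d", "d"),
                   evidence = c(1L, 2L, 3L, 5L))
  mkRecs <- function(mult) {
    pin <- interactionNetwork(transform(ed, evidence = evidence * mult))
    recs <- list(
      list(from = "a", to = "c", sign = 1L,
           candidates = data.frame(u = "a", v = "c"), novel = FALSE,
           reliability = NA_real_, weight = 1),
      list(from = "b", to = "d", sign = 1L,
           candidates = data.frame(u = "b", v = "d"), novel = FALSE,
           reliability = NA_real_, weight = 1))
    vapply(penaltyWeights(recs, pin), function(r) r$weight, 0)
  }
  expect_equal(order(mkRecs(1L)), order(mkRecs(4L)))
})

test_that("adding evidence never increases any pairwise distance", {
  set.seed(11)
  ed <- data.frame(a = c("a", "a", "b", "c", "d"),
                   b = c("b", "c", "c", "d", "e"),
                   evidence = sample(1:4, 5, replace = TRUE))
  pin <- interactionNetwork(ed)
  nodes <- unique(c(ed$a, ed$b))
  for (k in seq_len(nrow(ed))) {
    ed2 <- ed; ed2$evidence[k] <- ed2$evidence[k] + 3L
    pin2 <- interactionNetwork(ed2)
    for (u in nodes) for (v in nodes)
      expect_lte(shortestPathDistance(pin2, u, v),
                 shortestPathDistance(pin, u, v))
  }
})

test_that("reliability equals brute-force minimum over all simple paths", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(5:8, 1L)
    nodes <- sprintf("p%d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2L))
    take <- stats::runif(nrow(pairs)) < 0.4
    if (!any(take)) take[1L] <- TRUE
    ed <- data.frame(a = pairs[take, 1L], b = pairs[take, 2L],
                     evidence = sample(1:5, sum(take), replace = TRUE))
    pin <- interactionNetwork(ed)
    uv <- sample(nodes, 2L)
    rec <- list(from = uv[1L], to = uv[2L], sign = 1L,
                candidates = data.frame(u = uv[1L], v = uv[2L]),
                novel = FALSE, reliability = NA_real_, weight = 1)
    expect_equal(linkReliability(rec, pin)$reliability,
                 bruteForcePinDistance(pin, uv[1L], uv[2L]))
  }
})

test_that("hop-count report separates PKN, integrated and random pairs", {
  gs <- randomGoldStandard(seed = 21L)
  pkn <- gs$network
  pin <- syntheticPIN(pkn, nDecoys = 15L, seed = 21L)
  ds <- simulateDataset(gs, seed = 21L)
  comp <- compressNetwork(pkn)$network
  recs <- integrateLinks(comp, inferFEED(ds), pkn)$records
  rep1 <- pinMappingReport(pkn, recs, pin, nRandom = 50L, seed = 3L)
  expect_setequal(unique(rep1$group), c("pkn", "integrated", "random"))
  ## the PIN contains the PKN skeleton: every PKN edge is 1 hop
  expect_true(all(rep1$hops[rep1$group == "pkn"] == 1))
  ## random pairs are on average at least as far as PKN links
  rnd <- rep1$hops[rep1$group == "random"]
  expect_gte(mean(pmin(rnd, 10)), 1)
  ## deterministic given the seed
  rep2 <- pinMappingReport(pkn, recs, pin, nRandom = 50L, seed = 3L)
  expect_identical(rep1, rep2)
})
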