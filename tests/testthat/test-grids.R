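test_that("tensor products form Cartesian node sets with product weights", {
  g <- tensorGrid(list(legendreRule(11), legendreRule(11)))
  expect_equal(nrow(g$nodes), 121)
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  # 10 x M mixed rule: weights are all pairwise products
  rL <- legendreRule(10); rH <- hermiteRule(4)
  g2 <- tensorGrid(list(rL, rH))
  expect_equal(nrow(g2$nodes), 40)
  expect_equal(sort(g2$weights),
               sort(as.vector(outer(rL$weights, rH$weights))),
               tolerance = 1e-14)
  # a single rule is the grid of itself
  g1 <- tensorGrid(list(rL))
  expect_equal(g1$nodes[, 1], rL$nodes)
  expect_equal(g1$weights, rL$weights)
  expect_error(tensorGrid(list()), "non-empty")
})

test_that("nested family sizes follow 2^(i+1) - 1", {
  expect_identical(nestedFamilySize(0L), 1L)
  expect_identical(nestedFamilySize(2L), 7L)
  expect_identical(nestedFamilySize(6L), 127L)
  expect_identical(nestedFamilySize(0:3), c(1L, 3L, 7L, 15L))
  expect_error(nestedFamilySize(-1), "non-negative")
})

test_that("level-2 Smolyak grid equals the explicit two-dimensional combination", {
  # independent construction of A(2,2) term by term:
  # U0xU2 + U1xU1 + U2xU0 - U0xU1 - U1xU0, merged by brute force
  U <- lapply(nestedFamilySize(0:2), legendreRule)
  terms <- list(list(U[[1]], U[[3]], +1), list(U[[2]], U[[2]], +1),
                list(U[[3]], U[[1]], +1), list(U[[1]], U[[2]], -1),
                list(U[[2]], U[[1]], -1))
  pts <- do.call(rbind, lapply(terms, function(tr) {
    g <- expand.grid(seq_along(tr[[1]]$nodes), seq_along(tr[[2]]$nodes))
    cbind(tr[[1]]$nodes[g[, 1]], tr[[2]]$nodes[g[, 2]],
          tr[[3]] * tr[[1]]$weights[g[, 1]] * tr[[2]]$weights[g[, 2]])
  }))
  key <- paste(round(pts[, 1], 12), round(pts[, 2], 12))
  oracleW <- tapply(pts[, 3], key, sum)
  g <- smolyakGrid(2, 2)
  expect_equal(nrow(g$nodes), length(oracleW))
  gkey <- paste(round(g$nodes[, 1], 12), round(g$nodes[, 2], 12))
  expect_equal(g$weights, as.vector(oracleW[gkey]), tolerance = 1e-13)
})

test_that("Smolyak grids have the documented sizes and unit weight sums", {
  expect_equal(countDistinctNodes(smolyakGrid(0, 2)), 1)
  g0 <- smolyakGrid(0, 5)
  expect_equal(g0$nodes, matrix(0, 1, 5))
  expect_equal(g0$weights, 1)
  g22 <- smolyakGrid(2, 2)
  g32 <- smolyakGrid(3, 2)
  expect_equal(countDistinctNodes(g22), 21)
  expect_equal(countDistinctNodes(g32), 73)
  for (g in list(g22, g32, smolyakGrid(2, 3), smolyakGrid(4, 2)))
    expect_equal(sum(g$weights), 1, tolerance = 1e-10)
  # negative combination weights do appear
  expect_gt(sum(g32$weights < 0), 0)
})

test_that("distinct-node counting agrees with the pairwise merge oracle", {
  for (cfg in list(c(2, 2), c(3, 2), c(2, 3))) {
    g <- smolyakGrid(cfg[1], cfg[2])
    expect_equal(countDistinctNodes(g), bruteDistinctCount(g$nodes))
  }
  # a node set with near-duplicates below and above the tolerance
  m <- rbind(c(0, 0), c(0, 5e-13), c(0, 5e-12), c(1, 1))
  expect_equal(countDistinctNodes(m), bruteDistinctCount(m))
  expect_equal(countDistinctNodes(m), 3)
})

test_that("level-signature node counting matches built grids", {
  for (cfg in list(c(2, 2), c(3, 2), c(2, 3), c(4, 2), c(3, 3)))
    expect_equal(smolyakNodeCount(cfg[1], cfg[2]),
                 countDistinctNodes(smolyakGrid(cfg[1], cfg[2])))
})

test_that("sparse Gauss-Legendre grids integrate low-degree monomials exactly", {
  # total degree <= 2L+1 against the uniform density, checked against
  # analytic moments
  uniformMoment <- function(k) if (k %% 2) 0 else 1 / (k + 1)
  for (L in 1:3) {
    g <- smolyakGrid(L, 2)
    for (a in 0:(2 * L + 1)) for (b in 0:(2 * L + 1 - a)) {
      val <- sum(g$weights * g$nodes[, 1]^a * g$nodes[, 2]^b)
      expect_equal(val, uniformMoment(a) * uniformMoment(b),
                   tolerance = 1e-10)
    }
  }
})

test_that("grid nodes map to per-neuron parameters affinely", {
  rule <- legendreRule(5)
  axIapp <- hetAxis("Iapp", 17.5, 7.5, rule)
  axgNa <- hetAxis("gNa", 2.8, 0.25, hermiteRule(3))
  g <- tensorGrid(list(axIapp, axgNa))
  tab <- gridToParameters(g)
  expect_equal(tab$Iapp, 17.5 + 7.5 * g$nodes[, 1])
  expect_equal(tab$gNa, 2.8 + 0.25 * g$nodes[, 2])
  expect_equal(tab$weight, g$weights)
  # untouched parameters keep their base values
  expect_true(all(tab$gl == 2.4) && all(tab$VNa == 50))
  # a unit node maps to location + scale
  expect_equal(gridToParameters(tensorGrid(list(
    hetAxis("gNa", 2.8, 0.25, midpointRule(1)))))$gNa, 2.8)
  expect_error(gridToParameters(tensorGrid(list(axIapp, axIapp))),
               "duplicate")
  expect_error(hetAxis("notAParam", 0, 1, rule), "unknown parameter")
  expect_error(hetAxis("Iapp", 0, -1, rule), ">= 0")
})

test_that("the four-axis uniform setup spans the stated parameter ranges", {
  axes <- list(hetAxis("Iapp", 25, 7.5, legendreRule(3)),
               hetAxis("gNa", 2.8, 0.25, legendreRule(3)),
               hetAxis("Vsyn", 0, 1, legendreRule(3)),
               hetAxis("VNa", 50, 1, legendreRule(3)))
  tab <- gridToParameters(smolyakGrid(2, 4), axes = axes)
  expect_true(all(tab$Iapp >= 17.5 & tab$Iapp <= 32.5))
  expect_true(all(tab$gNa >= 2.55 & tab$gNa <= 3.05))
  expect_true(all(tab$Vsyn >= -1 & tab$Vsyn <= 1))
  expect_true(all(tab$VNa >= 49 & tab$VNa <= 51))
  expect_equal(nrow(tab), smolyakNodeCount(2, 4))
})

test_that("grids round-trip through CSV with axis metadata", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "grid.csv")
  axes <- list(hetAxis("Iapp", 25, 7.5, legendreRule(4)),
               hetAxis("gNa", 2.8, 0.25, monteCarloRule(3, seed = 42)))
  g <- tensorGrid(axes)
  writeGrid(g, path)
  g2 <- readGrid(path)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$weights, g$weights)
  expect_equal(g2$axes[[2]]$rule$seed, 42L)
  expect_equal(g2$axes[[2]]$rule$nodes, g$axes[[2]]$rule$nodes)
  expect_equal(g2$provenance$kind, "tensor")
})
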