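test_that("population mean and variance are the weighted moments", {
  expect_equal(populationMean(c(-60, -20), c(0.5, 0.5)), -40)
  expect_equal(populationVariance(c(-60, -20), c(0.5, 0.5)), 400)
  expect_equal(populationVariance(rep(-47, 5), rep(0.2, 5)), 0)
  # permutation invariance (with weights)
  V <- c(-60, -45, -30); w <- c(0.2, 0.3, 0.5)
  expect_equal(populationVariance(V[c(3, 1, 2)], w[c(3, 1, 2)]),
               populationVariance(V, w))
  # matrix form gives one value per time sample
  M <- rbind(c(-60, -20), c(-50, -30))
  expect_equal(populationMean(M, c(0.5, 0.5)), c(-40, -40))
  expect_equal(populationVariance(M, c(0.5, 0.5)), c(400, 100))
  expect_error(populationMean(c(-60, -20), c(1)), "mismatch")
})

test_that("h remains in [0, 1] and homogeneous populations stay identical", {
  tab <- collocationTable(legendreRule(8), Im = 17.5, Is = 7.5)
  tr <- integrateNetwork(tab, tSpan = c(0, 60))
  expect_true(all(tr$h >= 0 & tr$h <= 1))
  expect_true(all(is.finite(tr$V)))

  # zero spread + identical initial conditions: all nodes coincide with
  # the single self-coupled neuron trajectory
  tab0 <- collocationTable(legendreRule(5), Im = 17.5, Is = 0)
  V0 <- rep(-65, 5)
  tr0 <- integrateNetwork(tab0, init = c(V0, hinfGate(V0)),
                          tSpan = c(0, 40))
  expect_lt(max(abs(tr0$V - tr0$V[, 1])), 1e-8)
  tab1 <- collocationTable(legendreRule(1), Im = 17.5, Is = 0)
  tr1 <- integrateNetwork(tab1, init = c(-65, hinfGate(-65)),
                          tSpan = c(0, 40))
  expect_equal(tr0$V[, 3], tr1$V[, 1], tolerance = 1e-8)
})

test_that("an uncoupled neuron at high drive settles on its stable fixed point", {
  tab <- collocationTable(legendreRule(1), Im = 35, Is = 0,
                          params = modelParams(gsyn = 0))
  tr <- integrateNetwork(tab, tSpan = c(0, 200))
  late <- tr$V[tr$times > 150, 1]
  expect_lt(max(late) - min(late), 1e-6)
  fp <- findFixedPoint(tab)
  expect_true(fp$stable)
  expect_equal(late[length(late)], fp$V, tolerance = 1e-6)
})

test_that("the synchronized period is measured accurately and converged", {
  pe <- cached("periodGL10",
               findPeriod(collocationTable(legendreRule(10), 17.5, 7.5)))
  expect_true(pe$converged)
  expect_lt(pe$residual, 1e-9 * pe$period)
  # ten Gauss nodes already reproduce the reference period closely
  expect_equal(pe$period, refPeriod, tolerance = 1e-5)
  expect_true(all(diff(pe$crossings) > 0))
})

test_that("the period does not depend on the section level", {
  tab <- collocationTable(legendreRule(10), 17.5, 7.5)
  tr <- integrateNetwork(tab, tSpan = c(0, 140), dt = 0.02)
  vbar <- populationMean(tr$V[tr$times > 100, ], tab$weight)
  lo <- min(vbar) + 0.3 * (max(vbar) - min(vbar))
  hi <- min(vbar) + 0.7 * (max(vbar) - min(vbar))
  pLo <- findPeriod(tab, level = lo)$period
  pHi <- findPeriod(tab, level = hi)$period
  expect_equal(pLo, pHi, tolerance = 1e-8)
})

test_that("zero heterogeneity reduces the network period to the single neuron's", {
  V0 <- rep(-65, 6)
  pNet <- findPeriod(collocationTable(legendreRule(6), 17.5, 0),
                     init = c(V0, hinfGate(V0)))$period
  pOne <- findPeriod(collocationTable(legendreRule(1), 17.5, 0),
                     init = c(-65, hinfGate(-65)))$period
  expect_equal(pNet, pOne, tolerance = 1e-8)
})

test_that("non-oscillatory regimes are reported as such", {
  tab <- collocationTable(legendreRule(1), Im = 35, Is = 0,
                          params = modelParams(gsyn = 0))
  expect_error(findPeriod(tab, transient = 50, window = 20),
               class = "hetosc_no_oscillation")
})

test_that("fixed points satisfy their residual contract and lie on the nullclines", {
  tab <- collocationTable(legendreRule(10), Im = 35, Is = 7.5)
  fp <- findFixedPoint(tab)
  expect_lt(fp$residual, 1e-10)
  expect_lt(max(abs(networkDeriv(c(fp$V, fp$h), tab))), 1e-10)
  # h component sits on the h-nullcline
  expect_equal(fp$h, hinfGate(fp$V), tolerance = 1e-10)

  # single uncoupled neuron: the fixed point is the nullcline
  # intersection found independently by bisection
  p <- modelParams(gsyn = 0)
  for (Im in c(10, 15, 35)) {
    tab1 <- collocationTable(legendreRule(1), Im = Im, Is = 0, params = p)
    fp1 <- findFixedPoint(tab1)
    f <- function(V) -p$gNa * mGate(V) * hinfGate(V) * (V - p$VNa) -
      p$gl * (V - p$Vl) + Im
    expect_equal(fp1$V, uniroot(f, c(-90, 20), tol = 1e-13)$root,
                 tolerance = 1e-8)
    # and it is the only one over the physiological voltage range
    Vg <- seq(-90, 20, by = 0.01)
    expect_equal(sum(diff(sign(f(Vg))) != 0), 1)
  }
})

test_that("synchrony is detected for the reference configuration", {
  tab <- collocationTable(legendreRule(10), Im = 17.5, Is = 7.5)
  tr <- integrateNetwork(tab, tSpan = c(0, 140), dt = 0.02)
  post <- tr
  keep <- tr$times >= 100
  post$times <- tr$times[keep]
  post$V <- tr$V[keep, , drop = FALSE]
  post$h <- tr$h[keep, , drop = FALSE]
  sc <- synchronyCheck(post)
  expect_true(isTRUE(sc$synchronized))
  expect_true(all(sc$counts == sc$counts[1]))
  expect_lt(sc$maxOffset, sc$period / 4)

  # a single node is trivially synchronized
  tab1 <- collocationTable(legendreRule(1), Im = 17.5, Is = 0)
  tr1 <- integrateNetwork(tab1, tSpan = c(100, 140), dt = 0.02)
  expect_true(isTRUE(synchronyCheck(tr1)$synchronized))

  # a window shorter than two cycles is inconclusive
  short <- post
  keep2 <- post$times <= post$times[1] + 9
  short$times <- post$times[keep2]
  short$V <- post$V[keep2, , drop = FALSE]
  expect_true(is.na(synchronyCheck(short)$synchronized))
})

test_that("trajectories export to CSV with metadata", {
  dir <- withr::local_tempdir()
  tab <- collocationTable(legendreRule(3), 17.5, 7.5)
  tr <- integrateNetwork(tab, tSpan = c(0, 5), dt = 0.5)
  path <- file.path(dir, "traj.csv")
  writeTrajectory(tr, path)
  df <- read.csv(path)
  expect_named(df, c("time", paste0("V_", 1:3), paste0("h_", 1:3)))
  expect_equal(df$V_2, unname(tr$V[, 2]))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$nodes, 3)
  expect_equal(meta$rtol, 1e-12)
})
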