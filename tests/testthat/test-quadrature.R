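test_that("Gauss-Legendre rules match closed forms", {
  r1 <- legendreRule(1)
  expect_equal(r1$nodes, 0)
  expect_equal(r1$weights, 1)
  r3 <- legendreRule(3)
  expect_equal(r3$nodes, c(-sqrt(3 / 5), 0, sqrt(3 / 5)), tolerance = 1e-14)
  # textbook weights 5/9, 8/9, 5/9 halved against the uniform density
  expect_equal(r3$weights, c(5 / 18, 4 / 9, 5 / 18), tolerance = 1e-14)
})

test_that("Gauss-Legendre nodes and weights satisfy the root/weight formulas", {
  # independent check against the defining expressions: nodes are roots
  # of P_N, weights are 1/((1 - x^2) P_N'(x)^2)
  for (N in c(5, 10, 20)) {
    r <- legendreRule(N)
    lp <- legendrePoly(N, r$nodes)
    expect_lt(max(abs(lp$p)), 1e-13)
    expect_equal(r$weights, 1 / ((1 - r$nodes^2) * lp$dp^2),
                 tolerance = 1e-12)
  }
})

test_that("probabilists' Hermite rules match closed forms and Hermite formulas", {
  expect_equal(hermiteRule(1)$nodes, 0)
  expect_equal(hermiteRule(1)$weights, 1)
  r2 <- hermiteRule(2)
  expect_equal(r2$nodes, c(-1, 1), tolerance = 1e-14)   # roots of x^2 - 1
  expect_equal(r2$weights, c(0.5, 0.5), tolerance = 1e-14)
  # nodes are roots of He_N; weights are N!/(N He_{N-1}(x))^2
  for (N in c(5, 10)) {
    r <- hermiteRule(N)
    expect_lt(max(abs(hermitePoly(N, r$nodes))), 1e-8)
    expect_equal(r$weights,
                 factorial(N) / (N * hermitePoly(N - 1, r$nodes))^2,
                 tolerance = 1e-11)
  }
})

test_that("midpoint and inverse-CDF rules place nodes as specified", {
  r <- midpointRule(2)
  expect_equal(r$nodes, c(-0.5, 0.5))
  expect_equal(r$weights, c(0.5, 0.5))
  expect_equal(midpointRule(7)$nodes, -1 + 2 * (1:7 - 0.5) / 7)
  # inverse-CDF: standard-normal quantiles at (j - 1/2)/N
  expect_equal(inverseCdfRule(1)$nodes, 0)
  expect_equal(inverseCdfRule(2)$nodes, qnorm(c(0.25, 0.75)))
  expect_equal(inverseCdfRule(2)$nodes[2], 0.67449, tolerance = 1e-5)
  # for the uniform density the CDF is affine: identical to midpoint
  for (N in c(1, 4, 9))
    expect_equal(inverseCdfRule(N, "uniform")$nodes, midpointRule(N)$nodes)
})

test_that("all rules are probability-normalized with symmetric Gauss nodes", {
  mk <- list(function(n) legendreRule(n), function(n) midpointRule(n),
             function(n) hermiteRule(n), function(n) inverseCdfRule(n),
             function(n) monteCarloRule(n, seed = 7))
  for (f in mk) for (N in c(1, 2, 5, 12, 33)) {
    r <- f(N)
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
    expect_equal(r$nodes, sort(r$nodes))
  }
  for (f in list(legendreRule, hermiteRule)) for (N in c(4, 9, 16)) {
    r <- f(N)
    expect_equal(r$nodes, -rev(r$nodes))
    expect_equal(r$weights, rev(r$weights))
  }
})

test_that("Gauss rules integrate polynomials of degree 2N-1 exactly", {
  uniformMoment <- function(k) if (k %% 2) 0 else 1 / (k + 1)
  normalMoment <- function(k)
    if (k %% 2) 0 else if (k == 0) 1 else prod(seq(1, k - 1, by = 2))
  for (N in c(2, 5, 10, 25)) {
    rl <- legendreRule(N)
    rh <- hermiteRule(N)
    for (k in 0:(2 * N - 1)) {
      expect_equal(ruleMoment(rl, k), uniformMoment(k), tolerance = 1e-12)
      # relative to the natural cancellation-free scale sum w |x|^k
      scale <- sum(rh$weights * abs(rh$nodes)^k)
      expect_equal(ruleMoment(rh, k), normalMoment(k),
                   tolerance = 1e-12 * max(1, scale))
    }
    # and degree 2N fails for Legendre (sanity that exactness is sharp)
    if (N <= 10)
      expect_gt(abs(ruleMoment(rl, 2 * N) - uniformMoment(2 * N)), 1e-12)
  }
})

test_that("rules agree with an independent quadrature implementation", {
  for (N in c(6, 11)) {
    gl <- pracma::gaussLegendre(N, -1, 1)
    r <- legendreRule(N)
    expect_equal(r$nodes, gl$x, tolerance = 1e-12)
    expect_equal(r$weights, gl$w / 2, tolerance = 1e-12)
  }
})

test_that("Monte Carlo rules are seed-reproducible without touching the RNG", {
  a <- monteCarloRule(50, seed = 11)
  b <- monteCarloRule(50, seed = 11)
  expect_identical(a$nodes, b$nodes)
  expect_false(identical(a$nodes, monteCarloRule(50, seed = 12)$nodes))
  expect_error(monteCarloRule(10), "seed")
  # the global RNG stream is unaffected
  set.seed(99); x1 <- rnorm(3)
  set.seed(99); invisible(monteCarloRule(20, seed = 5)); x2 <- rnorm(3)
  expect_identical(x1, x2)
  # node sample mean consistent with the CLT over many seeds
  means <- vapply(1:50, function(s)
    mean(monteCarloRule(100, seed = s)$nodes), numeric(1))
  expect_lt(abs(mean(means)), 3 / sqrt(50 * 100))
})

test_that("error ordering on a smooth sigmoid: Gauss << midpoint << Monte Carlo", {
  # integrand shaped like the synaptic activation profile across the
  # population; truth from adaptive quadrature against the uniform density
  f <- function(x) 1 / (1 + exp(-(x + 0.2) / 0.25))
  truth <- integrate(function(x) f(x) / 2, -1, 1, rel.tol = 1e-13)$value
  N <- 16
  apply1 <- function(r) abs(sum(r$weights * f(r$nodes)) - truth)
  errG <- apply1(legendreRule(N))
  errM <- apply1(midpointRule(N))
  errMC <- mean(vapply(1:20, function(s)
    apply1(monteCarloRule(N, density = "uniform", seed = s)), numeric(1)))
  expect_lt(errG * 100, errM)
  expect_lt(errM * 10, errMC)
})

test_that("rule constructors reject invalid sizes", {
  for (f in list(legendreRule, midpointRule, hermiteRule, inverseCdfRule))
    expect_error(f(0), "positive integer")
  expect_error(legendreRule(2.5), "positive integer")
})
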