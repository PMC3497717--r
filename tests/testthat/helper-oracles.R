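# Independent oracles used across tests, plus a cache for expensive
# shared computations (reference periods, Hopf locations) so several
# test blocks can reuse one run.

# Legendre polynomial P_n and derivative at x, by the three-term
# recurrence (independent of the package's eigenvalue-based rules)
legendrePoly <- function(n, x) {
  pm1 <- rep(1, length(x)); p <- x
  if (n == 0) return(list(p = pm1, dp = rep(0, length(x))))
  if (n > 1) for (k in 1:(n - 1)) {
    pp1 <- ((2 * k + 1) * x * p - k * pm1) / (k + 1)
    pm1 <- p; p <- pp1
  }
  dp <- n * (x * p - pm1) / (x^2 - 1)
  list(p = p, dp = dp)
}

# probabilists' Hermite polynomial He_n at x
hermitePoly <- function(n, x) {
  if (n == 0) return(rep(1, length(x)))
  hm1 <- rep(1, length(x)); h <- x
  if (n > 1) for (k in 1:(n - 1)) {
    hp1 <- x * h - k * hm1
    hm1 <- h; h <- hp1
  }
  h
}

# literal finite-network right-hand side: explicit per-neuron loop with
# the (1/N) sum over s(V_j), written directly from the model equations
finiteNetworkDeriv <- function(V, h, Iapp, p) {
  N <- length(V)
  S <- sum(sapply(V, function(v) 1 / (1 + exp(-(v + 40) / 5)))) / N
  dV <- numeric(N); dh <- numeric(N)
  for (i in 1:N) {
    m <- 1 / (1 + exp(-(V[i] + 37) / 6))
    hinf <- 1 / (1 + exp((V[i] + 44) / 6))
    tau <- 1 / (p$eps * cosh((V[i] + 44) / 12))
    dV[i] <- (-p$gNa * m * h[i] * (V[i] - p$VNa) - p$gl * (V[i] - p$Vl) +
                p$gsyn * (p$Vsyn - V[i]) * S + Iapp[i]) / p$C
    dh[i] <- (hinf - h[i]) / tau
  }
  c(dV, dh)
}

# central finite-difference Jacobian of networkDeriv
fdJacobian <- function(state, tab, step = 1e-6) {
  n2 <- length(state)
  J <- matrix(0, n2, n2)
  for (j in 1:n2) {
    e <- rep(0, n2); e[j] <- step
    J[, j] <- (networkDeriv(state + e, tab) -
                 networkDeriv(state - e, tab)) / (2 * step)
  }
  J
}

# O(P^2) pairwise-distance duplicate counter for small grids
bruteDistinctCount <- function(nodes, tol = 1e-12) {
  P <- nrow(nodes)
  dup <- rep(FALSE, P)
  for (i in seq_len(P)) {
    if (dup[i]) next
    for (j in seq_len(P)) {
      if (j <= i) next
      if (all(abs(nodes[i, ] - nodes[j, ]) <= tol)) dup[j] <- TRUE
    }
  }
  sum(!dup)
}

# cache shared across test files (computed lazily, at most once per run)
.hcache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .hcache)) assign(key, expr, envir = .hcache)
  get(key, envir = .hcache)
}

# grid-converged reference values of the continuum-limit model
refPeriod <- 8.040104851819
refUpperHopf <- 33.1262
refLowerHopf <- 6.064

cachedPeriodGL100 <- function()
  cached("periodGL100",
         findPeriod(collocationTable(legendreRule(100), Im = 17.5,
                                     Is = 7.5)))
cachedLowerHopfGL80 <- function()
  cached("lowerHopfGL80", hopfIm(legendreRule(80), c(4, 8)))
cachedUpperHopfGL80 <- function()
  cached("upperHopfGL80", hopfIm(legendreRule(80), c(30, 36)))
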