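## Linear stability, Hopf-point location by eigenvalue bisection,
## two-parameter Hopf curves, and direct-simulation synchrony break-up.

#' Analytic Jacobian of the network right-hand side
#'
#' Closed-form 2P x 2P Jacobian of [networkDeriv()] at a given state.
#' The all-to-all coupling contributes a rank-one block
#' \eqn{\partial I_{syn,i}/\partial V_j = g_{syn}(V_{syn} - V_i) w_j
#' s'(V_j)} on top of the per-node diagonal terms.  With `gsyn = 0` the
#' matrix is block-diagonal with 2 x 2 node blocks.
#'
#' @param state State `c(V, h)` or list with `V`, `h`.
#' @param table A [neuronTable].
#' @return Dense numeric matrix, ordering `(V_1..V_P, h_1..h_P)`.
#' @export
networkJacobian <- function(state, table) {
  n <- nrow(table)
  if (is.list(state)) state <- c(state$V, state$h)
  if (length(state) != 2 * n) stop("state length must be 2 * nrow(table)")
  V <- state[1:n]; h <- state[(n + 1):(2 * n)]
  m <- mGate(V); hinf <- hinfGate(V)
  S <- sum(table$weight * sGate(V))
  J <- matrix(0, 2 * n, 2 * n)
  ## dV-row, V-columns: diagonal + rank-one coupling
  dVV <- (-table$gNa * h * (.mPrime(V) * (V - table$VNa) + m) -
            table$gl - table$gsyn * S) / table$C
  J[cbind(1:n, 1:n)] <- dVV
  J[1:n, 1:n] <- J[1:n, 1:n] +
    outer(table$gsyn * (table$Vsyn - V) / table$C,
          table$weight * .sPrime(V))
  ## dV-row, h-columns
  J[cbind(1:n, n + 1:n)] <- -table$gNa * m * (V - table$VNa) / table$C
  ## dh-row: dh = (hinf(V) - h) * eps * cosh((V+44)/12)
  th <- (V + 44) / 12
  J[cbind(n + 1:n, 1:n)] <- table$eps *
    (.hinfPrime(V) * cosh(th) + (hinf - h) * sinh(th) / 12)
  J[cbind(n + 1:n, n + 1:n)] <- -table$eps * cosh(th)
  J
}

#' Largest real part of the Jacobian spectrum
#'
#' Stability test function behind the bifurcation diagrams: negative
#' means the fixed point is linearly stable.  Accepts a `fixedPoint`
#' object (uses its stored spectrum) or a Jacobian matrix.
#'
#' @param x A `fixedPoint` from [findFixedPoint()] or a square matrix.
#' @return The maximum real part over the spectrum.
#' @export
maxRealEigenvalue <- function(x) {
  if (inherits(x, "fixedPoint")) return(max(Re(x$eigenvalues)))
  if (is.matrix(x))
    return(max(Re(eigen(x, only.values = TRUE)$values)))
  stop("x must be a fixedPoint or a Jacobian matrix")
}

## fixed point at one scan-parameter value: warm-started, falling back
## on the nullcline heuristic when the warm start is too far off-branch
.fpAt <- function(tableFun, p, guess) {
  tab <- tableFun(p)
  if (is.null(guess)) return(findFixedPoint(tab))
  tryCatch(findFixedPoint(tab, guess = guess),
           error = function(e) findFixedPoint(tab))
}

#' Locate a Hopf bifurcation along a fixed-point branch
#'
#' Continues the fixed point in a scan parameter across a bracket and
#' bisects on the sign of the largest real eigenvalue part until the
#' bracket is narrower than `tol`.  Each bisection step warm-starts
#' Newton from the nearest solved point, which keeps the continuation on
#' the same branch.  At the located point the critical conjugate pair's
#' imaginary part gives the Hopf frequency.
#'
#' @param tableFun Function mapping the scan-parameter value to a
#'   [neuronTable] (e.g. `function(Im) collocationTable(rule, Im, Is)`).
#' @param bracket Length-2 numeric: scan values enclosing exactly one
#'   sign change of the maximal real part.
#' @param guess Optional initial state for the first fixed-point solve.
#' @param tol Bracket width at termination (scan-parameter units).
#' @param eigTol Eigenvalues with `|Re|` below this at the located point
#'   are counted as the critical pair.
#' @return A `hopfPoint`: list with `value` (critical scan-parameter
#'   value), `frequency` (|Im| of the critical pair), `bracket` (final),
#'   `fp` (fixed point at `value`), `critical` (the eigenvalue pair).
#' @examples
#' \donttest{
#' hp <- locateHopf(function(Im) collocationTable(legendreRule(10), Im, 7.5),
#'                  bracket = c(30, 36))
#' hp$value   # about 33.13
#' }
#' @export
locateHopf <- function(tableFun, bracket, guess = NULL, tol = 1e-6,
                       eigTol = 1e-8) {
  stopifnot(is.function(tableFun), length(bracket) == 2)
  a <- min(bracket); b <- max(bracket)
  fpa <- .fpAt(tableFun, a, guess)
  fpb <- .fpAt(tableFun, b, c(fpa$V, fpa$h))
  sa <- sign(fpa$maxRe); sb <- sign(fpb$maxRe)
  if (sa == sb)
    stop("no sign change of max Re(eigenvalue) over the bracket [",
         a, ", ", b, "]: ", format(fpa$maxRe), " and ", format(fpb$maxRe))
  while (b - a > tol) {
    mid <- (a + b) / 2
    ## warm start from the closer resolved endpoint
    g <- if (abs(mid - a) <= abs(b - mid)) c(fpa$V, fpa$h)
         else c(fpb$V, fpb$h)
    fpm <- .fpAt(tableFun, mid, g)
    if (sign(fpm$maxRe) == sa) { a <- mid; fpa <- fpm }
    else { b <- mid; fpb <- fpm }
  }
  value <- (a + b) / 2
  fp <- .fpAt(tableFun, value, c(fpa$V, fpa$h))
  ev <- fp$eigenvalues
  crit <- ev[order(-Re(ev))][1:2]
  if (all(abs(Im(crit)) < eigTol))
    warning("critical eigenvalues are real: crossing may not be a Hopf ",
            "bifurcation")
  structure(list(value = value, frequency = max(abs(Im(crit))),
                 bracket = c(a, b), fp = fp, critical = crit),
            class = "hopfPoint")
}

#' @export
print.hopfPoint <- function(x, ...) {
  cat(sprintf(
    "Hopf point: parameter = %.7g (bracket width %.2g), frequency %.5g\n",
    x$value, diff(x$bracket), x$frequency))
  invisible(x)
}

#' Locate a Hopf bifurcation in the mean applied current
#'
#' Convenience wrapper around [locateHopf()] for the standard scan in
#' `Im` at fixed heterogeneity spread `Is`: the applied currents are
#' `Iapp = Im + Is * mu` at the nodes of `rule`.
#'
#' @param rule A [quadRule][legendreRule] on \[-1, 1\].
#' @param bracket `Im` bracket enclosing one stability change.
#' @param Is Heterogeneity spread.
#' @param params Homogeneous [modelParams()].
#' @param ... Passed to [locateHopf()].
#' @return A `hopfPoint`.
#' @export
hopfIm <- function(rule, bracket, Is = 7.5, params = modelParams(), ...) {
  locateHopf(function(Im) collocationTable(rule, Im, Is, params),
             bracket = bracket, ...)
}

#' Trace a Hopf curve in two parameters
#'
#' Follows one Hopf bifurcation (in `Im`) as a second parameter (`Is` or
#' `gsyn`) is stepped through a list of values, warm-starting each
#' bracket around the previous critical value and widening it until a
#' sign change is enclosed.  If a bracket cannot be re-established the
#' curve is truncated with a warning.
#'
#' @param rule A [quadRule][legendreRule] for the `Iapp` direction.
#' @param values Scan values of the second parameter, in order.
#' @param varying `"Is"` or `"gsyn"`.
#' @param bracket Initial `Im` bracket for the first value.
#' @param Is Heterogeneity spread held fixed when `varying = "gsyn"`.
#' @param params Base [modelParams()].
#' @param halfWidth Initial half-width of warm-started brackets.
#' @param ... Passed to [locateHopf()].
#' @return Data frame with columns `value` (second parameter), `Im`
#'   (critical current) and `frequency`.
#' @export
traceHopfCurve <- function(rule, values, varying = c("Is", "gsyn"),
                           bracket, Is = 7.5, params = modelParams(),
                           halfWidth = 1, ...) {
  varying <- match.arg(varying)
  out <- data.frame(value = numeric(0), Im = numeric(0),
                    frequency = numeric(0))
  br <- bracket
  guess <- NULL
  for (v in values) {
    tf <- if (varying == "Is")
      function(Im) collocationTable(rule, Im, v, params)
    else {
      pv <- params; pv$gsyn <- v
      function(Im) collocationTable(rule, Im, Is, pv)
    }
    hp <- NULL
    for (try in 0:3) {
      w <- halfWidth * 2^try
      brTry <- if (is.null(guess)) br else c(guess - w, guess + w)
      hp <- tryCatch(locateHopf(tf, brTry, ...), error = function(e) NULL)
      if (!is.null(hp)) break
      if (is.null(guess)) break
    }
    if (is.null(hp)) {
      warning("Hopf curve truncated at ", varying, " = ", v,
              ": bracket lost")
      break
    }
    out <- rbind(out, data.frame(value = v, Im = hp$value,
                                 frequency = hp$frequency))
    guess <- hp$value
  }
  out
}

#' Find the synchrony break-up current by direct simulation
#'
#' Steps the mean applied current `Im` downward from a synchronized
#' state, warm-starting each simulation from the previous final state,
#' letting the network settle and then applying [synchronyCheck()].
#' Returns the first `Im` at which synchrony fails, mirroring the
#' "slowly decrease Im until break-up" protocol.  The step size and
#' settle time are operational choices; results should be quoted
#' together with them.
#'
#' @param rule A [quadRule][legendreRule] for the `Iapp` direction.
#' @param ImStart Starting mean current (must be synchronized there).
#' @param ImMin Lower end of the sweep.
#' @param step Sweep decrement (> 0).
#' @param Is Heterogeneity spread.
#' @param params Base [modelParams()].
#' @param settle Settling time before each synchrony assessment.
#' @param window Length of the assessment window.
#' @param atol,rtol Integration tolerances (defaults looser than the
#'   reference tolerances; break-up detection does not need 1e-12).
#' @return List with `Im` (first non-synchronized value, or `NA` if none
#'   found above `ImMin`), `history` (data frame of Im, synchronized,
#'   maxOffset), and `desyncNodes` (indices of nodes whose cycle count
#'   differs at break-up; typically the lowest-current nodes).
#' @export
findBreakup <- function(rule, ImStart, ImMin, step = 0.25, Is = 7.5,
                        params = modelParams(), settle = 300, window = 80,
                        atol = 1e-8, rtol = 1e-8) {
  tab <- collocationTable(rule, ImStart, Is, params)
  state <- defaultInitialState(tab)
  history <- data.frame(Im = numeric(0), synchronized = logical(0),
                        maxOffset = numeric(0))
  ImSeq <- seq(ImStart, ImMin, by = -abs(step))
  first <- TRUE
  for (Im in ImSeq) {
    tab <- collocationTable(rule, Im, Is, params)
    settled <- integrateNetwork(tab, init = state, tSpan = c(0, settle),
                                dt = settle / 4, atol = atol, rtol = rtol)
    state <- c(settled$V[nrow(settled$V), ], settled$h[nrow(settled$h), ])
    traj <- integrateNetwork(tab, init = state, tSpan = c(0, window),
                             dt = 0.05, atol = atol, rtol = rtol)
    state <- c(traj$V[nrow(traj$V), ], traj$h[nrow(traj$h), ])
    sc <- synchronyCheck(traj)
    ok <- isTRUE(sc$synchronized)
    history <- rbind(history,
                     data.frame(Im = Im, synchronized = ok,
                                maxOffset = sc$maxOffset))
    if (first && !ok)
      stop("sweep must start in the synchronized regime (Im = ", Im,
           " is not)")
    first <- FALSE
    if (!ok) {
      ref <- as.integer(names(which.max(table(sc$counts))))
      return(list(Im = Im, history = history,
                  desyncNodes = which(sc$counts != ref)))
    }
  }
  list(Im = NA_real_, history = history, desyncNodes = integer(0))
}
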