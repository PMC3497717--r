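## Time integration of the reduced network, Poincare-section period
## measurement, fixed points, and weighted population observables.
##
## All integrations use deSolve's lsoda/lsodar on the compiled
## right-hand side, with the tolerances (absolute 1e-10, relative 1e-12)
## used for every reference computation in this package.

.defaultAtol <- 1e-10
.defaultRtol <- 1e-12

.noOscillation <- function(msg)
  stop(errorCondition(msg, class = "hetosc_no_oscillation"))

## low-level integration of a packed system; optionally collects section
## crossings of the weighted mean voltage through rpar's level slot
.integrateRaw <- function(y0, times, rpar, atol, rtol, roots = FALSE,
                          maxroot = 200) {
  if (roots) {
    out <- deSolve::lsodar(y0, times, func = "net_derivs", parms = NULL,
                           dllname = "hetosc", initfunc = NULL, nout = 1,
                           rpar = rpar, rootfunc = "net_root", nroot = 1,
                           events = list(func = "net_event", root = TRUE,
                                         maxroot = maxroot),
                           atol = atol, rtol = rtol, maxsteps = 500000)
  } else {
    out <- deSolve::lsoda(y0, times, func = "net_derivs", parms = NULL,
                          dllname = "hetosc", initfunc = NULL, nout = 1,
                          rpar = rpar, atol = atol, rtol = rtol,
                          maxsteps = 500000)
  }
  if (anyNA(out) || any(!is.finite(out)))
    stop("integration failed: non-finite state encountered ",
         "(istate diagnostics: ", paste(attr(out, "istate")[1],
                                        collapse = " "), ")")
  out
}

#' Default initial state for a network
#'
#' The attracting synchronized orbit (or the unique fixed point) is the
#' object of study, so any basin-interior start suffices.  The default
#' places each node near the leak reversal with a mild spread along the
#' first heterogeneity coordinate, `V_i = Vl_i + 5 * z_i`, and starts the
#' slow variable on its steady-state curve, `h_i = hinf(V_i)`.
#'
#' @param table A [neuronTable].
#' @return Numeric vector `c(V, h)`.
#' @export
defaultInitialState <- function(table) {
  z <- attr(table, "coords")
  z <- if (is.null(z)) rep(0, nrow(table)) else z[, 1]
  V <- table$Vl + 5 * z
  c(V, hinfGate(V))
}

.checkState <- function(init, table) {
  n <- nrow(table)
  if (is.list(init)) init <- c(init$V, init$h)
  if (length(init) != 2 * n)
    stop("initial state length must be 2 * nrow(table) = ", 2 * n)
  if (anyNA(init) || any(!is.finite(init))) stop("non-finite initial state")
  init
}

#' Integrate the reduced network
#'
#' Adaptive high-order integration (lsoda) of the collocation network
#' defined by a [neuronTable], with dense output on a regular time grid.
#'
#' @param table A [neuronTable].
#' @param init Initial state `c(V, h)` or list with `V`, `h`; defaults to
#'   [defaultInitialState()].
#' @param tSpan Length-2 vector, start and end time.
#' @param dt Output grid spacing (model time units).
#' @param atol,rtol Absolute / relative integration tolerances.
#' @return A `netTrajectory`: list with `times`, voltage matrix `V`
#'   (time x node), gating matrix `h`, population activation `S`, and the
#'   generating `table`.
#' @examples
#' tab <- collocationTable(legendreRule(5), Im = 17.5, Is = 7.5)
#' tr <- integrateNetwork(tab, tSpan = c(0, 30))
#' range(tr$h)   # h stays inside [0, 1]
#' @export
integrateNetwork <- function(table, init = NULL, tSpan = c(0, 100),
                             dt = 0.05, atol = .defaultAtol,
                             rtol = .defaultRtol) {
  stopifnot(inherits(table, "neuronTable"), length(tSpan) == 2,
            tSpan[2] > tSpan[1])
  n <- nrow(table)
  y0 <- if (is.null(init)) defaultInitialState(table)
        else .checkState(init, table)
  times <- seq(tSpan[1], tSpan[2], by = dt)
  if (times[length(times)] < tSpan[2]) times <- c(times, tSpan[2])
  out <- .integrateRaw(y0, times, .packRpar(table), atol, rtol)
  structure(list(times = out[, 1],
                 V = out[, 1 + 1:n, drop = FALSE],
                 h = out[, 1 + n + 1:n, drop = FALSE],
                 S = out[, 2 * n + 2],
                 table = table, atol = atol, rtol = rtol),
            class = "netTrajectory")
}

#' @export
print.netTrajectory <- function(x, ...) {
  cat(sprintf("Network trajectory: %d nodes, t in [%g, %g], %d samples\n",
              ncol(x$V), min(x$times), max(x$times), length(x$times)))
  invisible(x)
}

#' @export
plot.netTrajectory <- function(x, what = c("V", "h", "mean"), ...) {
  what <- match.arg(what)
  if (what == "mean") {
    graphics::plot(x$times, populationMean(x$V, x$table$weight),
                   type = "l", xlab = "time", ylab = "mean V", ...)
  } else {
    graphics::matplot(x$times, x[[what]], type = "l", lty = 1,
                      xlab = "time", ylab = what, ...)
  }
  invisible(x)
}

#' Weighted population mean and variance
#'
#' Population observables of the collocation network: the weighted mean
#' \eqn{\bar V = \sum_i w_i V_i} and variance
#' \eqn{\sum_i w_i (V_i - \bar V)^2}, the quadrature approximations of
#' the corresponding integrals over the heterogeneity density.
#'
#' @param V Voltages: vector (one instant) or time-by-node matrix.
#' @param weights Quadrature weights summing to 1.
#' @return Scalar or per-time vector.
#' @examples
#' populationMean(c(-60, -20), c(0.5, 0.5))       # -40
#' populationVariance(c(-60, -20), c(0.5, 0.5))   # 400
#' @export
populationMean <- function(V, weights) {
  if (is.matrix(V)) {
    if (ncol(V) != length(weights)) stop("V/weights dimension mismatch")
    return(drop(V %*% weights))
  }
  if (length(V) != length(weights)) stop("V/weights length mismatch")
  sum(weights * V)
}

#' @rdname populationMean
#' @export
populationVariance <- function(V, weights) {
  m <- populationMean(V, weights)
  if (is.matrix(V)) drop((V - m)^2 %*% weights)
  else sum(weights * (V - m)^2)
}

## upward level-crossing times of a sampled series, by linear
## interpolation between grid points
.gridUpCrossings <- function(t, x, level) {
  below <- x < level
  k <- which(below[-length(x)] & !below[-1])
  if (!length(k)) return(numeric(0))
  t[k] + (level - x[k]) * (t[k + 1] - t[k]) / (x[k + 1] - x[k])
}

#' Measure the period of the synchronized collective oscillation
#'
#' Integrates past a transient, builds a Poincare section on the weighted
#' mean voltage \eqn{\bar V(t)} (section level adaptive: the midpoint of
#' the observed post-transient range), and collects upward section
#' crossings with the solver's own dense root location.  The period is
#' the mean spacing of successive upward crossings; the estimate is
#' flagged converged once successive spacings agree to a relative
#' `relTol`.
#'
#' @param table A [neuronTable] in an oscillatory regime.
#' @param init Optional initial state (default [defaultInitialState()]).
#' @param transient Time discarded before any measurement.
#' @param nCross Number of upward crossings collected.
#' @param window Length of the calibration window used to set the
#'   section level and a first period guess.
#' @param dt Sampling interval of the calibration window.
#' @param level Optional fixed section level (overrides the adaptive
#'   choice; must be crossed by the orbit).
#' @param relTol Relative agreement of successive spacings required to
#'   declare convergence.
#' @param minAmplitude Minimal peak-to-peak range of \eqn{\bar V} (mV)
#'   below which the state is declared non-oscillatory.
#' @param atol,rtol Integration tolerances.
#' @return A `periodEstimate`: list with `period`, `crossings` (upward
#'   crossing times, absolute), `residual` (last spacing difference),
#'   `converged`, `level`, `nNodes`.
#' @examples
#' \donttest{
#' tab <- collocationTable(legendreRule(10), Im = 17.5, Is = 7.5)
#' findPeriod(tab)$period   # about 8.04
#' }
#' @export
findPeriod <- function(table, init = NULL, transient = 100, nCross = 12,
                       window = 40, dt = 0.02, level = NULL,
                       relTol = 1e-9, minAmplitude = 0.5,
                       atol = .defaultAtol, rtol = .defaultRtol) {
  stopifnot(inherits(table, "neuronTable"))
  n <- nrow(table)
  rpar <- .packRpar(table)
  y0 <- if (is.null(init)) defaultInitialState(table)
        else .checkState(init, table)

  ## 1: discard the transient
  out <- .integrateRaw(y0, c(0, transient), rpar, atol, rtol)
  y1 <- as.numeric(out[nrow(out), 1 + 1:(2 * n)])

  ## 2: calibrate section level and a rough period on a dense window
  calib <- .integrateRaw(y1, seq(0, window, by = dt), rpar, atol, rtol)
  vbar <- drop(calib[, 1 + 1:n, drop = FALSE] %*% table$weight)
  amp <- max(vbar) - min(vbar)
  if (amp < minAmplitude)
    .noOscillation(sprintf(
      "no oscillation detected: mean-voltage range %.3g mV within %g time units",
      amp, window))
  if (is.null(level)) level <- (max(vbar) + min(vbar)) / 2
  cross0 <- .gridUpCrossings(calib[, 1], vbar, level)
  if (length(cross0) < 2) {
    calib <- .integrateRaw(y1, seq(0, 4 * window, by = dt), rpar, atol,
                           rtol)
    vbar <- drop(calib[, 1 + 1:n, drop = FALSE] %*% table$weight)
    cross0 <- .gridUpCrossings(calib[, 1], vbar, level)
    if (length(cross0) < 2)
      .noOscillation(
        "no oscillation detected: mean voltage never crosses the section twice")
  }
  roughT <- mean(diff(cross0))
  calibEnd <- calib[nrow(calib), 1]
  y2 <- as.numeric(calib[nrow(calib), 1 + 1:(2 * n)])

  ## 3: precise crossing times from the solver's root finder
  rpar[2] <- level
  tmax <- roughT * (nCross + 3)
  times <- seq(0, tmax, by = dt)
  outr <- .integrateRaw(y2, times, rpar, atol, rtol, roots = TRUE,
                        maxroot = 4 * (nCross + 6))
  troot <- attributes(outr)$troot
  if (is.null(troot) || length(troot) < 4)
    .noOscillation("no oscillation detected: too few section crossings")
  vb3 <- drop(outr[, 1 + 1:n, drop = FALSE] %*% table$weight)
  ## crossings of a transversal section strictly alternate in direction:
  ## classify the first root from the mean of vbar over the following
  ## inter-root segment, then take every other root
  troot <- troot[c(TRUE, diff(troot) > 1e-8)]
  seg <- outr[, 1] > troot[1] & outr[, 1] < troot[2]
  segMean <- if (any(seg)) mean(vb3[seg])
             else stats::approx(outr[, 1], vb3,
                                xout = (troot[1] + troot[2]) / 2)$y
  firstUp <- segMean > level
  upt <- troot[seq(if (firstUp) 1 else 2, length(troot), by = 2)]
  if (length(upt) > nCross + 1) upt <- upt[seq_len(nCross + 1)]
  if (length(upt) < 3)
    .noOscillation("no oscillation detected: fewer than three upward crossings")
  spac <- diff(upt)
  residual <- abs(spac[length(spac)] - spac[length(spac) - 1])
  period <- mean(spac)
  structure(list(period = period,
                 crossings = transient + calibEnd + upt,
                 residual = residual,
                 converged = residual < relTol * period,
                 level = level, nNodes = n),
            class = "periodEstimate")
}

#' @export
print.periodEstimate <- function(x, ...) {
  cat(sprintf("Collective period: %.12g (%d nodes, %d crossings, %s)\n",
              x$period, x$nNodes, length(x$crossings),
              if (x$converged) sprintf("converged, residual %.2g",
                                       x$residual)
              else sprintf("NOT converged, residual %.2g", x$residual)))
  invisible(x)
}

## scalar nullcline-intersection heuristic: self-consistent initial guess
## for the network fixed point (h eliminated through h = hinf(V))
.fixedPointGuess <- function(table) {
  n <- nrow(table)
  Vg <- seq(-90, 20, by = 0.25)
  V <- rep(-60, n)
  S <- 0
  for (it in 1:8) {
    for (i in seq_len(n)) {
      f <- -table$gNa[i] * mGate(Vg) * hinfGate(Vg) * (Vg - table$VNa[i]) -
        table$gl[i] * (Vg - table$Vl[i]) +
        table$gsyn[i] * (table$Vsyn[i] - Vg) * S + table$Iapp[i]
      k <- which(f[-length(f)] * f[-1] <= 0)
      if (!length(k)) next
      cand <- Vg[k] - f[k] * 0.25 / (f[k + 1] - f[k])
      V[i] <- cand[which.min(abs(cand - V[i]))]
    }
    Snew <- sum(table$weight * sGate(V))
    if (abs(Snew - S) < 1e-12) { S <- Snew; break }
    S <- Snew
  }
  c(V, hinfGate(V))
}

#' Find a fixed point of the network
#'
#' Damped Newton iteration on the network right-hand side with the
#' analytic Jacobian of [networkJacobian()].  The returned object carries
#' the Jacobian spectrum at the solution, from which linear stability is
#' read off.
#'
#' @param table A [neuronTable].
#' @param guess Optional initial state `c(V, h)`; by default a
#'   self-consistent scalar nullcline-intersection heuristic.
#' @param tol Convergence threshold on the max-norm of the right-hand
#'   side.
#' @param maxIter Maximum Newton iterations.
#' @return A `fixedPoint`: list with `V`, `h`, `residual`, `eigenvalues`,
#'   `maxRe`, `stable`.
#' @examples
#' tab <- collocationTable(legendreRule(1), Im = 35, Is = 0,
#'                         params = modelParams(gsyn = 0))
#' fp <- findFixedPoint(tab)
#' fp$stable
#' @export
findFixedPoint <- function(table, guess = NULL, tol = 1e-10,
                           maxIter = 50) {
  stopifnot(inherits(table, "neuronTable"))
  n <- nrow(table)
  y <- if (is.null(guess)) .fixedPointGuess(table)
       else .checkState(guess, table)
  f <- networkDeriv(y, table)
  for (it in seq_len(maxIter)) {
    if (max(abs(f)) < tol) break
    J <- networkJacobian(y, table)
    step <- tryCatch(solve(J, f), error = function(e)
      stop("fixed-point solve failed: singular Jacobian (", e$message, ")"))
    lambda <- 1
    for (damp in 1:10) {
      yNew <- y - lambda * step
      fNew <- tryCatch(networkDeriv(yNew, table), error = function(e) NULL)
      if (!is.null(fNew) && max(abs(fNew)) < max(abs(f))) break
      lambda <- lambda / 2
    }
    y <- yNew; f <- fNew
  }
  if (max(abs(f)) >= tol)
    stop("fixed-point iteration did not converge (residual ",
         format(max(abs(f))), "); supply a better guess")
  ev <- eigen(networkJacobian(y, table), only.values = TRUE)$values
  maxRe <- max(Re(ev))
  structure(list(V = y[1:n], h = y[(n + 1):(2 * n)],
                 residual = max(abs(f)), eigenvalues = ev,
                 maxRe = maxRe, stable = maxRe < 0, table = table),
            class = "fixedPoint")
}

#' @export
print.fixedPoint <- function(x, ...) {
  cat(sprintf(
    "Fixed point: %d nodes, mean V = %.4f, residual %.2g, %s (max Re = %.4g)\n",
    length(x$V), populationMean(x$V, x$table$weight), x$residual,
    if (x$stable) "stable" else "unstable", x$maxRe))
  invisible(x)
}

#' Check synchrony of a network trajectory
#'
#' The population counts as synchronized when every node completes the
#' same number of cycles over the analysis window and the node-to-node
#' timing offsets stay below a quarter period.  Cycles are counted as
#' upward crossings of each node's own mid-range voltage level, inside a
#' window aligned to the reference node's crossings (extended by a
#' quarter period on both sides) so that pure phase lags do not alter
#' the counts at the window edges; nodes whose voltage range stays below
#' `minAmplitude` count zero cycles.
#' Windows shorter than two reference cycles give an inconclusive
#' verdict.
#'
#' @param traj A `netTrajectory` spanning several cycles (transient
#'   already discarded).
#' @param minAmplitude Peak-to-peak voltage below which a node is
#'   considered quiescent (mV).
#' @return List with `synchronized` (TRUE/FALSE/NA for inconclusive),
#'   per-node `counts`, `maxOffset`, and the reference `period`.
#' @export
synchronyCheck <- function(traj, minAmplitude = 1) {
  stopifnot(inherits(traj, "netTrajectory"))
  n <- ncol(traj$V)
  crossings <- vector("list", n)
  for (i in seq_len(n)) {
    v <- traj$V[, i]
    if (max(v) - min(v) < minAmplitude) {
      crossings[[i]] <- numeric(0)
    } else {
      crossings[[i]] <- .gridUpCrossings(traj$times, v,
                                         (max(v) + min(v)) / 2)
    }
  }
  rawCounts <- lengths(crossings)
  ref <- which.max(rawCounts)
  if (rawCounts[ref] < 2)
    return(list(synchronized = NA, counts = rawCounts, maxOffset = NA,
                period = NA))
  rc <- crossings[[ref]]
  period <- mean(diff(rc))
  if (diff(range(traj$times)) < 2 * period)
    return(list(synchronized = NA, counts = rawCounts, maxOffset = NA,
                period = period))
  ## count each node's crossings inside a reference-aligned window: a
  ## node with the same period and a phase offset within the quarter-
  ## period criterion contributes exactly one crossing per reference
  ## cycle, independent of where the analysis window happens to cut
  lo <- rc[1] - period / 4; hi <- rc[length(rc)] + period / 4
  inWin <- lapply(crossings, function(tc) tc[tc >= lo & tc <= hi])
  counts <- lengths(inWin)
  if (length(unique(counts)) > 1)
    return(list(synchronized = FALSE, counts = counts, maxOffset = Inf,
                period = period))
  if (n == 1)
    return(list(synchronized = TRUE, counts = counts, maxOffset = 0,
                period = period))
  k <- min(counts)
  offs <- vapply(seq_len(n), function(i)
    max(abs(inWin[[i]][1:k] - rc[1:k])), numeric(1))
  list(synchronized = max(offs) <= period / 4, counts = counts,
       maxOffset = max(offs), period = period)
}

#' Export a trajectory as CSV with JSON metadata
#'
#' Writes `time, V_1..V_P, h_1..h_P` rows to `path` and a `<path>.json`
#' sidecar recording the parameter table and tolerances, so the run is
#' reproducible from its files.
#'
#' @param traj A `netTrajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(inherits(traj, "netTrajectory"))
  n <- ncol(traj$V)
  df <- data.frame(time = traj$times)
  for (i in seq_len(n)) df[[paste0("V_", i)]] <- traj$V[, i]
  for (i in seq_len(n)) df[[paste0("h_", i)]] <- traj$h[, i]
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(nodes = n, atol = traj$atol, rtol = traj$rtol,
               table = as.list(as.data.frame(traj$table)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
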