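#' Model parameters for the reduced pre-Botzinger network
#'
#' Container for the constants of the two-variable (burst-envelope)
#' pre-Botzinger complex model: a persistent-sodium current with
#' instantaneous activation `m(V)` and slow inactivation `h`, a leak
#' current, and instantaneous excitatory synaptic coupling through the
#' sigmoid `s(V)`.  Voltages are nominally in mV; conductances, currents
#' and the capacitance are in the model's own units and are not converted
#' to SI.
#'
#' @param C Membrane capacitance (> 0).
#' @param gNa Persistent-sodium conductance (>= 0).
#' @param gl Leak conductance (>= 0).
#' @param VNa Sodium reversal potential (mV).
#' @param Vl Leak reversal potential (mV).
#' @param Vsyn Synaptic reversal potential (mV); 0 gives excitatory
#'   coupling.
#' @param gsyn Synaptic conductance (>= 0); 0 uncouples the population.
#' @param eps Rate scale of the slow gating variable `h` (> 0).  Smaller
#'   values give a stronger time-scale separation between `V` and `h`.
#' @return An object of class `modelParams` (a validated named list).
#' @examples
#' p <- modelParams()
#' p$gsyn
#' modelParams(gsyn = 0)   # uncoupled population
#' @export
modelParams <- function(C = 0.21, gNa = 2.8, gl = 2.4, VNa = 50, Vl = -65,
                        Vsyn = 0, gsyn = 0.3, eps = 0.1) {
  p <- list(C = C, gNa = gNa, gl = gl, VNa = VNa, Vl = Vl,
            Vsyn = Vsyn, gsyn = gsyn, eps = eps)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1))))
    stop("all model parameters must be finite numeric scalars")
  if (C <= 0) stop("capacitance C must be positive")
  if (eps <= 0) stop("gating rate scale eps must be positive")
  if (gNa < 0 || gl < 0 || gsyn < 0)
    stop("conductances gNa, gl, gsyn must be non-negative")
  structure(p, class = "modelParams")
}

#' @export
print.modelParams <- function(x, ...) {
  cat("Reduced pre-Botzinger model parameters:\n")
  cat(sprintf("  C=%g  gNa=%g  gl=%g  gsyn=%g\n", x$C, x$gNa, x$gl, x$gsyn))
  cat(sprintf("  VNa=%g  Vl=%g  Vsyn=%g  eps=%g\n",
              x$VNa, x$Vl, x$Vsyn, x$eps))
  invisible(x)
}

.checkVoltage <- function(V) {
  if (!is.numeric(V) || anyNA(V) || any(!is.finite(V)))
    stop("voltage must be finite numeric")
  V
}

#' Gating and synaptic activation functions
#'
#' The voltage-dependent functions of the model.  `sGate` is the
#' instantaneous synaptic activation, `mGate` the instantaneous
#' persistent-sodium activation, `hinfGate` the steady state of the slow
#' inactivation variable, and `tauGate` its voltage-dependent time
#' constant \eqn{\tau(V) = 1/(\epsilon \cosh[(V+44)/12])}.
#'
#' `sGate` and `mGate` are strictly increasing with range (0, 1);
#' `hinfGate` is strictly decreasing with range (0, 1); `tauGate` is
#' positive, even about V = -44 mV, and maximized there with value
#' `1/eps`.
#'
#' @param V Membrane potential (mV), vectorized.
#' @param eps Gating rate scale (> 0).
#' @return Numeric vector of the same length as `V`.
#' @examples
#' sGate(-40)        # sigmoid midpoint: 0.5
#' tauGate(-44)      # maximum: 1/eps = 10
#' hinfGate(-44)     # 0.5
#' @export
sGate <- function(V) 1 / (1 + exp(-(.checkVoltage(V) + 40) / 5))

#' @rdname sGate
#' @export
mGate <- function(V) 1 / (1 + exp(-(.checkVoltage(V) + 37) / 6))

#' @rdname sGate
#' @export
hinfGate <- function(V) 1 / (1 + exp((.checkVoltage(V) + 44) / 6))

#' @rdname sGate
#' @export
tauGate <- function(V, eps = 0.1) {
  if (!is.numeric(eps) || length(eps) != 1 || !is.finite(eps) || eps <= 0)
    stop("eps must be a positive finite scalar")
  1 / (eps * cosh((.checkVoltage(V) + 44) / 12))
}

## first derivatives of the gates (used in the analytic Jacobian)
.sPrime <- function(V) { s <- sGate(V); s * (1 - s) / 5 }
.mPrime <- function(V) { m <- mGate(V); m * (1 - m) / 6 }
.hinfPrime <- function(V) { h <- hinfGate(V); -h * (1 - h) / 6 }

#' Quadrature-weighted synaptic drive
#'
#' Per-node synaptic current of the all-to-all coupled population in its
#' continuum-limit form: every node receives the same population activation
#' \eqn{S = \sum_j w_j s(V_j)} (the quadrature approximation of the
#' activation integral over the heterogeneity density), scaled by its own
#' driving force,
#' \eqn{I_{syn,i} = g_{syn} (V_{syn} - V_i) S}.
#'
#' Composite weights from sparse grids may be negative; the sum is taken
#' as-is.
#'
#' @param V Voltages at the collocation nodes.
#' @param weights Quadrature weights (should sum to 1 for probability
#'   rules).
#' @param gsyn Synaptic conductance; scalar or per-node vector.
#' @param Vsyn Synaptic reversal potential; scalar or per-node vector.
#' @return Vector of per-node synaptic currents.
#' @examples
#' synapticDrive(c(-40, -40), c(0.5, 0.5))   # 0.3 * 40 * 0.5 = 6 each
#' @export
synapticDrive <- function(V, weights, gsyn = 0.3, Vsyn = 0) {
  if (length(V) != length(weights))
    stop("V and weights must have the same length")
  S <- sum(weights * sGate(V))
  gsyn * (Vsyn - V) * S
}

#' Build a per-neuron parameter table directly
#'
#' Low-level constructor of the `neuronTable` used by the integrator and
#' the bifurcation tools: one row per collocation node, with every model
#' parameter realized per node plus the applied current `Iapp` and the
#' coupling weight.  Most users should build tables through
#' [collocationTable()] (one heterogeneous current) or
#' [gridToParameters()] (arbitrary heterogeneity axes).
#'
#' @param params A [modelParams()] object supplying homogeneous values.
#' @param Iapp Applied current, scalar or one value per node.
#' @param weights Coupling (quadrature) weights, one per node; must sum
#'   to 1 up to accumulation error.
#' @param coords Optional matrix of standard-variable collocation
#'   coordinates (used to seed initial conditions); defaults to a mild
#'   spread over \[-1, 1\].
#' @param ... Named per-node overrides of model parameter columns, e.g.
#'   `gNa = c(...)`.
#' @return A `neuronTable` (data.frame subclass) with columns `C`, `gNa`,
#'   `gl`, `VNa`, `Vl`, `Vsyn`, `gsyn`, `eps`, `Iapp`, `weight`.
#' @export
neuronTable <- function(params = modelParams(), Iapp = 0, weights = 1,
                        coords = NULL, ...) {
  n <- max(length(Iapp), length(weights))
  if (length(weights) == 1 && n > 1) weights <- rep(weights, n)
  if (length(Iapp) == 1 && n > 1) Iapp <- rep(Iapp, n)
  if (length(Iapp) != n || length(weights) != n)
    stop("Iapp and weights lengths are inconsistent")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("coupling weights must sum to 1 (within accumulation error)")
  tab <- data.frame(C = rep(params$C, n), gNa = rep(params$gNa, n),
                    gl = rep(params$gl, n), VNa = rep(params$VNa, n),
                    Vl = rep(params$Vl, n), Vsyn = rep(params$Vsyn, n),
                    gsyn = rep(params$gsyn, n), eps = rep(params$eps, n),
                    Iapp = Iapp, weight = weights)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(tab)[1:8]) stop("unknown parameter column: ", nm)
    v <- dots[[nm]]
    if (length(v) == 1) v <- rep(v, n)
    if (length(v) != n) stop("override '", nm, "' has wrong length")
    tab[[nm]] <- v
  }
  if (is.null(coords)) {
    coords <- matrix(if (n == 1) 0 else seq(-1, 1, length.out = n), ncol = 1)
  }
  attr(tab, "coords") <- coords
  class(tab) <- c("neuronTable", "data.frame")
  tab
}

#' @export
print.neuronTable <- function(x, ...) {
  cat(sprintf("Neuron parameter table: %d collocation node%s\n",
              nrow(x), if (nrow(x) == 1) "" else "s"))
  het <- names(x)[vapply(x, function(col) length(unique(col)) > 1,
                         logical(1))]
  het <- setdiff(het, "weight")
  if (length(het))
    cat("  heterogeneous columns:", paste(het, collapse = ", "), "\n")
  else cat("  homogeneous population\n")
  NextMethod()
}

## pack a neuronTable into the rpar vector consumed by the C right-hand
## side; `level` is the Poincare section level used by the root function
.packRpar <- function(table, level = 0) {
  c(nrow(table), level, table$C, table$gNa, table$gl, table$VNa, table$Vl,
    table$Vsyn, table$gsyn, table$eps, table$Iapp, table$weight)
}

#' Network right-hand side (reference implementation)
#'
#' Evaluates the time derivative of the reduced network,
#' \deqn{C \dot V_i = -g_{Na} m(V_i) h_i (V_i - V_{Na})
#'   - g_l (V_i - V_l) + I_{syn,i} + I_{app,i}, \quad
#'   \dot h_i = (h_\infty(V_i) - h_i)/\tau(V_i),}
#' with the quadrature-weighted synaptic drive of [synapticDrive()].
#' This pure-R version defines the model; the integrator uses a compiled
#' translation of the same expressions, and the two are required to agree
#' to machine precision.
#'
#' @param state Either a list with elements `V` and `h` or a numeric
#'   vector `c(V, h)` of length `2 * nrow(table)`.
#' @param table A `neuronTable`.
#' @return Same shape as `state`: the derivative.
#' @examples
#' tab <- collocationTable(legendreRule(5), Im = 17.5, Is = 7.5)
#' V <- rep(-50, 5)
#' d <- networkDeriv(list(V = V, h = hinfGate(V)), tab)
#' max(abs(d$h))    # dh/dt = 0 exactly when h = hinf(V)
#' @export
networkDeriv <- function(state, table) {
  n <- nrow(table)
  asList <- is.list(state)
  if (asList) {
    V <- state$V; h <- state$h
  } else {
    if (length(state) != 2 * n) stop("state length must be 2 * nrow(table)")
    V <- state[1:n]; h <- state[(n + 1):(2 * n)]
  }
  if (length(V) != n || length(h) != n)
    stop("state dimensions do not match the parameter table")
  if (anyNA(V) || any(!is.finite(V)) || anyNA(h) || any(!is.finite(h)))
    stop("non-finite state passed to networkDeriv")
  S <- sum(table$weight * sGate(V))
  dV <- (-table$gNa * mGate(V) * h * (V - table$VNa) -
           table$gl * (V - table$Vl) +
           table$gsyn * (table$Vsyn - V) * S + table$Iapp) / table$C
  dh <- (hinfGate(V) - h) * table$eps * cosh((V + 44) / 12)
  if (asList) list(V = dV, h = dh) else c(dV, dh)
}
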