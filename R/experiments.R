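## Reproducible convergence and comparison experiments: period and Hopf
## convergence in the node count, competing node choices for a second
## (normally distributed) heterogeneous parameter, and sparse-versus-full
## grids in four heterogeneous dimensions.
##
## Every experiment returns a plain data frame plus a "meta" attribute
## (configuration echo, reference provenance, fitted slopes, seeds), and
## is bit-reproducible from that configuration.

#' Fit a log-log convergence slope
#'
#' Ordinary least squares of `log10(err)` on `log10(n)`.  Points already
#' saturated by the reference's own error are excluded: a point enters
#' the fit only if `err >= 10 * refError` (with the threshold recorded in
#' the result), otherwise the plateau would bias the slope.
#'
#' @param n Problem sizes.
#' @param err Absolute errors (positive).
#' @param refError Estimated error of the reference value itself
#'   (default 0: no exclusion).
#' @return List with `slope`, `intercept`, `used` (logical mask of
#'   points in the fit), `threshold`.
#' @examples
#' fitLoglogSlope(c(10, 20, 40, 80), 5 / c(10, 20, 40, 80)^2)$slope  # -2
#' @export
fitLoglogSlope <- function(n, err, refError = 0) {
  stopifnot(length(n) == length(err))
  used <- is.finite(err) & err >= 10 * refError & err > 0
  if (sum(used) < 2)
    return(list(slope = NA_real_, intercept = NA_real_, used = used,
                threshold = 10 * refError))
  fit <- stats::lm(log10(err[used]) ~ log10(n[used]))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       used = used, threshold = 10 * refError)
}

.ruleByName <- function(kind, n, seed = NULL) {
  switch(kind,
         gauss_legendre = , gauss = legendreRule(n),
         midpoint = midpointRule(n),
         gauss_hermite = , hermite = hermiteRule(n),
         inverse_cdf = , icdf = inverseCdfRule(n),
         monte_carlo = , mc = monteCarloRule(n, seed = seed),
         stop("unknown rule kind: ", kind))
}

#' Period convergence in the number of collocation nodes
#'
#' Measures the collective period with midpoint and Gauss-Legendre node
#' choices over a sweep of node counts and reports absolute errors
#' against a high-resolution Gauss-Legendre reference computed within the
#' experiment.  The Gauss errors fall spectrally fast until they are
#' dominated by the time integration; the midpoint errors decay as
#' `N^-2`.
#'
#' @param Ns Node counts to sweep.
#' @param rules Character vector of rule kinds to compare.
#' @param Im,Is Mean and spread of the applied current.
#' @param params Base [modelParams()].
#' @param refN Node count of the Gauss-Legendre reference.
#' @param refError A priori estimate of the reference period's own error
#'   (sets the saturation threshold for slope fitting).
#' @param ... Passed to [findPeriod()] (e.g. `transient`, `nCross`).
#' @return Data frame `(N, rule, period, absError)` with a `meta`
#'   attribute carrying the reference value and fitted slopes per rule.
#' @export
studyPeriodConvergence <- function(Ns = c(10, 20, 40, 80),
                                   rules = c("midpoint", "gauss_legendre"),
                                   Im = 17.5, Is = 7.5,
                                   params = modelParams(), refN = 200,
                                   refError = 1e-8, ...) {
  ref <- findPeriod(collocationTable(legendreRule(refN), Im, Is, params),
                    ...)
  rows <- list()
  for (kind in rules) for (N in Ns) {
    pe <- findPeriod(collocationTable(.ruleByName(kind, N), Im, Is,
                                      params), ...)
    rows[[length(rows) + 1]] <-
      data.frame(N = N, rule = kind, period = pe$period,
                 absError = abs(pe$period - ref$period))
  }
  out <- do.call(rbind, rows)
  slopes <- lapply(stats::setNames(rules, rules), function(kind) {
    sub <- out[out$rule == kind, ]
    fitLoglogSlope(sub$N, sub$absError, refError = refError)
  })
  attr(out, "meta") <- list(reference = ref$period, refN = refN,
                            refRule = "gauss_legendre",
                            refError = refError, Im = Im, Is = Is,
                            slopes = slopes)
  out
}

#' Hopf-location convergence in the number of collocation nodes
#'
#' Locates the upper or lower Hopf bifurcation in `Im` for a sweep of
#' node counts and both node-choice rules, with errors against a
#' Gauss-Legendre reference of `refN` nodes.  The Hopf location is only
#' resolved to the bisection tolerance, so Gauss errors plateau there.
#'
#' @param Ns Node counts to sweep.
#' @param rules Rule kinds to compare.
#' @param which `"upper"` or `"lower"` Hopf point.
#' @param bracket `Im` bracket enclosing that point (defaults chosen for
#'   `Is = 7.5`, `gsyn = 0.3`).
#' @param Is Heterogeneity spread.
#' @param params Base [modelParams()].
#' @param refN Reference node count.
#' @param tol Bisection tolerance passed to [locateHopf()].
#' @return Data frame `(N, rule, Im, absError)` with `meta` attribute
#'   (reference, slopes).
#' @export
studyHopfConvergence <- function(Ns = c(10, 20, 40, 80),
                                 rules = c("midpoint", "gauss_legendre"),
                                 which = c("upper", "lower"),
                                 bracket = NULL, Is = 7.5,
                                 params = modelParams(), refN = 80,
                                 tol = 1e-6) {
  which <- match.arg(which)
  if (is.null(bracket))
    bracket <- if (which == "upper") c(30, 36) else c(4, 8)
  ref <- hopfIm(legendreRule(refN), bracket, Is = Is, params = params,
                tol = tol)
  rows <- list()
  for (kind in rules) for (N in Ns) {
    hp <- hopfIm(.ruleByName(kind, N), bracket, Is = Is, params = params,
                 tol = tol)
    rows[[length(rows) + 1]] <-
      data.frame(N = N, rule = kind, Im = hp$value,
                 absError = abs(hp$value - ref$value))
  }
  out <- do.call(rbind, rows)
  slopes <- lapply(stats::setNames(rules, rules), function(kind) {
    sub <- out[out$rule == kind, ]
    fitLoglogSlope(sub$N, sub$absError, refError = tol)
  })
  attr(out, "meta") <- list(reference = ref$value, refN = refN,
                            which = which, bracket = bracket, Is = Is,
                            tol = tol, slopes = slopes)
  out
}

#' Competing node choices for a second heterogeneous parameter
#'
#' With the applied current heterogeneous (uniform, Gauss-Legendre nodes
#' held fixed) and the sodium conductance normally distributed
#' (`gNa = 2.8 + sigma * lambda`), compares Monte Carlo, inverse-CDF and
#' probabilists' Gauss-Hermite choices of the `lambda` nodes over a sweep
#' of their count `M`.  Period errors are measured against a
#' Gauss-Hermite reference with `refM` nodes; Monte Carlo errors are the
#' averages of absolute errors over the given seeds.
#'
#' @param Ms Sweep of node counts in the normal direction.
#' @param methods Subset of `"monte_carlo"`, `"inverse_cdf"`,
#'   `"gauss_hermite"`.
#' @param seeds Integer seeds for the Monte Carlo replicates.
#' @param Im,Is Mean and spread of the applied current.
#' @param sigma Standard deviation of `gNa`.
#' @param NMu Gauss-Legendre node count in the current direction.
#' @param params Base [modelParams()].
#' @param refM Hermite node count of the reference.
#' @param refError Saturation threshold for the slope fits.
#' @param atol,rtol,nCross,window Period-measurement settings passed to
#'   [findPeriod()].  The defaults are looser than the one-parameter
#'   reference tolerances: the discretization errors compared here are
#'   at least 1e-4, while these settings keep the measurement error near
#'   1e-10 at a fraction of the cost.
#' @param ... Further arguments passed to [findPeriod()].
#' @return Data frame `(M, method, meanAbsError)` with `meta` attribute
#'   (reference, seeds, slopes).
#' @export
studyTwoParamHeterogeneity <- function(Ms = c(5, 10, 20, 40, 80),
                                       methods = c("monte_carlo",
                                                   "inverse_cdf",
                                                   "gauss_hermite"),
                                       seeds = 1:10, Im = 25, Is = 7.5,
                                       sigma = 0.25, NMu = 10,
                                       params = modelParams(), refM = 60,
                                       refError = 1e-7, atol = 1e-9,
                                       rtol = 1e-10, nCross = 6,
                                       window = 30, ...) {
  muRule <- legendreRule(NMu)
  periodFor <- function(gRule) {
    grid <- tensorGrid(list(hetAxis("Iapp", Im, Is, muRule),
                            hetAxis("gNa", 2.8, sigma, gRule)))
    findPeriod(gridToParameters(grid, params), atol = atol, rtol = rtol,
               nCross = nCross, window = window, ...)$period
  }
  ref <- periodFor(hermiteRule(refM))
  rows <- list()
  for (method in methods) for (M in Ms) {
    err <- if (method == "monte_carlo") {
      mean(vapply(seeds, function(sd)
        abs(periodFor(monteCarloRule(M, seed = sd)) - ref), numeric(1)))
    } else {
      rule <- if (method == "inverse_cdf") inverseCdfRule(M)
              else hermiteRule(M)
      abs(periodFor(rule) - ref)
    }
    rows[[length(rows) + 1]] <-
      data.frame(M = M, method = method, meanAbsError = err)
  }
  out <- do.call(rbind, rows)
  slopes <- lapply(stats::setNames(methods, methods), function(mth) {
    sub <- out[out$method == mth, ]
    fitLoglogSlope(sub$M, sub$meanAbsError, refError = refError)
  })
  attr(out, "meta") <- list(reference = ref, refM = refM, NMu = NMu,
                            Im = Im, Is = Is, sigma = sigma,
                            seeds = seeds, refError = refError,
                            errorAveraging = "absolute errors averaged over seeds",
                            slopes = slopes)
  out
}

## the four-axis uniform heterogeneity setup used by the sparse-grid
## comparison: Iapp in [17.5, 32.5], gNa in [2.55, 3.05], Vsyn in [-1, 1],
## VNa in [49, 51]
.fourAxisSpecs <- function() list(
  list(param = "Iapp", location = 25, scale = 7.5),
  list(param = "gNa", location = 2.8, scale = 0.25),
  list(param = "Vsyn", location = 0, scale = 1),
  list(param = "VNa", location = 50, scale = 1))

.axesWithRules <- function(specs, rules) {
  mapply(function(sp, r) hetAxis(sp$param, sp$location, sp$scale, r),
         specs, rules, SIMPLIFY = FALSE)
}

#' Sparse versus full grids with four heterogeneous parameters
#'
#' Compares period errors of full tensor-product grids and Smolyak
#' sparse grids when four parameters are simultaneously and
#' independently uniformly heterogeneous (applied current, sodium
#' conductance, synaptic and sodium reversal potentials).  The reference
#' is a higher-level sparse grid computed within the experiment.  At
#' comparable node budgets the sparse grids are substantially more
#' accurate.
#'
#' @param levels Smolyak levels to evaluate.
#' @param tensorNs Per-dimension sizes of the full tensor grids.
#' @param refLevel Level of the sparse reference grid.
#' @param params Base [modelParams()].
#' @param atol,rtol,nCross,window Period-measurement settings passed to
#'   [findPeriod()] (see [studyTwoParamHeterogeneity()] for the
#'   rationale of the loosened defaults).
#' @param ... Further arguments passed to [findPeriod()].
#' @return Data frame `(kind, detail, nodes, period, absError)` with
#'   `meta` attribute.
#' @export
studySparseVsFull <- function(levels = 0:2, tensorNs = c(2, 3),
                              refLevel = 3, params = modelParams(),
                              atol = 1e-9, rtol = 1e-10, nCross = 6,
                              window = 30, ...) {
  specs <- .fourAxisSpecs()
  periodFor <- function(grid, axes) {
    tab <- gridToParameters(grid, params, axes = axes)
    findPeriod(tab, atol = atol, rtol = rtol, nCross = nCross,
               window = window, ...)$period
  }
  sparseFor <- function(L) {
    g <- smolyakGrid(L, 4)
    axes <- .axesWithRules(specs, lapply(rep(1, 4), legendreRule))
    list(grid = g, axes = axes)
  }
  refG <- sparseFor(refLevel)
  ref <- periodFor(refG$grid, refG$axes)
  rows <- list()
  for (L in levels) {
    sg <- sparseFor(L)
    p <- periodFor(sg$grid, sg$axes)
    rows[[length(rows) + 1]] <-
      data.frame(kind = "smolyak", detail = sprintf("level %d", L),
                 nodes = nrow(sg$grid$nodes), period = p,
                 absError = abs(p - ref))
  }
  for (N in tensorNs) {
    axes <- .axesWithRules(specs, lapply(rep(N, 4), legendreRule))
    g <- tensorGrid(axes)
    p <- periodFor(g, axes)
    rows[[length(rows) + 1]] <-
      data.frame(kind = "tensor", detail = sprintf("%d^4", N),
                 nodes = nrow(g$nodes), period = p,
                 absError = abs(p - ref))
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- list(reference = ref, refLevel = refLevel,
                            refNodes = nrow(refG$grid$nodes),
                            axes = specs)
  out
}

#' Write an experiment table with its metadata
#'
#' Saves the experiment's data frame as `<dir>/<name>.csv` and its
#' `meta` attribute (configuration, reference provenance, slopes, seeds)
#' as `<dir>/<name>.json`.
#'
#' @param result A data frame from one of the `study*` functions.
#' @param dir Output directory (created if missing).
#' @param name File stem.
#' @return The CSV path, invisibly.
#' @export
writeExperiment <- function(result, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(result, csv, row.names = FALSE)
  meta <- attr(result, "meta")
  if (!is.null(meta))
    jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  invisible(csv)
}
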