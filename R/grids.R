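## Multi-dimensional collocation grids: full tensor products and Smolyak
## sparse grids, plus the mapping from standard-variable nodes to
## per-neuron model parameters.

#' Describe one heterogeneous parameter direction
#'
#' A heterogeneity axis ties a model parameter to a standard random
#' variable through `value = location + scale * z`, where `z` follows the
#' axis density (uniform on \[-1, 1\] or standard normal) and is sampled
#' at the nodes of the attached quadrature rule.  For example, an applied
#' current uniform on \[10, 25\] is `hetAxis("Iapp", location = 17.5,
#' scale = 7.5, rule = legendreRule(10))`.
#'
#' @param param Name of the heterogeneous parameter: `"Iapp"` or any
#'   model-parameter field (`"gNa"`, `"Vsyn"`, `"VNa"`, ...).
#' @param location Center of the parameter distribution (e.g. the mean
#'   current Im, or 2.8 for gNa).
#' @param scale Spread (>= 0): half-width for the uniform density,
#'   standard deviation for the normal density.
#' @param rule A [quadRule][legendreRule] giving nodes/weights in the
#'   standard variable.
#' @return A `hetAxis` object.
#' @export
hetAxis <- function(param, location, scale, rule) {
  valid <- c("Iapp", "C", "gNa", "gl", "VNa", "Vl", "Vsyn", "gsyn", "eps")
  if (!param %in% valid)
    stop("unknown parameter '", param, "'; must be one of: ",
         paste(valid, collapse = ", "))
  if (!is.numeric(scale) || scale < 0) stop("axis scale must be >= 0")
  if (!inherits(rule, "quadRule")) stop("rule must be a quadRule")
  structure(list(param = param, location = location, scale = scale,
                 rule = rule), class = "hetAxis")
}

#' @export
print.hetAxis <- function(x, ...) {
  cat(sprintf("Heterogeneity axis: %s = %g + %g * z, %s, %s rule, %d nodes\n",
              x$param, x$location, x$scale, x$rule$density, x$rule$kind,
              x$rule$n))
  invisible(x)
}

.newParamGrid <- function(nodes, weights, provenance, axes = NULL) {
  nodes <- as.matrix(nodes)
  dimnames(nodes) <- NULL
  if (nrow(nodes) != length(weights))
    stop("node/weight count mismatch")
  structure(list(nodes = nodes, weights = weights,
                 provenance = provenance, axes = axes),
            class = "paramGrid")
}

#' @export
print.paramGrid <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("Parameter grid: %s, %d node%s in %d dimension%s\n",
              if (pv$kind == "smolyak")
                sprintf("Smolyak sparse (level %d)", pv$level)
              else "full tensor product",
              nrow(x$nodes), if (nrow(x$nodes) == 1) "" else "s",
              ncol(x$nodes), if (ncol(x$nodes) == 1) "" else "s"))
  cat(sprintf("  weight sum %.15g, %d negative weight%s\n",
              sum(x$weights), sum(x$weights < 0),
              if (sum(x$weights < 0) == 1) "" else "s"))
  if (!is.null(x$axes))
    for (a in x$axes)
      cat(sprintf("  axis: %s = %g + %g * z (%s)\n",
                  a$param, a$location, a$scale, a$rule$density))
  invisible(x)
}

.axesToRules <- function(objs) {
  if (all(vapply(objs, inherits, logical(1), "hetAxis")))
    return(list(rules = lapply(objs, `[[`, "rule"), axes = objs))
  if (all(vapply(objs, inherits, logical(1), "quadRule")))
    return(list(rules = objs, axes = NULL))
  stop("expected a list of quadRule or hetAxis objects")
}

#' Full tensor-product grid
#'
#' Cartesian product of one-dimensional quadrature rules: the node set is
#' the cross product of the 1-D node sets and each composite weight is
#' the product of the corresponding 1-D weights, so the grid integrates
#' separable functions exactly as the product of its factors.  The point
#' count is the product of the rule sizes (11 x 11 Gauss-Legendre gives
#' 121 points).
#'
#' @param rules Non-empty list of [quadRule][legendreRule] or
#'   [hetAxis()] objects (one per dimension, in column order).
#' @return A `paramGrid` with `P x D` node matrix and length-`P` weights.
#' @examples
#' g <- tensorGrid(list(legendreRule(11), legendreRule(11)))
#' nrow(g$nodes)   # 121
#' @export
tensorGrid <- function(rules) {
  if (!is.list(rules) || length(rules) == 0)
    stop("rules must be a non-empty list")
  ar <- .axesToRules(rules)
  nodeList <- lapply(ar$rules, `[[`, "nodes")
  wList <- lapply(ar$rules, `[[`, "weights")
  sizes <- lengths(nodeList)
  idx <- do.call(expand.grid, lapply(sizes, seq_len))
  nodes <- mapply(function(x, i) x[i], nodeList, idx)
  if (prod(sizes) == 1) nodes <- matrix(nodes, nrow = 1)
  w <- Reduce(`*`, mapply(function(x, i) x[i], wList, idx,
                          SIMPLIFY = FALSE))
  .newParamGrid(nodes, w,
                list(kind = "tensor", sizes = as.integer(sizes)),
                ar$axes)
}

#' Size of the nested Gauss rule family
#'
#' The level-`i` member of the rule family used to build Smolyak sparse
#' grids has \eqn{N_i = 2^{i+1} - 1} nodes (1, 3, 7, 15, ...).  Note the
#' family is nested in level index only: apart from 0, the Gauss-Legendre
#' node sets of different sizes share no points.
#'
#' @param i Level index (integer >= 0), vectorized.
#' @return Integer node count(s).
#' @examples
#' nestedFamilySize(0:3)   # 1 3 7 15
#' @export
nestedFamilySize <- function(i) {
  if (any(i < 0) || any(i != round(i)))
    stop("level index must be a non-negative integer")
  as.integer(2^(i + 1) - 1)
}

## all length-d vectors of non-negative integers summing to k
.compositions <- function(k, d) {
  if (d == 1) return(matrix(k, ncol = 1))
  out <- vector("list", k + 1)
  for (first in 0:k)
    out[[first + 1]] <- cbind(first, .compositions(k - first, d - 1))
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

#' Smolyak sparse grid
#'
#' Builds the level-`L`, dimension-`D` Smolyak combination of tensor
#' products of a nested-size family of one-dimensional rules
#' (\eqn{N_i = 2^{i+1} - 1} nodes at family level `i`):
#' \deqn{A(L, D) = \sum_{\max(0, L-D+1) \le |i| \le L}
#'   (-1)^{L - |i|} \binom{D-1}{L - |i|}
#'   \left(U^{i_1} \otimes \cdots \otimes U^{i_D}\right),}
#' which for `D = 2` reduces to the difference of the `|i| = L` and
#' `|i| = L - 1` tensor sums.  Coincident nodes (coordinates equal within
#' `tol`) are merged with their signed weights summed; zero-weight nodes
#' arising from cancellation are retained.  Composite weights can be
#' negative; they still sum to 1 because every 1-D rule integrates
#' constants exactly.
#'
#' @param L Level (integer >= 0).  `L = 0` gives the single node at the
#'   origin with weight 1.
#' @param D Dimension (integer >= 1).
#' @param family Function `n -> quadRule` used in every dimension
#'   (default [legendreRule]).
#' @param axes Optional list of `D` [hetAxis()] objects to attach.
#' @param tol Absolute coincidence tolerance for node merging.
#' @return A `paramGrid` with provenance `smolyak`.
#' @examples
#' countDistinctNodes(smolyakGrid(2, 2))   # 21
#' @export
smolyakGrid <- function(L, D, family = legendreRule, axes = NULL,
                        tol = 1e-12) {
  if (!is.numeric(L) || L < 0 || L != round(L)) stop("invalid level L")
  if (!is.numeric(D) || D < 1 || D != round(D)) stop("invalid dimension D")
  L <- as.integer(L); D <- as.integer(D)
  if (!is.null(axes) && length(axes) != D)
    stop("axes must have length D")
  rules <- lapply(0:L, function(l) family(nestedFamilySize(l)))
  nodeList <- lapply(rules, `[[`, "nodes")
  wList <- lapply(rules, `[[`, "weights")
  blocks <- list()
  for (k in max(0L, L - D + 1L):L) {
    coef <- (-1)^(L - k) * choose(D - 1, L - k)
    comps <- .compositions(k, D)
    for (r in seq_len(nrow(comps))) {
      lv <- comps[r, ]
      idx <- do.call(expand.grid, lapply(lv, function(l)
        seq_len(length(nodeList[[l + 1]]))))
      nd <- mapply(function(l, i) nodeList[[l + 1]][i], lv, idx)
      if (nrow(idx) == 1) nd <- matrix(nd, nrow = 1)
      wt <- coef * Reduce(`*`, mapply(function(l, i) wList[[l + 1]][i],
                                      lv, idx, SIMPLIFY = FALSE))
      dt <- data.table::as.data.table(nd)
      dt$W <- wt
      blocks[[length(blocks) + 1]] <- dt
    }
  }
  all <- data.table::rbindlist(blocks)
  cols <- setdiff(names(all), "W")
  ## family rules are shared across blocks, so coincident coordinates are
  ## bitwise identical; grouping by value implements the merge
  merged <- all[, list(W = sum(W)), by = cols]
  data.table::setorderv(merged, cols)
  .newParamGrid(as.matrix(merged[, cols, with = FALSE]), merged$W,
                list(kind = "smolyak", level = L, dim = D, tol = tol),
                axes)
}

#' Count distinct grid nodes
#'
#' Number of distinct node locations after merging coordinates that agree
#' within `tol` in every dimension.  Grids built by [smolyakGrid()] are
#' already merged, so this is simply their row count; for raw node sets
#' the count is taken over rounded coordinates.
#'
#' @param grid A `paramGrid`, or a numeric node matrix.
#' @param tol Absolute coincidence tolerance.
#' @return Integer count.
#' @export
countDistinctNodes <- function(grid, tol = 1e-12) {
  nodes <- if (inherits(grid, "paramGrid")) grid$nodes else as.matrix(grid)
  key <- data.table::as.data.table(round(nodes / tol))
  nrow(unique(key))
}

#' Predicted distinct-node count of a Smolyak Gauss-Legendre grid
#'
#' Closed-form enumeration of the distinct node locations of
#' [smolyakGrid()] with the nested-size Gauss-Legendre family, without
#' building the grid.  It relies on a coincidence property of this
#' family: nonzero roots of Legendre polynomials of different orders
#' never coincide, and every rule contains 0.  A distinct node is then
#' identified by its per-dimension "level signature" (0 where the
#' coordinate is 0, else the generating family level); a signature is
#' realized whenever some index vector of the combination matches it on
#' the active dimensions, which holds for all signatures with
#' \eqn{|s| \le L} except all-active ones below the combination window
#' (\eqn{|s| < L - D + 1}).  The count is evaluated by truncated
#' polynomial convolution over \eqn{\prod_{d: s_d \ge 1} (N_{s_d} - 1)}.
#'
#' @inheritParams smolyakGrid
#' @return Integer count of distinct nodes.
#' @examples
#' smolyakNodeCount(2, 2)   # 21
#' smolyakNodeCount(3, 2)   # 73
#' @export
smolyakNodeCount <- function(L, D) {
  if (L < 0 || D < 1) stop("invalid L or D")
  ## convolve signature-count polynomials truncated at degree L
  convPow <- function(p, D, maxDeg) {
    acc <- c(1, rep(0, maxDeg))
    for (d in seq_len(D)) {
      nxt <- rep(0, maxDeg + 1)
      for (a in 0:maxDeg) {
        if (acc[a + 1] == 0) next
        for (b in 0:(maxDeg - a)) nxt[a + b + 1] <- nxt[a + b + 1] +
            acc[a + 1] * p[b + 1]
      }
      acc <- nxt
    }
    acc
  }
  ## coefficient of x^l counts nonzero roots introduced at family level l
  p <- c(1, if (L >= 1) nestedFamilySize(1:L) - 1)
  total <- sum(convPow(p, D, L))
  ## signatures active in every dimension need their exact index vector
  ## in the combination window, so |s| >= L - D + 1; subtract the rest
  lowCut <- L - D   # all-active signatures with |s| <= L - D are absent
  if (lowCut >= D) {
    q <- c(0, p[-1])
    total <- total - sum(convPow(q, D, lowCut))
  }
  total
}

#' Map grid nodes to per-neuron parameters
#'
#' Realizes a collocation grid as a [neuronTable]: row `k` receives, for
#' each axis `d`, the parameter value `location_d + scale_d * nodes[k, d]`,
#' all other model parameters are copied from `base`, and the grid's
#' composite weight is attached as the coupling weight.
#'
#' @param grid A `paramGrid` whose axes (or the `axes` argument) name one
#'   distinct parameter per grid column.
#' @param base A [modelParams()] object for the homogeneous parameters.
#' @param axes Optional list of [hetAxis()] overriding `grid$axes`.
#' @param Iapp Homogeneous applied current used when no axis targets
#'   `Iapp`.
#' @return A `neuronTable` with one row per grid node; the standard-space
#'   node coordinates are kept in `attr(, "coords")`.
#' @export
gridToParameters <- function(grid, base = modelParams(), axes = NULL,
                             Iapp = 0) {
  stopifnot(inherits(grid, "paramGrid"))
  if (is.null(axes)) axes <- grid$axes
  if (is.null(axes))
    stop("grid carries no axes; supply them via the axes argument")
  if (length(axes) != ncol(grid$nodes))
    stop("number of axes must match grid dimension")
  nms <- vapply(axes, `[[`, character(1), "param")
  if (anyDuplicated(nms))
    stop("duplicate parameter names across axes: ",
         paste(nms[duplicated(nms)], collapse = ", "))
  tab <- neuronTable(base, Iapp = Iapp, weights = grid$weights,
                     coords = grid$nodes)
  for (d in seq_along(axes))
    tab[[nms[d]]] <- axes[[d]]$location + axes[[d]]$scale * grid$nodes[, d]
  tab
}

#' Collocation table for one heterogeneous applied current
#'
#' Convenience wrapper for the workhorse configuration: applied currents
#' `Iapp = Im + Is * mu` with `mu` at the nodes of a rule on \[-1, 1\]
#' (uniform heterogeneity), all other parameters homogeneous.
#'
#' @param rule A [quadRule][legendreRule] on the uniform density.
#' @param Im Mean applied current.
#' @param Is Heterogeneity spread (half-width of the current range).
#' @param params Homogeneous [modelParams()].
#' @return A `neuronTable`.
#' @examples
#' tab <- collocationTable(legendreRule(10), Im = 17.5, Is = 7.5)
#' range(tab$Iapp)
#' @export
collocationTable <- function(rule, Im, Is, params = modelParams()) {
  grid <- tensorGrid(list(hetAxis("Iapp", Im, Is, rule)))
  gridToParameters(grid, params)
}

#' Export / import a collocation grid
#'
#' `writeGrid` serializes a grid as a plain CSV (one row per node:
#' coordinates `x1..xD` and `weight`) plus a JSON sidecar
#' (`<path>.json`) with provenance and axis metadata, so a run can be
#' reproduced from its files alone.  `readGrid` reconstructs the
#' `paramGrid`, rebuilding axis quadrature rules from their recorded
#' kind, size, density and seed.
#'
#' @param grid A `paramGrid`.
#' @param path CSV file path (the sidecar gets `.json` appended).
#' @return `writeGrid` returns `path` invisibly; `readGrid` a
#'   `paramGrid`.
#' @export
writeGrid <- function(grid, path) {
  stopifnot(inherits(grid, "paramGrid"))
  df <- as.data.frame(grid$nodes)
  names(df) <- paste0("x", seq_len(ncol(grid$nodes)))
  df$weight <- grid$weights
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(provenance = grid$provenance,
               axes = if (!is.null(grid$axes))
                 lapply(grid$axes, function(a)
                   list(param = a$param, location = a$location,
                        scale = a$scale, kind = a$rule$kind, n = a$rule$n,
                        density = a$rule$density, seed = a$rule$seed)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.ruleFromMeta <- function(m) {
  switch(m$kind,
         gauss_legendre = legendreRule(m$n),
         midpoint = midpointRule(m$n),
         gauss_hermite = hermiteRule(m$n),
         inverse_cdf = inverseCdfRule(m$n, m$density),
         monte_carlo = monteCarloRule(m$n, m$density, seed = m$seed),
         stop("unknown rule kind in grid metadata: ", m$kind))
}

#' @rdname writeGrid
#' @export
readGrid <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE)
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  axes <- if (!is.null(meta$axes) && length(meta$axes))
    lapply(meta$axes, function(m)
      hetAxis(m$param, m$location, m$scale, .ruleFromMeta(m)))
  .newParamGrid(as.matrix(df[xcols]), df$weight, meta$provenance, axes)
}
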