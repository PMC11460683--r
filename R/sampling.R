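#' Set of sampled flux vectors
#'
#' @slot samples numeric matrix (samples x reactions).
#' @slot seed integer seed used.
#' @slot growthFloor biomass lower bound applied.
#' @slot thin thinning interval (steps between recorded samples).
#' @slot ranges data.frame of per-reaction empirical min/max.
#' @slot converged logical (split-chain diagnostic passed).
#' @export
setClass("SampleSet",
  representation(samples = "matrix", seed = "numeric",
                 growthFloor = "numeric", thin = "numeric",
                 ranges = "data.frame", converged = "logical"))

setMethod("show", "SampleSet", function(object) {
  cat("SampleSet:", nrow(object@samples), "samples x",
      ncol(object@samples), "reactions (seed", object@seed,
      if (object@converged) ", converged" else ", NOT converged", ")\n")
})

#' Uniform flux sampling by artificial-centering hit-and-run
#'
#' Samples the growth-constrained flux polytope \eqn{\{v : S v = 0,
#' lb \le v \le ub, v_{bio} \ge floor\}} with an artificial-centering
#' hit-and-run chain started from flux-variability warm-up points. Directions
#' are differences of stored points (hence stay in the null space of S);
#' samples are validated against flux variability ranges and a split-chain
#' convergence diagnostic is run.
#'
#' @param net a \code{\link{MetabolicNetwork}}.
#' @param n number of samples.
#' @param growthFloor biomass lower bound (default 0.1 1/h).
#' @param seed integer RNG seed (reproducible sampling).
#' @param thin steps between recorded samples.
#' @param warmupPerReaction logical; use all 2n FVA vertices as warm-up
#'   points (otherwise a capped subset).
#' @return a \code{\link{SampleSet}}; non-convergence is a warning, not an
#'   error.
#' @export
sampleFluxes <- function(net, n = 1000, growthFloor = 0.1, seed = 1,
                         thin = 100, warmupPerReaction = TRUE) {
  S <- stoichiometry(net)
  nr <- ncol(S)
  lb <- lowerBounds(net); ub <- upperBounds(net)
  bioJ <- match(biomassId(net), reactionIds(net))
  lb[bioJ] <- max(lb[bioJ], growthFloor)
  if (lb[bioJ] > ub[bioJ]) stop("infeasible polytope: growth floor above biomass bound")

  ## warm-up points: FVA vertices (also used for validation)
  net2 <- net
  net2@lowerBounds <- lb; net2@upperBounds <- ub
  fvaTab <- fluxVariability(net2, growthFloor = 0)
  pts <- .fvaVertices(net2)
  if (nrow(pts) < 2) stop("could not build warm-up points")

  set.seed(as.integer(seed))
  res <- .achr(pts, lb, ub, S, n, thin)
  samples <- res$samples
  colnames(samples) <- reactionIds(net)

  ## validity: all samples inside FVA ranges
  tolV <- 1e-6
  inside <- TRUE
  for (j in seq_len(nr)) {
    if (any(samples[, j] < fvaTab$min[j] - tolV) ||
        any(samples[, j] > fvaTab$max[j] + tolV)) inside <- FALSE
  }
  if (!inside) warning("some samples fall outside the FVA ranges")

  conv <- tryCatch(checkConvergence(samples), error = function(e) NULL)
  converged <- !is.null(conv) && isTRUE(conv$pass)
  if (!converged) warning("convergence diagnostic not passed; ",
                          "samples returned with warning status")
  ranges <- data.frame(reaction = reactionIds(net),
                       min = apply(samples, 2, min),
                       max = apply(samples, 2, max))
  new("SampleSet", samples = samples, seed = seed,
      growthFloor = growthFloor, thin = thin, ranges = ranges,
      converged = converged)
}

.fvaVertices <- function(net) {
  S <- stoichiometry(net)
  nr <- ncol(S)
  lb <- lowerBounds(net); ub <- upperBounds(net)
  pts <- list()
  for (j in seq_len(nr)) {
    obj <- numeric(nr); obj[j] <- 1
    for (mx in c(FALSE, TRUE)) {
      sol <- solveLp(obj, S, rep("==", nrow(S)), rep(0, nrow(S)), lb, ub,
                     maximize = mx)
      if (sol$status == "optimal") pts[[length(pts) + 1L]] <- sol$x
    }
  }
  do.call(rbind, pts)
}

## artificial-centering hit-and-run on {Sv=0, lb<=v<=ub}; warm-up points must
## satisfy the constraints; directions are differences of points, projected
## onto the null space of S every step so numerical drift cannot accumulate
.achr <- function(pts, lb, ub, S, n, thin) {
  nr <- ncol(pts)
  pts <- unique(pts)
  center <- colMeans(pts)
  npts <- nrow(pts)
  ## orthonormal basis of the row space of S (for null-space projection);
  ## pinned coordinates (lb = ub) are held fixed by treating their unit
  ## vectors as additional equality rows
  pinned <- which(ub - lb < 1e-9)
  Srows <- S
  if (length(pinned)) Srows <- rbind(S, diag(nr)[pinned, , drop = FALSE])
  sv <- svd(t(Srows))
  r <- sum(sv$d > max(dim(Srows)) * max(sv$d, 0) * 1e-12)
  V <- sv$u[, seq_len(r), drop = FALSE]
  projectNull <- function(v) v - V %*% crossprod(V, v)
  ## warm-up points are LP-feasible; only directions need projecting
  x <- pts[sample.int(npts, 1), ]
  x[pinned] <- (lb[pinned] + ub[pinned]) / 2
  samples <- matrix(0, n, nr)
  maxStored <- 2000L
  stored <- matrix(0, maxStored, nr)
  stored[seq_len(npts), ] <- pts
  nstored <- npts
  tolD <- 1e-8
  scale <- max(1, max(abs(pts)))
  got <- 0L; step <- 0L
  while (got < n) {
    step <- step + 1L
    d <- stored[sample.int(nstored, 1), ] - center
    d <- as.vector(projectNull(d))
    nd <- sqrt(sum(d^2))
    if (nd < tolD * scale) next
    d <- d / nd
    ## line limits from bounds
    tmax <- Inf; tmin <- -Inf
    posd <- d > tolD; negd <- d < -tolD
    if (any(posd)) {
      tmax <- min(tmax, min((ub[posd] - x[posd]) / d[posd]))
      tmin <- max(tmin, max((lb[posd] - x[posd]) / d[posd]))
    }
    if (any(negd)) {
      tmax <- min(tmax, min((lb[negd] - x[negd]) / d[negd]))
      tmin <- max(tmin, max((ub[negd] - x[negd]) / d[negd]))
    }
    if (!is.finite(tmax) || !is.finite(tmin) || tmax - tmin < tolD) next
    tmin <- min(tmin, 0); tmax <- max(tmax, 0)  # current point is feasible
    t <- stats::runif(1, tmin, tmax)
    x <- x + t * d
    center <- center + (x - center) / (nstored + 1)
    if (nstored < maxStored) {
      nstored <- nstored + 1L
      stored[nstored, ] <- x
    } else {
      stored[sample.int(nstored, 1), ] <- x
    }
    if (step %% thin == 0L) {
      got <- got + 1L
      samples[got, ] <- x
    }
  }
  list(samples = samples)
}

#' Sample fluxes restricted to one minimal pathway
#'
#' Fixes all subnetwork items outside the pathway to zero, requires a small
#' activity floor on the pathway's items, and samples the restricted
#' polytope. Every sample's subnetwork sign pattern then equals the pathway.
#'
#' @param std a \code{\link{StandardizedNetwork}}.
#' @param mp integer vector of item indices (one pattern from an MP
#'   collection) or a single-pattern \code{\link{PatternCollection}} row.
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @param growthFloor biomass lower bound.
#' @param eps activity floor on pathway items.
#' @param thin thinning interval.
#' @return a \code{\link{SampleSet}} over the original reactions.
#' @export
samplePerPathway <- function(std, mp, n = 1000, seed = 1,
                             growthFloor = 1e-4, eps = 1e-6, thin = 100) {
  net <- std@base
  items <- std@items
  if (is(mp, "PatternCollection")) {
    if (length(mp@patterns) != 1) stop("pass a single pattern")
    mp <- mp@patterns[[1]]
  }
  itemRxn <- std@originIndex[items$stdColumn]
  itemDir <- std@originDir[items$stdColumn]
  lb <- lowerBounds(net); ub <- upperBounds(net)
  outside <- setdiff(which(!items$isBiomass), mp)
  for (k in outside) {
    j <- itemRxn[k]
    if (itemDir[k] == "forward") ub[j] <- min(ub[j], 0)
    else lb[j] <- max(lb[j], 0)
  }
  for (k in setdiff(mp, which(items$isBiomass))) {
    j <- itemRxn[k]
    if (itemDir[k] == "forward") lb[j] <- max(lb[j], eps)
    else ub[j] <- min(ub[j], -eps)
  }
  if (any(lb > ub))
    stop("restricted polytope infeasible: pathway invalid at this growth floor")
  net2 <- net
  net2@lowerBounds <- lb; net2@upperBounds <- ub
  sampleFluxes(net2, n = n, growthFloor = growthFloor, seed = seed,
               thin = thin)
}

#' Split-chain convergence diagnostic
#'
#' Splits each reaction's sample series in half and computes the potential
#' scale reduction statistic; the diagnostic passes when every reaction's
#' statistic is at most the threshold.
#'
#' @param samples a \code{\link{SampleSet}} or a samples matrix.
#' @param threshold pass threshold (default 1.05).
#' @return list with \code{rhat} (named vector) and \code{pass} (logical).
#' @export
checkConvergence <- function(samples, threshold = 1.05) {
  M <- if (is(samples, "SampleSet")) samples@samples else as.matrix(samples)
  n <- nrow(M)
  if (n < 100) stop("too few samples for a convergence diagnostic (< 100)")
  half <- floor(n / 2)
  rhat <- vapply(seq_len(ncol(M)), function(j) {
    a <- M[seq_len(half), j]; b <- M[seq(half + 1, 2 * half), j]
    W <- (stats::var(a) + stats::var(b)) / 2
    B <- half * (mean(a) - mean(b))^2 / 2  # 2 chains: n * var of chain means
    if (W < 1e-12) return(1)               # constant (pinned) coordinate
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  names(rhat) <- colnames(M)
  list(rhat = rhat, pass = all(rhat <= threshold))
}
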