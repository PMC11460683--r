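## Independent brute-force oracles for the enumerative stages. These share no
## code with the double description / projection / search implementations:
## supports are tested by floating-point nullspace computations (SVD) and
## exhaustive subset enumeration, so agreement with the main path is a
## meaningful cross-check.

#' Brute-force minimal-support oracle (elementary flux modes)
#'
#' Enumerates every support of the standardized (all-irreversible) flux cone
#' that carries exactly one nullspace direction with all entries nonzero and
#' of one sign - the supports of the elementary flux modes. Futile
#' forward/backward two-cycle supports of split reversible reactions are
#' excluded.
#'
#' @param std a \code{\link{StandardizedNetwork}} (or integer matrix) with at
#'   most 18 standardized reactions.
#' @return list of integer support vectors (sorted), in lexicographic order.
#' @export
oracleMinimalSupports <- function(std) {
  Sstd <- if (is(std, "StandardizedNetwork")) std@Sstd else as.matrix(std)
  n <- ncol(Sstd)
  if (n > 18) stop("size guard exceeded: more than 18 standardized reactions")
  origin <- if (is(std, "StandardizedNetwork")) std@originIndex else seq_len(n)
  found <- list()
  for (size in seq_len(n)) {
    combs <- utils::combn(n, size)
    for (ci in seq_len(ncol(combs))) {
      T <- combs[, ci]
      ## skip supersets of already-found supports
      skip <- FALSE
      for (f in found) if (all(f %in% T)) { skip <- TRUE; break }
      if (skip) next
      A <- Sstd[, T, drop = FALSE]
      sv <- svd(A, nu = 0, nv = length(T))
      tolr <- max(dim(A)) * max(sv$d, 0) * 1e-10
      nullDim <- length(T) - sum(sv$d >= tolr)
      if (nullDim != 1) next
      v <- sv$v[, length(T)]
      if (any(abs(v) < 1e-8)) next          # not full support
      if (!(all(v > 0) || all(v < 0))) next # not sign-consistent
      ## exclude futile split two-cycles (collapse to zero original flux)
      if (size == 2 && origin[T[1]] == origin[T[2]]) next
      found[[length(found) + 1L]] <- T
    }
  }
  found[order(vapply(found, function(p)
    paste(sprintf("%05d", p), collapse = ","), character(1)))]
}

#' Exhaustive-subset LP oracle (minimal pathways)
#'
#' Enumerates, by exhaustive ascending-size subset search with an LP
#' feasibility test, all minimal subsets of the subnetwork items admitting a
#' feasible flux with biomass at least the growth floor.
#'
#' @param std a \code{\link{StandardizedNetwork}} with at most 14
#'   (non-biomass) subnetwork items.
#' @param growthFloor biomass lower bound.
#' @param homogeneousBounds as in \code{\link{enumerateMps}}.
#' @return list of sorted integer item vectors (each including the biomass
#'   item), in lexicographic order.
#' @export
oracleMinimalFeasibleSubsets <- function(std, growthFloor = 1e-4,
                                         homogeneousBounds = TRUE) {
  net <- std@base
  items <- std@items
  itemIdx <- which(!items$isBiomass)
  if (length(itemIdx) > 14) stop("size guard exceeded: more than 14 items")
  bioPos <- which(items$isBiomass)
  S <- stoichiometry(net)
  lb0 <- lowerBounds(net); ub0 <- upperBounds(net)
  if (homogeneousBounds) {
    lb0 <- ifelse(lb0 < 0, -Inf, 0)
    ub0 <- ifelse(ub0 > 0, Inf, 0)
  }
  bioJ <- match(biomassId(net), reactionIds(net))
  lb0[bioJ] <- max(lb0[bioJ], growthFloor)
  itemRxn <- std@originIndex[items$stdColumn]
  itemDir <- std@originDir[items$stdColumn]
  feas <- function(allowed) {
    lb <- lb0; ub <- ub0
    for (k in setdiff(itemIdx, allowed)) {
      j <- itemRxn[k]
      if (itemDir[k] == "forward") ub[j] <- min(ub[j], 0)
      else lb[j] <- max(lb[j], 0)
    }
    if (any(lb > ub)) return(FALSE)
    solveLp(numeric(ncol(S)), S, rep("==", nrow(S)), rep(0, nrow(S)),
            lb, ub)$status == "optimal"
  }
  found <- list()
  for (size in 0:length(itemIdx)) {
    combs <- if (size == 0) matrix(integer(), 0, 1)
             else utils::combn(itemIdx, size)
    for (ci in seq_len(ncol(combs))) {
      T <- if (size == 0) integer() else combs[, ci]
      skip <- FALSE
      for (f in found) if (all(f %in% T)) { skip <- TRUE; break }
      if (skip) next
      if (feas(T)) found[[length(found) + 1L]] <- T
    }
  }
  pats <- lapply(found, function(T) sort(c(T, bioPos)))
  pats[order(vapply(pats, function(p)
    paste(sprintf("%05d", p), collapse = ","), character(1)))]
}

#' Exhaustive union-closure oracle (elementary flux patterns)
#'
#' @param patterns list of sorted integer item vectors (a complete unique
#'   pattern family).
#' @return the sublist of patterns that are not equal to the union of their
#'   proper sub-patterns.
#' @export
oracleElementaryPatterns <- function(patterns) {
  if (length(patterns) > 2^14) stop("size guard exceeded")
  keep <- logical(length(patterns))
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    u <- integer()
    for (j in seq_along(patterns)) {
      if (i == j) next
      q <- patterns[[j]]
      if (length(q) < length(p) && all(q %in% p)) u <- union(u, q)
    }
    keep[i] <- !setequal(u, p)
  }
  patterns[keep]
}
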