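#' Enumerate minimal pathways
#'
#' A minimal pathway (MP) is a minimal set of subnetwork items (exchange
#' reactions split by direction) that must carry nonzero flux for the full
#' network's constraints - steady state, flux bounds, and a biomass growth
#' floor - to be satisfiable. Enumeration alternates feasibility LPs with a
#' systematic exclusion search: each feasible candidate is shrunk to a
#' minimal set by greedy single-item removal with LP re-checks, and the
#' search branches on excluding each item of every minimal set found, which
#' guarantees completeness (any other MP misses at least one item of each
#' found MP, so it survives along some branch).
#'
#' @param std a \code{\link{StandardizedNetwork}}.
#' @param growthFloor minimum biomass flux (default 1e-4 1/h).
#' @param tol activity threshold for declaring an item active in an LP
#'   witness.
#' @param eps minimum active flux enforced when verifying a minimal set.
#' @param homogeneousBounds logical (default TRUE): relax flux-bound
#'   magnitudes to pure direction constraints (reversibility) before adding
#'   the growth floor, so that MPs are enumerated under the same homogeneous
#'   constraints as the flux cone behind EFMs/ECMs/EFPs and the pattern
#'   hierarchy is checked under equivalent conditions. Set FALSE to honor
#'   the model's inhomogeneous bounds (e.g. ATP maintenance floors).
#' @param maxNodes search-node ceiling (abort rather than silently truncate).
#' @return a \code{\link{PatternCollection}} with definition "MP"; every
#'   pattern carries the (always active) biomass item and is
#'   growth-supporting by construction. If the growth floor itself is
#'   infeasible the collection is empty.
#' @export
enumerateMps <- function(std, growthFloor = 1e-4, tol = 1e-6, eps = 1e-8,
                         homogeneousBounds = TRUE, maxNodes = 1e5) {
  net <- std@base
  S <- stoichiometry(net)
  m <- nrow(S); n <- ncol(S)
  dirs <- rep("==", m); rhs <- rep(0, m)
  lb0 <- lowerBounds(net); ub0 <- upperBounds(net)
  if (homogeneousBounds) {
    lb0 <- ifelse(lb0 < 0, -Inf, 0)
    ub0 <- ifelse(ub0 > 0, Inf, 0)
  }
  bioJ <- match(biomassId(net), reactionIds(net))
  lb0[bioJ] <- max(lb0[bioJ], growthFloor)

  items <- std@items
  itemIdx <- which(!items$isBiomass)     # excludable items
  itemRxn <- std@originIndex[items$stdColumn]
  itemDir <- std@originDir[items$stdColumn]
  bioPos <- which(items$isBiomass)

  applyZeros <- function(zeros) {
    lb <- lb0; ub <- ub0
    for (k in zeros) {
      j <- itemRxn[k]
      if (itemDir[k] == "forward") ub[j] <- min(ub[j], 0)
      else lb[j] <- max(lb[j], 0)
    }
    list(lb = lb, ub = ub)
  }
  feasible <- function(zeros) {
    b <- applyZeros(zeros)
    if (any(b$lb > b$ub)) return(NULL)
    sol <- solveLp(numeric(n), S, dirs, rhs, b$lb, b$ub)
    if (sol$status == "infeasible") return(NULL)
    if (sol$status != "optimal") stop("solver failure: ", sol$status)
    sol$x
  }
  activeItems <- function(v) {
    act <- logical(nrow(items))
    for (k in seq_len(nrow(items))) {
      j <- itemRxn[k]
      act[k] <- if (itemDir[k] == "forward") v[j] > tol else v[j] < -tol
    }
    which(act & !items$isBiomass)
  }
  ## verify that every item of K can be simultaneously active (flux >= eps)
  verify <- function(K, zeros) {
    b <- applyZeros(union(zeros, setdiff(itemIdx, K)))
    for (k in K) {
      j <- itemRxn[k]
      if (itemDir[k] == "forward") b$lb[j] <- max(b$lb[j], eps)
      else b$ub[j] <- min(b$ub[j], -eps)
    }
    if (any(b$lb > b$ub)) return(FALSE)
    sol <- solveLp(numeric(n), S, dirs, rhs, b$lb, b$ub)
    sol$status == "optimal"
  }
  shrink <- function(start, zeros) {
    K <- sort(start)
    for (k in K) {
      if (!k %in% K) next
      v <- feasible(union(zeros, union(setdiff(itemIdx, K), k)))
      if (!is.null(v)) K <- intersect(K, activeItems(v))
    }
    if (!verify(K, zeros)) {
      ## fall back: minimality by explicit per-item removal from all items
      K <- setdiff(itemIdx, zeros)
      v <- feasible(union(zeros, setdiff(itemIdx, K)))
      K <- activeItems(v)
      for (k in sort(K)) {
        if (!k %in% K) next
        v <- feasible(union(zeros, union(setdiff(itemIdx, K), k)))
        if (!is.null(v)) K <- intersect(K, activeItems(v))
      }
    }
    sort(K)
  }

  found <- new.env(hash = TRUE)
  mps <- list()
  visited <- new.env(hash = TRUE)
  nodes <- 0L
  recurse <- function(zeros) {
    key <- paste0("z", paste(sort(zeros), collapse = ","))
    if (!is.null(visited[[key]])) return(invisible())
    visited[[key]] <- TRUE
    nodes <<- nodes + 1L
    if (nodes > maxNodes)
      stop("MP search-node ceiling exceeded (", length(mps),
           " minimal pathways found so far)", call. = FALSE)
    v <- feasible(zeros)
    if (is.null(v)) return(invisible())
    M <- shrink(activeItems(v), zeros)
    mkey <- paste0("m", paste(M, collapse = ","))
    if (is.null(found[[mkey]])) {
      found[[mkey]] <- TRUE
      mps[[length(mps) + 1L]] <<- M
    }
    for (k in M) recurse(c(zeros, k))
    invisible()
  }
  recurse(integer())

  pats <- lapply(mps, function(M) sort(c(M, bioPos)))
  ord <- order(vapply(pats, function(p) paste(sprintf("%05d", p), collapse = ","),
                      character(1)))
  new("PatternCollection", definition = "MP", items = items,
      patterns = pats[ord], growth = rep(TRUE, length(pats)),
      provenance = paste0("mp;floor=", growthFloor))
}
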