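#' Polyhedral cone in halfspace description
#'
#' Represents the cone \eqn{\{x \ge 0 : A x = 0, B x \ge 0\}} with exact
#' integer coefficients (rows are scaled to primitive integer vectors).
#' Nonnegativity of every coordinate is implicit.
#'
#' @slot eq integer-valued equality matrix (possibly 0 rows).
#' @slot ineq integer-valued extra-inequality matrix (possibly 0 rows).
#' @slot n number of coordinates.
#' @slot coordIds coordinate labels.
#' @export
setClass("ConeH",
  representation(eq = "matrix", ineq = "matrix", n = "numeric",
                 coordIds = "character"))

setValidity("ConeH", function(object) {
  msg <- character()
  if (object@n < 1) msg <- c(msg, "n must be >= 1")
  if (nrow(object@eq) && ncol(object@eq) != object@n)
    msg <- c(msg, "equality matrix width mismatch")
  if (nrow(object@ineq) && ncol(object@ineq) != object@n)
    msg <- c(msg, "inequality matrix width mismatch")
  if (length(object@coordIds) != object@n)
    msg <- c(msg, "coordinate labels must match n")
  if (length(msg)) msg else TRUE
})

#' @rdname ConeH-class
#' @param eq,ineq numeric matrices (rows = constraints); rationalized to
#'   integers internally.
#' @param n number of coordinates (defaults to matrix width).
#' @param coordIds coordinate labels.
#' @export
coneH <- function(eq = NULL, ineq = NULL, n = NULL, coordIds = NULL) {
  if (is.null(eq) && is.null(ineq) && is.null(n))
    stop("specify at least the dimension")
  width <- if (!is.null(eq)) ncol(eq) else if (!is.null(ineq)) ncol(ineq) else n
  if (is.null(n)) n <- width
  if (is.null(eq)) eq <- matrix(0, 0, n)
  if (is.null(ineq)) ineq <- matrix(0, 0, n)
  eq <- .integerizeRows(as.matrix(eq))
  ineq <- .integerizeRows(as.matrix(ineq))
  if (is.null(coordIds)) {
    coordIds <- colnames(eq)
    if (is.null(coordIds)) coordIds <- colnames(ineq)
    if (is.null(coordIds)) coordIds <- paste0("x", seq_len(n))
  }
  ## drop all-zero rows
  if (nrow(eq)) eq <- eq[rowSums(eq != 0) > 0, , drop = FALSE]
  if (nrow(ineq)) ineq <- ineq[rowSums(ineq != 0) > 0, , drop = FALSE]
  new("ConeH", eq = eq, ineq = ineq, n = n, coordIds = as.character(coordIds))
}

setMethod("show", "ConeH", function(object) {
  cat("ConeH: ", object@n, " nonnegative coordinates, ",
      nrow(object@eq), " equalities, ", nrow(object@ineq),
      " extra inequalities\n", sep = "")
})

## order rows deterministically: increasing nonzero count, ties by first
## nonzero position then lexicographically
.rowOrder <- function(M) {
  if (!nrow(M)) return(integer())
  nz <- rowSums(M != 0)
  first <- apply(M != 0, 1, function(r) if (any(r)) which(r)[1] else 0L)
  do.call(order, c(list(nz, first), lapply(seq_len(ncol(M)), function(j) M[, j])))
}

#' Enumerate the extreme rays of a pointed cone (double description)
#'
#' Processes equality rows (sorted by increasing nonzero count) and then any
#' extra inequality rows against the nonnegative orthant, maintaining the
#' exact extreme-ray set. All arithmetic is exact (integer); output rays are
#' primitive integer vectors in deterministic lexicographic order, so the
#' result is invariant to the input row order.
#'
#' @param cone a \code{\link{ConeH}}.
#' @param maxRays abort (with an error identifying the partial progress) if
#'   the intermediate ray count exceeds this ceiling.
#' @return a \code{\link{RaySet}}.
#' @export
doubleDescription <- function(cone, maxRays = 2e6) {
  validObject(cone)
  eq <- cone@eq; ineq <- cone@ineq
  if (nrow(eq)) eq <- eq[.rowOrder(eq), , drop = FALSE]
  if (nrow(ineq)) ineq <- ineq[.rowOrder(ineq), , drop = FALSE]
  cons <- rbind(eq, ineq)
  isEq <- c(rep(1L, nrow(eq)), rep(0L, nrow(ineq)))
  if (!nrow(cons)) {
    R <- diag(cone@n)
  } else {
    res <- .ddCore(cons, isEq, as.integer(cone@n), maxRays)
    if (isTRUE(res$truncated))
      stop("ray ceiling (", maxRays, ") exceeded after ",
           nrow(res$rays), " rays; increase maxRays or reduce the network",
           call. = FALSE)
    R <- res$rays
  }
  R <- .sortRaysLex(R)
  new("RaySet", raysInt = R, coordIds = cone@coordIds)
}

## deterministic lexicographic order on canonical (first-nonzero = 1) rays
.sortRaysLex <- function(R) {
  if (!nrow(R)) return(R)
  C <- R
  for (i in seq_len(nrow(C))) {
    nz <- which(C[i, ] != 0)
    if (length(nz)) C[i, ] <- C[i, ] / C[i, nz[1L]]
  }
  R[do.call(order, lapply(seq_len(ncol(C)), function(j) C[, j])), , drop = FALSE]
}

#' Project a cone onto a coordinate subset
#'
#' Computes an exact halfspace description of
#' \eqn{\{x_{keep} : \exists x_{drop} \ge 0,\; A x = 0,\; B x \ge 0\}}.
#' Variables are eliminated by Gaussian substitution where an equality allows
#' it and by Fourier-Motzkin combination otherwise; after each elimination
#' redundant inequalities are removed with an exact Farkas-certificate LP so
#' the description stays small.
#'
#' @param cone a \code{\link{ConeH}}.
#' @param keep coordinate indices (or labels) to keep.
#' @param redundancy logical; prune redundant inequalities by LP.
#' @return a \code{\link{ConeH}} over the kept coordinates (in increasing
#'   index order).
#' @export
projectCone <- function(cone, keep, redundancy = TRUE) {
  validObject(cone)
  if (is.character(keep)) keep <- match(keep, cone@coordIds)
  keep <- sort(unique(as.integer(keep)))
  if (!length(keep) || anyNA(keep) || any(keep < 1 | keep > cone@n))
    stop("keep must be a nonempty subset of coordinates")
  n <- cone@n
  drop <- setdiff(seq_len(n), keep)

  eq <- cone@eq
  ## inequality system includes a nonnegativity row for every coordinate
  ineq <- rbind(diag(n), cone@ineq)

  ## Phase A: eliminate dropped variables via equalities (substitution)
  remaining <- drop
  for (iter in seq_along(drop)) {
    if (!nrow(eq) || !length(remaining)) break
    cand <- which(colSums(eq[, remaining, drop = FALSE] != 0) > 0)
    if (!length(cand)) break
    ## choose (variable, pivot row) minimizing fill: fewest nonzeros in row
    best <- NULL
    for (d in remaining[cand]) {
      rows <- which(eq[, d] != 0)
      r <- rows[which.min(rowSums(eq[rows, , drop = FALSE] != 0))]
      sc <- sum(eq[r, ] != 0)
      if (is.null(best) || sc < best$sc) best <- list(d = d, r = r, sc = sc)
    }
    d <- best$d; r <- best$r
    piv <- eq[r, ]
    a <- piv[d]; sa <- sign(a); aa <- abs(a)
    elim <- function(M) {
      if (!nrow(M)) return(M)
      hit <- which(M[, d] != 0)
      for (i in hit) {
        M[i, ] <- .checkOverflow(aa * M[i, ] - (M[i, d] * sa) * piv)
        M[i, ] <- .primitive(M[i, ])
      }
      M
    }
    eq <- elim(eq[-r, , drop = FALSE])
    ineq <- elim(ineq)
    remaining <- setdiff(remaining, d)
    ineq <- .dedupeRows(ineq)
  }
  if (redundancy) ineq <- .pruneRedundant(ineq, eq, setdiff(seq_len(n), drop[!drop %in% remaining]))

  ## Phase B: Fourier-Motzkin on the remaining dropped variables
  active <- setdiff(seq_len(n), setdiff(drop, remaining))
  while (length(remaining)) {
    counts <- vapply(remaining, function(d) {
      s <- sign(ineq[, d])
      sum(s > 0) * sum(s < 0)
    }, numeric(1))
    d <- remaining[which.min(counts)]
    s <- sign(ineq[, d])
    P <- which(s > 0); N <- which(s < 0); Z <- which(s == 0)
    newRows <- ineq[Z, , drop = FALSE]
    if (length(P) && length(N)) {
      combos <- vector("list", length(P) * length(N))
      k <- 0L
      for (p in P) for (q in N) {
        k <- k + 1L
        row <- .checkOverflow((-ineq[q, d]) * ineq[p, ] + ineq[p, d] * ineq[q, ])
        combos[[k]] <- .primitive(row)
      }
      newRows <- rbind(newRows, do.call(rbind, combos))
    }
    ineq <- .dedupeRows(newRows)
    remaining <- setdiff(remaining, d)
    active <- setdiff(active, d)
    if (redundancy) ineq <- .pruneRedundant(ineq, eq, active)
  }

  ## restrict to kept coordinates
  eqK <- eq[, keep, drop = FALSE]
  inK <- ineq[, keep, drop = FALSE]
  ## drop rows that merely restate nonnegativity of a kept coordinate
  unitLike <- apply(inK, 1, function(r) sum(r != 0) == 1 && r[r != 0] > 0)
  inK <- inK[!unitLike, , drop = FALSE]
  coneH(eq = eqK, ineq = inK, n = length(keep),
        coordIds = cone@coordIds[keep])
}

.dedupeRows <- function(M) {
  if (!nrow(M)) return(M)
  M <- M[rowSums(M != 0) > 0, , drop = FALSE]
  if (!nrow(M)) return(M)
  keys <- apply(M, 1, paste, collapse = ",")
  M[!duplicated(keys), , drop = FALSE]
}

## Farkas-certificate redundancy pruning: inequality d is implied by the rest
## iff d = t(Drest) lambda + t(E) mu with lambda >= 0. Rows are tested (and
## possibly removed) one at a time, so the surviving system stays equivalent.
.pruneRedundant <- function(ineq, eq, activeCols) {
  if (nrow(ineq) <= 1) return(ineq)
  i <- 1L
  while (i <= nrow(ineq)) {
    d <- ineq[i, activeCols]
    rest <- ineq[-i, activeCols, drop = FALSE]
    E <- if (nrow(eq)) eq[, activeCols, drop = FALSE] else NULL
    nl <- nrow(rest); nm <- if (is.null(E)) 0L else nrow(E)
    A <- t(rest)
    if (nm) A <- cbind(A, t(E))
    sol <- solveLp(numeric(nl + nm), A,
                   rep("==", length(activeCols)), d,
                   lb = c(rep(0, nl), rep(-Inf, nm)), ub = Inf)
    if (sol$status == "optimal") {
      ineq <- ineq[-i, , drop = FALSE]
    } else {
      i <- i + 1L
    }
  }
  ineq
}
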