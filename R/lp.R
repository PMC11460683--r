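## Dense two-phase primal simplex.
##
## The enumeration and sampling machinery needs many small-to-medium dense LPs
## (feasibility witnesses, Farkas certificates for redundancy removal, FVA).
## All problems here are dense and have at most a few hundred variables, so a
## tableau simplex with Dantzig pricing and a Bland anti-cycling fallback is
## simple, dependency-free and fast enough.

#' Solve a linear program
#'
#' Minimizes (or maximizes) \code{obj \%*\% x} subject to general linear
#' constraints \code{A x (<=, >=, ==) rhs} and variable bounds
#' \code{lb <= x <= ub}. Bounds may be infinite.
#'
#' @param obj numeric objective vector.
#' @param A constraint matrix (may have zero rows).
#' @param dir character vector of constraint directions, one of
#'   \code{"<="}, \code{">="}, \code{"=="}.
#' @param rhs numeric right-hand side.
#' @param lb,ub numeric bounds, recycled to the number of variables.
#' @param maximize logical; maximize instead of minimize.
#' @param tol numeric pivot/feasibility tolerance.
#' @param useCpp logical; use the compiled simplex core (default). The pure-R
#'   core remains available for cross-checking.
#' @return list with elements \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}, \code{"maxit"}),
#'   \code{objval}, and \code{x} (primal solution on the original scale).
#' @export
solveLp <- function(obj, A, dir, rhs, lb = 0, ub = Inf,
                    maximize = FALSE, tol = 1e-9, useCpp = TRUE) {
  n <- length(obj)
  if (is.null(A)) A <- matrix(0, 0L, n)
  A <- as.matrix(A)
  stopifnot(ncol(A) == n, nrow(A) == length(rhs), nrow(A) == length(dir))
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }
  c0 <- if (maximize) -obj else obj

  ## Shift / split variables so every variable is nonnegative.
  ## x_i = lb_i + y_i            when lb_i finite
  ## x_i = ub_i - y_i            when lb_i = -Inf, ub_i finite
  ## x_i = y_i^+ - y_i^-         when both infinite
  map <- vector("list", n)
  cols <- list(); ccols <- numeric(0)
  shift <- numeric(n)
  k <- 0L
  for (i in seq_len(n)) {
    ai <- A[, i]
    if (is.finite(lb[i])) {
      k <- k + 1L; cols[[k]] <- ai; ccols[k] <- c0[i]
      map[[i]] <- c(k, 1); shift[i] <- lb[i]
    } else if (is.finite(ub[i])) {
      k <- k + 1L; cols[[k]] <- -ai; ccols[k] <- -c0[i]
      map[[i]] <- c(k, -1); shift[i] <- ub[i]
    } else {
      k <- k + 1L; cols[[k]] <- ai; ccols[k] <- c0[i]
      k <- k + 1L; cols[[k]] <- -ai; ccols[k] <- -c0[i]
      map[[i]] <- c(k - 1L, 1); shift[i] <- 0
    }
  }
  Ay <- if (k) do.call(cbind, cols) else matrix(0, nrow(A), 0L)
  by <- rhs - as.vector(A %*% shift)

  ## Upper bounds on shifted variables become explicit rows.
  extraA <- list(); extraB <- numeric(0); extraD <- character(0)
  for (i in seq_len(n)) {
    rng <- ub[i] - lb[i]
    if (is.finite(rng)) {
      row <- numeric(k); row[map[[i]][1]] <- 1
      extraA[[length(extraA) + 1L]] <- row
      extraB <- c(extraB, rng); extraD <- c(extraD, "<=")
    }
  }
  if (length(extraA)) {
    Ay <- rbind(Ay, do.call(rbind, extraA))
    by <- c(by, extraB)
    dir <- c(dir, extraD)
  }

  ## Slack/surplus to reach standard equality form.
  m <- nrow(Ay)
  slackCols <- list()
  for (r in seq_len(m)) {
    if (dir[r] == "<=") {
      col <- numeric(m); col[r] <- 1; slackCols[[length(slackCols) + 1L]] <- col
    } else if (dir[r] == ">=") {
      col <- numeric(m); col[r] <- -1; slackCols[[length(slackCols) + 1L]] <- col
    } else if (dir[r] != "==") stop("bad constraint direction: ", dir[r])
  }
  Sm <- if (length(slackCols)) do.call(cbind, slackCols) else NULL
  Afull <- if (is.null(Sm)) Ay else cbind(Ay, Sm)
  cfull <- c(ccols, rep(0, if (is.null(Sm)) 0L else ncol(Sm)))

  res <- if (useCpp) .simplexCore(cfull, Afull, by, tol = tol)
         else .simplexStandard(cfull, Afull, by, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objval = NA_real_, x = rep(NA_real_, n)))
  }
  x <- shift
  for (i in seq_len(n)) {
    mi <- map[[i]]
    if (mi[2] == 1 && !is.finite(lb[i]) && !is.finite(ub[i])) {
      x[i] <- res$x[mi[1]] - res$x[mi[1] + 1L]
    } else {
      x[i] <- shift[i] + mi[2] * res$x[mi[1]]
    }
  }
  objval <- sum(obj * x)
  list(status = "optimal", objval = objval, x = x)
}

## min c'x s.t. Ax = b, x >= 0 (dense two-phase tableau simplex)
.simplexStandard <- function(cvec, A, b, tol = 1e-9, maxit = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (is.null(maxit)) maxit <- max(2000L, 50L * (m + n))
  if (m == 0L) {
    if (any(cvec < -tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = rep(0, n), objval = 0))
  }
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  ## Phase 1: artificial basis.
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  redc <- c(-colSums(A), rep(0, m), -sum(b))  # row of (c_j - z_j), value = -obj

  pivot <- function(tab, redc, pr, pc) {
    pv <- tab[pr, pc]
    tab[pr, ] <- tab[pr, ] / pv
    fac <- tab[, pc]; fac[pr] <- 0
    tab <- tab - outer(fac, tab[pr, ])
    redc <- redc - redc[pc] * tab[pr, ]
    list(tab = tab, redc = redc)
  }

  runPhase <- function(tab, redc, basis, allowed, maxit) {
    it <- 0L; bland <- FALSE; stall <- 0L; lastObj <- redc[length(redc)]
    nc <- ncol(tab)
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(status = "maxit"))
      rc <- redc[seq_len(nc - 1L)]
      cand <- which(allowed & rc < -tol)
      if (!length(cand)) {
        return(list(status = "optimal", tab = tab, redc = redc, basis = basis))
      }
      pc <- if (bland) cand[1L] else cand[which.min(rc[cand])]
      colv <- tab[, pc]
      pos <- which(colv > tol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratio <- tab[pos, nc] / colv[pos]
      pr <- pos[which(ratio <= min(ratio) + tol)]
      pr <- if (bland) pr[which.min(basis[pr])] else pr[which.max(colv[pr])]
      pp <- pivot(tab, redc, pr, pc)
      tab <- pp$tab; redc <- pp$redc
      basis[pr] <- pc
      obj <- redc[nc]
      if (abs(obj - lastObj) < tol) stall <- stall + 1L else stall <- 0L
      lastObj <- obj
      if (stall > 2L * (nrow(tab) + nc)) bland <- TRUE
    }
  }

  allowed1 <- rep(TRUE, n + m); # artificials may re-enter in phase 1 only
  ph1 <- runPhase(tab, redc, basis, allowed1, maxit)
  if (ph1$status != "optimal") return(list(status = ph1$status))
  tab <- ph1$tab; redc <- ph1$redc; basis <- ph1$basis
  if (-redc[ncol(tab)] > 1e-7) return(list(status = "infeasible"))

  ## Drive artificials out of the basis (or drop redundant rows).
  keep <- rep(TRUE, m)
  for (r in seq_len(m)) {
    if (basis[r] > n) {
      cand <- which(abs(tab[r, seq_len(n)]) > tol)
      if (length(cand)) {
        pp <- pivot(tab, redc, r, cand[1L])
        tab <- pp$tab; redc <- pp$redc
        basis[r] <- cand[1L]
      } else keep[r] <- FALSE
    }
  }
  if (!all(keep)) {
    tab <- tab[keep, , drop = FALSE]
    basis <- basis[keep]
    m <- nrow(tab)
  }
  tab <- tab[, c(seq_len(n), n + m + seq_len(0L), ncol(tab)), drop = FALSE]
  tab <- tab[, c(seq_len(n), ncol(tab)), drop = FALSE]

  ## Phase 2 reduced costs for the true objective.
  cB <- cvec[basis]
  redc <- c(cvec - as.vector(cB %*% tab[, seq_len(n), drop = FALSE]),
            -sum(cB * tab[, n + 1L]))
  ph2 <- runPhase(tab, redc, basis, rep(TRUE, n), maxit)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  tab <- ph2$tab; basis <- ph2$basis
  x <- numeric(n)
  x[basis] <- tab[, ncol(tab)]
  list(status = "optimal", x = x, objval = sum(cvec * x))
}
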