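#' Standardize a network to all-irreversible form and select a subnetwork
#'
#' Re-encodes a metabolic network so that every reaction is irreversible with
#' nonnegative flux: irreversible reactions that only admit negative flux are
#' direction-flipped, and every reversible reaction is split into a forward
#' and a backward part (for boundary reactions this distinguishes export from
#' import). The analysis subnetwork is then selected: the split boundary
#' reactions (mode \code{"boundary"}), additionally the member-to-shared
#' compartment transfer reactions of a community model
#' (\code{"boundary_plus_intermicrobial"}), or an explicit reaction list. The
#' biomass reaction is always appended to the subnetwork so growth support is
#' visible in flux patterns.
#'
#' @param net a \code{\link{MetabolicNetwork}}.
#' @param subnetworkMode subnetwork selection mode.
#' @param subnetworkReactions reaction ids for \code{subnetworkMode =
#'   "explicit"}.
#' @return a \code{\link{StandardizedNetwork}}.
#' @export
standardize <- function(net,
                        subnetworkMode = c("boundary",
                                           "boundary_plus_intermicrobial",
                                           "explicit"),
                        subnetworkReactions = NULL) {
  subnetworkMode <- match.arg(subnetworkMode)
  validObject(net)
  if (any(lowerBounds(net) > upperBounds(net)))
    stop("reaction with lower bound above upper bound")
  Sint <- .integerizeRows(stoichiometry(net))
  n <- length(reactionIds(net))
  lb <- lowerBounds(net); ub <- upperBounds(net)
  rev <- reversible(net)

  cols <- list(); ids <- character(); oi <- integer(); od <- character()
  for (j in seq_len(n)) {
    id <- reactionIds(net)[j]
    if (rev[j]) {
      cols[[length(cols) + 1L]] <- Sint[, j]
      ids <- c(ids, id); oi <- c(oi, j); od <- c(od, "forward")
      cols[[length(cols) + 1L]] <- -Sint[, j]
      ids <- c(ids, paste0(id, "__rev")); oi <- c(oi, j); od <- c(od, "backward")
    } else if (ub[j] <= 0) {
      ## only negative flux allowed: flip direction
      cols[[length(cols) + 1L]] <- -Sint[, j]
      ids <- c(ids, paste0(id, "__rev")); oi <- c(oi, j); od <- c(od, "backward")
    } else {
      cols[[length(cols) + 1L]] <- Sint[, j]
      ids <- c(ids, id); oi <- c(oi, j); od <- c(od, "forward")
    }
  }
  Sstd <- do.call(cbind, cols)
  rownames(Sstd) <- metaboliteIds(net); colnames(Sstd) <- ids

  boundarySet <- boundaryReactions(net)
  sub <- switch(subnetworkMode,
    boundary = which(oi %in% boundarySet),
    boundary_plus_intermicrobial = {
      transfer <- .transferReactions(net)
      which(oi %in% c(boundarySet, transfer))
    },
    explicit = {
      if (is.null(subnetworkReactions)) stop("subnetworkReactions required")
      jx <- match(subnetworkReactions, reactionIds(net))
      if (anyNA(jx)) stop("unknown subnetwork reactions: ",
                          paste(subnetworkReactions[is.na(jx)], collapse = ", "))
      which(oi %in% jx)
    })
  bioJ <- match(biomassId(net), reactionIds(net))
  bioCol <- which(oi == bioJ & od == "forward")
  if (!length(bioCol)) stop("biomass reaction admits no forward flux")
  if (!bioCol %in% sub) sub <- c(sub, bioCol)
  sub <- sort(unique(sub))
  if (!length(sub)) stop("empty subnetwork")

  items <- .describeItems(net, Sstd, oi, od, sub, bioJ)
  new("StandardizedNetwork", base = net, Sstd = Sstd, stdIds = ids,
      originIndex = as.integer(oi), originDir = od,
      subnetwork = as.integer(sub), items = items,
      biomassIndex = as.integer(bioCol))
}

## community transfer reactions: non-boundary reactions of a member that touch
## a shared-compartment metabolite
.transferReactions <- function(net) {
  comps <- net@compartments
  shared <- names(comps)[comps == "shared"]
  if (!length(shared)) return(integer())
  S <- stoichiometry(net)
  mem <- net@reactionMember
  touches <- colSums(S[shared, , drop = FALSE] != 0) > 0
  cand <- which(touches & !(seq_len(ncol(S)) %in% boundaryReactions(net)))
  if (length(mem) == ncol(S)) cand <- cand[mem[cand] != ""]
  cand
}

.describeItems <- function(net, Sstd, oi, od, sub, bioJ) {
  S <- stoichiometry(net)
  comps <- net@compartments
  mem <- net@reactionMember
  sharedMets <- if (length(comps)) names(comps)[comps == "shared"] else character()
  entity <- character(length(sub)); direction <- character(length(sub))
  boundarySet <- boundaryReactions(net)
  for (k in seq_along(sub)) {
    c0 <- sub[k]; j <- oi[c0]
    nzMets <- rownames(Sstd)[Sstd[, c0] != 0]
    if (j %in% boundarySet) {
      met <- nzMets[1L]
      entity[k] <- met
      direction[k] <- if (Sstd[met, c0] < 0) "export" else "import"
    } else if (length(mem) == ncol(S) && j != bioJ && mem[j] != "" &&
               any(nzMets %in% sharedMets)) {
      sharedMet <- nzMets[nzMets %in% sharedMets][1L]
      memMet <- nzMets[!nzMets %in% sharedMets][1L]
      entity[k] <- paste0(mem[j], ":", sub("__shared$", "", sharedMet))
      direction[k] <- if (Sstd[memMet, c0] < 0) "export" else "import"
    } else {
      entity[k] <- reactionIds(net)[j]
      direction[k] <- if (od[c0] == "forward") "export" else "import"
    }
  }
  data.frame(entity = entity, direction = direction,
             stdColumn = sub,
             isBiomass = oi[sub] == bioJ & od[sub] == "forward",
             stringsAsFactors = FALSE)
}

#' Collapse a standardized flux vector back to original reaction coordinates
#'
#' @param std a \code{StandardizedNetwork}.
#' @param x numeric vector (or matrix with one row per vector) over
#'   standardized columns.
#' @return numeric vector/matrix over original reactions
#'   (forward minus backward parts).
#' @export
collapseStd <- function(std, x) {
  n <- length(reactionIds(std@base))
  sgn <- ifelse(std@originDir == "forward", 1, -1)
  M <- matrix(0, ncol(std@Sstd), n)
  M[cbind(seq_along(std@originIndex), std@originIndex)] <- sgn
  if (is.matrix(x)) {
    out <- x %*% M
    colnames(out) <- reactionIds(std@base)
    out
  } else {
    out <- as.vector(x %*% M)
    names(out) <- reactionIds(std@base)
    out
  }
}
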