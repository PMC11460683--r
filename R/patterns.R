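#' Convert subnetwork flux vectors to unique flux patterns
#'
#' A flux pattern is the set of active (entity, direction) items of a flux
#' vector over the (all-irreversible, hence nonnegative) subnetwork
#' coordinates: zero entries are dropped, duplicates removed, and the growth
#' flag is set from the biomass item.
#'
#' @param vectors numeric matrix, one flux vector per row, columns = the
#'   subnetwork coordinates of \code{std}.
#' @param std the \code{\link{StandardizedNetwork}} defining the items.
#' @param definition pattern-collection label ("EFM", "ECM", "EFP" or "MP").
#' @param tol activity threshold (0 for exact integer rays, 1e-6 for LP
#'   witnesses).
#' @param provenance character label recorded in the collection.
#' @return a \code{\link{PatternCollection}}.
#' @export
toPatterns <- function(vectors, std, definition = "EFM", tol = 0,
                       provenance = "") {
  items <- std@items
  if (ncol(vectors) != nrow(items))
    stop("vector dimension does not match the subnetwork")
  bioPos <- which(items$isBiomass)
  pats <- list(); growth <- logical(); seen <- new.env(hash = TRUE)
  for (i in seq_len(nrow(vectors))) {
    p <- unname(which(vectors[i, ] > tol))
    key <- paste0("p", paste(p, collapse = ","))
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      pats[[length(pats) + 1L]] <- p
      growth <- c(growth, length(bioPos) > 0 && bioPos %in% p)
    }
  }
  ord <- order(vapply(pats, function(p) paste(sprintf("%05d", p), collapse = ","),
                      character(1)))
  new("PatternCollection", definition = definition, items = items,
      patterns = pats[ord], growth = growth[ord], provenance = provenance)
}

#' Keep only growth-supporting patterns
#'
#' @param coll a \code{\link{PatternCollection}}.
#' @return the filtered collection (patterns with positive biomass flux).
#' @export
filterGrowth <- function(coll) {
  keep <- coll@growth
  initialize(coll, patterns = coll@patterns[keep],
             growth = coll@growth[keep])
}

#' Extract elementary flux patterns by union closure
#'
#' A pattern is elementary if it cannot be written as the cancellation-free
#' union of other patterns in the collection: pattern \eqn{p} is kept iff the
#' union of all patterns that are proper subsets of \eqn{p} differs from
#' \eqn{p}. The input must be the complete unique pattern set of the EFMs or
#' ECMs of the subnetwork.
#'
#' @param coll a \code{\link{PatternCollection}} (definition EFM or ECM).
#' @return a \code{\link{PatternCollection}} with definition "EFP".
#' @export
extractEfps <- function(coll) {
  pats <- coll@patterns
  np <- length(pats)
  ni <- nrow(coll@items)
  if (!np)
    return(initialize(coll, definition = "EFP"))
  M <- matrix(FALSE, np, ni)
  for (i in seq_len(np)) M[i, pats[[i]]] <- TRUE
  sizes <- rowSums(M)
  cross <- (M * 1) %*% t(M * 1)          # cross[q,p] = |q intersect p|
  keep <- logical(np)
  for (p in seq_len(np)) {
    subs <- which(cross[, p] == sizes & sizes < sizes[p])
    u <- which(colSums(M[subs, , drop = FALSE]) > 0)
    keep[p] <- !identical(as.integer(u), as.integer(pats[[p]]))
  }
  initialize(coll, definition = "EFP", patterns = pats[keep],
             growth = coll@growth[keep])
}
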