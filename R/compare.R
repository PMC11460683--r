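#' Compare pattern collections across pathway definitions
#'
#' Computes per-pattern lengths, cross-definition subset/superset counts
#' (how many MPs are subsets of each pattern; how many EFM/ECM patterns are
#' supersets), Venn overlap sizes, and the hierarchy verdict.
#'
#' @param colls named list of \code{\link{PatternCollection}} objects (names
#'   among "EFM", "ECM", "EFP", "MP"); all must share the same item universe
#'   and provenance footing (model, subnetwork, growth filtering).
#' @return list with elements \code{lengths} (list of integer vectors),
#'   \code{subsetCounts} and \code{supersetCounts} (lists of named count
#'   vectors per definition pair), \code{venn} (overlap sizes for every
#'   definition pair), \code{hierarchy} (verdict from
#'   \code{\link{verifyHierarchy}}), and \code{shortest} (the minimum-length
#'   pattern keys per definition).
#' @export
compareCollections <- function(colls) {
  stopifnot(length(colls) >= 1, !is.null(names(colls)))
  ni <- vapply(colls, function(cl) nrow(cl@items), numeric(1))
  if (length(unique(ni)) != 1)
    stop("collections have mismatched item universes")
  keys <- lapply(colls, patternKeys)
  mats <- lapply(colls, .patternMatrix)

  lengths <- lapply(colls, function(cl)
    vapply(cl@patterns, length, integer(1)))

  pairSubsetCounts <- function(a, b) {
    ## for each pattern of a: number of patterns of b that are subsets of it
    if (!nrow(mats[[a]]) || !nrow(mats[[b]])) {
      return(rep(0L, nrow(mats[[a]])))
    }
    cross <- (mats[[b]] * 1) %*% t(mats[[a]] * 1)
    sizesB <- rowSums(mats[[b]])
    vapply(seq_len(nrow(mats[[a]])), function(p)
      sum(cross[, p] == sizesB), integer(1))
  }

  defs <- names(colls)
  subsetCounts <- list(); supersetCounts <- list()
  if ("MP" %in% defs) {
    for (d in setdiff(defs, "MP")) {
      subsetCounts[[paste0("MP_in_", d)]] <- pairSubsetCounts(d, "MP")
    }
  }
  for (big in intersect(c("EFM", "ECM"), defs)) {
    for (d in setdiff(defs, big)) {
      ## supersets: patterns of `big` that contain each pattern of d
      if (nrow(mats[[big]]) && nrow(mats[[d]])) {
        cross <- (mats[[d]] * 1) %*% t(mats[[big]] * 1)
        sizesD <- rowSums(mats[[d]])
        supersetCounts[[paste0(big, "_over_", d)]] <-
          vapply(seq_len(nrow(mats[[d]])), function(p)
            sum(cross[p, ] == sizesD[p]), integer(1))
      }
    }
  }

  venn <- list()
  if (length(defs) > 1) {
    for (i in seq_len(length(defs) - 1)) {
      for (j in seq(i + 1, length(defs))) {
        venn[[paste(defs[i], defs[j], sep = "&")]] <-
          length(intersect(keys[[defs[i]]], keys[[defs[j]]]))
      }
    }
  }

  shortest <- lapply(defs, function(d) {
    ln <- lengths[[d]]
    if (!length(ln)) return(character())
    keys[[d]][ln == min(ln)]
  })
  names(shortest) <- defs

  list(lengths = lengths,
       subsetCounts = subsetCounts,
       supersetCounts = supersetCounts,
       venn = venn,
       hierarchy = verifyHierarchy(colls),
       shortest = shortest)
}

.patternMatrix <- function(coll) {
  np <- length(coll@patterns); ni <- nrow(coll@items)
  M <- matrix(FALSE, np, ni)
  for (i in seq_len(np)) M[i, coll@patterns[[i]]] <- TRUE
  M
}

#' Verify the hierarchy of pattern sets across pathway definitions
#'
#' Checks the chain of inclusions MP patterns within EFP patterns within ECM
#' patterns within EFM patterns over the definitions present (missing tiers
#' are skipped), and whether all present tiers are equal (which happens when
#' every pattern is support-minimal).
#'
#' @param colls named list of \code{\link{PatternCollection}} objects.
#' @return list with \code{holds} (logical), \code{equal} (logical),
#'   \code{links} (per-inclusion verdicts), and \code{witnesses} (offending
#'   pattern keys per violated link).
#' @export
verifyHierarchy <- function(colls) {
  order <- c("MP", "EFP", "ECM", "EFM")
  present <- order[order %in% names(colls)]
  keys <- lapply(colls[present], patternKeys)
  links <- list(); witnesses <- list()
  if (length(present) > 1) {
    for (i in seq_len(length(present) - 1)) {
      a <- present[i]; b <- present[i + 1]
      miss <- setdiff(keys[[a]], keys[[b]])
      links[[paste(a, "subsetOf", b)]] <- length(miss) == 0
      if (length(miss)) witnesses[[paste(a, "notIn", b)]] <- miss
    }
  }
  equal <- length(present) > 1 &&
    all(vapply(keys, function(k)
      setequal(k, keys[[1]]), logical(1)))
  list(holds = all(unlist(links)) || length(links) == 0,
       equal = isTRUE(equal),
       links = links,
       witnesses = witnesses)
}
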