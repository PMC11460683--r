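#' Metabolite exchange frequencies
#'
#' The fraction of patterns in a collection that include each
#' (entity, direction) item of the subnetwork universe. A frequency of one
#' means the exchange is essential (present in every pathway); zero entries
#' are listed explicitly.
#'
#' @param coll a nonempty \code{\link{PatternCollection}}.
#' @return data.frame (entity, direction, count, frequency) with attributes
#'   \code{denominator} and \code{definition}.
#' @export
exchangeFrequency <- function(coll) {
  np <- length(coll@patterns)
  if (!np) stop("empty pattern collection")
  counts <- integer(nrow(coll@items))
  for (p in coll@patterns) counts[p] <- counts[p] + 1L
  out <- data.frame(entity = coll@items$entity,
                    direction = coll@items$direction,
                    count = counts,
                    frequency = counts / np,
                    stringsAsFactors = FALSE)
  attr(out, "denominator") <- np
  attr(out, "definition") <- coll@definition
  out
}

#' Difference between two frequency tables
#'
#' @param a,b frequency tables from \code{\link{exchangeFrequency}} over the
#'   same item universe.
#' @return data.frame (entity, direction, difference, percentagePoints)
#'   sorted by decreasing absolute difference.
#' @export
frequencyDifference <- function(a, b) {
  if (!identical(paste(a$entity, a$direction),
                 paste(b$entity, b$direction)))
    stop("frequency tables have mismatched item universes")
  d <- a$frequency - b$frequency
  out <- data.frame(entity = a$entity, direction = a$direction,
                    difference = d,
                    percentagePoints = round(100 * d, 1),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$difference)), ]
}

#' Pairwise exchange frequencies
#'
#' Fraction of patterns containing each pair of items; the diagonal equals
#' the marginal exchange frequency.
#'
#' @param coll a nonempty \code{\link{PatternCollection}}.
#' @return symmetric numeric matrix over items (labelled entity:direction).
#' @export
pairwiseFrequency <- function(coll) {
  np <- length(coll@patterns)
  if (!np) stop("empty pattern collection")
  M <- .patternMatrix(coll) * 1
  P <- t(M) %*% M / np
  lab <- paste(coll@items$entity, coll@items$direction, sep = ":")
  dimnames(P) <- list(lab, lab)
  P
}

#' Producer-consumer interaction frequencies in a community
#'
#' For each (producer member, consumer member, metabolite) triple, the
#' fraction of patterns in which the metabolite is exported by the producer
#' and imported by the consumer through the shared compartment.
#'
#' @param coll a \code{\link{PatternCollection}} from a community model
#'   (member-qualified entities of the form "member:metabolite").
#' @param includeZeros also list triples with frequency zero.
#' @return data.frame (producer, consumer, metabolite, count, frequency).
#' @export
interactionFrequency <- function(coll, includeZeros = FALSE) {
  np <- length(coll@patterns)
  if (!np) stop("empty pattern collection")
  qual <- grepl(":", coll@items$entity, fixed = TRUE)
  if (!any(qual))
    stop("not a community collection: no member-qualified entities")
  member <- sub(":.*$", "", coll@items$entity)
  met <- sub("^[^:]*:", "", coll@items$entity)
  members <- unique(member[qual])
  mets <- unique(met[qual])
  key <- function(p, c, m) paste(p, c, m, sep = "\r")
  counts <- new.env(hash = TRUE)
  for (p in coll@patterns) {
    act <- coll@items[p, , drop = FALSE]
    aq <- grepl(":", act$entity, fixed = TRUE)
    am <- sub(":.*$", "", act$entity)
    amet <- sub("^[^:]*:", "", act$entity)
    for (mt in unique(amet[aq])) {
      prod <- am[aq & amet == mt & act$direction == "export"]
      cons <- am[aq & amet == mt & act$direction == "import"]
      for (pr in prod) for (cn in cons) {
        if (pr == cn) next
        k <- key(pr, cn, mt)
        counts[[k]] <- if (is.null(counts[[k]])) 1L else counts[[k]] + 1L
      }
    }
  }
  rows <- list()
  for (pr in members) for (cn in members) for (mt in mets) {
    if (pr == cn) next
    k <- key(pr, cn, mt)
    cnt <- if (is.null(counts[[k]])) 0L else counts[[k]]
    if (cnt > 0L || includeZeros)
      rows[[length(rows) + 1L]] <- data.frame(
        producer = pr, consumer = cn, metabolite = mt,
        count = cnt, frequency = cnt / np, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(producer = character(), consumer = character(),
                      metabolite = character(), count = integer(),
                      frequency = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$producer, out$consumer, out$metabolite), ]
}
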