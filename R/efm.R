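#' Set of elementary flux modes
#'
#' @slot raysStd integer-valued matrix of extreme rays of the standardized
#'   (all-irreversible) flux cone, one per row, futile split two-cycles
#'   removed. Both orientations of a fully reversible mode appear.
#' @slot efms numeric matrix of EFMs over the original reactions, one
#'   orientation per reversible mode (canonical: first nonzero positive).
#' @slot count number of EFMs under the native-reversibility convention.
#' @export
setClass("EfmSet",
  representation(raysStd = "matrix", efms = "matrix", count = "numeric"))

setMethod("show", "EfmSet", function(object) {
  cat("EfmSet:", object@count, "EFMs (",
      nrow(object@raysStd), "standardized rays )\n")
})

#' Enumerate elementary flux modes
#'
#' Runs the double description method on the standardized flux cone
#' \eqn{\{x \ge 0 : S_{std} x = 0\}}. Futile forward/backward two-cycles
#' created by splitting reversible reactions are removed, and mirror-image
#' orientations of fully reversible modes are merged (canonical orientation)
#' for the native EFM count.
#'
#' @param std a \code{\link{StandardizedNetwork}}.
#' @param maxRays ray-count ceiling (abort, never silent truncation).
#' @return an \code{\link{EfmSet}}.
#' @export
enumerateEfms <- function(std, maxRays = 2e6) {
  cone <- coneH(eq = std@Sstd, coordIds = std@stdIds)
  rs <- doubleDescription(cone, maxRays = maxRays)
  R <- rs@raysInt
  if (nrow(R)) {
    collapsed <- collapseStd(std, R)
    futile <- rowSums(collapsed != 0) == 0
    R <- R[!futile, , drop = FALSE]
    collapsed <- collapsed[!futile, , drop = FALSE]
  } else collapsed <- matrix(0, 0, length(reactionIds(std@base)))
  ## native-reversibility convention: a fully reversible mode appears as a
  ## mirror pair of standardized rays and is counted once in canonical
  ## orientation (first nonzero entry positive); modes using an irreversible
  ## reaction keep their (unique feasible) orientation
  if (nrow(collapsed)) {
    rev <- reversible(std@base)
    for (i in seq_len(nrow(collapsed))) {
      fullyRev <- all(rev[collapsed[i, ] != 0])
      collapsed[i, ] <- .primitive(collapsed[i, ], signNormalize = fullyRev)
    }
    keys <- apply(collapsed, 1, paste, collapse = ",")
    efms <- collapsed[!duplicated(keys), , drop = FALSE]
  } else efms <- collapsed
  colnames(efms) <- reactionIds(std@base)
  new("EfmSet", raysStd = R, efms = efms, count = nrow(efms))
}

#' Restrict elementary flux modes to the subnetwork
#'
#' Truncates each standardized ray to the subnetwork coordinates. Order is
#' preserved and duplicates are retained (deduplication happens at the
#' pattern level).
#'
#' @param efms an \code{\link{EfmSet}}.
#' @param std the \code{\link{StandardizedNetwork}} the EFMs came from.
#' @return numeric matrix (rays x subnetwork coordinates).
#' @export
restrictToSubnetwork <- function(efms, std) {
  M <- efms@raysStd[, std@subnetwork, drop = FALSE]
  colnames(M) <- paste(std@items$entity, std@items$direction, sep = ":")
  M
}
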