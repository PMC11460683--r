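#' Set of elementary conversion modes
#'
#' @slot raySet \code{\link{RaySet}} over the subnetwork coordinates.
#' @slot conversions numeric matrix (rays x exchanged metabolites) of net
#'   conversions: negative = import/consumption, positive = export/production.
#' @slot count number of (unique) ECMs.
#' @export
setClass("EcmSet",
  representation(raySet = "RaySet", conversions = "matrix", count = "numeric"))

setMethod("show", "EcmSet", function(object) {
  cat("EcmSet:", object@count, "ECMs over",
      length(object@raySet@coordIds), "subnetwork coordinates\n")
})

#' Enumerate elementary conversion modes
#'
#' ECMs are the extreme rays of the projection of the standardized flux cone
#' onto the subnetwork: the cone is projected exactly (Gaussian elimination
#' plus Fourier-Motzkin with LP redundancy removal) and the projection's
#' extreme rays are enumerated by double description. Rays are deduplicated
#' by canonical form and returned in deterministic order; net metabolite
#' conversions are computed from the original boundary stoichiometry.
#'
#' @param std a \code{\link{StandardizedNetwork}}.
#' @param maxRays ray-count ceiling.
#' @return an \code{\link{EcmSet}}.
#' @export
enumerateEcms <- function(std, maxRays = 2e6) {
  cone <- coneH(eq = std@Sstd, coordIds = std@stdIds)
  proj <- projectCone(cone, keep = std@subnetwork)
  rs <- doubleDescription(proj, maxRays = maxRays)
  ## drop futile two-cycles (simultaneous import/export of one exchange,
  ## zero net conversion): their support is the split column pair of one
  ## original reaction
  origin <- std@originIndex[std@subnetwork]
  R <- rs@raysInt
  if (nrow(R)) {
    futile <- apply(R, 1, function(r) {
      s <- which(r != 0)
      length(s) == 2 && origin[s[1]] == origin[s[2]]
    })
    R <- R[!futile, , drop = FALSE]
  }
  rs <- new("RaySet", raysInt = R, coordIds = rs@coordIds)
  conv <- .conversionsFromRays(std, R)
  new("EcmSet", raySet = rs, conversions = conv, count = nrow(R))
}

## net conversions over exchanged metabolites: for a boundary reaction with
## coefficient c on its metabolite, forward flux x contributes -c*x
## (export positive) and the backward split contributes +c*x
.conversionsFromRays <- function(std, R) {
  net <- std@base
  S <- stoichiometry(net)
  items <- std@items
  boundarySet <- boundaryReactions(net)
  ents <- unique(items$entity)
  conv <- matrix(0, nrow(R), length(ents), dimnames = list(NULL, ents))
  for (k in seq_len(nrow(items))) {
    c0 <- items$stdColumn[k]
    j <- std@originIndex[c0]
    if (!(j %in% boundarySet)) next
    met <- items$entity[k]
    coef <- S[met, j]
    sgn <- if (std@originDir[c0] == "forward") -1 else 1
    conv[, met] <- conv[, met] + sgn * coef * R[, std@subnetwork == c0]
  }
  conv
}

#' Summarize metabolite usage across conversion-cone rays
#'
#' @param ecms an \code{\link{EcmSet}}.
#' @return data.frame (metabolite, direction, rays) counting, per metabolite
#'   and direction, the number of rays using that exchange; directions never
#'   used are absent.
#' @export
conversionConeSummary <- function(ecms) {
  conv <- ecms@conversions
  if (!nrow(conv)) stop("empty ECM set")
  out <- list()
  for (met in colnames(conv)) {
    nImp <- sum(conv[, met] < 0)
    nExp <- sum(conv[, met] > 0)
    if (nImp) out[[length(out) + 1L]] <-
      data.frame(metabolite = met, direction = "import", rays = nImp)
    if (nExp) out[[length(out) + 1L]] <-
      data.frame(metabolite = met, direction = "export", rays = nExp)
  }
  if (!length(out))
    return(data.frame(metabolite = character(), direction = character(),
                      rays = integer()))
  do.call(rbind, out)
}
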