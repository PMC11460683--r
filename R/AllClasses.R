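#' Constraint-based metabolic network
#'
#' Holds the stoichiometric matrix of a constraint-based model together with
#' flux bounds, the set of boundary (exchange) reactions, and a designated
#' biomass reaction. Boundary reactions are reactions with exactly one nonzero
#' stoichiometric coefficient; for a boundary reaction written \code{met ->}
#' (coefficient -1), positive flux is export/secretion and negative flux is
#' import/uptake.
#'
#' For community models built with \code{\link{mergeCommunity}}, the
#' \code{reactionMember} and \code{metaboliteMember} slots record which member
#' each reaction/metabolite belongs to (\code{""} for shared or environmental
#' entities).
#'
#' @slot metaboliteIds character vector of unique metabolite identifiers.
#' @slot reactionIds character vector of unique reaction identifiers.
#' @slot S numeric m x n stoichiometric matrix.
#' @slot lowerBounds,upperBounds numeric flux bounds per reaction
#'   (1/h for biomass, mmol/gDW/h otherwise; units are not enforced).
#' @slot boundary integer indices of boundary reactions.
#' @slot biomassId identifier of the biomass reaction.
#' @slot compartments named character vector mapping metabolites to
#'   compartment labels (may be empty).
#' @slot reactionMember,metaboliteMember named character vectors giving the
#'   community member of each reaction/metabolite ("" outside communities).
#' @aliases stoichiometry metaboliteIds reactionIds lowerBounds upperBounds
#'   reversible boundaryReactions biomassId
#' @export
setClass("MetabolicNetwork",
  representation(
    metaboliteIds = "character",
    reactionIds = "character",
    S = "matrix",
    lowerBounds = "numeric",
    upperBounds = "numeric",
    boundary = "integer",
    biomassId = "character",
    compartments = "character",
    reactionMember = "character",
    metaboliteMember = "character"
  ),
  prototype(compartments = character(), reactionMember = character(),
            metaboliteMember = character())
)

setValidity("MetabolicNetwork", function(object) {
  msg <- character()
  m <- length(object@metaboliteIds); n <- length(object@reactionIds)
  if (anyDuplicated(object@metaboliteIds)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(object@reactionIds)) msg <- c(msg, "duplicate reaction ids")
  if (!all(dim(object@S) == c(m, n)))
    msg <- c(msg, sprintf("S must be %d x %d", m, n))
  if (length(object@lowerBounds) != n || length(object@upperBounds) != n)
    msg <- c(msg, "bounds must have one entry per reaction")
  if (any(object@lowerBounds > object@upperBounds))
    msg <- c(msg, "lower bound exceeds upper bound")
  if (length(object@biomassId) != 1 || !(object@biomassId %in% object@reactionIds))
    msg <- c(msg, "biomassId must name one reaction")
  if (length(object@boundary)) {
    nzero <- colSums(object@S[, object@boundary, drop = FALSE] != 0)
    if (any(nzero != 1))
      msg <- c(msg, "boundary reactions must touch exactly one metabolite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MetabolicNetwork
#'
#' @param S stoichiometric matrix (metabolites x reactions); dimnames are
#'   used as identifiers when \code{metaboliteIds}/\code{reactionIds} are
#'   missing.
#' @param lowerBounds,upperBounds numeric flux bounds.
#' @param biomassId identifier (or NULL to auto-detect by the patterns
#'   "biomass"/"^BIO" in reaction ids).
#' @param metaboliteIds,reactionIds identifier vectors.
#' @param compartments optional named character vector (metabolite ->
#'   compartment).
#' @param reactionMember,metaboliteMember optional member labels for
#'   community models.
#' @return a validated \code{MetabolicNetwork}; the boundary set is
#'   auto-detected as the reactions with exactly one nonzero coefficient.
#' @export
MetabolicNetwork <- function(S, lowerBounds, upperBounds, biomassId = NULL,
                             metaboliteIds = rownames(S),
                             reactionIds = colnames(S),
                             compartments = character(),
                             reactionMember = character(),
                             metaboliteMember = character()) {
  S <- as.matrix(S)
  if (is.null(metaboliteIds) || is.null(reactionIds))
    stop("metabolite and reaction identifiers are required")
  dimnames(S) <- list(metaboliteIds, reactionIds)
  if (is.null(biomassId)) {
    cand <- grep("biomass|^BIO|growth", reactionIds, ignore.case = TRUE, value = TRUE)
    if (!length(cand))
      stop("no biomass reaction candidate found; supply biomassId")
    biomassId <- cand[1L]
  }
  boundary <- which(colSums(S != 0) == 1L)
  new("MetabolicNetwork",
      metaboliteIds = as.character(metaboliteIds),
      reactionIds = as.character(reactionIds),
      S = S,
      lowerBounds = as.numeric(lowerBounds),
      upperBounds = as.numeric(upperBounds),
      boundary = as.integer(boundary),
      biomassId = biomassId,
      compartments = compartments,
      reactionMember = reactionMember,
      metaboliteMember = metaboliteMember)
}

#' @rdname MetabolicNetwork-class
#' @export
setMethod("stoichiometry", "MetabolicNetwork", function(object) object@S)
#' @rdname MetabolicNetwork-class
#' @export
setMethod("metaboliteIds", "MetabolicNetwork", function(object) object@metaboliteIds)
#' @rdname MetabolicNetwork-class
#' @export
setMethod("reactionIds", "MetabolicNetwork", function(object) object@reactionIds)
#' @rdname MetabolicNetwork-class
#' @export
setMethod("lowerBounds", "MetabolicNetwork", function(object) object@lowerBounds)
#' @rdname MetabolicNetwork-class
#' @export
setMethod("upperBounds", "MetabolicNetwork", function(object) object@upperBounds)
#' @rdname MetabolicNetwork-class
#' @export
setMethod("reversible", "MetabolicNetwork", function(object)
  object@lowerBounds < 0 & object@upperBounds > 0)
#' @rdname MetabolicNetwork-class
#' @export
setMethod("boundaryReactions", "MetabolicNetwork", function(object) object@boundary)
#' @rdname MetabolicNetwork-class
#' @export
setMethod("biomassId", "MetabolicNetwork", function(object) object@biomassId)

setMethod("show", "MetabolicNetwork", function(object) {
  cat("MetabolicNetwork:", length(object@metaboliteIds), "metabolites,",
      length(object@reactionIds), "reactions (",
      length(object@boundary), "boundary,",
      sum(reversible(object)), "reversible )\n")
  cat("  biomass:", object@biomassId, "\n")
  if (length(unique(object@reactionMember[object@reactionMember != ""])))
    cat("  community members:",
        paste(unique(object@reactionMember[object@reactionMember != ""]),
              collapse = ", "), "\n")
})

#' All-irreversible re-encoding of a metabolic network
#'
#' Every reversible reaction is split into a forward and a backward
#' nonnegative part, irreversible reactions admitting only negative flux are
#' direction-flipped, and an analysis subnetwork (typically the split boundary
#' reactions plus the biomass reaction) is selected. Stoichiometric rows are
#' scaled to integers so downstream cone computations are exact.
#'
#' @slot base the original \code{MetabolicNetwork}.
#' @slot Sstd integer-valued m x n' standardized stoichiometric matrix.
#' @slot stdIds character labels of standardized reactions.
#' @slot originIndex integer index of the original reaction per standardized
#'   column.
#' @slot originDir "forward" or "backward" per standardized column.
#' @slot subnetwork integer indices (into standardized columns) of the
#'   analysis subnetwork.
#' @slot items data.frame with one row per subnetwork column: \code{entity}
#'   (exchanged metabolite, member-qualified in communities, or reaction id)
#'   and \code{direction} ("import"/"export").
#' @slot biomassIndex standardized column index of the biomass (forward)
#'   reaction.
#' @aliases subnetworkItems
#' @export
setClass("StandardizedNetwork",
  representation(
    base = "MetabolicNetwork",
    Sstd = "matrix",
    stdIds = "character",
    originIndex = "integer",
    originDir = "character",
    subnetwork = "integer",
    items = "data.frame",
    biomassIndex = "integer"
  )
)

setValidity("StandardizedNetwork", function(object) {
  msg <- character()
  np <- ncol(object@Sstd)
  if (length(object@originIndex) != np || length(object@originDir) != np)
    msg <- c(msg, "origin map must be total")
  if (!all(object@subnetwork %in% seq_len(np)))
    msg <- c(msg, "subnetwork indices out of range")
  if (nrow(object@items) != length(object@subnetwork))
    msg <- c(msg, "items must describe each subnetwork column")
  rev <- reversible(object@base)
  for (j in which(rev)) {
    cols <- which(object@originIndex == j)
    if (length(cols) != 2L)
      msg <- c(msg, sprintf("reversible reaction %d must map to two columns", j))
    else if (any(object@Sstd[, cols[1L]] != -object@Sstd[, cols[2L]]))
      msg <- c(msg, sprintf("split columns of reaction %d must be negatives", j))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname StandardizedNetwork-class
#' @export
setMethod("subnetworkItems", "StandardizedNetwork", function(object) object@items)

setMethod("show", "StandardizedNetwork", function(object) {
  cat("StandardizedNetwork:", ncol(object@Sstd), "irreversible reactions,",
      "subnetwork of", length(object@subnetwork), "items\n")
})

#' Community model specification
#'
#' @slot members named list of \code{MetabolicNetwork} objects (names are the
#'   member labels).
#' @slot sharedMetabolites metabolite identifiers exchangeable via the shared
#'   compartment.
#' @slot environmentalExchanges subset of shared metabolites that can also be
#'   exchanged with the environment.
#' @slot biomassShares per-member weight in the community biomass.
#' @export
setClass("CommunitySpec",
  representation(
    members = "list",
    sharedMetabolites = "character",
    environmentalExchanges = "character",
    biomassShares = "numeric"
  )
)

setValidity("CommunitySpec", function(object) {
  msg <- character()
  if (is.null(names(object@members)) || anyDuplicated(names(object@members)))
    msg <- c(msg, "member labels must be unique and named")
  if (!all(vapply(object@members, is, logical(1), "MetabolicNetwork")))
    msg <- c(msg, "members must be MetabolicNetwork objects")
  if (length(object@biomassShares) != length(object@members) ||
      any(object@biomassShares <= 0))
    msg <- c(msg, "biomassShares must be strictly positive, one per member")
  if (!all(object@environmentalExchanges %in% object@sharedMetabolites))
    msg <- c(msg, "environmental exchanges must be shared metabolites")
  for (met in object@sharedMetabolites) {
    hit <- FALSE
    for (mem in object@members) {
      b <- boundaryReactions(mem)
      if (length(b)) {
        touched <- metaboliteIds(mem)[apply(
          stoichiometry(mem)[, b, drop = FALSE] != 0, 2, which)]
        if (met %in% touched) { hit <- TRUE; break }
      }
    }
    if (!hit) msg <- c(msg, paste0("shared metabolite without member boundary reaction: ", met))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CommunitySpec-class
#' @param members named list of \code{MetabolicNetwork} objects.
#' @param sharedMetabolites,environmentalExchanges character vectors.
#' @param biomassShares numeric weights (default equal shares).
#' @export
CommunitySpec <- function(members, sharedMetabolites,
                          environmentalExchanges = character(),
                          biomassShares = rep(1, length(members))) {
  new("CommunitySpec", members = members,
      sharedMetabolites = as.character(sharedMetabolites),
      environmentalExchanges = as.character(environmentalExchanges),
      biomassShares = as.numeric(biomassShares))
}

setMethod("show", "CommunitySpec", function(object) {
  cat("CommunitySpec:", length(object@members), "members (",
      paste(names(object@members), collapse = ", "), ")\n")
  cat("  shared metabolites:", length(object@sharedMetabolites),
      "| environmental:", length(object@environmentalExchanges), "\n")
})

#' Set of extreme rays of a polyhedral cone
#'
#' Rays are stored as primitive integer vectors (divided by their gcd) in a
#' deterministic lexicographic order; \code{rays()} returns the canonical
#' form with the first nonzero entry scaled to 1.
#'
#' @slot raysInt integer-valued matrix, one ray per row.
#' @slot coordIds coordinate labels.
#' @aliases rayCount rays
#' @export
setClass("RaySet",
  representation(raysInt = "matrix", coordIds = "character"))

setValidity("RaySet", function(object) {
  if (ncol(object@raysInt) != length(object@coordIds))
    "coordinate labels must match ray dimension" else TRUE
})

#' @rdname RaySet-class
#' @export
setMethod("rayCount", "RaySet", function(object) nrow(object@raysInt))

#' @rdname RaySet-class
#' @export
setMethod("rays", "RaySet", function(object) {
  R <- object@raysInt
  for (i in seq_len(nrow(R))) {
    nz <- which(R[i, ] != 0)
    if (length(nz)) R[i, ] <- R[i, ] / R[i, nz[1L]]
  }
  colnames(R) <- object@coordIds
  R
})

setMethod("show", "RaySet", function(object) {
  cat("RaySet:", nrow(object@raysInt), "rays in", ncol(object@raysInt),
      "coordinates\n")
})

#' Collection of unique flux patterns
#'
#' A flux pattern is the set of active (entity, direction) items of a flux
#' vector on the analysis subnetwork; the biomass item marks growth support.
#'
#' @slot definition one of "EFM", "ECM", "EFP", "MP".
#' @slot items data.frame (entity, direction) describing the item universe,
#'   one row per subnetwork coordinate.
#' @slot patterns list of sorted integer vectors (indices into the item
#'   universe).
#' @slot growth logical per pattern (positive biomass flux).
#' @slot provenance character label (model/subnetwork).
#' @aliases patternDefinition patternCount patternKeys
#' @export
setClass("PatternCollection",
  representation(
    definition = "character",
    items = "data.frame",
    patterns = "list",
    growth = "logical",
    provenance = "character"
  )
)

setValidity("PatternCollection", function(object) {
  msg <- character()
  if (!object@definition %in% c("EFM", "ECM", "EFP", "MP"))
    msg <- c(msg, "definition must be EFM, ECM, EFP or MP")
  if (length(object@growth) != length(object@patterns))
    msg <- c(msg, "growth flags must match pattern count")
  ni <- nrow(object@items)
  if (length(object@patterns) &&
      any(vapply(object@patterns, function(p) length(p) && (max(p) > ni || min(p) < 1),
                 logical(1))))
    msg <- c(msg, "pattern items outside the item universe")
  if (anyDuplicated(vapply(object@patterns, paste, character(1), collapse = ",")))
    msg <- c(msg, "patterns must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname PatternCollection-class
#' @export
setMethod("patternDefinition", "PatternCollection", function(object) object@definition)

#' @rdname PatternCollection-class
#' @export
setMethod("patternCount", "PatternCollection", function(object) length(object@patterns))

#' @rdname PatternCollection-class
#' @export
setMethod("patternKeys", "PatternCollection", function(object)
  vapply(object@patterns, paste, character(1), collapse = ","))

setMethod("show", "PatternCollection", function(object) {
  cat("PatternCollection [", object@definition, "]: ",
      length(object@patterns), " unique patterns (",
      sum(object@growth), " growth-supporting) over ",
      nrow(object@items), " items\n", sep = "")
})
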