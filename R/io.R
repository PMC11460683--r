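#' Read a constraint-based model
#'
#' Reads SBML Level 3 (with the flux-bounds extension) or the common JSON
#' constraint-based-model dialect (as used by COBRA tools: a list of
#' metabolites and a list of reactions with stoichiometry and bounds).
#' The boundary set is auto-detected as the reactions touching exactly one
#' metabolite; the biomass reaction is detected by id pattern unless
#' overridden.
#'
#' @param path file path.
#' @param dialect "json", "sbml", or "auto" (by file extension).
#' @param biomassId optional explicit biomass reaction id.
#' @return a validated \code{\link{MetabolicNetwork}}.
#' @examples
#' path <- system.file("extdata", "e_coli_core.json", package = "exopath")
#' net <- loadModel(path)
#' net
#' @export
loadModel <- function(path, dialect = c("auto", "json", "sbml"),
                      biomassId = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(dialect,
         json = .readCbmJson(path, biomassId),
         sbml = .readCbmSbml(path, biomassId))
}

.readCbmJson <- function(path, biomassId = NULL) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$metabolites) || is.null(j$reactions))
    stop("not a JSON constraint-based model: missing metabolites/reactions")
  if (is.null(biomassId) && !is.null(j$biomass)) biomassId <- j$biomass
  mets <- vapply(j$metabolites, function(x) x$id, character(1))
  comps <- vapply(j$metabolites, function(x)
    if (!is.null(x$compartment)) as.character(x$compartment) else "", character(1))
  names(comps) <- mets
  rxns <- vapply(j$reactions, function(x) x$id, character(1))
  if (anyDuplicated(mets)) stop("duplicate metabolite identifiers")
  if (anyDuplicated(rxns)) stop("duplicate reaction identifiers")
  m <- length(mets); n <- length(rxns)
  S <- matrix(0, m, n, dimnames = list(mets, rxns))
  lb <- ub <- numeric(n)
  for (i in seq_len(n)) {
    r <- j$reactions[[i]]
    for (met in names(r$metabolites)) {
      if (!met %in% mets)
        stop("reaction ", r$id, " names undeclared metabolite ", met)
      S[met, i] <- as.numeric(r$metabolites[[met]])
    }
    lb[i] <- if (!is.null(r$lower_bound)) as.numeric(r$lower_bound) else -1000
    ub[i] <- if (!is.null(r$upper_bound)) as.numeric(r$upper_bound) else 1000
  }
  MetabolicNetwork(S, lb, ub, biomassId = biomassId, compartments = comps)
}

.readCbmSbml <- function(path, biomassId = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("no species found; is this SBML Level 3?")
  mets <- xml2::xml_attr(sp, "id")
  comps <- xml2::xml_attr(sp, "compartment")
  bc <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  names(comps) <- mets
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- as.numeric(xml2::xml_attr(params, "value"))
  names(pval) <- xml2::xml_attr(params, "id")
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- xml2::xml_attr(rx, "id")
  if (anyDuplicated(mets)) stop("duplicate metabolite identifiers")
  if (anyDuplicated(rxns)) stop("duplicate reaction identifiers")
  m <- length(mets); n <- length(rxns)
  S <- matrix(0, m, n, dimnames = list(mets, rxns))
  lb <- rep(-1000, n); ub <- rep(1000, n)
  for (i in seq_len(n)) {
    node <- rx[[i]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, paste0("./s:", side, "/s:speciesReference"), ns)
      if (!length(refs)) next
      ids <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      sgn <- if (side == "listOfReactants") -1 else 1
      for (k in seq_along(ids)) {
        if (!ids[k] %in% mets)
          stop("reaction ", rxns[i], " names undeclared species ", ids[k])
        S[ids[k], i] <- S[ids[k], i] + sgn * st[k]
      }
    }
    lbRef <- xml2::xml_attr(node, "lowerFluxBound")
    ubRef <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lbRef) && lbRef %in% names(pval)) lb[i] <- pval[[lbRef]]
    if (!is.na(ubRef) && ubRef %in% names(pval)) ub[i] <- pval[[ubRef]]
    if (is.na(lbRef) && xml2::xml_attr(node, "reversible") %in% "false") lb[i] <- 0
  }
  ## species flagged as boundary condition act as unbalanced pools: drop rows
  if (any(bc)) {
    S <- S[!bc, , drop = FALSE]
    comps <- comps[!bc]
    mets <- mets[!bc]
  }
  MetabolicNetwork(S, lb, ub, biomassId = biomassId,
                   metaboliteIds = mets, reactionIds = rxns,
                   compartments = comps)
}

#' Write a model in the JSON constraint-based dialect
#'
#' @param net a \code{MetabolicNetwork}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeModelJson <- function(net, path) {
  mets <- metaboliteIds(net)
  comps <- net@compartments
  S <- stoichiometry(net)
  metList <- lapply(mets, function(m)
    list(id = m, compartment = if (m %in% names(comps)) comps[[m]] else ""))
  rxnList <- lapply(seq_along(reactionIds(net)), function(i) {
    nz <- which(S[, i] != 0)
    list(id = reactionIds(net)[i],
         metabolites = as.list(stats::setNames(S[nz, i], mets[nz])),
         lower_bound = lowerBounds(net)[i],
         upper_bound = upperBounds(net)[i])
  })
  jsonlite::write_json(list(id = "exopath_model", biomass = biomassId(net),
                            metabolites = metList, reactions = rxnList),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
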