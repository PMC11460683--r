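#' Merge single-species models into a community model
#'
#' Builds one network containing all member reactions (ids prefixed
#' \code{"<member>__"}). Member boundary reactions for shared metabolites are
#' rewired into internal transfer reactions between the member metabolite and
#' a shared-compartment metabolite (\code{"<met>__shared"}); new environmental
#' exchange reactions are created only for the designated environmental
#' metabolites. A community-biomass pseudo-metabolite is produced from the
#' member biomasses in proportion to \code{biomassShares}; member biomasses
#' can only leave the system through the community biomass reaction, which
#' enforces balanced growth of all members.
#'
#' @param spec a \code{\link{CommunitySpec}}.
#' @param environmentalBounds numeric length-2 bounds for the new
#'   environmental exchange reactions.
#' @return a \code{\link{MetabolicNetwork}} with member labels recorded in
#'   \code{reactionMember}/\code{metaboliteMember}.
#' @export
mergeCommunity <- function(spec, environmentalBounds = c(-1000, 1000)) {
  validObject(spec)
  labels <- names(spec@members)
  shared <- spec@sharedMetabolites

  metIds <- character(); metComp <- character(); metMem <- character()
  rxnIds <- character(); rxnMem <- character()
  lb <- numeric(); ub <- numeric()
  triplets <- list()  # (metId, rxnId, coef)

  addCoef <- function(met, rxn, coef)
    triplets[[length(triplets) + 1L]] <<- list(met = met, rxn = rxn, coef = coef)

  memberBiomassMet <- character(length(labels)); names(memberBiomassMet) <- labels

  for (lbl in labels) {
    mem <- spec@members[[lbl]]
    S <- stoichiometry(mem)
    mets <- metaboliteIds(mem); rxns <- reactionIds(mem)
    pmet <- paste0(lbl, "__", mets)
    metIds <- c(metIds, pmet)
    mc <- if (length(mem@compartments)) unname(mem@compartments[mets]) else rep("", length(mets))
    mc[is.na(mc)] <- ""
    metComp <- c(metComp, paste0(lbl, "_", mc))
    metMem <- c(metMem, rep(lbl, length(mets)))

    ## locate the member biomass metabolite
    bioJ <- match(biomassId(mem), rxns)
    bioMets <- which(S[, bioJ] != 0)
    bioMet <- NA_character_
    prods <- bioMets[S[bioMets, bioJ] > 0]
    hit <- prods[grepl("biomass|^BM|__BM|BIOMASS", mets[prods], ignore.case = TRUE)]
    if (length(hit)) {
      bioMet <- mets[hit[1L]]
    } else if (length(bioMets) == 1L && S[bioMets, bioJ] < 0) {
      bioMet <- mets[bioMets]  # biomass reaction is the exporter itself
    }
    dropRxn <- rep(FALSE, length(rxns))

    if (is.na(bioMet)) {
      ## internal biomass reaction without an identifiable product:
      ## attach a pseudo-metabolite to it
      bioMet <- paste0(lbl, "__BIOMASS")
      metIds <- c(metIds, bioMet); metComp <- c(metComp, paste0(lbl, "_c"))
      metMem <- c(metMem, lbl)
      memberBiomassMet[lbl] <- bioMet
      addCoef(bioMet, paste0(lbl, "__", biomassId(mem)), 1)
    } else {
      memberBiomassMet[lbl] <- paste0(lbl, "__", bioMet)
      ## drop boundary exporters of the member biomass metabolite
      bmRow <- match(bioMet, mets)
      for (b in boundaryReactions(mem)) {
        if (S[bmRow, b] != 0) dropRxn[b] <- TRUE
      }
    }

    for (j in seq_along(rxns)) {
      if (dropRxn[j]) next
      rid <- paste0(lbl, "__", rxns[j])
      nz <- which(S[, j] != 0)
      isBoundary <- j %in% boundaryReactions(mem)
      met1 <- if (length(nz) == 1L) mets[nz] else NA_character_
      rxnIds <- c(rxnIds, rid); rxnMem <- c(rxnMem, lbl)
      lb <- c(lb, lowerBounds(mem)[j]); ub <- c(ub, upperBounds(mem)[j])
      for (i in nz) addCoef(paste0(lbl, "__", mets[i]), rid, S[i, j])
      if (isBoundary && !is.na(met1) && met1 %in% shared) {
        ## rewire: the exported metabolite enters the shared compartment
        sm <- paste0(met1, "__shared")
        addCoef(sm, rid, -S[nz, j])
      }
    }
  }

  ## shared-compartment metabolites
  for (smet in shared) {
    metIds <- c(metIds, paste0(smet, "__shared"))
    metComp <- c(metComp, "shared"); metMem <- c(metMem, "")
  }

  ## environmental exchanges
  for (emet in spec@environmentalExchanges) {
    rid <- paste0("EX_", emet, "__shared")
    rxnIds <- c(rxnIds, rid); rxnMem <- c(rxnMem, "")
    lb <- c(lb, environmentalBounds[1]); ub <- c(ub, environmentalBounds[2])
    addCoef(paste0(emet, "__shared"), rid, -1)
  }

  ## community biomass: shares of member biomasses -> pseudo-metabolite
  cbm <- "biomass__community"
  metIds <- c(metIds, cbm); metComp <- c(metComp, "shared"); metMem <- c(metMem, "")
  rxnIds <- c(rxnIds, "community_biomass"); rxnMem <- c(rxnMem, "")
  lb <- c(lb, 0); ub <- c(ub, 1000)
  shares <- spec@biomassShares / sum(spec@biomassShares)
  for (k in seq_along(labels)) {
    addCoef(memberBiomassMet[labels[k]], "community_biomass", -shares[k])
  }
  addCoef(cbm, "community_biomass", 1)
  rxnIds <- c(rxnIds, "EX_biomass__community"); rxnMem <- c(rxnMem, "")
  lb <- c(lb, 0); ub <- c(ub, 1000)
  addCoef(cbm, "EX_biomass__community", -1)

  if (anyDuplicated(rxnIds)) stop("duplicate prefixed reaction ids")
  if (anyDuplicated(metIds)) stop("duplicate prefixed metabolite ids")
  S <- matrix(0, length(metIds), length(rxnIds),
              dimnames = list(metIds, rxnIds))
  for (tr in triplets) S[tr$met, tr$rxn] <- S[tr$met, tr$rxn] + tr$coef

  names(metComp) <- metIds
  names(rxnMem) <- rxnIds
  names(metMem) <- metIds
  MetabolicNetwork(S, lb, ub, biomassId = "EX_biomass__community",
                   compartments = metComp,
                   reactionMember = rxnMem, metaboliteMember = metMem)
}
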