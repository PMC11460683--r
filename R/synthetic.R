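#' Fixed small test network with known pathway structure
#'
#' A five-metabolite network (A-D and biomass BM) with five internal
#' reactions and three boundary reactions:
#' \preformatted{
#'   r1: 2 A -> C        b1: A  <-> (exchange)
#'   r2:   C -> D        b2: B  <-> (exchange)
#'   r3:   D -> BM       b3: BM ->  (growth)
#'   r4:   C -> B
#'   r5: B + C -> 2 D
#' }
#' Its conversion cone has exactly three elementary conversion modes
#' (2A -> BM, 2A -> B, and 2A + B -> 2BM), all three are elementary flux
#' patterns, and exactly one pattern - import A, export biomass - is a
#' minimal pathway, because every route to biomass needs A while B alone
#' supports no growth.
#'
#' @return a \code{\link{MetabolicNetwork}}.
#' @export
makeToyNetwork <- function() {
  mets <- c("A", "B", "C", "D", "BM")
  rxns <- c("r1", "r2", "r3", "r4", "r5", "b1", "b2", "b3")
  S <- matrix(0, 5, 8, dimnames = list(mets, rxns))
  S["A", "r1"] <- -2; S["C", "r1"] <- 1
  S["C", "r2"] <- -1; S["D", "r2"] <- 1
  S["D", "r3"] <- -1; S["BM", "r3"] <- 1
  S["C", "r4"] <- -1; S["B", "r4"] <- 1
  S["B", "r5"] <- -1; S["C", "r5"] <- -1; S["D", "r5"] <- 2
  S["A", "b1"] <- -1
  S["B", "b2"] <- -1
  S["BM", "b3"] <- -1
  lb <- c(0, 0, 0, 0, 0, -10, -10, 0)
  ub <- c(100, 100, 100, 100, 100, 10, 10, 10)
  MetabolicNetwork(S, lb, ub, biomassId = "b3",
                   compartments = stats::setNames(rep("c", 5), mets))
}

#' Recipe for random mass-balanced networks
#'
#' @param metabolites number of internal metabolites (excluding biomass).
#' @param internalReactions number of internal reactions.
#' @param boundaryMetabolites number of metabolites given boundary
#'   (exchange) reactions.
#' @param reversibleProb probability that a boundary reaction is reversible.
#' @param maxCoef largest stoichiometric coefficient.
#' @param biomassPrecursors number of biomass precursors (>= 1).
#' @param seed integer seed.
#' @return a list of class "NetworkRecipe".
#' @export
networkRecipe <- function(metabolites = 6, internalReactions = 7,
                          boundaryMetabolites = 3, reversibleProb = 0.3,
                          maxCoef = 2, biomassPrecursors = 1, seed = 1) {
  stopifnot(metabolites >= 2, internalReactions >= 1,
            boundaryMetabolites >= 2, biomassPrecursors >= 1)
  structure(list(metabolites = metabolites,
                 internalReactions = internalReactions,
                 boundaryMetabolites = boundaryMetabolites,
                 reversibleProb = reversibleProb,
                 maxCoef = maxCoef,
                 biomassPrecursors = biomassPrecursors,
                 seed = seed),
            class = "NetworkRecipe")
}

#' Generate a random mass-balanced network
#'
#' Draws random internal reactions with small integer coefficients, boundary
#' reactions for a subset of metabolites, and a biomass reaction consuming
#' random precursors. Networks are rejection-sampled until the biomass LP is
#' feasible at a growth of at least 1e-3, so every returned network supports
#' growth. Deterministic for a fixed seed.
#'
#' @param recipe a \code{\link{networkRecipe}}.
#' @param maxTries rejection budget.
#' @return a \code{\link{MetabolicNetwork}}.
#' @export
randomNetwork <- function(recipe, maxTries = 200) {
  stopifnot(inherits(recipe, "NetworkRecipe"))
  for (try in seq_len(maxTries)) {
    set.seed(recipe$seed * 1000L + try)
    net <- .drawNetwork(recipe)
    sol <- fba(net)
    if (sol$status == "optimal" && sol$objval >= 1e-3) return(net)
  }
  stop("rejection budget exhausted: recipe too restrictive")
}

.drawNetwork <- function(recipe) {
  m <- recipe$metabolites
  mets <- c(paste0("M", seq_len(m)), "BM")
  nInt <- recipe$internalReactions
  nB <- min(recipe$boundaryMetabolites, m)
  bMets <- sample(seq_len(m), nB)
  rxns <- c(paste0("r", seq_len(nInt)), "bio", paste0("b", seq_len(nB)), "bBM")
  S <- matrix(0, m + 1, nInt + nB + 2, dimnames = list(mets, rxns))
  for (j in seq_len(nInt)) {
    ns <- sample(1:2, 1); np <- sample(1:2, 1)
    subs <- sample(seq_len(m), ns)
    prods <- sample(setdiff(seq_len(m), subs), min(np, m - ns))
    S[subs, j] <- -sample(seq_len(recipe$maxCoef), ns, replace = TRUE)
    S[prods, j] <- sample(seq_len(recipe$maxCoef), length(prods), replace = TRUE)
  }
  prec <- sample(seq_len(m), recipe$biomassPrecursors)
  S[prec, "bio"] <- -1
  S["BM", "bio"] <- 1
  for (k in seq_len(nB)) S[bMets[k], nInt + 1 + k] <- -1
  S["BM", "bBM"] <- -1
  lb <- numeric(ncol(S)); ub <- rep(100, ncol(S))
  rev <- stats::runif(nB) < recipe$reversibleProb
  ## boundary reactions: importable (reversible) or export-only; make sure at
  ## least one boundary metabolite is importable
  if (!any(rev)) rev[sample.int(nB, 1)] <- TRUE
  lb[nInt + 1 + which(rev)] <- -100
  MetabolicNetwork(S, lb, ub, biomassId = "bio",
                   compartments = stats::setNames(rep("c", m + 1), mets))
}

#' Three-member cross-feeding community fixture
#'
#' Builds a stylized phototrophic-mat community: a phototroph ("syn") that
#' fixes CO2 using light and secretes acetate, glycolate and oxygen; a
#' photoheterotroph ("fap") that consumes the organic acids with oxygen or
#' light and releases CO2 and H2; and a reducer ("srb") that consumes acetate
#' with H2/CO2 exchange. Members are joined through a shared compartment with
#' environmental exchanges for light, CO2, ammonia and H2, and an
#' equal-shares community biomass (balanced growth).
#'
#' @param seed integer seed (kept for interface symmetry; the fixture is
#'   deterministic).
#' @return list with elements \code{spec} (a \code{\link{CommunitySpec}})
#'   and \code{model} (the merged \code{\link{MetabolicNetwork}}).
#' @export
makeToyCommunity <- function(seed = 1) {
  mkMember <- function(rxns, mets, biomass) {
    S <- matrix(0, length(mets), length(rxns$id),
                dimnames = list(mets, rxns$id))
    for (k in seq_along(rxns$id)) {
      for (met in names(rxns$stoich[[k]])) S[met, k] <- rxns$stoich[[k]][[met]]
    }
    MetabolicNetwork(S, rxns$lb, rxns$ub, biomassId = biomass,
                     compartments = stats::setNames(rep("c", length(mets)), mets))
  }
  ## phototroph: light + co2 + nh4 -> biomass, secreting ac, glyc, o2
  syn <- mkMember(list(
    id = c("fix", "photo_bio", "ac_syn", "glyc_syn",
           "EX_hv", "EX_co2", "EX_nh4", "EX_ac", "EX_glyc", "EX_o2", "EX_bm"),
    stoich = list(
      fix = c(hv = -1, co2 = -1, cx = 1, o2 = 1),
      photo_bio = c(cx = -2, nh4 = -1, bm_syn = 1),
      ac_syn = c(cx = -1, ac = 1),
      glyc_syn = c(cx = -1, glyc = 1),
      EX_hv = c(hv = -1), EX_co2 = c(co2 = -1), EX_nh4 = c(nh4 = -1),
      EX_ac = c(ac = -1), EX_glyc = c(glyc = -1), EX_o2 = c(o2 = -1),
      EX_bm = c(bm_syn = -1)),
    lb = c(0, 0, 0, 0, -100, -100, -100, 0, 0, 0, 0),
    ub = c(100, 100, 100, 100, 0, 0, 0, 100, 100, 100, 100)),
    mets = c("hv", "co2", "cx", "o2", "nh4", "ac", "glyc", "bm_syn"),
    biomass = "EX_bm")
  ## photoheterotroph: organics + o2 (or light) -> biomass + co2 + h2
  fap <- mkMember(list(
    id = c("resp", "photoassim", "h2_out", "fap_bio",
           "EX_ac", "EX_glyc", "EX_o2", "EX_hv", "EX_co2", "EX_h2",
           "EX_nh4", "EX_bm"),
    stoich = list(
      resp = c(ac = -1, o2 = -1, cx = 1, co2 = 1),
      photoassim = c(glyc = -1, hv = -1, cx = 1),
      h2_out = c(cx = -1, co2 = 1, h2 = 2),
      fap_bio = c(cx = -2, nh4 = -1, bm_fap = 1),
      EX_ac = c(ac = -1), EX_glyc = c(glyc = -1), EX_o2 = c(o2 = -1),
      EX_hv = c(hv = -1), EX_co2 = c(co2 = -1), EX_h2 = c(h2 = -1),
      EX_nh4 = c(nh4 = -1), EX_bm = c(bm_fap = -1)),
    lb = c(0, 0, 0, 0, -100, -100, -100, -100, -100, -100, -100, 0),
    ub = c(100, 100, 100, 100, 0, 0, 0, 0, 100, 100, 0, 100)),
    mets = c("ac", "glyc", "o2", "hv", "cx", "co2", "h2", "nh4", "bm_fap"),
    biomass = "EX_bm")
  ## reducer: acetate + h2 -> biomass, releasing co2
  srb <- mkMember(list(
    id = c("acred", "srb_bio", "EX_ac", "EX_h2", "EX_co2", "EX_nh4", "EX_bm"),
    stoich = list(
      acred = c(ac = -1, h2 = -1, cx = 1, co2 = 1),
      srb_bio = c(cx = -2, nh4 = -1, bm_srb = 1),
      EX_ac = c(ac = -1), EX_h2 = c(h2 = -1), EX_co2 = c(co2 = -1),
      EX_nh4 = c(nh4 = -1), EX_bm = c(bm_srb = -1)),
    lb = c(0, 0, -100, -100, -100, -100, 0),
    ub = c(100, 100, 0, 100, 100, 0, 100)),
    mets = c("ac", "h2", "cx", "co2", "nh4", "bm_srb"),
    biomass = "EX_bm")
  spec <- CommunitySpec(
    members = list(syn = syn, fap = fap, srb = srb),
    sharedMetabolites = c("hv", "co2", "nh4", "ac", "glyc", "o2", "h2"),
    environmentalExchanges = c("hv", "co2", "nh4", "h2", "o2"))
  list(spec = spec, model = mergeCommunity(spec))
}
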