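#' Run the full metabolite-exchange pathway analysis pipeline
#'
#' Standardizes the model, enumerates the requested pathway definitions
#' (EFMs, ECMs, EFPs by union closure, MPs), converts everything to unique
#' flux patterns, applies the growth filter, compares definitions and checks
#' the hierarchy of pattern sets, and computes exchange (and, for community
#' models, producer-consumer interaction) frequencies. Optionally samples the
#' growth-constrained flux polytope. All stages are deterministic for a fixed
#' configuration and seed.
#'
#' @param model a \code{\link{MetabolicNetwork}} or a model file path.
#' @param definitions subset of c("efm", "ecm", "efp", "mp"); "efp" requires
#'   "efm" or "ecm".
#' @param subnetworkMode passed to \code{\link{standardize}}.
#' @param growthFloor biomass floor for MP enumeration (1/h).
#' @param samplerN number of flux samples (0 disables sampling).
#' @param samplerFloor biomass floor for sampling (1/h).
#' @param seed integer seed for the sampler.
#' @param maxRays ray ceiling for enumeration.
#' @param outDir optional output directory for CSV/JSON reports.
#' @return list with elements \code{counts} (data.frame of raw/unique/growth
#'   counts per definition), \code{collections} (growth-supporting pattern
#'   collections), \code{collectionsAll} (unfiltered), \code{comparison},
#'   \code{hierarchy}, \code{frequencies}, \code{frequencyDifferences},
#'   \code{interactions} (communities only), \code{samples} (optional), and
#'   \code{manifest}.
#' @export
runPipeline <- function(model,
                        definitions = c("ecm", "efp", "mp"),
                        subnetworkMode = "boundary",
                        growthFloor = 1e-4,
                        samplerN = 0, samplerFloor = 0.1, seed = 1,
                        maxRays = 2e6,
                        outDir = NULL) {
  definitions <- match.arg(tolower(definitions),
                           c("efm", "ecm", "efp", "mp"), several.ok = TRUE)
  if (!length(definitions)) stop("at least one definition must be requested")
  if ("efp" %in% definitions && !any(c("efm", "ecm") %in% definitions))
    stop("the EFP tier requires the EFM or ECM tier")
  net <- if (is.character(model)) loadModel(model) else model
  validObject(net)
  std <- standardize(net, subnetworkMode = subnetworkMode)
  prov <- paste0(biomassId(net), ";", subnetworkMode)

  collectionsAll <- list(); raw <- c()
  if ("efm" %in% definitions) {
    efms <- enumerateEfms(std, maxRays = maxRays)
    restricted <- restrictToSubnetwork(efms, std)
    collectionsAll$EFM <- toPatterns(restricted, std, "EFM", provenance = prov)
    raw["EFM"] <- efms@count
  }
  if ("ecm" %in% definitions) {
    ecms <- enumerateEcms(std, maxRays = maxRays)
    collectionsAll$ECM <- toPatterns(ecms@raySet@raysInt, std, "ECM",
                                     provenance = prov)
    raw["ECM"] <- ecms@count
  }
  if ("efp" %in% definitions) {
    src <- if (!is.null(collectionsAll$EFM)) collectionsAll$EFM else collectionsAll$ECM
    collectionsAll$EFP <- extractEfps(src)
    raw["EFP"] <- patternCount(collectionsAll$EFP)
  }
  if ("mp" %in% definitions) {
    collectionsAll$MP <- enumerateMps(std, growthFloor = growthFloor)
    raw["MP"] <- patternCount(collectionsAll$MP)
  }

  collections <- lapply(collectionsAll, filterGrowth)
  counts <- data.frame(
    definition = names(collectionsAll),
    raw = as.numeric(raw[names(collectionsAll)]),
    uniquePatterns = vapply(collectionsAll, patternCount, numeric(1)),
    growthPatterns = vapply(collections, patternCount, numeric(1)),
    row.names = NULL)

  comparison <- if (length(collections) > 1) compareCollections(collections) else NULL
  hierarchy <- verifyHierarchy(collections)

  frequencies <- lapply(collections[vapply(collections, patternCount, numeric(1)) > 0],
                        exchangeFrequency)
  freqDiffs <- list()
  defsF <- names(frequencies)
  if (length(defsF) > 1) {
    for (i in seq_len(length(defsF) - 1)) {
      for (j in seq(i + 1, length(defsF))) {
        nm <- paste0(defsF[i], "-", defsF[j])
        freqDiffs[[nm]] <- frequencyDifference(frequencies[[defsF[i]]],
                                               frequencies[[defsF[j]]])
      }
    }
  }

  isCommunity <- any(net@reactionMember != "")
  interactions <- NULL
  if (isCommunity && length(collections)) {
    interactions <- lapply(collections[vapply(collections, patternCount,
                                              numeric(1)) > 0],
                           interactionFrequency)
  }

  samples <- NULL
  if (samplerN > 0) {
    samples <- sampleFluxes(net, n = samplerN, growthFloor = samplerFloor,
                            seed = seed)
  }

  manifest <- list(definitions = definitions, subnetworkMode = subnetworkMode,
                   growthFloor = growthFloor, samplerN = samplerN,
                   samplerFloor = samplerFloor, seed = seed, maxRays = maxRays,
                   nMetabolites = length(metaboliteIds(net)),
                   nReactions = length(reactionIds(net)),
                   nBoundary = length(boundaryReactions(net)))

  result <- list(counts = counts, collections = collections,
                 collectionsAll = collectionsAll, comparison = comparison,
                 hierarchy = hierarchy, frequencies = frequencies,
                 frequencyDifferences = freqDiffs,
                 interactions = interactions, samples = samples,
                 manifest = manifest)
  if (!is.null(outDir)) .writeReports(result, outDir)
  result
}

.writeReports <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$counts, file.path(outDir, "counts.csv"),
                   row.names = FALSE)
  for (d in names(result$frequencies)) {
    utils::write.csv(result$frequencies[[d]],
                     file.path(outDir, paste0("frequency_", d, ".csv")),
                     row.names = FALSE)
  }
  for (d in names(result$frequencyDifferences)) {
    utils::write.csv(result$frequencyDifferences[[d]],
                     file.path(outDir, paste0("frequency_diff_", d, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(result$interactions)) {
    for (d in names(result$interactions)) {
      utils::write.csv(result$interactions[[d]],
                       file.path(outDir, paste0("interactions_", d, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(manifest = result$manifest,
         hierarchy = list(holds = result$hierarchy$holds,
                          equal = result$hierarchy$equal)),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  ## pattern export: one row per (pattern, item)
  for (d in names(result$collections)) {
    coll <- result$collections[[d]]
    if (!patternCount(coll)) next
    rows <- do.call(rbind, lapply(seq_along(coll@patterns), function(i) {
      it <- coll@items[coll@patterns[[i]], , drop = FALSE]
      data.frame(pattern = i, entity = it$entity, direction = it$direction)
    }))
    utils::write.table(rows, file.path(outDir, paste0("patterns_", d, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(outDir)
}
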