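test_that("pattern extraction drops zeros, deduplicates and flags growth", {
  std <- standardize(makeToyNetwork())
  ni <- nrow(subnetworkItems(std))
  v1 <- rep(0, ni); v1[c(2, 5)] <- c(1, 2)      # A import + biomass
  v2 <- v1 * 7                                   # proportional duplicate
  v3 <- rep(0, ni); v3[2] <- 1                   # no growth
  coll <- toPatterns(rbind(v1, v2, v3), std, "ECM")
  expect_equal(patternCount(coll), 2)
  expect_equal(sum(coll@growth), 1)
  expect_error(toPatterns(matrix(0, 1, ni + 1), std), "dimension")

  g <- filterGrowth(coll)
  expect_equal(patternCount(g), 1)
  expect_true(all(g@growth))
  ## collection with no growth pattern filters to empty
  none <- toPatterns(rbind(v3), std, "ECM")
  expect_equal(patternCount(filterGrowth(none)), 0)
})

test_that("union closure removes constructible patterns", {
  std <- standardize(makeToyNetwork())
  ni <- nrow(subnetworkItems(std))
  mk <- function(items) { v <- rep(0, ni); v[items] <- 1; v }
  ## {a}, {b}, {a,b}: the union of the singletons removes the pair
  coll <- toPatterns(rbind(mk(1), mk(2), mk(c(1, 2))), std, "ECM")
  efp <- extractEfps(coll)
  expect_setequal(patternKeys(efp), c("1", "2"))
  expect_equal(patternDefinition(efp), "EFP")
})

test_that("EFP extraction equals the exhaustive oracle and is route-invariant", {
  nets <- c(list(makeToyNetwork()), randomBatch(8, seedOffset = 500))
  for (net in nets) {
    std <- standardize(net)
    if (ncol(std@Sstd) > 16) next
    efms <- enumerateEfms(std)
    ecms <- enumerateEcms(std)
    pEFM <- toPatterns(restrictToSubnetwork(efms, std), std, "EFM")
    pECM <- toPatterns(ecms@raySet@raysInt, std, "ECM")
    efp1 <- extractEfps(pECM)
    efp2 <- extractEfps(pEFM)
    expect_setequal(patternKeys(efp1), patternKeys(efp2))
    oracle <- oracleElementaryPatterns(pECM@patterns)
    expect_setequal(supportKeys(oracle), patternKeys(efp1))
  }
  ## empty family
  expect_equal(length(oracleElementaryPatterns(list())), 0)
})

test_that("minimal pathway enumeration matches forced cases and the subset LP oracle", {
  ## chain: the single MP is {A import, B export} (B export is the biomass item)
  std <- standardize(chainNetwork())
  mp <- enumerateMps(std)
  expect_equal(patternCount(mp), 1)
  it <- subnetworkItems(std)[mp@patterns[[1]], ]
  expect_setequal(paste(it$entity, it$direction), c("A import", "B export"))
  expect_true(all(mp@growth))

  ## infeasible growth floor (no carbon source): explicit empty result
  net2 <- chainNetwork()
  net2@lowerBounds[1] <- 0   # b1 can no longer import A
  expect_equal(patternCount(enumerateMps(standardize(net2))), 0)

  ## random networks: equality with the exhaustive-subset LP oracle
  for (net in randomBatch(8, seedOffset = 700)) {
    std <- standardize(net)
    if (sum(!subnetworkItems(std)$isBiomass) > 12) next
    mp <- enumerateMps(std)
    oracle <- oracleMinimalFeasibleSubsets(std)
    expect_setequal(patternKeys(mp), supportKeys(oracle))
  }
})

test_that("pattern comparison counts subsets and supersets like a direct recount", {
  std <- standardize(makeToyNetwork())
  efms <- enumerateEfms(std)
  ecms <- enumerateEcms(std)
  pEFM <- filterGrowth(toPatterns(restrictToSubnetwork(efms, std), std, "EFM"))
  pECM <- filterGrowth(toPatterns(ecms@raySet@raysInt, std, "ECM"))
  pEFP <- filterGrowth(extractEfps(toPatterns(ecms@raySet@raysInt, std, "ECM")))
  mp <- enumerateMps(std)
  cmp <- compareCollections(list(EFM = pEFM, ECM = pECM, EFP = pEFP, MP = mp))

  ## brute-force recount of MP-subset counts for EFPs
  recount <- vapply(pEFP@patterns, function(p)
    sum(vapply(mp@patterns, function(q) all(q %in% p), logical(1))), integer(1))
  expect_equal(unname(cmp$subsetCounts$MP_in_EFP), recount)

  ## identical collections: every pattern is its own subset and superset once
  cmp2 <- compareCollections(list(ECM = pECM, MP = pECM))
  expect_true(all(cmp2$venn$`ECM&MP` == patternCount(pECM)))

  ## shortest growth-supporting patterns agree across definitions
  expect_setequal(cmp$shortest$MP, cmp$shortest$EFP)
  expect_setequal(cmp$shortest$MP, cmp$shortest$ECM)
})

test_that("hierarchy verification flags equality and violations", {
  std <- standardize(chainNetwork())
  mp <- enumerateMps(std)
  ecms <- enumerateEcms(std)
  pECM <- toPatterns(ecms@raySet@raysInt, std, "ECM")
  h <- verifyHierarchy(list(MP = mp, ECM = pECM))
  expect_true(h$holds)
  expect_true(h$equal)   # all tiers support-minimal in a chain

  ## a fabricated violation is reported with witnesses
  fake <- mp
  fake@patterns <- list(c(1L))
  h2 <- verifyHierarchy(list(MP = fake, ECM = pECM))
  expect_false(h2$holds)
  expect_gt(length(h2$witnesses), 0)
})

test_that("no elementary pattern contains both directions of one exchange", {
  for (net in c(list(makeToyNetwork()), randomBatch(5, seedOffset = 900))) {
    std <- standardize(net)
    if (ncol(std@Sstd) > 16) next
    ecms <- enumerateEcms(std)
    pECM <- toPatterns(ecms@raySet@raysInt, std, "ECM")
    items <- subnetworkItems(std)
    for (p in pECM@patterns) {
      ent <- items$entity[p]
      expect_false(any(duplicated(ent)))
    }
  }
})
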