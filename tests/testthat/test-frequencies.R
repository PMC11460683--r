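test_that("exchange frequencies follow the definition (essential = 1, unused = 0)", {
  std <- standardize(makeToyNetwork())
  mp <- enumerateMps(std)
  f <- exchangeFrequency(mp)
  ## single MP: its items have frequency 1, all others 0, zeros listed
  expect_equal(nrow(f), nrow(subnetworkItems(std)))
  expect_setequal(f$frequency, c(1, 0))
  expect_equal(attr(f, "denominator"), patternCount(mp))

  ecms <- enumerateEcms(std)
  pECM <- toPatterns(ecms@raySet@raysInt, std, "ECM")
  fe <- exchangeFrequency(pECM)
  ## direct tally oracle
  for (r in seq_len(nrow(fe))) {
    cnt <- sum(vapply(pECM@patterns, function(p) r %in% p, logical(1)))
    expect_equal(fe$count[r], cnt)
  }
  ## A import occurs in every conversion of the toy network
  rowA <- fe$entity == "A" & fe$direction == "import"
  expect_equal(fe$frequency[rowA], 1)
  expect_error(exchangeFrequency(filterGrowth(toPatterns(
    matrix(0, 0, nrow(subnetworkItems(std))), std))), "empty")
})

test_that("frequency differences are elementwise and sorted by magnitude", {
  std <- standardize(makeToyNetwork())
  ecms <- enumerateEcms(std)
  pECM <- filterGrowth(toPatterns(ecms@raySet@raysInt, std, "ECM"))
  mp <- enumerateMps(std)
  fa <- exchangeFrequency(pECM); fb <- exchangeFrequency(mp)
  d <- frequencyDifference(fa, fb)
  expect_equal(sort(abs(d$difference), decreasing = TRUE), abs(d$difference))
  key <- paste(d$entity, d$direction)
  fkey <- paste(fa$entity, fa$direction)
  expect_equal(d$difference, (fa$frequency - fb$frequency)[match(key, fkey)])
  ## identical tables give all zeros
  expect_true(all(frequencyDifference(fa, fa)$difference == 0))
  ## universe mismatch is an error
  expect_error(frequencyDifference(fa, fb[seq_len(nrow(fb) - 1), ]), "mismatch")
})

test_that("pairwise frequencies are bounded by marginals with marginal diagonal", {
  std <- standardize(makeToyNetwork())
  ecms <- enumerateEcms(std)
  pECM <- toPatterns(ecms@raySet@raysInt, std, "ECM")
  P <- pairwiseFrequency(pECM)
  f <- exchangeFrequency(pECM)$frequency
  expect_equal(unname(diag(P)), f)
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    expect_lte(P[i, j], min(f[i], f[j]) + 1e-12)
  }
  ## brute-force double loop oracle
  M <- exopath:::.patternMatrix(pECM) * 1
  expect_equal(unname(P), unname(t(M) %*% M / patternCount(pECM)))
})

test_that("interaction frequencies tally producer-consumer pairs in communities", {
  tc <- makeToyCommunity()
  std <- standardize(tc$model, subnetworkMode = "boundary_plus_intermicrobial")
  mp <- enumerateMps(std)
  it <- interactionFrequency(mp)
  expect_gt(nrow(it), 0)
  expect_true(all(it$producer != it$consumer))
  expect_true(all(it$frequency > 0 & it$frequency <= 1))
  ## brute-force tally for one triple
  items <- subnetworkItems(std)
  tallyOne <- function(pr, cn, met) {
    sum(vapply(mp@patterns, function(p) {
      e <- items$entity[p]; d <- items$direction[p]
      any(e == paste0(pr, ":", met) & d == "export") &&
        any(e == paste0(cn, ":", met) & d == "import")
    }, logical(1)))
  }
  for (r in seq_len(nrow(it))) {
    expect_equal(it$count[r], tallyOne(it$producer[r], it$consumer[r],
                                       it$metabolite[r]))
  }
  ## single-member (non-community) collection is rejected
  mpS <- enumerateMps(standardize(makeToyNetwork()))
  expect_error(interactionFrequency(mpS), "not a community")
})

test_that("essential exchanges in MPs stay essential in the wider definitions", {
  tc <- makeToyCommunity()
  std <- standardize(tc$model, subnetworkMode = "boundary_plus_intermicrobial")
  mp <- enumerateMps(std)
  ecms <- enumerateEcms(std)
  gECM <- filterGrowth(toPatterns(ecms@raySet@raysInt, std, "ECM"))
  fm <- exchangeFrequency(mp); fe <- exchangeFrequency(gECM)
  essential <- which(fm$frequency == 1)
  expect_true(all(fe$frequency[essential] == 1))
})
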