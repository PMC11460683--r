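test_that("a linear chain has a single conversion: consume A, produce B", {
  std <- standardize(chainNetwork())
  ecms <- enumerateEcms(std)
  ## one conversion plus nothing else (biomass item is the B export itself)
  expect_equal(ecms@count, 1)
  conv <- ecms@conversions
  expect_equal(unname(conv[1, "A"]), -1)
  expect_equal(unname(conv[1, "B"]), 1)
})

test_that("the toy network has exactly the three known conversions", {
  std <- standardize(makeToyNetwork())
  ecms <- enumerateEcms(std)
  expect_equal(ecms@count, 3)
  keys <- apply(sign(ecms@conversions[, c("A", "B", "BM")]), 1, paste,
                collapse = ",")
  expect_setequal(keys, c("-1,0,1", "-1,-1,1", "-1,1,0"))
  ## stoichiometry: the pure growth conversion is 2A -> 1 BM
  i <- which(keys == "-1,0,1")
  expect_equal(unname(ecms@conversions[i, c("A", "BM")]), c(-2, 1))
})

test_that("ECM rays equal the LP-pruned conic hull of restricted EFMs", {
  nets <- c(list(makeToyNetwork()), randomBatch(6, seedOffset = 300))
  for (net in nets) {
    std <- standardize(net)
    if (ncol(std@Sstd) > 16) next
    efms <- enumerateEfms(std)
    ecms <- enumerateEcms(std)
    P <- restrictToSubnetwork(efms, std)
    P <- P[rowSums(P != 0) > 0, , drop = FALSE]
    if (nrow(P)) {
      prim <- t(apply(P, 1, exopath:::.primitive))
      prim <- prim[!duplicated(apply(prim, 1, paste, collapse = ",")), ,
                   drop = FALSE]
      keepRay <- vapply(seq_len(nrow(prim)), function(i)
        !inConicHull(prim[i, ], prim[-i, , drop = FALSE]), logical(1))
      prim <- prim[keepRay, , drop = FALSE]
      ## drop futile split two-cycles, as the enumerator does
      origin <- std@originIndex[std@subnetwork]
      futile <- apply(prim, 1, function(r) {
        s <- which(r != 0)
        length(s) == 2 && origin[s[1]] == origin[s[2]]
      })
      prim <- prim[!futile, , drop = FALSE]
    }
    k1 <- apply(exopath:::.sortRaysLex(ecms@raySet@raysInt), 1, paste, collapse = ",")
    k2 <- apply(exopath:::.sortRaysLex(prim), 1, paste, collapse = ",")
    expect_setequal(k1, k2)
  }
})

test_that("every ECM ray extends to a feasible full flux vector", {
  std <- standardize(makeToyNetwork())
  ecms <- enumerateEcms(std)
  Sstd <- std@Sstd
  sub <- std@subnetwork
  for (i in seq_len(ecms@count)) {
    y <- ecms@raySet@raysInt[i, ]
    A <- rbind(Sstd, diag(ncol(Sstd))[sub, , drop = FALSE])
    b <- c(rep(0, nrow(Sstd)), y)
    w <- solveLp(numeric(ncol(Sstd)), A, rep("==", nrow(A)), b, lb = 0)
    expect_equal(w$status, "optimal")
  }
})

test_that("conversion-cone summary equals a direct tally", {
  std <- standardize(makeToyNetwork())
  ecms <- enumerateEcms(std)
  tab <- conversionConeSummary(ecms)
  for (r in seq_len(nrow(tab))) {
    col <- ecms@conversions[, tab$metabolite[r]]
    n <- if (tab$direction[r] == "import") sum(col < 0) else sum(col > 0)
    expect_equal(tab$rays[r], n)
  }
  ## directions never used are absent
  expect_false(any(tab$metabolite == "BM" & tab$direction == "import"))
  ## single-ray set: each used metabolite counted once
  one <- enumerateEcms(standardize(chainNetwork()))
  t1 <- conversionConeSummary(one)
  expect_true(all(t1$rays == 1))
})
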