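test_that("a one-member community reduces to the member with relabeling", {
  net <- makeToyNetwork()
  spec <- CommunitySpec(members = list(solo = net),
                        sharedMetabolites = c("A", "B"),
                        environmentalExchanges = c("A", "B"))
  merged <- mergeCommunity(spec)
  ## growth capacity is preserved (community biomass consumes 1 BM per unit)
  expect_equal(fba(merged)$objval, fba(net)$objval, tolerance = 1e-6)
  ## member boundary reactions became internal transfers
  j <- match("solo__b1", reactionIds(merged))
  expect_false(j %in% boundaryReactions(merged))
  expect_equal(sum(stoichiometry(merged)[, j] != 0), 2)
})

test_that("merged community models conserve mass in the shared compartment", {
  tc <- makeToyCommunity()
  S <- stoichiometry(tc$model)
  comps <- tc$model@compartments
  shared <- setdiff(names(comps)[comps == "shared"], "biomass__community")
  ## every feasible steady-state flux keeps shared metabolites balanced by
  ## construction; structurally, each shared row couples transfers and (at
  ## most) one environmental exchange
  for (sm in shared) {
    cols <- which(S[sm, ] != 0)
    expect_gt(length(cols), 0)
    env <- grep("^EX_", reactionIds(tc$model)[cols])
    expect_lte(length(env), 1)
  }
  sol <- fba(tc$model)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-8)
})

test_that("community growth requires every member (equal-shares biomass)", {
  tc <- makeToyCommunity()
  expect_gt(fba(tc$model)$objval, 1e-6)
  for (lbl in names(tc$spec@members)) {
    m <- tc$model
    idx <- which(m@reactionMember == lbl)
    m@upperBounds[idx] <- pmin(m@upperBounds[idx], 0)
    m@lowerBounds[idx] <- pmax(m@lowerBounds[idx], 0)
    expect_lt(abs(fba(m)$objval), 1e-9)
  }
})

test_that("community spec validation catches inconsistent inputs", {
  net <- makeToyNetwork()
  expect_error(validObject(
    CommunitySpec(members = list(a = net),
                  sharedMetabolites = "ZZZ")), "boundary")
  expect_error(validObject(
    new("CommunitySpec", members = list(a = net, b = net),
        sharedMetabolites = character(),
        environmentalExchanges = character(),
        biomassShares = c(1, -1))), "positive")
})

test_that("the community subnetwork includes intermicrobial transfers", {
  tc <- makeToyCommunity()
  std <- standardize(tc$model, subnetworkMode = "boundary_plus_intermicrobial")
  items <- subnetworkItems(std)
  ## member-qualified entities present for transfers
  expect_true(any(grepl("^syn:", items$entity)))
  expect_true(any(grepl("^fap:", items$entity)))
  ## boundary-only mode drops them
  stdB <- standardize(tc$model, subnetworkMode = "boundary")
  expect_false(any(grepl(":", subnetworkItems(stdB)$entity)))
})
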