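test_that("JSON model IO round-trips a hand-written model", {
  net <- chainNetwork()
  path <- tempfile(fileext = ".json")
  writeModelJson(net, path)
  net2 <- loadModel(path)
  expect_equal(stoichiometry(net2), stoichiometry(net))
  expect_equal(lowerBounds(net2), lowerBounds(net))
  expect_equal(upperBounds(net2), upperBounds(net))
  expect_equal(biomassId(net2), "b2")
  expect_equal(boundaryReactions(net2), boundaryReactions(net))
})

test_that("model validation rejects malformed inputs", {
  bad <- tempfile(fileext = ".json")
  writeLines('{"metabolites":[{"id":"A"}],
    "reactions":[{"id":"r","metabolites":{"ZZZ":1},
                  "lower_bound":0,"upper_bound":1}]}', bad)
  expect_error(loadModel(bad), "undeclared metabolite")

  dup <- tempfile(fileext = ".json")
  writeLines('{"metabolites":[{"id":"A"},{"id":"A"}],
    "reactions":[{"id":"r","metabolites":{"A":1},
                  "lower_bound":0,"upper_bound":1}]}', dup)
  expect_error(loadModel(dup), "duplicate")

  nob <- tempfile(fileext = ".json")
  writeLines('{"metabolites":[{"id":"A"}],
    "reactions":[{"id":"r","metabolites":{"A":1},
                  "lower_bound":0,"upper_bound":1}]}', nob)
  expect_error(loadModel(nob), "biomass")
})

test_that("SBML level 3 + flux bounds models are read correctly", {
  path <- tempfile(fileext = ".xml")
  writeLines(chainSbml(), path)
  net <- loadModel(path)
  expect_equal(sort(metaboliteIds(net)), c("A", "B"))
  expect_equal(length(reactionIds(net)), 3)
  expect_equal(lowerBounds(net), c(-10, 0, 0))
  expect_equal(upperBounds(net), rep(10, 3))
  expect_equal(biomassId(net), "growth_b2")  # detected by id pattern
  expect_equal(stoichiometry(net)["A", "r1"], -1)
  expect_equal(length(boundaryReactions(net)), 2)
})

test_that("the bundled e_coli_core model has the expected structure", {
  net <- loadModel(ecoliModelPath())
  expect_equal(length(reactionIds(net)), 95)
  expect_equal(length(boundaryReactions(net)), 20)
  expect_equal(length(metaboliteIds(net)), 72)
  expect_equal(biomassId(net), "Biomass_Ecoli_core")
})

test_that("standardization flips, splits and maps back to the original network", {
  ## irreversible reaction with only-negative flux is direction-flipped
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "r"))
  net <- MetabolicNetwork(cbind(S, c(1, 0), c(0, -1)),
                          c(-10, 0, 0), c(0, 10, 10),
                          metaboliteIds = c("A", "B"),
                          reactionIds = c("r", "bA", "bB"),
                          biomassId = "bB")
  std <- standardize(net)
  j <- which(std@originIndex == 1)
  expect_equal(std@originDir[j], "backward")
  expect_equal(unname(std@Sstd[, j]), c(1, -1))

  ## reversible boundary reaction splits into export and import items
  net2 <- chainNetwork()
  std2 <- standardize(net2)
  items <- subnetworkItems(std2)
  expect_setequal(paste(items$entity, items$direction),
                  c("A export", "A import", "B export"))
  ## split columns are negatives of each other (class validity holds)
  expect_true(validObject(std2))

  ## collapse(origin) reproduces the original (integerized) stoichiometry
  Sint <- exopath:::.integerizeRows(stoichiometry(net2))
  for (jj in seq_along(reactionIds(net2))) {
    fwd <- which(std2@originIndex == jj & std2@originDir == "forward")
    expect_equal(unname(std2@Sstd[, fwd]), unname(Sint[, jj]))
  }

  ## feasible flux vectors of the standardized cone satisfy Sstd x = 0 exactly
  efms <- enumerateEfms(std2)
  expect_true(all(std2@Sstd %*% t(efms@raysStd) == 0))

  expect_error(standardize(net2, "explicit"), "subnetworkReactions")
})

test_that("flux variability matches pinned/blocked expectations and a vertex oracle", {
  net <- chainNetwork()
  ## pin r1 at 5
  net@lowerBounds[2] <- 5; net@upperBounds[2] <- 5
  fv <- fluxVariability(net)
  expect_equal(fv$min[2], 5); expect_equal(fv$max[2], 5)

  ## blocked reaction: no production route
  S <- matrix(0, 2, 3, dimnames = list(c("A", "B"), c("bA", "r", "bio")))
  S["A", "bA"] <- -1; S["A", "r"] <- -1; S["B", "r"] <- 1
  S["B", "bio"] <- -1
  net2 <- MetabolicNetwork(S, c(0, 0, 0), c(10, 10, 10), biomassId = "bio")
  ## bA can only export A, nothing produces A: all reactions blocked
  fv2 <- fluxVariability(net2)
  expect_true(all(abs(fv2$min) < 1e-9 & abs(fv2$max) < 1e-9))

  ## toy fixture ranges equal a brute-force vertex-enumeration oracle
  toy <- makeToyNetwork()
  fv3 <- fluxVariability(toy, growthFloor = 0.1)
  S3 <- stoichiometry(toy)
  lb <- lowerBounds(toy); ub <- upperBounds(toy)
  lb[match("b3", reactionIds(toy))] <- 0.1
  n <- ncol(S3); r <- qr(S3)$rank; d <- n - r
  verts <- list()
  for (fix in utils::combn(n, d, simplify = FALSE)) {
    grid <- expand.grid(rep(list(c(1, 2)), d))
    for (g in seq_len(nrow(grid))) {
      val <- ifelse(unlist(grid[g, ]) == 1, lb[fix], ub[fix])
      A <- rbind(S3, diag(n)[fix, , drop = FALSE])
      b <- c(rep(0, nrow(S3)), val)
      sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(A %*% sol - b)) < 1e-8 &&
          all(sol >= lb - 1e-8) && all(sol <= ub + 1e-8))
        verts[[length(verts) + 1L]] <- sol
    }
  }
  V <- do.call(rbind, verts)
  expect_equal(fv3$min, unname(apply(V, 2, min)), tolerance = 1e-6)
  expect_equal(fv3$max, unname(apply(V, 2, max)), tolerance = 1e-6)

  ## infeasible growth floor is reported distinctly
  expect_error(fluxVariability(toy, growthFloor = 1e6), "infeasible|floor")
})
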