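## small fixed polytope: one pinned inflow split across three uptakes
simplexNet <- function() {
  S <- matrix(c(1, -1, -1, -1), 1, 4,
              dimnames = list("A", c("in", "u1", "u2", "u3")))
  MetabolicNetwork(S, c(1, 0, 0, 0), c(1, 1, 1, 1), biomassId = "in")
}

test_that("pinned reactions stay constant and samples satisfy all constraints", {
  net <- simplexNet()
  ss <- sampleFluxes(net, n = 500, growthFloor = 0, seed = 1, thin = 5)
  expect_true(all(abs(ss@samples[, "in"] - 1) < 1e-9))
  S <- stoichiometry(net)
  expect_lt(max(abs(ss@samples %*% t(S))), 1e-6)
  expect_true(all(ss@samples >= matrix(lowerBounds(net), nrow(ss@samples),
                                       4, byrow = TRUE) - 1e-9))
  fv <- fluxVariability(net)
  for (j in seq_len(4)) {
    expect_true(all(ss@samples[, j] >= fv$min[j] - 1e-6))
    expect_true(all(ss@samples[, j] <= fv$max[j] + 1e-6))
  }
})

test_that("sampling is reproducible for a fixed seed", {
  net <- simplexNet()
  a <- sampleFluxes(net, n = 200, growthFloor = 0, seed = 9, thin = 5)
  b <- sampleFluxes(net, n = 200, growthFloor = 0, seed = 9, thin = 5)
  expect_identical(a@samples, b@samples)
  c <- sampleFluxes(net, n = 200, growthFloor = 0, seed = 10, thin = 5)
  expect_false(identical(a@samples, c@samples))
})

test_that("simplex coordinate means recover the analytic centroid", {
  net <- simplexNet()
  ss <- sampleFluxes(net, n = 10000, growthFloor = 0, seed = 42, thin = 5)
  m <- colMeans(ss@samples)
  se <- apply(ss@samples, 2, stats::sd) / sqrt(nrow(ss@samples))
  for (j in 2:4) {
    expect_lt(abs(m[j] - 1 / 3), 3 * se[j])
  }
})

test_that("the convergence diagnostic behaves on constructed chains", {
  ## identical constant chains: statistic 1
  const <- matrix(1, 200, 2)
  cv <- checkConvergence(const)
  expect_equal(unname(cv$rhat), c(1, 1))
  expect_true(cv$pass)

  ## independent uniform draws pass at n = 10,000
  set.seed(1)
  u <- matrix(runif(10000 * 2), 10000, 2)
  expect_true(checkConvergence(u)$pass)

  ## deliberately unmixed halves fail
  bad <- matrix(c(rnorm(500, 0), rnorm(500, 10)), ncol = 1)
  expect_false(checkConvergence(bad)$pass)

  expect_error(checkConvergence(matrix(0, 10, 2)), "too few")
})

test_that("infeasible polytopes are reported", {
  net <- simplexNet()
  expect_error(sampleFluxes(net, n = 10, growthFloor = 5, seed = 1),
               "infeasible")
})

test_that("per-pathway sampling reaches a region global sampling misses", {
  ## toy network with a sliver of B-import capacity: the B-importing pattern
  ## region is vanishingly small for the global sampler
  toy <- makeToyNetwork()
  j <- match("b2", reactionIds(toy))
  toy@lowerBounds[j] <- -1e-5
  global <- sampleFluxes(toy, n = 10000, growthFloor = 0.1, seed = 7, thin = 5)
  expect_equal(sum(global@samples[, j] < -1e-6), 0)

  std <- standardize(toy)
  items <- subnetworkItems(std)
  patt <- which((items$entity == "A" & items$direction == "import") |
                (items$entity == "B" & items$direction == "import") |
                items$isBiomass)
  ps <- samplePerPathway(std, patt, n = 300, seed = 3, growthFloor = 0.1,
                         thin = 5)
  expect_equal(nrow(ps@samples), 300)
  ## every sample's subnetwork sign pattern equals the requested pattern
  expect_true(all(ps@samples[, j] <= -1e-6 + 1e-12))          # B imported
  expect_true(all(ps@samples[, match("b1", reactionIds(toy))] < 0))  # A imported
  expect_true(all(ps@samples[, match("b3", reactionIds(toy))] >= 0.1 - 1e-9))

  ## an invalid pathway (growth without any carbon import) is reported
  items3 <- subnetworkItems(std)
  bad <- which((items3$entity == "B" & items3$direction == "export") |
               items3$isBiomass)
  expect_error(samplePerPathway(std, bad, n = 10, seed = 1), "infeasible")
})
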