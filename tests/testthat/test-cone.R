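test_that("double description handles forced small cones", {
  ## single equality x1 = x2 in the plane: one ray (1,1)
  rs <- doubleDescription(coneH(eq = matrix(c(1, -1), 1)))
  expect_equal(rayCount(rs), 1)
  expect_equal(unname(rays(rs)[1, ]), c(1, 1))

  ## no constraints: the orthant generators
  rs2 <- doubleDescription(coneH(n = 3))
  expect_equal(rayCount(rs2), 3)
  expect_equal(unname(rs2@raysInt[order(apply(rs2@raysInt, 1, which.max)), ]),
               diag(3))

  ## an extra inequality halves the plane: x1 >= x2 over the orthant
  rs3 <- doubleDescription(coneH(ineq = matrix(c(1, -1), 1), n = 2))
  expect_equal(rayCount(rs3), 2)
})

test_that("double description equals the brute-force support oracle on random cones", {
  set.seed(11)
  for (k in 1:20) {
    A <- matrix(sample(-2:2, 4 * 7, replace = TRUE), 4, 7)
    rs <- doubleDescription(coneH(eq = A))
    ## every ray satisfies the constraints exactly and is nonnegative
    if (rayCount(rs)) {
      expect_true(all(A %*% t(rs@raysInt) == 0))
      expect_true(all(rs@raysInt >= 0))
    }
    oracle <- oracleMinimalSupports(A)
    got <- lapply(seq_len(rayCount(rs)), function(i) which(rs@raysInt[i, ] != 0))
    expect_setequal(supportKeys(oracle), supportKeys(got))
  }
})

test_that("ray sets are invariant to equality row order", {
  set.seed(3)
  A <- matrix(sample(-2:2, 3 * 6, replace = TRUE), 3, 6)
  r1 <- doubleDescription(coneH(eq = A))
  r2 <- doubleDescription(coneH(eq = A[c(3, 1, 2), ]))
  expect_equal(rays(r1), rays(r2))
})

test_that("conic generation: random cone points decompose over the rays", {
  set.seed(5)
  A <- matrix(sample(-2:2, 3 * 6, replace = TRUE), 3, 6)
  rs <- doubleDescription(coneH(eq = A))
  R <- rs@raysInt
  for (k in 1:20) {
    lam <- runif(nrow(R))
    pt <- as.vector(lam %*% R)
    expect_true(inConicHull(pt, R))
  }
  ## no ray is a nonnegative combination of the others
  for (i in seq_len(nrow(R))) {
    expect_false(inConicHull(R[i, ], R[-i, , drop = FALSE]))
  }
})

test_that("cone projection is exact on forced examples", {
  ## identity projection
  A <- matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE)
  cone <- coneH(eq = A)
  proj <- projectCone(cone, keep = 1:3)
  expect_equal(rays(doubleDescription(proj)), rays(doubleDescription(cone)))

  ## chain cone {b1 = r1 = b2 >= 0} projected to (b1, b2): {b1 = b2 >= 0}
  proj2 <- projectCone(cone, keep = c(1, 3))
  rs <- doubleDescription(proj2)
  expect_equal(rayCount(rs), 1)
  expect_equal(unname(rays(rs)[1, ]), c(1, 1))
})

test_that("projection membership agrees with an existential LP oracle", {
  set.seed(17)
  for (k in 1:8) {
    n <- 6
    A <- matrix(sample(-2:2, 3 * n, replace = TRUE), 3, n)
    keep <- sort(sample(n, 3))
    proj <- projectCone(coneH(eq = A), keep = keep)
    for (j in 1:12) {
      y <- round(runif(3, 0, 2), 2)
      inProj <- all(y >= -1e-9) &&
        (!nrow(proj@eq) || max(abs(proj@eq %*% y)) < 1e-9) &&
        (!nrow(proj@ineq) || all(proj@ineq %*% y >= -1e-9))
      ## oracle: does a full nonnegative preimage exist?
      nn <- ncol(A)
      Afull <- rbind(A, diag(nn)[keep, , drop = FALSE])
      b <- c(rep(0, nrow(A)), y)
      ex <- solveLp(numeric(nn), Afull, rep("==", nrow(Afull)), b, lb = 0)
      expect_equal(inProj, ex$status == "optimal",
                   info = sprintf("seed-case %d:%d", k, j))
    }
  }
})

test_that("projection and extreme-ray enumeration commute", {
  set.seed(23)
  for (k in 1:10) {
    n <- 6
    A <- matrix(sample(-2:2, 3 * n, replace = TRUE), 3, n)
    keep <- sort(sample(n, 3))
    ## route 1: project, then enumerate
    r1 <- doubleDescription(projectCone(coneH(eq = A), keep = keep))
    ## route 2: enumerate, project the rays, prune to extreme rays by LP
    full <- doubleDescription(coneH(eq = A))
    P <- full@raysInt[, keep, drop = FALSE]
    P <- P[rowSums(P != 0) > 0, , drop = FALSE]
    if (nrow(P)) {
      prim <- t(apply(P, 1, exopath:::.primitive))
      prim <- prim[!duplicated(apply(prim, 1, paste, collapse = ",")), , drop = FALSE]
      keepRay <- vapply(seq_len(nrow(prim)), function(i)
        !inConicHull(prim[i, ], prim[-i, , drop = FALSE]), logical(1))
      P <- prim[keepRay, , drop = FALSE]
    }
    k1 <- apply(exopath:::.sortRaysLex(r1@raysInt), 1, paste, collapse = ",")
    k2 <- apply(exopath:::.sortRaysLex(P), 1, paste, collapse = ",")
    expect_setequal(k1, k2)
  }
})
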