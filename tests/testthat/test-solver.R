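test_that("anchored solve reproduces detailed balance on the truncated chain", {
  bd <- birth_death_net(k0 = 1, kd = 1)
  sp <- makeSpace(red = reduceNetwork(bd), alpha = 0L, beta = 2L)
  gen <- buildGenerator(bd, sp)
  sol <- solveAnchored(gen, j = stateIndex(sp, 1L))
  # detailed balance: pi(k+1)/pi(k) = k0/(kd (k+1)); anchored at state 1
  expect_equal(sol$p, c(0.4, 0.4, 0.2), tolerance = 1e-12)
  expect_equal(sol$eta, 2.5, tolerance = 1e-12)
  expect_equal(sol$p[stateIndex(sp, 1L)], 1 / sol$eta)

  # single state
  sp1 <- makeSpace(red = reduceNetwork(bd), alpha = 3L, beta = 3L)
  sol1 <- solveAnchored(buildGenerator(bd, sp1), 1L)
  expect_equal(sol1$p, 1)
})

test_that("truncated birth-death matches the Poisson law pointwise", {
  bd <- birth_death_net(k0 = 10, kd = 1)
  sp <- makeSpace(red = reduceNetwork(bd), alpha = 0L, beta = 40L)
  gen <- buildGenerator(bd, sp)
  sol <- solveAnchored(gen, stateIndex(sp, 10L))
  pois <- stats::dpois(0:40, 10)
  rel <- abs(sol$p[1:31] - pois[1:31]) / pois[1:31]
  expect_lt(max(rel), 1e-10)
})

test_that("symmetric isomerization yields the binomial law", {
  iso <- isomerization_net(total = 10, kf = 1, kb = 1)
  red <- reduceNetwork(iso)
  sp <- makeSpace(red = red, alpha = 0L, beta = 10L)
  gen <- buildGenerator(iso, sp)
  sol <- solveAnchored(gen, stateIndex(sp, 5L))
  expect_equal(sol$p, stats::dbinom(0:10, 10, 0.5), tolerance = 1e-10)
})

test_that("anchored solve agrees with the dense eigenvector oracle", {
  set.seed(21)
  for (rep in 1:10) {
    net <- random_fixture_net()
    sp <- random_fixture_space(net)
    gen <- buildGenerator(net, sp)
    j <- stateIndex(sp, attr(sp, "anchor"))
    pa <- solveAnchored(gen, j)$p
    pe <- eigenOracle(gen)
    expect_lt(max(abs(pa - pe)), 1e-8)
  }
  # oracle refuses dense work beyond its stated limit
  bd <- birth_death_net()
  spbig <- makeSpace(red = reduceNetwork(bd), alpha = 0L, beta = 2500L)
  expect_error(eigenOracle(buildGenerator(bd, spbig)), "2000")
})

test_that("adaptive expansion stops when expandable faces drop below eps", {
  bd <- birth_death_net(k0 = 10, kd = 1)
  dist <- adaptiveSolve(bd, eps = 1e-6, gamma0 = 2, gamma = 5)
  expect_gte(dist@expansions, 1L)
  expect_true(all(dist@faceMasses[dist@faceExpandable] < 1e-6))
  expect_valid_distribution(dist, bd)
  # the left face is pinned at zero and carries mass above eps: exact, not
  # expandable
  expect_false(dist@faceExpandable[1, "left"])
  expect_gt(dist@faceMasses[1, "left"], 1e-6)

  # converged noise is invariant to the initial box width once the face
  # tolerance sits below the comparison tolerance (eps leaves an eps-level
  # imprint on the final box)
  cvs <- vapply(c(2, 5, 20), function(g0) {
    coefficientOfVariation(adaptiveSolve(bd, eps = 1e-7, gamma0 = g0), "A")
  }, numeric(1))
  expect_lt(max(abs(cvs - cvs[1])) / cvs[1], 1e-6)
})

test_that("a network with no possible transitions keeps a point mass", {
  net <- parseReactionNetwork(c(
    "species A init 4", "species B init 0",
    "reaction r: A + B -> 0 @ 1"))   # B = 0 forever: propensity always 0
  dist <- adaptiveSolve(net)
  expect_equal(dist@expansions, 0L)
  expect_equal(sum(dist@p > 0), 1L)
  expect_equal(unname(stateMatrix(dist, full = TRUE)[which.max(dist@p), ]),
               c(4L, 0L))
})

test_that("captured-mass deficit diagnoses box adequacy", {
  bd <- birth_death_net(k0 = 10, kd = 1)
  red <- reduceNetwork(bd)
  wide <- adaptiveSolve(bd, eps = 1e-8)
  expect_lt(capturedMassDeficit(wide), 1e-6)

  sp_tight <- makeSpace(red = red, alpha = 8L, beta = 12L)
  sol <- solveAnchored(buildGenerator(bd, sp_tight), stateIndex(sp_tight, 10L))
  dist_tight <- new("SteadyStateDistribution", space = sp_tight, p = sol$p,
                    anchorIndex = stateIndex(sp_tight, 10L), eta = sol$eta,
                    faceMasses = matrix(0, 1, 2),
                    faceExpandable = matrix(TRUE, 1, 2),
                    expansions = 0L, deterministic = findSteadyState(bd),
                    settings = list())
  expect_gt(capturedMassDeficit(dist_tight), 0.1)

  sp1 <- makeSpace(red = red, alpha = 10L, beta = 10L)
  sol1 <- solveAnchored(buildGenerator(bd, sp1), 1L)
  dist1 <- new("SteadyStateDistribution", space = sp1, p = sol1$p,
               anchorIndex = 1L, eta = sol1$eta,
               faceMasses = matrix(0, 1, 2),
               faceExpandable = matrix(FALSE, 1, 2),
               expansions = 0L, deterministic = findSteadyState(bd),
               settings = list())
  expect_equal(capturedMassDeficit(dist1), 1)
})

test_that("solved distributions satisfy the stationarity conditions", {
  nets <- list(birth_death_net(3, 1),
               isomerization_net(12, 2, 0.5),
               cv2_net(A = 0.4),
               buildTypeIINetwork("II", B = 0.3))
  for (net in nets) {
    dist <- adaptiveSolve(net)
    expect_valid_distribution(dist, net)
    # anchor probability equals 1/eta and is among the dominant entries
    expect_equal(dist@p[dist@anchorIndex], 1 / dist@eta, tolerance = 1e-9)
    expect_gte(dist@p[dist@anchorIndex], max(dist@p) / 50)
  }
})
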