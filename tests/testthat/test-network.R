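test_that("parser handles minimal, realistic and malformed inputs", {
  net <- parseReactionNetwork(c(
    "# birth-death",
    "species A init 0",
    "reaction R1: 0 -> A @ 10",
    "reaction R2: A -> 0 @ 1"))
  expect_s4_class(net, "ReactionNetwork")
  expect_equal(dynamicSpecies(net), "A")
  expect_equal(nReactions(net), 2L)
  nu <- stateChangeMatrix(net)
  expect_equal(unname(nu), matrix(c(1L, -1L), 1))

  # params, clamps, stoichiometric multipliers
  net2 <- parseReactionNetwork(c(
    "param kon = 0.5",
    "clamp L = 2.5",
    "species R init 10",
    "species C init 0",
    "reaction bind: L + R -> C @ kon",
    "reaction dim: 2 R -> C @ 1"))
  expect_equal(clampValues(net2), c(L = 2.5))
  expect_equal(net2@reactions[[1]]$rate, 0.5)
  expect_equal(net2@reactions[[2]]$reactants, c(R = 2L))

  # representative intermediate-complex rates parse as plain decimals
  net3 <- buildCv2Network(k3 = 1.3282, km3 = 0.0100, k4 = 1.3282,
                          km4 = 0.0100, A = 0.3, dTotal = 105)
  expect_equal(length(dynamicSpecies(net3)), 5L)
  expect_equal(nReactions(net3), 8L)
  expect_equal(clampedSpecies(net3), "A")

  expect_error(parseReactionNetwork("reaction Rx: A + -> B @ 1"), "line 1")
  expect_error(parseReactionNetwork(c("species A init 0",
                                      "reaction R: A -> B @ 1")),
               "undeclared")
  expect_error(parseReactionNetwork(c("species A init 0",
                                      "reaction R: A -> 0 @ -2")),
               "positive")
  expect_error(parseReactionNetwork(c("species A init 0",
                                      "reaction R: 3 A -> 0 @ 1")),
               "order")
})

test_that("mass-action propensities follow the combinatorial rule", {
  net <- parseReactionNetwork(c(
    "species A init 2", "species B init 3", "species C init 0",
    "reaction R1: A + B -> C @ 0.5",
    "reaction R2: A -> 0 @ 1",
    "reaction R3: 2 A -> C @ 1"))
  a <- propensityVector(net, c(A = 2, B = 3, C = 0))
  expect_equal(a[[1]], 3.0)

  # brute-force oracle for the doubled reactant: count unordered pairs
  n_pairs <- function(x) nrow(t(utils::combn(seq_len(x), 2)))
  expect_equal(propensityVector(net, c(A = 4, B = 0, C = 0))[[3]],
               n_pairs(4))

  # empty state: degradation has nothing to act on
  expect_equal(propensityVector(net, c(A = 0, B = 5, C = 0))[[2]], 0)

  # clamped species multiply at clamp value
  net2 <- buildCv2Network(k3 = 1, km3 = 1, k4 = 1, km4 = 1, A = 2.5,
                          dTotal = 10)
  a2 <- propensityVector(net2, c(B = 4, C = 0, D = 10, E = 0, Z = 0))
  expect_equal(a2[[1]], 0.013282 * 2.5 * 4)   # A + B -> C
})

test_that("propensities are nonnegative and vanish below stoichiometric demand", {
  set.seed(11)
  for (rep in 1:10) {
    net <- random_fixture_net()
    dyn <- dynamicSpecies(net)
    st <- sample(0:3, length(dyn), replace = TRUE)
    a <- propensityVector(net, st)
    expect_true(all(a >= 0))
    for (m in seq_along(net@reactions)) {
      re <- net@reactions[[m]]$reactants
      re <- re[names(re) %in% dyn]
      if (length(re) && any(st[match(names(re), dyn)] < re)) {
        expect_equal(a[[m]], 0)
      }
    }
  }
})

test_that("state-change vectors match the declared stoichiometry", {
  net <- buildCv2Network(k3 = 1, km3 = 1, k4 = 1, km4 = 1, A = 0.3,
                         dTotal = 105)
  nu <- stateChangeMatrix(net)
  # receptor binding with clamped ligand: [-1 +1 0 0 0] over (B,C,D,E,Z)
  expect_equal(unname(nu[, 1]), c(-1L, 1L, 0L, 0L, 0L))
  # clamped A contributes no row; A + D -> E only moves D and E
  expect_equal(unname(nu[, 3]), c(0L, 0L, -1L, 1L, 0L))

  bd <- birth_death_net()
  expect_equal(unname(stateChangeMatrix(bd)[, 1]), 1L)

  # round trip: products - reactants over dynamic species
  set.seed(5)
  for (rep in 1:8) {
    rnet <- random_fixture_net()
    nu2 <- stateChangeMatrix(rnet)
    dyn <- dynamicSpecies(rnet)
    for (m in seq_along(rnet@reactions)) {
      rx <- rnet@reactions[[m]]
      expected <- integer(length(dyn))
      names(expected) <- dyn
      for (s in names(rx$reactants)) {
        if (s %in% dyn) expected[s] <- expected[s] - rx$reactants[[s]]
      }
      for (s in names(rx$products)) {
        if (s %in% dyn) expected[s] <- expected[s] + rx$products[[s]]
      }
      expect_equal(unname(nu2[, m]), unname(expected))
    }
  }
})

test_that("conservation basis is the exact integer left null space", {
  expect_equal(nrow(conservationBasis(birth_death_net())$basis), 0L)

  iso <- isomerization_net()
  cb <- conservationBasis(iso)
  expect_equal(unname(cb$basis), matrix(c(1L, 1L), 1))
  expect_equal(cb$totals, 10)

  net <- cv2_net()
  cb2 <- conservationBasis(net)
  expect_equal(nrow(cb2$basis), 2L)
  expect_equal(unname(cb2$basis[1, ]), c(1L, 1L, 0L, 0L, 1L))
  expect_equal(unname(cb2$basis[2, ]), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(cb2$totals, c(100, 105))
  # exact annihilation of every state change, integer arithmetic
  expect_true(all(cb2$basis %*% stateChangeMatrix(net) == 0))
})

test_that("reduction eliminates pools and reconstruction is exact", {
  net <- cv2_net()
  red <- reduceNetwork(net)
  dyn <- dynamicSpecies(net)
  expect_equal(dyn[red@keep], c("C", "E", "Z"))
  expect_equal(dyn[red@eliminated], c("B", "D"))
  # B = 100 - C - Z, D = 105 - E - Z
  z <- rbind(c(10L, 5L, 20L), c(0L, 0L, 0L), c(30L, 50L, 40L))
  full <- reconstructStates(red, z)
  expect_equal(unname(full[, "B"]), 100 - z[, 1] - z[, 3])
  expect_equal(unname(full[, "D"]), 105 - z[, 2] - z[, 3])
  expect_equal(unname(full[, c("C", "E", "Z")]), unname(z))

  nII <- buildTypeIINetwork("II", B = 0.3)
  redII <- reduceNetwork(nII)
  expect_equal(dynamicSpecies(nII)[redII@keep], c("BR1", "BR1R2"))

  # no conservation: identity reduction
  red0 <- reduceNetwork(birth_death_net())
  expect_equal(red0@keep, 1L)
  expect_equal(length(red0@eliminated), 0L)

  # reconstruction is the identity on states visited by an exact trajectory
  ssa <- gillespieRun(cv2_net(A = 0.3), endTime = 200, seed = 3)
  visited <- ssa@states
  kept <- visited[, red@keep, drop = FALSE]
  expect_equal(unname(reconstructStates(red, kept)), unname(visited))
})

test_that("Type II builders produce the three case topologies", {
  nI <- buildTypeIINetwork("I", B = 0.1)
  expect_equal(dynamicSpecies(nI), c("R1", "BR1"))
  expect_equal(nReactions(nI), 2L)
  expect_equal(length(reduceNetwork(nI)@keep), 1L)
  expect_equal(signalingSpecies("I"), "BR1")
  expect_equal(signalingSpecies("II"), "BR1R2")

  nII <- buildTypeIINetwork("II", B = 0.1)
  expect_equal(sort(vapply(nII@reactions, `[[`, "", "label")),
               c("r1", "r2", "r5", "r6"))

  nIII <- buildTypeIINetwork("III", B = 0.1)
  expect_equal(nReactions(nIII), 8L)
  expect_true("BR2" %in% dynamicSpecies(nIII))

  # zeroing the direct Type II binding rates recovers the Case II topology
  nIII0 <- buildTypeIINetwork("III", k2 = 0, km2 = 0, k4 = 0, km4 = 0,
                              B = 0.1)
  expect_equal(vapply(nIII0@reactions, `[[`, "", "label"),
               vapply(nII@reactions, `[[`, "", "label"))
  expect_equal(dynamicSpecies(nIII0), dynamicSpecies(nII))
})

test_that("shipped example network files parse and solve", {
  for (f in c("birth_death.rxn", "cv2_attenuation.rxn",
              "typeII_caseII.rxn")) {
    path <- system.file("extdata", f, package = "steadyCME")
    expect_true(nzchar(path))
    net <- parseReactionNetwork(file = path)
    expect_s4_class(net, "ReactionNetwork")
    expect_true(findSteadyState(net)@converged)
  }
  # the co-factor example file reproduces the builder's network
  net <- parseReactionNetwork(file = system.file(
    "extdata", "cv2_attenuation.rxn", package = "steadyCME"))
  ref <- buildCv2Network(k3 = 1.3282, km3 = 0.01, k4 = 1.3282, km4 = 0.01,
                         A = 0.4, dTotal = 105)
  expect_equal(stateChangeMatrix(net), stateChangeMatrix(ref))
  expect_equal(findSteadyState(net)@Y0, findSteadyState(ref)@Y0,
               tolerance = 1e-9)
})
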