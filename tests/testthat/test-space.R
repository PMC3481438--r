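test_that("box construction follows the anchor and clamps at zero", {
  red <- reduceNetwork(birth_death_net())
  sp <- makeSpace(anchor = 20L, gamma0 = 5, red = red)
  expect_equal(sp@alpha, 15L)
  expect_equal(sp@beta, 25L)
  expect_equal(stateCount(sp), 11L)

  sp2 <- makeSpace(anchor = 3L, gamma0 = 5, red = red)
  expect_equal(sp2@alpha, 0L)
  expect_equal(sp2@beta, 8L)

  # two-coordinate product box and index round trip
  iso2 <- parseReactionNetwork(c(
    "species A init 0", "species B init 0",
    "reaction bA: 0 -> A @ 1", "reaction dA: A -> 0 @ 1",
    "reaction bB: 0 -> B @ 1", "reaction dB: B -> 0 @ 1"))
  red2 <- reduceNetwork(iso2)
  sp3 <- makeSpace(red = red2, alpha = c(0L, 0L), beta = c(2L, 1L))
  expect_equal(stateCount(sp3), 6L)
  for (r in seq_len(stateCount(sp3))) {
    expect_equal(stateIndex(sp3, sp3@states[r, ]), r)
  }
  # enumeration order: last coordinate varies fastest
  expect_equal(sp3@states[1:2, 2], c(0L, 1L))

  # conservation caps bound the box
  iso <- isomerization_net(total = 10)
  spc <- makeSpace(anchor = 8L, gamma0 = 6, red = reduceNetwork(iso))
  expect_equal(spc@beta, 10L)
})

test_that("generator matches the hand-built truncated birth-death operator", {
  bd <- birth_death_net(k0 = 1, kd = 1)
  sp <- makeSpace(red = reduceNetwork(bd), alpha = 0L, beta = 2L)
  gen <- buildGenerator(bd, sp)
  expect_equal(as.matrix(gen@matrix),
               matrix(c(-1, 1, 0,
                        1, -2, 1,
                        0, 2, -2), 3, 3),
               ignore_attr = TRUE)
  expect_equal(max(abs(Matrix::colSums(gen@matrix))), 0)

  # single-state space: nothing flows
  sp1 <- makeSpace(red = reduceNetwork(bd), alpha = 5L, beta = 5L)
  g1 <- buildGenerator(bd, sp1)
  expect_equal(as.matrix(g1@matrix), matrix(0, 1, 1), ignore_attr = TRUE)
})

test_that("generator columns sum to zero with nonnegative off-diagonals", {
  set.seed(7)
  for (rep in 1:12) {
    net <- random_fixture_net()
    sp <- random_fixture_space(net)
    gen <- buildGenerator(net, sp)
    L <- gen@matrix
    expect_lte(max(abs(Matrix::colSums(L))), 1e-12 * max(abs(L@x), 1))
    off <- L - Matrix::Diagonal(nrow(L), Matrix::diag(L))
    expect_true(all(off@x >= 0))
    expect_true(all(Matrix::diag(L) <= 0))
  }
})

test_that("generators embed: interior columns are preserved under box growth", {
  bd <- birth_death_net(k0 = 4, kd = 1)
  red <- reduceNetwork(bd)
  small <- makeSpace(red = red, alpha = 2L, beta = 8L)
  large <- makeSpace(red = red, alpha = 0L, beta = 12L)
  gs <- buildGenerator(bd, small)@matrix
  gl <- buildGenerator(bd, large)@matrix
  for (st in 3:7) {   # interior states of the small box
    cs <- stateIndex(small, st)
    cl <- stateIndex(large, st)
    nbrs <- c(st - 1L, st, st + 1L)
    vs <- vapply(nbrs, function(x) gs[stateIndex(small, x), cs], numeric(1))
    vl <- vapply(nbrs, function(x) gl[stateIndex(large, x), cl], numeric(1))
    expect_equal(vs, vl)
  }
})

test_that("truncated chains on the feasible set are strongly connected", {
  skip_if_not_installed("igraph")
  nets <- list(cv2_net(A = 0.4),
               buildTypeIINetwork("II", B = 0.3))
  for (net in nets) {
    red <- reduceNetwork(net)
    det <- findSteadyState(net, red)
    sp <- makeSpace(anchor = det@anchor, gamma0 = 3, red = red)
    L <- buildGenerator(net, sp)@matrix
    tm <- as(L, "TsparseMatrix")
    keep <- tm@i != tm@j
    g <- igraph::graph_from_edgelist(
      cbind(tm@j[keep] + 1L, tm@i[keep] + 1L))
    expect_true(igraph::is_connected(g, mode = "strong"))
  }
})

test_that("face masses report edge probability correctly", {
  bd <- birth_death_net(k0 = 1, kd = 1)
  red <- reduceNetwork(bd)
  sp <- makeSpace(red = red, alpha = 0L, beta = 2L)
  # point mass strictly inside: zero on both faces
  p_point <- c(0, 1, 0)
  expect_equal(boundaryMass(p_point, sp, 1, "left"), 0)
  expect_equal(boundaryMass(p_point, sp, 1, "right"), 0)
  # uniform: each face holds 1/3
  p_unif <- rep(1 / 3, 3)
  expect_equal(boundaryMass(p_unif, sp, 1, "left"), 1 / 3)
  expect_equal(boundaryMass(p_unif, sp, 1, "right"), 1 / 3)
  # Poisson(10) truncated to [0, 40]: right face is deep in the tail
  bd10 <- birth_death_net(k0 = 10, kd = 1)
  sp40 <- makeSpace(red = reduceNetwork(bd10), alpha = 0L, beta = 40L)
  gen <- buildGenerator(bd10, sp40)
  p <- solveAnchored(gen, stateIndex(sp40, 10L))$p
  expect_lt(boundaryMass(p, sp40, 1, "right"), 1e-12)
})
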