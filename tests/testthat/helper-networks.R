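# Fixture networks built in code, plus shared expectations.

birth_death_net <- function(k0 = 10, kd = 1) {
  parseReactionNetwork(c(
    "species A init 0",
    sprintf("reaction b: 0 -> A @ %.17g", k0),
    sprintf("reaction d: A -> 0 @ %.17g", kd)))
}

isomerization_net <- function(total = 10, kf = 1, kb = 1) {
  parseReactionNetwork(c(
    sprintf("species A init %d", total),
    "species B init 0",
    sprintf("reaction f: A -> B @ %.17g", kf),
    sprintf("reaction b: B -> A @ %.17g", kb)))
}

cv2_net <- function(k3 = 1.3282, km3 = 0.01, k4 = 1.3282, km4 = 0.01,
                    A = 0.4, dTotal = 105) {
  buildCv2Network(k3 = k3, km3 = km3, k4 = k4, km4 = km4, A = A,
                  dTotal = dTotal)
}

# random small mass-action networks with strictly positive rates; both
# coordinates connected so the truncated chain is irreducible
random_fixture_net <- function() {
  d <- sample(1:2, 1)
  r <- function() round(stats::runif(1, 0.2, 5), 3)
  if (d == 1) {
    birth_death_net(k0 = r() * 4, kd = r())
  } else {
    parseReactionNetwork(c(
      "species A init 0", "species B init 0",
      sprintf("reaction bA: 0 -> A @ %.17g", r() * 4),
      sprintf("reaction dA: A -> 0 @ %.17g", r()),
      sprintf("reaction bB: 0 -> B @ %.17g", r() * 3),
      sprintf("reaction dB: B -> 0 @ %.17g", r()),
      sprintf("reaction c: A -> B @ %.17g", r()),
      sprintf("reaction u: B -> A @ %.17g", r())))
  }
}

# box around the deterministic anchor (the anchored solve presumes the
# stationary mode lies inside the box and near the anchor)
random_fixture_space <- function(net, max_states = 2000) {
  red <- reduceNetwork(net)
  d <- length(red@keep)
  w <- if (d == 1) sample(10:40, 1) else sample(4:12, 1)
  det <- findSteadyState(net, red)
  sp <- makeSpace(anchor = det@anchor, gamma0 = w, red = red)
  attr(sp, "anchor") <- det@anchor
  sp
}

# stationarity conditions every solved distribution must satisfy
expect_valid_distribution <- function(dist, net) {
  p <- probabilities(dist)
  expect_true(all(p >= 0))
  expect_lt(abs(sum(p) - 1), 1e-12)
  gen <- buildGenerator(net, dist@space)
  resid <- max(abs(gen@matrix %*% p))
  expect_lte(resid, 1e-9 * max(abs(gen@matrix@x)))
  invisible(dist)
}
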