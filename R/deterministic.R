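# Deterministic steady state, anchoring, uniqueness heuristic and ligand
# calibration.

#' Deterministic mass-action right-hand side
#'
#' `dy/dt = sum_mu nu_mu a_mu(y)` with the continuous mass-action rule: the
#' combinatorial factor `X(X-1)/2` of a doubled reactant becomes `y^2/2`.
#' Clamped species multiply at their clamp value.
#'
#' @param net a [ReactionNetwork-class].
#' @param y nonnegative numeric state over the dynamic species.
#' @return named numeric derivative vector.
#' @export
odeRHS <- function(net, y) {
  kin <- .reaction_kinetics(net)
  nu <- stateChangeMatrix(net)
  a <- vapply(kin, function(k) {
    v <- k$rate
    if (length(k$idx)) {
      for (q in seq_along(k$idx)) {
        x <- y[[k$idx[q]]]
        v <- v * if (k$coef[q] == 1L) x else x^2 / 2
      }
    }
    v
  }, numeric(1))
  drop(nu %*% a)
}

# rhs restricted to kept coordinates, eliminated species substituted
.reduced_rhs <- function(red, kin, nu_keep) {
  force(red); force(kin); force(nu_keep)
  n <- length(dynamicSpecies(red@network))
  function(z) {
    full <- numeric(n)
    full[red@keep] <- z
    if (length(red@eliminated)) {
      for (v in seq_along(red@eliminated)) {
        full[red@eliminated[v]] <-
          red@totals[v] - sum(red@basis[v, red@keep] * z)
      }
    }
    a <- vapply(kin, function(k) {
      vv <- k$rate
      if (length(k$idx)) {
        for (q in seq_along(k$idx)) {
          x <- full[k$idx[q]]
          vv <- vv * if (k$coef[q] == 1L) x else x^2 / 2
        }
      }
      vv
    }, numeric(1))
    drop(nu_keep %*% a)
  }
}

#' Deterministic steady state of the mass-action ODEs
#'
#' Integrates the conservation-reduced ODE system to near-stationarity, then
#' polishes with damped Newton (numerical Jacobian, step halving on residual
#' increase). Working in reduced coordinates preserves all conserved totals
#' exactly and keeps the Jacobian nonsingular for the networks this package
#' targets.
#'
#' @param net a [ReactionNetwork-class].
#' @param red optional precomputed [ConservationReduction-class].
#' @param init optional initial kept-coordinate vector (defaults to the
#'   declared initial counts).
#' @param tol relative residual tolerance on the converged state.
#' @param maxNewton maximum Newton iterations.
#' @return a [DeterministicSteadyState-class].
#' @export
#' @examples
#' bd <- parseReactionNetwork(c("species A init 0",
#'   "reaction b: 0 -> A @ 10", "reaction d: A -> 0 @ 1"))
#' findSteadyState(bd)@Y0   # 10
findSteadyState <- function(net, red = NULL, init = NULL, tol = 1e-10,
                            maxNewton = 60L) {
  if (is.null(red)) red <- reduceNetwork(net)
  kin <- .reaction_kinetics(net)
  nu <- stateChangeMatrix(net)
  nu_keep <- nu[red@keep, , drop = FALSE]
  g <- .reduced_rhs(red, kin, nu_keep)
  z <- if (is.null(init)) as.numeric(initialCounts(net)[red@keep]) else as.numeric(init)
  d <- length(z)

  if (d == 0) {
    y0 <- reconstructStates(red, matrix(numeric(0), 1, 0))[1, ]
    return(new("DeterministicSteadyState",
               Y0 = as.numeric(y0), anchor = integer(0),
               anchorFull = as.integer(y0),
               residual = 0, converged = TRUE, iterations = 0L))
  }

  # stage 1: relax by integration until the reduced rhs is small
  ode_fn <- function(t, state, parms) list(g(state))
  t_span <- 10
  scale <- 1 + max(abs(z), 1)
  for (rep in 1:14) {
    if (max(abs(g(z))) < 1e-6 * scale) break
    sol <- suppressWarnings(deSolve::ode(
      y = z, times = c(0, t_span), func = ode_fn, parms = NULL,
      method = "bdf", rtol = 1e-8, atol = 1e-8, maxsteps = 1e5))
    z <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    t_span <- t_span * 4
    scale <- 1 + max(abs(z), 1)
  }

  # stage 2: damped Newton
  jac <- function(z) {
    # central differences; coordinates span many decades (free receptor
    # pools vs near-zero intermediates), so the step is relative with a floor
    J <- matrix(0, d, d)
    for (i in seq_len(d)) {
      h <- max(1e-7 * abs(z[i]), 1e-8)
      zp <- z; zp[i] <- zp[i] + h
      zm <- z; zm[i] <- zm[i] - h
      J[, i] <- (g(zp) - g(zm)) / (2 * h)
    }
    J
  }
  it <- 0L
  resid <- max(abs(g(z)))
  while (it < maxNewton) {
    fz <- g(z)
    resid <- max(abs(fz))
    if (resid <= tol * (1 + max(abs(z)))) break
    step <- tryCatch(solve(jac(z), -fz), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (h in 1:30) {
      znew <- z + lambda * step
      if (all(znew > -1e-9 * (1 + max(abs(z))))) {
        fn <- max(abs(g(pmax(znew, 0))))
        if (fn < resid) {
          z <- pmax(znew, 0); improved <- TRUE; break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    it <- it + 1L
  }
  resid <- max(abs(g(z)))
  converged <- resid <= tol * (1 + max(abs(z)))
  if (!converged) {
    # fallback: prolonged integration
    for (rep in 1:6) {
      sol <- suppressWarnings(deSolve::ode(
        y = z, times = c(0, 10^(6 + rep)), func = ode_fn, parms = NULL,
        method = "bdf", rtol = 1e-12, atol = 1e-12, maxsteps = 1e5))
      z <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
      resid <- max(abs(g(z)))
      if (resid <= tol * (1 + max(abs(z)))) break
    }
    converged <- resid <= tol * (1 + max(abs(z)))
  }
  if (any(z < 0)) {
    if (any(z < -1e-9)) stop("steady state has a negative component")
    z[z < 0] <- 0
  }
  y0_full <- numeric(length(dynamicSpecies(net)))
  y0_full[red@keep] <- z
  if (length(red@eliminated)) {
    for (v in seq_along(red@eliminated)) {
      y0_full[red@eliminated[v]] <-
        red@totals[v] - sum(red@basis[v, red@keep] * z)
    }
  }
  names(y0_full) <- dynamicSpecies(net)
  anchor <- roundToAnchor(z, red)
  full <- reconstructStates(red, anchor)[1, ]
  new("DeterministicSteadyState",
      Y0 = y0_full, anchor = anchor, anchorFull = full,
      residual = resid, converged = converged, iterations = it)
}

#' Round a steady state to its discrete anchor
#'
#' Componentwise round-half-away-from-zero, then deterministic clipping into
#' feasibility: while any reconstructed eliminated count is negative, the
#' largest kept coordinate contributing to the most negative violation is
#' decremented (ties broken by lowest index).
#'
#' @param y nonnegative numeric vector in kept coordinates.
#' @param red optional [ConservationReduction-class]; when supplied the
#'   result is clipped so all reconstructed eliminated counts are
#'   nonnegative.
#' @return integer anchor vector in kept coordinates.
#' @export
#' @examples
#' roundToAnchor(c(2.4, 7.5))  # 2, 8
roundToAnchor <- function(y, red = NULL) {
  if (any(y < 0)) stop("y must be nonnegative")
  x <- as.integer(floor(y + 0.5))   # round half away from zero (y >= 0)
  if (is.null(red) || length(red@eliminated) == 0) return(x)
  caps <- red@caps
  x <- pmin(x, ifelse(is.finite(caps), as.integer(caps), x))
  repeat {
    elim <- red@totals - as.numeric(red@basis[, red@keep, drop = FALSE] %*% x)
    if (all(elim >= 0)) break
    v <- which.min(elim)
    contrib <- which(red@basis[v, red@keep] > 0 & x > 0)
    if (length(contrib) == 0) stop("cannot clip anchor into feasibility")
    i <- contrib[which.max(x[contrib])]
    x[i] <- x[i] - 1L
  }
  x
}

#' Heuristic uniqueness check for the deterministic steady state
#'
#' Runs [findSteadyState()] from random initial allocations consistent with
#' the conserved totals and clusters the fixed points at relative tolerance
#' 1e-6. A report, not a proof: the stationary solver requires a unique
#' deterministic equilibrium as a precondition.
#'
#' @param net a [ReactionNetwork-class].
#' @param nStarts number of random starts (>= 2).
#' @param seed RNG seed; identical seeds give identical reports.
#' @return list with `unique` (flag), `nFixedPoints`, `fixedPoints` (matrix
#'   of distinct kept-coordinate equilibria) and `failures`.
#' @export
checkUniqueSS <- function(net, nStarts = 20L, seed = 1L) {
  stopifnot(nStarts >= 2)
  red <- reduceNetwork(net)
  d <- length(red@keep)
  set.seed(seed)
  caps <- ifelse(is.finite(red@caps), red@caps,
                 2 * pmax(findSteadyState(net, red)@Y0[red@keep], 10))
  sols <- list()
  failures <- 0L
  for (s in seq_len(nStarts)) {
    z0 <- NULL
    for (try in 1:200) {
      cand <- round(stats::runif(d, 0, caps))
      elim <- red@totals - as.numeric(red@basis[, red@keep, drop = FALSE] %*% cand)
      if (length(elim) == 0 || all(elim >= 0)) { z0 <- cand; break }
    }
    if (is.null(z0)) { failures <- failures + 1L; next }
    fit <- tryCatch(findSteadyState(net, red, init = z0),
                    error = function(e) NULL)
    if (is.null(fit) || !fit@converged) { failures <- failures + 1L; next }
    sols[[length(sols) + 1]] <- fit@Y0[red@keep]
  }
  pts <- do.call(rbind, sols)
  clusters <- list()
  if (!is.null(pts)) {
    for (r in seq_len(nrow(pts))) {
      hit <- FALSE
      for (cl in seq_along(clusters)) {
        ref <- clusters[[cl]]
        if (max(abs(pts[r, ] - ref)) <= 1e-6 * (1 + max(abs(ref)))) {
          hit <- TRUE; break
        }
      }
      if (!hit) clusters[[length(clusters) + 1]] <- pts[r, ]
    }
  }
  fp <- do.call(rbind, clusters)
  list(unique = length(clusters) == 1, nFixedPoints = length(clusters),
       fixedPoints = fp, failures = failures)
}

#' Calibrate a clamped species to hit a target steady-state level
#'
#' Bisection on the clamp level (with automatic upper-bracket expansion)
#' until the deterministic steady state of `targetSpecies` equals
#' `targetValue` to relative tolerance `tol`. Requires the steady state to
#' increase with the clamp level across the bracket, which holds for the
#' ligand level in the binding networks this package ships.
#'
#' @param build function taking a clamp level and returning a
#'   [ReactionNetwork-class].
#' @param targetSpecies dynamic species name to calibrate.
#' @param targetValue positive target level (copies).
#' @param bracket initial search interval for the clamp level.
#' @param tol relative tolerance on the achieved level.
#' @param maxExpand maximum upper-bracket doublings.
#' @return the calibrated clamp level (numeric scalar) with attribute
#'   `achieved`.
#' @export
#' @examples
#' a <- calibrateLigand(
#'   function(a) buildTypeIINetwork("I", B = a, r1Total = 100),
#'   "BR1", 30)
#' findSteadyState(buildTypeIINetwork("I", B = a, r1Total = 100))@Y0[["BR1"]]
calibrateLigand <- function(build, targetSpecies, targetValue,
                            bracket = c(0, 1), tol = 1e-9,
                            maxExpand = 60L) {
  stopifnot(targetValue >= 0)
  if (targetValue == 0) return(structure(0, achieved = 0))
  warm <- NULL   # warm-start consecutive solves along the bisection
  ss_at <- function(a) {
    net <- build(a)
    red <- reduceNetwork(net)
    fit <- findSteadyState(net, red, init = warm)
    warm <<- fit@Y0[red@keep]
    fit@Y0[[targetSpecies]]
  }
  # feasibility: target must not exceed the conserved pool of the species
  net0 <- build(bracket[2])
  red <- reduceNetwork(net0)
  ti <- match(targetSpecies, dynamicSpecies(net0))
  if (is.na(ti)) stop(sprintf("unknown species '%s'", targetSpecies))
  pool <- Inf
  if (nrow(red@basis)) {
    for (v in seq_len(nrow(red@basis))) {
      w <- red@basis[v, ti]
      if (w > 0) pool <- min(pool, red@totals[v] / w)
    }
  }
  if (targetValue >= pool) {
    stop(sprintf("target %g infeasible: conserved pool limits %s to < %g",
                 targetValue, targetSpecies, pool))
  }
  lo <- max(bracket[1], 0)
  hi <- max(bracket[2], lo + 1e-12)
  f_lo <- ss_at(lo) - targetValue
  if (f_lo > 0) stop("non-monotone bracket: lower end already exceeds the target")
  f_hi <- ss_at(hi) - targetValue
  n_exp <- 0L
  while (f_hi < 0 && n_exp < maxExpand) {
    hi <- hi * 4
    f_hi <- ss_at(hi) - targetValue
    n_exp <- n_exp + 1L
  }
  if (f_hi < 0) stop("could not bracket the target within the expansion cap")
  achieved <- NA_real_
  mid <- (lo + hi) / 2
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    v <- ss_at(mid)
    achieved <- v
    if (abs(v - targetValue) <= tol * targetValue) break
    if (v < targetValue) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-15 * max(1, hi)) break
  }
  structure(mid, achieved = achieved)
}

setMethod("show", "DeterministicSteadyState", function(object) {
  cat("DeterministicSteadyState\n")
  cat("  Y0:", paste(sprintf("%s=%.6g", names(object@Y0), object@Y0),
                     collapse = ", "), "\n")
  cat("  anchor X0:", paste(sprintf("%s=%d", names(object@anchorFull),
                                    object@anchorFull), collapse = ", "), "\n")
  cat(sprintf("  residual %.3e, converged: %s\n", object@residual,
              object@converged))
  invisible(object)
})
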