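# Stationary solver: anchored linear system, dense eigen oracle, adaptive
# box expansion.

#' Solve the anchored stationary linear system
#'
#' The stationary condition `L q = 0` with the anchor entry pinned,
#' `q[j] = 1`, is equivalent (columns of `L` sum to zero, so one equation is
#' redundant) to the nonsingular system over the remaining entries:
#' `L[-j, -j] q' = -L[-j, j]`. The solution is assembled as
#' `P = q / eta` with `eta = 1 + sum(q')`, so `P` sums to one and
#' `P[j] = 1/eta`.
#'
#' Small systems (`K <= denseLimit`) are solved densely by LAPACK; larger
#' ones by ILU(0)-preconditioned BiCGSTAB with restarting and a true-residual
#' check, falling back to a sparse LU factorization if the iteration fails
#' to converge.
#'
#' @param gen a [GeneratorMatrix-class] (or a plain square matrix whose
#'   columns sum to zero).
#' @param j anchor state index.
#' @param clipTol entries of `P` in `(-clipTol, 0)` are clipped to zero;
#'   anything more negative is a hard error.
#' @param denseLimit largest K solved densely.
#' @param iterTol relative residual target of the iterative path.
#' @param x0 optional initial guess for the unnormalized solution `q`
#'   (length K, anchor entry included), e.g. a solution from a smaller
#'   embedded box.
#' @return list with `p` (probability vector), `eta`, `method` and `resid`
#'   (relative residual of the linear solve).
#' @export
#' @examples
#' net <- parseReactionNetwork(c("species A init 0",
#'   "reaction b: 0 -> A @ 1", "reaction d: A -> 0 @ 1"))
#' red <- reduceNetwork(net)
#' sp <- makeSpace(alpha = 0L, beta = 2L, red = red)
#' gen <- buildGenerator(net, sp)
#' solveAnchored(gen, j = stateIndex(sp, 1L))$p   # 0.4 0.4 0.2
solveAnchored <- function(gen, j, clipTol = 1e-12, denseLimit = 1500L,
                          iterTol = 1e-10, x0 = NULL) {
  L <- if (is(gen, "GeneratorMatrix")) gen@matrix else gen
  K <- nrow(L)
  stopifnot(j >= 1, j <= K)
  if (K == 1) {
    return(list(p = 1, eta = 1, method = "trivial", resid = 0))
  }
  if (length(L@x) == 0 || max(abs(L@x)) == 0) {
    # no retained transitions: stationary law is the point mass at the anchor
    p <- numeric(K); p[j] <- 1
    return(list(p = p, eta = 1, method = "point-mass", resid = 0))
  }
  Lpp <- L[-j, -j, drop = FALSE]
  b <- -as.numeric(L[-j, j])
  method <- NULL
  resid <- NA_real_
  qp <- NULL
  if (K <= denseLimit) {
    qp <- tryCatch(solve(as.matrix(Lpp), b),
                   error = function(e) {
                     stop(paste0("anchored system is singular (reducible ",
                                 "truncated chain): apply conservation ",
                                 "reduction / check network connectivity"),
                          call. = FALSE)
                   })
    method <- "dense"
    bn <- max(abs(b))
    resid <- if (bn > 0) max(abs(Lpp %*% qp - b)) / bn else 0
  } else {
    Lc <- as(Lpp, "CsparseMatrix")
    guess <- if (is.null(x0)) numeric(0) else as.numeric(x0[-j])
    it <- anchored_bicgstab(Lc@p, Lc@i, Lc@x, as.integer(K - 1L), b,
                            iterTol, 8000L, guess)
    bn <- max(abs(b))
    if (isTRUE(it$ok)) {
      qp <- it$x
      resid <- if (bn > 0) max(abs(Lpp %*% qp - b)) / bn else 0
    }
    method <- "bicgstab"
    if (is.null(qp) || !is.finite(resid) || resid > 1e-6) {
      qp <- tryCatch(as.numeric(Matrix::solve(Lpp, b)),
                     error = function(e) {
                       stop(paste0("anchored system could not be solved ",
                                   "(reducible truncated chain?)"),
                            call. = FALSE)
                     })
      method <- "sparse-lu"
      resid <- if (bn > 0) max(abs(Lpp %*% qp - b)) / bn else 0
    }
  }
  q <- numeric(K)
  q[-j] <- qp
  q[j] <- 1
  eta <- 1 + sum(qp)
  p <- q / eta
  neg <- p < 0
  if (any(neg)) {
    worst <- min(p)
    # roundoff scales with the accuracy of the linear solve: the iterative
    # path is allowed slack proportional to its achieved residual, the
    # direct paths keep the stated clip tolerance
    slack <- if (identical(method, "bicgstab")) {
      max(clipTol, 1e3 * resid * max(abs(p)), na.rm = TRUE)
    } else {
      clipTol
    }
    if (worst < -slack) {
      stop(sprintf(
        "numerical failure: stationary entry %.3e below tolerance -%.1e",
        worst, slack))
    }
    p[neg] <- 0
    p <- p / sum(p)
  }
  list(p = p, eta = eta, method = method, resid = resid)
}

#' Dense null-space oracle for the truncated generator
#'
#' Computes the full eigendecomposition of a dense copy of the generator and
#' returns the (sign-fixed, normalized) eigenvector of the eigenvalue
#' nearest zero. Quadratic memory and cubic time: a test oracle for the
#' anchored linear solve, refused above `K = 2000`.
#'
#' @param gen a [GeneratorMatrix-class] or square matrix.
#' @return probability vector of length K.
#' @export
eigenOracle <- function(gen) {
  L <- if (is(gen, "GeneratorMatrix")) gen@matrix else gen
  K <- nrow(L)
  if (K > 2000) stop("eigenOracle refuses K > 2000 (dense decomposition)")
  if (K == 1) return(1)
  Ld <- as.matrix(L)
  ev <- eigen(Ld)
  lam <- abs(ev$values)
  scale <- max(abs(Ld))
  null_ix <- which(lam < 1e-8 * max(scale, 1))
  if (length(null_ix) == 0) null_ix <- which.min(lam)
  if (length(null_ix) > 1) {
    stop("zero eigenvalue has multiplicity > 1: truncated chain is reducible")
  }
  v <- Re(ev$vectors[, null_ix])
  s <- sum(v)
  if (s < 0) v <- -v
  v[v < 0 & v > -1e-12] <- 0
  if (any(v < 0)) {
    v[abs(v) < 1e-10 * max(abs(v))] <- 0
    if (any(v < 0)) stop("null-space vector is not sign-definite")
  }
  v / sum(v)
}

#' Stationary distribution by adaptive truncated-space expansion
#'
#' The full pipeline: deterministic steady state, anchor rounding, box
#' initialization, generator assembly and anchored solve; then, while any
#' expandable face of the box carries probability mass `>= eps`, that
#' coordinate is widened by `gamma` on both sides and the system re-solved.
#' Faces pinned at zero or at a conservation cap are exact (no truncation
#' happens there) and do not trigger expansion.
#'
#' @param net a [ReactionNetwork-class] with a unique deterministic steady
#'   state (see [checkUniqueSS()]).
#' @param eps face-mass tolerance controlling the truncation error.
#' @param gamma0 initial half-width; default
#'   `max(5, ceiling(4 * sqrt(max(Y0_i, 1))))` per coordinate (a Gaussian
#'   spread heuristic around the deterministic mean).
#' @param gamma per-expansion widening.
#' @param maxExpansions cap on expansion rounds.
#' @param clipTol,denseLimit passed to [solveAnchored()].
#' @return a [SteadyStateDistribution-class].
#' @export
#' @examples
#' bd <- parseReactionNetwork(c("species A init 0",
#'   "reaction b: 0 -> A @ 10", "reaction d: A -> 0 @ 1"))
#' dist <- adaptiveSolve(bd, eps = 1e-6, gamma0 = 2, gamma = 5)
#' noiseSummary(dist)     # Poisson(10): mean 10, cv ~ 0.316
adaptiveSolve <- function(net, eps = 1e-6, gamma0 = NULL, gamma = 5L,
                          maxExpansions = 50L, clipTol = 1e-12,
                          denseLimit = 1500L) {
  stopifnot(eps > 0, eps < 1)
  red <- reduceNetwork(net)
  det <- findSteadyState(net, red)
  if (!det@converged) {
    stop("deterministic steady state did not converge; cannot anchor")
  }
  y_keep <- pmax(det@Y0[red@keep], 0)
  if (is.null(gamma0)) {
    gamma0 <- pmax(5, ceiling(4 * sqrt(pmax(y_keep, 1))))
  }
  gamma <- as.integer(gamma)
  anchor <- det@anchor
  d <- length(anchor)
  alpha <- pmax(0L, anchor - as.integer(rep_len(gamma0, d)))
  beta <- anchor + as.integer(rep_len(gamma0, d))
  expansions <- 0L
  prev <- NULL
  repeat {
    space <- makeSpace(red = red, alpha = alpha, beta = beta)
    alpha <- space@alpha; beta <- space@beta    # after caps
    gen <- buildGenerator(net, space)
    j <- stateIndex(space, anchor)
    if (is.na(j)) stop("anchor state fell outside the truncated space")
    x0 <- NULL
    if (!is.null(prev)) {
      # warm start: embed the previous (smaller-box) unnormalized solution
      off <- sweep(prev$space@states, 2, space@alpha, "-")
      idx <- space@lookup[drop(off %*% space@strides) + 1]
      ok <- !is.na(idx)
      x0 <- numeric(nrow(space@states))
      x0[idx[ok]] <- prev$q[ok]
    }
    sol <- solveAnchored(gen, j, clipTol = clipTol, denseLimit = denseLimit,
                         x0 = x0)
    prev <- list(space = space, q = sol$p * sol$eta)
    masses <- matrix(0, d, 2, dimnames = list(NULL, c("left", "right")))
    expandable <- matrix(TRUE, d, 2, dimnames = list(NULL, c("left", "right")))
    for (i in seq_len(d)) {
      masses[i, 1] <- boundaryMass(sol$p, space, i, "left")
      masses[i, 2] <- boundaryMass(sol$p, space, i, "right")
      expandable[i, 1] <- alpha[i] > 0
      cap <- red@caps[i]
      expandable[i, 2] <- !(is.finite(cap) && beta[i] >= cap)
    }
    trigger <- which(apply(masses >= eps & expandable, 1, any))
    if (length(trigger) == 0 || expansions >= maxExpansions) break
    if (d == 0) break
    alpha[trigger] <- pmax(0L, alpha[trigger] - gamma)
    beta[trigger] <- beta[trigger] + gamma
    expansions <- expansions + 1L
  }
  if (length(trigger) > 0) {
    warning(sprintf(
      "expansion cap reached with max face mass %.3e >= eps %.1e",
      max(masses[expandable]), eps))
  }
  kept_names <- dynamicSpecies(net)[red@keep]
  rownames(masses) <- kept_names
  rownames(expandable) <- kept_names
  dist <- new("SteadyStateDistribution",
              space = space, p = sol$p, anchorIndex = as.integer(j),
              eta = sol$eta, faceMasses = masses,
              faceExpandable = expandable, expansions = expansions,
              deterministic = det,
              settings = list(eps = eps, gamma0 = gamma0, gamma = gamma,
                              maxExpansions = maxExpansions,
                              clipTol = clipTol, denseLimit = denseLimit,
                              method = sol$method, solveResid = sol$resid))
  validObject(dist)
  dist
}

#' @rdname stateCount
#' @export
setMethod("stateCount", "SteadyStateDistribution",
          function(x) nrow(x@space@states))

#' @rdname stateCount
#' @export
setMethod("probabilities", "SteadyStateDistribution", function(x) x@p)

#' @rdname stateCount
#' @export
setMethod("stateMatrix", "SteadyStateDistribution", function(x, full = FALSE) {
  stateMatrix(x@space, full = full)
})

#' Total boundary probability mass of a solved distribution
#'
#' Mass of the union of the box faces where truncation actually happens:
#' a proxy upper bound for the tail probability that the truncation
#' redistributed into the box (the renormalized solution itself always
#' sums to one). Faces pinned at zero or at a conservation cap are exact
#' and are not counted. A single-state space with free faces returns 1 by
#' convention (its faces are the whole space).
#'
#' @param dist a [SteadyStateDistribution-class].
#' @return numeric scalar in [0, 1].
#' @export
capturedMassDeficit <- function(dist) {
  sp <- dist@space
  st <- sp@states
  caps <- sp@reduction@caps
  on_face <- rep(FALSE, nrow(st))
  for (i in seq_len(ncol(st))) {
    if (sp@alpha[i] > 0) on_face <- on_face | st[, i] == sp@alpha[i]
    if (!(is.finite(caps[i]) && sp@beta[i] >= caps[i])) {
      on_face <- on_face | st[, i] == sp@beta[i]
    }
  }
  sum(dist@p[on_face])
}

setMethod("show", "SteadyStateDistribution", function(object) {
  cat(sprintf(
    "SteadyStateDistribution: K = %d states, eta = %.6g, %d expansion(s)\n",
    length(object@p), object@eta, object@expansions))
  ns <- noiseSummary(object)
  for (r in seq_len(nrow(ns))) {
    cat(sprintf("  %-8s mean %10.4f  sd %9.4f  cv %s\n", ns$species[r],
                ns$mean[r], ns$sd[r],
                ifelse(is.na(ns$cv[r]), "NA", sprintf("%.6f", ns$cv[r]))))
  }
  mx <- max(object@faceMasses[object@faceExpandable], 0)
  cat(sprintf("  max expandable-face mass %.3e\n", mx))
  invisible(object)
})
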