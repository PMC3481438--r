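# Conservation-law detection and reduction to independent coordinates.
#
# The truncated chain must be irreducible on its feasible set: enumerating a
# full box over all dynamic species of a network with conserved pools would
# include states unreachable from the anchor and make the anchored linear
# system singular. Reduction is therefore applied before any truncation.

# Rational reconstruction of a double by continued fractions.
.rationalize <- function(x, maxden = 1e6, tol = 1e-9) {
  if (abs(x) < tol) return(c(0, 1))
  sgn <- sign(x); x <- abs(x)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; b <- x
  repeat {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > maxden) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(x - h / k) < tol * max(1, abs(x))) break
    if (abs(b - a) < 1e-14) break
    b <- 1 / (b - a)
  }
  c(sgn * h1, k1)
}

.gcd2 <- function(a, b) if (b == 0) abs(a) else .gcd2(b, a %% b)

# Scale a rational-valued vector to the smallest integer vector, first
# nonzero entry positive. Errors if entries cannot be rationalized.
.to_integer_vector <- function(v) {
  rats <- t(vapply(v, .rationalize, numeric(2)))
  den <- 1
  for (d in rats[, 2]) den <- den * d / .gcd2(den, d)
  ints <- round(rats[, 1] * (den / rats[, 2]))
  g <- 0
  for (z in ints) g <- .gcd2(g, z)
  if (g > 0) ints <- ints / g
  nz <- which(ints != 0)
  if (length(nz) && ints[nz[1]] < 0) ints <- -ints
  as.integer(ints)
}

# Reduced row-echelon form with partial pivoting; columns scanned in the
# given order. Returns the echelon matrix and pivot columns.
.rref <- function(A, col_order = seq_len(ncol(A)), tol = 1e-9) {
  A <- as.matrix(A) * 1.0
  m <- nrow(A)
  piv_rows <- integer(0)
  piv_cols <- integer(0)
  r <- 1L
  for (cc in col_order) {
    if (r > m) break
    p <- which.max(abs(A[r:m, cc])) + r - 1L
    if (abs(A[p, cc]) < tol) next
    if (p != r) A[c(p, r), ] <- A[c(r, p), ]
    A[r, ] <- A[r, ] / A[r, cc]
    for (q in seq_len(m)) {
      if (q != r && abs(A[q, cc]) > tol) A[q, ] <- A[q, ] - A[q, cc] * A[r, ]
    }
    piv_rows <- c(piv_rows, r)
    piv_cols <- c(piv_cols, cc)
    r <- r + 1L
  }
  list(mat = A, pivots = piv_cols, rank = length(piv_cols))
}

#' Conservation laws of a reaction network
#'
#' Maximal independent set of integer weight vectors `w` over the dynamic
#' species with `w' nu_mu = 0` for every reaction, each scaled to smallest
#' integers, together with the conserved totals `w' X(0)`. The basis is
#' arranged so that each vector carries unit weight on one species (its
#' pivot, the lowest-index unit-weight candidate) that appears in no other
#' vector; these pivots are the species eliminated by [reduceNetwork()].
#'
#' @param net a [ReactionNetwork-class].
#' @return list with `basis` (integer matrix, one vector per row, columns in
#'   dynamic-species order; zero rows if the network is open) and `totals`.
#' @export
#' @examples
#' net <- parseReactionNetwork(c(
#'   "species A init 10", "species B init 0",
#'   "reaction f: A -> B @ 1", "reaction b: B -> A @ 1"))
#' conservationBasis(net)   # single vector (1, 1), total 10
conservationBasis <- function(net) {
  nu <- stateChangeMatrix(net)
  n <- nrow(nu)
  dyn <- rownames(nu)
  # left null space of nu = null space of t(nu); scan species columns in
  # reverse order so free (eliminated) species take the lowest indices
  ech <- .rref(t(nu), col_order = rev(seq_len(n)))
  free_cols <- sort(setdiff(seq_len(n), ech$pivots))
  if (length(free_cols) == 0) {
    return(list(basis = matrix(integer(0), 0, n, dimnames = list(NULL, dyn)),
                totals = numeric(0)))
  }
  basis <- matrix(0, length(free_cols), n, dimnames = list(NULL, dyn))
  for (v in seq_along(free_cols)) {
    f <- free_cols[v]
    w <- numeric(n)
    w[f] <- 1
    # back-substitute: pivot variables in terms of the free one
    for (r in seq_along(ech$pivots)) {
      pc <- ech$pivots[r]
      w[pc] <- -ech$mat[r, f]
    }
    basis[v, ] <- .to_integer_vector(w)
    if (basis[v, f] != 1) {
      stop("unsupported network: conservation vector without a unit-weight species")
    }
  }
  if (any(basis %*% nu != 0)) {
    stop("internal error: conservation basis failed exact verification")
  }
  x0 <- initialCounts(net)
  list(basis = basis, totals = as.numeric(basis %*% x0))
}

#' Reduce a network to independent coordinates
#'
#' One species is eliminated per conservation law (the basis pivot); the
#' remaining kept species are the independent coordinates over which state
#' spaces are enumerated. Reconstruction of eliminated counts from kept
#' counts is exact integer arithmetic: `X_e = T - sum(w * X_kept)`.
#'
#' @param net a [ReactionNetwork-class].
#' @return a [ConservationReduction-class].
#' @export
#' @examples
#' net <- buildCv2Network(k3 = 1, km3 = 0.1, k4 = 1, km4 = 0.1, A = 0.3)
#' red <- reduceNetwork(net)
#' dynamicSpecies(net)[red@keep]        # C, E, Z
#' dynamicSpecies(net)[red@eliminated]  # B, D
reduceNetwork <- function(net) {
  cb <- conservationBasis(net)
  dyn <- dynamicSpecies(net)
  n <- length(dyn)
  nb <- nrow(cb$basis)
  if (nb == 0) {
    red <- new("ConservationReduction", network = net,
               basis = cb$basis, totals = numeric(0),
               keep = seq_len(n), eliminated = integer(0),
               caps = rep(Inf, n))
    validObject(red)
    return(red)
  }
  eliminated <- integer(nb)
  for (v in seq_len(nb)) {
    # pivot: lowest-index unit-weight species unique to this vector
    cand <- which(cb$basis[v, ] == 1)
    cand <- cand[colSums(cb$basis[-v, cand, drop = FALSE] != 0) == 0]
    if (length(cand) == 0) {
      stop("unsupported network: no eliminable unit-weight species in a conservation law")
    }
    eliminated[v] <- cand[1]
  }
  if (anyDuplicated(eliminated)) {
    stop("unsupported network: conservation laws share their only pivot species")
  }
  keep <- setdiff(seq_len(n), eliminated)
  caps <- rep(Inf, length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    for (v in seq_len(nb)) {
      w <- cb$basis[v, k]
      if (w > 0) caps[i] <- min(caps[i], floor(cb$totals[v] / w))
    }
  }
  red <- new("ConservationReduction", network = net,
             basis = cb$basis, totals = cb$totals,
             keep = as.integer(keep), eliminated = as.integer(eliminated),
             caps = caps)
  validObject(red)
  red
}

#' Reconstruct full dynamic states from kept coordinates
#'
#' @param red a [ConservationReduction-class].
#' @param z integer matrix of kept-coordinate states (rows = states), or a
#'   single state vector.
#' @return integer matrix, one column per dynamic species in declaration
#'   order. Reconstruction is exact; no feasibility check is applied (counts
#'   may be negative for infeasible inputs).
#' @export
reconstructStates <- function(red, z) {
  if (is.null(dim(z))) z <- matrix(z, 1)
  dyn <- dynamicSpecies(red@network)
  full <- matrix(0L, nrow(z), length(dyn), dimnames = list(NULL, dyn))
  full[, red@keep] <- as.integer(z)
  if (length(red@eliminated)) {
    for (v in seq_along(red@eliminated)) {
      w <- red@basis[v, red@keep]
      full[, red@eliminated[v]] <-
        as.integer(red@totals[v] - z %*% w)
    }
  }
  full
}

setMethod("show", "ConservationReduction", function(object) {
  dyn <- dynamicSpecies(object@network)
  nb <- nrow(object@basis)
  cat(sprintf("ConservationReduction: %d conserved total(s), %d independent coordinate(s)\n",
              nb, length(object@keep)))
  if (nb) {
    for (v in seq_len(nb)) {
      terms <- dyn[object@basis[v, ] != 0]
      w <- object@basis[v, object@basis[v, ] != 0]
      cat(sprintf("  %s = %g\n",
                  paste(ifelse(w == 1, terms, paste0(w, " ", terms)),
                        collapse = " + "),
                  object@totals[v]))
    }
  }
  cat("  kept:", paste(dyn[object@keep], collapse = ", "), "\n")
  invisible(object)
})
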