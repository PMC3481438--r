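# Truncated state-space enumeration and sparse generator assembly.

#' Build a truncated state space around an anchor
#'
#' Box `alpha_i = max(0, X0_i - gamma0_i)`, `beta_i = X0_i + gamma0_i` per
#' kept coordinate, with `beta` additionally capped at the
#' conservation-implied maximum of the coordinate. States are enumerated in
#' lexicographic order (last coordinate fastest) and filtered to those whose
#' reconstructed eliminated counts are nonnegative.
#'
#' @param anchor integer anchor state in kept coordinates.
#' @param gamma0 initial half-width, scalar or per-coordinate (>= 1).
#' @param red a [ConservationReduction-class].
#' @param alpha,beta optional explicit bounds overriding the
#'   anchor/gamma0 construction.
#' @return a [TruncatedSpace-class].
#' @export
#' @examples
#' net <- parseReactionNetwork(c("species A init 0",
#'   "reaction b: 0 -> A @ 10", "reaction d: A -> 0 @ 1"))
#' sp <- makeSpace(anchor = 20L, gamma0 = 5, red = reduceNetwork(net))
#' stateCount(sp)   # 11 states: [15, 25]
makeSpace <- function(anchor = NULL, gamma0 = 5, red, alpha = NULL,
                      beta = NULL) {
  d <- length(red@keep)
  if (is.null(alpha) || is.null(beta)) {
    stopifnot(!is.null(anchor), all(gamma0 >= 1))
    gamma0 <- as.integer(rep_len(gamma0, d))
    anchor <- as.integer(anchor)
    alpha <- pmax(0L, anchor - gamma0)
    beta <- anchor + gamma0
  }
  alpha <- as.integer(pmax(alpha, 0L))
  caps <- red@caps
  beta <- as.integer(ifelse(is.finite(caps), pmin(beta, caps), beta))
  alpha <- pmin(alpha, beta)
  widths <- beta - alpha + 1L
  K0 <- prod(as.numeric(widths))
  if (K0 > 5e7) {
    stop(sprintf("truncated box too large to enumerate (%g positions)", K0))
  }
  # last coordinate varies fastest
  strides <- rev(cumprod(rev(c(as.numeric(widths[-1]), 1))))
  pos <- 0:(K0 - 1)
  states <- matrix(0L, K0, d)
  for (i in seq_len(d)) {
    states[, i] <- alpha[i] + as.integer((pos %/% strides[i]) %% widths[i])
  }
  # feasibility of eliminated counts
  feas <- rep(TRUE, K0)
  if (length(red@eliminated)) {
    for (v in seq_along(red@eliminated)) {
      w <- red@basis[v, red@keep]
      elim <- red@totals[v] - as.numeric(states %*% w)
      feas <- feas & (elim >= 0)
    }
  }
  if (!any(feas)) stop("empty feasible state set")
  states <- states[feas, , drop = FALSE]
  lookup <- rep(NA_integer_, K0)
  lookup[which(feas)] <- seq_len(nrow(states))
  sp <- new("TruncatedSpace", reduction = red, alpha = alpha, beta = beta,
            states = states, lookup = lookup, strides = strides)
  validObject(sp)
  sp
}

#' @rdname stateCount
#' @export
setMethod("stateCount", "TruncatedSpace", function(x) nrow(x@states))

#' @rdname stateCount
#' @export
setMethod("stateMatrix", "TruncatedSpace", function(x, full = FALSE) {
  if (full) reconstructStates(x@reduction, x@states) else x@states
})

#' Index of a kept-coordinate state within a space
#'
#' @param space a [TruncatedSpace-class].
#' @param state integer kept-coordinate vector.
#' @return integer index in 1..K, or `NA` if outside the box or infeasible.
#' @export
stateIndex <- function(space, state) {
  state <- as.integer(state)
  if (any(state < space@alpha) || any(state > space@beta)) return(NA_integer_)
  pos <- sum((state - space@alpha) * space@strides) + 1
  space@lookup[pos]
}

setMethod("show", "TruncatedSpace", function(object) {
  dyn <- dynamicSpecies(object@reduction@network)
  kept <- dyn[object@reduction@keep]
  cat(sprintf("TruncatedSpace: %d states over %d coordinate(s)\n",
              nrow(object@states), length(kept)))
  for (i in seq_along(kept)) {
    cat(sprintf("  %s in [%d, %d]\n", kept[i], object@alpha[i],
                object@beta[i]))
  }
  invisible(object)
})

#' Assemble the truncated probability-flow generator
#'
#' For each enumerated state `c` and reaction `mu` with propensity
#' `a_mu(c) > 0`: when `c + nu_mu` lies in the truncated space, `a_mu(c)` is
#' added at `[index(c + nu_mu), c]` and subtracted on the diagonal; when it
#' leaves the space the transition is dropped entirely (its propensity is
#' treated as zero, with no diagonal loss). Columns therefore sum to zero
#' and the matrix is a proper generator on the box.
#'
#' @param net a [ReactionNetwork-class] (must be the reduction's network).
#' @param space a [TruncatedSpace-class].
#' @return a [GeneratorMatrix-class].
#' @export
buildGenerator <- function(net, space) {
  red <- space@reduction
  states <- space@states
  K <- nrow(states)
  full <- reconstructStates(red, states)
  A <- .propensity_matrix(net, full)
  nu <- stateChangeMatrix(net)[red@keep, , drop = FALSE]
  M <- ncol(A)
  ii <- vector("list", M); jj <- vector("list", M); xx <- vector("list", M)
  diag_acc <- numeric(K)
  for (m in seq_len(M)) {
    a <- A[, m]
    src <- which(a > 0)
    if (length(src) == 0) next
    move <- nu[, m]
    tgt <- states[src, , drop = FALSE] +
      matrix(move, length(src), length(move), byrow = TRUE)
    inbox <- rep(TRUE, length(src))
    for (i in seq_along(move)) {
      if (move[i] != 0) {
        inbox <- inbox & tgt[, i] >= space@alpha[i] & tgt[, i] <= space@beta[i]
      }
    }
    src <- src[inbox]
    if (length(src) == 0) next
    tgt <- tgt[inbox, , drop = FALSE]
    off <- sweep(tgt, 2, space@alpha, "-")
    lin <- drop(off %*% space@strides) + 1
    idx <- space@lookup[lin]
    ok <- !is.na(idx)
    src <- src[ok]
    if (length(src) == 0) next
    idx <- idx[ok]
    rate <- A[src, m]
    ii[[m]] <- idx; jj[[m]] <- src; xx[[m]] <- rate
    diag_acc[src] <- diag_acc[src] + rate
  }
  i_all <- unlist(ii); j_all <- unlist(jj); x_all <- unlist(xx)
  if (length(i_all) == 0) {
    L <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(K, K))
  } else {
    L <- Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all, dims = c(K, K))
  }
  L <- L - Matrix::Diagonal(K, diag_acc)
  new("GeneratorMatrix", matrix = L, space = space)
}

#' @rdname stateCount
#' @export
setMethod("stateCount", "GeneratorMatrix", function(x) nrow(x@matrix))

setMethod("show", "GeneratorMatrix", function(object) {
  K <- nrow(object@matrix)
  cat(sprintf("GeneratorMatrix: %d x %d, %d nonzeros\n", K, K,
              length(object@matrix@x)))
  invisible(object)
})

#' Triplet dump of a generator (for debugging)
#'
#' @param gen a [GeneratorMatrix-class].
#' @return data.frame with columns `to`, `from`, `rate` (1-based state
#'   indices, off-diagonal inflows and diagonal outflows).
#' @export
generatorTriplets <- function(gen) {
  tm <- as(gen@matrix, "TsparseMatrix")
  data.frame(to = tm@i + 1L, from = tm@j + 1L, rate = tm@x)
}

#' Probability mass on one face of the truncated box
#'
#' @param p normalized probability vector over the space's states.
#' @param space a [TruncatedSpace-class].
#' @param coordinate kept-coordinate index (1-based) or name.
#' @param side `"left"` (face at `alpha_i`) or `"right"` (at `beta_i`).
#' @return the face probability mass.
#' @export
boundaryMass <- function(p, space, coordinate, side = c("left", "right")) {
  side <- match.arg(side)
  if (is.character(coordinate)) {
    kept <- dynamicSpecies(space@reduction@network)[space@reduction@keep]
    coordinate <- match(coordinate, kept)
  }
  edge <- if (side == "left") space@alpha[coordinate] else space@beta[coordinate]
  sum(p[space@states[, coordinate] == edge])
}
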