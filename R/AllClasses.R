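#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Matrix Matrix
#' @useDynLib steadyCME, .registration = TRUE
NULL

#' Mass-action reaction network
#'
#' Holds an ordered species table and an ordered reaction list for a
#' stochastic mass-action network. Species are either \emph{dynamic} (they
#' carry a copy number and appear in state-change vectors) or \emph{clamped}
#' (held at a fixed, possibly non-integer level; they multiply propensities
#' but never change). The class is the common input of the deterministic
#' steady-state solver, the truncated-space stationary solver and the
#' Gillespie simulator.
#'
#' @slot species data.frame with columns `name`, `role` ("dynamic" or
#'   "clamped"), `init` (initial copy number, `NA` for clamped species) and
#'   `clamp` (fixed level, `NA` for dynamic species), in declaration order.
#' @slot reactions list; each element has `label`, `reactants` and `products`
#'   (named integer vectors of stoichiometric coefficients) and `rate`
#'   (positive mass-action rate constant, molecule-based units).
#' @slot parameters named numeric vector of file-level parameters.
#'
#' @seealso [parseReactionNetwork()], [buildCv2Network()],
#'   [buildTypeIINetwork()]
#' @export
setClass("ReactionNetwork",
  representation(
    species = "data.frame",
    reactions = "list",
    parameters = "numeric"
  )
)

setValidity("ReactionNetwork", function(object) {
  sp <- object@species
  msgs <- character(0)
  need <- c("name", "role", "init", "clamp")
  if (!all(need %in% names(sp))) {
    return(sprintf("species table must have columns %s",
                   paste(need, collapse = ", ")))
  }
  if (anyDuplicated(sp$name)) msgs <- c(msgs, "species names must be unique")
  if (!all(sp$role %in% c("dynamic", "clamped"))) {
    msgs <- c(msgs, "species role must be 'dynamic' or 'clamped'")
  }
  dyn <- sp$role == "dynamic"
  if (any(dyn & (is.na(sp$init) | sp$init < 0 | sp$init != floor(sp$init)))) {
    msgs <- c(msgs, "dynamic species need a nonnegative integer initial count")
  }
  if (any(!dyn & (is.na(sp$clamp) | sp$clamp < 0))) {
    msgs <- c(msgs, "clamped species need a nonnegative clamp level")
  }
  if (any(dyn & !is.na(sp$clamp)) || any(!dyn & !is.na(sp$init))) {
    msgs <- c(msgs, "init is for dynamic species only, clamp for clamped only")
  }
  for (rx in object@reactions) {
    refs <- c(names(rx$reactants), names(rx$products))
    if (length(refs) == 0) {
      msgs <- c(msgs, sprintf("reaction '%s' has empty reactants and products",
                              rx$label))
    }
    bad <- setdiff(refs, sp$name)
    if (length(bad)) {
      msgs <- c(msgs, sprintf("reaction '%s' references undeclared species %s",
                              rx$label, paste(bad, collapse = ", ")))
    }
    if (!is.numeric(rx$rate) || length(rx$rate) != 1 || is.na(rx$rate) ||
        rx$rate <= 0) {
      msgs <- c(msgs, sprintf("reaction '%s' needs a positive rate constant",
                              rx$label))
    }
    dynr <- intersect(names(rx$reactants), sp$name[dyn])
    if (length(dynr) && sum(rx$reactants[dynr]) > 2) {
      msgs <- c(msgs, sprintf(
        "reaction '%s': reactant order over dynamic species exceeds 2",
        rx$label))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Conservation-law reduction of a reaction network
#'
#' Integer left null space of the state-change matrix, arranged so that each
#' basis vector owns one eliminated species (unit weight, appearing in no
#' other vector). Kept species form the independent coordinates over which
#' the truncated state space is enumerated; eliminated counts are
#' reconstructed exactly as `total - sum(weights * kept counts)`.
#'
#' @slot network the [ReactionNetwork-class] the reduction was computed from.
#' @slot basis integer matrix, one conservation vector per row, columns in
#'   dynamic-species order.
#' @slot totals numeric conserved totals, one per basis vector, from the
#'   initial counts.
#' @slot keep integer indices (into dynamic species) of the independent
#'   coordinates, ascending.
#' @slot eliminated integer indices of the eliminated species, one per basis
#'   vector.
#' @slot caps numeric upper bounds on each kept coordinate implied by the
#'   conservation totals (`Inf` when unconstrained).
#' @export
setClass("ConservationReduction",
  representation(
    network = "ReactionNetwork",
    basis = "matrix",
    totals = "numeric",
    keep = "integer",
    eliminated = "integer",
    caps = "numeric"
  )
)

setValidity("ConservationReduction", function(object) {
  nu <- stateChangeMatrix(object@network)
  if (nrow(object@basis) > 0) {
    if (ncol(object@basis) != nrow(nu)) {
      return("basis columns must match dynamic species")
    }
    r <- object@basis %*% nu
    if (any(r != 0)) return("basis vectors must annihilate all state changes")
    for (v in seq_len(nrow(object@basis))) {
      e <- object@eliminated[v]
      if (object@basis[v, e] != 1) {
        return("each basis vector must have unit weight at its eliminated species")
      }
    }
  }
  if (length(object@keep) + length(object@eliminated) != nrow(nu)) {
    return("keep and eliminated must partition the dynamic species")
  }
  TRUE
})

#' Deterministic steady state and its discrete anchor
#'
#' @slot Y0 named numeric steady state over dynamic species (copies).
#' @slot anchor integer anchor state in kept (reduced) coordinates,
#'   `X0 = round(Y0)` clipped into feasibility.
#' @slot anchorFull named integer anchor reconstructed over all dynamic
#'   species.
#' @slot residual numeric max-norm of the ODE right-hand side at `Y0`.
#' @slot converged logical.
#' @slot iterations integer Newton iterations used.
#' @export
setClass("DeterministicSteadyState",
  representation(
    Y0 = "numeric",
    anchor = "integer",
    anchorFull = "integer",
    residual = "numeric",
    converged = "logical",
    iterations = "integer"
  )
)

#' Truncated state space
#'
#' Finite box `[alpha_i, beta_i]` over the conservation-reduced coordinates,
#' restricted to states whose reconstructed eliminated counts are
#' nonnegative. States are enumerated lexicographically with the last
#' coordinate varying fastest and indexed 1..K.
#'
#' @slot reduction the [ConservationReduction-class] defining coordinates.
#' @slot alpha,beta integer per-coordinate bounds.
#' @slot states integer matrix, K rows of kept-coordinate states in
#'   enumeration order.
#' @slot lookup integer vector over the full box mapping a box position to
#'   its state index (`NA` for infeasible positions).
#' @slot strides integer strides used for box-position arithmetic.
#' @export
setClass("TruncatedSpace",
  representation(
    reduction = "ConservationReduction",
    alpha = "integer",
    beta = "integer",
    states = "matrix",
    lookup = "integer",
    strides = "numeric"
  )
)

setValidity("TruncatedSpace", function(object) {
  if (any(object@alpha < 0)) return("alpha must be nonnegative")
  if (any(object@alpha > object@beta)) return("alpha must not exceed beta")
  if (nrow(object@states) == 0) return("empty feasible state set")
  TRUE
})

#' Truncated probability-flow generator
#'
#' Sparse K-by-K operator whose entry (r, c) is the probability inflow rate
#' into state r from state c; transitions leaving the truncated box are
#' dropped entirely (the propensity is zeroed, no diagonal loss), so every
#' column sums to zero and the matrix is a proper generator on the box.
#'
#' @slot matrix sparse `dgCMatrix` of the generator.
#' @slot space the [TruncatedSpace-class] the generator acts on.
#' @export
setClass("GeneratorMatrix",
  representation(
    matrix = "Matrix",
    space = "TruncatedSpace"
  )
)

#' Stationary distribution on a truncated state space
#'
#' @slot space the [TruncatedSpace-class] carrying the states.
#' @slot p numeric probability vector in state enumeration order, sums to 1.
#' @slot anchorIndex integer index j of the anchor state.
#' @slot eta normalization constant: `p[anchorIndex] == 1/eta`.
#' @slot faceMasses numeric matrix (coordinates x 2, columns left/right) of
#'   probability mass on each face of the box.
#' @slot faceExpandable logical matrix matching `faceMasses`; `FALSE` marks
#'   faces pinned at 0 or at a conservation cap, where truncation is exact.
#' @slot expansions integer count of adaptive box expansions performed.
#' @slot deterministic the [DeterministicSteadyState-class] used for
#'   anchoring.
#' @slot settings list of solver settings (eps, gamma0, gamma, ...).
#' @export
setClass("SteadyStateDistribution",
  representation(
    space = "TruncatedSpace",
    p = "numeric",
    anchorIndex = "integer",
    eta = "numeric",
    faceMasses = "matrix",
    faceExpandable = "matrix",
    expansions = "integer",
    deterministic = "DeterministicSteadyState",
    settings = "list"
  )
)

setValidity("SteadyStateDistribution", function(object) {
  if (length(object@p) != nrow(object@space@states)) {
    return("probability vector length must equal the state count")
  }
  if (any(object@p < 0)) return("probabilities must be nonnegative")
  if (abs(sum(object@p) - 1) > 1e-9) return("probabilities must sum to 1")
  TRUE
})

#' Result of a Gillespie stochastic simulation run
#'
#' Residence-time-weighted occupancy and moments of a single exact
#' trajectory, accumulated over `(burnIn, endTime]`.
#'
#' @slot network the simulated [ReactionNetwork-class].
#' @slot seed integer RNG seed used.
#' @slot endTime,burnIn simulated model time (seconds) and discarded initial
#'   span.
#' @slot states integer matrix of visited dynamic-species states (one row per
#'   distinct state).
#' @slot occupancy numeric residence-time fractions matching `states` rows.
#' @slot means,sds named numeric time-averaged moments per dynamic species.
#' @slot eventCount numeric number of reaction firings.
#' @export
setClass("SSAResult",
  representation(
    network = "ReactionNetwork",
    seed = "integer",
    endTime = "numeric",
    burnIn = "numeric",
    states = "matrix",
    occupancy = "numeric",
    means = "numeric",
    sds = "numeric",
    eventCount = "numeric"
  )
)

setValidity("SSAResult", function(object) {
  if (length(object@occupancy) &&
      abs(sum(object@occupancy) - 1) > 1e-9) {
    return("occupancy fractions must sum to 1")
  }
  TRUE
})
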