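# Gillespie direct-method reference simulator.

#' Run a Gillespie stochastic simulation
#'
#' Single exact trajectory of the direct method from the declared initial
#' state: exponential waiting times at total propensity `a0`, reaction
#' chosen with probability `a_mu/a0`. Occupancy and moments are
#' residence-time weighted over `(burnIn, endTime]`, the stationary-correct
#' estimator. When the total propensity vanishes the clock jumps to
#' `endTime` in the current state. Identical seed and inputs give an
#' identical trajectory.
#'
#' @param net a [ReactionNetwork-class].
#' @param endTime simulated model time (seconds).
#' @param seed integer RNG seed.
#' @param burnIn initial span discarded from the averages; default 10% of
#'   `endTime` (time-averaging from t = 0 would bias toward the initial
#'   state).
#' @param trackOccupancy record per-state residence fractions (disable for
#'   very large visited sets).
#' @param maxEvents safety cap on reaction firings.
#' @return an [SSAResult-class].
#' @export
#' @examples
#' bd <- parseReactionNetwork(c("species A init 0",
#'   "reaction b: 0 -> A @ 10", "reaction d: A -> 0 @ 1"))
#' res <- gillespieRun(bd, endTime = 1e4, seed = 7)
#' res@means   # close to 10
gillespieRun <- function(net, endTime, seed = 1L, burnIn = 0.1 * endTime,
                         trackOccupancy = TRUE, maxEvents = 5e8) {
  stopifnot(endTime > burnIn, burnIn >= 0)
  dyn <- dynamicSpecies(net)
  kin <- .reaction_kinetics(net)
  nu <- stateChangeMatrix(net)
  set.seed(as.integer(seed))
  out <- gillespie_core(
    x0 = as.integer(initialCounts(net)),
    nu = nu,
    rate = vapply(kin, `[[`, numeric(1), "rate"),
    reactIdx = lapply(kin, function(k) as.integer(k$idx - 1L)),
    reactCoef = lapply(kin, function(k) as.integer(k$coef)),
    tEnd = endTime, burnIn = burnIn,
    trackOccupancy = trackOccupancy, maxEvents = maxEvents)
  states <- out$states
  if (is.null(dim(states)) || ncol(states) != length(dyn)) {
    states <- matrix(integer(0), 0, length(dyn))
  }
  colnames(states) <- dyn
  means <- structure(as.numeric(out$means), names = dyn)
  sds <- structure(as.numeric(out$sds), names = dyn)
  res <- new("SSAResult", network = net, seed = as.integer(seed),
             endTime = endTime, burnIn = burnIn,
             states = states, occupancy = as.numeric(out$fractions),
             means = means, sds = sds, eventCount = out$events)
  validObject(res)
  res
}

#' Coefficient of variation from an SSA run
#'
#' Lambda from the time-averaged first and second moments.
#'
#' @param result an [SSAResult-class].
#' @param species dynamic species name.
#' @return numeric Lambda = sd/mean.
#' @export
cvFromSSA <- function(result, species) {
  i <- match(species, names(result@means))
  if (is.na(i)) stop(sprintf("unknown dynamic species '%s'", species))
  mu <- result@means[[i]]
  if (mu <= 0) {
    if (result@sds[[i]] == 0) return(NA_real_)
    stop("coefficient of variation undefined at zero mean")
  }
  result@sds[[i]] / mu
}

setMethod("show", "SSAResult", function(object) {
  cat(sprintf(
    "SSAResult: seed %d, endTime %g s (burn-in %g), %g events, %d states\n",
    object@seed, object@endTime, object@burnIn, object@eventCount,
    nrow(object@states)))
  for (s in names(object@means)) {
    mu <- object@means[[s]]
    cat(sprintf("  %-8s mean %10.4f  sd %9.4f  cv %s\n", s, mu,
                object@sds[[s]],
                ifelse(mu > 0, sprintf("%.6f", object@sds[[s]] / mu), "NA")))
  }
  invisible(object)
})

#' Total-variation distance between SSA occupancy and a direct solution
#'
#' @param ssa an [SSAResult-class] with occupancy tracking.
#' @param dist a [SteadyStateDistribution-class] over the same network.
#' @return numeric TV distance in [0, 1].
#' @export
occupancyTV <- function(ssa, dist) {
  if (nrow(ssa@states) == 0) stop("SSA result has no occupancy record")
  full <- stateMatrix(dist, full = TRUE)
  key <- function(m) apply(m, 1, paste, collapse = ",")
  pd <- structure(dist@p, names = key(full))
  po <- structure(ssa@occupancy, names = key(ssa@states))
  all_keys <- union(names(pd), names(po))
  a <- ifelse(all_keys %in% names(pd), pd[all_keys], 0)
  b <- ifelse(all_keys %in% names(po), po[all_keys], 0)
  sum(abs(a - b)) / 2
}
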