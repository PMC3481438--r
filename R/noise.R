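# Marginals, moments, coefficient of variation, percent noise change and
# response classification.

#' Marginal copy-number distribution of one species
#'
#' Sums probability over all states sharing the species count; eliminated
#' species are reconstructed first, so any dynamic species (kept or
#' eliminated) can be asked for.
#'
#' @param dist a [SteadyStateDistribution-class] or [SSAResult-class].
#' @param species dynamic species name.
#' @return named numeric vector mapping copy number to probability, counts
#'   ascending, summing to 1.
#' @export
marginalDistribution <- function(dist, species) {
  if (is(dist, "SSAResult")) {
    full <- dist@states
    p <- dist@occupancy
  } else {
    full <- stateMatrix(dist, full = TRUE)
    p <- dist@p
  }
  if (!species %in% colnames(full)) {
    stop(sprintf("unknown dynamic species '%s'", species))
  }
  counts <- full[, species]
  agg <- vapply(split(p, counts), sum, numeric(1))
  out <- agg[order(as.integer(names(agg)))]
  out
}

#' Moments and coefficient of variation of a marginal
#'
#' `mu = sum(k p(k))`, `sigma^2 = sum(k^2 p(k)) - mu^2`, `cv = sigma/mu`
#' (the noise measure Lambda; undefined and an error at `mu = 0` unless the
#' distribution is a point mass there).
#'
#' @param marginal named probability vector as from [marginalDistribution()].
#' @return list with `mean`, `sd`, `cv`.
#' @export
#' @examples
#' distributionMoments(c(`0` = 0.4, `1` = 0.4, `2` = 0.2))
distributionMoments <- function(marginal) {
  k <- as.numeric(names(marginal))
  if (is.null(names(marginal)) || anyNA(k)) {
    k <- seq_along(marginal) - 1
  }
  p <- as.numeric(marginal)
  s <- sum(p)
  if (abs(s - 1) > 1e-6) stop("marginal must be normalized")
  mu <- sum(k * p)
  v <- max(sum(k^2 * p) - mu^2, 0)
  sd <- sqrt(v)
  if (mu == 0) {
    if (sd > 0) stop("coefficient of variation undefined at zero mean")
    return(list(mean = 0, sd = 0, cv = NA_real_))
  }
  list(mean = mu, sd = sd, cv = sd / mu)
}

#' Noise summary over all dynamic species
#'
#' @param dist a [SteadyStateDistribution-class] or [SSAResult-class].
#' @return data.frame with columns `species`, `mean`, `sd`, `cv`.
#' @export
noiseSummary <- function(dist) {
  net <- if (is(dist, "SSAResult")) dist@network else
    dist@space@reduction@network
  dyn <- dynamicSpecies(net)
  rows <- lapply(dyn, function(s) {
    m <- distributionMoments(marginalDistribution(dist, s))
    data.frame(species = s, mean = m$mean, sd = m$sd, cv = m$cv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Coefficient of variation of one species
#'
#' @param dist a [SteadyStateDistribution-class] or [SSAResult-class].
#' @param species dynamic species name.
#' @return numeric Lambda = sd/mean.
#' @export
coefficientOfVariation <- function(dist, species) {
  distributionMoments(marginalDistribution(dist, species))$cv
}

#' Percent change in noise induced by a co-factor
#'
#' `100 * (cvWith - cvWithout) / cvWithout`: negative values are noise
#' attenuation, positive values amplification.
#'
#' @param cvWith coefficient of variation with the co-factor present.
#' @param cvWithout coefficient of variation without it (> 0).
#' @return percent change (vectorized).
#' @export
#' @examples
#' percentNoiseChange(0.05, 0.10)   # -50
percentNoiseChange <- function(cvWith, cvWithout) {
  if (any(cvWithout <= 0)) stop("cvWithout must be positive")
  100 * (cvWith - cvWithout) / cvWithout
}

#' Classify a co-factor noise response across target levels
#'
#' Compares two coefficient-of-variation curves over a common grid of target
#' signaling-complex levels: `"attenuation"` when the co-factor curve lies
#' below the reference everywhere, `"amplification"` when above everywhere,
#' `"mixed"` when the sign of the difference changes across the grid, and
#' `"neutral"` when the curves are indistinguishable within `tol`.
#'
#' @param cvWith,cvWithout numeric curves on the same target grid (names, if
#'   present, must agree).
#' @param tol tolerance on the Lambda difference treated as zero.
#' @return one of `"attenuation"`, `"amplification"`, `"mixed"`,
#'   `"neutral"`.
#' @export
classifyResponse <- function(cvWith, cvWithout, tol = 1e-9) {
  if (length(cvWith) != length(cvWithout)) {
    stop("curves must share the same target grid")
  }
  if (!is.null(names(cvWith)) && !is.null(names(cvWithout)) &&
      !identical(names(cvWith), names(cvWithout))) {
    stop("curves must share the same target grid")
  }
  if (any(cvWithout <= 0)) stop("reference curve must be positive")
  d <- cvWith - cvWithout
  lower <- any(d < -tol)
  higher <- any(d > tol)
  if (lower && higher) return("mixed")
  if (lower) return("attenuation")
  if (higher) return("amplification")
  "neutral"
}
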