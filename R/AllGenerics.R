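#' @rdname speciesNames
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname speciesNames
#' @export
setGeneric("dynamicSpecies", function(x) standardGeneric("dynamicSpecies"))

#' @rdname speciesNames
#' @export
setGeneric("clampedSpecies", function(x) standardGeneric("clampedSpecies"))

#' @rdname speciesNames
#' @export
setGeneric("initialCounts", function(x) standardGeneric("initialCounts"))

#' @rdname speciesNames
#' @export
setGeneric("clampValues", function(x) standardGeneric("clampValues"))

#' @rdname stateCount
#' @export
setGeneric("stateCount", function(x) standardGeneric("stateCount"))

#' @rdname stateCount
#' @export
setGeneric("stateMatrix", function(x, full = FALSE) standardGeneric("stateMatrix"))

#' @rdname stateCount
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' Species accessors
#'
#' `speciesNames` returns all declared species names; `dynamicSpecies` and
#' `clampedSpecies` their role subsets; `initialCounts` the initial copy
#' numbers of the dynamic species; `clampValues` the fixed levels of the
#' clamped species.
#'
#' @param x a [ReactionNetwork-class] (or an object carrying one).
#' @return character or named numeric vectors.
#' @name speciesNames
NULL

#' State-space accessors
#'
#' `stateCount` returns the number K of enumerated states; `stateMatrix` the
#' states themselves, in reduced coordinates or reconstructed over all
#' dynamic species (`full = TRUE`); `probabilities` the stationary
#' probability vector in enumeration order.
#'
#' @param x a [TruncatedSpace-class], [GeneratorMatrix-class] or
#'   [SteadyStateDistribution-class].
#' @param full logical; reconstruct eliminated species.
#' @name stateCount
NULL
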