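# Output writers: TSV distribution dumps and JSON summaries. Floating
# point is written at 17 significant digits so files round-trip bit-exact.

.fmt17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a stationary distribution as TSV
#'
#' One column per dynamic species (full reconstructed states) plus
#' `probability`, header row, states in enumeration order, tab-delimited,
#' '.' decimal separator.
#'
#' @param dist a [SteadyStateDistribution-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDistribution <- function(dist, path) {
  full <- stateMatrix(dist, full = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(colnames(full), "probability"), collapse = "\t"), con)
  lines <- paste(apply(full, 1, paste, collapse = "\t"),
                 .fmt17(dist@p), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read back a TSV distribution dump
#'
#' @param path file written by [writeDistribution()].
#' @return data.frame with species columns and `probability`.
#' @export
readDistribution <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Write a solution summary as JSON
#'
#' Per-species mean, sd and cv, the state count, box bounds, anchor, eta,
#' face masses, expansion count and solver settings, plus the package
#' version.
#'
#' @param dist a [SteadyStateDistribution-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSummary <- function(dist, path) {
  ns <- noiseSummary(dist)
  red <- dist@space@reduction
  kept <- dynamicSpecies(red@network)[red@keep]
  species <- lapply(seq_len(nrow(ns)), function(i) {
    list(mean = ns$mean[i], sd = ns$sd[i], cv = ns$cv[i])
  })
  names(species) <- ns$species
  obj <- list(
    version = as.character(utils::packageVersion("steadyCME")),
    K = nrow(dist@space@states),
    bounds = list(coordinates = kept,
                  alpha = dist@space@alpha, beta = dist@space@beta),
    anchor = structure(as.list(dist@deterministic@anchorFull),
                       names = names(dist@deterministic@anchorFull)),
    eta = dist@eta,
    faceMasses = list(left = unname(dist@faceMasses[, 1]),
                      right = unname(dist@faceMasses[, 2])),
    expansions = dist@expansions,
    species = species,
    settings = dist@settings[c("eps", "gamma0", "gamma", "maxExpansions",
                               "clipTol", "method")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write SSA occupancy as TSV
#'
#' Species columns plus `fraction`, analogous to [writeDistribution()].
#'
#' @param ssa an [SSAResult-class] with occupancy tracking.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeOccupancy <- function(ssa, path) {
  if (nrow(ssa@states) == 0) stop("SSA result has no occupancy record")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(colnames(ssa@states), "fraction"), collapse = "\t"), con)
  lines <- paste(apply(ssa@states, 1, paste, collapse = "\t"),
                 .fmt17(ssa@occupancy), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
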