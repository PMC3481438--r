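#' Construct a reaction network
#'
#' Low-level constructor; most users will go through
#' [parseReactionNetwork()] or the model builders. Species order and
#' reaction order are preserved as given and fix the indexing of state
#' vectors and state-change columns.
#'
#' @param species data.frame with columns `name`, `role`, `init`, `clamp`
#'   (see [ReactionNetwork-class]).
#' @param reactions list of reactions, each a list with `label`,
#'   `reactants`, `products` (named integer coefficient vectors; empty
#'   vectors allowed) and `rate`.
#' @param parameters named numeric vector, optional.
#' @return a validated [ReactionNetwork-class].
#' @export
#' @examples
#' bd <- reactionNetwork(
#'   species = data.frame(name = "A", role = "dynamic", init = 0, clamp = NA),
#'   reactions = list(
#'     list(label = "birth", reactants = integer(0),
#'          products = c(A = 1L), rate = 10),
#'     list(label = "death", reactants = c(A = 1L),
#'          products = integer(0), rate = 1)
#'   )
#' )
reactionNetwork <- function(species, reactions, parameters = numeric(0)) {
  species$name <- as.character(species$name)
  species$role <- as.character(species$role)
  species$init <- as.numeric(species$init)
  species$clamp <- as.numeric(species$clamp)
  reactions <- lapply(reactions, function(rx) {
    rx$reactants <- .coef_vector(rx$reactants)
    rx$products <- .coef_vector(rx$products)
    rx
  })
  new("ReactionNetwork", species = species, reactions = reactions,
      parameters = parameters)
}

.coef_vector <- function(v) {
  if (is.null(v) || length(v) == 0) {
    return(structure(integer(0), names = character(0)))
  }
  out <- as.integer(v)
  names(out) <- names(v)
  if (any(out <= 0)) stop("stoichiometric coefficients must be positive")
  out
}

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@species$name)

#' @rdname speciesNames
#' @export
setMethod("dynamicSpecies", "ReactionNetwork",
          function(x) x@species$name[x@species$role == "dynamic"])

#' @rdname speciesNames
#' @export
setMethod("clampedSpecies", "ReactionNetwork",
          function(x) x@species$name[x@species$role == "clamped"])

#' @rdname speciesNames
#' @export
setMethod("initialCounts", "ReactionNetwork", function(x) {
  dyn <- x@species$role == "dynamic"
  structure(x@species$init[dyn], names = x@species$name[dyn])
})

#' @rdname speciesNames
#' @export
setMethod("clampValues", "ReactionNetwork", function(x) {
  cl <- x@species$role == "clamped"
  structure(x@species$clamp[cl], names = x@species$name[cl])
})

#' Number of reactions
#' @param x a [ReactionNetwork-class].
#' @export
nReactions <- function(x) length(x@reactions)

setMethod("show", "ReactionNetwork", function(object) {
  dyn <- dynamicSpecies(object)
  cl <- clampedSpecies(object)
  cat(sprintf("ReactionNetwork: %d dynamic species, %d clamped, %d reactions\n",
              length(dyn), length(cl), length(object@reactions)))
  cat("  dynamic:", paste(dyn, collapse = ", "), "\n")
  if (length(cl)) {
    cv <- clampValues(object)
    cat("  clamped:", paste(sprintf("%s=%g", names(cv), cv), collapse = ", "),
        "\n")
  }
  for (rx in object@reactions) {
    side <- function(v) {
      if (length(v) == 0) return("0")
      paste(ifelse(v > 1, paste0(v, " ", names(v)), names(v)), collapse = " + ")
    }
    cat(sprintf("  %s: %s -> %s @ %g\n", rx$label, side(rx$reactants),
                side(rx$products), rx$rate))
  }
  invisible(object)
})

# --- kinetics helpers -------------------------------------------------------

# Per-reaction mass-action kinetics over the dynamic species: the clamped
# contribution is folded into an effective rate constant.
.reaction_kinetics <- function(net) {
  sp <- net@species
  dyn <- sp$name[sp$role == "dynamic"]
  clamp <- clampValues(net)
  lapply(net@reactions, function(rx) {
    re <- rx$reactants
    eff <- rx$rate
    d_idx <- integer(0)
    d_coef <- integer(0)
    for (s in names(re)) {
      if (s %in% dyn) {
        d_idx <- c(d_idx, match(s, dyn))
        d_coef <- c(d_coef, re[[s]])
      } else {
        eff <- eff * clamp[[s]]^re[[s]]
      }
    }
    list(rate = eff, idx = d_idx, coef = d_coef)
  })
}

# number of ordered tuples / combinatorial mass-action factor for one species
.propensity_factor <- function(x, coef) {
  if (coef == 1L) x else x * (x - 1) / 2
}

#' Mass-action propensities at a state
#'
#' Stochastic mass-action propensity of every reaction at a discrete state:
#' `k` for zeroth order, `k*X_i` for first order, `k*X_i*X_j` for distinct
#' bimolecular reactants and `k*X_i*(X_i-1)/2` for a doubled reactant.
#' Clamped species multiply at their clamp value.
#'
#' @param net a [ReactionNetwork-class].
#' @param state numeric vector of copy numbers over the dynamic species (in
#'   declaration order, names optional).
#' @return nonnegative numeric vector, one propensity per reaction.
#' @export
#' @examples
#' net <- parseReactionNetwork(c(
#'   "species A init 2", "species B init 3", "species C init 0",
#'   "reaction R1: A + B -> C @ 0.5"))
#' propensityVector(net, c(A = 2, B = 3, C = 0))  # 0.5 * 2 * 3 = 3
propensityVector <- function(net, state) {
  dyn <- dynamicSpecies(net)
  if (length(state) != length(dyn)) {
    stop("state must have one entry per dynamic species")
  }
  if (any(state < 0)) stop("state must be nonnegative")
  kin <- .reaction_kinetics(net)
  vapply(kin, function(k) {
    a <- k$rate
    if (length(k$idx)) {
      for (q in seq_along(k$idx)) {
        a <- a * .propensity_factor(state[[k$idx[q]]], k$coef[q])
      }
    }
    max(a, 0)
  }, numeric(1))
}

# Vectorized propensities for a matrix of full dynamic states (rows = states).
.propensity_matrix <- function(net, states) {
  kin <- .reaction_kinetics(net)
  K <- nrow(states)
  A <- matrix(0, K, length(kin))
  for (m in seq_along(kin)) {
    k <- kin[[m]]
    a <- rep.int(k$rate, K)
    if (length(k$idx)) {
      for (q in seq_along(k$idx)) {
        x <- states[, k$idx[q]]
        a <- a * .propensity_factor(x, k$coef[q])
      }
    }
    a[a < 0] <- 0
    A[, m] <- a
  }
  A
}

#' State-change (stoichiometry) matrix
#'
#' Column mu is `products - reactants` of reaction mu restricted to the
#' dynamic species; clamped species contribute no entry.
#'
#' @param net a [ReactionNetwork-class].
#' @return integer matrix, dynamic species x reactions, with dimnames.
#' @export
stateChangeMatrix <- function(net) {
  dyn <- dynamicSpecies(net)
  M <- length(net@reactions)
  nu <- matrix(0L, length(dyn), M,
               dimnames = list(dyn, vapply(net@reactions, `[[`, "", "label")))
  for (m in seq_len(M)) {
    rx <- net@reactions[[m]]
    for (s in names(rx$reactants)) {
      if (s %in% dyn) nu[s, m] <- nu[s, m] - rx$reactants[[s]]
    }
    for (s in names(rx$products)) {
      if (s %in% dyn) nu[s, m] <- nu[s, m] + rx$products[[s]]
    }
  }
  nu
}

# --- parser -----------------------------------------------------------------

#' Parse a reaction-network file
#'
#' Line-based plain-text format, `#` starts a comment:
#' \preformatted{
#' param  <name> = <number>
#' species <name> init <nonnegative integer>
#' clamp  <name> = <nonnegative number>
#' reaction <label>: <side> -> <side> @ <number-or-param>
#' }
#' where `<side>` is `0` (empty) or `+`-joined terms `[<int> ]<species>`.
#' Numbers are parsed as decimal floating point, stoichiometric multipliers
#' as integers. Declaration order of species and reactions is preserved.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @param file path to a file to read instead of `text`.
#' @return a validated [ReactionNetwork-class].
#' @export
#' @examples
#' net <- parseReactionNetwork(c(
#'   "species A init 0",
#'   "reaction R1: 0 -> A @ 10",
#'   "reaction R2: A -> 0 @ 1"))
#' stateChangeMatrix(net)
parseReactionNetwork <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) stop("give either text or file")
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  params <- numeric(0)
  species <- list()
  reactions <- list()
  perr <- function(i, msg) {
    stop(sprintf("line %d: %s", i, msg), call. = FALSE)
  }
  num_or_param <- function(tok, i) {
    v <- suppressWarnings(as.numeric(tok))
    if (!is.na(v)) return(v)
    if (tok %in% names(params)) return(params[[tok]])
    perr(i, sprintf("'%s' is neither a number nor a declared param", tok))
  }
  parse_side <- function(txt, i) {
    txt <- trimws(txt)
    if (txt == "0" || txt == "") {
      return(structure(integer(0), names = character(0)))
    }
    if (grepl("^\\+|\\+$|\\+\\s*\\+", txt)) {
      perr(i, "malformed reaction side (dangling '+')")
    }
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    if (any(terms == "")) perr(i, "malformed reaction side")
    out <- integer(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9]+[[:space:]]+)?([A-Za-z_][A-Za-z0-9_.]*)$", tm))[[1]]
      if (length(m) == 0) perr(i, sprintf("malformed term '%s'", tm))
      coef <- if (nzchar(trimws(m[2]))) as.integer(trimws(m[2])) else 1L
      s <- m[3]
      out[s] <- if (s %in% names(out)) out[[s]] + coef else coef
    }
    out
  }
  for (i in seq_along(text)) {
    ln <- sub("#.*$", "", text[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^param[[:space:]]", ln)) {
      m <- regmatches(ln, regexec(
        "^param[[:space:]]+([A-Za-z_][A-Za-z0-9_.]*)[[:space:]]*=[[:space:]]*(\\S+)$", ln))[[1]]
      if (length(m) == 0) perr(i, "malformed param line")
      v <- suppressWarnings(as.numeric(m[3]))
      if (is.na(v)) perr(i, sprintf("'%s' is not a number", m[3]))
      params[m[2]] <- v
    } else if (grepl("^species[[:space:]]", ln)) {
      m <- regmatches(ln, regexec(
        "^species[[:space:]]+([A-Za-z_][A-Za-z0-9_.]*)[[:space:]]+init[[:space:]]+([0-9]+)$", ln))[[1]]
      if (length(m) == 0) perr(i, "malformed species line (want: species <name> init <int>)")
      species[[length(species) + 1]] <- list(name = m[2], role = "dynamic",
                                             init = as.numeric(m[3]), clamp = NA_real_)
    } else if (grepl("^clamp[[:space:]]", ln)) {
      m <- regmatches(ln, regexec(
        "^clamp[[:space:]]+([A-Za-z_][A-Za-z0-9_.]*)[[:space:]]*=[[:space:]]*(\\S+)$", ln))[[1]]
      if (length(m) == 0) perr(i, "malformed clamp line")
      v <- num_or_param(m[3], i)
      if (is.na(v) || v < 0) perr(i, "clamp level must be nonnegative")
      species[[length(species) + 1]] <- list(name = m[2], role = "clamped",
                                             init = NA_real_, clamp = v)
    } else if (grepl("^reaction[[:space:]]", ln)) {
      m <- regmatches(ln, regexec(
        "^reaction[[:space:]]+([A-Za-z_][A-Za-z0-9_.']*)[[:space:]]*:(.*)->(.*)@(.*)$", ln))[[1]]
      if (length(m) == 0) perr(i, "malformed reaction line")
      rate <- num_or_param(trimws(m[5]), i)
      if (rate <= 0) perr(i, "rate constant must be positive")
      reactions[[length(reactions) + 1]] <- list(
        label = m[2],
        reactants = parse_side(m[3], i),
        products = parse_side(m[4], i),
        rate = rate)
    } else {
      perr(i, sprintf("unrecognized directive: '%s'", ln))
    }
  }
  if (length(species) == 0) stop("no species declared")
  spdf <- do.call(rbind, lapply(species, function(s) {
    data.frame(name = s$name, role = s$role, init = s$init, clamp = s$clamp,
               stringsAsFactors = FALSE)
  }))
  net <- reactionNetwork(spdf, reactions, params)
  validObject(net)
  net
}

# --- model builders ---------------------------------------------------------

#' BMP / Cv-2 co-factor network (simplified, ligand clamped)
#'
#' The 5-species, 8-reaction network of BMP ligand (A, clamped), Type I
#' receptor (B), signaling complex BMP:receptor (C), the secreted co-factor
#' Cv-2 (D), its ligand complex BMP:Cv-2 (E), and the tripartite transfer
#' intermediate BMP:receptor:Cv-2 (Z). Ligand production/decay is absorbed
#' into the clamp `A`; species order is (B, C, D, E, Z). The network carries
#' two conserved pools, `B + C + Z` (receptors) and `D + E + Z` (Cv-2).
#'
#' @param k1,km1 receptor binding `A + B <-> C` (forward molecule^-1 s^-1
#'   with A in molecules; reverse s^-1).
#' @param k2,km2 co-factor loading `A + D <-> E`.
#' @param k3,km3 intermediate formation `B + E <-> Z`.
#' @param k4,km4 intermediate formation `C + D <-> Z`.
#' @param A clamp level of free ligand (molecules, real-valued).
#' @param bTotal,dTotal receptor and Cv-2 pools (copies).
#' @return a [ReactionNetwork-class].
#' @export
#' @examples
#' net <- buildCv2Network(k3 = 1.3282, km3 = 0.01, k4 = 1.3282, km4 = 0.01,
#'                        A = 0.5, dTotal = 105)
#' conservationBasis(net)$basis
buildCv2Network <- function(k1 = 0.013282, km1 = 0.01,
                            k2 = 0.013282, km2 = 0.1,
                            k3, km3, k4, km4,
                            A, bTotal = 100, dTotal = 105) {
  stopifnot(k1 > 0, km1 > 0, k2 > 0, km2 > 0, k3 > 0, km3 > 0, k4 > 0,
            km4 > 0, A >= 0, bTotal >= 0, dTotal >= 0)
  sp <- data.frame(
    name = c("B", "C", "D", "E", "Z", "A"),
    role = c(rep("dynamic", 5), "clamped"),
    init = c(bTotal, 0, dTotal, 0, 0, NA),
    clamp = c(rep(NA, 5), A),
    stringsAsFactors = FALSE)
  rx <- list(
    list(label = "R1", reactants = c(A = 1L, B = 1L), products = c(C = 1L), rate = k1),
    list(label = "R2", reactants = c(C = 1L), products = c(A = 1L, B = 1L), rate = km1),
    list(label = "R3", reactants = c(A = 1L, D = 1L), products = c(E = 1L), rate = k2),
    list(label = "R4", reactants = c(E = 1L), products = c(A = 1L, D = 1L), rate = km2),
    list(label = "R5", reactants = c(B = 1L, E = 1L), products = c(Z = 1L), rate = k3),
    list(label = "R6", reactants = c(Z = 1L), products = c(B = 1L, E = 1L), rate = km3),
    list(label = "R7", reactants = c(C = 1L, D = 1L), products = c(Z = 1L), rate = k4),
    list(label = "R8", reactants = c(Z = 1L), products = c(C = 1L, D = 1L), rate = km4))
  net <- reactionNetwork(sp, rx)
  validObject(net)
  net
}

#' Type II receptor recruitment networks (Cases I-III)
#'
#' Ligand B is clamped. Case I is plain binding `B + R1 <-> BR1` with BR1 the
#' signaling complex. Case II adds recruitment of the Type II receptor to a
#' bound complex, `BR1 + R2 <-> BR1R2`, with the tripartite BR1R2 signaling.
#' Case III additionally allows direct `B + R2 <-> BR2` and `BR2 + R1 <->
#' BR1R2`; setting `k2 = km2 = k4 = km4 = 0` recovers Case II's reaction set.
#'
#' @param case "I", "II" or "III".
#' @param k1,km1 BMP : Type I binding.
#' @param k2,km2 BMP : Type II binding (Case III only).
#' @param k3,km3 Type II recruitment onto BR1.
#' @param k4,km4 Type I recruitment onto BR2 (Case III only).
#' @param B clamp level of free ligand (molecules).
#' @param r1Total,r2Total receptor pools (copies).
#' @return a [ReactionNetwork-class].
#' @export
buildTypeIINetwork <- function(case = c("II", "I", "III"),
                               k1 = 0.013282, km1 = 0.01,
                               k2 = 0.013282, km2 = 0.01,
                               k3 = 1.3282, km3 = 0.01,
                               k4 = 1.3282, km4 = 0.01,
                               B, r1Total = 100, r2Total = 100) {
  case <- match.arg(case)
  stopifnot(B >= 0, r1Total >= 0, r2Total >= 0, k1 > 0, km1 > 0)
  rx <- list(
    list(label = "r1", reactants = c(B = 1L, R1 = 1L), products = c(BR1 = 1L), rate = k1),
    list(label = "r2", reactants = c(BR1 = 1L), products = c(B = 1L, R1 = 1L), rate = km1))
  spn <- c("R1", "BR1")
  init <- c(r1Total, 0)
  if (case %in% c("II", "III")) {
    stopifnot(k3 > 0, km3 > 0)
    rx <- c(rx, list(
      list(label = "r5", reactants = c(BR1 = 1L, R2 = 1L), products = c(BR1R2 = 1L), rate = k3),
      list(label = "r6", reactants = c(BR1R2 = 1L), products = c(BR1 = 1L, R2 = 1L), rate = km3)))
    spn <- c("R1", "R2", "BR1", "BR1R2")
    init <- c(r1Total, r2Total, 0, 0)
  }
  if (case == "III") {
    direct <- c(k2, km2, k4, km4)
    if (all(direct == 0)) {
      # zeroed direct Type II binding: exactly the Case II reaction set
      return(buildTypeIINetwork("II", k1 = k1, km1 = km1, k3 = k3,
                                km3 = km3, B = B, r1Total = r1Total,
                                r2Total = r2Total))
    }
    stopifnot(k2 > 0, km2 > 0, k4 > 0, km4 > 0)
    rx <- c(rx, list(
      list(label = "r3", reactants = c(B = 1L, R2 = 1L), products = c(BR2 = 1L), rate = k2),
      list(label = "r4", reactants = c(BR2 = 1L), products = c(B = 1L, R2 = 1L), rate = km2),
      list(label = "r7", reactants = c(BR2 = 1L, R1 = 1L), products = c(BR1R2 = 1L), rate = k4),
      list(label = "r8", reactants = c(BR1R2 = 1L), products = c(BR2 = 1L, R1 = 1L), rate = km4)))
    spn <- c("R1", "R2", "BR1", "BR2", "BR1R2")
    init <- c(r1Total, r2Total, 0, 0, 0)
  }
  sp <- data.frame(
    name = c(spn, "B"),
    role = c(rep("dynamic", length(spn)), "clamped"),
    init = c(init, NA),
    clamp = c(rep(NA, length(spn)), B),
    stringsAsFactors = FALSE)
  net <- reactionNetwork(sp, rx)
  validObject(net)
  net
}

#' Signaling species of a Type II network case
#'
#' BR1 for Case I (sole complex), BR1R2 for Cases II and III.
#' @param case "I", "II" or "III".
#' @export
signalingSpecies <- function(case) {
  if (case == "I") "BR1" else "BR1R2"
}
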