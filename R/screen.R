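# Parameter screens: Cv-2 intermediate-kinetics grid with ligand calibration
# and noise-change classification; Type II recruitment comparison.

#' Logarithmically spaced grid
#'
#' `n` points geometrically spaced from `lo` to `hi` inclusive (evenly
#' spaced on a log scale), endpoints exact.
#'
#' @param lo,hi positive bounds, `lo < hi`.
#' @param n number of points (>= 2).
#' @return numeric vector of length `n`.
#' @export
#' @examples
#' logGrid(0.1, 10, 5)   # 0.1 0.3162 1 3.162 10
logGrid <- function(lo, hi, n) {
  stopifnot(lo > 0, hi > lo, n >= 2)
  v <- 10^seq(log10(lo), log10(hi), length.out = n)
  v[1] <- lo
  v[n] <- hi
  v
}

#' Four-parameter screen grid for the tripartite-intermediate kinetics
#'
#' Cartesian product of log-spaced grids over the forward rates `k3`, `k4`
#' (default decade range 0.1 to 10 nM^-1 s^-1) and the reverse rates `k-3`,
#' `k-4` (default 1e-3 to 1 s^-1), in nM-based units. Axis order: `k3`
#' outermost, `k-4` innermost (fastest varying).
#'
#' @param k3Range,km3Range,k4Range,km4Range two-element ranges.
#' @param n points per axis; the default 5 gives 625 parameter vectors.
#' @return data.frame with columns `k3`, `km3`, `k4`, `km4` (nM-based
#'   units for the forward rates).
#' @export
parameterGrid <- function(k3Range = c(0.1, 10), km3Range = c(1e-3, 1),
                          k4Range = c(0.1, 10), km4Range = c(1e-3, 1),
                          n = 5) {
  g3 <- logGrid(k3Range[1], k3Range[2], n)
  gm3 <- logGrid(km3Range[1], km3Range[2], n)
  g4 <- logGrid(k4Range[1], k4Range[2], n)
  gm4 <- logGrid(km4Range[1], km4Range[2], n)
  df <- expand.grid(km4 = gm4, k4 = g4, km3 = gm3, k3 = g3,
                    KEEP.OUT.ATTRS = FALSE)
  df[, c("k3", "km3", "k4", "km4")]
}

#' Run the Cv-2 co-factor noise screen
#'
#' For each parameter vector of the grid and each target level of bound
#' receptor (BR = species C): the free-ligand clamp is calibrated so the
#' deterministic BR level hits the target at each co-factor level (the BR
#' level must stay the same with and without Cv-2 for the noise comparison
#' to be meaningful), and the stationary distribution is solved at both
#' levels. The coefficient of variation of BR with and without Cv-2, the
#' percent noise change at the top target, and the response class of the
#' curve pair are recorded.
#'
#' The co-factor-free reference depends only on the receptor binding rates,
#' not on the screened intermediate kinetics, so calibration and reference
#' solves are shared across the grid.
#'
#' @param grid data.frame as from [parameterGrid()], nM-based forward
#'   rates. Default is the reduced 3-points-per-axis grid (81 vectors);
#'   pass `parameterGrid(n = 5)` for the full 625-vector screen.
#' @param targets target BR levels (copies); receptor occupancy is capped
#'   at 30% of `bTotal` by the default grid of 5 to 30.
#' @param bTotal receptor pool (copies).
#' @param cofactorLevels two Cv-2 pools: reference level (usually 0) and
#'   co-factor level.
#' @param baseRates named numeric with `k1`, `km1`, `k2`, `km2`
#'   (molecule-based units) for the ligand-receptor and ligand-co-factor
#'   binding steps.
#' @param conversion molecules per nM; applied to the grid's forward rates
#'   (reverse rates are first-order and unit-invariant).
#' @param eps,gamma0,gamma solver settings for [adaptiveSolve()].
#' @param recalibratePerLevel recalibrate the ligand at the co-factor level
#'   as well (default), so the deterministic BR level matches the target at
#'   both co-factor levels and the comparison isolates the noise change;
#'   `FALSE` holds the co-factor-free calibration fixed, letting Cv-2 shift
#'   the mean BR level itself.
#' @param verbose print one line per vector.
#' @return list with `records` (one row per vector and target) and
#'   `summary` (one row per vector: percent change at the top target and
#'   response class).
#' @export
runCv2Screen <- function(grid = parameterGrid(n = 3),
                         targets = c(5, 15, 30),
                         bTotal = 100,
                         cofactorLevels = c(0, 105),
                         baseRates = c(k1 = 0.013282, km1 = 0.01,
                                       k2 = 0.013282, km2 = 0.1),
                         conversion = 0.13282,
                         eps = 1e-6, gamma0 = NULL, gamma = 5L,
                         recalibratePerLevel = TRUE,
                         verbose = FALSE) {
  stopifnot(nrow(grid) >= 1, length(cofactorLevels) == 2,
            max(targets) <= bTotal)
  k1 <- baseRates[["k1"]]; km1 <- baseRates[["km1"]]
  k2 <- baseRates[["k2"]]; km2 <- baseRates[["km2"]]
  ref_level <- cofactorLevels[1]
  cof_level <- cofactorLevels[2]

  build <- function(vec, A, dTotal) {
    buildCv2Network(k1 = k1, km1 = km1, k2 = k2, km2 = km2,
                    k3 = vec$k3 * conversion, km3 = vec$km3,
                    k4 = vec$k4 * conversion, km4 = vec$km4,
                    A = A, bTotal = bTotal, dTotal = dTotal)
  }
  # reference network: when the reference co-factor level is 0 the
  # intermediate kinetics are inert and the reference is grid-independent
  ref_vec <- list(k3 = 1, km3 = 1, k4 = 1, km4 = 1)
  ref_indep <- ref_level == 0
  calib <- numeric(length(targets))
  cv_ref <- rep(NA_real_, length(targets))
  if (ref_indep) {
    for (ti in seq_along(targets)) {
      calib[ti] <- as.numeric(calibrateLigand(
        function(a) build(ref_vec, a, ref_level), "C", targets[ti]))
      d0 <- adaptiveSolve(build(ref_vec, calib[ti], ref_level), eps = eps,
                          gamma0 = gamma0, gamma = gamma)
      cv_ref[ti] <- coefficientOfVariation(d0, "C")
    }
  }

  records <- list()
  summaries <- list()
  for (v in seq_len(nrow(grid))) {
    vec <- as.list(grid[v, ])
    cv_w <- rep(NA_real_, length(targets))
    cv_wo <- cv_ref
    lig <- calib
    ss_aud <- rep(NA_real_, length(targets))
    failed <- FALSE
    for (ti in seq_along(targets)) {
      rec <- tryCatch({
        if (!ref_indep) {
          lig[ti] <- as.numeric(calibrateLigand(
            function(a) build(vec, a, ref_level), "C", targets[ti]))
          d0 <- adaptiveSolve(build(vec, lig[ti], ref_level), eps = eps,
                              gamma0 = gamma0, gamma = gamma)
          cv_wo[ti] <- coefficientOfVariation(d0, "C")
        }
        a_use <- lig[ti]
        if (recalibratePerLevel) {
          a_use <- as.numeric(calibrateLigand(
            function(a) build(vec, a, cof_level), "C", targets[ti]))
          lig[ti] <- a_use
        }
        netw <- build(vec, a_use, cof_level)
        ss_aud[ti] <- findSteadyState(netw)@Y0[["C"]]
        dw <- adaptiveSolve(netw, eps = eps, gamma0 = gamma0, gamma = gamma)
        cv_w[ti] <- coefficientOfVariation(dw, "C")
        TRUE
      }, error = function(e) {
        warning(sprintf("screen vector %d target %g failed: %s", v,
                        targets[ti], conditionMessage(e)))
        FALSE
      })
      if (!rec) failed <- TRUE
    }
    top <- length(targets)
    pct <- if (is.na(cv_w[top]) || is.na(cv_wo[top])) NA_real_ else
      percentNoiseChange(cv_w[top], cv_wo[top])
    cls <- if (failed || anyNA(cv_w) || anyNA(cv_wo)) "failed" else
      classifyResponse(cv_w, cv_wo)
    records[[v]] <- data.frame(
      vector = v, k3nm = vec$k3, km3 = vec$km3, k4nm = vec$k4,
      km4 = vec$km4, target = targets, ligand = lig,
      cvWithout = cv_wo, cvWith = cv_w,
      pctChange = ifelse(is.na(cv_w) | is.na(cv_wo), NA_real_,
                         100 * (cv_w - cv_wo) / cv_wo),
      ssTarget = ss_aud, stringsAsFactors = FALSE)
    summaries[[v]] <- data.frame(
      vector = v, k3nm = vec$k3, km3 = vec$km3, k4nm = vec$k4,
      km4 = vec$km4, pctChangeTop = pct, class = cls,
      stringsAsFactors = FALSE)
    if (verbose) {
      message(sprintf("vector %d/%d: pct %.2f class %s", v, nrow(grid),
                      pct, cls))
    }
  }
  list(records = do.call(rbind, records),
       summary = do.call(rbind, summaries),
       settings = list(targets = targets, bTotal = bTotal,
                       cofactorLevels = cofactorLevels,
                       baseRates = baseRates, conversion = conversion,
                       eps = eps))
}

#' Compare signaling noise across Type II recruitment cases
#'
#' For each case and each target level of the case's signaling complex
#' (BR1 in Case I, BR1R2 in Cases II and III), the free-ligand clamp is
#' calibrated to hit the target deterministically and the stationary
#' coefficient of variation of the signaling complex is computed, so the
#' noise of the tripartite complex can be compared directly with the noise
#' of plain BMP:Type-I binding at matched signal output.
#'
#' @param cases subset of `c("I", "II", "III")`.
#' @param targets signaling-complex targets (copies).
#' @param rates named numeric with molecule-based `k1`, `km1`, `k3`,
#'   `km3` (and `k2`, `km2`, `k4`, `km4` for Case III). The default uses
#'   fast recruitment: `k3` at the top of the screened decade.
#' @param r1Total,r2Total receptor pools. The default holds Type II in
#'   threefold excess of Type I so that recruitment itself, not Type II
#'   availability, is assayed; deplete `r2Total` toward `r1Total` (or sweep
#'   `r2Levels`) to see pool-limitation effects.
#' @param r2Levels optional vector of alternative R2 pools; Case II is
#'   re-run at each and reported in `byR2`.
#' @param eps,gamma0,gamma solver settings for [adaptiveSolve()].
#' @return list with `table` (per target: cv per case and the relative
#'   discrepancy of Case II vs Case I) and optionally `byR2`.
#' @export
runTypeIIComparison <- function(cases = c("I", "II"),
                                targets = 1:30,
                                rates = c(k1 = 0.013282, km1 = 0.01,
                                          k2 = 0.013282, km2 = 0.01,
                                          k3 = 1.3282, km3 = 0.01,
                                          k4 = 1.3282, km4 = 0.01),
                                r1Total = 100, r2Total = 300,
                                r2Levels = NULL,
                                eps = 1e-6, gamma0 = NULL, gamma = 5L) {
  stopifnot(all(cases %in% c("I", "II", "III")),
            max(targets) < r1Total)
  run_case <- function(case, r2tot) {
    sig <- signalingSpecies(case)
    build <- function(b) {
      buildTypeIINetwork(case, k1 = rates[["k1"]], km1 = rates[["km1"]],
                         k2 = rates[["k2"]], km2 = rates[["km2"]],
                         k3 = rates[["k3"]], km3 = rates[["km3"]],
                         k4 = rates[["k4"]], km4 = rates[["km4"]],
                         B = b, r1Total = r1Total, r2Total = r2tot)
    }
    vapply(targets, function(tg) {
      b <- tryCatch(as.numeric(calibrateLigand(build, sig, tg)),
                    error = function(e) NA_real_)
      if (is.na(b)) return(NA_real_)
      dist <- adaptiveSolve(build(b), eps = eps, gamma0 = gamma0,
                            gamma = gamma)
      coefficientOfVariation(dist, sig)
    }, numeric(1))
  }
  tab <- data.frame(target = targets)
  for (case in cases) {
    tab[[paste0("cv", case)]] <- run_case(case, r2Total)
  }
  if (all(c("I", "II") %in% cases)) {
    tab$relDiscrepancy <- abs(tab$cvII - tab$cvI) / tab$cvI
  }
  out <- list(table = tab,
              settings = list(rates = rates, r1Total = r1Total,
                              r2Total = r2Total, eps = eps))
  if (!is.null(r2Levels) && "II" %in% cases) {
    by <- lapply(r2Levels, function(r2) {
      cv <- run_case("II", r2)
      data.frame(r2Total = r2, target = targets, cvII = cv)
    })
    out$byR2 <- do.call(rbind, by)
    if ("cvI" %in% names(tab)) {
      out$byR2$relDiscrepancy <-
        abs(out$byR2$cvII - rep(tab$cvI, length(r2Levels))) /
        rep(tab$cvI, length(r2Levels))
    }
  }
  out
}
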