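#' Mean staying time as a function of the cholinergic reduction of inhibition
#'
#' For each value of \eqn{g_{ACh}} on the grid, integrates the mean field
#' from a pattern-loaded initial condition under the constant factor,
#' computes the overlap trace and the staying times above the threshold.
#' A value is reported as right-censored ("diverged") when no uncensored
#' exit occurs within the horizon: the memories have become attractors on
#' that horizon.
#'
#' @param network a \linkS4class{MemoryNetwork}.
#' @param gAchGrid values of \eqn{g_{ACh}} in [0, 1).
#' @param horizon integration time per grid point.
#' @param threshold overlap threshold for [stayingTimes()].
#' @param gridSize phase grid size.
#' @param pattern index of the initially loaded pattern.
#' @param gE constant cholinergic modulation of excitation.
#' @param transient discarded initial interval before analysis.
#' @param ... passed to [integrateFP()].
#' @return data.frame with columns \code{gAch}, \code{meanStayingTime}
#'   (NA when diverged), \code{nExits}, \code{diverged}.
#' @export
stayingTimeCurve <- function(network, gAchGrid, horizon = 1500,
                             threshold = 0.85, gridSize = 128, pattern = 1,
                             gE = 0, transient = 100, ...) {
  stopifnot(all(gAchGrid >= 0), all(gAchGrid < 1))
  rows <- lapply(gAchGrid, function(g) {
    st <- .pattern_visits(network, gAch = g, gE = gE, horizon = horizon,
                          threshold = threshold, gridSize = gridSize,
                          pattern = pattern, transient = transient, ...)
    iv <- st@intervals
    ok <- !iv$censored
    data.frame(gAch = g,
               meanStayingTime = st@meanStayingTime,
               nExits = sum(ok),
               diverged = !any(ok))
  })
  do.call(rbind, rows)
}

# shared driver: pattern-loaded constant-modulation run -> StayingTimeResult
.pattern_visits <- function(network, gAch, gE, horizon, threshold, gridSize,
                            pattern, transient = 100, ...) {
  sched <- ModulationSchedule(achLevel = gAch, gELevel = gE,
                              achWindow = c(0, Inf), achDecay = Inf)
  init <- initDensity(network, gridSize, "pattern", pattern = pattern)
  tr <- integrateFP(network, init, sched, duration = horizon + transient,
                    outputStride = 0.25, ...)
  ot <- overlapTrace(tr, network@patterns)
  keep <- ot@times >= transient
  ot2 <- new("OverlapTrace", times = ot@times[keep],
             m = ot@m[keep, , drop = FALSE],
             peakHeld = ot@peakHeld[keep, , drop = FALSE],
             normalized = ot@normalized[keep, , drop = FALSE])
  stayingTimes(ot2, threshold)
}

#' Classify the landscape at one modulation point
#'
#' Integrates the mean field from pattern-loaded initial conditions (one
#' start per stored pattern by default) under constant \eqn{(g_E,
#' g_{ACh})}.  The point is an \code{"attractor"} landscape if no start
#' exits its loaded pattern within the horizon, and a
#' \code{"quasi-attractor"} landscape otherwise.  The verdict is always a
#' finite-horizon statement; the horizon is returned with the result.
#'
#' @param network a \linkS4class{MemoryNetwork}.
#' @param gE,gAch constant modulation factors in [0, 1).
#' @param horizon integration time per start.
#' @param threshold overlap threshold.
#' @param gridSize phase grid size.
#' @param starts pattern indices used as initial conditions.
#' @param ... passed to [integrateFP()].
#' @return list with \code{landscape} ("attractor" or "quasi-attractor"),
#'   \code{exits} (per-start exit flags), \code{horizon}.
#' @export
classifyLandscape <- function(network, gE, gAch, horizon = 1000,
                              threshold = 0.85, gridSize = 128,
                              starts = seq_len(ncol(network@patterns@patterns)),
                              ...) {
  stopifnot(gE >= 0, gE < 1, gAch >= 0, gAch < 1)
  exits <- vapply(starts, function(pat) {
    st <- .pattern_visits(network, gAch = gAch, gE = gE, horizon = horizon,
                          threshold = threshold, gridSize = gridSize,
                          pattern = pat, ...)
    iv <- st@intervals
    # exit = the initially loaded pattern ends an interval before the horizon
    own <- iv[iv$pattern == pat, , drop = FALSE]
    if (!nrow(own)) TRUE else any(!own$censored)
  }, logical(1))
  list(landscape = if (any(exits)) "quasi-attractor" else "attractor",
       exits = exits, horizon = horizon)
}

#' Quasi-attractor/attractor boundary in the (gE, gACh) plane
#'
#' For each \eqn{g_E} on the grid, locates by bisection the smallest
#' \eqn{g_{ACh}} at which the landscape classification flips from
#' quasi-attractor to attractor.  After bisection the bracketing endpoints
#' are re-verified; a point where the initial bracket does not straddle
#' the boundary is reported as NA with a message rather than failing the
#' whole map.
#'
#' @param network a \linkS4class{MemoryNetwork}.
#' @param gEGrid values of \eqn{g_E}.
#' @param gAchRange initial bisection bracket.
#' @param tol bisection tolerance on \eqn{g_{ACh}}.
#' @param ... passed to [classifyLandscape()].
#' @return data.frame with columns \code{gE}, \code{gAchBoundary},
#'   \code{minInhibitoryFraction} (\eqn{1 - g_{ACh}} at the boundary).
#' @export
boundaryMap <- function(network, gEGrid, gAchRange = c(0, 0.08),
                        tol = 0.01, ...) {
  rows <- lapply(gEGrid, function(ge) {
    lo <- gAchRange[1]
    hi <- gAchRange[2]
    cl <- function(g) classifyLandscape(network, gE = ge, gAch = g,
                                        ...)$landscape
    lo_cl <- cl(lo)
    hi_cl <- cl(hi)
    if (lo_cl == "attractor" || hi_cl == "quasi-attractor") {
      message(sprintf(
        "gE = %g: bracket [%g, %g] does not straddle the boundary", ge, lo,
        hi))
      return(data.frame(gE = ge, gAchBoundary = NA_real_,
                        minInhibitoryFraction = NA_real_))
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (cl(mid) == "attractor") hi <- mid else lo <- mid
    }
    data.frame(gE = ge, gAchBoundary = hi,
               minInhibitoryFraction = 1 - hi)
  })
  do.call(rbind, rows)
}
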