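#' Scripted experiment protocols
#'
#' The five protocols reproduce the package's core phenomenology on any
#' memory network: the ongoing state (itinerancy among quasi-attractors at
#' baseline modulation), the stabilization sweep (staying time versus
#' \eqn{g_{ACh}}), selection of a memory by top-down Glu input combined
#' with cholinergic stabilization, selection with exponentially decaying
#' ACh, and the quasi-attractor/attractor boundary map in the
#' \eqn{(g_E, g_{ACh})} plane.
#'
#' @name experiments
NULL

# assemble a report from a finished mean-field run
.report <- function(name, network, tr, threshold, config,
                    analysisStart = 0) {
  ot <- overlapTrace(tr, network@patterns)
  if (analysisStart > 0) {
    keep <- ot@times >= analysisStart
    ot <- new("OverlapTrace", times = ot@times[keep],
              m = ot@m[keep, , drop = FALSE],
              peakHeld = ot@peakHeld[keep, , drop = FALSE],
              normalized = ot@normalized[keep, , drop = FALSE])
  }
  st <- stayingTimes(ot, threshold)
  new("ExperimentReport", name = name, flux = tr, overlap = ot,
      staying = st, visits = st@intervals, config = config)
}

#' Ongoing state: itinerant dynamics among quasi-attractors
#'
#' Long mean-field integration at baseline modulation
#' (\eqn{g_{ACh} = g_E = 0}, no Glu) from a pattern-loaded start.  In the
#' quasi-attractor landscape the trajectory visits several stored patterns,
#' each with overlap near 1 during its visit.
#'
#' @param network a \linkS4class{MemoryNetwork}.
#' @param horizon integration time.
#' @param threshold overlap threshold for visit detection.
#' @param gridSize phase grid size.
#' @param pattern initially loaded pattern.
#' @param ... passed to [integrateFP()].
#' @return An \linkS4class{ExperimentReport}; \code{visits} lists the
#'   pattern visits in order.
#' @export
runOngoing <- function(network, horizon = 2000, threshold = 0.85,
                       gridSize = 128, pattern = 1, ...) {
  init <- initDensity(network, gridSize, "pattern", pattern = pattern)
  tr <- integrateFP(network, init, NULL, duration = horizon,
                    outputStride = 0.25, ...)
  .report("ongoing", network, tr, threshold,
          list(horizon = horizon, threshold = threshold,
               gridSize = gridSize, pattern = pattern))
}

#' Selection of a memory by top-down Glu input and ACh
#'
#' From the ongoing state, a transient Glu volley targeted at the units
#' specific to one pattern makes the trajectory jump into that pattern's
#' basin; the concurrent cholinergic reduction of inhibition decides
#' whether the retrieved pattern is transient (\eqn{g_{ACh} = 0}), longer
#' lived, or persistent (stabilizing \eqn{g_{ACh}}).
#'
#' @param network a \linkS4class{MemoryNetwork}.
#' @param gAch plateau cholinergic factor from \code{achOnset} on.
#' @param gluUnits 1-based units receiving the Glu volley (default: the
#'   units active only in \code{targetPattern}).
#' @param gluIncrement drive increase during the volley.
#' @param gluWindow Glu interval.
#' @param achOnset start of the ACh plateau (held to the horizon).
#' @param achDecay decay constant of g_ACh after \code{achOffset}
#'   (default Inf: held).
#' @param achOffset end of the ACh plateau.
#' @param targetPattern the pattern addressed by the volley.
#' @param horizon total integration time.
#' @param threshold overlap threshold.
#' @param gridSize phase grid size.
#' @param startPattern pattern loaded at t = 0.
#' @param ... passed to [integrateFP()].
#' @return An \linkS4class{ExperimentReport}; its config records
#'   \code{retrieved}, the first pattern visited after the Glu window.
#' @export
runSelection <- function(network, gAch, gluUnits = NULL, gluIncrement = 0.4,
                         gluWindow = c(300, 350), achOnset = 300,
                         achDecay = Inf, achOffset = Inf,
                         targetPattern = 2, horizon = 900,
                         threshold = 0.85, gridSize = 128, startPattern = 1,
                         ...) {
  eta <- network@patterns@patterns
  if (is.null(gluUnits)) {
    only <- eta[, targetPattern] == 1 &
      rowSums(eta[, -targetPattern, drop = FALSE]) == 0
    gluUnits <- which(only)
  }
  sched <- ModulationSchedule(achLevel = gAch,
                              achWindow = c(achOnset, achOffset),
                              achDecay = achDecay, gluUnits = gluUnits,
                              gluIncrement = gluIncrement,
                              gluWindow = gluWindow)
  init <- initDensity(network, gridSize, "pattern", pattern = startPattern)
  tr <- integrateFP(network, init, sched, duration = horizon,
                    outputStride = 0.25, ...)
  rep <- .report("selection", network, tr, threshold,
                 list(gAch = gAch, gluUnits = gluUnits,
                      gluIncrement = gluIncrement, gluWindow = gluWindow,
                      achOnset = achOnset, achDecay = achDecay,
                      achOffset = achOffset,
                      targetPattern = targetPattern, horizon = horizon,
                      threshold = threshold, gridSize = gridSize,
                      startPattern = startPattern))
  iv <- rep@visits
  after <- iv[iv$end > gluWindow[2], , drop = FALSE]
  rep@config$retrieved <- if (nrow(after)) after$pattern[1] else NA_integer_
  # duration of the first visit to the target pattern after the volley
  tgt <- after[after$pattern == targetPattern, , drop = FALSE]
  rep@config$targetStay <- if (nrow(tgt))
    tgt$end[1] - max(tgt$start[1], gluWindow[1]) else 0
  rep@config$targetCensored <- if (nrow(tgt)) tgt$censored[1] else FALSE
  rep
}

#' Selection with exponentially decaying ACh
#'
#' Same protocol as [runSelection()] with a finite ACh plateau followed by
#' an exponential return of \eqn{g_{ACh}} to baseline, emulating gradual
#' clearance of ACh.
#'
#' @inheritParams runSelection
#' @param achOffset end of the ACh plateau; thereafter \eqn{g_{ACh}}
#'   decays exponentially with constant \code{achDecay}.
#' @export
runDecay <- function(network, gAch, achDecay = 200, gluUnits = NULL,
                     gluIncrement = 0.4, gluWindow = c(300, 350),
                     achOnset = 300, achOffset = 450, targetPattern = 2,
                     horizon = 900, threshold = 0.85, gridSize = 128,
                     startPattern = 1, ...) {
  rep <- runSelection(network, gAch = gAch, gluUnits = gluUnits,
                      gluIncrement = gluIncrement, gluWindow = gluWindow,
                      achOnset = achOnset, achDecay = achDecay,
                      achOffset = achOffset,
                      targetPattern = targetPattern, horizon = horizon,
                      threshold = threshold, gridSize = gridSize,
                      startPattern = startPattern, ...)
  rep@name <- "decay"
  rep
}

#' @describeIn ExperimentReport-class the visit table.
#' @param x an \linkS4class{ExperimentReport}.
#' @export
visits <- function(x) x@visits

#' @describeIn ExperimentReport-class the configuration list.
#' @export
reportConfig <- function(x) x@config

setMethod("show", "ExperimentReport", function(object) {
  cat(sprintf("ExperimentReport '%s'\n", object@name))
  show(object@staying)
  iv <- object@visits
  if (nrow(iv)) {
    seqs <- paste(iv$pattern, collapse = " -> ")
    cat("  visit sequence:", seqs, "\n")
  } else cat("  no pattern visits above threshold\n")
})
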