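#' Finite-N versus mean-field firing-rate agreement
#'
#' For each ensemble size N in \code{nValues}, simulates the finite-N unit
#' (keeping the 4:1 PYR:IN ratio), estimates the time-averaged excitatory
#' firing rate with a batch-means standard error, and compares it with the
#' time-averaged flux of the deterministic mean field at the same
#' parameters.  As N grows the discrepancy shrinks approximately like
#' \eqn{N^{-1/2}}.
#'
#' @param params a \linkS4class{UnitParams}; \code{nExc}/\code{nInh} are
#'   overridden by \code{nValues}.
#' @param horizon simulated time per N (after \code{transient}).
#' @param nValues excitatory ensemble sizes to test.
#' @param seed integer seed for the stochastic runs.
#' @param transient discarded initial interval.
#' @param dt Euler-Maruyama step.
#' @param gridSize phase grid for the mean field.
#' @param initPreset initial-condition preset for both paths
#'   (\code{"uniform"} ignites the synchronized regime,
#'   \code{"near-equilibrium"} the asynchronous one).
#' @param nBatches batches for the standard-error estimate.
#' @return data.frame with columns \code{n}, \code{rateMC}, \code{seMC},
#'   \code{rateFP}, \code{discrepancy}; the mean-field value is attached
#'   as attribute \code{"rateFP"}.
#' @export
mcFpAgreement <- function(params, horizon = 400, nValues = c(100, 300, 1000),
                          seed = 1, transient = 100, dt = 0.01,
                          gridSize = 128,
                          initPreset = c("uniform", "near-equilibrium"),
                          nBatches = 20) {
  initPreset <- match.arg(initPreset)
  net1 <- singleUnitNetwork(params)
  dpreset <- if (initPreset == "uniform") "uniform" else "equilibrium"
  st0 <- initDensity(net1, gridSize, dpreset)
  tr <- integrateFP(net1, st0, NULL, duration = transient + horizon,
                    outputStride = 0.25)
  sel <- tr@times >= transient
  rateFP <- mean(tr@fluxExc[sel, 1])
  rows <- lapply(nValues, function(n) {
    p <- params
    p@nExc <- as.integer(n)
    p@nInh <- as.integer(max(1, round(n / 4)))
    st <- initPhaseState(p, preset = initPreset, seed = seed + n)
    out <- simulateUnit(p, st, duration = transient + horizon, dt = dt,
                        seed = seed + n)
    ev <- out$raster@events
    te <- ev$time[ev$ensemble == "E" & ev$time >= transient]
    rate <- length(te) / (horizon * p@nExc)
    edges <- seq(transient, transient + horizon, length.out = nBatches + 1)
    cnt <- graphics::hist(te, breaks = edges, plot = FALSE)$counts
    brates <- cnt / (diff(edges) * p@nExc)
    se <- stats::sd(brates) / sqrt(nBatches)
    data.frame(n = n, rateMC = rate, seMC = se, rateFP = rateFP,
               discrepancy = abs(rate - rateFP))
  })
  out <- do.call(rbind, rows)
  attr(out, "rateFP") <- rateFP
  out
}
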