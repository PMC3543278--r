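#' @import methods
NULL

#' Parameters of one excitatory/inhibitory theta-neuron unit
#'
#' A unit is a globally coupled subnetwork of \code{nExc} excitatory
#' (pyramidal, PYR) and \code{nInh} inhibitory (fast-spiking interneuron, IN)
#' phase neurons.  Each neuron obeys the theta-neuron equation
#' \deqn{\dot\theta = (1-\cos\theta) + (1+\cos\theta)\,(r + \xi(t) + u(t)),}
#' where \eqn{r} is the constant external drive (negative values place the
#' neuron in the excitable regime below the saddle-node bifurcation),
#' \eqn{\xi} is Gaussian white noise of intensity \code{noiseIntensity}
#' (\eqn{\langle\xi(t)\xi(t')\rangle = D\,\delta(t-t')}), and \eqn{u} collects
#' the synaptic inputs.  A spike is the upward crossing of
#' \code{spikePhase} (\eqn{\pi} by convention).  Chemical synapses are
#' all-to-all with exponential postsynaptic currents of decay times
#' \code{kappaExc}/\code{kappaInh}; interneurons are additionally coupled
#' diffusively (gap junctions) with coefficient \code{gapStrength}.
#'
#' Coupling strengths are named source-to-target: \code{gEE} is PYR to PYR,
#' \code{gEI} PYR to IN, \code{gIE} IN to PYR, \code{gII} IN to IN.
#'
#' @slot nExc,nInh integer ensemble sizes (used by the finite-N simulator;
#'   the mean-field limit is independent of them).
#' @slot driveExc,driveInh external drive parameters \eqn{r_E}, \eqn{r_I}.
#' @slot gEE,gEI,gIE,gII intra-unit chemical coupling strengths.
#' @slot gapStrength diffusive IN-IN coupling coefficient.
#' @slot kappaExc,kappaInh exponential PSC decay times.
#' @slot noiseIntensity white-noise intensity \eqn{D \ge 0}.
#' @slot spikePhase phase whose upward crossing defines a firing time.
#' @exportClass UnitParams
setClass("UnitParams",
  representation(
    nExc = "integer", nInh = "integer",
    driveExc = "numeric", driveInh = "numeric",
    gEE = "numeric", gEI = "numeric", gIE = "numeric", gII = "numeric",
    gapStrength = "numeric",
    kappaExc = "numeric", kappaInh = "numeric",
    noiseIntensity = "numeric", spikePhase = "numeric"
  )
)

setValidity("UnitParams", function(object) {
  msg <- character(0)
  if (length(object@nExc) != 1L || object@nExc < 1L)
    msg <- c(msg, "nExc must be a positive count")
  if (length(object@nInh) != 1L || object@nInh < 1L)
    msg <- c(msg, "nInh must be a positive count")
  if (object@kappaExc <= 0 || object@kappaInh <= 0)
    msg <- c(msg, "PSC timescales must be > 0")
  if (object@noiseIntensity < 0)
    msg <- c(msg, "noiseIntensity must be >= 0")
  if (object@spikePhase <= -pi || object@spikePhase > pi)
    msg <- c(msg, "spikePhase must lie in (-pi, pi]")
  if (any(c(object@gEE, object@gEI, object@gIE, object@gII,
            object@gapStrength) < 0))
    msg <- c(msg, "coupling strengths must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Instantaneous phases and synaptic currents of a finite-N network
#'
#' Phases are stored wrapped to \eqn{(-\pi, \pi]}, one column per unit.
#' \code{synExc}/\code{synInh} hold the summed exponential postsynaptic
#' currents per unit.  \code{step} is the global integrator step index; it
#' indexes the counter-based noise streams so that a run split into chunks
#' reproduces a single continuous run bit-for-bit.
#'
#' @slot phasesExc,phasesInh numeric matrices (neurons x units), radians.
#' @slot synExc,synInh per-unit summed postsynaptic currents (>= 0).
#' @slot time simulation clock.
#' @slot step global step counter for the noise streams.
#' @exportClass PhaseState
setClass("PhaseState",
  representation(
    phasesExc = "matrix", phasesInh = "matrix",
    synExc = "numeric", synInh = "numeric",
    time = "numeric", step = "numeric"
  )
)

setValidity("PhaseState", function(object) {
  msg <- character(0)
  ph <- c(object@phasesExc, object@phasesInh)
  if (any(!is.finite(ph))) msg <- c(msg, "phases must be finite")
  if (any(ph <= -pi - 1e-9) || any(ph > pi + 1e-9))
    msg <- c(msg, "phases must be wrapped to (-pi, pi]")
  if (any(!is.finite(c(object@synExc, object@synInh))) ||
      any(c(object@synExc, object@synInh) < 0))
    msg <- c(msg, "synaptic currents must be finite and >= 0")
  if (ncol(object@phasesExc) != ncol(object@phasesInh))
    msg <- c(msg, "phasesExc and phasesInh must have one column per unit")
  if (length(msg)) msg else TRUE
})

#' Spike raster of a finite-N simulation
#'
#' @slot events data.frame with columns \code{time}, \code{ensemble}
#'   (\code{"E"} or \code{"I"}), \code{neuron} (1-based within ensemble) and
#'   \code{unit} (1-based), sorted by time.
#' @slot duration length of the recorded interval.
#' @slot nExc,nInh ensemble sizes (needed for rate normalization).
#' @slot nUnits number of units.
#' @exportClass SpikeRaster
setClass("SpikeRaster",
  representation(events = "data.frame", duration = "numeric",
                 nExc = "integer", nInh = "integer", nUnits = "integer")
)

setValidity("SpikeRaster", function(object) {
  ev <- object@events
  msg <- character(0)
  need <- c("time", "ensemble", "neuron", "unit")
  if (!all(need %in% names(ev)))
    return("events must have columns time, ensemble, neuron, unit")
  if (nrow(ev)) {
    if (is.unsorted(ev$time)) msg <- c(msg, "events must be sorted by time")
    if (any(ev$time < 0) || any(ev$time > object@duration + 1e-9))
      msg <- c(msg, "event times must lie within [0, duration]")
    if (!all(ev$ensemble %in% c("E", "I")))
      msg <- c(msg, "ensemble must be 'E' or 'I'")
  }
  if (length(msg)) msg else TRUE
})

#' Instantaneous firing-rate estimate
#'
#' Per-ensemble rates are normalized by ensemble size: the time integral of
#' each rate equals (spike count)/(ensemble size) up to kernel edge effects.
#'
#' @slot times sample grid.
#' @slot rateExc,rateInh matrices (time x unit) of rates (spikes per neuron
#'   per unit time).
#' @slot kernelWidth width of the Gaussian smoothing kernel.
#' @exportClass RateTrace
setClass("RateTrace",
  representation(times = "numeric", rateExc = "matrix", rateInh = "matrix",
                 kernelWidth = "numeric")
)

#' Stored binary patterns over the units of a memory network
#'
#' @slot patterns integer matrix (units x patterns) with entries in {0, 1}.
#' @slot activeFraction target mean fraction of active units per pattern
#'   (the pattern firing rate \eqn{a}).
#' @exportClass PatternSet
setClass("PatternSet",
  representation(patterns = "matrix", activeFraction = "numeric")
)

setValidity("PatternSet", function(object) {
  pm <- object@patterns
  msg <- character(0)
  if (!all(pm %in% c(0, 1))) msg <- c(msg, "pattern entries must be 0/1")
  if (ncol(pm) < 1L || nrow(pm) < 1L)
    msg <- c(msg, "need at least one pattern over at least one unit")
  a <- object@activeFraction
  if (a <= 0 || a >= 1) msg <- c(msg, "activeFraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Modified-Hebbian inter-unit weights
#'
#' Weight matrices are indexed target-by-source: \code{wEE[k, l]} couples the
#' excitatory ensemble of unit \code{l} to the excitatory ensemble of unit
#' \code{k}.  PYRs receive inter-unit input from PYRs (\code{wEE}) and from
#' INs (\code{wEI}); INs receive inter-unit input only from PYRs
#' (\code{wIE}) -- there is no IN-to-IN family.
#'
#' @slot wEE,wIE,wEI M x M weight matrices (PYR->PYR, PYR->IN, IN->PYR).
#' @slot intensities named numeric: positive scale parameters
#'   \code{ee}, \code{ie}, \code{ei} of the three families.
#' @slot regulationX regulating parameter replacing the complement factor in
#'   the IN->PYR pattern product.
#' @slot regulationC common regulation parameter from which the three
#'   subtraction constants are derived.
#' @exportClass InterUnitWeights
setClass("InterUnitWeights",
  representation(wEE = "matrix", wIE = "matrix", wEI = "matrix",
                 intensities = "numeric", regulationX = "numeric",
                 regulationC = "numeric")
)

setValidity("InterUnitWeights", function(object) {
  msg <- character(0)
  dms <- vapply(list(object@wEE, object@wIE, object@wEI), nrow, 1L)
  if (length(unique(c(dms, vapply(list(object@wEE, object@wIE, object@wEI),
                                  ncol, 1L)))) != 1L)
    msg <- c(msg, "weight matrices must be square with a common dimension")
  if (!all(c("ee", "ie", "ei") %in% names(object@intensities)))
    msg <- c(msg, "intensities must be named ee, ie, ei")
  else if (any(object@intensities[c("ee", "ie", "ei")] < 0))
    msg <- c(msg, "intensities must be positive")
  if (length(msg)) msg else TRUE
})

#' A multi-unit associative memory network
#'
#' @slot mUnits number of units M.
#' @slot unitParams shared \linkS4class{UnitParams} of every unit.
#' @slot weights \linkS4class{InterUnitWeights}.
#' @slot patterns \linkS4class{PatternSet}.
#' @exportClass MemoryNetwork
setClass("MemoryNetwork",
  representation(mUnits = "integer", unitParams = "UnitParams",
                 weights = "InterUnitWeights", patterns = "PatternSet")
)

setValidity("MemoryNetwork", function(object) {
  M <- object@mUnits
  msg <- character(0)
  if (nrow(object@weights@wEE) != M)
    msg <- c(msg, "weight dimension does not match mUnits")
  if (nrow(object@patterns@patterns) != M)
    msg <- c(msg, "pattern length does not match mUnits")
  if (length(msg)) msg else TRUE
})

#' Time courses of the neuromodulatory signals
#'
#' The cholinergic reduction of inhibition \eqn{g_{ACh}(t)} scales every
#' IN->PYR strength (intra-unit \code{gIE} and inter-unit \code{wEI}) by
#' \eqn{(1 - g_{ACh})}; the cholinergic modulation of excitation
#' \eqn{g_E(t)} scales every PYR->PYR strength (intra-unit \code{gEE} and
#' inter-unit \code{wEE}) by \eqn{(1 - g_E)}.  Both follow the same shape: 0
#' before \code{achWindow[1]}, the plateau level inside the window, and an
#' exponential relaxation with time constant \code{achDecay} after
#' \code{achWindow[2]} (\code{achDecay = 0} switches off instantly,
#' \code{achDecay = Inf} holds the plateau).  The top-down glutamatergic
#' drive adds \code{gluIncrement} to the excitatory drive of the units in
#' \code{gluUnits} during \code{gluWindow}.
#'
#' @slot achLevel,gELevel plateau values in [0, 1).
#' @slot achWindow numeric(2), plateau interval shared by both factors.
#' @slot achDecay exponential relaxation time constant after the window.
#' @slot gluUnits 1-based unit indices receiving the top-down drive.
#' @slot gluIncrement additive increase of the excitatory drive.
#' @slot gluWindow numeric(2), interval of the glutamatergic input.
#' @exportClass ModulationSchedule
setClass("ModulationSchedule",
  representation(achLevel = "numeric", gELevel = "numeric",
                 achWindow = "numeric", achDecay = "numeric",
                 gluUnits = "integer", gluIncrement = "numeric",
                 gluWindow = "numeric")
)

setValidity("ModulationSchedule", function(object) {
  msg <- character(0)
  if (object@achLevel < 0 || object@achLevel >= 1)
    msg <- c(msg, "achLevel must be in [0, 1)")
  if (object@gELevel < 0 || object@gELevel >= 1)
    msg <- c(msg, "gELevel must be in [0, 1)")
  if (length(object@achWindow) != 2L || diff(object@achWindow) < 0)
    msg <- c(msg, "achWindow must be an ascending pair")
  if (length(object@gluWindow) != 2L || diff(object@gluWindow) < 0)
    msg <- c(msg, "gluWindow must be an ascending pair")
  if (object@achDecay < 0) msg <- c(msg, "achDecay must be >= 0 (or Inf)")
  if (object@gluIncrement != 0 && object@achLevel > 0) {
    ach_eff <- diff(object@achWindow) +
      if (is.finite(object@achDecay)) 3 * object@achDecay else Inf
    # a zero-duration ACh course is no ACh signal; only a real course
    # constrains the (faster) glutamatergic input
    if (ach_eff > 0 && diff(object@gluWindow) > ach_eff)
      msg <- c(msg, "the Glu window must be shorter than the ACh effect")
  }
  if (length(msg)) msg else TRUE
})

#' State of the Fokker-Planck mean field
#'
#' Holds the phase densities of every ensemble on a uniform periodic grid
#' over \eqn{(-\pi, \pi]} together with the per-unit synaptic currents.
#' Densities integrate to 1 (trapezoidal rule on the periodic grid).
#'
#' @slot gridSize number of phase grid points K.
#' @slot densities numeric matrix (K x 2M): columns 1..M excitatory,
#'   M+1..2M inhibitory densities (probability per radian).
#' @slot synCurrents length-2M synaptic currents (E then I blocks).
#' @slot time mean-field clock.
#' @exportClass MeanFieldState
setClass("MeanFieldState",
  representation(gridSize = "integer", densities = "matrix",
                 synCurrents = "numeric", time = "numeric")
)

setValidity("MeanFieldState", function(object) {
  msg <- character(0)
  K <- object@gridSize
  if (nrow(object@densities) != K)
    msg <- c(msg, "densities must have gridSize rows")
  if (ncol(object@densities) %% 2L != 0L)
    msg <- c(msg, "densities must have 2M columns")
  h <- 2 * pi / K
  mass <- colSums(object@densities) * h
  if (any(abs(mass - 1) > 1e-6))
    msg <- c(msg, "each density must integrate to 1 (+/- 1e-6)")
  if (length(msg)) msg else TRUE
})

#' Population firing rates of a mean-field run
#'
#' \code{fluxExc}/\code{fluxInh} are the probability fluxes evaluated at the
#' spike phase, i.e. the instantaneous population firing rates in the
#' infinite-N limit.  \code{diagnostics} records solver statistics
#' (normalization drift, minimum density, accepted/rejected steps).
#'
#' @slot times output grid.
#' @slot fluxExc,fluxInh matrices (time x unit).
#' @slot synExc,synInh matrices (time x unit) of synaptic currents.
#' @slot finalState \linkS4class{MeanFieldState} at the end of the run.
#' @slot diagnostics named list of solver diagnostics.
#' @exportClass FluxTrace
setClass("FluxTrace",
  representation(times = "numeric", fluxExc = "matrix", fluxInh = "matrix",
                 synExc = "matrix", synInh = "matrix",
                 finalState = "MeanFieldState", diagnostics = "list")
)

#' Pattern-overlap time series
#'
#' @slot times sample grid.
#' @slot m matrix (time x patterns) of overlaps in [0, 1].
#' @slot peakHeld matrix (time x units): local-peak-held firing rates.
#' @slot normalized matrix (time x units): peak-held rates mapped to [0, 1].
#' @exportClass OverlapTrace
setClass("OverlapTrace",
  representation(times = "numeric", m = "matrix", peakHeld = "matrix",
                 normalized = "matrix")
)

setValidity("OverlapTrace", function(object) {
  if (any(object@m < -1e-9 | object@m > 1 + 1e-9))
    "overlaps must lie in [0, 1]" else TRUE
})

#' Staying times at quasi-attractors
#'
#' @slot intervals data.frame with columns \code{pattern}, \code{start},
#'   \code{end}, \code{censored}; maximal intervals during which one
#'   pattern's overlap stays above the threshold.
#' @slot meanStayingTime mean over uncensored intervals (NA if none).
#' @slot threshold overlap threshold used.
#' @slot horizon length of the analyzed trace.
#' @exportClass StayingTimeResult
setClass("StayingTimeResult",
  representation(intervals = "data.frame", meanStayingTime = "numeric",
                 threshold = "numeric", horizon = "numeric")
)

#' Largest Lyapunov exponent estimate
#'
#' @slot exponents estimated exponent(s), largest first.
#' @slot running running finite-time estimates (convergence diagnostic).
#' @slot converged TRUE when the relative drift of the running estimate over
#'   the final third of the run is below the tolerance.
#' @slot method description of the estimator.
#' @exportClass LyapunovResult
setClass("LyapunovResult",
  representation(exponents = "numeric", running = "numeric",
                 converged = "logical", method = "character")
)

#' Report of a scripted experiment
#'
#' @slot name experiment label.
#' @slot flux \linkS4class{FluxTrace} of the mean-field run.
#' @slot overlap \linkS4class{OverlapTrace}.
#' @slot staying \linkS4class{StayingTimeResult}.
#' @slot visits data.frame of pattern visits (pattern, start, end, censored).
#' @slot config named list with the full configuration of the run.
#' @exportClass ExperimentReport
setClass("ExperimentReport",
  representation(name = "character", flux = "FluxTrace",
                 overlap = "OverlapTrace", staying = "StayingTimeResult",
                 visits = "data.frame", config = "list")
)
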