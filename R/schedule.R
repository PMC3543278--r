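#' Construct a modulation schedule
#'
#' @param achLevel plateau value of the cholinergic reduction of inhibition
#'   \eqn{g_{ACh}} in [0, 1).
#' @param gELevel plateau value of the cholinergic modulation of excitation
#'   \eqn{g_E} in [0, 1).
#' @param achWindow numeric(2): interval during which the plateau holds.
#'   Use \code{c(0, Inf)} for a constant level.
#' @param achDecay time constant of the exponential relaxation after the
#'   window (0 = instant return to baseline, Inf = hold forever).
#' @param gluUnits 1-based indices of the units receiving the top-down
#'   glutamatergic drive.
#' @param gluIncrement additive increase of the excitatory drive of those
#'   units.
#' @param gluWindow numeric(2): interval of the glutamatergic input.
#' @return A \linkS4class{ModulationSchedule}.
#' @examples
#' # constant cholinergic reduction of inhibition at 0.1:
#' ModulationSchedule(achLevel = 0.1)
#' @export
ModulationSchedule <- function(achLevel = 0, gELevel = 0,
                               achWindow = c(0, Inf), achDecay = Inf,
                               gluUnits = integer(0), gluIncrement = 0,
                               gluWindow = c(0, 0)) {
  new("ModulationSchedule", achLevel = as.numeric(achLevel),
      gELevel = as.numeric(gELevel), achWindow = as.numeric(achWindow),
      achDecay = as.numeric(achDecay), gluUnits = as.integer(gluUnits),
      gluIncrement = as.numeric(gluIncrement),
      gluWindow = as.numeric(gluWindow))
}

#' Evaluate a modulation schedule at one time
#'
#' Returns the instantaneous factors \eqn{g_{ACh}(t)}, \eqn{g_E(t)} and the
#' per-unit drive increments.  Both cholinergic factors share the same time
#' course: 0 before the window, the plateau inside it, and an exponential
#' tail \eqn{\exp(-(t - t_1)/\tau)} after it.
#'
#' @param schedule a \linkS4class{ModulationSchedule}.
#' @param t time (scalar, >= 0).
#' @param nUnits number of units (length of the increment vector).
#' @return list with elements \code{gAch}, \code{gE}, \code{gluIncrements}.
#' @export
applySchedule <- function(schedule, t, nUnits) {
  stopifnot(length(t) == 1L, t >= 0)
  shape <- if (t < schedule@achWindow[1]) 0
    else if (t <= schedule@achWindow[2]) 1
    else if (schedule@achDecay == 0) 0
    else if (is.infinite(schedule@achDecay)) 1
    else exp(-(t - schedule@achWindow[2]) / schedule@achDecay)
  glu <- numeric(nUnits)
  if (schedule@gluIncrement != 0 && t >= schedule@gluWindow[1] &&
      t < schedule@gluWindow[2])
    glu[schedule@gluUnits] <- schedule@gluIncrement
  list(gAch = schedule@achLevel * shape, gE = schedule@gELevel * shape,
       gluIncrements = glu)
}

setMethod("show", "ModulationSchedule", function(object) {
  cat(sprintf("ModulationSchedule: gACh = %g, gE = %g on [%g, %g], decay tau = %g\n",
              object@achLevel, object@gELevel, object@achWindow[1],
              object@achWindow[2], object@achDecay))
  if (object@gluIncrement != 0)
    cat(sprintf("  Glu: +%g to units {%s} on [%g, %g)\n",
                object@gluIncrement,
                paste(object@gluUnits, collapse = ", "),
                object@gluWindow[1], object@gluWindow[2]))
})

# internal: schedule list for the C++ integrators
.sched_list <- function(s) {
  if (is.null(s))
    return(list(ach_level = 0, ach_t0 = 0, ach_t1 = Inf, ach_tau = Inf,
                ge_level = 0, ge_t0 = 0, ge_t1 = Inf, ge_tau = Inf,
                glu_inc = 0, glu_t0 = 0, glu_t1 = 0,
                glu_units = integer(0)))
  list(ach_level = s@achLevel, ach_t0 = s@achWindow[1],
       ach_t1 = s@achWindow[2], ach_tau = s@achDecay,
       ge_level = s@gELevel, ge_t0 = s@achWindow[1],
       ge_t1 = s@achWindow[2], ge_tau = s@achDecay,
       glu_inc = s@gluIncrement, glu_t0 = s@gluWindow[1],
       glu_t1 = s@gluWindow[2], glu_units = s@gluUnits - 1L)
}

#' Per-unit input assembly (reference implementation)
#'
#' Assembles the summed synaptic input to the PYR and IN ensembles of unit
#' \code{k} from the intra-unit couplings and the three inter-unit weight
#' families, with the modulation factors applied: every IN->PYR strength is
#' scaled by \eqn{(1 - g_{ACh})} and every PYR->PYR strength by
#' \eqn{(1 - g_E)}.  This plain-R routine defines the input contract; the
#' compiled integrators implement the identical assembly and are tested
#' against it.
#'
#' @param k 1-based unit index.
#' @param synExc,synInh per-unit synaptic currents (length M).
#' @param params \linkS4class{UnitParams}.
#' @param weights \linkS4class{InterUnitWeights}.
#' @param gAch,gE instantaneous modulation factors.
#' @return list with \code{inputExc} and \code{inputInh}.
#' @export
unitInput <- function(k, synExc, synInh, params, weights, gAch = 0, gE = 0) {
  M <- length(synExc)
  stopifnot(length(synInh) == M, k >= 1, k <= M)
  wEE <- weights@wEE; wIE <- weights@wIE; wEI <- weights@wEI
  inputExc <- (1 - gE) * (params@gEE * synExc[k] +
                            sum(wEE[k, ] * synExc)) -
    (1 - gAch) * (params@gIE * synInh[k] + sum(wEI[k, ] * synInh))
  inputInh <- params@gEI * synExc[k] + sum(wIE[k, ] * synExc) -
    params@gII * synInh[k]
  list(inputExc = inputExc, inputInh = inputInh)
}
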