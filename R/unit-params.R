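#' Construct the parameters of one theta-neuron unit
#'
#' All physical parameters must be given explicitly unless a named
#' \code{preset} is requested; there are no silent defaults.
#'
#' @param nExc,nInh ensemble sizes (positive integers).
#' @param driveExc,driveInh external drives \eqn{r_E}, \eqn{r_I}
#'   (dimensionless; negative = excitable).
#' @param gEE,gEI,gIE,gII intra-unit coupling strengths, source to target.
#' @param gapStrength diffusive IN-IN coupling coefficient.
#' @param kappaExc,kappaInh PSC decay times.
#' @param noiseIntensity white-noise intensity \eqn{D}.
#' @param spikePhase spike threshold phase (default \eqn{\pi}).
#' @return A \linkS4class{UnitParams} object.
#' @seealso [unitPreset()] for the calibrated reference parameter sets.
#' @examples
#' p <- UnitParams(nExc = 100, nInh = 25, driveExc = -0.025,
#'                 driveInh = -0.025, gEE = 0, gEI = 0, gIE = 0, gII = 0,
#'                 gapStrength = 0, noiseIntensity = 0.005)
#' @export
UnitParams <- function(nExc, nInh, driveExc, driveInh, gEE, gEI, gIE, gII,
                       gapStrength, kappaExc = 1, kappaInh = 1,
                       noiseIntensity, spikePhase = pi) {
  new("UnitParams",
      nExc = as.integer(nExc), nInh = as.integer(nInh),
      driveExc = as.numeric(driveExc), driveInh = as.numeric(driveInh),
      gEE = as.numeric(gEE), gEI = as.numeric(gEI), gIE = as.numeric(gIE),
      gII = as.numeric(gII), gapStrength = as.numeric(gapStrength),
      kappaExc = as.numeric(kappaExc), kappaInh = as.numeric(kappaInh),
      noiseIntensity = as.numeric(noiseIntensity),
      spikePhase = as.numeric(spikePhase))
}

#' Calibrated reference parameter sets for one unit
#'
#' \code{"bistable"} places the unit in the weak-noise regime where irregular
#' synchronized firing of the PYR-IN loop coexists with a near-silent
#' asynchronous state, the one-unit phenomenology of the model.
#' \code{"network"} is the operating point shared by every unit of the
#' memory-network presets: slow inhibition near the burst-failure crisis
#' makes the unit burst intermittently, and the quiet excursions of that
#' attractor are what allow activity to migrate between stored patterns.
#' \code{"excitable"} removes all couplings from the \code{"bistable"} unit
#' (noise-driven subthreshold dynamics), used for stationary-solution
#' checks.
#'
#' The numeric values are package calibrations: they were chosen, once, so
#' that the unit exhibits the qualitative regimes that define the model
#' (see the methods vignette), and they are used by every network preset.
#'
#' @param name \code{"bistable"}, \code{"network"} or \code{"excitable"}.
#' @param nExc,nInh ensemble sizes for finite-N simulation.
#' @return A \linkS4class{UnitParams} object.
#' @export
unitPreset <- function(name = c("bistable", "network", "excitable"),
                       nExc = 1000, nInh = 250) {
  name <- match.arg(name)
  base <- switch(name, network = .network_unit_values, .bistable_unit_values)
  if (name == "excitable") {
    base[c("gEE", "gEI", "gIE", "gII", "gapStrength")] <- 0
    # moderate noise: the uncoupled population relaxes to its stationary
    # state within a short horizon (weak noise leaves a long-lived
    # slowly-damped circulation transient)
    base["noiseIntensity"] <- 0.005
    base["kappaInh"] <- 1
  }
  UnitParams(nExc = nExc, nInh = nInh,
             driveExc = base[["driveExc"]], driveInh = base[["driveInh"]],
             gEE = base[["gEE"]], gEI = base[["gEI"]], gIE = base[["gIE"]],
             gII = base[["gII"]], gapStrength = base[["gapStrength"]],
             kappaExc = base[["kappaExc"]], kappaInh = base[["kappaInh"]],
             noiseIntensity = base[["noiseIntensity"]])
}

# Calibrated working points (see vignette, section "Calibration").
# One-unit regime: weak noise; a near-silent quiescent state coexists with
# irregular-amplitude synchronized firing of the PYR-IN loop.
.bistable_unit_values <- c(
  driveExc = -0.025, driveInh = -0.025,
  gEE = 8.1, gEI = 5.7, gIE = 3.9, gII = 3.85,
  gapStrength = 0, kappaExc = 1, kappaInh = 3,
  noiseIntensity = 0.002
)
# Network unit: slow inhibition near the burst-failure crisis gives an
# intermittently bursting attractor whose quiet excursions let the stored
# patterns exchange activity (itinerancy); the regulation constants
# preserve these one-unit dynamics inside an active pattern.
.network_unit_values <- c(
  driveExc = -0.025, driveInh = -0.025,
  gEE = 6.85, gEI = 5.29, gIE = 5.01, gII = 3.54,
  gapStrength = 0, kappaExc = 1, kappaInh = 5,
  noiseIntensity = 0.0052
)

# internal: parameter list handed to the C++ integrators
.pars_list <- function(p) {
  list(r_e = p@driveExc, r_i = p@driveInh, g_ee = p@gEE, g_ei = p@gEI,
       g_ie = p@gIE, g_ii = p@gII, g_gap = p@gapStrength,
       kappa_e = p@kappaExc, kappa_i = p@kappaInh, D = p@noiseIntensity)
}

setMethod("show", "UnitParams", function(object) {
  cat("UnitParams:", object@nExc, "PYRs +", object@nInh, "INs\n")
  cat(sprintf("  drive (rE, rI) = (%g, %g); D = %g\n", object@driveExc,
              object@driveInh, object@noiseIntensity))
  cat(sprintf("  g (EE, EI, IE, II) = (%g, %g, %g, %g); gap = %g\n",
              object@gEE, object@gEI, object@gIE, object@gII,
              object@gapStrength))
  cat(sprintf("  PSC decay (kE, kI) = (%g, %g); spike phase = %g\n",
              object@kappaExc, object@kappaInh, object@spikePhase))
})
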