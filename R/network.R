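#' Assemble a multi-unit associative memory network
#'
#' @param unitParams shared \linkS4class{UnitParams} for every unit.
#' @param patterns a \linkS4class{PatternSet}; its unit count fixes M.
#' @param weights an \linkS4class{InterUnitWeights}; if missing, built from
#'   \code{patterns} with \code{intensities}, \code{regulationX},
#'   \code{regulationC}.
#' @param intensities,regulationX,regulationC passed to
#'   [buildInterUnitWeights()] when \code{weights} is missing.
#' @return A \linkS4class{MemoryNetwork}.
#' @export
MemoryNetwork <- function(unitParams, patterns, weights = NULL,
                          intensities = NULL, regulationX = NULL,
                          regulationC = NULL) {
  if (is.null(weights)) {
    if (is.null(intensities) || is.null(regulationX) || is.null(regulationC))
      stop("either weights or (intensities, regulationX, regulationC) ",
           "must be given")
    weights <- buildInterUnitWeights(patterns, intensities, regulationX,
                                     regulationC)
  }
  new("MemoryNetwork", mUnits = nrow(patterns@patterns),
      unitParams = unitParams, weights = weights, patterns = patterns)
}

#' Calibrated memory-network presets
#'
#' \code{"sixteen"}: the reference network of M = 16 units storing the three
#' built-in patterns (see [presetPatterns()]).  \code{"reduced"}: M = 8
#' units, 2 patterns, used for desk-scale experiments and by the test
#' suite.  Both use the \code{"network"} unit preset and the calibrated
#' inter-unit intensities (see the methods vignette).
#'
#' @param name \code{"sixteen"} or \code{"reduced"}.
#' @param nExc,nInh finite-N ensemble sizes carried by the unit parameters.
#' @return A \linkS4class{MemoryNetwork}.
#' @export
networkPreset <- function(name = c("sixteen", "reduced"),
                          nExc = 1000, nInh = 250) {
  name <- match.arg(name)
  up <- unitPreset("network", nExc = nExc, nInh = nInh)
  ps <- presetPatterns(if (name == "sixteen") "sixteen" else "reduced")
  iw <- .interunit_values
  MemoryNetwork(up, ps,
                intensities = c(ee = iw[["ee"]], ie = iw[["ie"]],
                                ei = iw[["ei"]]),
                regulationX = iw[["X"]], regulationC = iw[["c"]])
}

# Calibrated inter-unit values (see vignette, section "Calibration").
.interunit_values <- c(ee = 1.5, ie = 1, ei = 0.6, X = 1, c = 2.67)

#' @describeIn MemoryNetwork-class number of units M.
#' @param x a \linkS4class{MemoryNetwork}.
#' @export
nUnits <- function(x) x@mUnits

#' @describeIn MemoryNetwork-class the shared unit parameters.
#' @export
unitParams <- function(x) x@unitParams

#' @describeIn MemoryNetwork-class the inter-unit weights.
#' @export
interUnitWeights <- function(x) x@weights

setMethod("show", "MemoryNetwork", function(object) {
  cat(sprintf("MemoryNetwork: %d units, %d stored pattern(s)\n",
              object@mUnits, ncol(object@patterns@patterns)))
  show(object@unitParams)
  show(object@weights)
})

#' A single unit viewed as a degenerate memory network
#'
#' Wraps one \linkS4class{UnitParams} as an M = 1 network with zero
#' inter-unit weights, so that every mean-field and Lyapunov routine can be
#' applied to the one-unit system.
#'
#' @param unitParams a \linkS4class{UnitParams}.
#' @return A \linkS4class{MemoryNetwork} with \code{mUnits = 1}.
#' @export
singleUnitNetwork <- function(unitParams) {
  ps <- PatternSet(matrix(1, 1, 1), activeFraction = 0.999)
  w <- new("InterUnitWeights", wEE = matrix(0, 1, 1), wIE = matrix(0, 1, 1),
           wEI = matrix(0, 1, 1), intensities = c(ee = 0, ie = 0, ei = 0),
           regulationX = 1, regulationC = 0)
  new("MemoryNetwork", mUnits = 1L, unitParams = unitParams, weights = w,
      patterns = ps)
}
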