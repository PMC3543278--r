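#' Modified-Hebbian inter-unit weights
#'
#' Builds the three inter-unit weight families from the stored patterns
#' \eqn{\eta^\mu \in \{0,1\}^M}.  With pattern co-activation sums
#' \deqn{S_{kl} = \sum_\mu \eta^\mu_k \eta^\mu_l, \qquad
#'       T_{kl} = \sum_\mu (X - \eta^\mu_k)\, \eta^\mu_l,}
#' the weights are
#' \deqn{w^{EE}_{kl} = \frac{G_{EE}}{aM}\,S_{kl} - c_E, \quad
#'       w^{IE}_{kl} = \frac{G_{IE}}{aM}\,S_{kl} - c_I, \quad
#'       w^{EI}_{kl} = \frac{G_{EI}}{aM}\,T_{kl} - c_X,}
#' where the excitatory families \eqn{w^{EE}} (PYR of l to PYR of k) and
#' \eqn{w^{IE}} (PYR of l to IN of k) connect co-active units and promote
#' inter-unit synchronization, while the inhibitory family \eqn{w^{EI}}
#' (IN of l to PYR of k) carries the regulated complement factor
#' \eqn{(X - \eta^\mu_k)}: INs of an active unit inhibit the PYRs of units
#' that are inactive in the same pattern, which breaks synchronization
#' across patterns.  In the conventional associative-memory rule the
#' complement factor is \eqn{(1 - \eta^\mu_k)}; \eqn{X} generalizes it and
#' regulates how strongly active units suppress the rest.
#'
#' The three subtraction constants are derived from one common regulation
#' parameter \eqn{c}:
#' \deqn{c_E = \frac{G_{EE}\,c}{M},\quad c_I = \frac{G_{IE}\,c}{M},\quad
#'       c_X = \frac{G_{EI}\,c}{M}.}
#' Their role: inside a synchronized pattern the summed inter-unit input to
#' a unit's ensembles would shift the effective intra-unit couplings and
#' destroy the one-unit working-point dynamics; subtracting the constants removes
#' (for \eqn{c \approx 1/a}, exactly under perfect synchrony of a single
#' stored pattern) that shift, so the one-unit dynamics survive inside the
#' active cluster.  Because synchrony is imperfect when several patterns
#' are stored, \eqn{c} is kept as a free regulation parameter.
#'
#' @param patterns a \linkS4class{PatternSet}.
#' @param intensities named numeric with positive entries \code{ee},
#'   \code{ie}, \code{ei} (the scales \eqn{G_{EE}, G_{IE}, G_{EI}}).
#' @param regulationX the regulating parameter \eqn{X}.
#' @param regulationC the common regulation parameter \eqn{c}.
#' @return An \linkS4class{InterUnitWeights} object.
#' @examples
#' ps <- presetPatterns("reduced")
#' w <- buildInterUnitWeights(ps, c(ee = 1, ie = 1, ei = 1), 1, 0)
#' weightsEE(w)
#' @export
buildInterUnitWeights <- function(patterns, intensities, regulationX,
                                  regulationC) {
  stopifnot(is(patterns, "PatternSet"))
  if (!all(c("ee", "ie", "ei") %in% names(intensities)))
    stop("intensities must be named ee, ie, ei")
  if (any(intensities[c("ee", "ie", "ei")] < 0))
    stop("intensities must be positive")
  eta <- patterns@patterns            # M x P
  M <- nrow(eta)
  a <- patterns@activeFraction
  S <- eta %*% t(eta)                 # co-activation counts, symmetric
  # T_kl = sum_mu (X - eta_k^mu) eta_l^mu = X * (#patterns with l active) - S_kl
  pat_count <- rowSums(eta)
  Tm <- regulationX * matrix(pat_count, M, M, byrow = TRUE) - S
  cE <- intensities[["ee"]] * regulationC / M
  cI <- intensities[["ie"]] * regulationC / M
  cX <- intensities[["ei"]] * regulationC / M
  new("InterUnitWeights",
      wEE = intensities[["ee"]] / (a * M) * S - cE,
      wIE = intensities[["ie"]] / (a * M) * S - cI,
      wEI = intensities[["ei"]] / (a * M) * Tm - cX,
      intensities = c(ee = intensities[["ee"]], ie = intensities[["ie"]],
                      ei = intensities[["ei"]]),
      regulationX = as.numeric(regulationX),
      regulationC = as.numeric(regulationC))
}

#' @describeIn InterUnitWeights-class PYR-to-PYR inter-unit weight matrix.
#' @param x an \linkS4class{InterUnitWeights}.
#' @export
weightsEE <- function(x) x@wEE

#' @describeIn InterUnitWeights-class PYR-to-IN inter-unit weight matrix.
#' @export
weightsIE <- function(x) x@wIE

#' @describeIn InterUnitWeights-class IN-to-PYR inter-unit weight matrix.
#' @export
weightsEI <- function(x) x@wEI

setMethod("show", "InterUnitWeights", function(object) {
  cat(sprintf("InterUnitWeights over %d units\n", nrow(object@wEE)))
  cat(sprintf("  intensities (EE, IE, EI) = (%g, %g, %g); X = %g, c = %g\n",
              object@intensities[["ee"]], object@intensities[["ie"]],
              object@intensities[["ei"]], object@regulationX,
              object@regulationC))
})

# internal: weight list for the C++ integrators
.weights_list <- function(w, M) {
  if (is.null(w)) {
    z <- matrix(0, M, M)
    list(wee = z, wie = z, wei = z)
  } else {
    list(wee = w@wEE, wie = w@wIE, wei = w@wEI)
  }
}
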