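#' Fourier spectral differentiation matrix on a periodic grid
#'
#' Standard first-derivative matrix for an even number of equispaced points
#' on one period; exact for trigonometric polynomials up to the Nyquist
#' mode.  Column sums vanish, so the semi-discrete Fokker-Planck operator
#' conserves probability mass exactly.
#'
#' @param K number of grid points (even, >= 16).
#' @return K x K numeric matrix.
#' @export
spectralDiffMatrix <- function(K) {
  stopifnot(K %% 2 == 0, K >= 16)
  h <- 2 * pi / K
  j <- seq_len(K)
  Dm <- outer(j, j, function(a, b) {
    r <- a - b
    ifelse(r == 0, 0, 0.5 * (-1)^r / tan(r * h / 2))
  })
  Dm
}

#' Phase grid used by the mean-field discretization
#'
#' @param K number of grid points.
#' @return numeric vector of phases \eqn{-\pi + j 2\pi/K}, j = 0..K-1.
#' @export
phaseGrid <- function(K) -pi + (seq_len(K) - 1) * 2 * pi / K

#' Initial density presets for the mean field
#'
#' \code{"uniform"}: flat densities.  \code{"bump"}: a von-Mises-like bump
#' at phase \code{center} with concentration \code{concentration} in every
#' ensemble (selects the synchronized regime in a bistable unit).
#' \code{"equilibrium"}: a sharp bump at the stable equilibrium phase of
#' the uncoupled neuron (selects the asynchronous regime).
#' \code{"pattern"}: bump densities in the units active in stored pattern
#' \code{pattern}, equilibrium densities elsewhere (starts the network
#' inside that pattern's quasi-attractor).
#'
#' @param network a \linkS4class{MemoryNetwork}.
#' @param gridSize number of phase grid points K (even).
#' @param preset one of \code{"uniform"}, \code{"bump"},
#'   \code{"equilibrium"}, \code{"pattern"}.
#' @param pattern pattern index for \code{preset = "pattern"}.
#' @param center,concentration bump location and concentration.
#' @return A \linkS4class{MeanFieldState} at time 0.
#' @export
initDensity <- function(network, gridSize = 128,
                        preset = c("uniform", "bump", "equilibrium",
                                   "pattern"),
                        pattern = 1L, center = 1.5, concentration = 4) {
  preset <- match.arg(preset)
  M <- network@mUnits
  K <- as.integer(gridSize)
  th <- phaseGrid(K)
  h <- 2 * pi / K
  norm1 <- function(v) v / (sum(v) * h)
  r <- network@unitParams@driveExc
  th_eq <- if (r < 0) -2 * atan(sqrt(-r)) else 0
  dens <- list(
    uniform = rep(1 / (2 * pi), K),
    bump = norm1(exp(concentration * cos(th - center))),
    equilibrium = norm1(exp(10 * cos(th - th_eq)))
  )
  cols <- switch(preset,
    uniform = rep(list(dens$uniform), 2 * M),
    bump = rep(list(dens$bump), 2 * M),
    equilibrium = rep(list(dens$equilibrium), 2 * M),
    pattern = {
      eta <- network@patterns@patterns
      if (pattern < 1 || pattern > ncol(eta))
        stop("no such pattern: ", pattern)
      on <- eta[, pattern] == 1
      c(lapply(seq_len(M), function(k)
          if (on[k]) dens$bump else dens$equilibrium),
        lapply(seq_len(M), function(k)
          if (on[k]) dens$bump else dens$equilibrium))
    })
  new("MeanFieldState", gridSize = K,
      densities = matrix(unlist(cols), K, 2 * M),
      synCurrents = numeric(2 * M), time = 0)
}

#' Integrate the Fokker-Planck mean field of a memory network
#'
#' Advances the phase densities of all ensembles under drift (the
#' theta-neuron right-hand side with coupling through the synaptic
#' currents) and diffusion (the noise intensity), with the probability flux
#' at the spike phase feeding the synaptic-current ODEs
#' \eqn{\dot I_X = (-I_X + J_X)/\kappa_X}.  The discretization is Fourier
#' pseudo-spectral in phase; time stepping is adaptive Dormand-Prince 5(4).
#' The run is fully deterministic: repeated calls reproduce identical
#' output.
#'
#' Probability mass is conserved by construction (the spectral derivative
#' annihilates the mean mode); the realized normalization drift is
#' monitored and available in \code{diagnostics(result)$massDrift}, and the
#' run aborts if it exceeds \code{massTol}.  Small negative density
#' excursions (spectral ringing) are tolerated up to \code{negTol} and
#' reported, never clipped.
#'
#' @param network a \linkS4class{MemoryNetwork} (use
#'   [singleUnitNetwork()] for one unit).
#' @param init a \linkS4class{MeanFieldState}, e.g. from [initDensity()].
#' @param schedule a \linkS4class{ModulationSchedule} or NULL.
#' @param duration integration horizon (from \code{init@time}).
#' @param outputStride spacing of output samples.
#' @param rtol,atol local error tolerances of the adaptive stepper.
#' @param maxStep upper bound on the internal step.
#' @param negTol abort when any density falls below \code{-negTol}.
#' @param massTol abort when any density's normalization drifts by more.
#' @param recordDensities if > 0, keep every that-many-th density snapshot.
#' @return A \linkS4class{FluxTrace}.
#' @examples
#' net <- singleUnitNetwork(unitPreset("excitable"))
#' st <- initDensity(net, 64, "uniform")
#' tr <- integrateFP(net, st, NULL, duration = 20, outputStride = 1)
#' range(fluxExc(tr))
#' @export
integrateFP <- function(network, init, schedule = NULL, duration,
                        outputStride = 0.25, rtol = 1e-7, atol = 1e-9,
                        maxStep = 1, negTol = 0.05, massTol = 1e-6,
                        recordDensities = 0) {
  stopifnot(is(network, "MemoryNetwork"), is(init, "MeanFieldState"),
            duration > 0)
  M <- network@mUnits
  K <- init@gridSize
  if (ncol(init@densities) != 2 * M)
    stop("initial state has ", ncol(init@densities) / 2,
         " units, network has ", M)
  res <- cpp_integrate_fp(init@densities, init@synCurrents, init@time,
                          init@time + duration, outputStride,
                          .pars_list(network@unitParams),
                          .weights_list(network@weights, M),
                          .sched_list(schedule), rtol, atol, 1e-3,
                          maxStep, as.integer(recordDensities), negTol,
                          massTol)
  final <- new("MeanFieldState", gridSize = K, densities = res$N_final,
               synCurrents = as.numeric(res$I_final), time = res$t_final)
  new("FluxTrace", times = res$times, fluxExc = res$flux_e,
      fluxInh = res$flux_i, synExc = res$syn_e, synInh = res$syn_i,
      finalState = final,
      diagnostics = list(massDrift = res$mass_drift,
                         minDensity = res$min_density,
                         nAccepted = res$n_accepted,
                         nRejected = res$n_rejected,
                         densities = res$dens))
}

#' Probability flux profile and spike-phase flux of a mean-field state
#'
#' Evaluates \eqn{J(\theta) = A(\theta)\,n - (D/2) B\,\partial_\theta(B n)}
#' with the same spectral discretization as the integrator.  At the spike
#' phase \eqn{\theta = \pi} the diffusion factor \eqn{B = 1 + \cos\theta}
#' vanishes, so the flux — the instantaneous population firing rate —
#' reduces to \eqn{2 n(\pi)}.
#'
#' @param network a \linkS4class{MemoryNetwork}.
#' @param state a \linkS4class{MeanFieldState}.
#' @param schedule optional \linkS4class{ModulationSchedule}.
#' @return list with \code{profile} (K x 2M flux values on the grid) and
#'   \code{atSpikePhase} (list with per-unit \code{fluxExc},
#'   \code{fluxInh}).
#' @export
fluxAtSpikePhase <- function(network, state, schedule = NULL) {
  stopifnot(is(state, "MeanFieldState"))
  M <- network@mUnits
  prof <- cpp_fp_flux_profile(state@densities, state@synCurrents,
                              state@time, .pars_list(network@unitParams),
                              .weights_list(network@weights, M),
                              .sched_list(schedule))
  list(profile = prof,
       atSpikePhase = list(fluxExc = 2 * state@densities[1, seq_len(M)],
                           fluxInh = 2 * state@densities[1, M + seq_len(M)]))
}

#' Stationary phase density and flux of one uncoupled noisy theta neuron
#'
#' Independent finite-difference route to the stationary state: builds the
#' stationary Fokker-Planck operator for a single population with constant
#' drive on a fine periodic grid (compact flux-form differences), solves
#' for its null vector under the normalization constraint, and returns the
#' (constant-in-phase) stationary probability flux.  Serves as the
#' cross-check oracle for the time-dependent spectral integrator.
#'
#' @param drive constant external drive r.
#' @param noiseIntensity noise intensity D.
#' @param gridSize number of finite-difference points.
#' @return list with \code{phases}, \code{density}, \code{flux}.
#' @export
stationarySolution <- function(drive, noiseIntensity, gridSize = 2048) {
  K <- gridSize
  h <- 2 * pi / K
  th <- -pi + (0:(K - 1)) * h
  A <- (1 - cos(th)) + (1 + cos(th)) * drive
  B <- 1 + cos(th)
  Bh <- 1 + cos(th + h / 2)
  D <- noiseIntensity
  idx <- function(j) ((j - 1) %% K) + 1
  L <- matrix(0, K, K)
  for (j in seq_len(K)) {
    jm <- idx(j - 1)
    jp <- idx(j + 1)
    L[j, jp] <- L[j, jp] - A[jp] / (2 * h) + D / 2 * Bh[j] * B[jp] / h^2
    L[j, jm] <- L[j, jm] + A[jm] / (2 * h) + D / 2 * Bh[jm] * B[jm] / h^2
    L[j, j] <- L[j, j] - D / 2 * (Bh[j] + Bh[jm]) * B[j] / h^2
  }
  L[K, ] <- h
  n <- solve(L, c(rep(0, K - 1), 1))
  flux <- A[1] * n[1] -
    D / 2 * B[1] * (B[2] * n[2] - B[K] * n[K]) / (2 * h)
  list(phases = th, density = n, flux = flux)
}

#' @describeIn FluxTrace-class output times.
#' @param x a \linkS4class{FluxTrace}.
#' @export
fluxTimes <- function(x) x@times

#' @describeIn FluxTrace-class excitatory population rates (time x unit).
#' @export
fluxExc <- function(x) x@fluxExc

#' @describeIn FluxTrace-class inhibitory population rates (time x unit).
#' @export
fluxInh <- function(x) x@fluxInh

#' @describeIn FluxTrace-class solver diagnostics list.
#' @export
diagnostics <- function(x) x@diagnostics

#' @describeIn FluxTrace-class final mean-field state (for chunked runs).
#' @export
finalState <- function(x) x@finalState

setMethod("show", "FluxTrace", function(object) {
  M <- ncol(object@fluxExc)
  cat(sprintf("FluxTrace: %d samples x %d unit(s), t in [%g, %g]\n",
              length(object@times), M, object@times[1],
              object@times[length(object@times)]))
  cat(sprintf("  mass drift %.3g, min density %.3g, %d steps (%d rejected)\n",
              object@diagnostics$massDrift, object@diagnostics$minDensity,
              object@diagnostics$nAccepted, object@diagnostics$nRejected))
})

setMethod("show", "MeanFieldState", function(object) {
  cat(sprintf("MeanFieldState: K = %d, %d unit(s), t = %g\n",
              object@gridSize, ncol(object@densities) / 2, object@time))
})
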