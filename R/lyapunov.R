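#' Largest Lyapunov exponent of the deterministic mean field
#'
#' Two-trajectory (Benettin) estimate on the discretized Fokker-Planck
#' system: a reference trajectory and a trajectory perturbed by a
#' mass-preserving density perturbation of norm \code{d0} are advanced in
#' renormalization intervals of length \code{tau}; after each interval the
#' log growth of their separation is accumulated and the perturbation is
#' rescaled back to \code{d0} along the current separation direction.  The
#' exponent is the mean log growth rate over the final two thirds of the
#' run; the full running trace is kept as a convergence diagnostic, and the
#' estimate is flagged unconverged when the running mean still drifts by
#' more than \code{convTol} (relative) over the final third.
#'
#' The mean-field path is deterministic, so a positive exponent certifies
#' deterministic chaos rather than noise-driven irregularity.
#'
#' @param network a \linkS4class{MemoryNetwork}.
#' @param init a \linkS4class{MeanFieldState}; a transient of length
#'   \code{transient} is discarded first.
#' @param schedule optional \linkS4class{ModulationSchedule} (constant
#'   factors only; time-varying schedules make the exponent ill-defined).
#' @param transient discarded initial interval.
#' @param duration length of the estimation run.
#' @param tau renormalization interval.
#' @param d0 perturbation norm.
#' @param convTol relative drift tolerance for the convergence flag.
#' @param ... passed to [integrateFP()] (tolerances, grid options).
#' @return A \linkS4class{LyapunovResult}.
#' @export
largestLyapunov <- function(network, init, schedule = NULL, transient = 200,
                            duration = 400, tau = 4, d0 = 1e-7,
                            convTol = 0.2, ...) {
  stopifnot(is(init, "MeanFieldState"), duration > tau)
  K <- init@gridSize
  h <- 2 * pi / K
  tr <- integrateFP(network, init, schedule, duration = transient,
                    outputStride = transient, ...)
  state <- finalState(tr)
  th <- phaseGrid(K)
  perturb <- function(N) {
    Np <- N * (1 + d0 * sin(th))
    sweep(Np, 2, colSums(Np) * h, "/")
  }
  N <- state@densities
  I <- state@synCurrents
  t <- state@time
  Np <- perturb(N)
  Ip <- I
  n_ren <- round(duration / tau)
  lams <- numeric(n_ren)
  for (i in seq_len(n_ren)) {
    s1 <- new("MeanFieldState", gridSize = K, densities = N,
              synCurrents = I, time = t)
    s2 <- new("MeanFieldState", gridSize = K, densities = Np,
              synCurrents = Ip, time = t)
    r1 <- integrateFP(network, s1, schedule, duration = tau,
                      outputStride = tau, ...)
    r2 <- integrateFP(network, s2, schedule, duration = tau,
                      outputStride = tau, ...)
    f1 <- finalState(r1)
    f2 <- finalState(r2)
    dN <- f2@densities - f1@densities
    dI <- f2@synCurrents - f1@synCurrents
    d <- sqrt(sum(dN^2) * h^2 + sum(dI^2))
    lams[i] <- log(d / d0) / tau
    N <- f1@densities
    I <- f1@synCurrents
    t <- f1@time
    Np <- N + dN * (d0 / d)
    Ip <- I + dI * (d0 / d)
  }
  running <- cumsum(lams) / seq_along(lams)
  use <- lams[seq.int(max(1L, n_ren %/% 3L), n_ren)]
  est <- mean(use)
  last3 <- running[seq.int(max(1L, 2L * n_ren %/% 3L), n_ren)]
  scale <- max(abs(est), 0.01)
  converged <- (max(last3) - min(last3)) <= convTol * scale
  if (!converged)
    warning("Lyapunov estimate not converged (running-estimate drift ",
            format((max(last3) - min(last3)) / scale, digits = 3),
            " relative)")
  new("LyapunovResult", exponents = est, running = running,
      converged = converged,
      method = "two-trajectory renormalization on the mean field")
}

#' Largest Lyapunov exponent of an arbitrary discrete-time propagator
#'
#' Generic Benettin estimator used for benchmark systems: \code{propagate}
#' maps a numeric state vector over one renormalization interval.
#'
#' @param propagate function(state) -> state after time \code{tau}.
#' @param state0 initial numeric state (transient already discarded).
#' @param tau time advanced by one \code{propagate} call.
#' @param nSteps number of renormalization intervals.
#' @param d0 perturbation norm.
#' @return A \linkS4class{LyapunovResult}.
#' @export
lyapunovOfMap <- function(propagate, state0, tau, nSteps = 200, d0 = 1e-8) {
  x <- state0
  v <- stats::rnorm(length(x))
  v <- v / sqrt(sum(v^2)) * d0
  lams <- numeric(nSteps)
  for (i in seq_len(nSteps)) {
    x1 <- propagate(x)
    x2 <- propagate(x + v)
    dv <- x2 - x1
    d <- sqrt(sum(dv^2))
    lams[i] <- log(d / d0) / tau
    x <- x1
    v <- dv * (d0 / d)
  }
  running <- cumsum(lams) / seq_along(lams)
  use <- lams[seq.int(max(1L, nSteps %/% 3L), nSteps)]
  new("LyapunovResult", exponents = mean(use), running = running,
      converged = TRUE, method = "two-trajectory renormalization (generic)")
}

#' @describeIn LyapunovResult-class the estimated exponent(s).
#' @param x a \linkS4class{LyapunovResult}.
#' @export
lyapunovExponent <- function(x) x@exponents

setMethod("show", "LyapunovResult", function(object) {
  cat(sprintf("LyapunovResult: largest exponent %.4g (%s)\n",
              object@exponents[1],
              if (object@converged) "converged" else "NOT converged"))
  cat(" ", object@method, "\n")
})
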