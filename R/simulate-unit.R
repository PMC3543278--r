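#' Initial phase states for the finite-N simulator
#'
#' \code{"uniform"}: independent phases uniform on \eqn{(-\pi, \pi]}.
#' \code{"near-equilibrium"}: all phases at the stable equilibrium of the
#' uncoupled excitable neuron (tight wrapped-normal scatter of width 0.05).
#' \code{"spread"}: wrapped-normal scatter around the equilibrium whose
#' width is itself drawn uniformly from \eqn{[0, \pi]} — a family of random
#' initial conditions that samples both basins of a bistable unit.
#'
#' @param params a \linkS4class{UnitParams}.
#' @param nUnits number of units M.
#' @param preset one of \code{"uniform"}, \code{"near-equilibrium"},
#'   \code{"spread"}.
#' @param seed integer seed.
#' @return A \linkS4class{PhaseState} at time 0.
#' @export
initPhaseState <- function(params, nUnits = 1,
                           preset = c("uniform", "near-equilibrium",
                                      "spread"),
                           seed = 1) {
  preset <- match.arg(preset)
  M <- as.integer(nUnits)
  NE <- params@nExc
  NI <- params@nInh
  r <- params@driveExc
  th_eq <- if (r < 0) -2 * atan(sqrt(-r)) else 0
  wrap <- function(x) {
    y <- (x + pi) %% (2 * pi) - pi
    y[y <= -pi] <- y[y <= -pi] + 2 * pi
    y
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  draw <- function(n) switch(preset,
    uniform = stats::runif(n, -pi, pi),
    `near-equilibrium` = wrap(th_eq + stats::rnorm(n, 0, 0.05)),
    spread = wrap(th_eq + stats::rnorm(n, 0, stats::runif(1, 0, pi))))
  pe <- matrix(0, NE, M)
  pi_ <- matrix(0, NI, M)
  for (k in seq_len(M)) {
    pe[, k] <- draw(NE)
    pi_[, k] <- draw(NI)
  }
  new("PhaseState", phasesExc = pe, phasesInh = pi_,
      synExc = numeric(M), synInh = numeric(M), time = 0, step = 0)
}

#' Simulate a finite-N network of theta-neuron units
#'
#' Integrates the coupled phase SDEs by Euler-Maruyama with a fixed step.
#' Spikes are upward crossings of the spike phase \eqn{\pi}, with the
#' crossing time interpolated linearly inside the step.  Noise is drawn
#' from counter-based streams indexed by (seed, neuron, step), so identical
#' \code{(params, init, seed)} reproduce an identical raster bit-for-bit,
#' whether the run is made in one call or split into chunks via the
#' returned final state.
#'
#' @param params a \linkS4class{UnitParams}.
#' @param init a \linkS4class{PhaseState}, e.g. from [initPhaseState()].
#' @param duration simulated time (> 0).
#' @param dt Euler-Maruyama step.
#' @param seed integer seed selecting the noise streams.
#' @param network optional \linkS4class{MemoryNetwork} supplying inter-unit
#'   weights for multi-unit simulations (default: zero inter-unit weights).
#' @param schedule optional \linkS4class{ModulationSchedule}.
#' @param recordPhases if > 0, keep every that-many-th phase snapshot.
#' @return list with components \code{raster} (a
#'   \linkS4class{SpikeRaster}), \code{state} (final
#'   \linkS4class{PhaseState}) and \code{trace} (phase snapshots or NULL).
#' @examples
#' p <- unitPreset("excitable", nExc = 20, nInh = 5)
#' st <- initPhaseState(p, preset = "near-equilibrium", seed = 2)
#' out <- simulateUnit(p, st, duration = 50, dt = 0.01, seed = 7)
#' nrow(spikeEvents(out$raster))
#' @export
simulateUnit <- function(params, init, duration, dt = 0.01, seed,
                         network = NULL, schedule = NULL,
                         recordPhases = 0) {
  stopifnot(is(params, "UnitParams"), is(init, "PhaseState"), duration > 0,
            dt > 0)
  M <- ncol(init@phasesExc)
  if (nrow(init@phasesExc) != params@nExc ||
      nrow(init@phasesInh) != params@nInh)
    stop("initial state is inconsistent with the ensemble sizes in params")
  if (!is.null(network) && network@mUnits != M)
    stop("network has ", network@mUnits, " units, initial state has ", M)
  n_steps <- ceiling(duration / dt - 1e-9)
  res <- cpp_simulate_network(init@phasesExc, init@phasesInh,
                              c(init@synExc, init@synInh), init@time,
                              n_steps, dt, .pars_list(params),
                              .weights_list(if (is.null(network)) NULL
                                            else network@weights, M),
                              .sched_list(schedule), seed, init@step,
                              as.integer(recordPhases))
  ev <- data.frame(time = res$spike_time,
                   ensemble = c("E", "I")[res$spike_ens + 1L],
                   neuron = as.integer(res$spike_id),
                   unit = as.integer(res$spike_unit))
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  raster <- new("SpikeRaster", events = ev,
                duration = res$t_end - init@time + init@time,
                nExc = params@nExc, nInh = params@nInh,
                nUnits = as.integer(M))
  state <- new("PhaseState", phasesExc = res$theta_e,
               phasesInh = res$theta_i,
               synExc = res$syn[seq_len(M)],
               synInh = res$syn[M + seq_len(M)],
               time = res$t_end, step = res$step_end)
  list(raster = raster, state = state, trace = res$trace)
}

#' Upward threshold crossings of a sampled phase trajectory
#'
#' Detects every upward crossing of \code{spikePhase} in a phase trajectory
#' sampled on a monotone time grid, interpolating the crossing time
#' linearly between the bracketing samples.  The periodic representation is
#' unwrapped first, so crossings are counted once even when the stored
#' phase wraps from \eqn{\pi} to \eqn{-\pi} between samples.
#'
#' @param times monotonically increasing sample times.
#' @param phases phase samples (radians, wrapped or not).
#' @param spikePhase threshold phase (default \eqn{\pi}).
#' @return numeric vector of crossing times.
#' @export
detectSpikes <- function(times, phases, spikePhase = pi) {
  stopifnot(length(times) == length(phases))
  if (length(times) < 2) return(numeric(0))
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  dphi <- diff(phases)
  dphi <- (dphi + pi) %% (2 * pi) - pi   # unwrap increments
  phi <- cumsum(c(phases[1], dphi))
  # upward crossings of spikePhase + 2*pi*m for any integer m
  lev <- floor((phi - spikePhase) / (2 * pi))
  out <- numeric(0)
  up <- which(diff(lev) >= 1)
  for (i in up) {
    for (m in seq_len(lev[i + 1] - lev[i])) {
      target <- (lev[i] + m) * 2 * pi + spikePhase
      frac <- (target - phi[i]) / (phi[i + 1] - phi[i])
      out <- c(out, times[i] + frac * (times[i + 1] - times[i]))
    }
  }
  out
}

#' Instantaneous firing rates from a spike raster
#'
#' Gaussian-kernel rate estimate per ensemble and unit, normalized by
#' ensemble size: the time integral of each rate equals (spike count) /
#' (ensemble size) up to kernel mass lost at the edges of the recording.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param kernelWidth standard deviation of the Gaussian kernel (> 0).
#' @param grid output sample times (non-empty).
#' @return A \linkS4class{RateTrace}.
#' @export
estimateFiringRate <- function(raster, kernelWidth, grid) {
  stopifnot(is(raster, "SpikeRaster"), kernelWidth > 0, length(grid) > 0)
  ev <- raster@events
  M <- raster@nUnits
  T <- length(grid)
  rE <- matrix(0, T, M)
  rI <- matrix(0, T, M)
  for (k in seq_len(M)) {
    for (ens in c("E", "I")) {
      tt <- ev$time[ev$ensemble == ens & ev$unit == k]
      if (!length(tt)) next
      dens <- vapply(grid, function(g)
        sum(stats::dnorm(g - tt, sd = kernelWidth)), 0)
      n <- if (ens == "E") raster@nExc else raster@nInh
      if (ens == "E") rE[, k] <- dens / n else rI[, k] <- dens / n
    }
  }
  new("RateTrace", times = as.numeric(grid), rateExc = rE, rateInh = rI,
      kernelWidth = kernelWidth)
}

#' @describeIn SpikeRaster-class the event table.
#' @param x a \linkS4class{SpikeRaster}.
#' @export
spikeEvents <- function(x) x@events

setMethod("show", "SpikeRaster", function(object) {
  ev <- object@events
  cat(sprintf(
    "SpikeRaster: %d spikes (%d E, %d I) from %d unit(s) over t <= %g\n",
    nrow(ev), sum(ev$ensemble == "E"), sum(ev$ensemble == "I"),
    object@nUnits, object@duration))
})

setMethod("show", "RateTrace", function(object) {
  cat(sprintf("RateTrace: %d samples x %d unit(s), kernel width %g\n",
              length(object@times), ncol(object@rateExc),
              object@kernelWidth))
})

#' Write a spike raster to a delimited text file or serialized container
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param file output path.
#' @param format \code{"tsv"} (header + tab-separated events) or
#'   \code{"rds"} (structured binary container for large runs).
#' @return \code{file}, invisibly.
#' @export
writeRaster <- function(raster, file, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "tsv")
    utils::write.table(raster@events, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  else saveRDS(raster, file)
  invisible(file)
}
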