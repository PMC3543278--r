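# Mean-field integrator: conservation, stationary oracle, determinism,
# flux evaluation, and the finite-volume cross-check.

# slow, independent reference: first-order upwind finite-volume step of the
# single-population density equation with explicit Euler in time
fv_reference <- function(n0, drive, D, dt, n_steps) {
  K <- length(n0)
  h <- 2 * pi / K
  th <- phaseGrid(K)
  th_half <- th + h / 2
  A_half <- (1 - cos(th_half)) + (1 + cos(th_half)) * drive
  B <- 1 + cos(th)
  Bh <- 1 + cos(th_half)
  n <- n0
  idx <- function(j) ((j - 1) %% K) + 1
  for (s in seq_len(n_steps)) {
    np <- n[idx(2:(K + 1))]
    # upwind advective flux at j+1/2
    Fa <- ifelse(A_half >= 0, A_half * n, A_half * np)
    # diffusive flux at j+1/2: -(D/2) B_{j+1/2} d(Bn)/dth
    Fd <- -D / 2 * Bh * (B[idx(2:(K + 1))] * np - B * n) / h
    Ftot <- Fa + Fd
    n <- n - dt / h * (Ftot - Ftot[idx(0:(K - 1))])
  }
  n
}

test_that("density normalization is conserved to 1e-6 over long horizons", {
  net <- singleUnitNetwork(unitPreset("bistable"))
  st <- initDensity(net, 128, "bump")
  tr <- integrateFP(net, st, NULL, duration = 300, outputStride = 1)
  expect_lt(diagnostics(tr)$massDrift, 1e-6)
  expect_true(all(abs(col_mass(finalState(tr)@densities) - 1) < 1e-6))
})

test_that("long-time flux of an uncoupled population matches the stationary null-space oracle", {
  p <- unitPreset("excitable")
  net <- singleUnitNetwork(p)
  st <- initDensity(net, 128, "bump")
  tr <- integrateFP(net, st, NULL, duration = 800, outputStride = 1)
  # average over the second half: a weakly damped circulation mode rings
  # around the stationary state and cancels over full periods
  fp_flux <- mean(fluxExc(tr)[fluxTimes(tr) >= 400, 1])
  oracle <- stationarySolution(p@driveExc, p@noiseIntensity, 2048)
  expect_lt(abs(fp_flux - oracle$flux) / oracle$flux, 1e-4)
  # the stationary density is nonnegative and normalized
  expect_true(all(oracle$density > -1e-12))
  expect_equal(sum(oracle$density) * 2 * pi / 2048, 1, tolerance = 1e-10)
})

test_that("the mean-field path is deterministic and chunkable", {
  net <- networkPreset("reduced")
  st <- initDensity(net, 128, "pattern", pattern = 1)
  a <- integrateFP(net, st, NULL, duration = 5, outputStride = 0.5,
                   negTol = 0.8)
  b <- integrateFP(net, st, NULL, duration = 5, outputStride = 0.5,
                   negTol = 0.8)
  expect_identical(fluxExc(a), fluxExc(b))
  expect_identical(finalState(a)@densities, finalState(b)@densities)
  # chunked continuation agrees closely (adaptive steps restart at the seam)
  c1 <- integrateFP(net, st, NULL, duration = 2.5, outputStride = 0.5,
                    negTol = 0.8)
  c2 <- integrateFP(net, finalState(c1), NULL, duration = 2.5,
                    outputStride = 0.5, negTol = 0.8)
  expect_equal(finalState(c2)@densities, finalState(a)@densities,
               tolerance = 1e-6)
})

test_that("spectral dynamics agree with an independent finite-volume upwind reference", {
  p <- unitPreset("excitable")
  net <- singleUnitNetwork(p)
  K <- 128
  st <- initDensity(net, K, "bump", center = 0.5, concentration = 2)
  dur <- 5
  tr <- integrateFP(net, st, NULL, duration = dur, outputStride = dur)
  n_spec <- finalState(tr)@densities[, 1]
  n_fv <- fv_reference(st@densities[, 1], p@driveExc, p@noiseIntensity,
                       dt = 2e-4, n_steps = dur / 2e-4)
  # the upwind reference is first-order; agreement at its accuracy
  expect_lt(max(abs(n_spec - n_fv)), 0.08 * max(n_spec))
})

test_that("the flux profile matches a manufactured closed form and the spike-phase rate", {
  p <- unitPreset("excitable")
  net <- singleUnitNetwork(p)
  K <- 64
  th <- phaseGrid(K)
  h <- 2 * pi / K
  # manufactured smooth density
  n <- exp(cos(th - 0.3)) ; n <- n / (sum(n) * h)
  N <- cbind(n, n)
  st <- new("MeanFieldState", gridSize = as.integer(K), densities = N,
            synCurrents = c(0, 0), time = 0)
  out <- fluxAtSpikePhase(net, st)
  r <- p@driveExc; D <- p@noiseIntensity
  A <- (1 - cos(th)) + (1 + cos(th)) * r
  B <- 1 + cos(th)
  dBn <- -sin(th) * n + B * n * (-sin(th - 0.3))  # d/dth [B n], closed form
  closed <- A * n - D / 2 * B * dBn
  expect_equal(out$profile[, 1], closed, tolerance = 1e-6)
  # at theta = pi the diffusion factor vanishes: flux = 2 n(pi)
  expect_equal(out$atSpikePhase$fluxExc, 2 * N[1, 1])
  # zero density and gradient at the spike phase -> zero flux
  n2 <- exp(12 * (cos(th) - 1)); n2 <- n2 / (sum(n2) * h)
  st2 <- new("MeanFieldState", gridSize = as.integer(K),
             densities = cbind(n2, n2), synCurrents = c(0, 0), time = 0)
  expect_lt(fluxAtSpikePhase(net, st2)$atSpikePhase$fluxExc[1], 1e-8)
})

test_that("abort diagnostics identify pathological runs", {
  net <- singleUnitNetwork(unitPreset("bistable"))
  st <- initDensity(net, 32, "equilibrium")  # too sharp for K = 32
  expect_error(integrateFP(net, st, NULL, duration = 50, outputStride = 1,
                           negTol = 1e-4),
               "below")
})

test_that("grid refinement leaves the time-averaged stationary flux unchanged", {
  p <- unitPreset("excitable")
  net <- singleUnitNetwork(p)
  flux_at <- function(K) {
    st <- initDensity(net, K, "bump")
    tr <- integrateFP(net, st, NULL, duration = 500, outputStride = 1)
    mean(fluxExc(tr)[fluxTimes(tr) >= 250, 1])
  }
  f128 <- flux_at(128)
  f256 <- flux_at(256)
  expect_lt(abs(f128 - f256) / f256, 1e-3)
})
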