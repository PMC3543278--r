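# Finite-N stochastic simulator: spike generation, detection, rates.

test_that("a subthreshold noise-free neuron is silent and settles at its equilibrium", {
  p <- one_neuron(drive = -0.04, D = 0)
  st <- initPhaseState(p, preset = "uniform", seed = 3)
  st@phasesExc[1, 1] <- 0.2   # start between the equilibria
  out <- simulateUnit(p, st, duration = 400, dt = 0.01, seed = 1)
  ev <- spikeEvents(out$raster)
  expect_identical(nrow(ev[ev$ensemble == "E", ]), 0L)
  th_eq <- -2 * atan(sqrt(0.04))
  expect_equal(out$state@phasesExc[1, 1], th_eq, tolerance = 1e-4)
})

test_that("suprathreshold ISI matches the quadrature period of the phase flow", {
  r <- 0.05
  period <- theta_period_quadrature(r)
  p <- one_neuron(drive = r, D = 0)
  st <- initPhaseState(p, preset = "uniform", seed = 1)
  st@phasesExc[1, 1] <- 0
  out <- simulateUnit(p, st, duration = 8 * period, dt = 0.002, seed = 1)
  tt <- spikeEvents(out$raster)$time
  tt <- tt[spikeEvents(out$raster)$ensemble == "E"]
  expect_gte(length(tt), 5)
  isi <- diff(tt)
  expect_equal(mean(isi), period, tolerance = 1e-3)
})

test_that("identical (params, init, seed) reproduce the raster bit-for-bit, also chunked", {
  p <- tiny_unit(gEE = 2, gEI = 1, gIE = 1, gII = 0.5,
                 noiseIntensity = 0.01)
  st <- initPhaseState(p, preset = "uniform", seed = 11)
  a <- simulateUnit(p, st, duration = 40, dt = 0.01, seed = 5)
  b <- simulateUnit(p, st, duration = 40, dt = 0.01, seed = 5)
  expect_identical(spikeEvents(a$raster), spikeEvents(b$raster))
  expect_identical(a$state@phasesExc, b$state@phasesExc)
  # chunked: two 20-unit chunks continue the same noise streams
  c1 <- simulateUnit(p, st, duration = 20, dt = 0.01, seed = 5)
  c2 <- simulateUnit(p, c1$state, duration = 20, dt = 0.01, seed = 5)
  ev_chunked <- rbind(spikeEvents(c1$raster), spikeEvents(c2$raster))
  rownames(ev_chunked) <- NULL
  expect_equal(ev_chunked, spikeEvents(a$raster))
  expect_identical(c2$state@phasesExc, a$state@phasesExc)
  # a different seed gives a different raster
  d <- simulateUnit(p, st, duration = 40, dt = 0.01, seed = 6)
  expect_false(identical(spikeEvents(a$raster), spikeEvents(d$raster)))
})

test_that("with zero noise, halving the step changes spike times at O(step)", {
  p <- one_neuron(drive = 0.05, D = 0)
  st <- initPhaseState(p, preset = "uniform", seed = 1)
  st@phasesExc[1, 1] <- 0
  t1 <- spikeEvents(simulateUnit(p, st, 60, dt = 0.02, seed = 1)$raster)$time[1]
  t2 <- spikeEvents(simulateUnit(p, st, 60, dt = 0.01, seed = 1)$raster)$time[1]
  t4 <- spikeEvents(simulateUnit(p, st, 60, dt = 0.005, seed = 1)$raster)$time[1]
  # successive differences shrink roughly linearly with the step
  expect_lt(abs(t2 - t4), abs(t1 - t2))
  expect_lt(abs(t1 - t2), 0.05)
})

test_that("zero-size ensembles and inconsistent states are rejected", {
  expect_error(UnitParams(nExc = 0, nInh = 5, driveExc = 0, driveInh = 0,
                          gEE = 0, gEI = 0, gIE = 0, gII = 0,
                          gapStrength = 0, noiseIntensity = 0),
               "positive count")
  p <- tiny_unit()
  st <- initPhaseState(tiny_unit(nExc = 10), preset = "uniform", seed = 1)
  expect_error(simulateUnit(p, st, 1, seed = 1), "inconsistent")
})

test_that("detectSpikes finds interpolated upward crossings and handles wrapping", {
  # constant below threshold
  expect_length(detectSpikes(0:10, rep(0.3, 11)), 0)
  # linear ramp crossing pi at a known time
  tt <- seq(0, 10, by = 0.05)
  ph <- -pi + 0.8 * tt          # crosses pi at t = 2*pi/0.8
  ph_wrapped <- (ph + pi) %% (2 * pi) - pi
  got <- detectSpikes(tt, ph_wrapped)
  expect_length(got, floor((0.8 * 10) / (2 * pi)) )
  expect_equal(got[1], 2 * pi / 0.8, tolerance = 0.05)
  # sinusoid-driven phase: compare against brute-force fine-grid re-scan
  phase_fun <- function(t) 2.5 * sin(0.7 * t) + 0.5 * t
  tt <- seq(0, 40, by = 0.08)
  fine <- seq(0, 40, by = 0.008)
  coarse_cross <- detectSpikes(tt, phase_fun(tt))
  fine_cross <- detectSpikes(fine, phase_fun(fine))
  expect_equal(length(coarse_cross), length(fine_cross))
  expect_equal(coarse_cross, fine_cross, tolerance = 0.08)
  # non-monotone grid rejected
  expect_error(detectSpikes(c(0, 1, 1), c(0, 1, 2)), "increasing")
})

test_that("firing-rate estimate is normalized per neuron and matches a Poisson oracle", {
  # empty raster -> identically zero
  p <- tiny_unit()
  st <- initPhaseState(p, preset = "near-equilibrium", seed = 1)
  empty <- new("SpikeRaster", events = data.frame(
    time = numeric(0), ensemble = character(0), neuron = integer(0),
    unit = integer(0)), duration = 10, nExc = 10L, nInh = 2L, nUnits = 1L)
  rt <- estimateFiringRate(empty, kernelWidth = 0.5,
                           grid = seq(0, 10, by = 0.1))
  expect_true(all(rt@rateExc == 0))
  # one spike from one of N neurons integrates to 1/N
  one <- new("SpikeRaster", events = data.frame(
    time = 5, ensemble = "E", neuron = 1L, unit = 1L), duration = 10,
    nExc = 10L, nInh = 2L, nUnits = 1L)
  grid <- seq(0, 10, by = 0.01)
  rt <- estimateFiringRate(one, kernelWidth = 0.3, grid = grid)
  expect_equal(sum(rt@rateExc[, 1]) * 0.01, 1 / 10, tolerance = 1e-3)
  # independent Poisson trains: time-averaged rate within 3 SE of count/T
  set.seed(42)
  lam <- 0.8; Tdur <- 200; N <- 25
  ev <- do.call(rbind, lapply(seq_len(N), function(i) {
    n <- rpois(1, lam * Tdur)
    data.frame(time = sort(runif(n, 0, Tdur)), ensemble = "E",
               neuron = i, unit = 1L)
  }))
  ev <- ev[order(ev$time), ]
  ras <- new("SpikeRaster", events = ev, duration = Tdur, nExc = as.integer(N),
             nInh = 1L, nUnits = 1L)
  grid <- seq(10, Tdur - 10, by = 0.1)   # avoid kernel edges
  rt <- estimateFiringRate(ras, kernelWidth = 1, grid = grid)
  oracle <- nrow(ev) / (Tdur * N)
  se <- sqrt(nrow(ev)) / (Tdur * N)
  expect_lt(abs(mean(rt@rateExc[, 1]) - oracle), 3 * se + 0.01 * lam)
  # empty grid rejected
  expect_error(estimateFiringRate(ras, 1, numeric(0)))
})
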