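# Overlap machinery: peak-hold filter, [0,1] overlap, staying times,
# Lyapunov benchmarks.

test_that("localPeakHold holds recent peak heights", {
  tt <- seq(0, 50, by = 0.05)
  # constant series passes through
  expect_equal(localPeakHold(rep(2, length(tt)), tt), rep(2, length(tt)))
  # pure sinusoid: held value converges to c + A after the third peak
  x <- 1.5 + 0.7 * sin(2 * tt)
  ph <- localPeakHold(x, tt)
  expect_equal(ph[length(ph)], 2.2, tolerance = 1e-3)
  first_peaks <- which(diff(sign(diff(x))) == -2)[3] + 1
  expect_true(all(abs(ph[(first_peaks + 1):length(ph)] - 2.2) < 0.01))
  # amplitude-modulated oscillation vs a 10x finer grid
  f <- function(t) (1 + 0.5 * sin(0.21 * t)) * (1 + sin(2.3 * t))
  fine <- seq(0, 50, by = 0.005)
  ph_c <- localPeakHold(f(tt), tt)
  ph_f <- localPeakHold(f(fine), fine)
  idx <- findInterval(tt, fine)
  expect_lt(stats::median(abs(ph_c - ph_f[idx])), 0.05)
  # too few peaks falls back to the running maximum with a warning
  expect_warning(ph2 <- localPeakHold(seq(0, 1, length.out = 20),
                                      seq_len(20)), "fewer than three")
  expect_equal(ph2, seq(0, 1, length.out = 20))
})

test_that("overlap is 1 on the pattern, 0 on its complement, and bounded for fuzz", {
  ps <- presetPatterns("reduced")
  eta <- patterns(ps)
  M <- nrow(eta)
  tt <- seq(0, 20, by = 0.05)
  mk_flux <- function(profile) {
    # oscillating rate whose peak-held value saturates F near 0/1
    rates <- vapply(seq_len(M), function(k)
      profile[k] * 60 * (1 + sin(3 * tt)) / 2 + 1e-6, numeric(length(tt)))
    new("FluxTrace", times = tt, fluxExc = rates, fluxInh = rates * 0,
        synExc = rates * 0, synInh = rates * 0,
        finalState = new("MeanFieldState", gridSize = 16L,
                         densities = matrix(1 / (2 * pi), 16, 2),
                         synCurrents = c(0, 0), time = 0),
        diagnostics = list())
  }
  ot <- overlapTrace(mk_flux(eta[, 1]), ps, halfRate = 0.2)
  expect_gt(overlaps(ot)[length(tt), 1], 0.98)
  otc <- overlapTrace(mk_flux(1 - eta[, 1]), ps, halfRate = 0.2)
  expect_lt(overlaps(otc)[length(tt), 1], 0.02)
  # fuzz: arbitrary nonnegative rate traces keep overlaps inside [0, 1]
  set.seed(1)
  for (i in 1:5) {
    rnd <- matrix(rexp(length(tt) * M), length(tt), M)
    fl <- mk_flux(runif(M))
    fl@fluxExc <- rnd
    o <- overlaps(overlapTrace(fl, ps))
    expect_true(all(o >= 0 & o <= 1))
  }
})

test_that("staying times recover constructed square-wave plateau widths", {
  tt <- seq(0, 100, by = 0.1)
  m1 <- ifelse(tt >= 10 & tt < 35, 0.95, 0.1)
  m2 <- ifelse(tt >= 50 & tt < 80, 0.92, 0.1)
  ot <- new("OverlapTrace", times = tt, m = cbind(m1, m2),
            peakHeld = cbind(m1, m2), normalized = cbind(m1, m2))
  st <- stayingTimes(ot, threshold = 0.85)
  iv <- stayingIntervals(st)
  expect_identical(iv$pattern, c(1L, 2L))
  expect_equal(iv$end - iv$start, c(25, 30), tolerance = 0.2)
  expect_false(any(iv$censored))
  expect_equal(meanStayingTime(st), 27.5, tolerance = 0.2)
  # constant above threshold -> one censored interval spanning the horizon
  ot2 <- new("OverlapTrace", times = tt, m = cbind(rep(0.9, length(tt))),
             peakHeld = cbind(m1), normalized = cbind(m1))
  st2 <- stayingTimes(ot2, 0.85)
  expect_identical(nrow(stayingIntervals(st2)), 1L)
  expect_true(all(stayingIntervals(st2)$censored))
  expect_true(is.na(meanStayingTime(st2)))
  # never above threshold -> empty list
  ot3 <- new("OverlapTrace", times = tt, m = cbind(rep(0.1, length(tt))),
             peakHeld = cbind(m1), normalized = cbind(m1))
  expect_identical(nrow(stayingIntervals(stayingTimes(ot3, 0.85))), 0L)
  # simultaneous threshold crossings resolved by argmax
  m3 <- cbind(rep(0.9, length(tt)), rep(0.95, length(tt)))
  ot4 <- new("OverlapTrace", times = tt, m = m3, peakHeld = m3,
             normalized = m3)
  expect_identical(stayingIntervals(stayingTimes(ot4, 0.85))$pattern, 2L)
})

test_that("staying-time estimation is stable under grid refinement", {
  mfun <- function(t) ifelse(t >= 12.3 & t < 47.7, 0.95, 0.2)
  for (dt in c(0.2, 0.05)) {
    tt <- seq(0, 100, by = dt)
    m <- cbind(mfun(tt))
    ot <- new("OverlapTrace", times = tt, m = m, peakHeld = m,
              normalized = m)
    iv <- stayingIntervals(stayingTimes(ot, 0.85))
    expect_equal(iv$end - iv$start, 35.4, tolerance = 2 * dt)
  }
})

test_that("the Lyapunov estimator is exact on a linear contraction and consistent across methods", {
  # dx/dt = -lambda x with lambda = 0.3: leading exponent -0.3
  lam <- 0.3
  tau <- 0.5
  prop <- function(x) x * exp(-lam * tau)
  res <- lyapunovOfMap(prop, c(1, 2), tau = tau, nSteps = 100)
  expect_equal(lyapunovExponent(res), -lam, tolerance = 1e-8)
  # benchmark chaotic map (Lorenz via RK4) : two independent estimates agree
  lorenz_step <- function(x, dt = 0.002, n = 250) {
    f <- function(s) c(10 * (s[2] - s[1]),
                       s[1] * (28 - s[3]) - s[2],
                       s[1] * s[2] - 8 / 3 * s[3])
    for (i in seq_len(n)) {
      k1 <- f(x); k2 <- f(x + dt / 2 * k1); k3 <- f(x + dt / 2 * k2)
      k4 <- f(x + dt * k3)
      x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    x
  }
  x0 <- lorenz_step(c(1, 1, 20), n = 2000)   # land on the attractor
  set.seed(2)
  e1 <- lyapunovExponent(lyapunovOfMap(lorenz_step, x0, tau = 0.5,
                                       nSteps = 260, d0 = 1e-7))
  set.seed(7)
  e2 <- lyapunovExponent(lyapunovOfMap(lorenz_step, x0, tau = 0.5,
                                       nSteps = 260, d0 = 1e-5))
  expect_gt(e1, 0)
  expect_lt(abs(e1 - e2) / e1, 0.05)
  # the literature value for these Lorenz parameters is about 0.9
  expect_equal(e1, 0.9, tolerance = 0.1)
})
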