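# Patterns, modified-Hebbian weights, input assembly, modulation schedule.

test_that("the built-in pattern sets satisfy their structural constraints", {
  ps <- presetPatterns("sixteen")
  pm <- patterns(ps)
  expect_identical(dim(pm), c(16L, 3L))
  # units 9 and 10 are active in pattern 2 and in no other pattern
  expect_equal(pm[9:10, 2], c(1, 1))
  expect_equal(unname(pm[9:10, c(1, 3)]), matrix(0, 2, 2))
  # distinct patterns, equal firing rate recomputed by direct counting
  expect_equal(unname(colSums(pm)), rep(16 * activeFraction(ps), 3))
  expect_identical(anyDuplicated(t(pm)), 0L)
  red <- presetPatterns("reduced")
  expect_identical(dim(patterns(red)), c(8L, 2L))
  expect_identical(anyDuplicated(t(patterns(red))), 0L)
})

test_that("generated patterns are reproducible and have hypergeometric overlaps", {
  a <- generatePatterns(16, 3, 0.375, seed = 7)
  b <- generatePatterns(16, 3, 0.375, seed = 7)
  expect_identical(patterns(a), patterns(b))
  expect_equal(unname(colSums(patterns(a))), rep(6, 3))
  # a = 1 would be rejected by the class validity; a small a is infeasible
  expect_error(generatePatterns(10, 1, 0.01), "infeasible")
  # empirical pairwise overlap vs hypergeometric mean k^2/m
  m <- 20; k <- 5
  ov <- vapply(1:400, function(s) {
    pm <- patterns(generatePatterns(m, 2, k / m, seed = s))
    sum(pm[, 1] * pm[, 2])
  }, 0)
  expect_equal(mean(ov), k^2 / m, tolerance = 0.08)
})

test_that("Hebbian weights match a brute-force entry-by-entry oracle", {
  ps <- generatePatterns(4, 1, 0.5, seed = 3)
  G <- c(ee = 1.4, ie = 0.8, ei = 2.2)
  X <- 1.3; cc <- 0.6
  w <- buildInterUnitWeights(ps, G, X, cc)
  eta <- patterns(ps); M <- 4; a <- activeFraction(ps)
  for (k in 1:M) for (l in 1:M) {
    S <- sum(eta[k, ] * eta[l, ])
    Tm <- sum((X - eta[k, ]) * eta[l, ])
    expect_equal(weightsEE(w)[k, l], G[["ee"]] / (a * M) * S -
                   G[["ee"]] * cc / M)
    expect_equal(weightsIE(w)[k, l], G[["ie"]] / (a * M) * S -
                   G[["ie"]] * cc / M)
    expect_equal(weightsEI(w)[k, l], G[["ei"]] / (a * M) * Tm -
                   G[["ei"]] * cc / M)
  }
  # symmetric Hebbian families
  expect_equal(weightsEE(w), t(weightsEE(w)))
  expect_equal(weightsIE(w), t(weightsIE(w)))
})

test_that("co-active units couple more strongly than unrelated units", {
  ps <- presetPatterns("sixteen")
  w <- buildInterUnitWeights(ps, c(ee = 2, ie = 1, ei = 4), 1, 2)
  wee <- weightsEE(w)
  pm <- patterns(ps)
  # unit 9 shares a pattern with 10 but none with unit 1
  expect_equal(sum(pm[9, ] * pm[1, ]), 0)
  expect_gt(wee[9, 10], wee[9, 1])
})

test_that("zero stored patterns reduce weights to the regulation offsets", {
  # a pattern set with an all-zero co-activation between two units gives
  # exactly the negative offsets there
  ps <- presetPatterns("sixteen")
  w <- buildInterUnitWeights(ps, c(ee = 2, ie = 1, ei = 4), 1, 2)
  expect_equal(weightsEE(w)[9, 1], -2 * 2 / 16)
  expect_equal(weightsIE(w)[9, 1], -1 * 2 / 16)
})

test_that("unit input assembly matches a naive double loop and modulation identities hold", {
  set.seed(9)
  net <- networkPreset("reduced")
  M <- nUnits(net)
  IE <- runif(M); II <- runif(M)
  p <- unitParams(net); w <- interUnitWeights(net)
  for (gach in c(0, 0.3)) for (ge in c(0, 0.2)) {
    for (k in seq_len(M)) {
      got <- unitInput(k, IE, II, p, w, gAch = gach, gE = ge)
      # naive double loop
      ue <- (1 - ge) * p@gEE * IE[k] - (1 - gach) * p@gIE * II[k]
      ui <- p@gEI * IE[k] - p@gII * II[k]
      for (l in seq_len(M)) {
        ue <- ue + (1 - ge) * weightsEE(w)[k, l] * IE[l] -
          (1 - gach) * weightsEI(w)[k, l] * II[l]
        ui <- ui + weightsIE(w)[k, l] * IE[l]
      }
      expect_equal(got$inputExc, ue)
      expect_equal(got$inputInh, ui)
    }
  }
  # all outputs zero -> zero recurrent input
  z <- unitInput(1, numeric(M), numeric(M), p, w, 0.5, 0.1)
  expect_equal(z$inputExc, 0)
  expect_equal(z$inputInh, 0)
})

test_that("increasing gAch weakly decreases every IN->PYR contribution and nothing else", {
  net <- networkPreset("reduced")
  M <- nUnits(net)
  IE <- rep(0.5, M); II <- rep(0.5, M)
  p <- unitParams(net); w <- interUnitWeights(net)
  base <- unitInput(1, IE, II, p, w, gAch = 0)
  mod <- unitInput(1, IE, II, p, w, gAch = 0.4)
  # the IN->PYR part of this row sums to a positive inhibition here,
  # so reducing it raises the excitatory input
  inh_row <- p@gIE * II[1] + sum(weightsEI(w)[1, ] * II)
  expect_equal(mod$inputExc - base$inputExc, 0.4 * inh_row)
  expect_identical(mod$inputInh, base$inputInh)
})

test_that("modulation schedules evaluate piecewise with exponential decay", {
  s <- ModulationSchedule(achLevel = 0.2, gELevel = 0.05,
                          achWindow = c(100, 200), achDecay = 50,
                          gluUnits = c(5L, 6L), gluIncrement = 0.3,
                          gluWindow = c(100, 120))
  before <- applySchedule(s, 10, 8)
  expect_equal(before$gAch, 0)
  expect_equal(before$gluIncrements, numeric(8))
  inside <- applySchedule(s, 110, 8)
  expect_equal(inside$gAch, 0.2)
  expect_equal(inside$gE, 0.05)
  expect_equal(which(inside$gluIncrements != 0), c(5L, 6L))
  # exponential branch: half level after tau * ln 2
  after <- applySchedule(s, 200 + 50 * log(2), 8)
  expect_equal(after$gAch, 0.1, tolerance = 1e-12)
  # glu window longer than the ACh effect is rejected
  expect_error(ModulationSchedule(achLevel = 0.2, achWindow = c(0, 10),
                                  achDecay = 0, gluUnits = 1L,
                                  gluIncrement = 0.1,
                                  gluWindow = c(0, 100)),
               "shorter")
  # levels outside [0, 1) are rejected
  expect_error(ModulationSchedule(achLevel = 1), "achLevel")
})
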