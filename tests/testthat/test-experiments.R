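# Scripted protocols on the reduced network.  These are desk-scale runs:
# shortened horizons relative to the full protocols in
# scripts/acceptance.R, exercising every code path.

test_that("experiment reports carry traceable configuration and are deterministic", {
  net <- networkPreset("reduced")
  rep <- runOngoing(net, horizon = 150, gridSize = 128, negTol = 0.8)
  expect_s4_class(rep, "ExperimentReport")
  cfg <- reportConfig(rep)
  expect_identical(cfg$horizon, 150)
  expect_identical(cfg$gridSize, 128)
  expect_true(is.data.frame(visits(rep)))
  # repeated runs are bitwise identical (deterministic mean field)
  rep2 <- runOngoing(net, horizon = 150, gridSize = 128, negTol = 0.8)
  expect_identical(overlaps(rep@overlap), overlaps(rep2@overlap))
  expect_identical(visits(rep), visits(rep2))
})

test_that("the ongoing state visits several patterns in alternation", {
  net <- networkPreset("reduced")
  rep <- runOngoing(net, horizon = 600, gridSize = 128, negTol = 0.8)
  iv <- visits(rep)
  iv <- iv[iv$end - iv$start > 10, ]
  expect_gte(length(unique(iv$pattern)), 2L)
})

test_that("a stabilized pattern yields a censored visit", {
  net <- networkPreset("reduced")
  st <- QLandscape:::.pattern_visits(
    net, gAch = 0.05, gE = 0, horizon = 400, threshold = 0.85,
    gridSize = 128, pattern = 1, transient = 50, negTol = 0.8)
  iv <- stayingIntervals(st)
  own <- iv[iv$pattern == 1, , drop = FALSE]
  expect_gte(nrow(own), 1L)
  expect_true(own$censored[nrow(own)])
})

test_that("selection jumps to the pattern addressed by the Glu volley", {
  net <- networkPreset("reduced")
  rep <- runSelection(net, gAch = 0.05, horizon = 600, negTol = 0.8)
  cfg <- reportConfig(rep)
  # the default Glu targets are the units specific to pattern 2
  eta <- patterns(net@patterns)
  expect_identical(cfg$gluUnits, which(eta[, 2] == 1 & eta[, 1] == 0))
  expect_identical(cfg$retrieved, 2L)
})

test_that("instant ACh decay reduces to the no-ACh protocol", {
  net <- networkPreset("reduced")
  base <- runSelection(net, gAch = 0, gluIncrement = 0.4,
                       gluWindow = c(100, 150), achOnset = 100,
                       horizon = 300, gridSize = 128, negTol = 0.8)
  dec0 <- runDecay(net, gAch = 0.05, achDecay = 0, achOnset = 100,
                   achOffset = 100, gluIncrement = 0.4,
                   gluWindow = c(100, 150), horizon = 300, gridSize = 128,
                   negTol = 0.8)
  # with a plateau and tail of measure zero the two runs coincide (up to
  # the single collocation point the integrator places at the onset)
  expect_equal(overlaps(dec0@overlap), overlaps(base@overlap),
               tolerance = 1e-4)
  # and an infinite decay constant reduces to the sustained-ACh protocol
  hold <- runSelection(net, gAch = 0.05, gluIncrement = 0.4,
                       gluWindow = c(100, 150), achOnset = 100,
                       horizon = 300, gridSize = 128, negTol = 0.8)
  decInf <- runDecay(net, gAch = 0.05, achDecay = Inf, achOnset = 100,
                     achOffset = 200, gluIncrement = 0.4,
                     gluWindow = c(100, 150), horizon = 300,
                     gridSize = 128, negTol = 0.8)
  expect_equal(overlaps(decInf@overlap), overlaps(hold@overlap),
               tolerance = 1e-8)
})

test_that("landscape classification flips exactly once along a gACh ray", {
  net <- networkPreset("reduced")
  cls <- vapply(c(0, 0.03), function(g)
    classifyLandscape(net, gE = 0, gAch = g, horizon = 400,
                      gridSize = 128, starts = 1L, negTol = 0.8)$landscape,
    character(1))
  expect_identical(cls[1], "quasi-attractor")
  expect_identical(cls[2], "attractor")
})

test_that("visit detection is insensitive to the staying-time threshold", {
  net <- networkPreset("reduced")
  rep <- runOngoing(net, horizon = 300, gridSize = 128, negTol = 0.8)
  seqs <- lapply(c(0.7, 0.75, 0.8, 0.85, 0.9, 0.95), function(th) {
    iv <- stayingIntervals(stayingTimes(rep@overlap, th))
    rle(iv$pattern[iv$end - iv$start > 10])$values
  })
  # the alternating visit sequence is identical across 0.7-0.85
  for (i in 2:4) expect_identical(seqs[[i]], seqs[[1]])
  expect_identical(seqs[[1]], rep(c(1L, 2L), length.out = length(seqs[[1]])))
  # very high thresholds shorten visits below the length filter but the
  # detected visits never reorder
  for (i in 5:6) expect_true(all(seqs[[i]] %in% c(1L, 2L)))
})
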