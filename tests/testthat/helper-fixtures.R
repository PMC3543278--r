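# Shared fixtures, built in code at test time.

tiny_unit <- function(...) {
  args <- list(nExc = 20, nInh = 5, driveExc = -0.025, driveInh = -0.025,
               gEE = 0, gEI = 0, gIE = 0, gII = 0, gapStrength = 0,
               noiseIntensity = 0.005)
  args[names(list(...))] <- list(...)
  do.call(UnitParams, args)
}

# deterministic suprathreshold single neuron
one_neuron <- function(drive, D = 0) {
  UnitParams(nExc = 1, nInh = 1, driveExc = drive, driveInh = -1,
             gEE = 0, gEI = 0, gIE = 0, gII = 0, gapStrength = 0,
             noiseIntensity = D)
}

# period of the noise-free theta neuron by adaptive quadrature of
# dt = dtheta / f(theta) over one full cycle (independent oracle)
theta_period_quadrature <- function(r) {
  stopifnot(r > 0)
  f <- function(th) (1 - cos(th)) + (1 + cos(th)) * r
  stats::integrate(function(th) 1 / f(th), -pi, pi,
                   rel.tol = 1e-10)$value
}

# mass of a density matrix column
col_mass <- function(N) colSums(N) * 2 * pi / nrow(N)
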