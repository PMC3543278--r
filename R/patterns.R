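#' Construct a set of stored binary patterns
#'
#' @param patterns integer matrix (units x patterns), entries in {0, 1}.
#' @param activeFraction the pattern firing rate \eqn{a}; defaults to the
#'   empirical mean activity of the supplied patterns.
#' @return A \linkS4class{PatternSet}.
#' @export
PatternSet <- function(patterns, activeFraction = mean(patterns)) {
  storage.mode(patterns) <- "double"
  new("PatternSet", patterns = patterns,
      activeFraction = as.numeric(activeFraction))
}

#' Random binary patterns with a fixed number of active units
#'
#' Each pattern activates exactly \code{round(a * m)} units, drawn uniformly
#' at random without replacement; the draw is reproducible by \code{seed}.
#'
#' @param m number of units.
#' @param p number of patterns.
#' @param a target active fraction in (0, 1); \code{round(a * m)} must be
#'   at least 1.
#' @param seed integer seed.
#' @return A \linkS4class{PatternSet}.
#' @examples
#' ps <- generatePatterns(16, 3, 0.375, seed = 1)
#' colSums(patterns(ps))  # 6 active units each
#' @export
generatePatterns <- function(m, p, a, seed) {
  stopifnot(m >= 1, p >= 1, a > 0, a <= 1)
  k <- round(a * m)
  if (k < 1) stop("infeasible active fraction: round(a * m) < 1")
  pm <- matrix(0, m, p)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    replicate(p, sample.int(m, k), simplify = FALSE)
  })
  for (j in seq_len(p)) pm[rng[[j]], j] <- 1
  PatternSet(pm, k / m)
}

#' The built-in 16-unit, 3-pattern memory
#'
#' The package's reference memory stores three binary patterns over M = 16
#' units, each activating 6 units (firing rate a = 0.375), with pairwise
#' overlaps of one unit and with units 9 and 10 active in pattern 2 and in
#' no other pattern (these two units therefore address pattern 2 uniquely
#' and are the targets of the top-down glutamatergic input in the selection
#' experiments).  The reduced preset stores two patterns of 3 active units
#' each over M = 8 units, sharing one unit, with units 4 and 5 specific to
#' pattern 2; it exercises every code path at desk scale.
#'
#' These pattern sets are synthetic package presets constructed to satisfy
#' the structural constraints above; \code{presetPatterns("sixteen")} is the
#' default memory of \code{\link{networkPreset}}.
#'
#' @param name \code{"sixteen"} (M = 16, P = 3) or \code{"reduced"}
#'   (M = 8, P = 2).
#' @return A \linkS4class{PatternSet}.
#' @export
presetPatterns <- function(name = c("sixteen", "reduced")) {
  name <- match.arg(name)
  if (name == "sixteen") {
    act <- list(c(1, 2, 3, 4, 5, 6),
                c(5, 7, 9, 10, 11, 12),
                c(3, 12, 13, 14, 15, 16))
    m <- 16L
  } else {
    act <- list(c(1, 2, 3), c(3, 4, 5))
    m <- 8L
  }
  pm <- matrix(0, m, length(act))
  for (j in seq_along(act)) pm[act[[j]], j] <- 1
  PatternSet(pm, length(act[[1]]) / m)
}

#' @describeIn PatternSet-class the unit x pattern 0/1 matrix.
#' @param x a \linkS4class{PatternSet}.
#' @export
patterns <- function(x) {
  stopifnot(is(x, "PatternSet"))
  x@patterns
}

#' @describeIn PatternSet-class the pattern firing rate a.
#' @export
activeFraction <- function(x) {
  stopifnot(is(x, "PatternSet"))
  x@activeFraction
}

setMethod("show", "PatternSet", function(object) {
  pm <- object@patterns
  cat(sprintf("PatternSet: %d pattern(s) over %d units (a = %.3g)\n",
              ncol(pm), nrow(pm), object@activeFraction))
  for (j in seq_len(ncol(pm)))
    cat(sprintf("  pattern %d: %s\n", j, paste(pm[, j], collapse = "")))
})
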