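#' Local-peak-held value of an oscillating series
#'
#' The instantaneous population rate of a synchronized unit oscillates on
#' the fast (collective-spike) timescale, so its raw value cannot be
#' compared with a stored binary pattern.  This filter detects the local
#' maxima of the series (strict local maxima with a minimum-prominence
#' guard, so fine fluctuations of the rate do not register as peaks) and
#' holds, at every time, the mean height of the (up to) three most recent
#' peaks that are close to the current time (within \code{maxAge}).  The
#' result keeps the peak value between collective spikes and changes
#' slowly when the oscillation amplitude changes; when a unit falls
#' silent, its held value relaxes to the raw series once the last peak
#' ages out of the window.  Before the third peak the running maximum of
#' the series is used as a fallback.
#'
#' @param series numeric series (one unit's rate).
#' @param times monotone sample grid.
#' @param minProminence a candidate peak is accepted when it exceeds the
#'   deepest neighboring trough by this amount, relative to the series
#'   range; default 0.05.
#' @param maxAge only peaks within this lookback window count as recent;
#'   default 25 time units (several collective-spike periods).
#' @return numeric vector: the peak-held series on the same grid.
#' @export
localPeakHold <- function(series, times, minProminence = 0.05,
                          maxAge = 25) {
  stopifnot(length(series) == length(times))
  n <- length(series)
  if (n < 3) return(cummax(series))
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  rng <- diff(range(series))
  if (rng == 0) return(series)
  prom <- minProminence * rng
  cand <- which(diff(sign(diff(series))) == -2) + 1L
  if (length(cand)) {
    keep <- logical(length(cand))
    bounds <- c(0L, cand, n + 1L)
    for (i in seq_along(cand)) {
      lo <- max(bounds[i], 1L)
      hi <- min(bounds[i + 2L], n)
      left_min <- min(series[lo:cand[i]])
      right_min <- min(series[cand[i]:hi])
      keep[i] <- series[cand[i]] - max(left_min, right_min) >= prom
    }
    cand <- cand[keep]
  }
  out <- numeric(n)
  if (length(cand) < 3) {
    warning("fewer than three peaks detected; falling back to running max")
    return(cummax(series))
  }
  ph <- series[cand]
  pt <- times[cand]
  j <- 0L
  run_max <- cummax(series)
  for (i in seq_len(n)) {
    while (j < length(cand) && cand[j + 1L] <= i) j <- j + 1L
    if (j < 1L) {
      out[i] <- run_max[i]
    } else {
      recent <- which(pt[seq_len(j)] >= times[i] - maxAge)
      if (!length(recent)) {
        out[i] <- series[i]
      } else {
        take <- recent[max(1L, length(recent) - 2L):length(recent)]
        out[i] <- mean(ph[take])
      }
    }
  }
  out
}

#' Pattern overlaps from per-unit rate traces
#'
#' Maps every unit's excitatory rate through [localPeakHold()] and a
#' saturating normalization to \eqn{[0, 1)},
#' \deqn{F_k(t) = \frac{P_k(t)}{P_k(t) + p_{1/2}},}
#' and computes, for each stored pattern \eqn{\eta^\mu}, the overlap
#' \deqn{m^\mu(t) = \Big(\frac{\sum_k \eta^\mu_k F_k}{aM}\Big)
#'   \Big(\frac{\sum_k (1-\eta^\mu_k)(1-F_k)}{(1-a)M}\Big),}
#' the product of the mean activation of the pattern's active units and the
#' mean silence of its inactive units.  By construction \eqn{m^\mu \in
#' [0, 1]}, with 1 exactly when the normalized profile equals the pattern
#' and 0 when it equals its complement.
#'
#' @param flux a \linkS4class{FluxTrace} (or a \linkS4class{RateTrace}).
#' @param patternSet a \linkS4class{PatternSet}.
#' @param halfRate the half-saturation rate \eqn{p_{1/2}}; default 0.05.
#' @param minProminence,maxAge passed to [localPeakHold()].
#' @return An \linkS4class{OverlapTrace}.
#' @export
overlapTrace <- function(flux, patternSet, halfRate = 0.05,
                         minProminence = 0.05, maxAge = 25) {
  stopifnot(is(patternSet, "PatternSet"))
  rates <- if (is(flux, "FluxTrace")) flux@fluxExc else flux@rateExc
  times <- if (is(flux, "FluxTrace")) flux@times else flux@times
  eta <- patternSet@patterns
  M <- nrow(eta)
  if (ncol(rates) != M)
    stop("trace has ", ncol(rates), " units, patterns have ", M)
  held <- vapply(seq_len(M), function(k)
    suppressWarnings(localPeakHold(rates[, k], times, minProminence,
                                   maxAge)),
    numeric(length(times)))
  # tiny negative rate values (Gibbs oscillation of the mean-field
  # reconstruction) are clamped: rates are nonnegative by definition
  held <- pmax(held, 0)
  Fk <- held / (held + halfRate)
  a <- patternSet@activeFraction
  P <- ncol(eta)
  m <- matrix(0, length(times), P)
  for (mu in seq_len(P)) {
    on <- eta[, mu] == 1
    act <- if (any(on)) rowMeans(Fk[, on, drop = FALSE]) else 0
    sil <- if (any(!on)) rowMeans(1 - Fk[, !on, drop = FALSE]) else 1
    m[, mu] <- act * sil
  }
  new("OverlapTrace", times = times, m = m, peakHeld = held,
      normalized = Fk)
}

#' @describeIn OverlapTrace-class the overlap matrix (time x pattern).
#' @param x an \linkS4class{OverlapTrace}.
#' @export
overlaps <- function(x) x@m

#' @describeIn OverlapTrace-class sample times.
#' @export
overlapTimes <- function(x) x@times

setMethod("show", "OverlapTrace", function(object) {
  cat(sprintf("OverlapTrace: %d samples x %d pattern(s); max overlaps: %s\n",
              nrow(object@m), ncol(object@m),
              paste(sprintf("%.2f", apply(object@m, 2, max)),
                    collapse = ", ")))
})

#' Staying times at quasi-attractors
#'
#' Finds the maximal intervals during which one pattern's overlap satisfies
#' \eqn{m^\mu(t) \ge} \code{threshold}.  When two patterns exceed the
#' threshold simultaneously the one with the larger overlap wins.
#' Two visits to the same pattern separated by a dip shorter than
#' \code{mergeGap} are merged: a momentary flicker of the overlap across
#' the threshold is measurement jitter of the peak-held rate, not an exit.
#' Intervals truncated by the start or end of the trace are flagged as
#' censored and excluded from the mean.
#'
#' @param overlap an \linkS4class{OverlapTrace}.
#' @param threshold overlap threshold in (0, 1); the package default is
#'   0.85 (see the methods vignette for the sensitivity analysis).
#' @param mergeGap same-pattern visits separated by less than this are
#'   one visit (default 5 time units, below any true inter-visit gap).
#' @return A \linkS4class{StayingTimeResult}.
#' @export
stayingTimes <- function(overlap, threshold = 0.85, mergeGap = 5) {
  stopifnot(is(overlap, "OverlapTrace"), threshold > 0, threshold < 1)
  m <- overlap@m
  tt <- overlap@times
  n <- length(tt)
  above <- m >= threshold
  win <- apply(m, 1, which.max)
  active <- ifelse(rowSums(above) > 0, win, NA_integer_)
  active[!is.na(active) & !above[cbind(seq_len(n), win)]] <- NA_integer_
  runs <- rle(ifelse(is.na(active), 0L, active))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L
  iv <- data.frame(pattern = runs$values[keep],
                   start = tt[starts[keep]], end = tt[ends[keep]])
  # merge same-pattern visits separated by sub-mergeGap flickers
  if (nrow(iv) > 1 && mergeGap > 0) {
    merged <- iv[1, , drop = FALSE]
    for (i in 2:nrow(iv)) {
      last <- nrow(merged)
      if (iv$pattern[i] == merged$pattern[last] &&
          iv$start[i] - merged$end[last] < mergeGap) {
        merged$end[last] <- iv$end[i]
      } else {
        merged <- rbind(merged, iv[i, ])
      }
    }
    iv <- merged
  }
  if (nrow(iv)) {
    iv$censored <- (iv$start <= tt[1]) | (iv$end >= tt[n])
  } else {
    iv$censored <- logical(0)
  }
  rownames(iv) <- NULL
  dur <- iv$end - iv$start
  mst <- if (any(!iv$censored)) mean(dur[!iv$censored]) else NA_real_
  new("StayingTimeResult", intervals = iv, meanStayingTime = mst,
      threshold = threshold, horizon = tt[n] - tt[1])
}

#' @describeIn StayingTimeResult-class the interval table.
#' @param x a \linkS4class{StayingTimeResult}.
#' @export
stayingIntervals <- function(x) x@intervals

#' @describeIn StayingTimeResult-class mean over uncensored intervals.
#' @export
meanStayingTime <- function(x) x@meanStayingTime

setMethod("show", "StayingTimeResult", function(object) {
  iv <- object@intervals
  cat(sprintf(
    "StayingTimeResult: %d interval(s) (%d censored) at threshold %.2f\n",
    nrow(iv), sum(iv$censored), object@threshold))
  cat(sprintf("  mean staying time (uncensored): %s over horizon %g\n",
              format(object@meanStayingTime), object@horizon))
})
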