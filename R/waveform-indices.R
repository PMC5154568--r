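## The eight pulse-waveform indices, each defined on the phase-normalized
## composite cycle. All accept a PulseCycle or a bare numeric vector of
## phase values.

.cycleValues <- function(cycle) {
  if (is(cycle, "PulseCycle")) cycle@phaseValues
  else if (is.numeric(cycle) && length(cycle) >= 2) as.numeric(cycle)
  else stop("cycle must be a PulseCycle or a numeric vector")
}

#' Blowout time (BOT)
#'
#' Percentage of the cardiac cycle during which the waveform exceeds the
#' half level between its minimum and maximum — the half width of the pulse
#' relative to the cycle duration. High BOT indicates well-maintained
#' perfusion between heartbeats. A flat cycle is defined as BOT = 100 (the
#' whole cycle sits at the level) with a warning.
#'
#' @param cycle a \linkS4class{PulseCycle} or numeric phase values.
#' @param level \code{"half"}: level = (min + max) / 2 (the standard
#'   half-width level, default); \code{"quarter"}: (min + max) / 4.
#' @return BOT in percent, in [0, 100].
#' @examples
#' blowoutTime(c(0, 0.5, 1, 0.5))  # symmetric triangle -> 50
#' @export
blowoutTime <- function(cycle, level = c("half", "quarter")) {
  v <- .cycleValues(cycle)
  level <- match.arg(level)
  mn <- min(v); mx <- max(v)
  if (mx == mn) {
    warning("flat cycle: blowout time defined as 100")
    return(100)
  }
  lev <- switch(level, half = (mn + mx) / 2, quarter = (mn + mx) / 4)
  100 * mean(v > lev)
}

#' Blowout score (BOS)
#'
#' Index of the constancy of blood flow across the cardiac cycle, built
#' from the maximum, minimum and mean MBR:
#' \code{BOS = 100 (1 - (max - min) / (2 mean))}. A flat cycle scores 100;
#' values outside [0, 100] (possible only for extreme pulsatility) are
#' clipped with a warning.
#'
#' @param cycle a \linkS4class{PulseCycle} or numeric phase values.
#' @return BOS in percent, in [0, 100].
#' @export
blowoutScore <- function(cycle) {
  v <- .cycleValues(cycle)
  m <- mean(v)
  if (m <= 0) stop("blowout score undefined: mean MBR is not positive")
  bos <- 100 * (1 - (max(v) - min(v)) / (2 * m))
  if (bos < 0 || bos > 100) {
    warning("blowout score outside [0, 100]; clipped")
    bos <- min(max(bos, 0), 100)
  }
  bos
}

#' Skew of the pulse waveform
#'
#' Temporal asymmetry of the waveform: the cycle is treated as a
#' distribution of flow over phase (weights \code{value - min}) and the
#' standardized third moment of phase under those weights is returned,
#' multiplied by a scale constant. Zero for a waveform symmetric in time;
#' positive for an early-peaked (leftward) pulse, whose mass sits early in
#' the cycle with a tail to the right — the arterial pattern — and larger
#' for a steeper post-peak decline. Reversing the cycle in time negates the
#' value.
#'
#' @param cycle a \linkS4class{PulseCycle} or numeric phase values.
#' @param scale multiplicative scale constant (default 10; the vendor
#'   scaling is unpublished, and all sign and symmetry properties are
#'   scale-free).
#' @return Scaled skew (AU).
#' @export
waveformSkew <- function(cycle, scale = 10) {
  v <- .cycleValues(cycle)
  if (length(unique(v)) < 3)
    stop("skew undefined: cycle needs at least 3 distinct values")
  w <- v - min(v)
  sw <- sum(w)
  if (sw <= 0 || stats::var(v) == 0)
    stop("skew undefined: zero variance cycle")
  w <- w / sw
  n <- length(v)
  u <- (seq_len(n) - 0.5) / n  # phase bin centres
  mu <- sum(w * u)
  m2 <- sum(w * (u - mu)^2)
  m3 <- sum(w * (u - mu)^3)
  if (m2 <= 0) stop("skew undefined: degenerate phase distribution")
  scale * m3 / m2^1.5
}

#' Acceleration time index (ATI)
#'
#' Percentage of the cardiac cycle elapsed before the waveform peak (first
#' occurrence on ties), i.e. the relative time to peak.
#'
#' @param cycle a \linkS4class{PulseCycle} or numeric phase values.
#' @return ATI in percent, in [0, 100).
#' @examples
#' accelerationTimeIndex(c(rep(0, 10), 1, rep(0, 29)))  # peak at bin 10 of 40
#' @export
accelerationTimeIndex <- function(cycle) {
  v <- .cycleValues(cycle)
  100 * (which.max(v) - 1) / length(v)
}

## Shared machinery of RR / FR: rotate the cycle to start at its (first)
## trough, then take the mean positive per-bin increment of the ascending
## limb (trough -> first peak) or the mean per-bin decrement of the
## descending limb (last peak -> trough, wrapping), normalized by mean MBR.
.limbRate <- function(v, which = c("rising", "falling")) {
  which <- match.arg(which)
  if (max(v) == min(v))
    stop("rate undefined: flat cycle")
  n <- length(v)
  t0 <- which.min(v)
  vr <- v[c(seq.int(t0, n), seq_len(t0 - 1))]
  m <- mean(v)
  if (which == "rising") {
    p1 <- which.max(vr)
    d <- diff(vr[seq_len(p1)])
    d <- d[d > 0]
    if (!length(d)) stop("rate undefined: no ascending limb")
    100 * mean(d) / m
  } else {
    p2 <- n + 1L - which.max(rev(vr))  # last occurrence of the maximum
    d <- -diff(c(vr[seq.int(p2, n)], vr[1]))
    d <- d[d > 0]
    if (!length(d)) stop("rate undefined: no descending limb")
    100 * mean(d) / m
  }
}

#' Rising rate (RR)
#'
#' Steepness of the ascending (systolic) limb: the mean positive per-bin
#' MBR increment from the trough to the peak, normalized by the mean MBR of
#' the cycle, in percent. Higher values indicate a more sudden increase of
#' MBR. Scale-invariant.
#'
#' @param cycle a \linkS4class{PulseCycle} or numeric phase values.
#' @return RR in percent (>= 0).
#' @export
risingRate <- function(cycle) .limbRate(.cycleValues(cycle), "rising")

#' Falling rate (FR)
#'
#' Steepness of the descending (diastolic) limb: the mean per-bin MBR
#' decrement from the peak back to the trough, normalized by the mean MBR,
#' in percent. Higher values indicate a more sudden decrease of MBR; FR
#' grows strictly as the diastolic decay constant shrinks.
#'
#' @param cycle a \linkS4class{PulseCycle} or numeric phase values.
#' @return FR in percent (>= 0).
#' @export
fallingRate <- function(cycle) .limbRate(.cycleValues(cycle), "falling")

#' Flow acceleration index (FAI)
#'
#' The largest MBR increment between two adjacent phase bins (cyclically),
#' i.e. the peak frame-to-frame acceleration of flow. Zero for a flat
#' cycle; always >= 0 since increments around a closed cycle sum to zero.
#'
#' @param cycle a \linkS4class{PulseCycle} or numeric phase values.
#' @return FAI in AU per phase bin.
#' @examples
#' flowAccelerationIndex(c(1, 2, 4, 3, 1, 1, 1, 1))  # largest step 4 - 2 = 2
#' @export
flowAccelerationIndex <- function(cycle) {
  v <- .cycleValues(cycle)
  max(diff(c(v, v[1])))
}

#' Resistivity index (RI)
#'
#' The ratio of the difference between maximum and minimum MBR to the
#' maximum MBR, \code{(max - min) / max} — the pulsatility / peripheral
#' resistance proxy. In [0, 1]; zero iff the cycle is flat.
#'
#' @param cycle a \linkS4class{PulseCycle} or numeric phase values.
#' @return RI, dimensionless.
#' @examples
#' resistivityIndex(c(10, 8, 6, 7, 9, 10, 10, 10))  # (10 - 6) / 10
#' @export
resistivityIndex <- function(cycle) {
  v <- .cycleValues(cycle)
  mx <- max(v)
  if (mx <= 0) stop("resistivity index undefined: maximum MBR is not positive")
  (mx - min(v)) / mx
}
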