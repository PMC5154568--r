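## Cardiac-cycle detection and phase normalization: trough-to-trough
## segmentation of the MBR series and the phase-averaged composite cycle.

#' Waveform-analysis configuration
#'
#' Settings of the pulse-waveform stage: number of phase bins of the
#' composite cycle, smoothing width of the cycle detector, the blowout-time
#' half-level rule, and the skew scale constant. Unknown keys are rejected.
#'
#' @param ... named overrides. Defaults: \code{phaseBins = 30} (about one
#'   bin per frame at heart rate 60 and 30 fps), \code{smoothWidth = 3}
#'   (samples), \code{botLevel = "half"} (level = (min + max) / 2; the
#'   alternative reading \code{"quarter"} uses (min + max) / 4),
#'   \code{skewScale = 10}.
#' @return A named list of waveform settings.
#' @export
waveformConfig <- function(...) {
  cfg <- list(phaseBins = 30, smoothWidth = 3, botLevel = "half",
              skewScale = 10)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("waveformConfig overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown waveform setting(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  if (cfg$phaseBins < 8) stop("phaseBins must be >= 8")
  if (!cfg$botLevel %in% c("half", "quarter"))
    stop("botLevel must be 'half' or 'quarter'")
  cfg
}

#' Detect cardiac cycles in an MBR series
#'
#' Locates successive diastolic troughs (local minima of a lightly smoothed
#' copy of the series) and returns the boundaries of the complete cardiac
#' cycles between them. Only cycle lengths corresponding to a heart rate in
#' the physiological window 40-120 bpm are admitted; when two candidate
#' troughs fall closer than the shortest admissible cycle the deeper one is
#' kept. A series with no pulsatility, or in which no admissible cycle can
#' be formed, raises a "no cardiac cycle detected" error — the analogue of
#' the study's scan-quality exclusion.
#'
#' @param series an \linkS4class{MbrSeries}.
#' @param smoothWidth moving-average width in samples (default 3).
#' @return A \linkS4class{CycleSegmentation}.
#' @examples
#' p <- simulateSubject(30, "male", seed = 5)
#' s <- generateMbrSeries(p, seed = 5, phaseOffset = 0)
#' detectCycles(s)
#' @export
detectCycles <- function(series, smoothWidth = 3) {
  stopifnot(is(series, "MbrSeries"))
  v <- series@values
  fr <- series@frameRate
  n <- length(v)
  sm <- .smooth(v, smoothWidth)
  if (diff(range(sm)) <= 1e-9 * max(1, max(abs(sm))))
    stop("no cardiac cycle detected: series has no pulsatility")
  minLen <- floor(fr * 60 / .HR_MAX)
  maxLen <- ceiling(fr * 60 / .HR_MIN)
  if (n < minLen + 1)
    stop("no cardiac cycle detected: series shorter than one cycle")
  w <- max(2L, as.integer(floor(minLen / 2)))
  rm <- .runMin(sm, w)
  cand <- which(sm <= rm)
  if (!length(cand))
    stop("no cardiac cycle detected")
  # collapse plateau runs of equal-minimum samples to their centre
  runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
  cand <- vapply(runs, function(ix) as.integer(round(mean(ix))), integer(1))
  # a genuine diastolic trough is followed by a rise within the window (so
  # the truncated decay tail at the record end never counts) and preceded by
  # a decline unless the record starts at the trough
  isTrough <- vapply(cand, function(i) {
    right <- sm[seq.int(min(i + 1, n), min(i + w, n))]
    left <- sm[seq.int(max(i - w, 1), max(i - 1, 1))]
    riseAfter <- i < n && any(right > sm[i])
    fallBefore <- i == 1 || i - 1 < w || any(left > sm[i])
    riseAfter && fallBefore
  }, logical(1))
  cand <- cand[isTrough]
  if (!length(cand))
    stop("no cardiac cycle detected: no admissible trough")
  bounds <- cand[1]
  for (i in cand[-1]) {
    last <- bounds[length(bounds)]
    d <- i - last
    if (d < minLen) {
      if (sm[i] < sm[last]) {
        prevOk <- length(bounds) == 1 ||
          (i - bounds[length(bounds) - 1]) <= maxLen
        if (prevOk) bounds[length(bounds)] <- i
      }
    } else if (d <= maxLen) {
      bounds <- c(bounds, i)
    } else if (length(bounds) < 2) {
      bounds <- i  # restart: gap too long to be one cycle
    }
  }
  if (length(bounds) < 2)
    stop("no cardiac cycle detected: no admissible trough-to-trough interval")
  new("CycleSegmentation", boundaries = as.integer(bounds), frameRate = fr)
}

#' Phase-normalized composite cardiac cycle
#'
#' Resamples every detected cycle onto \code{nPhaseBins} equally spaced
#' points of normalized phase [0, 1) by linear interpolation and averages
#' them pointwise — the single composite cycle on which all pulse-waveform
#' indices are computed. The cycle duration is the mean detected cycle
#' length in seconds.
#'
#' @param series the \linkS4class{MbrSeries} that was segmented.
#' @param seg the \linkS4class{CycleSegmentation} from
#'   \code{\link{detectCycles}} on the same series.
#' @param nPhaseBins number of phase bins (>= 8; default 30).
#' @return A \linkS4class{PulseCycle}.
#' @export
compositeCycle <- function(series, seg, nPhaseBins = 30) {
  stopifnot(is(series, "MbrSeries"), is(seg, "CycleSegmentation"))
  if (nPhaseBins < 8) stop("nPhaseBins must be >= 8")
  v <- series@values
  b <- seg@boundaries
  if (b[length(b)] > length(v)) stop("segmentation indexes beyond the series")
  k <- length(b) - 1L
  acc <- numeric(nPhaseBins)
  for (j in seq_len(k)) {
    L <- b[j + 1] - b[j]
    pos <- b[j] + (seq_len(nPhaseBins) - 1) / nPhaseBins * L
    acc <- acc + stats::approx(seq_along(v), v, xout = pos)$y
  }
  new("PulseCycle", phaseValues = pmax(acc / k, 0),
      cycleDuration = mean(diff(b)) / series@frameRate)
}

#' Full pulse-waveform analysis of one scan
#'
#' The single entry point used by the cohort simulator: cycle detection,
#' composite-cycle construction, then all eight pulse-waveform indices plus
#' the mean MBR of the composite cycle. Propagates the "no cardiac cycle
#' detected" error for series that defeat segmentation.
#'
#' @param series an \linkS4class{MbrSeries}.
#' @param config a \code{\link{waveformConfig}} list.
#' @return A \linkS4class{WaveformIndices}.
#' @examples
#' p <- simulateSubject(55, "female", seed = 9)
#' s <- generateMbrSeries(p, seed = 9)
#' waveformProfile(s)
#' @export
waveformProfile <- function(series, config = waveformConfig()) {
  seg <- detectCycles(series, smoothWidth = config$smoothWidth)
  cyc <- compositeCycle(series, seg, nPhaseBins = config$phaseBins)
  new("WaveformIndices",
      meanMbr = mean(cyc@phaseValues),
      bot = blowoutTime(cyc, level = config$botLevel),
      bos = blowoutScore(cyc),
      skew = waveformSkew(cyc, scale = config$skewScale),
      ati = accelerationTimeIndex(cyc),
      rr = risingRate(cyc),
      fr = fallingRate(cyc),
      fai = flowAccelerationIndex(cyc),
      ri = resistivityIndex(cyc))
}
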