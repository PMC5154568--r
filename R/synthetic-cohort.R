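## Synthetic cohort generator: subject profiles with age-dependent pulse
## shape, MBR time series, flow-map stacks, and the full long-format study
## table (4 age groups x 2 sexes x repeats x 2 pupil conditions).

#' Generator configuration
#'
#' Defaults of the synthetic cohort generator: the linear age maps of the
#' waveform-shape parameters, the systemic covariate models, the noise
#' scales of repeated scans, and the scan-failure probabilities. The age
#' maps encode the physiological premise that arterial (Windkessel)
#' buffering declines with age — the diastolic decay constant shrinks and
#' pulsatility grows — while mean tissue MBR declines.
#'
#' Units: time constants in seconds, MBR in AU, pressures in mmHg, slopes
#' per year of age.
#'
#' @param ... named overrides of the defaults listed below; unknown keys are
#'   rejected.
#' @return A named list of generator settings.
#' @details Defaults:
#' \itemize{
#'   \item \code{tauIntercept = 0.80}, \code{tauSlope = -0.006},
#'     \code{tauSd = 0.05}, \code{tauMin = 0.12}: diastolic decay constant
#'     (s), strictly decreasing in age.
#'   \item \code{riseIntercept = 0.305}, \code{riseSlope = -3e-4},
#'     \code{riseSd = 0.015}, bounds (0.16, 0.44): systolic rise fraction,
#'     weakly decreasing in age.
#'   \item \code{baselineIntercept = 7.8}, \code{baselineSlope = -0.025},
#'     \code{baselineSd = 0.9}, \code{baselineMin = 2}: diastolic tissue MBR
#'     floor (AU), decreasing in age.
#'   \item \code{amplitudeRatioMean = 1.35}, \code{amplitudeRatioSd = 0.12},
#'     \code{amplitudeRatioMin = 0.3}: pulse amplitude as a multiple of the
#'     baseline.
#'   \item \code{hrIntercept = 76}, \code{hrSlope = -0.12}, \code{hrSd = 8},
#'     bounds (45, 115): heart rate (bpm).
#'   \item \code{dbpIntercept = 73}, \code{dbpSlope = 0.13},
#'     \code{dbpSexDelta = 3.5}, \code{dbpSd = 7}, bounds (55, 105):
#'     diastolic blood pressure; the sex delta is added for males.
#'   \item \code{ppaIntercept = 40}, \code{ppaSlope = 0.10},
#'     \code{ppaSexDelta = 4}, \code{ppaSd = 8}, \code{ppaMin = 18}: pulse
#'     pressure amplitude; SBP = DBP + PPA.
#'   \item \code{iopMean = 12.8}, \code{iopSd = 2.4}, bounds (8, 21):
#'     intraocular pressure.
#'   \item \code{measurementNoiseSd = 0.4}, \code{betweenScanSd = 0.5}:
#'     within-scan additive noise and scan-to-scan level shift (AU).
#'   \item \code{vesselRatioMean = 3.36}, \code{vesselRatioSd = 0.25}:
#'     per-subject MV/MT ratio; \code{vesselFractionMean = 0.387},
#'     \code{vesselFractionSd = 0.03}, bounds (0.2, 0.6): vessel area
#'     fraction used to compose MA.
#'   \item \code{failProbUndilated = 15/240}, \code{failProbDilated = 3/240}:
#'     Bernoulli scan-failure probabilities per condition.
#'   \item \code{dilationOffsets}: additive index shifts under mydriasis.
#'   \item \code{nFrames = 118}, \code{scanFrameRate = 30}: scan geometry.
#' }
#' @examples
#' cfg <- generatorConfig(measurementNoiseSd = 0, betweenScanSd = 0)
#' @export
generatorConfig <- function(...) {
  cfg <- list(
    tauIntercept = 0.80, tauSlope = -0.006, tauSd = 0.05, tauMin = 0.12,
    riseIntercept = 0.305, riseSlope = -3e-4, riseSd = 0.015,
    riseMin = 0.16, riseMax = 0.44,
    baselineIntercept = 7.8, baselineSlope = -0.025, baselineSd = 0.9,
    baselineMin = 2,
    amplitudeRatioMean = 1.35, amplitudeRatioSd = 0.12,
    amplitudeRatioMin = 0.3,
    hrIntercept = 76, hrSlope = -0.12, hrSd = 8, hrMin = 45, hrMax = 115,
    dbpIntercept = 73, dbpSlope = 0.13, dbpSexDelta = 3.5, dbpSd = 7,
    dbpMin = 55, dbpMax = 105,
    ppaIntercept = 40, ppaSlope = 0.10, ppaSexDelta = 4, ppaSd = 8,
    ppaMin = 18,
    iopMean = 12.8, iopSd = 2.4, iopMin = 8, iopMax = 21,
    measurementNoiseSd = 0.4, betweenScanSd = 0.5,
    vesselRatioMean = 3.36, vesselRatioSd = 0.25,
    vesselFractionMean = 0.387, vesselFractionSd = 0.03,
    vesselFractionMin = 0.2, vesselFractionMax = 0.6,
    failProbUndilated = 15 / 240, failProbDilated = 3 / 240,
    dilationOffsets = c(MA = -0.2, MV = -0.4, MT = 0, BOT = -1.0,
                        BOS = -1.6, Skew = 0.6, ATI = -0.7, RR = 0.2,
                        FR = 0.2, FAI = 0.07, RI = 0.02),
    nFrames = 118, scanFrameRate = 30
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("generatorConfig overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown generator setting(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

## Draw one subject from the current RNG stream.
.drawSubject <- function(subjectId, age, sex, cfg) {
  tau <- .rnormTrunc(1, cfg$tauIntercept + cfg$tauSlope * age, cfg$tauSd,
                     lo = cfg$tauMin)
  rise <- .rnormTrunc(1, cfg$riseIntercept + cfg$riseSlope * age,
                      cfg$riseSd, lo = cfg$riseMin, hi = cfg$riseMax)
  base <- .rnormTrunc(1, cfg$baselineIntercept + cfg$baselineSlope * age,
                      cfg$baselineSd, lo = cfg$baselineMin)
  ampR <- .rnormTrunc(1, cfg$amplitudeRatioMean, cfg$amplitudeRatioSd,
                      lo = cfg$amplitudeRatioMin)
  hr <- .rnormTrunc(1, cfg$hrIntercept + cfg$hrSlope * age, cfg$hrSd,
                    lo = cfg$hrMin, hi = cfg$hrMax)
  male <- sex == "male"
  dbp <- .rnormTrunc(1, cfg$dbpIntercept + cfg$dbpSlope * age +
                       cfg$dbpSexDelta * male, cfg$dbpSd,
                     lo = cfg$dbpMin, hi = cfg$dbpMax)
  ppa <- .rnormTrunc(1, cfg$ppaIntercept + cfg$ppaSlope * age +
                       cfg$ppaSexDelta * male, cfg$ppaSd, lo = cfg$ppaMin)
  iop <- .rnormTrunc(1, cfg$iopMean, cfg$iopSd, lo = cfg$iopMin,
                     hi = cfg$iopMax)
  new("SubjectProfile", subjectId = subjectId, age = age, sex = sex,
      heartRate = hr, mbrBaseline = base, pulseAmplitude = ampR * base,
      systolicRiseFraction = rise, diastolicDecayTau = tau,
      sbp = dbp + ppa, dbp = dbp, iop = iop,
      measurementNoiseSd = cfg$measurementNoiseSd,
      betweenScanSd = cfg$betweenScanSd)
}

#' Simulate one subject profile
#'
#' Draws a \linkS4class{SubjectProfile} from the generator's age maps: the
#' diastolic decay constant strictly decreases in expectation with age, the
#' systolic rise fraction weakly decreases, the tissue MBR baseline
#' declines, and male profiles carry higher blood pressure on average.
#' Deterministic given the seed.
#'
#' @param age years, in [18, 80].
#' @param sex \code{"male"} or \code{"female"}.
#' @param seed integer seed.
#' @param config a \code{\link{generatorConfig}} list.
#' @param subjectId identifier for the profile.
#' @return A \linkS4class{SubjectProfile}.
#' @examples
#' simulateSubject(age = 30, sex = "female", seed = 7)
#' @export
simulateSubject <- function(age, sex, seed, config = generatorConfig(),
                            subjectId = "subject") {
  if (!is.numeric(age) || length(age) != 1 || age < 18 || age > 80)
    stop("age must lie in [18, 80]")
  sex <- match.arg(sex, c("male", "female"))
  .withSeed(seed, .drawSubject(subjectId, age, sex, config))
}

#' Analytic MBR pulse waveform
#'
#' The noise-free periodic tissue MBR waveform of a subject: a raised-cosine
#' systolic upstroke over \code{systolicRiseFraction} of the cardiac period
#' followed by an exponential diastolic decay toward the baseline with time
#' constant \code{diastolicDecayTau}. The upstroke starts at the value the
#' decay reached at the end of the previous cycle, so the waveform is
#' continuous and periodic with a single maximum per period (the classic
#' steep systolic incline / flatter diastolic decline shape).
#'
#' @param profile a \linkS4class{SubjectProfile}.
#' @param t times in seconds (vector, >= 0).
#' @return MBR values (AU) at \code{t}.
#' @examples
#' p <- simulateSubject(25, "male", seed = 1)
#' curve <- mbrWaveform(p, seq(0, 2, by = 0.01))
#' @export
mbrWaveform <- function(profile, t) {
  stopifnot(is(profile, "SubjectProfile"))
  if (any(t < 0)) stop("t must be >= 0")
  P <- 60 / profile@heartRate
  b <- profile@mbrBaseline
  A <- profile@pulseAmplitude
  if (A == 0) return(rep(b, length(t)))
  s <- profile@systolicRiseFraction
  tau <- profile@diastolicDecayTau
  u <- (t %% P) / P
  v0 <- b + A * exp(-(1 - s) * P / tau)  # diastolic floor (end of decay)
  out <- numeric(length(t))
  ris <- u <= s
  out[ris] <- v0 + (b + A - v0) * 0.5 * (1 - cos(pi * u[ris] / s))
  out[!ris] <- b + A * exp(-(u[!ris] - s) * P / tau)
  out
}

#' Generate a noisy MBR time series for one scan
#'
#' Samples the analytic waveform at frame times shifted by a random phase
#' offset (uniform over one cardiac period) and adds Gaussian measurement
#' noise of SD \code{noiseSd}, truncated at zero. Deterministic given the
#' seed. The record must span at least two full cardiac cycles so that
#' downstream cycle detection has at least one complete cycle to work with.
#'
#' @param profile a \linkS4class{SubjectProfile}.
#' @param nFrames number of frames (default 118).
#' @param frameRate frames per second (default 30).
#' @param seed integer seed (or NULL to use the current RNG stream).
#' @param phaseOffset fixed phase offset in seconds; if NULL (default) it is
#'   drawn uniformly over one period.
#' @param noiseSd additive noise SD (AU); defaults to the profile's
#'   \code{measurementNoiseSd}.
#' @param scanId identifier for the series.
#' @return An \linkS4class{MbrSeries} (region label \code{"tissue"}).
#' @examples
#' p <- simulateSubject(40, "female", seed = 2)
#' s <- generateMbrSeries(p, seed = 11)
#' @export
generateMbrSeries <- function(profile, nFrames = 118, frameRate = 30,
                              seed = NULL, phaseOffset = NULL,
                              noiseSd = profile@measurementNoiseSd,
                              scanId = "scan") {
  stopifnot(is(profile, "SubjectProfile"))
  P <- 60 / profile@heartRate
  if (nFrames / frameRate < 2 * P)
    stop(sprintf(
      "record too short: %d frames at %g fps span %.2f s < 2 cardiac cycles (%.2f s)",
      nFrames, frameRate, nFrames / frameRate, 2 * P))
  .withSeed(seed, {
    if (is.null(phaseOffset)) phaseOffset <- stats::runif(1, 0, P)
    t <- (seq_len(nFrames) - 1) / frameRate + phaseOffset
    v <- mbrWaveform(profile, t)
    if (noiseSd > 0) v <- v + stats::rnorm(nFrames, 0, noiseSd)
    MbrSeries(pmax(v, 0), frameRate = frameRate, scanId = scanId,
              regionLabel = "tissue")
  })
}

## Time-mean of the normalized waveform over one period (fine grid).
.waveformTimeMean <- function(profile, nGrid = 4096) {
  P <- 60 / profile@heartRate
  mean(mbrWaveform(profile, (seq_len(nGrid) - 0.5) / nGrid * P))
}

#' Generate a synthetic flow-map stack
#'
#' Renders the scan of a ground-truth scene: each pixel carries its region's
#' flow scale (vessel or tissue) modulated by the subject's normalized pulse
#' waveform (time mean 1), plus optional Gaussian pixel noise truncated at
#' zero. Vessel pixels therefore exceed tissue pixels in time-averaged
#' value by construction. Deterministic given the seed.
#'
#' @param profile a \linkS4class{SubjectProfile}.
#' @param scene a \linkS4class{GroundTruthScene}.
#' @param nFrames,frameRate scan geometry (defaults 118 frames at 30 fps).
#' @param seed integer seed.
#' @param noiseSd pixel noise SD (AU).
#' @param phaseOffset phase offset in seconds (NULL = drawn uniformly).
#' @return A \linkS4class{FlowMapStack}.
#' @export
generateFlowMapStack <- function(profile, scene, nFrames = 118,
                                 frameRate = 30, seed = NULL, noiseSd = 0,
                                 phaseOffset = 0) {
  stopifnot(is(profile, "SubjectProfile"), is(scene, "GroundTruthScene"))
  validObject(scene)
  P <- 60 / profile@heartRate
  base <- ifelse(scene@vesselMask, scene@vesselFlowScale,
                 scene@tissueFlowScale)
  .withSeed(seed, {
    if (is.null(phaseOffset)) phaseOffset <- stats::runif(1, 0, P)
    t <- (seq_len(nFrames) - 1) / frameRate + phaseOffset
    wn <- mbrWaveform(profile, t) / .waveformTimeMean(profile)
    h <- nrow(base); w <- ncol(base)
    fr <- array(as.vector(base) %o% wn, dim = c(h, w, nFrames))
    if (noiseSd > 0)
      fr <- fr + array(stats::rnorm(length(fr), 0, noiseSd), dim = dim(fr))
    new("FlowMapStack", frames = pmax(fr, 0), frameRate = frameRate,
        exposure = 1 / 500)
  })
}

#' Simulate a full study cohort
#'
#' Generates the long-format study table: 4 age groups (18-34, 35-49,
#' 50-64, 65-80) x 2 sexes x \code{nPerCell} subjects, each scanned
#' \code{repeats} times per pupil condition. Every successful scan is an MBR
#' series pushed through the waveform-analysis pipeline
#' (\code{\link{waveformProfile}}), so the index columns are produced by the
#' method under test, not copied from formulas. MT is the scan's mean MBR;
#' MV and MA are composed through the subject's vessel ratio and vessel area
#' fraction. Scans fail at the configured per-condition Bernoulli rates (and
#' a scan whose series defeats cycle detection is likewise marked
#' unsuccessful); failed scans carry NA indices. Under mydriasis the
#' configured small index offsets are added. Deterministic given the seed.
#'
#' When every noise SD is zero the generator collapses to its analytic
#' core: the per-scan phase offset is pinned to zero so repeated scans are
#' identical and downstream repeatability statistics are exactly degenerate
#' (COV 0, ICC 1).
#'
#' @param nPerCell subjects per (age group x sex) cell (default 10, i.e. 80
#'   subjects).
#' @param repeats scans per condition per subject (2 or 3; default 3).
#' @param seed integer seed.
#' @param config a \code{\link{generatorConfig}} list.
#' @param waveform a \code{\link{waveformConfig}} list.
#' @param conditions which pupil conditions to simulate.
#' @return A \linkS4class{CohortDataset}.
#' @examples
#' coh <- simulateCohort(nPerCell = 1, repeats = 2, seed = 3)
#' cohortTable(coh)[1:4, 1:10]
#' @export
simulateCohort <- function(nPerCell = 10, repeats = 3, seed = 1,
                           config = generatorConfig(),
                           waveform = waveformConfig(),
                           conditions = c("undilated", "dilated")) {
  if (nPerCell < 1) stop("nPerCell must be >= 1")
  if (repeats < 2)
    stop("repeats must be >= 2 (repeatability statistics are undefined otherwise)")
  if (repeats > 3) stop("at most 3 repeats per (subject, condition)")
  conditions <- match.arg(conditions, c("undilated", "dilated"),
                          several.ok = TRUE)
  groups <- list(c(18, 34), c(35, 49), c(50, 64), c(65, 80))
  zeroNoise <- config$measurementNoiseSd == 0 && config$betweenScanSd == 0
  off <- config$dilationOffsets[.INDEX_COLUMNS]
  .withSeed(seed, {
    rows <- vector("list", 8 * nPerCell * length(conditions) * repeats)
    ri <- 0L
    sid <- 0L
    for (g in seq_along(groups)) for (sex in c("male", "female")) {
      ages <- sample(seq(groups[[g]][1], groups[[g]][2]), nPerCell,
                     replace = TRUE)
      for (i in seq_len(nPerCell)) {
        sid <- sid + 1L
        id <- sprintf("S%03d", sid)
        prof <- .drawSubject(id, ages[i], sex, config)
        vR <- .rnormTrunc(1, config$vesselRatioMean, config$vesselRatioSd,
                          lo = 1.2)
        vF <- .rnormTrunc(1, config$vesselFractionMean,
                          config$vesselFractionSd,
                          lo = config$vesselFractionMin,
                          hi = config$vesselFractionMax)
        P <- 60 / prof@heartRate
        for (cond in conditions) {
          pFail <- if (cond == "dilated") config$failProbDilated
                   else config$failProbUndilated
          for (r in seq_len(repeats)) {
            fail <- stats::runif(1) < pFail
            idx <- rep(NA_real_, length(.INDEX_COLUMNS))
            names(idx) <- .INDEX_COLUMNS
            ok <- FALSE
            if (!fail) {
              phase <- if (zeroNoise) 0 else stats::runif(1, 0, P)
              shift <- if (config$betweenScanSd > 0)
                stats::rnorm(1, 0, config$betweenScanSd) else 0
              t <- (seq_len(config$nFrames) - 1) / config$scanFrameRate +
                phase
              v <- mbrWaveform(prof, t) + shift
              if (config$measurementNoiseSd > 0)
                v <- v + stats::rnorm(config$nFrames, 0,
                                      config$measurementNoiseSd)
              series <- MbrSeries(pmax(v, 0),
                                  frameRate = config$scanFrameRate,
                                  scanId = sprintf("%s_%s_%d", id, cond, r))
              wi <- tryCatch(waveformProfile(series, waveform),
                             error = function(e) NULL)
              if (!is.null(wi)) {
                ok <- TRUE
                mt <- wi@meanMbr
                mv <- mt * vR
                ma <- vF * mv + (1 - vF) * mt
                idx[] <- c(ma, mv, mt, wi@bot, wi@bos, wi@skew, wi@ati,
                           wi@rr, wi@fr, wi@fai, wi@ri)
                if (cond == "dilated") idx <- idx + off
              }
            }
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
              subject_id = id, age = prof@age, sex = sex,
              sbp = round(prof@sbp, 1), dbp = round(prof@dbp, 1),
              hr = round(prof@heartRate, 1), iop = round(prof@iop, 1),
              condition = cond, "repeat" = r, scan_success = ok,
              as.list(idx), check.names = FALSE)
          }
        }
      }
    }
    CohortDataset(do.call(rbind, rows[seq_len(ri)]))
  })
}
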