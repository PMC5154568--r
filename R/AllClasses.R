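#' @import methods
NULL

## Physiological admissibility window for heart rate used throughout cycle
## detection and segmentation validity (beats per minute).
.HR_MIN <- 40
.HR_MAX <- 120

## Column order of the cohort interchange table (CSV header contract).
.COHORT_COLUMNS <- c(
  "subject_id", "age", "sex", "sbp", "dbp", "hr", "iop",
  "condition", "repeat", "scan_success",
  "MA", "MV", "MT", "BOT", "BOS", "Skew", "ATI", "RR", "FR", "FAI", "RI"
)

.INDEX_COLUMNS <- c("MA", "MV", "MT", "BOT", "BOS", "Skew", "ATI", "RR",
                    "FR", "FAI", "RI")

#' MbrSeries: a per-scan mean-blur-rate time series
#'
#' Ordered MBR samples (arbitrary units, AU) acquired at a fixed frame rate,
#' the raw material of all pulse-waveform analysis. MBR is a relative
#' blood-flow-velocity measure; values are nonnegative.
#'
#' @slot values numeric vector of MBR samples (AU), length >= 2, all >= 0.
#' @slot frameRate acquisition rate in frames per second (> 0).
#' @slot scanId opaque scan identifier.
#' @slot regionLabel one of \code{"all"}, \code{"vessel"}, \code{"tissue"} —
#'   which part of the optic nerve head the series summarises.
#' @exportClass MbrSeries
setClass("MbrSeries",
  slots = c(values = "numeric", frameRate = "numeric",
            scanId = "character", regionLabel = "character"),
  prototype = prototype(frameRate = 30, scanId = "scan",
                        regionLabel = "tissue"))

setValidity("MbrSeries", function(object) {
  msg <- character()
  if (length(object@values) < 2)
    msg <- c(msg, "an MbrSeries needs at least 2 samples")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "MBR values must be finite and >= 0")
  if (length(object@frameRate) != 1 || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (!object@regionLabel %in% c("all", "vessel", "tissue"))
    msg <- c(msg, "regionLabel must be 'all', 'vessel' or 'tissue'")
  if (length(msg)) msg else TRUE
})

#' Construct an MbrSeries
#'
#' @param values numeric MBR samples (AU).
#' @param frameRate frames per second.
#' @param scanId opaque scan identifier.
#' @param regionLabel region the series summarises.
#' @return An \linkS4class{MbrSeries}.
#' @examples
#' s <- MbrSeries(10 + sin(seq(0, 8 * pi, length.out = 120)), frameRate = 30)
#' frameRate(s)
#' @export
MbrSeries <- function(values, frameRate = 30, scanId = "scan",
                      regionLabel = "tissue") {
  new("MbrSeries", values = as.numeric(values), frameRate = frameRate,
      scanId = scanId, regionLabel = regionLabel)
}

#' CycleSegmentation: detected cardiac-cycle boundaries
#'
#' Sample indices (1-based) of successive diastolic troughs delimiting the
#' complete cardiac cycles of an \linkS4class{MbrSeries}. Cycles are
#' half-open: cycle j spans samples \code{[boundaries[j], boundaries[j+1])}.
#' Every cycle length must correspond to a heart rate in the physiological
#' window 40–120 bpm.
#'
#' @slot boundaries strictly increasing integer sample indices.
#' @slot frameRate frames per second of the segmented series.
#' @exportClass CycleSegmentation
setClass("CycleSegmentation",
  slots = c(boundaries = "integer", frameRate = "numeric"))

setValidity("CycleSegmentation", function(object) {
  b <- object@boundaries
  msg <- character()
  if (length(b) < 2)
    msg <- c(msg, "need at least 2 boundaries (1 complete cycle)")
  if (length(b) >= 2) {
    d <- diff(b)
    if (any(d <= 0)) msg <- c(msg, "boundaries must be strictly increasing")
    lo <- object@frameRate * 60 / .HR_MAX
    hi <- object@frameRate * 60 / .HR_MIN
    if (any(d < lo - 1e-9) || any(d > hi + 1e-9))
      msg <- c(msg, sprintf(
        "cycle lengths must lie in [%.1f, %.1f] samples (HR %d-%d bpm)",
        lo, hi, .HR_MIN, .HR_MAX))
  }
  if (length(msg)) msg else TRUE
})

#' PulseCycle: one phase-normalized composite cardiac cycle
#'
#' MBR values at equally spaced phase points spanning one full cardiac cycle,
#' obtained by resampling each detected cycle onto a common phase grid and
#' averaging. All eight pulse-waveform indices are defined on this object.
#'
#' @slot phaseValues MBR (AU) at \code{n} equally spaced phases in [0, 1).
#' @slot cycleDuration mean cycle duration in seconds.
#' @exportClass PulseCycle
setClass("PulseCycle",
  slots = c(phaseValues = "numeric", cycleDuration = "numeric"))

setValidity("PulseCycle", function(object) {
  msg <- character()
  if (length(object@phaseValues) < 8)
    msg <- c(msg, "a PulseCycle needs at least 8 phase bins")
  if (any(!is.finite(object@phaseValues)) || any(object@phaseValues < 0))
    msg <- c(msg, "phase values must be finite and >= 0")
  if (length(object@cycleDuration) != 1 || !is.finite(object@cycleDuration) ||
      object@cycleDuration <= 0)
    msg <- c(msg, "cycleDuration must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a PulseCycle from raw phase values
#'
#' @param phaseValues MBR values on an equally spaced phase grid.
#' @param cycleDuration cycle duration in seconds.
#' @return A \linkS4class{PulseCycle}.
#' @examples
#' cyc <- PulseCycle(10 + 5 * sin(2 * pi * (0:29) / 30), cycleDuration = 0.9)
#' resistivityIndex(cyc)
#' @export
PulseCycle <- function(phaseValues, cycleDuration = 1) {
  new("PulseCycle", phaseValues = as.numeric(phaseValues),
      cycleDuration = cycleDuration)
}

#' WaveformIndices: the pulse-waveform parameter set of one scan
#'
#' The eight pulse-waveform indices plus the mean MBR, computed on the
#' composite cycle of one scan and region. Units: BOT, BOS, ATI, RR, FR in
#' percent; skew in AU (scaled, see \code{\link{waveformSkew}}); FAI in
#' AU per phase bin; RI dimensionless; meanMbr in AU.
#'
#' @slot meanMbr mean MBR of the composite cycle (AU, > 0).
#' @slot bot blowout time (percent of cycle above the half level).
#' @slot bos blowout score (flow constancy index, percent).
#' @slot skew temporal asymmetry of the waveform (AU).
#' @slot ati acceleration time index (percent of cycle before the peak).
#' @slot rr rising rate (percent).
#' @slot fr falling rate (percent).
#' @slot fai flow acceleration index (largest per-bin MBR increment, AU).
#' @slot ri resistivity index ((max - min)/max, in [0, 1]).
#' @exportClass WaveformIndices
setClass("WaveformIndices",
  slots = c(meanMbr = "numeric", bot = "numeric", bos = "numeric",
            skew = "numeric", ati = "numeric", rr = "numeric",
            fr = "numeric", fai = "numeric", ri = "numeric"))

setValidity("WaveformIndices", function(object) {
  msg <- character()
  chk1 <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x)) c(sprintf("%s must be a finite scalar", nm))
    else character()
  }
  for (nm in c("meanMbr", "bot", "bos", "skew", "ati", "rr", "fr", "fai", "ri"))
    msg <- c(msg, chk1(slot(object, nm), nm))
  if (!length(msg)) {
    if (object@meanMbr <= 0) msg <- c(msg, "meanMbr must be > 0")
    if (object@bot < 0 || object@bot > 100) msg <- c(msg, "bot must be in [0, 100]")
    if (object@bos < 0 || object@bos > 100) msg <- c(msg, "bos must be in [0, 100]")
    if (object@ati < 0 || object@ati > 100) msg <- c(msg, "ati must be in [0, 100]")
    if (object@ri < 0 || object@ri > 1) msg <- c(msg, "ri must be in [0, 1]")
    if (object@fai < 0) msg <- c(msg, "fai must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' SubjectProfile: generative parameters of one synthetic subject
#'
#' The physiological parameters from which a subject's MBR waveform and
#' systemic covariates are generated: a Windkessel-style pulse shape
#' (diastolic floor, systolic amplitude, rise fraction, diastolic decay time
#' constant) plus blood pressure, heart rate, intraocular pressure and the
#' noise scales of repeated scans.
#'
#' @slot subjectId opaque identifier.
#' @slot age years, in [18, 80].
#' @slot sex \code{"male"} or \code{"female"}.
#' @slot heartRate beats per minute, in [40, 120].
#' @slot mbrBaseline diastolic floor of tissue MBR (AU).
#' @slot pulseAmplitude systolic rise above the floor (AU, > 0 unless the
#'   degenerate flat waveform is wanted).
#' @slot systolicRiseFraction fraction of the cycle before the peak (0, 0.5).
#' @slot diastolicDecayTau diastolic decay time constant (seconds, > 0).
#' @slot sbp systolic blood pressure (mmHg).
#' @slot dbp diastolic blood pressure (mmHg), < sbp.
#' @slot iop intraocular pressure (mmHg).
#' @slot measurementNoiseSd within-scan additive noise SD (AU, >= 0).
#' @slot betweenScanSd scan-to-scan level shift SD (AU, >= 0).
#' @exportClass SubjectProfile
setClass("SubjectProfile",
  slots = c(subjectId = "character", age = "numeric", sex = "character",
            heartRate = "numeric", mbrBaseline = "numeric",
            pulseAmplitude = "numeric", systolicRiseFraction = "numeric",
            diastolicDecayTau = "numeric", sbp = "numeric", dbp = "numeric",
            iop = "numeric", measurementNoiseSd = "numeric",
            betweenScanSd = "numeric"))

setValidity("SubjectProfile", function(object) {
  msg <- character()
  if (object@age < 18 || object@age > 80)
    msg <- c(msg, "age must be in [18, 80]")
  if (!object@sex %in% c("male", "female"))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (object@heartRate < .HR_MIN || object@heartRate > .HR_MAX)
    msg <- c(msg, sprintf("heartRate must be in [%d, %d]", .HR_MIN, .HR_MAX))
  if (object@mbrBaseline <= 0) msg <- c(msg, "mbrBaseline must be > 0")
  if (object@pulseAmplitude < 0) msg <- c(msg, "pulseAmplitude must be >= 0")
  if (object@systolicRiseFraction <= 0 || object@systolicRiseFraction >= 0.5)
    msg <- c(msg, "systolicRiseFraction must be in (0, 0.5)")
  if (object@diastolicDecayTau <= 0)
    msg <- c(msg, "diastolicDecayTau must be > 0")
  if (!(object@sbp > object@dbp && object@dbp > 0))
    msg <- c(msg, "need sbp > dbp > 0")
  if (object@iop < 0) msg <- c(msg, "iop must be >= 0")
  if (object@measurementNoiseSd < 0 || object@betweenScanSd < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' EllipseRoi: the ellipsoid optic-nerve-head region of interest
#'
#' The ONH margin is delineated on the composite map by an ellipse with
#' variable centre, semi-axes and rotation; the same ROI is re-applied to all
#' repeat scans of a subject.
#'
#' @slot center (x, y) centre in pixel coordinates.
#' @slot semiAxes (a, b) semi-axes in pixels, both > 0.
#' @slot rotation rotation in degrees (counter-clockwise).
#' @exportClass EllipseRoi
setClass("EllipseRoi",
  slots = c(center = "numeric", semiAxes = "numeric", rotation = "numeric"),
  prototype = prototype(rotation = 0))

setValidity("EllipseRoi", function(object) {
  msg <- character()
  if (length(object@center) != 2 || any(!is.finite(object@center)))
    msg <- c(msg, "center must be (x, y)")
  if (length(object@semiAxes) != 2 || any(object@semiAxes <= 0))
    msg <- c(msg, "semiAxes must be two positive numbers")
  if (length(object@rotation) != 1 || !is.finite(object@rotation))
    msg <- c(msg, "rotation must be a single number (degrees)")
  if (length(msg)) msg else TRUE
})

#' Construct an EllipseRoi
#'
#' @param center (x, y) centre, pixels.
#' @param semiAxes (a, b) semi-axes, pixels.
#' @param rotation degrees counter-clockwise.
#' @return An \linkS4class{EllipseRoi}.
#' @export
EllipseRoi <- function(center, semiAxes, rotation = 0) {
  new("EllipseRoi", center = as.numeric(center),
      semiAxes = as.numeric(semiAxes), rotation = as.numeric(rotation))
}

#' GroundTruthScene: geometry and flow scales of a synthetic fundus scene
#'
#' Ground truth for segmentation tests: the ONH ellipse, the binary surface
#' vessel mask inside it, and the tissue and vessel flow scales. Vessels
#' carry higher MBR than tissue by construction.
#'
#' @slot roi the ONH \linkS4class{EllipseRoi}.
#' @slot vesselMask logical matrix (rows = image rows), TRUE = surface vessel.
#' @slot tissueFlowScale mean tissue MBR level (AU, > 0).
#' @slot vesselFlowScale mean vessel MBR level (AU, > tissueFlowScale).
#' @exportClass GroundTruthScene
setClass("GroundTruthScene",
  slots = c(roi = "EllipseRoi", vesselMask = "matrix",
            tissueFlowScale = "numeric", vesselFlowScale = "numeric"))

setValidity("GroundTruthScene", function(object) {
  msg <- character()
  if (!is.logical(object@vesselMask))
    msg <- c(msg, "vesselMask must be a logical matrix")
  if (!(object@vesselFlowScale > object@tissueFlowScale &&
        object@tissueFlowScale > 0))
    msg <- c(msg, "need vesselFlowScale > tissueFlowScale > 0")
  ext <- .ellipseExtent(object@roi)
  h <- nrow(object@vesselMask); w <- ncol(object@vesselMask)
  if (ext["xmin"] < 0.5 || ext["ymin"] < 0.5 ||
      ext["xmax"] > w + 0.5 || ext["ymax"] > h + 0.5)
    msg <- c(msg, "ROI ellipse must lie fully inside the frame")
  if (length(msg)) msg else TRUE
})

#' FlowMapStack: a stack of two-dimensional MBR flow maps
#'
#' The frame sequence of one LSFG scan: per-pixel MBR maps acquired at a
#' fixed frame rate. Stored as a (height, width, frames) array.
#'
#' @slot frames numeric array, dim = (height, width, nFrames), values >= 0.
#' @slot frameRate frames per second (default 30).
#' @slot exposure exposure time per frame in seconds (metadata).
#' @exportClass FlowMapStack
setClass("FlowMapStack",
  slots = c(frames = "array", frameRate = "numeric", exposure = "numeric"),
  prototype = prototype(frameRate = 30, exposure = 1 / 500))

setValidity("FlowMapStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3)
    msg <- c(msg, "frames must be a (height, width, nFrames) array")
  else if (dim(object@frames)[3] < 2)
    msg <- c(msg, "need at least 2 frames")
  if (any(object@frames < 0)) msg <- c(msg, "MBR values must be >= 0")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' CompositeMap: per-pixel mean MBR over one cardiac cycle
#'
#' The composite map: the time average of each pixel of a
#' \linkS4class{FlowMapStack} over the complete detected cardiac cycles,
#' depicting the distribution of mean blood flow.
#'
#' @slot values numeric matrix (AU), same shape as the source frames.
#' @exportClass CompositeMap
setClass("CompositeMap", slots = c(values = "matrix"))

setValidity("CompositeMap", function(object) {
  if (any(object@values < 0)) "composite map values must be >= 0" else TRUE
})

#' OnhMeasurement: regional mean MBR of one composite map
#'
#' MA (whole ONH area), MV (vessel area) and MT (tissue area) mean MBR, plus
#' the vessel area fraction and the automatic threshold that produced the
#' vessel/tissue split. The exact decomposition
#' \code{ma = f * mv + (1 - f) * mt} holds with \code{f = vesselFraction}.
#'
#' @slot ma mean MBR of the whole ONH area (AU).
#' @slot mv mean MBR of the vessel area (AU).
#' @slot mt mean MBR of the tissue area (AU).
#' @slot vesselFraction vessel pixel fraction of the ROI, in (0, 1).
#' @slot threshold the automatic MBR threshold (AU).
#' @exportClass OnhMeasurement
setClass("OnhMeasurement",
  slots = c(ma = "numeric", mv = "numeric", mt = "numeric",
            vesselFraction = "numeric", threshold = "numeric"))

setValidity("OnhMeasurement", function(object) {
  msg <- character()
  if (object@mv < object@mt)
    msg <- c(msg, "mv must be >= mt (vessels carry higher MBR)")
  if (object@ma < min(object@mv, object@mt) - 1e-9 ||
      object@ma > max(object@mv, object@mt) + 1e-9)
    msg <- c(msg, "ma must lie between mt and mv")
  if (object@vesselFraction <= 0 || object@vesselFraction >= 1)
    msg <- c(msg, "vesselFraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' CohortDataset: the long-format study table
#'
#' One row per (subject, condition, repeat) scan with the per-scan waveform
#' indices, regional MBR and per-subject systemic covariates. The derived
#' hemodynamic quantities MAP/PPA/OPP are not stored but computed on demand
#' by \code{\link{derivedHemodynamics}}.
#'
#' @slot tbl data.frame with exactly the columns
#'   \code{subject_id, age, sex, sbp, dbp, hr, iop, condition, repeat,
#'   scan_success, MA, MV, MT, BOT, BOS, Skew, ATI, RR, FR, FAI, RI}.
#' @exportClass CohortDataset
setClass("CohortDataset", slots = c(tbl = "data.frame"))

setValidity("CohortDataset", function(object) {
  tbl <- object@tbl
  msg <- character()
  missing <- setdiff(.COHORT_COLUMNS, names(tbl))
  if (length(missing))
    msg <- c(msg, paste("missing column(s):", paste(missing, collapse = ", ")))
  extra <- setdiff(names(tbl), .COHORT_COLUMNS)
  if (length(extra))
    msg <- c(msg, paste("unknown column(s):", paste(extra, collapse = ", ")))
  if (!length(msg) && nrow(tbl)) {
    if (!all(tbl$condition %in% c("undilated", "dilated")))
      msg <- c(msg, "condition must be 'undilated' or 'dilated'")
    cnt <- table(tbl$subject_id, tbl$condition)
    if (any(cnt > 3))
      msg <- c(msg, "at most 3 repeats per (subject, condition)")
    if (!is.logical(tbl$scan_success))
      msg <- c(msg, "scan_success must be logical")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortDataset from a data.frame
#'
#' @param tbl data.frame with the cohort schema (see
#'   \linkS4class{CohortDataset}).
#' @return A \linkS4class{CohortDataset}.
#' @export
CohortDataset <- function(tbl) {
  new("CohortDataset", tbl = as.data.frame(tbl, check.names = FALSE))
}
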