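#' Accessor generics
#'
#' Small accessor generics for the package's data classes: \code{mbrValues}
#' (raw samples or phase values), \code{frameRate}, \code{nCycles},
#' \code{cycleBoundaries}, \code{nPhaseBins}, \code{cycleDuration},
#' \code{cohortTable} and \code{mapValues}.
#'
#' @param object an object of one of the package's classes.
#' @return The accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mbrValues", function(object) standardGeneric("mbrValues"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("cycleBoundaries", function(object) standardGeneric("cycleBoundaries"))

#' @rdname accessors
#' @export
setGeneric("nCycles", function(object) standardGeneric("nCycles"))

#' @rdname accessors
#' @export
setGeneric("nPhaseBins", function(object) standardGeneric("nPhaseBins"))

#' @rdname accessors
#' @export
setGeneric("cycleDuration", function(object) standardGeneric("cycleDuration"))

#' @rdname accessors
#' @export
setGeneric("cohortTable", function(object) standardGeneric("cohortTable"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setMethod("mbrValues", "MbrSeries", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("mbrValues", "PulseCycle", function(object) object@phaseValues)

#' @rdname accessors
#' @export
setMethod("frameRate", "MbrSeries", function(object) object@frameRate)

#' @rdname accessors
#' @export
setMethod("frameRate", "FlowMapStack", function(object) object@frameRate)

#' @rdname accessors
#' @export
setMethod("cycleBoundaries", "CycleSegmentation",
          function(object) object@boundaries)

#' @rdname accessors
#' @export
setMethod("nCycles", "CycleSegmentation",
          function(object) length(object@boundaries) - 1L)

#' @rdname accessors
#' @export
setMethod("nPhaseBins", "PulseCycle",
          function(object) length(object@phaseValues))

#' @rdname accessors
#' @export
setMethod("cycleDuration", "PulseCycle", function(object) object@cycleDuration)

#' @rdname accessors
#' @export
setMethod("cohortTable", "CohortDataset", function(object) object@tbl)

#' @rdname accessors
#' @export
setMethod("mapValues", "CompositeMap", function(object) object@values)

#' Coerce WaveformIndices to a one-row data.frame
#'
#' Columns follow the cohort index order \code{MA/MV/MT} excluded:
#' \code{meanMbr, BOT, BOS, Skew, ATI, RR, FR, FAI, RI}.
#'
#' @param x a \linkS4class{WaveformIndices}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return A one-row data.frame.
#' @export
as.data.frame.WaveformIndices <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(meanMbr = x@meanMbr, BOT = x@bot, BOS = x@bos, Skew = x@skew,
             ATI = x@ati, RR = x@rr, FR = x@fr, FAI = x@fai, RI = x@ri)
}

setMethod("show", "MbrSeries", function(object) {
  cat(sprintf("MbrSeries '%s' (%s): %d samples @ %.4g fps, MBR %.3g-%.3g AU\n",
              object@scanId, object@regionLabel, length(object@values),
              object@frameRate, min(object@values), max(object@values)))
})

setMethod("show", "CycleSegmentation", function(object) {
  cat(sprintf("CycleSegmentation: %d complete cycle(s), boundaries %s\n",
              length(object@boundaries) - 1L,
              paste(object@boundaries, collapse = ", ")))
})

setMethod("show", "PulseCycle", function(object) {
  cat(sprintf(
    "PulseCycle: %d phase bins, duration %.3f s, MBR %.3g-%.3g AU\n",
    length(object@phaseValues), object@cycleDuration,
    min(object@phaseValues), max(object@phaseValues)))
})

setMethod("show", "WaveformIndices", function(object) {
  cat("WaveformIndices\n")
  df <- as.data.frame(object)
  print(round(df, 3), row.names = FALSE)
})

setMethod("show", "SubjectProfile", function(object) {
  cat(sprintf(
    paste0("SubjectProfile '%s': %s, %.0f y, HR %.0f bpm\n",
           "  waveform: baseline %.2f AU, amplitude %.2f AU, rise %.3f,",
           " tau %.3f s\n  SBP/DBP %.0f/%.0f mmHg, IOP %.1f mmHg\n"),
    object@subjectId, object@sex, object@age, object@heartRate,
    object@mbrBaseline, object@pulseAmplitude, object@systolicRiseFraction,
    object@diastolicDecayTau, object@sbp, object@dbp, object@iop))
})

setMethod("show", "FlowMapStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FlowMapStack: %d frames of %d x %d px @ %.4g fps\n",
              d[3], d[1], d[2], object@frameRate))
})

setMethod("show", "CompositeMap", function(object) {
  cat(sprintf("CompositeMap: %d x %d px, MBR %.3g-%.3g AU\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "OnhMeasurement", function(object) {
  cat(sprintf(
    "OnhMeasurement: MA %.2f, MV %.2f, MT %.2f AU (vessel fraction %.3f, threshold %.2f)\n",
    object@ma, object@mv, object@mt, object@vesselFraction, object@threshold))
})

setMethod("show", "CohortDataset", function(object) {
  tbl <- object@tbl
  cat(sprintf("CohortDataset: %d scan rows, %d subject(s), conditions: %s\n",
              nrow(tbl), length(unique(tbl$subject_id)),
              paste(unique(tbl$condition), collapse = ", ")))
})

setMethod("show", "GroundTruthScene", function(object) {
  cat(sprintf(
    "GroundTruthScene: %d x %d px, vessel fraction (ROI) %.3f, scales %.3g/%.3g AU\n",
    nrow(object@vesselMask), ncol(object@vesselMask),
    {
      m <- .ellipseMask(nrow(object@vesselMask), ncol(object@vesselMask),
                        object@roi)
      sum(object@vesselMask & m) / sum(m)
    },
    object@tissueFlowScale, object@vesselFlowScale))
})

setMethod("show", "EllipseRoi", function(object) {
  cat(sprintf("EllipseRoi: center (%.1f, %.1f), semi-axes (%.1f, %.1f), rotation %.1f deg\n",
              object@center[1], object@center[2], object@semiAxes[1],
              object@semiAxes[2], object@rotation))
})
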