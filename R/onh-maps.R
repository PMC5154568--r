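## Composite-map construction, ellipsoid ROI, vessel extraction and the
## regional mean MBR triple (MA / MV / MT).

## Axis-aligned bounding box of a rotated ellipse in pixel coordinates.
.ellipseExtent <- function(roi) {
  th <- roi@rotation * pi / 180
  a <- roi@semiAxes[1]; b <- roi@semiAxes[2]
  hw <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  hh <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  c(xmin = roi@center[1] - hw, xmax = roi@center[1] + hw,
    ymin = roi@center[2] - hh, ymax = roi@center[2] + hh)
}

## Center-of-pixel, boundary-inclusive ellipse membership test.
## Pixel (row i, col j) has centre (x = j, y = i).
.ellipseMask <- function(h, w, roi) {
  th <- roi@rotation * pi / 180
  x <- matrix(seq_len(w), h, w, byrow = TRUE) - roi@center[1]
  y <- matrix(seq_len(h), h, w) - roi@center[2]
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  (xr / roi@semiAxes[1])^2 + (yr / roi@semiAxes[2])^2 <= 1
}

#' Mean MBR time series of a flow-map stack
#'
#' Collapses each frame to the mean MBR over the frame (or over a pixel
#' mask), yielding the scan-level series on which cardiac cycles are
#' detected before compositing.
#'
#' @param stack a \linkS4class{FlowMapStack}.
#' @param mask optional logical matrix restricting the per-frame mean.
#' @param regionLabel region label for the resulting series.
#' @return An \linkS4class{MbrSeries}.
#' @export
stackMeanSeries <- function(stack, mask = NULL, regionLabel = "all") {
  stopifnot(is(stack, "FlowMapStack"))
  d <- dim(stack@frames)
  if (is.null(mask)) {
    v <- colMeans(matrix(stack@frames, d[1] * d[2], d[3]))
  } else {
    stopifnot(identical(dim(mask), d[1:2]))
    m <- matrix(stack@frames, d[1] * d[2], d[3])[as.vector(mask), , drop = FALSE]
    v <- colMeans(m)
  }
  MbrSeries(v, frameRate = stack@frameRate, scanId = "stack",
            regionLabel = regionLabel)
}

#' Composite map over complete cardiac cycles
#'
#' Averages each pixel over the frames belonging to the complete detected
#' cardiac cycles only (frames before the first and after the last detected
#' trough are discarded), producing the composite map of mean blood-flow
#' distribution during one cardiac cycle.
#'
#' @param stack a \linkS4class{FlowMapStack}.
#' @param seg a \linkS4class{CycleSegmentation} obtained from the stack's
#'   mean series (see \code{\link{stackMeanSeries}} and
#'   \code{\link{detectCycles}}).
#' @return A \linkS4class{CompositeMap}.
#' @examples
#' scene <- makeScene(height = 60, width = 80, seed = 1)
#' prof <- simulateSubject(age = 40, sex = "female", seed = 1)
#' st <- generateFlowMapStack(prof, scene, nFrames = 60, frameRate = 30,
#'                            seed = 1, noiseSd = 0)
#' seg <- detectCycles(stackMeanSeries(st))
#' cm <- compositeMap(st, seg)
#' @export
compositeMap <- function(stack, seg) {
  stopifnot(is(stack, "FlowMapStack"), is(seg, "CycleSegmentation"))
  b <- seg@boundaries
  if (length(b) < 2)
    stop("no complete cardiac cycle: cannot build a composite map")
  idx <- seq.int(b[1], b[length(b)] - 1L)  # half-open [first, last)
  d <- dim(stack@frames)
  if (max(idx) > d[3]) stop("segmentation indexes beyond the stack")
  m <- matrix(stack@frames, d[1] * d[2], d[3])
  new("CompositeMap",
      values = matrix(rowMeans(m[, idx, drop = FALSE]), d[1], d[2]))
}

#' Ellipsoid region-of-interest mask
#'
#' Marks every pixel whose centre lies inside (boundary inclusive) the
#' rotated ellipse delineating the ONH margin. Errors if the ellipse is not
#' fully inside the frame.
#'
#' @param map a \linkS4class{CompositeMap} (or a numeric matrix).
#' @param roi an \linkS4class{EllipseRoi}.
#' @return A logical matrix of the map's shape.
#' @export
roiMask <- function(map, roi) {
  vals <- if (is(map, "CompositeMap")) map@values else as.matrix(map)
  stopifnot(is(roi, "EllipseRoi"))
  h <- nrow(vals); w <- ncol(vals)
  ext <- .ellipseExtent(roi)
  if (ext["xmin"] < 0.5 || ext["ymin"] < 0.5 ||
      ext["xmax"] > w + 0.5 || ext["ymax"] > h + 0.5)
    stop("ROI ellipse extends outside the frame")
  .ellipseMask(h, w, roi)
}

#' Automatic vessel extraction by intensity thresholding
#'
#' Splits the in-ROI composite-map intensity distribution into visible
#' surface vessels (high MBR) and ONH tissue (low MBR) with an automatically
#' chosen threshold. The default method is Otsu's between-class-variance
#' threshold on the in-ROI values; a fixed-percentile threshold is available
#' as an alternative. Vessel pixels are those with value strictly above the
#' threshold.
#'
#' @param map a \linkS4class{CompositeMap}.
#' @param mask logical ROI mask (from \code{\link{roiMask}}).
#' @param method \code{"otsu"} (default) or \code{"percentile"}.
#' @param percentile quantile used when \code{method = "percentile"}.
#' @return A list with \code{vesselMask} (logical matrix) and
#'   \code{threshold} (AU).
#' @export
extractVessels <- function(map, mask, method = c("otsu", "percentile"),
                           percentile = 0.75) {
  stopifnot(is(map, "CompositeMap"), is.logical(mask),
            identical(dim(mask), dim(map@values)))
  method <- match.arg(method)
  vals <- map@values[mask]
  if (length(vals) == 0) stop("empty ROI mask")
  rng <- range(vals)
  if (diff(rng) <= 0)
    stop("no vessel/tissue contrast: all in-ROI values are equal")
  thr <- switch(method,
    otsu = {
      # Otsu on the in-ROI histogram, normalized to [0, 1] over the data
      # range so the threshold is translation- and scale-equivariant.
      z <- (vals - rng[1]) / diff(rng)
      t01 <- EBImage::otsu(EBImage::Image(matrix(z, nrow = 1)),
                           range = c(0, 1))
      rng[1] + t01 * diff(rng)
    },
    percentile = as.numeric(stats::quantile(vals, percentile)))
  vesselMask <- mask & (map@values > thr)
  if (!any(vesselMask) || !any(mask & !vesselMask))
    stop("degenerate threshold: vessel or tissue class is empty")
  list(vesselMask = vesselMask, threshold = thr)
}

#' Regional mean MBR: MA, MV and MT
#'
#' Mean MBR over the whole ONH area (MA), its vessel area (MV) and its
#' tissue area (MT = ROI minus vessels). The exact weighted-mean identity
#' \code{ma = f * mv + (1 - f) * mt} holds with \code{f} the vessel pixel
#' fraction.
#'
#' @param map a \linkS4class{CompositeMap}.
#' @param mask logical ROI mask.
#' @param vesselMask logical vessel mask (subset of \code{mask}).
#' @param threshold the threshold that produced \code{vesselMask}
#'   (stored in the result; default NA).
#' @return An \linkS4class{OnhMeasurement}.
#' @export
regionalMbr <- function(map, mask, vesselMask, threshold = NA_real_) {
  stopifnot(is(map, "CompositeMap"), is.logical(mask), is.logical(vesselMask),
            identical(dim(mask), dim(map@values)),
            identical(dim(vesselMask), dim(map@values)))
  if (any(vesselMask & !mask)) stop("vesselMask must be a subset of the ROI")
  tissue <- mask & !vesselMask
  if (!any(vesselMask)) stop("empty vessel class")
  if (!any(tissue)) stop("empty tissue class")
  mv <- mean(map@values[vesselMask])
  mt <- mean(map@values[tissue])
  ma <- mean(map@values[mask])
  f <- sum(vesselMask) / sum(mask)
  new("OnhMeasurement", ma = ma, mv = max(mv, mt), mt = min(mv, mt),
      vesselFraction = f, threshold = as.numeric(threshold))
}

#' Analyse a flow-map stack end to end
#'
#' Convenience wrapper: mean series -> cycle detection -> composite map ->
#' ROI -> vessel extraction -> MA/MV/MT.
#'
#' @param stack a \linkS4class{FlowMapStack}.
#' @param roi an \linkS4class{EllipseRoi}.
#' @param method threshold method, see \code{\link{extractVessels}}.
#' @return A list with \code{measurement} (\linkS4class{OnhMeasurement}),
#'   \code{map}, \code{mask}, \code{vesselMask}, \code{segmentation}.
#' @export
analyzeStack <- function(stack, roi, method = "otsu") {
  seg <- detectCycles(stackMeanSeries(stack))
  cm <- compositeMap(stack, seg)
  mask <- roiMask(cm, roi)
  vx <- extractVessels(cm, mask, method = method)
  list(measurement = regionalMbr(cm, mask, vx$vesselMask, vx$threshold),
       map = cm, mask = mask, vesselMask = vx$vesselMask, segmentation = seg)
}

#' Build a synthetic ground-truth fundus scene
#'
#' Constructs the geometry of a synthetic ONH scene: the ellipsoid ROI
#' centred in the frame and a branching pattern of straight vessel bands
#' crossing it. Ground truth for segmentation tests; the vessel fraction
#' inside the ROI lands near the requested target.
#'
#' @param height,width frame size in pixels (LSFG sensor default 360 x 750).
#' @param semiAxes ROI semi-axes; default a quarter of the frame dimensions.
#' @param rotation ROI rotation, degrees.
#' @param nVessels number of vessel bands.
#' @param vesselWidth band half-width, pixels.
#' @param tissueFlowScale,vesselFlowScale mean MBR levels (AU); vessels must
#'   exceed tissue.
#' @param seed integer seed controlling the band placement.
#' @return A \linkS4class{GroundTruthScene}.
#' @export
makeScene <- function(height = 360, width = 750, semiAxes = NULL,
                      rotation = 0, nVessels = 5, vesselWidth = 3,
                      tissueFlowScale = 10, vesselFlowScale = 34,
                      seed = 1) {
  if (is.null(semiAxes)) semiAxes <- c(width, height) / 4
  roi <- EllipseRoi(center = c((width + 1) / 2, (height + 1) / 2),
                    semiAxes = semiAxes, rotation = rotation)
  vessel <- matrix(FALSE, height, width)
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  y <- matrix(seq_len(height), height, width)
  .withSeed(seed, {
    for (k in seq_len(nVessels)) {
      # band through a point near the ROI centre at a random angle
      th <- stats::runif(1, 0, pi)
      px <- roi@center[1] + stats::runif(1, -0.3, 0.3) * semiAxes[1]
      py <- roi@center[2] + stats::runif(1, -0.3, 0.3) * semiAxes[2]
      d <- abs((x - px) * sin(th) - (y - py) * cos(th))
      vessel <- vessel | (d <= vesselWidth)
    }
  })
  new("GroundTruthScene", roi = roi, vesselMask = vessel,
      tissueFlowScale = tissueFlowScale, vesselFlowScale = vesselFlowScale)
}
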