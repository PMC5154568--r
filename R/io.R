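## Interchange helpers: ellipse ROI as JSON, MBR series as delimited text,
## flow-map stacks as a flat array file with a JSON sidecar.

#' Read / write an ellipse ROI as JSON
#'
#' The ROI interchange format is a flat JSON object
#' \code{{cx, cy, a, b, rot_deg}} in pixel coordinates.
#'
#' @param path JSON path.
#' @return \code{readRoiJson}: an \linkS4class{EllipseRoi}.
#' @export
readRoiJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("cx", "cy", "a", "b")
  if (!all(need %in% names(j)))
    stop("ROI JSON must contain cx, cy, a, b (and optionally rot_deg)")
  EllipseRoi(center = c(j$cx, j$cy), semiAxes = c(j$a, j$b),
             rotation = if (is.null(j$rot_deg)) 0 else j$rot_deg)
}

#' @rdname readRoiJson
#' @param roi an \linkS4class{EllipseRoi}.
#' @export
writeRoiJson <- function(roi, path) {
  stopifnot(is(roi, "EllipseRoi"))
  jsonlite::write_json(
    list(cx = roi@center[1], cy = roi@center[2],
         a = roi@semiAxes[1], b = roi@semiAxes[2], rot_deg = roi@rotation),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write an MBR series as delimited text
#'
#' Two-column tab-separated text (frame_index, mbr_au) with a
#' \code{# frame_rate:} header comment carrying the acquisition rate.
#'
#' @param path file path.
#' @return \code{readMbrSeries}: an \linkS4class{MbrSeries}.
#' @export
readMbrSeries <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  fr <- 30
  m <- regmatches(hdr, regexec("frame_rate:\\s*([0-9.]+)", hdr))
  for (g in m) if (length(g) == 2) fr <- as.numeric(g[2])
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t")
  MbrSeries(tab[[2]], frameRate = fr)
}

#' @rdname readMbrSeries
#' @param series an \linkS4class{MbrSeries}.
#' @export
writeMbrSeries <- function(series, path) {
  stopifnot(is(series, "MbrSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate: %g", series@frameRate), con)
  utils::write.table(
    data.frame(frame_index = seq_along(series@values) - 1L,
               mbr_au = series@values),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a flow-map stack
#'
#' The stack is persisted as a flat little-endian double array (row-major
#' by frame) with a JSON sidecar (\code{<path>.json}) recording the
#' dimensions, frame rate and exposure.
#'
#' @param path array file path.
#' @return \code{readFlowMapStack}: a \linkS4class{FlowMapStack}.
#' @export
readFlowMapStack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(side$dim)
  v <- readBin(path, what = "double", n = n, endian = "little")
  new("FlowMapStack", frames = array(v, dim = side$dim),
      frameRate = side$frame_rate, exposure = side$exposure)
}

#' @rdname readFlowMapStack
#' @param stack a \linkS4class{FlowMapStack}.
#' @export
writeFlowMapStack <- function(stack, path) {
  stopifnot(is(stack, "FlowMapStack"))
  writeBin(as.vector(stack@frames), path, endian = "little")
  jsonlite::write_json(
    list(dim = dim(stack@frames), frame_rate = stack@frameRate,
         exposure = stack@exposure),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
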