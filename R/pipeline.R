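## Pipeline orchestration and file interchange: configuration bundle,
## cohort-level report tables, CSV round trip, and the simulate -> analyze
## -> report driver.

#' Statistics configuration
#'
#' @param ... named overrides. Defaults: \code{iccForm = "icc3"},
#'   \code{yates = FALSE} (uncorrected chi-square), \code{alpha = 0.05},
#'   \code{mapFormula = "standard"}, \code{varEqual = TRUE} (pooled-variance
#'   independent t-test). Unknown keys are rejected. No multiple-testing
#'   correction is applied anywhere (each test is reported at its nominal
#'   p-value).
#' @return A named list of statistics settings.
#' @export
statisticsConfig <- function(...) {
  cfg <- list(iccForm = "icc3", yates = FALSE, alpha = 0.05,
              mapFormula = "standard", varEqual = TRUE)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("statisticsConfig overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown statistics setting(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Pipeline configuration bundle
#'
#' Bundles the generator, waveform and statistics settings together with
#' the cohort size. Every setting has a documented default; unknown keys
#' are rejected by the component constructors.
#'
#' @param generator a \code{\link{generatorConfig}} list.
#' @param waveform a \code{\link{waveformConfig}} list.
#' @param statistics a \code{\link{statisticsConfig}} list.
#' @param nPerCell subjects per (age group x sex) cell (default 10).
#' @param repeats scans per condition (default 3).
#' @return A named list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(generator = generatorConfig(),
                           waveform = waveformConfig(),
                           statistics = statisticsConfig(),
                           nPerCell = 10, repeats = 3) {
  structure(list(generator = generator, waveform = waveform,
                 statistics = statistics, nPerCell = nPerCell,
                 repeats = repeats), class = "pipelineConfig")
}

## Per-subject means of the successful scans of one condition, joined with
## the per-subject covariates (and derived PPA).
.subjectMeans <- function(cohort, condition, mapFormula = "standard") {
  tbl <- cohortTable(cohort)
  tbl <- tbl[tbl$condition == condition & tbl$scan_success, , drop = FALSE]
  if (!nrow(tbl)) stop("no successful scans for condition ", condition)
  ids <- unique(tbl$subject_id)
  agg <- stats::aggregate(tbl[.INDEX_COLUMNS],
                          by = list(subject_id = tbl$subject_id), mean)
  cov <- unique(tbl[c("subject_id", "age", "sex", "sbp", "dbp", "hr", "iop")])
  out <- merge(cov, agg, by = "subject_id")
  hd <- derivedHemodynamics(out$sbp, out$dbp, out$iop,
                            mapFormula = mapFormula)
  out$map <- hd$map; out$ppa <- hd$ppa; out$opp <- hd$opp
  out[order(out$subject_id), , drop = FALSE]
}

#' Per-index repeatability table (COV and ICC)
#'
#' For every waveform index and pupil condition: the coefficient of
#' variation and the ANOVA-based intraclass correlation of the repeated
#' scans. Subjects with any unsuccessful or missing repeat in a condition
#' are dropped from that condition's computation.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param form ICC form, see \code{\link{intraclassCorrelation}}.
#' @return A data.frame with columns \code{index, condition, cov, icc,
#'   nSubjects, nRepeats}.
#' @export
repeatabilityTable <- function(cohort, form = "icc3") {
  tbl <- cohortTable(cohort)
  out <- list()
  for (cond in unique(tbl$condition)) {
    sub <- tbl[tbl$condition == cond, , drop = FALSE]
    k <- max(sub[["repeat"]])
    for (ix in .INDEX_COLUMNS) {
      m <- stats::reshape(
        sub[c("subject_id", "repeat", ix)],
        idvar = "subject_id", timevar = "repeat", direction = "wide")
      mm <- as.matrix(m[, -1, drop = FALSE])
      mm <- mm[stats::complete.cases(mm), , drop = FALSE]
      icc <- intraclassCorrelation(mm, form = form)
      out[[length(out) + 1]] <- data.frame(
        index = ix, condition = cond,
        cov = coefficientOfVariation(mm), icc = icc$icc,
        nSubjects = nrow(mm), nRepeats = k)
    }
  }
  do.call(rbind, out)
}

#' Per-index association table (Pearson r with age and PPA)
#'
#' Correlates each waveform index with subject age and pulse pressure
#' amplitude, using the per-subject mean of the successful scans of the
#' chosen condition (by convention the mydriatic scans).
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param condition which condition's means to use (default "dilated").
#' @param covariates covariate columns (default age and derived ppa).
#' @param mapFormula passed to \code{\link{derivedHemodynamics}}.
#' @return A data.frame with columns \code{index, covariate, r, p, slope,
#'   intercept, n}.
#' @export
associationTable <- function(cohort, condition = "dilated",
                             covariates = c("age", "ppa"),
                             mapFormula = "standard") {
  sm <- .subjectMeans(cohort, condition, mapFormula = mapFormula)
  out <- list()
  for (cv in covariates) for (ix in .INDEX_COLUMNS) {
    # a degenerate (zero-variance) index yields an NA row, not an abort
    a <- tryCatch(associationTest(sm[[cv]], sm[[ix]]), error = function(e)
      list(r = NA_real_, p = NA_real_, slope = NA_real_,
           intercept = NA_real_, n = sum(stats::complete.cases(sm[[cv]],
                                                               sm[[ix]]))))
    out[[length(out) + 1]] <- data.frame(
      index = ix, covariate = cv, r = a$r, p = a$p, slope = a$slope,
      intercept = a$intercept, n = a$n)
  }
  do.call(rbind, out)
}

#' Paired dilation comparison per index
#'
#' Paired t-test of each index before versus after pupil dilation, on the
#' per-subject means of successful scans; only subjects successful in both
#' conditions contribute.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @return A data.frame with columns \code{index, meanBefore, meanAfter,
#'   meanDiff, t, df, p, n}.
#' @export
dilationComparison <- function(cohort) {
  before <- .subjectMeans(cohort, "undilated")
  after <- .subjectMeans(cohort, "dilated")
  ids <- intersect(before$subject_id, after$subject_id)
  b <- before[match(ids, before$subject_id), ]
  a <- after[match(ids, after$subject_id), ]
  out <- lapply(.INDEX_COLUMNS, function(ix) {
    pc <- pairedComparison(b[[ix]], a[[ix]])
    data.frame(index = ix, meanBefore = pc$meanBefore,
               meanAfter = pc$meanAfter, meanDiff = pc$meanDiff,
               t = pc$t, df = pc$df, p = pc$p, n = pc$n)
  })
  do.call(rbind, out)
}

#' Sex comparison per index
#'
#' Independent-samples t-test of each index between male and female
#' subjects, on the per-subject means of the chosen condition.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param condition which condition's means to use (default "dilated").
#' @param varEqual pooled variance if TRUE.
#' @return A data.frame with columns \code{index, meanMale, meanFemale,
#'   meanDiff, t, df, p}.
#' @export
sexComparison <- function(cohort, condition = "dilated", varEqual = TRUE) {
  sm <- .subjectMeans(cohort, condition)
  out <- lapply(.INDEX_COLUMNS, function(ix) {
    gc <- groupComparison(sm[[ix]][sm$sex == "male"],
                          sm[[ix]][sm$sex == "female"], varEqual = varEqual)
    data.frame(index = ix, meanMale = gc$meanA, meanFemale = gc$meanB,
               meanDiff = gc$meanDiff, t = gc$t, df = gc$df, p = gc$p)
  })
  do.call(rbind, out)
}

#' Scan success-rate summary and chi-square comparison
#'
#' Counts successful scans per condition and compares the undilated and
#' dilated success rates with the (by default uncorrected) chi-square test.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param correct Yates' continuity correction (default FALSE).
#' @return A list with \code{counts} (data.frame per condition) and
#'   \code{test} (see \code{\link{successRateTest}}), or counts only if a
#'   single condition is present.
#' @export
successRateSummary <- function(cohort, correct = FALSE) {
  tbl <- cohortTable(cohort)
  counts <- stats::aggregate(scan_success ~ condition, data = tbl,
                             FUN = function(x) c(sum(x), length(x)))
  counts <- data.frame(condition = counts$condition,
                       success = counts$scan_success[, 1],
                       total = counts$scan_success[, 2])
  counts$rate <- round(100 * counts$success / counts$total, 1)
  if (!all(c("undilated", "dilated") %in% counts$condition))
    return(list(counts = counts, test = NULL))
  u <- counts[counts$condition == "undilated", ]
  d <- counts[counts$condition == "dilated", ]
  list(counts = counts,
       test = successRateTest(u$success, u$total, d$success, d$total,
                              correct = correct))
}

#' Read a cohort table from CSV
#'
#' Reads the long-format cohort interchange CSV (one row per subject,
#' condition and repeat; schema of \linkS4class{CohortDataset}). A missing
#' required column raises a schema error naming the column; rows whose
#' numeric fields fail to parse are reported with their line numbers; an
#' empty file is a "no rows" error.
#'
#' @param path CSV path.
#' @return A \linkS4class{CohortDataset}.
#' @export
readCohortCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tbl <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse CSV: ", conditionMessage(e)))
  if (!nrow(tbl)) stop("no rows in cohort file ", path)
  missing <- setdiff(.COHORT_COLUMNS, names(tbl))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  tbl <- tbl[.COHORT_COLUMNS]
  numCols <- c("age", "sbp", "dbp", "hr", "iop", "repeat", .INDEX_COLUMNS)
  bad <- integer()
  for (cl in numCols) {
    raw <- tbl[[cl]]
    conv <- suppressWarnings(as.numeric(raw))
    bad <- union(bad, which(!is.na(raw) & raw != "" & raw != "NA" &
                              is.na(conv)))
    tbl[[cl]] <- conv
  }
  succ <- toupper(trimws(tbl$scan_success))
  okSucc <- succ %in% c("TRUE", "FALSE")
  bad <- sort(union(bad, which(!okSucc)))
  if (length(bad))
    stop("malformed row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  tbl$scan_success <- succ == "TRUE"
  CohortDataset(tbl)
}

#' Write a cohort table to CSV
#'
#' UTF-8, comma-separated, "." decimal, one row per (subject, condition,
#' repeat), header exactly in the cohort schema order.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  stopifnot(is(cohort, "CohortDataset"))
  utils::write.csv(cohortTable(cohort)[.COHORT_COLUMNS], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

## Report rounding: one decimal for percent-scaled quantities, three for
## correlation-type quantities.
.roundReport <- function(df) {
  for (cl in intersect(c("cov", "meanBefore", "meanAfter", "meanDiff",
                         "meanMale", "meanFemale"), names(df)))
    df[[cl]] <- round(df[[cl]], 1)
  for (cl in intersect(c("icc", "r", "p", "slope", "intercept", "t"),
                       names(df)))
    df[[cl]] <- round(df[[cl]], 3)
  df
}

#' Write the report tables of a pipeline run
#'
#' @param tables a named list of data.frames (as produced by
#'   \code{\link{runPipeline}}).
#' @param dir output directory (created if needed).
#' @return The written file paths, invisibly.
#' @export
writeReport <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    if (!is.data.frame(tables[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(.roundReport(tables[[nm]]), p, row.names = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Run the full simulate -> analyze -> report pipeline
#'
#' Simulates a cohort at the configured scale, runs every study statistic —
#' the per-index repeatability table (COV/ICC, both conditions), the
#' age and PPA association table, the paired dilation comparison, the sex
#' comparison and the success-rate chi-square — and optionally writes the
#' cohort CSV, the report tables and a run log (seed and configuration
#' hash) to a directory. Deterministic given the seed: all randomness flows
#' from it.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param seed integer seed.
#' @param outDir optional output directory.
#' @return A list with \code{cohort} (\linkS4class{CohortDataset}) and the
#'   report tables \code{repeatability}, \code{association},
#'   \code{dilation}, \code{sex}, \code{successRate}, plus \code{seed}.
#' @examples
#' res <- runPipeline(pipelineConfig(nPerCell = 1, repeats = 2), seed = 4)
#' res$successRate$counts
#' @export
runPipeline <- function(config = pipelineConfig(), seed = 1, outDir = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  st <- config$statistics
  cohort <- simulateCohort(nPerCell = config$nPerCell,
                           repeats = config$repeats, seed = seed,
                           config = config$generator,
                           waveform = config$waveform)
  tables <- list(
    repeatability = repeatabilityTable(cohort, form = st$iccForm),
    association = associationTable(cohort, mapFormula = st$mapFormula),
    dilation = dilationComparison(cohort),
    sex = sexComparison(cohort, varEqual = st$varEqual))
  sr <- successRateSummary(cohort, correct = st$yates)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCohortCsv(cohort, file.path(outDir, "cohort.csv"))
    writeReport(tables, outDir)
    utils::write.csv(sr$counts, file.path(outDir, "success_rate.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    cfgPath <- file.path(outDir, "config.yaml")
    yaml::write_yaml(unclass(config), cfgPath)
    log <- c(sprintf("seed: %d", as.integer(seed)),
             sprintf("config_md5: %s", unname(tools::md5sum(cfgPath))),
             sprintf("icc_form: %s", st$iccForm),
             sprintf("yates: %s", st$yates),
             sprintf("map_formula: %s", st$mapFormula),
             sprintf("bot_level: %s", config$waveform$botLevel),
             sprintf("phase_bins: %d", config$waveform$phaseBins),
             sprintf("skew_scale: %g", config$waveform$skewScale),
             sprintf("n_rows: %d", nrow(cohortTable(cohort))))
    writeLines(log, file.path(outDir, "run_log.txt"))
  }
  c(list(cohort = cohort), tables,
    list(successRate = sr, seed = as.integer(seed)))
}
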