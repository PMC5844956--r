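## Reading and writing motion-parameter files and phenotype tables.
##
## Motion files are plain text, whitespace-delimited, six numeric columns
## per frame, '#' comments allowed -- the "1D" output convention of
## standard fMRI volume-registration tools. The column order is not
## standardized across tools, so it is an explicit argument.

#' Read a 6-column rigid-body motion-parameter file
#'
#' @param path Path to a whitespace-delimited text file with six numeric
#'   columns per row and optional `#` comment lines.
#' @param samplingInterval Seconds per frame for this scan (> 0).
#' @param subjectId Identifier for the returned trace; defaults to the
#'   file name without extension.
#' @param columnOrder `"rotations-first"` (default: columns 1-3 are roll,
#'   pitch, yaw; columns 4-6 are x, y, z translations) or
#'   `"translations-first"`.
#' @param rotationUnit `"degrees"` (default) or `"radians"`; radians are
#'   converted to degrees on read.
#' @return A [MotionTrace].
#' @examples
#' f <- tempfile(fileext = ".1D")
#' writeLines(c("# demo", "0 0 0 0 0 0", "0.1 0 0 1 0 0", "0.2 0 0 2 0 0"), f)
#' readMotionFile(f, samplingInterval = 0.5)
#' @export
readMotionFile <- function(path, samplingInterval,
                           subjectId = sub("\\.[^.]*$", "", basename(path)),
                           columnOrder = c("rotations-first", "translations-first"),
                           rotationUnit = c("degrees", "radians")) {
  columnOrder <- match.arg(columnOrder)
  rotationUnit <- match.arg(rotationUnit)
  if (!file.exists(path)) formatError("motion file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  rowNo <- which(keep)
  if (length(body) < 2L)
    formatError("motion file %s has %d data rows; at least 2 frames required",
                path, length(body))
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 6L))
    formatError("motion file %s: row %d has %d columns, expected 6",
                path, rowNo[which(nf != 6L)[1L]], nf[nf != 6L][1L])
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(6)))
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1L]
    formatError("motion file %s: non-numeric value in row %d", path, rowNo[bad])
  }
  m <- t(vals)
  if (columnOrder == "rotations-first") {
    rot <- m[, 1:3, drop = FALSE]; tra <- m[, 4:6, drop = FALSE]
  } else {
    tra <- m[, 1:3, drop = FALSE]; rot <- m[, 4:6, drop = FALSE]
  }
  if (rotationUnit == "radians") rot <- rot * 180 / pi
  MotionTrace(subjectId, rot, tra, samplingInterval)
}

#' Write a motion trace in the 6-column text format
#'
#' @param trace A [MotionTrace].
#' @param path Output path.
#' @param columnOrder Column convention, as in [readMotionFile()].
#' @return Invisibly, `path`.
#' @export
writeMotionFile <- function(trace, path,
                            columnOrder = c("rotations-first", "translations-first")) {
  columnOrder <- match.arg(columnOrder)
  m <- if (columnOrder == "rotations-first")
    cbind(trace@rotations, trace@translations)
  else cbind(trace@translations, trace@rotations)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# motion parameters for %s: %s; sampling interval %.10g s",
                     trace@subjectId, columnOrder, trace@samplingInterval), con)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

phenotypeColumns <- c("SUB_ID", "SITE_ID", "DX_PRIMARY", "DX_DSM_IV_TR",
                      "AGE_AT_SCAN", "SEX", "MEDICATION")

#' Read a phenotype table
#'
#' Expects a CSV with the fixed header `SUB_ID, SITE_ID, DX_PRIMARY,
#' DX_DSM_IV_TR, AGE_AT_SCAN, SEX, MEDICATION`. Empty or missing
#' `DX_DSM_IV_TR` and `MEDICATION` cells become `"unreported"` rather than
#' being dropped. Each subject's site must appear in `samplingRates`; the
#' derived `SR_CLASS` column is `"SR0"` for sampling rates below 1 Hz and
#' `"SR1"` otherwise, and `SAMPLING_INTERVAL` carries the seconds per
#' frame.
#'
#' @param path CSV path.
#' @param samplingRates Named numeric vector: seconds per frame by
#'   `SITE_ID`.
#' @return A data.frame of subject records with the derived columns
#'   appended.
#' @export
readPhenotypes <- function(path, samplingRates) {
  if (!file.exists(path)) formatError("phenotype file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(phenotypeColumns, names(df))
  if (length(missing))
    formatError("phenotype table %s lacks mandatory column(s): %s",
                path, paste(missing, collapse = ", "))
  df$AGE_AT_SCAN <- as.numeric(df$AGE_AT_SCAN)
  if (anyNA(df$AGE_AT_SCAN) || any(df$AGE_AT_SCAN <= 0))
    formatError("phenotype table %s: AGE_AT_SCAN must be positive numbers", path)
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  df$DX_DSM_IV_TR[blank(df$DX_DSM_IV_TR)] <- "unreported"
  df$MEDICATION[blank(df$MEDICATION)] <- "unreported"
  unknown <- setdiff(unique(df$SITE_ID), names(samplingRates))
  if (length(unknown))
    lookupError("no sampling rate supplied for site(s): %s",
                paste(unknown, collapse = ", "))
  df$SAMPLING_INTERVAL <- unname(samplingRates[df$SITE_ID])
  df$SR_CLASS <- ifelse(1 / df$SAMPLING_INTERVAL < 1, "SR0", "SR1")
  df
}

groupLabels <- c("TD", "ASD", "ASD_DSM", "AS", "ASMIX", "FEM", "MALES",
                 "MEDS", "NoMEDS")

#' Select a comparison group from subject records
#'
#' Implements the labelled selections used throughout the analysis:
#' \describe{
#'   \item{TD}{primary diagnosis column equals TD.}
#'   \item{ASD}{primary diagnosis column equals ASD.}
#'   \item{ASD_DSM}{DSM-IV-TR column equals ASD.}
#'   \item{AS}{DSM-IV-TR column equals AS (Asperger's).}
#'   \item{ASMIX}{DSM-IV-TR column is AS, PDD or PDDNOS -- the DSM-IV ASD
#'     subtype is deliberately excluded.}
#'   \item{FEM / MALES}{all female / male subjects regardless of diagnosis.}
#'   \item{MEDS}{subjects with a reported medication status of "yes".}
#'   \item{NoMEDS}{subjects on the autism spectrum (primary ASD or any
#'     DSM-IV-TR subtype) whose reported medication status is "no".}
#' }
#' Subjects whose medication field is `"unreported"` never enter MEDS or
#' NoMEDS.
#'
#' @param records Data.frame from [readPhenotypes()] or
#'   [generateCohort()]`$phenotypes`.
#' @param label One of the nine group labels.
#' @return The subset of `records` matching the label.
#' @export
selectGroup <- function(records, label) {
  if (!is.character(label) || length(label) != 1L || !label %in% groupLabels)
    invalidParameter("unknown group label '%s'; valid labels: %s",
                     as.character(label)[1L], paste(groupLabels, collapse = ", "))
  spectrumDsm <- c("ASD", "AS", "PDD", "PDDNOS")
  keep <- switch(label,
    TD      = records$DX_PRIMARY == "TD",
    ASD     = records$DX_PRIMARY == "ASD",
    ASD_DSM = records$DX_DSM_IV_TR == "ASD",
    AS      = records$DX_DSM_IV_TR == "AS",
    ASMIX   = records$DX_DSM_IV_TR %in% c("AS", "PDD", "PDDNOS"),
    FEM     = records$SEX == "F",
    MALES   = records$SEX == "M",
    MEDS    = records$MEDICATION == "yes",
    NoMEDS  = (records$DX_PRIMARY == "ASD" |
               records$DX_DSM_IV_TR %in% spectrumDsm) &
              records$MEDICATION == "no"
  )
  records[keep, , drop = FALSE]
}
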