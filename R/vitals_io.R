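# Tabular I/O, schema validation and run configuration.
#
# Interchange dialect: UTF-8 CSV with fixed headers, "." decimal, offsets
# in integer minutes from admission (time zero = admission), so no
# timezone handling is needed anywhere in the pipeline.

#' Default physiologic plausibility bounds
#'
#' Per-vital (low, high) ranges used to drop artifactual raw measurements
#' before resampling. Values outside these ranges are not compatible with
#' life or with the measurement device and are treated as charting
#' artifacts.
#'
#' @return Named list of length-2 numeric vectors (low, high), one per
#'   vital.
#' @export
plausibilityBounds <- function() {
  list(
    SBP = c(30, 300), DBP = c(10, 200), HR = c(20, 300),
    RR = c(4, 80), SpO2 = c(50, 100), Temp = c(30, 43)
  )
}

#' Run configuration for the physiotype pipeline
#'
#' Bundles the tunable choices every stage shares: the observation window,
#' the vitals included in the feature matrix (sensitivity analyses drop
#' temperature, or temperature plus DBP and RR), plausibility bounds, and
#' the consensus clustering parameters.
#'
#' @param windowHours Observation window in hours; 6 (default) or 12.
#' @param includedVitals Character subset of [vitalNames()]; defaults to
#'   all six.
#' @param bounds Plausibility bounds as from [plausibilityBounds()].
#' @param kRange Candidate cluster numbers, contiguous from 2.
#' @param nResamples Number of consensus resamples.
#' @param subsampleFraction Fraction of encounters drawn per resample.
#' @param seed Base seed for the resampling seed ladder.
#'
#' @return A list with class \code{"physioRunConfig"}.
#' @export
runConfig <- function(windowHours = 6, includedVitals = vitalNames(),
                      bounds = plausibilityBounds(), kRange = 2:8,
                      nResamples = 100L, subsampleFraction = 0.8,
                      seed = 1L) {
  if (!windowHours %in% c(6, 12))
    stop("windowHours must be 6 or 12")
  if (!length(includedVitals) || !all(includedVitals %in% vitalNames()))
    stop("includedVitals must be a non-empty subset of the six vitals")
  for (v in names(bounds))
    if (bounds[[v]][1] >= bounds[[v]][2])
      stop("plausibility bounds for ", v, " must satisfy low < high")
  structure(
    list(
      windowHours = as.integer(windowHours),
      includedVitals = includedVitals,
      bounds = bounds,
      kRange = as.integer(kRange),
      nResamples = as.integer(nResamples),
      subsampleFraction = subsampleFraction,
      seed = as.integer(seed)
    ),
    class = "physioRunConfig"
  )
}

#' Read a long-format vitals table
#'
#' Expects columns \code{encounter_id}, \code{vital},
#' \code{offset_minutes}, \code{value}. Rows are validated (known vital
#' names, numeric non-negative offsets, numeric values) and returned
#' sorted by encounter, vital and offset; malformed rows raise an error
#' naming the offending row number.
#'
#' @param path CSV file path.
#' @return Data frame with the four schema columns, offset-sorted within
#'   each (encounter, vital) series.
#' @export
readVitals <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validateVitals(df)
}

#' Validate an in-memory vitals table
#'
#' @param df Data frame with the vitals schema columns.
#' @return The validated, sorted data frame.
#' @export
validateVitals <- function(df) {
  need <- c("encounter_id", "vital", "offset_minutes", "value")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("vitals table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$vital %in% vitalNames())
  if (length(bad))
    stop("unknown vital name '", df$vital[bad[1]], "' at row ", bad[1])
  off <- suppressWarnings(as.numeric(df$offset_minutes))
  bad <- which(is.na(off))
  if (length(bad)) stop("non-numeric offset_minutes at row ", bad[1])
  bad <- which(off < 0)
  if (length(bad)) stop("negative offset_minutes at row ", bad[1])
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(val))
  if (length(bad)) stop("non-numeric value at row ", bad[1])
  df$offset_minutes <- off
  df$value <- val
  df <- df[order(df$encounter_id, df$vital, df$offset_minutes), , drop = FALSE]
  rownames(df) <- NULL
  df[, need]
}

#' Write a long-format vitals table
#'
#' @param df Vitals data frame (validated on the way out).
#' @param path Destination CSV path.
#' @return Invisibly, the path.
#' @export
writeVitals <- function(df, path) {
  df <- validateVitals(df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-encounter table
#'
#' @param path CSV file path; must contain an \code{encounter_id} column.
#' @return Data frame, one row per encounter.
#' @export
readEncounters <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"encounter_id" %in% colnames(df))
    stop("encounters table missing column encounter_id")
  if (anyDuplicated(df$encounter_id))
    stop("duplicate encounter_id in encounters table")
  df
}

#' Write a per-encounter table
#'
#' @param df Encounters data frame.
#' @param path Destination CSV path.
#' @return Invisibly, the path.
#' @export
writeEncounters <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Chronological train/validation/test split
#'
#' Splits encounters by admission date into three chronologically ordered
#' cohorts, the design used for model development on an early slice and
#' validation/testing on later slices. Boundaries are either two dates
#' (encounters admitted on or before the first date train, on or before
#' the second validation, the rest test) or two fractions in (0, 1)
#' applied to the date-sorted table. Ties in admission date are broken by
#' ascending \code{encounter_id} so the split is deterministic.
#'
#' @param encounters Data frame with \code{encounter_id} and
#'   \code{admission_date} (Date or coercible).
#' @param boundaries Length-2 vector: two cut dates or two increasing
#'   fractions.
#' @return List with data frames \code{train}, \code{validation},
#'   \code{test}; their row counts always sum to \code{nrow(encounters)}.
#' @export
splitCohort <- function(encounters, boundaries) {
  if (!"admission_date" %in% colnames(encounters))
    stop("encounters must carry admission_date")
  if (length(boundaries) != 2)
    stop("boundaries must have length 2")
  dates <- as.Date(encounters$admission_date)
  ord <- order(dates, encounters$encounter_id)
  enc <- encounters[ord, , drop = FALSE]
  n <- nrow(enc)
  if (is.numeric(boundaries)) {
    if (boundaries[1] >= boundaries[2])
      stop("fraction boundaries must be increasing")
    if (any(boundaries <= 0) || any(boundaries >= 1))
      stop("fraction boundaries must lie in (0, 1)")
    cut1 <- floor(boundaries[1] * n)
    cut2 <- floor(boundaries[2] * n)
  } else {
    b <- as.Date(boundaries)
    if (b[1] >= b[2]) stop("date boundaries must be increasing")
    d <- as.Date(enc$admission_date)
    cut1 <- sum(d <= b[1])
    cut2 <- sum(d <= b[2])
  }
  idx <- seq_len(n)
  out <- list(
    train = enc[idx <= cut1, , drop = FALSE],
    validation = enc[idx > cut1 & idx <= cut2, , drop = FALSE],
    test = enc[idx > cut2, , drop = FALSE]
  )
  if (nrow(out$validation) == 0)
    warning("validation partition is empty for the given boundaries")
  out
}
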