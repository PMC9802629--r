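# SOFA and MEWS acuity scoring from shipped lookup tables. The tables
# are data, not code, so institutional variants can be swapped in.

#' Load the acuity score tables
#'
#' @param path Optional path to a JSON table file; defaults to the
#'   tables shipped with the package (encoded from the original score
#'   publications).
#' @return Nested list with elements \code{sofa} and \code{mews}.
#' @export
acuityTables <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "acuity_tables.json",
                        package = "physiotypes")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# score a numeric vector against a half-open band list; NA stays NA
.bandScore <- function(x, bands) {
  out <- rep(NA_real_, length(x))
  for (b in bands) {
    hi <- if (is.null(b$hi)) Inf else b$hi
    hitIdx <- !is.na(x) & x >= b$lo & x < hi
    out[hitIdx] <- b$score
  }
  out
}

#' Compute SOFA organ subscores and total
#'
#' Scores the six organ systems (respiratory PaO2/FiO2, coagulation
#' platelets, liver bilirubin, cardiovascular MAP/vasopressor,
#' neurologic GCS, renal creatinine) from worst-in-window values against
#' the shipped lookup table. The renal subscore is creatinine-based
#' (no urine-output criterion). A missing component is scored per
#' \code{missingPolicy}: \code{"normal"} (default) scores it 0 and tags
#' it, which never inflates acuity. A vasopressor flag scores the lowest
#' pressor tier of the cardiovascular subscore.
#'
#' @param inputs Data frame (or coercible list) with columns
#'   \code{pao2_fio2}, \code{platelets} (x10^9/L), \code{bilirubin}
#'   (mg/dL), \code{map_mmHg}, \code{vasopressor} (0/1), \code{gcs}
#'   (3-15), \code{creatinine} (mg/dL); any may be absent or NA.
#' @param tables Score tables from [acuityTables()].
#' @param missingPolicy Only \code{"normal"} is implemented.
#' @return Data frame with the six subscores, \code{sofa_total},
#'   \code{sofa_gt6} and \code{sofa_missing} (comma-separated tags of
#'   defaulted components).
#' @export
computeSofa <- function(inputs, tables = acuityTables(),
                        missingPolicy = c("normal")) {
  missingPolicy <- match.arg(missingPolicy)
  inputs <- as.data.frame(inputs)
  n <- nrow(inputs)
  getCol <- function(nm) {
    if (nm %in% colnames(inputs)) inputs[[nm]] else rep(NA_real_, n)
  }
  systems <- c("respiratory", "coagulation", "liver", "cardiovascular",
               "neurologic", "renal")
  sub <- matrix(NA_real_, n, length(systems),
                dimnames = list(NULL, paste0("sofa_", systems)))
  for (s in systems) {
    spec <- tables$sofa[[s]]
    x <- getCol(spec$variable)
    sc <- .bandScore(x, spec$bands)
    if (s == "cardiovascular") {
      vaso <- getCol("vasopressor")
      onPressor <- !is.na(vaso) & vaso > 0
      sc[onPressor] <- pmax(sc[onPressor], spec$pressor_flag_score,
                            na.rm = TRUE)
      # a pressor flag alone still scores even if MAP is missing
      sc[is.na(sc) & onPressor] <- spec$pressor_flag_score
    }
    sub[, paste0("sofa_", s)] <- sc
  }
  if (any(rowSums(!is.na(sub)) == 0))
    stop("at least one SOFA component must be present per encounter")
  missTags <- apply(sub, 1, function(r)
    paste(systems[is.na(r)], collapse = ","))
  sub[is.na(sub)] <- 0
  total <- rowSums(sub)
  out <- data.frame(sub, sofa_total = total, sofa_gt6 = total > 6,
                    sofa_missing = missTags, stringsAsFactors = FALSE)
  if ("encounter_id" %in% colnames(inputs))
    out <- cbind(encounter_id = inputs$encounter_id, out)
  out
}

#' Compute the Modified Early Warning Score
#'
#' Scores systolic blood pressure, heart rate, respiratory rate,
#' temperature and consciousness (AVPU) against the shipped table.
#' Inputs are one worst-in-window value per component; when scoring raw
#' multi-measurement windows use [computeAcuity()], which takes the
#' maximum points over all in-window measurements per component. A
#' missing AVPU defaults to Alert (0 points, tagged); temperature may
#' be missing (tagged); SBP, heart rate and respiratory rate are
#' required.
#'
#' @param inputs Data frame with columns \code{sbp}, \code{hr},
#'   \code{rr} and optionally \code{temp_c}, \code{avpu}.
#' @param tables Score tables from [acuityTables()].
#' @return Data frame with per-component points, \code{mews_total},
#'   \code{mews_ge5} and \code{mews_missing}.
#' @export
computeMews <- function(inputs, tables = acuityTables()) {
  inputs <- as.data.frame(inputs)
  n <- nrow(inputs)
  for (req in c("sbp", "hr", "rr")) {
    if (!req %in% colnames(inputs) || all(is.na(inputs[[req]])))
      stop("MEWS requires ", req)
  }
  pts <- data.frame(
    mews_sbp = .bandScore(inputs$sbp, tables$mews$sbp$bands),
    mews_hr = .bandScore(inputs$hr, tables$mews$hr$bands),
    mews_rr = .bandScore(inputs$rr, tables$mews$rr$bands),
    mews_temp = if ("temp_c" %in% colnames(inputs))
      .bandScore(inputs$temp_c, tables$mews$temp_c$bands)
      else rep(NA_real_, n)
  )
  avpu <- if ("avpu" %in% colnames(inputs)) as.character(inputs$avpu)
          else rep(NA_character_, n)
  lv <- tables$mews$avpu$levels
  badLevel <- !is.na(avpu) & !avpu %in% names(lv)
  if (any(badLevel))
    stop("unknown AVPU level: ", avpu[which(badLevel)[1]])
  pts$mews_avpu <- ifelse(is.na(avpu), NA_real_,
                          unlist(lv)[avpu])
  if (any(rowSums(!is.na(pts[c("mews_sbp", "mews_hr", "mews_rr")])) == 0))
    stop("at least one of sbp/hr/rr must be present per encounter")
  comp <- c("sbp", "hr", "rr", "temp", "avpu")
  missTags <- apply(pts, 1, function(r)
    paste(comp[is.na(r)], collapse = ","))
  pts[is.na(pts)] <- 0
  total <- rowSums(pts)
  out <- data.frame(pts, mews_total = total, mews_ge5 = total >= 5,
                    mews_missing = missTags, stringsAsFactors = FALSE)
  if ("encounter_id" %in% colnames(inputs))
    out <- cbind(encounter_id = inputs$encounter_id, out)
  out
}

# AVPU level from GCS, the usual clinical mapping
.gcsToAvpu <- function(gcs) {
  ifelse(is.na(gcs), NA_character_,
         ifelse(gcs >= 14, "Alert",
                ifelse(gcs >= 9, "Voice",
                       ifelse(gcs >= 7, "Pain", "Unresponsive"))))
}

#' Acuity scoring for a whole cohort
#'
#' Computes SOFA from the per-encounter worst-in-window inputs carried
#' in the encounters table, and MEWS from the raw vitals by scoring
#' every in-window measurement and keeping the worst (maximum points)
#' per component, so both tails of each vital can flag. AVPU is mapped
#' from GCS when present.
#'
#' @param encounters Per-encounter table with the SOFA input columns.
#' @param vitals Long-format vitals table.
#' @param tables Score tables from [acuityTables()].
#' @param windowHours Scoring window (default 24 h).
#' @return Data frame with subscores, totals and threshold flags
#'   (\code{sofa_gt6}, \code{mews_ge5}) per encounter.
#' @export
computeAcuity <- function(encounters, vitals, tables = acuityTables(),
                          windowHours = 24) {
  sofa <- computeSofa(encounters, tables)
  inWin <- vitals[vitals$offset_minutes < windowHours * 60, , drop = FALSE]
  mewsVital <- c(SBP = "sbp", HR = "hr", RR = "rr", Temp = "temp_c")
  worstPts <- matrix(NA_real_, nrow(encounters), length(mewsVital),
                     dimnames = list(encounters$encounter_id,
                                     paste0("mews_", c("sbp", "hr", "rr", "temp"))))
  for (v in names(mewsVital)) {
    sub <- inWin[inWin$vital == v, , drop = FALSE]
    if (!nrow(sub)) next
    pts <- .bandScore(sub$value, tables$mews[[mewsVital[v]]]$bands)
    agg <- tapply(pts, factor(sub$encounter_id,
                              levels = encounters$encounter_id),
                  max, na.rm = TRUE)
    col <- paste0("mews_", c(SBP = "sbp", HR = "hr", RR = "rr",
                             Temp = "temp")[v])
    worstPts[, col] <- as.numeric(agg)
  }
  avpuPts <- unlist(tables$mews$avpu$levels)[.gcsToAvpu(encounters$gcs)]
  pts <- as.data.frame(worstPts)
  pts$mews_avpu <- as.numeric(avpuPts)
  comp <- c("sbp", "hr", "rr", "temp", "avpu")
  missTags <- apply(pts, 1, function(r)
    paste(comp[is.na(r)], collapse = ","))
  pts[is.na(pts)] <- 0
  total <- rowSums(pts)
  mews <- data.frame(encounter_id = encounters$encounter_id, pts,
                     mews_total = total, mews_ge5 = total >= 5,
                     mews_missing = missTags, stringsAsFactors = FALSE,
                     row.names = NULL)
  merge(sofa, mews, by = "encounter_id", sort = FALSE)
}
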