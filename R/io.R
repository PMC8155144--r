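#' Write a cohort's tables to CSV fixtures
#'
#' Writes `participants.csv`, `mrs_scans.csv`, `cortisol.csv`, `vams.csv`
#' and (when present) `ema_surveys.csv` into `dir`. Timestamps are written
#' as ISO-8601 UTC; missing values as empty fields. The files round-trip
#' losslessly through [read_cohort()].
#'
#' @param tables Named list with some or all of `participants`, `scans`,
#'   `cortisol`, `vams`, `ema_surveys`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_cohort <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(participants = "participants.csv", scans = "mrs_scans.csv",
             cortisol = "cortisol.csv", vams = "vams.csv",
             ema_surveys = "ema_surveys.csv")
  present <- intersect(names(files), names(tables))
  if (!length(present)) abort("`tables` contains none of the cohort tables.")
  paths <- character(0)
  for (nm in present) {
    path <- file.path(dir, files[[nm]])
    readr::write_csv(tables[[nm]], path, na = "")
    paths[[nm]] <- path
  }
  invisible(paths)
}

cohort_col_types <- list(
  participants = readr::cols(
    id = "c", group = "c", condition = "c", site = "c", age = "d", sex = "c",
    pss = "d", rating_stress = "d", rating_unpleasant = "d",
    rating_difficulty = "d", strain_acute_count = "d",
    strain_chronic_count = "d"
  ),
  scans = readr::cols(
    id = "c", session = "c", glu_cr = "d", glx_cr = "d", cho_cr = "d",
    snr = "d", fwhm = "d", crlb_glu = "d"
  ),
  cortisol = readr::cols(id = "c", timepoint = "c", nmol_per_l = "d"),
  vams = readr::cols(id = "c", timepoint = "d", item = "c", score = "d",
                     positive_pole = "c"),
  ema_surveys = readr::cols(
    id = "c", date = readr::col_date(), schedule_index = "d",
    sent_at = readr::col_datetime(), started_at = readr::col_datetime(),
    completed_at = readr::col_datetime(),
    enthusiastic = "d", cheerful = "d", relaxed = "d",
    irritable = "d", anxious = "d", sad = "d",
    expectation = "d", happened = "l", outcome = "d",
    .default = readr::col_character()
  )
)

#' Read cohort CSV fixtures
#'
#' Inverse of [write_cohort()]: reads whichever of the cohort CSV files are
#' present in `dir` with typed column specifications.
#'
#' @param dir Directory containing the CSV files.
#' @return Named list of tibbles (only the files present).
#' @export
read_cohort <- function(dir) {
  files <- c(participants = "participants.csv", scans = "mrs_scans.csv",
             cortisol = "cortisol.csv", vams = "vams.csv",
             ema_surveys = "ema_surveys.csv")
  out <- list()
  for (nm in names(files)) {
    path <- file.path(dir, files[[nm]])
    if (file.exists(path)) {
      out[[nm]] <- readr::read_csv(path, col_types = cohort_col_types[[nm]],
                                   na = c("", "NA"), progress = FALSE)
    }
  }
  if (!length(out)) abort(sprintf("no cohort CSV files found in '%s'", dir))
  out
}
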