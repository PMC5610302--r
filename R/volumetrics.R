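#' Volumetric mismatch (FLAIR - DWI)
#'
#' Difference between the lesion volume on post-treatment FLAIR and the
#' lesion volume on pre-treatment DWI. Negative values mean the lesion
#' shrank over the month.
#'
#' @param dwi_pre_cm3,flair_post_cm3 Lesion volumes in cm^3, both >= 0.
#' @return `flair_post_cm3 - dwi_pre_cm3`, in cm^3 (vectorized).
#' @export
mismatch <- function(dwi_pre_cm3, flair_post_cm3) {
  if (any(dwi_pre_cm3 < 0) || any(flair_post_cm3 < 0))
    stop("volumes must be >= 0", call. = FALSE)
  flair_post_cm3 - dwi_pre_cm3
}

#' FLAIR/DWI volume ratio
#'
#' Ratio of the post-treatment FLAIR lesion volume to the pre-treatment DWI
#' lesion volume; values below 1 mean shrinkage. Reports round it to two
#' decimals, internal values keep full precision.
#'
#' @param dwi_pre_cm3,flair_post_cm3 Lesion volumes in cm^3; the DWI volume
#'   must be > 0.
#' @return Dimensionless ratio (vectorized).
#' @export
flair_dwi_rate <- function(dwi_pre_cm3, flair_post_cm3) {
  if (any(flair_post_cm3 < 0)) stop("volumes must be >= 0", call. = FALSE)
  if (any(dwi_pre_cm3 <= 0))
    stop("DWI pre-treatment volume must be > 0 for a ratio", call. = FALSE)
  flair_post_cm3 / dwi_pre_cm3
}

#' Classify lesion evolution from the volumetric mismatch
#'
#' @param mismatch_cm3 FLAIR - DWI volume difference, cm^3 (vectorized).
#' @return Character: `"reduced"` (negative), `"grew"` (positive), or
#'   `"unchanged"` (exactly zero).
#' @export
classify_evolution <- function(mismatch_cm3) {
  ifelse(mismatch_cm3 < 0, "reduced",
         ifelse(mismatch_cm3 > 0, "grew", "unchanged"))
}

#' Change from baseline of a clinical score
#'
#' Follow-up scores are compared with the baseline score:
#' `score(visit) - score(baseline)`. An absent visit propagates as `NA`
#' (never imputed).
#'
#' @param record A [patient_record()].
#' @param scale One of `"nihss"`, `"bi"`, `"mrs"`.
#' @param visit One of the follow-up visits in [VISITS].
#' @return Signed change from baseline, or `NA` if the visit is absent.
#' @export
score_change <- function(record, scale = c("nihss", "bi", "mrs"),
                         visit = c("day5", "month1", "month3", "month12")) {
  stopifnot(inherits(record, "patient_record"))
  scale <- match.arg(scale)
  visit <- match.arg(visit)
  scores <- record[[scale]]
  baseline <- scores[match("baseline", VISITS)]
  if (is.na(baseline)) stop("baseline score is absent", call. = FALSE)
  scores[match(visit, VISITS)] - baseline
}

# report convention: half away from zero (2.675 -> 2.68, -0.365 -> -0.37),
# unlike base round()'s banker's rounding
round_half_out <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Cohort summary report
#'
#' Builds the per-patient cohort table: stimulation dose, the three clinical
#' scales at all five visits, pre/post lesion volumes, volumetric mismatch
#' and FLAIR/DWI rate (recomputed from the volumes), the evolution class,
#' and the magnetic dose summary where available; plus per-dose-group counts
#' of reduced/grew/unchanged lesions (available cases only).
#'
#' @param records List of [patient_record()]s with unique ids.
#' @return An object of class `cohort_report`: list with `patients` (data
#'   frame, one row per patient) and `groups` (data frame of per-group
#'   evolution counts).
#' @export
summarize_cohort <- function(records) {
  if (length(records) < 1L) stop("need at least one record", call. = FALSE)
  stopifnot(all(vapply(records, inherits, TRUE, "patient_record")))
  ids <- vapply(records, function(r) as.character(r$patient_id), "")
  if (anyDuplicated(ids))
    stop("duplicate patient_id: ", ids[duplicated(ids)][1], call. = FALSE)
  score_cols <- function(r, scale) {
    v <- r[[scale]]
    names(v) <- paste(scale, VISITS, sep = "_")
    v
  }
  rows <- lapply(records, function(r) {
    mm <- mismatch(r$dwi_pre_cm3, r$flair_post_cm3)
    dose <- r$dose
    data.frame(patient_id = as.character(r$patient_id),
               stim_minutes = r$stim_minutes,
               t(score_cols(r, "nihss")), t(score_cols(r, "bi")),
               t(score_cols(r, "mrs")),
               dwi_pre_cm3 = r$dwi_pre_cm3,
               flair_post_cm3 = r$flair_post_cm3,
               mismatch_cm3 = mm,
               flair_dwi_rate = flair_dwi_rate(r$dwi_pre_cm3,
                                               r$flair_post_cm3),
               evolution = classify_evolution(mm),
               d_min_cm = if (is.null(dose)) NA_real_ else dose$d_min_cm,
               d_max_cm = if (is.null(dose)) NA_real_ else dose$d_max_cm,
               b_min_mT = if (is.null(dose)) NA_real_ else dose$b_min_mT,
               b_max_mT = if (is.null(dose)) NA_real_ else dose$b_max_mT,
               check.names = FALSE)
  })
  patients <- do.call(rbind, rows)
  rownames(patients) <- NULL
  groups <- do.call(rbind, lapply(split(patients, patients$stim_minutes),
    function(g) data.frame(stim_minutes = g$stim_minutes[1],
                           n = nrow(g),
                           reduced = sum(g$evolution == "reduced"),
                           grew = sum(g$evolution == "grew"),
                           unchanged = sum(g$evolution == "unchanged"))))
  rownames(groups) <- NULL
  structure(list(patients = patients, groups = groups),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d patients\n", nrow(x$patients)))
  show <- x$patients[, c("patient_id", "stim_minutes", "dwi_pre_cm3",
                         "flair_post_cm3", "mismatch_cm3", "flair_dwi_rate",
                         "evolution")]
  show$mismatch_cm3 <- round_half_out(show$mismatch_cm3)
  show$flair_dwi_rate <- round_half_out(show$flair_dwi_rate)
  print(show, row.names = FALSE)
  cat("\nEvolution by dose group:\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Write the cohort report to CSV
#'
#' Mismatch and rate columns are rounded half-away-from-zero to two
#' decimals, the table convention; all other values are written at full
#' precision. Decimal point, UTF-8, one row per patient.
#'
#' @param report A `cohort_report` from [summarize_cohort()] (or its
#'   `patients` data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  df <- if (inherits(report, "cohort_report")) report$patients else report
  df$mismatch_cm3 <- round_half_out(df$mismatch_cm3)
  df$flair_dwi_rate <- round_half_out(df$flair_dwi_rate)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' Read back a cohort report CSV
#' @param path CSV path written by [write_cohort_report()].
#' @return A data frame.
#' @export
read_cohort_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
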