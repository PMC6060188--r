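cohort_histologies <- c("oligodendroglioma", "diffuse astrocytoma",
                        "anaplastic astrocytoma", "glioblastoma")

#' Read a lesion cohort table
#'
#' Parses a tab-separated cohort table with one row per lesion. Expected
#' columns: `lesion_id`, `patient_id`, `sex`, `age`, `histology`,
#' `who_grade`, `verification`, `days_before_pet`, `ki67_percent`.
#' Histology must belong to the controlled vocabulary (oligodendroglioma,
#' diffuse astrocytoma, anaplastic astrocytoma, glioblastoma); WHO grade
#' must be II, III or IV; verification SB (stereotactic biopsy) or EB
#' (excisional biopsy / partial resection). The Ki-67 column may hold a
#' number, the token `"<1"`, or `"N/A"` (missing); the raw token is kept
#' in `ki67` and a numeric reading in `ki67_value` (see [ki67_numeric()]).
#' A `grade_class` column is derived: WHO II is LGG; WHO III and IV are
#' HGG. Multiple lesions may share a `patient_id`.
#'
#' @param path Path to the TSV file (UTF-8, header row).
#' @param less_than_one Numeric reading of the `"<1"` token (default 0.5,
#'   the midpoint of the reported interval).
#' @return Data.frame of class `lesion_cohort`. An empty file yields an
#'   empty data.frame with a warning.
#' @examples
#' cohort <- read_cohort(system.file("extdata", "cohort_table1.tsv",
#'                                   package = "flucipet"))
#' nrow(cohort)                         # 18 lesions
#' length(unique(cohort$patient_id))    # 16 patients
#' @export
read_cohort <- function(path, less_than_one = 0.5) {
  d <- utils::read.delim(path, sep = "\t", colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(d) == 0) {
    warning("cohort file '", path, "' contains no records")
    return(structure(d, class = c("lesion_cohort", "data.frame")))
  }
  need <- c("lesion_id", "patient_id", "sex", "age", "histology",
            "who_grade", "verification", "days_before_pet", "ki67_percent")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop_("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (i in seq_len(nrow(d))) {
    if (!(d$histology[i] %in% cohort_histologies))
      stop_("row ", i, ": unknown histology '", d$histology[i], "'")
    if (!(d$who_grade[i] %in% c("II", "III", "IV")))
      stop_("row ", i, ": unknown WHO grade '", d$who_grade[i], "'")
    if (!(d$verification[i] %in% c("SB", "EB")))
      stop_("row ", i, ": unknown verification '", d$verification[i], "'")
    dy <- suppressWarnings(as.numeric(d$days_before_pet[i]))
    if (!is.finite(dy) || dy < 0 || dy != round(dy))
      stop_("row ", i, ": days_before_pet must be a non-negative integer")
  }
  out <- data.frame(
    lesion_id = d$lesion_id, patient_id = d$patient_id, sex = d$sex,
    age = as.numeric(d$age), histology = d$histology,
    who_grade = d$who_grade, verification = d$verification,
    days_before_pet = as.integer(d$days_before_pet),
    ki67 = d$ki67_percent,
    ki67_value = ki67_numeric(d$ki67_percent, less_than_one),
    grade_class = ifelse(d$who_grade == "II", "LGG", "HGG"),
    stringsAsFactors = FALSE)
  structure(out, class = c("lesion_cohort", "data.frame"))
}

#' Numeric reading of Ki-67 tokens
#'
#' @param tokens Character vector of Ki-67 entries: numbers, `"<1"`, or
#'   `"N/A"`/empty (missing).
#' @param less_than_one Value assigned to `"<1"` (default 0.5).
#' @return Numeric vector with `NA` for missing entries.
#' @export
ki67_numeric <- function(tokens, less_than_one = 0.5) {
  out <- rep(NA_real_, length(tokens))
  tok <- trimws(tokens)
  out[tok == "<1"] <- less_than_one
  plain <- !(tok %in% c("<1", "N/A", "NA", ""))
  v <- suppressWarnings(as.numeric(tok[plain]))
  if (any(is.na(v))) stop_("unparseable Ki-67 value(s): ",
                           paste(tok[plain][is.na(v)], collapse = ", "))
  out[plain] <- v
  out
}

#' Write a lesion cohort table
#'
#' Inverse of [read_cohort()]: writes the raw columns (including the
#' original Ki-67 tokens) as TSV, so that reading the file back yields
#' equal records.
#'
#' @param cohort A `lesion_cohort` data.frame.
#' @param path Output TSV path.
#' @export
write_cohort <- function(cohort, path) {
  d <- data.frame(lesion_id = cohort$lesion_id, patient_id = cohort$patient_id,
                  sex = cohort$sex, age = cohort$age,
                  histology = cohort$histology, who_grade = cohort$who_grade,
                  verification = cohort$verification,
                  days_before_pet = cohort$days_before_pet,
                  ki67_percent = cohort$ki67, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize a lesion cohort
#'
#' Lesion and patient counts, histology and grade-class tallies, and
#' patient-level means (one value per patient) of age and of the
#' verification-to-PET interval.
#'
#' @param cohort A [read_cohort()] data.frame with >= 1 record.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  per_patient <- function(col) {
    tapply(cohort[[col]], cohort$patient_id, function(v) mean(unique(v)))
  }
  structure(list(
    n_lesions = nrow(cohort),
    n_patients = length(unique(cohort$patient_id)),
    histology_counts = table(cohort$histology),
    grade_counts = table(cohort$who_grade),
    grade_class_counts = table(cohort$grade_class),
    mean_days_before_pet = mean(per_patient("days_before_pet")),
    mean_age = mean(per_patient("age")),
    n_ki67_available = sum(!is.na(cohort$ki67_value)),
    n_ki67_missing = sum(is.na(cohort$ki67_value))),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d lesions from %d patients\n", x$n_lesions, x$n_patients))
  cat("  histology:", paste(sprintf("%s %d", names(x$histology_counts),
                                    x$histology_counts), collapse = "; "), "\n")
  cat("  grade class:", paste(sprintf("%s %d", names(x$grade_class_counts),
                                      x$grade_class_counts), collapse = "; "), "\n")
  cat(sprintf("  mean verification-to-PET interval: %.1f days (per patient)\n",
              x$mean_days_before_pet))
  cat(sprintf("  Ki-67 available for %d lesions\n", x$n_ki67_available))
  invisible(x)
}
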