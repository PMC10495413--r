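#' Assemble and validate a longitudinal MS cohort
#'
#' Bundles the three tables describing a cohort — static patient covariates,
#' longitudinal EDSS assessments, and relapse dates — into a validated
#' \code{ms_cohort} object. Validation enforces the EDSS grid (0, 1.0, 1.5,
#' ..., 10.0), unique patient ids, unique visit dates within a patient,
#' \code{diagnosis_date <= baseline_date}, and referential integrity of the
#' visits table. Visits are sorted by date within each patient. Relapse rows
#' whose \code{patient_id} matches no patient are rejected (dropped with a
#' warning).
#'
#' @param patients data.frame with columns \code{patient_id}, \code{sex}
#'   (\code{"F"}/\code{"M"}), \code{age_at_baseline} (years),
#'   \code{diagnosis_date}, \code{baseline_date} (therapy initiation, ISO
#'   dates), \code{course} (\code{"RRMS"}/\code{"PPMS"}),
#'   \code{n_prior_dmts}; optionally \code{cd19_detectable} (logical or 0/1,
#'   NA allowed) and worse-eye OCT metrics \code{prnfl_worse} (micrometre),
#'   \code{mrnfl_worse}, \code{gcipl_worse} (cubic millimetre).
#' @param visits data.frame with \code{patient_id}, \code{visit_date},
#'   \code{edss}.
#' @param relapses data.frame with \code{patient_id}, \code{relapse_date},
#'   or NULL for a relapse-free cohort.
#' @return An object of class \code{ms_cohort}: a list with elements
#'   \code{patients}, \code{visits}, \code{relapses}.
#' @seealso [read_cohort()], [write_cohort()], [derive_baseline()]
#' @export
ms_cohort <- function(patients, visits, relapses = NULL) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)
  if (is.null(relapses) || !nrow(as.data.frame(relapses))) {
    relapses <- data.frame(patient_id = character(),
                           relapse_date = as.Date(character()))
  }
  relapses <- as.data.frame(relapses, stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing column(s): %s",
                   what, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(patients, c("patient_id", "sex", "age_at_baseline", "diagnosis_date",
                   "baseline_date", "course", "n_prior_dmts"), "patients")
  need(visits, c("patient_id", "visit_date", "edss"), "visits")
  need(relapses, c("patient_id", "relapse_date"), "relapses")

  patients$patient_id <- as.character(patients$patient_id)
  visits$patient_id <- as.character(visits$patient_id)
  relapses$patient_id <- as.character(relapses$patient_id)

  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients table: ",
         patients$patient_id[duplicated(patients$patient_id)][1],
         call. = FALSE)
  }
  if (!all(patients$sex %in% c("F", "M"))) {
    stop("patients$sex must be 'F' or 'M'", call. = FALSE)
  }
  if (!all(patients$course %in% c("RRMS", "PPMS"))) {
    stop("patients$course must be 'RRMS' or 'PPMS'", call. = FALSE)
  }
  if (any(is.na(patients$n_prior_dmts)) || any(patients$n_prior_dmts < 0)) {
    stop("patients$n_prior_dmts must be a non-negative count", call. = FALSE)
  }
  patients$diagnosis_date <- parse_date(patients$diagnosis_date, "patients$diagnosis_date")
  patients$baseline_date <- parse_date(patients$baseline_date, "patients$baseline_date")
  late <- which(patients$diagnosis_date > patients$baseline_date)
  if (length(late)) {
    stop(sprintf("patient %s: diagnosis_date after baseline_date",
                 patients$patient_id[late[1]]), call. = FALSE)
  }

  # optional covariates: fill with NA when absent
  if (!"cd19_detectable" %in% names(patients)) patients$cd19_detectable <- NA
  patients$cd19_detectable <- as.logical(patients$cd19_detectable)
  for (col in c("prnfl_worse", "mrnfl_worse", "gcipl_worse")) {
    if (!col %in% names(patients)) patients[[col]] <- NA_real_
    patients[[col]] <- as.numeric(patients[[col]])
  }

  visits$visit_date <- parse_date(visits$visit_date, "visits$visit_date")
  visits$edss <- as.numeric(visits$edss)
  bad <- which(!is_edss(visits$edss))
  if (length(bad)) {
    stop(sprintf("visits row %d (patient %s): edss = %s is not on the EDSS grid",
                 bad[1], visits$patient_id[bad[1]],
                 format(visits$edss[bad[1]])), call. = FALSE)
  }
  unknown <- setdiff(visits$patient_id, patients$patient_id)
  if (length(unknown)) {
    stop("visits reference unknown patient_id: ", unknown[1], call. = FALSE)
  }
  key <- paste(visits$patient_id, visits$visit_date)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate visit for patient %s on %s",
                 visits$patient_id[d], visits$visit_date[d]), call. = FALSE)
  }
  visits <- visits[order(visits$patient_id, visits$visit_date), , drop = FALSE]
  rownames(visits) <- NULL

  relapses$relapse_date <- parse_date(relapses$relapse_date, "relapses$relapse_date")
  orphan <- !(relapses$patient_id %in% patients$patient_id)
  if (any(orphan)) {
    warning(sprintf("rejected %d relapse row(s) without a matching patient", sum(orphan)))
    relapses <- relapses[!orphan, , drop = FALSE]
  }
  relapses <- relapses[order(relapses$patient_id, relapses$relapse_date), , drop = FALSE]
  rownames(relapses) <- NULL
  rownames(patients) <- NULL

  structure(list(patients = patients, visits = visits, relapses = relapses),
            class = "ms_cohort")
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf("ms_cohort: %d patients, %d EDSS visits, %d relapses\n",
              nrow(x$patients), nrow(x$visits), nrow(x$relapses)))
  cat(sprintf("  course: %s\n",
              paste(sprintf("%s=%d", names(table(x$patients$course)),
                            as.integer(table(x$patients$course))), collapse = ", ")))
  invisible(x)
}

# per-patient slices ---------------------------------------------------------

patient_visits <- function(cohort, id) {
  v <- cohort$visits[cohort$visits$patient_id == id, , drop = FALSE]
  rownames(v) <- NULL
  v
}

patient_relapses <- function(cohort, id) {
  cohort$relapses$relapse_date[cohort$relapses$patient_id == id]
}

# subset a cohort to a set of patient ids, keeping table order
subset_cohort <- function(cohort, ids) {
  ms_cohort(cohort$patients[cohort$patients$patient_id %in% ids, , drop = FALSE],
            cohort$visits[cohort$visits$patient_id %in% ids, , drop = FALSE],
            cohort$relapses[cohort$relapses$patient_id %in% ids, , drop = FALSE])
}

#' Read a cohort from its three-CSV representation
#'
#' @param visits_path CSV with columns \code{patient_id, visit_date, edss}.
#' @param relapses_path CSV with \code{patient_id, relapse_date}.
#' @param patients_path CSV with the patient covariate columns documented in
#'   [ms_cohort()] (\code{cd19_detectable} coded 0/1/NA).
#' @return A validated [ms_cohort()].
#' @export
read_cohort <- function(visits_path, relapses_path, patients_path) {
  for (p in c(visits_path, relapses_path, patients_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  # sex must be read as character ("F" would otherwise parse as FALSE)
  rd <- function(p) {
    cls <- c(patient_id = "character")
    if (grepl("sex", readLines(p, n = 1))) cls <- c(cls, sex = "character")
    utils::read.csv(p, stringsAsFactors = FALSE, colClasses = cls)
  }
  ms_cohort(patients = rd(patients_path),
            visits = rd(visits_path),
            relapses = rd(relapses_path))
}

#' Write a cohort to three CSV files
#'
#' Inverse of [read_cohort()]: \code{read_cohort()} on the written files
#' reproduces the cohort.
#'
#' @param cohort an [ms_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths (visits, relapses, patients).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ms_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("visits.csv", "relapses.csv", "patients.csv"))
  utils::write.csv(cohort$visits, paths[1], row.names = FALSE)
  utils::write.csv(cohort$relapses, paths[2], row.names = FALSE)
  p <- cohort$patients
  p$cd19_detectable <- as.integer(p$cd19_detectable)
  utils::write.csv(p, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Derive per-patient baseline quantities
#'
#' For each patient: the treatment-baseline EDSS (first visit on or after
#' \code{baseline_date}), disease duration in years at baseline
#' (\code{baseline_date - diagnosis_date}, at 365.25 d/y), the annualized
#' relapse rate over the two years before baseline (relapses in
#' \code{[baseline - 730 d, baseline)} divided by 2), and follow-up in months
#' (30.44 d/month) from baseline to the last visit.
#'
#' @param cohort an [ms_cohort()].
#' @param patient_id optional character vector restricting to some patients.
#' @return data.frame with columns \code{patient_id, disease_duration,
#'   baseline_edss, baseline_edss_date, baseline_arr, followup_months}.
#' @export
derive_baseline <- function(cohort, patient_id = NULL) {
  stopifnot(inherits(cohort, "ms_cohort"))
  ids <- patient_id %||% cohort$patients$patient_id
  rows <- lapply(ids, function(id) {
    p <- cohort$patients[cohort$patients$patient_id == id, ]
    if (!nrow(p)) stop("unknown patient_id: ", id, call. = FALSE)
    v <- patient_visits(cohort, id)
    on_tx <- v[v$visit_date >= p$baseline_date, , drop = FALSE]
    if (!nrow(on_tx)) {
      stop(sprintf("patient %s: no baseline EDSS (no visit on/after baseline_date)", id),
           call. = FALSE)
    }
    r <- patient_relapses(cohort, id)
    n_pre <- sum(r >= p$baseline_date - 730 & r < p$baseline_date)
    data.frame(
      patient_id = id,
      disease_duration = years_between(p$diagnosis_date, p$baseline_date),
      baseline_edss = on_tx$edss[1],
      baseline_edss_date = on_tx$visit_date[1],
      baseline_arr = n_pre / 2,
      followup_months = months_between(p$baseline_date, max(v$visit_date)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-patient outcome labels to CSV
#'
#' @param outcomes a data.frame of outcomes (as produced by
#'   [classify_cohort()], whose result may also be passed directly).
#' @param path output CSV path. Columns written: \code{patient_id, label,
#'   event_date, edss_change, followup_months}.
#' @return Invisibly, \code{path}.
#' @export
write_outcomes <- function(outcomes, path) {
  if (inherits(outcomes, "cda_classification")) outcomes <- outcomes$outcomes
  outcomes <- as.data.frame(outcomes)
  if (!nrow(outcomes)) stop("outcomes must be non-empty", call. = FALSE)
  cols <- c("patient_id", "label", "event_date", "edss_change", "followup_months")
  utils::write.csv(outcomes[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read an outcomes CSV written by [write_outcomes()]
#' @param path CSV path.
#' @return data.frame of outcomes with \code{event_date} parsed as Date.
#' @export
read_outcomes <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  out$event_date <- as.Date(out$event_date)
  out
}
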