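#' Classifier configuration
#'
#' Collects every threshold and window of the event definitions, with the
#' study defaults: a confirmed disability accumulation (CDA) event is an EDSS
#' increase over the previous assessment (the roving reference) of >= 1.0
#' point when the reference EDSS is <= 5.5, or >= 0.5 point when it is
#' > 5.5, confirmed at a later visit 12 or more weeks (84 days) after the
#' increase. PIRA additionally requires a relapse-free window of 84 days
#' before the reference visit and no relapse between reference and increase
#' visit.
#'
#' @param confirmation_days minimum days between increase and confirmation
#'   visit (default 84 = 12 weeks).
#' @param step_low_edss required EDSS step when reference EDSS <=
#'   \code{edss_cut} (default 1.0).
#' @param step_high_edss required step when reference EDSS > \code{edss_cut}
#'   (default 0.5).
#' @param edss_cut reference-EDSS cutpoint switching the step size (5.5).
#' @param pira_prewindow_days relapse-free window required before the
#'   reference visit for PIRA (default 84).
#' @param pira_relapse_window \code{"to_increase"} (default): relapses
#'   between increase and confirmation do not void PIRA (they count as
#'   superimposed relapses); \code{"to_confirmation"}: they do void PIRA.
#' @param baseline_relapse_exclusion_days eligibility: no relapse within this
#'   many days before therapy start (default 90 = three months).
#' @param min_followup_months eligibility: minimum follow-up (default 6).
#' @param max_baseline_edss eligibility: maximum baseline EDSS (default 7.0).
#' @param min_age,max_age eligibility age range in years (default 18-70).
#' @param require_sustained if TRUE (default), visits between the increase
#'   and its confirmation that fall back below threshold void the event.
#' @return An object of class \code{classifier_config}.
#' @export
classifier_config <- function(confirmation_days = 84,
                              step_low_edss = 1.0,
                              step_high_edss = 0.5,
                              edss_cut = 5.5,
                              pira_prewindow_days = 84,
                              pira_relapse_window = c("to_increase", "to_confirmation"),
                              baseline_relapse_exclusion_days = 90,
                              min_followup_months = 6,
                              max_baseline_edss = 7.0,
                              min_age = 18,
                              max_age = 70,
                              require_sustained = TRUE) {
  pira_relapse_window <- match.arg(pira_relapse_window)
  for (d in c(confirmation_days, pira_prewindow_days,
              baseline_relapse_exclusion_days, min_followup_months)) {
    if (!is.numeric(d) || length(d) != 1 || d <= 0) {
      stop("durations in classifier_config must be positive scalars", call. = FALSE)
    }
  }
  for (s in c(step_low_edss, step_high_edss)) {
    if (s <= 0 || abs(s * 2 - round(s * 2)) > 1e-8) {
      stop("step thresholds must be positive multiples of 0.5", call. = FALSE)
    }
  }
  structure(list(confirmation_days = confirmation_days,
                 step_low_edss = step_low_edss,
                 step_high_edss = step_high_edss,
                 edss_cut = edss_cut,
                 pira_prewindow_days = pira_prewindow_days,
                 pira_relapse_window = pira_relapse_window,
                 baseline_relapse_exclusion_days = baseline_relapse_exclusion_days,
                 min_followup_months = min_followup_months,
                 max_baseline_edss = max_baseline_edss,
                 min_age = min_age, max_age = max_age,
                 require_sustained = require_sustained),
            class = "classifier_config")
}

required_step <- function(ref_edss, config) {
  ifelse(ref_edss <= config$edss_cut, config$step_low_edss, config$step_high_edss)
}

#' Screen a set of patient records against the eligibility criteria
#'
#' Keeps records with relapsing-remitting course, age within
#' \code{[min_age, max_age]}, baseline EDSS <= \code{max_baseline_edss}, at
#' least two EDSS assessments on or after therapy start, follow-up of at
#' least \code{min_followup_months}, and no relapse in the
#' \code{baseline_relapse_exclusion_days} before baseline. Each excluded
#' patient is logged once with the first failing reason, checked in the
#' order: PPMS, incomplete data, short follow-up, high baseline EDSS, age,
#' recent relapse.
#'
#' @param cohort an [ms_cohort()] of candidate records.
#' @param config a [classifier_config()].
#' @return A list with \code{cohort} (the eligible [ms_cohort()]) and
#'   \code{exclusions} (data.frame \code{patient_id, reason}).
#' @export
screen_eligibility <- function(cohort, config = classifier_config()) {
  stopifnot(inherits(cohort, "ms_cohort"))
  reasons <- character(0)
  excluded <- character(0)
  for (i in seq_len(nrow(cohort$patients))) {
    p <- cohort$patients[i, ]
    v <- patient_visits(cohort, p$patient_id)
    on_tx <- v[v$visit_date >= p$baseline_date, , drop = FALSE]
    r <- patient_relapses(cohort, p$patient_id)
    reason <-
      if (p$course == "PPMS") "PPMS"
      else if (nrow(on_tx) < 2) "incomplete data"
      else if (months_between(p$baseline_date, max(on_tx$visit_date)) <
               config$min_followup_months)
        sprintf("follow-up < %g months", config$min_followup_months)
      else if (on_tx$edss[1] > config$max_baseline_edss)
        sprintf("baseline EDSS > %g", config$max_baseline_edss)
      else if (p$age_at_baseline < config$min_age ||
               p$age_at_baseline > config$max_age)
        sprintf("age outside %g-%g", config$min_age, config$max_age)
      else if (any(r >= p$baseline_date - config$baseline_relapse_exclusion_days &
                   r < p$baseline_date)) "recent relapse"
      else NA_character_
    if (!is.na(reason)) {
      excluded <- c(excluded, p$patient_id)
      reasons <- c(reasons, reason)
    }
  }
  keep <- setdiff(cohort$patients$patient_id, excluded)
  list(cohort = subset_cohort(cohort, keep),
       exclusions = data.frame(patient_id = excluded, reason = reasons,
                               stringsAsFactors = FALSE))
}

#' Detect confirmed disability-accumulation events for one patient
#'
#' Scans consecutive visit pairs with a roving reference (the previous
#' assessment). A qualifying increase becomes a CDA event if the earliest
#' visit at least \code{confirmation_days} after the increase still meets
#' the step threshold versus the same reference; with
#' \code{require_sustained} (default) every visit between increase and
#' confirmation must meet it as well. Events are returned in chronological
#' order of the increase visit, which dates the event.
#'
#' @param visits data.frame of one patient's visits (\code{visit_date},
#'   \code{edss}), sorted by date.
#' @param config a [classifier_config()].
#' @return data.frame with one row per event: reference, increase and
#'   confirmation dates and EDSS values, and the required step.
#' @export
detect_cda_events <- function(visits, config = classifier_config()) {
  visits <- as.data.frame(visits)
  n <- nrow(visits)
  empty <- data.frame(reference_date = as.Date(character()), reference_edss = numeric(),
                      increase_date = as.Date(character()), increase_edss = numeric(),
                      confirmation_date = as.Date(character()), confirmation_edss = numeric(),
                      step_required = numeric())
  if (n < 3) return(empty)
  dates <- visits$visit_date
  edss <- visits$edss
  out <- empty
  for (i in 2:n) {
    ref <- i - 1L
    step <- required_step(edss[ref], config)
    if (edss[i] - edss[ref] < step) next
    later <- which(as.numeric(dates - dates[i]) >= config$confirmation_days)
    if (!length(later)) next
    j <- later[1]
    confirmed <- edss[j] - edss[ref] >= step
    if (confirmed && config$require_sustained && j > i + 1) {
      confirmed <- all(edss[(i + 1):(j - 1)] - edss[ref] >= step)
    }
    if (!confirmed) next
    out <- rbind(out, data.frame(
      reference_date = dates[ref], reference_edss = edss[ref],
      increase_date = dates[i], increase_edss = edss[i],
      confirmation_date = dates[j], confirmation_edss = edss[j],
      step_required = step))
  }
  rownames(out) <- NULL
  out
}

#' Subtype one CDA event as RAW, PIRA or unclassified
#'
#' RAW: at least one relapse in the qualifying interval
#' \code{(reference_date, increase_date]} (a relapse on the day of a visit
#' belongs to the interval ending at that visit). Otherwise PIRA if no
#' relapse occurred in \code{[reference_date - pira_prewindow_days,
#' reference_date]} (and, under \code{pira_relapse_window =
#' "to_confirmation"}, none in \code{(increase_date, confirmation_date]}).
#' A relapse-free qualifying interval with a relapse shortly before the
#' reference is neither: \code{"unclassified"}.
#'
#' @param event a one-row data.frame from [detect_cda_events()].
#' @param relapses vector of relapse dates (or a data.frame with a
#'   \code{relapse_date} column).
#' @param config a [classifier_config()].
#' @return \code{"RAW"}, \code{"PIRA"} or \code{"unclassified"}.
#' @export
classify_event <- function(event, relapses, config = classifier_config()) {
  if (is.data.frame(relapses)) relapses <- relapses$relapse_date
  r <- as.Date(relapses)
  ref <- as.Date(event$reference_date)
  inc <- as.Date(event$increase_date)
  conf <- as.Date(event$confirmation_date)
  if (any(r > ref & r <= inc)) return("RAW")
  pre_free <- !any(r >= ref - config$pira_prewindow_days & r <= ref)
  post_free <- if (config$pira_relapse_window == "to_confirmation") {
    !any(r > inc & r <= conf)
  } else TRUE
  if (pre_free && post_free) "PIRA" else "unclassified"
}

# window of dates that defines a PIRA event (relapses inside cannot be SIR)
pira_window <- function(event, config) {
  end <- if (config$pira_relapse_window == "to_confirmation") {
    as.Date(event$confirmation_date)
  } else as.Date(event$increase_date)
  c(as.Date(event$reference_date) - config$pira_prewindow_days, end)
}

#' Label one patient from their classified CDA events
#'
#' The first CDA event determines the label: RAW -> \code{"RAW"};
#' PIRA -> \code{"PIRA_SIR"} if any on-treatment relapse lies outside the
#' PIRA-defining window (a superimposed relapse), else \code{"PIRA_noSIR"};
#' an unclassifiable first event -> \code{"CDA_unclassified"}. Patients with
#' no event are \code{"stable"}. EDSS change is last EDSS minus
#' treatment-baseline EDSS; follow-up runs from baseline to the last visit.
#'
#' @param visits one patient's visits (\code{visit_date}, \code{edss}).
#' @param relapses relapse dates (vector or data.frame).
#' @param baseline_date therapy initiation date.
#' @param config a [classifier_config()].
#' @param events optional precomputed [detect_cda_events()] output.
#' @param patient_id id copied into the result.
#' @return One-row data.frame: \code{patient_id, label, event_date,
#'   edss_change, followup_months, had_any_relapse}.
#' @export
label_patient <- function(visits, relapses, baseline_date,
                          config = classifier_config(),
                          events = NULL, patient_id = "") {
  visits <- as.data.frame(visits)
  if (is.data.frame(relapses)) relapses <- relapses$relapse_date
  relapses <- as.Date(relapses)
  baseline_date <- as.Date(baseline_date)
  if (is.null(events)) events <- detect_cda_events(visits, config)
  # relapses under therapy; pre-baseline relapses feed the ARR, not SIR
  on_tx_rel <- relapses[relapses >= baseline_date]

  if (nrow(events)) {
    first <- events[1, ]
    subtype <- classify_event(first, relapses, config)
    label <- switch(subtype,
      RAW = "RAW",
      unclassified = "CDA_unclassified",
      PIRA = {
        w <- pira_window(first, config)
        if (any(on_tx_rel < w[1] | on_tx_rel > w[2])) "PIRA_SIR" else "PIRA_noSIR"
      })
    event_date <- as.Date(first$increase_date)
  } else {
    label <- "stable"
    event_date <- as.Date(NA)
  }
  on_tx_visits <- visits[visits$visit_date >= baseline_date, , drop = FALSE]
  b_edss <- on_tx_visits$edss[1]
  last <- nrow(visits)
  data.frame(patient_id = patient_id,
             label = label,
             event_date = event_date,
             edss_change = visits$edss[last] - b_edss,
             followup_months = months_between(baseline_date, visits$visit_date[last]),
             had_any_relapse = length(on_tx_rel) > 0,
             stringsAsFactors = FALSE)
}

#' Classify every patient of an eligible cohort
#'
#' Runs [detect_cda_events()], [classify_event()] and [label_patient()] over
#' the cohort and tallies the outcome summary: CDA, PIRA and RAW as
#' percentages of the cohort and PIRA/RAW as percentages of CDA patients
#' (half-up rounding to one decimal).
#'
#' @param cohort an eligible [ms_cohort()] (see [screen_eligibility()]).
#' @param config a [classifier_config()].
#' @return Object of class \code{cda_classification}: list with
#'   \code{outcomes} (one row per patient), \code{events} (all CDA events
#'   with subtype), \code{summary} (counts and percentages), \code{config}.
#' @examples
#' cls <- classify_cohort(generate_fixture_cohort())
#' cls$summary$n_cda    # 23
#' cls$summary$pct_cda  # 23.7
#' @export
classify_cohort <- function(cohort, config = classifier_config()) {
  stopifnot(inherits(cohort, "ms_cohort"))
  outcome_rows <- list()
  event_rows <- list()
  for (id in cohort$patients$patient_id) {
    p <- cohort$patients[cohort$patients$patient_id == id, ]
    v <- patient_visits(cohort, id)
    r <- patient_relapses(cohort, id)
    ev <- detect_cda_events(v, config)
    if (nrow(ev)) {
      tagged <- ev
      tagged$subtype <- vapply(seq_len(nrow(ev)),
                               function(k) classify_event(ev[k, ], r, config),
                               character(1))
      event_rows[[id]] <- cbind(patient_id = id, tagged, stringsAsFactors = FALSE)
    }
    outcome_rows[[id]] <- label_patient(v, r, p$baseline_date, config,
                                        events = ev, patient_id = id)
  }
  outcomes <- do.call(rbind, outcome_rows)
  rownames(outcomes) <- NULL
  events <- if (length(event_rows)) {
    e <- do.call(rbind, event_rows); rownames(e) <- NULL; e
  } else {
    data.frame(patient_id = character(), reference_date = as.Date(character()),
               reference_edss = numeric(), increase_date = as.Date(character()),
               increase_edss = numeric(), confirmation_date = as.Date(character()),
               confirmation_edss = numeric(), step_required = numeric(),
               subtype = character())
  }

  n <- nrow(outcomes)
  n_cda <- sum(outcomes$label != "stable")
  n_pira <- sum(outcomes$label %in% c("PIRA_noSIR", "PIRA_SIR"))
  n_raw <- sum(outcomes$label == "RAW")
  pct <- function(x, d) if (d > 0) round_half_up(100 * x / d, 1) else 0.0
  summary <- list(
    n = n, n_cda = n_cda, n_pira = n_pira, n_raw = n_raw,
    n_pira_sir = sum(outcomes$label == "PIRA_SIR"),
    n_unclassified = sum(outcomes$label == "CDA_unclassified"),
    n_stable = sum(outcomes$label == "stable"),
    pct_cda = pct(n_cda, n), pct_pira = pct(n_pira, n), pct_raw = pct(n_raw, n),
    pira_pct_of_cda = pct(n_pira, n_cda), raw_pct_of_cda = pct(n_raw, n_cda))

  structure(list(outcomes = outcomes, events = events,
                 summary = summary, config = config),
            class = "cda_classification")
}

#' @export
print.cda_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Disability-accumulation classification of %d patients\n", s$n))
  cat(sprintf("  CDA : %2d (%.1f%%)\n", s$n_cda, s$pct_cda))
  cat(sprintf("  PIRA: %2d (%.1f%% of cohort, %.1f%% of CDA; %d with superimposed relapses)\n",
              s$n_pira, s$pct_pira, s$pira_pct_of_cda, s$n_pira_sir))
  cat(sprintf("  RAW : %2d (%.1f%% of cohort, %.1f%% of CDA)\n",
              s$n_raw, s$pct_raw, s$raw_pct_of_cda))
  if (s$n_unclassified) {
    cat(sprintf("  CDA unclassified: %d\n", s$n_unclassified))
  }
  cat(sprintf("  stable: %d\n", s$n_stable))
  invisible(x)
}

#' @export
summary.cda_classification <- function(object, ...) {
  tab <- table(factor(object$outcomes$label,
                      levels = c("stable", "RAW", "PIRA_noSIR", "PIRA_SIR",
                                 "CDA_unclassified")))
  list(label_counts = tab, summary = object$summary)
}
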