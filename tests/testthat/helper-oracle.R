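# Independent brute-force oracles and tiny random-data generators.
# These re-derive the event definitions directly from the stated predicates,
# without sharing code with the package internals.

# enumerate all (reference, increase, confirmation) visit triples and apply
# the threshold/window predicates literally; reference is the assessment
# immediately before the increase, confirmation the earliest visit >= 84 d
# after the increase, with every intermediate visit still above threshold
oracle_detect <- function(visits, confirmation_days = 84) {
  n <- nrow(visits)
  found <- list()
  if (n >= 3) for (i in 2:n) {
    r <- i - 1
    step <- if (visits$edss[r] <= 5.5) 1.0 else 0.5
    for (j in seq_len(n)) {
      if (j <= i) next
      if (as.numeric(visits$visit_date[j] - visits$visit_date[i]) < confirmation_days) next
      ok <- visits$edss[i] - visits$edss[r] >= step &&
        visits$edss[j] - visits$edss[r] >= step
      if (ok && j > i + 1) {
        for (k in (i + 1):(j - 1)) {
          if (visits$edss[k] - visits$edss[r] < step) ok <- FALSE
        }
      }
      if (ok) {
        found[[length(found) + 1]] <- data.frame(
          reference_date = visits$visit_date[r],
          increase_date = visits$visit_date[i],
          confirmation_date = visits$visit_date[j])
      }
      break # only the earliest qualifying confirmation visit counts
    }
  }
  if (length(found)) do.call(rbind, found) else
    data.frame(reference_date = as.Date(character()),
               increase_date = as.Date(character()),
               confirmation_date = as.Date(character()))
}

oracle_classify <- function(ref, inc, conf, relapses, prewindow = 84) {
  raw <- FALSE
  pre <- FALSE
  for (r in relapses) {
    if (r > ref && r <= inc) raw <- TRUE
    if (r >= ref - prewindow && r <= ref) pre <- TRUE
  }
  if (raw) "RAW" else if (!pre) "PIRA" else "unclassified"
}

random_patient_timeline <- function(max_visits = 8) {
  n <- sample(2:max_visits, 1)
  dates <- as.Date("2020-01-01") + sort(sample(0:700, n))
  k <- sample(0:3, 1)
  list(visits = data.frame(visit_date = dates,
                           edss = sample(edss_grid(), n, replace = TRUE)),
       relapses = if (k) as.Date("2020-01-01") + sort(sample(0:700, k)) else as.Date(character()))
}

# minimal valid cohort around hand-built timelines
toy_cohort <- function(visits_list, relapses_list = NULL, course = "RRMS",
                       baseline = as.Date("2020-01-01")) {
  ids <- sprintf("T%02d", seq_along(visits_list))
  pats <- data.frame(
    patient_id = ids, sex = rep(c("F", "M"), length.out = length(ids)),
    age_at_baseline = 40, diagnosis_date = baseline - 3000,
    baseline_date = baseline, course = course,
    n_prior_dmts = 1, stringsAsFactors = FALSE)
  vis <- do.call(rbind, lapply(seq_along(ids), function(i)
    cbind(patient_id = ids[i], visits_list[[i]])))
  rel <- NULL
  if (!is.null(relapses_list)) {
    rel <- do.call(rbind, Filter(Negate(is.null), lapply(seq_along(ids), function(i) {
      if (!length(relapses_list[[i]])) return(NULL)
      data.frame(patient_id = ids[i], relapse_date = relapses_list[[i]])
    })))
  }
  ms_cohort(pats, vis, rel)
}

d0 <- as.Date("2020-01-01")
visits_df <- function(offsets, edss) data.frame(visit_date = d0 + offsets, edss = edss)
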