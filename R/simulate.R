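#' Parameters of the stochastic cohort simulator
#'
#' Defaults describe a single-centre RRMS cohort starting B cell-depleting
#' therapy: 97 patients seen roughly every 6 months for 6-51 months, with
#' baseline EDSS 3.5 +/- 2.2 on the legal grid, pre-baseline annualized
#' relapse rate 0.7, a low on-treatment relapse rate, and a small
#' per-interval hazard of relapse-independent confirmed worsening.
#'
#' @param n_patients cohort size.
#' @param visit_interval_days mean days between visits.
#' @param visit_jitter_days uniform jitter (+/- days) on each interval.
#' @param followup_months_range min and max follow-up in months.
#' @param relapse_rate on-treatment relapses per patient-year.
#' @param prebaseline_arr target mean annualized relapse rate over the two
#'   years before baseline (relapses are placed 91-730 days before baseline,
#'   so every simulated patient passes the recent-relapse screen).
#' @param p_residual_deficit probability that an interval containing a
#'   relapse is given a confirmed threshold EDSS step (a RAW event).
#' @param pira_hazard per-interval probability of a relapse-independent
#'   confirmed EDSS step (a PIRA event) in intervals where one is legal.
#' @param edss_noise probability of a transient +/- 0.5 fluctuation at a
#'   visit; fluctuations never persist at two consecutive visits, so noise
#'   alone cannot be confirmed. Still, a downward fluctuation at a reference
#'   visit can manufacture an apparent confirmed step, as in real data.
#' @param baseline_edss_mean,baseline_edss_sd baseline EDSS distribution
#'   (snapped to the grid, clamped to [0, 6.5]).
#' @param disease_duration_mean,disease_duration_sd years since diagnosis.
#' @param age_mean,age_sd age at baseline, clamped to [18, 70].
#' @param p_female probability of female sex.
#' @param prior_dmts_mean Poisson mean of prior DMT count.
#' @param p_oct probability a patient has worse-eye OCT measurements.
#' @param p_cd19_detectable probability of detectable CD19+ B cells
#'   (>= 1 cell/ul) at end of infusion cycle, among measured patients.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return Object of class \code{simulation_params}.
#' @export
simulation_params <- function(n_patients = 97,
                              visit_interval_days = 180,
                              visit_jitter_days = 30,
                              followup_months_range = c(6, 51),
                              relapse_rate = 0.05,
                              prebaseline_arr = 0.7,
                              p_residual_deficit = 0.3,
                              pira_hazard = 0.045,
                              edss_noise = 0.05,
                              baseline_edss_mean = 3.5,
                              baseline_edss_sd = 2.2,
                              disease_duration_mean = 10.5,
                              disease_duration_sd = 8.5,
                              age_mean = 42.3,
                              age_sd = 10.7,
                              p_female = 0.486,
                              prior_dmts_mean = 2.3,
                              p_oct = 0.38,
                              p_cd19_detectable = 0.3,
                              seed = 1L) {
  p <- as.list(environment())
  probs <- c(p$p_residual_deficit, p$pira_hazard, p$edss_noise, p$p_female,
             p$p_oct, p$p_cd19_detectable)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (p$visit_interval_days <= 0) stop("visit_interval_days must be > 0", call. = FALSE)
  if (length(p$followup_months_range) != 2 ||
      diff(p$followup_months_range) < 0 || p$followup_months_range[1] <= 0) {
    stop("followup_months_range must be an increasing positive pair", call. = FALSE)
  }
  structure(p, class = "simulation_params")
}

#' Simulate a longitudinal MS cohort with known implanted events
#'
#' Generates EDSS trajectories on the legal grid with three ingredients:
#' relapse-associated confirmed steps (implanted in intervals containing a
#' relapse, with probability \code{p_residual_deficit}), relapse-independent
#' confirmed steps (per-interval hazard \code{pira_hazard}, only in
#' intervals with no relapse inside and none within 84 days before the
#' reference visit), and transient measurement noise. Implanted steps are
#' permanent, so every implant is confirmable at the next visit >= 84 days
#' later; implants are only placed where such a visit exists. No relapse is
#' placed within 90 days before baseline, so simulated patients are eligible
#' by construction.
#'
#' The generator keeps a ground-truth event log: attribute
#' \code{"event_log"} (data.frame \code{patient_id, type, reference_date,
#' increase_date}) and attribute \code{"trials"} (named counts of intervals
#' at risk of a PIRA or relapse-residual implant), supporting closure and
#' parameter-recovery checks against the classifier.
#'
#' @param params a [simulation_params()].
#' @return An [ms_cohort()] with attributes \code{event_log} and
#'   \code{trials}.
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  origin <- as.Date("2019-01-01")
  pat <- list(); vis <- list(); rel <- list(); log <- list()
  trials <- c(pira = 0L, raw = 0L)

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  for (i in seq_len(params$n_patients)) {
    id <- sprintf("S%04d", i)
    baseline <- origin + sample.int(365L, 1L) - 1L

    fu_days <- round(stats::runif(1, params$followup_months_range[1],
                                  params$followup_months_range[2]) * DAYS_PER_MONTH)
    offs <- 0
    repeat {
      gap <- max(30, round(params$visit_interval_days +
                             stats::runif(1, -params$visit_jitter_days,
                                          params$visit_jitter_days)))
      nxt <- offs[length(offs)] + gap
      if (nxt > fu_days) break
      offs <- c(offs, nxt)
    }
    # close the series at the end of follow-up so observed follow-up matches
    if (fu_days - offs[length(offs)] >= 30) offs <- c(offs, fu_days)
    else offs[length(offs)] <- fu_days
    nv <- length(offs)
    dates <- baseline + offs

    # relapses: pre-baseline (ARR calibration, outside the 90-day exclusion)
    # and on-treatment
    k_pre <- stats::rpois(1, 2 * params$prebaseline_arr)
    pre_rel <- if (k_pre) baseline - sample(91:730, k_pre, replace = TRUE) else as.Date(character())
    yrs <- offs[nv] / DAYS_PER_YEAR
    k_post <- stats::rpois(1, params$relapse_rate * yrs)
    post_rel <- if (k_post) baseline + sample.int(offs[nv], k_post, replace = TRUE) else as.Date(character())
    relapses <- sort(c(pre_rel, post_rel))

    # true trajectory with implanted confirmed steps
    b0 <- snap_edss(clamp(stats::rnorm(1, params$baseline_edss_mean,
                                       params$baseline_edss_sd), 0, 6.5))
    edss_true <- numeric(nv)
    edss_true[1] <- b0
    if (nv >= 2) for (v in 2:nv) {
      edss_true[v] <- edss_true[v - 1]
      confirmable <- any(offs >= offs[v] + 84)
      if (!confirmable || edss_true[v - 1] >= 10) next
      step <- if (edss_true[v - 1] <= 5.5) 1.0 else 0.5
      rel_in <- any(relapses > dates[v - 1] & relapses <= dates[v])
      rel_pre <- any(relapses >= dates[v - 1] - 84 & relapses <= dates[v - 1])
      implant <- NA_character_
      if (rel_in) {
        trials["raw"] <- trials["raw"] + 1L
        if (stats::runif(1) < params$p_residual_deficit) implant <- "RAW"
      } else if (!rel_pre) {
        trials["pira"] <- trials["pira"] + 1L
        if (stats::runif(1) < params$pira_hazard) implant <- "PIRA"
      }
      if (!is.na(implant)) {
        edss_true[v] <- min(edss_true[v - 1] + step, 10)
        log[[length(log) + 1]] <- data.frame(
          patient_id = id, type = implant,
          reference_date = dates[v - 1], increase_date = dates[v],
          stringsAsFactors = FALSE)
      }
    }

    # transient +/- 0.5 noise, never at two consecutive visits, grid-legal
    edss_obs <- edss_true
    if (params$edss_noise > 0 && nv >= 2) {
      prev_noisy <- FALSE
      for (v in seq_len(nv)) {
        if (!prev_noisy && stats::runif(1) < params$edss_noise) {
          cand <- edss_true[v] + sample(c(-0.5, 0.5), 1)
          if (is_edss(cand)) {
            edss_obs[v] <- cand
            prev_noisy <- TRUE
            next
          }
        }
        prev_noisy <- FALSE
      }
    }

    dd <- max(0.3, stats::rnorm(1, params$disease_duration_mean,
                                params$disease_duration_sd))
    has_oct <- stats::runif(1) < params$p_oct
    cd19 <- if (stats::runif(1) < 0.9) {
      stats::runif(1) < params$p_cd19_detectable
    } else NA

    pat[[i]] <- data.frame(
      patient_id = id,
      sex = if (stats::runif(1) < params$p_female) "F" else "M",
      age_at_baseline = round(clamp(stats::rnorm(1, params$age_mean, params$age_sd), 18, 70), 1),
      diagnosis_date = baseline - round(dd * DAYS_PER_YEAR),
      baseline_date = baseline,
      course = "RRMS",
      n_prior_dmts = stats::rpois(1, params$prior_dmts_mean),
      cd19_detectable = cd19,
      prnfl_worse = if (has_oct) round(stats::rnorm(1, 85, 13), 1) else NA_real_,
      mrnfl_worse = if (has_oct) round(stats::rnorm(1, 0.80, 0.12), 3) else NA_real_,
      gcipl_worse = if (has_oct) round(stats::rnorm(1, 1.68, 0.18), 3) else NA_real_,
      stringsAsFactors = FALSE)
    vis[[i]] <- data.frame(patient_id = id, visit_date = dates, edss = edss_obs,
                           stringsAsFactors = FALSE)
    if (length(relapses)) {
      rel[[i]] <- data.frame(patient_id = id, relapse_date = relapses,
                             stringsAsFactors = FALSE)
    }
  }

  cohort <- ms_cohort(do.call(rbind, pat), do.call(rbind, vis),
                      if (length(rel)) do.call(rbind, rel) else NULL)
  event_log <- if (length(log)) do.call(rbind, log) else {
    data.frame(patient_id = character(), type = character(),
               reference_date = as.Date(character()),
               increase_date = as.Date(character()))
  }
  event_log <- event_log[order(event_log$patient_id, event_log$increase_date), , drop = FALSE]
  rownames(event_log) <- NULL
  attr(cohort, "event_log") <- event_log
  attr(cohort, "trials") <- trials
  cohort
}
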