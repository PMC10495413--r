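#' Class composition of the deterministic fixture cohort
#'
#' Default counts reproduce the published cohort structure: 71 stable
#' patients without relapse, 3 with relapses and full remission (stable
#' EDSS), 3 with relapse-associated worsening, 16 with PIRA and no
#' superimposed relapse, 4 with PIRA plus superimposed relapses — 97
#' patients, of whom 23 carry a confirmed disability-accumulation event
#' (20 PIRA, 3 RAW).
#'
#' @param n_stable_no_relapse,n_relapse_full_remission,n_raw,n_pira_no_sir,n_pira_sir
#'   non-negative archetype counts.
#' @return Object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_stable_no_relapse = 71,
                         n_relapse_full_remission = 3,
                         n_raw = 3,
                         n_pira_no_sir = 16,
                         n_pira_sir = 4) {
  s <- as.list(environment())
  if (any(unlist(s) < 0)) stop("fixture counts must be >= 0", call. = FALSE)
  structure(s, class = "fixture_spec")
}

# one deterministic timeline following an archetype; i is the global
# patient index driving the covariate cycles, j the within-archetype index
fixture_patient <- function(i, j, archetype) {
  baseline <- as.Date("2019-07-01")
  id <- sprintf("P%03d", i)

  # covariate cycles chosen to approximate the published cohort marginals
  # (age 42.3 +/- 10.7, 48/97 female, mean prior DMTs 2.3, ARR 0.7,
  # shorter disease duration and fewer DMTs in the PIRA group)
  sex <- if (i == 97) "M" else if (i %% 2 == 1) "F" else "M"
  age <- 30 + ((i * 7) %% 26)
  pira <- archetype %in% c("pira_nosir", "pira_sir")
  dd_long <- c(1.5, 2.6, 4, 6, 9, 11, 13, 15.3, 18, 22, 27, 8, 3, 10, 16,
               5.5, 12, 20, 2, 14)
  dd_short <- c(0.8, 1.5, 2.2, 3, 4.5, 6, 7.5, 9, 11, 13.5, 2.6, 5, 16, 21)
  dd <- if (pira) dd_short[(j - 1) %% length(dd_short) + 1]
        else dd_long[(i - 1) %% length(dd_long) + 1]
  dmts <- if (pira) (j %% 4) else (i %% 5)
  cd19_pool <- c(FALSE, FALSE, TRUE, NA)
  cd19 <- cd19_pool[(i - 1) %% 4 + 1]
  has_oct <- (i %% 5) %in% c(1, 3)
  prnfl <- if (has_oct) 60 + ((i * 11) %% 46) else NA_real_
  mrnfl <- if (has_oct) 0.6 + ((i * 7) %% 41) / 100 else NA_real_
  gcipl <- if (has_oct) 1.4 + ((i * 9) %% 61) / 100 else NA_real_
  arr_counts <- c(0, 2, 1, 0, 3, 2, 0, 1, 4, 0, 2, 1, 3, 0, 1, 2)
  k_pre <- arr_counts[(i - 1) %% length(arr_counts) + 1]
  pre_rel <- if (k_pre) baseline - c(100, 200, 350, 500, 650)[seq_len(k_pre)] else NULL

  edss_pool <- c(1, 2, 2.5, 3, 3.5, 4, 1.5, 5, 3, 6, 2, 4.5, 3.5, 7, 0)

  relapse_offs <- integer(0)
  if (archetype == "stable") {
    nv <- 3 + (i %% 7)
    offs <- seq(0, by = 180, length.out = nv)
    b <- edss_pool[(j - 1) %% length(edss_pool) + 1]
    edss <- rep(b, nv)
    if (j %% 5 == 0 && b >= 1.5) edss[nv] <- b - 0.5
  } else if (archetype == "relapse_remission") {
    offs <- seq(0, by = 180, length.out = 5)
    b <- c(2, 3, 4)[(j - 1) %% 3 + 1]
    edss <- rep(b, 5)
    relapse_offs <- 250
  } else if (archetype == "raw") {
    offs <- seq(0, by = 180, length.out = 5)
    b <- c(2, 3, 4)[(j - 1) %% 3 + 1]
    edss <- c(b, rep(b + 1, 4))
    relapse_offs <- 150
  } else { # pira_nosir / pira_sir
    offs <- seq(0, by = 180, length.out = 6)
    if (archetype == "pira_nosir") {
      b_pool <- c(1, 2, 3, 3.5, 2.5, 4, 1.5, 3, 2, 5, 4.5, 3.5, 2, 6, 1, 3)
      t_pool <- c(1, 2, 2, 3, 1, 2, 3, 2, 1, 2, 2, 1, 3, 1, 2, 1)
    } else {
      b_pool <- c(2, 3, 2.5, 3.5)
      t_pool <- c(2, 2, 3, 3)
      relapse_offs <- 650
    }
    b <- b_pool[(j - 1) %% length(b_pool) + 1]
    target <- t_pool[(j - 1) %% length(t_pool) + 1]
    edss <- rep(b, 6)
    v <- 2
    while (edss[v - 1] - b < target && v <= 5) {
      step <- if (edss[v - 1] <= 5.5) 1.0 else 0.5
      edss[v:6] <- edss[v - 1] + step
      v <- v + 1
    }
  }

  list(
    patient = data.frame(
      patient_id = id, sex = sex, age_at_baseline = age,
      diagnosis_date = baseline - round(dd * DAYS_PER_YEAR),
      baseline_date = baseline, course = "RRMS", n_prior_dmts = dmts,
      cd19_detectable = cd19, prnfl_worse = prnfl, mrnfl_worse = mrnfl,
      gcipl_worse = gcipl, stringsAsFactors = FALSE),
    visits = data.frame(patient_id = id, visit_date = baseline + offs,
                        edss = edss, stringsAsFactors = FALSE),
    relapses = {
      dts <- c(pre_rel, if (length(relapse_offs)) baseline + relapse_offs)
      if (length(dts)) data.frame(patient_id = id, relapse_date = as.Date(dts, origin = "1970-01-01"),
                                  stringsAsFactors = FALSE) else NULL
    })
}

#' Generate the deterministic fixture cohort
#'
#' Builds hard-coded timeline archetypes (no randomness) whose downstream
#' classification reproduces the requested class counts exactly. With the
#' default [fixture_spec()] this is a 97-patient cohort in which
#' [classify_cohort()] finds 23 CDA patients (23.7%), 20 PIRA (20.6%, 4 of
#' them with superimposed relapses) and 3 RAW (3.1%). Covariates follow
#' fixed cycles that approximate the published cohort marginals; this is a
#' synthetic stand-in, not patient data.
#'
#' @param spec a [fixture_spec()].
#' @return An [ms_cohort()].
#' @export
generate_fixture_cohort <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  plan <- c(rep("stable", spec$n_stable_no_relapse),
            rep("relapse_remission", spec$n_relapse_full_remission),
            rep("raw", spec$n_raw),
            rep("pira_nosir", spec$n_pira_no_sir),
            rep("pira_sir", spec$n_pira_sir))
  if (!length(plan)) stop("fixture_spec with zero patients", call. = FALSE)
  within_idx <- stats::ave(seq_along(plan), plan, FUN = seq_along)
  parts <- lapply(seq_along(plan), function(i)
    fixture_patient(i, within_idx[i], plan[i]))
  rel <- do.call(rbind, Filter(Negate(is.null), lapply(parts, `[[`, "relapses")))
  ms_cohort(do.call(rbind, lapply(parts, `[[`, "patient")),
            do.call(rbind, lapply(parts, `[[`, "visits")),
            rel)
}

#' Generate the deterministic 200-record registry fixture
#'
#' Emulates the pre-screening registry of everyone who received at least one
#' infusion: the 97 eligible RRMS records of [generate_fixture_cohort()]
#' plus 56 PPMS records, 33 with incomplete EDSS series, 7 with follow-up
#' under six months, and 7 with baseline EDSS above 7.0. Running
#' [screen_eligibility()] on it reproduces the 200 -> 97 selection flow.
#'
#' @return An [ms_cohort()] of 200 records.
#' @export
generate_registry_fixture <- function() {
  eligible <- generate_fixture_cohort()
  baseline <- as.Date("2019-07-01")
  mk <- function(ids, course, offs, edss_val, age = 45, dd = 8) {
    list(
      patients = data.frame(
        patient_id = ids, sex = rep(c("F", "M"), length.out = length(ids)),
        age_at_baseline = age,
        diagnosis_date = baseline - round(dd * DAYS_PER_YEAR),
        baseline_date = baseline, course = course,
        n_prior_dmts = 1, cd19_detectable = NA,
        prnfl_worse = NA_real_, mrnfl_worse = NA_real_, gcipl_worse = NA_real_,
        stringsAsFactors = FALSE),
      visits = do.call(rbind, lapply(ids, function(id)
        data.frame(patient_id = id, visit_date = baseline + offs,
                   edss = edss_val, stringsAsFactors = FALSE))))
  }
  ppms <- mk(sprintf("XP%03d", 1:56), "PPMS", c(0, 180, 360), 4.0, age = 52, dd = 10)
  incomplete <- mk(sprintf("XI%03d", 1:33), "RRMS", 0, 3.0)
  short_fu <- mk(sprintf("XS%03d", 1:7), "RRMS", c(0, 120), 3.0)
  high_edss <- mk(sprintf("XE%03d", 1:7), "RRMS", c(0, 180, 360, 540), 7.5)
  extras <- list(ppms, incomplete, short_fu, high_edss)
  ms_cohort(rbind(eligible$patients, do.call(rbind, lapply(extras, `[[`, "patients"))),
            rbind(eligible$visits, do.call(rbind, lapply(extras, `[[`, "visits"))),
            eligible$relapses)
}
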