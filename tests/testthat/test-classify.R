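test_that("qualifying increases need the step for their reference EDSS and a confirmation", {
  cfg <- classifier_config()
  # 1.0-point increase from EDSS 3.0 confirmed 100 d later -> one event at d180
  ev <- detect_cda_events(visits_df(c(0, 180, 280), c(3, 4, 4)), cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$increase_date, d0 + 180)
  expect_equal(ev$confirmation_date, d0 + 280)
  # 0.5 step is not enough at reference <= 5.5
  expect_equal(nrow(detect_cda_events(visits_df(c(0, 180, 280), c(5.5, 6, 6)), cfg)), 0)
  # but suffices at reference > 5.5
  expect_equal(nrow(detect_cda_events(visits_df(c(0, 180, 280), c(6, 6.5, 6.5)), cfg)), 1)
  # unconfirmed increase (no third visit) is no event
  expect_equal(nrow(detect_cda_events(visits_df(c(0, 180), c(3, 4)), cfg)), 0)
  # confirmation visit must be >= 84 d after the increase
  expect_equal(nrow(detect_cda_events(visits_df(c(0, 180, 260), c(3, 4, 4)), cfg)), 0)
  # intermediate drop below threshold voids the event under the default config
  expect_equal(nrow(detect_cda_events(visits_df(c(0, 60, 180, 300), c(3, 4, 3.5, 4)), cfg)), 0)
})

test_that("event subtyping applies the relapse windows", {
  cfg <- classifier_config()
  ev <- detect_cda_events(visits_df(c(0, 180, 280), c(3, 4, 4)), cfg)[1, ]
  expect_equal(classify_event(ev, d0 + 150, cfg), "RAW")          # relapse in interval
  expect_equal(classify_event(ev, as.Date(character()), cfg), "PIRA")
  expect_equal(classify_event(ev, d0 - 30, cfg), "unclassified")  # within 84 d before reference
  expect_equal(classify_event(ev, d0 - 100, cfg), "PIRA")         # outside the prewindow
  # relapse on the increase day belongs to the interval ending there -> RAW
  expect_equal(classify_event(ev, d0 + 180, cfg), "RAW")
  # relapse between increase and confirmation: PIRA by default,
  # voided under the stricter window
  expect_equal(classify_event(ev, d0 + 230, cfg), "PIRA")
  strict <- classifier_config(pira_relapse_window = "to_confirmation")
  expect_equal(classify_event(ev, d0 + 230, strict), "unclassified")
})

test_that("a relapse shortly before a roving reference yields an unclassified CDA", {
  # visits (d0,3),(d90,3),(d180,4),(d270,4); relapse d30: the event's
  # reference is d90, the relapse sits 60 d before it
  cfg <- classifier_config()
  v <- visits_df(c(0, 90, 180, 270), c(3, 3, 4, 4))
  ev <- detect_cda_events(v, cfg)
  expect_equal(ev$reference_date, d0 + 90)
  expect_equal(classify_event(ev[1, ], d0 + 30, cfg), "unclassified")
  out <- label_patient(v, d0 + 30, d0, cfg)
  expect_equal(out$label, "CDA_unclassified")
})

test_that("patient labels follow the first event and superimposed relapses", {
  cfg <- classifier_config()
  v <- visits_df(c(0, 180, 360, 540), c(3, 4, 4, 4))
  # PIRA with a relapse far outside the defining window -> PIRA_SIR
  expect_equal(label_patient(v, d0 + 500, d0, cfg)$label, "PIRA_SIR")
  # no relapses ever -> PIRA_noSIR
  out <- label_patient(v, as.Date(character()), d0, cfg)
  expect_equal(out$label, "PIRA_noSIR")
  expect_false(out$had_any_relapse)
  expect_equal(out$edss_change, 1)
  # relapse with full remission -> stable but had_any_relapse
  vs <- visits_df(c(0, 180, 360), c(3, 3, 3))
  out <- label_patient(vs, d0 + 200, d0, cfg)
  expect_equal(out$label, "stable")
  expect_true(out$had_any_relapse)
  # pre-baseline relapses count neither as SIR nor as had_any_relapse
  out <- label_patient(v, d0 - 120, d0, cfg)
  expect_equal(out$label, "PIRA_noSIR")
  expect_false(out$had_any_relapse)
})

test_that("eligibility screening applies each rule with its reason", {
  cfg <- classifier_config()
  mk <- function(course = "RRMS", offs = c(0, 180, 360), edss = 3, age = 40,
                 rel = NULL) {
    co <- toy_cohort(list(visits_df(offs, rep(edss, length(offs)))),
                     if (!is.null(rel)) list(rel), course = course)
    co$patients$age_at_baseline <- age
    co
  }
  ok <- screen_eligibility(mk(), cfg)
  expect_equal(nrow(ok$cohort$patients), 1)
  expect_equal(nrow(ok$exclusions), 0)

  cases <- list(
    list(co = mk(course = "PPMS"), reason = "PPMS"),
    list(co = mk(offs = 0), reason = "incomplete data"),
    list(co = mk(offs = c(0, 150)), reason = "follow-up < 6 months"),
    list(co = mk(edss = 7.5), reason = "baseline EDSS > 7"),
    list(co = mk(age = 75), reason = "age outside 18-70"),
    list(co = mk(rel = d0 - 30), reason = "recent relapse"))
  for (cs in cases) {
    sc <- screen_eligibility(cs$co, cfg)
    expect_equal(nrow(sc$cohort$patients), 0)
    expect_equal(sc$exclusions$reason, cs$reason)
  }
  # a 5-month follow-up is too short
  sc <- screen_eligibility(mk(offs = c(0, 76, 152)), cfg)
  expect_equal(sc$exclusions$reason, "follow-up < 6 months")
})

test_that("detection and subtyping agree with the brute-force oracle", {
  set.seed(42)
  cfg <- classifier_config()
  for (rep in 1:200) {
    tl <- random_patient_timeline()
    got <- detect_cda_events(tl$visits, cfg)
    want <- oracle_detect(tl$visits)
    expect_equal(nrow(got), nrow(want), info = sprintf("rep %d", rep))
    if (nrow(want)) {
      expect_equal(got$reference_date, want$reference_date)
      expect_equal(got$increase_date, want$increase_date)
      expect_equal(got$confirmation_date, want$confirmation_date)
      for (k in seq_len(nrow(got))) {
        expect_equal(classify_event(got[k, ], tl$relapses, cfg),
                     oracle_classify(want$reference_date[k], want$increase_date[k],
                                     want$confirmation_date[k], tl$relapses))
      }
    }
  }
})

test_that("every patient receives exactly one label and counts partition the cohort", {
  for (s in 1:5) {
    co <- simulate_cohort(simulation_params(n_patients = 40, seed = s))
    cls <- classify_cohort(co)
    expect_equal(nrow(cls$outcomes), 40)
    expect_true(all(cls$outcomes$label %in%
      c("stable", "RAW", "PIRA_noSIR", "PIRA_SIR", "CDA_unclassified")))
    s0 <- cls$summary
    expect_equal(s0$n_stable + s0$n_cda, s0$n)
    expect_equal(s0$n_pira + s0$n_raw + s0$n_unclassified, s0$n_cda)
  }
})

test_that("longer confirmation and prewindow requirements never add events", {
  set.seed(11)
  for (rep in 1:40) {
    tl <- random_patient_timeline()
    n84 <- nrow(detect_cda_events(tl$visits, classifier_config(confirmation_days = 84)))
    n168 <- nrow(detect_cda_events(tl$visits, classifier_config(confirmation_days = 168)))
    expect_lte(n168, n84)
    ev <- detect_cda_events(tl$visits, classifier_config())
    if (nrow(ev)) {
      pira_n <- function(pw) sum(vapply(seq_len(nrow(ev)), function(k)
        classify_event(ev[k, ], tl$relapses,
                       classifier_config(pira_prewindow_days = pw)),
        character(1)) == "PIRA")
      expect_lte(pira_n(168), pira_n(84))
    }
  }
})

test_that("patients with non-increasing EDSS are stable regardless of relapses", {
  set.seed(5)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    edss <- sort(sample(edss_grid(), n, replace = TRUE), decreasing = TRUE)
    v <- visits_df(sort(sample(0:700, n)), edss)
    rel <- d0 + sample(0:700, sample(0:3, 1))
    expect_equal(label_patient(v, rel, d0)$label, "stable")
  }
})

test_that("summary percentages are computed from the cohort and CDA denominators", {
  cls <- classify_cohort(generate_fixture_cohort(fixture_spec(10, 0, 1, 3, 0)))
  s <- cls$summary
  expect_equal(s$pct_cda, round_half_up(100 * 4 / 14, 1))
  expect_equal(s$pira_pct_of_cda, round_half_up(100 * 3 / 4, 1))
  # all-stable cohort: every percentage 0
  s0 <- classify_cohort(generate_fixture_cohort(fixture_spec(5, 0, 0, 0, 0)))$summary
  expect_equal(s0$n_cda, 0)
  expect_equal(c(s0$pct_cda, s0$pct_pira, s0$pct_raw), c(0, 0, 0))
})
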