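fixture_cls <- local({
  co <- generate_fixture_cohort()
  list(cohort = co, cls = classify_cohort(co))
})

test_that("survival datasets count events and censorings per event type", {
  d_pira <- build_survival_dataset(fixture_cls$cls, fixture_cls$cohort, "PIRA")
  expect_equal(sum(d_pira$event), 20)
  expect_equal(sum(!d_pira$event), 77)
  expect_true(all(d_pira$time > 0))
  d_raw <- build_survival_dataset(fixture_cls$cls, fixture_cls$cohort, "RAW")
  expect_equal(sum(d_raw$event), 3)
  d_cda <- build_survival_dataset(fixture_cls$cls, fixture_cls$cohort, "CDA")
  expect_equal(sum(d_cda$event), 23)
  # event time is the increase visit, in months from baseline
  hit <- d_pira[d_pira$event, ][1, ]
  o <- fixture_cls$cls$outcomes
  expect_equal(hit$time,
               as.numeric(o$event_date[o$patient_id == hit$patient_id] -
                          as.Date("2019-07-01")) / 30.44)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  d <- data.frame(time = c(10, 20, 20, 30), event = c(TRUE, TRUE, FALSE, FALSE))
  km <- kaplan_meier(d)
  # by hand: S(10) = 3/4; at t=20 the event precedes the censoring:
  # S(20) = 3/4 * 2/3 = 1/2
  expect_equal(surv_prob(km, c(5, 10, 20, 25)), c(1, 0.75, 0.5, 0.5))
  # Greenwood variance at t=10: S^2 * d/(n(n-d)) = 0.75^2 * 1/12
  expect_equal(km$table$std_err[km$table$time == 10],
               sqrt(0.75^2 * 1 / 12), tolerance = 1e-8)

  # no events: flat survival at 1
  km0 <- kaplan_meier(data.frame(time = c(5, 8), event = c(FALSE, FALSE)))
  expect_equal(surv_prob(km0, c(1, 10)), c(1, 1))

  # all events, distinct times: equals the empirical survival function
  set.seed(1)
  tt <- sample(1:1000, 25)
  km1 <- kaplan_meier(data.frame(time = tt, event = TRUE))
  grid <- c(0, sort(tt))
  expect_equal(surv_prob(km1, grid), vapply(grid, function(g) mean(tt > g), numeric(1)))
})

test_that("KM estimates are monotone and CDA dominates its subtypes", {
  kms <- lapply(c("CDA", "PIRA", "RAW"), function(et)
    kaplan_meier(build_survival_dataset(fixture_cls$cls, fixture_cls$cohort, et)))
  for (km in kms) {
    s <- km$table$survival
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s <= 1 & s >= 0))
  }
  grid <- seq(0, 50, by = 1)
  s_cda <- surv_prob(kms[[1]], grid)
  expect_true(all(1 - s_cda >= 1 - surv_prob(kms[[2]], grid) - 1e-12))
  expect_true(all(1 - s_cda >= 1 - surv_prob(kms[[3]], grid) - 1e-12))
})

test_that("strata assignment uses interpolated quartiles with ties going low", {
  co <- fixture_cls$cohort
  st <- assign_strata(co, "disease_duration", "quartiles")
  v <- st$assignment$value
  q <- quantile(v, c(.25, .5, .75), type = 7, names = FALSE)
  expect_equal(st$cutpoints, q)
  expect_true(all(st$assignment$group[v <= q[1]] == "Q1"))
  expect_true(all(st$assignment$group[v > q[3]] == "Q4"))
  # a value exactly on a cutpoint goes to the lower group
  on_cut <- which(abs(v - q[1]) < 1e-12)
  if (length(on_cut)) expect_true(all(st$assignment$group[on_cut] == "Q1"))

  thr <- assign_strata(co, "baseline_edss", "threshold", cutpoints = 4.0)
  a <- thr$assignment
  expect_setequal(levels(a$group), c("<= 4", "> 4"))
  expect_true(all((a$value <= 4) == (a$group == "<= 4")))

  # missing values are excluded and counted
  oct <- assign_strata(co, "prnfl_worse", "quartiles")
  expect_equal(oct$n_missing, sum(is.na(co$patients$prnfl_worse)))
  expect_equal(nrow(oct$assignment) + oct$n_missing, nrow(co$patients))

  # constant variable: single stratum with a warning
  co2 <- co
  co2$patients$age_at_baseline <- 40
  expect_warning(st2 <- assign_strata(co2, "age_at_baseline", "quartiles"), "constant")
  expect_equal(nlevels(factor(st2$assignment$group)), 1)

  co3 <- co
  co3$patients$prnfl_worse <- NA_real_
  expect_error(assign_strata(co3, "prnfl_worse", "quartiles"), "missing for all")
})

test_that("the Cox fit maximizes the partial likelihood (brute-force check)", {
  # 6 subjects, distinct event times, one binary covariate; with no ties the
  # Efron fit equals the plain partial-likelihood maximizer
  d <- data.frame(patient_id = as.character(1:6),
                  time = c(3, 5, 7, 9, 11, 13),
                  event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                  x = c(1, 0, 1, 1, 0, 0))
  logpl <- function(b) {
    lp <- b * d$x
    s <- 0
    for (i in which(d$event)) {
      risk <- d$time >= d$time[i]
      s <- s + lp[i] - log(sum(exp(lp[risk])))
    }
    s
  }
  b_hat <- optimize(logpl, c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d, ties = "efron")
  expect_equal(unname(coef(fit)), b_hat, tolerance = 1e-6)
  # the package wrapper reports the same hazard ratio
  d$.grp <- factor(d$x)
  cr <- cox_fit(d, ".grp", adjust = character(0))
  expect_equal(cr$terms$hr, exp(b_hat), tolerance = 1e-5)
})

test_that("cox_fit recovers a known hazard ratio and errors sensibly", {
  set.seed(20)
  n <- 400
  grp <- rep(c(0, 1), each = n / 2)
  haz <- 0.05 * 2^grp                # true HR = 2
  t_event <- rexp(n, haz)
  t_cens <- runif(n, 10, 40)
  d <- data.frame(patient_id = as.character(1:n),
                  time = pmin(t_event, t_cens),
                  event = t_event <= t_cens,
                  g = factor(grp, labels = c("low", "high")))
  cr <- cox_fit(d, "g", adjust = character(0))
  expect_gt(cr$terms$hr[1], 1.6)
  expect_lt(cr$terms$hr[1], 2.5)
  expect_true(cr$terms$lower[1] < cr$terms$hr[1] & cr$terms$hr[1] < cr$terms$upper[1])

  d0 <- d; d0$event <- FALSE
  expect_error(cox_fit(d0, "g", adjust = character(0)), "no events")
  # monotone likelihood (all events in one group before any in the other)
  ds <- data.frame(patient_id = as.character(1:8),
                   time = c(1, 2, 3, 4, 10, 11, 12, 13),
                   event = c(rep(TRUE, 4), rep(FALSE, 4)),
                   g = factor(rep(c("a", "b"), each = 4)))
  expect_error(cox_fit(ds, "g", adjust = character(0)), "converge|separation")
})

test_that("under the null the group p-values are approximately uniform", {
  set.seed(99)
  pvals <- replicate(200, {
    n <- 100
    d <- data.frame(patient_id = as.character(1:n),
                    time = rexp(n, 0.1) + 0.01,
                    event = runif(n) < 0.7,
                    g = factor(sample(c("a", "b"), n, replace = TRUE)))
    cox_fit(d, "g", adjust = character(0))$terms$p[1]
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # CI coverage of the null HR = 1
  cover <- mean(replicate(100, {
    n <- 120
    d <- data.frame(patient_id = as.character(1:n),
                    time = rexp(n, 0.1) + 0.01,
                    event = runif(n) < 0.7,
                    g = factor(sample(c("a", "b"), n, replace = TRUE)))
    cr <- cox_fit(d, "g", adjust = character(0))
    cr$terms$lower[1] <= 1 && 1 <= cr$terms$upper[1]
  }))
  expect_gte(cover, 0.9)
})

test_that("adjustment covariates defining the grouping are dropped", {
  d <- build_survival_dataset(fixture_cls$cls, fixture_cls$cohort, "PIRA")
  st <- assign_strata(fixture_cls$cohort, "sex", "binary")
  cr <- cox_fit(d, st)
  expect_false(any(grepl("^sex$", all.vars(formula(cr$fit)))))
  expect_true(any(grepl("baseline_edss", cr$terms$term)))
})
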