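#' Build a time-to-first-event dataset
#'
#' One row per patient: \code{time} in months (days / 30.44) from baseline
#' to the increase visit of the patient's first CDA event when that event
#' matches \code{event_type} (for \code{"CDA"}, any subtype), otherwise to
#' the last visit with \code{event = FALSE} (right censoring). The first of
#' the two visits showing the EDSS increase dates the event. Baseline
#' covariates and derived quantities are attached for adjustment and
#' stratification.
#'
#' @param classification a [classify_cohort()] result.
#' @param cohort the [ms_cohort()] that was classified.
#' @param event_type one of \code{"CDA"}, \code{"PIRA"}, \code{"RAW"}.
#' @return data.frame with \code{patient_id, time, event} and covariate
#'   columns (\code{age_at_baseline, sex, baseline_edss, baseline_arr,
#'   disease_duration, n_prior_dmts, first_line, cd19_detectable,
#'   prnfl_worse, mrnfl_worse, gcipl_worse, followup_months}).
#' @export
build_survival_dataset <- function(classification, cohort,
                                   event_type = c("CDA", "PIRA", "RAW")) {
  event_type <- match.arg(event_type)
  stopifnot(inherits(classification, "cda_classification"),
            inherits(cohort, "ms_cohort"))
  if (!nrow(cohort$patients)) stop("empty cohort", call. = FALSE)
  out <- classification$outcomes
  base <- derive_baseline(cohort)
  rows <- lapply(out$patient_id, function(id) {
    o <- out[out$patient_id == id, ]
    p <- cohort$patients[cohort$patients$patient_id == id, ]
    b <- base[base$patient_id == id, ]
    hit <- switch(event_type,
      CDA = o$label != "stable",
      PIRA = o$label %in% c("PIRA_noSIR", "PIRA_SIR"),
      RAW = o$label == "RAW")
    time <- if (hit) months_between(p$baseline_date, o$event_date) else o$followup_months
    data.frame(patient_id = id, time = time, event = hit,
               age_at_baseline = p$age_at_baseline, sex = p$sex,
               baseline_edss = b$baseline_edss, baseline_arr = b$baseline_arr,
               disease_duration = b$disease_duration,
               n_prior_dmts = p$n_prior_dmts,
               first_line = p$n_prior_dmts == 0,
               cd19_detectable = p$cd19_detectable,
               prnfl_worse = p$prnfl_worse, mrnfl_worse = p$mrnfl_worse,
               gcipl_worse = p$gcipl_worse,
               followup_months = o$followup_months,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps \code{survival::survfit}: product-limit survival with Greenwood
#' standard errors, ties handled by processing events before censorings at
#' equal times. The cumulative event probability is \code{1 - S(t)}.
#'
#' @param data a data.frame with \code{time} and logical/0-1 \code{event}
#'   columns (e.g. from [build_survival_dataset()]).
#' @param group optional name of a grouping column in \code{data}, or a
#'   [assign_strata()] result merged by \code{patient_id}.
#' @param conf_level confidence level for the pointwise interval.
#' @return Object of class \code{km_estimate}: list with \code{table}
#'   (stratum, time, n_risk, n_event, n_censor, survival, std_err, lower,
#'   upper) and the underlying \code{survfit} object.
#' @export
kaplan_meier <- function(data, group = NULL, conf_level = 0.95) {
  data <- as.data.frame(data)
  if (!nrow(data)) stop("need at least one observation", call. = FALSE)
  data$.event <- as.integer(data$event)
  if (!is.null(group)) {
    if (inherits(group, "strata_assignment")) {
      data <- merge(data, group$assignment[, c("patient_id", "group")],
                    by = "patient_id")
      data$.group <- data$group
    } else {
      data$.group <- data[[group]]
    }
    fit <- survival::survfit(survival::Surv(time, .event) ~ .group,
                             data = data, conf.int = conf_level)
  } else {
    fit <- survival::survfit(survival::Surv(time, .event) ~ 1,
                             data = data, conf.int = conf_level)
  }
  s <- summary(fit, censored = TRUE)
  tab <- data.frame(
    stratum = if (is.null(s$strata)) "all" else sub("^\\.group=", "", as.character(s$strata)),
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, survival = s$surv, std_err = s$std.err,
    lower = s$lower, upper = s$upper, stringsAsFactors = FALSE)
  structure(list(table = tab, fit = fit, conf_level = conf_level),
            class = "km_estimate")
}

#' Evaluate a Kaplan-Meier estimate at given times
#'
#' @param km a [kaplan_meier()] result.
#' @param times numeric vector of times.
#' @param stratum stratum label (default: the single stratum).
#' @return Numeric vector of survival probabilities S(t) (right-continuous
#'   step function; 1 before the first event).
#' @export
surv_prob <- function(km, times, stratum = NULL) {
  stopifnot(inherits(km, "km_estimate"))
  tab <- km$table
  if (is.null(stratum)) {
    if (length(unique(tab$stratum)) > 1) stop("specify a stratum", call. = FALSE)
  } else {
    tab <- tab[tab$stratum == stratum, , drop = FALSE]
    if (!nrow(tab)) stop("unknown stratum: ", stratum, call. = FALSE)
  }
  drop <- tab[tab$n_event > 0, , drop = FALSE]
  if (!nrow(drop)) return(rep(1, length(times)))
  f <- stats::stepfun(drop$time, c(1, drop$survival), right = FALSE)
  f(times)
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate\n")
  print(x$fit)
  invisible(x)
}

#' Assign patients to strata of a baseline variable
#'
#' Supports the stratification schemes used in the subgroup analyses:
#' quartiles (cutpoints by linear interpolation of order statistics, type-7
#' quantiles), a median split, an explicit threshold, or the variable's own
#' categories (\code{"binary"}). Values equal to a cutpoint go to the lower
#' group. Patients with missing values are excluded and counted.
#'
#' @param cohort an [ms_cohort()].
#' @param variable covariate name: a column of the patients table, or a
#'   derived quantity (\code{disease_duration, baseline_edss, baseline_arr,
#'   followup_months, first_line}).
#' @param scheme \code{"quartiles"}, \code{"median"}, \code{"threshold"} or
#'   \code{"binary"}.
#' @param cutpoints required for \code{"threshold"}: ordered numeric
#'   cutpoint(s).
#' @return Object of class \code{strata_assignment}: list with
#'   \code{variable, scheme, cutpoints}, \code{assignment} (data.frame
#'   \code{patient_id, value, group}) and \code{n_missing}.
#' @export
assign_strata <- function(cohort, variable,
                          scheme = c("quartiles", "median", "threshold", "binary"),
                          cutpoints = NULL) {
  scheme <- match.arg(scheme)
  v <- covariate_values(cohort, variable)
  miss <- is.na(v)
  if (all(miss)) stop("variable '", variable, "' is missing for all patients", call. = FALSE)
  vv <- v[!miss]
  ids <- names(v)[!miss]
  if (scheme == "binary") {
    grp <- factor(vv)
    cutpoints <- NULL
  } else {
    cutpoints <- switch(scheme,
      quartiles = stats::quantile(vv, c(0.25, 0.5, 0.75), type = 7, names = FALSE),
      median = stats::median(vv),
      threshold = {
        if (is.null(cutpoints)) stop("threshold scheme needs cutpoints", call. = FALSE)
        sort(cutpoints)
      })
    if (scheme == "quartiles" && length(vv) < 4) {
      stop("quartile stratification needs >= 4 non-missing values", call. = FALSE)
    }
    br <- unique(c(-Inf, cutpoints, Inf))
    if (length(unique(vv)) == 1) {
      warning("variable '", variable, "' is constant; single stratum")
      grp <- factor(rep("all", length(vv)))
    } else {
      labs <- if (scheme == "quartiles" && length(br) == 5) {
        paste0("Q", 1:4)
      } else if (length(br) == 3) {
        c(sprintf("<= %g", br[2]), sprintf("> %g", br[2]))
      } else NULL
      grp <- cut(vv, breaks = br, right = TRUE, labels = labs)
    }
  }
  structure(list(variable = variable, scheme = scheme, cutpoints = cutpoints,
                 assignment = data.frame(patient_id = ids, value = vv,
                                         group = grp, stringsAsFactors = FALSE),
                 n_missing = sum(miss)),
            class = "strata_assignment")
}

# look up a covariate vector (named by patient_id), deriving when needed
covariate_values <- function(cohort, variable) {
  p <- cohort$patients
  if (variable %in% names(p)) {
    v <- p[[variable]]
  } else if (variable == "first_line") {
    v <- p$n_prior_dmts == 0
  } else if (variable %in% c("disease_duration", "baseline_edss",
                             "baseline_arr", "followup_months")) {
    v <- derive_baseline(cohort)[[variable]]
  } else {
    stop("unknown covariate: ", variable, call. = FALSE)
  }
  stats::setNames(v, p$patient_id)
}

#' Covariate-adjusted Cox proportional-hazards subgroup model
#'
#' Partial-likelihood fit (\code{survival::coxph}, Efron tie handling) of
#' the time-to-event data on the stratification groups, adjusted by default
#' for age at therapy initiation, sex, baseline EDSS and baseline ARR; an
#' adjustment covariate is dropped automatically when it defines the
#' grouping. Hazard ratios with Wald confidence intervals and p-values.
#'
#' @param data a [build_survival_dataset()] data.frame.
#' @param group a [assign_strata()] result (merged by \code{patient_id}) or
#'   the name of a factor column in \code{data}.
#' @param adjust adjustment covariate names.
#' @param conf_level confidence level.
#' @return Object of class \code{cox_result}: list with \code{terms}
#'   (data.frame \code{term, hr, lower, upper, p}), \code{n},
#'   \code{n_events}, the grouping \code{variable}, and the fitted model.
#' @export
cox_fit <- function(data, group,
                    adjust = c("age_at_baseline", "sex", "baseline_edss", "baseline_arr"),
                    conf_level = 0.95) {
  data <- as.data.frame(data)
  grouping_var <- NULL
  if (inherits(group, "strata_assignment")) {
    grouping_var <- group$variable
    data <- merge(data, stats::setNames(group$assignment[, c("patient_id", "group")],
                                        c("patient_id", ".group")),
                  by = "patient_id")
  } else if (is.character(group) && length(group) == 1) {
    grouping_var <- group
    data$.group <- data[[group]]
  } else {
    stop("group must be a strata_assignment or a column name", call. = FALSE)
  }
  data$.group <- factor(data$.group)
  data <- data[!is.na(data$.group), , drop = FALSE]
  adjust <- setdiff(adjust, grouping_var)
  keep <- stats::complete.cases(data[, c("time", "event", adjust), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  data$.group <- droplevels(data$.group)
  if (nlevels(data$.group) < 2) stop("fewer than 2 groups with data", call. = FALSE)
  if (sum(data$event) < 1) stop("no events", call. = FALSE)

  rhs <- paste(c(".group", adjust), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, as.integer(event)) ~", rhs))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("infinite|converge", warn))) {
    stop("Cox model did not converge (possible complete separation): ",
         paste(warn, collapse = "; "), call. = FALSE)
  }
  sm <- summary(fit, conf.int = conf_level)
  co <- sm$coefficients
  ci <- sm$conf.int
  terms <- data.frame(term = sub("^\\.group", paste0(grouping_var, ":"), rownames(co)),
                      hr = unname(co[, "exp(coef)"]),
                      lower = unname(ci[, 3]), upper = unname(ci[, 4]),
                      p = unname(co[, "Pr(>|z|)"]),
                      stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  structure(list(terms = terms, n = nrow(data), n_events = sum(data$event),
                 variable = grouping_var, fit = fit, warnings = warn),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards model: %d patients, %d events (grouping: %s)\n",
              x$n, x$n_events, x$variable))
  tt <- x$terms
  tt$hr <- signif(tt$hr, digits); tt$lower <- signif(tt$lower, digits)
  tt$upper <- signif(tt$upper, digits); tt$p <- signif(tt$p, digits)
  print(tt, row.names = FALSE)
  invisible(x)
}
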