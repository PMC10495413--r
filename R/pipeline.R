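default_stratifications <- function() {
  list(list(variable = "disease_duration", scheme = "quartiles"),
       list(variable = "n_prior_dmts", scheme = "median"),
       list(variable = "first_line", scheme = "binary"),
       list(variable = "baseline_arr", scheme = "median"),
       list(variable = "baseline_edss", scheme = "threshold", cutpoints = 4.0),
       list(variable = "sex", scheme = "binary"),
       list(variable = "cd19_detectable", scheme = "binary"),
       list(variable = "prnfl_worse", scheme = "quartiles"),
       list(variable = "mrnfl_worse", scheme = "quartiles"),
       list(variable = "gcipl_worse", scheme = "quartiles"))
}

#' Run the full disability-accumulation analysis
#'
#' End-to-end orchestration of the pipeline: load (or generate) a cohort,
#' screen eligibility, classify CDA/PIRA/RAW outcomes, build the cohort
#' characteristics table, compare EDSS change across the four outcome
#' groups (Kruskal-Wallis + Dunn), estimate Kaplan-Meier curves per event
#' type, fit covariate-adjusted Cox subgroup models for each configured
#' stratification (PIRA as the outcome), and compute the propensity-score
#' comparison table. Deterministic given the configuration and seed.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Recognized keys (all optional): \code{input} — either
#'   \code{list(type = "fixture")} (default), \code{list(type = "simulate",
#'   params...)} with [simulation_params()] fields, or \code{list(type =
#'   "csv", visits = , relapses = , patients = )}; \code{classifier} —
#'   overrides for [classifier_config()] fields; \code{event_types};
#'   \code{stratifications} — list of \code{list(variable, scheme,
#'   cutpoints)}; \code{seed}.
#' @param out_dir optional directory: all tables are written there as CSV
#'   plus a plain-text summary.
#' @return Object of class \code{analysis_report}; see Details for
#'   components.
#' @details The report holds \code{exclusions} (flow log), the
#'   \code{classification}, \code{table1}, \code{group_comparison} (EDSS
#'   change across stable/RAW/PIRA-SIR/PIRA+SIR), \code{km} (per event
#'   type), \code{cox} (per stratification; entries that fail — e.g. no
#'   events in a stratum — carry the error message instead), the
#'   \code{propensity} table, and a \code{provenance} block (config hash,
#'   seed, package version).
#' @export
run_analysis <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  input <- config$input %||% list(type = "fixture")
  registry <- stage("load", switch(input$type %||% "fixture",
    fixture = generate_fixture_cohort(do.call(
      fixture_spec, input[setdiff(names(input), "type")])),
    simulate = {
      prm <- input[setdiff(names(input), "type")]
      if (is.null(prm$seed)) prm$seed <- seed
      simulate_cohort(do.call(simulation_params, prm))
    },
    csv = read_cohort(input$visits, input$relapses, input$patients),
    stop("unknown input type: ", input$type)))

  cfg <- stage("config", do.call(classifier_config, config$classifier %||% list()))
  screened <- stage("screen", screen_eligibility(registry, cfg))
  cohort <- screened$cohort
  cls <- stage("classify", classify_cohort(cohort, cfg))
  tab1 <- stage("table1", summarize_table1(cohort, cls))

  grp_cmp <- stage("group_comparison", {
    lv <- c(stable = "stable", RAW = "RAW", `PIRA-SIR` = "PIRA_noSIR",
            `PIRA+SIR` = "PIRA_SIR")
    groups <- lapply(lv, function(l)
      cls$outcomes$edss_change[cls$outcomes$label == l])
    groups <- groups[lengths(groups) > 0]
    if (length(groups) >= 2) kruskal_wallis_dunn(groups) else NULL
  })

  event_types <- config$event_types %||% c("CDA", "PIRA", "RAW")
  km <- stage("kaplan_meier", {
    out <- lapply(event_types, function(et)
      kaplan_meier(build_survival_dataset(cls, cohort, et)))
    stats::setNames(out, event_types)
  })

  strats <- config$stratifications %||% default_stratifications()
  surv_pira <- stage("survival_dataset", build_survival_dataset(cls, cohort, "PIRA"))
  cox <- lapply(strats, function(s) {
    tryCatch({
      grp <- do.call(assign_strata,
                     c(list(cohort = cohort, variable = s$variable,
                            scheme = s$scheme),
                       if (!is.null(s$cutpoints)) list(cutpoints = s$cutpoints)))
      cox_fit(surv_pira, grp)
    }, error = function(e) {
      list(variable = s$variable, error = conditionMessage(e))
    })
  })
  names(cox) <- vapply(strats, `[[`, character(1), "variable")

  propensity <- tryCatch(propensity_scores(cohort, cls),
                         error = function(e) list(error = conditionMessage(e)))

  tmp <- tempfile()
  writeLines(utils::capture.output(utils::str(config)), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  report <- structure(list(
    n_input = nrow(registry$patients),
    exclusions = screened$exclusions,
    classification = cls,
    table1 = tab1,
    group_comparison = grp_cmp,
    km = km,
    cox = cox,
    propensity = propensity,
    provenance = list(config_hash = cfg_hash, seed = seed,
                      package_version = as.character(utils::packageVersion("pira")))),
    class = "analysis_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# write the report bundle as CSVs plus a readable summary
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(report$exclusions, "exclusions.csv")
  write_outcomes(report$classification, file.path(out_dir, "outcomes.csv"))
  w(report$classification$events, "events.csv")
  for (et in names(report$km)) w(report$km[[et]]$table, sprintf("km_%s.csv", tolower(et)))
  cox_rows <- do.call(rbind, lapply(names(report$cox), function(v) {
    cr <- report$cox[[v]]
    if (!is.null(cr$error)) {
      data.frame(variable = v, term = NA, hr = NA, lower = NA, upper = NA,
                 p = NA, n = NA, n_events = NA, note = cr$error)
    } else {
      cbind(variable = v, cr$terms, n = cr$n, n_events = cr$n_events, note = "")
    }
  }))
  w(cox_rows, "cox.csv")
  if (is.null(report$propensity$error)) {
    w(report$propensity$comparisons, "propensity.csv")
  }
  writeLines(utils::capture.output(print(report)), file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis of %d screened records -> %d eligible patients\n",
              x$n_input, x$classification$summary$n))
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$reason)
    for (r in names(tab)) cat(sprintf("  excluded, %s: %d\n", r, tab[[r]]))
  }
  print(x$classification)
  if (!is.null(x$group_comparison)) {
    cat(sprintf("EDSS change across outcome groups: Kruskal-Wallis H = %.3f, p = %.3g\n",
                x$group_comparison$statistic, x$group_comparison$p))
  }
  for (v in names(x$cox)) {
    cr <- x$cox[[v]]
    if (!is.null(cr$error)) {
      cat(sprintf("Cox [%s]: not fitted (%s)\n", v, cr$error))
    } else {
      i <- which.min(cr$terms$p[grepl(paste0("^", v), cr$terms$term)])
      t0 <- cr$terms[grepl(paste0("^", v), cr$terms$term), ][i, ]
      cat(sprintf("Cox [%s]: HR %.2f (%.2f-%.2f), p = %.3g (%d events)\n",
                  v, t0$hr, t0$lower, t0$upper, t0$p, cr$n_events))
    }
  }
  cat(sprintf("Provenance: seed %s, config %s, pira %s\n",
              x$provenance$seed, substr(x$provenance$config_hash, 1, 8),
              x$provenance$package_version))
  invisible(x)
}
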