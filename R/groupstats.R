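#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration when both samples have at most 8 observations and no
#' ties are present; otherwise the tie-corrected normal approximation with
#' continuity correction. \code{U} is the statistic for the first sample
#' (number of pairs \code{(a_i, b_j)} with \code{a_i > b_j}, counting ties
#' as 1/2), so \code{U(a, b) + U(b, a) = n_a * n_b}.
#'
#' @param a,b numeric samples.
#' @return List with \code{U}, two-sided \code{p}, sample sizes and the
#'   method used.
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_a = length(a), n_b = length(b),
       method = if (exact) "exact" else "normal approximation (tie-corrected)")
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with chi-squared p-value, followed by
#' Dunn's pairwise z-tests on mean ranks (tie-corrected) with Bonferroni
#' adjustment over all pairs.
#'
#' @param groups named list of numeric samples (>= 2 groups, all
#'   non-empty). Unnamed lists get labels \code{g1, g2, ...}.
#' @param p_adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (default \code{"bonferroni"}).
#' @return Object of class \code{group_comparison}: per-group summary
#'   (\code{n, mean, sd, median}), the test name, \code{statistic}
#'   (H), \code{df}, \code{p}, and \code{pairwise} (data.frame with z,
#'   unadjusted and adjusted p per pair).
#' @export
kruskal_wallis_dunn <- function(groups, p_adjust = "bonferroni") {
  if (!is.list(groups) || length(groups) < 2) {
    stop("groups must be a list of >= 2 samples", call. = FALSE)
  }
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- stats::kruskal.test(x, g)

  r <- rank(x)
  N <- length(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term

  combos <- utils::combn(names(groups), 2)
  z <- p_raw <- numeric(ncol(combos))
  for (k in seq_len(ncol(combos))) {
    gi <- combos[1, k]; gj <- combos[2, k]
    se <- sqrt(v0 * (1 / ns[[gi]] + 1 / ns[[gj]]))
    z[k] <- (rbar[[gi]] - rbar[[gj]]) / se
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  pairwise <- data.frame(group_1 = combos[1, ], group_2 = combos[2, ],
                         z = z, p = p_raw,
                         p_adj = stats::p.adjust(p_raw, method = p_adjust),
                         stringsAsFactors = FALSE)
  summ <- data.frame(group = names(groups),
                     n = as.integer(lengths(groups)),
                     mean = vapply(groups, mean, numeric(1)),
                     sd = vapply(groups, stats::sd, numeric(1)),
                     median = vapply(groups, stats::median, numeric(1)),
                     stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  structure(list(summary = summ, test = "Kruskal-Wallis rank sum test",
                 statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, pairwise = pairwise, p_adjust = p_adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("%s: H = %.3f, df = %d, p = %.4g\n",
              x$test, x$statistic, x$df, x$p))
  print(x$summary, row.names = FALSE)
  cat(sprintf("Pairwise Dunn z-tests (%s-adjusted):\n", x$p_adjust))
  pw <- x$pairwise
  pw$z <- signif(pw$z, digits); pw$p <- signif(pw$p, digits)
  pw$p_adj <- signif(pw$p_adj, digits)
  print(pw, row.names = FALSE)
  invisible(x)
}

# logistic fit with explicit separation detection
fit_logistic <- function(formula, data) {
  flags <- character(0)
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("fitted probabilities numerically 0 or 1|did not converge", flags))) {
    stop("complete separation in logistic model (fitted probabilities of 0/1); ",
         "a covariate perfectly predicts the outcome", call. = FALSE)
  }
  fit
}

#' Propensity scores for PIRA occurrence
#'
#' Fits an unpenalized maximum-likelihood logistic regression of PIRA
#' occurrence on sex, baseline EDSS, baseline ARR and age at therapy
#' initiation; the fitted probabilities are the per-patient propensity
#' scores. Subgroup pairs are compared with two-sided Mann-Whitney U tests
#' on the score distributions, mirroring the published comparison table:
#' PIRA vs no PIRA, lowest vs highest disease-duration quartile, prior-DMT
#' count below vs above the median, first- vs second-line therapy, CD19
#' not detectable vs detectable, and lowest vs highest quartile of each
#' worse-eye OCT measure (skipped when too few patients carry the
#' variable).
#'
#' @param cohort an [ms_cohort()].
#' @param outcomes outcome labels: a [classify_cohort()] result or its
#'   \code{outcomes} data.frame.
#' @return Object of class \code{propensity_result}: \code{scores}
#'   (data.frame \code{patient_id, score, pira}), \code{model}, and
#'   \code{comparisons} (one row per subgroup pair with per-group n, mean,
#'   SD and the Mann-Whitney p-value).
#' @export
propensity_scores <- function(cohort, outcomes) {
  stopifnot(inherits(cohort, "ms_cohort"))
  if (inherits(outcomes, "cda_classification")) outcomes <- outcomes$outcomes
  base <- derive_baseline(cohort)
  d <- merge(merge(cohort$patients, base, by = "patient_id"),
             outcomes[, c("patient_id", "label")], by = "patient_id")
  d$pira <- d$label %in% c("PIRA_noSIR", "PIRA_SIR")
  d$sex01 <- as.integer(d$sex == "F")
  if (nrow(d) < 10) warning("propensity model fitted on fewer than 10 patients")

  fit <- fit_logistic(pira ~ sex01 + baseline_edss + baseline_arr + age_at_baseline, d)
  d$score <- as.numeric(stats::fitted(fit))

  cmp_row <- function(label_a, label_b, in_a, in_b) {
    sa <- d$score[in_a]; sb <- d$score[in_b]
    if (length(sa) < 2 || length(sb) < 2) return(NULL)
    mw <- mann_whitney(sa, sb)
    data.frame(group_1 = label_a, group_2 = label_b,
               n_1 = length(sa), n_2 = length(sb),
               mean_1 = mean(sa), sd_1 = stats::sd(sa),
               mean_2 = mean(sb), sd_2 = stats::sd(sb),
               p = mw$p, stringsAsFactors = FALSE)
  }
  quart_pair <- function(v, what, unit = "") {
    ok <- !is.na(v)
    if (sum(ok) < 8) return(NULL)
    q <- stats::quantile(v[ok], c(0.25, 0.75), type = 7, names = FALSE)
    cmp_row(sprintf("%s lowest quartile (<= %g%s)", what, q[1], unit),
            sprintf("%s highest quartile (>= %g%s)", what, q[2], unit),
            ok & v <= q[1], ok & v >= q[2])
  }
  med_dmt <- stats::median(d$n_prior_dmts)
  rows <- list(
    cmp_row("PIRA", "No PIRA", d$pira, !d$pira),
    quart_pair(d$disease_duration, "Disease duration", " years"),
    cmp_row(sprintf("Prior DMTs < median (%g)", med_dmt),
            sprintf("Prior DMTs > median (%g)", med_dmt),
            d$n_prior_dmts < med_dmt, d$n_prior_dmts > med_dmt),
    cmp_row("First-line", "Second-line",
            d$n_prior_dmts == 0, d$n_prior_dmts > 0),
    cmp_row("CD19+ not detectable", "CD19+ detectable",
            !is.na(d$cd19_detectable) & !d$cd19_detectable,
            !is.na(d$cd19_detectable) & d$cd19_detectable),
    quart_pair(d$prnfl_worse, "pRNFL", " um"),
    quart_pair(d$mrnfl_worse, "mRNFL", " mm3"),
    quart_pair(d$gcipl_worse, "GCIPL", " mm3"))
  comparisons <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(comparisons) <- NULL
  structure(list(scores = d[, c("patient_id", "score", "pira")],
                 model = fit, comparisons = comparisons),
            class = "propensity_result")
}

#' @export
print.propensity_result <- function(x, ...) {
  cat(sprintf("Propensity scores for PIRA occurrence (n = %d, mean = %.3f)\n",
              nrow(x$scores), mean(x$scores$score)))
  cc <- x$comparisons
  cc$mean_1 <- round(cc$mean_1, 3); cc$sd_1 <- round(cc$sd_1, 3)
  cc$mean_2 <- round(cc$mean_2, 3); cc$sd_2 <- round(cc$sd_2, 3)
  cc$p <- signif(cc$p, 3)
  print(cc, row.names = FALSE)
  invisible(x)
}

#' Cohort characteristics table (all / PIRA / no PIRA)
#'
#' Reproduces the structure of the published baseline table: continuous
#' characteristics (age, disease duration, therapy duration, prior DMT
#' count, pre-baseline ARR, baseline EDSS, on-treatment EDSS change) as
#' mean, SD and median per column with two-sided Mann-Whitney p-values for
#' PIRA vs no PIRA, plus count rows (female sex, treatment-naive).
#'
#' @param cohort an [ms_cohort()].
#' @param outcomes a [classify_cohort()] result or its \code{outcomes}
#'   data.frame.
#' @return Object of class \code{table_one} with elements
#'   \code{continuous}, \code{counts} and the group sizes.
#' @export
summarize_table1 <- function(cohort, outcomes) {
  stopifnot(inherits(cohort, "ms_cohort"))
  if (inherits(outcomes, "cda_classification")) outcomes <- outcomes$outcomes
  base <- derive_baseline(cohort)
  d <- merge(merge(cohort$patients, base, by = "patient_id"),
             outcomes[, c("patient_id", "label", "edss_change")],
             by = "patient_id")
  d$pira <- d$label %in% c("PIRA_noSIR", "PIRA_SIR")
  if (!any(d$pira) || all(d$pira)) {
    warning("a comparison group is empty; p-values reported as NA")
  }
  vars <- c("Age at baseline (years)" = "age_at_baseline",
            "Disease duration at baseline (years)" = "disease_duration",
            "Therapy duration (months)" = "followup_months",
            "Prior DMTs (n)" = "n_prior_dmts",
            "Annualized relapse rate before baseline" = "baseline_arr",
            "EDSS at baseline" = "baseline_edss",
            "EDSS change on treatment" = "edss_change")
  stat3 <- function(v) c(mean = mean(v), sd = stats::sd(v), median = stats::median(v))
  cont <- do.call(rbind, lapply(names(vars), function(lbl) {
    v <- d[[vars[[lbl]]]]
    a <- stat3(v); pp <- stat3(v[d$pira]); np <- stat3(v[!d$pira])
    p <- if (any(d$pira) && !all(d$pira)) mann_whitney(v[d$pira], v[!d$pira])$p else NA_real_
    data.frame(characteristic = lbl,
               all_mean = a["mean"], all_sd = a["sd"], all_median = a["median"],
               pira_mean = pp["mean"], pira_sd = pp["sd"], pira_median = pp["median"],
               nopira_mean = np["mean"], nopira_sd = np["sd"], nopira_median = np["median"],
               p = p, stringsAsFactors = FALSE)
  }))
  rownames(cont) <- NULL
  cnt <- function(lbl, flag) {
    data.frame(characteristic = lbl,
               all_n = sum(flag), all_pct = round_half_up(100 * mean(flag), 1),
               pira_n = sum(flag & d$pira),
               pira_pct = if (any(d$pira)) round_half_up(100 * mean(flag[d$pira]), 1) else NA_real_,
               nopira_n = sum(flag & !d$pira),
               nopira_pct = if (any(!d$pira)) round_half_up(100 * mean(flag[!d$pira]), 1) else NA_real_,
               stringsAsFactors = FALSE)
  }
  counts <- rbind(cnt("Female sex", d$sex == "F"),
                  cnt("Treatment naive at baseline", d$n_prior_dmts == 0))
  structure(list(n_all = nrow(d), n_pira = sum(d$pira), n_nopira = sum(!d$pira),
                 continuous = cont, counts = counts),
            class = "table_one")
}

#' @export
print.table_one <- function(x, ...) {
  cat(sprintf("Cohort characteristics: all n = %d | PIRA n = %d (%.1f%%) | no PIRA n = %d (%.1f%%)\n",
              x$n_all, x$n_pira, round_half_up(100 * x$n_pira / x$n_all, 1),
              x$n_nopira, round_half_up(100 * x$n_nopira / x$n_all, 1)))
  cc <- x$continuous
  num <- vapply(cc, is.numeric, logical(1))
  cc[num] <- lapply(cc[num], function(v) round(v, 2))
  print(cc, row.names = FALSE)
  print(x$counts, row.names = FALSE)
  invisible(x)
}
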