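# Cohort-level evaluation: alert reliability (PPV) and condition
# sensitivity per scenario, per-class attribution tables, cross-scenario
# substitution analysis with crude odds ratios, and multivariate logistic
# mortality models.

#' Crude odds ratio with a Woolf confidence interval
#'
#' For the 2x2 table (`a`, `b` = events and non-events in the exposed group;
#' `c`, `d` in the reference group): OR = (a/b)/(c/d), with the log-OR
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)` and a Wald 95% interval on
#' the log scale. When any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe continuity correction) with a warning.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `ci_lower`, `ci_upper`, `se_log_or`, `cells`.
#' @export
#' @examples
#' or_2x2(118, 422, 286, 1321)  # 1.29 (1.02, 1.64)
or_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (any(cells == 0)) {
    warning("zero cell: applying 0.5 continuity correction", call. = FALSE)
    cells <- cells + 0.5
  }
  or <- (cells["a"] / cells["b"]) / (cells["c"] / cells["d"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(or),
       ci_lower = unname(exp(log(or) - z * se)),
       ci_upper = unname(exp(log(or) + z * se)),
       se_log_or = se,
       cells = cells)
}

.merge_alerts_labels <- function(alerts, infection) {
  m <- merge(data.table::as.data.table(alerts),
             data.table::as.data.table(infection)[
               , c("encounter_id", "suspected_infection")],
             by = "encounter_id")
  if (nrow(m) < nrow(alerts)) {
    stop("alerts and infection labels do not cover the same cohort",
         call. = FALSE)
  }
  m
}

#' Evaluate one scenario against the reference
#'
#' Computes the scenario's confusion-matrix performance on suspected
#' infection: alert reliability (PPV, the proportion of flagged encounters
#' with suspected infection) and condition sensitivity. Because no
#' gold-standard sepsis adjudication exists, the sensitivity denominator is
#' the set of suspected-infection patients flagged by the reference
#' (SEP-2-based) scenario, which therefore scores 100% by construction. Also
#' tabulates flagged encounters by attributed parameter class.
#'
#' @param alerts [screen_cohort()] output for the scenario under evaluation.
#' @param infection [label_infection()] output for the same cohort.
#' @param reference_alerts [screen_cohort()] output for the reference
#'   scenario; defaults to `alerts` itself (self-reference).
#' @param scenario Scenario name for reporting (defaults to the `scenario`
#'   attribute of `alerts`).
#' @return A `scenario_evaluation`: `scenario`, `n_flagged`,
#'   `n_flagged_infected`, `ppv` (`NA` with a warning when nothing is
#'   flagged), `sensitivity`, `relative_change_vs_reference` (signed change
#'   in flagged count), `lactate_measured_prop` (among flagged
#'   suspected-infection patients), and `per_class` (`data.table`: class,
#'   `n_flagged`, `n_infected`, `pct_infected`).
#' @export
evaluate_scenario <- function(alerts, infection, reference_alerts = NULL,
                              scenario = attr(alerts, "scenario")) {
  if (is.null(reference_alerts)) reference_alerts <- alerts
  m <- .merge_alerts_labels(alerts, infection)
  ref <- .merge_alerts_labels(reference_alerts, infection)

  n_flagged <- sum(m$flagged)
  n_flagged_infected <- sum(m$flagged & m$suspected_infection)
  if (n_flagged == 0L) {
    warning("no encounters flagged: PPV undefined", call. = FALSE)
    ppv <- NA_real_
  } else {
    ppv <- n_flagged_infected / n_flagged
  }

  ref_pos <- ref$encounter_id[ref$flagged & ref$suspected_infection]
  sens <- if (length(ref_pos)) {
    sum(m$flagged & m$encounter_id %in% ref_pos) / length(ref_pos)
  } else {
    NA_real_
  }
  n_ref_flagged <- sum(ref$flagged)
  rel_change <- if (n_ref_flagged) {
    (n_flagged - n_ref_flagged) / n_ref_flagged
  } else {
    NA_real_
  }

  lact <- if ("lactate_measured" %in% names(infection)) {
    mm <- merge(m, data.table::as.data.table(infection)[
      , c("encounter_id", "lactate_measured")], by = "encounter_id")
    flag_inf <- mm$flagged & mm$suspected_infection
    if (any(flag_inf)) mean(mm$lactate_measured[flag_inf]) else NA_real_
  } else {
    NA_real_
  }

  flagged <- m[m$flagged]
  attributed_class <- suspected_infection <- NULL
  per_class <- flagged[, .(n_flagged = .N,
                           n_infected = sum(suspected_infection)),
                       by = attributed_class]
  per_class[, pct_infected := 100 * n_infected / n_flagged]
  per_class <- per_class[order(match(attributed_class, alert_classes()))]

  structure(list(
    scenario = scenario,
    n_flagged = n_flagged,
    n_flagged_infected = n_flagged_infected,
    ppv = ppv,
    sensitivity = sens,
    relative_change_vs_reference = rel_change,
    lactate_measured_prop = lact,
    per_class = per_class[]
  ), class = "scenario_evaluation")
}

#' @export
print.scenario_evaluation <- function(x, ...) {
  cat(sprintf("<scenario_evaluation> %s\n", x$scenario))
  cat(sprintf("  flagged: %d, with suspected infection: %d (PPV %s)\n",
              x$n_flagged, x$n_flagged_infected,
              ifelse(is.na(x$ppv), "NA", sprintf("%.0f%%", 100 * x$ppv))))
  cat(sprintf("  sensitivity vs reference: %s, flagged-count change: %s\n",
              ifelse(is.na(x$sensitivity), "NA",
                     sprintf("%.0f%%", 100 * x$sensitivity)),
              ifelse(is.na(x$relative_change_vs_reference), "NA",
                     sprintf("%+.0f%%",
                             100 * x$relative_change_vs_reference))))
  print(x$per_class)
  invisible(x)
}

#' Cross-scenario substitution analysis
#'
#' Restricted to suspected-infection patients flagged by both scenarios
#' (dual membership), counts those whose attributed parameter class differs
#' in the comparison scenario (reclassified), summarizes the organ system of
#' the new class, and contrasts mortality between the reclassified and
#' same-class subgroups as a crude odds ratio with a Woolf 95% interval
#' ([or_2x2()]).
#'
#' @param alerts_ref Reference-scenario [screen_cohort()] output.
#' @param alerts_cmp Comparison-scenario [screen_cohort()] output.
#' @param infection [label_infection()] output.
#' @param mortality Data frame with `encounter_id` and logical `died`
#'   (e.g. built from [mortality_outcome()]).
#' @return A `substitution_result`: scenario pair, `n_dual_membership`,
#'   `n_reclassified`, `reclass_distribution` (`data.table` of the new
#'   class, its organ system, count and proportion among reclassified),
#'   `deaths_2x2` (reclassified/same by died/survived), `mortality_rate_*`,
#'   and `crude_or` with `ci_lower`/`ci_upper`.
#' @export
substitution_analysis <- function(alerts_ref, alerts_cmp, infection,
                                  mortality) {
  a <- data.table::as.data.table(alerts_ref)[
    , c("encounter_id", "flagged", "attributed_class")]
  b <- data.table::as.data.table(alerts_cmp)[
    , c("encounter_id", "flagged", "attributed_class")]
  m <- merge(a, b, by = "encounter_id", suffixes = c("_ref", "_cmp"))
  m <- merge(m, data.table::as.data.table(infection)[
    , c("encounter_id", "suspected_infection")], by = "encounter_id")
  m <- merge(m, data.table::as.data.table(mortality)[
    , c("encounter_id", "died")], by = "encounter_id")

  dual <- m[m$flagged_ref & m$flagged_cmp & m$suspected_infection]
  dual[, reclassified := attributed_class_cmp != attributed_class_ref]

  new_class <- died <- reclassified <- NULL
  rc <- dual[reclassified == TRUE,
             .(n = .N), by = .(new_class = attributed_class_cmp)]
  if (nrow(rc)) {
    rc[, `:=`(system = ifelse(new_class == "mods", "mods",
                              organ_systems()[new_class]),
              proportion = n / sum(n))]
    rc <- rc[order(match(new_class, alert_classes()))]
  }

  cells <- c(a = sum(dual$reclassified & dual$died),
             b = sum(dual$reclassified & !dual$died),
             c = sum(!dual$reclassified & dual$died),
             d = sum(!dual$reclassified & !dual$died))
  or <- if (nrow(dual)) do.call(or_2x2, as.list(cells)) else
    list(or = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
         se_log_or = NA_real_, cells = cells)

  structure(list(
    scenario_ref = attr(alerts_ref, "scenario"),
    scenario_cmp = attr(alerts_cmp, "scenario"),
    n_dual_membership = nrow(dual),
    n_reclassified = sum(dual$reclassified),
    reclass_distribution = rc,
    deaths_2x2 = cells,
    mortality_rate_reclassified =
      if (any(dual$reclassified)) mean(dual$died[dual$reclassified])
      else NA_real_,
    mortality_rate_same =
      if (any(!dual$reclassified)) mean(dual$died[!dual$reclassified])
      else NA_real_,
    crude_or = or$or, ci_lower = or$ci_lower, ci_upper = or$ci_upper,
    se_log_or = or$se_log_or
  ), class = "substitution_result")
}

#' @export
print.substitution_result <- function(x, ...) {
  cat(sprintf("<substitution_result> %s vs %s\n",
              x$scenario_ref, x$scenario_cmp))
  cat(sprintf("  dual membership: %d; reclassified: %d (%.0f%%)\n",
              x$n_dual_membership, x$n_reclassified,
              100 * x$n_reclassified / max(x$n_dual_membership, 1)))
  cat(sprintf("  mortality %.0f%% vs %.0f%%; crude OR %.2f (%.2f-%.2f)\n",
              100 * x$mortality_rate_reclassified,
              100 * x$mortality_rate_same,
              x$crude_or, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Logistic mortality model for one parameter class
#'
#' Fits a binary logistic regression of mortality on the presence of one
#' attributed parameter class (absence of that class is the reference)
#' among the supplied patients — by design, the suspected-infection patients
#' flagged by one scenario. Default covariates are age in years
#' (continuous), sex, and NEWS acuity category (factor with the lowest band
#' as reference). Maximum-likelihood fit via iteratively reweighted least
#' squares (`stats::glm`), convergence tolerance `1e-8`; non-convergence or
#' (quasi-)separation is reported as a failed fit with a diagnostic, never
#' silently.
#'
#' @param patients Data frame with columns `died` (logical),
#'   `attributed_class`, and any covariates used.
#' @param parameter_class One of [alert_classes()].
#' @param covariates Character vector of covariate column names; use
#'   `character()` for a crude (covariate-free) fit, which equals the
#'   closed-form [or_2x2()] estimate.
#' @param scenario Scenario name for reporting.
#' @return A `mortality_model`: `parameter_class`, `scenario`,
#'   `odds_ratio`, `ci_lower`, `ci_upper` (Wald 95%), `n`, `n_events`,
#'   `n_with_parameter`, `converged`, `status` (`"ok"`, `"non-convergence"`
#'   or `"possible separation"`), and the fitted coefficient table.
#' @export
fit_mortality_model <- function(patients, parameter_class,
                                covariates = c("age_years", "sex",
                                               "news_category"),
                                scenario = NULL) {
  stopifnot(parameter_class %in% alert_classes())
  d <- data.table::as.data.table(patients)
  missing_cols <- setdiff(c("died", "attributed_class", covariates), names(d))
  if (length(missing_cols)) {
    stop("patients table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- data.table::copy(d)
  d[, param_present := attributed_class == parameter_class]
  if ("news_category" %in% covariates) {
    d[, news_category := droplevels(
      factor(news_category, levels = .NEWS_CATEGORIES))]
  }
  fml <- stats::reformulate(c("param_present", covariates), response = "died")
  fit <- stats::glm(fml, family = stats::binomial(), data = d,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  co <- summary(fit)$coefficients
  beta <- co["param_presentTRUE", "Estimate"]
  se <- co["param_presentTRUE", "Std. Error"]

  status <- "ok"
  if (!fit$converged) {
    status <- "non-convergence"
  } else if (abs(beta) > 15 || se > 50) {
    status <- "possible separation"
  }
  if (status != "ok") {
    warning(sprintf("mortality model for '%s' failed: %s",
                    parameter_class, status), call. = FALSE)
  }
  structure(list(
    parameter_class = parameter_class,
    scenario = scenario,
    odds_ratio = exp(beta),
    ci_lower = exp(beta - stats::qnorm(0.975) * se),
    ci_upper = exp(beta + stats::qnorm(0.975) * se),
    n = nrow(d),
    n_events = sum(d$died),
    n_with_parameter = sum(d$param_present),
    converged = fit$converged && status == "ok",
    status = status,
    coefficients = co
  ), class = "mortality_model")
}

#' @export
print.mortality_model <- function(x, ...) {
  cat(sprintf(
    "<mortality_model> %s%s: OR %.2f (%.2f-%.2f), n=%d, events=%d [%s]\n",
    x$parameter_class,
    if (!is.null(x$scenario)) paste0(" @ ", x$scenario) else "",
    x$odds_ratio, x$ci_lower, x$ci_upper, x$n, x$n_events, x$status))
  invisible(x)
}

#' Assemble the analysis table for mortality modelling
#'
#' Joins alerts, infection labels, acuity profiles, encounter covariates and
#' the mortality outcome, restricted to suspected-infection patients flagged
#' by the scenario — the population the mortality models are fit on.
#'
#' @param cohort A `sepsis_cohort`.
#' @param alerts [screen_cohort()] output.
#' @param infection [label_infection()] output.
#' @param acuity [acuity_cohort()] output.
#' @return `data.table` with one row per flagged suspected-infection patient:
#'   `encounter_id`, `died`, `attributed_class`, `age_years`, `sex`,
#'   `news_category`.
#' @export
mortality_analysis_set <- function(cohort, alerts, infection, acuity) {
  enc <- cohort$encounters[, c("encounter_id", "age_years", "sex",
                               "disposition")]
  m <- merge(data.table::as.data.table(alerts), enc, by = "encounter_id")
  m <- merge(m, data.table::as.data.table(infection)[
    , c("encounter_id", "suspected_infection")], by = "encounter_id")
  m <- merge(m, data.table::as.data.table(acuity)[
    , c("encounter_id", "news_category")], by = "encounter_id")
  m <- m[m$flagged & m$suspected_infection]
  m[, died := mortality_outcome(disposition)]
  m[, c("encounter_id", "died", "attributed_class", "age_years", "sex",
        "news_category"), with = FALSE]
}
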