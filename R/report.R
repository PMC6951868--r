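# Report bundle: machine-readable result tables plus a forest plot of the
# per-parameter mortality odds ratios.

#' Build the analysis report bundle
#'
#' Collects scenario evaluations, substitution results and mortality models
#' into tidy tables; optionally writes them to a directory
#' (`scenario_metrics.csv`, `attribution_table.csv`, `substitution.csv`,
#' `mortality_models.csv`, and `forest.svg` when any model is present).
#' Output is deterministic: two runs on the same inputs produce identical
#' tables. When nothing was flagged the metrics table carries an explicit
#' `no_alerts` marker instead of silently empty sections.
#'
#' @param evaluations List of [evaluate_scenario()] results.
#' @param substitutions List of [substitution_analysis()] results (may be
#'   empty).
#' @param models List of [fit_mortality_model()] results (may be empty).
#' @param out_dir Optional output directory.
#' @return Invisibly, a named list of `data.table`s: `scenario_metrics`,
#'   `attribution_table`, `substitution`, `mortality_models`.
#' @export
build_report <- function(evaluations, substitutions = list(),
                         models = list(), out_dir = NULL) {
  stopifnot(length(evaluations) > 0)
  metrics <- data.table::rbindlist(lapply(evaluations, function(e) {
    data.table::data.table(
      scenario = e$scenario,
      n_flagged = e$n_flagged,
      n_flagged_infected = e$n_flagged_infected,
      ppv = e$ppv,
      sensitivity = e$sensitivity,
      relative_change_vs_reference = e$relative_change_vs_reference,
      lactate_measured_prop = e$lactate_measured_prop,
      no_alerts = e$n_flagged == 0L
    )
  }))
  attribution <- data.table::rbindlist(lapply(evaluations, function(e) {
    if (nrow(e$per_class) == 0L) {
      return(data.table::data.table(scenario = e$scenario,
                                    attributed_class = "no_alerts",
                                    n_flagged = 0L, n_infected = 0L,
                                    pct_infected = NA_real_))
    }
    data.table::data.table(scenario = e$scenario, e$per_class)
  }))
  substitution_proto <- data.table::data.table(
    scenario_ref = character(), scenario_cmp = character(),
    n_dual_membership = integer(), n_reclassified = integer(),
    deaths_reclassified = integer(), deaths_same = integer(),
    mortality_rate_reclassified = numeric(), mortality_rate_same = numeric(),
    crude_or = numeric(), ci_lower = numeric(), ci_upper = numeric())
  substitution <- data.table::rbindlist(lapply(substitutions, function(s) {
    data.table::data.table(
      scenario_ref = s$scenario_ref, scenario_cmp = s$scenario_cmp,
      n_dual_membership = s$n_dual_membership,
      n_reclassified = s$n_reclassified,
      deaths_reclassified = s$deaths_2x2[["a"]],
      deaths_same = s$deaths_2x2[["c"]],
      mortality_rate_reclassified = s$mortality_rate_reclassified,
      mortality_rate_same = s$mortality_rate_same,
      crude_or = s$crude_or, ci_lower = s$ci_lower, ci_upper = s$ci_upper
    )
  }))
  if (nrow(substitution) == 0L) substitution <- substitution_proto
  mortality_proto <- data.table::data.table(
    scenario = character(), parameter_class = character(),
    odds_ratio = numeric(), ci_lower = numeric(), ci_upper = numeric(),
    n = integer(), n_events = integer(), status = character())
  mortality <- data.table::rbindlist(lapply(models, function(mdl) {
    data.table::data.table(
      scenario = if (is.null(mdl$scenario)) NA_character_ else mdl$scenario,
      parameter_class = mdl$parameter_class,
      odds_ratio = mdl$odds_ratio,
      ci_lower = mdl$ci_lower, ci_upper = mdl$ci_upper,
      n = mdl$n, n_events = mdl$n_events, status = mdl$status
    )
  }))
  if (nrow(mortality) == 0L) mortality <- mortality_proto

  out <- list(scenario_metrics = metrics, attribution_table = attribution,
              substitution = substitution, mortality_models = mortality)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      data.table::fwrite(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    if (nrow(mortality)) {
      p <- forest_plot(mortality)
      try(ggplot2::ggsave(file.path(out_dir, "forest.svg"), p,
                          width = 7, height = 1 + 0.6 * nrow(mortality)),
          silent = TRUE)
    }
  }
  invisible(out)
}

#' Forest plot of mortality odds ratios
#'
#' Point estimates with 95% intervals per parameter class, one panel per
#' scenario, on a log-scaled axis with the null line at OR = 1.
#'
#' @param mortality_models `mortality_models` table from [build_report()],
#'   or a list of [fit_mortality_model()] results.
#' @return A ggplot object.
#' @export
forest_plot <- function(mortality_models) {
  if (!is.data.frame(mortality_models)) {
    mortality_models <- data.table::rbindlist(lapply(
      mortality_models, function(mdl) {
        data.table::data.table(
          scenario = if (is.null(mdl$scenario)) "" else mdl$scenario,
          parameter_class = mdl$parameter_class,
          odds_ratio = mdl$odds_ratio,
          ci_lower = mdl$ci_lower, ci_upper = mdl$ci_upper)
      }))
  }
  d <- data.table::as.data.table(mortality_models)
  d[, parameter_class := factor(parameter_class,
                                levels = rev(alert_classes()))]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio,
                                  y = .data$parameter_class)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "Mortality odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_bw()
}
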