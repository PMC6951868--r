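# Scenario configurations: a named parameterization of the SIRS +
# organ-dysfunction screen. Three immutable presets ship with the package.

#' Build a screening scenario configuration
#'
#' All thresholds default to the SEP-2-based severe-sepsis screen (the CMS
#' style definition): SIRS when >=2 of {temperature >38.3 or <36.0 C,
#' heart rate >90/min, respiratory rate >20/min, WBC >12000 or <4000 per mm3
#' or band forms >10%}; organ dysfunction when >=1 of {SBP <90 or MAP <65
#' mmHg, SBP decrease >40 mmHg from the baseline (first) in-window reading,
#' lactate >2.0 mmol/L, bilirubin >=2.0 mg/dL, creatinine >=2.0 mg/dL,
#' platelets <100000/uL, INR >1.5}. Lookbacks: 12 h for lactate, 72 h for
#' creatinine, 30 h for every other criterion.
#'
#' @param name Scenario name.
#' @param sbp_drop_enabled Include the SBP-decrease-from-baseline parameter.
#' @param sbp_drop_mmHg Strict drop threshold (exceeds, not meets).
#' @param sbp_low_mmHg,map_low_mmHg Hypotension thresholds (strict `<`).
#' @param lactate_high_mmol_L Strict `>` threshold.
#' @param bilirubin_low_mg_dL Inclusive `>=` threshold.
#' @param bilirubin_cap_mg_dL Optional inclusive upper bound; bilirubin above
#'   the cap does not qualify (used by the conservative preset to avoid
#'   flagging primary liver injury). `NULL` = no cap.
#' @param creatinine_high_mg_dL Inclusive `>=` threshold.
#' @param creatinine_delta_required Additionally require a rise of at least
#'   `creatinine_delta_mg_dL` within the creatinine lookback, ending at the
#'   qualifying high value (conservative preset).
#' @param creatinine_delta_mg_dL Inclusive rise threshold.
#' @param platelets_inr_enabled Include the hematologic parameters.
#' @param platelets_low_per_uL Strict `<` threshold.
#' @param inr_high Strict `>` threshold.
#' @param lookback_lactate_h,lookback_creatinine_h,lookback_default_h Window
#'   lengths in hours.
#' @param sirs Named list of SIRS thresholds (see defaults).
#' @return A `scenario_config`.
#' @seealso [scenario_preset()] for the three shipped presets.
#' @export
scenario_config <- function(name = "custom",
                            sbp_drop_enabled = TRUE,
                            sbp_drop_mmHg = 40,
                            sbp_low_mmHg = 90,
                            map_low_mmHg = 65,
                            lactate_high_mmol_L = 2.0,
                            bilirubin_low_mg_dL = 2.0,
                            bilirubin_cap_mg_dL = NULL,
                            creatinine_high_mg_dL = 2.0,
                            creatinine_delta_required = FALSE,
                            creatinine_delta_mg_dL = 0.5,
                            platelets_inr_enabled = TRUE,
                            platelets_low_per_uL = 1e5,
                            inr_high = 1.5,
                            lookback_lactate_h = 12,
                            lookback_creatinine_h = 72,
                            lookback_default_h = 30,
                            sirs = list(temp_high_C = 38.3, temp_low_C = 36.0,
                                        hr_high_bpm = 90, rr_high_bpm = 20,
                                        wbc_high_per_mm3 = 12000,
                                        wbc_low_per_mm3 = 4000,
                                        band_high_pct = 10)) {
  cfg <- list(
    name = name,
    sbp_drop_enabled = isTRUE(sbp_drop_enabled),
    sbp_drop_mmHg = sbp_drop_mmHg,
    sbp_low_mmHg = sbp_low_mmHg,
    map_low_mmHg = map_low_mmHg,
    lactate_high_mmol_L = lactate_high_mmol_L,
    bilirubin_low_mg_dL = bilirubin_low_mg_dL,
    bilirubin_cap_mg_dL = bilirubin_cap_mg_dL,
    creatinine_high_mg_dL = creatinine_high_mg_dL,
    creatinine_delta_required = isTRUE(creatinine_delta_required),
    creatinine_delta_mg_dL = creatinine_delta_mg_dL,
    platelets_inr_enabled = isTRUE(platelets_inr_enabled),
    platelets_low_per_uL = platelets_low_per_uL,
    inr_high = inr_high,
    lookback_lactate_h = lookback_lactate_h,
    lookback_creatinine_h = lookback_creatinine_h,
    lookback_default_h = lookback_default_h,
    sirs = sirs
  )
  structure(cfg, class = "scenario_config")
}

#' Load one of the three shipped scenario presets
#'
#' * `sep2_based`: the full screen described in [scenario_config()].
#' * `near_sep2`: identical except the SBP-decrease-from-baseline parameter is
#'   disabled (that parameter is prone to firing on normalization after
#'   stress-induced blood-pressure elevation).
#' * `conservative`: additionally requires a creatinine rise of >=0.5 mg/dL
#'   within 72 h on top of the >=2.0 mg/dL threshold, excludes bilirubin
#'   above 10 mg/dL, and drops the platelets/INR parameters (which may
#'   reflect primary liver injury).
#'
#' The presets are committed YAML files under `inst/scenarios/` and are
#' immutable; [read_scenario()] loads a custom YAML of the same shape.
#'
#' @param name `"sep2_based"`, `"near_sep2"` or `"conservative"`.
#' @return A `scenario_config`.
#' @export
#' @examples
#' scenario_preset("near_sep2")
scenario_preset <- function(name = c("sep2_based", "near_sep2",
                                     "conservative")) {
  name <- match.arg(name)
  read_scenario(system.file("scenarios", paste0(name, ".yaml"),
                            package = "sepscreen", mustWork = TRUE))
}

#' @rdname scenario_preset
#' @param path Path to a scenario YAML file.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(scenario_config)))]
  do.call(scenario_config, args)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$name, "\n")
  cat("  SBP-drop parameter:  ",
      if (x$sbp_drop_enabled) sprintf("> %g mmHg from baseline", x$sbp_drop_mmHg)
      else "disabled", "\n")
  cat("  creatinine:           >=", x$creatinine_high_mg_dL, "mg/dL",
      if (x$creatinine_delta_required)
        sprintf("and rise >= %g over %g h", x$creatinine_delta_mg_dL,
                x$lookback_creatinine_h) else "", "\n")
  cat("  bilirubin:            >=", x$bilirubin_low_mg_dL, "mg/dL",
      if (!is.null(x$bilirubin_cap_mg_dL))
        sprintf("(<= %g)", x$bilirubin_cap_mg_dL) else "", "\n")
  cat("  platelets/INR:       ",
      if (x$platelets_inr_enabled) "enabled" else "disabled", "\n")
  invisible(x)
}
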