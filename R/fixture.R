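#' @title Built-in base-case model configuration
#' @name fixture
#' @description The published base case: chemotherapy-based mobilization
#'   (cyclophosphamide 4 g/m2 + G-CSF, with on-demand plerixafor) as the
#'   comparator versus chemotherapy-free mobilization (G-CSF with on-demand
#'   plerixafor) as the treatment, costed from the societal perspective in
#'   EUR 2019.
NULL

# 95% CI helpers used when a parameter's interval is not reported directly:
# gamma at the model-wide CV of 0.4 (shape 6.25), beta at the dispersion
# convention for probabilities. Rounded to the precision of the printed tables.
gq <- function(mean) round(stats::qgamma(c(0.025, 0.975), 6.25, scale = mean * 0.16), 2)
bq <- function(mean) {
  d <- beta_from_mean_sd(mean, beta_sd_convention(mean))
  round(d$source_ci, 4)
}

uq_gamma <- function(name, mean, ci = NULL, units = "") {
  if (is.null(ci)) ci <- gq(mean)
  uncertain_quantity(name, mean, ci[1], ci[2], "gamma", units)
}
uq_beta <- function(name, mean, units = "probability") {
  ci <- bq(mean)
  uncertain_quantity(name, mean, ci[1], ci[2], "beta", units)
}
uq_fixed <- function(name, mean, ci = c(NA_real_, NA_real_), units = "EUR") {
  uncertain_quantity(name, mean, ci[1], ci[2], "fixed", units)
}

#' The published base-case configuration
#'
#' Builds the in-model base case: every printed cost item of both arms, the
#' effectiveness parameters (on-demand plerixafor probabilities 0.47 and 0.09;
#' success probabilities 0.838 with and 0.702 without plerixafor), resource
#' quantities with their reported gamma 95% CIs, and unit costs. Unit costs
#' that are not printed directly are fixed by arithmetic on the published cost
#' table (e.g. plerixafor EUR 5064.86 per vial, apheresis session EUR 438.99,
#' missed-apheresis opportunity cost EUR 438.99 per session, cyclophosphamide
#' administration EUR 211.04 per inpatient day); items whose decomposition is
#' not recoverable are carried at their printed amounts with quantity one.
#' Drug acquisition costs and wage rates are held fixed (no distribution).
#'
#' @return a validated [model_config()] object.
#' @export
#' @examples
#' cfg <- base_case_fixture()
#' compare_strategies(cfg)
base_case_fixture <- function() {
  params <- list(
    # demographic and anthropometric parameters (range for age; CV 0.4 gammas)
    uq_fixed("age", 57.62, c(51.38, 62.38), units = "years"),
    uq_gamma("bodyweight", 70.00, c(26.34, 134.61), "kg"),
    uq_gamma("height", 170.00, c(136.68, 203.32), "cm"),

    # shared effectiveness parameters (probability of successful 4e6 CD34+ apheresis)
    uq_beta("e_with_plx", 0.838),
    uq_beta("e_without_plx", 0.702),

    # shared plerixafor parameters
    uq_gamma("plx_vials_per_user", 1.51, units = "vials"),
    uq_fixed("plx_price_per_vial", 5064.86),
    uq_gamma("plx_admin_per_user", 195.75, units = "EUR"),

    # shared tariffs
    uq_gamma("fbc_unit_cost", 4.76, units = "EUR"),
    uq_gamma("flow_cytometry_cost", 51.00, units = "EUR"),
    uq_gamma("sc_processing_cost", 668.00, units = "EUR"),
    uq_gamma("sc_freezing_cost", 510.00, units = "EUR"),
    uq_gamma("sc_thawing_cost", 148.00, units = "EUR"),
    uq_gamma("missed_session_cost", 438.99, units = "EUR"),

    # chemotherapy-free arm (G-CSF +/- on-demand plerixafor)
    uq_beta("p_plx_gcsf", 0.47),
    uq_fixed("gcsf_drug_cost_gcsf", 1332.52),
    uq_gamma("apheresis_sessions_gcsf", 2.00, c(0.75, 3.85), "sessions"),
    uq_gamma("session_cost_gcsf", 438.99, units = "EUR"),
    uq_gamma("missed_sessions_gcsf", 0.48, c(0.18, 0.92), "sessions"),
    uq_gamma("transport_cost_gcsf", 92.29, units = "EUR"),
    uq_gamma("parking_cost_gcsf", 30.00, units = "EUR"),
    uq_gamma("productivity_hours_gcsf", 11.47, c(0.01, 58.96), "hours"),
    uq_fixed("productivity_rate_gcsf", 249.17 / 11.47, units = "EUR/hour"),
    uq_gamma("informal_hours_gcsf", 11.34, c(0.01, 58.29), "hours"),
    uq_fixed("informal_rate_gcsf", 174.13 / 11.34, units = "EUR/hour"),

    # chemotherapy arm (CTX 4 g/m2 + G-CSF +/- on-demand plerixafor)
    uq_beta("p_plx_ctx", 0.09),
    uq_fixed("ctx_drug_cost", 128.13),
    uq_fixed("gcsf_drug_cost_ctx", 1110.43),
    uq_gamma("ctx_days", 2.00, c(0.75, 3.85), "days"),
    uq_gamma("ctx_day_cost", 211.04, units = "EUR"),
    uq_gamma("fn_days", 0.35, c(0.00, 2.04), "days"),
    uq_gamma("fn_day_cost", 149.15 / 0.35, units = "EUR"),
    uq_gamma("rbc_units", 0.24, c(0.00, 1.68), "transfusions"),
    uq_gamma("rbc_unit_cost", 495.89 / 0.24, units = "EUR"),
    uq_gamma("plt_units", 0.12, c(0.00, 1.10), "transfusions"),
    uq_gamma("plt_unit_cost", 243.38 / 0.12, units = "EUR"),
    uq_gamma("cvc_cost", 150.58, units = "EUR"),
    uq_gamma("apheresis_sessions_ctx", 1.60, c(0.60, 3.08), "sessions"),
    uq_gamma("session_cost_ctx", 479.95, units = "EUR"),
    uq_gamma("missed_sessions_ctx", 0.95, c(0.36, 1.83), "sessions"),
    uq_gamma("fbc_apheresis_ctx_cost", 12.02, units = "EUR"),
    uq_gamma("transport_cost_ctx", 242.70, units = "EUR"),
    uq_gamma("parking_cost_ctx", 79.20, units = "EUR"),
    uq_gamma("productivity_hours_ctx", 78.08, c(17.50, 182.84), "hours"),
    uq_fixed("productivity_rate_ctx", 1695.84 / 78.08, units = "EUR/hour"),
    uq_gamma("informal_hours_ctx", 76.46, c(16.85, 180.59), "hours"),
    uq_fixed("informal_rate_ctx", 1236.40 / 76.46, units = "EUR/hour")
  )
  names(params) <- vapply(params, function(p) p$name, character(1))

  ctx <- strategy_definition(
    name = "CTX 4 g/m2 + G-CSF (on-demand PLX)",
    cost_items = list(
      cost_item("CTX drug", "mobilization_drugs", "INHS", character(), "ctx_drug_cost"),
      cost_item("G-CSF drug", "mobilization_drugs", "INHS", character(), "gcsf_drug_cost_ctx"),
      cost_item("PLX drug (on demand)", "mobilization_drugs", "INHS",
                c("p_plx_ctx", "plx_vials_per_user"), "plx_price_per_vial"),
      cost_item("CTX administration (inpatient)", "mobilization_admin", "INHS",
                "ctx_days", "ctx_day_cost"),
      cost_item("PLX administration (day hospital)", "mobilization_admin", "INHS",
                "p_plx_ctx", "plx_admin_per_user"),
      cost_item("Full blood count (mobilization)", "full_blood_count", "INHS",
                character(), "fbc_unit_cost"),
      cost_item("Central venous catheter", "central_venous_catheter", "INHS",
                character(), "cvc_cost"),
      cost_item("Febrile neutropenia hospitalization", "febrile_neutropenia", "INHS",
                "fn_days", "fn_day_cost"),
      cost_item("RBC transfusions", "transfusions", "INHS", "rbc_units", "rbc_unit_cost"),
      cost_item("PLT transfusions", "transfusions", "INHS", "plt_units", "plt_unit_cost"),
      cost_item("Flow cytometry", "apheresis_procedures", "INHS",
                character(), "flow_cytometry_cost"),
      cost_item("Full blood count (apheresis)", "apheresis_procedures", "INHS",
                character(), "fbc_apheresis_ctx_cost"),
      cost_item("Apheresis sessions", "apheresis_procedures", "INHS",
                "apheresis_sessions_ctx", "session_cost_ctx"),
      cost_item("Missed apheresis (opportunity cost)", "missed_apheresis", "INHS",
                "missed_sessions_ctx", "missed_session_cost"),
      cost_item("SC processing", "stem_cell_handling", "INHS", character(), "sc_processing_cost"),
      cost_item("SC freezing", "stem_cell_handling", "INHS", character(), "sc_freezing_cost"),
      cost_item("SC thawing", "stem_cell_handling", "INHS", character(), "sc_thawing_cost"),
      cost_item("Transportation", "transportation", "out_of_pocket",
                character(), "transport_cost_ctx"),
      cost_item("Parking", "parking", "out_of_pocket", character(), "parking_cost_ctx"),
      cost_item("Patient loss of working hours", "productivity_loss", "patient_time",
                "productivity_hours_ctx", "productivity_rate_ctx"),
      cost_item("Informal care", "informal_care", "patient_time",
                "informal_hours_ctx", "informal_rate_ctx")
    ),
    p_plx = "p_plx_ctx", e_with_plx = "e_with_plx", e_without_plx = "e_without_plx"
  )

  gcsf <- strategy_definition(
    name = "G-CSF (on-demand PLX)",
    cost_items = list(
      cost_item("G-CSF drug", "mobilization_drugs", "INHS", character(), "gcsf_drug_cost_gcsf"),
      cost_item("PLX drug (on demand)", "mobilization_drugs", "INHS",
                c("p_plx_gcsf", "plx_vials_per_user"), "plx_price_per_vial"),
      cost_item("PLX administration (day hospital)", "mobilization_admin", "INHS",
                "p_plx_gcsf", "plx_admin_per_user"),
      cost_item("Full blood count (mobilization)", "full_blood_count", "INHS",
                character(), "fbc_unit_cost"),
      cost_item("Flow cytometry", "apheresis_procedures", "INHS",
                character(), "flow_cytometry_cost"),
      cost_item("Full blood count (apheresis)", "apheresis_procedures", "INHS",
                character(), "fbc_unit_cost"),
      cost_item("Apheresis sessions", "apheresis_procedures", "INHS",
                "apheresis_sessions_gcsf", "session_cost_gcsf"),
      cost_item("Missed apheresis (opportunity cost)", "missed_apheresis", "INHS",
                "missed_sessions_gcsf", "missed_session_cost"),
      cost_item("SC processing", "stem_cell_handling", "INHS", character(), "sc_processing_cost"),
      cost_item("SC freezing", "stem_cell_handling", "INHS", character(), "sc_freezing_cost"),
      cost_item("SC thawing", "stem_cell_handling", "INHS", character(), "sc_thawing_cost"),
      cost_item("Transportation", "transportation", "out_of_pocket",
                character(), "transport_cost_gcsf"),
      cost_item("Parking", "parking", "out_of_pocket", character(), "parking_cost_gcsf"),
      cost_item("Patient loss of working hours", "productivity_loss", "patient_time",
                "productivity_hours_gcsf", "productivity_rate_gcsf"),
      cost_item("Informal care", "informal_care", "patient_time",
                "informal_hours_gcsf", "informal_rate_gcsf")
    ),
    p_plx = "p_plx_gcsf", e_with_plx = "e_with_plx", e_without_plx = "e_without_plx"
  )

  model_config(
    strategies = list(ctx, gcsf),  # comparator first, treatment second
    parameters = params,
    demographics = list(age = "age", employed_fraction = 0.5, retirement_age = 70),
    wages = list(gross = 28.08, net = 15.36),
    currency_year = "EUR2019"
  )
}
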