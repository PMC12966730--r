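#' Default prevalences of the harmonized binary risk items
#'
#' Baseline prevalences used by [sim_config()] for the binary risk-factor
#' items of the synthetic ageing cohort. Values are plausible for a
#' Norwegian population aged ~58-90 at risk assessment and cover the union
#' of items referenced by the shipped score configurations (cardio-metabolic
#' factors, lifestyle factors, sensory impairment, psychosocial factors,
#' APOE-e4 carriership and area deprivation).
#'
#' @return Named numeric vector of probabilities in \[0, 1\].
#' @export
default_factor_prevalences <- function() {
  c(
    smoking = 0.22, diabetes = 0.09, hypertension = 0.45, obesity = 0.22,
    depression = 0.12, physical_inactivity = 0.30, high_cholesterol = 0.40,
    heart_disease = 0.10, stroke = 0.04, hearing_loss = 0.20,
    social_isolation = 0.15, alcohol_high = 0.08, tbi = 0.05,
    visual_impairment = 0.10, air_pollution = 0.10, sleep_problems = 0.15,
    renal_disease = 0.03, low_cognitive_activity = 0.30,
    unhealthy_diet = 0.35, family_history_dementia = 0.25,
    apoe4 = 0.27, deprivation = 0.12
  )
}

#' Configuration of the synthetic two-visit cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults emulate a large ageing cohort with risk factors measured at a
#' baseline wave and MoCA (0-30) assessed at two later visits roughly four
#' years apart: ages 57.8-89.9 (mean 66.3, SD 5.6) at risk assessment,
#' 54.1% women, 12.7 (SD 2.3) years of education, follow-up intervals of
#' 2.9-5.2 years (mean 4.2, SD 0.3), and health- and age-dependent attrition
#' at the second cognitive visit.
#'
#' The latent cognitive trajectory of participant *i* is
#' \deqn{y_i(t) = b_{0i} + \lambda r_i + (\beta_0 + \gamma r_i + u_{1i}) t + e_{it}}
#' where \eqn{r_i} is the true risk burden (a weighted sum of the generated
#' risk items, see `risk_weights`), \eqn{\lambda} = `level_per_risk_unit`,
#' \eqn{\gamma} = `slope_per_risk_unit`, \eqn{\beta_0} = `base_slope`, and
#' \eqn{u_{1i}} a random slope correlated with the random level \eqn{b_{0i}}.
#' Observed MoCA is the latent value rounded half-away-from-zero and clamped
#' to \[0, 30\].
#'
#' @param n_participants Number of participants (non-negative integer).
#' @param seed Integer seed; expanded internally into per-stage substreams.
#' @param age_mean_sd,age_range_baseline Mean/SD and truncation range of
#'   baseline age in years.
#' @param sex_female_prob Probability of female sex.
#' @param education_mean_sd,education_range Mean/SD and truncation range of
#'   education in years.
#' @param factor_prevalences Named probabilities of the binary risk items.
#' @param risk_weights Named weights defining the true risk burden
#'   `true_risk` as a deterministic weighted sum. Binary items enter as 0/1;
#'   the special names `age` and `education` enter centred at 65 and 12
#'   years respectively so that the burden scale is anchored at a typical
#'   participant.
#' @param level_per_risk_unit MoCA points of visit-1 level per unit burden.
#' @param slope_per_risk_unit MoCA points/year of additional annual change
#'   per unit burden (negative = faster decline).
#' @param base_slope Mean annual MoCA change (points/year) at zero burden.
#' @param baseline_moca_mean_sd Mean/SD of the random cognitive level
#'   \eqn{b_{0i}} (points).
#' @param random_slope_sd SD of the participant-specific slope deviation
#'   \eqn{u_{1i}} (points/year).
#' @param intercept_slope_cor Correlation between \eqn{b_{0i}} and
#'   \eqn{u_{1i}} (lower-functioning participants decline faster when
#'   positive... the sign convention is cor(level, slope), so a positive
#'   value means higher level goes with less negative slope).
#' @param residual_sd SD of the occasion-level measurement noise (points).
#' @param followup_interval_mean_sd,followup_range Mean/SD and truncation
#'   range of the visit-1 to visit-2 interval (years).
#' @param attrition_coefficients Named log-odds for the attrition model
#'   (must include `(Intercept)`); names refer to cohort columns, `sex`
#'   codes male = 1. `latent_level` targets the participant's true baseline
#'   cognitive level, making attrition informative.
#' @param item_missingness_rates Named per-item probabilities of blanking a
#'   risk item (missing completely at random).
#' @return An object of class `drs_sim_config` (a validated list).
#' @seealso [generate_cohort()], [write_sim_config()]
#' @export
sim_config <- function(n_participants = 7221,
                       seed = 1L,
                       age_mean_sd = c(66.3, 5.6),
                       age_range_baseline = c(57.8, 89.9),
                       sex_female_prob = 0.541,
                       education_mean_sd = c(12.7, 2.3),
                       education_range = c(5, 25),
                       factor_prevalences = default_factor_prevalences(),
                       risk_weights = default_risk_weights(),
                       level_per_risk_unit = -0.35,
                       slope_per_risk_unit = -0.05,
                       base_slope = -0.05,
                       baseline_moca_mean_sd = c(25.1, 2.5),
                       random_slope_sd = 0.15,
                       intercept_slope_cor = 0.3,
                       residual_sd = 1.2,
                       followup_interval_mean_sd = c(4.2, 0.3),
                       followup_range = c(2.9, 5.2),
                       attrition_coefficients = default_attrition_coefficients(),
                       item_missingness_rates = default_missingness_rates()) {
  cfg <- list(
    n_participants = n_participants, seed = seed,
    age_mean_sd = age_mean_sd, age_range_baseline = age_range_baseline,
    sex_female_prob = sex_female_prob,
    education_mean_sd = education_mean_sd, education_range = education_range,
    factor_prevalences = factor_prevalences, risk_weights = risk_weights,
    level_per_risk_unit = level_per_risk_unit,
    slope_per_risk_unit = slope_per_risk_unit, base_slope = base_slope,
    baseline_moca_mean_sd = baseline_moca_mean_sd,
    random_slope_sd = random_slope_sd,
    intercept_slope_cor = intercept_slope_cor,
    residual_sd = residual_sd,
    followup_interval_mean_sd = followup_interval_mean_sd,
    followup_range = followup_range,
    attrition_coefficients = attrition_coefficients,
    item_missingness_rates = item_missingness_rates
  )
  validate_sim_config(cfg)
  structure(cfg, class = "drs_sim_config")
}

#' @rdname sim_config
#' @export
default_risk_weights <- function() {
  w <- rep(1, length(default_factor_prevalences()))
  names(w) <- names(default_factor_prevalences())
  c(w, age = 0.05, education = -0.05)
}

#' @rdname sim_config
#' @export
default_attrition_coefficients <- function() {
  # calibrated to ~65% second-visit attendance with older, lower-functioning
  # participants dropping out preferentially
  c(`(Intercept)` = 4.53, age_baseline = -0.08, latent_level = 0.06)
}

#' @rdname sim_config
#' @export
default_missingness_rates <- function() {
  r <- rep(0.015, length(default_factor_prevalences()))
  names(r) <- names(default_factor_prevalences())
  r
}

validate_sim_config <- function(cfg) {
  num_fields <- c(
    "n_participants", "seed", "age_mean_sd", "age_range_baseline",
    "sex_female_prob", "education_mean_sd", "education_range",
    "factor_prevalences", "risk_weights", "level_per_risk_unit",
    "slope_per_risk_unit", "base_slope", "baseline_moca_mean_sd",
    "random_slope_sd", "intercept_slope_cor", "residual_sd",
    "followup_interval_mean_sd", "followup_range",
    "attrition_coefficients", "item_missingness_rates"
  )
  for (f in num_fields) {
    v <- cfg[[f]]
    if (is.null(v)) stop_config("sim_config field '", f, "' is missing")
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop_config("sim_config field '", f, "' must be finite numeric")
    }
  }
  if (cfg$n_participants < 0 || cfg$n_participants != floor(cfg$n_participants)) {
    stop_config("n_participants must be a non-negative integer")
  }
  assert_prob(cfg$sex_female_prob, "sex_female_prob")
  assert_prob(cfg$factor_prevalences, "factor_prevalences")
  assert_prob(cfg$item_missingness_rates, "item_missingness_rates")
  if (length(cfg$factor_prevalences) &&
      is.null(names(cfg$factor_prevalences))) {
    stop_config("factor_prevalences must be named")
  }
  if (length(cfg$item_missingness_rates)) {
    unknown <- setdiff(names(cfg$item_missingness_rates),
                       names(cfg$factor_prevalences))
    if (length(unknown)) {
      stop_config("item_missingness_rates names not in factor_prevalences: ",
                  paste(unknown, collapse = ", "))
    }
  }
  if (abs(cfg$intercept_slope_cor) > 1) {
    stop_config("intercept_slope_cor must lie in [-1, 1]")
  }
  if (cfg$residual_sd < 0 || cfg$random_slope_sd < 0) {
    stop_config("standard deviations must be non-negative")
  }
  if (diff(cfg$followup_range) <= 0 || cfg$followup_range[1] <= 0) {
    stop_config("followup_range must be an increasing positive interval")
  }
  if (is.null(names(cfg$attrition_coefficients)) ||
      !"(Intercept)" %in% names(cfg$attrition_coefficients)) {
    stop_config("attrition_coefficients must be named and include (Intercept)")
  }
  invisible(cfg)
}

#' Read and write simulation configurations as YAML
#'
#' @param config A `drs_sim_config` object.
#' @param path File path of the YAML document.
#' @return `read_sim_config()` returns a validated `drs_sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "drs_sim_config"))
  out <- unclass(config)
  # named numeric vectors must become lists to serialize as YAML maps
  for (f in c("factor_prevalences", "risk_weights", "attrition_coefficients",
              "item_missingness_rates")) {
    out[[f]] <- as.list(out[[f]])
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  listy <- c("factor_prevalences", "risk_weights", "attrition_coefficients",
             "item_missingness_rates")
  for (f in listy) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(sim_config, raw)
}
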