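test_that("an empty cohort request yields a typed empty table", {
  co <- generate_cohort(quick_config(0, 1))
  expect_s3_class(co, "drs_cohort")
  expect_identical(nrow(co), 0L)
  expect_true(all(c("id", "age_baseline", "sex", "education", "true_risk",
                    "moca_visit1", "moca_visit2", "followup_years",
                    "attended_followup") %in% names(co)))
})

test_that("generation is deterministic for a fixed configuration", {
  cfg <- sim_config(n_participants = 300, seed = 42)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other <- generate_cohort(sim_config(n_participants = 300, seed = 43))
  expect_false(identical(generate_cohort(cfg)$moca_visit1, other$moca_visit1))
})

test_that("item prevalences match their generating probabilities", {
  n <- 5000
  cfg <- sim_config(n_participants = n, seed = 11,
                    factor_prevalences = c(diabetes = 0.10),
                    risk_weights = c(diabetes = 1),
                    attrition_coefficients = c(`(Intercept)` = 20),
                    item_missingness_rates = no_missingness())
  co <- generate_cohort(cfg)
  # exact binomial 99% interval around 0.10
  bounds <- qbinom(c(0.005, 0.995), n, 0.10)
  expect_gte(sum(co$diabetes), bounds[1])
  expect_lte(sum(co$diabetes), bounds[2])
})

test_that("zero noise and zero risk effects give identical visit scores", {
  cfg <- quick_config(400, 5, residual_sd = 0, slope_per_risk_unit = 0,
                      level_per_risk_unit = 0, base_slope = 0,
                      random_slope_sd = 0,
                      attrition_coefficients = c(`(Intercept)` = 20))
  co <- generate_cohort(cfg)
  att <- co$attended_followup
  expect_true(all(att))
  expect_identical(co$moca_visit1[att], co$moca_visit2[att])
})

test_that("MoCA observations are integers within the instrument bounds", {
  co <- generate_cohort(sim_config(n_participants = 2000, seed = 9,
                                   baseline_moca_mean_sd = c(27, 6),
                                   residual_sd = 4))
  expect_true(is.integer(co$moca_visit1))
  expect_true(all(co$moca_visit1 >= 0 & co$moca_visit1 <= 30))
  v2 <- co$moca_visit2[!is.na(co$moca_visit2)]
  expect_true(all(v2 >= 0 & v2 <= 30))
  expect_gt(attr(co, "n_clamped"), 0)
})

test_that("attrition follows its logistic model", {
  n <- 5000
  cfg <- quick_config(n, 13, attrition_coefficients = c(`(Intercept)` = 0))
  co <- generate_cohort(cfg)
  bounds <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(sum(co$attended_followup), bounds[1])
  expect_lte(sum(co$attended_followup), bounds[2])

  all_in <- apply_attrition(co, c(`(Intercept)` = 20), seed = 1)
  expect_true(all(all_in$attended_followup))

  aged <- apply_attrition(co, c(`(Intercept)` = 6.6, age_baseline = -0.1),
                          seed = 2)
  tt <- t.test(aged$age_baseline[!aged$attended_followup],
               aged$age_baseline[aged$attended_followup],
               alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  expect_true(all(is.na(aged$moca_visit2[!aged$attended_followup])))
})

test_that("attrition on an unknown covariate is a configuration error", {
  co <- generate_cohort(quick_config(20, 1))
  expect_error(apply_attrition(co, c(`(Intercept)` = 0, nonexistent = 1), 1),
               class = "drs_config_error")
})

test_that("item missingness hits its per-item rates and nothing else", {
  n <- 5000
  cfg <- quick_config(n, 17, attrition_coefficients = c(`(Intercept)` = 20))
  co <- generate_cohort(cfg)

  expect_identical(apply_item_missingness(co, stats::setNames(
    rep(0, 2), c("smoking", "diabetes")), seed = 3), co)

  all_gone <- apply_item_missingness(co, c(smoking = 1), seed = 3)
  expect_true(all(is.na(all_gone$smoking)))
  expect_identical(all_gone$diabetes, co$diabetes)

  some <- apply_item_missingness(co, c(diabetes = 0.2), seed = 4)
  bounds <- qbinom(c(0.005, 0.995), n, 0.2)
  expect_gte(sum(is.na(some$diabetes)), bounds[1])
  expect_lte(sum(is.na(some$diabetes)), bounds[2])

  expect_error(apply_item_missingness(co, c(diabetes = 1.2), 1),
               class = "drs_config_error")
  expect_error(apply_item_missingness(co, c(age_baseline = 0.1), 1),
               class = "drs_config_error")
})

test_that("the generative slope is recoverable from observed change", {
  cfg <- quick_config(2000, 23, residual_sd = 0.3, random_slope_sd = 0,
                      attrition_coefficients = c(`(Intercept)` = 20))
  co <- generate_cohort(cfg)
  rate <- (co$moca_visit2 - co$moca_visit1) / co$followup_years
  fit <- lm(rate ~ co$true_risk)
  est <- coef(summary(fit))["co$true_risk", ]
  expect_lt(abs(est["Estimate"] - cfg$slope_per_risk_unit),
            2 * est["Std. Error"])
})

test_that("cohort CSV and sim-config YAML round-trip", {
  cfg <- sim_config(n_participants = 150, seed = 31)
  co <- generate_cohort(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, csv)
  back <- read_cohort(csv)
  for (nm in names(co)) expect_identical(back[[nm]], co[[nm]], info = nm)

  yml <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, yml)
  cfg2 <- read_sim_config(yml)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
  expect_identical(generate_cohort(cfg2), co)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_participants = -1), class = "drs_config_error")
  expect_error(sim_config(sex_female_prob = 1.4), class = "drs_config_error")
  expect_error(sim_config(residual_sd = NaN), class = "drs_config_error")
  expect_error(sim_config(factor_prevalences = c(diabetes = -0.1)),
               class = "drs_config_error")
})
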