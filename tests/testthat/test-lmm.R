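make_scores <- function(cohort, z = NULL, tertile = NULL) {
  data.frame(id = cohort$id,
             z = z %||% cohort$true_risk,
             tertile = tertile %||% "low")
}

test_that("the long table has one row per available visit", {
  co <- generate_cohort(quick_config(5, 2,
                                     attrition_coefficients = c(`(Intercept)` = 20)))
  co$attended_followup[1:2] <- FALSE
  co$moca_visit2[1:2] <- NA_integer_
  tab <- build_long_table(co, make_scores(co), "continuous")
  expect_identical(nrow(tab), 8L)
  expect_true(all(tab$time[!duplicated(tab$id)] == 0))
  expect_true(all(tab$time[duplicated(tab$id)] > 0))
})

test_that("tertile coding uses low as the reference group", {
  co <- generate_cohort(quick_config(9, 3,
                                     attrition_coefficients = c(`(Intercept)` = 20)))
  tert <- rep(c("low", "medium", "high"), 3)
  tab <- build_long_table(co, make_scores(co, tertile = tert), "tertile")
  low_rows <- tab$risk_group == "low"
  expect_true(all(tab$tertile_medium[low_rows] == 0))
  expect_true(all(tab$tertile_high[low_rows] == 0))
  expect_identical(levels(tab$risk_group), c("low", "medium", "high"))
})

test_that("a follow-up score without a baseline score is a data error", {
  co <- generate_cohort(quick_config(5, 2,
                                     attrition_coefficients = c(`(Intercept)` = 20)))
  co$moca_visit1[3] <- NA_integer_
  expect_error(build_long_table(co, make_scores(co), "continuous"),
               class = "drs_config_error")
})

test_that("a generative time x score effect is recovered within its CI", {
  cfg <- quick_config(2000, 101, slope_per_risk_unit = -0.20,
                      random_slope_sd = 0,
                      attrition_coefficients = c(`(Intercept)` = 0.7))
  co <- generate_cohort(cfg)
  fit <- fit_lmm(build_long_table(co, make_scores(co), "continuous"),
                 random_slopes = FALSE)
  row <- fit$fixed[fit$fixed$term == "time:score_z", ]
  expect_gt(-0.20, row$ci_lo)
  expect_lt(-0.20, row$ci_hi)
})

test_that("a permuted score shows no interaction", {
  cfg <- quick_config(2000, 103, random_slope_sd = 0,
                      attrition_coefficients = c(`(Intercept)` = 0.7))
  co <- generate_cohort(cfg)
  set.seed(1)
  shuffled <- sample(co$true_risk)
  fit <- fit_lmm(build_long_table(co, make_scores(co, z = shuffled),
                                  "continuous"), random_slopes = FALSE)
  row <- fit$fixed[fit$fixed$term == "time:score_z", ]
  expect_lt(abs(row$estimate), 3 * row$se)
})

test_that("noiseless linear trajectories are recovered almost exactly", {
  cfg <- quick_config(500, 107, residual_sd = 0, random_slope_sd = 0,
                      slope_per_risk_unit = -0.13,
                      attrition_coefficients = c(`(Intercept)` = 20))
  co <- generate_cohort(cfg)
  tab <- build_long_table(co, make_scores(co), "continuous")
  # bypass the bounded integer observation: evaluate the latent trajectory
  lat <- co[match(tab$id, co$id), ]
  tab$moca <- lat$latent_level + lat$latent_slope * tab$time
  fit <- fit_lmm(tab, random_slopes = FALSE)
  expect_equal(interaction_estimate(fit), -0.13, tolerance = 1e-4)
})

test_that("weights of one reproduce the unweighted fit exactly", {
  co <- generate_cohort(quick_config(400, 109))
  sc <- make_scores(co)
  unit <- stats::setNames(rep(1, nrow(co)), as.character(co$id))
  f0 <- fit_lmm(build_long_table(co, sc, "continuous"))
  f1 <- fit_lmm(build_long_table(co, sc, "continuous", weights = unit))
  expect_identical(f1$fixed$estimate, f0$fixed$estimate)
  expect_identical(f1$logLik, f0$logLik)
})

test_that("model comparison reports LRT and AIC differences", {
  cfg <- quick_config(2000, 113, random_slope_sd = 0.6,
                      intercept_slope_cor = 0, residual_sd = 0.6,
                      attrition_coefficients = c(`(Intercept)` = 20))
  co <- generate_cohort(cfg)
  tab <- build_long_table(co, make_scores(co), "continuous")
  ri <- fit_lmm(tab, ml = TRUE, random_slopes = FALSE)
  rs <- fit_lmm(tab, ml = TRUE, random_slopes = TRUE)

  self <- compare_models(ri, ri)
  expect_equal(self$lrt_stat, 0)
  expect_equal(self$delta_aic, 0)
  expect_identical(self$df, 0L)

  cmp <- compare_models(ri, rs)
  expect_gte(cmp$lrt_stat, 0)
  # true slope heterogeneity: the random-slope model must fit better
  expect_lt(cmp$delta_aic, 0)
  expect_match(cmp$boundary_note, "variance components")

  short <- fit_lmm(tab[tab$id %in% unique(tab$id)[1:500], ], ml = TRUE,
                   random_slopes = FALSE)
  expect_error(compare_models(short, rs), class = "drs_config_error")
})

test_that("moderation terms recover group-specific score-related decline", {
  set.seed(211)
  n <- 4000
  id <- seq_len(n)
  z <- rnorm(n)
  age_group <- factor(sample(c("<65", ">=65"), n, TRUE),
                      levels = c("<65", ">=65"))
  sex <- factor(sample(c("female", "male"), n, TRUE),
                levels = c("female", "male"))
  b0 <- rnorm(n, 24, 2)
  slope <- -0.1 - 0.05 * z - 0.15 * z * (age_group == ">=65") -
    0.10 * z * (sex == "male")
  t2 <- runif(n, 2.9, 5.2)
  tab <- rbind(
    data.frame(id, time = 0, moca = b0 + rnorm(n, 0, 0.8),
               score_z = z, age_group, sex, weight = 1),
    data.frame(id, time = t2, moca = b0 + slope * t2 + rnorm(n, 0, 0.8),
               score_z = z, age_group, sex, weight = 1)
  )
  fit <- fit_lmm_moderation(tab, random_slopes = FALSE)
  fx <- fit$fixed
  three_age <- fx[fx$term == "time:score_z:age_group>=65", ]
  three_sex <- fx[fx$term == "time:score_z:sexmale", ]
  expect_lt(three_age$estimate, 0)
  expect_lt(abs(three_age$estimate - (-0.15)), 2 * three_age$se)
  expect_lt(three_sex$estimate, 0)
  expect_lt(abs(three_sex$estimate - (-0.10)), 2 * three_sex$se)
})

test_that("independent moderators show null moderation terms", {
  set.seed(223)
  n <- 3000
  id <- seq_len(n)
  z <- rnorm(n)
  age_group <- factor(sample(c("<65", ">=65"), n, TRUE),
                      levels = c("<65", ">=65"))
  sex <- factor(sample(c("female", "male"), n, TRUE),
                levels = c("female", "male"))
  b0 <- rnorm(n, 24, 2)
  t2 <- runif(n, 2.9, 5.2)
  tab <- rbind(
    data.frame(id, time = 0, moca = b0 + rnorm(n, 0, 0.8),
               score_z = z, age_group, sex, weight = 1),
    data.frame(id, time = t2, moca = b0 + (-0.1 - 0.1 * z) * t2 +
                 rnorm(n, 0, 0.8), score_z = z, age_group, sex, weight = 1)
  )
  fit <- fit_lmm_moderation(tab, random_slopes = FALSE)
  fx <- fit$fixed
  for (term in c("time:score_z:age_group>=65", "time:score_z:sexmale")) {
    row <- fx[fx$term == term, ]
    expect_lt(abs(row$estimate), 3 * row$se)
  }
})

test_that("the 65-year threshold splits a realistic cohort in two", {
  co <- generate_cohort(sim_config(n_participants = 3000, seed = 71))
  tab <- build_long_table(co, make_scores(co), "continuous")
  counts <- base::table(tab$age_group[!duplicated(tab$id)])
  expect_true(all(counts > 0))
  share_under <- counts["<65"] / sum(counts)
  expect_gt(share_under, 0.3)
  expect_lt(share_under, 0.7)
})

test_that("an empty moderator cell is reported by name", {
  co <- generate_cohort(quick_config(200, 5,
                                     attrition_coefficients = c(`(Intercept)` = 20)))
  co$age_baseline <- 70  # everyone >= 65
  tab <- build_long_table(co, make_scores(co), "continuous")
  expect_error(fit_lmm_moderation(tab), class = "drs_config_error")
})
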