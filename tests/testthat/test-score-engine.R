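test_that("complete toy profiles score by direct item sum", {
  def <- toy_def_smoking_diabetes()
  res <- compute_score(list(smoking = 1, diabetes = 1), def)
  expect_equal(res$raw_points, 3.5)
  expect_true(res$complete)
  expect_equal(res$prorated, 3.5)

  none <- compute_score(list(smoking = 0, diabetes = 0), def)
  expect_equal(none$raw_points, 0)
  expect_equal(none$prorated, 0)
})

test_that("a missing item triggers prorating to the theoretical scale", {
  def <- toy_def_smoking_diabetes()
  res <- compute_score(list(smoking = 1, diabetes = NA), def)
  expect_equal(res$raw_points, 2.0)
  expect_equal(res$max_available, 2.0)
  expect_equal(res$theoretical_max, 3.5)
  expect_equal(res$prorated, 2.0 / 2.0 * 3.5)
  expect_false(res$complete)
})

test_that("a profile with no observed item is unscorable, never zero", {
  def <- toy_def_smoking_diabetes()
  expect_error(compute_score(list(smoking = NA, diabetes = NA), def),
               class = "drs_unscorable_error")
  expect_error(compute_score(list(), def), class = "drs_unscorable_error")
})

test_that("prorate implements the observed/available x maximum formula", {
  expect_identical(prorate(5, 10, 20), 10)
  expect_identical(prorate(0, 10, 20), 0)
  set.seed(1)
  for (i in 1:50) {
    x <- runif(1, -5, 20)
    M <- runif(1, 0.5, 30)
    expect_equal(prorate(x, M, M), x)
  }
  expect_error(prorate(1, 0, 10), class = "drs_unscorable_error")
  expect_error(prorate(1, -2, 10), class = "drs_unscorable_error")
  expect_error(prorate(1, 2, 0), class = "drs_config_error")
})

test_that("theoretical maximum sums per-item maxima, protective items at 0", {
  expect_equal(theoretical_max_for(toy_def_smoking_diabetes()), 3.5)

  def <- score_definition("prot", list(
    score_item("risk", "binary", points_present = 2),
    score_item("protect", "binary", points_present = 0, points_absent = -1)
  ))
  expect_equal(theoretical_max_for(def), 2.0)

  lin <- score_definition("lin", list(
    score_item("age", "linear", source = "age_baseline",
               slope = 0.07, anchor = 100, demographic = TRUE)
  ))
  expect_equal(theoretical_max_for(lin), 7.0)
  expect_error(score_item("age", "linear", slope = 0.07, anchor = NULL),
               class = "drs_config_error")
})

test_that("demographic augmentation and stripping are inverse", {
  base <- toy_def_smoking_diabetes()
  demo <- list(
    score_item("age", "banded", source = "age_baseline", demographic = TRUE,
               bands = list(list(upper = 64.99, points = 0),
                            list(upper = Inf, points = 3))),
    score_item("sex", "categorical", source = "sex", demographic = TRUE,
               mapping = c(female = 0, male = 1))
  )
  aug <- augment_with_demographics(base, demo)
  expect_setequal(names(aug$items), c("smoking", "diabetes", "age", "sex"))
  expect_equal(theoretical_max_for(aug),
               theoretical_max_for(base) +
                 theoretical_max_for(score_definition("d", demo)))
  expect_identical(names(strip_demographics(aug)$items), names(base$items))
  expect_identical(strip_demographics(base), base)
  expect_identical(augment_with_demographics(base, list()), base)
  expect_error(augment_with_demographics(aug, demo),
               class = "drs_config_error")
})

test_that("the shipped UKBDRS table strips to its clinical items", {
  defs <- load_score_definitions()
  stripped <- strip_demographics(defs$ukbdrs)
  expect_false(any(c("age", "sex", "education") %in% names(stripped$items)))
  expect_true(all(c("diabetes", "stroke", "hypertension") %in%
                    names(stripped$items)))
  # augmented modifiable-factor scores carry borrowed age/sex items
  expect_true(all(c("age", "sex") %in% names(defs$lancet$items)))
  expect_false("education" %in% names(defs$lancet$items))
  expect_identical(names(strip_demographics(defs$lancet)$items),
                   setdiff(names(defs$lancet$items),
                           c("low_education", "age", "sex")))
})

test_that("z-standardization uses the n-1 standard deviation", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z$z, c(-1, 0, 1))
  set.seed(4)
  x <- rnorm(100, 50, 7)
  expect_lt(abs(mean(zscore(x)$z)), 1e-9)
  expect_equal(sd(zscore(x)$z), 1, tolerance = 1e-9)
  expect_error(zscore(c(5, 5, 5)), class = "drs_degenerate_error")
  # scale equivariance
  expect_equal(zscore(3 * x + 10)$z, zscore(x)$z, tolerance = 1e-12)
})

test_that("tertile assignment follows the lower-group tie convention", {
  t9 <- assign_tertiles(1:9)
  expect_identical(as.character(t9),
                   rep(c("low", "medium", "high"), each = 3))
  set.seed(8)
  x <- rnorm(200)
  expect_identical(as.character(assign_tertiles(x)),
                   as.character(assign_tertiles(exp(x))))
  expect_warning(t_deg <- assign_tertiles(rep(2, 5)), "degenerate")
  expect_identical(as.character(t_deg), rep("low", 5))
  # ties exactly at a cutpoint fall to the lower group
  t_tie <- assign_tertiles(c(1, 1, 1, 2, 2, 2, 3, 3, 3))
  expect_identical(as.character(t_tie), rep(c("low", "medium", "high"), each = 3))
})

test_that("the engine matches a brute-force oracle on random profiles", {
  defs <- list(toy_def_smoking_diabetes(), toy_def_mixed())
  set.seed(99)
  for (i in 1:300) {
    prof <- random_toy_profile()
    for (def in defs) {
      orc <- oracle_score(prof, def)
      if (orc$observed == 0L) {
        expect_error(compute_score(prof, def), class = "drs_unscorable_error")
      } else {
        res <- compute_score(prof, def)
        expect_identical(res$raw_points, orc$raw)
        expect_identical(res$max_available, orc$max_avail)
        expect_identical(res$observed_items, orc$observed)
      }
    }
  }
})

test_that("vectorized cohort scoring agrees with per-profile scoring", {
  co <- generate_cohort(sim_config(n_participants = 120, seed = 77))
  def <- toy_def_mixed()
  tab <- score_cohort(co, def)
  for (i in seq_len(nrow(co))) {
    prof <- as.list(co[i, ])
    if (!tab$scorable[i]) next
    res <- compute_score(prof, def)
    expect_equal(tab$raw[i], res$raw_points)
    expect_equal(tab$prorated[i], res$prorated)
  }
  expect_identical(attr(tab, "n_unscorable"), sum(!tab$scorable))
})

test_that("adding a risk item never decreases a nonnegative-weight score", {
  def <- toy_def_smoking_diabetes()
  set.seed(12)
  for (i in 1:100) {
    prof <- list(smoking = sample(0:1, 1), diabetes = sample(0:1, 1))
    base <- compute_score(prof, def)$raw_points
    for (nm in c("smoking", "diabetes")) {
      if (prof[[nm]] == 0) {
        bumped <- prof
        bumped[[nm]] <- 1
        expect_gte(compute_score(bumped, def)$raw_points, base)
      }
    }
  }
})

test_that("scores are configuration-driven: swapping tables changes output", {
  dir <- withr::local_tempdir()
  write_toy_score_yaml(dir, "table_a", 2.0, 1.5)
  defs <- load_score_definitions(dir)
  prof <- list(smoking = 1, diabetes = 1)
  expect_equal(compute_score(prof, defs$table_a)$raw_points, 3.5)

  write_toy_score_yaml(dir, "table_a", 5.0, 0.5)
  defs2 <- load_score_definitions(dir)
  expect_equal(compute_score(prof, defs2$table_a)$raw_points, 5.5)
})
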