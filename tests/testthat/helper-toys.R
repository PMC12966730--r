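# shared fixtures: toy score definitions, brute-force oracles, small cohorts

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_def_smoking_diabetes <- function() {
  score_definition("toy_sd", list(
    score_item("smoking", "binary", points_present = 2.0),
    score_item("diabetes", "binary", points_present = 1.5)
  ))
}

# mixed item types incl. a protective item and demographics
toy_def_mixed <- function() {
  score_definition("toy_mixed", list(
    score_item("age", "banded", source = "age_baseline", demographic = TRUE,
               bands = list(list(upper = 64.99, points = 0),
                            list(upper = 74.99, points = 2),
                            list(upper = Inf, points = 4))),
    score_item("sex", "categorical", source = "sex", demographic = TRUE,
               mapping = c(female = 0, male = 1)),
    score_item("smoking", "binary", points_present = 1.5),
    score_item("diet", "binary", source = "unhealthy_diet",
               points_present = 0, points_absent = -1.0)
  ))
}

# independent brute-force item sum: re-derives points per item from the
# definition structure without calling the engine internals
oracle_score <- function(profile, def) {
  raw <- 0
  max_avail <- 0
  observed <- 0L
  for (it in def$items) {
    v <- profile[[it$source]]
    if (is.null(v) || is.na(v)) next
    pts <- switch(it$type,
      binary = if (as.logical(v)) it$points_present else it$points_absent,
      categorical = unname(it$mapping[[as.character(v)]]),
      banded = it$band_points[[which(v <= it$band_upper)[1]]],
      linear = it$slope * v
    )
    imax <- switch(it$type,
      binary = max(it$points_present, it$points_absent),
      categorical = max(it$mapping),
      banded = max(it$band_points),
      linear = it$slope * it$anchor
    )
    raw <- raw + pts
    max_avail <- max_avail + max(0, imax)
    observed <- observed + 1L
  }
  list(raw = raw, max_avail = max_avail, observed = observed)
}

# all-pairs AUC with half credit for ties (double loop)
oracle_auc <- function(marker, labels) {
  pos <- marker[as.logical(labels)]
  neg <- marker[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

random_toy_profile <- function() {
  list(
    smoking = sample(c(0L, 1L, NA), 1, prob = c(0.45, 0.45, 0.10)),
    diabetes = sample(c(0L, 1L, NA), 1, prob = c(0.45, 0.45, 0.10)),
    unhealthy_diet = sample(c(0L, 1L, NA), 1, prob = c(0.45, 0.45, 0.10)),
    age_baseline = round(runif(1, 55, 95), 1),
    sex = sample(c("female", "male"), 1)
  )
}

no_missingness <- function() stats::setNames(numeric(0), character(0))

# small fast cohort configuration for model tests
quick_config <- function(n, seed, ...) {
  sim_config(n_participants = n, seed = seed,
             item_missingness_rates = no_missingness(), ...)
}

# the informative-attrition regime: attrition driven by the latent baseline
# cognitive level, with correlated level/slope heterogeneity, so unweighted
# two-visit fits understate score-related decline
informative_attrition_config <- function(n, seed) {
  sim_config(
    n_participants = n, seed = seed,
    level_per_risk_unit = -1.0, slope_per_risk_unit = -0.2,
    base_slope = -0.1, baseline_moca_mean_sd = c(25, 2.5),
    random_slope_sd = 0.6, intercept_slope_cor = 0.8,
    residual_sd = 0.8,
    attrition_coefficients = c(`(Intercept)` = -12.0, latent_level = 0.6),
    item_missingness_rates = no_missingness()
  )
}

# true-risk long table: z column carries the (unstandardized) generative
# burden so the time x score coefficient equals slope_per_risk_unit
true_risk_scores <- function(cohort) {
  data.frame(id = cohort$id, z = cohort$true_risk, tertile = "low")
}

interaction_estimate <- function(fit) {
  fit$fixed$estimate[fit$fixed$term == "time:score_z"]
}

write_toy_score_yaml <- function(dir, name, smoking_w, diabetes_w) {
  path <- file.path(dir, paste0(name, ".yaml"))
  writeLines(c(
    paste0("name: ", name),
    "items:",
    paste0("  - {name: smoking, type: binary, points_present: ", smoking_w, "}"),
    paste0("  - {name: diabetes, type: binary, points_present: ", diabetes_w, "}")
  ), path)
  path
}
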