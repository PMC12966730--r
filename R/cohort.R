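# truncated-normal draws via inverse-CDF so a single runif() vector is
# consumed per stage regardless of acceptance/rejection
rtnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(clamp(mean, lo, hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

risk_item_names <- function(config) names(config$factor_prevalences)

# deterministic weighted sum defining the latent burden; age and education
# enter centred (65 y, 12 y) so binary items and demographics share a scale
compute_true_risk <- function(tab, weights) {
  risk <- numeric(nrow(tab))
  for (nm in names(weights)) {
    x <- switch(nm,
      age = tab$age_baseline - 65,
      education = tab$education - 12,
      {
        if (is.null(tab[[nm]])) {
          stop_config("risk_weights names unknown cohort column: ", nm)
        }
        tab[[nm]]
      }
    )
    risk <- risk + weights[[nm]] * x
  }
  risk
}

#' Generate a synthetic two-visit cohort
#'
#' Draws a full synthetic cohort under the generative model described in
#' [sim_config()]: demographics, independent binary risk items, a latent
#' cognitive trajectory whose level and slope depend on the true risk
#' burden, bounded integer MoCA observations at two visits, informative
#' attrition at the second visit and item-level missingness in the risk
#' items. Attrition and missingness are applied through
#' [apply_attrition()] and [apply_item_missingness()] using per-stage
#' substreams of `config$seed`, so the cohort is byte-reproducible for a
#' fixed configuration.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` of class `drs_cohort` with one row per
#'   participant: `id`, `age_baseline`, `sex` ("female"/"male"),
#'   `education`, one 0/1 column per risk item, `true_risk`,
#'   `latent_level`, `latent_slope` (generative diagnostics),
#'   `followup_years`, `attended_followup`, `moca_visit1`, `moca_visit2`
#'   (NA for non-attendees). The number of observations clamped at the
#'   MoCA bounds is recorded in `attr(, "n_clamped")`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- as.integer(config$n_participants)
  items <- risk_item_names(config)
  if (n == 0L) {
    out <- empty_cohort(items)
    return(out)
  }

  demo <- with_stage_seed(config$seed, "demographics", {
    age <- round(rtnorm(n, config$age_mean_sd[1], config$age_mean_sd[2],
                        config$age_range_baseline[1], config$age_range_baseline[2]), 1)
    sex <- ifelse(runif(n) < config$sex_female_prob, "female", "male")
    edu <- round(rtnorm(n, config$education_mean_sd[1], config$education_mean_sd[2],
                        config$education_range[1], config$education_range[2]), 1)
    data.frame(id = seq_len(n), age_baseline = age, sex = sex, education = edu,
               stringsAsFactors = FALSE)
  })

  item_tab <- with_stage_seed(config$seed, "risk_items", {
    cols <- lapply(items, function(it) {
      as.integer(runif(n) < config$factor_prevalences[[it]])
    })
    names(cols) <- items
    as.data.frame(cols)
  })

  tab <- cbind(demo, item_tab)
  tab$true_risk <- compute_true_risk(tab, config$risk_weights)

  traj <- with_stage_seed(config$seed, "trajectory", {
    b0 <- rnorm(n, config$baseline_moca_mean_sd[1], config$baseline_moca_mean_sd[2])
    z <- rnorm(n)
    b0s <- if (config$baseline_moca_mean_sd[2] > 0) {
      (b0 - config$baseline_moca_mean_sd[1]) / config$baseline_moca_mean_sd[2]
    } else numeric(n)
    u1 <- config$random_slope_sd *
      (config$intercept_slope_cor * b0s +
         sqrt(1 - config$intercept_slope_cor^2) * z)
    list(b0 = b0, u1 = u1)
  })

  tab$latent_level <- traj$b0 + config$level_per_risk_unit * tab$true_risk
  tab$latent_slope <- config$base_slope +
    config$slope_per_risk_unit * tab$true_risk + traj$u1

  tab$followup_years <- with_stage_seed(config$seed, "followup", {
    round(rtnorm(n, config$followup_interval_mean_sd[1],
                 config$followup_interval_mean_sd[2],
                 config$followup_range[1], config$followup_range[2]), 3)
  })

  moca <- with_stage_seed(config$seed, "moca", {
    e1 <- rnorm(n, 0, config$residual_sd)
    e2 <- rnorm(n, 0, config$residual_sd)
    lat1 <- tab$latent_level + e1
    lat2 <- tab$latent_level + tab$latent_slope * tab$followup_years + e2
    list(v1 = observe_moca(lat1), v2 = observe_moca(lat2))
  })
  tab$moca_visit1 <- moca$v1$score
  tab$moca_visit2 <- moca$v2$score
  tab$attended_followup <- TRUE
  n_clamped <- moca$v1$n_clamped + moca$v2$n_clamped

  tab <- apply_attrition(tab, config$attrition_coefficients,
                         seed = stage_seed(config$seed, "attrition"))
  tab <- apply_item_missingness(tab, config$item_missingness_rates,
                                seed = stage_seed(config$seed, "missingness"))
  attr(tab, "n_clamped") <- n_clamped
  class(tab) <- c("drs_cohort", "data.frame")
  tab
}

# integer MoCA observation: round half away from zero, clamp to [0, 30]
observe_moca <- function(latent) {
  r <- round_half_away(latent)
  s <- clamp(r, 0, 30)
  list(score = as.integer(s), n_clamped = sum(r != s))
}

empty_cohort <- function(items) {
  tab <- data.frame(id = integer(), age_baseline = numeric(),
                    sex = character(), education = numeric(),
                    stringsAsFactors = FALSE)
  for (it in items) tab[[it]] <- integer()
  tab$true_risk <- numeric()
  tab$latent_level <- numeric()
  tab$latent_slope <- numeric()
  tab$followup_years <- numeric()
  tab$attended_followup <- logical()
  tab$moca_visit1 <- integer()
  tab$moca_visit2 <- integer()
  class(tab) <- c("drs_cohort", "data.frame")
  tab
}

attrition_design_column <- function(cohort, nm) {
  if (nm == "sex") return(as.numeric(cohort$sex == "male"))
  x <- cohort[[nm]]
  if (is.null(x)) {
    stop_config("attrition coefficient names unknown cohort column: ", nm)
  }
  as.numeric(x)
}

#' Apply (informative) attrition at the follow-up visit
#'
#' Draws second-visit attendance from a logistic model
#' \eqn{P(\mathrm{attend}) = \mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j x_j)}
#' over cohort columns and blanks `moca_visit2` and `followup_years` for
#' non-attendees. The special name `sex` codes male = 1; `latent_level`
#' makes attrition depend on the participant's true baseline cognition (a
#' quantity an analyst never observes, which is what makes unweighted
#' longitudinal estimates attrition-biased).
#'
#' @param cohort A `drs_cohort` data frame in which everyone is still an
#'   attendee (or whose attendance is to be redrawn).
#' @param coefficients Named log-odds including `(Intercept)`.
#' @param seed Integer seed for the Bernoulli draws.
#' @return The cohort with `attended_followup`, `moca_visit2` and
#'   `followup_years` updated.
#' @export
apply_attrition <- function(cohort, coefficients, seed) {
  if (is.null(names(coefficients)) || !"(Intercept)" %in% names(coefficients)) {
    stop_config("attrition coefficients must be named and include (Intercept)")
  }
  if (any(!is.finite(coefficients))) {
    stop_config("attrition coefficients must be finite")
  }
  n <- nrow(cohort)
  lp <- rep(coefficients[["(Intercept)"]], n)
  for (nm in setdiff(names(coefficients), "(Intercept)")) {
    lp <- lp + coefficients[[nm]] * attrition_design_column(cohort, nm)
  }
  p <- plogis(lp)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  attend <- runif(n) < p
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", envir = globalenv(), old)
  cohort$attended_followup <- attend
  cohort$moca_visit2[!attend] <- NA_integer_
  cohort$followup_years[!attend] <- NA_real_
  cohort
}

#' Blank risk items completely at random
#'
#' Independently sets each listed risk item to missing with its configured
#' rate, emulating item-level nonresponse in questionnaire-derived risk
#' factors. Demographics (`age_baseline`, `sex`, `education`) are never
#' blanked.
#'
#' @param cohort A `drs_cohort` data frame.
#' @param rates Named per-item missingness probabilities.
#' @param seed Integer seed.
#' @return The cohort with NAs injected into the listed item columns.
#' @export
apply_item_missingness <- function(cohort, rates, seed) {
  if (length(rates) == 0) return(cohort)
  if (is.null(names(rates))) stop_config("missingness rates must be named")
  assert_prob(rates, "item missingness rates")
  protected <- c("age_baseline", "sex", "education", "id")
  bad <- intersect(names(rates), protected)
  if (length(bad)) {
    stop_config("demographics are never blanked: ", paste(bad, collapse = ", "))
  }
  unknown <- setdiff(names(rates), names(cohort))
  if (length(unknown)) {
    stop_config("missingness rates name unknown items: ",
                paste(unknown, collapse = ", "))
  }
  n <- nrow(cohort)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  for (nm in names(rates)) {
    miss <- runif(n) < rates[[nm]]
    cohort[[nm]][miss] <- NA
  }
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", envir = globalenv(), old)
  cohort
}

#' Read and write cohorts as CSV
#'
#' `write_cohort()` serializes every numeric column through `%.17g` so the
#' CSV round-trips doubles exactly; `read_cohort()` restores column types
#' and the `drs_cohort` class.
#'
#' @param cohort A `drs_cohort` data frame.
#' @param path CSV path.
#' @return `read_cohort()` returns a `drs_cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA, sprintf("%.17g", out[[nm]]))
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if ("attended_followup" %in% names(tab)) {
    tab$attended_followup <- as.logical(tab$attended_followup)
  }
  for (nm in c("moca_visit1", "moca_visit2", "id")) {
    if (nm %in% names(tab)) tab[[nm]] <- as.integer(tab[[nm]])
  }
  class(tab) <- c("drs_cohort", "data.frame")
  tab
}
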