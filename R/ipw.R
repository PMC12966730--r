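#' Fit the follow-up participation model
#'
#' Maximum-likelihood logistic regression of second-visit attendance on
#' baseline covariates (default: age, education and a set of health
#' factors established as predictors of attrition in ageing cohorts).
#' Complete cases on the listed covariates are used. Perfect separation and
#' outcome degeneracy are raised as errors rather than returned as a
#' numerically unstable fit.
#'
#' @param cohort A `drs_cohort`.
#' @param covariates Character vector of cohort columns; `sex` is allowed
#'   and coded male = 1.
#' @return A list of class `drs_participation_model`: `model` (the `glm`),
#'   `coefficients`, `se`, `aic`, `converged`, `n`, `covariates`.
#' @export
fit_participation_model <- function(cohort,
                                    covariates = c("age_baseline", "education",
                                                   "heart_disease", "depression",
                                                   "diabetes", "hypertension",
                                                   "stroke")) {
  missing_cols <- setdiff(covariates, c(names(cohort), "sex"))
  if (length(missing_cols)) {
    stop_config("cohort lacks participation covariates: ",
                paste(missing_cols, collapse = ", "))
  }
  dat <- data.frame(.attend = as.numeric(cohort$attended_followup))
  for (nm in covariates) dat[[nm]] <- attrition_design_column(cohort, nm)
  dat <- na.omit(dat)
  if (nrow(dat) == 0L) stop_config("no complete cases for participation model")
  if (length(unique(dat$.attend)) < 2L) {
    stop_config("attendance has no variation: participation model is degenerate")
  }
  form <- as.formula(paste(".attend ~", paste(covariates, collapse = " + ")))
  warn_sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        warn_sep <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("algorithm did not converge", msg)) {
        # handled below via fit$converged
        invokeRestart("muffleWarning")
      }
    }
  )
  if (warn_sep || !fit$converged || any(abs(coef(fit)[-1]) > 15)) {
    sds <- vapply(dat[covariates], sd, numeric(1))
    scaled <- abs(coef(fit)[covariates]) * sds
    worst <- covariates[which.max(scaled)]
    stop(structure(
      class = c("drs_separation_error", "error", "condition"),
      list(message = paste0("participation model shows (quasi-)separation; ",
                            "most extreme covariate: ", worst),
           call = sys.call())
    ))
  }
  structure(list(model = fit, coefficients = coef(fit),
                 se = sqrt(diag(vcov(fit))), aic = AIC(fit),
                 converged = fit$converged, n = nrow(dat),
                 covariates = covariates),
            class = "drs_participation_model")
}

#' Predicted participation probabilities for a cohort
#'
#' @param model A `drs_participation_model`.
#' @param cohort Cohort to predict for.
#' @return Numeric vector of probabilities (NA where covariates are
#'   missing).
#' @export
predict_participation <- function(model, cohort) {
  dat <- data.frame(row.names = seq_len(nrow(cohort)))
  for (nm in model$covariates) dat[[nm]] <- attrition_design_column(cohort, nm)
  as.numeric(predict(model$model, newdata = dat, type = "response"))
}

#' Inverse probability of attrition weights with upper truncation
#'
#' Weights are the reciprocal of the predicted participation probability;
#' to limit the influence of extreme weights, the upper tail is truncated
#' at the `truncation_quantile` empirical quantile (linear-interpolation
#' quantile; every weight above the cap, ties included, is set to the cap).
#'
#' @param p_hat Predicted participation probabilities in (0, 1].
#' @param truncation_quantile Cap quantile (default 0.99, i.e. the upper
#'   1\% of the weight distribution is truncated at the 99th percentile).
#' @return A list of class `drs_ipw`: `p_hat`, `weight`,
#'   `truncated_weight`, `cap_value`, `n_truncated`.
#' @export
compute_ipw <- function(p_hat, truncation_quantile = 0.99) {
  if (any(!is.finite(p_hat)) || any(p_hat <= 0) || any(p_hat > 1)) {
    stop_config("participation probabilities must lie in (0, 1]")
  }
  assert_prob(truncation_quantile, "truncation_quantile")
  w <- 1 / p_hat
  cap <- unname(quantile(w, truncation_quantile, names = FALSE))
  tw <- pmin(w, cap)
  structure(list(p_hat = p_hat, weight = w, truncated_weight = tw,
                 cap_value = cap, n_truncated = sum(w > cap)),
            class = "drs_ipw")
}

#' Write IPW weights as CSV
#'
#' @param ipw A `drs_ipw` object.
#' @param id Participant ids aligned with the weights.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ipw <- function(ipw, id, path) {
  out <- data.frame(id = id,
                    p_hat = sprintf("%.17g", ipw$p_hat),
                    weight = sprintf("%.17g", ipw$weight),
                    truncated_weight = sprintf("%.17g", ipw$truncated_weight))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
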