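#' Build the person-period table for mixed modelling
#'
#' Expands a cohort and one score's standardized results into long format:
#' a visit-1 row (time 0) for every scorable participant with a first MoCA,
#' and a visit-2 row (time = follow-up years) for attendees, so
#' non-returners still inform the level part of the model. Age group
#' (under/over 65 at risk assessment) and sex are carried as moderators.
#'
#' @param cohort A `drs_cohort`.
#' @param scores Per-participant data frame with `id`, `z` and `tertile`
#'   (one score's rows from [score_table()]); rows with NA `z` are dropped.
#' @param form "continuous" (z covariate) or "tertile" (low/medium/high
#'   with indicator columns, low as reference).
#' @param weights Optional named vector of observation weights keyed by
#'   participant id (defaults to 1).
#' @return Data frame of class `drs_long_table`: `id`, `time`, `moca`,
#'   `score_z` and/or `risk_group` (+ `tertile_medium`/`tertile_high`
#'   indicators), `age_group`, `sex`, `weight`.
#' @export
build_long_table <- function(cohort, scores,
                             form = c("continuous", "tertile"),
                             weights = NULL) {
  form <- match.arg(form)
  idx <- match(cohort$id, scores$id)
  sc <- scores[idx, , drop = FALSE]
  keep <- !is.na(sc$z) & !is.na(cohort$moca_visit1)
  bad <- !is.na(cohort$moca_visit2) & is.na(cohort$moca_visit1)
  if (any(bad)) {
    stop_config("participants with a follow-up MoCA but no baseline MoCA: ",
                paste(utils::head(cohort$id[bad], 5), collapse = ", "))
  }
  co <- cohort[keep, , drop = FALSE]
  sc <- sc[keep, , drop = FALSE]
  w <- rep(1, nrow(co))
  if (!is.null(weights)) {
    m <- match(as.character(co$id), names(weights))
    w <- ifelse(is.na(m), 1, as.numeric(weights[m]))
  }
  base <- data.frame(
    id = co$id, age_group = ifelse(co$age_baseline < 65, "<65", ">=65"),
    sex = co$sex, weight = w, stringsAsFactors = FALSE
  )
  if (form == "continuous") {
    base$score_z <- sc$z
  } else {
    base$risk_group <- factor(sc$tertile, levels = c("low", "medium", "high"))
    base$tertile_medium <- as.numeric(base$risk_group == "medium")
    base$tertile_high <- as.numeric(base$risk_group == "high")
  }
  v1 <- cbind(base, time = 0, moca = co$moca_visit1)
  has2 <- co$attended_followup & !is.na(co$moca_visit2)
  v2 <- cbind(base[has2, , drop = FALSE],
              time = co$followup_years[has2], moca = co$moca_visit2[has2])
  out <- rbind(v1, v2)
  out <- out[order(out$id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out$age_group <- factor(out$age_group, levels = c("<65", ">=65"))
  out$sex <- factor(out$sex, levels = c("female", "male"))
  class(out) <- c("drs_long_table", "data.frame")
  attr(out, "form") <- form
  out
}

lmm_fixed_formula <- function(table, moderators = NULL) {
  score_term <- if (!is.null(table$score_z)) "score_z" else "risk_group"
  if (is.null(moderators)) {
    paste("moca ~ time *", score_term)
  } else {
    paste0("moca ~ time * ", score_term, " * (",
           paste(moderators, collapse = " + "), ")")
  }
}

fit_lmer_checked <- function(formula, table, reml) {
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(as.formula(formula), data = table, weights = table$weight,
               REML = reml,
               # two observations per participant put the random-slope model
               # at lme4's obs-vs-RE identifiability guard; attempt the fit
               # anyway and let the singular-fit fallback handle degeneracy
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           check.nobs.vs.rankZ = "ignore",
                                           calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  list(fit = fit, messages = msgs)
}

#' Fit the MoCA level-and-change mixed model
#'
#' Linear mixed-effects model with fixed effects for time (years since the
#' first cognitive visit), the risk score (continuous z or tertile group)
#' and their interaction — the time x score term is the additional annual
#' MoCA change per SD (or per group vs low). Random intercepts and slopes
#' per participant are requested by default; with only two visits the
#' random-slope variance is weakly identified, so singular fits fall back,
#' with a logged notice, to random intercepts only (the fixed effects are
#' the estimand). Observation weights (IPW) enter as observation-level
#' weights; weights of 1 reproduce the unweighted fit.
#'
#' @param table A [build_long_table()] result.
#' @param ml Fit by maximum likelihood instead of REML (use ML when the fit
#'   feeds a likelihood-ratio test of fixed effects).
#' @param random_slopes Try a per-participant random slope for time
#'   (default TRUE, with the singular fallback).
#' @param moderators Optional character vector (e.g. `c("age_group",
#'   "sex")`) crossed with score and time up to three-way terms.
#' @return A list of class `drs_lmm`: `fixed` (term/estimate/se/ci/p),
#'   `random` (variance components), `logLik`, `aic`, `n_participants`,
#'   `n_rows`, `reml`, `singular_fallback`, `messages`, `formula`, `model`.
#' @export
fit_lmm <- function(table, ml = FALSE, random_slopes = TRUE,
                    moderators = NULL) {
  stopifnot(is.data.frame(table))
  n2 <- sum(duplicated(table$id))
  if (n2 < 2L) stop_config("need participants with two visits to model change")
  if (!is.null(moderators)) {
    for (m in moderators) {
      tab <- table(table[[m]], table$time > 0)
      if (any(tab == 0)) {
        empty <- which(tab == 0, arr.ind = TRUE)
        stop_config("empty moderator cell for '", m, "': level ",
                    rownames(tab)[empty[1, 1]])
      }
    }
  }
  fixed <- lmm_fixed_formula(table, moderators)
  singular_fallback <- FALSE
  if (random_slopes) {
    res <- fit_lmer_checked(paste(fixed, "+ (1 + time | id)"), table,
                            reml = !ml)
    if (lme4::isSingular(res$fit, tol = 1e-4)) {
      singular_fallback <- TRUE
      message("random-slope covariance is singular; ",
              "falling back to random intercepts only")
      res <- fit_lmer_checked(paste(fixed, "+ (1 | id)"), table, reml = !ml)
    }
  } else {
    res <- fit_lmer_checked(paste(fixed, "+ (1 | id)"), table, reml = !ml)
  }
  conv_fail <- grepl("failed to converge", res$messages, fixed = TRUE)
  if (any(conv_fail)) {
    stop_config("mixed model failed to converge: ",
                paste(res$messages[conv_fail], collapse = "; "))
  }
  as_drs_lmm(res$fit, singular_fallback = singular_fallback,
             messages = res$messages, reml = !ml)
}

as_drs_lmm <- function(fit, singular_fallback, messages, reml) {
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  fixed <- data.frame(
    term = rownames(sm), estimate = unname(est), se = unname(se),
    ci_lo = unname(est - qnorm(0.975) * se),
    ci_hi = unname(est + qnorm(0.975) * se),
    p = unname(2 * pnorm(-abs(est / se))),
    stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  ll <- logLik(fit)
  structure(list(
    fixed = fixed, random = vc, logLik = as.numeric(ll),
    df = attr(ll, "df"), aic = AIC(fit),
    n_participants = lme4::ngrps(fit)[["id"]], n_rows = stats::nobs(fit),
    reml = reml, singular_fallback = singular_fallback,
    messages = messages, formula = deparse1(stats::formula(fit)),
    model = fit
  ), class = "drs_lmm")
}

#' @export
print.drs_lmm <- function(x, ...) {
  cat("Linear mixed model:", x$formula, "\n")
  cat(sprintf("%d participants, %d rows; %s; AIC %.1f%s\n",
              x$n_participants, x$n_rows,
              if (x$reml) "REML" else "ML", x$aic,
              if (x$singular_fallback) " (random-intercept fallback)" else ""))
  print(x$fixed, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Moderation model for age group and sex
#'
#' Convenience wrapper around [fit_lmm()] adding moderator main effects and
#' all score/time interactions up to the three-way terms that express
#' group-specific score-related decline. Intended for demographics-stripped
#' scores (demographic moderators of a score that already contains age or
#' sex weights are collinear by construction).
#'
#' @inheritParams fit_lmm
#' @param moderators Moderator columns of the long table.
#' @return A `drs_lmm`.
#' @export
fit_lmm_moderation <- function(table, moderators = c("age_group", "sex"),
                               ml = FALSE, random_slopes = TRUE) {
  fit_lmm(table, ml = ml, random_slopes = random_slopes,
          moderators = moderators)
}

#' Likelihood-ratio and AIC comparison of nested mixed models
#'
#' Refits by maximum likelihood when needed (REML likelihoods are not
#' comparable across fixed-effect structures) and reports the LRT statistic
#' 2(logLik_full - logLik_restricted), its degrees of freedom and p-value,
#' and the AIC difference. When the models differ only in variance
#' components the p-value is conservative (boundary issue), which is noted
#' in the returned object.
#'
#' @param fit_restricted,fit_full `drs_lmm` fits on identical rows.
#' @return List: `lrt_stat`, `df`, `p`, `delta_aic` (full - restricted),
#'   `boundary_note`.
#' @export
compare_models <- function(fit_restricted, fit_full) {
  stopifnot(inherits(fit_restricted, "drs_lmm"), inherits(fit_full, "drs_lmm"))
  if (fit_restricted$n_rows != fit_full$n_rows) {
    stop_config("models were fitted on different numbers of rows (",
                fit_restricted$n_rows, " vs ", fit_full$n_rows, ")")
  }
  m0 <- fit_restricted$model
  m1 <- fit_full$model
  if (lme4::isREML(m0)) m0 <- update(m0, REML = FALSE)
  if (lme4::isREML(m1)) m1 <- update(m1, REML = FALSE)
  ll0 <- logLik(m0)
  ll1 <- logLik(m1)
  df <- attr(ll1, "df") - attr(ll0, "df")
  lrt <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  same_fixed <- identical(deparse1(stats::formula(m0, fixed.only = TRUE)),
                          deparse1(stats::formula(m1, fixed.only = TRUE)))
  list(
    lrt_stat = lrt, df = df,
    p = if (df > 0) pchisq(lrt, df, lower.tail = FALSE) else NA_real_,
    delta_aic = AIC(m1) - AIC(m0),
    boundary_note = if (same_fixed)
      "models differ in variance components; LRT p-value is conservative (boundary)"
    else NULL
  )
}
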