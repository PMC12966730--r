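# tiny polynomial string hash for config provenance (hex), dependency-free;
# modulus keeps every intermediate exactly representable in a double
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Configure an end-to-end pipeline run
#'
#' @param simulate A [sim_config()] describing the cohort to generate, or
#'   NULL when `cohort_csv` supplies the cohort.
#' @param cohort_csv Optional path to a cohort CSV (schema of
#'   [write_cohort()]) used instead of simulation.
#' @param score_dir Directory of score YAMLs (default: shipped tables).
#' @param seed Seed governing every stochastic stage; overrides the seed
#'   inside `simulate`.
#' @param out_dir Output directory (created if needed).
#' @param use_ipw Weight follow-up observations by truncated inverse
#'   participation probabilities.
#' @param strip_demographics Also run all analyses on demographics-stripped
#'   scores.
#' @param complete_case Restrict to participants whose every score is
#'   complete (no prorating).
#' @param decline_threshold MoCA-point drop defining binary decline.
#' @param forms Which score parameterizations to model.
#' @param moderation Fit the age-group/sex moderation models (on stripped
#'   scores).
#' @param sensitivity Run the threshold x floor sensitivity grid.
#' @return A list of class `drs_run_config`.
#' @export
run_config <- function(simulate = sim_config(), cohort_csv = NULL,
                       score_dir = system.file("extdata", "scores",
                                               package = "drscompare"),
                       seed = 1L, out_dir = NULL,
                       use_ipw = TRUE, strip_demographics = FALSE,
                       complete_case = FALSE, decline_threshold = 3,
                       forms = c("continuous", "tertile"),
                       moderation = TRUE, sensitivity = TRUE) {
  if (is.null(simulate) && is.null(cohort_csv)) {
    stop_config("run_config needs either a simulation config or a cohort CSV")
  }
  if (!is.null(cohort_csv) && !file.exists(cohort_csv)) {
    stop_config("cohort CSV does not exist: ", cohort_csv)
  }
  if (!dir.exists(score_dir)) stop_config("score_dir does not exist: ", score_dir)
  if (!is.null(simulate)) simulate$seed <- seed
  structure(list(simulate = simulate, cohort_csv = cohort_csv,
                 score_dir = score_dir, seed = seed, out_dir = out_dir,
                 use_ipw = isTRUE(use_ipw),
                 strip_demographics = isTRUE(strip_demographics),
                 complete_case = isTRUE(complete_case),
                 decline_threshold = decline_threshold,
                 forms = match.arg(forms, several.ok = TRUE),
                 moderation = isTRUE(moderation),
                 sensitivity = isTRUE(sensitivity)),
            class = "drs_run_config")
}

lmm_table_rows <- function(fit, score_name, form) {
  fx <- fit$fixed
  fx$score <- score_name
  fx$form <- form
  fx$aic <- fit$aic
  fx$singular_fallback <- fit$singular_fallback
  fx[, c("score", "form", "term", "estimate", "se", "ci_lo", "ci_hi", "p",
         "aic", "singular_fallback")]
}

#' Run the full benchmarking pipeline
#'
#' Executes simulate (or load) -> score -> standardize -> attrition weights
#' -> mixed models (continuous and tertile, optionally age/sex moderation
#' on demographics-stripped scores) -> binary-decline classification with
#' AUC and paired DeLong comparisons against the age + education benchmark
#' -> sensitivity grids, and (when `out_dir` is set) writes CSV/JSON/
#' markdown outputs plus a provenance record. Every stage is seeded from
#' `config$seed`, so identical configurations give byte-identical output
#' files. Any stage failure is re-raised with the stage name attached.
#'
#' @param config A [run_config()].
#' @return A list of class `drs_run_report` with elements `cohort`,
#'   `scores`, `ipw`, `lmm` (long data frame of fixed effects),
#'   `moderation`, `model_comparison`, `decline` (per-marker coefficients,
#'   AUC, DeLong vs demographics), `sensitivity`, `descriptives`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "drs_run_config"))
  log <- list(seed = config$seed,
              package_version = as.character(packageVersion("drscompare")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_config("pipeline stage '", name, "' failed [stage_error:", name,
                  "]: ", conditionMessage(e))
    })
  }

  cohort <- stage("simulate", {
    if (!is.null(config$cohort_csv)) read_cohort(config$cohort_csv)
    else generate_cohort(config$simulate)
  })
  log$n_participants <- nrow(cohort)
  log$n_clamped_moca <- attr(cohort, "n_clamped") %||% NA_integer_

  defs <- stage("score", load_score_definitions(config$score_dir))
  if (config$strip_demographics) {
    defs <- lapply(defs, strip_demographics)
  }
  scores <- stage("score", score_table(cohort, defs))
  log$n_unscorable <- attr(scores, "n_unscorable")
  log$n_incomplete <- vapply(split(scores, scores$score),
                             function(s) sum(!s$complete), numeric(1))

  if (config$complete_case) {
    incomplete_ids <- unique(scores$id[!scores$complete | !scores$scorable])
    log$n_excluded_complete_case <- length(incomplete_ids)
    cohort <- cohort[!cohort$id %in% incomplete_ids, , drop = FALSE]
    scores <- stage("score", score_table(cohort, defs))
  }

  ipw <- NULL
  weights <- NULL
  if (config$use_ipw) {
    ipw <- stage("weights", {
      pm <- fit_participation_model(cohort)
      p_hat <- predict_participation(pm, cohort)
      usable <- !is.na(p_hat)
      w <- compute_ipw(p_hat[usable])
      full <- rep(1, nrow(cohort))
      full[usable] <- w$truncated_weight
      list(model = pm, weights = w,
           by_id = stats::setNames(full, as.character(cohort$id)),
           n_default_weight = sum(!usable))
    })
    weights <- ipw$by_id
    log$participation_rate <- mean(cohort$attended_followup)
    log$ipw_cap <- ipw$weights$cap_value
    log$ipw_n_truncated <- ipw$weights$n_truncated
  }

  lmm_rows <- list()
  comparisons <- list()
  for (score_name in unique(scores$score)) {
    sc <- scores[scores$score == score_name, , drop = FALSE]
    for (form in config$forms) {
      fit <- stage("lmm", {
        tab <- build_long_table(cohort, sc, form = form, weights = weights)
        fit_lmm(tab)
      })
      lmm_rows[[paste(score_name, form)]] <-
        lmm_table_rows(fit, score_name, form)
      if (form == "continuous") {
        cmp <- stage("lmm", {
          tab <- build_long_table(cohort, sc, form = form, weights = weights)
          full <- fit_lmm(tab, ml = TRUE)
          restricted <- suppressMessages(
            fit_lmer_checked("moca ~ time + score_z + (1 | id)", tab,
                             reml = FALSE))
          restricted <- as_drs_lmm(restricted$fit, FALSE,
                                   restricted$messages, reml = FALSE)
          compare_models(restricted, full)
        })
        comparisons[[score_name]] <- data.frame(
          score = score_name, lrt_stat = cmp$lrt_stat, df = cmp$df,
          p = cmp$p, delta_aic = cmp$delta_aic)
      }
    }
  }
  lmm_df <- do.call(rbind, c(lmm_rows, list(make.row.names = FALSE)))
  comparison_df <- do.call(rbind, c(comparisons, list(make.row.names = FALSE)))

  moderation_df <- NULL
  if (config$moderation) {
    stripped <- lapply(defs, function(d) {
      tryCatch(strip_demographics(d), error = function(e) NULL)
    })
    stripped <- Filter(Negate(is.null), stripped)
    mod_scores <- stage("lmm_moderation", score_table(cohort, stripped))
    mod_rows <- lapply(unique(mod_scores$score), function(score_name) {
      sc <- mod_scores[mod_scores$score == score_name, , drop = FALSE]
      fit <- stage("lmm_moderation", {
        tab <- build_long_table(cohort, sc, form = "continuous",
                                weights = weights)
        fit_lmm_moderation(tab)
      })
      lmm_table_rows(fit, score_name, "continuous_stripped_moderation")
    })
    moderation_df <- do.call(rbind, c(mod_rows, list(make.row.names = FALSE)))
  }

  decline <- stage("classify", {
    labels <- label_decline(cohort, threshold = config$decline_threshold)
    lab_cohort <- cohort[match(labels$id, cohort$id), , drop = FALSE]
    w <- if (is.null(weights)) NULL else
      as.numeric(weights[as.character(labels$id)])
    demo_fit <- fit_logistic(labels$declined,
                             data.frame(age = lab_cohort$age_baseline,
                                        education = lab_cohort$education),
                             weights = w)
    demo_auc <- auc_mann_whitney(demo_fit$linear_predictor, labels$declined)
    rows <- list(data.frame(
      marker = "demographics_age_education", coef = NA_real_,
      ci_lo = NA_real_, ci_hi = NA_real_, aic = demo_fit$aic,
      auc = demo_auc$auc, auc_ci_lo = demo_auc$ci[1],
      auc_ci_hi = demo_auc$ci[2], delong_vs_demo_p = NA_real_,
      n = nrow(labels), n_declined = sum(labels$declined)))
    markers <- data.frame(id = labels$id)
    for (score_name in unique(scores$score)) {
      sc <- scores[scores$score == score_name, , drop = FALSE]
      z <- sc$z[match(labels$id, sc$id)]
      ok <- !is.na(z)
      fitl <- fit_logistic(labels$declined[ok], data.frame(z = z[ok]),
                           weights = if (is.null(w)) NULL else w[ok])
      a <- auc_mann_whitney(z[ok], labels$declined[ok])
      dl <- delong_test(z[ok], demo_fit$linear_predictor[ok],
                        labels$declined[ok])
      co <- fitl$coefficients[fitl$coefficients$term == "z", ]
      rows[[length(rows) + 1L]] <- data.frame(
        marker = score_name, coef = co$estimate, ci_lo = co$ci_lo,
        ci_hi = co$ci_hi, aic = fitl$aic, auc = a$auc,
        auc_ci_lo = a$ci[1], auc_ci_hi = a$ci[2], delong_vs_demo_p = dl$p,
        n = sum(ok), n_declined = sum(labels$declined[ok]))
      markers[[score_name]] <- z
    }
    markers$demographics_age_education <- demo_fit$linear_predictor
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         markers = markers, labels = labels)
  })

  sensitivity_df <- NULL
  if (config$sensitivity) {
    sensitivity_df <- stage("classify",
                            run_sensitivity_grid(cohort, decline$markers,
                                                 floor_exclusions =
                                                   c(NA, 18, 20, 22, 24)))
  }

  descriptives <- stage("report", summarize_cohort(cohort, scores))

  report <- structure(list(
    config = config, cohort = cohort, scores = scores, ipw = ipw,
    lmm = lmm_df, model_comparison = comparison_df,
    moderation = moderation_df, decline = decline$table,
    sensitivity = sensitivity_df, descriptives = descriptives, log = log
  ), class = "drs_run_report")

  if (!is.null(config$out_dir)) {
    stage("report", write_run_report(report, config$out_dir))
  }
  report
}

format_num_cols <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA, sprintf("%.12g", df[[nm]]))
    }
  }
  df
}

md_table <- function(df, digits = 3) {
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", formatC(x, digits = digits,
                                                    format = "g"))
    else ifelse(is.na(x), "", as.character(x))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Write a run report to disk
#'
#' Emits the pipeline outputs as CSV (cohort, scores, weights, sensitivity
#' grid, descriptives), JSON (model tables and the run log) and a
#' markdown summary whose every number is taken from those stage outputs.
#' No timestamps are written, so identical runs produce byte-identical
#' files.
#'
#' @param report A `drs_run_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_cohort(report$cohort, p("cohort.csv"))
  write_scores(report$scores, p("scores.csv"))
  if (!is.null(report$ipw)) {
    write_ipw(report$ipw$weights,
              report$cohort$id[!is.na(predict_participation(
                report$ipw$model, report$cohort))], p("weights.csv"))
  }
  jsonlite::write_json(
    list(lmm = report$lmm, model_comparison = report$model_comparison,
         moderation = report$moderation, decline = report$decline),
    p("models.json"), dataframe = "rows", na = "null", auto_unbox = TRUE,
    digits = NA)
  if (!is.null(report$sensitivity)) {
    write.csv(format_num_cols(report$sensitivity), p("sensitivity.csv"),
              row.names = FALSE, na = "")
  }
  write.csv(format_num_cols(report$descriptives$scores),
            p("descriptives_scores.csv"), row.names = FALSE, na = "")
  write.csv(format_num_cols(report$descriptives$comparisons),
            p("descriptives_comparisons.csv"), row.names = FALSE, na = "")
  hashable <- unclass(report$config)
  hashable$out_dir <- NULL  # output location is not part of the analysis
  cfg_yaml <- yaml::as.yaml(lapply(hashable, function(x) {
    if (inherits(x, "drs_sim_config")) unclass(x) else x
  }), precision = 15L)
  jsonlite::write_json(
    c(report$log, list(config_hash = fnv1a(cfg_yaml))),
    p("run.json"), auto_unbox = TRUE, digits = NA, na = "null")
  md <- c(
    "# Dementia risk score benchmarking run",
    "", paste0("Seed: ", report$log$seed, "; participants: ",
               report$log$n_participants, "; config hash: ",
               fnv1a(cfg_yaml)),
    "", "## Mixed models (fixed effects)", "", md_table(report$lmm),
    "", "## Random-slope model comparison (LRT)", "",
    md_table(report$model_comparison),
    "", "## Binary decline classification", "", md_table(report$decline),
    ""
  )
  if (!is.null(report$moderation)) {
    md <- c(md, "## Age/sex moderation (demographics-stripped scores)", "",
            md_table(report$moderation), "")
  }
  writeLines(md, p("report.md"))
  invisible(out_dir)
}

#' Cohort and score descriptives
#'
#' Summarizes each score (mean, SD, min, max of the prorated totals) and
#' compares returners with non-returners on demographics and baseline
#' MoCA: t-tests for means, chi-squared for sex, significance at p < 0.05.
#' Degenerate groups are reported as not estimable.
#'
#' @param cohort A `drs_cohort`.
#' @param scores A [score_table()] result.
#' @return List of class `drs_descriptives`: `scores`, `comparisons`.
#' @export
summarize_cohort <- function(cohort, scores) {
  sc <- lapply(split(scores, scores$score), function(s) {
    x <- s$prorated[s$scorable]
    data.frame(score = s$score[1], n = length(x), mean = mean(x),
               sd = sd(x), min = min(x), max = max(x))
  })
  sc_df <- do.call(rbind, c(sc, list(make.row.names = FALSE)))

  att <- cohort$attended_followup
  cmp_row <- function(variable, x, type = c("mean", "prop")) {
    type <- match.arg(type)
    g1 <- x[att]
    g0 <- x[!att]
    est <- length(g1) > 1 && length(g0) > 1
    if (type == "mean") {
      pv <- if (est && (sd(g1, na.rm = TRUE) > 0 || sd(g0, na.rm = TRUE) > 0))
        tryCatch(t.test(g1, g0)$p.value, error = function(e) NA_real_)
      else NA_real_
      data.frame(variable = variable,
                 returners = mean(g1, na.rm = TRUE),
                 non_returners = if (length(g0)) mean(g0, na.rm = TRUE) else NA_real_,
                 p = pv, estimable = est)
    } else {
      tab <- base::table(factor(att, c(FALSE, TRUE)), x)
      pv <- if (est && all(dim(tab) > 1))
        tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                 error = function(e) NA_real_)
      else NA_real_
      data.frame(variable = variable,
                 returners = mean(g1 == levels(factor(x))[1], na.rm = TRUE),
                 non_returners = if (length(g0))
                   mean(g0 == levels(factor(x))[1], na.rm = TRUE) else NA_real_,
                 p = pv, estimable = est)
    }
  }
  comparisons <- rbind(
    cmp_row("age_baseline", cohort$age_baseline),
    cmp_row("education", cohort$education),
    cmp_row("moca_visit1", cohort$moca_visit1),
    cmp_row("sex_female_share", cohort$sex, type = "prop")
  )
  structure(list(scores = sc_df, comparisons = comparisons),
            class = "drs_descriptives")
}
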