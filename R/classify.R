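#' Label binary cognitive decline
#'
#' Declares a participant declined when the first-visit MoCA exceeds the
#' second by at least `threshold` points (default 3, roughly one SD of
#' MoCA change — a magnitude usually taken to indicate real rather than
#' random change). Only participants with both assessments are labelled;
#' the number excluded is recorded in `attr(, "n_excluded")`.
#'
#' @param cohort A `drs_cohort`.
#' @param threshold Minimum point drop counted as decline.
#' @return Data frame `id`, `delta` (visit1 - visit2), `declined`.
#' @export
label_decline <- function(cohort, threshold = 3) {
  has_both <- !is.na(cohort$moca_visit1) & !is.na(cohort$moca_visit2)
  delta <- cohort$moca_visit1[has_both] - cohort$moca_visit2[has_both]
  out <- data.frame(id = cohort$id[has_both], delta = delta,
                    declined = delta >= threshold)
  attr(out, "n_excluded") <- sum(!has_both)
  attr(out, "threshold") <- threshold
  out
}

# placement values: for each positive case, the fraction of negatives it
# outranks (ties half-credit), and symmetrically for negatives
delong_placements <- function(marker, labels) {
  pos <- marker[labels]
  neg <- marker[!labels]
  m <- length(pos)
  n <- length(neg)
  if (m < 1L || n < 1L) {
    stop_config("AUC needs at least one case in each class (",
                m, " positive, ", n, " negative)")
  }
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp), m = m, n = n)
}

#' Mann-Whitney AUC with DeLong variance
#'
#' The area under the ROC curve computed as the Mann-Whitney probability
#' that a randomly chosen decliner's marker exceeds a non-decliner's, with
#' ties counted half. The variance is DeLong's placement-value estimator
#' \eqn{\mathrm{var}(V_{10})/m + \mathrm{var}(V_{01})/n}, giving a normal
#' 95\% CI clipped to \[0, 1\].
#'
#' @param marker Numeric marker (higher = more at risk).
#' @param labels Logical (or 0/1) decline labels.
#' @return List of class `drs_auc`: `auc`, `variance`, `ci`, `n_pos`,
#'   `n_neg`.
#' @export
auc_mann_whitney <- function(marker, labels) {
  labels <- as.logical(labels)
  if (anyNA(marker) || anyNA(labels)) stop_config("marker/labels contain NA")
  pl <- delong_placements(marker, labels)
  auc <- mean(pl$v10)
  v <- (if (pl$m > 1) var(pl$v10) / pl$m else 0) +
    (if (pl$n > 1) var(pl$v01) / pl$n else 0)
  ci <- clamp(auc + c(-1, 1) * qnorm(0.975) * sqrt(v), 0, 1)
  structure(list(auc = auc, variance = v, ci = ci,
                 n_pos = pl$m, n_neg = pl$n),
            class = "drs_auc")
}

#' DeLong's test for two correlated AUCs
#'
#' Paired comparison of two markers scored on the same labelled set:
#' \eqn{z = (\mathrm{AUC}_a - \mathrm{AUC}_b)/\sqrt{v_a + v_b - 2c_{ab}}}
#' with variances and the covariance estimated from placement values, and a
#' two-sided normal p-value. Comparing a marker with itself (or any
#' strictly increasing transform of it) gives a zero difference and p = 1.
#'
#' @param marker_a,marker_b Markers on the identical participants.
#' @param labels Logical decline labels.
#' @return List of class `drs_delong`: `auc_a`, `auc_b`, `var_diff`, `z`,
#'   `p`.
#' @export
delong_test <- function(marker_a, marker_b, labels) {
  labels <- as.logical(labels)
  if (length(marker_a) != length(marker_b) ||
      length(marker_a) != length(labels)) {
    stop_config("markers and labels must be scored on the identical set")
  }
  pa <- delong_placements(marker_a, labels)
  pb <- delong_placements(marker_b, labels)
  auc_a <- mean(pa$v10)
  auc_b <- mean(pb$v10)
  m <- pa$m
  n <- pa$n
  s10 <- if (m > 1) stats::cov(cbind(pa$v10, pb$v10)) else matrix(0, 2, 2)
  s01 <- if (n > 1) stats::cov(cbind(pa$v01, pb$v01)) else matrix(0, 2, 2)
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- auc_a - auc_b
  if (var_diff <= .Machine$double.eps) {
    if (abs(d) <= sqrt(.Machine$double.eps)) {
      return(structure(list(auc_a = auc_a, auc_b = auc_b, var_diff = 0,
                            z = 0, p = 1), class = "drs_delong"))
    }
    stop_config("degenerate DeLong variance: placements carry no variation")
  }
  z <- d / sqrt(var_diff)
  structure(list(auc_a = auc_a, auc_b = auc_b, var_diff = var_diff,
                 z = z, p = 2 * pnorm(-abs(z))),
            class = "drs_delong")
}

#' Logistic model of decline
#'
#' Maximum-likelihood logistic regression of the decline label on one or
#' more markers (a standardized risk score, or the age + education
#' demographics benchmark), honouring IPW as observation weights.
#' Coefficient estimates are invariant to rescaling all weights.
#'
#' @param labels Logical decline labels.
#' @param markers Data frame (or named list) of predictor columns aligned
#'   with `labels`.
#' @param weights Optional observation weights.
#' @return List of class `drs_logistic`: `coefficients` (term/estimate/se/
#'   ci/p), `aic`, `linear_predictor`, `model`.
#' @export
fit_logistic <- function(labels, markers, weights = NULL) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) {
    stop_config("decline labels have no variation: logistic fit is degenerate")
  }
  dat <- as.data.frame(markers)
  dat$.y <- as.numeric(labels)
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else as.numeric(weights)
  form <- as.formula(paste(".y ~",
                           paste(setdiff(names(dat), c(".y", ".w")),
                                 collapse = " + ")))
  warn_sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat, weights = dat$.w),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) warn_sep <<- TRUE
      if (grepl("non-integer #successes", msg) ||
          grepl("fitted probabilities numerically 0 or 1", msg)) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (warn_sep || any(abs(coef(fit)[-1]) > 15)) {
    stop(structure(class = c("drs_separation_error", "error", "condition"),
                   list(message = "logistic decline model shows (quasi-)separation",
                        call = sys.call())))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(list(
    coefficients = data.frame(
      term = names(est), estimate = unname(est), se = unname(se),
      ci_lo = unname(est - qnorm(0.975) * se),
      ci_hi = unname(est + qnorm(0.975) * se),
      p = unname(2 * pnorm(-abs(est / se))), stringsAsFactors = FALSE
    ),
    aic = AIC(fit),
    linear_predictor = as.numeric(predict(fit, type = "link")),
    model = fit
  ), class = "drs_logistic")
}

#' Sensitivity grid over decline thresholds and floor exclusions
#'
#' Re-evaluates each marker's discrimination across decline thresholds and
#' baseline-MoCA floor exclusions (dropping participants whose first-visit
#' score is below the floor, to limit floor effects in the change score).
#' Cells where one class is empty are reported as not estimable rather
#' than raising.
#'
#' @param cohort A `drs_cohort`.
#' @param markers Data frame with `id` and one numeric column per marker.
#' @param thresholds Decline thresholds in MoCA points.
#' @param floor_exclusions Baseline floors; NA means no exclusion.
#' @return Long data frame: `threshold`, `floor`, `marker`, `n`,
#'   `n_declined`, `auc`, `ci_lo`, `ci_hi`, `estimable`.
#' @export
run_sensitivity_grid <- function(cohort, markers,
                                 thresholds = c(2, 3, 4, 6, 9),
                                 floor_exclusions = c(NA, 18, 20, 22, 24)) {
  marker_names <- setdiff(names(markers), "id")
  rows <- list()
  for (fl in floor_exclusions) {
    sub <- if (is.na(fl)) cohort else
      cohort[!is.na(cohort$moca_visit1) & cohort$moca_visit1 >= fl, ,
             drop = FALSE]
    for (th in thresholds) {
      lab <- label_decline(sub, threshold = th)
      mk <- markers[match(lab$id, markers$id), , drop = FALSE]
      for (nm in marker_names) {
        ok <- !is.na(mk[[nm]])
        labs <- lab$declined[ok]
        est <- sum(labs) >= 1L && sum(!labs) >= 1L && length(labs) > 1L
        if (est) {
          a <- auc_mann_whitney(mk[[nm]][ok], labs)
          rows[[length(rows) + 1L]] <- data.frame(
            threshold = th, floor = fl, marker = nm, n = length(labs),
            n_declined = sum(labs), auc = a$auc,
            ci_lo = a$ci[1], ci_hi = a$ci[2], estimable = TRUE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            threshold = th, floor = fl, marker = nm, n = length(labs),
            n_declined = sum(labs), auc = NA_real_,
            ci_lo = NA_real_, ci_hi = NA_real_, estimable = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
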