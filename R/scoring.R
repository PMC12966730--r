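# vectorized evaluation of one item over a vector of profile values;
# NA in -> NA out, values outside a categorical domain are an error
item_points <- function(item, values) {
  if (item$type == "binary") {
    v <- if (is.logical(values)) values else {
      if (is.character(values)) {
        out <- rep(NA, length(values))
        out[values %in% c("yes", "present", "1", "TRUE", "true")] <- TRUE
        out[values %in% c("no", "absent", "0", "FALSE", "false")] <- FALSE
        bad <- !is.na(values) & is.na(out)
        if (any(bad)) {
          stop_config("binary item '", item$name, "' has undeclared values: ",
                      paste(unique(values[bad]), collapse = ", "))
        }
        out
      } else values != 0
    }
    return(ifelse(is.na(v), NA_real_,
                  ifelse(v, item$points_present, item$points_absent)))
  }
  if (item$type == "categorical") {
    v <- as.character(values)
    bad <- !is.na(v) & !v %in% names(item$mapping)
    if (any(bad)) {
      stop_config("categorical item '", item$name, "' has undeclared levels: ",
                  paste(unique(v[bad]), collapse = ", "))
    }
    return(as.numeric(item$mapping[v]))
  }
  if (item$type == "banded") {
    v <- as.numeric(values)
    idx <- findInterval(v, item$band_upper, left.open = TRUE) + 1L
    return(ifelse(is.na(v), NA_real_, item$band_points[idx]))
  }
  item$slope * as.numeric(values)
}

#' Prorate a partially observed score to its theoretical range
#'
#' Rescales the points observed on available items to the score's full
#' theoretical scale:
#' \deqn{\frac{\sum \mathrm{ObservedItemPoints}}
#'            {\sum \mathrm{MaxPossibleRiskPointsForAvailableItems}}
#'       \times \mathrm{MaximumRiskScore}}
#'
#' @param observed_points Sum of points over observed items.
#' @param max_available Maximum attainable risk points over those items.
#' @param theoretical_max The score's theoretical maximum.
#' @return The prorated score in points.
#' @export
prorate <- function(observed_points, max_available, theoretical_max) {
  if (any(!is.finite(max_available)) || any(max_available <= 0)) {
    stop(unscorable_error("prorating denominator (max available risk points) must be > 0"))
  }
  if (any(!is.finite(theoretical_max)) || any(theoretical_max <= 0)) {
    stop_config("theoretical_max must be > 0")
  }
  observed_points / max_available * theoretical_max
}

unscorable_error <- function(msg) {
  structure(class = c("drs_unscorable_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Score one participant profile
#'
#' Applies a [score_definition()] to a single harmonized profile. Items
#' whose value is missing contribute nothing and are excluded from the
#' prorating denominator; a profile with no observed item at all raises an
#' explicit unscorable error rather than silently returning 0.
#'
#' @param profile Named list (or single-row data frame) of harmonized
#'   values keyed by item source names.
#' @param definition A [score_definition()].
#' @return A list of class `drs_score_result`: `score`, `raw_points`,
#'   `observed_items`, `max_available`, `theoretical_max`, `prorated`,
#'   `complete`.
#' @export
compute_score <- function(profile, definition) {
  stopifnot(inherits(definition, "drs_score_definition"))
  profile <- as.list(profile)
  pts <- vapply(definition$items, function(it) {
    v <- profile[[it$source]]
    if (is.null(v) || length(v) != 1L || is.na(v)) return(NA_real_)
    item_points(it, v)
  }, numeric(1))
  observed <- !is.na(pts)
  if (!any(observed)) {
    stop(unscorable_error(paste0(
      "profile has no observed item for score '", definition$name, "'")))
  }
  raw <- sum(pts[observed])
  max_avail <- sum(vapply(definition$items[observed], item_risk_max, numeric(1)))
  tmax <- theoretical_max_for(definition)
  complete <- all(observed)
  pro <- if (complete) raw else prorate(raw, max_avail, tmax)
  structure(list(score = definition$name, raw_points = raw,
                 observed_items = sum(observed), max_available = max_avail,
                 theoretical_max = tmax, prorated = pro, complete = complete),
            class = "drs_score_result")
}

#' Score every participant of a cohort
#'
#' Vectorized counterpart of [compute_score()]. Participants with zero
#' observed items for the score are not an error here: they get NA results,
#' are flagged `scorable = FALSE` and counted in `attr(, "n_unscorable")`,
#' so they can be excluded from that score's analyses and reported in the
#' run log.
#'
#' @param cohort A `drs_cohort` (or any data frame with the item source
#'   columns).
#' @param definition A [score_definition()].
#' @return Data frame: `id`, `score`, `raw`, `observed_items`,
#'   `max_available`, `prorated`, `complete`, `scorable`.
#' @export
score_cohort <- function(cohort, definition) {
  stopifnot(inherits(definition, "drs_score_definition"))
  n <- nrow(cohort)
  items <- definition$items
  pts <- matrix(NA_real_, nrow = n, ncol = length(items),
                dimnames = list(NULL, names(items)))
  for (j in seq_along(items)) {
    src <- items[[j]]$source
    if (is.null(cohort[[src]])) {
      stop_config("cohort lacks column '", src, "' needed by score '",
                  definition$name, "'")
    }
    pts[, j] <- item_points(items[[j]], cohort[[src]])
  }
  obs <- !is.na(pts)
  observed_items <- rowSums(obs)
  raw <- rowSums(pts, na.rm = TRUE)
  risk_max <- vapply(items, item_risk_max, numeric(1))
  max_avail <- as.numeric(obs %*% risk_max)
  tmax <- theoretical_max_for(definition)
  scorable <- observed_items > 0L
  complete <- observed_items == length(items)
  prorated <- rep(NA_real_, n)
  prorated[complete] <- raw[complete]
  part <- scorable & !complete
  if (any(part)) {
    ok <- part & max_avail > 0
    prorated[ok] <- raw[ok] / max_avail[ok] * tmax
    # partially observed profiles whose observed items are all protective
    # have no attainable risk points; treat as unscorable rather than divide
    # by zero
    scorable[part & max_avail <= 0] <- FALSE
  }
  raw[!scorable] <- NA_real_
  prorated[!scorable] <- NA_real_
  out <- data.frame(
    id = cohort$id %||% seq_len(n), score = definition$name,
    raw = raw, observed_items = observed_items, max_available = max_avail,
    prorated = prorated, complete = complete, scorable = scorable,
    stringsAsFactors = FALSE
  )
  attr(out, "n_unscorable") <- sum(!scorable)
  out
}

#' Z-standardize a score
#'
#' Centers and scales with the sample mean and the n-1 standard deviation,
#' the convention of mainstream statistical software. Standardization is
#' meant to be computed once on the full baseline analysis sample and its
#' `mean_used`/`sd_used` reused for subsamples.
#'
#' @param values Numeric vector (NAs allowed, ignored for the moments).
#' @param mean_used,sd_used Optionally reuse moments from a reference
#'   sample instead of recomputing.
#' @return List of class `drs_standardized`: `z`, `mean_used`, `sd_used`.
#' @export
zscore <- function(values, mean_used = NULL, sd_used = NULL) {
  x <- values[!is.na(values)]
  if (is.null(mean_used) || is.null(sd_used)) {
    if (length(x) < 2L) stop_config("need at least 2 values to standardize")
    mean_used <- mean(x)
    sd_used <- sd(x)
    if (!is.finite(sd_used) || sd_used <= 0) {
      stop(structure(class = c("drs_degenerate_error", "error", "condition"),
                     list(message = "constant input: standard deviation is zero",
                          call = sys.call())))
    }
  }
  structure(list(z = (values - mean_used) / sd_used,
                 mean_used = mean_used, sd_used = sd_used),
            class = "drs_standardized")
}

#' Assign tertile risk groups
#'
#' Cuts at the 1/3 and 2/3 empirical quantiles of the standardization
#' sample; values at or below the first cutpoint are "low", at or below the
#' second "medium", above it "high" (ties at a cutpoint go to the lower
#' group). With fewer than 3 distinct values a warning is issued and the
#' degenerate grouping returned.
#'
#' @param values Numeric vector (NAs allowed and propagated).
#' @param cutpoints Optionally reuse cutpoints from a reference sample.
#' @return Factor with levels low/medium/high and attribute `"cutpoints"`.
#' @export
assign_tertiles <- function(values, cutpoints = NULL) {
  x <- values[!is.na(values)]
  if (is.null(cutpoints)) {
    if (length(x) < 3L) stop_config("need at least 3 values for tertiles")
    cutpoints <- unname(quantile(x, c(1, 2) / 3, names = FALSE))
    if (length(unique(x)) < 3L) {
      warning("fewer than 3 distinct values: degenerate tertile grouping")
    }
  }
  g <- ifelse(is.na(values), NA_character_,
              ifelse(values <= cutpoints[1], "low",
                     ifelse(values <= cutpoints[2], "medium", "high")))
  f <- factor(g, levels = c("low", "medium", "high"))
  attr(f, "cutpoints") <- cutpoints
  f
}

#' Standardize and group every score of a cohort
#'
#' Convenience wrapper: runs [score_cohort()] for each definition, then
#' [zscore()] and [assign_tertiles()] on the prorated totals of scorable
#' participants (the full baseline analysis sample).
#'
#' @param cohort A `drs_cohort`.
#' @param definitions Named list of [score_definition()]s.
#' @return A long data frame (one row per participant x score) with
#'   columns of [score_cohort()] plus `z` and `tertile`.
#' @export
score_table <- function(cohort, definitions) {
  out <- lapply(definitions, function(def) {
    sc <- score_cohort(cohort, def)
    std <- zscore(sc$prorated)
    sc$z <- std$z
    tert <- assign_tertiles(sc$prorated)
    sc$tertile <- as.character(tert)
    attr(sc, "mean_used") <- std$mean_used
    attr(sc, "sd_used") <- std$sd_used
    attr(sc, "cutpoints") <- attr(tert, "cutpoints")
    sc
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "n_unscorable") <-
    vapply(out, function(s) attr(s, "n_unscorable"), numeric(1))
  res
}

#' Write per-participant score results as CSV
#'
#' @param scores Output of [score_table()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- as.data.frame(scores)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA, sprintf("%.17g", out[[nm]]))
    }
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
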