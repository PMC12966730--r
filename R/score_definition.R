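#' Declare one item of a risk score
#'
#' A score item maps one harmonized profile variable onto points. Four item
#' types cover the shipped indices:
#' \describe{
#'   \item{binary}{0/1 risk factor; `points_present` when present,
#'     `points_absent` (default 0) when absent. Protective factors are
#'     encoded with a negative `points_absent` on the corresponding
#'     risk-coded variable (absence of the risk behaviour earns the
#'     protective weight).}
#'   \item{categorical}{named `mapping` from level to points; the mapping
#'     must be total over the declared domain.}
#'   \item{banded}{a continuous variable cut at `bands` (ascending
#'     inclusive `upper` bounds, last typically `Inf`), each band carrying
#'     points — the usual encoding of age/education point tables.}
#'   \item{linear}{points = `slope` x value; `anchor` is the value at which
#'     the item's theoretical-maximum contribution is evaluated (the
#'     UKBDRS convention: age anchored at 100 years, education at 20).}
#' }
#'
#' @param name Item name (unique within a definition).
#' @param type One of "binary", "categorical", "banded", "linear".
#' @param source Cohort/profile column the item reads (default: `name`).
#' @param points_present,points_absent Binary-item points.
#' @param mapping Named numeric vector for categorical items.
#' @param bands List of `list(upper =, points =)` for banded items.
#' @param slope,anchor Linear-item weight per unit and anchor value.
#' @param demographic Logical; demographic items (age, sex, education) are
#'   the ones removed by [strip_demographics()] and added by
#'   [augment_with_demographics()].
#' @return A `drs_score_item`.
#' @export
score_item <- function(name, type,
                       source = name,
                       points_present = NULL, points_absent = 0,
                       mapping = NULL, bands = NULL,
                       slope = NULL, anchor = NULL,
                       demographic = FALSE) {
  type <- match.arg(type, c("binary", "categorical", "banded", "linear"))
  it <- list(name = name, type = type, source = source,
             demographic = isTRUE(demographic))
  if (type == "binary") {
    if (is.null(points_present)) stop_config("binary item '", name,
                                             "' needs points_present")
    it$points_present <- as.numeric(points_present)
    it$points_absent <- as.numeric(points_absent)
  } else if (type == "categorical") {
    if (is.null(mapping) || is.null(names(mapping))) {
      stop_config("categorical item '", name, "' needs a named mapping")
    }
    it$mapping <- unlist(mapping)
  } else if (type == "banded") {
    if (is.null(bands) || !length(bands)) {
      stop_config("banded item '", name, "' needs bands")
    }
    uppers <- vapply(bands, function(b) as.numeric(b$upper), numeric(1))
    pts <- vapply(bands, function(b) as.numeric(b$points), numeric(1))
    if (is.unsorted(uppers, strictly = TRUE)) {
      stop_config("bands of item '", name, "' must have strictly increasing uppers")
    }
    if (!is.infinite(uppers[length(uppers)])) {
      stop_config("last band of item '", name, "' must have upper = Inf ",
                  "so the mapping is total")
    }
    it$band_upper <- uppers
    it$band_points <- pts
  } else {
    if (is.null(slope)) stop_config("linear item '", name, "' needs a slope")
    if (is.null(anchor)) {
      stop_config("unbounded linear item '", name, "' needs an anchor ",
                  "for its theoretical maximum")
    }
    it$slope <- as.numeric(slope)
    it$anchor <- as.numeric(anchor)
  }
  structure(it, class = "drs_score_item")
}

# maximum points attainable on this item over its declared domain
# (linear items: evaluated at the configured anchor, by convention)
item_max_points <- function(item) {
  switch(item$type,
    binary = max(item$points_present, item$points_absent),
    categorical = max(item$mapping),
    banded = max(item$band_points),
    linear = item$slope * item$anchor
  )
}

item_min_points <- function(item) {
  switch(item$type,
    binary = min(item$points_present, item$points_absent),
    categorical = min(item$mapping),
    banded = min(item$band_points),
    linear = min(0, item$slope * item$anchor)
  )
}

# an item's contribution to "maximum possible risk points": protective-only
# items contribute 0 so the prorating denominator stays positive
item_risk_max <- function(item) max(0, item_max_points(item))

#' Declare a risk score
#'
#' @param name Score name.
#' @param items List of [score_item()]s with unique names.
#' @param theoretical_max Optional override of the theoretical maximum; by
#'   default it is computed by [theoretical_max_for()].
#' @param description Free-text provenance note (e.g. which published
#'   weight table the configuration transcribes).
#' @return A `drs_score_definition`.
#' @export
score_definition <- function(name, items, theoretical_max = NULL,
                             description = NULL) {
  if (!length(items)) stop_config("score '", name, "' has no items")
  items <- lapply(items, function(it) {
    if (!inherits(it, "drs_score_item")) do.call(score_item, it) else it
  })
  nms <- vapply(items, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop_config("duplicate item names in score '", name, "'")
  }
  names(items) <- nms
  structure(
    list(name = name, items = items,
         theoretical_max_override = theoretical_max,
         description = description),
    class = "drs_score_definition"
  )
}

#' Theoretical maximum of a risk score
#'
#' The default is the sum over items of each item's maximum attainable
#' points, where protective-only discrete items (maximum at or below zero)
#' contribute nothing and linear items are evaluated at their configured
#' anchor (e.g. age 100 years, education 20 years for UKBDRS-style linear
#' weights). A definition-level `theoretical_max` override wins if present.
#'
#' @param definition A [score_definition()].
#' @return The theoretical maximum in points.
#' @export
theoretical_max_for <- function(definition) {
  stopifnot(inherits(definition, "drs_score_definition"))
  if (!is.null(definition$theoretical_max_override)) {
    return(as.numeric(definition$theoretical_max_override))
  }
  sum(vapply(definition$items, function(it) {
    if (it$type == "linear") it$slope * it$anchor else item_risk_max(it)
  }, numeric(1)))
}

demographic_items <- function(definition) {
  Filter(function(it) isTRUE(it$demographic), definition$items)
}

#' Add demographic items to a score
#'
#' Appends demographic items (typically another index's age and sex point
#' tables) to a score that lacks native demographic weights, so that
#' purely modifiable-factor indices can be compared head-to-head with
#' indices that include demographics. The theoretical maximum is
#' recomputed (or, when overridden, incremented by the demographic items'
#' own maximum).
#'
#' @param definition A [score_definition()].
#' @param demo_items List of [score_item()]s flagged `demographic`.
#' @return A new `drs_score_definition` named `<name>+demo` when any item
#'   is added.
#' @export
augment_with_demographics <- function(definition, demo_items) {
  stopifnot(inherits(definition, "drs_score_definition"))
  if (!length(demo_items)) return(definition)
  demo_items <- lapply(demo_items, function(it) {
    if (!inherits(it, "drs_score_item")) do.call(score_item, it) else it
  })
  if (!all(vapply(demo_items, function(it) isTRUE(it$demographic), logical(1)))) {
    stop_config("all augmentation items must be flagged demographic")
  }
  new_names <- vapply(demo_items, `[[`, character(1), "name")
  clash <- intersect(new_names, names(definition$items))
  if (length(clash)) {
    stop_config("augmentation collides with existing items: ",
                paste(clash, collapse = ", "))
  }
  out <- definition
  out$items <- c(definition$items, stats::setNames(demo_items, new_names))
  if (!is.null(out$theoretical_max_override)) {
    out$theoretical_max_override <- out$theoretical_max_override +
      sum(vapply(demo_items, function(it) {
        if (it$type == "linear") it$slope * it$anchor else item_risk_max(it)
      }, numeric(1)))
  }
  out
}

#' Remove demographic items from a score
#'
#' Drops every item flagged `demographic` (age, sex, education), leaving
#' the modifiable/clinical content; the theoretical maximum is recomputed.
#' Inverse of [augment_with_demographics()] on the item set.
#'
#' @param definition A [score_definition()].
#' @return A `drs_score_definition` without demographic items.
#' @export
strip_demographics <- function(definition) {
  stopifnot(inherits(definition, "drs_score_definition"))
  demo <- demographic_items(definition)
  if (!length(demo)) return(definition)
  out <- definition
  out$items <- Filter(function(it) !isTRUE(it$demographic), definition$items)
  if (!length(out$items)) {
    stop_config("stripping demographics leaves score '", definition$name,
                "' with no items")
  }
  if (!is.null(out$theoretical_max_override)) {
    out$theoretical_max_override <- out$theoretical_max_override -
      sum(vapply(demo, function(it) {
        if (it$type == "linear") it$slope * it$anchor else item_risk_max(it)
      }, numeric(1)))
  }
  out
}

#' Read score definitions from YAML
#'
#' Each YAML file declares one score: `name`, optional `description` and
#' `theoretical_max`, optional `augment_demographics_from` (the name of
#' another shipped score whose demographic items are appended by
#' [load_score_definitions()]), and `items` following the [score_item()]
#' schema. The weight tables shipped under
#' `system.file("extdata", "scores", package = "drscompare")` are editable
#' transcriptions of the published indices; replacing a file changes the
#' scores with no code change.
#'
#' @param path YAML file path.
#' @return A `drs_score_definition`; any `augment_demographics_from`
#'   request is kept in attribute `"augment_from"` for the loader.
#' @export
read_score_definition <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$name) || is.null(raw$items)) {
    stop_config("score YAML must have 'name' and 'items': ", path)
  }
  items <- lapply(raw$items, function(spec) {
    spec$demographic <- isTRUE(spec$demographic)
    if (!is.null(spec$mapping)) spec$mapping <- unlist(spec$mapping)
    do.call(score_item, spec)
  })
  def <- score_definition(raw$name, items,
                          theoretical_max = raw$theoretical_max,
                          description = raw$description)
  attr(def, "augment_from") <- raw$augment_demographics_from
  attr(def, "augment_items") <- raw$augment_items
  def
}

#' @rdname read_score_definition
#' @param dir Directory of `*.yaml` score files (default: the shipped
#'   tables).
#' @param augment Apply `augment_demographics_from` requests (default TRUE).
#' @return `load_score_definitions()`: a named list of definitions.
#' @export
load_score_definitions <- function(dir = system.file("extdata", "scores",
                                                     package = "drscompare"),
                                   augment = TRUE) {
  files <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  if (!length(files)) stop_config("no score YAML files in ", dir)
  defs <- lapply(files, read_score_definition)
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  if (augment) {
    defs <- lapply(defs, function(def) {
      src <- attr(def, "augment_from")
      if (is.null(src)) return(def)
      if (!src %in% names(defs)) {
        stop_config("score '", def$name, "' requests demographics from ",
                    "unknown score '", src, "'")
      }
      demo <- demographic_items(defs[[src]])
      wanted <- attr(def, "augment_items")
      if (!is.null(wanted)) {
        missing_items <- setdiff(wanted, names(demo))
        if (length(missing_items)) {
          stop_config("score '", src, "' has no demographic item(s): ",
                      paste(missing_items, collapse = ", "))
        }
        demo <- demo[wanted]
      }
      augment_with_demographics(def, demo)
    })
  }
  defs
}
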