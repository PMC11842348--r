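#' Scoring schema for the QOL-E instrument
#'
#' A scoring schema describes the 29 items of the QOL-E: which of the six
#' domains each item belongs to (the first two items assess general
#' well-being and are never scored), the raw response range of each item,
#' whether the item is worded so that a higher raw response means a *worse*
#' outcome (`reversed`), how the three summary scores are composed from the
#' domains, and the minimum fraction of a domain's items that must be
#' answered before the domain is scored.
#'
#' Domain codes: `FIS` physical well-being, `FUN` functional well-being,
#' `SOC` social/family well-being, `SEX` sexual well-being, `FAT` fatigue,
#' `MDSS` MDS-specific disturbances; `GENERAL` marks the two unscored
#' general-health items. Summary codes: `GEN` (mean of all domains except
#' MDSS), `ALL` (mean of GEN and MDSS), `TOI` (treatment outcome index, mean
#' of FIS, FUN and MDSS).
#'
#' @param items A data frame with columns `item_id` (character), `domain`
#'   (one of FIS, FUN, SOC, SEX, FAT, MDSS, GENERAL), `raw_min`, `raw_max`
#'   (integers, `raw_max > raw_min`) and `reversed` (logical).
#' @param summary_composition Named list mapping each summary score to the
#'   character vector of its constituents.
#' @param min_answered_fraction Proportion in (0, 1] of a domain's items
#'   that must be answered for the domain to be scored. Default 0.5.
#'
#' @return An object of class `qole_schema`.
#' @seealso [default_schema()], [minimum_possible_change()]
#' @export
qole_schema <- function(items,
                        summary_composition = list(
                          GEN = c("FIS", "FUN", "SOC", "SEX", "FAT"),
                          ALL = c("GEN", "MDSS"),
                          TOI = c("FIS", "FUN", "MDSS")
                        ),
                        min_answered_fraction = 0.5) {
  items <- tibble::as_tibble(items)
  required <- c("item_id", "domain", "raw_min", "raw_max", "reversed")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    stop("schema items lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  schema <- structure(
    list(
      items = items[required],
      summary_composition = summary_composition,
      min_answered_fraction = min_answered_fraction
    ),
    class = "qole_schema"
  )
  validate_schema(schema)
  schema
}

#' @export
print.qole_schema <- function(x, ...) {
  cat("<qole_schema>", nrow(x$items), "items\n")
  tab <- table(x$items$domain)
  for (d in names(tab)) {
    rng <- domain_raw_range(x, d)
    cat(sprintf("  %-7s %d item(s)%s\n", d, tab[[d]],
                if (d == "GENERAL") " (unscored)" else sprintf(", raw range %d", rng)))
  }
  cat("  summaries:", paste(names(x$summary_composition), collapse = ", "), "\n")
  invisible(x)
}

#' Validate a scoring schema
#'
#' Checks the structural invariants of a [qole_schema()]: 29 items in total,
#' 27 items assigned to the six scored domains, exactly 2 general-well-being
#' items, every item with `raw_max > raw_min`, valid domain codes, and a
#' summary composition whose entries are known domains or summaries.
#'
#' @param schema A `qole_schema`.
#' @return `schema`, invisibly; errors describe the first violated invariant.
#' @export
validate_schema <- function(schema) {
  items <- schema$items
  domains <- c("FIS", "FUN", "SOC", "SEX", "FAT", "MDSS", "GENERAL")
  bad <- setdiff(unique(items$domain), domains)
  if (length(bad) > 0) {
    stop("unknown domain code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(items$item_id)) {
    stop("duplicate item_id in schema", call. = FALSE)
  }
  if (nrow(items) != 29) {
    stop("schema must contain exactly 29 items, found ", nrow(items), call. = FALSE)
  }
  n_general <- sum(items$domain == "GENERAL")
  if (n_general != 2) {
    stop("schema must contain exactly 2 GENERAL items, found ", n_general,
         call. = FALSE)
  }
  if (any(items$raw_max <= items$raw_min)) {
    stop("every item must have raw_max > raw_min", call. = FALSE)
  }
  maf <- schema$min_answered_fraction
  if (!is.numeric(maf) || length(maf) != 1 || maf <= 0 || maf > 1) {
    stop("min_answered_fraction must be a single number in (0, 1]", call. = FALSE)
  }
  known <- c(domains, names(schema$summary_composition))
  for (s in names(schema$summary_composition)) {
    bad <- setdiff(schema$summary_composition[[s]], known)
    if (length(bad) > 0) {
      stop("summary ", s, " refers to unknown score(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(schema)
}

#' Default QOL-E scoring schema
#'
#' The published instrument's item-level scoring sheet is distributed with
#' the questionnaire rather than in the validation literature, so this
#' default is a reconstruction constrained to the instrument's documented
#' structure: 29 items, of which Items 1 and 2 assess general well-being and
#' 27 form the six domains, with per-domain total raw ranges of 8 (FIS), 9
#' (FUN), 4 (SOC), 12 (SEX), 21 (FAT) and 42 (MDSS), so that the minimum
#' possible change of each standardized score (100 / range) matches the
#' published values. Items worded as symptoms or impacts carry
#' `reversed = TRUE`. Swap in the official sheet via [qole_schema()] or
#' [read_schema()] when available.
#'
#' @return A `qole_schema`.
#' @export
default_schema <- function() {
  items <- tibble::tribble(
    ~item_id, ~domain, ~raw_min, ~raw_max, ~reversed,
    # general well-being; q1: excellent(0)..poor(3); q2: health vs one month
    # ago, much worse(0)..much better(6). Never enter domain scores.
    "q1",   "GENERAL", 0L, 3L, TRUE,
    "q2",   "GENERAL", 0L, 6L, FALSE,
    # physical well-being
    "q3",   "FIS",     0L, 4L, FALSE,
    "q4",   "FIS",     0L, 4L, TRUE,
    # functional well-being
    "q5",   "FUN",     0L, 3L, TRUE,
    "q6a",  "FUN",     0L, 3L, TRUE,
    "q6b",  "FUN",     0L, 3L, TRUE,
    # social/family well-being
    "q7",   "SOC",     0L, 2L, TRUE,
    "q8",   "SOC",     0L, 2L, TRUE,
    # sexual well-being
    "q9a",  "SEX",     0L, 4L, FALSE,
    "q9b",  "SEX",     0L, 4L, TRUE,
    "q9c",  "SEX",     0L, 4L, TRUE,
    # fatigue
    "q10",  "FAT",     0L, 3L, TRUE,
    "q11a", "FAT",     0L, 3L, TRUE,
    "q11b", "FAT",     0L, 3L, TRUE,
    "q11c", "FAT",     0L, 3L, TRUE,
    "q11d", "FAT",     0L, 3L, TRUE,
    "q12",  "FAT",     0L, 3L, TRUE,
    "q13",  "FAT",     0L, 3L, TRUE,
    # MDS-specific disturbances
    "q14a", "MDSS",    0L, 4L, TRUE,
    "q14b", "MDSS",    0L, 4L, TRUE,
    "q14c", "MDSS",    0L, 4L, TRUE,
    "q14d", "MDSS",    0L, 4L, TRUE,
    "q14e", "MDSS",    0L, 4L, TRUE,
    "q14f", "MDSS",    0L, 4L, TRUE,
    "q14g", "MDSS",    0L, 4L, TRUE,
    "q14h", "MDSS",    0L, 4L, TRUE,
    "q14i", "MDSS",    0L, 5L, TRUE,
    "q14j", "MDSS",    0L, 5L, TRUE
  )
  qole_schema(items)
}

#' Scored domain and summary codes
#' @return Character vectors of the six domain codes and the nine score codes.
#' @keywords internal
qole_domains <- function() c("FIS", "FUN", "SOC", "SEX", "FAT", "MDSS")

#' @rdname qole_domains
#' @keywords internal
qole_scores <- function() c(qole_domains(), "GEN", "ALL", "TOI")

# Total raw range of a scored domain (sum of item ranges).
domain_raw_range <- function(schema, domain) {
  it <- schema$items[schema$items$domain == domain, ]
  sum(it$raw_max - it$raw_min)
}

#' Minimum possible change of a standardized domain score
#'
#' The smallest nonzero step an individual patient can make on a 0-100
#' standardized domain score: one raw point on one item, i.e.
#' 100 / (total raw range of the domain). Reported rounded to one decimal,
#' matching the precision at which thresholds are triangulated.
#'
#' @param schema A [qole_schema()].
#' @param domain One of FIS, FUN, SOC, SEX, FAT, MDSS, or a vector of them;
#'   `NULL` (default) returns all six.
#' @param digits Decimal places for rounding; `NA` for full precision.
#' @return Named numeric vector of minimum possible changes, in score points.
#' @export
minimum_possible_change <- function(schema, domain = NULL, digits = 1) {
  if (is.null(domain)) domain <- qole_domains()
  if (any(domain == "GENERAL")) {
    stop("GENERAL items are not scored; no minimum possible change is defined",
         call. = FALSE)
  }
  bad <- setdiff(domain, qole_domains())
  if (length(bad) > 0) {
    stop("unknown domain(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  mpc <- vapply(domain, function(d) 100 / domain_raw_range(schema, d), numeric(1))
  if (!is.na(digits)) mpc <- round(mpc, digits)
  mpc
}

#' Read or write a scoring schema
#'
#' Schemas round-trip through YAML (`.yaml`/`.yml`) or JSON (`.json`)
#' documents whose top-level keys mirror the `qole_schema` fields: `items`
#' (list of records), `summary_composition`, `min_answered_fraction`.
#'
#' @param path File path; the extension selects the format.
#' @param schema A `qole_schema` (for writing).
#' @return `read_schema()` returns a validated `qole_schema`;
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  items <- doc$items
  if (!is.data.frame(items)) {
    items <- dplyr::bind_rows(lapply(items, tibble::as_tibble))
  }
  items$raw_min <- as.integer(items$raw_min)
  items$raw_max <- as.integer(items$raw_max)
  items$reversed <- as.logical(items$reversed)
  comp <- lapply(doc$summary_composition, unlist)
  qole_schema(items, summary_composition = comp,
              min_answered_fraction = doc$min_answered_fraction)
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  doc <- list(
    items = lapply(seq_len(nrow(schema$items)), function(i) as.list(schema$items[i, ])),
    summary_composition = schema$summary_composition,
    min_answered_fraction = schema$min_answered_fraction
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}
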