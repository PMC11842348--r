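#' Score QOL-E domains for one patient-visit
#'
#' Computes the six 0-100 domain scores from a single record of item
#' responses. Each response is first oriented so that a higher value means a
#' better outcome (reversing items flagged `reversed` in the schema), then
#' the domain score is the answered fraction of the domain's raw range,
#' linearly standardized:
#' `100 * sum(oriented responses) / sum(answered item ranges)`.
#' A domain is scored only when at least `min_answered_fraction` of its
#' items are answered; otherwise it is `NA`. Scoring over the answered
#' items' own ranges prorates missing items from the mean response level of
#' the answered ones.
#'
#' @param record Named list or vector of item responses (`item_id` ->
#'   integer, `NA` for missing), or a one-row data frame containing the item
#'   columns. Names not present in the schema raise an error; responses
#'   outside the item's raw range raise an error naming item and value.
#'   Non-item columns of a data frame (`patient_id`, `trial`, `visit`,
#'   `qlq_*`, clinical outcomes) are ignored.
#' @param schema A [qole_schema()].
#' @return Named numeric vector of the six domain scores (FIS, FUN, SOC,
#'   SEX, FAT, MDSS), each in \[0, 100\] or `NA`.
#' @export
#' @examples
#' sch <- default_schema()
#' best <- stats::setNames(sch$items$raw_max, sch$items$item_id)
#' best[sch$items$reversed] <- sch$items$raw_min[sch$items$reversed]
#' score_domains(best, sch) # all 100
score_domains <- function(record, schema) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    keep <- intersect(names(record), schema$items$item_id)
    record <- as.list(record[keep])
  } else {
    record <- as.list(record)
    unknown <- setdiff(names(record), schema$items$item_id)
    if (length(unknown) > 0) {
      stop("unknown item_id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  mat <- matrix(NA_real_, nrow = 1, ncol = nrow(schema$items),
                dimnames = list(NULL, schema$items$item_id))
  for (id in names(record)) mat[1, id] <- as.numeric(record[[id]])
  drop(score_item_matrix(mat, schema))
}

# Vectorized domain scorer: `mat` is n x items (columns named by item_id;
# absent schema items count as all-missing). Returns n x 6 matrix.
score_item_matrix <- function(mat, schema) {
  items <- schema$items
  present <- intersect(items$item_id, colnames(mat))
  full <- matrix(NA_real_, nrow = nrow(mat), ncol = nrow(items),
                 dimnames = list(NULL, items$item_id))
  full[, present] <- as.matrix(mat[, present, drop = FALSE])

  # range validation, naming the offending item and value
  for (j in seq_len(nrow(items))) {
    x <- full[, j]
    bad <- which(!is.na(x) & (x < items$raw_min[j] | x > items$raw_max[j]))
    if (length(bad) > 0) {
      stop(sprintf("response %s out of range [%d, %d] for item %s",
                   format(x[bad[1]]), items$raw_min[j], items$raw_max[j],
                   items$item_id[j]), call. = FALSE)
    }
  }

  # orient: higher = better, shifted to start at 0
  oriented <- full
  rev_idx <- which(items$reversed)
  for (j in seq_len(nrow(items))) {
    oriented[, j] <- if (items$reversed[j]) {
      items$raw_max[j] - full[, j]
    } else {
      full[, j] - items$raw_min[j]
    }
  }

  out <- matrix(NA_real_, nrow = nrow(mat), ncol = 6,
                dimnames = list(NULL, qole_domains()))
  for (d in qole_domains()) {
    idx <- which(items$domain == d)
    sub <- oriented[, idx, drop = FALSE]
    ranges <- items$raw_max[idx] - items$raw_min[idx]
    answered <- !is.na(sub)
    n_ans <- rowSums(answered)
    denom <- answered %*% ranges
    score <- 100 * rowSums(sub, na.rm = TRUE) / as.vector(denom)
    score[n_ans / length(idx) < schema$min_answered_fraction] <- NA_real_
    score[n_ans == 0] <- NA_real_
    out[, d] <- score
  }
  out
}

#' Compute QOL-E summary scores from domain scores
#'
#' `GEN` is the mean of FIS, FUN, SOC, SEX and FAT; `ALL` the mean of GEN
#' and MDSS; `TOI` the mean of FIS, FUN and MDSS. Because the sexual
#' well-being domain is frequently skipped and its psychometric performance
#' is known to be weak, a missing SEX is dropped from GEN (which is then the
#' mean of the remaining four domains); any other missing constituent makes
#' the summary missing.
#'
#' @param domains Named numeric vector (or one-row data frame) with elements
#'   FIS, FUN, SOC, SEX, FAT, MDSS in \[0, 100\] or `NA`.
#' @param schema A [qole_schema()]; its `summary_composition` drives the
#'   calculation, so alternative compositions are honoured.
#' @return Named numeric vector of summary scores (by default GEN, ALL, TOI).
#' @export
score_summaries <- function(domains, schema = default_schema()) {
  if (is.data.frame(domains)) domains <- unlist(domains[1, , drop = TRUE])
  vals <- as.list(domains)
  out <- numeric(0)
  for (s in names(schema$summary_composition)) {
    parts <- schema$summary_composition[[s]]
    x <- vapply(parts, function(p) {
      v <- c(vals, as.list(out))[[p]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    # SEX may be dropped when missing; all other constituents are required
    droppable <- parts == "SEX"
    if (any(is.na(x) & !droppable) || all(is.na(x))) {
      out[s] <- NA_real_
    } else {
      out[s] <- mean(x[!is.na(x)])
    }
  }
  out
}

#' Score a whole cohort into a panel of standardized scores
#'
#' Applies [score_domains()] and [score_summaries()] to every patient-visit
#' row of a wide cohort table.
#'
#' @param cohort Wide cohort tibble: one row per patient-visit with columns
#'   `patient_id`, `trial`, `visit` and the item response columns (see
#'   [generate_cohort()] / [read_cohort()]).
#' @param schema A [qole_schema()].
#' @return A score panel: tibble with `patient_id`, `trial`, `visit` and the
#'   nine score columns FIS, FUN, SOC, SEX, FAT, MDSS, GEN, ALL, TOI.
#' @export
score_cohort <- function(cohort, schema = default_schema()) {
  stopifnot(all(c("patient_id", "trial", "visit") %in% names(cohort)))
  item_cols <- intersect(schema$items$item_id, names(cohort))
  mat <- as.matrix(cohort[item_cols])
  dom <- score_item_matrix(mat, schema)
  summ <- t(apply(dom, 1, score_summaries, schema = schema))
  tibble::as_tibble(cbind(
    cohort[c("patient_id", "trial", "visit")],
    tibble::as_tibble(dom),
    tibble::as_tibble(summ)
  ))
}

#' Restrict a score panel to the analysis population
#'
#' Keeps every patient with at least one non-missing baseline domain score
#' (all of that patient's rows are retained). Excluded patients are recorded
#' in an `exclusions` attribute. Analyses that involve the EORTC QLQ-C30
#' must additionally drop the trial in which it was not administered; see
#' `drop_no_qlq_trial()`.
#'
#' @param panel A score panel from [score_cohort()].
#' @return The filtered panel, with attribute `exclusions` (a tibble of
#'   `patient_id`, `reason`).
#' @export
filter_analysis_population <- function(panel) {
  if (nrow(panel) == 0) {
    warning("empty score panel; nothing to filter")
    out <- panel
    attr(out, "exclusions") <- tibble::tibble(patient_id = character(),
                                              reason = character())
    return(out)
  }
  base <- panel[panel$visit == "baseline", , drop = FALSE]
  dom <- as.matrix(base[qole_domains()])
  ok <- rowSums(!is.na(dom)) >= 1
  keep_ids <- unique(base$patient_id[ok])
  all_ids <- unique(panel$patient_id)
  dropped <- setdiff(all_ids, keep_ids)
  out <- panel[panel$patient_id %in% keep_ids, , drop = FALSE]
  attr(out, "exclusions") <- tibble::tibble(
    patient_id = dropped,
    reason = rep("no non-missing baseline domain score", length(dropped))
  )
  out
}

#' @rdname filter_analysis_population
#' @param x A panel or cohort tibble with a `trial` column.
#' @param trial Trial code whose patients never received the QLQ-C30.
#' @export
drop_no_qlq_trial <- function(x, trial = "T4_rev_like") {
  x[x$trial != trial, , drop = FALSE]
}

#' Read and write cohort tables
#'
#' The wide CSV has one row per patient-visit with the item, QLQ-C30 and
#' clinical-outcome columns; the long CSV has one row per patient-visit
#' measurement with columns `patient_id`, `trial`, `visit`, `variable`,
#' `value`. Missing values are empty cells. `read_cohort()` validates every
#' item response against the schema's raw ranges.
#'
#' @param path CSV file path.
#' @param schema A [qole_schema()] used for validation.
#' @param format `"auto"` (default; detected from the columns), `"wide"` or
#'   `"long"`.
#' @return `read_cohort()` returns a wide cohort tibble.
#' @export
read_cohort <- function(path, schema = default_schema(), format = "auto") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "auto") {
    format <- if (all(c("variable", "value") %in% names(df))) "long" else "wide"
  }
  if (format == "long") {
    df <- tidyr::pivot_wider(tibble::as_tibble(df),
                             names_from = "variable", values_from = "value")
  }
  cohort <- tibble::as_tibble(df)
  items <- schema$items
  for (j in seq_len(nrow(items))) {
    id <- items$item_id[j]
    if (!id %in% names(cohort)) next
    x <- cohort[[id]]
    bad <- which(!is.na(x) & (x < items$raw_min[j] | x > items$raw_max[j] |
                                x != round(x)))
    if (length(bad) > 0) {
      stop(sprintf("invalid response %s for item %s (allowed %d..%d)",
                   format(x[bad[1]]), id, items$raw_min[j], items$raw_max[j]),
           call. = FALSE)
    }
  }
  cohort
}

#' @rdname read_cohort
#' @param cohort A wide cohort tibble.
#' @export
write_cohort <- function(cohort, path, format = "wide") {
  if (format == "long") {
    long <- tidyr::pivot_longer(cohort,
                                cols = -dplyr::all_of(c("patient_id", "trial", "visit")),
                                names_to = "variable", values_to = "value",
                                values_drop_na = FALSE)
    utils::write.csv(long, path, row.names = FALSE, na = "")
  } else {
    utils::write.csv(cohort, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname read_cohort
#' @param panel A score panel from [score_cohort()].
#' @export
write_score_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}
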