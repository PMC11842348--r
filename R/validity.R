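#' Spearman rank correlation with magnitude classification
#'
#' Spearman's rho with average ranks for ties and a two-sided P value from
#' the t approximation on n - 2 degrees of freedom. The absolute coefficient
#' is classified into the conventional magnitude bands: weak (|r| < 0.3),
#' moderate (0.3 <= |r| < 0.7), strong (0.7 <= |r| < 0.9), very strong
#' (|r| >= 0.9).
#'
#' @param x,y Paired numeric vectors; pairs with a missing value are dropped.
#' @return One-row tibble with `n` (complete pairs), `r`, `p`, `magnitude`.
#'   Fewer than 3 complete pairs gives `r = NA` with a warning.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) {
    warning("fewer than 3 complete pairs; correlation not computed")
    return(tibble::tibble(n = n, r = NA_real_, p = NA_real_,
                          magnitude = NA_character_))
  }
  r <- stats::cor(x[ok], y[ok], method = "spearman")
  if (is.na(r) || abs(r) >= 1) {
    p <- if (is.na(r)) NA_real_ else 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(n = n, r = r, p = p, magnitude = magnitude_class(r))
}

#' @rdname spearman
#' @param r Correlation coefficient(s).
#' @export
magnitude_class <- function(r) {
  cut(abs(r), breaks = c(-Inf, 0.3, 0.7, 0.9, Inf), right = FALSE,
      labels = c("weak", "moderate", "strong", "very_strong")) |>
    as.character()
}

#' Pooled convergent/divergent validity correlations
#'
#' Spearman correlations between each QOL-E score and each external measure
#' (QLQ-C30 scales and clinical outcomes), stacking baseline and Week 24
#' observations so each patient contributes up to two rows. Patients from
#' the trial that did not administer the QLQ-C30 are excluded from rows
#' involving `qlq_*` measures.
#'
#' @param panel Score panel from [score_cohort()].
#' @param cohort Wide cohort tibble carrying the external measures.
#' @param measures Character vector of external-measure column names;
#'   default: every `qlq_*` column plus the four clinical outcomes present.
#' @param scores QOL-E score columns (default all nine).
#' @return Tibble with `measure`, `score`, `n`, `r`, `p`, `magnitude`.
#' @export
convergent_validity <- function(panel, cohort, measures = NULL,
                                scores = qole_scores()) {
  clin <- intersect(c("hb_g_dl", "rbc_units_8wk", "platelet_count_e9_l",
                      "platelet_units_8wk"), names(cohort))
  if (is.null(measures)) {
    scales <- setdiff(grep("^qlq_", names(cohort), value = TRUE),
                      c("qlq_item29", "qlq_item30")) # anchor items, not scales
    measures <- c(scales, clin)
  }
  joined <- dplyr::inner_join(
    panel[panel$visit %in% c("baseline", "week24"), ],
    cohort[c("patient_id", "visit", setdiff(measures, names(panel)))],
    by = c("patient_id", "visit")
  )
  rows <- list()
  for (m in measures) {
    dat <- if (grepl("^qlq_", m)) drop_no_qlq_trial(joined) else joined
    for (s in scores) {
      res <- suppressWarnings(spearman(dat[[s]], dat[[m]]))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(measure = m, score = s), res
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Evaluate correlations against a prespecified hypothesis grid
#'
#' Compares each observed correlation with the expectation stated in the
#' grid. The verdict is `as_hypothesized` when the observed magnitude band
#' equals the expected band and the sign matches; `stronger` / `weaker` when
#' the band is above / below the expectation; `wrong_sign` when the sign
#' disagrees and the correlation is significant (P <= 0.05); a
#' non-significant wrong-sign correlation is `indeterminate`.
#'
#' @param results Correlation tibble from [convergent_validity()] (columns
#'   `measure`, `score`, `r`, `p`, `magnitude`).
#' @param grid Hypothesis grid: tibble with `measure`, `score`,
#'   `expected_magnitude` (weak/moderate/strong/very_strong) and
#'   `expected_sign` (+1 or -1). Every tested pair must appear exactly once;
#'   see [default_hypothesis_grid()].
#' @return `results` with columns `expected_magnitude`, `expected_sign`,
#'   `verdict` appended.
#' @export
evaluate_hypothesis_grid <- function(results, grid) {
  key_r <- paste(results$measure, results$score)
  key_g <- paste(grid$measure, grid$score)
  if (anyDuplicated(key_g)) {
    stop("hypothesis grid has duplicate pairs", call. = FALSE)
  }
  missing <- setdiff(key_r, key_g)
  if (length(missing) > 0) {
    stop("pair(s) missing from hypothesis grid: ",
         paste(utils::head(missing, 5), collapse = "; "), call. = FALSE)
  }
  idx <- match(key_r, key_g)
  bands <- c(weak = 1, moderate = 2, strong = 3, very_strong = 4)
  expected_m <- grid$expected_magnitude[idx]
  expected_s <- grid$expected_sign[idx]
  verdict <- character(nrow(results))
  for (i in seq_len(nrow(results))) {
    r <- results$r[i]
    p <- results$p[i]
    if (is.na(r)) {
      verdict[i] <- NA_character_
    } else if (sign(r) != expected_s[i] && r != 0) {
      verdict[i] <- if (!is.na(p) && p > 0.05) "indeterminate" else "wrong_sign"
    } else {
      obs <- bands[[results$magnitude[i]]]
      exp_b <- bands[[expected_m[i]]]
      verdict[i] <- if (obs == exp_b) "as_hypothesized"
        else if (obs > exp_b) "stronger" else "weaker"
    }
  }
  dplyr::bind_cols(results, tibble::tibble(
    expected_magnitude = expected_m,
    expected_sign = expected_s,
    verdict = verdict
  ))
}

#' Default convergent/divergent hypothesis grid
#'
#' The prespecified grid of expected correlation magnitudes and signs
#' between QOL-E scores and external measures, reconstructed from the
#' rationale of the validation design: moderate positive associations with
#' the QLQ-C30 global and functioning scales, moderate negative with the
#' symptom scales most related to each domain (fatigue in particular), weak
#' for the sexual well-being domain throughout, and weak associations with
#' all clinical outcomes. Editable and replaceable via a YAML file with the
#' same columns.
#'
#' @param cohort Optional cohort tibble; when given, the grid is restricted
#'   to measures present in it.
#' @return Tibble with `measure`, `score`, `expected_magnitude`,
#'   `expected_sign`.
#' @export
default_hypothesis_grid <- function(cohort = NULL) {
  qlq_better <- c("qlq_global", "qlq_physical", "qlq_role", "qlq_emotional",
                  "qlq_cognitive", "qlq_social")
  qlq_worse <- c("qlq_fatigue", "qlq_nausea", "qlq_pain", "qlq_dyspnea",
                 "qlq_insomnia", "qlq_appetite", "qlq_constipation",
                 "qlq_diarrhea", "qlq_financial")
  clin_pos <- c("hb_g_dl", "platelet_count_e9_l")
  clin_neg <- c("rbc_units_8wk", "platelet_units_8wk")
  scores <- qole_scores()
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(measure = qlq_better, score = scores) |>
      dplyr::mutate(expected_magnitude = "moderate", expected_sign = 1),
    tidyr::expand_grid(measure = qlq_worse, score = scores) |>
      dplyr::mutate(
        expected_magnitude = dplyr::if_else(
          .data$measure %in% c("qlq_fatigue", "qlq_pain", "qlq_dyspnea"),
          "moderate", "weak"),
        expected_sign = -1
      ),
    tidyr::expand_grid(measure = c(clin_pos, clin_neg), score = scores) |>
      dplyr::mutate(expected_magnitude = "weak",
                    expected_sign = dplyr::if_else(
                      .data$measure %in% clin_pos, 1, -1))
  )
  # the sexual well-being domain is expected to track external measures weakly
  grid$expected_magnitude[grid$score == "SEX"] <- "weak"
  if (!is.null(cohort)) {
    grid <- grid[grid$measure %in% names(cohort), , drop = FALSE]
  }
  grid
}

#' Known-groups validity
#'
#' Compares score distributions (n, median, Q1, Q3) across groups defined by
#' (i) the baseline response to the overall-health item (Item 1: excellent,
#' good, acceptable, poor) or (ii) baseline RBC transfusion dependency
#' (dependent = at least one RBC unit transfused in the previous 8 weeks).
#' Scores are pooled across baseline and Week 24; the grouping is fixed at
#' its baseline value. Pairwise overlap flags report whether the closed
#' interquartile intervals \[Q1, Q3\] of adjacent groups intersect (a shared
#' endpoint counts as overlap).
#'
#' @param panel Score panel from [score_cohort()].
#' @param cohort Wide cohort tibble (provides `q1` and `rbc_units_8wk`).
#' @param grouping `"item1_response"` or `"transfusion_dependency"`.
#' @param scores Score columns to summarize (default all nine).
#' @return List with `summary` (tibble: `score`, `group`, `n`, `median`,
#'   `q1`, `q3`) and `overlap` (tibble of adjacent-group IQR overlap flags).
#' @export
known_groups <- function(panel, cohort,
                         grouping = c("item1_response", "transfusion_dependency"),
                         scores = qole_scores()) {
  grouping <- match.arg(grouping)
  base <- cohort[cohort$visit == "baseline", , drop = FALSE]
  if (grouping == "item1_response") {
    levels_ <- c("excellent", "good", "acceptable", "poor")
    grp <- factor(levels_[base$q1 + 1], levels = levels_)
  } else {
    grp <- factor(ifelse(is.na(base$rbc_units_8wk), NA,
                         ifelse(base$rbc_units_8wk >= 1, "dependent",
                                "independent")),
                  levels = c("independent", "dependent"))
  }
  grp_tbl <- tibble::tibble(patient_id = base$patient_id, group = grp)
  grp_tbl <- grp_tbl[!is.na(grp_tbl$group), ]
  if (length(unique(grp_tbl$group)) < 2) {
    stop("known-groups analysis needs at least 2 non-empty groups", call. = FALSE)
  }
  pooled <- dplyr::inner_join(
    panel[panel$visit %in% c("baseline", "week24"), ], grp_tbl,
    by = "patient_id"
  )
  rows <- list()
  for (s in scores) {
    for (g in levels(grp)) {
      x <- pooled[[s]][pooled$group == g]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1]] <- tibble::tibble(
        score = s, group = g, n = length(x),
        median = if (length(x)) stats::median(x) else NA_real_,
        q1 = if (length(x)) unname(stats::quantile(x, 0.25)) else NA_real_,
        q3 = if (length(x)) unname(stats::quantile(x, 0.75)) else NA_real_
      )
    }
  }
  summary <- dplyr::bind_rows(rows)
  lv <- levels(grp)
  overlap <- list()
  for (s in scores) {
    sub <- summary[summary$score == s, ]
    for (i in seq_len(length(lv) - 1)) {
      a <- sub[sub$group == lv[i], ]
      b <- sub[sub$group == lv[i + 1], ]
      ov <- if (is.na(a$q1) || is.na(b$q1)) NA else (a$q1 <= b$q3 && b$q1 <= a$q3)
      overlap[[length(overlap) + 1]] <- tibble::tibble(
        score = s, group_a = lv[i], group_b = lv[i + 1], iqr_overlap = ov
      )
    }
  }
  list(summary = summary, overlap = dplyr::bind_rows(overlap))
}
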