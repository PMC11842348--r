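#' Change from baseline to Week 24
#'
#' Per-patient change (Week 24 minus baseline) in every score; a change is
#' missing when either visit's score is missing. Summary-score changes are
#' computed from the summary scores themselves, not from changed domains.
#'
#' @param panel Score panel from [score_cohort()].
#' @param scores Score columns (default all nine).
#' @return Tibble with `patient_id`, `trial` and one change column per score.
#' @export
change_from_baseline <- function(panel, scores = qole_scores()) {
  bas <- panel[panel$visit == "baseline", , drop = FALSE]
  wk <- panel[panel$visit == "week24", , drop = FALSE]
  ids <- intersect(bas$patient_id, wk$patient_id)
  bas <- bas[match(ids, bas$patient_id), ]
  wk <- wk[match(ids, wk$patient_id), ]
  out <- tibble::tibble(patient_id = ids, trial = bas$trial)
  for (s in scores) out[[s]] <- wk[[s]] - bas[[s]]
  out
}

#' Anchor change variables
#'
#' Builds the per-patient change (or absolute follow-up) variable for each
#' candidate anchor, oriented so that positive values mean improvement:
#' \describe{
#'   \item{item1}{Overall-health item: baseline level minus Week 24 level
#'     (the item is coded 0 = excellent ... 3 = poor, so a drop is an
#'     improvement). One unit = one verbal category.}
#'   \item{item2}{Health-compared-to-a-month-ago item at Week 24, recentred
#'     at its "unchanged" midpoint; the absolute follow-up score is used
#'     because the item measures change directly.}
#'   \item{qlq_item29, qlq_item30}{Week 24 minus baseline on the QLQ-C30
#'     global health / global QoL items (1-7, higher = better).}
#'   \item{hb}{Week 24 minus baseline hemoglobin, categorized at
#'     +/- `hb_cut` g/dL into worsened / no change / improved.}
#'   \item{rbc}{Week 24 minus baseline RBC units transfused in the previous
#'     8 weeks; a reduction of at least `rbc_cut` units is an improvement.}
#' }
#' The hemoglobin and transfusion cut-points are configuration defaults,
#' not published values.
#'
#' @param cohort Wide cohort tibble.
#' @param hb_cut Hemoglobin change (g/dL) defining a category step.
#' @param rbc_cut RBC-unit change defining a category step.
#' @return List with `change` (tibble of continuous anchor change variables)
#'   and `category` (tibble of ordinal anchor levels, positive = improved).
#' @export
anchor_changes <- function(cohort, hb_cut = 1.5, rbc_cut = 2) {
  bas <- cohort[cohort$visit == "baseline", , drop = FALSE]
  wk <- cohort[cohort$visit == "week24", , drop = FALSE]
  ids <- intersect(bas$patient_id, wk$patient_id)
  bas <- bas[match(ids, bas$patient_id), ]
  wk <- wk[match(ids, wk$patient_id), ]
  q2_mid <- 3 # "unchanged" midpoint of the 0-6 change-direct item
  change <- tibble::tibble(
    patient_id = ids,
    trial = bas$trial,
    item1 = bas$q1 - wk$q1,
    item2 = wk$q2 - q2_mid,
    qlq_item29 = wk$qlq_item29 - bas$qlq_item29,
    qlq_item30 = wk$qlq_item30 - bas$qlq_item30,
    hb = wk$hb_g_dl - bas$hb_g_dl,
    rbc = wk$rbc_units_8wk - bas$rbc_units_8wk
  )
  category <- tibble::tibble(
    patient_id = ids,
    trial = bas$trial,
    item1 = as.integer(change$item1),
    item2 = as.integer(change$item2),
    qlq_item29 = as.integer(change$qlq_item29),
    qlq_item30 = as.integer(change$qlq_item30),
    hb = ifelse(is.na(change$hb), NA_integer_,
                as.integer(sign(change$hb) * (abs(change$hb) >= hb_cut))),
    rbc = ifelse(is.na(change$rbc), NA_integer_,
                 as.integer(-sign(change$rbc) * (abs(change$rbc) >= rbc_cut)))
  )
  list(change = change, category = category)
}

#' Responsiveness correlations between score and anchor changes
#'
#' Spearman correlations between the change in every QOL-E score and the
#' change in every candidate anchor. Rows involving QLQ-C30 anchors exclude
#' patients from the trial without the QLQ-C30.
#'
#' @param score_changes Output of [change_from_baseline()].
#' @param anchor_change Tibble of anchor change variables (`$change` from
#'   [anchor_changes()]).
#' @param anchors Anchor column names (default all six candidates).
#' @param scores Score columns (default all nine).
#' @return Tibble with `anchor`, `score`, `n`, `r`, `p`, `magnitude`.
#' @export
responsiveness_correlations <- function(score_changes, anchor_change,
                                        anchors = c("item1", "item2",
                                                    "qlq_item29", "qlq_item30",
                                                    "hb", "rbc"),
                                        scores = qole_scores()) {
  joined <- dplyr::inner_join(score_changes, anchor_change,
                              by = c("patient_id", "trial"))
  rows <- list()
  for (a in anchors) {
    dat <- if (grepl("^qlq_", a)) drop_no_qlq_trial(joined) else joined
    for (s in scores) {
      res <- suppressWarnings(spearman(dat[[s]], dat[[a]]))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(anchor = a, score = s), res
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Select eligible anchors
#'
#' An anchor qualifies for the anchor-based analysis when the absolute
#' correlation between its change and the change in *every* QOL-E domain
#' and summary score — except the sexual well-being domain, whose
#' responsiveness is not established — exceeds `threshold`.
#'
#' @param corr_table Output of [responsiveness_correlations()].
#' @param threshold Absolute-correlation cutoff (default 0.3, strict).
#' @param exclude_scores Scores exempt from the rule (default `"SEX"`).
#' @return Character vector of eligible anchor names (possibly empty).
#' @export
select_anchors <- function(corr_table, threshold = 0.3,
                           exclude_scores = "SEX") {
  anchors <- unique(corr_table$anchor)
  if (length(anchors) == 0) stop("empty candidate anchor set", call. = FALSE)
  keep <- vapply(anchors, function(a) {
    sub <- corr_table[corr_table$anchor == a &
                        !(corr_table$score %in% exclude_scores), ]
    nrow(sub) > 0 && all(!is.na(sub$r)) && all(abs(sub$r) > threshold)
  }, logical(1))
  anchors[keep]
}

#' Build anchor groups with small-group collapsing
#'
#' Patients are grouped by their ordinal level of anchor change (positive =
#' improvement, 0 = no change). Any group of at most `min_n` patients is
#' merged into the adjacent group toward "no change", working outward-in and
#' repeating until every group exceeds `min_n`. Collapsing never crosses the
#' no-change boundary: if an entire side cannot exceed `min_n` it is kept as
#' one flagged group rather than absorbed into "no change".
#'
#' @param change Numeric vector of score changes (one per patient).
#' @param category Integer vector of anchor levels, same length.
#' @param min_n Groups with `n <= min_n` are collapsed (default 10).
#' @return Tibble with one row per final group: `level_min`, `level_max`,
#'   `label`, `n`, `mean_change`, `median_change`, `flagged` (side kept
#'   whole below the size rule), plus attribute `collapse_log` (character).
#' @export
build_anchor_groups <- function(change, category, min_n = 10) {
  ok <- !is.na(change) & !is.na(category)
  change <- change[ok]
  category <- as.integer(category[ok])
  if (length(change) == 0) {
    stop("no patients with both score change and anchor category", call. = FALSE)
  }
  levels_ <- sort(unique(category))
  groups <- lapply(levels_, function(l) {
    list(lo = l, hi = l, values = change[category == l])
  })
  log <- character(0)
  if (length(levels_) == 1) {
    warning("all patients in a single anchor category")
  }
  collapse_side <- function(groups, side) {
    # side = +1: improvement levels (> 0); side = -1: worsening (< 0)
    repeat {
      idx <- which(vapply(groups, function(g) sign(g$lo) == side, logical(1)))
      if (length(idx) <= 1) break
      sizes <- vapply(groups[idx], function(g) length(g$values), integer(1))
      if (all(sizes > min_n)) break
      # outermost small group first
      ord <- if (side > 0) rev(idx) else idx
      small <- ord[vapply(groups[ord], function(g) length(g$values) <= min_n,
                          logical(1))][1]
      # adjacent group toward no change
      nb <- if (side > 0) small - 1 else small + 1
      log <<- c(log, sprintf("merged level [%d,%d] (n=%d) into [%d,%d]",
                             groups[[small]]$lo, groups[[small]]$hi,
                             length(groups[[small]]$values),
                             groups[[nb]]$lo, groups[[nb]]$hi))
      groups[[nb]]$lo <- min(groups[[nb]]$lo, groups[[small]]$lo)
      groups[[nb]]$hi <- max(groups[[nb]]$hi, groups[[small]]$hi)
      groups[[nb]]$values <- c(groups[[nb]]$values, groups[[small]]$values)
      groups[[small]] <- NULL
    }
    groups
  }
  groups <- collapse_side(groups, +1)
  groups <- collapse_side(groups, -1)
  rows <- lapply(groups, function(g) {
    label <- if (g$lo == g$hi) {
      sprintf("%+d", g$lo)
    } else if (g$hi > 0 && g$lo > 0) {
      sprintf(">=%+d", g$lo)
    } else if (g$lo < 0 && g$hi < 0) {
      sprintf("<=%+d", g$hi)
    } else {
      sprintf("%+d..%+d", g$lo, g$hi)
    }
    if (g$lo == 0 && g$hi == 0) label <- "0"
    tibble::tibble(
      level_min = g$lo, level_max = g$hi, label = label,
      n = length(g$values),
      mean_change = mean(g$values),
      median_change = stats::median(g$values),
      flagged = length(g$values) <= min_n
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$level_min), ]
  attr(out, "collapse_log") <- log
  out
}

#' Empirical-CDF separation between a change group and the no-change group
#'
#' Codifies the visual "clear and consistent separation" judgement: both
#' eCDFs are evaluated on the pooled grid of observed change values, and the
#' side group is declared separated when (a) its eCDF lies strictly on the
#' correct side of the no-change eCDF (below for improvement, above for
#' worsening) at 80% or more of the grid points where the curves are not
#' both 0 or both 1, and (b) the between-group median difference is at
#' least `mpc`, the score's minimum possible change, in the correct
#' direction.
#'
#' @param side_changes Score changes of the >= 1-level improvement (or
#'   worsening) group.
#' @param nochange_changes Score changes of the no-change group.
#' @param side `"improvement"` or `"worsening"`.
#' @param mpc Minimum possible change of the score, in points.
#' @param dominance Required fraction of grid points (default 0.8).
#' @return List with `separated` (logical, `NA` when the side group has
#'   fewer than 3 patients), `dominance_fraction`, `median_difference`, and
#'   `grid` (tibble of `x`, `F_side`, `F_nochange`).
#' @export
ecdf_separation <- function(side_changes, nochange_changes,
                            side = c("improvement", "worsening"),
                            mpc, dominance = 0.8) {
  side <- match.arg(side)
  side_changes <- side_changes[!is.na(side_changes)]
  nochange_changes <- nochange_changes[!is.na(nochange_changes)]
  if (length(nochange_changes) == 0) {
    stop("empty no-change group", call. = FALSE)
  }
  grid <- sort(unique(c(side_changes, nochange_changes)))
  Fs <- stats::ecdf(side_changes)(grid)
  Fn <- stats::ecdf(nochange_changes)(grid)
  out_grid <- tibble::tibble(x = grid, F_side = Fs, F_nochange = Fn)
  med_diff <- stats::median(side_changes) - stats::median(nochange_changes)
  if (length(side_changes) < 3) {
    return(list(separated = NA, dominance_fraction = NA_real_,
                median_difference = med_diff, grid = out_grid))
  }
  informative <- !((Fs == 0 & Fn == 0) | (Fs == 1 & Fn == 1))
  if (!any(informative)) {
    frac <- 0
  } else if (side == "improvement") {
    frac <- mean(Fs[informative] < Fn[informative])
  } else {
    frac <- mean(Fs[informative] > Fn[informative])
  }
  med_ok <- if (side == "improvement") med_diff >= mpc else med_diff <= -mpc
  list(separated = frac >= dominance && med_ok,
       dominance_fraction = frac,
       median_difference = med_diff,
       grid = out_grid)
}

#' Distribution-based threshold estimates
#'
#' `sem_points()` is the standard error of measurement, the baseline SD of a
#' score multiplied by sqrt(1 - ICC) — the conventional lower bound for a
#' meaningful-change threshold. `half_sd()` is half the baseline SD,
#' corresponding to a 0.5 effect size.
#'
#' @param sd_baseline Baseline standard deviation of the score, in points.
#' @param icc Test-retest intraclass correlation in \[0, 1\].
#' @return Points on the 0-100 scale.
#' @export
sem_points <- function(sd_baseline, icc) {
  if (any(sd_baseline < 0, na.rm = TRUE)) stop("sd must be >= 0", call. = FALSE)
  if (any(icc < 0 | icc > 1, na.rm = TRUE)) {
    stop("icc must lie in [0, 1]", call. = FALSE)
  }
  sd_baseline * sqrt(1 - icc)
}

#' @rdname sem_points
#' @export
half_sd <- function(sd_baseline) {
  if (any(sd_baseline < 0, na.rm = TRUE)) stop("sd must be >= 0", call. = FALSE)
  sd_baseline / 2
}

#' Assemble triangulation inputs
#'
#' Bundles, per score, the distribution-based estimates (SEM, 0.5*SD), the
#' minimum possible change, the anchor-group mean/median change estimates,
#' and the per-side eCDF-separation verdicts into the structure consumed by
#' [triangulate_mwpc()].
#'
#' @param stats Tibble with `score`, `sem`, `half_sd`, `mpc` (`mpc` may be
#'   `NA` for summary scores, whose minimum step is too small to matter).
#' @param anchors Tibble with `score`, `anchor`, `side` (`"improvement"` /
#'   `"worsening"`), `n`, `mean_change`, `median_change`.
#' @param eligibility Tibble with `score`, `side`, `eligible`; sides absent
#'   from the table are treated as eligible.
#' @param primary_anchor Anchor used by the summary-score rule (default
#'   `"item1"`, the overall-health item).
#' @return A `triangulation_inputs` list.
#' @export
triangulation_inputs <- function(stats, anchors,
                                 eligibility = NULL,
                                 primary_anchor = "item1") {
  if (is.null(eligibility)) {
    eligibility <- tibble::tibble(score = character(), side = character(),
                                  eligible = logical())
  }
  structure(
    list(stats = tibble::as_tibble(stats),
         anchors = tibble::as_tibble(anchors),
         eligibility = tibble::as_tibble(eligibility),
         primary_anchor = primary_anchor),
    class = "triangulation_inputs"
  )
}

#' Domain-score MWPC threshold rule
#'
#' The proposed improvement threshold is the smallest achievable change —
#' i.e. the smallest positive integer multiple of the score's minimum
#' possible change — that clears the larger of SEM and 0.5*SD, allowing a
#' 0.5-point tolerance that absorbs one-decimal rounding of the published
#' statistics; the multiple is then floored to an integer number of points.
#' The worsening threshold is its negative.
#'
#' @param sem,half_sd Distribution-based estimates, in points.
#' @param mpc Minimum possible change of the score, in points (> 0).
#' @param tol Rounding tolerance in points (default 0.5).
#' @return Integer improvement threshold, in points.
#' @export
mwpc_domain_threshold <- function(sem, half_sd, mpc, tol = 0.5) {
  if (is.na(mpc) || mpc <= 0) stop("mpc must be a positive number", call. = FALSE)
  d <- max(sem, half_sd)
  k <- max(1, ceiling((d - tol) / mpc))
  as.integer(floor(k * mpc))
}

#' Common summary-score MWPC threshold rule
#'
#' A single threshold is chosen across the summary scores for practical
#' use: the floor of the smallest primary-anchor mean improvement among
#' them, required to clear each summary's max(SEM, 0.5*SD) minus the
#' rounding tolerance. If the floor of the smallest mean fails that bound,
#' the next larger candidate mean is used.
#'
#' @param mean_improvements Primary-anchor mean improvement of each summary
#'   score, in points.
#' @param sems,half_sds Distribution-based estimates per summary score.
#' @param tol Rounding tolerance in points (default 0.5).
#' @return Integer common improvement threshold.
#' @export
mwpc_summary_threshold <- function(mean_improvements, sems, half_sds,
                                   tol = 0.5) {
  if (length(mean_improvements) == 0 || all(is.na(mean_improvements))) {
    stop("no primary-anchor mean improvements available", call. = FALSE)
  }
  d <- pmax(sems, half_sds)
  bound <- max(d, na.rm = TRUE) - tol
  candidates <- sort(floor(mean_improvements[!is.na(mean_improvements)]))
  ok <- candidates[candidates >= bound]
  thr <- if (length(ok) > 0) ok[1] else max(candidates)
  as.integer(thr)
}

#' Triangulate MWPC thresholds
#'
#' Applies the codified triangulation rules to assembled inputs. Domain
#' scores (rows of `stats` with a non-missing `mpc`) use
#' [mwpc_domain_threshold()]; summary scores share a single common
#' threshold from [mwpc_summary_threshold()]. For each score the anchor
#' range is reported as \[max(D, smallest eligible estimate), largest
#' eligible estimate\] per side, where D = max(SEM, 0.5*SD) and the
#' estimates are the mean and median changes of anchor sides that passed
#' the eCDF-separation check (a side with no eligible estimates contributes
#' an open-ended range \[D, Inf)). The `consistent` flag records whether the
#' proposed threshold lies within \[range_min - 1, range_max + 1\].
#'
#' @param inputs A [triangulation_inputs()] object.
#' @param summary_scores Scores pooled under the common summary rule
#'   (default GEN, ALL, TOI; set to `character(0)` to treat every row as a
#'   domain).
#' @return Tibble with one row per score: `score`, `rule`,
#'   `improvement_threshold`, `worsening_threshold`, `anchor_range_lo`,
#'   `anchor_range_hi` (improvement side, signed), `wors_range_lo`,
#'   `wors_range_hi`, `consistent`, `rationale`.
#' @export
triangulate_mwpc <- function(inputs, summary_scores = c("GEN", "ALL", "TOI")) {
  stopifnot(inherits(inputs, "triangulation_inputs"))
  st <- inputs$stats
  anc <- inputs$anchors
  elig <- inputs$eligibility

  side_eligible <- function(score, side) {
    row <- elig[elig$score == score & elig$side == side, ]
    if (nrow(row) == 0) TRUE else isTRUE(row$eligible[1])
  }
  side_estimates <- function(score, side) {
    if (!side_eligible(score, side)) return(numeric(0))
    sub <- anc[anc$score == score & anc$side == side, ]
    c(sub$mean_change, sub$median_change)
  }
  anchor_range <- function(score, side, d) {
    est <- abs(side_estimates(score, side))
    if (length(est) == 0) c(d, Inf) else c(max(d, min(est)), max(est))
  }

  summary_scores <- intersect(summary_scores, st$score)
  common <- NULL
  if (length(summary_scores) > 0) {
    prim <- anc[anc$anchor == inputs$primary_anchor &
                  anc$side == "improvement" &
                  anc$score %in% summary_scores, ]
    idx <- match(summary_scores, st$score)
    common <- mwpc_summary_threshold(
      prim$mean_change[match(summary_scores, prim$score)],
      st$sem[idx], st$half_sd[idx]
    )
  }

  rows <- lapply(seq_len(nrow(st)), function(i) {
    score <- st$score[i]
    d <- max(st$sem[i], st$half_sd[i])
    is_summary <- score %in% summary_scores
    if (is_summary) {
      thr <- common
      rationale <- paste("common summary threshold: floor of the smallest",
                         "primary-anchor mean improvement across summary",
                         "scores, clearing max(SEM, 0.5*SD) - 0.5")
    } else {
      if (is.na(st$mpc[i])) {
        stop("mpc missing for domain score ", score, call. = FALSE)
      }
      thr <- mwpc_domain_threshold(st$sem[i], st$half_sd[i], st$mpc[i])
      k <- round(thr / st$mpc[i])
      rationale <- sprintf(
        "smallest multiple (%d) of the minimum possible change (%.1f) clearing max(SEM, 0.5*SD) = %.1f minus 0.5",
        max(1, ceiling((d - 0.5) / st$mpc[i])), st$mpc[i], d)
    }
    imp_rng <- anchor_range(score, "improvement", d)
    wor_rng <- anchor_range(score, "worsening", d)
    consistent <- thr >= imp_rng[1] - 1 &&
      (is.infinite(imp_rng[2]) || thr <= imp_rng[2] + 1)
    tibble::tibble(
      score = score,
      rule = if (is_summary) "summary" else "domain",
      improvement_threshold = as.integer(thr),
      worsening_threshold = -as.integer(thr),
      anchor_range_lo = imp_rng[1], anchor_range_hi = imp_rng[2],
      wors_range_lo = -wor_rng[2], wors_range_hi = -wor_rng[1],
      consistent = consistent,
      rationale = rationale
    )
  })
  dplyr::bind_rows(rows)
}

#' Published triangulation inputs for the QOL-E
#'
#' The anchor-group estimates, SEM, 0.5*SD and minimum-possible-change
#' values reported for the QOL-E in the pooled multi-trial validation,
#' shipped with the package as `inst/extdata/reference_triangulation.csv`
#' and assembled into a [triangulation_inputs()] object. Feeding these into
#' [triangulate_mwpc()] reproduces the published thresholds (FIS +/-12,
#' FUN +/-22, SOC +/-25, FAT +/-9, MDSS +/-14, summaries +/-13).
#'
#' @return A `triangulation_inputs` object covering FIS, FUN, SOC, FAT,
#'   MDSS, GEN, ALL, TOI (the sexual well-being domain was not triangulated
#'   because its responsiveness was not demonstrated).
#' @export
reference_triangulation_inputs <- function() {
  path <- system.file("extdata", "reference_triangulation.csv",
                      package = "qolemwpc", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats <- unique(df[c("score", "sem", "half_sd", "mpc")])
  anchors <- df[!is.na(df$anchor) & df$anchor != "",
                c("score", "anchor", "side", "n", "mean_change", "median_change")]
  elig <- unique(df[c("score", "side", "eligible")])
  elig <- elig[!is.na(elig$eligible), ]
  triangulation_inputs(stats = stats, anchors = anchors, eligibility = elig,
                       primary_anchor = "item1")
}
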