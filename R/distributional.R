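#' Distributional summary of standardized scores
#'
#' Descriptive statistics (n, mean, SD, median, Q1, Q3, min, max), ten-point
#' incremental bin counts, and floor/ceiling percentages for each score at
#' each visit. Bins are half-open \[0,10), \[10,20), ..., \[90,100), with a
#' score of exactly 100 its own category. Quartiles use linear interpolation
#' between order statistics (`stats::quantile` type 7). Missing values are
#' excluded from all denominators. A floor (ceiling) effect is flagged when
#' strictly more than 15% of the non-missing scores equal 0 (100).
#'
#' @param panel Score panel from [score_cohort()], or any tibble with a
#'   `visit` column and the score columns.
#' @param scores Score columns to summarize (default all nine).
#' @param visits Visits to summarize (default baseline and week24).
#' @return Tibble with one row per (score, visit): the descriptive
#'   statistics, `floor_pct`, `ceiling_pct`, `floor_flag`, `ceiling_flag`,
#'   and a list-column `bins` (tibble of `bin`, `count`, `pct`).
#' @export
summarize_distribution <- function(panel, scores = qole_scores(),
                                   visits = c("baseline", "week24")) {
  rows <- list()
  for (v in visits) {
    sub <- panel[panel$visit == v, , drop = FALSE]
    for (s in scores) {
      x <- sub[[s]]
      x <- x[!is.na(x)]
      n <- length(x)
      if (n == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          score = s, visit = v, n = 0L, mean = NA_real_, sd = NA_real_,
          median = NA_real_, q1 = NA_real_, q3 = NA_real_, min = NA_real_,
          max = NA_real_, floor_pct = NA_real_, ceiling_pct = NA_real_,
          floor_flag = NA, ceiling_flag = NA, bins = list(decile_bins(numeric(0)))
        )
        next
      }
      floor_pct <- 100 * mean(x == 0)
      ceiling_pct <- 100 * mean(x == 100)
      rows[[length(rows) + 1]] <- tibble::tibble(
        score = s, visit = v, n = n, mean = mean(x), sd = stats::sd(x),
        median = stats::median(x),
        q1 = unname(stats::quantile(x, 0.25)),
        q3 = unname(stats::quantile(x, 0.75)),
        min = min(x), max = max(x),
        floor_pct = floor_pct, ceiling_pct = ceiling_pct,
        floor_flag = flag_floor_ceiling(floor_pct),
        ceiling_flag = flag_floor_ceiling(ceiling_pct),
        bins = list(decile_bins(x))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @rdname summarize_distribution
#' @param x Numeric vector of non-missing scores in \[0, 100\].
#' @export
decile_bins <- function(x) {
  labels <- c(paste0("[", seq(0, 90, 10), ",", seq(10, 100, 10), ")"), "100")
  counts <- integer(11)
  for (i in 1:10) counts[i] <- sum(x >= (i - 1) * 10 & x < i * 10)
  counts[11] <- sum(x == 100)
  tibble::tibble(
    bin = labels, count = counts,
    pct = if (length(x) > 0) 100 * counts / length(x) else rep(NA_real_, 11)
  )
}

#' @rdname summarize_distribution
#' @param pct Percentage of scores at the floor (0) or ceiling (100).
#' @param threshold Flagging threshold (default 15, strict inequality).
#' @export
flag_floor_ceiling <- function(pct, threshold = 15) {
  pct > threshold
}

#' Flatten a distribution summary to CSV-ready columns
#'
#' Spreads the decile-bin list-column into `pct_*` columns and encodes the
#' floor/ceiling flags as 0/1.
#'
#' @param summary Output of [summarize_distribution()].
#' @return A plain tibble without list-columns.
#' @export
distribution_report <- function(summary) {
  bins <- lapply(seq_len(nrow(summary)), function(i) {
    b <- summary$bins[[i]]
    nm <- gsub("^_+|_+$", "", gsub("[^0-9]+", "_", b$bin))
    stats::setNames(as.list(b$pct), paste0("pct_", nm))
  })
  flat <- dplyr::bind_rows(lapply(bins, tibble::as_tibble))
  out <- dplyr::bind_cols(summary[setdiff(names(summary), "bins")], flat)
  out$floor_flag <- as.integer(out$floor_flag)
  out$ceiling_flag <- as.integer(out$ceiling_flag)
  out
}
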