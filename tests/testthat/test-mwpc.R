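test_that("change from baseline requires both visits", {
  panel <- tibble::tibble(
    patient_id = c("a", "a", "b", "b", "c"),
    trial = "T1_medalist_like",
    visit = c("baseline", "week24", "baseline", "week24", "baseline"),
    FIS = c(50, 62, NA, 40, 30)
  )
  ch <- change_from_baseline(panel, scores = "FIS")
  expect_equal(ch$FIS[ch$patient_id == "a"], 12)
  expect_true(is.na(ch$FIS[ch$patient_id == "b"]))
  expect_false("c" %in% ch$patient_id)
})

test_that("summary change comes from summary scores, not domain changes", {
  # SEX missing at baseline only: GEN uses 5 domains at week24, 4 at baseline
  panel <- tibble::tibble(
    patient_id = c("a", "a"), trial = "T1_medalist_like",
    visit = c("baseline", "week24"),
    FIS = c(40, 50), FUN = c(40, 50), SOC = c(40, 50), SEX = c(NA, 0),
    FAT = c(40, 50), MDSS = c(40, 50)
  )
  sch <- default_schema()
  panel <- dplyr::bind_cols(
    panel,
    dplyr::bind_rows(lapply(seq_len(nrow(panel)), function(i) {
      tibble::as_tibble(as.list(score_summaries(panel[i, c("FIS", "FUN", "SOC",
                                                           "SEX", "FAT",
                                                           "MDSS")], sch)))
    }))
  )
  ch <- change_from_baseline(panel)
  expect_equal(ch$GEN, 40 - 40) # mean(50,50,50,0,50) - mean(40,40,40,40)
  # a naive mean of domain changes would have said +10 for the four shared
  expect_false(isTRUE(all.equal(ch$GEN, mean(c(10, 10, 10, 10)))))
})

test_that("anchor selection applies the 0.3 rule outside the sexual domain", {
  scores <- setdiff(qolemwpc:::qole_scores(), character(0))
  tbl <- tidyr::expand_grid(
    anchor = c("item1", "item2", "qlq_item29", "qlq_item30", "hb", "rbc"),
    score = scores
  )
  # pattern mirroring the published responsiveness table: only the
  # overall-health item and QLQ-C30 item 29 clear 0.3 everywhere but SEX
  base_r <- c(item1 = 0.36, item2 = 0.24, qlq_item29 = 0.35,
              qlq_item30 = 0.29, hb = 0.2, rbc = 0.08)
  tbl$r <- base_r[tbl$anchor]
  tbl$r[tbl$score == "SEX"] <- 0.07
  expect_setequal(select_anchors(tbl), c("item1", "qlq_item29"))
  # boundary: exactly 0.3 does not qualify, 0.31 does
  tbl2 <- tbl[tbl$anchor == "item1", ]
  tbl2$r[tbl2$score != "SEX"] <- 0.30
  expect_length(select_anchors(tbl2), 0)
  tbl2$r[tbl2$score != "SEX"] <- 0.31
  expect_equal(select_anchors(tbl2), "item1")
  # a single sub-threshold domain disqualifies the anchor
  tbl3 <- tbl[tbl$anchor == "qlq_item29", ]
  tbl3$r[tbl3$score == "FUN"] <- 0.25
  expect_length(select_anchors(tbl3), 0)
  expect_error(select_anchors(tbl[0, ]), "empty")
})

test_that("anchor selection is monotone in the correlations", {
  set.seed(61)
  scores <- qolemwpc:::qole_scores()
  for (i in 1:20) {
    tbl <- tidyr::expand_grid(anchor = c("a1", "a2"), score = scores)
    tbl$r <- stats::runif(nrow(tbl), 0, 0.6)
    before <- select_anchors(tbl)
    j <- sample(nrow(tbl), 1)
    tbl$r[j] <- min(1, tbl$r[j] + stats::runif(1, 0, 0.4))
    after <- select_anchors(tbl)
    expect_true(all(before %in% after))
  }
})

test_that("anchor groups collapse toward no change and conserve patients", {
  lv <- c(rep(2, 4), rep(1, 20), rep(0, 50), rep(-1, 15))
  ch <- stats::rnorm(length(lv), mean = 10 * lv, sd = 1)
  g <- build_anchor_groups(ch, lv)
  expect_equal(g$n, c(15, 50, 24))
  expect_equal(g$label[g$level_min == 1], ">=+1")
  expect_equal(sum(g$n), length(lv))
  expect_length(attr(g, "collapse_log"), 1)
  # already-large groups stay untouched
  lv2 <- c(rep(1, 20), rep(0, 30), rep(-1, 25))
  g2 <- build_anchor_groups(stats::rnorm(75), lv2)
  expect_equal(g2$n, c(25, 30, 20))
  expect_length(attr(g2, "collapse_log"), 0)
})

test_that("a side that cannot reach the size rule is kept whole and flagged", {
  lv <- c(rep(3, 2), rep(2, 3), rep(1, 4), rep(0, 40))
  ch <- stats::rnorm(length(lv), mean = 5 * lv)
  g <- build_anchor_groups(ch, lv)
  imp <- g[g$level_min >= 1, ]
  expect_equal(nrow(imp), 1)
  expect_equal(imp$n, 9)
  expect_true(imp$flagged)
  expect_equal(g$n[g$level_min == 0], 40) # never absorbed across the boundary
  expect_equal(sum(g$n), length(lv))
})

test_that("single-category anchors warn and return one group", {
  expect_warning(g <- build_anchor_groups(stats::rnorm(12), rep(0, 12)),
                 "single anchor category")
  expect_equal(nrow(g), 1)
})

test_that("eCDF separation detects shifted groups and respects direction", {
  set.seed(9)
  none <- stats::rnorm(60, 0, 8)
  up <- none + 20
  sep <- ecdf_separation(up, none, side = "improvement", mpc = 12.5)
  expect_true(sep$separated)
  expect_gte(sep$dominance_fraction, 0.8)
  down <- none - 20
  sep2 <- ecdf_separation(down, none, side = "worsening", mpc = 12.5)
  expect_true(sep2$separated)
  # identical groups cannot separate
  sep3 <- ecdf_separation(none, none, side = "improvement", mpc = 12.5)
  expect_false(sep3$separated)
  # a shift in the wrong direction fails the worsening check
  sep4 <- ecdf_separation(up, none, side = "worsening", mpc = 12.5)
  expect_false(sep4$separated)
  # tiny side groups give a missing verdict
  sep5 <- ecdf_separation(up[1:2], none, side = "improvement", mpc = 12.5)
  expect_true(is.na(sep5$separated))
})

test_that("SEM and half-SD follow their definitions", {
  expect_equal(sem_points(20, 1), 0)
  expect_equal(sem_points(20, 0), 20)
  expect_equal(sem_points(20, 0.75), 10)
  expect_equal(half_sd(21.4), 10.7)
  expect_equal(half_sd(0), 0)
  expect_error(sem_points(10, 1.2), "\\[0, 1\\]")
  # decreasing in ICC, linear in SD
  iccs <- seq(0, 1, 0.1)
  expect_true(all(diff(sem_points(15, iccs)) < 0))
  expect_equal(half_sd(c(10, 20, 40)), c(5, 10, 20))
})

test_that("domain rule picks the smallest minimum-change multiple clearing the noise floor", {
  expect_equal(mwpc_domain_threshold(sem = 12.6, half_sd = 10.7, mpc = 12.5), 12L)
  expect_equal(mwpc_domain_threshold(sem = 21.1, half_sd = 16.2, mpc = 11.1), 22L)
  expect_equal(mwpc_domain_threshold(sem = 18.1, half_sd = 18.8, mpc = 25.0), 25L)
  expect_equal(mwpc_domain_threshold(sem = 7.5, half_sd = 7.0, mpc = 4.8), 9L)
  expect_equal(mwpc_domain_threshold(sem = 12.9, half_sd = 11.9, mpc = 2.4), 14L)
  # a tiny noise floor still yields at least one step
  expect_equal(mwpc_domain_threshold(sem = 0.1, half_sd = 0.1, mpc = 12.5), 12L)
  expect_error(mwpc_domain_threshold(1, 1, NA), "positive")
})

test_that("triangulation of the published inputs reproduces all thresholds", {
  ti <- reference_triangulation_inputs()
  out <- triangulate_mwpc(ti)
  got <- stats::setNames(out$improvement_threshold, out$score)
  expect_equal(got[c("FIS", "FUN", "SOC", "FAT", "MDSS")],
               c(FIS = 12L, FUN = 22L, SOC = 25L, FAT = 9L, MDSS = 14L))
  expect_equal(unname(got[c("GEN", "ALL", "TOI")]), rep(13L, 3))
  expect_equal(out$worsening_threshold, -out$improvement_threshold)
  # published anchor ranges are recovered by the codified range rule
  fis <- out[out$score == "FIS", ]
  expect_equal(c(fis$anchor_range_lo, fis$anchor_range_hi), c(12.6, 15.1))
  expect_equal(c(fis$wors_range_lo, fis$wors_range_hi), c(-25.0, -12.6))
  fun <- out[out$score == "FUN", ]
  expect_equal(fun$anchor_range_lo, 21.1) # improvement side failed the eCDF check
  expect_true(is.infinite(fun$anchor_range_hi))
  # the noise floor D = 21.1 caps the worsening lower bound because one
  # anchor median (-16.7) falls below it
  expect_equal(c(fun$wors_range_lo, fun$wors_range_hi), c(-24.6, -21.1))
  expect_true(all(out$consistent))
})

test_that("end-to-end anchor estimates track their large-sample values", {
  # large-cohort reference for the mean FAT change among >= 1-level
  # overall-health improvers
  big_cfg <- cohort_config(per_trial_n = c(T1_medalist_like = 8000L,
                                           T2_darb_like = 0L,
                                           T3_eqol_like = 0L,
                                           T4_rev_like = 0L),
                           seed = 1234)
  co <- generate_cohort(big_cfg)
  pan <- score_cohort(co)
  ch <- change_from_baseline(pan)
  cat_ <- anchor_changes(co)$category
  joined <- dplyr::inner_join(ch, cat_, by = c("patient_id", "trial"))
  ref <- mean(joined$FAT[joined$item1 >= 1], na.rm = TRUE)
  mpc_fat <- 4.8
  hits <- vapply(1:12, function(s) {
    cfg <- cohort_config(seed = 500 + s)
    co_s <- generate_cohort(cfg)
    pan_s <- filter_analysis_population(score_cohort(co_s))
    ch_s <- change_from_baseline(pan_s)
    cat_s <- anchor_changes(co_s)$category
    j <- dplyr::inner_join(ch_s, cat_s, by = c("patient_id", "trial"))
    est <- mean(j$FAT[j$item1 >= 1], na.rm = TRUE)
    abs(est - ref) <= mpc_fat
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
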