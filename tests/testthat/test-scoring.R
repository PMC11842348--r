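sch <- default_schema()

test_that("default schema satisfies the instrument's structural invariants", {
  expect_equal(nrow(sch$items), 29)
  expect_equal(sum(sch$items$domain != "GENERAL"), 27)
  expect_equal(sum(sch$items$domain == "GENERAL"), 2)
  ranges <- vapply(qolemwpc:::qole_domains(), function(d) {
    it <- sch$items[sch$items$domain == d, ]
    sum(it$raw_max - it$raw_min)
  }, numeric(1))
  expect_equal(ranges,
               c(FIS = 8, FUN = 9, SOC = 4, SEX = 12, FAT = 21, MDSS = 42))
})

test_that("standardization anchors: all-best scores 100, all-worst scores 0", {
  expect_equal(unname(score_domains(extreme_record(sch, best = TRUE), sch)),
               rep(100, 6))
  expect_equal(unname(score_domains(extreme_record(sch, best = FALSE), sch)),
               rep(0, 6))
})

test_that("one raw step above worst on the social domain scores 25", {
  rec <- extreme_record(sch, best = FALSE)
  soc_items <- sch$items$item_id[sch$items$domain == "SOC"]
  # SOC items are reversed; moving one raw point down improves by one step
  rec[soc_items[1]] <- rec[soc_items[1]] - 1L
  expect_equal(unname(score_domains(rec, sch)["SOC"]), 25.0)
})

test_that("domain scores are affine in the oriented raw sum (exhaustive)", {
  soc <- sch$items[sch$items$domain == "SOC", ]
  combos <- expand.grid(a = soc$raw_min[1]:soc$raw_max[1],
                        b = soc$raw_min[2]:soc$raw_max[2])
  for (i in seq_len(nrow(combos))) {
    rec <- stats::setNames(c(combos$a[i], combos$b[i]), soc$item_id)
    oriented <- (soc$raw_max[1] - combos$a[i]) + (soc$raw_max[2] - combos$b[i])
    expect_equal(unname(score_domains(rec, sch)["SOC"]), 100 * oriented / 4)
  }
})

test_that("minimum possible change equals the smallest achievable score step", {
  mpc_exact <- minimum_possible_change(sch, digits = NA)
  for (d in qolemwpc:::qole_domains()) {
    it <- sch$items[sch$items$domain == d, ]
    sums <- achievable_sums(it$raw_max - it$raw_min)
    scores <- 100 * sums / max(sums)
    expect_equal(min(diff(sort(unique(scores)))), mpc_exact[[d]])
  }
})

test_that("default schema reproduces the published minimum-change row", {
  expect_equal(minimum_possible_change(sch, c("FIS", "FUN", "SOC", "FAT", "MDSS")),
               c(FIS = 12.5, FUN = 11.1, SOC = 25.0, FAT = 4.8, MDSS = 2.4))
  expect_equal(unname(minimum_possible_change(sch, "SOC")), 25.0)
  expect_error(minimum_possible_change(sch, "GENERAL"), "not scored")
})

test_that("reversing an item twice restores the oriented value", {
  it <- sch$items[sch$items$reversed, ][1, ]
  raw <- it$raw_min:it$raw_max
  once <- it$raw_max + it$raw_min - raw
  twice <- it$raw_max + it$raw_min - once
  expect_identical(twice, raw)
})

test_that("summary scores follow the composition rules", {
  doms <- c(FIS = 50, FUN = 50, SOC = 50, SEX = 50, FAT = 50, MDSS = 50)
  expect_equal(score_summaries(doms, sch),
               c(GEN = 50, ALL = 50, TOI = 50))
  doms2 <- c(FIS = 60, FUN = 80, SOC = 40, SEX = 20, FAT = 70, MDSS = 40)
  expect_equal(unname(score_summaries(doms2, sch)["TOI"]), 60)
  # missing SEX is dropped from GEN
  doms3 <- c(FIS = 40, FUN = 60, SOC = 20, SEX = NA, FAT = 80, MDSS = 30)
  out <- score_summaries(doms3, sch)
  expect_equal(unname(out["GEN"]), 50)
  expect_equal(unname(out["ALL"]), 40)
  # any other missing constituent silences the summary
  doms4 <- c(FIS = NA, FUN = 60, SOC = 20, SEX = 50, FAT = 80, MDSS = 30)
  out4 <- score_summaries(doms4, sch)
  expect_true(is.na(out4["GEN"]))
  expect_true(is.na(out4["TOI"]))
})

test_that("domains are prorated when enough items are answered, else missing", {
  fat_items <- sch$items$item_id[sch$items$domain == "FAT"]
  rec <- stats::setNames(rep(0L, 7), fat_items) # reversed: 0 = best
  rec[1:3] <- NA # 4 of 7 answered -> score kept, prorated
  expect_equal(unname(score_domains(rec, sch)["FAT"]), 100)
  rec[1:4] <- NA # 3 of 7 answered -> below the half rule
  expect_true(is.na(score_domains(rec, sch)["FAT"]))
})

test_that("out-of-range and unknown responses raise informative errors", {
  expect_error(score_domains(c(q3 = 9L), sch), "out of range.*q3")
  expect_error(score_domains(c(nope = 1L), sch), "unknown item_id")
})

test_that("schema round-trips through YAML and JSON", {
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_schema(sch, path)
    back <- read_schema(path)
    expect_equal(back$items, sch$items)
    expect_equal(back$summary_composition, sch$summary_composition)
    expect_equal(back$min_answered_fraction, sch$min_answered_fraction)
  }
})

test_that("analysis population keeps patients with any baseline domain score", {
  panel <- tibble::tibble(
    patient_id = c("a", "a", "b", "b", "c", "c"),
    trial = "T1_medalist_like",
    visit = rep(c("baseline", "week24"), 3),
    FIS = c(NA, 50, 40, 50, NA, NA), FUN = NA_real_, SOC = c(NA, NA, NA, NA, 30, NA),
    SEX = NA_real_, FAT = NA_real_, MDSS = NA_real_,
    GEN = NA_real_, ALL = NA_real_, TOI = NA_real_
  )
  # patient a has no baseline domain; b has FIS; c has SOC only
  out <- filter_analysis_population(panel)
  expect_setequal(unique(out$patient_id), c("b", "c"))
  expect_equal(attr(out, "exclusions")$patient_id, "a")
  expect_warning(filter_analysis_population(panel[0, ]), "empty")
})

test_that("cohort tables round-trip through wide and long CSV", {
  co <- generate_cohort(cohort_config(
    per_trial_n = c(T1_medalist_like = 5L, T2_darb_like = 2L,
                    T3_eqol_like = 2L, T4_rev_like = 2L),
    seed = 5
  ))
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, wide)
  write_cohort(co, long, format = "long")
  back_w <- read_cohort(wide)
  back_l <- read_cohort(long)
  expect_equal(score_cohort(back_w), score_cohort(co))
  expect_equal(score_cohort(back_l)[order(back_l$patient_id, back_l$visit), ],
               score_cohort(co)[order(co$patient_id, co$visit), ],
               ignore_attr = TRUE)
  bad <- co
  bad$q3[1] <- 99
  badfile <- withr::local_tempfile(fileext = ".csv")
  write_cohort(bad, badfile)
  expect_error(read_cohort(badfile), "q3")
})
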