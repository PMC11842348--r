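test_that("perfect agreement gives ICC(A,1) = 1 and is column-symmetric", {
  m <- cbind(c(1, 3, 5, 9), c(1, 3, 5, 9))
  expect_equal(icc_a1(m)$icc, 1)
  m2 <- cbind(c(1, 3, 5, 7), c(2, 3, 6, 7))
  expect_equal(icc_a1(m2)$icc, icc_a1(m2[, 2:1])$icc)
})

test_that("ICC(A,1) matches the aov-based oracle on a worked matrix", {
  m <- matrix(c(1, 2, 3, 3, 5, 6, 7, 7), ncol = 2, byrow = TRUE)
  expect_equal(icc_a1(m)$icc, oracle_icc_a1(m), tolerance = 1e-10)
})

test_that("ICC(A,1) matches the aov oracle on 100 random matrices", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    k <- sample(2:4, 1)
    m <- matrix(stats::rnorm(n * k, sd = sample(1:3, 1)), n, k) +
      stats::rnorm(n) # subject effects
    expect_equal(icc_a1(m)$icc, oracle_icc_a1(m), tolerance = 1e-10)
  }
})

test_that("constant matrices yield a missing ICC with a warning", {
  expect_warning(res <- icc_a1(matrix(5, 4, 2)), "undefined")
  expect_true(is.na(res$icc))
  expect_error(icc_a1(matrix(1:4, 2, 2)), "n >= 3")
})

test_that("standardized alpha has its closed form on equicorrelated items", {
  dat <- make_exact_cor_data(40, equicorrelated(3, 0.5), seed = 3)
  a <- cronbach_alpha(dat)
  expect_equal(a$alpha_standardized, 0.75, tolerance = 1e-10)
})

test_that("duplicated items give alpha of 1", {
  x <- stats::rnorm(25)
  a <- cronbach_alpha(cbind(x, x, x))
  expect_equal(a$alpha_raw, 1)
  expect_equal(a$alpha_standardized, 1)
})

test_that("item-deleted alphas equal recomputation on each subset", {
  set.seed(8)
  m <- matrix(stats::rnorm(80), 20, 4) + stats::rnorm(20)
  colnames(m) <- paste0("i", 1:4)
  a <- cronbach_alpha(m)
  for (j in 1:4) {
    expect_equal(a$alpha_if_deleted[[paste0("i", j)]],
                 cronbach_alpha(m[, -j])$alpha_standardized)
  }
})

test_that("raw and standardized alpha coincide for equal-variance items", {
  set.seed(15)
  for (i in 1:5) {
    m <- matrix(stats::rnorm(200), 50, 4) + stats::rnorm(50)
    m <- scale(m) # unit variances
    a <- cronbach_alpha(m)
    expect_equal(a$alpha_raw, a$alpha_standardized, tolerance = 1e-10)
  }
})

test_that("zero-variance items are excluded from standardized alpha", {
  m <- cbind(a = stats::rnorm(20), b = stats::rnorm(20), c = rep(1, 20))
  expect_warning(res <- cronbach_alpha(m), "zero-variance")
  expect_false("c" %in% names(res$alpha_if_deleted))
})

test_that("omega has its closed form on the exact one-factor matrix", {
  R <- tcrossprod(rep(0.8, 3))
  diag(R) <- 1
  o <- mcdonald_omega(R)
  expect_equal(o$omega, 5.76 / 6.84, tolerance = 1e-6)
  expect_equal(o$loadings, rep(0.8, 3), tolerance = 1e-5)
})

test_that("omega equals standardized alpha under tau-equivalence", {
  dat <- make_exact_cor_data(200, equicorrelated(4, 0.49), seed = 6)
  a <- cronbach_alpha(dat)
  o <- mcdonald_omega(dat)
  expect_equal(o$omega, a$alpha_standardized, tolerance = 1e-6)
})

test_that("omega recovers the generating value at large n", {
  lambda <- c(0.9, 0.7, 0.5, 0.6)
  R <- tcrossprod(lambda)
  diag(R) <- 1
  truth <- sum(lambda)^2 / (sum(lambda)^2 + sum(1 - lambda^2))
  set.seed(42)
  dat <- MASS::mvrnorm(5000, rep(0, 4), R)
  o <- mcdonald_omega(dat)
  expect_lt(abs(o$omega - truth), 0.03)
})

test_that("Heywood cases are clipped at zero and flagged, omega stays in [0,1]", {
  # a dominant item forces its uniqueness against the boundary
  R <- matrix(c(1, 0.95, 0.9,
                0.95, 1, 0.8,
                0.9, 0.8, 1), 3, 3)
  o <- mcdonald_omega(R)
  expect_true(all(o$uniquenesses >= 0))
  expect_true(o$omega >= 0 && o$omega <= 1)
})

test_that("test-retest stage uses stable first-trial patients only", {
  co <- generate_cohort(cohort_config(seed = 23))
  pan <- score_cohort(co)
  stable <- make_stable_flag(co)
  ids <- stable$patient_id[which(stable$stable)]
  # all stable ids belong to the trial with a screening visit
  t1_ids <- unique(co$patient_id[co$trial == "T1_medalist_like"])
  expect_true(all(ids %in% t1_ids))
  icc <- test_retest_icc(pan, ids, scores = c("FAT", "GEN"))
  expect_true(all(icc$n <= length(ids)))
  expect_true(all(icc$icc > 0.4 & icc$icc < 1))
})

test_that("domain internal consistency runs per domain with if-deleted values", {
  co <- generate_cohort(cohort_config(seed = 17))
  ic <- domain_internal_consistency(co)
  expect_equal(ic$domain, c("FIS", "FUN", "SOC", "SEX", "FAT", "MDSS"))
  expect_true(all(ic$alpha_standardized > 0.5, na.rm = TRUE))
  fat <- ic$alpha_if_deleted[[which(ic$domain == "FAT")]]
  expect_length(fat, 7)
  # two-item domains have no omega (single-factor fit needs k >= 3)
  expect_true(is.na(ic$omega[ic$domain == "SOC"]))
  expect_false(is.na(ic$omega[ic$domain == "FAT"]))
})

test_that("corrected summaries exclude the domain in question", {
  set.seed(30)
  n <- 50
  doms <- matrix(stats::runif(n * 6, 0, 100), n, 6,
                 dimnames = list(NULL, c("FIS", "FUN", "SOC", "SEX", "FAT",
                                         "MDSS")))
  panel <- tibble::as_tibble(doms)
  panel$patient_id <- as.character(1:n)
  panel$trial <- "T1_medalist_like"
  panel$visit <- "baseline"
  panel$GEN <- rowMeans(doms[, c("FIS", "FUN", "SOC", "SEX", "FAT")])
  panel$ALL <- rowMeans(cbind(panel$GEN, doms[, "MDSS"]))
  panel$TOI <- rowMeans(doms[, c("FIS", "FUN", "MDSS")])
  out <- corrected_summary_correlations(panel)
  # pairs only where the domain is a constituent
  expect_false(any(out$domain == "SOC" & out$summary == "TOI"))
  expect_true(any(out$domain == "SEX" & out$summary == "GEN"))
  # GEN corrected for SEX is the mean of the other four domains
  corrected <- rowMeans(doms[, c("FIS", "FUN", "SOC", "FAT")])
  expected <- spearman(doms[, "SEX"], corrected)
  row <- out[out$domain == "SEX" & out$summary == "GEN", ]
  expect_equal(row$r, expected$r)
  # a domain identical in rank to its corrected summary correlates at 1
  panel2 <- panel
  panel2$FIS <- rowMeans(doms[, c("FUN", "SOC", "SEX", "FAT")])
  out2 <- corrected_summary_correlations(panel2)
  expect_equal(out2$r[out2$domain == "FIS" & out2$summary == "GEN"], 1)
})
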