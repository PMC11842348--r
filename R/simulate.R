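#' Configuration for the synthetic multi-trial cohort
#'
#' Defines the statistical structure of the generated cohort: four trials
#' (defaults 227/34/158/39 patients) assessed at baseline and Week 24, with
#' an additional screening visit 14-35 days before baseline in the first
#' (MEDALIST-like) trial only, and no QLQ-C30 in the fourth (RevMDS-like)
#' trial. Item responses follow a graded cumulative-threshold model: each
#' domain has a latent trait loading on a shared general factor, an
#' occasion-level disturbance calibrated so the test-retest reliability of
#' the observed domain score approximates `occasion_reliability`, and
#' item-level noise; thresholds are placed at the normal quantiles of the
#' target per-level response probabilities, which therefore fix the
#' baseline marginal distribution (domain means, floor and ceiling mass)
#' exactly. A Week 24 latent shift, shared across domains through a change
#' factor, drives both the score changes and the ordinal anchor readouts.
#'
#' @param per_trial_n Named integer vector of patients per trial.
#' @param occasion_reliability Named numeric vector (per domain) of target
#'   test-retest ICCs; defaults near the published values.
#' @param general_loading Loading of each domain trait on the shared
#'   general factor (default 0.6).
#' @param sex_loading Loading of the sexual well-being trait on the general
#'   factor (default 0.2; this domain tracks the others weakly).
#' @param item_noise_var Item-specific latent noise variance (default 0.15).
#' @param level_probs Per-domain target response-level probabilities
#'   (oriented worst to best), keyed by number of levels.
#' @param change_sd SD of the Week 24 latent shift, in between-subject SD
#'   units (default 1.1).
#' @param change_loading Loading of each domain's shift on the shared
#'   change factor (default 0.9; the sexual domain uses
#'   `sex_change_loading`, default 0.15, so its responsiveness is weak).
#' @param sex_change_loading See `change_loading`.
#' @param trial_drift Named vector of mean latent drift per trial at
#'   Week 24.
#' @param anchor_model List of anchor readout parameters: `q1_change`
#'   /`q1_noise` (overall-health item), `q2_change`/`q2_noise`,
#'   `item29_change`/`item29_noise`, `item30_change`/`item30_noise`,
#'   `hb_change`/`hb_noise` (g/dL), `rbc_rate` (baseline mean extra units
#'   for dependent patients) and `rbc_change` (log-rate response).
#' @param clinical_model List: `hb_mean`, `hb_sd`, `hb_health_loading`,
#'   `p_transfusion_dep`, `platelet_meanlog`, `platelet_sdlog`.
#' @param missingness List of missing-data probabilities: `item`,
#'   `sex_item`, `qlq_visit`, `hb`, `rbc`, `platelet`.
#' @param seed Integer root seed; all randomness flows from it through
#'   named substreams.
#' @return A `qole_cohort_config` list.
#' @export
cohort_config <- function(per_trial_n = c(T1_medalist_like = 227L,
                                          T2_darb_like = 34L,
                                          T3_eqol_like = 158L,
                                          T4_rev_like = 39L),
                          occasion_reliability = c(FIS = 0.66, FUN = 0.57,
                                                   SOC = 0.77, SEX = 0.81,
                                                   FAT = 0.72, MDSS = 0.71),
                          general_loading = 0.6,
                          sex_loading = 0.2,
                          item_noise_var = 0.15,
                          level_probs = default_level_probs(),
                          change_sd = 1.1,
                          change_loading = 0.9,
                          sex_change_loading = 0.15,
                          trial_drift = c(T1_medalist_like = 0.00,
                                          T2_darb_like = 0.15,
                                          T3_eqol_like = 0.05,
                                          T4_rev_like = 0.10),
                          anchor_model = list(q1_change = 1.4, q1_noise = 0.7,
                                              q2_change = 0.55, q2_noise = 1.1,
                                              item29_change = 1.3,
                                              item29_noise = 0.7,
                                              item30_change = 0.8,
                                              item30_noise = 0.9,
                                              hb_change = 0.3, hb_noise = 1.0,
                                              rbc_rate = 1.8,
                                              rbc_change = 0.25),
                          clinical_model = list(hb_mean = 9.5, hb_sd = 1.9,
                                                hb_health_loading = 0.25,
                                                p_transfusion_dep = 0.683,
                                                platelet_meanlog = 4.808,
                                                platelet_sdlog = 1.012),
                          missingness = list(item = 0.02, sex_item = 0.12,
                                             qlq_visit = 0.06, hb = 0.118,
                                             rbc = 0.03, platelet = 0.12),
                          seed = 1L) {
  if (any(per_trial_n < 0)) stop("per_trial_n must be >= 0", call. = FALSE)
  if (sum(per_trial_n) <= 0) stop("at least one trial must have n > 0",
                                  call. = FALSE)
  if (any(occasion_reliability < 0 | occasion_reliability > 1)) {
    stop("occasion_reliability must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  structure(
    list(per_trial_n = per_trial_n,
         occasion_reliability = occasion_reliability,
         general_loading = general_loading, sex_loading = sex_loading,
         item_noise_var = item_noise_var, level_probs = level_probs,
         change_sd = change_sd, change_loading = change_loading,
         sex_change_loading = sex_change_loading, trial_drift = trial_drift,
         anchor_model = anchor_model, clinical_model = clinical_model,
         missingness = missingness, seed = as.integer(seed)),
    class = "qole_cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_level_probs <- function() {
  list(
    FIS = list(`5` = c(0.09, 0.18, 0.27, 0.30, 0.16)),
    FUN = list(`4` = c(0.09, 0.24, 0.30, 0.37)),
    SOC = list(`3` = c(0.32, 0.41, 0.27)),
    SEX = list(`5` = c(0.10, 0.12, 0.15, 0.18, 0.45)),
    FAT = list(`4` = c(0.05, 0.15, 0.33, 0.47)),
    MDSS = list(`5` = c(0.07, 0.13, 0.22, 0.29, 0.29),
                `6` = c(0.05, 0.09, 0.15, 0.21, 0.27, 0.23))
  )
}

# Seed a named substream derived from the root seed, so item, anchor,
# clinical and missingness draws are independently reproducible.
substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  set.seed(as.integer((abs(as.numeric(seed)) * 2654435 + h * 97) %% 2147483629))
}

# Attenuation of an ordinal cut of a standard normal variable: squared
# correlation between the category index and the underlying variable,
# expressed as a noise-to-signal variance ratio (1 - lambda^2) / lambda^2.
categorization_noise <- function(probs) {
  cum <- cumsum(probs)[-length(probs)]
  z <- stats::qnorm(cum)
  g <- seq_along(probs) - 1
  m <- sum(g * probs)
  v <- sum(g^2 * probs) - m^2
  lambda <- sum(stats::dnorm(z)) / sqrt(v)
  (1 - lambda^2) / lambda^2
}

#' Generate a synthetic cohort
#'
#' Draws a full multi-trial cohort under a [cohort_config()]: item
#' responses, the two general-well-being items, QLQ-C30 scale scores and
#' Items 29/30, and clinical outcomes, at baseline and Week 24 for every
#' patient plus a screening visit for the first trial. Output is the wide
#' cohort tibble consumed by [score_cohort()] and [anchor_changes()]. The
#' same config and seed give identical output.
#'
#' @param config A [cohort_config()].
#' @param schema A [qole_schema()]; item ids, ranges and reversal flags
#'   drive the response generation.
#' @return Wide cohort tibble, one row per patient-visit.
#' @export
generate_cohort <- function(config = cohort_config(),
                            schema = default_schema()) {
  stopifnot(inherits(config, "qole_cohort_config"))
  trials <- names(config$per_trial_n)
  n_per <- config$per_trial_n
  n <- sum(n_per)
  trial <- rep(trials, n_per)
  patient_id <- sprintf("P%04d", seq_len(n))
  seed <- config$seed

  # --- latent structure -----------------------------------------------
  substream(seed, "latent")
  G <- stats::rnorm(n)
  C <- stats::rnorm(n) # shared change factor
  doms <- qole_domains()
  load <- stats::setNames(rep(config$general_loading, 6), doms)
  load["SEX"] <- config$sex_loading
  U <- matrix(stats::rnorm(n * 6), n, 6, dimnames = list(NULL, doms))
  xi <- matrix(stats::rnorm(n * 6), n, 6, dimnames = list(NULL, doms))
  theta <- sapply(doms, function(d) load[d] * G + sqrt(1 - load[d]^2) * U[, d])

  shift <- config$change_sd * C + unname(config$trial_drift[trial])
  w <- stats::setNames(rep(config$change_loading, 6), doms)
  w["SEX"] <- config$sex_change_loading
  delta <- sapply(doms, function(d) {
    rho <- config$occasion_reliability[[d]]
    sqrt(rho) * (w[d] * shift +
                   config$change_sd * sqrt(1 - w[d]^2) * xi[, d])
  })

  # --- per-domain variance budget -------------------------------------
  items <- schema$items
  scored <- items[items$domain != "GENERAL", ]
  dom_info <- lapply(doms, function(d) {
    it <- scored[scored$domain == d, ]
    nlev <- it$raw_max - it$raw_min + 1
    probs <- lapply(nlev, function(L) config$level_probs[[d]][[as.character(L)]])
    if (any(vapply(probs, is.null, logical(1)))) {
      stop("no level probabilities configured for a ", d, " item", call. = FALSE)
    }
    v_cat <- mean(vapply(probs, categorization_noise, numeric(1)))
    rho <- config$occasion_reliability[[d]]
    k <- nrow(it)
    eps2 <- if (rho >= 1) 0 else config$item_noise_var
    occ2 <- if (rho >= 1) 0 else {
      max(0.01, 1 - rho - (eps2 + v_cat) / k)
    }
    total <- rho + occ2 + eps2
    thresholds <- lapply(probs, function(p) {
      stats::qnorm(cumsum(p)[-length(p)]) * sqrt(total)
    })
    list(items = it, k = k, rho = rho, occ2 = occ2, eps2 = eps2,
         thresholds = thresholds)
  })
  names(dom_info) <- doms

  # --- visit frame -----------------------------------------------------
  has_screening <- trial == "T1_medalist_like"
  visit_rows <- rbind(
    data.frame(pat = which(has_screening), visit = "screening"),
    data.frame(pat = seq_len(n), visit = "baseline"),
    data.frame(pat = seq_len(n), visit = "week24")
  )
  m <- nrow(visit_rows)
  is_wk <- visit_rows$visit == "week24"
  pat <- visit_rows$pat

  # --- item responses --------------------------------------------------
  substream(seed, "items")
  occ <- matrix(stats::rnorm(m * 6), m, 6, dimnames = list(NULL, doms))
  resp <- matrix(NA_integer_, m, nrow(scored),
                 dimnames = list(NULL, scored$item_id))
  for (d in doms) {
    info <- dom_info[[d]]
    base_latent <- sqrt(info$rho) * theta[pat, d] + delta[pat, d] * is_wk +
      sqrt(info$occ2) * occ[, d]
    for (j in seq_len(info$k)) {
      it <- info$items[j, ]
      y <- base_latent + sqrt(info$eps2) * stats::rnorm(m)
      level <- findInterval(y, info$thresholds[[j]]) # 0 = worst
      raw <- if (it$reversed) it$raw_max - level else it$raw_min + level
      resp[, it$item_id] <- as.integer(raw)
    }
  }

  # --- general well-being items and QLQ-C30 anchors --------------------
  substream(seed, "anchors")
  am <- config$anchor_model
  q1_probs <- c(poor = 0.195, acceptable = 0.494, good = 0.294,
                excellent = 0.017) # worst-first on the welfare scale
  q1_scale <- sqrt(1 + am$q1_noise^2)
  q1_tau <- stats::qnorm(cumsum(q1_probs)[-4]) * q1_scale
  q1_latent <- G[pat] + am$q1_change * shift[pat] * is_wk +
    am$q1_noise * stats::rnorm(m)
  q1 <- 3L - findInterval(q1_latent, q1_tau) # 0 = excellent ... 3 = poor

  # change-direct item: 7 levels centred on "unchanged" (stored 0..6)
  q2_probs <- c(0.02, 0.08, 0.20, 0.40, 0.20, 0.08, 0.02)
  q2_scale <- sqrt(am$q2_change^2 + am$q2_noise^2)
  q2_tau <- stats::qnorm(cumsum(q2_probs)[-7]) * q2_scale
  q2_latent <- am$q2_change * shift[pat] * is_wk + am$q2_noise * stats::rnorm(m)
  q2 <- findInterval(q2_latent, q2_tau)

  c30_probs <- c(0.02, 0.06, 0.15, 0.27, 0.27, 0.16, 0.07)
  gen_item <- function(change_load, noise) {
    sc <- sqrt(1 + noise^2)
    tau <- stats::qnorm(cumsum(c30_probs)[-7]) * sc
    lat <- G[pat] + change_load * shift[pat] * is_wk + noise * stats::rnorm(m)
    1L + findInterval(lat, tau) # raw 1..7, higher = better
  }
  qlq_item29 <- gen_item(am$item29_change, am$item29_noise)
  qlq_item30 <- gen_item(am$item30_change, am$item30_noise)

  qlq_scales <- c("qlq_global", "qlq_physical", "qlq_role", "qlq_emotional",
                  "qlq_cognitive", "qlq_social", "qlq_fatigue", "qlq_nausea",
                  "qlq_pain", "qlq_dyspnea", "qlq_insomnia", "qlq_appetite",
                  "qlq_constipation", "qlq_diarrhea", "qlq_financial")
  symptom <- c("qlq_fatigue", "qlq_nausea", "qlq_pain", "qlq_dyspnea",
               "qlq_insomnia", "qlq_appetite", "qlq_constipation",
               "qlq_diarrhea", "qlq_financial")
  H <- G[pat] + 0.8 * shift[pat] * is_wk
  qlq <- sapply(qlq_scales, function(sc) {
    if (sc %in% symptom) {
      pmin(100, pmax(0, 35 - 16 * H + stats::rnorm(m, sd = 14)))
    } else {
      pmin(100, pmax(0, 55 + 16 * H + stats::rnorm(m, sd = 14)))
    }
  })

  # --- clinical outcomes ----------------------------------------------
  substream(seed, "clinical")
  cm <- config$clinical_model
  hb_base_pat <- cm$hb_mean + cm$hb_sd *
    (cm$hb_health_loading * G +
       sqrt(1 - cm$hb_health_loading^2) * stats::rnorm(n))
  hb <- hb_base_pat[pat] +
    (am$hb_change * shift[pat] + am$hb_noise * stats::rnorm(m)) * is_wk
  dep <- stats::rbinom(n, 1, cm$p_transfusion_dep)
  rbc_base_pat <- dep * (1L + stats::rpois(n, am$rbc_rate))
  rbc <- integer(m)
  rbc[!is_wk] <- rbc_base_pat[pat[!is_wk]]
  lam <- (1 + am$rbc_rate) * exp(-am$rbc_change * shift[pat[is_wk]])
  rbc[is_wk] <- dep[pat[is_wk]] * stats::rpois(sum(is_wk), lam)
  plt_base_pat <- stats::rlnorm(n, cm$platelet_meanlog, cm$platelet_sdlog)
  plt <- plt_base_pat[pat] * exp(stats::rnorm(m, sd = 0.2) * is_wk)
  plt_units <- stats::rpois(m, ifelse(plt < 50, 1.0, 0.05))

  # --- assemble and impose missingness --------------------------------
  cohort <- tibble::as_tibble(cbind(
    tibble::tibble(patient_id = patient_id[pat], trial = trial[pat],
                   visit = visit_rows$visit),
    tibble::tibble(q1 = q1, q2 = q2),
    tibble::as_tibble(resp),
    tibble::as_tibble(qlq),
    tibble::tibble(qlq_item29 = qlq_item29, qlq_item30 = qlq_item30,
                   hb_g_dl = hb, rbc_units_8wk = rbc,
                   platelet_count_e9_l = plt, platelet_units_8wk = plt_units)
  ))

  substream(seed, "missingness")
  ms <- config$missingness
  for (id in scored$item_id) {
    p <- if (scored$domain[match(id, scored$item_id)] == "SEX") {
      ms$sex_item
    } else {
      ms$item
    }
    drop <- stats::runif(m) < p
    cohort[[id]][drop] <- NA_integer_
  }
  qlq_cols <- c(qlq_scales, "qlq_item29", "qlq_item30")
  qlq_missing <- stats::runif(m) < ms$qlq_visit
  qlq_missing <- qlq_missing | cohort$trial == "T4_rev_like"
  for (col in qlq_cols) cohort[[col]][qlq_missing] <- NA
  cohort$hb_g_dl[stats::runif(m) < ms$hb] <- NA_real_
  cohort$rbc_units_8wk[stats::runif(m) < ms$rbc] <- NA_integer_
  cohort$platelet_count_e9_l[stats::runif(m) < ms$platelet] <- NA_real_

  ord <- order(match(cohort$patient_id, patient_id),
               match(cohort$visit, c("screening", "baseline", "week24")))
  cohort[ord, ]
}

#' Flag stable patients for test-retest analysis
#'
#' A patient is "stable" when the overall-health item (Item 1) response is
#' identical at the screening and baseline visits. Patients lacking either
#' visit, or the item at either visit, get a missing flag; in the default
#' design only the first trial has a screening visit.
#'
#' @param cohort Wide cohort tibble with `q1` responses.
#' @return Tibble with `patient_id` and logical `stable`.
#' @export
make_stable_flag <- function(cohort) {
  scr <- cohort[cohort$visit == "screening", c("patient_id", "q1")]
  bas <- cohort[cohort$visit == "baseline", c("patient_id", "q1")]
  ids <- unique(cohort$patient_id)
  s <- scr$q1[match(ids, scr$patient_id)]
  b <- bas$q1[match(ids, bas$patient_id)]
  tibble::tibble(patient_id = ids, stable = s == b)
}
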