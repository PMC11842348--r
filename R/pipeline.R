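#' End-to-end MWPC analysis
#'
#' Runs the full responder-threshold workflow on a scored cohort:
#' change scores, anchor change variables, responsiveness correlations,
#' anchor selection (absolute correlation above 0.3 on every score except
#' the sexual well-being domain), pooled >= 1-level improvement / worsening
#' anchor estimates with eCDF-separation checks against the no-change
#' group, distribution-based estimates (SEM from the screening-baseline
#' ICC and half the baseline SD, both on the first trial's patients, the
#' only trial with a retest design), and triangulation into integer
#' thresholds. The sexual well-being domain is excluded from triangulation.
#'
#' @param panel Score panel from [score_cohort()] (after
#'   [filter_analysis_population()]).
#' @param cohort Wide cohort tibble.
#' @param schema A [qole_schema()].
#' @param anchors Anchor set to use; `NULL` (default) selects eligible
#'   anchors by the correlation rule, falling back with a warning to the
#'   overall-health item if none qualify.
#' @param min_group_n Anchor groups of at most this size are collapsed.
#' @return List with `responsiveness` (correlation table), `anchors`
#'   (selected names), `groups` (per score x anchor collapsed group
#'   tables), `ecdf` (per score/side separation results), `stats`
#'   (SEM/half-SD/mpc per score), and `thresholds` (the
#'   [triangulate_mwpc()] output).
#' @export
mwpc_analysis <- function(panel, cohort, schema = default_schema(),
                          anchors = NULL, min_group_n = 10) {
  changes <- change_from_baseline(panel)
  anch <- anchor_changes(cohort)
  corr <- responsiveness_correlations(changes, anch$change)
  if (is.null(anchors)) {
    anchors <- select_anchors(corr)
    if (length(anchors) == 0) {
      warning("no anchor met the correlation rule; using the overall-health item")
      anchors <- "item1"
    }
  }
  scores <- setdiff(qole_scores(), "SEX")

  # distribution-based estimates on the retest-design trial
  t1 <- panel[panel$trial == "T1_medalist_like", , drop = FALSE]
  stable <- make_stable_flag(cohort)
  stable_ids <- stable$patient_id[which(stable$stable)]
  icc_tbl <- test_retest_icc(t1, stable_ids, scores = scores)
  base_t1 <- t1[t1$visit == "baseline", , drop = FALSE]
  mpc <- minimum_possible_change(schema)
  step <- summary_min_step(schema)
  stats <- dplyr::bind_rows(lapply(scores, function(s) {
    sdb <- stats::sd(base_t1[[s]], na.rm = TRUE)
    icc <- icc_tbl$icc[icc_tbl$score == s]
    icc <- if (length(icc) == 0 || is.na(icc)) NA_real_ else min(max(icc, 0), 1)
    tibble::tibble(
      score = s,
      sem = if (is.na(icc)) NA_real_ else sem_points(sdb, icc),
      half_sd = half_sd(sdb),
      mpc = if (s %in% qole_domains()) mpc[[s]] else NA_real_
    )
  }))

  # pooled >= 1-level anchor estimates, group tables, eCDF checks
  joined <- dplyr::inner_join(changes, anch$category,
                              by = c("patient_id", "trial"),
                              suffix = c("", "_cat"))
  est_rows <- list()
  groups <- list()
  ecdf_rows <- list()
  for (a in anchors) {
    cat_col <- joined[[a]]
    dat <- if (grepl("^qlq_", a)) drop_no_qlq_trial(joined) else joined
    cat_a <- dat[[a]]
    for (s in scores) {
      ch <- dat[[s]]
      ok <- !is.na(ch) & !is.na(cat_a)
      if (sum(ok) == 0) next
      groups[[paste(s, a, sep = ".")]] <-
        build_anchor_groups(ch[ok], cat_a[ok], min_n = min_group_n)
      none <- ch[ok & cat_a == 0]
      mpc_eff <- if (s %in% qole_domains()) mpc[[s]] else step[[s]]
      for (side in c("improvement", "worsening")) {
        sel <- if (side == "improvement") cat_a >= 1 else cat_a <= -1
        grp <- ch[ok & sel]
        if (length(grp) == 0) next
        est_rows[[length(est_rows) + 1]] <- tibble::tibble(
          score = s, anchor = a, side = side, n = length(grp),
          mean_change = mean(grp), median_change = stats::median(grp)
        )
        sep <- ecdf_separation(grp, none, side = side, mpc = mpc_eff)
        ecdf_rows[[length(ecdf_rows) + 1]] <- tibble::tibble(
          score = s, anchor = a, side = side,
          separated = sep$separated,
          dominance_fraction = sep$dominance_fraction,
          median_difference = sep$median_difference
        )
      }
    }
  }
  est <- dplyr::bind_rows(est_rows)
  ecdf_tbl <- dplyr::bind_rows(ecdf_rows)

  # a side is eligible when every anchor's curves separate consistently
  elig <- ecdf_tbl |>
    dplyr::group_by(.data$score, .data$side) |>
    dplyr::summarise(eligible = all(.data$separated %in% TRUE),
                     .groups = "drop")

  inputs <- triangulation_inputs(stats = stats, anchors = est,
                                 eligibility = elig,
                                 primary_anchor = anchors[1])
  thresholds <- triangulate_mwpc(inputs)
  list(responsiveness = corr, anchors = anchors, groups = groups,
       ecdf = ecdf_tbl, stats = stats, thresholds = thresholds)
}

# Smallest achievable step of a summary score, from the recursive mean
# structure (a one-raw-point move on the finest constituent item).
summary_min_step <- function(schema) {
  mpc <- minimum_possible_change(schema, digits = NA)
  comp <- schema$summary_composition
  step <- as.list(mpc)
  for (s in names(comp)) {
    parts <- comp[[s]]
    vals <- vapply(parts, function(p) step[[p]], numeric(1))
    step[[s]] <- min(vals) / length(parts)
  }
  unlist(step[names(comp)])
}

#' Configure a pipeline run
#'
#' @param out_dir Output directory (created if needed).
#' @param stages Stages to run, in order, among `score`, `distrib`,
#'   `validity`, `reliability`, `mwpc`.
#' @param cohort Wide cohort tibble, or `NULL` to simulate one from
#'   `sim_config`.
#' @param cohort_path Path to a cohort CSV (alternative to `cohort`).
#' @param sim_config A [cohort_config()] used when no cohort is supplied.
#' @param schema A [qole_schema()].
#' @param seed Root seed; overrides `sim_config$seed` when given.
#' @return A `qole_run_config` list.
#' @export
run_config <- function(out_dir,
                       stages = c("score", "distrib", "validity",
                                  "reliability", "mwpc"),
                       cohort = NULL, cohort_path = NULL,
                       sim_config = NULL, schema = default_schema(),
                       seed = NULL) {
  known <- c("score", "distrib", "validity", "reliability", "mwpc")
  if (length(stages) == 0) stop("stage list must be non-empty", call. = FALSE)
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  structure(list(out_dir = out_dir, stages = stages, cohort = cohort,
                 cohort_path = cohort_path, sim_config = sim_config,
                 schema = schema, seed = seed),
            class = "qole_run_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order on a supplied,
#' loaded, or freshly simulated cohort, writing one or more CSV outputs per
#' stage plus a JSON sidecar recording the stage, its inputs, the seed and
#' the parameters. Reruns with an identical configuration and seed produce
#' byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @return The run manifest: tibble with `stage`, `output`, `sidecar`,
#'   `elapsed_s`; warnings raised by stages are accumulated in the
#'   `warnings` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qole_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  schema <- config$schema
  warnings_log <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  cohort <- config$cohort
  cohort_source <- "supplied"
  if (is.null(cohort) && !is.null(config$cohort_path)) {
    if (!file.exists(config$cohort_path)) {
      stop("stage 'score': missing input cohort file ", config$cohort_path,
           call. = FALSE)
    }
    cohort <- read_cohort(config$cohort_path, schema)
    cohort_source <- config$cohort_path
  }
  if (is.null(cohort)) {
    if (is.null(config$sim_config)) {
      stop("stage 'score': no input cohort (supply `cohort`, `cohort_path` or `sim_config`)",
           call. = FALSE)
    }
    sim <- config$sim_config
    if (!is.null(config$seed)) sim$seed <- as.integer(config$seed)
    cohort <- generate_cohort(sim, schema)
    cohort_source <- "simulated"
  }
  seed <- if (!is.null(config$seed)) config$seed else
    if (!is.null(config$sim_config)) config$sim_config$seed else NA

  manifest <- list()
  emit <- function(stage, name, df, params = list()) {
    out <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, out, row.names = FALSE, na = "")
    sidecar <- file.path(config$out_dir, paste0(name, ".json"))
    jsonlite::write_json(
      list(stage = stage, output = basename(out), cohort = cohort_source,
           seed = seed, params = params),
      sidecar, auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, output = out, sidecar = sidecar, elapsed_s = NA_real_
    )
  }

  panel <- NULL
  for (stage in c("score", setdiff(config$stages, "score"))) {
    if (!stage %in% c("score", config$stages)) next
    if (stage != "score" && !stage %in% config$stages) next
    t0 <- proc.time()[["elapsed"]]
    switch(stage,
      score = {
        panel <- collect(filter_analysis_population(score_cohort(cohort, schema)))
        if ("score" %in% config$stages) {
          emit("score", "scores", panel,
               params = list(min_answered_fraction = schema$min_answered_fraction))
        }
      },
      distrib = {
        emit("distrib", "distribution",
             distribution_report(collect(summarize_distribution(panel))))
      },
      validity = {
        cv <- collect(convergent_validity(panel, cohort))
        grid <- default_hypothesis_grid(cohort)
        cv <- collect(evaluate_hypothesis_grid(cv, grid))
        emit("validity", "validity_correlations", cv)
        kg1 <- collect(known_groups(panel, cohort, "item1_response"))
        kg2 <- collect(known_groups(panel, cohort, "transfusion_dependency"))
        kg <- dplyr::bind_rows(
          dplyr::mutate(kg1$summary, grouping = "item1_response"),
          dplyr::mutate(kg2$summary, grouping = "transfusion_dependency")
        )
        emit("validity", "known_groups", kg)
      },
      reliability = {
        stable <- make_stable_flag(cohort)
        icc <- collect(test_retest_icc(
          panel[panel$trial == "T1_medalist_like", ],
          stable$patient_id[which(stable$stable)]
        ))
        emit("reliability", "test_retest_icc", icc)
        ic <- collect(domain_internal_consistency(cohort, schema))
        emit("reliability", "internal_consistency",
             ic[setdiff(names(ic), "alpha_if_deleted")])
        emit("reliability", "corrected_summary_correlations",
             collect(corrected_summary_correlations(panel, schema)))
      },
      mwpc = {
        res <- collect(mwpc_analysis(panel, cohort, schema))
        emit("mwpc", "responsiveness", res$responsiveness,
             params = list(anchors = res$anchors))
        emit("mwpc", "mwpc_thresholds", res$thresholds,
             params = list(anchors = res$anchors))
      }
    )
    el <- proc.time()[["elapsed"]] - t0
    for (i in seq_along(manifest)) {
      if (manifest[[i]]$stage == stage && is.na(manifest[[i]]$elapsed_s)) {
        manifest[[i]]$elapsed_s <- el
      }
    }
  }
  out <- dplyr::bind_rows(manifest)
  out <- out[out$stage %in% config$stages, , drop = FALSE]
  attr(out, "warnings") <- warnings_log
  out
}
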