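#' Intraclass correlation ICC(A,1) from a two-way mixed ANOVA
#'
#' Absolute-agreement, single-measurement intraclass correlation (McGraw &
#' Wong ICC(A,1)) for an n-subjects by k-occasions matrix of scores,
#' computed from the two-way mean squares:
#' \deqn{ICC(A,1) = \frac{MS_r - MS_e}{MS_r + (k-1) MS_e + \frac{k}{n}(MS_c - MS_e)}}
#' where \eqn{MS_r}, \eqn{MS_c} and \eqn{MS_e} are the between-subjects,
#' between-occasions and residual mean squares. Used for test-retest
#' reliability of domain scores between a screening and a baseline visit on
#' the stable subset of patients.
#'
#' @param mat Numeric matrix, n subjects (rows) x k occasions (columns),
#'   n >= 3, k >= 2, no missing cells.
#' @return List with `icc` (NA with a warning for a constant matrix) and
#'   `anova`, the decomposition (`n_subjects`, `k_occasions`, `MS_rows`,
#'   `MS_cols`, `MS_error`).
#' @export
icc_a1 <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("icc_a1 requires a listwise-complete matrix", call. = FALSE)
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 3 || k < 2) stop("icc_a1 needs n >= 3 subjects and k >= 2 occasions",
                           call. = FALSE)
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  decomp <- list(n_subjects = n, k_occasions = k,
                 MS_rows = ms_rows, MS_cols = ms_cols, MS_error = ms_err)
  denom <- ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err)
  if (isTRUE(all.equal(denom, 0)) || ss_tot == 0) {
    warning("zero total variance; ICC(A,1) undefined")
    return(list(icc = NA_real_, anova = decomp))
  }
  list(icc = (ms_rows - ms_err) / denom, anova = decomp)
}

#' Test-retest reliability of domain and summary scores
#'
#' Builds, for each QOL-E score, the two-occasion matrix of screening and
#' baseline values over the supplied stable patients and computes ICC(A,1).
#' Patients are used listwise per score (both occasions non-missing).
#'
#' @param panel Score panel containing `screening` and `baseline` rows.
#' @param stable_ids Patient ids of the stable subset (same overall-health
#'   response at both occasions); see [make_stable_flag()].
#' @param scores Score columns to evaluate (default all nine).
#' @return Tibble with `score`, `n` (complete pairs) and `icc`.
#' @export
test_retest_icc <- function(panel, stable_ids, scores = qole_scores()) {
  scr <- panel[panel$visit == "screening" & panel$patient_id %in% stable_ids, ]
  bas <- panel[panel$visit == "baseline" & panel$patient_id %in% stable_ids, ]
  ids <- intersect(scr$patient_id, bas$patient_id)
  scr <- scr[match(ids, scr$patient_id), ]
  bas <- bas[match(ids, bas$patient_id), ]
  rows <- lapply(scores, function(s) {
    m <- cbind(scr[[s]], bas[[s]])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    icc <- if (nrow(m) >= 3) icc_a1(m)$icc else NA_real_
    tibble::tibble(score = s, n = nrow(m), icc = icc)
  })
  dplyr::bind_rows(rows)
}

#' Cronbach alpha for an item matrix
#'
#' Raw alpha `(k/(k-1)) * (1 - sum(item variances) / variance of the total)`
#' and standardized alpha `k * rbar / (1 + (k-1) * rbar)` with `rbar` the
#' mean pairwise Pearson correlation, plus the standardized alpha obtained
#' after deleting each item in turn. Rows with any missing item are dropped
#' (listwise deletion); items with zero variance are excluded from the
#' standardized coefficients with a warning.
#'
#' @param items Numeric matrix or data frame, n observations x k >= 2 items.
#' @return List with `n` (complete rows used), `alpha_raw`,
#'   `alpha_standardized`, and `alpha_if_deleted` (named vector).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2) stop("cronbach_alpha needs at least 2 items", call. = FALSE)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  n <- nrow(items)
  k <- ncol(items)
  v <- apply(items, 2, stats::var)
  alpha_raw <- if (stats::var(rowSums(items)) > 0) {
    (k / (k - 1)) * (1 - sum(v) / stats::var(rowSums(items)))
  } else {
    NA_real_
  }
  keep <- v > 0
  if (!all(keep)) {
    warning("excluding zero-variance item(s) from standardized alpha: ",
            paste(colnames(items)[!keep], collapse = ", "))
  }
  std_alpha <- function(m) {
    kk <- ncol(m)
    if (kk < 2) return(NA_real_)
    r <- stats::cor(m)
    rbar <- mean(r[lower.tri(r)])
    kk * rbar / (1 + (kk - 1) * rbar)
  }
  sub <- items[, keep, drop = FALSE]
  alpha_std <- std_alpha(sub)
  deleted <- vapply(seq_len(ncol(sub)), function(j) {
    std_alpha(sub[, -j, drop = FALSE])
  }, numeric(1))
  names(deleted) <- colnames(sub)
  list(n = n, alpha_raw = alpha_raw, alpha_standardized = alpha_std,
       alpha_if_deleted = deleted)
}

# Single-factor minimum-residual fit: minimizes the sum of squared
# off-diagonal residuals of R - lambda lambda'. Returns loadings,
# uniquenesses (Heywood cases clipped at 0 and flagged), and convergence.
minres_one_factor <- function(R, tol = 1e-8, maxit = 500) {
  k <- ncol(R)
  e <- eigen(R, symmetric = TRUE)
  lambda <- e$vectors[, 1] * sqrt(max(e$values[1], .Machine$double.eps))
  if (sum(lambda) < 0) lambda <- -lambda
  obj <- function(l) {
    resid <- R - tcrossprod(l)
    sum(resid[lower.tri(resid)]^2)
  }
  gr <- function(l) {
    resid <- R - tcrossprod(l)
    diag(resid) <- 0
    -2 * as.vector(resid %*% l)
  }
  fit <- stats::optim(lambda, obj, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = tol))
  lambda <- fit$par
  if (sum(lambda) < 0) lambda <- -lambda
  psi <- 1 - lambda^2
  heywood <- psi < 0
  psi[heywood] <- 0
  list(loadings = lambda, uniquenesses = psi,
       heywood = any(heywood), converged = fit$convergence == 0,
       objective = fit$value)
}

#' McDonald omega from a single-factor model
#'
#' Fits a one-factor model to the item correlation matrix by the
#' minimum-residual criterion (objective tolerance 1e-8, at most 500
#' iterations) and returns
#' \deqn{\omega = \frac{(\sum_i \lambda_i)^2}{(\sum_i \lambda_i)^2 + \sum_i \psi_i}}
#' where \eqn{\lambda_i} are the standardized loadings and \eqn{\psi_i} the
#' uniquenesses. Unlike Cronbach alpha this does not assume tau-equivalence.
#' Heywood cases (negative uniqueness) are clipped at 0 and flagged.
#'
#' @param items Numeric matrix/data frame of n observations x k >= 3 items,
#'   or a k x k correlation matrix (detected as square symmetric with unit
#'   diagonal).
#' @return List with `omega`, `loadings`, `uniquenesses`, `heywood`,
#'   `converged`, and `n` (rows used; `NA` when a correlation matrix is
#'   supplied). On non-convergence `omega` is `NA` with a warning.
#' @export
mcdonald_omega <- function(items) {
  items <- as.matrix(items)
  is_cor <- nrow(items) == ncol(items) &&
    isTRUE(all.equal(unname(diag(items)), rep(1, ncol(items)))) &&
    isTRUE(all.equal(items, t(items)))
  if (is_cor) {
    R <- items
    n <- NA_integer_
  } else {
    items <- items[stats::complete.cases(items), , drop = FALSE]
    n <- nrow(items)
    R <- stats::cor(items)
  }
  if (ncol(R) < 3) stop("mcdonald_omega needs at least 3 items", call. = FALSE)
  fit <- minres_one_factor(R)
  if (!fit$converged) {
    warning("single-factor fit did not converge; omega is NA")
    return(list(omega = NA_real_, loadings = fit$loadings,
                uniquenesses = fit$uniquenesses, heywood = fit$heywood,
                converged = FALSE, n = n))
  }
  sl <- sum(fit$loadings)
  omega <- sl^2 / (sl^2 + sum(fit$uniquenesses))
  list(omega = omega, loadings = fit$loadings,
       uniquenesses = fit$uniquenesses, heywood = fit$heywood,
       converged = TRUE, n = n)
}

#' Internal consistency of every domain
#'
#' Runs [cronbach_alpha()] and [mcdonald_omega()] on the oriented item
#' responses of each scored domain at a given visit. Items are oriented so
#' that higher = better before analysis, which changes no coefficient but
#' keeps loadings positive for well-behaved domains.
#'
#' @param cohort Wide cohort tibble.
#' @param schema A [qole_schema()].
#' @param visit Visit to analyse (default `"baseline"`).
#' @return Tibble with `domain`, `n_items`, `n`, `alpha_raw`,
#'   `alpha_standardized`, `omega`, and a list-column `alpha_if_deleted`.
#' @export
domain_internal_consistency <- function(cohort, schema = default_schema(),
                                        visit = "baseline") {
  sub <- cohort[cohort$visit == visit, , drop = FALSE]
  items <- schema$items
  rows <- lapply(qole_domains(), function(d) {
    ids <- items$item_id[items$domain == d]
    mat <- as.matrix(sub[, ids, drop = FALSE])
    for (j in seq_along(ids)) {
      row <- items[items$item_id == ids[j], ]
      if (row$reversed) mat[, j] <- row$raw_max - mat[, j]
    }
    a <- cronbach_alpha(mat)
    o <- if (length(ids) >= 3) {
      tryCatch(mcdonald_omega(mat)$omega, error = function(e) NA_real_)
    } else {
      NA_real_
    }
    tibble::tibble(domain = d, n_items = length(ids), n = a$n,
                   alpha_raw = a$alpha_raw,
                   alpha_standardized = a$alpha_standardized,
                   omega = o,
                   alpha_if_deleted = list(a$alpha_if_deleted))
  })
  dplyr::bind_rows(rows)
}

#' Correlations between domains and corrected summary scores
#'
#' For every (domain, summary) pair where the domain is a constituent of the
#' summary, the summary is recomputed *excluding* that domain and the
#' Spearman correlation between the domain and the corrected summary is
#' reported, pooled across baseline and Week 24 observations.
#'
#' @param panel Score panel from [score_cohort()].
#' @param schema A [qole_schema()]; its summary composition defines the
#'   constituent sets (with GEN's constituents substituted into ALL).
#' @return Tibble with `domain`, `summary`, `n`, `r`, `p`, `magnitude`.
#' @export
corrected_summary_correlations <- function(panel, schema = default_schema()) {
  pooled <- panel[panel$visit %in% c("baseline", "week24"), , drop = FALSE]
  comp <- schema$summary_composition
  expand <- function(parts) {
    out <- character(0)
    for (p in parts) {
      if (p %in% names(comp)) out <- c(out, expand(comp[[p]])) else out <- c(out, p)
    }
    unique(out)
  }
  # recompute a summary with one domain excluded, respecting the nesting
  # (ALL excluding SOC = mean(GEN without SOC, MDSS)) and the SEX-missing
  # drop rule used by the scorer
  eval_summary <- function(name, exclude) {
    if (!name %in% names(comp)) {
      if (name == exclude) return(NULL)
      return(pooled[[name]])
    }
    parts <- lapply(comp[[name]], eval_summary, exclude = exclude)
    keep <- !vapply(parts, is.null, logical(1))
    parts <- parts[keep]
    part_names <- comp[[name]][keep]
    if (length(parts) == 0) return(NULL)
    m <- do.call(cbind, parts)
    required <- part_names != "SEX"
    val <- rowMeans(m, na.rm = TRUE)
    val[rowSums(is.na(m[, required, drop = FALSE])) > 0] <- NA_real_
    val[rowSums(!is.na(m)) == 0] <- NA_real_
    val
  }
  rows <- list()
  for (s in names(comp)) {
    for (d in expand(comp[[s]])) {
      corrected <- eval_summary(s, exclude = d)
      if (is.null(corrected)) next
      res <- spearman(pooled[[d]], corrected)
      rows[[length(rows) + 1]] <- tibble::tibble(
        domain = d, summary = s, n = res$n, r = res$r, p = res$p,
        magnitude = res$magnitude
      )
    }
  }
  dplyr::bind_rows(rows)
}
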