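# Independent oracle implementations used to check the package's
# estimators. These deliberately take a different route than the package
# code (stats::aov, rank-then-Pearson, closed forms, enumeration).

# ICC(A,1) computed from a stats::aov two-way decomposition of the long
# data, rather than from direct mean-square sums.
oracle_icc_a1 <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  long <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), times = k)),
    occasion = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(y ~ subject + occasion, data = long)
  tab <- summary(fit)[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["occasion", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Spearman rho as Pearson on average ranks, written out by hand.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# n x k data matrix whose sample correlation matrix is exactly R.
make_exact_cor_data <- function(n, R, seed = 1) {
  set.seed(seed)
  MASS::mvrnorm(n, mu = rep(0, ncol(R)), Sigma = R, empirical = TRUE)
}

equicorrelated <- function(k, r) {
  R <- matrix(r, k, k)
  diag(R) <- 1
  R
}

# All achievable oriented raw sums of a domain (dynamic programming over
# the item ranges), for brute-force checks of score granularity.
achievable_sums <- function(ranges) {
  Reduce(function(acc, r) sort(unique(as.vector(outer(acc, 0:r, "+")))),
         ranges, accumulate = FALSE, 0L)
}

# A record with every item at its best (or worst) level.
extreme_record <- function(schema, best = TRUE) {
  it <- schema$items
  val <- ifelse(it$reversed == best, it$raw_min, it$raw_max)
  stats::setNames(as.integer(val), it$item_id)
}
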