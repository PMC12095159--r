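# ---- internal helpers -------------------------------------------------------

new_test_result <- function(statistic, p_value, method, n1, n2, alternative) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         n1 = n1, n2 = n2, alternative = alternative),
    class = "pwabs_test"
  )
}

#' @export
print.pwabs_test <- function(x, ...) {
  cat(sprintf("pwabs test (%s, %s): statistic = %g, p = %g (n1 = %d, n2 = %d)\n",
              x$method, x$alternative, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

# Exact null distribution of the Mann-Whitney U statistic by full enumeration
# of the C(n1+n2, n1) assignments of ranks to the first group. Only called for
# tie-free data with small groups, where enumeration is cheap.
mwu_exact_dist <- function(n1, n2) {
  combos <- utils::combn(n1 + n2, n1)
  u <- colSums(combos) - n1 * (n1 + 1) / 2
  tab <- tabulate(u + 1L, nbins = n1 * n2 + 1L)
  tab / sum(tab)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic counts
#' pairs (x_i > y_j) plus half of the tied pairs. The p-value is exact (full
#' enumeration of rank assignments) when both groups have at most
#' `exact_limit` observations and the pooled data are tie-free; otherwise a
#' normal approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param alternative One of `"two.sided"`, `"greater"` (x tends larger),
#'   `"less"`.
#' @param exact_limit Largest per-group size for which the exact distribution
#'   is enumerated (default 8, matching small clinical group sizes).
#' @return A `pwabs_test` object with fields `statistic` (U for the x sample),
#'   `p_value`, `method` (`"exact"` or `"approximate"`), `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "greater", "less"),
                           exact_limit = 8L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop("mann_whitney_u: both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("mann_whitney_u: missing values not allowed")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L

  if (!has_ties && n1 <= exact_limit && n2 <= exact_limit) {
    dist <- mwu_exact_dist(n1, n2)
    # distribution over u = 0..n1*n2; symmetric about n1*n2/2
    p_le <- sum(dist[seq_len(u + 1L)])
    p_ge <- sum(dist[(u + 1L):length(dist)])
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater   = p_ge,
      less      = p_le)
    return(new_test_result(u, p, "exact", n1, n2, alternative))
  }

  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    # all observations identical: no evidence either way
    return(new_test_result(u, 1, "approximate", n1, n2, alternative))
  }
  sigma <- sqrt(sigma2)
  # continuity correction pulls |u - mu| toward zero by 0.5
  z_two <- (abs(u - mu) - 0.5) / sigma
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-max(z_two, 0)),
    greater   = stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
    less      = stats::pnorm((u - mu + 0.5) / sigma))
  p <- min(1, max(0, p))
  new_test_result(u, p, "approximate", n1, n2, alternative)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), with the
#' p-value from the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho`, `p_value`, `n`, and `flagged` (TRUE when either
#'   input is constant, in which case `rho` and `p_value` are `NA`).
#' @export
spearman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("spearman: inputs must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("spearman: need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, flagged = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  rho <- max(-1, min(1, rho))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, flagged = FALSE)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities of all tables
#' with the same margins whose probability does not exceed that of the
#' observed table.
#'
#' @param table A 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts.
#' @return A `pwabs_test` object; `statistic` is the odds-ratio estimate
#'   (ad/bc, `Inf` or `NA` where undefined).
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("fisher_exact_2x2: need a 2x2 table")
  if (any(m < 0) || any(abs(m - round(m)) > 1e-8))
    stop("fisher_exact_2x2: counts must be non-negative integers")
  m <- round(m)
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  new_test_result(or, p, "exact", r1, sum(m[2, ]), "two.sided")
}

#' ROC area under the curve
#'
#' Rank-based AUC: (concordant pairs + half the tied pairs) divided by the
#' number of positive-negative pairs. Equals the Mann-Whitney U of the
#' positive-class scores divided by n1 * n0.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or a two-level factor where the
#'   second level is positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  scores <- as.numeric(scores)
  if (length(scores) != length(y)) stop("roc_auc: length mismatch")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("roc_auc: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall area under the curve (average precision)
#'
#' Average-precision form: the sum over positives, taken in decreasing score
#' order, of the precision at each positive's rank times that positive's
#' recall increment. Tied scores are ordered by original position; the
#' step-integral (not trapezoidal) convention is used.
#'
#' @inheritParams roc_auc
#' @return Average precision in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  scores <- as.numeric(scores)
  if (length(scores) != length(y)) stop("pr_auc: length mismatch")
  n_pos <- sum(y == 1L)
  if (n_pos == 0L) stop("pr_auc: positive class must be present")
  ord <- order(-scores)
  y_sorted <- y[ord]
  tp <- cumsum(y_sorted)
  k <- seq_along(y_sorted)
  precision_at_k <- tp / k
  sum(precision_at_k[y_sorted == 1L]) / n_pos
}

#' Threshold classification metrics
#'
#' Accuracy, precision, recall and F1 from the confusion matrix obtained by
#' calling scores at or above `threshold` positive. Precision is reported as 0
#' (with `precision_defined = FALSE`) when there are no positive predictions.
#'
#' @param prob Numeric scores or probabilities.
#' @param labels Binary labels (see [roc_auc]).
#' @param threshold Decision cutoff, default 0.5.
#' @return A list with `accuracy`, `precision`, `recall`, `f1`,
#'   `precision_defined`, and the confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
threshold_metrics <- function(prob, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  pred <- as.integer(as.numeric(prob) >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  n <- length(y)
  precision_defined <- (tp + fp) > 0L
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- if ((tp + fn) > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(accuracy = (tp + tn) / n, precision = precision, recall = recall,
       f1 = f1, precision_defined = precision_defined,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels factor must have exactly 2 levels")
    return(as.integer(labels == levels(labels)[2L]))
  }
  y <- as.integer(as.logical(as.numeric(labels)))
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
  y
}

#' Ordinary least squares with coefficient tests
#'
#' Solves the least-squares problem by QR decomposition and reports, per
#' coefficient, the estimate, standard error, t statistic and two-sided
#' p-value on n - k degrees of freedom. The design matrix is used as given
#' (include an intercept column yourself).
#'
#' @param y Numeric response.
#' @param X Numeric design matrix (rows > columns, full column rank).
#' @return A data.frame with one row per column of `X` (`term`, `estimate`,
#'   `std_error`, `t_value`, `p_value`) plus attributes `sigma`, `df_residual`
#'   and `r_squared`.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("ols_fit: length(y) must equal nrow(X)")
  if (n <= k) stop("ols_fit: need more observations than coefficients")
  qrx <- qr(X)
  if (qrx$rank < k) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1L):k]]
    if (is.null(dep)) dep <- paste0("column ", qrx$pivot[(qrx$rank + 1L):k])
    stop("ols_fit: design is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  resid <- y - X %*% beta
  df <- n - k
  sigma2 <- sum(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  pval <- 2 * stats::pt(-abs(tval), df = df)
  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("x", seq_len(k))
  out <- data.frame(term = terms, estimate = as.numeric(beta),
                    std_error = se, t_value = as.numeric(tval),
                    p_value = as.numeric(pval), stringsAsFactors = FALSE)
  tss <- sum((y - mean(y))^2)
  attr(out, "sigma") <- sqrt(sigma2)
  attr(out, "df_residual") <- df
  attr(out, "r_squared") <- if (tss > 0) 1 - sum(resid^2) / tss else NA_real_
  out
}

#' Benjamini-Hochberg adjustment (opt-in)
#'
#' Thin wrapper over [stats::p.adjust]; screening defaults use raw p-values,
#' this is available where a false-discovery-rate control is wanted instead.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
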