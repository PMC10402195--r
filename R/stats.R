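# Univariate discrimination statistics and ROC machinery.

#' Cohen's d with pooled standard deviation
#'
#' `(mean_a - mean_b) / s_pooled`, where the pooled standard deviation uses
#' n-1 weighting of the two group variances.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return Cohen's d (signed).
#' @export
cohens_d <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation; d undefined")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Mann-Whitney U test
#'
#' U computed from midranks (ties count one half); the two-sided p-value
#' comes from exact enumeration when both groups have at most 20
#' observations and there are no ties, and from the tie-corrected normal
#' approximation otherwise (via [stats::wilcox.test()]).
#'
#' @param group_a,group_b numeric vectors.
#' @return list with `U` (for `group_a`) and `p_two_sided`.
#' @export
mann_whitney <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 1L || nb < 1L) stop("each group needs at least 1 value")
  r <- rank(c(group_a, group_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- !has_ties && na <= 20L && nb <= 20L
  p <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact)$p.value
  )
  list(U = U, p_two_sided = min(p, 1))
}

#' Area under the ROC curve
#'
#' The probability that a random positive outranks a random negative, with
#' ties counted one half; computed by the rank formula, identical to
#' `U / (n1 * n0)`.
#'
#' @param scores numeric predictor values.
#' @param labels binary labels (logical, 0/1, or two-level factor; the
#'   higher/`TRUE` level is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  ok <- !is.na(scores) & !is.na(lab)
  scores <- scores[ok]; lab <- lab[ok]
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) > 2L) stop("labels must be binary")
    return(as.integer(labels) - 1L)
  }
  u <- sort(unique(stats::na.omit(labels)))
  if (length(u) > 2L) stop("labels must be binary")
  as.integer(labels == u[length(u)])
}

#' Empirical ROC curve
#'
#' Sensitivity/specificity sweep over all observed score thresholds
#' (classifying `score >= threshold` as positive).
#'
#' @inheritParams auc_score
#' @return data.frame with `threshold`, `fpr`, `tpr` (threshold decreasing,
#'   so the curve runs from (0,0) to (1,1)).
#' @export
roc_curve <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  ok <- !is.na(scores) & !is.na(lab)
  scores <- scores[ok]; lab <- lab[ok]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & lab == 1L) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & lab == 0L) / n0, 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Optimal operating point of an ROC curve (Youden's J)
#'
#' Maximizes J = sensitivity + specificity - 1; ties resolved toward the
#' lower threshold (the more sensitive operating point).
#'
#' @param roc a data.frame from [roc_curve()].
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
optimal_operating_point <- function(roc) {
  if (nrow(roc) == 0L) stop("empty ROC")
  j <- roc$tpr - roc$fpr
  best <- which(j >= max(j) - 1e-12)
  i <- best[which.min(roc$threshold[best])]
  list(threshold = roc$threshold[i], sensitivity = roc$tpr[i],
       specificity = 1 - roc$fpr[i], youden_j = j[i])
}

#' Confusion matrix at a threshold
#'
#' @inheritParams auc_score
#' @param threshold classify `score >= threshold` as positive.
#' @return 2x2 integer matrix (rows truth, cols predicted).
#' @export
confusion_at <- function(scores, labels, threshold) {
  lab <- as_binary_labels(labels)
  pred <- as.integer(scores >= threshold)
  table(truth = factor(lab, c(0, 1)), predicted = factor(pred, c(0, 1)))
}

# Placement values: for each positive, the fraction of negatives it beats
# (ties 1/2), and symmetrically for negatives.
delong_placements <- function(scores, lab) {
  pos <- scores[lab == 1L]; neg <- scores[lab == 0L]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(p) (sum(p > neg) + 0.5 * sum(p == neg)) / n, 0)
  v01 <- vapply(neg, function(q) (sum(pos > q) + 0.5 * sum(pos == q)) / m, 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors on the same subjects using the
#' covariance of placement values; `z = (auc_1 - auc_2) / sqrt(var)` with a
#' two-sided normal p-value. A degenerate variance (e.g. identical scores)
#' yields a missing p with a diagnostic rather than an error.
#'
#' @param scores_1,scores_2 paired predictor values on identical subjects.
#' @param labels binary labels shared by both score vectors.
#' @return list with `auc_1`, `auc_2`, `z`, `p_two_sided`, `var_diff`.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  lab <- as_binary_labels(labels)
  ok <- !is.na(scores_1) & !is.na(scores_2) & !is.na(lab)
  scores_1 <- scores_1[ok]; scores_2 <- scores_2[ok]; lab <- lab[ok]
  if (sum(lab == 1L) < 2L || sum(lab == 0L) < 2L) {
    stop("need at least 2 subjects per class")
  }
  p1 <- delong_placements(scores_1, lab)
  p2 <- delong_placements(scores_2, lab)
  m <- sum(lab == 1L); n <- sum(lab == 0L)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(var_diff) || var_diff <= 0) {
    if (isTRUE(all.equal(p1$auc, p2$auc))) {
      return(list(auc_1 = p1$auc, auc_2 = p2$auc, z = 0, p_two_sided = 1,
                  var_diff = var_diff))
    }
    return(list(auc_1 = p1$auc, auc_2 = p2$auc, z = NA_real_,
                p_two_sided = NA_real_, var_diff = var_diff,
                diagnostic = "degenerate DeLong variance"))
  }
  z <- (p1$auc - p2$auc) / sqrt(var_diff)
  list(auc_1 = p1$auc, auc_2 = p2$auc, z = z,
       p_two_sided = 2 * stats::pnorm(-abs(z)), var_diff = var_diff)
}

#' 2x2 contingency test
#'
#' Chi-square with Yates continuity correction (1 df) by default, matching
#' the categorical comparisons of the cohort characteristics table; Fisher's
#' exact test is available as a fallback for sparse tables.
#'
#' @param table_2x2 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @param method `"chisq"` (Yates-corrected, default) or `"fisher"`.
#' @return list with `statistic` (`NA` for Fisher) and `p_two_sided`.
#' @export
contingency_test <- function(table_2x2, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(table_2x2)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("both margins must be positive")
  if (method == "chisq") {
    ht <- stats::chisq.test(tab, correct = TRUE)
    list(statistic = unname(ht$statistic), p_two_sided = ht$p.value)
  } else {
    ht <- stats::fisher.test(tab)
    list(statistic = NA_real_, p_two_sided = ht$p.value)
  }
}
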