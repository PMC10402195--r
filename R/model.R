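#' Columns of the cohort table used as model features
#'
#' @param cohort a cohort table (see [cohort_table()]).
#' @param feature_set `"sense_only"` (clinical score alone), `"sense_implant"`
#'   (score + implant distance), or `"sense_ieeg"` (score + the iEEG
#'   abnormality-distance panel).
#' @return character vector of column names.
#' @export
focality_feature_columns <- function(cohort, feature_set = c("sense_only", "sense_implant", "sense_ieeg")) {
  feature_set <- match.arg(feature_set)
  abn_cols <- grep("^abn_", names(cohort), value = TRUE)
  switch(feature_set,
    sense_only = "sense_score",
    sense_implant = c("sense_score", "implant_distance"),
    sense_ieeg = c("sense_score", abn_cols)
  )
}

impute_standardize <- function(x_train, x_test) {
  med <- apply(x_train, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  fill <- function(x) { for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]; x }
  x_train <- fill(x_train); x_test <- fill(x_test)
  mu <- colMeans(x_train); sdv <- apply(x_train, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(train = sweep(sweep(x_train, 2L, mu), 2L, sdv, `/`),
       test = sweep(sweep(x_test, 2L, mu), 2L, sdv, `/`))
}

fit_penalized_logit <- function(x, y, penalty, C) {
  if (ncol(x) < 2L) {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y, family = stats::binomial()))
    coefs <- fit$coefficients
    list(predict = function(newx) {
      eta <- cbind(1, newx) %*% coefs
      as.numeric(1 / (1 + exp(-eta)))
    }, coef = stats::setNames(coefs[-1L], colnames(x)))
  } else {
    # sklearn-style C: glmnet's per-observation loss scaling gives
    # lambda = 1 / (C * n)
    alpha <- if (penalty == "l1") 1 else 0
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                          lambda = 1 / (C * length(y)), standardize = FALSE)
    list(predict = function(newx) {
      as.numeric(stats::predict(fit, newx = newx, type = "response"))
    }, coef = stats::setNames(as.numeric(stats::coef(fit))[-1L], colnames(x)))
  }
}

#' Leave-one-out cross-validated focality model
#'
#' Penalized logistic regression (lasso by default, `C = 1` on the
#' sklearn scale, i.e. `lambda = 1/(C n)`) predicting focal vs non-focal
#' network from a chosen feature set. Each patient is predicted by a model
#' trained on all others; features are median-imputed and standardized using
#' training-fold statistics only (a missingness indicator column is added
#' for any feature with missing values). The cross-validated AUC is computed
#' on the pooled out-of-fold probabilities.
#'
#' @param cohort cohort table with one row per patient: `label_focality`
#'   (`"focal"`/`"non_focal"`), `sense_score`, `implant_distance`, and
#'   `abn_*` abnormality-distance columns.
#' @param feature_set see [focality_feature_columns()].
#' @param penalty `"l1"` (lasso, default) or `"l2"` (ridge).
#' @param C inverse regularization strength (default 1).
#' @param seed RNG seed (kept for interface stability; LOOCV itself is
#'   deterministic and invariant to patient order).
#' @return object of class `focality_model`: `predictions` (out-of-fold
#'   probability of focal, one per patient), `auc`, `roc`, `operating_point`,
#'   `confusion`, `coefficients` (mean and sd across folds), `feature_set`,
#'   `penalty`, `C`.
#' @export
fit_focality_model <- function(cohort, feature_set = c("sense_only", "sense_implant", "sense_ieeg"),
                               penalty = c("l1", "l2"), C = 1, seed = 1) {
  feature_set <- match.arg(feature_set)
  penalty <- match.arg(penalty)
  if (nrow(cohort) < 10L) stop("need at least 10 patients")
  y <- as.integer(cohort$label_focality == "focal")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  cols <- focality_feature_columns(cohort, feature_set)
  x <- as.matrix(cohort[, cols, drop = FALSE])
  miss <- colnames(x)[colSums(is.na(x)) > 0L]
  if (length(miss) > 0L) {
    ind <- 1 * is.na(x[, miss, drop = FALSE])
    colnames(ind) <- paste0("missing_", miss)
    x <- cbind(x, ind)
  }
  set.seed(seed)
  n <- nrow(x)
  preds <- rep(NA_real_, n)
  coef_mat <- matrix(NA_real_, n, ncol(x), dimnames = list(NULL, colnames(x)))
  for (i in seq_len(n)) {
    y_tr <- y[-i]
    if (length(unique(y_tr)) < 2L) {
      warning("fold ", i, " has a single class in training; skipped")
      next
    }
    xs <- impute_standardize(x[-i, , drop = FALSE], x[i, , drop = FALSE])
    fit <- fit_penalized_logit(xs$train, y_tr, penalty, C)
    preds[i] <- fit$predict(xs$test)
    coef_mat[i, ] <- fit$coef
  }
  roc <- roc_curve(preds, y)
  opp <- optimal_operating_point(roc)
  structure(list(
    predictions = preds,
    labels = y,
    auc = auc_score(preds, y),
    roc = roc,
    operating_point = opp,
    confusion = confusion_at(preds, y, opp$threshold),
    coefficients = data.frame(
      feature = colnames(x),
      mean = colMeans(coef_mat, na.rm = TRUE),
      sd = apply(coef_mat, 2L, stats::sd, na.rm = TRUE),
      row.names = NULL
    ),
    feature_set = feature_set, penalty = penalty, C = C
  ), class = "focality_model")
}

#' @export
print.focality_model <- function(x, ...) {
  cat(sprintf("<focality_model> %s (%s, C=%g): cross-validated AUC %.3f, specificity %.0f%% at optimal point\n",
              x$feature_set, x$penalty, x$C, x$auc,
              100 * x$operating_point$specificity))
  invisible(x)
}

#' Subgroup AUCs of model predictions
#'
#' AUC of the out-of-fold predicted probability restricted to each level of
#' a grouping column. Subgroups missing one class, or whose predictions are
#' all identical, are reported as `NA`.
#'
#' @param cohort the cohort table used to fit the model.
#' @param predictions out-of-fold probabilities (e.g. `model$predictions`).
#' @param grouping name of a column of `cohort` (e.g. `"implant_type"`).
#' @param labels binary labels; defaults to focality.
#' @return named numeric vector, one AUC per subgroup level.
#' @export
subgroup_auc <- function(cohort, predictions, grouping,
                         labels = cohort$label_focality == "focal") {
  g <- cohort[[grouping]]
  if (is.null(g)) stop("no column `", grouping, "` in cohort")
  vapply(sort(unique(stats::na.omit(g))), function(level) {
    idx <- which(g == level)
    lab <- as_binary_labels(labels[idx])
    pr <- predictions[idx]
    if (length(unique(lab)) < 2L || length(unique(stats::na.omit(pr))) < 2L) {
      return(NA_real_)
    }
    auc_score(pr, lab)
  }, 0)
}

#' AUC of focality predictions for clinical endpoints
#'
#' How well the model's predicted probability of a focal network separates
#' (a) therapy choice (surgery vs device) and (b) favorable surgical outcome
#' (ILAE 1-2 vs 3-6 at 2 years, among surgical patients).
#'
#' @param cohort cohort table with `therapy` and `outcome_ilae` columns.
#' @param predictions out-of-fold probabilities of focal.
#' @param endpoint `"therapy"` or `"outcome"`.
#' @return AUC (`NA` when a class is absent).
#' @export
endpoint_auc <- function(cohort, predictions, endpoint = c("therapy", "outcome")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "therapy") {
    lab <- cohort$therapy == "surgery"
    pr <- predictions
  } else {
    idx <- which(cohort$therapy == "surgery" & !is.na(cohort$outcome_ilae))
    lab <- cohort$outcome_ilae[idx] <= 2
    pr <- predictions[idx]
  }
  if (length(unique(lab)) < 2L) return(NA_real_)
  auc_score(pr, lab)
}

#' Univariate discrimination panel
#'
#' For every candidate feature, Cohen's d, Mann-Whitney U and p, and AUC for
#' focal vs non-focal. P-values are raw (no multiplicity correction is
#' applied across the panel).
#'
#' @param cohort cohort table.
#' @param features columns to test; default the clinical score, implant
#'   distance and all abnormality distances.
#' @return data.frame with one row per feature.
#' @export
univariate_panel <- function(cohort,
                             features = c("sense_score", "implant_distance",
                                          grep("^abn_", names(cohort), value = TRUE))) {
  focal <- cohort$label_focality == "focal"
  do.call(rbind, lapply(features, function(f) {
    v <- cohort[[f]]
    ok <- !is.na(v)
    a <- v[ok & focal]; b <- v[ok & !focal]
    mw <- mann_whitney(a, b)
    data.frame(feature = f,
               d = cohens_d(a, b),
               U = mw$U, p = mw$p_two_sided,
               auc = auc_score(v[ok], focal[ok]),
               stringsAsFactors = FALSE)
  }))
}
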