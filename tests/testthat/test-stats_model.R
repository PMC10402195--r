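test_that("Cohen's d matches hand-computed cases", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(30)
  a <- rnorm(5000, 1, 1); b <- rnorm(5000, 0, 1)
  expect_equal(cohens_d(a, b), 1, tolerance = 0.06)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2.0)
  expect_error(cohens_d(rep(1, 3), rep(1, 3)), "pooled")
})

test_that("Mann-Whitney U and p match enumeration and rank identities", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_two_sided, 0.1)  # 2/20 arrangements as extreme
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_two_sided, 0.9)
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(sample(2:30, 1)); b <- rnorm(sample(2:30, 1))
    expect_equal(mann_whitney(a, b)$U + mann_whitney(b, a)$U,
                 length(a) * length(b))
  }
})

test_that("AUC equals the pair-counting oracle and the U identity", {
  auc_brute <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  expect_equal(auc_score(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  set.seed(32)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    scores <- sample(rnorm(n), n, replace = TRUE)  # induce ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_score(scores, labels), auc_brute(scores, labels))
    u <- mann_whitney(scores[labels == 1], scores[labels == 0])$U
    expect_equal(auc_score(scores, labels),
                 u / (sum(labels == 1) * sum(labels == 0)))
  }
  expect_error(auc_score(1:5, rep(1, 5)), "both classes")
})

test_that("DeLong test is exact under self-comparison and rank invariance", {
  set.seed(33)
  scores <- rnorm(40); labels <- rbinom(40, 1, 0.5)
  self <- delong_test(scores, scores, labels)
  expect_equal(self$z, 0)
  expect_equal(self$p_two_sided, 1)
  mono <- delong_test(scores, exp(scores), labels)
  expect_equal(mono$auc_1, mono$auc_2)
  expect_equal(mono$p_two_sided, 1)
})

test_that("DeLong agrees with an independent implementation and a bootstrap oracle", {
  set.seed(34)
  n <- 60
  labels <- rbinom(n, 1, 0.5)
  s1 <- rnorm(n) + labels
  s2 <- 0.5 * s1 + rnorm(n)
  res <- delong_test(s1, s2, labels)
  # independent cross-check
  rt <- pROC::roc.test(pROC::roc(labels, s1, quiet = TRUE),
                       pROC::roc(labels, s2, quiet = TRUE), method = "delong")
  expect_equal(res$p_two_sided, rt$p.value, tolerance = 1e-9)
  # bootstrap oracle for the variance of the AUC difference
  B <- 4000
  diffs <- vapply(seq_len(B), function(b) {
    idx <- c(sample(which(labels == 1), sum(labels == 1), TRUE),
             sample(which(labels == 0), sum(labels == 0), TRUE))
    auc_score(s1[idx], labels[idx]) - auc_score(s2[idx], labels[idx])
  }, 0)
  expect_lt(abs(res$var_diff - var(diffs)) / var(diffs), 0.15)
})

test_that("contingency test reproduces independence and cohort-table cases", {
  even <- contingency_test(matrix(10, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_two_sided, 1)
  lesion <- contingency_test(rbind(c(5, 12), c(28, 14)))
  expect_equal(round(lesion$p_two_sided, 2), 0.02)
  surgery <- contingency_test(rbind(c(11, 15), c(52, 7)))
  expect_lt(surgery$p_two_sided, 0.001)
  expect_error(contingency_test(rbind(c(0, 0), c(1, 2))), "margin")
  fisher <- contingency_test(rbind(c(1, 9), c(11, 3)), method = "fisher")
  expect_lt(fisher$p_two_sided, 0.01)
})

test_that("the optimal operating point maximizes Youden's J", {
  perfect <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  opp <- optimal_operating_point(perfect)
  expect_equal(opp$sensitivity, 1)
  expect_equal(opp$specificity, 1)
  # exhaustive sweep oracle on a small score set
  set.seed(35)
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.9)
  labels <- c(0, 0, 1, 1, 0, 1)
  roc <- roc_curve(scores, labels)
  opp <- optimal_operating_point(roc)
  sweep_j <- sapply(c(-Inf, scores), function(t) {
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
  })
  expect_equal(opp$youden_j, max(sweep_j))
})

test_that("LOOCV focality model separates separable data and stays at chance under permutation", {
  set.seed(36)
  n <- 60
  tab <- data.frame(
    sense_score = c(rnorm(n / 2, 5), rnorm(n / 2, -5)),
    implant_distance = rnorm(n),
    abn_power_gamma = rnorm(n),
    label_focality = rep(c("focal", "non_focal"), each = n / 2),
    stringsAsFactors = FALSE
  )
  m <- fit_focality_model(tab, "sense_only")
  expect_equal(m$auc, 1.0)
  expect_true(all(m$predictions >= 0 & m$predictions <= 1))

  set.seed(37)
  n <- 200
  null_tab <- data.frame(
    sense_score = rnorm(n),
    implant_distance = rnorm(n),
    abn_power_gamma = rnorm(n),
    label_focality = sample(rep(c("focal", "non_focal"), each = n / 2)),
    stringsAsFactors = FALSE
  )
  m0 <- fit_focality_model(null_tab, "sense_ieeg")
  expect_gt(m0$auc, 0.4)
  expect_lt(m0$auc, 0.6)
})

test_that("LOOCV predictions are invariant to patient ordering and impute missing values", {
  tab <- cohort_table(generate_cohort(cohort_spec(n_patients = 40, seed = 38)))
  tab$abn_power_gamma[c(3, 17)] <- NA
  m1 <- fit_focality_model(tab, "sense_ieeg")
  perm <- sample(nrow(tab))
  m2 <- fit_focality_model(tab[perm, ], "sense_ieeg")
  expect_equal(m2$predictions, m1$predictions[perm], tolerance = 1e-9)
  expect_equal(m2$auc, m1$auc, tolerance = 1e-9)
  expect_false(anyNA(m1$predictions))
})

test_that("cross-validated AUC recovers the analytic value of the generating score", {
  # two equal-variance Gaussians separated by d have AUC = pnorm(d / sqrt(2))
  sp <- cohort_spec(n_patients = 400, effect_size_sense = 1,
                    effect_size_wsd = 0, implant_effect = 0, seed = 39)
  tab <- cohort_table(generate_cohort(sp))
  m <- fit_focality_model(tab, "sense_only")
  expect_equal(m$auc, pnorm(1 / sqrt(2)), tolerance = 0.05)
})

test_that("subgroup and endpoint AUCs restrict correctly", {
  tab <- cohort_table(generate_cohort(cohort_spec(n_patients = 80, seed = 40)))
  m <- fit_focality_model(tab, "sense_ieeg")
  tab$everyone <- "all"
  expect_equal(unname(subgroup_auc(tab, m$predictions, "everyone")), m$auc)
  sub <- subgroup_auc(tab, m$predictions, "implant_type")
  expect_true(all(names(sub) %in% c("ecog", "seeg")))
  # identical predictions are undefined, reported missing
  expect_true(is.na(subgroup_auc(tab, rep(0.5, nrow(tab)), "everyone")))
  expect_true(is.finite(endpoint_auc(tab, m$predictions, "therapy")))
})
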