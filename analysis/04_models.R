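#!/usr/bin/env Rscript
# Cross-validated focality models: the clinical score alone, score +
# implant distance, and score + iEEG abnormality distances; DeLong model
# comparisons; endpoint (therapy, outcome) and implant-type subgroup AUCs.
library(ieegfocal)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

tab <- cohort_table(generate_cohort(cohort_spec(seed = seed)))
focal <- tab$label_focality == "focal"
sets <- c("sense_only", "sense_implant", "sense_ieeg")
models <- lapply(setNames(sets, sets), function(fs)
  fit_focality_model(tab, fs, seed = seed))

dir.create("results", showWarnings = FALSE)
summary <- data.frame(
  feature_set = sets,
  auc = sapply(models, `[[`, "auc"),
  sensitivity = sapply(models, function(m) m$operating_point$sensitivity),
  specificity = sapply(models, function(m) m$operating_point$specificity)
)
write.csv(summary, "results/models.csv", row.names = FALSE)
print(summary, row.names = FALSE, digits = 3)

cmp <- do.call(rbind, lapply(combn(sets, 2, simplify = FALSE), function(pr) {
  d <- delong_test(models[[pr[2]]]$predictions, models[[pr[1]]]$predictions, focal)
  data.frame(model_1 = pr[2], model_2 = pr[1],
             auc_1 = d$auc_1, auc_2 = d$auc_2, p = d$p_two_sided)
}))
write.csv(cmp, "results/model_comparisons.csv", row.names = FALSE)

pred <- models$sense_ieeg$predictions
sub <- subgroup_auc(tab, pred, "implant_type")
extra <- data.frame(
  analysis = c("therapy_surgery_vs_device", "outcome_ilae_1_2_vs_3_6",
               paste0("implant_", names(sub))),
  auc = c(endpoint_auc(tab, pred, "therapy"), endpoint_auc(tab, pred, "outcome"),
          unname(sub))
)
write.csv(extra, "results/subgroup_auc.csv", row.names = FALSE)
cat("\nendpoint and subgroup AUCs of the combined model:\n")
print(extra, row.names = FALSE, digits = 3)
coefs <- models$sense_ieeg$coefficients
cat("\nlargest mean |coefficient| in the combined model:",
    as.character(coefs$feature[which.max(abs(coefs$mean))]), "\n")
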