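test_that("cohort generation is deterministic and allocates groups by count", {
  sp <- cohort_spec(n_patients = 30, seed = 1)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(cohort_table(c1), cohort_table(c2))
  expect_identical(c1$patients[[5]]$weights, c2$patients[[5]]$weights)
  expect_identical(c1$patients[[5]]$electrode_table, c2$patients[[5]]$electrode_table)

  tab <- cohort_table(generate_cohort(cohort_spec(n_patients = 100,
                                                  focal_fraction = 0.65, seed = 2)))
  expect_equal(sum(tab$label_focality == "focal"), 65)
  expect_equal(sum(tab$label_focality == "non_focal"), 35)
})

test_that("cohort spec validation rejects bad inputs", {
  expect_error(cohort_spec(n_patients = 0), "positive")
  expect_error(cohort_spec(focal_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_spec(n_contacts_range = c(50, 10)), "increasing")
  expect_error(cohort_spec(abnormal_gamma_boost = -1), ">= 0")
})

test_that("patients carry consistent labels, subtypes and tables", {
  coh <- generate_cohort(cohort_spec(n_patients = 40, seed = 3))
  for (p in coh$patients) {
    expect_true(p$label_focality %in% c("focal", "non_focal"))
    if (p$label_focality == "focal") expect_equal(p$label_subtype, "unifocal")
    else expect_true(p$label_subtype %in% c("bifocal", "multifocal", "broad"))
    expect_true(p$therapy %in% c("surgery", "device"))
    expect_true(p$outcome_ilae %in% 1:6)
    expect_true(all(rownames(p$weights) %in% p$electrode_table$label))
  }
  tab <- cohort_table(coh)
  expect_equal(nrow(tab), 40)
  expect_true(all(c("sense_score", "implant_distance", "abn_power_gamma") %in% names(tab)))
})

test_that("clinical-score effect size and label rates converge to the requested values", {
  tab <- cohort_table(generate_cohort(cohort_spec(n_patients = 2000, seed = 4)))
  focal <- tab$label_focality == "focal"
  d <- cohens_d(tab$sense_score[focal], tab$sense_score[!focal])
  expect_equal(d, 0.72, tolerance = 0.1)
  # therapy rates follow the focality-conditional probabilities
  expect_lt(abs(mean(tab$therapy[focal] == "surgery") - 52 / 65), 0.05)
  expect_lt(abs(mean(tab$therapy[!focal] == "surgery") - 11 / 36), 0.05)
  # focal abnormality is spatially contracted relative to non-focal
  d_gamma <- cohens_d(tab$abn_power_gamma[!focal], tab$abn_power_gamma[focal])
  expect_gt(d_gamma, 0.4)
})

test_that("synthesized clips hit their band-power targets", {
  et <- make_electrode_table(matrix(0, 3, 3), labels = paste0("A", 1:3))
  rec <- synthesize_clip(et, c(0, 0, 1, 0, 0), 0, duration_s = 60, fs = 200, seed = 5)
  rp <- relative_band_power(rec)
  expect_true(all(rp[, "alpha"] > 0.9))
  expect_error(synthesize_clip(et, c(0.5, 0.5, 0.5, 0, 0), 0, 10, 200, 1), "sum to 1")
  expect_error(synthesize_clip(et, c(0.2, 0.2, 0.2, 0.2, 0.2), 0, 10, fs = 100, 1),
               "below 2x")
})

test_that("synthesized coherence matches its target within estimation error", {
  et <- make_electrode_table(matrix(0, 2, 3), labels = c("A1", "A2"))
  prof <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  # independent channels stay below the Welch bias floor
  rec0 <- synthesize_clip(et, prof, 0, duration_s = 60, fs = 200, seed = 6)
  co0 <- msc(rec0)["A1", "A2", "broadband"]
  n_seg <- welch_spectra(rec0)$n_segments
  reps <- vapply(1:5, function(s) {
    msc(synthesize_clip(et, prof, 0, 60, 200, seed = 10 + s))["A1", "A2", "broadband"]
  }, 0)
  expect_lt(co0, msc_bias_floor(n_seg) + 3 * sd(reps))
  # strong shared source induces the requested coherence
  rec8 <- synthesize_clip(et, prof, 0.8, duration_s = 60, fs = 200, seed = 7)
  co8 <- msc(rec8)["A1", "A2", "broadband"]
  expect_gt(co8, 0.6)
  expect_lt(co8, 0.95)
})

test_that("signal-mode cohorts carry clips aligned with the electrode table", {
  coh <- generate_cohort(cohort_spec(n_patients = 2, n_contacts_range = c(10, 12), seed = 8),
                         mode = "signal", n_clips = 2, clip_duration_s = 6)
  p <- coh$patients[[1]]
  expect_length(p$clips, 2)
  expect_equal(p$clips[[1]]$channel_labels, p$electrode_table$label)
  expect_equal(recording_duration(p$clips[[1]]), 6)
})

test_that("recording CSV serialization round-trips", {
  rec <- make_noise_recording(n_channels = 2, duration_s = 2, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
})
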