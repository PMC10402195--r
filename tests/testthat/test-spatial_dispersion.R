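test_that("standard distance matches hand-computable configurations", {
  expect_equal(standard_distance(matrix(1, 4, 3) * 5), 0)
  expect_equal(standard_distance(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(standard_distance(cube), sqrt(0.75))
  expect_error(standard_distance(matrix(0, 1, 3)), "at least 2")
})

test_that("weighted standard distance matches its hand-evaluated oracle", {
  coords <- rbind(c(0, 0, 0), c(3, 0, 0))
  w <- c(1, 3)
  d <- weighted_standard_distance(coords, w)
  expect_equal(as.numeric(d), sqrt(1.6875), tolerance = 1e-12)
  expect_equal(unname(attr(d, "weighted_center")), c(2.25, 0, 0))
})

test_that("WSD reduces to SD for uniform weights and to 0 for a point mass", {
  set.seed(20)
  coords <- matrix(rnorm(30 * 3, sd = 20), 30)
  expect_equal(as.numeric(weighted_standard_distance(coords, rep(2.7, 30))),
               standard_distance(coords), tolerance = 1e-12)
  w <- c(1, rep(0, 29))
  expect_equal(as.numeric(weighted_standard_distance(coords, w)), 0)
  expect_error(weighted_standard_distance(coords, rep(0, 30)), "all zero")
  expect_error(weighted_standard_distance(coords, c(-1, rep(1, 29))), "nonnegative")
})

test_that("SD and WSD agree with the direct-formula oracle on random clouds", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(3:200, 1)
    coords <- matrix(rnorm(n * 3, sd = runif(1, 1, 50)), n)
    w <- runif(n)
    expect_equal(standard_distance(coords), sd_oracle(coords), tolerance = 1e-12)
    expect_equal(as.numeric(weighted_standard_distance(coords, w)),
                 wsd_oracle(coords, w), tolerance = 1e-12)
  }
})

test_that("SD and WSD are invariant to rigid motions, equivariant to scaling", {
  set.seed(22)
  coords <- matrix(rnorm(40 * 3, sd = 15), 40)
  w <- runif(40)
  rot <- random_rotation()
  shift <- rnorm(3, sd = 100)
  moved <- sweep(coords %*% rot, 2, shift, `+`)
  expect_equal(standard_distance(moved), standard_distance(coords), tolerance = 1e-9)
  expect_equal(as.numeric(weighted_standard_distance(moved, w)),
               as.numeric(weighted_standard_distance(coords, w)), tolerance = 1e-9)
  expect_equal(standard_distance(coords * -2.5), 2.5 * standard_distance(coords),
               tolerance = 1e-9)
  expect_equal(as.numeric(weighted_standard_distance(coords, 13 * w)),
               as.numeric(weighted_standard_distance(coords, w)), tolerance = 1e-12)
})

test_that("WSD never exceeds the diameter of the positively weighted support", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    coords <- matrix(rnorm(n * 3, sd = 20), n)
    w <- runif(n) * rbinom(n, 1, 0.7)
    if (sum(w > 0) < 2) next
    pos <- coords[w > 0, , drop = FALSE]
    expect_lte(as.numeric(weighted_standard_distance(coords, w)),
               max(dist(pos)))
  }
})

test_that("patient dispersion reduces correctly and handles missing features", {
  set.seed(24)
  coords <- matrix(rnorm(20 * 3, sd = 25), 20)
  et <- make_electrode_table(coords)
  et$tissue[1:2] <- c("white", "outside")
  w <- matrix(1.3, 20, 2, dimnames = list(et$label, c("power_gamma", "coherence_gamma")))
  w[, "coherence_gamma"] <- NA
  disp <- patient_dispersion(et, w)
  gray_coords <- coords[-(1:2), ]
  expect_equal(disp$implant_distance, standard_distance(gray_coords))
  expect_equal(unname(disp$abnormality_distance["power_gamma"]),
               disp$implant_distance, tolerance = 1e-12)
  expect_true(is.na(disp$abnormality_distance["coherence_gamma"]))
  expect_equal(disp$n_contacts_used, 18)

  # weights concentrated in a tight cluster contract the distance
  w2 <- w
  w2[, "coherence_gamma"] <- 1e-6
  near <- order(rowSums(sweep(coords, 2, coords[5, ])^2))[1:4]
  w2[near, "coherence_gamma"] <- 100
  disp2 <- patient_dispersion(et, w2)
  expect_lt(disp2$abnormality_distance["coherence_gamma"], disp2$implant_distance)
})

test_that("matched focal and dispersed patients order their abnormality distances", {
  for (seed in 1:10) {
    pair <- matched_focality_pair(seed = seed)
    coords <- as.matrix(pair$electrode_table[, c("x", "y", "z")])
    wsd_f <- as.numeric(weighted_standard_distance(coords, pair$weights_focal))
    wsd_nf <- as.numeric(weighted_standard_distance(coords, pair$weights_nonfocal))
    expect_lt(wsd_f, wsd_nf)
    expect_equal(sum(pair$weights_focal), sum(pair$weights_nonfocal))
  }
})
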