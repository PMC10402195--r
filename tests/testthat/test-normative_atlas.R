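test_that("synthetic atlas has the right cell counts and is seed-deterministic", {
  rois <- paste0("roi", 1:10)
  bands <- c("delta", "theta", "alpha", "beta", "gamma", "broadband")
  a1 <- generate_atlas(rois, bands, n_contacts_per_roi = 5, seed = 3)
  a2 <- generate_atlas(rois, bands, n_contacts_per_roi = 5, seed = 3)
  expect_equal(nrow(a1$nodes), 60)          # 10 ROIs x 6 bands
  expect_equal(nrow(a1$edges), 6 * 45)      # 6 bands x C(10, 2) pairs
  expect_identical(a1$nodes, a2$nodes)
  expect_identical(a1$edges, a2$edges)
  expect_true(all(is.finite(a1$nodes$mean)))
  expect_true(all(a1$nodes$sd > 0))
  expect_error(generate_atlas(rois, bands, n_contacts_per_roi = 1), ">= 2")
})

test_that("z-scoring the atlas construction samples standardizes every cell", {
  a <- generate_atlas(paste0("roi", 1:4), c("alpha", "gamma"), 30, seed = 5)
  for (k in seq_len(nrow(a$nodes))) {
    cell <- a$nodes[k, ]
    z <- vapply(attr(a, "node_samples")[[paste(cell$roi, cell$band, cell$kind, sep = "|")]],
                zscore_node, 0, roi = cell$roi, band = cell$band, atlas = a)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
  }
  for (k in seq_len(nrow(a$edges))) {
    cell <- a$edges[k, ]
    z <- vapply(attr(a, "edge_samples")[[paste(cell$roi_a, cell$roi_b, cell$band, sep = "|")]],
                zscore_edge, 0, roi_a = cell$roi_a, roi_b = cell$roi_b,
                band = cell$band, atlas = a)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
  }
})

test_that("node and edge z-scores are affine and order-free in the ROI pair", {
  a <- generate_atlas(c("roiA", "roiB"), "alpha", 10, seed = 6)
  cell <- a$nodes[1, ]
  expect_equal(zscore_node(cell$mean, cell$roi, cell$band, a), 0)
  expect_equal(zscore_node(cell$mean + cell$sd, cell$roi, cell$band, a), 1)
  expect_equal(zscore_node(cell$mean - 2 * cell$sd, cell$roi, cell$band, a), -2)
  expect_equal(zscore_edge(0.4, "roiA", "roiB", "alpha", a),
               zscore_edge(0.4, "roiB", "roiA", "alpha", a))
  miss <- zscore_node(0.2, "nowhere", "alpha", a)
  expect_true(is.na(miss))
  expect_match(attr(miss, "diagnostic"), "nowhere")
})

test_that("atlas construction pools across subjects and honors the normal mask", {
  set.seed(7)
  make_subject <- function(rois, seed) {
    et <- make_electrode_table(matrix(rnorm(12), 4), rois = rois,
                               labels = paste0("S", seed, "_", 1:4))
    rec <- make_noise_recording(n_channels = 4, duration_s = 10, seed = seed)
    rec$channel_labels <- et$label
    rownames(rec$data) <- et$label
    list(et = et, feats = clip_features(rec))
  }
  s1 <- make_subject(c("roiA", "roiA", "roiB", "roiB"), 1)
  s2 <- make_subject(c("roiC", "roiC", "roiD", "roiD"), 2)
  masks <- list(
    setNames(c(TRUE, TRUE, TRUE, FALSE), s1$et$label),
    setNames(rep(TRUE, 4), s2$et$label)
  )
  atlas <- build_atlas(list(s1$feats, s2$feats), list(s1$et, s2$et), masks)
  expect_setequal(unique(atlas$nodes$roi), c("roiA", "roiB", "roiC", "roiD"))
  # the masked-out roiB contact leaves a single roiB value -> unusable cell
  roiB <- atlas$nodes[atlas$nodes$roi == "roiB" & atlas$nodes$band == "alpha", ]
  expect_equal(roiB$n, 1L)
  expect_false(roiB$usable)
  # z of construction values against their own cell re-standardizes
  roiA <- atlas$nodes[atlas$nodes$roi == "roiA" & atlas$nodes$band == "alpha", ]
  vals <- s1$feats$rel_power[1:2, "alpha"]
  z <- vapply(vals, zscore_node, 0, roi = "roiA", band = "alpha", atlas = atlas)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_error(build_atlas(list(), list(), list()), "no subjects")
})

test_that("abnormality aggregation reduces clips by the median of |z|", {
  labs <- c("E1", "E2")
  bands <- "gamma"
  mk <- function(z1, z2) {
    zn <- matrix(c(z1, z2), 2, 1, dimnames = list(labs, bands))
    ze <- array(NA_real_, c(2, 2, 1), dimnames = list(labs, labs, bands))
    ze[1, 2, 1] <- ze[2, 1, 1] <- z1
    list(z_node = zn, z_edge = ze)
  }
  one <- aggregate_abnormality(list(mk(-1.7, 0.4)))
  expect_equal(unname(one$weights["E1", "power_gamma"]), 1.7)
  expect_equal(unname(one$weights["E2", "power_gamma"]), 0.4)
  three <- aggregate_abnormality(list(mk(-3, 0), mk(0, 0), mk(3, 0)))
  expect_equal(unname(three$weights["E1", "power_gamma"]), 3)  # median of {3,0,3}
  # clip-order invariance
  perm <- aggregate_abnormality(list(mk(3, 0), mk(-3, 0), mk(0, 0)))
  expect_equal(three$weights, perm$weights)
  # constant z across clips is preserved
  const <- aggregate_abnormality(list(mk(1.2, 1.2), mk(1.2, 1.2)))
  expect_equal(unname(const$weights[, "power_gamma"]), c(1.2, 1.2))
})

test_that("in-distribution patients produce half-normal-median weights", {
  # z ~ N(0,1) per clip: median over clips of |z| has expectation ~ 0.674
  set.seed(8)
  n_contacts <- 400; n_clips <- 21
  labs <- paste0("E", seq_len(n_contacts))
  clips <- lapply(seq_len(n_clips), function(k) {
    zn <- matrix(rnorm(n_contacts), n_contacts, 1, dimnames = list(labs, "alpha"))
    ze <- array(NA_real_, c(n_contacts, n_contacts, 1),
                dimnames = list(labs, labs, "alpha"))
    list(z_node = zn, z_edge = ze)
  })
  w <- suppressWarnings(aggregate_abnormality(clips))
  expect_equal(mean(w$weights[, "power_alpha"]), qnorm(0.75), tolerance = 0.03)
})

test_that("atlas JSON serialization round-trips", {
  a <- generate_atlas(paste0("roi", 1:3), c("alpha", "beta"), 6, seed = 9)
  path <- tempfile(fileext = ".json")
  write_atlas_json(a, path)
  b <- read_atlas_json(path)
  expect_equal(a$nodes$mean, b$nodes$mean)
  expect_equal(a$edges$sd, b$edges$sd)
  expect_equal(zscore_node(0.2, "roi1", "alpha", a), zscore_node(0.2, "roi1", "alpha", b))
})
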