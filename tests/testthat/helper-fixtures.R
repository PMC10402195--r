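# Shared fixtures: deterministic toy recordings and electrode tables.

# Sum of sinusoids + small white noise, identical across channels unless
# `per_channel` amplitudes are given.
make_sine_recording <- function(freqs, amps = rep(1, length(freqs)),
                                fs = 200, duration_s = 10, n_channels = 1,
                                noise_sd = 1e-3, labels = NULL, seed = 42) {
  set.seed(seed)
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  base <- colSums(amps * t(sapply(freqs, function(f) sin(2 * pi * f * t))))
  if (length(freqs) == 1L) base <- amps[1] * sin(2 * pi * freqs[1] * t)
  data <- t(sapply(seq_len(n_channels), function(i) base + rnorm(length(t), 0, noise_sd)))
  if (is.null(labels)) labels <- paste0("LA", seq_len(n_channels))
  new_recording(data, fs, labels)
}

make_noise_recording <- function(n_channels = 2, fs = 200, duration_s = 60, seed = 7) {
  set.seed(seed)
  new_recording(matrix(rnorm(n_channels * fs * duration_s), n_channels),
                fs, paste0("LA", seq_len(n_channels)))
}

# Minimal gray-matter electrode table at given coordinates.
make_electrode_table <- function(coords, rois = "roi1", tissue = "gray",
                                 labels = NULL) {
  coords <- as.matrix(coords)
  if (is.null(labels)) labels <- paste0("E", seq_len(nrow(coords)))
  data.frame(label = labels, x = coords[, 1], y = coords[, 2], z = coords[, 3],
             roi = rep_len(rois, nrow(coords)),
             tissue = rep_len(tissue, nrow(coords)), stringsAsFactors = FALSE)
}

# Random 3-D rotation matrix via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Direct-formula dispersion oracles: center, square, sum per axis.
sd_oracle <- function(coords) {
  n <- nrow(coords)
  sqrt(sum(vapply(1:3, function(a) sum((coords[, a] - mean(coords[, a]))^2) / n, 0)))
}
wsd_oracle <- function(coords, w) {
  ctr <- vapply(1:3, function(a) sum(w * coords[, a]) / sum(w), 0)
  sqrt(sum(vapply(1:3, function(a) sum(w * (coords[, a] - ctr[a])^2) / sum(w), 0)))
}
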