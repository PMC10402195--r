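# Signal-level synthesis: band-structured multichannel noise with
# controllable relative band power and pairwise coherence, and a synthetic
# normative atlas for the z-scoring path.

# Unit-variance Gaussian noise band-limited to [lo, hi) by FFT masking.
band_noise <- function(n, lo, hi, fs) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1L) * fs / n
  f_fold <- pmin(f, fs - f)  # two-sided spectrum frequencies
  keep <- f_fold >= lo & f_fold < hi
  y <- Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("degenerate band noise")
  y / s
}

#' Synthesize a band-structured multichannel iEEG clip
#'
#' Each channel is a sum over the five canonical bands of independently
#' band-limited Gaussian noise, scaled so the relative band power matches
#' `band_profile`. Within each band a shared source is mixed into every
#' channel to induce pairwise coherence: with per-channel coherence level
#' `c_i`, the magnitude-squared coherence between channels i and j is
#' `sqrt(c_i * c_j)` (so a common scalar target `c` yields MSC `c` for every
#' pair). The mixing coefficient is `alpha_i^2 = sqrt(c_i) / (1 - sqrt(c_i))`,
#' exact for unit-variance private noise.
#'
#' @param electrode_table electrode table; one output channel per row.
#' @param band_profile relative power targets over the five narrow bands:
#'   a length-5 vector (all channels) or a channels x 5 matrix; each row
#'   must be nonnegative and sum to 1.
#' @param coherence_targets per-channel coherence level in `[0, 1)`: scalar
#'   or length-channels vector (pair MSC is the geometric mean of the two
#'   channel levels).
#' @param duration_s clip duration in seconds.
#' @param fs sampling rate in Hz; must be at least twice the highest band
#'   edge (160 Hz for the canonical gamma band).
#' @param seed integer seed.
#' @return an `ieeg_recording`.
#' @export
synthesize_clip <- function(electrode_table, band_profile, coherence_targets = 0,
                            duration_s = 60, fs = 200, seed = 1) {
  bands <- canonical_bands(FALSE)
  n_ch <- nrow(electrode_table)
  if (fs < 2 * max(bands$hi)) {
    stop("fs = ", fs, " Hz is below 2x the highest band edge (", max(bands$hi), " Hz)")
  }
  if (is.null(dim(band_profile))) {
    band_profile <- matrix(band_profile, n_ch, nrow(bands), byrow = TRUE)
  }
  if (ncol(band_profile) != nrow(bands) || nrow(band_profile) != n_ch) {
    stop("`band_profile` must be channels x 5")
  }
  if (any(band_profile < 0) || any(abs(rowSums(band_profile) - 1) > 1e-6)) {
    stop("band targets must be nonnegative and sum to 1 over the five bands")
  }
  cc <- rep(coherence_targets, length.out = n_ch)
  if (any(cc < 0) || any(cc >= 1)) stop("coherence targets must be in [0, 1)")
  alpha <- sqrt(sqrt(cc) / (1 - sqrt(cc)))
  set.seed(seed)
  n <- round(duration_s * fs)
  x <- matrix(0, n_ch, n)
  for (b in seq_len(nrow(bands))) {
    shared <- band_noise(n, bands$lo[b], bands$hi[b], fs)
    for (i in seq_len(n_ch)) {
      p <- band_profile[i, b]
      if (p <= 0) next
      private <- band_noise(n, bands$lo[b], bands$hi[b], fs)
      comp <- (private + alpha[i] * shared) / sqrt(1 + alpha[i]^2)
      x[i, ] <- x[i, ] + sqrt(p) * comp
    }
  }
  new_recording(x, fs, electrode_table$label)
}

#' Generate a synthetic normative atlas
#'
#' Draws, for every (ROI, band) node cell and every unordered (ROI pair,
#' band) edge cell, `n_contacts_per_roi` construction samples from a
#' cell-specific Gaussian, and summarizes each cell by its sample mean,
#' standard deviation and count. The construction samples are attached as
#' attributes so standardization can be verified against them.
#'
#' @param rois character vector of ROI names.
#' @param bands character vector of band names.
#' @param n_contacts_per_roi samples per cell (>= 2).
#' @param seed integer seed.
#' @return a `normative_atlas` with attributes `node_samples` and
#'   `edge_samples` (named lists of the construction draws).
#' @export
generate_atlas <- function(rois, bands, n_contacts_per_roi, seed = 1) {
  if (n_contacts_per_roi < 2L) stop("`n_contacts_per_roi` must be >= 2")
  set.seed(seed)
  node_samples <- list()
  for (r in rois) for (b in bands) {
    mu <- stats::runif(1, 0.05, 0.35)
    sig <- stats::runif(1, 0.02, 0.08)
    node_samples[[node_key(r, b, "power")]] <- stats::rnorm(n_contacts_per_roi, mu, sig)
  }
  edge_samples <- list()
  if (length(rois) >= 2L) {
    pairs <- utils::combn(sort(rois), 2L)
    for (j in seq_len(ncol(pairs))) for (b in bands) {
      mu <- stats::runif(1, 0.1, 0.6)
      sig <- stats::runif(1, 0.05, 0.15)
      edge_samples[[edge_key(pairs[1L, j], pairs[2L, j], b)]] <-
        stats::rnorm(n_contacts_per_roi, mu, sig)
    }
  }
  nodes <- summarize_cells(node_samples)
  parts <- do.call(rbind, strsplit(nodes$key, "|", fixed = TRUE))
  nodes <- data.frame(roi = parts[, 1], band = parts[, 2], kind = parts[, 3],
                      nodes[, c("mean", "sd", "n")], stringsAsFactors = FALSE)
  if (length(edge_samples) > 0L) {
    edges <- summarize_cells(edge_samples)
    parts <- do.call(rbind, strsplit(edges$key, "|", fixed = TRUE))
    edges <- data.frame(roi_a = parts[, 1], roi_b = parts[, 2], band = parts[, 3],
                        edges[, c("mean", "sd", "n")], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(roi_a = character(0), roi_b = character(0),
                        band = character(0), mean = numeric(0), sd = numeric(0),
                        n = integer(0))
  }
  atlas <- new_atlas(nodes, edges)
  attr(atlas, "node_samples") <- node_samples
  attr(atlas, "edge_samples") <- edge_samples
  atlas
}
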