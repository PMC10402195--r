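#' Relative band power per contact
#'
#' Welch power spectral density (2 s Hamming windows, 1 s overlap) integrated
#' over each canonical band and divided by broadband (0.5-80 Hz) power. The
#' five narrow-band values partition broadband, so they sum to 1 for every
#' contact. The `broadband` column carries the *absolute* broadband power
#' (units^2), the quantity that enters models alongside the relative bands.
#'
#' @param recording an `ieeg_recording`, at least 2 s long.
#' @param bands band definition data.frame as from [canonical_bands()].
#' @param window_s,overlap_s Welch segmentation (seconds).
#' @return matrix contacts x bands; narrow-band columns are relative power in
#'   `[0, 1]`, the `broadband` column is absolute power. Silent (zero
#'   variance) channels are reported as `NA`, never as 0/0.
#' @export
relative_band_power <- function(recording, bands = canonical_bands(),
                                window_s = 2, overlap_s = 1) {
  sp <- welch_spectra(recording, window_s, overlap_s, cross = FALSE)
  out <- matrix(NA_real_, nrow(recording$data), nrow(bands),
                dimnames = list(recording$channel_labels, bands$name))
  bb <- bands[bands$name == "broadband", ]
  if (nrow(bb) == 0L) bb <- data.frame(lo = 0.5, hi = 80)
  total <- band_integral(sp$freq, sp$psd, bb$lo[1], bb$hi[1])
  silent <- apply(recording$data, 1L, stats::var) <= 0
  for (j in seq_len(nrow(bands))) {
    p <- band_integral(sp$freq, sp$psd, bands$lo[j], bands$hi[j])
    out[, j] <- if (bands$name[j] == "broadband") p else p / total
  }
  out[silent, ] <- NA_real_
  out
}

#' Magnitude-squared coherence per channel pair and band
#'
#' MSC from Welch auto- and cross-spectra with the same 2 s Hamming / 1 s
#' overlap segmentation as [relative_band_power()]. The band value is the
#' unweighted mean of per-bin MSC over the band's frequency bins.
#'
#' @inheritParams relative_band_power
#' @return numeric array channels x channels x bands, symmetric with unit
#'   diagonal in every band slice.
#' @export
msc <- function(recording, bands = canonical_bands(),
                window_s = 2, overlap_s = 1) {
  sp <- welch_spectra(recording, window_s, overlap_s, cross = TRUE)
  if (sp$n_segments < 3L) {
    stop("MSC needs at least 3 Welch segments (got ", sp$n_segments,
         "); single-segment coherence is degenerate at 1")
  }
  n_ch <- nrow(recording$data)
  n_freq <- length(sp$freq)
  coh <- array(NA_real_, dim = c(n_ch, n_ch, n_freq))
  for (k in seq_len(n_freq)) {
    s <- sp$csd[, , k]
    auto <- Re(diag(s))
    denom <- tcrossprod(auto)
    coh[, , k] <- ifelse(denom > 0, Mod(s)^2 / denom, NA_real_)
  }
  out <- array(NA_real_, dim = c(n_ch, n_ch, nrow(bands)),
               dimnames = list(recording$channel_labels,
                               recording$channel_labels, bands$name))
  for (j in seq_len(nrow(bands))) {
    idx <- which(sp$freq >= bands$lo[j] - 1e-9 & sp$freq < bands$hi[j] - 1e-9)
    if (bands$name[j] == "broadband") {
      idx <- which(sp$freq >= bands$lo[j] - 1e-9 & sp$freq <= bands$hi[j] + 1e-9)
    }
    out[, , j] <- apply(coh[, , idx, drop = FALSE], c(1L, 2L), mean)
    diag(out[, , j]) <- 1
  }
  out
}

#' Expected small-sample bias of Welch MSC for independent signals
#'
#' For two independent stationary signals the Welch MSC estimator has
#' expectation approximately `1 / K_eff`, where `K_eff` is the effective
#' number of independent segments. With 50% overlap the segments are
#' correlated; for a Hamming taper the squared normalized lag-correlation of
#' the window is about 0.054, giving `K_eff = K / (1 + 2 * 0.054)`. Used as
#' the noise floor when checking independence.
#'
#' @param n_segments number of averaged Welch segments.
#' @param overlap_rho squared window correlation between adjacent segments
#'   (0 for non-overlapping segments; default Hamming at 50% overlap).
#' @return approximate expected MSC under independence.
#' @export
msc_bias_floor <- function(n_segments, overlap_rho = 0.054) {
  (1 + 2 * overlap_rho) / n_segments
}

#' Features of one clip: relative band power + coherence
#'
#' Convenience wrapper bundling [relative_band_power()] and [msc()] into the
#' per-clip feature object that atlas z-scoring consumes.
#'
#' @inheritParams relative_band_power
#' @return list of class `contact_features` with elements `rel_power`
#'   (contacts x bands) and `coherence` (contacts x contacts x bands).
#' @export
clip_features <- function(recording, bands = canonical_bands(),
                          window_s = 2, overlap_s = 1) {
  structure(
    list(rel_power = relative_band_power(recording, bands, window_s, overlap_s),
         coherence = msc(recording, bands, window_s, overlap_s)),
    class = "contact_features"
  )
}

#' Serialize clip features to long-format CSV
#'
#' One row per (contact-or-pair, band, value); `pair` is `NA` for power rows.
#'
#' @param features a `contact_features` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  p <- features$rel_power
  power <- data.frame(
    contact = rep(rownames(p), ncol(p)), pair = NA_character_,
    kind = "power", band = rep(colnames(p), each = nrow(p)),
    value = as.vector(p), stringsAsFactors = FALSE
  )
  co <- features$coherence
  labs <- dimnames(co)[[1]]
  ut <- which(upper.tri(co[, , 1]), arr.ind = TRUE)
  coh <- do.call(rbind, lapply(seq_len(dim(co)[3]), function(j) {
    data.frame(contact = labs[ut[, 1]], pair = labs[ut[, 2]],
               kind = "coherence", band = dimnames(co)[[3]][j],
               value = co[, , j][ut], stringsAsFactors = FALSE)
  }))
  utils::write.csv(rbind(power, coh), path, row.names = FALSE)
  invisible(path)
}
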