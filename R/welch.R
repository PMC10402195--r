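# Welch spectral machinery shared by band power, coherence and the
# wakefulness detector. Segmentation: 2 s Hamming windows, 1 s overlap.

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

welch_segments <- function(n_samples, seg_len, step) {
  if (seg_len > n_samples) return(integer(0))
  seq(1L, n_samples - seg_len + 1L, by = step)
}

#' Welch auto- and cross-spectral estimates
#'
#' Computes one-sided Welch spectral density estimates for every channel of a
#' recording and, optionally, cross-spectra for every channel pair. Segments
#' are mean-detrended, Hamming-tapered, and averaged.
#'
#' @param recording an `ieeg_recording`.
#' @param window_s segment length in seconds (default 2).
#' @param overlap_s segment overlap in seconds (default 1).
#' @param cross if `TRUE`, also return the averaged complex cross-spectra
#'   needed for magnitude-squared coherence.
#' @return list with `freq` (Hz), `psd` (channels x frequencies, density in
#'   units^2/Hz), `n_segments`, and when `cross = TRUE` a complex array
#'   `csd` of dimension channels x channels x frequencies.
#' @export
welch_spectra <- function(recording, window_s = 2, overlap_s = 1, cross = FALSE) {
  x <- recording$data
  fs <- recording$fs
  seg_len <- round(window_s * fs)
  step <- round((window_s - overlap_s) * fs)
  if (step < 1L) stop("overlap must be smaller than the window")
  starts <- welch_segments(ncol(x), seg_len, step)
  if (length(starts) == 0L) {
    stop("recording shorter than one Welch segment (", window_s, " s)")
  }
  win <- hamming_window(seg_len)
  scale <- fs * sum(win^2)
  n_freq <- seg_len %/% 2L + 1L
  freq <- (seq_len(n_freq) - 1L) * fs / seg_len
  n_ch <- nrow(x)

  psd_acc <- matrix(0, n_ch, n_freq)
  csd_acc <- if (cross) array(0i, dim = c(n_ch, n_ch, n_freq)) else NULL
  for (s in starts) {
    seg <- x[, s:(s + seg_len - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2L, win, `*`)
    ft <- t(stats::mvfft(t(seg)))[, seq_len(n_freq), drop = FALSE]
    psd_acc <- psd_acc + Re(ft * Conj(ft))
    if (cross) {
      for (k in seq_len(n_freq)) {
        csd_acc[, , k] <- csd_acc[, , k] + tcrossprod(ft[, k], Conj(ft[, k]))
      }
    }
  }
  n_seg <- length(starts)
  # one-sided density: double all bins except DC (and Nyquist when seg_len even)
  one_sided <- rep(2, n_freq)
  one_sided[1L] <- 1
  if (seg_len %% 2L == 0L) one_sided[n_freq] <- 1
  psd <- sweep(psd_acc / (n_seg * scale), 2L, one_sided, `*`)
  rownames(psd) <- recording$channel_labels
  out <- list(freq = freq, psd = psd, n_segments = n_seg)
  if (cross) {
    csd <- csd_acc / (n_seg * scale)
    for (k in seq_len(n_freq)) csd[, , k] <- csd[, , k] * one_sided[k]
    out$csd <- csd
  }
  out
}

# Trapezoidal band integral of a density sampled on `freq`, over [lo, hi].
# Band edges of the canonical scheme fall on the Welch grid (0.5 Hz at
# fs = 200, 2 s windows), so adjacent band integrals share edge ordinates and
# the five narrow bands sum exactly to the broadband integral.
band_integral <- function(freq, dens, lo, hi) {
  idx <- which(freq >= lo - 1e-9 & freq <= hi + 1e-9)
  if (length(idx) < 2L) return(NA_real_)
  f <- freq[idx]
  if (is.matrix(dens)) {
    d <- dens[, idx, drop = FALSE]
    dx <- diff(f)
    as.numeric((d[, -1L, drop = FALSE] + d[, -length(f), drop = FALSE]) %*% dx / 2)
  } else {
    sum(diff(f) * (dens[idx][-1L] + dens[idx][-length(idx)]) / 2)
  }
}
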