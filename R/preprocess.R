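#' Bipolar re-referencing along electrode shanks
#'
#' Re-references a recording to differences of numerically adjacent contacts
#' on the same shank (LA1-LA2, LA2-LA3, ...). Channel labels must parse as a
#' shank name followed by a trailing contact number (case-sensitive);
#' contacts without a same-shank successor are dropped.
#'
#' @param recording an `ieeg_recording` with parseable labels.
#' @return an `ieeg_recording` of bipolar channels labelled `"A-B"`.
#' @export
bipolar_reference <- function(recording) {
  labs <- recording$channel_labels
  m <- regmatches(labs, regexec("^(.*[^0-9])([0-9]+)$", labs))
  bad <- labs[vapply(m, length, 1L) != 3L]
  if (length(bad) > 0L) {
    stop("channel label(s) not parseable as shank + contact number: ",
         paste(bad, collapse = ", "))
  }
  shank <- vapply(m, `[`, "", 2L)
  idx <- as.integer(vapply(m, `[`, "", 3L))
  keep <- integer(0); succ <- integer(0)
  for (i in seq_along(labs)) {
    j <- which(shank == shank[i] & idx == idx[i] + 1L)
    if (length(j) == 1L) { keep <- c(keep, i); succ <- c(succ, j) }
  }
  if (length(keep) == 0L) stop("no adjacent same-shank contact pairs found")
  data <- recording$data[keep, , drop = FALSE] - recording$data[succ, , drop = FALSE]
  new_recording(data, recording$fs,
                paste0(labs[keep], "-", labs[succ]), recording$t_start)
}

#' Band-pass filter, notch, and downsample a recording
#'
#' Zero-phase (forward-backward) 3rd-order Butterworth band-pass between
#' `lo` and `hi` Hz, a Butterworth band-stop notch around `notch` Hz, then
#' resampling to `fs_out`. The 80 Hz low-pass edge provides anti-aliasing
#' for the 200 Hz target rate; polyphase resampling handles non-integer
#' rate ratios. Upsampling is refused.
#'
#' @param recording an `ieeg_recording` with `fs >= fs_out`.
#' @param lo,hi band-pass edges in Hz.
#' @param notch line-noise frequency in Hz (`NULL` to skip).
#' @param fs_out output sampling rate in Hz.
#' @param order Butterworth order (applied forward-backward, so the
#'   effective roll-off is doubled).
#' @return the filtered, resampled `ieeg_recording`.
#' @export
filter_and_resample <- function(recording, lo = 0.5, hi = 80, notch = 60,
                                fs_out = 200, order = 3) {
  fs <- recording$fs
  if (fs < fs_out) stop("input fs (", fs, ") below target ", fs_out, " Hz; refusing to upsample")
  bp <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  x <- t(apply(recording$data, 1L, function(ch) signal::filtfilt(bp, ch)))
  if (!is.null(notch) && notch < fs / 2) {
    bs <- signal::butter(order, c(notch - 2, notch + 2) / (fs / 2), type = "stop")
    x <- t(apply(x, 1L, function(ch) signal::filtfilt(bs, ch)))
  }
  if (fs != fs_out) {
    n_out <- round(ncol(x) * fs_out / fs)
    x <- t(apply(x, 1L, resample_fft, n_out = n_out))
  }
  new_recording(x, fs_out, recording$channel_labels, recording$t_start)
}

# Exact band-limited (Fourier) resampling: truncate the spectrum to the new
# Nyquist and invert. Unit passband gain for any rate ratio; appropriate
# here because the band-pass has already confined content well below the
# output Nyquist. Assumes effective periodicity (edge transients are
# negligible for clip-length inputs after zero-phase filtering).
resample_fft <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  if (n_out > n) stop("upsampling not supported")
  X <- stats::fft(x)
  Y <- complex(n_out)
  half <- (n_out - 1L) %/% 2L
  Y[1L] <- X[1L]
  if (half >= 1L) {
    idx <- seq_len(half)
    Y[1L + idx] <- X[1L + idx]
    Y[n_out + 1L - idx] <- X[n + 1L - idx]
  }
  if (n_out %% 2L == 0L) {
    # new Nyquist bin: average the two conjugate source bins to stay real
    Y[n_out / 2L + 1L] <- Re(X[n_out / 2L + 1L])
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Alpha/delta power ratio (wakefulness proxy)
#'
#' Log of the ratio of alpha-band (8-12 Hz) to delta-band (0.5-4 Hz) Welch
#' power, averaged over channels. High values indicate alpha-dominant
#' (awake) iEEG; low values delta-dominant (sleep) iEEG.
#'
#' @param recording an `ieeg_recording` of at least 2 s.
#' @return a single ADR value (log power ratio).
#' @export
adr <- function(recording) {
  if (recording_duration(recording) < 2) stop("ADR requires at least 2 s of data")
  if (all(recording$data == 0)) stop("ADR undefined for an all-zero recording")
  sp <- welch_spectra(recording)
  alpha <- band_integral(sp$freq, sp$psd, 8, 12)
  delta <- band_integral(sp$freq, sp$psd, 0.5, 4)
  mean(log(alpha / delta))
}

#' Normalize an ADR series across a patient's candidate windows
#'
#' Z-normalization (mean 0, sd 1) of the per-window ADR values; the
#' wakefulness threshold (default -0.40) is applied on this normalized
#' scale. A zero-variance series maps to all zeros.
#'
#' @param adr_series numeric vector, length >= 2.
#' @return normalized series of the same length (order-preserving).
#' @export
normalize_adr <- function(adr_series) {
  if (length(adr_series) < 2L) stop("need at least 2 ADR values to normalize")
  s <- stats::sd(adr_series)
  if (!is.finite(s) || s == 0) return(rep(0, length(adr_series)))
  (adr_series - mean(adr_series)) / s
}

#' Select awake interictal clip windows
#'
#' Chooses up to `n_clips` one-minute windows uniformly at random among
#' eligible candidates. Candidate windows tile the stay on a `clip_len_s`
#' grid. A window is eligible when it does not overlap the first 72 h after
#' implantation or the +/- 2 h neighbourhood of any seizure, and its
#' normalized ADR is at or above `adr_threshold` (wakefulness).
#'
#' @param timeline_duration total recorded duration in seconds.
#' @param annotations an [annotation_set()].
#' @param adr_values raw ADR value per candidate window (recycled rules not
#'   applied; must match the candidate grid length), or `NULL` to skip the
#'   wakefulness filter.
#' @param n_clips number of clips requested.
#' @param clip_len_s clip length in seconds (default 60).
#' @param seed RNG seed for the uniform draw.
#' @param adr_threshold eligibility threshold on the normalized ADR scale.
#' @param post_implant_exclusion_s excluded period after implantation
#'   (default 72 h).
#' @param peri_seizure_exclusion_s excluded margin around each seizure
#'   (default 2 h).
#' @return numeric vector of selected window start times (seconds), possibly
#'   shorter than `n_clips` (with a warning) or empty with a `diagnostic`
#'   attribute when no window is eligible.
#' @export
select_clips <- function(timeline_duration, annotations, adr_values = NULL,
                         n_clips = 20, clip_len_s = 60, seed = 1,
                         adr_threshold = -0.40,
                         post_implant_exclusion_s = 72 * 3600,
                         peri_seizure_exclusion_s = 2 * 3600) {
  if (n_clips < 1) stop("`n_clips` must be >= 1")
  if (clip_len_s <= 0) stop("`clip_len_s` must be positive")
  starts <- seq(0, timeline_duration - clip_len_s, by = clip_len_s)
  if (timeline_duration < clip_len_s) starts <- numeric(0)
  ends <- starts + clip_len_s

  excl <- list(c(annotations$implant_time,
                 annotations$implant_time + post_implant_exclusion_s))
  for (sz in annotations$seizure_times) {
    excl <- c(excl, list(c(sz - peri_seizure_exclusion_s,
                           sz + peri_seizure_exclusion_s)))
  }
  eligible <- rep(TRUE, length(starts))
  for (iv in excl) {
    eligible <- eligible & (ends <= iv[1] | starts >= iv[2])
  }
  if (!is.null(adr_values)) {
    if (length(adr_values) != length(starts)) {
      stop("`adr_values` length (", length(adr_values),
           ") must match the candidate-window grid (", length(starts), ")")
    }
    if (length(adr_values) >= 2L) {
      eligible <- eligible & (normalize_adr(adr_values) >= adr_threshold)
    }
  }
  elig_starts <- starts[eligible]
  if (length(elig_starts) == 0L) {
    out <- numeric(0)
    attr(out, "diagnostic") <- sprintf(
      "no eligible windows: %d candidates, all excluded by implant/seizure/ADR rules",
      length(starts))
    return(out)
  }
  set.seed(seed)
  k <- min(n_clips, length(elig_starts))
  if (k < n_clips) {
    warning("only ", k, " eligible windows for ", n_clips, " requested clips")
  }
  sort(sample(elig_starts, k, replace = FALSE))
}
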