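#' Canonical iEEG frequency bands
#'
#' The five canonical bands plus broadband used throughout the pipeline:
#' delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz,
#' gamma 30-80 Hz, broadband 0.5-80 Hz. Band intervals are treated as
#' `[lo, hi)` so the five narrow bands partition broadband exactly.
#'
#' @param include_broadband include the 0.5-80 Hz broadband row.
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
canonical_bands <- function(include_broadband = TRUE) {
  b <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma", "broadband"),
    lo   = c(0.5, 4, 8, 12, 30, 0.5),
    hi   = c(4, 8, 12, 30, 80, 80),
    stringsAsFactors = FALSE
  )
  if (!include_broadband) b <- b[b$name != "broadband", ]
  b
}

band_names <- function() canonical_bands(TRUE)$name

narrow_band_names <- function() canonical_bands(FALSE)$name
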