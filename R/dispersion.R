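#' Standard distance of an electrode point cloud (implant distance)
#'
#' The 3-D standard deviation of contact coordinates: the square root of the
#' summed per-axis population variances (divide-by-n), i.e. the square root
#' of the trace of the population covariance of the point cloud. A large
#' value indicates spatially broad electrode coverage; a small value compact
#' coverage. Units are those of the coordinates (mm).
#'
#' The square root makes the statistic a distance in mm; `sqrt = FALSE`
#' returns the summed variance form instead.
#'
#' @param coords numeric matrix, n x 3 (mm), n >= 2.
#' @param sqrt apply the square root (default `TRUE`).
#' @return standard distance in mm.
#' @export
standard_distance <- function(coords, sqrt = TRUE) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("standard distance needs at least 2 contacts")
  if (ncol(coords) != 3L) stop("`coords` must be n x 3")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  ctr <- colMeans(coords)
  ss <- sum(sweep(coords, 2L, ctr)^2) / nrow(coords)
  if (sqrt) base::sqrt(ss) else ss
}

#' Weighted standard distance (abnormality distance)
#'
#' The standard distance with each contact weighted by a nonnegative
#' abnormality value: the square root of the summed per-axis weighted
#' variances about the weighted mean center
#' \eqn{\bar{X}_w = \sum w_i x_i / \sum w_i}. Equal weights reduce it to
#' [standard_distance()]. A small value means abnormality is spatially
#' concentrated; a large value means it is dispersed.
#'
#' @param coords numeric matrix, n x 3 (mm), n >= 2.
#' @param weights nonnegative weights, length n, at least two strictly
#'   positive.
#' @param sqrt apply the square root (default `TRUE`).
#' @return weighted standard distance in mm.
#' @export
weighted_standard_distance <- function(coords, weights, sqrt = TRUE) {
  coords <- as.matrix(coords)
  weights <- as.numeric(weights)
  if (nrow(coords) < 2L) stop("weighted standard distance needs at least 2 contacts")
  if (ncol(coords) != 3L) stop("`coords` must be n x 3")
  if (length(weights) != nrow(coords)) stop("one weight per contact required")
  if (anyNA(weights) || any(weights < 0)) stop("weights must be nonnegative and non-missing")
  if (sum(weights) <= 0) stop("weights must not be all zero")
  ctr <- colSums(coords * weights) / sum(weights)
  ss <- sum(weights * rowSums(sweep(coords, 2L, ctr)^2)) / sum(weights)
  out <- if (sqrt) base::sqrt(ss) else ss
  attr(out, "weighted_center") <- ctr
  out
}

#' Per-patient dispersion summary
#'
#' Computes the implant distance (standard distance over gray-matter
#' contacts) and one abnormality distance (weighted standard distance) per
#' abnormality feature. Contacts with a missing weight for a feature are
#' dropped from that feature's WSD (never zero-weighted); a feature with
#' fewer than `min_contacts` weighted contacts yields a missing distance.
#'
#' @param electrode_table data.frame with columns `label`, `x`, `y`, `z`,
#'   `roi`, `tissue` (`tissue` in gray/white/outside).
#' @param abnormality an `abnormality_map` (see [aggregate_abnormality()]),
#'   or a plain contacts x features weight matrix with rownames matching
#'   `electrode_table$label`.
#' @param min_contacts minimum weighted contacts per feature (default 3).
#' @return list of class `dispersion_result`: `implant_distance` (mm),
#'   `abnormality_distance` (named vector, mm, one per feature),
#'   `weighted_center` (per feature), `n_contacts_used`.
#' @export
patient_dispersion <- function(electrode_table, abnormality, min_contacts = 3L) {
  gray <- electrode_table[electrode_table$tissue == "gray", , drop = FALSE]
  if (nrow(gray) < 2L) stop("need at least 2 gray-matter contacts")
  coords <- as.matrix(gray[, c("x", "y", "z")])
  rownames(coords) <- gray$label

  weights <- if (inherits(abnormality, "abnormality_map")) abnormality$weights else abnormality
  weights <- as.matrix(weights)
  common <- intersect(gray$label, rownames(weights))

  implant <- standard_distance(coords)
  feats <- colnames(weights)
  abn <- stats::setNames(rep(NA_real_, length(feats)), feats)
  centers <- stats::setNames(vector("list", length(feats)), feats)
  for (f in feats) {
    w <- weights[common, f]
    ok <- !is.na(w)
    if (sum(ok) >= min_contacts && sum(w[ok]) > 0 && sum(w[ok] > 0) >= 2L) {
      d <- weighted_standard_distance(coords[common[ok], , drop = FALSE], w[ok])
      abn[f] <- as.numeric(d)
      centers[[f]] <- attr(d, "weighted_center")
    }
  }
  structure(
    list(implant_distance = implant, abnormality_distance = abn,
         weighted_center = centers, n_contacts_used = nrow(gray)),
    class = "dispersion_result"
  )
}
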