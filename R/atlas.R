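# Normative atlas: pooled distributions of iEEG features from contacts
# presumed healthy, used as the reference for z-scoring patient features.

node_key <- function(roi, band, kind) paste(roi, band, kind, sep = "|")
edge_key <- function(roi_a, roi_b, band) {
  lo <- pmin(roi_a, roi_b); hi <- pmax(roi_a, roi_b)
  paste(lo, hi, band, sep = "|")
}

summarize_cells <- function(values_by_key) {
  keys <- names(values_by_key)
  data.frame(
    key = keys,
    mean = vapply(values_by_key, mean, 0),
    sd = vapply(values_by_key, stats::sd, 0),
    n = vapply(values_by_key, length, 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Build a normative iEEG atlas from designated-normal contacts
#'
#' Pools per-contact relative band power (node cells, keyed by ROI and band)
#' and pairwise coherence (edge cells, keyed by unordered ROI pair and band)
#' across subjects, restricted to contacts flagged normal. Each cell stores
#' the pooled mean, sample standard deviation, and count; cells with fewer
#' than 2 values or zero spread are marked unusable and propagate as missing
#' when applied.
#'
#' @param features_list list of `contact_features`, one per subject.
#' @param electrode_tables list of electrode tables (same order), each with
#'   columns `label`, `roi`, `tissue`.
#' @param normal_masks list of logical vectors (same order), named by contact
#'   label; `TRUE` marks a presumed-healthy contact. Masked-in contacts must
#'   be in gray matter.
#' @return object of class `normative_atlas` with `nodes` and `edges`
#'   data.frames (`roi`/`roi_a`,`roi_b`, `band`, `kind`, `mean`, `sd`, `n`,
#'   `usable`).
#' @export
build_atlas <- function(features_list, electrode_tables, normal_masks) {
  if (length(features_list) == 0L) stop("no subjects supplied")
  stopifnot(length(features_list) == length(electrode_tables),
            length(features_list) == length(normal_masks))
  node_vals <- list(); edge_vals <- list()
  for (s in seq_along(features_list)) {
    et <- electrode_tables[[s]]
    mask <- normal_masks[[s]]
    norm_labels <- names(mask)[mask]
    row <- match(norm_labels, et$label)
    if (anyNA(row)) stop("normal mask names missing from electrode table")
    if (any(et$tissue[row] != "gray")) {
      stop("every masked-in normal contact must have a gray-matter ROI label")
    }
    rois <- stats::setNames(et$roi[row], norm_labels)
    rp <- features_list[[s]]$rel_power
    co <- features_list[[s]]$coherence
    bands <- colnames(rp)
    for (lab in intersect(norm_labels, rownames(rp))) {
      for (b in bands) {
        v <- rp[lab, b]
        if (is.na(v)) next
        k <- node_key(rois[lab], b, "power")
        node_vals[[k]] <- c(node_vals[[k]], v)
      }
    }
    labs <- intersect(norm_labels, dimnames(co)[[1]])
    if (length(labs) >= 2L) {
      pairs <- utils::combn(labs, 2L)
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1L, j]; b2 <- pairs[2L, j]
        for (b in dimnames(co)[[3]]) {
          v <- co[a, b2, b]
          if (is.na(v)) next
          k <- edge_key(rois[a], rois[b2], b)
          edge_vals[[k]] <- c(edge_vals[[k]], v)
        }
      }
    }
  }
  nodes <- summarize_cells(node_vals)
  parts <- do.call(rbind, strsplit(nodes$key, "|", fixed = TRUE))
  nodes <- data.frame(roi = parts[, 1], band = parts[, 2], kind = parts[, 3],
                      nodes[, c("mean", "sd", "n")], stringsAsFactors = FALSE)
  edges <- summarize_cells(edge_vals)
  parts <- do.call(rbind, strsplit(edges$key, "|", fixed = TRUE))
  edges <- data.frame(roi_a = parts[, 1], roi_b = parts[, 2], band = parts[, 3],
                      edges[, c("mean", "sd", "n")], stringsAsFactors = FALSE)
  new_atlas(nodes, edges)
}

new_atlas <- function(nodes, edges) {
  nodes$usable <- nodes$n >= 2L & is.finite(nodes$sd) & nodes$sd > 0
  edges$usable <- edges$n >= 2L & is.finite(edges$sd) & edges$sd > 0
  structure(list(nodes = nodes, edges = edges), class = "normative_atlas")
}

#' @export
print.normative_atlas <- function(x, ...) {
  cat(sprintf("<normative_atlas> %d node cells, %d edge cells (%d/%d usable)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$nodes$usable), sum(x$edges$usable)))
  invisible(x)
}

#' Z-score a node (contact) feature against the atlas
#'
#' `(value - cell mean) / cell sd` for the cell matching the contact's ROI,
#' band and feature kind. Missing or unusable cells yield `NA` with a
#' diagnostic attribute rather than an error, so batch application can
#' proceed contact by contact.
#'
#' @param value observed feature value.
#' @param roi parcellation ROI of the contact.
#' @param band band name.
#' @param atlas a `normative_atlas`.
#' @param kind feature kind (default `"power"`).
#' @return z-score, or `NA` with attribute `diagnostic`.
#' @export
zscore_node <- function(value, roi, band, atlas, kind = "power") {
  nd <- atlas$nodes
  i <- which(nd$roi == roi & nd$band == band & nd$kind == kind)
  if (length(i) != 1L || !nd$usable[i]) {
    out <- NA_real_
    attr(out, "diagnostic") <- sprintf("no usable atlas cell for (%s, %s, %s)", roi, band, kind)
    return(out)
  }
  (value - nd$mean[i]) / nd$sd[i]
}

#' Z-score an edge (connection) feature against the atlas
#'
#' As [zscore_node()] for a coherence value between two ROIs; the ROI pair is
#' unordered.
#'
#' @param value observed coherence.
#' @param roi_a,roi_b the two ROIs (order-free).
#' @param band band name.
#' @param atlas a `normative_atlas`.
#' @return z-score, or `NA` with attribute `diagnostic`.
#' @export
zscore_edge <- function(value, roi_a, roi_b, band, atlas) {
  ed <- atlas$edges
  lo <- min(roi_a, roi_b); hi <- max(roi_a, roi_b)
  i <- which(ed$roi_a == lo & ed$roi_b == hi & ed$band == band)
  if (length(i) != 1L || !ed$usable[i]) {
    out <- NA_real_
    attr(out, "diagnostic") <- sprintf("no usable atlas cell for (%s--%s, %s)", roi_a, roi_b, band)
    return(out)
  }
  (value - ed$mean[i]) / ed$sd[i]
}

#' Z-score one clip's features against the atlas
#'
#' Applies [zscore_node()] to every gray-matter contact x band relative-power
#' value and [zscore_edge()] to every gray-gray contact pair x band coherence
#' value. White-matter and outside-brain contacts are excluded before any
#' z-scoring.
#'
#' @param features a `contact_features` object for one clip.
#' @param electrode_table electrode table with `label`, `roi`, `tissue`.
#' @param atlas a `normative_atlas`.
#' @return list with `z_node` (contacts x bands) and `z_edge` (contacts x
#'   contacts x bands, symmetric, `NA` diagonal).
#' @export
apply_atlas <- function(features, electrode_table, atlas) {
  gray <- electrode_table[electrode_table$tissue == "gray", , drop = FALSE]
  labs <- intersect(gray$label, rownames(features$rel_power))
  rois <- stats::setNames(gray$roi[match(labs, gray$label)], labs)
  bands <- colnames(features$rel_power)
  z_node <- matrix(NA_real_, length(labs), length(bands),
                   dimnames = list(labs, bands))
  for (lab in labs) for (b in bands) {
    z_node[lab, b] <- zscore_node(features$rel_power[lab, b], rois[lab], b, atlas)
  }
  z_edge <- array(NA_real_, dim = c(length(labs), length(labs), length(bands)),
                  dimnames = list(labs, labs, bands))
  if (length(labs) >= 2L) {
    pairs <- utils::combn(labs, 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b2 <- pairs[2L, j]
      for (b in bands) {
        z <- zscore_edge(features$coherence[a, b2, b], rois[a], rois[b2], b, atlas)
        z_edge[a, b2, b] <- z
        z_edge[b2, a, b] <- z
      }
    }
  }
  list(z_node = z_node, z_edge = z_edge)
}

#' Aggregate per-clip z-scores into one abnormality weight per contact
#'
#' Reduces the distribution of z-scores over interictal clips to a single
#' nonnegative abnormality per contact and feature: the per-clip node
#' abnormality is `|z|`, the per-clip edge abnormality of a contact is the
#' mean `|z|` over its incident edges, and the across-clip reduction is the
#' median (configurable to mean or max). These aggregates are the weights
#' used by [weighted_standard_distance()].
#'
#' @param z_clips list of per-clip results from [apply_atlas()].
#' @param agg across-clip reduction: `"median"` (default), `"mean"`, `"max"`.
#' @param edge_reduce within-clip incident-edge reduction: `"mean"`
#'   (default), `"median"`, `"max"`.
#' @return object of class `abnormality_map` with `weights`: a contacts x
#'   features matrix, features named `power_<band>` and `coherence_<band>`.
#'   Contacts with no usable value for a feature are `NA` (flagged, never
#'   zero-filled).
#' @export
aggregate_abnormality <- function(z_clips, agg = c("median", "mean", "max"),
                                  edge_reduce = c("mean", "median", "max")) {
  agg <- match.arg(agg)
  edge_reduce <- match.arg(edge_reduce)
  if (length(z_clips) < 1L) stop("need at least one clip")
  red <- function(v, how) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_real_)
    switch(how, median = stats::median(v), mean = mean(v), max = max(v))
  }
  labs <- rownames(z_clips[[1L]]$z_node)
  bands <- colnames(z_clips[[1L]]$z_node)
  feats <- c(paste0("power_", bands), paste0("coherence_", bands))
  weights <- matrix(NA_real_, length(labs), length(feats),
                    dimnames = list(labs, feats))
  for (b in bands) {
    node_mat <- vapply(z_clips, function(z) abs(z$z_node[, b]), numeric(length(labs)))
    node_mat <- matrix(node_mat, nrow = length(labs))
    weights[, paste0("power_", b)] <- apply(node_mat, 1L, red, how = agg)
    edge_mat <- vapply(z_clips, function(z) {
      apply(abs(z$z_edge[, , b, drop = TRUE]), 1L, red, how = edge_reduce)
    }, numeric(length(labs)))
    edge_mat <- matrix(edge_mat, nrow = length(labs))
    weights[, paste0("coherence_", b)] <- apply(edge_mat, 1L, red, how = agg)
  }
  dropped <- labs[apply(weights, 1L, function(r) all(is.na(r)))]
  if (length(dropped) > 0L) {
    warning("contact(s) with no usable z-score in any clip: ",
            paste(dropped, collapse = ", "))
  }
  structure(list(weights = weights, agg = agg, edge_reduce = edge_reduce),
            class = "abnormality_map")
}

#' Read / write the atlas JSON schema
#'
#' Schema: `{"nodes": [{"roi","band","kind","mean","sd","n"}], "edges":
#' [{"roi_a","roi_b","band","mean","sd","n"}]}`, compatible with externally
#' supplied atlases re-exported to this layout.
#'
#' @param atlas a `normative_atlas`.
#' @param path file path.
#' @return `write_atlas_json` returns `path` invisibly; `read_atlas_json`
#'   returns a `normative_atlas`.
#' @export
write_atlas_json <- function(atlas, path) {
  jsonlite::write_json(
    list(nodes = atlas$nodes[, c("roi", "band", "kind", "mean", "sd", "n")],
         edges = atlas$edges[, c("roi_a", "roi_b", "band", "mean", "sd", "n")]),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_atlas_json
#' @export
read_atlas_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$nodes$kind)) x$nodes$kind <- "power"
  new_atlas(x$nodes, x$edges)
}
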