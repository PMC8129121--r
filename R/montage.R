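#' Electrode clusters defining the four regions of interest
#'
#' The analysis operates on four clusters of 10-20 electrodes: left and
#' right frontal (4 electrodes each) and left and right parieto-occipital
#' (3 electrodes each), 14 electrodes in total.
#'
#' @return Named list of character vectors of electrode labels.
#' @export
#' @examples
#' electrode_clusters()
electrode_clusters <- function() {
  list(
    frontal_L   = c("F1", "FC1", "C1", "FC3"),
    frontal_R   = c("F2", "FC2", "C2", "FC4"),
    posterior_L = c("PO7", "PO3", "O1"),
    posterior_R = c("PO8", "PO4", "O2")
  )
}

#' Fixed electrode ordering of the 14-channel cluster connectivity matrix
#' @return Character vector of 14 labels.
#' @export
cluster_electrode_order <- function() {
  unlist(electrode_clusters(), use.names = FALSE)
}

#' Standard montage label sets
#'
#' `montage_cluster14()` is the minimal montage carrying exactly the 14
#' cluster electrodes. `montage_std64()` is a standard 64-label 10-10
#' montage superset.
#'
#' @return Character vector of channel labels.
#' @export
montage_cluster14 <- function() cluster_electrode_order()

#' @rdname montage_cluster14
#' @export
montage_std64 <- function() {
  c("FP1", "FPZ", "FP2", "AF7", "AF3", "AFZ", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POZ", "PO4", "PO8", "O1", "OZ", "O2",
    "TP9", "TP10", "PO9", "PO10")
}

# Planar (x, y) coordinates for 10-10 labels on a unit head: y from the
# anterior-posterior row letter, x from the lateral index (odd = left).
montage_positions <- function(labels) {
  labels <- toupper(labels)
  row_y <- c(FP = 0.95, AF = 0.75, F = 0.55, FT = 0.30, FC = 0.30,
             T = 0.00, C = 0.00, TP = -0.30, CP = -0.30,
             P = -0.55, PO = -0.75, O = -0.95)
  pos <- t(vapply(labels, function(lb) {
    m <- regmatches(lb, regexec("^([A-Z]+?)(Z|[0-9]+)$", lb))[[1]]
    if (length(m) != 3L) stop("cannot parse electrode label: ", lb)
    row <- m[2]; idx <- m[3]
    if (!row %in% names(row_y)) stop("unknown electrode row: ", lb)
    y <- row_y[[row]]
    if (idx == "Z") {
      x <- 0
    } else {
      n <- as.integer(idx)
      side <- if (n %% 2L == 1L) -1 else 1
      x <- side * 0.18 * ceiling(n / 2)
    }
    c(x = x, y = y)
  }, numeric(2)))
  rownames(pos) <- labels
  pos
}

#' Spatial topography of a source over a montage
#'
#' Gaussian-falloff weights centred on the centroid of the source's
#' electrode cluster; the weight peaks (value 1) over the cluster.
#'
#' @param montage character vector of channel labels.
#' @param cluster character vector of the source's cluster electrodes.
#' @param sigma falloff width on the unit-head planar montage.
#' @return Numeric weight vector, one entry per montage channel.
#' @export
source_topography <- function(montage, cluster, sigma = 0.25) {
  pos <- montage_positions(montage)
  missing <- setdiff(toupper(cluster), rownames(pos))
  if (length(missing) > 0)
    stop("montage missing cluster electrodes: ", paste(missing, collapse = ", "))
  centroid <- colMeans(pos[toupper(cluster), , drop = FALSE])
  d2 <- (pos[, "x"] - centroid["x"])^2 + (pos[, "y"] - centroid["y"])^2
  w <- exp(-d2 / (2 * sigma^2))
  w / max(w)
}

#' Topography templates of the four regions of interest
#'
#' One unit-norm spatial template per ROI over the given montage, used by
#' [match_templates()] to identify which decomposition components carry
#' each ROI's activity.
#'
#' @param montage character vector of channel labels.
#' @return channels x 4 numeric matrix with ROI names as column names.
#' @export
topography_templates <- function(montage = montage_cluster14()) {
  cl <- electrode_clusters()
  tmpl <- vapply(cl, function(cluster) {
    w <- source_topography(montage, cluster)
    w / sqrt(sum(w^2))
  }, numeric(length(montage)))
  rownames(tmpl) <- toupper(montage)
  tmpl
}
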