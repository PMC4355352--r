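# Between-group analysis: ordination on group centroids with samples
# projected onto the discriminant axes.

#' Between-group analysis of an expression matrix
#'
#' Probe-centered data are summarized by their group centroids; principal
#' axes are computed on the centroid matrix weighted by group sizes, and
#' every data set is projected onto those axes. With g groups at most g - 1
#' axes carry between-group inertia.
#'
#' @param x Numeric matrix, probes x data sets.
#' @param labels Group label per column (e.g. growth stage).
#' @return An object of class `bga_result`: `axes` (probe loadings),
#'   `sample_scores` (data sets x axes), `group_centroids` (groups x axes),
#'   `inertia_explained`, `labels`.
#' @export
between_group_analysis <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != ncol(x))
    stop("labels must match the number of data sets (columns)")
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 groups")
  if (any(counts < 2))
    stop("group(s) with a single member: ",
         paste(names(counts)[counts < 2], collapse = ", "))

  xc <- x - rowMeans(x)
  groups <- names(counts)
  centroids <- vapply(groups,
                      function(g) rowMeans(xc[, labels == g, drop = FALSE]),
                      numeric(nrow(xc)))
  w <- as.numeric(counts) / ncol(x)
  sv <- svd(centroids %*% diag(sqrt(w), length(w)))
  n_axes <- length(groups) - 1
  axes <- sv$u[, seq_len(n_axes), drop = FALSE]
  ev <- sv$d[seq_len(n_axes)]^2
  inertia <- if (sum(sv$d^2) > 0) ev / sum(sv$d^2) else rep(0, n_axes)

  scores <- crossprod(xc, axes)
  rownames(scores) <- colnames(x)
  cent_scores <- crossprod(centroids, axes)
  rownames(cent_scores) <- groups
  colnames(scores) <- colnames(cent_scores) <- colnames(axes) <-
    paste0("Axis", seq_len(n_axes))
  structure(list(axes = axes, sample_scores = scores,
                 group_centroids = cent_scores,
                 inertia_explained = inertia, labels = labels),
            class = "bga_result")
}

#' Group-separation score of a between-group analysis
#'
#' Mean silhouette width of the data-set scores in BGA space under the group
#' labels: near 1 for cleanly segregated groups, near 0 for arbitrary labels,
#' negative for overlapping/mixed groups.
#'
#' @param result A `bga_result`.
#' @return Scalar in \[-1, 1\].
#' @export
separation_score <- function(result) {
  scores <- result$sample_scores
  d <- stats::dist(scores)
  if (max(d) <= .Machine$double.eps) return(0)  # degenerate: all points coincide
  sil <- cluster::silhouette(as.integer(factor(result$labels)), d)
  mean(sil[, "sil_width"])
}
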