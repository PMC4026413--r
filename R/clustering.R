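# Heatmap preparation: gene-wise z-transform and complete-linkage
# hierarchical clustering of rows (columns are left in design order).

#' Gene-wise z-transform
#'
#' Centers and scales each row to mean 0 and sample standard deviation 1
#' (n - 1 denominator). Constant rows become all-zero and are flagged in
#' the `constant_rows` attribute.
#'
#' @param m numeric matrix with at least 2 columns.
#' @return the transformed matrix; `attr(, "constant_rows")` is a
#'   logical vector marking rows with zero variance.
#' @export
z_transform_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) lel_error("lel_invalid_input", "z-transform needs at least 2 columns")
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  constant <- s == 0 | !is.finite(s)
  s[constant] <- 1
  z <- (m - mu) / s
  z[constant, ] <- 0
  attr(z, "constant_rows") <- constant
  z
}

#' Complete-linkage hierarchical clustering of rows
#'
#' Agglomerative clustering with Euclidean distance and complete linkage
#' (`D(A, B)` = maximum pairwise distance), as used to re-order heatmap
#' rows. Delegates to [stats::hclust()].
#'
#' @param m numeric matrix with at least 2 rows and no non-finite
#'   values.
#' @return an object of class `hclust` (merge sequence, heights, leaf
#'   order).
#' @export
hierarchical_cluster <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) lel_error("lel_invalid_input", "clustering needs at least 2 rows")
  if (any(!is.finite(m))) lel_error("lel_invalid_input", "matrix contains non-finite values")
  stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
}

#' Prepare a matrix for heatmap display
#'
#' Z-transforms rows and re-orders them by complete-linkage hierarchical
#' clustering.
#'
#' @param m numeric matrix (e.g. the glog expression of selected
#'   probes).
#' @return list with `z` (row-reordered z-matrix), `order` (row
#'   permutation), and `hclust` (the dendrogram).
#' @export
heatmap_prepare <- function(m) {
  z <- z_transform_rows(m)
  hc <- hierarchical_cluster(z)
  list(z = z[hc$order, , drop = FALSE], order = hc$order, hclust = hc)
}
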