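#' Restrict a methylation matrix to the most variable loci
#'
#' Ranks loci by the across-sample variance of beta and keeps the top `k`,
#' discarding noisy and uninformative (near-constant) loci before
#' clustering. Ties in variance are broken by genomic position
#' (chromosome, then position) for determinism.
#'
#' @param matrix A `meth_matrix`.
#' @param k Number of loci to keep, default 10000; if fewer loci exist,
#'   all are kept with a warning.
#' @return The restricted `meth_matrix`.
#' @export
select_top_variance_loci <- function(matrix, k = 10000) {
  n <- nrow(matrix$beta)
  if (n <= k) {
    if (n < k) warning("only ", n, " loci available; keeping all")
    return(matrix)
  }
  v <- apply(matrix$beta, 1L, stats::var, na.rm = TRUE)
  v[is.na(v)] <- -Inf
  ord <- order(-v, matrix$loci$chrom, matrix$loci$pos)
  keep <- sort(ord[seq_len(k)])
  subset_meth_matrix(matrix, keep)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on Euclidean distances between
#' their beta profiles. The optional covariance mode clusters on Euclidean
#' distances between the rows of the sample-by-sample covariance matrix of
#' the beta profiles instead of the profiles themselves.
#'
#' @param matrix A `meth_matrix` (typically after
#'   [select_top_variance_loci()]).
#' @param linkage Agglomeration method passed to [stats::hclust()];
#'   default "average".
#' @param mode "profiles" (default) or "covariance".
#' @return List of class `cluster_result`: `hclust` (the merge tree),
#'   `leaf_order` (sample labels in dendrogram order) and `dist`.
#' @export
hierarchical_cluster <- function(matrix, linkage = "average",
                                 mode = c("profiles", "covariance")) {
  mode <- match.arg(mode)
  if (ncol(matrix$beta) < 2L) stop("need at least 2 samples to cluster")
  x <- if (mode == "profiles") t(matrix$beta)
       else stats::cov(matrix$beta, use = "pairwise.complete.obs")
  d <- stats::dist(x, method = "euclidean")
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order], dist = d),
            class = "cluster_result")
}

#' Flat cluster labels at a cut
#' @param result A `cluster_result`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(result, k) {
  stats::cutree(result$hclust, k = k)
}

#' Write a dendrogram in Newick format
#' @param result A `cluster_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(result, path) {
  ape::write.tree(ape::as.phylo(result$hclust), file = path)
  invisible(path)
}
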