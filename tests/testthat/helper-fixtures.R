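# Shared fixtures: hand-built methylation matrices and tiny count tables.

# meth_matrix directly from a beta matrix (array-like: no counts).
mm_from_beta <- function(beta, groups, chrom = NULL, pos = NULL) {
  n <- nrow(beta)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  ids <- colnames(beta)
  if (is.null(ids)) {
    ids <- paste0("s", seq_len(ncol(beta)))
    colnames(beta) <- ids
  }
  structure(list(loci = data.frame(chrom = chrom, pos = as.integer(pos),
                                   stringsAsFactors = FALSE),
                 beta = beta, m = compute_m(beta),
                 coverage = NULL, meth = NULL,
                 groups = stats::setNames(
                   factor(groups, levels = unique(groups)), ids),
                 cte = 0.01),
            class = "meth_matrix")
}

# meth_matrix from count matrices (RRBS-like).
mm_from_counts <- function(meth, cov, groups, chrom = NULL, pos = NULL) {
  out <- mm_from_beta(meth / cov, groups, chrom, pos)
  dimnames(meth) <- dimnames(cov) <- dimnames(out$beta)
  out$meth <- meth
  out$coverage <- cov
  out
}

# Small two-group count-table list with a fixed seed.
toy_tables <- function(n_loci = 20, n_per_group = 3, coverage = 20,
                       seed = 42) {
  set.seed(seed)
  pos <- sort(sample.int(5000L, n_loci))
  beta <- runif(n_loci, 0.1, 0.9)
  ids <- c(paste0("control_", seq_len(n_per_group)),
           paste0("tumour_", seq_len(n_per_group)))
  tables <- lapply(ids, function(id)
    cpg_counts(id, chrom = rep("chr1", n_loci), pos = pos,
               n_meth = rbinom(n_loci, coverage, beta),
               n_total = rep(coverage, n_loci)))
  groups <- stats::setNames(
    factor(rep(c("control", "tumour"), each = n_per_group),
           levels = c("control", "tumour")), ids)
  list(tables = tables, groups = groups)
}

expect_same_partition <- function(labels, groups) {
  tab <- table(labels, groups)
  expect_true(all(apply(tab > 0, 1, sum) == 1) &&
                all(apply(tab > 0, 2, sum) == 1))
}
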