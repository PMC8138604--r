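#' Beta-value from read counts
#'
#' Methylation fraction at a locus: methylated reads over total reads.
#'
#' @param n_meth Methylated read count(s).
#' @param n_total Total read count(s); must be positive.
#' @return Numeric fraction(s) in `[0, 1]`.
#' @export
compute_beta <- function(n_meth, n_total) {
  if (any(n_total == 0)) stop("n_total must be positive to compute beta")
  if (any(n_meth < 0) || any(n_meth > n_total))
    stop("n_meth must lie in [0, n_total]")
  n_meth / n_total
}

#' M-value transform of beta
#'
#' `M = log2((beta + cte) / (1 - beta + cte))` with a small stabilising
#' constant keeping the transform finite at beta 0 and 1. M-values have the
#' near-constant variance that linear modelling assumes, while beta stays
#' the interpretable scale.
#'
#' @param beta Methylation fraction(s) in `[0, 1]`.
#' @param cte Stabilising constant, default 0.01.
#' @return M-value(s).
#' @export
compute_m <- function(beta, cte = 0.01) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta must lie in [0, 1]")
  log2((beta + cte) / (1 - beta + cte))
}

#' Inverse of the M-value transform
#' @param m M-value(s).
#' @param cte Stabilising constant used in the forward transform.
#' @return Beta fraction(s).
#' @export
beta_from_m <- function(m, cte = 0.01) {
  r <- 2^m
  (r * (1 + cte) - cte) / (1 + r)
}

#' Merge technical replicates by summing counts
#'
#' Technical replicates of the same biological sample are collapsed into a
#' single table by summing methylated and total read counts per locus; a
#' locus present in only some replicates keeps the counts it has.
#'
#' @param tables List of [cpg_counts()] tables.
#' @param replicate_map Named character vector mapping each sample id to the
#'   id of the merged sample it belongs to.
#' @return List of merged `cpg_counts` tables, one per distinct target id,
#'   in first-appearance order.
#' @export
merge_technical_replicates <- function(tables, replicate_map) {
  ids <- vapply(tables, sample_id, "")
  unknown <- setdiff(names(replicate_map), ids)
  if (length(unknown))
    stop("replicate_map references unknown sample(s): ",
         paste(unknown, collapse = ", "))
  target <- ifelse(ids %in% names(replicate_map),
                   replicate_map[ids], ids)
  lapply(unique(target), function(tgt) {
    members <- tables[target == tgt]
    if (length(members) == 1L) {
      out <- members[[1L]]
      attr(out, "sample_id") <- tgt
      return(out)
    }
    all <- do.call(rbind, lapply(members, as.data.frame))
    key <- paste(all$chrom, all$pos)
    nm <- rowsum(all$n_meth, key)
    nt <- rowsum(all$n_total, key)
    first <- !duplicated(key)
    k <- key[first]
    cpg_counts(tgt, chrom = all$chrom[first], pos = all$pos[first],
               n_meth = nm[k, 1L], n_total = nt[k, 1L])
  })
}

#' Loci-by-samples methylation matrix
#'
#' Assembles per-sample count tables into aligned loci-by-samples matrices
#' of beta-values, M-values, coverage and methylated counts over the union
#' of loci; entries missing in a sample are `NA` (coverage 0).
#'
#' @param tables List of [cpg_counts()] tables.
#' @param groups Character/factor of group labels, one per table (named by
#'   sample id or in table order).
#' @param cte M-value stabilising constant.
#' @return Object of class `meth_matrix` with elements `loci` (data.frame
#'   `chrom`, `pos`), `beta`, `m`, `coverage`, `meth` (matrices) and
#'   `groups` (factor named by sample).
#' @export
build_meth_matrix <- function(tables, groups, cte = 0.01) {
  ids <- vapply(tables, sample_id, "")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  if (!is.null(names(groups))) groups <- groups[ids]
  if (length(groups) != length(tables))
    stop("one group label per sample required")
  keys <- lapply(tables, function(t) paste(t$chrom, t$pos, sep = ":"))
  all_df <- do.call(rbind, lapply(tables, function(t)
    data.frame(chrom = t$chrom, pos = t$pos, stringsAsFactors = FALSE)))
  all_key <- paste(all_df$chrom, all_df$pos, sep = ":")
  loci <- all_df[!duplicated(all_key), , drop = FALSE]
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  rownames(loci) <- NULL
  lkey <- paste(loci$chrom, loci$pos, sep = ":")
  n <- nrow(loci)
  cov <- meth <- matrix(NA_real_, n, length(tables),
                        dimnames = list(lkey, ids))
  for (j in seq_along(tables)) {
    idx <- match(keys[[j]], lkey)
    cov[idx, j] <- tables[[j]]$n_total
    meth[idx, j] <- tables[[j]]$n_meth
  }
  beta <- meth / cov
  structure(list(loci = loci, beta = beta, m = compute_m(beta, cte),
                 coverage = cov, meth = meth,
                 groups = stats::setNames(factor(as.character(groups)), ids),
                 cte = cte),
            class = "meth_matrix")
}

#' Methylation matrix from an array dataset
#'
#' Wraps array beta-values as a `meth_matrix` (no coverage; probes indexed
#' by annotated genomic position, falling back to a probe-ordinal position
#' for unannotated probes).
#'
#' @param ds An [array_dataset()].
#' @param groups Group labels per sample (named or in column order).
#' @param cte M-value stabilising constant.
#' @return A `meth_matrix` without `coverage`/`meth`.
#' @export
array_to_meth_matrix <- function(ds, groups, cte = 0.01) {
  ann <- ds$probe_annotation
  chrom <- ifelse(is.na(ann$chrom), "unplaced", ann$chrom)
  pos <- ifelse(is.na(ann$pos), seq_len(nrow(ann)), ann$pos)
  ids <- colnames(ds$beta)
  if (!is.null(names(groups))) groups <- groups[ids]
  beta <- ds$beta
  rownames(beta) <- ann$probe
  structure(list(loci = data.frame(chrom = chrom, pos = as.integer(pos),
                                   probe = ann$probe, gene = ann$gene,
                                   stringsAsFactors = FALSE),
                 beta = beta, m = compute_m(beta, cte),
                 coverage = NULL, meth = NULL,
                 groups = stats::setNames(factor(as.character(groups)), ids),
                 cte = cte),
            class = "meth_matrix")
}

#' Coverage and methylated-read filtering of RRBS loci
#'
#' Two quality rules: (i) a locus must reach the minimum coverage in every
#' sample (the across-sample minimum coverage must not fall below
#' `min_coverage`); (ii) summed across all samples, at least
#' `min_meth_reads_total` methylated reads must be present, so that some
#' methylation signal exists at the locus.
#'
#' @param matrix A `meth_matrix` with coverage (RRBS mode).
#' @param min_coverage Minimum per-sample coverage, default 8.
#' @param min_meth_reads_total Minimum summed methylated reads, default 6.
#' @return The filtered `meth_matrix`, with attribute `filter_counts`
#'   giving the number of loci removed by each rule (rule i applied first).
#' @export
filter_loci <- function(matrix, min_coverage = 8, min_meth_reads_total = 6) {
  if (is.null(matrix$coverage))
    stop("matrix has no coverage (array data); use filter_array_probes()")
  cov <- matrix$coverage
  cov[is.na(cov)] <- 0
  meth <- matrix$meth
  min_cov <- apply(cov, 1L, min)
  keep1 <- min_cov >= min_coverage
  total_meth <- rowSums(meth, na.rm = TRUE)
  keep2 <- total_meth >= min_meth_reads_total
  removed <- c(coverage = sum(!keep1), meth_reads = sum(keep1 & !keep2))
  out <- subset_meth_matrix(matrix, keep1 & keep2)
  attr(out, "filter_counts") <- removed
  out
}

subset_meth_matrix <- function(matrix, keep) {
  matrix$loci <- matrix$loci[keep, , drop = FALSE]
  rownames(matrix$loci) <- NULL
  for (f in c("beta", "m", "coverage", "meth"))
    if (!is.null(matrix[[f]]))
      matrix[[f]] <- matrix[[f]][keep, , drop = FALSE]
  matrix
}

#' Detection p-value filtering of array probes
#'
#' Removes probes whose detection p-value exceeds the threshold in any
#' sample.
#'
#' @param ds An [array_dataset()].
#' @param max_detection_p Threshold, default 0.01.
#' @return Filtered `array_dataset` with attribute `n_removed`.
#' @export
filter_array_probes <- function(ds, max_detection_p = 0.01) {
  bad <- apply(ds$detection_p > max_detection_p, 1L, any)
  out <- array_dataset(ds$beta[!bad, , drop = FALSE],
                       ds$detection_p[!bad, , drop = FALSE],
                       ds$probe_annotation[!bad, , drop = FALSE])
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Group comparison of average methylation
#'
#' Computes each sample's mean beta over the retained loci and compares
#' group averages by one-way ANOVA, with Tukey HSD contrasts when more than
#' two groups are present. With exactly two groups the ANOVA p-value equals
#' the two-sided pooled-variance t-test.
#'
#' @param matrix A `meth_matrix`.
#' @return List of class `group_mean_summary`: `sample_means`, `group_means`,
#'   `anova_f`, `anova_p` and a `contrasts` data.frame (estimate, p_adj,
#'   testable flag).
#' @export
average_methylation <- function(matrix) {
  sm <- colMeans(matrix$beta, na.rm = TRUE)
  gr <- matrix$groups
  if (nlevels(droplevels(gr)) < 2L) stop("need at least 2 groups")
  gr <- droplevels(gr)
  gm <- c(tapply(sm, gr, mean))
  sizes <- table(gr)
  df <- data.frame(y = sm, g = gr)
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1L]]
  degenerate <- stats::var(sm) < 1e-24  # all sample means identical
  if (degenerate) {
    an[["F value"]][1L] <- 0
    an[["Pr(>F)"]][1L] <- 1
  }
  pairs <- utils::combn(levels(gr), 2L)
  testable_all <- all(sizes >= 2L)
  if (degenerate) {
    contrasts <- data.frame(
      group1 = pairs[2L, ], group2 = pairs[1L, ], estimate = 0,
      p_adj = 1, testable = testable_all, row.names = NULL,
      stringsAsFactors = FALSE)
  } else if (nlevels(gr) > 2L && testable_all) {
    tk <- stats::TukeyHSD(fit)$g
    contrasts <- data.frame(
      group1 = pairs[2L, ], group2 = pairs[1L, ],
      estimate = tk[, "diff"], p_adj = tk[, "p adj"],
      testable = TRUE, row.names = NULL, stringsAsFactors = FALSE)
  } else {
    contrasts <- data.frame(
      group1 = pairs[2L, ], group2 = pairs[1L, ],
      estimate = gm[pairs[2L, ]] - gm[pairs[1L, ]],
      p_adj = if (testable_all) an[["Pr(>F)"]][1L] else NA_real_,
      testable = testable_all, row.names = NULL, stringsAsFactors = FALSE)
  }
  contrasts$testable <- contrasts$testable &
    sizes[contrasts$group1] >= 2L & sizes[contrasts$group2] >= 2L
  contrasts$p_adj[!contrasts$testable] <- NA_real_
  structure(list(sample_means = sm, group_means = gm,
                 anova_f = an[["F value"]][1L],
                 anova_p = an[["Pr(>F)"]][1L],
                 contrasts = contrasts),
            class = "group_mean_summary")
}

#' Pearson correlation with validity checks
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y, method = "pearson")
}

#' Hydroxymethylation estimate from paired BS / oxBS data
#'
#' Standard bisulfite conversion reads 5mC + 5hmC while the oxidative arm
#' reads 5mC only, so the per-locus difference `beta_BS - beta_oxBS`
#' estimates 5hmC (and may go negative through noise). The dataset-level
#' verdict compares the magnitude of the mean estimate with a multiple of
#' its standard error: when the mean does not exceed `z_mult` standard
#' errors, 5hmC is reported as indistinguishable from noise.
#'
#' @param bs,oxbs `meth_matrix` objects sharing loci and samples.
#' @param z_mult Standard-error multiple for the verdict, default 2.
#' @return List of class `hmc_assessment`: `estimate` (loci-by-samples
#'   matrix), `mean_estimate`, `se`, `z`, `verdict` ("noise" or "signal").
#' @export
assess_hydroxymethylation <- function(bs, oxbs, z_mult = 2) {
  if (!identical(bs$loci[c("chrom", "pos")], oxbs$loci[c("chrom", "pos")]) ||
      !identical(names(bs$groups), names(oxbs$groups)))
    stop("BS and oxBS matrices must share loci and samples")
  est <- bs$beta - oxbs$beta
  v <- as.vector(est)
  v <- v[!is.na(v)]
  m <- mean(v)
  se <- stats::sd(v) / sqrt(length(v))
  z <- if (se > 0) m / se else if (m == 0) 0 else Inf
  structure(list(estimate = est, mean_estimate = m, se = se, z = z,
                 verdict = if (abs(z) <= z_mult) "noise" else "signal"),
            class = "hmc_assessment")
}
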