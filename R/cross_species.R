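#' Assign differentially methylated loci to genes
#'
#' A locus maps to every gene whose body, or whose promoter window upstream
#' of the TSS, contains it; loci in neither map to no gene (intergenic).
#' A locus inside two overlapping genes (for example a pair on opposite
#' strands) is assigned to both.
#'
#' @param dm A `dm_result` with `chrom` and `pos` columns.
#' @param annotation A [gene_annotation()] table.
#' @param promoter_window_bp Promoter window upstream of the TSS, default
#'   1500.
#' @return data.frame with columns `locus` (row index into `dm`) and
#'   `gene`.
#' @export
annotate_loci_to_genes <- function(dm, annotation,
                                   promoter_window_bp = 1500) {
  ext_start <- ifelse(annotation$strand == "+",
                      pmax(1L, annotation$start - promoter_window_bp),
                      annotation$start)
  ext_end <- ifelse(annotation$strand == "+", annotation$end,
                    annotation$end + promoter_window_bp)
  genes <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(ext_start, ext_end))
  loci <- GenomicRanges::GRanges(dm$chrom, IRanges::IRanges(dm$pos, dm$pos))
  hits <- GenomicRanges::findOverlaps(loci, genes)
  data.frame(locus = S4Vectors::queryHits(hits),
             gene = annotation$symbol[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Per-gene differential methylation summary
#'
#' Collapses locus-level calls to gene level: the number of tested and
#' significant loci, the largest absolute beta-difference among significant
#' loci, the direction at that strongest locus, and two flags: `has_dm`
#' (any significant locus) and `has_clear_dm` (a significant locus with at
#' least `clear_delta` absolute beta-difference, i.e. clearly
#' differentially methylated).
#'
#' @param dm A `dm_result`.
#' @param assignments Locus-to-gene table from [annotate_loci_to_genes()].
#' @param clear_delta Clear-difference threshold on `|delta_beta|`,
#'   default 0.30.
#' @return data.frame of class `gene_dm_summary`, one row per gene with at
#'   least one tested locus.
#' @export
summarize_genes <- function(dm, assignments, clear_delta = 0.30) {
  assignments <- assignments[dm$testable[assignments$locus], , drop = FALSE]
  parts <- split(assignments$locus, assignments$gene)
  rows <- lapply(names(parts), function(g) {
    idx <- parts[[g]]
    sig <- idx[dm$significant[idx]]
    if (length(sig)) {
      top <- sig[which.max(abs(dm$delta_beta[sig]))]
      mx <- abs(dm$delta_beta[top])
      dir <- dm$direction[top]
    } else {
      mx <- NA_real_; dir <- NA_character_
    }
    data.frame(gene = g, n_tested_loci = length(idx),
               n_significant_loci = length(sig),
               max_abs_delta_beta = mx, direction = dir,
               has_dm = length(sig) > 0L,
               has_clear_dm = length(sig) > 0L && mx >= clear_delta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gene_dm_summary", "data.frame")
  out
}

# Pearson chi-squared (no continuity correction) on a 2x2 count table.
chisq_2x2 <- function(tab, correct = FALSE) {
  if (any(suppressWarnings(stats::chisq.test(tab))$expected < 5))
    warning("chi-squared expected cell count below 5")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Cross-species enrichment of differential methylation
#'
#' Tests, per human subtype, whether human orthologs of mouse genes with
#' differential methylation are themselves more often differentially
#' methylated than the remaining tested human genes, using a 2x2 Pearson
#' chi-squared test (no continuity correction) with Bonferroni adjustment
#' across subtypes.
#'
#' @param mouse_summary `gene_dm_summary` for the mouse dataset.
#' @param human_summaries Named list of `gene_dm_summary`, one per human
#'   subtype.
#' @param ortholog_map An `ortholog_map`.
#' @param n_subtype_tests Number of tests for Bonferroni; defaults to the
#'   number of subtypes supplied.
#' @param correct Continuity correction flag, default FALSE.
#' @return data.frame, one row per subtype: ortholog-set and baseline
#'   `has_dm` fractions, counts, chi-squared statistic, raw and adjusted p.
#' @export
enrichment_test <- function(mouse_summary, human_summaries, ortholog_map,
                            n_subtype_tests = length(human_summaries),
                            correct = FALSE) {
  mouse_dm <- mouse_summary$gene[mouse_summary$has_dm]
  target_human <- unique(
    ortholog_map$human_gene[ortholog_map$mouse_gene %in% mouse_dm])
  rows <- lapply(names(human_summaries), function(subtype) {
    hs <- human_summaries[[subtype]]
    in_set <- hs$gene %in% target_human
    tab <- rbind(set = c(dm = sum(hs$has_dm[in_set]),
                         not_dm = sum(!hs$has_dm[in_set])),
                 baseline = c(dm = sum(hs$has_dm[!in_set]),
                              not_dm = sum(!hs$has_dm[!in_set])))
    ct <- chisq_2x2(tab, correct)
    data.frame(subtype = subtype,
               n_set = sum(in_set), n_baseline = sum(!in_set),
               set_fraction = mean(hs$has_dm[in_set]),
               baseline_fraction = mean(hs$has_dm[!in_set]),
               statistic = ct$statistic, p_value = ct$p_value,
               p_adj = min(1, ct$p_value * n_subtype_tests),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-species direction concordance
#'
#' For genes differentially methylated in both species, computes per human
#' subtype the fraction whose direction of change (hyper/hypo) agrees
#' between mouse and human, and compares concordant/discordant counts
#' between the first two subtypes with a 2x2 Pearson chi-squared test.
#'
#' @inheritParams enrichment_test
#' @return List with `per_subtype` (gene counts and concordant fractions)
#'   and, when two or more subtypes each have shared genes, `statistic` and
#'   `p_value` for the between-subtype comparison (`testable = FALSE`
#'   otherwise).
#' @export
direction_concordance <- function(mouse_summary, human_summaries,
                                  ortholog_map, correct = FALSE) {
  mouse_dir <- stats::setNames(mouse_summary$direction, mouse_summary$gene)
  per <- lapply(names(human_summaries), function(subtype) {
    hs <- human_summaries[[subtype]]
    pairs <- ortholog_map[
      ortholog_map$mouse_gene %in%
        mouse_summary$gene[mouse_summary$has_dm] &
      ortholog_map$human_gene %in% hs$gene[hs$has_dm], , drop = FALSE]
    hdir <- stats::setNames(hs$direction, hs$gene)
    conc <- mouse_dir[pairs$mouse_gene] == hdir[pairs$human_gene]
    data.frame(subtype = subtype, n_shared = length(conc),
               n_concordant = sum(conc),
               concordant_fraction =
                 if (length(conc)) mean(conc) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  out <- list(per_subtype = per, testable = FALSE,
              statistic = NA_real_, p_value = NA_real_)
  ok <- per$n_shared > 0L
  if (sum(ok) >= 2L) {
    a <- per[ok, ][1L, ]; b <- per[ok, ][2L, ]
    tab <- rbind(c(a$n_concordant, a$n_shared - a$n_concordant),
                 c(b$n_concordant, b$n_shared - b$n_concordant))
    if (any(colSums(tab) == 0L)) {
      # both subtypes fully concordant (or fully discordant): no
      # between-subtype difference to test
      out$testable <- TRUE
      out$statistic <- 0
      out$p_value <- 1
    } else if (all(rowSums(tab) > 0L)) {
      ct <- chisq_2x2(tab, correct)
      out$testable <- TRUE
      out$statistic <- ct$statistic
      out$p_value <- ct$p_value
    }
  }
  out
}

#' Genes of major relevance in both species
#'
#' Genes clearly differentially methylated (significant locus with at
#' least the clear-difference threshold) in BOTH species, linked through
#' the ortholog map; sorted by the weaker of the two species' maximal
#' absolute beta-differences, descending.
#'
#' @param mouse_summary,human_summary `gene_dm_summary` tables.
#' @param ortholog_map An `ortholog_map`.
#' @return data.frame with the ortholog pair, both species' maxima and
#'   directions, and `min_max_abs_delta_beta` (sort key).
#' @export
major_relevance_genes <- function(mouse_summary, human_summary,
                                  ortholog_map) {
  ms <- mouse_summary[mouse_summary$has_clear_dm, , drop = FALSE]
  hs <- human_summary[human_summary$has_clear_dm, , drop = FALSE]
  pairs <- ortholog_map[ortholog_map$mouse_gene %in% ms$gene &
                        ortholog_map$human_gene %in% hs$gene, , drop = FALSE]
  mi <- match(pairs$mouse_gene, ms$gene)
  hi <- match(pairs$human_gene, hs$gene)
  out <- data.frame(mouse_gene = pairs$mouse_gene,
                    human_gene = pairs$human_gene,
                    mouse_max_abs_delta_beta = ms$max_abs_delta_beta[mi],
                    human_max_abs_delta_beta = hs$max_abs_delta_beta[hi],
                    mouse_direction = ms$direction[mi],
                    human_direction = hs$direction[hi],
                    stringsAsFactors = FALSE)
  out$min_max_abs_delta_beta <- pmin(out$mouse_max_abs_delta_beta,
                                     out$human_max_abs_delta_beta)
  out <- out[order(-out$min_max_abs_delta_beta, out$mouse_gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Risk-group direction concordance at a target gene
#'
#' Compares, at a single gene, the direction of differential methylation
#' between a high-risk-vs-low-risk contrast and a tumour-vs-control
#' contrast. Loci enter when they are significant in the risk contrast and
#' clearly differentially methylated (significant with
#' `|delta_beta| > clear_threshold`) in the tumour contrast; the
#' probability of observing at least the observed number of
#' direction-concordant loci under a fair-coin null is the exact one-sided
#' binomial tail.
#'
#' @param risk_dm `dm_result` of the high-vs-low-risk contrast, restricted
#'   to the target gene's loci.
#' @param tumour_dm `dm_result` of the tumour-vs-control contrast,
#'   restricted to the same gene.
#' @param clear_threshold Clear-difference threshold for the tumour
#'   contrast, default 0.30.
#' @return List with `n` (shared qualifying loci), `k` (concordant),
#'   `p_value` (one-sided exact binomial, `P(X >= k)` at p = 0.5) and
#'   `testable`.
#' @export
risk_concordance <- function(risk_dm, tumour_dm, clear_threshold = 0.30) {
  key <- function(dm) if (!is.null(dm$probe)) dm$probe
                      else paste(dm$chrom, dm$pos)
  rk <- risk_dm[risk_dm$significant, , drop = FALSE]
  tk <- tumour_dm[tumour_dm$significant &
                  abs(tumour_dm$delta_beta) > clear_threshold, ,
                  drop = FALSE]
  shared <- intersect(key(rk), key(tk))
  n <- length(shared)
  if (n == 0L)
    return(list(n = 0L, k = 0L, p_value = NA_real_, testable = FALSE))
  rdir <- rk$direction[match(shared, key(rk))]
  tdir <- tk$direction[match(shared, key(tk))]
  k <- sum(rdir == tdir)
  list(n = n, k = k,
       p_value = stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE),
       testable = TRUE)
}
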