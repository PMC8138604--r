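#' Agglomerate CpGs into candidate regions
#'
#' Greedy left-to-right scan per chromosome over loci with sufficient
#' sample presence: a window is grown while its 1-based inclusive span stays
#' within `max_span_bp`, and a maximal window is emitted as a candidate
#' region when it holds at least `min_cpgs` member CpGs. Emitted regions
#' never overlap; when a maximal window is too small the scan advances by
#' one locus.
#'
#' @param matrix A `meth_matrix` with coverage.
#' @param min_cpgs Minimum member CpGs per candidate, default 15.
#' @param max_span_bp Maximum region span in bp (1-based inclusive width),
#'   default 200.
#' @param min_presence Minimum fraction of samples in which each member CpG
#'   must be covered (>= 1 read), default 0.75.
#' @return List of candidate regions, each a list with `chrom`, `start`,
#'   `end`, `n_cpgs` and `members` (row indices into `matrix$loci`).
#' @export
find_candidate_regions <- function(matrix, min_cpgs = 15, max_span_bp = 200,
                                   min_presence = 0.75) {
  cov <- matrix$coverage
  if (is.null(cov)) stop("candidate regions require coverage (RRBS mode)")
  present <- rowMeans(!is.na(cov) & cov >= 1) >= min_presence
  loci <- matrix$loci
  out <- list()
  for (chr in unique(loci$chrom)) {
    idx <- which(loci$chrom == chr & present)
    if (length(idx) == 0L) next
    idx <- idx[order(loci$pos[idx])]
    pos <- loci$pos[idx]
    i <- 1L
    while (i <= length(idx)) {
      j <- i
      while (j < length(idx) && pos[j + 1L] - pos[i] + 1L <= max_span_bp)
        j <- j + 1L
      if (j - i + 1L >= min_cpgs) {
        out[[length(out) + 1L]] <- list(chrom = chr, start = pos[i],
                                        end = pos[j], n_cpgs = j - i + 1L,
                                        members = idx[i:j])
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  out
}

# Beta-binomial log-likelihood with mean mu (per observation) and
# intra-class correlation rho; rho ~ 0 collapses to the binomial.
bb_loglik <- function(y, n, mu, rho) {
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  if (rho < 1e-12)
    return(sum(lchoose(n, y) + y * log(mu) + (n - y) * log(1 - mu)))
  phi <- (1 - rho) / rho
  a <- mu * phi
  b <- (1 - mu) * phi
  sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

#' Beta-binomial likelihood-ratio test of a candidate region
#'
#' Models the methylated read counts of all member CpGs with a
#' logit-linear mean (intercept plus group effect shared across the region)
#' and a single region-level beta-binomial dispersion, fitted by maximum
#' likelihood. The region p-value is the likelihood-ratio test of the group
#' coefficient against a chi-squared reference with 1 degree of freedom.
#' In the zero-dispersion limit this is the logistic-binomial LRT.
#'
#' @param meth,cov Member-CpG by sample matrices of methylated and total
#'   read counts (NAs allowed for uncovered cells).
#' @param design Two-level group labels per sample column.
#' @param fixed_rho Optionally fix the dispersion instead of estimating it
#'   (0 gives the exact binomial model).
#' @return List with `p_value`, `coef` (group effect on the logit scale),
#'   `rho` and `converged`; non-convergence yields `p_value = NA`.
#' @export
beta_binomial_region_test <- function(meth, cov, design, fixed_rho = NULL) {
  design <- droplevels(factor(design))
  stopifnot(nlevels(design) == 2L)
  z <- as.numeric(design == levels(design)[2L])
  zc <- matrix(z, nrow(meth), ncol(meth), byrow = TRUE)
  ok <- !is.na(meth) & !is.na(cov) & cov > 0
  y <- meth[ok]; n <- cov[ok]; zz <- zc[ok]
  if (length(y) == 0L || length(unique(zz)) < 2L)
    return(list(p_value = NA_real_, coef = NA_real_, rho = NA_real_,
                converged = FALSE))
  rate <- function(sel) (sum(y[sel]) + 0.5) / (sum(n[sel]) + 1)
  b0_start <- stats::qlogis(rate(zz == 0))
  b1_start <- stats::qlogis(rate(zz == 1)) - b0_start
  nll <- function(par, with_group, rho_free) {
    b0 <- par[1L]
    b1 <- if (with_group) par[2L] else 0
    rho <- if (rho_free) stats::plogis(par[length(par)])
           else fixed_rho
    mu <- stats::plogis(b0 + b1 * zz)
    -bb_loglik(y, n, mu, rho)
  }
  rho_free <- is.null(fixed_rho)
  run <- function(par, with_group) {
    # Nelder-Mead is unreliable (and warns) in one dimension
    method <- if (length(par) == 1L) "BFGS" else "Nelder-Mead"
    ctrl <- if (method == "BFGS") list(maxit = 500, reltol = 1e-12)
            else list(maxit = 2000, reltol = 1e-10)
    stats::optim(par, nll, with_group = with_group, rho_free = rho_free,
                 method = method, control = ctrl)
  }
  s0 <- stats::qlogis(0.05)
  full <- tryCatch(
    run(c(b0_start, b1_start, if (rho_free) s0), TRUE),
    error = function(e) NULL)
  null <- tryCatch(
    run(c(b0_start, if (rho_free) s0), FALSE),
    error = function(e) NULL)
  if (is.null(full) || is.null(null) ||
      full$convergence != 0L || null$convergence != 0L) {
    warning("beta-binomial fit did not converge; region excluded from FDR")
    return(list(p_value = NA_real_, coef = NA_real_, rho = NA_real_,
                converged = FALSE))
  }
  lrt <- max(0, 2 * (null$value - full$value))
  list(p_value = stats::pchisq(lrt, df = 1L, lower.tail = FALSE),
       coef = full$par[2L],
       rho = if (rho_free) stats::plogis(full$par[3L]) else fixed_rho,
       converged = TRUE)
}

#' Summarise a candidate region
#'
#' Reports group medians and the median difference over member CpGs:
#' `control_median` and `tumour_median` are medians across member CpGs of
#' the per-CpG group-mean beta, and `median_difference` is the median
#' across member CpGs of the per-CpG difference (case mean minus control
#' mean) — note this is not the difference of the two median columns unless
#' the CpGs are homogeneous. Gene context is resolved against the
#' annotation: regions overlapping a gene body are `genic`, otherwise
#' regions overlapping a promoter window upstream of a TSS are `promoter`,
#' otherwise `intergenic`.
#'
#' @param region A candidate region from [find_candidate_regions()].
#' @param matrix The `meth_matrix` the candidates came from.
#' @param annotation Optional [gene_annotation()] table.
#' @param promoter_window_bp Promoter window upstream of the TSS, default
#'   1500.
#' @param cpg_p Optional per-locus p-values (parallel to `matrix$loci`)
#'   whose region median is reported as `median_p`.
#' @return One-row data.frame with the Table-style columns (`gene`, `type`,
#'   coordinates, `width`, `n_cpgs`, `median_p`, medians and difference).
#' @export
summarize_region <- function(region, matrix, annotation = NULL,
                             promoter_window_bp = 1500, cpg_p = NULL) {
  idx <- region$members
  design <- matrix$groups
  lv <- levels(droplevels(design))
  b1 <- rowMeans(matrix$beta[idx, design == lv[1L], drop = FALSE],
                 na.rm = TRUE)
  b2 <- rowMeans(matrix$beta[idx, design == lv[2L], drop = FALSE],
                 na.rm = TRUE)
  ctx <- region_gene_context(region, annotation, promoter_window_bp)
  data.frame(gene = ctx$gene, type = ctx$type, chrom = region$chrom,
             start = region$start, end = region$end,
             width = region$end - region$start + 1L,
             n_cpgs = region$n_cpgs,
             median_p = if (is.null(cpg_p)) NA_real_ else
               stats::median(cpg_p[idx], na.rm = TRUE),
             control_median = stats::median(b1, na.rm = TRUE),
             tumour_median = stats::median(b2, na.rm = TRUE),
             median_difference = stats::median(b2 - b1, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

region_gene_context <- function(region, annotation, promoter_window_bp) {
  if (is.null(annotation) || nrow(annotation) == 0L)
    return(list(gene = "", type = "intergenic"))
  same <- annotation[annotation$chrom == region$chrom, , drop = FALSE]
  body <- same$start <= region$end & same$end >= region$start
  if (any(body))
    return(list(gene = paste(sort(same$symbol[body]), collapse = ", "),
                type = "genic"))
  p_start <- ifelse(same$strand == "+",
                    pmax(1L, same$start - promoter_window_bp), same$end + 1L)
  p_end <- ifelse(same$strand == "+",
                  same$start - 1L, same$end + promoter_window_bp)
  prom <- p_start <= region$end & p_end >= region$start
  if (any(prom))
    return(list(gene = paste(sort(same$symbol[prom]), collapse = ", "),
                type = "promoter"))
  list(gene = "", type = "intergenic")
}

#' Rank regions and compute region-level FDR
#'
#' Benjamini-Hochberg adjustment over the converged region tests, then
#' ordering by descending absolute median difference (ties broken by
#' chromosome and start), the ordering used for top-region tables.
#'
#' @param regions data.frame of summarised regions with a `p_value` column.
#' @param fdr_threshold Region significance threshold, default 0.10.
#' @return The regions with `fdr`, `significant` and `direction` columns,
#'   reordered; class `dm_regions`.
#' @export
rank_and_fdr_regions <- function(regions, fdr_threshold = 0.10) {
  regions$fdr <- rep(NA_real_, nrow(regions))
  ok <- !is.na(regions$p_value)
  regions$fdr[ok] <- bh_fdr(regions$p_value[ok])
  regions$significant <- !is.na(regions$fdr) & regions$fdr < fdr_threshold
  regions$direction <- ifelse(regions$median_difference >= 0,
                              "hyper", "hypo")
  ord <- order(-abs(regions$median_difference), regions$chrom,
               regions$start)
  regions <- regions[ord, , drop = FALSE]
  rownames(regions) <- NULL
  class(regions) <- c("dm_regions", "data.frame")
  regions
}

#' Full DMR calling pipeline
#'
#' Candidate agglomeration, beta-binomial region testing, summarisation and
#' FDR ranking in one call.
#'
#' @param matrix A filtered `meth_matrix` with counts.
#' @param annotation Optional [gene_annotation()].
#' @param dm Optional `dm_result` on the same matrix supplying per-CpG
#'   p-values for the `median_p` column.
#' @param min_cpgs,max_span_bp,min_presence Candidate thresholds (see
#'   [find_candidate_regions()]).
#' @param fdr_threshold Region significance threshold, default 0.10.
#' @param promoter_window_bp Promoter window for gene context.
#' @return A ranked `dm_regions` data.frame.
#' @export
call_dmrs <- function(matrix, annotation = NULL, dm = NULL, min_cpgs = 15,
                      max_span_bp = 200, min_presence = 0.75,
                      fdr_threshold = 0.10, promoter_window_bp = 1500) {
  cands <- find_candidate_regions(matrix, min_cpgs, max_span_bp,
                                  min_presence)
  if (length(cands) == 0L) {
    out <- data.frame(gene = character(), type = character(),
                      chrom = character(), start = integer(),
                      end = integer(), width = integer(),
                      n_cpgs = integer(), median_p = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      control_median = numeric(), tumour_median = numeric(),
                      median_difference = numeric(),
                      significant = logical(), direction = character())
    class(out) <- c("dm_regions", "data.frame")
    return(out)
  }
  cpg_p <- if (is.null(dm)) NULL else dm$p_value
  rows <- lapply(cands, function(r) {
    s <- summarize_region(r, matrix, annotation, promoter_window_bp, cpg_p)
    tst <- beta_binomial_region_test(
      matrix$meth[r$members, , drop = FALSE],
      matrix$coverage[r$members, , drop = FALSE], matrix$groups)
    s$p_value <- tst$p_value
    s
  })
  regions <- do.call(rbind, rows)
  rank_and_fdr_regions(regions, fdr_threshold)
}
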