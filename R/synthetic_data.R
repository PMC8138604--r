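#' Simulation configuration
#'
#' Bundles every knob of the synthetic RRBS / array generator with
#' defaults sized to emulate a small solar-UV tumour-vs-control study:
#' 6 tumours vs 6 matched controls, negative-binomial coverage around 30x,
#' a bimodal CpG methylation baseline (most CpG-dense loci lowly
#' methylated, a high mode near 0.8), mild within-group beta-binomial
#' overdispersion, a small fraction of genes carrying planted DMRs with a
#' 0.4 beta-difference, and a global tumour hypermethylation shift
#' targeting a +12.8 percentage-point mean increase.
#'
#' @param n_genes Number of simulated genes.
#' @param loci_per_gene_mean Poisson mean of background CpGs per gene.
#' @param n_control,n_tumour Sample sizes per group.
#' @param coverage_mean,coverage_size Negative-binomial coverage law
#'   (mean and size); zero-coverage draws make the locus missing in that
#'   sample.
#' @param low_weight,baseline_low,baseline_high Mixture weight of the low
#'   mode and Beta shape pairs for the low/high baseline modes.
#' @param rho Within-group beta-binomial intra-class correlation.
#' @param dmr_gene_fraction Fraction of genes receiving a planted DMR.
#' @param dmr_delta_beta Planted beta-difference magnitude; injected as a
#'   per-CpG logit offset chosen to realise this difference exactly at the
#'   group-mean level.
#' @param dmr_n_cpgs,dmr_span_bp CpGs per planted DMR and their span.
#' @param dmr_hyper_prob Probability a planted DMR is hypermethylated.
#' @param global_shift_mean_beta Target overall increase in tumour mean
#'   beta across all loci, planted regional effects included; realised by
#'   a common logit offset solved numerically. 0 disables the global
#'   shift (planted DMR effects remain untouched).
#' @param shared_fraction Fraction of DMR genes flagged as shared with the
#'   human datasets.
#' @param n_array_control,n_array_tumour Array sample sizes per group.
#' @param array_probes_per_gene Probes simulated per human gene.
#' @param array_noise_sd Logit-scale noise SD of array beta-values.
#' @param array_delta_beta Planted beta-difference on arrays.
#' @param concordance_prob Probability a planted human effect shares the
#'   mouse direction.
#' @param bad_probe_fraction Fraction of probes with failing detection
#'   p-values.
#' @param seed Random seed; a fixed seed makes all outputs byte-identical.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500, loci_per_gene_mean = 20,
                       n_control = 6, n_tumour = 6,
                       coverage_mean = 30, coverage_size = 8,
                       low_weight = 0.6, baseline_low = c(1.5, 13.5),
                       baseline_high = c(12, 3), rho = 0.02,
                       dmr_gene_fraction = 0.05, dmr_delta_beta = 0.4,
                       dmr_n_cpgs = 20, dmr_span_bp = 150,
                       dmr_hyper_prob = 0.95,
                       global_shift_mean_beta = 0.128,
                       shared_fraction = 0.8,
                       n_array_control = 10, n_array_tumour = 10,
                       array_probes_per_gene = 8, array_noise_sd = 0.5,
                       array_delta_beta = 0.35, concordance_prob = 0.85,
                       bad_probe_fraction = 0.05, seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_genes >= 1, n_control >= 1, n_tumour >= 1,
              coverage_mean > 0, rho >= 0, rho < 1,
              dmr_gene_fraction >= 0, dmr_gene_fraction <= 1,
              dmr_delta_beta >= 0, dmr_delta_beta < 0.8,
              dmr_hyper_prob >= 0, dmr_hyper_prob <= 1,
              shared_fraction >= 0, shared_fraction <= 1,
              concordance_prob >= 0, concordance_prob <= 1,
              bad_probe_fraction >= 0, bad_probe_fraction <= 1)
  })
  if (cfg$dmr_span_bp < cfg$dmr_n_cpgs)
    stop("infeasible config: dmr_span_bp (", cfg$dmr_span_bp,
         ") cannot hold ", cfg$dmr_n_cpgs, " distinct CpG positions")
  class(cfg) <- c("sim_config", "list")
  cfg
}

# Draw baseline beta-values from the bimodal mixture.
draw_baseline <- function(n, cfg) {
  low <- stats::runif(n) < cfg$low_weight
  b <- numeric(n)
  b[low] <- stats::rbeta(sum(low), cfg$baseline_low[1L],
                         cfg$baseline_low[2L])
  b[!low] <- stats::rbeta(sum(!low), cfg$baseline_high[1L],
                          cfg$baseline_high[2L])
  pmin(pmax(b, 1e-4), 1 - 1e-4)
}

# Common logit offset such that the overall tumour-vs-control increase in
# mean beta (including the planted regional offsets) hits the target; a
# target of 0 disables the shift entirely rather than cancelling the
# planted effects.
solve_global_offset <- function(baseline, dmr_offset, target) {
  if (target == 0) return(0)
  lg <- stats::qlogis(baseline) + dmr_offset
  f <- function(c) mean(stats::plogis(lg + c)) - mean(baseline) - target
  stats::uniroot(f, c(-10, 10), tol = 1e-10)$root
}

# Beta-binomial draws with mean mu and intra-class correlation rho.
rbetabinom <- function(n_draws, size, mu, rho) {
  if (rho <= 0) return(stats::rbinom(n_draws, size, mu))
  phi <- (1 - rho) / rho
  p <- stats::rbeta(n_draws, mu * phi, (1 - mu) * phi)
  stats::rbinom(n_draws, size, p)
}

#' Simulate an RRBS-like tumour-vs-control dataset with known truth
#'
#' Lays genes along a few chromosomes, scatters background CpGs with
#' bimodal baseline methylation through each gene body, plants a DMR
#' (contiguous CpG cluster with a logit-scale tumour effect realising the
#' configured beta-difference) in a random subset of genes, applies the
#' global tumour hypermethylation offset, and draws per-sample coverage
#' (negative binomial; zeros become missing records) and methylated reads
#' (beta-binomial with the configured intra-class correlation).
#'
#' @param config A [sim_config()].
#' @return List with `tables` (per-sample [cpg_counts()]), `groups`
#'   (named factor), `annotation` ([gene_annotation()]), `truth` (list
#'   with `loci` and `regions` data.frames) and `config`.
#' @export
simulate_rrbs <- function(config) {
  set.seed(config$seed)
  gene_len <- 10000L
  spacing <- 20000L
  n_chrom <- 5L
  g <- seq_len(config$n_genes)
  chrom <- paste0("chr", (g - 1L) %% n_chrom + 1L)
  start <- ((g - 1L) %/% n_chrom) * spacing + 1L
  ann <- gene_annotation(chrom, start, start + gene_len - 1L,
                         sample(c("+", "-"), config$n_genes, TRUE),
                         sprintf("Gene%04d", g))
  n_dmr <- round(config$dmr_gene_fraction * config$n_genes)
  dmr_genes <- sort(sample(g, n_dmr))
  loci <- list()
  for (i in g) {
    is_dmr <- i %in% dmr_genes
    excl_lo <- excl_hi <- -1L
    if (is_dmr) {
      off <- sample.int(gene_len - config$dmr_span_bp, 1L)
      s0 <- ann$start[i] + off - 1L
      mpos <- unique(round(seq(s0, s0 + config$dmr_span_bp - 1L,
                               length.out = config$dmr_n_cpgs)))
      hyper <- stats::runif(1) < config$dmr_hyper_prob
      d <- config$dmr_delta_beta
      base <- if (hyper) stats::runif(length(mpos), 0.1, 0.9 - d)
              else stats::runif(length(mpos), 0.1 + d, 0.9)
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = ann$chrom[i], pos = as.integer(mpos), gene = ann$symbol[i],
        is_dmr = TRUE, baseline = base,
        target = base + if (hyper) d else -d,
        stringsAsFactors = FALSE)
      excl_lo <- s0 - 200L; excl_hi <- s0 + config$dmr_span_bp + 200L
    }
    n_bg <- max(3L, stats::rpois(1L, config$loci_per_gene_mean))
    cand <- setdiff(seq.int(ann$start[i], ann$end[i]),
                    seq.int(max(ann$start[i], excl_lo),
                            min(ann$end[i], max(excl_hi, ann$start[i]))))
    bpos <- sort(sample(cand, min(n_bg, length(cand))))
    base <- draw_baseline(length(bpos), config)
    loci[[length(loci) + 1L]] <- data.frame(
      chrom = ann$chrom[i], pos = as.integer(bpos), gene = ann$symbol[i],
      is_dmr = FALSE, baseline = base, target = base,
      stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, loci)
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  rownames(loci) <- NULL
  dmr_off <- ifelse(loci$is_dmr,
                    stats::qlogis(loci$target) - stats::qlogis(loci$baseline),
                    0)
  c_off <- solve_global_offset(loci$baseline, dmr_off,
                               config$global_shift_mean_beta)
  mu_control <- loci$baseline
  mu_tumour <- stats::plogis(stats::qlogis(loci$baseline) + dmr_off + c_off)
  ids <- c(sprintf("control_%d", seq_len(config$n_control)),
           sprintf("tumour_%d", seq_len(config$n_tumour)))
  grp <- factor(rep(c("control", "tumour"),
                    c(config$n_control, config$n_tumour)),
                levels = c("control", "tumour"))
  tables <- lapply(seq_along(ids), function(j) {
    mu <- if (grp[j] == "control") mu_control else mu_tumour
    cov <- stats::rnbinom(nrow(loci), mu = config$coverage_mean,
                          size = config$coverage_size)
    keep <- cov > 0L
    y <- rbetabinom(sum(keep), cov[keep], mu[keep], config$rho)
    cpg_counts(ids[j], chrom = loci$chrom[keep], pos = loci$pos[keep],
               n_meth = y, n_total = cov[keep])
  })
  truth_loci <- data.frame(chrom = loci$chrom, pos = loci$pos,
                           gene = loci$gene, is_dmr = loci$is_dmr,
                           mu_control = mu_control, mu_tumour = mu_tumour,
                           true_delta_beta = mu_tumour - mu_control,
                           stringsAsFactors = FALSE)
  regions <- do.call(rbind, lapply(ann$symbol[dmr_genes], function(sym) {
    sub <- truth_loci[truth_loci$gene == sym & truth_loci$is_dmr, ,
                      drop = FALSE]
    data.frame(gene = sym, chrom = sub$chrom[1L], start = min(sub$pos),
               end = max(sub$pos),
               true_delta_beta = stats::median(sub$true_delta_beta),
               direction = if (stats::median(sub$true_delta_beta) >= 0)
                 "hyper" else "hypo",
               stringsAsFactors = FALSE)
  }))
  if (is.null(regions)) regions <- data.frame(
    gene = character(), chrom = character(), start = integer(),
    end = integer(), true_delta_beta = numeric(), direction = character())
  regions$shared <- stats::runif(nrow(regions)) < config$shared_fraction
  list(tables = tables, groups = stats::setNames(grp, ids),
       annotation = ann,
       truth = list(loci = truth_loci, regions = regions),
       config = config)
}

#' Fabricate an ortholog candidate table for simulated genes
#'
#' One true high-confidence candidate per mouse gene (the human symbol is
#' the upper-cased mouse symbol), plus controlled ambiguity: a configurable
#' fraction of genes receive decoy candidates of lower or tied homology so
#' every resolution rule is exercised.
#'
#' @param annotation Mouse [gene_annotation()] from [simulate_rrbs()].
#' @param ambiguous_fraction Fraction of genes with decoy candidates.
#' @param seed Random seed.
#' @return An [ortholog_candidates()] table.
#' @export
simulate_ortholog_candidates <- function(annotation,
                                         ambiguous_fraction = 0.3,
                                         seed = 1) {
  set.seed(seed)
  mouse <- annotation$symbol
  human <- toupper(mouse)
  rows <- data.frame(mouse_gene = mouse, human_gene = human,
                     confidence = "high",
                     homology_pct = round(stats::runif(length(mouse),
                                                       80, 99), 2),
                     stringsAsFactors = FALSE)
  amb <- which(stats::runif(length(mouse)) < ambiguous_fraction)
  decoys <- lapply(amb, function(i) {
    kind <- sample(c("low", "tied_high", "weaker_high"), 1L)
    hp <- switch(kind,
                 low = round(stats::runif(1, 40, 79), 2),
                 tied_high = rows$homology_pct[i],
                 weaker_high = max(0, rows$homology_pct[i] - 5))
    data.frame(mouse_gene = mouse[i],
               human_gene = paste0(human[i], "B"),
               confidence = if (kind == "low") "low" else "high",
               homology_pct = hp, stringsAsFactors = FALSE)
  })
  all <- rbind(rows, do.call(rbind, decoys))
  ortholog_candidates(all$mouse_gene, all$human_gene, all$confidence,
                      all$homology_pct)
}

#' Simulate a human-like methylation array dataset
#'
#' Generates probes for the human orthologs of the simulated mouse genes:
#' beta-values are logit-scale noise around group means, planted human
#' differential methylation appears in genes whose mouse DMR is flagged
#' shared (direction agreeing with the mouse direction with the configured
#' concordance probability), and a configured fraction of probes carries
#' failing detection p-values.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element of a [simulate_rrbs()] result.
#' @param ortholog_map An `ortholog_map` linking the simulated species.
#' @param seed Seed for this dataset (distinct subtypes should use
#'   distinct seeds); default `config$seed + 1`.
#' @param concordance_prob Override of `config$concordance_prob`.
#' @return List with `dataset` ([array_dataset()]), `groups`, and `truth`
#'   (per-probe data.frame with planted effect and direction).
#' @export
simulate_array <- function(config, truth, ortholog_map,
                           seed = config$seed + 1,
                           concordance_prob = config$concordance_prob) {
  set.seed(seed)
  hg <- unique(ortholog_map$human_gene)
  n_g <- length(hg)
  gchrom <- paste0("chr", (seq_len(n_g) - 1L) %% 22 + 1L)
  gstart <- ((seq_len(n_g) - 1L) %/% 22) * 20000L + 1L
  ppg <- config$array_probes_per_gene
  probe_gene <- rep(hg, each = ppg)
  probe_chrom <- rep(gchrom, each = ppg)
  probe_pos <- rep(gstart, each = ppg) +
    as.integer(round(seq(100, 9900, length.out = ppg)))
  n_p <- length(probe_gene)
  probes <- sprintf("cg%07d", seq_len(n_p))
  shared <- truth$regions[truth$regions$shared, , drop = FALSE]
  shared_mouse <- shared$gene
  mouse_dir <- stats::setNames(shared$direction, shared$gene)
  m2h <- ortholog_map[ortholog_map$mouse_gene %in% shared_mouse, ,
                      drop = FALSE]
  hdm_genes <- unique(m2h$human_gene)
  gene_dir <- vapply(hdm_genes, function(h) {
    md <- mouse_dir[m2h$mouse_gene[m2h$human_gene == h][1L]]
    conc <- stats::runif(1) < concordance_prob
    if (conc) md else setdiff(c("hyper", "hypo"), md)
  }, "")
  base <- draw_baseline(n_p, config)
  delta <- numeric(n_p)
  d <- config$array_delta_beta
  for (h in hdm_genes) {
    idx <- which(probe_gene == h)
    planted <- idx[seq_len(max(1L, length(idx) %/% 2L))]
    sgn <- if (gene_dir[[h]] == "hyper") 1 else -1
    base[planted] <- pmin(pmax(base[planted], 0.1 + d * (sgn < 0)),
                          0.9 - d * (sgn > 0))
    delta[planted] <- sgn * d
  }
  mu_control <- base
  mu_tumour <- base + delta
  ids <- c(sprintf("hcontrol_%d", seq_len(config$n_array_control)),
           sprintf("htumour_%d", seq_len(config$n_array_tumour)))
  grp <- factor(rep(c("control", "tumour"),
                    c(config$n_array_control, config$n_array_tumour)),
                levels = c("control", "tumour"))
  beta <- vapply(seq_along(ids), function(j) {
    mu <- if (grp[j] == "control") mu_control else mu_tumour
    stats::plogis(stats::qlogis(pmin(pmax(mu, 1e-4), 1 - 1e-4)) +
                    stats::rnorm(n_p, 0, config$array_noise_sd))
  }, numeric(n_p))
  dimnames(beta) <- list(probes, ids)
  detp <- matrix(stats::runif(n_p * length(ids), 0, 0.005), n_p,
                 dimnames = list(probes, ids))
  bad <- stats::runif(n_p) < config$bad_probe_fraction
  detp[bad, ] <- stats::runif(sum(bad) * length(ids), 0.02, 1)
  annot <- data.frame(probe = probes, chrom = probe_chrom,
                      pos = probe_pos, gene = probe_gene,
                      stringsAsFactors = FALSE)
  probe_truth <- data.frame(probe = probes, gene = probe_gene,
                            is_dm = delta != 0, true_delta_beta = delta,
                            direction = ifelse(delta >= 0, "hyper", "hypo"),
                            stringsAsFactors = FALSE)
  list(dataset = array_dataset(beta, detp, annot),
       groups = stats::setNames(grp, ids), truth = probe_truth,
       gene_directions = gene_dir)
}

#' Confusion-matrix evaluation of calls against simulation truth
#'
#' At CpG level, a testable locus is a true positive when it belongs to a
#' planted DMR and is called significant; at region level, a significant
#' called region is a true positive when it overlaps a planted region on
#' the same chromosome. Power is the fraction of planted units recovered;
#' observed FDR is the fraction of significant calls without planted
#' support (reported as `NA` when nothing is called). Beta-difference
#' recovery (bias and RMSE of the estimate minus truth) is computed over
#' true positives.
#'
#' @param calls A `dm_result` (CpG level) or `dm_regions` (region level).
#' @param truth The `truth` element of [simulate_rrbs()].
#' @param level "cpg" or "region".
#' @return List with `power`, `observed_fdr`, `n_calls`, `delta_bias` and
#'   `delta_rmse`.
#' @export
evaluate_calls <- function(calls, truth, level = c("cpg", "region")) {
  level <- match.arg(level)
  if (level == "cpg") {
    key <- paste(calls$chrom, calls$pos)
    tkey <- paste(truth$loci$chrom, truth$loci$pos)
    planted <- tkey[truth$loci$is_dmr]
    sig <- calls$significant
    tested_planted <- calls$testable & key %in% planted
    power <- if (any(tested_planted)) mean(sig[tested_planted])
             else NA_real_
    n_calls <- sum(sig)
    fdr <- if (n_calls > 0) mean(!(key[sig] %in% planted)) else NA_real_
    tp <- sig & key %in% planted
    err <- calls$delta_beta[tp] -
      truth$loci$true_delta_beta[match(key[tp], tkey)]
  } else {
    tr <- truth$regions
    sig <- calls[calls$significant, , drop = FALSE]
    overlaps <- function(a_chrom, a_start, a_end, b) {
      any(b$chrom == a_chrom & b$start <= a_end & b$end >= a_start)
    }
    hit_truth <- vapply(seq_len(nrow(tr)), function(i)
      overlaps(tr$chrom[i], tr$start[i], tr$end[i], sig), TRUE)
    power <- if (nrow(tr)) mean(hit_truth) else NA_real_
    call_tp <- vapply(seq_len(nrow(sig)), function(i)
      overlaps(sig$chrom[i], sig$start[i], sig$end[i], tr), TRUE)
    n_calls <- nrow(sig)
    fdr <- if (n_calls > 0) mean(!call_tp) else NA_real_
    err <- vapply(which(call_tp), function(i) {
      j <- which(tr$chrom == sig$chrom[i] & tr$start <= sig$end[i] &
                 tr$end >= sig$start[i])[1L]
      sig$median_difference[i] - tr$true_delta_beta[j]
    }, 0)
  }
  list(power = power, observed_fdr = fdr, n_calls = n_calls,
       delta_bias = if (length(err)) mean(err) else NA_real_,
       delta_rmse = if (length(err)) sqrt(mean(err^2)) else NA_real_)
}
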