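#' Pipeline configuration
#'
#' Collects every analysis threshold with its default: RRBS loci need 8x
#' coverage in every sample and 6 methylated reads summed over samples;
#' CpG significance is FDR < 0.10 for RRBS and FDR < 0.05 for arrays;
#' a clear difference is 30 percentage points of beta; candidate regions
#' need 15 CpGs within 200 bp present in 75% of samples; clustering uses
#' the 10,000 most variable loci; array probes need detection p <= 0.01;
#' promoters extend 1,500 bp upstream of the TSS.
#'
#' @param min_coverage,min_meth_reads RRBS locus filters.
#' @param rrbs_fdr,array_fdr Significance thresholds.
#' @param clear_delta Clear-difference threshold on `|delta_beta|`.
#' @param dmr_min_cpgs,dmr_max_span_bp,dmr_min_presence Candidate-region
#'   rules.
#' @param top_k Loci used for clustering.
#' @param detection_p Array detection p-value threshold.
#' @param promoter_window_bp Promoter window.
#' @param seed Random seed for simulation-backed runs.
#' @param outdir Output directory.
#' @param sim A [sim_config()] for simulation-backed runs (its seed is
#'   kept in sync with `seed`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_coverage = 8, min_meth_reads = 6,
                            rrbs_fdr = 0.10, array_fdr = 0.05,
                            clear_delta = 0.30, dmr_min_cpgs = 15,
                            dmr_max_span_bp = 200, dmr_min_presence = 0.75,
                            top_k = 10000, detection_p = 0.01,
                            promoter_window_bp = 1500, seed = 1,
                            outdir = "methcross_out", sim = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_coverage >= 1, cfg$min_meth_reads >= 0,
            cfg$rrbs_fdr > 0, cfg$rrbs_fdr < 1,
            cfg$array_fdr > 0, cfg$array_fdr < 1,
            cfg$clear_delta >= 0, cfg$clear_delta <= 1,
            cfg$dmr_min_cpgs >= 2, cfg$dmr_max_span_bp >= 1,
            cfg$dmr_min_presence > 0, cfg$dmr_min_presence <= 1,
            cfg$top_k >= 1, cfg$detection_p > 0, cfg$detection_p <= 1,
            cfg$promoter_window_bp >= 0)
  if (is.null(cfg$sim)) cfg$sim <- sim_config(seed = cfg$seed)
  cfg$sim$seed <- cfg$seed
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(lapply(config, function(x)
    if (inherits(x, "sim_config")) unclass(x) else x)), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$sim)) do.call(sim_config, raw$sim)
  raw$sim <- NULL
  do.call(pipeline_config, c(raw, list(sim = sim)))
}

log_msg <- function(...) message("[methcross] ", ...)

#' Run a pipeline subcommand
#'
#' Orchestrates the analysis stages over a simulation-backed workspace.
#' `simulate` writes synthetic RRBS coverage files, gene annotation,
#' ortholog candidates and two human-like array datasets (subtypes
#' "stem" and "keratinocyte") into `config$outdir`; the analysis
#' subcommands read those files back through the package readers, so the
#' file formats are exercised end to end. `all` runs every stage. Outputs
#' are deterministic for a fixed seed.
#'
#' @param name One of "simulate", "dm-cpg", "dmr", "cluster",
#'   "cross-species", "risk", "all".
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of artifact paths.
#' @export
run_subcommand <- function(name, config) {
  valid <- c("simulate", "dm-cpg", "dmr", "cluster", "cross-species",
             "risk", "all")
  if (!name %in% valid)
    stop("unknown subcommand '", name, "'; expected one of: ",
         paste(valid, collapse = ", "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  steps <- if (name == "all")
    c("simulate", "dm-cpg", "dmr", "cluster", "cross-species", "risk")
  else name
  arts <- list()
  for (s in steps) arts <- c(arts, switch(
    s,
    "simulate" = step_simulate(config),
    "dm-cpg" = step_dm_cpg(config),
    "dmr" = step_dmr(config),
    "cluster" = step_cluster(config),
    "cross-species" = step_cross_species(config),
    "risk" = step_risk(config)))
  invisible(arts)
}

out_path <- function(config, ...) file.path(config$outdir, ...)

step_simulate <- function(config) {
  sim <- simulate_rrbs(config$sim)
  dir.create(out_path(config, "data"), showWarnings = FALSE)
  for (t in sim$tables)
    write_bismark_coverage(t, out_path(config, "data",
                                       paste0(sample_id(t), ".cov")))
  write_gene_annotation(sim$annotation, out_path(config, "data",
                                                 "genes.bed"))
  cands <- simulate_ortholog_candidates(sim$annotation,
                                        seed = config$seed + 7)
  utils::write.table(as.data.frame(cands),
                     out_path(config, "data", "ortholog_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  map <- resolve_orthologs(cands)
  subtype_seeds <- c(stem = config$seed + 11,
                     keratinocyte = config$seed + 12)
  subtype_conc <- c(stem = config$sim$concordance_prob,
                    keratinocyte = max(0, config$sim$concordance_prob - 0.2))
  for (st in names(subtype_seeds)) {
    arr <- simulate_array(config$sim, sim$truth, map,
                          seed = subtype_seeds[[st]],
                          concordance_prob = subtype_conc[[st]])
    write_array_files(arr, config, st)
  }
  risk <- simulate_array(config$sim, sim$truth, map,
                         seed = config$seed + 13,
                         concordance_prob = config$sim$concordance_prob)
  write_array_files(risk, config, "risk")
  utils::write.table(sim$truth$loci,
                     out_path(config, "data", "truth_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$regions,
                     out_path(config, "data", "truth_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("simulated ", length(sim$tables), " coverage files, ",
          nrow(sim$truth$regions), " planted DMRs")
  list(data_dir = out_path(config, "data"))
}

write_array_files <- function(arr, config, tag) {
  ds <- arr$dataset
  wr <- function(m, f) {
    df <- data.frame(probe = rownames(m), m, check.names = FALSE)
    utils::write.table(df, out_path(config, "data", f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(ds$beta, paste0("array_", tag, "_beta.tsv"))
  wr(ds$detection_p, paste0("array_", tag, "_detp.tsv"))
  utils::write.table(ds$probe_annotation,
                     out_path(config, "data",
                              paste0("array_", tag, "_annot.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

read_simulated_rrbs <- function(config) {
  files <- sort(list.files(out_path(config, "data"), pattern = "\\.cov$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no coverage files in ", out_path(config, "data"),
         "; run the simulate step first")
  tables <- lapply(files, function(f)
    read_bismark_coverage(f, sub("\\.cov$", "", basename(f))))
  ids <- vapply(tables, sample_id, "")
  groups <- stats::setNames(
    factor(sub("_.*$", "", ids), levels = c("control", "tumour")), ids)
  build_meth_matrix(tables, groups)
}

read_simulated_array <- function(config, tag) {
  ds <- read_array_dataset(
    out_path(config, "data", paste0("array_", tag, "_beta.tsv")),
    out_path(config, "data", paste0("array_", tag, "_detp.tsv")),
    out_path(config, "data", paste0("array_", tag, "_annot.tsv")))
  ds <- filter_array_probes(ds, config$detection_p)
  ids <- colnames(ds$beta)
  groups <- stats::setNames(
    factor(sub("^h(control|tumour)_.*$", "\\1", ids),
           levels = c("control", "tumour")), ids)
  array_to_meth_matrix(ds, groups)
}

filtered_rrbs_matrix <- function(config) {
  mat <- read_simulated_rrbs(config)
  fl <- filter_loci(mat, config$min_coverage, config$min_meth_reads)
  cnt <- attr(fl, "filter_counts")
  log_msg("filtered loci: ", cnt[["coverage"]], " by coverage, ",
          cnt[["meth_reads"]], " by methylated-read support; ",
          nrow(fl$loci), " retained")
  fl
}

step_dm_cpg <- function(config) {
  mat <- filtered_rrbs_matrix(config)
  dm <- call_dm_cpgs(mat, fdr_threshold = config$rrbs_fdr)
  write_dm_table(dm, out_path(config, "dm_cpgs.tsv"))
  grp_beta <- rowMeans(mat$beta, na.rm = TRUE)
  write_signed_bedgraph(dm, grp_beta, out_path(config, "dm_cpgs.bedgraph"))
  avg <- average_methylation(mat)
  utils::write.table(avg$contrasts, out_path(config, "group_means.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg(sum(dm$significant), " significant CpGs of ", sum(dm$testable),
          " tested (FDR < ", config$rrbs_fdr, ")")
  list(dm_cpgs = out_path(config, "dm_cpgs.tsv"),
       bedgraph = out_path(config, "dm_cpgs.bedgraph"),
       group_means = out_path(config, "group_means.tsv"))
}

step_dmr <- function(config) {
  mat <- filtered_rrbs_matrix(config)
  ann <- read_gene_annotation(out_path(config, "data", "genes.bed"))
  dm <- call_dm_cpgs(mat, fdr_threshold = config$rrbs_fdr)
  regions <- call_dmrs(mat, ann, dm, config$dmr_min_cpgs,
                       config$dmr_max_span_bp, config$dmr_min_presence,
                       config$rrbs_fdr, config$promoter_window_bp)
  write_dmr_table(regions, out_path(config, "dmrs.tsv"))
  log_msg(sum(regions$significant), " significant DMRs of ",
          nrow(regions), " candidates (",
          sum(regions$significant & regions$direction == "hyper"),
          " hyper, ",
          sum(regions$significant & regions$direction == "hypo"), " hypo)")
  list(dmrs = out_path(config, "dmrs.tsv"))
}

step_cluster <- function(config) {
  mat <- filtered_rrbs_matrix(config)
  top <- suppressWarnings(select_top_variance_loci(mat, config$top_k))
  cl <- hierarchical_cluster(top)
  write_dendrogram_newick(cl, out_path(config, "dendrogram.nwk"))
  labels <- cut_clusters(cl, 2L)
  utils::write.table(
    data.frame(sample = names(labels), cluster = labels,
               group = as.character(mat$groups[names(labels)])),
    out_path(config, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  list(dendrogram = out_path(config, "dendrogram.nwk"),
       clusters = out_path(config, "clusters.tsv"))
}

step_cross_species <- function(config) {
  mat <- filtered_rrbs_matrix(config)
  ann <- read_gene_annotation(out_path(config, "data", "genes.bed"))
  dm <- call_dm_cpgs(mat, fdr_threshold = config$rrbs_fdr)
  assign <- annotate_loci_to_genes(dm, ann, config$promoter_window_bp)
  mouse_sum <- summarize_genes(dm, assign, config$clear_delta)
  cands <- read_ortholog_candidates(
    out_path(config, "data", "ortholog_candidates.tsv"))
  map <- resolve_orthologs(cands)
  write_ortholog_map(map, out_path(config, "ortholog_map.tsv"))
  human_sums <- lapply(c(stem = "stem", keratinocyte = "keratinocyte"),
                       function(st) {
    hmat <- read_simulated_array(config, st)
    hdm <- call_dm_cpgs(hmat, fdr_threshold = config$array_fdr)
    hassign <- data.frame(locus = seq_len(nrow(hdm)), gene = hdm$gene)
    hassign <- hassign[nzchar(hassign$gene), , drop = FALSE]
    summarize_genes(hdm, hassign, config$clear_delta)
  })
  enr <- enrichment_test(mouse_sum, human_sums, map)
  utils::write.table(enr, out_path(config, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  conc <- direction_concordance(mouse_sum, human_sums, map)
  utils::write.table(
    cbind(conc$per_subtype,
          between_subtype_p = conc$p_value),
    out_path(config, "direction_concordance.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  major <- major_relevance_genes(mouse_sum, human_sums[["stem"]], map)
  utils::write.table(major, out_path(config, "major_relevance_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg(nrow(major), " major-relevance gene pairs (stem subtype)")
  list(enrichment = out_path(config, "enrichment.tsv"),
       concordance = out_path(config, "direction_concordance.tsv"),
       major = out_path(config, "major_relevance_genes.tsv"))
}

step_risk <- function(config) {
  risk_mat <- read_simulated_array(config, "risk")
  tum_mat <- read_simulated_array(config, "stem")
  risk_dm <- call_dm_cpgs(risk_mat, fdr_threshold = config$array_fdr)
  tum_dm <- call_dm_cpgs(tum_mat, fdr_threshold = config$array_fdr)
  genes <- unique(tum_dm$gene[tum_dm$significant &
                              abs(tum_dm$delta_beta) > config$clear_delta])
  genes <- genes[nzchar(genes)]
  rows <- lapply(genes, function(g) {
    rc <- risk_concordance(risk_dm[risk_dm$gene == g, , drop = FALSE],
                           tum_dm[tum_dm$gene == g, , drop = FALSE],
                           config$clear_delta)
    data.frame(gene = g, n = rc$n, k = rc$k, p_value = rc$p_value,
               testable = rc$testable, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), n = integer(), k = integer(),
               p_value = numeric(), testable = logical())
  out <- out[order(out$p_value), , drop = FALSE]
  utils::write.table(out, out_path(config, "risk_concordance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(risk = out_path(config, "risk_concordance.tsv"))
}
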