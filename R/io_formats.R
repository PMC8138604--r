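#' Per-sample CpG methylation count table
#'
#' Constructs the container holding per-CpG methylated/total read counts for
#' one sample. Coordinates are 1-based positions of the cytosine.
#'
#' @param sample_id Single character label for the sample.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param n_meth Integer vector of methylated read counts.
#' @param n_total Integer vector of total read counts (methylated +
#'   unmethylated); must be positive.
#' @return An object of class `cpg_counts`: a data.frame with columns
#'   `chrom`, `pos`, `n_meth`, `n_total` and a `sample_id` attribute.
#' @export
cpg_counts <- function(sample_id, chrom = character(), pos = integer(),
                       n_meth = integer(), n_total = integer()) {
  stopifnot(length(sample_id) == 1L, is.character(sample_id))
  n <- length(chrom)
  if (length(pos) != n || length(n_meth) != n || length(n_total) != n)
    stop("chrom, pos, n_meth and n_total must have equal length")
  pos <- as.integer(pos); n_meth <- as.integer(n_meth)
  n_total <- as.integer(n_total)
  if (n > 0) {
    if (any(pos < 1L)) stop("positions must be >= 1 (1-based coordinates)")
    if (any(n_meth < 0L)) stop("n_meth must be non-negative")
    if (any(n_total < 1L)) stop("n_total must be positive")
    if (any(n_meth > n_total)) stop("n_meth must not exceed n_total")
    if (anyDuplicated(paste(chrom, pos)))
      stop("duplicate (chrom, pos) records in sample '", sample_id, "'")
  }
  out <- data.frame(chrom = as.character(chrom), pos = pos,
                    n_meth = n_meth, n_total = n_total,
                    stringsAsFactors = FALSE)
  ord <- order(out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  class(out) <- c("cpg_counts", "data.frame")
  out
}

#' Sample identifier of a count table
#' @param x A `cpg_counts` object.
#' @return The sample label.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Read a Bismark coverage file
#'
#' Parses the 6-column coverage output of the Bismark methylation extractor
#' (chrom, start, end, methylation percentage, count methylated, count
#' unmethylated). The start column is taken as the CpG position; records with
#' zero total reads carry no information and are dropped with a warning.
#'
#' @param path Path to a (possibly empty) tab-separated coverage file.
#' @param sample_id Label to attach to the resulting table.
#' @return A [cpg_counts()] table with `n_total = count_meth + count_unmeth`.
#' @export
read_bismark_coverage <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty coverage file: ", path)
    return(cpg_counts(sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) != 6L)
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path,
         ": expected 6 tab-separated columns")
  mat <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(mat[, 2L]))
  nm  <- suppressWarnings(as.numeric(mat[, 5L]))
  nu  <- suppressWarnings(as.numeric(mat[, 6L]))
  bad <- which(is.na(pos) | is.na(nm) | is.na(nu))
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path, ": non-numeric field")
  bad <- which(nm < 0 | nu < 0)
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path, ": negative count")
  total <- nm + nu
  drop <- total == 0
  if (any(drop))
    warning(sum(drop), " zero-coverage record(s) dropped from ", path)
  keep <- !drop
  cpg_counts(sample_id, chrom = mat[keep, 1L], pos = pos[keep],
             n_meth = nm[keep], n_total = total[keep])
}

#' Write a count table in Bismark coverage format
#'
#' Inverse of [read_bismark_coverage()]: emits the 6-column tab-separated
#' coverage layout so that a write/read round trip reproduces counts exactly.
#'
#' @param counts A `cpg_counts` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bismark_coverage <- function(counts, path) {
  stopifnot(inherits(counts, "cpg_counts"))
  pct <- ifelse(counts$n_total > 0, 100 * counts$n_meth / counts$n_total, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   counts$chrom, counts$pos, counts$pos,
                   formatC(pct, digits = 6, format = "g"),
                   counts$n_meth, counts$n_total - counts$n_meth)
  writeLines(lines, path)
  invisible(path)
}

#' Array-style methylation dataset
#'
#' Bundles a probe-by-sample beta-value matrix, the matching detection
#' p-value matrix and a probe annotation table, as produced by Infinium-type
#' platforms after import.
#'
#' @param beta Numeric matrix of beta-values in `[0, 1]`, probes in rows.
#' @param detection_p Numeric matrix of detection p-values, same dimnames.
#' @param probe_annotation data.frame with columns `probe`, `chrom`, `pos`,
#'   `gene` (empty string when unannotated).
#' @return An object of class `array_dataset`.
#' @export
array_dataset <- function(beta, detection_p, probe_annotation) {
  stopifnot(is.matrix(beta), is.matrix(detection_p))
  if (!identical(dimnames(beta), dimnames(detection_p)))
    stop("beta and detection_p must share identical probe and sample names")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta-values must lie in [0, 1]")
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
    stop("detection p-values must lie in [0, 1]")
  probes <- rownames(beta)
  ann <- probe_annotation[match(probes, probe_annotation$probe), , drop = FALSE]
  missing <- is.na(ann$probe)
  ann$probe <- probes
  ann$gene[missing] <- ""
  ann$chrom[missing] <- NA_character_
  ann$pos[missing] <- NA_integer_
  rownames(ann) <- NULL
  structure(list(beta = beta, detection_p = detection_p,
                 probe_annotation = ann),
            class = "array_dataset")
}

#' Read an array dataset from beta / detection-p / annotation files
#'
#' The beta and detection-p files are tab-separated matrices with probe ids
#' in the first column and sample names in the header; the annotation file
#' has columns `probe`, `chrom`, `pos`, `gene`. Probes missing from the
#' annotation are retained with an empty gene symbol.
#'
#' @param beta_path,detp_path,annot_path File paths.
#' @return An [array_dataset()].
#' @export
read_array_dataset <- function(beta_path, detp_path, annot_path) {
  beta <- as.matrix(utils::read.delim(beta_path, row.names = 1,
                                      check.names = FALSE))
  detp <- as.matrix(utils::read.delim(detp_path, row.names = 1,
                                      check.names = FALSE))
  if (!setequal(colnames(beta), colnames(detp))) {
    d1 <- setdiff(colnames(beta), colnames(detp))
    d2 <- setdiff(colnames(detp), colnames(beta))
    stop("sample sets differ between beta and detection-p files: ",
         "only in beta: {", paste(d1, collapse = ", "), "}; ",
         "only in detection-p: {", paste(d2, collapse = ", "), "}")
  }
  if (!setequal(rownames(beta), rownames(detp)))
    stop("probe sets differ between beta and detection-p files")
  detp <- detp[rownames(beta), colnames(beta), drop = FALSE]
  ann <- utils::read.delim(annot_path, stringsAsFactors = FALSE,
                           colClasses = c(probe = "character",
                                          chrom = "character",
                                          pos = "integer",
                                          gene = "character"))
  array_dataset(beta, detp, ann)
}

#' Gene annotation table
#'
#' @param chrom,start,end,strand,symbol Per-gene fields; coordinates are
#'   1-based inclusive.
#' @return A data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(chrom, start, end, strand, symbol) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("gene start must not exceed end")
  if (anyDuplicated(symbol)) stop("gene symbols must be unique")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    strand = as.character(strand),
                    symbol = as.character(symbol), stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Read gene annotation from a BED6 file
#'
#' BED intervals are 0-based half-open; they are converted to the internal
#' 1-based inclusive convention on read.
#'
#' @param path Path to a 6-column BED file (chrom, start, end, name, score,
#'   strand).
#' @return A [gene_annotation()] table.
#' @export
read_gene_annotation <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop("expected BED6: 6 tab-separated columns")
  gene_annotation(chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
                  strand = bed[[6]], symbol = bed[[4]])
}

#' Write gene annotation as BED6
#' @param annotation A [gene_annotation()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", annotation$chrom,
                   annotation$start - 1L, annotation$end,
                   annotation$symbol, annotation$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog candidate table
#'
#' @param path TSV with columns `mouse_gene`, `human_gene`, `confidence`
#'   (high/low) and `homology_pct` (0-100).
#' @return A data.frame of class `ortholog_candidates`.
#' @export
read_ortholog_candidates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  ortholog_candidates(tab$mouse_gene, tab$human_gene, tab$confidence,
                      tab$homology_pct)
}

#' Ortholog candidate table constructor
#' @param mouse_gene,human_gene Gene symbols.
#' @param confidence "high" or "low" orthology-likelihood flag.
#' @param homology_pct Percent homology in `[0, 100]`.
#' @return A data.frame of class `ortholog_candidates`.
#' @export
ortholog_candidates <- function(mouse_gene, human_gene, confidence,
                                homology_pct) {
  if (!all(confidence %in% c("high", "low")))
    stop("confidence must be 'high' or 'low'")
  homology_pct <- as.numeric(homology_pct)
  if (any(homology_pct < 0 | homology_pct > 100))
    stop("homology_pct must lie in [0, 100]")
  out <- data.frame(mouse_gene = as.character(mouse_gene),
                    human_gene = as.character(human_gene),
                    confidence = as.character(confidence),
                    homology_pct = homology_pct, stringsAsFactors = FALSE)
  if (anyDuplicated(out)) stop("fully duplicated candidate rows")
  class(out) <- c("ortholog_candidates", "data.frame")
  out
}

#' Write a signed BedGraph methylation track
#'
#' Encodes per-CpG group-mean methylation with the differential-methylation
#' call in the sign: significant CpGs are written with a positive value in
#' `[0, 1]`, nonsignificant CpGs with the negated value. A nonsignificant
#' locus with beta exactly 0 is emitted as the literal `-0.0` so the flag
#' survives the round trip. Intervals are converted from internal 1-based
#' inclusive positions to the 0-based half-open BedGraph convention.
#'
#' @param dm A `dm_result` table (see [call_dm_cpgs()]) with columns
#'   `chrom`, `pos` and `significant`.
#' @param group_mean_beta Numeric vector of per-locus mean beta, parallel
#'   to the rows of `dm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signed_bedgraph <- function(dm, group_mean_beta, path) {
  stopifnot(length(group_mean_beta) == nrow(dm),
            !is.null(dm$significant))
  val <- sprintf("%.8g", group_mean_beta)
  val <- ifelse(dm$significant, val, paste0("-", val))
  lines <- sprintf("%s\t%d\t%d\t%s", dm$chrom, dm$pos - 1L, dm$pos, val)
  writeLines(lines, path)
  invisible(path)
}

#' Write a table of differentially methylated regions
#'
#' Emits one TSV row per region with the genomic span (1-based inclusive;
#' `width = end - start + 1`), the CpG count, the median per-CpG p and the
#' region FDR, and the group medians and median difference as fractions.
#'
#' @param regions A `dm_regions` data.frame (see [summarize_region()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(regions, path) {
  cols <- c("gene", "type", "chrom", "start", "end", "width", "n_cpgs",
            "median_p", "fdr", "control_median", "tumour_median",
            "median_difference")
  if (nrow(regions) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- regions[, cols, drop = FALSE]
  stopifnot(all(out$width == out$end - out$start + 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
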