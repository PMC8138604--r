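#' Resolve one human ortholog per mouse gene
#'
#' Applies, per mouse gene, the cascade of tie-breaking rules used to turn
#' an ambiguous ortholog candidate table into a (mostly) one-to-one map:
#' (1) if any high-likelihood candidate exists, drop the low-likelihood
#' ones; (2) keep only candidates with the maximal homology percentage
#' (compared after rounding to 4 decimals to avoid float noise); (3) among
#' remaining ties prefer candidates whose human and mouse symbols are
#' identical case-insensitively (human genes are conventionally upper-case
#' where mouse genes are title-case); (4) any survivors are all kept as
#' candidate orthologs.
#'
#' @param candidates An [ortholog_candidates()] table.
#' @return data.frame of class `ortholog_map` with columns `mouse_gene`,
#'   `human_gene`, `confidence`, `homology_pct` and `resolution_rule`
#'   (one of "high-conf-max-homology", "max-homology", "symbol-match",
#'   "all-kept"), ordered by mouse gene.
#' @export
resolve_orthologs <- function(candidates) {
  resolve_one <- function(sub) {
    used_high <- any(sub$confidence == "high")
    if (used_high) sub <- sub[sub$confidence == "high", , drop = FALSE]
    h <- round(sub$homology_pct, 4L)
    sub <- sub[h == max(h), , drop = FALSE]
    rule <- if (used_high) "high-conf-max-homology" else "max-homology"
    if (nrow(sub) > 1L) {
      sym <- tolower(sub$human_gene) == tolower(sub$mouse_gene)
      if (any(sym)) {
        sub <- sub[sym, , drop = FALSE]
        rule <- "symbol-match"
      }
      if (nrow(sub) > 1L) rule <- "all-kept"
    }
    sub$resolution_rule <- rule
    sub[order(sub$human_gene), , drop = FALSE]
  }
  parts <- split(as.data.frame(candidates), candidates$mouse_gene)
  out <- do.call(rbind, lapply(parts, resolve_one))
  out <- out[order(out$mouse_gene, out$human_gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_map", "data.frame")
  out
}

#' Write an ortholog map as TSV
#' @param map An `ortholog_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
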