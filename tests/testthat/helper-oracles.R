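# Independent oracles used by several test files: each re-derives the
# expected behaviour by brute force, without calling package internals.

# BH step-up by direct enumeration over the ranked p-values.
bh_brute <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(which(p[ord] >= p[ord][i]), function(j)
      p[ord][j] * n / j, 0)
    q[ord[i]] <- min(1, min(cand))
  }
  q
}

# O(n^2) enumeration of the greedy maximal-window agglomeration rule:
# from each scan position take the largest window within the span limit
# (found by checking every end), emit it if big enough, then jump past it.
greedy_windows_oracle <- function(pos, min_cpgs, max_span) {
  out <- list()
  i <- 1L
  while (i <= length(pos)) {
    ok <- which(vapply(seq(i, length(pos)), function(j)
      pos[j] - pos[i] + 1L <= max_span, TRUE))
    j <- i + max(ok) - 1L
    if (j - i + 1L >= min_cpgs) {
      out[[length(out) + 1L]] <- c(start = pos[i], end = pos[j],
                                   n = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Fully covered count matrix at the given positions (for region tests).
full_cov_mm <- function(pos, n_samples = 4, chrom = NULL) {
  n <- length(pos)
  cov <- matrix(10, n, n_samples)
  meth <- matrix(5, n, n_samples)
  mm_from_counts(meth, cov, rep(c("control", "tumour"),
                                length.out = n_samples),
                 chrom = if (is.null(chrom)) rep("chr1", n) else chrom,
                 pos = pos)
}

# Closed-form Pearson chi-squared for a 2x2 table (no correction).
chisq_closed_form <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Exhaustive re-application of the ortholog tie-breaking rules.
resolve_oracle <- function(cand) {
  do.call(rbind, lapply(split(as.data.frame(cand), cand$mouse_gene),
                        function(s) {
    if (any(s$confidence == "high")) s <- s[s$confidence == "high", ]
    s <- s[round(s$homology_pct, 4) == max(round(s$homology_pct, 4)), ]
    sym <- tolower(s$human_gene) == tolower(s$mouse_gene)
    if (nrow(s) > 1 && any(sym)) s <- s[sym, ]
    s[order(s$human_gene), c("mouse_gene", "human_gene")]
  }))
}

# Minimal dm_result-shaped data.frame for cross-species tests.
fake_dm <- function(chrom, pos, delta, sig, probe = NULL) {
  out <- data.frame(chrom = chrom, pos = as.integer(pos),
                    delta_beta = delta,
                    significant = sig,
                    direction = ifelse(delta >= 0, "hyper", "hypo"),
                    testable = TRUE, stringsAsFactors = FALSE)
  if (!is.null(probe)) out$probe <- probe
  class(out) <- c("dm_result", "data.frame")
  out
}
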