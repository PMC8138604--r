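test_that("candidate regions follow the 15-CpG / 200-bp / presence rule", {
  pos15 <- as.integer(seq(1000, 1190, length.out = 15))  # 190 bp span
  cands <- find_candidate_regions(full_cov_mm(pos15))
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$n_cpgs, 15L)
  expect_equal(cands[[1]]$start, 1000L)
  expect_equal(cands[[1]]$end, 1190L)

  pos14 <- as.integer(seq(1000, 1049, length.out = 14))  # 50 bp, 14 CpGs
  expect_length(find_candidate_regions(full_cov_mm(pos14)), 0L)
})

test_that("low-presence CpGs are excluded from candidate membership", {
  pos <- as.integer(seq(1000, 1190, length.out = 15))
  mm <- full_cov_mm(pos)
  mm$coverage[1, 1:2] <- NA  # present in 2/4 samples < 75%
  mm$meth[1, 1:2] <- NA
  cands <- find_candidate_regions(mm)
  expect_length(cands, 0L)  # only 14 eligible CpGs remain
})

test_that("agglomeration equals the exhaustive window-enumeration oracle", {
  pos <- as.integer(seq(1000, by = 13, length.out = 30))  # uniform 13 bp
  mm <- full_cov_mm(pos)
  got <- find_candidate_regions(mm)
  want <- greedy_windows_oracle(pos, 15L, 200L)
  expect_length(got, length(want))
  for (k in seq_along(want)) {
    expect_equal(got[[k]]$start, unname(want[[k]]["start"]))
    expect_equal(got[[k]]$end, unname(want[[k]]["end"]))
    expect_equal(got[[k]]$n_cpgs, unname(want[[k]]["n"]))
  }
  set.seed(17)
  for (rep in 1:10) {
    pos <- sort(sample.int(2000L, 150L))
    got <- find_candidate_regions(full_cov_mm(pos), min_cpgs = 8)
    want <- greedy_windows_oracle(pos, 8L, 200L)
    expect_equal(vapply(got, function(r) r$start, 0L),
                 vapply(want, function(w) unname(w["start"]), 0L))
    # emitted regions never overlap and never exceed the span
    if (length(got) > 1L) {
      starts <- vapply(got, function(r) r$start, 0L)
      ends <- vapply(got, function(r) r$end, 0L)
      expect_true(all(starts[-1L] > ends[-length(ends)]))
      expect_true(all(ends - starts + 1L <= 200L))
    }
  }
})

test_that("zero-dispersion region test agrees with the binomial GLM", {
  set.seed(23)
  for (rep in 1:4) {
    n_cpg <- 10; n_s <- 6
    cov <- matrix(rpois(n_cpg * n_s, 30), n_cpg)
    grp <- factor(rep(c("control", "tumour"), each = 3))
    p0 <- runif(1, 0.2, 0.5); p1 <- p0 + runif(1, 0, 0.2)
    mu <- matrix(rep(ifelse(grp == "tumour", p1, p0), each = n_cpg), n_cpg)
    meth <- matrix(rbinom(n_cpg * n_s, cov, mu), n_cpg)
    res <- beta_binomial_region_test(meth, cov, grp, fixed_rho = 0)
    y <- as.vector(meth); n <- as.vector(cov)
    z <- rep(as.numeric(grp == "tumour"), each = n_cpg)
    full <- glm(cbind(y, n - y) ~ z, family = binomial())
    null <- glm(cbind(y, n - y) ~ 1, family = binomial())
    p_glm <- anova(null, full, test = "LRT")[2, "Pr(>Chi)"]
    expect_lt(abs(res$p_value - p_glm), 1e-3)
  }
})

test_that("identical group counts give a null region test", {
  cov <- matrix(20, 10, 6)
  meth <- matrix(rep(c(2, 5, 9, 12, 4, 7, 3, 10, 6, 8), 6), 10)
  grp <- factor(rep(c("control", "tumour"), each = 3))
  res <- beta_binomial_region_test(meth, cov, grp)
  expect_lt(abs(res$coef), 0.05)
  expect_gt(res$p_value, 0.5)
})

test_that("planted regional effects yield small p-values across seeds", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n_cpg <- 20; n_s <- 12
    cov <- matrix(rpois(n_cpg * n_s, 30), n_cpg)
    grp <- factor(rep(c("control", "tumour"), each = 6))
    base <- runif(n_cpg, 0.2, 0.4)
    mu <- outer(base, as.numeric(grp == "tumour") * 0.4, `+`)
    phi <- (1 - 0.02) / 0.02
    p <- matrix(rbeta(n_cpg * n_s, mu * phi, (1 - mu) * phi), n_cpg)
    meth <- matrix(rbinom(n_cpg * n_s, cov, p), n_cpg)
    beta_binomial_region_test(meth, cov, grp)$p_value < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("region summaries use the median of per-CpG differences", {
  # median difference != difference of medians with heterogeneous CpGs
  ctrl <- c(0.30, 0.36, 0.38, 0.3423, 0.32)
  tum <- c(0.6987, 0.70, 0.7602, 0.79, 0.80)
  beta <- cbind(ctrl, ctrl, tum, tum)
  colnames(beta) <- paste0("s", 1:4)
  mm <- mm_from_beta(beta, rep(c("control", "tumour"), each = 2))
  region <- list(chrom = "chr16", start = 57391482L, end = 57391657L,
                 n_cpgs = 5L, members = 1:5)
  s <- summarize_region(region, mm)
  expect_equal(s$control_median, 0.3423)
  expect_equal(s$tumour_median, 0.7602)
  expect_equal(s$median_difference, 0.3987)
  expect_false(isTRUE(all.equal(s$median_difference,
                                s$tumour_median - s$control_median)))
  expect_equal(s$width, 176L)

  # constant-difference case: the two readings coincide
  beta2 <- cbind(rep(0.3423, 3), rep(0.3423, 3), rep(0.7602, 3),
                 rep(0.7602, 3))
  colnames(beta2) <- paste0("s", 1:4)
  mm2 <- mm_from_beta(beta2, rep(c("control", "tumour"), each = 2))
  s2 <- summarize_region(list(chrom = "chr1", start = 1L, end = 3L,
                              n_cpgs = 3L, members = 1:3), mm2)
  expect_equal(s2$median_difference, 0.7602 - 0.3423)

  # simple odd-count median
  beta3 <- cbind(rep(0.1, 3), rep(0.1, 3), c(0.2, 0.3, 0.4),
                 c(0.2, 0.3, 0.4))
  colnames(beta3) <- paste0("s", 1:4)
  mm3 <- mm_from_beta(beta3, rep(c("control", "tumour"), each = 2))
  s3 <- summarize_region(list(chrom = "chr1", start = 1L, end = 3L,
                              n_cpgs = 3L, members = 1:3), mm3)
  expect_equal(s3$median_difference, 0.2)
})

test_that("gene context distinguishes genic, promoter and intergenic", {
  ann <- gene_annotation(c("chr1", "chr1"), c(5000L, 20000L),
                         c(8000L, 22000L), c("+", "-"), c("GeneA", "GeneB"))
  mk <- function(start, end) list(chrom = "chr1", start = start, end = end,
                                  n_cpgs = 15L, members = 1L)
  beta <- matrix(0.5, 1, 4, dimnames = list(NULL, paste0("s", 1:4)))
  mm <- mm_from_beta(beta, rep(c("control", "tumour"), each = 2))
  expect_equal(summarize_region(mk(6000L, 6100L), mm, ann)$type, "genic")
  # 1 kb upstream of GeneA TSS (plus strand)
  expect_equal(summarize_region(mk(4000L, 4100L), mm, ann)$type, "promoter")
  # 1 kb upstream of GeneB TSS (minus strand: beyond end)
  expect_equal(summarize_region(mk(22500L, 22600L), mm, ann)$type,
               "promoter")
  expect_equal(summarize_region(mk(12000L, 12100L), mm, ann)$type,
               "intergenic")
})

test_that("region ranking applies BH and orders by |median difference|", {
  regions <- data.frame(
    gene = c("A", "B", "C"), type = "genic", chrom = c("chr2", "chr1", "chr1"),
    start = c(500L, 100L, 900L), end = c(600L, 200L, 1000L),
    width = 101L, n_cpgs = 15L, median_p = 0.01,
    p_value = c(0.001, 0.5, 0.2),
    control_median = c(0.2, 0.3, 0.4), tumour_median = c(0.6, 0.5, 0.6),
    median_difference = c(0.4, 0.2, 0.4))
  ranked <- rank_and_fdr_regions(regions[1:2, ])
  expect_equal(ranked$fdr[ranked$gene == "A"], 0.002)
  expect_equal(ranked$fdr[ranked$gene == "B"], 0.5)
  expect_equal(ranked$gene, c("A", "B"))
  expect_equal(sum(ranked$direction == "hypo"), 0L)

  # ties in |median_difference| broken by (chrom, start)
  ranked3 <- rank_and_fdr_regions(regions)
  expect_equal(ranked3$gene, c("C", "A", "B"))
})

test_that("the full DMR pipeline recovers a planted region end to end", {
  cfg <- sim_config(n_genes = 40, dmr_gene_fraction = 0.1,
                    global_shift_mean_beta = 0, seed = 29)
  sim <- simulate_rrbs(cfg)
  mat <- filter_loci(build_meth_matrix(sim$tables, sim$groups))
  regions <- call_dmrs(mat, sim$annotation)
  expect_gt(nrow(regions), 0L)
  expect_true(all(regions$width == regions$end - regions$start + 1L))
  ev <- evaluate_calls(regions, sim$truth, level = "region")
  expect_gte(ev$power, 0.5)
  top <- regions[1, ]
  expect_true(top$significant)
  expect_match(top$gene, "^Gene")
})
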