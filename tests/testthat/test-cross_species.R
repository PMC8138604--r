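test_that("loci are assigned to gene bodies, promoters, or neither", {
  ann <- gene_annotation(c("chr3", "chr3", "chr3"),
                         c(10000L, 12000L, 50000L),
                         c(15000L, 13000L, 60000L),
                         c("+", "-", "+"),
                         c("Filip1l", "Cmss1", "Far1"))
  dm <- fake_dm("chr3", c(12500L, 9000L, 30000L, 61000L),
                rep(0.4, 4), rep(TRUE, 4))
  asg <- annotate_loci_to_genes(dm, ann)
  # locus inside two opposite-strand gene bodies maps to both
  expect_setequal(asg$gene[asg$locus == 1], c("Filip1l", "Cmss1"))
  # 1,000 bp upstream of a plus-strand TSS: promoter window
  expect_equal(asg$gene[asg$locus == 2], "Filip1l")
  # intergenic locus maps to nothing
  expect_false(3 %in% asg$locus)
  # 1,000 bp downstream of a plus-strand gene end is not a promoter
  expect_false(4 %in% asg$locus)
})

test_that("gene summaries apply the clear-difference rule at 30%", {
  dm <- fake_dm("chr1", c(100, 200, 300, 400, 500),
                c(0.3987, 0.29, -0.35, 0.5, 0.1),
                c(TRUE, TRUE, FALSE, FALSE, FALSE))
  asg <- data.frame(locus = 1:5,
                    gene = c("A", "B", "C", "C", "D"))
  gs <- summarize_genes(dm, asg)
  a <- gs[gs$gene == "A", ]
  expect_true(a$has_dm && a$has_clear_dm)
  expect_equal(a$direction, "hyper")
  expect_equal(a$max_abs_delta_beta, 0.3987)
  b <- gs[gs$gene == "B", ]
  expect_true(b$has_dm)
  expect_false(b$has_clear_dm)  # 0.29 < 0.30
  cc <- gs[gs$gene == "C", ]
  expect_false(cc$has_dm)       # no significant locus
  expect_true(is.na(cc$max_abs_delta_beta))
  expect_equal(cc$n_tested_loci, 2L)
})

test_that("enrichment statistics equal the closed-form chi-squared", {
  mouse <- data.frame(gene = c("A", "B", "C"), has_dm = c(TRUE, TRUE, FALSE),
                      direction = "hyper")
  # human: orthologs of A,B in the target set; 40/50 DM in set,
  # 400/800 outside
  human <- data.frame(
    gene = c(paste0("SET", 1:50), paste0("BG", 1:800)),
    has_dm = c(rep(c(TRUE, FALSE), c(40, 10)),
               rep(c(TRUE, FALSE), c(400, 400))),
    direction = "hyper")
  map <- data.frame(mouse_gene = c("A", "B"),
                    human_gene = c("SET1", "SET2"))
  # make every SET gene an ortholog of a mouse DM gene
  map <- data.frame(mouse_gene = rep(c("A", "B"), 25),
                    human_gene = paste0("SET", 1:50))
  res <- suppressWarnings(
    enrichment_test(mouse, list(stem = human), map, n_subtype_tests = 2))
  expect_equal(res$set_fraction, 0.8)
  expect_equal(res$baseline_fraction, 0.5)
  expect_equal(res$statistic, chisq_closed_form(40, 10, 400, 400),
               tolerance = 1e-12)
  expect_equal(res$p_adj, min(1, res$p_value * 2))
  # identical fractions give statistic 0, p 1
  human0 <- data.frame(gene = c("SET1", "SET2", "BG1", "BG2"),
                       has_dm = c(TRUE, FALSE, TRUE, FALSE),
                       direction = "hyper")
  res0 <- suppressWarnings(
    enrichment_test(mouse, list(stem = human0), map, n_subtype_tests = 1))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("Bonferroni adjustment multiplies and caps at 1", {
  expect_equal(min(1, 0.004 * 2), 0.008)
  mouse <- data.frame(gene = "A", has_dm = TRUE, direction = "hyper")
  human <- data.frame(gene = c("AH", paste0("B", 1:9)),
                      has_dm = rep(c(TRUE, FALSE), c(5, 5)),
                      direction = "hyper")
  map <- data.frame(mouse_gene = "A", human_gene = "AH")
  res <- suppressWarnings(
    enrichment_test(mouse, list(s1 = human, s2 = human), map))
  expect_equal(res$p_adj, pmin(1, res$p_value * 2))
})

test_that("direction concordance compares subtypes by chi-squared", {
  n1 <- 240; k1 <- 198; n2 <- 248; k2 <- 163
  mouse <- data.frame(gene = sprintf("m%03d", 1:248),
                      has_dm = TRUE,
                      direction = "hyper")
  map <- data.frame(mouse_gene = mouse$gene,
                    human_gene = toupper(mouse$gene))
  mk_human <- function(n, k) data.frame(
    gene = toupper(mouse$gene)[1:n], has_dm = TRUE,
    direction = rep(c("hyper", "hypo"), c(k, n - k)))
  res <- direction_concordance(
    mouse, list(stem = mk_human(n1, k1), keratinocyte = mk_human(n2, k2)),
    map)
  expect_true(res$testable)
  expect_equal(res$per_subtype$concordant_fraction, c(k1 / n1, k2 / n2))
  expect_equal(res$statistic,
               chisq_closed_form(k1, n1 - k1, k2, n2 - k2),
               tolerance = 1e-12)
  # fully concordant subtypes: fraction 1, p 1
  res1 <- direction_concordance(
    mouse, list(stem = mk_human(50, 50), keratinocyte = mk_human(40, 40)),
    map)
  expect_equal(res1$per_subtype$concordant_fraction, c(1, 1))
  expect_equal(res1$p_value, 1)
  # a single shared gene is not testable but does not crash
  res2 <- direction_concordance(mouse, list(stem = mk_human(1, 1)), map)
  expect_false(res2$testable)
  expect_equal(res2$per_subtype$n_shared, 1L)
})

test_that("chi-squared matches the closed form on random 2x2 tables", {
  set.seed(43)
  for (i in 1:20) {
    tab <- matrix(sample(5:200, 4), 2)
    got <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(unname(got$statistic),
                 chisq_closed_form(tab[1, 1], tab[1, 2],
                                   tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("major-relevance genes require clear DM in both species", {
  mouse <- data.frame(gene = c("A", "B", "C"),
                      has_clear_dm = c(TRUE, TRUE, FALSE),
                      max_abs_delta_beta = c(0.3987, 0.40, 0.40),
                      direction = c("hyper", "hyper", "hyper"))
  human <- data.frame(gene = c("AH", "BH", "CH"),
                      has_clear_dm = c(TRUE, FALSE, TRUE),
                      max_abs_delta_beta = c(0.45, 0.25, 0.40),
                      direction = c("hyper", "hyper", "hyper"))
  map <- data.frame(mouse_gene = c("A", "B", "C"),
                    human_gene = c("AH", "BH", "CH"))
  mr <- major_relevance_genes(mouse, human, map)
  # A: clear in both -> included; B: human below threshold; C: mouse
  # locus not significant/clear
  expect_equal(mr$mouse_gene, "A")
  expect_equal(mr$min_max_abs_delta_beta, 0.3987)
})

test_that("risk concordance equals the exact binomial tail", {
  mk_pair <- function(n, k) {
    # n shared probes; k with agreeing direction
    tum <- fake_dm("chr1", seq_len(n) * 10, rep(0.4, n), rep(TRUE, n),
                   probe = sprintf("cg%03d", seq_len(n)))
    risk_delta <- c(rep(0.2, k), rep(-0.2, n - k))
    risk <- fake_dm("chr1", seq_len(n) * 10, risk_delta, rep(TRUE, n),
                    probe = sprintf("cg%03d", seq_len(n)))
    list(risk = risk, tum = tum)
  }
  p89 <- mk_pair(9, 8)
  rc <- risk_concordance(p89$risk, p89$tum)
  expect_equal(rc$n, 9L)
  expect_equal(rc$k, 8L)
  expect_equal(rc$p_value, 10 / 512)
  expect_lt(rc$p_value, 0.05)
  expect_equal(risk_concordance(mk_pair(9, 9)$risk,
                                mk_pair(9, 9)$tum)$p_value, 1 / 512)
  expect_equal(risk_concordance(mk_pair(9, 5)$risk,
                                mk_pair(9, 5)$tum)$p_value, 0.5)
  # full-enumeration oracle for n up to 20
  set.seed(47)
  for (i in 1:10) {
    n <- sample(1:20, 1); k <- sample(0:n, 1)
    pair <- mk_pair(max(n, 1), k)
    rc <- risk_concordance(pair$risk, pair$tum)
    expect_equal(rc$p_value, sum(choose(n, k:n)) / 2^n, tolerance = 1e-12)
  }
  # loci failing the clear-difference rule do not enter
  weak <- mk_pair(5, 5)
  weak$tum$delta_beta <- rep(0.2, 5)
  rc0 <- risk_concordance(weak$risk, weak$tum)
  expect_false(rc0$testable)
  expect_true(is.na(rc0$p_value))
})

test_that("planted shared genes are recovered as major-relevance genes", {
  cfg <- sim_config(n_genes = 80, dmr_gene_fraction = 0.15,
                    global_shift_mean_beta = 0, shared_fraction = 1,
                    concordance_prob = 1, bad_probe_fraction = 0,
                    seed = 53)
  sim <- simulate_rrbs(cfg)
  mat <- filter_loci(build_meth_matrix(sim$tables, sim$groups))
  dm <- call_dm_cpgs(mat, fdr_threshold = 0.10)
  asg <- annotate_loci_to_genes(dm, sim$annotation)
  mouse_sum <- summarize_genes(dm, asg)
  cands <- simulate_ortholog_candidates(sim$annotation, seed = 53)
  map <- resolve_orthologs(cands)
  arr <- simulate_array(cfg, sim$truth, map)
  hmm <- array_to_meth_matrix(arr$dataset, arr$groups)
  hdm <- call_dm_cpgs(hmm, fdr_threshold = 0.05)
  hasg <- data.frame(locus = seq_len(nrow(hdm)), gene = hdm$gene)
  human_sum <- summarize_genes(hdm, hasg)
  mr <- major_relevance_genes(mouse_sum, human_sum, map)
  planted <- sim$truth$regions$gene[sim$truth$regions$shared]
  sens <- mean(planted %in% mr$mouse_gene)
  fdp <- if (nrow(mr)) mean(!(mr$mouse_gene %in% planted)) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.1)
})
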