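# integration layer: correlations, cross-classification, TE association

test_that("Pearson correlations match hand-computed covariance arithmetic", {
  m <- data.table::data.table(gene_id = c("a", "b", "c"),
                              value = c(1, 2, 3), stratum = "s")
  expect_equal(correlate_meth_expr(m, c(a = 3, b = 2, c = 1))$pearson_r, -1)
  expect_equal(correlate_meth_expr(m, c(a = 1, b = 2, c = 3))$pearson_r, 1)
  # constant methylation vector -> missing correlation, n reported
  m2 <- data.table::data.table(gene_id = letters[1:4], value = 0.5,
                               stratum = "s")
  r2 <- correlate_meth_expr(m2, setNames(rnorm(4), letters[1:4]))
  expect_true(is.na(r2$pearson_r))
  expect_equal(r2$n, 4L)
  # from-scratch oracle on random vectors, 1e-12 agreement
  set.seed(14)
  x <- rnorm(100); y <- 0.3 * x + rnorm(100)
  ids <- paste0("g", 1:100)
  mm <- data.table::data.table(gene_id = ids, value = x, stratum = "s")
  got <- correlate_meth_expr(mm, setNames(y, ids))$pearson_r
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got, oracle, tolerance = 1e-12)
  # exact t-transform p-value with n - 2 df
  tstat <- oracle * sqrt(98 / (1 - oracle^2))
  expect_equal(correlate_meth_expr(mm, setNames(y, ids))$p_value,
               2 * pt(-abs(tstat), 98), tolerance = 1e-10)
})

test_that("cross-classification counts a constructed toy exactly", {
  dmr_genes <- data.table::data.table(
    dmr_id = paste0("D", 1:5),
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    hit = "body", context = "CG",
    direction = c("hyper", "hyper", "hyper", "hypo", "hypo"))
  degs <- data.table::data.table(
    gene_id = paste0("g", 1:6),
    status = c("up", "up", "up", "down", "down", "ns"))
  cc <- cross_classify(dmr_genes, degs, region = "body")
  expect_equal(cc[meth_class == "hyper" & deg_class == "up", n_genes], 3L)
  expect_equal(cc[meth_class == "hyper" & deg_class == "down", n_genes], 0L)
  expect_equal(cc[meth_class == "hypo" & deg_class == "up", n_genes], 0L)
  expect_equal(cc[meth_class == "hypo" & deg_class == "down", n_genes], 2L)
  venn <- attr(cc, "venn")$body.CG
  expect_setequal(venn$DMR_Hypergenes, c("g1", "g2", "g3"))
  expect_setequal(venn$DEG_downgenes, c("g4", "g5"))
  # disjoint DEG and DMR-gene sets -> all cells zero
  cc0 <- cross_classify(dmr_genes,
                        data.table::data.table(gene_id = "g9", status = "up"),
                        region = "body")
  expect_true(all(cc0$n_genes == 0L))
})

test_that("genes hit by both hyper- and hypo-DMRs are counted in both classes", {
  dmr_genes <- data.table::data.table(
    dmr_id = c("D1", "D2"), gene_id = "g1", hit = "body", context = "CG",
    direction = c("hyper", "hypo"))
  degs <- data.table::data.table(gene_id = "g1", status = "up")
  cc <- cross_classify(dmr_genes, degs, region = "body")
  expect_equal(cc[meth_class == "hyper" & deg_class == "up", n_genes], 1L)
  expect_equal(cc[meth_class == "hypo" & deg_class == "up", n_genes], 1L)
  expect_equal(attr(cc, "dual_class")$body.CG, "g1")
})

test_that("DMR-gene expression association keeps per-gene bookkeeping", {
  dmr_genes <- data.table::data.table(
    dmr_id = "D1", gene_id = "g1", hit = "promoter", context = "CG",
    direction = "hyper")
  dmrs <- data.table::data.table(dmr_id = "D1", mean_diff = 0.35)
  degs <- data.table::data.table(gene_id = "g1", log2_fold_change = -1,
                                 status = "down")
  out <- dmr_gene_expression_association(dmr_genes, dmrs, degs)
  g <- out$genes
  expect_equal(g$direction, "hyper")
  expect_equal(g$deg_status, "down")
  expect_true(g$concordant)
  expect_equal(g$meth_diff, 0.35)
})

test_that("DEG profile classes: 'all' is the union of up and down", {
  fix <- small_fixture()
  degs <- data.table::data.table(
    gene_id = fix$genes$gene_id[1:6],
    status = c("up", "up", "down", "down", "down", "ns"))
  pr <- deg_methylation_profiles(fix$bs, fix$genes, degs)
  expect_true(all(c("all", "up", "down") %in% pr$group))
  n_genes_all <- pr[group == "all", max(n_genes)]
  expect_lte(n_genes_all, 5L)   # union excludes the ns gene
  expect_gte(n_genes_all, pr[group == "up", max(n_genes)])
  # both conditions profiled
  expect_setequal(unique(pr$condition), c("WT", "RT"))
  # no DEGs at all -> empty result
  none <- data.table::data.table(gene_id = character(), status = character())
  expect_equal(nrow(suppressMessages(
    deg_methylation_profiles(fix$bs, fix$genes, none))), 0L)
})

test_that("TE association emits exactly the in-domain triples", {
  genes <- gene_models("chr1", tss = 10000L, tes = 13000L, strand = "+",
                       gene_id = "g1", seqlengths = c(chr1 = 50000L))
  tes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(9000L, 11000L, 11400L, 30000L),
                     c(9500L, 11300L, 11900L, 30500L)))
  tes$te_id <- paste0("T", 1:4)
  tes$te_class <- c("classI", "classI", "classII", "classI")
  tes$family <- c("Copia", "Copia", "Helitron", "Gypsy")
  dmrs <- data.table::data.table(
    dmr_id = c("D1", "D2"), chrom = "chr1",
    start = c(11200L, 30100L), end = c(11500L, 30400L),
    context = "CHH", direction = c("hypo", "hyper"))
  degs <- data.table::data.table(gene_id = "g1", log2_fold_change = 1.2,
                                 status = "up")
  idx <- build_feature_index(genes, NULL, tes)
  ann <- annotate_dmrs(dmrs, idx)
  # force g1 into the DMR-related set via a promoter DMR-free body overlap:
  # D1 overlaps the gene body already
  expect_true("g1" %in% ann$genes$gene_id)
  out <- te_dmr_deg_association(dmrs, ann, degs, genes, tes)
  # D1 spans T2 and T3 (both in domain) -> two triples; T4/D2 outside every
  # gene domain -> excluded; T1 is in the domain but has no DMR
  expect_equal(nrow(out$triples), 2L)
  expect_setequal(out$triples$te_id, c("T2", "T3"))
  expect_true(all(out$triples$dmr_id == "D1"))
  expect_true(all(out$triples$te_position == "body"))
  expect_equal(out$triples$deg_status, rep("up", 2))
  # summary: one of two CHH-hypo DMRs lies in TEs
  smry <- out$te_dmr_summary
  expect_equal(smry[direction == "hypo", n_dmrs_in_te], 1L)
})

test_that("planted coupling surfaces as negative promoter correlation", {
  fix <- small_fixture()
  degs <- detect_degs(fix$expr$counts, fix$expr$condition)
  wt <- fix$bs$samples[fix$bs$condition == "WT"]
  rt <- fix$bs$samples[fix$bs$condition == "RT"]
  pw <- gene_region_methylation(fix$bs, fix$genes, "promoter", samples = wt)
  pr <- gene_region_methylation(fix$bs, fix$genes, "promoter", samples = rt)
  pm <- merge(pw, pr, by = c("gene_id", "context"))
  pm <- pm[, .(value = mean(mean_level.x - mean_level.y)), by = gene_id]
  lfc <- setNames(degs$log2_fold_change, degs$gene_id)
  keep <- fix$expr$truth_expr[class == "normal", gene_id]
  r <- correlate_meth_expr(pm[gene_id %in% keep][, stratum := "s"], lfc)
  expect_lt(r$pearson_r, 0)
})
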