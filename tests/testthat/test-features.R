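# feature labeling, metagene profiles, gene grouping, TE density

# toy annotation on a 20-kb contig: one gene per strand plus one TE
toy_annotation <- function() {
  genes <- gene_models(chrom = c("chr1", "chr1"),
                       tss = c(5000L, 16000L), tes = c(8000L, 13000L),
                       strand = c("+", "-"),
                       gene_id = c("gp", "gm"),
                       seqlengths = c(chr1 = 20000L))
  exons <- GenomicRanges::GRangesList(
    gp = GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(5000L, 7000L), c(6000L, 8000L))),
    gm = GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(13000L, 15000L), c(14000L, 16000L))))
  tes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7200L, 7400L))
  tes$te_id <- "TE0001"; tes$te_class <- "classI"; tes$family <- "Copia"
  list(genes = genes, exons = exons, tes = tes)
}

# brute-force per-base labeling oracle over explicit intervals
oracle_labels <- function(pos) {
  labs <- character()
  if (pos >= 5000 && pos <= 8000) labs <- c(labs, "body")
  if (pos >= 13000 && pos <= 16000) labs <- c(labs, "body")
  if ((pos >= 3000 && pos <= 4999) ||        # + gene upstream
      (pos >= 16001 && pos <= 18000))        # - gene upstream (higher coords)
    labs <- c(labs, "promoter", "up2k")
  if ((pos >= 8001 && pos <= 10000) ||       # + gene downstream
      (pos >= 11000 && pos <= 12999))        # - gene downstream (lower coords)
    labs <- c(labs, "down2k")
  if ((pos >= 5000 && pos <= 6000) || (pos >= 7000 && pos <= 8000) ||
      (pos >= 13000 && pos <= 14000) || (pos >= 15000 && pos <= 16000))
    labs <- c(labs, "exon")
  if ((pos >= 6001 && pos <= 6999) || (pos >= 14001 && pos <= 14999))
    labs <- c(labs, "intron")
  if (pos >= 7200 && pos <= 7400) labs <- c(labs, "te")
  if (!any(c("body", "promoter", "down2k") %in% labs))
    labs <- c(labs, "intergenic")
  labs
}

test_that("position labels match the brute-force oracle on both strands", {
  ann <- toy_annotation()
  idx <- build_feature_index(ann$genes, ann$exons, ann$tes)
  probe <- c(1000, 2999, 3000, 4999, 5000, 5500, 6001, 6500, 7000, 7300,
             8000, 8001, 10000, 10001, 10999, 11000, 12999, 13000, 14500,
             16000, 16001, 18000, 18001, 19999)
  for (p in probe) {
    expect_setequal(position_labels(idx, "chr1", p), oracle_labels(p))
  }
  # 500 bp 5' of the minus-strand gene's TSS = numerically greater coordinate
  expect_true(all(c("promoter", "up2k") %in%
                    position_labels(idx, "chr1", 16500)))
})

test_that("TE intragenic status means overlap with any gene body", {
  ann <- toy_annotation()
  idx <- build_feature_index(ann$genes, ann$exons, ann$tes)
  expect_true(idx$tes$intragenic)   # TE at 7200-7400 inside gene gp
  tes2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000L, 1500L))
  tes2$te_id <- "TE0002"; tes2$te_class <- "classII"; tes2$family <- "hAT"
  idx2 <- build_feature_index(ann$genes, ann$exons, tes2)
  expect_false(idx2$tes$intragenic)
})

test_that("misordered TSS/TES raises an annotation error", {
  expect_error(gene_models("chr1", tss = 500L, tes = 100L, strand = "+",
                           gene_id = "bad"), "annotation error")
  expect_error(gene_models("chr1", tss = 100L, tes = 500L, strand = "-",
                           gene_id = "bad"), "annotation error")
  # and the valid orientations pass
  expect_silent(gene_models("chr1", tss = 100L, tes = 500L, strand = "+",
                            gene_id = "ok"))
  expect_silent(gene_models("chr1", tss = 500L, tes = 100L, strand = "-",
                            gene_id = "ok"))
})

test_that("uniform site levels give uniform region means; empty strata are missing", {
  ann <- toy_annotation()
  idx <- build_feature_index(ann$genes, ann$exons, ann$tes)
  pos <- seq(100L, 19900L, by = 100L)
  bs <- toy_bs(pos, M = matrix(5L, length(pos), 2),
               N = matrix(10L, length(pos), 2), context = "CG",
               condition = c("WT", "RT"))
  rm_ <- region_methylation(bs, idx)
  expect_true(all(abs(rm_$regions$mean_level - 0.5) < 1e-12))
  # CHH never occurs -> no CHH rows, not zeros
  expect_false("CHH" %in% rm_$regions$context)
  expect_true(all(c("body", "promoter", "intron", "te",
                    "intergenic") %in% rm_$regions$label))
})

test_that("metagene profile is flat for a uniform methylome", {
  ann <- toy_annotation()
  pos <- seq(2000L, 19000L, by = 20L)
  bs <- toy_bs(pos, M = matrix(3L, length(pos), 1),
               N = matrix(10L, length(pos), 1), context = "CG",
               condition = "WT")
  pr <- metagene_profile(bs, ann$genes)
  expect_true(all(abs(pr$mean_level - 0.3) < 1e-12))
  expect_equal(sort(unique(pr$bin)), 1:50)
  expect_equal(levels(pr$region), c("upstream", "body", "downstream"))
})

test_that("minus-strand genes profile identically to their mirrored plus twin", {
  # one gene per strand, mirror-image geometries and site layouts
  L <- 30000L
  gp <- gene_models("chr1", tss = 10000L, tes = 12000L, strand = "+",
                    gene_id = "fw", seqlengths = c(chr1 = L))
  gm <- gene_models("chr1", tss = L - 10000L + 1L, tes = L - 12000L + 1L,
                    strand = "-", gene_id = "rv", seqlengths = c(chr1 = L))
  off <- seq(-2500L, 4500L, by = 37L)     # offsets relative to the TSS
  lvl <- round(seq(10, 90, length.out = length(off)))
  pos_p <- 10000L + off
  pos_m <- (L - 10000L + 1L) - off
  ord_m <- order(pos_m)
  bs_p <- toy_bs(pos_p, M = matrix(as.integer(lvl), ncol = 1),
                 N = matrix(100L, length(off), 1), condition = "WT")
  bs_m <- toy_bs(pos_m[ord_m], M = matrix(as.integer(lvl[ord_m]), ncol = 1),
                 N = matrix(100L, length(off), 1), condition = "WT")
  pr_p <- metagene_profile(bs_p, gp)
  pr_m <- metagene_profile(bs_m, gm)
  merged <- merge(pr_p, pr_m, by = c("context", "region", "bin"))
  expect_gt(nrow(merged), 50L)
  expect_equal(merged$mean_level.x, merged$mean_level.y)
})

test_that("metagene profile is invariant under coordinate translation", {
  ann <- toy_annotation()
  pos <- seq(2500L, 11000L, by = 73L)
  set.seed(11)
  M <- matrix(as.integer(rbinom(length(pos), 20, 0.4)), ncol = 1)
  N <- matrix(20L, length(pos), 1)
  bs1 <- toy_bs(pos, M, N, condition = "WT")
  shift <- 1234L
  g2 <- gene_models("chr1", tss = 5000L + shift, tes = 8000L + shift,
                    strand = "+", gene_id = "gp")
  bs2 <- toy_bs(pos + shift, M, N, condition = "WT")
  pr1 <- metagene_profile(bs1, ann$genes[ann$genes$gene_id == "gp"])
  pr2 <- metagene_profile(bs2, g2)
  expect_equal(pr1$mean_level, pr2$mean_level)
  expect_equal(pr1$n_sites, pr2$n_sites)
})

test_that("expression quartile groups follow the chosen percentile rule", {
  f <- c(a = 0.5, b = 2, c = 10, d = 100)
  # linear-interpolation percentiles over the 3 expressed genes: 6 and 55
  g7 <- expression_groups(f)
  expect_equal(g7$fpkm_25, 6)
  expect_equal(g7$fpkm_75, 55)
  expect_equal(as.character(g7$assignment), c("no", "low", "medium", "high"))
  # inverse-ecdf percentiles give boundaries 2 and 100
  g1 <- expression_groups(f, quantile_type = 1)
  expect_equal(g1$fpkm_25, 2)
  expect_equal(g1$fpkm_75, 100)
  expect_equal(as.character(g1$assignment), c("no", "medium", "medium", "high"))
  # the 75th-percentile boundary is inclusive for "high"
  expect_equal(as.character(g7$assignment["d"]), "high")
  # all unexpressed
  g0 <- expression_groups(c(0.1, 0.2, 0.9))
  expect_true(all(g0$assignment == "no"))
  expect_error(expression_groups(c(0.5, 2, 3)), "fewer than 3")
  # groups partition the gene set
  set.seed(2)
  f2 <- setNames(rlnorm(200, 1, 2), paste0("g", 1:200))
  gg <- expression_groups(f2)
  expect_equal(sum(table(gg$assignment)), 200L)
})

test_that("methylation quintiles split evenly and handle missing/degenerate input", {
  lv <- setNames(seq(0, 1, length.out = 100), paste0("g", 1:100))
  mg <- methylation_groups(lv)
  expect_true(all(abs(table(mg$assignment) - 20L) <= 1L))
  # boundary membership: >= level_80 is group 5
  expect_equal(as.integer(mg$assignment[which(lv >= mg$boundaries[4])[1]]), 5L)
  # NA levels excluded and counted
  lv2 <- c(lv, gNA = NA)
  mg2 <- methylation_groups(lv2)
  expect_equal(mg2$n_excluded, 1L)
  expect_warning(methylation_groups(rep(0.5, 10)), "degenerate")
  # frequency table covers every group and sums to the gene count
  f <- setNames(rlnorm(100, 1, 1), names(lv))
  tab <- group_expression_table(mg, f)
  expect_equal(sum(tab$count), 100L)
})

test_that("TE density profile reflects planted TE placement", {
  g <- gene_models("chr1", tss = 10000L, tes = 12500L, strand = "+",
                   gene_id = "g1")
  expect_equal(nrow(te_density_profile(GenomicRanges::GRanges(), g)), 0L)
  # a TE exactly covering upstream bins 1-10 (the far end of the flank)
  te1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8000L, 8399L))
  te1$te_id <- "T1"; te1$te_class <- "classI"; te1$family <- "Copia"
  d <- te_density_profile(te1, g)
  expect_equal(d[region == "upstream" & bin <= 10, fraction], rep(1, 10))
  expect_equal(d[region == "body", sum(fraction)], 0)
  # LTRs planted only in flanks dominate flank bins over body bins
  te2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(8100L, 12600L), c(9900L, 14300L)))
  te2$te_id <- c("T2", "T3"); te2$te_class <- "classI"
  te2$family <- "Gypsy"
  d2 <- te_density_profile(te2, g)
  expect_gt(d2[region != "body", mean(fraction)],
            d2[region == "body", mean(fraction)])
})
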