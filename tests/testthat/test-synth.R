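# synthetic genome / methylome / expression generator

test_that("identical configuration yields byte-identical fixture files", {
  cfg <- sim_config(genome_length = 6e4, n_chromosomes = 1L, n_genes = 4L,
                    n_tes = 5L, n_dmrs = 3L, seed = 7)
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  p1 <- write_fixture_set(suppressWarnings(simulate_fixture(cfg)), d1)
  p2 <- write_fixture_set(suppressWarnings(simulate_fixture(cfg)), d2)
  flatten <- function(p) unlist(p, use.names = FALSE)
  for (k in seq_along(flatten(p1))) {
    f1 <- flatten(p1)[k]; f2 <- flatten(p2)[k]
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)),
                     label = basename(f1))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero genes still yields a genome; infeasible sizing errors out", {
  cfg <- sim_config(genome_length = 5e4, n_chromosomes = 1L, n_genes = 0L,
                    n_tes = 0L, n_dmrs = 0L)
  ann <- generate_genome(cfg)
  expect_length(ann$genes, 0L)
  expect_gte(length(ann$genome), 2L)  # chromosome + spike-in contig
  expect_error(generate_genome(
    sim_config(genome_length = 5e4, n_chromosomes = 1L, n_genes = 50L)),
    "cannot fit")
})

test_that("emitted gene models have 2-kb strand-respecting promoters", {
  fix <- small_fixture()
  dir <- file.path(tempdir(), "fixgff")
  paths <- write_fixture_set(fix, dir)
  gm <- read_gene_models(paths$genes_path)
  expect_length(gm$genes, 20L)
  prom <- methexpr:::promoter_regions(gm$genes)
  expect_true(all(width(prom) == 2000L))
  # brute-force orientation scan on the emitted coordinates
  gdt <- as.data.frame(gm$genes)
  pdt <- as.data.frame(prom)
  for (i in seq_len(nrow(gdt))) {
    if (gdt$strand[i] == "+") {
      expect_equal(pdt$end[i], gdt$start[i] - 1L)
      expect_equal(pdt$start[i], gdt$start[i] - 2000L)
    } else {
      expect_equal(pdt$start[i], gdt$end[i] + 1L)
      expect_equal(pdt$end[i], gdt$end[i] + 2000L)
    }
  }
  # every exon lies within its gene body
  for (gid in gdt$gene_id) {
    ex <- gm$exons[[gid]]
    g <- gm$genes[gm$genes$gene_id == gid]
    expect_true(all(start(ex) >= start(g) & end(ex) <= end(g)))
  }
  unlink(dir, recursive = TRUE)
})

test_that("cytosine reports round-trip and respect count conservation", {
  fix <- small_fixture()
  expect_true(all(fix$bs$M <= fix$bs$N))
  expect_true(all(fix$bs$M >= 0L))
  dir <- file.path(tempdir(), "fixcx")
  paths <- write_fixture_set(fix, dir)
  back <- read_cx_reports(paths$cx_paths, names(paths$cx_paths),
                          condition = as.character(fix$bs$condition))
  expect_equal(back$M, fix$bs$M, ignore_attr = TRUE)
  expect_equal(back$N, fix$bs$N, ignore_attr = TRUE)
  expect_equal(back$sites$context, fix$bs$sites$context)
  # every emitted record sits on a genuine cytosine of the genome
  idx <- sample(nrow(back$sites), 200)
  for (i in idx) {
    expect_identical(
      classify_context(fix$genome, back$sites$chrom[i], back$sites$pos[i],
                       back$sites$strand[i]),
      back$sites$context[i])
  }
  unlink(dir, recursive = TRUE)
})

test_that("with zero dispersion and no DMRs, context means match the baselines", {
  cfg <- sim_config(genome_length = 1e5, n_chromosomes = 1L, n_genes = 0L,
                    n_tes = 0L, n_dmrs = 0L, nonconversion_rate = 0,
                    dispersion = c(CG = 0, CHG = 0, CHH = 0), seed = 3)
  ann <- generate_genome(cfg)
  sim <- simulate_methylome(ann$genome, ann$genes, ann$tes, cfg)
  bs <- sim$bs
  for (cx in c("CG", "CHG", "CHH")) {
    i <- bs$sites$context == cx
    lv <- methylation_level(bs$M[i, 1], bs$N[i, 1] - bs$M[i, 1])
    lv <- lv[!is.na(lv)]
    mu <- cfg$baseline_levels[[cx]]
    se <- sqrt(mu * (1 - mu) / cfg$depth_mean / length(lv))
    expect_lt(abs(mean(lv) - mu), 3 * se + 1e-3)
  }
})

test_that("planted regions realize their methylation shift in the counts", {
  fix <- small_fixture()
  bs <- fix$bs
  wt <- which(bs$condition == "WT"); rt <- which(bs$condition == "RT")
  for (d in seq_len(nrow(fix$truth_dmrs))) {
    tr <- fix$truth_dmrs[d]
    i <- which(bs$sites$chrom == tr$chrom & bs$sites$pos >= tr$start &
                 bs$sites$pos <= tr$end & bs$sites$context == tr$context)
    diff <- sum(bs$M[i, wt]) / sum(bs$N[i, wt]) -
      sum(bs$M[i, rt]) / sum(bs$N[i, rt])
    expect_lt(abs(diff - tr$realized_effect), 0.08)
  }
  # effects beyond [0,1] are clipped with a warning
  expect_warning(
    simulate_methylome(fix$genome, fix$genes, fix$tes,
                       small_config()),
    "clipped")
})

test_that("expression matrix has one column per sample and realizes the coupling", {
  fix <- small_fixture()
  expect_equal(ncol(fix$expr$counts), 6L)
  expect_equal(colnames(fix$expr$counts),
               c("WT1", "WT2", "WT3", "RT1", "RT2", "RT3"))
  # analytic mean ratio: log(mu_WT / mu_RT) = coupling_slope * delta
  te <- fix$expr$truth_expr
  expect_equal(te$true_lfc_ln, fix$config$coupling_slope * te$delta_promoter)
  # empirical check pooled over coupled genes (shared relative error)
  coupled <- which(te$delta_promoter != 0 & te$class == "normal")
  expect_gt(length(coupled), 0L)
  obs <- log(rowMeans(fix$expr$counts[coupled, 1:3, drop = FALSE]) + 0.5) -
    log(rowMeans(fix$expr$counts[coupled, 4:6, drop = FALSE]) + 0.5)
  expect_lt(mean(abs(obs - te$true_lfc_ln[coupled])), 0.35)
})

test_that("a zero coupling slope leaves no planted expression effect", {
  cfg <- small_config()
  cfg$coupling_slope <- 0
  fix <- suppressWarnings(simulate_fixture(cfg))
  expect_true(all(fix$expr$truth_expr$true_lfc_ln == 0))
})

test_that("truth records reference existing genes and TEs", {
  fix <- small_fixture()
  tr <- fix$truth_dmrs
  gid <- tr$gene_id[!is.na(tr$gene_id)]
  expect_true(all(gid %in% fix$genes$gene_id))
  tid <- tr$te_id[!is.na(tr$te_id)]
  expect_true(all(tid %in% fix$tes$te_id))
  expect_true(all(tr$n_sites >= fix$config$dmr_min_sites))
})
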