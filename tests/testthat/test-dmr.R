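# differential methylation: smoothing, dispersion, Wald test, DMR merging

test_that("smoothing is a depth-weighted moving average with identity edge cases", {
  # isolated site keeps its own level
  expect_equal(smooth_levels(100L, 0.7, 10, 500), 0.7)
  # three equidistant equal-depth sites, window spans all: center is the mean
  sm <- smooth_levels(c(100L, 200L, 300L), c(0, 0.5, 1), c(10, 10, 10), 500)
  expect_equal(sm[2], 0.5)
  # window 0 disables smoothing entirely
  lv <- c(0.1, 0.9, 0.4)
  expect_identical(smooth_levels(c(1L, 2L, 3L), lv, c(5, 5, 5), 0), lv)
  # depth weighting: heavy site dominates
  sm2 <- smooth_levels(c(100L, 110L), c(0, 1), c(90, 10), 500)
  expect_equal(sm2[1], 0.1)
})

test_that("method-of-moments dispersion matches the closed-form hand oracle", {
  # replicates (3/10, 7/10): pbar = 0.5, s2 = 0.08,
  # phi = (0.08/0.25 - 1/10) / (9/10) = 0.24444...
  est <- estimate_dispersion(matrix(c(3L, 7L), 1, 2), matrix(10L, 1, 2),
                             shrink = FALSE)
  expect_equal(est$phi_mom, (0.08 / 0.25 - 0.1) / 0.9, tolerance = 1e-12)
})

test_that("dispersion estimates are consistent on simulated beta-binomial data", {
  set.seed(5)
  n <- 1000; R <- 3
  N <- matrix(rpois(n * R, 30), n, R)
  M <- matrix(rbetabinom(n * R, as.vector(N), 0.3, 0.05), n, R)
  est <- estimate_dispersion(M, N)
  expect_gt(median(est$phi), 0.03)
  expect_lt(median(est$phi), 0.08)
  # floor honored when replicates agree perfectly at high depth
  est0 <- estimate_dispersion(matrix(50L, 5, 3), matrix(100L, 5, 3))
  expect_true(all(est0$phi >= 1e-4))
  expect_lt(max(est0$phi), 0.02)
})

test_that("Wald test returns null identity and extreme separation correctly", {
  # identical counts in both conditions -> stat 0, p 1
  M <- matrix(c(5L, 7L, 6L, 5L, 7L, 6L), 1)
  N <- matrix(20L, 1, 6)
  bs <- toy_bs(1000L, M, N, condition = rep(c("WT", "RT"), each = 3))
  res <- dml_test(bs, window_bp = 0)
  expect_equal(res$stat, 0)
  expect_equal(res$pval, 1)
  # complete separation at depth 50 x 3 -> vanishing p
  bs2 <- toy_bs(1000L, matrix(c(50L, 50L, 50L, 0L, 0L, 0L), 1),
                matrix(50L, 1, 6), condition = rep(c("WT", "RT"), each = 3))
  res2 <- dml_test(bs2, window_bp = 0)
  expect_equal(res2$diff, 1)
  expect_lt(res2$pval, 1e-10)
  # positive diff means higher in the first (reference) condition
  expect_gt(res2$stat, 0)
})

test_that("per-site test is calibrated on an iid beta-binomial null", {
  set.seed(17)
  n <- 10000
  N <- matrix(rpois(n * 6, 30), n, 6)
  M <- matrix(rbetabinom(length(N), as.vector(N), 0.3, 0.05), n, 6)
  bs <- toy_bs(seq_len(n) * 1000L, M, N,
               condition = rep(c("WT", "RT"), each = 3))
  res <- dml_test(bs, window_bp = 0)
  t1 <- mean(res$pval < 0.05)
  expect_gt(t1, 0.03); expect_lt(t1, 0.07)
})

test_that("Wald ordering agrees with a brute-force likelihood-ratio oracle", {
  set.seed(23)
  n_sites <- 20
  N <- matrix(rpois(n_sites * 6, 30), n_sites, 6)
  mu1 <- runif(n_sites, 0.15, 0.85)
  mu2 <- pmin(pmax(mu1 + sample(c(-1, 1), n_sites, TRUE) *
                     runif(n_sites, 0, 0.45), 0.02), 0.98)
  M <- matrix(0L, n_sites, 6)
  for (j in 1:3) M[, j] <- rbetabinom(n_sites, N[, j], mu1, 0.05)
  for (j in 4:6) M[, j] <- rbetabinom(n_sites, N[, j], mu2, 0.05)
  bs <- toy_bs(seq_len(n_sites) * 10000L, M, N,
               condition = rep(c("WT", "RT"), each = 3))
  res <- dml_test(bs, window_bp = 0)
  # oracle: beta-binomial likelihood-ratio statistic at the known phi,
  # maximizing the common-mean and separate-mean likelihoods numerically
  bb_ll <- function(mu, y, n, phi = 0.05) {
    s <- (1 - phi) / phi; a <- mu * s; b <- (1 - mu) * s
    sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
  }
  nll_hat <- function(y, n)
    optimize(function(m) -bb_ll(m, y, n), c(1e-4, 1 - 1e-4))$objective
  lr <- sapply(seq_len(n_sites), function(i)
    nll_hat(M[i, ], N[i, ]) - nll_hat(M[i, 1:3], N[i, 1:3]) -
      nll_hat(M[i, 4:6], N[i, 4:6]))
  expect_gte(cor(abs(res$stat), lr, method = "spearman"), 0.9)
})

# minimal DML table for merge-rule tracing
dml_row <- function(pos, diff, pval, context = "CG") {
  data.table::data.table(
    chrom = "chr1", pos = as.integer(pos), strand = "+", context = context,
    mu1 = 0.5 + diff / 2, mu2 = 0.5 - diff / 2, phi1 = 0.01, phi2 = 0.01,
    diff = diff, se = 0.05, stat = diff / 0.05, pval = pval,
    padj = pval, raw_diff = diff, raw_stat = diff / 0.05,
    raw_pval = pmin(pval * 10, 1), depth1 = 90, depth2 = 90)
}

test_that("merge rules produce exactly the regions traced by hand", {
  # five significant same-sign CG sites within 200 bp -> one hyper DMR
  dml <- rbind(dml_row(seq(100, 300, by = 50), 0.4, 1e-8),
               dml_row(c(50, 350), 0.01, 0.5))
  dmrs <- call_dmrs(dml)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$start, 99L)      # 0-based half-open
  expect_equal(dmrs$end, 300L)
  expect_equal(dmrs$n_sites, 5L)
  expect_equal(dmrs$direction, "hyper")
  # no significant sites -> no regions
  expect_equal(nrow(call_dmrs(dml_row(1:10 * 100, 0.2, 0.2))), 0L)
  # a sign flip mid-run splits into two regions of opposite direction
  dml2 <- rbind(dml_row(seq(100, 200, by = 50), 0.4, 1e-8),
                dml_row(seq(250, 350, by = 50), -0.4, 1e-8))
  dmrs2 <- call_dmrs(dml2)
  expect_equal(nrow(dmrs2), 2L)
  expect_equal(dmrs2$direction, c("hyper", "hypo"))
  # a gap larger than max_gap splits a run
  dml3 <- rbind(dml_row(seq(100, 200, by = 50), 0.4, 1e-8),
                dml_row(seq(600, 700, by = 50), 0.4, 1e-8))
  expect_equal(nrow(call_dmrs(dml3)), 2L)
  # min_sites and min_len filters
  expect_equal(nrow(call_dmrs(dml_row(c(100, 200), 0.4, 1e-8))), 0L)
  expect_equal(nrow(call_dmrs(dml_row(c(100, 110, 120), 0.4, 1e-8),
                              min_len = 50L)), 0L)
})

test_that("called DMRs conserve the raw count-level direction", {
  fix <- small_fixture()
  bs <- fix$bs
  dmrs <- small_dmrs()
  expect_gt(nrow(dmrs), 0L)
  wt <- which(bs$condition == "WT"); rt <- which(bs$condition == "RT")
  for (d in seq_len(nrow(dmrs))) {
    i <- which(bs$sites$chrom == dmrs$chrom[d] &
                 bs$sites$pos > dmrs$start[d] & bs$sites$pos <= dmrs$end[d] &
                 bs$sites$context == dmrs$context[d])
    diff <- sum(bs$M[i, wt]) / sum(bs$N[i, wt]) -
      sum(bs$M[i, rt]) / sum(bs$N[i, rt])
    expect_equal(sign(diff), if (dmrs$direction[d] == "hyper") 1 else -1,
                 label = dmrs$dmr_id[d])
  }
})

test_that("planted regions are recovered with matching direction on the small fixture", {
  ev <- evaluate_dmr_recovery(small_dmrs(), small_fixture()$truth_dmrs,
                              min_effect = 0.3, min_sites = 5L)
  expect_gt(ev$n_qualifying, 3L)
  expect_gte(ev$recovery_rate, 0.8)
  expect_equal(ev$direction_match_rate, 1)
})

test_that("DMR annotation applies the 1-bp overlap rule for genes and promoters", {
  genes <- gene_models("chr1", tss = 5000L, tes = 8000L, strand = "+",
                       gene_id = "g1", seqlengths = c(chr1 = 20000L))
  tes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6000L, 6400L))
  tes$te_id <- "T1"; tes$te_class <- "classII"; tes$family <- "Helitron"
  idx <- build_feature_index(genes, NULL, tes)
  dmrs <- data.table::data.table(
    dmr_id = c("D1", "D2", "D3"), chrom = "chr1",
    start = c(3499L, 4899L, 9999L), end = c(3800L, 5200L, 10400L),
    context = "CG", direction = c("hyper", "hypo", "hyper"))
  ann <- annotate_dmrs(dmrs, idx)
  # D1 fully inside the promoter: promoter hit only
  expect_identical(ann$genes[dmr_id == "D1", hit], "promoter")
  # D2 spans the TSS: listed under both
  expect_setequal(ann$genes[dmr_id == "D2", hit], c("body", "promoter"))
  # D3 outside everything: no gene hits
  expect_equal(nrow(ann$genes[dmr_id == "D3"]), 0L)
  # no TE overlap for these regions
  expect_equal(nrow(ann$tes), 0L)
  # a DMR inside the TE is annotated with class and intragenic status
  dmr_te <- data.table::data.table(dmr_id = "D4", chrom = "chr1",
                                   start = 6100L, end = 6200L,
                                   context = "CHH", direction = "hyper")
  ann2 <- annotate_dmrs(dmr_te, idx)
  expect_equal(ann2$tes$te_id, "T1")
  expect_true(ann2$tes$intragenic)
})
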