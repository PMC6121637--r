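#' Configuration for the synthetic WGBS + RNA-seq fixture generator
#'
#' Defines the study conditions emulated by the generator: a small
#' diploid-like genome, two conditions (default WT = white petal tissue,
#' RT = red petal tissue) with three biological replicates each,
#' beta-binomially distributed per-site methylation counts with
#' context-dependent baselines, planted hyper-/hypomethylated regions in
#' promoters, gene bodies, TEs and intergenic space, negative-binomial
#' expression counts coupled to promoter methylation differences, and an
#' unmethylated spike-in contig for the bisulfite non-conversion rate.
#'
#' @param genome_length total genome length in bases (excluding spike-in).
#' @param n_chromosomes number of chromosomes.
#' @param n_genes,n_tes number of genes / transposable elements.
#' @param te_class_fractions proportions over `c(classI, classII)`; must sum
#'   to 1.
#' @param conditions two condition labels, first is the reference (its
#'   methylation is shifted inside planted DMRs).
#' @param replicates_per_condition biological replicates per condition (>= 2).
#' @param baseline_levels mean methylation proportion per context
#'   `c(CG, CHG, CHH)`.
#' @param dispersion beta-binomial replicate-to-replicate overdispersion per
#'   context.
#' @param depth_mean mean per-site read depth (Poisson).
#' @param n_dmrs number of planted differentially methylated regions.
#' @param dmr_effect signed additive shift(s) in methylation proportion for
#'   the first condition inside planted DMRs; recycled over DMRs (the default
#'   alternates hyper and hypo regions).
#' @param dmr_placement proportions over
#'   `c(promoter, body, te, intergenic)`; must sum to 1.
#' @param coupling_slope expression log-fold-change (natural log, condition 1
#'   vs condition 2) per unit of planted promoter-methylation difference.
#' @param nonconversion_rate bisulfite non-conversion rate in \[0, 0.05\].
#' @param seed integer seed; the fixture is byte-identical given the same
#'   configuration.
#' @param gene_length_range,te_length_range,dmr_length_range min/max lengths
#'   (bp) for gene bodies, TEs, and planted DMRs.
#' @param dmr_min_sites minimum cytosines of the target context a planted
#'   DMR must contain.
#' @param spikein_length length of the unmethylated control contig.
#' @param expr_mean_log,expr_sd_log log-normal parameters of the relative
#'   baseline gene expression weights.
#' @param library_size expected total assigned fragments per sample; gene
#'   means are scaled to this depth so FPKM thresholds behave as in a real
#'   library.
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @param frac_silent,frac_wt_specific,frac_rt_specific fractions of genes
#'   planted as unexpressed or condition-specific.
#' @param te_intragenic_fraction fraction of TEs placed inside gene bodies.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2.4e6,
                       n_chromosomes = 2L,
                       n_genes = 300L,
                       n_tes = 200L,
                       te_class_fractions = c(classI = 0.6, classII = 0.4),
                       conditions = c("WT", "RT"),
                       replicates_per_condition = 3L,
                       baseline_levels = c(CG = 0.380, CHG = 0.204, CHH = 0.092),
                       dispersion = c(CG = 0.05, CHG = 0.05, CHH = 0.05),
                       depth_mean = 30,
                       n_dmrs = 60L,
                       dmr_effect = c(0.4, -0.4),
                       dmr_placement = c(promoter = 0.4, body = 0.3,
                                         te = 0.2, intergenic = 0.1),
                       coupling_slope = -2,
                       nonconversion_rate = 0.005,
                       seed = 1L,
                       gene_length_range = c(1000L, 2500L),
                       te_length_range = c(300L, 3000L),
                       dmr_length_range = c(200L, 1000L),
                       dmr_min_sites = 5L,
                       spikein_length = 5000L,
                       expr_mean_log = log(200),
                       expr_sd_log = 1,
                       library_size = 2e6,
                       nb_dispersion = 0.05,
                       frac_silent = 0.10,
                       frac_wt_specific = 0.03,
                       frac_rt_specific = 0.03,
                       te_intragenic_fraction = 0.5) {
  cfg <- as.list(environment())
  stopifnot(genome_length > 0, n_chromosomes >= 1, n_genes >= 0, n_tes >= 0)
  if (length(conditions) != 2L) stop("exactly two condition labels required")
  if (replicates_per_condition < 2L)
    stop("replicates_per_condition must be >= 2")
  if (abs(sum(te_class_fractions) - 1) > 1e-8)
    stop("te_class_fractions must sum to 1")
  if (abs(sum(dmr_placement) - 1) > 1e-8)
    stop("dmr_placement must sum to 1")
  for (nm in c("baseline_levels", "dispersion")) {
    v <- cfg[[nm]]
    if (!all(c("CG", "CHG", "CHH") %in% names(v)))
      stop(nm, " must be named with CG, CHG, CHH")
    if (any(v < 0 | v > 1)) stop(nm, " values must lie in [0, 1]")
  }
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (nonconversion_rate < 0 || nonconversion_rate > 0.05)
    stop("nonconversion_rate must lie in [0, 0.05]")
  if (any(abs(dmr_effect) > 1)) stop("dmr_effect must lie in [-1, 1]")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %.2g Mb / %d chromosomes, %d genes, %d TEs\n",
    "  %s x %d replicates, depth ~ Pois(%g), r = %g\n",
    "  baselines CG/CHG/CHH = %.3f/%.3f/%.3f, dispersion %.3g\n",
    "  %d DMRs (effect %s), coupling slope %g, seed %d\n"),
    x$genome_length / 1e6, x$n_chromosomes, x$n_genes, x$n_tes,
    paste(x$conditions, collapse = "/"), x$replicates_per_condition,
    x$depth_mean, x$nonconversion_rate,
    x$baseline_levels[["CG"]], x$baseline_levels[["CHG"]],
    x$baseline_levels[["CHH"]], x$dispersion[["CG"]],
    x$n_dmrs, paste(x$dmr_effect, collapse = "/"), x$coupling_slope, x$seed))
  invisible(x)
}

#' Generate a synthetic genome with gene and TE annotations
#'
#' Chromosome sequences are uniform random DNA; gene bodies are placed in
#' non-overlapping slots at least 2 kb from chromosome edges (so 2-kb
#' promoters and flanks always exist and never overlap a neighboring body),
#' each with 1-3 exons; TEs are placed both inside gene bodies and in
#' intergenic space with class/family labels. A separate unmethylated
#' control contig `lambda_control` is appended for non-conversion
#' estimation. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`, chromosomes plus
#'   `lambda_control`), `genes` (GRanges of gene bodies, strand-aware, with
#'   `gene_id`), `exons` (`GRangesList` keyed by gene), `tes` (GRanges with
#'   `te_id`, `te_class`, `family`).
#' @export
generate_genome <- function(config) {
  stopifnot(is(config, "sim_config"))
  with_seed(config$seed, {
    n_chr <- config$n_chromosomes
    chr_len <- rep(floor(config$genome_length / n_chr), n_chr)
    chr_names <- paste0("chr", seq_len(n_chr))
    glen_max <- config$gene_length_range[2]

    # distribute genes over chromosomes
    n_per <- rep(floor(config$n_genes / n_chr), n_chr)
    extra <- config$n_genes - sum(n_per)
    if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L

    for (i in seq_len(n_chr)) {
      usable <- chr_len[i] - 4000L
      if (n_per[i] > 0 && usable / n_per[i] < glen_max + 4000L)
        stop(sprintf(paste0("cannot fit %d genes of up to %d bp (plus 2-kb ",
                            "flanks) on a %d bp chromosome; enlarge the ",
                            "genome or reduce n_genes"),
                     n_per[i], glen_max, chr_len[i]))
    }

    seqs <- vapply(chr_len, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    spike <- paste(sample(c("A", "C", "G", "T"), config$spikein_length,
                          replace = TRUE), collapse = "")
    genome <- DNAStringSet(c(setNames(seqs, chr_names),
                             lambda_control = spike))

    gene_rows <- list(); exon_rows <- list()
    gid <- 0L
    for (i in seq_len(n_chr)) {
      if (n_per[i] == 0) next
      slot_w <- floor((chr_len[i] - 4000L) / n_per[i])
      for (k in seq_len(n_per[i])) {
        gid <- gid + 1L
        glen <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1L)
        slot_start <- 2000L + (k - 1L) * slot_w
        lo <- slot_start + 2000L
        hi <- slot_start + slot_w - 2000L - glen
        gstart <- if (hi > lo) lo + sample.int(hi - lo, 1L) else lo  # 1-based
        gend <- gstart + glen - 1L
        strand <- sample(c("+", "-"), 1L)
        gene_id <- sprintf("G%04d", gid)
        gene_rows[[gid]] <- data.table(chrom = chr_names[i], start = gstart,
                                       end = gend, strand = strand,
                                       gene_id = gene_id)
        # 1-3 exons separated by introns of >= 50 bp
        n_ex <- sample(1:3, 1L)
        if (n_ex == 1L || glen < 2L * n_ex * 60L) {
          ex <- data.table(start = gstart, end = gend)
        } else {
          n_seg <- 2L * n_ex - 1L
          w <- runif(n_seg, 0.5, 1.5)
          seg <- pmax(50L, floor(glen * w / sum(w)))
          seg[n_seg] <- glen - sum(seg[-n_seg])
          if (seg[n_seg] < 50L) { seg <- rep(floor(glen / n_seg), n_seg)
                                  seg[n_seg] <- glen - sum(seg[-n_seg]) }
          ends <- gstart - 1L + cumsum(seg)
          starts <- c(gstart, head(ends, -1L) + 1L)
          keep <- seq(1L, n_seg, by = 2L)
          ex <- data.table(start = starts[keep], end = ends[keep])
        }
        exon_rows[[gid]] <- ex[, .(chrom = chr_names[i], start, end,
                                   strand = strand, gene_id = gene_id)]
      }
    }
    genes_dt <- if (gid > 0) rbindlist(gene_rows) else
      data.table(chrom = character(), start = integer(), end = integer(),
                 strand = character(), gene_id = character())
    exons_dt <- if (gid > 0) rbindlist(exon_rows) else copy(genes_dt)

    seqlens <- setNames(c(chr_len, config$spikein_length),
                        c(chr_names, "lambda_control"))
    genes <- makeGRangesFromDataFrame(genes_dt, keep.extra.columns = TRUE,
                                      seqinfo = seqlens)
    exons_gr <- makeGRangesFromDataFrame(exons_dt, keep.extra.columns = TRUE,
                                         seqinfo = seqlens)
    exons <- GenomicRanges::split(exons_gr, exons_gr$gene_id)

    # TEs: a fraction inside gene bodies, the rest in intergenic space
    te_rows <- list()
    if (config$n_tes > 0) {
      n_intra <- if (gid > 0) round(config$n_tes * config$te_intragenic_fraction) else 0L
      n_inter <- config$n_tes - n_intra
      te_class <- sample(names(config$te_class_fractions), config$n_tes,
                         replace = TRUE, prob = config$te_class_fractions)
      fam_of <- function(cl) if (cl == "classI")
        sample(c("Copia", "Gypsy", "L1"), 1L) else sample(c("Helitron", "hAT"), 1L)
      t <- 0L
      if (n_intra > 0) {
        host <- sample(seq_len(nrow(genes_dt)), n_intra, replace = TRUE)
        for (k in seq_len(n_intra)) {
          t <- t + 1L
          g <- genes_dt[host[k]]
          tlen <- min(sample(config$te_length_range[1]:config$te_length_range[2], 1L),
                      g$end - g$start + 1L)
          ts <- g$start + sample.int(g$end - g$start + 2L - tlen, 1L) - 1L
          te_rows[[t]] <- data.table(chrom = g$chrom, start = ts,
                                     end = ts + tlen - 1L,
                                     te_class = te_class[t], family = fam_of(te_class[t]))
        }
      }
      for (k in seq_len(n_inter)) {
        t <- t + 1L
        for (try in 1:50) {
          ci <- sample.int(n_chr, 1L)
          tlen <- sample(config$te_length_range[1]:config$te_length_range[2], 1L)
          ts <- sample.int(chr_len[ci] - tlen, 1L)
          hit <- genes_dt[chrom == chr_names[ci] & start <= ts + tlen - 1L & end >= ts]
          if (nrow(hit) == 0L) break
        }
        te_rows[[t]] <- data.table(chrom = chr_names[ci], start = ts,
                                   end = ts + tlen - 1L,
                                   te_class = te_class[t], family = fam_of(te_class[t]))
      }
    }
    tes_dt <- if (length(te_rows)) rbindlist(te_rows) else
      data.table(chrom = character(), start = integer(), end = integer(),
                 te_class = character(), family = character())
    if (nrow(tes_dt)) {
      setorder(tes_dt, chrom, start)
      tes_dt[, te_id := sprintf("TE%04d", .I)]
    } else tes_dt[, te_id := character()]
    tes <- makeGRangesFromDataFrame(tes_dt, keep.extra.columns = TRUE,
                                    seqinfo = seqlens)
    list(genome = genome, genes = genes, exons = exons, tes = tes)
  })
}

# choose planted DMR windows over annotated features; internal
place_dmrs <- function(sites, ann, config) {
  if (config$n_dmrs == 0L)
    return(data.table(dmr_id = character(), chrom = character(),
                      start = integer(), end = integer(), context = character(),
                      feature_type = character(), gene_id = character(),
                      te_id = character(), effect = numeric()))
  types <- sample(rep(names(config$dmr_placement),
                      round_preserve(config$dmr_placement * config$n_dmrs)))
  contexts <- rep(c("CG", "CHG", "CHH"), length.out = length(types))
  effects <- rep(config$dmr_effect, length.out = length(types))
  genes_dt <- as.data.table(ann$genes)[, .(chrom = as.character(seqnames),
                                           start, end, strand = as.character(strand),
                                           gene_id)]
  tes_dt <- as.data.table(ann$tes)[, .(chrom = as.character(seqnames),
                                       start, end, te_id)]
  # promoters: 2 kb upstream of TSS, strand-aware
  prom_dt <- copy(genes_dt)
  prom_dt[, `:=`(pstart = ifelse(strand == "+", start - 2000L, end + 1L),
                 pend = ifelse(strand == "+", start - 1L, end + 2000L))]
  gene_pool <- sample(seq_len(nrow(genes_dt)))
  te_pool <- sample(seq_len(max(nrow(tes_dt), 0L)))
  # intergenic space: outside gene bodies +/- 2 kb
  occ <- reduce(c(GRanges(genes_dt$chrom, IRanges(genes_dt$start - 2000L,
                                                  genes_dt$end + 2000L)),
                  GRanges(tes_dt$chrom, IRanges(tes_dt$start, tes_dt$end))))
  rows <- list(); gi <- 0L; ti <- 0L
  setkey(sites, chrom, pos)
  n_ctx_sites <- function(chr, lo, hi, ctx)
    nrow(sites[chrom == chr & pos >= lo & pos <= hi & context == ctx])
  for (d in seq_along(types)) {
    ty <- types[d]; ctx <- contexts[d]
    placed <- FALSE
    for (try in 1:30) {
      wlen <- sample(config$dmr_length_range[1]:config$dmr_length_range[2], 1L)
      gene_id <- NA_character_; te_id <- NA_character_
      if (ty == "promoter" || ty == "body") {
        if (gi >= length(gene_pool)) break
        gi <- gi + 1L
        g <- genes_dt[gene_pool[gi]]
        gene_id <- g$gene_id
        if (ty == "promoter") {
          p <- prom_dt[prom_dt$gene_id == g$gene_id]
          lo <- p$pstart; hi <- p$pend
        } else { lo <- g$start; hi <- g$end }
        chr <- g$chrom
      } else if (ty == "te") {
        if (ti >= length(te_pool)) break
        ti <- ti + 1L
        te <- tes_dt[te_pool[ti]]
        te_id <- te$te_id; chr <- te$chrom; lo <- te$start; hi <- te$end
      } else { # intergenic
        free <- gaps(occ)
        free <- free[strand(free) == "*" & width(free) >= wlen & start(free) > 1]
        if (length(free) == 0L) break
        f <- free[sample.int(length(free), 1L)]
        chr <- as.character(seqnames(f)); lo <- start(f); hi <- end(f)
      }
      span <- hi - lo + 1L
      wlen2 <- min(wlen, span)
      ws <- lo + if (span > wlen2) sample.int(span - wlen2 + 1L, 1L) - 1L else 0L
      we <- ws + wlen2 - 1L
      if (n_ctx_sites(chr, ws, we, ctx) >= config$dmr_min_sites) {
        # grow to feature bounds if the window undershoots the site minimum
        rows[[length(rows) + 1L]] <- data.table(
          chrom = chr, start = ws, end = we, context = ctx,
          feature_type = ty, gene_id = gene_id, te_id = te_id,
          effect = effects[d])
        placed <- TRUE
        break
      }
      if (n_ctx_sites(chr, lo, hi, ctx) >= config$dmr_min_sites) {
        rows[[length(rows) + 1L]] <- data.table(
          chrom = chr, start = lo, end = hi, context = ctx,
          feature_type = ty, gene_id = gene_id, te_id = te_id,
          effect = effects[d])
        placed <- TRUE
        break
      }
    }
    if (!placed) next
  }
  out <- rbindlist(rows)
  if (nrow(out) < length(types))
    warning(sprintf("placed %d of %d requested DMRs (site-count constraints)",
                    nrow(out), length(types)))
  setorder(out, chrom, start)
  out[, dmr_id := sprintf("DMR%04d", .I)]
  setcolorder(out, "dmr_id")
  out[]
}

round_preserve <- function(x) {
  f <- floor(x)
  rem <- round(sum(x) - sum(f))
  if (rem > 0) {
    idx <- order(x - f, decreasing = TRUE)[seq_len(rem)]
    f[idx] <- f[idx] + 1
  }
  as.integer(f)
}

#' Simulate a replicated two-condition methylome over a synthetic genome
#'
#' Every cytosine site found in the genome receives, per sample, a Poisson
#' read depth and a beta-binomial methylated count whose mean is the
#' context baseline, shifted by the planted DMR effect for the first
#' condition inside each planted region, then mixed with the non-conversion
#' floor (`mu_obs = mu + (1 - mu) r`). The spike-in contig is emitted with
#' true methylation 0. Effects pushing the mean outside \[0, 1\] are clipped
#' with a warning; the truth table records the realized (post-clipping)
#' between-condition difference.
#'
#' @param genome,genes,tes components from [generate_genome()] (`tes` may be
#'   empty).
#' @param config the [sim_config()] used throughout.
#' @param exons optional `GRangesList` (carried through for callers).
#' @return list with `bs` (BSCounts over the chromosomes), `spike`
#'   (BSCounts over `lambda_control`), `truth_dmrs` (data.table: placement,
#'   nominal `effect`, realized per-condition means `mu1`/`mu2`,
#'   `realized_effect`, `n_sites`).
#' @export
simulate_methylome <- function(genome, genes, tes, config, exons = NULL) {
  stopifnot(is(config, "sim_config"))
  with_seed(config$seed + 1L, {
    sites_all <- find_cytosines(genome)
    is_spike <- sites_all$chrom == "lambda_control"
    sites <- sites_all[!is_spike]
    spike_sites <- sites_all[is_spike]

    truth <- place_dmrs(copy(sites), list(genes = genes, tes = tes), config)

    base <- config$baseline_levels[sites$context]
    mu1 <- as.numeric(base); mu2 <- as.numeric(base)
    truth[, `:=`(mu_base = NA_real_, mu1 = NA_real_, mu2 = NA_real_,
                 realized_effect = NA_real_, n_sites = NA_integer_)]
    clipped <- FALSE
    for (d in seq_len(nrow(truth))) {
      idx <- sites[, .I[chrom == truth$chrom[d] & pos >= truth$start[d] &
                          pos <= truth$end[d] & context == truth$context[d]]]
      mb <- config$baseline_levels[[truth$context[d]]]
      shifted <- mb + truth$effect[d]
      if (shifted < 0 || shifted > 1) clipped <- TRUE
      shifted <- min(max(shifted, 0), 1)
      mu1[idx] <- shifted
      truth[d, `:=`(mu_base = mb, mu1 = shifted, mu2 = mb,
                    realized_effect = shifted - mb, n_sites = length(idx))]
    }
    if (clipped)
      warning("some planted DMR effects pushed the methylation mean outside ",
              "[0, 1] and were clipped; see truth table 'realized_effect'")

    R <- config$replicates_per_condition
    samples <- paste0(rep(config$conditions, each = R), seq_len(R))
    condition <- rep(config$conditions, each = R)
    r <- config$nonconversion_rate
    phi <- config$dispersion[sites$context]
    ns <- nrow(sites)
    M <- matrix(0L, ns, length(samples)); N <- M
    for (k in seq_along(samples)) {
      mu <- if (condition[k] == config$conditions[1]) mu1 else mu2
      n_k <- rpois(ns, config$depth_mean)
      p <- draw_betabinom_p(mu, phi)
      p_obs <- p + (1 - p) * r
      M[, k] <- rbinom(ns, n_k, p_obs)
      N[, k] <- n_k
    }
    bs <- bs_counts(sites[, .(chrom, pos, strand, context, trinucleotide)],
                    M, N, samples, condition)

    nss <- nrow(spike_sites)
    Ms <- matrix(0L, nss, length(samples)); Ns <- Ms
    for (k in seq_along(samples)) {
      n_k <- rpois(nss, config$depth_mean)
      Ms[, k] <- rbinom(nss, n_k, r)
      Ns[, k] <- n_k
    }
    spike <- bs_counts(spike_sites[, .(chrom, pos, strand, context, trinucleotide)],
                       Ms, Ns, samples, condition)
    list(bs = bs, spike = spike, truth_dmrs = truth[])
  })
}

# one beta draw per site: mean mu, overdispersion phi (Var = mu(1-mu)phi)
draw_betabinom_p <- function(mu, phi) {
  p <- mu
  i <- which(phi > 0 & mu > 0 & mu < 1)
  if (length(i)) {
    s <- (1 - phi[i]) / phi[i]
    p[i] <- rbeta(length(i), mu[i] * s, (1 - mu[i]) * s)
  }
  p
}

#' Simulate a gene-level expression count matrix coupled to methylation
#'
#' Baseline gene means are log-normal; planted promoter DMRs modulate the
#' between-condition mean ratio as
#' `exp(coupling_slope * delta_promoter)` (condition 1 over condition 2,
#' natural log), split symmetrically across conditions. A configurable
#' fraction of genes without planted DMRs is made silent or
#' condition-specific. Counts are negative-binomial with per-sample library
#' factors.
#'
#' @param genes GRanges from [generate_genome()].
#' @param exons `GRangesList` from [generate_genome()] (defines gene length
#'   as the exon-union length).
#' @param truth_dmrs truth table from [simulate_methylome()] (supplies the
#'   per-gene promoter methylation difference).
#' @param config the shared [sim_config()].
#' @return list with `counts` (genes x samples integer matrix), `lengths`
#'   (exon-union bp per gene), `samples`, `condition`, `truth_expr`
#'   (data.table: `gene_id`, `class`, `delta_promoter`, `true_lfc_ln`,
#'   baseline mean).
#' @export
simulate_expression <- function(genes, exons, truth_dmrs, config) {
  stopifnot(is(config, "sim_config"))
  with_seed(config$seed + 2L, {
    gene_ids <- genes$gene_id
    ng <- length(gene_ids)
    R <- config$replicates_per_condition
    samples <- paste0(rep(config$conditions, each = R), seq_len(R))
    condition <- rep(config$conditions, each = R)
    lens <- vapply(exons[gene_ids], function(g) sum(width(reduce(g))), numeric(1))

    delta <- setNames(rep(0, ng), gene_ids)
    if (nrow(truth_dmrs)) {
      pd <- truth_dmrs[feature_type == "promoter" & !is.na(gene_id),
                       .(delta = sum(realized_effect)), by = gene_id]
      delta[pd$gene_id] <- pd$delta
    }
    dmr_genes <- unique(truth_dmrs$gene_id[!is.na(truth_dmrs$gene_id)])
    free <- setdiff(gene_ids, dmr_genes)
    n_sil <- round(config$frac_silent * ng)
    n_wt <- round(config$frac_wt_specific * ng)
    n_rt <- round(config$frac_rt_specific * ng)
    picks <- sample(free, min(length(free), n_sil + n_wt + n_rt))
    class <- setNames(rep("normal", ng), gene_ids)
    class[picks[seq_len(min(n_sil, length(picks)))]] <- "silent"
    if (length(picks) > n_sil)
      class[picks[(n_sil + 1):min(n_sil + n_wt, length(picks))]] <- "wt_specific"
    if (length(picks) > n_sil + n_wt)
      class[picks[(n_sil + n_wt + 1):length(picks)]] <- "rt_specific"

    base_mu <- rlnorm(ng, config$expr_mean_log, config$expr_sd_log)
    lfc <- config$coupling_slope * delta          # natural-log fold change
    mu_c1 <- base_mu * exp(lfc / 2)
    mu_c2 <- base_mu * exp(-lfc / 2)
    mu_c2[class == "wt_specific"] <- 0
    mu_c1[class == "wt_specific"] <- pmax(base_mu[class == "wt_specific"], 50)
    mu_c1[class == "rt_specific"] <- 0
    mu_c2[class == "rt_specific"] <- pmax(base_mu[class == "rt_specific"], 50)
    mu_c1[class == "silent"] <- 0; mu_c2[class == "silent"] <- 0
    # scale to the configured sequencing depth, preserving fold changes,
    # then give silent/off-condition genes a fixed trace-read mean
    s <- config$library_size / mean(c(sum(mu_c1), sum(mu_c2)))
    mu_c1 <- mu_c1 * s; mu_c2 <- mu_c2 * s
    trace <- 0.2
    mu_c1[mu_c1 == 0] <- trace; mu_c2[mu_c2 == 0] <- trace

    lib <- exp(rnorm(length(samples), 0, 0.05))
    counts <- matrix(0L, ng, length(samples),
                     dimnames = list(gene_ids, samples))
    for (k in seq_along(samples)) {
      mu_k <- (if (condition[k] == config$conditions[1]) mu_c1 else mu_c2) * lib[k]
      counts[, k] <- rnbinom(ng, mu = mu_k, size = 1 / config$nb_dispersion)
    }
    truth_expr <- data.table(gene_id = gene_ids, class = as.character(class),
                             delta_promoter = as.numeric(delta),
                             true_lfc_ln = as.numeric(lfc),
                             base_mean = base_mu * s)
    list(counts = counts, lengths = setNames(as.integer(lens), gene_ids),
         samples = samples, condition = condition, truth_expr = truth_expr)
  })
}

#' Generate the complete in-memory synthetic fixture
#'
#' Convenience wrapper running [generate_genome()], [simulate_methylome()]
#' and [simulate_expression()] under one configuration.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `genes`, `exons`, `tes`, `bs`, `spike`,
#'   `truth_dmrs`, `expr` (see [simulate_expression()]), and `config`.
#' @export
simulate_fixture <- function(config = sim_config()) {
  ann <- generate_genome(config)
  meth <- simulate_methylome(ann$genome, ann$genes, ann$tes, config)
  expr <- simulate_expression(ann$genes, ann$exons, meth$truth_dmrs, config)
  c(ann, meth, list(expr = expr, config = config))
}

#' Write a fixture to disk in standard formats
#'
#' Emits FASTA (genome including the `lambda_control` contig), GFF3
#' (gene/mRNA/exon), BED6 TEs (name field `class:family`), per-sample
#' cytosine reports for genome and spike-in, the gene-count TSV (gene_id,
#' length_bp, one column per sample), and the truth tables.
#'
#' @param fix fixture list from [simulate_fixture()].
#' @param dir output directory.
#' @return named list of written paths (class `fixture_set`).
#' @export
write_fixture_set <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_path <- file.path(dir, "genome.fa")
  writeXStringSet(fix$genome, genome_path, width = 70L)

  genes_path <- file.path(dir, "genes.gff3")
  write_gene_models(fix$genes, fix$exons, genes_path)

  tes_path <- file.path(dir, "tes.bed")
  tes_dt <- as.data.table(fix$tes)
  if (nrow(tes_dt)) {
    bed <- tes_dt[, .(chrom = as.character(seqnames), start = start - 1L, end,
                      name = paste0(te_class, ":", family), score = 0L,
                      strand = "+")]
  } else {
    bed <- data.table(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(), strand = character())
  }
  fwrite(bed, tes_path, sep = "\t", col.names = FALSE)

  cx_paths <- write_cx_reports(fix$bs, dir, fix$bs$sites$trinucleotide)
  spikein_paths <- write_cx_reports(fix$spike, dir,
                                    fix$spike$sites$trinucleotide,
                                    prefix = "spikein_")

  counts_path <- file.path(dir, "gene_counts.tsv")
  cdt <- data.table(gene_id = rownames(fix$expr$counts),
                    length_bp = fix$expr$lengths[rownames(fix$expr$counts)])
  cdt <- cbind(cdt, as.data.table(fix$expr$counts))
  fwrite(cdt, counts_path, sep = "\t")

  truth_path <- file.path(dir, "truth_dmrs.tsv")
  fwrite(fix$truth_dmrs, truth_path, sep = "\t")
  truth_expr_path <- file.path(dir, "truth_expression.tsv")
  fwrite(fix$expr$truth_expr, truth_expr_path, sep = "\t")

  structure(list(genome_path = genome_path, genes_path = genes_path,
                 tes_path = tes_path, cx_paths = cx_paths,
                 spikein_paths = spikein_paths, counts_path = counts_path,
                 truth_path = truth_path, truth_expr_path = truth_expr_path),
            class = "fixture_set")
}

# write gene models as GFF3 with gene/mRNA/exon features
write_gene_models <- function(genes, exons, path) {
  if (length(genes) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gdt <- as.data.table(genes)
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(gdt))) {
    g <- gdt[i]
    ex <- as.data.table(exons[[g$gene_id]])
    mid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      sprintf("%s\tmethexpr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$seqnames, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\tmethexpr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$seqnames, g$start, g$end, g$strand, mid, g$gene_id),
      sprintf("%s\tmethexpr\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              ex$seqnames, ex$start, ex$end, ex$strand,
              mid, seq_len(nrow(ex)), mid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with gene and exon features (exons linked to genes
#'   through their mRNA `Parent`).
#' @return list with `genes` (GRanges, `gene_id` metadata) and `exons`
#'   (`GRangesList` keyed by gene).
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  genes$gene_id <- genes$ID
  mrna <- gff[gff$type == "mRNA"]
  tx2gene <- setNames(as.character(mrna$Parent), mrna$ID)
  ex <- gff[gff$type == "exon"]
  ex$gene_id <- tx2gene[as.character(ex$Parent)]
  exons <- GenomicRanges::split(ex, ex$gene_id)
  keep <- c("gene_id")
  mcols(genes) <- mcols(genes)[, keep, drop = FALSE]
  list(genes = genes, exons = exons)
}

#' Read a TE annotation from BED6
#'
#' The name field carries `class:family` labels (e.g. `classI:Copia`).
#'
#' @param path BED file.
#' @return GRanges with `te_id`, `te_class`, `family`.
#' @export
read_te_annotation <- function(path) {
  bed <- fread(path, header = FALSE,
               col.names = c("chrom", "start", "end", "name", "score", "strand"))
  if (nrow(bed) == 0L)
    return(GRanges())
  parts <- tstrsplit(bed$name, ":", fixed = TRUE)
  gr <- GRanges(bed$chrom, IRanges(bed$start + 1L, bed$end))
  gr$te_id <- sprintf("TE%04d", seq_along(gr))
  gr$te_class <- parts[[1]]
  gr$family <- if (length(parts) > 1L) parts[[2]] else NA_character_
  gr
}

#' Evaluate DMR recovery against the planted truth
#'
#' Matches each qualifying planted region (absolute realized effect and
#' site count at or above the thresholds) to the called DMRs of the same
#' context by best interval Jaccard (intersection over union). A region is
#' recovered when the best Jaccard reaches `min_jaccard`; direction matches
#' when the recovering DMR is `hyper` for a positive realized effect (first
#' condition higher) and `hypo` for a negative one.
#'
#' @param dmrs [call_dmrs()] table.
#' @param truth `truth_dmrs` table from [simulate_methylome()].
#' @param min_effect,min_sites qualification thresholds for planted regions.
#' @param min_jaccard overlap threshold counting a recovery (default 0.5).
#' @return list with `table` (per qualifying planted region: best Jaccard,
#'   recovered, direction_match), `n_qualifying`, `n_recovered`,
#'   `recovery_rate`, `direction_match_rate` (among recoveries).
#' @export
evaluate_dmr_recovery <- function(dmrs, truth, min_effect = 0.3,
                                  min_sites = 8L, min_jaccard = 0.5) {
  truth <- as.data.table(truth)
  dmrs <- as.data.table(dmrs)
  qual <- truth[abs(realized_effect) >= min_effect & n_sites >= min_sites]
  if (nrow(qual) == 0L)
    return(list(table = qual, n_qualifying = 0L, n_recovered = 0L,
                recovery_rate = NA_real_, direction_match_rate = NA_real_))
  res <- lapply(seq_len(nrow(qual)), function(i) {
    tr <- qual[i]
    cand <- dmrs[chrom == tr$chrom & context == tr$context &
                   start < tr$end & end > tr$start - 1L]
    if (nrow(cand) == 0L)
      return(data.table(best_jaccard = 0, recovered = FALSE,
                        direction_match = NA))
    inter <- pmin(cand$end, tr$end) - pmax(cand$start, tr$start - 1L)
    uni <- pmax(cand$end, tr$end) - pmin(cand$start, tr$start - 1L)
    jac <- inter / uni
    best <- which.max(jac)
    data.table(best_jaccard = jac[best],
               recovered = jac[best] >= min_jaccard,
               direction_match = cand$direction[best] ==
                 (if (tr$realized_effect > 0) "hyper" else "hypo"))
  })
  tab <- cbind(qual, rbindlist(res))
  rec <- tab[recovered == TRUE]
  list(table = tab[], n_qualifying = nrow(tab), n_recovered = nrow(rec),
       recovery_rate = nrow(rec) / nrow(tab),
       direction_match_rate = if (nrow(rec)) mean(rec$direction_match) else NA_real_)
}
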