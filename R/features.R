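#' Build gene models from TSS/TES coordinates
#'
#' Small constructor validating strand consistency: on the plus strand the
#' transcription start site (TSS) must precede the transcription end site
#' (TES), and conversely on the minus strand.
#'
#' @param chrom,tss,tes,strand,gene_id parallel vectors describing genes.
#' @param seqlengths optional named contig lengths.
#' @return GRanges of gene bodies (TSS to TES) with `gene_id`.
#' @export
gene_models <- function(chrom, tss, tes, strand, gene_id,
                        seqlengths = NULL) {
  bad <- (strand == "+" & tes < tss) | (strand == "-" & tes > tss)
  if (any(bad))
    stop("annotation error: TES precedes TSS on its strand for gene(s): ",
         paste(gene_id[bad], collapse = ", "))
  gr <- GRanges(chrom, IRanges(pmin(tss, tes), pmax(tss, tes)),
                strand = strand)
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr$gene_id <- gene_id
  gr
}

# strand-aware 2-kb regions; trimmed at contig edges when seqlengths known
promoter_regions <- function(genes, width = 2000L) {
  suppressWarnings(GenomicRanges::trim(promoters(genes, upstream = width,
                                                 downstream = 0L)))
}
downstream_regions <- function(genes, width = 2000L) {
  suppressWarnings(GenomicRanges::trim(flank(genes, width = width,
                                             start = FALSE)))
}

#' Build a queryable index of gene functional regions and TEs
#'
#' Labels every genomic position with the (possibly multiple) features
#' covering it: `promoter`/`up2k` (the 2-kb region upstream of the TSS,
#' strand-aware; the two labels are synonymous and both reported), `body`
#' (TSS-TES), `exon`, `intron` (body minus exons), `down2k` (2-kb downstream
#' of the TES), `te` (with class/family and intragenic/intergenic status:
#' intragenic = overlapping any gene body), and `intergenic` (covered by no
#' gene body or 2-kb flank). Overlapping labels are all retained - a
#' promoter may well lie inside another gene's body.
#'
#' @param genes GRanges of gene bodies with `gene_id` (strand-aware).
#' @param exons `GRangesList` of exons keyed by gene (optional; without it
#'   exon/intron labels are unavailable).
#' @param tes GRanges of TEs with `te_id`, `te_class`, `family` (optional).
#' @return object of class `feature_index`.
#' @export
build_feature_index <- function(genes, exons = NULL, tes = NULL) {
  if (any(width(genes) < 1L)) stop("annotation error: empty gene body")
  promoter <- promoter_regions(genes)
  promoter$gene_id <- genes$gene_id
  down2k <- downstream_regions(genes)
  down2k$gene_id <- genes$gene_id
  introns <- NULL
  if (!is.null(exons) && length(exons)) {
    exu <- unlist(exons, use.names = FALSE)
    ids <- if (!is.null(exu$gene_id)) exu$gene_id else rep(names(exons), lengths(exons))
    gl <- GenomicRanges::split(GRanges(seqnames(exu), IRanges(start(exu), end(exu))), ids)
    bodies <- genes[match(names(gl), genes$gene_id)]
    bl <- as(GRanges(seqnames(bodies), IRanges(start(bodies), end(bodies))), "GRangesList")
    intr <- GenomicRanges::psetdiff(unlist(bl), gl)
    intr_u <- unlist(intr, use.names = FALSE)
    intr_u$gene_id <- rep(names(gl), lengths(intr))
    introns <- intr_u
  }
  if (!is.null(tes) && length(tes)) {
    tes$intragenic <- IRanges::overlapsAny(tes, genes, ignore.strand = TRUE)
  }
  structure(list(genes = genes, exons = exons, tes = tes,
                 promoter = promoter, down2k = down2k, introns = introns),
            class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  cat(sprintf("feature_index: %d genes, %d TEs (%d intragenic)\n",
              length(x$genes),
              if (is.null(x$tes)) 0L else length(x$tes),
              if (is.null(x$tes)) 0L else sum(x$tes$intragenic)))
  invisible(x)
}

#' Labels covering one genomic position
#'
#' @param index a [build_feature_index()] object.
#' @param chrom,pos position (1-based).
#' @return character vector of labels (possibly several; `"intergenic"` when
#'   no gene body or flank covers the position).
#' @export
position_labels <- function(index, chrom, pos) {
  p <- GRanges(chrom, IRanges(pos, pos))
  labs <- character()
  ov <- function(gr) !is.null(gr) && length(gr) &&
    length(findOverlaps(p, gr, ignore.strand = TRUE))
  if (ov(index$genes)) labs <- c(labs, "body")
  if (ov(index$promoter)) labs <- c(labs, "promoter", "up2k")
  if (ov(index$down2k)) labs <- c(labs, "down2k")
  if (!is.null(index$exons) && ov(unlist(index$exons))) labs <- c(labs, "exon")
  if (ov(index$introns)) labs <- c(labs, "intron")
  if (ov(index$tes)) labs <- c(labs, "te")
  if (!any(c("body", "promoter", "down2k") %in% labs))
    labs <- c(labs, "intergenic")
  labs
}

# sites (data.table chrom/pos) as width-1 GRanges
sites_granges <- function(sites) {
  GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
}

#' Mean methylation level per functional region and context
#'
#' For every feature label, context, and sample: the unweighted mean of
#' per-site methylation levels over covered sites (zero-coverage sites are
#' excluded; a label x context stratum with no covered sites is simply
#' absent, not reported as zero). Also returns fixed-width window density
#' tracks of pooled per-condition levels for chromosome-scale views.
#'
#' @param bs BSCounts object.
#' @param index a [build_feature_index()].
#' @param r optional non-conversion rate; levels are corrected via
#'   [correct_level()] when supplied.
#' @param window_bp width of the density-track windows (default 50 kb).
#' @return list with `regions` (data.table: label, context, sample,
#'   mean_level, n_sites) and `density` (data.table: chrom, win_start,
#'   win_end, context, condition, mean_level, n_sites).
#' @export
region_methylation <- function(bs, index, r = NULL, window_bp = 50000L) {
  stopifnot(is(bs, "BSCounts"), is(index, "feature_index"))
  sgr <- sites_granges(bs$sites)
  label_sets <- list(
    body = index$genes, promoter = index$promoter, up2k = index$promoter,
    down2k = index$down2k,
    exon = if (!is.null(index$exons)) unlist(index$exons) else NULL,
    intron = index$introns, te = index$tes)
  cov_any <- rep(FALSE, length(sgr))
  rows <- list()
  for (lab in names(label_sets)) {
    gr <- label_sets[[lab]]
    if (is.null(gr) || length(gr) == 0L) next
    hit <- unique(queryHits(findOverlaps(sgr, gr, ignore.strand = TRUE)))
    if (lab %in% c("body", "promoter", "down2k")) cov_any[hit] <- TRUE
    if (length(hit) == 0L) next
    rows[[lab]] <- site_level_summary(bs, hit, lab, r)
  }
  inter <- which(!cov_any)
  if (length(inter)) rows[["intergenic"]] <- site_level_summary(bs, inter, "intergenic", r)
  regions <- rbindlist(rows)

  # pooled per-condition density windows
  dens <- list()
  for (cond in levels(bs$condition)) {
    j <- which(bs$condition == cond)
    m <- rowSums(bs$M[, j, drop = FALSE]); n <- rowSums(bs$N[, j, drop = FALSE])
    dt <- data.table(chrom = bs$sites$chrom, pos = bs$sites$pos,
                     context = bs$sites$context, m = m, n = n)[n > 0]
    dt[, win_start := (pos - 1L) %/% window_bp * window_bp + 1L]
    d <- dt[, .(mean_level = sum(m) / sum(n), n_sites = .N),
            by = .(chrom, win_start, context)]
    if (!is.null(r)) d[, mean_level := correct_level(mean_level, r)]
    d[, `:=`(win_end = win_start + window_bp - 1L, condition = cond)]
    dens[[cond]] <- d
  }
  density <- rbindlist(dens)[, .(chrom, win_start, win_end, context,
                                 condition, mean_level, n_sites)]
  list(regions = regions, density = density)
}

site_level_summary <- function(bs, idx, lab, r = NULL) {
  out <- list()
  ctx <- bs$sites$context[idx]
  for (k in seq_along(bs$samples)) {
    lv <- methylation_level(bs$M[idx, k], bs$N[idx, k] - bs$M[idx, k])
    if (!is.null(r)) lv <- correct_level(lv, r)
    dt <- data.table(context = ctx, level = lv)[!is.na(level)]
    if (nrow(dt) == 0L) next
    out[[k]] <- dt[, .(label = lab, sample = bs$samples[k],
                       mean_level = mean(level), n_sites = .N),
                   by = context]
  }
  rbindlist(out)[, .(label, context, sample, mean_level, n_sites)]
}

#' Metagene methylation profile over gene bodies and 2-kb flanks
#'
#' Each gene contributes a 150-bin profile: 50 fixed 40-bp bins over the
#' 2-kb upstream region (bin 50 adjacent to the TSS), 50 length-normalized
#' fractional bins over the body (bin 1 at the TSS), and 50 fixed 40-bp bins
#' downstream of the TES. Site levels are pooled over the selected samples
#' (sum of methylated over total reads), averaged within each gene's bin,
#' then averaged across the genes of each group, so every gene carries equal
#' weight regardless of length or site density.
#'
#' @param bs BSCounts object.
#' @param genes GRanges of gene bodies with `gene_id`.
#' @param groups named vector mapping `gene_id` to a group label; `NULL`
#'   places all genes in group `"all"`. Genes absent from `groups` are
#'   dropped.
#' @param samples samples to pool (default: all).
#' @param n_bins bins per region (default 50).
#' @param flank flank width in bp (default 2000).
#' @param r optional non-conversion rate for level correction.
#' @return data.table: `group`, `context`, `region`
#'   (`upstream`/`body`/`downstream`), `bin` (1..n_bins), `mean_level`,
#'   `n_sites`, `n_genes`.
#' @export
metagene_profile <- function(bs, genes, groups = NULL, samples = NULL,
                             n_bins = 50L, flank = 2000L, r = NULL) {
  stopifnot(is(bs, "BSCounts"))
  if (is.null(groups)) {
    groups <- setNames(rep("all", length(genes)), genes$gene_id)
  }
  genes <- genes[genes$gene_id %in% names(groups)]
  if (length(genes) == 0L)
    return(data.table(group = character(), context = character(),
                      region = character(), bin = integer(),
                      mean_level = numeric(), n_sites = integer(),
                      n_genes = integer()))
  j <- if (is.null(samples)) seq_along(bs$samples) else match(samples, bs$samples)
  m <- rowSums(bs$M[, j, drop = FALSE]); n <- rowSums(bs$N[, j, drop = FALSE])
  lv <- ifelse(n > 0, m / n, NA_real_)
  if (!is.null(r)) lv <- correct_level(lv, r)
  sgr <- sites_granges(bs$sites)

  gdt <- data.table(gene_id = genes$gene_id,
                    strand = as.character(strand(genes)),
                    gstart = start(genes), gend = end(genes))
  gdt[, `:=`(tss = ifelse(strand == "+", gstart, gend),
             tes = ifelse(strand == "+", gend, gstart),
             glen = gend - gstart + 1L)]
  if (any(gdt$glen < n_bins))
    message(sum(gdt$glen < n_bins),
            " gene(s) shorter than n_bins; fractional binning applied")

  regions <- list(
    upstream = promoter_regions(genes, flank),
    body = genes,
    downstream = downstream_regions(genes, flank))
  pieces <- list()
  for (reg in names(regions)) {
    gr <- regions[[reg]]
    ov <- findOverlaps(sgr, gr, ignore.strand = TRUE)
    if (length(ov) == 0L) next
    dt <- data.table(site = queryHits(ov), gi = subjectHits(ov))
    dt[, `:=`(pos = bs$sites$pos[site], context = bs$sites$context[site],
              level = lv[site])]
    dt <- cbind(dt, gdt[dt$gi])
    dt <- dt[!is.na(level)]
    if (nrow(dt) == 0L) next
    if (reg == "body") {
      dt[, frac := ifelse(strand == "+", (pos - gstart) / glen,
                          (gend - pos) / glen)]
      dt[, bin := pmin(floor(frac * n_bins), n_bins - 1L) + 1L]
    } else if (reg == "upstream") {
      dt[, dist := ifelse(strand == "+", tss - pos, pos - tss)]
      dt <- dt[dist >= 1L & dist <= flank]
      dt[, bin := n_bins - pmin(ceiling(dist / (flank / n_bins)), n_bins) + 1L]
    } else {
      dt[, dist := ifelse(strand == "+", pos - tes, tes - pos)]
      dt <- dt[dist >= 1L & dist <= flank]
      dt[, bin := pmin(ceiling(dist / (flank / n_bins)), n_bins)]
    }
    per_gene <- dt[, .(gl = mean(level), ns = .N),
                   by = .(gene_id, context, bin)]
    per_gene[, group := groups[gene_id]]
    pieces[[reg]] <- per_gene[, .(region = reg, mean_level = mean(gl),
                                  n_sites = sum(ns), n_genes = .N),
                              by = .(group, context, bin)]
  }
  out <- rbindlist(pieces)
  if (nrow(out) == 0L) return(out)
  out[, region := factor(region, levels = c("upstream", "body", "downstream"))]
  setorder(out, group, context, region, bin)
  out[, .(group, context, region, bin, mean_level, n_sites, n_genes)]
}

#' Group genes by expression level (no/low/medium/high)
#'
#' Unexpressed genes are those with FPKM below `expressed_threshold` (1 by
#' default); among expressed genes the 25th and 75th FPKM percentiles split
#' low, medium and high expression, with the high class inclusive of its
#' boundary (FPKM >= 75th percentile). Percentiles are computed over
#' expressed genes only (the "low" class starts at the expression
#' threshold, so unexpressed genes are not part of the percentile
#' population); the quantile interpolation rule is exposed.
#'
#' @param fpkm named numeric vector of per-gene (replicate-averaged) FPKM.
#' @param expressed_threshold FPKM threshold for "expressed" (default 1).
#' @param quantile_type interpolation rule passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return list of class `expression_groups`: `assignment` (named factor
#'   with levels no/low/medium/high), `fpkm_25`, `fpkm_75`, `n_expressed`.
#' @export
expression_groups <- function(fpkm, expressed_threshold = 1,
                              quantile_type = 7) {
  expressed <- fpkm[!is.na(fpkm) & fpkm >= expressed_threshold]
  if (all(is.na(fpkm))) stop("no FPKM values supplied")
  if (length(expressed) > 0L && length(expressed) < 3L)
    stop("fewer than 3 expressed genes; cannot form quartile groups")
  q <- if (length(expressed)) quantile(expressed, c(0.25, 0.75),
                                       type = quantile_type, names = FALSE)
       else c(NA_real_, NA_real_)
  assignment <- rep("no", length(fpkm))
  assignment[fpkm >= expressed_threshold & fpkm < q[1]] <- "low"
  assignment[fpkm >= q[1] & fpkm < q[2]] <- "medium"
  assignment[fpkm >= q[2]] <- "high"
  assignment <- factor(assignment, levels = c("no", "low", "medium", "high"))
  names(assignment) <- names(fpkm)
  structure(list(assignment = assignment, fpkm_25 = q[1], fpkm_75 = q[2],
                 n_expressed = length(expressed)),
            class = "expression_groups")
}

#' Group genes into methylation-level quintiles
#'
#' Splits genes into five groups at the 20/40/60/80th percentiles of their
#' region methylation level (group 1 below the 20th percentile, group 5 at
#' or above the 80th). Genes with no measurable level in the region x
#' context (e.g. promoters lacking any CHH site) are excluded and counted.
#'
#' @param gene_levels named numeric vector of per-gene mean methylation for
#'   one region and context; `NA` = no sites.
#' @param quantile_type interpolation rule for [stats::quantile()].
#' @return list of class `methylation_groups`: `assignment` (named integer
#'   factor 1-5), `boundaries` (the four percentile values), `n_excluded`.
#' @export
methylation_groups <- function(gene_levels, quantile_type = 7) {
  ok <- !is.na(gene_levels)
  x <- gene_levels[ok]
  if (length(x) == 0L) stop("no genes with a measurable methylation level")
  b <- quantile(x, c(0.2, 0.4, 0.6, 0.8), type = quantile_type, names = FALSE)
  if (length(unique(x)) == 1L) {
    warning("degenerate methylation distribution (all levels equal); ",
            "single group returned")
    g <- rep(1L, length(x))
  } else {
    g <- findInterval(x, b, left.open = FALSE) + 1L
    # findInterval counts boundaries as passed when x >= boundary,
    # matching: group 1 < b20, ..., group 5 >= b80
  }
  assignment <- factor(g, levels = 1:5)
  names(assignment) <- names(x)
  structure(list(assignment = assignment, boundaries = b,
                 n_excluded = sum(!ok)),
            class = "methylation_groups")
}

#' Gene-frequency table of expression by methylation group
#'
#' The coordinate system behind methylation-quintile figures: expression on
#' the x-axis (log10(FPKM + 0.1) bins), gene frequency on the y-axis, one
#' series per methylation group.
#'
#' @param groups a [methylation_groups()] result.
#' @param fpkm named FPKM vector.
#' @param n_bins number of expression bins.
#' @return data.table: `group`, `bin`, `expr_low`, `expr_high`, `count`.
#' @export
group_expression_table <- function(groups, fpkm, n_bins = 20L) {
  g <- groups$assignment
  common <- intersect(names(g), names(fpkm))
  x <- log10(fpkm[common] + 0.1)
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(findInterval(x, brk, rightmost.closed = TRUE), n_bins)
  dt <- data.table(group = as.integer(as.character(g[common])), bin = bin)
  grid <- CJ(group = sort(unique(dt$group)), bin = seq_len(n_bins))
  out <- dt[, .(count = .N), by = .(group, bin)][grid, on = c("group", "bin")]
  out[is.na(count), count := 0L]
  out[, `:=`(expr_low = brk[bin], expr_high = brk[bin + 1L])]
  setorder(out, group, bin)
  out[, .(group, bin, expr_low, expr_high, count)]
}

#' Per-gene mean methylation of a functional region
#'
#' Depth-weighted mean of site levels (pooled methylated reads over pooled
#' total reads) within a region of each gene, per context.
#'
#' @param bs BSCounts object.
#' @param genes GRanges with `gene_id`.
#' @param region one of `"body"`, `"promoter"`, `"down2k"`.
#' @param samples samples to pool (default all).
#' @param r optional non-conversion correction.
#' @param flank flank width for promoter/down2k.
#' @return data.table: `gene_id`, `context`, `mean_level`, `n_sites` (genes
#'   or contexts without covered sites are absent).
#' @export
gene_region_methylation <- function(bs, genes,
                                    region = c("body", "promoter", "down2k"),
                                    samples = NULL, r = NULL, flank = 2000L) {
  region <- match.arg(region)
  gr <- switch(region, body = genes,
               promoter = promoter_regions(genes, flank),
               down2k = downstream_regions(genes, flank))
  gr$gene_id <- genes$gene_id
  j <- if (is.null(samples)) seq_along(bs$samples) else match(samples, bs$samples)
  m <- rowSums(bs$M[, j, drop = FALSE]); n <- rowSums(bs$N[, j, drop = FALSE])
  ov <- findOverlaps(sites_granges(bs$sites), gr, ignore.strand = TRUE)
  dt <- data.table(gene_id = gr$gene_id[subjectHits(ov)],
                   context = bs$sites$context[queryHits(ov)],
                   m = m[queryHits(ov)], n = n[queryHits(ov)])[n > 0]
  out <- dt[, .(mean_level = sum(m) / sum(n), n_sites = .N),
            by = .(gene_id, context)]
  if (!is.null(r)) out[, mean_level := correct_level(mean_level, r)]
  out[]
}

#' TE density profile over gene bodies and flanks
#'
#' For the metagene coordinate system (50 bins per region), the fraction of
#' aggregate bin length covered by TEs of each family: per bin, total TE
#' overlap length across genes divided by total bin length.
#'
#' @param tes GRanges with `family` (and `te_class`).
#' @param genes GRanges with `gene_id`.
#' @param n_bins bins per region.
#' @param flank flank width (bp).
#' @return data.table: `family`, `region`, `bin`, `covered_bp`, `total_bp`,
#'   `fraction`.
#' @export
te_density_profile <- function(tes, genes, n_bins = 50L, flank = 2000L) {
  fams <- if (length(tes)) sort(unique(tes$family)) else character()
  regions <- c("upstream", "body", "downstream")
  grid <- CJ(family = fams, region = regions, bin = seq_len(n_bins))
  if (length(tes) == 0L || length(genes) == 0L) {
    grid[, `:=`(covered_bp = 0, total_bp = 0, fraction = 0)]
    if (nrow(grid) == 0L)
      grid <- data.table(family = character(), region = character(),
                         bin = integer(), covered_bp = numeric(),
                         total_bp = numeric(), fraction = numeric())
    return(grid[])
  }
  bins <- make_metagene_bins(genes, n_bins, flank)
  out <- list()
  for (fam in fams) {
    tf <- reduce(tes[tes$family == fam], ignore.strand = TRUE)
    ov <- findOverlaps(bins, tf, ignore.strand = TRUE)
    covered <- rep(0, length(bins))
    if (length(ov)) {
      w <- width(pintersect(bins[queryHits(ov)], tf[subjectHits(ov)]))
      cv <- data.table(i = queryHits(ov), w = w)[, .(w = sum(w)), by = i]
      covered[cv$i] <- cv$w
    }
    dt <- data.table(family = fam, region = bins$region, bin = bins$bin,
                     covered_bp = covered, total_bp = width(bins))
    out[[fam]] <- dt[, .(covered_bp = sum(covered_bp),
                         total_bp = sum(total_bp)),
                     by = .(family, region, bin)]
  }
  res <- rbindlist(out)
  res[, fraction := ifelse(total_bp > 0, covered_bp / total_bp, 0)]
  res[, region := factor(region, levels = regions)]
  setorder(res, family, region, bin)
  res[]
}

# per-gene metagene bin ranges (strand-oriented), as a flat GRanges
make_metagene_bins <- function(genes, n_bins = 50L, flank = 2000L) {
  gdt <- data.table(chrom = as.character(seqnames(genes)),
                    gstart = start(genes), gend = end(genes),
                    strand = as.character(strand(genes)))
  rows <- list()
  for (i in seq_len(nrow(gdt))) {
    g <- gdt[i]
    bw <- flank / n_bins
    # body: near-equal integer partition
    bb <- floor(g$gstart + (g$gend - g$gstart + 1L) * (0:n_bins) / n_bins)
    body_s <- bb[-(n_bins + 1L)]; body_e <- bb[-1L] - 1L
    body_e[n_bins] <- g$gend
    if (g$strand == "+") {
      up_s <- g$gstart - flank + (0:(n_bins - 1L)) * bw
      up_e <- up_s + bw - 1L
      dn_s <- g$gend + 1L + (0:(n_bins - 1L)) * bw
      dn_e <- dn_s + bw - 1L
      bbin <- seq_len(n_bins)
    } else {
      up_s <- g$gend + 1L + ((n_bins - 1L):0) * bw
      up_e <- up_s + bw - 1L
      dn_s <- g$gstart - flank + ((n_bins - 1L):0) * bw
      dn_e <- dn_s + bw - 1L
      bbin <- rev(seq_len(n_bins))
    }
    rows[[i]] <- data.table(
      chrom = g$chrom,
      start = c(up_s, body_s, dn_s),
      end = c(up_e, body_e, dn_e),
      region = rep(c("upstream", "body", "downstream"), each = n_bins),
      bin = c(seq_len(n_bins), bbin, seq_len(n_bins)))
  }
  dt <- rbindlist(rows)
  dt <- dt[start >= 1L]
  gr <- GRanges(dt$chrom, IRanges(dt$start, dt$end))
  gr$region <- dt$region; gr$bin <- dt$bin
  gr
}
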