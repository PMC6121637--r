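# rolling windowed sum over sorted integer positions: for each i, sum of
# x[j] with |pos[j] - pos[i]| <= half
roll_window_sum <- function(pos, x, half) {
  if (half <= 0) return(x)
  cs <- c(0, cumsum(x))
  lo <- findInterval(pos - half - 0.5, pos) + 1L
  hi <- findInterval(pos + half + 0.5 - 1e-9, pos)
  cs[hi + 1L] - cs[lo]
}

#' Depth-weighted moving-average smoothing of methylation levels
#'
#' Smooths per-site levels over a window of `window_bp` (plus/minus half the
#' window), weighting each neighboring site by its read depth; a site with
#' no covered neighbors keeps its own level. `window_bp <= 0` disables
#' smoothing (identity).
#'
#' @param pos sorted 1-based positions (one chromosome).
#' @param level per-site methylation levels.
#' @param depth per-site read depths (weights).
#' @param window_bp window width in bp.
#' @return numeric vector of smoothed levels.
#' @export
smooth_levels <- function(pos, level, depth, window_bp) {
  stopifnot(length(pos) == length(level), length(level) == length(depth))
  if (window_bp <= 0) return(level)
  if (is.unsorted(pos)) stop("'pos' must be sorted")
  half <- window_bp / 2
  num <- roll_window_sum(pos, depth * level, half)
  den <- roll_window_sum(pos, depth, half)
  ifelse(den > 0, num / den, level)
}

#' Beta-binomial dispersion per site with empirical-Bayes shrinkage
#'
#' Method-of-moments estimate of the beta-binomial overdispersion from
#' replicate counts at each site, shrunk toward the context-wide median.
#' With replicate proportions `p_r = m_r / n_r`, the replicate variance has
#' expectation `p(1-p) * mean((1 + (n_r - 1) phi) / n_r)`, which is solved
#' for `phi`; the estimate (truncated at 0) is then combined with the
#' context median with weight `(R - 1) / (R + 1)` on the site estimate
#' (sites with more replicates trust their own estimate more), and floored.
#'
#' @param M,N matrices (sites x replicates) of methylated / total counts
#'   for one condition.
#' @param context optional per-site context for the shrinkage target
#'   grouping; `NULL` pools all sites.
#' @param shrink logical; `FALSE` returns the raw truncated MoM estimate.
#' @param floor lower bound on the returned dispersion (default 1e-4).
#' @return list with `phi` (shrunk, floored), `phi_mom` (raw MoM, may be
#'   negative or `NA`), `trend` (named per-context medians).
#' @export
estimate_dispersion <- function(M, N, context = NULL, shrink = TRUE,
                                floor = 1e-4) {
  M <- as.matrix(M); N <- as.matrix(N)
  R <- ncol(M)
  if (R < 2L) {
    warning("single replicate: falling back to the context-wide dispersion floor")
    return(list(phi = rep(floor, nrow(M)), phi_mom = rep(NA_real_, nrow(M)),
                trend = c(all = floor)))
  }
  P <- M / N                     # NaN where N == 0
  P[!is.finite(P)] <- NA
  R_eff <- rowSums(N > 0)
  pbar <- rowMeans(P, na.rm = TRUE)
  s2 <- rowSums((P - pbar)^2, na.rm = TRUE) / pmax(R_eff - 1L, 1L)
  invN <- 1 / N; invN[!is.finite(invN)] <- NA
  mean_inv <- rowMeans(invN, na.rm = TRUE)
  ratio <- (N - 1) / N; ratio[!is.finite(ratio)] <- NA
  mean_nm1 <- rowMeans(ratio, na.rm = TRUE)
  denom <- pbar * (1 - pbar)
  phi_mom <- (s2 / denom - mean_inv) / mean_nm1
  phi_mom[!is.finite(phi_mom) | R_eff < 2L] <- NA_real_

  # shrinkage target: context mean of the *untruncated* MoM estimates.
  # the site-wise MoM is unbiased but extremely noisy at 2-3 replicates;
  # truncating at 0 (or taking the median of the right-skewed distribution)
  # biases the target low and inflates the Wald test, so negative site
  # estimates are kept when averaging.
  grp <- if (is.null(context)) rep("all", nrow(M)) else as.character(context)
  trend <- vapply(split(phi_mom, grp), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) max(mean(v), floor) else floor
  }, numeric(1))
  if (!shrink) {
    phi <- pmax(phi_mom, floor)
    phi[is.na(phi)] <- pmax(trend[grp][is.na(phi_mom)], floor)
    return(list(phi = phi, phi_mom = phi_mom, trend = trend))
  }
  w <- (R_eff - 1) / (R_eff + 3)
  site <- pmax(phi_mom, 0)
  tg <- as.numeric(trend[grp])
  phi <- ifelse(is.na(site), tg, w * site + (1 - w) * tg)
  phi <- pmax(phi, floor)
  list(phi = phi, phi_mom = phi_mom, trend = trend)
}

# per-condition site summaries used by the Wald test:
# pbar (replicate-mean level), d (pooled depth), cj (variance coefficient
# sum_r (1+(n_r-1)phi)/n_r / R^2 over covered replicates)
condition_site_stats <- function(M, N, context, floor = 1e-4) {
  P <- M / N; P[!is.finite(P)] <- NA
  R_eff <- rowSums(N > 0)
  pbar <- rowMeans(P, na.rm = TRUE)
  d <- rowSums(N)
  disp <- estimate_dispersion(M, N, context, floor = floor)
  term <- (1 + (N - 1) * disp$phi) / N
  term[!is.finite(term)] <- NA
  cj <- rowSums(term, na.rm = TRUE) / pmax(R_eff, 1L)^2
  list(pbar = pbar, d = d, cj = cj, phi = disp$phi, R_eff = R_eff)
}

#' Per-site differential-methylation Wald test (beta-binomial, replicated)
#'
#' For each cytosine covered in both conditions, tests the difference of
#' condition mean methylation levels with a Wald statistic under a
#' beta-binomial replicate model. Condition means are the depth-weighted
#' moving averages of replicate-mean levels over `window_bp` (spatial
#' smoothing borrows information from neighboring sites of the same
#' context); their variance combines the per-site beta-binomial variance
#' `mu (1 - mu) (1 + (n_r - 1) phi) / n_r / R^2` (summed over replicates)
#' with the squared smoothing weights. Dispersions come from
#' [estimate_dispersion()]. With `window_bp = 0` the statistic reduces to
#' the plain per-site Wald test. Unsmoothed ("raw") per-site differences,
#' statistics and p-values are carried alongside for boundary refinement
#' and direction checks.
#'
#' @param bs BSCounts with a two-level condition factor.
#' @param cond1,cond2 condition labels; defaults to the factor's levels in
#'   order (the first is the reference: positive differences mean higher
#'   methylation there).
#' @param window_bp smoothing window (default 500 bp; 0 disables).
#' @param dispersion_floor lower bound for dispersion estimates.
#' @return data.table with one row per testable site: `chrom`, `pos`,
#'   `strand`, `context`, `mu1`, `mu2` (smoothed), `phi1`, `phi2`, `diff`,
#'   `se`, `stat`, `pval`, `padj` (BH within context), `raw_diff`,
#'   `raw_stat`, `raw_pval`, `depth1`, `depth2`. Sites with zero pooled
#'   depth in either condition are excluded (their count is reported in the
#'   `n_skipped` attribute).
#' @export
dml_test <- function(bs, cond1 = NULL, cond2 = NULL, window_bp = 500,
                     dispersion_floor = 1e-4) {
  stopifnot(is(bs, "BSCounts"))
  lev <- levels(bs$condition)
  cond1 <- cond1 %||% lev[1]; cond2 <- cond2 %||% lev[2]
  j1 <- which(bs$condition == cond1); j2 <- which(bs$condition == cond2)
  if (!length(j1) || !length(j2)) stop("unknown condition label")
  ctx <- bs$sites$context
  s1 <- condition_site_stats(bs$M[, j1, drop = FALSE], bs$N[, j1, drop = FALSE],
                             ctx, dispersion_floor)
  s2 <- condition_site_stats(bs$M[, j2, drop = FALSE], bs$N[, j2, drop = FALSE],
                             ctx, dispersion_floor)
  ok <- s1$d > 0 & s2$d > 0
  n_skipped <- sum(!ok)
  dt <- data.table(i = which(ok),
                   chrom = bs$sites$chrom[ok], pos = bs$sites$pos[ok],
                   strand = bs$sites$strand[ok], context = ctx[ok],
                   p1 = s1$pbar[ok], d1 = s1$d[ok], c1 = s1$cj[ok],
                   p2 = s2$pbar[ok], d2 = s2$d[ok], c2 = s2$cj[ok],
                   phi1 = s1$phi[ok], phi2 = s2$phi[ok])
  setorder(dt, chrom, context, pos)

  smooth_group <- function(pos, p, d, cc) {
    half <- window_bp / 2
    if (window_bp <= 0) {
      mu <- p
      v <- mu * (1 - mu) * cc
    } else {
      D <- roll_window_sum(pos, d, half)
      mu <- roll_window_sum(pos, d * p, half) / D
      v <- roll_window_sum(pos, d^2 * mu * (1 - mu) * cc, half) / D^2
    }
    list(mu = mu, v = v)
  }
  dt[, c("mu1", "v1") := smooth_group(pos, p1, d1, c1), by = .(chrom, context)]
  dt[, c("mu2", "v2") := smooth_group(pos, p2, d2, c2), by = .(chrom, context)]
  dt[, `:=`(diff = mu1 - mu2, se = sqrt(v1 + v2))]
  dt[, stat := fifelse(se > 0, diff / se, fifelse(diff == 0, 0, Inf * sign(diff)))]
  dt[, pval := wald_pvalue(stat)]
  dt[, padj := p.adjust(pval, "BH"), by = context]
  # unsmoothed per-site statistics (boundary refinement, direction checks)
  dt[, `:=`(raw_diff = p1 - p2,
            raw_se = sqrt(p1 * (1 - p1) * c1 + p2 * (1 - p2) * c2))]
  dt[, raw_stat := fifelse(raw_se > 0, raw_diff / raw_se,
                           fifelse(raw_diff == 0, 0, Inf * sign(raw_diff)))]
  dt[, raw_pval := wald_pvalue(raw_stat)]
  out <- dt[, .(chrom, pos, strand, context, mu1, mu2, phi1, phi2,
                diff, se, stat, pval, padj, raw_diff, raw_stat, raw_pval,
                depth1 = d1, depth2 = d2)]
  setattr(out, "n_skipped", n_skipped)
  setattr(out, "conditions", c(cond1, cond2))
  out[]
}

#' Merge differentially methylated loci into regions
#'
#' Significant sites (`pval < p_threshold`) of the same context and
#' difference sign, separated by at most `max_gap` bp, are merged into
#' candidate regions. Because spatial smoothing smears significance past a
#' region's true boundary, each candidate is then trimmed to the span of
#' its sites with unsmoothed (raw) per-site support
#' (`raw_pval < refine_alpha` and concordant sign); if no site has raw
#' support the original span is kept. Regions are retained when they reach
#' `min_len` bp, `min_sites` significant sites, and a fraction of at least
#' `pct_sig` significant sites among the covered sites of that context in
#' the span. Direction is `hyper` when the first condition is the more
#' methylated (positive mean raw difference).
#'
#' @param dml result of [dml_test()].
#' @param p_threshold per-site p-value threshold (default 1e-5).
#' @param min_len minimum region length in bp (default 50).
#' @param min_sites minimum number of significant member sites (default 3).
#' @param max_gap maximum gap between consecutive significant sites
#'   (default 100 bp).
#' @param pct_sig minimum fraction of covered sites that are significant
#'   (default 0.5).
#' @param refine logical: apply raw-support boundary trimming (default
#'   TRUE).
#' @param refine_alpha raw per-site p-value threshold used for trimming.
#' @return data.table of DMRs: `dmr_id`, `chrom`, `start` (0-based), `end`
#'   (half-open), `context`, `direction` (`hyper`/`hypo`), `n_sites`
#'   (significant members), `n_covered`, `mean_diff` (mean raw difference
#'   over covered sites), `mean_mu1`, `mean_mu2`, `area_stat`, `length`.
#' @export
call_dmrs <- function(dml, p_threshold = 1e-5, min_len = 50L, min_sites = 3L,
                      max_gap = 100L, pct_sig = 0.5, refine = TRUE,
                      refine_alpha = 0.05) {
  dml <- as.data.table(dml)
  empty <- data.table(dmr_id = character(), chrom = character(),
                      start = integer(), end = integer(), context = character(),
                      direction = character(), n_sites = integer(),
                      n_covered = integer(), mean_diff = numeric(),
                      mean_mu1 = numeric(), mean_mu2 = numeric(),
                      area_stat = numeric(), length = integer())
  if (nrow(dml) == 0L) return(empty)
  setorder(dml, chrom, context, pos)
  rows <- list()
  for (grp in split(dml, by = c("chrom", "context"))) {
    sig <- which(!is.na(grp$pval) & grp$pval < p_threshold & grp$diff != 0)
    if (length(sig) == 0L) next
    sgn <- sign(grp$diff[sig])
    gap_break <- c(TRUE, diff(grp$pos[sig]) > max_gap | diff(sgn) != 0)
    run <- cumsum(gap_break)
    for (ri in unique(run)) {
      members <- sig[run == ri]
      dir_sign <- sgn[run == ri][1]
      if (refine) {
        support <- !is.na(grp$raw_pval[members]) &
          grp$raw_pval[members] < refine_alpha &
          sign(grp$raw_diff[members]) == dir_sign
        if (any(support)) {
          members <- members[min(which(support)):max(which(support))]
        }
      }
      span <- range(grp$pos[members])
      covered <- which(grp$pos >= span[1] & grp$pos <= span[2])
      n_sig <- length(members)
      reg_len <- span[2] - span[1] + 1L
      if (reg_len < min_len || n_sig < min_sites) next
      if (n_sig / length(covered) < pct_sig) next
      mean_diff <- mean(grp$raw_diff[covered])
      rows[[length(rows) + 1L]] <- data.table(
        chrom = grp$chrom[1], start = span[1] - 1L, end = span[2],
        context = grp$context[1],
        direction = if (mean_diff > 0) "hyper" else "hypo",
        n_sites = n_sig, n_covered = length(covered),
        mean_diff = mean_diff,
        mean_mu1 = mean(grp$mu1[covered]), mean_mu2 = mean(grp$mu2[covered]),
        area_stat = sum(grp$stat[members]), length = reg_len)
    }
  }
  if (!length(rows)) return(empty)
  out <- rbindlist(rows)
  setorder(out, chrom, start, context)
  out[, dmr_id := sprintf("DMR%05d", .I)]
  setcolorder(out, "dmr_id")
  out[]
}

#' Annotate DMRs against gene bodies, promoters and TEs
#'
#' A DMR-related gene is a gene whose body (TSS-TES) or promoter (2-kb
#' upstream of the TSS) overlaps a DMR by at least one base. TE overlaps
#' carry the element's class/family and intragenic/intergenic status; the
#' genome-wide distribution of DMR length over functional labels is also
#' reported.
#'
#' @param dmrs data.table from [call_dmrs()].
#' @param index a [build_feature_index()].
#' @return list with
#'   `genes` (data.table: dmr_id, gene_id, hit = body/promoter, context,
#'   direction), `gene_context_sets` (per gene and hit, the set of DMR
#'   contexts, for Venn-style cross-tabulation), `tes` (dmr_id, te_id,
#'   te_class, family, intragenic, context, direction), and
#'   `region_fractions` (per context and direction, the fraction of total
#'   DMR length overlapping each functional label).
#' @export
annotate_dmrs <- function(dmrs, index) {
  stopifnot(is(index, "feature_index"))
  dmrs <- as.data.table(dmrs)
  if (nrow(dmrs) == 0L) {
    return(list(genes = data.table(dmr_id = character(), gene_id = character(),
                                   hit = character(), context = character(),
                                   direction = character()),
                gene_context_sets = data.table(gene_id = character(),
                                               hit = character(),
                                               contexts = character()),
                tes = data.table(dmr_id = character(), te_id = character(),
                                 te_class = character(), family = character(),
                                 intragenic = logical(), context = character(),
                                 direction = character()),
                region_fractions = data.table()))
  }
  dgr <- GRanges(dmrs$chrom, IRanges(dmrs$start + 1L, dmrs$end))
  hit_table <- function(gr, lab) {
    if (is.null(gr) || length(gr) == 0L) return(NULL)
    ov <- findOverlaps(dgr, gr, ignore.strand = TRUE)
    if (!length(ov)) return(NULL)
    data.table(dmr_id = dmrs$dmr_id[queryHits(ov)],
               gene_id = gr$gene_id[subjectHits(ov)], hit = lab,
               context = dmrs$context[queryHits(ov)],
               direction = dmrs$direction[queryHits(ov)])
  }
  genes_tab <- rbindlist(list(hit_table(index$genes, "body"),
                              hit_table(index$promoter, "promoter")))
  if (is.null(genes_tab) || nrow(genes_tab) == 0L)
    genes_tab <- data.table(dmr_id = character(), gene_id = character(),
                            hit = character(), context = character(),
                            direction = character())
  gene_sets <- genes_tab[, .(contexts = paste(sort(unique(context)),
                                              collapse = ",")),
                         by = .(gene_id, hit)]

  tes_tab <- data.table(dmr_id = character(), te_id = character(),
                        te_class = character(), family = character(),
                        intragenic = logical(), context = character(),
                        direction = character())
  if (!is.null(index$tes) && length(index$tes)) {
    ov <- findOverlaps(dgr, index$tes, ignore.strand = TRUE)
    if (length(ov))
      tes_tab <- data.table(dmr_id = dmrs$dmr_id[queryHits(ov)],
                            te_id = index$tes$te_id[subjectHits(ov)],
                            te_class = index$tes$te_class[subjectHits(ov)],
                            family = index$tes$family[subjectHits(ov)],
                            intragenic = index$tes$intragenic[subjectHits(ov)],
                            context = dmrs$context[queryHits(ov)],
                            direction = dmrs$direction[queryHits(ov)])
  }

  label_sets <- list(
    promoter = index$promoter, exon = if (!is.null(index$exons))
      unlist(index$exons) else NULL,
    intron = index$introns, body = index$genes, down2k = index$down2k,
    te = index$tes)
  frac_rows <- list()
  for (key in split(seq_len(nrow(dmrs)), dmrs[, paste(context, direction)])) {
    sub <- reduce(dgr[key], ignore.strand = TRUE)
    tot <- sum(width(sub))
    for (lab in names(label_sets)) {
      gr <- label_sets[[lab]]
      if (is.null(gr) || length(gr) == 0L) next
      ovw <- sum(width(GenomicRanges::intersect(
        sub, reduce(GRanges(seqnames(gr), IRanges(start(gr), end(gr)))),
        ignore.strand = TRUE)))
      frac_rows[[length(frac_rows) + 1L]] <- data.table(
        context = dmrs$context[key[1]], direction = dmrs$direction[key[1]],
        label = lab, dmr_bp = tot, overlap_bp = ovw,
        fraction = if (tot > 0) ovw / tot else 0)
    }
  }
  list(genes = genes_tab[], gene_context_sets = gene_sets[],
       tes = tes_tab[],
       region_fractions = if (length(frac_rows)) rbindlist(frac_rows)
                          else data.table())
}
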