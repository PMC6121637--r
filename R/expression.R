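#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across genes of the ratio
#' of a sample's count to the gene's geometric mean over samples, computed
#' over genes with all-positive counts.
#'
#' @param counts genes x samples count matrix.
#' @return numeric vector of size factors (geometric mean 1 when defined).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) stop("no gene has positive counts in every sample")
  sf <- apply(counts[use, , drop = FALSE], 2, function(k)
    exp(median(log(k) - log_gm[use])))
  sf
}

#' Compute FPKM from gene counts
#'
#' `fpkm = counts * 1e9 / (length_bp * library_size)`; the library size is
#' the column sum of the count matrix unless supplied.
#'
#' @param counts genes x samples matrix of assigned fragment counts.
#' @param gene_lengths named vector of gene lengths in bp (> 0).
#' @param library_sizes optional per-sample library sizes.
#' @return matrix of FPKM values, same shape as `counts`.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("'counts' must have gene_id rownames")
  len <- gene_lengths[rownames(counts)]
  if (any(is.na(len))) stop("gene lengths missing for some genes")
  if (any(len <= 0)) stop("gene lengths must be positive")
  lib <- library_sizes %||% colSums(counts)
  if (any(lib <= 0)) stop("library sizes must be positive")
  sweep(counts * 1e9 / len, 2, lib, "/")
}

#' Classify genes as expressed or condition-specific
#'
#' A gene is expressed in a condition when its replicate-mean FPKM reaches
#' the threshold; expressed genes present in only one condition are that
#' condition's specific genes.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param condition per-sample condition labels (two conditions).
#' @param threshold FPKM threshold (default 1).
#' @return data.table: `gene_id`, per-condition mean FPKM columns
#'   (`mean_<cond>`), `expressed_in` (`both` / one condition label /
#'   `neither`).
#' @export
classify_expressed <- function(fpkm, condition, threshold = 1) {
  condition <- as.character(condition)
  conds <- unique(condition)
  if (length(conds) != 2L) stop("exactly two conditions expected")
  m1 <- rowMeans(fpkm[, condition == conds[1], drop = FALSE])
  m2 <- rowMeans(fpkm[, condition == conds[2], drop = FALSE])
  e1 <- m1 >= threshold; e2 <- m2 >= threshold
  status <- fifelse(e1 & e2, "both",
                    fifelse(e1, conds[1], fifelse(e2, conds[2], "neither")))
  out <- data.table(gene_id = rownames(fpkm), mean1 = m1, mean2 = m2,
                    expressed_in = status)
  setnames(out, c("mean1", "mean2"), paste0("mean_", conds))
  out[]
}

# parametric mean-dispersion trend alpha(mu) = a0 + a1 / mu, fitted to
# positive gene-wise MoM estimates (gamma-family GLM style, here a simple
# trimmed least-squares fit on the inverse-mean covariate)
fit_dispersion_trend <- function(mu, alpha) {
  ok <- is.finite(mu) & mu > 0 & is.finite(alpha) & alpha > 0
  if (sum(ok) < 10L) return(c(a0 = max(median(alpha[ok], na.rm = TRUE), 0.01,
                                       na.rm = TRUE), a1 = 0))
  x <- 1 / mu[ok]; y <- alpha[ok]
  for (i in 1:3) {              # trim gross outliers, refit
    fit <- stats::lm(y ~ x)
    res <- stats::residuals(fit)
    keep <- abs(res) <= 3 * stats::sd(res)
    if (all(keep)) break
    x <- x[keep]; y <- y[keep]
  }
  a <- stats::coef(fit)
  c(a0 = max(unname(a[1]), 1e-4), a1 = max(unname(a[2]), 0))
}

#' Negative-binomial two-group differential-expression test
#'
#' Minimal replicated NB test: size-factor normalization (median of
#' ratios), gene-wise method-of-moments dispersion shrunk toward a
#' parametric mean-dispersion trend `alpha(mu) = a0 + a1/mu`, and a Wald
#' test on the difference of log condition means with a delta-method
#' variance `Var(log mean_c) = [mu sum_r 1/sf_r + R alpha mu^2] / (R mu)^2`
#' referred to a moderated t distribution whose total degrees of freedom
#' reflect the dispersion shrinkage (`d_res / shrink_weight`; the plug-in
#' variance at three replicates is not chi-square enough for a plain normal
#' reference). P-values are
#' BH-adjusted; genes pass at `p_adjusted < alpha`, `up` meaning higher in
#' the first condition.
#'
#' @param counts genes x samples count matrix.
#' @param condition per-sample condition labels (two conditions, >= 2
#'   replicates each); the first label in `conditions` (or first
#'   encountered) is the reference.
#' @param conditions optional explicit condition order `c(ref, other)`.
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param shrink_weight weight of the gene-wise dispersion estimate against
#'   the trend (default 0.25; replicate NB dispersion estimates from three
#'   samples are noisy, so the trend dominates).
#' @param pseudo_mean small mean floor guarding the log transform.
#' @return data.table: `gene_id`, `base_mean` (mean normalized count),
#'   `mean1`, `mean2`, `log2_fold_change`, `lfc_se`, `stat`, `pval`,
#'   `padj`, `status` (`up`/`down`/`ns`), `dispersion`.
#' @export
detect_degs <- function(counts, condition, conditions = NULL, alpha = 0.05,
                        shrink_weight = 0.25, pseudo_mean = 1e-8) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  conds <- conditions %||% unique(condition)
  if (length(conds) != 2L) stop("exactly two conditions expected")
  j1 <- which(condition == conds[1]); j2 <- which(condition == conds[2])
  if (length(j1) < 2L || length(j2) < 2L)
    stop("at least two replicates per condition required")
  sf <- size_factors(counts)
  Q <- sweep(counts, 2, sf, "/")            # normalized counts
  base_mean <- rowMeans(Q)

  # gene-wise MoM dispersion from *within-condition* normalized-count
  # variance (the condition effect must not contribute):
  # Var(q) ~ mu_c * mean(1/sf) + alpha * mu_c^2 per condition
  alpha_cond <- function(jj) {
    m <- rowMeans(Q[, jj, drop = FALSE])
    s2 <- rowSums((Q[, jj, drop = FALSE] - m)^2) / (length(jj) - 1L)
    (s2 - m * mean(1 / sf[jj])) / m^2
  }
  a1c <- alpha_cond(j1); a2c <- alpha_cond(j2)
  w1 <- length(j1) - 1L; w2 <- length(j2) - 1L
  alpha_mom <- (fifelse(is.finite(a1c), a1c, 0) * w1 * is.finite(a1c) +
                fifelse(is.finite(a2c), a2c, 0) * w2 * is.finite(a2c)) /
    pmax(w1 * is.finite(a1c) + w2 * is.finite(a2c), 1L)
  alpha_mom[!is.finite(a1c) & !is.finite(a2c)] <- NA
  trend <- fit_dispersion_trend(base_mean, alpha_mom)
  alpha_trend <- trend["a0"] + trend["a1"] / pmax(base_mean, pseudo_mean)
  disp <- shrink_weight * pmax(alpha_mom, 0) + (1 - shrink_weight) * alpha_trend
  disp[is.na(alpha_mom)] <- alpha_trend[is.na(alpha_mom)]
  disp <- pmax(disp, 1e-8)

  m1 <- rowMeans(Q[, j1, drop = FALSE]); m2 <- rowMeans(Q[, j2, drop = FALSE])
  # delta-method variance of log condition means
  vlog <- function(mu, jj) {
    # Var(q_r) = mu / sf_r + disp * mu^2, so
    # Var(log mean) ~ [mu * sum(1/sf) + R * disp * mu^2] / (R * mu)^2
    s <- mu * sum(1 / sf[jj]) + length(jj) * disp * mu^2
    s / (length(jj) * pmax(mu, pseudo_mean))^2
  }
  v1 <- vlog(m1, j1); v2 <- vlog(m2, j2)
  lfc_ln <- log(pmax(m1, pseudo_mean)) - log(pmax(m2, pseudo_mean))
  se <- sqrt(v1 + v2)
  stat <- ifelse(se > 0, lfc_ln / se, ifelse(lfc_ln == 0, 0, Inf * sign(lfc_ln)))
  # moderated-t reference: the shrink weight w = d_res / (d_res + d_prior)
  # implies a prior df of d_res (1 - w) / w, and the moderated statistic
  # carries d_res + d_prior total df (w -> 1 gives the plain t, w -> 0 the
  # normal reference)
  d_res <- length(j1) + length(j2) - 2L
  df_total <- if (shrink_weight > 0) d_res / shrink_weight else Inf
  pval <- if (is.finite(df_total)) 2 * pt(-abs(stat), df = df_total)
          else wald_pvalue(stat)
  pval[is.nan(stat)] <- NA_real_
  allzero <- rowSums(counts) == 0
  bothzero <- m1 == 0 & m2 == 0
  stat[bothzero] <- 0; pval[allzero | bothzero] <- 1
  padj <- p.adjust(pval, "BH")
  status <- fifelse(padj < alpha & stat > 0, "up",
                    fifelse(padj < alpha & stat < 0, "down", "ns"))
  data.table(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             base_mean = base_mean, mean1 = m1, mean2 = m2,
             log2_fold_change = lfc_ln / log(2), lfc_se = se / log(2),
             stat = stat, pval = pval, padj = padj, status = status,
             dispersion = disp)
}
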