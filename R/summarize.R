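#' Summarize methylated-site counts per context from a count table
#'
#' Pure arithmetic layer of the genome-wide context summary: given per-sample
#' counts of reference cytosines (`n_sites`) and of sites called methylated
#' (`n_methylated`) per context, computes per-sample ratios, per-condition
#' and grand averages, and the relative proportion each context contributes
#' to a sample's methylated sites. This is the layout of the standard
#' "methylation of C contexts mapping to the reference genome" table, and is
#' independent of how the site calls were made (see [summarize_contexts()]
#' for the record-level entry point).
#'
#' @param counts data.frame with columns `sample`, `condition`, `context`,
#'   `n_sites`, `n_methylated` (one row per sample x context).
#' @return object of class `context_summary`: list with
#'   \describe{
#'     \item{summary}{data.table with `row_label` (each sample, each
#'       `<condition>-average`, and `average`), `condition`, `context`
#'       (`"all"`, `"CG"`, `"CHG"`, `"CHH"`), `n_sites`, `n_methylated`,
#'       `ratio` (= n_methylated / n_sites; for average rows, the arithmetic
#'       mean of the constituent samples' ratios).}
#'     \item{proportions}{data.table with `row_label`, `context`,
#'       `proportion`: each context's share of the sample's methylated
#'       sites, with cross-sample average rows.}
#'   }
#' @export
summarize_context_counts <- function(counts) {
  dt <- as.data.table(counts)
  req <- c("sample", "condition", "context", "n_sites", "n_methylated")
  if (!all(req %in% names(dt)))
    stop("'counts' must have columns: ", paste(req, collapse = ", "))
  if (any(dt$n_methylated > dt$n_sites))
    stop("n_methylated exceeds n_sites in some rows")
  ctx_levels <- c("CG", "CHG", "CHH")
  if (!all(dt$context %in% ctx_levels))
    stop("context must be one of: ", paste(ctx_levels, collapse = ", "))

  # per-sample rows: totals over contexts plus each context
  tot <- dt[, .(context = "all", n_sites = sum(n_sites),
                n_methylated = sum(n_methylated)),
            by = .(sample, condition)]
  per_sample <- rbind(tot, dt[, .(sample, condition, context,
                                  n_sites, n_methylated)])
  per_sample[, ratio := n_methylated / n_sites]

  avg_over <- function(d, lab, cond) {
    d[, .(row_label = lab, condition = cond, n_sites = mean(n_sites),
          n_methylated = mean(n_methylated), ratio = mean(ratio)),
      by = context]
  }
  cond_rows <- rbindlist(lapply(unique(per_sample$condition), function(cd) {
    avg_over(per_sample[condition == cd], paste0(cd, "-average"), cd)
  }))
  grand <- avg_over(per_sample, "average", NA_character_)
  samp_rows <- per_sample[, .(row_label = sample, condition, context,
                              n_sites = as.numeric(n_sites),
                              n_methylated = as.numeric(n_methylated), ratio)]
  summary <- rbind(samp_rows,
                   cond_rows[, .(row_label, condition, context,
                                 n_sites, n_methylated, ratio)],
                   grand[, .(row_label, condition, context,
                             n_sites, n_methylated, ratio)])
  summary[, context := factor(context, levels = c("all", ctx_levels))]
  setorder(summary, context)

  # relative proportions: per sample, context share of methylated sites
  prop <- merge(dt, tot[, .(sample, n_meth_total = n_methylated)],
                by = "sample")
  prop <- prop[, .(row_label = sample, context,
                   proportion = n_methylated / n_meth_total)]
  prop_avg <- prop[, .(row_label = "average", proportion = mean(proportion)),
                   by = context][, .(row_label, context, proportion)]
  proportions <- rbind(prop, prop_avg)

  structure(list(summary = summary[], proportions = proportions[]),
            class = "context_summary")
}

#' @export
print.context_summary <- function(x, ...) {
  wide <- dcast(x$summary, row_label ~ context,
                value.var = c("n_methylated", "ratio"))
  cat("Context summary (counts of methylated sites and ratios):\n")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Call methylated sites against the non-conversion background
#'
#' A covered site is called methylated when its methylated read count is
#' improbably high under the null that every apparent methylation is a
#' conversion failure: one-sided binomial test of `M >= m` under
#' `Binomial(N, r)`, Benjamini-Hochberg corrected within each context per
#' sample, called at `q < q_threshold` (and at least one methylated read).
#'
#' @param bs BSCounts object.
#' @param r bisulfite non-conversion rate (from [estimate_nonconversion()]).
#' @param q_threshold BH-adjusted significance threshold (default 0.01).
#' @return logical matrix, sites x samples (`NA` where a site is uncovered).
#' @export
call_methylated_sites <- function(bs, r, q_threshold = 0.01) {
  stopifnot(is(bs, "BSCounts"))
  stopifnot_scalar_prob(r, "r")
  ctx <- bs$sites$context
  calls <- matrix(NA, nrow(bs$sites), length(bs$samples),
                  dimnames = list(NULL, bs$samples))
  for (k in seq_along(bs$samples)) {
    n <- bs$N[, k]; m <- bs$M[, k]
    covered <- n > 0L
    p <- rep(NA_real_, length(n))
    # P(X >= m | X ~ Bin(n, r)); m = 0 gives p = 1
    p[covered] <- pbinom(m[covered] - 1L, n[covered], r, lower.tail = FALSE)
    call_k <- rep(NA, length(n))
    for (cx in unique(ctx)) {
      i <- which(covered & ctx == cx)
      call_k[i] <- p.adjust(p[i], "BH") < q_threshold & m[i] >= 1L
    }
    calls[, k] <- call_k
  }
  calls
}

#' Genome-wide context summary from per-cytosine records
#'
#' Tabulates, per sample and context, the number of covered reference
#' cytosines and the number called methylated (via
#' [call_methylated_sites()]), then applies the [summarize_context_counts()]
#' arithmetic to produce the ratio table and relative context proportions.
#'
#' @param bs BSCounts object.
#' @param r non-conversion rate used by the methylated-site caller; 0 treats
#'   every read supporting methylation as genuine.
#' @param q_threshold BH threshold for the site caller.
#' @param site_calls optional precomputed logical matrix from
#'   [call_methylated_sites()] (overrides `r`/`q_threshold`).
#' @return A `context_summary` object (see [summarize_context_counts()]).
#' @export
summarize_contexts <- function(bs, r = 0, q_threshold = 0.01,
                               site_calls = NULL) {
  stopifnot(is(bs, "BSCounts"))
  if (is.null(site_calls)) site_calls <- call_methylated_sites(bs, r, q_threshold)
  covered <- bs$N > 0L
  universes <- apply(covered, 2, function(z) paste(which(z), collapse = ","))
  if (length(unique(universes)) > 1L)
    warning("samples cover unequal site sets; ",
            "summaries computed over each sample's own covered sites")
  ctx <- bs$sites$context
  rows <- list()
  for (k in seq_along(bs$samples)) {
    for (cx in c("CG", "CHG", "CHH")) {
      i <- ctx == cx
      rows[[length(rows) + 1L]] <- data.table(
        sample = bs$samples[k],
        condition = as.character(bs$condition[k]),
        context = cx,
        n_sites = sum(covered[i, k]),
        n_methylated = sum(site_calls[i, k], na.rm = TRUE))
    }
  }
  summarize_context_counts(rbindlist(rows))
}

#' Histogram of per-site methylation levels by context
#'
#' Bins site methylation levels into fixed-width bins (default 10%):
#' `[0,0.1), ..., [0.9,1]`; the top bin is closed so a fully methylated site
#' is counted. `NA` levels (uncovered sites) are dropped.
#'
#' @param levels numeric vector of site methylation levels in \[0, 1\].
#' @param context character vector of site contexts, parallel to `levels`.
#' @param bin_width bin width as a proportion (default 0.1).
#' @return data.table with `context`, `bin_low`, `bin_high`, `count`; per
#'   context, counts sum to the number of non-`NA` sites.
#' @export
level_histogram <- function(levels, context, bin_width = 0.1) {
  stopifnot(length(levels) == length(context), bin_width > 0, bin_width <= 1)
  keep <- !is.na(levels)
  levels <- levels[keep]; context <- context[keep]
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  n_bins <- ceiling(1 / bin_width)
  idx <- pmin(floor(levels / bin_width), n_bins - 1L) + 1L  # top bin closed
  dt <- data.table(context = context, bin = idx)
  grid <- CJ(context = unique(context), bin = seq_len(n_bins))
  out <- dt[, .(count = .N), by = .(context, bin)][grid, on = c("context", "bin")]
  out[is.na(count), count := 0L]
  out[, `:=`(bin_low = (bin - 1L) * bin_width,
             bin_high = pmin(bin * bin_width, 1))]
  setorder(out, context, bin)
  out[, .(context, bin_low, bin_high, count)]
}

#' Example context-count table from a six-library petal WGBS experiment
#'
#' Per-sample counts of reference cytosines and methylated-called sites per
#' context for six *Prunus mume* petal-tissue WGBS libraries (white and red
#' petal tissue, three biological replicates each), as published for that
#' experiment. Useful as a worked example for
#' [summarize_context_counts()].
#'
#' @return data.table with columns `sample`, `condition`, `context`,
#'   `n_sites`, `n_methylated`.
#' @export
example_context_counts <- function() {
  path <- system.file("extdata", "pmume_petal_context_counts.tsv",
                      package = "methexpr", mustWork = TRUE)
  fread(path)
}
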