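#' Stratified Pearson correlation of methylation and expression
#'
#' For each stratum (typically region x context), the Pearson correlation
#' between a per-gene methylation quantity (level, or between-condition
#' difference) and a per-gene expression quantity (log FPKM, or log fold
#' change), with the exact two-sided t-test p-value on n - 2 degrees of
#' freedom. Strata with fewer than 3 complete pairs, or with a constant
#' vector, are reported with `NA` correlation.
#'
#' @param meth data.table with columns `gene_id`, `value`, plus any stratum
#'   columns (e.g. `region`, `context`).
#' @param expr named numeric vector of the expression quantity per gene.
#' @param strata character vector of stratum column names present in
#'   `meth` (default: all columns except gene_id/value).
#' @return data.table: stratum columns, `pearson_r`, `p_value`, `n`.
#' @export
correlate_meth_expr <- function(meth, expr, strata = NULL) {
  meth <- as.data.table(meth)
  stopifnot(all(c("gene_id", "value") %in% names(meth)))
  strata <- strata %||% setdiff(names(meth), c("gene_id", "value"))
  meth[, y := expr[gene_id]]
  one <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(pearson_r = NA_real_, p_value = NA_real_, n = n))
    ct <- cor.test(x, y, method = "pearson")
    list(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = n)
  }
  if (length(strata)) meth[, one(value, y), by = strata]
  else meth[, one(value, y)]
}

#' Metagene methylation profiles of differentially expressed genes
#'
#' Profiles the `all` (union of up- and downregulated), `up` and `down` DEG
#' classes separately per condition, reusing [metagene_profile()]
#' (gene-weighted averaging, 50 bins per region).
#'
#' @param bs BSCounts object.
#' @param genes GRanges with `gene_id`.
#' @param degs [detect_degs()] table.
#' @param n_bins,flank,r passed to [metagene_profile()].
#' @return data.table with the [metagene_profile()] columns plus
#'   `condition`; empty when there are no DEGs.
#' @export
deg_methylation_profiles <- function(bs, genes, degs, n_bins = 50L,
                                     flank = 2000L, r = NULL) {
  degs <- as.data.table(degs)
  up <- degs[status == "up", gene_id]
  down <- degs[status == "down", gene_id]
  sets <- list(all = c(up, down), up = up, down = down)
  out <- list()
  for (cond in levels(bs$condition)) {
    samp <- bs$samples[bs$condition == cond]
    for (gl in names(sets)) {
      ids <- sets[[gl]]
      if (length(ids) == 0L) {
        message("no DEGs in class '", gl, "'; skipped")
        next
      }
      pr <- metagene_profile(bs, genes,
                             groups = setNames(rep(gl, length(ids)), ids),
                             samples = samp, n_bins = n_bins, flank = flank,
                             r = r)
      if (nrow(pr)) { pr[, condition := cond]; out[[paste(cond, gl)]] <- pr }
    }
  }
  if (!length(out))
    return(data.table(group = character(), context = character(),
                      region = character(), bin = integer(),
                      mean_level = numeric(), n_sites = integer(),
                      n_genes = integer(), condition = character()))
  rbindlist(out)
}

#' Associate DMR-related genes with expression differences
#'
#' For every gene hit by at least one DMR in its body or promoter, pairs
#' the gene's methylation-level difference (mean raw DMR difference,
#' reference condition minus the other) with its expression log fold
#' change, labels concordance under the negative-coupling expectation
#' (hyper & down, or hypo & up), and reports stratified correlations per
#' context and region.
#'
#' @param dmr_genes `genes` table from [annotate_dmrs()].
#' @param dmrs [call_dmrs()] table (for the per-DMR mean difference).
#' @param degs [detect_degs()] table.
#' @return list with `genes` (per gene x region x context: `meth_diff`,
#'   `direction`, `log2_fold_change`, `deg_status`, `concordant`) and
#'   `correlations` (per region x context Pearson r of meth_diff vs LFC).
#' @export
dmr_gene_expression_association <- function(dmr_genes, dmrs, degs) {
  dmr_genes <- as.data.table(dmr_genes)
  dmrs <- as.data.table(dmrs)
  degs <- as.data.table(degs)
  if (nrow(dmr_genes) == 0L)
    return(list(genes = data.table(), correlations = data.table()))
  tab <- merge(dmr_genes, dmrs[, .(dmr_id, mean_diff)], by = "dmr_id")
  per_gene <- tab[, .(meth_diff = mean(mean_diff),
                      n_dmrs = .N,
                      direction = if (mean(mean_diff) > 0) "hyper" else "hypo"),
                  by = .(gene_id, hit, context)]
  per_gene <- merge(per_gene,
                    degs[, .(gene_id, log2_fold_change, deg_status = status)],
                    by = "gene_id", all.x = TRUE)
  per_gene[, concordant := (direction == "hyper" & deg_status == "down") |
                           (direction == "hypo" & deg_status == "up")]
  lfc <- setNames(degs$log2_fold_change, degs$gene_id)
  cors <- correlate_meth_expr(
    per_gene[, .(gene_id, value = meth_diff, hit, context)], lfc,
    strata = c("hit", "context"))
  list(genes = per_gene[], correlations = cors[])
}

#' Cross-classify DMR-related genes against DEG direction
#'
#' The headline 2x2 layout: hypermethylated / hypomethylated DMR-related
#' genes against up- / downregulated DEGs, per context and region, with the
#' gene lists behind each cell and the genes belonging to both methylation
#' classes (hit by hyper- and hypo-DMRs of the same context and region).
#'
#' @param dmr_genes `genes` table from [annotate_dmrs()] (one row per
#'   DMR x gene hit, with `context` and `direction`).
#' @param degs [detect_degs()] table.
#' @param region `"body"`, `"promoter"`, or `"both"` (default: analyze each
#'   separately and return both).
#' @return data.table with `region`, `context`, `meth_class`
#'   (`hyper`/`hypo`), `deg_class` (`up`/`down`), `n_genes`, `genes`
#'   (comma-separated ids); attribute `"venn"` carries the named gene-set
#'   lists per region x context, and attribute `"dual_class"` the genes in
#'   both methylation classes.
#' @export
cross_classify <- function(dmr_genes, degs, region = c("both", "body", "promoter")) {
  region <- match.arg(region)
  dmr_genes <- as.data.table(dmr_genes)
  degs <- as.data.table(degs)
  regions <- if (region == "both") c("body", "promoter") else region
  up <- degs[status == "up", gene_id]
  down <- degs[status == "down", gene_id]
  rows <- list(); venn <- list(); dual <- list()
  for (reg in regions) {
    sub <- dmr_genes[hit == reg]
    for (cx in sort(unique(sub$context))) {
      hyper <- unique(sub[context == cx & direction == "hyper", gene_id])
      hypo <- unique(sub[context == cx & direction == "hypo", gene_id])
      cells <- list(c("hyper", "up"), c("hyper", "down"),
                    c("hypo", "up"), c("hypo", "down"))
      for (cl in cells) {
        mset <- if (cl[1] == "hyper") hyper else hypo
        dset <- if (cl[2] == "up") up else down
        g <- intersect(mset, dset)
        rows[[length(rows) + 1L]] <- data.table(
          region = reg, context = cx, meth_class = cl[1], deg_class = cl[2],
          n_genes = length(g), genes = paste(sort(g), collapse = ","))
      }
      key <- paste(reg, cx, sep = ".")
      venn[[key]] <- list(DMR_Hypergenes = hyper, DMR_Hypogenes = hypo,
                          DEG_upgenes = up, DEG_downgenes = down)
      dual[[key]] <- intersect(hyper, hypo)
    }
  }
  out <- if (length(rows)) rbindlist(rows) else
    data.table(region = character(), context = character(),
               meth_class = character(), deg_class = character(),
               n_genes = integer(), genes = character())
  setattr(out, "venn", venn)
  setattr(out, "dual_class", dual)
  out[]
}

#' DMR / TE / DEG association triples
#'
#' Emits one row per (gene, TE, DMR) triple where the gene is a DMR-related
#' gene that is differentially expressed, the TE lies within the gene's
#' extended domain (body plus 2-kb flanks), and the DMR overlaps that TE.
#' A DMR spanning two TEs yields two triples. Also reports, per context and
#' direction, how many DMRs fall within TEs and the fraction of DMR length
#' in TEs.
#'
#' @param dmrs [call_dmrs()] table.
#' @param annotation result of [annotate_dmrs()] (supplies DMR-related
#'   genes).
#' @param degs [detect_degs()] table.
#' @param genes GRanges with `gene_id`.
#' @param tes GRanges with `te_id`, `te_class`, `family`.
#' @param flank domain flank width (default 2000).
#' @return list with `triples` (data.table: gene_id, deg_status, te_id,
#'   te_class, family, te_position = body/up2k/down2k, dmr_id, context,
#'   direction) and `te_dmr_summary` (per context x direction: n_dmrs_in_te,
#'   fraction of DMR length within TEs).
#' @export
te_dmr_deg_association <- function(dmrs, annotation, degs, genes, tes,
                                   flank = 2000L) {
  dmrs <- as.data.table(dmrs)
  degs <- as.data.table(degs)
  empty <- data.table(gene_id = character(), deg_status = character(),
                      te_id = character(), te_class = character(),
                      family = character(), te_position = character(),
                      dmr_id = character(), context = character(),
                      direction = character())
  deg_ids <- degs[status %in% c("up", "down"), gene_id]
  cand <- intersect(unique(annotation$genes$gene_id), deg_ids)
  summary_tab <- te_dmr_summary(dmrs, tes)
  if (length(cand) == 0L || length(tes) == 0L || nrow(dmrs) == 0L)
    return(list(triples = empty, te_dmr_summary = summary_tab))

  g <- genes[genes$gene_id %in% cand]
  domain <- GRanges(seqnames(g), IRanges(start(g) - flank, end(g) + flank))
  domain$gene_id <- g$gene_id
  ov_gt <- findOverlaps(domain, tes, ignore.strand = TRUE)
  if (!length(ov_gt)) return(list(triples = empty, te_dmr_summary = summary_tab))
  dgr <- GRanges(dmrs$chrom, IRanges(dmrs$start + 1L, dmrs$end))
  ov_td <- findOverlaps(tes, dgr, ignore.strand = TRUE)
  te_dmr <- data.table(ti = queryHits(ov_td), di = subjectHits(ov_td))
  gt <- data.table(gi = queryHits(ov_gt), ti = subjectHits(ov_gt))
  trip <- merge(gt, te_dmr, by = "ti", allow.cartesian = TRUE)
  if (nrow(trip) == 0L) return(list(triples = empty, te_dmr_summary = summary_tab))
  bodies <- g
  te_mid <- (start(tes)[trip$ti] + end(tes)[trip$ti]) / 2
  gs <- start(bodies)[trip$gi]; ge <- end(bodies)[trip$gi]
  gstrand <- as.character(strand(bodies))[trip$gi]
  pos_lab <- fifelse(te_mid >= gs & te_mid <= ge, "body",
             fifelse((te_mid < gs & gstrand == "+") | (te_mid > ge & gstrand == "-"),
                     "up2k", "down2k"))
  status_map <- setNames(degs$status, degs$gene_id)
  triples <- data.table(
    gene_id = bodies$gene_id[trip$gi],
    deg_status = status_map[bodies$gene_id[trip$gi]],
    te_id = tes$te_id[trip$ti], te_class = tes$te_class[trip$ti],
    family = tes$family[trip$ti], te_position = pos_lab,
    dmr_id = dmrs$dmr_id[trip$di], context = dmrs$context[trip$di],
    direction = dmrs$direction[trip$di])
  setorder(triples, gene_id, te_id, dmr_id)
  list(triples = unique(triples), te_dmr_summary = summary_tab)
}

te_dmr_summary <- function(dmrs, tes) {
  if (nrow(dmrs) == 0L)
    return(data.table(context = character(), direction = character(),
                      n_dmrs = integer(), n_dmrs_in_te = integer(),
                      dmr_bp = integer(), dmr_bp_in_te = numeric(),
                      fraction_in_te = numeric()))
  dgr <- GRanges(dmrs$chrom, IRanges(dmrs$start + 1L, dmrs$end))
  te_red <- if (length(tes)) reduce(GRanges(seqnames(tes),
                                            IRanges(start(tes), end(tes))))
            else GRanges()
  in_te <- IRanges::overlapsAny(dgr, te_red)
  ovw <- rep(0, length(dgr))
  if (length(te_red)) {
    ov <- findOverlaps(dgr, te_red)
    if (length(ov)) {
      w <- width(pintersect(dgr[queryHits(ov)], te_red[subjectHits(ov)]))
      agg <- data.table(i = queryHits(ov), w = w)[, .(w = sum(w)), by = i]
      ovw[agg$i] <- agg$w
    }
  }
  dt <- data.table(context = dmrs$context, direction = dmrs$direction,
                   len = dmrs$end - dmrs$start, in_te = in_te, ovw = ovw)
  dt[, .(n_dmrs = .N, n_dmrs_in_te = sum(in_te), dmr_bp = sum(len),
         dmr_bp_in_te = sum(ovw), fraction_in_te = sum(ovw) / sum(len)),
     by = .(context, direction)]
}

#' Run the four-level methylation-by-expression integration
#'
#' Levels, in order: (1) global correlation of per-gene region methylation
#' with expression; (2) metagene methylation profiles of DEGs; (3)
#' DMR-related-gene expression association; (4) DMR x DEG cross-
#' classification and the TE association. Upstream results (DML test, DMR
#' calls, DEG table) are computed here from the raw inputs; pass
#' pre-computed tables to reuse them.
#'
#' @param bs BSCounts of the two-condition methylome.
#' @param genes,exons,tes annotation (GRanges / GRangesList).
#' @param counts genes x samples expression count matrix.
#' @param gene_lengths named vector of gene lengths (bp).
#' @param expr_condition condition label per expression sample.
#' @param r optional non-conversion rate.
#' @param dml,dmrs,degs optional precomputed tables.
#' @param dml_args,dmr_args,deg_args argument lists forwarded to
#'   [dml_test()], [call_dmrs()], [detect_degs()].
#' @param outdir optional directory: every table is also written as TSV.
#' @return list with `fpkm`, `expressed`, `degs`, `dml`, `dmrs`,
#'   `annotation`, `correlations` (level 1), `deg_profiles` (level 2),
#'   `dmr_expression` (level 3), `cross` and `te_association` (level 4).
#' @export
run_integration <- function(bs, genes, exons, tes, counts, gene_lengths,
                            expr_condition, r = NULL,
                            dml = NULL, dmrs = NULL, degs = NULL,
                            dml_args = list(), dmr_args = list(),
                            deg_args = list(), outdir = NULL) {
  index <- build_feature_index(genes, exons, tes)
  fpkm <- compute_fpkm(counts, gene_lengths)
  expressed <- classify_expressed(fpkm, expr_condition)
  if (is.null(degs))
    degs <- do.call(detect_degs,
                    c(list(counts = counts, condition = expr_condition),
                      deg_args))
  if (is.null(dml)) dml <- do.call(dml_test, c(list(bs = bs), dml_args))
  if (is.null(dmrs)) dmrs <- do.call(call_dmrs, c(list(dml = dml), dmr_args))
  annotation <- annotate_dmrs(dmrs, index)

  # level 1: per-gene region methylation vs log expression
  lfc <- setNames(degs$log2_fold_change, degs$gene_id)
  mean_fpkm <- rowMeans(fpkm)
  log_expr <- setNames(log2(mean_fpkm + 1), rownames(fpkm))
  lev1 <- list()
  for (reg in c("body", "promoter", "down2k")) {
    gm <- gene_region_methylation(bs, genes, region = reg, r = r)
    lev1[[reg]] <- gm[, .(gene_id, value = mean_level, region = reg, context)]
  }
  lev1 <- rbindlist(lev1)
  correlations <- correlate_meth_expr(lev1, log_expr,
                                      strata = c("region", "context"))

  # level 2: DEG metagene profiles per condition
  deg_profiles <- deg_methylation_profiles(bs, genes, degs, r = r)

  # level 3: DMR-related gene expression association
  dmr_expression <- dmr_gene_expression_association(annotation$genes, dmrs, degs)

  # level 4: cross-classification + TE association
  cross <- cross_classify(annotation$genes, degs)
  te_association <- te_dmr_deg_association(dmrs, annotation, degs, genes, tes)

  res <- list(fpkm = fpkm, expressed = expressed, degs = degs, dml = dml,
              dmrs = dmrs, annotation = annotation,
              correlations = correlations, deg_profiles = deg_profiles,
              dmr_expression = dmr_expression, cross = cross,
              te_association = te_association)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) fwrite(as.data.table(x), file.path(outdir, f), sep = "\t")
    wt(data.table(gene_id = rownames(fpkm), fpkm), "fpkm.tsv")
    wt(expressed, "expressed_genes.tsv")
    wt(degs, "degs.tsv")
    wt(dml, "dml.tsv")
    wt(dmrs, "dmrs.tsv")
    wt(annotation$genes, "dmr_genes.tsv")
    wt(annotation$tes, "dmr_tes.tsv")
    wt(correlations, "correlations.tsv")
    wt(deg_profiles, "deg_profiles.tsv")
    wt(dmr_expression$genes, "dmr_gene_expression.tsv")
    wt(dmr_expression$correlations, "dmr_gene_correlations.tsv")
    wt(cross, "cross_classification.tsv")
    wt(te_association$triples, "te_dmr_deg_triples.tsv")
    wt(te_association$te_dmr_summary, "te_dmr_summary.tsv")
  }
  res
}
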