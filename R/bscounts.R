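#' Per-cytosine methylation count container
#'
#' A light container holding one row per reference cytosine site and one
#' column per sample for methylated and total read counts. Positions are
#' 1-based (cytosine-report convention); `context` is the strand-aware
#' trinucleotide class (CG, CHG or CHH).
#'
#' @param sites data.frame/data.table with columns `chrom`, `pos` (1-based
#'   integer), `strand` (`"+"`/`"-"`), `context` (`"CG"`, `"CHG"`, `"CHH"`).
#' @param M integer matrix of methylated read counts, sites x samples.
#' @param N integer matrix of total read counts (methylated + unmethylated),
#'   same dimensions as `M`.
#' @param samples character vector of sample labels (column names).
#' @param condition factor/character of condition labels, one per sample.
#'
#' @return An object of class `BSCounts`: a list with elements `sites`
#'   (data.table), `M`, `N` (matrices), `samples`, `condition`.
#' @export
bs_counts <- function(sites, M, N, samples, condition) {
  sites <- as.data.table(sites)
  req <- c("chrom", "pos", "strand", "context")
  if (!all(req %in% names(sites)))
    stop("'sites' must have columns: ", paste(req, collapse = ", "))
  M <- as.matrix(M); N <- as.matrix(N)
  storage.mode(M) <- "integer"; storage.mode(N) <- "integer"
  if (!all(dim(M) == dim(N)) || nrow(M) != nrow(sites))
    stop("'M' and 'N' must be sites x samples matrices of equal dimension")
  if (length(samples) != ncol(M))
    stop("'samples' length must match the number of count columns")
  if (any(M > N, na.rm = TRUE))
    stop("methylated counts exceed total counts at some sites")
  colnames(M) <- colnames(N) <- samples
  structure(
    list(sites = sites, M = M, N = N,
         samples = as.character(samples),
         # keep the supplied condition order (first level = reference)
         condition = factor(condition, levels = unique(as.character(condition)))),
    class = "BSCounts")
}

#' @export
print.BSCounts <- function(x, ...) {
  cat(sprintf("BSCounts: %d sites x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(levels(x$condition), table(x$condition), sep = ":", collapse = ", ")))
  ctx <- table(x$sites$context)
  cat("contexts:", paste(names(ctx), ctx, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.BSCounts <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a BSCounts object by site index and/or sample
#'
#' @param x BSCounts object.
#' @param i row (site) index.
#' @param j sample index or names.
#' @param ... unused.
#' @return BSCounts restricted to the selected sites/samples.
#' @export
`[.BSCounts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_along(x$samples)
  if (is.character(j)) j <- match(j, x$samples)
  bs_counts(x$sites[i], x$M[i, j, drop = FALSE], x$N[i, j, drop = FALSE],
            x$samples[j], x$condition[j])
}

#' Read Bismark-style cytosine reports into a BSCounts object
#'
#' Expects one tab-separated file per sample with columns: chrom, 1-based
#' position, strand, count_methylated, count_unmethylated, context
#' (CG/CHG/CHH), trinucleotide. All files must cover the identical site set
#' (the usual situation when reports are produced against one reference).
#'
#' @param paths character vector of file paths, one per sample.
#' @param samples sample labels; defaults to file basenames.
#' @param condition condition label per sample.
#' @return A [bs_counts()] object.
#' @export
read_cx_reports <- function(paths, samples = NULL, condition = NULL) {
  if (is.null(samples)) samples <- sub("\\.[^.]*$", "", basename(paths))
  cols <- c("chrom", "pos", "strand", "meth", "unmeth", "context", "trinucleotide")
  tabs <- lapply(paths, function(p) {
    dt <- fread(p, header = FALSE, col.names = cols,
                colClasses = list(character = c(1, 3, 6, 7), integer = c(2, 4, 5)))
    setorder(dt, chrom, pos, strand)
    dt
  })
  key0 <- tabs[[1]][, .(chrom, pos, strand, context)]
  for (k in seq_along(tabs)[-1]) {
    if (!identical(tabs[[k]][, .(chrom, pos, strand, context)], key0))
      stop("cytosine reports do not cover identical site sets: ", paths[k])
  }
  M <- vapply(tabs, function(d) d$meth, integer(nrow(key0)))
  N <- M + vapply(tabs, function(d) d$unmeth, integer(nrow(key0)))
  if (is.null(condition)) condition <- rep("unknown", length(samples))
  bs_counts(key0, M, N, samples, condition)
}

#' Write per-sample cytosine reports
#'
#' Writes one tab-separated cytosine report per sample in the dialect read by
#' [read_cx_reports()] (chrom, pos, strand, count_methylated,
#' count_unmethylated, context, trinucleotide).
#'
#' @param bs BSCounts object.
#' @param dir output directory (created if missing).
#' @param trinucleotide optional character vector of trinucleotides per site;
#'   if `NULL` the context string is written in its place.
#' @param prefix file-name prefix.
#' @return Invisibly, the vector of written file paths (named by sample).
#' @export
write_cx_reports <- function(bs, dir, trinucleotide = NULL, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tri <- trinucleotide %||% bs$sites$context
  paths <- setNames(file.path(dir, paste0(prefix, bs$samples, ".CX_report.txt")),
                    bs$samples)
  for (k in seq_along(bs$samples)) {
    out <- data.table(bs$sites$chrom, bs$sites$pos, bs$sites$strand,
                      bs$M[, k], bs$N[, k] - bs$M[, k], bs$sites$context, tri)
    fwrite(out, paths[k], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}

#' Read a gene-level count table
#'
#' Tab-separated with header: `gene_id`, `length_bp`, then one column per
#' sample.
#'
#' @param path file path.
#' @return list with `counts` (matrix genes x samples), `lengths` (named
#'   integer vector), `samples`.
#' @export
read_gene_counts <- function(path) {
  dt <- fread(path)
  if (!all(c("gene_id", "length_bp") %in% names(dt)))
    stop("count table must have 'gene_id' and 'length_bp' columns")
  samples <- setdiff(names(dt), c("gene_id", "length_bp"))
  counts <- as.matrix(dt[, ..samples])
  rownames(counts) <- dt$gene_id
  list(counts = counts,
       lengths = setNames(dt$length_bp, dt$gene_id),
       samples = samples)
}
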