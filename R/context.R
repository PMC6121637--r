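#' Classify the sequence context of a cytosine
#'
#' Determines whether the cytosine at `(chrom, pos, strand)` lies in a CG,
#' CHG or CHH context (H = A, T or C). On the plus strand the two bases
#' downstream of the cytosine are inspected; on the minus strand the two
#' bases upstream on the reference (downstream on the read strand) are
#' inspected after reverse complementation. A site whose required downstream
#' bases fall off the contig end is classified only as far as the available
#' bases permit: a terminal `CG` call needs one base, `CHG`/`CHH` need two;
#' otherwise the site is `"ambiguous"`.
#'
#' @param genome `DNAStringSet` (or named character vector of sequences).
#' @param chrom contig name.
#' @param pos 1-based position.
#' @param strand `"+"` or `"-"`.
#' @return `"CG"`, `"CHG"`, `"CHH"`, `"ambiguous"` (context truncated by the
#'   contig end), or `NA` if the strand base at `pos` is not a cytosine.
#' @seealso [find_cytosines()] for the vectorized genome-wide scan.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  seqs <- as_seq_chars(genome)
  if (!chrom %in% names(seqs)) stop("unknown contig: ", chrom)
  s <- seqs[[chrom]]
  L <- length(s)
  if (pos < 1L || pos > L) stop("position out of range for contig ", chrom)
  if (strand == "+") {
    if (s[pos] != "C") return(NA_character_)
    b1 <- if (pos + 1L <= L) s[pos + 1L] else ""
    b2 <- if (pos + 2L <= L) s[pos + 2L] else ""
    classify_from_next(b1, b2)
  } else if (strand == "-") {
    if (s[pos] != "G") return(NA_character_)
    b1 <- if (pos - 1L >= 1L) comp_base(s[pos - 1L]) else ""
    b2 <- if (pos - 2L >= 1L) comp_base(s[pos - 2L]) else ""
    classify_from_next(b1, b2)
  } else stop("strand must be '+' or '-'")
}

# context from the two bases following the cytosine (read-strand orientation);
# "" marks a base beyond the contig end
classify_from_next <- function(b1, b2) {
  H <- c("A", "T", "C")
  if (b1 == "G") return("CG")
  if (b1 == "") return("ambiguous")
  if (!b1 %in% H) return("ambiguous")   # non-ACGT base
  if (b2 == "G") return("CHG")
  if (b2 == "") return("ambiguous")
  if (!b2 %in% H) return("ambiguous")
  "CHH"
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

as_seq_chars <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- genome
  } else stop("'genome' must be a DNAStringSet or named character vector")
  if (is.null(names(seqs))) stop("'genome' sequences must be named")
  lapply(seqs, function(x) strsplit(x, "", fixed = TRUE)[[1]])
}

#' Scan a genome for all cytosine sites and their contexts
#'
#' Vectorized equivalent of [classify_context()] over every position and both
#' strands. Sites with truncated (ambiguous) context at contig ends are
#' dropped.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @return data.table with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, `trinucleotide` (read-strand orientation), sorted by
#'   `(chrom, pos, strand)`.
#' @export
find_cytosines <- function(genome) {
  seqs <- as_seq_chars(genome)
  out <- lapply(names(seqs), function(chr) {
    s <- seqs[[chr]]
    L <- length(s)
    if (L < 3L) return(NULL)
    # plus strand: s[i] == C, look at i+1, i+2
    ip <- which(s == "C")
    ip <- ip[ip <= L - 1L]
    b1 <- s[ip + 1L]
    ctx_p <- ifelse(b1 == "G", "CG", NA_character_)
    need2 <- which(is.na(ctx_p) & ip <= L - 2L)
    if (length(need2)) {
      b2 <- s[ip[need2] + 2L]
      ctx_p[need2] <- ifelse(b2 == "G", "CHG", "CHH")
    }
    keep_p <- !is.na(ctx_p)
    tri_p <- paste0("C", s[ip + 1L],
                    ifelse(ip + 2L <= L, s[pmin(ip + 2L, L)], ""))
    dtp <- data.table(chrom = chr, pos = ip[keep_p], strand = "+",
                      context = ctx_p[keep_p], trinucleotide = tri_p[keep_p])
    # minus strand: s[i] == G, look at i-1, i-2 (complemented)
    im <- which(s == "G")
    im <- im[im >= 2L]
    c1 <- s[im - 1L]                 # complement "G" on read strand <=> "C" here
    ctx_m <- ifelse(c1 == "C", "CG", NA_character_)
    need2 <- which(is.na(ctx_m) & im >= 3L)
    if (length(need2)) {
      c2 <- s[im[need2] - 2L]
      ctx_m[need2] <- ifelse(c2 == "C", "CHG", "CHH")
    }
    keep_m <- !is.na(ctx_m)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    tri_m <- paste0("C", comp[c1],
                    ifelse(im >= 3L, comp[s[pmax(im - 2L, 1L)]], ""))
    dtm <- data.table(chrom = chr, pos = im[keep_m], strand = "-",
                      context = ctx_m[keep_m], trinucleotide = tri_m[keep_m])
    rbind(dtp, dtm)
  })
  res <- rbindlist(out)
  setorder(res, chrom, pos, strand)
  res[]
}

#' Per-site methylation level
#'
#' The fraction of reads supporting methylation at a cytosine:
#' `meth / (meth + unmeth)`. Sites with zero coverage have no defined level
#' and are returned as `NA` (they must be excluded, not treated as 0).
#'
#' @param meth,unmeth non-negative read counts (vectorized).
#' @return numeric vector of proportions in \[0, 1\], `NA` where coverage is 0.
#' @export
methylation_level <- function(meth, unmeth) {
  if (any(meth < 0 | unmeth < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  n <- meth + unmeth
  ifelse(n > 0, meth / n, NA_real_)
}

#' Correct methylation levels for bisulfite non-conversion
#'
#' Inverts the false-methylation floor introduced by incomplete bisulfite
#' conversion: `(ml - r) / (1 - r)`, clipped to \[0, 1\]. With observed level
#' `ml = mu + (1 - mu) r` for true level `mu`, this recovers `mu` exactly in
#' expectation.
#'
#' @param ml observed methylation level(s) in \[0, 1\].
#' @param r bisulfite non-conversion rate, `0 <= r < 1`.
#' @return corrected level(s), clipped to \[0, 1\]; `NA` passes through.
#' @export
correct_level <- function(ml, r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r >= 1)
    stop("non-conversion rate 'r' must be a single value in [0, 1)")
  pmin(pmax((ml - r) / (1 - r), 0), 1)
}

#' Estimate the bisulfite non-conversion rate from a spike-in control
#'
#' The control contig (an unmethylated spike-in such as lambda DNA) should
#' carry no true methylation, so any read reporting methylation there
#' reflects failed conversion. The rate is the total count of
#' apparently-methylated reads over all reads covering control cytosines,
#' pooled over the supplied samples.
#'
#' @param bs BSCounts object holding control-contig records (e.g. the subset
#'   of a full object, or a dedicated spike-in report).
#' @param control_chrom name of the control contig; records on other contigs
#'   are ignored. Use `NULL` to pool every record in `bs`.
#' @param samples samples to pool; default all.
#' @return object of class `nonconversion_rate`: list with `r`,
#'   `n_reads`, `n_methylated`, `n_sites`.
#' @export
estimate_nonconversion <- function(bs, control_chrom = "lambda_control",
                                   samples = NULL) {
  stopifnot(is(bs, "BSCounts"))
  idx <- if (is.null(control_chrom)) seq_len(nrow(bs$sites))
         else which(bs$sites$chrom == control_chrom)
  if (length(idx) == 0L)
    stop("no control records found", if (!is.null(control_chrom))
      paste0(" on contig '", control_chrom, "'"),
      "; supply 'r' manually to downstream steps")
  j <- if (is.null(samples)) seq_along(bs$samples) else match(samples, bs$samples)
  n_meth <- sum(bs$M[idx, j])
  n_tot <- sum(bs$N[idx, j])
  if (n_tot == 0L) stop("control records carry no reads")
  structure(list(r = n_meth / n_tot, n_reads = n_tot,
                 n_methylated = n_meth, n_sites = length(idx)),
            class = "nonconversion_rate")
}

#' @export
print.nonconversion_rate <- function(x, ...) {
  cat(sprintf("non-conversion rate r = %.5f (%d / %d reads over %d control sites)\n",
              x$r, x$n_methylated, x$n_reads, x$n_sites))
  invisible(x)
}
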