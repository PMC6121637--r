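# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small planted fixture: 0.2 Mb, 20 genes, 9 DMRs (all three contexts,
# alternating sign), used by most module tests
small_config <- function(seed = 7) {
  sim_config(genome_length = 2e5, n_chromosomes = 1L, n_genes = 20L,
             n_tes = 20L, n_dmrs = 9L, seed = seed)
}

small_fixture <- function() {
  cached("small_fix", suppressWarnings(simulate_fixture(small_config())))
}

small_dml <- function() {
  cached("small_dml", dml_test(small_fixture()$bs))
}

small_dmrs <- function() {
  cached("small_dmrs", call_dmrs(small_dml()))
}

# hand-rolled BSCounts builder for toy cases
toy_bs <- function(pos, M, N, context = "CG", chrom = "chr1", strand = "+",
                   samples = NULL, condition = NULL) {
  M <- as.matrix(M); N <- as.matrix(N)
  ns <- ncol(M)
  if (is.null(samples)) samples <- paste0("S", seq_len(ns))
  if (is.null(condition))
    condition <- rep(c("WT", "RT"), each = ceiling(ns / 2))[seq_len(ns)]
  sites <- data.table::data.table(
    chrom = rep(chrom, length(pos))[seq_along(pos)],
    pos = as.integer(pos),
    strand = rep(strand, length.out = length(pos)),
    context = rep(context, length.out = length(pos)))
  bs_counts(sites, M, N, samples, condition)
}

# beta-binomial sampler used as an independent data source in tests
rbetabinom <- function(n, size, mu, phi) {
  if (phi <= 0) return(rbinom(n, size, mu))
  s <- (1 - phi) / phi
  p <- rbeta(n, mu * s, (1 - mu) * s)
  rbinom(n, size, p)
}
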