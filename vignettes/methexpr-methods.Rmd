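---
title: "Methods: differential methylation and methylome-transcriptome integration in methexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and methylome-transcriptome integration in methexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

methexpr analyzes a replicated two-condition whole-genome bisulfite
sequencing (WGBS) experiment together with matched RNA-seq counts. The
motivating design is a bicolored-petal study: white (WT) and red (RT) petal
tissue from one ornamental tree, three biological replicates each, with an
unmethylated lambda spike-in for conversion control. This vignette explains
the models behind each stage, the defaults and why they were chosen, what
the synthetic-data generator does and does not emulate, and the numerical
decisions a careful reader will want to know.

## Methylation levels, contexts, and non-conversion correction

A cytosine's methylation level is the fraction of reads supporting
methylation, `ML = m / (m + u)`; a site with zero coverage has no level and
is excluded (never imputed as zero). Contexts are the plant-standard CG,
CHG, CHH classes (H = A, T or C), classified strand-aware from the
reference: on the minus strand the two reference bases *upstream* are
reverse-complemented before applying the same rules. At contig ends a CG
call needs one downstream base and CHG/CHH need two; anything shorter is
flagged ambiguous rather than guessed.

Incomplete bisulfite conversion makes a fraction `r` of truly unmethylated
cytosines appear methylated. We estimate `r` from the spike-in contig as
pooled apparently-methylated reads over all control reads, and invert the
mixing with `ML_corr = (ML - r) / (1 - r)`, clipped to [0, 1]. Under the
generator's mixing model `ML_obs = mu + (1 - mu) r` the correction is exact
in expectation except at `mu = 0`, where clipping leaves a small positive
bias (about 0.004 at `r = 0.005`, depth 30 -- the price of keeping levels
in [0, 1]).

Genome-wide context summaries (`summarize_contexts()`) count covered sites
and sites called methylated per sample and context. The methylated-site
caller is a one-sided binomial test of the methylated count against
`Binomial(n, r)`, BH-corrected within context at q < 0.01: the published
tables this layout mirrors never state their caller, so ours is the
standard WGBS choice and is exposed. The summary arithmetic itself
(ratios, condition averages, context shares of methylated sites) is kept
exact; note that the published reference table we bundle as a worked
example truncates per-sample percentages at two decimals and averages the
truncated values, which the acceptance checks reproduce explicitly.

## Feature model and metagene profiles

Genes are TSS-to-TES bodies with exons; promoters are the 2-kb window
upstream of the TSS (strand-aware), and `up2k`/`down2k` are the 2-kb
flanks. Labels deliberately overlap -- a promoter may lie inside a
neighbor's body and a position carries every label covering it -- because
de-overlapping rules would be an invention with no basis in the designs
this package mirrors. A TE is *intragenic* when it overlaps any gene body
by at least one base. *Intergenic* means covered by no body or flank.

Metagene profiles use 50 bins per region: fixed 40-bp bins across each
2-kb flank and fractional (length-normalized) bins across the body, with
bin 1 of the body at the TSS and flank bins oriented by strand. Site
levels are pooled across the selected samples (summed counts), averaged
within each gene's bin, then averaged across genes -- genes are weighted
equally so a 20-kb gene cannot dominate a 1-kb one. Genes shorter than the
bin count simply leave some bins empty and are noted.

Expression groups follow the quartile convention: `no` below FPKM 1, then
`low`/`medium`/`high` split at the 25th and 75th FPKM percentiles of
*expressed* genes (the "low" class starts at 1, so unexpressed genes are
not part of the percentile population; published thresholds well above 1
are consistent only with this reading). The interpolation rule is exposed
(`quantile_type`, default 7 -- linear interpolation); inverse-ECDF
percentiles (type 1) are supported and reproduce the alternative worked
grouping. Methylation quintiles split gene-level region methylation at the
20/40/60/80th percentiles, with group 5 inclusive of its boundary; genes
lacking any site of a context in the region (common for CHH in promoters)
are excluded and counted.

## Differential methylation

The caller is a from-scratch implementation of the beta-binomial
replicate model familiar from DSS-style analyses; it does not aim for
numerical parity with any existing tool.

**Dispersion.** For replicate counts `m_r / n_r` with mean level `p`, the
replicate variance satisfies
`E[s^2] = p (1 - p) * mean((1 + (n_r - 1) phi) / n_r)`, which is solved
for the site-wise method-of-moments estimate of the overdispersion `phi`.
At three replicates this estimate is extremely noisy, so it is shrunk
toward a context-wide target with weight `(R - 1) / (R + 3)` on the site.
The target is the context **mean of the untruncated** site estimates: the
estimate distribution is right-skewed, and either truncating negatives
before averaging or taking the median biases the target to roughly half
the true value, which measurably inflates the null test (type-I error
0.07-0.08 instead of 0.05). Keeping negative estimates in the average
makes the target unbiased; the final per-site value is floored at 1e-4.

**Smoothing and the Wald statistic.** Condition means are depth-weighted
moving averages of replicate-mean levels over a 500-bp window, computed
separately per context (baselines differ by context, so cross-context
smoothing would bias means). The variance of the smoothed mean combines
the per-site beta-binomial variance
`mu (1 - mu)(1 + (n_r - 1) phi) / n_r / R^2` with the squared smoothing
weights; with the window set to 0 the statistic reduces exactly to the
plain per-site Wald test. Sites uncovered in either condition are skipped
and counted. Two-sided normal p-values are BH-adjusted within context for
reporting; region calling uses the unadjusted p-values (region-level
filters provide the error control, and this is stated rather than hidden).

**Region merging.** Significant sites (p < 1e-5) of the same context and
sign within 100 bp of each other merge into candidates. Smoothing smears
significance up to a few hundred bp past a true boundary, so each
candidate is trimmed to the span of its sites with *unsmoothed* per-site
support (raw p < 0.05, concordant sign); without this step short regions
fail interval-overlap checks even when detection is certain. Regions pass
at >= 50 bp, >= 3 significant sites, and >= 50% significant among covered
sites. `hyper` means more methylated in the first (reference) condition;
published two-condition comparisons often leave their reference
unstated, so the convention is explicit and configurable here. The
defaults (window 500 bp, p 1e-5, min length 50, min sites 3, gap 100,
50% significant) are the conventions of the tool family this stage
mirrors, not values fitted to any dataset.

**DMR-related genes.** A gene is DMR-related when its body or promoter
overlaps a DMR by at least one base -- the published definition specifies
no minimum overlap, so none is imposed.

## Differential expression

FPKM is `counts * 1e9 / (length * library_size)` with exon-union gene
lengths and column-sum library sizes (overridable). "Expressed" means
replicate-mean FPKM >= 1 in a condition; genes expressed in exactly one
condition are that condition's specific set.

The DEG test is a deliberately minimal NB two-group test: median-of-ratios
size factors; gene-wise method-of-moments dispersion computed from
*within-condition* normalized-count variance (the condition effect must
not leak into the dispersion); shrinkage with weight 0.25 toward a
parametric trend `alpha(mu) = a0 + a1 / mu` fitted across genes; and a
Wald statistic on the difference of log condition means with delta-method
variance. The reference distribution is a moderated t whose total degrees
of freedom are `d_res / shrink_weight` (16 at 3 vs 3): the shrink weight
`w = d_res / (d_res + d_prior)` implies a prior df, exactly as in
moderated-statistics practice. A plain normal reference is measurably
anticonservative in the far tail at three replicates (mixed-simulation
FDR ~0.10 at BH 0.05 versus ~0.03 with the moderated reference, at equal
~0.93 power). `up` means higher in the first condition, BH-adjusted
p < 0.05.

## Integration

Level 1 correlates per-gene region methylation (depth-weighted mean of
site levels, i.e. pooled counts -- the aggregation is stated because
published analyses usually leave it implicit) with log expression,
stratified by region and context; Pearson r with the exact t-transform
p-value on n - 2 df, no cross-stratum correction. Level 2 profiles DEG
classes (`all` = union of up and down) per condition through the metagene
machinery. Level 3 pairs each DMR-related gene's methylation difference
with its expression fold change and labels concordance under the
negative-coupling expectation (hyper & down, or hypo & up) -- a label,
never a filter. Level 4 cross-classifies hyper/hypo DMR-related genes
against up/down DEGs per region and context (genes hit by both hyper- and
hypo-DMRs count in both classes, and are also reported separately), and
associates DMRs, TEs and DEGs: one triple per (gene, TE, DMR) with the TE
inside the gene's body +/- 2 kb and the DMR overlapping that TE.

Two analysis definitions deserve emphasis. First, correlations against
log fold change are computed over genes expressed in both conditions: the
fold change of a gene with essentially no counts on one side is a
boundary artifact with enormous magnitude and no methylation content, and
a handful of such genes otherwise dominates the correlation variance.
Second, the coupling-recovery check asks what fraction of planted coupled
genes *recovered by both detectors* (promoter DMR found, DEG called) land
in the concordant cells -- including detector misses in the denominator
would measure detector power, which is checked separately, not
integration correctness.

## The synthetic-data generator

`sim_config()` defaults are the emulated study conditions: 2.4 Mb over
two chromosomes, 300 genes (1-2.5 kb bodies, 1-3 exons, >= 2 kb from
edges so flanks always exist), 200 TEs (60% class I), two conditions x
three replicates, Poisson depth 30 (the reported coverage scale),
context baselines CG 0.380 / CHG 0.204 / CHH 0.092 (the genome-average
context ratios of the motivating experiment), beta-binomial replicate
dispersion 0.05 per context (replicate dispersion is never stated for the
real data; 0.05 is a realistic same-tree value and is exposed),
non-conversion rate 0.005 (conversion > 99%), 60 planted DMRs of
200-1000 bp alternating +0.4/-0.4 effects across rotating contexts and
placed 40/30/20/10% in promoters/bodies/TEs/intergenic space, and
expression coupling slope -2 (natural-log fold change per unit promoter
methylation difference). Expression counts are NB with dispersion 0.05,
gene means scaled to a 2-million-fragment library so FPKM thresholds
behave as in real data; 10% of genes are silent and 3% + 3%
condition-specific. Effects that would push a mean outside [0, 1] are
clipped with a warning and the truth table records the realized
difference -- a planted "-0.4" on a 0.092 baseline is really -0.092, and
recovery statistics are computed against realized effects.

What the generator does **not** emulate, and what passing tests therefore
do not establish about real data: per-site levels are unimodal around the
context baseline, whereas real methylomes are strongly bimodal (most CG
sites near 0 or 1) -- the generator reproduces marginal means, ratios and
differences, not the shape of the per-site level distribution, so the
level-histogram machinery is exercised for correctness, not realism.
There is no read-level simulation: no sequencing error, no M-bias, no
PCR duplicates, no mapping bias; spatial methylation correlation within a
region is a step function (constant inside a planted DMR), flattering the
smoother relative to real autocorrelation structure; and TE placement is
uniform rather than clustered in pericentromeric space.

## Problem sizes and numerical choices

The test suite exercises: a 0.2-Mb planted fixture shared across modules;
null calibration on ten 1-Mb genomes (about 500,000 cytosines each, all
three contexts); planted-region recovery on the full 2.4-Mb fixture with
90 regions of at least 8 target-context cytosines; a 10,000-gene DEG
simulation with 1,000 planted four-fold changes; and the integration
fixture with 54 planted promoter DMRs. These sizes make every stochastic
check stable at fixed seeds while the whole suite stays fast.

Ties and degenerate inputs: a site with zero variance and zero difference
scores a Wald statistic of 0 (p = 1), complete separation scores infinite
(p = 0); all-zero genes are `ns` with p = 1; a degenerate methylation
distribution collapses to a single quintile with a warning; constant
vectors yield a missing correlation, not an error. Dispersions are floored
at 1e-4 (beta-binomial) and 1e-8 (NB). All interval work is 1-based
closed internally for cytosine reports (the report dialect) and 0-based
half-open in emitted DMR tables, and both conventions are stated in the
relevant docs.

## Known limitations

The DMR caller's variance model assumes sites are independent within the
smoothing window given the regional mean; real data violate this and the
test is then somewhat anticonservative at region edges. The moderated-df
choice for the DEG test is calibrated for the 3 vs 3 design family, not
asymptotically derived. Correlation p-values across many strata are not
corrected for multiplicity, matching the descriptive use they serve.
Dataset-scale results of the motivating experiment (tens of thousands of
DMRs, specific gene identities) depend on its deposited raw data and are
out of scope; the synthetic recovery properties above are the package's
evidence of correctness.
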