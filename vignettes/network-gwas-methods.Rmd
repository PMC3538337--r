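---
title: "Methods: coexpression-network analysis of GWAS gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coexpression-network analysis of GWAS gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gwasnet turns a table of SNP-level association P-values into a weighted
gene coexpression network over the nominally associated genes and asks
three questions of that network: which biological gene sets concentrate in
which modules, which modules relate to the clinical phenotype, and whether
network position (hubness) predicts replication in an independent GWAS
better than the association P-value itself. This vignette explains the
models behind each stage, the tunable parameters, the synthetic data the
package is validated on, and the limits of both.

## From SNPs to gene-wide P-values

GWAS P-values attach to SNPs, not genes, and two confounders make the
naive "best SNP per gene" score misleading: linkage disequilibrium (LD)
spreads one association across many SNPs and genes, and long or densely
typed genes harbor small minimum P-values by chance alone.

`clusterSnpsByLd()` groups SNPs into *proxy clusters*: connected
components of the graph whose edges are SNP pairs with r² ≥ 0.80 (the
`r2_threshold` argument). A cluster behaves as one association unit and is
anchored at its minimum-P SNP. `assignClustersToGenes()` assigns each
cluster to the gene whose interval — extended 1 kbp on the strand-aware
upstream side to cover promoters (`upstream_ext`) — contains the anchor,
or failing that to the nearest gene on the chromosome. Equidistant ties go
to the gene with the smaller start coordinate, then lexicographic id, so
runs are reproducible. `genePvalues()` then scores each gene:

* unadjusted P = the minimum SNP P over all clusters and singletons
  assigned to the gene;
* adjusted P = unadjusted P × number of SNPs assigned, capped at 1.

The multiplier is the SNP count, not the cluster count; a
`multiplier = "clusters"` switch provides the more conservative Bonferroni
unit for comparison. Genes with adjusted P ≤ 0.05 in at least one trait
form the *nominally significant GWAS gene set* (NSGG,
`selectNsgg()`).

`biasDiagnostics()` quantifies the confounding and its removal: Pearson
correlations of −log10 P against gene length and SNP density, over all
scored genes. The −log10 scale is where the minimum-P artifact is linear.
Restricting the correlation to genes already passing a significance cutoff
(available as `scope = "significant"`) largely erases the gradient — the
conditional distribution of an exponential-tailed minimum above a
threshold barely depends on the number of draws — so the default reports
the full-table correlations, where the unadjusted score shows a strong
positive length correlation and the adjusted score shows none.

## Expression preparation

`filterExpressed()` keeps candidate-gene probes whose mean expression
exceeds the median of all row means of the array — the usual
"expressed above the array median" rule. The array median is fixed at the
first pass and carried in the object's metadata, making the filter
idempotent. `detectOutlierSamples()` standardizes each sample's mean
correlation with all other samples and flags scores below −`z_cut`
(default 2.5); removal is a separate, auditable call
(`removeSamples()`). The published analysis identified outliers by
clustering and PCA inspection; the standardized mean inter-sample
correlation is a deterministic surrogate for that judgment.
`selectProbePerGene()` resolves multi-probe genes by keeping the probe
with the highest preliminary soft-thresholded connectivity, using the
same power β as the final network.

## The weighted coexpression network

For genes *i*, *j* with expression profiles *x*ᵢ, *x*ⱼ, the unsigned
adjacency is

  *a*ᵢⱼ = |cor(*x*ᵢ, *x*ⱼ)|^β,

with zero diagonal. The topological overlap measure (TOM)

  TOMᵢⱼ = (Σᵤ *a*ᵢᵤ*a*ᵤⱼ + *a*ᵢⱼ) / (min(*k*ᵢ, *k*ⱼ) + 1 − *a*ᵢⱼ)

rewards genes that connect to the same neighbours; modules are found by
average-linkage hierarchical clustering on 1 − TOM with a static branch
cut at `cut_height` (default 0.99), merging clusters smaller than
`min_module_size` (default 30) into "grey". Surviving modules get color
labels by descending size (turquoise, blue, brown, ...), so module names
are stable across runs. This is a deterministic simplification of Dynamic
Tree Cut; to compensate for the static cut's tendency to sweep weakly
attached genes into large branches, `buildNetwork()` finishes with the
standard eigengene-membership cleanup: genes whose |kME| (correlation with
their module's eigengene) is below `mm_min` (default 0.5) are moved to
grey. Set `mm_min = 0` for the raw static cut.

The soft power β defaults to 6, a standard choice for unsigned networks at
a few dozen samples. `pickSoftThreshold()` implements the scale-free
criterion — the smallest β whose log-log regression of the binned
connectivity distribution reaches R² ≥ 0.8 with negative slope, with a
declared fallback otherwise — and `beta = "auto"` uses it, but note two
small-sample caveats: null data can satisfy the criterion at large powers,
and strongly blocked synthetic data is bimodal in connectivity rather than
scale-free, so the automatic choice wanders. At these problem sizes every
moderate power recovers the planted partitions; the fixed default is the
reproducible choice.

Each module is summarized by its eigengene (`moduleEigengenes()`): the
first right singular vector of the row-standardized module submatrix,
oriented so it correlates non-negatively with the module's mean profile,
with the explained variance share reported.

## Module metrics

`computeGeneStats()` produces, per gene: module membership MM =
cor(*x*ᵢ, eigengene of its module); signed gene significance =
cor(*x*ᵢ, phenotype) with GS its absolute value; total connectivity
*k.total* = Σⱼ *a*ᵢⱼ and intramodular connectivity *k.in* (the same sum
restricted to the gene's module); and the within-module k.in rank.
`moduleCohesiveness()` reports mean MM ± SEM per module;
`halfSplitRobustness()` probes module stability by repeatedly splitting
samples in half and correlating the two half-derived k.in vectors (the
"real versus half" variant is available via `mode`); an odd sample goes to
half 1. `mmGsCorrelation()` tests, per module, whether MM predicts GS,
with Bonferroni significance at 0.05 divided by the number of modules
tested — exactly 0.05/n rather than a rounded threshold.

## Enrichment and permutation nulls

`fisherEnrichment()` tests a gene set's concentration in a module with a
one-sided (greater) Fisher's exact test. Published module enrichments are
sometimes quoted with the module left inside the background margins, so
both 2×2 constructions are returned: `fisher_p` for the disjoint table and
`fisher_p_overlap` for the overlapping one. On the oxidative-
phosphorylation counts from the osteoporosis monocyte study (16 of 356
module genes versus 114 of 20,080 array genes, i.e. 4.5% vs 0.6%) the
overlapping construction gives 1.3 × 10⁻⁹ and the disjoint one
1.8 × 10⁻¹⁰, bracketing the reported 1.8 × 10⁻⁹.

Two permutation nulls calibrate observed enrichments.
`randomNetworkSpecificity()` rebuilds networks from random gene draws of
the same size, with the same filtering and network parameters (the fixed
β is reused rather than re-fitted), and reports the fraction of random
modules at least as enriched. `submoduleMeanCorrelationTest()` draws
random same-size gene sets from within a module and compares their mean
signed GS with the observed submodule's. Both use the +1-corrected
empirical P, (1 + hits)/(1 + draws), which can never report zero.
`extractSubmodule()` exports TOM-thresholded subgraphs (optionally the ego
network of one anchor gene) as SIF plus node attributes for external
viewers.

## Replication by network position

`replicationRates()` compares three ways of nominating genes for
replication in a second GWAS: intramodular connectivity (k.in, ranked
within each chosen module and pooled across them; a pooled-global
alternative via `kin_mode`), gene significance, and the discovery
adjusted P-value. A nominated gene replicates if its *unadjusted*
gene-wide P in the replication study is at or below the level for any
replication trait — unadjusted deliberately, matching how replication
was declared in the source analysis. Ties in every ranking break by
(metric, smaller discovery adjusted P, gene id), so the rate table is
deterministic.

## The synthetic bundle

`simulateBundle()` generates every input the pipeline needs with the
statistical couplings the analysis assumes; the defaults are a fixed,
desk-scale emulation of the osteoporosis study design (a two-trait
hip/spine BMD discovery GWAS, 24 monocyte arrays split 12 low / 12 high
BMD, a three-trait replication GWAS), at roughly 1/20 scale: 900 genes on 3
chromosomes, 600 true association genes, three planted modules of
80/60/50 genes, module 1 phenotype-coupled at c = 0.6.

*Expression.* x₍gs₎ = μ_g + λ_g f₍m(g),s₎ + ε₍gs₎. Loadings λ_g are
U(0.4, 1.3) and noise has sd 0.55, calibrated so per-module mean MM falls
in the 0.60–0.75 band reported for real monocyte modules (tighter
loadings make modules implausibly uniform and leave the MM–GS correlation
unidentified). For a coupled module, f = c·z + √(1−c²)·η with z the
standardized binary phenotype and η orthogonalized against z in-sample,
so the realized factor-phenotype correlation equals c exactly; c = 0
means a fully independent factor. Baselines μ_g put module genes and true
genes in the expressed (high) mode and background genes in a lower mode,
so the array-median filter behaves as it does on real arrays.

*GWAS.* Gene lengths are U(5, 60) kbp; SNP counts scale with length
(range 2–12); LD blocks span a roughly constant genomic scale, so block
count also scales with length. Association Z-scores are drawn per block
and trait — mean `true_gene_effect` (default 3) for planted genes, 0
otherwise — with correlation `trait_cor` (default 0.7) across traits of
one study, since skeletal-site BMD measures are strongly correlated;
SNP-level Z-scores share their block score with correlation √r², and
P-values are two-sided so null SNPs are exactly Uniform(0,1). LD records
are emitted directly as pairwise r² (exactly `within_block_r2` = 0.9
within blocks, < 0.5 between adjacent blocks) rather than simulated from
genotypes: the analysis consumes only r². The replication GWAS re-plants
the effect in a `replication_signal_share` (0.6) of module-member true
genes only — module co-membership, not the discovery P-value, carries the
replication signal — which is the generative premise behind the
hub-versus-P-value comparison.

*Truth and auxiliary files.* The bundle carries per-gene truth labels
(true association, module, pathway membership, replication planting), a
GMT with a planted pathway (16 genes inside the target module plus 14
scattered) and three decoy sets, and writes the PLINK-style `.ld`, BED6,
TSV and GMT files the readers consume. One `set.seed` at entry drives all
sub-generators in a fixed order, so a seed plus a config is a complete
specification of the bundle.

What the generator does *not* emulate: genotypes or coalescent LD (r² is
asserted, not estimated), probe-level microarray artifacts and
normalization, correlated noise between modules, effect-size
heterogeneity across true genes, and any annotation error in SNP-to-gene
truth. Passing tests therefore show that the pipeline recovers structure
it is pointed at under clean factor-model and block-LD assumptions — not
that it is robust to normalization artifacts or mis-annotation in real
data.

## Validation problem sizes and expectations

The test suite and `scripts/acceptance.R` run the whole pipeline on the
default bundle over 10 seeds (~370 network genes per run) and check that:
module detection recovers the planted partition with mean adjusted Rand
index ≥ 0.8; the coupled module has the largest MM–GS correlation and the
planted pathway's best enrichment lands in its planted module in ≥ 9/10
seeds; and k.in-based selection replicates at least as well as P-value
selection at the top-5% cut in ≥ 8/10 seeds (observed means: roughly 64%
vs 49% at α = 0.05). The length-bias experiment uses 1000 genes with SNP
counts 1–40 over 5 seeds: unadjusted −log10 P correlates with length at
r ≈ 0.3 while the adjusted correlation sits within ±0.05 of zero. Exact
oracle checks (brute-force adjacency, TOM, eigengene and hypergeometric
enumeration) run on random instances of up to 20 genes at tolerances of
1e−10 to 1e−12.

## Known limitations

* The static branch cut plus kME cleanup approximates, but is not,
  Dynamic Tree Cut; deeply nested modules will not be split.
* Pearson correlation throughout; no robust (bicor) option.
* The scale-free criterion is unreliable at 24 samples (see above); the
  pipeline default is a fixed β.
* No blockwise TOM: memory is quadratic in gene count, comfortable to a
  few thousand genes.
* Empirical P-values inherit the resolution of their draw counts; the
  +1 correction makes them conservative at small `n_perm`.
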