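---
title: "Methylation-weighted pathway analysis of GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-weighted pathway analysis of GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmpath)
```

## The problem and the model

Single-marker genome-wide association scans of complex psychiatric traits
rarely yield replicable loci, because risk is spread over many variants of
small effect. Gene-set (pathway) analysis aggregates association signal
over genes that share a biological function. `asmpath` implements a
pathway analysis of GWAS *summary statistics* that additionally
incorporates allele-specific methylation (ASM): a curated list of SNP–CpG
pairs in which a SNP's alleles are associated with the methylation level
of a CpG site, either in *cis* (SNP within 1 Mb of the CpG) or in *trans*.
SNPs that regulate methylation are plausibly functional even when they are
not the most significant marker in a gene, and the method up-weights the
part of a pathway whose genes carry such regulatory variants when that
part is carrying more of the association signal.

The pipeline has four stages.

**1. Gene scores.** Every SNP is assigned to each gene whose region
(±5 kb of the gene ends, boundaries inclusive) contains it; a SNP may
belong to several overlapping genes, and genes without mapped SNPs are
excluded. Mapped genes are partitioned into an **ASM set** — genes that
contain an ASM-list SNP, or that contain a CpG site regulated by an
ASM-list SNP (the pair's target gene) — and a **non-ASM set**. The
gene-level p-value is the *min-p*: for ASM genes the smallest p-value
among their ASM-list SNPs, for non-ASM genes the smallest over all their
SNPs. Because min-p favors SNP-rich genes, it is normalized by
resampling: the null for a gene with $k$ SNPs is $B$ minima of $k$
p-values drawn without replacement from the pool of all analyzed SNP
p-values ($B = 10{,}000$ by default), and the adjusted p-value is the
add-one tail rank $(1 + r)/(1 + B)$. The gene score is the 1-df
chi-square value at that upper-tail probability, so scores are on a common
$\chi^2_1$ scale regardless of gene size.

**2. ASM weights.** A gene is *informative* when its fraction of SNPs
with $p < 0.05$ strictly exceeds the genome-wide fraction (about 10–11%
in the real bipolar-disorder cohorts this method was designed around).
For one pathway let $n, m$ be the ASM / non-ASM gene counts on its mapped
list and $k_n, k_m$ the informative counts, with proportions
$R_n = k_n/n$, $R_m = k_m/m$ and harmonic average
$H = 2/(1/R_n + 1/R_m)$. The weights are

* $w_\text{ASM} = R_n/H$, $w_\text{non-ASM} = R_m/H$ when $R_n > R_m$
  (so $w_\text{ASM} \ge 1 \ge w_\text{non-ASM}$);
* an integer weight 1–6 for the ASM set, binned on $R_n$ at cutoffs
  0.1, 0.3, 0.5, 0.7, 0.9, when the non-ASM set has no informative genes;
* equal weights (1, 1) otherwise.

Weights multiply the member genes' scores before the set statistics are
computed; the unweighted mode is the identity, so "with vs without
weighting" is a continuous contrast.

**3. Set statistics and permutation p-values.** Three statistics are
computed per pathway: a GSEA-style enrichment score (maximum of a running
sum over the genome-wide score ranking that rises by
$\text{score}/N_R$ at members and falls by $1/(N - N_H)$ at
non-members — a competitive test), and the sum and sum-of-squares of the
member scores (self-contained tests). Empirical p-values come from
permutations that jointly shuffle the per-gene (score, informative-flag)
tuples across all mapped genes while pathway membership and per-gene ASM
labels stay fixed; weights are recomputed inside every permutation so the
weighting step is part of the null. The add-one estimator
$(1 + r)/(1 + B)$ is used with $B = 5{,}000$ by default. Pathways with
fewer than 10 or more than 380 mapped genes are removed before testing,
and Benjamini–Hochberg adjustment is applied per statistic and mode, with
FDR < 0.01 declared significant.

**4. Follow-up.** Genes of enriched non-GO pathways are tested for GO-term
over-representation with a one-sided hypergeometric test over the
mapped-gene universe (top 50 terms at raw $p < 0.05$; exploratory, no
multiplicity correction), and an over-represented-gene report lists genes
occurring in more than 20% of the enriched pathways that have at least one
SNP with $p < 0.05$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_bp` | 5,000 | bp added to both gene ends for SNP mapping (inclusive) |
| `cis_alpha`, `trans_alpha` | 0.05 | strict selection thresholds for ASM pairs |
| `snp_alpha` | 0.05 | per-SNP significance for informative/over-representation rules |
| `score_perms` | 10,000 | resamples for the gene-size adjustment |
| `pathway_perms` | 5,000 | label permutations per pathway analysis |
| `min_size`, `max_size` | 10, 380 | mapped-size filter for pathways |
| `fdr_threshold` | 0.01 | BH significance cutoff |
| `gene_stat` | `"adjusted"` | gene statistic; `"raw_chisq"` uses the unadjusted min-p chi-square |

## Design choices where the design was open

* **Cis boundary.** "Within 1 Mb" is read inclusively
  ($|d| \le 1{,}000{,}000$).
* **Coordinates.** External BED is 0-based half-open; everything internal
  is 1-based inclusive, converted once at ingestion.
* **Missing p-values** are dropped with logged counts, never imputed:
  min-p statistics tolerate row removal, silent coercion corrupts them.
* **Size adjustment.** With only summary statistics, phenotype
  permutation is impossible; the gene-size normalization resamples SNP
  p-values from the genome-wide pool, ignoring LD. A gene whose min-p is
  itself a null draw then has an approximately uniform adjusted p-value
  (verified by a calibration test, KS < 0.05).
* **CpG-target-only ASM genes** have no in-gene ASM SNP, so the ASM
  min-p rule is undefined for them; they fall back to the minimum over
  all their SNPs, and the membership route is recorded per gene so the
  choice is auditable.
* **Informative** means *strictly* greater than the genome-wide
  proportion; a gene exactly at the average is not informative.
* **Bin boundaries** for the 1–6 weight are left-closed on the printed
  cutoffs, which makes weight 6 reachable at proportion 1.
* **Degenerate pathways** (entirely ASM or entirely non-ASM) get equal
  weights — there is no contrast to weight — and are flagged
  `degenerate_equal`. $k_n = 0$ never counts as "greater", avoiding a
  division by zero in $H$.
* **Permutation scheme.** Shuffling (score, informative) tuples across
  genes keeps the score distribution fixed, makes the GSEA statistic
  competitive and gives the sum statistics a genomic-background null;
  weights are recomputed per permutation so an unusually informative ASM
  subset cannot manufacture significance by itself.
* **Ranking ties** (identical scores are common because adjusted
  p-values are granular at $1/(B+1)$) break by gene id, making every
  result bit-reproducible.
* **GO universe.** The hypergeometric follow-up uses the mapped genes as
  universe, replacing the external annotation web service, so results are
  reproducible offline.

## The synthetic-study generator

Real inputs for this method are controlled-access GWA datasets, so the
package ships a generator whose defaults emulate their scale: 15,000
genes averaging 13 SNPs each (~195k autosomal SNPs), 13% ASM genes, 4,000
pathways of 10–380 genes, and a background fraction of significant SNPs
of 0.11 (null p-values are uniform, i.e. a 0.05 fraction; a spiked
fraction of SNPs lifts it to the target, emulating polygenic background).
Null SNP p-values are i.i.d. uniform; an enriched pathway gives each
member gene one SNP whose statistic is drawn from a noncentral
$\chi^2_1$ with configurable noncentrality, and within ASM genes that SNP
is an ASM SNP with probability `asm_concentration`, so the ASM weighting
route is exercised end to end. ASM genes receive cis pairs to their own
CpGs, about 10% are members only through a trans CpG-target pair, and a
few decoy pairs above the 0.05 threshold exercise the filter. A single
master seed drives fixed per-component streams; the same seed reproduces
the bundle bit for bit.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (the method itself never models LD), genotype-level data, realistic
gene-length/SNP-density correlation beyond the geometric SNP-count
distribution, and overlapping genes (synthetic genes are spaced so no SNP
maps twice — multi-mapping is covered by unit tests instead). A green
calibration test therefore establishes correct behavior under an
idealized independent-SNP null, not robustness to LD.

Scaled-down tests use 2,000 genes, ~20,000 SNPs, 60 pathways of 10–50
genes, 500 pathway permutations and 500 score resamples, which keeps the
full suite inside a desktop-minutes budget; the defaults stay at the
full emulated scale.

## Worked example

```{r example, eval = FALSE}
library(asmpath)

cfg <- synthetic_study_config(
  n_genes = 2000, snps_per_gene = c(min = 1, max = 60, mean = 10),
  gene_length_bp = c(2000, 20000), n_pathways = 60, pathway_size = c(10, 50),
  enriched_pathways = lapply(c(5, 20, 40), function(i)
    list(index = i, noncentrality = 8, asm_concentration = 0.9)),
  background_alpha_fraction = 0.05, seed = 1)
study <- generate_study(cfg)

gene_table <- score_genes(study$snps, study$genes,
                          filter_asm_pairs(study$asm_pairs),
                          score_perms = 500, seed = 2)
results <- pathway_analysis(gene_table, study$pathways, B = 3000, seed = 3)
significant_pathways(results, fdr_threshold = 0.01)
```

The empirical-p floor interacts with BH across pathways: with `P`
pathways and `k` of them at the permutation floor, the smallest
attainable adjusted p is `P / (k (B + 1))`, so `B` must be large enough
for the FDR threshold to be reachable at all (the README's worked
example uses `B = 3000` for 60 pathways at FDR 0.01).

## Known limitations

* Weighting does not uniformly lower empirical p-values, even when the
  signal is concentrated in ASM genes: the permutation null recomputes
  weights from shuffled informative flags, and occasional large binned
  weights fatten the weighted null tail — most visibly for the
  sum-square statistic, whose squaring amplifies them. The sum-statistic
  benefits most reliably from weighting; reporting both modes side by
  side (the default) is the intended usage.
* LD is ignored both in the size adjustment and in the permutation null;
  with real data, correlated SNPs make gene scores locally dependent and
  the self-contained tests anti-conservative.
* The min-p statistic discards all but one SNP per gene.
* Empirical p-values are bounded below by $1/(B+1)$; BH adjustment of
  many tied floor values is coarse at small $B$.
* Results inherit the completeness and curation quality of the supplied
  gene-set database.
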