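---
title: "Non-additive genome scans in pedigreed populations: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-additive genome scans in pedigreed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pedscan implements a single-SNP mixed linear model genome scan for
additive, dominance and pairwise additive-by-additive effects on
quantitative traits in pedigreed livestock populations with repeated
records, together with the surrounding machinery a complete analysis
needs: pedigree-based relationship matrices, allele-frequency-corrected
genotype codings, REML variance components, a closed-form false discovery
rate for scan thresholds, cross-population validation, and a conditional
re-test that exposes interaction signals manufactured by linkage
disequilibrium (LD). A synthetic-data generator with a truth ledger makes
every stage testable without access to proprietary cattle data.

## The model

Each scan fits, one SNP (or SNP pair) at a time,

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{X}\mathbf{b} + \mathbf{Z}\mathbf{u}
 + \mathbf{W}\mathbf{pe} + \mathbf{e},$$

where $\mathbf{y}$ holds pre-corrected repeated records,
$\mathbf{u} \sim N(0, \mathbf{A}\sigma_g^2)$ is the polygenic effect with
$\mathbf{A}$ the pedigree numerator relationship matrix,
$\mathbf{pe} \sim N(0, \mathbf{I}\sigma_{pe}^2)$ is a permanent-environment
effect absorbing the covariance among a cow's repeated records, and
$\mathbf{e} \sim N(0, \mathbf{I}\sigma_e^2)$. $\mathbf{Z}$ and $\mathbf{W}$
both allocate records to animals. The content of $\mathbf{Xb}$ depends on
the variant tested:

* additive: $x_{a}a_j$;
* dominance: $x_{a}a_j + x_{d}d_j$, with the test on $d_j$;
* epistasis: $x_{a,j}a_j + x_{a,k}a_k + (x_{a,j} \odot x_{a,k})\,a_{jk}$,
  with the test on the interaction coefficient $a_{jk}$.

Genotype codes 0/1/2 (aa, Aa, AA) are corrected for the population allele
frequency $p$ of A: the additive covariate is $\{-2p,\; q-p,\; 2q\}$ and
the dominance covariate $\{-2p^2,\; 2pq,\; -2q^2\}$. Under exact
Hardy–Weinberg class frequencies both covariates are centered and mutually
orthogonal, so $a_j$ keeps its meaning as the allele-substitution effect
when $d_j$ enters the model. The per-SNP variances
$\sigma_a^2 = 2pq\,a^2$ and $\sigma_d^2 = 4p^2q^2 d^2$ are reported as
percentages of the null-model phenotypic variance
$\sigma_p^2 = \sigma_g^2 + \sigma_{pe}^2 + \sigma_e^2$.

The exact functional form of the pairwise interaction covariate is a
design choice here: we use the elementwise product of the two centered
additive covariates, the standard additive-by-additive contrast. Note the
documented hazard: for two SNPs in complete LD the product degenerates to
the square of a single additive covariate — a dominance-like contrast —
and such pairs are flagged not-testable.

## Pre-correction

Raw records are pre-corrected by ordinary least squares for
herd-year-season, parity, age-at-calving class and month of calving on the
*full* recorded population; the residuals for genotyped animals are the
scan response. Two remarks:

* Age at calving enters as a factor with configurable bins; the generator
  emits class labels directly.
* Pre-correction is not cosmetic. Fixed-effect variance left in the
  response is absent from $\mathbf{V}$, deflates every standard error and
  inflates every test statistic — in our simulations skipping it inflates
  Wald $t$ values by roughly half. The package's calibration tests
  pre-correct for exactly this reason.

A mixed-model pre-correction (random herd-year-season) would be a
reasonable alternative; OLS is the simpler reading of "pre-corrected using
the full set of records" and its adequacy at simulated scale is covered by
the property test comparing pre-corrected scans against joint fits.

## Relationship matrix and REML

`build_A()` uses the tabular method with inbreeding,
$a_{ii} = 1 + \tfrac12 a_{s d}$, treating unknown parents as unrelated,
non-inbred founders (no genetic groups). Pedigrees are topologically
sorted on input, phantom parents are added as founders, and
`prune_pedigree()` restricts to phenotyped animals plus ancestors — the
phenotyped block of $\mathbf{A}$ is identical either way.

`reml_null()` estimates $(\sigma_g^2, \sigma_{pe}^2, \sigma_e^2)$ by
average-information REML with an EM-REML fallback and step-halving when
the AI step fails or decreases the likelihood. Numerical choices:

* All $\mathbf{V}^{-1}$ products use the Woodbury identity at animal-level
  cost; the record-level $\mathbf{V}$ is never formed. The small-instance
  test oracle *does* form and invert $\mathbf{V}$ explicitly, keeping the
  check independent of this path.
* Components are kept non-negative by projection to a floor of
  $10^{-8}\,\mathrm{var}(y)$; values still at the floor on exit are
  reported as zero.
* Convergence requires both the log-likelihood change and the relative
  parameter change to fall below $10^{-6}$; exceeding 100 iterations is an
  error carrying the likelihood trace.
* Without repeated records $\sigma_{pe}^2$ is unidentifiable and is fixed
  at zero with a warning; a near-singular AI matrix (weak identifiability,
  e.g. founders-only pedigrees) triggers a warning with its condition
  number.

Per-SNP fits default to reusing the null-model components (`fixed-vc`), a
standard and accurate shortcut at scan scale; `per-snp-reml` re-estimates
components per SNP, and the suite asserts the two agree to
$|\Delta(-\log_{10} p)| < 0.15$ at MAF > 0.05. Tests are two-sided Wald
$F$ on one numerator degree of freedom with denominator
$n_\text{records} - \mathrm{rank}(\text{fixed design})$.

## Thresholds and the closed-form FDR

Genome-wide significance defaults to Bonferroni $\alpha/T$; the
`power10_rounding` option rounds to the nearest power of ten (0.05/408,255
becomes $10^{-7}$), a convention common in large dairy-cattle scans.
When nothing passes, suggestive thresholds of $10^{-4}$ (discovery) and
$10^{-2}$ (validation) are conventional and configurable. For any
threshold $P$ with $S$ of $T$ tests significant,

$$\%\mathrm{FDR} = \frac{P\,(1 - S/T)}{(S/T)\,(1 - P)} \times 100,$$

which can exceed 100% when significance is rarer than chance expectation.
This is a closed-form expected false-discovery proportion, not
Benjamini–Hochberg. `fdr_percent()` is strictly increasing in $P$ and
decreasing in $S$; both properties are tested.

Significant SNPs are merged into regions by single linkage within 1 Mbp —
the scale over which strong LD persists in these cattle populations — with
the top SNP chosen by smallest p, ties broken by position.

## Cross-population validation

Individual validation re-tests each discovery hit in the second
population at threshold $P_v$ and records sign concordance of the
A-allele effects (each population coded with its own allele frequencies).
Segment validation declares a hit replicated when any validation SNP
within a symmetric, inclusive 500 kb window is significant, accounting for
different markers tagging the same causal variant in different
populations. The segment-stage FDR needs a definition of $T$; we use the
number of distinct validation SNPs in the union of windows and record
that definition in the report metadata, since segment FDRs are only
comparable across analyses that share it.

## The epistasis screen and the LD artifact

Pairs are formed only from SNPs with significant additive effects in the
discovery population — $n(n-1)/2$ tests. The headline danger of this
screen is that *pure additive* variation at an untyped causal variant can
masquerade as epistasis: two imperfect tags jointly resolve the causal
allele through their haplotype combination better than either tag alone,
and the product covariate soaks up that extra information. The package
exposes this with `conditional_rescan()`, which adds the additive
covariate of the strongest regional peak to every significant pair model;
interactions that merely proxied the causal variant collapse.

The generator reproduces the phenomenon deterministically via its
`tag_mode = "split"` hidden-causal option: each tag's allele covers every
causal haplotype plus an independent mask ($D' = 1$, mimicking a young
mutation on an ancestral haplotype), so the causal allele is recovered as
the AND of any two tag haplotypes while single-tag $r^2$ stays moderate
(targets 0.4–0.55 in the shipped test, inside the 0.3–0.9 band of
realistic tagging). A `proxy_r2 = 1` panel SNP 20 kb away plays the role
of the high-LD chip variant that conditional models use in practice; it
tops the additive scan and is therefore the natural conditioning choice.
The acceptance test runs this end to end over 12 replicates of 2,000 cows
and requires that conditioning clears at least 95% of replicates that
produced significant pairs.

A related power property is also asserted: detection of an additive
effect through a tag decays with $r^2$, while dominance (and interaction)
detection decays with $r^4$, so additive power dominates dominance power
at every $r^2 < 1$ when the causal variant carries equal additive and
dominance variance.

## What the generator emulates — and what it does not

`sim_config()` defaults describe a desk-scale analogue of a dairy-cattle
study population: a discrete-generation pedigree ending in a cohort of
2,000 all-female records-bearing animals, 5,000 SNPs on 5 chromosomes,
founder haplotypes drawn as mosaics of a small base pool (LD decaying on
the `mosaic_block_bp` = 1 Mb scale), gene dropping with recombination at
1 cM/Mb, 1–5 records per cow (the recorded-population averages are about
three), herd-year-season/parity/age/month fixed effects, and variance
targets $(\sigma_g^2, \sigma_{pe}^2, \sigma_e^2) = (0.3, 0.1, 0.6)$ —
a moderately heritable yield-like trait. Setting $\sigma_g^2$ near
0.03–0.05 of the total emulates a low-heritability fertility-like trait.
`simulate_two_breeds()` shares a configurable fraction of the base
haplotype pool between two populations so that some causal variants
segregate in both and some effectively in one, which is what makes
legitimate non-replication possible in validation tests.

Known departures from real data: LD comes from a finite haplotype pool
rather than a coalescent process, so its fine structure is cruder than
real bovine LD; allele frequency spectra are uniform rather than
U-shaped; selection, drift trends, genotyping error, imputation error and
missing-record censoring are absent; the X chromosome is treated like an
autosome (defensible for all-female cohorts); calving-interval censoring
is not modelled. Passing tests therefore demonstrate correctness of the
statistical machinery under a faithful covariance structure, not
robustness to every artefact of real chip data.

## Problem sizes used by the shipped tests

Simulation sizes in the test suite are chosen to make Monte-Carlo checks
sharp at desk scale: GLS-oracle instances use ~45 cows so the explicit
$\mathbf{V}^{-1}$ oracle stays exact; type-I calibration uses 5,000 null
SNPs on 500 cows with two records each; parameter recovery uses 100
replicates at 2,000 cows; REML recovery uses 40 replicates at 500 cows;
the LD-artifact experiment uses 12 replicates at 2,000 cows; the power
ordering uses 200 replicates per $r^2$ level. The pedigree gene-dropping
oracle validates `build_A()` against 20,000 allele-drop replicates on a
small inbred pedigree.

## Limitations

No genomic or dominance relationship matrices, no genetic groups, no
multi-SNP or Bayesian whole-genome alternatives, no imputation or chip QC,
and no gene annotation: the scan emits plot-ready and table-ready output
for those downstream steps instead. Validation-stage thresholds have no
single principled derivation and are exposed as configuration rather
than hard-coded.
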