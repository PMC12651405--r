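---
title: "Methods: combining ability, GCA-GWAS and era trends in NCII testcross trials"
author: "nciiGCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining ability, GCA-GWAS and era trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nciiGCA)
```

## The trial and its analysis

The package analyses North Carolina design II (line × tester) testcross
trials: `f` candidate inbred lines each crossed to `m` testers, the
resulting `f × m` hybrids grown in a randomized complete block design with
`B` blocks at each of `L` locations. The canonical dimensions used
throughout documentation and validation are `f = 218`, `m = 2`, `L = 3`,
with plot counts per cross of `r = B` (per location) or `r = B·L` (pooled).

Five analysis stages are chained: multi-environment BLUP of hybrid values;
Griffing-style GCA/SCA estimation; balanced factorial ANOVA; variant QC and
single-marker GCA-GWAS; and era-trend / allele-trajectory analysis.

### Combining ability

`estimateCombiningAbility()` uses the totals form of the line × tester
estimators (grand mean `T../(mfr)`; line GCA `T_f/(rm) − μ̂`; tester GCA
`T_m/(rf) − μ̂`; SCA `T_ij/r − T_f/(rm) − T_m/(rf) + μ̂`). This is the
unique linear decomposition of cross means satisfying simultaneously the
zero-sum constraints (line and tester GCAs sum to zero; every SCA row and
column sums to zero) and exact reconstruction of the cross means; the suite
verifies the equivalence against an independent cell-means computation on
randomly generated balanced tables.

Two scopes are exposed, because multi-location practice uses both: the
plot-totals route (`scope = "pooled"` or `"per-location"`, `r` = number of
contributing plots), used when cross-checking ANOVA partitions; and the
BLUP route (`combiningFromHybridValues()`, `r = 1` on shrunken hybrid
values), the default phenotype source for GWAS since it removes
environment and block noise before decomposition. Balance is a hard
precondition of the totals formulas: strict mode raises an error on
unequal replication, and the explicit `onUnbalanced = "means"` fallback
recomputes from cross means with a warning.

Ranking by GCA (`rankByGca()`) takes an explicit `direction` argument
rather than assuming that numerically larger is better: for traits such as
tassel branch number or plant height a *smaller* (more negative) GCA is
the favourable direction in modern breeding, so the caller must state the
convention.

### Balanced factorial ANOVA

`perTesterAnova()` (sources Blo, Loc, Cro and all interactions, within one
tester) and `jointCombiningAnova()` (Loc, Blo, Line, Line×Loc, Tester,
Tester×Loc, Line×Tester, Line×Tester×Loc) compute sums of squares by
inclusion–exclusion over factor-subset marginal totals — exact for
complete balanced data and far cheaper than a saturated linear-model fit
at 218-line scale. Blocks are treated as a crossed factor (Blo appears as
a main effect pooled over locations in the joint layout), the only
structure consistent with the degrees of freedom such trials report
(e.g. Blo×Cro = 3·217 = 651 with 4 blocks and 218 crosses);
incomplete-block layouts are deliberately not supported.

Choice of error stratum: the per-tester layout has one plot per
Blo×Loc×Cro cell, so the highest-order interaction mean square is the
residual denominator; the joint layout has `B` replicate plots per
Line×Tester×Loc cell, and the pooled within-cell remainder (total SS minus
the eight listed sources) is the error stratum. Since the
expected-mean-squares testing scheme of such tables is rarely stated, the
default F-denominator is the residual for every source, with
`testAgainstInteraction = TRUE` switching Line and Tester to their ×Loc
interaction mean squares (the mixed-model convention). P-values are
right-tail F probabilities with no multiplicity correction, starred at
0.05/0.01.

### Multi-environment BLUP

`fitMultienvBlup()` fits `y = μ + Env + (1|Hybrid) + (1|Hybrid:Env) +
(1|Env:Rep) + error` by REML through `lme4::lmer`. Terms are assigned
fixed/random by standard multi-environment-trial practice: environments
are few and chosen (fixed, sum-to-zero coded so the intercept is the grand
mean), hybrids and their environment interactions are the inferential
target (random, hence shrunken), and Rep is identified with block within
location — the only replication structure in the design. REML is solved
by lme4's deterministic bounded optimizer rather than EM; variance
proposals cannot go negative in its Cholesky parameterisation, which is
the clamp-at-zero behaviour wanted for degenerate components. The balanced
closed form — hybrid BLUP equal to `k (ȳ_i − μ̂)` with
`k = σ²_L / (σ²_L + σ²_LE/L + σ²_e/(L·B))` — is used as the analytic check
of the solver at its own fitted components.

One pipeline-order ambiguity deserves note: descriptions of such analyses
sometimes read as if phenotypes were "optimized based on GCA" before
association mapping, inverting the order. This package always computes
BLUP → pooled GCA → GWAS; the per-location GCA route remains available for
users who want the alternative.

### Variant QC and GCA-GWAS

`qcFilterVariants()` applies, in order: biallelic records only; missing
rate < 0.2; minor-allele individuals ≥ 5; heterozygosity rate < 0.1; MAF >
0.05. The MAF rule is implemented in the removal direction (drop MAF ≤
0.05): the opposite reading would discard every informative variant, and
reported significant markers in this literature all have MAF above 0.05.
Counts are reported per criterion in application order (each criterion
sees only survivors of the previous ones, which makes the chain
idempotent); note a monomorphic variant falls at the minor-carrier step,
which precedes the MAF step.

`runGwas()` is a deliberately transparent single-marker engine: per
variant, OLS of per-line GCA on alternate-allele dosage (additive coding,
heterozygote = 1) plus the top `nPcs` genotype principal components
(default 3, mean-imputed dosages), two-sided t-test on the dosage
coefficient, lines with a missing call dropped for that variant only, and
zero-variance variants flagged degenerate with `beta = 0, p = 1`.
Iterative multi-locus marker-selection models (BLINK and kin) are cited
external methods, not reimplemented here; this substitution is stated in
the run manifest. The significance threshold is a configuration value
defaulting to 3.5e-5 — the conventionally printed figure — even though a
strict Bonferroni correction at millions of SNPs would be orders of
magnitude smaller; `significantHits()` accepts any threshold, so users can
apply 1e-6 or a computed Bonferroni bound instead.

### Era trends and allele trajectories

Lines are grouped into three breeding eras (AGE1 1960s–70s, AGE2
1980s–90s, AGE3 2000s–10s). `gcaTrend()` summarises GCA per era and tests
consecutive pairs plus AGE1–AGE3. The default test is Welch's t
(era groups have unequal sizes and no variance-homogeneity guarantee),
with a Mann–Whitney option; no multiplicity correction by default, a
Bonferroni option via `adjust`. `alleleTrajectory()` reports per-era
frequencies of the two homozygote classes at a SNP — heterozygous and
missing calls are excluded and counted, the inbred-panel convention — plus
per-class GCA summaries and a within-era class comparison.
`eliteAlleleReport()` labels the class with the better pooled mean GCA as
favourable, under a per-trait favorability direction that must be supplied
(the package does not guess which direction of, say, tassel branch number
a breeder wants); exact ties are flagged and left unlabeled.

## The synthetic-data generator

Because real trial phenotypes and genotypes of this kind are typically
available only on request, the generator is a first-class module that
emulates the statistical structure the analysis assumes.

*Genotypes* (`simulateGenotypes()`): biallelic SNPs on inbred lines drawn
homozygous from a per-SNP allele frequency; heterozygous calls injected
uniformly at `hetRate`, missing calls at `missingRate` (both independent
of era — the QC thresholds bound them but real data suggest no particular
structure). Lines are assigned to eras independently with probabilities
`eraProportions` (release dates per line are not modelled). Causal SNPs
shift their minor-allele frequency by `eraFreqShift` per era step; the
AGE1 base frequency is used exactly as configured (so an allele can be
genuinely absent early), while shifted frequencies are clamped into
[0.01, 0.99].

*Phenotypes* (`simulateTestcrossTrial()`): one plot per line × tester ×
location × block, as grand mean + location + block(location) + line GCA +
tester GCA + SCA + line×location + residual. True line GCA is the centered
causal-dosage score, topped up with an independent polygenic normal
deviate (or rescaled down) so its variance equals `var_gca_line` exactly —
keeping that variance interpretable as a single knob regardless of the
marker architecture. All other effects are drawn from their configured
variances and centered, so the stored ground truth satisfies exact
zero-sum constraints for parameter-recovery testing. Location and block
effects are drawn once per trial, matching an RCBD generative story. One
seeded RNG stream orders all draws deterministically.

*Defaults and why.* `nLines = 218`, `nTesters = 2`, `nLocations = 3`
mirror the canonical trial; `nBlocks = 3` follows the three-replicate
RCBD reading of that layout. `eraFreqShift = 0.055` per step gives an
11-point allele-frequency gain from AGE1 to AGE3, the magnitude reported
for elite alleles in Northeast-China maize panels. Variance components
(`var_gca_line = 6, var_gca_tester = 2, var_sca = 1, var_loc = 8,
var_block_within_loc = 1, var_line_x_loc = 1, var_residual = 2`, trait
units²) encode the qualitative structure of multi-environment maize
trials — line GCA clearly dominant over SCA and G×E, and large location
effects — while no published magnitudes exist for the real trial; they
were chosen once for testability and are not tuned. `missingRate = 0.05`
and `hetRate = 0.02` sit comfortably inside the QC bounds, as a
post-filter inbred panel would.

`simulateEraGca()` additionally draws per-line GCA directly from
configured era means (e.g. 2.51, 0.6, −1.28 with sd 1 for a declining
TBN-like trait): the genotype-driven simulator produces era trends only
indirectly, with random sign, so trend-recovery checks use this direct
construction.

*What the generator does not emulate* — and hence what passing tests do
not establish about real data: linkage disequilibrium and population
structure beyond era (the PC covariates in GWAS therefore correct nothing
real here), pedigree relatedness, heterotic-group structure, multi-allelic
variants, spatial field trends, unbalanced or lost plots, and any
dependence of missingness/heterozygosity on era or genotype.

## Numerical choices

- Combining-ability zero-sum validity is enforced at `1e-9` relative to
  the effect scale; oracle equivalence is tested at `1e-10`.
- ANOVA SS from inclusion–exclusion are floored at 0 against round-off;
  oracle agreement is tested at `1e-9` relative.
- REML uses lme4 defaults (deterministic given data); the balanced
  shrinkage identity is checked at `1e-8`.
- GWAS p-values are clamped into `(0, 1]`; an exact fit (zero residual)
  reports the smallest representable p rather than 0.
- Ties in GCA ranking break lexicographically by line id; exact ties in
  elite-class labeling are flagged, not broken.
- VCF output is minimal v4.2 with GT only, `./.` for missing, unphased.

## Validation problem sizes

The shipped suite exercises: full-dimension design enumeration (218 × 2 ×
3 × 3 = 3924 plots); 1000 random balanced tables for estimator/oracle
equivalence; 3⁴ layouts for ANOVA oracle agreement; 100 REML
parameter-recovery replicates at 218 hybrids × 3 environments × 3 blocks;
null-GWAS calibration pooled over 3 × 5000 variants at n = 218; 200
era-trend replicates at ~73 lines per era; and allele trajectories seeded
absent-then-present at frequencies 0/0.15/0.30. Smaller configurations
(6–40 lines) drive the per-module unit tests.

## Known limitations

Balanced complete data are assumed everywhere the Griffing totals or the
inclusion–exclusion ANOVA are used; the only unbalanced-data concession
is the cross-means fallback. The GWAS engine is single-marker OLS — no
kinship, no LD pruning, no candidate-gene windowing. Era labels are
exchangeable draws, not historical records. The ANOVA module does not
derive expected mean squares; its residual-denominator default is a
documented convention, not an inference from the design.
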