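---
title: "Genomic prediction in family-structured aquaculture populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in family-structured aquaculture populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquagp)
```

## The problem this package addresses

Selective breeding programs in aquaculture increasingly rely on genomic
selection: a mixed model is trained on phenotyped, genotyped individuals and
the genomic estimated breeding values (GEBVs) of selection candidates are
predicted from their markers alone. Cultured fish populations are typically
produced as dozens of full-sib families from a small founder set, often with
no recorded pedigree, so two marker-based tasks precede any prediction:
reconstructing the pedigree (who are the parents, which offspring belong to
which pair), and estimating genome-wide relatedness. A practical question
follows: how few SNPs can a genotyping panel carry before either task
degrades?

`aquagp` implements that full workflow — population simulation, genotype QC
and imputation, relationship-matrix construction, marker-based pedigree
reconstruction, REML/BLUP prediction, and a SNP-density downsampling
experiment — so the whole analysis can be exercised and tested end to end
on synthetic data with known truth.

## The model

The core statistical machinery is a single-kernel additive mixed model

$$y = \mu + Z a + e, \qquad
a \sim N(0, K\sigma^2_a), \qquad e \sim N(0, I\sigma^2_e),$$

where $K$ is either the genomic relationship matrix $G$ (GBLUP) or the
pedigree numerator relationship matrix $A$ (PBLUP; "inf-PBLUP" when the
pedigree was itself inferred from markers). The GRM follows VanRaden's
first method with sample allele frequencies: with dosages $M$ and
frequencies $p_k$, $Z = M - 2p$ and $G = ZZ^\top / c$ with
$c = 2\sum_k p_k(1-p_k)$. Narrow-sense heritability is
$h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$.

REML is solved by profiling the restricted likelihood over the variance
ratio $\delta = \sigma^2_e/\sigma^2_a$ after rotating the recorded-subset
kernel into its eigenbasis: the likelihood then costs $O(n)$ per
$\delta$-evaluation. The profile is scanned on a 61-point grid over
$\log\delta \in [-10, 10]$ and refined by golden-section search to a
relative tolerance of $10^{-8}$; solutions at the grid boundary are flagged.
Kernels whose smallest eigenvalue falls below $10^{-8}$ are repaired by a
minimal ridge; genuinely indefinite kernels are an error. The unit tests
pin this solver against an independent brute-force oracle that evaluates
the restricted likelihood by explicit matrix inversion on a dense
heritability grid.

*Predictive ability* is the Pearson correlation between observed phenotypes
and cross-validated GEBVs; *prediction accuracy* divides ability by
$\sqrt{h^2}$. Cross-validation is ten-fold with replicates; variance
components are re-estimated inside each training fold by default (the
conservative choice; a fixed-component mode is available). Ability is
computed on predictions pooled across a replicate's ten folds — one
correlation per replicate — with per-fold averaging available behind a
flag.

## The synthetic population

The simulator (`sim_config()`, `simulate_population()`) emulates a
two-generation breeding design: 28 founders (9 dams, 19 sires) structured
as six full-sib families, two half-sib pairs and one weakly related female;
129 full-sib families totalling 712 offspring; and a medium-density panel
of 4075 biallelic SNPs with ancestral minor allele frequencies uniform on
(0.01, 0.4), spread over 22 chromosomes of 100 cM. Three polygenic traits
mirror a standard length / body weight / testes weight design
($h^2$ = 0.538, 0.557, 0.686), the third recorded only in 246 males; the
first two are recorded in 695 of the 712 offspring.

Design choices that were genuinely open:

- **Linkage is simulated.** Mendelian-sampling variance among full sibs —
  the quantity that separates GBLUP from PBLUP — vanishes if loci are
  unlinked, so meioses use a Poisson crossover count per chromosome
  (Haldane, no interference) on a 22-chromosome map; no genetic map was
  available to copy, so chromosome lengths default to 100 cM each.
- **Founder relatedness is genuine.** Founders are bred from unobserved
  grandparents drawn in linkage equilibrium, so founder full-sib groups
  share real haplotypes rather than being labelled as related. The
  singleton female is made a third-degree relative of the first half-sib
  pair (her hidden parent is a half-sib of that pair), so her kinship to
  that pair falls in the third-degree band by construction.
- **Family sizes.** Only the total offspring count and the family count are
  fixed by the design; each of the 129 (dam, sire) pairs receives one
  offspring and the remainder are allocated multinomial-uniform.
- **Trait construction.** SNP effects are i.i.d. normal over (by default)
  all SNPs; the residual variance is set from the realized variance of the
  true breeding values so the configured $h^2$ holds in expectation.
  An optional per-trait `c2` adds a full-sib-family common environmental
  effect, used to study the inflation of pedigree-based heritability when
  family and environment are confounded; it defaults to 0.
- **Genotyping noise.** Each call is independently set missing (default
  rate 0.05) and surviving calls are independently corrupted to a different
  dosage (default rate 0.005, a typical order for amplicon assays). Because
  the missing model is per-call i.i.d., the ≥60% call-rate QC filter rarely
  fires on simulated data at these rates; its behaviour is exercised by
  targeted fixtures in the tests instead.

What the generator deliberately does **not** model: sequence-level reads
and variant calling, mutation, selection, dominance/epistasis,
genotype-by-environment interaction, and half-missing diploid calls.
Passing tests on this population therefore demonstrate the statistical
machinery under an idealised additive, family-structured world — they do
not certify performance on real data with, say, batch effects or
mis-specified trait architecture.

All randomness flows from one root seed through named substreams
(`substream_seed()`), so every stage is independently reproducible and the
whole pipeline is bit-identical under a fixed configuration.

## Genotype QC and imputation

QC follows the two-generation amplicon convention: a strict minor
allele frequency window (0.01, 0.4) applied within each generation (MAF
computed once on non-missing calls, before call-rate filtering), then call
rate ≥ 0.6 in the parental generation, then — on the survivors — call rate
≥ 0.6 in the offspring generation. Each removed SNP is attributed to the
first rule that rejects it, so the report's counts always sum to the input
count. The upper MAF bound of 0.4 is unusual for population data but is a
property of the assay design being emulated; it is implemented verbatim.

Missing calls are imputed by LD-kNNi: for a missing call the 30 sites in
strongest LD with the target (dosage $r^2$, pairwise-complete) define a
Manhattan distance (+1 pseudo-count) between individuals, and the call is
voted by the 5 nearest neighbours weighted by inverse distance. 30 and 5
are the published LD-kNNi defaults and are exposed as arguments. Since no
phasing exists, $r^2$ uses dosage correlations, not haplotype $D'$.
A masked-recovery test verifies the method strictly beats per-site modal
imputation on linked panels.

## Pedigree reconstruction

Pairwise kinship between parents uses the KING-robust between-family
estimator over co-observed sites, classified into the standard half-open
degree bands (1st degree [0.177, 0.354), etc.; closed below to resolve the
published bands' overlapping endpoints). Parent-offspring assignment uses
an admixture model: the binomial likelihood with $K$ clusters is maximised
by EM (FRAPPE-type multiplicative updates) with random restarts, plus a
squared-extrapolation (SQUAREM-type) acceleration that falls back to the
plain EM step whenever extrapolation would not improve the likelihood, so
the ascent property is preserved exactly — the tests assert trace
monotonicity. Entry-wise five-fold cross-validation (`select_K()`)
estimates held-out dosage error for choosing $K$.

Each offspring is scored against every (dam, sire) pair by the Euclidean
distance between its admixture proportions and the pair's midpoint; the
best pair wins and a gap to the runner-up below 0.05 flags the assignment
ambiguous. This midpoint rule is this package's formalisation of
"offspring share their parents' cluster axes" — the qualitative criterion
used in practice — not a claim about any other implementation's internals.

Two practical notes discovered on synthetic data and adopted as defaults:

- $K$ should exceed the number of candidate parents when the parents are
  themselves siblings: with $K$ equal to the parent count, members of the
  same founder full-sib family share cluster axes and their offspring
  cannot be assigned uniquely. The pipeline defaults to
  $K = \mathrm{round}(1.2\,n_\mathrm{parents})$ (34 for 28 parents) —
  consistent with cross-validated $K$ choices exceeding the parent count
  in real analyses of this design.
- Parent separation stabilises long before full likelihood convergence;
  the pipeline's parentage stage caps the accelerated EM at 60 cycles by
  default (configurable), which resolves assignments at desk scale.

Founders are optionally grouped into sib families by single-linkage over
1st/2nd-degree kinship calls; ambiguous offspring are excluded from the
reconstructed pedigree and reported. The $A$ matrix is built by the tabular
recursion, founders unrelated by default; inferred founder relationships
can be injected as priors but are off by default (matching the convention
of building $A$ from the reconstructed pedigree alone).

## The density experiment

`run_density_experiment()` draws replicated uniform SNP subsets (default:
the eleven sizes 200–4000, ten replicates each) and, per subset: builds the
GRM, estimates $h^2$, cross-validates ability and accuracy (the accuracy
denominator is the **per-subset** full-data $h^2$, which is what produces
the characteristic accuracy inflation at low density as $h^2$ collapses
faster than ability), and compares against the full panel via GEBV
correlation, family-mean GEBV correlation (families = identical (dam, sire)
pairs), and the Mantel correlation of the two GRMs (lower-triangle Pearson;
permutation p-values via `vegan::mantel` with the add-one convention when
requested). GEBV correlations are computed over all kernel individuals by
default, with an offspring-only option.

On the default synthetic population the experiment reproduces the
qualitative findings it was built to study: heritability, ability, GEBV
correlation and Mantel correlation all fall as the panel shrinks, with a
clear knee below ~1200 SNPs; family-mean GEBV correlations stay high
(> 0.95) at 400 SNPs even as individual-level correlations drop — family
structure needs far fewer markers than Mendelian-sampling resolution; and
parentage assignment remains essentially perfect at 400 SNPs while
ambiguity rises at 200.

## Problem sizes used in tests and the acceptance script

The test suite runs the pipeline at the full study scale (712 offspring,
4000–4075 SNPs) but scales the replication to desk size as its own choice
of experimental design: heritability recovery uses 10 simulation seeds;
the GBLUP-vs-PBLUP contrast uses 10 seeds with one 10-fold CV replicate
each; the density experiment uses four sizes (200, 400, 1200, 4000) with
three subset replicates and two CV replicates; parentage uses one full-scale
population plus three subsets each at 400 and 200 SNPs. The acceptance
script mirrors these sizes. One consequence of simulating the assay rather
than the post-QC panel: after transmission drift, roughly 15% of the 4075
simulated sites leave the strict MAF window and are removed by QC, so
QC-dependent stages run on ~3400 SNPs while the density experiment runs on
the clean panel where subsets up to 4000 SNPs are defined.

## Numerical conventions and edge cases

- Dosages are integers 0/1/2 with `NA` for missing; monomorphic columns
  contribute zero to both the GRM numerator and its normalisation, and an
  all-monomorphic panel is an explicit error.
- KING kinship for a pair whose smaller heterozygote count is zero is
  undefined (`NA`), not an error; duplicate genotypes give exactly 0.5.
- Admixture cluster frequencies are clamped to $[10^{-6}, 1-10^{-6}]$ so
  fixed sites cannot produce infinite log-likelihoods; Q rows are
  renormalised onto the simplex after every update.
- Ties in nearest-neighbour distances and in imputation votes resolve
  deterministically (stable order; lowest dosage first), keeping runs
  bit-reproducible.
- A cross-validation replicate whose pooled predictions are constant (e.g.
  under an identity kernel) reports an undefined ability for that replicate
  and errors only if every replicate is degenerate.

## Known limitations

- The admixture stage is an EM implementation chosen for transparency; it
  is slower than block-relaxation solvers and, like any local optimiser,
  can land in poor optima on very sparse panels — restarts mitigate but do
  not eliminate this.
- PBLUP heritability inflation relative to GBLUP (reported for real data)
  appears in simulation only when family and environment are confounded
  (`c2 > 0`); the default generator has no shared-environment effect, so
  simulated PBLUP $h^2$ is roughly unbiased instead of inflated.
- The VanRaden GRM uses in-sample allele frequencies; in a small structured
  sample (28 founders) this shifts the centring of relationship estimates
  by a few hundredths relative to pedigree expectations. This is a property
  of the estimator, not a bug; the tests quantify it.
- `simulate_traits()` requires complete genotypes; run the trait stage on
  the clean simulated matrix, not on noisy data.
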