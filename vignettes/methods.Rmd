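---
title: "Models and methods behind paleoadmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleoadmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the estimators, their assumptions, the tunable parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## Data model

Genotypes live in a `geno_matrix`: biallelic sites × individuals, entries
counting alternate-allele copies (0/1/2, `NA` missing). Low-coverage
ancient individuals are **pseudo-haploid**: at each covered site one
sequencing read is drawn uniformly among ref/alt-matching reads and its
allele doubled, so their calls are restricted to {0, 2, NA}. In
population allele frequencies a pseudo-haploid call contributes **one**
observed allele (a diploid call two): the call is a single draw from the
individual's two chromosomes, and counting it as two would understate the
sampling variance of every downstream statistic.

On disk the package speaks EIGENSTRAT (`.geno`/`.snp`/`.ind`, ASCII and
packed 2-bit reads, ASCII writes; the geno digit counts the alternate
allele, 9 = missing), pileup TSVs (chrom, pos, A/C/G/T counts), and TSV/
JSON for results. Genetic positions are Morgans internally; centimorgans
appear only in display. When two panels are merged, sites are intersected
on (chrom, physical position); allele-swapped records are recoded
(0 ↔ 2), and strand-ambiguous A/T and C/G sites whose alleles disagree are
dropped — merge rules are a conservative default, since no single
convention is universal.

## Block jackknife

Every f-statistic SE is a weighted delete-one-block jackknife (Busing's
formula) over contiguous blocks of at most 0.05 M genetic span per
chromosome — the block convention of the ADMIXTOOLS ecosystem — with block
site-counts as weights, because real maps give unequal blocks. Blocks of
5 cM comfortably exceed the range of background LD in humans, which is
what makes the SEs linkage-robust. With equal blocks the formula reduces
to the classic delete-one jackknife; a property test checks agreement with
the i.i.d. SE at 10,000 sites.

## f3, D, scans and the deviation test

Outgroup f3 is the plain mean of `(p_out − p_A)(p_out − p_B)` over sites
complete in all three populations — no heterozygosity normalisation and no
inbreeding correction, i.e. outgroup mode. Missing data are dropped *per
statistic*, not globally, matching the usual qp3Pop/qpDstat behaviour.
The D statistic is the ratio of block-summed numerator and denominator;
its leave-one-out values are ratios of partial sums, so the jackknife
respects the ratio structure. Scans sort candidates by estimate with
lexicographic tie-breaks and keep failed candidates as annotated rows.

The pairwise-f3 deviation test regresses one scan on another by OLS and
asks which candidates sit off the line. Since the line itself is
estimated, each candidate's residual SE comes from a jackknife in which
*both* f3 vectors and the regression are recomputed with each block
deleted. |Z| ≥ 3 is flagged, mirroring the usual reporting threshold in
this literature. How deviation significance "should" be computed is not
settled; this block-jackknife construction is a principled choice, not a
reconstruction of any specific tool's internals.

## qpAdm as GLS on f4 profiles

For left population L and rights R₁…R_k (R₁ the base), the f4 profile is
the vector `f4(L, R1; Rj, R1), j = 2..k`. The admixture model says the
target's profile is the weight-mixture of the sources' profiles; the
residual `e(a)` is driven to zero in the generalized-least-squares metric
`T(a) = e'C⁻¹e` under the constraint `Σa = 1` (affine reparameterisation,
no box constraints — infeasible weights are reported, never clipped, which
is how qpAdm-style results are usually read). `C` is the weighted
block-jackknife covariance of `e`, which depends on `a`; a short
fixed-point iteration (covariance at current weights → GLS solve →
repeat, tolerance 1e-9) converges in a handful of steps. Model fit:
`P = χ²(T; df = k − m)` upper tail. Weight SEs come from refitting with
each block deleted under the converged covariance.

Numerical edges handled explicitly:

* **Singular covariance** — ridge `ε·mean(diag(C))` with `ε` escalating
  from 1e-10, logged as a warning. This arises in small fixtures and in
  degenerate models, not in realistic panels.
* **Exactly interpolating models** (the target literally is a frequency
  mixture of the sources, as in noise-free synthetic fixtures): both `e`
  and `C` collapse to rounding noise and their ratio is meaningless, so a
  residual below 1e-9 of the profile scale is reported as a perfect fit
  (T = 0).
* **Nested comparison** — `ΔT = T_reduced − T_full` is only χ²(1) if both
  statistics are minima of the *same* quadratic form, so
  `nested_model_test()` re-minimises the reduced model under the full
  model's covariance (where the reduced constraint set is genuinely
  contained in the full one and `ΔT ≥ 0` holds structurally). Fitting
  each model with its own iterated covariance — the obvious
  implementation — allowed `ΔT < 0` and broke the size of the test; this
  was found and fixed during calibration. The comparison requires the
  same site set; fit the submodel with `sites = full_fit$sites`.
* **Complete cases** — only sites observed in the target, all sources and
  all rights enter a fit (an "allsnps: NO" policy), the conservative
  choice when per-population missingness differs.

The downsampling experiment wraps this machinery: binomially thin the
target's pileups to a lower mean coverage, re-call pseudo-haploid
genotypes, fit both models and the nested test per replicate (per-replicate
seeds derived deterministically from the master seed), and count
replicates whose full model remains adequate and whose nested test remains
significant.

## Admixture-LD dating

For an individual admixed `t` generations ago between sources A and B,
ancestry tracts decay with recombination and the covariance of
source-informative genotype residuals across site pairs at genetic
distance `d` falls off as `exp(−t·d)`. Sites are weighted by
`w = p_A − p_B`; residuals are `w·(g/2 − (p_A + p_B)/2)`; pair products
accumulate into 0.1 cM bins up to 20 cM, and `A₀·exp(−λd) + c` is fitted
by pair-count-weighted Levenberg–Marquardt (`minpack.lm::nls.lm`, chosen
over the `nls`-object wrappers because it is robust on numerically
perfect curves) with `λ ≥ 0` bounded and flagged if at the bound. The
default fit range starts at 0.45 cM: the shortest distances are dominated
by background LD, which the affine term `c` absorbs only partially. All
defaults are arguments.

The jackknife unit is the **chromosome** — pairs never span chromosomes,
so chromosomes are the natural exchangeable unit — with per-chromosome
pair counts as weights. `t = λ` (per Morgan) converts to calendar years
as `BP = sample_age + t · generation_time`; the sample age and generation
time (default 30 y) are explicit parameters, never hard-coded, because
dating is relative to the sampled individual.

Single-sample mode is first-class: one pseudo-haploid genome suffices, at
the cost of wide SEs (the validation runs at ~1× coverage see SEs of
10–16 generations on 50,000 sites — consistent with the precision
published for comparable single-genome datings).

## PCA projection

The reference panel (sites with ≤ 5% panel missingness, polymorphic) is
centred by `2p̂` and scaled by `√(p̂(1−p̂))`, mean-imputed, and decomposed
by SVD. Each eigenvector is oriented so its largest-magnitude loading is
positive, making signs reproducible across runs. A low-coverage sample is
placed by least-squares regression of its centred, scaled, non-missing
genotypes on the eigenvector rows at those sites — the "lsqproject" idea —
which reproduces a complete reference individual's coordinates exactly
and degrades gracefully under missingness (a property test masks 50% of
sites and requires the median PC1 displacement below 10% of the panel
range). Pseudo-haploid individuals may be included in the reference panel
(both analysis variants are supported); they receive no special
normalisation correction, which slightly inflates their noise loading.

## Sample QC

`ry_sex()` implements the Y-fraction statistic `nY/(nX+nY)` with a
normal-approximation 95% CI and the conventional 0.016/0.075 calling
thresholds (configurable — the thresholds are a community convention, not
a law). `damage_profile()` tabulates position-wise C→T (5′) and G→A (3′)
mismatch rates from aligned read/reference pairs; degraded ancient DNA
shows a geometric decay from the termini, and the simulator produces
matching reads with terminal rate exactly δ at position 1 decaying as
`δ·exp(−(i−1)/5)`.

## The synthetic-data generator

Reference populations are simulated at the **allele-frequency level** on
an admixture graph: ancestral frequencies Uniform(0.05, 0.95), each branch
applying Balding–Nichols drift `Beta(p(1−F)/F, (1−p)(1−F)/F)` (mean p,
variance `F·p(1−p)`), admixed nodes taking α-mixtures. This is fast,
deterministic given a seed, and has analytic expectations — which is what
f-statistic machinery needs — but it is not a coalescent: no within-locus
genealogical noise, no background LD between sites, no mutation-model or
ascertainment structure. Passing tests therefore validate the estimators
against their own model assumptions, not against every complication of
real data (reference bias and ascertainment in particular are out of
scope).

Finite panels are drawn as binomial allele counts of 15 diploids per
reference population — the sufficient statistic of simulating those
individuals — while PCA and I/O tests materialise actual individuals.
Admixed targets are **two-ancestry tract mosaics**: resampling events at
rate `t` per Morgan along each chromosome, each drawing ancestry from the
stationary proportions. That yields a stationary ancestry fraction α and
an ancestry autocovariance `∝ exp(−t·d)` — exactly the decay the dating
module inverts. Three-way targets add the third source at the frequency
level (each allele draw's frequency blended with β of the third source's),
which gives qpAdm the right mixture structure while keeping dating a
two-source problem — the same structure the motivating analyses assume,
where the dated pulse predates the third ancestry's arrival. Reads are
Poisson-coverage with geometric terminal deamination; the default
scenario sequences the target at 1× with δ = 0.02.

The default scenario (`okhotsk_scenario()`) mirrors the northeast-Asian
study design this package is built around: a deep outgroup (F = 0.2 from
the root), six rights — two southern East Asian populations sharing a
clade with the Jomon-like source, a Beringian population sharing drift
with the Kamchatka-like source (shared branch F = 0.03), a Siberian
population sharing drift with the Amur-like source (F = 0.04), plus
American and Oceanian outliers — and a 0.46/0.40/0.14 three-way target
admixed 25 generations before sampling. The shared-branch depths matter:
qpAdm's power to separate two northern sources comes entirely from rights
differentially related to them, and the chosen values are the realistic
scale for strongly drifted Siberian panels. With shallower sharing
(F ≈ 0.01) the right set becomes uninformative and nested-test power
collapses — a useful reminder that qpAdm conclusions are only as good as
the right set.

## Validation-study sizes

The shipped acceptance suite runs, per check: 100 replicates of two-way
weight recovery at α = 0.3 (50,000 sites, 22 × 1 M chromosomes; mean
error < 0.02, CI coverage 88–99%); 25 replicates of three-way truth with
α₃ = 0.3 rejecting the two-way submodel (≥ 80%); 200 replicates of
nested-test size under two-way truth at 20,000 sites (rejection count
within the exact binomial 95% band of 5%); dating recovery at t = 25 and
monotonicity of mean t̂ over t ∈ {5, 15, 25, 50} (20 replicates each,
30,000 sites); and a 20-replicate downsampling experiment (4× → 1×) on a
66% third-source target. The 20,000/30,000-site replicate sizes are the
package's chosen validation conditions: large enough for the asymptotics
the tests assert, small enough to keep the suite pleasant to run.

## Known limitations

* Exact numerical equality with ADMIXTOOLS binaries is not promised: the
  estimands match the published descriptions, but internal details (qpAdm
  rank handling, qp3Pop normalisation modes) differ.
* The nested-model χ² is a documented stand-in for qpAdm's internal
  likelihood-ratio computation, which is not described in the literature
  at implementation precision; its size is verified by simulation here.
* Single-pulse dating only; multiple pulses or continuous migration bias
  `t` toward an average of the mixing times.
* The generator's lack of background LD means jackknife blocks are
  conservative on synthetic data relative to real genomes.
* Reference bias, contamination and ascertainment — major practical
  concerns for real ancient genomes — are quality-control problems
  upstream of this package's scope; only the transversion replication and
  the deamination/sex summaries touch them.
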