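---
title: "Methods: weighted single-step GWAS for sow reproduction traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted single-step GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical machinery
it implements, the choices made where the method leaves room, and what
the synthetic test bed does and does not establish about real data.

## The model and its assumptions

The evaluation model is the standard animal model
$y = X\beta + Zu + e$, with $u \sim N(0,\, \Sigma_a \otimes H)$ and
$e \sim N(0,\, \Sigma_e \otimes I)$. Fixed effects are categorical (farm,
last parity, last farrow-month, last farrow-year), one-hot coded with the
first-observed level as reference plus an intercept; estimates of
estimable functions, variance components and GEBVs are invariant to that
reference choice (tested). Each animal contributes at most one aggregated
record per trait; repeatability, maternal and dominance effects are out
of scope.

Single-step evaluation replaces the pedigree relationship inverse by

$$H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1}
\end{bmatrix},$$

so non-genotyped animals contribute information through the pedigree
while genotyped animals carry marker-based relationships.

* $A$ is built by the tabular recursion with inbreeding; $A^{-1}$ by
  Henderson's rules with Meuwissen–Luo mendelian-sampling variances
  (dense $A$ is never formed on that path).
* $A_{22}$ is the genotyped-animal block of $A$ and is inverted densely —
  subsetting $A^{-1}$ instead would be wrong.
* $G = ZDZ'q$ uses genotype codes (0/1/2 counts of the second allele)
  centered by twice the allele frequency; missing codes are mean-imputed
  (centered value 0). Scaling is two-stage: a variance-sum base
  $G_0 = ZDZ' / \sum_j d_j\,2p_j(1-p_j)$, then a multiplier $q$ matching
  the mean diagonal of $G$ to that of $A_{22}$, so that reweighting $D$
  across iterations does not drift the scale.

## The iterative weighting loop

Starting from $D = I$: build $G$, solve the mixed-model equations under
$H^{-1}$, back-solve the genotyped animals' GEBVs into SNP effects
$\hat u = qDZ'G^{-1}\hat a_g$, update the weights
$d_i = \hat u_i^2\, 2p_i(1-p_i)$, normalize them to sum to the marker
count (conserving $\mathrm{tr}(D)$), rebuild $G$, and repeat. The default
is two solve/back-solve passes — the weights used by the final pass come
from one update — and `nIterations = 0` gives the classical unweighted
pass. Variance components are estimated once and held fixed across
passes; the weights change $G$, not $\Sigma_a$.

Window association is scored per trait as
$100\cdot\mathrm{Var}\!\left(\sum_{j \in w} z_j \hat u_j\right)/\sigma^2_a$
over genotyped animals, for every 5-SNP sliding window (stride 1) within
a chromosome; windows never span chromosome boundaries. Windows at or
above 1% are selected and overlapping selected windows merge into
regions that report the maximum window percentage. The denominator
defaults to the REML total additive variance; an `"empirical"` option
divides by $\mathrm{Var}(Z\hat u)$ instead, which makes the all-marker
window of a single chromosome score exactly 100% and is useful as a
variance-accounting check. Whether published window percentages use one
or the other denominator is generally not stated, so both are exposed
and the choice is logged in the scan output.

## Numerical choices

**Blending, tuning and the singular-$G$ trap.** When the centering
frequencies are computed from the genotyped panel itself, every centered
column of $Z$ sums to exactly zero, so the unblended $G$ has the all-ones
vector in its null space: it is singular *by construction*, not by
accident. The MME therefore use a blended
$G \leftarrow (1-\tau)G + \tau A_{22}$ with default $\tau = 0.05$.
Back-solving deliberately uses the *unblended* $G$ — blending is a
numerical device, not part of the SNP-effect map — through a $10^{-8}$
diagonal ridge when the panel's own frequencies are in use. If
frequencies come from a wider reference population (e.g. all genotyped
candidates before subsetting, supplied via the `p` argument of
`runSsgwas()`), the unblended $G$ is generically invertible, no ridge is
needed, and the reconstruction identity $Z\hat u = \hat a_g$ holds to
machine precision; the test suite asserts it at $10^{-8}$ in that
regime.

**EM-REML.** Variance components are estimated by expectation-
maximization REML: monotone in the restricted likelihood (asserted in
tests with $10^{-6}$ slack for round-off), derivative-free, and naturally
non-negative; diagonal components are additionally floored at $10^{-10}$
of the phenotypic variance. Convergence is a relative parameter change
below $10^{-8}$, capped at 1000 rounds with an explicit `converged`
flag — never silent. Two computational paths give identical iterates
(tested to machine precision): a generic dense path that factorizes the
multivariate MME every round, and a structure-exploiting path used when
a single trait is analysed and every animal has exactly one record, in
which one eigendecomposition of the relationship inverse plus Woodbury
absorption of the fixed effects makes every round $O(np^2)$. EM is slow
near variance boundaries; the round cap plus flag make that visible.
Average-information acceleration would be the natural extension.

**Degenerate inputs.** All-missing markers, all-zero weight updates,
monomorphic-only panels, singular unblended $G$, rank-deficient fixed
blocks (pseudo-inverse fallback) and cyclic pedigrees all produce
explicit errors or flagged results rather than silent propagation.

## Trait derivation

Per sow over her recorded litters (at most 10 parities): PWL and BAL are
litter means; W2CL is the mean wean-to-conception interval with an open
last litter excluded from numerator and denominator; LSY is (total
gestation days / 115) / (herd days / 365); PWSY is the identity
LSY × PWL (asserted exactly per sow). The NPD definition "365 minus
productive days multiplied by LSY" is grammatically ambiguous; the
default reading is NPD = 365 − (mean productive days per litter) × LSY,
which keeps NPD in [0, 365] for plausible records and is consistent with
LSY ≈ (365 − NPD)/cycle length, while the literal left-to-right reading
(365 − total productive days) × LSY sits behind
`npdFormula = "literal"`. Neither is asserted as the published intent.
NPD values outside [0, 365] are kept and flagged as data issues, not
clamped. Coefficient of variation and moment-based skewness/excess
kurtosis ($g_1$, $g_2$) serve as the normality diagnostic, with
`NaN` flags for near-zero means or variances.

## The synthetic test bed

The generator emulates the *structure* of a commercial multi-farm sow
population genotyped on a medium-density chip, at package scale:
discrete generations under random mating, founder genotypes in
Hardy–Weinberg proportions at MAFs drawn uniformly from (0.05, 0.5],
gene dropping with a Haldane crossover model (1 Morgan per chromosome by
default — 5-SNP windows are only interesting with local correlation),
missingness, and a genotyped panel filled from the youngest generation
backwards, mirroring a few hundred genotyped animals among thousands
recorded. Breeding values are a planted-QTL part plus a polygenic part
generated by the mendelian-sampling recursion (founders
$N(0, \Sigma_a)$; non-founders parent-average plus a deviation with
variance $\tfrac12(1-(F_s+F_d)/2)\Sigma_a$), so the simulated covariance
is exactly $A \otimes \Sigma_a$. The default six-trait regime uses
published Large White variance components and genetic/phenotypic
correlations; because the reported ±0.99 LSY/NPD correlations leave the
implied matrices marginally indefinite, both are projected to the
nearest positive semi-definite matrix once, at construction. Fixed-level
effects are specified on the residual-SD scale so they matter equally
across traits. One seed governs each stage through fixed offsets
(pedigree +0, genotypes +1, phenotypes +2), making stages independently
and jointly reproducible.

What the generator does *not* emulate: coalescent-realistic LD and allele
frequency spectra, selection and non-random mating, overlapping
generations, unbalanced trait recording, genotyping-batch effects, and
litter-size/culling distributions of any particular herd system. Passing
tests therefore establish the correctness of the algebra and the
statistical calibration of the estimators under the stated generating
model — not that real-data scans will rank the same regions.

## Problem sizes and design choices in the checks

The recovery and detection checks run at sizes chosen for adequate
statistical power: heritability recovery uses 20 replicates of ~1500
animals (three generations from 200 founders, all phenotyped) at true
$h^2 = 0.25$; planted-QTL detection uses ten replicates of a ~1200-animal
pedigree with ~26% genotyped — mirroring the ratio of a few hundred
genotyped among thousands recorded — and 500 linked markers on five
chromosomes, with one QTL at forced founder MAF 0.4 sized to 20% of the
total genetic variance. Under those conditions the QTL-bearing window
ranks in the top 1% of ~480 windows and clears the 1% selection rule in
essentially every replicate. The null-variance boundary check asserts
the *average* REML estimate over ten replicates, because a single null
draw is half-normal with a standard error comparable to the bound
itself. The multivariate REML path assumes identical record sets across
traits (the simulator produces balanced data); heavily unbalanced
multi-trait data are a documented limitation.

## Pipeline and interfaces

The stages compose as exported functions (`applyQc`, `deriveTraits`,
`emReml`, `runSsgwas`, `windowVariance`, `selectRegions`,
`annotateRegions`, `summarizeCandidates`), and `runPipeline()` drives
them from one YAML/JSON config: QC → trait table → REML → scan →
annotation, writing TSV artifacts and a manifest of MD5 hashes with the
config echoed, so identical config + inputs reproduce identical
manifests. Annotation is strictly local (a user-supplied BED or GFF3);
"upstream/downstream" follow chromosome coordinates, ignoring strand,
with distances measured SNP-to-nearest-gene-boundary and printed
truncated to two decimals in kb, matching the convention of published
candidate tables. Flanking search stops at 2.0 Mb by default.
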