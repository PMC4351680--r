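---
title: "Methods: detecting climate-adaptive footprints in promoter polymorphisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting climate-adaptive footprints in promoter polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscan)
```

adaptscan implements the statistical chain used in landscape-genomics
candidate-gene studies: population-genetic summaries of a multi-breed
genotype panel, differentiation and distance analysis, two complementary
genotype-environment association methods (PLS regression and per-allele
logistic scans), island-model FST-outlier detection, and cross-species
divergence statistics for the same promoter region.  This vignette explains
each model, its assumptions, the tunable parameters, and the choices made
where the design was genuinely open.

## Input model: published tables, reconstructed counts

The package's primary input is a *breed panel*: per-breed genotype-class and
allele frequencies for a set of biallelic promoter variants (SNPs and
INDELs), printed to two decimals, plus per-breed chromosome counts.  All
statistics run on integer genotype counts reconstructed from those
frequencies by largest-remainder rounding (`largest_remainder_counts()`):
each class is rounded, then the total is repaired one unit at a time in
order of fractional remainder, ties to the lower class index.  This makes
every downstream number an exact, reproducible function of the printed
tables.

Published tables contain corrupted cells, so `breed_panel()` validates
every breed-by-locus cell and reconciles the two frequency sources.  A
genotype row summing to 1 within tolerance (default 0.02, the published
rounding) is used directly; a row that exactly mirrors the published allele
frequency (implied frequency matching 1 minus the published value) is
treated as a class-order reversal and flipped; a row failing the sum check
falls back to Hardy-Weinberg-imputed counts from the published allele
frequencies; a published allele pair failing its own sum check is replaced
by the genotype-implied value.  Every action is recorded in `panel$flags`.
On the packaged 31-breed panel this reconciliation touches 28 cells, all
individually inspected: one column of the allele table is corrupt in 19
breeds, one genotype row is class-reversed, three rows sum to 0.91 or 0.01,
and four rows disagree with their allele pair without being reversals (kept
as printed, flagged).

The climate table carries 14 numeric variables per breed: latitude and
longitude (degrees), minimum/maximum/hottest-month/annual mean temperatures
(&deg;C), thermal width `TW = MAXaT - MINaT`, total/maximum/minimum rainfall
(mm), three relative humidities (%), and the temperature-humidity index

$$\mathrm{THI} = T - 0.31\,(1 - \mathrm{RH})\,(T - 14.4),$$

a heat-stress indicator computed from the maximum average temperature and
mean relative humidity (fraction).  `read_climate_table()` recomputes TW and
THI and checks the categorical climate type against its rainfall bands;
disagreements warn rather than error because the printed labels take
precedence (the packaged table has two rows whose printed TW is internally
inconsistent; they are used as printed).

## Diversity and linkage

`pooled_diversity()` reports per-locus minor-allele frequency, observed
heterozygosity (fraction of heterozygotes), expected heterozygosity
$H_e = 2p(1-p)$, and the exact Hardy-Weinberg test.  $H_e$ uses the plain
(uncorrected) form because pooled published values match it; the
$2n/(2n-1)$ correction is available by flag.  "All breeds joined" means
counts are summed over breeds before computing per-locus values, and the
reported averages are plain means over loci.

`hwe_exact_test()` is the probability-ordering exact test: conditional on
allele counts, every heterozygote count is enumerated and the p-value sums
the probabilities of tables no more probable than the observed one.
Monomorphic samples return 1 by convention.

`ld_r2()` estimates two-locus haplotype frequencies from unphased genotypes
by EM over the phase of double heterozygotes, started at linkage
equilibrium, converging when the largest frequency change drops below
1e-10 (cap 1000 iterations); $r^2 = D^2 / (p_A p_a p_B p_b)$.  Missing
genotypes are dropped pairwise.  `ld_blocks()` groups loci by single
linkage at a configurable $r^2$ threshold — note that single linkage joins
chains (a-b and b-c strong, a-c weak still yields one block), which is the
documented behaviour.

## Differentiation and distances

`wc_components()` implements the Weir-Cockerham (1984) method-of-moments
variance components $a$, $b$, $c$ for diploid data, using observed
heterozygote counts, with $\theta = a/(a+b+c)$; multilocus and pairwise
estimates are ratios of summed components.  Negative estimates are
reported as such but clipped to zero before the Reynolds transform
$D = -\ln(1 - F_{ST})$, which is linear in divergence time under pure
drift (the printed minimum distance of 0 corresponds to the clip).
Pairwise significance comes from permutation: genotypes are reassigned
between the two breeds, loci independently, because tabulated panels carry
no real multi-locus individuals whose within-individual structure could be
preserved across loci (within a locus the genotype pair stays intact).
Under an exchangeable null the resulting p-values are uniform, which the
test suite verifies by simulation.

`exact_differentiation_test()` tests random allele distribution between two
populations.  Per locus the biallelic 2x2 table yields the two-sided Fisher
exact p by enumeration (a Metropolis chain estimating the same quantity is
available and validated against the enumeration).  Across loci the default
global p uses Fisher's combined probability — the convention of the
standard population-genetics packages, and the one under which the packaged
panel reproduces the published differentiation histogram (mean count of
significantly different populations 22.8 against a published 22.2) — while
`combine = "chain"` runs a single Metropolis chain over the concatenated
tables with the product-probability statistic.

## PLS regression of allele frequencies on environment

The genotype-environment association model regresses the matrix of modelled
allele frequencies (breeds x responses) on the climate matrix (breeds x
predictors), both centred and scaled to unit variance.  Components are
extracted sequentially: the weight vector is the leading left singular
vector of the deflated $X'Y$; scores $t = Xw$; $X$ (and $Y$) are deflated
by their rank-one score regressions.  Signs are fixed so each weight
vector's largest entry is positive, making the fit deterministic.  With as
many components as the rank of $X$ the fit equals ordinary least squares,
and successive score vectors are orthogonal — both asserted in the tests.
`plsr_fit()` returns a classed model object with the usual `print`,
`summary`, `coef`, `predict`, `fitted` and `residuals` methods.

Model assessment uses leave-one-out cross-validation (`press_q2()`):
the model — and, by default, the centring/scaling — is refit without each
row and the held-out response predicted; $\mathrm{PRESS}$ is the sum of
squared prediction errors on the scaled response and
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{SSY}$.  Responses may be cross-validated
per response (independent single-response fits, the default, matching the
per-polymorphism description of the study design) or jointly;  the choice
matters.  On the packaged panel the joint, globally-scaled 3-component
model gives $Q^2$ per response of about 0.29/0.23/0.43/-0.05/-0.25/0.11,
while the corresponding full-fit explained variations $R^2$ are
0.41/0.39/0.53/0.19/0.06/0.31.  The published per-response values
(0.46/0.47/0.53/0.20/0.10/0.33) track the $R^2$ sequence far more closely
than any cross-validated variant we can produce, so cross-validated
predictions reported here are systematically more conservative than the
published figures; both quantities are returned so users can see the gap.
$Q^2 \le R^2$ on every fixture and simulation run in the suite.

Component count is chosen by minimum PRESS softened by the van der Voet
comparison: `van_der_voet_test()` sign-flips the paired differences of
squared LOO residuals (exhaustive over all $2^n$ patterns for $n \le 12$,
2000 Monte-Carlo draws otherwise), and `select_n_components()` picks the
fewest components whose residuals are not significantly larger than the
minimum-PRESS model's (p > 0.1).  Because the sign-flip test is scale-free
it can flag negligible but consistent improvements; on the packaged panel
the minimum-PRESS count is 3 (matching the published choice) while the
parsimony rule alone would stop at 1.

Variable screening follows the two-filter rule: keep predictors with
Variable Importance in Projection $\mathrm{VIP}_j =
\sqrt{p \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a \mathrm{SSY}_a} > 0.83$
*and* top-two-component explained variance $\mathrm{VT2}_j \ge 40\%$.
Squared VIPs average to 1 by construction.  On the packaged panel the four
predictors the published screen discarded (MAXaT, HrMx, HrMi, THI) all fail
the VIP criterion here too; one further predictor (LON) sits exactly at the
VT2 = 40 boundary (39.6 here against a published 40.001), a reminder that
hard thresholds on rounded inputs are fragile at the boundary.  The
reduced-model analyses therefore pin the retained set explicitly rather
than recomputing it.  `eliminate_variables()` reports PRESS for the full
and reduced models — on the packaged panel the root-mean-PRESS pair is
0.976/0.957 — and whether elimination improved prediction.

## Per-allele logistic scans

The spatial-analysis method codes, for every allele, presence 1 if an
individual carries at least one copy (heterozygotes are positive for both
alleles) and regresses presence on one environmental variable at a time by
maximum-likelihood logistic regression.  Two statistics assess each model
against the intercept-only null: the likelihood-ratio $G$ and the Wald
$W = (\hat\beta/\mathrm{SE})^2$, both on $\chi^2_1$; a model counts as
significant only when *both* reject at the Bonferroni threshold
$ST = \alpha / (2LV)$ over $2L$ alleles and $V$ variables (for 6 loci, 14
variables and family $\alpha = 0.01$, $ST = 5.952\times10^{-5}$).

Individuals within a breed share the breed's environmental value.  The
resulting pseudo-replication is a known property of the method, not
corrected here: with real between-breed drift, breed-level frequency noise
is amplified by the individual-level sample size, so scans on strongly
structured panels over-reject relative to the nominal level.  The family-wise
error control verified in the test suite therefore uses an essentially
unstructured panel; on structured data the scan should be read as a
ranking device whose hits require confirmation by the outlier test below.
Complete separation (|slope| > 15 on the standardised variable) flags the
Wald statistic as unreliable while $G$ remains valid.  `sam_correlogram()`
evaluates the fitted presence probability over 100 grid points spanning the
observed range and reports the difference between the curve's extremes.

## Island-model FST-outlier detection

The outlier engine asks whether a locus's $F_{ST}$ is extreme relative to
neutral expectation at its heterozygosity.  The null joint distribution of
$(H_e, F_{ST})$ is simulated from the island model's stationary
allele-frequency distribution: ancestral frequency uniform on (0.01, 0.99),
per-population frequencies Balding-Nichols
$\mathrm{Beta}\!\left(p_0\frac{1-F}{F},\,(1-p_0)\frac{1-F}{F}\right)$,
genotypes in Hardy-Weinberg proportions at the observed per-population
sample sizes, and — critically — the *same* Weir-Cockerham and pooled-He
estimators applied to simulated and observed loci.  This beta-binomial
approximation replaces the coalescent simulator of the classic outlier
software; it matches the island model's stationary distribution and is
calibrated (simulated multilocus $F_{ST}$ unbiased within 0.01 across
$F \in \{0.02, 0.07, 0.2\}$ in the tests), but its conditional spread
differs from the coalescent's, so tail p-values are not expected to match
published ones to the third decimal — the reproduction target is the
qualitative outlier structure.

`conditional_p()` computes $P(\text{sim } F_{ST} < \text{obs } F_{ST})$
among simulated loci within an $H_e$ band of ±0.05 (widened by half its
width until at least 200 neighbours), ties counted half.
`fst_outlier_scan()` runs the published three-stage procedure: scan at the
all-locus multilocus $F_{ST}$; drop loci outside the central 99% band and
re-estimate the neutral $F_{ST}$ from the remainder; rescan *all* loci at
the refined value.  Classification tails (default 0.025/0.975) are
deliberately independent of the removal band.  Defaults: 100,000 simulated
loci per stage; the test suite scales this to 3,000-20,000, which leaves
the conditional p-values' Monte-Carlo error well below the decision tails
in use.  On the packaged six-locus panel the refined neutral $F_{ST}$ is
about 0.09 (published: 0.0725 after a trim our wider tails do not trigger)
and the two published outliers occupy the extreme tails in the expected
directions — the low-He SNP lowest (balancing side), the high-$F_{ST}$
INDEL highest (directional side) — without crossing the 0.025/0.975
thresholds under this engine.

## Cross-species divergence and neutrality

`t92_distance()` implements the Tamura three-parameter distance, which
corrects for transition/transversion bias and GC content: with transition
and transversion proportions $P, Q$ over pairwise-usable sites and
$h = 2\theta(1-\theta)$ from the pair's pooled GC content $\theta$,

$$d = -h \ln\!\left(1 - \frac{P}{h} - Q\right) - \frac{1-h}{2}\ln(1 - 2Q).$$

With gamma-rate variation of shape $a$ each $\ln x$ becomes
$-a(x^{-1/a} - 1)$, the continuous-gamma transform; the shape used for the
promoter analyses is 5.6803.  The continuous transform is used rather than
a 5-category discretisation, which is a maximum-likelihood inference detail
outside the distance computation.  At $\theta = 0.5$ the formula reduces
exactly to Kimura's two-parameter distance (asserted in tests), and the
gamma correction can only increase a distance.  Sites with gaps or
ambiguity codes are removed pairwise, not globally.  Species-level
divergence (`divergence_matrix()`) is the plain mean over cross-species
haplotype pairs, without subtracting within-species variation, with
standard errors from site bootstrap (default 1000 replicates).

`tajimas_d()` contrasts mean pairwise diversity with Watterson's
segregating-sites estimator using the standard variance constants;
biallelic segregating sites only, columns with missing data ignored.
`nj_tree()` wraps standard neighbor-joining, zeroing negative branch
lengths and transferring their magnitude to the sibling branch;
`nj_bootstrap()` reports bipartition support from column-resampled
replicates.

## Synthetic data: what it emulates, and what it does not

The generators produce inputs with the statistical structure each stage
assumes, sized by default like the real study: 31 breeds of 27 animals and
11 biallelic loci at island-model differentiation $F_{ST} = 0.07$ (the
study's neutral estimate, rounded).  Climate tables are multivariate normal
over the 12 base variables with configurable means, SDs and correlation
(defaults chosen to resemble the real table's ranges; TW, THI and the
climate type are derived, never drawn).  Selected loci follow a logistic
cline in one standardised climate variable with Balding-Nichols noise;
outlier loci override the island $F_{ST}$; individuals are drawn in
Hardy-Weinberg proportions and the panel re-tabulated from them, exactly
as real data would be.  A single top-level seed fans out to fixed per-stage
substreams.

What the generators do *not* emulate: linkage between loci (each locus is
drawn independently, so LD-block structure is absent), demographic history
beyond the island model (no bottlenecks or admixture graphs), genotyping
error, and spatial autocorrelation of climate beyond the configured
correlation matrix.  Passing the planted-signal recovery tests therefore
shows the chain detects clines and outliers under the island model's
assumptions — not that it is robust to admixture or shared history, which
is precisely why the association scans and the outlier test are meant to be
read together on real data.

Alignment generators evolve sites independently down a tree under the T92
rate matrix (root drawn from the stationary composition; optional per-site
gamma rate multipliers), and `coalescent_sample()` draws standard neutral
coalescent genealogies with infinite-sites mutation, providing the
calibration oracles for the divergence and neutrality statistics
(Watterson and pairwise expectations are checked to 5%).

## Numerical choices and problem sizes

Tolerances: EM convergence 1e-10; logistic fits IRLS at 1e-8 with 100
iteration cap; PLS component extraction stops when the singular value or
score norm drops below 1e-12; frequency-sum validation 0.02.  Tie-breaks:
largest-remainder ties to the lower class index; NJ ties resolved by the
agglomeration backend's deterministic order; EM starts at equilibrium so
likelihood ties resolve toward the equilibrium-closest solution.  Degenerate
inputs: monomorphic loci yield HWE p = 1, undefined $r^2$ and undefined
per-locus $F_{ST}$ (excluded from multilocus sums); saturated sequence
pairs yield infinite distance with a warning.

The test suite runs simulations at reduced but statistically adequate
sizes — 3,000-20,000 simulated loci per outlier stage, 25-50 replicates for
power properties, 200-500 replicates for calibration properties — chosen so
that Monte-Carlo error is small relative to each assertion's margin; the
full-size defaults (100,000 simulations, 90,000 permutations, 5,000
bootstrap replicates) remain the package defaults.
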