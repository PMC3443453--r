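---
title: "Zygotic linkage disequilibrium and its genic components: models and methods"
author: "zygoticLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zygotic linkage disequilibrium and its genic components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zygoticLD)
```

## The problem

Gametic linkage disequilibrium (LD) — the association between alleles
carried on the same gamete — is the workhorse of association mapping and
genomic selection. But gametic LD cannot be observed directly in unphased
SNP genotypes, and the usual expedient of estimating it under an assumed
Hardy-Weinberg equilibrium (HWE) is questionable in populations with
recent admixture, such as composite livestock populations built by
repeated crossbreeding. In a general non-equilibrium diploid population,
the association between two biallelic loci decomposes into a hierarchy of
*genic disequilibria* that are all estimable from unphased genotypes
without any HWE assumption:

* **Hardy-Weinberg disequilibrium** at each locus,
  $D_A = P_{AA} - p_A^2$, with fixation index $f_A = D_A/(p_A p_a)$;
* **digenic** disequilibria: the gametic LD $D_{AB}$ (within a gamete) and
  the nongametic LD (between an allele on one gamete and an allele at the
  other locus on the partner gamete). Their sum is the **composite LD**
  $\Delta_{AB}$, which is estimable from genotype counts alone;
* **trigenic** disequilibria $D_{AAB}$ and $D_{ABB}$: residual three-gene
  associations after removing all digenic terms and HWD;
* the **composite quadrigenic** disequilibrium $\Delta_{AABB}$: the
  residual four-gene association, absorbing the product of gametic and
  nongametic digenic terms that unphased data cannot separate;
* the **zygotic LD** $\omega_{AABB} = P_{AABB} - P_{AA}P_{BB}$: the
  deviation of the double-homozygote frequency from the product of its
  margins, a complex function of all lower-order terms:
  $$\omega_{AABB} = 2p_A D_{ABB} + 2p_B D_{AAB}
    + 2 p_A p_B \Delta_{AB} + \Delta_{AB}^2 + \Delta_{AABB}.$$

Under random union of gametes (RUG) every nongametic and higher-order
term vanishes, $\Delta_{AB} = D_{AB}$, and
$\omega_{AABB} = 2p_Ap_B D_{AB} + D_{AB}^2$ — the classical
double-homozygosity route to gametic LD. The interest of the full
decomposition is precisely that it does not require RUG.

## Estimation

The saturated multinomial model for the nine unphased two-locus genotype
classes has as many free parameters as degrees of freedom, so maximum
likelihood estimation reduces to the plug-in rule: every parameter formula
is applied to observed genotype proportions. `pairDiseq()` implements the
hierarchy constructively from the 3×3 table of counts $n_{xy}$ (x, y =
dosage of the designated A and B alleles):

* $\hat p_A = \sum_{x,y} x\, n_{xy} / 2n$, $\hat P_{AA} = n_{2\cdot}/n$,
  $\hat D_A = \hat P_{AA} - \hat p_A^2$;
* $\hat\Delta_{AB} = \sum_{x,y} x y\, n_{xy}/2n - 2\hat p_A \hat p_B$;
* trigenic frequencies as per-individual counts of (A, A, B) gene triples,
  $\hat P_{AAB} = \sum_y y\, n_{2y}/2n$ (and symmetrically
  $\hat P_{ABB}$), from which
  $\hat D_{AAB} = \hat P_{AAB} - \hat p_A^2 \hat p_B - \hat p_B \hat D_A -
  \hat p_A \hat\Delta_{AB}$;
* $\hat\Delta_{AABB}$ by exact inversion of the $\omega_{AABB}$ expansion,
  so that the reconstruction of $P_{AABB}$ from the estimated components
  reproduces the observed $n_{22}/n$ to machine precision for *any* table
  — an identity the test suite checks on random tables.

The same functions accept a table of exact population cell probabilities
(`n = Inf` mode); the generator truths used throughout the tests are
defined by the identical formulas, so estimator and truth can never drift
apart (the plug-in identity).

Gametic LD itself is estimated by the standard two-locus EM algorithm
(`emGameticLD()`): only the double-heterozygote cell is phase-ambiguous,
and its coupling/repulsion split is re-weighted by the current haplotype
frequency estimates. We initialize at linkage equilibrium and declare
convergence when no haplotype frequency moves by more than `tol` (1e-10).
A table consisting only of double heterozygotes leaves the likelihood
flat at the starting point; rather than pick a phase arbitrarily the
estimate is reported as $\hat D = 0$ with an `em_flat` flag. Note that
the E-step's within-cell weighting is a random-union argument; the
composite LD is the estimate that is entirely free of HWE assumptions,
which is why the two are reported side by side.

Missing genotypes are handled by pairwise-complete deletion: every
statistic uses the animals with both (or, for single-locus summaries, the
one) markers called, and the per-pair $n$ records that count. This is a
package design choice; with SNP-chip missingness well below a few percent
it is inconsequential, but users with structured missingness should
filter first.

## Testing and the generalized squared correlation

Each component is tested against zero with a one-degree-of-freedom
chi-square statistic:

* for gametic, composite and zygotic LD, $X^2 = n r^2$ with the
  appropriate squared correlation: $r^2_{GLD} = \hat D^2/(\hat p_A \hat
  p_a \hat p_B \hat p_b)$; $r^2_{CLD} = \hat\Delta^2/[(\hat\pi_A + \hat
  D_A)(\hat\pi_B + \hat D_B)]$ with $\pi = p(1-p)$ (the no-higher-order
  approximation of the composite-LD variance); and $r^2_{ZLD}$ from the
  2×2 collapse of double-homozygote indicators at the two loci;
* for the trigenic and quadrigenic components, $X^2 = \hat D^2 /
  \widehat{\mathrm{Var}}(\hat D)$ with a sampling variance from the
  delta-method engine below.

Strength is summarized by the generalized squared correlation
$\varphi^2 = X^2/n$, which coincides with $r^2$ exactly for the 2×2-table
statistics (GLD, ZLD) and approximately for CLD. $\varphi^2$ values
outside $[0, 1]$ are treated as outliers: `oobFilter()` removes them
before any summary and tallies the below-zero and above-one cases
separately per component.

The critical value is the 95th percentile of $\chi^2_1$, 3.84 at two
decimals. Following the convention of reporting "power when the
hypothesis tested is true", the empirical rejection rate under a true
null equals the significance level; the acceptance script and the test
suite verify this calibration for the composite-LD and zygotic-LD tests
on 2,000 null pairs at $n = 1023$.

### The delta-method variance engine

All statistics here are smooth functions $T(q)$ of the nine cell
proportions, which under multinomial sampling of $n$ diploids have
covariance $\Sigma_{kl} = (\delta_{kl} q_k - q_k q_l)/n$. The engine
computes $\mathrm{Var}(T) \approx g^\top \Sigma g$ with $g = \partial
T/\partial q$ — analytically for the built-in statistics (the gradients
are cross-checked against central differences in the tests, step 1e-6)
and numerically for any user-supplied `statFun`. Because $\Sigma$
annihilates the all-ones direction, the gradient may be taken treating
the nine cells as free coordinates. Two consequences matter:

* $g^\top \Sigma g \ge 0$, so this engine cannot produce negative
  variance estimates; the below-zero branch of the out-of-bound tally is
  structurally empty. Closed-form textbook variance expressions, which
  estimate several moments separately, *can* go negative in finite
  samples — the plug-in slot `deltaVariance(..., statFun = )` accepts
  such alternatives, and negative values then propagate to
  $\varphi^2 < 0$ and are counted by `oobFilter()`.
* the approximation is first-order; the test suite verifies agreement
  with empirical sampling variances within 10% at $n = 1023$ for a
  mixture population with MAF 0.3, and with the nonparametric bootstrap
  on a fixed table.

Estimator bias is of order $1/n$ (e.g. $E(\hat p_A^2) - p_A^2 =
[p_A(1-p_A) + D_A]/2n$, an exact identity the tests confirm by
simulation) and is ignored at the sample sizes this package targets,
consistent with large-sample inference.

## Quality control and allele orientation

`qcFilter()` applies five ordered removal rules — monomorphic, unmapped,
sex chromosome, MAF ≤ 0.02 (strict), single-locus HWD $X^2 = n\hat f^2 >
600$ — with each marker counted under the first rule that removes it, so
the QC report categories are additive. The HWD statistic is the standard
one-df chi-square; the defaults mirror common SNP-chip practice for
composite beef populations. After filtering, dosages are re-oriented so
the designated A allele is the minor allele; the orientation is recorded
and never re-derived downstream, keeping the signs of all disequilibria
consistent within a run.

The zygotic LD is defined for one double-homozygote corner of the table.
The package defaults to the corner of the designated (minor) alleles and
exposes `zygotic = "opposite"` for the major-allele corner. The two are
not equivalent: at low MAF the minor-corner double homozygote is rare and
its test is weak, while the major-corner test is strong — so the
*direction* in which ZLD power moves across MAF classes depends on this
convention. With the major-allele corner the package reproduces, as a
relative trend against composite LD, the empirical observation that the
zygotic-LD test loses power at intermediate allele frequencies where the
digenic tests gain it; the absolute direction of that trend in any given
dataset depends on how association strength co-varies with allele
frequency in that population, and the test suite asserts only the
relative form.

## The synthetic-data generators

No genotype data are distributed with the package; all validation runs on
simulated populations with known truth.

* `simulateRUG()` draws $2n$ gametes i.i.d. from four haplotype
  frequencies — the null model in which only gametic LD exists.
* `simulateCellProbs()` samples the saturated nine-cell distribution —
  arbitrary truth for estimator recovery tests.
* `simulateAdmixture()` emulates a multi-breed composite: generation 0
  assigns each animal a founder line (Wahlund regime — HWE and linkage
  equilibrium within line, admixture-induced HWD and LD at all distances
  between lines), and optional later generations apply random union of
  gametes with recombination at min(0.5, d × 1e-8) between markers d bp
  apart (the 1 cM = 1 Mb equivalence). The exact population truth is
  available in closed form: the generation-0 mixture cells, and from
  generation 1 on a RUG population whose gametic LD decays by (1 − c)
  per generation — so HWD and the higher-order terms vanish after one
  generation of full random mating, as theory requires.
* `simulateGenome()` builds a genome-scale panel: marker positions
  uniform on each chromosome; per-line allele frequencies deviate from a
  base frequency by a latent Gaussian field on the logit scale,
  autocorrelated along the chromosome as a mixture of exponential scales
  (0.02, 0.1, 0.5, 2.5 and 12.5 × the 1 Mb decay scale, with variance
  shares 0.15/0.15/0.2/0.3/0.2). A single exponential scale produces LD
  that dies abruptly; the scale mixture gives the slower-than-exponential
  decay over 25 kb to 5 Mb that genome-wide panels actually show, plus a
  long-range floor from line differentiation that persists between
  unlinked and non-syntenic markers. Defaults emulate a composite beef
  population: 29 bovine-like autosomes, n = 1023 animals, 12 founder
  lines with gently unequal contributions, logit-scale differentiation
  1.2 (breed-level $F_{st}$ of roughly 0.05-0.15 at intermediate
  frequencies).

What the generator does **not** emulate: selection (so any selection-
induced long-range LD is absent), pedigree structure and family
correlation, genotyping error, and drift in small sire families. Passing
tests on these populations therefore demonstrate correctness of the
estimators and the qualitative architecture (decay with distance, digenic
> trigenic > quadrigenic ordering, calibrated nulls), not quantitative
agreement with any real cattle population.

## Problem sizes used in validation

The test suite exercises the full pipeline at sizes chosen to make the
asserted properties statistically stable: the genome-architecture checks
use 16 chromosomes of 6 Mb with 110 markers each (≈ 96,000 syntenic
pairs) and 600 animals; null calibration uses 2,000 pairs of 1,023
animals; estimator-recovery runs 200 replicates at n = 10,000; the
variance-engine check 5,000 replicates at n = 1,023; the bias-law check
10,000 replicates. Full bovine-scale scans (tens of millions of syntenic
pairs) are outside what a single scan call is meant to do in one go;
`enumeratePairs()` supports distance capping and seeded subsampling, with
the enumerated total recorded so proportions remain estimable.

## Numerical notes and limitations

* All pair statistics are computed vectorized over pairs from indicator
  cross products, so a scan is a handful of matrix products plus
  column-wise algebra; results are deterministic given the panel, the
  pair list and the seed.
* Pairs that are monomorphic among their pairwise-complete animals, or
  whose zygotic margins are degenerate, carry `NA` statistics and flags;
  summaries exclude undefined tests from numerators and denominators and
  report exclusion counts.
* Distance bins are half-open $[lo, hi)$; MAF classes are half-open with
  a closed top at 0.5; the linked/unlinked split is ≤ 50 Mb vs > 50 Mb
  exactly.
* No multiple-testing correction is applied anywhere — the reported
  "power" values are per-test rejection rates by design.
* Only biallelic loci and two-locus (digenic through quadrigenic)
  structures are in scope; three-locus disequilibria and phased data are
  not.
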