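---
title: "Joint association patterns across GWAS and omics QTL summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint association patterns across GWAS and omics QTL summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patmix)
```

## The problem

A SNP reported by a GWAS usually sits in a non-coding region, and the
mechanistic question — does it act through expression, methylation, protein
abundance, in which tissue? — is best asked by integrating the GWAS
statistics with several sets of omics QTL summary statistics.  Two
obstacles make the naive lookup ("is it significant in each study?")
unreliable: the studies may share samples, so their test statistics are
correlated even at null SNPs, and linkage disequilibrium (LD) makes a SNP
appear associated with a molecular trait merely because it travels with
the region's lead QTL.

`patmix` addresses both.  For $m$ SNPs and $J$ studies it models the
$m \times J$ statistic matrix $T$ as a mixture over the $K = 2^J$
*joint association patterns* $q_k \in \{0,1\}^J$: pattern
$q_k = (1,0,1)$, say, means "associated with traits 1 and 3, not 2".
The posterior probability that SNP $i$ carries pattern $k$ is

$$
P(a_i = k \mid T_i) \;=\;
\frac{\pi_k\, D_k(T_i)}{\sum_{b=1}^{K} \pi_b\, D_b(T_i)},
$$

where $\pi_k$ is the genome-wide frequency of pattern $k$ and $D_k$ the
joint density of a statistic vector under that pattern.  The $\pi_k$
separate *biological co-occurrence* from the *sample-overlap correlation*
$\Gamma$, which enters $D_k$ instead.

## Per-study marginal densities

### t-statistic mode

Each study contributes an empirical null and alternative marginal density
estimated from all of its statistics, in the moderated-t framework:

* the residual variance of each single-SNP regression is recovered from
  the reported standard error, the minor allele frequency and the sample
  size, $s^2 = \mathrm{se}^2 \cdot 2N\,\mathrm{MAF}(1-\mathrm{MAF})$
  (covariates assumed independent of genotype);
* a scaled inverse-chi-squared prior with hyperparameters $(d_0, s_0^2)$
  is fitted to the $s^2$ by moment matching on $\log s^2$
  (digamma/trigamma equations, via `limma::fitFDist`), and each SNP's
  variance is shrunk to its posterior value;
* the moderated t-statistic $t = \hat\beta / \sqrt{\tilde s^2 w}$, with
  $w = 1/(2N\,\mathrm{MAF}(1-\mathrm{MAF}))$, has $d = d_0 + d_1$ degrees
  of freedom under the null;
* under the alternative the statistic is modeled as a scaled t variable
  with SNP-specific scaling $v = \sqrt{1 + v_0/w} \ge 1$, where $v_0$ is
  the variance of the effect-size prior.

The only user-set parameter is $\theta^1_j$, the marginal proportion of
truly associated SNPs in study $j$.  Defaults are $10^{-3}$ for omics QTL
studies and $10^{-5}$ for GWAS; mild under-specification is safe (and is
checked in the misspecification harness), over-specification by an order
of magnitude inflates the FDR.

**The $v_0$ estimator.**  The literature the moderated-t machinery comes
from does not pin down $v_0$ estimation for this setting, so the package
fixes one variant and tests its recovery.  Take the
$\lceil \theta^1 m \rceil$ largest $|t|$; the statistic of rank $r$ has
expected two-sided mixture tail probability $(r - 0.5)/m$, which can be
solved for the implied alternative tail probability and hence an implied
scaling $(t/q_{\text{target}})^2$ and an implied $v_0$, clipped at zero.
Terms whose implied alternative tail probability reaches $1/2$ are
excluded from the average: there the target quantile approaches zero and
the inversion becomes ill-conditioned (any finite statistic would imply
an enormous $v_0$); each retained term is individually consistent for
$v_0$, so the restriction costs nothing asymptotically.  Recovery within
20% relative error at $m = 10^6$ is part of the test suite, as is a
cross-check against `limma::tmixture.vector`.

### P-value mode

When only $P$ values are available (one-sided tests, F tests, \dots) the
statistics are $t = -2\log p$, which are $\chi^2_2$ under the null.  The
genome-wide alternative — a mixture of non-central chi-squared
distributions — is approximated by a scaled chi-squared $A\chi^2_{d'}$
whose parameters minimize a rank-based tail criterion: the mixture CDF
evaluated at the top-ranked statistics should match their nominal tail
probabilities $(r-0.5)/m$, summed over ranks up to
$\max(20, \tfrac{m}{2}\theta^1)$.  The optimizer is a derivative-free
Nelder–Mead on $(\log A, \log d')$ from a $4\times4$ multi-start grid
($A \in \{0.5,1,2,4\}$, $d' \in \{2,4,8,16\}$), with a coarse-lattice
fallback.  A sanity check on the null median of $-2\log p$ guards against
accidentally supplying decimal-log-transformed values.

## Pattern-specific joint densities

With independent studies, $D_k$ is the product of the chosen marginal
null/alternative densities.  With possibly overlapping samples the t-mode
marginals are approximated by zero-mean normals with variances
$v^{2q_{kj}}\, d_j/(d_j - 2)$ and coupled through $\Gamma$:
$D_k = \mathcal N(0, \Sigma_k^{1/2} \Gamma \Sigma_k^{1/2})$.  This
normal/t asymmetry between the independent and correlated paths is
deliberate — the normal approximation makes $K$ density evaluations per
SNP cheap and yields closed-form conditional densities later — and the
two paths agree when $\Gamma = I$ and $d \to \infty$ (asserted in the
tests).

$\Gamma$ is estimated once, as the Pearson correlation of the statistics
over SNPs with $|t| < 5$ in every study (a configurable threshold): at
null SNPs the only correlation left is the sample-driven one.  Truncation
can leave the sample correlation indefinite, so it is projected to the
PSD cone by eigenvalue clipping at $10^{-8}$ and diagonal renormalization.
$\Gamma$ is never updated afterwards.

In correlated P-value mode the published construction ("multivariate
gamma") is not defined constructively; the package couples the exact
chi-squared-family marginals with a Gaussian copula with correlation
$\Gamma$, and documents this as an approximation.  It is excluded from
the calibration targets.

## Estimating the mixing proportions

The $\pi_k$ are estimated by EM with the densities held fixed — there is
no need to re-estimate $D_k$ within the loop.  Numerical choices:

* initialization at the independence product
  $\pi_k^{(0)} \propto \prod_j (\theta^1_j)^{q_{kj}} (1-\theta^1_j)^{1-q_{kj}}$,
  which is strictly positive and consistent with the user's marginals;
* a working floor of $1/(100m)$ on the proportions prevents sparse
  patterns from being absorbed at zero (an EM fixed point); the floor is
  removed from the reported estimate;
* convergence when $\max_k |\Delta\pi_k| < 10^{-6}$, capped at 1000
  iterations; the observed-data log-likelihood is non-decreasing across
  iterations and this is asserted in the tests;
* posterior rows are computed by log-sum-exp and sum to 1 within
  $10^{-10}$; exact posterior ties resolve to the pattern with fewer
  associations (the conservative call).

Pattern groups ("associated with the trait and at least one omics
trait") are posterior sums over their member patterns, and multiple
testing uses the posterior-based estimated FDR
$\mathrm{estFDR}(\lambda) = \sum_i (1-\hat P_i)\,1(\hat P_i \ge \lambda) /
\#\{\hat P_i \ge \lambda\}$, reported as `NA` when no SNP reaches the
threshold.  The cutoff $\lambda$ is user-facing and never optimized
internally.  For more than 15 studies the pattern space is not
enumerated; studies are grouped and group-level no-association
probabilities combine as $1 - \prod_g \Pr(\text{null in } g)$.

## Conditional analysis in LD regions

Within a region harboring a trait-associated focal SNP, each omics
study's lead SNP (largest collapsed association probability; ties to the
smaller $P$ value) is a conditioning candidate, excluded when it *is* the
focal SNP, lies within 5 kb, or has $r^2 > 0.9$ with it — in those cases
the two signals cannot be separated, and the pair is flagged rather than
conditioned.  The joint statistic vector of (focal, leads) in study $j$
is modeled as multivariate normal with covariance built from the
pattern-specific standard deviations and the genotype correlations:
$\Lambda_{ab} = \sigma_a \sigma_b \rho_{ab}$, the focal entry under the
null or alternative, each lead under its most plausible (maximum
posterior) pattern.  Partitioning $\Lambda$ gives the focal statistic's
conditional normal density — mean $\Lambda_{12}\Lambda_{22}^{-1}t_{I'}$,
variance the Schur complement — under both focal hypotheses; these
replace the marginal densities, studies are recombined through $\Gamma$,
and the posterior is re-evaluated with the genome-wide $\pi$ held fixed.
A focal SNP "loses" an association when its top pattern changes.

Degenerate cases: an empty lead set reproduces the marginal posterior
exactly; an indefinite assembled covariance receives a $10^{-6}$ ridge on
the lead block; a singular lead block drops the most collinear lead
(largest mean $|\rho|$ with the others) and retries.

After conditioning, the estimated FDR is corrected by counting each
discovery that failed the conditional pass as a full estimated false
discovery (its numerator term becomes 1), with the denominator frozen at
the pre-conditioning discovery count so the two stages are comparable.

## What the synthetic-data generators emulate

`simulate_stats_direct()` draws each SNP's pattern from $\pi$ and its
statistics as correlated normals, with alternative means
$\sqrt{N}\,\beta$, $\beta \sim N(0, \sigma^2)$ — the non-centrality a
single-variant test of that effect would have.  It reproduces the
statistical structure the inference sees (sparse patterns, overlap
correlation) without genotypes; the sparse three-study calibration runs
use it at $10^6$ SNPs per replicate with effect SD 1 and
$N$-equivalent 1000.

`simulate_geno_pheno()` generates Binomial(2, MAF) genotypes
(MAF ~ U(0.05, 0.5)) in gene regions of 500 SNPs, additive phenotypes
with error terms correlated 0.2 across traits, and computes true
single-variant regression summary statistics; studies with smaller
sample sizes analyze subject subsets resampled from the common pool, so
their samples overlap.

The LD-confounder design (`ld_blocks = TRUE`, J = 4, regions of 1000
SNPs) plants in every region a triple — a focal "known trait-associated
SNP" (MAF > 0.1) and two confounders — with all three pairwise genotype
correlations inside [0.5, 0.8].  The triple is a chain of
copy-and-resample toggles in random order, so the two directly coupled
pairs sit high in the range and the indirect pair spans its lower part;
realized correlations are verified and the block is resampled if the
target is unreachable.  In 20% of regions the focal SNP carries pattern
(1,0,1,0) with confounders (1,1,0,0) and (0,1,1,1); in another 20% the
focal is (1,1,1,1) with single-trait confounders; 60% are null.  Effect
magnitudes are uniform on [0.1, 0.4] with random signs and are applied
per standard deviation of genotype dosage, i.e. an effect of 0.3
explains the same trait variance at any MAF — the convention of
variance-standardized molecular phenotypes; with sample sizes
(1000, 500, 300, 200) this puts the smallest study's non-centralities in
the detectable-but-not-saturated range.  Unit residual error SD
throughout.

What these generators do *not* emulate: realistic LD beyond the planted
triples (every other SNP is independent), allele-frequency spectra,
winner's-curse selection of the focal SNPs, or study-specific genomic
inflation.  Passing the calibration harness therefore demonstrates
correctness of the estimation machinery under the stated structure, not
performance on real cohorts.

A structural caveat worth stating plainly: with pairwise LD of
0.5–0.8 and bounded effect magnitudes, a focal SNP's LD-leaked
statistics are $\rho$ times its confounders' — the same order as a true
weak signal — so the mixture genuinely (and correctly, in the purely
associational sense) assigns such SNPs high multi-trait probabilities,
and the conditional adjustment, whose focal-null conditional mean
carries the coefficient $\rho\,\sigma_{f0}/\sigma_\ell \approx \rho/v$,
discounts only borderline calls.  Causal false discovery rates among
LD-confounded focal SNPs therefore remain well above the
posterior-implied estimates in this design; the conditional pass tempers
rather than eliminates them.

## Reproducibility and problem sizes

All generators are seed-deterministic (identical spec and seed give
bit-identical output; replicates and blocks derive independent
sub-seeds).  The shipped calibration harness (`run_scenario()`, also
driven by `scripts/acceptance.R` and the acceptance tests) uses
$10^6$ SNPs x 5 replicates for the sparse three-study design and
100 regions x 1000 SNPs x 20 replicates for the LD design — sizes chosen
so a full calibration completes in minutes on a single core while
keeping Monte-Carlo error well inside the comparison tolerances.

## Known limitations

* The correlated P-value path is a copula approximation, not the
  published (undefined) multivariate-gamma construction.
* Conditional analysis assumes the supplied genotype correlations match
  the population the summary statistics came from; mismatched LD
  reference panels will mis-calibrate the conditional densities.
* SNP matching is by exact identifier with no allele harmonization:
  callers must pre-harmonize effect alleles, since a silent strand flip
  would corrupt statistic signs undetectably.
* Patterns are enumerated exhaustively; beyond 15 studies use the
  grouping extension.
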