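---
title: "Selection efficiency and deleterious load in tumor evolution: models and methods"
author: "tumorload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection efficiency and deleterious load in tumor evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Somatic tumor evolution is asexual: without recombination, selection acts on
whole genomes rather than on individual mutations. Linked selection
(Hill-Robertson interference) then lets deleterious passenger mutations fix by
hitchhiking alongside strong drivers, and lets Muller's ratchet erode the
fittest genotype class, so the signature of negative selection in cancer
genomes (dN/dS < 1 in non-driver genes) is expected to fade as the genome-wide
mutational burden rises. This package provides the four ingredients needed to
quantify that prediction end to end on synthetic data with known ground truth:

1. a non-parametric, permutation-based dN/dS estimator for somatic SNVs
   (`perm_dnds()`, `bootstrap_dnds()`);
2. dE/dI selection statistics for copy-number alterations with a
   length-preserving permutation null (`dedi()`, `permute_cnas()`);
3. a stochastic birth-death simulator of tumor progression with drivers,
   passengers and density regulation (`run_simulation()`);
4. approximate Bayesian computation over a driver/passenger fitness-effect
   grid (`run_param_sweep()`, `rejection_and_adjust()`).

# The permutation dN/dS estimator

Mutational processes in cancer are biased by trinucleotide context, gene and
patient; an unadjusted dN/dS confounds these biases with selection. The
estimator here replaces parametric bias models with an exhaustive,
highly constrained permutation. Every observed coding mutation is permuted
over all CDS positions *of the same gene* where the *same base change in the
same trinucleotide context* could occur. Because the permutation set per
mutation is small and fully enumerable, the expectation is computed
analytically: a mutation of type $i$ in gene $g$ contributes
$N_{ig}/(N_{ig}+S_{ig})$ to the expected nonsynonymous tally and
$S_{ig}/(N_{ig}+S_{ig})$ to the expected synonymous tally, where $N_{ig}$ and
$S_{ig}$ count the nonsynonymous and synonymous opportunities of type $i$ in
gene $g$ (`enumerate_opportunities()`). No resampling is involved, and the
two expected tallies sum exactly to the number of observed mutations. The
statistic is

$$ dN/dS \;=\; \frac{d_N^{obs} / d_N^{perm}}{d_S^{obs} / d_S^{perm}}. $$

Confidence intervals and p-values come from bootstrapping patient samples on
the log scale (log transformation stabilizes the ratio and increases power
when aggregating). Pooling is deliberate: within a burden bin all variants
are pooled and one joint estimate formed, because per-gene estimates are
hopelessly underpowered in the low-burden regime of interest.

Two conventions worth noting: mutation channels use the pyrimidine-strand
96-channel convention (6 base changes x 16 flanking pairs), and the first and
last CDS positions are excluded from enumeration since they lack an
intragenic trinucleotide context. Nonsense changes count as nonsynonymous.
Stop-loss substitutions in a terminal stop codon are classified as missense.

The synthetic cohort generator (`simulate_cohort()`) inverts the estimator's
logic to create ground truth: mutations are placed on context-eligible sites
with probability proportional to a signature-mix weight times site
availability, then selection of known strength $\omega$ is injected by
thinning nonsynonymous mutations at rate $1-\omega$ (for $\omega < 1$; for
$\omega > 1$ synonymous mutations are thinned at $1-1/\omega$, an extension
used to exercise the driver side). The bundled signature mixes are
deliberately skewed synthetic spectra (CpG-heavy, UV-like, APOBEC-like, and a
single-channel extreme); they are not catalog signatures, and nothing in the
tests depends on real signature weights.

# dE/dI for copy-number alterations

For CNAs the analog of dN/dS compares CNA signal density on exonic versus
non-coding (intronic + intergenic) tracks. Two metrics are supported:
*breakpoint frequency* (each CNA deposits one unit of mass at each terminus)
and *fractional overlap* (density $1/L$ across the spanned interval, total
mass 1). The statistic is the ratio of mass per mappable base on the exonic
track to the same density on the intronic+intergenic track; masked telomere
and centromere regions are excluded from both the tallies and the track
lengths. Under uniform random placement both densities estimate the same
constant, so dE/dI is ~1 without selection — verified by the
length-preserving permutation null (`permute_cnas()`), which redraws each
CNA's position uniformly on its own chromosome while keeping its length.

Numerical conventions: CNA intervals are half-open `[start, end)` with
`L = end - start`; the termini are `start` and `end - 1`; breakpoint
membership in a track interval is decided by simple containment of the
terminus base. Non-focal CNAs (a terminus inside a masked region) are
aggregated with the long (> 100 kb) class. Sample-level CNA burden is simply
the CNA count per sample. Cross-chromosome moves during permutation are
disallowed (conservative choice; placement is per chromosome).

# The evolutionary simulator

`run_simulation()` implements a continuous-time birth-death process over a
well-mixed population of tumor cells. Cell fitness starts at 1; at each
division the daughter acquires `Poisson(mu * T_drivers)` drivers and
`Poisson(mu * T_passengers)` passengers with exponentially distributed
effects (drivers positive with mean `s_drivers`, passengers negative with
mean `s_passengers`). Fitness composes multiplicatively,
$f = \prod_i (1+s_i)$, or under diminishing returns,
$\Delta f = s/(1+\nu f)$ with $\nu = 1$. Birth rate is proportional to $f$;
the per-cell death rate $D(N; N^0) = \ln(1 + N(e-1)/N^0)$ rises with
population size, which yields Gompertzian density regulation with
equilibrium at $N^0$ for neutral populations ($D(N^0) = 1$ balances the unit
birth rate). A simulation ends in extinction ($N=0$), malignancy
($N \ge 10^6$ cells at full scale), or timeout (18,500 generations,
about 100 years). The default target sizes are 286,886 driver loci (a
300-gene driver set) and 20,451,136 passenger loci (the rest of the coding
genome); the full-scale mutation-rate prior is log-uniform over
$10^{-12}$–$10^{-7}$ per nucleotide per generation.

Mutations affect the birth rate exclusively, and crowding affects the death
rate exclusively; birth rate proportional to $f$ is the only convention
under which drivers are advantageous, and is the one implemented. Because
birth and death rates stay nearly balanced through most of a tumor's
history, this partition does not itself shape the dynamics.

Implementation: identical genotypes are aggregated into clones, and two
Fenwick trees index clones by birth weight (`count * fitness`) and by count,
so event selection costs O(log #clones) even in the Muller's-ratchet regime
where every division founds a new clone. This aggregation is statistically
identical to per-cell simulation. The full genealogy is retained, and at
termination the most recent common ancestor of the surviving clones is
extracted exactly; *fixed* mutations are those on the root-to-MRCA path.
The generation clock advances by `dt * <B>` where `<B>` is the mean per-cell
birth rate (generation time `1/<B>`). `t_MRCA` is recorded as the
generation count at the MRCA clone's birth — with clone aggregation the
per-lineage division count is not tracked individually, and one division
per generation per surviving lineage is the model's own expectation.

Because only nonsynonymous mutations carry fitness effects, synonymous
mutations are attached to outcomes afterwards as Poisson draws with mean
$(\mu T / r)\, t_{MRCA}$ for each target region, where $r = 2.795$ is the
genome-wide nonsynonymous-to-synonymous locus ratio. Models with synonymous
drivers relabel each fixed nonsynonymous driver as synonymous with
probability 0–20%, keeping its fitness effect.

## Calibration of the initial population size

The probability that a simulated tumor progresses depends strongly on
$N^0$. `calibrate_n0()` finds the $N^0 \in [1, 100]$ at which the
progression probability is 0.5, by stochastic bisection over pilot
simulation batches with Wilson score intervals; the first-order manifold
$N^0 \approx T_p s_p / (T_d s_d)$ seeds the search. Two simplifications are
deliberate. First, the separate mean-waiting-time condition is subsumed by
the empirical estimate, because pilot simulations enforce the
18,500-generation cap (a tumor that would take longer counts as a failure).
Second, in the grid sweep $N^0$ is calibrated once per cell at a reference
mutation rate of $3.2\times10^{-9}$ (the center of the malignancy-feasible
range) and shared across that cell's tumors, rather than per tumor; the
closed-form progression-probability manifold that would make per-tumor
calibration cheap belongs to prior work and is out of scope here. At pilot
budgets of a few dozen simulations, the `progression_impossible` annotation
means "no progression observed within the pilot budget" rather than a
calibrated bound of 0.1%.

# Summary statistics and ABC

Nine statistics summarize a cohort: driver and passenger dN/dS in the burden
bins (0,10], (10,100], (100,1000]; the two parameters of a negative binomial
fit to mutational burdens over the support [1, 1000] (truncated maximum
likelihood, quasi-Newton with moment-based multi-start); and the shape $k$
of a gamma fit to transformation times (the scale $\theta$ is a pure time
gauge — simulations measure generations, not years — and is excluded).
Observed-style cohorts use the permutation dN/dS; simulated cohorts use the
locus-ratio-corrected count ratio $d_N/(d_S \cdot r)$. Gamma fits use the
CDF by least squares for observed incidence curves (ages under 20 excluded,
curve normalized to a proper CDF) and the PDF by maximum likelihood for
simulated times, which all start at $t = 0$.

ABC compares summary vectors with a log-Euclidean distance (all nine
statistics live on $[0,\infty)$; logs tame heteroscedasticity; variances are
deliberately not normalized). The rejection step keeps the nearest
`tolerance` fraction of simulations; the regression adjustment fits a
bagged ensemble of single-hidden-layer neural networks (`nnet`) predicting
log-parameters from summaries and shifts each accepted draw by the
difference between the ensemble-median prediction at the observed summaries
and the draw's own out-of-bag prediction. Out-of-bag residuals matter at
small accepted counts: an interpolating ensemble would otherwise drive the
residuals — and with them the whole posterior — to a point, manufacturing
precision the reference table cannot support; a parameter the summaries
cannot predict keeps a posterior as wide as its accepted draws.
Posterior draws are unweighted; point estimates are modes of
Gaussian kernel densities over adjusted log-parameters (plug-in bandwidth),
and intervals are posterior quantiles. The ensemble defaults to 100
networks at desk scale — the median prediction stabilizes far below the
10,000 used in full-scale reproduction — and leave-one-out cross-validation
(`loo_cv()`) compares method x tolerance configurations by mean squared
log-parameter prediction error. Model choice over synonymous-driver
fractions uses a multinomial logistic regression of the model indicator on
log summaries over the accepted set; the posterior mass at fraction 0 acts
as a one-sided p-value for the no-synonymous-drivers null.

# Desk-scale study conditions and their consequences

The package's own analyses and tests run at desk scale: an 8x8 grid over
the priors ($s_{drivers} \in [10^{-2},10^0]$,
$s_{passengers} \in [10^{-4},10^{-2}]$, both log-spaced), 200 simulation
attempts per cell, malignancy at $10^4$ cells, and the full log-uniform
mutation-rate prior. Full-scale reproduction (20x20 cells, 10,000 cancers
per cell, $10^6$-cell malignancy, observed tumor-cohort and registry
incidence summaries) is a
cluster-scale computation and is intentionally out of desk scope, as are
the headline fitness-effect point estimates that require the observed data.

Two desk-scale consequences are handled explicitly rather than silently:

* **Sparse synonymous drivers.** The driver target is ~1% of coding loci,
  so in low-burden bins the expected synonymous driver count per tumor is
  of order 0.03; with hundreds rather than thousands of cancers per cell, a
  zero tally in the (0,10] bin is the norm, and a dN/dS built on it is
  undefined. The estimator's contract prescribes widening the bin in that
  case, so `binned_dnds(..., widen = TRUE)` merges a zero-$d_S$ bin with its
  right neighbor (the last bin widens leftward) and fills both entries with
  the merged estimate. The sweep applies the same rule to every cell and to
  the pseudo-observed cohort, keeping the nine-dimensional summary
  comparable across the table. The default remains a hard error.
* **Cells that cannot support the summaries.** Cells flagged
  `progression_impossible`, or whose malignant outcomes cannot support all
  nine statistics even after widening (too few cancers for the burden fit,
  for instance), carry `NA` summaries and are excluded from the regression,
  mirroring the annotation-and-exclude treatment of impossible cells at
  full scale.

What passing desk-scale tests does and does not show: the generators
emulate signature-biased spectra, negative-binomial burdens,
length-distributed CNAs and burden-linked expression, with every ground
truth recoverable by the corresponding pipeline stage; they do not emulate
real human genome structure, real signature catalogs, subclonal copy-number
complexity, or purity/ploidy artifacts, so desk-scale green means the
*methods* are correct and calibrated, not that any biological claim about
real tumors has been re-established.

# Numerical choices and degenerate inputs

* dN/dS with $d_S^{obs} = 0$ or a zero expectation is an error, never an
  Inf; callers widen bins.
* The purity adjustment is `vaf / purity`, capped at 1; missing VAF or
  purity yields clonality `"unknown"`. The threshold (default 0.2) applies
  to the adjusted VAF, with ties going to "clonal".
* Negative binomial and gamma fits use log/logit-transformed parameters,
  multi-start quasi-Newton optimization, and fail loudly on degenerate
  input (all-equal burdens, fewer than 5 time points, fewer than 30
  burdens in support).
* Neural-network inputs are z-scored with zero-variance guards; zero-spread
  posterior draws fall back to the draw itself as the mode.
* Fitness driven to or below zero marks a lethal cell (birth rate zero)
  rather than an error.
* All generators restore the caller's RNG state; every stochastic function
  takes an explicit seed, and identical seeds reproduce identical output
  byte for byte.

# Known limitations

A quantitative property of the pooled permutation estimator deserves
explicit notice. When selection acts on individual sites (each
nonsynonymous mutation surviving with probability $\omega$), categories —
(gene, channel) cells of the opportunity table — whose nonsynonymous
opportunity fraction is close to 1 contribute almost identically to the
observed and the permuted nonsynonymous tallies, so pooling over
heterogeneous categories attenuates strong selection slightly toward 1.
The size of the effect is computable from the opportunity table alone: on
the default synthetic gene models the asymptotic estimate is about 0.54
for a true $\omega$ of 0.5 and about 0.82 for 0.8, and the effect vanishes
at neutrality ($\omega = 1$ is recovered exactly in expectation; the
conservation identity is unconditional). Cohort-level validation schemes
that derive observed tallies from the permuted proportions at the context
level are exact by construction and cannot reveal this attenuation; the
site-level generator used here is the stricter test, and the recovery
tables in `analysis/01_dnds_validation.R` report what it actually
measures.

Other limitations:

* The simulator ignores spatial structure, dominance, ploidy and LOH — by
  the model's own design; fitness-effect estimates are therefore
  heterozygous-effect estimates.
* Desk-scale posterior intervals are wide: an 8x8 table with ~200 attempts
  per cell localizes parameters to within roughly half a decade, not the
  full-scale precision of a 400-cell, 10,000-cancer table.
* `t_MRCA` uses the generation clock, not per-lineage division counts;
  the two agree in expectation but not realization by realization.
* The observed-incidence gamma fit normalizes the input curve to a proper
  CDF, which discards the absolute incidence level; only the shape is
  meaningful downstream, which is also the only quantity the ABC uses.
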