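# tumorload

Selection efficiency and deleterious load in tumor evolution.

Tumors evolve without recombination, so natural selection must judge whole
genomes, not individual mutations. Linked selection (Hill–Robertson
interference) then predicts that the efficiency of selection — against
deleterious passenger mutations and for advantageous drivers — should fall
as the genome-wide mutational burden rises: deleterious passengers hitchhike
with strong drivers and accumulate through Muller's ratchet. `tumorload` is
an R package plus analysis workflow for quantifying that prediction. It is
aimed at researchers in cancer population genetics who want a tested,
ground-truth-validated implementation of the full inference chain on
synthetic data.

## What is inside

* **Permutation dN/dS** (`perm_dnds`, `bootstrap_dnds`): a non-parametric
  null model of mutagenesis. Every observed mutation is permuted over all
  same-gene CDS sites carrying the same base change in the same
  trinucleotide context; because the permutation set is exhaustively
  enumerable, the expectation is analytic,

  `dN/dS = (dN_obs / dN_perm) / (dS_obs / dS_perm)`,

  with `dN_perm + dS_perm = n` exactly. Bootstrap over patient samples on
  the log scale gives intervals and p-values.
* **dE/dI for copy-number alterations** (`dedi`, `permute_cnas`): breakpoint
  frequency and fractional overlap densities on exonic versus
  intronic+intergenic tracks, masked for telomeres/centromeres, with a
  length-preserving permutation null (~1 without selection).
* **A birth–death tumor simulator** (`run_simulation`, Rcpp core):
  Poisson-arriving drivers and passengers with exponential fitness effects,
  multiplicative or diminishing-returns epistasis, birth rate proportional
  to fitness, Gompertzian death rate `log(1 + N(e-1)/N0)`, exact MRCA
  extraction for fixed-mutation reporting, and N0 calibration to a 50%
  progression probability (`calibrate_n0`).
* **ABC inference** (`run_param_sweep`, `rejection_and_adjust`, `loo_cv`,
  `model_posterior`): nine summary statistics (burden-binned driver and
  passenger dN/dS, negative-binomial burden parameters, gamma incidence
  shape), log-Euclidean distance, rejection plus a single-hidden-layer
  neural-network ensemble adjustment, and model comparison over
  synonymous-driver fractions.
* **Synthetic-data generators** (`simulate_cohort`, `simulate_cnas`,
  `make_genome_tracks`, `simulate_expression`, `make_gene_models`): every
  pipeline input with injectable ground truth — signature-biased spectra
  with known true dN/dS, negative-binomial burdens, length-distributed
  CNAs with optional track enrichment, and burden-linked expression.

## Worked example

Recover a known selection strength from a cohort generated under an extreme
trinucleotide bias:

```r
library(tumorload)

gm    <- make_gene_models(n_genes = 100, n_codons = 433, seed = 1)
sites <- enumerate_sites(gm)
opp   <- enumerate_opportunities(sites)

coh <- simulate_cohort(gm, mix = "aging_like", omega = 0.8,
                       burden_dist = 50, n_samples = 100, seed = 3,
                       sites = sites)
est <- bootstrap_dnds(coh$variants, opp, n_boot = 300, seed = 4)
est
#> dN/dS = 0.8069  (dN 2737/2943.47, dS 1562/1355.53)
#>   95% CI [0.7568, 0.8636], p = 0.00333 (300 bootstrap resamples)
```

The cohort was thinned so that a nonsynonymous mutation survives with
probability 0.8; the estimator returns 0.81 with a 95% interval covering
the truth, despite the CpG>T-dominated spectrum. The same machinery drives
the burden-stratified analyses: pool variants within log-scale burden bins
(`burden_bins`, `assign_burden_bin`) and estimate each bin jointly.

The numbered scripts under `analysis/` run the full workflow at desk scale
and write their tables under `results/`:

| script | what it shows |
|---|---|
| `01_dnds_validation.R` | dN/dS recovery for ω ∈ {0.5, 0.8, 1} under five spectra |
| `02_burden_stratified_dnds.R` | driver/passenger dN/dS by burden bin |
| `03_cna_selection.R` | dE/dI neutrality, driver-track enrichment, dilution |
| `04_tumor_simulations.R` | simulator regimes and fixation bias of mild passengers |
| `05_abc_inference.R` | 8×8 sweep, ABC posterior at a known grid point, LOO CV |

`05_abc_inference.R` is the long step (~10–15 minutes); the rest run in
seconds to a couple of minutes.

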