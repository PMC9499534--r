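#!/usr/bin/env Rscript
# Validates the permutation dN/dS estimator on synthetic cohorts with known
# selection strength under strongly skewed mutational spectra. For each
# signature mix and true omega, a cohort is generated by thinning
# nonsynonymous mutations, and the estimator is asked to recover omega.
# Writes results/dnds_validation.tsv.

suppressPackageStartupMessages(library(tumorload))
dir.create("results", showWarnings = FALSE)

gm <- make_gene_models(n_genes = 100, n_codons = 433, seed = 1)
sites <- enumerate_sites(gm)
opp <- enumerate_opportunities(sites)

rows <- list()
mixes <- c("flat", "aging_like", "uv_like", "apobec_like",
           "single_channel")
for (mi in seq_along(mixes)) {
  mix <- mixes[mi]
  for (om in c(0.5, 0.8, 1.0)) {
    coh <- simulate_cohort(gm, mix, omega = om, burden_dist = 50,
                           n_samples = 100, seed = 1000 + 37 * mi + om * 10,
                           sites = sites)
    est <- bootstrap_dnds(coh$variants, opp, n_boot = 300,
                          seed = 2000 + 37 * mi + om * 10)
    rows[[length(rows) + 1]] <- data.frame(
      mix = mix, true_omega = om, n_mutations = nrow(coh$variants),
      dnds = est$ratio, ci_low = est$ci[1], ci_high = est$ci[2],
      covered = est$ci[1] <= om & om <= est$ci[2])
  }
}
out <- do.call(rbind, rows)
write.table(out, "results/dnds_validation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Recovery of injected selection under signature skew:\n")
print(out, digits = 3)
cat(sprintf("\nmax |dN/dS - truth| = %.3f; CI coverage %d/%d\n",
            max(abs(out$dnds - out$true_omega)), sum(out$covered),
            nrow(out)))
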