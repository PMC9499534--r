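# Brute-force oracle: classify every possible substitution of a CDS by
# direct codon mutation and translation, independent of enumerate_sites().
brute_force_sites <- function(seq) {
  gc <- Biostrings::GENETIC_CODE
  b <- strsplit(seq, "")[[1]]
  L <- length(b)
  out <- list()
  for (pos in 2:(L - 1)) {
    for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      mutated <- b
      mutated[pos] <- alt
      prot0 <- gc[substring(seq, seq(1, L, 3), seq(3, L, 3))]
      ms <- paste0(mutated, collapse = "")
      prot1 <- gc[substring(ms, seq(1, L, 3), seq(3, L, 3))]
      ci <- (pos - 1) %/% 3 + 1
      cons <- if (prot1[ci] == "*") "nonsense"
              else if (prot0[ci] == prot1[ci]) "synonymous" else "missense"
      out[[length(out) + 1]] <- data.frame(pos = pos, alt_base = alt,
                                           consequence = cons)
    }
  }
  do.call(rbind, out)
}

test_that("site enumeration matches a brute-force oracle over all 3L subs", {
  for (seq in c("ATGTAA", "ATGCATGCATAG",
                as.character(make_gene_models(1, 20, seed = 5)$cds[[1]]))) {
    gm <- list(cds = stats::setNames(seq, "g1"))
    sites <- enumerate_sites(gm)
    oracle <- brute_force_sites(seq)
    expect_equal(nrow(sites), nrow(oracle))
    merged <- merge(sites, oracle, by = c("pos", "alt_base"))
    expect_equal(merged$consequence.x, merged$consequence.y)
  }
})

test_that("degenerate gene models are handled", {
  expect_equal(nrow(enumerate_sites(list(cds = c(g = "")))), 0)
  expect_error(enumerate_sites(list(cds = c(g = "ATGT"))), "divisible")
  expect_error(enumerate_sites(list(cds = c(g = "TAAATG"))), "stop")
})

test_that("permutation expectation redistributes mass within gene/type", {
  opp <- data.frame(gene = c("g1", "g2"), context96 = c(5L, 5L),
                    n_loci = c(3L, 4L), s_loci = c(1L, 0L))
  v1 <- data.frame(gene = "g1", context96 = 5L)
  e1 <- permutation_expectation(v1, opp)
  expect_equal(unname(e1), c(0.75, 0.25))
  # S = 0: mass goes wholly to the nonsynonymous tally
  v2 <- data.frame(gene = "g2", context96 = 5L)
  e2 <- permutation_expectation(v2, opp)
  expect_equal(unname(e2), c(1, 0))
  # missing entry names the gene and channel
  v3 <- data.frame(gene = "g3", context96 = 5L)
  expect_error(permutation_expectation(v3, opp), "g3")
})

test_that("analytic expectation equals explicit random permutation", {
  set.seed(42)
  sites <- fx_sites()
  opp <- fx_opportunities()
  # 10 observed mutations across 3 genes
  genes <- unique(sites$gene)[1:3]
  pool <- sites[sites$gene %in% genes, ]
  obs <- pool[sample.int(nrow(pool), 10), ]
  analytic <- permutation_expectation(obs, opp)
  # oracle: permute each mutation uniformly over its same-gene same-channel
  # sites, 1e5 draws
  n_draw <- 1e5
  dn <- 0
  for (i in seq_len(nrow(obs))) {
    elig <- pool[pool$gene == obs$gene[i] &
                   pool$context96 == obs$context96[i], ]
    draw <- elig$consequence[sample.int(nrow(elig), n_draw, replace = TRUE)]
    dn <- dn + mean(draw != "synonymous")
  }
  mc_err <- 4 * sqrt(nrow(obs) * 0.25 / n_draw)
  expect_lt(abs(analytic[["dn_exp"]] - dn), mc_err)
  expect_equal(analytic[["dn_exp"]] + analytic[["ds_exp"]], nrow(obs))
})

test_that("dN/dS ratio follows the observed/permuted definition", {
  # neutrality: observed ratio equal to expected ratio
  expect_equal(dnds(6, 2, 6, 2)$ratio, 1)
  expect_equal(dnds(6, 4, 7.5, 2.5)$ratio, 0.5)
  expect_error(dnds(6, 0, 7.5, 2.5), "widen")
  expect_error(dnds(6, 1, 0, 2.5), "zero")
})

test_that("injected selection is recovered under signature skew", {
  gm <- fx_gene_models()
  sites <- fx_sites()
  opp <- fx_opportunities()
  for (om in c(0.6, 1.0)) {
    coh <- simulate_cohort(gm, "apobec_like", omega = om, burden_dist = 40,
                           n_samples = 100, seed = 300 + om * 10,
                           sites = sites)
    est <- perm_dnds(coh$variants, opp)
    expect_lt(abs(est$ratio - om), 0.08)
    expect_equal(est$dn_exp + est$ds_exp, est$dn_obs + est$ds_obs)
  }
})

test_that("bootstrap CI behaves on degenerate and neutral cohorts", {
  sites <- fx_sites()
  opp <- fx_opportunities()
  one <- sites[1:20, ]
  one$sample_id <- "s1"
  expect_error(bootstrap_dnds(one, opp), "2 samples")

  # identical samples: zero-width interval
  v <- do.call(rbind, lapply(sprintf("s%d", 1:8), function(id) {
    x <- sites[5:40, ]; x$sample_id <- id; x
  }))
  bs <- bootstrap_dnds(v, opp, n_boot = 50, seed = 3)
  expect_equal(bs$ci[1], bs$ci[2])

  # neutral cohort: interval covers 1
  coh <- simulate_cohort(fx_gene_models(), "flat", omega = 1,
                         burden_dist = 40, n_samples = 60, seed = 9,
                         sites = sites)
  bs2 <- bootstrap_dnds(coh$variants, opp, n_boot = 200, seed = 4)
  expect_true(bs2$ci[1] <= 1 && 1 <= bs2$ci[2])
  expect_gt(bs2$p_value, 0.05)
})

test_that("neutral bootstrap intervals achieve near-nominal coverage", {
  sites <- fx_sites()
  opp <- fx_opportunities()
  covered <- 0
  n_rep <- 15
  for (i in seq_len(n_rep)) {
    coh <- simulate_cohort(fx_gene_models(), "aging_like", omega = 1,
                           burden_dist = 30, n_samples = 50, seed = 500 + i,
                           sites = sites)
    bs <- bootstrap_dnds(coh$variants, opp, n_boot = 200, seed = i)
    if (bs$ci[1] <= 1 && 1 <= bs$ci[2]) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.9)
})
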