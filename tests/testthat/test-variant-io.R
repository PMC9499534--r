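test_that("read_maf keeps coding substitutions and counts burden", {
  rows <- list(
    c("s1", "TP53", "17", "100", "C", "T", "Missense_Mutation"),
    c("s1", "KRAS", "12", "200", "G", "A", "Missense_Mutation"),
    c("s1", "TP53", "17", "150", "A", "G", "Intron"))
  res <- suppressMessages(read_maf(write_toy_maf(rows)))
  expect_equal(nrow(res$variants), 2)
  expect_equal(res$samples$burden, 2)

  # missense + synonymous + nonsense all count toward burden
  rows3 <- list(
    c("s1", "TP53", "17", "100", "C", "T", "Missense_Mutation"),
    c("s1", "TP53", "17", "110", "G", "A", "Silent"),
    c("s1", "TP53", "17", "120", "C", "A", "Nonsense_Mutation"))
  res3 <- read_maf(write_toy_maf(rows3))
  expect_equal(res3$samples$burden, 3)

  # splice-site rows survive as consequence "other" but do not add burden
  rows4 <- c(rows3, list(c("s1", "TP53", "17", "130", "A", "T",
                           "Splice_Site")))
  res4 <- read_maf(write_toy_maf(rows4))
  expect_equal(nrow(res4$variants), 4)
  expect_equal(res4$samples$burden, 3)
})

test_that("read_maf on an empty table returns empty frames", {
  path <- tempfile(fileext = ".maf")
  writeLines(paste(c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
                     "Start_Position", "Reference_Allele",
                     "Tumor_Seq_Allele2", "Variant_Classification"),
                   collapse = "\t"), path)
  res <- read_maf(path)
  expect_equal(nrow(res$variants), 0)
  expect_equal(nrow(res$samples), 0)
})

test_that("read_maf fails fast on a missing required column", {
  path <- tempfile(fileext = ".maf")
  writeLines("Tumor_Sample_Barcode\tHugo_Symbol", path)
  expect_error(read_maf(path), "required column missing")
})

test_that("write_maf/read_maf round-trips retained fields", {
  coh <- simulate_cohort(fx_gene_models(), "flat", omega = 1,
                         burden_dist = 10, n_samples = 5, seed = 7,
                         sites = fx_sites())
  path <- tempfile(fileext = ".maf")
  write_maf(coh$variants, path)
  back <- read_maf(path)$variants
  for (col in c("sample_id", "gene", "pos", "ref_base", "alt_base",
                "consequence")) {
    expect_equal(back[[col]], coh$variants[[col]], info = col)
  }
})

test_that("every coding variant contributes to exactly one sample's burden", {
  coh <- simulate_cohort(fx_gene_models(), "aging_like", omega = 1,
                         burden_dist = function(n) sample(5:40, n, TRUE),
                         n_samples = 40, seed = 11, sites = fx_sites())
  burdens <- compute_burden(coh$variants)
  expect_equal(sum(burdens$burden), nrow(coh$variants))
  bins <- burden_bins()
  assigned <- assign_burden_bin(burdens$burden, bins)
  expect_equal(sum(table(assigned)), nrow(burdens))  # bins partition samples
})

test_that("burden bins are half-open (low, high]", {
  bins <- burden_bins(edges = c(3, 10, 100))
  lab <- assign_burden_bin(c(1, 3, 4, 10, 11, 100), bins)
  expect_equal(as.character(lab),
               c("(0,3]", "(0,3]", "(3,10]", "(3,10]", "(10,100]",
                 "(10,100]"))
  expect_true(is.na(assign_burden_bin(101, bins)))
})

test_that("clonality uses purity-adjusted VAF against the 0.2 threshold", {
  # vaf 0.30 at purity 0.60 adjusts to 0.50: clonal
  expect_equal(classify_clonality(0.30, 0.60), "clonal")
  # vaf 0.05 at purity 1 stays below 0.2: subclonal
  expect_equal(classify_clonality(0.05, 1.0), "subclonal")
  expect_equal(classify_clonality(NA_real_, 1.0), "unknown")
  expect_equal(classify_clonality(0.3, NA_real_), "unknown")
  expect_error(classify_clonality(0.3, 0), "positive")
  expect_error(classify_clonality(0.3, 1, threshold = 0), "threshold")
})

test_that("pathogenic fraction counts damaging over categorized missense", {
  v <- data.frame(
    sample_id = rep(c("s1", "s2"), 5),
    consequence = "missense",
    polyphen = c("probably_damaging", "probably_damaging",
                 "probably_damaging", "possibly_damaging", rep("benign", 6)),
    stringsAsFactors = FALSE)
  pf <- pathogenic_fraction(v, n_boot = 100, seed = 1)
  expect_equal(pf$fraction, 0.4)
  expect_true(pf$ci[1] >= 0 && pf$ci[2] <= 1)
  v$polyphen <- "benign"
  expect_equal(pathogenic_fraction(v, n_boot = 0)$fraction, 0)
  v$polyphen <- NA_character_
  expect_error(pathogenic_fraction(v), "categorized")
})

test_that("germline flagging partitions variants and recomputes burden", {
  v <- data.frame(sample_id = "s1", gene = "g", chrom = "1",
                  pos = c(10, 20, 30), ref_base = "C", alt_base = "T",
                  consequence = "missense", stringsAsFactors = FALSE)
  none <- flag_germline(v, data.frame(chrom = character(), pos = integer(),
                                      alt = character()))
  expect_equal(nrow(none$flagged), 0)
  one <- flag_germline(v, data.frame(chrom = "1", pos = 20, alt = "T"))
  expect_equal(nrow(one$flagged), 1)
  expect_equal(one$samples$burden, 2)
  all3 <- flag_germline(v, data.frame(chrom = "1", pos = c(10, 20, 30),
                                      alt = "T"))
  expect_equal(nrow(all3$retained), 0)
  expect_equal(all3$samples$burden, 0)
})

test_that("purity filter drops low-purity samples and their variants", {
  samples <- data.frame(sample_id = c("a", "b", "c"),
                        purity = c(0.9, 0.3, NA))
  v <- data.frame(sample_id = c("a", "a", "b", "c"), gene = "g",
                  chrom = "1", pos = 1:4, ref_base = "C", alt_base = "T",
                  consequence = "missense", stringsAsFactors = FALSE)
  out <- filter_by_purity(v, samples, min_purity = 0.5)
  expect_equal(out$samples$sample_id, "a")
  expect_equal(nrow(out$variants), 2)
  lax <- filter_by_purity(v, samples, min_purity = 0.5,
                          drop_missing = FALSE)
  expect_setequal(lax$samples$sample_id, c("a", "c"))
})
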