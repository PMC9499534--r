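# Shared fixtures, built once per test run. Everything is generated in code
# under fixed seeds; nothing is read from disk.

fx_gene_models <- function() {
  if (is.null(.fx$gm)) .fx$gm <- make_gene_models(25, 120, seed = 101)
  .fx$gm
}

fx_sites <- function() {
  if (is.null(.fx$sites)) .fx$sites <- enumerate_sites(fx_gene_models())
  .fx$sites
}

fx_opportunities <- function() {
  if (is.null(.fx$opp)) .fx$opp <- enumerate_opportunities(fx_sites())
  .fx$opp
}

fx_genome <- function() {
  if (is.null(.fx$genome)) .fx$genome <- make_genome_tracks(seed = 101)
  .fx$genome
}

.fx <- new.env(parent = emptyenv())
.fx$gm <- NULL; .fx$sites <- NULL; .fx$opp <- NULL; .fx$genome <- NULL

# A minimal hand-built genome with one chromosome, the left half exonic and
# the right half intergenic, no masked bases. For hand-computed dE/dI.
toy_half_exonic_genome <- function(len = 10000) {
  list(chrom_lengths = c(chr1 = len),
       exonic = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, len / 2)),
       intronic = GenomicRanges::GRanges(),
       intergenic = GenomicRanges::GRanges("chr1",
         IRanges::IRanges(len / 2 + 1, len)),
       masked = GenomicRanges::GRanges())
}

# Write a small MAF-like file and return its path.
write_toy_maf <- function(rows, path = tempfile(fileext = ".maf")) {
  header <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
              "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
              "Variant_Classification")
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- header
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
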