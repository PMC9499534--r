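#' Generate synthetic protein-coding gene models
#'
#' Builds random in-frame CDS sequences with no internal stop codons, as a
#' ground-truth substrate for site enumeration and cohort simulation. The
#' default sizing echoes a driver-like target: a few hundred genes of roughly
#' 1.3 kb of coding sequence each.
#'
#' @param n_genes Number of genes.
#' @param n_codons Codons per gene; a single value, a vector of length
#'   `n_genes`, or a function of `n` returning codon counts.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class `gene_models` with elements `cds` (a
#'   [Biostrings::DNAStringSet] named by gene) and `genes` (character vector).
#' @export
make_gene_models <- function(n_genes = 100, n_codons = 433, seed = 1) {
  stopifnot(n_genes >= 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (is.function(n_codons)) {
    nc <- n_codons(n_genes)
  } else {
    nc <- rep_len(as.integer(n_codons), n_genes)
  }
  stopifnot(all(nc >= 3))
  sense <- .sense_codons()
  seqs <- vapply(nc, function(k) {
    paste0(sample(sense, k, replace = TRUE), collapse = "")
  }, character(1))
  genes <- sprintf("gene%04d", seq_len(n_genes))
  cds <- Biostrings::DNAStringSet(seqs)
  names(cds) <- genes
  structure(list(cds = cds, genes = genes), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes, total",
      sum(Biostrings::width(x$cds)), "coding bases\n")
  invisible(x)
}

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Preserve caller's RNG state across internally seeded generators, so
# generators are deterministic under their own seed without disturbing the
# session stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
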