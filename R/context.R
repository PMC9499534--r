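#' @useDynLib tumorload, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
.CHANGES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.complement <- function(b) unname(.COMPLEMENT[b])

#' Labels of the 96 trinucleotide mutation channels
#'
#' Mutation channels follow the pyrimidine-strand convention used for somatic
#' mutational signatures: six base changes (C>A, C>G, C>T, T>A, T>C, T>G)
#' crossed with the 16 combinations of 5' and 3' flanking bases. Channel
#' indices run 0--95 in the order `16 * change + 4 * five_prime + three_prime`
#' with bases ordered A, C, G, T.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`, indexed by
#'   channel + 1.
#' @export
context96_labels <- function() {
  out <- character(96)
  for (ch in 0:5) {
    for (f in 0:3) {
      for (t in 0:3) {
        out[16 * ch + 4 * f + t + 1] <-
          paste0(.BASES[f + 1], "[", .CHANGES[ch + 1], "]", .BASES[t + 1])
      }
    }
  }
  out
}

#' Encode mutations into 96-channel trinucleotide context
#'
#' Purine-reference mutations are reverse-complemented onto the pyrimidine
#' strand (the two flanks are swapped and complemented), so a substitution
#' and its reverse-strand counterpart map to the same channel.
#'
#' @param ref,alt Reference and alternate bases (vectors of "A","C","G","T").
#' @param five,three 5' and 3' flanking bases on the same strand as `ref`.
#' @return Integer vector of channel indices in 0--95.
#' @examples
#' context96("C", "T", "A", "G") == context96("G", "A", "C", "T")
#' @export
context96 <- function(ref, alt, five, three) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(five) == n, length(three) == n)
  ok <- ref %in% .BASES & alt %in% .BASES & five %in% .BASES & three %in% .BASES
  if (!all(ok)) stop("non-ACGT base in context96() input")
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    r <- ref; a <- alt; f <- five; t3 <- three
    ref[flip] <- .complement(r[flip])
    alt[flip] <- .complement(a[flip])
    five[flip] <- .complement(t3[flip])
    three[flip] <- .complement(f[flip])
  }
  change <- match(paste0(ref, ">", alt), .CHANGES) - 1L
  16L * change + 4L * (match(five, .BASES) - 1L) + (match(three, .BASES) - 1L)
}

#' Annotate variants with their trinucleotide context channel
#'
#' Looks up each variant's position in its gene's CDS, checks that the
#' reference base matches, and encodes the substitution into the 96-channel
#' pyrimidine-strand convention. Positions are 1-based CDS coordinates;
#' the first and last CDS positions have no intragenic flank and raise an
#' error.
#'
#' @param variants Data frame with columns `gene`, `pos`, `ref_base`,
#'   `alt_base`.
#' @param gene_models Gene models as returned by [make_gene_models()], or any
#'   named character vector / `DNAStringSet` of CDS sequences.
#' @return `variants` with a `context96` integer column added.
#' @export
annotate_context <- function(variants, gene_models) {
  cds <- .cds_strings(gene_models)
  idx <- match(variants$gene, names(cds))
  if (anyNA(idx)) {
    stop("gene(s) absent from gene models: ",
         paste(unique(variants$gene[is.na(idx)]), collapse = ", "))
  }
  seqs <- cds[idx]
  len <- nchar(seqs)
  if (any(variants$pos < 2 | variants$pos > len - 1)) {
    bad <- which(variants$pos < 2 | variants$pos > len - 1)[1]
    stop("position ", variants$pos[bad], " in gene ", variants$gene[bad],
         " lacks a CDS trinucleotide context")
  }
  ref_here <- substr(seqs, variants$pos, variants$pos)
  mism <- ref_here != variants$ref_base
  if (any(mism)) {
    bad <- which(mism)[1]
    stop("reference mismatch at ", variants$gene[bad], ":", variants$pos[bad],
         " (CDS has ", ref_here[bad], ", variant claims ",
         variants$ref_base[bad], ")")
  }
  five <- substr(seqs, variants$pos - 1, variants$pos - 1)
  three <- substr(seqs, variants$pos + 1, variants$pos + 1)
  variants$context96 <- context96(variants$ref_base, variants$alt_base,
                                  five, three)
  variants
}

# Accept gene model lists, DNAStringSets or named character vectors.
.cds_strings <- function(gene_models) {
  if (is.list(gene_models) && !is.null(gene_models$cds)) {
    gene_models <- gene_models$cds
  }
  if (methods::is(gene_models, "DNAStringSet")) {
    out <- as.character(gene_models)
  } else {
    out <- as.character(gene_models)
    names(out) <- names(gene_models)
  }
  if (is.null(names(out))) stop("gene models must be named by gene")
  out
}
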