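#' MAF dialect: mapping from internal fields to file columns
#'
#' The reader and writer are driven by a column map so that MAF-like tables
#' from different callers can be ingested without editing the files. The
#' default follows common MAF headers. Coordinates in the file are 1-based
#' inclusive; internally positions stay 1-based CDS/genome coordinates.
#'
#' @param sample_id,gene,chrom,pos,ref,alt,classification,vaf,polyphen
#'   Column names in the file; `vaf` and `polyphen` may be absent.
#' @return Named list of class `maf_dialect`.
#' @export
maf_dialect <- function(sample_id = "Tumor_Sample_Barcode",
                        gene = "Hugo_Symbol",
                        chrom = "Chromosome",
                        pos = "Start_Position",
                        ref = "Reference_Allele",
                        alt = "Tumor_Seq_Allele2",
                        classification = "Variant_Classification",
                        vaf = "VAF",
                        polyphen = "PolyPhen") {
  structure(list(sample_id = sample_id, gene = gene, chrom = chrom,
                 pos = pos, ref = ref, alt = alt,
                 classification = classification, vaf = vaf,
                 polyphen = polyphen),
            class = "maf_dialect")
}

.CODING_CLASSES <- c(Missense_Mutation = "missense",
                     Nonsense_Mutation = "nonsense",
                     Silent = "synonymous",
                     Splice_Site = "other",
                     Nonstop_Mutation = "other",
                     Translation_Start_Site = "other")

#' Read a MAF-like somatic variant table
#'
#' Keeps one variant per coding single-nucleotide substitution. Indels
#' (ref/alt not single A/C/G/T) and non-coding rows are dropped, with a
#' message reporting the counts. Splice-site and nonstop substitutions are
#' retained with `consequence = "other"` but never count toward burden;
#' burden is the per-sample count of missense, nonsense and synonymous
#' substitutions.
#'
#' @param path Tab-separated file with a header row.
#' @param dialect A [maf_dialect()].
#' @return List with `variants` (data frame: `sample_id`, `gene`, `chrom`,
#'   `pos`, `ref_base`, `alt_base`, `consequence`, `vaf`, `polyphen`) and
#'   `samples` (data frame: `sample_id`, `burden`).
#' @export
read_maf <- function(path, dialect = maf_dialect()) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                "classification")
  for (f in required) {
    if (!dialect[[f]] %in% names(tab)) {
      stop("required column missing from MAF: ", dialect[[f]])
    }
  }
  n0 <- nrow(tab)
  if (n0 == 0) {
    return(list(variants = .empty_variants(), samples = .empty_samples()))
  }
  pos <- suppressWarnings(as.numeric(tab[[dialect$pos]]))
  bad_row <- is.na(pos)
  if (any(bad_row)) {
    warning(sum(bad_row), " row(s) with unparseable position skipped")
  }
  ref <- toupper(tab[[dialect$ref]])
  alt <- toupper(tab[[dialect$alt]])
  is_snv <- ref %in% .BASES & alt %in% .BASES & ref != alt
  cls <- tab[[dialect$classification]]
  is_coding <- cls %in% names(.CODING_CLASSES)
  keep <- !bad_row & is_snv & is_coding
  n_indel <- sum(!is_snv & !bad_row)
  n_noncoding <- sum(is_snv & !is_coding & !bad_row)
  if (n_indel + n_noncoding > 0) {
    message("read_maf: dropped ", n_indel, " non-SNV and ", n_noncoding,
            " non-coding row(s)")
  }
  variants <- data.frame(
    sample_id = as.character(tab[[dialect$sample_id]][keep]),
    gene = as.character(tab[[dialect$gene]][keep]),
    chrom = as.character(tab[[dialect$chrom]][keep]),
    pos = as.integer(pos[keep]),
    ref_base = ref[keep],
    alt_base = alt[keep],
    consequence = unname(.CODING_CLASSES[cls[keep]]),
    stringsAsFactors = FALSE
  )
  variants$vaf <- if (dialect$vaf %in% names(tab)) {
    suppressWarnings(as.numeric(tab[[dialect$vaf]][keep]))
  } else NA_real_
  variants$polyphen <- if (dialect$polyphen %in% names(tab)) {
    pp <- as.character(tab[[dialect$polyphen]][keep])
    ifelse(pp %in% c("benign", "possibly_damaging", "probably_damaging"),
           pp, NA_character_)
  } else NA_character_
  list(variants = variants, samples = compute_burden(variants))
}

#' Write variants back out in the same MAF dialect
#'
#' Round-trips the fields [read_maf()] retains.
#'
#' @param variants Variant data frame.
#' @param path Output path.
#' @param dialect A [maf_dialect()].
#' @export
write_maf <- function(variants, path, dialect = maf_dialect()) {
  inv_class <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
                 synonymous = "Silent", other = "Splice_Site")
  out <- data.frame(variants$sample_id, variants$gene, variants$chrom,
                    variants$pos, variants$ref_base, variants$alt_base,
                    unname(inv_class[variants$consequence]),
                    variants$vaf, variants$polyphen,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c(dialect$sample_id, dialect$gene, dialect$chrom, dialect$pos,
                  dialect$ref, dialect$alt, dialect$classification,
                  dialect$vaf, dialect$polyphen)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.empty_variants <- function() {
  data.frame(sample_id = character(), gene = character(), chrom = character(),
             pos = integer(), ref_base = character(), alt_base = character(),
             consequence = character(), vaf = numeric(),
             polyphen = character(), stringsAsFactors = FALSE)
}

.empty_samples <- function() {
  data.frame(sample_id = character(), burden = integer(),
             stringsAsFactors = FALSE)
}

#' Per-sample mutational burden
#'
#' Burden is the count of protein-coding substitutions (missense, nonsense
#' and synonymous) per sample -- the proxy used when only exome data is
#' available. `consequence = "other"` rows are excluded.
#'
#' @param variants Variant data frame.
#' @param sample_ids Optional vector of samples to report (zero-burden
#'   samples included); defaults to samples present in `variants`.
#' @return Data frame `sample_id`, `burden`.
#' @export
compute_burden <- function(variants, sample_ids = NULL) {
  coding <- variants[variants$consequence %in%
                       c("missense", "nonsense", "synonymous"), ]
  if (is.null(sample_ids)) sample_ids <- sort(unique(variants$sample_id))
  counts <- table(factor(coding$sample_id, levels = sample_ids))
  data.frame(sample_id = sample_ids, burden = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Log-scale burden bins
#'
#' Tumors are stratified by their total substitution count on a log scale.
#' The default half-decade edges reproduce the landmark thresholds used to
#' discuss low (<=3) and high (>10, >100) burden tumors. Bins are half-open
#' `(low, high]`.
#'
#' @param edges Ascending thresholds; bin `i` is `(edges[i], edges[i+1]]`,
#'   with an implicit lower bound of 0 before the first edge.
#' @return Object of class `burden_bins` with `breaks` and `labels`.
#' @export
burden_bins <- function(edges = c(1, 3, 10, 30, 100, 300, 1000, 3000,
                                  10000)) {
  stopifnot(all(diff(edges) > 0), all(edges > 0))
  breaks <- c(0, edges)
  labels <- paste0("(", breaks[-length(breaks)], ",", breaks[-1], "]")
  structure(list(breaks = breaks, labels = labels), class = "burden_bins")
}

#' Assign burdens to bins
#'
#' @param burden Integer vector of burdens.
#' @param bins A [burden_bins()].
#' @return Factor of bin labels; burdens outside `(0, max(edges)]` are `NA`.
#' @export
assign_burden_bin <- function(burden, bins = burden_bins()) {
  cut(burden, breaks = bins$breaks, labels = bins$labels, right = TRUE)
}

#' Clonality from purity-adjusted variant allele frequency
#'
#' The VAF is divided by tumor purity (capped at 1) and compared to a
#' threshold: below is subclonal, at or above is clonal. Missing VAF or
#' purity gives `"unknown"`.
#'
#' @param vaf Variant allele frequencies in `[0, 1]` (NA allowed).
#' @param purity Tumor purity in `(0, 1]` (NA allowed), recycled.
#' @param threshold Clonality threshold on the adjusted VAF, default 0.2.
#' @return Character vector: `"clonal"`, `"subclonal"` or `"unknown"`.
#' @export
classify_clonality <- function(vaf, purity = 1, threshold = 0.2) {
  stopifnot(threshold > 0, threshold < 1)
  purity <- rep_len(purity, length(vaf))
  if (any(!is.na(purity) & purity <= 0)) stop("purity must be positive")
  adj <- pmin(vaf / purity, 1)
  out <- ifelse(is.na(adj), "unknown",
                ifelse(adj < threshold, "subclonal", "clonal"))
  out
}

#' Fraction of pathogenic missense mutations
#'
#' Among missense variants with a PolyPhen-style label, the fraction
#' classified "probably damaging" or "possibly damaging" out of all
#' categorized variants, with a bootstrap confidence interval obtained by
#' resampling patient samples.
#'
#' @param variants Variant data frame with `consequence`, `polyphen`,
#'   `sample_id`.
#' @param n_boot Bootstrap resamples (0 disables the CI).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return List with `fraction`, `n`, and (if `n_boot > 0`) `ci`.
#' @export
pathogenic_fraction <- function(variants, n_boot = 1000, seed = 1,
                                conf = 0.95) {
  v <- variants[variants$consequence == "missense" &
                  !is.na(variants$polyphen), ]
  if (nrow(v) == 0) stop("no categorized missense variants")
  patho <- v$polyphen %in% c("probably_damaging", "possibly_damaging")
  out <- list(fraction = mean(patho), n = nrow(v))
  if (n_boot > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    ids <- unique(v$sample_id)
    by_sample <- split(patho, v$sample_id)
    frac <- replicate(n_boot, {
      take <- sample(ids, length(ids), replace = TRUE)
      mean(unlist(by_sample[take], use.names = FALSE))
    })
    alpha <- (1 - conf) / 2
    out$ci <- stats::quantile(frac, c(alpha, 1 - alpha), names = FALSE,
                              na.rm = TRUE)
  }
  out
}

#' Partition variants by membership in a common-SNP site list
#'
#' Variants matching a supplied (chrom, pos, alt) site -- e.g. common
#' germline SNPs -- are flagged as likely germline contamination; the rest
#' are retained and burdens recomputed on the retained set.
#'
#' @param variants Variant data frame.
#' @param snp_sites Data frame with columns `chrom`, `pos`, `alt`.
#' @return List with `retained`, `flagged`, and `samples` (burdens on the
#'   retained set).
#' @export
flag_germline <- function(variants, snp_sites) {
  if (nrow(snp_sites) == 0 || nrow(variants) == 0) {
    flagged <- rep(FALSE, nrow(variants))
  } else {
    key_v <- paste(variants$chrom, variants$pos, variants$alt_base, sep = "\r")
    key_s <- paste(snp_sites$chrom, snp_sites$pos, snp_sites$alt, sep = "\r")
    flagged <- key_v %in% key_s
  }
  retained <- variants[!flagged, , drop = FALSE]
  list(retained = retained,
       flagged = variants[flagged, , drop = FALSE],
       samples = compute_burden(retained,
                                sample_ids = sort(unique(variants$sample_id))))
}

#' Filter a cohort by minimum tumor purity
#'
#' Sensitivity-analysis helper: drops samples whose purity estimate is
#' below a threshold (or missing, optionally) and restricts the variant
#' table to the remaining samples.
#'
#' @param variants Variant data frame.
#' @param samples Sample data frame with `sample_id` and `purity`.
#' @param min_purity Minimum purity retained.
#' @param drop_missing Drop samples with missing purity (default TRUE).
#' @return List with filtered `variants` and `samples`.
#' @export
filter_by_purity <- function(variants, samples, min_purity = 0,
                             drop_missing = TRUE) {
  stopifnot("purity" %in% names(samples))
  keep <- !is.na(samples$purity) & samples$purity >= min_purity
  if (!drop_missing) keep <- keep | is.na(samples$purity)
  kept <- samples[keep, , drop = FALSE]
  list(variants = variants[variants$sample_id %in% kept$sample_id, ,
                           drop = FALSE],
       samples = kept)
}
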