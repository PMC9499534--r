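#' Mutational signature mixes over the 96 trinucleotide channels
#'
#' A signature mix is a probability vector over the 96 channels. Built-in
#' mixes are deliberately skewed spectra in the spirit of single-base
#' substitution signatures (an aging-like CpG>T spectrum, a UV-like CC>TT
#' neighborhood, an APOBEC-like TpC spectrum), used to stress-test the
#' permutation null under extreme trinucleotide bias; they are synthetic,
#' not catalog signatures.
#'
#' @param weights Either a numeric vector of length 96 (non-negative,
#'   renormalized to sum to 1) or the name of a built-in mix: `"flat"`,
#'   `"aging_like"`, `"uv_like"`, `"apobec_like"`, `"single_channel"`.
#' @return Numeric vector of length 96 of class `signature_mix`.
#' @export
signature_mix <- function(weights = "flat") {
  if (is.character(weights)) {
    name <- match.arg(weights, c("flat", "aging_like", "uv_like",
                                 "apobec_like", "single_channel"))
    labels <- context96_labels()
    w <- rep(1, 96)
    if (name == "aging_like") {
      # C>T at NpCpG, strongly dominant
      w[grepl("\\[C>T\\]G", labels)] <- 60
    } else if (name == "uv_like") {
      w[grepl("\\[C>T\\]", labels)] <- 30
      w[grepl("T\\[C>T\\]", labels)] <- 90
    } else if (name == "apobec_like") {
      w[grepl("T\\[C>[GT]\\]", labels)] <- 80
    } else if (name == "single_channel") {
      w <- rep(0, 96)
      w[match("T[C>T]A", labels)] <- 1
    }
    weights <- w
  }
  stopifnot(length(weights) == 96, all(weights >= 0), sum(weights) > 0)
  structure(weights / sum(weights), class = "signature_mix")
}

#' Simulate a somatic SNV cohort with known selection
#'
#' Mutations are placed on context-eligible CDS sites with probability
#' proportional to the signature-mix weight of the site's channel times site
#' availability (so the realized spectrum reflects both mutational bias and
#' sequence composition). Selection with known strength is then injected by
#' thinning: with true `omega < 1`, each nonsynonymous mutation is removed
#' with probability `1 - omega`; with `omega > 1`, synonymous mutations are
#' removed with probability `1 - 1/omega`. The permutation dN/dS estimator
#' should recover `omega` on the surviving cohort.
#'
#' @param gene_models Gene models from [make_gene_models()].
#' @param mix A [signature_mix()] (or name of a built-in mix).
#' @param omega True dN/dS. Either a single value for all genes, or a named
#'   vector of gene-set values (e.g. `c(driver = 2, passenger = 0.8)`) with
#'   `driver_genes` supplied.
#' @param burden_dist Function of `n` returning per-sample pre-selection
#'   mutation counts, or a single number used for every sample.
#' @param n_samples Number of tumor samples.
#' @param seed Integer seed; output is reproducible given the seed.
#' @param driver_genes Character vector of driver gene names (required when
#'   `omega` is a named vector).
#' @param sites Optional precomputed [enumerate_sites()] table.
#' @return List of class `synthetic_cohort`: `variants`, `samples`,
#'   `true_omega`, `seed`.
#' @export
simulate_cohort <- function(gene_models, mix = signature_mix("flat"),
                            omega = 1,
                            burden_dist = 50,
                            n_samples = 100, seed = 1,
                            driver_genes = NULL, sites = NULL) {
  if (is.character(mix)) mix <- signature_mix(mix)
  stopifnot(all(omega > 0), all(omega <= 2))
  if (is.null(sites)) sites <- enumerate_sites(gene_models)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  have_sites <- unique(sites$context96)
  active <- which(unclass(mix) > 0) - 1L
  orphan <- setdiff(active, have_sites)
  if (length(orphan) > 0) {
    warning(length(orphan),
            " signature channel(s) have no eligible site; renormalizing")
    w <- unclass(mix); w[orphan + 1L] <- 0
    mix <- signature_mix(w)
  }
  burdens <- if (is.function(burden_dist)) burden_dist(n_samples)
             else rep_len(burden_dist, n_samples)
  stopifnot(all(burdens >= 1))
  n_total <- sum(burdens)
  site_w <- unclass(mix)[sites$context96 + 1L]
  draw <- sample.int(nrow(sites), n_total, replace = TRUE, prob = site_w)
  v <- sites[draw, ]
  v$sample_id <- rep(sprintf("s%04d", seq_len(n_samples)), times = burdens)
  # thinning injects known selection
  om <- .omega_for_genes(v$gene, omega, driver_genes)
  nonsyn <- v$consequence != "synonymous"
  u <- stats::runif(nrow(v))
  drop <- (nonsyn & om < 1 & u > om) |
          (!nonsyn & om > 1 & u > 1 / om)
  v <- v[!drop, ]
  variants <- data.frame(
    sample_id = v$sample_id, gene = v$gene, chrom = v$gene, pos = v$pos,
    ref_base = v$ref_base, alt_base = v$alt_base,
    consequence = v$consequence, context96 = v$context96,
    vaf = NA_real_, polyphen = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(variants) <- NULL
  structure(list(variants = variants,
                 samples = compute_burden(variants,
                                          sprintf("s%04d", seq_len(n_samples))),
                 true_omega = omega, seed = seed),
            class = "synthetic_cohort")
}

.omega_for_genes <- function(genes, omega, driver_genes) {
  if (length(omega) == 1 && is.null(names(omega))) {
    return(rep(unname(omega), length(genes)))
  }
  if (is.null(driver_genes)) {
    stop("named omega requires driver_genes")
  }
  stopifnot(all(c("driver", "passenger") %in% names(omega)))
  ifelse(genes %in% driver_genes, omega[["driver"]], omega[["passenger"]])
}

#' Build a synthetic genome with annotation tracks
#'
#' Constructs chromosomes with masked telomeres and a masked centromere,
#' and tiles the mappable interior with gene loci (exons separated by
#' introns) embedded in intergenic sequence. The exonic, intronic and
#' intergenic tracks are disjoint and, together with the masked regions,
#' partition the genome. A random subset of genes is designated as drivers,
#' giving driver/passenger exonic subtracks for enrichment experiments.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bases).
#' @param genes_per_chrom Gene loci per chromosome.
#' @param exons_per_gene,exon_length,intron_length Gene structure (bases).
#' @param telomere,centromere Masked lengths at the ends / middle.
#' @param driver_fraction Fraction of genes labeled drivers.
#' @param seed Integer seed (gene placement is randomized).
#' @return List of class `genome_tracks`: `chrom_lengths` (named), GRanges
#'   tracks `exonic`, `intronic`, `intergenic`, `masked`, `genes` (named by
#'   gene), and `driver_genes`.
#' @export
make_genome_tracks <- function(n_chrom = 4, chrom_length = 5e6,
                               genes_per_chrom = 60, exons_per_gene = 8,
                               exon_length = 200, intron_length = 2000,
                               telomere = 5e4, centromere = 1e5,
                               driver_fraction = 0.1, seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  chrom_lengths <- stats::setNames(rep(chrom_length, n_chrom), chroms)
  gene_len <- exons_per_gene * exon_length +
    (exons_per_gene - 1) * intron_length
  ex_l <- vector("list", 0); in_l <- vector("list", 0)
  gene_l <- vector("list", 0); mask_l <- vector("list", 0)
  gene_id <- 0
  for (ch in chroms) {
    cen_start <- chrom_length %/% 2 - centromere %/% 2
    mask_l[[length(mask_l) + 1]] <- GenomicRanges::GRanges(
      factor(ch, levels = chroms), IRanges::IRanges(
        start = c(1, cen_start, chrom_length - telomere + 1),
        end = c(telomere, cen_start + centromere - 1, chrom_length)))
    # two mappable arms; genes placed on a jittered grid within each arm
    arms <- rbind(c(telomere + 1, cen_start - 1),
                  c(cen_start + centromere, chrom_length - telomere))
    per_arm <- genes_per_chrom %/% 2
    for (a in 1:2) {
      arm_len <- arms[a, 2] - arms[a, 1] + 1
      slot <- arm_len %/% per_arm
      stopifnot(slot > gene_len)
      jitter_max <- slot - gene_len
      starts <- arms[a, 1] + (seq_len(per_arm) - 1) * slot +
        sample.int(jitter_max, per_arm, replace = TRUE)
      for (s in starts) {
        gene_id <- gene_id + 1
        ex_starts <- s + (seq_len(exons_per_gene) - 1) *
          (exon_length + intron_length)
        ex_l[[length(ex_l) + 1]] <- GenomicRanges::GRanges(
          factor(ch, levels = chroms),
          IRanges::IRanges(start = ex_starts, width = exon_length))
        if (exons_per_gene > 1) {
          in_l[[length(in_l) + 1]] <- GenomicRanges::GRanges(
            factor(ch, levels = chroms),
            IRanges::IRanges(start = ex_starts[-exons_per_gene] + exon_length,
                             width = intron_length))
        }
        g <- GenomicRanges::GRanges(factor(ch, levels = chroms),
          IRanges::IRanges(start = s, end = s + gene_len - 1))
        names(g) <- sprintf("g%04d", gene_id)
        gene_l[[length(gene_l) + 1]] <- g
      }
    }
  }
  exonic <- GenomicRanges::reduce(do.call(c, ex_l))
  intronic <- GenomicRanges::reduce(do.call(c, in_l))
  genes <- do.call(c, gene_l)
  masked <- GenomicRanges::reduce(do.call(c, mask_l))
  genome_gr <- GenomicRanges::GRanges(chroms,
    IRanges::IRanges(1, chrom_lengths))
  covered <- GenomicRanges::reduce(c(exonic, intronic, masked))
  intergenic <- GenomicRanges::setdiff(genome_gr, covered)
  n_drivers <- max(1, round(driver_fraction * length(genes)))
  driver_genes <- sort(sample(names(genes), n_drivers))
  structure(list(chrom_lengths = chrom_lengths, exonic = exonic,
                 intronic = intronic, intergenic = intergenic,
                 masked = masked, genes = genes,
                 driver_genes = driver_genes),
            class = "genome_tracks")
}

#' Simulate copy-number alterations on a synthetic genome
#'
#' Each CNA gets a length from `length_dist` and a chromosome drawn with
#' probability proportional to chromosome length, then a uniform start.
#' Optional enrichment accepts placements overlapping a named track with
#' `fold`-times the probability of non-overlapping placements (fold 1 is
#' the uniform null). Intervals are half-open `[start, end)` with
#' `length = end - start`.
#'
#' @param n Number of CNAs.
#' @param genome A [make_genome_tracks()] object.
#' @param length_dist Function of `n` returning lengths, or a single length.
#' @param enrichment `NULL`, or `list(track = <GRanges>, fold = <numeric>)`.
#' @param n_samples Number of samples CNAs are assigned to (uniformly).
#' @param seed Integer seed.
#' @return Data frame: `sample_id`, `chrom`, `start`, `end`.
#' @export
simulate_cnas <- function(n, genome,
                          length_dist = function(k)
                            pmax(1000, round(stats::rlnorm(k, log(1e5), 1))),
                          enrichment = NULL, n_samples = 50, seed = 1) {
  if (!is.null(enrichment)) {
    stopifnot(is.list(enrichment), enrichment$fold >= 0)
    if (enrichment$fold == 0) stop("enrichment fold must be positive")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  lens <- genome$chrom_lengths
  out_chrom <- character(n); out_start <- numeric(n); out_len <- numeric(n)
  filled <- 0
  while (filled < n) {
    m <- n - filled
    L <- if (is.function(length_dist)) round(length_dist(m))
         else rep_len(round(length_dist), m)
    L <- pmin(L, min(lens) - 1)
    chrom <- sample(names(lens), m, replace = TRUE, prob = lens)
    start <- floor(stats::runif(m, min = 1, max = lens[chrom] - L + 1))
    if (is.null(enrichment) || enrichment$fold == 1) {
      keep <- rep(TRUE, m)
    } else {
      gr <- GenomicRanges::GRanges(chrom,
              IRanges::IRanges(start = start, end = start + L - 1))
      hits <- suppressWarnings(IRanges::overlapsAny(gr, enrichment$track))
      w <- ifelse(hits, enrichment$fold, 1)
      keep <- stats::runif(m) < w / max(enrichment$fold, 1)
    }
    k <- sum(keep)
    if (k > 0) {
      idx <- filled + seq_len(k)
      out_chrom[idx] <- chrom[keep]
      out_start[idx] <- start[keep]
      out_len[idx] <- L[keep]
      filled <- filled + k
    }
  }
  data.frame(
    sample_id = sprintf("c%04d", sample.int(n_samples, n, replace = TRUE)),
    chrom = out_chrom,
    start = out_start,
    end = out_start + out_len,
    stringsAsFactors = FALSE
  )
}

#' Simulate a burden-linked expression matrix
#'
#' Genes in `gene_set` get a mean expression shift of
#' `slope * log10(burden)` per sample; all other genes are pure noise. Used
#' to validate the expression-burden association statistic against a known
#' trend.
#'
#' @param n_genes Number of genes (named gene0001...).
#' @param samples Data frame with `sample_id` and `burden`.
#' @param gene_set Character vector of gene names receiving the trend.
#' @param slope Shift per log10 burden unit.
#' @param noise Gaussian noise SD.
#' @param seed Integer seed.
#' @return Numeric matrix, genes x samples.
#' @export
simulate_expression <- function(n_genes, samples, gene_set, slope = 1,
                                noise = 1, seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  stopifnot(all(gene_set %in% genes), all(samples$burden >= 1))
  m <- matrix(stats::rnorm(n_genes * nrow(samples), sd = noise),
              nrow = n_genes, dimnames = list(genes, samples$sample_id))
  shift <- slope * log10(samples$burden)
  m[gene_set, ] <- m[gene_set, , drop = FALSE] +
    matrix(shift, nrow = length(gene_set), ncol = nrow(samples), byrow = TRUE)
  m
}
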