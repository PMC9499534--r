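#' Genomic signal of a single CNA
#'
#' Under the breakpoint-frequency metric a CNA contributes one unit of mass
#' at each terminus (total 2); under fractional overlap it contributes a
#' uniform density 1/L over the interval it spans (total 1). Mass falling in
#' masked regions (telomeres/centromeres) is removed. CNAs are half-open
#' `[start, end)`, so the termini are `start` and `end - 1`.
#'
#' @param cna One-row data frame (or list) with `chrom`, `start`, `end`.
#' @param metric `"breakpoint"` or `"fractional"`.
#' @param masked Optional GRanges of masked regions.
#' @return GRanges with a `score` metadata column; total mass is
#'   `sum(score * width)`.
#' @export
cna_signal <- function(cna, metric = c("breakpoint", "fractional"),
                       masked = NULL) {
  metric <- match.arg(metric)
  stopifnot(cna$end > cna$start)
  L <- cna$end - cna$start
  if (metric == "breakpoint") {
    gr <- GenomicRanges::GRanges(cna$chrom,
      IRanges::IRanges(start = c(cna$start, cna$end - 1), width = 1))
    S4Vectors::mcols(gr)$score <- 1
  } else {
    gr <- GenomicRanges::GRanges(cna$chrom,
      IRanges::IRanges(start = cna$start, end = cna$end - 1))
    S4Vectors::mcols(gr)$score <- 1 / L
  }
  if (!is.null(masked)) {
    keep <- GenomicRanges::setdiff(gr, masked)
    hit <- GenomicRanges::findOverlaps(keep, gr, select = "first")
    S4Vectors::mcols(keep)$score <- S4Vectors::mcols(gr)$score[hit]
    gr <- keep
  }
  gr
}

.cna_granges <- function(cnas) {
  GenomicRanges::GRanges(cnas$chrom,
    IRanges::IRanges(start = cnas$start, end = cnas$end - 1))
}

.track_minus_masked <- function(track, masked) {
  GenomicRanges::setdiff(GenomicRanges::reduce(track), masked)
}

# Mass deposited by a set of CNAs on a track (already masked-subtracted).
.track_mass <- function(cnas, track, metric) {
  if (nrow(cnas) == 0) return(0)
  if (metric == "breakpoint") {
    bp <- GenomicRanges::GRanges(rep(cnas$chrom, 2),
      IRanges::IRanges(start = c(cnas$start, cnas$end - 1), width = 1))
    sum(suppressWarnings(IRanges::overlapsAny(bp, track)))
  } else {
    gr <- .cna_granges(cnas)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, track))
    if (length(hits) == 0) return(0)
    ov <- IRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                              track[S4Vectors::subjectHits(hits)])
    L <- (cnas$end - cnas$start)[S4Vectors::queryHits(hits)]
    sum(IRanges::width(ov) / L)
  }
}

#' dE/dI: CNA selection statistic on exonic vs non-coding tracks
#'
#' Compares the per-mappable-base density of CNA signal (breakpoints, or
#' length-normalized fractional overlap) on an exonic track against the
#' combined intronic + intergenic track. Masked telomere/centromere regions
#' are excluded both from the tallies and from the track lengths. Under
#' random CNA placement the two densities are equal and the ratio is ~1;
#' positive selection on coding regions pushes it above 1, negative
#' selection below 1.
#'
#' @param cnas Data frame with `sample_id`, `chrom`, `start`, `end`
#'   (half-open).
#' @param genome A [make_genome_tracks()] object, or any list with GRanges
#'   `exonic`, `intronic`, `intergenic`, `masked`. An `exonic_track`
#'   override lets callers score driver or passenger exon subsets.
#' @param metric `"breakpoint"` or `"fractional"`.
#' @param burden_range Optional `(low, high]` range; only CNAs from samples
#'   whose total CNA count lies in the range are scored.
#' @param length_class `"all"`, `"gt100kb"` (length > 100 kb or non-focal)
#'   or `"le100kb"` (focal and <= 100 kb).
#' @param exonic_track Optional GRanges replacing `genome$exonic` as the
#'   numerator track.
#' @param n_boot Bootstrap resamples over samples for a CI (0 disables).
#' @param seed Seed for the bootstrap.
#' @return List of class `dedi_estimate`: `ratio`, per-track densities and
#'   masses, `n_cnas`, and optionally `ci`.
#' @export
dedi <- function(cnas, genome, metric = c("breakpoint", "fractional"),
                 burden_range = NULL, length_class = c("all", "gt100kb",
                                                       "le100kb"),
                 exonic_track = NULL, n_boot = 0, seed = 1) {
  metric <- match.arg(metric)
  length_class <- match.arg(length_class)
  if (!is.null(burden_range)) {
    counts <- table(cnas$sample_id)
    keep_samples <- names(counts)[counts > burden_range[1] &
                                    counts <= burden_range[2]]
    cnas <- cnas[cnas$sample_id %in% keep_samples, , drop = FALSE]
  }
  if (length_class != "all") {
    L <- cnas$end - cnas$start
    term <- GenomicRanges::GRanges(rep(cnas$chrom, 2),
      IRanges::IRanges(start = c(cnas$start, cnas$end - 1), width = 1))
    in_mask <- suppressWarnings(IRanges::overlapsAny(term, genome$masked))
    focal <- !(in_mask[seq_len(nrow(cnas))] |
                 in_mask[nrow(cnas) + seq_len(nrow(cnas))])
    long <- L > 1e5 | !focal   # non-focal CNAs aggregate with the long class
    cnas <- cnas[if (length_class == "gt100kb") long else !long, ,
                 drop = FALSE]
  }
  e_track <- .track_minus_masked(
    if (is.null(exonic_track)) genome$exonic else exonic_track,
    genome$masked)
  i_track <- .track_minus_masked(
    c(GenomicRanges::reduce(genome$intronic),
      GenomicRanges::reduce(genome$intergenic)), genome$masked)
  e_len <- sum(IRanges::width(e_track))
  i_len <- sum(IRanges::width(i_track))
  stopifnot(e_len > 0, i_len > 0)
  point <- function(d) {
    e <- .track_mass(d, e_track, metric) / e_len
    i <- .track_mass(d, i_track, metric) / i_len
    c(e = e, i = i)
  }
  dens <- point(cnas)
  if (dens[["i"]] == 0) stop("no CNA mass on the intronic+intergenic track")
  out <- structure(list(metric = metric, ratio = dens[["e"]] / dens[["i"]],
                        numerator_density = dens[["e"]],
                        denominator_density = dens[["i"]],
                        n_cnas = nrow(cnas)),
                   class = "dedi_estimate")
  if (n_boot > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    ids <- unique(cnas$sample_id)
    by_sample <- split(seq_len(nrow(cnas)), cnas$sample_id)
    ratios <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      d <- cnas[unlist(by_sample[take], use.names = FALSE), , drop = FALSE]
      p <- point(d)
      if (p[["i"]] > 0) ratios[b] <- p[["e"]] / p[["i"]]
    }
    out$ci <- stats::quantile(ratios, c(0.025, 0.975), names = FALSE,
                              na.rm = TRUE)
  }
  out
}

#' @export
print.dedi_estimate <- function(x, ...) {
  cat(sprintf("dE/dI (%s) = %.4f over %d CNAs\n", x$metric, x$ratio,
              x$n_cnas))
  if (!is.null(x$ci)) cat(sprintf("  95%% CI [%.4f, %.4f]\n",
                                  x$ci[1], x$ci[2]))
  invisible(x)
}

#' Length-preserving random permutation of CNA positions
#'
#' Places each CNA uniformly at random on its own chromosome, preserving
#' its length, to build a neutral reference set. Cross-chromosome moves are
#' not made.
#'
#' @param cnas Data frame with `sample_id`, `chrom`, `start`, `end`.
#' @param genome A [make_genome_tracks()] object (for chromosome lengths).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Data frame of the same shape with new `start`/`end`.
#' @export
permute_cnas <- function(cnas, genome, seed = 1) {
  lens <- genome$chrom_lengths[cnas$chrom]
  L <- cnas$end - cnas$start
  if (any(L > lens)) {
    stop("CNA longer than its chromosome cannot be placed")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  start <- floor(stats::runif(nrow(cnas), min = 1, max = lens - L + 1))
  out <- cnas
  out$start <- start
  out$end <- start + L
  out
}
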