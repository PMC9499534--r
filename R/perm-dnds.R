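#' Enumerate every possible coding substitution in a set of gene models
#'
#' Walks each CDS and classifies all three alternative bases at every
#' internal position (the first and last CDS positions lack a trinucleotide
#' context and are skipped). Nonsense changes count as nonsynonymous.
#' Positions with ambiguous bases are skipped with a warning.
#'
#' @param gene_models Gene models ([make_gene_models()] output or a named
#'   CDS vector). CDS lengths must be divisible by 3 and contain no internal
#'   stop codon.
#' @return Data frame with one row per possible substitution: `gene`, `pos`
#'   (1-based CDS coordinate), `ref_base`, `alt_base`, `context96`,
#'   `consequence` (`synonymous`, `missense` or `nonsense`).
#' @export
enumerate_sites <- function(gene_models) {
  cds <- .cds_strings(gene_models)
  gc_tab <- Biostrings::GENETIC_CODE
  pieces <- vector("list", length(cds))
  for (g in seq_along(cds)) {
    s <- cds[[g]]
    L <- nchar(s)
    if (L == 0) next
    if (L %% 3 != 0) stop("CDS length of ", names(cds)[g],
                          " not divisible by 3")
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    if (any(!b %in% .BASES)) {
      warning("ambiguous bases in ", names(cds)[g], "; positions skipped")
    }
    codon_of <- function(i) (i - 1L) %/% 3L + 1L
    codons <- substring(s, seq(1, L, 3), seq(3, L, 3))
    internal <- codons[-length(codons)]
    if (any(gc_tab[internal] == "*" & !is.na(gc_tab[internal])))
      stop("internal stop codon in ", names(cds)[g])
    pos <- 2:(L - 1)
    pos <- pos[b[pos] %in% .BASES & b[pos - 1] %in% .BASES &
                 b[pos + 1] %in% .BASES]
    if (length(pos) == 0) next
    # 3 alternative bases per position
    ref <- b[pos]
    alt_map <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))
    pos3 <- rep(pos, each = 3)
    ref3 <- rep(ref, each = 3)
    alt3 <- unlist(alt_map[ref], use.names = FALSE)
    within <- (pos3 - 1L) %% 3L           # 0,1,2 within codon
    cod <- codons[codon_of(pos3)]
    c1 <- substr(cod, 1, 1); c2 <- substr(cod, 2, 2); c3 <- substr(cod, 3, 3)
    mut_cod <- ifelse(within == 0L, paste0(alt3, c2, c3),
               ifelse(within == 1L, paste0(c1, alt3, c3),
                                    paste0(c1, c2, alt3)))
    aa0 <- gc_tab[cod]
    aa1 <- gc_tab[mut_cod]
    consequence <- ifelse(aa1 == "*", "nonsense",
                          ifelse(aa0 == aa1, "synonymous", "missense"))
    ok_codon <- !is.na(consequence)
    pos3 <- pos3[ok_codon]; ref3 <- ref3[ok_codon]; alt3 <- alt3[ok_codon]
    consequence <- consequence[ok_codon]
    if (length(pos3) == 0) next
    pieces[[g]] <- data.frame(
      gene = names(cds)[g],
      pos = pos3,
      ref_base = ref3,
      alt_base = alt3,
      context96 = context96(ref3, alt3, b[pos3 - 1L], b[pos3 + 1L]),
      consequence = consequence,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(gene = character(), pos = integer(),
                      ref_base = character(), alt_base = character(),
                      context96 = integer(), consequence = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Per-gene, per-channel opportunity table
#'
#' For each gene and 96-channel mutation type, counts the CDS substitutions
#' of that type that would be nonsynonymous (`n_loci`, missense + nonsense)
#' versus synonymous (`s_loci`). These counts are derived by exhaustive
#' enumeration of every possible single substitution, so the permutation
#' expectation downstream needs no resampling.
#'
#' @param gene_models Gene models, or a precomputed site table from
#'   [enumerate_sites()].
#' @return Data frame with columns `gene`, `context96`, `n_loci`, `s_loci`.
#' @export
enumerate_opportunities <- function(gene_models) {
  sites <- if (is.data.frame(gene_models)) gene_models
           else enumerate_sites(gene_models)
  if (nrow(sites) == 0) {
    return(data.frame(gene = character(), context96 = integer(),
                      n_loci = integer(), s_loci = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(sites$gene, sites$context96, sep = "\r")
  nonsyn <- sites$consequence != "synonymous"
  n_tab <- tapply(nonsyn, key, sum)
  s_tab <- tapply(!nonsyn, key, sum)
  parts <- strsplit(names(n_tab), "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, character(1), 1),
    context96 = as.integer(vapply(parts, `[`, character(1), 2)),
    n_loci = as.integer(n_tab),
    s_loci = as.integer(s_tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene, out$context96), ]
  rownames(out) <- NULL
  out
}

#' Analytic permutation expectation for observed mutations
#'
#' Each observed mutation is permuted over every CDS position in the same
#' gene where the same base change in the same trinucleotide context could
#' occur. Because the permutation set is exhaustively enumerable, the
#' expectation is computed analytically: a mutation of type `i` in gene `g`
#' contributes `n_loci/(n_loci+s_loci)` to the expected nonsynonymous tally
#' and `s_loci/(n_loci+s_loci)` to the expected synonymous tally. The two
#' tallies always sum to the number of observed mutations.
#'
#' @param variants Data frame with `gene` and `context96` columns.
#' @param opportunities Output of [enumerate_opportunities()].
#' @return Named numeric vector with elements `dn_exp` and `ds_exp`.
#' @export
permutation_expectation <- function(variants, opportunities) {
  if (nrow(variants) == 0) return(c(dn_exp = 0, ds_exp = 0))
  key_v <- paste(variants$gene, variants$context96, sep = "\r")
  key_o <- paste(opportunities$gene, opportunities$context96, sep = "\r")
  idx <- match(key_v, key_o)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("no opportunity entry for gene ", variants$gene[bad],
         ", channel ", variants$context96[bad])
  }
  n <- opportunities$n_loci[idx]
  s <- opportunities$s_loci[idx]
  tot <- n + s
  c(dn_exp = sum(n / tot), ds_exp = sum(s / tot))
}

#' Permutation-based dN/dS
#'
#' The selection statistic is the ratio of observed-to-expected
#' nonsynonymous counts over observed-to-expected synonymous counts,
#' \deqn{dN/dS = \frac{d_N^{obs}/d_N^{perm}}{d_S^{obs}/d_S^{perm}},}
#' where the permuted tallies come from the exhaustive context-preserving
#' permutation ([permutation_expectation()]). Values below 1 indicate
#' negative selection, ~1 neutral or inefficient selection, above 1
#' positive selection.
#'
#' @param dn_obs,ds_obs Observed nonsynonymous / synonymous counts.
#' @param dn_exp,ds_exp Expected tallies under the permutation null.
#' @return Object of class `dnds_estimate`.
#' @export
dnds <- function(dn_obs, ds_obs, dn_exp, ds_exp) {
  if (ds_obs <= 0) stop("ds_obs is zero: dN/dS undefined; widen the bin")
  if (dn_exp <= 0 || ds_exp <= 0) stop("permutation expectation is zero")
  structure(list(
    dn_obs = dn_obs, ds_obs = ds_obs,
    dn_exp = dn_exp, ds_exp = ds_exp,
    ratio = (dn_obs / dn_exp) / (ds_obs / ds_exp)
  ), class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("dN/dS = %.4f  (dN %g/%.2f, dS %g/%.2f)\n",
              x$ratio, x$dn_obs, x$dn_exp, x$ds_obs, x$ds_exp))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI [%.4f, %.4f], p = %.3g (%d bootstrap resamples)\n",
                x$ci[1], x$ci[2], x$p_value, x$n_boot))
  }
  invisible(x)
}

#' Pooled permutation dN/dS for a cohort of variants
#'
#' Pools all variants (typically one burden bin x gene set), tallies observed
#' nonsynonymous (missense + nonsense) and synonymous counts, computes the
#' analytic permutation expectation, and returns the dN/dS estimate.
#'
#' @param variants Data frame with `gene`, `context96`, `consequence`.
#' @param opportunities Output of [enumerate_opportunities()].
#' @return A `dnds_estimate`.
#' @export
perm_dnds <- function(variants, opportunities) {
  coding <- variants[variants$consequence %in%
                       c("missense", "nonsense", "synonymous"), ]
  dn_obs <- sum(coding$consequence != "synonymous")
  ds_obs <- sum(coding$consequence == "synonymous")
  ex <- permutation_expectation(coding, opportunities)
  dnds(dn_obs, ds_obs, ex[["dn_exp"]], ex[["ds_exp"]])
}

#' Bootstrap confidence interval and p-value for pooled dN/dS
#'
#' Resamples patient samples with replacement, recomputes the pooled
#' log(dN/dS) on each resample, and returns the percentile confidence
#' interval together with a two-sided p-value against dN/dS = 1. The log
#' scale is used throughout for aggregation and testing. Resamples with no
#' synonymous mutations are dropped and counted.
#'
#' @param variants Data frame with `sample_id`, `gene`, `context96`,
#'   `consequence`.
#' @param opportunities Output of [enumerate_opportunities()].
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed (bootstrap is deterministic given the seed).
#' @param conf Confidence level.
#' @return A `dnds_estimate` with `ci`, `p_value`, `n_boot` and `n_dropped`.
#' @export
bootstrap_dnds <- function(variants, opportunities, n_boot = 1000, seed = 1,
                           conf = 0.95) {
  samples <- unique(variants$sample_id)
  if (length(samples) < 2) stop("need at least 2 samples to bootstrap")
  est <- perm_dnds(variants, opportunities)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  by_sample <- split(seq_len(nrow(variants)), variants$sample_id)
  log_ratios <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    take <- sample(samples, length(samples), replace = TRUE)
    rows <- unlist(by_sample[take], use.names = FALSE)
    v <- variants[rows, ]
    ds_obs <- sum(v$consequence == "synonymous")
    if (ds_obs == 0) next
    e <- perm_dnds(v, opportunities)
    log_ratios[b] <- log(e$ratio)
  }
  kept <- log_ratios[!is.na(log_ratios)]
  if (length(kept) == 0) stop("every bootstrap resample lacked synonymous mutations")
  alpha <- (1 - conf) / 2
  est$ci <- exp(stats::quantile(kept, c(alpha, 1 - alpha), names = FALSE))
  p <- mean(kept <= 0)
  est$p_value <- max(2 * min(p, 1 - p), 1 / length(kept))
  est$n_boot <- n_boot
  est$n_dropped <- n_boot - length(kept)
  est
}
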