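.SUMMARY_NAMES <- c("dnds_drv_b1", "dnds_drv_b2", "dnds_drv_b3",
                    "dnds_pas_b1", "dnds_pas_b2", "dnds_pas_b3",
                    "nb_n", "nb_p", "gamma_k")

#' Burden-binned dN/dS for drivers and passengers
#'
#' Summarizes selection by decade-sized mutational-burden bins
#' `(0,10], (10,100], (100,1000]`, separately for driver and passenger
#' gene sets -- six values in all.
#'
#' Observed cohorts (`kind = "observed"`) use the permutation estimator
#' ([perm_dnds()]); pass `variants`, `opportunities` and `driver_genes`.
#' Simulated cohorts (`kind = "simulated"`) use the locus-ratio-corrected
#' count ratio `dN / (dS * r)`; pass the tumor table from
#' [run_tumor_batch()].
#'
#' @param x Variant data frame (observed) or tumor table (simulated).
#' @param kind `"observed"` or `"simulated"`.
#' @param opportunities Opportunity table (observed cohorts).
#' @param driver_genes Character vector of driver genes (observed cohorts).
#' @param r Nonsynonymous-to-synonymous locus ratio (simulated cohorts).
#' @param bins Bin edges, default `c(0, 10, 100, 1000)`.
#' @param widen Simulated cohorts only: when `TRUE`, a bin whose synonymous
#'   tally is zero is merged with its right neighbor (widening the bin, the
#'   standard remedy for a zero-dS estimate) and the merged estimate fills
#'   both entries; when `FALSE` (default) such a bin is an error. The
#'   rightmost bin widens leftward.
#' @return Named numeric vector of 6 dN/dS values.
#' @export
binned_dnds <- function(x, kind = c("observed", "simulated"),
                        opportunities = NULL, driver_genes = NULL,
                        r = 2.795, bins = c(0, 10, 100, 1000),
                        widen = FALSE) {
  kind <- match.arg(kind)
  n_bin <- length(bins) - 1
  out <- stats::setNames(rep(NA_real_, 2 * n_bin),
                         c(paste0("dnds_drv_b", seq_len(n_bin)),
                           paste0("dnds_pas_b", seq_len(n_bin))))
  if (kind == "simulated") {
    tum <- x[x$status == "malignant", , drop = FALSE]
    bin <- as.integer(cut(tum$burden, bins, right = TRUE))
    count_bin <- function(b) {
      tb <- tum[!is.na(bin) & bin %in% b, , drop = FALSE]
      c(dn_d = sum(tb$dn_driver), ds_d = sum(tb$ds_driver),
        dn_p = sum(tb$dn_passenger), ds_p = sum(tb$ds_passenger))
    }
    for (b in seq_len(n_bin)) {
      use <- b
      cc <- count_bin(use)
      while (widen && (cc[["ds_d"]] == 0 || cc[["ds_p"]] == 0) &&
               length(use) < n_bin) {
        # widen: absorb the right neighbor (leftward for the last bin)
        use <- if (max(use) < n_bin) c(use, max(use) + 1)
               else c(min(use) - 1, use)
        cc <- count_bin(use)
      }
      if (cc[["ds_d"]] == 0 || cc[["ds_p"]] == 0) {
        stop("burden bin (", bins[b], ",", bins[b + 1],
             "] has no synonymous mutations; cannot form dN/dS")
      }
      out[b] <- cc[["dn_d"]] / (cc[["ds_d"]] * r)
      out[n_bin + b] <- cc[["dn_p"]] / (cc[["ds_p"]] * r)
    }
  } else {
    stopifnot(!is.null(opportunities), !is.null(driver_genes))
    burden <- compute_burden(x)
    bin <- cut(burden$burden, bins, right = TRUE)
    sample_bin <- stats::setNames(as.integer(bin), burden$sample_id)
    v_bin <- sample_bin[x$sample_id]
    is_driver <- x$gene %in% driver_genes
    for (b in seq_len(n_bin)) {
      for (set in c(TRUE, FALSE)) {
        v <- x[!is.na(v_bin) & v_bin == b & is_driver == set, , drop = FALSE]
        if (nrow(v) == 0 || sum(v$consequence == "synonymous") == 0) {
          stop("burden bin (", bins[b], ",", bins[b + 1], "] has no ",
               if (set) "driver" else "passenger",
               " synonymous mutations; cannot form dN/dS")
        }
        est <- perm_dnds(v, opportunities)
        out[(if (set) 0 else n_bin) + b] <- est$ratio
      }
    }
  }
  out
}

#' Maximum-likelihood negative binomial fit to mutational burdens
#'
#' Fits `P(MB = k; n, p) = C(k+n-1, n-1) p^n (1-p)^k` to burdens restricted
#' to the support `[1, 1000]`, by maximum likelihood of the
#' support-truncated pmf (quasi-Newton optimization, multi-start).
#'
#' @param burdens Integer burdens; values outside the support are dropped.
#' @param support Inclusive support bounds, default `c(1, 1000)`.
#' @param min_obs Minimum observations required.
#' @return List of class `negbin_fit`: `n`, `p`, `loglik`, `n_obs`.
#' @export
fit_negbin <- function(burdens, support = c(1, 1000), min_obs = 30) {
  k <- burdens[burdens >= support[1] & burdens <= support[2]]
  if (length(k) < min_obs) {
    stop("need at least ", min_obs, " burdens in support, got ", length(k))
  }
  if (length(unique(k)) == 1) stop("degenerate burden distribution")
  nll <- function(par) {
    size <- exp(par[1]); prob <- stats::plogis(par[2])
    z <- suppressWarnings(
      stats::pnbinom(support[2], size = size, prob = prob) -
        stats::pnbinom(support[1] - 1, size = size, prob = prob))
    if (!is.finite(z) || z <= 0) return(1e10)
    ll <- suppressWarnings(
      sum(stats::dnbinom(k, size = size, prob = prob, log = TRUE)))
    if (!is.finite(ll)) return(1e10)
    -ll + length(k) * log(z)
  }
  m <- mean(k); v <- max(stats::var(k), m + 1e-6)
  # moment start: mean = n(1-p)/p, var = n(1-p)/p^2
  p0 <- min(max(m / v, 1e-3), 0.999)
  n0 <- max(m * p0 / (1 - p0), 1e-2)
  starts <- list(c(log(n0), stats::qlogis(p0)),
                 c(log(n0 * 3), stats::qlogis(min(p0 * 1.5, 0.99))),
                 c(log(max(n0 / 3, 1e-3)), stats::qlogis(p0 / 1.5)))
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, nll, method = "BFGS",
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("negative binomial fit failed")
  structure(list(n = exp(best$par[1]), p = stats::plogis(best$par[2]),
                 loglik = -best$value, n_obs = length(k),
                 support = support),
            class = "negbin_fit")
}

#' Gamma fit to cancer incidence ages or transformation times
#'
#' Age-incidence curves are summarized by a gamma distribution: the shape
#' `k` generalizes the number of driver events needed for transformation in
#' multistage models, while the scale `theta` is a pure time gauge (the
#' simulations measure time in generations, so only `k` is comparable and
#' only `k` enters the ABC summary vector).
#'
#' Two modes: `"pdf_mle"` fits individual transformation times by maximum
#' likelihood (used for simulated tumors, which all start at t = 0);
#' `"cdf_leastsq"` fits a cumulative incidence-by-age table by least
#' squares after normalizing it to a proper CDF, excluding ages below 20
#' (used for observed incidence curves).
#'
#' @param x Numeric vector of times (`pdf_mle`) or a data frame with
#'   columns `age` and `incidence` (cumulative; `cdf_leastsq`).
#' @param mode `"pdf_mle"` or `"cdf_leastsq"`.
#' @param min_age Minimum age retained in `cdf_leastsq` mode.
#' @return List of class `gamma_fit`: `k`, `theta`, `mode`.
#' @export
fit_gamma_incidence <- function(x, mode = c("pdf_mle", "cdf_leastsq"),
                                min_age = 20) {
  mode <- match.arg(mode)
  if (mode == "pdf_mle") {
    t <- x[is.finite(x) & x > 0]
    if (length(t) < 5) stop("need at least 5 positive times")
    sc <- mean(t)
    fit <- suppressWarnings(MASS::fitdistr(t / sc, "gamma"))
    k <- unname(fit$estimate["shape"])
    theta <- sc / unname(fit$estimate["rate"])
  } else {
    stopifnot(is.data.frame(x), all(c("age", "incidence") %in% names(x)))
    d <- x[x$age >= min_age, ]
    if (nrow(d) < 5) stop("need at least 5 age points above ", min_age)
    cdf <- d$incidence / max(d$incidence)
    obj <- function(par) {
      kk <- exp(par[1]); th <- exp(par[2])
      sum((stats::pgamma(d$age, shape = kk, scale = th) /
             stats::pgamma(max(d$age), shape = kk, scale = th) - cdf)^2)
    }
    best <- NULL
    for (s in list(c(log(3), log(20)), c(log(6), log(12)),
                   c(log(1.5), log(40)))) {
      fit <- try(stats::optim(s, obj, method = "BFGS",
                              control = list(maxit = 1000)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) stop("gamma CDF fit failed")
    k <- exp(best$par[1]); theta <- exp(best$par[2])
  }
  structure(list(k = k, theta = theta, mode = mode), class = "gamma_fit")
}

#' The nine ABC summary statistics of a simulated cohort
#'
#' Six burden-binned dN/dS values (drivers and passengers over
#' `(0,10], (10,100], (100,1000]`), the two negative-binomial burden
#' parameters, and the gamma shape of the transformation-time
#' distribution.
#'
#' @param tumors Tumor table from [run_tumor_batch()].
#' @param r Nonsynonymous-to-synonymous locus ratio.
#' @param min_obs Minimum burdens required by the negative binomial fit.
#' @param widen Passed to [binned_dnds()]: widen zero-dS burden bins
#'   instead of erroring (used by the sweep, where per-cell cohorts are
#'   small).
#' @return Named numeric vector of length 9.
#' @export
summarize_outcomes <- function(tumors, r = 2.795, min_obs = 30,
                               widen = FALSE) {
  mal <- tumors[tumors$status == "malignant", , drop = FALSE]
  if (nrow(mal) == 0) stop("no malignant tumors to summarize")
  dnds6 <- binned_dnds(mal, kind = "simulated", r = r, widen = widen)
  nb <- fit_negbin(mal$burden, min_obs = min_obs)
  ga <- fit_gamma_incidence(mal$generations, mode = "pdf_mle")
  out <- c(dnds6, nb_n = nb$n, nb_p = nb$p, gamma_k = ga$k)
  stats::setNames(out, .SUMMARY_NAMES)
}

#' Association between gene-set expression and mutational burden
#'
#' Per sample, the median expression over the gene set is z-scored against
#' the cohort; samples are then binned by burden, the mean z per bin taken,
#' and a linear trend of mean z on log10 bin-midpoint burden fitted with
#' bins weighted by their sample counts.
#'
#' @param expr Genes x samples numeric matrix (rownames genes, colnames
#'   samples).
#' @param gene_set Character vector of gene names.
#' @param burdens Data frame with `sample_id` and `burden`.
#' @param bins A [burden_bins()] object.
#' @return List: `bin_stats` (data frame of bin, n, mean z),
#'   `r_squared` (weighted), `slope`.
#' @export
expression_burden_association <- function(expr, gene_set, burdens,
                                          bins = burden_bins()) {
  genes <- intersect(gene_set, rownames(expr))
  if (length(genes) == 0) stop("gene set disjoint from expression matrix")
  common <- intersect(colnames(expr), burdens$sample_id)
  if (length(common) == 0) stop("no shared samples")
  med <- apply(expr[genes, common, drop = FALSE], 2, stats::median)
  if (stats::sd(med) == 0) stop("constant expression: z-scores undefined")
  z <- (med - mean(med)) / stats::sd(med)
  b <- burdens$burden[match(common, burdens$sample_id)]
  bin <- assign_burden_bin(b, bins)
  keep <- !is.na(bin)
  agg <- stats::aggregate(z[keep], list(bin = bin[keep]), mean)
  cnt <- table(bin[keep])
  mids <- (bins$breaks[-1] + bins$breaks[-length(bins$breaks)]) / 2
  names(mids) <- bins$labels
  df <- data.frame(bin = agg$bin, n = as.integer(cnt[as.character(agg$bin)]),
                   mean_z = agg$x,
                   log10_mid = log10(mids[as.character(agg$bin)]))
  if (nrow(df) < 3) stop("need at least 3 occupied burden bins")
  fit <- stats::lm(mean_z ~ log10_mid, data = df, weights = df$n)
  list(bin_stats = df, r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]))
}
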