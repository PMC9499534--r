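#' Log-spaced prior grid over driver and passenger fitness effects
#'
#' @param n_drivers,n_passengers Grid points per axis (the full-scale
#'   analysis uses 20 x 20).
#' @param s_drivers_range Prior range of the mean driver benefit,
#'   default `[1e-2, 1e0]`.
#' @param s_passengers_range Prior range of the mean passenger cost,
#'   default `[1e-4, 1e-2]`.
#' @return Data frame with one row per grid cell: `s_drivers`,
#'   `s_passengers`.
#' @export
prior_grid <- function(n_drivers = 20, n_passengers = 20,
                       s_drivers_range = c(1e-2, 1e0),
                       s_passengers_range = c(1e-4, 1e-2)) {
  sd_vals <- 10^seq(log10(s_drivers_range[1]), log10(s_drivers_range[2]),
                    length.out = n_drivers)
  sp_vals <- 10^seq(log10(s_passengers_range[1]),
                    log10(s_passengers_range[2]),
                    length.out = n_passengers)
  expand.grid(s_drivers = sd_vals, s_passengers = sp_vals,
              KEEP.OUT.ATTRS = FALSE)
}

#' Simulate the parameter sweep and build the ABC reference table
#'
#' For each grid cell, calibrates `N0` at a reference mutation rate, then
#' attempts `n_tumors` simulations with per-tumor mutation rates drawn
#' log-uniformly from `mu_prior`, and summarizes the malignant outcomes
#' into the nine ABC statistics. Cells where progression is (next to)
#' impossible, or whose malignant outcomes cannot support all nine
#' statistics (e.g. an empty burden bin), are flagged and carry `NA`
#' summaries.
#'
#' @param grid Data frame from [prior_grid()].
#' @param base_params A [sim_params()] giving everything but `mu`,
#'   `s_drivers`, `s_passengers`, `n0`.
#' @param n_tumors Simulation attempts per cell.
#' @param mu_prior Log-uniform mutation-rate prior range.
#' @param mu_ref Reference rate for the N0 calibration.
#' @param calib_sims Pilot-simulation budget per cell for [calibrate_n0()].
#' @param calib_batch Pilot simulations per calibration evaluation.
#' @param seed Integer seed.
#' @param syn_driver_fraction Synonymous-driver fraction passed through to
#'   [run_tumor_batch()].
#' @param min_obs Minimum burdens for the negative binomial fit.
#' @return Data frame of class `abc_sim_table`: grid columns, `n0`,
#'   `status` (`ok` or `progression_impossible` / `insufficient`),
#'   `n_malignant`, and the nine summary columns.
#' @export
run_param_sweep <- function(grid, base_params = sim_params(),
                            n_tumors = 200, mu_prior = c(1e-12, 1e-7),
                            mu_ref = 3.2e-9, calib_sims = 48,
                            calib_batch = 12, seed = 1,
                            syn_driver_fraction = 0, min_obs = 30) {
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- base_params
    p$s_drivers <- grid$s_drivers[i]
    p$s_passengers <- grid$s_passengers[i]
    p$mu <- mu_ref
    cal <- calibrate_n0(p, batch = calib_batch, max_sims = calib_sims,
                        seed = seed + 7919L * i)
    row <- cbind(grid[i, , drop = FALSE],
                 data.frame(n0 = NA_real_, status = "progression_impossible",
                            n_malignant = 0L, stringsAsFactors = FALSE))
    smry <- stats::setNames(rep(NA_real_, 9), .SUMMARY_NAMES)
    if (!cal$progression_impossible) {
      p$n0 <- cal$n0
      row$n0 <- cal$n0
      tumors <- run_tumor_batch(p, n_tumors, seed = seed + 104729L * i,
                                mu_prior = mu_prior,
                                syn_driver_fraction = syn_driver_fraction)
      row$n_malignant <- sum(tumors$status == "malignant")
      s <- try(summarize_outcomes(tumors, r = p$r, min_obs = min_obs,
                                  widen = TRUE),
               silent = TRUE)
      if (inherits(s, "try-error")) {
        row$status <- "insufficient"
      } else {
        row$status <- "ok"
        smry <- s
      }
    }
    rows[[i]] <- cbind(row, as.data.frame(as.list(smry)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("abc_sim_table", class(out))
  out
}

#' Log-Euclidean distance between summary vectors
#'
#' Euclidean norm of the difference of element-wise logarithms. All nine
#' summary statistics live on `[0, Inf)`; the log transform tames their
#' heteroscedasticity. Variances are deliberately not normalized.
#'
#' @param a,b Positive numeric vectors of equal length.
#' @return Non-negative scalar; 0 iff `a == b`.
#' @export
abc_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a <= 0) || any(b <= 0)) {
    stop("summary statistics must be positive for the log-Euclidean distance")
  }
  sqrt(sum((log(a) - log(b))^2))
}

.summary_cols <- function(sim_table) {
  stopifnot(all(.SUMMARY_NAMES %in% names(sim_table)))
  as.matrix(sim_table[, .SUMMARY_NAMES])
}

.usable_rows <- function(sim_table) {
  s <- .summary_cols(sim_table)
  ok <- stats::complete.cases(s) & apply(s > 0, 1, all)
  if ("status" %in% names(sim_table)) ok <- ok & sim_table$status == "ok"
  ok
}

# Bagged ensemble of single-hidden-layer networks regressing targets on log
# summaries. Each member is fitted on a bootstrap resample; a row's own
# prediction is the median over the members that did NOT see it (out-of-bag),
# so the residuals entering the regression adjustment keep an honest spread
# even when individual networks interpolate the accepted set. The prediction
# at the observed summaries uses the full ensemble.
.nn_ensemble <- function(x, y, x_obs, n_nets, size = 3, decay = 0.01,
                         maxit = 400) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  xo <- (x_obs - ctr) / scl
  n <- nrow(x)
  pred_rows <- array(NA_real_, c(n_nets, n, ncol(y)))
  pred_obs <- array(NA_real_, c(n_nets, ncol(y)))
  inbag <- matrix(FALSE, n_nets, n)
  for (j in seq_len(n_nets)) {
    bs <- sample.int(n, n, replace = TRUE)
    inbag[j, unique(bs)] <- TRUE
    fit <- nnet::nnet(xs[bs, , drop = FALSE], y[bs, , drop = FALSE],
                      size = size, linout = TRUE, decay = decay,
                      maxit = maxit, trace = FALSE)
    pred_rows[j, , ] <- stats::predict(fit, xs)
    pred_obs[j, ] <- stats::predict(fit, matrix(xo, nrow = 1))
  }
  rows <- matrix(NA_real_, n, ncol(y))
  for (i in seq_len(n)) {
    oob <- which(!inbag[, i])
    use <- if (length(oob) >= 3) oob else seq_len(n_nets)
    rows[i, ] <- apply(pred_rows[use, i, , drop = FALSE], 3, stats::median)
  }
  list(rows = rows, obs = apply(pred_obs, 2, stats::median))
}

#' ABC rejection with neural-network regression adjustment
#'
#' Retains the `tolerance` fraction of simulations nearest the observed
#' summary vector under the log-Euclidean distance, then adjusts the
#' accepted log-parameters with a single-hidden-layer neural-network
#' regression: a bagged ensemble of networks is fitted to predict
#' log-parameters from summaries, and each accepted draw is shifted by the
#' difference between the ensemble-median prediction at the observed
#' summaries and its own out-of-bag prediction (out-of-bag residuals keep
#' the posterior spread honest when the accepted set is small). Point
#' estimates are the modes of Gaussian kernel densities over the adjusted
#' log-parameters; intervals are posterior quantiles.
#'
#' @param sim_table An `abc_sim_table` (or any data frame with `s_drivers`,
#'   `s_passengers` and the nine summary columns).
#' @param observed Named summary vector of the observed cohort.
#' @param tolerance Fraction of simulations accepted, in `(0, 1]`.
#' @param method `"neuralnet"` (regression adjustment) or `"rejection"`.
#' @param n_nets Ensemble size (the full-scale analysis uses 10,000; the
#'   median prediction stabilizes far below that).
#' @param min_accepted Minimum accepted simulations required.
#' @param seed Integer seed.
#' @return List of class `abc_posterior`: `accepted` (original accepted
#'   parameters + distances), `adjusted` (posterior draws, natural scale),
#'   `mle`, `ci95`, `tolerance`, `method`.
#' @export
rejection_and_adjust <- function(sim_table, observed, tolerance = 0.5,
                                 method = c("neuralnet", "rejection"),
                                 n_nets = 100, min_accepted = 50, seed = 1) {
  method <- match.arg(method)
  stopifnot(tolerance > 0, tolerance <= 1)
  ok <- .usable_rows(sim_table)
  tab <- sim_table[ok, , drop = FALSE]
  s <- .summary_cols(tab)
  obs <- observed[.SUMMARY_NAMES]
  d <- apply(s, 1, abc_distance, b = obs)
  n_keep <- ceiling(tolerance * nrow(tab))
  keep <- order(d)[seq_len(n_keep)]
  if (n_keep < min_accepted) {
    stop("only ", n_keep, " accepted simulations (< ", min_accepted, ")")
  }
  acc <- tab[keep, , drop = FALSE]
  acc$distance <- d[keep]
  theta <- log(as.matrix(acc[, c("s_drivers", "s_passengers")]))
  if (method == "neuralnet") {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    ens <- .nn_ensemble(log(s[keep, , drop = FALSE]), theta, log(obs),
                        n_nets)
    adj <- sweep(theta - ens$rows, 2, ens$obs, "+")
  } else {
    adj <- theta
  }
  colnames(adj) <- c("s_drivers", "s_passengers")
  mle <- apply(adj, 2, .kde_mode)
  ci <- apply(adj, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(accepted = acc, adjusted = exp(adj),
                 mle = exp(mle),
                 ci95 = exp(ci),
                 tolerance = tolerance, method = method),
            class = "abc_posterior")
}

.kde_mode <- function(x) {
  if (length(unique(x)) == 1) return(x[1])
  d <- stats::density(x, kernel = "gaussian")
  d$x[which.max(d$y)]
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("ABC posterior (%s, tolerance %.2f, %d accepted)\n",
              x$method, x$tolerance, nrow(x$accepted)))
  for (p in colnames(x$adjusted)) {
    cat(sprintf("  %s: MLE %.4g, 95%% CI [%.4g, %.4g]\n", p, x$mle[[p]],
                x$ci95[1, p], x$ci95[2, p]))
  }
  invisible(x)
}

#' Leave-one-out cross-validation of ABC configurations
#'
#' Each usable simulation is held out in turn and its parameters predicted
#' from the rest; the mean squared error of the log-parameters measures the
#' quality of each method x tolerance configuration.
#'
#' @param sim_table An `abc_sim_table`.
#' @param methods Methods to compare.
#' @param tolerances Tolerances to compare.
#' @param n_nets Ensemble size per held-out fit (kept small: LOO fits many
#'   ensembles).
#' @param n_folds Number of held-out simulations (defaults to all).
#' @param seed Integer seed.
#' @return Data frame of class `abc_cv_report`: `method`, `tolerance`,
#'   `mse_log` (mean over parameters and folds).
#' @export
loo_cv <- function(sim_table, methods = c("rejection", "neuralnet"),
                   tolerances = c(0.25, 0.5, 1), n_nets = 10,
                   n_folds = NULL, seed = 1) {
  ok <- which(.usable_rows(sim_table))
  tab <- sim_table[ok, , drop = FALSE]
  n <- nrow(tab)
  folds <- if (is.null(n_folds)) seq_len(n) else seq_len(min(n_folds, n))
  cfg <- expand.grid(method = methods, tolerance = tolerances,
                     stringsAsFactors = FALSE)
  cfg$mse_log <- NA_real_
  for (ci in seq_len(nrow(cfg))) {
    errs <- matrix(NA_real_, length(folds), 2)
    for (f in folds) {
      train <- tab[-f, , drop = FALSE]
      obs <- unlist(tab[f, .SUMMARY_NAMES])
      truth <- log(unlist(tab[f, c("s_drivers", "s_passengers")]))
      post <- try(rejection_and_adjust(train, obs,
                                       tolerance = cfg$tolerance[ci],
                                       method = cfg$method[ci],
                                       n_nets = n_nets, min_accepted = 2,
                                       seed = seed + f), silent = TRUE)
      if (inherits(post, "try-error")) next
      pred <- colMeans(log(post$adjusted))
      errs[f, ] <- (pred - truth)^2
    }
    cfg$mse_log[ci] <- mean(errs, na.rm = TRUE)
  }
  class(cfg) <- c("abc_cv_report", class(cfg))
  cfg
}

#' Posterior model probabilities over synonymous-driver fractions
#'
#' Treats each synonymous-driver fraction as a model. Simulations from all
#' models are pooled, the nearest `tolerance` fraction to the observed
#' summaries is accepted, and a multinomial logistic regression of the
#' model indicator on the log summaries, evaluated at the observed
#' summaries, gives the posterior mass of each model. The mass at fraction
#' 0 (the base model without synonymous drivers) serves as a one-sided
#' p-value for the null that synonymous drivers are absent.
#'
#' @param sim_table An `abc_sim_table` with a `syn_fraction` column.
#' @param observed Named summary vector.
#' @param tolerance Accepted fraction.
#' @param seed Integer seed.
#' @return List of class `abc_model_posterior`: `mass` (named by fraction,
#'   sums to 1), `p_base` (mass at fraction 0), `posterior_mean_fraction`.
#' @export
model_posterior <- function(sim_table, observed, tolerance = 0.5, seed = 1) {
  stopifnot("syn_fraction" %in% names(sim_table))
  ok <- .usable_rows(sim_table)
  tab <- sim_table[ok, , drop = FALSE]
  s <- .summary_cols(tab)
  obs <- observed[.SUMMARY_NAMES]
  d <- apply(s, 1, abc_distance, b = obs)
  keep <- order(d)[seq_len(ceiling(tolerance * nrow(tab)))]
  acc <- tab[keep, , drop = FALSE]
  levels_all <- sort(unique(tab$syn_fraction))
  n_per <- table(factor(acc$syn_fraction, levels = levels_all))
  if (any(n_per == 0)) {
    stop("model(s) with no accepted simulations: ",
         paste(levels_all[n_per == 0], collapse = ", "))
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  y <- factor(acc$syn_fraction, levels = levels_all)
  x <- log(.summary_cols(acc))
  if (length(levels_all) == 1) {
    mass <- stats::setNames(1, levels_all)
  } else {
    df <- data.frame(y = y, x)
    fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 400)
    nd <- as.data.frame(as.list(log(obs)))
    names(nd) <- colnames(x)
    pr <- stats::predict(fit, nd, type = "probs")
    if (length(levels_all) == 2) {
      # two-model case: predict() returns P(second level) as a scalar
      mass <- stats::setNames(c(1 - pr, pr), levels_all)
    } else {
      mass <- stats::setNames(as.numeric(pr[as.character(levels_all)]),
                              levels_all)
    }
  }
  mass <- mass / sum(mass)
  structure(list(mass = mass,
                 p_base = unname(mass[as.character(min(levels_all))]),
                 posterior_mean_fraction =
                   sum(as.numeric(names(mass)) * mass)),
            class = "abc_model_posterior")
}
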