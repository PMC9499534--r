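#' Simulation parameters for the tumor evolution model
#'
#' The model is a well-mixed population of cells that stochastically divide
#' and die. During division a cell acquires Poisson-distributed advantageous
#' drivers (rate `mu * T_drivers`) and deleterious passengers (rate
#' `mu * T_passengers`) with exponentially distributed fitness effects.
#' Birth rate is proportional to cellular fitness; death rate
#' `D(N; N0) = log(1 + N(e-1)/N0)` rises with population size, giving
#' Gompertzian density regulation with equilibrium at `N0` for neutral
#' populations. A tumor ends extinct (N = 0), malignant
#' (N >= `n_malignant`), or timed out (~100 years, 18,500 generations).
#'
#' @param mu Mutation rate (mutations per nucleotide per generation).
#' @param t_drivers,t_passengers Nonsynonymous target sizes (loci). Defaults
#'   are a 300-gene driver target (286,886 loci) and the remaining coding
#'   genome (20,451,136 loci).
#' @param s_drivers,s_passengers Mean fitness effects of the exponential
#'   DFEs (drivers beneficial, passengers deleterious). `s_drivers = 0`
#'   disables adaptive evolution (drivers confer no benefit).
#' @param n0 Initial / regulation population size (cells).
#' @param epistasis `"multiplicative"` (`f = prod(1+s_i)`) or
#'   `"diminishing_returns"` (`df = s/(1 + nu*f)`).
#' @param nu Diminishing-returns strength.
#' @param n_malignant Malignancy threshold (cells).
#' @param max_generations Time cap in generations (~100 years).
#' @param r Genome-wide nonsynonymous-to-synonymous locus ratio, used when
#'   attaching synonymous mutations to outcomes.
#' @param event_cap Hard cap on simulation events; exceeding it aborts.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(mu = 1e-9,
                       t_drivers = 286886,
                       t_passengers = 20451136,
                       s_drivers = 0.1,
                       s_passengers = 0.001,
                       n0 = 10,
                       epistasis = c("multiplicative", "diminishing_returns"),
                       nu = 1,
                       n_malignant = 1e6,
                       max_generations = 18500,
                       r = 2.795,
                       event_cap = 1e9) {
  epistasis <- match.arg(epistasis)
  stopifnot(mu >= 0, t_drivers > 0, t_passengers > 0,
            s_drivers >= 0, s_passengers >= 0, n0 > 0,
            n_malignant > 1, max_generations > 0, r > 0)
  structure(list(mu = mu, t_drivers = t_drivers, t_passengers = t_passengers,
                 s_drivers = s_drivers, s_passengers = s_passengers,
                 n0 = n0, epistasis = epistasis, nu = nu,
                 n_malignant = n_malignant,
                 max_generations = max_generations, r = r,
                 event_cap = event_cap),
            class = "sim_params")
}

#' Poisson number of new mutations per division
#'
#' @param mu Mutation rate per nucleotide per generation.
#' @param target Target size in loci.
#' @param n Number of divisions to draw for.
#' @return Integer vector of mutation counts.
#' @export
draw_mutations <- function(mu, target, n = 1) {
  stopifnot(mu >= 0, target >= 0)
  stats::rpois(n, mu * target)
}

#' Exponentially distributed fitness effects
#'
#' Drivers draw positive effects, passengers negative, both with
#' exponential magnitude of the given mean.
#'
#' @param mean_s Mean |effect| of the DFE (> 0).
#' @param sign `"driver"` (positive) or `"passenger"` (negative).
#' @param n Number of draws.
#' @return Numeric vector of signed effects.
#' @export
draw_effect <- function(mean_s, sign = c("driver", "passenger"), n = 1) {
  sign <- match.arg(sign)
  if (mean_s <= 0) stop("mean_s must be positive")
  x <- stats::rexp(n, rate = 1 / mean_s)
  if (sign == "passenger") -x else x
}

#' Apply a mutation's effect to cellular fitness
#'
#' @param f Current fitness.
#' @param effect Signed fitness effect.
#' @param mode Epistasis mode.
#' @param nu Diminishing-returns strength.
#' @return Updated fitness; values driven at or below 0 are floored at 0
#'   (lethal: the cell can no longer divide).
#' @export
update_fitness <- function(f, effect,
                           mode = c("multiplicative", "diminishing_returns"),
                           nu = 1) {
  mode <- match.arg(mode)
  out <- if (mode == "multiplicative") f * (1 + effect)
         else f + effect / (1 + nu * f)
  pmax(out, 0)
}

#' Density-dependent per-cell death rate
#'
#' `D(N; N0) = log(1 + N(e-1)/N0)`: zero at N = 0, exactly 1 at N = N0
#' (balancing the unit birth rate of a neutral cell), increasing and
#' concave in N.
#'
#' @param n Population size.
#' @param n0 Regulation size.
#' @return Death rate per cell.
#' @export
death_rate <- function(n, n0) {
  if (any(n0 <= 0)) stop("n0 must be positive")
  out <- log1p(n * (exp(1) - 1) / n0)
  # the identity D(N0; N0) = log(e) = 1 holds exactly, not to 1 ulp
  out[n == n0] <- 1
  out
}

#' Run one tumor simulation
#'
#' Event-driven (Gillespie) birth-death simulation of the model in
#' [sim_params()]. Identical genotypes are aggregated into clones; the
#' genealogy is retained so the most recent common ancestor of the final
#' population can be extracted exactly. Only mutations present in the MRCA
#' are "fixed". RNG comes from R's stream: `set.seed()` before calling
#' makes the outcome deterministic.
#'
#' @param params A [sim_params()] object.
#' @return List of class `sim_outcome`: `status` (`extinct`, `malignant`,
#'   `timeout`), `generations`, `n_final`, `mean_fitness`, `mean_n`
#'   (time-weighted mean population size), `t_mrca` (generations until the
#'   MRCA arose), `fixed` (data frame `class`, `coding`, `effect`), `mu`,
#'   and event diagnostics.
#' @export
run_simulation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  res <- sim_tumor_cpp(params$mu * params$t_drivers,
                       params$mu * params$t_passengers,
                       params$s_drivers, params$s_passengers,
                       params$n0,
                       as.integer(params$epistasis == "multiplicative"),
                       params$nu, params$n_malignant,
                       params$max_generations, params$event_cap)
  if (res$status == "event_cap") {
    stop("simulation exceeded event cap (", params$event_cap,
         " events) at N = ", res$n_final, ", generation ",
         round(res$generations))
  }
  fixed <- data.frame(
    class = c("driver", "passenger")[res$fixed_class + 1L],
    coding = rep("nonsyn", length(res$fixed_class)),
    effect = res$fixed_effects,
    stringsAsFactors = FALSE
  )
  structure(list(status = res$status, generations = res$generations,
                 n_final = res$n_final, mean_fitness = res$mean_fitness,
                 mean_n = res$mean_n, t_mrca = res$t_mrca, fixed = fixed,
                 mu = params$mu, n_events = res$n_events,
                 n_clones = res$n_clones),
            class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf("tumor %s after %.0f generations (N = %g, %d fixed mutations)\n",
              x$status, x$generations, x$n_final, nrow(x$fixed)))
  invisible(x)
}

#' Synonymous mutation counts for a simulated tumor
#'
#' Simulated mutations are nonsynonymous (they carry fitness effects);
#' neutral synonymous hitchhikers are attached afterwards as a Poisson draw
#' with mean `(mu * target / r) * t_mrca`, separately for the driver and
#' passenger target regions.
#'
#' @param mu Mutation rate.
#' @param target Nonsynonymous target size (loci).
#' @param r Nonsynonymous-to-synonymous locus ratio (default 2.795).
#' @param t_mrca Divisions until the MRCA arose.
#' @param n Number of draws.
#' @return Integer vector of synonymous counts.
#' @export
emit_synonymous <- function(mu, target, r = 2.795, t_mrca, n = 1) {
  if (any(t_mrca < 0)) stop("t_mrca must be non-negative")
  stats::rpois(n, (mu * target / r) * t_mrca)
}

#' Relabel a fraction of fixed nonsynonymous drivers as synonymous
#'
#' Models positive selection on synonymous driver sites: each fixed
#' nonsynonymous driver is independently relabeled `coding = "syn"` with
#' the given probability, keeping its fitness effect. Total fixed-mutation
#' count is conserved.
#'
#' @param outcome A `sim_outcome`.
#' @param fraction Relabeling probability in `[0, 0.2]`.
#' @return The outcome with relabeled `fixed$coding`.
#' @export
relabel_synonymous_drivers <- function(outcome, fraction) {
  if (fraction < 0 || fraction > 0.2) {
    stop("synonymous-driver fraction must be in [0, 0.2]")
  }
  if (fraction == 0 || nrow(outcome$fixed) == 0) return(outcome)
  idx <- which(outcome$fixed$class == "driver" &
                 outcome$fixed$coding == "nonsyn")
  flip <- idx[stats::runif(length(idx)) < fraction]
  outcome$fixed$coding[flip] <- "syn"
  outcome
}

#' Simulate a batch of tumors at one parameter set
#'
#' Runs `n_tumors` independent simulations, attaches synonymous counts to
#' malignant outcomes, and returns one row per tumor with the quantities
#' the ABC summaries need.
#'
#' @param params A [sim_params()] object; if `mu_prior` is given, each
#'   tumor's `mu` is drawn log-uniformly from that range instead of
#'   `params$mu`.
#' @param n_tumors Number of tumors to attempt.
#' @param seed Integer seed.
#' @param mu_prior Optional `c(low, high)` range for a log-uniform mutation
#'   rate prior (the full-model prior is `c(1e-12, 1e-7)`).
#' @param syn_driver_fraction Fraction of fixed nonsynonymous drivers
#'   relabeled synonymous (default 0).
#' @return Data frame, one row per tumor: `status`, `mu`, `generations`,
#'   `t_mrca`, `dn_driver`, `dn_passenger`, `ds_driver`, `ds_passenger`,
#'   `burden`, `mean_fitness`, `mean_passenger_effect`, `sum_driver_effect`,
#'   `sum_passenger_effect`.
#' @export
run_tumor_batch <- function(params, n_tumors, seed = 1, mu_prior = NULL,
                            syn_driver_fraction = 0) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  rows <- vector("list", n_tumors)
  for (i in seq_len(n_tumors)) {
    p <- params
    if (!is.null(mu_prior)) {
      p$mu <- 10^stats::runif(1, log10(mu_prior[1]), log10(mu_prior[2]))
    }
    out <- run_simulation(p)
    dn_d <- dn_p <- ds_d <- ds_p <- 0L
    mpe <- NA_real_; sde <- spe <- 0
    if (out$status == "malignant") {
      if (syn_driver_fraction > 0) {
        out <- relabel_synonymous_drivers(out, syn_driver_fraction)
      }
      fx <- out$fixed
      drv <- fx$class == "driver"
      dn_d <- sum(drv & fx$coding == "nonsyn")
      ds_d <- sum(drv & fx$coding == "syn") +
        emit_synonymous(p$mu, p$t_drivers, p$r, out$t_mrca)
      dn_p <- sum(!drv)
      ds_p <- emit_synonymous(p$mu, p$t_passengers, p$r, out$t_mrca)
      if (any(!drv)) mpe <- mean(abs(fx$effect[!drv]))
      sde <- sum(fx$effect[drv])
      spe <- sum(fx$effect[!drv])
    }
    rows[[i]] <- data.frame(
      status = out$status, mu = p$mu, generations = out$generations,
      t_mrca = out$t_mrca, dn_driver = dn_d, dn_passenger = dn_p,
      ds_driver = as.integer(ds_d), ds_passenger = as.integer(ds_p),
      burden = dn_d + dn_p + as.integer(ds_d) + as.integer(ds_p),
      mean_fitness = out$mean_fitness, mean_passenger_effect = mpe,
      sum_driver_effect = sde, sum_passenger_effect = spe,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Calibrate the initial population size N0
#'
#' The probability of progression to malignancy rises with `N0`. This
#' routine finds, by stochastic bisection on pilot simulation batches, the
#' `N0` in `[1, 100]` at which the progression probability is 0.5 (the time
#' cap is folded into the estimate: a tumor that would need more than
#' `max_generations` counts as a failure). Wilson score intervals on each
#' batch decide whether more pilots are needed before moving the bracket.
#'
#' @param params A [sim_params()] object; its `n0` is ignored.
#' @param target Target progression probability (0.5).
#' @param tol Acceptable |estimate - target|.
#' @param batch Pilot simulations per evaluation round.
#' @param max_sims Total pilot simulation budget.
#' @param n0_range Admissible N0 range.
#' @param seed Integer seed.
#' @return List: `n0`, `p_hat` (progression probability there), `n_sims`.
#'   If no `N0` in range reaches a progression probability of 0.1%, the
#'   parameter set is annotated `progression_impossible = TRUE` and `n0` is
#'   `NA`.
#' @export
calibrate_n0 <- function(params, target = 0.5, tol = 0.05, batch = 25,
                         max_sims = 600, n0_range = c(1, 100), seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  used <- 0
  p_cancer <- function(n0, n_min) {
    p <- params; p$n0 <- n0
    succ <- 0; tot <- 0
    while (tot < n_min && used < max_sims) {
      k <- min(batch, max_sims - used)
      st <- vapply(seq_len(k), function(i) run_simulation(p)$status,
                   character(1))
      succ <- succ + sum(st == "malignant"); tot <- tot + k; used <<- used + k
      # stop early once the Wilson interval separates from the target
      ci <- .wilson(succ, tot)
      if (ci[1] > target + tol || ci[2] < target - tol) break
      if (abs(succ / tot - target) < tol && tot >= n_min) break
    }
    list(p = if (tot > 0) succ / tot else NA_real_, n = tot)
  }
  # first-order manifold (deleterious flux balancing adaptive flux) seeds
  # the bisection; most parameter sets converge in one or two evaluations
  guess <- params$t_passengers * params$s_passengers /
    max(params$t_drivers * params$s_drivers, .Machine$double.eps)
  guess <- round(min(max(guess, n0_range[1]), n0_range[2]))
  g_eval <- p_cancer(guess, batch)
  if (!is.na(g_eval$p) && abs(g_eval$p - target) <= tol) {
    return(list(n0 = guess, p_hat = g_eval$p, n_sims = used,
                progression_impossible = FALSE))
  }
  if (is.na(g_eval$p)) {
    return(list(n0 = guess, p_hat = NA_real_, n_sims = used,
                progression_impossible = FALSE))
  }
  if (g_eval$p < target) {
    if (guess >= n0_range[2] || used >= max_sims) {
      return(list(n0 = n0_range[2], p_hat = g_eval$p, n_sims = used,
                  progression_impossible = g_eval$p < 0.001 &&
                    guess >= n0_range[2]))
    }
    hi <- p_cancer(n0_range[2], batch)
    if (!is.na(hi$p) && hi$p < 0.001) {
      # no progression observed anywhere in range at this pilot budget
      return(list(n0 = NA_real_, p_hat = hi$p, n_sims = used,
                  progression_impossible = TRUE))
    }
    if (is.na(hi$p) || hi$p <= target) {
      return(list(n0 = n0_range[2], p_hat = hi$p, n_sims = used,
                  progression_impossible = FALSE))
    }
    lo <- guess; hi_n <- n0_range[2]
    best <- if (abs(hi$p - target) < abs(g_eval$p - target)) {
      list(n0 = n0_range[2], p_hat = hi$p)
    } else list(n0 = guess, p_hat = g_eval$p)
  } else {
    lo <- n0_range[1]; hi_n <- guess
    best <- list(n0 = guess, p_hat = g_eval$p)
  }
  while (used + batch <= max_sims && (hi_n - lo) > 1) {
    mid <- round(exp((log(max(lo, 1)) + log(hi_n)) / 2))
    if (mid <= lo || mid >= hi_n) mid <- (lo + hi_n) %/% 2
    if (mid <= lo || mid >= hi_n) break
    ev <- p_cancer(mid, batch)
    if (is.na(ev$p)) break
    # keep the evaluated point whose estimate is closest to the target
    if (abs(ev$p - target) < abs(best$p_hat - target)) {
      best <- list(n0 = mid, p_hat = ev$p)
    }
    if (abs(ev$p - target) <= tol) break
    if (ev$p < target) lo <- mid else hi_n <- mid
  }
  list(n0 = best$n0, p_hat = best$p_hat, n_sims = used,
       progression_impossible = FALSE)
}

.wilson <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(0, 1))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, mid - hw), min(1, mid + hw))
}
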