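test_that("negative binomial parameters are recovered from truncated draws", {
  set.seed(21)
  k <- stats::rnbinom(12000, size = 5, prob = 0.3)
  fit <- fit_negbin(k)
  expect_true(fit$n > 4.5 && fit$n < 5.5)
  expect_true(fit$p > 0.27 && fit$p < 0.33)
  # support filter drops 0 and > 1000
  expect_equal(fit$n_obs, sum(k >= 1 & k <= 1000))
  # optimum: perturbing parameters lowers the likelihood
  ll <- function(n, p) {
    z <- stats::pnbinom(1000, n, p) - stats::pnbinom(0, n, p)
    kk <- k[k >= 1 & k <= 1000]
    sum(stats::dnbinom(kk, n, p, log = TRUE)) - length(kk) * log(z)
  }
  expect_gt(fit$loglik, ll(fit$n * 1.2, fit$p))
  expect_gt(fit$loglik, ll(fit$n, min(fit$p * 1.2, 0.99)))
  expect_error(fit_negbin(rep(5, 100)), "degenerate")
  expect_error(fit_negbin(stats::rnbinom(10, 5, 0.3)), "at least")
})

test_that("gamma shape is recovered by pdf MLE and is scale invariant", {
  set.seed(22)
  t5 <- stats::rgamma(10000, shape = 5, scale = 12)
  fit <- fit_gamma_incidence(t5, "pdf_mle")
  expect_true(fit$k > 4.8 && fit$k < 5.2)
  expect_lt(abs(fit$theta - 12) / 12, 0.1)
  # theta is a pure gauge: rescaling time leaves k unchanged
  fit_scaled <- fit_gamma_incidence(t5 * 37, "pdf_mle")
  expect_lt(abs(fit_scaled$k - fit$k) / fit$k, 1e-6)
  # exponential special case has shape 1
  fe <- fit_gamma_incidence(stats::rexp(10000, 1 / 30), "pdf_mle")
  expect_lt(abs(fe$k - 1), 0.05)
  expect_error(fit_gamma_incidence(c(1, 2, 3), "pdf_mle"), "at least 5")
})

test_that("gamma CDF least squares fits an exact incidence curve", {
  ages <- seq(20, 90, by = 5)
  curve <- data.frame(age = ages,
                      incidence = stats::pgamma(ages, shape = 6, scale = 11))
  fit <- fit_gamma_incidence(curve, "cdf_leastsq")
  expect_lt(abs(fit$k - 6) / 6, 0.05)
  # ages below 20 are excluded
  with_young <- rbind(data.frame(age = c(5, 10), incidence = c(0.5, 0.6)),
                      curve)
  fit2 <- fit_gamma_incidence(with_young, "cdf_leastsq")
  expect_lt(abs(fit2$k - fit$k) / fit$k, 0.05)
})

test_that("simulated binned dN/dS uses the r-corrected count ratio", {
  tum <- data.frame(status = "malignant",
                    burden = c(5, 50, 500),
                    dn_driver = c(4, 28, 60), ds_driver = c(2, 4, 30),
                    dn_passenger = c(6, 90, 800),
                    ds_passenger = c(2, 30, 280))
  out <- binned_dnds(tum, "simulated")
  expect_equal(out[["dnds_drv_b2"]], 28 / (4 * 2.795))
  expect_equal(unname(out["dnds_drv_b2"]), 2.504, tolerance = 1e-3)
  # neutral construction: dn = r * ds in every bin gives 1
  neutral <- transform(tum, dn_driver = round(ds_driver * 2.795),
                       dn_passenger = round(ds_passenger * 2.795))
  expect_equal(unname(binned_dnds(neutral, "simulated")["dnds_pas_b1"]),
               round(2 * 2.795) / (2 * 2.795))
  # empty bin errors by default, widens on request
  sparse <- tum[2:3, ]
  expect_error(binned_dnds(sparse, "simulated"), "\\(0,10\\]")
  widened <- binned_dnds(sparse, "simulated", widen = TRUE)
  expect_equal(widened[["dnds_drv_b1"]], widened[["dnds_drv_b2"]])
})

test_that("observed binned dN/dS pools variants within burden bins", {
  gm <- fx_gene_models()
  sites <- fx_sites()
  opp <- fx_opportunities()
  drivers <- gm$genes[1:5]
  coh <- simulate_cohort(gm, "flat",
                         omega = c(driver = 1.6, passenger = 0.7),
                         burden_dist = function(n)
                           sample(c(5, 50, 400), n, TRUE),
                         n_samples = 150, seed = 23,
                         driver_genes = drivers, sites = sites)
  out <- binned_dnds(coh$variants, "observed", opportunities = opp,
                     driver_genes = drivers, bins = c(0, 10, 100, 1000))
  expect_true(all(out[1:3] > 1))    # drivers under positive selection
  expect_true(all(out[4:6] < 0.85)) # passengers under negative selection
})

test_that("summary vector has nine positive entries for a dense cohort", {
  tum <- data.frame(status = "malignant",
                    burden = pmax(1, stats::rnbinom(200, 4, 0.2)),
                    generations = stats::rgamma(200, 4, scale = 500))
  tum$ds_driver <- stats::rpois(200, 2) + 1
  tum$dn_driver <- stats::rpois(200, 2 * 2.795)
  tum$ds_passenger <- stats::rpois(200, 5) + 1
  tum$dn_passenger <- stats::rpois(200, 5 * 2.795)
  s <- summarize_outcomes(tum, widen = TRUE)
  expect_equal(length(s), 9)
  expect_named(s, c("dnds_drv_b1", "dnds_drv_b2", "dnds_drv_b3",
                    "dnds_pas_b1", "dnds_pas_b2", "dnds_pas_b3",
                    "nb_n", "nb_p", "gamma_k"))
  expect_true(all(s > 0))
})

test_that("expression-burden association finds an injected trend", {
  set.seed(24)
  samples <- data.frame(sample_id = sprintf("s%03d", 1:300),
                        burden = round(10^stats::runif(300, 0, 3)))
  gs <- sprintf("gene%04d", 1:30)
  expr <- simulate_expression(200, samples, gs, slope = 2, noise = 0.5,
                              seed = 25)
  hit <- expression_burden_association(expr, gs, samples)
  expect_gt(hit$r_squared, 0.9)
  expect_gt(hit$slope, 0)
  # no trend without a slope
  expr0 <- simulate_expression(200, samples, gs, slope = 0, noise = 0.5,
                               seed = 26)
  null <- expression_burden_association(expr0, gs, samples)
  expect_lt(null$r_squared, 0.5)
  # shuffled burdens destroy the association
  shuffled <- samples
  shuffled$burden <- sample(shuffled$burden)
  shuf <- expression_burden_association(expr, gs, shuffled)
  expect_lt(shuf$r_squared, 0.5)
  # degenerate inputs
  const <- expr; const[] <- 1
  expect_error(expression_burden_association(const, gs, samples),
               "constant")
  expect_error(expression_burden_association(expr, "nope", samples),
               "disjoint")
})
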