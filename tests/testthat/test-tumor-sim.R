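test_that("death rate is exactly 1 at N0, 0 at 0, increasing and concave", {
  expect_equal(death_rate(0, 10), 0)
  expect_equal(death_rate(10, 10), 1)
  expect_equal(death_rate(50, 50), 1)
  n <- seq(0, 1000, by = 10)
  d <- death_rate(n, 100)
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(diff(d)) < 0))
  expect_error(death_rate(10, 0), "positive")
})

test_that("fitness updates follow the two epistasis models", {
  expect_equal(update_fitness(1, 0.1, "multiplicative"), 1.1)
  expect_equal(update_fitness(1, 0.1, "diminishing_returns", nu = 1), 1.05)
  # multiplicative product is order-independent
  effects <- c(0.2, -0.05, 0.1, -0.01)
  f1 <- Reduce(function(f, s) update_fitness(f, s, "multiplicative"),
               effects, accumulate = FALSE, init = 1)
  f2 <- Reduce(function(f, s) update_fitness(f, s, "multiplicative"),
               rev(effects), accumulate = FALSE, init = 1)
  expect_equal(f1, f2)
  # lethal floor
  expect_equal(update_fitness(1, -1.5, "multiplicative"), 0)
})

test_that("mutation counts are Poisson with the right moments", {
  expect_true(all(draw_mutations(0, 1e6, 100) == 0))
  set.seed(1)
  x <- draw_mutations(1e-6, 1e4, 1e5)   # lambda = 0.01
  lam <- 0.01
  tol <- 3 * sqrt(lam / 1e5)
  expect_lt(abs(mean(x) - lam), tol)
  expect_lt(abs(stats::var(x) - lam), 5 * tol)
})

test_that("fitness effects are exponential with the right sign and mean", {
  set.seed(2)
  d <- draw_effect(0.0103, "driver", 1e5)
  p <- draw_effect(0.0103, "passenger", 1e5)
  expect_true(all(d > 0))
  expect_true(all(p < 0))
  expect_lt(abs(mean(d) - 0.0103), 3 * 0.0103 / sqrt(1e5))
  expect_lt(abs(mean(-p) - 0.0103), 3 * 0.0103 / sqrt(1e5))
  expect_error(draw_effect(0, "driver"), "positive")
})

test_that("a mutation-free population fluctuates about N0", {
  set.seed(10)
  out <- run_simulation(sim_params(mu = 0, n0 = 60, n_malignant = 1e4,
                                   max_generations = 1500))
  expect_equal(out$status, "timeout")
  expect_equal(nrow(out$fixed), 0)
  expect_lt(abs(out$mean_n - 60) / 60, 0.15)
})

test_that("identical parameters and seed give identical outcomes", {
  p <- sim_params(mu = 5e-9, s_drivers = 0.3, s_passengers = 1e-3,
                  n0 = 10, n_malignant = 5e3)
  set.seed(77); a <- run_simulation(p)
  set.seed(77); b <- run_simulation(p)
  expect_identical(a, b)
})

test_that("malignant status implies the population threshold was reached", {
  set.seed(12)
  for (i in 1:5) {
    out <- run_simulation(sim_params(mu = 1e-8, s_drivers = 0.4,
                                     s_passengers = 1e-3, n0 = 10,
                                     n_malignant = 2e3,
                                     max_generations = 5000))
    if (out$status == "malignant") expect_gte(out$n_final, 2e3)
  }
})

test_that("strong passengers at high mutation rate drive extinction", {
  # Muller's ratchet regime: mean passenger cost 10%, muT_passengers ~ 1
  set.seed(13)
  p <- sim_params(mu = 5e-8, s_drivers = 0.01, s_passengers = 0.1,
                  n0 = 50, n_malignant = 1e4, max_generations = 2000)
  st <- replicate(20, run_simulation(p)$status)
  expect_gt(mean(st == "extinct"), 0.5)
})

test_that("synonymous counts are Poisson in t_MRCA with the r correction", {
  expect_equal(emit_synonymous(1e-9, 1e6, t_mrca = 0), 0)
  set.seed(14)
  lam <- (1e-8 * 2e6 / 2.795) * 500
  x <- emit_synonymous(1e-8, 2e6, r = 2.795, t_mrca = 500, n = 2e4)
  expect_lt(abs(mean(x) - lam), 3 * sqrt(lam / 2e4))
  expect_error(emit_synonymous(1e-9, 1e6, t_mrca = -1), "non-negative")
})

test_that("synonymous-driver relabeling conserves mutations", {
  fx <- data.frame(class = rep(c("driver", "passenger"), c(200, 100)),
                   coding = "nonsyn", effect = 0.1,
                   stringsAsFactors = FALSE)
  out <- list(fixed = fx)
  expect_identical(relabel_synonymous_drivers(out, 0), out)
  expect_error(relabel_synonymous_drivers(out, 0.5), "0.2")
  set.seed(15)
  flipped <- replicate(50, {
    o <- relabel_synonymous_drivers(out, 0.2)
    expect_equal(nrow(o$fixed), nrow(fx))
    sum(o$fixed$coding == "syn")
  })
  expect_lt(abs(mean(flipped) / 200 - 0.2), 0.02)
})

test_that("N0 calibration responds to driver strength and hits its target", {
  base <- sim_params(mu = 1e-8, s_passengers = 5e-3, n0 = 10,
                     n_malignant = 2e3, max_generations = 3000)
  n0s <- vapply(c(0.15, 0.4, 1.0), function(sd) {
    p <- base; p$s_drivers <- sd
    cal <- calibrate_n0(p, batch = 15, max_sims = 90, seed = 31)
    expect_false(cal$progression_impossible)
    expect_true(cal$n0 >= 1 && cal$n0 <= 100)
    cal$n0
  }, numeric(1))
  # stronger drivers need a weakly smaller initial population
  expect_true(all(diff(n0s) <= 0))

  # without beneficial drivers, progression is impossible
  p0 <- base; p0$s_drivers <- 0
  cal0 <- calibrate_n0(p0, batch = 10, max_sims = 30, seed = 32)
  expect_true(cal0$progression_impossible)
})

test_that("fixed passengers are milder than the DFE mean", {
  # fixation favors the mildest passengers; compare |effect| of fixed
  # passengers to the DFE mean they were drawn from
  p <- sim_params(mu = 2e-8, s_drivers = 0.4, s_passengers = 0.01,
                  n0 = 10, n_malignant = 1e4)
  set.seed(16)
  effs <- c()
  for (i in 1:30) {
    out <- run_simulation(p)
    if (out$status == "malignant") {
      pas <- out$fixed$effect[out$fixed$class == "passenger"]
      effs <- c(effs, abs(pas))
    }
  }
  expect_gt(length(effs), 20)
  expect_lt(mean(effs), 0.01)
})
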