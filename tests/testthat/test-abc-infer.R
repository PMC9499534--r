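# Synthetic ABC reference tables with a known, smooth parameter-to-summary
# map let the inference machinery be tested independently of the simulator.
fake_sim_table <- function(n_side = 12, noise = 0, seed = 1,
                           syn_fraction = NULL) {
  set.seed(seed)
  g <- prior_grid(n_side, n_side)
  f <- function(sd, sp) {
    cbind(dnds_drv_b1 = 5 * sd^0.3, dnds_drv_b2 = 3 * sd^0.2,
          dnds_drv_b3 = 1.5 * sd^0.1, dnds_pas_b1 = 0.5 + 20 * sp,
          dnds_pas_b2 = 0.7 + 15 * sp, dnds_pas_b3 = 0.9 + 5 * sp,
          nb_n = 2 + 100 * sp, nb_p = 0.1 + sd / 10,
          gamma_k = 1 + 2 * sd + 50 * sp)
  }
  s <- f(g$s_drivers, g$s_passengers)
  if (noise > 0) s <- s * exp(matrix(stats::rnorm(length(s), 0, noise),
                                     nrow(s)))
  tab <- cbind(g, as.data.frame(s))
  tab$status <- "ok"
  tab$n_malignant <- 200L
  if (!is.null(syn_fraction)) {
    out <- do.call(rbind, lapply(syn_fraction, function(fr) {
      t2 <- tab
      t2$syn_fraction <- fr
      # synonymous drivers depress apparent driver dN/dS
      t2$dnds_drv_b1 <- t2$dnds_drv_b1 / (1 + 3 * fr)
      t2$dnds_drv_b2 <- t2$dnds_drv_b2 / (1 + 2 * fr)
      t2
    }))
    return(out)
  }
  tab
}

test_that("log-Euclidean distance has metric properties", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  names(a) <- names(b) <- letters[1:3]
  expect_equal(abc_distance(a, b), 0)
  b2 <- b; b2[2] <- b[2] * exp(1)
  expect_equal(abc_distance(a, b2), 1)
  expect_equal(abc_distance(a, b2), abc_distance(b2, a))
  expect_error(abc_distance(c(1, -1, 2), b), "positive")
  set.seed(31)
  for (i in 1:50) {
    x <- stats::rlnorm(5); y <- stats::rlnorm(5); z <- stats::rlnorm(5)
    expect_lte(abc_distance(x, z),
               abc_distance(x, y) + abc_distance(y, z) + 1e-12)
  }
})

summary_names <- c("dnds_drv_b1", "dnds_drv_b2", "dnds_drv_b3",
                   "dnds_pas_b1", "dnds_pas_b2", "dnds_pas_b3",
                   "nb_n", "nb_p", "gamma_k")

test_that("tolerance retains exactly the requested fraction", {
  tab <- fake_sim_table(10, noise = 0.05, seed = 2)
  obs <- unlist(tab[37, summary_names])
  post <- rejection_and_adjust(tab, obs, tolerance = 0.5,
                               method = "rejection", min_accepted = 10)
  expect_equal(nrow(post$accepted), ceiling(0.5 * nrow(tab)))
  expect_error(rejection_and_adjust(tab, obs, tolerance = 0.1,
                                    min_accepted = 50), "accepted")
})

test_that("posterior concentrates on the generating cell", {
  tab <- fake_sim_table(12, noise = 0, seed = 3)
  truth_row <- 67
  obs <- unlist(tab[truth_row, summary_names])
  post <- rejection_and_adjust(tab, obs, tolerance = 1, min_accepted = 10,
                               n_nets = 20, seed = 4)
  truth <- unlist(tab[truth_row, c("s_drivers", "s_passengers")])
  expect_true(post$ci95[1, "s_drivers"] <= truth["s_drivers"] &&
                truth["s_drivers"] <= post$ci95[2, "s_drivers"])
  expect_true(post$ci95[1, "s_passengers"] <= truth["s_passengers"] &&
                truth["s_passengers"] <= post$ci95[2, "s_passengers"])
  # pure rejection at tolerance 1 keeps everything: the accepted set is
  # the full usable table
  r <- rejection_and_adjust(tab, obs, tolerance = 1, method = "rejection",
                            min_accepted = 10)
  expect_equal(nrow(r$accepted), nrow(tab))
  # nearest simulation is the generating one
  expect_equal(which.min(r$accepted$distance[order(r$accepted$distance)]), 1)
})

test_that("regression adjustment beats pure rejection on noisy tables", {
  tab <- fake_sim_table(10, noise = 0.08, seed = 5)
  cv <- loo_cv(tab, methods = c("rejection", "neuralnet"),
               tolerances = 0.5, n_nets = 8, n_folds = 25, seed = 6)
  expect_equal(nrow(cv), 2)
  mse_rej <- cv$mse_log[cv$method == "rejection"]
  mse_nn <- cv$mse_log[cv$method == "neuralnet"]
  expect_lt(mse_nn, mse_rej)
})

test_that("LOO CV error is near zero on a noise-free table", {
  # summaries are a deterministic bijection of the parameters, so an
  # interpolating method should predict a held-out cell almost exactly;
  # pure rejection is limited by the grid spacing
  tab <- fake_sim_table(10, noise = 0, seed = 7)
  cv <- loo_cv(tab, methods = c("rejection", "neuralnet"),
               tolerances = c(0.05, 0.5), n_nets = 8, n_folds = 20,
               seed = 8)
  expect_equal(nrow(cv), 4)       # one row per requested configuration
  # tight tolerance on exact summaries localizes better than a loose one
  rej <- cv[cv$method == "rejection", ]
  expect_lt(rej$mse_log[rej$tolerance == 0.05],
            rej$mse_log[rej$tolerance == 0.5])
  nn <- cv[cv$method == "neuralnet", ]
  expect_lt(min(nn$mse_log), 0.05)
})

test_that("model posterior recovers the synonymous-driver fraction", {
  fractions <- seq(0, 0.2, by = 0.04)
  tab <- fake_sim_table(8, noise = 0.04, seed = 9,
                        syn_fraction = fractions)
  # observed generated under the base model (fraction 0)
  base_row <- which(tab$syn_fraction == 0)[30]
  obs0 <- unlist(tab[base_row, summary_names])
  mp0 <- model_posterior(tab, obs0, tolerance = 0.5, seed = 10)
  expect_equal(sum(mp0$mass), 1)
  expect_equal(unname(which.max(mp0$mass)), 1)
  expect_equal(mp0$p_base, max(mp0$mass))
  # observed generated under fraction 0.12
  mid_row <- which(tab$syn_fraction == 0.12)[30]
  obs12 <- unlist(tab[mid_row, summary_names])
  mp12 <- model_posterior(tab, obs12, tolerance = 0.5, seed = 11)
  expect_lt(abs(mp12$posterior_mean_fraction - 0.12), 0.05)
  expect_lt(mp12$p_base, 0.5)
})
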