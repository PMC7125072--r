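test_that("objective is zero for a perfect fit and additive in unit residuals", {
  spec <- ref_spec("first_order")
  data <- noiseless_dataset(spec)
  ini <- std_initial()
  expect_lt(fit_objective(spec, ini, data), 1e-10)

  # one observation displaced by exactly its scale contributes 1
  d1 <- as.data.frame(data)
  row <- which(d1$variable == "H")[4]
  d1$sd[row] <- 2
  d1$value[row] <- d1$value[row] + 2
  expect_equal(fit_objective(spec, ini, ts_dataset(d1)), 1, tolerance = 1e-7)

  # two unit residuals on two different variables add to 2
  d2 <- d1
  row2 <- which(d2$variable == "P")[5]
  d2$sd[row2] <- 0.5
  d2$value[row2] <- d2$value[row2] - 0.5
  expect_equal(fit_objective(spec, ini, ts_dataset(d2)), 2, tolerance = 1e-7)
})

test_that("objective is invariant to dataset row permutation and skips missing values", {
  spec <- ref_spec("t1")
  gen <- generate_dataset(bernalier_like_scenario(seed = 5))
  ini <- initial_from_data(gen$dataset)
  base <- fit_objective(spec, ini, gen$dataset)
  perm <- as.data.frame(gen$dataset)
  perm <- perm[order(perm$time_h, perm$variable), ]  # different row order
  expect_equal(fit_objective(spec, ini, ts_dataset(perm)), base)
  # NA observations contribute nothing
  nadat <- as.data.frame(gen$dataset)
  drop_row <- which(nadat$variable == "X")[3]
  with_na <- nadat; with_na$value[drop_row] <- NA
  without <- nadat[-drop_row, ]
  expect_equal(fit_objective(spec, ini, ts_dataset(with_na)),
               fit_objective(spec, ini, ts_dataset(without)))
})

test_that("R^2 matches its closed forms", {
  obs <- c(1, 2, 3, 4, 5)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(rep(mean(obs), 5), obs), 0)
  # constant offset c: R^2 = 1 - n c^2 / SS_tot
  c0 <- 0.7
  expect_equal(r_squared(obs + c0, obs), 1 - 5 * c0^2 / sum((obs - 3)^2))
  expect_error(r_squared(c(1, 2, 3), c(2, 2, 2)),
               class = "acetokin_undefined_r_squared")
  expect_error(r_squared(1, 1), class = "acetokin_invalid_input")
})

test_that("parameter correlation recovers exact linear dependence and independence", {
  ch <- acetokin:::with_seed(99, {
    a <- rnorm(1e4); cbind(a = a, b = rnorm(1e4))
  })
  expect_lt(abs(parameter_correlation(ch)["a", "b"]), 0.05)
  ch2 <- cbind(p1 = 1:100, p2 = 2 * (1:100))
  expect_equal(parameter_correlation(ch2)["p1", "p2"], 1)
  ch3 <- cbind(p1 = rnorm(50), p2 = rep(1, 50))
  expect_true(is.na(parameter_correlation(ch3)["p1", "p2"]))
})

test_that("split-Rhat is near 1 for identical or well-mixed chains and large for disjoint ones", {
  x <- acetokin:::with_seed(1, matrix(rnorm(4000), ncol = 1,
                                      dimnames = list(NULL, "p")))
  expect_equal(unname(convergence_diagnostic(list(x, x, x, x))$rhat), 1,
               tolerance = 0.01)
  # four independent well-mixed chains of the same target
  chains <- lapply(1:4, function(k)
    acetokin:::with_seed(k, matrix(rnorm(1e4), ncol = 1,
                                   dimnames = list(NULL, "p"))))
  expect_lt(unname(convergence_diagnostic(chains)$rhat), 1.01)
  expect_true(convergence_diagnostic(chains)$converged)
  # disjoint supports
  far <- list(x, x + 100)
  expect_gt(unname(convergence_diagnostic(far)$rhat), 1.1)
  expect_false(convergence_diagnostic(far)$converged)
  expect_error(convergence_diagnostic(list(x[1:3, , drop = FALSE])),
               class = "acetokin_insufficient_samples")
})

test_that("mcmc_fit is bit-reproducible given the seed", {
  gen <- generate_dataset(bernalier_like_scenario(seed = 2))
  cfg <- fit_config(n_iterations = 300, n_chains = 2, seed = 7)
  f1 <- mcmc_fit(ref_spec("t1"), gen$dataset, cfg)
  f2 <- mcmc_fit(ref_spec("t1"), gen$dataset, cfg)
  expect_identical(f1$best_fit, f2$best_fit)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$ci95, f2$ci95)
})

test_that("a one-iteration fit returns exactly the initial sample", {
  gen <- generate_dataset(bernalier_like_scenario(seed = 2))
  fit <- mcmc_fit(ref_spec("t1"), gen$dataset,
                  fit_config(n_iterations = 1, n_chains = 1, seed = 1,
                             burn_in_fraction = 0))
  expect_equal(nrow(fit$chains[[1]]), 1L)
  expect_equal(fit$best_fit, unlist(flatten_params(ref_spec("t1"))),
               tolerance = 1e-12)
})

test_that("noiseless first-order data is recovered to within 5%", {
  spec <- ref_spec("first_order")
  data <- noiseless_dataset(spec)
  truth <- unlist(flatten_params(spec))
  start <- acetokin:::with_seed(31, truth * exp(rnorm(3, 0, 0.3)))
  fit <- mcmc_fit(acetokin:::spec_from_flat("first_order", as.list(start)),
                  data,
                  fit_config(n_iterations = 3000, n_chains = 2,
                             burn_in_fraction = 0.5, seed = 4),
                  initial = std_initial())
  expect_lt(max(abs(fit$best_fit - truth) / truth), 0.05)
  expect_lt(fit$objective_at_best, 1e-3)
})

test_that("extension parameters can be fitted with the base model held fixed", {
  scen <- dsmz_like_scenario("t3", seed = 8)
  gen <- generate_dataset(scen)
  fit <- mcmc_fit(scen$spec, gen$dataset,
                  fit_config(n_iterations = 400, n_chains = 2, seed = 3),
                  initial = scen$initial,
                  fixed = c("mu_max_H", "mu_max_R", "K_H", "K_R", "Y"))
  expect_setequal(fit$free, c("k_d", "eta_E", "Y_E", "b_EP"))
  expect_equal(unname(fit$best_spec$params$K_H), 295.8)
})

test_that("non-linearised structures are refused without the explicit flag", {
  gen <- generate_dataset(bernalier_like_scenario(seed = 2))
  spec <- model_spec("t1_nonlinear",
                     t1_nonlinear_params(0.4, 300, 0.0014, 0.014, 86.2))
  expect_error(mcmc_fit(spec, gen$dataset, fit_config(n_iterations = 10)),
               class = "acetokin_invalid_input")
  fit <- mcmc_fit(spec, gen$dataset,
                  fit_config(n_iterations = 50, n_chains = 1, seed = 1),
                  allow_nonidentifiable = TRUE)
  expect_s3_class(fit, "fit_result")
})

test_that("fit results serialize to JSON and chains to CSV", {
  gen <- generate_dataset(bernalier_like_scenario(seed = 2))
  fit <- mcmc_fit(ref_spec("t1"), gen$dataset,
                  fit_config(n_iterations = 200, n_chains = 2, seed = 5))
  tmp <- tempfile(fileext = ".json"); tmpc <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmp, tmpc)))
  write_fit_json(fit, tmp)
  back <- read_fit_json(tmp)
  expect_equal(back$best_fit$H_t, unname(fit$best_fit["H_t"]))
  expect_equal(back$terminal_prediction$P,
               fit$terminal_prediction$P)
  write_chains_csv(fit, tmpc)
  ch <- read.csv(tmpc)
  expect_equal(nrow(ch), 2 * nrow(fit$chains[[1]]))
  expect_true(all(c("eta", "H_t", "chain", "objective") %in% names(ch)))
})
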