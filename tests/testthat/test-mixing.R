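test_that("model and schedule specifications validate their invariants", {
  expect_error(mixing_model_spec(matrix(1, 2, 1), matrix(1, 2, 1)), "two sources")
  expect_error(make_test_spec(source_sd = -1), "SDs")
  expect_error(mixing_model_spec(matrix(1, 2, 3), matrix(0, 2, 3),
                                 alpha = c(1, 1, 0)), "alpha")
  expect_error(mcmc_config(1000, 1000), "iterations > burn_in")
  expect_error(mcmc_config(1000, 0, 0), "thin")
})

test_that("log-posterior matches a direct term-by-term density computation", {
  set.seed(15)
  spec <- make_test_spec()
  for (i in 1:20) {
    p <- as.numeric(rmultinom(1, 60, rep(1, 3))) / 60
    rs <- runif(2, 0.05, 1.9)
    x <- c(runif(1, -25, -10), runif(1, 3, 12))
    got <- log_posterior(p, rs, x, spec)
    expect_equal(as.numeric(got), oracle_log_posterior(p, rs, x, spec),
                 tolerance = 1e-12)
  }
  # loglik/logprior attributes decompose the total
  v <- log_posterior(c(0.2, 0.3, 0.5), c(0.5, 0.5), c(-16, 8), spec)
  expect_equal(attr(v, "loglik") + attr(v, "logprior"), as.numeric(v))
})

test_that("log-posterior degenerate and symmetry cases behave", {
  # zero residual at the mode: likelihood term is 2*log(1/sqrt(2*pi)),
  # up to the 0.01-permil SD floor
  s <- matrix(c(-17, 5.3, -11, 3.8, -23, 5.9), 2)
  spec0 <- mixing_model_spec(s, matrix(0, 2, 3))
  v <- log_posterior(c(1, 0, 0), c(1, 1), c(-17, 5.3), spec0)
  expect_equal(attr(v, "loglik"), 2 * log(1 / sqrt(2 * pi)), tolerance = 1e-3)
  # relabeling two identical sources leaves the density unchanged
  s2 <- matrix(c(-17, 9, -17, 9, -23, 3.8), 2)
  spec2 <- mixing_model_spec(s2, matrix(0.5, 2, 3))
  a <- log_posterior(c(0.6, 0.1, 0.3), c(0.4, 0.4), c(-18, 7), spec2)
  b <- log_posterior(c(0.1, 0.6, 0.3), c(0.4, 0.4), c(-18, 7), spec2)
  expect_equal(as.numeric(a), as.numeric(b))
  # domain checks
  spec <- make_test_spec()
  expect_error(log_posterior(c(0.7, 0.7, -0.4), c(1, 1), c(-16, 8), spec),
               "simplex")
  expect_error(log_posterior(c(0.5, 0.4, 0.1), c(-1, 1), c(-16, 8), spec),
               "resid_sd")
  out <- log_posterior(c(0.5, 0.4, 0.1), c(1, 10), c(-16, 8), make_test_spec())
  expect_identical(as.numeric(out), -Inf)  # above the prior's upper bound
})

test_that("retained-draw count follows the schedule law and seeds reproduce", {
  spec <- make_test_spec()
  for (cfg in list(c(2000, 500, 7), c(1500, 0, 1), c(3000, 1000, 15))) {
    ps <- sample_posterior(c(-16, 8), spec,
                           mcmc_config(cfg[1], cfg[2], cfg[3], seed = 2))
    expect_identical(nrow(ps$draws), as.integer(floor((cfg[1] - cfg[2]) / cfg[3])))
  }
  a <- sample_posterior(c(-16, 8), spec, mcmc_config(4000, 500, 5, seed = 31))
  b <- sample_posterior(c(-16, 8), spec, mcmc_config(4000, 500, 5, seed = 31))
  expect_identical(a$draws, b$draws)
  expect_identical(a$resid_draws, b$resid_draws)
})

test_that("every draw stays on the simplex", {
  ps <- sample_posterior(c(-16, 8), make_test_spec(),
                         mcmc_config(5000, 500, 3, seed = 19))
  expect_true(all(ps$draws >= 0))
  expect_true(all(abs(rowSums(ps$draws) - 1) < 1e-9))
  expect_true(all(ps$resid_draws > 0 & ps$resid_draws <= 2))
})

test_that("prior sampling recovers the uniform-Dirichlet mean", {
  ps <- sample_posterior(c(0, 0), make_test_spec(), mcmc_config(seed = 9),
                         prior_only = TRUE)
  expect_true(all(abs(ps$mean_p - 1 / 3) < 0.02))
})

test_that("interchangeable sources get equal posterior mass", {
  s2 <- matrix(c(-17, 9, -17, 9, -23, 3.8), 2,
               dimnames = list(c("d13C", "d15N"), c("A", "B", "C")))
  spec <- mixing_model_spec(s2, matrix(0.5, 2, 3))
  ps <- sample_posterior(c(-19, 7.5), spec, mcmc_config(50000, 5000, 5, seed = 27))
  expect_lt(abs(ps$mean_p[["A"]] - ps$mean_p[["B"]]), 0.02)
})

test_that("the sampler matches dense grid integration (2 sources, 1 isotope)", {
  s <- matrix(c(4, 9), 1, 2, dimnames = list("d15N", c("A", "B")))
  spec <- mixing_model_spec(s, matrix(c(0.6, 0.8), 1, 2))
  ps <- sample_posterior(6.2, spec, mcmc_config(seed = 5), fix_resid_sd = 0.5)
  oracle <- grid_posterior_mean_p1(6.2, spec, 0.5)
  expect_lt(abs(mean(ps$draws[, 1]) - oracle), 0.02)
})

test_that("a synthetic site at p = (0.6, 0.3, 0.1) is recovered within 0.05", {
  spec <- mixing_model_spec(
    matrix(c(-14, 10, -8, 3, -26, 3), 2,
           dimnames = list(c("d13C", "d15N"),
                           c("mole_crab", "amphipod", "coquina"))),
    matrix(0.5, 2, 3), rbind(0, rep(2.3, 3)), rbind(0, rep(0.5, 3)))
  p_true <- c(0.6, 0.3, 0.1)
  set.seed(77)
  post <- lapply(1:8, function(i) {
    sample_posterior(draw_consumer(p_true, spec), spec,
                     mcmc_config(20000, 2000, 5, seed = 770 + i),
                     site = "A", crab_id = paste0("c", i))
  })
  est <- as.numeric(summarize_diet(post)$sites[, c("p_mole_crab", "p_amphipod",
                                                   "p_coquina")])
  expect_lt(max(abs(est - p_true)), 0.05)
})

test_that("diet summaries average individuals within sites", {
  p1 <- fake_posterior(matrix(rep(c(0.2, 0.3, 0.5), each = 10), 10), "A", "c1")
  out1 <- summarize_diet(list(p1))
  expect_equal(as.numeric(out1$sites[, 3:5]), c(0.2, 0.3, 0.5))
  p2 <- fake_posterior(matrix(rep(c(1, 0, 0), each = 5), 5), "B", "c2")
  p3 <- fake_posterior(matrix(rep(c(0, 1, 0), each = 5), 5), "B", "c3")
  out <- summarize_diet(list(p2, p3))
  b <- out$sites[out$sites$site == "B", ]
  expect_equal(as.numeric(b[, 3:5]), c(0.5, 0.5, 0))
  expect_equal(b$n_crabs, 2L)
  # site outputs stay on the simplex
  expect_lt(abs(sum(out$sites[1, 3:5]) - 1), 1e-9)
  expect_warning(summarize_diet(list(p1, fake_posterior(diag(3), NA, "x"))),
                 "without a site label")
})
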