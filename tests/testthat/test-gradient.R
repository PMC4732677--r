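test_that("proportion and density transforms hit their closed forms", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.25), pi / 6)
  g <- seq(0, 1, by = 0.05)
  expect_true(all(diff(arcsine_sqrt(g)) > 0))
  expect_error(arcsine_sqrt(1.01), "\\[0, 1\\]")
  expect_error(arcsine_sqrt(-0.1), "\\[0, 1\\]")

  expect_equal(as.numeric(log10_density(1)), 0)
  expect_equal(as.numeric(log10_density(100)), 2)
  z <- log10_density(c(0, 10))
  expect_equal(as.numeric(z), c(log10(0.01), 1))
  expect_identical(attr(z, "offset_applied"), c(TRUE, FALSE))
  expect_error(log10_density(-1), ">= 0")
})

test_that("stepwise keeps a perfect predictor and rejects pure noise", {
  set.seed(1)
  X <- data.frame(good = rnorm(16), junk1 = rnorm(16), junk2 = rnorm(16))
  fit <- stepwise_select(3 * X$good - 1, X)
  expect_identical(fit$selected, "good")
  expect_equal(fit$r_squared, 1)
  # all-noise candidates at n = 16 leave the model empty most of the time
  set.seed(100)
  empty <- 0
  for (i in 1:100) {
    y <- rnorm(16)
    Xn <- data.frame(a = rnorm(16), b = rnorm(16), c = rnorm(16), d = rnorm(16))
    if (length(stepwise_select(y, Xn)$selected) == 0) empty <- empty + 1
  }
  expect_gte(empty, 70)
  expect_error(stepwise_select(rnorm(4), data.frame(a = rnorm(4))),
               "at least 5")
})

test_that("stepwise is order-invariant and internally F-stable", {
  set.seed(2)
  X <- data.frame(u = rnorm(20), v = rnorm(20), w = rnorm(20))
  y <- 2 * X$u - 1.5 * X$v + rnorm(20, 0, 0.5)
  fit <- stepwise_select(y, X)
  expect_setequal(fit$selected, c("u", "v"))
  # permuting candidate order cannot change the selection
  fit2 <- stepwise_select(y, X[, c("w", "v", "u")])
  expect_setequal(fit2$selected, fit$selected)
  # stability: every included term is above f_remove, every excluded below f_enter
  co <- fit$coefficients
  expect_true(all(co$f_to_remove[co$term != "(Intercept)"] >= 3.9))
  expect_true(all(fit$excluded$f_to_enter < 4.0))
  # collinear candidate is dropped with a warning, not silently used
  Xc <- cbind(X, dup = X$u)
  expect_warning(fitc <- stepwise_select(y, Xc), "collinear")
  expect_false("dup" %in% fitc$selected)
})

test_that("Gaussian peak fits recover generating parameters", {
  x <- seq(10, 100, length.out = 16)
  f <- fit_gaussian3(x, 2 * exp(-0.5 * ((x - 40) / 10)^2))
  expect_equal(unname(f$parameters), c(2, 40, 10), tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$df, c(2, 13))
  # noisy recovery: median center error below 3 m over 50 seeded replicates
  errs <- vapply(1:50, function(i) {
    set.seed(400 + i)
    y <- 2 * exp(-0.5 * ((x - 40) / 10)^2) + rnorm(16, 0, 0.05)
    abs(fit_gaussian3(x, y)$parameters[["x0"]] - 40)
  }, numeric(1))
  expect_lt(median(errs), 3)
  expect_error(fit_gaussian3(x, rep(2, 16)), "degenerate")
  expect_error(fit_gaussian3(x[1:3], x[1:3]), "at least 4")
})

test_that("saturating hyperbola fits recover parameters and pass the origin", {
  xh <- seq(0, 30, length.out = 12)
  f <- fit_hyperbola2(xh, 3.5 * (1 - exp(-0.1 * xh)))
  expect_equal(unname(f$parameters), c(3.5, 0.1), tolerance = 1e-6)
  a <- f$parameters[["a"]]; b <- f$parameters[["b"]]
  expect_equal(a * (1 - exp(-b * 0)), 0)   # functional form pins x = 0 to 0
  # saturated data: asymptote within 5% of the plateau mean
  set.seed(50)
  xs <- seq(0, 60, length.out = 20)
  ys <- 4 * (1 - exp(-0.2 * xs)) + rnorm(20, 0, 0.05)
  fs <- fit_hyperbola2(xs, ys)
  plateau <- mean(ys[xs >= 40])
  expect_lt(abs(fs$parameters[["a"]] - plateau) / plateau, 0.05)
  expect_error(fit_hyperbola2(c(-1, 2, 3), 1:3), "x >= 0")
})

test_that("multi-start fits never return uphill from their initializations", {
  set.seed(60)
  x <- seq(10, 100, length.out = 16)
  for (i in 1:10) {
    y <- runif(1, 0.5, 3) * exp(-0.5 * ((x - runif(1, 25, 75)) / runif(1, 6, 25))^2) +
      rnorm(16, 0, 0.1)
    f <- fit_gaussian3(x, y)
    sse_fit <- f$ss_res
    # rebuild the deterministic starts the fitter uses
    r <- diff(range(x)); a0 <- max(y); xm <- x[which.max(y)]
    qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    starts <- list(c(a0, xm, r / 6), c(a0, qs[1], r / 4), c(a0, qs[2], r / 4),
                   c(a0, qs[3], r / 4), c(a0, xm, r / 2))
    for (st in starts) {
      sse0 <- sum((y - st[1] * exp(-0.5 * ((x - st[2]) / st[3])^2))^2)
      expect_lte(sse_fit, sse0 + 1e-9)
    }
  }
})

test_that("the gradient battery runs, degrades cleanly, and honors exclusions", {
  cfg <- scenario_config(seed = 44)
  sites <- simulate_sites(cfg)
  tr <- simulate_truth(sites, cfg)
  diet <- data.frame(site = sites$site, p_mole_crab = tr$p[, 1],
                     p_amphipod = tr$p[, 2], p_coquina = tr$p[, 3])
  tp <- data.frame(site = sites$site,
                   tp = 3 - 0.01 * (sites$width_m - 60) + rnorm(16, 0, 0.1))
  rep1 <- gradient_analysis(sites, diet, tp)
  expect_s3_class(rep1, "gradient_report")
  expect_true(all(c("mole_stepwise", "amph_gaussian_width", "density_stepwise",
                    "tp_stepwise", "tp_mole_hyperbola") %in% names(rep1$models)))
  expect_true(is.data.frame(rep1$table) && nrow(rep1$table) > 10)

  # all-constant responses: every model reports a clean empty/degenerate status
  dietc <- data.frame(site = sites$site, p_mole_crab = 1 / 3,
                      p_amphipod = 1 / 3, p_coquina = 1 / 3)
  tpc <- data.frame(site = sites$site, tp = 3)
  sitesc <- sites; sitesc$burrow_density <- 2
  repc <- gradient_analysis(sitesc, dietc, tpc)
  for (id in names(repc$models)) {
    mres <- repc$models[[id]]
    ok_empty <- !is.null(mres$fit) && inherits(mres$fit, "stepwise_fit") &&
      length(mres$fit$selected) == 0
    ok_degen <- startsWith(mres$status, "degenerate")
    expect_true(ok_empty || ok_degen, label = paste("model", id))
  }

  # excluding one site changes n by exactly 1 in the affected fit only
  rep2 <- gradient_analysis(sites, diet, tp,
                            exclude = list(tp_amph_linear = sites$site[3]))
  expect_equal(rep2$models$tp_amph_linear$n, rep1$models$tp_amph_linear$n - 1L)
  others <- setdiff(names(rep1$models), "tp_amph_linear")
  expect_identical(vapply(rep1$models[others], `[[`, integer(1), "n"),
                   vapply(rep2$models[others], `[[`, integer(1), "n"))

  expect_error(gradient_analysis(sites[, -2], diet, tp), "missing column")
})
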