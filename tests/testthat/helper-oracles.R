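# Independent oracles and shared fixtures for the test suite.

# Dirichlet log-density, written out directly (independent of the package's
# compiled code).
ddirichlet_log <- function(p, alpha) {
  lgamma(sum(alpha)) - sum(lgamma(alpha)) +
    sum(ifelse(alpha == 1, 0, (alpha - 1) * log(p)))
}

# Direct (term-by-term) log-posterior of the mixing model, on the natural
# scale, using plain dnorm/dunif calls.
oracle_log_posterior <- function(p, resid_sd, consumer, spec) {
  ll <- 0
  for (j in seq_len(spec$J)) {
    sg <- ifelse(spec$source_sds[j, ] <= 0, 0.01, spec$source_sds[j, ])
    tu <- ifelse(spec$tef_sds[j, ] <= 0, 0.01, spec$tef_sds[j, ])
    mu <- sum(p * (spec$source_means[j, ] + spec$tef_means[j, ]))
    v <- sum(p^2 * (sg^2 + tu^2)) + resid_sd[j]^2
    ll <- ll + stats::dnorm(consumer[j], mu, sqrt(v), log = TRUE)
  }
  ll + ddirichlet_log(p, spec$alpha) +
    sum(stats::dunif(resid_sd, 0, spec$resid_upper, log = TRUE))
}

# Posterior mean of p1 for a 2-source, 1-isotope model with fixed residual SD,
# by dense trapezoid integration over p1 in [0, 1] (uniform Dirichlet prior).
grid_posterior_mean_p1 <- function(consumer, spec, resid_sd, n_grid = 4001) {
  g <- seq(0, 1, length.out = n_grid)
  sg <- ifelse(spec$source_sds[1, ] <= 0, 0.01, spec$source_sds[1, ])
  tu <- ifelse(spec$tef_sds[1, ] <= 0, 0.01, spec$tef_sds[1, ])
  mu <- g * (spec$source_means[1, 1] + spec$tef_means[1, 1]) +
    (1 - g) * (spec$source_means[1, 2] + spec$tef_means[1, 2])
  v <- g^2 * (sg[1]^2 + tu[1]^2) + (1 - g)^2 * (sg[2]^2 + tu[2]^2) + resid_sd^2
  f <- stats::dnorm(consumer, mu, sqrt(v))
  w <- rep(1, n_grid); w[c(1, n_grid)] <- 0.5
  sum(w * g * f) / sum(w * f)
}

# Standard 3-source 2-isotope spec with a well-conditioned source triangle
# (pairwise centroid separation >= 3 permil in isotope space).
make_test_spec <- function(source_sd = 0.5, tef_n = 2.3, tau_n = 0.5,
                           alpha = NULL, resid_upper = 2) {
  s <- matrix(c(-17, 9, -11, 3.8, -23, 3.8), nrow = 2,
              dimnames = list(c("d13C", "d15N"),
                              c("mole_crab", "amphipod", "coquina")))
  mixing_model_spec(s, matrix(source_sd, 2, 3),
                    rbind(0, rep(tef_n, 3)), rbind(0, rep(tau_n, 3)),
                    alpha = alpha, resid_upper = resid_upper)
}

# Forward-draw one consumer signature from the mixing model's own equations.
draw_consumer <- function(p, spec, resid_sd = c(0.3, 0.3)) {
  mu <- v <- numeric(spec$J)
  for (j in seq_len(spec$J)) {
    mu[j] <- sum(p * (spec$source_means[j, ] + spec$tef_means[j, ]))
    v[j] <- sum(p^2 * (spec$source_sds[j, ]^2 + spec$tef_sds[j, ]^2)) +
      resid_sd[j]^2
  }
  stats::rnorm(spec$J, mu, sqrt(v))
}

# Minimal diet_posterior stand-in with prescribed draws (for summarize_diet
# bookkeeping tests).
fake_posterior <- function(draws, site, crab_id) {
  draws <- as.matrix(draws)
  colnames(draws) <- c("mole_crab", "amphipod", "coquina")
  structure(list(draws = draws,
                 mean_p = colMeans(draws),
                 ci = apply(draws, 2, stats::quantile, probs = c(0.025, 0.975)),
                 site = site, crab_id = crab_id),
            class = "diet_posterior")
}

# Site-level diet recovery on a simulated scenario, mixing with the known
# (generating) TEF; returns mean absolute error against the truth ledger.
recovery_mae <- function(cfg, iterations = 20000, burn_in = 2000, thin = 5) {
  sc <- simulate_scenario(cfg)
  summ <- suppressMessages(
    build_source_summaries(sc$signatures, sc$wrack_components,
                           sites = sc$sites$site))$summaries
  tef <- list(c_C = 0, tau_C = 0, c_N = cfg$tef_true[[1]], tau_N = cfg$tef_true[[2]])
  post <- list(); k <- 0
  for (st in sc$sites$site) {
    spec <- site_mixing_spec(summ[summ$site == st, ], tef)
    crabs <- sc$consumers[sc$consumers$site == st, ]
    for (i in seq_len(nrow(crabs))) {
      k <- k + 1
      post[[k]] <- sample_posterior(c(crabs$d13C[i], crabs$d15N[i]), spec,
                                    mcmc_config(iterations, burn_in, thin,
                                                seed = cfg$seed + k),
                                    site = st, crab_id = crabs$crab_id[i])
    }
  }
  est <- summarize_diet(post)$sites
  est <- est[match(sc$sites$site, est$site), ]
  mean(abs(as.matrix(est[, c("p_mole_crab", "p_amphipod", "p_coquina")]) -
             sc$truth$p))
}
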