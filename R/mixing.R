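#' Specify the single-consumer mixing model
#'
#' Houses every quantity of the likelihood for a Bayesian J-isotope, K-source
#' diet mixing model for one consumer: the consumer's signature for isotope j
#' is `Normal(sum_k p_k (s_jk + c_jk),
#' sum_k p_k^2 (sigma_jk^2 + tau_jk^2) + sigma_res_j^2)`, with a
#' Dirichlet(alpha) prior on the diet proportions p and independent
#' uniform(0, `resid_upper`) priors on the per-isotope residual SDs. The study
#' case is J = 2 (d13C, d15N) and K = 3 (mole crab, amphipod, coquina) with
#' carbon enrichment fixed at zero, but the specification is general.
#'
#' @param source_means J x K matrix of source means `s` (permil); rows are
#'   isotopes, columns sources.
#' @param source_sds J x K matrix of source SDs `sigma` (>= 0).
#' @param tef_means J x K matrix of trophic enrichment means `c` (defaults to
#'   all zero).
#' @param tef_sds J x K matrix of enrichment SDs `tau` (>= 0, default zero).
#' @param alpha Dirichlet concentration, length K, all > 0 (default all ones).
#' @param resid_upper Upper bound (permil) of the uniform residual-SD prior.
#'   With a single observation per fit the residual SD is not identified by
#'   the likelihood, so the bound must be vague only on the physical scale of
#'   isotope residuals; the default of 2 permil is an order of magnitude above
#'   measurement repeatability while keeping the posterior informative.
#' @return Object of class `mixing_model_spec`.
#' @export
mixing_model_spec <- function(source_means, source_sds,
                              tef_means = NULL, tef_sds = NULL,
                              alpha = NULL, resid_upper = 2) {
  s <- as.matrix(source_means)
  J <- nrow(s); K <- ncol(s)
  if (K < 2) stop("mixing model needs at least two sources")
  sig <- as.matrix(source_sds)
  if (is.null(tef_means)) tef_means <- matrix(0, J, K)
  if (is.null(tef_sds)) tef_sds <- matrix(0, J, K)
  cc <- as.matrix(tef_means); tau <- as.matrix(tef_sds)
  if (!all(dim(sig) == c(J, K)) || !all(dim(cc) == c(J, K)) ||
      !all(dim(tau) == c(J, K))) {
    stop("source_sds, tef_means and tef_sds must all be ", J, " x ", K, " matrices")
  }
  if (any(sig < 0) || any(tau < 0)) stop("source and TEF SDs must be >= 0")
  if (is.null(alpha)) alpha <- rep(1, K)
  if (length(alpha) != K || any(alpha <= 0)) {
    stop("alpha must have length ", K, " with all entries > 0")
  }
  if (resid_upper <= 0) stop("resid_upper must be positive")
  structure(list(source_means = s, source_sds = sig, tef_means = cc,
                 tef_sds = tau, alpha = as.numeric(alpha),
                 resid_upper = resid_upper, J = J, K = K,
                 sources = colnames(s), isotopes = rownames(s)),
            class = "mixing_model_spec")
}

#' @export
print.mixing_model_spec <- function(x, ...) {
  cat(sprintf("Mixing model: %d isotope(s) x %d source(s), Dirichlet alpha = (%s), residual SD ~ U(0, %g)\n",
              x$J, x$K, paste(format(x$alpha), collapse = ", "), x$resid_upper))
  invisible(x)
}

#' MCMC run schedule
#'
#' Defaults follow the standard solo-model schedule: 100,000 iterations,
#' 10,000 burn-in, thinning by 15, retaining exactly 6,000 draws.
#'
#' @param iterations Total iterations (> `burn_in`).
#' @param burn_in Dropped initial iterations (>= 0).
#' @param thin Keep every `thin`-th post-burn-in iteration (>= 1).
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @param proposal_scale Initial random-walk proposal SD.
#' @param adapt Adapt per-component proposal scales during burn-in (targets
#'   roughly 20--50% acceptance).
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 100000L, burn_in = 10000L, thin = 15L,
                        seed = NULL, proposal_scale = 0.5, adapt = TRUE) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in < 0 || iterations <= burn_in) {
    stop("need iterations > burn_in >= 0")
  }
  if (thin < 1) stop("thin must be >= 1")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 proposal_scale = proposal_scale, adapt = isTRUE(adapt)),
            class = "mcmc_config")
}

#' Log-posterior density of the mixing model
#'
#' Reference implementation on the natural scale (no sampling-transform
#' Jacobians): the sum over isotopes of Normal log-densities at the
#' mixture mean and variance, plus the Dirichlet log-prior on `p` and the
#' uniform log-prior on each residual SD. Source/TEF SDs equal to zero are
#' floored at 0.01 permil. The returned value carries the likelihood and
#' prior contributions as attributes `loglik` and `logprior`.
#'
#' @param p Diet proportions, length K, on the simplex (checked to 1e-6).
#' @param resid_sd Residual SDs, length J, each >= 0; values outside the
#'   prior support give `-Inf`.
#' @param consumer Consumer signature, numeric length J (same isotope order
#'   as the spec's rows).
#' @param spec A [mixing_model_spec()].
#' @param prior_only Drop the likelihood term (prior density only).
#' @return Log-density (scalar), with attributes `loglik` and `logprior`.
#' @export
log_posterior <- function(p, resid_sd, consumer, spec, prior_only = FALSE) {
  stopifnot(inherits(spec, "mixing_model_spec"))
  if (length(p) != spec$K) stop("p must have length ", spec$K)
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop("p is off the simplex beyond tolerance")
  }
  p <- pmax(p, 0); p <- p / sum(p)
  if (length(resid_sd) != spec$J) stop("resid_sd must have length ", spec$J)
  if (any(resid_sd < 0)) stop("resid_sd must be >= 0")
  consumer <- as.numeric(consumer)
  if (length(consumer) != spec$J) stop("consumer must have length ", spec$J)
  full <- cpp_log_posterior(p, resid_sd, consumer, spec$source_means,
                            spec$source_sds, spec$tef_means, spec$tef_sds,
                            spec$alpha, spec$resid_upper, prior_only)
  pri <- cpp_log_posterior(p, resid_sd, consumer, spec$source_means,
                           spec$source_sds, spec$tef_means, spec$tef_sds,
                           spec$alpha, spec$resid_upper, TRUE)
  structure(full, loglik = if (prior_only) 0 else full - pri, logprior = pri)
}

#' Sample the diet posterior for one consumer
#'
#' Metropolis-within-Gibbs: component-wise random-walk Metropolis on the
#' additive-log-ratio transform of the diet proportions and on the log
#' residual SDs, with proposal-scale adaptation during burn-in. Initialization
#' is the uniform diet (1/3, ..., 1/3) and residual SD 1 permil. Draws are
#' retained after burn-in, every `thin`-th iteration:
#' `floor((iterations - burn_in)/thin)` draws in total.
#'
#' @param consumer Numeric length-J consumer signature (permil), isotope order
#'   matching `spec`.
#' @param spec A [mixing_model_spec()].
#' @param mcmc An [mcmc_config()].
#' @param fix_resid_sd Optional numeric length-J: hold the residual SDs fixed
#'   at these values instead of sampling them.
#' @param prior_only Sample the prior (likelihood disabled).
#' @param crab_id,site Optional labels stored on the result.
#' @return Object of class `diet_posterior`: retained `draws` (matrix, one
#'   column per source), `resid_draws`, posterior `mean_p`, 95% credible
#'   interval `ci`, acceptance rates, labels and the run schedule.
#' @export
sample_posterior <- function(consumer, spec, mcmc = mcmc_config(),
                             fix_resid_sd = NULL, prior_only = FALSE,
                             crab_id = NA_character_, site = NA_character_) {
  stopifnot(inherits(spec, "mixing_model_spec"), inherits(mcmc, "mcmc_config"))
  consumer <- as.numeric(consumer)
  if (length(consumer) != spec$J) stop("consumer must have length ", spec$J)
  if (!is.null(fix_resid_sd)) {
    if (length(fix_resid_sd) != spec$J || any(fix_resid_sd <= 0) ||
        any(fix_resid_sd > spec$resid_upper)) {
      stop("fix_resid_sd must be length ", spec$J,
           ", positive, and within the prior support")
    }
  }
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  res <- cpp_sample_mixing(consumer, spec$source_means, spec$source_sds,
                           spec$tef_means, spec$tef_sds, spec$alpha,
                           spec$resid_upper, mcmc$iterations, mcmc$burn_in,
                           mcmc$thin, mcmc$proposal_scale, mcmc$adapt,
                           prior_only,
                           if (is.null(fix_resid_sd)) numeric(0) else fix_resid_sd,
                           1.0)
  draws <- res$p
  colnames(draws) <- spec$sources
  resid_draws <- res$resid
  colnames(resid_draws) <- spec$isotopes
  mean_p <- colMeans(draws)
  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(draws = draws, resid_draws = resid_draws, mean_p = mean_p,
                 ci = ci, accept = res$accept, crab_id = crab_id, site = site,
                 mcmc = mcmc, consumer = consumer),
            class = "diet_posterior")
}

#' @export
print.diet_posterior <- function(x, ...) {
  cat(sprintf("Diet posterior (%s%s): %d retained draws\n",
              ifelse(is.na(x$site), "", paste0(x$site, "/")),
              ifelse(is.na(x$crab_id), "consumer", x$crab_id), nrow(x$draws)))
  m <- rbind(mean = x$mean_p, x$ci)
  print(round(m, 3))
  invisible(x)
}

#' Site-level diet summaries from individual posteriors
#'
#' Each individual's posterior-mean proportions are averaged within a site to
#' give the site's mean dietary composition; per-site outputs sum to one.
#'
#' @param posteriors List of [sample_posterior()] results, each carrying a
#'   `site` label.
#' @return List with `individuals` (one row per crab: site, crab_id, mean
#'   proportions, CI bounds) and `sites` (one row per site: `n_crabs` and the
#'   mean proportion columns, prefixed `p_`).
#' @export
summarize_diet <- function(posteriors) {
  stopifnot(length(posteriors) >= 1)
  src <- colnames(posteriors[[1]]$draws)
  ind <- do.call(rbind, lapply(posteriors, function(ps) {
    row <- data.frame(site = ps$site, crab_id = ps$crab_id,
                      stringsAsFactors = FALSE)
    for (k in seq_along(src)) {
      row[[paste0("p_", src[k])]] <- ps$mean_p[k]
      row[[paste0("lo_", src[k])]] <- ps$ci[1, k]
      row[[paste0("hi_", src[k])]] <- ps$ci[2, k]
    }
    row
  }))
  keep <- !is.na(ind$site)
  if (any(!keep)) {
    warning(sprintf("summarize_diet: dropping %d posterior(s) without a site label",
                    sum(!keep)))
    ind <- ind[keep, , drop = FALSE]
  }
  if (nrow(ind) == 0) stop("no site-labelled posteriors to summarize")
  pc <- paste0("p_", src)
  sites <- do.call(rbind, lapply(split(ind, ind$site), function(g) {
    out <- data.frame(site = g$site[1], n_crabs = nrow(g), stringsAsFactors = FALSE)
    for (cn in pc) out[[cn]] <- mean(g[[cn]])
    out
  }))
  rownames(sites) <- NULL
  list(individuals = ind, sites = sites[order(sites$site), , drop = FALSE])
}

#' Build a mixing-model spec for one site from summaries and a TEF
#'
#' Assembles the 2-isotope x 3-source specification from per-site source
#' summaries (ordered mole crab, amphipod, coquina) and a site TEF. Source
#' SDs missing because only one replicate was measured are replaced by 0.5
#' permil.
#'
#' @param source_summaries Rows of the summary table for one site (three
#'   taxa), with `taxon`, `d13C_mean`, `d13C_sd`, `d15N_mean`, `d15N_sd`.
#' @param tef A [estimate_tef()] result.
#' @param alpha,resid_upper Passed to [mixing_model_spec()].
#' @return A `mixing_model_spec`.
#' @export
site_mixing_spec <- function(source_summaries, tef, alpha = NULL,
                             resid_upper = 2) {
  taxa <- c("mole_crab", "amphipod", "coquina")
  ss <- source_summaries[match(taxa, source_summaries$taxon), ]
  if (any(is.na(ss$taxon))) {
    stop("source summaries must cover taxa: ", paste(taxa, collapse = ", "))
  }
  fill <- function(v) ifelse(is.finite(v), v, 0.5)
  s <- rbind(d13C = ss$d13C_mean, d15N = ss$d15N_mean)
  sig <- rbind(d13C = fill(ss$d13C_sd), d15N = fill(ss$d15N_sd))
  cc <- rbind(d13C = rep(tef$c_C, 3), d15N = rep(tef$c_N, 3))
  tau <- rbind(d13C = rep(tef$tau_C, 3), d15N = rep(tef$tau_N, 3))
  colnames(s) <- colnames(sig) <- colnames(cc) <- colnames(tau) <- taxa
  mixing_model_spec(s, sig, cc, tau, alpha = alpha, resid_upper = resid_upper)
}
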