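#' Arcsine square-root transform for proportions
#'
#' `asin(sqrt(p))` in radians; the usual variance-stabilizing transform
#' applied to compositional diet proportions before regression.
#'
#' @param p Proportions in \[0, 1\].
#' @return Transformed values.
#' @export
arcsine_sqrt <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  asin(sqrt(p))
}

#' Log10 transform for burrow densities
#'
#' `log10(d)`; exact zeros are offset by `zero_offset` (default 0.01) before
#' the log, and the positions where the offset was applied are recorded in the
#' `"offset_applied"` attribute rather than hidden. Negative densities are an
#' error.
#'
#' @param d Densities per 100 m^2 (>= 0).
#' @param zero_offset Offset added to exact zeros.
#' @return Transformed values with attribute `offset_applied` (logical).
#' @export
log10_density <- function(d, zero_offset = 0.01) {
  if (any(!is.finite(d)) || any(d < 0)) stop("densities must be >= 0")
  off <- d == 0
  out <- log10(d + ifelse(off, zero_offset, 0))
  attr(out, "offset_applied") <- off
  out
}

## ---- stepwise selection ----------------------------------------------------

.partial_f_enter <- function(y, X, model, cand) {
  df <- data.frame(y = y, X, check.names = FALSE)
  f0 <- stats::lm(stats::reformulate(if (length(model)) sprintf("`%s`", model) else "1",
                                     response = "y"), data = df)
  f1 <- stats::lm(stats::reformulate(sprintf("`%s`", c(model, cand)), response = "y"),
                  data = df)
  if (any(is.na(stats::coef(f1)))) return(list(F = NA_real_, p = NA_real_, aliased = TRUE))
  rss0 <- sum(stats::resid(f0)^2); rss1 <- sum(stats::resid(f1)^2)
  dfres <- f1$df.residual
  if (rss0 - rss1 <= 0) return(list(F = 0, p = 1, aliased = FALSE))
  if (dfres <= 0 || rss1 <= 0) return(list(F = Inf, p = 0, aliased = FALSE))
  Fv <- (rss0 - rss1) / (rss1 / dfres)
  list(F = Fv, p = stats::pf(Fv, 1, dfres, lower.tail = FALSE), aliased = FALSE)
}

.partial_f_remove <- function(y, X, model, term) {
  df <- data.frame(y = y, X, check.names = FALSE)
  f1 <- stats::lm(stats::reformulate(sprintf("`%s`", model), response = "y"), data = df)
  rest <- setdiff(model, term)
  f0 <- stats::lm(stats::reformulate(if (length(rest)) sprintf("`%s`", rest) else "1",
                                     response = "y"), data = df)
  rss0 <- sum(stats::resid(f0)^2); rss1 <- sum(stats::resid(f1)^2)
  dfres <- f1$df.residual
  if (rss0 - rss1 <= 0) return(list(F = 0, p = 1))
  if (dfres <= 0 || rss1 <= 0) return(list(F = Inf, p = 0))
  Fv <- (rss0 - rss1) / (rss1 / dfres)
  list(F = Fv, p = stats::pf(Fv, 1, dfres, lower.tail = FALSE))
}

#' Forward stepwise regression with F thresholds
#'
#' Least-squares forward selection with backward removal: repeatedly adds the
#' candidate with the largest partial F (if at least `f_enter`), then removes
#' any included variable whose F-to-remove falls below `f_remove`. A visited-
#' model guard ensures termination. Aliased (collinear) candidates are dropped
#' with a warning. For excluded variables the F-to-enter at the final step is
#' reported. A p-value mode is also provided (`mode = "p"`), entering on
#' p <= `p_enter` and removing on p > `p_remove`.
#'
#' @param response Numeric response vector.
#' @param candidates Data frame of candidate predictors (named columns).
#' @param f_enter,f_remove F thresholds (defaults 4.0 / 3.9).
#' @param mode `"F"` (default) or `"p"`.
#' @param p_enter,p_remove p-value thresholds for `mode = "p"`.
#' @return Object of class `stepwise_fit`: selected terms, the final `lm`
#'   fit, a coefficient table (with standardized coefficients and F-to-remove),
#'   an excluded-variable table (F-to-enter, p), and overall `r_squared`,
#'   `F_model`, `df`, `p_model`, `n`.
#' @export
stepwise_select <- function(response, candidates,
                            f_enter = 4.0, f_remove = 3.9,
                            mode = c("F", "p"), p_enter = 0.05, p_remove = 0.10) {
  mode <- match.arg(mode)
  candidates <- as.data.frame(candidates)
  ok <- is.finite(response) & stats::complete.cases(candidates)
  y <- response[ok]; X <- candidates[ok, , drop = FALSE]
  n <- length(y)
  if (n < 5) stop("stepwise selection needs at least 5 complete observations")
  vars <- names(X)
  model <- character(0)
  seen <- character(0)
  enters <- function(st) {
    if (mode == "F") is.finite(st$F) && st$F >= f_enter
    else is.finite(st$p) && st$p <= p_enter
  }
  removes <- function(st) {
    if (mode == "F") is.finite(st$F) && st$F < f_remove
    else is.finite(st$p) && st$p > p_remove
  }
  repeat {
    sig <- paste(sort(model), collapse = "+")
    if (sig %in% seen) break  # cycle guard
    seen <- c(seen, sig)
    out_vars <- setdiff(vars, model)
    if (length(out_vars) == 0) break
    stats_in <- lapply(out_vars, function(v) .partial_f_enter(y, X, model, v))
    names(stats_in) <- out_vars
    aliased <- vapply(stats_in, function(s) isTRUE(s$aliased), logical(1))
    if (any(aliased)) {
      warning("dropping collinear candidate(s): ",
              paste(out_vars[aliased], collapse = ", "))
      vars <- setdiff(vars, out_vars[aliased])
      stats_in <- stats_in[!aliased]
      out_vars <- out_vars[!aliased]
      if (length(out_vars) == 0) break
    }
    fv <- vapply(stats_in, function(s) if (is.finite(s$F)) s$F else -Inf, numeric(1))
    best <- out_vars[which.max(fv)]
    if (!enters(stats_in[[best]])) break
    model <- c(model, best)
    # backward sweep
    repeat {
      if (length(model) == 0) break
      rem <- lapply(model, function(v) .partial_f_remove(y, X, model, v))
      names(rem) <- model
      rf <- vapply(rem, function(s) if (is.finite(s$F)) s$F else Inf, numeric(1))
      worst <- model[which.min(rf)]
      if (removes(rem[[worst]])) model <- setdiff(model, worst) else break
    }
  }

  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(stats::reformulate(if (length(model)) sprintf("`%s`", model) else "1",
                                      response = "y"), data = df)
  sm <- suppressWarnings(summary(fit))  # silence perfect-fit chatter
  coefs <- NULL
  if (length(model)) {
    ct <- sm$coefficients
    terms <- rownames(ct)
    clean <- gsub("`", "", terms)
    std <- vapply(seq_along(terms), function(i) {
      v <- clean[i]
      if (v == "(Intercept)") NA_real_
      else unname(ct[i, 1]) * stats::sd(X[[v]]) / stats::sd(y)
    }, numeric(1))
    frem <- vapply(clean, function(v) {
      if (v == "(Intercept)") NA_real_ else .partial_f_remove(y, X, model, v)$F
    }, numeric(1))
    prem <- vapply(clean, function(v) {
      if (v == "(Intercept)") NA_real_ else .partial_f_remove(y, X, model, v)$p
    }, numeric(1))
    coefs <- data.frame(term = clean, coeff = unname(ct[, 1]),
                        std_coeff = std, std_error = unname(ct[, 2]),
                        f_to_remove = frem, p = prem, stringsAsFactors = FALSE)
  }
  excl <- setdiff(vars, model)
  excluded <- NULL
  if (length(excl)) {
    st <- lapply(excl, function(v) .partial_f_enter(y, X, model, v))
    excluded <- data.frame(term = excl,
                           f_to_enter = vapply(st, function(s) s$F, numeric(1)),
                           p = vapply(st, function(s) s$p, numeric(1)),
                           stringsAsFactors = FALSE)
  }
  fstat <- sm$fstatistic
  structure(list(family = "stepwise-linear", selected = model, fit = fit,
                 coefficients = coefs, excluded = excluded,
                 r_squared = if (length(model)) sm$r.squared else NA_real_,
                 F_model = if (!is.null(fstat)) unname(fstat[1]) else NA_real_,
                 df = if (!is.null(fstat)) unname(fstat[2:3]) else c(NA, fit$df.residual),
                 p_model = if (!is.null(fstat))
                   stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
                 else NA_real_,
                 n = n, mode = mode,
                 thresholds = c(f_enter = f_enter, f_remove = f_remove)),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  if (length(x$selected) == 0) {
    cat("Stepwise regression: no variable entered the model (None)\n")
  } else {
    cat(sprintf("Stepwise regression: %s (R2 = %.3f, F = %.2f, p = %.3g, n = %d)\n",
                paste(x$selected, collapse = " + "), x$r_squared, x$F_model,
                x$p_model, x$n))
    print(x$coefficients, digits = 4)
  }
  if (!is.null(x$excluded)) {
    cat("Variables not in the model (F-to-enter):\n")
    print(x$excluded, digits = 4)
  }
  invisible(x)
}

## ---- nonlinear fits --------------------------------------------------------

.nls_stats <- function(x, y, pred, n_par) {
  n <- length(y)
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  df_model <- n_par - 1
  df_res <- n - n_par
  ss_model <- ss_tot - ss_res
  ms_model <- ss_model / df_model
  ms_res <- ss_res / df_res
  Fv <- ms_model / ms_res
  list(r_squared = r2, r_squared_flag = r2 < 0, ss_model = ss_model,
       ss_res = ss_res, ms_model = ms_model, ms_res = ms_res, F_model = Fv,
       df = c(df_model, df_res),
       p_model = stats::pf(Fv, df_model, df_res, lower.tail = FALSE), n = n)
}

.multistart_nls <- function(x, y, formula, starts, fn, lower = NULL) {
  sses <- vapply(starts, function(st) sum((y - fn(x, st))^2), numeric(1))
  fits <- list()
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(formula, data = data.frame(x = x, y = y), start = st,
                        lower = lower,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0) {
    stop("nonlinear fit error: no multi-start initialization converged ",
         sprintf("(best initial SSE %.4g over %d starts)", min(sses), length(starts)))
  }
  fit_sse <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  best <- fits[[which.min(fit_sse)]]
  # no-uphill guarantee: polish from any initialization that still beats the fit
  if (min(sses) < min(fit_sse)) {
    st <- starts[[which.min(sses)]]
    op <- stats::optim(unlist(st), function(par) {
      sum((y - fn(x, as.list(par)))^2)
    }, method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
    if (op$value < min(fit_sse)) {
      f2 <- tryCatch(
        minpack.lm::nlsLM(formula, data = data.frame(x = x, y = y),
                          start = as.list(op$par), lower = lower,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
        error = function(e) NULL)
      if (!is.null(f2) && sum(stats::resid(f2)^2) < min(fit_sse)) best <- f2
    }
  }
  best
}

#' Three-parameter Gaussian peak fit
#'
#' Least-squares fit of `y = a * exp(-0.5 * ((x - x0)/b)^2)` by
#' Levenberg-Marquardt from five deterministic starts spanning the data
#' range. Used for peaked responses over the width gradient (amphipod diet
#' share, predator density).
#'
#' @param x,y Numeric vectors (>= 4 points; `y` must not be constant).
#' @return Object of class `nonlinear_fit` with `parameters` (`a`, `x0`,
#'   `b`), `r_squared` (1 - SS_res/SS_tot; may be negative, flagged),
#'   `F_model` (MS_model/MS_residual with df_model = 2), `df`, `p_model`,
#'   sums of squares, and the underlying `nls` fit.
#' @export
fit_gaussian3 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("gaussian fit needs at least 4 points")
  if (stats::sd(y) == 0) stop("degenerate input: constant response")
  r <- diff(range(x))
  if (r == 0) stop("degenerate input: constant predictor")
  a0 <- max(y)
  xm <- x[which.max(y)]
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- list(
    list(a = a0, x0 = xm, b = r / 6),
    list(a = a0, x0 = qs[1], b = r / 4),
    list(a = a0, x0 = qs[2], b = r / 4),
    list(a = a0, x0 = qs[3], b = r / 4),
    list(a = a0, x0 = xm, b = r / 2)
  )
  fn <- function(x, p) p$a * exp(-0.5 * ((x - p$x0) / p$b)^2)
  fit <- .multistart_nls(x, y, y ~ a * exp(-0.5 * ((x - x0) / b)^2), starts, fn)
  par <- as.list(stats::coef(fit))
  par$b <- abs(par$b)
  st <- .nls_stats(x, y, stats::predict(fit), 3)
  structure(c(list(family = "gaussian3",
                   parameters = c(a = par$a, x0 = par$x0, b = par$b),
                   fit = fit), st),
            class = "nonlinear_fit")
}

#' Two-parameter saturating hyperbola fit
#'
#' Least-squares fit of the exponential saturating form
#' `y = a * (1 - exp(-b * x))` (passes through the origin), by
#' Levenberg-Marquardt from five deterministic starts. Used for saturating
#' responses such as trophic position against the mole-crab diet share.
#'
#' @param x Non-negative predictor (>= 3 points).
#' @param y Response.
#' @return Object of class `nonlinear_fit` with `parameters` (`a`, `b`) and
#'   the same fit statistics as [fit_gaussian3()] (df_model = 1).
#' @export
fit_hyperbola2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("hyperbola fit needs at least 3 points")
  if (any(x < 0)) stop("hyperbola fit requires x >= 0")
  if (stats::sd(y) == 0) stop("degenerate input: constant response")
  xm <- max(x)
  if (xm == 0) stop("degenerate input: constant predictor")
  a0 <- max(abs(y)) * sign(y[which.max(abs(y))])
  starts <- list(
    list(a = a0, b = 1 / mean(x[x > 0])),
    list(a = a0, b = 3 / xm),
    list(a = a0, b = 0.3 / xm),
    list(a = mean(y[x >= stats::quantile(x, 2 / 3)]), b = 2 / xm),
    list(a = a0 * 1.5, b = 10 / xm)
  )
  fn <- function(x, p) p$a * (1 - exp(-p$b * x))
  fit <- .multistart_nls(x, y, y ~ a * (1 - exp(-b * x)), starts, fn,
                         lower = c(a = -Inf, b = 1e-10))
  st <- .nls_stats(x, y, stats::predict(fit), 2)
  structure(c(list(family = "hyperbola2",
                   parameters = stats::coef(fit), fit = fit), st),
            class = "nonlinear_fit")
}

#' @export
print.nonlinear_fit <- function(x, ...) {
  cat(sprintf("Nonlinear fit (%s): R2 = %.3f%s, F(%d, %d) = %.2f, p = %.3g\n",
              x$family, x$r_squared, ifelse(x$r_squared_flag, " [negative]", ""),
              x$df[1], x$df[2], x$F_model, x$p_model))
  print(round(x$parameters, 5))
  invisible(x)
}

## ---- battery ---------------------------------------------------------------

.physical_vars <- c("width_m", "slope_deg", "grain_mm", "wrack_g")

.fit_or_status <- function(expr) {
  tryCatch(list(fit = expr, status = "ok"),
           warning = function(w) {
             f <- suppressWarnings(tryCatch(expr, error = function(e) NULL))
             list(fit = f, status = paste("warning:", conditionMessage(w)))
           },
           error = function(e) list(fit = NULL,
                                    status = paste("degenerate:", conditionMessage(e))))
}

#' Run the gradient regression battery
#'
#' Reproduces the study's model suite on a merged per-site table: forward
#' stepwise regression of each arcsine-square-root-transformed diet
#' proportion on the physical parameters (width, slope, grain size, wrack
#' biomass); a Gaussian fit of the (transformed) amphipod share against
#' width; stepwise plus per-parameter Gaussian fits for log10 burrow density;
#' stepwise for trophic position against the physical parameters; and linear
#' fits of trophic position against each raw diet proportion, with a
#' saturating-hyperbola alternative for the mole-crab share. Individual
#' models may exclude flagged sites.
#'
#' @param sites Data frame (`sites` schema).
#' @param diet_sites Site diet table from [summarize_diet()].
#' @param tp_table Data frame from [trophic_position_table()].
#' @param f_enter,f_remove Stepwise thresholds.
#' @param exclude Named list mapping model ids to site codes excluded from
#'   that fit only (e.g. `list(tp_amph_linear = "S05")`).
#' @return Object of class `gradient_report`: list of per-model results
#'   (each `fit` + `status` + `n`) and a tidy `table` of coefficients and
#'   fit statistics.
#' @export
gradient_analysis <- function(sites, diet_sites, tp_table,
                              f_enter = 4.0, f_remove = 3.9, exclude = NULL) {
  need_sites <- c("site", .physical_vars, "burrow_density")
  miss <- setdiff(need_sites, names(sites))
  if (length(miss)) stop("sites is missing column(s): ", paste(miss, collapse = ", "))
  taxa <- c("mole_crab", "amphipod", "coquina")
  pc <- paste0("p_", taxa)
  miss <- setdiff(c("site", pc), names(diet_sites))
  if (length(miss)) stop("diet_sites is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("site", "tp"), names(tp_table))
  if (length(miss)) stop("tp_table is missing column(s): ", paste(miss, collapse = ", "))

  m <- merge(merge(sites, diet_sites, by = "site"), tp_table, by = "site")
  models <- list()
  sub_model <- function(id) {
    ex <- exclude[[id]]
    if (is.null(ex)) m else m[!(m$site %in% ex), , drop = FALSE]
  }
  add <- function(id, response, variable, res, n) {
    models[[id]] <<- c(res, list(response = response, variable = variable, n = n))
  }

  short <- c(mole_crab = "mole", amphipod = "amph", coquina = "coq")
  for (tx in taxa) {
    id <- paste0(short[[tx]], "_stepwise")
    d <- sub_model(id)
    add(id, paste0(tx, "_proportion"), "stepwise",
        .fit_or_status(stepwise_select(arcsine_sqrt(d[[paste0("p_", tx)]]),
                                       d[, .physical_vars],
                                       f_enter = f_enter, f_remove = f_remove)),
        nrow(d))
  }
  d <- sub_model("amph_gaussian_width")
  add("amph_gaussian_width", "amphipod_proportion", "width_m",
      .fit_or_status(fit_gaussian3(d$width_m, arcsine_sqrt(d$p_amphipod))), nrow(d))

  d <- sub_model("density_stepwise")
  add("density_stepwise", "log10_density", "stepwise",
      .fit_or_status(stepwise_select(as.numeric(log10_density(d$burrow_density)),
                                     d[, .physical_vars],
                                     f_enter = f_enter, f_remove = f_remove)),
      nrow(d))
  for (v in .physical_vars) {
    id <- paste0("density_gaussian_", base::sub("_.*", "", v))
    d <- sub_model(id)
    add(id, "log10_density", v,
        .fit_or_status(fit_gaussian3(d[[v]],
                                     as.numeric(log10_density(d$burrow_density)))),
        nrow(d))
  }

  d <- sub_model("tp_stepwise")
  add("tp_stepwise", "trophic_position", "stepwise",
      .fit_or_status(stepwise_select(d$tp, d[, .physical_vars],
                                     f_enter = f_enter, f_remove = f_remove)),
      nrow(d))

  for (tx in taxa) {
    id <- paste0("tp_", short[[tx]], "_linear")
    d <- sub_model(id)
    add(id, "trophic_position", paste0(tx, "_proportion"),
        .fit_or_status(stepwise_select(d$tp, d[, paste0("p_", tx), drop = FALSE],
                                       f_enter = 0, f_remove = -1)),
        nrow(d))
  }
  d <- sub_model("tp_mole_hyperbola")
  add("tp_mole_hyperbola", "trophic_position", "mole_crab_proportion",
      .fit_or_status(fit_hyperbola2(d$p_mole_crab, d$tp)), nrow(d))

  structure(list(models = models, table = .gradient_table(models)),
            class = "gradient_report")
}

# Flatten the model list into a Table-1-shaped data frame.
.gradient_table <- function(models) {
  rows <- list()
  push <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...,
                                                                 stringsAsFactors = FALSE)
  for (id in names(models)) {
    mres <- models[[id]]
    f <- mres$fit
    if (is.null(f)) {
      push(model = id, response = mres$response, variable = mres$variable,
           in_model = NA, coeff = NA_real_, std_coeff = NA_real_,
           std_error = NA_real_, F = NA_real_, P = NA_real_, R2 = NA_real_,
           df_model = NA_real_, df_residual = NA_real_, SS = NA_real_,
           MS = NA_real_, n = mres$n, status = mres$status)
      next
    }
    if (inherits(f, "stepwise_fit")) {
      if (length(f$selected) == 0) {
        push(model = id, response = mres$response, variable = "None",
             in_model = FALSE, coeff = NA_real_, std_coeff = NA_real_,
             std_error = NA_real_, F = NA_real_, P = NA_real_, R2 = NA_real_,
             df_model = NA_real_, df_residual = NA_real_, SS = NA_real_,
             MS = NA_real_, n = f$n, status = mres$status)
      } else {
        for (i in seq_len(nrow(f$coefficients))) {
          co <- f$coefficients[i, ]
          push(model = id, response = mres$response, variable = co$term,
               in_model = TRUE, coeff = co$coeff, std_coeff = co$std_coeff,
               std_error = co$std_error, F = co$f_to_remove, P = co$p,
               R2 = f$r_squared, df_model = f$df[1], df_residual = f$df[2],
               SS = NA_real_, MS = NA_real_, n = f$n, status = mres$status)
        }
      }
      if (!is.null(f$excluded)) {
        for (i in seq_len(nrow(f$excluded))) {
          ex <- f$excluded[i, ]
          push(model = id, response = mres$response, variable = ex$term,
               in_model = FALSE, coeff = NA_real_, std_coeff = NA_real_,
               std_error = NA_real_, F = ex$f_to_enter, P = ex$p,
               R2 = NA_real_, df_model = NA_real_, df_residual = NA_real_,
               SS = NA_real_, MS = NA_real_, n = f$n, status = mres$status)
        }
      }
    } else if (inherits(f, "nonlinear_fit")) {
      push(model = id, response = mres$response, variable = mres$variable,
           in_model = TRUE, coeff = NA_real_, std_coeff = NA_real_,
           std_error = NA_real_, F = f$F_model, P = f$p_model,
           R2 = f$r_squared, df_model = f$df[1], df_residual = f$df[2],
           SS = f$ss_model, MS = f$ms_model, n = f$n, status = mres$status)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.gradient_report <- function(x, ...) {
  cat(sprintf("Gradient regression battery: %d model(s)\n", length(x$models)))
  ok <- vapply(x$models, function(mres) identical(mres$status, "ok"), logical(1))
  if (any(!ok)) {
    cat("  non-ok models:", paste(names(x$models)[!ok], collapse = ", "), "\n")
  }
  invisible(x)
}
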