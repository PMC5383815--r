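# Hierarchical Bayesian logistic regression of search occurrence.
#
# y_ij ~ Bernoulli(theta_ij),  logit(theta_ij) = x_ij' beta + alpha_k
# beta_j  ~ Normal(mu_beta_j, sigma_beta_j^2)
# alpha_k ~ Normal(mu_alpha,  sigma_alpha^2)
# mu_beta_j, mu_alpha ~ Normal(0, precision 0.001)
# sigma_beta_j, sigma_alpha ~ Uniform(0, 10)
#
# By default each fixed effect carries its own Normal hyper-prior
# ("coefficient"), so the coefficient priors are effectively uninformative;
# alternatives are one hyper-prior shared across all fixed effects
# ("shared", which shrinks coefficients towards each other) and fixed
# Normal(0, 1000) priors ("independent").
#
# Sampling is a true Gibbs sampler: Polya-Gamma data augmentation makes the
# beta and alpha conditionals Gaussian; the hyper-means are conjugate and the
# hyper-sds are updated by shrinkage slice sampling within their bounded
# support. An adaptive random-walk Metropolis fallback is provided.

#' Canonical model predictors
#'
#' The fixed-effect covariates of the search model, in their model units:
#' dive duration (minutes), mean ODBA (g), bathymetry (m, negative), dive
#' ratio (proportion), bottom time (proportion) and shore distance (km).
#' @return Character vector of column names.
#' @export
search_predictors <- function() {
  c("duration_min", "mean_odba", "bathymetry_m", "dive_ratio",
    "bottom_prop", "shore_km")
}

#' Add model-unit covariate columns to a dive table
#'
#' Dive tables from the sensor pipeline carry duration in seconds and bottom
#' time in percent; the model uses minutes and proportions (coefficients are
#' reported in those units). Adds `duration_min` and `bottom_prop` columns.
#'
#' @param dives Dive tibble with `duration_s` and `bottom_pct`.
#' @return The tibble with model-unit columns appended.
#' @export
prepare_model_frame <- function(dives) {
  check_columns(dives, c("duration_s", "bottom_pct"), "dive table")
  mutate(dives, duration_min = .data$duration_s / 60,
         bottom_prop = .data$bottom_pct / 100)
}

#' Build the design matrix for the search model
#'
#' Predictor columns are taken verbatim (no standardization; raw model
#' units) in the order requested, with an optional leading intercept column.
#'
#' @param dives Dive tibble with the predictor columns, a logical/0-1
#'   `searching` response and `seal_id`.
#' @param predictors Character vector of predictor column names.
#' @param include_intercept Prepend an all-ones column? (default `TRUE`).
#' @return List: `X` (matrix), `y` (0/1 vector), `seal` (integer index),
#'   `seal_levels`.
#' @export
build_design <- function(dives, predictors = search_predictors(),
                         include_intercept = TRUE) {
  check_columns(dives, c(predictors, "searching", "seal_id"), "model frame")
  vals <- as.matrix(dives[predictors])
  if (!all(is.finite(vals))) {
    abort("non-finite predictor values in the model frame.",
          class = "sealsearch_schema_error")
  }
  constant <- apply(vals, 2, function(v) diff(range(v)) == 0)
  if (any(constant)) {
    warn(sprintf("constant predictor column(s): %s — the model is degenerate in them.",
                 paste(predictors[constant], collapse = ", ")))
  }
  X <- if (include_intercept) cbind("(Intercept)" = 1, vals) else vals
  y <- as.integer(dives$searching)
  if (length(unique(y)) < 2) {
    warn("response is constant (complete separation): coefficients are not identified.")
  }
  seal_levels <- sort(unique(dives$seal_id))
  list(X = X, y = y, seal = match(dives$seal_id, seal_levels),
       seal_levels = seal_levels)
}

# shrinkage slice sampler for sigma on (lo, hi) given m deviations with
# sum of squares ss:  log f = -m log(sigma) - ss / (2 sigma^2)
slice_sigma <- function(sigma0, m, ss, hi = 10, lo = 1e-6) {
  ss <- max(ss, 1e-12)
  logf <- function(s) -m * log(s) - ss / (2 * s^2)
  ly <- logf(sigma0) - rexp(1)
  l <- lo; u <- hi
  for (i in 1:200) {
    s1 <- runif(1, l, u)
    if (logf(s1) >= ly) return(s1)
    if (s1 < sigma0) l <- s1 else u <- s1
  }
  sigma0
}

run_pg_chain <- function(X, y, seal, K, n_iter, burn_in, chain_seed,
                         prior, mu_prec, sigma_upper) {
  set.seed(chain_seed)
  p <- ncol(X); n <- nrow(X)
  kappa <- y - 0.5
  beta <- rnorm(p, 0, 2)
  alpha <- rnorm(K, 0, 1)
  mu_b <- rep(0, p); mu_a <- 0
  sig_b <- runif(p, 0.5, 0.95 * sigma_upper)
  sig_a <- runif(1, 0.5, 0.95 * sigma_upper)
  keep <- n_iter - burn_in
  draws <- matrix(NA_real_, keep, p + K + 4)
  grp <- factor(seal, levels = seq_len(K))
  for (it in seq_len(n_iter)) {
    psi <- drop(X %*% beta) + alpha[seal]
    omega <- rpg_devroye(psi)
    prior_prec <- switch(prior,
      coefficient = 1 / sig_b^2,                 # per-coefficient hierarchy
      shared = rep(1 / sig_b[1]^2, p),           # one hyper-prior for all betas
      independent = rep(0.001, p))               # fixed N(0, 1000)
    prior_mean <- switch(prior,
      coefficient = mu_b,
      shared = rep(mu_b[1], p),
      independent = rep(0, p))
    v_inv <- crossprod(X, X * omega) + diag(prior_prec, p)
    b <- drop(crossprod(X, kappa - omega * alpha[seal])) + prior_prec * prior_mean
    ch <- chol(v_inv)
    m <- backsolve(ch, forwardsolve(t(ch), b))
    beta <- drop(m + backsolve(ch, rnorm(p)))
    xb <- drop(X %*% beta)
    s_om <- drop(rowsum(omega, grp))
    s_res <- drop(rowsum(kappa - omega * xb, grp))
    prec_a <- s_om + 1 / sig_a^2
    alpha <- rnorm(K, (s_res + mu_a / sig_a^2) / prec_a, 1 / sqrt(prec_a))
    if (prior == "coefficient") {
      pr <- 1 / sig_b^2 + mu_prec
      mu_b <- rnorm(p, (beta / sig_b^2) / pr, 1 / sqrt(pr))
      for (j in seq_len(p)) {
        sig_b[j] <- slice_sigma(sig_b[j], 1, (beta[j] - mu_b[j])^2,
                                hi = sigma_upper)
      }
    } else if (prior == "shared") {
      pr <- p / sig_b[1]^2 + mu_prec
      mu_b[] <- rnorm(1, sum(beta) / sig_b[1]^2 / pr, 1 / sqrt(pr))
      sig_b[] <- slice_sigma(sig_b[1], p, sum((beta - mu_b[1])^2),
                             hi = sigma_upper)
    }
    pr <- K / sig_a^2 + mu_prec
    mu_a <- rnorm(1, sum(alpha) / sig_a^2 / pr, 1 / sqrt(pr))
    sig_a <- slice_sigma(sig_a, K, sum((alpha - mu_a)^2), hi = sigma_upper)
    if (it > burn_in) {
      draws[it - burn_in, ] <- c(beta, alpha, mean(mu_b), mean(sig_b),
                                 mu_a, sig_a)
    }
  }
  draws
}

run_rwm_chain <- function(X, y, seal, K, n_iter, burn_in, chain_seed,
                          prior, mu_prec, sigma_upper) {
  set.seed(chain_seed)
  p <- ncol(X); kappa <- y - 0.5
  beta <- rnorm(p, 0, 2); alpha <- rnorm(K, 0, 1)
  mu_b <- rep(0, p); mu_a <- 0
  sig_b <- runif(p, 0.5, 0.95 * sigma_upper)
  sig_a <- runif(1, 0.5, 0.95 * sigma_upper)
  scales <- rep(0.1, p + K)
  acc <- rep(0, p + K)
  loglik <- function(beta, alpha) {
    psi <- drop(X %*% beta) + alpha[seal]
    sum(y * psi - log1p(exp(psi)))
  }
  ll <- loglik(beta, alpha)
  keep <- n_iter - burn_in
  draws <- matrix(NA_real_, keep, p + K + 4)
  for (it in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      prop <- beta; prop[j] <- beta[j] + rnorm(1, 0, scales[j])
      pm <- switch(prior, coefficient = mu_b[j], shared = mu_b[1], independent = 0)
      pv <- switch(prior, coefficient = sig_b[j]^2, shared = sig_b[1]^2,
                   independent = 1000)
      ll_p <- loglik(prop, alpha)
      lr <- ll_p - ll + ((beta[j] - pm)^2 - (prop[j] - pm)^2) / (2 * pv)
      if (log(runif(1)) < lr) { beta <- prop; ll <- ll_p; acc[j] <- acc[j] + 1 }
    }
    for (k in seq_len(K)) {
      prop <- alpha; prop[k] <- alpha[k] + rnorm(1, 0, scales[p + k])
      ll_p <- loglik(beta, prop)
      lr <- ll_p - ll +
        ((alpha[k] - mu_a)^2 - (prop[k] - mu_a)^2) / (2 * sig_a^2)
      if (log(runif(1)) < lr) { alpha <- prop; ll <- ll_p; acc[p + k] <- acc[p + k] + 1 }
    }
    if (it %% 50 == 0 && it <= burn_in) {      # adapt during burn-in only
      rate <- acc / 50
      scales <- scales * exp(rate - 0.44)
      acc[] <- 0
    }
    if (prior == "coefficient") {
      pr <- 1 / sig_b^2 + mu_prec
      mu_b <- rnorm(p, (beta / sig_b^2) / pr, 1 / sqrt(pr))
      for (j in seq_len(p)) {
        sig_b[j] <- slice_sigma(sig_b[j], 1, (beta[j] - mu_b[j])^2,
                                hi = sigma_upper)
      }
    } else if (prior == "shared") {
      pr <- p / sig_b[1]^2 + mu_prec
      mu_b[] <- rnorm(1, sum(beta) / sig_b[1]^2 / pr, 1 / sqrt(pr))
      sig_b[] <- slice_sigma(sig_b[1], p, sum((beta - mu_b[1])^2),
                             hi = sigma_upper)
    }
    pr <- K / sig_a^2 + mu_prec
    mu_a <- rnorm(1, sum(alpha) / sig_a^2 / pr, 1 / sqrt(pr))
    sig_a <- slice_sigma(sig_a, K, sum((alpha - mu_a)^2), hi = sigma_upper)
    if (it > burn_in) draws[it - burn_in, ] <- c(beta, alpha, mean(mu_b),
                                                 mean(sig_b), mu_a, sig_a)
  }
  draws
}

#' Fit the hierarchical search-occurrence model
#'
#' Fits the Bayesian logistic regression with per-seal random intercepts by
#' MCMC. The default sampler is a true Gibbs sampler using Polya-Gamma data
#' augmentation; `method = "metropolis"` switches to an adaptive
#' random-walk Metropolis-within-Gibbs fallback. Deterministic given `seed`
#' and chain count (chain seeds derive from the master seed).
#'
#' @param dives Dive tibble (see [build_design()]); alternatively pass a
#'   prebuilt design via `design`.
#' @param predictors Predictor columns (default [search_predictors()]).
#' @param include_intercept Include an intercept column (default `TRUE`).
#' @param n_iter Iterations per chain (default 7500).
#' @param burn_in Burn-in discarded per chain (default 2000).
#' @param n_chains Number of chains (default 3).
#' @param seed Master RNG seed.
#' @param method `"gibbs"` (Polya-Gamma) or `"metropolis"`.
#' @param prior Reading of the fixed-effect hyper-prior. `"coefficient"`
#'   (default): each coefficient has its own Normal(mu_j, sigma_j^2)
#'   hyper-prior — effectively uninformative per predictor. `"shared"`: one
#'   hyper-prior for all fixed effects (shrinks coefficients towards a
#'   common mean — informative when predictors differ in scale).
#'   `"independent"`: fixed Normal(0, 1000) priors, no hyper-parameters.
#'   The reported `mu_beta`/`sigma_beta` are averages across coefficients
#'   under `"coefficient"`, and are not updated under `"independent"`.
#' @param mu_prec Precision of the Normal(0, .) hyper-mean prior (0.001,
#'   i.e. variance 1000).
#' @param sigma_upper Upper bound of the Uniform prior on the hyper-sds.
#' @param design Optional result of [build_design()] (overrides `dives`).
#' @return A `search_fit` object: draws, parameter names, summary,
#'   diagnostics. Use [tidy()], [glance()], [autoplot()],
#'   [posterior_draws()].
#' @export
fit_search_model <- function(dives = NULL, predictors = search_predictors(),
                             include_intercept = TRUE,
                             n_iter = 7500, burn_in = 2000, n_chains = 3,
                             seed = 1, method = c("gibbs", "metropolis"),
                             prior = c("coefficient", "shared", "independent"),
                             mu_prec = 0.001, sigma_upper = 10,
                             design = NULL) {
  method <- match.arg(method); prior <- match.arg(prior)
  if (n_iter <= burn_in) abort("`n_iter` must exceed `burn_in`.")
  if (is.null(design)) design <- build_design(dives, predictors, include_intercept)
  X <- design$X; y <- design$y; seal <- design$seal
  K <- length(design$seal_levels)
  if (K < 2) {
    abort("only one seal: a random intercept is not estimable; drop it and fit a fixed-intercept model (e.g. compare_models()).",
          class = "sealsearch_config_error")
  }
  par_names <- c(colnames(X), paste0("alpha[", design$seal_levels, "]"),
                 "mu_beta", "sigma_beta", "mu_alpha", "sigma_alpha")
  runner <- if (method == "gibbs") run_pg_chain else run_rwm_chain
  chains <- purrr::map(seq_len(n_chains), function(cc) {
    d <- runner(X, y, seal, K, n_iter, burn_in, derive_seed(seed, 4L, cc),
                prior, mu_prec, sigma_upper)
    colnames(d) <- par_names
    d
  })
  separation <- length(unique(y)) < 2
  fit <- structure(
    list(chains = chains, par_names = par_names,
         n_beta = ncol(X), seal_levels = design$seal_levels,
         n_iter = n_iter, burn_in = burn_in, n_chains = n_chains,
         n_obs = nrow(X), method = method, prior = prior, seed = seed,
         separation = separation),
    class = "search_fit")
  fit$summary <- summarize_fit(fit)
  fit
}

all_draws <- function(fit, par) {
  unlist(purrr::map(fit$chains, ~ .x[, par]), use.names = FALSE)
}

summarize_fit <- function(fit, prob = 0.95) {
  rh <- gelman_rhat(fit$chains)
  gz <- purrr::map(fit$par_names, function(par) {
    vapply(fit$chains, function(ch) geweke_z(ch[, par]), numeric(1))
  })
  purrr::map_dfr(seq_along(fit$par_names), function(j) {
    par <- fit$par_names[j]
    x <- all_draws(fit, par)
    h <- hpd(x, prob)
    tibble(term = par, estimate = mean(x), std.error = sd(x),
           conf.low = h$lower, conf.high = h$upper,
           spans_zero = h$spans_zero,
           rhat = rh[par],
           geweke_z_max = if (all(is.na(gz[[j]]))) NA_real_ else
             max(abs(gz[[j]]), na.rm = TRUE))
  })
}

#' @export
print.search_fit <- function(x, ...) {
  cat(sprintf(
    "<search_fit> %s sampler, %d chains x %d iterations (burn-in %d), %d dives, %d seals\n",
    x$method, x$n_chains, x$n_iter, x$burn_in, x$n_obs, length(x$seal_levels)))
  if (x$separation) cat("  ! response was constant: coefficients not identified\n")
  print(x$summary[seq_len(x$n_beta), ])
  invisible(x)
}

#' Tidy a fitted search model
#'
#' One row per parameter: posterior mean, sd, 95% HPD bounds, whether the
#' HPD spans zero, split-chain Gelman-Rubin `rhat` and the largest absolute
#' per-chain Geweke z.
#'
#' @param x A `search_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.search_fit <- function(x, ...) x$summary

#' Glance at a fitted search model
#' @param x A `search_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit-level information.
#' @export
glance.search_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_seals = length(x$seal_levels),
         n_chains = x$n_chains, n_iter = x$n_iter, burn_in = x$burn_in,
         n_draws = x$n_chains * (x$n_iter - x$burn_in),
         method = x$method, prior = x$prior,
         max_rhat = max(x$summary$rhat, na.rm = TRUE),
         separation = x$separation)
}

#' Posterior draws in long format
#' @param fit A `search_fit`.
#' @return Tibble `chain, iteration, term, value`.
#' @export
posterior_draws <- function(fit) {
  purrr::map_dfr(seq_along(fit$chains), function(cc) {
    d <- fit$chains[[cc]]
    as_tibble(d) %>%
      mutate(chain = cc, iteration = row_number()) %>%
      tidyr::pivot_longer(cols = all_of(fit$par_names),
                          names_to = "term", values_to = "value")
  })
}

#' Highest posterior density interval
#'
#' Shortest interval containing `prob` posterior mass, by the sorted-window
#' method.
#'
#' @param draws Numeric vector of posterior draws (>= 100 recommended).
#' @param prob Interval mass in (0, 1) (default 0.95).
#' @return List `lower`, `upper`, `spans_zero`.
#' @export
hpd <- function(draws, prob = 0.95) {
  if (!is.numeric(prob) || prob <= 0 || prob >= 1) {
    abort("`prob` must lie in (0, 1).", class = "sealsearch_domain_error")
  }
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (n == 0) abort("no finite draws.", class = "sealsearch_domain_error")
  gap <- max(1L, min(n - 1L, round(n * prob)))
  if (n == 1L) {
    lo <- hi <- x
  } else {
    starts <- seq_len(n - gap)
    i <- which.min(x[starts + gap] - x[starts])
    lo <- x[i]; hi <- x[i + gap]
  }
  list(lower = lo, upper = hi, spans_zero = lo < 0 && hi > 0)
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so one long drifting chain is also caught). Values near 1 indicate
#' convergence.
#'
#' @param chains List of draw matrices (iterations x parameters) or a list
#'   of numeric vectors for a single parameter.
#' @return Named vector of R-hat per parameter (`NA` with a warning for a
#'   single chain that cannot be split).
#' @export
gelman_rhat <- function(chains) {
  if (is.numeric(chains[[1]]) && is.null(dim(chains[[1]]))) {
    chains <- purrr::map(chains, ~ matrix(.x, ncol = 1,
                                          dimnames = list(NULL, "par")))
  }
  pars <- colnames(chains[[1]])
  n <- nrow(chains[[1]])
  if (length(chains) < 2 && n < 4) {
    warn("R-hat needs at least two (split) chains; returning NA.")
    return(setNames(rep(NA_real_, length(pars)), pars))
  }
  half <- floor(n / 2)
  split_chains <- purrr::flatten(purrr::map(chains, function(ch) {
    list(ch[seq_len(half), , drop = FALSE],
         ch[seq.int(n - half + 1, n), , drop = FALSE])
  }))
  m <- length(split_chains)
  out <- vapply(pars, function(par) {
    mat <- vapply(split_chains, function(ch) ch[, par], numeric(half))
    means <- colMeans(mat)
    vars <- apply(mat, 2, var)
    w <- mean(vars)
    b <- half * var(means)
    if (w == 0) return(ifelse(b == 0, 1, Inf))
    sqrt(((half - 1) / half * w + b / half) / w)
  }, numeric(1))
  setNames(out, pars)
}

# spectral density of a series at frequency zero, via an AR fit
spectrum0_ar <- function(x) {
  if (var(x) == 0) return(0)
  fit <- tryCatch(ar(x, aic = TRUE, order.max = min(30, length(x) %/% 4)),
                  error = function(e) NULL)
  if (is.null(fit)) return(var(x))
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' z-score comparing the mean of the first `frac1` of a chain with the mean
#' of the last `frac2`, with variances estimated from the spectral density
#' at frequency zero. |z| > 2 suggests the chain has not reached
#' stationarity. A constant chain has no defined z and returns `NA`.
#'
#' @param x Numeric vector: one chain of one parameter.
#' @param frac1,frac2 Early and late window fractions (defaults 0.1, 0.5).
#' @return The z-score (`NA` for a degenerate chain).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  n1 <- max(2, floor(frac1 * n)); n2 <- max(2, floor(frac2 * n))
  a <- x[seq_len(n1)]
  b <- x[seq.int(n - n2 + 1, n)]
  if (var(x) == 0) return(NA_real_)
  sv <- spectrum0_ar(a) / n1 + spectrum0_ar(b) / n2
  if (sv <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sv)
}

#' Screen out highly correlated predictors
#'
#' Functionally redundant predictors (e.g. dive depth and bathymetry for a
#' benthic forager) destabilise model selection. Walking the predictors in
#' the given priority order, a predictor is dropped when its absolute
#' Pearson correlation with an already-kept predictor exceeds `threshold`.
#'
#' @param dives Dive tibble.
#' @param predictors Candidate predictor columns, in priority order.
#' @param threshold Absolute correlation above which the later predictor is
#'   dropped (default 0.7).
#' @return Character vector of retained predictors, with the dropped ones
#'   in attribute `"dropped"`.
#' @export
drop_correlated <- function(dives, predictors = search_predictors(),
                            threshold = 0.7) {
  check_columns(dives, predictors, "model frame")
  cm <- abs(stats::cor(as.matrix(dives[predictors])))
  keep <- character(0); dropped <- character(0)
  for (p in predictors) {
    if (length(keep) > 0 && any(cm[p, keep] > threshold, na.rm = TRUE)) {
      dropped <- c(dropped, p)
    } else {
      keep <- c(keep, p)
    }
  }
  structure(keep, dropped = dropped)
}

#' Compare candidate fixed-effect models by ML logistic fits
#'
#' Each candidate (a character vector of predictor columns; `character(0)`
#' for the null model) is fitted by maximum likelihood (IRLS via
#' [stats::glm()], no random effect). Information criteria are computed
#' from the deviance: `AIC = deviance + 2k`, `BIC = deviance + k log(n)`
#' (k counts the intercept). Candidates are ranked by BIC; a non-convergent
#' fit is flagged, not dropped.
#'
#' @param dives Dive tibble with `searching` and the predictor columns.
#' @param candidates Named list of character vectors of predictors.
#' @return Tibble: one row per candidate with `k, null_deviance,
#'   residual_deviance, aic, bic, converged`, ordered by BIC.
#' @export
compare_models <- function(dives, candidates) {
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- purrr::map_chr(candidates, function(v) {
      if (length(v) == 0) "null" else paste(v, collapse = "+")
    })
  }
  n <- nrow(dives)
  out <- purrr::imap_dfr(candidates, function(preds, nm) {
    f <- if (length(preds) == 0) "searching ~ 1" else
      paste("searching ~", paste(preds, collapse = " + "))
    fit <- glm(stats::as.formula(f), family = binomial(), data = dives)
    k <- length(coef(fit))
    tibble(model = nm, k = k,
           null_deviance = fit$null.deviance,
           residual_deviance = fit$deviance,
           aic = fit$deviance + 2 * k,
           bic = fit$deviance + k * log(n),
           converged = fit$converged)
  })
  arrange(out, .data$bic)
}
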