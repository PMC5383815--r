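balanced_cfg <- function(n_per_seal = 100, n_seals = 4, sigma_alpha = 0.3) {
  # a well-identified regime: one strong predictor, outcomes near 50/50
  cfg <- sim_config(n_seals = n_seals, n_trips_per_seal = 1,
                    n_dives_per_trip = n_per_seal,
                    beta0 = -3.3, sigma_alpha = sigma_alpha)
  cfg$beta <- c(duration_min = 0.66)
  cfg
}

test_that("build_design takes predictors verbatim in the requested order", {
  d <- tibble::tibble(seal_id = c("a", "a", "b"), searching = c(TRUE, FALSE, TRUE),
                      p1 = c(1, 2, 3), p2 = c(10, 20, 30))
  des <- build_design(d, c("p2", "p1"))
  expect_equal(colnames(des$X), c("(Intercept)", "p2", "p1"))
  expect_equal(des$X[, "p2"], c(10, 20, 30))
  expect_equal(des$y, c(1L, 0L, 1L))
  expect_equal(des$seal, c(1L, 1L, 2L))
  # order follows the predictors argument, not the data frame
  des2 <- build_design(d, c("p1", "p2"), include_intercept = FALSE)
  expect_equal(colnames(des2$X), c("p1", "p2"))

  expect_error(build_design(d, "nope"), class = "sealsearch_schema_error")
  expect_warning(build_design(dplyr::mutate(d, p1 = 1), c("p1", "p2")),
                 "constant")
  expect_warning(build_design(dplyr::mutate(d, searching = TRUE), "p1"),
                 "separation")
})

test_that("hpd matches closed-form normal quantiles and degenerate cases", {
  expect_equal(hpd(rep(3, 500))$lower, 3)
  expect_equal(hpd(rep(3, 500))$upper, 3)

  withr::local_seed(51)
  z <- rnorm(1e6)
  h <- hpd(z, 0.95)
  expect_equal(h$lower, -1.96, tolerance = 0.02 / 1.96)
  expect_equal(h$upper, 1.96, tolerance = 0.02 / 1.96)
  expect_true(h$spans_zero)

  expect_false(hpd(abs(z) + 0.1)$spans_zero)
  expect_error(hpd(z, prob = 1.2), class = "sealsearch_domain_error")

  # shortest-interval property on a skewed sample: narrower than the
  # equal-tail interval
  x <- rgamma(2e5, shape = 2)
  h <- hpd(x, 0.9)
  et <- unname(quantile(x, c(0.05, 0.95)))
  expect_lte(h$upper - h$lower, et[2] - et[1])
})

test_that("Gelman-Rubin is ~1 on iid chains and large on divergent chains", {
  withr::local_seed(52)
  iid <- list(rnorm(4000), rnorm(4000))
  expect_lt(abs(gelman_rhat(iid)[[1]] - 1), 0.01)

  apart <- list(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(gelman_rhat(apart)[[1]], 1.1)
})

test_that("Geweke flags drifting chains and reports constants as undefined", {
  withr::local_seed(53)
  expect_lt(abs(geweke_z(rnorm(5000))), 3)
  drift <- cumsum(rnorm(3000, 0.01))
  expect_gt(abs(geweke_z(drift)), 3)
  expect_true(is.na(geweke_z(rep(2, 1000))))
})

test_that("model comparison reproduces the closed-form null deviance and ranks by BIC", {
  d <- tibble::tibble(searching = rep(c(TRUE, FALSE), 50),
                      seal_id = "a",
                      x1 = rnorm(100), x2 = rnorm(100))
  tab <- compare_models(d, list(null = character(0), one = "x1",
                                two = c("x1", "x2")))
  null_row <- tab[tab$model == "null", ]
  expect_equal(null_row$null_deviance, 200 * log(2), tolerance = 1e-9)
  expect_equal(null_row$residual_deviance, 200 * log(2), tolerance = 1e-9)
  expect_equal(null_row$aic, null_row$residual_deviance + 2)
  expect_equal(null_row$bic, null_row$residual_deviance + log(100))
  # nested candidates: residual deviance is non-increasing with predictors
  expect_lte(tab$residual_deviance[tab$model == "two"],
             tab$residual_deviance[tab$model == "one"])
  expect_lte(tab$residual_deviance[tab$model == "one"],
             tab$residual_deviance[tab$model == "null"])
  expect_equal(tab$model[1], tab$model[which.min(tab$bic)])
})

test_that("the one-predictor ML fit agrees with a brute-force likelihood grid", {
  withr::local_seed(54)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 0.9 * x))
  d <- tibble::tibble(searching = y == 1, seal_id = "a", x = x)
  dev_at <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  }
  # nested grid refinement around the deviance minimum
  ctr <- c(0, 0); width <- 4
  for (r in 1:6) {
    b0s <- seq(ctr[1] - width, ctr[1] + width, length.out = 41)
    b1s <- seq(ctr[2] - width, ctr[2] + width, length.out = 41)
    devs <- outer(b0s, b1s, Vectorize(dev_at))
    ix <- arrayInd(which.min(devs), dim(devs))
    ctr <- c(b0s[ix[1]], b1s[ix[2]]); width <- width / 10
  }
  fit <- glm(searching ~ x, binomial(), data = d)
  expect_equal(unname(coef(fit)), ctr, tolerance = 1e-4)
  tab <- compare_models(d, list(one = "x"))
  expect_equal(tab$residual_deviance, dev_at(ctr[1], ctr[2]), tolerance = 1e-6)
})

test_that("the Gibbs sampler is deterministic given the seed", {
  sim <- simulate_dive_table(balanced_cfg(50, 3), seed = 55)
  f1 <- fit_search_model(sim$dives, predictors = "duration_min",
                         n_iter = 300, burn_in = 100, n_chains = 2, seed = 8)
  f2 <- fit_search_model(sim$dives, predictors = "duration_min",
                         n_iter = 300, burn_in = 100, n_chains = 2, seed = 8)
  expect_identical(f1$chains, f2$chains)
  f3 <- fit_search_model(sim$dives, predictors = "duration_min",
                         n_iter = 300, burn_in = 100, n_chains = 2, seed = 9)
  expect_false(identical(f1$chains, f3$chains))
})

test_that("an intercept-only fit on theta = 0.5 data centres on zero", {
  cfg <- balanced_cfg(500, 4, sigma_alpha = 0)
  cfg$beta <- c(duration_min = 0)
  cfg$beta0 <- 0
  sim <- simulate_dive_table(cfg, seed = 56)
  fit <- fit_search_model(sim$dives, predictors = character(0),
                          n_iter = 2000, burn_in = 500, n_chains = 2, seed = 5)
  # the intercept and the random-intercept mean are only identified through
  # their sum: centre the check on the population-level intercept
  alpha_cols <- grep("^alpha\\[", fit$par_names)
  pop_intercept <- mean(vapply(fit$chains, function(ch) {
    mean(ch[, "(Intercept)"] + rowMeans(ch[, alpha_cols]))
  }, numeric(1)))
  expect_lt(abs(pop_intercept), 0.1)
})

test_that("a single seal is rejected with guidance", {
  sim <- simulate_dive_table(balanced_cfg(50, 2), seed = 57)
  one <- dplyr::filter(sim$dives, seal_id == "sim01")
  expect_error(fit_search_model(one, predictors = "duration_min"),
               class = "sealsearch_config_error")
})

test_that("the Gibbs posterior matches an independent JAGS fit of the same hierarchy", {
  skip_if_not_installed("rjags")
  sim <- simulate_dive_table(balanced_cfg(200, 4), seed = 58)
  des <- build_design(sim$dives, "duration_min")
  fit <- fit_search_model(design = des, n_iter = 4000, burn_in = 1000,
                          n_chains = 2, seed = 6)
  model_str <- "model{
    for (i in 1:n) { y[i] ~ dbern(ilogit(b0 + b1 * x[i] + alpha[seal[i]])) }
    b0 ~ dnorm(mu0, pow(s0, -2));  b1 ~ dnorm(mu1, pow(s1, -2))
    mu0 ~ dnorm(0, 0.001); mu1 ~ dnorm(0, 0.001)
    s0 ~ dunif(0, 10); s1 ~ dunif(0, 10)
    for (k in 1:K) { alpha[k] ~ dnorm(mu_a, pow(sig_a, -2)) }
    mu_a ~ dnorm(0, 0.001); sig_a ~ dunif(0, 10)
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = des$y, x = des$X[, 2], n = length(des$y),
                seal = des$seal, K = 4),
    inits = list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 1),
    n.chains = 2, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  s <- summary(rjags::coda.samples(jm, c("b0", "b1", "alpha"), 4000,
                                   progress.bar = "none"))$statistics
  # compare identified quantities: the slope, and the intercept combined
  # with the mean random intercept (the two are confounded individually)
  mine_b1 <- fit$summary[fit$summary$term == "duration_min", ]
  expect_equal(mine_b1$estimate, unname(s["b1", "Mean"]), tolerance = 0.05)
  expect_equal(mine_b1$std.error, unname(s["b1", "SD"]), tolerance = 0.15)
  alpha_cols <- grep("^alpha\\[", fit$par_names)
  mine_pop <- mean(vapply(fit$chains, function(ch) {
    mean(ch[, "(Intercept)"] + rowMeans(ch[, alpha_cols]))
  }, numeric(1)))
  jags_pop <- unname(s["b0", "Mean"] +
                       mean(s[grep("^alpha", rownames(s)), "Mean"]))
  expect_equal(mine_pop, jags_pop, tolerance = 0.1)
})

test_that("posterior sd shrinks roughly as 1/sqrt(n)", {
  sds <- vapply(c(500, 2000, 8000), function(n_total) {
    cfg <- balanced_cfg(n_total / 4, 4)
    sim <- simulate_dive_table(cfg, seed = 59)
    fit <- fit_search_model(sim$dives, predictors = "duration_min",
                            n_iter = 1200, burn_in = 400, n_chains = 1,
                            seed = 3)
    fit$summary$std.error[fit$summary$term == "duration_min"]
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  ratio <- sds[1] / sds[3]           # expect ~ sqrt(16) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("with no between-seal heterogeneity the posterior matches the ML fit", {
  cfg <- balanced_cfg(400, 4, sigma_alpha = 0)
  sim <- simulate_dive_table(cfg, seed = 60)
  fit <- fit_search_model(sim$dives, predictors = "duration_min",
                          n_iter = 2500, burn_in = 500, n_chains = 2, seed = 4)
  ml <- glm(searching ~ duration_min, binomial(), data = sim$dives)
  sm <- fit$summary
  b1 <- sm[sm$term == "duration_min", ]
  expect_lt(abs(b1$estimate - coef(ml)[["duration_min"]]),
            3 * summary(ml)$coefficients["duration_min", "Std. Error"])
  # sigma_alpha posterior concentrates near zero
  expect_lt(sm$estimate[sm$term == "sigma_alpha"], 0.6)
})

test_that("the Metropolis fallback reproduces the Gibbs posterior", {
  sim <- simulate_dive_table(balanced_cfg(150, 3), seed = 61)
  g <- fit_search_model(sim$dives, predictors = "duration_min",
                        n_iter = 3000, burn_in = 1000, n_chains = 1, seed = 2)
  m <- fit_search_model(sim$dives, predictors = "duration_min",
                        n_iter = 6000, burn_in = 2000, n_chains = 1, seed = 2,
                        method = "metropolis")
  gb <- g$summary$estimate[g$summary$term == "duration_min"]
  mb <- m$summary$estimate[m$summary$term == "duration_min"]
  expect_lt(abs(gb - mb),
            3 * sqrt(sum(g$summary$std.error[2]^2 + m$summary$std.error[2]^2) / 50))
})

test_that("tidiers and accessors expose the fit consistently", {
  sim <- simulate_dive_table(balanced_cfg(50, 3), seed = 62)
  fit <- fit_search_model(sim$dives, predictors = "duration_min",
                          n_iter = 400, burn_in = 100, n_chains = 2, seed = 1)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high",
                    "rhat") %in% names(td)))
  expect_true(all(td$conf.low < td$conf.high |
                    (td$conf.low == td$conf.high)))
  gl <- glance(fit)
  expect_equal(gl$n_draws, 2 * 300)
  expect_equal(gl$n_obs, 150)
  dr <- posterior_draws(fit)
  expect_equal(nrow(dr), 2 * 300 * length(fit$par_names))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("correlated-predictor screening keeps the earlier of a redundant pair", {
  withr::local_seed(63)
  n <- 200
  depth <- runif(n, -100, -5)
  d <- tibble::tibble(bathy = depth + rnorm(n, 0, 3),
                      max_depth = depth + rnorm(n, 0, 3),
                      odba = rnorm(n))
  kept <- drop_correlated(d, c("bathy", "max_depth", "odba"))
  expect_equal(as.character(kept), c("bathy", "odba"))
  expect_equal(attr(kept, "dropped"), "max_depth")
  # nothing dropped when all pairs are below the threshold
  ind <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  expect_equal(as.character(drop_correlated(ind, c("a", "b"))), c("a", "b"))
})
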