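test_that("asymptote prior matches its quantile anchors", {
  for (mass in c(0.95, 0.98)) {
    pr <- build_rho_prior(0.0078, 0.025, mass)
    a <- (1 - mass) / 2
    expect_equal(qlnorm(a, pr$meanlog, pr$sdlog), 0.0078, tolerance = 1e-6)
    expect_equal(qlnorm(1 - a, pr$meanlog, pr$sdlog), 0.025, tolerance = 1e-6)
    # sampled central mass within one percentage point of the target
    x <- withr::with_seed(1, rlnorm(2e5, pr$meanlog, pr$sdlog))
    expect_lt(abs(mean(x > 0.0078 & x < 0.025) - mass), 0.01)
  }
  # near-degenerate anchor pair still honoured
  pr <- build_rho_prior(0.01, 0.01 * 1.0000001, 0.95)
  expect_equal(qlnorm(0.025, pr$meanlog, pr$sdlog), 0.01, tolerance = 1e-6)
  expect_error(build_rho_prior(0.02, 0.01), class = "prior_construction_failure")
})

test_that("input validation rejects unusable series", {
  ser <- generate_incidence_series(incidence_config(), 28, seed = 1)
  expect_error(fit_growth_model(ser[1:5, ]), class = "invalid_argument")
  bad <- ser; bad$se[3] <- 0
  expect_error(fit_growth_model(bad), class = "invalid_argument")
  expect_error(mcmc_control(chains = 1), class = "invalid_argument")
})

test_that("posterior recovers generating parameters on a synthetic series", {
  cf <- cached_default_fit() # truth: rho 0.018, lam0 -1.54, lam1 0.0454
  d <- cf$fit$draws
  truth <- c(rho = 0.018, lam0 = -1.54, lam1 = 0.0454)
  for (v in names(truth)) {
    ci <- quantile(d[[v]], c(0.025, 0.975))
    expect_true(ci[1] <= truth[v] && truth[v] <= ci[2],
                label = sprintf("95%% CI for %s covers the truth", v))
  }
  # per-draw projections respect the asymptote and monotonicity
  expect_true(all(cf$fit$mu_proj < d$rho + 1e-15))
  expect_true(all(cf$fit$mu_proj > 0))
  up <- d$lam1 > 0
  expect_true(all(cf$fit$mu_proj[up, 43] >= cf$fit$mu_proj[up, 1]))
})

test_that("a flat series yields a flat fitted curve and flat projections", {
  # NB: lam1 itself is not identified here -- a saturated curve (mu ~ rho
  # with large lam1) explains a constant series as well as lam1 = 0 --
  # so the no-growth statement is about the fitted mean, not the slope
  flat <- data.frame(year = 1980:2007, rate = 0.006, se = 5e-5)
  f <- suppressWarnings(fit_growth_model(
    flat, control = mcmc_control(chains = 2, warmup = 2000, iter = 2000, seed = 9)))
  d <- f$draws
  mu_at <- function(t) d$rho / (1 + exp(-(d$lam0 + d$lam1 * t)))
  growth <- mu_at(28) - mu_at(1)
  expect_lt(abs(mean(growth)), 2e-4)
  expect_lt(abs(mean(mu_at(14)) - 0.006), 2e-4)
  # projections stay near the observed level instead of growing
  expect_lt(abs(mean(f$mu_proj[, "2050"]) - 0.006), 1e-3)
})

test_that("scenario extraction gives ordered low/middle/high bands", {
  cf <- cached_default_fit()
  sc <- extract_scenarios(cf$fit)
  expect_identical(sc$year, 2008:2050)
  expect_true(all(sc$low <= sc$middle & sc$middle <= sc$high))
  expect_true(all(sc$low > 0))

  # degenerate posterior: all draws identical
  deg <- cf$fit
  deg$mu_proj <- matrix(0.01, nrow = 300, ncol = 43)
  deg$draws <- deg$draws[rep(1, 300), ]
  expect_equal(unique(unlist(extract_scenarios(deg)[, c("low", "middle", "high")])),
               0.01)

  # normal-quantile closed form on an i.i.d. synthetic posterior
  fake <- cf$fit
  fake$mu_proj <- withr::with_seed(11, matrix(rnorm(50000 * 3, 0.01, 0.001),
                                              ncol = 3))
  fake$proj_years <- 2008:2010
  sc2 <- extract_scenarios(fake)
  expect_equal(sc2$low, rep(0.01 - 1.959964 * 0.001, 3), tolerance = 0.02)
  expect_equal(sc2$high, rep(0.01 + 1.959964 * 0.001, 3), tolerance = 0.02)

  few <- cf$fit
  few$draws <- few$draws[1:50, ]
  expect_error(extract_scenarios(few), class = "insufficient_posterior")
})

test_that("AR(1) residuals pass a posterior-predictive whiteness check", {
  mc <- cached_model_consistent_fit()
  f <- mc$fit
  ser <- mc$series
  # magnitude: fitted residuals stay within surveillance noise scale
  expect_lt(max(abs(f$residuals$mean)), 1e-3)

  n <- nrow(ser)
  idx <- round(seq(1, nrow(f$draws), length.out = 200))
  exceed <- withr::with_seed(99, vapply(idx, function(j) {
    d <- f$draws[j, ]
    mu <- d$rho / (1 + exp(-(d$lam0 + d$lam1 * (1:n))))
    S <- diabproj:::error_cov("ar1", n, d$sigma, d$phi)
    diag(S) <- diag(S) + ser$se^2
    ch <- chol(S)
    w_obs <- backsolve(ch, ser$rate - mu, transpose = TRUE)
    eps <- numeric(n)
    eps[1] <- rnorm(1, 0, d$sigma / sqrt(1 - d$phi^2))
    for (k in 2:n) eps[k] <- d$phi * eps[k - 1] + rnorm(1, 0, d$sigma)
    yrep <- mu + eps + rnorm(n, 0, ser$se)
    w_rep <- backsolve(ch, yrep - mu, transpose = TRUE)
    cor(w_rep[-1], w_rep[-n]) > cor(w_obs[-1], w_obs[-n])
  }, logical(1)))
  # no left-over lag-1 serial correlation at the Monte-Carlo threshold
  expect_gt(mean(exceed), 0.025)
})

test_that("sampler agrees with an independent MCMC engine", {
  # white-noise fixture, unstructured errors: both engines converge
  # cleanly, so posterior means must match within sampling error
  ser <- generate_incidence_series(incidence_config(phi = 0, sigma = 2e-4),
                                   28, seed = 7)
  pr <- build_rho_prior()
  f <- suppressWarnings(fit_growth_model(
    ser, pr, "unstructured",
    mcmc_control(chains = 2, warmup = 3000, iter = 3000, seed = 7)))

  mdl <- "model {
    for (t in 1:T) {
      y[t] ~ dnorm(g[t], 1/(s[t]*s[t]))
      g[t] <- mu[t] + eps[t]
      eps[t] ~ dnorm(0, tau)
      mu[t] <- rho/(1+exp(-(lam0+lam1*t)))
    }
    sigma ~ dnorm(0, 1/(0.01*0.01)) T(0,)
    tau <- pow(sigma,-2)
    rho ~ dlnorm(ml, 1/(sl*sl))
    lam0 ~ dnorm(0, 1.0E-4)
    lam1 ~ dnorm(0, 1.0E-4)
  }"
  jm <- rjags::jags.model(
    textConnection(mdl),
    data = list(y = ser$rate, s = ser$se, T = 28,
                ml = pr$meanlog, sl = pr$sdlog),
    inits = list(
      list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 1,
           rho = 0.012, lam0 = -1.5, lam1 = 0.05),
      list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 2,
           rho = 0.015, lam0 = -1.0, lam1 = 0.04)),
    n.chains = 2, n.adapt = 1000, quiet = TRUE)
  update(jm, 3000, progress.bar = "none")
  sm <- coda::as.mcmc(do.call(rbind, rjags::coda.samples(
    jm, c("rho", "lam0", "lam1"), n.iter = 6000, progress.bar = "none")))

  for (v in c("rho", "lam0", "lam1")) {
    expect_lt(abs(mean(f$draws[[v]]) - mean(sm[, v])) / sd(sm[, v]), 0.5,
              label = sprintf("posterior mean of %s matches rjags", v))
  }
})

test_that("error-structure comparison prefers parsimony when ties occur", {
  ctrl <- mcmc_control(warmup = 3000, iter = 3000, seed = 11)
  ser <- generate_incidence_series(incidence_config(phi = 0.7, sigma = 3e-4),
                                   28, seed = 11)
  tab <- suppressWarnings(compare_error_structures(ser, control = ctrl))
  expect_identical(tab$structure, c("unstructured", "ar1", "ma1", "arma11"))
  expect_false(any(tab$failed))
  # serially correlated data: AR(1) beats the unstructured fit
  expect_lte(tab$resid_ss[tab$structure == "ar1"],
             tab$resid_ss[tab$structure == "unstructured"])
  expect_identical(sum(tab$selected), 1L)

  # white noise: the four structures are near-indistinguishable and the
  # most parsimonious wins
  ser0 <- generate_incidence_series(incidence_config(phi = 0, sigma = 2e-4),
                                    28, seed = 12)
  tab0 <- suppressWarnings(compare_error_structures(ser0, control = ctrl))
  ss <- tab0$resid_ss
  expect_lt(diff(range(ss)) / min(ss), 0.10)
  expect_identical(tab0$structure[tab0$selected], "unstructured")
})
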