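#' Log-normal prior for the incidence asymptote
#'
#' Constructs the informative prior for the logistic asymptote `rho` as the
#' log-normal distribution placing a stated central probability mass
#' between two quantile anchors (e.g. 95% between the 2007 US diagnosed
#' incidence 0.0078 and the Pima Indian rate 0.025). Log-normality gives
#' positive support with the two free parameters exactly determined by the
#' two anchors.
#'
#' @param q_low,q_high lower and upper quantile anchors (rates, `0 < q_low
#'   < q_high < 1`).
#' @param mass central prior probability between the anchors.
#' @return list of class `rho_prior` with `meanlog`, `sdlog` and the inputs.
#' @export
#' @examples
#' pr <- build_rho_prior(0.0078, 0.025, 0.95)
#' qlnorm(c(0.025, 0.975), pr$meanlog, pr$sdlog)
build_rho_prior <- function(q_low = 0.0078, q_high = 0.025, mass = 0.95) {
  if (!(q_low > 0 && q_high > q_low && q_high < 1)) {
    stop_diabproj("prior_construction_failure", "need 0 < q_low < q_high < 1")
  }
  if (!(mass > 0 && mass < 1)) {
    stop_diabproj("prior_construction_failure", "mass must be in (0, 1)")
  }
  z <- qnorm(1 - (1 - mass) / 2)
  structure(list(
    meanlog = (log(q_low) + log(q_high)) / 2,
    sdlog = (log(q_high) - log(q_low)) / (2 * z),
    q_low = q_low, q_high = q_high, mass = mass
  ), class = "rho_prior")
}

#' MCMC control settings
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param warmup adaptation/burn-in iterations per chain (discarded).
#' @param iter retained iterations per chain.
#' @param seed integer seed; all chain seeds derive from it.
#' @param rhat_max convergence threshold on the split potential scale
#'   reduction factor.
#' @param lam_prior_sd standard deviation of the diffuse normal priors on
#'   the logistic coefficients `lam0`, `lam1`.
#' @param sigma_prior_scale scale of the half-normal prior on the
#'   innovation standard deviation (rate units).
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, warmup = 10000, iter = 10000,
                         seed = 20100929L, rhat_max = 1.01,
                         lam_prior_sd = 100, sigma_prior_scale = 0.01) {
  if (chains < 2) stop_diabproj("invalid_argument", "need >= 2 chains")
  structure(list(chains = chains, warmup = warmup, iter = iter,
                 seed = as.integer(seed) %% .Machine$integer.max,
                 rhat_max = rhat_max, lam_prior_sd = lam_prior_sd,
                 sigma_prior_scale = sigma_prior_scale),
            class = "mcmc_control")
}

# stationary autocovariance matrix of the error process (n x n)
error_cov <- function(structure, n, sigma, phi = 0, psi = 0) {
  lag <- abs(outer(seq_len(n), seq_len(n), "-"))
  switch(structure,
    unstructured = diag(sigma^2, n),
    ar1 = sigma^2 / (1 - phi^2) * phi^lag,
    ma1 = {
      g <- matrix(0, n, n)
      g[lag == 0] <- sigma^2 * (1 + psi^2)
      g[lag == 1] <- sigma^2 * psi
      g
    },
    arma11 = {
      g1 <- sigma^2 * (1 + phi * psi) * (phi + psi) / (1 - phi^2)
      g <- g1 * phi^(lag - 1)
      diag(g) <- sigma^2 * (1 + 2 * phi * psi + psi^2) / (1 - phi^2)
      g
    },
    stop_diabproj("invalid_argument", "unknown error structure '%s'", structure)
  )
}

# Sampling-coordinate layouts per error structure. The growth curve is
# parameterized by (log rho, log mu(1), log mu(n)) rather than
# (log rho, lam0, lam1): the two endpoint means are pinned by the data
# and nearly independent of the prior-identified asymptote, which removes
# the banana-shaped ridge the natural parameterization exhibits. Error
# parameters are atanh(phi)/atanh(psi) and log sigma.
par_layout <- function(structure) {
  switch(structure,
    unstructured = c("lrho", "lmu1", "lmun", "lsigma"),
    ar1 = c("lrho", "lmu1", "lmun", "aphi", "lsigma"),
    ma1 = c("lrho", "lmu1", "lmun", "apsi", "lsigma"),
    arma11 = c("lrho", "lmu1", "lmun", "aphi", "apsi", "lsigma"))
}

# map a sampling-coordinate vector to the natural parameters; returns NULL
# when the endpoint means are not strictly below the asymptote
natural_params <- function(nm, par, span) {
  rho <- exp(par[nm == "lrho"])
  m1 <- exp(par[nm == "lmu1"])
  mn <- exp(par[nm == "lmun"])
  if (m1 >= rho || mn >= rho) return(NULL)
  g1 <- log(m1 / (rho - m1))
  gn <- log(mn / (rho - mn))
  lam1 <- (gn - g1) / span
  list(rho = rho, lam0 = g1 - lam1, lam1 = lam1,
       phi = if ("aphi" %in% nm) tanh(par[nm == "aphi"]) else 0,
       psi = if ("apsi" %in% nm) tanh(par[nm == "apsi"]) else 0,
       sigma = exp(par[nm == "lsigma"]))
}

# log posterior on the sampling scale (error process integrated out:
# y ~ MVN(mu(rho, lam0, lam1), Sigma_err + diag(s^2)))
make_logpost <- function(y, s, t, structure, prior, control) {
  nm <- par_layout(structure)
  n <- length(y)
  span <- n - 1
  D <- s^2
  force(prior); force(control)
  function(par) {
    p <- natural_params(nm, par, span)
    if (is.null(p)) return(-Inf)
    mu <- logistic_rate(t, p$rho, p$lam0, p$lam1)
    Sig <- error_cov(structure, n, p$sigma, p$phi, p$psi)
    diag(Sig) <- diag(Sig) + D
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    r <- y - mu
    ll <- -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, r, transpose = TRUE)^2)
    rho <- p$rho
    lp <- dnorm(par[nm == "lrho"], prior$meanlog, prior$sdlog, log = TRUE) +
      dnorm(p$lam0, 0, control$lam_prior_sd, log = TRUE) +
      dnorm(p$lam1, 0, control$lam_prior_sd, log = TRUE) +
      # Jacobian of (lam0, lam1) wrt (log mu(1), log mu(n)) at fixed rho:
      # |det| = [rho/(rho - mu1)] * [rho/(rho - mun)] / span
      log(rho / (rho - exp(par[nm == "lmu1"]))) +
      log(rho / (rho - exp(par[nm == "lmun"]))) - log(span) +
      # half-normal on sigma, plus log-scale jacobian
      dnorm(p$sigma, 0, control$sigma_prior_scale, log = TRUE) + log(p$sigma)
    # uniform(-1,1) priors on phi/psi via tanh: jacobian log(1 - x^2)
    if ("aphi" %in% nm) lp <- lp + log1p(-p$phi^2)
    if ("apsi" %in% nm) lp <- lp + log1p(-p$psi^2)
    ll + lp
  }
}

# adaptive Metropolis warmup, one chain. The random-walk proposal
# covariance is adapted to the chain history (Haario-style) and the global
# scale tuned toward the multivariate optimum acceptance rate ~0.234
# (Robbins-Monro on the log scale); both are frozen for sampling.
amh_warmup <- function(logpost, init, warmup, seed) {
  d <- length(init)
  withr::with_seed(seed, {
    cur <- init
    curlp <- logpost(cur)
    if (!is.finite(curlp)) stop_diabproj("invalid_argument", "init has zero posterior density")
    S <- diag(d) * 0.01
    scale <- 2.38 / sqrt(d)
    hist <- matrix(NA_real_, warmup, d)
    batch_acc <- 0L
    n_batch <- 0L
    R <- chol(S + 1e-12 * diag(d))
    for (i in seq_len(warmup)) {
      prop <- cur + drop(rnorm(d) %*% R) * scale
      plp <- logpost(prop)
      if (is.finite(plp) && log(runif(1)) < plp - curlp) {
        cur <- prop; curlp <- plp; batch_acc <- batch_acc + 1L
      }
      hist[i, ] <- cur
      if (i %% 100 == 0) {
        n_batch <- n_batch + 1L
        scale <- scale * exp((batch_acc / 100 - 0.234) / sqrt(n_batch))
        batch_acc <- 0L
        if (i >= 400) {
          S <- var(hist[max(1, i - 3000):i, , drop = FALSE])
          R <- chol(S + 1e-12 * diag(d))
        }
      }
    }
    list(cur = cur, curlp = curlp, R = R, scale = scale,
         hist = hist[max(1, warmup - 3000):warmup, , drop = FALSE])
  })
}

# sampling phase: frozen random-walk kernel mixed with an independence
# proposal (20% of moves, standard MH correction) from a multivariate t
# (df = 4) fitted to the pooled warmup histories of all chains. The
# shared, heavy-tailed independence kernel lets a chain regenerate after
# excursions into the near-unit-root tail of the AR coefficient, and lets
# a chain that warmed up in a minority mode jump to the dominant mode in
# proportion to posterior mass.
amh_sample <- function(logpost, ws, iter, seed, ind) {
  d <- length(ws$cur)
  df <- 4
  withr::with_seed(seed, {
    cur <- ws$cur
    curlp <- ws$curlp
    draws <- matrix(NA_real_, iter, d)
    lps <- numeric(iter)
    acc <- 0L
    q_ind <- function(x) {
      # multivariate-t log density (additive constants dropped)
      z2 <- sum(backsolve(ind$R, x - ind$m, transpose = TRUE)^2)
      -ind$ldet - 0.5 * (df + d) * log1p(z2 / df)
    }
    for (i in seq_len(iter)) {
      if (runif(1) < 0.2) {
        u <- sqrt(df / stats::rchisq(1, df))
        prop <- ind$m + drop(rnorm(d) %*% ind$R) * u
        plp <- logpost(prop)
        lratio <- plp - curlp + q_ind(cur) - q_ind(prop)
      } else {
        prop <- cur + drop(rnorm(d) %*% ws$R) * ws$scale
        plp <- logpost(prop)
        lratio <- plp - curlp
      }
      if (is.finite(plp) && log(runif(1)) < lratio) {
        cur <- prop; curlp <- plp; acc <- acc + 1L
      }
      draws[i, ] <- cur
      lps[i] <- curlp
    }
    list(draws = draws, lp = lps, accept = acc / iter)
  })
}

# overdispersed starting points, one per chain; endpoint means start near
# the observed endpoints, the asymptote above both
growth_inits <- function(structure, prior, chains, seed, y) {
  nm <- par_layout(structure)
  n <- length(y)
  y1 <- max(y[1], 1e-5)
  yn <- max(y[n], 2e-5)
  withr::with_seed(seed, {
    lapply(seq_len(chains), function(k) {
      m1 <- y1 * exp(rnorm(1, 0, 0.1))
      mn <- yn * exp(rnorm(1, 0, 0.1))
      rho <- max(exp(rnorm(1, prior$meanlog, prior$sdlog / 2)),
                 1.2 * max(m1, mn))
      init <- c(log(rho), log(m1), log(mn))
      if ("aphi" %in% nm) init <- c(init, atanh(runif(1, -0.3, 0.8)))
      if ("apsi" %in% nm) init <- c(init, atanh(runif(1, -0.3, 0.5)))
      c(init, log(runif(1, 5e-5, 1e-3)))
    })
  })
}

#' Fit the Bayesian logistic growth model to an incidence series
#'
#' Fits `y_t ~ Normal(mu_t + eps_t, s_t^2)` with logistic mean
#' `mu_t = rho / (1 + exp(-(lam0 + lam1 t)))` (t = 1 in the first observed
#' year), a log-normal prior on the asymptote `rho` from
#' [build_rho_prior()], diffuse normal priors on `lam0`, `lam1`, and a
#' stationary error process `eps_t` chosen by `error_structure`. The error
#' process and observation noise are integrated out analytically, so the
#' sampler works on the 4-6 dimensional marginal posterior (adaptive
#' random-walk Metropolis, several chains). Projections `mu_t` for the
#' requested future years are simulated per retained draw.
#'
#' Convergence is assessed with the potential scale reduction factor
#' across chains; exceeding `control$rhat_max` raises a
#' `convergence_warning` (with diagnostics attached to the result), never
#' a silent success.
#'
#' @param series data.frame with columns `year`, `rate`, `se` (>= 10 rows).
#' @param prior a [build_rho_prior()] object.
#' @param error_structure one of `"ar1"` (default), `"unstructured"`,
#'   `"ma1"`, `"arma11"`.
#' @param control a [mcmc_control()].
#' @param project_years calendar years to project (default 2008-2050).
#' @return object of class `growth_posterior`: `draws` (data.frame of
#'   `rho`, `lam0`, `lam1`, `phi`, `psi`, `sigma`), `mu_proj` (draws x
#'   years matrix of projected rates), `proj_years`, `diagnostics` (Rhat,
#'   effective sizes, acceptance rates, `converged`), `residuals`
#'   (posterior-mean fitted residuals and per-draw residual sums of
#'   squares), plus the inputs.
#' @export
fit_growth_model <- function(series, prior = build_rho_prior(),
                             error_structure = c("ar1", "unstructured", "ma1", "arma11"),
                             control = mcmc_control(),
                             project_years = 2008:2050) {
  error_structure <- match.arg(error_structure)
  if (nrow(series) < 10) stop_diabproj("invalid_argument", "need >= 10 observations")
  if (any(!is.finite(series$se) | series$se <= 0)) {
    stop_diabproj("invalid_argument", "standard errors must be positive and finite")
  }
  t_obs <- seq_len(nrow(series))
  lp <- make_logpost(series$rate, series$se, t_obs, error_structure, prior, control)
  inits <- growth_inits(error_structure, prior, control$chains, control$seed,
                        series$rate)
  warm <- lapply(seq_len(control$chains), function(k) {
    amh_warmup(lp, inits[[k]], control$warmup,
               seed = (control$seed + 7919L * k) %% .Machine$integer.max)
  })
  pooled <- do.call(rbind, lapply(warm, `[[`, "hist"))
  d <- ncol(pooled)
  # independence kernel: pooled-warmup Gaussian, inflated 2x in covariance
  R_ind <- chol(2 * var(pooled) + 1e-12 * diag(d))
  ind <- list(m = colMeans(pooled), R = R_ind, ldet = sum(log(diag(R_ind))))
  chains <- lapply(seq_len(control$chains), function(k) {
    amh_sample(lp, warm[[k]], control$iter,
               seed = (control$seed + 104729L * k) %% .Machine$integer.max,
               ind = ind)
  })

  nm <- par_layout(error_structure)
  all_draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  span <- nrow(series) - 1
  rho <- exp(all_draws[, nm == "lrho"])
  m1 <- exp(all_draws[, nm == "lmu1"])
  mn <- exp(all_draws[, nm == "lmun"])
  g1 <- log(m1 / (rho - m1))
  gn <- log(mn / (rho - mn))
  lam1 <- (gn - g1) / span
  draws <- data.frame(
    rho = rho,
    lam0 = g1 - lam1,
    lam1 = lam1,
    phi = if ("aphi" %in% nm) tanh(all_draws[, nm == "aphi"]) else NA_real_,
    psi = if ("apsi" %in% nm) tanh(all_draws[, nm == "apsi"]) else NA_real_,
    sigma = exp(all_draws[, nm == "lsigma"])
  )

  par_cols <- c("rho", "lam0", "lam1",
                if ("aphi" %in% nm) "phi", if ("apsi" %in% nm) "psi", "sigma")
  per_chain <- split_chains(as.matrix(draws[, par_cols]), control$chains)
  rhat <- rank_rhat(per_chain)
  ess <- tryCatch(
    coda::effectiveSize(coda::mcmc.list(lapply(per_chain, coda::mcmc))),
    error = function(e) setNames(rep(NA_real_, length(par_cols)), par_cols))
  names(rhat) <- names(ess) <- par_cols

  t_proj <- project_years - series$year[1] + 1
  mu_proj <- sapply(t_proj, function(tt) {
    logistic_rate(tt, draws$rho, draws$lam0, draws$lam1)
  })
  colnames(mu_proj) <- project_years

  resid <- growth_residuals(series, draws, error_structure,
                            max_draws = min(nrow(draws), 1000))

  converged <- all(is.finite(rhat)) && max(rhat) <= control$rhat_max
  out <- structure(list(
    draws = draws, mu_proj = mu_proj, proj_years = project_years,
    diagnostics = list(rhat = rhat, ess = ess,
                       accept = vapply(chains, `[[`, numeric(1), "accept"),
                       converged = converged),
    residuals = resid,
    series = series, error_structure = error_structure,
    prior = prior, control = control
  ), class = "growth_posterior")
  if (!converged) {
    warn_diabproj("convergence_warning",
                  "max Rhat %.3f exceeds %.3f; inspect $diagnostics",
                  max(rhat), control$rhat_max)
  }
  out
}

split_chains <- function(mat, chains) {
  n <- nrow(mat) / chains
  lapply(seq_len(chains), function(k) mat[((k - 1) * n + 1):(k * n), , drop = FALSE])
}

# rank-normalized split-Rhat (Vehtari et al. 2021): robust to heavy tails
# and non-normal margins, the current standard convergence diagnostic
rank_rhat <- function(mat_list) {
  half <- floor(nrow(mat_list[[1]]) / 2)
  halves <- unlist(lapply(mat_list, function(m) {
    list(m[seq_len(half), , drop = FALSE],
         m[(half + 1):(2 * half), , drop = FALSE])
  }), recursive = FALSE)
  vapply(seq_len(ncol(mat_list[[1]])), function(j) {
    x <- vapply(halves, function(m) m[, j], numeric(half))
    z <- qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4))
    dim(z) <- dim(x)
    W <- mean(apply(z, 2, var))
    B <- half * var(colMeans(z))
    sqrt((half - 1) / half + B / (W * half))
  }, numeric(1))
}

# fitted residuals y - (mu + E[eps | y, params]) per (thinned) draw
growth_residuals <- function(series, draws, structure, max_draws = 1000) {
  n <- nrow(series)
  t_obs <- seq_len(n)
  D <- diag(series$se^2, n)
  idx <- unique(round(seq(1, nrow(draws), length.out = max_draws)))
  ss <- numeric(length(idx))
  rsum <- numeric(n)
  for (j in seq_along(idx)) {
    d <- draws[idx[j], ]
    mu <- logistic_rate(t_obs, d$rho, d$lam0, d$lam1)
    Se <- error_cov(structure, n, d$sigma,
                    if (is.na(d$phi)) 0 else d$phi,
                    if (is.na(d$psi)) 0 else d$psi)
    eps_hat <- Se %*% solve(Se + D, series$rate - mu)
    r <- series$rate - mu - drop(eps_hat)
    ss[j] <- sum(r^2)
    rsum <- rsum + r
  }
  list(mean = rsum / length(idx), ss_draws = ss)
}

#' Compare error structures for the growth model
#'
#' Fits all four error structures (unstructured, AR(1), MA(1), ARMA(1,1))
#' to the same series and reports the posterior mean residual sum of
#' squares of each. Among structures whose residual SS is within 5% of the
#' best, the one with fewest parameters is selected, so AR(1) is preferred
#' over ARMA(1,1) when the two are indistinguishable.
#'
#' @inheritParams fit_growth_model
#' @return data.frame with one row per structure: `structure`, `n_params`,
#'   `resid_ss` (posterior mean), `max_rhat`, `failed`, `selected`. Fits
#'   are attached as attribute `"fits"`.
#' @export
compare_error_structures <- function(series, prior = build_rho_prior(),
                                     control = mcmc_control()) {
  structs <- c("unstructured", "ar1", "ma1", "arma11")
  fits <- lapply(structs, function(st) {
    tryCatch(suppressWarnings(
      fit_growth_model(series, prior, st, control)
    ), error = function(e) e)
  })
  names(fits) <- structs
  ok <- !vapply(fits, inherits, logical(1), "error")
  tab <- data.frame(
    structure = structs,
    n_params = vapply(structs, function(st) length(par_layout(st)), numeric(1)),
    resid_ss = vapply(seq_along(structs), function(i) {
      if (ok[i]) mean(fits[[i]]$residuals$ss_draws) else NA_real_
    }, numeric(1)),
    max_rhat = vapply(seq_along(structs), function(i) {
      if (ok[i]) max(fits[[i]]$diagnostics$rhat) else NA_real_
    }, numeric(1)),
    failed = !ok
  )
  best <- min(tab$resid_ss, na.rm = TRUE)
  cand <- which(!tab$failed & tab$resid_ss <= 1.05 * best)
  sel <- cand[which.min(tab$n_params[cand])]
  tab$selected <- seq_len(nrow(tab)) == sel
  attr(tab, "fits") <- fits
  tab
}

#' Extract low/middle/high incidence scenarios from the posterior
#'
#' Per projected year, the low scenario is the pointwise 2.5th percentile
#' of the projected-rate draws, the middle scenario the posterior mean,
#' and the high scenario the 97.5th percentile.
#'
#' @param post a `growth_posterior` from [fit_growth_model()].
#' @return data.frame with columns `year`, `low`, `middle`, `high`
#'   (`low <= middle <= high` pointwise).
#' @export
extract_scenarios <- function(post) {
  if (nrow(post$draws) < 200) {
    stop_diabproj("insufficient_posterior", "need >= 200 retained draws")
  }
  qs <- apply(post$mu_proj, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(year = post$proj_years,
             low = qs[1, ],
             middle = colMeans(post$mu_proj),
             high = qs[2, ])
}

#' Single-scenario incidence series
#'
#' Convenience accessor returning one labelled scenario as `(year, rate)`,
#' the shape the state models consume.
#'
#' @param scenarios data.frame from [extract_scenarios()] (or any frame
#'   with `year` plus scenario columns).
#' @param label one of `"low"`, `"middle"`, `"high"`.
#' @return data.frame with columns `year`, `rate`.
#' @export
scenario_series <- function(scenarios, label = c("middle", "low", "high")) {
  label <- match.arg(label)
  data.frame(year = scenarios$year, rate = scenarios[[label]])
}
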