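# Shared fixtures, built in code. MCMC fits are cached per session so
# several test files can reuse the same posterior.

.fit_cache <- new.env(parent = emptyenv())

# default US-like synthetic series and an AR(1) fit at moderate settings
cached_default_fit <- function() {
  if (is.null(.fit_cache$default)) {
    ser <- generate_incidence_series(incidence_config(), 28, seed = 3)
    .fit_cache$default <- list(
      series = ser,
      fit = suppressWarnings(fit_growth_model(
        ser, control = mcmc_control(warmup = 4000, iter = 4000, seed = 3))))
  }
  .fit_cache$default
}

# series drawn from the fitted model's own observation process
# (logistic trend + AR(1) process error + N(0, se^2) measurement error)
cached_model_consistent_fit <- function() {
  if (is.null(.fit_cache$modelcons)) {
    ser <- generate_incidence_series(incidence_config(), 28, seed = 4)
    ser$rate <- ser$rate + withr::with_seed(1004, stats::rnorm(28, 0, ser$se))
    .fit_cache$modelcons <- list(
      series = ser,
      fit = suppressWarnings(fit_growth_model(
        ser, control = mcmc_control(warmup = 4000, iter = 4000, seed = 4))))
  }
  .fit_cache$modelcons
}

# standard state-model inputs: US-like census, base-year state, default
# calibration, and the generator's noise-free incidence curve as a
# deterministic diagnosed-incidence scenario
us_fixture <- function() {
  if (is.null(.fit_cache$us)) {
    census <- generate_census(2007, 2050)
    state0 <- generate_initial_state(census$N[1], 0.0535, 0.0765)
    calib <- calibrate(calibration_config(), state0)
    cfg <- incidence_config()
    t <- (2008:2050) - cfg$start_year + 1
    curve <- cfg$rho / (1 + exp(-(cfg$lam0 + cfg$lam1 * t)))
    .fit_cache$us <- list(
      census = census, state0 = state0, calib = calib,
      scenario = data.frame(year = 2008:2050, rate = curve))
  }
  .fit_cache$us
}

# tiny closed-population census for arithmetic-level checks
toy_census <- function(years = 2007:2012, n0 = 1000, d = 0, b = 0, m = 0) {
  generate_census(years[1], years[length(years)], n0,
                  profile = list(d = d, b = b, m = m))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}
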