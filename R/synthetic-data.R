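#' US-like demographic growth profile
#'
#' Default profile for [generate_census()]: adult population anchors rising
#' from about 215.75M (2007) to 306.3M (2050), interpolated with a monotone
#' (Hyman) cubic spline; an annual death rate declining linearly from
#' `d_first` to `d_last`; and a constant net adult in-migration. Cohorts
#' "turning 18" each year (the model's births) are derived so the census
#' recursion `N(t) = N(t-1)(1 - d(t)) + b(t) + m(t)` holds exactly.
#'
#' @param d_first,d_last annual death rate in the first/last projected year.
#' @param migration net adult migrants per year (persons; may be negative).
#' @return a list with elements `anchors` (data.frame `year`, `N`),
#'   `d_first`, `d_last`, `migration`, usable as the `profile` argument of
#'   [generate_census()].
#' @export
census_profile_us <- function(d_first = 0.0090, d_last = 0.0078,
                              migration = 1.0e6) {
  list(
    anchors = data.frame(
      year = c(2007, seq(2010, 2050, by = 5)),
      N = c(215750418, 1e6 * c(223.7, 235.9, 247.5, 258.5, 267.9,
                               276.9, 285.5, 292.9, 306.3))
    ),
    d_first = d_first, d_last = d_last, migration = migration
  )
}

#' Generate a synthetic demographic projection
#'
#' Builds an annual demographic projection `(year, N, b, m, d)` satisfying
#' the census-consistency recursion `N(t) = N(t-1)(1 - d(t)) + b(t) + m(t)`
#' exactly for every year after the first. Two profile modes are supported:
#'
#' * **anchor mode** (`profile$anchors` present, e.g. [census_profile_us()]):
#'   the population path is a monotone cubic spline through the anchors
#'   (rescaled so the first year equals `n0` when given), death rates vary
#'   linearly from `d_first` to `d_last`, migration is `profile$migration`,
#'   and births `b(t)` are back-derived from the recursion;
#' * **explicit mode** (`profile` has `d`, `b`, `m`, scalars or per-year
#'   vectors): the population is computed by forward recursion from `n0`.
#'
#' @param start_year,end_year first and last calendar year (inclusive).
#' @param n0 population in `start_year`; defaults to the anchor value.
#' @param profile growth profile; see Details.
#' @return data.frame with columns `year`, `N`, `b`, `m`, `d` (`b`, `m`, `d`
#'   are `NA` in the first year, which is the initial stock).
#' @export
#' @examples
#' generate_census(2007, 2009, 1000, list(d = 0, b = 0, m = 0))
#' cen <- generate_census(2007, 2050)
#' range(cen$N) / 1e6
generate_census <- function(start_year, end_year, n0 = NULL,
                            profile = census_profile_us()) {
  if (!is.numeric(start_year) || !is.numeric(end_year) ||
      end_year <= start_year || start_year != floor(start_year)) {
    stop_diabproj("invalid_argument", "need integer years with end_year > start_year")
  }
  years <- start_year:end_year
  ny <- length(years)

  if (!is.null(profile$anchors)) {
    a <- profile$anchors
    fn <- splinefun(a$year, a$N, method = "hyman")
    N <- fn(years)
    if (!is.null(n0)) N <- N * (n0 / N[1])
    d <- c(NA, seq(profile$d_first, profile$d_last, length.out = ny - 1))
    check_prob(d[-1], "death rate", open_upper = TRUE)
    m <- c(NA, rep_len(profile$migration, ny - 1))
    b <- c(NA, N[-1] - N[-ny] * (1 - d[-1]) - m[-1])
    if (any(b[-1] < 0)) {
      stop_diabproj("infeasible_profile",
                    "profile implies negative births in year(s) %s",
                    paste(years[-1][b[-1] < 0], collapse = ", "))
    }
  } else {
    if (is.null(n0) || n0 <= 0) {
      stop_diabproj("invalid_argument", "explicit profiles need n0 > 0")
    }
    d <- c(NA, rep_len(profile$d, ny - 1))
    b <- c(NA, rep_len(profile$b, ny - 1))
    m <- c(NA, rep_len(profile$m, ny - 1))
    check_prob(d[-1], "death rate", open_upper = TRUE)
    if (any(b[-1] < 0)) stop_diabproj("invalid_argument", "births must be >= 0")
    N <- numeric(ny)
    N[1] <- n0
    for (k in 2:ny) {
      N[k] <- N[k - 1] * (1 - d[k]) + b[k] + m[k]
      if (N[k] <= 0) {
        stop_diabproj("infeasible_profile",
                      "profile implies nonpositive population in %d", years[k])
      }
    }
  }
  data.frame(year = years, N = N, b = b, m = m, d = d)
}

#' Synthetic incidence-series configuration
#'
#' Parameters of the generative model for an annual diagnosed-diabetes
#' incidence series: a logistic trend `rho / (1 + exp(-(lam0 + lam1 * t)))`
#' (t = 1 in the first year) plus a stationary AR(1) deviation with
#' coefficient `phi` and innovation standard deviation `sigma`. Reported
#' standard errors are `se_scale * sqrt(trend)` with mild lognormal jitter,
#' emulating surveillance standard errors that scale with the rate.
#'
#' Defaults emulate the US diagnosed-incidence series: the noise-free curve
#' passes through 3.3 per 1,000 in 1980 and 7.8 per 1,000 in 2007 and rises
#' toward 14.7 per 1,000 by 2050 with asymptote 18 per 1,000.
#'
#' @param rho asymptote of the logistic trend (rate, per person-year).
#' @param lam0,lam1 logistic location and slope (`lam1 > 0` gives growth).
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @param sigma AR(1) innovation standard deviation (rate units).
#' @param se_scale standard-error multiplier (`se = se_scale * sqrt(rate)`).
#' @param start_year calendar year of t = 1.
#' @return a list of class `incidence_config`.
#' @export
incidence_config <- function(rho = 0.018, lam0 = -1.54, lam1 = 0.0454,
                             phi = 0.6, sigma = 2e-4, se_scale = 0.0042,
                             start_year = 1980) {
  if (rho <= 0 || rho >= 1) stop_diabproj("invalid_argument", "need 0 < rho < 1")
  if (sigma < 0) stop_diabproj("invalid_argument", "need sigma >= 0")
  if (se_scale <= 0) stop_diabproj("invalid_argument", "need se_scale > 0")
  if (abs(phi) >= 1) stop_diabproj("nonstationary_error", "need |phi| < 1")
  structure(list(rho = rho, lam0 = lam0, lam1 = lam1, phi = phi,
                 sigma = sigma, se_scale = se_scale, start_year = start_year),
            class = "incidence_config")
}

logistic_rate <- function(t, rho, lam0, lam1) rho / (1 + exp(-(lam0 + lam1 * t)))

#' Generate a synthetic annual incidence series
#'
#' Draws `y_t = rho/(1 + exp(-(lam0 + lam1 t))) + eps_t` with `eps_t` a
#' stationary AR(1) process, plus per-year standard errors. With
#' `sigma = 0` the series is exactly the logistic curve. Identical
#' `cfg` + `seed` give bitwise-identical output; the global RNG state is
#' left untouched.
#'
#' @param cfg an [incidence_config()].
#' @param n_years number of annual observations (>= 3).
#' @param seed integer random seed (explicit, never global state).
#' @return data.frame with columns `year`, `rate`, `se`.
#' @export
#' @examples
#' head(generate_incidence_series(incidence_config(), 28, seed = 1))
generate_incidence_series <- function(cfg, n_years, seed = 1L) {
  stopifnot(inherits(cfg, "incidence_config"))
  if (n_years < 3) stop_diabproj("invalid_argument", "need n_years >= 3")
  t <- seq_len(n_years)
  mu <- logistic_rate(t, cfg$rho, cfg$lam0, cfg$lam1)
  withr::with_seed(seed, {
    eps <- numeric(n_years)
    if (cfg$sigma > 0) {
      eps[1] <- rnorm(1, 0, cfg$sigma / sqrt(1 - cfg$phi^2))
      for (k in seq_len(n_years)[-1]) {
        eps[k] <- cfg$phi * eps[k - 1] + rnorm(1, 0, cfg$sigma)
      }
    }
    se <- cfg$se_scale * sqrt(mu) * exp(rnorm(n_years, 0, 0.05))
  })
  data.frame(year = cfg$start_year - 1 + t, rate = mu + eps, se = se)
}

#' Split a population into initial disease-state counts
#'
#' @param N0 total adult population (persons).
#' @param theta1 prevalence of undiagnosed diabetes (proportion).
#' @param theta2 prevalence of diagnosed diabetes (proportion).
#' @return named numeric vector `c(X =, Z =, Y =)` (no diabetes,
#'   undiagnosed, diagnosed) summing exactly to `N0`.
#' @export
#' @examples
#' generate_initial_state(1000, 0.05, 0.09)
generate_initial_state <- function(N0, theta1, theta2) {
  if (N0 <= 0) stop_diabproj("invalid_argument", "need N0 > 0")
  if (theta1 < 0 || theta2 < 0 || theta1 + theta2 >= 1) {
    stop_diabproj("invalid_argument",
                  "prevalences must be >= 0 with theta1 + theta2 < 1")
  }
  Z <- theta1 * N0
  Y <- theta2 * N0
  c(X = N0 - Z - Y, Z = Z, Y = Y)
}

#' Validate the census-consistency recursion of a demographic projection
#'
#' @param census data.frame from [generate_census()] or equivalent.
#' @param tol maximum allowed relative residual.
#' @return invisibly `TRUE`; errors if the recursion fails.
#' @export
validate_census <- function(census, tol = 1e-9) {
  n <- nrow(census)
  res <- census$N[-1] -
    (census$N[-n] * (1 - census$d[-1]) + census$b[-1] + census$m[-1])
  if (any(abs(res) > tol * census$N[-1])) {
    stop_diabproj("invalid_argument", "census recursion violated (max rel %.3g)",
                  max(abs(res) / census$N[-1]))
  }
  invisible(TRUE)
}
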