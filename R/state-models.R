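#' Mortality relative-risk sets
#'
#' Relative risks of death versus the nondiabetic population for the
#' undiagnosed (`r1`) and diagnosed (`r2`) compartments, constant over
#' time. The two published sets are *low mortality risk*
#' `(r1 = 1.77, r2 = 2.11)` and *high mortality risk*
#' `(r1 = 1.00, r2 = 4.08)`.
#'
#' @param r1,r2 relative risks (>= and usually > 1).
#' @return named numeric `c(r1 =, r2 =)`.
#' @export
#' @examples
#' default_risk_sets()$low
mortality_risks <- function(r1, r2) {
  if (r1 < 1 || r2 < 1) stop_diabproj("invalid_argument", "relative risks must be >= 1")
  c(r1 = r1, r2 = r2)
}

#' @rdname mortality_risks
#' @export
default_risk_sets <- function() {
  list(low = mortality_risks(1.77, 2.11),
       high = mortality_risks(1.00, 4.08))
}

#' Back-calculate the nondiabetic death rate
#'
#' Census consistency requires total deaths in year t to equal
#' `d(t) * N(t-1)`. With constant relative risks this pins down the
#' nondiabetic death rate `gamma` through
#' `gamma * (X + r1 Z + r2 Y) = d * N(t-1)`.
#'
#' @param d census death rate for year t.
#' @param Nprev total population at t-1 (must equal `X + Z + Y`).
#' @param X,Z,Y compartment counts at t-1.
#' @param risks a [mortality_risks()] set.
#' @return the nondiabetic death rate `gamma` (per person-year).
#' @export
back_calculate_gamma <- function(d, Nprev, X, Z, Y, risks) {
  check_prob(d, "death rate", open_upper = TRUE)
  if (abs(X + Z + Y - Nprev) > 1e-6 * Nprev) {
    stop_diabproj("invalid_argument", "X + Z + Y must equal Nprev")
  }
  gamma <- d * Nprev / (X + risks[["r1"]] * Z + risks[["r2"]] * Y)
  if (gamma * risks[["r2"]] >= 1 || gamma * risks[["r1"]] >= 1) {
    stop_diabproj("mortality_overflow", "implied diabetic death rate >= 1")
  }
  gamma
}

#' Annual undiagnosed-to-diagnosed rate from the diagnosed-incidence identity
#'
#' Given a projected diagnosed-diabetes incidence `i_t` over the at-risk
#' pool (nondiabetic plus undiagnosed), solves
#' `xi1 * beta * X + beta * Z = i_t * (X + Z)` for `beta(t)`.
#'
#' @param i_t diagnosed incidence rate for year t.
#' @param X,Z compartment counts at t-1.
#' @param xi1 calibrated nondiabetic-to-diagnosed multiplier.
#' @return `beta(t)` (per person-year).
#' @export
solve_beta <- function(i_t, X, Z, xi1) {
  beta <- i_t * (X + Z) / (xi1 * X + Z)
  if (!is.finite(beta) || beta < 0 || beta >= 1) {
    stop_diabproj("infeasible_rates", "implied beta = %.4g outside [0,1)", beta)
  }
  beta
}

#' One row of the three-state annual transition matrix
#'
#' Destinations are `X` (no diabetes), `Z` (undiagnosed), `Y` (diagnosed),
#' `dead`; each row is nonnegative and sums to one. The diagnosed row has
#' zero mass back to `X` or `Z` (no remission).
#'
#' @param state source compartment, `"X"`, `"Z"`, or `"Y"`.
#' @param gamma nondiabetic death rate for the year.
#' @param beta undiagnosed-to-diagnosed rate for the year.
#' @param xi1,xi2 onset multipliers from [solve_xi()].
#' @param risks a [mortality_risks()] set.
#' @return named probability vector over `c(X, Z, Y, dead)`.
#' @export
build_transition_row <- function(state = c("X", "Z", "Y"), gamma, beta,
                                 xi1, xi2, risks) {
  state <- match.arg(state)
  row <- switch(state,
    X = c(X = 1 - gamma - (xi1 + xi2) * beta,
          Z = xi2 * beta, Y = xi1 * beta, dead = gamma),
    Z = c(X = 0, Z = 1 - risks[["r1"]] * gamma - beta,
          Y = beta, dead = risks[["r1"]] * gamma),
    Y = c(X = 0, Z = 0, Y = 1 - risks[["r2"]] * gamma,
          dead = risks[["r2"]] * gamma))
  if (any(row < 0)) {
    stop_diabproj("infeasible_rates",
                  "negative stay probability in the %s row", state)
  }
  row
}

# year lookup helpers
demog_row <- function(demog, year) {
  k <- match(year, demog$year)
  if (is.na(k)) stop_diabproj("invalid_argument", "year %d not in demography", year)
  demog[k, ]
}
scenario_rate <- function(scenario, year) {
  k <- match(year, scenario$year)
  if (is.na(k)) stop_diabproj("invalid_argument", "year %d not in scenario", year)
  scenario$rate[k]
}

#' Advance the three-state model by one year
#'
#' Applies the annual transition matrix (competing risks of death and
#' disease transition), then adds the new 18-year-old cohort (all
#' nondiabetic) and allocates net migration across states in proportion to
#' the start-of-year state shares. The result sums exactly to
#' `N(t) = N(t-1)(1 - d) + b + m`.
#'
#' @param state named counts `c(X =, Z =, Y =)` at t-1.
#' @param b,m,d births into adulthood, net migration, census death rate
#'   for year t.
#' @param i_t diagnosed incidence rate for year t.
#' @param calib a `calibration_set` from [calibrate()].
#' @param risks a [mortality_risks()] set.
#' @return list with `state` (counts at t) and `flows` (named vector:
#'   incident diagnosed and total cases, deaths by state).
#' @export
step_three_state <- function(state, b, m, d, i_t, calib, risks) {
  X <- state[["X"]]; Z <- state[["Z"]]; Y <- state[["Y"]]
  Nprev <- X + Z + Y
  gamma <- back_calculate_gamma(d, Nprev, X, Z, Y, risks)
  beta <- solve_beta(i_t, X, Z, calib$xi1)
  rX <- build_transition_row("X", gamma, beta, calib$xi1, calib$xi2, risks)
  rZ <- build_transition_row("Z", gamma, beta, calib$xi1, calib$xi2, risks)
  rY <- build_transition_row("Y", gamma, beta, calib$xi1, calib$xi2, risks)
  g <- c(X, Z, Y) / Nprev # migration allocation: start-of-year shares
  Xn <- X * rX[["X"]] + b + m * g[1]
  Zn <- Z * rZ[["Z"]] + X * rX[["Z"]] + m * g[2]
  Yn <- Y * rY[["Y"]] + X * rX[["Y"]] + Z * rZ[["Y"]] + m * g[3]
  if (min(Xn, Zn, Yn) < 0) {
    stop_diabproj("infeasible_rates", "negative compartment after step")
  }
  list(state = c(X = Xn, Z = Zn, Y = Yn),
       flows = c(incident_diagnosed = X * rX[["Y"]] + Z * rZ[["Y"]],
                 incident_total = X * (rX[["Y"]] + rX[["Z"]]),
                 deaths_X = gamma * X,
                 deaths_Z = risks[["r1"]] * gamma * Z,
                 deaths_Y = risks[["r2"]] * gamma * Y,
                 gamma = gamma, beta = beta))
}

trajectory_frame <- function(years, model, risks) {
  structure(data.frame(year = years), model = model, risks = risks)
}

#' Run the three-state projection
#'
#' Propagates the initial `(X, Z, Y)` partition through every year of the
#' demographic projection using the given diagnosed-incidence scenario.
#' Deterministic given its inputs.
#'
#' @param initial named counts `c(X =, Z =, Y =)` at the first demography
#'   year (e.g. from [generate_initial_state()]).
#' @param demog demographic projection from [generate_census()].
#' @param scenario data.frame `year`, `rate` (diagnosed incidence) covering
#'   every year after the first.
#' @param calib a `calibration_set` from [calibrate()].
#' @param risks a [mortality_risks()] set.
#' @return data.frame (class `trajectory`) with per-year states `X`, `Z`,
#'   `Y`, total `N`, rates `gamma`, `beta`, flows (incident and death
#'   counts), and prevalences `theta1` (undiagnosed), `theta2`
#'   (diagnosed), `theta = theta1 + theta2`.
#' @export
run_three_state <- function(initial, demog, scenario, calib, risks) {
  years <- demog$year
  n <- length(years)
  out <- data.frame(year = years, X = NA_real_, Z = NA_real_, Y = NA_real_,
                    N = NA_real_, gamma = NA_real_, beta = NA_real_,
                    incident_diagnosed = NA_real_, incident_total = NA_real_,
                    deaths = NA_real_)
  state <- initial
  out[1, c("X", "Z", "Y")] <- state
  out$N[1] <- sum(state)
  for (k in 2:n) {
    st <- step_three_state(state, demog$b[k], demog$m[k], demog$d[k],
                           scenario_rate(scenario, years[k]), calib, risks)
    state <- st$state
    out[k, c("X", "Z", "Y")] <- state
    out$N[k] <- sum(state)
    out$gamma[k] <- st$flows[["gamma"]]
    out$beta[k] <- st$flows[["beta"]]
    out$incident_diagnosed[k] <- st$flows[["incident_diagnosed"]]
    out$incident_total[k] <- st$flows[["incident_total"]]
    out$deaths[k] <- sum(st$flows[c("deaths_X", "deaths_Z", "deaths_Y")])
  }
  out$theta1 <- out$Z / out$N
  out$theta2 <- out$Y / out$N
  out$theta <- out$theta1 + out$theta2
  attr(out, "model") <- "three"
  attr(out, "risks") <- risks
  class(out) <- c("trajectory", "data.frame")
  out
}

# shared stepper for the stratified (four-/five-state) models; the
# four-state model is the nu = 0, regression_rate = 0 special case.
# `rates` optionally supplies per-year (beta, lambda_high, lambda_low)
# from a baseline run; otherwise they are solved from the scenario along
# the trajectory itself. gamma is always back-calculated from the run's
# own state so census consistency holds.
run_strata_model <- function(initial, demog, scenario, calib, risks,
                             p, c_rel, q, nu = 0, regression_rate = 0,
                             model = "four", rates = NULL) {
  years <- demog$year
  n <- length(years)
  X0 <- initial[["X"]]
  state <- c(IX = p * X0, LX = (1 - p) * X0, LXI = 0,
             Z = initial[["Z"]], Y = initial[["Y"]])
  out <- data.frame(year = years, IX = NA_real_, LX = NA_real_, LXI = NA_real_,
                    X = NA_real_, Z = NA_real_, Y = NA_real_, N = NA_real_,
                    gamma = NA_real_, beta = NA_real_,
                    lambda_high = NA_real_, lambda_low = NA_real_,
                    alpha1 = NA_real_, p_t = NA_real_,
                    incident_diagnosed = NA_real_, incident_total = NA_real_,
                    deaths = NA_real_)
  fill <- function(k, st, extra = rep(NA_real_, 8)) {
    out[k, c("IX", "LX", "LXI")] <<- st[c("IX", "LX", "LXI")]
    out$X[k] <<- st[["IX"]] + st[["LX"]] + st[["LXI"]]
    out[k, c("Z", "Y")] <<- st[c("Z", "Y")]
    out$N[k] <<- sum(st)
    out[k, c("gamma", "beta", "lambda_high", "lambda_low", "alpha1",
             "incident_diagnosed", "incident_total", "deaths")] <<- extra
    out$p_t[k] <<- st[["IX"]] / (st[["IX"]] + st[["LX"]])
  }
  fill(1, state)
  for (k in 2:n) {
    IX <- state[["IX"]]; LX <- state[["LX"]]; LXI <- state[["LXI"]]
    Z <- state[["Z"]]; Y <- state[["Y"]]
    Xp <- IX + LX + LXI
    Nprev <- Xp + Z + Y
    d <- demog$d[k]; b <- demog$b[k]; m <- demog$m[k]
    gamma <- back_calculate_gamma(d, Nprev, Xp, Z, Y, risks)
    if (is.null(rates)) {
      beta <- solve_beta(scenario_rate(scenario, years[k]), Xp, Z, calib$xi1)
      I_t <- (calib$xi1 + calib$xi2) * beta
      lamL <- I_t / (p * c_rel + 1 - p)
      lamH <- c_rel * lamL
    } else {
      j <- match(years[k], rates$year)
      beta <- rates$beta[j]
      lamH <- rates$lambda_high[j]
      lamL <- rates$lambda_low[j]
    }
    lamI <- (1 - nu) * lamH
    stayI <- 1 - gamma - lamI - regression_rate
    stayL <- 1 - gamma - lamL
    if (min(stayI, stayL, 1 - risks[["r1"]] * gamma - beta) < 0) {
      stop_diabproj("infeasible_rates", "negative stay probability in %d", years[k])
    }
    onset <- lamI * IX + lamL * (LX + LXI) # new diabetes from the nondiabetic pool
    g <- state / Nprev
    IXn <- IX * stayI + p * b + m * g[["IX"]]
    LXn <- LX * stayL + (1 - p) * b + m * g[["LX"]]
    LXIn <- LXI * stayL + regression_rate * IX + m * g[["LXI"]]
    Zn <- Z * (1 - risks[["r1"]] * gamma - beta) + (1 - calib$eta) * onset + m * g[["Z"]]
    Yn <- Y * (1 - risks[["r2"]] * gamma) + beta * Z + calib$eta * onset + m * g[["Y"]]
    # inter-strata correction: retain fraction q of the surviving
    # nondiabetic high-risk stock, then balance from the low-risk stratum
    # so the high-risk share of (IX + LX) stays at p
    alpha1 <- q * stayI
    gross_out <- (1 - q) * stayI * IX
    target <- p * (IXn + LXn)
    in_flow <- target - (IXn - gross_out)
    if (in_flow < -1e-9 * (IXn + LXn) || in_flow > LXn + gross_out) {
      stop_diabproj("infeasible_strata",
                    "strata rebalancing infeasible in %d", years[k])
    }
    S <- IXn + LXn
    IXn <- target
    LXn <- S - target
    if (min(IXn, LXn, LXIn, Zn, Yn) < 0) {
      stop_diabproj("infeasible_rates", "negative compartment in %d", years[k])
    }
    state <- c(IX = IXn, LX = LXn, LXI = LXIn, Z = Zn, Y = Yn)
    fill(k, state, c(gamma, beta, lamH, lamL, alpha1,
                     calib$eta * onset + beta * Z, onset,
                     gamma * (Xp + risks[["r1"]] * Z + risks[["r2"]] * Y)))
  }
  out$theta1 <- out$Z / out$N
  out$theta2 <- out$Y / out$N
  out$theta <- out$theta1 + out$theta2
  attr(out, "model") <- model
  attr(out, "risks") <- risks
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Run the four-state projection (high/low-risk split)
#'
#' Expands the three-state model by splitting the nondiabetic compartment
#' into a high-risk stratum `HX` (reported as column `IX`) and a low-risk
#' stratum `LX`, with stratum incidences from the constant relative
#' incidence `c` and inter-strata flows that hold the high-risk share at
#' `p` every year (retention fraction `q` of the surviving nondiabetic
#' high-risk stock, balancing inflow from the low-risk stratum). The
#' marginal `X = HX + LX`, `Z`, `Y` reproduce the three-state trajectory.
#'
#' @inheritParams run_three_state
#' @param strata list with `p` (high-risk share), `c` (relative
#'   incidence), `q` (retention); defaults taken from `calib`.
#' @return a `trajectory` data.frame with stratum columns, `alpha1` (the
#'   high-risk retention probability), and `p_t`.
#' @export
run_four_state <- function(initial, demog, scenario, calib, risks,
                           strata = NULL) {
  if (is.null(strata)) strata <- list(p = calib$p28, c = calib$c, q = calib$q)
  stopifnot(strata$p > 0, strata$p < 1, strata$c >= 1)
  run_strata_model(initial, demog, scenario, calib, risks,
                   p = strata$p, c_rel = strata$c, q = strata$q,
                   nu = 0, regression_rate = 0, model = "four")
}

#' Run the five-state projection (preventive intervention)
#'
#' As [run_four_state()], but the high-risk stratum `IX` is under an
#' intervention reducing its annual diabetes incidence by the factor
#' `1 - nu`, and an optional flow at `regression_rate` moves intervention
#' participants who regressed to low risk into the `LXI` state (which has
#' low-risk incidence and starts empty). With `nu = 0` and
#' `regression_rate = 0` the trajectory is identical to the four-state
#' model.
#'
#' The annual transition rates (`beta(t)` and the stratum incidences) are
#' taken from the no-intervention baseline: the intervention scales down
#' the high-risk incidence the baseline population experienced, rather
#' than re-deriving rates from the intervention population's own
#' diagnosed-incidence identity. Only the nondiabetic death rate
#' `gamma(t)` is re-back-calculated along the intervention trajectory so
#' census consistency still holds exactly.
#'
#' @inheritParams run_four_state
#' @param intervention list with `nu` (effective incidence reduction, see
#'   [effective_reduction()]) and `regression_rate`; defaults
#'   `nu = calib$nu`, `regression_rate = 0`.
#' @param baseline optional four-state `trajectory` supplying the per-year
#'   baseline rates; computed internally with [run_four_state()] when
#'   `NULL`.
#' @return a `trajectory` data.frame.
#' @export
run_five_state <- function(initial, demog, scenario, calib, risks,
                           strata = NULL, intervention = NULL,
                           baseline = NULL) {
  if (is.null(strata)) strata <- list(p = calib$p28, c = calib$c, q = calib$q)
  if (is.null(intervention)) intervention <- list(nu = calib$nu, regression_rate = 0)
  nu <- intervention$nu
  reg <- if (is.null(intervention$regression_rate)) 0 else intervention$regression_rate
  check_prob(nu, "nu")
  check_prob(reg, "regression_rate", open_upper = TRUE)
  if (is.null(baseline)) {
    baseline <- run_four_state(initial, demog, scenario, calib, risks, strata)
  }
  run_strata_model(initial, demog, scenario, calib, risks,
                   p = strata$p, c_rel = strata$c, q = strata$q,
                   nu = nu, regression_rate = reg, model = "five",
                   rates = baseline[, c("year", "beta", "lambda_high", "lambda_low")])
}

#' Incident cases prevented or delayed by an intervention
#'
#' @param base,interv `trajectory` objects over the same years and
#'   demography (typically a three-/four-state baseline and a five-state
#'   intervention run).
#' @return data.frame `year`, `base`, `intervention`, `difference`
#'   (base minus intervention incident total-diabetes cases).
#' @export
incident_case_difference <- function(base, interv) {
  if (!identical(base$year, interv$year)) {
    stop_diabproj("invalid_argument", "trajectories cover different years")
  }
  data.frame(year = base$year,
             base = base$incident_total,
             intervention = interv$incident_total,
             difference = base$incident_total - interv$incident_total)
}
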