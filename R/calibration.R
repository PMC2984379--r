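#' Absolute incidence of a glycemic subgroup
#'
#' Multiplies the absolute annual diabetes incidence of the normoglycemic
#' (NG) referent group by a subgroup's relative risk, e.g. NG incidence
#' 0.32%/yr times RR 5.5 for isolated IGT gives 1.76%/yr.
#'
#' @param ng_incidence annual incidence in the NG group (per person-year).
#' @param relative_risk annualized relative risk versus NG (>= 1 typical).
#' @return annual incidence (per person-year), full precision; use
#'   [round_half_up()] on the percent scale for reporting.
#' @export
#' @examples
#' 100 * subgroup_incidence(0.0032, 5.5) # 1.76 (%)
subgroup_incidence <- function(ng_incidence, relative_risk) {
  if (ng_incidence <= 0 || relative_risk <= 0) {
    stop_diabproj("invalid_argument", "inputs must be positive")
  }
  out <- ng_incidence * relative_risk
  if (out >= 1) stop_diabproj("invalid_rate", "implied incidence >= 1")
  out
}

#' Median normoglycemic incidence across studies
#'
#' @param study_rates annual NG incidences from individual cohort studies.
#' @return the sample median (even-length lists average the two central
#'   values), full precision.
#' @export
#' @examples
#' median_ng_incidence(c(0.0019, 0.0025, 0.0038, 0.0064)) # 0.0032
median_ng_incidence <- function(study_rates) {
  if (length(study_rates) == 0 || any(study_rates <= 0)) {
    stop_diabproj("invalid_argument", "need a non-empty list of positive rates")
  }
  median(study_rates)
}

#' Total diabetes incidence among nondiabetic adults
#'
#' Prevalence-weighted sum of subgroup incidences over the mutually
#' exclusive glycemic subgroups of the nondiabetic population (NG, IIFG,
#' IIGT, CIFGT).
#'
#' @param profile list with `prevalence` (proportions summing to 1) and
#'   `incidence` (annual subgroup incidences, same order).
#' @return annual total-diabetes incidence (per person-year).
#' @export
total_incidence <- function(profile) {
  p <- profile$prevalence
  inc <- profile$incidence
  if (length(p) != length(inc) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop_diabproj("invalid_argument", "prevalences must be a simplex matching incidences")
  }
  sum(p * inc)
}

#' Constant-hazard calibration of the undiagnosed duration
#'
#' Assuming a constant hazard of diagnosis such that a fraction
#' `frac_within` of people spend less than `horizon` years undiagnosed,
#' returns the hazard and the implied six-month and annual transition
#' probabilities (e.g. 95% within 7 years gives a 0.19 six-month
#' probability).
#'
#' @param frac_within probability of diagnosis within `horizon` (in (0,1)).
#' @param horizon duration bound in years.
#' @return list with `hazard` (per year), `p_six_month`, `p_annual`.
#' @export
#' @examples
#' undiagnosed_duration_hazard(0.95, 7)
undiagnosed_duration_hazard <- function(frac_within, horizon) {
  if (frac_within >= 1) stop_diabproj("infinite_hazard", "frac_within must be < 1")
  if (frac_within <= 0 || horizon <= 0) {
    stop_diabproj("invalid_argument", "need 0 < frac_within < 1 and horizon > 0")
  }
  h <- -log(1 - frac_within) / horizon
  list(hazard = h,
       p_six_month = 1 - exp(-h / 2),
       p_annual = 1 - exp(-h))
}

#' Relative incidence of the high- versus low-risk nondiabetic strata
#'
#' Solves for the constant ratio `c` of high-risk to low-risk annual
#' total-diabetes incidence, given the high-risk incidence, the high-risk
#' share of the nondiabetic pool, and the pool-wide incidence:
#' `c = lambda_high / ((I_total - p * lambda_high) / (1 - p))`.
#'
#' @param lambda_high annual incidence in the high-risk stratum.
#' @param p high-risk proportion of the nondiabetic population.
#' @param I_total pool-wide annual total-diabetes incidence.
#' @return the relative incidence `c` (dimensionless, full precision;
#'   report with [round_half_up()] to 1 decimal).
#' @export
#' @examples
#' round_half_up(solve_relative_incidence(0.0287, 0.257, 0.0106), 1) # 6.6
solve_relative_incidence <- function(lambda_high, p, I_total) {
  check_prob(p, "p")
  low <- (I_total - p * lambda_high) / (1 - p)
  if (low <= 0 || lambda_high < I_total) {
    stop_diabproj("infeasible_calibration",
                  "need p * lambda_high < I_total <= lambda_high")
  }
  lambda_high / low
}

#' Stratum incidence rates from total incidence and relative incidence
#'
#' Inverse of [solve_relative_incidence()]: splits the pool-wide incidence
#' into low- and high-risk rates with `high = c * low` and
#' `p * high + (1 - p) * low = I_total`.
#'
#' @param I_total pool-wide annual total-diabetes incidence.
#' @param p high-risk proportion of the nondiabetic population.
#' @param c relative incidence (high/low).
#' @return named numeric `c(high =, low =)`.
#' @export
#' @examples
#' strata_incidence_rates(0.0106, 0.257, 6.6)
strata_incidence_rates <- function(I_total, p, c) {
  check_prob(p, "p")
  if (I_total <= 0 || c <= 0) stop_diabproj("invalid_argument", "rates must be positive")
  low <- I_total / (p * c + 1 - p)
  c(high = c * low, low = low)
}

#' Effective incidence reduction of a partial-coverage intervention
#'
#' @param coverage proportion of the high-risk group reached.
#' @param efficacy proportional incidence reduction among participants.
#' @return effective reduction `nu = coverage * efficacy` applied to the
#'   whole high-risk stratum.
#' @export
#' @examples
#' effective_reduction(0.5, 0.5) # 0.25
effective_reduction <- function(coverage, efficacy) {
  check_prob(coverage, "coverage"); check_prob(efficacy, "efficacy")
  coverage * efficacy
}

#' Solve the nondiabetic onset multipliers
#'
#' Determines `(xi1, xi2)` — the constant multipliers mapping the annual
#' undiagnosed-to-diagnosed rate `beta(t)` to the nondiabetic-to-diagnosed
#' and nondiabetic-to-undiagnosed rates — together with the base-year
#' `beta`, from three constraints at the first projected year:
#'
#' 1. total new-diabetes flow from X matches `I29`:
#'    `(xi1 + xi2) * beta = I29`;
#' 2. observed diagnosed incidence over the at-risk pool matches `i29`:
#'    `xi1 * beta * X28 + beta * Z28 = i29 * (X28 + Z28)`;
#' 3. the diagnosed share of new cases is `eta`: `xi1 / (xi1 + xi2) = eta`.
#'
#' The system is scale-free in the state counts and has the closed-form
#' solution `beta = (i29 (X28 + Z28) - eta I29 X28) / Z28`,
#' `xi1 = eta I29 / beta`, `xi2 = (1 - eta) I29 / beta` (when `Z28 = 0`,
#' feasibility requires `eta = 1` and `i29 = I29`, giving `xi2 = 0`).
#'
#' @param i29 observed diagnosed-diabetes incidence in the base year.
#' @param I29 total (diagnosed or undiagnosed) incidence among nondiabetics.
#' @param eta diagnosed share of new diabetes cases, in (0, 1].
#' @param state28 named counts `c(X =, Z =, Y =)` at the base year.
#' @return list with `xi1`, `xi2`, `beta29`, `eta`.
#' @export
solve_xi <- function(i29, I29, eta, state28) {
  if (!(i29 > 0 && i29 < I29 + 1e-15 && I29 < 1)) {
    stop_diabproj("invalid_argument", "need 0 < i29 <= I29 < 1")
  }
  check_prob(eta, "eta")
  X <- state28[["X"]]; Z <- state28[["Z"]]
  if (Z == 0) {
    if (abs(eta - 1) > 1e-12 || abs(i29 - I29) > 1e-12) {
      stop_diabproj("infeasible_calibration",
                    "with Z = 0 the constraints force eta = 1 and i29 = I29")
    }
    # beta unidentified without an undiagnosed pool; any beta with
    # xi1 * beta = I29 works. Pin beta = I29 (xi1 = 1) by convention.
    return(list(xi1 = 1, xi2 = 0, beta29 = I29, eta = 1))
  }
  beta <- (i29 * (X + Z) - eta * I29 * X) / Z
  if (beta <= 0 || beta >= 1) {
    stop_diabproj("infeasible_calibration",
                  "diagnosed-incidence constraint gives beta = %.4g outside (0,1)", beta)
  }
  xi1 <- eta * I29 / beta
  xi2 <- (1 - eta) * I29 / beta
  if (xi1 <= 0 || xi2 < 0) {
    stop_diabproj("infeasible_calibration", "no positive (xi1, xi2) solution")
  }
  list(xi1 = xi1, xi2 = xi2, beta29 = beta, eta = eta)
}

#' Default calibration configuration
#'
#' Scalar inputs for [calibrate()], with defaults taken from the published
#' US calibration: base-year diagnosed incidence 0.0084, total nondiabetic
#' incidence 0.0106 (the glycemic-subgroup weighted sum), high-risk (IFG)
#' incidence 0.0287 and proportion 0.257, high-risk retention `q = 0.93`,
#' intervention coverage and efficacy 0.5 each, and the 95%-within-7-years
#' undiagnosed-duration assumption. `undiag_alloc_a`/`undiag_alloc_b` are
#' literature constants carried for provenance; they are not independently
#' derivable from the other inputs and the default birth/migration
#' allocation does not use them.
#'
#' @return named list of calibration inputs.
#' @export
calibration_config <- function() {
  list(
    i29 = 0.0084, I29 = 0.0106,
    lambda_high = 0.0287, p28 = 0.257, q = 0.93,
    coverage = 0.5, efficacy = 0.5,
    frac_within = 0.95, horizon = 7,
    eta = NULL, # NULL = derive from the constant-hazard duration argument
    undiag_alloc_a = 0.398, undiag_alloc_b = 0.129
  )
}

#' Derive the full calibration set for the state models
#'
#' Combines the worked scalar calibrations: the constant-hazard
#' undiagnosed-duration argument (giving the diagnosed share of new cases
#' `eta` unless supplied), the onset multipliers `(xi1, xi2)` via
#' [solve_xi()], the high/low-risk relative incidence `c` via
#' [solve_relative_incidence()], the stratum rates, and the effective
#' intervention reduction `nu`.
#'
#' @param config list as from [calibration_config()].
#' @param state28 named base-year counts `c(X =, Z =, Y =)`.
#' @return list of class `calibration_set` with all derived constants.
#' @export
calibrate <- function(config = calibration_config(), state28) {
  dur <- undiagnosed_duration_hazard(config$frac_within, config$horizon)
  eta <- if (is.null(config$eta)) dur$p_annual else config$eta
  xi <- solve_xi(config$i29, config$I29, eta, state28)
  c_rel <- solve_relative_incidence(config$lambda_high, config$p28, config$I29)
  strata <- strata_incidence_rates(config$I29, config$p28, c_rel)
  structure(list(
    eta = eta, xi1 = xi$xi1, xi2 = xi$xi2, beta29 = xi$beta29,
    i29 = config$i29, I29 = config$I29,
    c = c_rel, lambda_high = strata[["high"]], lambda_low = strata[["low"]],
    p28 = config$p28, q = config$q,
    nu = effective_reduction(config$coverage, config$efficacy),
    duration = dur,
    undiag_alloc_a = config$undiag_alloc_a,
    undiag_alloc_b = config$undiag_alloc_b
  ), class = "calibration_set")
}
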