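#' Per-year total-diabetes prevalence across a scenario grid
#'
#' Tabulates `theta(t) = (Z + Y) / N` for each cell of a scenario grid
#' (incidence scenario x mortality-risk set), with a sanity flag that the
#' middle-incidence prevalence is at least the low-incidence prevalence
#' within each risk set.
#'
#' @param trajectories named list of `trajectory` objects; names like
#'   `"low_lowrisk"`, `"middle_highrisk"` (incidence scenario first).
#' @return data.frame with `year`, one prevalence column per cell, and
#'   `ordering_ok` (logical) when both incidence scenarios are present.
#' @export
make_prevalence_report <- function(trajectories) {
  years <- trajectories[[1]]$year
  for (tr in trajectories) {
    if (!identical(tr$year, years)) {
      stop_diabproj("invalid_argument", "trajectories cover different years")
    }
  }
  out <- data.frame(year = years)
  for (nm in names(trajectories)) out[[nm]] <- trajectories[[nm]]$theta
  cells <- names(trajectories)
  risk_tags <- unique(sub("^(low|middle|high)_", "", cells))
  ok <- rep(TRUE, length(years))
  any_pair <- FALSE
  for (rt in risk_tags) {
    lo <- paste0("low_", rt); mid <- paste0("middle_", rt)
    if (lo %in% cells && mid %in% cells) {
      any_pair <- TRUE
      ok <- ok & (out[[mid]] >= out[[lo]] - 1e-12)
    }
  }
  if (any_pair) out$ordering_ok <- ok
  out
}

#' Format projection results as publication-style summary tables
#'
#' `style = "table1"`: numbers of people (millions, 1 decimal) without
#' diabetes, with undiagnosed, and with diagnosed diabetes, every fifth
#' year 2010-2050, as `(low, middle)` incidence pairs per mortality-risk
#' set, plus the total adult population. `style = "table2"`: incident
#' total-diabetes cases (thousands, 1 decimal) without and with
#' intervention and their difference. Rounding is half away from zero and
#' applied only here; trajectory objects keep full precision.
#'
#' @param trajectories named list of `trajectory` objects. For `table1`,
#'   names `<scenario>_<risk>` with scenarios `low`, `middle` and risks
#'   `lowrisk`, `highrisk`. For `table2`, additionally
#'   `<scenario>_<risk>_interv` cells for the intervention runs.
#' @param style `"table1"` or `"table2"`.
#' @param years report years (default every 5th, 2010-2050).
#' @return data.frame shaped like the corresponding published table.
#' @export
format_table <- function(trajectories, style = c("table1", "table2"),
                         years = seq(2010, 2050, by = 5)) {
  style <- match.arg(style)
  risks <- default_risk_sets()
  get_cell <- function(nm) {
    tr <- trajectories[[nm]]
    if (is.null(tr)) stop_diabproj("invalid_argument", "missing grid cell '%s'", nm)
    if (!all(years %in% tr$year)) {
      stop_diabproj("incomplete_trajectory", "cell '%s' lacks report years", nm)
    }
    tr[match(years, tr$year), ]
  }
  rows <- list()
  for (rk in c("lowrisk", "highrisk")) {
    lo <- get_cell(paste0("low_", rk))
    mid <- get_cell(paste0("middle_", rk))
    rr <- risks[[sub("risk$", "", rk)]]
    if (style == "table1") {
      rows[[rk]] <- data.frame(
        year = years, r1 = rr[["r1"]], r2 = rr[["r2"]],
        no_diabetes_low = round_half_up(lo$X / 1e6, 1),
        no_diabetes_middle = round_half_up(mid$X / 1e6, 1),
        undiagnosed_low = round_half_up(lo$Z / 1e6, 1),
        undiagnosed_middle = round_half_up(mid$Z / 1e6, 1),
        diagnosed_low = round_half_up(lo$Y / 1e6, 1),
        diagnosed_middle = round_half_up(mid$Y / 1e6, 1),
        total_population = round_half_up(lo$N / 1e6, 1))
    } else {
      loi <- get_cell(paste0("low_", rk, "_interv"))
      midi <- get_cell(paste0("middle_", rk, "_interv"))
      rows[[rk]] <- data.frame(
        year = years, r1 = rr[["r1"]], r2 = rr[["r2"]],
        no_intervention_low = round_half_up(lo$incident_total / 1e3, 1),
        no_intervention_middle = round_half_up(mid$incident_total / 1e3, 1),
        intervention_low = round_half_up(loi$incident_total / 1e3, 1),
        intervention_middle = round_half_up(midi$incident_total / 1e3, 1),
        difference_low = round_half_up((lo$incident_total - loi$incident_total) / 1e3, 1),
        difference_middle = round_half_up((mid$incident_total - midi$incident_total) / 1e3, 1))
    }
  }
  out <- rbind(rows$lowrisk, rows$highrisk)
  out <- out[order(out$year, -out$r1), ]
  rownames(out) <- NULL
  out
}
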