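#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used for
#' all reported values (base [round()] rounds half to even). Internal
#' results are never rounded; this is presentation-layer only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.5, 0)   # 3, not 2
#' round_half_up(0.315, 2) # 0.32
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by one ulp so that values stored just below a .5 tie (e.g. 0.315)
  # still round up, matching decimal half-away-from-zero arithmetic
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

stop_diabproj <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "diabproj_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_diabproj <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "diabproj_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_prob <- function(x, name, open_upper = FALSE) {
  bad <- !is.finite(x) | x < 0 | (if (open_upper) x >= 1 else x > 1)
  if (any(bad)) {
    stop_diabproj("invalid_argument", "%s must lie in [0, 1%s), got %s",
                  name, if (open_upper) "" else "]", paste(x[bad], collapse = ", "))
  }
  invisible(x)
}
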