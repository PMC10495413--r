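# Calendar conversions used throughout: the clinical literature reports
# follow-up in months and disease duration in years, while visit arithmetic
# is done at day granularity.
DAYS_PER_MONTH <- 30.44
DAYS_PER_YEAR <- 365.25

#' Legal EDSS values
#'
#' The Expanded Disability Status Scale takes values 0 and 1.0, 1.5, ..., 10.0
#' in half-point steps; 0.5 does not exist on the scale.
#'
#' @return Numeric vector of the 20 legal EDSS values.
#' @export
edss_grid <- function() c(0, seq(1, 10, by = 0.5))

# TRUE where x is a legal EDSS value (NA -> FALSE)
is_edss <- function(x) {
  g <- edss_grid()
  vapply(x, function(v) !is.na(v) && any(abs(v - g) < 1e-8), logical(1))
}

# snap a continuous value to the nearest legal EDSS point
snap_edss <- function(x) {
  g <- edss_grid()
  g[max.col(-abs(outer(x, g, "-")), ties.method = "first")]
}

months_between <- function(from, to) as.numeric(to - from) / DAYS_PER_MONTH
years_between <- function(from, to) as.numeric(to - from) / DAYS_PER_YEAR

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; cohort percentages are reported
#' with conventional half-up rounding (e.g. 23.65 -> 23.7).
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # pre-round at 9 decimals so values stored just below a half (binary
  # representation of e.g. 23.65) still round up
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

# parse ISO-8601 dates, with an error naming the offending row
parse_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  xs <- as.character(x)
  d <- as.Date(xs, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(xs) & nzchar(xs) & xs != "NA")
  if (length(bad)) {
    stop(sprintf("%s: malformed date '%s' at row %d (expected YYYY-MM-DD)",
                 what, xs[bad[1]], bad[1]), call. = FALSE)
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
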