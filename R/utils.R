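#' @keywords internal
#' @useDynLib drylandsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Internal helpers shared across modules. Kept deliberately small: argument
# checking that would sit in a hot loop lives at the loop entry instead.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, msg, call. = FALSE) {
  if (isTRUE(cond)) stop(msg, call. = call.)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

#' Month lengths for a calendar year
#' @param year integer year (Gregorian)
#' @return integer vector of 12 month lengths
#' @keywords internal
month_lengths <- function(year) {
  feb <- if (is_leap_year(year)) 29L else 28L
  c(31L, feb, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
}

#' Validate a daily weather table
#'
#' Required columns: year, month, day, doy, tmax, tmin, precip. Used at the
#' entry of every consumer so that per-day code can skip checks.
#' @keywords internal
check_weather <- function(weather) {
  need <- c("year", "month", "day", "doy", "tmax", "tmin", "precip")
  miss <- setdiff(need, names(weather))
  stop_if(length(miss) > 0,
          paste0("weather table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  stop_if(any(weather$tmax < weather$tmin),
          "weather table violates tmax >= tmin")
  stop_if(any(weather$precip < 0), "weather table has negative precipitation")
  invisible(weather)
}

# Column-wise all.equal tolerance used for closure checks (mm)
.CLOSURE_TOL <- 1e-6
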