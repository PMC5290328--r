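# Hybrid-delta construction of future daily forcing: monthly change signals
# (additive for temperature, multiplicative for precipitation) derived from
# paired historical/future GCM monthly series, applied to an observed daily
# record so that the day count and wet-day pattern are preserved.

#' Derive monthly change signals from paired GCM series
#'
#' In `"mean"` mode the delta for each calendar month is the future-minus-
#' historical mean temperature and the future/historical mean precipitation
#' ratio. In `"quantile"` mode each month carries an empirical quantile
#' mapping with `n_quantiles` bins: the temperature delta and precipitation
#' ratio are functions of quantile level, evaluated when the deltas are
#' applied (each observed month is ranked within its own climatology and
#' receives the change signal at the matched quantile).
#'
#' @param gcm_hist,gcm_fut monthly GCM series: data.frames with columns
#'   `year, month, temp, precip` covering at least `min_years` years each
#' @param mode `"mean"` or `"quantile"`
#' @param n_quantiles number of quantile bins (quantile mode)
#' @param ratio_cap upper cap on precipitation ratios (guards near-zero
#'   historical months)
#' @param min_years minimum years required in each series
#' @param gcm_label,rcp_label provenance labels
#' @return a `gcm_delta` object (mean mode) or a `gcm_delta_quantile` object
#'   (quantile mode: per-month matrices of quantile levels, temperature
#'   deltas and precipitation ratios)
#' @export
derive_deltas <- function(gcm_hist, gcm_fut, mode = c("quantile", "mean"),
                          n_quantiles = 17, ratio_cap = 5,
                          min_years = 20,
                          gcm_label = "GCM", rcp_label = "RCP") {
  mode <- match.arg(mode)
  for (d in list(gcm_hist, gcm_fut)) {
    stop_if(!all(c("year", "month", "temp", "precip") %in% names(d)),
            "GCM series need columns year, month, temp, precip")
    stop_if(length(unique(d$year)) < min_years,
            paste0("GCM series must cover at least ", min_years, " years"))
  }
  if (mode == "mean") {
    td <- pr <- numeric(12)
    for (m in 1:12) {
      h <- gcm_hist[gcm_hist$month == m, ]
      f <- gcm_fut[gcm_fut$month == m, ]
      td[m] <- mean(f$temp) - mean(h$temp)
      hm <- mean(h$precip)
      pr[m] <- if (hm > 0) min(ratio_cap, mean(f$precip) / hm) else
        if (mean(f$precip) > 0) ratio_cap else 1
      pr[m] <- max(pr[m], 1e-9)
    }
    return(gcm_delta_params(td, pr, gcm_label, rcp_label))
  }
  probs <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  td <- pr <- matrix(0, 12, n_quantiles)
  for (m in 1:12) {
    h <- gcm_hist[gcm_hist$month == m, ]
    f <- gcm_fut[gcm_fut$month == m, ]
    qt_h <- stats::quantile(h$temp, probs, names = FALSE, type = 7)
    qt_f <- stats::quantile(f$temp, probs, names = FALSE, type = 7)
    qp_h <- stats::quantile(h$precip, probs, names = FALSE, type = 7)
    qp_f <- stats::quantile(f$precip, probs, names = FALSE, type = 7)
    td[m, ] <- qt_f - qt_h
    pr[m, ] <- ifelse(qp_h > 0, pmin(ratio_cap, qp_f / qp_h),
                      ifelse(qp_f > 0, ratio_cap, 1))
  }
  structure(list(probs = probs, temp_delta = td,
                 precip_ratio = pmax(pr, 1e-9),
                 gcm_label = gcm_label, rcp_label = rcp_label),
            class = "gcm_delta_quantile")
}

#' Apply monthly change signals to a daily series
#'
#' Temperature deltas are added to both tmax and tmin of every day of the
#' matching calendar month (diurnal range unchanged); precipitation is
#' scaled multiplicatively. With a quantile delta set, each (year, month) of
#' the observed record is first ranked within its own monthly climatology
#' and receives the change signal interpolated at the matched quantile.
#' Zero deltas and unit ratios return the input unchanged; the wet-day
#' pattern is always preserved.
#'
#' @param weather daily weather table
#' @param deltas a `gcm_delta` or `gcm_delta_quantile` object
#' @return daily weather table of the same shape
#' @export
apply_deltas <- function(weather, deltas) {
  check_weather(weather)
  out <- weather
  if (inherits(deltas, "gcm_delta")) {
    out$tmax <- weather$tmax + deltas$temp_delta[weather$month]
    out$tmin <- weather$tmin + deltas$temp_delta[weather$month]
    out$precip <- weather$precip * deltas$precip_ratio[weather$month]
    return(out)
  }
  stop_if(!inherits(deltas, "gcm_delta_quantile"),
          "deltas must be a gcm_delta or gcm_delta_quantile object")
  yrs <- unique(weather$year)
  tmean <- (weather$tmax + weather$tmin) / 2
  for (m in 1:12) {
    sel_m <- weather$month == m
    mt <- vapply(yrs, function(y) mean(tmean[sel_m & weather$year == y]),
                 numeric(1))
    mp <- vapply(yrs, function(y) sum(weather$precip[sel_m & weather$year == y]),
                 numeric(1))
    q_t <- (rank(mt, ties.method = "average") - 0.5) / length(yrs)
    q_p <- (rank(mp, ties.method = "average") - 0.5) / length(yrs)
    dt_y <- stats::approx(deltas$probs, deltas$temp_delta[m, ], xout = q_t,
                          rule = 2)$y
    pr_y <- stats::approx(deltas$probs, deltas$precip_ratio[m, ], xout = q_p,
                          rule = 2)$y
    for (k in seq_along(yrs)) {
      sel <- sel_m & weather$year == yrs[k]
      out$tmax[sel] <- weather$tmax[sel] + dt_y[k]
      out$tmin[sel] <- weather$tmin[sel] + dt_y[k]
      out$precip[sel] <- weather$precip[sel] * pr_y[k]
    }
  }
  out
}
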