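# Synthetic forcing: seeded generators for daily weather, soil profiles,
# cell grids and per-GCM monthly change signals. These stand in for the
# global reanalysis / soil / GCM archives a full-scale run would consume,
# with just enough statistical structure (seasonal cycles, wet/dry spells,
# interannual noise, texture variation) for the downstream stages to be
# exercised and tested.

#' Weather generator parameters
#'
#' Bundles and validates the parameters of the daily weather generator.
#'
#' @param mat_target target mean annual temperature, degrees C
#' @param map_target target mean annual precipitation, mm/yr (> 0)
#' @param temp_seasonal_amplitude amplitude of the annual temperature cycle,
#'   degrees C (half peak-to-trough)
#' @param precip_seasonality fraction of annual precipitation falling in the
#'   three climatologically coldest months, in `[0, 1]`
#' @param wet_day_prob daily probability of precipitation occurrence, in (0, 1]
#' @param interannual_cv coefficient of variation of annual precipitation
#'   totals across years (>= 0)
#' @param years number of complete calendar years to generate (>= 2)
#' @param seed integer RNG seed; the generator is deterministic given the seed
#' @param lat latitude, degrees; the sign sets the hemisphere and hence the
#'   phase of the seasonal cycle (southern-hemisphere winter is Jun-Aug)
#' @param start_year first calendar year of the series (leap years follow the
#'   Gregorian calendar)
#' @param temp_noise_sd standard deviation of day-to-day temperature noise, C
#' @param temp_noise_ar1 lag-1 autocorrelation of the temperature noise
#' @param diurnal_range mean diurnal temperature range (tmax - tmin), C
#' @return an object of class `weather_gen_params` (a validated list)
#' @export
weather_gen_params <- function(mat_target, map_target,
                               temp_seasonal_amplitude = 10,
                               precip_seasonality = 0.35,
                               wet_day_prob = 0.25,
                               interannual_cv = 0.2,
                               years = 31L, seed = 1L, lat = 40,
                               start_year = 1980L,
                               temp_noise_sd = 2.0, temp_noise_ar1 = 0.7,
                               diurnal_range = 11) {
  stop_if(!is.numeric(map_target) || map_target <= 0,
          "map_target must be positive")
  stop_if(!is_count(years, min = 2L), "years must be an integer >= 2")
  stop_if(!is_prob(precip_seasonality),
          "precip_seasonality must lie in [0, 1]")
  stop_if(!is.numeric(wet_day_prob) || wet_day_prob <= 0 || wet_day_prob > 1,
          "wet_day_prob must lie in (0, 1]")
  stop_if(interannual_cv < 0, "interannual_cv must be >= 0")
  stop_if(abs(lat) > 90, "lat must lie in [-90, 90]")
  structure(list(mat_target = mat_target, map_target = map_target,
                 temp_seasonal_amplitude = temp_seasonal_amplitude,
                 precip_seasonality = precip_seasonality,
                 wet_day_prob = wet_day_prob,
                 interannual_cv = interannual_cv,
                 years = as.integer(years), seed = as.integer(seed),
                 lat = lat, start_year = as.integer(start_year),
                 temp_noise_sd = temp_noise_sd,
                 temp_noise_ar1 = temp_noise_ar1,
                 diurnal_range = diurnal_range),
            class = "weather_gen_params")
}

# Climatological mean temperature for a day-of-year. Phase convention:
# the annual cycle is cos(2*pi*(doy - peak)/365.25) with the warm peak at
# doy 197 (mid-July) in the northern hemisphere and doy 15 in the southern.
seasonal_temp <- function(doy, mat, amplitude, lat) {
  peak <- if (lat >= 0) 197 else 15
  mat + amplitude * cos(2 * pi * (doy - peak) / 365.25)
}

# Indices of the three climatologically coldest calendar months.
coldest_months <- function(mat, amplitude, lat) {
  mids <- cumsum(c(0, month_lengths(2001L)[-12])) + month_lengths(2001L) / 2
  order(seasonal_temp(mids, mat, amplitude, lat))[1:3]
}

#' Generate a daily weather series
#'
#' Produces `years` complete calendar years of daily maximum/minimum
#' temperature and precipitation. Temperature is a sinusoidal annual cycle
#' plus AR(1) noise, recentred so the realized MAT equals the target exactly.
#' Precipitation occurrence is a Bernoulli process with amounts drawn from an
#' exponential distribution; month totals are rescaled so that the realized
#' MAP equals the target while the seasonal split and the wet/dry day pattern
#' are preserved. Annual totals vary with coefficient of variation
#' `interannual_cv` around the target.
#'
#' @param params a [weather_gen_params()] object
#' @return a `data.frame` with columns `year, month, day, doy, tmax, tmin,
#'   precip`, one row per day
#' @examples
#' w <- gen_daily_weather(weather_gen_params(8, 300, years = 3, seed = 42))
#' mean((w$tmax + w$tmin) / 2)  # ~8
#' @export
gen_daily_weather <- function(params) {
  stop_if(!inherits(params, "weather_gen_params"),
          "params must be created with weather_gen_params()")
  p <- params
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(p$seed)

  yrs <- seq(p$start_year, length.out = p$years)
  mlen <- lapply(yrs, month_lengths)
  ndays_y <- vapply(mlen, sum, integer(1))
  n <- sum(ndays_y)
  year <- rep(yrs, ndays_y)
  month <- unlist(lapply(mlen, function(m) rep.int(1:12, m)))
  day <- unlist(lapply(mlen, function(m) unlist(lapply(m, seq_len))))
  doy <- unlist(lapply(ndays_y, seq_len))

  # temperature: cycle + centred AR(1) noise, then exact recentring
  clim <- seasonal_temp(doy, p$mat_target, p$temp_seasonal_amplitude, p$lat)
  eps <- as.numeric(stats::filter(stats::rnorm(n, 0, p$temp_noise_sd),
                                  p$temp_noise_ar1, method = "recursive"))
  tmean <- clim + (eps - mean(eps))
  tmean <- tmean + (p$mat_target - mean(tmean))
  dtr <- pmax(1, stats::rnorm(n, p$diurnal_range, 1.5))
  tmax <- tmean + dtr / 2
  tmin <- tmean - dtr / 2

  # precipitation: monthly climatological targets from the seasonality split
  cold <- coldest_months(p$mat_target, p$temp_seasonal_amplitude, p$lat)
  share <- rep((1 - p$precip_seasonality) / 9, 12)
  share[cold] <- p$precip_seasonality / 3
  target_m <- p$map_target * share

  wet <- stats::runif(n) < p$wet_day_prob
  amount <- ifelse(wet, stats::rexp(n, rate = 1), 0)

  # interannual multipliers (lognormal, normalized to mean exactly 1) and
  # month-level variability; each year is rescaled to its annual target
  if (p$interannual_cv > 0) {
    sdl <- sqrt(log(1 + p$interannual_cv^2))
    m_y <- stats::rlnorm(p$years, -sdl^2 / 2, sdl)
    m_y <- m_y / mean(m_y)
  } else m_y <- rep(1, p$years)
  u_ym <- matrix(stats::rlnorm(p$years * 12, -0.3^2 / 2, 0.3), p$years, 12)

  precip <- numeric(n)
  for (yi in seq_len(p$years)) {
    sel_y <- year == yrs[yi]
    raw_m <- numeric(12)
    for (m in 1:12) {
      sel <- sel_y & month == m
      if (target_m[m] > 0 && !any(amount[sel] > 0)) {
        # force one wet day so a non-zero monthly target is attainable
        amount[which(sel)[1 + (yi + m) %% sum(sel)]] <- 1
      }
      raw_m[m] <- sum(amount[sel])
    }
    want_m <- target_m * u_ym[yi, ]
    want_m <- if (sum(want_m) > 0) want_m * (p$map_target * m_y[yi] / sum(want_m)) else want_m
    for (m in 1:12) {
      sel <- sel_y & month == m
      precip[sel] <- if (raw_m[m] > 0) amount[sel] * (want_m[m] / raw_m[m]) else 0
    }
  }

  data.frame(year = year, month = month, day = day, doy = doy,
             tmax = tmax, tmin = tmin, precip = precip)
}

# Campbell retention-curve parameters from texture via the Cosby et al.
# pedotransfer regressions: theta_sat, air-entry potential (MPa, negative)
# and shape exponent b; field capacity and wilting point evaluated on the
# curve at -0.033 and -1.5 MPa.
campbell_params <- function(sand, clay) {
  theta_sat <- 0.489 - 0.126 * sand
  psi_sat <- -(10^(1.88 - 1.31 * sand)) * 9.807e-5   # cm H2O -> MPa
  b <- 2.91 + 15.9 * clay
  fc <- theta_sat * (-0.033 / psi_sat)^(-1 / b)
  wp <- theta_sat * (-1.5 / psi_sat)^(-1 / b)
  list(theta_sat = theta_sat, psi_sat = psi_sat, b = b,
       field_capacity = fc, wilting_point = wp)
}

#' Generate a layered soil profile
#'
#' The top 0-20 cm is always split into two 10 cm layers (surface processes
#' are resolved there); deeper layers follow at 20 cm increments down to
#' `total_depth`. Hydraulic parameters per layer come from texture
#' regressions (Campbell retention curve).
#'
#' @param sand,clay texture fractions in `[0, 1]` with `sand + clay <= 1`
#' @param total_depth profile depth, cm (>= 20)
#' @param sand_gradient additive change in sand fraction per metre of depth
#'   (clamped so fractions stay valid); default 0 (uniform texture)
#' @return a `data.frame` of class `soil_profile` with columns `top, bottom,
#'   sand, clay, theta_sat, psi_sat, b, field_capacity, wilting_point` and an
#'   attribute `too_sandy` flagging profiles with any layer at >= 90% sand
#'   (such soils are excluded from the dryland study area).
#' @export
gen_soil_profile <- function(sand, clay, total_depth, sand_gradient = 0) {
  stop_if(sand < 0 || sand > 1 || clay < 0 || clay > 1 || sand + clay > 1,
          "sand and clay must be fractions with sand + clay <= 1")
  stop_if(total_depth < 20, "total_depth must be >= 20 cm")
  bounds <- c(0, 10, 20)
  if (total_depth > 20) bounds <- c(bounds, seq(40, by = 20,
      length.out = ceiling((total_depth - 20) / 20)))
  bounds[length(bounds)] <- total_depth
  top <- bounds[-length(bounds)]
  bottom <- bounds[-1]
  mid_m <- (top + bottom) / 200
  s <- pmin(1, pmax(0, sand + sand_gradient * mid_m))
  cl <- pmin(1 - s, pmax(0, clay))
  cp <- campbell_params(s, cl)
  prof <- data.frame(layer = seq_along(top), top = top, bottom = bottom,
                     sand = s, clay = cl,
                     theta_sat = cp$theta_sat, psi_sat = cp$psi_sat, b = cp$b,
                     field_capacity = cp$field_capacity,
                     wilting_point = cp$wilting_point)
  class(prof) <- c("soil_profile", "data.frame")
  attr(prof, "too_sandy") <- any(s >= 0.90)
  prof
}

#' Global raster geometry
#'
#' The analysis raster: 0.3125 degree square cells covering the globe, cell
#' centres at `-90 + (i + 0.5) * res` latitude and `-180 + (j + 0.5) * res`
#' longitude.
#'
#' @param resolution cell size in degrees (default 0.3125)
#' @return list with `nlon`, `nlat`, `n_cells`, `resolution`, and vectors
#'   `lat_centers`, `lon_centers`
#' @export
global_grid <- function(resolution = 0.3125) {
  stop_if(resolution <= 0, "resolution must be positive")
  nlon <- round(360 / resolution)
  nlat <- round(180 / resolution)
  list(nlon = nlon, nlat = nlat, n_cells = nlon * nlat,
       resolution = resolution,
       lat_centers = -90 + (seq_len(nlat) - 0.5) * resolution,
       lon_centers = -180 + (seq_len(nlon) - 0.5) * resolution)
}

snap_to_grid <- function(x, origin, resolution) {
  origin + (round((x - origin) / resolution - 0.5) + 0.5) * resolution
}

# parameter ranges per stratification target; drawn uniformly with jitter
.cell_strata <- list(
  temperate_dryland = list(mat = c(5, 11),  amp = c(11, 14), map = c(220, 380),
                           seas = c(0.40, 0.60), sand = c(0.30, 0.60),
                           lat = c(35, 48)),
  subtropical       = list(mat = c(16, 19), amp = c(5, 7),   map = c(260, 420),
                           seas = c(0.30, 0.45), sand = c(0.30, 0.60),
                           lat = c(28, 34)),
  boreal            = list(mat = c(0.3, 1.5), amp = c(10, 12), map = c(230, 330),
                           seas = c(0.30, 0.45), sand = c(0.30, 0.60),
                           lat = c(55, 62)),
  too_wet           = list(mat = c(6, 10),  amp = c(11, 14), map = c(950, 1250),
                           seas = c(0.30, 0.40), sand = c(0.30, 0.60),
                           lat = c(40, 50)),
  too_sandy         = list(mat = c(5, 11),  amp = c(11, 14), map = c(220, 380),
                           seas = c(0.40, 0.60), sand = c(0.92, 0.97),
                           lat = c(35, 48))
)

.regions <- c("North America", "South America", "Eastern Asia",
              "Western and Central Asia", "Western Mediterranean")

#' Generate a synthetic cell table
#'
#' Each cell carries a grid location (snapped to the 0.3125 degree raster), a
#' region label and the weather/soil generator parameters for that cell. With
#' `stratify = TRUE` (default) the cells cycle through five construction
#' targets -- temperate dryland, subtropical, boreal, too wet, too sandy --
#' so every branch of the dryland classifier is represented.
#'
#' @param n_cells number of cells (>= 1)
#' @param seed integer RNG seed
#' @param stratify cycle through classification strata (default `TRUE`);
#'   otherwise all cells are drawn from the temperate-dryland stratum
#' @param resolution grid resolution in degrees
#' @return `data.frame` with one row per cell: `cell_id, lat, lon, region,
#'   stratum, mat, temp_amp, map, precip_seasonality, wet_day_prob,
#'   interannual_cv, sand, clay, soil_depth, rh, wind, cloud`
#' @export
gen_cell_grid <- function(n_cells, seed = 1L, stratify = TRUE,
                          resolution = 0.3125) {
  stop_if(!is_count(n_cells), "n_cells must be a positive integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  strata <- if (stratify) {
    rep(names(.cell_strata), length.out = n_cells)
  } else rep("temperate_dryland", n_cells)
  runifr <- function(r, n = 1L) stats::runif(n, r[1], r[2])
  rows <- lapply(seq_len(n_cells), function(i) {
    s <- .cell_strata[[strata[i]]]
    lat <- snap_to_grid(runifr(s$lat), -90, resolution)
    lon <- snap_to_grid(stats::runif(1, -180, 180), -180, resolution)
    data.frame(cell_id = i, lat = lat, lon = lon,
               region = .regions[1 + (i - 1) %% length(.regions)],
               stratum = strata[i],
               mat = runifr(s$mat), temp_amp = runifr(s$amp),
               map = runifr(s$map), precip_seasonality = runifr(s$seas),
               wet_day_prob = stats::runif(1, 0.18, 0.3),
               interannual_cv = stats::runif(1, 0.1, 0.25),
               sand = (sv <- runifr(s$sand)),
               clay = stats::runif(1, 0.02, max(0.03, min(0.25, 1 - sv))),
               soil_depth = sample(c(100, 120, 140), 1),
               rh = stats::runif(1, 0.35, 0.65),
               wind = stats::runif(1, 1.5, 4.5),
               cloud = stats::runif(1, 0.3, 0.6))
  })
  do.call(rbind, rows)
}

#' Monthly climate normals from a daily series
#'
#' Averages a multi-year daily weather series into 12 monthly mean
#' temperatures and 12 mean monthly precipitation totals, plus MAT and MAP.
#' Only complete calendar years are accepted.
#'
#' @param weather daily weather `data.frame` (see [gen_daily_weather()])
#' @return list with `monthly_temp` (12), `monthly_precip` (12), `mat`,
#'   `map`, `n_years`
#' @export
monthly_normals <- function(weather) {
  check_weather(weather)
  yrs <- unique(weather$year)
  for (y in yrs) {
    stop_if(sum(weather$year == y) != sum(month_lengths(y)),
            paste0("year ", y, " is incomplete"))
  }
  tmean <- (weather$tmax + weather$tmin) / 2
  monthly_temp <- vapply(1:12, function(m) mean(tmean[weather$month == m]),
                         numeric(1))
  monthly_precip <- vapply(1:12, function(m)
    sum(weather$precip[weather$month == m]) / length(yrs), numeric(1))
  list(monthly_temp = monthly_temp, monthly_precip = monthly_precip,
       mat = mean(tmean), map = sum(monthly_precip), n_years = length(yrs))
}

#' GCM monthly change signal
#'
#' @param temp_delta_by_month 12 additive temperature deltas, degrees C
#' @param precip_ratio_by_month 12 multiplicative precipitation ratios (> 0)
#' @param gcm_label,rcp_label provenance labels
#' @return object of class `gcm_delta`
#' @export
gcm_delta_params <- function(temp_delta_by_month, precip_ratio_by_month,
                             gcm_label = "GCM", rcp_label = "RCP8.5") {
  stop_if(length(temp_delta_by_month) != 12 ||
          length(precip_ratio_by_month) != 12,
          "deltas and ratios must have 12 entries")
  stop_if(any(precip_ratio_by_month <= 0),
          "precipitation ratios must be strictly positive")
  structure(list(temp_delta = as.numeric(temp_delta_by_month),
                 precip_ratio = as.numeric(precip_ratio_by_month),
                 gcm_label = gcm_label, rcp_label = rcp_label),
            class = "gcm_delta")
}

#' Generate an ensemble of synthetic GCM change signals
#'
#' Emulates monthly projections from a GCM ensemble: annual warming drawn in
#' `warming_range` (default +3 to +7 C, the spread of end-of-century
#' high-emission projections) with small month-to-month structure, and
#' precipitation ratios within about +/- `precip_shift` of unity, optionally
#' tilted toward cold-season increases.
#'
#' @param n_gcm number of GCMs
#' @param seed integer RNG seed
#' @param warming_range range of annual-mean warming, degrees C
#' @param precip_shift half-width of the precipitation ratio perturbation
#' @param winter_tilt additive extra ratio applied to Dec-Feb (N hemisphere
#'   convention; the cold months of the consuming cell are resolved when the
#'   deltas are applied); default 0
#' @param rcp_label label attached to every member
#' @return list of [gcm_delta_params()] objects
#' @export
gen_gcm_deltas <- function(n_gcm, seed = 1L, warming_range = c(3, 7),
                           precip_shift = 0.2, winter_tilt = 0,
                           rcp_label = "RCP8.5") {
  stop_if(!is_count(n_gcm), "n_gcm must be a positive integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n_gcm), function(g) {
    warm <- stats::runif(1, warming_range[1], warming_range[2])
    td <- warm + stats::rnorm(12, 0, 0.5)
    base <- stats::runif(1, 1 - precip_shift, 1 + precip_shift)
    pr <- pmax(0.05, base * exp(stats::rnorm(12, 0, 0.05)))
    pr[c(12, 1, 2)] <- pr[c(12, 1, 2)] + winter_tilt
    gcm_delta_params(td, pr, gcm_label = sprintf("GCM%02d", g),
                     rcp_label = rcp_label)
  })
}
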