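# Shared fixtures: small deterministic objects rebuilt in code at test time.

tiny_weather <- function(years = 2, seed = 11, mat = 8, map = 300,
                         amp = 12, seas = 0.5, lat = 42, ...) {
  gen_daily_weather(weather_gen_params(
    mat, map, temp_seasonal_amplitude = amp, precip_seasonality = seas,
    years = years, seed = seed, lat = lat, ...))
}

tiny_profile <- function(sand = 0.45, clay = 0.2, depth = 100) {
  gen_soil_profile(sand, clay, depth)
}

tiny_veg <- function(weather = tiny_weather(), profile = tiny_profile()) {
  build_vegetation(monthly_normals(weather), profile)
}

tiny_sim <- function(years = 2, seed = 11, ...) {
  w <- tiny_weather(years = years, seed = seed, ...)
  p <- tiny_profile()
  simulate_water_balance(w, p, tiny_veg(w, p), lat = 42)
}

# independent run-length oracle: longest stretch of TRUE by explicit
# window extension (no rle)
brute_longest_run <- function(q) {
  best <- 0L
  for (s in seq_along(q)) {
    if (!q[s]) next
    e <- s
    while (e < length(q) && q[e + 1]) e <- e + 1L
    best <- max(best, e - s + 1L)
  }
  best
}

# independent monthly GCM series for downscaling tests
monthly_series <- function(years, temp_fn, precip_fn, start = 1960) {
  yrs <- rep(seq(start, length.out = years), each = 12)
  mos <- rep(1:12, years)
  data.frame(year = yrs, month = mos,
             temp = temp_fn(yrs, mos), precip = precip_fn(yrs, mos))
}
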