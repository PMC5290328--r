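test_that("weather generation is deterministic under a fixed seed", {
  p <- weather_gen_params(8, 300, years = 2, seed = 99)
  expect_identical(gen_daily_weather(p), gen_daily_weather(p))
  p2 <- weather_gen_params(8, 300, years = 2, seed = 100)
  expect_false(identical(gen_daily_weather(p), gen_daily_weather(p2)))
})

test_that("generated series hit their climate targets", {
  for (case in list(c(mat = 8, map = 300), c(mat = 2, map = 600),
                    c(mat = 15, map = 150))) {
    w <- gen_daily_weather(weather_gen_params(case[["mat"]], case[["map"]],
                                              years = 3, seed = 5))
    # recompute normals directly from the output
    mat_real <- mean((w$tmax + w$tmin) / 2)
    map_real <- sum(w$precip) / length(unique(w$year))
    expect_lt(abs(mat_real - case[["mat"]]), 0.5)
    expect_lt(abs(map_real - case[["map"]]) / case[["map"]], 0.1)
  }
})

test_that("precip_seasonality = 1 puts all precipitation in the coldest quarter", {
  w <- gen_daily_weather(weather_gen_params(5, 300, precip_seasonality = 1,
                                            years = 2, seed = 3, lat = 45))
  wet_months <- sort(unique(w$month[w$precip > 0]))
  expect_true(all(wet_months %in% c(12, 1, 2)))
  # southern hemisphere: winter flips to Jun-Aug
  ws <- gen_daily_weather(weather_gen_params(5, 300, precip_seasonality = 1,
                                             years = 2, seed = 3, lat = -45))
  expect_true(all(sort(unique(ws$month[ws$precip > 0])) %in% 6:8))
})

test_that("weather invariants hold across random parameter draws", {
  set.seed(42)
  for (k in 1:8) {
    p <- weather_gen_params(runif(1, -5, 20), runif(1, 100, 900),
                            temp_seasonal_amplitude = runif(1, 4, 18),
                            precip_seasonality = runif(1, 0, 1),
                            wet_day_prob = runif(1, 0.05, 0.6),
                            interannual_cv = runif(1, 0, 0.4),
                            years = 2, seed = k,
                            lat = runif(1, -60, 60))
    w <- gen_daily_weather(p)
    expect_true(all(w$tmax >= w$tmin))
    expect_true(all(w$precip >= 0))
    expect_equal(nrow(w), sum(vapply(unique(w$year),
      function(y) sum(drylandsim:::month_lengths(y)), integer(1))))
  }
})

test_that("invalid weather parameters are rejected", {
  expect_error(weather_gen_params(8, -10), "map_target")
  expect_error(weather_gen_params(8, 300, years = 1), "years")
  expect_error(weather_gen_params(8, 300, wet_day_prob = 0), "wet_day_prob")
  expect_error(gen_daily_weather(list()), "weather_gen_params")
})

test_that("soil profiles follow the layering convention", {
  p <- gen_soil_profile(0.4, 0.2, 100)
  expect_equal(p$top, c(0, 10, 20, 40, 60, 80))
  expect_equal(p$bottom, c(10, 20, 40, 60, 80, 100))
  p20 <- gen_soil_profile(0.4, 0.2, 20)
  expect_equal(nrow(p20), 2L)
  expect_equal(p20$bottom, c(10, 20))
  # non-multiple depth: last layer is partial
  p130 <- gen_soil_profile(0.4, 0.2, 130)
  expect_equal(max(p130$bottom), 130)
  expect_error(gen_soil_profile(0.4, 0.2, 15), "total_depth")
  expect_error(gen_soil_profile(0.8, 0.4, 100), "sand")
})

test_that("sandy profiles are flagged, and hydraulics are ordered", {
  sandy <- gen_soil_profile(0.95, 0.02, 60)
  expect_true(attr(sandy, "too_sandy"))
  expect_false(attr(gen_soil_profile(0.5, 0.2, 60), "too_sandy"))
  p <- gen_soil_profile(0.3, 0.3, 100)
  expect_true(all(p$wilting_point > 0))
  expect_true(all(p$wilting_point < p$field_capacity))
  expect_true(all(p$field_capacity < p$theta_sat))
  expect_true(all(p$psi_sat < 0))
})

test_that("global grid has the exact cell geometry", {
  g <- global_grid()
  expect_identical(g$n_cells, 1152 * 576)
  expect_equal(g$lat_centers[1], -90 + 0.5 * 0.3125)
  expect_equal(g$lon_centers[1], -179.84375)
  expect_equal(diff(g$lat_centers)[1], 0.3125)
})

test_that("stratified cell grids cover every classification stratum", {
  cells <- gen_cell_grid(5, seed = 2)
  expect_setequal(cells$stratum,
                  c("temperate_dryland", "subtropical", "boreal",
                    "too_wet", "too_sandy"))
  # cell centres sit on the global raster
  g <- global_grid()
  expect_true(all(cells$lat %in% g$lat_centers))
  expect_true(all(cells$lon %in% g$lon_centers))
  expect_identical(gen_cell_grid(7, seed = 9), gen_cell_grid(7, seed = 9))
})

test_that("monthly normals reduce daily series correctly", {
  # hand-built constant single year
  ml <- drylandsim:::month_lengths(1981L)
  w <- data.frame(year = 1981L, month = rep.int(1:12, ml),
                  day = unlist(lapply(ml, seq_len)), doy = 1:365,
                  tmax = 12, tmin = 8, precip = 1)
  nrm <- monthly_normals(w)
  expect_equal(nrm$monthly_temp, rep(10, 12))
  expect_equal(nrm$map, 365)
  expect_equal(nrm$monthly_precip, ml * 1)

  # multi-year: equals brute-force month-by-month averaging
  w3 <- tiny_weather(years = 3, seed = 8)
  nrm3 <- monthly_normals(w3)
  tmean <- (w3$tmax + w3$tmin) / 2
  for (m in c(1, 6, 11)) {
    expect_equal(nrm3$monthly_temp[m], mean(tmean[w3$month == m]))
    expect_equal(nrm3$monthly_precip[m],
                 sum(w3$precip[w3$month == m]) / 3)
  }
  expect_error(monthly_normals(w3[-1, ]), "incomplete")
})

test_that("GCM delta validation holds", {
  expect_error(gcm_delta_params(rep(1, 11), rep(1, 12)), "12 entries")
  expect_error(gcm_delta_params(rep(1, 12), c(rep(1, 11), 0)), "positive")
  d <- gen_gcm_deltas(3, seed = 4)
  expect_length(d, 3)
  expect_true(all(vapply(d, function(x) all(x$precip_ratio > 0), logical(1))))
  expect_identical(gen_gcm_deltas(3, seed = 4), d)
})
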