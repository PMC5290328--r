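test_that("PET responds to correction, temperature and day length", {
  base <- pet_daily(172, 45, 25, 10, 0.4, 2, 0.4, correction = 1)
  expect_equal(pet_daily(172, 45, 25, 10, 0.4, 2, 0.4, correction = 1.2),
               1.2 * base)

  # strictly increasing in temperature, all else fixed
  temps <- seq(-10, 35, by = 5)
  pets <- pet_daily(172, 45, temps + 8, temps - 3, 0.4, 2, 0.4)
  expect_true(all(diff(pets) > 0))

  # summer hemisphere beats winter hemisphere at identical temperature
  summer <- pet_daily(172, 45, 20, 5, 0.4, 2, 0.4)
  winter <- pet_daily(355, 45, 20, 5, 0.4, 2, 0.4)
  expect_gt(summer, winter)

  # polar night: non-negative and essentially zero
  polar <- pet_daily(172, -80, -15, -25, 0.7, 2, 0.5)
  expect_gte(polar, 0)
  expect_lt(polar, 0.05)
  expect_error(pet_daily(10, 95, 10, 0, 0.5, 2, 0.5), "lat")
})

test_that("retention curve behaves as a Campbell power law", {
  lay <- gen_soil_profile(0.45, 0.2, 20)[1, ]
  expect_equal(swp_from_theta(lay$theta_sat, lay), lay$psi_sat)
  th <- 0.3 * lay$theta_sat
  # halving theta makes psi more negative by exactly 2^b
  expect_equal(swp_from_theta(th / 2, lay) / swp_from_theta(th, lay),
               2^lay$b, tolerance = 1e-12)
  th_seq <- seq(0.05, lay$theta_sat, length.out = 20)
  expect_true(all(diff(swp_from_theta(th_seq, lay)) > 0))
  expect_error(swp_from_theta(0, lay), "theta")

  # psi/psi_sat at relative saturation r is r^(-b) per texture (closed form);
  # at equal absolute theta, clay is drier (more negative)
  sand_l <- gen_soil_profile(0.8, 0.05, 20)[1, ]
  clay_l <- gen_soil_profile(0.2, 0.45, 20)[1, ]
  rel <- 0.5
  for (l in list(sand_l, clay_l)) {
    expect_equal(swp_from_theta(rel * l$theta_sat, l) / l$psi_sat,
                 rel^(-l$b), tolerance = 1e-12)
  }
  expect_lt(swp_from_theta(0.18, clay_l), swp_from_theta(0.18, sand_l))
})

test_that("snow partition and degree-day melt", {
  ps <- partition_precip_snow(10, -5)
  expect_equal(ps$snowfall, 10)
  expect_equal(ps$rain, 0)
  ps2 <- partition_precip_snow(c(4, 6), c(-1, 3))
  expect_equal(ps2$rain + ps2$snowfall, c(4, 6))
  expect_equal(melt_snow(3, 10, coef = 2), 3)          # capped by storage
  expect_equal(melt_snow(100, 2, coef = 2), 4)         # 2 mm/C/day * 2 C
  expect_equal(melt_snow(100, -3, coef = 2), 0)
})

test_that("interception is capacity- and supply-capped", {
  ic0 <- intercept(8, 0, 0)
  expect_equal(ic0$throughfall, 8)
  expect_equal(ic0$interception_loss, 0)
  # capacity 2 mm (coef * mass = 2)
  ic1 <- intercept(1, 1000, 1000, coef = 0.001)
  expect_equal(ic1$interception_loss, 1)               # supply-capped
  ic2 <- intercept(10, 1000, 1000, coef = 0.001)
  expect_equal(ic2$interception_loss, 2)
  expect_equal(ic2$throughfall, 8)
  ic3 <- intercept(10, 1000, 1000, coef = 0.001, demand_cap = 0.5)
  expect_equal(ic3$interception_loss, 0.5)
})

test_that("cascading-bucket infiltration conserves water", {
  prof <- gen_soil_profile(0.45, 0.2, 40)
  thick10 <- (prof$bottom - prof$top) * 10
  fc_mm <- prof$field_capacity * thick10
  w_dry <- prof$wilting_point * thick10

  r0 <- infiltrate_and_percolate(0, w_dry, fc_mm)
  expect_equal(r0$w, w_dry)
  expect_equal(r0$deep_drainage, 0)

  # less than layer 1 deficit: all retained in layer 1
  d1 <- fc_mm[1] - w_dry[1]
  r1 <- infiltrate_and_percolate(d1 * 0.5, w_dry, fc_mm)
  expect_equal(r1$w[1], w_dry[1] + d1 * 0.5)
  expect_equal(r1$w[-1], w_dry[-1])

  # more than the whole profile deficit: excess drains
  tot_def <- sum(fc_mm - w_dry)
  r2 <- infiltrate_and_percolate(tot_def + 7, w_dry, fc_mm)
  expect_equal(r2$w, fc_mm)
  expect_equal(r2$deep_drainage, 7)
  expect_equal(sum(r2$w) - sum(w_dry) + r2$deep_drainage, tot_def + 7)
})

test_that("bare-soil evaporation follows the SWP stress ramp", {
  prof <- gen_soil_profile(0.45, 0.2, 60)
  thick10 <- (prof$bottom - prof$top) * 10
  params <- wb_params()
  w_sat <- prof$theta_sat * thick10
  psi <- swp_from_theta(prof$theta_sat, prof)
  r <- bare_soil_evap(w_sat, psi, 3, prof, params)
  expect_equal(r$evap, 3)                              # no stress

  w_dry <- drylandsim:::theta_from_swp(params$evap_dry_swp, prof) * thick10
  psi_d <- rep(params$evap_dry_swp, nrow(prof))
  expect_equal(bare_soil_evap(w_dry, psi_d, 3, prof, params)$evap, 0)

  # intermediate: equals the piecewise-linear factor times demand
  psi_mid <- rep(-7, nrow(prof))
  w_mid <- drylandsim:::theta_from_swp(-7, prof) * thick10
  fac <- (-7 - params$evap_dry_swp) / (params$evap_wet_swp - params$evap_dry_swp)
  r_mid <- bare_soil_evap(w_mid, psi_mid, 3, prof, params)
  expect_equal(r_mid$evap, 3 * fac, tolerance = 1e-9)
})

test_that("transpiration weights uptake by roots and stress", {
  prof <- gen_soil_profile(0.45, 0.2, 40)
  thick10 <- (prof$bottom - prof$top) * 10
  params <- wb_params()
  roots <- rbind(shrub = c(0.5, 0.5, 0), c3 = c(0, 0.6, 0.4))
  w <- prof$field_capacity * thick10
  psi <- swp_from_theta(prof$field_capacity, prof)
  r <- transpire(w, psi, pot = c(shrub = 2, c3 = 1), roots,
                 critical_swp = c(shrub = -3.9, c3 = -3.5), prof, params)
  expect_equal(unname(r$uptake["shrub", 3]), 0)        # no roots, no uptake
  expect_equal(unname(r$uptake["c3", 1]), 0)

  # all layers at or below critical: zero transpiration
  w_c <- drylandsim:::theta_from_swp(-3.9, prof) * thick10
  psi_c <- rep(-3.9, nrow(prof))
  r0 <- transpire(w_c, psi_c, c(shrub = 2, c3 = 1), roots,
                  c(shrub = -3.9, c3 = -3.5), prof, params)
  expect_equal(sum(r0$uptake), 0)

  # one wet, one dry layer: uptake follows the compensatory stress weights
  psi_mix <- c(-0.1, -3.0, -0.1)
  w_mix <- drylandsim:::theta_from_swp(psi_mix, prof) * thick10
  r1 <- transpire(w_mix, psi_mix, c(shrub = 1, c3 = 0),
                  rbind(shrub = c(0.5, 0.5, 0), c3 = c(0, 0.6, 0.4)),
                  c(shrub = -3.9, c3 = -3.5), prof, params)
  s_wet <- 1  # psi above wet limit
  s_dry <- (-3.0 + 3.9) / (params$transp_wet_swp + 3.9)
  wts <- c(0.5 * s_wet, 0.5 * s_dry, 0)
  exp_uptake <- 1 * wts / max(sum(wts), params$transp_demand_sat)
  expect_equal(unname(r1$uptake["shrub", ]), exp_uptake, tolerance = 1e-9)
  expect_gt(r1$uptake["shrub", 1], r1$uptake["shrub", 2])  # wet layer wins
  expect_lte(sum(r1$uptake), 1)
})

test_that("hydraulic redistribution conserves water and follows gradients", {
  prof <- gen_soil_profile(0.45, 0.2, 60)
  thick10 <- (prof$bottom - prof$top) * 10
  params <- wb_params()
  roots_tot <- rep(1 / nrow(prof), nrow(prof))

  w_even <- prof$field_capacity * thick10
  psi_even <- swp_from_theta(prof$field_capacity, prof)
  r0 <- hydraulic_redistribute(w_even, psi_even, roots_tot, prof, params)
  expect_equal(r0$flux, rep(0, nrow(prof)))

  # dry surface, wet deep: water moves upward into layer 1
  psi <- c(-5, -5, -0.05, -0.05)
  w <- drylandsim:::theta_from_swp(psi, prof) * thick10
  r1 <- hydraulic_redistribute(w, psi, roots_tot, prof, params)
  expect_gt(r1$flux[2], 0)
  expect_lt(r1$flux[3], 0)
  expect_equal(sum(r1$flux), 0, tolerance = 1e-12)

  set.seed(77)
  for (k in 1:10) {
    psi_r <- -runif(nrow(prof), 0.01, 10)
    w_r <- drylandsim:::theta_from_swp(psi_r, prof) * thick10
    rr <- hydraulic_redistribute(w_r, psi_r, roots_tot, prof, params)
    expect_equal(sum(rr$flux), 0, tolerance = 1e-9)
    expect_true(all(abs(rr$flux) <= 2 * params$hr_max_rate + 1e-12))
  }
})

test_that("simulation closes the water balance and bounds the stores", {
  sim <- tiny_sim(years = 3, seed = 21)
  expect_lt(max(abs(sim$fluxes$residual)), 1e-6)
  expect_true(all(sim$theta <= sim$profile$theta_sat[col(sim$theta)] + 1e-12))
  expect_true(all(sim$theta > 0))
  expect_true(all(sim$fluxes$swe >= 0))

  # annual AET <= PET and <= precip + initial storage
  aet <- sim$fluxes$evap + sim$fluxes$transp + sim$fluxes$interception
  for (y in unique(sim$year)) {
    sel <- sim$year == y
    expect_lte(sum(aet[sel]), sum(sim$fluxes$pet[sel]))
  }
  init_storage <- sum(sim$profile$field_capacity *
                        (sim$profile$bottom - sim$profile$top) * 10)
  expect_lte(sum(aet), sum(sim$fluxes$precip) + init_storage)
})

test_that("a rainless simulation only dries and never drains", {
  w <- tiny_weather(years = 2, seed = 3)
  w$precip <- 0
  prof <- tiny_profile()
  veg <- tiny_veg(tiny_weather(years = 2, seed = 3), prof)
  sim <- simulate_water_balance(w, prof, veg, lat = 42,
                                init = rep(prof$theta_sat[1], nrow(prof)))
  expect_true(all(diff(sim$fluxes$storage) <= 1e-12))
  expect_true(all(sim$fluxes$drainage[-1] == 0))
})

test_that("doubling precipitation never reduces annual transpiration", {
  for (seed in c(4, 9)) {
    w <- tiny_weather(years = 2, seed = seed)
    prof <- tiny_profile()
    veg <- tiny_veg(w, prof)
    s1 <- simulate_water_balance(w, prof, veg, lat = 42)
    w2 <- w; w2$precip <- 2 * w$precip
    s2 <- simulate_water_balance(w2, prof, veg, lat = 42)
    expect_gte(sum(s2$fluxes$transp), sum(s1$fluxes$transp))
  }
})

test_that("the simulator composes the exported daily operators exactly", {
  sim <- tiny_sim(years = 2, seed = 13)
  w <- tiny_weather(years = 2, seed = 13)
  prof <- sim$profile; veg <- sim$veg; params <- sim$params
  thick10 <- (prof$bottom - prof$top) * 10
  fc_mm <- prof$field_capacity * thick10
  sched <- veg$schedule
  groups <- rownames(veg$roots)
  roots_total <- colSums(veg$roots * veg$composition[groups])

  for (t in c(40, 200, 431, 600)) {
    w_prev <- sim$theta[t - 1, ] * thick10
    swe_prev <- sim$fluxes$swe[t - 1]
    m <- w$month[t]
    tmean <- (w$tmax[t] + w$tmin[t]) / 2
    pet <- pet_daily(w$doy[t], 42, w$tmax[t], w$tmin[t], 0.5, 2, 0.5,
                     correction = params$pet_correction)
    ps <- partition_precip_snow(w$precip[t], tmean, params$snow_temp)
    swe <- swe_prev + ps$snowfall
    melt <- melt_snow(swe, tmean, params$melt_coef, params$melt_temp)
    swe <- swe - melt
    bm <- sum(sched$biomass[sched$month == m])
    lt <- sum(sched$litter[sched$month == m])
    ic <- intercept(ps$rain + melt, bm, lt, params$intercept_coef,
                    demand_cap = pet)
    pet_rem <- pet - ic$interception_loss
    inf <- infiltrate_and_percolate(ic$throughfall, w_prev, fc_mm)
    ww <- inf$w
    psi <- swp_from_theta(pmax(ww / thick10, 1e-9), prof)
    live_g <- vapply(groups, function(g)
      sched$biomass[sched$group == g & sched$month == m] *
        sched$live_frac[sched$group == g & sched$month == m], numeric(1))
    cover <- min(1, sum(live_g) / params$cover_ref)
    share <- if (sum(live_g) > 0) live_g / sum(live_g) else rep(0, 3)
    ev <- bare_soil_evap(ww, psi, pet_rem * (1 - cover), prof, params)
    ww <- ev$w
    psi <- swp_from_theta(pmax(ww / thick10, 1e-9), prof)
    pt <- if (w$tmin[t] > params$transp_frost_temp) pet_rem * cover else 0
    tr <- transpire(ww, psi, pt * share, veg$roots,
                    veg$critical_swp, prof, params)
    ww <- tr$w
    psi <- swp_from_theta(pmax(ww / thick10, 1e-9), prof)
    hr <- hydraulic_redistribute(ww, psi, roots_total, prof, params)
    ww <- hr$w

    expect_equal(ww, sim$theta[t, ] * thick10, tolerance = 1e-10)
    expect_equal(sim$fluxes$evap[t], ev$evap, tolerance = 1e-10)
    expect_equal(sim$fluxes$transp[t], sum(tr$transp_layer),
                 tolerance = 1e-10)
    expect_equal(sim$fluxes$drainage[t], inf$deep_drainage,
                 tolerance = 1e-10)
    expect_equal(sim$fluxes$swe[t], swe, tolerance = 1e-10)
  }
})

test_that("compiled and reference engines produce identical trajectories", {
  w <- tiny_weather(years = 2, seed = 55)
  prof <- tiny_profile(sand = 0.35, clay = 0.25, depth = 120)
  veg <- tiny_veg(w, prof)
  s_cpp <- simulate_water_balance(w, prof, veg, lat = 42, engine = "cpp")
  s_r <- simulate_water_balance(w, prof, veg, lat = 42, engine = "r")
  expect_lt(max(abs(s_cpp$theta - s_r$theta)), 1e-10)
  expect_lt(max(abs(s_cpp$transp_layer - s_r$transp_layer)), 1e-10)
  expect_lt(max(abs(as.matrix(s_cpp$fluxes) - as.matrix(s_r$fluxes))), 1e-9)
})
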