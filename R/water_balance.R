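# Daily, multi-layer, process-based ecosystem water balance for one cell.
# The daily operator order is fixed (and closure depends on it):
#   PET -> snow partition/melt -> interception -> infiltration/percolation
#       -> bare-soil evaporation -> transpiration -> hydraulic redistribution
# All stores are in mm of water; volumetric content theta converts via
# layer thickness (cm) * 10. Soil water potential follows a Campbell
# power-law retention curve with texture-derived parameters.

#' Water-balance parameters
#'
#' Process parameters of the daily simulator, all exposed here so no hidden
#' constants exist in the code path.
#'
#' @param pet_correction multiplier applied to the Penman estimate
#'   (default 1.2, compensating the dry-region low bias of reanalysis-driven
#'   Penman PET)
#' @param snow_temp snow/rain partition threshold on daily mean temperature, C
#' @param melt_coef degree-day melt coefficient, mm/C/day
#' @param melt_temp melt threshold temperature, C
#' @param intercept_coef canopy+litter interception capacity per unit
#'   biomass, mm per (g/m2)
#' @param evap_depth depth of soil subject to bare-soil evaporation, cm
#' @param evap_wet_swp,evap_dry_swp SWP (MPa) bounds of the evaporation
#'   stress ramp (1 at/above wet, 0 at/below dry)
#' @param transp_wet_swp SWP (MPa) at/above which transpiration is
#'   unstressed; the dry end is the per-group critical SWP
#' @param transp_demand_sat saturation point of compensatory root water
#'   uptake: with layer weights `w_l = root_l * stress_l` and
#'   `S = sum(w_l)`, uptake is `pot * w_l / max(S, transp_demand_sat)` --
#'   demand unmet in stressed layers redistributes to wetter rooted layers,
#'   and the full potential is reached once S exceeds this value. Set to 1
#'   to disable compensation (uptake then equals `pot * w_l`)
#' @param cover_ref live biomass (g/m2) giving full canopy cover
#' @param transp_frost_temp daily minimum temperature (C) at or below which
#'   transpiration shuts off entirely (stomata closed on frost days,
#'   consistent with the frost-free definition of the growing period); set
#'   to `-Inf` to disable the gate
#' @param hr_enabled enable hydraulic redistribution
#' @param hr_max_rate cap on redistribution between a layer pair, mm/day
#' @param hr_coef redistribution rate per MPa of potential difference,
#'   mm/day/MPa
#' @param residual_swp SWP (MPa) defining the immobile residual water content
#' @return named list of class `wb_params`
#' @export
wb_params <- function(pet_correction = 1.2,
                      snow_temp = 0, melt_coef = 2, melt_temp = 0,
                      intercept_coef = 0.0015,
                      evap_depth = 15, evap_wet_swp = -0.2,
                      evap_dry_swp = -15,
                      transp_wet_swp = -0.2,
                      transp_demand_sat = 0.5,
                      cover_ref = 300,
                      transp_frost_temp = 0,
                      hr_enabled = TRUE, hr_max_rate = 0.1, hr_coef = 0.05,
                      residual_swp = -100) {
  structure(as.list(environment()), class = "wb_params")
}

#' Daily potential evapotranspiration (Penman-family, day-length aware)
#'
#' A Penman combination estimate: radiation term from extraterrestrial
#' radiation attenuated by cloud cover, aerodynamic term from vapour
#' pressure deficit and wind, weighted by the slope of the saturation
#' vapour-pressure curve. The aerodynamic term scales with relative day
#' length, so at equal temperature the summer hemisphere has the larger
#' PET. The result is floored at zero and multiplied by `correction`.
#' Vectorized over days.
#'
#' @param doy day of year (1-366)
#' @param lat latitude, degrees, in `[-90, 90]`
#' @param tmax,tmin daily temperature extremes, C
#' @param rh mean relative humidity, fraction
#' @param wind mean wind speed, m/s
#' @param cloud mean cloud cover, fraction
#' @param correction multiplicative PET correction (default 1.2)
#' @return PET, mm/day (>= 0)
#' @export
pet_daily <- function(doy, lat, tmax, tmin, rh, wind, cloud,
                      correction = 1.2) {
  stop_if(any(lat < -90 | lat > 90), "lat must lie in [-90, 90]")
  tmean <- (tmax + tmin) / 2
  latr <- lat * pi / 180
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(1, pmax(-1, -tan(latr) * tan(decl)))
  ws <- acos(x)                       # sunset hour angle
  daylen <- 24 / pi * ws
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  ra <- (24 * 60 / pi) * 0.082 * dr *
    (ws * sin(latr) * sin(decl) + cos(latr) * cos(decl) * sin(ws))
  ra <- pmax(0, ra)                   # MJ m-2 d-1
  rs <- (0.25 + 0.5 * (1 - cloud)) * ra
  e0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  es <- (e0(tmax) + e0(tmin)) / 2
  ea <- rh * es
  rso <- pmax(0.75 * ra, 1e-9)
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) *
    pmax(0, 1.35 * pmin(rs / rso, 1) - 0.35)
  rn <- pmax(0, 0.77 * rs - rnl)
  delta <- 4098 * e0(tmean) / (tmean + 237.3)^2
  gamma <- 0.066
  aero <- 2.6 * (1 + 0.536 * wind) * pmax(0, es - ea) * (daylen / 12)
  pet <- (delta * rn / 2.45 + gamma * aero) / (delta + gamma)
  pmax(0, pet) * correction
}

#' Soil water potential from volumetric water content
#'
#' Campbell retention curve `psi = psi_sat * (theta/theta_sat)^(-b)` with
#' `psi_sat < 0` (MPa); more negative = drier; strictly increasing in theta.
#'
#' @param theta volumetric water content, fraction (> 0); values above
#'   saturation are clamped to saturation
#' @param layer a row of a `soil_profile` (or vectors `theta_sat`, `psi_sat`,
#'   `b` via `...` equivalents in the row)
#' @return SWP, MPa (<= psi_sat)
#' @export
swp_from_theta <- function(theta, layer) {
  stop_if(any(theta <= 0), "theta must be positive")
  rel <- pmin(1, theta / layer$theta_sat)
  layer$psi_sat * rel^(-layer$b)
}

# inverse: theta at a given psi (psi <= psi_sat), vectorized over layers
theta_from_swp <- function(psi, layer) {
  layer$theta_sat * (psi / layer$psi_sat)^(-1 / layer$b)
}

#' Partition precipitation into rain and snowfall
#'
#' All precipitation falls as snow below the threshold daily mean
#' temperature, as rain at or above it. Vectorized.
#'
#' @param precip precipitation, mm (>= 0)
#' @param tmean daily mean temperature, C
#' @param threshold partition temperature, C (default 0)
#' @return list with `rain` and `snowfall`, `rain + snowfall == precip`
#' @export
partition_precip_snow <- function(precip, tmean, threshold = 0) {
  stop_if(any(precip < 0), "precip must be >= 0")
  snow <- ifelse(tmean < threshold, precip, 0)
  list(rain = precip - snow, snowfall = snow)
}

#' Degree-day snowmelt
#'
#' @param swe snow water equivalent, mm (>= 0)
#' @param tmean daily mean temperature, C
#' @param coef melt coefficient, mm/C/day
#' @param threshold melt threshold, C
#' @return melt, mm (capped at `swe`)
#' @export
melt_snow <- function(swe, tmean, coef = 2, threshold = 0) {
  pmin(swe, coef * pmax(0, tmean - threshold))
}

#' Canopy and litter interception
#'
#' Intercepted water evaporates; the rest reaches the soil as throughfall.
#' The interception capacity scales with standing biomass plus litter.
#'
#' @param precip_liquid liquid water reaching the canopy (rain + melt), mm
#' @param biomass standing biomass, g/m2
#' @param litter litter mass, g/m2
#' @param coef capacity per unit mass, mm per (g/m2)
#' @param demand_cap upper bound from remaining atmospheric demand, mm
#'   (default `Inf`)
#' @return list with `interception_loss` and `throughfall`
#' @export
intercept <- function(precip_liquid, biomass, litter, coef = 0.0015,
                      demand_cap = Inf) {
  stop_if(any(precip_liquid < 0) || any(biomass < 0) || any(litter < 0),
          "inputs must be >= 0")
  capacity <- coef * (biomass + litter)
  loss <- pmin(precip_liquid, capacity, demand_cap)
  list(interception_loss = loss, throughfall = precip_liquid - loss)
}

#' Cascading-bucket infiltration and percolation
#'
#' Water entering the soil fills each layer toward field capacity from the
#' top; the excess percolates to the next layer; water leaving the bottom
#' layer is deep drainage. Mass is conserved exactly.
#'
#' @param water_in infiltrating water, mm (>= 0)
#' @param w per-layer soil water, mm
#' @param fc_mm per-layer field capacity, mm
#' @return list with updated `w`, `percolation` (mm passing each layer's
#'   bottom) and `deep_drainage` (mm)
#' @export
infiltrate_and_percolate <- function(water_in, w, fc_mm) {
  stop_if(water_in < 0, "water_in must be >= 0")
  deficit <- pmax(0, fc_mm - w)
  cum_before <- cumsum(c(0, deficit[-length(deficit)]))
  retained <- pmin(deficit, pmax(0, water_in - cum_before))
  perc <- water_in - cumsum(retained)
  list(w = w + retained, percolation = perc,
       deep_drainage = perc[length(perc)])
}

# piecewise-linear stress ramp on psi: 1 at/above wet, 0 at/below dry
swp_stress <- function(psi, wet, dry) {
  pmin(1, pmax(0, (psi - dry) / (wet - dry)))
}

#' Bare-soil evaporation
#'
#' Removes water from layers within the evaporation depth, at the potential
#' rate scaled by a piecewise-linear stress ramp on each layer's SWP
#' (1 at/above the wet limit, 0 at/below the dry limit). Demand is shared
#' across evaporating layers in proportion to their thickness within the
#' evaporation depth.
#'
#' @param w per-layer soil water, mm
#' @param psi per-layer SWP, MPa
#' @param pet_share evaporative demand reaching the soil surface, mm
#' @param profile `soil_profile`
#' @param params `wb_params`
#' @return list with updated `w` and `evap` (total mm, <= pet_share)
#' @export
bare_soil_evap <- function(w, psi, pet_share, profile, params = wb_params()) {
  stop_if(pet_share < 0, "pet_share must be >= 0")
  depth_in <- pmax(0, pmin(profile$bottom, params$evap_depth) - profile$top)
  if (sum(depth_in) == 0 || pet_share == 0) {
    return(list(w = w, evap = 0))
  }
  wt <- depth_in / sum(depth_in)
  stress <- swp_stress(psi, params$evap_wet_swp, params$evap_dry_swp)
  demand <- pet_share * wt * stress
  floor_mm <- theta_from_swp(params$evap_dry_swp, profile) *
    (profile$bottom - profile$top) * 10
  take <- pmin(demand, pmax(0, w - floor_mm))
  list(w = w - take, evap = sum(take))
}

#' Per-layer, per-group transpiration
#'
#' Uptake per layer is proportional to the product of the group's root
#' fraction and a stress factor that is 1 at/above the wet SWP limit and 0
#' at/below the group's critical SWP (piecewise-linear between). Uptake is
#' compensatory: demand that stressed layers cannot meet redistributes to
#' wetter rooted layers (see `transp_demand_sat` in [wb_params()]), and the
#' total never exceeds the potential. Uptake is additionally capped by the
#' water held above the critical content of each layer.
#'
#' @param w per-layer soil water, mm
#' @param psi per-layer SWP, MPa
#' @param pot per-group potential transpiration, mm (named shrub/c3/c4)
#' @param roots group x layer root-fraction matrix
#' @param critical_swp per-group critical SWP, MPa
#' @param profile `soil_profile`
#' @param params `wb_params`
#' @return list with updated `w`, `uptake` (group x layer matrix, mm) and
#'   `transp_layer` (per-layer totals)
#' @export
transpire <- function(w, psi, pot, roots, critical_swp, profile,
                      params = wb_params()) {
  nl <- length(w)
  uptake <- matrix(0, nrow(roots), nl, dimnames = dimnames(roots))
  thick10 <- (profile$bottom - profile$top) * 10
  for (g in seq_len(nrow(roots))) {
    if (pot[g] <= 0) next
    crit <- critical_swp[g]
    stress <- swp_stress(psi, params$transp_wet_swp, crit)
    wl <- roots[g, ] * stress
    demand <- pot[g] * wl / max(sum(wl), params$transp_demand_sat)
    floor_mm <- theta_from_swp(crit, profile) * thick10
    take <- pmin(demand, pmax(0, w - floor_mm))
    uptake[g, ] <- take
    w <- w - take
  }
  list(w = w, uptake = uptake, transp_layer = colSums(uptake))
}

#' Hydraulic redistribution between adjacent layers
#'
#' Passive, root-mediated movement of water from wetter (higher SWP) to
#' drier (lower SWP) adjacent layers. The flux between a pair is
#' proportional to the potential difference, capped at `hr_max_rate`, and
#' limited so the donor stays above residual water and the recipient below
#' saturation. The net flux over all layers is zero by construction.
#'
#' @param w per-layer soil water, mm
#' @param psi per-layer SWP, MPa
#' @param roots_total per-layer total root fraction (across groups,
#'   normalized); redistribution scales with the smaller of the pair
#' @param profile `soil_profile`
#' @param params `wb_params`
#' @return list with updated `w` and `flux` (signed per-layer mm; positive =
#'   water received)
#' @export
hydraulic_redistribute <- function(w, psi, roots_total, profile,
                                   params = wb_params()) {
  nl <- length(w)
  flux <- numeric(nl)
  if (!params$hr_enabled || nl < 2) return(list(w = w, flux = flux))
  thick10 <- (profile$bottom - profile$top) * 10
  resid_mm <- theta_from_swp(params$residual_swp, profile) * thick10
  sat_mm <- profile$theta_sat * thick10
  i <- seq_len(nl - 1)
  dpsi <- psi[i] - psi[i + 1]          # >0: upper wetter, water moves down
  amt <- pmin(params$hr_max_rate,
              params$hr_coef * abs(dpsi) * pmin(roots_total[i],
                                                roots_total[i + 1]) * nl)
  donor <- ifelse(dpsi > 0, i, i + 1)
  recip <- ifelse(dpsi > 0, i + 1, i)
  # each layer can appear as donor in at most two pairs: cap at half its
  # mobile water so a single vectorized pass cannot overdraw
  amt <- pmin(amt,
              0.5 * pmax(0, w[donor] - resid_mm[donor]),
              0.5 * pmax(0, sat_mm[recip] - w[recip]))
  amt[abs(dpsi) < 1e-12] <- 0
  for (k in i) {
    flux[donor[k]] <- flux[donor[k]] - amt[k]
    flux[recip[k]] <- flux[recip[k]] + amt[k]
  }
  list(w = w + flux, flux = flux)
}

#' Simulate the daily ecosystem water balance of one cell
#'
#' Runs the full daily operator chain over a multi-year weather series and
#' returns the complete water-budget ledger. The first simulated year is
#' conventionally treated as spin-up by downstream aggregation (it is kept
#' in the output). Deterministic: no randomness is used.
#'
#' @param weather daily weather table (see [gen_daily_weather()])
#' @param profile `soil_profile`
#' @param veg vegetation description from [build_vegetation()]
#' @param lat latitude, degrees
#' @param rh,wind,cloud mean monthly (here climatological) relative
#'   humidity, wind speed (m/s) and cloud cover; scalars or vectors of 12
#' @param params `wb_params`
#' @param init `"field_capacity"` (default), `"wilting_point"`, or a numeric
#'   vector of initial per-layer theta
#' @param engine `"cpp"` (compiled inner loop, default) or `"r"` (reference
#'   implementation composing the exported operator functions); both produce
#'   the same trajectories to floating-point accuracy
#' @return list of class `wb_simulation`: `fluxes` (data.frame, one row per
#'   day: pet, precip, rain, snowfall, melt, swe, interception, infiltration,
#'   evap, transp, drainage, hr_abs, storage, residual), `theta` (day x
#'   layer), `transp_layer` (day x layer), `transp_group` (day x group),
#'   plus the inputs (`profile`, `veg`, `params`, and the `weather` columns
#'   year/month/doy/tmin for downstream metrics)
#' @export
simulate_water_balance <- function(weather, profile, veg, lat = 40,
                                   rh = 0.5, wind = 2, cloud = 0.5,
                                   params = wb_params(),
                                   init = "field_capacity",
                                   engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  check_weather(weather)
  stop_if(!inherits(profile, "soil_profile"), "profile must be a soil_profile")
  stop_if(length(unique(weather$year)) < 2,
          "at least 2 simulated years are required (the first is spin-up)")
  n <- nrow(weather)
  nl <- nrow(profile)
  thick10 <- (profile$bottom - profile$top) * 10
  fc_mm <- profile$field_capacity * thick10
  month <- weather$month
  tmean <- (weather$tmax + weather$tmin) / 2

  rh12 <- rep(rh, length.out = 12)
  wind12 <- rep(wind, length.out = 12)
  cloud12 <- rep(cloud, length.out = 12)
  pet <- pet_daily(weather$doy, lat, weather$tmax, weather$tmin,
                   rh12[month], wind12[month], cloud12[month],
                   correction = params$pet_correction)
  ps <- partition_precip_snow(weather$precip, tmean, params$snow_temp)
  rain <- ps$rain; snowfall <- ps$snowfall

  # monthly vegetation lookups
  sched <- veg$schedule
  groups <- rownames(veg$roots)
  live_gm <- vapply(groups, function(g)
    sched$biomass[sched$group == g] * sched$live_frac[sched$group == g],
    numeric(12))                                   # 12 x 3
  biomass_m <- vapply(1:12, function(m)
    sum(sched$biomass[sched$month == m]), numeric(1))
  litter_m <- vapply(1:12, function(m)
    sum(sched$litter[sched$month == m]), numeric(1))
  live_tot_m <- rowSums(live_gm)
  cover_m <- pmin(1, live_tot_m / params$cover_ref)
  share_gm <- live_gm / ifelse(live_tot_m > 0, live_tot_m, 1)  # 12 x 3

  roots_total <- colSums(veg$roots * veg$composition[groups])

  w <- switch(if (is.character(init)) init else "numeric",
              field_capacity = fc_mm,
              wilting_point = profile$wilting_point * thick10,
              as.numeric(init) * thick10)
  swe <- 0

  # hot-loop constants as plain vectors (the loop body inlines the daily
  # operators for speed; test-water-balance verifies it composes the
  # exported operator functions exactly)
  theta_sat <- profile$theta_sat; psi_sat <- profile$psi_sat
  b <- profile$b; neg_b <- -b
  sat_mm <- theta_sat * thick10
  resid_mm <- theta_from_swp(params$residual_swp, profile) * thick10
  evap_floor <- theta_from_swp(params$evap_dry_swp, profile) * thick10
  depth_in <- pmax(0, pmin(profile$bottom, params$evap_depth) - profile$top)
  evap_wt <- if (sum(depth_in) > 0) depth_in / sum(depth_in) else depth_in
  ngr <- length(groups)
  crit_floor <- matrix(0, ngr, nl)
  for (g in seq_len(ngr)) {
    crit_floor[g, ] <- theta_from_swp(veg$critical_swp[g], profile) * thick10
  }
  crit_g <- as.numeric(veg$critical_swp)
  wet_t <- params$transp_wet_swp
  demand_sat <- params$transp_demand_sat
  wet_e <- params$evap_wet_swp; dry_e <- params$evap_dry_swp
  hr_on <- params$hr_enabled && nl >= 2
  hr_pairs <- seq_len(nl - 1)
  hr_root <- pmin(roots_total[hr_pairs], roots_total[hr_pairs + 1]) * nl
  zero_l <- numeric(nl)
  icap_m <- params$intercept_coef * (biomass_m + litter_m)
  roots_g <- veg$roots

  if (engine == "cpp") {
    res <- wb_daily_loop(weather$precip, rain, snowfall, tmean, pet,
                         as.integer(month), fc_mm, sat_mm, resid_mm,
                         evap_floor, evap_wt, psi_sat, b, thick10,
                         roots_g, crit_floor, crit_g, icap_m, cover_m,
                         share_gm, hr_root, w,
                         weather$tmin > params$transp_frost_temp,
                         wet_t, demand_sat, wet_e, dry_e,
                         params$melt_coef, params$melt_temp, hr_on,
                         params$hr_max_rate, params$hr_coef)
    theta_out <- res$theta
    transp_layer_out <- res$transp_layer
    transp_group_out <- res$transp_group
    dimnames(transp_group_out) <- list(NULL, groups)
    melt_v <- res$melt; swe_v <- res$swe; iloss_v <- res$iloss
    thru_v <- res$thru; evap_v <- res$evap; transp_v <- res$transp
    drain_v <- res$drain; hrabs_v <- res$hr_abs; stor_v <- res$storage
  } else {
  theta_out <- matrix(0, n, nl)
  transp_layer_out <- matrix(0, n, nl)
  transp_group_out <- matrix(0, n, ngr, dimnames = list(NULL, groups))
  melt_v <- swe_v <- iloss_v <- thru_v <- evap_v <- transp_v <- drain_v <-
    hrabs_v <- stor_v <- numeric(n)
  psi_of <- function(w) psi_sat * pmin(1, pmax(w / sat_mm, 1e-9))^neg_b

  for (t in seq_len(n)) {
    m <- month[t]
    swe <- swe + snowfall[t]
    melt <- min(swe, params$melt_coef * max(0, tmean[t] - params$melt_temp))
    swe <- swe - melt
    liquid <- rain[t] + melt

    iloss <- min(liquid, icap_m[m], pet[t])
    thru <- liquid - iloss
    pet_rem <- pet[t] - iloss

    # cascading-bucket infiltration
    deficit <- fc_mm - w
    deficit[deficit < 0] <- 0
    cum_after <- cumsum(deficit)
    retained <- pmin(deficit, pmax(0, thru - (cum_after - deficit)))
    w <- w + retained
    drain <- thru - sum(retained)

    psi <- psi_of(w)

    # bare-soil evaporation
    pe <- pet_rem * (1 - cover_m[m])
    if (pe > 0) {
      stress <- (psi - dry_e) / (wet_e - dry_e)
      stress[stress < 0] <- 0; stress[stress > 1] <- 1
      take <- pmin(pe * evap_wt * stress, pmax(0, w - evap_floor))
      w <- w - take
      evap <- sum(take)
      psi <- psi_of(w)
    } else evap <- 0

    # transpiration per group (stress from the psi at entry, as transpire());
    # frost days carry no transpiration
    pt <- if (weather$tmin[t] > params$transp_frost_temp)
      pet_rem * cover_m[m] else 0
    tl <- zero_l
    if (pt > 0) {
      for (g in seq_len(ngr)) {
        pot <- pt * share_gm[m, g]
        if (pot <= 0) next
        stress <- (psi - crit_g[g]) / (wet_t - crit_g[g])
        stress[stress < 0] <- 0; stress[stress > 1] <- 1
        wl <- roots_g[g, ] * stress
        take <- pmin(pot * wl / max(sum(wl), demand_sat),
                     pmax(0, w - crit_floor[g, ]))
        w <- w - take
        tl <- tl + take
        transp_group_out[t, g] <- sum(take)
      }
      psi <- psi_of(w)
    }
    transp_tot <- sum(tl)

    # hydraulic redistribution (single vectorized pass over adjacent pairs)
    hr_abs <- 0
    if (hr_on) {
      i <- hr_pairs
      dpsi <- psi[i] - psi[i + 1]
      adpsi <- abs(dpsi)
      if (any(adpsi > 1e-12)) {
        amt <- pmin(params$hr_max_rate, params$hr_coef * adpsi * hr_root)
        down <- dpsi > 0
        donor <- i + !down
        recip <- i + down
        amt <- pmin(amt, 0.5 * pmax(0, w[donor] - resid_mm[donor]),
                    0.5 * pmax(0, sat_mm[recip] - w[recip]))
        amt[adpsi < 1e-12] <- 0
        flux <- zero_l
        for (k in i) {
          flux[donor[k]] <- flux[donor[k]] - amt[k]
          flux[recip[k]] <- flux[recip[k]] + amt[k]
        }
        w <- w + flux
        hr_abs <- sum(abs(flux))
      }
    }

    theta_out[t, ] <- w / thick10
    transp_layer_out[t, ] <- tl
    melt_v[t] <- melt; swe_v[t] <- swe; iloss_v[t] <- iloss
    thru_v[t] <- thru; evap_v[t] <- evap; transp_v[t] <- transp_tot
    drain_v[t] <- drain; hrabs_v[t] <- hr_abs; stor_v[t] <- sum(w)
  }
  }

  stor_prev <- c(sum(switch(if (is.character(init)) init else "numeric",
                            field_capacity = fc_mm,
                            wilting_point = profile$wilting_point * thick10,
                            as.numeric(init) * thick10)),
                 stor_v[-n])
  swe_prev <- c(0, swe_v[-n])
  residual <- weather$precip - (swe_v - swe_prev) - (stor_v - stor_prev) -
    iloss_v - evap_v - transp_v - drain_v
  fx <- cbind(pet = pet, precip = weather$precip, rain = rain,
              snowfall = snowfall, melt = melt_v, swe = swe_v,
              interception = iloss_v, infiltration = thru_v, evap = evap_v,
              transp = transp_v, drainage = drain_v, hr_abs = hrabs_v,
              storage = stor_v, residual = residual)

  structure(list(fluxes = as.data.frame(fx),
                 theta = theta_out,
                 transp_layer = transp_layer_out,
                 transp_group = transp_group_out,
                 year = weather$year, month = month, doy = weather$doy,
                 tmin = weather$tmin,
                 profile = profile, veg = veg, params = params),
            class = "wb_simulation")
}
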