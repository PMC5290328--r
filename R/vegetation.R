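# Potential vegetation from cell climate: composition of the three dryland
# functional groups (shrubs, C3 grasses, C4 grasses), monthly biomass and
# phenology schedules, and rooting-depth profiles. Composition and phenology
# are climate relationships with configurable coefficients; the defaults are
# chosen to satisfy the directional behaviour expected of dryland vegetation
# (C4 favoured by warm/wet growing seasons, C3 by winter precipitation,
# shrubs by aridity) rather than to reproduce any specific regression.

#' Default vegetation parameters
#'
#' @param beta per-group root-distribution decay parameters (dimensionless,
#'   in (0,1); larger = deeper roots). Defaults follow published global root
#'   syntheses: shrubs root deepest.
#' @param critical_swp per-group soil water potential (MPa) below which water
#'   extraction ceases
#' @param biomass_cap per-group peak aboveground biomass at unlimited
#'   precipitation, g/m2
#' @param map_ref precipitation (mm/yr) at which biomass saturates
#' @param t_base per-group temperature (C) at which the growing season opens
#' @param t_ramp temperature ramp width (C) over which live fraction rises
#'   from 0 to 1
#' @param max_root_depth per-group maximum rooting depth, cm
#' @return named list of parameter sets
#' @export
veg_params <- function(beta = c(shrub = 0.964, c3 = 0.943, c4 = 0.943),
                       critical_swp = c(shrub = -3.9, c3 = -3.5, c4 = -3.5),
                       biomass_cap = c(shrub = 900, c3 = 700, c4 = 700),
                       map_ref = 600,
                       t_base = c(shrub = 4, c3 = 2, c4 = 8),
                       t_ramp = 6,
                       max_root_depth = c(shrub = 200, c3 = 120, c4 = 120)) {
  stop_if(any(beta <= 0 | beta >= 1), "beta must lie in (0, 1)")
  list(beta = beta, critical_swp = critical_swp, biomass_cap = biomass_cap,
       map_ref = map_ref, t_base = t_base, t_ramp = t_ramp,
       max_root_depth = max_root_depth)
}

#' Default composition coefficients
#'
#' Linear predictors feeding a softmax; see [potential_composition()].
#' @return named list of coefficient vectors, one per functional group
#' @export
composition_coef <- function() {
  list(
    c4    = c(intercept = -4.0, warm_temp = 0.18, warm_precip = 0.004),
    c3    = c(intercept = -0.5, winter_frac = 2.0, mat = -0.05),
    shrub = c(intercept = 0.0, dryness = 0.8)
  )
}

#' Potential vegetation composition from climate normals
#'
#' Shares of shrubs, C3 and C4 grasses from a softmax over linear climate
#' predictors: the C4 score increases with warm-season temperature and
#' warm-season precipitation, the C3 score with the winter share of
#' precipitation (and cooler MAT), and the shrub score with dryness. The
#' result is a valid composition (non-negative, sums to 1) for any input.
#'
#' @param mat mean annual temperature, C
#' @param map mean annual precipitation, mm/yr
#' @param winter_frac fraction of annual precipitation in the winter
#'   quarter, in `[0, 1]`
#' @param warm_temp mean temperature of the three warmest months, C
#' @param warm_precip precipitation of the three warmest months, mm
#' @param coef coefficients, see [composition_coef()]
#' @return named numeric vector `c(shrub=, c3=, c4=)` summing to 1
#' @export
potential_composition <- function(mat, map, winter_frac, warm_temp,
                                  warm_precip, coef = composition_coef()) {
  s_c4 <- coef$c4[["intercept"]] + coef$c4[["warm_temp"]] * warm_temp +
    coef$c4[["warm_precip"]] * warm_precip
  s_c3 <- coef$c3[["intercept"]] + coef$c3[["winter_frac"]] * winter_frac +
    coef$c3[["mat"]] * (mat - 8)
  s_sh <- coef$shrub[["intercept"]] +
    coef$shrub[["dryness"]] * (1 - min(map, 1000) / 1000)
  e <- exp(c(shrub = s_sh, c3 = s_c3, c4 = s_c4) -
             max(s_sh, s_c3, s_c4))  # overflow-safe softmax
  e / sum(e)
}

#' Monthly biomass and phenology schedule
#'
#' Builds a 12-month, per-group schedule of total aboveground biomass, live
#' fraction and litter. Total biomass scales piecewise-linearly with MAP up
#' to a per-group cap; the live fraction follows a temperature window that
#' opens at the group's base temperature (so warmer normals widen the
#' growing season). Litter is a fixed fraction of mean standing biomass.
#'
#' @param comp composition vector from [potential_composition()]
#' @param monthly_temp 12 monthly mean temperatures, C
#' @param map mean annual precipitation, mm/yr
#' @param params vegetation parameters, see [veg_params()]
#' @return `data.frame` with columns `month, group, biomass, live_frac,
#'   litter` (36 rows)
#' @export
monthly_biomass_phenology <- function(comp, monthly_temp, map,
                                      params = veg_params()) {
  stop_if(length(monthly_temp) != 12, "monthly_temp must have 12 entries")
  stop_if(abs(sum(comp) - 1) > 1e-9, "composition must sum to 1")
  groups <- c("shrub", "c3", "c4")
  out <- do.call(rbind, lapply(groups, function(g) {
    lf <- pmin(1, pmax(0, (monthly_temp - params$t_base[[g]]) / params$t_ramp))
    total <- comp[[g]] * params$biomass_cap[[g]] * min(1, map / params$map_ref)
    biomass <- total * (0.5 + 0.5 * lf)
    data.frame(month = 1:12, group = g, biomass = biomass, live_frac = lf,
               litter = 0.4 * mean(biomass))
  }))
  rownames(out) <- NULL
  out
}

#' Root fraction per soil layer
#'
#' Cumulative root fraction above depth d follows 1 - beta^d; the fraction
#' in a layer `[top, bottom]` is `beta^top - beta^bottom`, renormalized over
#' the profile so the fractions sum to 1 (roots below the profile are folded
#' back in proportionally).
#'
#' @param profile a `soil_profile` (see [gen_soil_profile()])
#' @param beta decay parameter in (0, 1); smaller = shallower roots
#' @return numeric vector of per-layer root fractions summing to 1
#' @export
rooting_profile <- function(profile, beta) {
  stop_if(!is.numeric(beta) || beta <= 0 || beta >= 1,
          "beta must lie in (0, 1)")
  raw <- beta^profile$top - beta^profile$bottom
  raw / sum(raw)
}

#' Soil depth from maximum rooting depth
#'
#' When the reference soil description is deeper than 1 m, the simulated
#' soil depth is 95% of the maximum rooting depth, rounded to the nearest
#' 50 cm interval (ties rounded up). When the reference soil is at most 1 m
#' deep the reference depth is used as-is.
#'
#' @param max_root_depth maximum rooting depth, cm (> 0)
#' @param reference_depth depth of the reference soil description, cm, or
#'   `NULL` when unknown (rule is then always applied)
#' @return soil depth, cm
#' @export
soil_depth_from_roots <- function(max_root_depth, reference_depth = NULL) {
  stop_if(max_root_depth <= 0, "max_root_depth must be positive")
  if (!is.null(reference_depth) && reference_depth <= 100) {
    return(reference_depth)
  }
  max(50, floor(0.95 * max_root_depth / 50 + 0.5) * 50)
}

#' Assemble the vegetation description for a cell and climate condition
#'
#' Convenience constructor combining [potential_composition()],
#' [monthly_biomass_phenology()] and [rooting_profile()] into the object
#' [simulate_water_balance()] consumes. Vegetation is climate-driven, so
#' this is re-evaluated per climate condition.
#'
#' @param normals monthly climate normals from [monthly_normals()]
#' @param profile a `soil_profile`
#' @param params vegetation parameters, see [veg_params()]
#' @param hemisphere `"north"` or `"south"` (sets the winter quarter)
#' @param coef composition coefficients, see [composition_coef()]
#' @return list with `composition`, `schedule`, `roots` (group x layer
#'   matrix), `critical_swp` and `params`
#' @export
build_vegetation <- function(normals, profile, params = veg_params(),
                             hemisphere = "north",
                             coef = composition_coef()) {
  warm <- order(normals$monthly_temp, decreasing = TRUE)[1:3]
  comp <- potential_composition(
    mat = normals$mat, map = normals$map,
    winter_frac = if (normals$map > 0) {
      winter_precipitation(normals$monthly_precip, hemisphere) / normals$map
    } else 0,
    warm_temp = mean(normals$monthly_temp[warm]),
    warm_precip = sum(normals$monthly_precip[warm]),
    coef = coef)
  sched <- monthly_biomass_phenology(comp, normals$monthly_temp, normals$map,
                                     params)
  groups <- c("shrub", "c3", "c4")
  roots <- t(vapply(groups, function(g)
    rooting_profile(profile, params$beta[[g]]), numeric(nrow(profile))))
  rownames(roots) <- groups
  list(composition = comp, schedule = sched, roots = roots,
       critical_swp = params$critical_swp[groups], params = params)
}
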