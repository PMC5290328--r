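# Ecological drought metrics from daily simulation output: the duration of
# the longest continuous drought during growing periods (DDGP) for surface
# (0-20 cm) and deep (>20 cm) soil, and the fraction of transpiration drawn
# from deep soil (T20/T), aggregated across simulation years with the first
# year discarded as spin-up.

#' Snow-free, frost-free day eligibility
#'
#' A day can count toward a growing-period drought only when there is no
#' snowpack and the daily minimum temperature is above the frost threshold.
#'
#' @param tmin daily minimum temperature, C
#' @param swe daily snow water equivalent, mm
#' @param frost_threshold frost temperature, C (a day with
#'   `tmin <= frost_threshold` is frosty); default 0
#' @return logical vector
#' @export
eligible_days <- function(tmin, swe, frost_threshold = 0) {
  stop_if(length(tmin) != length(swe), "tmin and swe must be aligned")
  swe == 0 & tmin > frost_threshold
}

#' Depth-grouped soil water potential
#'
#' Splits the profile at `depth_split` into a surface and a deep group,
#' computes the thickness-weighted mean water content of each group per day
#' and converts it to SWP through a retention curve with thickness-weighted
#' parameters. Layers must not straddle the split (guaranteed by
#' [gen_soil_profile()] for the default 20 cm).
#'
#' @param theta day x layer matrix (or a single day's vector) of volumetric
#'   water content
#' @param profile `soil_profile`
#' @param depth_split boundary depth, cm (default 20)
#' @return list with `surface` and `deep` daily SWP vectors (MPa); a group
#'   with no layers yields `NA`
#' @export
layer_group_swp <- function(theta, profile, depth_split = 20) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  stop_if(any(profile$top < depth_split & profile$bottom > depth_split),
          "a soil layer straddles the depth split")
  grp <- function(sel) {
    if (!any(sel)) return(rep(NA_real_, nrow(theta)))
    th <- profile$bottom[sel] - profile$top[sel]
    wbar <- as.numeric(theta[, sel, drop = FALSE] %*% th) / sum(th)
    lay <- list(theta_sat = sum(profile$theta_sat[sel] * th) / sum(th),
                psi_sat = sum(profile$psi_sat[sel] * th) / sum(th),
                b = sum(profile$b[sel] * th) / sum(th))
    swp_from_theta(pmax(wbar, 1e-9), lay)
  }
  list(surface = grp(profile$bottom <= depth_split),
       deep = grp(profile$top >= depth_split))
}

#' Drought duration during growing periods (DDGP)
#'
#' The length, per calendar year, of the longest run of consecutive days
#' that are simultaneously eligible (snow-free, frost-free) and in drought
#' (SWP strictly below the threshold). Runs do not cross year boundaries.
#'
#' @param swp daily group SWP, MPa
#' @param eligible logical vector from [eligible_days()]
#' @param year calendar year per day
#' @param threshold drought threshold, MPa (default -3.0; strict `<`)
#' @return named numeric vector of run lengths, one per year
#' @export
ddgp <- function(swp, eligible, year, threshold = -3.0) {
  stop_if(length(swp) != length(eligible) || length(swp) != length(year),
          "inputs must be aligned")
  qual <- eligible & !is.na(swp) & swp < threshold
  yrs <- unique(year)
  out <- vapply(yrs, function(y) {
    r <- rle(qual[year == y])
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }, numeric(1))
  names(out) <- yrs
  out
}

#' Deep-transpiration fraction (T20/T)
#'
#' Annual ratio of transpiration taken up from layers below `depth_split`
#' to total transpiration. Years with zero total transpiration yield `NA`.
#'
#' @param transp_layer day x layer matrix of transpiration, mm
#' @param profile `soil_profile`
#' @param year calendar year per day
#' @param depth_split boundary depth, cm (default 20)
#' @return named numeric vector per year, values in `[0, 1]` or `NA`
#' @export
deep_transp_fraction <- function(transp_layer, profile, year,
                                 depth_split = 20) {
  stop_if(nrow(transp_layer) != length(year), "inputs must be aligned")
  deep_sel <- profile$top >= depth_split
  yrs <- unique(year)
  out <- vapply(yrs, function(y) {
    rows <- year == y
    total <- sum(transp_layer[rows, , drop = FALSE])
    if (total <= 0) return(NA_real_)
    sum(transp_layer[rows, deep_sel, drop = FALSE]) / total
  }, numeric(1))
  names(out) <- yrs
  out
}

#' Aggregate annual values across simulation years
#'
#' Discards the first `spin_up` years and returns the mean and standard
#' deviation of the rest.
#'
#' @param values per-year numeric vector (>= 2 years)
#' @param spin_up number of leading years to discard (default 1)
#' @return list with `mean`, `sd`, `n` (years retained)
#' @export
aggregate_years <- function(values, spin_up = 1) {
  stop_if(length(values) < 2, "at least 2 years are required")
  stop_if(spin_up >= length(values), "spin-up leaves no years to aggregate")
  v <- values[-seq_len(spin_up)]
  list(mean = mean(v, na.rm = TRUE),
       sd = if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0,
       n = length(v))
}

#' Drought metrics for one simulation
#'
#' Convenience wrapper: computes DDGP for the surface and deep soil groups
#' and the deep-transpiration fraction from a [simulate_water_balance()]
#' result, aggregated over post-spin-up years.
#'
#' @param sim a `wb_simulation`
#' @param threshold drought SWP threshold, MPa
#' @param frost_threshold frost temperature, C
#' @param depth_split depth split, cm
#' @param spin_up spin-up years to discard
#' @return list of class `drought_metrics` with elements `ddgp0`, `ddgp20`,
#'   `t20_over_t` (each `list(mean, sd, n)`) and `per_year` (data.frame)
#' @export
drought_metrics <- function(sim, threshold = -3.0, frost_threshold = 0,
                            depth_split = 20, spin_up = 1) {
  stop_if(!inherits(sim, "wb_simulation"), "sim must be a wb_simulation")
  elig <- eligible_days(sim$tmin, sim$fluxes$swe, frost_threshold)
  swp <- layer_group_swp(sim$theta, sim$profile, depth_split)
  d0 <- ddgp(swp$surface, elig, sim$year, threshold)
  d20 <- if (all(is.na(swp$deep))) NULL else
    ddgp(swp$deep, elig, sim$year, threshold)
  tf <- deep_transp_fraction(sim$transp_layer, sim$profile, sim$year,
                             depth_split)
  per_year <- data.frame(year = as.integer(names(d0)), ddgp0 = unname(d0),
                         ddgp20 = if (is.null(d20)) NA_real_ else unname(d20),
                         t20_over_t = unname(tf))
  structure(list(ddgp0 = aggregate_years(d0, spin_up),
                 ddgp20 = if (is.null(d20)) NULL else
                   aggregate_years(d20, spin_up),
                 t20_over_t = aggregate_years(tf, spin_up),
                 per_year = per_year),
            class = "drought_metrics")
}
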