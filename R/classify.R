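# Climatological classification of temperate drylands: Trewartha climate
# groups from monthly mean temperatures, the UNEP aridity index, the
# conjunction of criteria defining a temperate dryland, shift zones between
# climate conditions, GCM agreement accounting, and two climate descriptors
# (warm/wet season overlap, winter precipitation).

#' Trewartha climate group from monthly mean temperatures
#'
#' Group rules, applied in order: tropical if all 12 monthly means are
#' >= 18 C; otherwise by the count of months with mean temperature >= 10 C:
#' >= 8 subtropical, 4-7 temperate (group D), 1-3 boreal, 0 other.
#' Temperatures are compared at full floating precision.
#'
#' @param monthly_temp numeric vector of exactly 12 monthly mean temperatures
#' @return one of `"tropical"`, `"subtropical"`, `"temperate_D"`, `"boreal"`,
#'   `"other"`
#' @export
trewartha_group <- function(monthly_temp) {
  stop_if(length(monthly_temp) != 12 || !is.numeric(monthly_temp),
          "monthly_temp must be a numeric vector of length 12")
  if (all(monthly_temp >= 18)) return("tropical")
  n10 <- sum(monthly_temp >= 10)
  if (n10 >= 8) "subtropical"
  else if (n10 >= 4) "temperate_D"
  else if (n10 >= 1) "boreal"
  else "other"
}

#' UNEP aridity index
#'
#' AI = MAP / PET. Drylands are `0.05 <= AI < 0.5` (arid and semiarid,
#' excluding hyper-arid); the bounds are applied elsewhere
#' ([classify_temperate_dryland()]).
#'
#' @param map mean annual precipitation, mm/yr (>= 0)
#' @param pet annual potential evapotranspiration, mm/yr (> 0)
#' @return dimensionless AI >= 0
#' @export
aridity_index <- function(map, pet) {
  stop_if(any(pet <= 0), "pet must be positive")
  stop_if(any(map < 0), "map must be non-negative")
  map / pet
}

#' Classify a cell as temperate dryland
#'
#' A cell is a temperate dryland when all four criteria hold: MAT > 0 C;
#' Trewartha group D; `0.05 <= AI < 0.5`; maximum sand fraction across soil
#' layers < 0.90. The function is pure: it is re-evaluated per climate
#' condition because the study area itself is climate-dependent.
#'
#' @param mat mean annual temperature, C
#' @param monthly_temp 12 monthly mean temperatures, C
#' @param ai aridity index (MAP/PET)
#' @param sand_max maximum sand fraction over the profile's layers
#' @param ai_bounds dryland AI interval, left-closed right-open
#' @param sand_limit exclusive upper sand bound
#' @return list of class `cell_classification` with fields `mat`, `ai`,
#'   `trewartha_group`, `sand_max`, `is_temperate_dryland` and `reasons`
#'   (character vector naming the failed criteria, empty when classified)
#' @export
classify_temperate_dryland <- function(mat, monthly_temp, ai, sand_max,
                                       ai_bounds = c(0.05, 0.5),
                                       sand_limit = 0.90) {
  grp <- trewartha_group(monthly_temp)
  reasons <- character(0)
  if (!(mat > 0)) reasons <- c(reasons, "MAT")
  if (grp != "temperate_D") reasons <- c(reasons, "trewartha")
  if (!(ai >= ai_bounds[1] && ai < ai_bounds[2])) reasons <- c(reasons, "AI")
  if (!(sand_max < sand_limit)) reasons <- c(reasons, "sand")
  structure(list(mat = mat, ai = ai, trewartha_group = grp,
                 sand_max = sand_max,
                 is_temperate_dryland = length(reasons) == 0L,
                 reasons = reasons),
            class = "cell_classification")
}

#' Shift zone between two climate conditions
#'
#' @param current,future logical dryland flags under the current and a future
#'   climate condition (vectorized)
#' @return character vector: `"contracting"` (dryland now, not in future),
#'   `"stable"` (both), `"expanding"` (future only), `"outside"` (neither)
#' @export
classify_shift_zone <- function(current, future) {
  stop_if(length(current) != length(future), "inputs must have equal length")
  out <- ifelse(current & !future, "contracting",
         ifelse(current & future, "stable",
         ifelse(!current & future, "expanding", "outside")))
  out
}

#' Attribute a dryland shift to the criteria that flipped
#'
#' For a cell whose dryland status changed between conditions, names the
#' climate-group transition (e.g. temperate to subtropical) and/or the
#' aridity-class transition responsible. Stable and outside cells yield an
#' empty attribution.
#'
#' @param current,future `cell_classification` objects for the same cell
#' @return character vector of attributions (possibly empty)
#' @export
attribute_shift <- function(current, future) {
  stop_if(!inherits(current, "cell_classification") ||
          !inherits(future, "cell_classification"),
          "inputs must be cell_classification objects")
  if (current$is_temperate_dryland == future$is_temperate_dryland) {
    return(character(0))
  }
  out <- character(0)
  if (current$trewartha_group != future$trewartha_group) {
    out <- c(out, paste0("climate: ",
                         sub("_D$", "", current$trewartha_group), "→",
                         sub("_D$", "", future$trewartha_group)))
  }
  ac <- aridity_class(current$ai)
  af <- aridity_class(future$ai)
  if (ac != af) out <- c(out, paste0("aridity: ", ac, "→", af))
  if (!(current$mat > 0) != !(future$mat > 0)) out <- c(out, "MAT")
  if (!(current$sand_max < 0.9) != !(future$sand_max < 0.9)) {
    out <- c(out, "sand")
  }
  out
}

# UNEP aridity classes used for shift attribution
aridity_class <- function(ai) {
  if (ai < 0.05) "hyper-arid"
  else if (ai < 0.2) "arid"
  else if (ai < 0.5) "semiarid"
  else if (ai < 0.65) "dry sub-humid"
  else "humid"
}

#' GCM agreement histogram
#'
#' Counts, per cell, how many GCMs classify it as temperate dryland, and
#' tallies cells by agreement level 0..n_gcm.
#'
#' @param flags logical matrix, cells x GCMs (or a list of equal-length
#'   per-cell logical vectors)
#' @return list with `per_cell` (integer agreement count per cell) and
#'   `histogram` (named counts over levels `0..n_gcm`; sums to the number of
#'   cells)
#' @export
gcm_agreement <- function(flags) {
  if (is.list(flags) && !is.data.frame(flags)) {
    len <- lengths(flags)
    stop_if(length(unique(len)) != 1, "ragged per-cell GCM flags")
    flags <- do.call(rbind, flags)
  }
  stop_if(!is.matrix(flags) && !is.data.frame(flags),
          "flags must be a cells x GCMs matrix")
  flags <- as.matrix(flags)
  n_gcm <- ncol(flags)
  per_cell <- as.integer(rowSums(flags))
  hist <- vapply(0:n_gcm, function(k) sum(per_cell == k), integer(1))
  names(hist) <- as.character(0:n_gcm)
  list(per_cell = per_cell, histogram = hist)
}

#' Warm/wet season overlap
#'
#' Pearson correlation between the 12 monthly mean temperatures and monthly
#' precipitation totals. +1 means the wet season coincides with the warm
#' season, -1 with the cold season. Undefined (returns `NA`) when either
#' series is constant.
#'
#' @param monthly_temp,monthly_precip numeric vectors of length 12
#' @return correlation in `[-1, 1]`, or `NA_real_`
#' @export
warm_wet_overlap <- function(monthly_temp, monthly_precip) {
  stop_if(length(monthly_temp) != 12 || length(monthly_precip) != 12,
          "both series must have 12 entries")
  if (stats::sd(monthly_temp) == 0 || stats::sd(monthly_precip) == 0) {
    return(NA_real_)
  }
  stats::cor(monthly_temp, monthly_precip)
}

#' Winter precipitation
#'
#' Sum of mean monthly precipitation over the climatological winter:
#' December-February in the northern hemisphere, June-August in the southern.
#'
#' @param monthly_precip numeric vector of length 12 (Jan..Dec)
#' @param hemisphere `"north"` or `"south"`
#' @return winter precipitation, mm
#' @export
winter_precipitation <- function(monthly_precip,
                                 hemisphere = c("north", "south")) {
  stop_if(length(monthly_precip) != 12, "monthly_precip must have 12 entries")
  hemisphere <- match.arg(hemisphere)
  idx <- if (hemisphere == "north") c(12, 1, 2) else c(6, 7, 8)
  sum(monthly_precip[idx])
}
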