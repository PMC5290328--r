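# Summary machinery: two-step GCM regional summaries, unique-variance
# partitioning with additive factor models, Budyko-framework curve fitting
# via Fuh's one-parameter equation, and a symmetric agreement index.

#' Two-step regional summary across GCMs
#'
#' Step 1: for each GCM, the summary statistic over that GCM's member cells
#' of a (region, zone) stratum (membership is GCM-specific because zones
#' are). Step 2: the median of the per-GCM statistics, with the min-max GCM
#' range as the spread indicator. A GCM with no member cells contributes a
#' missing value, excluded from step 2.
#'
#' @param value per-observation values
#' @param gcm,region,zone per-observation labels (equal length)
#' @param stat `"median"` (default) or `"mean"` for step 1
#' @return `data.frame` with one row per (region, zone): `region, zone,
#'   median, gcm_min, gcm_max, n_gcm`
#' @export
regional_summary <- function(value, gcm, region, zone,
                             stat = c("median", "mean")) {
  stat <- match.arg(stat)
  n <- length(value)
  stop_if(length(gcm) != n || length(region) != n || length(zone) != n,
          "all inputs must have equal length")
  f1 <- if (stat == "median") stats::median else mean
  strata <- unique(data.frame(region = region, zone = zone,
                              stringsAsFactors = FALSE))
  gcms <- unique(gcm)
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    r <- strata$region[i]; z <- strata$zone[i]
    per_gcm <- vapply(gcms, function(g) {
      sel <- gcm == g & region == r & zone == z
      if (!any(sel)) NA_real_ else f1(value[sel], na.rm = TRUE)
    }, numeric(1))
    per_gcm <- per_gcm[!is.na(per_gcm)]
    if (length(per_gcm) == 0) return(NULL)
    data.frame(region = r, zone = z,
               median = stats::median(per_gcm),
               gcm_min = min(per_gcm), gcm_max = max(per_gcm),
               n_gcm = length(per_gcm))
  }))
  rownames(out) <- NULL
  out
}

#' Unique-variance partition across design factors
#'
#' Partitions the total sum of squares of `value` into components uniquely
#' attributable to each factor, using additive (main-effect) linear models:
#' the unique component of factor f is the explained SS of the full
#' additive model minus the explained SS of the model omitting f, as a
#' percentage of the total SS. Whatever the unique components do not cover
#' (shared and residual variation) is reported as `shared_residual`;
#' components always sum to 100.
#'
#' @param value numeric response
#' @param factors data.frame of grouping columns (e.g. cell, region, zone,
#'   gcm, rcp); columns with fewer than 2 levels contribute 0
#' @return `data.frame` with columns `factor, percent`; includes a
#'   `shared_residual` row
#' @export
variance_partition <- function(value, factors) {
  stop_if(nrow(factors) != length(value),
          "factors must have one row per value")
  total_ss <- sum((value - mean(value))^2)
  fac_names <- names(factors)
  if (total_ss <= 0) {
    warning("constant response: all variance components are zero")
    return(data.frame(factor = c(fac_names, "shared_residual"),
                      percent = c(rep(0, length(fac_names)), 0)))
  }
  dat <- as.data.frame(lapply(factors, factor))
  usable <- vapply(dat, function(f) nlevels(f) >= 2, logical(1))
  expl <- function(cols) {
    if (length(cols) == 0) return(0)
    fit <- stats::lm(value ~ ., data = dat[, cols, drop = FALSE])
    total_ss - sum(stats::residuals(fit)^2)
  }
  all_cols <- fac_names[usable]
  ss_full <- expl(all_cols)
  unique_pct <- vapply(fac_names, function(f) {
    if (!usable[[f]]) return(0)
    100 * (ss_full - expl(setdiff(all_cols, f))) / total_ss
  }, numeric(1))
  out <- data.frame(factor = c(fac_names, "shared_residual"),
                    percent = c(unique_pct, 100 - sum(unique_pct)))
  rownames(out) <- NULL
  out
}

#' Fuh's Budyko-family curve
#'
#' `F = 1 + AI_b - (1 + AI_b^omega)^(1/omega)` relating the
#' evapotranspiration ratio F = AET/P to the Budyko aridity index
#' AI_b = PET/P. For `omega >= 1`, F lies in `[0, min(1, AI_b)]`; `omega`
#' absorbs all non-climatic controls (vegetation, soil, seasonality).
#'
#' @param ai_b Budyko aridity index, >= 0 (vectorized)
#' @param omega curve parameter, > 0
#' @return F (same length as `ai_b`)
#' @export
fuh_curve <- function(ai_b, omega) {
  stop_if(any(omega <= 0), "omega must be positive")
  stop_if(any(ai_b < 0), "ai_b must be >= 0")
  1 + ai_b - (1 + ai_b^omega)^(1 / omega)
}

#' Fit Fuh's omega to simulated cells
#'
#' Computes F = AET/P and AI_b = PET/P per cell and finds the omega
#' minimizing the sum of squared differences between F and the Fuh curve,
#' by deterministic golden-section/parabolic search on (1, `upper`].
#'
#' @param aet actual evapotranspiration, mm/yr, per cell
#' @param pet potential evapotranspiration, mm/yr, per cell
#' @param p precipitation, mm/yr, per cell (> 0)
#' @param region optional label carried through
#' @param upper upper bound of the search interval (default 20)
#' @return list of class `budyko_fit`: `omega`, `sse`, `n`, `region`
#' @export
fit_omega <- function(aet, pet, p, region = NA_character_, upper = 20) {
  stop_if(length(aet) < 3, "at least 3 cells are required")
  stop_if(any(p <= 0), "precipitation must be positive")
  stop_if(length(pet) != length(aet) || length(p) != length(aet),
          "inputs must have equal length")
  f_obs <- aet / p
  ai_b <- pet / p
  sse <- function(om) sum((f_obs - fuh_curve(ai_b, om))^2)
  opt <- stats::optimize(sse, interval = c(1 + 1e-8, upper), tol = 1e-10)
  if (stats::sd(ai_b) == 0 && stats::sd(f_obs) == 0) {
    warning("degenerate input: objective may be flat in omega")
  }
  structure(list(omega = opt$minimum, sse = opt$objective,
                 n = length(aet), region = region),
            class = "budyko_fit")
}

#' Symmetric agreement index (lambda)
#'
#' An index in `[0, 1]` between two series: 1 for identical series, 0 for no
#' agreement; symmetric in its arguments; penalizes both systematic bias
#' and unsystematic deviation. Implemented as
#' `lambda = 1 - MSD / (var_x + var_y + (mean_x - mean_y)^2 + kappa)` with
#' population variances, MSD the mean squared deviation between the series,
#' and `kappa = 2|cov(x, y)|` when the correlation is negative (0
#' otherwise).
#'
#' @param x,y numeric series of equal length >= 2, not both constant
#' @return lambda in `[0, 1]`, or `NA` when both series are constant
#' @export
duveiller_lambda <- function(x, y) {
  stop_if(length(x) != length(y), "x and y must have equal length")
  stop_if(length(x) < 2, "series must have length >= 2")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0) return(NA_real_)
  cv <- mean((x - mx) * (y - my))
  kappa <- if (cv < 0) 2 * abs(cv) else 0
  msd <- mean((x - y)^2)
  1 - msd / (vx + vy + (mx - my)^2 + kappa)
}
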