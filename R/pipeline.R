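# End-to-end orchestration: a validated run configuration, schema-checked
# tabular IO, the pipeline itself (generate -> classify current -> downscale
# per GCM/RCP -> simulate -> drought metrics -> classify future -> shift
# zones & agreement -> summaries), and a small command-line front end.

.pipeline_stages <- c("generate", "classify", "simulate", "metrics",
                      "summarize")

#' Build and validate a run configuration
#'
#' All thresholds used anywhere in the pipeline are carried here, with the
#' conventional defaults: drought SWP -3.0 MPa, dryland AI in [0.05, 0.5),
#' sand exclusion at 0.90, frost at 0 C, depth split at 20 cm, PET
#' correction 1.2, 31 simulation years with 1 year of spin-up.
#'
#' @param n_cells number of synthetic cells
#' @param n_gcm number of synthetic GCMs per RCP
#' @param rcps character vector of RCP labels
#' @param years simulated years per condition (>= 2)
#' @param spin_up spin-up years discarded in aggregation
#' @param seed master seed; all other seeds derive from it
#' @param stratify stratified cell generation (see [gen_cell_grid()])
#' @param resolution grid resolution, degrees
#' @param swp_threshold drought threshold, MPa
#' @param ai_bounds dryland AI interval
#' @param sand_limit sand exclusion bound
#' @param frost_threshold frost temperature, C
#' @param depth_split surface/deep boundary, cm
#' @param pet_correction PET multiplier
#' @param warming_range per-RCP named list of warming ranges (C), or a
#'   single range applied to all RCPs
#' @param precip_shift GCM precipitation ratio half-width
#' @param winter_tilt additive winter precipitation ratio increment
#' @param outdir output directory
#' @return validated list of class `run_config`
#' @export
run_config <- function(n_cells = 20L, n_gcm = 2L, rcps = "RCP8.5",
                       years = 31L, spin_up = 1L, seed = 1L,
                       stratify = TRUE, resolution = 0.3125,
                       swp_threshold = -3.0, ai_bounds = c(0.05, 0.5),
                       sand_limit = 0.90, frost_threshold = 0,
                       depth_split = 20, pet_correction = 1.2,
                       warming_range = list(RCP4.5 = c(2, 4),
                                            RCP8.5 = c(3, 7)),
                       precip_shift = 0.2, winter_tilt = 0,
                       outdir = tempfile("drylandsim_run_")) {
  stop_if(!is_count(n_cells), "n_cells must be a positive integer")
  stop_if(!is_count(n_gcm), "n_gcm must be a positive integer")
  stop_if(!is_count(years, 2L), "years must be an integer >= 2")
  stop_if(spin_up >= years, "spin_up must leave at least one year")
  stop_if(length(ai_bounds) != 2 || ai_bounds[1] >= ai_bounds[2],
          "ai_bounds must be an increasing pair")
  if (!is.list(warming_range)) {
    warming_range <- stats::setNames(rep(list(warming_range), length(rcps)),
                                     rcps)
  }
  stop_if(!all(rcps %in% names(warming_range)),
          "warming_range must cover every RCP")
  structure(list(n_cells = as.integer(n_cells), n_gcm = as.integer(n_gcm),
                 rcps = as.character(rcps), years = as.integer(years),
                 spin_up = as.integer(spin_up), seed = as.integer(seed),
                 stratify = isTRUE(stratify), resolution = resolution,
                 swp_threshold = swp_threshold, ai_bounds = ai_bounds,
                 sand_limit = sand_limit,
                 frost_threshold = frost_threshold,
                 depth_split = depth_split,
                 pet_correction = pet_correction,
                 warming_range = warming_range[rcps],
                 precip_shift = precip_shift, winter_tilt = winter_tilt,
                 outdir = outdir),
            class = "run_config")
}

#' Write / read a run configuration (JSON)
#'
#' `read_config()` re-validates through [run_config()], so a configuration
#' round-trips unchanged.
#' @param config a `run_config`
#' @param path file path
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `run_config`
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Schema-checked tabular IO
#'
#' Plain tab-delimited text with a header row; `schema` is a named character
#' vector mapping required column names to classes (`"integer"`,
#' `"numeric"`, `"character"`, `"logical"`). Decimal parsing is
#' locale-independent ("." always). Missing columns raise an error naming
#' them.
#'
#' @param df data.frame to write
#' @param path file path
#' @param schema named character vector of column classes (read side)
#' @return `write_table` returns `path` invisibly; `read_table` a data.frame
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = TRUE,
                     dec = ".")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, dec = ".")
  if (!is.null(schema)) {
    miss <- setdiff(names(schema), names(df))
    stop_if(length(miss) > 0,
            paste0("table ", path, " is missing required column(s): ",
                   paste(miss, collapse = ", ")))
    for (cl in names(schema)) {
      df[[cl]] <- switch(schema[[cl]],
                         integer = as.integer(df[[cl]]),
                         numeric = as.numeric(df[[cl]]),
                         logical = as.logical(df[[cl]]),
                         character = as.character(df[[cl]]),
                         df[[cl]])
    }
  }
  df
}

# Annual PET (mm/yr) averaged over the complete years of a daily series.
#' Annual potential evapotranspiration of a daily series
#' @param weather daily weather table
#' @param lat latitude, degrees
#' @param rh,wind,cloud monthly climatological drivers (scalar or 12)
#' @param correction PET multiplier
#' @return mean annual PET, mm/yr
#' @export
pet_annual <- function(weather, lat, rh = 0.5, wind = 2, cloud = 0.5,
                       correction = 1.2) {
  rh12 <- rep(rh, length.out = 12)
  wind12 <- rep(wind, length.out = 12)
  cloud12 <- rep(cloud, length.out = 12)
  pet <- pet_daily(weather$doy, lat, weather$tmax, weather$tmin,
                   rh12[weather$month], wind12[weather$month],
                   cloud12[weather$month], correction = correction)
  sum(pet) / length(unique(weather$year))
}

# classification of one cell under one climate condition
classify_condition <- function(weather, cell, profile, config) {
  nrm <- monthly_normals(weather)
  pet <- pet_annual(weather, cell$lat, cell$rh, cell$wind, cell$cloud,
                    config$pet_correction)
  ai <- aridity_index(nrm$map, pet)
  cls <- classify_temperate_dryland(nrm$mat, nrm$monthly_temp, ai,
                                    max(profile$sand),
                                    ai_bounds = config$ai_bounds,
                                    sand_limit = config$sand_limit)
  list(normals = nrm, pet = pet, cls = cls)
}

#' Run the full analysis pipeline
#'
#' Generates synthetic cells and forcing, classifies each cell under the
#' current climate, constructs future forcing per GCM and RCP (hybrid
#' delta), simulates the daily water balance for every condition, derives
#' drought metrics, determines shift zones and GCM agreement, and writes
#' regional summaries, a variance partition, Budyko fits and a manifest.
#' Deterministic under a fixed configuration. A failing GCM scenario is
#' logged with a warning and skipped; the run continues.
#'
#' @param config a [run_config()]
#' @param stage last pipeline stage to execute (`"generate"`, `"classify"`,
#'   `"simulate"`, `"metrics"` or `"summarize"`; default runs everything)
#' @param quiet suppress progress messages
#' @return invisibly, a list with the result tables (`cells`,
#'   `classification`, `zones`, `agreement`, `metrics`, `summary`,
#'   `partition`, `budyko`, `manifest`); tables are also written under
#'   `config$outdir`
#' @export
run_pipeline <- function(config, stage = "summarize", quiet = FALSE) {
  stop_if(!inherits(config, "run_config"),
          "config must be created with run_config()")
  stage_i <- match(match.arg(stage, .pipeline_stages), .pipeline_stages)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  say("stage generate: %d cells, seed %d", config$n_cells, config$seed)
  cells <- gen_cell_grid(config$n_cells, seed = config$seed,
                         stratify = config$stratify,
                         resolution = config$resolution)
  deltas <- list()
  for (ri in seq_along(config$rcps)) {
    rcp <- config$rcps[ri]
    deltas[[rcp]] <- gen_gcm_deltas(
      config$n_gcm, seed = config$seed + 1000L * ri,
      warming_range = config$warming_range[[rcp]],
      precip_shift = config$precip_shift,
      winter_tilt = config$winter_tilt, rcp_label = rcp)
  }
  out <- list(cells = cells)
  write_table(cells, file.path(config$outdir, "cells.tsv"))
  if (stage_i < 2) return(invisible(out))

  class_rows <- list(); metric_rows <- list(); budyko_rows <- list()
  wbp <- wb_params(pet_correction = config$pet_correction)
  do_sim <- stage_i >= 3

  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    hemi <- if (cell$lat >= 0) "north" else "south"
    cell_seed <- (config$seed * 10007L + cell$cell_id) %% 2147483647L
    wp <- weather_gen_params(cell$mat, cell$map,
                             temp_seasonal_amplitude = cell$temp_amp,
                             precip_seasonality = cell$precip_seasonality,
                             wet_day_prob = cell$wet_day_prob,
                             interannual_cv = cell$interannual_cv,
                             years = config$years, seed = cell_seed,
                             lat = cell$lat)
    weather <- gen_daily_weather(wp)
    profile <- gen_soil_profile(cell$sand, cell$clay, cell$soil_depth)

    run_one <- function(w, condition, gcm, rcp) {
      cc <- classify_condition(w, cell, profile, config)
      row <- data.frame(cell_id = cell$cell_id, region = cell$region,
                        condition = condition, gcm = gcm, rcp = rcp,
                        mat = cc$normals$mat, map = cc$normals$map,
                        pet = cc$pet, ai = cc$cls$ai,
                        trewartha = cc$cls$trewartha_group,
                        sand_max = max(profile$sand),
                        dryland = cc$cls$is_temperate_dryland,
                        reasons = paste(cc$cls$reasons, collapse = ";"),
                        warm_wet_overlap = warm_wet_overlap(
                          cc$normals$monthly_temp, cc$normals$monthly_precip),
                        winter_precip = winter_precipitation(
                          cc$normals$monthly_precip, hemi))
      mrow <- NULL
      if (do_sim) {
        veg <- build_vegetation(cc$normals, profile, hemisphere = hemi)
        sim <- simulate_water_balance(w, profile, veg, lat = cell$lat,
                                      rh = cell$rh, wind = cell$wind,
                                      cloud = cell$cloud, params = wbp)
        dm <- drought_metrics(sim, threshold = config$swp_threshold,
                              frost_threshold = config$frost_threshold,
                              depth_split = config$depth_split,
                              spin_up = config$spin_up)
        keep <- sim$year > min(sim$year) + config$spin_up - 1
        mrow <- data.frame(
          cell_id = cell$cell_id, region = cell$region,
          condition = condition, gcm = gcm, rcp = rcp,
          ddgp0_mean = dm$ddgp0$mean, ddgp0_sd = dm$ddgp0$sd,
          ddgp20_mean = dm$ddgp20$mean %||% NA_real_,
          ddgp20_sd = dm$ddgp20$sd %||% NA_real_,
          t20_mean = dm$t20_over_t$mean, t20_sd = dm$t20_over_t$sd,
          aet = sum(sim$fluxes$evap[keep] + sim$fluxes$transp[keep] +
                      sim$fluxes$interception[keep]) /
            (length(unique(sim$year)) - config$spin_up),
          dryland = row$dryland)
      }
      list(class = row, metric = mrow)
    }

    cur <- run_one(weather, "current", "none", "none")
    class_rows[[length(class_rows) + 1L]] <- cur$class
    if (do_sim) {
      metric_rows[[length(metric_rows) + 1L]] <- cur$metric
      budyko_rows[[length(budyko_rows) + 1L]] <- data.frame(
        cell_id = cell$cell_id, region = cell$region,
        aet = cur$metric$aet, pet = cur$class$pet, p = cur$class$map)
    }
    for (rcp in config$rcps) {
      for (g in seq_along(deltas[[rcp]])) {
        d <- deltas[[rcp]][[g]]
        res <- tryCatch(
          run_one(apply_deltas(weather, d), "future", d$gcm_label, rcp),
          error = function(e) {
            warning(sprintf("cell %d %s %s failed: %s; skipped",
                            cell$cell_id, d$gcm_label, rcp,
                            conditionMessage(e)))
            NULL
          })
        if (is.null(res)) next
        class_rows[[length(class_rows) + 1L]] <- res$class
        if (do_sim) metric_rows[[length(metric_rows) + 1L]] <- res$metric
      }
    }
    if (i %% 25 == 0) say("  ...cell %d/%d done", i, nrow(cells))
  }

  classification <- do.call(rbind, class_rows)
  write_table(classification, file.path(config$outdir, "classification.tsv"))
  out$classification <- classification

  # shift zones and agreement, per RCP
  cur_flags <- classification[classification$condition == "current", ]
  fut <- classification[classification$condition == "future", ]
  zones <- NULL
  agreement <- NULL
  if (nrow(fut) > 0) {
    zones <- fut
    zones$zone <- classify_shift_zone(
      cur_flags$dryland[match(zones$cell_id, cur_flags$cell_id)],
      zones$dryland)
    zones <- zones[, c("cell_id", "region", "gcm", "rcp", "zone")]
    write_table(zones, file.path(config$outdir, "zones.tsv"))
    agreement <- do.call(rbind, lapply(config$rcps, function(rcp) {
      sub <- fut[fut$rcp == rcp, ]
      flags <- matrix(sub$dryland[order(sub$gcm, sub$cell_id)],
                      ncol = length(unique(sub$gcm)))
      ag <- gcm_agreement(flags)
      data.frame(rcp = rcp, level = as.integer(names(ag$histogram)),
                 n_cells = as.integer(ag$histogram))
    }))
    write_table(agreement, file.path(config$outdir, "agreement.tsv"))
  }
  out$zones <- zones; out$agreement <- agreement

  if (do_sim && stage_i >= 4) {
    metrics <- do.call(rbind, metric_rows)
    write_table(metrics, file.path(config$outdir, "metrics.tsv"))
    out$metrics <- metrics
  }

  if (stage_i >= 5 && do_sim) {
    metrics <- out$metrics
    cur_m <- metrics[metrics$condition == "current", ]
    fut_m <- metrics[metrics$condition == "future", ]
    if (nrow(fut_m) > 0) {
      idx <- match(fut_m$cell_id, cur_m$cell_id)
      chg <- fut_m
      chg$ddgp0_change <- fut_m$ddgp0_mean - cur_m$ddgp0_mean[idx]
      chg$ddgp20_change <- fut_m$ddgp20_mean - cur_m$ddgp20_mean[idx]
      chg$t20_change <- fut_m$t20_mean - cur_m$t20_mean[idx]
      zkey <- paste(zones$cell_id, zones$gcm, zones$rcp)
      chg$zone <- zones$zone[match(paste(chg$cell_id, chg$gcm, chg$rcp),
                                   zkey)]
      out$changes <- chg
      summaries <- do.call(rbind, lapply(
        c("ddgp0_change", "ddgp20_change", "t20_change"), function(v) {
          s <- regional_summary(chg[[v]], chg$gcm, chg$region, chg$zone)
          if (is.null(s) || nrow(s) == 0) return(NULL)
          s$variable <- v
          s
        }))
      write_table(summaries, file.path(config$outdir, "summary.tsv"))
      out$summary <- summaries
      part <- do.call(rbind, lapply(
        c("ddgp0_change", "ddgp20_change", "t20_change"), function(v) {
          ok <- !is.na(chg[[v]])
          p <- variance_partition(chg[[v]][ok],
                                  data.frame(cell = chg$cell_id,
                                             region = chg$region,
                                             zone = chg$zone,
                                             gcm = chg$gcm,
                                             rcp = chg$rcp)[ok, ])
          p$variable <- v
          p
        }))
      write_table(part, file.path(config$outdir, "partition.tsv"))
      out$partition <- part
    }
    bud <- do.call(rbind, budyko_rows)
    fits <- lapply(split(bud, bud$region), function(b) {
      if (nrow(b) < 3) return(NULL)
      f <- fit_omega(b$aet, b$pet, b$p, region = b$region[1])
      data.frame(region = f$region, omega = f$omega, sse = f$sse, n = f$n)
    })
    fits$overall <- {
      f <- fit_omega(bud$aet, bud$pet, bud$p, region = "overall")
      data.frame(region = "overall", omega = f$omega, sse = f$sse, n = f$n)
    }
    budyko <- do.call(rbind, fits)
    rownames(budyko) <- NULL
    write_table(budyko, file.path(config$outdir, "budyko.tsv"))
    out$budyko <- budyko
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(
    package = "drylandsim",
    version = as.character(utils::packageVersion("drylandsim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    config_hash = sprintf("%08x",
                          sum(utf8ToInt(cfg_json) *
                                seq_along(utf8ToInt(cfg_json))) %% 4294967291))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  say("pipeline complete: outputs in %s", config$outdir)
  invisible(out)
}

#' Command-line entry point
#'
#' Verbs: `generate`, `classify`, `simulate`, `metrics`, `summarize`,
#' `run-all` (each runs the pipeline up to the corresponding stage).
#' Options: `--config` (JSON produced by [write_config()]), `--seed`,
#' `--outdir`, `--gcms`, `--rcp`, `--years` override the configuration.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments)
#' @return invisibly, the [run_pipeline()] result
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  stop_if(length(args) < 1,
          "usage: drylandsim <verb> [--config F] [--seed N] [--outdir D] [--gcms N] [--rcp R] [--years N]")
  verb <- args[1]
  stage <- switch(verb,
                  "generate" = "generate", "classify" = "classify",
                  "simulate" = "simulate", "metrics" = "metrics",
                  "summarize" = , "run-all" = "summarize",
                  stop("unknown verb: ", verb, call. = FALSE))
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--outdir", type = "character", default = NULL),
    optparse::make_option("--gcms", type = "integer", default = NULL),
    optparse::make_option("--rcp", type = "character", default = NULL),
    optparse::make_option("--years", type = "integer", default = NULL)))
  opt <- optparse::parse_args(parser, args = args[-1])
  config <- if (!is.null(opt$config)) read_config(opt$config) else run_config()
  cfg <- unclass(config)
  if (!is.null(opt$seed)) cfg$seed <- opt$seed
  if (!is.null(opt$outdir)) cfg$outdir <- opt$outdir
  if (!is.null(opt$gcms)) cfg$n_gcm <- opt$gcms
  if (!is.null(opt$rcp)) cfg$rcps <- opt$rcp
  if (!is.null(opt$years)) cfg$years <- opt$years
  config <- do.call(run_config, cfg)
  invisible(run_pipeline(config, stage = stage))
}
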