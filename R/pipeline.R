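## Scenario orchestration: reclassify -> detect change -> shares/demand ->
## drivers -> transition models (+ Skill Measure) -> per-country allocation ->
## mosaic -> carbon ledgers.

#' Regional SSP forest-area trajectories
#'
#' `asia_ssp_table()` emulates the Asian-region baseline forest-area
#' trajectories of the five shared socioeconomic pathways over 2015-2050:
#' the sustainability pathway (SSP1) gains about 38 million ha and the
#' regional-rivalry pathway (SSP3) loses about 10 million ha by 2050; the
#' intermediate pathways are scaled to the reported ordering of net changes
#' (gains SSP1 > SSP2 > SSP4, losses SSP3 > SSP5). The 2015 base area
#' (600 Mha) is a round regional figure; only differences between years enter
#' the analysis. `synthetic_ssp_table()` rescales the whole table so its 2015
#' area equals a supplied area in hectares — handy for driving toy landscapes
#' with realistic relative demands.
#'
#' @return an [ssp_projection_table()] (columns scenario, year, area_mha).
#' @export
asia_ssp_table <- function() {
  deltas <- c(SSP1 = 38, SSP2 = 28.5, SSP3 = -10, SSP4 = 20.6, SSP5 = -6)
  years <- c(2015, 2025, 2035, 2045, 2050)
  frac <- (years - 2015) / (2050 - 2015)
  tab <- do.call(rbind, lapply(names(deltas), function(sc)
    data.frame(scenario = sc, year = years,
               area_mha = 600 + deltas[[sc]] * frac)))
  ssp_projection_table(tab)
}

#' @rdname asia_ssp_table
#' @param area_2015_ha regional forest area in 2015, hectares.
#' @export
synthetic_ssp_table <- function(area_2015_ha) {
  tab <- asia_ssp_table()
  tab$area_mha <- tab$area_mha * (area_2015_ha / 1e6) / 600
  tab
}

#' Run one forest-cover-change scenario end to end
#'
#' Full pipeline on a landscape bundle: the land-cover epochs are reclassified
#' to F/NF maps; the long epoch pair gives each country's historical share of
#' regional change; the SSP table gives the regional 2015-2050 net change,
#' split into per-country pixel demands (largest-remainder conserved); the
#' calibration epoch pair trains one transition-potential model per country
#' (balanced samples, Skill Measure validation); each country's demand is
#' allocated to its highest-potential pixels and the countries are mosaicked;
#' finally the forest is sub-classified by age, carbon density is projected
#' to the horizon and zonal AFCS ledgers (country, province, forest class,
#' intact forest, protected area) are computed, with annualised rates and CO2
#' equivalents.
#'
#' @param bundle a `landscape_bundle` from [generate_landscape()] (or an
#'   equivalently shaped list of real grids).
#' @param ssp_table an [ssp_projection_table()] scaled to the landscape; by
#'   default [synthetic_ssp_table()] at the bundle's 2015 forest area.
#' @param scenario scenario id (e.g. `"SSP1"`).
#' @param seed master seed; every stochastic stage derives its own from it.
#' @param n_per_class balanced sample size per class (see [draw_samples()]).
#' @param hidden,maxit transition-model architecture overrides
#'   (see [train_tpm()]).
#' @param horizon scenario span in years for annualisation, default 35.
#' @return an `fcc_scenario` object: demand table, per-country `tpm_model`s,
#'   validation table, allocation log, end-state F/NF map and change grid,
#'   zonal ledger, historical-loss ledger, and annualised totals.
#' @export
run_scenario <- function(bundle, ssp_table = NULL, scenario = "SSP1",
                         seed = 1, n_per_class = NULL, hidden = NULL,
                         maxit = 200, horizon = 35) {
  cs <- bundle$cell_size
  n_ep <- length(bundle$landcover)
  if (n_ep < 3) stop("bundle needs at least 3 land-cover epochs")
  fnf <- lapply(seq_len(n_ep), function(i)
    reclassify_to_fnf(bundle$landcover[[i]], cell_size = cs,
                      epoch = names(bundle$landcover)[i]))
  fnf_start <- fnf[[1]]; fnf_mid <- fnf[[n_ep - 1]]; fnf_end <- fnf[[n_ep]]
  if (is.null(ssp_table))
    ssp_table <- synthetic_ssp_table(area_of(forest_count(fnf_end), cs))

  change_long <- detect_change(fnf_start, fnf_end)   # shares (1992 -> 2015)
  change_cal <- detect_change(fnf_mid, fnf_end)      # calibration (2005 -> 2015)
  change_prev <- detect_change(fnf_start, fnf_mid)   # drivers (1992 -> 2005)

  net_ha <- regional_net_change(ssp_table, scenario)
  direction <- if (net_ha >= 0) "gain" else "loss"
  shares <- historical_shares(change_long, bundle$countries, direction)
  demand <- allocate_demand(net_ha, shares, cell_size = cs, scenario = scenario)

  ## Drivers are measured at the START of the calibration pair: edge
  ## distance on the mid-epoch forest, dist_change and province shares from
  ## the period before it. Predictors must never encode the transition they
  ## are asked to predict.
  drivers <- build_driver_stack(
    bundle$elevation, bundle$road_mask, bundle$urban_mask, fnf_mid,
    change_prev, bundle$provinces, bundle$countries,
    direction = direction, cell_size = cs)

  ## sampling eligibility: persisted in the source class over the calibration
  ## pair (minus urban/water for gains); allocation eligibility: source class
  ## at the start of the simulation (2015), same exclusions.
  excl <- bundle$urban_mask == 1 | bundle$water_mask == 1
  samp_elig <- if (direction == "loss") {
    !is.na(change_cal) & change_cal == CHANGE_FOREST_PERSIST
  } else {
    !is.na(change_cal) & change_cal == CHANGE_NONFOREST_PERSIST & !excl
  }
  alloc_elig <- if (direction == "loss") {
    !is.na(fnf_end) & unclass(fnf_end) == 1L
  } else {
    !is.na(fnf_end) & unclass(fnf_end) == 0L & !excl
  }

  models <- list(); results <- list()
  for (i in seq_len(nrow(demand))) {
    ctry <- demand$country[i]
    in_ctry <- !is.na(bundle$countries) & bundle$countries == as.integer(ctry)
    ch_c <- change_cal
    ch_c[!in_ctry] <- NA_integer_
    ## a country whose calibration pools are too thin borrows the regional
    ## samples (its potentials still come from its own pixels' drivers)
    plan <- tryCatch(
      draw_samples(ch_c, samp_elig & in_ctry, direction = direction,
                   n_per_class = n_per_class, seed = seed + 10L * i),
      error = function(e) {
        warning("country ", ctry, ": too few calibration pixels; ",
                "training on regional samples", call. = FALSE)
        draw_samples(change_cal, samp_elig, direction = direction,
                     n_per_class = n_per_class, seed = seed + 10L * i)
      })
    model <- train_tpm(plan, drivers, hidden = hidden, maxit = maxit,
                       seed = seed + 10L * i + 1L)
    tpm_c <- predict(model, newdata = drivers,
                     eligible = alloc_elig & in_ctry)
    ## the country owns all its pixels in the mosaic
    tpm_alloc <- tpm_c
    tpm_alloc[in_ctry & is.na(tpm_c)] <- -1  # covered but ineligible
    res <- allocate(tpm_alloc, fnf_end, demand$demand_px[i],
                    direction = direction,
                    exclusion = !alloc_elig | !in_ctry,
                    tie_seed = seed + 10L * i + 2L)
    models[[ctry]] <- model
    results[[ctry]] <- res
  }
  mos <- mosaic(fnf_end, results)

  ## carbon accounting
  acd_ref <- acd_from_agb(bundle$agb_t1)
  classified <- classify_forest(fnf_end, bundle$ifl, acd_ref, bundle$csr,
                                bundle$ecozones, bundle$geographies,
                                og_floor = bundle$og_floor)
  zones <- list(country = bundle$countries, province = bundle$provinces,
                forest_class = classified$class,
                intact_forest = bundle$ifl, protected_area = bundle$pa)
  if (direction == "loss") {
    acd_2050 <- project_acd_2050(classified, acd_ref, bundle$csr,
                                 bundle$ecozones, bundle$geographies)
    ledger <- afcs_loss_projected(mos$change, acd_2050, cell_size = cs,
                                  zones = zones, scenario = scenario)
  } else {
    gain_idx <- which(!is.na(mos$change) & mos$change == CHANGE_GAIN)
    acd_new <- matrix(0, nrow(fnf_end), ncol(fnf_end))
    if (length(gain_idx)) {
      rate <- csr_lookup(bundle$csr,
                         rep("young_secondary", length(gain_idx)),
                         bundle$ecozones[gain_idx],
                         bundle$geographies[gain_idx])
      acd_new[gain_idx] <- acd_new_forest(rate)
    }
    ledger <- afcs_gain_projected(mos$change, acd_new, cell_size = cs,
                                  zones = zones, scenario = scenario)
  }
  historical <- afcs_change_detect(
    change_cal, acd_from_agb(bundle$agb_t0), cell_size = cs,
    zones = list(country = bundle$countries, province = bundle$provinces))

  total_tg <- ledger$afcs_tg_c[ledger$zone_type == "region"]
  validation <- do.call(rbind, lapply(names(models), function(ctry) {
    v <- models[[ctry]]$validation
    data.frame(country = ctry, A = v$A, T = v$T, P = v$P, SM = v$SM,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    scenario = scenario, direction = direction, seed = seed,
    demand = demand, shares = shares, models = models,
    validation = validation, allocation_log = mos$log,
    fnf_end = mos$fnf_end, change = mos$change,
    classified = classified, ledger = ledger,
    historical_ledger = historical,
    totals = c(list(afcs_tg_c = total_tg),
               annualize_and_convert(total_tg, horizon = horizon)),
    horizon = horizon
  ), class = "fcc_scenario")
}

#' @export
print.fcc_scenario <- function(x, ...) {
  cat(sprintf("<fcc_scenario %s (%s): %d countries, AFCS %s %.3f Tg C (%.2f Tg C/yr, %.3f Pg CO2)>\n",
              x$scenario, x$direction, nrow(x$demand), x$direction,
              x$totals$afcs_tg_c, x$totals$rate_tg_c_yr, x$totals$total_pg_co2))
  invisible(x)
}

#' @export
summary.fcc_scenario <- function(object, ...) {
  x <- object
  cat("Scenario ", x$scenario, " (net ", x$direction, ")\n", sep = "")
  cat("Demand (pixels):\n")
  print(x$demand[c("country", "direction", "demand_ha", "demand_px")],
        row.names = FALSE)
  cat("Allocation:\n")
  print(x$allocation_log, row.names = FALSE)
  cat("Model validation (Skill Measure):\n")
  print(x$validation, row.names = FALSE)
  cat(sprintf("AFCS %s: %.4f Tg C = %.4f Tg C/yr over %d yr; %.4f Pg CO2 (%.2f Tg CO2/yr)\n",
              x$direction, x$totals$afcs_tg_c, x$totals$rate_tg_c_yr,
              x$horizon, x$totals$total_pg_co2, x$totals$rate_tg_co2_yr))
  invisible(x)
}

#' Summarise a zonal ledger
#'
#' Per zone type: zones ordered by absolute AFCS change (ties broken by zone
#' id), with each zone's percentage share of the regional total, truncated to
#' the top `n`. An empty ledger yields an empty report.
#'
#' @param ledger a `zonal_ledger` (e.g. `run_scenario(...)$ledger`).
#' @param n keep the top n zones per zone type (default 10).
#' @return data.frame (zone_type, zone_id, direction, pixels, area_ha,
#'   afcs_tg_c, share_pct) ordered within zone type.
#' @export
afcs_report <- function(ledger, n = 10) {
  if (!nrow(ledger))
    return(data.frame(zone_type = character(), zone_id = character(),
                      direction = character(), pixels = integer(),
                      area_ha = numeric(), afcs_tg_c = numeric(),
                      share_pct = numeric()))
  total <- ledger$afcs_tg_c[ledger$zone_type == "region"][1]
  out <- list()
  for (zt in setdiff(unique(ledger$zone_type), "region")) {
    sub <- ledger[ledger$zone_type == zt, ]
    sub <- sub[order(-abs(sub$afcs_tg_c), sub$zone_id), ]
    sub <- utils::head(sub, n)
    sub$share_pct <- if (total > 0) 100 * sub$afcs_tg_c / total else 0
    out[[zt]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("zone_type", "zone_id", "direction", "pixels", "area_ha",
        "afcs_tg_c", "share_pct")]
}

#' Write scenario artefacts to a directory
#'
#' End-state and change grids as TIFF (+ sidecars), demand, allocation log
#' and ledgers as CSV, and per-country validation reports as JSON, plus a
#' `manifest.yml` with the scenario id, seed and architecture.
#'
#' @param scn an `fcc_scenario`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_grid(scn$fnf_end, file.path(dir, "fnf_end.tif"),
             meta = list(band = "fnf_end", scenario = scn$scenario))
  write_grid(scn$change, file.path(dir, "change.tif"),
             meta = list(band = "change", codes = change_levels(),
                         scenario = scn$scenario))
  utils::write.csv(scn$demand, file.path(dir, "demand.csv"), row.names = FALSE)
  utils::write.csv(scn$allocation_log, file.path(dir, "allocation_log.csv"),
                   row.names = FALSE)
  utils::write.csv(scn$ledger, file.path(dir, "ledger.csv"), row.names = FALSE)
  utils::write.csv(scn$historical_ledger,
                   file.path(dir, "historical_ledger.csv"), row.names = FALSE)
  for (ctry in names(scn$models))
    write_validation_report(scn$models[[ctry]],
                            file.path(dir, paste0("validation_", ctry, ".json")))
  yaml::write_yaml(list(scenario = scn$scenario, direction = scn$direction,
                        seed = scn$seed, horizon = scn$horizon,
                        totals = scn$totals),
                   file.path(dir, "manifest.yml"))
  invisible(dir)
}
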