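## Aboveground forest carbon accounting: forest age-class sub-classification,
## carbon-density projection with class-, ecozone- and geography-specific
## sequestration rates, zonal AFCS ledgers, and annualisation / CO2
## conversion of totals.

#' Carbon model constants
#'
#' Named defaults of the carbon projection: the growth period for old growth
#' and old secondary forest (`gp_old`, 40 yr, the 2010 carbon-density epoch to
#' the 2050 horizon), the minimum age of old secondary forest (`t_age`,
#' 21 yr), the growth period credited to newly gained forest (`gp_new`,
#' 17.5 yr — trees are assumed planted uniformly across the 35-year scenario
#' window, so the average stand is half the window old), the carbon fraction
#' of aboveground biomass (`c_ratio`, 0.5) and the CO2-per-carbon mass ratio
#' (`co2_per_c`, 3.67).
#'
#' @return named list of constants.
#' @export
carbon_constants <- function() {
  list(gp_old = 40, t_age = 21, gp_new = 17.5, c_ratio = 0.5, co2_per_c = 3.67)
}

#' Forest age-class labels
#'
#' Class codes used by [classify_forest()]: 0 non-forest, 1 old growth,
#' 2 old secondary, 3 young secondary.
#' @return named integer vector.
#' @export
forest_class_codes <- function() {
  c(nonforest = 0L, old_growth = 1L, old_secondary = 2L, young_secondary = 3L)
}

#' Carbon sequestration rate table
#'
#' CSRs (Mg C ha-1 yr-1) keyed by forest class x ecozone x geography
#' (continental/insular). [default_csr_table()] ships documented placeholder
#' rates obeying the ecological ordering young secondary > old secondary >
#' old growth within every stratum, with mild ecozone and geography
#' variation; replace it with measured rates for real analyses.
#'
#' @param table data.frame with columns `forest_class` (one of
#'   `"old_growth"`, `"old_secondary"`, `"young_secondary"`), `ecozone`,
#'   `geography` (integer labels) and `csr` (> 0).
#' @return validated data.frame of class `csr_table`.
#' @export
csr_table <- function(table) {
  req <- c("forest_class", "ecozone", "geography", "csr")
  if (!all(req %in% names(table)))
    stop("CSR table needs columns: ", paste(req, collapse = ", "))
  if (any(table$csr <= 0)) stop("CSRs must be > 0")
  key <- with(table, paste(forest_class, ecozone, geography))
  if (anyDuplicated(key)) stop("duplicate CSR strata")
  ## within each stratum, young secondary must outpace old secondary
  strata <- unique(table[c("ecozone", "geography")])
  for (i in seq_len(nrow(strata))) {
    sel <- table$ecozone == strata$ecozone[i] &
      table$geography == strata$geography[i]
    y <- table$csr[sel & table$forest_class == "young_secondary"]
    o <- table$csr[sel & table$forest_class == "old_secondary"]
    if (length(y) && length(o) && y < o)
      stop("young-secondary CSR below old-secondary CSR in stratum ",
           strata$ecozone[i], "/", strata$geography[i])
  }
  class(table) <- unique(c("csr_table", class(table)))
  table
}

#' @rdname csr_table
#' @param ecozones,geographies integer label values the table must cover.
#' @export
default_csr_table <- function(ecozones = 1:2, geographies = 1:2) {
  grid <- expand.grid(forest_class = c("old_growth", "old_secondary",
                                       "young_secondary"),
                      ecozone = ecozones, geography = geographies,
                      stringsAsFactors = FALSE)
  base <- c(old_growth = 0.5, old_secondary = 1.2, young_secondary = 3.0)
  grid$csr <- base[grid$forest_class] *
    (1 + 0.1 * (match(grid$ecozone, ecozones) - 1)) *
    (1 + 0.05 * (match(grid$geography, geographies) - 1))
  csr_table(grid)
}

#' Look up CSRs for pixel strata
#'
#' Vectorised lookup; any unresolvable (class, ecozone, geography) key is an
#' error that names the missing stratum.
#'
#' @param table a [csr_table()].
#' @param forest_class character vector of class names.
#' @param ecozone,geography integer label vectors.
#' @return numeric CSR vector.
#' @export
csr_lookup <- function(table, forest_class, ecozone, geography) {
  key <- paste(forest_class, ecozone, geography)
  tab_key <- with(table, paste(forest_class, ecozone, geography))
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop("no CSR for stratum: ", paste(miss, collapse = "; "))
  }
  table$csr[idx]
}

#' Carbon density from aboveground biomass
#'
#' `ACD = 0.5 x AGB` (Mg C ha-1 from Mg ha-1), the standard carbon fraction
#' of woody biomass.
#'
#' @param agb non-negative AGB grid or vector (Mg ha-1).
#' @param c_ratio carbon fraction, default 0.5.
#' @return ACD, same shape as `agb`.
#' @export
acd_from_agb <- function(agb, c_ratio = carbon_constants()$c_ratio) {
  if (any(agb < 0, na.rm = TRUE)) stop("AGB must be >= 0")
  agb * c_ratio
}

#' Sub-classify forest into age classes
#'
#' Splits the forest pixels of an F/NF map into old growth, old secondary and
#' young secondary. Old growth is forest inside the intact forest landscape
#' (IFL) mask whose carbon density clears a configurable floor (set
#' `ifl_only = TRUE` to drop the floor). All other forest is aged by the
#' inverse of the young-secondary accumulation model, `age = ACD / CSR_young`
#' for the pixel's ecozone x geography stratum: ages of at most 20 years are
#' young secondary (the age is recorded), older pixels are old secondary
#' (minimum age 21). Degradation is not modelled, so low-density old stands
#' classify as young — a deliberately conservative rule.
#'
#' @param fnf [fnf_grid()] of the classification epoch.
#' @param ifl logical/0-1 intact-forest mask.
#' @param acd carbon-density grid (Mg C ha-1) of the reference epoch.
#' @param csr a [csr_table()] resolving every forest pixel's stratum.
#' @param ecozones,geographies integer label grids.
#' @param og_floor old-growth ACD floor (Mg C ha-1), default 100.
#' @param ifl_only if `TRUE`, IFL membership alone defines old growth.
#' @return a `forest_class_grid`: list with `class` (codes of
#'   [forest_class_codes()]) and `age` (years; `NA` outside young secondary).
#' @export
classify_forest <- function(fnf, ifl, acd, csr, ecozones, geographies,
                            og_floor = 100, ifl_only = FALSE) {
  stopifnot_same_shape(fnf, ifl, acd, ecozones, geographies)
  cls <- matrix(forest_class_codes()[["nonforest"]], nrow(fnf), ncol(fnf))
  age <- matrix(NA_real_, nrow(fnf), ncol(fnf))
  forest <- !is.na(fnf) & unclass(fnf) == 1L
  og <- forest & (ifl != 0) & (ifl_only | acd >= og_floor)
  cls[og] <- forest_class_codes()[["old_growth"]]
  rest <- which(forest & !og)
  if (length(rest)) {
    csr_y <- csr_lookup(csr, rep("young_secondary", length(rest)),
                        ecozones[rest], geographies[rest])
    g <- acd[rest] / csr_y
    old_sec <- g > 20
    cls[rest[old_sec]] <- forest_class_codes()[["old_secondary"]]
    cls[rest[!old_sec]] <- forest_class_codes()[["young_secondary"]]
    age[rest[!old_sec]] <- g[!old_sec]
  }
  structure(list(class = cls, age = age), class = "forest_class_grid")
}

#' @export
print.forest_class_grid <- function(x, ...) {
  n <- table(factor(x$class, levels = forest_class_codes(),
                    labels = names(forest_class_codes())))
  cat("<forest_class_grid: ", paste(names(n), n, sep = " = ", collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}

#' Project carbon density of old forest to the horizon
#'
#' Mature-forest accumulation: `ACD_2050 = ACD + CSR x GP` with a default
#' growth period of 40 years (carbon-density epoch 2010 to horizon 2050),
#' applied to old growth and old secondary pixels with their stratum CSRs.
#'
#' @param acd reference-epoch carbon density (Mg C ha-1), vector or grid.
#' @param csr stratum CSR (Mg C ha-1 yr-1), recycled as needed.
#' @param gp growth period in years, default 40.
#' @return projected ACD, same shape as `acd`.
#' @export
project_acd_old <- function(acd, csr, gp = carbon_constants()$gp_old) {
  acd + csr * gp
}

#' Project carbon density of young secondary forest (two-phase growth)
#'
#' A young stand of age `G = ACD / CSR_young` first grows at its
#' young-secondary rate until it turns 21 (the old-secondary minimum age):
#' `ACD_21 = ACD + CSR_young x (21 - G)`. It then grows as old secondary for
#' the remaining `GP = horizon - (21 - G)` years:
#' `ACD_2050 = ACD_21 + CSR_old x GP`. This encodes the transition of young
#' secondary into old secondary during the projection period. Ages above the
#' transition age are a classification error and raise.
#'
#' @param acd reference-epoch carbon density (Mg C ha-1), vector or grid.
#' @param csr_young,csr_old stratum CSRs for the two phases.
#' @param t_age old-secondary minimum age, default 21.
#' @param horizon projection span in years from the carbon-density epoch,
#'   default 40 (2010 -> 2050).
#' @return projected ACD at the horizon.
#' @examples
#' # age 10 stand: 30 + 3 * 11 = 63 at age 21, then 63 + 0.6 * 29 = 80.4
#' project_acd_young(30, csr_young = 3, csr_old = 0.6)
#' @export
project_acd_young <- function(acd, csr_young, csr_old,
                              t_age = carbon_constants()$t_age,
                              horizon = carbon_constants()$gp_old) {
  g <- acd / csr_young
  if (any(g > t_age, na.rm = TRUE))
    stop("age ACD/CSR exceeds the old-secondary transition age; ",
         "pixel(s) should have been classified old secondary")
  acd_t <- acd + csr_young * (t_age - g)
  gp <- horizon - (t_age - g)
  acd_t + csr_old * gp
}

#' Carbon density of newly gained forest
#'
#' Projected gain pixels are new young secondary forest assumed planted
#' uniformly across the scenario window, so they are credited half the
#' window: `ACD_2050 = CSR_young x 17.5`.
#'
#' @param csr_young stratum young-secondary CSR (vector or grid).
#' @param gp growth period in years, default 17.5.
#' @return projected ACD.
#' @export
acd_new_forest <- function(csr_young, gp = carbon_constants()$gp_new) {
  csr_young * gp
}

#' Project a classified carbon-density grid to the horizon
#'
#' Applies [project_acd_old()] to old growth and old secondary pixels and
#' [project_acd_young()] to young secondary pixels, each with its stratum
#' CSRs, and mosaics the classes into one horizon-year ACD grid (0 off
#' forest).
#'
#' @param classified a `forest_class_grid` from [classify_forest()].
#' @param acd reference-epoch ACD grid.
#' @param csr a [csr_table()].
#' @param ecozones,geographies integer label grids.
#' @param constants list from [carbon_constants()].
#' @return projected ACD grid.
#' @export
project_acd_2050 <- function(classified, acd, csr, ecozones, geographies,
                             constants = carbon_constants()) {
  codes <- forest_class_codes()
  out <- matrix(0, nrow(acd), ncol(acd))
  for (class_name in c("old_growth", "old_secondary")) {
    idx <- which(classified$class == codes[[class_name]])
    if (!length(idx)) next
    rate <- csr_lookup(csr, rep(class_name, length(idx)),
                       ecozones[idx], geographies[idx])
    out[idx] <- project_acd_old(acd[idx], rate, gp = constants$gp_old)
  }
  idx <- which(classified$class == codes[["young_secondary"]])
  if (length(idx)) {
    rate_y <- csr_lookup(csr, rep("young_secondary", length(idx)),
                         ecozones[idx], geographies[idx])
    rate_o <- csr_lookup(csr, rep("old_secondary", length(idx)),
                         ecozones[idx], geographies[idx])
    out[idx] <- project_acd_young(acd[idx], rate_y, rate_o,
                                  t_age = constants$t_age,
                                  horizon = constants$gp_old)
  }
  out
}

## Shared zonal summation: sum ACD x pixel-area over a pixel set, per zone.
zonal_afcs <- function(mask, acd, cell_size, zones, scenario, direction) {
  stopifnot_same_shape(mask, acd)
  px_area <- area_of(1, cell_size)
  idx <- which(mask)
  rows <- list(data.frame(
    scenario = scenario, zone_type = "region", zone_id = "all",
    direction = direction, pixels = length(idx),
    area_ha = area_of(length(idx), cell_size),
    afcs_tg_c = sum(acd[idx]) * px_area / 1e6, stringsAsFactors = FALSE))
  for (zt in names(zones)) {
    z <- zones[[zt]]
    stopifnot_same_shape(mask, z)
    vals <- sort(unique(as.vector(z[!is.na(z)])))
    for (v in vals) {
      sel <- idx[!is.na(z[idx]) & z[idx] == v]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scenario, zone_type = zt, zone_id = as.character(v),
        direction = direction, pixels = length(sel),
        area_ha = area_of(length(sel), cell_size),
        afcs_tg_c = sum(acd[sel]) * px_area / 1e6, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- unique(c("zonal_ledger", class(out)))
  out
}

#' Historical AFCS loss ledger
#'
#' Sums `ACD x pixel area` over the detected forest-loss pixels of a
#' historical change grid, per zone:
#' `AFCS Loss = sum_i ACD_i x A_i`, reported in Tg C (1 Tg = 1e6 Mg).
#'
#' @param change historical `change_grid` (e.g. 2005 -> 2015).
#' @param acd carbon-density grid of the pre-loss reference epoch.
#' @param cell_size cell edge length in metres.
#' @param zones named list of zone label grids (e.g. `country`, `province`).
#' @param scenario label carried into the ledger.
#' @return a `zonal_ledger` data.frame (scenario, zone_type, zone_id,
#'   direction, pixels, area_ha, afcs_tg_c), including a `region/all` row.
#' @export
afcs_change_detect <- function(change, acd, cell_size = NULL, zones = list(),
                               scenario = "historical") {
  cs <- cell_size_of(change, cell_size)
  zonal_afcs(!is.na(change) & change == CHANGE_LOSS, acd, cs, zones,
             scenario, "loss")
}

#' Projected AFCS loss ledger
#'
#' Sums horizon-year `ACD x pixel area` over projected forest-loss pixels per
#' zone (deforestation is assumed to occur at the horizon, so lost stands are
#' credited their full projected density). Pass forest-class, intact-forest
#' and protected-area label grids in `zones` to obtain the class/IF/PA
#' splits.
#'
#' @inheritParams afcs_change_detect
#' @param acd_2050 projected carbon-density grid from [project_acd_2050()].
#' @export
afcs_loss_projected <- function(change, acd_2050, cell_size = NULL,
                                zones = list(), scenario = NA_character_) {
  cs <- cell_size_of(change, cell_size)
  zonal_afcs(!is.na(change) & change == CHANGE_LOSS, acd_2050, cs, zones,
             scenario, "loss")
}

#' Projected AFCS gain ledger
#'
#' Sums new-forest `ACD x pixel area` over projected forest-gain pixels per
#' zone: `AFCS Gain = sum_q ACD_q x A_q`.
#'
#' @inheritParams afcs_change_detect
#' @param acd_new new-forest carbon-density grid from [acd_new_forest()].
#' @export
afcs_gain_projected <- function(change, acd_new, cell_size = NULL,
                                zones = list(), scenario = NA_character_) {
  cs <- cell_size_of(change, cell_size)
  zonal_afcs(!is.na(change) & change == CHANGE_GAIN, acd_new, cs, zones,
             scenario, "gain")
}

#' Annualise an AFCS total and convert to CO2
#'
#' Converts a scenario AFCS change into an annual carbon rate over the
#' scenario horizon and into CO2 equivalents at 3.67 Mg CO2 per Mg C.
#'
#' @param total_tg_c AFCS change in Tg C.
#' @param horizon scenario span in years, default 35 (2015 -> 2050).
#' @param co2_per_c mass ratio, default 3.67.
#' @return list: `rate_tg_c_yr`, `total_pg_co2`, `rate_tg_co2_yr`.
#' @examples
#' annualize_and_convert(1651)  # ~47 Tg C/yr, ~6.1 Pg CO2, ~173 Tg CO2/yr
#' @export
annualize_and_convert <- function(total_tg_c, horizon = 35,
                                  co2_per_c = carbon_constants()$co2_per_c) {
  if (horizon <= 0) stop("`horizon` must be > 0")
  list(rate_tg_c_yr = total_tg_c / horizon,
       total_pg_co2 = total_tg_c * co2_per_c / 1000,
       rate_tg_co2_yr = total_tg_c * co2_per_c / horizon)
}
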