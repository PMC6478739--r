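## Demand quantification: turn a regional SSP forest-area trajectory into
## per-country net change demands using historical change shares.

#' Validate an SSP forest-area projection table
#'
#' The table holds the regional forest-area trajectory per scenario:
#' columns `scenario` (e.g. "SSP1".."SSP5"), `year`, `area_mha`
#' (million hectares). Years must be strictly increasing within a scenario
#' and areas positive.
#'
#' @param table a data.frame with columns `scenario`, `year`, `area_mha`.
#' @return the validated data.frame (invisibly classed `ssp_table`).
#' @export
ssp_projection_table <- function(table) {
  req <- c("scenario", "year", "area_mha")
  if (!all(req %in% names(table)))
    stop("SSP table needs columns: ", paste(req, collapse = ", "))
  if (any(table$area_mha <= 0)) stop("forest areas must be > 0")
  for (sc in unique(table$scenario)) {
    y <- table$year[table$scenario == sc]
    if (any(diff(y) <= 0)) stop("years must be strictly increasing for ", sc)
  }
  class(table) <- unique(c("ssp_table", class(table)))
  table
}

#' Regional net forest-area change under a scenario
#'
#' `area(end) - area(start)` in hectares; the sign decides whether the
#' scenario is forest-gaining (positive) or forest-losing (negative). In the
#' Asian-region trajectories the sustainability scenario gains on the order of
#' 38 million ha over 2015-2050 while the regional-rivalry scenario loses
#' about 10 million ha.
#'
#' @param table an [ssp_projection_table()].
#' @param scenario scenario id present in the table.
#' @param start,end projection years (default 2015 and 2050).
#' @return signed change in hectares.
#' @export
regional_net_change <- function(table, scenario, start = 2015, end = 2050) {
  table <- ssp_projection_table(as.data.frame(table))
  rows <- table[table$scenario == scenario, ]
  if (!nrow(rows)) stop("scenario not in table: ", scenario)
  a0 <- rows$area_mha[rows$year == start]
  a1 <- rows$area_mha[rows$year == end]
  if (!length(a0)) stop("missing year ", start, " for ", scenario)
  if (!length(a1)) stop("missing year ", end, " for ", scenario)
  (a1 - a0) * 1e6
}

#' Per-country shares of historical regional change
#'
#' The fraction each country contributed to the region's total historical
#' forest loss (or gain) in pixels, from a calibration-period change grid.
#' Shares are non-negative and sum to 1.
#'
#' @param change a `change_grid` (typically the long calibration pair,
#'   e.g. 1992 -> 2015).
#' @param countries integer country label grid.
#' @param direction `"loss"` or `"gain"`.
#' @return named numeric vector of shares (names = country ids).
#' @export
historical_shares <- function(change, countries, direction = c("loss", "gain")) {
  direction <- match.arg(direction)
  stopifnot_same_shape(change, countries)
  code <- if (direction == "loss") CHANGE_LOSS else CHANGE_GAIN
  changed <- !is.na(change) & change == code
  ids <- sort(unique(as.vector(countries[!is.na(countries)])))
  counts <- vapply(ids, function(i)
    sum(changed & countries == i, na.rm = TRUE), numeric(1))
  if (sum(counts) == 0)
    stop("no historical ", direction, " anywhere in the region; shares undefined")
  stats::setNames(counts / sum(counts), ids)
}

#' Largest-remainder rounding
#'
#' Splits an integer total across weights so the parts are whole numbers that
#' sum exactly to the total: floor the exact quotas, then hand the leftover
#' units to the largest fractional remainders (ties by order).
#'
#' @param total non-negative integer.
#' @param weights non-negative weights (need not sum to 1).
#' @return integer vector summing to `total`.
#' @examples
#' round_largest_remainder(100, c(1, 1, 1) / 3)  # 34 33 33
#' @export
round_largest_remainder <- function(total, weights) {
  if (total < 0) stop("`total` must be >= 0")
  if (any(weights < 0)) stop("weights must be >= 0")
  if (sum(weights) == 0) stop("weights sum to 0")
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Allocate the regional demand to countries
#'
#' Multiplies the absolute regional 2015-2050 net change by each country's
#' historical share, yielding one demand per country, all in the same
#' direction (a scenario either gains or loses forest, never both: the SSP
#' source only supports net change). Pixel counts are rounded by largest
#' remainder so the regional pixel total is conserved exactly.
#'
#' @param regional_change_ha signed regional change in hectares
#'   (from [regional_net_change()]).
#' @param shares named share vector (from [historical_shares()]),
#'   must sum to 1.
#' @param cell_size cell edge length in metres.
#' @param scenario optional scenario id carried into the output.
#' @return data.frame with columns `country`, `scenario`, `direction`,
#'   `demand_ha`, `demand_px`.
#' @export
allocate_demand <- function(regional_change_ha, shares, cell_size = 300,
                            scenario = NA_character_) {
  if (any(shares < 0)) stop("negative share")
  if (abs(sum(shares) - 1) > 1e-8) stop("shares must sum to 1")
  direction <- if (regional_change_ha >= 0) "gain" else "loss"
  total_ha <- abs(regional_change_ha)
  total_px <- pixels_of(total_ha, cell_size)
  px <- round_largest_remainder(total_px, shares)
  data.frame(
    country = names(shares),
    scenario = scenario,
    direction = direction,
    demand_ha = total_ha * as.numeric(shares),
    demand_px = px,
    stringsAsFactors = FALSE
  )
}
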