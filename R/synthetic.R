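## Synthetic landscape generator: co-registered grids with the statistical
## structure the pipeline assumes (change concentrated near roads and forest
## edges via a known logistic process, biomass consistent with the forest-age
## model), so every downstream stage is testable without external data.

#' Parameters of the synthetic change-generating process
#'
#' The "true" process the transition models are later asked to learn: per
#' epoch step, a fixed fraction of the forest is lost and a fixed fraction
#' (of the forest count) is gained, with per-pixel selection probability
#' `sigma(beta0 + sum beta_k z_k)` over z-scored drivers (distance to road
#' and distance to forest edge). Negative coefficients concentrate change
#' near roads and edges, the canonical accessibility pattern of tropical
#' deforestation.
#'
#' @param beta0 intercept.
#' @param beta_road,beta_edge coefficients on z-scored distance-to-road and
#'   distance-to-edge.
#' @param loss_frac,gain_frac per-step change fractions, each in \[0, 1),
#'   both expressed relative to the epoch's forest pixel count.
#' @return a `change_process_params` list.
#' @export
change_process_params <- function(beta0 = 0, beta_road = -1.5,
                                  beta_edge = -1.5,
                                  loss_frac = 0.05, gain_frac = 0.02) {
  stopifnot(is.finite(c(beta0, beta_road, beta_edge)))
  if (loss_frac < 0 || loss_frac >= 1 || gain_frac < 0 || gain_frac >= 1)
    stop("loss and gain fractions must be in [0, 1)")
  structure(list(beta0 = beta0, beta_road = beta_road, beta_edge = beta_edge,
                 loss_frac = loss_frac, gain_frac = gain_frac),
            class = "change_process_params")
}

## Smoothed standard-normal random field, rescaled to [0, 1].
smooth_field <- function(shape, sigma) {
  f <- EBImage::imageData(EBImage::gblur(
    matrix(stats::rnorm(prod(shape)), shape[1], shape[2]),
    sigma = sigma, boundary = "replicate"))
  f <- as.matrix(f)
  (f - min(f)) / (max(f) - min(f) + 1e-12)
}

## Nearest-seed (Voronoi) labelling of the grid.
voronoi_labels <- function(shape, pts, labels = seq_len(nrow(pts))) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1], shape[2])
  best <- matrix(Inf, shape[1], shape[2])
  lab <- matrix(labels[1], shape[1], shape[2])
  for (i in seq_len(nrow(pts))) {
    d <- (rows - pts[i, 1])^2 + (cols - pts[i, 2])^2
    sel <- d < best
    best[sel] <- d[sel]
    lab[sel] <- labels[i]
  }
  lab
}

## Integer raster line (Bresenham).
raster_line <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dr - dc
  out <- matrix(integer(0), 0, 2)
  r <- r0; c <- c0
  repeat {
    out <- rbind(out, c(r, c))
    if (r == r1 && c == c1) break
    e2 <- 2 * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr)  { err <- err + dr; c <- c + sc }
  }
  out
}

## z-score that tolerates constant fields (returns zeros).
zscore0 <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

## Land-cover codes used by the generator (ESA-CCI dialect subset).
LC_FOREST <- 50L
LC_CROP <- 10L
LC_URBAN <- 190L
LC_WATER <- 210L

#' Evolve a land-cover grid under the synthetic change process
#'
#' Steps a class-coded land-cover grid through `epochs - 1` change events.
#' Each step loses `loss_frac x forest count` forest pixels and gains
#' `gain_frac x forest count` new forest pixels; changing pixels are drawn
#' without replacement with selection weights `sigma(beta . drivers)`, so
#' realised fractions match the requested fractions exactly (up to rounding)
#' while the spatial pattern follows the logistic. Losses come only from
#' forest; gains land only on plain non-forest (never urban or water). A gain
#' demand larger than the eligible non-forest pool is an explicit error.
#'
#' @param landcover starting class-coded grid (codes 50/10/190/210).
#' @param params a [change_process_params()].
#' @param epochs total number of epochs to return (>= 2).
#' @param road_mask binary road mask used by the driver logistic.
#' @param cell_size cell edge length in metres.
#' @param seed RNG seed.
#' @return list of `epochs` land-cover grids (the first is the input).
#' @export
evolve_landcover <- function(landcover, params, epochs = 2, road_mask,
                             cell_size = 300, seed = 1) {
  if (epochs < 2) stop("`epochs` must be >= 2")
  if (!inherits(params, "change_process_params"))
    stop("`params` must come from change_process_params()")
  stopifnot_same_shape(landcover, road_mask)
  dist_road <- if (any(road_mask != 0))
    euclidean_distance(road_mask, cell_size) else landcover * 0
  out <- vector("list", epochs)
  out[[1]] <- landcover
  lc <- landcover
  with_seed(seed, {
    for (t in 2:epochs) {
      forest <- which(lc == LC_FOREST)
      open <- which(lc == LC_CROP)
      n_loss <- round(params$loss_frac * length(forest))
      n_gain <- round(params$gain_frac * length(forest))
      if (n_gain > length(open))
        stop(sprintf("gain demand (%d px) exceeds eligible non-forest pool (%d px)",
                     n_gain, length(open)))
      if (n_loss > length(forest))
        stop("loss demand exceeds the forest pool")
      edge_in <- edge_out <- lc * 0
      if (length(forest) && length(forest) < length(lc)) {
        fnf01 <- matrix(0L, nrow(lc), ncol(lc)); fnf01[forest] <- 1L
        edge_in <- euclidean_distance(fnf01 == 0, cell_size)
        edge_out <- euclidean_distance(fnf01 == 1, cell_size)
      }
      if (n_loss > 0) {
        z1 <- zscore0(dist_road[forest]); z2 <- zscore0(edge_in[forest])
        p <- stats::plogis(params$beta0 + params$beta_road * z1 +
                             params$beta_edge * z2)
        lc[sample(forest, n_loss, prob = p)] <- LC_CROP
      }
      if (n_gain > 0) {
        z1 <- zscore0(dist_road[open]); z2 <- zscore0(edge_out[open])
        p <- stats::plogis(params$beta0 + params$beta_road * z1 +
                             params$beta_edge * z2)
        lc[sample(open, n_gain, prob = p)] <- LC_FOREST
      }
      out[[t]] <- lc
    }
  })
  out
}

#' Synthetic aboveground biomass consistent with the age model
#'
#' Builds an AGB grid (Mg ha-1) from planted stand ages so the carbon
#' module's inverse exactly recovers them: for secondary forest,
#' `AGB = 2 x age x CSR_young(stratum)`, hence `ACD / CSR = age`. Forest
#' inside the intact-forest mask is old growth with ACD fixed at
#' `1.5 x og_floor` (safely above the classification floor). Non-forest
#' pixels get 0. Optional multiplicative lognormal noise (`sigma`) emulates
#' biomass-map error; the default 0 keeps exact recovery.
#'
#' @param fnf [fnf_grid()] of the epoch.
#' @param age stand-age grid in years (> 0 on forest outside the IFL).
#' @param csr a [csr_table()].
#' @param ecozones,geographies integer label grids.
#' @param ifl optional intact-forest mask (old-growth pixels).
#' @param og_floor old-growth ACD floor used downstream, default 100.
#' @param sigma lognormal noise sd on the log scale, default 0.
#' @param seed RNG seed (used only when `sigma > 0`).
#' @return AGB matrix (Mg ha-1).
#' @export
generate_agb <- function(fnf, age, csr, ecozones, geographies, ifl = NULL,
                         og_floor = 100, sigma = 0, seed = 1) {
  stopifnot_same_shape(fnf, age, ecozones, geographies)
  forest <- !is.na(fnf) & unclass(fnf) == 1L
  if (any(forest & (is.na(age) | age < 0) & !(if (is.null(ifl)) FALSE else ifl != 0)))
    stop("every non-intact forest pixel needs a non-negative age")
  agb <- matrix(0, nrow(fnf), ncol(fnf))
  og <- if (is.null(ifl)) forest & FALSE else forest & (ifl != 0)
  sec <- which(forest & !og)
  if (length(sec)) {
    rate <- csr_lookup(csr, rep("young_secondary", length(sec)),
                       ecozones[sec], geographies[sec])
    agb[sec] <- 2 * age[sec] * rate
  }
  agb[og] <- 2 * (1.5 * og_floor)
  if (sigma > 0) {
    idx <- which(forest)
    with_seed(seed, {
      agb[idx] <- agb[idx] * exp(stats::rnorm(length(idx), -sigma^2 / 2, sigma))
    })
  }
  agb
}

#' Generate a complete synthetic landscape bundle
#'
#' Builds all co-registered grids the pipeline consumes on one equal-area
#' grid: a smoothed random elevation field, rasterised road polylines, urban
#' and water masks (disjoint), Voronoi country labels with nested province
#' sub-partitions, ecozone and continental/insular labels, a land-cover epoch
#' series evolved under a known logistic change process, intact-forest and
#' protected-area masks, stand-age grids and age-consistent AGB for the two
#' biomass epochs. Deterministic under `seed`.
#'
#' @param shape grid dimensions `c(rows, cols)`, each >= 32.
#' @param cell_size cell edge length in metres, default 300.
#' @param seed RNG seed.
#' @param forest_fraction initial forest fraction of the land area
#'   (in \[0, 1\]), default 0.5.
#' @param n_countries,n_provinces countries in the region and provinces per
#'   country.
#' @param n_roads number of road polylines.
#' @param params a [change_process_params()] for the epoch evolution.
#' @param epochs number of land-cover epochs (default 3, labelled
#'   1992/2005/2015).
#' @param csr a [csr_table()]; default [default_csr_table()].
#' @param og_floor old-growth ACD floor (Mg C ha-1).
#' @param agb_sigma lognormal AGB noise (0 = exact age recovery).
#' @return a `landscape_bundle` list; see the fields in the source and the
#'   methods vignette.
#' @export
generate_landscape <- function(shape = c(64, 64), cell_size = 300, seed = 1,
                               forest_fraction = 0.5, n_countries = 2,
                               n_provinces = 2, n_roads = 3,
                               params = change_process_params(), epochs = 3,
                               csr = default_csr_table(), og_floor = 100,
                               agb_sigma = 0) {
  if (length(shape) != 2 || any(shape < 32))
    stop("shape too small: need at least 32x32 to place roads, towns and zones")
  if (cell_size <= 0) stop("`cell_size` must be > 0")
  if (forest_fraction < 0 || forest_fraction > 1)
    stop("`forest_fraction` must be in [0, 1]")
  nr <- shape[1]; nc <- shape[2]
  b <- with_seed(seed, {
    sig <- max(2, min(shape) / 16)
    elevation <- 1500 * smooth_field(shape, sig)

    ## countries and nested provinces (Voronoi, provinces sub-partition)
    cpts <- cbind(sample(nr, n_countries), sample(nc, n_countries))
    countries <- voronoi_labels(shape, cpts)
    provinces <- matrix(NA_integer_, nr, nc)
    for (ctry in seq_len(n_countries)) {
      inside <- which(countries == ctry)
      k <- min(n_provinces, length(inside))
      ppts_idx <- sample(inside, k)
      ppts <- cbind((ppts_idx - 1) %% nr + 1, (ppts_idx - 1) %/% nr + 1)
      plab <- voronoi_labels(shape, ppts, labels = ctry * 100L + seq_len(k))
      provinces[inside] <- plab[inside]
    }

    ## roads: polylines between random border points
    road_mask <- matrix(0L, nr, nc)
    border <- function() {
      side <- sample(4, 1)
      switch(side, c(1, sample(nc, 1)), c(nr, sample(nc, 1)),
             c(sample(nr, 1), 1), c(sample(nr, 1), nc))
    }
    for (i in seq_len(n_roads)) {
      a <- border(); z <- border()
      pts <- raster_line(a[1], a[2], z[1], z[2])
      road_mask[pts] <- 1L
    }

    ## towns on roads (3x3 blobs); water from a smoothed field, kept disjoint
    urban_mask <- matrix(0L, nr, nc)
    road_idx <- which(road_mask == 1L)
    for (ctr in sample(road_idx, min(3, length(road_idx)))) {
      r <- (ctr - 1) %% nr + 1; c <- (ctr - 1) %/% nr + 1
      rr <- max(1, r - 1):min(nr, r + 1); cc <- max(1, c - 1):min(nc, c + 1)
      urban_mask[rr, cc] <- 1L
    }
    wf <- smooth_field(shape, sig)
    water_mask <- (wf <= stats::quantile(wf, 0.04)) * 1L
    water_mask[urban_mask == 1L] <- 0L

    ## initial forest: top fraction of a smoothed suitability field on land
    land <- urban_mask == 0L & water_mask == 0L
    ff <- smooth_field(shape, sig)
    lc0 <- matrix(LC_CROP, nr, nc)
    lc0[urban_mask == 1L] <- LC_URBAN
    lc0[water_mask == 1L] <- LC_WATER
    n_forest <- round(forest_fraction * sum(land))
    if (n_forest > 0) {
      land_idx <- which(land)
      lc0[land_idx[order(ff[land_idx], decreasing = TRUE)[seq_len(n_forest)]]] <-
        LC_FOREST
    }

    ## ecozones (Voronoi) and continental/insular geography (per country)
    epts <- cbind(sample(nr, 2), sample(nc, 2))
    ecozones <- voronoi_labels(shape, epts)
    geo_of_country <- rep_len(1:2, n_countries)
    geographies <- matrix(geo_of_country[countries], nr, nc)

    ## protected area: a disk around a random centre (~15% of the region)
    ctr <- c(sample(nr, 1), sample(nc, 1))
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    pa <- ((rows - ctr[1])^2 + (cols - ctr[2])^2 <=
             (0.22 * min(shape))^2) * 1L

    list(elevation = elevation, countries = countries, provinces = provinces,
         road_mask = road_mask, urban_mask = urban_mask,
         water_mask = water_mask, lc0 = lc0, ecozones = ecozones,
         geographies = geographies, pa = pa, ifl_field = smooth_field(shape, sig))
  })

  lc_series <- evolve_landcover(b$lc0, params, epochs = epochs,
                                road_mask = b$road_mask,
                                cell_size = cell_size, seed = seed + 1L)
  epoch_labels <- if (epochs <= 3) c(1992, 2005, 2015)[seq_len(epochs)] else
    seq_len(epochs)
  names(lc_series) <- epoch_labels
  lc_mid <- lc_series[[max(1, epochs - 1)]]
  lc_end <- lc_series[[epochs]]

  ## intact forest: high-suitability contiguous core of the final forest
  forest_end <- lc_end == LC_FOREST
  ifl <- matrix(0L, nr, nc)
  if (any(forest_end)) {
    thr <- stats::quantile(b$ifl_field[forest_end], 0.85)
    ifl[forest_end & b$ifl_field >= thr] <- 1L
  }

  ## stand ages (years) and age-consistent AGB for the two biomass epochs
  fnf_mid <- fnf_grid((lc_mid == LC_FOREST) * 1L, cell_size,
                      epoch = epoch_labels[max(1, epochs - 1)])
  fnf_end <- fnf_grid(forest_end * 1L, cell_size, epoch = epoch_labels[epochs])
  ages <- with_seed(seed + 2L, {
    a0 <- matrix(NA_real_, nr, nc)
    i0 <- which(lc_mid == LC_FOREST)
    a0[i0] <- sample(40L, length(i0), replace = TRUE)
    a1 <- matrix(NA_real_, nr, nc)
    i1 <- which(forest_end)
    a1[i1] <- sample(40L, length(i1), replace = TRUE)
    list(a0 = a0, a1 = a1)
  })
  agb_t0 <- generate_agb(fnf_mid, ages$a0, csr, b$ecozones, b$geographies,
                         ifl = ifl, og_floor = og_floor, sigma = agb_sigma,
                         seed = seed + 3L)
  agb_t1 <- generate_agb(fnf_end, ages$a1, csr, b$ecozones, b$geographies,
                         ifl = ifl, og_floor = og_floor, sigma = agb_sigma,
                         seed = seed + 4L)

  structure(list(
    shape = shape, cell_size = cell_size, seed = seed,
    landcover = lc_series, elevation = b$elevation,
    road_mask = b$road_mask, urban_mask = b$urban_mask,
    water_mask = b$water_mask,
    countries = b$countries, provinces = b$provinces,
    ecozones = b$ecozones, geographies = b$geographies,
    ifl = ifl, pa = b$pa,
    age_t0 = ages$a0, age_t1 = ages$a1,
    agb_t0 = agb_t0, agb_t1 = agb_t1,
    params = params, forest_fraction = forest_fraction,
    og_floor = og_floor, csr = csr
  ), class = "landscape_bundle")
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat(sprintf("<landscape_bundle %dx%d @ %g m, seed %d: %d epochs (%s), %d countries>\n",
              x$shape[1], x$shape[2], x$cell_size, x$seed,
              length(x$landcover), paste(names(x$landcover), collapse = ", "),
              length(unique(as.vector(x$countries)))))
  invisible(x)
}
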