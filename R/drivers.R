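## The seven spatial driver grids used as transition-potential predictors:
## elevation, slope, distance to road, distance to urban, province change
## share, distance to past change, and distance to forest edge.

#' Slope from elevation (Horn's method)
#'
#' Computes slope in degrees from an elevation grid with the Horn 3x3 kernel
#' (weighted central differences). The grid is padded by linear extrapolation
#' so edge pixels reduce to one-sided differences; a planar ramp therefore has
#' constant slope everywhere, edges included.
#'
#' @param elevation numeric matrix, metres.
#' @param cell_size cell edge length in metres.
#' @return slope matrix in degrees, values in \[0, 90).
#' @examples
#' ramp <- matrix(rep(seq(0, 300 * 7, by = 300), each = 8), 8)
#' slope_from_elevation(ramp, 300)[1, 1]  # 45 degrees
#' @export
slope_from_elevation <- function(elevation, cell_size) {
  if (cell_size <= 0) stop("`cell_size` must be > 0")
  if (any(!is.finite(elevation))) stop("elevation must be finite")
  nr <- nrow(elevation); nc <- ncol(elevation)
  ## pad by linear extrapolation: p = 2 * edge - inner
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- elevation
  z[1, 2:(nc + 1)] <- 2 * elevation[1, ] - elevation[min(2, nr), ]
  z[nr + 2, 2:(nc + 1)] <- 2 * elevation[nr, ] - elevation[max(nr - 1, 1), ]
  z[, 1] <- 2 * z[, 2] - z[, 3]
  z[, nc + 2] <- 2 * z[, nc + 1] - z[, nc]
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  ## column index = x, row index = y
  dzdx <- ((z[i - 1, j + 1] + 2 * z[i, j + 1] + z[i + 1, j + 1]) -
           (z[i - 1, j - 1] + 2 * z[i, j - 1] + z[i + 1, j - 1])) / (8 * cell_size)
  dzdy <- ((z[i + 1, j - 1] + 2 * z[i + 1, j] + z[i + 1, j + 1]) -
           (z[i - 1, j - 1] + 2 * z[i - 1, j] + z[i - 1, j + 1])) / (8 * cell_size)
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}

#' Euclidean distance to the nearest masked pixel
#'
#' Exact centre-to-centre Euclidean distance (metres) from every pixel to the
#' nearest `TRUE` pixel of the mask, via a distance transform. Pixels inside
#' the mask are at distance 0.
#'
#' @param mask logical or 0/1 matrix with at least one `TRUE` pixel.
#' @param cell_size cell edge length in metres.
#' @return numeric matrix of distances in metres.
#' @export
euclidean_distance <- function(mask, cell_size) {
  if (cell_size <= 0) stop("`cell_size` must be > 0")
  m <- (as.matrix(mask) != 0) * 1
  if (!any(m == 1)) stop("distance target mask is empty")
  ## distmap: each non-zero pixel gets distance to the nearest zero pixel,
  ## so invert: targets become background.
  d <- EBImage::imageData(EBImage::distmap(1 - m, metric = "euclidean"))
  as.matrix(d) * cell_size
}

#' Distance to forest edge, inward or outward
#'
#' `inward` gives, for every forest pixel, the distance to the nearest
#' non-forest pixel (depth into the forest interior; used by loss models) and
#' 0 on non-forest. `outward` gives, for every non-forest pixel, the distance
#' to the nearest forest pixel (used by gain models) and 0 on forest. A
#' boundary pixel is one cell from the other class, never zero.
#'
#' @param fnf an [fnf_grid()] (or 0/1 matrix) with both classes present.
#' @param direction `"inward"` or `"outward"`.
#' @param cell_size cell edge length in metres; defaults to the grid's.
#' @return numeric matrix of distances in metres.
#' @export
forest_edge_distance <- function(fnf, direction = c("inward", "outward"),
                                 cell_size = NULL) {
  direction <- match.arg(direction)
  cs <- cell_size_of(fnf, cell_size)
  m <- unclass(fnf)
  m[is.na(m)] <- 0L
  if (!any(m == 1) || !any(m == 0))
    stop("forest_edge_distance requires both forest and non-forest pixels")
  if (direction == "inward") {
    euclidean_distance(m == 0, cs) # forest pixels: distance to non-forest
  } else {
    euclidean_distance(m == 1, cs) # non-forest pixels: distance to forest
  }
}

#' Per-province historical change share grid
#'
#' Every pixel of province p carries p's share of its country's historical
#' forest change (loss or gain) in pixels. Within each country the province
#' shares sum to 1; a country with no historical change in the requested
#' direction gets an all-zero grid with a warning.
#'
#' @param change a `change_grid` from [detect_change()].
#' @param provinces,countries integer label grids (provinces nest in countries).
#' @param direction `"loss"` or `"gain"`.
#' @return numeric matrix of shares in \[0, 1\].
#' @export
province_share_grid <- function(change, provinces, countries,
                                direction = c("loss", "gain")) {
  direction <- match.arg(direction)
  stopifnot_same_shape(change, provinces, countries)
  code <- if (direction == "loss") CHANGE_LOSS else CHANGE_GAIN
  changed <- !is.na(change) & change == code
  out <- matrix(0, nrow(change), ncol(change))
  for (ctry in sort(unique(as.vector(countries[!is.na(countries)])))) {
    in_ctry <- !is.na(countries) & countries == ctry
    total <- sum(changed & in_ctry)
    if (total == 0) {
      warning(sprintf("country %s has no historical %s; province shares set to 0",
                      ctry, direction))
      next
    }
    provs <- unique(as.vector(provinces[in_ctry]))
    for (p in provs[!is.na(provs)]) {
      in_prov <- in_ctry & !is.na(provinces) & provinces == p
      out[in_prov] <- sum(changed & in_prov) / total
    }
  }
  out
}

#' Assemble the seven-driver predictor stack
#'
#' Builds the named driver grids a transition model consumes: `elevation`,
#' `slope`, `dist_road`, `dist_urban`, `province_share`, `dist_change`
#' (distance to historical loss pixels for loss models, gain pixels for gain
#' models) and `dist_edge` (inward forest-edge distance for loss, outward for
#' gain). All grids are checked for co-registration and finiteness.
#'
#' @param elevation elevation grid (m).
#' @param road_mask,urban_mask binary masks.
#' @param fnf present-epoch [fnf_grid()].
#' @param change historical `change_grid` (calibration period).
#' @param provinces,countries integer label grids.
#' @param direction `"loss"` or `"gain"`.
#' @param cell_size cell edge length in metres.
#' @return a named list of 7 matrices with class `driver_stack` and attributes
#'   `direction` and `cell_size`.
#' @export
build_driver_stack <- function(elevation, road_mask, urban_mask, fnf, change,
                               provinces, countries,
                               direction = c("loss", "gain"), cell_size = 300) {
  direction <- match.arg(direction)
  stopifnot_same_shape(elevation, road_mask, urban_mask, fnf, change,
                       provinces, countries)
  code <- if (direction == "loss") CHANGE_LOSS else CHANGE_GAIN
  changed_mask <- !is.na(change) & change == code
  dist_change <- if (any(changed_mask)) {
    euclidean_distance(changed_mask, cell_size)
  } else {
    warning("no historical ", direction, " pixels; dist_change is constant 0")
    matrix(0, nrow(change), ncol(change))
  }
  stack <- list(
    elevation = elevation,
    slope = slope_from_elevation(elevation, cell_size),
    dist_road = euclidean_distance(road_mask, cell_size),
    dist_urban = euclidean_distance(urban_mask, cell_size),
    province_share = province_share_grid(change, provinces, countries, direction),
    dist_change = dist_change,
    dist_edge = forest_edge_distance(
      fnf, if (direction == "loss") "inward" else "outward", cell_size)
  )
  for (nm in names(stack))
    if (any(!is.finite(stack[[nm]])))
      stop("driver `", nm, "` contains non-finite values")
  structure(stack, direction = direction, cell_size = cell_size,
            class = "driver_stack")
}

#' @export
print.driver_stack <- function(x, ...) {
  cat(sprintf("<driver_stack (%s) %dx%d: %s>\n", attr(x, "direction"),
              nrow(x[[1]]), ncol(x[[1]]), paste(names(x), collapse = ", ")))
  invisible(x)
}
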