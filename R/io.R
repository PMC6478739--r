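## Grid and table I/O.  Grids are written as single-band 32-bit float TIFF
## with a YAML sidecar (<path>.yml) carrying cell size, epoch, value scaling,
## the nodata sentinel and the generator seed; the TIFF payload is
## min-max-scaled to [0, 1] and reconstructed on read from the sidecar.

#' Write a grid as TIFF with a YAML sidecar
#'
#' @param grid numeric matrix (NA allowed).
#' @param path output `.tif` path; the sidecar is written at `<path>.yml`.
#' @param cell_size cell edge length in metres.
#' @param meta optional named list of extra metadata (epoch, seed, dialect,
#'   band name, ...) stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, cell_size = attr(grid, "cell_size") %||% 300,
                       meta = list()) {
  g <- unclass(grid)
  finite <- g[is.finite(g)]
  lo <- if (length(finite)) min(finite) else 0
  hi <- if (length(finite)) max(finite) else 0
  span <- if (hi > lo) hi - lo else 1
  scaled <- (g - lo) / span
  scaled[!is.finite(scaled)] <- 0  # nodata sentinel position recorded below
  nodata_idx <- which(!is.finite(g))
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  sidecar <- c(list(cell_size = cell_size, nrow = nrow(g), ncol = ncol(g),
                    value_min = lo, value_max = hi,
                    nodata_cells = as.integer(nodata_idx)), meta)
  yaml::write_yaml(sidecar, paste0(path, ".yml"))
  invisible(path)
}

#' Read a grid written by [write_grid()]
#'
#' @param path the `.tif` path.
#' @return numeric matrix with a `cell_size` attribute and a `meta` attribute
#'   holding the full sidecar.
#' @export
read_grid <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yml"))
  scaled <- tiff::readTIFF(path)
  g <- scaled * (side$value_max - side$value_min) + side$value_min
  if (side$value_max == side$value_min) g[] <- side$value_min
  if (length(side$nodata_cells)) g[side$nodata_cells] <- NA_real_
  structure(matrix(g, side$nrow, side$ncol),
            cell_size = side$cell_size, meta = side)
}

#' Write a landscape bundle to a directory
#'
#' One TIFF per grid plus a `bundle.yml` manifest (shape, cell size, seed,
#' change-process parameters, epoch labels) and the CSR table as CSV.
#'
#' @param bundle a `landscape_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grids <- c(list(elevation = bundle$elevation, road_mask = bundle$road_mask,
                  urban_mask = bundle$urban_mask, water_mask = bundle$water_mask,
                  countries = bundle$countries, provinces = bundle$provinces,
                  ecozones = bundle$ecozones, geographies = bundle$geographies,
                  ifl = bundle$ifl, pa = bundle$pa,
                  agb_t0 = bundle$agb_t0, agb_t1 = bundle$agb_t1),
             stats::setNames(bundle$landcover,
                             paste0("landcover_", names(bundle$landcover))))
  for (nm in names(grids))
    write_grid(grids[[nm]], file.path(dir, paste0(nm, ".tif")),
               cell_size = bundle$cell_size,
               meta = list(band = nm, seed = bundle$seed,
                           dialect = "esa_cci_v2.07"))
  yaml::write_yaml(list(shape = bundle$shape, cell_size = bundle$cell_size,
                        seed = bundle$seed, epochs = names(bundle$landcover),
                        forest_fraction = bundle$forest_fraction,
                        og_floor = bundle$og_floor,
                        params = unclass(bundle$params)),
                   file.path(dir, "bundle.yml"))
  utils::write.csv(bundle$csr, file.path(dir, "csr.csv"), row.names = FALSE)
  invisible(dir)
}
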