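## Reclassification of class-coded land cover to forest/non-forest, change
## detection between epochs, and pixel-count -> hectare arithmetic.

#' ESA-CCI-style forest class codes
#'
#' The tree-cover classes of the ESA-CCI v2.07 legend treated as forest:
#' broadleaved evergreen/deciduous (50, 60-62), needleleaved (70-72, 80-82),
#' mixed leaf type (90) and flooded tree cover (160, 170).
#'
#' @return integer vector of class codes.
#' @export
esa_forest_codes <- function() {
  c(50L, 60L, 61L, 62L, 70L, 71L, 72L, 80L, 81L, 82L, 90L, 160L, 170L)
}

#' Land-cover reclassification dialect
#'
#' A dialect maps every class code that may appear in a land-cover grid to one
#' of `forest`, `nonforest` or `nodata`. The default covers the ESA-CCI v2.07
#' legend, with code 0 as nodata and everything that is not tree cover
#' (cropland, grassland, urban 190, water 210, ...) as non-forest.
#'
#' @param forest,nonforest,nodata integer code vectors; must be disjoint.
#' @return a list with class `lc_dialect`.
#' @export
lc_dialect <- function(forest, nonforest, nodata = integer()) {
  all_codes <- c(forest, nonforest, nodata)
  if (anyDuplicated(all_codes)) stop("dialect code sets overlap")
  structure(list(forest = as.integer(forest),
                 nonforest = as.integer(nonforest),
                 nodata = as.integer(nodata)),
            class = "lc_dialect")
}

#' @rdname lc_dialect
#' @export
esa_cci_dialect <- function() {
  lc_dialect(
    forest = esa_forest_codes(),
    nonforest = c(10L, 11L, 12L, 20L, 30L, 40L, 100L, 110L, 120L, 121L, 122L,
                  130L, 140L, 150L, 151L, 152L, 153L, 180L, 190L, 200L, 201L,
                  202L, 210L, 220L),
    nodata = 0L
  )
}

#' Reclassify a land-cover grid to forest/non-forest
#'
#' Applies a total code mapping to produce a binary F/NF map. Any code present
#' in the grid but absent from the dialect is an error (all offending codes are
#' listed), so silent misclassification is impossible.
#'
#' @param landcover integer matrix of class codes.
#' @param dialect an [lc_dialect()]; default [esa_cci_dialect()].
#' @param cell_size cell edge length in metres.
#' @param epoch optional epoch label forwarded to the result.
#' @return an [fnf_grid()].
#' @examples
#' lc <- matrix(c(50, 190, 170, 10), 2)
#' reclassify_to_fnf(lc)  # codes 50 and 170 are forest
#' @export
reclassify_to_fnf <- function(landcover, dialect = esa_cci_dialect(),
                              cell_size = 300, epoch = NULL) {
  if (!inherits(dialect, "lc_dialect")) stop("`dialect` must be an lc_dialect")
  codes <- unique(as.vector(landcover))
  codes <- codes[!is.na(codes)]
  known <- c(dialect$forest, dialect$nonforest, dialect$nodata)
  unknown <- setdiff(codes, known)
  if (length(unknown))
    stop("unknown land-cover class codes: ", paste(sort(unknown), collapse = ", "))
  out <- matrix(NA_integer_, nrow(landcover), ncol(landcover))
  out[landcover %in% dialect$forest] <- 1L
  out[landcover %in% dialect$nonforest] <- 0L
  fnf_grid(out, cell_size = cell_size, epoch = epoch)
}

#' Detect forest cover change between two epochs
#'
#' Compares two co-registered F/NF maps and labels every pixel as forest loss
#' (1 -> 0), forest gain (0 -> 1), forest persistence or non-forest
#' persistence. A pixel that is nodata in either epoch is nodata in the
#' result: no change claim without both observations.
#'
#' @param fnf_t1,fnf_t2 [fnf_grid()] objects, `t1` the earlier epoch.
#' @return a `change_grid` (codes 1..4, see [change_levels()]).
#' @export
detect_change <- function(fnf_t1, fnf_t2) {
  stopifnot_same_shape(fnf_t1, fnf_t2)
  cs <- cell_size_of(fnf_t1)
  out <- matrix(NA_integer_, nrow(fnf_t1), ncol(fnf_t1))
  ok <- !is.na(fnf_t1) & !is.na(fnf_t2)
  a <- unclass(fnf_t1); b <- unclass(fnf_t2)
  out[ok & a == 1 & b == 0] <- CHANGE_LOSS
  out[ok & a == 0 & b == 1] <- CHANGE_GAIN
  out[ok & a == 1 & b == 1] <- CHANGE_FOREST_PERSIST
  out[ok & a == 0 & b == 0] <- CHANGE_NONFOREST_PERSIST
  new_change_grid(out, cell_size = cs,
                  epochs = c(attr(fnf_t1, "epoch") %||% NA,
                             attr(fnf_t2, "epoch") %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a pixel count to hectares
#'
#' Constant-cell-area arithmetic: `pixels * cell_size^2 / 10000`. Pixel counts
#' are the package's internal currency; hectares are derived at reporting time.
#'
#' @param pixels non-negative pixel count.
#' @param cell_size cell edge length in metres.
#' @return area in hectares.
#' @examples
#' area_of(1, 300)  # 9 ha
#' @export
area_of <- function(pixels, cell_size) {
  if (cell_size <= 0) stop("`cell_size` must be > 0")
  pixels * cell_size^2 / 1e4
}

#' Convert hectares to a whole pixel count
#'
#' @param hectares area in hectares.
#' @param cell_size cell edge length in metres.
#' @return rounded pixel count.
#' @export
pixels_of <- function(hectares, cell_size) {
  if (cell_size <= 0) stop("`cell_size` must be > 0")
  as.integer(round(hectares / (cell_size^2 / 1e4)))
}
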