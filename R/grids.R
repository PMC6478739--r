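## Lightweight grid containers.  All spatial layers are plain R matrices on a
## common equal-area grid; cell geometry is carried as attributes, never as
## geodesy.  Constant cell area (cell_size^2 m2 -> ha) is the working model.

#' Forest/non-forest grid
#'
#' Wraps a binary matrix (1 = forest, 0 = non-forest, `NA` = nodata) with its
#' cell size and an epoch label. This is the central state object of the
#' pipeline: change detection, transition modelling and allocation all operate
#' on pairs of these.
#'
#' @param values integer or numeric matrix with values in \{0, 1, NA\}.
#' @param cell_size cell edge length in metres (> 0).
#' @param epoch optional epoch label (e.g. a year).
#' @return An object of class `fnf_grid`: the matrix with `cell_size` and
#'   `epoch` attributes.
#' @examples
#' f <- fnf_grid(matrix(c(1, 0, 1, 0), 2), cell_size = 300, epoch = 2015)
#' forest_count(f)
#' @export
fnf_grid <- function(values, cell_size = 300, epoch = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (cell_size <= 0) stop("`cell_size` must be > 0")
  v <- values[!is.na(values)]
  if (length(v) && !all(v %in% c(0, 1)))
    stop("fnf_grid values must be 0, 1 or NA")
  structure(values, cell_size = cell_size, epoch = epoch,
            class = c("fnf_grid", class(values)))
}

#' @export
print.fnf_grid <- function(x, ...) {
  cat(sprintf("<fnf_grid %dx%d, cell %g m, epoch %s: %d forest / %d non-forest / %d nodata>\n",
              nrow(x), ncol(x), attr(x, "cell_size"),
              if (is.null(attr(x, "epoch"))) "?" else format(attr(x, "epoch")),
              sum(x == 1, na.rm = TRUE), sum(x == 0, na.rm = TRUE), sum(is.na(x))))
  invisible(x)
}

#' @rdname fnf_grid
#' @param x an `fnf_grid`.
#' @export
forest_count <- function(x) sum(x == 1, na.rm = TRUE)

#' @rdname fnf_grid
#' @export
nonforest_count <- function(x) sum(x == 0, na.rm = TRUE)

cell_size_of <- function(x, cell_size = NULL) {
  cs <- if (is.null(cell_size)) attr(x, "cell_size") else cell_size
  if (is.null(cs)) stop("cell size neither supplied nor carried by the grid")
  cs
}

## Change category codes (internal currency; labels for reporting).
CHANGE_LOSS <- 1L
CHANGE_GAIN <- 2L
CHANGE_FOREST_PERSIST <- 3L
CHANGE_NONFOREST_PERSIST <- 4L

#' Change category labels
#'
#' Category labels used by [detect_change()] grids, in code order 1..4.
#' @return character vector of length 4.
#' @export
change_levels <- function() {
  c("loss", "gain", "forest_persistence", "nonforest_persistence")
}

new_change_grid <- function(codes, cell_size, epochs) {
  structure(codes, cell_size = cell_size, epochs = epochs,
            class = c("change_grid", class(codes)))
}

#' @export
print.change_grid <- function(x, ...) {
  n <- change_counts(x)
  cat(sprintf("<change_grid %dx%d, %s -> %s: loss %d, gain %d, persistence %d/%d>\n",
              nrow(x), ncol(x),
              format(attr(x, "epochs")[1]), format(attr(x, "epochs")[2]),
              n["loss"], n["gain"], n["forest_persistence"],
              n["nonforest_persistence"]))
  invisible(x)
}

#' Count pixels per change category
#'
#' @param change a `change_grid` from [detect_change()].
#' @return named integer vector over [change_levels()].
#' @export
change_counts <- function(change) {
  out <- vapply(1:4, function(k) sum(change == k, na.rm = TRUE), integer(1))
  names(out) <- change_levels()
  out
}

## Run code under a temporary RNG state so generators do not clobber the
## caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(code)
}

stopifnot_same_shape <- function(...) {
  gs <- list(...)
  d <- dim(gs[[1]])
  for (g in gs[-1])
    if (!identical(dim(g), d))
      stop(sprintf("grids are not co-registered: %s vs %s",
                   paste(d, collapse = "x"), paste(dim(g), collapse = "x")))
  invisible(TRUE)
}
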