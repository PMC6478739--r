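## Spatial allocation: satisfy each country's net change demand by flipping
## the highest-potential eligible pixels, then mosaic countries back into a
## regional end-state map.

#' Build the 2x2 transition matrix for a net-change demand
#'
#' Expresses the demanded transition as proportions of the start-year class
#' totals: for a loss demand of d pixels out of F forest pixels, F->NF = d/F
#' and F->F = 1 - d/F (the non-forest row is the identity), and symmetrically
#' for gains. Exactly one off-diagonal entry is non-zero: a scenario is
#' net-gaining or net-losing, never both.
#'
#' @param demand_px demanded pixel count (>= 0).
#' @param direction `"loss"` or `"gain"`.
#' @param n_forest,n_nonforest start-year class totals in pixels.
#' @return 2x2 matrix with dimnames `from`/`to` in \{forest, nonforest\},
#'   rows summing to 1.
#' @export
build_transition_matrix <- function(demand_px, direction = c("loss", "gain"),
                                    n_forest, n_nonforest) {
  direction <- match.arg(direction)
  if (demand_px < 0) stop("`demand_px` must be >= 0")
  src <- if (direction == "loss") n_forest else n_nonforest
  if (src <= 0) stop("source class for the demanded transition is empty")
  if (demand_px > src)
    stop(sprintf("demand (%d px) exceeds the %s source class (%d px)",
                 demand_px, direction, src))
  p <- demand_px / src
  m <- diag(2)
  dimnames(m) <- list(from = c("forest", "nonforest"),
                      to = c("forest", "nonforest"))
  if (direction == "loss") {
    m["forest", "nonforest"] <- p
    m["forest", "forest"] <- 1 - p
  } else {
    m["nonforest", "forest"] <- p
    m["nonforest", "nonforest"] <- 1 - p
  }
  m
}

#' Allocate a change demand to the highest-potential pixels
#'
#' Greedy rank allocation: the demanded number of pixels is satisfied by
#' selecting eligible pixels in decreasing order of transition potential until
#' the demand is met. Eligibility is the source class of the transition minus
#' the exclusion mask (for gains, urban and water are always excluded: forest
#' never replaces built-up areas or water bodies). Ties at the cut are broken
#' by a seeded random key, so reruns are reproducible. If the eligible pool is
#' smaller than the demand the whole pool is flipped and the shortfall is
#' reported — demand is never silently dropped.
#'
#' @param tpm transition potential matrix in \[0, 1\] (`NA` = not eligible /
#'   outside the modelled area), e.g. the `tpm` of a [train_tpm()] model,
#'   possibly masked to one country.
#' @param fnf start-year [fnf_grid()].
#' @param demand_px demanded pixel count.
#' @param direction `"loss"` or `"gain"`.
#' @param exclusion optional logical matrix of pixels that must not change.
#' @param tie_seed seed for the tie-breaking key.
#' @return an `allocation_result`: list with `fnf_end`, `change`
#'   (a `change_grid` over the allocation's coverage), `selected` (indices),
#'   `demanded`, `realised`, `shortfall`, `cut_potential`, `coverage`
#'   (logical matrix of pixels this allocation owns).
#' @export
allocate <- function(tpm, fnf, demand_px, direction = c("loss", "gain"),
                     exclusion = NULL, tie_seed = 1) {
  direction <- match.arg(direction)
  stopifnot_same_shape(tpm, fnf)
  if (demand_px < 0) stop("`demand_px` must be >= 0")
  src_val <- if (direction == "loss") 1L else 0L
  eligible <- !is.na(tpm) & !is.na(fnf) & unclass(fnf) == src_val
  if (!is.null(exclusion)) {
    stopifnot_same_shape(tpm, exclusion)
    eligible <- eligible & !exclusion
  }
  pool <- which(eligible)
  k <- min(length(pool), demand_px)
  shortfall <- demand_px - k
  selected <- integer(0)
  cut <- NA_real_
  if (k > 0) {
    key <- with_seed(tie_seed, stats::runif(length(pool)))
    ord <- order(-tpm[pool], key)
    selected <- pool[ord[seq_len(k)]]
    cut <- tpm[selected[k]]
  }
  fnf_end <- unclass(fnf)
  fnf_end[selected] <- 1L - src_val
  coverage <- !is.na(tpm)
  change <- matrix(NA_integer_, nrow(fnf), ncol(fnf))
  keep <- coverage & !is.na(fnf)
  change[keep & unclass(fnf) == 1L] <- CHANGE_FOREST_PERSIST
  change[keep & unclass(fnf) == 0L] <- CHANGE_NONFOREST_PERSIST
  change[selected] <- if (direction == "loss") CHANGE_LOSS else CHANGE_GAIN
  structure(list(
    fnf_end = fnf_grid(fnf_end, cell_size = attr(fnf, "cell_size"),
                       epoch = "end"),
    change = new_change_grid(change, cell_size = attr(fnf, "cell_size"),
                             epochs = c(attr(fnf, "epoch") %||% NA, NA)),
    selected = selected, demanded = as.integer(demand_px),
    realised = as.integer(k), shortfall = as.integer(shortfall),
    cut_potential = cut, direction = direction, coverage = coverage,
    tie_seed = tie_seed
  ), class = "allocation_result")
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("<allocation (%s): demanded %d, realised %d, shortfall %d, cut %.4f>\n",
              x$direction, x$demanded, x$realised, x$shortfall,
              if (is.na(x$cut_potential)) NaN else x$cut_potential))
  invisible(x)
}

#' Mosaic per-country allocation results into a regional map
#'
#' Applies each country's selected change pixels to the shared start-year
#' map. Coverages must be disjoint; any overlap is an error. Totals are
#' additive: the regional change count is the sum of the country counts.
#'
#' @param fnf start-year regional [fnf_grid()].
#' @param results list of `allocation_result` objects with disjoint coverage.
#' @return list with `fnf_end` (regional end-state [fnf_grid()]), `change`
#'   (regional `change_grid`), and `log` (data.frame: one row per result with
#'   demanded/realised/shortfall/cut).
#' @export
mosaic <- function(fnf, results) {
  if (!length(results)) stop("no allocation results to mosaic")
  cover_sum <- Reduce(`+`, lapply(results, function(r) r$coverage * 1L))
  if (any(cover_sum > 1)) stop("allocation coverages overlap; cannot mosaic")
  fnf_end <- unclass(fnf)
  change <- matrix(NA_integer_, nrow(fnf), ncol(fnf))
  ok <- !is.na(fnf)
  change[ok & fnf_end == 1L] <- CHANGE_FOREST_PERSIST
  change[ok & fnf_end == 0L] <- CHANGE_NONFOREST_PERSIST
  for (r in results) {
    src_val <- if (r$direction == "loss") 1L else 0L
    fnf_end[r$selected] <- 1L - src_val
    change[r$selected] <- if (r$direction == "loss") CHANGE_LOSS else CHANGE_GAIN
  }
  log <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(unit = if (is.null(names(results))) as.character(i) else
                 names(results)[i],
               direction = r$direction, demanded = r$demanded,
               realised = r$realised, shortfall = r$shortfall,
               cut_potential = r$cut_potential, stringsAsFactors = FALSE)
  }))
  list(
    fnf_end = fnf_grid(fnf_end, cell_size = attr(fnf, "cell_size"),
                       epoch = "end"),
    change = new_change_grid(change, cell_size = attr(fnf, "cell_size"),
                             epochs = c(attr(fnf, "epoch") %||% NA, NA)),
    log = log
  )
}
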