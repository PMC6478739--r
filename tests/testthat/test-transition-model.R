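make_cal <- function(seed = 11) {
  b <- small_bundle()
  fnf0 <- reclassify_to_fnf(b$landcover[[1]], cell_size = b$cell_size)
  fnf1 <- reclassify_to_fnf(b$landcover[[2]], cell_size = b$cell_size)
  fnf2 <- reclassify_to_fnf(b$landcover[[3]], cell_size = b$cell_size)
  ch <- detect_change(fnf1, fnf2)
  # drivers from the previous period's change: predictors never encode the
  # transition being learned
  list(b = b, fnf2 = fnf2, ch = ch,
       elig = !is.na(ch) & ch == 3,  # forest persistence
       stack = build_driver_stack(b$elevation, b$road_mask, b$urban_mask,
                                  fnf1, detect_change(fnf0, fnf1),
                                  b$provinces, b$countries,
                                  "loss", b$cell_size))
}

test_that("balanced sampling plans are equal-sized, disjoint, split 50/50 and reproducible", {
  x <- make_cal()
  pl <- draw_samples(x$ch, x$elig, "loss", n_per_class = 60, seed = 4)
  expect_equal(length(pl$train_changed), 30)
  expect_equal(length(pl$test_changed), 30)
  expect_equal(length(pl$train_persist), 30)
  expect_equal(length(pl$test_persist), 30)
  expect_length(intersect(pl$train_changed, pl$test_changed), 0)
  expect_length(intersect(c(pl$train_changed, pl$test_changed),
                          c(pl$train_persist, pl$test_persist)), 0)
  expect_identical(pl, draw_samples(x$ch, x$elig, "loss", 60, seed = 4))
  expect_false(identical(pl$train_changed,
                         draw_samples(x$ch, x$elig, "loss", 60, seed = 5)$train_changed))
})

test_that("a sample request beyond the pool is clamped with a warning", {
  x <- make_cal()
  n_changed <- sum(x$ch == 1, na.rm = TRUE)
  expect_warning(pl <- draw_samples(x$ch, x$elig, "loss",
                                    n_per_class = n_changed + 500, seed = 1),
                 "reduced")
  expect_equal(pl$n_per_class, n_changed)
  expect_true(pl$clamped)
})

test_that("the skill measure is the chance-corrected affine map of accuracy", {
  expect_identical(skill_measure(1, 1, 1), 1)
  expect_identical(skill_measure(0.5, 1, 1), 0)
  expect_identical(skill_measure(0, 1, 1), -1)
  expect_equal(skill_measure(0.78, 1, 1), 0.56)
  # E(A) = 1/(T+P): chance-level accuracy maps to 0 for any class count
  for (tp in list(c(2, 1), c(3, 2), c(1, 4)))
    expect_equal(skill_measure(1 / sum(tp), tp[1], tp[2]), 0)
  expect_error(skill_measure(1.2, 1, 1), "A must")
  expect_error(skill_measure(0.5, 0, 1), ">= 1")
})

test_that("the network separates a threshold rule almost perfectly", {
  # changed iff dist_road below its median: a separable toy
  x <- make_cal()
  droad <- x$stack$dist_road
  forest <- which(!is.na(x$ch) & (x$ch == 1 | x$ch == 3))
  thr <- stats::median(droad[forest])
  truth <- matrix(NA_integer_, nrow(droad), ncol(droad))
  truth[forest] <- ifelse(droad[forest] < thr, 1L, 3L)
  ch2 <- detect_change(fnf_grid(matrix(1L, 64, 64)),
                       fnf_grid((truth != 1) * 1L))
  elig <- !is.na(truth)
  pl <- draw_samples(ch2, elig, "loss", n_per_class = 400, seed = 2)
  m <- train_tpm(pl, x$stack, seed = 2)
  expect_gte(m$validation$A, 0.95)
  expect_gte(m$validation$SM, 0.9)
})

test_that("predicted potentials are probabilities with a balanced prior", {
  x <- make_cal()
  pl <- draw_samples(x$ch, x$elig, "loss", seed = 6)
  m <- train_tpm(pl, x$stack, seed = 6)
  tpm <- predict(m)
  vals <- tpm[!is.na(tpm)]
  expect_true(all(vals >= 0 & vals <= 1))
  # mean potential over the balanced test set is consistent with prior 0.5
  expect_gte(m$mean_test_potential, 0.35)
  expect_lte(m$mean_test_potential, 0.65)
  # potential is defined exactly on the eligible pixels
  expect_equal(which(!is.na(tpm)), pl$eligible)
})

test_that("constant drivers are excluded with a warning", {
  x <- make_cal()
  st <- x$stack
  st$elevation <- matrix(5, 64, 64)
  pl <- draw_samples(x$ch, x$elig, "loss", n_per_class = 50, seed = 1)
  expect_warning(m <- train_tpm(pl, st, seed = 1), "elevation")
  expect_false("elevation" %in% m$drivers_used)
})

test_that("validation reports serialise to JSON with the statistic's inputs", {
  x <- make_cal()
  pl <- draw_samples(x$ch, x$elig, "loss", n_per_class = 50, seed = 3)
  m <- train_tpm(pl, x$stack, seed = 3)
  path <- tempfile(fileext = ".json")
  write_validation_report(m, path)
  rep_ <- jsonlite::read_json(path)
  expect_equal(rep_$T, 1)
  expect_equal(rep_$P, 1)
  expect_equal(rep_$SM, (rep_$A - 0.5) / 0.5, tolerance = 1e-12)
})
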